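#' Read and write radiograph-like images
#'
#' `readGrayImage()` loads a PNG or JPEG into a [GrayImage-class],
#' converting color inputs with the Rec. 601 luma transform
#' (0.299 R + 0.587 G + 0.114 B); `writeGrayImage()` writes one out.
#' File handling is delegated to EBImage.
#'
#' @param path file path (PNG or JPEG).
#' @return `readGrayImage()` a [GrayImage-class]; `writeGrayImage()` the
#'   path, invisibly.
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) ddhValidationStop(sprintf("no such file: %s", path))
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) {
    nch <- dim(d)[3]
    coef <- if (nch >= 3L) c(0.299, 0.587, 0.114) else rep(1 / nch, nch)
    g <- matrix(0, dim(d)[1], dim(d)[2])
    for (ch in seq_along(coef)) g <- g + coef[ch] * d[, , ch]
    d <- g
  }
  grayImage(round(pmin(pmax(t(d) * 255, 0), 255)))
}

#' @rdname readGrayImage
#' @param image a [GrayImage-class].
#' @export
writeGrayImage <- function(image, path) {
  EBImage::writeImage(EBImage::Image(t(image@pixels) / 255), path)
  invisible(path)
}

.ANNOTATION_SCHEMA_VERSION <- "1.0"

#' Read and write annotation files
#'
#' Annotation files are JSON objects with fields `schema_version`,
#' optional `patient` (`nationality`, `sex`, `age_years`), optional
#' `image` (path), and `landmarks`: a list of
#' `{label, side, x, y}` records with at most one record per
#' (label, side). Reading validates the schema and rejects duplicates;
#' write-then-read round-trips exactly.
#'
#' @param path file path.
#' @return `readAnnotations()` returns `list(schemaVersion, patient,
#'   imagePath, annotations)` (`patient`/`imagePath` `NULL` when absent);
#'   `writeAnnotations()` the path, invisibly.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) ddhValidationStop(sprintf("no such file: %s", path))
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    ddhValidationStop(sprintf("malformed JSON in %s: %s", path,
                                              conditionMessage(e))))
  if (is.null(obj$landmarks))
    ddhValidationStop(sprintf("%s: missing required field 'landmarks'", path))
  lm <- as.data.frame(obj$landmarks)
  for (f in c("label", "side", "x", "y"))
    if (is.null(lm[[f]]))
      ddhValidationStop(sprintf("%s: landmarks entries lack field '%s'",
                                path, f))
  ann <- tryCatch(annotationSet(lm), error = function(e)
    ddhValidationStop(sprintf("%s: %s", path, conditionMessage(e))))
  patient <- NULL
  if (!is.null(obj$patient)) {
    for (f in c("nationality", "sex", "age_years"))
      if (is.null(obj$patient[[f]]))
        ddhValidationStop(sprintf("%s: patient lacks field '%s'", path, f))
    patient <- tryCatch(
      patientInfo(obj$patient$nationality, obj$patient$sex,
                  obj$patient$age_years),
      error = function(e)
        ddhValidationStop(sprintf("%s: %s", path, conditionMessage(e))))
  }
  list(schemaVersion = if (is.null(obj$schema_version)) NA_character_
       else obj$schema_version,
       patient = patient,
       imagePath = if (is.null(obj$image)) NULL else obj$image,
       annotations = ann)
}

#' @rdname readAnnotations
#' @param annotations an [AnnotationSet-class].
#' @param patient optional [PatientInfo-class].
#' @param imagePath optional image path recorded in the file.
#' @export
writeAnnotations <- function(annotations, path, patient = NULL,
                             imagePath = NULL) {
  obj <- list(schema_version = .ANNOTATION_SCHEMA_VERSION)
  if (!is.null(patient))
    obj$patient <- list(nationality = patient@nationality, sex = patient@sex,
                        age_years = patient@ageYears)
  if (!is.null(imagePath)) obj$image <- imagePath
  obj$landmarks <- landmarks(annotations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read and write criteria tables
#'
#' The clinician-editable format is a TSV with header
#' `nationality sex side age_min age_max mean_deg sd_deg`; an equivalent
#' JSON array of objects is accepted by extension `.json`. All
#' [CriteriaTable-class] invariants (positive sd, ordered half-open age
#' brackets, no overlapping brackets within a stratum) are checked at
#' load and violations reported with their line number.
#'
#' @param path file path (`.tsv`/`.txt` or `.json`).
#' @param sourceLabel provenance label attached to the table.
#' @return `readCriteria()` a [CriteriaTable-class];
#'   `writeCriteria()` the path, invisibly.
#' @export
readCriteria <- function(path, sourceLabel = basename(path)) {
  if (!file.exists(path)) ddhValidationStop(sprintf("no such file: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    e <- tryCatch(as.data.frame(jsonlite::fromJSON(path)),
                  error = function(err)
                    ddhValidationStop(sprintf("malformed JSON in %s: %s", path,
                                              conditionMessage(err))))
  } else {
    e <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  tryCatch(criteriaTable(e, sourceLabel = sourceLabel),
           error = function(err)
             ddhValidationStop(sprintf(
               "%s: %s (row numbers refer to data rows; add 1 for the header line)",
               path, conditionMessage(err))))
}

#' @rdname readCriteria
#' @param table a [CriteriaTable-class].
#' @export
writeCriteria <- function(table, path) {
  utils::write.table(criteriaEntries(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.configToList <- function(config) {
  list(windowSize = config@windowSize, gaussianKernel = config@gaussianKernel,
       gaussianSigma = config@gaussianSigma,
       adaptiveBlock = config@adaptiveBlock,
       adaptiveOffset = config@adaptiveOffset,
       maxSnapDistance = config@maxSnapDistance,
       enabledLabels = config@enabledLabels)
}

#' Read a refinement configuration from JSON
#'
#' A flat JSON object whose keys mirror the [RefinementConfig-class]
#' fields; absent keys keep their defaults.
#'
#' @param path JSON file path.
#' @return a [RefinementConfig-class].
#' @export
readRefinementConfig <- function(path) {
  if (!file.exists(path)) ddhValidationStop(sprintf("no such file: %s", path))
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e)
                    ddhValidationStop(sprintf("malformed JSON in %s: %s", path,
                                              conditionMessage(e))))
  args <- formals(refinementConfig)
  known <- names(args)
  bad <- setdiff(names(obj), known)
  if (length(bad))
    ddhValidationStop(sprintf("%s: unknown config key '%s'", path, bad[1]))
  tryCatch(do.call(refinementConfig, obj),
           error = function(e)
             ddhValidationStop(sprintf("%s: %s", path, conditionMessage(e))))
}

#' Serialize a study report
#'
#' `reportToList()` flattens a [StudyReport-class] (plus the
#' configuration echo and input checksums) into plain lists;
#' `writeReport()` writes it as JSON with full float precision, so
#' re-running the tool on the echoed inputs reproduces the file
#' byte-exactly. `readReport()` parses such a file back into lists.
#'
#' @param report a [StudyReport-class].
#' @param config optional [RefinementConfig-class] echoed into the
#'   report.
#' @param inputs character vector of input file paths; their MD5
#'   checksums are recorded.
#' @return `reportToList()` a nested list; `writeReport()` the path,
#'   invisibly; `readReport()` the parsed list.
#' @export
reportToList <- function(report, config = NULL, inputs = character()) {
  hips <- lapply(report@hips, function(h) {
    d <- h$diagnosis
    list(ai_deg = aiDeg(h$parameters),
         lcea_deg = if (is.na(lceaDeg(h$parameters))) NULL
         else lceaDeg(h$parameters),
         head_center_source = headCenterSource(h$parameters),
         ihdi_grade = h$grade,
         diagnosis = list(category = d@category,
                          ihdi = if (is.na(d@ihdi)) NULL else d@ihdi,
                          ai_deg = d@aiDeg, threshold_deg = d@thresholdDeg,
                          criteria_source = d@criteriaSource),
         warnings = c(h$parameters@warnings, d@warnings))
  })
  checksums <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else NULL
  list(tool = "DDHdx",
       version = as.character(utils::packageVersion("DDHdx")),
       patient = list(nationality = report@patient@nationality,
                      sex = report@patient@sex,
                      age_years = report@patient@ageYears),
       annotations = landmarks(report@annotations),
       hips = hips,
       refinement = report@refinement,
       warnings = report@warnings,
       config = if (is.null(config)) NULL else .configToList(config),
       input_checksums = checksums)
}

#' @rdname reportToList
#' @param path output path.
#' @export
writeReport <- function(report, path, config = NULL, inputs = character()) {
  jsonlite::write_json(reportToList(report, config, inputs), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname reportToList
#' @export
readReport <- function(path) {
  if (!file.exists(path)) ddhValidationStop(sprintf("no such file: %s", path))
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Plain-text summary of a study report
#'
#' @param report a [StudyReport-class].
#' @return a character vector of aligned summary lines.
#' @export
formatReport <- function(report) {
  lines <- c(sprintf("Patient: %s %s, age %.2f y", report@patient@nationality,
                     report@patient@sex, report@patient@ageYears))
  for (side in .SIDES) {
    h <- report@hips[[side]]
    if (is.null(h)) next
    d <- h$diagnosis
    lines <- c(lines, sprintf(
      "%-5s hip: AI %6.2f deg  LCEA %6s  IHDI %d  threshold %5.2f  -> %s%s",
      side, aiDeg(h$parameters),
      if (is.na(lceaDeg(h$parameters))) "NA"
      else sprintf("%.2f", lceaDeg(h$parameters)),
      h$grade, thresholdDeg(d), diagnosisCategory(d),
      if (!is.na(ihdiGrade(d))) sprintf(" (IHDI %d)", ihdiGrade(d)) else ""))
  }
  if (length(report@warnings))
    lines <- c(lines, paste("warning:", report@warnings))
  lines
}
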