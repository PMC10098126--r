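#' Select the diagnostic criteria stratum for a patient
#'
#' Finds the unique [CriteriaTable-class] row matching the patient's
#' nationality and sex, the requested side, and the half-open age bracket
#' `[age_min, age_max)` containing the patient's age. A side-specific row
#' (`left`/`right`) takes precedence over an `either` row for the same
#' stratum.
#'
#' @param table a validated [CriteriaTable-class].
#' @param patient a [PatientInfo-class].
#' @param side `"left"` or `"right"`.
#' @return the matching entry as a one-row data.frame.
#' @examples
#' tab <- criteriaTable(data.frame(
#'   nationality = "chinese", sex = "female", side = "either",
#'   age_min = 1, age_max = 2, mean_deg = 23, sd_deg = 4))
#' lookupCriteria(tab, patientInfo("chinese", "female", 1.4), "left")
#' @export
lookupCriteria <- function(table, patient, side) {
  e <- criteriaEntries(table)
  base <- e$nationality == patient@nationality & e$sex == patient@sex &
    e$age_min <= patient@ageYears & patient@ageYears < e$age_max
  hit <- which(base & e$side == side)
  if (length(hit) == 0L) hit <- which(base & e$side == "either")
  if (length(hit) == 0L)
    ddhValidationStop(sprintf(
      "no criteria bracket covers a %s %s aged %.2f years (side %s)",
      patient@nationality, patient@sex, patient@ageYears, side))
  e[hit[1], , drop = FALSE]
}

#' Diagnose one hip from its AI and IHDI grade
#'
#' Applies the built-in decision rule: the hip is DDH when its acetabular
#' index strictly exceeds the stratum threshold `mean + 2 sd` (carrying
#' the IHDI grade as severity); otherwise it is an "other dislocation"
#' when displaced (IHDI grade >= `dislocatedGrade`, default 2, i.e. the
#' H-point lies lateral to Perkin's line) and normal when located.
#' Equality with the threshold counts as normal; results within 0.5
#' degrees of the threshold carry a borderline warning either way.
#'
#' @param aiDeg measured acetabular index, degrees.
#' @param grade IHDI grade, integer 1..4.
#' @param entry a criteria entry as returned by [lookupCriteria()].
#' @param criteriaSource provenance label recorded in the diagnosis.
#' @param dislocatedGrade smallest IHDI grade regarded as dislocated for
#'   the normal / other-dislocation split.
#' @return a [HipDiagnosis-class].
#' @examples
#' entry <- data.frame(mean_deg = 23, sd_deg = 4)
#' diagnoseHip(32, 1L, entry)   # ddh, IHDI 1 (threshold 31)
#' diagnoseHip(30, 3L, entry)   # other_dislocation
#' @export
diagnoseHip <- function(aiDeg, grade, entry, criteriaSource = "unspecified",
                        dislocatedGrade = 2L) {
  grade <- as.integer(grade)
  if (!grade %in% 1:4) ddhValidationStop("grade must be an integer in 1..4")
  threshold <- entry$mean_deg + 2 * entry$sd_deg
  warnings <- character(0)
  if (abs(aiDeg - threshold) <= 0.5)
    warnings <- sprintf("borderline AI: %.2f deg within 0.5 deg of threshold %.2f",
                        aiDeg, threshold)
  if (aiDeg > threshold) {
    category <- "ddh"; ihdi <- grade
  } else if (grade >= dislocatedGrade) {
    category <- "other_dislocation"; ihdi <- NA_integer_
  } else {
    category <- "normal"; ihdi <- NA_integer_
  }
  new("HipDiagnosis", category = category, ihdi = ihdi, aiDeg = aiDeg,
      thresholdDeg = threshold, criteriaSource = criteriaSource,
      warnings = warnings)
}

#' Run the full diagnostic pipeline on one study
#'
#' Orchestrates the three-step workflow on one annotated radiograph: when
#' an image is supplied, eligible landmarks are first snapped onto the
#' bony rim ([refineAnnotations()]); the reference geometry is then built
#' and AI, LCEA and the IHDI grade measured per hip
#' ([buildReferenceGeometry()], [measureHip()], [classifyIhdi()]);
#' finally the patient-matched criteria are looked up and the per-hip
#' diagnosis made ([lookupCriteria()], [diagnoseHip()]). The report keeps
#' every intermediate value, so each diagnosis is reproducible from its
#' recorded inputs. The whole computation is deterministic.
#'
#' @param annotations a complete (8-landmark) [AnnotationSet-class].
#' @param patient a [PatientInfo-class].
#' @param table a [CriteriaTable-class].
#' @param image optional [GrayImage-class]; when omitted the annotations
#'   are measured as given.
#' @param config a [RefinementConfig-class] used when `image` is given.
#' @param headCenter optional named list (`left`, `right`) of explicit
#'   femoral-head centers for LCEA.
#' @param dislocatedGrade passed to [diagnoseHip()].
#' @return a [StudyReport-class].
#' @export
diagnoseStudy <- function(annotations, patient, table, image = NULL,
                          config = refinementConfig(),
                          headCenter = list(left = NULL, right = NULL),
                          dislocatedGrade = 2L) {
  if (length(annotations) != 8L)
    ddhValidationStop("a full study requires all 8 landmarks")
  statuses <- list()
  if (!is.null(image)) {
    ref <- refineAnnotations(image, annotations, config)
    annotations <- ref$annotations
    statuses <- ref$statuses
  }
  geometry <- buildReferenceGeometry(annotations)
  warnings <- if (ageWarning(patient))
    sprintf("age %.2f years outside the 0.4-8.0 range the criteria cover",
            patient@ageYears) else character(0)
  hips <- list()
  for (side in .SIDES) {
    params <- measureHip(geometry, annotations, side, headCenter[[side]])
    grade <- classifyIhdi(geometry, side)
    entry <- tryCatch(lookupCriteria(table, patient, side),
                      ddhValidationError = function(e)
                        ddhValidationStop(sprintf("side %s: %s", side,
                                                  conditionMessage(e))))
    diag <- diagnoseHip(aiDeg(params), grade, entry,
                        criteriaSource = criteriaSource(table),
                        dislocatedGrade = dislocatedGrade)
    hips[[side]] <- list(parameters = params, grade = grade, diagnosis = diag)
    warnings <- c(warnings, params@warnings, diag@warnings)
  }
  new("StudyReport", patient = patient, annotations = annotations,
      hips = hips, refinement = statuses, warnings = warnings)
}
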