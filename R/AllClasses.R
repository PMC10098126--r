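#' @import methods
NULL

## controlled vocabularies used throughout -------------------------------

.LANDMARK_LABELS <- c("lateral_acetabular_edge", "triradiate_top",
                      "metaphysis_inner", "metaphysis_outer")
.SIDES <- c("left", "right")
.NATIONALITIES <- c("chinese", "other")
.SEXES <- c("female", "male")
.DIAGNOSIS_CATEGORIES <- c("normal", "other_dislocation", "ddh")

#' Landmark vocabulary
#'
#' The four anatomical key-point labels annotated on each hip of an
#' anteroposterior pelvic radiograph, and the two sides. Together they form
#' the 8 landmarks a full study requires: the lateral acetabular edge, the
#' top of the triradiate cartilage, and the inner and outer points of the
#' proximal femoral metaphysis, bilaterally.
#'
#' @return `landmarkLabels()` returns the four label strings;
#'   `hipSides()` returns `c("left", "right")`.
#' @examples
#' landmarkLabels()
#' hipSides()
#' @export
landmarkLabels <- function() .LANDMARK_LABELS

#' @rdname landmarkLabels
#' @export
hipSides <- function() .SIDES

## GrayImage --------------------------------------------------------------

#' 8-bit grayscale image
#'
#' A minimal carrier for radiograph-like images. Pixels are stored as a
#' numeric matrix with rows indexed by the image row (y, increasing
#' downward) and columns by the image column (x, increasing rightward);
#' all coordinates exposed by the package are 0-based, so pixel (x, y)
#' lives at `imagePixels(img)[y + 1, x + 1]`.
#'
#' @slot pixels numeric matrix of intensities in [0, 255].
#' @export
setClass("GrayImage", representation(pixels = "matrix"))

setValidity("GrayImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p) || length(p) == 0L)
    return("pixels must be a non-empty numeric matrix")
  if (anyNA(p) || any(!is.finite(p)))
    return("pixel intensities must be finite")
  if (min(p) < 0 || max(p) > 255)
    return("pixel intensities must lie in [0, 255]")
  TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric matrix (rows = y, columns = x) of intensities in
#'   [0, 255].
#' @return a [GrayImage-class] object.
#' @examples
#' img <- grayImage(matrix(0, 10, 20))
#' dim(img)   # height 10, width 20
#' @export
grayImage <- function(pixels) {
  new("GrayImage", pixels = pixels)
}

#' @describeIn grayImage image dimensions as `c(height, width)`.
#' @param x a GrayImage.
#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @describeIn grayImage the pixel matrix.
#' @param image a GrayImage.
#' @export
imagePixels <- function(image) image@pixels

#' @describeIn grayImage image width in pixels.
#' @export
imageWidth <- function(image) ncol(image@pixels)

#' @describeIn grayImage image height in pixels.
#' @export
imageHeight <- function(image) nrow(image@pixels)

#' @export
setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage %d x %d px, intensities [%g, %g]\n",
              imageWidth(object), imageHeight(object),
              min(object@pixels), max(object@pixels)))
})

## AnnotationSet ----------------------------------------------------------

#' Annotated anatomical key points
#'
#' Holds the clicked key points of a study in pixel coordinates, keyed by
#' landmark label and side. A full study carries all 8 (label, side)
#' combinations; partial sets are permitted for intermediate work.
#' Coordinates are continuous: integer pixel clicks are promoted to real
#' values once measurement begins.
#'
#' @slot points data.frame with columns `label`, `side`, `x`, `y`.
#' @export
setClass("AnnotationSet", representation(points = "data.frame"))

setValidity("AnnotationSet", function(object) {
  p <- object@points
  need <- c("label", "side", "x", "y")
  if (!all(need %in% names(p)))
    return(sprintf("points must have columns %s", paste(need, collapse = ", ")))
  if (!all(p$label %in% .LANDMARK_LABELS))
    return("unknown landmark label")
  if (!all(p$side %in% .SIDES))
    return("side must be 'left' or 'right'")
  if (anyDuplicated(paste(p$side, p$label)))
    return("duplicate (label, side) combination")
  if (!is.numeric(p$x) || !is.numeric(p$y) || anyNA(p$x) || anyNA(p$y) ||
      any(!is.finite(p$x)) || any(!is.finite(p$y)))
    return("coordinates must be finite numbers")
  TRUE
})

#' Construct an AnnotationSet
#'
#' @param label,side,x,y parallel vectors describing one landmark per
#'   element, or `label` may be a data.frame already holding the four
#'   columns.
#' @return an [AnnotationSet-class].
#' @examples
#' ann <- annotationSet(
#'   label = rep(c("triradiate_top", "lateral_acetabular_edge"), 2),
#'   side  = rep(c("left", "right"), each = 2),
#'   x = c(300, 340, 100, 60), y = c(200, 180, 200, 182))
#' getPoint(ann, "triradiate_top", "left")
#' @export
annotationSet <- function(label, side = NULL, x = NULL, y = NULL) {
  if (is.data.frame(label)) {
    df <- label[, c("label", "side", "x", "y")]
  } else {
    df <- data.frame(label = as.character(label), side = as.character(side),
                     x = as.numeric(x), y = as.numeric(y),
                     stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  new("AnnotationSet", points = df)
}

#' @describeIn annotationSet the landmark table (label, side, x, y).
#' @param annotations an AnnotationSet.
#' @export
landmarks <- function(annotations) annotations@points

#' @describeIn annotationSet coordinates `c(x, y)` of one landmark, or
#'   `NULL` when absent.
#' @param annotations an AnnotationSet.
#' @export
getPoint <- function(annotations, label, side) {
  p <- annotations@points
  i <- which(p$label == label & p$side == side)
  if (length(i) == 0L) return(NULL)
  c(x = p$x[i], y = p$y[i])
}

#' @describeIn annotationSet replace (or add) one landmark; returns the
#'   modified set.
#' @param point numeric `c(x, y)`.
#' @export
setPoint <- function(annotations, label, side, point) {
  p <- annotations@points
  i <- which(p$label == label & p$side == side)
  if (length(i) == 0L) {
    p <- rbind(p, data.frame(label = label, side = side,
                             x = point[[1]], y = point[[2]]))
  } else {
    p$x[i] <- point[[1]]
    p$y[i] <- point[[2]]
  }
  annotationSet(p)
}

#' @describeIn annotationSet number of landmarks present.
#' @export
setMethod("length", "AnnotationSet", function(x) nrow(x@points))

#' @export
setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet with %d of 8 landmarks\n", nrow(object@points)))
  print(object@points, row.names = FALSE)
})

## RefinementConfig -------------------------------------------------------

#' Landmark-refinement settings
#'
#' Parameters of the edge-snapping step: the analysis window intercepted
#' around an annotated point, the Gaussian pre-filter, the local-mean
#' adaptive threshold used to separate radiodense bone from background,
#' and a guard distance beyond which no snap is accepted.
#'
#' @slot windowSize side of the square analysis window, pixels.
#' @slot gaussianKernel odd Gaussian kernel size, pixels.
#' @slot gaussianSigma Gaussian standard deviation, pixels.
#' @slot adaptiveBlock odd local-mean block size, pixels.
#' @slot adaptiveOffset threshold offset above the local mean, intensity
#'   units.
#' @slot maxSnapDistance largest accepted snap, pixels.
#' @slot enabledLabels landmark labels eligible for refinement.
#' @export
setClass("RefinementConfig",
         representation(windowSize = "numeric", gaussianKernel = "numeric",
                        gaussianSigma = "numeric", adaptiveBlock = "numeric",
                        adaptiveOffset = "numeric", maxSnapDistance = "numeric",
                        enabledLabels = "character"))

setValidity("RefinementConfig", function(object) {
  if (object@windowSize < 3) return("windowSize must be >= 3")
  for (s in c("gaussianKernel", "adaptiveBlock")) {
    v <- slot(object, s)
    if (v < 3 || v %% 2 != 1) return(sprintf("%s must be odd and >= 3", s))
  }
  if (object@gaussianSigma <= 0) return("gaussianSigma must be > 0")
  if (object@maxSnapDistance <= 0) return("maxSnapDistance must be > 0")
  if (!all(object@enabledLabels %in% .LANDMARK_LABELS))
    return("enabledLabels contains an unknown label")
  TRUE
})

#' Construct a RefinementConfig
#'
#' Defaults follow the 30 x 30 pixel analysis window with a small Gaussian
#' pre-filter and an 11-pixel local-mean threshold; all eight landmark
#' labels are eligible for snapping, guarded by `maxSnapDistance`.
#'
#' @param windowSize,gaussianKernel,gaussianSigma,adaptiveBlock,adaptiveOffset,maxSnapDistance
#'   see [RefinementConfig-class].
#' @param enabledLabels labels to refine; default all four.
#' @return a [RefinementConfig-class].
#' @export
refinementConfig <- function(windowSize = 30, gaussianKernel = 5,
                             gaussianSigma = 1.0, adaptiveBlock = 11,
                             adaptiveOffset = 2, maxSnapDistance = 15,
                             enabledLabels = landmarkLabels()) {
  new("RefinementConfig", windowSize = windowSize,
      gaussianKernel = gaussianKernel, gaussianSigma = gaussianSigma,
      adaptiveBlock = adaptiveBlock, adaptiveOffset = adaptiveOffset,
      maxSnapDistance = maxSnapDistance, enabledLabels = enabledLabels)
}

## PatientInfo ------------------------------------------------------------

#' Patient metadata used to select diagnostic criteria
#'
#' @slot nationality `"chinese"` or `"other"` (selects between the two
#'   families of published normal-AI criteria).
#' @slot sex `"female"` or `"male"`.
#' @slot ageYears age in decimal years; values outside [0.4, 8.0] carry a
#'   warning flag (see [ageWarning()]).
#' @export
setClass("PatientInfo",
         representation(nationality = "character", sex = "character",
                        ageYears = "numeric"))

setValidity("PatientInfo", function(object) {
  if (!object@nationality %in% .NATIONALITIES)
    return("nationality must be 'chinese' or 'other'")
  if (!object@sex %in% .SEXES) return("sex must be 'female' or 'male'")
  if (!is.finite(object@ageYears) || object@ageYears <= 0)
    return("ageYears must be a positive number")
  TRUE
})

#' Construct a PatientInfo
#' @param nationality,sex,ageYears see [PatientInfo-class].
#' @return a [PatientInfo-class].
#' @examples
#' p <- patientInfo("chinese", "female", 1.4)
#' ageWarning(p)
#' @export
patientInfo <- function(nationality, sex, ageYears) {
  new("PatientInfo", nationality = nationality, sex = sex,
      ageYears = as.numeric(ageYears))
}

#' @describeIn patientInfo `TRUE` when the age falls outside the 0.4-8.0
#'   year range the AI criteria are intended for.
#' @param patient a PatientInfo.
#' @export
ageWarning <- function(patient) {
  patient@ageYears < 0.4 || patient@ageYears > 8.0
}

#' @export
setMethod("show", "PatientInfo", function(object) {
  cat(sprintf("PatientInfo: %s %s, %.2f years%s\n", object@nationality,
              object@sex, object@ageYears,
              if (ageWarning(object)) " [outside 0.4-8.0 y]" else ""))
})

## CriteriaTable ----------------------------------------------------------

#' Stratified normal acetabular-index criteria
#'
#' Rows give the normal-AI mean and standard deviation for a stratum of
#' nationality, sex, side and half-open age bracket `[age_min, age_max)`.
#' A hip is dysplastic when its AI exceeds `mean_deg + 2 * sd_deg` for the
#' matching stratum. The package ships a synthetic transcription template
#' (`system.file("extdata", "criteria_synthetic_template.tsv", package =
#' "DDHdx")`); numeric values for clinical use must be transcribed from
#' the published normal-range references.
#'
#' @slot entries data.frame with columns `nationality`, `sex`, `side`
#'   (`left`, `right` or `either`), `age_min`, `age_max`, `mean_deg`,
#'   `sd_deg`.
#' @slot sourceLabel free-text provenance of the numbers.
#' @export
setClass("CriteriaTable",
         representation(entries = "data.frame", sourceLabel = "character"))

setValidity("CriteriaTable", function(object) {
  e <- object@entries
  need <- c("nationality", "sex", "side", "age_min", "age_max",
            "mean_deg", "sd_deg")
  if (!all(need %in% names(e)))
    return(sprintf("entries must have columns %s", paste(need, collapse = ", ")))
  if (!all(e$nationality %in% .NATIONALITIES)) return("bad nationality value")
  if (!all(e$sex %in% .SEXES)) return("bad sex value")
  if (!all(e$side %in% c(.SIDES, "either"))) return("bad side value")
  if (any(e$sd_deg <= 0)) {
    i <- which(e$sd_deg <= 0)[1]
    return(sprintf("sd_deg must be > 0 (row %d)", i))
  }
  if (any(e$age_min >= e$age_max)) {
    i <- which(e$age_min >= e$age_max)[1]
    return(sprintf("age_min must be < age_max (row %d)", i))
  }
  # non-overlapping brackets within each (nationality, sex, side) stratum
  key <- paste(e$nationality, e$sex, e$side)
  for (k in unique(key)) {
    idx <- which(key == k)
    o <- idx[order(e$age_min[idx])]
    if (length(o) > 1L) {
      bad <- which(e$age_min[o][-1] < e$age_max[o][-length(o)])
      if (length(bad) > 0L)
        return(sprintf("overlapping age brackets in stratum '%s' (rows %d and %d)",
                       k, o[bad[1]], o[bad[1] + 1L]))
    }
  }
  TRUE
})

#' Construct a CriteriaTable
#' @param entries data.frame, see [CriteriaTable-class].
#' @param sourceLabel provenance text.
#' @return a [CriteriaTable-class].
#' @export
criteriaTable <- function(entries, sourceLabel = "unspecified") {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  new("CriteriaTable", entries = entries, sourceLabel = sourceLabel)
}

#' @describeIn criteriaTable the criteria rows.
#' @param table a CriteriaTable.
#' @export
criteriaEntries <- function(table) table@entries

#' @describeIn criteriaTable the provenance label.
#' @export
criteriaSource <- function(table) table@sourceLabel

#' @export
setMethod("show", "CriteriaTable", function(object) {
  cat(sprintf("CriteriaTable: %d strata (source: %s)\n",
              nrow(object@entries), object@sourceLabel))
  print(utils::head(object@entries, 8), row.names = FALSE)
})

## HipParameters / HipDiagnosis / StudyReport -----------------------------

#' Measured hip parameters
#'
#' @slot aiDeg acetabular index, signed degrees (positive when the lateral
#'   acetabular edge lies superior to Hilgenreiner's line).
#' @slot lceaDeg lateral center-edge angle, signed degrees (positive when
#'   the edge lies lateral to the vertical through the head center), or
#'   `NA` when not measured.
#' @slot headCenterSource `"explicit"` when a femoral-head center was
#'   supplied, `"h_point_proxy"` when the metaphysis midpoint stood in.
#' @slot warnings out-of-convention geometry warnings.
#' @export
setClass("HipParameters",
         representation(aiDeg = "numeric", lceaDeg = "numeric",
                        headCenterSource = "character", warnings = "character"))

setValidity("HipParameters", function(object) {
  if (!is.na(object@aiDeg) && (object@aiDeg <= -90 || object@aiDeg >= 90))
    return("aiDeg must lie in (-90, 90)")
  if (!is.na(object@lceaDeg) && (object@lceaDeg <= -90 || object@lceaDeg >= 90))
    return("lceaDeg must lie in (-90, 90)")
  if (!object@headCenterSource %in% c("explicit", "h_point_proxy", "none"))
    return("bad headCenterSource")
  TRUE
})

#' @describeIn measureHip acetabular index in degrees.
#' @param parameters a HipParameters.
#' @export
aiDeg <- function(parameters) parameters@aiDeg

#' @describeIn measureHip lateral center-edge angle in degrees (`NA` when
#'   absent).
#' @export
lceaDeg <- function(parameters) parameters@lceaDeg

#' @describeIn measureHip provenance of the head center used for LCEA.
#' @export
headCenterSource <- function(parameters) parameters@headCenterSource

#' @export
setMethod("show", "HipParameters", function(object) {
  cat(sprintf("HipParameters: AI %.2f deg, LCEA %s deg (%s)%s\n",
              object@aiDeg,
              if (is.na(object@lceaDeg)) "NA" else sprintf("%.2f", object@lceaDeg),
              object@headCenterSource,
              if (length(object@warnings)) paste0(" [", paste(object@warnings,
                                                  collapse = "; "), "]") else ""))
})

#' Per-hip diagnosis
#'
#' @slot category `"normal"`, `"other_dislocation"` or `"ddh"`.
#' @slot ihdi IHDI grade 1-4; present (non-`NA`) iff category is `"ddh"`.
#' @slot aiDeg the AI the decision was made on, degrees.
#' @slot thresholdDeg the `mean + 2 sd` threshold applied, degrees.
#' @slot criteriaSource provenance label of the criteria table used.
#' @slot warnings e.g. borderline proximity to the threshold.
#' @export
setClass("HipDiagnosis",
         representation(category = "character", ihdi = "integer",
                        aiDeg = "numeric", thresholdDeg = "numeric",
                        criteriaSource = "character", warnings = "character"))

setValidity("HipDiagnosis", function(object) {
  if (!object@category %in% .DIAGNOSIS_CATEGORIES) return("bad category")
  if (!is.na(object@ihdi) && !object@ihdi %in% 1:4)
    return("ihdi must be in 1..4")
  if ((object@category == "ddh") != !is.na(object@ihdi))
    return("ihdi grade must be present iff category is 'ddh'")
  if ((object@category == "ddh") != (object@aiDeg > object@thresholdDeg))
    return("category 'ddh' must correspond exactly to aiDeg > thresholdDeg")
  TRUE
})

#' @describeIn diagnoseHip the diagnosis category.
#' @param diagnosis a HipDiagnosis.
#' @export
diagnosisCategory <- function(diagnosis) diagnosis@category

#' @describeIn diagnoseHip the IHDI grade (`NA` unless DDH).
#' @export
ihdiGrade <- function(diagnosis) diagnosis@ihdi

#' @describeIn diagnoseHip the AI threshold (mean + 2 sd) applied, degrees.
#' @export
thresholdDeg <- function(diagnosis) diagnosis@thresholdDeg

#' @export
setMethod("show", "HipDiagnosis", function(object) {
  cat(sprintf("HipDiagnosis: %s%s (AI %.2f vs threshold %.2f deg)%s\n",
              object@category,
              if (!is.na(object@ihdi)) sprintf(" IHDI %d", object@ihdi) else "",
              object@aiDeg, object@thresholdDeg,
              if (length(object@warnings)) paste0(" [", paste(object@warnings,
                                                  collapse = "; "), "]") else ""))
})

#' Full study report
#'
#' Everything [diagnoseStudy()] computed: the final annotations, the
#' per-hip parameters, IHDI grades and diagnoses, the refinement statuses
#' when an image was supplied, and accumulated warnings. Each diagnosis is
#' reproducible from the recorded intermediates.
#'
#' @slot patient the [PatientInfo-class] echo.
#' @slot annotations the (possibly refined) [AnnotationSet-class] used.
#' @slot hips named list (`left`, `right`) of
#'   `list(parameters, grade, diagnosis)`.
#' @slot refinement named list of per-landmark refinement statuses, or
#'   empty when no image was supplied.
#' @slot warnings study-level warnings.
#' @export
setClass("StudyReport",
         representation(patient = "PatientInfo", annotations = "AnnotationSet",
                        hips = "list", refinement = "list",
                        warnings = "character"))

#' @describeIn diagnoseStudy per-side results:
#'   `list(parameters, grade, diagnosis)`.
#' @param report a StudyReport.
#' @param side `"left"` or `"right"`.
#' @export
hipResult <- function(report, side) report@hips[[side]]

#' @describeIn diagnoseStudy the annotations the measurements used.
#' @export
reportAnnotations <- function(report) report@annotations

#' @describeIn diagnoseStudy per-landmark refinement statuses (empty list
#'   when no image was supplied).
#' @export
refinementStatuses <- function(report) report@refinement

#' @export
setMethod("show", "StudyReport", function(object) {
  cat("StudyReport\n")
  show(object@patient)
  for (s in .SIDES) {
    h <- object@hips[[s]]
    if (is.null(h)) { cat(sprintf("  %s: not evaluated\n", s)); next }
    cat(sprintf("  %s: AI %.2f deg, LCEA %s, IHDI %d -> %s%s\n", s,
                aiDeg(h$parameters),
                if (is.na(lceaDeg(h$parameters))) "NA"
                else sprintf("%.2f deg", lceaDeg(h$parameters)),
                h$grade, diagnosisCategory(h$diagnosis),
                if (!is.na(ihdiGrade(h$diagnosis)))
                  sprintf(" (grade %d)", ihdiGrade(h$diagnosis)) else ""))
  }
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

## Phantom specs ----------------------------------------------------------

#' Parametric specification of one phantom hip
#'
#' @slot aiDeg acetabular index the rendered roof realizes, degrees.
#' @slot hPointOffset numeric `c(u, v)`: H-point position relative to the
#'   Perkin-Hilgenreiner junction in the side's lateral (u) / superior (v)
#'   frame, pixels. `(negative u, negative v)` is a located hip.
#' @slot roofLength acetabular-roof length from triradiate top to lateral
#'   edge, pixels.
#' @slot metaphysisWidth distance between inner and outer metaphysis
#'   points, pixels.
#' @slot headRadius femoral-head circle radius in pixels, or `NA` to omit
#'   (ossific nucleus not yet visible).
#' @export
setClass("PhantomHipSpec",
         representation(aiDeg = "numeric", hPointOffset = "numeric",
                        roofLength = "numeric", metaphysisWidth = "numeric",
                        headRadius = "numeric"))

setValidity("PhantomHipSpec", function(object) {
  if (object@roofLength <= 0) return("roofLength must be > 0")
  if (object@metaphysisWidth <= 0) return("metaphysisWidth must be > 0")
  if (length(object@hPointOffset) != 2L || anyNA(object@hPointOffset))
    return("hPointOffset must be numeric c(u, v)")
  if (abs(object@aiDeg) >= 90) return("aiDeg must lie in (-90, 90)")
  TRUE
})

#' @rdname makePhantom
#' @param aiDeg,hPointOffset,roofLength,metaphysisWidth,headRadius see
#'   [PhantomHipSpec-class].
#' @export
phantomHipSpec <- function(aiDeg = 25, hPointOffset = c(-15, -40),
                           roofLength = 110, metaphysisWidth = 36,
                           headRadius = NA_real_) {
  new("PhantomHipSpec", aiDeg = aiDeg, hPointOffset = as.numeric(hPointOffset),
      roofLength = roofLength, metaphysisWidth = metaphysisWidth,
      headRadius = headRadius)
}

#' Parametric specification of a pelvis phantom
#'
#' @slot width,height image size, pixels.
#' @slot midlineX pelvic midline column, pixels.
#' @slot hlineY row of Hilgenreiner's line at the midline, pixels.
#' @slot hlineTiltDeg tilt of Hilgenreiner's line, degrees (positive =
#'   image-right end inferior).
#' @slot left,right [PhantomHipSpec-class] per side (left = image-left).
#' @slot boneIntensity,backgroundIntensity 8-bit intensities,
#'   bone > background.
#' @slot noiseSd additive Gaussian noise standard deviation, intensity
#'   units.
#' @slot seed integer seed governing the noise.
#' @export
setClass("PhantomSpec",
         representation(width = "numeric", height = "numeric",
                        midlineX = "numeric", hlineY = "numeric",
                        hlineTiltDeg = "numeric", left = "PhantomHipSpec",
                        right = "PhantomHipSpec", boneIntensity = "numeric",
                        backgroundIntensity = "numeric", noiseSd = "numeric",
                        seed = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (object@width < 32 || object@height < 32)
    return("image must be at least 32 x 32")
  ints <- c(object@boneIntensity, object@backgroundIntensity)
  if (any(ints < 0) || any(ints > 255)) return("intensities must be in [0, 255]")
  if (object@boneIntensity <= object@backgroundIntensity)
    return("boneIntensity must exceed backgroundIntensity")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' @rdname makePhantom
#' @param width,height,midlineX,hlineY,hlineTiltDeg,left,right,boneIntensity,backgroundIntensity,noiseSd,seed
#'   see [PhantomSpec-class].
#' @export
phantomSpec <- function(width = 640, height = 480, midlineX = 320,
                        hlineY = 240, hlineTiltDeg = 0,
                        left = phantomHipSpec(), right = phantomHipSpec(),
                        boneIntensity = 200, backgroundIntensity = 40,
                        noiseSd = 2, seed = 1) {
  new("PhantomSpec", width = width, height = height, midlineX = midlineX,
      hlineY = hlineY, hlineTiltDeg = hlineTiltDeg, left = left,
      right = right, boneIntensity = boneIntensity,
      backgroundIntensity = backgroundIntensity, noiseSd = noiseSd,
      seed = seed)
}

#' Ground truth of a rendered phantom
#'
#' @slot annotations exact (pre-noise, real-valued) landmark coordinates.
#' @slot aiDeg named numeric, true AI per side, degrees.
#' @slot grade named integer, true IHDI grade per side.
#' @slot hPoint named list of true H-point coordinates per side.
#' @export
setClass("PhantomTruth",
         representation(annotations = "AnnotationSet", aiDeg = "numeric",
                        grade = "integer", hPoint = "list"))

#' @describeIn makePhantom the exact landmark annotations of a phantom.
#' @param truth a PhantomTruth.
#' @export
truthAnnotations <- function(truth) truth@annotations

#' @describeIn makePhantom named true AI per side, degrees.
#' @export
truthAI <- function(truth) truth@aiDeg

#' @describeIn makePhantom named true IHDI grade per side.
#' @export
truthGrade <- function(truth) truth@grade

#' @export
setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: AI L %.1f / R %.1f deg, IHDI L %d / R %d\n",
              object@aiDeg[["left"]], object@aiDeg[["right"]],
              object@grade[["left"]], object@grade[["right"]]))
})
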