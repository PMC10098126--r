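# distance from the pelvic midline to each triradiate top, as a fraction
# of the image width (stylized pelvis layout)
.TRI_OFFSET_FRAC <- 0.11
# thickness of the rendered acetabular-roof bar, px
.ROOF_THICKNESS <- 6
# gap between the roof line and the ilium block, px; keeps the roof's
# superior boundary (which carries two landmarks) a detectable edge
.ILIUM_GAP <- 10
.ILIUM_DEPTH <- 60
.METAPHYSIS_DEPTH <- 28

# analytic landmark geometry of one phantom; all coordinates real-valued,
# 0-based pixel coordinates
.phantomGeometry <- function(spec) {
  tilt <- spec@hlineTiltDeg * pi / 180
  dir <- c(cos(tilt), sin(tilt))          # along the H-line, toward image right
  m <- c(spec@midlineX, spec@hlineY)
  triOffset <- .TRI_OFFSET_FRAC * spec@width
  out <- list()
  for (side in .SIDES) {
    hs <- slot(spec, side)
    s <- if (side == "left") -1 else 1    # left hip rendered on image left
    tri <- m + s * triOffset * dir
    u <- s * dir
    v <- perpVector(u)
    if (v[2] > 0) v <- -v
    ai <- hs@aiDeg * pi / 180
    roofDir <- cos(ai) * u + sin(ai) * v
    edge <- tri + hs@roofLength * roofDir
    junction <- tri + hs@roofLength * cos(ai) * u
    hPoint <- junction + hs@hPointOffset[1] * u + hs@hPointOffset[2] * v
    inner <- hPoint - hs@metaphysisWidth / 2 * u
    outer <- hPoint + hs@metaphysisWidth / 2 * u
    off <- hs@hPointOffset
    grade <- if (off[2] > 0) 4L else if (off[1] <= 0) 1L else
      if (off[1] <= -off[2]) 2L else 3L
    out[[side]] <- list(tri = tri, edge = edge, junction = junction,
                        hPoint = hPoint, inner = inner, outer = outer,
                        u = u, v = v, roofDir = roofDir, grade = grade,
                        spec = hs)
  }
  out
}

.phantomTruth <- function(spec, geom) {
  rows <- do.call(rbind, lapply(.SIDES, function(side) {
    g <- geom[[side]]
    data.frame(label = c("lateral_acetabular_edge", "triradiate_top",
                         "metaphysis_inner", "metaphysis_outer"),
               side = side,
               x = c(g$edge[1], g$tri[1], g$inner[1], g$outer[1]),
               y = c(g$edge[2], g$tri[2], g$inner[2], g$outer[2]))
  }))
  new("PhantomTruth", annotations = annotationSet(rows),
      aiDeg = c(left = geom$left$spec@aiDeg, right = geom$right$spec@aiDeg),
      grade = c(left = geom$left$grade, right = geom$right$grade),
      hPoint = list(left = geom$left$hPoint, right = geom$right$hPoint))
}

.checkPhantomBounds <- function(spec, geom) {
  for (side in .SIDES) {
    g <- geom[[side]]
    pts <- list(lateral_acetabular_edge = g$edge, triradiate_top = g$tri,
                metaphysis_inner = g$inner, metaphysis_outer = g$outer)
    for (nm in names(pts)) {
      p <- pts[[nm]]
      if (p[1] < 0 || p[1] > spec@width - 1 || p[2] < 0 ||
          p[2] > spec@height - 1)
        ddhValidationStop(sprintf(
          "phantom landmark %s.%s at (%.1f, %.1f) falls outside the %d x %d image",
          side, nm, p[1], p[2], spec@width, spec@height))
    }
  }
  invisible(TRUE)
}

#' Render a synthetic AP-pelvis phantom with exact ground truth
#'
#' Constructs a stylized anteroposterior-pelvis scene analytically and
#' rasterizes it: per hip an acetabular-roof bar whose superior boundary
#' runs from the triradiate top to the lateral acetabular edge at exactly
#' the specified acetabular index, an iliac block above it, a proximal
#' femoral metaphysis bar whose superior edge joins the inner and outer
#' metaphysis points (midpoint = H-point at the specified offset from the
#' Perkin-Hilgenreiner junction), and optionally a femoral-head disc.
#' Bone is rendered bright on a darker background and seeded Gaussian
#' noise is added and clipped to [0, 255]. The exact pre-noise landmark
#' coordinates, true AI and true IHDI grade are returned as ground truth,
#' so the phantom serves as a test surrogate for radiographs with known
#' answers.
#'
#' @param spec a [PhantomSpec-class].
#' @return `list(image = GrayImage, truth = PhantomTruth)`.
#' @examples
#' ph <- makePhantom(phantomSpec(seed = 7))
#' truthAI(ph$truth)
#' @export
makePhantom <- function(spec) {
  geom <- .phantomGeometry(spec)
  .checkPhantomBounds(spec, geom)
  W <- spec@width; H <- spec@height
  X <- matrix(rep(0:(W - 1), each = H), H, W)
  Y <- matrix(rep(0:(H - 1), W), H, W)
  bone <- matrix(FALSE, H, W)

  for (side in .SIDES) {
    g <- geom[[side]]
    rn <- perpVector(g$roofDir)            # superior normal of the roof line
    if (sum(rn * g$v) < 0) rn <- -rn
    ax <- (X - g$tri[1]) * g$roofDir[1] + (Y - g$tri[2]) * g$roofDir[2]
    bx <- (X - g$tri[1]) * rn[1] + (Y - g$tri[2]) * rn[2]
    along <- ax >= 0 & ax <= g$spec@roofLength
    bone <- bone | (along & bx <= 0 & bx >= -.ROOF_THICKNESS)           # roof
    bone <- bone | (along & bx >= .ILIUM_GAP &
                      bx <= .ILIUM_GAP + .ILIUM_DEPTH)                  # ilium
    am <- (X - g$hPoint[1]) * g$u[1] + (Y - g$hPoint[2]) * g$u[2]
    bm <- (X - g$hPoint[1]) * g$v[1] + (Y - g$hPoint[2]) * g$v[2]
    bone <- bone | (abs(am) <= g$spec@metaphysisWidth / 2 &
                      bm <= 0 & bm >= -.METAPHYSIS_DEPTH)               # metaphysis
    if (!is.na(g$spec@headRadius)) {
      ctr <- g$hPoint + g$spec@headRadius * g$v
      bone <- bone | ((X - ctr[1])^2 + (Y - ctr[2])^2 <= g$spec@headRadius^2)
    }
  }

  px <- spec@backgroundIntensity +
    (spec@boneIntensity - spec@backgroundIntensity) * bone
  if (spec@noiseSd > 0)
    px <- px + withSeed(spec@seed,
                        matrix(stats::rnorm(H * W, 0, spec@noiseSd), H, W))
  px <- round(pmin(pmax(px, 0), 255))
  list(image = grayImage(px), truth = .phantomTruth(spec, geom))
}

#' Simulate imprecise annotation clicks
#'
#' Adds independent, integer-rounded Gaussian displacements (standard
#' deviation `sigma` pixels) to every landmark, emulating the clicking
#' imprecision of a human annotator. Seeded and reproducible; when bounds
#' are supplied, jittered points are clamped inside them.
#'
#' @param annotations an [AnnotationSet-class].
#' @param sigma displacement standard deviation per axis, pixels
#'   (`sigma = 0` returns the input unchanged).
#' @param seed integer seed.
#' @param bounds optional [GrayImage-class] or `c(width, height)` to clamp
#'   against.
#' @return the jittered [AnnotationSet-class].
#' @export
jitterAnnotations <- function(annotations, sigma, seed, bounds = NULL) {
  if (sigma < 0) ddhValidationStop("sigma must be >= 0")
  p <- landmarks(annotations)
  if (sigma > 0 && nrow(p) > 0L) {
    d <- withSeed(seed, round(stats::rnorm(2L * nrow(p), 0, sigma)))
    p$x <- p$x + d[seq_len(nrow(p))]
    p$y <- p$y + d[nrow(p) + seq_len(nrow(p))]
  }
  if (!is.null(bounds)) {
    wh <- if (is(bounds, "GrayImage")) c(imageWidth(bounds),
                                         imageHeight(bounds)) else bounds
    p$x <- pmin(wh[1] - 1, pmax(0, p$x))
    p$y <- pmin(wh[2] - 1, pmax(0, p$y))
  }
  annotationSet(p)
}

#' Synthetic criteria table used by phantom studies
#'
#' A SYNTHETIC transcription template with one wide stratum per
#' nationality and sex (normal AI mean 23, sd 4 degrees, ages 0.4-8.0),
#' giving a dysplasia threshold of 31 degrees everywhere. The values are
#' placeholders with plausible magnitudes, not the published Zhao/Tonnis
#' norms; clinical use requires transcribing those references into the
#' same format.
#'
#' @return a [CriteriaTable-class].
#' @export
defaultCriteriaTable <- function() {
  e <- expand.grid(nationality = .NATIONALITIES, sex = .SEXES,
                   stringsAsFactors = FALSE)
  criteriaTable(data.frame(e, side = "either", age_min = 0.4, age_max = 8.0,
                           mean_deg = 23, sd_deg = 4),
                sourceLabel = "synthetic template (placeholder strata)")
}

# per-class sampling regions for the H-point offset (u lateral, v superior,
# px), each kept >= 2 px from every IHDI boundary so truth grades are
# unambiguous under rounding
.sampleOffset <- function(class) {
  g <- switch(class,
              normal = 1L, ddh1 = 1L, ddh2 = 2L, ddh3 = 3L, ddh4 = 4L,
              other = sample(2:3, 1L))
  switch(as.character(g),
         "1" = c(stats::runif(1, -30, -2), stats::runif(1, -60, -20)),
         "2" = { v <- stats::runif(1, -60, -25)
                 c(stats::runif(1, 2, -v - 2), v) },
         "3" = { v <- stats::runif(1, -40, -2)
                 c(stats::runif(1, -v + 2, 80), v) },
         "4" = c(stats::runif(1, 0, 60), stats::runif(1, 2, 25)))
}

#' Generate a batch of phantom studies with known diagnoses
#'
#' Samples per-hip truth classes from `gradeMix`, draws acetabular indices
#' from the per-class ranges (kept at least 1 degree away from the
#' diagnostic threshold) and H-point offsets from the matching IHDI
#' region (kept at least 2 px from every boundary), and emits one phantom
#' study per draw together with a patient consistent with `table`. All
#' randomness flows from `seed`; the manifest records the drawn classes so
#' a batch can be regenerated bit-exactly.
#'
#' @param n number of studies.
#' @param gradeMix named probabilities over the truth classes `normal`,
#'   `ddh1`..`ddh4` (dysplastic AI with that IHDI grade) and `other`
#'   (normal AI, dislocated H-point); must sum to 1.
#' @param seed integer seed.
#' @param aiRanges named list with elements `normal`, `ddh`, `other`, each
#'   `c(min, max)` degrees; defaults match the synthetic criteria
#'   threshold of 31 degrees.
#' @param table the [CriteriaTable-class] patients are matched against.
#' @param render when `FALSE`, skip rasterization (`image = NULL`);
#'   geometry and truth are still exact.
#' @return list of `n` studies, each
#'   `list(image, truth, patient, labels, spec)` with `labels` the named
#'   per-side truth classes; the drawn class table is attached as
#'   `attr(, "manifest")`.
#' @export
phantomBatch <- function(n, gradeMix = c(normal = 0.5, ddh1 = 0.1,
                                         ddh2 = 0.1, ddh3 = 0.1,
                                         ddh4 = 0.1, other = 0.1),
                         seed = 1, aiRanges = NULL,
                         table = defaultCriteriaTable(), render = TRUE) {
  classes <- c("normal", "ddh1", "ddh2", "ddh3", "ddh4", "other")
  if (!all(names(gradeMix) %in% classes))
    ddhValidationStop("gradeMix names must be among normal, ddh1..ddh4, other")
  if (abs(sum(gradeMix) - 1) > 1e-8)
    ddhValidationStop("gradeMix must sum to 1")
  if (is.null(aiRanges))
    aiRanges <- list(normal = c(15, 30), ddh = c(32, 40), other = c(15, 30))

  withSeed(seed, {
    studies <- vector("list", n)
    manifest <- data.frame(study = integer(0), side = character(0),
                           class = character(0))
    for (i in seq_len(n)) {
      patient <- patientInfo("chinese", sample(.SEXES, 1L),
                             stats::runif(1, 0.5, 7.5))
      hipSpecs <- list(); labels <- c()
      for (side in .SIDES) {
        cls <- sample(names(gradeMix), 1L, prob = gradeMix)
        thr <- with(lookupCriteria(table, patient, side),
                    mean_deg + 2 * sd_deg)
        rng <- aiRanges[[if (startsWith(cls, "ddh")) "ddh" else cls]]
        rng <- if (startsWith(cls, "ddh")) {
          c(max(rng[1], thr + 1), rng[2])
        } else c(rng[1], min(rng[2], thr - 1))
        if (rng[1] >= rng[2])
          ddhValidationStop(sprintf(
            "infeasible AI range for class %s after the 1-degree margin", cls))
        hipSpecs[[side]] <- phantomHipSpec(
          aiDeg = stats::runif(1, rng[1], rng[2]),
          hPointOffset = .sampleOffset(cls))
        labels[side] <- cls
        manifest <- rbind(manifest,
                          data.frame(study = i, side = side, class = cls))
      }
      spec <- phantomSpec(left = hipSpecs$left, right = hipSpecs$right,
                          seed = sample.int(.Machine$integer.max, 1L))
      if (render) {
        ph <- makePhantom(spec)
      } else {
        geom <- .phantomGeometry(spec)
        .checkPhantomBounds(spec, geom)
        ph <- list(image = NULL, truth = .phantomTruth(spec, geom))
      }
      studies[[i]] <- list(image = ph$image, truth = ph$truth,
                           patient = patient, labels = labels, spec = spec)
    }
    structure(studies, manifest = manifest)
  })
}
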