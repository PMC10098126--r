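#' Construct the diagnostic reference geometry
#'
#' Builds, from the annotated key points, the constructs the diagnosis
#' relies on: Hilgenreiner's line (through the tops of the bilateral
#' triradiate cartilages), per side a Perkin's line (perpendicular to
#' Hilgenreiner's line through the lateral acetabular edge), the 45-degree
#' diagonal line from their junction, the H-point (midpoint of the
#' proximal femoral metaphysis), and a tilt-invariant lateral/superior
#' frame.
#'
#' The frame's `u` axis points along Hilgenreiner's line away from the
#' pelvic midline (realized as the midpoint of the two triradiate tops),
#' and `v` is perpendicular to `u` pointing superiorly. Superior is
#' determined anatomically — the acetabular roofs lie on the iliac side
#' of Hilgenreiner's line (with the femoral metaphyses as fallback vote
#' and the image orientation as last resort) — so every downstream angle
#' and grade is invariant under arbitrary in-plane rotation, translation
#' and scaling of the radiograph.
#'
#' @param annotations an [AnnotationSet-class]; both triradiate tops are
#'   required, the per-side lines additionally need that side's lateral
#'   acetabular edge, and the H-point needs both metaphysis points.
#' @return an object of class `ReferenceGeometry`: a list with `hLine`
#'   (`list(anchor, direction)`), `midline` (point), and per side a list
#'   `perkinLine`, `diagonalLine`, `junction`, `u`, `v`, `hPoint` (the
#'   latter `NULL` when that side's landmarks are absent).
#' @examples
#' ann <- annotationSet(
#'   label = c("triradiate_top", "triradiate_top", "lateral_acetabular_edge",
#'             "metaphysis_inner", "metaphysis_outer"),
#'   side  = c("right", "left", "left", "left", "left"),
#'   x = c(100, 300, 340, 330, 350), y = c(200, 200, 180, 225, 235))
#' g <- buildReferenceGeometry(ann)
#' g$left$junction   # (340, 200)
#' @export
buildReferenceGeometry <- function(annotations) {
  triL <- unname(getPoint(annotations, "triradiate_top", "left"))
  triR <- unname(getPoint(annotations, "triradiate_top", "right"))
  if (is.null(triL)) ddhValidationStop("missing landmark: left triradiate_top")
  if (is.null(triR)) ddhValidationStop("missing landmark: right triradiate_top")
  if (all(triL == triR))
    ddhStop("degenerate geometry: the two triradiate tops coincide")

  m <- (triL + triR) / 2
  dir <- unitVector(triR - triL)
  sup <- .superiorNormal(annotations, m, dir)
  geom <- list(hLine = list(anchor = m, direction = dir), midline = m)

  tri <- list(left = triL, right = triR)
  for (side in .SIDES) {
    s <- sign(sum((tri[[side]] - m) * dir))
    u <- s * dir
    v <- sup
    edge <- unname(getPoint(annotations, "lateral_acetabular_edge", side))
    entry <- list(u = u, v = v, hPoint = .hPoint(annotations, side))
    if (!is.null(edge)) {
      junction <- m + sum((edge - m) * dir) * dir
      entry$junction <- junction
      entry$perkinLine <- list(anchor = edge, direction = v)
      entry$diagonalLine <- list(anchor = junction,
                                 direction = (u - v) / sqrt(2))
    }
    geom[[side]] <- entry
  }
  structure(geom, class = "ReferenceGeometry")
}

# superior unit normal of the H-line, determined anatomically so every
# measurement is invariant under arbitrary in-plane rotation of the
# radiograph: the acetabular roofs (lateral acetabular edges) lie on the
# iliac, i.e. superior, side of the line. When both edges sit exactly on
# the line the femoral metaphyses vote instead (H-points lie inferior),
# and only a fully degenerate configuration falls back to the image
# orientation (y decreasing upward).
.superiorNormal <- function(annotations, m, dir) {
  cand <- perpVector(dir)
  perpComp <- function(p) sum((p - m) * cand)
  vote <- 0
  for (side in .SIDES) {
    edge <- getPoint(annotations, "lateral_acetabular_edge", side)
    if (!is.null(edge)) vote <- vote + perpComp(edge)
  }
  if (abs(vote) > 1e-9) return(sign(vote) * cand)
  vote <- 0
  for (side in .SIDES) {
    hp <- .hPoint(annotations, side)
    if (!is.null(hp)) vote <- vote - perpComp(hp)
  }
  if (abs(vote) > 1e-9) return(sign(vote) * cand)
  if (cand[2] != 0) return(-sign(cand[2]) * cand)
  -sign(cand[1]) * cand
}

.hPoint <- function(annotations, side) {
  inner <- getPoint(annotations, "metaphysis_inner", side)
  outer <- getPoint(annotations, "metaphysis_outer", side)
  if (is.null(inner) || is.null(outer)) return(NULL)
  unname((inner + outer) / 2)
}

#' @export
print.ReferenceGeometry <- function(x, ...) {
  cat("ReferenceGeometry\n")
  cat(sprintf("  H-line: anchor (%.1f, %.1f), direction (%.3f, %.3f)\n",
              x$hLine$anchor[1], x$hLine$anchor[2],
              x$hLine$direction[1], x$hLine$direction[2]))
  for (side in c("left", "right")) {
    e <- x[[side]]
    if (is.null(e$junction)) next
    cat(sprintf("  %s: junction (%.1f, %.1f), H-point %s\n", side,
                e$junction[1], e$junction[2],
                if (is.null(e$hPoint)) "absent"
                else sprintf("(%.1f, %.1f)", e$hPoint[1], e$hPoint[2])))
  }
  invisible(x)
}

.needSide <- function(geometry, side, what) {
  e <- geometry[[side]]
  for (w in what)
    if (is.null(e[[w]]))
      ddhValidationStop(sprintf("missing landmark or construct '%s' for side %s",
                                w, side))
  e
}

#' Measure the acetabular index
#'
#' The acetabular index (AI) is the angle between Hilgenreiner's line and
#' the acetabular-roof line from the top of the triradiate cartilage to
#' the lateral acetabular edge. It is computed as `atan2(d_v, d_u)` in
#' degrees, with `d` the roof vector expressed in the side's
#' lateral/superior frame, so the sign is positive when the acetabular
#' edge lies superior to Hilgenreiner's line (the usual configuration; the
#' steeper the roof, the larger the AI, the shallower the acetabulum).
#'
#' @param geometry a `ReferenceGeometry` from [buildReferenceGeometry()].
#' @param annotations the [AnnotationSet-class] the geometry was built
#'   from.
#' @param side `"left"` or `"right"`.
#' @return `list(aiDeg, warnings)`; a warning is attached (value still
#'   returned) when the acetabular edge lies medial to the triradiate top.
#' @examples
#' ann <- annotationSet(
#'   label = c("triradiate_top", "triradiate_top", "lateral_acetabular_edge"),
#'   side  = c("right", "left", "left"),
#'   x = c(100, 300, 340), y = c(200, 200, 180))
#' g <- buildReferenceGeometry(ann)
#' measureAI(g, ann, "left")$aiDeg   # 26.57
#' @export
measureAI <- function(geometry, annotations, side) {
  e <- .needSide(geometry, side, c("u", "v"))
  tri <- getPoint(annotations, "triradiate_top", side)
  edge <- getPoint(annotations, "lateral_acetabular_edge", side)
  if (is.null(tri))
    ddhValidationStop(sprintf("missing landmark: %s triradiate_top", side))
  if (is.null(edge))
    ddhValidationStop(sprintf("missing landmark: %s lateral_acetabular_edge", side))
  d <- edge - tri
  du <- sum(d * e$u); dv <- sum(d * e$v)
  warnings <- character(0)
  if (du <= 0)
    warnings <- sprintf("%s acetabular edge lies medial to the triradiate top",
                        side)
  list(aiDeg = degAtan2(dv, du), warnings = warnings)
}

#' Measure the lateral center-edge angle
#'
#' The lateral center-edge angle (LCEA) is the angle between the vertical
#' through the femoral-head center and the line from that center to the
#' lateral acetabular edge. "Vertical" is realized as the frame's `v`
#' axis, i.e. perpendicular to Hilgenreiner's line, making the angle
#' invariant to radiograph tilt. When no explicit head center is supplied
#' (the ossific nucleus is often not yet visible in the relevant age
#' range) the H-point serves as proxy and the provenance is flagged.
#'
#' @inheritParams measureAI
#' @param headCenter optional explicit femoral-head center `c(x, y)`.
#' @return `list(lceaDeg, headCenterSource, warnings)`; positive when the
#'   edge lies lateral to the vertical through the center. A warning is
#'   attached when the edge lies at or below the center.
#' @export
measureLCEA <- function(geometry, annotations, side, headCenter = NULL) {
  e <- .needSide(geometry, side, c("u", "v"))
  edge <- getPoint(annotations, "lateral_acetabular_edge", side)
  if (is.null(edge))
    ddhValidationStop(sprintf("missing landmark: %s lateral_acetabular_edge", side))
  if (!is.null(headCenter)) {
    ctr <- c(headCenter[[1]], headCenter[[2]])
    src <- "explicit"
  } else if (!is.null(e$hPoint)) {
    ctr <- e$hPoint
    src <- "h_point_proxy"
  } else {
    ddhValidationStop(sprintf(
      "no head center: supply one or annotate the %s metaphysis points", side))
  }
  d <- edge - ctr
  eu <- sum(d * e$u); ev <- sum(d * e$v)
  warnings <- character(0)
  if (ev <= 0)
    warnings <- sprintf("%s acetabular edge lies at or below the head center",
                        side)
  list(lceaDeg = degAtan2(eu, ev), headCenterSource = src,
       warnings = warnings)
}

#' Grade hip displacement on the IHDI scale
#'
#' Classifies the H-point (midpoint of the proximal femoral metaphysis)
#' against the three reference lines, following the IHDI scheme:
#' \describe{
#'   \item{1}{H-point at or medial to Perkin's line.}
#'   \item{2}{lateral to Perkin's line, at or medial to the diagonal
#'     line.}
#'   \item{3}{lateral to the diagonal line, at or inferior to
#'     Hilgenreiner's line.}
#'   \item{4}{superior to Hilgenreiner's line.}
#' }
#' With `p` the H-point relative to the Perkin-Hilgenreiner junction in
#' lateral/superior coordinates `(p_u, p_v)`: grade 4 iff `p_v > 0`; else
#' grade 1 iff `p_u <= 0`; else grade 2 iff `p_u <= -p_v`; else grade 3.
#' Boundary ties resolve to the lower grade ("at or medial / at or
#' inferior").
#'
#' @inheritParams measureAI
#' @return integer IHDI grade in 1..4.
#' @export
classifyIhdi <- function(geometry, side) {
  e <- .needSide(geometry, side, c("u", "v", "junction", "hPoint"))
  p <- e$hPoint - e$junction
  pu <- sum(p * e$u); pv <- sum(p * e$v)
  if (pv > 0) return(4L)
  if (pu <= 0) return(1L)
  if (pu <= -pv) return(2L)
  3L
}

#' Measure both hip parameters of one side
#'
#' Convenience wrapper bundling [measureAI()] and [measureLCEA()] into a
#' [HipParameters-class] object.
#'
#' @inheritParams measureLCEA
#' @return a [HipParameters-class].
#' @export
measureHip <- function(geometry, annotations, side, headCenter = NULL) {
  ai <- measureAI(geometry, annotations, side)
  lcea <- tryCatch(measureLCEA(geometry, annotations, side, headCenter),
                   ddhValidationError = function(e) NULL)
  new("HipParameters",
      aiDeg = ai$aiDeg,
      lceaDeg = if (is.null(lcea)) NA_real_ else lcea$lceaDeg,
      headCenterSource = if (is.null(lcea)) "none" else lcea$headCenterSource,
      warnings = c(ai$warnings, if (!is.null(lcea)) lcea$warnings))
}
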