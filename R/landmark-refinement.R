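#' Detect the bony rim inside a local analysis window
#'
#' Intercepts a square window around an annotated point, smooths it with a
#' small Gaussian filter, separates radiodense (bright) bone from
#' background with a local-mean adaptive threshold, and returns the
#' boundary of the thresholded foreground: foreground pixels with at least
#' one 4-adjacent background pixel (inside the window) whose smoothed
#' intensity is lower by at least the threshold offset, i.e. the side of
#' the foreground where intensity actually drops off. This boundary is
#' the "bony rim" that annotated points are snapped onto.
#'
#' The window covers `center +/- floor(windowSize / 2)` in each axis and is
#' clipped at image borders. A pixel is foreground when its smoothed
#' intensity exceeds the local block mean by more than `adaptiveOffset`
#' (bright bone on darker background); uniform regions therefore contain
#' no foreground and produce no edges.
#'
#' @param image a [GrayImage-class].
#' @param center integer-valued `c(x, y)` in 0-based pixel coordinates;
#'   must lie within the image.
#' @param config a [RefinementConfig-class].
#' @return integer matrix with columns `x`, `y` (absolute 0-based
#'   coordinates) listing the edge pixels, ordered by `y` then `x`;
#'   zero rows when no edge is found.
#' @examples
#' px <- matrix(30, 100, 100); px[, 41:100] <- 220
#' img <- grayImage(px)
#' edges <- binarizeWindow(img, c(36, 50), refinementConfig())
#' unique(edges[, "x"])
#' @export
binarizeWindow <- function(image, center, config = refinementConfig()) {
  if (!pointInImage(center, image))
    ddhValidationStop(sprintf("window center (%g, %g) lies outside the image",
                              center[[1]], center[[2]]))
  cx <- round(center[[1]]); cy <- round(center[[2]])
  h <- floor(config@windowSize / 2)
  W <- imageWidth(image); H <- imageHeight(image)
  x0 <- max(0, cx - h); x1 <- min(W - 1, cx + h)
  y0 <- max(0, cy - h); y1 <- min(H - 1, cy + h)
  win <- image@pixels[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]

  gk <- EBImage::makeBrush(config@gaussianKernel, shape = "Gaussian",
                           sigma = config@gaussianSigma)
  sm <- EBImage::filter2(win, gk, boundary = "replicate")
  bk <- EBImage::makeBrush(config@adaptiveBlock, shape = "box")
  bk <- bk / sum(bk)
  mu <- EBImage::filter2(sm, bk, boundary = "replicate")
  fg <- sm > mu + config@adaptiveOffset

  edge <- .maskBoundary(fg, sm, config@adaptiveOffset)
  idx <- which(edge, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  out <- cbind(x = x0 + idx[, "col"] - 1L, y = y0 + idx[, "row"] - 1L)
  out[order(out[, "y"], out[, "x"]), , drop = FALSE]
}

# rim pixels: foreground pixels 4-adjacent to a background pixel that is
# genuinely darker (smoothed intensity at least `offset` below the pixel's).
# The local-mean threshold marks a band along each intensity transition;
# the darker-neighbor condition keeps the bone-to-background boundary of
# that band and discards its interior side, where the neighboring
# background pixel is equally bright. Neighbors outside the window do not
# count as background.
.maskBoundary <- function(fg, sm, offset) {
  nr <- nrow(fg); nc <- ncol(fg)
  bg <- !fg
  nb <- matrix(FALSE, nr, nc)
  if (nr > 1L) {
    nb[-1, ] <- nb[-1, ] | (bg[-nr, ] & sm[-nr, ] <= sm[-1, ] - offset)
    nb[-nr, ] <- nb[-nr, ] | (bg[-1, ] & sm[-1, ] <= sm[-nr, ] - offset)
  }
  if (nc > 1L) {
    nb[, -1] <- nb[, -1] | (bg[, -nc] & sm[, -nc] <= sm[, -1] - offset)
    nb[, -nc] <- nb[, -nc] | (bg[, -1] & sm[, -1] <= sm[, -nc] - offset)
  }
  fg & nb
}

#' Snap one annotated point onto the nearest rim pixel
#'
#' Runs [binarizeWindow()] around the point and returns the edge pixel
#' `(a, b)` minimizing the Euclidean distance
#' `Ed = sqrt((x - a)^2 + (y - b)^2)` to the annotated point `(x, y)`.
#' Ties are broken toward the smallest `y`, then smallest `x`, making the
#' result deterministic. The point is returned unchanged when it already
#' lies on the rim (`already_on_edge`), when no rim is detected
#' (`no_edge_found`), or when the nearest rim pixel is farther than
#' `maxSnapDistance` (`beyond_max_distance`, guarding against capture by
#' distant structures).
#'
#' @inheritParams binarizeWindow
#' @param point `c(x, y)` in 0-based pixel coordinates, within the image.
#' @return `list(point = c(x, y), status = list(outcome, snapDistance))`;
#'   `snapDistance` is present only for outcomes `snapped` and
#'   `already_on_edge`.
#' @export
refinePoint <- function(image, point, config = refinementConfig()) {
  if (!pointInImage(point, image))
    ddhValidationStop(sprintf("point (%g, %g) lies outside the image",
                              point[[1]], point[[2]]))
  edges <- binarizeWindow(image, point, config)
  px <- point[[1]]; py <- point[[2]]
  if (nrow(edges) == 0L)
    return(list(point = c(x = px, y = py),
                status = list(outcome = "no_edge_found")))
  d2 <- (edges[, "x"] - px)^2 + (edges[, "y"] - py)^2
  best <- order(d2, edges[, "y"], edges[, "x"])[1]
  dist <- sqrt(d2[best])
  if (dist == 0)
    return(list(point = c(x = px, y = py),
                status = list(outcome = "already_on_edge", snapDistance = 0)))
  if (dist > config@maxSnapDistance)
    return(list(point = c(x = px, y = py),
                status = list(outcome = "beyond_max_distance")))
  list(point = c(x = unname(edges[best, "x"]), y = unname(edges[best, "y"])),
       status = list(outcome = "snapped", snapDistance = unname(dist)))
}

#' Snap every eligible landmark of an annotation set
#'
#' Applies [refinePoint()] to each landmark whose label appears in
#' `config@enabledLabels`; other landmarks pass through unchanged and get
#' no status. The output carries exactly the same (label, side) set as the
#' input.
#'
#' @inheritParams binarizeWindow
#' @param annotations an [AnnotationSet-class] with all points inside the
#'   image.
#' @return `list(annotations = AnnotationSet,
#'   statuses = named list)` where names are `"side.label"`.
#' @export
refineAnnotations <- function(image, annotations,
                              config = refinementConfig()) {
  p <- landmarks(annotations)
  statuses <- list()
  for (i in seq_len(nrow(p))) {
    if (!p$label[i] %in% config@enabledLabels) next
    res <- tryCatch(
      refinePoint(image, c(p$x[i], p$y[i]), config),
      ddhError = function(e)
        ddhValidationStop(sprintf("landmark %s.%s: %s", p$side[i], p$label[i],
                                  conditionMessage(e))))
    p$x[i] <- res$point[["x"]]
    p$y[i] <- res$point[["y"]]
    statuses[[paste(p$side[i], p$label[i], sep = ".")]] <- res$status
  }
  list(annotations = annotationSet(p), statuses = statuses)
}
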