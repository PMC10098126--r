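# internal helpers: classed conditions, seeded evaluation, small geometry

# validation errors (bad user input / malformed files) are distinguished
# from runtime errors so the CLI can map them to exit code 2
ddhStop <- function(msg, class = "ddhError", call = sys.call(-1)) {
  stop(structure(class = c(class, "ddhError", "error", "condition"),
                 list(message = msg, call = call)))
}

ddhValidationStop <- function(msg, call = sys.call(-1)) {
  ddhStop(msg, class = "ddhValidationError", call = call)
}

# evaluate expr with a fixed RNG state, restoring the caller's afterwards
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

unitVector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) ddhStop("cannot normalize a zero vector")
  v / n
}

# counter-clockwise-in-image-coordinates 90 degree rotation candidates
perpVector <- function(v) c(-v[2], v[1])

degAtan2 <- function(y, x) atan2(y, x) * 180 / pi

pointInImage <- function(point, image) {
  x <- point[[1]]; y <- point[[2]]
  is.finite(x) && is.finite(y) &&
    x >= 0 && x <= imageWidth(image) - 1 &&
    y >= 0 && y <= imageHeight(image) - 1
}
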