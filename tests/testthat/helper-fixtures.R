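# shared fixture builders; everything is generated in code

# axis-aligned full annotation set: horizontal Hilgenreiner line at y = 200,
# midline x = 200, both hips located (IHDI 1)
axisAlignedAnnotations <- function() {
  annotationSet(
    label = rep(c("triradiate_top", "lateral_acetabular_edge",
                  "metaphysis_inner", "metaphysis_outer"), 2),
    side = rep(c("left", "right"), each = 4),
    x = c(300, 340, 330, 350, 100, 60, 50, 70),
    y = c(200, 180, 225, 235, 200, 182, 228, 232))
}

# annotation set whose left H-point sits at junction + (pu, pv) in the
# left hip's lateral/superior frame (u = +x, v = -y); junction is (340, 200)
annotationsWithOffset <- function(pu, pv) {
  hp <- c(340 + pu, 200 - pv)
  ann <- axisAlignedAnnotations()
  ann <- setPoint(ann, "metaphysis_inner", "left", hp - c(5, 0))
  setPoint(ann, "metaphysis_outer", "left", hp + c(5, 0))
}

# vertical step-edge image: dark (30) for columns < 40, bright (220) beyond
stepEdgeImage <- function(w = 100, h = 100, at = 40, lo = 30, hi = 220) {
  px <- matrix(lo, h, w)
  px[, (at + 1):w] <- hi
  grayImage(px)
}

# apply rotation (deg), uniform scale and translation to every landmark
transformAnnotations <- function(annotations, thetaDeg = 0, scale = 1,
                                 shift = c(0, 0), center = c(0, 0)) {
  th <- thetaDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p <- landmarks(annotations)
  xy <- t(R %*% (t(as.matrix(p[, c("x", "y")])) - center) * scale +
            center + shift)
  p$x <- xy[, 1]; p$y <- xy[, 2]
  annotationSet(p)
}

# mean Euclidean landmark error between two annotation sets
landmarkError <- function(a, b) {
  pa <- landmarks(a); pb <- landmarks(b)
  key <- paste(pa$side, pa$label)
  pb <- pb[match(key, paste(pb$side, pb$label)), ]
  mean(sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2))
}

# brute-force Mann-Whitney AUC (ties counted half)
bruteAUC <- function(truth, scores) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# the truth class a hip diagnosis should reproduce
expectedCategory <- function(label) {
  if (label == "normal") "normal"
  else if (label == "other") "other_dislocation"
  else "ddh"
}

testCriteriaEntry <- function(mean_deg = 23, sd_deg = 4) {
  data.frame(nationality = "chinese", sex = "female", side = "either",
             age_min = 1, age_max = 2, mean_deg = mean_deg, sd_deg = sd_deg)
}
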