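test_that("measuring a phantom's ground truth recovers its specification", {
  cases <- list(
    phantomSpec(left = phantomHipSpec(aiDeg = 25), seed = 1),
    phantomSpec(left = phantomHipSpec(aiDeg = 38,
                                      hPointOffset = c(30, -15)),   # grade 3
                right = phantomHipSpec(aiDeg = 18,
                                       hPointOffset = c(10, -40)),  # grade 2
                seed = 2),
    phantomSpec(hlineTiltDeg = 8,
                left = phantomHipSpec(aiDeg = 30,
                                      hPointOffset = c(20, 10)),    # grade 4
                seed = 3))
  for (spec in cases) {
    ph <- makePhantom(spec)
    ta <- truthAnnotations(ph$truth)
    g <- buildReferenceGeometry(ta)
    for (side in hipSides()) {
      expect_equal(measureAI(g, ta, side)$aiDeg,
                   truthAI(ph$truth)[[side]], tolerance = 0.5)
      expect_identical(classifyIhdi(g, side), truthGrade(ph$truth)[[side]])
    }
  }
  # the stated grade-3 example offset
  ph3 <- makePhantom(phantomSpec(right = phantomHipSpec(
    hPointOffset = c(80, -10)), seed = 5))
  expect_identical(truthGrade(ph3$truth)[["right"]], 3L)
  g3 <- buildReferenceGeometry(truthAnnotations(ph3$truth))
  expect_identical(classifyIhdi(g3, "right"), 3L)
})

test_that("rendering is seeded and bit-reproducible", {
  a <- makePhantom(phantomSpec(seed = 11))
  b <- makePhantom(phantomSpec(seed = 11))
  expect_identical(imagePixels(a$image), imagePixels(b$image))
  c <- makePhantom(phantomSpec(seed = 12))
  expect_false(identical(imagePixels(a$image), imagePixels(c$image)))
  # bone is brighter than background on average
  expect_gt(max(imagePixels(a$image)), 150)
  expect_lt(min(imagePixels(a$image)), 80)
})

test_that("out-of-bounds phantom geometry is rejected with the landmark named", {
  expect_error(makePhantom(phantomSpec(left = phantomHipSpec(roofLength = 400),
                                       seed = 1)),
               "lateral_acetabular_edge", class = "ddhValidationError")
})

test_that("annotation jitter has the declared scale and seeding behavior", {
  ann <- axisAlignedAnnotations()
  expect_identical(landmarks(jitterAnnotations(ann, 0, seed = 1)),
                   landmarks(ann))
  expect_false(identical(landmarks(jitterAnnotations(ann, 3, seed = 1)),
                         landmarks(jitterAnnotations(ann, 3, seed = 2))))
  expect_identical(landmarks(jitterAnnotations(ann, 3, seed = 1)),
                   landmarks(jitterAnnotations(ann, 3, seed = 1)))

  # displacement sd over 1,000 landmark draws is close to sigma = 3
  base <- landmarks(ann)
  disp <- unlist(lapply(1:125, function(s) {
    j <- landmarks(jitterAnnotations(ann, 3, seed = 1000 + s))
    c(j$x - base$x, j$y - base$y)
  }))
  expect_equal(sd(disp), 3, tolerance = 0.15)

  # clamping respects image bounds
  edgeAnn <- setPoint(ann, "triradiate_top", "left", c(0, 0))
  j <- jitterAnnotations(edgeAnn, 5, seed = 7, bounds = c(400, 300))
  p <- landmarks(j)
  expect_true(all(p$x >= 0 & p$x <= 399 & p$y >= 0 & p$y <= 299))
})

test_that("batch generation draws the recorded class mix with unambiguous truth", {
  mix <- c(normal = 0.5, ddh1 = 0.2, ddh3 = 0.2, other = 0.1)
  b <- phantomBatch(20, gradeMix = mix, seed = 8, render = FALSE)
  expect_length(b, 20)
  man <- attr(b, "manifest")
  expect_equal(nrow(man), 40)
  expect_true(all(man$class %in% names(mix)))
  for (i in seq_along(b)) {
    st <- b[[i]]
    expect_identical(unname(st$labels),
                     man$class[man$study == i][match(hipSides(),
                                                    man$side[man$study == i])])
    for (side in hipSides()) {
      lab <- st$labels[[side]]
      grade <- truthGrade(st$truth)[[side]]
      ai <- truthAI(st$truth)[[side]]
      if (lab == "normal") expect_identical(grade, 1L)
      if (startsWith(lab, "ddh")) {
        expect_identical(grade, as.integer(substring(lab, 4)))
        expect_gte(ai, 32)   # threshold 31 plus the 1-degree margin
      } else {
        expect_lte(ai, 30)
      }
      if (lab == "other") expect_gte(grade, 2L)
    }
  }
  # reproducibility of the whole batch
  b2 <- phantomBatch(20, gradeMix = mix, seed = 8, render = FALSE)
  expect_identical(attr(b2, "manifest"), man)
  expect_equal(truthAI(b2[[7]]$truth), truthAI(b[[7]]$truth))

  expect_error(phantomBatch(3, gradeMix = c(normal = 0.7), seed = 1),
               "sum to 1", class = "ddhValidationError")
  expect_error(phantomBatch(3, gradeMix = c(normal = 1),
                            aiRanges = list(normal = c(31, 35),
                                            ddh = c(32, 40),
                                            other = c(15, 30)),
                            seed = 1, render = FALSE),
               "infeasible", class = "ddhValidationError")
})

test_that("refinement reduces the AI measurement error of jittered studies", {
  # paired seeded comparison: the same jittered annotations measured raw
  # and after snapping; snapping corrects the error component
  # perpendicular to the bony rim, which is what the roof angle depends on
  rawErr <- c(); refErr <- c()
  for (seed in 1:12) {
    ph <- makePhantom(phantomSpec(left = phantomHipSpec(aiDeg = 33),
                                  right = phantomHipSpec(aiDeg = 24),
                                  seed = seed))
    truth <- truthAnnotations(ph$truth)
    jit <- jitterAnnotations(truth, 2, seed = seed + 300, bounds = ph$image)
    ref <- refineAnnotations(ph$image, jit)$annotations
    gj <- buildReferenceGeometry(jit)
    gr <- buildReferenceGeometry(ref)
    for (side in hipSides()) {
      t0 <- truthAI(ph$truth)[[side]]
      rawErr <- c(rawErr, abs(measureAI(gj, jit, side)$aiDeg - t0))
      refErr <- c(refErr, abs(measureAI(gr, ref, side)$aiDeg - t0))
    }
  }
  expect_lt(mean(refErr), mean(rawErr))
})
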