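test_that("criteria lookup matches stratum, bracket and side precedence", {
  tab <- criteriaTable(testCriteriaEntry())
  hit <- lookupCriteria(tab, patientInfo("chinese", "female", 1.4), "left")
  expect_equal(hit$mean_deg, 23)

  # half-open bracket: age 2.0 is outside [1, 2)
  expect_error(lookupCriteria(tab, patientInfo("chinese", "female", 2.0),
                              "left"),
               "no criteria bracket", class = "ddhValidationError")

  # a side-specific row beats the 'either' row of the same stratum
  two <- rbind(testCriteriaEntry(), testCriteriaEntry(mean_deg = 20))
  two$side <- c("either", "left")
  tab2 <- criteriaTable(two)
  expect_equal(lookupCriteria(tab2, patientInfo("chinese", "female", 1.5),
                              "left")$mean_deg, 20)
  expect_equal(lookupCriteria(tab2, patientInfo("chinese", "female", 1.5),
                              "right")$mean_deg, 23)

  # overlapping brackets are rejected at construction
  bad <- rbind(testCriteriaEntry(), testCriteriaEntry())
  bad$age_min <- c(1, 1.5); bad$age_max <- c(3, 4)
  expect_error(criteriaTable(bad), "overlap")
})

test_that("the decision rule splits ddh / other dislocation / normal", {
  entry <- testCriteriaEntry()   # threshold 23 + 2*4 = 31
  d <- diagnoseHip(32, 1L, entry)
  expect_equal(diagnosisCategory(d), "ddh")
  expect_identical(ihdiGrade(d), 1L)
  expect_equal(thresholdDeg(d), 31)

  expect_equal(diagnosisCategory(diagnoseHip(30, 1L, entry)), "normal")
  d3 <- diagnoseHip(30, 3L, entry)
  expect_equal(diagnosisCategory(d3), "other_dislocation")
  expect_true(is.na(ihdiGrade(d3)))

  # threshold equality is not "exceeded": normal, with a borderline warning
  db <- diagnoseHip(31, 1L, entry)
  expect_equal(diagnosisCategory(db), "normal")
  expect_match(db@warnings, "borderline")

  # the dislocation cut is configurable
  expect_equal(diagnosisCategory(diagnoseHip(30, 2L, entry,
                                             dislocatedGrade = 3L)), "normal")
})

test_that("category tracks the threshold invariant and is monotone in AI", {
  entry <- testCriteriaEntry()
  set.seed(42)
  for (i in 1:200) {
    ai <- runif(1, 10, 45)
    g <- sample(1:4, 1)
    d <- diagnoseHip(ai, g, entry)
    expect_identical(diagnosisCategory(d) == "ddh", ai > thresholdDeg(d))
    expect_identical(!is.na(ihdiGrade(d)), diagnosisCategory(d) == "ddh")
  }
  # increasing AI never leaves the ddh category
  cats <- vapply(seq(25, 40, by = 0.25),
                 function(a) diagnosisCategory(diagnoseHip(a, 1L, entry)),
                 character(1))
  firstDdh <- match("ddh", cats)
  expect_true(all(cats[firstDdh:length(cats)] == "ddh"))
})

test_that("the full pipeline reproduces phantom truth end to end", {
  tab <- defaultCriteriaTable()   # threshold 31 everywhere
  pat <- patientInfo("chinese", "female", 1.4)

  # dysplastic left hip, located: ddh with IHDI 1
  spec <- phantomSpec(left = phantomHipSpec(aiDeg = 33),
                      right = phantomHipSpec(aiDeg = 20), seed = 3)
  ph <- makePhantom(spec)
  rep <- diagnoseStudy(truthAnnotations(ph$truth), pat, tab)
  expect_equal(diagnosisCategory(hipResult(rep, "left")$diagnosis), "ddh")
  expect_identical(ihdiGrade(hipResult(rep, "left")$diagnosis), 1L)
  expect_equal(diagnosisCategory(hipResult(rep, "right")$diagnosis), "normal")
  expect_equal(aiDeg(hipResult(rep, "left")$parameters), 33,
               tolerance = 1e-6)

  # both hips plainly normal
  spec2 <- phantomSpec(left = phantomHipSpec(aiDeg = 20),
                       right = phantomHipSpec(aiDeg = 20), seed = 4)
  ph2 <- makePhantom(spec2)
  rep2 <- diagnoseStudy(truthAnnotations(ph2$truth), pat, tab)
  for (s in hipSides())
    expect_equal(diagnosisCategory(hipResult(rep2, s)$diagnosis), "normal")

  # refinement bypass: no image behaves exactly like refinement disabled,
  # and snapping ground-truth annotations must not change any diagnosis
  noimg <- diagnoseStudy(truthAnnotations(ph$truth), pat, tab)
  disabled <- diagnoseStudy(truthAnnotations(ph$truth), pat, tab,
                            image = ph$image,
                            config = refinementConfig(enabledLabels = character(0)))
  expect_equal(landmarks(reportAnnotations(noimg)),
               landmarks(reportAnnotations(disabled)))
  expect_equal(aiDeg(hipResult(noimg, "left")$parameters),
               aiDeg(hipResult(disabled, "left")$parameters))
  refined <- diagnoseStudy(truthAnnotations(ph$truth), pat, tab,
                           image = ph$image)
  for (s in hipSides()) {
    expect_equal(diagnosisCategory(hipResult(refined, s)$diagnosis),
                 diagnosisCategory(hipResult(noimg, s)$diagnosis))
    expect_length(refinementStatuses(refined)[[paste0(s, ".triradiate_top")]],
                  2)
  }

  # incomplete studies are refused
  partial <- annotationSet(landmarks(axisAlignedAnnotations())[1:5, ])
  expect_error(diagnoseStudy(partial, pat, tab),
               class = "ddhValidationError")
})

test_that("every diagnosis is reproducible from its recorded intermediates", {
  tab <- defaultCriteriaTable()
  b <- phantomBatch(6, seed = 99, render = FALSE)
  for (st in b) {
    rep <- diagnoseStudy(truthAnnotations(st$truth), st$patient, tab)
    for (s in hipSides()) {
      h <- hipResult(rep, s)
      redo <- diagnoseHip(aiDeg(h$parameters), h$grade,
                          data.frame(mean_deg = thresholdDeg(h$diagnosis) - 8,
                                     sd_deg = 4))
      expect_equal(diagnosisCategory(redo), diagnosisCategory(h$diagnosis))
      expect_identical(ihdiGrade(redo), ihdiGrade(h$diagnosis))
    }
  }
})
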