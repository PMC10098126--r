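test_that("binary metrics reproduce the published reader statistics", {
  # junior reader, conventional method
  m <- binaryMetrics(tp = 309, fn = 54, tn = 677, fp = 46)
  expect_equal(round(m$sensitivity, 2), 85.12)
  expect_equal(round(m$specificity, 2), 93.64)
  expect_equal(round(m$accuracy, 2), 90.79)
  expect_equal(round(m$auc, 3), 0.894)

  # intermediate reader, conventional method
  m2 <- binaryMetrics(tp = 348, fn = 15, tn = 691, fp = 32)
  expect_equal(round(m2$sensitivity, 2), 95.87)
  expect_equal(round(m2$accuracy, 2), 95.67)
  expect_equal(round(m2$auc, 3), 0.957)

  # perfect classifier
  m3 <- binaryMetrics(tp = 7, fn = 0, tn = 11, fp = 0)
  expect_equal(m3$sensitivity, 100)
  expect_equal(m3$specificity, 100)
  expect_equal(m3$accuracy, 100)
  expect_equal(m3$auc, 1)

  expect_error(binaryMetrics(0, 0, 5, 5), "sensitivity",
               class = "ddhValidationError")
  expect_error(binaryMetrics(5, 5, 0, 0), "specificity",
               class = "ddhValidationError")
})

test_that("DeLong comparison handles endpoints and matches a bootstrap oracle", {
  truth <- rep(c(1, 0), each = 10)
  a <- c(0.9, 0.8, 0.7, 0.85, 0.6, 0.4, 0.95, 0.75, 0.65, 0.5,
         0.3, 0.2, 0.4, 0.5, 0.1, 0.6, 0.35, 0.25, 0.45, 0.15)
  b <- c(0.8, 0.6, 0.9, 0.5, 0.7, 0.3, 0.85, 0.65, 0.4, 0.55,
         0.4, 0.3, 0.2, 0.6, 0.5, 0.45, 0.1, 0.35, 0.55, 0.25)

  # identical scores: zero difference reported as z = 0, p = 1
  same <- delongPaired(truth, a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_equal(same$aucA, bruteAUC(truth, a))

  # endpoint AUCs: perfect vs uninformative scorer
  ends <- delongPaired(truth, truth, rep(0.5, 20))
  expect_equal(ends$aucA, 1)
  expect_equal(ends$aucB, 0.5)

  # paired bootstrap oracle for the AUC-difference test
  res <- delongPaired(truth, a, b)
  expect_equal(res$aucA, bruteAUC(truth, a))
  expect_equal(res$aucB, bruteAUC(truth, b))
  set.seed(1234)
  pos <- which(truth == 1); neg <- which(truth == 0)
  diffs <- replicate(20000, {
    ip <- sample(pos, replace = TRUE); ineg <- sample(neg, replace = TRUE)
    i <- c(ip, ineg); t2 <- truth[i]
    bruteAUC(t2, a[i]) - bruteAUC(t2, b[i])
  })
  zBoot <- (res$aucA - res$aucB) / sd(diffs)
  pBoot <- 2 * pnorm(-abs(zBoot))
  expect_lt(abs(res$p - pBoot), 0.02)

  expect_error(delongPaired(rep(1, 5), 1:5, 1:5), "degenerate",
               class = "ddhValidationError")
})

test_that("Bland-Altman limits match hand computation", {
  # d = (0, 2, 4): bias 2, sd 2, limits -1.92 .. 5.92
  r <- blandAltman(c(10, 12, 14), c(10, 10, 10))
  expect_equal(r$bias, 2)
  expect_equal(r$loaLow, 2 - 1.96 * 2)
  expect_equal(r$loaHigh, 2 + 1.96 * 2)
  expect_equal(r$biasP, t.test(c(0, 2, 4))$p.value)

  # identical nonconstant series: all zero, p treated as 1
  r0 <- blandAltman(c(1, 5, 9), c(1, 5, 9))
  expect_equal(c(r0$bias, r0$loaLow, r0$loaHigh), c(0, 0, 0))
  expect_equal(r0$biasP, 1)

  # constant offset: zero-width limits around the bias
  r1 <- blandAltman(c(2, 3, 4) + 1, c(2, 3, 4))
  expect_equal(r1$bias, 1)
  expect_equal(r1$loaHigh - r1$loaLow, 0)
  expect_equal(r1$biasP, 0)

  expect_error(blandAltman(1, 1), class = "ddhValidationError")
})

test_that("ICC(A,1) matches the mean-square formula and its limits", {
  expect_equal(iccAgreement(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)

  # 6 subjects x 2 raters: evaluate the two-way ANOVA MS formula directly
  a <- c(9, 6, 8, 7, 10, 6)
  b <- c(2, 1, 4, 1, 5, 2)
  n <- 6; k <- 2
  grand <- mean(c(a, b))
  subj <- (a + b) / 2
  rat <- c(mean(a), mean(b))
  msr <- k * sum((subj - grand)^2) / (n - 1)
  msc <- n * sum((rat - grand)^2) / (k - 1)
  sst <- sum((c(a, b) - grand)^2)
  mse <- (sst - k * sum((subj - grand)^2) - n * sum((rat - grand)^2)) /
    ((n - 1) * (k - 1))
  manual <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(iccAgreement(a, b), manual)

  # independent noise: ICC near zero
  set.seed(55)
  expect_lt(abs(iccAgreement(rnorm(500), rnorm(500))), 0.1)

  expect_error(iccAgreement(c(2, 2, 2), c(2, 2, 2)), "between-subject",
               class = "ddhValidationError")
  expect_error(iccAgreement(1:2, 1:2), class = "ddhValidationError")
})

test_that("weighted kappa matches the linear-weight formula and its limits", {
  expect_equal(weightedKappa(c(1, 2, 3, 1), c(1, 2, 3, 1), 1:3), 1)

  # 3-category contingency evaluated by the formula directly:
  # r1/r2 pairs giving counts: (1,1)x3 (1,2)x1 (2,2)x4 (2,3)x2 (3,3)x5 (3,1)x1
  r1 <- c(rep(1, 4), rep(2, 6), rep(3, 6))
  r2 <- c(1, 1, 1, 2, 2, 2, 2, 2, 3, 3, 3, 3, 3, 3, 3, 1)
  n <- length(r1)
  O <- table(factor(r1, levels = 1:3), factor(r2, levels = 1:3)) / n
  E <- outer(rowSums(O), colSums(O))
  w <- abs(outer(1:3, 1:3, "-")) / 2
  manual <- 1 - sum(w * O) / sum(w * E)
  expect_equal(weightedKappa(r1, r2, 1:3), manual)

  # independent uniform ratings: kappa near zero
  set.seed(99)
  expect_lt(abs(weightedKappa(sample(1:4, 2000, TRUE),
                              sample(1:4, 2000, TRUE), 1:4)), 0.1)

  expect_error(weightedKappa(c(1, 1, 1), c(1, 2, 3), 1:3), "single category",
               class = "ddhValidationError")
  expect_error(weightedKappa(c(1, 5), c(1, 2), 1:3), class = "ddhValidationError")
})

test_that("confusion matrices tally labels exactly and conserve counts", {
  labs <- c("normal", "other", "ihdi1", "ihdi2", "ihdi3", "ihdi4")
  x <- c("normal", "ihdi1", "ihdi1", "other")
  m <- multiclassConfusion(x, x, labs)
  expect_equal(sum(m), 4)
  expect_equal(unname(diag(m)), c(1, 1, 2, 0, 0, 0))
  expect_equal(sum(m) - sum(diag(m)), 0)

  empty <- multiclassConfusion(character(0), character(0), labs)
  expect_true(all(empty == 0))

  set.seed(7)
  truth <- sample(labs, 300, TRUE)
  pred <- sample(labs, 300, TRUE)
  m2 <- multiclassConfusion(truth, pred, labs)
  # brute-force tally oracle
  for (i in labs) for (j in labs)
    expect_equal(m2[i, j], sum(truth == i & pred == j))

  expect_error(multiclassConfusion(c("normal", "weird"), c("normal", "normal"),
                                   labs), class = "ddhValidationError")
})

test_that("the two-point AUC equals the DeLong AUC of binary predictions", {
  set.seed(31)
  truth <- rep(c(1, 0), c(40, 60))
  pred <- ifelse(runif(100) < 0.8, truth, 1 - truth)
  tp <- sum(truth == 1 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0); fp <- sum(truth == 0 & pred == 1)
  m <- binaryMetrics(tp, fn, tn, fp)
  d <- delongPaired(truth, pred, pred)
  expect_equal(m$auc, d$aucA)
  expect_true(m$sensitivity >= 0 && m$sensitivity <= 100)
  expect_true(m$auc >= 0 && m$auc <= 1)
})
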