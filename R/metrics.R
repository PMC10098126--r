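#' Rates and two-point AUC of a binary confusion table
#'
#' Sensitivity, specificity and accuracy (percent) from the four counts of
#' a binary confusion table, plus the area under the two-point ROC curve
#' of a single-threshold binary rater: the trapezoid through (0, 0),
#' (1 - specificity, sensitivity) and (1, 1), which equals
#' `(sensitivity + specificity) / 2` on the proportion scale. This is the
#' AUC a reader operating at one decision threshold realizes.
#'
#' @param tp,fn,tn,fp non-negative counts (true/false positives/negatives).
#' @return `list(sensitivity, specificity, accuracy, auc)`; rates in
#'   percent, `auc` in [0, 1].
#' @examples
#' m <- binaryMetrics(tp = 309, fn = 54, tn = 677, fp = 46)
#' round(m$auc, 3)            # 0.894
#' round(m$sensitivity, 2)    # 85.12
#' @export
binaryMetrics <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || anyNA(counts))
    ddhValidationStop("confusion counts must be non-negative")
  if (tp + fn == 0) ddhValidationStop("sensitivity undefined: tp + fn = 0")
  if (tn + fp == 0) ddhValidationStop("specificity undefined: tn + fp = 0")
  sens <- tp / (tp + fn) * 100
  spec <- tn / (tn + fp) * 100
  list(sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / sum(counts) * 100,
       auc = (sens + spec) / 200)
}

#' Compare two correlated AUCs with DeLong's paired test
#'
#' Estimates the Mann-Whitney AUC of each score vector against the common
#' binary truth and tests their difference with DeLong's method for
#' paired (same-case) ROC curves, via [pROC::roc.test()]. Identical score
#' vectors have zero difference and zero variance; this degenerate case
#' is reported as `z = 0`, `p = 1`.
#'
#' @param truth binary vector (0/1 or logical), at least one of each
#'   class.
#' @param scoresA,scoresB numeric scores aligned with `truth`; higher
#'   scores indicate the positive class.
#' @return `list(aucA, aucB, z, p)`.
#' @export
delongPaired <- function(truth, scoresA, scoresB) {
  truth <- as.integer(truth)
  if (!all(truth %in% c(0L, 1L)))
    ddhValidationStop("truth must be binary (0/1)")
  if (length(unique(truth)) < 2L)
    ddhValidationStop("degenerate truth: need both classes present")
  if (length(scoresA) != length(truth) || length(scoresB) != length(truth))
    ddhValidationStop("scores must be aligned with truth")
  rocA <- pROC::roc(truth, scoresA, levels = c(0, 1), direction = "<",
                    quiet = TRUE)
  rocB <- pROC::roc(truth, scoresB, levels = c(0, 1), direction = "<",
                    quiet = TRUE)
  if (identical(as.numeric(scoresA), as.numeric(scoresB)))
    return(list(aucA = as.numeric(pROC::auc(rocA)),
                aucB = as.numeric(pROC::auc(rocB)), z = 0, p = 1))
  tst <- pROC::roc.test(rocA, rocB, method = "delong", paired = TRUE)
  z <- as.numeric(tst$statistic)
  p <- as.numeric(tst$p.value)
  if (!is.finite(z)) { z <- 0; p <- 1 }
  list(aucA = as.numeric(pROC::auc(rocA)),
       aucB = as.numeric(pROC::auc(rocB)), z = z, p = p)
}

#' Bland-Altman agreement of two paired measurement series
#'
#' Bias (mean difference `a - b`), 95% limits of agreement
#' `bias +/- 1.96 sd` (sample standard deviation, n - 1 denominator), and
#' the two-sided p-value of a one-sample t-test of the differences
#' against zero. When the differences are constant the t statistic is
#' degenerate; the p-value is then 1 for zero bias and 0 otherwise.
#'
#' @param a,b equal-length numeric vectors (n >= 2) of paired
#'   measurements, e.g. two raters' angles in degrees.
#' @return `list(bias, loaLow, loaHigh, biasP)`.
#' @examples
#' blandAltman(c(10, 12, 14), c(10, 10, 10))   # bias 2, LoA -1.92..5.92
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b))
    ddhValidationStop("a and b must have equal length")
  if (length(a) < 2L)
    ddhValidationStop("need at least 2 pairs")
  if (anyNA(a) || anyNA(b)) ddhValidationStop("missing values not allowed")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  p <- if (s == 0) {
    if (bias == 0) 1 else 0
  } else stats::t.test(d)$p.value
  list(bias = bias, loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s,
       biasP = p)
}

#' Intraclass correlation for test-retest agreement
#'
#' ICC for a two-way model with absolute agreement, single measurement
#' (the standard choice for test-retest reliability of a continuous
#' measurement), computed from the mean squares of the two-way ANOVA of
#' the n x 2 measurement table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with `k = 2`.
#'
#' @param a,b equal-length numeric vectors (n >= 3): the two measurement
#'   occasions per subject.
#' @return the ICC point estimate (a single number <= 1).
#' @export
iccAgreement <- function(a, b) {
  if (length(a) != length(b))
    ddhValidationStop("a and b must have equal length")
  n <- length(a)
  if (n < 3L) ddhValidationStop("need at least 3 subjects")
  if (anyNA(a) || anyNA(b)) ddhValidationStop("missing values not allowed")
  if (stats::var((a + b) / 2) == 0)
    ddhValidationStop("ICC undefined: zero between-subject variance")
  df <- data.frame(value = c(a, b),
                   subject = factor(rep(seq_len(n), 2L)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(value ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  as.numeric((msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse)))
}

#' Cohen's linear weighted kappa
#'
#' Chance-corrected agreement of two raters on an ordered categorical
#' scale with linear disagreement weights `w_ij = |i - j| / (k - 1)`:
#' `kappa = 1 - sum(w O) / sum(w E)` where `O` is the observed and `E`
#' the chance-expected (marginal-product) proportion table.
#'
#' @param r1,r2 equal-length rating vectors; every value must appear in
#'   `categories`.
#' @param categories the ordered category list (k >= 2).
#' @return the kappa point estimate (a single number <= 1).
#' @export
weightedKappa <- function(r1, r2, categories) {
  k <- length(categories)
  if (k < 2L) ddhValidationStop("need at least 2 categories")
  if (length(r1) != length(r2))
    ddhValidationStop("r1 and r2 must have equal length")
  if (!all(r1 %in% categories) || !all(r2 %in% categories))
    ddhValidationStop("rating outside the declared category list")
  f1 <- factor(r1, levels = categories)
  f2 <- factor(r2, levels = categories)
  if (length(unique(r1)) < 2L || length(unique(r2)) < 2L)
    ddhValidationStop("kappa undefined: a rater used a single category")
  O <- table(f1, f2) / length(r1)
  E <- outer(rowSums(O), colSums(O))
  w <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  as.numeric(1 - sum(w * O) / sum(w * E))
}

#' Multi-class confusion matrix
#'
#' Tallies truth (rows) against prediction (columns) over a declared
#' label set, e.g. the specific hip classification (normal, other
#' dislocation, IHDI 1-4). Counts are conserved: the matrix sums to the
#' number of cases.
#'
#' @param truth,pred equal-length label vectors.
#' @param labels the ordered label list; every value of `truth` and
#'   `pred` must appear in it.
#' @return integer matrix with `labels` as dimnames.
#' @export
multiclassConfusion <- function(truth, pred, labels) {
  if (length(truth) != length(pred))
    ddhValidationStop("truth and pred must have equal length")
  if (!all(truth %in% labels) || !all(pred %in% labels))
    ddhValidationStop("label outside the declared label list")
  m <- table(factor(truth, levels = labels), factor(pred, levels = labels))
  m <- unclass(m)
  names(dimnames(m)) <- c("truth", "pred")
  m
}

#' Published confusion counts of the validation study
#'
#' The binary (DDH vs non-DDH, 1,086 hips) confusion counts printed for
#' the clinical validation of the diagnostic strategy: the conventional
#' manual method read by a junior and an intermediate orthopedist, and
#' the bounds of the software-assisted readings. These counts are inputs
#' for [binaryMetrics()]; they reproduce the published rates and
#' two-point AUCs.
#'
#' @return data.frame with columns `group`, `reader`, `tp`, `fn`, `tn`,
#'   `fp`.
#' @examples
#' cc <- reportedConfusionCounts()
#' with(cc[1, ], round(binaryMetrics(tp, fn, tn, fp)$auc, 3))   # 0.894
#' @export
reportedConfusionCounts <- function() {
  data.frame(
    group = c("conventional", "conventional", "software", "software"),
    reader = c("junior", "intermediate", "lower_bound", "upper_bound"),
    tp = c(309, 348, 356, 363),
    fn = c(54, 15, 7, 0),
    tn = c(677, 691, 720, 720),
    fp = c(46, 32, 3, 3))
}
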