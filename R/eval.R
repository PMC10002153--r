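# Segmentation evaluation (IoU, confusion maps) and the agreement-statistics
# battery used to compare measurement methods with an expert reference.

#' Pixel-wise segmentation evaluation
#'
#' Counts true-positive, false-positive and false-negative pixels of an
#' inferred mask against the ground truth and computes
#' `IoU = TP / (TP + FN + FP)`. The per-pixel confusion map uses the
#' conventional color code when plotted: green TP, orange FP, red FN.
#'
#' @param truth,inferred Logical masks of equal shape.
#' @param region Label carried through to reports: `"coronal"`, `"apical"`
#'   or `"overall"` (the overall region is conventionally the union of the
#'   two instance masks on each side).
#' @return Object of class `segmentation_eval`: counts, `iou`, `region`,
#'   a factor-coded `confusion_map`, and `degenerate = TRUE` when both masks
#'   are empty (IoU reported as 1).
#' @export
segmentation_eval <- function(truth, inferred, region = c("overall", "coronal", "apical")) {
  assert_mask(truth, "truth"); assert_mask(inferred, "inferred")
  region <- match.arg(region)
  if (!all(dim(truth) == dim(inferred))) {
    abort_shape_mismatch("truth and inferred masks must share a shape")
  }
  tp <- sum(truth & inferred)
  fp <- sum(!truth & inferred)
  fn <- sum(truth & !inferred)
  degenerate <- (tp + fp + fn) == 0L
  iou <- if (degenerate) 1.0 else tp / (tp + fn + fp)
  cm <- matrix("TN", nrow(truth), ncol(truth))
  cm[truth & inferred] <- "TP"
  cm[!truth & inferred] <- "FP"
  cm[truth & !inferred] <- "FN"
  structure(list(tp = tp, fp = fp, fn = fn, iou = iou, region = region,
                 confusion_map = cm, degenerate = degenerate),
            class = "segmentation_eval")
}

#' @export
print.segmentation_eval <- function(x, ...) {
  cat(sprintf("<segmentation_eval %s> IoU = %.4f (TP %d, FP %d, FN %d)%s\n",
              x$region, x$iou, x$tp, x$fp, x$fn,
              if (x$degenerate) " [both masks empty]" else ""))
  invisible(x)
}

#' @export
tidy.segmentation_eval <- function(x, ...) {
  tibble::tibble(region = x$region, tp = x$tp, fp = x$fp, fn = x$fn,
                 iou = x$iou, degenerate = x$degenerate)
}

#' Mean absolute error with sample standard deviation
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @return Named vector `c(mae, sd_ae)`; the SD uses the `n - 1` denominator.
#' @export
mae_sd <- function(x, y) {
  if (length(x) != length(y)) abort_shape_mismatch("x and y must have equal length")
  stopifnot(length(x) >= 2L)
  ae <- abs(x - y)
  c(mae = mean(ae), sd_ae = stats::sd(ae))
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the exact
#' t-transformation with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Named vector `c(r, p)`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort_shape_mismatch("x and y must have equal length")
  stopifnot(length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_constant_series("correlation is undefined for a constant series")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  c(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired two-sided Student t-test
#'
#' @param x,y Equal-length numeric vectors; the test runs on `d = x - y`
#'   with `n - 1` degrees of freedom.
#' @return Named vector `c(t, p)`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) abort_shape_mismatch("x and y must have equal length")
  stopifnot(length(x) >= 2L)
  d <- x - y
  if (stats::sd(d) == 0) {
    abort_constant_series("paired differences are all identical")
  }
  tt <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  c(t = unname(tt$statistic), p = tt$p.value)
}

#' McNemar test on paired binary decisions
#'
#' Counts the discordant pairs `n01` / `n10`. With fewer than
#' `exact_threshold` discordant pairs the two-sided exact binomial p-value
#' is used (standard for samples of a few dozen teeth); otherwise the
#' chi-square statistic `(n01 - n10)^2 / (n01 + n10)` on 1 df without
#' continuity correction.
#'
#' @param decisions_a,decisions_b Equal-length vectors over two labels.
#' @param exact_threshold Discordant-pair count at which the chi-square
#'   approximation takes over.
#' @return List with `statistic`, `p_value`, `n01`, `n10`, `method`.
#' @export
mcnemar_test <- function(decisions_a, decisions_b, exact_threshold = 25L) {
  if (length(decisions_a) != length(decisions_b)) {
    abort_shape_mismatch("decision vectors must have equal length")
  }
  lev <- sort(unique(c(as.character(decisions_a), as.character(decisions_b))))
  if (length(lev) > 2L) abort_label("decisions must be binary")
  if (length(lev) == 1L) lev <- c(lev, paste0("not_", lev))
  a <- as.character(decisions_a); b <- as.character(decisions_b)
  n01 <- sum(a == lev[1] & b == lev[2])
  n10 <- sum(a == lev[2] & b == lev[1])
  nd <- n01 + n10
  stat <- if (nd > 0L) (n01 - n10)^2 / nd else 0
  if (nd < exact_threshold) {
    p <- if (nd == 0L) 1.0 else stats::binom.test(n01, nd, p = 0.5)$p.value
    method <- "exact-binomial"
  } else {
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-square"
  }
  list(statistic = stat, p_value = p, n01 = n01, n10 = n10, method = method)
}

#' Fraction of identical paired decisions
#'
#' @param decisions_a,decisions_b Equal-length label vectors (length >= 1).
#' @return Proportion of positions where the labels agree.
#' @export
decision_agreement <- function(decisions_a, decisions_b) {
  if (length(decisions_a) != length(decisions_b)) {
    abort_shape_mismatch("decision vectors must have equal length")
  }
  stopifnot(length(decisions_a) >= 1L)
  mean(as.character(decisions_a) == as.character(decisions_b))
}

#' Full comparison report between two I3M series
#'
#' Bundles the statistics battery for comparing a method's I3M scores (and
#' minor/adult decisions) against a reference series, typically an expert:
#' MAE +/- SD of the absolute score error, Pearson correlation, paired
#' two-sided t-test, McNemar test on the decisions, and the raw decision
#' agreement fraction.
#'
#' @param scores,reference Equal-length numeric I3M vectors.
#' @param decisions,reference_decisions Optional label vectors; derived from
#'   the scores via [classify_age()] at `threshold` when absent.
#' @param threshold Decision cut-off.
#' @param alpha Type-1 error used when printing significance calls.
#' @return Object of class `i3m_comparison` with a [tidy()] method.
#' @export
compare_scores <- function(scores, reference,
                           decisions = NULL, reference_decisions = NULL,
                           threshold = 0.08, alpha = 0.01) {
  if (length(scores) != length(reference)) {
    abort_shape_mismatch("score vectors must have equal length")
  }
  if (is.null(decisions)) decisions <- classify_age(scores, threshold)
  if (is.null(reference_decisions)) reference_decisions <- classify_age(reference, threshold)
  err <- mae_sd(scores, reference)
  r <- tryCatch(pearson_r(scores, reference),
                i3m_error = function(e) c(r = NA_real_, p = NA_real_))
  tt <- tryCatch(paired_t_test(scores, reference),
                 i3m_error = function(e) c(t = NA_real_, p = NA_real_))
  mc <- mcnemar_test(decisions, reference_decisions)
  structure(list(mae = unname(err["mae"]), sd_ae = unname(err["sd_ae"]),
                 pearson_r = unname(r["r"]), pearson_p = unname(r["p"]),
                 t_stat = unname(tt["t"]), t_p = unname(tt["p"]),
                 mcnemar_stat = mc$statistic, mcnemar_p = mc$p_value,
                 mcnemar_method = mc$method,
                 agreement_fraction = decision_agreement(decisions, reference_decisions),
                 n = length(scores), alpha = alpha, threshold = threshold),
            class = "i3m_comparison")
}

#' @export
print.i3m_comparison <- function(x, ...) {
  cat(sprintf("<i3m_comparison> n = %d\n", x$n))
  cat(sprintf("  MAE +/- SD : %.4f +/- %.4f\n", x$mae, x$sd_ae))
  cat(sprintf("  Pearson r  : %.4f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  cat(sprintf("  paired t   : %.3f (p = %.3g, alpha = %.2g)\n", x$t_stat, x$t_p, x$alpha))
  cat(sprintf("  McNemar    : %.3f (p = %.3g, %s)\n", x$mcnemar_stat, x$mcnemar_p, x$mcnemar_method))
  cat(sprintf("  agreement  : %.1f%%\n", 100 * x$agreement_fraction))
  invisible(x)
}

#' @export
tidy.i3m_comparison <- function(x, ...) {
  tibble::tibble(mae = x$mae, sd_ae = x$sd_ae,
                 pearson_r = x$pearson_r, pearson_p = x$pearson_p,
                 t_stat = x$t_stat, t_p = x$t_p,
                 mcnemar_stat = x$mcnemar_stat, mcnemar_p = x$mcnemar_p,
                 agreement_fraction = x$agreement_fraction, n = x$n)
}

#' @export
glance.i3m_comparison <- function(x, ...) tidy(x)

#' Mean IoU over a set of segmentation evaluations
#'
#' Unweighted mean of the per-image IoU values.
#'
#' @param evals List of `segmentation_eval` objects (or numeric IoUs).
#' @return Mean IoU.
#' @export
mean_iou <- function(evals) {
  v <- vapply(evals, function(e) if (inherits(e, "segmentation_eval")) e$iou else as.numeric(e),
              numeric(1))
  mean(v)
}
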