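# Pairwise concordance (psi) matrix between positive and negative scores:
# 1 when the positive scores higher, 0.5 on ties, 0 otherwise.
psi_matrix <- function(pos, neg) {
  outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
}

#' Empirical (Mann-Whitney) AUROC
#'
#' Tie-aware concordance probability: the mean over all (positive,
#' negative) pairs of 1 / 0.5 / 0 as the positive scores higher / ties /
#' scores lower. Computed via midranks, equivalent to the pairwise mean.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels class labels, logical or 0/1 (1 = positive).
#' @return The AUROC as a bare number in `[0, 1]`.
#' @examples
#' empirical_auc(c(1, 2, 2, 3), c(0, 0, 1, 1))  # 0.875
#' @export
empirical_auc <- function(scores, labels) {
  labels <- check_labels(labels)
  stopifnot(length(scores) == length(labels))
  check_both_classes(labels)
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  r <- rank(scores)                      # midranks handle ties
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

#' AUROC with a DeLong confidence interval
#'
#' Nonparametric variance from the DeLong placement values: each positive's
#' mean concordance against all negatives and vice versa form the two
#' structural components, whose empirical variances give
#' `var(AUC) = S10/m + S01/n`. The normal-approximation interval is clipped
#' to `[0, 1]`. A degenerate zero variance (perfect separation) collapses
#' the CI to a point and is flagged.
#'
#' @inheritParams empirical_auc
#' @param level confidence level.
#' @return A list of class `nicpw_roc`: `auc`, `ci_low`, `ci_high`, `se`,
#'   `n_pos`, `n_neg`, `level`, `method = "delong"`, `degenerate` flag, and
#'   the ROC `curve` (tibble of sensitivity/specificity at every cutoff).
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  labels <- check_labels(labels)
  stopifnot(length(scores) == length(labels))
  check_both_classes(labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos)
  n <- length(neg)
  if (m < 2 || n < 2) abort("need at least 2 observations per class.")

  psi <- psi_matrix(pos, neg)
  auc <- mean(psi)
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  v <- var(v10) / m + var(v01) / n
  degenerate <- v <= 0
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - level) / 2)

  cuts <- sort(unique(scores))
  curve <- tibble::tibble(
    cutoff = c(-Inf, cuts),
    sensitivity = vapply(c(-Inf, cuts), function(ct) mean(pos > ct), 1),
    specificity = vapply(c(-Inf, cuts), function(ct) mean(neg <= ct), 1)
  )

  structure(
    list(auc = auc,
         ci_low = max(0, auc - z * se),
         ci_high = min(1, auc + z * se),
         se = se, n_pos = m, n_neg = n, level = level,
         method = "delong", degenerate = degenerate, curve = curve),
    class = "nicpw_roc"
  )
}

#' Compare two paired AUROCs (DeLong test)
#'
#' Both score sets must be measured on the same subjects; the covariance of
#' the placement values accounts for the pairing. Two-sided p from the
#' normal reference.
#'
#' @param scores_a,scores_b paired scores on identical subjects.
#' @inheritParams empirical_auc
#' @return One-row tibble: `auc_a`, `auc_b`, `delta`, `z`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  labels <- check_labels(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    abort("`scores_a`, `scores_b` and `labels` must have equal length.")
  }
  check_both_classes(labels)
  ipos <- labels == 1
  psi_a <- psi_matrix(scores_a[ipos], scores_a[!ipos])
  psi_b <- psi_matrix(scores_b[ipos], scores_b[!ipos])
  m <- sum(ipos)
  n <- sum(!ipos)
  auc_a <- mean(psi_a)
  auc_b <- mean(psi_b)
  d10 <- rowMeans(psi_a) - rowMeans(psi_b)
  d01 <- colMeans(psi_a) - colMeans(psi_b)
  v <- var(d10) / m + var(d01) / n
  if (v <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- (auc_a - auc_b) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  tibble::tibble(auc_a = auc_a, auc_b = auc_b, delta = auc_a - auc_b,
                 z = z, p_value = p)
}

#' Sensitivity/specificity at a fixed cutoff
#'
#' Predicted positive iff `score > cutoff` (strict by default, matching the
#' printed clinical cutoffs); Wilson 95% intervals on both proportions.
#'
#' @inheritParams empirical_auc
#' @param cutoff decision cutoff.
#' @param strict if `TRUE`, positivity is `score > cutoff`, else `>=`.
#' @param level confidence level for the Wilson intervals.
#' @return One-row tibble of class `nicpw_cutoff`: `cutoff`, `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `sens_low`, `sens_high`, `specificity`,
#'   `spec_low`, `spec_high`.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff, strict = TRUE,
                                level = 0.95) {
  labels <- check_labels(labels)
  stopifnot(length(scores) == length(labels))
  check_both_classes(labels)
  pred <- if (strict) scores > cutoff else scores >= cutoff
  tp <- sum(pred & labels == 1)
  fn <- sum(!pred & labels == 1)
  fp <- sum(pred & labels == 0)
  tn <- sum(!pred & labels == 0)
  sens_ci <- wilson_ci(tp, tp + fn, level)
  spec_ci <- wilson_ci(tn, tn + fp, level)
  out <- tibble::tibble(
    cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn),
    sens_low = sens_ci[["low"]], sens_high = sens_ci[["high"]],
    specificity = tn / (tn + fp),
    spec_low = spec_ci[["low"]], spec_high = spec_ci[["high"]]
  )
  class(out) <- c("nicpw_cutoff", class(out))
  out
}

#' Youden-optimal cutoff
#'
#' Maximises `J = sensitivity + specificity - 1` over the midpoints of
#' adjacent sorted unique scores (strict `>` positivity); ties go to the
#' lowest cutoff.
#'
#' @inheritParams empirical_auc
#' @return One-row tibble: `cutoff`, `J`, `sensitivity`, `specificity`.
#' @export
youden_optimal <- function(scores, labels) {
  labels <- check_labels(labels)
  check_both_classes(labels)
  u <- sort(unique(scores))
  cuts <- if (length(u) == 1) u else (u[-1] + u[-length(u)]) / 2
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  sens <- vapply(cuts, function(ct) mean(pos > ct), 1)
  spec <- vapply(cuts, function(ct) mean(neg <= ct), 1)
  j <- sens + spec - 1
  i <- which.max(j)        # first max = lowest cutoff on the sorted grid
  tibble::tibble(cutoff = cuts[i], J = j[i],
                 sensitivity = sens[i], specificity = spec[i])
}

#' Pearson correlation with a t-based test
#'
#' @param x,y numeric vectors, `n >= 3`, non-constant.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined.")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' @export
print.nicpw_roc <- function(x, ...) {
  cat(sprintf("AUROC %.3f [%d%% CI %.3f-%.3f], DeLong; n_pos=%d, n_neg=%d%s\n",
              x$auc, round(100 * x$level), x$ci_low, x$ci_high,
              x$n_pos, x$n_neg,
              if (x$degenerate) " (degenerate variance)" else ""))
  invisible(x)
}

#' @export
tidy.nicpw_roc <- function(x, ...) x$curve

#' @export
glance.nicpw_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
                 se = x$se, n_pos = x$n_pos, n_neg = x$n_neg,
                 level = x$level, method = x$method,
                 degenerate = x$degenerate)
}
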