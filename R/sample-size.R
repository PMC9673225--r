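# Hanley-McNeil exponential-approximation variance of an empirical AUROC.
hanley_mcneil_var <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
      (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
}

#' Sample size for testing an AUROC against a null value
#'
#' Smallest total n (respecting the negative:positive allocation ratio)
#' such that a two-sided alpha-level test of `H0: AUC = auc_null` attains
#' the target power at `AUC = auc_alt`, using the Hanley-McNeil
#' exponential-approximation variance under both hypotheses:
#' `z_{1-alpha/2} * SE0 + z_{power} * SE1 <= auc_alt - auc_null`.
#' Solved by integer search over the positive-class count.
#'
#' @param auc_alt alternative-hypothesis AUROC (`auc_null < auc_alt < 1`).
#' @param auc_null null-hypothesis AUROC (>= 0.5).
#' @param power target power in (0, 1).
#' @param alpha two-sided significance level in (0, 1).
#' @param neg_pos_ratio negatives per positive (>= 1).
#' @return One-row tibble: `n_total`, `n_pos`, `n_neg`.
#' @export
auc_sample_size <- function(auc_alt, auc_null = 0.6, power = 0.8,
                            alpha = 0.05, neg_pos_ratio = 1) {
  if (!(auc_null >= 0.5 && auc_null < auc_alt && auc_alt < 1)) {
    abort("infeasible: need 0.5 <= auc_null < auc_alt < 1.")
  }
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1, neg_pos_ratio >= 1)
  z_a <- qnorm(1 - alpha / 2)
  z_b <- qnorm(power)
  delta <- auc_alt - auc_null
  for (n_pos in 2:100000) {
    n_neg <- max(2L, as.integer(ceiling(neg_pos_ratio * n_pos)))
    se0 <- sqrt(hanley_mcneil_var(auc_null, n_pos, n_neg))
    se1 <- sqrt(hanley_mcneil_var(auc_alt, n_pos, n_neg))
    if (z_a * se0 + z_b * se1 <= delta) {
      return(tibble::tibble(n_total = n_pos + n_neg,
                            n_pos = n_pos, n_neg = n_neg))
    }
  }
  abort("no feasible n below 100000 positives.")
}

#' Simulated power of the AUROC test at a given design
#'
#' Monte-Carlo check of [auc_sample_size()]: draws equal-variance binormal
#' scores with true AUROC `auc_alt`, computes the empirical AUROC, and
#' rejects when it exceeds the null by `z_{1-alpha/2}` null-hypothesis
#' Hanley-McNeil standard errors (the same critical region the sample-size
#' search assumes).
#'
#' @inheritParams auc_sample_size
#' @param n_pos,n_neg class sizes.
#' @param n_rep Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return Estimated power (a bare number).
#' @export
simulate_auc_power <- function(auc_alt, auc_null = 0.6, alpha = 0.05,
                               n_pos, n_neg, n_rep = 2000, seed = 1L) {
  stopifnot(auc_alt > 0.5, auc_alt < 1)
  delta_mu <- sqrt(2) * qnorm(auc_alt)
  z_a <- qnorm(1 - alpha / 2)
  se0 <- sqrt(hanley_mcneil_var(auc_null, n_pos, n_neg))
  crit <- auc_null + z_a * se0
  with_local_seed(seed, {
    mean(vapply(seq_len(n_rep), function(i) {
      sc <- c(rnorm(n_pos, delta_mu, 1), rnorm(n_neg, 0, 1))
      lb <- rep(c(1L, 0L), c(n_pos, n_neg))
      empirical_auc(sc, lb) > crit
    }, logical(1)))
  })
}
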