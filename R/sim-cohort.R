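#' Calibrate a binormal score model to printed operating points
#'
#' Finds the means and SDs of two normal score distributions (IHT-positive
#' and IHT-negative patients on the P2/P1 scale) that jointly reproduce a
#' target AUROC together with a target sensitivity and specificity at a
#' stated cutoff:
#' \deqn{P(X_{pos} > c) = sens,\quad P(X_{neg} \le c) = spec,\quad
#'       \Phi\!\big((\mu_{pos}-\mu_{neg})/\sqrt{\sigma_{pos}^2+\sigma_{neg}^2}\big) = AUC.}
#' Three equations in four unknowns: `sd_neg` is held fixed (default 0.15,
#' keeping negative-class ratios in a physiologic band around the cutoff) and
#' the remaining system is solved numerically. When the AUC equation admits
#' two positive-SD roots, the root on the decreasing branch of
#' `AUC(sd_pos)` beyond its maximum is taken (the wider-positive-class
#' solution). Residuals of all three equations are verified to be < 1e-8.
#'
#' @param target_auc target AUROC, in (0.5, 1).
#' @param target_sens,target_spec target sensitivity/specificity in (0, 1).
#' @param cutoff the operating cutoff (scores strictly above are positive).
#' @param sd_neg fixed SD of the negative class (> 0).
#' @return A list of class `nicpw_binormal`: `mu_pos`, `sd_pos`, `mu_neg`,
#'   `sd_neg`, plus the targets.
#' @examples
#' calibrate_binormal()  # defaults reproduce AUROC 0.88, sens 85%, spec 77%
#' @export
calibrate_binormal <- function(target_auc = 0.88, target_sens = 0.85,
                               target_spec = 0.77, cutoff = 1.2,
                               sd_neg = 0.15) {
  if (!(target_auc > 0.5 && target_auc < 1)) {
    abort("calibration infeasible: `target_auc` must lie in (0.5, 1).")
  }
  stopifnot(target_sens > 0, target_sens < 1,
            target_spec > 0, target_spec < 1,
            is.finite(cutoff), sd_neg > 0)

  mu_neg <- cutoff - qnorm(target_spec) * sd_neg
  mu_pos_of <- function(s) cutoff + qnorm(target_sens) * s
  auc_of <- function(s) {
    pnorm((mu_pos_of(s) - mu_neg) / sqrt(s^2 + sd_neg^2))
  }

  lo <- 1e-6; hi <- 50
  pk <- optimize(auc_of, c(lo, hi), maximum = TRUE)
  f <- function(s) auc_of(s) - target_auc
  root <- NULL
  if (f(pk$maximum) >= 0 && f(hi) <= 0) {
    root <- uniroot(f, c(pk$maximum, hi), tol = 1e-12)$root
  } else if (f(lo) <= 0 && f(pk$maximum) >= 0) {
    root <- uniroot(f, c(lo, pk$maximum), tol = 1e-12)$root
  }
  if (is.null(root) || root <= 0) {
    abort("calibration infeasible: no positive-SD solution in the search box.")
  }

  out <- list(mu_pos = mu_pos_of(root), sd_pos = root,
              mu_neg = mu_neg, sd_neg = sd_neg,
              target_auc = target_auc, target_sens = target_sens,
              target_spec = target_spec, cutoff = cutoff)
  resid <- c(
    (1 - pnorm(cutoff, out$mu_pos, out$sd_pos)) - target_sens,
    pnorm(cutoff, out$mu_neg, out$sd_neg) - target_spec,
    pnorm((out$mu_pos - out$mu_neg) /
            sqrt(out$sd_pos^2 + out$sd_neg^2)) - target_auc
  )
  if (max(abs(resid)) > 1e-8) {
    abort("calibration infeasible: residuals exceed 1e-8.")
  }
  structure(out, class = "nicpw_binormal")
}

#' Draw patient scores from a calibrated binormal model
#'
#' @param n number of patients.
#' @param prevalence fraction of positives (IHT) in (0, 1); the positive
#'   count is `round(n * prevalence)`.
#' @param params a [calibrate_binormal()] result.
#' @param seed RNG seed.
#' @return Tibble with `score` and `label` (1 = positive).
#' @export
draw_binormal_scores <- function(n, prevalence = 0.18,
                                 params = calibrate_binormal(), seed = 1L) {
  stopifnot(inherits(params, "nicpw_binormal"),
            n >= 2, prevalence > 0, prevalence < 1)
  n_pos <- round(n * prevalence)
  n_neg <- n - n_pos
  if (n_pos < 1 || n_neg < 1) abort("both classes must be non-empty.")
  with_local_seed(seed, {
    tibble::tibble(
      score = c(rnorm(n_pos, params$mu_pos, params$sd_pos),
                rnorm(n_neg, params$mu_neg, params$sd_neg)),
      label = rep(c(1L, 0L), c(n_pos, n_neg))
    )
  })
}

# Log-normal fit to a (median, Q1, Q3) triple: the median fixes meanlog and
# the log-scale IQR fixes sdlog. Returns the fit and its analytic SD.
fit_lognormal_quartiles <- function(median, q1, q3) {
  if (!(q1 < median && median < q3)) {
    abort("infeasible quantile triple: need q1 < median < q3.")
  }
  meanlog <- log(median)
  sdlog <- (log(q3) - log(q1)) / (2 * qnorm(0.75))
  sd <- sqrt((exp(sdlog^2) - 1) * exp(2 * meanlog + sdlog^2))
  list(meanlog = meanlog, sdlog = sdlog, sd = sd)
}

#' Parameters of a simulated patient cohort
#'
#' Session mean ICP is drawn from a log-normal fitted to the stated
#' (median, Q1, Q3) triple (right-skewed, as session mICP summaries are),
#' and the session P2/P1 follows a linear link
#' `p2p1 = link_intercept + link_slope * micp + e`, `e ~ N(0, link_noise_sd)`,
#' truncated to `ratio_bounds`. When `link_noise_sd` is `NULL` it is derived
#' from the correlation identity `r = b * sigma / sqrt(b^2 sigma^2 + sigma_e^2)`
#' at `target_r`, with `sigma` the fitted log-normal's own SD, so the
#' realised cohort correlation lands on the target.
#'
#' @param n_patients cohort size.
#' @param prevalence_iht nominal IHT prevalence implied by the mICP fit
#'   (default 0.18); used by score-level simulations.
#' @param micp_median,micp_q1,micp_q3 mICP quartile targets, mmHg.
#' @param link_slope P2/P1 change per mmHg of mICP.
#' @param link_intercept link intercept (unitless).
#' @param link_noise_sd residual SD of the link; `NULL` = derive from
#'   `target_r`.
#' @param target_r target Pearson correlation between mICP and P2/P1.
#' @param ratio_bounds truncation interval for simulated ratios.
#' @param group_probs named probabilities of the short-term-outcome groups
#'   SB / MV / ED.
#' @param seed RNG seed.
#' @return An object of class `nicpw_cohort_params`.
#' @export
cohort_sim_params <- function(n_patients = 72,
                              prevalence_iht = 0.18,
                              micp_median = 14, micp_q1 = 11, micp_q3 = 19,
                              link_slope = 0.02, link_intercept = 0.82,
                              link_noise_sd = NULL, target_r = 0.49,
                              ratio_bounds = c(0.4, 2.2),
                              group_probs = c(SB = 15, MV = 47, ED = 10) / 72,
                              seed = 1L) {
  stopifnot(n_patients >= 1, prevalence_iht > 0, prevalence_iht < 1,
            length(ratio_bounds) == 2, ratio_bounds[1] < ratio_bounds[2],
            length(group_probs) == 3, all(group_probs >= 0))
  fit <- fit_lognormal_quartiles(micp_median, micp_q1, micp_q3)
  if (is.null(link_noise_sd)) {
    stopifnot(target_r > 0, target_r < 1)
    link_noise_sd <- link_slope * fit$sd * sqrt(1 / target_r^2 - 1)
  }
  if (link_noise_sd < 0) abort("`link_noise_sd` must be >= 0.")
  structure(
    list(n_patients = n_patients, prevalence_iht = prevalence_iht,
         micp_median = micp_median, micp_q1 = micp_q1, micp_q3 = micp_q3,
         link_slope = link_slope, link_intercept = link_intercept,
         link_noise_sd = link_noise_sd, target_r = target_r,
         ratio_bounds = ratio_bounds,
         group_probs = group_probs / sum(group_probs),
         lognormal_fit = fit, seed = seed),
    class = "nicpw_cohort_params"
  )
}

#' Simulate a patient cohort with ground truth
#'
#' One row per patient with session mean ICP, session P2/P1 from the linear
#' link, the brain compliance index `bci = micp * p2p1`, the intracranial
#' hypertension flag (`micp > 20`), a short-term-outcome group label, and
#' plausible covariates. Reproducible for a fixed seed.
#'
#' @param params a [cohort_sim_params()].
#' @return Tibble: `id`, `group`, `micp`, `p2p1`, `bci`, `iht`, `age`,
#'   `sex`, `pathology`, `neurosurgery`.
#' @examples
#' coh <- simulate_cohort(cohort_sim_params(n_patients = 72, seed = 3))
#' dplyr::count(coh, group, iht)
#' @export
simulate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "nicpw_cohort_params"))
  p <- params
  fit <- p$lognormal_fit
  with_local_seed(p$seed, {
    micp <- rlnorm(p$n_patients, fit$meanlog, fit$sdlog)
    ratio <- p$link_intercept + p$link_slope * micp +
      rnorm(p$n_patients, 0, p$link_noise_sd)
    ratio <- pmin(pmax(ratio, p$ratio_bounds[1]), p$ratio_bounds[2])
    group <- sample(names(p$group_probs), p$n_patients, replace = TRUE,
                    prob = p$group_probs)
    tibble::tibble(
      id = sprintf("pt%03d", seq_len(p$n_patients)),
      group = group,
      micp = micp,
      p2p1 = ratio,
      bci = micp * ratio,
      iht = micp > 20,
      age = pmin(pmax(round(rnorm(p$n_patients, 39, 21)), 18), 95),
      sex = sample(c("male", "female"), p$n_patients, replace = TRUE,
                   prob = c(0.65, 0.35)),
      pathology = sample(
        c("TBI", "SAH", "ischemic stroke", "hemorrhagic stroke", "neoplasm"),
        p$n_patients, replace = TRUE,
        prob = c(49, 12, 7, 3, 1) / 72),
      neurosurgery = sample(c("none", "craniotomy", "craniectomy"),
                            p$n_patients, replace = TRUE,
                            prob = c(17, 32, 21) / 70)
    )
  })
}
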