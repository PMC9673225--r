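#' Session mean ICP from per-minute means
#'
#' The session mICP is the mean of the per-minute ICP means, mirroring how
#' the per-minute averaged pulses are pooled.
#'
#' @param minute_icp_means numeric vector of per-minute ICP means, mmHg.
#' @return Session mICP, mmHg.
#' @export
session_micp <- function(minute_icp_means) {
  x <- minute_icp_means[is.finite(minute_icp_means)]
  if (length(x) == 0) abort("no minute ICP means supplied.")
  mean(x)
}

#' Brain compliance index
#'
#' `BCI = mICP x P2/P1` — the product couples the pressure level with the
#' pulse-morphology marker of exhausted compliance; it carries mmHg units
#' since the ratio is unitless.
#'
#' @param micp session mean ICP, mmHg (>= 0).
#' @param p2p1 session P2/P1 ratio (> 0).
#' @return BCI, mmHg. Vectorized.
#' @examples
#' compute_bci(21.5, 1.25)  # 26.875
#' @export
compute_bci <- function(micp, p2p1) {
  if (any(!is.finite(micp)) || any(!is.finite(p2p1))) {
    abort("`micp` and `p2p1` must be finite.")
  }
  if (any(micp < 0)) abort("`micp` must be >= 0.")
  if (any(p2p1 <= 0)) abort("`p2p1` must be > 0.")
  micp * p2p1
}

#' Threshold classifications for session metrics
#'
#' All cutoffs are strict (`>`), so boundary values classify negative:
#' intracranial hypertension is `micp > 20` mmHg, an elevated ratio is
#' `p2p1 > 1.2`, an elevated compliance index is `bci > 19.3` by default.
#'
#' @param metrics data frame with columns `micp`, `p2p1` and optionally
#'   `bci` (recomputed when absent).
#' @param iht_cutoff,p2p1_cutoff,bci_cutoff classification cutoffs.
#' @return `metrics` with added logical columns `iht`, `p2p1_high`,
#'   `bci_high` (and `bci` if it was missing).
#' @export
classify_sessions <- function(metrics, iht_cutoff = 20, p2p1_cutoff = 1.2,
                              bci_cutoff = 19.3) {
  stopifnot(is.data.frame(metrics),
            all(c("micp", "p2p1") %in% names(metrics)))
  if (!"bci" %in% names(metrics)) {
    metrics$bci <- compute_bci(metrics$micp, metrics$p2p1)
  }
  metrics |>
    dplyr::mutate(
      iht = .data$micp > iht_cutoff,
      p2p1_high = .data$p2p1 > p2p1_cutoff,
      bci_high = .data$bci > bci_cutoff
    )
}

#' Assemble a per-session metrics row
#'
#' @param micp session mean ICP, mmHg.
#' @param p2p1 session P2/P1 ratio.
#' @param n_valid_minutes number of QC-valid minutes behind the estimates.
#' @param config an [analysis_config()] supplying the cutoffs.
#' @return One-row tibble: `micp`, `p2p1`, `bci`, `iht`, `p2p1_high`,
#'   `bci_high`, `n_valid_minutes`.
#' @export
session_metrics <- function(micp, p2p1, n_valid_minutes,
                            config = analysis_config()) {
  out <- tibble::tibble(micp = micp, p2p1 = p2p1,
                        bci = compute_bci(micp, p2p1),
                        n_valid_minutes = n_valid_minutes)
  classify_sessions(out, config$iht_cutoff, config$p2p1_cutoff,
                    config$bci_cutoff)
}
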