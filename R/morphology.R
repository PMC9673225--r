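#' Locate P1/P2 (and P3) on an averaged pulse
#'
#' P1 is the highest local maximum with latency inside `p1_window` (fraction
#' of the cycle), P2 the highest local maximum inside `p2_window`; both
#' amplitudes are measured above the onset-trough baseline (the first sample
#' of the averaged pulse), which makes the P2/P1 ratio invariant to gain and
#' offset of the raw signal. When a window holds no local maximum the pulse
#' is searched for a shoulder — a zero-crossing of the second derivative
#' after 5-point smoothing (the common "P1 rides on the P2 upstroke"
#' morphology); when neither exists the window's maximal value is used and
#' the result flagged `merged-fallback`. Ties between equal maxima go to the
#' earlier latency. P3 is located in `p3_window` and reported but feeds no
#' downstream index.
#'
#' @param pulse numeric averaged pulse on the 100-point normalized base (any
#'   length >= 20 is accepted).
#' @param p1_window,p2_window,p3_window latency windows as fractions of the
#'   cycle; P1's window is closed, the others half-open `(lo, hi]`.
#' @return One-row tibble: `p1_amp`, `p2_amp`, `p3_amp`, `p1_lat`, `p2_lat`,
#'   `p3_lat`, `p2p1`, `time_to_peak`, `method`
#'   (`two-peaks`/`shoulder`/`merged-fallback`).
#' @examples
#' pm <- simulate_pulse(pulse_shape(), fs_hz = 200)
#' locate_peaks(pm$samples$value)
#' @export
locate_peaks <- function(pulse,
                         p1_window = c(0.05, 0.28),
                         p2_window = c(0.28, 0.60),
                         p3_window = c(0.60, 0.90)) {
  v <- as.numeric(pulse)
  L <- length(v)
  if (L < 20 || anyNA(v)) abort("invalid averaged pulse.")
  # peak-preserving denoising: residual minute-level noise otherwise
  # inflates the window maxima (a max-selection bias on the ratio)
  if (L >= 11) v <- signal::sgolayfilt(v, p = 3, n = 9)
  frac <- (seq_len(L) - 1) / (L - 1)
  baseline <- v[1]

  maxima <- local_maxima(v)
  sm <- moving_average(v, 5)
  d2 <- diff(sm, differences = 2)       # curvature at samples 2..L-1
  cross <- which(d2[-length(d2)] * d2[-1] < 0) + 1L   # sample index of crossing

  find_in <- function(win, closed_left) {
    idx <- if (closed_left) which(frac >= win[1] & frac <= win[2]) else
      which(frac > win[1] & frac <= win[2])
    if (length(idx) == 0) return(NULL)
    mx <- maxima[maxima %in% idx]
    if (length(mx) > 0) {
      i <- mx[which.max(v[mx])]
      return(list(idx = i, method = "peak"))
    }
    cr <- cross[cross %in% idx]
    if (length(cr) > 0) {
      i <- cr[which.max(v[cr])]
      return(list(idx = i, method = "shoulder"))
    }
    list(idx = idx[which.max(v[idx])], method = "merged")
  }

  p1 <- find_in(p1_window, closed_left = TRUE)
  p2 <- find_in(p2_window, closed_left = FALSE)
  p3 <- find_in(p3_window, closed_left = FALSE)
  if (is.null(p1) || is.null(p2)) abort("invalid averaged pulse.")

  p1_amp <- v[p1$idx] - baseline
  p2_amp <- max(0, v[p2$idx] - baseline)
  p3_amp <- if (is.null(p3)) NA_real_ else max(0, v[p3$idx] - baseline)
  if (p1_amp <= 0) abort("undefined ratio: P1 amplitude is zero.")

  method <- if (p1$method == "merged" || p2$method == "merged") {
    "merged-fallback"
  } else if (p1$method == "shoulder" || p2$method == "shoulder") {
    "shoulder"
  } else {
    "two-peaks"
  }

  tibble::tibble(
    p1_amp = p1_amp, p2_amp = p2_amp, p3_amp = p3_amp,
    p1_lat = frac[p1$idx], p2_lat = frac[p2$idx],
    p3_lat = if (is.null(p3)) NA_real_ else frac[p3$idx],
    p2p1 = p2_amp / p1_amp,
    time_to_peak = frac[which.max(v)],
    method = method
  )
}

#' P2/P1 amplitude ratio of a located morphology
#'
#' @param morph a one-row tibble (or list) with `p1_amp` and `p2_amp`.
#' @return The ratio `p2_amp / p1_amp`.
#' @export
p2p1_ratio <- function(morph) {
  if (!all(c("p1_amp", "p2_amp") %in% names(morph))) {
    abort("`morph` must carry `p1_amp` and `p2_amp`.")
  }
  p1 <- morph$p1_amp
  if (any(p1 <= 0)) abort("undefined ratio: P1 amplitude is zero.")
  morph$p2_amp / p1
}

#' Session-level P2/P1 from per-minute morphologies
#'
#' The session statistic pools the per-minute ratios of the minutes that
#' passed quality control; the default is the arithmetic mean (a median is
#' available via `stat`).
#'
#' @param minute_morphs tibble with a `p2p1` column and (optionally) a
#'   `valid` flag column; invalid minutes are excluded.
#' @param stat `"mean"` or `"median"`.
#' @return One-row tibble: `session_p2p1`, `n_minutes`.
#' @export
session_p2p1 <- function(minute_morphs, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  r <- minute_morphs$p2p1
  if ("valid" %in% names(minute_morphs)) r <- r[minute_morphs$valid]
  r <- r[is.finite(r)]
  if (length(r) == 0) abort("no valid minutes: session P2/P1 undefined.")
  tibble::tibble(
    session_p2p1 = if (stat == "mean") mean(r) else median(r),
    n_minutes = length(r)
  )
}
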