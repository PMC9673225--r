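#' Band-pass filter a raw pulsatile recording
#'
#' Zero-phase (forward-backward) 2nd-order Butterworth band-pass, default
#' 0.5--15 Hz: removes the DC level and respiratory-band baseline drift
#' while keeping the cardiac fundamental and the harmonics that carry the
#' P1/P2 sub-peak structure. Length is preserved and the output is
#' (numerically) zero-mean.
#'
#' @param x numeric signal (arbitrary units).
#' @param fs_hz sampling rate, Hz; must exceed twice the upper band edge.
#' @param band lower/upper passband edges, Hz.
#' @return Filtered numeric vector, same length as `x`.
#' @export
preprocess_signal <- function(x, fs_hz, band = c(0.5, 15)) {
  stopifnot(is.numeric(x), length(band) == 2, band[1] > 0, band[1] < band[2])
  if (length(x) < 2 * fs_hz) abort("need at least 2 s of signal.")
  if (fs_hz < 2 * band[2]) {
    abort("`fs_hz` must be at least twice the upper band edge.")
  }
  bf <- signal::butter(2, band / (fs_hz / 2), type = "pass")
  # reflection padding suppresses the forward/backward edge transients
  # (even reflection keeps a trough or peak sitting at the record edge)
  n <- length(x)
  pad <- min(n - 1, 3 * round(fs_hz))
  xc <- x - mean(x)
  xp <- c(xc[(pad + 1):2], xc, xc[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1):(pad + n)]
}

#' Detect pulse onsets (trough-to-trough segmentation anchors)
#'
#' Onsets are the troughs that open each cardiac cycle. The expected beat
#' period is first estimated from the autocorrelation peak in the 0.33--2 s
#' lag band; candidate troughs (local minima of a lightly smoothed copy) are
#' then accepted deepest-first under an adaptive refractory window of 0.6x
#' the period (never below 0.33 s), and each accepted trough is refined to
#' the exact local minimum of the unsmoothed signal. A trough sitting at the
#' very start of the recording is recovered when its depth is consistent
#' with the detected troughs. Every threshold is relative, so
#' detection is invariant to the gain and offset of the raw signal.
#'
#' @param filtered band-passed signal from [preprocess_signal()].
#' @param fs_hz sampling rate, Hz.
#' @return Integer vector of onset sample indices (1-based), increasing.
#' @export
detect_onsets <- function(filtered, fs_hz) {
  x <- as.numeric(filtered)
  n <- length(x)
  if (n < 5 * fs_hz) abort("need at least 5 s of signal.")
  if (sd(x) == 0) abort("no pulses detected: flat signal.")

  # beat period from the autocorrelation peak in the physiologic lag band
  lag_max <- min(ceiling(2 * fs_hz), n - 1)
  ac <- acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  band <- seq(max(2, ceiling(0.33 * fs_hz)), lag_max)
  cand_lags <- band[band + 1 <= length(ac)]
  if (length(cand_lags) == 0) abort("no pulses detected: signal too short.")
  acv <- ac[cand_lags + 1]
  mx <- local_maxima(acv)
  if (length(mx) == 0 || max(acv) < 0.15) {
    abort("no pulses detected: no autocorrelation peak in the 0.33-2 s band.")
  }
  # guard against subharmonics: a lag of 2 beats can edge out the
  # fundamental under beat-to-beat jitter, so take the smallest lag among
  # the near-maximal peaks
  strong <- mx[acv[mx] >= 0.7 * max(acv[mx])]
  period <- cand_lags[min(strong)]

  refractory <- max(round(0.33 * fs_hz), round(0.6 * period))

  sm <- moving_average(x, max(3, round(0.1 * period)))
  cand <- local_minima(sm)
  if (length(cand) == 0) abort("no pulses detected.")

  # deepest-first greedy selection under the refractory window
  ord <- cand[order(sm[cand])]
  blocked <- logical(n)
  keep <- logical(length(ord))
  for (i in seq_along(ord)) {
    c_i <- ord[i]
    if (!blocked[c_i]) {
      keep[i] <- TRUE
      lo <- max(1, c_i - refractory + 1L)
      hi <- min(n, c_i + refractory - 1L)
      blocked[lo:hi] <- TRUE
    }
  }
  onsets <- sort(ord[keep])

  # refine each trough within a narrow window; the smoothed signal keeps
  # sample noise from jittering the refined position (alignment jitter
  # smears the narrow P1 peak in the ensemble average)
  w <- max(1L, round(0.05 * period))
  sm_ref <- moving_average(x, max(3, round(0.03 * period)))
  onsets <- vapply(onsets, function(i) {
    lo <- max(1, i - w); hi <- min(n, i + w)
    (lo:hi)[which.min(sm_ref[lo:hi])]
  }, integer(1))
  onsets <- sort(unique(onsets))

  # depth consistency: a genuine trough sits near the level of its peers
  # (relative thresholds only, so gain/offset of the raw signal is moot)
  trough_lvl <- median(x[onsets])
  amp_ref <- diff(quantile(x, c(0.05, 0.95), names = FALSE))
  thr <- trough_lvl + 0.3 * amp_ref
  onsets <- onsets[x[onsets] <= thr]
  if (length(onsets) == 0) abort("no pulses detected.")

  # a terminal trough cannot anchor a following beat; drop it
  onsets <- onsets[onsets <= n - 0.25 * period]
  if (length(onsets) == 0) abort("no pulses detected.")

  # recover a leading trough the interior-minimum rule cannot see (the
  # session may open mid-valley)
  if (onsets[1] > refractory) {
    head_idx <- 1:(onsets[1] - refractory)
    j <- head_idx[which.min(x[head_idx])]
    if (x[j] <= thr) onsets <- c(j, onsets)
  }
  as.integer(onsets)
}

#' Cut a filtered recording into per-beat segments
#'
#' One segment per consecutive onset pair, half-open `[onset, end)` in
#' sample indices; the trailing partial beat (after the last onset) is
#' dropped. Each segment is assigned to the session minute containing its
#' onset.
#'
#' @param filtered band-passed signal.
#' @param onsets onset sample indices from [detect_onsets()].
#' @param fs_hz sampling rate, Hz.
#' @return Tibble: `minute_index` (0-based), `onset_idx`, `end_idx`,
#'   `samples` (list-column of numeric segments).
#' @export
segment_pulses <- function(filtered, onsets, fs_hz) {
  if (length(onsets) < 2) abort("need at least 2 onsets to form a segment.")
  onsets <- as.integer(onsets)
  start <- onsets[-length(onsets)]
  end <- onsets[-1]
  tibble::tibble(
    minute_index = as.integer((start - 1) %/% (60 * fs_hz)),
    onset_idx = start,
    end_idx = end,
    samples = purrr::map2(start, end, function(a, b) filtered[a:(b - 1L)])
  )
}

resample_100 <- function(x, n_out = 100L) {
  approx(seq_along(x), x, xout = seq(1, length(x), length.out = n_out))$y
}

#' Quality-control per-beat segments within each minute
#'
#' Each segment is resampled to the common 100-point normalized time base
#' and compared to the pointwise median pulse of its minute. A segment is
#' accepted iff its Pearson correlation with that median template is at
#' least `min_corr` and its peak-to-trough amplitude lies within
#' `amp_band` times the minute's median amplitude — motion artifacts fail
#' the amplitude band, distorted beats fail the correlation. A minute with
#' a single segment is accepted by convention (it is its own median).
#'
#' @param segments tibble from [segment_pulses()].
#' @param min_corr acceptance threshold on the template correlation.
#' @param amp_band multiplicative amplitude acceptance band.
#' @return `segments` with added columns `resampled` (list, length-100),
#'   `quality`, `amplitude`, `accepted`.
#' @export
filter_pulses <- function(segments, min_corr = 0.8, amp_band = c(0.3, 3)) {
  if (nrow(segments) < 1) abort("need at least one segment.")
  segments$resampled <- purrr::map(segments$samples, resample_100)
  segments$amplitude <- vapply(segments$samples,
                               function(s) diff(range(s)), numeric(1))
  out <- segments |>
    dplyr::group_by(.data$minute_index) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) == 1) {
        d$quality <- 1
        d$accepted <- TRUE
        return(d)
      }
      m <- do.call(rbind, d$resampled)
      template <- apply(m, 2, median)
      d$quality <- apply(m, 1, function(row) {
        if (sd(row) == 0 || sd(template) == 0) return(0)
        cor(row, template)
      })
      med_amp <- median(d$amplitude)
      d$accepted <- d$quality >= min_corr &
        d$amplitude >= amp_band[1] * med_amp &
        d$amplitude <= amp_band[2] * med_amp
      d
    }) |>
    dplyr::ungroup()
  out[order(out$onset_idx), ]
}

# Shift each row of the segment matrix (columns = normalized time) to the
# lag in -max_shift..max_shift that best correlates with the template,
# padding with the row's edge values. Residual onset-timing jitter
# otherwise smears the narrow P1 peak in the ensemble mean.
align_to_template <- function(m, template, max_shift = 6L) {
  L <- ncol(m)
  shifts <- -max_shift:max_shift
  t(apply(m, 1, function(row) {
    sc <- vapply(shifts, function(s) {
      if (s >= 0) {
        a <- row[(1 + s):L]; b <- template[1:(L - s)]
      } else {
        a <- row[1:(L + s)]; b <- template[(1 - s):L]
      }
      if (sd(a) == 0 || sd(b) == 0) return(-Inf)
      cor(a, b)
    }, numeric(1))
    s <- shifts[which.max(sc)]
    if (s > 0) c(row[(1 + s):L], rep(row[L], s))
    else if (s < 0) c(rep(row[1], -s), row[1:(L + s)])
    else row
  }))
}

#' Ensemble-average accepted pulses within each minute
#'
#' Pointwise mean of the accepted, time-normalized (100-point) segments of
#' each minute, after aligning each segment to the minute's median template
#' by cross-correlation over small lags (coherent averaging; unaligned
#' averaging lets onset-timing jitter smear the sharp percussion peak). A
#' minute is `valid` only when at least `min_pulses` beats contributed; a
#' minute with zero accepted beats yields an invalid row, not an error.
#'
#' @param segments QC'd tibble from [filter_pulses()].
#' @param min_pulses minimum accepted beats for a valid minute (default 30).
#' @return Tibble: `minute_index`, `n_pulses`, `n_total`, `valid`,
#'   `pulse` (list-column, length-100 mean pulse or NULL).
#' @export
average_by_minute <- function(segments, min_pulses = 30) {
  stopifnot("resampled" %in% names(segments), "accepted" %in% names(segments))
  segments |>
    dplyr::group_by(.data$minute_index) |>
    dplyr::summarise(
      n_pulses = sum(.data$accepted),
      n_total = dplyr::n(),
      pulse = list(
        if (sum(.data$accepted) > 0) {
          m <- do.call(rbind, .data$resampled[.data$accepted])
          if (nrow(m) > 1) {
            template <- apply(m, 2, median)
            m <- align_to_template(m, template)
          }
          colMeans(m)
        } else {
          NULL
        }
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(valid = .data$n_pulses >= min_pulses) |>
    dplyr::select("minute_index", "n_pulses", "n_total", "valid", "pulse")
}
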