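#' Analyse one recording end to end
#'
#' Raw samples to session metrics: band-pass filtering, trough-to-trough
#' beat segmentation, per-minute QC and ensemble averaging, P1/P2
#' localisation on each valid minute's averaged pulse, then the session
#' P2/P1 (pooled over valid minutes) and — when a co-recorded invasive ICP
#' channel is present — the session mICP (mean of per-minute means) and the
#' brain compliance index with its threshold classifications.
#'
#' @param recording either a data frame with columns `time_s`, `nicpw_au`
#'   and optionally `icp_mmhg`, a numeric vector of samples, or a
#'   `nicpw_sim` object from [simulate_recording()].
#' @param fs_hz sampling rate, Hz (taken from the object for `nicpw_sim`
#'   input; otherwise inferred from `time_s` when missing).
#' @param config an [analysis_config()].
#' @return A list of class `nicpw_session`: `minutes` (per-minute tibble:
#'   QC counts, validity, morphology, mean ICP), `session` (one-row metrics
#'   tibble), `qc` (accepted/rejected totals).
#' @examples
#' sim <- simulate_recording(session_sim_params(duration_s = 120, seed = 9))
#' fit <- analyze_recording(sim)
#' glance(fit)
#' @export
analyze_recording <- function(recording, fs_hz = NULL,
                              config = analysis_config()) {
  icp <- NULL
  if (inherits(recording, "nicpw_sim")) {
    fs_hz <- recording$fs_hz
    icp <- recording$recording$icp_mmhg
    x <- recording$recording$nicpw_au
  } else if (is.data.frame(recording)) {
    if (!all(c("time_s", "nicpw_au") %in% names(recording))) {
      abort("recording data frame needs `time_s` and `nicpw_au` columns.")
    }
    x <- recording$nicpw_au
    if ("icp_mmhg" %in% names(recording)) icp <- recording$icp_mmhg
    if (is.null(fs_hz)) {
      fs_hz <- 1 / median(diff(recording$time_s))
    }
  } else {
    x <- as.numeric(recording)
    if (is.null(fs_hz)) abort("`fs_hz` is required for bare numeric input.")
  }

  filtered <- preprocess_signal(x, fs_hz, band = config$band)
  onsets <- detect_onsets(filtered, fs_hz)
  segs <- segment_pulses(filtered, onsets, fs_hz)
  segs <- filter_pulses(segs, min_corr = config$qc_min_corr,
                        amp_band = config$qc_amp_band)
  avg <- average_by_minute(segs, min_pulses = config$min_pulses)

  morphs <- purrr::map2(avg$pulse, avg$valid, function(pl, ok) {
    if (!ok || is.null(pl)) return(NULL)
    tryCatch(
      locate_peaks(pl, config$p1_window, config$p2_window, config$p3_window),
      error = function(e) NULL
    )
  })
  morph_tbl <- dplyr::bind_rows(lapply(morphs, function(m) {
    if (is.null(m)) {
      tibble::tibble(p1_amp = NA_real_, p2_amp = NA_real_, p3_amp = NA_real_,
                     p1_lat = NA_real_, p2_lat = NA_real_, p3_lat = NA_real_,
                     p2p1 = NA_real_, time_to_peak = NA_real_,
                     method = NA_character_)
    } else {
      m
    }
  }))
  minutes <- dplyr::bind_cols(avg, morph_tbl)
  minutes$valid <- minutes$valid & is.finite(minutes$p2p1)

  if (!is.null(icp)) {
    minute_of <- as.integer(((seq_along(icp) - 1) / fs_hz) %/% 60)
    icp_means <- tapply(icp, minute_of, mean)
    minutes$icp_mean <- as.numeric(icp_means[as.character(minutes$minute_index)])
  } else {
    minutes$icp_mean <- NA_real_
  }

  sess_ratio <- session_p2p1(minutes, stat = config$session_stat)
  session <- if (!is.null(icp)) {
    micp <- session_micp(minutes$icp_mean[minutes$valid])
    session_metrics(micp, sess_ratio$session_p2p1,
                    sess_ratio$n_minutes, config)
  } else {
    tibble::tibble(micp = NA_real_, p2p1 = sess_ratio$session_p2p1,
                   bci = NA_real_, n_valid_minutes = sess_ratio$n_minutes,
                   iht = NA, p2p1_high = sess_ratio$session_p2p1 >
                     config$p2p1_cutoff, bci_high = NA)
  }

  structure(
    list(
      minutes = minutes,
      session = session,
      qc = tibble::tibble(
        n_segments = nrow(segs),
        n_accepted = sum(segs$accepted),
        n_rejected = sum(!segs$accepted),
        n_valid_minutes = sum(minutes$valid),
        n_minutes = nrow(minutes)
      )
    ),
    class = "nicpw_session"
  )
}

#' @export
print.nicpw_session <- function(x, ...) {
  s <- x$session
  cat("<nicpw_session>\n")
  cat(sprintf("  valid minutes: %d/%d (%d/%d beats accepted)\n",
              x$qc$n_valid_minutes, x$qc$n_minutes,
              x$qc$n_accepted, x$qc$n_segments))
  cat(sprintf("  session P2/P1: %.3f", s$p2p1))
  if (is.finite(s$micp)) {
    cat(sprintf("; mICP: %.1f mmHg; BCI: %.1f mmHg", s$micp, s$bci))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.nicpw_session <- function(x, ...) {
  dplyr::select(x$minutes, -"pulse")
}

#' @export
glance.nicpw_session <- function(x, ...) {
  x$session
}
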