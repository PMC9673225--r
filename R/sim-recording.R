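#' Parameters of a simulated monitoring session
#'
#' Bundles everything needed to synthesise a single monitoring session:
#' the pulse template, heart rate and its beat-to-beat variability,
#' respiratory-band baseline drift, additive sensor noise, motion
#' artifacts, and the constant true mean ICP driving the co-recorded
#' invasive channel. Defaults emulate a 10-minute bedside session
#' (>= 700 heart beats) sampled at 200 Hz.
#'
#' @param shape pulse template, a [pulse_shape()].
#' @param heart_rate_bpm mean heart rate, beats/min (in (20, 220)); the
#'   default 72 is typical of sedated neuro-ICU patients and keeps a
#'   10-minute session above 700 beats even with beat-to-beat jitter.
#' @param hr_jitter_frac relative beat-to-beat SD of the heart rate (>= 0).
#' @param drift_amp baseline drift amplitude (arbitrary units).
#' @param drift_freq_hz drift frequency, Hz (respiratory band).
#' @param noise_sd additive white-noise SD (arbitrary units).
#' @param artifact_rate_per_min expected motion artifacts per minute (>= 0).
#' @param duration_s total session length, s.
#' @param fs_hz sampling rate, Hz (>= 50).
#' @param micp_mmhg constant true mean ICP of the invasive channel, mmHg.
#' @param seed RNG seed (one seeded stream per call; no global state).
#' @return An object of class `nicpw_session_params`.
#' @export
session_sim_params <- function(shape = pulse_shape(),
                               heart_rate_bpm = 72,
                               hr_jitter_frac = 0.03,
                               drift_amp = 0.5,
                               drift_freq_hz = 0.25,
                               noise_sd = 0.08,
                               artifact_rate_per_min = 1,
                               duration_s = 600,
                               fs_hz = 200,
                               micp_mmhg = 14,
                               seed = 1L) {
  stopifnot(inherits(shape, "nicpw_shape"))
  if (heart_rate_bpm <= 20 || heart_rate_bpm >= 220) {
    abort("`heart_rate_bpm` must lie in (20, 220).")
  }
  if (hr_jitter_frac < 0 || noise_sd < 0 || artifact_rate_per_min < 0) {
    abort("jitter, noise and artifact rates must be >= 0.")
  }
  if (duration_s <= 0) abort("`duration_s` must be > 0.")
  if (fs_hz < 50) abort("`fs_hz` must be >= 50.")
  structure(
    list(shape = shape, heart_rate_bpm = heart_rate_bpm,
         hr_jitter_frac = hr_jitter_frac, drift_amp = drift_amp,
         drift_freq_hz = drift_freq_hz, noise_sd = noise_sd,
         artifact_rate_per_min = artifact_rate_per_min,
         duration_s = duration_s, fs_hz = fs_hz,
         micp_mmhg = micp_mmhg, seed = seed),
    class = "nicpw_session_params"
  )
}

#' Simulate a monitoring session with known ground truth
#'
#' Concatenates template pulses beat by beat (beat k lasts `60 / HR_k`
#' seconds, with `HR_k` drawn around the mean heart rate at the stated
#' relative jitter), then adds sinusoidal baseline drift, white noise, and
#' motion artifacts (0.3-s half-sine transients, 5x the pulse amplitude, at
#' Poisson times). The co-recorded invasive channel is the true mean ICP
#' plus a scaled, mean-centred copy of the clean pulsatile signal plus
#' measurement noise, so its per-minute means recover `micp_mmhg`.
#'
#' With zero jitter the number of generated onsets is exactly
#' `floor(duration_s / (60 / heart_rate_bpm))`; identical seeds give
#' bit-identical output.
#'
#' @param params a [session_sim_params()].
#' @return A list of class `nicpw_sim`: `recording` (tibble `time_s`,
#'   `nicpw_au`, `icp_mmhg`), `fs_hz`, and `truth` (onset times in s, the
#'   template's achieved `true_p2p1`, `true_micp`, artifact windows).
#' @examples
#' sim <- simulate_recording(session_sim_params(duration_s = 30, seed = 42))
#' length(sim$truth$onsets)
#' @export
simulate_recording <- function(params = session_sim_params()) {
  stopifnot(inherits(params, "nicpw_session_params"))
  p <- params
  base_period <- 60 / p$heart_rate_bpm
  if (p$duration_s < base_period) {
    abort("`duration_s` is too short for a single beat.")
  }

  with_local_seed(p$seed, {
    # --- beat schedule ------------------------------------------------
    onsets <- numeric(0)
    periods <- numeric(0)
    t <- 0
    repeat {
      hr_k <- p$heart_rate_bpm
      if (p$hr_jitter_frac > 0) {
        hr_k <- hr_k * (1 + p$hr_jitter_frac * rnorm(1))
        hr_k <- max(hr_k, 20)
      }
      per_k <- 60 / hr_k
      if (t + per_k > p$duration_s + 1e-9) break
      onsets <- c(onsets, t)
      periods <- c(periods, per_k)
      t <- t + per_k
    }
    if (length(onsets) == 0) abort("`duration_s` is too short for a single beat.")

    n <- round(p$duration_s * p$fs_hz)
    time_s <- (seq_len(n) - 1) / p$fs_hz
    # beats are summed with their Gaussian tails overlapping the
    # neighbouring cycles (as in the physiologic waveform); half a beat of
    # support on each side captures every non-negligible tail
    clean <- numeric(n)
    # a warm-up beat before t = 0 puts the first recorded trough in the
    # same periodic steady state as every later one
    gen_onsets <- c(-periods[1], onsets)
    gen_periods <- c(periods[1], periods)
    for (k in seq_along(gen_onsets)) {
      i0 <- max(1L, floor((gen_onsets[k] - 0.5 * gen_periods[k]) * p$fs_hz) + 1L)
      i1 <- min(ceiling((gen_onsets[k] + 1.5 * gen_periods[k]) * p$fs_hz), n)
      if (i0 > n) break
      idx <- i0:i1
      clean[idx] <- clean[idx] + eval_pulse(p$shape, time_s[idx] - gen_onsets[k],
                                            period = gen_periods[k])
    }

    # --- disturbances -------------------------------------------------
    drift <- p$drift_amp * sin(2 * pi * p$drift_freq_hz * time_s +
                                 runif(1, 0, 2 * pi))
    noise <- rnorm(n, 0, p$noise_sd)

    amp_ref <- diff(range(clean))
    n_art <- rpois(1, p$artifact_rate_per_min * p$duration_s / 60)
    art <- numeric(n)
    art_windows <- tibble::tibble(start = numeric(0), end = numeric(0))
    if (n_art > 0) {
      starts <- sort(runif(n_art, 0, max(p$duration_s - 0.3, 0)))
      for (s in starts) {
        j0 <- floor(s * p$fs_hz) + 1L
        j1 <- min(j0 + round(0.3 * p$fs_hz) - 1L, n)
        tloc <- (seq(j0, j1) - j0) / p$fs_hz
        art[j0:j1] <- art[j0:j1] + 5 * amp_ref * sin(pi * tloc / 0.3)
      }
      art_windows <- tibble::tibble(start = starts, end = starts + 0.3)
    }

    nicpw <- clean + drift + noise + art
    icp <- p$micp_mmhg + (clean - mean(clean)) * (3 / max(amp_ref, 1e-12)) +
      rnorm(n, 0, 0.3)

    truth <- list(
      onsets = onsets,
      # measured on the periodic steady-state waveform: that is the pulse a
      # trough-to-trough segment actually contains
      true_p2p1 = achieved_morphology(p$shape, periodic = TRUE)$p2p1,
      true_micp = p$micp_mmhg,
      artifact_windows = art_windows
    )
    structure(
      list(
        recording = tibble::tibble(time_s = time_s, nicpw_au = nicpw,
                                   icp_mmhg = icp),
        fs_hz = p$fs_hz,
        truth = truth
      ),
      class = "nicpw_sim"
    )
  })
}
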