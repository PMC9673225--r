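test_that("well-separated peaks are located to oracle accuracy", {
  sh <- pulse_shape_for_ratio(1.25, periodic = FALSE)
  out <- simulate_pulse(sh, 200)
  v100 <- approx(seq_along(out$samples$value), out$samples$value,
                 xout = seq(1, nrow(out$samples), length.out = 100))$y
  m <- locate_peaks(v100)
  expect_equal(m$method, "two-peaks")
  expect_equal(m$p2p1, 1.25, tolerance = 0.02)
  expect_lt(m$p1_lat, m$p2_lat)
})

test_that("a P2-free pulse falls back to shoulder or window maximum", {
  v <- simulate_pulse(pulse_shape(amp = c(1, 0, 0)), 200)$samples$value
  v100 <- approx(seq_along(v), v, xout = seq(1, length(v),
                                             length.out = 100))$y
  m <- locate_peaks(v100)
  expect_true(m$method %in% c("shoulder", "merged-fallback"))
  expect_lt(m$p2p1, 1)
})

test_that("the ratio is invariant to gain and offset of the pulse", {
  v <- simulate_pulse(pulse_shape(), 200)$samples$value
  v100 <- approx(seq_along(v), v, xout = seq(1, length(v),
                                             length.out = 100))$y
  m1 <- locate_peaks(v100)
  m2 <- locate_peaks(3.7 * v100 + 12)
  expect_equal(m2$p2p1, m1$p2p1, tolerance = 1e-12)
  expect_identical(m2$p1_lat, m1$p1_lat)
})

test_that("degenerate averaged pulses are rejected", {
  expect_error(locate_peaks(c(1, 2, 3)), "invalid")
  expect_error(locate_peaks(rep(NA_real_, 100)), "invalid")
  # monotone-decreasing pulse: P1 amplitude above onset is zero
  expect_error(locate_peaks(seq(1, 0, length.out = 100)), "undefined ratio")
})

test_that("p2p1_ratio divides the located amplitudes", {
  expect_equal(p2p1_ratio(list(p1_amp = 2, p2_amp = 2)), 1.0)
  expect_equal(p2p1_ratio(list(p1_amp = 1, p2_amp = 1.2)), 1.2)
  expect_error(p2p1_ratio(list(p1_amp = 0, p2_amp = 1)), "undefined")
  expect_error(p2p1_ratio(list(p2_amp = 1)), "p1_amp")
})

test_that("session ratio pools valid minutes only", {
  mm <- tibble::tibble(p2p1 = c(1.0, 1.2, 1.4), valid = TRUE)
  expect_equal(session_p2p1(mm)$session_p2p1, 1.2)
  expect_equal(session_p2p1(mm)$n_minutes, 3)
  one <- tibble::tibble(p2p1 = 0.9, valid = TRUE)
  expect_equal(session_p2p1(one)$session_p2p1, 0.9)
  mixed <- tibble::tibble(p2p1 = c(1.0, 99), valid = c(TRUE, FALSE))
  expect_equal(session_p2p1(mixed)$session_p2p1, 1.0)
  expect_equal(session_p2p1(tibble::tibble(p2p1 = c(1, 2), valid = TRUE),
                            stat = "median")$session_p2p1, 1.5)
  expect_error(session_p2p1(tibble::tibble(p2p1 = 1.1, valid = FALSE)),
               "no valid minutes")
})

test_that("estimated ratio is monotone in the generator's amp2", {
  est <- vapply(seq(0.5, 1.8, length.out = 7), function(a2) {
    v <- simulate_pulse(pulse_shape(amp = c(1, a2, 0.6)), 200)$samples$value
    v100 <- approx(seq_along(v), v,
                   xout = seq(1, length(v), length.out = 100))$y
    locate_peaks(v100)$p2p1
  }, numeric(1))
  expect_true(all(diff(est) >= -1e-9))
})

test_that("a session with known constant ratio is recovered within 0.05", {
  sh <- pulse_shape_for_ratio(1.15)
  sim <- simulate_recording(session_sim_params(shape = sh, seed = 17))
  fit <- analyze_recording(sim)
  expect_equal(fit$session$p2p1, 1.15, tolerance = 0.05)
})
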