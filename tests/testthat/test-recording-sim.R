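test_that("zero-jitter beat count is exactly floor(duration / period)", {
  p <- session_sim_params(heart_rate_bpm = 72, hr_jitter_frac = 0,
                          duration_s = 600, seed = 1)
  sim <- simulate_recording(p)
  expect_length(sim$truth$onsets, 720)        # floor(600 / (60/72))
  expect_true(all(diff(sim$truth$onsets) > 0))

  p2 <- session_sim_params(heart_rate_bpm = 60, hr_jitter_frac = 0,
                           duration_s = 61.5, seed = 1)
  expect_length(simulate_recording(p2)$truth$onsets, 61)
})

test_that("identical seeds give bit-identical recordings", {
  p <- session_sim_params(duration_s = 60, seed = 99)
  a <- simulate_recording(p)
  b <- simulate_recording(p)
  expect_identical(a$recording, b$recording)
  expect_identical(a$truth, b$truth)
  c <- simulate_recording(session_sim_params(duration_s = 60, seed = 100))
  expect_false(identical(a$recording$nicpw_au, c$recording$nicpw_au))
})

test_that("a default 10-minute session holds at least 700 beats", {
  sim <- simulate_recording(session_sim_params(seed = 4))
  expect_gte(length(sim$truth$onsets), 700)
})

test_that("simulator calls do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(simulate_recording(session_sim_params(duration_s = 30, seed = 8)))
  expect_identical(rnorm(1), before)
})

test_that("artifacts are recorded as windows and scale with the rate", {
  p <- session_sim_params(duration_s = 300, artifact_rate_per_min = 4,
                          seed = 21)
  sim <- simulate_recording(p)
  aw <- sim$truth$artifact_windows
  expect_gt(nrow(aw), 0)
  expect_equal(aw$end - aw$start, rep(0.3, nrow(aw)))
  p0 <- session_sim_params(duration_s = 300, artifact_rate_per_min = 0,
                           seed = 21)
  expect_equal(nrow(simulate_recording(p0)$truth$artifact_windows), 0)
})

test_that("too-short sessions error", {
  expect_error(
    simulate_recording(session_sim_params(duration_s = 0.4,
                                          heart_rate_bpm = 60)),
    "too short")
})

test_that("the invasive channel recovers the true mean ICP per minute", {
  sim <- simulate_recording(session_sim_params(duration_s = 180,
                                               micp_mmhg = 22, seed = 13))
  minute <- as.integer((sim$recording$time_s) %/% 60)
  mins <- tapply(sim$recording$icp_mmhg, minute, mean)
  expect_true(all(abs(mins - 22) < 0.5))
})
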