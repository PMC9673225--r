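# A deterministic 72-patient cohort with the printed per-group structure:
# 15 SB / 47 MV / 10 ED, IHT counts (3, 5, 5), P2/P1 > 1.2 counts (5, 19, 7).
make_printed_cohort <- function() {
  sizes <- c(SB = 15, MV = 47, ED = 10)
  iht_k <- c(SB = 3, MV = 5, ED = 5)
  high_k <- c(SB = 5, MV = 19, ED = 7)
  purrr::map_dfr(names(sizes), function(g) {
    n <- sizes[[g]]
    iht <- rep(c(TRUE, FALSE), c(iht_k[[g]], n - iht_k[[g]]))
    high <- rep(c(TRUE, FALSE), c(high_k[[g]], n - high_k[[g]]))
    tibble::tibble(
      id = paste0(g, seq_len(n)), group = g,
      micp = ifelse(iht, 25, 12),
      p2p1 = ifelse(high, 1.4, 1.0),
      iht = iht, p2p1_high = high,
      neurosurgery = "none"
    )
  })
}

test_that("overall categorical counts are sums over the group cells", {
  coh <- make_printed_cohort()
  tab <- build_summary_table(coh, variables = c("iht", "p2p1_high"))
  iht_row <- tab[tab$variable == "iht", ]
  expect_equal(iht_row$overall, "13 (18%)")
  expect_equal(iht_row$SB, "3 (20%)")
  expect_equal(iht_row$MV, "5 (11%)")
  expect_equal(iht_row$ED, "5 (50%)")
  high_row <- tab[tab$variable == "p2p1_high", ]
  expect_equal(high_row$overall, "31 (43%)")
})

test_that("empty variable lists and unknown labels are handled", {
  coh <- make_printed_cohort()
  expect_equal(nrow(build_summary_table(coh, variables = character(0))), 0)
  bad <- coh
  bad$group[1] <- "XX"
  expect_error(build_summary_table(bad, variables = "iht",
                                   groups = c("SB", "MV", "ED")),
               "unknown group label")
  expect_error(build_summary_table(coh, variables = "nope"),
               "unknown variables")
})

test_that("continuous rows are screened into the right format and test", {
  set.seed(44)
  coh <- make_printed_cohort()
  coh$age <- round(rnorm(72, 40, 10))          # passes normality screen
  tab <- build_summary_table(coh, variables = "age")
  expect_match(tab$overall, "±")
  expect_equal(tab$test_used, "anova")
  coh$skewed <- rlnorm(72, 2, 0.8)
  tab2 <- build_summary_table(coh, variables = "skewed")
  expect_match(tab2$overall, "\\(")
  expect_equal(tab2$test_used, "kruskal-wallis")
})

test_that("the craniectomy subgroup filter removes exactly the DC patients", {
  coh <- simulate_cohort(cohort_sim_params(seed = 5))
  coh$neurosurgery <- rep(c("craniectomy", "craniotomy", "none"),
                          length.out = 72)
  coh$neurosurgery[1:21] <- "craniectomy"
  coh$neurosurgery[22:72] <- rep(c("craniotomy", "none"), length.out = 51)
  out <- suppressMessages(subgroup_filter(coh, TRUE))
  expect_equal(nrow(out), 51)
  expect_equal(attr(out, "n_excluded"), 21)
  expect_false(any(out$neurosurgery == "craniectomy"))
  ident <- subgroup_filter(coh, FALSE)
  expect_equal(nrow(ident), 72)
  all_dc <- coh
  all_dc$neurosurgery <- "craniectomy"
  expect_warning(suppressMessages(subgroup_filter(all_dc, TRUE)),
                 "all patients excluded")
})

test_that("cohort CSV round-trips and bad rows are excluded with a warning", {
  coh <- simulate_cohort(cohort_sim_params(n_patients = 20, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_equal(back$micp, coh$micp)
  expect_equal(back$p2p1, coh$p2p1)

  lines <- readr::read_lines(path)
  lines[3] <- sub("^[^,]*,[^,]*,[^,]*,", "ptX,MV,not_a_number,", lines[3])
  lines[5] <- sub(",MV,", ",??,", lines[5])
  readr::write_lines(lines, path)
  expect_warning(cleaned <- read_cohort_csv(path), "invalid cohort row")
  expect_equal(nrow(cleaned), 18)
})

test_that("analysis configs validate, round-trip through JSON, and reject junk", {
  cfg <- analysis_config(p2p1_cutoff = 1.3, session_stat = "median")
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$p2p1_cutoff, 1.3)
  expect_equal(back$session_stat, "median")
  expect_error(analysis_config(iht_cutoff = Inf), "finite")
  expect_error(analysis_config(p1_window = c(0.3, 0.1)), "ordered")
  jsonlite::write_json(list(bogus_field = 1), path, auto_unbox = TRUE)
  expect_error(read_config(path), "unknown config fields")
})

test_that("the orchestrator runs end to end and is deterministic", {
  recs <- list(
    pt001 = simulate_recording(session_sim_params(duration_s = 120,
                                                  seed = 41)),
    pt002 = simulate_recording(session_sim_params(
      shape = preset_shape("poor-compliance"), micp_mmhg = 24,
      duration_s = 120, seed = 42))
  )
  cfg <- analysis_config(min_pulses = 30)
  coh <- simulate_cohort(cohort_sim_params(seed = 9))
  rep1 <- run_pipeline(cfg, recordings = recs)
  expect_equal(nrow(rep1$sessions), 2)
  expect_gt(rep1$sessions$p2p1[2], rep1$sessions$p2p1[1])
  expect_true(rep1$sessions$iht[2])

  # cohort-only path skips the pulse stages but still yields table + ROC
  rep2 <- run_pipeline(cfg, cohort = coh)
  expect_null(rep2$sessions)
  expect_s3_class(rep2$roc_iht, "nicpw_roc")
  expect_false(is.null(rep2$summary_table))
  expect_equal(rep2$correlation$n, 72)

  # rerun with the same config and inputs is identical
  rep3 <- run_pipeline(cfg, cohort = coh)
  expect_identical(glance(rep2$roc_iht), glance(rep3$roc_iht))
  expect_identical(rep2$cohort, rep3$cohort)
})

test_that("the DC-exclusion sensitivity analysis reruns the ROC analyses", {
  coh <- simulate_cohort(cohort_sim_params(n_patients = 150, seed = 18))
  cfg <- analysis_config(exclude_craniectomy = TRUE)
  rep <- suppressMessages(run_pipeline(cfg, cohort = coh))
  expect_false(is.null(rep$subgroup))
  expect_equal(rep$subgroup$n_retained + rep$subgroup$n_excluded, 150)
  expect_s3_class(rep$subgroup$roc_iht, "nicpw_roc")
})
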