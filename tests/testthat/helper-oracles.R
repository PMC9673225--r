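# Independent oracles used across the suite. These deliberately do not
# call the package's own internals.

# Dense-grid oracle for the achieved P2/P1 of a three-Gaussian pulse:
# evaluate the analytic sum on a fine grid and read off the local maxima
# inside the P1/P2 latency windows, relative to the onset value.
grid_oracle_ratio <- function(amp, lat, width, n_grid = 1e5,
                              periodic = FALSE) {
  fr <- seq(0, 1, length.out = n_grid)
  g <- function(f) {
    amp[1] * exp(-(f - lat[1])^2 / (2 * width[1]^2)) +
      amp[2] * exp(-(f - lat[2])^2 / (2 * width[2]^2)) +
      amp[3] * exp(-(f - lat[3])^2 / (2 * width[3]^2))
  }
  v <- g(fr)
  if (periodic) v <- v + g(fr + 1) + g(fr - 1)
  peaks <- which(diff(sign(diff(v))) < 0) + 1
  pick <- function(lo, hi) {
    in_win <- peaks[fr[peaks] > lo & fr[peaks] <= hi]
    if (length(in_win) == 0) return(NA_real_)
    max(v[in_win])
  }
  p1 <- pick(0.049, 0.28)
  p2 <- pick(0.28, 0.60)
  (p2 - v[1]) / (p1 - v[1])
}

# Brute-force pairwise AUROC (the Mann-Whitney concordance definition).
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Stratified bootstrap SE of the empirical AUROC.
bootstrap_auc_se <- function(scores, labels, n_boot = 2000, seed = 1) {
  set.seed(seed)
  ip <- which(labels == 1)
  ineg <- which(labels == 0)
  aucs <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    empirical_auc(scores[idx], labels[idx])
  }, numeric(1))
  sd(aucs)
}

# A small default-noise simulated session (shared fixture, built in code).
quiet_sim <- function(duration_s = 120, seed = 1, ...) {
  simulate_recording(session_sim_params(duration_s = duration_s,
                                        seed = seed, ...))
}
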