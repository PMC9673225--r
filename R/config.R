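#' Analysis configuration
#'
#' Central home for every tunable threshold of the pipeline. The printed
#' clinical cutoffs (IHT 20 mmHg, P2/P1 1.2, BCI 19.3) are defaults, not
#' constants, so sensitivity analyses can move them; QC thresholds and peak
#' windows are design defaults documented in the methods vignette.
#'
#' @param iht_cutoff mICP cutoff for intracranial hypertension, mmHg.
#' @param p2p1_cutoff elevated-ratio cutoff (strict `>`).
#' @param bci_cutoff elevated-BCI cutoff, mmHg (strict `>`).
#' @param band band-pass edges, Hz.
#' @param qc_min_corr minimum template correlation for beat acceptance.
#' @param qc_amp_band multiplicative amplitude acceptance band.
#' @param min_pulses minimum accepted beats for a valid minute.
#' @param p1_window,p2_window,p3_window peak-search latency windows
#'   (fractions of the cycle).
#' @param session_stat `"mean"` or `"median"` pooling of minute ratios.
#' @param exclude_craniectomy drop decompressive-craniectomy patients in
#'   cohort analyses (subgroup sensitivity analysis).
#' @param seed seed for every random element of a pipeline run.
#' @return A validated list of class `nicpw_config`.
#' @export
analysis_config <- function(iht_cutoff = 20, p2p1_cutoff = 1.2,
                            bci_cutoff = 19.3,
                            band = c(0.5, 15),
                            qc_min_corr = 0.8, qc_amp_band = c(0.3, 3),
                            min_pulses = 30,
                            p1_window = c(0.05, 0.28),
                            p2_window = c(0.28, 0.60),
                            p3_window = c(0.60, 0.90),
                            session_stat = c("mean", "median"),
                            exclude_craniectomy = FALSE,
                            seed = 1L) {
  session_stat <- match.arg(session_stat)
  cuts <- c(iht_cutoff, p2p1_cutoff, bci_cutoff)
  if (any(!is.finite(cuts))) abort("all cutoffs must be finite.")
  for (w in list(band, qc_amp_band, p1_window, p2_window, p3_window)) {
    if (length(w) != 2 || w[1] >= w[2]) abort("windows must be ordered pairs.")
  }
  structure(
    list(iht_cutoff = iht_cutoff, p2p1_cutoff = p2p1_cutoff,
         bci_cutoff = bci_cutoff, band = band,
         qc_min_corr = qc_min_corr, qc_amp_band = qc_amp_band,
         min_pulses = min_pulses, p1_window = p1_window,
         p2_window = p2_window, p3_window = p3_window,
         session_stat = session_stat,
         exclude_craniectomy = isTRUE(exclude_craniectomy),
         seed = as.integer(seed)),
    class = "nicpw_config"
  )
}

#' Read / write an analysis configuration as JSON
#'
#' @param path file path.
#' @param config an [analysis_config()].
#' @return `read_config()` returns a validated `nicpw_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config fields: ", paste(unknown, collapse = ", ")))
  }
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "nicpw_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
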