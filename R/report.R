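#' Run the full cohort analysis pipeline
#'
#' End-to-end orchestrator: optional raw recordings are analysed into
#' session metrics ([analyze_recording()]); the (supplied or derived)
#' cohort table is summarised ([build_summary_table()]); and the
#' diagnostic-accuracy analyses are run — the mICP~P2/P1 correlation, the
#' P2/P1 AUROC for intracranial hypertension with operating-point
#' performance at the configured cutoff, and the P2/P1 and BCI AUROCs for
#' early death with a paired DeLong comparison. With
#' `config$exclude_craniectomy` the same analyses are repeated on the
#' decompressive-craniectomy-free subgroup. Every random element is seeded
#' from the config, so reruns are byte-identical.
#'
#' @param config an [analysis_config()].
#' @param recordings optional named list of recordings (see
#'   [analyze_recording()] for accepted forms); names become patient ids.
#' @param cohort optional cohort tibble (as from [simulate_cohort()] or
#'   [read_cohort_csv()]); when recordings are also given, their session
#'   metrics replace the matching `micp`/`p2p1` columns by id.
#' @return A list of class `nicpw_report`: `sessions`, `cohort`,
#'   `summary_table`, `correlation`, `roc_iht`, `cutoff_iht`, `roc_ed`
#'   (P2/P1 and BCI, plus their paired comparison), and optionally
#'   `subgroup` (the same analyses after DC exclusion), `qc_log`.
#' @export
run_pipeline <- function(config = analysis_config(), recordings = NULL,
                         cohort = NULL) {
  stopifnot(inherits(config, "nicpw_config"))
  if (is.null(recordings) && is.null(cohort)) {
    abort("supply at least one recording or a cohort table.")
  }

  sessions <- NULL
  qc_log <- list()
  if (!is.null(recordings)) {
    ids <- names(recordings) %||% sprintf("rec%03d", seq_along(recordings))
    sessions <- purrr::map_dfr(seq_along(recordings), function(i) {
      fit <- tryCatch(
        analyze_recording(recordings[[i]], config = config),
        error = function(e) {
          abort(sprintf("stage analyze_recording [%s]: %s",
                        ids[i], conditionMessage(e)))
        }
      )
      qc_log[[ids[i]]] <<- fit$qc
      dplyr::bind_cols(tibble::tibble(id = ids[i]), fit$session)
    })
  }

  if (is.null(cohort)) {
    cohort <- sessions
  } else if (!is.null(sessions)) {
    keep <- setdiff(names(cohort),
                    c("micp", "p2p1", "bci", "iht", "p2p1_high", "bci_high"))
    cohort <- dplyr::inner_join(cohort[keep], sessions, by = "id")
  }
  cohort <- classify_sessions(cohort, config$iht_cutoff, config$p2p1_cutoff,
                              config$bci_cutoff)

  analyse_cohort <- function(coh) {
    out <- list(
      correlation = tryCatch(pearson_r(coh$micp, coh$p2p1),
                             error = function(e) NULL),
      summary_table = if ("group" %in% names(coh) &&
                          length(unique(coh$group)) >= 2) {
        build_summary_table(
          coh, intersect(c("age", "sex", "micp", "iht", "p2p1", "p2p1_high",
                           "bci", "pathology", "neurosurgery"), names(coh)))
      } else {
        NULL
      }
    )
    if (sum(coh$iht) >= 2 && sum(!coh$iht) >= 2) {
      out$roc_iht <- delong_ci(coh$p2p1, coh$iht)
      out$cutoff_iht <- confusion_at_cutoff(coh$p2p1, coh$iht,
                                            config$p2p1_cutoff)
    }
    if ("group" %in% names(coh)) {
      ed <- coh$group == "ED"
      if (length(unique(ed)) == 2 && sum(ed) >= 2) {
        out$roc_ed <- list(
          p2p1 = delong_ci(coh$p2p1, ed),
          bci = delong_ci(coh$bci, ed),
          comparison = delong_compare(coh$p2p1, coh$bci, ed)
        )
        out$cutoff_ed_bci <- confusion_at_cutoff(coh$bci, ed,
                                                 config$bci_cutoff)
      }
    }
    out
  }

  main <- analyse_cohort(cohort)
  report <- list(sessions = sessions, cohort = cohort,
                 summary_table = main$summary_table,
                 correlation = main$correlation,
                 roc_iht = main$roc_iht, cutoff_iht = main$cutoff_iht,
                 roc_ed = main$roc_ed, cutoff_ed_bci = main$cutoff_ed_bci,
                 qc_log = qc_log, config = config)
  if (config$exclude_craniectomy && "neurosurgery" %in% names(cohort)) {
    sub <- subgroup_filter(cohort, TRUE)
    report$subgroup <- c(analyse_cohort(sub),
                         list(n_excluded = attr(sub, "n_excluded"),
                              n_retained = nrow(sub)))
  }
  structure(report, class = "nicpw_report")
}

#' @export
print.nicpw_report <- function(x, ...) {
  cat("<nicpw_report>\n")
  cat(sprintf("  cohort: %d patients\n", nrow(x$cohort)))
  if (!is.null(x$correlation)) {
    cat(sprintf("  mICP ~ P2/P1: r = %.2f (p = %.3g)\n",
                x$correlation$r, x$correlation$p_value))
  }
  if (!is.null(x$roc_iht)) {
    cat(sprintf("  P2/P1 -> IHT: AUROC %.2f [%.2f-%.2f]\n",
                x$roc_iht$auc, x$roc_iht$ci_low, x$roc_iht$ci_high))
  }
  if (!is.null(x$roc_ed)) {
    cat(sprintf("  P2/P1 -> ED: AUROC %.2f; BCI -> ED: AUROC %.2f\n",
                x$roc_ed$p2p1$auc, x$roc_ed$bci$auc))
  }
  invisible(x)
}

#' Export the cohort scatter of mICP against P2/P1
#'
#' @param patients cohort tibble (`micp`, `p2p1`, optional `group`).
#' @param path CSV path.
#' @export
export_scatter_csv <- function(patients, path) {
  cols <- intersect(c("id", "group", "micp", "p2p1", "bci"), names(patients))
  readr::write_csv(patients[cols], path)
  invisible(path)
}
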