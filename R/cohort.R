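#' Read a cohort table from CSV
#'
#' Expected columns: `id`, `group` (SB/MV/ED), `micp`, `p2p1`, and
#' optionally `age`, `sex`, `pathology`, `neurosurgery`. Rows with a
#' malformed group label, non-finite mICP or non-positive ratio are dropped
#' with a warning naming the offending data rows; the run continues on the
#' clean remainder.
#'
#' @param path CSV file path.
#' @return A validated tibble with recomputed `bci` and `iht` columns.
#' @export
read_cohort_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    warn(paste0("malformed CSV cells in rows: ",
                paste(unique(pr$row), collapse = ", ")))
  }
  need <- c("id", "group", "micp", "p2p1")
  if (!all(need %in% names(df))) {
    abort(paste0("cohort CSV must have columns: ",
                 paste(need, collapse = ", ")))
  }
  df$micp <- suppressWarnings(as.numeric(df$micp))
  df$p2p1 <- suppressWarnings(as.numeric(df$p2p1))
  bad <- !(df$group %in% c("SB", "MV", "ED")) |
    !is.finite(df$micp) | df$micp < 0 |
    !is.finite(df$p2p1) | df$p2p1 <= 0
  if (any(bad)) {
    warn(paste0("excluding ", sum(bad), " invalid cohort row(s): ",
                paste(which(bad), collapse = ", ")))
    df <- df[!bad, ]
  }
  if (nrow(df) == 0) abort("no valid cohort rows.")
  df |>
    dplyr::mutate(bci = compute_bci(.data$micp, .data$p2p1)) |>
    classify_sessions()
}

#' Write a cohort table to CSV
#'
#' @param patients cohort tibble.
#' @param path output path.
#' @export
write_cohort_csv <- function(patients, path) {
  readr::write_csv(patients, path)
  invisible(path)
}

#' Subgroup filter: exclude decompressive-craniectomy patients
#'
#' Decompressive craniectomy alters cranial mechanics and may change the
#' deformation signal; the subgroup sensitivity analysis reruns everything
#' without those patients.
#'
#' @param patients cohort tibble with a `neurosurgery` column.
#' @param exclude_craniectomy if `FALSE`, the identity.
#' @return The filtered tibble; attribute `n_excluded` records the count.
#' @export
subgroup_filter <- function(patients, exclude_craniectomy = TRUE) {
  if (!exclude_craniectomy) {
    attr(patients, "n_excluded") <- 0L
    return(patients)
  }
  if (!"neurosurgery" %in% names(patients)) {
    abort("`patients` needs a `neurosurgery` column for the DC subgroup.")
  }
  keep <- patients$neurosurgery != "craniectomy"
  out <- patients[keep, ]
  attr(out, "n_excluded") <- sum(!keep)
  if (nrow(out) == 0) warn("all patients excluded by the craniectomy filter.")
  inform(sprintf("craniectomy subgroup filter: %d excluded, %d retained",
                 sum(!keep), sum(keep)))
  out
}

summary_cell_categorical <- function(k, n) {
  sprintf("%d (%d%%)", k, round(100 * k / n))
}

summary_cell_continuous <- function(x, normal) {
  if (normal) {
    sprintf("%.1f ± %.1f", mean(x), sd(x))
  } else {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.1f (%.1f–%.1f)", q[2], q[1], q[3])
  }
}

#' Build a cohort summary table
#'
#' One row per variable (and per level for multi-level categoricals) with
#' an overall cell, per-group cells, and the omnibus p-value from the
#' appropriate test: chi-square/Fisher for categoricals (expected-count
#' dispatch), ANOVA or Kruskal-Wallis for continuous variables
#' (Shapiro-Wilk screen). Overall categorical counts are computed by
#' summation across groups. Cells follow the usual clinical-table formats:
#' `count (%)`, `mean +/- SD`, or `median (Q1-Q3)`.
#'
#' @param patients cohort tibble with a `group` column.
#' @param variables character vector of columns to summarise; default =
#'   every column except `id` and `group`. Logical and character/factor
#'   columns are treated as categorical, numeric as continuous.
#' @param groups allowed group labels; any other label is an error. `NULL`
#'   (default) accepts whatever labels occur.
#' @return A tibble: `variable`, `level`, `overall`, one column per group,
#'   `p_value`, `test_used`.
#' @export
build_summary_table <- function(patients, variables = NULL, groups = NULL) {
  stopifnot(is.data.frame(patients), "group" %in% names(patients))
  seen <- sort(unique(as.character(patients$group)))
  if (!is.null(groups)) {
    bad <- setdiff(seen, groups)
    if (length(bad) > 0) {
      abort(paste0("unknown group label(s): ", paste(bad, collapse = ", ")))
    }
    seen <- intersect(groups, seen)
  }
  groups <- seen
  if (length(groups) < 2) abort("need at least 2 groups.")
  if (is.null(variables)) {
    variables <- setdiff(names(patients), c("id", "group"))
  }
  missing_vars <- setdiff(variables, names(patients))
  if (length(missing_vars) > 0) {
    abort(paste0("unknown variables: ", paste(missing_vars, collapse = ", ")))
  }
  if (length(variables) == 0) {
    out <- tibble::tibble(variable = character(0), level = character(0),
                          overall = character(0))
    for (g in groups) out[[g]] <- character(0)
    out$p_value <- numeric(0)
    out$test_used <- character(0)
    return(out)
  }

  by_group <- split(patients, as.character(patients$group))[groups]
  n_by_group <- vapply(by_group, nrow, integer(1))
  n_all <- sum(n_by_group)

  rows <- purrr::map_dfr(variables, function(v) {
    x <- patients[[v]]
    if (is.numeric(x)) {
      normal <- all(vapply(by_group, function(d) {
        s <- d[[v]][is.finite(d[[v]])]
        if (length(s) < 3 || sd(s) == 0) return(FALSE)
        shapiro.test(s)$p.value >= 0.05
      }, logical(1)))
      cmp <- group_compare_continuous(
        data.frame(val = x, grp = as.character(patients$group)),
        val, grp, family = if (normal) "anova" else "kw")
      row <- tibble::tibble(variable = v, level = NA_character_,
                            overall = summary_cell_continuous(
                              x[is.finite(x)], normal))
      for (g in groups) {
        s <- by_group[[g]][[v]]
        row[[g]] <- summary_cell_continuous(s[is.finite(s)], normal)
      }
      row$p_value <- cmp$omnibus$p_value
      row$test_used <- cmp$omnibus$test
      row
    } else {
      x_chr <- if (is.logical(x)) ifelse(x, "yes", "no") else as.character(x)
      levels_v <- if (is.logical(x)) "yes" else sort(unique(x_chr))
      tab <- table(factor(as.character(patients$group), levels = groups),
                   factor(x_chr))
      cmp <- if (ncol(tab) >= 2) {
        group_compare_categorical(unclass(tab))
      } else {
        tibble::tibble(statistic = NA_real_, df = NA_real_,
                       p_value = NA_real_, test_used = "none")
      }
      purrr::map_dfr(seq_along(levels_v), function(i) {
        lv <- levels_v[i]
        # per-group counts summed across groups give the overall count
        k_by_group <- vapply(by_group, function(d) {
          xi <- d[[v]]
          xi_chr <- if (is.logical(xi)) ifelse(xi, "yes", "no") else
            as.character(xi)
          sum(xi_chr == lv, na.rm = TRUE)
        }, integer(1))
        row <- tibble::tibble(
          variable = v,
          level = if (is.logical(x)) NA_character_ else lv,
          overall = summary_cell_categorical(sum(k_by_group), n_all)
        )
        for (g in groups) {
          row[[g]] <- summary_cell_categorical(k_by_group[[g]],
                                               n_by_group[[g]])
        }
        row$p_value <- if (i == 1) cmp$p_value else NA_real_
        row$test_used <- if (i == 1) cmp$test_used else NA_character_
        row
      })
    }
  })
  rows
}
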