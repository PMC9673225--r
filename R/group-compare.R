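#' Compare a categorical variable across groups
#'
#' Pearson chi-square without continuity correction when every expected
#' count is at least 5, otherwise Fisher's exact test ("as appropriate"
#' dispatch). The dispatch can be forced for sensitivity checks.
#'
#' @param tab a 2-D nonnegative integer contingency table (groups x levels),
#'   all margins positive.
#' @param force `"auto"` (expected-count rule), `"chisq"`, or `"fisher"`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `test_used`.
#' @examples
#' group_compare_categorical(rbind(c(3, 12), c(5, 42), c(5, 5)),
#'                           force = "chisq")
#' @export
group_compare_categorical <- function(tab,
                                      force = c("auto", "chisq", "fisher")) {
  force <- match.arg(force)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must hold nonnegative integers.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("all margins of `tab` must be positive.")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_chisq <- switch(force,
                      auto = all(expected >= 5),
                      chisq = TRUE,
                      fisher = FALSE)
  if (use_chisq) {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble::tibble(statistic = unname(ct$statistic),
                   df = unname(ct$parameter),
                   p_value = ct$p.value, test_used = "chisq")
  } else {
    ft <- fisher.test(tab)
    tibble::tibble(statistic = NA_real_, df = NA_real_,
                   p_value = ft$p.value, test_used = "fisher")
  }
}

# Dunn's rank-based post hoc test with Bonferroni adjustment; the tie
# correction uses the pooled-rank tie counts.
dunn_posthoc <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  gl <- split(r, groups)
  means <- vapply(gl, mean, numeric(1))
  sizes <- vapply(gl, length, numeric(1))
  combs <- utils::combn(names(gl), 2)
  k <- ncol(combs)
  purrr::map_dfr(seq_len(k), function(i) {
    g1 <- combs[1, i]; g2 <- combs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / sizes[g1] + 1 / sizes[g2]))
    z <- if (se > 0) (means[[g1]] - means[[g2]]) / se else 0
    tibble::tibble(group1 = g1, group2 = g2, statistic = z,
                   p_adj = min(1, 2 * pnorm(-abs(z)) * k))
  })
}

#' Compare a continuous variable across groups
#'
#' One-way ANOVA with Tukey HSD post hoc when every group passes a
#' Shapiro-Wilk normality screen at alpha = 0.05 (and has at least 3
#' observations), otherwise Kruskal-Wallis with Dunn's test and Bonferroni
#' adjustment. The branch can be forced via `family`.
#'
#' @param data a data frame.
#' @param value <tidy-eval> column of values.
#' @param group <tidy-eval> column of group labels (>= 2 groups, each
#'   n >= 2).
#' @param family `"auto"`, `"anova"`, or `"kw"`.
#' @return A list of class `nicpw_groupcmp`: `omnibus` (one-row tibble:
#'   `test`, `statistic`, `df`, `p_value`), `posthoc` (pairwise tibble),
#'   `family`.
#' @examples
#' df <- data.frame(g = rep(c("a", "b", "c"), each = 20),
#'                  y = rnorm(60) + rep(c(0, 0, 2), each = 20))
#' glance(group_compare_continuous(df, y, g))
#' @export
group_compare_continuous <- function(data, value, group,
                                     family = c("auto", "anova", "kw")) {
  family <- match.arg(family)
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  sizes <- table(g)
  if (length(sizes) < 2) abort("need at least 2 groups.")
  if (any(sizes < 2)) abort("every group needs at least 2 observations.")

  if (family == "auto") {
    normal <- all(vapply(split(v, g), function(s) {
      if (length(s) < 3 || sd(s) == 0) return(FALSE)
      shapiro.test(s)$p.value >= 0.05
    }, logical(1)))
    family <- if (normal) "anova" else "kw"
  }

  if (family == "anova") {
    fit <- aov(v ~ g)
    a <- summary(fit)[[1]]
    omnibus <- tibble::tibble(test = "anova",
                              statistic = a[["F value"]][1],
                              df = a[["Df"]][1],
                              p_value = a[["Pr(>F)"]][1])
    tk <- TukeyHSD(fit)$g
    posthoc <- tibble::tibble(
      group1 = sub("-.*", "", rownames(tk)),
      group2 = sub(".*-", "", rownames(tk)),
      statistic = tk[, "diff"],
      p_adj = tk[, "p adj"]
    )
  } else {
    if (length(unique(v)) == 1) {
      # pure ties: no evidence of any group difference
      omnibus <- tibble::tibble(test = "kruskal-wallis", statistic = 0,
                                df = length(levels(g)) - 1, p_value = 1)
    } else {
      kw <- kruskal.test(v, g)
      omnibus <- tibble::tibble(test = "kruskal-wallis",
                                statistic = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p_value = kw$p.value)
    }
    posthoc <- dunn_posthoc(v, g)
  }
  structure(list(omnibus = omnibus, posthoc = posthoc, family = family),
            class = "nicpw_groupcmp")
}

#' @export
print.nicpw_groupcmp <- function(x, ...) {
  o <- x$omnibus
  cat(sprintf("%s: statistic %.3f (df %s), p = %.4g\n",
              o$test, o$statistic, format(o$df), o$p_value))
  invisible(x)
}

#' @export
tidy.nicpw_groupcmp <- function(x, ...) x$posthoc

#' @export
glance.nicpw_groupcmp <- function(x, ...) x$omnibus
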