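#' Plot the per-minute averaged pulses of a session
#'
#' One curve per valid minute on the normalized time base, with the located
#' P1 and P2 positions marked.
#'
#' @param object a `nicpw_session` from [analyze_recording()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.nicpw_session <- function(object, ...) {
  m <- object$minutes[object$minutes$valid, ]
  if (nrow(m) == 0) abort("no valid minutes to plot.")
  curves <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    tibble::tibble(minute = m$minute_index[i],
                   frac = seq(0, 1, length.out = 100),
                   value = m$pulse[[i]])
  })
  marks <- tidyr::pivot_longer(
    m[, c("minute_index", "p1_lat", "p2_lat")],
    cols = c("p1_lat", "p2_lat"), names_to = "peak", values_to = "frac") |>
    dplyr::mutate(peak = toupper(sub("_lat", "", .data$peak)))
  marks$value <- purrr::map2_dbl(marks$minute_index, marks$frac, function(mi, fr) {
    pl <- m$pulse[[match(mi, m$minute_index)]]
    pl[round(fr * 99) + 1]
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$frac, .data$value,
                                       group = .data$minute,
                                       colour = factor(.data$minute))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(data = marks,
                        ggplot2::aes(.data$frac, .data$value,
                                     shape = .data$peak),
                        inherit.aes = FALSE, size = 2) +
    ggplot2::labs(x = "fraction of cardiac cycle", y = "amplitude (a.u.)",
                  colour = "minute", shape = "peak",
                  title = "Per-minute ensemble-averaged pulses") +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object a `nicpw_roc` from [delong_ci()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.nicpw_roc <- function(object, ...) {
  cv <- object$curve[order(1 - object$curve$specificity,
                           object$curve$sensitivity), ]
  ggplot2::ggplot(cv, ggplot2::aes(1 - .data$specificity,
                                   .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("AUROC %.2f [%.2f-%.2f]",
                      object$auc, object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Cohort scatter of mICP against P2/P1
#'
#' @param patients cohort tibble with `micp`, `p2p1` and optionally
#'   `group`.
#' @param iht_cutoff,p2p1_cutoff reference lines.
#' @return A ggplot.
#' @export
plot_cohort <- function(patients, iht_cutoff = 20, p2p1_cutoff = 1.2) {
  stopifnot(all(c("micp", "p2p1") %in% names(patients)))
  aes <- if ("group" %in% names(patients)) {
    ggplot2::aes(.data$micp, .data$p2p1, colour = .data$group)
  } else {
    ggplot2::aes(.data$micp, .data$p2p1)
  }
  ggplot2::ggplot(patients, aes) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = iht_cutoff, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = p2p1_cutoff, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "session mICP (mmHg)", y = "session P2/P1") +
    ggplot2::theme_minimal()
}
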