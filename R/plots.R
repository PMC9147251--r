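spectrum_bar_data <- function(spec, min_n = 3L) {
  d <- spectrum_percentages(spec, min_n = min_n)
  d$k <- factor(d$k, levels = d$k)
  d
}

#' Bar graph of an identity-run spectrum
#'
#' Run lengths from `min_n` upward as percent of their total, the standard
#' presentation of micro-modular cluster frequencies.
#'
#' @param object an `mm_run_spectrum`.
#' @param min_n smallest run length shown (default 3).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mm_run_spectrum <- function(object, min_n = 3L, ...) {
  d <- spectrum_bar_data(object, min_n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "identity-run length (nt)",
                  y = sprintf("percent of runs >= %d", min_n)) +
    ggplot2::theme_minimal()
}

#' Bar graph of a randomized-pair ensemble spectrum
#'
#' @param object an `mm_ensemble`.
#' @param min_n smallest run length shown.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mm_ensemble <- function(object, min_n = 3L, ...) {
  autoplot.mm_run_spectrum(object$spectrum, min_n = min_n) +
    ggplot2::labs(subtitle = sprintf(
      "%d random pairs of %d nt, mean identity %.1f%%",
      object$n_pairs, object$length, object$mean_identity))
}

#' Shuffled-score distribution with its fitted Gumbel density
#'
#' @param object an `mm_shuffle_null`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mm_shuffle_null <- function(object, ...) {
  d <- tidy(object)
  dens <- function(x) exp(-(x - object$mu) / object$beta -
                            exp(-(x - object$mu) / object$beta)) / object$beta
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey70", color = "white") +
    ggplot2::stat_function(fun = dens, color = "firebrick") +
    ggplot2::geom_vline(xintercept = object$observed_score,
                        linetype = "dashed") +
    ggplot2::labs(x = "local alignment score of shuffled queries",
                  y = "density",
                  subtitle = sprintf("observed %.1f, E = %.3g",
                                     object$observed_score, object$e_value)) +
    ggplot2::theme_minimal()
}
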