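#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Panel-power summary
#'
#' One row: the criterion, threshold, panel size, the smallest panel
#' reaching the threshold, and the full-panel cumulative probability.
#'
#' @param x A [panel_power()] result.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.str_panel_power <- function(x, ...) {
  tibble::tibble(criterion = attr(x, "criterion"),
                 threshold = attr(x, "threshold"),
                 n_loci = nrow(x),
                 min_loci = attr(x, "min_loci"),
                 cumulative_final = x$cumulative[nrow(x)])
}

#' @rdname glance.str_panel_power
#' @export
tidy.str_panel_power <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Cumulative identity-power curve
#'
#' Plots the running product of per-locus identity probabilities against
#' panel size (log scale), with the decision threshold as a dashed line.
#'
#' @param object A [panel_power()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.str_panel_power <- function(object, ...) {
  lab <- if (attr(object, "criterion") == "pid") {
    expression(P[ID])
  } else {
    expression(P[ID(sib)])
  }
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rank, y = .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "loci in panel (most informative first)",
                  y = "cumulative probability of identity",
                  title = lab) +
    ggplot2::theme_minimal()
}

#' Concordance summary
#'
#' @param x A [genotype_concordance()] result.
#' @param ... Unused.
#' @return `glance`: the one-row rate tibble; `tidy`: the per-pair
#'   classification.
#' @export
glance.str_concordance <- function(x, ...) x$rates

#' @rdname glance.str_concordance
#' @export
tidy.str_concordance <- function(x, ...) x$pairs

#' Per-locus heterozygosity overview
#'
#' Dot plot of observed versus unbiased expected heterozygosity per locus;
#' loci above the diagonal show heterozygote excess, below it a deficit.
#'
#' @param object A [locus_stats()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.str_locus_stats <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$he_unbiased, y = .data$ho)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = expression(H[E] ~ "(unbiased)"),
                  y = expression(H[O])) +
    ggplot2::theme_minimal()
}
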