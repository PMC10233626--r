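# ggplot2 views of survey and superposition results.

#' Histogram of latch-region lengths
#'
#' Bin width 5 residues, one bar colour per length cluster.
#'
#' @param regions Region table (needs a `length` column), e.g. from
#'   [run_latch_survey()] or [map_alignment_region()].
#' @param gap_threshold Passed to [cluster_lengths()] for colouring.
#' @return A ggplot object.
#' @export
plot_length_histogram <- function(regions, gap_threshold = 6) {
  lens <- regions$length[regions$length > 0]
  cl <- cluster_lengths(lens, gap_threshold)
  d <- tibble(length = lens)
  d$cluster <- factor(purrr::map_int(d$length, function(l) {
    cl$cluster[which(l >= cl$min_length & l <= cl$max_length)[1]]
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length, fill = .data$cluster)) +
    ggplot2::geom_histogram(binwidth = 5, boundary = 0, colour = "grey20") +
    ggplot2::labs(x = "latch length (residues)", y = "sequences",
                  fill = "cluster") +
    ggplot2::theme_minimal()
}

#' Charge-per-length versus length scatter plot
#'
#' @param regions Region table with `length` and `charge_per_length`
#'   columns (e.g. `run_latch_survey()$regions`).
#' @return A ggplot object.
#' @export
plot_charge_vs_length <- function(regions) {
  d <- regions[regions$length > 0, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length,
                                  y = .data$charge_per_length,
                                  colour = .data$charge_per_length > 0)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = "latch length (residues)",
                  y = "net charge per residue (pH 7)") +
    ggplot2::theme_minimal()
}

#' Residual plot for a superposition
#'
#' Per-atom residuals in pairing order, rejected atoms highlighted.
#'
#' @param object A `superposition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.superposition <- function(object, ...) {
  d <- tidy(object)
  d$index <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$residual,
                                  colour = .data$used)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$rmsd, linetype = 2) +
    ggplot2::labs(x = "paired atom", y = "residual (Å)",
                  colour = "retained") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
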