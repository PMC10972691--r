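#' Plot a sliding-window divergence scan
#'
#' Line plot of windowed `d_xy` along each chromosome, optionally shading
#' inversion intervals.
#'
#' @param object A `dxy_scan` from [sliding_window_dxy()].
#' @param inversions Optional tibble (`chrom`, `start`, `end`) to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dxy_scan <- function(object, inversions = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$mid / 1e6,
                                            y = .data$dxy)) +
    ggplot2::geom_line(linewidth = 0.4, colour = "#2c7fb8") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(d[xy]),
                  title = "Sliding-window divergence") +
    ggplot2::theme_minimal()
  if (!is.null(inversions) && nrow(inversions)) {
    p <- p + ggplot2::geom_rect(
      data = inversions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "#d95f02",
      inherit.aes = FALSE)
  }
  p
}

#' Plot a bSFS tally
#'
#' Bar chart of the most frequent blockwise mutation configurations.
#'
#' @param tally A tally tibble from [tally_bsfs()] or [sim_tally()].
#' @param top Number of configurations to show (default 20).
#' @return A ggplot object.
#' @export
plot_bsfs <- function(tally, top = 20) {
  k <- attr(tally, "kmax")
  lab <- function(v) ifelse(!is.null(k) & v > k, ">k", as.character(v))
  d <- dplyr::mutate(tally,
                     config = paste(lab(.data$hetA), lab(.data$hetB),
                                    lab(.data$hetAB), lab(.data$fixed),
                                    sep = "/"),
                     freq = .data$n / sum(.data$n))
  d <- head(dplyr::arrange(d, dplyr::desc(.data$freq)), top)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$config, -.data$freq),
                                  y = .data$freq)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "configuration (hetA/hetB/hetAB/fixed)",
                  y = "frequency", title = "Blockwise SFS") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a parametric-bootstrap null distribution
#'
#' Histogram of the null `delta lnCL` with the observed value marked.
#'
#' @param object A `param_bootstrap` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.param_bootstrap <- function(object, ...) {
  p <- ggplot2::ggplot(object$null, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey65", colour = "white") +
    ggplot2::geom_vline(xintercept = object$critical, linetype = 2) +
    ggplot2::labs(x = expression(Delta * lnCL), y = "replicates",
                  title = "Parametric bootstrap null (DIV)") +
    ggplot2::theme_minimal()
  if (!is.null(object$observed_delta)) {
    p <- p + ggplot2::geom_vline(xintercept = object$observed_delta,
                                 colour = "#d95f02", linewidth = 1)
  }
  p
}

#' Plot inversion-null distributions
#'
#' Null distributions of mean `d_xy` per inversion with observed values.
#'
#' @param object An `inv_null` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.inv_null <- function(object, ...) {
  d <- tidyr::unnest(
    dplyr::select(object$results, "partition", "null"), "null")
  obs <- dplyr::select(object$results, "partition", "dxy_obs")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dxy)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey65", colour = "white") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$dxy_obs),
                        colour = "#d95f02", linewidth = 1) +
    ggplot2::facet_wrap(~partition, scales = "free") +
    ggplot2::labs(x = expression(d[xy]), y = "null replicates",
                  title = "Gene-conversion-only null vs observed") +
    ggplot2::theme_minimal()
}
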