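# ggplot2 displays for the main result containers.

#' @describeIn build_oxford_grid Bubble-plot display of an Oxford grid.
#' @param object An `oxford_grid`.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.oxford_grid <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(.data$n > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$chrom_b, .data$chrom_a,
                                   size = .data$n)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(x = "genome B chromosome", y = "genome A chromosome",
                  size = "shared\northologs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @describeIn correlation_eigenvectors Line display of eigenvector profiles.
#' @param object An `eigen_profiles` object.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.eigen_profiles <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~eigen_rank, ncol = 1, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "bin", y = "eigenvector value",
                  title = object$chrom) +
    ggplot2::theme_minimal()
}

#' @describeIn fdtv_profile Kernel-density display per copy-number stratum.
#' @param object An `fdtv_profile` object.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.fdtv_profile <- function(object, ...) {
  ggplot2::ggplot(object$densities,
                  ggplot2::aes(.data$fdtv, .data$density,
                               colour = .data$stratum)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "transversions per fourfold-degenerate site",
                  y = "density", colour = "stratum") +
    ggplot2::theme_minimal()
}

#' Raster display of a compartment saddle matrix
#'
#' @param saddle Square saddle matrix (from [compartment_saddle]).
#' @return A ggplot object.
#' @export
plot_saddle <- function(saddle) {
  df <- as.data.frame.table(saddle, responseName = "oe") |>
    tibble::as_tibble() |>
    dplyr::mutate(row = as.integer(.data$Var1), col = as.integer(.data$Var2))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = log2(.data$oe))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::labs(x = "eigenvector class", y = "eigenvector class",
                  fill = "log2 O/E") +
    ggplot2::theme_minimal()
}
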