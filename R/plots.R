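#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Contact-decay profile of a contact table
#'
#' Mean band total per cell against genomic distance (band index), on a log
#' scale: the band bias that BandNorm equalizes.
#'
#' @param t A `contact_table`.
#' @param chrom Chromosome (default first).
#' @return A ggplot.
#' @export
plot_band_decay <- function(t, chrom = names(ct_chrom_bins(t))[1]) {
  df <- t |>
    dplyr::filter(.data$chrom == !!chrom, .data$bin2 > .data$bin1) |>
    dplyr::mutate(band = .data$bin2 - .data$bin1) |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(mean_band_total = sum(.data$count) /
                       length(unique(t$cell)), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band,
                                   y = .data$mean_band_total)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "band (genomic distance in bins)",
                  y = "mean band total per cell",
                  title = paste("Contact decay,", chrom)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of an embedding
#'
#' @param e Matrix (cells x >= 2 dims); the first two columns are drawn.
#' @param labels Optional point labels (e.g. cell type or batch).
#' @param dims Which two columns to plot.
#' @return A ggplot.
#' @export
plot_embedding <- function(e, labels = NULL, dims = c(1, 2)) {
  e <- as.matrix(e)
  df <- tibble::tibble(x = e[, dims[1]], y = e[, dims[2]])
  if (!is.null(labels)) df$label <- as.character(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = paste("dim", dims[1]), y = paste("dim", dims[2])) +
    ggplot2::theme_minimal()
  if (is.null(labels)) {
    p + ggplot2::geom_point(size = 1)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 1) +
      ggplot2::labs(colour = NULL)
  }
}

#' ELBO training traces of a fitted band model
#' @param object An `scvi3d_fit`.
#' @param ... Unused.
#' @return A ggplot, one facet per band group.
#' @export
autoplot.scvi3d_fit <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(object$fits, function(f) {
    tibble::tibble(
      group = paste0(f$chrom, ":", min(f$bands), "-", max(f$bands)),
      epoch = seq_along(f$elbo_trace),
      elbo = f$elbo_trace
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$elbo)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(y = "ELBO (per cell)") +
    ggplot2::theme_minimal()
}

#' Decay profile of BandNorm factors
#' @param object A `band_norm` object.
#' @param ... Unused.
#' @return A ggplot of `alpha(v)` against band per chromosome.
#' @export
autoplot.band_norm <- function(object, ...) {
  ggplot2::ggplot(object$factors,
                  ggplot2::aes(x = .data$band, y = .data$alpha,
                               colour = .data$chrom)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "band", y = expression(alpha(v)), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Distribution of standardized scGAD scores
#' @param object A `gad_matrix`.
#' @param ... Unused.
#' @return A ggplot density of per-cell z-scores.
#' @export
autoplot.gad_matrix <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$z), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "standardized scGAD score") +
    ggplot2::theme_minimal()
}
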