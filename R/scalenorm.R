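#' CellScale: library-size normalization
#'
#' Scales each cell's contacts so that its total interaction frequency across
#' all chromosomes equals a common target (10,000 by default). A single size
#' factor per cell; genomic-distance bias is untouched.
#'
#' @param t A `contact_table`.
#' @param target Common post-normalization library size.
#' @return A `contact_table` with real-valued counts.
#' @export
cell_scale <- function(t, target = 10000) {
  totals <- t |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  zero <- totals$cell[totals$total == 0]
  if (length(zero) > 0L) {
    warning("skipping cell(s) with zero total: ", paste(zero, collapse = ", "))
  }
  out <- t |>
    dplyr::left_join(totals, by = "cell") |>
    dplyr::mutate(count = ifelse(.data$total > 0,
                                 .data$count / .data$total * target,
                                 .data$count)) |>
    dplyr::select(-"total")
  restore_ct(out, t)
}

#' BandScale: per-band depth normalization within each cell
#'
#' Divides each locus pair by the mean interaction frequency of its band
#' within the same cell and chromosome, i.e. `C = Y / (L^{cv} / m_v)` where
#' `L^{cv}` is the cell's band total and `m_v = D - v` the number of pairs in
#' the band. Removes both library-size and distance bias within a cell; bands
#' with zero total are left at zero. Every non-empty band has mean exactly 1
#' afterwards.
#'
#' @param t A `contact_table`.
#' @return A `contact_table` with real-valued counts.
#' @export
band_scale <- function(t) {
  d <- ct_chrom_bins(t)
  out <- t |>
    dplyr::mutate(
      band = .data$bin2 - .data$bin1,
      m_v = unname(d[.data$chrom]) - .data$band
    ) |>
    dplyr::group_by(.data$cell, .data$chrom, .data$band) |>
    dplyr::mutate(L = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(count = ifelse(.data$L > 0,
                                 .data$count / (.data$L / .data$m_v),
                                 .data$count)) |>
    dplyr::select(-"band", -"m_v", -"L")
  restore_ct(out, t)
}

#' BandNorm: band normalization with a common contact-decay profile
#'
#' Removes genomic-distance bias and sequencing depth within each cell, then
#' adds back a shared band-dependent decay estimate:
#' `C_r^{cv} = Y_r^{cv} / L^{cv} * alpha(v)`, where `L^{cv}` is the total
#' interaction frequency of cell `c` in band `v` (per chromosome) and
#' `alpha(v) = sum_c L^{cv} / N` is the mean band total across all `N`
#' retained cells, cells with an empty band included. After normalization
#' every cell with `L^{cv} > 0` has band total exactly `alpha(v)`.
#'
#' Precomputed factors (e.g. from a training set) can be supplied to normalize
#' held-out cells against a fixed decay profile; the output is then invariant
#' to rescaling any single cell's counts.
#'
#' @param t A `contact_table`.
#' @param factors Optional precomputed factor table as returned in
#'   `$factors`: a tibble with columns `chrom`, `band`, `alpha`.
#' @return A list of class `band_norm` with elements `table` (normalized
#'   `contact_table`) and `factors` (tibble `chrom`, `band`, `m_v`, `alpha`,
#'   `n_cells`).
#' @export
band_norm <- function(t, factors = NULL) {
  d <- ct_chrom_bins(t)
  n_cells <- length(unique(t$cell))
  w <- t |>
    dplyr::mutate(band = .data$bin2 - .data$bin1) |>
    dplyr::group_by(.data$cell, .data$chrom, .data$band) |>
    dplyr::mutate(L = sum(.data$count)) |>
    dplyr::ungroup()
  if (is.null(factors)) {
    factors <- w |>
      dplyr::distinct(.data$cell, .data$chrom, .data$band, .data$L) |>
      dplyr::group_by(.data$chrom, .data$band) |>
      dplyr::summarise(alpha = sum(.data$L) / n_cells, .groups = "drop") |>
      dplyr::mutate(m_v = unname(d[.data$chrom]) - .data$band,
                    n_cells = n_cells) |>
      dplyr::select("chrom", "band", "m_v", "alpha", "n_cells")
  } else {
    stopifnot(all(c("chrom", "band", "alpha") %in% names(factors)))
  }
  out <- w |>
    dplyr::left_join(factors[c("chrom", "band", "alpha")],
                     by = c("chrom", "band")) |>
    dplyr::mutate(count = ifelse(.data$L > 0 & !is.na(.data$alpha),
                                 .data$count / .data$L * .data$alpha,
                                 0)) |>
    dplyr::select(-"band", -"L", -"alpha")
  structure(
    list(table = restore_ct(out, t), factors = tibble::as_tibble(factors)),
    class = "band_norm"
  )
}

#' @export
print.band_norm <- function(x, ...) {
  cat("# band_norm:", length(unique(x$table$cell)), "cells,",
      nrow(x$factors), "chromosome/band factors\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-band factors of a BandNorm fit
#' @param x A `band_norm` object.
#' @param ... Unused.
#' @return The factor tibble (`chrom`, `band`, `m_v`, `alpha`, `n_cells`).
#' @export
tidy.band_norm <- function(x, ...) x$factors

#' One-row summary of a BandNorm fit
#' @param x A `band_norm` object.
#' @param ... Unused.
#' @export
glance.band_norm <- function(x, ...) {
  tibble::tibble(
    n_cells = length(unique(x$table$cell)),
    n_chroms = length(unique(x$factors$chrom)),
    n_bands = nrow(x$factors),
    total_count = sum(x$table$count)
  )
}

#' Vectorize a contact table into a cells-by-locus-pair matrix
#'
#' One column per locus pair observed in at least one cell (optionally
#' restricted to bands `<= max_band`); missing entries are 0. This is the
#' input for PCA / clustering of scaling-normalized data.
#'
#' @param t A `contact_table`.
#' @param max_band Optional maximum genomic distance (in bins) to keep.
#' @param cells Optional row ordering; default sorted cells.
#' @return A sparse `dgCMatrix` (cells x pairs) with a `pairs` attribute
#'   (tibble `chrom`, `bin1`, `bin2` describing the columns).
#' @export
vectorize_cells <- function(t, max_band = NULL, cells = NULL) {
  x <- tibble::as_tibble(t)
  if (!is.null(max_band)) {
    x <- x |> dplyr::filter(.data$bin2 - .data$bin1 <= max_band)
  }
  if (is.null(cells)) cells <- sort(unique(t$cell))
  pairs <- x |>
    dplyr::distinct(.data$chrom, .data$bin1, .data$bin2) |>
    dplyr::arrange(.data$chrom, .data$bin1, .data$bin2)
  key <- function(ch, i, j) paste(ch, i, j, sep = ":")
  pk <- key(pairs$chrom, pairs$bin1, pairs$bin2)
  m <- Matrix::sparseMatrix(
    i = match(x$cell, cells),
    j = match(key(x$chrom, x$bin1, x$bin2), pk),
    x = x$count,
    dims = c(length(cells), nrow(pairs)),
    dimnames = list(cells, pk)
  )
  attr(m, "pairs") <- pairs
  m
}
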