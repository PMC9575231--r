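#' Construct a single-cell contact table
#'
#' The universal exchange type of the package: sparse per-cell binned
#' intra-chromosomal contacts in long format. Only the upper triangle of each
#' symmetric contact map is stored (`bin1 <= bin2`); records supplied with
#' `bin1 > bin2` are flipped and duplicate `(cell, chrom, bin1, bin2)` keys are
#' summed, so total counts are conserved.
#'
#' Bins are 0-based, half-open genomic windows `[k*res, (k+1)*res)`; a position
#' maps to bin `floor(pos/res)`.
#'
#' @param x A data frame with columns `cell`, `chrom`, `bin1`, `bin2`, `count`.
#' @param resolution Bin width in base pairs.
#' @param chrom_sizes Chromosome lengths in base pairs: a named numeric vector,
#'   or a data frame whose first two columns are chromosome name and length
#'   (e.g. read from a BED-style chrom-sizes file).
#' @return A tibble of class `contact_table` with attributes `resolution`,
#'   `chrom_bins` (bins per chromosome, `D = ceiling(size/resolution)`) and
#'   `chrom_sizes` (bp).
#' @export
contact_table <- function(x, resolution, chrom_sizes) {
  stopifnot(is.data.frame(x), is.numeric(resolution), resolution > 0)
  sizes <- as_chrom_sizes(chrom_sizes)
  need <- c("cell", "chrom", "bin1", "bin2", "count")
  if (!all(need %in% names(x))) {
    stop("contact table needs columns: ", paste(need, collapse = ", "))
  }
  x <- tibble::as_tibble(x)[need]
  if (nrow(x) == 0L) stop("empty contact input")
  if (any(x$count < 0)) stop("negative counts are not allowed")
  unknown <- setdiff(unique(x$chrom), names(sizes))
  if (length(unknown) > 0L) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  chrom_bins <- ceiling(sizes / resolution)
  storage.mode(chrom_bins) <- "integer"

  # canonicalize to upper triangle, then merge duplicate keys by summing
  swap <- x$bin1 > x$bin2
  if (any(swap)) {
    tmp <- x$bin1[swap]
    x$bin1[swap] <- x$bin2[swap]
    x$bin2[swap] <- tmp
  }
  d <- chrom_bins[x$chrom]
  if (any(x$bin1 < 0L) || any(x$bin2 >= d)) {
    stop("bin index out of range for declared chromosome sizes")
  }
  x <- x |>
    dplyr::group_by(.data$cell, .data$chrom, .data$bin1, .data$bin2) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")

  new_contact_table(x, resolution, chrom_bins, sizes)
}

new_contact_table <- function(x, resolution, chrom_bins, chrom_sizes) {
  x <- tibble::as_tibble(x)
  attr(x, "resolution") <- as.numeric(resolution)
  attr(x, "chrom_bins") <- chrom_bins
  attr(x, "chrom_sizes") <- chrom_sizes
  class(x) <- unique(c("contact_table", class(x)))
  x
}

# rebuild metadata after a dplyr verb stripped attributes
restore_ct <- function(x, template) {
  new_contact_table(
    x,
    attr(template, "resolution"),
    attr(template, "chrom_bins"),
    attr(template, "chrom_sizes")
  )
}

as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    sizes <- as.numeric(chrom_sizes[[2L]])
    names(sizes) <- as.character(chrom_sizes[[1L]])
  } else {
    sizes <- as.numeric(chrom_sizes)
    names(sizes) <- names(chrom_sizes)
  }
  if (is.null(names(sizes)) || any(!nzchar(names(sizes)))) {
    stop("chrom_sizes must be named by chromosome")
  }
  if (any(sizes <= 0)) stop("chromosome sizes must be positive")
  sizes
}

#' @export
print.contact_table <- function(x, ...) {
  cat(
    "# contact_table:", length(unique(x$cell)), "cells,",
    length(attr(x, "chrom_bins")), "chromosome(s), resolution",
    format(attr(x, "resolution"), big.mark = ","), "bp\n"
  )
  NextMethod()
}

#' Bin resolution of a contact table
#' @param x A `contact_table`.
#' @return Resolution in base pairs.
#' @export
ct_resolution <- function(x) attr(x, "resolution")

#' Bins per chromosome of a contact table
#' @param x A `contact_table`.
#' @return Named integer vector of bin counts `D`.
#' @export
ct_chrom_bins <- function(x) attr(x, "chrom_bins")
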