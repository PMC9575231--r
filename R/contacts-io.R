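#' Read sparse single-cell contact data
#'
#' Reads either one long-format TSV covering all cells, or a directory of
#' per-cell triplet files (one file per cell; the cell id is the file name
#' without extension). Two coordinate conventions are supported, detected from
#' the header: pre-binned (`bin1`/`bin2`) or base-pair positions
#' (`pos1`/`pos2`), the latter mapped to bins by `floor(pos/resolution)`.
#' An optional two-chromosome header (`chrom1`, `chrom2`) is accepted;
#' inter-chromosomal records are dropped with a message reporting the count,
#' since all downstream modeling is intra-chromosomal.
#'
#' Duplicate triplets (e.g. the same pair listed in both orientations, or the
#' same pair appearing in several input chunks) are always summed.
#'
#' @param path Path to a long-format TSV, or to a directory of per-cell files.
#' @param resolution Bin width in base pairs.
#' @param chrom_sizes Chromosome lengths in bp (named vector or data frame).
#' @return A [contact_table()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("cell\tchrom\tbin1\tbin2\tcount", "c1\tchr1\t3\t5\t2"), tf)
#' read_contacts(tf, resolution = 1e6, chrom_sizes = c(chr1 = 10e6))
#' @export
read_contacts <- function(path, resolution, chrom_sizes) {
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    files <- files[!dir.exists(files)]
    if (length(files) == 0L) stop("empty input directory: ", path)
    parts <- lapply(files, function(f) {
      df <- read_contact_file(f, resolution)
      if (!"cell" %in% names(df)) {
        df$cell <- sub("\\.[^.]*$", "", basename(f))
      }
      df
    })
    raw <- dplyr::bind_rows(parts)
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- read_contact_file(path, resolution)
    if (!"cell" %in% names(raw)) stop("long-format input needs a 'cell' column")
  }
  contact_table(raw, resolution = resolution, chrom_sizes = chrom_sizes)
}

read_contact_file <- function(f, resolution) {
  df <- readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
  names(df) <- tolower(names(df))
  if (all(c("chrom1", "chrom2") %in% names(df))) {
    inter <- df$chrom1 != df$chrom2
    if (any(inter)) {
      message("dropped ", sum(inter), " inter-chromosomal record(s) from ",
              basename(f))
      df <- df[!inter, , drop = FALSE]
    }
    df$chrom <- df$chrom1
  }
  if (!"chrom" %in% names(df)) stop(f, ": no chromosome column")
  if (!"count" %in% names(df)) stop(f, ": no count column")
  if (nrow(df) == 0L) stop(f, ": empty input")
  if (any(df$count != round(df$count))) {
    stop(f, ": raw contact counts must be integers")
  }
  if (all(c("pos1", "pos2") %in% names(df))) {
    if (is.null(resolution)) stop(f, ": position input requires a resolution")
    df$bin1 <- as.integer(floor(df$pos1 / resolution))
    df$bin2 <- as.integer(floor(df$pos2 / resolution))
  }
  if (!all(c("bin1", "bin2") %in% names(df))) {
    stop(f, ": need bin1/bin2 or pos1/pos2 columns")
  }
  keep <- intersect(c("cell", "chrom", "bin1", "bin2", "count"), names(df))
  df[keep]
}

#' Read a BED-style chromosome-sizes file
#'
#' Two tab-separated columns, no header: chromosome name and length in bp.
#'
#' @param path File path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "size"),
                        show_col_types = FALSE, progress = FALSE)
  as_chrom_sizes(df)
}

#' Write a contact table as long-format TSV
#' @param t A `contact_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(t, path) {
  readr::write_tsv(tibble::as_tibble(t), path, progress = FALSE)
  invisible(path)
}

#' Remove extremely sparse cells
#'
#' Two filters used for quality control of scHi-C data. `"mb_rule"` (for 1 Mb
#' bins): a cell is removed if on any chromosome its number of non-zero locus
#' pairs is strictly below `x/6`, where `x` is the chromosome length in Mb
#' (not rounded). `"sparsity_rule"` (for finer bins, e.g. 100 kb): a cell is
#' removed if on any chromosome the fraction of zero entries in its
#' upper-triangular contact map (diagonal included, `D(D+1)/2` entries)
#' exceeds `threshold` (default 0.999).
#'
#' Both filters consider every chromosome declared in the table's chromosome
#' sizes; a cell with no contacts at all on a declared chromosome fails the
#' rule there.
#'
#' @param t A `contact_table`.
#' @param mode `"mb_rule"` or `"sparsity_rule"`.
#' @param threshold Zero-fraction threshold for `"sparsity_rule"`.
#' @return A list with `table` (the filtered `contact_table`) and
#'   `removed_cells` (character vector of removed cell ids).
#' @export
filter_sparse_cells <- function(t, mode = c("mb_rule", "sparsity_rule"),
                                threshold = 0.999) {
  mode <- match.arg(mode)
  chrom_bins <- ct_chrom_bins(t)
  sizes_bp <- attr(t, "chrom_sizes")
  cells <- unique(t$cell)

  nz <- t |>
    dplyr::filter(.data$count > 0) |>
    dplyr::count(.data$cell, .data$chrom, name = "n_nonzero") |>
    tidyr::complete(
      cell = cells,
      chrom = names(chrom_bins),
      fill = list(n_nonzero = 0L)
    )

  if (mode == "mb_rule") {
    x_mb <- sizes_bp[nz$chrom] / 1e6
    bad <- nz$n_nonzero < x_mb / 6
  } else {
    d <- chrom_bins[nz$chrom]
    total <- d * (d + 1) / 2
    bad <- (1 - nz$n_nonzero / total) > threshold
  }
  removed <- sort(unique(nz$cell[bad]))
  kept <- t |> dplyr::filter(!(.data$cell %in% removed))
  if (nrow(kept) == 0L) {
    message("filter_sparse_cells removed every cell")
  }
  list(table = restore_ct(kept, t), removed_cells = removed)
}

#' Split one chromosome into diagonal band matrices
#'
#' Stratifies the upper-triangular contact map of each cell into diagonal
#' bands: band `v` holds the locus pairs `(i, j)` with `j - i = v`, which for a
#' chromosome of `D` bins gives `m_v = D - v` pairs. Bands from the same
#' genomic distance are combined across cells into a cells-by-pairs band
#' matrix. The diagonal band `v = 0` is excluded by default, since all
#' modeling and downstream analysis uses off-diagonal pairs only.
#'
#' @param t A `contact_table`.
#' @param chrom Chromosome to split.
#' @param drop_diagonal Omit band `v = 0`? Default `TRUE`.
#' @param cells Optional cell ordering; defaults to sorted cells of `t`.
#' @return A list of `band_matrix` objects, one per band `v` (named `"1"`,
#'   `"2"`, ...), each with fields `chrom`, `bands`, `cell_ids`, `cols`
#'   (tibble of band/bin1/bin2 per column) and `matrix` (sparse cells x m_v).
#' @export
band_split <- function(t, chrom, drop_diagonal = TRUE, cells = NULL) {
  if (!chrom %in% names(ct_chrom_bins(t))) stop("unknown chromosome: ", chrom)
  d <- ct_chrom_bins(t)[[chrom]]
  if (is.null(cells)) cells <- sort(unique(t$cell))
  sub <- t |>
    dplyr::filter(.data$chrom == !!chrom, .data$cell %in% cells) |>
    dplyr::mutate(band = .data$bin2 - .data$bin1)
  v_min <- if (drop_diagonal) 1L else 0L
  bands <- seq.int(v_min, d - 1L)
  lapply(stats::setNames(bands, bands), function(v) {
    cols <- tibble::tibble(
      band = v,
      bin1 = seq.int(0L, d - 1L - v),
      bin2 = seq.int(v, d - 1L)
    )
    rec <- sub |> dplyr::filter(.data$band == v)
    m <- Matrix::sparseMatrix(
      i = match(rec$cell, cells),
      j = rec$bin1 + 1L,
      x = rec$count,
      dims = c(length(cells), nrow(cols)),
      dimnames = list(cells, NULL)
    )
    new_band_matrix(chrom, v, cells, cols, m)
  })
}

new_band_matrix <- function(chrom, bands, cell_ids, cols, matrix) {
  structure(
    list(chrom = chrom, bands = bands, cell_ids = cell_ids,
         cols = cols, matrix = matrix),
    class = "band_matrix"
  )
}

#' @export
print.band_matrix <- function(x, ...) {
  cat("# band_matrix:", x$chrom, "band(s)",
      paste(x$bands, collapse = ","), "-",
      length(x$cell_ids), "cells x", nrow(x$cols), "locus pairs\n")
  invisible(x)
}

#' Concatenate band matrices into one pooled band matrix
#' @param bms List of `band_matrix` objects for the same chromosome and cells.
#' @return A single pooled `band_matrix`.
#' @export
band_pool <- function(bms) {
  stopifnot(length(bms) > 0L)
  cells <- bms[[1L]]$cell_ids
  for (b in bms) {
    stopifnot(identical(b$cell_ids, cells), identical(b$chrom, bms[[1L]]$chrom))
  }
  new_band_matrix(
    chrom = bms[[1L]]$chrom,
    bands = unlist(lapply(bms, `[[`, "bands")),
    cell_ids = cells,
    cols = dplyr::bind_rows(lapply(bms, `[[`, "cols")),
    matrix = do.call(cbind, lapply(bms, `[[`, "matrix"))
  )
}

#' Reassemble a contact table from band matrices
#'
#' Inverse of [band_split()] on the off-diagonal entries: concatenating the
#' bands of one chromosome recovers every off-diagonal locus pair exactly once.
#'
#' @param bms List of `band_matrix` objects (possibly several chromosomes).
#' @param template A `contact_table` supplying resolution and chromosome sizes.
#' @return A `contact_table` with zero entries dropped.
#' @export
band_merge <- function(bms, template) {
  rows <- lapply(bms, function(b) {
    m <- as(as(b$matrix, "CsparseMatrix"), "TsparseMatrix")
    tibble::tibble(
      cell = b$cell_ids[m@i + 1L],
      chrom = b$chrom,
      bin1 = b$cols$bin1[m@j + 1L],
      bin2 = b$cols$bin2[m@j + 1L],
      count = m@x
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::filter(.data$count != 0) |>
    dplyr::arrange(.data$cell, .data$chrom, .data$bin1, .data$bin2)
  restore_ct(out, template)
}

#' Aggregate cells into pseudo-bulk contact tables
#'
#' Sums contact values per locus pair within each cell group (e.g. cell type),
#' yielding one pseudo-bulk "cell" per group. Works on raw, normalized, or
#' de-noised tables.
#'
#' @param t A `contact_table`.
#' @param labels Cell grouping: a named vector (names = cell ids) or a data
#'   frame with columns `cell` and `group`.
#' @return A `contact_table` whose `cell` column holds group names.
#' @export
aggregate_pseudobulk <- function(t, labels) {
  if (is.data.frame(labels)) {
    lab <- stats::setNames(as.character(labels$group), labels$cell)
  } else {
    lab <- stats::setNames(as.character(labels), names(labels))
  }
  cells <- unique(t$cell)
  unlabeled <- setdiff(cells, names(lab))
  if (length(unlabeled) > 0L) {
    warning("dropping ", length(unlabeled), " unlabeled cell(s)")
  }
  empty <- setdiff(unique(lab), lab[intersect(cells, names(lab))])
  if (length(empty) > 0L) {
    warning("group(s) with no cells: ", paste(empty, collapse = ", "))
  }
  out <- t |>
    dplyr::filter(.data$cell %in% names(lab)) |>
    dplyr::mutate(cell = unname(lab[.data$cell])) |>
    dplyr::group_by(.data$cell, .data$chrom, .data$bin1, .data$bin2) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  restore_ct(out, t)
}
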