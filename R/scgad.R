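#' Read gene annotations from a BED file
#'
#' BED6 (or BED4+) with columns chrom, start, end, name, score, strand.
#'
#' @param path BED file.
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_genes_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE, comment = "#")
  if (ncol(df) < 4L) stop("BED input needs at least 4 columns")
  tibble::tibble(
    gene = as.character(df[[4L]]),
    chrom = as.character(df[[1L]]),
    start = as.numeric(df[[2L]]),
    end = as.numeric(df[[3L]]),
    strand = if (ncol(df) >= 6L) as.character(df[[6L]]) else "*"
  )
}

# per-gene bin span at the working resolution; 0-based inclusive bins
gene_bin_span <- function(genes, resolution) {
  genes |>
    dplyr::mutate(
      bin_a = as.integer(floor(.data$start / resolution)),
      bin_b = as.integer(floor((.data$end - 1) / resolution))
    )
}

# sum of contact values over off-diagonal pairs (i, j), lo <= i < j <= hi,
# per cell, for one chromosome; returns named vector over `cells`
window_pair_sum <- function(sub, lo, hi, cells) {
  w <- sub |>
    dplyr::filter(.data$bin1 >= lo, .data$bin2 <= hi,
                  .data$bin1 < .data$bin2) |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(s = sum(.data$count), .groups = "drop")
  out <- stats::setNames(numeric(length(cells)), cells)
  out[w$cell] <- w$s
  out
}

#' Single-cell gene associating domain (scGAD) scores
#'
#' For each cell and gene, the ratio of the interaction frequency summed over
#' off-diagonal locus pairs within the gene body to the average of the same
#' quantity over the immediately adjacent upstream and downstream windows of
#' equal bin length. Scores are computed on BandNorm-normalized contacts and
#' then standardized per cell into z-scores across genes.
#'
#' Only genes at least 100 kb long and spanning at least 2 bins are scoreable.
#' A flank truncated by a chromosome edge is dropped and the remaining flank
#' alone forms the denominator; a gene with no usable flank, or whose flank
#' scores are both zero, is missing (`NA`) and excluded from all downstream
#' tests.
#'
#' @param t A BandNorm-normalized `contact_table`.
#' @param genes Gene table (`gene`, `chrom`, `start`, `end`), e.g. from
#'   [read_genes_bed()] or [simulate_genes()].
#' @param min_gene_length Minimum gene length in bp (default 100,000).
#' @return Object of class `gad_matrix`: list with `raw` and `z` (cells x
#'   genes matrices, NA = missing) and `genes` (the scoreable gene table).
#' @export
compute_scgad <- function(t, genes, min_gene_length = 1e5) {
  res <- ct_resolution(t)
  d <- ct_chrom_bins(t)
  genes <- gene_bin_span(tibble::as_tibble(genes), res) |>
    dplyr::filter(.data$end - .data$start >= min_gene_length,
                  .data$bin_b - .data$bin_a + 1L >= 2L,
                  .data$chrom %in% names(d))
  if (nrow(genes) == 0L) stop("no scoreable genes")
  cells <- sort(unique(t$cell))
  raw <- matrix(NA_real_, length(cells), nrow(genes),
                dimnames = list(cells, genes$gene))
  for (ch in unique(genes$chrom)) {
    sub <- t |> dplyr::filter(.data$chrom == ch)
    dch <- d[[ch]]
    gch <- genes |> dplyr::filter(.data$chrom == ch)
    for (k in seq_len(nrow(gch))) {
      a <- gch$bin_a[k]; b <- gch$bin_b[k]
      w <- b - a + 1L
      within <- window_pair_sum(sub, a, b, cells)
      up_ok <- (a - w) >= 0L
      dn_ok <- (b + w) <= (dch - 1L)
      flanks <- list()
      if (up_ok) flanks$up <- window_pair_sum(sub, a - w, a - 1L, cells)
      if (dn_ok) flanks$dn <- window_pair_sum(sub, b + 1L, b + w, cells)
      if (length(flanks) == 0L) next
      denom <- Reduce(`+`, flanks) / length(flanks)
      val <- ifelse(denom > 0, within / denom, NA_real_)
      raw[, gch$gene[k]] <- val
    }
  }
  z <- t(apply(raw, 1L, function(x) {
    ok <- !is.na(x)
    if (sum(ok) >= 2L && stats::sd(x[ok]) > 0) {
      x[ok] <- (x[ok] - mean(x[ok])) / stats::sd(x[ok])
    } else if (sum(ok) > 0L) {
      x[ok] <- 0
    }
    x
  }))
  dimnames(z) <- dimnames(raw)
  structure(list(raw = raw, z = z, genes = genes), class = "gad_matrix")
}

#' @export
print.gad_matrix <- function(x, ...) {
  cat("# gad_matrix:", nrow(x$z), "cells x", ncol(x$z), "genes (",
      sum(is.na(x$z)), "missing entries )\n")
  invisible(x)
}

#' Tidy a scGAD score matrix
#' @param x A `gad_matrix`.
#' @param ... Unused.
#' @return Long tibble `cell`, `gene`, `raw`, `z`.
#' @export
tidy.gad_matrix <- function(x, ...) {
  tibble::tibble(
    cell = rep(rownames(x$z), times = ncol(x$z)),
    gene = rep(colnames(x$z), each = nrow(x$z)),
    raw = as.vector(x$raw),
    z = as.vector(x$z)
  )
}

#' High-score threshold from the score-vs-rank curve
#'
#' Genes are ranked by their mean standardized scGAD score across cells; both
#' the mean scores and the ranks are min-max scaled to `[0, 1]`. The threshold
#' is the (unscaled) score at the point where the tangent of the
#' monotone-spline-smoothed curve has slope 1. If the curve has slope 1
#' everywhere (an exact straight line) the midpoint is returned; with several
#' crossings the largest rank (most selective threshold) wins.
#'
#' @param g A `gad_matrix`.
#' @return The threshold on the standardized-score scale.
#' @export
gad_score_threshold <- function(g) {
  mu <- colMeans(g$z, na.rm = TRUE)
  mu <- mu[!is.na(mu)]
  if (length(mu) < 10L) stop("need at least 10 scoreable genes")
  mu <- sort(mu)
  rng <- range(mu)
  if (diff(rng) == 0) stop("degenerate score curve (constant scores)")
  x <- (seq_along(mu) - 1) / (length(mu) - 1)
  y <- (mu - rng[1L]) / diff(rng)
  f <- stats::splinefun(x, y, method = "hyman")
  grid <- seq(0, 1, length.out = 2001L)
  slope <- f(grid, deriv = 1L)
  if (all(abs(slope - 1) < 1e-8)) {
    y_star <- f(0.5)
  } else {
    cross <- which(diff(sign(slope - 1)) != 0)
    if (length(cross) == 0L) {
      # no interior crossing: take the grid point with slope closest to 1
      x_star <- grid[which.min(abs(slope - 1))]
    } else {
      i <- cross[length(cross)]  # largest-rank crossing
      x_star <- stats::uniroot(function(v) f(v, deriv = 1L) - 1,
                               c(grid[i], grid[i + 1L]))$root
    }
    y_star <- f(x_star)
  }
  unname(rng[1L] + y_star * diff(rng))
}

#' Per-type test for genes with high scGAD scores
#'
#' For each cell type and gene, a one-sided (greater) one-sample Wilcoxon
#' signed-rank test of the cell-level standardized scores against the
#' threshold; Benjamini-Hochberg adjustment across genes within each type.
#' Exact null distribution for n <= 25, normal approximation with continuity
#' correction above.
#'
#' @param g A `gad_matrix`.
#' @param labels Cell types: named vector (names = cells) or data frame
#'   `cell`, `group`.
#' @param threshold Score threshold, e.g. from [gad_score_threshold()].
#' @return Tibble `type`, `gene`, `n`, `p`, `p_adj`.
#' @export
high_scgad_test <- function(g, labels, threshold) {
  lab <- as_label_vector(labels)
  res <- list()
  for (ty in sort(unique(lab))) {
    cells <- names(lab)[lab == ty]
    cells <- intersect(cells, rownames(g$z))
    if (length(cells) < 3L) next
    for (gene in colnames(g$z)) {
      x <- g$z[cells, gene]
      x <- x[!is.na(x)]
      if (length(x) < 3L) next
      p <- wilcoxon_signed_rank_p(x, threshold)
      res[[length(res) + 1L]] <- tibble::tibble(
        type = ty, gene = gene, n = length(x), p = p
      )
    }
  }
  out <- dplyr::bind_rows(res)
  out |>
    dplyr::group_by(.data$type) |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup()
}

# one-sided (greater) one-sample Wilcoxon signed-rank p-value against mu;
# exact for n <= 25 without ties, otherwise normal approximation with
# continuity correction (zeros dropped, as in the classical test)
wilcoxon_signed_rank_p <- function(x, mu) {
  dif <- x - mu
  dif <- dif[dif != 0]
  n <- length(dif)
  if (n == 0L) return(1)
  r <- rank(abs(dif))
  stat <- sum(r[dif > 0])
  ties <- any(duplicated(abs(dif)))
  if (n <= 25L && !ties) {
    stats::psignrank(stat - 1, n, lower.tail = FALSE)
  } else {
    ex <- n * (n + 1) / 4
    tie_tab <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    stats::pnorm((stat - ex - 0.5) / sqrt(v), lower.tail = FALSE)
  }
}

as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    stats::setNames(as.character(labels$group), labels$cell)
  } else {
    stats::setNames(as.character(labels), names(labels))
  }
}

#' Cell-type-specific marker genes from scGAD scores
#'
#' One-vs-rest marker detection mirroring the standard single-cell workflow:
#' raw scores are per-cell total-normalized (scaled to 10,000 and
#' log1p-transformed) and per-gene z-scaled across cells; candidate genes must
#' be detected (positive normalized score) in at least `min_pct` of in-group
#' cells and have in-group minus out-group mean normalized score of at least
#' `logfc_threshold`; the positive-direction Wilcoxon rank-sum test is then
#' BH-adjusted within each type.
#'
#' @param g A `gad_matrix`.
#' @param labels Cell types (named vector or data frame `cell`, `group`).
#' @param min_pct Minimum detected fraction among in-group cells.
#' @param logfc_threshold Minimum in-group minus out-group mean difference on
#'   the log-normalized scale.
#' @param p_adj_cutoff Adjusted-p cutoff for the returned `marker` flag.
#' @return Tibble `type`, `gene`, `pct_in`, `pct_out`, `effect`, `p`, `p_adj`,
#'   `marker`.
#' @export
celltype_markers <- function(g, labels, min_pct = 0.1,
                             logfc_threshold = 0.25, p_adj_cutoff = 0.05) {
  lab <- as_label_vector(labels)
  types <- sort(unique(lab))
  if (length(types) < 2L) stop("need at least 2 cell types")
  raw <- g$raw[intersect(rownames(g$raw), names(lab)), , drop = FALSE]
  lab <- lab[rownames(raw)]

  # per-cell total-normalization (library-size style) then log1p
  norm <- raw
  norm[is.na(norm)] <- 0
  tot <- rowSums(norm)
  tot[tot == 0] <- 1
  norm <- log1p(norm / tot * 1e4)

  res <- list()
  for (ty in types) {
    in_cells <- rownames(norm)[lab == ty]
    out_cells <- rownames(norm)[lab != ty]
    if (length(in_cells) < 3L) {
      warning("type ", ty, " has fewer than 3 cells; skipped")
      next
    }
    for (gene in colnames(norm)) {
      xi <- norm[in_cells, gene]
      xo <- norm[out_cells, gene]
      pct_in <- mean(xi > 0)
      pct_out <- mean(xo > 0)
      effect <- mean(xi) - mean(xo)
      if (pct_in < min_pct || effect < logfc_threshold) next
      p <- stats::wilcox.test(xi, xo, alternative = "greater",
                              exact = FALSE, correct = TRUE)$p.value
      res[[length(res) + 1L]] <- tibble::tibble(
        type = ty, gene = gene, pct_in = pct_in, pct_out = pct_out,
        effect = effect, p = p
      )
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble::tibble(type = character(), gene = character(),
                          pct_in = numeric(), pct_out = numeric(),
                          effect = numeric(), p = numeric(),
                          p_adj = numeric(), marker = logical()))
  }
  out |>
    dplyr::group_by(.data$type) |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(marker = .data$p_adj < p_adj_cutoff)
}

#' Differential scGAD scores between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene of a supplied gene set, with BH
#' adjustment across the set. A gene missing in at least half of either group
#' is flagged (`sparse_gene`) but still tested on the available cells.
#'
#' @param g A `gad_matrix`.
#' @param labels Two-group labeling (named vector or data frame `cell`,
#'   `group`); exactly two distinct groups.
#' @param gene_set Genes to test (default: all scored genes).
#' @return Tibble `gene`, `n1`, `n2`, `direction` (+1 if group 1 mean higher),
#'   `sparse_gene`, `p`, `p_adj`.
#' @export
differential_scgad <- function(g, labels, gene_set = colnames(g$z)) {
  lab <- as_label_vector(labels)
  groups <- sort(unique(lab))
  if (length(groups) != 2L) stop("need exactly two groups")
  c1 <- intersect(names(lab)[lab == groups[1L]], rownames(g$z))
  c2 <- intersect(names(lab)[lab == groups[2L]], rownames(g$z))
  if (length(c1) == 0L || length(c2) == 0L) stop("both groups must be non-empty")
  gene_set <- intersect(gene_set, colnames(g$z))
  res <- lapply(gene_set, function(gene) {
    x1 <- g$z[c1, gene]; x1 <- x1[!is.na(x1)]
    x2 <- g$z[c2, gene]; x2 <- x2[!is.na(x2)]
    sparse_gene <- length(x1) < length(c1) / 2 || length(x2) < length(c2) / 2
    if (length(x1) == 0L || length(x2) == 0L) {
      return(tibble::tibble(gene = gene, n1 = length(x1), n2 = length(x2),
                            direction = NA_real_, sparse_gene = TRUE,
                            p = NA_real_))
    }
    if (length(x1) == length(x2) &&
        isTRUE(all.equal(unname(sort(x1)), unname(sort(x2))))) {
      p <- 1
    } else {
      n_tot <- length(x1) + length(x2)
      p <- stats::wilcox.test(x1, x2, alternative = "two.sided",
                              exact = n_tot <= 25L, correct = TRUE)$p.value
    }
    tibble::tibble(gene = gene, n1 = length(x1), n2 = length(x2),
                   direction = sign(mean(x1) - mean(x2)),
                   sparse_gene = sparse_gene, p = p)
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "BH"))
}

#' Overlap enrichment between two marker-gene sets
#'
#' Builds the 2x2 membership table of `set_a` and `set_b` over `universe` and
#' tests enrichment with a one-sided Fisher exact test. The returned odds
#' ratio is the sample odds ratio `(both * neither) / (only_a * only_b)`, not
#' the conditional MLE.
#'
#' @param set_a,set_b Character vectors of genes (subsets of `universe`).
#' @param universe All candidate genes.
#' @return Tibble `n_both`, `n_a_only`, `n_b_only`, `n_neither`, `odds_ratio`,
#'   `p`.
#' @export
marker_overlap <- function(set_a, set_b, universe) {
  if (length(universe) == 0L) stop("empty universe")
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                2L, 2L, byrow = TRUE)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (is.nan(or)) or <- ifelse(tab[1, 1] > 0, Inf, 0)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  tibble::tibble(
    n_both = tab[1, 1], n_a_only = tab[1, 2],
    n_b_only = tab[2, 1], n_neither = tab[2, 2],
    odds_ratio = or, p = p
  )
}
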