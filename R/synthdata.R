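#' Configuration for the synthetic scHi-C generator
#'
#' The generator emulates the statistical structure the normalization and
#' de-noising methods assume: a per-type power-law contact decay over bands,
#' log-normal library sizes, optional multiplicative per-batch band effects,
#' cell-type-specific locus-pair enrichment, Bernoulli dropout, and planted
#' within-gene marker enrichment for scGAD tests.
#'
#' The expected rate of cell `c` (type `t`, batch `s`) at pair `r` in band `v`
#' is `l_c * beta_s(v) * A_t * v^(-gamma_t) / m_v * f(t, r)`; counts are
#' Poisson draws thinned to zero by independent Bernoulli(`dropout`) events.
#'
#' @param n_cells_per_type Cells per type.
#' @param types Type names.
#' @param gamma Power-law decay exponent per type.
#' @param amplitude Amplitude `A_t` per type.
#' @param n_bins Bins per chromosome (`D`).
#' @param chromosomes Chromosome names.
#' @param resolution Bin width in bp.
#' @param lib_meanlog,lib_sdlog Log-normal library-size parameters (`l_c`).
#' @param n_batches Number of batches (cells assigned round-robin within each
#'   type so batch and type are not confounded).
#' @param batch_band_sdlog Log-sd of the per-batch, per-band log-normal
#'   multipliers `beta_s(v)`; only used when `n_batches > 1`.
#' @param dropout Bernoulli zero-inflation probability `p0` in `[0, 1)`.
#' @param enriched_fraction Fraction of locus pairs enriched per type.
#' @param enriched_fold Fold change `f` at enriched pairs.
#' @param gene_bins Gene length in bins for [simulate_genes()].
#' @param marker_genes_per_type Planted scGAD marker genes per type.
#' @param marker_fold Within-gene fold for marker genes in their target type.
#' @param seed RNG seed; the same seed yields byte-identical output.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells_per_type = 100,
                             types = c("A", "B", "C"),
                             gamma = seq(0.8, 1.2, length.out = length(types)),
                             amplitude = rep(1, length(types)),
                             n_bins = 60,
                             chromosomes = "chr1",
                             resolution = 1e6,
                             lib_meanlog = log(2000),
                             lib_sdlog = 0.4,
                             n_batches = 1,
                             batch_band_sdlog = 0.3,
                             dropout = 0.1,
                             enriched_fraction = 0.05,
                             enriched_fold = 3,
                             gene_bins = 2,
                             marker_genes_per_type = 0,
                             marker_fold = 3,
                             seed = 1) {
  stopifnot(length(gamma) == length(types),
            length(amplitude) == length(types),
            dropout >= 0, dropout < 1,
            all(amplitude > 0), n_bins >= 4)
  structure(
    list(n_cells_per_type = as.integer(n_cells_per_type),
         types = types, gamma = gamma, amplitude = amplitude,
         n_bins = as.integer(n_bins), chromosomes = chromosomes,
         resolution = resolution,
         lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
         n_batches = as.integer(n_batches),
         batch_band_sdlog = batch_band_sdlog,
         dropout = dropout,
         enriched_fraction = enriched_fraction,
         enriched_fold = enriched_fold,
         gene_bins = as.integer(gene_bins),
         marker_genes_per_type = as.integer(marker_genes_per_type),
         marker_fold = marker_fold,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Simulate a non-overlapping gene annotation
#'
#' Genes of `gene_bins` bins are tiled along each chromosome with gaps equal
#' to the gene length, so every gene's upstream and downstream flank windows
#' (used by scGAD) lie fully on the chromosome and never overlap another gene
#' body. All genes satisfy the 100 kb and 2-bin scGAD rules provided
#' `gene_bins * resolution >= 1e5` and `gene_bins >= 2`.
#'
#' @param cfg A [synthetic_config()].
#' @return Tibble `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
simulate_genes <- function(cfg) {
  w <- cfg$gene_bins
  stopifnot(w >= 2L, w * cfg$resolution >= 1e5)
  rows <- list()
  for (ch in cfg$chromosomes) {
    a <- seq.int(w, cfg$n_bins - 2L * w, by = 2L * w)
    a <- a[a + 2L * w - 1L <= cfg$n_bins - 1L]
    if (length(a) == 0L) next
    rows[[ch]] <- tibble::tibble(
      chrom = ch,
      start = a * cfg$resolution,
      end = (a + w) * cfg$resolution,
      strand = "+"
    )
  }
  out <- dplyr::bind_rows(rows)
  out$gene <- sprintf("gene_%03d", seq_len(nrow(out)))
  out[c("gene", "chrom", "start", "end", "strand")]
}

#' Simulate a synthetic scHi-C dataset
#'
#' Draws per-cell off-diagonal contact counts under the generative model of
#' [synthetic_config()] and returns the contact table, the cell metadata, and
#' a truth record holding every latent quantity (library sizes, batch band
#' multipliers, enriched pair sets, planted marker genes) for recovery tests.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `contacts` (a `contact_table`), `meta` (tibble `cell`,
#'   `cell_type`, `batch`), `genes` (tibble, only when markers are planted)
#'   and `truth` (list; see [true_rate_matrix()]).
#' @export
simulate_cells <- function(cfg) {
  set.seed(cfg$seed)
  n_types <- length(cfg$types)
  n <- cfg$n_cells_per_type * n_types
  meta <- tibble::tibble(
    cell = sprintf("cell_%04d", seq_len(n)),
    cell_type = rep(cfg$types, each = cfg$n_cells_per_type)
  )
  meta$batch <- paste0("batch", ((seq_len(n) - 1L) %% cfg$n_batches) + 1L)

  d <- cfg$n_bins
  pairs <- tidyr::crossing(bin1 = 0:(d - 2L), bin2 = 1:(d - 1L)) |>
    dplyr::filter(.data$bin2 > .data$bin1) |>
    dplyr::mutate(band = .data$bin2 - .data$bin1,
                  m_v = d - .data$band)
  n_pairs <- nrow(pairs)

  # per-batch per-band multiplicative effects
  beta <- matrix(1, cfg$n_batches, d - 1L,
                 dimnames = list(paste0("batch", seq_len(cfg$n_batches)),
                                 as.character(1:(d - 1L))))
  if (cfg$n_batches > 1L) {
    beta[] <- stats::rlnorm(length(beta), 0, cfg$batch_band_sdlog)
  }

  # type-specific enriched pair sets
  enriched <- lapply(stats::setNames(cfg$types, cfg$types), function(ty) {
    k <- round(cfg$enriched_fraction * n_pairs)
    if (k == 0L) return(integer(0))
    sort(sample.int(n_pairs, k))
  })

  # planted scGAD marker genes: within-gene pair enrichment in the target type
  genes <- NULL
  markers <- tibble::tibble(gene = character(), type = character())
  marker_idx <- lapply(stats::setNames(cfg$types, cfg$types),
                       function(ty) integer(0))
  if (cfg$marker_genes_per_type > 0L) {
    genes <- simulate_genes(cfg)
    need <- cfg$marker_genes_per_type * n_types
    if (need > nrow(genes)) stop("not enough genes to plant markers")
    picked <- sample(genes$gene, need)
    markers <- tibble::tibble(gene = picked,
                              type = rep(cfg$types,
                                         each = cfg$marker_genes_per_type))
    gb <- gene_bin_span(genes, cfg$resolution)
    for (ty in cfg$types) {
      gs <- gb[gb$gene %in% markers$gene[markers$type == ty], ]
      idx <- integer(0)
      for (k in seq_len(nrow(gs))) {
        sel <- pairs$bin1 >= gs$bin_a[k] & pairs$bin2 <= gs$bin_b[k]
        idx <- c(idx, which(sel))
      }
      marker_idx[[ty]] <- sort(unique(idx))
    }
  }

  lib <- stats::rlnorm(n, cfg$lib_meanlog, cfg$lib_sdlog)

  rows <- vector("list", n * length(cfg$chromosomes))
  ri <- 0L
  for (ch in cfg$chromosomes) {
    base_by_type <- lapply(seq_len(n_types), function(ti) {
      f <- rep(1, n_pairs)
      f[enriched[[cfg$types[ti]]]] <- cfg$enriched_fold
      mi <- marker_idx[[cfg$types[ti]]]
      f[mi] <- f[mi] * cfg$marker_fold
      cfg$amplitude[ti] * pairs$band^(-cfg$gamma[ti]) / pairs$m_v * f
    })
    for (i in seq_len(n)) {
      ti <- match(meta$cell_type[i], cfg$types)
      bi <- match(meta$batch[i], rownames(beta))
      rate <- lib[i] * beta[bi, pairs$band] * base_by_type[[ti]]
      y <- stats::rpois(n_pairs, rate)
      if (cfg$dropout > 0) {
        y <- y * stats::rbinom(n_pairs, 1L, 1 - cfg$dropout)
      }
      nz <- y > 0
      ri <- ri + 1L
      rows[[ri]] <- tibble::tibble(
        cell = meta$cell[i], chrom = ch,
        bin1 = pairs$bin1[nz], bin2 = pairs$bin2[nz],
        count = as.numeric(y[nz])
      )
    }
  }
  contacts <- contact_table(
    dplyr::bind_rows(rows[seq_len(ri)]),
    resolution = cfg$resolution,
    chrom_sizes = stats::setNames(rep(cfg$n_bins * cfg$resolution,
                                      length(cfg$chromosomes)),
                                  cfg$chromosomes)
  )
  truth <- list(
    config = cfg,
    lib = stats::setNames(lib, meta$cell),
    beta = beta,
    pairs = pairs,
    enriched = enriched,
    markers = markers,
    marker_pair_idx = marker_idx
  )
  list(contacts = contacts, meta = meta, genes = genes, truth = truth)
}

#' True (pre-dropout) expected rate matrix of a simulation
#'
#' Reconstructs the Poisson rate for every cell and off-diagonal locus pair of
#' one chromosome from the truth record, for recovery tests (e.g. correlating
#' de-noised values with the generating rates).
#'
#' @param truth The `truth` element returned by [simulate_cells()].
#' @param meta The matching metadata tibble.
#' @param cells Cells to include (default all, in `meta` order).
#' @return Dense matrix cells x pairs; the pair grid is `truth$pairs`.
#' @export
true_rate_matrix <- function(truth, meta, cells = meta$cell) {
  cfg <- truth$config
  pairs <- truth$pairs
  out <- matrix(0, length(cells), nrow(pairs),
                dimnames = list(cells, NULL))
  for (i in seq_along(cells)) {
    row <- meta[meta$cell == cells[i], ]
    ti <- match(row$cell_type, cfg$types)
    f <- rep(1, nrow(pairs))
    f[truth$enriched[[row$cell_type]]] <- cfg$enriched_fold
    mi <- truth$marker_pair_idx[[row$cell_type]]
    f[mi] <- f[mi] * cfg$marker_fold
    out[i, ] <- truth$lib[[row$cell]] *
      truth$beta[match(row$batch, rownames(truth$beta)), pairs$band] *
      cfg$amplitude[ti] * pairs$band^(-cfg$gamma[ti]) / pairs$m_v * f
  }
  out
}
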