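# Shared toy builders and cached expensive fixtures. Fixtures are built once
# per test run and reused across files (including the acceptance tests).

toy_ct <- function(df, res = 1e6, sizes = c(chr1 = 10e6)) {
  contact_table(df, resolution = res, chrom_sizes = sizes)
}

# random sparse upper-triangular map for property tests
random_ct <- function(n_cells = 5, d = 8, seed = 1, density = 0.5,
                      res = 1e6, chrom = "chr1") {
  set.seed(seed)
  pairs <- expand.grid(bin1 = 0:(d - 1), bin2 = 0:(d - 1))
  pairs <- pairs[pairs$bin2 >= pairs$bin1, ]
  rows <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    keep <- runif(nrow(pairs)) < density
    if (!any(keep)) keep[1] <- TRUE
    data.frame(cell = sprintf("c%02d", i), chrom = chrom,
               bin1 = pairs$bin1[keep], bin2 = pairs$bin2[keep],
               count = rpois(sum(keep), 4) + 1)
  }))
  toy_ct(rows, res = res, sizes = stats::setNames(d * res, chrom))
}

.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# 2-type negative binomial band-matrix dataset with known rates, plus its fit
nb_recovery_fixture <- function() fixture("nb_recovery", function() {
  set.seed(7)
  n <- 200; P <- 50
  cells <- sprintf("c%03d", seq_len(n))
  type <- rep(c("A", "B"), each = n / 2)
  frA <- rgamma(P, 2); frA <- frA / sum(frA)
  frB <- rgamma(P, 2); frB <- frB / sum(frB)
  lib <- rlnorm(n, log(300), 0.3)
  rates <- t(vapply(seq_len(n), function(i) {
    lib[i] * (if (type[i] == "A") frA else frB)
  }, numeric(P)))
  Y <- matrix(rnbinom(n * P, mu = rates, size = 2), n, P)
  Y <- Y * matrix(rbinom(n * P, 1, 0.9), n, P)
  cols <- tibble::tibble(band = 1L, bin1 = seq_len(P) - 1L, bin2 = seq_len(P))
  bm <- schicnorm:::new_band_matrix("chr1", 1L, cells, cols, Y)
  fit <- fit_band_group(bm, cfg = scvi_config(latent_dim = 10, epochs = 400,
                                              seed = 11))
  list(bm = bm, Y = Y, rates = rates, type = stats::setNames(type, cells),
       fit = fit)
})

# 3-type simulation at the default study conditions, with BandNorm and the
# pooled band-model fit
end_to_end_fixture <- function() fixture("end_to_end", function() {
  cfg <- synthetic_config(seed = 5)
  sim <- simulate_cells(cfg)
  bn <- band_norm(sim$contacts)
  fit <- scvi3d(sim$contacts, sim$meta,
                scvi_config(latent_dim = 10, epochs = 400, seed = 9))
  list(cfg = cfg, sim = sim, bn = bn, fit = fit)
})

# scGAD marker-recovery simulation: 20 planted marker genes, fold 3
scgad_fixture <- function() fixture("scgad", function() {
  cfg <- synthetic_config(
    n_cells_per_type = 100, types = c("A", "B"), gamma = c(1, 1),
    n_bins = 200, resolution = 1e5, enriched_fraction = 0,
    gene_bins = 2, marker_genes_per_type = 10, marker_fold = 3, seed = 21
  )
  sim <- simulate_cells(cfg)
  bn <- band_norm(sim$contacts)
  gad <- compute_scgad(bn$table, sim$genes)
  list(cfg = cfg, sim = sim, gad = gad,
       labels = stats::setNames(sim$meta$cell_type, sim$meta$cell))
})

# brute-force oracles ---------------------------------------------------------

ari_bruteforce <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  2 * (n00 * n11 - n01 * n10) /
    ((n00 + n01) * (n01 + n11) + (n00 + n10) * (n10 + n11))
}

silhouette_bruteforce <- function(e, labels) {
  e <- as.matrix(e)
  n <- nrow(e)
  dm <- as.matrix(stats::dist(e))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(dm[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(dm[i, labels == l])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

snn_bruteforce <- function(e, k) {
  e <- as.matrix(e)
  n <- nrow(e)
  dm <- as.matrix(stats::dist(e))
  sets <- lapply(seq_len(n), function(i) {
    ord <- order(dm[i, ], seq_len(n))
    ord <- c(i, setdiff(ord, i))
    ord[seq_len(k)]
  })
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      out[i, j] <- length(intersect(sets[[i]], sets[[j]])) /
        length(union(sets[[i]], sets[[j]]))
    }
  }
  out
}

# exact one-sided signed-rank p by enumerating all sign assignments
signed_rank_bruteforce <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- signs %*% r
  mean(stats >= obs)
}

# exact two-sided rank-sum p by enumerating group-1 allocations (R convention)
rank_sum_bruteforce <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1)
  r <- rank(pooled)
  obs_u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  if (obs_u > n1 * length(x2) / 2) {
    min(1, 2 * mean(us >= obs_u))
  } else {
    min(1, 2 * mean(us <= obs_u))
  }
}

fisher_bruteforce <- function(n_both, n_a, n_b, n_universe) {
  ks <- n_both:min(n_a, n_b)
  sum(vapply(ks, function(k) {
    choose(n_a, k) * choose(n_universe - n_a, n_b - k) / choose(n_universe, n_b)
  }, numeric(1)))
}
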