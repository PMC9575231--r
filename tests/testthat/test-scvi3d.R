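test_that("pooling schedules follow the five published compositions", {
  s1 <- pooling_schedule(10, 1)
  expect_equal(s1$groups, list(1L, 2:3, 4:6, 7:10))

  s2 <- pooling_schedule(20, 2)
  expect_equal(s2$groups[1:10], as.list(1:10))
  expect_equal(s2$groups[11:13], list(11:12, 13:15, 16:19))
  expect_equal(s2$groups[[14]], 20L)

  s3 <- pooling_schedule(40, 3)
  expect_equal(s3$groups, list(1:5, 6:15, 16:35, 36:40))

  expect_equal(pooling_schedule(25, 4)$groups, list(1:10, 11:20, 21:25))

  s5 <- pooling_schedule(25, 5)
  expect_equal(s5$groups[1:10], as.list(1:10))
  expect_equal(s5$groups[11:12], list(11:20, 21:25))

  # V = 1 collapses to a single group for every strategy
  for (s in 1:5) expect_equal(pooling_schedule(1, s)$groups, list(1L))

  # groups always partition 1..V
  for (s in 1:5) for (V in c(2, 5, 9, 23, 57)) {
    g <- pooling_schedule(V, s)$groups
    expect_equal(sort(unlist(g)), seq_len(V))
  }

  # strategy 1 with a group cap absorbs the tail into the final group
  sc <- pooling_schedule(30, 1, max_groups = 3)
  expect_length(sc$groups, 3L)
  expect_equal(sc$groups[[3]], 4:30)
})

test_that("select_variable_bands ranks bands by across-cell total variance", {
  t <- random_ct(n_cells = 6, d = 8, seed = 31)
  bands <- band_split(t, "chr1")
  expect_identical(select_variable_bands(bands, 1), bands)

  # force one band to be constant across cells: it must be dropped first
  bands[[2]]$matrix[] <- 1
  kept <- select_variable_bands(bands, (length(bands) - 1) / length(bands))
  expect_false("2" %in% names(kept))

  v <- vapply(bands, function(b) var(Matrix::rowSums(b$matrix)), numeric(1))
  kept2 <- select_variable_bands(bands, 3 / length(bands))
  expect_setequal(names(kept2),
                  names(sort(v, decreasing = TRUE))[1:3])
})

test_that("analytic ELBO gradients match finite differences", {
  set.seed(42)
  n <- 6; P <- 5; K <- 3; H <- 4; B <- 2
  Y <- matrix(rpois(n * P, 3), n, P)
  Y[1, 1] <- 0; Y[2, ] <- c(0, 0, 1, 0, 2)
  X <- log1p(Y)
  S <- cbind(rep(c(1, 0), 3), rep(c(0, 1), 3))
  theta_map <- c(1, 1, 2, 2, 2)
  pm <- rep(1, n); ps <- rep(0.5, n)
  par <- schicnorm:::vae_init_params(P, K, H, B, 2)
  eps_z <- matrix(rnorm(n * K), n, K)
  eps_d <- matrix(rnorm(n), n, 1)
  lg <- schicnorm:::vae_loss_grads(par, Y, X, S, theta_map, pm, ps,
                                   eps_z, eps_d)
  num <- function(nm, i) {
    h <- 1e-6
    f <- function(p) schicnorm:::vae_loss_grads(
      p, Y, X, S, theta_map, pm, ps, eps_z, eps_d, want_grads = FALSE)$loss
    p1 <- par; p1[[nm]][i] <- p1[[nm]][i] + h
    p2 <- par; p2[[nm]][i] <- p2[[nm]][i] - h
    (f(p1) - f(p2)) / (2 * h)
  }
  for (nm in names(par)) {
    for (i in sample(length(par[[nm]]), min(2, length(par[[nm]])))) {
      expect_equal(lg$grads[[nm]][i], num(nm, i), tolerance = 1e-3)
    }
  }
})

test_that("with no dropout and large dispersion the likelihood is Poisson", {
  y <- c(0, 1, 3, 7, 12)
  m <- c(0.5, 1, 2.5, 6.2, 11)
  ll <- schicnorm:::zinb_loglik(y, m, 1e8, -30)
  expect_equal(as.numeric(ll), dpois(y, m, log = TRUE), tolerance = 1e-5)

  # and the zero-inflation term mixes in correctly at moderate dropout
  g <- 0.3
  pi <- plogis(g)
  manual0 <- log(pi + (1 - pi) * dnbinom(0, size = 2, mu = 1.5))
  expect_equal(as.numeric(schicnorm:::zinb_loglik(0, 1.5, 2, g)), manual0)
  manual2 <- log(1 - pi) + dnbinom(2, size = 2, mu = 1.5, log = TRUE)
  expect_equal(as.numeric(schicnorm:::zinb_loglik(2, 1.5, 2, g)), manual2)
})

test_that("fitting is deterministic and filters zero-interaction cells", {
  set.seed(1)
  n <- 12; P <- 8
  Y <- matrix(rpois(n * P, 2), n, P)
  Y[3, ] <- 0; Y[9, ] <- 0
  cols <- tibble::tibble(band = 1L, bin1 = 0:(P - 1), bin2 = 1:P)
  bm <- schicnorm:::new_band_matrix("chr1", 1L, sprintf("c%02d", 1:n),
                                    cols, Y)
  cfg <- scvi_config(latent_dim = 3, hidden_dim = 8, epochs = 30, seed = 4)
  f1 <- fit_band_group(bm, cfg = cfg)
  f2 <- fit_band_group(bm, cfg = cfg)
  expect_identical(f1$z, f2$z)
  expect_setequal(f1$filtered_cell_ids, c("c03", "c09"))
  expect_false(any(c("c03", "c09") %in% f1$kept_cell_ids))

  # mean fractions sum to one per cell; dispersion and size factors positive
  expect_equal(rowSums(f1$mu), rep(1, length(f1$kept_cell_ids)))
  expect_true(all(f1$pi >= 0 & f1$pi <= 1))
  expect_true(all(f1$theta > 0))
  expect_true(all(f1$d > 0))

  # under 2 usable cells the group is skipped with a warning
  Y2 <- Y; Y2[-1, ] <- 0
  bm2 <- schicnorm:::new_band_matrix("chr1", 1L, sprintf("c%02d", 1:n),
                                     cols, Y2)
  expect_warning(out <- fit_band_group(bm2, cfg = cfg), "fewer than 2")
  expect_null(out)
})

test_that("latent assembly zero-imputes filtered cells and orders groups", {
  mk_fit <- function(chrom, bands, cells, k, seed) {
    set.seed(seed)
    structure(list(chrom = chrom, bands = bands, kept_cell_ids = cells,
                   filtered_cell_ids = character(),
                   z = matrix(rnorm(length(cells) * k), length(cells), k)),
              class = "band_vae_fit")
  }
  all_cells <- c("a", "b", "c")
  f1 <- mk_fit("chr1", 1L, c("a", "b", "c"), 3, 1)
  f2 <- mk_fit("chr1", 2:3, c("a", "c"), 3, 2)  # cell b filtered here
  emb <- assemble_latent(list(f1, f2), all_cells)
  expect_equal(dim(emb), c(3L, 6L))
  expect_equal(unname(emb["b", 4:6]), rep(0, 3))
  expect_equal(unname(emb["a", 1:3]), f1$z[1, ])

  # permuting the input order leaves the assembled matrix unchanged
  emb2 <- assemble_latent(list(f2, f1), all_cells)
  expect_identical(emb, emb2)

  expect_error(assemble_latent(list(f1), c("a", "a", "b")), "duplicate")
})

test_that("de-noised values are non-negative and sum to the size factor", {
  fx <- nb_recovery_fixture()
  den <- denoise_band_group(fx$fit)
  expect_true(all(den$matrix >= 0))
  expect_equal(unname(rowSums(den$matrix)), unname(fx$fit$d),
               tolerance = 1e-8)
  expect_identical(den$cell_ids, fx$fit$kept_cell_ids)
})

test_that("the band model recovers planted structure from ZINB counts", {
  fx <- nb_recovery_fixture()
  fit <- fx$fit
  truth_types <- fx$type[fit$kept_cell_ids]
  km <- kmeans_labels(fit$z, 2, seed = 1)
  expect_gte(adjusted_rand_index(km, truth_types), 0.8)

  den <- denoise_band_group(fit)
  tru <- fx$rates[match(fit$kept_cell_ids, names(fx$type)), ]
  expect_gte(cor(as.vector(den$matrix), as.vector(tru)), 0.8)

  # de-noised values track the generating rates better than the raw counts
  raw <- fx$Y[match(fit$kept_cell_ids, names(fx$type)), ]
  sp_den <- mean(vapply(seq_len(nrow(tru)), function(i) {
    cor(den$matrix[i, ], tru[i, ], method = "spearman")
  }, numeric(1)))
  sp_raw <- mean(vapply(seq_len(nrow(tru)), function(i) {
    cor(raw[i, ], tru[i, ], method = "spearman")
  }, numeric(1)))
  expect_gt(sp_den, sp_raw)
})

test_that("the ELBO trace improves and is smoothly non-decreasing", {
  fx <- nb_recovery_fixture()
  tr <- fx$fit$elbo_trace
  expect_gt(tr[length(tr)], tr[1])
  sm <- stats::filter(tr, rep(1 / 25, 25), sides = 1)
  sm <- sm[!is.na(sm)]
  steps <- diff(sm)
  expect_gt(mean(steps), 0)
  expect_gte(mean(steps >= -1e-3), 0.8)
})

test_that("a batch-aware fit mixes planted batches better than an unaware fit", {
  build <- function(batch_aware) {
    cfg <- synthetic_config(n_cells_per_type = 50, types = c("A", "B"),
                            gamma = c(0.9, 1.2), n_bins = 25, n_batches = 2,
                            batch_band_sdlog = 0.6, seed = 13)
    sim <- simulate_cells(cfg)
    vc <- scvi_config(latent_dim = 8, epochs = 250, seed = 3,
                      batch_aware = batch_aware)
    fit <- scvi3d(sim$contacts, sim$meta, vc)
    b <- sim$meta$batch[match(rownames(fit$latent), sim$meta$cell)]
    median(ilisi_scores(fit$latent, b, perplexity = 20))
  }
  i_unaware <- fixture("ilisi_unaware", function() build(FALSE))
  i_aware <- fixture("ilisi_aware", function() build(TRUE))
  expect_gt(i_aware, i_unaware)
})
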