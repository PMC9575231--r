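#' Band pooling schedules
#'
#' Distant bands are sparse; pooling concatenates several band matrices into
#' one model fit. Five strategies over bands `1..V`:
#'
#' * **1** (default, progressive): group sizes 1, 2, 3, 4, ... — band 1 alone,
#'   then bands 2-3, 4-6, 7-10, and so on. With a finite `max_groups` the last
#'   group absorbs all remaining bands.
#' * **2**: bands 1-10 each alone, then sizes 2, 3, 4, ... (11-12, 13-15,
#'   16-19, ...).
#' * **3**: sizes 5, 10, 20, 40, ... (doubling).
#' * **4**: every ten bands merged (sizes 10, 10, ...).
#' * **5**: bands 1-10 each alone, then sizes 10, 10, ...
#'
#' @param V Number of off-diagonal bands.
#' @param strategy Integer 1-5.
#' @param max_groups Cap on the number of groups (strategy 1); once reached the
#'   final group pools all remaining bands. Default `Inf`.
#' @return An object of class `pooling_schedule`: list with `strategy` and
#'   `groups`, a list of integer band-index vectors partitioning `1:V`.
#' @export
pooling_schedule <- function(V, strategy = 1, max_groups = Inf) {
  stopifnot(V >= 1, strategy %in% 1:5)
  sizes <- switch(as.character(strategy),
    "1" = seq_len(V),
    "2" = c(rep(1L, 10L), seq.int(2L, V + 1L)),
    "3" = 5L * 2L^(0:ceiling(log2(max(V / 5, 1)) + 1L)),
    "4" = rep(10L, ceiling(V / 10)),
    "5" = c(rep(1L, 10L), rep(10L, ceiling(V / 10)))
  )
  groups <- list()
  nxt <- 1L
  for (s in sizes) {
    if (nxt > V) break
    if (strategy == 1 && is.finite(max_groups) &&
        length(groups) == max_groups - 1L) {
      groups[[length(groups) + 1L]] <- seq.int(nxt, V)
      nxt <- V + 1L
      break
    }
    hi <- min(nxt + s - 1L, V)
    groups[[length(groups) + 1L]] <- seq.int(nxt, hi)
    nxt <- hi + 1L
  }
  if (nxt <= V) groups[[length(groups) + 1L]] <- seq.int(nxt, V)
  structure(list(strategy = strategy, groups = groups),
            class = "pooling_schedule")
}

#' @export
print.pooling_schedule <- function(x, ...) {
  cat("# pooling_schedule (strategy ", x$strategy, "): ",
      paste(vapply(x$groups, function(g) {
        if (length(g) == 1L) as.character(g) else paste0(g[1], "-", g[length(g)])
      }, character(1)), collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' Select high-variance bands
#'
#' Optional pre-filter: bands are ranked by the across-cell variance of their
#' band totals, and the top fraction is kept (original band order preserved).
#'
#' @param bands List of `band_matrix` objects.
#' @param keep_fraction Fraction in (0, 1] of bands to keep.
#' @return Subset of `bands`.
#' @export
select_variable_bands <- function(bands, keep_fraction) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  if (keep_fraction == 1) return(bands)
  v <- vapply(bands, function(b) stats::var(Matrix::rowSums(b$matrix)),
              numeric(1))
  n_keep <- max(1L, ceiling(keep_fraction * length(bands)))
  keep <- sort(order(v, decreasing = TRUE)[seq_len(n_keep)])
  bands[keep]
}

#' Configuration for the band variational autoencoder
#'
#' @param latent_dim Latent dimension `K` (default 100; reduce for small
#'   problems).
#' @param hidden_dim Hidden-layer width of the encoder and decoders.
#' @param epochs Full-batch training epochs.
#' @param learning_rate Adam step size.
#' @param seed Master seed; fans out to initialization and sampling, making
#'   fits bit-for-bit reproducible on one device.
#' @param dispersion `"per-band"` (each constituent band of a pooled group has
#'   its own Gamma dispersion) or `"per-group"`.
#' @param batch_aware Condition the decoders on the cell batch label?
#' @param keep_fraction Optional fraction for [select_variable_bands()];
#'   `NULL` keeps all bands.
#' @param pool_strategy Pooling strategy id (1-5), see [pooling_schedule()].
#' @param max_groups Group-count cap for strategy 1.
#' @return A list of class `scvi_config`.
#' @export
scvi_config <- function(latent_dim = 100, hidden_dim = 128, epochs = 400,
                        learning_rate = 1e-3, seed = 1,
                        dispersion = c("per-band", "per-group"),
                        batch_aware = FALSE, keep_fraction = NULL,
                        pool_strategy = 1, max_groups = Inf) {
  stopifnot(latent_dim >= 1, hidden_dim >= 1, epochs >= 1)
  structure(
    list(latent_dim = as.integer(latent_dim),
         hidden_dim = as.integer(hidden_dim),
         epochs = as.integer(epochs),
         learning_rate = learning_rate,
         seed = as.integer(seed),
         dispersion = match.arg(dispersion),
         batch_aware = isTRUE(batch_aware),
         keep_fraction = keep_fraction,
         pool_strategy = pool_strategy,
         max_groups = max_groups),
    class = "scvi_config"
  )
}

# ---- zero-inflated negative binomial likelihood -----------------------------

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Element-wise ZINB log-likelihood. y: counts; m: NB mean; th: dispersion;
# g: dropout logit (P(dropout) = sigmoid(g)). NB parametrized so that
# var = m + m^2/th; the Gamma-Poisson mixture with shape th and mean m.
zinb_loglik <- function(y, m, th, g) {
  a <- th * (log(th) - log(th + m))
  # y == 0: log( pi + (1 - pi) * NB(0) ) with pi = sigmoid(g)
  mx <- pmax(g, a)
  ll0 <- mx + log(exp(g - mx) + exp(a - mx)) - softplus(g)
  # y > 0: log(1 - pi) + NB log density
  ll1 <- -softplus(g) + lgamma(y + th) - lgamma(th) - lgamma(y + 1) +
    a + y * (log(m) - log(th + m))
  out <- ifelse(y > 0, ll1, ll0)
  if (is.matrix(y)) out <- matrix(out, nrow(y), ncol(y)) else out
  out
}

# Gradients of the element-wise ZINB log-likelihood wrt m, th, g.
zinb_grads <- function(y, m, th, g) {
  pos <- y > 0
  sig <- stats::plogis(g)
  a <- th * (log(th) - log(th + m))
  mx <- pmax(g, a)
  eg <- exp(g - mx); ea <- exp(a - mx)
  wa <- ea / (eg + ea)
  wg <- 1 - wa
  dm <- wa * (-th / (th + m))
  dth <- wa * (log(th / (th + m)) + m / (th + m))
  dg <- wg - sig
  dm1 <- y / m - (th + y) / (th + m)
  dth1 <- digamma(y + th) - digamma(th) + log(th) + 1 -
    log(th + m) - (th + y) / (th + m)
  dm[pos] <- dm1[pos]
  dth[pos] <- dth1[pos]
  dg[pos] <- -sig[pos]
  list(dm = dm, dth = dth, dg = dg)
}

# ---- parameter plumbing -----------------------------------------------------

vae_init_params <- function(P, K, H, B, n_theta) {
  gl <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, sd = sqrt(1 / nin)), nin, nout)
  }
  list(
    W1 = gl(P, H), b1 = numeric(H),
    Wm = gl(H, K), bm = numeric(K),
    Wv = gl(H, K), bv = numeric(K),
    Wd = gl(H, 1), bd = numeric(1),
    We = gl(H, 1), be = numeric(1),
    W2 = gl(K + B, H), b2 = numeric(H),
    Wr = gl(H, P), br = numeric(P),
    Wp = gl(H, P), bp = numeric(P) - 2,  # start with low dropout probability
    log_theta = numeric(n_theta)
  )
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

row_softmax <- function(R) {
  R <- R - apply(R, 1L, max)
  E <- exp(R)
  E / rowSums(E)
}

# Forward pass. eps_z/eps_d NULL means deterministic (posterior means).
vae_forward <- function(par, X, S, theta_col, eps_z = NULL, eps_d = NULL) {
  H1 <- tanh(sweep(X %*% par$W1, 2L, par$b1, "+"))
  mu_z <- sweep(H1 %*% par$Wm, 2L, par$bm, "+")
  ls_z <- pmin(pmax(sweep(H1 %*% par$Wv, 2L, par$bv, "+"), -12), 8)
  mu_d <- sweep(H1 %*% par$Wd, 2L, par$bd, "+")
  ls_d <- pmin(pmax(sweep(H1 %*% par$We, 2L, par$be, "+"), -12), 8)
  z <- if (is.null(eps_z)) mu_z else mu_z + exp(ls_z / 2) * eps_z
  u <- if (is.null(eps_d)) mu_d else mu_d + exp(ls_d / 2) * eps_d
  dvec <- exp(pmin(pmax(u, -30), 30))
  A <- cbind(z, S)
  H2 <- tanh(sweep(A %*% par$W2, 2L, par$b2, "+"))
  MU <- row_softmax(sweep(H2 %*% par$Wr, 2L, par$br, "+"))
  G <- sweep(H2 %*% par$Wp, 2L, par$bp, "+")
  M <- as.vector(dvec) * MU
  TH <- matrix(theta_col, nrow(X), length(theta_col), byrow = TRUE)
  list(H1 = H1, mu_z = mu_z, ls_z = ls_z, mu_d = mu_d, ls_d = ls_d,
       z = z, u = u, dvec = as.vector(dvec), A = A, H2 = H2,
       MU = MU, G = G, M = M, TH = TH)
}

# Loss (mean negative ELBO per cell) and analytic gradients.
vae_loss_grads <- function(par, Y, X, S, theta_map, prior_mu, prior_sd,
                           eps_z, eps_d, want_grads = TRUE) {
  n <- nrow(Y); P <- ncol(Y); K <- ncol(par$Wm); B <- ncol(S)
  theta_col <- exp(par$log_theta)[theta_map]
  fw <- vae_forward(par, X, S, theta_col, eps_z, eps_d)
  M <- pmax(fw$M, 1e-10)
  ll <- zinb_loglik(Y, M, fw$TH, fw$G)
  kl_z <- 0.5 * (fw$mu_z^2 + exp(fw$ls_z) - fw$ls_z - 1)
  sd_q2 <- exp(fw$ls_d)
  kl_d <- log(prior_sd) - fw$ls_d / 2 +
    (sd_q2 + (fw$mu_d - prior_mu)^2) / (2 * prior_sd^2) - 0.5
  loss <- (-sum(ll) + sum(kl_z) + sum(kl_d)) / n
  if (!want_grads) return(list(loss = loss, elbo = -loss))
  sc <- 1 / n

  gr <- zinb_grads(Y, M, fw$TH, fw$G)
  gM <- -sc * gr$dm
  gG <- -sc * gr$dg
  gTH <- -sc * gr$dth
  # dispersion: theta = exp(log_theta[theta_map]) shared down columns
  g_log_theta <- as.vector(
    tapply(colSums(gTH) * theta_col, theta_map, sum)[as.character(
      seq_along(par$log_theta))])
  g_log_theta[is.na(g_log_theta)] <- 0

  gMu <- gM * fw$dvec                     # row-broadcast of d
  gd <- rowSums(gM * fw$MU)
  gR <- fw$MU * (gMu - rowSums(gMu * fw$MU))
  gH2 <- gR %*% t(par$Wr) + gG %*% t(par$Wp)
  gpre2 <- gH2 * (1 - fw$H2^2)
  gA <- gpre2 %*% t(par$W2)
  gz <- gA[, seq_len(K), drop = FALSE]

  gu <- gd * fw$dvec                      # chain through d = exp(u)
  gmu_z <- sc * fw$mu_z + gz
  gls_z <- sc * 0.5 * (exp(fw$ls_z) - 1)
  gmu_d <- sc * (fw$mu_d - prior_mu) / prior_sd^2 + gu
  gls_d <- sc * (exp(fw$ls_d) / (2 * prior_sd^2) - 0.5)
  if (!is.null(eps_z)) gls_z <- gls_z + gz * eps_z * 0.5 * exp(fw$ls_z / 2)
  if (!is.null(eps_d)) gls_d <- gls_d + gu * eps_d * 0.5 * exp(fw$ls_d / 2)

  gH1 <- gmu_z %*% t(par$Wm) + gls_z %*% t(par$Wv) +
    gmu_d %*% t(par$Wd) + gls_d %*% t(par$We)
  gpre1 <- gH1 * (1 - fw$H1^2)

  grads <- list(
    W1 = t(X) %*% gpre1, b1 = colSums(gpre1),
    Wm = t(fw$H1) %*% gmu_z, bm = colSums(gmu_z),
    Wv = t(fw$H1) %*% gls_z, bv = colSums(gls_z),
    Wd = t(fw$H1) %*% gmu_d, bd = sum(gmu_d),
    We = t(fw$H1) %*% gls_d, be = sum(gls_d),
    W2 = t(fw$A) %*% gpre2, b2 = colSums(gpre2),
    Wr = t(fw$H2) %*% gR, br = colSums(gR),
    Wp = t(fw$H2) %*% gG, bp = colSums(gG),
    log_theta = g_log_theta
  )
  list(loss = loss, elbo = -loss, grads = grads)
}

# ---- fitting ----------------------------------------------------------------

#' Fit the zero-inflated Gamma-Poisson model to one (pooled) band matrix
#'
#' A compact amortized variational inference implementation of the band model:
#' a latent cell state `z ~ Normal(0, I_K)` and a latent log size factor
#' `log d ~ Normal(mu_d, sigma_d^2)` (prior moments matched to the observed
#' log band-group totals, per batch when batch-aware) generate counts through
#' a decoder that maps `(z, batch)` to per-pair mean fractions `mu` (softmax,
#' so fractions are non-negative and sum to 1 per cell, making `d` the group
#' total scale) and dropout logits. The Gamma-Poisson mixture with per-band
#' dispersion `delta^v` gives marginally negative binomial counts with mean
#' `d * mu`; an observed zero arises from dropout or from the NB itself.
#' Trained full-batch with Adam on the reparametrized ELBO.
#'
#' Cells with zero total across all locus pairs in the group are removed
#' before fitting and reported in `filtered_cell_ids`.
#'
#' @param bm A `band_matrix` (possibly pooled, see [band_pool()]).
#' @param meta Optional cell metadata with columns `cell` and (if
#'   `cfg$batch_aware`) `batch`.
#' @param cfg A [scvi_config()].
#' @return An object of class `band_vae_fit` with latent means `z`
#'   (kept cells x K), mean fractions `mu`, dropout probabilities `pi`, size
#'   factors `d`, per-band dispersions `theta`, the ELBO trace, and the
#'   column/band bookkeeping needed by [denoise_band_group()]. `NULL` (with a
#'   warning) if fewer than 2 cells remain.
#' @export
fit_band_group <- function(bm, meta = NULL, cfg = scvi_config()) {
  Y <- as.matrix(bm$matrix)
  totals <- rowSums(Y)
  keep <- totals > 0
  filtered <- bm$cell_ids[!keep]
  if (sum(keep) < 2L) {
    warning("band group ", paste(range(bm$bands), collapse = "-"),
            ": fewer than 2 cells with interactions; skipped")
    return(NULL)
  }
  Y <- Y[keep, , drop = FALSE]
  cells <- bm$cell_ids[keep]
  n <- nrow(Y); P <- ncol(Y); K <- cfg$latent_dim; H <- cfg$hidden_dim

  # batch design
  if (cfg$batch_aware && !is.null(meta) && "batch" %in% names(meta)) {
    bvec <- meta$batch[match(cells, meta$cell)]
    if (anyNA(bvec)) stop("metadata is missing batch labels for some cells")
    levels_b <- sort(unique(as.character(bvec)))
    S <- outer(as.character(bvec), levels_b, `==`) * 1
  } else {
    levels_b <- "all"
    S <- matrix(1, n, 1L)
  }
  B <- ncol(S)

  # LogNormal prior moments for the size factor, from observed log totals
  lt <- log(rowSums(Y))
  prior_mu <- numeric(n); prior_sd <- numeric(n)
  for (b in seq_len(B)) {
    idx <- S[, b] == 1
    prior_mu[idx] <- mean(lt[idx])
    prior_sd[idx] <- max(stats::sd(lt[idx]), 0.1)
    if (is.na(prior_sd[idx][1])) prior_sd[idx] <- 1
  }

  theta_map <- if (cfg$dispersion == "per-band") {
    match(bm$cols$band, sort(unique(bm$cols$band)))
  } else rep(1L, P)
  n_theta <- max(theta_map)

  set.seed(cfg$seed)
  par <- vae_init_params(P, K, H, B, n_theta)
  st <- adam_init(par)
  X <- log1p(Y)
  trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    eps_z <- matrix(stats::rnorm(n * K), n, K)
    eps_d <- matrix(stats::rnorm(n), n, 1L)
    lg <- vae_loss_grads(par, Y, X, S, theta_map, prior_mu, prior_sd,
                         eps_z, eps_d)
    if (!is.finite(lg$loss)) {
      stop("non-finite loss at epoch ", ep,
           " (band group ", paste(range(bm$bands), collapse = "-"), ")")
    }
    trace[ep] <- lg$elbo
    up <- adam_step(par, lg$grads, st, cfg$learning_rate)
    par <- up$params; st <- up$state
  }

  # deterministic pass at the posterior means
  theta_col <- exp(par$log_theta)[theta_map]
  fw <- vae_forward(par, X, S, theta_col)
  structure(
    list(
      chrom = bm$chrom,
      bands = bm$bands,
      cols = bm$cols,
      kept_cell_ids = cells,
      filtered_cell_ids = filtered,
      z = fw$mu_z,
      mu = fw$MU,
      pi = stats::plogis(fw$G),
      d = fw$dvec,
      theta = stats::setNames(exp(par$log_theta),
                              if (cfg$dispersion == "per-band")
                                sort(unique(bm$cols$band)) else "group"),
      batch_levels = levels_b,
      elbo_trace = trace,
      config = cfg,
      params = par
    ),
    class = "band_vae_fit"
  )
}

#' @export
print.band_vae_fit <- function(x, ...) {
  cat("# band_vae_fit:", x$chrom, "bands",
      paste(range(x$bands), collapse = "-"), "-",
      length(x$kept_cell_ids), "cells,", nrow(x$cols), "pairs, K =",
      ncol(x$z), "\n")
  invisible(x)
}

#' Tidy the latent coordinates of a band-group fit
#' @param x A `band_vae_fit`.
#' @param ... Unused.
#' @return Tibble: `cell`, `dimension`, `value`.
#' @export
tidy.band_vae_fit <- function(x, ...) {
  tibble::tibble(
    cell = rep(x$kept_cell_ids, times = ncol(x$z)),
    dimension = rep(seq_len(ncol(x$z)), each = nrow(x$z)),
    value = as.vector(x$z)
  )
}

#' One-row summary of a band-group fit
#' @param x A `band_vae_fit`.
#' @param ... Unused.
#' @export
glance.band_vae_fit <- function(x, ...) {
  tibble::tibble(
    chrom = x$chrom,
    band_lo = min(x$bands), band_hi = max(x$bands),
    n_cells = length(x$kept_cell_ids),
    n_filtered = length(x$filtered_cell_ids),
    n_pairs = nrow(x$cols),
    latent_dim = ncol(x$z),
    final_elbo = x$elbo_trace[length(x$elbo_trace)]
  )
}

#' De-noised contact values from a fitted band group
#'
#' The dropout-free expected count for each kept cell and locus pair:
#' `d_c * mu_rc`, the negative binomial mean. Per cell these sum to `d_c`
#' because the mean fractions sum to 1.
#'
#' @param fit A `band_vae_fit`.
#' @return A `band_matrix` of de-noised values (filtered cells omitted).
#' @export
denoise_band_group <- function(fit) {
  new_band_matrix(
    chrom = fit$chrom,
    bands = fit$bands,
    cell_ids = fit$kept_cell_ids,
    cols = fit$cols,
    matrix = fit$d * fit$mu
  )
}

#' Concatenate latent embeddings across band groups
#'
#' Columns are ordered by (chromosome, band group); cells filtered from a
#' group (no interactions there) get exactly 0 in that group's columns.
#'
#' @param fits List of `band_vae_fit` objects.
#' @param all_cells Character vector of all cell ids (rows of the result).
#' @return A numeric matrix `length(all_cells) x sum(K)` with rownames, plus a
#'   `provenance` attribute (tibble `column`, `chrom`, `band_lo`, `band_hi`,
#'   `dim`).
#' @export
assemble_latent <- function(fits, all_cells) {
  fits <- Filter(Negate(is.null), fits)
  stopifnot(length(fits) > 0L)
  if (anyDuplicated(all_cells)) stop("duplicate cell ids")
  ord <- order(vapply(fits, `[[`, character(1), "chrom"),
               vapply(fits, function(f) min(f$bands), numeric(1)))
  fits <- fits[ord]
  mats <- lapply(fits, function(f) {
    k <- ncol(f$z)
    m <- matrix(0, length(all_cells), k,
                dimnames = list(all_cells, NULL))
    idx <- match(f$kept_cell_ids, all_cells)
    if (anyNA(idx)) stop("fit contains cells absent from all_cells")
    m[idx, ] <- f$z
    m
  })
  out <- do.call(cbind, mats)
  prov <- dplyr::bind_rows(lapply(seq_along(fits), function(i) {
    tibble::tibble(
      chrom = fits[[i]]$chrom,
      band_lo = min(fits[[i]]$bands),
      band_hi = max(fits[[i]]$bands),
      dim = seq_len(ncol(fits[[i]]$z))
    )
  }))
  prov$column <- seq_len(nrow(prov))
  attr(out, "provenance") <- prov[c("column", "chrom", "band_lo",
                                    "band_hi", "dim")]
  out
}

#' Fit the band model across chromosomes and pooled band groups
#'
#' High-level driver: splits each chromosome into bands, optionally keeps only
#' high-variance bands, pools bands by the configured schedule, fits the
#' zero-inflated Gamma-Poisson model per group, and concatenates the latent
#' means into one embedding (missing cells imputed with 0). Per-group seeds
#' are derived deterministically from the master seed.
#'
#' @param t A `contact_table` of raw counts.
#' @param meta Optional cell metadata (`cell`, optional `batch`).
#' @param cfg A [scvi_config()].
#' @param chroms Chromosomes to fit; default all in `t`.
#' @param denoise Also return de-noised contacts as a `contact_table`?
#' @return Object of class `scvi3d_fit`: list with `latent` (cells x columns
#'   matrix), `fits` (per-group `band_vae_fit`s), `denoised` (or `NULL`) and
#'   `config`.
#' @export
scvi3d <- function(t, meta = NULL, cfg = scvi_config(), chroms = NULL,
                   denoise = FALSE) {
  if (is.null(chroms)) chroms <- names(ct_chrom_bins(t))
  all_cells <- sort(unique(t$cell))
  fits <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    bands <- band_split(t, ch, drop_diagonal = TRUE, cells = all_cells)
    if (!is.null(cfg$keep_fraction)) {
      bands <- select_variable_bands(bands, cfg$keep_fraction)
    }
    V <- length(bands)
    sched <- pooling_schedule(V, cfg$pool_strategy, cfg$max_groups)
    for (gi in seq_along(sched$groups)) {
      bm <- band_pool(bands[sched$groups[[gi]]])
      gcfg <- cfg
      gcfg$seed <- (cfg$seed + 7919L * ci + 104729L * gi) %% 2147483647L
      fits[[length(fits) + 1L]] <- fit_band_group(bm, meta, gcfg)
    }
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) stop("no band group could be fitted")
  latent <- assemble_latent(fits, all_cells)
  denoised <- NULL
  if (denoise) {
    denoised <- band_merge(lapply(fits, denoise_band_group), t)
  }
  structure(list(latent = latent, fits = fits, denoised = denoised,
                 config = cfg, cell_ids = all_cells),
            class = "scvi3d_fit")
}

#' @export
print.scvi3d_fit <- function(x, ...) {
  cat("# scvi3d_fit:", length(x$cell_ids), "cells,", length(x$fits),
      "band group(s),", ncol(x$latent), "latent columns\n")
  invisible(x)
}

#' One-row-per-group summary of a full fit
#' @param x An `scvi3d_fit`.
#' @param ... Unused.
#' @export
tidy.scvi3d_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(x$fits, glance))
}

#' One-row summary of a full fit
#' @param x An `scvi3d_fit`.
#' @param ... Unused.
#' @export
glance.scvi3d_fit <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$cell_ids),
    n_groups = length(x$fits),
    latent_columns = ncol(x$latent),
    mean_final_elbo = mean(vapply(x$fits, function(f)
      f$elbo_trace[length(f$elbo_trace)], numeric(1)))
  )
}
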