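test_that("uniform contact maps give raw ratio 1 for interior genes", {
  d <- 20
  pairs <- expand.grid(bin1 = 0:(d - 1), bin2 = 0:(d - 1))
  pairs <- pairs[pairs$bin2 > pairs$bin1, ]
  t <- toy_ct(data.frame(cell = "c1", chrom = "chr1",
                         bin1 = pairs$bin1, bin2 = pairs$bin2, count = 2),
              res = 1e5, sizes = c(chr1 = d * 1e5))
  genes <- tibble::tibble(gene = c("g1", "g2"), chrom = "chr1",
                          start = c(5e5, 10e5), end = c(8e5, 13e5),
                          strand = "+")
  gad <- compute_scgad(t, genes)
  expect_equal(unname(gad$raw["c1", ]), c(1, 1))
})

test_that("the hand-enumerated toy gene gives raw ratio 2", {
  # gene bins [10,12]: within pairs (10,11)=1, (10,12)=2, (11,12)=3, sum 6
  # upstream [7,9] sums to 2; downstream [13,15] sums to 4; ratio 6/3 = 2
  df <- data.frame(
    cell = "c1", chrom = "chr1",
    bin1 = c(10, 10, 11, 7, 7, 8, 13, 13, 14),
    bin2 = c(11, 12, 12, 8, 9, 9, 14, 15, 15),
    count = c(1, 2, 3, 1, 0.5, 0.5, 2, 1, 1)
  )
  t <- toy_ct(df, res = 1e5, sizes = c(chr1 = 20e5))
  genes <- tibble::tibble(gene = "g", chrom = "chr1",
                          start = 10e5, end = 13e5, strand = "+")
  gad <- compute_scgad(t, genes)
  expect_equal(unname(gad$raw["c1", "g"]), 2)
})

test_that("scores are per-cell standardized and scale-invariant", {
  fx <- scgad_fixture()
  z <- fx$gad$z
  mu <- apply(z, 1, mean, na.rm = TRUE)
  sd_ <- apply(z, 1, sd, na.rm = TRUE)
  expect_true(all(abs(mu) < 1e-6))
  expect_true(all(abs(sd_ - 1) < 1e-6))

  # multiplying a single cell's contacts by a positive constant changes nothing
  t <- random_ct(n_cells = 3, d = 30, seed = 77, density = 0.8, res = 1e5)
  genes <- tibble::tibble(gene = paste0("g", 1:5), chrom = "chr1",
                          start = c(3, 8, 13, 18, 23) * 1e5,
                          end = c(5, 10, 15, 20, 25) * 1e5, strand = "+")
  g1 <- compute_scgad(t, genes)
  t2 <- tibble::as_tibble(t)
  t2$count[t2$cell == "c02"] <- t2$count[t2$cell == "c02"] * 9.3
  g2 <- compute_scgad(toy_ct(t2, res = 1e5, sizes = c(chr1 = 30e5)), genes)
  expect_equal(g1$z, g2$z, tolerance = 1e-12)
  expect_equal(g1$raw, g2$raw, tolerance = 1e-12)
})

test_that("the slope-1 tangent threshold matches closed-form cases", {
  # convex curve y = x^2: tangent slope 1 at x = 0.5, scaled score 0.25
  n <- 101
  x <- seq(0, 1, length.out = n)
  g <- structure(list(z = matrix(rep(3 + 10 * x^2, each = 4), nrow = 4,
                                 dimnames = list(paste0("c", 1:4),
                                                 paste0("g", 1:n)))),
                 class = "gad_matrix")
  expect_equal(gad_score_threshold(g), 3 + 10 * 0.25, tolerance = 1e-3)

  # exact straight line: every point has slope 1, midpoint returned
  g2 <- structure(list(z = matrix(rep(seq(2, 12, length.out = 20), each = 4),
                                  nrow = 4,
                                  dimnames = list(paste0("c", 1:4),
                                                  paste0("g", 1:20)))),
                  class = "gad_matrix")
  expect_equal(gad_score_threshold(g2), 7)

  # threshold always falls inside the observed score range
  fx <- scgad_fixture()
  thr <- gad_score_threshold(fx$gad)
  mu <- colMeans(fx$gad$z, na.rm = TRUE)
  expect_gte(thr, min(mu))
  expect_lte(thr, max(mu))

  expect_error(gad_score_threshold(structure(
    list(z = matrix(1, 4, 15)), class = "gad_matrix")), "degenerate")
})

test_that("the one-sample signed-rank p matches exact enumeration", {
  set.seed(3)
  for (rep in 1:5) {
    x <- round(rnorm(6, 0.3, 1), 3)
    thr <- 0
    p_pkg <- schicnorm:::wilcoxon_signed_rank_p(x, thr)
    expect_equal(p_pkg, signed_rank_bruteforce(x, thr), tolerance = 1e-12)
  }
  # all scores below threshold: one-sided p at least 0.5
  expect_gte(schicnorm:::wilcoxon_signed_rank_p(c(-3, -1, -2, -0.5), 0), 0.5)
  # all equal to the threshold: p = 1 by convention
  expect_equal(schicnorm:::wilcoxon_signed_rank_p(rep(2, 5), 2), 1)
})

test_that("high_scgad_test applies BH within type and holds its type-I error", {
  fx <- scgad_fixture()
  thr <- gad_score_threshold(fx$gad)
  ht <- high_scgad_test(fx$gad, fx$labels, thr)
  expect_true(all(c("type", "gene", "p", "p_adj") %in% names(ht)))
  expect_true(all(ht$p_adj >= ht$p - 1e-15))
  # BH never exceeds 1 and is monotone in p within type
  for (ty in unique(ht$type)) {
    sub <- ht[ht$type == ty, ]
    expect_true(all(sub$p_adj <= 1))
    expect_false(is.unsorted(sub$p_adj[order(sub$p)]))
  }

  # null simulation: scores symmetric around the threshold, p < 0.05 in ~5%
  set.seed(9)
  n_genes <- 400
  zn <- matrix(rnorm(20 * n_genes), 20,
               dimnames = list(paste0("c", 1:20), paste0("g", 1:n_genes)))
  gn <- structure(list(z = zn), class = "gad_matrix")
  hn <- high_scgad_test(gn, stats::setNames(rep("t1", 20), rownames(zn)), 0)
  frac <- mean(hn$p < 0.05)
  se <- sqrt(0.05 * 0.95 / n_genes)
  expect_lt(abs(frac - 0.05), 3 * se + 1e-9)
})

test_that("planted marker genes are recovered and filters behave", {
  fx <- scgad_fixture()
  mk <- celltype_markers(fx$gad, fx$labels)
  planted <- fx$sim$truth$markers
  hits <- mk[mk$marker, ]
  recall <- mean(mapply(function(g, ty) {
    any(hits$gene == g & hits$type == ty)
  }, planted$gene, planted$type))
  expect_gte(recall, 0.9)
  # and planted genes are not called in the wrong type
  wrong <- merge(hits, planted, by = "gene")
  wrong <- wrong[wrong$type.x != wrong$type.y, ]
  expect_equal(nrow(wrong), 0L)
})

test_that("the detected-fraction filter excludes rarely detected genes", {
  # gene detected in 5% of in-group cells is excluded by min.pct = 0.1
  set.seed(12)
  n <- 40
  raw <- matrix(rexp(n * 10, 1) + 0.5, n, 10,
                dimnames = list(sprintf("c%02d", 1:n), paste0("g", 1:10)))
  raw[, "g1"] <- 0
  in_cells <- 1:20
  raw[in_cells[1], "g1"] <- 50  # detected in 1/20 = 5% of in-group cells
  g <- structure(list(raw = raw, z = raw), class = "gad_matrix")
  labels <- stats::setNames(rep(c("in", "out"), each = 20), rownames(raw))
  mk <- celltype_markers(g, labels)
  expect_false(any(mk$type == "in" & mk$gene == "g1"))
})

test_that("null gene distributions are almost never called markers", {
  set.seed(31)
  n_rep <- 20L
  n_genes <- 8L
  marker_calls <- 0L
  for (r in seq_len(n_rep)) {
    raw <- matrix(rexp(60 * n_genes, 1), 60, n_genes,
                  dimnames = list(sprintf("c%02d", 1:60),
                                  paste0("g", 1:n_genes)))
    g <- structure(list(raw = raw, z = raw), class = "gad_matrix")
    labels <- stats::setNames(rep(c("a", "b"), each = 30), rownames(raw))
    mk <- celltype_markers(g, labels)
    marker_calls <- marker_calls + sum(mk$marker)
  }
  # per gene-and-type combination, a marker call under the null is rare
  total <- n_rep * n_genes * 2L
  expect_lte(marker_calls / total, 0.05)
})

test_that("differential_scgad matches the exact rank-sum oracle", {
  mkgad <- function(v1, v2) {
    z <- matrix(c(v1, v2), ncol = 1,
                dimnames = list(c(paste0("a", seq_along(v1)),
                                  paste0("b", seq_along(v2))), "g1"))
    structure(list(z = z), class = "gad_matrix")
  }
  lab <- function(n1, n2) stats::setNames(rep(c("g1grp", "g2grp"), c(n1, n2)),
                                          c(paste0("a", 1:n1),
                                            paste0("b", 1:n2)))
  set.seed(5)
  for (rep in 1:5) {
    v1 <- round(rnorm(3, 1), 3); v2 <- round(rnorm(3), 3)
    res <- differential_scgad(mkgad(v1, v2), lab(3, 3))
    expect_equal(res$p, rank_sum_bruteforce(v1, v2), tolerance = 1e-12)
    expect_equal(res$direction, sign(mean(v1) - mean(v2)))
    # swapping the group labels flips the direction
    lab_sw <- lab(3, 3)
    lab_sw[] <- ifelse(lab_sw == "g1grp", "g2grp", "g1grp")
    res_sw <- differential_scgad(mkgad(v1, v2), lab_sw)
    expect_equal(res_sw$direction, -res$direction)
  }

  # identical groups give p = 1
  v <- c(0.2, 1.4, -0.7)
  expect_equal(differential_scgad(mkgad(v, v), lab(3, 3))$p, 1)
})

test_that("marker_overlap reports the sample odds ratio and exact p", {
  # disjoint sets covering the universe: odds ratio 0
  u <- paste0("g", 1:40)
  res0 <- marker_overlap(u[1:20], u[21:40], u)
  expect_equal(res0$odds_ratio, 0)

  # [[10,10],[10,70]] against the hypergeometric summation oracle
  u2 <- paste0("g", 1:100)
  a <- u2[1:20]; b <- c(u2[1:10], u2[21:30])
  res <- marker_overlap(a, b, u2)
  expect_equal(res$n_both, 10)
  expect_equal(res$odds_ratio, (10 * 70) / (10 * 10))
  expect_equal(res$p, fisher_bruteforce(10, 20, 20, 100), tolerance = 1e-12)

  # identical half-splits are maximally enriched
  u3 <- paste0("g", 1:60)
  res3 <- marker_overlap(u3[1:30], u3[1:30], u3)
  expect_lt(res3$p, 1e-6)

  expect_error(marker_overlap("a", "b", character(0)), "empty")
})
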