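# schicnorm

Normalization, de-noising and gene-level scoring of single-cell Hi-C
(scHi-C) data in R.

## The problem

scHi-C assays measure 3D genome organization one cell at a time. The
resulting per-cell contact matrices are extremely sparse and carry two large
systematic biases: interaction frequencies decay with the genomic distance
between the two loci (the *band bias*), and sequencing depth varies strongly
between cells and batches. Both must be removed before cells can be compared,
clustered into cell types, or scored at gene level.

`schicnorm` works on *band-transformed* data: the upper triangle of each
cell's contact matrix is stratified into diagonal bands, where band `v` holds
the `m_v = D - v` locus pairs `(i, j)` with `j - i = v` for a chromosome of
`D` bins, and bands at the same distance are stacked across cells into a
cells × locus-pairs band matrix. On top of this the package provides:

* **Scaling normalizers.** *CellScale* rescales each cell's total to a common
  library size (10,000). *BandScale* divides each pair by its cell's band
  mean `L^{cv}/m_v`. *BandNorm* removes depth and distance bias per cell and
  adds back a shared decay profile:

  `C_r^{cv} = Y_r^{cv} / L^{cv} · α(v)`,   `α(v) = Σ_c L^{cv} / N`,

  where `L^{cv}` is the band total of cell `c` in band `v` and `α(v)` the
  mean band total across all `N` cells.

* **A zero-inflated Gamma-Poisson variational autoencoder** fitted
  independently per (pooled) band group. Each count is modeled as
  `Y ~ ZINB(d_cv · μ_r^{cv}, δ^v, π_r^{cv})` with a latent cell state
  `z ~ N(0, I_K)`, a log-normal size factor `d_cv` whose prior moments come
  from the observed log band totals, a softmax decoder `η(z, batch)` for the
  mean fractions, and a dropout decoder `ω(z, batch)`. Per-cell latent means
  are concatenated across band groups (cells absent from a group are
  zero-imputed) into one embedding; the dropout-free NB means `d_cv · μ` are
  the de-noised contacts. Distant, sparse bands are pooled by progressive
  schedules (sizes 1, 2, 3, 4, ... by default; four alternatives included).

* **scGAD scores.** Per cell and gene, the ratio of interaction frequency
  within the gene body to the mean over equal-length flanking windows,
  computed on BandNorm-normalized contacts and standardized per cell —
  plus the slope-1 tangent rule for the high-score threshold, one-sample
  signed-rank tests against it, one-vs-rest marker detection
  (min.pct = 0.1, effect ≥ 0.25, BH correction), two-group differential
  tests, and Fisher overlap tests between marker sets.

* **Evaluation metrics.** Adjusted Rand index, mean silhouette, K-means with
  300 restarts, Louvain clustering with a resolution bisection targeting a
  cluster count, iLISI batch-mixing scores, SNN-Jaccard similarity, and
  average-linkage cell-type dendrograms.

* **A synthetic-data generator** with known ground truth (power-law decay,
  type-specific pair enrichment, log-normal depths, band-wise batch effects,
  dropout, planted marker genes) so every claim above is testable offline.

## Worked example

```r
library(schicnorm)

cfg <- synthetic_config(seed = 5)     # 3 cell types x 100 cells, D = 60 bins
sim <- simulate_cells(cfg)

bn <- band_norm(sim$contacts)
tidy(bn)                               # per-band factors: chrom, band, m_v, alpha
pc <- embed_pca(vectorize_cells(bn$table), 50)
truth <- sim$meta$cell_type[match(rownames(pc), sim$meta$cell)]
adjusted_rand_index(kmeans_labels(pc, 3, seed = 2), truth)
#> [1] 1

fit <- scvi3d(sim$contacts, sim$meta,
              scvi_config(latent_dim = 10, epochs = 400, seed = 9))
adjusted_rand_index(kmeans_labels(fit$latent, 3, seed = 2), truth)
#> [1] 0.9502229
```

BandNorm followed by PCA and K-means recovers the three simulated cell types
perfectly (ARI 1); the pooled band model reaches ARI 0.95 from its
concatenated latent embedding. `autoplot(fit)` shows the per-group ELBO
traces and `plot_embedding(pc, truth)` the separation.

A command-line front end wrapping the same functions ships in
`inst/cli/schic.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/schic.R", package="schicnorm"))')" \
    simulate --out sim/ --seed 2
```

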