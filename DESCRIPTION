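Package: schicnorm
Title: Normalization, De-Noising and Gene-Level Scoring of Single-Cell Hi-C Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-cell Hi-C (scHi-C) contact matrices: band
    transformation of sparse per-cell contact maps, scaling normalizers that
    correct sequencing-depth and genomic-distance (band) bias (CellScale,
    BandScale, BandNorm), a zero-inflated Gamma-Poisson variational
    autoencoder fitted per pooled band group that yields per-cell latent
    embeddings and de-noised contacts, single-cell gene associating domain
    (scGAD) scores with marker-gene statistics, clustering and batch-mixing
    evaluation metrics (ARI, silhouette, iLISI, SNN similarity), and a
    synthetic-data generator emulating contact decay, library-size variation,
    batch effects and dropout for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    mclust,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
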