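Package: tcrdiff
Title: Denoising Diffusion Modelling of Epitope-Specific TCR CDR3beta
    Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates epitope-specific T cell receptor (TCR) CDR3beta
    sequences at the nucleotide level with a conditional denoising
    diffusion probabilistic model (DDPM), and predicts TCR-epitope
    binding with classifiers built on the diffusion model's encoder.
    Includes codon back-translation and one-hot nucleotide encoding,
    corpus assembly with healthy-repertoire negative sampling, a
    synthetic repertoire generator for fully offline training and
    evaluation, a pluggable 1024-dimensional epitope encoder, and the
    quantitative evaluation suite: position-wise Pearson correlation of
    nucleotide frequencies, cosine-similarity comparisons, latent-space
    analysis (PCA, UMAP, k-nearest-neighbour purity), classification
    metrics, and position-frequency-matrix export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
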