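# Shared study fixtures for the end-to-end tests: a two-class mutation-free
# repertoire and one conditional diffusion model trained on it (trained
# lazily, once per test run), plus the labelled corpus used for the binding
# predictor. Sizes follow the package's compact study configuration.

.study <- new.env(parent = emptyenv())

study_spec <- function() {
  synthetic_spec(n_epitopes = 2L, tcrs_per_epitope = 50L, mutation_rate = 0,
                 seed = 42L)
}

study_repertoire <- function() {
  if (is.null(.study$rep)) .study$rep <- generate_repertoire(study_spec())
  .study$rep
}

study_model <- function() {
  if (is.null(.study$model)) {
    .study$model <- train_generator(study_repertoire()$pairs,
                                    config = study_generator_config(),
                                    seed = 7L)
  }
  .study$model
}

# Separable labelled corpus for the predictor: cognate pairs (label 1) and
# healthy-pool decoys (label 0), 100 + 100.
study_binding_pairs <- function() {
  if (is.null(.study$bp_pairs)) {
    spec <- synthetic_spec(n_epitopes = 2L, tcrs_per_epitope = 50L,
                           mutation_rate = 0.1, seed = 42L)
    rep <- generate_repertoire(spec)
    pool <- generate_healthy_pool(120L, spec)
    neg <- make_negatives(pool, rep$epitopes, 100L, "random",
                          positives = rep$pairs, seed = 3L)
    .study$bp_pool <- pool
    .study$bp_rep <- rep
    .study$bp_pairs <- dplyr::bind_rows(
      dplyr::select(rep$pairs, "cdr3b", "epitope", "label"),
      dplyr::select(neg, "cdr3b", "epitope", "label")
    )
  }
  .study$bp_pairs
}
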