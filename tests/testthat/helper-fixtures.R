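# Shared fixtures: a tiny denoiser configuration for fast structural and
# determinism tests (12-nt sequences, narrow channels), and a small
# two-class repertoire.

tiny_unet_config <- function() {
  unet_config(l_max = 12L, channels = c(4L), bottleneck = 8L,
              t_dim = 8L, n_blocks = 1L)
}

tiny_diffusion_config <- function(max_epochs = 5L) {
  diffusion_config(lr = 2e-3, max_epochs = max_epochs, batch_size = Inf,
                   early_stop_patience = Inf, unet = tiny_unet_config())
}

tiny_pairs <- function(n = 8L, epitope = "GILGFVFTL") {
  tibble::tibble(
    cdr3b = rep("CASF", n),
    epitope = epitope,
    hla = "HLA-A*02:01",
    label = 1L
  )
}

tiny_trained_model <- function(seed = 5L, max_epochs = 4L) {
  train_generator(tiny_pairs(), config = tiny_diffusion_config(max_epochs),
                  seed = seed)
}

random_peptide <- function(len) {
  paste0(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V"), len, replace = TRUE),
         collapse = "")
}

random_nt <- function(len) {
  paste0(sample(c("A", "T", "G", "C"), len, replace = TRUE), collapse = "")
}

# Brute-force oracle: per-position Pearson correlation between the
# nucleotide-frequency columns of two sets, written directly from the
# textbook covariance formula.
brute_positionwise_r <- function(set_a, set_b, l_max) {
  count_col <- function(seqs, p) {
    vapply(c("A", "T", "G", "C"), function(nuc) {
      mean(vapply(seqs, function(s) {
        p <= nchar(s) && substr(s, p, p) == nuc
      }, logical(1)))
    }, numeric(1))
  }
  vapply(seq_len(l_max), function(p) {
    a <- count_col(set_a, p)
    b <- count_col(set_b, p)
    ca <- a - mean(a)
    cb <- b - mean(b)
    den <- sqrt(sum(ca^2) * sum(cb^2))
    if (den == 0) NA_real_ else sum(ca * cb) / den
  }, numeric(1))
}

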