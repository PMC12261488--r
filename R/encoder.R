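EMBED_DIM <- 1024L

# Deterministic 31-bit polynomial string hash (platform independent; doubles
# stay below 2^53 so the modular arithmetic is exact).
string_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  h
}

#' Epitope encoders
#'
#' Every stage that conditions on an epitope peptide consumes a fixed
#' 1024-dimensional embedding, matching the output width of large protein
#' language models. The encoder is pluggable: any deterministic function
#' `peptide -> numeric(1024)` wrapped with [epitope_encoder_custom()] is
#' accepted, so a protein-language-model backend (e.g. mean-pooled
#' per-residue states projected to 1024) can be swapped in without touching
#' the pipeline. The default encoder is a lightweight, fully offline
#' featurization: hashed k-mer counts (k = 1..3) plus sinusoidal positional
#' features folded into 1024 bins, then unit-normalized. It is injective in
#' practice on short peptides, position sensitive and needs no weights.
#'
#' @return An object of class `epitope_encoder`.
#' @export
default_epitope_encoder <- function() {
  epitope_encoder_custom(default_epitope_features, name = "hashed_kmer_sinusoidal")
}

#' @param fn Function mapping a single peptide string to a finite
#'   numeric vector of length 1024.
#' @param name Backend name recorded in run manifests.
#' @rdname default_epitope_encoder
#' @export
epitope_encoder_custom <- function(fn, name = "custom") {
  structure(
    list(fn = fn, name = name, dim = EMBED_DIM, cache = new.env(parent = emptyenv())),
    class = "epitope_encoder"
  )
}

default_epitope_features <- function(epitope) {
  res <- strsplit(epitope, "")[[1]]
  v <- numeric(EMBED_DIM)
  for (k in 1:3) {
    if (length(res) < k) next
    for (i in seq_len(length(res) - k + 1)) {
      kmer <- paste0(res[i:(i + k - 1)], collapse = "")
      bin <- string_hash(paste0(k, ":", kmer)) %% EMBED_DIM + 1
      v[bin] <- v[bin] + 1
    }
  }
  # positional channel: residue-keyed bins accumulate smooth functions of the
  # position, so permutations of the same residues embed differently
  for (i in seq_along(res)) {
    bs <- string_hash(paste0("sin:", res[i])) %% EMBED_DIM + 1
    bc <- string_hash(paste0("cos:", res[i])) %% EMBED_DIM + 1
    v[bs] <- v[bs] + sin(i * 0.7)
    v[bc] <- v[bc] + cos(i * 0.7)
  }
  v / sqrt(sum(v^2))
}

#' Embed epitope peptides
#'
#' Maps peptides to the 1024-dimensional conditioning vectors injected into
#' every denoiser layer and consumed by the binding predictors. Results are
#' cached per peptide within the encoder object.
#'
#' @param epitopes Character vector of epitope peptides (standard residues).
#' @param encoder An `epitope_encoder`; default [default_epitope_encoder()].
#' @return A numeric matrix, one row per peptide, 1024 columns.
#' @export
embed_epitopes <- function(epitopes, encoder = default_epitope_encoder()) {
  stopifnot(inherits(encoder, "epitope_encoder"))
  out <- matrix(0, nrow = length(epitopes), ncol = EMBED_DIM)
  for (i in seq_along(epitopes)) {
    p <- epitopes[i]
    if (is.na(p) || !nzchar(p)) abort("epitope must be non-empty")
    bad <- setdiff(strsplit(p, "")[[1]], AA_STANDARD)
    if (length(bad) > 0) {
      abort(sprintf("invalid residue '%s' in epitope '%s'", bad[1], p))
    }
    if (is.null(encoder$cache[[p]])) {
      v <- encoder$fn(p)
      if (length(v) != EMBED_DIM || any(!is.finite(v))) {
        abort(sprintf("encoder must return a finite vector of length %d", EMBED_DIM))
      }
      encoder$cache[[p]] <- as.numeric(v)
    }
    out[i, ] <- encoder$cache[[p]]
  }
  out
}

#' @param epitope A single peptide.
#' @rdname embed_epitopes
#' @export
embed_epitope <- function(epitope, encoder = default_epitope_encoder()) {
  drop(embed_epitopes(epitope, encoder))
}
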