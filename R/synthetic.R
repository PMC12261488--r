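#' Specification for a synthetic TCR repertoire
#'
#' Describes the statistical structure the generator emulates: CDR3beta
#' sequences with conserved terminal residues (default prefix `CASS`,
#' suffix `F`) and a variable middle region; several epitope classes, each
#' with a class-specific core motif shared (up to point mutations) by its
#' cognate TCRs; lengths in the conventional 7-24 residue window. Epitopes
#' are random 9-mers and HLA loci are assigned uniformly over A/B/C.
#'
#' @param n_epitopes Number of epitope classes.
#' @param tcrs_per_epitope Cognate TCRs per epitope class (default 50,
#'   within the typical 45-60 per-epitope depth of curated repertoires).
#' @param length_range Inclusive CDR3beta length bounds in residues.
#' @param prefix,suffix Conserved terminal residues.
#' @param motif_len Length of the class-specific core motif.
#' @param mutation_rate Per-position probability that a core residue is
#'   mutated away from the class motif (default 0.1).
#' @param seed Integer seed; all outputs are deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_epitopes = 2L, tcrs_per_epitope = 50L,
                           length_range = c(7L, 24L),
                           prefix = "CASS", suffix = "F",
                           motif_len = 5L, mutation_rate = 0.1,
                           seed = 42L) {
  spec <- structure(list(
    n_epitopes = as.integer(n_epitopes),
    tcrs_per_epitope = as.integer(tcrs_per_epitope),
    length_range = as.integer(length_range),
    prefix = prefix, suffix = suffix,
    motif_len = as.integer(motif_len),
    mutation_rate = mutation_rate,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  min_len <- nchar(spec$prefix) + spec$motif_len + nchar(spec$suffix)
  if (min_len > 24 || min_len > spec$length_range[2]) {
    abort(sprintf(
      "infeasible spec: prefix + motif + suffix needs %d residues but max length is %d",
      min_len, min(24L, spec$length_range[2])
    ))
  }
  if (spec$mutation_rate < 0 || spec$mutation_rate > 1) {
    abort("mutation_rate must be in [0, 1]")
  }
  if (spec$n_epitopes < 1 || spec$tcrs_per_epitope < 1) {
    abort("n_epitopes and tcrs_per_epitope must be positive")
  }
  invisible(spec)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d epitopes x %d TCRs, lengths %d-%d, %s...%s, motif %d, mutation %.2f, seed %d\n",
    x$n_epitopes, x$tcrs_per_epitope, x$length_range[1], x$length_range[2],
    x$prefix, x$suffix, x$motif_len, x$mutation_rate, x$seed
  ))
  invisible(x)
}

random_peptides <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste0(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
  }, character(1))
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Class identities (epitope 9-mers, core motifs, HLA loci) are a pure
# function of the spec, shared by generate_repertoire() and
# generate_healthy_pool(). Motifs are resampled until pairwise Hamming
# distance >= motif_len / 2, guaranteeing separable classes.
class_identities <- function(spec) {
  withr::with_seed(spec$seed, {
    epitopes <- random_peptides(spec$n_epitopes, 9L)
    motifs <- character(0)
    tries <- 0L
    while (length(motifs) < spec$n_epitopes) {
      tries <- tries + 1L
      if (tries > 1000L) abort("could not sample pairwise-distant class motifs")
      cand <- random_peptides(1L, spec$motif_len)
      if (all(vapply(motifs, hamming, numeric(1), b = cand) >= spec$motif_len / 2)) {
        motifs <- c(motifs, cand)
      }
    }
    hla <- sample(c("HLA-A", "HLA-B", "HLA-C"), spec$n_epitopes, replace = TRUE)
    list(epitopes = epitopes, motifs = motifs, hla = hla)
  })
}

synth_cdr3b <- function(spec, core) {
  min_len <- nchar(spec$prefix) + nchar(core) + nchar(spec$suffix)
  lo <- max(spec$length_range[1], min_len)
  target <- sample(seq(lo, spec$length_range[2]), 1L)
  filler_len <- target - min_len
  filler <- if (filler_len > 0) {
    paste0(sample(AA_STANDARD, filler_len, replace = TRUE), collapse = "")
  } else ""
  paste0(spec$prefix, core, filler, spec$suffix)
}

mutate_motif <- function(motif, rate) {
  res <- strsplit(motif, "")[[1]]
  hit <- stats::runif(length(res)) < rate
  if (any(hit)) {
    res[hit] <- vapply(res[hit], function(a) sample(setdiff(AA_STANDARD, a), 1L),
                       character(1))
  }
  paste0(res, collapse = "")
}

#' Generate a synthetic epitope-specific repertoire
#'
#' For each synthetic epitope, emits `tcrs_per_epitope` cognate CDR3beta
#' sequences built as `prefix + mutated class motif + random filler +
#' suffix`, with lengths drawn uniformly from the spec's range. All pairs
#' carry label 1 (binder) and the class HLA locus; nucleotide sequences are
#' back-translated with the shipped codon table.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `pairs` (tibble: `cdr3b`, `nt`, `epitope`, `hla`,
#'   `label`, `source`), `epitopes` (character) and `motifs` (character,
#'   named by epitope).
#' @export
generate_repertoire <- function(spec = synthetic_spec()) {
  validate_synthetic_spec(spec)
  ids <- class_identities(spec)
  tab <- codon_table()
  pairs <- withr::with_seed(spec$seed + 1L, {
    purrr::map_dfr(seq_len(spec$n_epitopes), function(k) {
      cdr3b <- vapply(seq_len(spec$tcrs_per_epitope), function(i) {
        synth_cdr3b(spec, mutate_motif(ids$motifs[k], spec$mutation_rate))
      }, character(1))
      tibble(
        cdr3b = cdr3b,
        epitope = ids$epitopes[k],
        hla = ids$hla[k],
        label = 1L,
        source = "synthetic"
      )
    })
  })
  pairs$nt <- back_translate(pairs$cdr3b, tab)
  list(
    pairs = pairs[, c("cdr3b", "nt", "epitope", "hla", "label", "source")],
    epitopes = ids$epitopes,
    motifs = stats::setNames(ids$motifs, ids$epitopes)
  )
}

#' Generate a synthetic healthy (non-binding) TCR pool
#'
#' Emits TCRs with the same conserved termini and length distribution as
#' the repertoire, but with core regions drawn independently of every
#' epitope class motif (cores equal to a class motif are rejected), so no
#' pool member carries a binding signal. No epitope or label is attached.
#'
#' @param n Pool size.
#' @param spec The same [synthetic_spec()] used for the repertoire, so the
#'   class motifs to avoid are reconstructed from the seed.
#' @return A tibble with columns `cdr3b`, `nt`, `hla`, `source`.
#' @export
generate_healthy_pool <- function(n, spec = synthetic_spec()) {
  stopifnot(n >= 0)
  validate_synthetic_spec(spec)
  if (n == 0) {
    return(tibble(cdr3b = character(0), nt = character(0),
                  hla = character(0), source = character(0)))
  }
  ids <- class_identities(spec)
  tab <- codon_table()
  withr::with_seed(spec$seed + 2L, {
    cdr3b <- vapply(seq_len(n), function(i) {
      repeat {
        core <- paste0(sample(AA_STANDARD, spec$motif_len, replace = TRUE), collapse = "")
        if (!core %in% ids$motifs) break
      }
      synth_cdr3b(spec, core)
    }, character(1))
    tibble(
      cdr3b = cdr3b,
      nt = back_translate(cdr3b, tab),
      hla = sample(c("HLA-A", "HLA-B", "HLA-C"), n, replace = TRUE),
      source = "synthetic_healthy"
    )
  })
}

#' Read a synthetic spec from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
read_synthetic_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(synthetic_spec, vals)
}
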