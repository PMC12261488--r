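#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

NUCLEOTIDES <- c("A", "T", "G", "C")
AA_STANDARD <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Codon table for back-translation
#'
#' Loads a one-codon-per-amino-acid lookup table. The shipped default maps
#' each of the 20 standard residues to the most frequently used human codon,
#' so back-translated CDR3beta sequences resemble natural human coding
#' sequence. Users may supply their own table (e.g. for a different organism)
#' as a two-column TSV.
#'
#' @param path Path to a TSV with columns `amino_acid` and `codon`. `NULL`
#'   (default) loads the table shipped with the package.
#' @return A named character vector: names are one-letter amino-acid codes,
#'   values are codons over A/T/G/C.
#' @export
#' @examples
#' codon_table()["M"] # "ATG"
codon_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "human_codons.tsv", package = "tcrdiff")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("amino_acid", "codon") %in% names(tab))) {
    abort("codon table must have columns 'amino_acid' and 'codon'")
  }
  codons <- stats::setNames(toupper(tab$codon), toupper(tab$amino_acid))
  missing <- setdiff(AA_STANDARD, names(codons))
  if (length(missing) > 0) {
    abort(paste0("codon table is missing amino acids: ", paste(missing, collapse = ", ")))
  }
  bad <- !grepl("^[ATGC]{3}$", codons)
  if (any(bad)) abort("codons must be 3-letter strings over A/T/G/C")
  # every codon must translate back to its amino acid; no stops
  code <- Biostrings::GENETIC_CODE
  back <- unname(code[codons[AA_STANDARD]])
  if (any(back == "*")) abort("stop codons are not allowed in a codon table")
  if (!identical(back, AA_STANDARD)) {
    abort("codon table is inconsistent with the standard genetic code")
  }
  codons[AA_STANDARD]
}

#' Back-translate peptides to nucleotide sequences
#'
#' Converts amino-acid sequences to nucleotide sequences using one codon per
#' residue. Translating the result under the standard genetic code recovers
#' the input exactly.
#'
#' @param peptide Character vector of uppercase amino-acid sequences
#'   (standard 20-letter alphabet).
#' @param table Codon lookup as returned by [codon_table()].
#' @return Character vector of nucleotide sequences, each 3x the peptide
#'   length.
#' @export
#' @examples
#' back_translate("CASSF")
back_translate <- function(peptide, table = codon_table()) {
  vapply(peptide, function(p) {
    if (is.na(p) || !nzchar(p)) abort("peptide must be non-empty")
    res <- strsplit(p, "")[[1]]
    bad <- which(!res %in% AA_STANDARD)
    if (length(bad) > 0) {
      abort(sprintf(
        "invalid residue '%s' at position %d in '%s'", res[bad[1]], bad[1], p
      ))
    }
    paste0(table[res], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate nucleotide sequences to peptides
#'
#' Standard genetic code, reading frame 1. If a stop codon occurs the
#' peptide is truncated before it and flagged; this is how decoded samples
#' from the generative model are screened for validity.
#'
#' @param nt Character vector of nucleotide sequences over A/T/G/C, lengths
#'   divisible by 3.
#' @return A tibble with columns `nt`, `peptide`, `ok` (`FALSE` when a stop
#'   codon truncated the translation).
#' @export
#' @examples
#' translate_nt("ATGTGG") # MW, ok
translate_nt <- function(nt) {
  code <- Biostrings::GENETIC_CODE
  out <- lapply(nt, function(s) {
    if (is.na(s) || !nzchar(s)) abort("nucleotide sequence must be non-empty")
    if (nchar(s) %% 3 != 0) {
      abort(sprintf("sequence length %d is not divisible by 3", nchar(s)))
    }
    if (grepl("[^ATGC]", s)) abort("sequence contains characters outside A/T/G/C")
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- unname(code[codons])
    stop_at <- which(aa == "*")
    if (length(stop_at) > 0) {
      list(peptide = paste0(aa[seq_len(stop_at[1] - 1)], collapse = ""), ok = FALSE)
    } else {
      list(peptide = paste0(aa, collapse = ""), ok = TRUE)
    }
  })
  tibble(
    nt = nt,
    peptide = vapply(out, `[[`, character(1), "peptide"),
    ok = vapply(out, `[[`, logical(1), "ok")
  )
}

#' One-hot encode a nucleotide sequence
#'
#' Encodes a sequence as an `l_max` x 4 matrix over channels (A, T, G, C):
#' A = (1,0,0,0), T = (0,1,0,0), G = (0,0,1,0), C = (0,0,0,1). Positions
#' beyond the sequence length are all-zero rows (padding).
#'
#' @param nt A single nucleotide sequence.
#' @param l_max Padded length in nucleotides (default 72 = 24 residues).
#' @return An object of class `nt_onehot`: list with `matrix` (`l_max` x 4)
#'   and `length` (number of real positions).
#' @export
one_hot_encode <- function(nt, l_max = 72L) {
  if (is.na(nt) || !nzchar(nt)) abort("sequence must be non-empty")
  if (grepl("[^ATGC]", nt)) abort("sequence contains characters outside A/T/G/C")
  n <- nchar(nt)
  if (n > l_max) {
    abort(sprintf("sequence length %d exceeds l_max = %d", n, l_max))
  }
  idx <- match(strsplit(nt, "")[[1]], NUCLEOTIDES)
  m <- matrix(0, nrow = l_max, ncol = 4, dimnames = list(NULL, NUCLEOTIDES))
  m[cbind(seq_len(n), idx)] <- 1
  structure(list(matrix = m, length = n), class = "nt_onehot")
}

#' Decode a (possibly noisy) one-hot matrix to a nucleotide sequence
#'
#' Scans positions left to right. A position whose maximum channel value
#' falls below `pad_threshold` terminates the sequence (it is read as
#' padding); otherwise the arg-max channel's nucleotide is emitted, ties
#' broken in fixed channel order A > T > G > C. The result is truncated down
#' to a multiple of 3 so it stays in frame.
#'
#' @param mat Numeric matrix with 4 columns (channels A, T, G, C), e.g. a
#'   denoised sample from [ancestral_sample()].
#' @param pad_threshold Value below which a position is read as padding
#'   (default 0.5).
#' @return A nucleotide string (possibly empty).
#' @export
one_hot_decode <- function(mat, pad_threshold = 0.5) {
  if (is.list(mat) && !is.null(mat$matrix)) mat <- mat$matrix
  stopifnot(is.matrix(mat), ncol(mat) == 4)
  if (any(!is.finite(mat))) abort("matrix must be finite")
  out <- character(0)
  for (i in seq_len(nrow(mat))) {
    row <- mat[i, ]
    m <- max(row)
    if (m < pad_threshold) break
    out <- c(out, NUCLEOTIDES[which.max(row)]) # which.max: first max wins ties
  }
  n <- length(out) - length(out) %% 3
  paste0(out[seq_len(n)], collapse = "")
}

#' Read or write plain sequence lists as FASTA
#'
#' Thin wrappers over Biostrings for nucleotide or amino-acid FASTA files.
#'
#' @param path File path.
#' @param alphabet `"nt"` or `"aa"`.
#' @return `read_fasta()` returns a tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  set <- if (alphabet == "nt") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  tibble(id = names(set), seq = unname(as.character(set)))
}

#' @param seqs Character vector of sequences.
#' @param ids Record names; defaults to `seq_1`, `seq_2`, ...
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, ids = NULL, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  ids <- ids %||% paste0("seq_", seq_along(seqs))
  set <- if (alphabet == "nt") {
    Biostrings::DNAStringSet(seqs)
  } else {
    Biostrings::AAStringSet(seqs)
  }
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
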