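#' @importFrom dplyr filter mutate select arrange bind_rows distinct anti_join
#'   group_by ungroup n row_number slice left_join
NULL

#' Filter CDR3beta records by amino-acid length
#'
#' Keeps records whose CDR3beta length lies in `[min_len, max_len]`
#' (defaults 7 and 24, the conventional CDR3beta length window). Order is
#' preserved; the number of removed records is reported.
#'
#' @param records A data frame with a `cdr3b` column of amino-acid strings.
#' @param min_len,max_len Inclusive length bounds in residues.
#' @param quiet Suppress the removal message.
#' @return The filtered records as a tibble.
#' @export
filter_by_length <- function(records, min_len = 7L, max_len = 24L, quiet = FALSE) {
  stopifnot(is.data.frame(records))
  if (!"cdr3b" %in% names(records)) abort("records must have a 'cdr3b' column")
  records <- as_tibble(records)
  len <- nchar(records$cdr3b)
  keep <- len >= min_len & len <= max_len
  if (!quiet && any(!keep)) {
    message(sprintf(
      "filter_by_length: removed %d of %d records outside [%d, %d]",
      sum(!keep), length(keep), min_len, max_len
    ))
  }
  records[keep, , drop = FALSE]
}

#' Construct negative (non-binder) TCR-epitope pairs
#'
#' Emulates decoy construction from an unselected ("healthy") repertoire:
#' each negative pair matches a uniformly sampled healthy TCR with a
#' uniformly sampled epitope. With `mode = "random"` the epitopes are those
#' of the positive set; with `mode = "iedb"` a caller-supplied list of
#' experimentally negative epitopes is used instead. Emitted pairs never
#' collide with a positive (cdr3b, epitope) pair and are de-duplicated.
#'
#' @param healthy_pool Data frame of non-binding TCRs with a `cdr3b` column.
#' @param epitopes Character vector of epitopes to pair against.
#' @param n Number of negative pairs to draw.
#' @param mode `"random"` (positive-set epitopes) or `"iedb"`
#'   (caller-supplied negative epitopes); recorded in `negative_mode`.
#' @param positives Data frame with `cdr3b` and `epitope` columns giving the
#'   known binder pairs to exclude.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param max_tries Resampling budget before declaring the pool exhausted.
#' @return A tibble of pairs with columns `cdr3b`, `epitope`, `hla`,
#'   `label` (all 0) and `negative_mode`.
#' @export
make_negatives <- function(healthy_pool, epitopes, n,
                           mode = c("random", "iedb"),
                           positives = NULL, seed = 1L,
                           max_tries = 50L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(healthy_pool), n >= 0)
  if (nrow(healthy_pool) == 0 || length(epitopes) == 0) {
    abort("healthy_pool and epitopes must be non-empty")
  }
  if (n == 0) {
    return(tibble(
      cdr3b = character(0), epitope = character(0), hla = character(0),
      label = integer(0), negative_mode = character(0)
    ))
  }
  pos_key <- if (is.null(positives)) character(0) else {
    paste(positives$cdr3b, positives$epitope, sep = "\r")
  }
  withr::with_seed(seed, {
    out <- tibble(cdr3b = character(0), epitope = character(0), hla = character(0))
    tries <- 0L
    while (nrow(out) < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort(sprintf(
          "sampling exhausted: found only %d of %d distinct negative pairs",
          nrow(out), n
        ))
      }
      need <- n - nrow(out)
      i <- sample.int(nrow(healthy_pool), need, replace = TRUE)
      cand <- tibble(
        cdr3b = healthy_pool$cdr3b[i],
        epitope = sample(epitopes, need, replace = TRUE),
        hla = if ("hla" %in% names(healthy_pool)) healthy_pool$hla[i] else NA_character_
      )
      cand <- cand[!paste(cand$cdr3b, cand$epitope, sep = "\r") %in% pos_key, , drop = FALSE]
      out <- distinct(bind_rows(out, cand), .data$cdr3b, .data$epitope, .keep_all = TRUE)
    }
    mutate(out[seq_len(n), ], label = 0L, negative_mode = mode)
  })
}

#' Split binding pairs into generation and prediction halves
#'
#' Uniformly random disjoint partition of the rows into two halves whose
#' sizes differ by at most one: one half trains the generative model, the
#' other trains the binding predictor, so neither model sees the other's
#' data. Duplicate (cdr3b, epitope) rows are removed first to prevent
#' leakage across the halves.
#'
#' @param pairs Data frame of pairs with `cdr3b` and `epitope` columns.
#' @param seed Integer seed.
#' @param dedup Drop duplicate (cdr3b, epitope) rows before splitting.
#' @param quiet Suppress the de-duplication message.
#' @return A list with tibbles `generation` and `prediction`.
#' @export
split_halves <- function(pairs, seed = 1L, dedup = TRUE, quiet = FALSE) {
  stopifnot(is.data.frame(pairs))
  pairs <- as_tibble(pairs)
  if (dedup && all(c("cdr3b", "epitope") %in% names(pairs))) {
    n0 <- nrow(pairs)
    pairs <- distinct(pairs, .data$cdr3b, .data$epitope, .keep_all = TRUE)
    if (!quiet && nrow(pairs) < n0) {
      message(sprintf("split_halves: removed %d duplicate pairs", n0 - nrow(pairs)))
    }
  }
  if (nrow(pairs) < 2) abort("need at least 2 pairs to split")
  withr::with_seed(seed, {
    idx <- sample.int(nrow(pairs))
    half <- floor(nrow(pairs) / 2)
    list(
      generation = pairs[sort(idx[seq_len(half)]), , drop = FALSE],
      prediction = pairs[sort(idx[-seq_len(half)]), , drop = FALSE]
    )
  })
}

pair_required_cols <- c("cdr3b", "epitope")

#' Read and write TCR-epitope pair tables
#'
#' TSV/CSV with a mandatory header. Columns `cdr3b` and `epitope` are
#' required; `hla` and `label` are filled with `NA` when absent. Unknown
#' columns are preserved on a round trip.
#'
#' @param path File path.
#' @param delim Field delimiter; `"\t"` (default) or `","`.
#' @return A tibble of pairs.
#' @export
read_pairs <- function(path, delim = "\t") {
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(pair_required_cols, names(tab))
  if (length(missing) > 0) {
    abort(paste0("pair table is missing mandatory column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"hla" %in% names(tab)) tab$hla <- NA_character_
  if (!"label" %in% names(tab)) tab$label <- NA_integer_
  tab$label <- as.integer(tab$label)
  as_tibble(tab)
}

#' @param pairs Data frame of pairs.
#' @rdname read_pairs
#' @export
write_pairs <- function(pairs, path, delim = "\t") {
  missing <- setdiff(pair_required_cols, names(pairs))
  if (length(missing) > 0) {
    abort(paste0("pair table is missing mandatory column(s): ", paste(missing, collapse = ", ")))
  }
  readr::write_delim(pairs, path, delim = delim, progress = FALSE)
  invisible(path)
}
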