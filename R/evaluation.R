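# Quantitative evaluation of generated repertoires and latent spaces.

encode_set <- function(seqs, l_max) {
  if (length(seqs) == 0) abort("sequence set must be non-empty")
  X <- array(0, c(l_max, 4L, length(seqs)))
  for (i in seq_along(seqs)) X[, , i] <- one_hot_encode(seqs[i], l_max)$matrix
  X
}

#' Position-wise Pearson correlation between two sequence sets
#'
#' Both sets are one-hot encoded to a common padded length and reduced to
#' position frequency matrices; at each position the Pearson correlation
#' between the two sets' 4-entry nucleotide-frequency columns is computed.
#' Positions where either column has zero variance (e.g. a column that is
#' all one nucleotide, or all padding) are flagged undefined rather than
#' given a number. High terminal correlation with lower mid-region
#' correlation is the signature of conserved CDR3beta termini around a
#' variable loop.
#'
#' @param set_a,set_b Character vectors of nucleotide sequences.
#' @param l_max Common padded length.
#' @return A tibble with columns `position`, `r`, `defined`.
#' @export
positionwise_pearson <- function(set_a, set_b, l_max = 72L) {
  Xa <- encode_set(set_a, l_max)
  Xb <- encode_set(set_b, l_max)
  fa <- apply(Xa, c(1, 2), mean)
  fb <- apply(Xb, c(1, 2), mean)
  r <- vapply(seq_len(l_max), function(p) {
    a <- fa[p, ]
    b <- fb[p, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  }, numeric(1))
  tibble(position = seq_len(l_max), r = r, defined = !is.na(r))
}

#' Mean pairwise cosine similarity between two sequence sets
#'
#' Sequences are one-hot encoded, zero-padded to a common length, and
#' flattened; the cosine similarity of every cross pair is computed. For
#' one-hot inputs the value lies in `[0, 1]` and equals the fraction of
#' aligned matching positions normalized by the geometric mean length.
#'
#' @param set_a,set_b Character vectors of nucleotide sequences, or numeric
#'   `L x 4 x n` arrays of (possibly denoised) one-hot matrices.
#' @param l_max Common padded length (ignored for array input).
#' @return A list with `mean` (scalar) and `matrix`
#'   (`length(set_a)` x `length(set_b)` pairwise similarities).
#' @export
mean_cosine <- function(set_a, set_b, l_max = 72L) {
  Va <- cosine_flat(set_a, l_max)
  Vb <- cosine_flat(set_b, l_max)
  na <- sqrt(rowSums(Va^2))
  nb <- sqrt(rowSums(Vb^2))
  if (any(na == 0) || any(nb == 0)) abort("zero vectors have no cosine similarity")
  M <- (Va %*% t(Vb)) / outer(na, nb)
  list(mean = mean(M), matrix = M)
}

cosine_flat <- function(x, l_max) {
  if (is.character(x)) {
    X <- encode_set(x, l_max)
  } else if (length(dim(x)) == 3) {
    X <- x
  } else {
    abort("expected sequences or an L x 4 x n array")
  }
  t(apply(X, 3, as.numeric))
}

#' Extract latent TCR embeddings from the denoiser encoder
#'
#' Runs each (clean, uncorrupted) one-hot sequence through the model's
#' down-sampling stage at timestep 0 with a zero epitope embedding, so the
#' representation reflects the TCR alone, and average-pools the bottleneck
#' feature map over positions. One vector per TCR, of the bottleneck width.
#'
#' @param model A trained `tcr_diffusion` model.
#' @param tcrs Data frame with an `nt` or `cdr3b` column, and optionally an
#'   `epitope` label column carried through to the output.
#' @return A tibble with `tcr_id`, `epitope` and a `latent` matrix-column.
#' @export
extract_latents <- function(model, tcrs) {
  stopifnot(inherits(model, "tcr_diffusion"), is.data.frame(tcrs))
  if (!"nt" %in% names(tcrs)) tcrs$nt <- back_translate(tcrs$cdr3b)
  l_max <- model$net$config$l_max
  X <- encode_set(tcrs$nt, l_max)
  if (isTRUE(model$config$rescale)) X <- 2 * X - 1
  B <- dim(X)[3]
  zero_e <- matrix(0, B, EMBED_DIM)
  feat <- encode_fwd(model$net, X, rep(0L, B), zero_e)$feat
  tibble(
    tcr_id = seq_len(B),
    epitope = if ("epitope" %in% names(tcrs)) tcrs$epitope else NA_character_,
    latent = feat
  )
}

latent_matrix <- function(latents) {
  if (is.data.frame(latents) && "latent" %in% names(latents)) {
    as.matrix(latents$latent)
  } else {
    as.matrix(latents)
  }
}

#' Reduce latent embeddings to PCA scores
#'
#' @param latents Output of [extract_latents()] or a numeric matrix.
#' @param n_components Number of principal components (default 10).
#' @return An `n x n_components` score matrix.
#' @export
latent_pca <- function(latents, n_components = 10L) {
  m <- latent_matrix(latents)
  n_components <- min(n_components, ncol(m), nrow(m) - 1L)
  stats::prcomp(m, center = TRUE, scale. = FALSE)$x[, seq_len(n_components), drop = FALSE]
}

#' Two-dimensional latent map (PCA then UMAP)
#'
#' Latent vectors are reduced to 10 principal components and then embedded
#' in 2-D with UMAP (n_neighbors = 15, min_dist = 0.3, spread = 0.5,
#' metric = "hamming"), the layout used throughout for repertoire
#' visualization. The UMAP stage runs through the Python `umap-learn`
#' package (invoked as a subprocess); PCA and every downstream statistic
#' are computed in R.
#'
#' @param latents Output of [extract_latents()] or a numeric matrix.
#' @param seed Integer seed passed to UMAP's `random_state`.
#' @param n_neighbors,min_dist,spread,metric UMAP hyperparameters.
#' @param n_components PCA components preceding UMAP (default 10).
#' @return A tibble with `tcr_id`, `x`, `y` and `epitope` (when available).
#' @export
latent_map <- function(latents, seed = 1L, n_neighbors = 15L, min_dist = 0.3,
                       spread = 0.5, metric = "hamming", n_components = 10L) {
  m <- latent_matrix(latents)
  if (nrow(m) < 16) abort("need at least 16 points for a UMAP neighbourhood")
  scores <- latent_pca(m, n_components)
  py <- Sys.which("python")
  if (py == "") abort("latent_map requires a 'python' executable with umap-learn")
  tmp_in <- tempfile(fileext = ".csv")
  tmp_out <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  utils::write.table(scores, tmp_in, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- system.file("python", "umap_embed.py", package = "tcrdiff")
  status <- system2(py, c(script, tmp_in, tmp_out, seed, n_neighbors, min_dist,
                          spread, metric),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(tmp_out)) abort("UMAP subprocess failed")
  xy <- utils::read.csv(tmp_out, header = FALSE)
  out <- tibble(tcr_id = seq_len(nrow(m)), x = xy[[1]], y = xy[[2]])
  if (is.data.frame(latents) && "epitope" %in% names(latents)) {
    out$epitope <- latents$epitope
  }
  class(out) <- c("tcr_latent_map", class(out))
  out
}

#' k-nearest-neighbour label purity
#'
#' For each point, the fraction of its k nearest neighbours (Euclidean,
#' self excluded) sharing its label; the mean over points is returned.
#' Computed in the PCA-reduced latent space (10 components by default),
#' where a high value means TCRs binding the same epitope cluster together.
#'
#' @param latents Output of [extract_latents()] or a numeric matrix.
#' @param labels Class labels, one per point; defaults to the `epitope`
#'   column when `latents` carries one.
#' @param k Neighbourhood size (default 5).
#' @param pca Reduce to 10 principal components first (default `TRUE`).
#' @return Scalar purity in `[0, 1]`.
#' @export
knn_purity <- function(latents, labels = NULL, k = 5L, pca = TRUE) {
  m <- latent_matrix(latents)
  if (is.null(labels)) {
    if (is.data.frame(latents) && "epitope" %in% names(latents)) {
      labels <- latents$epitope
    } else {
      abort("labels are required")
    }
  }
  n <- nrow(m)
  if (k >= n) abort("k must be smaller than the number of points")
  if (length(labels) != n) abort("one label per point is required")
  if (pca) m <- latent_pca(m, 10L)
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  mean(vapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    mean(labels[nb] == labels[i])
  }, numeric(1)))
}

#' Binary classification metrics
#'
#' Accuracy, F1 and the confusion counts at a probability threshold.
#'
#' @param labels Binary ground truth (0/1).
#' @param predictions Predicted probabilities or scores.
#' @param threshold Decision threshold (default 0.5).
#' @return A list with `accuracy`, `f1`, `tp`, `fp`, `tn`, `fn`.
#' @export
classification_metrics <- function(labels, predictions, threshold = 0.5) {
  if (length(labels) != length(predictions)) abort("length mismatch")
  if (length(labels) == 0) abort("empty input")
  yhat <- as.integer(predictions >= threshold)
  y <- as.integer(labels)
  tp <- sum(y == 1 & yhat == 1)
  fp <- sum(y == 0 & yhat == 1)
  tn <- sum(y == 0 & yhat == 0)
  fn <- sum(y == 1 & yhat == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(accuracy = (tp + tn) / length(y), f1 = f1, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Position frequency matrix of a sequence set
#'
#' Per-position symbol frequencies over the nucleotide or amino-acid
#' alphabet — the numeric form of a sequence logo, writable as TSV for any
#' logo-rendering tool. Only positions covered by at least one sequence are
#' emitted; each emitted row sums to 1.
#'
#' @param sequences Character vector over a single alphabet.
#' @param alphabet `"nt"` (A/T/G/C) or `"aa"` (20 standard residues).
#' @return A `tcr_pfm`: tibble with `position`, `n` (coverage) and one
#'   frequency column per symbol.
#' @export
pfm_export <- function(sequences, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (length(sequences) == 0) abort("sequence set must be non-empty")
  symbols <- if (alphabet == "nt") NUCLEOTIDES else AA_STANDARD
  chars <- strsplit(sequences, "")
  bad <- setdiff(unique(unlist(chars)), symbols)
  if (length(bad) > 0) {
    abort(sprintf("symbols outside the %s alphabet: %s", alphabet,
                  paste(bad, collapse = ", ")))
  }
  l <- max(lengths(chars))
  rows <- lapply(seq_len(l), function(p) {
    at <- unlist(lapply(chars, function(x) if (length(x) >= p) x[p] else NULL))
    counts <- table(factor(at, levels = symbols))
    c(position = p, n = length(at), as.numeric(counts) / length(at))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("position", "n", symbols)
  out <- as_tibble(m)
  class(out) <- c("tcr_pfm", class(out))
  attr(out, "alphabet") <- alphabet
  out
}

#' Write a position frequency matrix as TSV
#' @param pfm A [pfm_export()] result.
#' @param path Output path.
#' @export
write_pfm <- function(pfm, path) {
  readr::write_tsv(pfm, path, progress = FALSE)
  invisible(path)
}
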