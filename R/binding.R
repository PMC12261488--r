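#' One-hot encode an HLA allele at locus resolution
#'
#' Class-I loci are encoded as HLA-A = (1,0,0), HLA-B = (0,1,0),
#' HLA-C = (0,0,1); any allele-resolution suffix is accepted and ignored.
#'
#' @param allele Character vector of allele strings, e.g. `"HLA-A*02:01"`.
#' @return A `length(allele)` x 3 binary matrix with columns A, B, C.
#' @export
encode_hla <- function(allele) {
  m <- matrix(0L, nrow = length(allele), ncol = 3,
              dimnames = list(NULL, c("A", "B", "C")))
  for (i in seq_along(allele)) {
    a <- allele[i]
    locus <- if (grepl("^HLA-A", a)) 1L else if (grepl("^HLA-B", a)) 2L
             else if (grepl("^HLA-C", a)) 3L else {
      abort(sprintf("unsupported locus in '%s': only HLA-A/B/C are encoded", a))
    }
    m[i, locus] <- 1L
  }
  m
}

#' Binding-predictor configuration
#'
#' Two variants are supported. `"bp"` ignores HLA and stacks 7 linear
#' layers after the encoder; `"bp_hla"` incorporates the HLA locus one-hot,
#' concatenated to the input of every head layer, and stacks 5 linear
#' layers. Dropout (default 0.6) is applied after every head layer except
#' the final one. Hidden widths taper geometrically from the concatenated
#' input width down to 1.
#'
#' @param variant `"bp"` (no HLA, 7 layers) or `"bp_hla"` (HLA-aware,
#'   5 layers).
#' @param dropout Dropout rate on all head layers except the last.
#' @param freeze_encoder If `TRUE` the denoiser encoder is not fine-tuned.
#' @export
predictor_config <- function(variant = c("bp", "bp_hla"), dropout = 0.6,
                             freeze_encoder = FALSE) {
  variant <- match.arg(variant)
  structure(list(
    variant = variant,
    head_depth = if (variant == "bp") 7L else 5L,
    use_hla = variant == "bp_hla",
    dropout = dropout,
    freeze_encoder = freeze_encoder
  ), class = "predictor_config")
}

#' Build a TCR-epitope binding predictor on the denoiser encoder
#'
#' The predictor reuses the diffusion model's down-sampling stage: the TCR
#' one-hot is encoded (at timestep 0, conditioned on the epitope embedding),
#' the bottleneck feature map is average-pooled over positions, the pooled
#' vector is concatenated with the 1024-dim epitope embedding, and the
#' result is passed through the variant's linear stack to a single sigmoid
#' binding probability.
#'
#' @param denoiser A trained [train_generator()] model (or a fresh one).
#' @param config A [predictor_config()].
#' @param seed Seed for head-weight initialization.
#' @return An object of class `tcr_predictor`.
#' @export
build_predictor <- function(denoiser, config = predictor_config(), seed = 1L) {
  stopifnot(inherits(denoiser, "tcr_diffusion"))
  feat_dim <- denoiser$net$config$bottleneck
  in_dim <- feat_dim + EMBED_DIM
  D <- config$head_depth
  # geometric taper with a floor: very narrow late layers starve the signal
  # under heavy dropout, so hidden widths never drop below 64
  widths <- as.integer(pmax(1, round(exp(seq(log(in_dim), log(1), length.out = D + 1)))))[-1]
  widths[-D] <- pmax(widths[-D], 64L)
  widths[D] <- 1L
  hla_extra <- if (config$use_hla) 3L else 0L
  pred <- new.env(parent = emptyenv())
  pred$params <- list()
  pred$grads <- list()
  withr::with_seed(seed, {
    prev <- in_dim
    for (i in seq_len(D)) {
      param_add(pred, sprintf("head.l%d.W", i), he_init(widths[i], prev + hla_extra))
      param_add(pred, sprintf("head.l%d.b", i), numeric(widths[i]))
      prev <- widths[i]
    }
  })
  adam_init(pred)
  structure(list(
    store = pred, denoiser = denoiser, config = config,
    head_widths = widths, feat_dim = feat_dim,
    metrics = tibble(epoch = integer(0), accuracy = numeric(0), f1 = numeric(0)),
    trained = FALSE
  ), class = "tcr_predictor")
}

#' Number of linear layers in a predictor head
#' @param predictor A `tcr_predictor`.
#' @export
head_depth <- function(predictor) {
  sum(grepl("^head\\.l\\d+\\.W$", names(predictor$store$params)))
}

head_fwd <- function(predictor, feat, eemb, hla, train) {
  cfg <- predictor$config
  st <- predictor$store
  D <- cfg$head_depth
  x <- cbind(feat, eemb)
  tape <- vector("list", D)
  for (i in seq_len(D)) {
    if (cfg$use_hla) x <- cbind(x, hla)
    lf <- lin_fwd(x, st$params[[sprintf("head.l%d.W", i)]],
                  st$params[[sprintf("head.l%d.b", i)]])
    if (i < D) {
      sf <- silu_fwd(lf$Y)
      df <- dropout_fwd(sf$Y, cfg$dropout, train)
      x <- df$Y
      tape[[i]] <- list(lin = lf$cache, silu = sf$cache, drop = df$cache)
    } else {
      tape[[i]] <- list(lin = lf$cache)
      x <- lf$Y
    }
  }
  p <- 1 / (1 + exp(-drop(x)))
  list(p = p, z = drop(x), tape = tape)
}

# Backward through the head given dL/dz of the final pre-sigmoid unit.
head_bwd <- function(predictor, dz, tape) {
  cfg <- predictor$config
  st <- predictor$store
  D <- cfg$head_depth
  dx <- matrix(dz, ncol = 1)
  for (i in rev(seq_len(D))) {
    if (i < D) {
      dx <- dropout_bwd(dx, tape[[i]]$drop)
      dx <- silu_bwd(dx, tape[[i]]$silu)
    }
    lb <- lin_bwd(dx, tape[[i]]$lin, st$params[[sprintf("head.l%d.W", i)]])
    grad_acc(st, sprintf("head.l%d.W", i), lb$dW)
    grad_acc(st, sprintf("head.l%d.b", i), lb$db)
    dx <- lb$dX
    if (cfg$use_hla) dx <- dx[, seq_len(ncol(dx) - 3L), drop = FALSE]
  }
  # dx now spans cbind(feat, eemb); return the feature part for fine-tuning
  dx[, seq_len(predictor$feat_dim), drop = FALSE]
}

predictor_fwd <- function(predictor, X, eemb, hla, train) {
  net <- predictor$denoiser$net
  B <- dim(X)[3]
  enc <- encode_fwd(net, X, rep(0L, B), eemb)
  hf <- head_fwd(predictor, enc$feat, eemb, hla, train)
  list(p = hf$p, z = hf$z, head_tape = hf$tape, enc_tape = enc$tape)
}

#' Train a binding predictor
#'
#' Binary cross-entropy objective with Adam; a held-out fifth of the pairs
#' (disjoint by (cdr3b, epitope) key) is scored for accuracy and F1 after
#' every epoch. The encoder is fine-tuned jointly with the head unless the
#' config froze it.
#'
#' @param predictor A [build_predictor()] object.
#' @param pairs Data frame with `cdr3b` (or `nt`), `epitope`, `label`
#'   (both classes required) and, for the HLA-aware variant, `hla`.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param holdout_frac Held-out fraction for the metric trace (default 1/5).
#' @param batch_size Minibatch size; `Inf` trains full-batch.
#' @param seed Integer seed; the run is deterministic given the seed.
#' @param quiet Suppress progress messages.
#' @return The trained `tcr_predictor` with a per-epoch metric trace.
#' @export
train_predictor <- function(predictor, pairs, epochs = 30L, lr = 1e-3,
                            holdout_frac = 0.2, batch_size = Inf,
                            seed = 1L, quiet = TRUE) {
  stopifnot(inherits(predictor, "tcr_predictor"), is.data.frame(pairs))
  if (length(unique(pairs$label)) < 2) {
    abort("training pairs must contain both labels")
  }
  cfg <- predictor$config
  net <- predictor$denoiser$net
  encoder <- predictor$denoiser$encoder
  l_max <- net$config$l_max
  dat <- pairs_to_batch(pairs, l_max, encoder)
  if (isTRUE(predictor$denoiser$config$rescale)) dat$X <- 2 * dat$X - 1
  y <- as.numeric(pairs$label)
  hla <- if (cfg$use_hla) encode_hla(pairs$hla) else NULL
  sub_rows <- function(m, idx) if (is.null(m)) NULL else m[idx, , drop = FALSE]
  n <- nrow(pairs)
  withr::with_seed(seed, {
    hold <- sample.int(n, max(1L, round(holdout_frac * n)))
    train_idx <- setdiff(seq_len(n), hold)
    # leakage guard: no shared (cdr3b, epitope) key across the split
    key <- paste(pairs$cdr3b, pairs$epitope)
    hold <- hold[!key[hold] %in% key[train_idx]]
    metrics <- predictor$metrics
    bs <- min(batch_size, length(train_idx))
    for (epoch in seq_len(epochs)) {
      ord <- sample(train_idx)
      for (start in seq(1, length(ord), by = bs)) {
        idx <- ord[start:min(start + bs - 1, length(ord))]
        fw <- predictor_fwd(predictor,
                            dat$X[, , idx, drop = FALSE],
                            dat$E[idx, , drop = FALSE],
                            sub_rows(hla, idx), train = TRUE)
        dz <- (fw$p - y[idx]) / length(idx)    # BCE + sigmoid gradient
        dfeat <- head_bwd(predictor, dz, fw$head_tape)
        adam_step(predictor$store, lr)
        if (!cfg$freeze_encoder) {
          encode_bwd(net, dfeat, fw$enc_tape)
          adam_step(net, lr)
        }
      }
      if (length(hold) > 0) {
        ph <- predictor_fwd(predictor,
                            dat$X[, , hold, drop = FALSE],
                            dat$E[hold, , drop = FALSE],
                            sub_rows(hla, hold), train = FALSE)
        cm <- classification_metrics(y[hold], ph$p)
      } else {
        cm <- list(accuracy = NA_real_, f1 = NA_real_)
      }
      metrics <- dplyr::bind_rows(metrics, tibble(
        epoch = epoch, accuracy = cm$accuracy, f1 = cm$f1
      ))
      if (!quiet) {
        message(sprintf("epoch %d: held-out acc %.3f, F1 %.3f",
                        epoch, cm$accuracy, cm$f1))
      }
    }
    predictor$metrics <- metrics
    predictor$holdout <- hold
    predictor$trained <- TRUE
  })
  predictor
}

#' Predict binding probabilities
#'
#' Evaluation mode (dropout off); deterministic for fixed weights.
#'
#' @param predictor A trained `tcr_predictor`.
#' @param cdr3b Character vector of CDR3beta amino-acid sequences.
#' @param epitope Epitope peptide(s), length 1 or `length(cdr3b)`.
#' @param hla HLA allele strings; required for the HLA-aware variant.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_binding <- function(predictor, cdr3b, epitope, hla = NULL) {
  stopifnot(inherits(predictor, "tcr_predictor"))
  cfg <- predictor$config
  if (cfg$use_hla && is.null(hla)) {
    abort("the HLA-aware variant requires HLA alleles")
  }
  epitope <- rep_len(epitope, length(cdr3b))
  pairs <- tibble(cdr3b = cdr3b, epitope = epitope)
  dat <- pairs_to_batch(pairs, predictor$denoiser$net$config$l_max,
                        predictor$denoiser$encoder)
  if (isTRUE(predictor$denoiser$config$rescale)) dat$X <- 2 * dat$X - 1
  hm <- if (cfg$use_hla) encode_hla(rep_len(hla, length(cdr3b))) else NULL
  fw <- predictor_fwd(predictor, dat$X, dat$E, hm, train = FALSE)
  unname(fw$p)
}

#' @export
print.tcr_predictor <- function(x, ...) {
  cat(sprintf(
    "<tcr_predictor> variant %s, %d head layers (widths %s), dropout %.1f%s\n",
    x$config$variant, x$config$head_depth,
    paste(x$head_widths, collapse = "-"), x$config$dropout,
    if (x$trained) sprintf(", held-out acc %.3f", utils::tail(x$metrics$accuracy, 1)) else ""
  ))
  invisible(x)
}
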