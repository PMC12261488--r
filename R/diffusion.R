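#' Linear noise schedule
#'
#' Builds the variance schedule of the forward diffusion process: `beta` is
#' linearly spaced from `beta_start` to `beta_end` over `timesteps` steps
#' (defaults 1e-4 to 0.1 over 10 steps), `alpha_t = 1 - beta_t`, and
#' `alpha_bar_t` is the cumulative product of the alphas, which governs the
#' closed-form corruption of the clean data.
#'
#' @param timesteps Number of diffusion steps T.
#' @param beta_start,beta_end First and last noise variances, in (0, 1).
#' @return An object of class `noise_schedule` with fields `timesteps`,
#'   `beta`, `alpha`, `alpha_bar`.
#' @export
#' @examples
#' sch <- linear_schedule(10)
#' sch$alpha_bar[10]
linear_schedule <- function(timesteps = 10L, beta_start = 1e-4, beta_end = 0.1) {
  if (timesteps < 1) abort("timesteps must be >= 1")
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1)) {
    abort("need 0 < beta_start <= beta_end < 1")
  }
  beta <- if (timesteps == 1) beta_start else seq(beta_start, beta_end, length.out = timesteps)
  alpha <- 1 - beta
  structure(list(
    timesteps = as.integer(timesteps), beta = beta, alpha = alpha,
    alpha_bar = cumprod(alpha)
  ), class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule> T = %d, beta %.2g..%.2g, alpha_bar_T = %.4f\n",
              x$timesteps, x$beta[1], x$beta[x$timesteps], x$alpha_bar[x$timesteps]))
  invisible(x)
}

check_shapes <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
    abort("shape mismatch between data and noise")
  }
}

#' Forward diffusion in closed form
#'
#' Jumps directly from the clean data to timestep `t`:
#' `x_t = sqrt(alpha_bar_t) * x0 + sqrt(1 - alpha_bar_t) * eps`.
#'
#' @param x0 Clean data (any numeric array, e.g. an L x 4 one-hot matrix).
#' @param t Timestep in `1..T`.
#' @param schedule A [linear_schedule()].
#' @param eps Gaussian noise with the same shape as `x0`.
#' @return The corrupted state `x_t`, same shape as `x0`.
#' @export
forward_sample <- function(x0, t, schedule, eps) {
  stopifnot(t >= 1, t <= schedule$timesteps)
  check_shapes(x0, eps)
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Single-step forward transition
#'
#' One step of the forward Markov chain:
#' `x_t = sqrt(1 - beta_t) * x_prev + sqrt(beta_t) * eps`.
#'
#' @param x_prev State at timestep `t - 1`.
#' @inheritParams forward_sample
#' @export
step_kernel_sample <- function(x_prev, t, schedule, eps) {
  stopifnot(t >= 1, t <= schedule$timesteps)
  check_shapes(x_prev, eps)
  b <- schedule$beta[t]
  sqrt(1 - b) * x_prev + sqrt(b) * eps
}

#' Noise-prediction (MSE) training loss
#'
#' Corrupts `x0` to `x_t` with the given noise, asks the network for its
#' noise estimate, and returns the mean squared error between true and
#' predicted noise — the standard DDPM objective.
#'
#' @param network Either a trained denoiser (a `tcr_diffusion` model or its
#'   internal network) or a plain function `(xt, t, eemb) -> eps_hat` taking
#'   an `L x 4 x B` array; useful for oracle checks.
#' @param x0 Clean one-hot matrix (L x 4) or `L x 4 x B` array.
#' @param cond Epitope embedding (numeric 1024-vector, or B x 1024 matrix).
#' @param t Timestep(s) in `1..T` (length 1 or B).
#' @param schedule A [linear_schedule()].
#' @param eps Noise with the shape of `x0`.
#' @return Non-negative scalar loss.
#' @export
diffusion_loss <- function(network, x0, cond, t, schedule, eps) {
  xb <- as_batch(x0)
  eb <- as_batch(eps)
  B <- dim(xb)[3]
  tvec <- rep_len(t, B)
  ab <- schedule$alpha_bar[tvec]
  xt <- sweep(xb, 3, sqrt(ab), `*`) + sweep(eb, 3, sqrt(1 - ab), `*`)
  eemb <- if (is.matrix(cond)) cond else matrix(cond, nrow = B, ncol = length(cond), byrow = TRUE)
  eps_hat <- apply_denoiser(network, xt, tvec, eemb)
  if (any(!is.finite(eps_hat))) abort("denoiser produced non-finite output")
  mean((eb - eps_hat)^2)
}

as_batch <- function(x) {
  if (length(dim(x)) == 3) x else array(x, c(dim(x), 1L))
}

apply_denoiser <- function(network, xt, t, eemb) {
  if (inherits(network, "tcr_diffusion")) network <- network$net
  if (is.function(network)) {
    network(xt, t, eemb)
  } else {
    unet_fwd(network, xt, t, eemb)$eps
  }
}

#' Sinusoidal timestep embedding
#'
#' Standard sin/cos positional encoding of the diffusion timestep over
#' `dim / 2` geometrically spaced frequencies; all values lie in `[-1, 1]`.
#'
#' @param t Non-negative integer timestep(s).
#' @param dim Even embedding width.
#' @return A numeric vector (scalar `t`) or `length(t) x dim` matrix.
#' @export
sinusoidal_embed <- function(t, dim) {
  if (dim %% 2 != 0) abort("embedding dim must be even")
  if (any(t < 0)) abort("t must be >= 0")
  half <- dim / 2
  freqs <- 10000^(-(seq_len(half) - 1) / half)
  m <- cbind(sin(outer(t, freqs)), cos(outer(t, freqs)))
  if (length(t) == 1) drop(m) else m
}

#' One reverse (denoising) step
#'
#' The ancestral-sampling recursion
#' `x_{t-1} = (x_t - beta_t / sqrt(1 - alpha_bar_t) * eps_hat) / sqrt(alpha_t)
#'  + sigma_t * z`, with `sigma_t = sqrt(beta_t)` and `z = 0` at `t = 1`.
#'
#' @param xt State at timestep `t`.
#' @param t Timestep.
#' @param schedule A [linear_schedule()].
#' @param eps_hat The network's noise prediction at `(xt, t)`.
#' @param z Gaussian innovation; pass 0 to make the step deterministic.
#' @export
reverse_step <- function(xt, t, schedule, eps_hat, z = 0) {
  b <- schedule$beta[t]
  a <- schedule$alpha[t]
  ab <- schedule$alpha_bar[t]
  (xt - (b / sqrt(1 - ab)) * eps_hat) / sqrt(a) + sqrt(b) * z
}

#' Draw sequences from the reverse diffusion process
#'
#' Starts from pure Gaussian noise and applies [reverse_step()] for
#' `t = T..1`, conditioning every denoiser call on the epitope embedding.
#' Deterministic given `seed`.
#'
#' @param network A trained `tcr_diffusion` model, its network, or a
#'   function `(xt, t, eemb) -> eps_hat`.
#' @param cond Epitope embedding vector (length 1024) shared by all samples.
#' @param n Number of samples.
#' @param schedule A [linear_schedule()].
#' @param seed Integer seed.
#' @param l_max Sequence axis length of the samples.
#' @return An `l_max x 4 x n` array of denoised matrices.
#' @export
ancestral_sample <- function(network, cond, n, schedule, seed = 1L, l_max = 72L) {
  if (inherits(network, "tcr_diffusion")) {
    l_max <- network$net$config$l_max
  }
  eemb <- matrix(cond, nrow = n, ncol = length(cond), byrow = TRUE)
  withr::with_seed(seed, {
    x <- array(stats::rnorm(l_max * 4 * n), c(l_max, 4L, n))
    for (t in schedule$timesteps:1) {
      eps_hat <- apply_denoiser(network, x, rep(t, n), eemb)
      if (any(!is.finite(eps_hat))) {
        abort(sprintf("reverse process diverged at t = %d", t))
      }
      z <- if (t > 1) array(stats::rnorm(length(x)), dim(x)) else 0
      x <- reverse_step(x, t, schedule, eps_hat, z)
    }
    x
  })
}

#' Epoch at which early stopping halts training
#'
#' Training halts when the per-epoch loss has failed to improve by at least
#' `delta` for `patience` consecutive epochs. Given a loss trace, returns
#' the 1-based epoch after which training stops, or `NA` if the rule never
#' fires.
#'
#' @param losses Numeric vector of per-epoch mean losses.
#' @param delta Minimum improvement (default 0.001).
#' @param patience Consecutive sub-threshold epochs required (default 3).
#' @export
early_stop_epoch <- function(losses, delta = 0.001, patience = 3L) {
  if (length(losses) <= patience) return(NA_integer_)
  imp <- -diff(losses)
  below <- imp < delta
  run <- 0L
  for (e in seq_along(below)) {
    run <- if (below[e]) run + 1L else 0L
    if (run >= patience) return(e + 1L)   # epochs are 1-based; imp[e] is epoch e+1
  }
  NA_integer_
}

#' Training configuration for the generative model
#'
#' @param timesteps,beta_start,beta_end Noise-schedule parameters.
#' @param lr Adam learning rate (default 1e-4).
#' @param max_epochs Upper bound on training epochs.
#' @param early_stop_delta,early_stop_patience Early-stopping rule: halt
#'   when the epoch loss fails to improve by at least `early_stop_delta`
#'   for `early_stop_patience` consecutive epochs. `patience = Inf`
#'   disables the rule, useful for small noisy batches where per-epoch
#'   losses fluctuate by more than the delta.
#' @param batch_size Minibatch size; `Inf` trains full-batch.
#' @param lr_decay_at Epoch after which the learning rate is multiplied by
#'   `lr_decay_factor` (`NA` disables decay). A late low-rate phase
#'   sharpens the denoiser once the loss has plateaued.
#' @param lr_decay_factor Multiplier applied after `lr_decay_at`.
#' @param rescale Diffuse signed encodings `2*x - 1` instead of raw 0/1
#'   one-hots. With raw encodings a padding row (all zeros) coincides with
#'   the mean of the noise, so the sequence boundary carries no signal; the
#'   signed encoding makes padding an active state the denoiser can commit
#'   to. Decoding maps back before thresholding.
#' @param unet A [unet_config()].
#' @export
diffusion_config <- function(timesteps = 10L, beta_start = 1e-4, beta_end = 0.1,
                             lr = 1e-4, max_epochs = 100L,
                             early_stop_delta = 0.001, early_stop_patience = 3L,
                             batch_size = Inf, lr_decay_at = NA,
                             lr_decay_factor = 0.2, rescale = FALSE,
                             unet = unet_config()) {
  structure(list(
    timesteps = as.integer(timesteps), beta_start = beta_start,
    beta_end = beta_end, lr = lr, max_epochs = as.integer(max_epochs),
    early_stop_delta = early_stop_delta,
    early_stop_patience = early_stop_patience,
    batch_size = batch_size, lr_decay_at = lr_decay_at,
    lr_decay_factor = lr_decay_factor, rescale = rescale, unet = unet
  ), class = "diffusion_config")
}

pairs_to_batch <- function(pairs, l_max, encoder) {
  if (!"nt" %in% names(pairs) || any(is.na(pairs$nt))) {
    pairs$nt <- back_translate(pairs$cdr3b)
  }
  B <- nrow(pairs)
  X <- array(0, c(l_max, 4L, B))
  for (i in seq_len(B)) X[, , i] <- one_hot_encode(pairs$nt[i], l_max)$matrix
  E <- embed_epitopes(pairs$epitope, encoder)
  list(X = X, E = E)
}

#' Train the epitope-conditional diffusion generator
#'
#' Trains the U-Net denoiser on one-hot-encoded nucleotide CDR3beta
#' sequences with the noise-prediction MSE objective: per example a
#' timestep is drawn uniformly, the clean matrix is corrupted in closed
#' form, and the network learns to recover the injected noise. Adam with
#' learning rate 1e-4 by default; early stopping halts training when the
#' epoch loss stops improving by at least 0.001 for 3 consecutive epochs.
#'
#' @param pairs Data frame with columns `cdr3b` (or `nt`) and `epitope`.
#' @param encoder An epitope encoder; see [default_epitope_encoder()].
#' @param config A [diffusion_config()].
#' @param seed Integer seed controlling initialization, timestep and noise
#'   draws; the whole run is deterministic given the seed.
#' @param quiet Suppress per-epoch progress messages.
#' @return A `tcr_diffusion` model: the trained network, schedule, config,
#'   encoder and the per-epoch loss trace.
#' @export
train_generator <- function(pairs, encoder = default_epitope_encoder(),
                            config = diffusion_config(), seed = 1L,
                            quiet = TRUE) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0) abort("training pairs must be non-empty")
  schedule <- linear_schedule(config$timesteps, config$beta_start, config$beta_end)
  net <- unet_new(config$unet, seed = seed)
  dat <- pairs_to_batch(pairs, config$unet$l_max, encoder)
  if (isTRUE(config$rescale)) dat$X <- 2 * dat$X - 1
  B <- dim(dat$X)[3]
  bs <- min(config$batch_size, B)
  losses <- numeric(0)
  withr::with_seed(seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(B)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1, B, by = bs)) {
        idx <- ord[start:min(start + bs - 1, B)]
        x0 <- dat$X[, , idx, drop = FALSE]
        eemb <- dat$E[idx, , drop = FALSE]
        nB <- length(idx)
        tvec <- sample.int(schedule$timesteps, nB, replace = TRUE)
        eps <- array(stats::rnorm(length(x0)), dim(x0))
        ab <- schedule$alpha_bar[tvec]
        xt <- sweep(x0, 3, sqrt(ab), `*`) + sweep(eps, 3, sqrt(1 - ab), `*`)
        fw <- unet_fwd(net, xt, tvec, eemb)
        diffm <- fw$eps - eps
        loss <- mean(diffm^2)
        if (!is.finite(loss)) abort("training diverged (non-finite loss)")
        unet_bwd(net, 2 * diffm / length(diffm), fw$tape)
        cur_lr <- if (!is.na(config$lr_decay_at) && epoch > config$lr_decay_at) {
          config$lr * config$lr_decay_factor
        } else config$lr
        adam_step(net, cur_lr)
        ep_loss <- ep_loss + loss
        nb <- nb + 1L
      }
      losses <- c(losses, ep_loss / nb)
      if (!quiet) message(sprintf("epoch %d: loss %.5f", epoch, losses[epoch]))
      stop_at <- early_stop_epoch(losses, config$early_stop_delta,
                                  config$early_stop_patience)
      if (!is.na(stop_at) && stop_at <= epoch) break
    }
  })
  structure(list(
    net = net, schedule = schedule, config = config, encoder = encoder,
    losses = tibble(epoch = seq_along(losses), loss = losses),
    epochs_trained = length(losses),
    stopped_early = length(losses) < config$max_epochs,
    seed = seed
  ), class = "tcr_diffusion")
}

#' @export
print.tcr_diffusion <- function(x, ...) {
  cat(sprintf(
    "<tcr_diffusion> %d params, T = %d, %d epochs (early stop: %s), final loss %.5f\n",
    n_params(x$net), x$schedule$timesteps, x$epochs_trained,
    ifelse(x$stopped_early, "yes", "no"), utils::tail(x$losses$loss, 1)
  ))
  invisible(x)
}

#' Generate epitope-specific CDR3beta sequences
#'
#' Draws denoised one-hot matrices from the reverse diffusion process
#' conditioned on the epitope, decodes them to nucleotide sequences, and
#' translates the result. Samples whose translation hits a stop codon are
#' flagged `ok = FALSE`.
#'
#' @param model A trained `tcr_diffusion` model.
#' @param epitope Target epitope peptide.
#' @param n Number of sequences to generate.
#' @param seed Integer seed.
#' @param pad_threshold Decoder padding threshold; see [one_hot_decode()].
#' @return A tibble with columns `epitope`, `nt`, `peptide`, `ok`.
#' @export
generate_tcrs <- function(model, epitope, n, seed = 1L, pad_threshold = 0.5) {
  stopifnot(inherits(model, "tcr_diffusion"))
  cond <- embed_epitope(epitope, model$encoder)
  xs <- ancestral_sample(model, cond, n, model$schedule, seed = seed)
  if (isTRUE(model$config$rescale)) xs <- (xs + 1) / 2
  nt <- vapply(seq_len(n), function(i) {
    one_hot_decode(xs[, , i], pad_threshold)
  }, character(1))
  out <- tibble(epitope = epitope, nt = nt, peptide = "", ok = FALSE)
  nonempty <- nzchar(nt)
  if (any(nonempty)) {
    tr <- translate_nt(nt[nonempty])
    out$peptide[nonempty] <- tr$peptide
    out$ok[nonempty] <- tr$ok
  }
  out
}

#' Untrained generator scaffold
#'
#' Builds a `tcr_diffusion` object with freshly initialised weights and no
#' training history — the starting point for [train_generator()]-free uses
#' such as constructing a binding predictor whose encoder is trained from
#' scratch, or for oracle tests.
#'
#' @param config A [diffusion_config()].
#' @param seed Seed for weight initialisation.
#' @param encoder An epitope encoder.
#' @return An untrained `tcr_diffusion`.
#' @export
new_generator <- function(config = diffusion_config(), seed = 1L,
                          encoder = default_epitope_encoder()) {
  structure(list(
    net = unet_new(config$unet, seed = seed),
    schedule = linear_schedule(config$timesteps, config$beta_start, config$beta_end),
    config = config, encoder = encoder,
    losses = tibble(epoch = integer(0), loss = numeric(0)),
    epochs_trained = 0L, stopped_early = FALSE, seed = seed
  ), class = "tcr_diffusion")
}

#' Compact study configurations
#'
#' The configurations used by the package's worked analyses (tests,
#' acceptance script, vignette): a narrow U-Net sized so the full pipeline
#' trains in minutes on one CPU. `study_generator_config()` is the
#' generative-model setup (channels 16-32, bottleneck 64, Adam 2e-3 with a
#' x0.2 decay after epoch 300, minibatch 25, 450 epochs, early stopping
#' disabled because small-batch epoch losses fluctuate beyond the delta);
#' `study_predictor_config()` is the smaller encoder configuration used
#' when a binding predictor is trained from scratch.
#'
#' @return A [diffusion_config()].
#' @export
study_generator_config <- function() {
  diffusion_config(
    lr = 2e-3, max_epochs = 450L, batch_size = 25L,
    early_stop_patience = Inf, lr_decay_at = 300L, lr_decay_factor = 0.2,
    unet = unet_config(l_max = 72L, channels = c(16L, 32L), bottleneck = 64L,
                       t_dim = 32L, n_blocks = 2L)
  )
}

#' @rdname study_generator_config
#' @export
study_predictor_config <- function() {
  diffusion_config(
    unet = unet_config(l_max = 72L, channels = c(8L, 16L), bottleneck = 32L,
                       t_dim = 32L, n_blocks = 2L)
  )
}
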