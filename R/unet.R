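# Conditional 1-D U-Net noise predictor.
#
# The denoiser maps (noisy one-hot matrix, timestep, epitope embedding) to a
# predicted noise matrix of the same shape. The down-sampling stage halves
# the position axis per level while widening channels up to the bottleneck;
# the up-sampling stage mirrors it, with skip connections joining matching
# resolutions. The sinusoidal timestep embedding (through a small MLP) and
# the 1024-dim epitope embedding are projected to each block's channel width
# and injected into every block, so every layer is conditioned on both the
# diffusion stage and the target epitope. A learned positional embedding is
# added after the stem: convolutions alone are translation equivariant, but
# CDR3beta structure is anchored to absolute sequence positions.
#
# Internally feature maps use the flat (L*B) x C layout of R/nn.R; the
# public entry points unet_fwd()/encode_fwd() take and return L x 4 x B
# arrays.

#' Denoiser network configuration
#'
#' @param l_max Padded sequence length in nucleotides; must be divisible by
#'   `2 ^ length(channels)`.
#' @param channels Channel widths of the down-sampling levels.
#' @param bottleneck Bottleneck channel width (default 512); also the
#'   dimension of the latent TCR representation.
#' @param kernel Convolution kernel size (odd).
#' @param t_dim Sinusoidal timestep-embedding width (even).
#' @param n_blocks Channel-preserving residual conv blocks per level.
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(l_max = 72L, channels = c(64L, 128L, 256L),
                        bottleneck = 512L, kernel = 3L, t_dim = 128L,
                        n_blocks = 2L) {
  if (l_max %% (2^length(channels)) != 0) {
    abort("l_max must be divisible by 2^length(channels)")
  }
  if (kernel %% 2 != 1) abort("kernel must be odd")
  if (t_dim %% 2 != 0) abort("t_dim must be even")
  structure(list(
    l_max = as.integer(l_max), channels = as.integer(channels),
    bottleneck = as.integer(bottleneck), kernel = as.integer(kernel),
    t_dim = as.integer(t_dim), n_blocks = as.integer(n_blocks),
    e_dim = EMBED_DIM
  ), class = "unet_config")
}

unet_new <- function(config = unet_config(), seed = 1L) {
  net <- new.env(parent = emptyenv())
  net$config <- config
  net$params <- list()
  net$grads <- list()
  k <- config$kernel
  ch <- config$channels
  nl <- length(ch)
  widths <- c(ch, config$bottleneck)
  withr::with_seed(seed, {
    add_conv <- function(name, cin, cout) {
      param_add(net, paste0(name, ".W"), he_init(cout, cin * k))
      param_add(net, paste0(name, ".b"), numeric(cout))
    }
    add_lin <- function(name, cin, cout) {
      param_add(net, paste0(name, ".W"), he_init(cout, cin))
      param_add(net, paste0(name, ".b"), numeric(cout))
    }
    add_block <- function(name, c) {
      param_add(net, paste0(name, ".gn.gamma"), rep(1, c))
      param_add(net, paste0(name, ".gn.beta"), numeric(c))
      # zero-init the residual branch so every block starts as the identity
      param_add(net, paste0(name, ".conv.W"), matrix(0, c, c * k))
      param_add(net, paste0(name, ".conv.b"), numeric(c))
      add_lin(paste0(name, ".condt"), config$t_dim, c)
      add_lin(paste0(name, ".conde"), config$e_dim, c)
    }
    add_lin("tmlp.l1", config$t_dim, config$t_dim)
    add_lin("tmlp.l2", config$t_dim, config$t_dim)
    add_conv("stem", 4L, ch[1])
    # learned positional embedding: convolutions alone are translation
    # equivariant, but CDR3beta structure is anchored to absolute positions
    param_add(net, "pos.P", matrix(stats::rnorm(config$l_max * ch[1], sd = 0.1),
                                   config$l_max, ch[1]))
    for (i in seq_len(nl)) {
      for (j in seq_len(config$n_blocks)) add_block(sprintf("down%d.block%d", i, j), ch[i])
      add_conv(sprintf("down%d.down", i), widths[i], widths[i + 1])
    }
    for (j in seq_len(config$n_blocks)) add_block(sprintf("mid.block%d", j), config$bottleneck)
    for (i in rev(seq_len(nl))) {
      add_conv(sprintf("up%d.upconv", i), widths[i + 1], ch[i])
      add_conv(sprintf("up%d.merge", i), 2L * ch[i], ch[i])
      for (j in seq_len(config$n_blocks)) add_block(sprintf("up%d.block%d", i, j), ch[i])
    }
    # zero-init the output projection: the denoiser predicts zero noise at
    # initialization, so the first loss sits at the standard-normal baseline
    param_add(net, "out.W", matrix(0, 4L, ch[1] * k))
    param_add(net, "out.b", numeric(4L))
  })
  adam_init(net)
  net
}

n_params <- function(store) sum(vapply(store$params, length, numeric(1)))

# One residual conv block: x + conv(silu(gn(x))) + cond, where cond projects
# the timestep and epitope embeddings to the block's channel width and is
# broadcast over positions.
block_fwd <- function(net, name, H, temb, eemb, L, B) {
  p <- net$params
  g <- gn_fwd(H, p[[paste0(name, ".gn.gamma")]], p[[paste0(name, ".gn.beta")]],
              gn_groups_for(ncol(H)), L, B)
  s <- silu_fwd(g$Y)
  cv <- conv1d_fwd(s$Y, p[[paste0(name, ".conv.W")]], p[[paste0(name, ".conv.b")]], L, B)
  ct <- lin_fwd(temb, p[[paste0(name, ".condt.W")]], p[[paste0(name, ".condt.b")]])
  ce <- lin_fwd(eemb, p[[paste0(name, ".conde.W")]], p[[paste0(name, ".conde.b")]])
  cond <- ct$Y + ce$Y                     # B x C
  grp_b <- rep(seq_len(B), each = L)
  list(Y = H + cv$Y + cond[grp_b, , drop = FALSE],
       cache = list(g = g$cache, s = s$cache, cv = cv$cache,
                    ct = ct$cache, ce = ce$cache, grp_b = grp_b))
}

block_bwd <- function(net, name, dY, cache) {
  p <- net$params
  dcond <- rowsum(dY, cache$grp_b, reorder = FALSE)   # B x C
  lt <- lin_bwd(dcond, cache$ct, p[[paste0(name, ".condt.W")]])
  le <- lin_bwd(dcond, cache$ce, p[[paste0(name, ".conde.W")]])
  grad_acc(net, paste0(name, ".condt.W"), lt$dW)
  grad_acc(net, paste0(name, ".condt.b"), lt$db)
  grad_acc(net, paste0(name, ".conde.W"), le$dW)
  grad_acc(net, paste0(name, ".conde.b"), le$db)
  cb <- conv1d_bwd(dY, cache$cv, p[[paste0(name, ".conv.W")]])
  grad_acc(net, paste0(name, ".conv.W"), cb$dW)
  grad_acc(net, paste0(name, ".conv.b"), cb$db)
  ds <- silu_bwd(cb$dX, cache$s)
  gb <- gn_bwd(ds, cache$g, p[[paste0(name, ".gn.gamma")]])
  grad_acc(net, paste0(name, ".gn.gamma"), gb$dgamma)
  grad_acc(net, paste0(name, ".gn.beta"), gb$dbeta)
  list(dX = dY + gb$dX, dtemb = lt$dX)    # residual path + branch
}

conv_wrap_fwd <- function(net, name, H, L, B, stride = 1L) {
  conv1d_fwd(H, net$params[[paste0(name, ".W")]], net$params[[paste0(name, ".b")]],
             L, B, stride)
}

conv_wrap_bwd <- function(net, name, dY, cache) {
  cb <- conv1d_bwd(dY, cache, net$params[[paste0(name, ".W")]])
  grad_acc(net, paste0(name, ".W"), cb$dW)
  grad_acc(net, paste0(name, ".b"), cb$db)
  cb$dX
}

tmlp_fwd <- function(net, t, B) {
  temb0 <- sinusoidal_embed(t, net$config$t_dim)
  if (is.null(dim(temb0))) temb0 <- matrix(temb0, nrow = B, ncol = net$config$t_dim, byrow = TRUE)
  l1 <- lin_fwd(temb0, net$params[["tmlp.l1.W"]], net$params[["tmlp.l1.b"]])
  s1 <- silu_fwd(l1$Y)
  l2 <- lin_fwd(s1$Y, net$params[["tmlp.l2.W"]], net$params[["tmlp.l2.b"]])
  list(Y = l2$Y, cache = list(l1 = l1$cache, s1 = s1$cache, l2 = l2$cache))
}

tmlp_bwd <- function(net, dtemb, cache) {
  b2 <- lin_bwd(dtemb, cache$l2, net$params[["tmlp.l2.W"]])
  grad_acc(net, "tmlp.l2.W", b2$dW)
  grad_acc(net, "tmlp.l2.b", b2$db)
  ds <- silu_bwd(b2$dX, cache$s1)
  b1 <- lin_bwd(ds, cache$l1, net$params[["tmlp.l1.W"]])
  grad_acc(net, "tmlp.l1.W", b1$dW)
  grad_acc(net, "tmlp.l1.b", b1$db)
  invisible(NULL)
}

array_to_flat <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(1, 3, 2)), d[1] * d[3], d[2])
}

flat_to_array <- function(H, L, B) {
  aperm(array(H, c(L, B, ncol(H))), c(1, 3, 2))
}

# Down-sampling stage (the "encoder"): stem + positional embedding,
# per-level blocks + strided convolution, bottleneck blocks. Returns the
# bottleneck feature map and the per-level skip activations.
unet_down_fwd <- function(net, H, temb, eemb, B) {
  cfg <- net$config
  nl <- length(cfg$channels)
  L <- cfg$l_max
  tape <- list()
  st <- conv_wrap_fwd(net, "stem", H, L, B)
  tape$stem <- st$cache
  h <- st$Y + net$params[["pos.P"]][rep.int(seq_len(L), B), , drop = FALSE]
  skips <- vector("list", nl)
  for (i in seq_len(nl)) {
    for (j in seq_len(cfg$n_blocks)) {
      nm <- sprintf("down%d.block%d", i, j)
      bf <- block_fwd(net, nm, h, temb, eemb, L, B)
      tape[[nm]] <- bf$cache
      h <- bf$Y
    }
    skips[[i]] <- h
    dn <- conv_wrap_fwd(net, sprintf("down%d.down", i), h, L, B, stride = 2L)
    tape[[sprintf("down%d.down", i)]] <- dn$cache
    h <- dn$Y
    L <- L %/% 2L
  }
  for (j in seq_len(cfg$n_blocks)) {
    nm <- sprintf("mid.block%d", j)
    bf <- block_fwd(net, nm, h, temb, eemb, L, B)
    tape[[nm]] <- bf$cache
    h <- bf$Y
  }
  list(h = h, skips = skips, tape = tape, L = L)
}

unet_down_bwd <- function(net, dh, tape, B) {
  cfg <- net$config
  nl <- length(cfg$channels)
  dtemb <- 0
  for (j in rev(seq_len(cfg$n_blocks))) {
    nm <- sprintf("mid.block%d", j)
    bb <- block_bwd(net, nm, dh, tape[[nm]])
    dh <- bb$dX
    dtemb <- dtemb + bb$dtemb
  }
  for (i in rev(seq_len(nl))) {
    dh <- conv_wrap_bwd(net, sprintf("down%d.down", i), dh, tape[[sprintf("down%d.down", i)]])
    extra <- tape$.dskip_extra[[i]]
    if (!is.null(extra)) dh <- dh + extra
    for (j in rev(seq_len(cfg$n_blocks))) {
      nm <- sprintf("down%d.block%d", i, j)
      bb <- block_bwd(net, nm, dh, tape[[nm]])
      dh <- bb$dX
      dtemb <- dtemb + bb$dtemb
    }
  }
  grad_acc(net, "pos.P", rowsum(dh, rep.int(seq_len(cfg$l_max), B), reorder = FALSE))
  dX <- conv_wrap_bwd(net, "stem", dh, tape$stem)
  list(dX = dX, dtemb = dtemb)
}

# Full denoiser forward: eps_hat = f(X_t, t, epitope embedding).
unet_fwd <- function(net, X, t, eemb) {
  cfg <- net$config
  nl <- length(cfg$channels)
  B <- dim(X)[3]
  tm <- tmlp_fwd(net, t, B)
  temb <- tm$Y
  dn <- unet_down_fwd(net, array_to_flat(X), temb, eemb, B)
  tape <- dn$tape
  tape$tmlp <- tm$cache
  h <- dn$h
  L <- dn$L
  for (i in rev(seq_len(nl))) {
    hu <- up2_fwd(h, L, B)
    L <- L * 2L
    uc <- conv_wrap_fwd(net, sprintf("up%d.upconv", i), hu$Y, L, B)
    tape[[sprintf("up%d.upconv", i)]] <- uc$cache
    tape[[sprintf("up%d.upsrc", i)]] <- hu$src
    mg <- conv_wrap_fwd(net, sprintf("up%d.merge", i), cbind(uc$Y, dn$skips[[i]]), L, B)
    tape[[sprintf("up%d.merge", i)]] <- mg$cache
    h <- mg$Y
    for (j in seq_len(cfg$n_blocks)) {
      nm <- sprintf("up%d.block%d", i, j)
      bf <- block_fwd(net, nm, h, temb, eemb, L, B)
      tape[[nm]] <- bf$cache
      h <- bf$Y
    }
  }
  oc <- conv_wrap_fwd(net, "out", h, cfg$l_max, B)
  tape$out <- oc$cache
  list(eps = flat_to_array(oc$Y, cfg$l_max, B), tape = tape)
}

unet_bwd <- function(net, dEps, tape) {
  cfg <- net$config
  nl <- length(cfg$channels)
  B <- dim(dEps)[3]
  dtemb <- 0
  dh <- conv_wrap_bwd(net, "out", array_to_flat(dEps), tape$out)
  dskips <- vector("list", nl)
  for (i in seq_len(nl)) {                # reverse of the up path (i ran nl..1)
    for (j in rev(seq_len(cfg$n_blocks))) {
      nm <- sprintf("up%d.block%d", i, j)
      bb <- block_bwd(net, nm, dh, tape[[nm]])
      dh <- bb$dX
      dtemb <- dtemb + bb$dtemb
    }
    dcat <- conv_wrap_bwd(net, sprintf("up%d.merge", i), dh, tape[[sprintf("up%d.merge", i)]])
    c_i <- cfg$channels[i]
    dskips[[i]] <- dcat[, c_i + seq_len(c_i), drop = FALSE]
    duc <- conv_wrap_bwd(net, sprintf("up%d.upconv", i), dcat[, seq_len(c_i), drop = FALSE],
                         tape[[sprintf("up%d.upconv", i)]])
    dh <- up2_bwd(duc, tape[[sprintf("up%d.upsrc", i)]])
  }
  tape$.dskip_extra <- dskips
  db <- unet_down_bwd(net, dh, tape, B)
  tmlp_bwd(net, db$dtemb + dtemb, tape$tmlp)
  invisible(flat_to_array(db$dX, cfg$l_max, B))
}

# Pooled bottleneck features (the latent TCR representation): mean over
# positions of the bottleneck feature map.
encode_fwd <- function(net, X, t, eemb) {
  B <- dim(X)[3]
  tm <- tmlp_fwd(net, t, B)
  dn <- unet_down_fwd(net, array_to_flat(X), tm$Y, eemb, B)
  grp_b <- rep(seq_len(B), each = dn$L)
  feat <- rowsum(dn$h, grp_b, reorder = FALSE) / dn$L   # B x bottleneck
  tape <- dn$tape
  tape$tmlp <- tm$cache
  tape$.L <- dn$L
  list(feat = feat, tape = tape)
}

encode_bwd <- function(net, dfeat, tape) {
  B <- nrow(dfeat)
  L <- tape$.L
  dh <- dfeat[rep(seq_len(B), each = L), , drop = FALSE] / L
  tape$.dskip_extra <- NULL
  db <- unet_down_bwd(net, dh, tape, B)
  tmlp_bwd(net, db$dtemb, tape$tmlp)
  invisible(flat_to_array(db$dX, net$config$l_max, B))
}
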