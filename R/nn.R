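# Low-level neural-network primitives on batched 1-D feature maps.
#
# Feature maps are stored flat as (L*B) x C matrices: rows ordered position-
# fastest within sample (row = l + (b-1)*L), columns are channels. This
# layout keeps every operation a plain matrix op (BLAS matmul, rowsum,
# column sweep) with no array transposition. Every *_fwd returns
# list(Y, cache); the matching *_bwd consumes the cache and returns input
# and parameter gradients. All gradients are verified against numerical
# differentiation in the test suite.

# Shift rows by `off` positions within each sample, zero-filling across
# sample boundaries.
shift_rows <- function(H, L, B, off) {
  if (off == 0) return(H)
  l <- rep.int(seq_len(L), B)
  ok <- (l + off >= 1) & (l + off <= L)
  Y <- matrix(0, L * B, ncol(H))
  Y[ok, ] <- H[which(ok) + off, , drop = FALSE]
  Y
}

# 1-D convolution, zero ("same") padding, odd kernel. W is O x (Cin*K) with
# columns blocked tap-major; stride > 1 subsamples positions.
conv1d_fwd <- function(H, W, b, L, B, stride = 1L) {
  Cin <- ncol(H)
  K <- ncol(W) / Cin
  offs <- seq_len(K) - (K + 1L) / 2
  M <- matrix(0, L * B, Cin * K)
  l <- rep.int(seq_len(L), B)
  for (j in seq_len(K)) {
    o <- offs[j]
    cols <- ((j - 1) * Cin + 1):(j * Cin)
    if (o == 0) {
      M[, cols] <- H
    } else {
      ok <- which((l + o >= 1) & (l + o <= L))
      M[ok, cols] <- H[ok + o, , drop = FALSE]
    }
  }
  Y <- tcrossprod(M, W)
  Y <- Y + matrix(b, nrow(Y), length(b), byrow = TRUE)
  if (stride > 1L) {
    sel <- which(rep.int(seq_len(L), B) %% stride == 1L)
    Y <- Y[sel, , drop = FALSE]
  }
  list(Y = Y, cache = list(M = M, L = L, B = B, stride = stride, K = K))
}

conv1d_bwd <- function(dY, cache, W) {
  L <- cache$L; B <- cache$B; K <- cache$K; stride <- cache$stride
  Cin <- ncol(cache$M) / K
  if (stride > 1L) {
    full <- matrix(0, L * B, ncol(dY))
    sel <- which(rep.int(seq_len(L), B) %% stride == 1L)
    full[sel, ] <- dY
    dY <- full
  }
  dW <- crossprod(dY, cache$M)
  db <- colSums(dY)
  dM <- dY %*% W
  offs <- seq_len(K) - (K + 1L) / 2
  dX <- matrix(0, L * B, Cin)
  for (j in seq_len(K)) {
    blk <- dM[, ((j - 1) * Cin + 1):(j * Cin), drop = FALSE]
    dX <- dX + shift_rows(blk, L, B, -offs[j])
  }
  list(dX = dX, dW = dW, db = db)
}

# Group normalization: statistics over (positions x in-group channels) per
# sample. grp_c maps channels to groups; rowsum() does the per-sample sums.
gn_fwd <- function(H, gamma, beta, groups, L, B, eps = 1e-5) {
  C <- ncol(H)
  Cg <- C / groups
  grp_b <- rep(seq_len(B), each = L)
  grp_c <- rep(seq_len(groups), each = Cg)
  ind <- outer(grp_c, seq_len(groups), `==`) * 1   # C x G indicator
  S <- rowsum(H, grp_b, reorder = FALSE) %*% ind    # B x G
  S2 <- rowsum(H * H, grp_b, reorder = FALSE) %*% ind
  n_el <- L * Cg
  mu <- S / n_el
  va <- S2 / n_el - mu * mu
  istd <- 1 / sqrt(pmax(va, 0) + eps)
  xhat <- (H - mu[grp_b, grp_c, drop = FALSE]) * istd[grp_b, grp_c, drop = FALSE]
  Y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(Y = Y, cache = list(xhat = xhat, istd = istd, grp_b = grp_b,
                           grp_c = grp_c, ind = ind, n_el = n_el, L = L, B = B))
}

gn_bwd <- function(dY, cache, gamma) {
  xhat <- cache$xhat
  grp_b <- cache$grp_b
  grp_c <- cache$grp_c
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, `*`)
  m1 <- (rowsum(dxhat, grp_b, reorder = FALSE) %*% cache$ind) / cache$n_el
  m2 <- (rowsum(dxhat * xhat, grp_b, reorder = FALSE) %*% cache$ind) / cache$n_el
  dX <- (dxhat - m1[grp_b, grp_c] - xhat * m2[grp_b, grp_c]) *
    cache$istd[grp_b, grp_c]
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

silu_fwd <- function(X) {
  S <- 1 / (1 + exp(-X))
  list(Y = X * S, cache = list(X = X, S = S))
}

silu_bwd <- function(dY, cache) {
  dY * (cache$S * (1 + cache$X * (1 - cache$S)))
}

# Dense layer on row-major batches (B x I); W is O x I.
lin_fwd <- function(X, W, b) {
  Y <- tcrossprod(X, W)
  list(Y = Y + matrix(b, nrow(Y), length(b), byrow = TRUE), cache = list(X = X))
}

lin_bwd <- function(dY, cache, W) {
  list(dX = dY %*% W, dW = crossprod(dY, cache$X), db = colSums(dY))
}

# Nearest-neighbour x2 upsampling along positions.
up2_fwd <- function(H, L, B) {
  src <- as.vector(outer(rep(seq_len(L), each = 2), (seq_len(B) - 1L) * L, `+`))
  list(Y = H[src, , drop = FALSE], src = src)
}

up2_bwd <- function(dY, src) {
  rowsum(dY, src)   # groups 1..(L*B) in sorted order = original layout
}

dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(Y = X, cache = NULL))
  mask <- matrix(stats::rbinom(length(X), 1, 1 - p) / (1 - p), nrow(X), ncol(X))
  list(Y = X * mask, cache = mask)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

gn_groups_for <- function(ch) {
  for (g in c(8L, 4L, 2L)) if (ch %% g == 0 && ch >= 2 * g) return(g)
  1L
}

# --- parameter store helpers -------------------------------------------------

he_init <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / ncol)), nrow, ncol)
}

param_add <- function(store, name, value) {
  store$params[[name]] <- value
  g <- value
  g[] <- 0
  store$grads[[name]] <- g
  invisible(store)
}

grad_acc <- function(store, name, g) {
  store$grads[[name]] <- store$grads[[name]] + g
  invisible(store)
}

adam_init <- function(store) {
  store$opt <- list(
    t = 0L,
    m = lapply(store$params, function(p) p * 0),
    v = lapply(store$params, function(p) p * 0)
  )
  invisible(store)
}

adam_step <- function(store, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  store$opt$t <- store$opt$t + 1L
  bc1 <- 1 - beta1^store$opt$t
  bc2 <- 1 - beta2^store$opt$t
  for (nm in names(store$params)) {
    g <- store$grads[[nm]]
    store$opt$m[[nm]] <- beta1 * store$opt$m[[nm]] + (1 - beta1) * g
    store$opt$v[[nm]] <- beta2 * store$opt$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (store$opt$m[[nm]] / bc1) / (sqrt(store$opt$v[[nm]] / bc2) + eps)
    store$params[[nm]] <- store$params[[nm]] - step
    store$grads[[nm]][] <- 0
  }
  invisible(store)
}

zero_grads <- function(store) {
  for (nm in names(store$grads)) store$grads[[nm]][] <- 0
  invisible(store)
}
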