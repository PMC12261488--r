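test_that("linear schedule hits its endpoints and satisfies the product algebra", {
  sch <- linear_schedule(10, 1e-4, 0.1)
  expect_equal(sch$beta[1], 1e-4)
  expect_equal(sch$beta[10], 0.1)
  expect_equal(sch$alpha, 1 - sch$beta)
  # direct-product oracle computed independently of cumprod
  direct <- 1
  for (b in sch$beta) direct <- direct * (1 - b)
  expect_equal(sch$alpha_bar[10], direct, tolerance = 1e-12)
  # monotonicity and the ratio identity alpha_bar_t / alpha_bar_{t-1} = alpha_t
  expect_true(all(diff(sch$alpha_bar) < 0))
  expect_equal(sch$alpha_bar[-1] / sch$alpha_bar[-10], sch$alpha[-1],
               tolerance = 1e-14)
  expect_error(linear_schedule(10, 0.2, 0.1), "beta")
  expect_error(linear_schedule(0), "timesteps")
})

test_that("closed-form forward corruption obeys its limits", {
  sch <- linear_schedule(10)
  x0 <- one_hot_encode("ATGTGG", 12L)$matrix
  # noiseless limit
  expect_equal(forward_sample(x0, 4, sch, x0 * 0), sqrt(sch$alpha_bar[4]) * x0)
  # identity limit with a hypothetical alpha_bar = 1 schedule
  idsch <- structure(list(timesteps = 1L, beta = 0, alpha = 1, alpha_bar = 1),
                     class = "noise_schedule")
  eps <- matrix(rnorm(48), 12)
  expect_equal(forward_sample(x0, 1, idsch, eps), x0)
  expect_error(forward_sample(x0, 2, sch, matrix(0, 2, 2)), "shape")
})

test_that("single-step kernel matches its closed form and identity limit", {
  sch <- linear_schedule(10)
  x <- matrix(rnorm(24), 6)
  expect_equal(step_kernel_sample(x, 5, sch, x * 0), sqrt(1 - sch$beta[5]) * x)
  small <- linear_schedule(3, 1e-12, 1e-12)
  expect_equal(step_kernel_sample(x, 1, small, x * 0), x, tolerance = 1e-9)
})

test_that("composed step kernels match the closed form in first two moments", {
  sch <- linear_schedule(10)
  x0 <- one_hot_encode("ATG", 3L)$matrix
  n <- 20000L
  withr::with_seed(33, {
    # direct closed form at T
    xt_direct <- replicate(n, forward_sample(x0, 10, sch, matrix(rnorm(12), 3)))
    # step-kernel composition t = 1..T
    xt_comp <- replicate(n, {
      x <- x0
      for (t in 1:10) x <- step_kernel_sample(x, t, sch, matrix(rnorm(12), 3))
      x
    })
  })
  se <- sqrt(1 / n) * 3   # 3 Monte-Carlo standard errors on a unit-variance mean
  expect_lt(max(abs(apply(xt_direct, c(1, 2), mean) - apply(xt_comp, c(1, 2), mean))), se)
  expect_lt(max(abs(apply(xt_direct, c(1, 2), var) - apply(xt_comp, c(1, 2), var))),
            3 * sqrt(2 / n) * 3)
})

test_that("the noise-prediction loss is zero for the oracle and ~1 for the zero net", {
  sch <- linear_schedule(10)
  x0 <- one_hot_encode("ATGTGGTGC", 12L)$matrix
  eps <- matrix(rnorm(48), 12)
  oracle <- function(xt, t, eemb) array(eps, c(12, 4, 1))
  zero_net <- function(xt, t, eemb) array(0, c(12, 4, 1))
  cond <- embed_epitope("GILGFVFTL")
  expect_equal(diffusion_loss(oracle, x0, cond, 3, sch, eps), 0)
  withr::with_seed(14, {
    losses <- replicate(200, {
      e <- matrix(rnorm(48), 12)
      diffusion_loss(zero_net, x0, cond, 7, sch, e)
    })
  })
  expect_equal(mean(losses), 1, tolerance = 0.05)
  expect_true(all(losses >= 0))
})

test_that("reverse steps follow the posterior-mean formula with noise suppressed", {
  sch <- linear_schedule(10)
  xt <- matrix(rnorm(24), 6)
  for (t in c(10, 5, 2)) {
    expect_equal(reverse_step(xt, t, sch, xt * 0, z = 0), xt / sqrt(sch$alpha[t]))
  }
  # with a nonzero prediction the full formula applies
  eh <- matrix(rnorm(24), 6)
  want <- (xt - sch$beta[4] / sqrt(1 - sch$alpha_bar[4]) * eh) / sqrt(sch$alpha[4])
  expect_equal(reverse_step(xt, 4, sch, eh, z = 0), want)
})

test_that("ancestral sampling is shape-correct and bit-reproducible by seed", {
  sch <- linear_schedule(10)
  zero_net <- function(xt, t, eemb) xt * 0
  cond <- embed_epitope("GILGFVFTL")
  s1 <- ancestral_sample(zero_net, cond, 3, sch, seed = 21, l_max = 12L)
  s2 <- ancestral_sample(zero_net, cond, 3, sch, seed = 21, l_max = 12L)
  expect_identical(dim(s1), c(12L, 4L, 3L))
  expect_identical(s1, s2)
  s3 <- ancestral_sample(zero_net, cond, 3, sch, seed = 22, l_max = 12L)
  expect_false(identical(s1, s3))
  diverge <- function(xt, t, eemb) xt * Inf
  expect_error(ancestral_sample(diverge, cond, 1, sch, seed = 1, l_max = 12L),
               "diverged at t = 10")
})

test_that("sinusoidal timestep embeddings are bounded, distinct, and zero-phase at t = 0", {
  v0 <- sinusoidal_embed(0, 64)
  expect_equal(v0[1:32], rep(0, 32))
  expect_equal(v0[33:64], rep(1, 32))
  M <- sinusoidal_embed(1:10, 64)
  expect_true(all(M >= -1 & M <= 1))
  expect_identical(nrow(unique(round(M, 12))), 10L)
  expect_error(sinusoidal_embed(1, 63), "even")
})

test_that("early stopping fires after the third consecutive sub-threshold improvement", {
  # improvements: 0.01, 0.0005, 0.0004, 0.0003 -> halt at epoch 5
  losses <- c(0.05, 0.04, 0.0395, 0.0391, 0.0388)
  expect_identical(early_stop_epoch(losses, delta = 0.001, patience = 3), 5L)
  # a recovery resets the run
  expect_true(is.na(early_stop_epoch(c(0.05, 0.0495, 0.049, 0.03, 0.0295),
                                     delta = 0.001, patience = 3)))
  expect_true(is.na(early_stop_epoch(c(0.05, 0.04), delta = 0.001, patience = 3)))
})

test_that("generator training is deterministic, lossy data overfits, and early stop engages", {
  pairs <- tiny_pairs(20)
  cfg <- tiny_diffusion_config(max_epochs = 30L)
  m1 <- train_generator(pairs, config = cfg, seed = 9)
  m2 <- train_generator(pairs, config = cfg, seed = 9)
  expect_identical(m1$losses, m2$losses)
  expect_identical(m1$net$params, m2$net$params)
  # single-sequence data: the final-epoch loss beats the first epoch
  expect_lt(dplyr::last(m1$losses$loss), m1$losses$loss[1])
  # with a huge delta every epoch counts as non-improving: halt at patience + 1
  cfg_stop <- tiny_diffusion_config(max_epochs = 30L)
  cfg_stop$early_stop_delta <- 10
  cfg_stop$early_stop_patience <- 3L
  m3 <- train_generator(pairs, config = cfg_stop, seed = 9)
  expect_identical(m3$epochs_trained, 4L)
  expect_true(m3$stopped_early)
  expect_error(train_generator(pairs[0, ], config = cfg), "non-empty")
})

test_that("generated sequences decode, translate, and reproduce by seed", {
  m <- tiny_trained_model()
  g1 <- generate_tcrs(m, "GILGFVFTL", 4, seed = 3)
  g2 <- generate_tcrs(m, "GILGFVFTL", 4, seed = 3)
  expect_identical(g1, g2)
  expect_identical(nrow(g1), 4L)
  expect_true(all(nchar(g1$nt) %% 3 == 0))
})
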