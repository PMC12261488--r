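test_that("position-wise Pearson matches the brute-force column oracle", {
  expect_error(positionwise_pearson(character(0), "ATG"), "non-empty")
  # identical sets correlate perfectly wherever defined
  set <- c("ATGTGC", "ATGAAA", "TTGTGC", "ATGTGA")
  same <- positionwise_pearson(set, set, 6L)
  expect_true(all(abs(same$r[same$defined] - 1) < 1e-12))
  # zero-variance columns (all padding, or uniform frequencies) are undefined
  und <- positionwise_pearson(c("AAT", "AAG"), c("AAC", "AAG"), 6L)
  expect_false(any(und$defined[4:6]))    # beyond every sequence: all-zero columns
  uni <- positionwise_pearson(c("AAA", "TAA", "GAA", "CAA"), c("AAA", "TAA"), 3L)
  expect_false(uni$defined[1])           # uniform 0.25 column has no variance
  # randomized instances against the oracle
  withr::with_seed(27, {
    for (rep in 1:100) {
      la <- sample(2:5, 1) * 3
      a <- replicate(4, random_nt(la))
      b <- replicate(4, random_nt(sample(2:5, 1) * 3))
      got <- positionwise_pearson(a, b, 15L)
      want <- brute_positionwise_r(a, b, 15L)
      expect_equal(got$r, want, tolerance = 1e-12)
    }
  })
})

test_that("cosine similarity matches hand values and the pairwise brute force", {
  expect_equal(mean_cosine("ATG", "ATG", 6L)$mean, 1)
  expect_equal(mean_cosine("AA", "AT", 4L)$mean, 0.5)
  # mean over a 3x3 set equals the average of the 9 pairwise values
  a <- c("ATGTGC", "ATGAAA", "TTGTGC")
  b <- c("ATGTGA", "CCCAAA", "ATGTGC")
  got <- mean_cosine(a, b, 9L)
  flat <- function(s) as.numeric(one_hot_encode(s, 9L)$matrix)
  want <- outer(seq_along(a), seq_along(b), Vectorize(function(i, j) {
    va <- flat(a[i]); vb <- flat(b[j])
    sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  }))
  expect_equal(unname(got$matrix), want)
  expect_equal(got$mean, mean(want))
  # symmetry and [0, 1] bounds for one-hot inputs
  expect_equal(mean_cosine(b, a, 9L)$mean, got$mean)
  expect_true(all(got$matrix >= -1e-12 & got$matrix <= 1 + 1e-12))
  expect_error(mean_cosine(matrix(0, 3, 4), "ATG"), "zero vectors|array")
})

test_that("latent embeddings have bottleneck width, are deterministic, and separate classes", {
  m <- tiny_trained_model()
  tcrs <- tibble::tibble(cdr3b = c("CASF", "CVSF", "WRRW"), epitope = c("E1", "E1", "E2"))
  l1 <- extract_latents(m, tcrs)
  l2 <- extract_latents(m, tcrs)
  expect_identical(l1, l2)
  expect_identical(ncol(l1$latent), m$net$config$bottleneck)
  expect_identical(nrow(l1), 3L)
})

test_that("knn purity is exact on constructed geometries", {
  # single-class data is pure by definition
  withr::with_seed(31, one <- matrix(rnorm(40), 20))
  expect_equal(knn_purity(one, rep("x", 20), k = 5, pca = FALSE), 1)
  # two clusters separated far beyond their diameters
  withr::with_seed(32, {
    a <- matrix(rnorm(60, 0, 0.1), 30)
    b <- matrix(rnorm(60, 50, 0.1), 30)
  })
  expect_equal(knn_purity(rbind(a, b), rep(c("a", "b"), each = 30), k = 5,
                          pca = FALSE), 1)
  expect_error(knn_purity(one, rep("x", 20), k = 20), "smaller")
  # randomized agreement with a direct neighbour scan
  withr::with_seed(33, {
    for (rep in 1:20) {
      n <- sample(8:15, 1)
      m <- matrix(rnorm(n * 3), n)
      lab <- sample(c("p", "q"), n, replace = TRUE)
      if (length(unique(lab)) < 2) lab[1] <- setdiff(c("p", "q"), lab[2])
      k <- sample(2:4, 1)
      d <- as.matrix(dist(m))
      diag(d) <- Inf
      want <- mean(sapply(seq_len(n), function(i) {
        mean(lab[order(d[i, ])[1:k]] == lab[i])
      }))
      expect_equal(knn_purity(m, lab, k = k, pca = FALSE), want)
    }
  })
})

test_that("classification metrics match direct confusion-table computation", {
  expect_equal(classification_metrics(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2))$accuracy, 1)
  expect_equal(classification_metrics(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2))$f1, 1)
  # all-positive predictions on a balanced set: accuracy 0.5, F1 = 2/3
  allpos <- classification_metrics(rep(c(1, 0), 25), rep(1, 50))
  expect_equal(allpos$accuracy, 0.5)
  expect_equal(allpos$f1, 2 / 3)
  expect_identical(c(allpos$tp, allpos$fp, allpos$tn, allpos$fn), c(25L, 25L, 0L, 0L))
  expect_error(classification_metrics(c(1, 0), 0.5), "length mismatch")
  expect_error(classification_metrics(numeric(0), numeric(0)), "empty")
  # randomized agreement with a direct computation
  withr::with_seed(41, {
    for (rep in 1:100) {
      n <- sample(5:40, 1)
      y <- rbinom(n, 1, 0.5)
      p <- runif(n)
      got <- classification_metrics(y, p)
      yh <- as.integer(p >= 0.5)
      expect_equal(got$accuracy, mean(yh == y))
      tp <- sum(y & yh); fp <- sum(!y & yh); fn <- sum(y & !yh)
      f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
      expect_equal(got$f1, f1)
    }
  })
})

test_that("position frequency matrices match hand counts and stay column-stochastic", {
  single <- pfm_export("ATG", "nt")
  expect_equal(single$A, c(1, 0, 0))
  expect_equal(single$G, c(0, 0, 1))
  hand <- pfm_export(c("AAT", "AAG", "ACT", "GCT"), "nt")
  expect_equal(hand$A, c(0.75, 0.5, 0, 0)[1:3], ignore_attr = TRUE)
  expect_equal(hand$C[2], 0.5)
  expect_equal(hand$T[3], 0.75)
  sums <- rowSums(as.matrix(hand[, c("A", "T", "G", "C")]))
  expect_equal(sums, rep(1, 3), ignore_attr = TRUE)
  # ragged sets count only covering sequences
  rag <- pfm_export(c("AT", "ATG"), "nt")
  expect_identical(rag$n, c(2, 2, 1))
  expect_equal(rag$G[3], 1)
  aa <- pfm_export(c("CASS", "CASR"), "aa")
  expect_equal(aa$C[1], 1)
  expect_error(pfm_export(c("ATG", "CASS1"), "nt"), "alphabet")
  expect_error(pfm_export(character(0)), "non-empty")
})

test_that("PCA scores order variance and feed a reproducible 2-D UMAP layout", {
  withr::with_seed(44, m <- matrix(rnorm(40 * 16), 40))
  sc <- latent_pca(m, 10L)
  expect_identical(dim(sc), c(40L, 10L))
  vars <- apply(sc, 2, var)
  expect_true(all(diff(vars) <= 1e-12))
  lm1 <- latent_map(m, seed = 3)
  lm2 <- latent_map(m, seed = 3)
  expect_identical(dim(lm1)[1], 40L)
  expect_identical(colnames(lm1)[2:3], c("x", "y"))
  expect_equal(lm1$x, lm2$x)
  expect_error(latent_map(m[1:10, ]), "16 points")
})
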