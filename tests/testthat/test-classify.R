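test_that("probe separates linearly separable data and is deterministic", {
  withr::with_seed(1, {
    X <- matrix(c(rnorm(50, -1, 0.1), rnorm(50, 1, 0.1)), ncol = 1)
  })
  y <- rep(c("neg", "pos"), each = 50)
  probe <- fitLinearProbe(X, y, lambda = 1)
  expect_lte(probe@gradNorm, 1e-6)
  expect_equal(mean(predictedLabels(predictProba(probe, X)) == y), 1)

  probe2 <- fitLinearProbe(X, y, lambda = 1)
  expect_lt(max(abs(probeWeights(probe) - probeWeights(probe2))), 1e-8)
  expect_lt(max(abs(probeBiases(probe) - probeBiases(probe2))), 1e-8)

  expect_error(fitLinearProbe(X, rep("a", 100)), "at least 2 classes")
  expect_error(fitLinearProbe(matrix(c(NA, 1, 2, 3), 2), c("a", "b")),
               "non-finite")
})

test_that("identically distributed classes give near-uniform probabilities", {
  withr::with_seed(2, {
    X <- matrix(rnorm(2000 * 4), 2000, 4)
    y <- rep(c("a", "b"), 1000)
  })
  probe <- fitLinearProbe(X, y, lambda = 1)
  p <- probabilities(predictProba(probe, X))
  expect_lt(max(abs(colMeans(p) - 0.5)), 0.02)
  expect_lt(mean(abs(p - 0.5)), 0.05)
})

test_that("softmax prediction matches hand-computed probabilities", {
  std1 <- new("Standardizer", mu = 0, sigma = 1, kind = "population")
  # zero weights: uniform probabilities, lowest-index argmax
  probe0 <- new("LinearProbe", W = matrix(0, 2, 1), b = c(0, 0),
                classes = c("a", "b"), standardizer = std1, lambda = 1,
                seed = 0L, gradNorm = 0)
  pred0 <- predictProba(probe0, matrix(c(-3, 0, 7), 3))
  expect_equal(unname(probabilities(pred0)), matrix(0.5, 3, 2))
  expect_equal(predictedLabels(pred0), rep("a", 3))

  # logits (2, 0): e^2/(e^2+1)
  probe1 <- new("LinearProbe", W = matrix(c(2, 0), 2, 1), b = c(0, 0),
                classes = c("a", "b"), standardizer = std1, lambda = 1,
                seed = 0L, gradNorm = 0)
  p <- probabilities(predictProba(probe1, matrix(1)))
  expect_equal(unname(p[1, ]), c(0.8807971, 0.1192029), tolerance = 1e-6)

  withr::with_seed(6, X <- matrix(rnorm(30), 10, 3))
  probeR <- fitLinearProbe(X, rep(c("a", "b"), 5))
  expect_equal(rowSums(probabilities(predictProba(probeR, X))), rep(1, 10),
               tolerance = 1e-12)
  expect_error(predictProba(probeR, matrix(0, 2, 5)), "feature columns")
})

test_that("fit reaches at least the penalized optimum found by nnet", {
  # independent solver cross-check: evaluate nnet::multinom's parameters
  # under our objective; our optimum must not be worse
  withr::with_seed(7, {
    X <- matrix(rnorm(120 * 3), 120, 3)
    y <- factor(ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(120, 0, 0.5) > 0,
                       "b", "a"))
  })
  lambda <- 1
  obj <- function(W, b) {  # penalized NLL in the last-class-pinned form
    lg <- sweep(X %*% t(W), 2, b, "+")
    lse <- apply(lg, 1, function(r) log(sum(exp(r - max(r)))) + max(r))
    sum(lse - lg[cbind(seq_len(nrow(X)), as.integer(y))]) +
      lambda / 2 * sum(W[1, ]^2)
  }
  ours <- fitLinearProbe(X, y, lambda = lambda)
  oursVal <- obj(probeWeights(ours), probeBiases(ours))
  ref <- nnet::multinom(y ~ X, decay = lambda, trace = FALSE,
                        maxit = 500, reltol = 1e-12)
  cf <- coef(ref)  # "b" relative to "a"; convert to last-class-pinned form
  refVal <- obj(rbind(-cf[-1], 0), c(-cf[1], 0))
  expect_lte(oursVal, refVal + 1e-4)
  # and the two solvers agree on training labels
  expect_equal(predictedLabels(predictProba(ours, X)),
               as.character(predict(ref)))
})

test_that("rescaling features with rescaled penalty keeps decisions invariant", {
  withr::with_seed(10, {
    Xtr <- matrix(rnorm(200 * 5), 200, 5)
    ytr <- ifelse(Xtr[, 1] - Xtr[, 3] + rnorm(200, 0, 0.3) > 0, "a", "b")
    Xte <- matrix(rnorm(100 * 5), 100, 5)
  })
  k <- 3.7
  p1 <- fitLinearProbe(Xtr, ytr, lambda = 1)
  # with x -> k x, the same decision function has W -> W/k, so the
  # penalty matches when lambda -> lambda / k^2
  p2 <- fitLinearProbe(k * Xtr, ytr, lambda = 1 / k^2)
  expect_equal(predictedLabels(predictProba(p1, Xte)),
               predictedLabels(predictProba(p2, k * Xte)))
})

test_that("training accuracy does not improve as label noise is injected", {
  sim <- generateEmbeddingClusters(
    embeddingClusterSpec(D = 16, separation = 90, sigma = 0.2,
                         per_class = 150), seed = 4)
  X <- embMatrix(applyStandardizer(l2Normalize(sim$embeddings),
                                   fitStandardizer(l2Normalize(sim$embeddings))))
  accs <- vapply(c(0, 0.1, 0.2), function(rate) {
    y <- sim$labels
    if (rate > 0) {
      flip <- withr::with_seed(99, sample(length(y), round(rate * length(y))))
      y[flip] <- 1L - y[flip]
    }
    probe <- fitLinearProbe(X, y, lambda = 1)
    mean(predictedLabels(predictProba(probe, X)) == as.character(y))
  }, numeric(1))
  expect_false(is.unsorted(rev(accs)))
})

test_that("model JSON round-trips every parameter", {
  sim <- generateEmbeddingClusters(
    embeddingClusterSpec(D = 8, separation = 120, sigma = 0.2,
                         per_class = 40), seed = 6)
  z <- l2Normalize(sim$embeddings)
  st <- fitStandardizer(z)
  probe <- fitLinearProbe(applyStandardizer(z, st),
                          c("dandelion", "hazel")[sim$labels + 1],
                          lambda = 0.5, standardizer = st, seed = 123L)
  f <- withr::local_tempfile(fileext = ".json")
  writeProbeModel(probe, f)
  back <- readProbeModel(f)
  expect_equal(probeWeights(back), unname(probeWeights(probe)))
  expect_equal(probeBiases(back), probeBiases(probe))
  expect_equal(probeClasses(back), probeClasses(probe))
  expect_equal(probeStandardizer(back)@mu, st@mu)
  expect_equal(probeStandardizer(back)@sigma, st@sigma)
  expect_equal(back@lambda, 0.5)
  expect_equal(back@seed, 123L)
})

test_that("confidence histogram bins max probabilities on [1/K, 1]", {
  mk <- function(conf) {
    p <- cbind(conf, 1 - conf)
    new("PredictionSet", probabilities = p,
        label = c("a", "b")[max.col(p, ties.method = "first")],
        confidence = apply(p, 1, max))
  }
  h <- confidenceHistogram(mk(rep(0.5, 7)), n_bins = 10)
  expect_equal(h$counts, c(7, rep(0, 9)))
  expect_equal(h$breaks[1], 0.5)
  # hand binning: width-0.05 bins on [0.5, 1]
  h2 <- confidenceHistogram(mk(c(0.55, 0.95, 0.97)), n_bins = 10)
  expect_equal(h2$counts, c(0, 1, 0, 0, 0, 0, 0, 0, 0, 2))
  withr::with_seed(15, conf <- runif(200, 0.5, 1))
  expect_equal(sum(confidenceHistogram(mk(conf), 7)$counts), 200)
})
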