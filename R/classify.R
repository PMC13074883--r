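# The linear probe: multinomial logistic regression with softmax on
# standardized embeddings, plus prediction-confidence summaries and JSON
# model serialization.
#
# The probe is deliberately linear: its accuracy measures the linear
# separability of the embedding space rather than classifier capacity.
# Fitting minimizes the L2-penalized multinomial cross-entropy
#   sum_i -log P(y_i | x_i) + lambda/2 * ||W||^2
# in the reference-class parameterization (last class pinned to zero,
# penalty on weights only), which makes the optimum unique. The solver is
# L-BFGS-B with analytic gradients and zero initialization, so refits are
# bit-deterministic; convergence is asserted on the gradient norm.

softmaxRows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fit the multinomial logistic-regression linear probe
#'
#' @param x standardized embeddings ([PollenEmbeddings-class] with state
#'   `"standardized"`, or a plain matrix).
#' @param y class labels (factor, character or integer), >= 2 classes.
#' @param lambda L2 penalty strength (default 1).
#' @param standardizer optional [Standardizer-class] to embed in the model
#'   for prediction-time preprocessing.
#' @param seed integer recorded for provenance (the fit itself is
#'   deterministic).
#' @param grad_tol gradient-norm tolerance at the optimum (default 1e-6).
#' @param maxit maximum L-BFGS-B iterations.
#' @return a [LinearProbe-class].
#' @export
fitLinearProbe <- function(x, y, lambda = 1, standardizer = NULL,
                           seed = 0L, grad_tol = 1e-6, maxit = 2000L) {
  X <- getEmb(x)
  if (any(!is.finite(X))) stop("fitLinearProbe: non-finite features")
  yf <- factor(y)
  classes <- levels(yf)
  K <- length(classes)
  if (K < 2) stop("fitLinearProbe: need at least 2 classes in y")
  n <- nrow(X); D <- ncol(X)
  stopifnot(length(yf) == n)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(yf))] <- 1

  # parameters: (K-1) x D weights then (K-1) biases; class K pinned at 0
  unpack <- function(par) {
    W <- matrix(par[seq_len((K - 1) * D)], K - 1, D)
    b <- par[(K - 1) * D + seq_len(K - 1)]
    list(W = rbind(W, 0), b = c(b, 0))
  }
  logits <- function(p) sweep(tcrossprod(X, p$W), 2, p$b, "+")
  objective <- function(par) {
    p <- unpack(par)
    lg <- logits(p)
    lse <- apply(lg, 1, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
    nll <- sum(lse - lg[cbind(seq_len(n), as.integer(yf))])
    nll + lambda / 2 * sum(p$W[seq_len(K - 1), ]^2)
  }
  gradient <- function(par) {
    p <- unpack(par)
    P <- softmaxRows(logits(p))
    R <- (P - Y)[, seq_len(K - 1), drop = FALSE]
    GW <- t(R) %*% X + lambda * p$W[seq_len(K - 1), , drop = FALSE]
    Gb <- colSums(R)
    c(as.numeric(GW), Gb)
  }
  par0 <- numeric((K - 1) * (D + 1))
  fit <- stats::optim(par0, objective, gradient, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e1))
  # polish until the gradient norm meets tolerance (plain gradient steps
  # are enough this close to the strongly convex optimum)
  par <- fit$par
  g <- gradient(par)
  tries <- 0
  while (sqrt(sum(g^2)) > grad_tol && tries < 5) {
    fit <- stats::optim(par, objective, gradient, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 1))
    par <- fit$par
    g <- gradient(par)
    tries <- tries + 1
  }
  p <- unpack(par)
  if (is.null(standardizer))
    standardizer <- new("Standardizer", mu = numeric(D),
                        sigma = rep(1, D), kind = "population")
  new("LinearProbe", W = p$W, b = p$b, classes = classes,
      standardizer = standardizer, lambda = lambda,
      seed = as.integer(seed), gradNorm = sqrt(sum(g^2)))
}

#' Predict class probabilities with a linear probe
#'
#' Softmax over the probe's class scores; the predicted label is the
#' argmax with lowest-index tie-break, and the confidence is the maximum
#' class probability.
#'
#' @param model a [LinearProbe-class].
#' @param x embeddings whose column count matches the probe (expected to
#'   be L2-normalized and standardized with the probe's own statistics).
#' @return a [PredictionSet-class].
#' @export
predictProba <- function(model, x) {
  stopifnot(is(model, "LinearProbe"))
  X <- getEmb(x)
  if (ncol(X) != ncol(model@W))
    stop(sprintf("predictProba: %d feature columns vs %d in the model",
                 ncol(X), ncol(model@W)))
  P <- softmaxRows(sweep(tcrossprod(X, model@W), 2, model@b, "+"))
  colnames(P) <- model@classes
  idx <- max.col(P, ties.method = "first")
  new("PredictionSet", probabilities = P,
      label = model@classes[idx],
      confidence = P[cbind(seq_len(nrow(P)), idx)])
}

#' Histogram of maximum prediction confidence
#'
#' Bins the per-sample maximum class probability into `n_bins` equal-width
#' bins on `[1/K, 1]` (a K-class softmax confidence cannot fall below
#' 1/K).
#'
#' @param predictions a [PredictionSet-class].
#' @param n_bins number of bins (>= 1, default 10).
#' @return `list(breaks =, counts =)`; counts sum to the sample count.
#' @export
confidenceHistogram <- function(predictions, n_bins = 10) {
  stopifnot(n_bins >= 1)
  K <- ncol(probabilities(predictions))
  breaks <- seq(1 / K, 1, length.out = n_bins + 1)
  conf <- confidences(predictions)
  idx <- clamp(findInterval(conf, breaks, rightmost.closed = TRUE), 1, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  list(breaks = breaks, counts = counts)
}

#' Serialize / load a linear probe as JSON
#'
#' The model file carries everything needed for standalone prediction:
#' class names, the K x D weight matrix and biases, the training-set
#' standardizer statistics, the penalty strength and the seed.
#'
#' @param model a [LinearProbe-class].
#' @param path file path.
#' @return `readProbeModel` returns the [LinearProbe-class].
#' @export
writeProbeModel <- function(model, path) {
  obj <- list(schema_version = 1L,
              classes = model@classes,
              W = unname(model@W),
              b = as.numeric(model@b),
              mu = as.numeric(model@standardizer@mu),
              sigma = as.numeric(model@standardizer@sigma),
              sigma_kind = model@standardizer@kind,
              l2_strength = model@lambda,
              seed = model@seed,
              grad_norm = model@gradNorm)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeProbeModel
#' @export
readProbeModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  W <- as.matrix(obj$W)
  new("LinearProbe", W = W, b = as.numeric(obj$b),
      classes = as.character(obj$classes),
      standardizer = new("Standardizer", mu = as.numeric(obj$mu),
                         sigma = as.numeric(obj$sigma),
                         kind = obj$sigma_kind),
      lambda = as.numeric(obj$l2_strength),
      seed = as.integer(obj$seed),
      gradNorm = as.numeric(obj$grad_norm))
}
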