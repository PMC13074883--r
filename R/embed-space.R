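# Embedding-vector algebra: L2 normalization, cosine similarity, z-score
# standardization and cosine-distance silhouette analysis.
#
# The processing order is fixed: raw -> l2_normalized -> standardized,
# each applied exactly once. L2 normalization puts every embedding on the
# unit hypersphere so dot products are cosine similarities; the subsequent
# z-score removes the unit norm but preserves the angular structure while
# equalizing per-component scales for the linear probe.

SIGMA_EPS <- 1e-12  # guard for zero-variance components; layout preserved

getEmb <- function(x) if (is(x, "PollenEmbeddings")) embMatrix(x) else as.matrix(x)

#' L2-normalize embedding rows
#'
#' Rescales each row to unit Euclidean norm, preserving its direction.
#'
#' @param embeddings a [PollenEmbeddings-class] (state `"raw"` or
#'   `"l2_normalized"`) or a plain matrix.
#' @return a [PollenEmbeddings-class] with state `"l2_normalized"`.
#' @examples
#' embMatrix(l2Normalize(matrix(c(3, 4), 1)))  # (0.6, 0.8)
#' @export
l2Normalize <- function(embeddings) {
  if (is(embeddings, "PollenEmbeddings") &&
      embState(embeddings) == "standardized")
    stop("l2Normalize: embeddings are already standardized; ",
         "the processing order is raw -> l2_normalized -> standardized")
  m <- getEmb(embeddings)
  norms <- sqrt(rowSums(m^2))
  bad <- which(norms == 0)
  if (length(bad))
    stop(sprintf("l2Normalize: zero-norm row(s): %s",
                 paste(bad, collapse = ", ")))
  PollenEmbeddings(m / norms, state = "l2_normalized")
}

#' Cosine similarity of two unit vectors
#'
#' For unit-norm inputs the similarity is simply the dot product, equal to
#' the cosine of the angle between the original vectors and bounded in
#' \[-1, 1\].
#'
#' @param u,v numeric unit vectors (norm within 1e-6 of 1).
#' @return the cosine similarity.
#' @export
cosineSimilarity <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  stopifnot(length(u) == length(v))
  if (abs(sqrt(sum(u^2)) - 1) > 1e-6 || abs(sqrt(sum(v^2)) - 1) > 1e-6)
    stop("cosineSimilarity: inputs must be unit-norm (deviation > 1e-6)")
  sum(u * v)
}

#' Fit per-component z-score statistics on training embeddings
#'
#' Means and standard deviations are computed on the training rows only,
#' so no statistic of validation or test data leaks into preprocessing.
#' The standard deviation uses the population (1/N) formula by default.
#'
#' @param train_embeddings training rows ([PollenEmbeddings-class] or
#'   matrix), >= 2 rows.
#' @param kind `"population"` (default) or `"sample"`.
#' @return a [Standardizer-class].
#' @export
fitStandardizer <- function(train_embeddings, kind = c("population", "sample")) {
  kind <- match.arg(kind)
  m <- getEmb(train_embeddings)
  if (nrow(m) < 2)
    stop("fitStandardizer: need at least 2 training rows")
  mu <- colMeans(m)
  ctr <- sweep(m, 2, mu)
  ss <- colSums(ctr^2)
  sigma <- sqrt(ss / if (kind == "population") nrow(m) else (nrow(m) - 1))
  if (any(sigma == 0))
    warning(sprintf("fitStandardizer: %d zero-variance component(s); the %.0e guard applies",
                    sum(sigma == 0), SIGMA_EPS))
  new("Standardizer", mu = unname(mu), sigma = unname(sigma), kind = kind)
}

#' Apply z-score standardization
#'
#' `x_ij = (f_ij - mu_j) / max(sigma_j, 1e-12)`; the epsilon guard keeps
#' zero-variance components in place rather than dropping them, preserving
#' the embedding layout.
#'
#' @param embeddings rows to standardize ([PollenEmbeddings-class] or
#'   matrix) whose column count matches the standardizer.
#' @param stats a [Standardizer-class] fitted with [fitStandardizer()].
#' @return a [PollenEmbeddings-class] with state `"standardized"`.
#' @export
applyStandardizer <- function(embeddings, stats) {
  stopifnot(is(stats, "Standardizer"))
  m <- getEmb(embeddings)
  if (ncol(m) != length(stats@mu))
    stop(sprintf("applyStandardizer: %d columns vs %d fitted components",
                 ncol(m), length(stats@mu)))
  if (is(embeddings, "PollenEmbeddings") &&
      embState(embeddings) == "standardized")
    stop("applyStandardizer: embeddings are already standardized")
  out <- sweep(sweep(m, 2, stats@mu), 2, pmax(stats@sigma, SIGMA_EPS), "/")
  PollenEmbeddings(out, state = "standardized")
}

#' Silhouette analysis with cosine distance
#'
#' Cluster-separability diagnostic on L2-normalized embeddings. With
#' `d(i, j) = 1 - cos(f_i, f_j)`, each sample gets
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a(i)` is its mean
#' intra-class distance (excluding itself) and `b(i)` the smallest mean
#' distance to any other class. Samples in singleton classes get
#' `s(i) = 0`. Values near 1 indicate well-separated classes; values near
#' or below 0 indicate overlap.
#'
#' @param embeddings unit-norm rows ([PollenEmbeddings-class] with state
#'   `"l2_normalized"`, or a matrix of unit rows).
#' @param labels class label per row (>= 2 distinct values).
#' @return `list(values = per-sample silhouettes, mean = their mean)`.
#' @export
silhouetteCosine <- function(embeddings, labels) {
  m <- getEmb(embeddings)
  n <- nrow(m)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2)
    stop("silhouetteCosine: need at least 2 distinct classes")
  norms <- sqrt(rowSums(m^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("silhouetteCosine: rows must be L2-normalized")
  d <- 1 - tcrossprod(m)
  d[d < 0] <- 0  # numerical guard; exact zeros on the diagonal
  labs <- as.character(labels)
  ulabs <- unique(labs)
  sizes <- table(labs)[ulabs]
  # mean distance of each sample to every class, via one matrix product
  member <- vapply(ulabs, function(l) as.numeric(labs == l), numeric(n))
  sums <- d %*% member                      # n x K total distance per class
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labs[i]
    nOwn <- sizes[[own]]
    if (nOwn == 1) { s[i] <- 0; next }
    a <- sums[i, own] / (nOwn - 1)
    others <- setdiff(ulabs, own)
    b <- min(sums[i, others] / as.numeric(sizes[others]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(values = s, mean = mean(s))
}
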