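#' Intraclass correlation coefficient of a feature set
#'
#' ICC(1,1) from a one-way random-effects ANOVA with samples as subjects and
#' the cluster's features as repeated measures: `(MSB - MSW) / (MSB +
#' (k - 1) * MSW)` where MSB and MSW are the between- and within-subject mean
#' squares. Columns are standardized first so feature scale does not leak
#' into the metric. This is the default information value a reduced feature
#' reports: it answers "how much of each member's variation does the shared
#' subject signal explain".
#'
#' @param cluster Numeric matrix or data frame of the member features
#'   (samples x features).
#'
#' @return A single number `<= 1`. A singleton (one feature) returns exactly
#'   `1`: an unreduced feature loses no information. Negative values are
#'   possible and returned as-is; they simply fail any nonnegative
#'   information threshold.
#' @export
#'
#' @examples
#' x <- rnorm(20)
#' icc(cbind(f1 = x, f2 = x))        # identical features: 1
#' icc(cbind(f1 = x, f2 = rnorm(20)))  # unrelated features: near 0
icc <- function(cluster) {
  x <- as.matrix(cluster)
  k <- ncol(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (k == 1) {
    standardize_columns(x)  # still reject a constant feature
    return(1)
  }
  z <- standardize_columns(x)
  m <- rowMeans(z)
  msb <- k * sum(m^2) / (n - 1)
  msw <- sum((z - m)^2) / (n * (k - 1))
  if (msb + (k - 1) * msw == 0) return(1)
  (msb - msw) / (msb + (k - 1) * msw)
}

# Equal-frequency binning: B bins of (near-)equal occupancy via ranks.
bin_equal_freq <- function(v, B) {
  ceiling(rank(v, ties.method = "first") * B / length(v))
}

# Miller-Madow corrected plug-in entropy (nats) from bin counts.
entropy_mm <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p)) + (length(p) - 1) / (2 * n)
}

# Normalized mutual information between two vectors on equal-frequency bins
# (B = max(2, ceiling(n^(1/3))) per axis), Miller-Madow bias corrected,
# normalized by the geometric mean of the marginal entropies, clamped to
# [0, 1].
normalized_mi <- function(a, b) {
  n <- length(a)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (diff(range(a)) == 0 || diff(range(b)) == 0) {
    stop("constant feature", call. = FALSE)
  }
  B <- max(2L, as.integer(ceiling(n^(1 / 3))))
  ia <- bin_equal_freq(a, B)
  ib <- bin_equal_freq(b, B)
  hx <- entropy_mm(tabulate(ia, B), n)
  hy <- entropy_mm(tabulate(ib, B), n)
  hxy <- entropy_mm(tabulate((ia - 1L) * B + ib, B * B), n)
  mi <- hx + hy - hxy
  min(1, max(0, mi / sqrt(hx * hy)))
}

#' Normalized mutual-information score of a reduction
#'
#' The minimum, over member features, of a normalized mutual-information
#' estimate between the member and the reduced vector. MI is estimated with
#' a bias-corrected plug-in estimator on equal-frequency bins and normalized
#' by the geometric mean of the marginal entropies, so the score lies in
#' `[0, 1]` with 1 meaning every member is fully predictable from the
#' reduced feature. Intended for non-Gaussian data where the ICC is a poor
#' information summary.
#'
#' @param cluster Numeric matrix or data frame of the member features.
#' @param reduced Numeric vector of length `nrow(cluster)`, the candidate
#'   reduced feature.
#'
#' @return A single number in `[0, 1]`; a singleton cluster returns `1`.
#' @export
mutual_information_metric <- function(cluster, reduced) {
  x <- as.matrix(cluster)
  if (ncol(x) == 1) {
    standardize_columns(x)
    return(1)
  }
  if (length(reduced) != nrow(x)) {
    stop("`reduced` must have one value per sample", call. = FALSE)
  }
  min(vapply(seq_len(ncol(x)), function(j) normalized_mi(x[, j], reduced),
             numeric(1)))
}

#' Pairwise feature distances
#'
#' Correlation-based distances between the columns of a feature matrix:
#' `1 - r` (default) ranks anticorrelated pairs far apart, which suits the
#' scaled-mean reducer; `1 - |r|` treats sign as irrelevant.
#'
#' @param x Numeric matrix or data frame (samples x features), all columns
#'   nonconstant.
#' @param method `"one_minus_r"` or `"one_minus_abs_r"`.
#'
#' @return A symmetric `n_features` x `n_features` matrix with zero
#'   diagonal; entries in `[0, 2]` (or `[0, 1]` for the absolute variant).
#' @export
correlation_distance <- function(x, method = c("one_minus_r", "one_minus_abs_r")) {
  method <- match.arg(method)
  z <- standardize_columns(as.matrix(x))
  r <- crossprod(z) / (nrow(z) - 1)
  r[r > 1] <- 1
  r[r < -1] <- -1
  d <- if (method == "one_minus_abs_r") 1 - abs(r) else 1 - r
  diag(d) <- 0
  d
}

#' Reduce a feature set to its scaled row means
#'
#' Each column is standardized (mean 0, sd 1) and the row-wise mean is
#' returned; a singleton returns its standardized values.
#'
#' @param cluster Numeric matrix or data frame of the member features.
#'
#' @return Numeric vector of length `nrow(cluster)`.
#' @export
reduce_mean <- function(cluster) {
  z <- standardize_columns(as.matrix(cluster))
  rowMeans(z)
}

#' Reduce a feature set to its first principal component
#'
#' Scores on the first principal component of the standardized columns.
#' The sign is fixed so the scores correlate positively with the scaled row
#' means, removing the eigenvector sign ambiguity.
#'
#' @param cluster Numeric matrix or data frame of the member features.
#'
#' @return Numeric vector of length `nrow(cluster)`.
#' @export
reduce_pc1 <- function(cluster) {
  z <- standardize_columns(as.matrix(cluster))
  if (ncol(z) == 1) return(z[, 1])
  sv <- svd(z, nu = 0, nv = 1)
  scores <- drop(z %*% sv$v[, 1])
  if (sum(scores * rowMeans(z)) < 0) scores <- -scores
  scores
}

get_reducer <- function(id) {
  switch(id, mean = reduce_mean, pc1 = reduce_pc1,
         stop("unknown reducer: ", id, call. = FALSE))
}

# Metric dispatch: ICC scores the member columns directly; MI scores each
# member against the candidate reduced vector.
score_information <- function(cluster, reduced, metric) {
  switch(metric,
         icc = icc(cluster),
         mi = mutual_information_metric(cluster, reduced),
         stop("unknown metric: ", metric, call. = FALSE))
}
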