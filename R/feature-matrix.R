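#' Coerce and validate a feature matrix
#'
#' A feature matrix holds samples in rows and features in columns, with a
#' unique name per feature. All algorithms in this package operate on this
#' representation.
#'
#' @param x A numeric matrix or data frame (samples x features) with unique
#'   column names.
#'
#' @return A numeric matrix with validated dimnames.
#' @export
#'
#' @examples
#' as_feature_matrix(data.frame(f1 = rnorm(5), f2 = rnorm(5)))
as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("`x` must be a matrix or data frame", call. = FALSE)
  if (!is.numeric(x)) stop("feature matrix must be numeric", call. = FALSE)
  nms <- colnames(x)
  if (is.null(nms) || anyNA(nms) || any(nms == "")) {
    stop("feature matrix must have a complete header of feature names",
         call. = FALSE)
  }
  if (anyDuplicated(nms)) stop("duplicate feature names", call. = FALSE)
  if (nrow(x) < 2) stop("need at least 2 samples (rows)", call. = FALSE)
  if (ncol(x) < 1) stop("feature matrix has no columns", call. = FALSE)
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  x
}

# Column-standardize (mean 0, sd 1). Errors on (near-)constant columns, which
# carry no information and break every metric downstream.
standardize_columns <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  s <- sqrt(colSums(xc^2) / (n - 1))
  bad <- s <= 1e-12 * pmax(abs(mu), 1)
  if (any(bad)) {
    stop("constant feature: ",
         paste(colnames(x)[bad], collapse = ", "), call. = FALSE)
  }
  sweep(xc, 2, s, "/")
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
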