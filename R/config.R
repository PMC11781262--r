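#' Reduction configuration
#'
#' Collects every tunable of the reduction in one validated object.
#'
#' @param ilc_threshold Information loss criterion: the minimum information
#'   value (by default the minimum ICC) any accepted multi-feature cluster
#'   must achieve. In `[0, 1]`; default `0.6`.
#' @param max_cluster_size Maximum super-cluster size `c`; clusters larger
#'   than this are split before the reduction engine runs. Default `4000`.
#' @param gini_threshold Gini-index threshold `g` for the constrained
#'   single-linkage step; when the inequality of current cluster sizes
#'   exceeds `g`, merges are forced to involve a smallest cluster. Default
#'   `0.05`, which strongly penalizes small stray clusters.
#' @param small_split_limit If an iterative re-split of an oversized cluster
#'   produces a part of this size or smaller, that split is rejected and a
#'   k-means split is used instead. Default `50`.
#' @param metric Information metric: `"icc"` (intraclass correlation,
#'   one-way random effects) or `"mi"` (normalized mutual information).
#' @param reducer How a feature set collapses to one vector: `"mean"`
#'   (scaled row means) or `"pc1"` (first principal component).
#' @param distance Feature distance: `"one_minus_r"` (1 - Pearson r) or
#'   `"one_minus_abs_r"` (1 - |r|).
#' @param seed Integer seed controlling every stochastic step (k-means
#'   fallback initialization).
#'
#' @return An object of class `reduction_config`.
#' @export
#'
#' @examples
#' reduction_config(ilc_threshold = 0.5, max_cluster_size = 100)
reduction_config <- function(ilc_threshold = 0.6,
                             max_cluster_size = 4000,
                             gini_threshold = 0.05,
                             small_split_limit = 50,
                             metric = c("icc", "mi"),
                             reducer = c("mean", "pc1"),
                             distance = c("one_minus_r", "one_minus_abs_r"),
                             seed = 42L) {
  metric <- match.arg(metric)
  reducer <- match.arg(reducer)
  distance <- match.arg(distance)
  stopifnot(
    is.numeric(ilc_threshold), length(ilc_threshold) == 1,
    ilc_threshold >= 0, ilc_threshold <= 1,
    is.numeric(max_cluster_size), length(max_cluster_size) == 1,
    max_cluster_size >= 2,
    is.numeric(gini_threshold), length(gini_threshold) == 1,
    gini_threshold >= 0, gini_threshold <= 1,
    is.numeric(small_split_limit), length(small_split_limit) == 1,
    small_split_limit >= 1,
    is.numeric(seed), length(seed) == 1
  )
  structure(
    list(
      ilc_threshold = as.numeric(ilc_threshold),
      max_cluster_size = as.integer(max_cluster_size),
      gini_threshold = as.numeric(gini_threshold),
      small_split_limit = as.integer(small_split_limit),
      metric = metric,
      reducer = reducer,
      distance = distance,
      seed = as.integer(seed)
    ),
    class = "reduction_config"
  )
}

#' @export
print.reduction_config <- function(x, ...) {
  cat("Reduction configuration\n")
  cat(sprintf("  ILC threshold:      %.3g\n", x$ilc_threshold))
  cat(sprintf("  max cluster size:   %d\n", x$max_cluster_size))
  cat(sprintf("  Gini threshold:     %.3g\n", x$gini_threshold))
  cat(sprintf("  small-split limit:  %d\n", x$small_split_limit))
  cat(sprintf("  metric / reducer:   %s / %s\n", x$metric, x$reducer))
  cat(sprintf("  distance:           %s\n", x$distance))
  cat(sprintf("  seed:               %d\n", x$seed))
  invisible(x)
}

as_reduction_config <- function(config) {
  if (inherits(config, "reduction_config")) return(config)
  if (is.list(config)) return(do.call(reduction_config, config))
  stop("`config` must be a reduction_config or a list of its fields",
       call. = FALSE)
}
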