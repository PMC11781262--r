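#' Scalable information-loss-constrained reduction
#'
#' End-to-end reduction for wide feature matrices: the feature set is first
#' split into size-bounded super-clusters ([form_superpartition()]), the
#' greedy reduction engine ([partition()]) runs independently inside each
#' cluster, and the per-cluster results are recombined into a single
#' surjective mapping with sequentially named reduced variables. Because
#' features in different super-clusters are never merged, the output always
#' contains at least `ceiling(N / c)` features, and the information bound
#' holds locally within each cluster.
#'
#' With `max_cluster_size >= n_features` the super-step forms a single
#' cluster and the result coincides with plain [partition()].
#'
#' @param data Feature matrix (samples x features) or data frame with
#'   unique column names; all columns nonconstant.
#' @param config A [reduction_config()].
#'
#' @return A `partition_result` (see [partition()]) with an additional
#'   `superpartition` element: the `cluster_assignment` used, including its
#'   split trace.
#' @export
#'
#' @examples
#' sim <- generate_block_data(n_samples = 80, block_sizes = rep(4, 5),
#'                            rho = 0.9, seed = 7)
#' res <- super_partition(sim$data,
#'                        reduction_config(ilc_threshold = 0.5,
#'                                         max_cluster_size = 10))
#' res
super_partition <- function(data, config = reduction_config()) {
  config <- as_reduction_config(config)
  x <- as_feature_matrix(data)
  sp <- form_superpartition(x, config)
  K <- length(sp$sizes)
  results <- lapply(seq_len(K), function(kid) {
    partition(x[, sp$labels == kid, drop = FALSE], config)
  })
  out <- recombine(results, seq_len(K))
  out$config <- config
  out$superpartition <- sp
  out
}

#' Recombine per-cluster reduction results
#'
#' Concatenates the reduced columns of several `partition_result` objects
#' (one per super-cluster, processed sequentially in the given order) into
#' one result. Multi-member outputs are renamed `reduced_var_1`,
#' `reduced_var_2`, ... sequentially across clusters; singletons keep their
#' original feature names. Member sets must be disjoint across results.
#'
#' @param results List of `partition_result` objects.
#' @param cluster_order Integer permutation giving the order in which the
#'   results are concatenated; defaults to the given order.
#'
#' @return A combined `partition_result`.
#' @export
recombine <- function(results, cluster_order = seq_along(results)) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "partition_result")))
  if (!setequal(cluster_order, seq_along(results))) {
    stop("`cluster_order` must be a permutation of the result indices",
         call. = FALSE)
  }
  results <- results[cluster_order]

  all_members <- unlist(lapply(results, function(r) unlist(r$mapping$members)))
  if (anyDuplicated(all_members)) stop("non-disjoint clusters", call. = FALSE)

  counter <- 0L
  pieces <- lapply(results, function(r) {
    map <- r$mapping
    multi <- map$n_members > 1
    if (any(multi)) {
      map$name[multi] <- paste0("reduced_var_", counter + seq_len(sum(multi)))
      counter <<- counter + sum(multi)
    }
    reduced <- r$reduced_data
    names(reduced) <- map$name
    list(map = map, reduced = reduced)
  })

  mapping <- do.call(rbind, lapply(pieces, `[[`, "map"))
  reduced <- do.call(cbind, lapply(pieces, `[[`, "reduced"))
  structure(
    list(reduced_data = tibble::as_tibble(reduced), mapping = mapping,
         config = results[[1]]$config),
    class = "partition_result"
  )
}
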