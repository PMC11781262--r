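#' Gini index of cluster sizes
#'
#' Normalized inequality of a vector of cluster sizes: 0 when all clusters
#' are equal, 1 at maximal inequality. Computed as
#' `sum_i (k + 1 - 2i) * n_(i) / ((k - 1) * sum(n))` over sizes sorted in
#' nonincreasing order, which equals the pairwise-difference form
#' `sum_{i<j} |n_i - n_j| / ((k - 1) * sum(n))`.
#'
#' @param sizes Vector of positive integer cluster sizes.
#'
#' @return A number in `[0, 1]`; 0 for a single cluster.
#' @export
#'
#' @examples
#' gini_index(c(1, 1, 1, 1))  # 0
#' gini_index(c(1, 3))        # 0.5
gini_index <- function(sizes) {
  if (length(sizes) == 0) stop("`sizes` must be nonempty", call. = FALSE)
  if (any(sizes <= 0)) stop("cluster sizes must be positive", call. = FALSE)
  k <- length(sizes)
  if (k == 1) return(0)
  s <- sort(sizes, decreasing = TRUE)
  sum((k + 1 - 2 * seq_len(k)) * s) / ((k - 1) * sum(s))
}

# Minimum spanning tree of a dense symmetric distance matrix (Prim).
# Returns a data.frame of edges (i, j, weight) sorted by ascending weight,
# ties kept in discovery order.
mst_edges <- function(d) {
  n <- nrow(d)
  if (n == 1) {
    return(data.frame(i = integer(0), j = integer(0), weight = numeric(0)))
  }
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best_w <- d[, 1]
  best_from <- rep(1L, n)
  best_w[1] <- Inf
  ei <- integer(n - 1)
  ej <- integer(n - 1)
  ew <- numeric(n - 1)
  for (e in seq_len(n - 1)) {
    cand <- best_w
    cand[in_tree] <- Inf
    v <- which.min(cand)
    ei[e] <- best_from[v]
    ej[e] <- v
    ew[e] <- best_w[v]
    in_tree[v] <- TRUE
    upd <- !in_tree & d[, v] < best_w
    best_w[upd] <- d[upd, v]
    best_from[upd] <- v
  }
  ord <- order(ew)
  data.frame(i = ei[ord], j = ej[ord], weight = ew[ord])
}

#' Gini-constrained single-linkage clustering
#'
#' Agglomerative merging over the minimum-spanning-tree edges of a distance
#' matrix, taken in ascending weight order (which reproduces single
#' linkage), with one modification: before each merge, if the Gini index of
#' the current cluster sizes exceeds `g`, the merge performed is the
#' cheapest remaining edge incident to a cluster of minimal current size.
#' This forces stray small clusters to be absorbed early and prevents the
#' chaining behavior of plain single linkage from producing one giant
#' cluster plus singletons. With `g = 1` the constraint never binds and the
#' result equals a single-linkage dendrogram cut at `k`.
#'
#' @param dist Symmetric numeric matrix with zero diagonal.
#' @param k Number of clusters to stop at, `1 <= k <= n`.
#' @param g Gini threshold in `[0, 1]`.
#'
#' @return A list of class `cluster_assignment`: `labels` (integer per
#'   item, 1..k, numbered by first occurrence), `sizes`, and `merges`, a
#'   data frame recording for every merge the Gini index before it, whether
#'   the constraint was active, the two merged sizes and the minimal
#'   cluster size at that moment.
#' @export
genie_cluster <- function(dist, k, g) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    stop("`dist` must be a symmetric matrix", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("`dist` must have a zero diagonal", call. = FALSE)
  if (k < 1 || k > n) stop("`k` must be between 1 and n", call. = FALSE)

  edges <- mst_edges(d)
  parent <- seq_len(n)
  size <- rep(1L, n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }

  n_merges <- n - k
  used <- logical(nrow(edges))
  merges <- data.frame(
    gini_before = numeric(n_merges), constrained = logical(n_merges),
    size_a = integer(n_merges), size_b = integer(n_merges),
    min_size = integer(n_merges), weight = numeric(n_merges)
  )

  for (step in seq_len(n_merges)) {
    roots <- unique(vapply(seq_len(n), find, integer(1)))
    sizes_now <- size[roots]
    gini_now <- gini_index(sizes_now)
    min_size <- min(sizes_now)

    pick <- NA_integer_
    constrained <- gini_now > g
    if (constrained) {
      # cheapest remaining edge touching a minimal-size cluster
      for (e in which(!used)) {
        ra <- find(edges$i[e])
        rb <- find(edges$j[e])
        if (size[ra] == min_size || size[rb] == min_size) {
          pick <- e
          break
        }
      }
    }
    if (is.na(pick)) pick <- which(!used)[1]

    used[pick] <- TRUE
    ra <- find(edges$i[pick])
    rb <- find(edges$j[pick])
    merges[step, ] <- list(gini_now, constrained, size[ra], size[rb],
                           min_size, edges$weight[pick])
    parent[rb] <- ra
    size[ra] <- size[ra] + size[rb]
  }

  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  structure(
    list(labels = labels, sizes = as.integer(tabulate(labels)),
         merges = merges),
    class = "cluster_assignment"
  )
}

#' Cluster features with k-means in sample space
#'
#' Features are treated as points in sample space (each feature's
#' standardized values form its coordinates) and clustered with Lloyd's
#' algorithm from a k-means++ style initialization. Used as the fallback
#' when the Gini-constrained split of an oversized cluster degenerates into
#' tiny parts, because k-means tends to produce evenly sized parts.
#'
#' @param data Feature matrix or data frame.
#' @param k Number of clusters, `1 <= k <= n_features`.
#' @param seed Integer seed for the initialization.
#'
#' @return A `cluster_assignment` (labels numbered by first occurrence; all
#'   clusters nonempty).
#' @export
kmeans_features <- function(data, k, seed = 42L) {
  x <- as_feature_matrix(data)
  p <- ncol(x)
  if (k < 1 || k > p) stop("`k` must be between 1 and n_features",
                           call. = FALSE)
  if (k == 1) {
    labels <- rep(1L, p)
  } else if (k == p) {
    labels <- seq_len(p)
  } else {
    pts <- t(standardize_columns(x))
    labels <- NULL
    for (attempt in 0:9) {
      labels <- tryCatch({
        centers <- with_seed(seed + attempt * 1009L, kmeanspp_init(pts, k))
        fit <- suppressWarnings(
          stats::kmeans(pts, centers = centers, iter.max = 300,
                        algorithm = "Lloyd")
        )
        as.integer(fit$cluster)
      }, error = function(e) NULL)
      if (!is.null(labels)) break
    }
    if (is.null(labels)) {
      stop("k-means failed to produce ", k, " nonempty clusters",
           call. = FALSE)
    }
  }
  labels <- match(labels, unique(labels))
  structure(
    list(labels = labels, sizes = as.integer(tabulate(labels)),
         merges = NULL),
    class = "cluster_assignment"
  )
}

# k-means++ seeding: first center uniform, then each next center sampled
# with probability proportional to squared distance from the nearest chosen
# center. Falls back to uniform sampling among distinct remaining points if
# all residual distances are zero.
kmeanspp_init <- function(pts, k) {
  n <- nrow(pts)
  chosen <- integer(k)
  chosen[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(pts, 2, pts[chosen[1], ], "-")^2)
  for (i in seq_len(k - 1)) {
    if (sum(d2) > 0) {
      idx <- sample.int(n, 1, prob = d2 / sum(d2))
    } else {
      idx <- sample(setdiff(seq_len(n), chosen[seq_len(i)]), 1)
    }
    chosen[i + 1] <- idx
    d2 <- pmin(d2, rowSums(sweep(pts, 2, pts[idx, ], "-")^2))
  }
  pts[chosen, , drop = FALSE]
}

#' Form a size-bounded super-partition of the feature set
#'
#' Splits `N` features into at least `ceiling(N / c)` clusters, none larger
#' than `c` (the configured maximum cluster size), so the reduction engine
#' can run independently within each cluster. The first cut uses
#' Gini-constrained single-linkage clustering at `k = ceiling(N / c)` on
#' the configured feature distance. Any cluster still larger than `c` is
#' re-split at `k = ceiling(N_k / c)`; if that split yields a part of size
#' `small_split_limit` or smaller (highly correlated features resist
#' balanced linkage cuts), the split is rejected and k-means with the same
#' number of centroids is used instead. Every split decision is recorded in
#' the trace.
#'
#' @param data Feature matrix or data frame.
#' @param config A [reduction_config()].
#'
#' @return A `cluster_assignment` with `labels`, `sizes` (all `<= c`) and
#'   `trace`, a data frame with one row per split decision (`method`,
#'   `input_size`, `output_sizes`, `accepted`, `smallest_part`, `k`).
#' @export
form_superpartition <- function(data, config = reduction_config()) {
  config <- as_reduction_config(config)
  x <- as_feature_matrix(data)
  N <- ncol(x)
  cmax <- config$max_cluster_size

  trace0 <- data.frame(
    method = character(0), input_size = integer(0),
    output_sizes = character(0), accepted = logical(0),
    smallest_part = integer(0), k = integer(0)
  )
  if (N <= cmax) {
    return(structure(
      list(labels = rep(1L, N), sizes = N, trace = trace0),
      class = "cluster_assignment"
    ))
  }

  D <- correlation_distance(x, config$distance)
  k0 <- ceiling(N / cmax)
  first <- genie_cluster(D, k0, config$gini_threshold)
  labels <- first$labels
  trace <- rbind(trace0, data.frame(
    method = "genie", input_size = N,
    output_sizes = paste(sort(first$sizes, decreasing = TRUE),
                         collapse = ","),
    accepted = TRUE, smallest_part = min(first$sizes), k = k0
  ))

  round <- 0L
  repeat {
    sizes <- tabulate(labels)
    big <- which(sizes > cmax)
    if (length(big) == 0) break
    round <- round + 1L
    if (round > N) stop("super-partition failed to terminate", call. = FALSE)

    id <- big[1]
    idx <- which(labels == id)
    nk <- length(idx)
    kk <- ceiling(nk / cmax)
    sub <- genie_cluster(D[idx, idx, drop = FALSE], kk,
                         config$gini_threshold)
    smallest <- min(sub$sizes)
    if (smallest <= config$small_split_limit) {
      trace <- rbind(trace, data.frame(
        method = "genie", input_size = nk,
        output_sizes = paste(sort(sub$sizes, decreasing = TRUE),
                             collapse = ","),
        accepted = FALSE, smallest_part = smallest, k = kk
      ))
      sub <- kmeans_features(x[, idx, drop = FALSE], kk,
                             seed = config$seed + round * 1013L)
      method <- "kmeans"
    } else {
      method <- "genie"
    }
    trace <- rbind(trace, data.frame(
      method = method, input_size = nk,
      output_sizes = paste(sort(sub$sizes, decreasing = TRUE),
                           collapse = ","),
      accepted = TRUE, smallest_part = min(sub$sizes), k = kk
    ))
    new_base <- max(labels)
    labels[idx] <- ifelse(sub$labels == 1L, id, new_base + sub$labels - 1L)
  }

  labels <- match(labels, unique(labels))
  structure(
    list(labels = labels, sizes = as.integer(tabulate(labels)),
         trace = trace),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Cluster assignment: %d items in %d clusters\n",
              length(x$labels), length(x$sizes)))
  cat("  sizes:", paste(sort(x$sizes, decreasing = TRUE), collapse = ", "),
      "\n")
  if (!is.null(x$trace) && nrow(x$trace) > 0) {
    cat(sprintf("  %d split decisions (%d k-means fallbacks)\n",
                nrow(x$trace), sum(x$trace$method == "kmeans")))
  }
  invisible(x)
}
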