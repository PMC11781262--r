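#' Greedy information-loss-constrained feature reduction
#'
#' The Partition engine. Every feature starts as its own variable; at each
#' step the closest pair of current variables (by the configured distance
#' between their vectors) is tentatively merged: the union of their member
#' features is collapsed with the configured reducer and scored with the
#' configured metric against the *original* member columns. The merge is kept
#' only if the score reaches `ilc_threshold`; otherwise the pair is marked
#' rejected and the next-closest pair is tried. Rejection memory for a
#' variable is cleared whenever that variable changes. The algorithm stops
#' when every remaining pair has been rejected, so by construction every
#' multi-member output retains at least the requested information.
#'
#' The mapping is surjective: each original feature belongs to exactly one
#' output feature.
#'
#' @param data Feature matrix (samples x features) or data frame with unique
#'   column names; all columns nonconstant.
#' @param config A [reduction_config()].
#'
#' @return An object of class `partition_result`: a list with
#'   * `reduced_data` — tibble of reduced features (one column per output);
#'   * `mapping` — tibble with `name`, `members` (list-column of original
#'     feature names), `n_members`, `information`;
#'   * `config` — the configuration used.
#' @export
#'
#' @examples
#' set.seed(1)
#' sim <- generate_block_data(n_samples = 100, block_sizes = c(3, 3),
#'                            rho = 0.9, seed = 1)
#' res <- partition(sim$data, reduction_config(ilc_threshold = 0.5))
#' res$mapping
partition <- function(data, config = reduction_config()) {
  config <- as_reduction_config(config)
  x <- as_feature_matrix(data)
  z <- standardize_columns(x)  # also rejects constant columns up front
  N <- ncol(x)
  feature_names <- colnames(x)
  reducer <- get_reducer(config$reducer)

  members <- lapply(seq_len(N), identity)  # original column indices
  vectors <- z                             # current variable vectors
  info <- rep(1, N)
  reps <- feature_names                    # lexicographic tie-break keys

  if (N >= 2) {
    D <- vector_distance(vectors, config$distance)
    rejected <- matrix(FALSE, N, N)

    repeat {
      m <- length(members)
      if (m == 1) break
      ut <- which(upper.tri(D), arr.ind = TRUE)
      open <- !rejected[ut]
      if (!any(open)) break
      ut <- ut[open, , drop = FALSE]
      dvals <- D[ut]
      r1 <- pmin(reps[ut[, 1]], reps[ut[, 2]])
      r2 <- pmax(reps[ut[, 1]], reps[ut[, 2]])
      ord <- order(dvals, r1, r2)

      accepted <- FALSE
      for (t in ord) {
        i <- ut[t, 1]
        j <- ut[t, 2]
        mem <- sort(c(members[[i]], members[[j]]))
        cand <- try_reduce(x[, mem, drop = FALSE], reducer, config$metric)
        if (cand$information >= config$ilc_threshold) {
          # accept: variable i absorbs j, rejection memory involving either
          # is void because both variables ceased to exist
          members[[i]] <- mem
          members[[j]] <- NULL
          vectors[, i] <- cand$vector
          vectors <- vectors[, -j, drop = FALSE]
          info[i] <- cand$information
          info <- info[-j]
          reps[i] <- min(reps[i], reps[j])
          reps <- reps[-j]
          rejected[i, ] <- FALSE
          rejected[, i] <- FALSE
          rejected <- rejected[-j, -j, drop = FALSE]
          D <- D[-j, -j, drop = FALSE]
          newd <- vector_distance_to(vectors, vectors[, i], config$distance)
          D[i, ] <- newd
          D[, i] <- newd
          D[i, i] <- 0
          accepted <- TRUE
          break
        }
        rejected[i, j] <- TRUE
        rejected[j, i] <- TRUE
      }
      if (!accepted) break
    }
  }

  build_partition_result(x, members, vectors, info, config)
}

# Tentative merge: reduce + score, treating a degenerate (constant) reduced
# vector as an automatic rejection rather than an error.
try_reduce <- function(cols, reducer, metric) {
  out <- tryCatch({
    vec <- reducer(cols)
    if (diff(range(vec)) == 0) {
      list(vector = vec, information = -Inf)
    } else {
      list(vector = vec, information = score_information(cols, vec, metric))
    }
  }, error = function(e) {
    if (grepl("constant feature", conditionMessage(e))) {
      list(vector = NULL, information = -Inf)
    } else {
      stop(e)
    }
  })
  out
}

# Distances between the columns of a plain matrix of current vectors.
vector_distance <- function(v, method) {
  r <- stats::cor(v)
  r[r > 1] <- 1
  r[r < -1] <- -1
  d <- if (method == "one_minus_abs_r") 1 - abs(r) else 1 - r
  diag(d) <- 0
  d
}

vector_distance_to <- function(v, vec, method) {
  r <- drop(stats::cor(v, vec))
  r[r > 1] <- 1
  r[r < -1] <- -1
  if (method == "one_minus_abs_r") 1 - abs(r) else 1 - r
}

# Assemble a partition_result; outputs ordered by smallest original member
# index, multi-member outputs named reduced_var_<i> in that order.
build_partition_result <- function(x, members, vectors, info, config) {
  feature_names <- colnames(x)
  first_idx <- vapply(members, min, integer(1))
  ord <- order(first_idx)
  members <- members[ord]
  vectors <- vectors[, ord, drop = FALSE]
  info <- info[ord]

  n_mem <- lengths(members)
  names_out <- character(length(members))
  names_out[n_mem == 1] <- feature_names[unlist(members[n_mem == 1])]
  names_out[n_mem > 1] <- paste0("reduced_var_", seq_len(sum(n_mem > 1)))

  colnames(vectors) <- names_out
  structure(
    list(
      reduced_data = tibble::as_tibble(as.data.frame(vectors,
                                                     check.names = FALSE)),
      mapping = tibble::tibble(
        name = names_out,
        members = lapply(members, function(i) feature_names[i]),
        n_members = as.integer(n_mem),
        information = info
      ),
      config = config
    ),
    class = "partition_result"
  )
}

#' Reduce one named feature set to a single feature
#'
#' A single merge step: applies the configured reducer to the named member
#' columns and scores the result with the configured metric against those
#' columns.
#'
#' @param members Character vector of feature names, all present in `data`.
#' @param data Feature matrix or data frame.
#' @param config A [reduction_config()].
#' @param name Output feature name; defaults to the member name for a
#'   singleton and `"reduced_var_1"` otherwise.
#'
#' @return A list with `name`, `members`, `vector` and `information`.
#' @export
reduce_cluster <- function(members, data, config = reduction_config(),
                           name = NULL) {
  config <- as_reduction_config(config)
  x <- as_feature_matrix(data)
  if (length(members) == 0) stop("`members` must be nonempty", call. = FALSE)
  missing <- setdiff(members, colnames(x))
  if (length(missing) > 0) {
    stop("unknown member name: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cols <- x[, members, drop = FALSE]
  vec <- get_reducer(config$reducer)(cols)
  information <- if (length(members) == 1) {
    1
  } else {
    score_information(cols, vec, config$metric)
  }
  if (is.null(name)) {
    name <- if (length(members) == 1) members else "reduced_var_1"
  }
  list(name = name, members = members, vector = vec,
       information = information)
}

#' @export
print.partition_result <- function(x, ...) {
  n_in <- sum(x$mapping$n_members)
  n_out <- nrow(x$mapping)
  multi <- x$mapping$n_members > 1
  cat(sprintf("Partition result: %d features -> %d (%.2f%% reduction)\n",
              n_in, n_out, 100 * (1 - n_out / n_in)))
  if (any(multi)) {
    cat(sprintf("  %d reduced variables; minimum information captured: %.4f\n",
                sum(multi), min(x$mapping$information[multi])))
  } else {
    cat("  no features were merged\n")
  }
  cat(sprintf("  ILC threshold %.3g, metric %s, reducer %s\n",
              x$config$ilc_threshold, x$config$metric, x$config$reducer))
  invisible(x)
}
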