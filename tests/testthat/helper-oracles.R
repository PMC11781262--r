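# Independent oracles used to check the package implementations. These
# deliberately take different computational routes than the package code.

# ICC(1,1) via a one-way fixed-effects fit (lm/anova mean squares), long
# format, standardized columns.
icc_oracle <- function(x) {
  z <- scale(x)
  long <- data.frame(
    y = as.vector(z),
    subject = factor(rep(seq_len(nrow(z)), ncol(z)))
  )
  ms <- stats::anova(stats::lm(y ~ subject, data = long))[["Mean Sq"]]
  msb <- ms[1]
  msw <- ms[2]
  k <- ncol(z)
  (msb - msw) / (msb + (k - 1) * msw)
}

# Pearson correlation from raw sums (hand formula).
pearson_oracle <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# Gini index by the pairwise-difference definition (double loop).
gini_pairwise <- function(sizes) {
  k <- length(sizes)
  if (k == 1) return(0)
  tot <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) tot <- tot + abs(sizes[i] - sizes[j])
  }
  tot / ((k - 1) * sum(sizes))
}

# All set partitions of n items as integer label vectors (restricted growth
# strings); length is the Bell number (203 for n = 6).
enumerate_set_partitions <- function(n) {
  parts <- list(1L)
  for (item in seq_len(n - 1)) {
    nxt <- list()
    for (p in parts) {
      for (lab in seq_len(max(p) + 1L)) {
        nxt[[length(nxt) + 1L]] <- c(p, lab)
      }
    }
    parts <- nxt
  }
  parts
}

# Do two label vectors induce the same grouping (up to relabeling)?
same_grouping <- function(a, b) {
  isTRUE(all(outer(a, a, "==") == outer(b, b, "==")))
}

# Canonical form of a result's member sets: sorted within, ordered by first
# member, for exact cross-result comparison.
mapping_sets <- function(res) {
  s <- lapply(res$mapping$members, sort)
  s[order(vapply(s, `[`, character(1), 1))]
}

# Every multi-member output must reach the configured information floor.
min_multi_information <- function(res) {
  multi <- res$mapping$n_members > 1
  if (!any(multi)) return(1)
  min(res$mapping$information[multi])
}

# Surjectivity: member sets disjoint and exhaustive over the input names.
is_surjective <- function(res, feature_names) {
  members <- unlist(res$mapping$members)
  !anyDuplicated(members) && setequal(members, feature_names) &&
    length(members) == length(feature_names)
}

# Random block layout for property tests; returns generate_block_data args.
random_block_layout <- function(seed, max_features = 14) {
  set.seed(seed)
  n_blocks <- sample(2:4, 1)
  sizes <- sample(1:4, n_blocks, replace = TRUE)
  while (sum(sizes) > max_features) sizes <- sizes[-1]
  if (length(sizes) == 0) sizes <- 2
  list(block_sizes = sizes, rho = runif(1, 0.4, 0.95))
}

# Adversarial 300+5 fixture: a hub feature with 299 leaves correlated only
# through it (the minimum spanning tree is a star, so constrained linkage
# grows one giant cluster), plus a 5-feature satellite group. Engineered so
# the iterative re-split of the oversized cluster degenerates into a tiny
# part and triggers the k-means fallback.
make_fallback_fixture <- function(n = 40, seed = 99) {
  set.seed(seed)
  center <- rnorm(n)
  leaves <- 0.8 * scale(center)[, 1] +
    matrix(rnorm(n * 299, sd = sqrt(1 - 0.8^2)), n, 299)
  sat_base <- rnorm(n)
  sats <- 0.85 * scale(sat_base)[, 1] +
    matrix(rnorm(n * 5, sd = sqrt(1 - 0.85^2)), n, 5)
  x <- cbind(center, leaves, sats)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}
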