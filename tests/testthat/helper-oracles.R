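# Independent oracles used across the suite. These re-derive quantities by
# brute force (exhaustive enumeration, closed forms, direct definitions) and
# must stay independent of the package implementation they check.

# Modularity of a partition, straight from the definition
# Q = sum_c (e_c / m - (d_c / 2m)^2).
modularity_of_partition <- function(edges, n_nodes, membership) {
  m <- nrow(edges)
  q <- 0
  for (comm in unique(membership)) {
    nodes <- which(membership == comm)
    within <- sum(edges[, 1] %in% nodes & edges[, 2] %in% nodes)
    deg <- sum(edges[, 1] %in% nodes) + sum(edges[, 2] %in% nodes)
    q <- q + within / m - (deg / (2 * m))^2
  }
  q
}

# Best modularity over every partition of <= 8 nodes (restricted growth
# strings enumerate set partitions).
exhaustive_modularity <- function(edges, n_nodes) {
  stopifnot(n_nodes <= 8)
  best <- -Inf
  assignment <- integer(n_nodes)
  recurse <- function(i, k) {
    if (i > n_nodes) {
      best <<- max(best, modularity_of_partition(edges, n_nodes,
                                                 assignment))
      return(invisible())
    }
    for (c in seq_len(k + 1)) {
      assignment[i] <<- c
      recurse(i + 1, max(k, c))
    }
  }
  recurse(1, 0)
  best
}

# Benjamini-Hochberg step-up from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

# LMG shares by explicit enumeration of all p! orderings.
lmg_oracle <- function(data, response, predictors) {
  r2 <- function(preds) {
    if (!length(preds)) return(0)
    summary(stats::lm(stats::reformulate(preds, response), data))$r.squared
  }
  p <- length(predictors)
  perms <- combinat_permutations(seq_len(p))
  shares <- numeric(p)
  for (ord in perms) {
    prev <- character()
    for (j in ord) {
      gain <- r2(c(prev, predictors[j])) - r2(prev)
      shares[j] <- shares[j] + gain
      prev <- c(prev, predictors[j])
    }
  }
  shares / length(perms)
}

combinat_permutations <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_permutations(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# Great-circle distance by the spherical law of cosines (not haversine).
law_of_cosines_m <- function(lat1, lon1, lat2, lon2, r = 6371000) {
  to_rad <- pi / 180
  r * acos(pmin(1, pmax(-1,
    sin(lat1 * to_rad) * sin(lat2 * to_rad) +
      cos(lat1 * to_rad) * cos(lat2 * to_rad) * cos((lon2 - lon1) * to_rad))))
}

# Build a cooccurrence_network directly from an edge list for topology tests.
toy_network <- function(n_nodes, edge_pairs, ses = NULL, id = "toy") {
  taxa <- sprintf("t%02d", seq_len(n_nodes))
  mat <- matrix(1L, 2, n_nodes, dimnames = list(c("s1", "s2"), taxa))
  edges <- tibble::tibble(
    taxon_a = taxa[vapply(edge_pairs, function(p) as.integer(p[1]), integer(1))],
    taxon_b = taxa[vapply(edge_pairs, function(p) as.integer(p[2]), integer(1))],
    ses = ses %||% rep(1, length(edge_pairs)),
    p = 1e-9, q = 1e-9, retained = TRUE
  )
  if (!length(edge_pairs)) {
    edges <- edges[0, ]
  }
  build_network(mat, edges, id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small landscape-free sample table for io/stratification tests.
make_samples <- function(n = 20, watersheds = c("W1", "W2"), seed = 1,
                         taxa_pool = paste0("g", 1:12)) {
  withr::with_seed(seed, tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    site_id = sprintf("x%03d", seq_len(n)),
    watershed_id = rep(watersheds, length.out = n),
    latitude = runif(n, 33, 41),
    longitude = runif(n, -123, -115),
    altitude_m = runif(n, 0, 2000),
    landuse_pct = runif(n, 0, 100),
    csci = runif(n, 0.3, 1.2),
    taxa = lapply(seq_len(n), function(i) {
      sort(sample(taxa_pool, sample(2:6, 1)))
    })
  ))
}
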