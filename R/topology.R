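# Topology measures of co-occurrence networks.
#
# Five measures per network: size N (genera present, isolated nodes
# included), connectance C = 2E / (N(N-1)), mean co-occurrence strength S
# (mean SES over edges), modularity M (greedy agglomerative maximization on
# the unweighted graph) and degree heterogeneity zeta = <k^2>/<k>^2.
# Networks without edges get missing S, M and zeta and are excluded from
# model fitting.

#' Connectance
#'
#' Fraction of realized undirected edges, `2E / (N(N-1))`; isolated nodes
#' count in N. Undefined (NA) for N < 2.
#'
#' @param network a `cooccurrence_network`.
#' @return numeric in `[0, 1]`, or `NA` if N < 2.
#' @export
connectance <- function(network) {
  n <- igraph::vcount(network$graph)
  if (n < 2) return(NA_real_)
  2 * igraph::ecount(network$graph) / (n * (n - 1))
}

#' Mean co-occurrence strength
#'
#' Arithmetic mean of the SES edge weights; `NA` when the network has no
#' edges.
#'
#' @param network a `cooccurrence_network`.
#' @return numeric, or `NA` for an edgeless network.
#' @export
mean_strength <- function(network) {
  if (igraph::ecount(network$graph) == 0) return(NA_real_)
  mean(igraph::E(network$graph)$ses)
}

#' Greedy modularity
#'
#' Greedy agglomerative modularity maximization (fast-greedy merging of
#' communities) on the unweighted graph; isolated nodes sit in singleton
#' communities and contribute nothing. Returns the best modularity found
#' and its partition.
#'
#' @param network a `cooccurrence_network`.
#' @return list with `modularity` (NA for an edgeless network) and
#'   `membership` (integer community labels).
#' @export
modularity_greedy <- function(network) {
  g <- network$graph
  if (igraph::ecount(g) == 0) {
    return(list(modularity = NA_real_,
                membership = seq_len(igraph::vcount(g))))
  }
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  membership <- as.integer(igraph::membership(cl))
  q <- igraph::modularity(g, membership)
  # the greedy cut can miss trivial partitions (e.g. one community for a
  # complete graph); never return less than those
  q_single <- igraph::modularity(g, rep(1L, igraph::vcount(g)))
  if (q_single > q) {
    q <- q_single
    membership <- rep(1L, igraph::vcount(g))
  }
  list(modularity = q, membership = membership)
}

#' Degree heterogeneity
#'
#' `zeta = mean(k^2) / mean(k)^2` over all nodes (isolated nodes included
#' with degree 0). Equal to 1 for regular graphs and >= 1 always
#' (Cauchy-Schwarz); `NA` for an edgeless network.
#'
#' @param network a `cooccurrence_network`.
#' @return numeric >= 1, or `NA` for an edgeless network.
#' @export
degree_heterogeneity <- function(network) {
  if (igraph::ecount(network$graph) == 0) return(NA_real_)
  k <- igraph::degree(network$graph)
  mean(k^2) / mean(k)^2
}

#' Summarize one network's topology
#'
#' @param network a `cooccurrence_network`.
#' @return one-row tibble: `group_id`, `n_taxa`, `n_edges`, `connectance`,
#'   `mean_strength`, `modularity`, `degree_heterogeneity`.
#' @export
summarize_topology <- function(network) {
  zeta <- degree_heterogeneity(network)
  if (!is.na(zeta) && zeta < 1 - 1e-9) {
    stop("degree heterogeneity below 1; degree bookkeeping is corrupt")
  }
  tibble::tibble(
    group_id = network$group_id,
    n_taxa = igraph::vcount(network$graph),
    n_edges = igraph::ecount(network$graph),
    connectance = connectance(network),
    mean_strength = mean_strength(network),
    modularity = modularity_greedy(network)$modularity,
    degree_heterogeneity = zeta
  )
}

#' Paired observed-vs-null topology comparison
#'
#' Wilcoxon signed-rank test on paired observed and null-counterpart values
#' of a topology measure. Zero differences are dropped; the exact signed-rank
#' distribution is used for up to 25 informative pairs and the normal
#' approximation above that. Pairs where either value is missing are
#' removed first.
#'
#' @param observed,null paired numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return tibble with `n_pairs` (informative pairs), `statistic` (V) and
#'   `p_value`. If every difference is zero, `p_value` is 1 with a warning.
#' @export
null_topology_comparison <- function(observed, null,
                                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(observed) == length(null))
  ok <- stats::complete.cases(observed, null)
  d <- observed[ok] - null[ok]
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero")
    return(tibble::tibble(n_pairs = 0L, statistic = NA_real_, p_value = 1))
  }
  ht <- suppressWarnings(stats::wilcox.test(
    d, alternative = alternative, exact = length(d) <= 25, correct = TRUE
  ))
  tibble::tibble(n_pairs = length(d),
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value)
}
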