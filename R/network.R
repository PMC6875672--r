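# Null-model co-occurrence networks.
#
# For each sample group: build the presence/absence site x genus matrix,
# generate R randomized communities preserving each site's richness, score
# every genus pair as a standardized effect size (SES) against the null
# ensemble, and keep positive associations passing both the per-pair
# significance and the Benjamini-Hochberg false-discovery threshold.

#' Build a presence/absence matrix for a sample group
#'
#' @param members sample tibble rows of the group's members (>= 2 rows,
#'   each with a non-empty `taxa` list entry).
#' @return binary matrix, sites (sample ids) x genera; columns restricted to
#'   genera present in at least one member and ordered lexicographically.
#' @export
build_presence_matrix <- function(members) {
  stopifnot(nrow(members) >= 2, all(lengths(members$taxa) >= 1))
  genera <- sort(unique(unlist(members$taxa)))
  mat <- matrix(0L, nrow(members), length(genera),
                dimnames = list(members$sample_id, genera))
  for (i in seq_len(nrow(members))) {
    mat[i, match(members$taxa[[i]], genera)] <- 1L
  }
  mat
}

#' Generate richness-preserving null communities
#'
#' Each replicate redraws every site independently: the site receives
#' exactly its observed number of genera, sampled uniformly without
#' replacement from the group's genus pool (the matrix columns). Per-site
#' richness is therefore preserved exactly while column (genus) totals are
#' free.
#'
#' @param mat presence matrix from [build_presence_matrix()].
#' @param n_null number of replicates R (default 100).
#' @param seed integer seed for the ensemble's RNG substream.
#' @return list of `n_null` binary matrices with the same dimnames as `mat`.
#' @export
generate_null_ensemble <- function(mat, n_null = 100, seed = 1L) {
  stopifnot(n_null >= 2)
  n_taxa <- ncol(mat)
  row_sums <- rowSums(mat)
  stopifnot(all(row_sums <= n_taxa))
  with_seed(seed, {
    lapply(seq_len(n_null), function(r) {
      null <- matrix(0L, nrow(mat), n_taxa, dimnames = dimnames(mat))
      for (i in seq_len(nrow(mat))) {
        null[i, sample.int(n_taxa, row_sums[i])] <- 1L
      }
      stopifnot(identical(rowSums(null), row_sums))
      null
    })
  })
}

#' Pairwise co-occurrence statistic
#'
#' The default statistic is the joint-occurrence count: for genera i and j,
#' the number of sites where both occur. The `pearson` alternative is the
#' Pearson correlation of the two binary occurrence columns; pairs where
#' either column is constant are undefined (`NA`) and never become edge
#' candidates.
#'
#' @param mat binary site x genus matrix.
#' @param method `"joint_count"` (default) or `"pearson"`.
#' @return symmetric genus x genus matrix of the statistic.
#' @export
pairwise_statistic <- function(mat, method = c("joint_count", "pearson")) {
  method <- match.arg(method)
  stopifnot(nrow(mat) >= 2, ncol(mat) >= 2)
  if (method == "joint_count") {
    crossprod(mat)
  } else {
    suppressWarnings(stats::cor(mat))
  }
}

#' Standardized effect sizes and edge retention
#'
#' For each genus pair the SES is `(obs - null_mean) / null_sd`, with the
#' null mean and SD taken across the ensemble replicates. One-sided upper
#' tail p-values come from the standard normal approximation to the SES
#' (with only R ~ 100 replicates an empirical rank can never resolve the
#' 1e-4 threshold); q-values are Benjamini-Hochberg across the candidate
#' pairs of this network. Retained edges have `ses > 0`, `p < alpha` and
#' `q < alpha`. Pairs whose null SD is zero cannot be standardized and are
#' excluded (counted in the `n_zero_sd` attribute).
#'
#' @param obs_stats observed statistic matrix from [pairwise_statistic()].
#' @param null_stats list of statistic matrices, one per null replicate.
#' @param alpha significance and FDR threshold (default 1e-4).
#' @return tibble of all candidate pairs (`taxon_a`, `taxon_b`, `obs_stat`,
#'   `null_mean`, `null_sd`, `ses`, `p`, `q`, `retained`), taxon_a < taxon_b.
#' @export
ses_edge_stats <- function(obs_stats, null_stats, alpha = 1e-4) {
  stopifnot(alpha > 0, alpha < 1, length(null_stats) >= 2)
  taxa <- colnames(obs_stats)
  iu <- which(upper.tri(obs_stats))
  nr <- length(null_stats)
  sums <- 0; sqs <- 0; cnt <- 0
  for (s in null_stats) {
    v <- s[iu]
    ok <- is.finite(v)
    v[!ok] <- 0
    sums <- sums + v
    sqs <- sqs + v * v
    cnt <- cnt + ok
  }
  null_mean <- ifelse(cnt > 0, sums / cnt, NA_real_)
  null_var <- ifelse(cnt > 1, pmax(0, (sqs - cnt * null_mean^2) / (cnt - 1)),
                     NA_real_)
  null_sd <- sqrt(null_var)
  obs <- obs_stats[iu]
  pair_idx <- arrayInd(iu, dim(obs_stats))
  candidate <- is.finite(obs) & is.finite(null_sd) & null_sd > 0 &
    cnt >= max(2, nr %/% 2)
  n_zero_sd <- sum(is.finite(obs) & !is.na(null_sd) & null_sd == 0)

  ses <- (obs - null_mean) / null_sd
  out <- tibble::tibble(
    taxon_a = taxa[pair_idx[, 1]],
    taxon_b = taxa[pair_idx[, 2]],
    obs_stat = obs,
    null_mean = null_mean,
    null_sd = null_sd,
    ses = ifelse(candidate, ses, NA_real_)
  )[candidate, ]
  out$p <- stats::pnorm(out$ses, lower.tail = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$retained <- out$ses > 0 & out$p < alpha & out$q < alpha
  attr(out, "n_zero_sd") <- n_zero_sd
  out
}

#' Assemble a co-occurrence network
#'
#' Nodes are all genera of the presence matrix (isolated genera are kept:
#' network size counts genera present, not connected ones); edges are the
#' retained pairs, weighted by SES.
#'
#' @param mat presence matrix (defines the node set).
#' @param edges edge-stats tibble from [ses_edge_stats()] (only rows with
#'   `retained = TRUE` become edges).
#' @param group_id optional provenance label.
#' @return object of class `cooccurrence_network`: a list with `graph`
#'   (igraph, edge attribute `ses`), `edges` (tibble) and `group_id`.
#' @export
build_network <- function(mat, edges, group_id = NA_character_) {
  kept <- edges[edges$retained %||% rep(TRUE, nrow(edges)), , drop = FALSE]
  stopifnot(all(kept$taxon_a %in% colnames(mat)),
            all(kept$taxon_b %in% colnames(mat)),
            all(kept$taxon_a != kept$taxon_b))
  key <- paste(pmin(kept$taxon_a, kept$taxon_b),
               pmax(kept$taxon_a, kept$taxon_b))
  if (anyDuplicated(key)) stop("duplicate edges for a taxon pair")
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = kept$taxon_a, to = kept$taxon_b, ses = kept$ses),
    directed = FALSE,
    vertices = data.frame(name = colnames(mat))
  )
  structure(list(graph = g, edges = kept, group_id = group_id),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("<cooccurrence_network> %s: %d genera, %d edges\n",
              x$group_id, igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Build the observed network and its null counterpart for one group
#'
#' Runs the whole per-group procedure: presence matrix, null ensemble,
#' SES scoring, edge filtering and network assembly. The null counterpart
#' is the network obtained by treating the first null replicate as if it
#' were the observed community and scoring it against the same ensemble
#' with the same filter; under a correct null it retains edges only at the
#' false-discovery rate.
#'
#' @param members sample tibble rows of the group's members.
#' @param group_id provenance label.
#' @param n_null ensemble size R.
#' @param alpha edge threshold.
#' @param method statistic passed to [pairwise_statistic()].
#' @param seed seed for this group's ensemble substream.
#' @return list with `network`, `null_network`, `edge_stats` and `matrix`.
#' @export
group_network <- function(members, group_id = NA_character_, n_null = 100,
                          alpha = 1e-4, method = "joint_count", seed = 1L) {
  mat <- build_presence_matrix(members)
  if (ncol(mat) < 2) {
    empty <- tibble::tibble(taxon_a = character(), taxon_b = character(),
                            obs_stat = numeric(), null_mean = numeric(),
                            null_sd = numeric(), ses = numeric(),
                            p = numeric(), q = numeric(), retained = logical())
    net <- build_network(mat, empty, group_id)
    return(list(network = net, null_network = net, edge_stats = empty,
                matrix = mat))
  }
  ensemble <- generate_null_ensemble(mat, n_null = n_null, seed = seed)
  null_stats <- lapply(ensemble, pairwise_statistic, method = method)
  edge_stats <- ses_edge_stats(pairwise_statistic(mat, method = method),
                               null_stats, alpha = alpha)
  null_edge_stats <- ses_edge_stats(null_stats[[1]], null_stats, alpha = alpha)
  list(
    network = build_network(mat, edge_stats, group_id),
    null_network = build_network(mat, null_edge_stats,
                                 paste0(group_id, ".null")),
    edge_stats = edge_stats,
    matrix = mat
  )
}

#' Export a network as GraphML and an edge-list CSV
#'
#' @param network a `cooccurrence_network`.
#' @param graphml,edge_csv output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
export_network <- function(network, graphml = NULL, edge_csv = NULL) {
  if (!is.null(graphml)) {
    g <- network$graph
    edges_df <- network$edges
    igraph::E(g)$p <- edges_df$p
    igraph::E(g)$q <- edges_df$q
    igraph::V(g)$genus <- igraph::V(g)$name
    igraph::write_graph(g, graphml, format = "graphml")
  }
  if (!is.null(edge_csv)) {
    readr::write_csv(network$edges, edge_csv)
  }
  invisible(c(graphml = graphml, edge_csv = edge_csv))
}
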