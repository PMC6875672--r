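# End-to-end pipeline: read/simulate -> filter -> stratify -> subsample ->
# networks -> topology -> index model.

#' Pipeline configuration
#'
#' @param min_samples_per_watershed watershed inclusion threshold (default 15).
#' @param group_size samples per group g (default 10).
#' @param n_repeats replicate group draws per stratification cell
#'   (default 100).
#' @param n_nulls null communities per group R (default 100).
#' @param alpha edge significance and FDR threshold (default 1e-4).
#' @param fdr_scope family for the Benjamini-Hochberg correction: `"run"`
#'   (default) pools the candidate pairs of all networks of the run into one
#'   family, so a single SES threshold applies everywhere; `"network"`
#'   adjusts within each network's own candidate pairs, which ties the
#'   threshold to network size.
#' @param n_quintiles strata per stratification variable (default 5).
#' @param statistic co-occurrence statistic, `"joint_count"` or `"pearson"`.
#' @param cv_folds,cv_repeats cross-validation setup (defaults 10, 100).
#' @param seed root RNG seed; every random stage derives its own substream.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_samples_per_watershed = 15,
                            group_size = 10,
                            n_repeats = 100,
                            n_nulls = 100,
                            alpha = 1e-4,
                            fdr_scope = c("run", "network"),
                            n_quintiles = 5,
                            statistic = "joint_count",
                            cv_folds = 10,
                            cv_repeats = 100,
                            seed = 1L) {
  cfg <- as.list(environment())
  cfg$fdr_scope <- match.arg(fdr_scope)
  stopifnot(
    cfg$min_samples_per_watershed >= 1, cfg$group_size >= 2,
    cfg$n_repeats >= 1, cfg$n_nulls >= 2,
    cfg$alpha > 0, cfg$alpha < 1, cfg$n_quintiles >= 2,
    cfg$statistic %in% c("joint_count", "pearson"),
    cfg$cv_folds >= 2, cfg$cv_repeats >= 1
  )
  structure(cfg, class = "pipeline_config")
}

#' Run the full bioassessment network pipeline
#'
#' Stages: (optionally simulate then) read and validate samples, filter
#' watersheds, assign global land-use and altitude quintiles, draw
#' stratified sample groups, build the observed and null co-occurrence
#' network per group, summarize topology, and fit the index models of mean
#' CSCI on topology (with and without network size). Fully reproducible
#' from (config, seed).
#'
#' @param config a [pipeline_config()].
#' @param samples,occurrences,taxa input tables or CSV paths (see
#'   [read_samples()] and [read_taxa()]); leave `samples` NULL to simulate
#'   data with `generator` instead.
#' @param generator a [generator_config()] used when no sample table is
#'   given (its seed is re-derived from the pipeline seed).
#' @param outdir optional output directory; when given, writes the group
#'   table, topology table, model report JSON, fitted-vs-observed CSV and
#'   the run manifest.
#' @return list of class `pipeline_result`: `samples`, `groups`,
#'   `topology` (one row per group, observed and null metrics joined with
#'   group covariates), `model_full`, `model_reduced` (without network
#'   size), `trends` (feeding-group proportion models, when a taxon table
#'   is available) and `manifest` (stage counts, config snapshot, seeds).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         samples = NULL, occurrences = NULL, taxa = NULL,
                         generator = generator_config(),
                         outdir = NULL) {
  manifest <- list(config = unclass(config), seed = config$seed,
                   started = format(Sys.time(), tz = "UTC"), stages = list())

  if (is.null(samples)) {
    generator$seed <- derive_seed(config$seed, "generator")
    dataset <- simulate_bmi_dataset(generator)
    samples <- dataset$samples
    occurrences <- dataset$occurrences
    taxa <- dataset$taxa
    manifest$stages$simulate <- list(n_samples = nrow(samples),
                                     generator = unclass(generator))
  }
  samples <- read_samples(samples, occurrences)
  if (!is.null(taxa)) taxa <- read_taxa(taxa)
  manifest$stages$read <- list(n_samples = nrow(samples),
                               n_watersheds = dplyr::n_distinct(samples$watershed_id))

  samples <- filter_watersheds(samples, config$min_samples_per_watershed)
  manifest$stages$filter <- list(
    n_samples = nrow(samples),
    n_watersheds = attr(samples, "n_watersheds_kept"))

  if (nrow(samples) == 0) {
    manifest$stages$groups <- list(n_groups = 0L)
    return(structure(list(samples = samples, groups = tibble::tibble(),
                          topology = tibble::tibble(), model_full = NULL,
                          model_reduced = NULL, trends = NULL,
                          manifest = manifest),
                     class = "pipeline_result"))
  }

  samples <- stratify_samples(samples, config$n_quintiles)
  groups <- subsample_groups(samples, group_size = config$group_size,
                             n_repeats = config$n_repeats,
                             seed = derive_seed(config$seed, "groups"))
  manifest$stages$groups <- list(
    n_groups = nrow(groups),
    n_cells_eligible = attr(groups, "n_cells_eligible"),
    n_cells_skipped = attr(groups, "n_cells_skipped"))

  topology <- pipeline_networks(samples, groups, config)
  manifest$stages$networks <- list(
    n_networks = nrow(topology),
    n_networks_no_edges = sum(topology$n_edges == 0))

  model_full <- model_reduced <- NULL
  modeling <- topology[stats::complete.cases(
    topology[c("mean_csci", "n_taxa", "connectance", "mean_strength",
               "modularity", "degree_heterogeneity")]), ]
  manifest$stages$model <- list(n_rows_modeled = nrow(modeling))
  if (nrow(modeling) >= 3 * config$cv_folds) {
    model_full <- fit_index_model(
      modeling, cv_folds = config$cv_folds, cv_repeats = config$cv_repeats,
      eliminate = TRUE, seed = derive_seed(config$seed, "cv-full"))
    model_reduced <- fit_index_model(
      modeling,
      predictors = c("connectance", "mean_strength", "modularity",
                     "degree_heterogeneity"),
      cv_folds = config$cv_folds, cv_repeats = config$cv_repeats,
      eliminate = FALSE, seed = derive_seed(config$seed, "cv-reduced"))
    manifest$stages$model$cv_r_squared_full <- model_full$cv_r_squared
    manifest$stages$model$cv_r_squared_reduced <- model_reduced$cv_r_squared
  }

  trends <- NULL
  if (!is.null(taxa)) {
    props <- ffg_proportions(samples, taxa)
    trends <- trend_models(props, samples)
  }

  manifest$finished <- format(Sys.time(), tz = "UTC")
  result <- structure(list(samples = samples, groups = groups,
                           topology = topology, model_full = model_full,
                           model_reduced = model_reduced, trends = trends,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_result(result, outdir)
  result
}

#' @noRd
pipeline_networks <- function(samples, groups, config) {
  sample_rows <- stats::setNames(seq_len(nrow(samples)), samples$sample_id)
  # pass 1: score every group; keep only sub-alpha candidates (the only
  # pairs that can survive either FDR scope) plus each family's size
  scored <- purrr::map(seq_len(nrow(groups)), function(i) {
    members <- samples[sample_rows[groups$member_sample_ids[[i]]], ]
    mat <- build_presence_matrix(members)
    if (ncol(mat) < 2) {
      return(list(nodes = colnames(mat), m = 0L,
                  cand = empty_edge_stats(), cand_null = empty_edge_stats()))
    }
    ensemble <- generate_null_ensemble(
      mat, n_null = config$n_nulls,
      seed = derive_seed(config$seed, "ensemble", groups$group_id[i]))
    null_stats <- lapply(ensemble, pairwise_statistic,
                         method = config$statistic)
    es <- ses_edge_stats(pairwise_statistic(mat, method = config$statistic),
                         null_stats, alpha = config$alpha)
    esn <- ses_edge_stats(null_stats[[1]], null_stats, alpha = config$alpha)
    list(nodes = colnames(mat), m = nrow(es),
         cand = es[es$p < config$alpha, ],
         cand_null = esn[esn$p < config$alpha, ])
  })

  if (config$fdr_scope == "run") {
    # one BH family over all observed candidate pairs of the run. The
    # step-up cutoff depends only on the sub-alpha p-values and the family
    # size, both retained from pass 1: any p above alpha has
    # p * m / rank > alpha and can neither be retained nor lower the
    # running step-up minimum below alpha.
    m_total <- sum(vapply(scored, function(s) as.numeric(s$m), numeric(1)))
    p_all <- sort(unlist(lapply(scored, function(s) s$cand$p)))
    q_all <- if (length(p_all)) {
      pmin(1, rev(cummin(rev(p_all * m_total / seq_along(p_all)))))
    } else numeric()
    k_max <- max(c(0L, which(q_all < config$alpha)))
    p_star <- if (k_max > 0) p_all[k_max] else -Inf
    refilter <- function(es) {
      idx <- findInterval(es$p, p_all)
      es$q <- ifelse(idx >= 1, q_all[pmax(idx, 1)],
                     pmin(1, es$p * m_total))
      es$retained <- es$ses > 0 & es$p < config$alpha & es$p <= p_star
      es
    }
    scored <- lapply(scored, function(s) {
      s$cand <- refilter(s$cand)
      s$cand_null <- refilter(s$cand_null)
      s
    })
  }

  rows <- purrr::map(seq_len(nrow(groups)), function(i) {
    s <- scored[[i]]
    mat_stub <- matrix(0L, 1, length(s$nodes),
                       dimnames = list("stub", s$nodes))
    net <- build_network(mat_stub, s$cand, groups$group_id[i])
    nul <- build_network(mat_stub, s$cand_null,
                         paste0(groups$group_id[i], ".null"))
    obs <- summarize_topology(net)
    nult <- summarize_topology(nul)
    names(nult) <- paste0("null_", names(nult))
    dplyr::bind_cols(obs, nult[-1])
  })
  topo <- dplyr::bind_rows(rows)
  dplyr::left_join(
    dplyr::select(groups, -"member_sample_ids"), topo, by = "group_id")
}

#' @noRd
empty_edge_stats <- function() {
  tibble::tibble(taxon_a = character(), taxon_b = character(),
                 obs_stat = numeric(), null_mean = numeric(),
                 null_sd = numeric(), ses = numeric(), p = numeric(),
                 q = numeric(), retained = logical())
}

#' @export
print.pipeline_result <- function(x, ...) {
  st <- x$manifest$stages
  cat("<pipeline_result>\n")
  cat(sprintf("  samples: %d in %d watersheds (after filter)\n",
              st$filter$n_samples, st$filter$n_watersheds))
  cat(sprintf("  groups: %d, networks: %d (%d without edges)\n",
              st$groups$n_groups %||% 0L, st$networks$n_networks %||% 0L,
              st$networks$n_networks_no_edges %||% 0L))
  if (!is.null(x$model_full)) {
    cat(sprintf("  index model: CV-R^2 = %.3f (full), %.3f (no size)\n",
                x$model_full$cv_r_squared, x$model_reduced$cv_r_squared))
  }
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' Writes the group table, topology table, model report (JSON), the
#' fitted-vs-observed scatter data (CSV) and the run manifest (JSON).
#'
#' @param result a `pipeline_result`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_pipeline_result <- function(result, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character()
  groups_flat <- result$groups
  if (nrow(groups_flat)) {
    groups_flat$member_sample_ids <-
      vapply(groups_flat$member_sample_ids, paste, character(1), collapse = ";")
    p <- file.path(outdir, "groups.csv")
    readr::write_csv(groups_flat, p); paths <- c(paths, p)
  }
  if (nrow(result$topology)) {
    p <- file.path(outdir, "topology.csv")
    readr::write_csv(result$topology, p); paths <- c(paths, p)
  }
  if (!is.null(result$model_full)) {
    report <- list(
      full = model_report(result$model_full),
      reduced = model_report(result$model_reduced)
    )
    p <- file.path(outdir, "model.json")
    jsonlite::write_json(report, p, digits = NA, auto_unbox = TRUE)
    paths <- c(paths, p)
    scatter <- result$model_full$data
    scatter$fitted_csci <- predict(result$model_full, scatter)
    p <- file.path(outdir, "fitted_vs_observed.csv")
    readr::write_csv(
      scatter[c("group_id", "mean_csci", "fitted_csci", "mean_landuse_pct")],
      p)
    paths <- c(paths, p)
  }
  p <- file.path(outdir, "manifest.json")
  jsonlite::write_json(result$manifest, p, digits = NA, auto_unbox = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' @noRd
model_report <- function(model) {
  list(
    predictors = model$predictors,
    coefficients = as.list(model$coefficients),
    aic = model$aic,
    r_squared = model$r_squared,
    cv_r_squared = model$cv_r_squared,
    f_statistics = as.list(model$f_statistics),
    relative_importance = model$relative_importance,
    n = model$n
  )
}
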