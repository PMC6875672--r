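# Watershed-structured community simulator with known stress effects.
#
# The generator emulates the features of statewide BMI bioassessment data
# that the downstream pipeline depends on: a land-use stress gradient along
# which taxon richness declines, specialist genera dropping out while
# generalists persist, positive co-occurrence induced by shared latent niche
# responses, a long tail of rare genera beneath a band of widespread ones,
# and a CSCI-like integrity index that declines with stress but is
# independent of altitude by construction.

#' Configuration for the synthetic BMI data generator
#'
#' Returns the generator's study conditions as a validated list. Defaults
#' describe a California-like landscape: watersheds as spatial clusters with
#' a skewed developed-land-use distribution, 334 candidate genera in eight
#' functional feeding groups, logit-normal baseline prevalences (a long rare
#' tail under a band of widespread taxa), and a latent-factor logistic
#' occurrence model in which genera load on guild-clustered niche axes.
#'
#' Stress enters occurrence probabilities three ways: a guild slope
#' (`slope_generalist` >= 0, `slope_specialist` < 0, other guilds get
#' `slope_other`), a community-wide richness decline (`richness_decline`,
#' subtracted from every slope), and an occupancy-tolerance coupling
#' (`tolerance_coupling` times the centred baseline prevalence): widespread
#' taxa tolerate or even increase with development while rare taxa are lost
#' first, the standard macroecological pattern in degraded streams.
#'
#' @param n_watersheds,sites_per_watershed landscape size (default 56 x 25).
#' @param n_genera number of candidate genera (default 334).
#' @param generalist_fraction,specialist_fraction expected fractions of
#'   genera in generalist (gatherer/filterer/omnivore) and specialist
#'   (scraper/shredder) feeding groups; the remainder are predators,
#'   parasites and piercers, which belong to neither guild.
#' @param target_richness expected genera per sample at the gradient centre.
#' @param prevalence_sd SD of baseline log-odds prevalence across genera.
#' @param slope_generalist,slope_specialist,slope_other guild land-use
#'   slopes per SD of land use (generalist must be >= 0, specialist < 0).
#' @param richness_decline community-wide land-use decline applied on top of
#'   the guild slopes (>= 0).
#' @param tolerance_coupling occupancy-tolerance coupling (>= 0).
#' @param altitude_slope_sd SD of per-genus altitude responses.
#' @param n_latent_factors number of latent niche axes; generalists load on
#'   the first two broad axes, specialists spread over the axes beyond the
#'   first.
#' @param factor_loading loading magnitude on a genus's primary axis
#'   (non-guild genera load at half of this, spread over all axes).
#' @param watershed_factor_share fraction of latent-axis variance shared by
#'   all sites of a watershed (the rest is site-level).
#' @param landuse_site_sd,altitude_site_sd within-watershed site SDs for
#'   land use (percent) and altitude (m).
#' @param csci_intercept,csci_stress_slope,csci_richness_slope,csci_noise_sd
#'   coefficients of the simulated integrity index
#'   `csci = b0 + b1 z(landuse) + b2 richness/target + noise`; `b1` must be
#'   negative and the index never depends on altitude.
#' @param seed integer root seed for all generator randomness.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_watersheds = 56,
                             sites_per_watershed = 25,
                             n_genera = 334,
                             generalist_fraction = 0.47,
                             specialist_fraction = 0.26,
                             target_richness = 30,
                             prevalence_sd = 1.6,
                             slope_generalist = 0.25,
                             slope_specialist = -1.1,
                             slope_other = -0.35,
                             richness_decline = 0.4,
                             tolerance_coupling = 0.6,
                             altitude_slope_sd = 0.3,
                             n_latent_factors = 5,
                             factor_loading = 2.5,
                             watershed_factor_share = 0.2,
                             landuse_site_sd = 6,
                             altitude_site_sd = 150,
                             csci_intercept = 0.5,
                             csci_stress_slope = -0.2,
                             csci_richness_slope = 0.5,
                             csci_noise_sd = 0.08,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_watersheds >= 1, cfg$sites_per_watershed >= 2, cfg$n_genera >= 2,
    cfg$generalist_fraction >= 0, cfg$specialist_fraction >= 0,
    cfg$generalist_fraction + cfg$specialist_fraction <= 1,
    cfg$slope_generalist >= 0, cfg$slope_specialist < 0,
    cfg$richness_decline >= 0, cfg$tolerance_coupling >= 0,
    cfg$n_latent_factors >= 1, cfg$csci_stress_slope < 0,
    cfg$csci_noise_sd > 0, cfg$target_richness >= 1
  )
  structure(cfg, class = "generator_config")
}

# Functional feeding groups and the generalist/specialist guild mapping.
# Gatherers, filterers and omnivores feed on broadly available resources
# (generalists); scrapers and shredders depend on specific substrates
# (specialists); predators, parasites and piercers belong to neither guild.
FFG_LEVELS <- c("gatherer", "filterer", "omnivore", "scraper", "shredder",
                "predator", "parasite", "piercer")
GENERALIST_FFGS <- c("gatherer", "filterer", "omnivore")
SPECIALIST_FFGS <- c("scraper", "shredder")

#' Map functional feeding groups to generalist/specialist guilds
#'
#' @param ffg character vector of feeding-group labels.
#' @return character vector: "generalist" for gatherers, filterers and
#'   omnivores; "specialist" for scrapers and shredders; "unassigned"
#'   otherwise.
#' @export
assign_guild <- function(ffg) {
  dplyr::case_when(
    ffg %in% GENERALIST_FFGS ~ "generalist",
    ffg %in% SPECIALIST_FFGS ~ "specialist",
    TRUE ~ "unassigned"
  )
}

#' Simulate the sampling landscape
#'
#' Lays watersheds out as spatial clusters inside a California-like
#' bounding box. Each watershed gets a mean developed-land-use level drawn
#' from a right-skewed distribution (most watersheds lightly developed, a
#' few heavily) and a mean altitude; sites scatter around both with the
#' configured site-level noise.
#'
#' @param config a [generator_config()].
#' @return tibble with one row per sample: `sample_id`, `site_id`,
#'   `watershed_id`, `latitude`, `longitude`, `altitude_m`, `landuse_pct`.
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  W <- config$n_watersheds
  S <- config$sites_per_watershed
  with_seed(derive_seed(config$seed, "landscape"), {
    stress_w <- 100 * stats::rbeta(W, 0.8, 1.6)
    alt_w <- stats::runif(W, 100, 2500)
    lat_w <- stats::runif(W, 33, 41.5)
    lon_w <- stats::runif(W, -124, -115)
    n <- W * S
    idx <- rep(seq_len(W), each = S)
    tibble::tibble(
      sample_id = sprintf("samp%05d", seq_len(n)),
      site_id = sprintf("site%05d", seq_len(n)),
      watershed_id = sprintf("HUC%05d", idx),
      latitude = pmin(42, pmax(32.5, lat_w[idx] + stats::rnorm(n, 0, 0.15))),
      longitude = pmin(-114, pmax(-124.4, lon_w[idx] + stats::rnorm(n, 0, 0.15))),
      altitude_m = pmax(0, alt_w[idx] + stats::rnorm(n, 0, config$altitude_site_sd)),
      landuse_pct = pmin(100, pmax(0, stress_w[idx] +
                                     stats::rnorm(n, 0, config$landuse_site_sd)))
    )
  })
}

#' @noRd
simulate_taxon_pool <- function(config) {
  G <- config$n_genera
  K <- config$n_latent_factors
  with_seed(derive_seed(config$seed, "taxa"), {
    p_gen <- config$generalist_fraction
    p_spec <- config$specialist_fraction
    p_other <- 1 - p_gen - p_spec
    # fixed within-guild FFG mix
    probs <- c(
      p_gen * c(gatherer = .60, filterer = .30, omnivore = .10),
      p_spec * c(scraper = .62, shredder = .38),
      p_other * c(predator = .74, parasite = .15, piercer = .11)
    )
    ffg <- sample(names(probs), G, replace = TRUE, prob = probs)
    guild <- assign_guild(ffg)
    a0 <- stats::rnorm(G, 0, config$prevalence_sd)
    slope <- dplyr::case_when(
      guild == "generalist" ~ config$slope_generalist,
      guild == "specialist" ~ config$slope_specialist,
      TRUE ~ config$slope_other
    ) + config$tolerance_coupling * a0 - config$richness_decline +
      stats::rnorm(G, 0, 0.15)
    alt_slope <- stats::rnorm(G, 0, config$altitude_slope_sd)
    # primary latent axis, clustered by guild; loading magnitude jittered
    # generalists cluster on the first two broad axes, specialists
    # partition the remaining niche axes, other guilds spread weakly
    gen_axes <- seq_len(max(1, min(2, K)))
    spec_axes <- if (K > 1) seq(2, K) else seq_len(K)
    axis <- ifelse(guild == "generalist", sample(gen_axes, G, replace = TRUE),
            ifelse(guild == "specialist", sample(spec_axes, G, replace = TRUE),
                   sample(seq_len(K), G, replace = TRUE)))
    loading <- config$factor_loading *
      ifelse(guild == "unassigned", 0.5, 1) * stats::runif(G, 0.8, 1.2)
    lambda <- matrix(0, G, K)
    lambda[cbind(seq_len(G), axis)] <- loading
    # calibrate intercepts so expected richness at the gradient centre,
    # averaged over the latent factors, matches the target
    fmc <- matrix(stats::rnorm(400 * K), 400, K)
    shift <- stats::uniroot(function(d) {
      mean(stats::plogis(sweep(fmc %*% t(lambda), 2, a0 + d, "+"))) *
        G - config$target_richness
    }, c(-15, 10))$root
    list(
      taxa = tibble::tibble(genus = sprintf("genus%03d", seq_len(G)),
                            ffg = ffg, guild = guild),
      intercept = a0 + shift,
      landuse_slope = slope,
      altitude_slope = alt_slope,
      lambda = lambda
    )
  })
}

#' Simulate genus occurrences over a landscape
#'
#' Occurrence of genus *j* at site *i* is Bernoulli with probability
#' `plogis(a_j + b_j z(landuse_i) + c_j z(altitude_i) + lambda_j . f_i)`.
#' The latent niche axes `f_i` are standard normal with a watershed-shared
#' component, so genera loading on the same axis co-occur within and across
#' watersheds. A sample that draws zero taxa is redrawn once and, failing
#' that, assigned the single most prevalent genus (counted in the
#' `forced_nonempty` attribute).
#'
#' @param landscape output of [simulate_landscape()].
#' @param config a [generator_config()].
#' @return a list with `occurrences` (long tibble `sample_id`, `genus`),
#'   `taxa` (tibble `genus`, `ffg`, `guild`) and `truth` (the genus-level
#'   parameters actually used, for recovery tests).
#' @export
simulate_occurrences <- function(landscape, config) {
  stopifnot(inherits(config, "generator_config"))
  pool <- simulate_taxon_pool(config)
  n <- nrow(landscape)
  G <- config$n_genera
  K <- config$n_latent_factors
  z_lu <- as.numeric(scale(landscape$landuse_pct))
  z_alt <- as.numeric(scale(landscape$altitude_m))
  if (anyNA(z_lu)) z_lu <- rep(0, n)    # degenerate constant gradient
  if (anyNA(z_alt)) z_alt <- rep(0, n)
  X <- with_seed(derive_seed(config$seed, "occurrences"), {
    ws <- as.integer(factor(landscape$watershed_id))
    Fw <- matrix(stats::rnorm(max(ws) * K), max(ws), K)
    rho <- config$watershed_factor_share
    f <- sqrt(rho) * Fw[ws, , drop = FALSE] +
      sqrt(1 - rho) * matrix(stats::rnorm(n * K), n, K)
    eta <- matrix(pool$intercept, n, G, byrow = TRUE) +
      outer(z_lu, pool$landuse_slope) +
      outer(z_alt, pool$altitude_slope) +
      f %*% t(pool$lambda)
    prob <- stats::plogis(eta)
    X <- matrix(stats::rbinom(n * G, 1, prob), n, G)
    # no sample may be empty: redraw once, then force the most prevalent genus
    forced <- 0L
    for (i in which(rowSums(X) == 0)) {
      X[i, ] <- stats::rbinom(G, 1, prob[i, ])
      if (sum(X[i, ]) == 0) {
        X[i, which.max(pool$intercept)] <- 1L
        forced <- forced + 1L
      }
    }
    attr(X, "forced_nonempty") <- forced
    X
  })
  idx <- which(X == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  occurrences <- tibble::tibble(
    sample_id = landscape$sample_id[idx[, 1]],
    genus = pool$taxa$genus[idx[, 2]]
  )
  list(
    occurrences = occurrences,
    taxa = pool$taxa,
    truth = list(
      intercept = pool$intercept,
      landuse_slope = pool$landuse_slope,
      altitude_slope = pool$altitude_slope,
      lambda = pool$lambda,
      forced_nonempty = attr(X, "forced_nonempty")
    )
  )
}

#' Simulate a CSCI-like biotic-integrity score
#'
#' The simulated index declines linearly with standardized land use and
#' rises with the sample's richness relative to the unstressed expectation;
#' it never depends on altitude, mimicking an index designed to have
#' minimal influence from natural gradients.
#'
#' @param landscape output of [simulate_landscape()].
#' @param richness integer vector of per-sample genus counts, aligned with
#'   `landscape` rows.
#' @param config a [generator_config()].
#' @return numeric vector of index scores.
#' @export
simulate_csci <- function(landscape, richness, config) {
  stopifnot(inherits(config, "generator_config"),
            length(richness) == nrow(landscape))
  z_lu <- as.numeric(scale(landscape$landuse_pct))
  if (anyNA(z_lu)) z_lu <- rep(0, nrow(landscape))
  with_seed(derive_seed(config$seed, "csci"), {
    config$csci_intercept +
      config$csci_stress_slope * z_lu +
      config$csci_richness_slope * richness / config$target_richness +
      stats::rnorm(nrow(landscape), 0, config$csci_noise_sd)
  })
}

#' Simulate a complete BMI bioassessment dataset
#'
#' Chains [simulate_landscape()], [simulate_occurrences()] and
#' [simulate_csci()] and returns the exact tables the reading functions
#' consume.
#'
#' @param config a [generator_config()].
#' @return list with `samples` (sample table including `csci`),
#'   `occurrences` (long sample x genus table), `taxa` (genus -> feeding
#'   group) and `truth` (generator ground truth for recovery tests).
#' @export
simulate_bmi_dataset <- function(config = generator_config()) {
  landscape <- simulate_landscape(config)
  occ <- simulate_occurrences(landscape, config)
  richness <- dplyr::count(occ$occurrences, .data$sample_id)
  richness <- richness$n[match(landscape$sample_id, richness$sample_id)]
  richness[is.na(richness)] <- 0L
  landscape$csci <- simulate_csci(landscape, richness, config)
  list(samples = landscape, occurrences = occ$occurrences,
       taxa = occ$taxa, truth = occ$truth)
}

#' Write a simulated dataset to CSV (plus ground-truth JSON)
#'
#' @param dataset output of [simulate_bmi_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_bmi_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    samples = file.path(dir, "samples.csv"),
    occurrences = file.path(dir, "occurrences.csv"),
    taxa = file.path(dir, "taxa.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(dataset$samples, paths[["samples"]])
  occ <- dataset$occurrences
  occ$abundance <- 1L
  readr::write_csv(occ, paths[["occurrences"]])
  readr::write_csv(dataset$taxa[c("genus", "ffg")], paths[["taxa"]])
  truth <- dataset$truth
  truth$lambda <- as.data.frame(truth$lambda)
  jsonlite::write_json(truth, paths[["truth"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
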