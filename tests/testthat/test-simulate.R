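# Generator contracts: landscape structure, stress effects, co-occurrence.

small_config <- function(seed = 1, ...) {
  generator_config(n_watersheds = 12, sites_per_watershed = 25,
                   n_genera = 120, target_richness = 15, seed = seed, ...)
}

test_that("landscape has watershed structure and valid ranges", {
  cfg <- generator_config(n_watersheds = 1, sites_per_watershed = 20, seed = 2)
  land <- simulate_landscape(cfg)
  expect_equal(nrow(land), 20)
  expect_equal(dplyr::n_distinct(land$watershed_id), 1)
  cfg2 <- small_config()
  land2 <- simulate_landscape(cfg2)
  expect_true(all(land2$landuse_pct >= 0 & land2$landuse_pct <= 100))
  expect_true(all(land2$latitude >= 32.5 & land2$latitude <= 42))
  expect_true(all(land2$altitude_m >= 0))
  # zero site noise: all sites of a watershed share the land-use level
  cfg3 <- generator_config(n_watersheds = 3, sites_per_watershed = 5,
                           landuse_site_sd = 1e-12, seed = 3)
  land3 <- simulate_landscape(cfg3)
  spread <- tapply(land3$landuse_pct, land3$watershed_id,
                   function(x) diff(range(x)))
  expect_true(all(spread < 1e-6))
})

test_that("different seeds give different draws with the same marginals", {
  cfg_a <- generator_config(seed = 101)
  cfg_b <- generator_config(seed = 202)
  la <- simulate_landscape(cfg_a)
  lb <- simulate_landscape(cfg_b)
  expect_false(identical(la$latitude, lb$latitude))
  # site values cluster within watersheds, so compare the (exchangeable)
  # watershed-level means
  ws_mean <- function(l, v) as.numeric(tapply(l[[v]], l$watershed_id, mean))
  expect_gt(stats::ks.test(ws_mean(la, "landuse_pct"),
                           ws_mean(lb, "landuse_pct"))$p.value, 0.01)
  expect_gt(stats::ks.test(ws_mean(la, "altitude_m"),
                           ws_mean(lb, "altitude_m"))$p.value, 0.01)
})

test_that("specialist richness declines along the stress gradient", {
  cfg <- generator_config(n_watersheds = 20, sites_per_watershed = 25,
                          seed = 7)
  land <- simulate_landscape(cfg)
  occ <- simulate_occurrences(land, cfg)
  spec <- occ$taxa$genus[occ$taxa$guild == "specialist"]
  spec_rich <- tapply(occ$occurrences$genus %in% spec,
                      factor(occ$occurrences$sample_id, land$sample_id), sum)
  spec_rich[is.na(spec_rich)] <- 0
  lo <- land$landuse_pct < stats::median(land$landuse_pct)
  ht <- stats::wilcox.test(spec_rich[lo], spec_rich[!lo],
                           alternative = "greater")
  expect_lt(ht$p.value, 1e-4)
  # total richness also declines
  expect_lt(pearson_screen(as.numeric(tapply(occ$occurrences$sample_id,
              factor(occ$occurrences$sample_id, land$sample_id), length)),
            land$landuse_pct)$r, 0)
})

test_that("structure-free settings give iid occurrences and ~no edges", {
  cfg <- generator_config(n_watersheds = 8, sites_per_watershed = 25,
                          n_genera = 40, target_richness = 14,
                          prevalence_sd = 1e-9, slope_generalist = 0,
                          slope_specialist = -1e-9, slope_other = 0,
                          richness_decline = 0, tolerance_coupling = 0,
                          altitude_slope_sd = 0, factor_loading = 0,
                          seed = 31)
  land <- simulate_landscape(cfg)
  occ <- simulate_occurrences(land, cfg)
  samples <- read_samples(
    dplyr::mutate(land, csci = 1), occ$occurrences)
  suppressWarnings(samples <- stratify_samples(samples))
  samples$watershed_id <- "all"   # one big pool of exchangeable sites
  samples$landuse_quintile <- 1L
  samples$altitude_quintile <- 1L
  groups <- subsample_groups(samples, 10, 20, seed = 5)
  retained <- 0; candidates <- 0
  for (i in seq_len(nrow(groups))) {
    members <- samples[match(groups$member_sample_ids[[i]],
                             samples$sample_id), ]
    gn <- group_network(members, n_null = 60, seed = i)
    retained <- retained + sum(gn$edge_stats$retained)
    candidates <- candidates + nrow(gn$edge_stats)
  }
  expect_gt(candidates, 5000)
  expect_lte(retained / candidates, 1e-3)
})

test_that("latent loadings create co-occurrence signal on shared axes", {
  # genera loading on the same niche axis score systematically higher SES
  # than cross-axis pairs; the contrast is sharper than the pooled |SES|
  # because the richness-preserving null absorbs part of any block signal
  # through the row sums it conserves
  cfg <- generator_config(n_watersheds = 10, sites_per_watershed = 20,
                          n_genera = 120, target_richness = 30,
                          prevalence_sd = 0.3, tolerance_coupling = 0,
                          n_latent_factors = 6, factor_loading = 2.5,
                          seed = 9)
  land <- simulate_landscape(cfg)
  occ <- simulate_occurrences(land, cfg)
  axis <- apply(occ$truth$lambda, 1, which.max)
  names(axis) <- occ$taxa$genus
  samples <- read_samples(dplyr::mutate(land, csci = 1), occ$occurrences)
  same <- c(); cross <- c()
  for (w in unique(samples$watershed_id)[1:5]) {
    members <- samples[samples$watershed_id == w, ][1:10, ]
    es <- group_network(members, n_null = 50, seed = 2)$edge_stats
    is_same <- axis[es$taxon_a] == axis[es$taxon_b]
    same <- c(same, es$ses[is_same])
    cross <- c(cross, es$ses[!is_same])
  }
  expect_gt(mean(same, na.rm = TRUE), mean(cross, na.rm = TRUE) + 0.3)
  expect_lt(stats::t.test(same, cross, alternative = "greater")$p.value, 1e-10)
})

test_that("the simulated index tracks stress and richness, not altitude", {
  cfg <- small_config(seed = 17)
  ds <- simulate_bmi_dataset(cfg)
  r_lu <- pearson_screen(ds$samples$csci, ds$samples$landuse_pct)
  expect_lt(r_lu$r, -0.5)
  # two otherwise-identical sites differing only in land use order by index
  land2 <- tibble::tibble(
    sample_id = c("a", "b"), site_id = c("a", "b"), watershed_id = "W",
    latitude = 35, longitude = -120, altitude_m = 500,
    landuse_pct = c(0, 100))
  cfg2 <- generator_config(csci_noise_sd = 1e-9, seed = 3)
  csci <- simulate_csci(land2, c(20L, 20L), cfg2)
  expect_gt(csci[1], csci[2])
  # near-zero slopes: index independent of stress
  cfg3 <- small_config(seed = 23, csci_stress_slope = -1e-9,
                       csci_richness_slope = 0, csci_noise_sd = 0.1)
  land3 <- simulate_landscape(cfg3)
  csci3 <- simulate_csci(land3, rep(15L, nrow(land3)), cfg3)
  ci <- stats::confint(stats::lm(csci3 ~ land3$landuse_pct))[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("no sample is ever empty and the forced counter is recorded", {
  cfg <- generator_config(n_watersheds = 4, sites_per_watershed = 10,
                          n_genera = 10, target_richness = 1,
                          prevalence_sd = 0.5, seed = 12)
  land <- simulate_landscape(cfg)
  occ <- simulate_occurrences(land, cfg)
  rich <- table(factor(occ$occurrences$sample_id, land$sample_id))
  expect_true(all(rich >= 1))
  expect_gte(occ$truth$forced_nonempty, 0)
})
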