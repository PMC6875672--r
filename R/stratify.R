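# Watershed filtering, quintile stratification and sample-group selection.

#' Keep only watersheds with enough unique samples
#'
#' @param samples sample tibble (one row per sample).
#' @param min_n minimum number of unique samples a watershed must have
#'   (default 15).
#' @return the retained samples, with attributes `n_watersheds_kept` and
#'   `n_samples_kept`. Warns (does not error) if nothing survives.
#' @export
filter_watersheds <- function(samples, min_n = 15) {
  stopifnot(min_n >= 1)
  counts <- table(samples$watershed_id[!duplicated(samples$sample_id)])
  keep_ws <- names(counts)[counts >= min_n]
  out <- samples[samples$watershed_id %in% keep_ws, ]
  if (nrow(out) == 0) {
    warning("no watershed has ", min_n, " or more samples; result is empty")
  }
  attr(out, "n_watersheds_kept") <- length(keep_ws)
  attr(out, "n_samples_kept") <- nrow(out)
  out
}

#' Assign empirical quantile-bin labels
#'
#' Break points are the empirical quantiles of `x` (probabilities
#' `1/n, ..., (n-1)/n`); intervals are half-open and right-closed, so a
#' value equal to a break falls in the lower bin.
#'
#' @param x numeric vector.
#' @param n_quantiles number of bins (default 5: quintiles).
#' @return integer labels in `1..n_quantiles`. If all values are identical
#'   every label is 1, with a warning.
#' @export
assign_quintiles <- function(x, n_quantiles = 5) {
  stopifnot(n_quantiles >= 2, is.numeric(x))
  breaks <- unique(stats::quantile(x, probs = seq_len(n_quantiles - 1) / n_quantiles,
                                   names = FALSE, na.rm = FALSE))
  if (length(unique(x)) == 1) {
    warning("all values identical; every observation assigned to bin 1")
    return(rep(1L, length(x)))
  }
  .bincode(x, breaks = c(-Inf, breaks, Inf), right = TRUE)
}

#' Add land-use and altitude quintile labels to a sample table
#'
#' Quintile breaks are computed once over the whole (filtered) table, not
#' per watershed.
#'
#' @param samples sample tibble.
#' @param n_quintiles number of strata per variable (default 5).
#' @return `samples` with integer columns `landuse_quintile` and
#'   `altitude_quintile`.
#' @export
stratify_samples <- function(samples, n_quintiles = 5) {
  samples$landuse_quintile <- assign_quintiles(samples$landuse_pct, n_quintiles)
  samples$altitude_quintile <- assign_quintiles(samples$altitude_m, n_quintiles)
  samples
}

#' Draw stratified sample groups within watersheds
#'
#' For every replicate and every joint stratification cell
#' (watershed x land-use quintile x altitude quintile) holding at least
#' `group_size` samples, draws `group_size` samples uniformly without
#' replacement. Each (replicate, cell) draw uses its own derived RNG
#' substream, so any single group is reproducible in isolation. Cells with
#' fewer than `group_size` samples are skipped (counted in the
#' `n_cells_skipped` attribute).
#'
#' @param samples stratified samples from [stratify_samples()].
#' @param group_size samples per group (default 10).
#' @param n_repeats replicate draws per cell (default 100).
#' @param seed integer root seed.
#' @return tibble with one row per group: `group_id`, `watershed_id`,
#'   `landuse_quintile`, `altitude_quintile`, `replicate`, and
#'   `member_sample_ids` (list-column), plus the covariates of
#'   [group_covariates()].
#' @export
subsample_groups <- function(samples, group_size = 10, n_repeats = 100,
                             seed = 1L) {
  abort_missing_columns(samples, c("landuse_quintile", "altitude_quintile"),
                        "stratified sample table")
  cell_key <- paste(samples$watershed_id, samples$landuse_quintile,
                    samples$altitude_quintile, sep = ".")
  cells <- split(seq_len(nrow(samples)), cell_key)
  eligible <- cells[lengths(cells) >= group_size]
  n_skipped <- length(cells) - length(eligible)
  eligible <- eligible[order(names(eligible))]

  rows <- list()
  for (r in seq_len(n_repeats)) {
    for (cell in names(eligible)) {
      idx <- with_seed(derive_seed(seed, "group", r, cell),
                       sample(eligible[[cell]], group_size))
      members <- samples[idx, ]
      cov <- group_covariates(members)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group_id = sprintf("%s.r%03d", cell, r),
        watershed_id = members$watershed_id[1],
        landuse_quintile = members$landuse_quintile[1],
        altitude_quintile = members$altitude_quintile[1],
        replicate = r,
        member_sample_ids = list(members$sample_id),
        !!!cov
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  attr(out, "n_cells_eligible") <- length(eligible)
  attr(out, "n_cells_skipped") <- n_skipped
  out
}

#' Covariates of one sample group
#'
#' Means and sample (n-1) standard deviations of altitude and land use, the
#' mean CSCI, and the mean great-circle separation over all unordered pairs
#' of member sites (haversine, Earth radius 6,371,000 m).
#'
#' @param members sample tibble rows of the group's members (>= 2 rows).
#' @return named list of covariates.
#' @export
group_covariates <- function(members) {
  stopifnot(nrow(members) >= 2)
  coords <- unique(cbind(members$longitude, members$latitude))
  dist_m <- if (nrow(coords) < 2) {
    warning("fewer than 2 distinct coordinates in group; distance set to 0")
    0
  } else {
    d <- geosphere::distm(cbind(members$longitude, members$latitude),
                          fun = function(p1, p2) {
                            geosphere::distHaversine(p1, p2, r = 6371000)
                          })
    mean(d[upper.tri(d)])
  }
  list(
    n_members = nrow(members),
    mean_altitude_m = mean(members$altitude_m),
    sd_altitude_m = stats::sd(members$altitude_m),
    mean_landuse_pct = mean(members$landuse_pct),
    sd_landuse_pct = stats::sd(members$landuse_pct),
    mean_pairwise_distance_m = dist_m,
    mean_csci = mean(members$csci)
  )
}
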