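# Reading and validating sample, occurrence and taxon tables.

SAMPLE_COLUMNS <- c("sample_id", "site_id", "watershed_id", "latitude",
                    "longitude", "altitude_m", "landuse_pct", "csci")

#' Read and validate a sample table with its occurrences
#'
#' Joins the per-sample covariate table with genus occurrences and returns
#' one row per sample with the genera present as a list-column. Occurrences
#' may be given long (columns `sample_id`, `genus` and optionally
#' `abundance`) or as a wide samples x genera matrix whose first column is
#' `sample_id`. Any positive abundance is collapsed to presence; the
#' analysis is presence/absence throughout.
#'
#' @param samples a data frame or CSV path with columns `sample_id`,
#'   `site_id`, `watershed_id`, `latitude`, `longitude`, `altitude_m`,
#'   `landuse_pct`, `csci`.
#' @param occurrences a data frame or CSV path, long or wide (see above).
#' @return tibble of validated samples with a `taxa` list-column of genus
#'   identifiers (every sample non-empty).
#' @export
read_samples <- function(samples, occurrences) {
  if (is.character(samples)) {
    samples <- readr::read_csv(samples, show_col_types = FALSE,
                               progress = FALSE)
  }
  samples <- tibble::as_tibble(samples)
  abort_missing_columns(samples, SAMPLE_COLUMNS, "sample table")
  if (anyDuplicated(samples$sample_id)) {
    stop("sample table has duplicated sample_id values", call. = FALSE)
  }
  bad <- which(samples$landuse_pct < 0 | samples$landuse_pct > 100 |
                 is.na(samples$landuse_pct))
  if (length(bad)) {
    stop(sprintf("landuse_pct outside [0, 100] for sample(s): %s",
                 paste(utils::head(samples$sample_id[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  stopifnot(all(samples$latitude >= -90 & samples$latitude <= 90),
            all(samples$longitude >= -180 & samples$longitude <= 180))

  occ <- read_occurrences(occurrences)
  if (!all(occ$sample_id %in% samples$sample_id)) {
    stop("occurrence table references sample_id values absent from the sample table",
         call. = FALSE)
  }
  taxa_by_sample <- split(occ$genus, occ$sample_id)
  samples$taxa <- lapply(samples$sample_id,
                         function(id) sort(unique(taxa_by_sample[[id]])))
  empty <- lengths(samples$taxa) == 0
  if (any(empty)) {
    stop(sprintf("sample(s) with no genera present: %s",
                 paste(utils::head(samples$sample_id[empty], 5), collapse = ", ")),
         call. = FALSE)
  }
  samples
}

#' @noRd
read_occurrences <- function(occurrences) {
  if (is.character(occurrences)) {
    occurrences <- readr::read_csv(occurrences, show_col_types = FALSE,
                                   progress = FALSE)
  }
  occurrences <- tibble::as_tibble(occurrences)
  if (all(c("sample_id", "genus") %in% names(occurrences))) {
    if ("abundance" %in% names(occurrences)) {
      occurrences <- occurrences[occurrences$abundance > 0, ]
    }
    occ <- occurrences[c("sample_id", "genus")]
  } else if (names(occurrences)[1] == "sample_id") {
    # wide binary matrix: samples x genera
    occ <- tidyr::pivot_longer(occurrences, -"sample_id",
                               names_to = "genus", values_to = "abundance")
    occ <- occ[occ$abundance > 0, c("sample_id", "genus")]
  } else {
    stop("occurrence table must be long (sample_id, genus[, abundance]) or wide with a sample_id first column",
         call. = FALSE)
  }
  if (any(is.na(occ$genus) | occ$genus == "")) {
    stop("occurrence table contains empty genus identifiers", call. = FALSE)
  }
  occ
}

#' Read a genus -> functional feeding group table
#'
#' @param taxa a data frame or CSV path with columns `genus` and `ffg`.
#' @return tibble with `genus`, `ffg` and the derived `guild`
#'   (see [assign_guild()]).
#' @export
read_taxa <- function(taxa) {
  if (is.character(taxa)) {
    taxa <- readr::read_csv(taxa, show_col_types = FALSE, progress = FALSE)
  }
  taxa <- tibble::as_tibble(taxa)
  abort_missing_columns(taxa, c("genus", "ffg"), "taxon table")
  taxa$guild <- assign_guild(taxa$ffg)
  taxa[c("genus", "ffg", "guild")]
}

#' Per-sample functional-feeding-group and guild proportions
#'
#' For each sample, the proportion of the unique genera present that belong
#' to each feeding group (genera missing from the taxon table count as
#' `unassigned`), plus the generalist/specialist guild proportions. FFG
#' proportions (the eight groups plus `unassigned`) sum to one per sample.
#'
#' @param samples validated samples from [read_samples()].
#' @param taxa taxon table from [read_taxa()].
#' @return tibble with one row per sample: `sample_id`, one proportion
#'   column per feeding group, `unassigned`, and guild proportions
#'   `generalist`, `specialist`.
#' @export
ffg_proportions <- function(samples, taxa) {
  stopifnot(all(lengths(samples$taxa) >= 1))
  ffg_of <- stats::setNames(taxa$ffg, taxa$genus)
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    genera <- unique(samples$taxa[[i]])
    ffg <- unname(ffg_of[genera])
    ffg[is.na(ffg) | !(ffg %in% FFG_LEVELS)] <- "unassigned"
    counts <- table(factor(ffg, levels = c(FFG_LEVELS, "unassigned")))
    props <- as.numeric(counts) / length(genera)
    guild <- assign_guild(ffg)
    c(props,
      generalist = mean(guild == "generalist"),
      specialist = mean(guild == "specialist"))
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- c(FFG_LEVELS, "unassigned", "generalist", "specialist")
  out <- tibble::as_tibble(mat)
  dplyr::bind_cols(tibble::tibble(sample_id = samples$sample_id), out)
}
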