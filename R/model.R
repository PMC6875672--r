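# Linear models of mean biotic integrity on network topology.

#' Ordinary least-squares fit with per-predictor F statistics
#'
#' Wraps `stats::lm` for a data-frame-first interface and adds the
#' quantities the index model reports: Gaussian AIC (error variance counted
#' as a parameter), R-squared, and the drop-one F statistic (1 numerator df)
#' for every predictor.
#'
#' @param data data frame holding response and predictors.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names.
#' @return object of class `ols_fit`: list with `fit` (the lm), `response`,
#'   `predictors`, `coefficients`, `aic`, `r_squared`, `f_statistics`
#'   (named, drop-one F), `n`.
#' @export
ols_fit <- function(data, response, predictors) {
  stopifnot(length(predictors) >= 1,
            all(c(response, predictors) %in% names(data)))
  data <- data[stats::complete.cases(data[c(response, predictors)]),
               c(response, predictors)]
  if (nrow(data) <= length(predictors) + 1) {
    stop("need more observations than parameters", call. = FALSE)
  }
  form <- stats::reformulate(predictors, response)
  fit <- stats::lm(form, data = data)
  if (fit$rank < length(predictors) + 1) {
    dropped <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient predictor matrix; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  dr <- stats::drop1(fit, test = "F")
  fstats <- stats::setNames(dr$`F value`[-1], rownames(dr)[-1])[predictors]
  structure(list(
    fit = fit,
    response = response,
    predictors = predictors,
    coefficients = stats::coef(fit),
    aic = stats::AIC(fit),
    r_squared = summary(fit)$r.squared,
    f_statistics = fstats,
    n = nrow(data)
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> %s ~ %s\n  n = %d, R^2 = %.3f, AIC = %.1f\n",
              x$response, paste(x$predictors, collapse = " + "),
              x$n, x$r_squared, x$aic))
  invisible(x)
}

#' Backward elimination by AIC
#'
#' Starting from the full model, repeatedly removes the predictor whose
#' removal lowers the AIC the most; stops when no removal lowers it.
#' Ties are broken by predictor name order, so the procedure is
#' deterministic.
#'
#' @inheritParams ols_fit
#' @return list with `retained` (character vector), `fit` (the final
#'   [ols_fit()]) and `steps` (tibble of the elimination path).
#' @export
backward_eliminate_aic <- function(data, response, predictors) {
  current <- sort(predictors)
  fit <- ols_fit(data, response, current)
  steps <- list(tibble::tibble(step = 0L, dropped = NA_character_,
                               aic = fit$aic))
  repeat {
    if (length(current) == 1) break
    candidates <- vapply(current, function(p) {
      ols_fit(data, response, setdiff(current, p))$aic
    }, numeric(1))
    best <- names(candidates)[which.min(candidates)]  # first = name order
    if (candidates[best] >= fit$aic) break
    current <- setdiff(current, best)
    fit <- ols_fit(data, response, current)
    steps[[length(steps) + 1L]] <- tibble::tibble(
      step = length(steps), dropped = best, aic = fit$aic)
  }
  list(retained = current, fit = fit, steps = dplyr::bind_rows(steps))
}

#' Repeated k-fold cross-validated R-squared
#'
#' Per repeat: shuffle, split into k folds, fit on k-1 folds, predict the
#' held-out fold; the repeat's R-squared is `1 - pooled held-out SSE /
#' pooled TSS`. The reported value is the mean over repeats.
#'
#' @inheritParams ols_fit
#' @param k number of folds (default 10).
#' @param repeats number of repeats (default 100).
#' @param seed integer seed (fold assignment uses one substream per repeat).
#' @return numeric cross-validated R-squared.
#' @export
repeated_kfold_r2 <- function(data, response, predictors, k = 10,
                              repeats = 100, seed = 1L) {
  data <- data[stats::complete.cases(data[c(response, predictors)]),
               c(response, predictors)]
  n <- nrow(data)
  stopifnot(n >= 2 * k)
  form <- stats::reformulate(predictors, response)
  y <- data[[response]]
  tss <- sum((y - mean(y))^2)
  per_repeat <- vapply(seq_len(repeats), function(r) {
    folds <- with_seed(derive_seed(seed, "cv", r),
                       sample(rep(seq_len(k), length.out = n)))
    pred <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      hold <- folds == f
      if (sum(!hold) < 2) stop("fold with fewer than 2 training observations")
      m <- stats::lm(form, data = data[!hold, , drop = FALSE])
      pred[hold] <- stats::predict(m, newdata = data[hold, , drop = FALSE])
    }
    1 - sum((y - pred)^2) / tss
  }, numeric(1))
  mean(per_repeat)
}

#' LMG relative importance decomposition
#'
#' For each predictor, the average over all orderings of model entry of the
#' increase in R-squared when that predictor enters. Computed by subset
#' enumeration with the standard ordering weights `s!(p-s-1)!/p!`, so the
#' shares sum exactly to the full model's R-squared. Limited to p <= 10
#' predictors (exact enumeration).
#'
#' @inheritParams ols_fit
#' @return tibble with `predictor`, `share_total_variance` (fraction of
#'   total response variance; sums to the full-model R-squared) and
#'   `share_explained_pct` (percent of explained variance; sums to 100).
#' @export
lmg_relative_importance <- function(data, response, predictors) {
  p <- length(predictors)
  if (p > 10) {
    stop("more than 10 predictors; exact enumeration over orderings is not feasible (sampling of orderings is not implemented)",
         call. = FALSE)
  }
  data <- data[stats::complete.cases(data[c(response, predictors)]),
               c(response, predictors)]
  y <- data[[response]]
  X <- as.matrix(data[predictors])
  # R^2 of every predictor subset from the joint covariance (exact OLS)
  cv <- stats::cov(cbind(y, X))
  syy <- cv[1, 1]
  r2_of <- function(subset_idx) {
    if (!length(subset_idx)) return(0)
    sxx <- cv[subset_idx + 1L, subset_idx + 1L, drop = FALSE]
    sxy <- cv[subset_idx + 1L, 1L]
    as.numeric(crossprod(sxy, solve(sxx, sxy)) / syy)
  }
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  r2 <- vapply(subsets, r2_of, numeric(1))
  mask_of <- vapply(subsets, function(s) sum(2^(s - 1)), numeric(1))
  r2_lookup <- stats::setNames(r2, mask_of)
  shares <- vapply(seq_len(p), function(j) {
    contrib <- 0
    for (i in seq_along(subsets)) {
      s <- subsets[[i]]
      if (j %in% s) next
      w <- factorial(length(s)) * factorial(p - length(s) - 1) / factorial(p)
      with_j <- r2_lookup[[as.character(mask_of[i] + 2^(j - 1))]]
      contrib <- contrib + w * (with_j - r2[i])
    }
    contrib
  }, numeric(1))
  tibble::tibble(
    predictor = predictors,
    share_total_variance = shares,
    share_explained_pct = 100 * shares / sum(shares)
  )
}

#' Pearson correlation screen
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @return tibble with `r`, `p_value` (t transform, n-2 df) and `n`.
#' @export
pearson_screen <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ht$estimate), p_value = ht$p.value,
                 n = length(x))
}

#' Land-use and altitude trends in feeding-group proportions
#'
#' One two-predictor linear model per feeding-group/guild category:
#' `proportion ~ landuse_pct + altitude_m`, fitted on per-sample rows.
#'
#' @param proportions output of [ffg_proportions()].
#' @param samples the matching sample table (provides the covariates).
#' @return tibble with one row per category and term: `category`, `term`,
#'   `estimate`, `p_value`, plus a `degenerate` flag for constant responses.
#' @export
trend_models <- function(proportions, samples) {
  stopifnot(all(proportions$sample_id == samples$sample_id))
  categories <- setdiff(names(proportions), "sample_id")
  purrr::map_dfr(categories, function(cat) {
    y <- proportions[[cat]]
    if (stats::sd(y) == 0) {
      return(tibble::tibble(category = cat,
                            term = c("landuse_pct", "altitude_m"),
                            estimate = NA_real_, p_value = NA_real_,
                            degenerate = TRUE))
    }
    fit <- stats::lm(y ~ landuse_pct + altitude_m,
                     data = data.frame(y = y,
                                       landuse_pct = samples$landuse_pct,
                                       altitude_m = samples$altitude_m))
    sm <- summary(fit)$coefficients
    tibble::tibble(category = cat,
                   term = rownames(sm)[-1],
                   estimate = sm[-1, "Estimate"],
                   p_value = sm[-1, "Pr(>|t|)"],
                   degenerate = FALSE)
  })
}

#' Fit the full index model of mean CSCI on network topology
#'
#' Backward-eliminates the topology predictors by AIC, then reports the
#' retained model's coefficients, AIC, R-squared, repeated k-fold
#' cross-validated R-squared, per-predictor F statistics and LMG relative
#' importances.
#'
#' @param data modeling table (one row per network with topology metrics
#'   and group covariates; rows with missing values are dropped).
#' @param response response column (default `"mean_csci"`).
#' @param predictors topology predictor columns.
#' @param cv_folds,cv_repeats cross-validation setup (defaults 10 and 100).
#' @param eliminate run AIC backward elimination first (default TRUE).
#' @param seed RNG seed for the CV substreams.
#' @return object of class `index_model`: the [ols_fit()] fields plus
#'   `cv_r_squared`, `relative_importance`, `eliminated` and `steps`.
#' @export
fit_index_model <- function(data,
                            response = "mean_csci",
                            predictors = c("n_taxa", "connectance",
                                           "mean_strength", "modularity",
                                           "degree_heterogeneity"),
                            cv_folds = 10, cv_repeats = 100,
                            eliminate = TRUE, seed = 1L) {
  data <- data[stats::complete.cases(data[c(response, predictors)]), ]
  if (eliminate) {
    elim <- backward_eliminate_aic(data, response, predictors)
    retained <- elim$retained
    fit <- elim$fit
    steps <- elim$steps
  } else {
    retained <- predictors
    fit <- ols_fit(data, response, retained)
    steps <- NULL
  }
  cv <- repeated_kfold_r2(data, response, retained, k = cv_folds,
                          repeats = cv_repeats, seed = seed)
  lmg <- lmg_relative_importance(data, response, retained)
  structure(c(unclass(fit), list(
    cv_r_squared = cv,
    relative_importance = lmg,
    eliminated = setdiff(predictors, retained),
    steps = steps,
    data = data
  )), class = c("index_model", "ols_fit"))
}

#' @export
print.index_model <- function(x, ...) {
  cat(sprintf("<index_model> %s ~ %s\n  n = %d, R^2 = %.3f, CV-R^2 = %.3f, AIC = %.1f\n",
              x$response, paste(x$predictors, collapse = " + "),
              x$n, x$r_squared, x$cv_r_squared, x$aic))
  if (length(x$eliminated)) {
    cat("  eliminated:", paste(x$eliminated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict mean CSCI from topology values
#'
#' @param object an `index_model` or `ols_fit`.
#' @param newdata data frame of topology values.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.ols_fit <- function(object, newdata, ...) {
  stats::predict(object$fit, newdata = newdata)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an index-model fit
#'
#' @param x an `ols_fit` or `index_model`.
#' @param ... unused.
#' @return tibble with one row per term: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, and for predictors the drop-one `f_statistic`
#'   and the LMG importance shares when available.
#' @method tidy ols_fit
#' @export
tidy.ols_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  out <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p_value = sm[, "Pr(>|t|)"]
  )
  out$f_statistic <- c(NA_real_, x$f_statistics)[match(out$term, c("(Intercept)", names(x$f_statistics)))]
  if (!is.null(x$relative_importance)) {
    ri <- x$relative_importance
    out$importance_pct_explained <-
      ri$share_explained_pct[match(out$term, ri$predictor)]
  }
  out
}

#' One-row model summary
#'
#' @param x an `ols_fit` or `index_model`.
#' @param ... unused.
#' @return one-row tibble: `n`, `r_squared`, `cv_r_squared` (NA for a plain
#'   [ols_fit()]), `aic`.
#' @method glance ols_fit
#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    r_squared = x$r_squared,
    cv_r_squared = x$cv_r_squared %||% NA_real_,
    aic = x$aic
  )
}
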