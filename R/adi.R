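#' Configuration for Area Deprivation Index construction
#'
#' @param coefficients Named numeric vector of factor score coefficients over
#'   the 17 ADI items, with sign-flipped items entering via negative
#'   coefficients. `NULL` (the default) estimates coefficients from the input
#'   data by single-factor principal-axis factoring
#'   (see [estimate_adi_coefficients()]).
#' @param exclusion_min_housing_units Block groups with fewer housing units
#'   than this are excluded (strict `<`, default 30).
#' @param exclusion_min_population Block groups with fewer people than this
#'   are excluded (strict `<`, default 100).
#' @param exclusion_max_gq_fraction Block groups with a group-quarters share
#'   above this are excluded (strict `>`, default 1/3).
#' @param standard_mean,standard_sd Location and scale of the standardized
#'   index (defaults 100 and 20).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#'   SD convention used in standardization.
#' @param aggregate_on Which block-group quantity is population-weighted to
#'   the tract: `"percentile"` (default, the released form of the index) or
#'   `"standardized"`.
#' @return A list of class `adi_config`.
#' @export
adi_config <- function(coefficients = NULL,
                       exclusion_min_housing_units = 30,
                       exclusion_min_population = 100,
                       exclusion_max_gq_fraction = 1 / 3,
                       standard_mean = 100,
                       standard_sd = 20,
                       sd_type = c("sample", "population"),
                       aggregate_on = c("percentile", "standardized")) {
  if (standard_sd <= 0) stop("config error: standard_sd must be positive")
  if (!is.null(coefficients)) {
    extra <- setdiff(names(coefficients), adi_items())
    miss <- setdiff(adi_items(), names(coefficients))
    if (length(extra) || length(miss))
      stop("config error: coefficients must cover exactly the 17 ADI items; ",
           if (length(miss)) paste("missing:", paste(miss, collapse = ", ")),
           if (length(extra)) paste(" unknown:", paste(extra, collapse = ", ")))
  }
  structure(list(
    coefficients = coefficients,
    directions = stats::setNames(
      ifelse(adi_items() %in% adi_negative_items(), -1, 1), adi_items()),
    exclusion_min_housing_units = exclusion_min_housing_units,
    exclusion_min_population = exclusion_min_population,
    exclusion_max_gq_fraction = exclusion_max_gq_fraction,
    standard_mean = standard_mean,
    standard_sd = standard_sd,
    sd_type = match.arg(sd_type),
    aggregate_on = match.arg(aggregate_on)
  ), class = "adi_config")
}

#' Apply the ADI block-group exclusion rules
#'
#' A block group is excluded when it has fewer than 30 housing units, fewer
#' than 100 people, more than one third of its population in group quarters,
#' or a census-acknowledged data error (the `census_error` flag). When
#' several rules are violated the first in that order is recorded.
#'
#' @param blockgroups Block-group table with columns `blockgroup_id`,
#'   `population`, `housing_units`, `group_quarters_pop` and optionally
#'   `census_error`.
#' @param config An [adi_config()].
#' @return Data frame with columns `blockgroup_id`, `excluded`,
#'   `exclusion_reason` (`"housing_units"`, `"population"`,
#'   `"group_quarters"`, `"census_error"` or `"none"`).
#' @export
apply_exclusions <- function(blockgroups, config = adi_config()) {
  hu <- blockgroups$housing_units < config$exclusion_min_housing_units
  pop <- blockgroups$population < config$exclusion_min_population
  # zero population cannot support the group-quarters fraction; it is already
  # excluded by the population rule
  gq <- ifelse(blockgroups$population > 0,
               blockgroups$group_quarters_pop / blockgroups$population >
                 config$exclusion_max_gq_fraction,
               FALSE)
  err <- if ("census_error" %in% names(blockgroups))
    isTRUE_vec(blockgroups$census_error) else rep(FALSE, nrow(blockgroups))
  reason <- rep("none", nrow(blockgroups))
  reason[err] <- "census_error"
  reason[gq] <- "group_quarters"
  reason[pop] <- "population"
  reason[hu] <- "housing_units"
  data.frame(
    blockgroup_id = blockgroups$blockgroup_id,
    excluded = reason != "none",
    exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Estimate ADI factor score coefficients by principal-axis factoring
#'
#' Fits a single common factor to the correlation matrix of the standardized
#' 17 items by iterated principal-axis factoring (communalities start at
#' squared multiple correlations), then converts loadings to regression-method
#' factor score coefficients `w = R^{-1} lambda`. The solution is
#' sign-oriented so the poverty-rate item receives a positive coefficient,
#' making larger scores mean more deprivation.
#'
#' @param blockgroups Block-group table containing the 17 ADI item columns.
#' @param max_iter,tol Iteration control for the communality fixed point.
#' @return Named numeric vector of 17 coefficients.
#' @export
estimate_adi_coefficients <- function(blockgroups, max_iter = 200, tol = 1e-8) {
  X <- as.matrix(blockgroups[, adi_items()])
  if (nrow(X) < ncol(X) + 1)
    stop("degenerate input: too few block groups to estimate coefficients")
  R <- stats::cor(X)
  Rinv <- solve(R)
  h2 <- 1 - 1 / diag(Rinv) # squared multiple correlations
  for (iter in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h2
    e <- eigen(Rh, symmetric = TRUE)
    lambda <- sqrt(max(e$values[1], 0)) * e$vectors[, 1]
    h2_new <- pmin(lambda^2, 0.999)
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  Rh <- R
  diag(Rh) <- h2
  e <- eigen(Rh, symmetric = TRUE)
  lambda <- sqrt(max(e$values[1], 0)) * e$vectors[, 1]
  w <- as.vector(Rinv %*% lambda)
  names(w) <- adi_items()
  if (w["pct_below_poverty"] < 0) w <- -w
  w
}

#' Factor-weighted raw ADI scores
#'
#' Each item is multiplied by its factor score coefficient and the products
#' are summed within each block group. Items are standardized (z-scored over
#' the retained block groups) before weighting when `standardize_items` is
#' `TRUE`, which is required when coefficients are estimated from the data.
#'
#' @param blockgroups Block-group table with the 17 ADI item columns.
#' @param config An [adi_config()]; `config$coefficients = NULL` triggers
#'   estimation via [estimate_adi_coefficients()].
#' @param exclusions Optional result of [apply_exclusions()]; excluded block
#'   groups are skipped (raw score `NA`).
#' @param standardize_items Z-score items before weighting (default `TRUE`).
#' @return Named numeric vector of raw scores, `NA` for excluded block groups
#'   or block groups with a missing item value.
#' @export
compute_raw_adi <- function(blockgroups, config = adi_config(),
                            exclusions = NULL, standardize_items = TRUE) {
  keep <- rep(TRUE, nrow(blockgroups))
  if (!is.null(exclusions)) {
    stopifnot(identical(exclusions$blockgroup_id, blockgroups$blockgroup_id))
    keep <- !exclusions$excluded
  }
  X <- as.matrix(blockgroups[, adi_items()])
  coef <- config$coefficients
  if (is.null(coef)) coef <- estimate_adi_coefficients(blockgroups[keep, ])
  coef <- coef[adi_items()]
  if (standardize_items) {
    mu <- colMeans(X[keep, , drop = FALSE], na.rm = TRUE)
    sdv <- apply(X[keep, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
    sdv[sdv == 0] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  }
  raw <- as.vector(X %*% coef) # NA propagates from missing items, not zeroed
  raw[!keep] <- NA_real_
  stats::setNames(raw, blockgroups$blockgroup_id)
}

#' Standardize raw index scores to a fixed mean and SD
#'
#' Linearly rescales raw scores so that the retained scores have mean
#' `standard_mean` (100) and standard deviation `standard_sd` (20).
#'
#' @param raw Numeric vector of raw scores (`NA` = excluded/missing).
#' @param config An [adi_config()]; `sd_type` selects the sample (n-1) or
#'   population SD convention.
#' @return Numeric vector of standardized scores, `NA` preserved.
#' @export
standardize_index <- function(raw, config = adi_config()) {
  ok <- !is.na(raw)
  n <- sum(ok)
  if (n < 2) stop("degenerate input: need at least 2 non-missing raw scores")
  m <- mean(raw[ok])
  s <- stats::sd(raw[ok])
  if (config$sd_type == "population") s <- s * sqrt((n - 1) / n)
  if (s == 0) stop("degenerate input: raw scores are constant, SD undefined")
  config$standard_mean + config$standard_sd * (raw - m) / s
}

#' Percentile rank on a 0-100 scale
#'
#' `100 * (rank - 1) / (n - 1)` with average ranks for ties, over the
#' non-missing values: the minimum maps to 0 and the maximum to 100, with 100
#' the greatest deprivation when applied to ADI scores.
#'
#' @param values Numeric vector; `NA` preserved.
#' @param scale Output upper bound: 100 (default) or 1.
#' @return Numeric vector of percentiles in `[0, scale]`.
#' @export
percentile_rank <- function(values, scale = 100) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) stop("degenerate input: need at least 2 non-missing values")
  out <- rep(NA_real_, length(values))
  out[ok] <- scale * (rank(values[ok], ties.method = "average") - 1) / (n - 1)
  out
}

#' Population-weighted aggregation of block-group scores to tracts
#'
#' @param bg_scores Numeric vector of block-group scores (typically national
#'   percentiles), `NA` for excluded block groups.
#' @param blockgroups Block-group table aligned with `bg_scores`, providing
#'   `tract_id` and `population` weights.
#' @return Data frame with `tract_id`, `value` (weighted mean over retained
#'   members; `NA` when all members are excluded) and `missing`.
#' @export
aggregate_to_tract <- function(bg_scores, blockgroups) {
  stopifnot(length(bg_scores) == nrow(blockgroups))
  ok <- !is.na(bg_scores) & blockgroups$population > 0
  tract_ids <- sort(unique(blockgroups$tract_id))
  f <- factor(blockgroups$tract_id[ok], levels = tract_ids)
  w <- blockgroups$population[ok]
  num <- as.vector(tapply(w * bg_scores[ok], f, sum))
  den <- as.vector(tapply(w, f, sum))
  value <- ifelse(is.na(den) | den == 0, NA_real_, num / den)
  data.frame(tract_id = tract_ids, value = value,
             missing = is.na(value), stringsAsFactors = FALSE)
}

#' Rank-based decile assignment (1 = least, 10 = most deprived)
#'
#' Units are ordered by value with ties broken by a stable sort on the unit
#' identifier, then cut into 10 contiguous rank groups whose sizes differ by
#' at most one.
#'
#' @param values Numeric vector (`NA` allowed, gets `NA` decile).
#' @param ids Unit identifiers used as the deterministic tie-break; defaults
#'   to the input order.
#' @return Integer vector of deciles 1-10 aligned with `values`.
#' @export
assign_deciles <- function(values, ids = seq_along(values)) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 10) stop("degenerate input: need at least 10 non-missing values")
  ord <- order(values[ok], ids[ok])
  dec_sorted <- as.integer(ceiling(seq_len(n) * 10 / n))
  dec <- rep(NA_integer_, length(values))
  dec[ok][ord] <- dec_sorted
  dec
}

#' End-to-end ADI construction
#'
#' Runs exclusions, factor-weighted raw scores, mean-100/SD-20
#' standardization and national percentile ranking at the block-group level,
#' then population-weighted aggregation to tracts and tract decile ranking.
#'
#' @param blockgroups Block-group table (identifiers, counts, 17 ADI items).
#' @param config An [adi_config()].
#' @return List with `blockgroup_scores` (id, excluded, exclusion_reason,
#'   raw, standardized, percentile), `tract_scores` (tract_id, value, decile,
#'   missing) and `coefficients` (the vector actually used).
#' @export
compute_adi <- function(blockgroups, config = adi_config()) {
  excl <- apply_exclusions(blockgroups, config)
  coef <- config$coefficients
  if (is.null(coef))
    coef <- estimate_adi_coefficients(blockgroups[!excl$excluded, ])
  cfg <- config
  cfg$coefficients <- coef
  raw <- compute_raw_adi(blockgroups, cfg, exclusions = excl)
  standardized <- standardize_index(raw, cfg)
  percentile <- percentile_rank(standardized)
  bg_scores <- data.frame(
    blockgroup_id = blockgroups$blockgroup_id,
    excluded = excl$excluded,
    exclusion_reason = excl$exclusion_reason,
    raw = raw,
    standardized = standardized,
    percentile = percentile,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  agg_source <- if (cfg$aggregate_on == "percentile") percentile else standardized
  tract_scores <- aggregate_to_tract(agg_source, blockgroups)
  tract_scores$decile <- assign_deciles(tract_scores$value, tract_scores$tract_id)
  list(blockgroup_scores = bg_scores, tract_scores = tract_scores,
       coefficients = coef)
}
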