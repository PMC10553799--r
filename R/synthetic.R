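#' Parameters for the synthetic census-geography generator
#'
#' The generator emulates the statistical structure of the census indicator
#' tables the two indices are built from: a nested geography (1-5 block
#' groups per tract, tracts within states), one dominant latent deprivation
#' factor loading on all 27 indicator items, and a second latent
#' housing-market factor loading only on the three housing-cost items
#' (median home value, mortgage, gross rent) that is elevated in urban
#' tracts. Proportions are logit-normal, dollar amounts log-normal.
#'
#' @param n_states Number of states.
#' @param tracts_per_state Tracts per state.
#' @param blockgroups_per_tract_range Integer interval `c(lo, hi)`, `lo >= 1`:
#'   block groups per tract are drawn uniformly from this range.
#' @param urban_probability Probability a tract is urban (RUCA codes 1-3).
#' @param deprivation_loading Named numeric vector of signed loadings of each
#'   item on the latent deprivation factor (logit scale for proportion items,
#'   log scale for dollar items). Defaults weight poverty, income and
#'   education most heavily.
#' @param housing_confound_strength Nonnegative scale of the idiosyncratic
#'   (non-urban-driven) component of the latent housing-market factor. 0
#'   makes housing costs a deterministic function of urbanicity and
#'   deprivation only.
#' @param housing_urban_shift Nonnegative mean shift of the housing-market
#'   factor in urban tracts, in latent units. The default combined with the
#'   default item sensitivities gives urban home values roughly twice rural
#'   ones at the median, before the idiosyncratic market component; because
#'   dollar items are log-normal, the same market draw moves urban tracts
#'   much further in dollars than rural ones.
#' @param noise_sd Item-specific disturbance SD on the latent (logit/log)
#'   scale. Most of it is drawn at tract level, emulating that real indicator
#'   values are far from exchangeable given a single deprivation level; the
#'   block-group component is half this scale, and dollar items use 0.3 times
#'   this scale (administrative medians are more stable than small-sample
#'   survey rates). The default gives item-factor correlations around
#'   0.5-0.8, in the range reported for census deprivation indicators.
#' @param population_range Integer interval for block-group population.
#' @param exclusion_edge_fraction Fraction of block groups forced to violate
#'   one ADI exclusion rule (tiny housing stock, tiny population, dominant
#'   group-quarters population, or a flagged census error).
#' @param seed Integer seed; identical params + seed give identical tables.
#'
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_states = 5,
                             tracts_per_state = 200,
                             blockgroups_per_tract_range = c(1L, 5L),
                             urban_probability = 0.3,
                             deprivation_loading = default_loadings(),
                             housing_confound_strength = 1,
                             housing_urban_shift = 2.5,
                             noise_sd = 0.85,
                             population_range = c(600L, 3000L),
                             exclusion_edge_fraction = 0.02,
                             seed = 1L) {
  p <- list(
    n_states = as.integer(n_states),
    tracts_per_state = as.integer(tracts_per_state),
    blockgroups_per_tract_range = as.integer(blockgroups_per_tract_range),
    urban_probability = urban_probability,
    deprivation_loading = deprivation_loading,
    housing_confound_strength = housing_confound_strength,
    housing_urban_shift = housing_urban_shift,
    noise_sd = noise_sd,
    population_range = as.integer(population_range),
    exclusion_edge_fraction = exclusion_edge_fraction,
    seed = as.integer(seed)
  )
  class(p) <- "synthetic_params"
  validate_synthetic_params(p)
  p
}

validate_synthetic_params <- function(p) {
  stopifnot(length(p$blockgroups_per_tract_range) == 2,
            length(p$population_range) == 2)
  if (p$n_states < 0 || p$tracts_per_state < 0)
    stop("parameter error: n_states and tracts_per_state must be nonnegative counts")
  if (p$n_states > 0 && p$tracts_per_state == 0)
    stop("parameter error: tracts_per_state must be positive")
  if (p$blockgroups_per_tract_range[1] < 1 ||
      p$blockgroups_per_tract_range[2] < p$blockgroups_per_tract_range[1])
    stop("parameter error: blockgroups_per_tract_range must satisfy 1 <= lo <= hi")
  if (p$population_range[1] < 1 || p$population_range[2] < p$population_range[1])
    stop("parameter error: population_range must satisfy 1 <= lo <= hi")
  if (p$urban_probability < 0 || p$urban_probability > 1)
    stop("parameter error: urban_probability must lie in [0,1]")
  if (p$exclusion_edge_fraction < 0 || p$exclusion_edge_fraction > 1)
    stop("parameter error: exclusion_edge_fraction must lie in [0,1]")
  if (p$noise_sd <= 0) stop("parameter error: noise_sd must be positive")
  if (p$housing_confound_strength < 0 || p$housing_urban_shift < 0)
    stop("parameter error: housing factor parameters must be nonnegative")
  miss <- setdiff(all_items(), names(p$deprivation_loading))
  if (length(miss))
    stop("parameter error: deprivation_loading missing items: ",
         paste(miss, collapse = ", "))
  invisible(p)
}

#' Default deprivation-factor loadings
#'
#' Signed loadings of each indicator item on the latent deprivation factor.
#' Poverty, income and education items carry the largest magnitudes; items
#' where larger values indicate affluence (income, education, ownership,
#' housing costs) load negatively. The three housing-cost items load only
#' weakly: in the present-day cross-section, urban market heterogeneity and
#' gentrification largely decouple housing prices from neighborhood
#' deprivation (see [adi_reference_coefficients()] for the calibration-era
#' contrast).
#'
#' @return Named numeric vector over [all_items()].
#' @export
default_loadings <- function() {
  c(
    pct_below_poverty = 1.0,
    pct_below_150_poverty = 0.95,
    income_disparity = 0.6,
    median_family_income = -0.65,
    per_capita_income = -0.65,
    pct_unemployed = 0.6,
    pct_white_collar = -0.8,
    pct_hs_diploma_or_higher = -0.9,
    pct_no_hs_diploma = 0.9,
    pct_less_than_9th_grade = 0.8,
    pct_owner_occupied = -0.5,
    median_mortgage = -0.12,
    median_gross_rent = -0.12,
    median_home_value = -0.15,
    pct_single_parent = 0.7,
    pct_age_65_plus = 0.1,
    pct_age_17_under = 0.15,
    pct_disability = 0.5,
    pct_no_telephone = 0.6,
    pct_no_vehicle = 0.6,
    pct_no_plumbing = 0.4,
    pct_multi_unit = 0.3,
    pct_crowding = 0.6,
    pct_mobile_homes = 0.2,
    pct_group_quarters = 0.1,
    pct_minority = 0.7,
    pct_limited_english = 0.5
  )
}

# Item generation profile: baseline level (latent scale), transform, and
# sensitivity gamma to the housing-market factor (positive only for the
# three housing-cost items).
item_profile <- function() {
  items <- all_items()
  base <- c(
    pct_below_poverty = stats::qlogis(0.13),
    pct_below_150_poverty = stats::qlogis(0.22),
    income_disparity = log(1.5),
    median_family_income = log(70000),
    per_capita_income = log(32000),
    pct_unemployed = stats::qlogis(0.05),
    pct_white_collar = stats::qlogis(0.35),
    pct_hs_diploma_or_higher = stats::qlogis(0.87),
    pct_no_hs_diploma = stats::qlogis(0.13),
    pct_less_than_9th_grade = stats::qlogis(0.05),
    pct_owner_occupied = stats::qlogis(0.65),
    median_mortgage = log(1300),
    median_gross_rent = log(950),
    median_home_value = log(180000),
    pct_single_parent = stats::qlogis(0.10),
    pct_age_65_plus = stats::qlogis(0.16),
    pct_age_17_under = stats::qlogis(0.22),
    pct_disability = stats::qlogis(0.13),
    pct_no_telephone = stats::qlogis(0.02),
    pct_no_vehicle = stats::qlogis(0.08),
    pct_no_plumbing = stats::qlogis(0.005),
    pct_multi_unit = stats::qlogis(0.10),
    pct_crowding = stats::qlogis(0.03),
    pct_mobile_homes = stats::qlogis(0.05),
    pct_group_quarters = stats::qlogis(0.02),
    pct_minority = stats::qlogis(0.30),
    pct_limited_english = stats::qlogis(0.04)
  )
  gamma <- stats::setNames(numeric(length(items)), items)
  gamma["median_home_value"] <- 0.30
  gamma["median_mortgage"] <- 0.27
  gamma["median_gross_rent"] <- 0.24
  # dollar medians come from administrative-scale aggregates and are less
  # noisy than small-sample survey rates
  noise_mult <- ifelse(items %in% c(dollar_items(), "income_disparity"),
                       0.3, 1.0)
  data.frame(
    item = items,
    transform = ifelse(items %in% c(dollar_items(), "income_disparity"),
                       "log", "logit"),
    base = base[items],
    gamma = gamma[items],
    noise_mult = noise_mult,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

empty_blockgroup_table <- function() {
  cols <- c("blockgroup_id", "tract_id", "state_code", "population",
            "housing_units", "group_quarters_pop", "census_error",
            adi_items())
  df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  for (col in c("blockgroup_id", "tract_id", "state_code"))
    df[[col]] <- character(0)
  df$census_error <- logical(0)
  df
}

empty_tract_table <- function() {
  cols <- c("tract_id", "state_code", "population", "ruca_code", "urban",
            svi_items())
  df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  for (col in c("tract_id", "state_code")) df[[col]] <- character(0)
  df$urban <- logical(0)
  df
}

#' Generate a nested synthetic census geography with indicator tables
#'
#' Draws per-tract latent deprivation `D ~ N(0,1)`, an urban flag
#' `~ Bernoulli(urban_probability)`, and a latent housing-market factor
#' `H = housing_urban_shift * urban + housing_confound_strength * eps`
#' (`eps ~ N(0,1)`). Block-group indicator items are inverse-logit
#' (proportions) or exponential (dollar amounts, income disparity) transforms
#' of `base + loading * D + gamma * H + noise`, with `gamma > 0` only for
#' median home value, mortgage and gross rent. Tract items are
#' population-weighted means of their block groups' items. A fraction
#' `exclusion_edge_fraction` of block groups is forced to violate one ADI
#' exclusion rule.
#'
#' The random draw order is independent of the parameter values, so two runs
#' with the same seed and e.g. different `housing_confound_strength` share
#' all latent and noise draws.
#'
#' @param params A [synthetic_params()] object.
#' @return List with elements `blockgroups` (one row per block group:
#'   identifiers, population, housing counts, census-error flag, 17 ADI
#'   items) and `tracts` (one row per tract: identifiers, population, RUCA
#'   code, urban flag, 15 SVI items).
#' @export
generate_geography <- function(params) {
  validate_synthetic_params(params)
  if (params$n_states == 0)
    return(list(blockgroups = empty_blockgroup_table(),
                tracts = empty_tract_table()))

  set.seed(params$seed)
  nt <- params$n_states * params$tracts_per_state
  state_idx <- rep(seq_len(params$n_states), each = params$tracts_per_state)
  state_code <- sprintf("S%02d", state_idx)
  tract_id <- sprintf("%02d001%06d", state_idx,
                      rep(seq_len(params$tracts_per_state), params$n_states))

  # tract-level latents, drawn first and in fixed order
  D <- stats::rnorm(nt)
  urban <- stats::runif(nt) < params$urban_probability
  eps_h <- stats::rnorm(nt)
  H <- params$housing_urban_shift * urban +
    params$housing_confound_strength * eps_h
  ruca_draw <- stats::runif(nt)
  ruca_code <- ifelse(urban, 1L + floor(ruca_draw * 3), 4L + floor(ruca_draw * 7))

  bg_range <- params$blockgroups_per_tract_range
  nbg <- bg_range[1] + sample.int(bg_range[2] - bg_range[1] + 1L, nt,
                                  replace = TRUE) - 1L
  n_bg <- sum(nbg)
  bg_tract <- rep(seq_len(nt), nbg)
  bg_seq <- sequence(nbg)

  pop_range <- params$population_range
  population <- pop_range[1] +
    sample.int(pop_range[2] - pop_range[1] + 1L, n_bg, replace = TRUE) - 1L
  housing_units <- pmax(1L, as.integer(round(
    population / 2.5 * stats::runif(n_bg, 0.8, 1.2))))

  prof <- item_profile()
  # item-specific disturbances: a tract-level term at full noise_sd (real
  # indicator values are far from exchangeable given overall deprivation) and
  # a block-group term at half scale for within-tract dispersion
  vals <- matrix(NA_real_, n_bg, nrow(prof),
                 dimnames = list(NULL, prof$item))
  for (k in seq_len(nrow(prof))) {
    item_sd <- params$noise_sd * prof$noise_mult[k]
    tract_noise <- stats::rnorm(nt, 0, item_sd)
    lp <- prof$base[k] +
      params$deprivation_loading[[prof$item[k]]] * D[bg_tract] +
      prof$gamma[k] * H[bg_tract] +
      tract_noise[bg_tract] +
      stats::rnorm(n_bg, 0, item_sd / 2)
    vals[, k] <- if (prof$transform[k] == "log") exp(lp) else stats::plogis(lp)
  }

  group_quarters_pop <- as.integer(round(vals[, "pct_group_quarters"] * population))
  census_error <- rep(FALSE, n_bg)

  # force exclusion-rule edge cases on a random subset of block groups
  n_edge <- round(params$exclusion_edge_fraction * n_bg)
  if (n_edge > 0) {
    edge_idx <- sample.int(n_bg, n_edge)
    edge_rule <- sample(c("housing_units", "population", "group_quarters",
                          "census_error"), n_edge, replace = TRUE)
    edge_draw <- stats::runif(n_edge)
    for (j in seq_len(n_edge)) {
      i <- edge_idx[j]
      switch(edge_rule[j],
        housing_units = { housing_units[i] <- as.integer(floor(edge_draw[j] * 30)) },
        population = {
          population[i] <- 30L + as.integer(floor(edge_draw[j] * 70))
          group_quarters_pop[i] <- min(group_quarters_pop[i], population[i])
        },
        group_quarters = {
          group_quarters_pop[i] <-
            as.integer(round(population[i] * (0.4 + 0.5 * edge_draw[j])))
          vals[i, "pct_group_quarters"] <- group_quarters_pop[i] / population[i]
        },
        census_error = { census_error[i] <- TRUE }
      )
    }
  }

  blockgroups <- data.frame(
    blockgroup_id = paste0(tract_id[bg_tract], bg_seq),
    tract_id = tract_id[bg_tract],
    state_code = state_code[bg_tract],
    population = population,
    housing_units = housing_units,
    group_quarters_pop = group_quarters_pop,
    census_error = census_error,
    stringsAsFactors = FALSE
  )
  for (item in adi_items()) blockgroups[[item]] <- vals[, item]

  # tract items: population-weighted means over member block groups
  bg_tract_f <- factor(bg_tract, levels = seq_len(nt))
  tract_pop <- as.vector(tapply(population, bg_tract_f, sum))
  tracts <- data.frame(
    tract_id = tract_id,
    state_code = state_code,
    population = as.integer(tract_pop),
    ruca_code = as.integer(ruca_code),
    urban = urban,
    stringsAsFactors = FALSE
  )
  for (item in svi_items()) {
    wsum <- as.vector(tapply(vals[, item] * population, bg_tract_f, sum))
    tracts[[item]] <- wsum / tract_pop
  }

  list(blockgroups = blockgroups, tracts = tracts)
}

#' ADI coefficients calibrated on a confound-free reference geography
#'
#' The deployed ADI applies factor score coefficients fixed by a historical
#' calibration, an era when housing costs tracked neighborhood deprivation
#' closely; urban housing markets have since decoupled from deprivation,
#' which is what lets housing-cost items distort the index today. This
#' helper reproduces that situation for synthetic studies: it estimates
#' coefficients by principal-axis factoring on a matched generator run with
#' the housing-market factor switched off (`housing_confound_strength = 0`,
#' `housing_urban_shift = 0`, same seed) and with the housing-cost items
#' loading strongly on the deprivation factor (`reference_housing_loading`),
#' so the resulting weights treat housing costs as a valid deprivation
#' signal. Applying them to a confounded geography emulates a fixed,
#' historically calibrated index.
#'
#' @param params The [synthetic_params()] of the study geography.
#' @param reference_housing_loading Calibration-era deprivation loadings of
#'   median home value, mortgage and gross rent.
#' @return Named numeric vector of 17 factor score coefficients, suitable for
#'   `adi_config(coefficients = )`.
#' @export
adi_reference_coefficients <- function(params,
                                       reference_housing_loading =
                                         c(median_home_value = -0.65,
                                           median_mortgage = -0.6,
                                           median_gross_rent = -0.55)) {
  ref <- params
  ref$housing_confound_strength <- 0
  ref$housing_urban_shift <- 0
  ref$deprivation_loading[names(reference_housing_loading)] <-
    reference_housing_loading
  geo <- generate_geography(ref)
  excl <- apply_exclusions(geo$blockgroups)
  estimate_adi_coefficients(geo$blockgroups[!excl$excluded, , drop = FALSE])
}
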