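#' Indicator item registry for the two deprivation indices
#'
#' The Area Deprivation Index (ADI) uses 17 block-group indicators of income,
#' education, employment and housing quality; the Social Vulnerability Index
#' (SVI) uses 15 tract indicators grouped into four themes. Five items are
#' shared, giving 27 unique items. Names are fixed snake_case column names
#' used by every reader, writer and scoring function in the package.
#'
#' @return Character vector of item names.
#' @export
adi_items <- function() {
  c(
    # income
    "pct_below_poverty", "pct_below_150_poverty", "income_disparity",
    "median_family_income",
    # employment
    "pct_unemployed", "pct_white_collar",
    # education
    "pct_hs_diploma_or_higher", "pct_less_than_9th_grade",
    # housing
    "pct_owner_occupied", "median_mortgage", "median_gross_rent",
    "median_home_value",
    # household characteristics
    "pct_single_parent", "pct_no_telephone", "pct_no_vehicle",
    "pct_no_plumbing",
    # housing type
    "pct_crowding"
  )
}

#' @rdname adi_items
#' @export
svi_items <- function() {
  c(
    # socioeconomic status
    "pct_below_poverty", "pct_unemployed", "per_capita_income",
    "pct_no_hs_diploma",
    # household composition & disability
    "pct_age_65_plus", "pct_age_17_under", "pct_disability",
    "pct_single_parent",
    # minority status & language
    "pct_minority", "pct_limited_english",
    # housing type & transportation
    "pct_multi_unit", "pct_mobile_homes", "pct_crowding",
    "pct_no_vehicle", "pct_group_quarters"
  )
}

#' @rdname adi_items
#' @export
all_items <- function() union(adi_items(), svi_items())

#' ADI items with negative factor loadings
#'
#' Items where a larger value indicates *less* deprivation (income, white
#' collar occupation, education, home ownership and the three housing-cost
#' items). Their factor score coefficients are negative in the weighted sum.
#'
#' @return Character vector, subset of [adi_items()].
#' @export
adi_negative_items <- function() {
  c(
    "median_family_income", "pct_white_collar", "pct_hs_diploma_or_higher",
    "pct_owner_occupied", "median_mortgage", "median_gross_rent",
    "median_home_value"
  )
}

#' Default SVI theme membership
#'
#' @return Named character vector mapping each of the 15 SVI items to one of
#'   the four themes: `socioeconomic_status`,
#'   `household_composition_disability`, `minority_status_language`,
#'   `housing_type_transportation`.
#' @export
svi_theme_map <- function() {
  c(
    pct_below_poverty = "socioeconomic_status",
    pct_unemployed = "socioeconomic_status",
    per_capita_income = "socioeconomic_status",
    pct_no_hs_diploma = "socioeconomic_status",
    pct_age_65_plus = "household_composition_disability",
    pct_age_17_under = "household_composition_disability",
    pct_disability = "household_composition_disability",
    pct_single_parent = "household_composition_disability",
    pct_minority = "minority_status_language",
    pct_limited_english = "minority_status_language",
    pct_multi_unit = "housing_type_transportation",
    pct_mobile_homes = "housing_type_transportation",
    pct_crowding = "housing_type_transportation",
    pct_no_vehicle = "housing_type_transportation",
    pct_group_quarters = "housing_type_transportation"
  )
}

#' Items measured in dollars (log-scale in the generator)
#' @keywords internal
dollar_items <- function() {
  c("median_family_income", "per_capita_income", "median_mortgage",
    "median_gross_rent", "median_home_value")
}

# Items where a LOWER value means MORE deprivation/vulnerability, used to
# orient percentile ranks so that higher rank = more deprived for every item.
lower_is_deprived_items <- function() {
  union(adi_negative_items(), "per_capita_income")
}
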