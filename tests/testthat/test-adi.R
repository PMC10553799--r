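bg_row <- function(housing_units, population, gq, census_error = FALSE, id = "b1") {
  df <- data.frame(blockgroup_id = id, tract_id = substr(id, 1, 2),
                   state_code = "S", population = population,
                   housing_units = housing_units, group_quarters_pop = gq,
                   census_error = census_error, stringsAsFactors = FALSE)
  for (item in adi_items()) df[[item]] <- 0.1
  df
}

test_that("exclusion rules use strict thresholds in the stated order", {
  ex <- function(...) apply_exclusions(bg_row(...))
  r <- ex(29, 500, 0)
  expect_true(r$excluded); expect_equal(r$exclusion_reason, "housing_units")
  r <- ex(200, 99, 0)
  expect_true(r$excluded); expect_equal(r$exclusion_reason, "population")
  # boundary cases that do NOT violate the strict inequalities
  r <- ex(30, 100, 33)
  expect_false(r$excluded); expect_equal(r$exclusion_reason, "none")
  # just above one third of the population in group quarters
  r <- ex(200, 300, 101)
  expect_true(r$excluded); expect_equal(r$exclusion_reason, "group_quarters")
  r <- ex(200, 300, 100)
  expect_false(r$excluded)
  # rule-order tie-break: housing-unit rule recorded first
  r <- ex(10, 99, 0)
  expect_equal(r$exclusion_reason, "housing_units")
  # census-error flag forces exclusion when nothing else does
  r <- ex(200, 500, 0, census_error = TRUE)
  expect_true(r$excluded); expect_equal(r$exclusion_reason, "census_error")
  # zero population is caught by the population rule, no division error
  r <- ex(200, 0, 0)
  expect_true(r$excluded); expect_equal(r$exclusion_reason, "population")
})

test_that("raw scores are the coefficient-weighted item sums", {
  set.seed(1)
  n <- 50
  bg <- do.call(rbind, lapply(seq_len(n), function(i)
    bg_row(100, 1000, 0, id = sprintf("t%02d%03d", i %% 7, i))))
  for (item in adi_items()) bg[[item]] <- runif(n)
  coef <- stats::setNames(rnorm(17), adi_items())

  raw <- compute_raw_adi(bg, adi_config(coefficients = coef),
                         standardize_items = FALSE)
  byhand <- apply(as.matrix(bg[, adi_items()]), 1, function(v) sum(coef * v))
  expect_equal(unname(raw), unname(byhand), tolerance = 1e-12)

  zero <- compute_raw_adi(bg, adi_config(
    coefficients = stats::setNames(rep(0, 17), adi_items())),
    standardize_items = FALSE)
  expect_true(all(zero == 0))

  one <- stats::setNames(rep(0, 17), adi_items())
  one["pct_below_poverty"] <- 2.5
  raw1 <- compute_raw_adi(bg, adi_config(coefficients = one),
                          standardize_items = FALSE)
  expect_equal(unname(raw1), 2.5 * bg$pct_below_poverty, tolerance = 1e-12)

  # a missing item value propagates, it is not silently zeroed
  bg2 <- bg
  bg2$pct_crowding[3] <- NA
  raw2 <- compute_raw_adi(bg2, adi_config(coefficients = coef),
                          standardize_items = FALSE)
  expect_true(is.na(raw2[3]))
  expect_false(anyNA(raw2[-3]))
})

test_that("standardization fixes mean 100 and SD 20", {
  set.seed(7)
  raw <- rnorm(500, 3, 9)
  s <- standardize_index(raw)
  expect_equal(mean(s), 100, tolerance = 1e-9)
  expect_equal(sd(s), 20, tolerance = 1e-9)

  # idempotence on an input already on the target scale
  expect_equal(standardize_index(s), s, tolerance = 1e-9)

  # closed forms for {0,1} under each SD convention
  expect_equal(standardize_index(c(0, 1)),
               c(100 - 20 / sqrt(2), 100 + 20 / sqrt(2)), tolerance = 1e-12)
  expect_equal(standardize_index(c(0, 1), adi_config(sd_type = "population")),
               c(80, 120), tolerance = 1e-12)

  expect_error(standardize_index(rep(4, 10)), "constant")
  expect_error(standardize_index(c(1, NA, NA)), "degenerate")
})

test_that("percentile ranks span 0-100 with average ranks for ties", {
  expect_equal(percentile_rank(c(5, 9)), c(0, 100))
  expect_equal(percentile_rank(c(1, 2, 2, 3)), c(0, 50, 50, 100))
  set.seed(11)
  x <- sample(1:40, 200, replace = TRUE)
  expect_equal(percentile_rank(x), oracle_percentile(x), tolerance = 1e-12)
  # unique extremes map exactly to the endpoints (100 = greatest deprivation)
  xu <- c(x, max(x) + 1, min(x) - 1)
  expect_equal(percentile_rank(xu)[which.max(xu)], 100)
  expect_equal(percentile_rank(xu)[which.min(xu)], 0)
  expect_error(percentile_rank(c(3, NA)), "degenerate")
  # NA values are preserved, not dropped
  p <- percentile_rank(c(1, NA, 3))
  expect_true(is.na(p[2])); expect_equal(p[c(1, 3)], c(0, 100))
})

test_that("percentiles and deciles are invariant to increasing transforms", {
  set.seed(13)
  x <- rnorm(250)
  for (f in list(function(v) 3 * v + 7, exp, function(v) v^3)) {
    expect_equal(percentile_rank(f(x)), percentile_rank(x), tolerance = 1e-9)
    expect_equal(assign_deciles(f(x)), assign_deciles(x))
  }
})

test_that("tract aggregation is the population-weighted mean over retained members", {
  bg <- tiny_blockgroups()
  # one tract with a single member: tract value equals the member's value
  pct <- c(37, NA, 20, 40, 10, 50)
  agg <- aggregate_to_tract(pct, bg)
  expect_equal(agg$value[agg$tract_id == "01001000001"], 37) # second member NA
  expect_equal(agg$value[agg$tract_id == "01001000002"], 30) # equal populations
  expect_equal(agg$value[agg$tract_id == "01001000003"],
               (2000 * 10 + 1000 * 50) / 3000)
  # hand-computed weighted mean with unequal weights
  bg2 <- bg[1:2, ]
  bg2$population <- c(100L, 300L)
  agg2 <- aggregate_to_tract(c(10, 50), bg2)
  expect_equal(agg2$value, 40)
  # all members excluded -> tract missing
  agg3 <- aggregate_to_tract(c(NA, NA), bg2)
  expect_true(agg3$missing)
  # aggregation bounds
  set.seed(2)
  bgn <- tiny_blockgroups()
  v <- runif(6, 0, 100)
  aggn <- aggregate_to_tract(v, bgn)
  for (i in seq_len(nrow(aggn))) {
    members <- v[bgn$tract_id == aggn$tract_id[i]]
    expect_gte(aggn$value[i], min(members))
    expect_lte(aggn$value[i], max(members))
  }
})

test_that("decile assignment matches a sort-and-slice oracle and stays balanced", {
  expect_equal(assign_deciles(c(30, 10, 50, 20, 90, 60, 40, 100, 70, 80)),
               c(3L, 1L, 5L, 2L, 9L, 6L, 4L, 10L, 7L, 8L))
  d20 <- assign_deciles(sample(seq_len(20)))
  expect_true(all(table(d20) == 2))
  set.seed(19)
  x <- c(rnorm(900), sample(rnorm(20), 100, replace = TRUE)) # many ties
  ids <- sprintf("u%04d", seq_along(x))
  expect_equal(assign_deciles(x, ids), oracle_decile(x, ids))
  # occupancy when n is not divisible by 10
  for (n in c(17, 95, 1003)) {
    occ <- table(assign_deciles(rnorm(n)))
    expect_true(all(occ %in% c(floor(n / 10), ceiling(n / 10))))
  }
  expect_error(assign_deciles(rnorm(9)), "degenerate")
})

test_that("estimated coefficients orient poverty positively and score sensibly", {
  p <- synthetic_params(n_states = 2, tracts_per_state = 80, seed = 31)
  geo <- generate_geography(p)
  coef <- estimate_adi_coefficients(geo$blockgroups)
  expect_named(coef, adi_items(), ignore.order = TRUE)
  expect_gt(coef[["pct_below_poverty"]], 0)
  # income and education coefficients pick up their negative orientation
  expect_lt(coef[["median_family_income"]], 0)
  expect_lt(coef[["pct_hs_diploma_or_higher"]], 0)

  adi <- compute_adi(geo$blockgroups)
  bs <- adi$blockgroup_scores
  expect_true(all(is.na(bs$raw[bs$excluded])))
  ok <- !bs$excluded
  expect_equal(mean(bs$standardized[ok]), 100, tolerance = 1e-9)
  expect_equal(sd(bs$standardized[ok]), 20, tolerance = 1e-9)
  expect_true(all(bs$percentile[ok] >= 0 & bs$percentile[ok] <= 100))
  # block groups in poorer latent tracts score as more deprived overall
  expect_gt(cor(bs$percentile[ok], geo$blockgroups$pct_below_poverty[ok]), 0.3)
  ts <- adi$tract_scores
  expect_true(all(ts$decile[!ts$missing] %in% 1:10))
})
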