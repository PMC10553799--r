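# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

oracle_rank <- function(x) {
  vapply(x, function(xi) (sum(x < xi) + 1 + sum(x <= xi)) / 2, numeric(1))
}

oracle_percentile <- function(x, scale = 100) {
  r <- oracle_rank(x)
  scale * (r - 1) / (length(x) - 1)
}

oracle_decile <- function(x, ids = seq_along(x)) {
  n <- length(x)
  ord <- order(x, ids)
  bounds <- floor(seq_len(10) * n / 10)
  dec_sorted <- vapply(seq_len(n), function(r) which(r <= bounds)[1], integer(1))
  out <- integer(n)
  out[ord] <- dec_sorted
  out
}

oracle_crosstab <- function(adi_dec, svi_dec) {
  m <- matrix(0L, 10, 10)
  for (k in seq_along(adi_dec))
    m[adi_dec[k], svi_dec[k]] <- m[adi_dec[k], svi_dec[k]] + 1L
  m
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_spearman <- function(x, y) oracle_pearson(oracle_rank(x), oracle_rank(y))

oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

oracle_cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  (mean(x) - mean(y)) / sp
}

# small handmade geography: 3 tracts in 1 state, hand-set counts
tiny_blockgroups <- function() {
  set.seed(42)
  n <- 6
  df <- data.frame(
    blockgroup_id = sprintf("0100100000%d%d", rep(1:3, each = 2), rep(1:2, 3)),
    tract_id = rep(sprintf("0100100000%d", 1:3), each = 2),
    state_code = "S01",
    population = c(500L, 1500L, 800L, 800L, 2000L, 1000L),
    housing_units = c(200L, 600L, 300L, 320L, 700L, 400L),
    group_quarters_pop = c(0L, 10L, 5L, 0L, 20L, 0L),
    census_error = FALSE,
    stringsAsFactors = FALSE
  )
  for (item in adi_items()) {
    df[[item]] <- if (grepl("^pct_|^income", item)) runif(n, 0.01, 0.6)
    else runif(n, 500, 300000)
  }
  df
}

# a paired agreement-record fixture with hand-assigned deciles and values
handmade_records <- function() {
  data.frame(
    tract_id = sprintf("T%02d", 1:10),
    adi_value = c(95, 91, 88, 15, 5, 50, 45, 99, 2, 60),
    svi_value = c(0.97, 0.30, 0.92, 0.85, 0.05, 0.55, 0.50, 0.99, 0.70, 0.10),
    adi_decile = c(10L, 10L, 9L, 2L, 1L, 5L, 4L, 10L, 1L, 6L),
    svi_decile = c(10L, 3L, 9L, 8L, 1L, 6L, 5L, 10L, 7L, 2L),
    state_code = rep(c("S01", "S02"), 5),
    urban = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# default mechanism-study conditions (strong urban housing confound)
mechanism_params <- function(strength, seed) {
  synthetic_params(housing_confound_strength = strength,
                   urban_probability = 0.3, seed = seed)
}

run_agreement <- function(params, coefficients = NULL) {
  geo <- generate_geography(params)
  adi <- compute_adi(geo$blockgroups, adi_config(coefficients = coefficients))
  svi <- compute_svi(geo$tracts)
  rec <- classify_agreement(
    pair_indices(adi$tract_scores, svi$tract_scores, geo$tracts, quiet = TRUE))
  list(records = rec, geo = geo, adi = adi, svi = svi)
}
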