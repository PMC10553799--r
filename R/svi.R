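#' Configuration for Social Vulnerability Index construction
#'
#' @param theme_map Named character vector mapping each of the 15 SVI items
#'   to its theme; default [svi_theme_map()].
#' @param directions Named character vector over the 15 items with values
#'   `"higher_is_vulnerable"` or `"lower_is_vulnerable"`. By default per
#'   capita income is the only reversed item.
#' @param overall_from `"theme_sums"` (default; the overall score ranks the
#'   sum of the four theme sums, i.e. the sum of all 15 item percentiles) or
#'   `"theme_percentiles"` (ranks the sum of the four theme percentile
#'   rankings instead).
#' @return A list of class `svi_config`.
#' @export
svi_config <- function(theme_map = svi_theme_map(),
                       directions = NULL,
                       overall_from = c("theme_sums", "theme_percentiles")) {
  if (is.null(directions)) {
    directions <- stats::setNames(
      rep("higher_is_vulnerable", length(svi_items())), svi_items())
    directions["per_capita_income"] <- "lower_is_vulnerable"
  }
  items <- names(theme_map)
  if (length(items) != 15 || anyDuplicated(items))
    stop("config error: theme_map must cover exactly 15 distinct items")
  if (length(unique(theme_map)) != 4)
    stop("config error: theme_map must use four non-empty themes")
  if (!setequal(names(directions), items))
    stop("config error: directions must cover the theme_map items")
  structure(list(theme_map = theme_map, directions = directions,
                 overall_from = match.arg(overall_from)),
            class = "svi_config")
}

#' Directional item percentile ranks for SVI
#'
#' For each item, computes `(rank - 1) / (n - 1)` with average ranks for
#' ties across tracts, after orienting the item so a larger transformed value
#' means more vulnerability (per capita income is rank-reversed).
#'
#' @param tracts Tract table with `tract_id` and the 15 SVI item columns.
#' @param config An [svi_config()].
#' @return Data frame: `tract_id` plus one percentile column per item, all
#'   values in `[0, 1]`; tracts with a missing item get `NA` for that item.
#' @export
svi_rank_items <- function(tracts, config = svi_config()) {
  items <- names(config$theme_map)
  missing_cols <- setdiff(items, names(tracts))
  if (length(missing_cols))
    stop("schema error: tract table lacks item columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tracts) < 2)
    stop("degenerate input: need at least 2 tracts to rank")
  out <- data.frame(tract_id = tracts$tract_id, stringsAsFactors = FALSE)
  for (item in items) {
    v <- tracts[[item]]
    if (config$directions[[item]] == "lower_is_vulnerable") v <- -v
    out[[item]] <- percentile_rank(v, scale = 1)
  }
  out
}

#' Theme sums and theme percentile rankings
#'
#' Item percentiles are summed within each of the four themes; the theme sums
#' are then percentile-ranked across tracts.
#'
#' @param item_percentiles Output of [svi_rank_items()].
#' @param config An [svi_config()].
#' @return List of two data frames keyed by `tract_id`: `theme_sums` and
#'   `theme_percentiles`, one column per theme.
#' @export
svi_theme_scores <- function(item_percentiles, config = svi_config()) {
  themes <- unique(unname(config$theme_map))
  sums <- data.frame(tract_id = item_percentiles$tract_id,
                     stringsAsFactors = FALSE)
  pcts <- sums
  for (th in themes) {
    th_items <- names(config$theme_map)[config$theme_map == th]
    M <- as.matrix(item_percentiles[, th_items, drop = FALSE])
    s <- rowSums(M) # NA if any member item missing
    sums[[th]] <- s
    pcts[[th]] <- percentile_rank(s, scale = 1)
  }
  list(theme_sums = sums, theme_percentiles = pcts)
}

#' Overall SVI score and percentile ranking
#'
#' The overall sum adds the four theme sums (equivalently, all 15 item
#' percentiles); the overall percentile is its rank across tracts, in
#' `[0, 1]` with the maximum at 1.
#'
#' @param theme_scores Output of [svi_theme_scores()].
#' @param config An [svi_config()]; `overall_from = "theme_percentiles"`
#'   ranks the sum of theme percentile rankings instead of theme sums.
#' @return Data frame with `tract_id`, `overall_sum`, `overall_percentile`.
#' @export
svi_overall <- function(theme_scores, config = svi_config()) {
  base <- if (config$overall_from == "theme_sums")
    theme_scores$theme_sums else theme_scores$theme_percentiles
  s <- rowSums(as.matrix(base[, -1, drop = FALSE]))
  data.frame(tract_id = base$tract_id,
             overall_sum = s,
             overall_percentile = percentile_rank(s, scale = 1),
             stringsAsFactors = FALSE)
}

#' End-to-end SVI construction
#'
#' Directional item percentile ranking, theme sums and rankings, overall
#' percentile ranking and decile assignment, at the tract level.
#'
#' @param tracts Tract table with `tract_id` and the 15 SVI item columns.
#' @param config An [svi_config()].
#' @return List with `item_percentiles`, `theme_sums`, `theme_percentiles`
#'   and `tract_scores` (tract_id, overall_sum, overall_percentile, decile,
#'   missing).
#' @export
compute_svi <- function(tracts, config = svi_config()) {
  ip <- svi_rank_items(tracts, config)
  th <- svi_theme_scores(ip, config)
  ov <- svi_overall(th, config)
  ov$decile <- assign_deciles(ov$overall_percentile, ov$tract_id)
  ov$missing <- is.na(ov$overall_percentile)
  list(item_percentiles = ip,
       theme_sums = th$theme_sums,
       theme_percentiles = th$theme_percentiles,
       tract_scores = ov)
}
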