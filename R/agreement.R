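#' Decile-difference thresholds defining good and poor index agreement
#'
#' Good agreement is a 0-1 decile difference between a tract's ADI and SVI
#' deciles; poor agreement is a difference of at least 6 deciles.
#'
#' @param good_max_delta Largest decile difference still classed `good`
#'   (default 1).
#' @param poor_min_delta Smallest decile difference classed `poor`
#'   (default 6).
#' @return A list of class `agreement_thresholds`.
#' @export
agreement_thresholds <- function(good_max_delta = 1L, poor_min_delta = 6L) {
  good_max_delta <- as.integer(good_max_delta)
  poor_min_delta <- as.integer(poor_min_delta)
  if (!(0 <= good_max_delta && good_max_delta < poor_min_delta &&
        poor_min_delta <= 9))
    stop("config error: need 0 <= good_max_delta < poor_min_delta <= 9")
  structure(list(good_max_delta = good_max_delta,
                 poor_min_delta = poor_min_delta),
            class = "agreement_thresholds")
}

#' Pair tract-level ADI and SVI scores
#'
#' Inner-joins the two score tables on `tract_id` and drops tracts missing
#' either index (the dropped count is reported via a message). Optionally
#' carries state and urban attributes.
#'
#' @param tract_adi ADI tract table (`tract_id`, `value` in 0-100, `decile`).
#' @param tract_svi SVI tract table (`tract_id`, `overall_percentile` in 0-1,
#'   `decile`).
#' @param tracts Optional tract attribute table supplying `state_code` and
#'   `urban`.
#' @param quiet Suppress the dropped-tract message.
#' @return Data frame of agreement records: `tract_id`, `adi_value`,
#'   `svi_value`, `adi_decile`, `svi_decile`, `delta`, plus `state_code` and
#'   `urban` when available.
#' @export
pair_indices <- function(tract_adi, tract_svi, tracts = NULL, quiet = FALSE) {
  adi <- data.frame(tract_id = tract_adi$tract_id,
                    adi_value = tract_adi$value,
                    adi_decile = tract_adi$decile,
                    stringsAsFactors = FALSE)
  svi <- data.frame(tract_id = tract_svi$tract_id,
                    svi_value = tract_svi$overall_percentile,
                    svi_decile = tract_svi$decile,
                    stringsAsFactors = FALSE)
  m <- merge(adi, svi, by = "tract_id")
  n_union <- length(union(adi$tract_id, svi$tract_id))
  keep <- !is.na(m$adi_value) & !is.na(m$svi_value) &
    !is.na(m$adi_decile) & !is.na(m$svi_decile)
  dropped <- n_union - sum(keep)
  if (dropped > 0 && !quiet)
    message(sprintf("pair_indices: dropped %d tract(s) lacking one index", dropped))
  m <- m[keep, , drop = FALSE]
  m$delta <- abs(m$adi_decile - m$svi_decile)
  if (!is.null(tracts)) {
    attrs <- intersect(c("state_code", "urban"), names(tracts))
    m <- merge(m, tracts[, c("tract_id", attrs), drop = FALSE],
               by = "tract_id", all.x = TRUE)
  }
  m <- m[order(m$tract_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Spearman rank correlation with average ranks
#'
#' Pearson correlation of average ranks; pairs with a missing member are
#' dropped first. Returns `NA` when either sequence is constant.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("degenerate input: need at least 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  unname(stats::cor(x[ok], y[ok], method = "spearman"))
}

#' 10 x 10 decile cross-tabulation of paired index scores
#'
#' @param records Agreement records from [pair_indices()].
#' @return 10 x 10 integer matrix; rows are ADI deciles 1-10, columns SVI
#'   deciles 1-10, cells are tract counts.
#' @export
decile_crosstab <- function(records) {
  tab <- table(factor(records$adi_decile, levels = 1:10),
               factor(records$svi_decile, levels = 1:10))
  m <- matrix(as.integer(tab), 10, 10,
              dimnames = list(adi_decile = 1:10, svi_decile = 1:10))
  m
}

#' Classify tract-level index agreement
#'
#' @param records Agreement records from [pair_indices()].
#' @param thresholds An [agreement_thresholds()].
#' @return `records` with an added `agreement_class` column
#'   (`good`/`intermediate`/`poor`).
#' @export
classify_agreement <- function(records, thresholds = agreement_thresholds()) {
  if (is.null(records$delta))
    records$delta <- abs(records$adi_decile - records$svi_decile)
  cls <- ifelse(records$delta <= thresholds$good_max_delta, "good",
                ifelse(records$delta >= thresholds$poor_min_delta, "poor",
                       "intermediate"))
  records$agreement_class <- cls
  records
}

#' National agreement summary
#'
#' @param records Classified agreement records.
#' @return List: `n_total`, `share_good`, `share_poor`, `rho_continuous`
#'   (Spearman correlation of the continuous index values) and `rho_decile`
#'   (of the decile scores), all on the identical tract set.
#' @export
agreement_summary <- function(records) {
  n <- nrow(records)
  list(
    n_total = n,
    share_good = mean(records$agreement_class == "good"),
    share_poor = mean(records$agreement_class == "poor"),
    rho_continuous = spearman_rho(records$adi_value, records$svi_value),
    rho_decile = spearman_rho(records$adi_decile, records$svi_decile)
  )
}

#' Printed-arithmetic helper: gap between two reported group means
#'
#' Both means are rounded to one decimal before differencing, matching how
#' reported mean gaps are computed from published group means.
#'
#' @param mean_adi Mean ADI score (0-100 scale).
#' @param mean_svi_x100 Mean SVI score multiplied by 100.
#' @return Absolute difference of the rounded means.
#' @export
comparison_gap <- function(mean_adi, mean_svi_x100) {
  abs(round(mean_adi, 1) - round(mean_svi_x100, 1))
}

#' Printed-arithmetic helper: subgroup share of an anchor decile
#'
#' @param n_subgroup,n_anchor Tract counts.
#' @param digits Rounding applied to the percentage (default 1).
#' @return Share of the anchor count as a percentage.
#' @export
subgroup_share_pct <- function(n_subgroup, n_anchor, digits = 1) {
  round(100 * n_subgroup / n_anchor, digits)
}

#' Extreme-decile comparison groups (1a-4b)
#'
#' Four comparisons anchor on the extreme deciles: I = top ADI decile, II =
#' top SVI decile, III = bottom ADI decile, IV = bottom SVI decile. Within
#' each anchor set, subgroup `a` holds the good-agreement tracts and `b` the
#' poor-agreement tracts, and mean index scores are compared (SVI scaled by
#' 100; the reported gap differences the means after rounding to 1 decimal).
#'
#' @param records Classified agreement records.
#' @return Data frame of 8 rows with columns `label`, `anchor_index`, `tail`,
#'   `subgroup`, `n_anchor`, `n_subgroup`, `share`, `share_all`, `mean_adi`,
#'   `mean_svi_x100`, `abs_difference`, `gap_unrounded`.
#' @export
build_comparisons <- function(records) {
  spec <- data.frame(
    comparison = c("I", "I", "II", "II", "III", "III", "IV", "IV"),
    label = c("1a", "1b", "2a", "2b", "3a", "3b", "4a", "4b"),
    anchor_index = c("ADI", "ADI", "SVI", "SVI", "ADI", "ADI", "SVI", "SVI"),
    tail = c("top", "top", "top", "top", "bottom", "bottom", "bottom", "bottom"),
    subgroup = rep(c("good", "poor"), 4),
    stringsAsFactors = FALSE
  )
  n_total <- nrow(records)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    anchor_decile <- if (s$tail == "top") 10L else 1L
    anchor <- if (s$anchor_index == "ADI")
      records$adi_decile == anchor_decile else records$svi_decile == anchor_decile
    n_anchor <- sum(anchor)
    sub <- records[anchor & records$agreement_class == s$subgroup, , drop = FALSE]
    n_sub <- nrow(sub)
    mean_adi <- if (n_sub) mean(sub$adi_value) else NA_real_
    mean_svi <- if (n_sub) 100 * mean(sub$svi_value) else NA_real_
    data.frame(
      s,
      n_anchor = n_anchor,
      n_subgroup = n_sub,
      share = if (n_anchor) n_sub / n_anchor else NA_real_,
      share_all = if (n_total) n_sub / n_total else NA_real_,
      mean_adi = mean_adi,
      mean_svi_x100 = mean_svi,
      abs_difference = if (n_sub) comparison_gap(mean_adi, mean_svi) else NA_real_,
      gap_unrounded = if (n_sub) abs(mean_adi - mean_svi) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Good/poor agreement counts by state
#'
#' @param records Classified agreement records carrying `state_code`.
#' @return Data frame per state: `n_total`, `n_good`, `n_poor`.
#' @export
summarize_by_state <- function(records) {
  if (is.null(records$state_code))
    stop("schema error: records lack state_code")
  states <- sort(unique(records$state_code))
  f <- factor(records$state_code, levels = states)
  data.frame(
    state_code = states,
    n_total = as.integer(table(f)),
    n_good = as.integer(tapply(records$agreement_class == "good", f, sum)),
    n_poor = as.integer(tapply(records$agreement_class == "poor", f, sum)),
    stringsAsFactors = FALSE
  )
}

#' Marginal decile counts diagnostic
#'
#' Tract counts of one index's extreme decile across the other index's
#' deciles: the non-monotone shape of these margins is what motivates the
#' poor-agreement cutoff.
#'
#' @param records Agreement records.
#' @param anchor_index `"ADI"` or `"SVI"`.
#' @param anchor_decile Extreme decile of the anchor index (default 10).
#' @return Integer vector of length 10: counts by the other index's decile.
#' @export
decile_margin_counts <- function(records, anchor_index = c("ADI", "SVI"),
                                 anchor_decile = 10L) {
  anchor_index <- match.arg(anchor_index)
  in_anchor <- if (anchor_index == "ADI")
    records$adi_decile == anchor_decile else records$svi_decile == anchor_decile
  other <- if (anchor_index == "ADI")
    records$svi_decile[in_anchor] else records$adi_decile[in_anchor]
  as.integer(table(factor(other, levels = 1:10)))
}
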