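#' Tract-level table of all 27 unique index items
#'
#' SVI items are taken from the tract table directly; ADI-only items are
#' population-weighted means of the block-group values over each tract's
#' members.
#'
#' @param blockgroups Block-group table with the 17 ADI item columns.
#' @param tracts Tract table with the 15 SVI item columns.
#' @return Data frame keyed by `tract_id` with one column per unique item,
#'   on each item's native scale.
#' @export
tract_item_table <- function(blockgroups, tracts) {
  out <- tracts[, c("tract_id", svi_items()), drop = FALSE]
  adi_only <- setdiff(adi_items(), svi_items())
  f <- factor(blockgroups$tract_id, levels = out$tract_id)
  den <- as.vector(tapply(blockgroups$population, f, sum))
  for (item in adi_only) {
    num <- as.vector(tapply(blockgroups$population * blockgroups[[item]], f, sum))
    out[[item]] <- num / den
  }
  out
}

#' Deprivation-oriented percentile ranks of item values across tracts
#'
#' Each item is percentile-ranked across tracts on a 0-100 scale, oriented so
#' a higher rank means more deprivation (income, education, white-collar,
#' home-ownership and housing-cost items are rank-reversed).
#'
#' @param item_table Output of [tract_item_table()].
#' @return Data frame of the same shape with percentile ranks in `[0, 100]`.
#' @export
item_percentile_table <- function(item_table) {
  out <- item_table["tract_id"]
  for (item in setdiff(names(item_table), "tract_id")) {
    v <- item_table[[item]]
    if (item %in% lower_is_deprived_items()) v <- -v
    out[[item]] <- percentile_rank(v, scale = 100)
  }
  out
}

#' Item-by-item comparison of poor- vs good-agreement tracts
#'
#' Two-sided Welch (unequal-variance) t-test per item, with Cohen's d =
#' (mean_poor - mean_good) / pooled SD, pooled SD =
#' sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)). Items whose values all
#' lie in [0, 1] are multiplied by 100 before comparison when
#' `scale01_x100 = TRUE`, so proportions are reported in percent.
#'
#' @param poor_group,good_group Data frames of tract item values (one row per
#'   tract) holding the columns in `items`.
#' @param items Item columns to compare; defaults to the shared columns.
#' @param scale01_x100 Rescale items bounded in `[0, 1]` to percent.
#' @param var_equal Use Student's pooled-variance t-test instead of Welch.
#' @param d_denominator `"pooled"` (classic Cohen, default) or `"glass"`
#'   (control = good group SD).
#' @return Data frame: item, n_poor, n_good, mean_poor, mean_good,
#'   t_statistic, degrees_freedom, p_value, cohens_d, effect_class.
#' @export
compare_items <- function(poor_group, good_group, items = NULL,
                          scale01_x100 = TRUE, var_equal = FALSE,
                          d_denominator = c("pooled", "glass")) {
  d_denominator <- match.arg(d_denominator)
  if (is.null(items))
    items <- setdiff(intersect(names(poor_group), names(good_group)), "tract_id")
  rows <- lapply(items, function(item) {
    x <- poor_group[[item]]
    y <- good_group[[item]]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (scale01_x100 && length(c(x, y)) &&
        all(c(x, y) >= 0) && all(c(x, y) <= 1)) {
      x <- 100 * x
      y <- 100 * y
    }
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2)
      return(data.frame(item = item, n_poor = n1, n_good = n2,
                        mean_poor = if (n1) mean(x) else NA_real_,
                        mean_good = if (n2) mean(y) else NA_real_,
                        t_statistic = NA_real_, degrees_freedom = NA_real_,
                        p_value = NA_real_, cohens_d = NA_real_,
                        effect_class = NA_character_,
                        stringsAsFactors = FALSE))
    tt <- tryCatch(stats::t.test(x, y, var.equal = var_equal),
                   error = function(e) NULL)
    s_pooled <- switch(d_denominator,
      pooled = sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
                      (n1 + n2 - 2)),
      glass = stats::sd(y))
    d <- if (is.na(s_pooled) || s_pooled == 0) NA_real_
         else (mean(x) - mean(y)) / s_pooled
    data.frame(
      item = item, n_poor = n1, n_good = n2,
      mean_poor = mean(x), mean_good = mean(y),
      t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      degrees_freedom = if (is.null(tt)) NA_real_ else unname(tt$parameter),
      p_value = if (is.null(tt)) NA_real_ else tt$p.value,
      cohens_d = d,
      effect_class = classify_effect(d),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a Cohen's d effect size
#'
#' `|d| < 0.20` negligible, `0.20 <= |d| < 0.50` small, `0.50 <= |d| < 0.80`
#' medium, `|d| >= 0.80` large.
#'
#' @param d Numeric vector of signed effect sizes.
#' @return Character vector of classes; `NA` in gives `NA` out.
#' @export
classify_effect <- function(d) {
  a <- abs(d)
  ifelse(is.na(a), NA_character_,
         ifelse(a < 0.20, "negligible",
                ifelse(a < 0.50, "small",
                       ifelse(a < 0.80, "medium", "large"))))
}

#' Flag the items driving poor agreement
#'
#' A driver is an item with a significant mean comparison (p < `alpha`) and a
#' large effect size (|d| >= 0.80). No multiple-testing adjustment is applied
#' by default; `adjust = "BH"` applies Benjamini-Hochberg before the
#' significance cut.
#'
#' @param comparisons Output of [compare_items()].
#' @param alpha Significance level (default 0.05).
#' @param adjust `p.adjust` method, `"none"` by default.
#' @return `comparisons` with added `p_used` and `is_driver` columns.
#' @export
select_drivers <- function(comparisons, alpha = 0.05, adjust = "none") {
  p <- stats::p.adjust(comparisons$p_value, method = adjust)
  comparisons$p_used <- p
  comparisons$is_driver <- !is.na(p) & p < alpha &
    !is.na(comparisons$effect_class) & comparisons$effect_class == "large"
  comparisons
}

#' Driver analysis for one extreme-decile comparison
#'
#' Splits the anchor decile of one comparison (I-IV) into its poor- and
#' good-agreement subgroups and runs [compare_items()] on both the native
#' item scale and the deprivation-oriented percentile-rank scale, flagging
#' drivers on the native scale.
#'
#' @param records Classified agreement records.
#' @param item_table Output of [tract_item_table()].
#' @param comparison `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param ... Passed to [compare_items()] / [select_drivers()].
#' @return List with `native` and `percentile` comparison tables and the
#'   subgroup sizes.
#' @export
driver_analysis <- function(records, item_table,
                            comparison = c("I", "II", "III", "IV"), ...) {
  comparison <- match.arg(comparison)
  anchor_index <- switch(comparison, I = "ADI", II = "SVI", III = "ADI", IV = "SVI")
  anchor_decile <- switch(comparison, I = 10L, II = 10L, III = 1L, IV = 1L)
  dec <- if (anchor_index == "ADI") records$adi_decile else records$svi_decile
  anchor <- records[dec == anchor_decile, , drop = FALSE]
  poor_ids <- anchor$tract_id[anchor$agreement_class == "poor"]
  good_ids <- anchor$tract_id[anchor$agreement_class == "good"]
  pct_table <- item_percentile_table(item_table)
  pick <- function(tbl, ids) tbl[match(ids, tbl$tract_id), , drop = FALSE]
  native <- select_drivers(
    compare_items(pick(item_table, poor_ids), pick(item_table, good_ids), ...))
  percentile <- select_drivers(
    compare_items(pick(pct_table, poor_ids), pick(pct_table, good_ids),
                  scale01_x100 = FALSE))
  list(comparison = comparison, n_poor = length(poor_ids),
       n_good = length(good_ids), native = native, percentile = percentile)
}

#' Urban tract fractions by comparison subgroup
#'
#' @param records Classified agreement records carrying an `urban` flag.
#' @return Data frame per comparison x subgroup: `n`, `n_urban`,
#'   `urban_share`.
#' @export
urban_fractions <- function(records) {
  if (is.null(records$urban)) stop("schema error: records lack urban flag")
  spec <- expand.grid(comparison = c("I", "II", "III", "IV"),
                      subgroup = c("good", "poor"),
                      stringsAsFactors = FALSE)
  spec <- spec[order(spec$comparison, spec$subgroup), ]
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    cmp <- spec$comparison[i]
    anchor_index <- switch(cmp, I = "ADI", II = "SVI", III = "ADI", IV = "SVI")
    anchor_decile <- switch(cmp, I = 10L, II = 10L, III = 1L, IV = 1L)
    dec <- if (anchor_index == "ADI") records$adi_decile else records$svi_decile
    sub <- records[dec == anchor_decile &
                     records$agreement_class == spec$subgroup[i], , drop = FALSE]
    n <- nrow(sub)
    nu <- sum(sub$urban, na.rm = TRUE)
    data.frame(comparison = cmp, subgroup = spec$subgroup[i], n = n,
               n_urban = nu, urban_share = if (n) nu / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
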