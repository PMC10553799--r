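# CSV schemas (fixed headers, see read_blockgroups/read_tracts):
#   blockgroups.csv: blockgroup_id,tract_id,state_code,population,
#     housing_units,group_quarters_pop,census_error,<17 ADI items>
#   tracts.csv: tract_id,state_code,population,ruca_code,<15 SVI items>

bg_schema <- function() {
  c("blockgroup_id", "tract_id", "state_code", "population", "housing_units",
    "group_quarters_pop", "census_error", adi_items())
}

tract_schema <- function() {
  c("tract_id", "state_code", "population", "ruca_code", svi_items())
}

# print doubles with enough digits that read.csv recovers them exactly
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_
    else if (is.finite(v) && v == round(v) && abs(v) < 2^53) sprintf("%.0f", v)
    else sprintf("%.17g", v)
  }, character(1))
  out
}

write_schema_csv <- function(df, path, numeric_cols) {
  out <- df
  for (col in intersect(numeric_cols, names(out)))
    out[[col]] <- fmt_num(as.numeric(out[[col]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a synthetic geography as fixture CSVs
#'
#' Emits `blockgroups.csv` and `tracts.csv` in the package's fixed schemas
#' (plus `geography.csv` linking block groups to tracts and states). Numeric
#' values are written with full precision so the files round-trip losslessly
#' through [read_blockgroups()] and [read_tracts()].
#'
#' @param geo List with `blockgroups` and `tracts` from
#'   [generate_geography()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(geo, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bg_path <- file.path(dir, "blockgroups.csv")
  tr_path <- file.path(dir, "tracts.csv")
  geo_path <- file.path(dir, "geography.csv")
  bg <- geo$blockgroups[, bg_schema(), drop = FALSE]
  tr <- geo$tracts[, tract_schema(), drop = FALSE]
  write_schema_csv(bg, bg_path,
                   c("population", "housing_units", "group_quarters_pop",
                     adi_items()))
  write_schema_csv(tr, tr_path, c("population", "ruca_code", svi_items()))
  geog <- geo$blockgroups[, c("blockgroup_id", "tract_id", "state_code",
                              "population")]
  if (nrow(geog) > 0 && nrow(geo$tracts) > 0)
    geog$urban <- geo$tracts$urban[match(geog$tract_id, geo$tracts$tract_id)]
  else geog$urban <- logical(nrow(geog))
  write_schema_csv(geog, geo_path, "population")
  invisible(c(blockgroups = bg_path, tracts = tr_path, geography = geo_path))
}

check_columns <- function(df, required, path) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
}

flag_nonnumeric <- function(df, cols, path, quiet) {
  n_flagged <- 0L
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(as.character(v)))
      bad <- !is.na(as.character(v)) & nzchar(trimws(as.character(v))) & is.na(parsed)
      n_flagged <- n_flagged + sum(bad)
      df[[col]] <- parsed
    }
  }
  if (n_flagged > 0 && !quiet)
    message(sprintf("%s: flagged %d unparseable value(s) as missing",
                    basename(path), n_flagged))
  df
}

#' Read a block-group indicator CSV
#'
#' Validates the fixed schema, parses numerics (unparseable values become
#' `NA` with a logged count rather than dropped rows), and derives `tract_id`
#' from 12-digit block-group identifiers when the column is absent.
#'
#' @param path CSV path.
#' @param quiet Suppress the flagged-row message.
#' @return Block-group data frame.
#' @export
read_blockgroups <- function(path, quiet = FALSE) {
  # identifiers keep leading zeros; numeric columns are parsed explicitly
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!"tract_id" %in% names(df) && "blockgroup_id" %in% names(df))
    df$tract_id <- substr(df$blockgroup_id, 1, 11)
  check_columns(df, setdiff(bg_schema(), "census_error"), path)
  if (!"census_error" %in% names(df)) df$census_error <- FALSE
  df$tract_id <- as.character(df$tract_id)
  df$state_code <- as.character(df$state_code)
  df <- flag_nonnumeric(df, c("population", "housing_units",
                              "group_quarters_pop", adi_items()), path, quiet)
  df$census_error <- isTRUE_vec(df$census_error)
  df[, bg_schema(), drop = FALSE]
}

#' Read a tract indicator CSV
#'
#' Validates the fixed schema, parses numerics, and maps the RUCA code to an
#' urban flag.
#'
#' @param path CSV path.
#' @param ruca_urban_codes RUCA codes classified urban (default 1-3).
#' @param quiet Suppress the flagged-row message.
#' @return Tract data frame with an added `urban` logical column.
#' @export
read_tracts <- function(path, ruca_urban_codes = c(1L, 2L, 3L), quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  check_columns(df, tract_schema(), path)
  df$tract_id <- as.character(df$tract_id)
  df$state_code <- as.character(df$state_code)
  df <- flag_nonnumeric(df, c("population", "ruca_code", svi_items()),
                        path, quiet)
  df$urban <- df$ruca_code %in% ruca_urban_codes
  df[, c(tract_schema(), "urban"), drop = FALSE]
}

#' Export agreement records as a GeoJSON feature collection
#'
#' One feature per tract with the decile pair, decile difference and
#' agreement class as properties. Geometries are optional: supply a named
#' list of GeoJSON geometry objects keyed by tract id, or `geometry =
#' "grid"` to lay tracts out as synthetic unit grid-cell polygons
#' (longitude/latitude order, closed rings). Tracts without a matching
#' geometry get `geometry: null` with a warning.
#'
#' @param records Classified agreement records.
#' @param geometry `NULL`, `"grid"`, or a named list of geometry objects.
#' @param path Optional output file; when given, the JSON is written there.
#' @return The feature collection as a list (invisibly when `path` given).
#' @export
export_geojson <- function(records, geometry = NULL, path = NULL) {
  if (identical(geometry, "grid")) geometry <- grid_geometry(records$tract_id)
  n_missing_geom <- 0L
  features <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    geom <- NULL
    if (!is.null(geometry)) {
      geom <- geometry[[r$tract_id]]
      if (is.null(geom)) n_missing_geom <<- n_missing_geom + 1L
    }
    props <- list(
      tract_id = r$tract_id,
      adi_decile = r$adi_decile,
      svi_decile = r$svi_decile,
      delta = r$delta,
      agreement_class = r$agreement_class
    )
    if (!is.null(r$state_code)) props$state_code <- r$state_code
    if (!is.null(r$urban)) props$urban <- r$urban
    list(type = "Feature", properties = props, geometry = geom)
  })
  if (n_missing_geom > 0)
    warning(sprintf("export_geojson: %d tract(s) had no matching geometry",
                    n_missing_geom))
  fc <- list(type = "FeatureCollection", features = features)
  if (!is.null(path)) {
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(fc))
  }
  fc
}

#' Synthetic grid-cell polygons for tract ids
#'
#' Lays tracts out row-major on a near-square grid of 0.01-degree cells near
#' the origin; used to give synthetic runs mappable geometries.
#'
#' @param tract_ids Character vector of tract ids.
#' @return Named list of GeoJSON Polygon geometry objects.
#' @export
grid_geometry <- function(tract_ids) {
  n <- length(tract_ids)
  if (n == 0) return(list())
  ncol_grid <- ceiling(sqrt(n))
  cell <- 0.01
  geoms <- lapply(seq_len(n) - 1L, function(k) {
    x0 <- (k %% ncol_grid) * cell
    y0 <- (k %/% ncol_grid) * cell
    ring <- list(c(x0, y0), c(x0 + cell, y0), c(x0 + cell, y0 + cell),
                 c(x0, y0 + cell), c(x0, y0))
    list(type = "Polygon", coordinates = list(ring))
  })
  stats::setNames(geoms, tract_ids)
}

#' Assemble a pipeline run configuration
#'
#' @param blockgroup_csv,tract_csv Input CSV paths.
#' @param output_dir Output directory.
#' @param adi An [adi_config()].
#' @param svi An [svi_config()].
#' @param thresholds An [agreement_thresholds()].
#' @param ruca_urban_codes RUCA codes classed urban.
#' @param seed Integer seed recorded in the manifest.
#' @param quiet Suppress INFO messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(blockgroup_csv, tract_csv, output_dir,
                       adi = adi_config(), svi = svi_config(),
                       thresholds = agreement_thresholds(),
                       ruca_urban_codes = c(1L, 2L, 3L),
                       seed = 1L, quiet = FALSE) {
  structure(list(blockgroup_csv = blockgroup_csv, tract_csv = tract_csv,
                 output_dir = output_dir, adi = adi, svi = svi,
                 thresholds = thresholds,
                 ruca_urban_codes = as.integer(ruca_urban_codes),
                 seed = as.integer(seed), quiet = quiet),
            class = "run_config")
}

#' Run the full index-agreement pipeline
#'
#' Reads the block-group and tract tables, constructs ADI and SVI, pairs and
#' classifies tract agreement, builds the decile cross-tab, the 8-row
#' extreme-decile comparison table, the driver tables for all four
#' comparisons, the state summary, urban fractions and a GeoJSON export, and
#' writes every table plus a JSON run manifest under `output_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every computed table and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  blockgroups <- stage("read_blockgroups",
                       read_blockgroups(config$blockgroup_csv, quiet = config$quiet))
  tracts <- stage("read_tracts",
                  read_tracts(config$tract_csv, config$ruca_urban_codes,
                              quiet = config$quiet))

  adi <- stage("adi", compute_adi(blockgroups, config$adi))
  svi <- stage("svi", compute_svi(tracts, config$svi))
  records <- stage("agreement", {
    r <- pair_indices(adi$tract_scores, svi$tract_scores, tracts,
                      quiet = config$quiet)
    classify_agreement(r, config$thresholds)
  })
  summary <- agreement_summary(records)
  crosstab <- decile_crosstab(records)
  comparisons <- build_comparisons(records)
  states <- summarize_by_state(records)
  urban <- urban_fractions(records)
  item_table <- stage("drivers", tract_item_table(blockgroups, tracts))
  drivers <- lapply(c(I = "I", II = "II", III = "III", IV = "IV"),
                    function(cmp) driver_analysis(records, item_table, cmp))

  # outputs
  p <- function(f) file.path(out_dir, f)
  num_cols <- function(df) names(df)[vapply(df, is.numeric, logical(1))]
  wr <- function(df, f) write_schema_csv(df, p(f), num_cols(df))
  wr(adi$blockgroup_scores, "adi_blockgroups.csv")
  wr(adi$tract_scores, "adi_tracts.csv")
  wr(svi$tract_scores, "svi_tracts.csv")
  wr(records, "agreement.csv")
  ct <- as.data.frame.matrix(crosstab)
  ct <- cbind(adi_decile = rownames(crosstab), ct, total = rowSums(crosstab))
  ct <- rbind(ct, c(adi_decile = "total", as.list(colSums(crosstab)),
                    total = sum(crosstab)))
  utils::write.csv(ct, p("crosstab.csv"), row.names = FALSE, quote = FALSE)
  wr(comparisons, "comparisons.csv")
  wr(states, "state_summary.csv")
  wr(urban, "urban_fractions.csv")
  for (cmp in names(drivers)) {
    wr(drivers[[cmp]]$native, sprintf("drivers_%s_native.csv", cmp))
    wr(drivers[[cmp]]$percentile, sprintf("drivers_%s_percentile.csv", cmp))
  }
  export_geojson(records, geometry = "grid", path = p("agreement.geojson"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("deprindex")),
    seed = config$seed,
    thresholds = list(good_max_delta = config$thresholds$good_max_delta,
                      poor_min_delta = config$thresholds$poor_min_delta),
    n_blockgroups = nrow(blockgroups),
    n_blockgroups_excluded = sum(adi$blockgroup_scores$excluded),
    exclusion_reasons = as.list(table(
      adi$blockgroup_scores$exclusion_reason[adi$blockgroup_scores$excluded])),
    n_tracts_input = nrow(tracts),
    n_tracts_paired = summary$n_total,
    n_tracts_dropped = nrow(tracts) - summary$n_total,
    share_good = summary$share_good,
    share_poor = summary$share_poor,
    rho_continuous = summary$rho_continuous,
    rho_decile = summary$rho_decile
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!config$quiet)
    message(sprintf(
      "pipeline: %d block groups (%d excluded), %d tracts paired (%d dropped)",
      manifest$n_blockgroups, manifest$n_blockgroups_excluded,
      manifest$n_tracts_paired, manifest$n_tracts_dropped))

  invisible(list(adi = adi, svi = svi, records = records, summary = summary,
                 crosstab = crosstab, comparisons = comparisons,
                 states = states, urban = urban, drivers = drivers,
                 manifest = manifest))
}
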