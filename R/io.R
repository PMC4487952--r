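# CSV interfaces.  Schemas:
#   consumption.csv: year,item_id,production_kg,imports_kg,exports_kg
#   items.csv:       item_id,land_category,world_yield_kg_per_ha
#   population.csv:  year,population
#   areas.csv:       year,land_category,total_area_ha
#   factors.csv:     land_category,yield_factor,equivalence_factor
#   indicators.csv:  year,indicator_id,value
#   indicator_meta.csv: indicator_id,layer,polarity,description

#' Read the footprint-accounting inputs from a directory
#'
#' Expects `consumption.csv`, `items.csv`, `population.csv`, `areas.csv`
#' and optionally `factors.csv` (falling back to the packaged default
#' factor table).
#'
#' @param dir Directory containing the CSV files.
#' @return List with `consumption`, `population`, `areas`, `items`,
#'   `factors` ready for [run_efa()].
#' @export
read_efa_inputs <- function(dir) {
  rd <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  consumption <- rd("consumption.csv")
  names(consumption) <- sub("_kg$", "", names(consumption))
  items <- rd("items.csv")
  names(items) <- sub("^world_yield_kg_per_ha$", "world_yield", names(items))
  areas <- rd("areas.csv")
  names(areas) <- sub("^total_area_ha$", "total_area", names(areas))
  factors <- if (file.exists(file.path(dir, "factors.csv"))) {
    factor_table(rd("factors.csv"))
  } else {
    default_factor_table()
  }
  list(consumption = consumption, population = rd("population.csv"),
       areas = areas, items = items, factors = factors)
}

#' Write synthetic panels in the CSV input schemas
#'
#' Writes the output of [gen_efa_panels()] (and optionally
#' [gen_ism_panel()]) to a directory in the same schemas
#' [read_efa_inputs()] and [read_indicator_panel()] consume.
#'
#' @param panels List from [gen_efa_panels()].
#' @param dir Output directory (created if needed).
#' @param ism Optional list from [gen_ism_panel()].
#' @return `dir`, invisibly.
#' @export
write_scenario_panels <- function(panels, dir, ism = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)
  cons <- panels$consumption
  names(cons) <- c("year", "item_id", "production_kg", "imports_kg",
                   "exports_kg")
  wr(cons, "consumption.csv")
  items <- panels$items
  names(items) <- c("item_id", "land_category", "world_yield_kg_per_ha")
  wr(items, "items.csv")
  wr(panels$population, "population.csv")
  areas <- panels$areas
  names(areas) <- c("year", "land_category", "total_area_ha")
  wr(areas, "areas.csv")
  if (!is.null(ism)) {
    x <- ism$matrix
    long <- data.frame(year = as.integer(rep(rownames(x), ncol(x))),
                       indicator_id = rep(colnames(x), each = nrow(x)),
                       value = as.vector(x))
    wr(long, "indicators.csv")
    wr(ism$meta, "indicator_meta.csv")
  }
  invisible(dir)
}

#' Read a year-by-indicator panel and its metadata
#'
#' @param values_path CSV `year,indicator_id,value`.
#' @param meta_path CSV `indicator_id,layer,polarity[,description]`;
#'   default: the packaged 20-indicator metadata.
#' @return List with `matrix` (judgement matrix) and `meta`.
#' @export
read_indicator_panel <- function(values_path, meta_path = NULL) {
  panel <- read.csv(values_path, stringsAsFactors = FALSE)
  meta <- if (is.null(meta_path)) {
    read.csv(system.file("extdata", "indicator_meta.csv", package = "landcc",
                         mustWork = TRUE), stringsAsFactors = FALSE)
  } else {
    read.csv(meta_path, stringsAsFactors = FALSE)
  }
  list(matrix = judgement_matrix(panel), meta = meta)
}

#' Write a footprint ledger to CSV and JSON
#'
#' Writes `ledger.csv` (per year and land category), `totals.csv` (per
#' year) and a JSON mirror `ledger.json`.
#'
#' @param ledger A `footprint_ledger` from [run_efa()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ledger <- function(ledger, dir) {
  stopifnot(inherits(ledger, "footprint_ledger"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(ledger$cells, file.path(dir, "ledger.csv"), row.names = FALSE)
  write.csv(ledger$totals, file.path(dir, "totals.csv"), row.names = FALSE)
  jsonlite::write_json(list(cells = as.list(ledger$cells),
                            totals = as.list(ledger$totals),
                            set_aside = ledger$set_aside),
                       file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write an index-system series to CSV and JSON
#'
#' Writes `lcc_series.csv` (year, layer scores, integrated score, grade),
#' `weights.csv` and a JSON mirror `lcc_series.json`.
#'
#' @param series An `lcc_series` from [run_ism()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_lcc_series <- function(series, dir) {
  stopifnot(inherits(series, "lcc_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(series$series, file.path(dir, "lcc_series.csv"),
            row.names = FALSE)
  write.csv(series$weights, file.path(dir, "weights.csv"), row.names = FALSE)
  jsonlite::write_json(list(series = as.list(series$series),
                            weights = as.list(series$weights)),
                       file.path(dir, "lcc_series.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
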