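# Comparative reporting: trend classification of the footprint ledger and
# the side-by-side EFA vs ISM report.  The renderer never recomputes:
# every number in a report traces to a ledger or series cell.

#' Classify surplus/deficit trends per land category
#'
#' Labels each land category by the sign of its ecological balance in the
#' last year and the first-to-last change: a deficit that grows more
#' negative is "widening deficit", a surplus that shrinks is "narrowing
#' surplus", and a change smaller than `tolerance` is "stable".
#'
#' @param ledger A `footprint_ledger` from [run_efa()], or its `cells`
#'   data frame.
#' @param tolerance Absolute change (ha per capita) below which a series
#'   counts as stable.  Default 1e-6.
#' @return Data frame `land_category`, `first_year`, `last_year`,
#'   `first_balance`, `last_balance`, `change`, `label`.
#' @export
classify_trends <- function(ledger, tolerance = 1e-6) {
  cells <- if (inherits(ledger, "footprint_ledger")) ledger$cells
           else as.data.frame(ledger)
  years <- sort(unique(cells$year))
  if (length(years) < 2) {
    stop("trend classification needs at least two years", call. = FALSE)
  }
  first <- cells[cells$year == years[1], ]
  last <- cells[cells$year == years[length(years)], ]
  cats <- unique(cells$land_category)
  out <- data.frame(
    land_category = cats,
    first_year = years[1],
    last_year = years[length(years)],
    first_balance = first$balance[match(cats, first$land_category)],
    last_balance = last$balance[match(cats, last$land_category)]
  )
  out$change <- out$last_balance - out$first_balance
  out$label <- ifelse(
    abs(out$change) < tolerance, "stable",
    ifelse(out$last_balance < 0,
           ifelse(out$change < 0, "widening deficit", "narrowing deficit"),
           ifelse(out$change > 0, "widening surplus", "narrowing surplus")))
  out
}

#' Comparative report of the two assessments
#'
#' Joins the footprint ledger's yearly totals with the index system's
#' yearly scores over their overlapping years, attaches the per-category
#' trend classification, and derives concordance notes (e.g. a widening
#' total deficit alongside a rising integrated score).  The report is
#' assembled strictly from the two inputs; no new quantities are computed.
#'
#' @param ledger A `footprint_ledger` from [run_efa()].
#' @param series An `lcc_series` from [run_ism()].
#' @param tolerance Passed to [classify_trends()].
#' @return An `lcc_report`: list with `years` (joined yearly table),
#'   `trends` (per-category classification) and `notes` (character).
#' @export
#' @examples
#' cfg <- scenario_config(seed = 1)
#' panels <- gen_efa_panels(cfg)
#' ledger <- run_efa(panels$consumption, panels$population, panels$areas,
#'                   panels$items)
#' panel <- gen_ism_panel(cfg)
#' compare_assessments(ledger, run_ism(panel$matrix, panel$meta))
compare_assessments <- function(ledger, series, tolerance = 1e-6) {
  stopifnot(inherits(ledger, "footprint_ledger"),
            inherits(series, "lcc_series"))
  s <- series$series
  common <- intersect(ledger$totals$year, s$year)
  if (length(common) == 0) {
    stop("ledger and series have no overlapping years", call. = FALSE)
  }
  common <- sort(common)
  tot <- ledger$totals[match(common, ledger$totals$year), ]
  srow <- s[match(common, s$year), ]
  years <- data.frame(year = common,
                      pef_II = tot$pef_II, pbc = tot$pbc,
                      balance_II = tot$balance_II,
                      F = srow$F, grade = srow$grade)
  rownames(years) <- NULL

  single <- length(common) < 2
  trends <- if (single) NULL else {
    cells <- ledger$cells[ledger$cells$year %in% common, ]
    classify_trends(cells, tolerance)
  }

  notes <- character(0)
  if (!single) {
    d_bal <- years$balance_II[nrow(years)] - years$balance_II[1]
    d_f <- years$F[nrow(years)] - years$F[1]
    bal_dir <- if (abs(d_bal) < tolerance) "stable" else
      if (d_bal < 0) "widening" else "narrowing"
    f_dir <- if (abs(d_f) < tolerance) "stable" else
      if (d_f > 0) "rising" else "falling"
    notes <- c(notes, paste0(
      "Total ecological balance (line II) is ", bal_dir,
      " while the integrated index score is ", f_dir,
      " over ", years$year[1], "-", years$year[nrow(years)], "."))
    widening <- trends$land_category[trends$label == "widening deficit"]
    if (length(widening) > 0) {
      notes <- c(notes, paste0("Categories with widening deficits: ",
                               paste(widening, collapse = ", "), "."))
    }
  }

  structure(list(years = years, trends = trends, notes = notes),
            class = "lcc_report")
}

# Canonical list form used for (de)serialization; column-oriented so the
# JSON round-trips byte-identically.
.report_to_list <- function(report) {
  list(years = as.list(report$years),
       trends = if (is.null(report$trends)) NULL else as.list(report$trends),
       notes = as.list(report$notes))
}

.list_to_report <- function(x) {
  structure(list(
    years = as.data.frame(x$years, stringsAsFactors = FALSE),
    trends = if (is.null(x$trends) || length(x$trends) == 0) NULL
             else as.data.frame(x$trends, stringsAsFactors = FALSE),
    notes = as.character(unlist(x$notes))
  ), class = "lcc_report")
}

#' Write a comparative report
#'
#' `"json"` writes a machine-readable mirror that [read_report()] parses
#' back to an identical object (serialize-parse-serialize is
#' byte-identical); `"md"` writes the rendered text.
#'
#' @param report An `lcc_report` from [compare_assessments()].
#' @param path Output file path.
#' @param format `"json"` (default) or `"md"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "md")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "lcc_report"))
  if (format == "json") {
    jsonlite::write_json(.report_to_list(report), path,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  } else {
    writeLines(format(report), path)
  }
  invisible(path)
}

#' Read back a JSON comparative report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return An `lcc_report`.
#' @export
read_report <- function(path) {
  .list_to_report(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE))
}

#' @export
format.lcc_report <- function(x, digits = 2, ...) {
  fmt_df <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) & names(df) != "year"
    df[num] <- lapply(df[num], round, digits = digits)
    utils::capture.output(print(df, row.names = FALSE))
  }
  out <- c("# Land carrying capacity: footprint vs index assessment", "",
           "## Yearly totals and scores", "", fmt_df(x$years), "")
  if (!is.null(x$trends)) {
    out <- c(out, "## Ecological balance trends by land category", "",
             fmt_df(x$trends), "")
  }
  if (length(x$notes) > 0) {
    out <- c(out, "## Notes", "", paste0("- ", x$notes))
  }
  out
}

#' @export
print.lcc_report <- function(x, ...) {
  cat(format(x, ...), sep = "\n")
  invisible(x)
}
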