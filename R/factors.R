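#' Canonical biologically productive land categories
#'
#' Six land categories spanning supply and demand in ecological footprint
#' accounting.  `fossil_energy` is the hypothetical land needed to absorb
#' CO2 from fossil-fuel combustion; it carries demand only (its yield
#' factor is 0 in the default factor table, so it never contributes
#' biocapacity).
#'
#' @return Character vector of the six category names.
#' @export
#' @examples
#' land_categories()
land_categories <- function() {
  c("arable", "forest", "pasture", "fishery", "built_up", "fossil_energy")
}

#' Construct and validate a factor table
#'
#' A factor table holds, per land category, the yield factor (regional
#' productivity relative to a reference average) and the equivalence factor
#' (category productivity relative to the all-land average), both
#' dimensionless.  They make footprint and biocapacity areas comparable
#' across categories and regions.
#'
#' @param x Data frame with columns `land_category`, `yield_factor`,
#'   `equivalence_factor`, covering all six [land_categories()] exactly once.
#' @return The validated data frame, classed `"factor_table"`, with rows
#'   ordered as [land_categories()].
#' @export
#' @examples
#' factor_table(default_factor_table())
factor_table <- function(x) {
  x <- as.data.frame(x)
  need <- c("land_category", "yield_factor", "equivalence_factor")
  if (!all(need %in% names(x))) {
    stop("factor table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cats <- land_categories()
  if (!setequal(x$land_category, cats) || anyDuplicated(x$land_category)) {
    stop("factor table must cover each of the six land categories exactly once",
         call. = FALSE)
  }
  x <- x[match(cats, x$land_category), need]
  rownames(x) <- NULL
  if (any(!is.finite(x$yield_factor)) || any(x$yield_factor < 0)) {
    stop("yield factors must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(x$equivalence_factor)) || any(x$equivalence_factor <= 0)) {
    stop("equivalence factors must be finite and > 0", call. = FALSE)
  }
  class(x) <- c("factor_table", "data.frame")
  x
}

#' Default yield and equivalence factors
#'
#' The packaged factor set used throughout the examples and the synthetic
#' scenario: provincial NPP-based yield factors together with the standard
#' global equivalence factors, as used in Chinese city footprint accounting.
#' Fossil energy land has yield factor 0 (demand-only: a hypothetical land
#' with no real supply).
#'
#' @return A [factor_table()].
#' @export
#' @examples
#' default_factor_table()
default_factor_table <- function() {
  path <- system.file("extdata", "factors.csv", package = "landcc",
                      mustWork = TRUE)
  factor_table(read.csv(path, stringsAsFactors = FALSE))
}

# Internal: named lookup vectors from a factor table.
.factor_lookup <- function(factors, what = c("equivalence_factor", "yield_factor")) {
  what <- match.arg(what)
  setNames(factors[[what]], factors$land_category)
}
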