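#' Packaged reference constants
#'
#' Loads the constants packaged with landcc: the default factor table, the
#' 20-indicator metadata (three criterion layers with polarities), the
#' published reference table of index weights and normalized values for a
#' coastal Chinese city panel (2000, 2005, 2012 observed; 2015, 2020, 2030
#' projected), and the five-level grading standard.  The loader validates
#' the tables (weights sum to 1, normalized values in \[0, 1\], bins
#' partition \[0, 1\]) and fails on corrupted package data.
#'
#' @return List with elements `factors` ([factor_table()]), `meta`
#'   (indicator metadata data frame), `ism_reference` (data frame
#'   `indicator_id`, `layer`, `weight`, `nv_2000` ... `nv_2030`), and
#'   `grade_scale` ([grade_scale()]).
#' @export
#' @examples
#' fx <- lcc_fixtures()
#' fx$factors
lcc_fixtures <- function() {
  meta <- read.csv(system.file("extdata", "indicator_meta.csv",
                               package = "landcc", mustWork = TRUE),
                   stringsAsFactors = FALSE)
  ref <- read.csv(system.file("extdata", "ism_reference.csv",
                              package = "landcc", mustWork = TRUE),
                  stringsAsFactors = FALSE)
  nv <- as.matrix(ref[, grep("^nv_", names(ref))])
  if (!setequal(ref$indicator_id, meta$indicator_id) ||
      abs(sum(ref$weight) - 1) > 1e-6 ||
      any(ref$weight < 0) || any(nv < 0 | nv > 1)) {
    stop("packaged reference table failed integrity checks", call. = FALSE)
  }
  list(factors = default_factor_table(),
       meta = meta,
       ism_reference = ref,
       grade_scale = default_grade_scale())
}

#' Normalized matrix from the packaged reference table
#'
#' Reshapes the reference table's normalized-value columns into a
#' years-by-indicators matrix, the same shape [normalize_indicators()]
#' produces, so the scoring stages can be run directly from the published
#' normalized values (bypassing projection and normalization).
#'
#' @param ref The `ism_reference` element of [lcc_fixtures()].
#' @return Numeric matrix with rownames the reference years and colnames
#'   the indicator ids.
#' @export
ref_normalized_matrix <- function(ref = lcc_fixtures()$ism_reference) {
  nv_cols <- grep("^nv_", names(ref), value = TRUE)
  y <- t(as.matrix(ref[, nv_cols]))
  dimnames(y) <- list(sub("^nv_", "", nv_cols), ref$indicator_id)
  y
}

#' Weight vector from the packaged reference table
#'
#' @inheritParams ref_normalized_matrix
#' @return Named numeric vector of published index weights.
#' @export
ref_weight_vector <- function(ref = lcc_fixtures()$ism_reference) {
  setNames(ref$weight, ref$indicator_id)
}
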