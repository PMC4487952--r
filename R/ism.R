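#' Build a judgement matrix from a long indicator panel
#'
#' @param panel Data frame `year`, `indicator_id`, `value` with one record
#'   per cell.
#' @return Numeric matrix, one row per year (rownames = years), one column
#'   per indicator, with no missing cells.
#' @export
judgement_matrix <- function(panel) {
  panel <- as.data.frame(panel)
  years <- sort(unique(panel$year))
  ids <- unique(panel$indicator_id)
  x <- matrix(NA_real_, length(years), length(ids),
              dimnames = list(years, ids))
  x[cbind(match(panel$year, years), match(panel$indicator_id, ids))] <-
    panel$value
  if (anyNA(x)) {
    stop("judgement matrix has missing cells; every (year, indicator) pair ",
         "must be observed", call. = FALSE)
  }
  x
}

# Internal: validate meta against a matrix's columns; returns meta reordered.
.check_meta <- function(x, meta) {
  meta <- as.data.frame(meta)
  need <- c("indicator_id", "layer", "polarity")
  if (!all(need %in% names(meta))) {
    stop("indicator metadata needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(colnames(x), meta$indicator_id)
  if (length(missing) > 0) {
    stop("no metadata for indicator(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(meta$polarity %in% c("positive", "negative"))) {
    stop("polarity must be 'positive' or 'negative'", call. = FALSE)
  }
  meta[match(colnames(x), meta$indicator_id), ]
}

#' Min-max normalize a judgement matrix with indicator polarity
#'
#' Rescales every indicator column to \[0, 1\] so that 1 is always the best
#' observed condition: positive indicators (larger is better) map through
#' `(x - min) / (max - min)`; negative indicators (larger is worse) through
#' `(max - x) / (max - min)`.  A constant column is degenerate under
#' min-max scaling; it is set to 0.5 with a warning, and receives weight 0
#' downstream (zero dispersion), so the 0.5 never influences scores.
#'
#' @param x Judgement matrix (years by indicators), >= 2 rows.
#' @param meta Data frame `indicator_id`, `layer`, `polarity` covering every
#'   column of `x`.
#' @return Matrix of the same shape with entries in \[0, 1\].
#' @export
#' @examples
#' x <- cbind(C1 = c(2, 4, 6))
#' rownames(x) <- 2000:2002
#' meta <- data.frame(indicator_id = "C1", layer = "B1", polarity = "positive")
#' normalize_indicators(x, meta)
normalize_indicators <- function(x, meta) {
  if (nrow(x) < 2) stop("need at least two years to normalize", call. = FALSE)
  meta <- .check_meta(x, meta)
  y <- x
  constant <- character(0)
  for (j in seq_len(ncol(x))) {
    lo <- min(x[, j]); hi <- max(x[, j])
    if (hi == lo) {
      y[, j] <- 0.5
      constant <- c(constant, colnames(x)[j])
    } else if (meta$polarity[j] == "positive") {
      y[, j] <- (x[, j] - lo) / (hi - lo)
    } else {
      y[, j] <- (hi - x[, j]) / (hi - lo)
    }
  }
  if (length(constant) > 0) {
    warning("constant indicator column(s) set to 0.5 (zero dispersion, ",
            "weight 0): ", paste(constant, collapse = ", "), call. = FALSE)
  }
  y
}

#' Dispersion-based (mean-squared-error) indicator weights
#'
#' Weights each indicator by how much its normalized values vary across
#' years: an indicator that hardly changes carries little information about
#' the trajectory and gets little weight.  Per column the dispersion is the
#' root mean squared deviation from the column mean (the population standard
#' deviation); weights are dispersions normalized to sum to 1.
#'
#' @param y Normalized matrix from [normalize_indicators()], >= 2 rows.
#' @param dispersion `"sd"` (default): root mean squared deviation;
#'   `"ssd"`: plain sum of squared deviations, for sensitivity analysis of
#'   the radical convention.
#' @return Named numeric vector of weights, one per column, summing to 1.
#' @export
#' @examples
#' y <- cbind(A = c(0, 1), B = c(0, 0.5))
#' mse_weights(y)  # 2/3, 1/3
mse_weights <- function(y, dispersion = c("sd", "ssd")) {
  dispersion <- match.arg(dispersion)
  if (nrow(y) < 2) stop("need at least two years to weight", call. = FALSE)
  dev2 <- colSums((y - rep(colMeans(y), each = nrow(y)))^2)
  s <- switch(dispersion, sd = sqrt(dev2 / nrow(y)), ssd = dev2)
  if (sum(s) == 0) {
    stop("every indicator column is constant; dispersion weighting is ",
         "undefined", call. = FALSE)
  }
  s / sum(s)
}

#' Criterion-layer score
#'
#' Weight-inclusive partial sum of Eq-10 type aggregation over one criterion
#' layer: `sum_{j in layer} Y_ij * W_j` per year.  Because the weights are
#' global (not renormalized within the layer), the three layer scores add up
#' exactly to the integrated score.
#'
#' @param y Normalized matrix (years by indicators).
#' @param weights Named weight vector covering the layer's indicators.
#' @param meta Indicator metadata with `indicator_id` and `layer`.
#' @param layer Layer id to score (e.g. `"B2"`).
#' @return Named numeric vector, one score per year (row of `y`).
#' @export
layer_score <- function(y, weights, meta, layer) {
  meta <- as.data.frame(meta)
  ids <- meta$indicator_id[meta$layer == layer]
  if (length(ids) == 0) stop("unknown layer: ", layer, call. = FALSE)
  missing <- setdiff(ids, intersect(colnames(y), names(weights)))
  if (length(missing) > 0) {
    stop("normalized values or weights missing for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  drop(y[, ids, drop = FALSE] %*% weights[ids])
}

#' Integrated carrying-capacity score
#'
#' The weighted sum `F_i = sum_j Y_ij * W_j` per year.  With weights summing
#' to 1 and normalized values in \[0, 1\], `F` lies in \[0, 1\].
#'
#' @param y Normalized matrix (years by indicators).
#' @param weights Named weight vector covering all columns of `y`.
#' @return Named numeric vector of scores, one per year.
#' @export
integrated_lcc <- function(y, weights) {
  missing <- setdiff(colnames(y), names(weights))
  if (length(missing) > 0) {
    stop("weights missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  drop(y %*% weights[colnames(y)])
}

#' Construct and validate a grading scale
#'
#' @param x Data frame with columns `lower`, `upper`, `label`, whose bins
#'   partition \[0, 1\] with no gaps or overlaps (ascending).  Bins are
#'   closed below and open above; the top bin is closed.
#' @return The validated data frame, classed `"grade_scale"`.
#' @export
grade_scale <- function(x) {
  x <- as.data.frame(x)
  need <- c("lower", "upper", "label")
  if (!all(need %in% names(x))) {
    stop("grade scale needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x <- x[order(x$lower), need]
  rownames(x) <- NULL
  ok <- nrow(x) >= 1 && x$lower[1] == 0 && x$upper[nrow(x)] == 1 &&
    all(x$upper > x$lower) &&
    (nrow(x) == 1 || all(x$lower[-1] == x$upper[-nrow(x)]))
  if (!ok) {
    stop("grade bins must partition [0, 1] with no gaps or overlaps",
         call. = FALSE)
  }
  class(x) <- c("grade_scale", "data.frame")
  x
}

#' Default five-level grading standard
#'
#' Scores in \[0, 1\] map to five ordinal classes: 0-0.2 Weakest,
#' 0.2-0.4 Weak, 0.4-0.6 Medium, 0.6-0.8 Strong, 0.8-1 Strongest.
#' Boundaries belong to the upper bin (0.6 grades "Strong", 0.8
#' "Strongest").
#'
#' @return A [grade_scale()].
#' @export
default_grade_scale <- function() {
  path <- system.file("extdata", "grades.csv", package = "landcc",
                      mustWork = TRUE)
  grade_scale(read.csv(path, stringsAsFactors = FALSE))
}

#' Grade an integrated score
#'
#' @param score Numeric score(s) in \[0, 1\].
#' @param scale A [grade_scale()]; default [default_grade_scale()].
#' @return Character vector of grade labels.
#' @export
#' @examples
#' lcc_grade(c(0.58, 0.758))  # "Medium", "Strong"
lcc_grade <- function(score, scale = default_grade_scale()) {
  scale <- grade_scale(scale)
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  scale$label[findInterval(score, scale$lower)]
}

#' Project indicators linearly to future years
#'
#' Fits, per indicator, an ordinary least-squares line of raw value against
#' year and evaluates it at the target years, under the assumption that
#' every indicator follows a linear change over time.  Historical rows are
#' returned unchanged, with projected rows appended.
#'
#' @param x Judgement matrix (years by indicators), >= 2 rows.
#' @param target_years Integer vector of years to project to (years already
#'   present are ignored).
#' @return Extended matrix with one appended row per new target year.
#' @export
#' @examples
#' x <- cbind(C1 = c(1, 2, 3))
#' rownames(x) <- 2000:2002
#' project_indicators(x, 2003)
project_indicators <- function(x, target_years) {
  if (nrow(x) < 2) {
    stop("need at least two historical years to project", call. = FALSE)
  }
  years <- as.numeric(rownames(x))
  if (anyNA(years)) stop("matrix rownames must be years", call. = FALSE)
  new_years <- sort(setdiff(as.numeric(target_years), years))
  if (length(new_years) == 0) return(x)
  yc <- years - mean(years)
  slope <- colSums(yc * x) / sum(yc^2)
  intercept <- colMeans(x) - slope * mean(years)
  proj <- outer(new_years, slope) + rep(intercept, each = length(new_years))
  dimnames(proj) <- list(new_years, colnames(x))
  rbind(x, proj)
}

#' Run the full index system pipeline
#'
#' Pipeline: project raw indicators to target years (OLS lines), min-max
#' normalize jointly over history and projections, derive dispersion-based
#' weights from the full normalized matrix, score the three criterion layers
#' and the integrated index per year, and grade each year's score.
#'
#' @param x Judgement matrix (years by indicators).
#' @param meta Indicator metadata (`indicator_id`, `layer`, `polarity`).
#' @param target_years Optional years to project to; `NULL` for none.
#' @param scale A [grade_scale()]; default [default_grade_scale()].
#' @param dispersion Passed to [mse_weights()].
#' @return An `lcc_series`: list with
#'   * `series`: data frame `year`, one column per layer, `F`, `grade`,
#'     `projected` (logical);
#'   * `weights`: data frame `indicator_id`, `layer`, `weight`;
#'   * `normalized`: the normalized matrix used.
#' @export
#' @examples
#' panel <- gen_ism_panel(scenario_config(seed = 1))
#' run_ism(panel$matrix, panel$meta, target_years = c(2015, 2020, 2030))
run_ism <- function(x, meta, target_years = NULL,
                    scale = default_grade_scale(),
                    dispersion = c("sd", "ssd")) {
  meta <- .check_meta(x, meta)
  hist_years <- as.numeric(rownames(x))
  if (!is.null(target_years)) x <- project_indicators(x, target_years)
  y <- normalize_indicators(x, meta)
  w <- mse_weights(y, dispersion)
  layers <- unique(meta$layer)
  series <- data.frame(year = as.numeric(rownames(y)))
  for (lay in layers) series[[lay]] <- layer_score(y, w, meta, lay)
  series$F <- integrated_lcc(y, w)
  series$grade <- lcc_grade(pmin(pmax(series$F, 0), 1), scale)
  series$projected <- !(series$year %in% hist_years)
  rownames(series) <- NULL
  weights <- data.frame(indicator_id = names(w),
                        layer = meta$layer[match(names(w), meta$indicator_id)],
                        weight = unname(w))
  structure(list(series = series, weights = weights, normalized = y),
            class = "lcc_series")
}

#' @export
print.lcc_series <- function(x, digits = 2, ...) {
  s <- x$series
  cat("Integrated land carrying capacity, ", min(s$year), "-", max(s$year),
      if (any(s$projected)) " (projections marked)", "\n\n", sep = "")
  num <- vapply(s, is.numeric, logical(1)) & names(s) != "year"
  s[num] <- lapply(s[num], round, digits = digits)
  print(s, row.names = FALSE)
  invisible(x)
}
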