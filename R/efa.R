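#' Per-capita annual consumption of an item
#'
#' Apparent consumption per head: `(production + imports - exports) /
#' population`.  A negative result (exports exceeding local supply plus
#' imports) is returned as-is with a data-quality warning; downstream
#' footprint aggregation floors such contributions at zero, since a region
#' cannot exert negative land demand.
#'
#' @param production,imports,exports Annual flows in kg (or a consistent
#'   physical unit per item).  Vectorized.
#' @param population Persons; must be > 0.
#' @return Per-capita consumption, same unit as the flows per person.
#' @export
#' @examples
#' per_capita_consumption(1000, 200, 100, 50)  # 22
per_capita_consumption <- function(production, imports, exports, population) {
  if (any(!is.finite(population)) || any(population <= 0)) {
    stop("population must be finite and > 0", call. = FALSE)
  }
  out <- (production + imports - exports) / population
  if (any(out < 0)) {
    warning("negative net consumption (exports exceed production + imports) ",
            "for ", sum(out < 0), " record(s); region is a net exporter ",
            "of the item", call. = FALSE)
  }
  out
}

#' Footprint component of one consumption item
#'
#' Converts per-capita consumption into the biologically productive area
#' needed to produce it, by dividing by the item's world-average yield.
#'
#' @param consumption Per-capita consumption (kg per capita).
#' @param world_yield World-average yield of the item (kg per hectare);
#'   must be > 0.
#' @return Per-capita actual biologically productive land, ha per capita.
#' @export
#' @examples
#' component_footprint(22, 2750)  # 0.008
component_footprint <- function(consumption, world_yield) {
  if (any(!is.finite(world_yield)) || any(world_yield <= 0)) {
    stop("world_yield must be finite and > 0", call. = FALSE)
  }
  consumption / world_yield
}

#' Per-capita ecological footprint from item components
#'
#' Aggregates item-level footprint components into equivalence-weighted
#' demand: `sum_j e_j * sum_i aa_i` over the included land categories.
#' Footprint I excludes fossil energy land (`include_fossil = FALSE`);
#' footprint II includes it.  Negative components (net-exported items) are
#' floored at zero before aggregation.
#'
#' @param components Data frame with columns `land_category` and `aa`
#'   (per-item footprint component, ha per capita).
#' @param factors A [factor_table()].
#' @param include_fossil Include the fossil-energy category?  Default `TRUE`
#'   (footprint II).
#' @return List with `total` (ha per capita) and `by_category` (data frame
#'   `land_category`, `pef` over the included categories; sums to `total`).
#' @export
#' @examples
#' comp <- data.frame(land_category = c("arable", "forest"), aa = c(0.01, 0.1))
#' per_capita_ef(comp, default_factor_table())
per_capita_ef <- function(components, factors, include_fossil = TRUE) {
  factors <- factor_table(factors)
  components <- as.data.frame(components)
  if (nrow(components) > 0 &&
      !all(components$land_category %in% factors$land_category)) {
    bad <- setdiff(unique(components$land_category), factors$land_category)
    stop("unknown land categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cats <- factors$land_category
  if (!include_fossil) cats <- setdiff(cats, "fossil_energy")
  e <- .factor_lookup(factors, "equivalence_factor")
  by_cat <- vapply(cats, function(cat) {
    aa <- components$aa[components$land_category == cat]
    e[[cat]] * sum(pmax(aa, 0))
  }, numeric(1))
  list(total = sum(by_cat),
       by_category = data.frame(land_category = cats, pef = unname(by_cat)))
}

#' Per-capita biocapacity from land areas
#'
#' Equivalence- and yield-weighted supply with a biodiversity set-aside:
#' `(1 - set_aside) * sum_j a_j * y_j * e_j`, where `a_j` is the per-capita
#' area of category `j`.  The default 12% set-aside reserves land for
#' biodiversity protection.
#'
#' @param areas Data frame with columns `land_category` and `area`
#'   (per-capita area, ha per capita, >= 0).
#' @param factors A [factor_table()].
#' @param set_aside Fraction of biocapacity withheld for biodiversity,
#'   in `[0, 1)`.  Default 0.12.
#' @return List with `total` (ha per capita) and `by_category` (data frame
#'   `land_category`, `pbc`, each cell already carrying the `(1 - set_aside)`
#'   factor; sums to `total`).
#' @export
#' @examples
#' per_capita_bc(data.frame(land_category = "forest", area = 1),
#'               default_factor_table())
per_capita_bc <- function(areas, factors, set_aside = 0.12) {
  factors <- factor_table(factors)
  areas <- as.data.frame(areas)
  if (length(set_aside) != 1 || !is.finite(set_aside) ||
      set_aside < 0 || set_aside >= 1) {
    stop("set_aside must be a single value in [0, 1)", call. = FALSE)
  }
  if (nrow(areas) > 0 && any(areas$area < 0)) {
    stop("areas must be >= 0", call. = FALSE)
  }
  if (nrow(areas) > 0 &&
      !all(areas$land_category %in% factors$land_category)) {
    bad <- setdiff(unique(areas$land_category), factors$land_category)
    stop("unknown land categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  y <- .factor_lookup(factors, "yield_factor")
  e <- .factor_lookup(factors, "equivalence_factor")
  by_cat <- vapply(factors$land_category, function(cat) {
    a <- sum(areas$area[areas$land_category == cat])
    (1 - set_aside) * a * y[[cat]] * e[[cat]]
  }, numeric(1))
  list(total = sum(by_cat),
       by_category = data.frame(land_category = factors$land_category,
                                pbc = unname(by_cat)))
}

#' Ecological balance: surplus or deficit
#'
#' Biocapacity minus footprint.  Positive means the land supplies more than
#' the population demands (ecological surplus); negative means demand
#' exceeds supply (ecological deficit).
#'
#' @param pbc,pef Per-capita biocapacity and footprint (ha per capita).
#'   Vectorized.
#' @return Data frame with columns `balance` (pbc - pef) and `status`
#'   (`"surplus"`, `"deficit"`, or `"balanced"`).
#' @export
#' @examples
#' ecological_balance(0.23, 1.49)  # deficit of 1.26 ha per capita
ecological_balance <- function(pbc, pef) {
  balance <- pbc - pef
  status <- ifelse(balance > 0, "surplus",
                   ifelse(balance < 0, "deficit", "balanced"))
  data.frame(balance = balance, status = status)
}

#' Change in area of a per-capita series between two years
#'
#' Simple end-minus-start difference, used to decompose footprint and
#' biocapacity trends into area change per land category.
#'
#' @param series Data frame with columns `year` and `value` (ha per capita).
#' @param start_year,end_year Years present in `series`.
#' @return `value(end_year) - value(start_year)`, ha per capita.
#' @export
change_in_area <- function(series, start_year, end_year) {
  series <- as.data.frame(series)
  v <- .series_value(series, c(start_year, end_year))
  v[[2]] - v[[1]]
}

#' Compound annual growth rate of a per-capita series
#'
#' Annual change in intensity between two years under the compound-growth
#' convention: `(value(end) / value(start))^(1 / (end - start)) - 1`.
#'
#' @inheritParams change_in_area
#' @return Fraction per year (0.05 means +5% per year).
#' @export
annual_intensity <- function(series, start_year, end_year) {
  series <- as.data.frame(series)
  if (end_year <= start_year) {
    stop("end_year must be after start_year", call. = FALSE)
  }
  v <- .series_value(series, c(start_year, end_year))
  if (!is.finite(v[[1]]) || v[[1]] <= 0) {
    stop("series value at start_year must be > 0", call. = FALSE)
  }
  (v[[2]] / v[[1]])^(1 / (end_year - start_year)) - 1
}

.series_value <- function(series, years) {
  idx <- match(years, series$year)
  if (anyNA(idx)) {
    stop("year(s) not present in series: ",
         paste(years[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  series$value[idx]
}

#' Run the full ecological footprint accounting pipeline
#'
#' Composes the four accounting steps over a multi-year panel: per-capita
#' consumption of each item, item footprint components, equivalence-weighted
#' per-capita footprint (with and without fossil energy land), and
#' set-aside-corrected per-capita biocapacity, closing with the ecological
#' balance per land category and per year.
#'
#' @param consumption Data frame `year`, `item_id`, `production`, `imports`,
#'   `exports` (kg, or the item's physical unit).
#' @param population Data frame `year`, `population` (persons).
#' @param areas Data frame `year`, `land_category`, `total_area` (ha).
#' @param items Item registry: data frame `item_id`, `land_category`,
#'   `world_yield` (unit per ha matching the item's flow unit).
#' @param factors A [factor_table()]; default [default_factor_table()].
#' @param set_aside Biodiversity set-aside fraction, default 0.12.
#' @return A `footprint_ledger`: list with
#'   * `cells`: data frame `year`, `land_category`, `pef`, `pbc`, `balance`;
#'   * `totals`: data frame `year`, `pef_I` (excl. fossil energy), `pef_II`,
#'     `pbc`, `balance_I`, `balance_II`;
#'   * `set_aside`: the fraction used.
#'   All values in ha per capita; `balance = pbc - pef` throughout.
#' @export
#' @examples
#' panels <- gen_efa_panels(scenario_config(seed = 1))
#' ledger <- run_efa(panels$consumption, panels$population, panels$areas,
#'                   panels$items)
#' ledger
run_efa <- function(consumption, population, areas, items,
                    factors = default_factor_table(), set_aside = 0.12) {
  factors <- factor_table(factors)
  consumption <- as.data.frame(consumption)
  population <- as.data.frame(population)
  areas <- as.data.frame(areas)
  items <- as.data.frame(items)

  years <- sort(unique(population$year))
  if ((nrow(consumption) > 0 && !setequal(unique(consumption$year), years)) ||
      !setequal(unique(areas$year), years)) {
    stop("consumption, population and areas must cover identical year ranges",
         call. = FALSE)
  }
  if (anyDuplicated(population$year)) {
    stop("population must have one row per year", call. = FALSE)
  }
  unmapped <- setdiff(unique(consumption$item_id), items$item_id)
  if (length(unmapped) > 0) {
    stop("consumption items missing from the item registry: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(items$item_id)) {
    stop("item registry must map each item_id exactly once", call. = FALSE)
  }
  if (!all(items$land_category %in% factors$land_category)) {
    stop("item registry contains unknown land categories", call. = FALSE)
  }

  pop <- setNames(population$population, population$year)
  cats <- factors$land_category
  e <- .factor_lookup(factors, "equivalence_factor")
  y <- .factor_lookup(factors, "yield_factor")

  # Demand side: item components aggregated per (year, category),
  # negative net consumption floored at zero when aggregating.
  grid <- expand.grid(year = years, land_category = cats,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(consumption) > 0) {
    cons <- merge(consumption, items, by = "item_id", sort = FALSE)
    ci <- per_capita_consumption(cons$production, cons$imports, cons$exports,
                                 pop[as.character(cons$year)])
    aa <- pmax(component_footprint(ci, cons$world_yield), 0)
    agg <- aggregate(list(aa = aa),
                     by = list(year = cons$year,
                               land_category = cons$land_category),
                     FUN = sum)
    grid <- merge(grid, agg, by = c("year", "land_category"), all.x = TRUE,
                  sort = FALSE)
    grid$aa[is.na(grid$aa)] <- 0
  } else {
    grid$aa <- 0
  }
  grid$pef <- e[grid$land_category] * grid$aa

  # Supply side: per-capita areas, yield- and equivalence-weighted,
  # with the biodiversity set-aside.
  if (length(set_aside) != 1 || !is.finite(set_aside) ||
      set_aside < 0 || set_aside >= 1) {
    stop("set_aside must be a single value in [0, 1)", call. = FALSE)
  }
  if (any(areas$total_area < 0)) stop("areas must be >= 0", call. = FALSE)
  if (!all(areas$land_category %in% cats)) {
    stop("areas contain unknown land categories", call. = FALSE)
  }
  ar <- aggregate(list(total_area = areas$total_area),
                  by = list(year = areas$year,
                            land_category = areas$land_category),
                  FUN = sum)
  grid <- merge(grid, ar, by = c("year", "land_category"), all.x = TRUE,
                sort = FALSE)
  grid$total_area[is.na(grid$total_area)] <- 0
  a_pc <- grid$total_area / pop[as.character(grid$year)]
  grid$pbc <- (1 - set_aside) * a_pc * y[grid$land_category] *
    e[grid$land_category]

  cells <- grid[order(grid$year, match(grid$land_category, cats)),
                c("year", "land_category", "pef", "pbc")]
  cells$balance <- cells$pbc - cells$pef
  rownames(cells) <- NULL

  fossil <- cells$land_category == "fossil_energy"
  totals <- data.frame(
    year = years,
    pef_I = tapply(cells$pef * !fossil, cells$year, sum)[as.character(years)],
    pef_II = tapply(cells$pef, cells$year, sum)[as.character(years)],
    pbc = tapply(cells$pbc, cells$year, sum)[as.character(years)]
  )
  totals$balance_I <- totals$pbc - totals$pef_I
  totals$balance_II <- totals$pbc - totals$pef_II
  rownames(totals) <- NULL

  structure(list(cells = cells, totals = totals, set_aside = set_aside),
            class = "footprint_ledger")
}

#' @export
print.footprint_ledger <- function(x, digits = 2, ...) {
  yr <- range(x$totals$year)
  cat("Ecological footprint ledger, ", yr[1], "-", yr[2],
      " (ha per capita, set-aside ", format(x$set_aside), ")\n\n", sep = "")
  tot <- x$totals
  tot[-1] <- lapply(tot[-1], round, digits = digits)
  print(tot, row.names = FALSE)
  invisible(x)
}
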