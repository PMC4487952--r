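# Synthetic-city generator: seeded multi-year panels with known ground
# truth for both assessment pipelines.  Flows follow geometric trends with
# multiplicative lognormal noise (keeps positivity); indicators follow
# linear trends with additive Gaussian noise (allows both polarities).

#' Default consumption-item scenario
#'
#' Twelve biotic items (six arable, two forest, three pasture, one fishery)
#' and nine energy items (two final-energy items on built-up land, seven
#' primary-energy items on fossil energy land), with baseline city-scale
#' flows, per-year geometric trends and lognormal noise levels.  Biotic
#' world yields are typical global averages (kg/ha); energy items use
#' land-conversion coefficients derived from standard heat contents and
#' global-average energy footprints per hectare, expressed in the item's
#' flow unit per hectare.
#'
#' @return Data frame `item_id`, `land_category`, `world_yield`,
#'   `base_production`, `base_imports`, `base_exports`, `trend`, `noise_cv`.
#' @export
default_item_scenario <- function() {
  df <- read.csv(text = "
item_id,land_category,world_yield,base_production,base_imports,base_exports,trend,noise_cv
crops,arable,2744,2.0e8,3.0e8,2.0e7,0.015,0.05
oil_plants,arable,1856,8.0e6,2.0e7,1.0e6,0.010,0.05
vegetables,arable,18000,5.0e8,1.0e8,5.0e7,0.030,0.05
poultry,arable,457,3.0e7,1.0e7,2.0e6,0.040,0.05
pork,arable,74,2.5e7,5.0e6,1.0e6,0.035,0.05
eggs,arable,400,2.5e7,5.0e6,1.0e6,0.030,0.05
fruits,forest,3500,8.0e7,4.0e7,1.0e7,0.035,0.05
tea,forest,566,4.0e6,1.0e6,2.0e6,0.020,0.05
beef,pasture,33,5.0e6,3.0e6,0,0.040,0.05
mutton,pasture,33,2.0e6,1.0e6,0,0.040,0.05
milk_dairy,pasture,502,4.0e7,2.0e7,1.0e6,0.050,0.05
aquatic_products,fishery,29,8.0e7,2.0e7,3.0e7,0.020,0.05
heating_power,built_up,93,6.0e6,0,0,0.050,0.05
electricity,built_up,277778,8.0e9,2.0e9,0,0.060,0.05
raw_coal,fossil_energy,380,1.0e8,2.6e8,0,0.050,0.05
coal_products,fossil_energy,516,2.0e7,3.0e7,0,0.040,0.05
natural_gas,fossil_energy,587,0,6.0e7,0,0.080,0.05
petroleum,fossil_energy,449,0,1.2e8,0,0.055,0.05
diesel_oil,fossil_energy,459,0,8.0e7,0,0.050,0.05
lpg,fossil_energy,540,0,5.0e7,0,0.045,0.05
fuel_oil,fossil_energy,449,0,6.0e7,0,0.035,0.05
", stringsAsFactors = FALSE, strip.white = TRUE)
  df
}

#' Default land-area scenario
#'
#' Baseline areas (ha) and geometric trends for the six land categories of
#' a rapidly urbanizing coastal city: shrinking arable land, slowly
#' declining forest and fishery, expanding built-up land; fossil energy
#' land has no real area (demand-only).
#'
#' @return Data frame `land_category`, `base_area`, `trend`.
#' @export
default_area_scenario <- function() {
  data.frame(
    land_category = land_categories(),
    base_area = c(40000, 60000, 2000, 15000, 31000, 0),
    trend = c(-0.020, -0.005, -0.010, -0.005, 0.050, 0)
  )
}

#' Default indicator scenario
#'
#' Twenty socioeconomic indicators in three criterion layers with the
#' packaged polarities, linear per-year slopes and Gaussian noise.  The
#' trajectory mirrors a rapidly urbanizing city: density and energy use
#' rise, per-capita arable land falls, environmental treatment rates and
#' economic output improve.
#'
#' @return Data frame `indicator_id`, `layer`, `polarity`, `baseline`,
#'   `slope`, `noise_cv` (noise sd = `noise_cv * |baseline|`).
#' @export
default_indicator_scenario <- function() {
  meta <- read.csv(system.file("extdata", "indicator_meta.csv",
                               package = "landcc", mustWork = TRUE),
                   stringsAsFactors = FALSE)
  sc <- data.frame(
    indicator_id = paste0("C", 1:20),
    baseline = c(1200, 94, 42, 12, 900, 0.02, 55, 35, 70, 85,
                 3.5, 40, 50, 500, 800, 40, 150, 12, 1.2, 55),
    slope = c(45, 0.15, -0.8, 0.45, 60, -6e-4, 1.5, 0.6, 1.8, 0.9,
              -0.05, 3.5, 3.2, 90, 120, 0.7, 35, -0.25, -0.05, 0.9),
    noise_cv = 0.05
  )
  merge(meta[c("indicator_id", "layer", "polarity")], sc,
        by = "indicator_id", sort = FALSE)
}

#' Build a synthetic-city scenario configuration
#'
#' Bundles everything the generators need: the year range, population
#' baseline and geometric growth, the consumption-item scenario, the
#' land-area scenario, the indicator scenario, and the random seed.
#' Identical configurations (including the seed) yield identical panels on
#' every run and platform: the generators draw from R's Mersenne-Twister
#' generator with inversion normals, explicitly selected.
#'
#' @param years Year range; default 2000:2012 (a 13-year panel).
#' @param seed Integer random seed stored in the config.
#' @param population List with `baseline` (persons in the first year) and
#'   `growth` (geometric fraction/yr).
#' @param items,areas,indicators Scenario tables; see
#'   [default_item_scenario()], [default_area_scenario()],
#'   [default_indicator_scenario()] for the required columns.
#' @return A validated list, classed `"scenario_config"`.
#' @export
#' @examples
#' cfg <- scenario_config(seed = 7)
scenario_config <- function(years = 2000:2012, seed = 1,
                            population = list(baseline = 2.05e6,
                                              growth = 0.025),
                            items = default_item_scenario(),
                            areas = default_area_scenario(),
                            indicators = default_indicator_scenario()) {
  years <- sort(unique(as.integer(years)))
  if (length(years) < 2) stop("need at least two years", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  if (population$baseline <= 0) {
    stop("population baseline must be > 0", call. = FALSE)
  }
  items <- as.data.frame(items)
  flows <- c("base_production", "base_imports", "base_exports")
  if (any(items[flows] < 0) || any(items$noise_cv < 0) ||
      any(items$world_yield <= 0)) {
    stop("item scenario: flows and noise must be >= 0, world yields > 0",
         call. = FALSE)
  }
  if (!all(items$land_category %in% land_categories())) {
    stop("item scenario contains unknown land categories", call. = FALSE)
  }
  areas <- as.data.frame(areas)
  if (any(areas$base_area < 0)) {
    stop("area scenario: areas must be >= 0", call. = FALSE)
  }
  indicators <- as.data.frame(indicators)
  if (any(indicators$noise_cv < 0)) {
    stop("indicator scenario: noise must be >= 0", call. = FALSE)
  }
  structure(list(years = years, seed = as.integer(seed),
                 population = population, items = items, areas = areas,
                 indicators = indicators),
            class = "scenario_config")
}

# Internal: evaluate code under the config's seed with a fixed RNG
# algorithm, restoring the caller's RNG state afterwards.
.with_config_seed <- function(config, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Generate synthetic consumption, population and area panels
#'
#' Each flow follows `base * (1 + trend)^(year - first_year)` with
#' multiplicative lognormal noise of log-sd `noise_cv` (so flows stay
#' non-negative; zero baselines stay exactly zero).  Population and land
#' areas follow deterministic geometric trends, keeping the supply side an
#' exact closed-form function of the configuration.
#'
#' @param config A [scenario_config()].
#' @return List with `consumption` (data frame `year`, `item_id`,
#'   `production`, `imports`, `exports`), `population` (`year`,
#'   `population`), `areas` (`year`, `land_category`, `total_area`) and
#'   `items` (registry: `item_id`, `land_category`, `world_yield`) — the
#'   inputs [run_efa()] expects.
#' @export
#' @examples
#' panels <- gen_efa_panels(scenario_config(seed = 1))
#' head(panels$consumption)
gen_efa_panels <- function(config) {
  if (!inherits(config, "scenario_config")) config <- scenario_config(config)
  years <- config$years
  k <- years - years[1]
  items <- config$items

  pop <- data.frame(
    year = years,
    population = config$population$baseline *
      (1 + config$population$growth)^k
  )
  areas <- do.call(rbind, lapply(seq_len(nrow(config$areas)), function(i) {
    row <- config$areas[i, ]
    data.frame(year = years, land_category = row$land_category,
               total_area = row$base_area * (1 + row$trend)^k)
  }))

  consumption <- .with_config_seed(config, {
    do.call(rbind, lapply(seq_len(nrow(items)), function(i) {
      row <- items[i, ]
      growth <- (1 + row$trend)^k
      noise <- function(base) {
        if (base == 0 || row$noise_cv == 0) rep(1, length(k))
        else exp(rnorm(length(k), 0, row$noise_cv))
      }
      data.frame(year = years, item_id = row$item_id,
                 production = row$base_production * growth *
                   noise(row$base_production),
                 imports = row$base_imports * growth * noise(row$base_imports),
                 exports = row$base_exports * growth * noise(row$base_exports))
    }))
  })
  rownames(consumption) <- rownames(areas) <- NULL

  list(consumption = consumption, population = pop, areas = areas,
       items = items[c("item_id", "land_category", "world_yield")])
}

#' Generate a synthetic indicator panel
#'
#' Each indicator follows `baseline + slope * (year - first_year)` with
#' additive Gaussian noise of sd `noise_cv * |baseline|`, so known linear
#' ground truth underlies every column and both polarities can move in
#' either direction.
#'
#' @param config A [scenario_config()].
#' @return List with `matrix` (judgement matrix, years by indicators) and
#'   `meta` (data frame `indicator_id`, `layer`, `polarity`) — the inputs
#'   [run_ism()] expects.
#' @export
#' @examples
#' panel <- gen_ism_panel(scenario_config(seed = 1))
#' panel$matrix[1:3, 1:4]
gen_ism_panel <- function(config) {
  if (!inherits(config, "scenario_config")) config <- scenario_config(config)
  years <- config$years
  k <- years - years[1]
  ind <- config$indicators

  x <- .with_config_seed(config, {
    vapply(seq_len(nrow(ind)), function(j) {
      row <- ind[j, ]
      row$baseline + row$slope * k +
        rnorm(length(k), 0, row$noise_cv * abs(row$baseline))
    }, numeric(length(k)))
  })
  dimnames(x) <- list(years, ind$indicator_id)

  list(matrix = x, meta = ind[c("indicator_id", "layer", "polarity")])
}
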