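# Independent straight-line oracles and tiny hand-built fixtures.

# Brute-force footprint accounting for one year: explicit loops over items
# and categories, kept independent of run_efa's vectorized path.
efa_oracle_one_year <- function(consumption, population, areas, items,
                                factors, set_aside = 0.12) {
  cats <- factors$land_category
  pef <- pbc <- setNames(numeric(length(cats)), cats)
  for (cat in cats) {
    total_aa <- 0
    for (id in items$item_id[items$land_category == cat]) {
      row <- consumption[consumption$item_id == id, ]
      if (nrow(row) == 0) next
      ci <- (row$production + row$imports - row$exports) / population
      aa <- ci / items$world_yield[items$item_id == id]
      total_aa <- total_aa + max(aa, 0)
    }
    e <- factors$equivalence_factor[factors$land_category == cat]
    y <- factors$yield_factor[factors$land_category == cat]
    a <- sum(areas$total_area[areas$land_category == cat]) / population
    pef[cat] <- e * total_aa
    pbc[cat] <- (1 - set_aside) * a * y * e
  }
  list(pef = pef, pbc = pbc)
}

# Double-loop weighted sum, independent of the matrix-product path.
integrated_oracle <- function(y, w) {
  out <- setNames(numeric(nrow(y)), rownames(y))
  for (i in seq_len(nrow(y))) {
    for (j in seq_len(ncol(y))) {
      out[i] <- out[i] + y[i, j] * w[[colnames(y)[j]]]
    }
  }
  out
}

# Uniform factor table (all yields and equivalences 1) for unit checks.
unit_factor_table <- function() {
  factor_table(data.frame(land_category = land_categories(),
                          yield_factor = 1, equivalence_factor = 1))
}

# Tiny one-year fixture: three items over two categories.
tiny_efa_fixture <- function() {
  items <- data.frame(
    item_id = c("grain", "timber", "fish"),
    land_category = c("arable", "forest", "fishery"),
    world_yield = c(2750, 1.99, 29)
  )
  consumption <- data.frame(
    year = 2000,
    item_id = items$item_id,
    production = c(1000000, 40000, 260000),
    imports = c(250000, 5000, 20000),
    exports = c(50000, 0, 80000)
  )
  areas <- data.frame(
    year = 2000,
    land_category = land_categories(),
    total_area = c(400, 900, 30, 210, 120, 0)
  )
  population <- data.frame(year = 2000, population = 5000)
  list(consumption = consumption, population = population, areas = areas,
       items = items)
}

# Random normalized-style matrix with year rownames and indicator colnames.
random_norm_matrix <- function(n = 5, m = 20) {
  y <- matrix(runif(n * m), n, m,
              dimnames = list(2000 + seq_len(n) - 1, paste0("C", seq_len(m))))
  y
}
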