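meta1 <- function(ids, polarity = "positive", layer = "B1") {
  data.frame(indicator_id = ids, layer = layer,
             polarity = rep(polarity, length.out = length(ids)))
}

test_that("min-max normalization respects indicator polarity", {
  x <- cbind(up = c(2, 4, 6), down = c(2, 4, 6))
  rownames(x) <- 2000:2002
  y <- normalize_indicators(x, data.frame(
    indicator_id = c("up", "down"), layer = "B1",
    polarity = c("positive", "negative")))
  expect_equal(unname(y[, "up"]), c(0, 0.5, 1))
  expect_equal(unname(y[, "down"]), c(1, 0.5, 0))
})

test_that("constant columns normalize to 0.5 with a warning", {
  x <- cbind(flat = c(3, 3, 3), live = c(1, 2, 3))
  rownames(x) <- 2000:2002
  expect_warning(y <- normalize_indicators(x, meta1(c("flat", "live"))),
                 "constant")
  expect_equal(unname(y[, "flat"]), c(0.5, 0.5, 0.5))
})

test_that("normalization requires metadata for every column", {
  x <- cbind(a = 1:3, b = 4:6)
  rownames(x) <- 2000:2002
  expect_error(normalize_indicators(x, meta1("a")), "no metadata")
  expect_error(normalize_indicators(x[1, , drop = FALSE], meta1(c("a", "b"))),
               "two years")
})

test_that("translation invariance: shifting a raw column changes nothing", {
  set.seed(11)
  x <- matrix(runif(30, 10, 20), 10, 3,
              dimnames = list(2000:2009, c("a", "b", "c")))
  y1 <- normalize_indicators(x, meta1(c("a", "b", "c")))
  x2 <- x
  x2[, "b"] <- x2[, "b"] + 100
  y2 <- normalize_indicators(x2, meta1(c("a", "b", "c")))
  expect_equal(y1, y2)
  expect_equal(mse_weights(y1), mse_weights(y2))
})

test_that("dispersion weights follow the root-mean-square convention", {
  sym <- cbind(a = c(0, 0.5, 1), b = c(1, 0.5, 0))
  expect_equal(unname(mse_weights(sym)), c(0.5, 0.5))

  with_flat <- cbind(a = c(0, 0.5, 1), b = c(0.5, 0.5, 0.5))
  expect_equal(unname(mse_weights(with_flat)), c(1, 0))

  two <- cbind(a = c(0, 1), b = c(0, 0.5))
  expect_equal(unname(mse_weights(two)), c(2 / 3, 1 / 3))

  all_flat <- cbind(a = c(1, 1), b = c(2, 2))
  expect_error(mse_weights(all_flat), "constant")
})

test_that("the literal sum-of-squares convention is available and differs", {
  y <- cbind(a = c(0, 0.2, 1), b = c(0, 0.5, 0.9), c = c(0.4, 0.1, 0.8))
  w_sd <- mse_weights(y, dispersion = "sd")
  w_ssd <- mse_weights(y, dispersion = "ssd")
  expect_equal(sum(w_sd), 1, tolerance = 1e-12)
  expect_equal(sum(w_ssd), 1, tolerance = 1e-12)
  expect_gt(max(abs(w_sd - w_ssd)), 1e-3)
})

test_that("weights sum to one on random normalized matrices", {
  set.seed(7)
  for (i in 1:20) {
    y <- random_norm_matrix(sample(3:12, 1), sample(2:25, 1))
    expect_equal(sum(mse_weights(y)), 1, tolerance = 1e-9)
  }
})

test_that("layer scores are weight-inclusive partial sums of F", {
  fx <- lcc_fixtures()
  y <- ref_normalized_matrix(fx$ism_reference)
  w <- ref_weight_vector(fx$ism_reference)
  ones <- y
  ones[] <- 1
  b2_max <- layer_score(ones, w, fx$meta, "B2")
  expect_equal(unname(b2_max),
               rep(sum(w[paste0("C", 8:13)]), nrow(y)))
  f <- integrated_lcc(y, w)
  total <- layer_score(y, w, fx$meta, "B1") +
    layer_score(y, w, fx$meta, "B2") + layer_score(y, w, fx$meta, "B3")
  expect_equal(f, total)
  expect_error(layer_score(y, w, fx$meta, "B9"), "unknown layer")
})

test_that("integrated score matches the double-loop oracle and stays in [0,1]", {
  set.seed(13)
  for (i in 1:25) {
    y <- random_norm_matrix(5, 20)
    w <- mse_weights(y)
    f <- integrated_lcc(y, w)
    expect_equal(f, integrated_oracle(y, w), tolerance = 1e-12)
    expect_true(all(f >= 0 & f <= 1))
  }
  ones <- random_norm_matrix(3, 4)
  ones[] <- 1
  w <- setNames(rep(0.25, 4), colnames(ones))
  expect_equal(unname(integrated_lcc(ones, w)), rep(1, 3))
  zeros <- ones
  zeros[] <- 0
  expect_equal(unname(integrated_lcc(zeros, w)), rep(0, 3))
})

test_that("monotonicity: improving a positive indicator never lowers F", {
  set.seed(17)
  meta <- meta1(paste0("C", 1:6))
  for (i in 1:10) {
    x <- matrix(runif(60, 0, 10), 10, 6,
                dimnames = list(2000:2009, meta$indicator_id))
    j <- sample(6, 1)
    interior <- setdiff(order(x[, j]), c(which.min(x[, j]), which.max(x[, j])))
    i_row <- interior[1]
    x2 <- x
    x2[i_row, j] <- min(x[i_row, j] + 0.1, max(x[, j]))
    w <- mse_weights(normalize_indicators(x, meta))
    f1 <- integrated_lcc(normalize_indicators(x, meta), w)
    f2 <- integrated_lcc(normalize_indicators(x2, meta), w)
    expect_gte(f2[i_row] + 1e-12, f1[i_row])
  }
})

test_that("grading maps scores to the five-level standard", {
  expect_equal(lcc_grade(0.58), "Medium")
  expect_equal(lcc_grade(0.758), "Strong")
  expect_equal(lcc_grade(0), "Weakest")
  expect_equal(lcc_grade(1), "Strongest")
  # boundaries belong to the upper bin
  expect_equal(lcc_grade(c(0.2, 0.4, 0.6, 0.8)),
               c("Weak", "Medium", "Strong", "Strongest"))
  expect_error(lcc_grade(1.2), "\\[0, 1\\]")
  expect_error(lcc_grade(-0.1), "\\[0, 1\\]")
})

test_that("grade scales must partition [0,1]", {
  gap <- data.frame(lower = c(0, 0.5), upper = c(0.4, 1), label = c("a", "b"))
  expect_error(grade_scale(gap), "partition")
  overlap <- data.frame(lower = c(0, 0.3), upper = c(0.5, 1),
                        label = c("a", "b"))
  expect_error(grade_scale(overlap), "partition")
  ok <- grade_scale(data.frame(lower = c(0, 0.5), upper = c(0.5, 1),
                               label = c("lo", "hi")))
  expect_equal(lcc_grade(c(0.49, 0.5), ok), c("lo", "hi"))
})

test_that("linear projection extends exact lines and constants", {
  x <- cbind(lin = c(1, 2, 3), flat = c(5, 5, 5))
  rownames(x) <- 2000:2002
  ext <- project_indicators(x, c(2003, 2010))
  expect_equal(unname(ext["2003", ]), c(4, 5))
  expect_equal(unname(ext["2010", ]), c(11, 5))
  expect_equal(ext[1:3, ], x)
  expect_error(project_indicators(x[1, , drop = FALSE], 2003), "two historical")
})

test_that("projection recovers a noisy slope within sampling error", {
  set.seed(23)
  years <- 2000:2012
  slope <- 1.7
  sigma <- 0.5
  x <- cbind(C1 = 10 + slope * (years - 2000) + rnorm(13, 0, sigma))
  rownames(x) <- years
  fit <- lm(x[, 1] ~ years)
  se <- summary(fit)$coefficients["years", "Std. Error"]
  ext <- project_indicators(x, 2013)
  expect_lt(abs(coef(fit)[[2]] - slope), 3 * se)
  expect_equal(unname(ext["2013", 1]),
               unname(coef(fit)[[1]] + coef(fit)[[2]] * 2013))
})

test_that("full pipeline is monotone and deterministic", {
  years <- 2000:2009
  meta <- meta1(paste0("C", 1:4))
  x <- sapply(1:4, function(j) j + 0.3 * j * (years - 2000))
  dimnames(x) <- list(years, meta$indicator_id)
  res <- run_ism(x, meta, target_years = c(2012, 2015))
  expect_true(all(diff(res$series$F) > 0))
  expect_equal(res$series$F[1], 0)
  expect_equal(res$series$F[nrow(res$series)], 1)
  res2 <- run_ism(x, meta, target_years = c(2012, 2015))
  expect_identical(res, res2)
})

test_that("pipeline normalizes jointly over history and projections", {
  years <- 2000:2009
  meta <- meta1(c("a", "b"))
  x <- cbind(a = 1 + 0.5 * (years - 2000), b = 20 - (years - 2000))
  dimnames(x) <- list(years, meta$indicator_id)
  res <- run_ism(x, meta, target_years = 2030)
  # rising indicator attains its max (1) only in the projected year
  norm_a <- res$normalized[, "a"]
  expect_equal(unname(norm_a[["2030"]]), 1)
  expect_lt(max(norm_a[as.character(years)]), 1)
})
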