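test_that("headspace gas accounting follows the ideal gas law", {
  cyc <- growth_cycle(c(0, 24), c(20, 10), c(10, 9), c(1e6, 2e6))
  expect_equal(headspace_ch4_carbon_g(0, cyc), 0)
  # 20% of 110 mL at 1 atm, 303.15 K: n = 0.2*0.110/(0.082057*303.15)
  expect_equal(headspace_ch4_carbon_g(20, cyc),
               0.2 * 0.110 / (0.082057 * 303.15) * 12.011)
  expect_equal(headspace_ch4_carbon_g(20, cyc), 1.062e-2, tolerance = 1e-3)
  # linear in headspace volume
  cyc2 <- growth_cycle(c(0, 24), c(20, 10), c(10, 9), c(1e6, 2e6),
                       headspace_volume_mL = 220)
  expect_equal(headspace_ch4_carbon_g(20, cyc2),
               2 * headspace_ch4_carbon_g(20, cyc))
  # inversely proportional to temperature
  cyc3 <- growth_cycle(c(0, 24), c(20, 10), c(10, 9), c(1e6, 2e6),
                       temperature_K = 2 * 303.15)
  expect_equal(headspace_ch4_carbon_g(20, cyc3),
               headspace_ch4_carbon_g(20, cyc) / 2)
})

test_that("consumption fractions handle the documented cases", {
  expect_equal(consumption_fraction(c(100, 75)), 0.25)
  expect_equal(consumption_fraction(c(5, 5, 5)), 0)
  # the highest-consuming low-resource bottle: 20.0% -> 12.16% headspace CH4
  expect_equal(consumption_fraction(c(20.0, 12.16)), 0.392)
  expect_warning(fr <- consumption_fraction(c(10, 11)), "clipped")
  expect_equal(fr, 0)
  expect_error(consumption_fraction(c(0, 1)), "> 0")
})

test_that("cell yields are simple ratios with dimensional consistency", {
  expect_equal(cell_yield(1e6, 0.01), 1e8)
  expect_equal(cell_yield(0, 0.01), 0)
  set.seed(41)
  for (i in 1:10) {
    d <- runif(1, 1e5, 1e8); g <- runif(1, 1e-3, 1)
    k <- runif(1, 0.1, 10)
    expect_equal(cell_yield(d, g), d / g)
    expect_equal(cell_yield(k * d, k * g), cell_yield(d, g))
  }
  expect_error(cell_yield(1e6, 0), "> 0")
})

test_that("yield ratios reproduce the reference enrichment comparisons", {
  yields <- read.csv(system.file("extdata", "enrichment_cell_yields.csv",
                                 package = "phaquant"))
  cy <- function(cond, basis)
    yields$mean_1e6_cells_per_g[yields$condition == cond &
                                  yields$basis == basis] * 1e6
  expect_equal(round(yield_ratio(cy("low", "carbon"), cy("high", "carbon")),
                     1), 12.7)
  expect_equal(round(yield_ratio(cy("low", "nitrogen"),
                                 cy("high", "nitrogen")), 2), 0.89)
  expect_equal(yield_ratio(3, 3), 1)
  expect_error(yield_ratio(1, 0), "> 0")
})

test_that("mean_sd recovers the reference summary and matches stats::sd", {
  gc <- read.csv(system.file("extdata", "enrichment_gc_pha_content.csv",
                             package = "phaquant"))
  vals <- gc$pha_pct_mm[gc$method == "gc"]
  ms <- mean_sd(vals, "population")
  expect_equal(round(unname(ms["mean"]), 1), 12.6)
  expect_equal(round(unname(ms["sd"]), 1), 2.4)
  # sample mode gives the larger, divisor n-1 value
  expect_equal(round(unname(mean_sd(vals, "sample")["sd"]), 1), 2.9)
  expect_equal(unname(mean_sd(c(4.2), "population")), c(4.2, 0))
  expect_error(mean_sd(numeric()), "non-empty")
  expect_error(mean_sd(5, "sample"), "two values")
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(sample(2:30, 1), sd = 10)
    n <- length(x)
    expect_equal(unname(mean_sd(x, "sample")), c(mean(x), stats::sd(x)))
    expect_equal(unname(mean_sd(x, "population")["sd"]),
                 stats::sd(x) * sqrt((n - 1) / n))
    expect_lte(unname(mean_sd(x, "population")["sd"]),
               unname(mean_sd(x, "sample")["sd"]))
  }
})

test_that("abundance normalization scales PHA content as expected", {
  expect_equal(normalized_pha_content(12.563, 100), 12.563)
  expect_equal(normalized_pha_content(10, 25), 2 * normalized_pha_content(10, 50))
  expect_error(normalized_pha_content(10, 0), "0, 100")
})

test_that("growth-cycle yields integrate gas, nitrogen and cell series", {
  cyc <- growth_cycle(times = c(0, 48, 96),
                      ch4_headspace_pct = c(20, 14, 9.4),
                      nh4_mM = c(10, 9.3, 8.7),
                      cells_per_mL = c(5e6, 5e7, 7.4e7))
  yr <- growth_cycle_yields(cyc)
  expect_equal(yr$ch4_consumed_fraction, (20 - 9.4) / 20)
  expect_equal(yr$nh4_consumed_fraction, (10 - 8.7) / 10)
  dcells <- (7.4e7 - 5e6) * 50
  expect_equal(yr$delta_cells_total, dcells)
  gC <- headspace_ch4_carbon_g(20, cyc) - headspace_ch4_carbon_g(9.4, cyc)
  expect_equal(yr$yield_C, dcells / gC)
  gN <- (10 - 8.7) / 1000 * 0.050 * 14.007
  expect_equal(yr$yield_N, dcells / gN)
})

test_that("growth-cycle CSVs round-trip through the reader", {
  d <- data.frame(time_h = c(0, 24, 48), ch4_pct = c(0.2, 0.15, 0.12),
                  nh4_mM = c(0.1, 0.05, 0), cells_per_mL = c(1e6, 2e6, 3e6))
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  cyc <- read_growth_cycle(f)
  expect_s3_class(cyc, "growth_cycle")
  expect_equal(cyc$ch4_headspace_pct, d$ch4_pct)
  expect_error(read_growth_cycle(tempfile()), "not found")
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_growth_cycle(bad), "columns")
})

test_that("growth cycle validation catches malformed series", {
  expect_error(growth_cycle(c(0, 0), c(1, 1), c(1, 1), c(1, 1)),
               "strictly increasing")
  expect_error(growth_cycle(c(0, 1), c(1, 101), c(1, 1), c(1, 1)), "0, 100")
  expect_error(growth_cycle(0, 1, 1, 1, temperature_K = -1), "> 0")
})
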