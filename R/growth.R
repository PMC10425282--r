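#' Growth cycle of one enrichment bottle
#'
#' Time series of headspace methane, dissolved ammonium and cell counts over
#' one batch growth cycle, together with the bottle geometry and incubation
#' conditions needed for gas accounting. Defaults describe a 160-mL serum
#' bottle with 50 mL of medium incubated at 30 degrees C under atmospheric
#' pressure.
#'
#' @param times Sampling times in hours, strictly increasing.
#' @param ch4_headspace_pct Headspace CH4 in % v/v per timepoint.
#' @param nh4_mM Dissolved NH4+ in mM per timepoint.
#' @param cells_per_mL Cell concentration in cells/mL per timepoint.
#' @param liquid_volume_mL Medium volume (mL).
#' @param headspace_volume_mL Headspace volume (mL).
#' @param temperature_K Incubation temperature (K).
#' @param pressure_atm Total headspace pressure (atm).
#' @return An object of class `growth_cycle`.
#' @export
growth_cycle <- function(times, ch4_headspace_pct, nh4_mM, cells_per_mL,
                         liquid_volume_mL = 50, headspace_volume_mL = 110,
                         temperature_K = 303.15, pressure_atm = 1) {
  n <- length(times)
  if (n < 1L) stop("at least one timepoint is required")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (length(ch4_headspace_pct) != n || length(nh4_mM) != n ||
      length(cells_per_mL) != n)
    stop("all series must have the same length as `times`")
  if (any(ch4_headspace_pct < 0) || any(ch4_headspace_pct > 100))
    stop("`ch4_headspace_pct` must lie in [0, 100]")
  if (any(nh4_mM < 0) || any(cells_per_mL < 0))
    stop("concentrations must be >= 0")
  if (liquid_volume_mL <= 0 || headspace_volume_mL <= 0 ||
      temperature_K <= 0 || pressure_atm <= 0)
    stop("volumes, temperature and pressure must be > 0")
  structure(list(times = times, ch4_headspace_pct = ch4_headspace_pct,
                 nh4_mM = nh4_mM, cells_per_mL = cells_per_mL,
                 liquid_volume_mL = liquid_volume_mL,
                 headspace_volume_mL = headspace_volume_mL,
                 temperature_K = temperature_K, pressure_atm = pressure_atm),
            class = "growth_cycle")
}

#' Read a growth-cycle CSV
#'
#' Expects columns `time_h`, `ch4_pct`, `nh4_mM`, `cells_per_mL`.
#'
#' @param path CSV file path.
#' @param ... Bottle geometry passed on to [growth_cycle()].
#' @return A [growth_cycle()].
#' @export
read_growth_cycle <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path)
  need <- c("time_h", "ch4_pct", "nh4_mM", "cells_per_mL")
  if (!all(need %in% names(d)))
    stop("growth-cycle CSV must have columns: ", paste(need, collapse = ", "))
  growth_cycle(d$time_h, d$ch4_pct, d$nh4_mM, d$cells_per_mL, ...)
}

#' Grams of methane-carbon in the headspace
#'
#' Converts a headspace CH4 percentage to grams of CH4-carbon with the ideal
#' gas law: `n = (pct/100) * P * V / (R * T)` mol, times 12.011 g C/mol,
#' with `R = 0.082057 L atm / (mol K)` and the bottle's configured pressure,
#' headspace volume and temperature. Linear in `pct`, `P` and `V`, inversely
#' proportional to `T`.
#'
#' @param pct Headspace CH4 in % v/v (vectorized, in `[0, 100]`).
#' @param cycle A [growth_cycle()] supplying the bottle geometry.
#' @return Grams of CH4-derived carbon.
#' @examples
#' cyc <- growth_cycle(0, 20, 10, 1e6)
#' headspace_ch4_carbon_g(20, cyc)  # ~0.0106 g C
#' @export
headspace_ch4_carbon_g <- function(pct, cycle) {
  stopifnot(inherits(cycle, "growth_cycle"))
  if (any(pct < 0) || any(pct > 100)) stop("`pct` must lie in [0, 100]")
  R_gas <- 0.082057  # L atm / (mol K)
  v_L <- cycle$headspace_volume_mL / 1000
  mol <- (pct / 100) * cycle$pressure_atm * v_L /
    (R_gas * cycle$temperature_K)
  mol * 12.011
}

#' Fraction of the initial substrate consumed
#'
#' `(initial - final) / initial` over a per-timepoint amount series. A
#' negative value (measurement fluctuation) is clipped to 0 with a warning;
#' values are clipped to at most 1.
#'
#' @param series Substrate amounts per timepoint (any consistent unit);
#'   first element is the initial amount (> 0), last the final.
#' @return Dimensionless consumed fraction in `[0, 1]`.
#' @examples
#' consumption_fraction(c(20, 12.16))  # 0.392
#' @export
consumption_fraction <- function(series) {
  if (length(series) < 1L || anyNA(series)) stop("invalid series")
  init <- series[1L]; final <- series[length(series)]
  if (init <= 0) stop("initial amount must be > 0")
  fr <- (init - final) / init
  if (fr < 0) {
    warning("final amount exceeds initial (", signif(-100 * fr, 3),
            "% increase); consumed fraction clipped to 0")
    fr <- 0
  }
  min(1, fr)
}

#' Cell yield per gram of substrate consumed
#'
#' @param delta_cells_total Cells gained over the cycle (final minus initial
#'   concentration times the liquid volume); negative gains are an error.
#' @param substrate_consumed_g Grams of substrate (CH4-C or NH4-N) consumed
#'   (> 0).
#' @return Yield in cells per gram.
#' @examples
#' cell_yield(1e6, 0.01)  # 1e8 cells/g
#' @export
cell_yield <- function(delta_cells_total, substrate_consumed_g) {
  if (substrate_consumed_g <= 0)
    stop("`substrate_consumed_g` must be > 0")
  if (delta_cells_total < 0) stop("negative cell gain")
  delta_cells_total / substrate_consumed_g
}

#' Ratio of two yields
#'
#' @param a,b Yields in the same unit; `b > 0`.
#' @return `a / b`.
#' @examples
#' yield_ratio(128.81e6, 10.12e6)  # ~12.7
#' @export
yield_ratio <- function(a, b) {
  if (b <= 0) stop("`b` must be > 0")
  a / b
}

#' Mean and standard deviation
#'
#' Arithmetic mean with either the population (divisor `n`) or sample
#' (divisor `n - 1`) standard deviation. Population is the default reporting
#' mode for small per-core replicate sets.
#'
#' @param values Numeric vector (non-empty; a single value is allowed in
#'   population mode, where its sd is 0).
#' @param mode `"population"` or `"sample"`.
#' @return Named numeric vector `c(mean = , sd = )`.
#' @examples
#' mean_sd(c(13.47, 9.27, 14.95))  # mean 12.56, population sd 2.41
#' @export
mean_sd <- function(values, mode = c("population", "sample")) {
  mode <- match.arg(mode)
  n <- length(values)
  if (n < 1L || anyNA(values)) stop("`values` must be non-empty and complete")
  m <- mean(values)
  s <- if (mode == "sample") {
    if (n < 2L) stop("sample sd needs at least two values")
    stats::sd(values)
  } else {
    sqrt(sum((values - m)^2) / n)
  }
  c(mean = m, sd = s)
}

#' PHA content normalized by methanotroph relative abundance
#'
#' Divides a community-level PHA content by the relative abundance of the
#' PHA-storing methanotroph population, estimating the PHA content of that
#' population alone: `100 * mean_pha_pct / abundance_pct`.
#'
#' @param mean_pha_pct Community PHA content in % (m/m).
#' @param methanotroph_rel_abundance_pct Methanotroph relative abundance in
#'   % (0 < abundance <= 100).
#' @return Normalized PHA content in % (m/m).
#' @examples
#' normalized_pha_content(12.563, 47.6)  # ~26.4
#' @export
normalized_pha_content <- function(mean_pha_pct,
                                   methanotroph_rel_abundance_pct) {
  if (methanotroph_rel_abundance_pct <= 0 ||
      methanotroph_rel_abundance_pct > 100)
    stop("`methanotroph_rel_abundance_pct` must lie in (0, 100]")
  100 * mean_pha_pct / methanotroph_rel_abundance_pct
}

#' Carbon- and nitrogen-based cell yields of a growth cycle
#'
#' Computes, from a bottle's time series: the consumed fractions of CH4 and
#' NH4+, grams of CH4-C and NH4-N consumed (ideal-gas headspace accounting
#' for CH4; `mM x liquid volume x 14.007 g/mol` for N), the total cell gain
#' (`(final - initial) cells/mL x liquid volume`), and the resulting yields
#' in cells per gram of C and of N.
#'
#' @param cycle A [growth_cycle()].
#' @return A list of class `yield_result`: `yield_C` (cells/g CH4-C),
#'   `yield_N` (cells/g N), `ch4_consumed_fraction`, `nh4_consumed_fraction`,
#'   `ch4_c_consumed_g`, `nh4_n_consumed_g`, `delta_cells_total`.
#' @export
growth_cycle_yields <- function(cycle) {
  stopifnot(inherits(cycle, "growth_cycle"))
  n <- length(cycle$times)
  if (n < 2L) stop("a growth cycle needs at least two timepoints")

  ch4_g <- headspace_ch4_carbon_g(cycle$ch4_headspace_pct, cycle)
  ch4_fr <- consumption_fraction(ch4_g)
  ch4_consumed <- ch4_g[1L] - ch4_g[n]

  v_L <- cycle$liquid_volume_mL / 1000
  n_g <- cycle$nh4_mM / 1000 * v_L * 14.007
  nh4_fr <- consumption_fraction(n_g)
  n_consumed <- n_g[1L] - n_g[n]

  dcells <- (cycle$cells_per_mL[n] - cycle$cells_per_mL[1L]) *
    cycle$liquid_volume_mL

  structure(list(
    yield_C = cell_yield(dcells, ch4_consumed),
    yield_N = cell_yield(dcells, n_consumed),
    ch4_consumed_fraction = ch4_fr,
    nh4_consumed_fraction = nh4_fr,
    ch4_c_consumed_g = ch4_consumed,
    nh4_n_consumed_g = n_consumed,
    delta_cells_total = dcells
  ), class = "yield_result")
}

#' @export
print.yield_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<yield_result> %.3g cells gained\n  C yield: %.4g cells/g CH4-C ",
    "(%.1f%% CH4 consumed)\n  N yield: %.4g cells/g N (%.1f%% NH4+ ",
    "consumed)\n"),
    x$delta_cells_total, x$yield_C, 100 * x$ch4_consumed_fraction,
    x$yield_N, 100 * x$nh4_consumed_fraction))
  invisible(x)
}
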