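#' Area/volume/mass conversion parameters
#'
#' Controls the per-cell conversion of PHA cross-sectional area fractions to
#' volume and mass fractions.
#'
#' @param density_ratio PHA-to-biomass density ratio (dimensionless, > 0).
#'   Default 1.099.
#' @param mass_model `"mixture"` (default) treats the cell as a two-component
#'   mixture, `w = rho*v / (rho*v + (1 - v))`, which satisfies `w(1) = 1`;
#'   `"linear"` uses `w = rho*v` (for sensitivity analysis only — it exceeds
#'   the physical bound for large `v`, and is clipped at 1).
#' @param volume_model `"aggregate"` (default) applies the sphere assumption
#'   to the summed granule cross-section and the cell cross-section, giving
#'   `v = f^(3/2)`; `"per_granule"` converts each granule separately,
#'   `v = sum(A_i^(3/2)) / A_cell^(3/2)`, which is unbiased for multiple
#'   equal spherical granules (the aggregate form overestimates a
#'   k-granule cell by about `sqrt(k)`).
#' @return An object of class `conversion_params`.
#' @export
conversion_params <- function(density_ratio = 1.099,
                              mass_model = c("mixture", "linear"),
                              volume_model = c("aggregate", "per_granule")) {
  if (density_ratio <= 0) stop("`density_ratio` must be > 0")
  structure(list(density_ratio = density_ratio,
                 mass_model = match.arg(mass_model),
                 volume_model = match.arg(volume_model)),
            class = "conversion_params")
}

#' Per-cell PHA area fraction
#'
#' Fraction of the cell's membrane cross-sectional area occupied by its
#' assigned PHA particles, `f = min(1, sum(pha_areas) / membrane_area)`.
#' Clipped at 1 because thresholding can make the granule mask spill slightly
#' past the membrane mask.
#'
#' @param membrane_area_px Cell area in pixels (>= 1).
#' @param pha_areas_px Numeric vector of assigned granule areas in pixels
#'   (possibly empty).
#' @return Dimensionless area fraction in `[0, 1]`.
#' @examples
#' cell_area_fraction(100, c(10, 15))  # 0.25
#' @export
cell_area_fraction <- function(membrane_area_px, pha_areas_px = numeric()) {
  if (length(membrane_area_px) != 1L || is.na(membrane_area_px) ||
      membrane_area_px < 1)
    stop("`membrane_area_px` must be a single count >= 1 (degenerate cell)")
  if (length(pha_areas_px) && any(pha_areas_px < 0))
    stop("granule areas must be >= 0")
  min(1, sum(pha_areas_px) / membrane_area_px)
}

#' Area fraction to volume fraction (sphere assumption)
#'
#' Both the cell and the (aggregate) PHA cross-section are assumed to be
#' equatorial sections of spheres: a cross-section of area `A` corresponds to
#' a volume `(4/3) * pi * (A/pi)^(3/2)`, so the ratio of PHA to cell volume
#' reduces to `v = f^(3/2)`.
#'
#' @param f Area fraction in `[0, 1]` (vectorized).
#' @return Volume fraction `v = f^(3/2)` in `[0, 1]`.
#' @examples
#' area_to_volume_fraction(0.25)  # 0.125
#' @export
area_to_volume_fraction <- function(f) {
  if (any(is.na(f)) || any(f < 0) || any(f > 1))
    stop("`f` must lie in [0, 1]")
  f^1.5
}

#' Per-granule area-to-volume conversion
#'
#' Alternative to [area_to_volume_fraction()] in which each granule's
#' cross-section is converted to a sphere volume separately:
#' `v = sum(A_i^(3/2)) / A_cell^(3/2)`, capped at 1.
#'
#' @param membrane_area_px Cell area in pixels (>= 1).
#' @param pha_areas_px Vector of individual granule areas in pixels.
#' @return Volume fraction in `[0, 1]`.
#' @export
per_granule_volume_fraction <- function(membrane_area_px,
                                        pha_areas_px = numeric()) {
  if (length(membrane_area_px) != 1L || membrane_area_px < 1)
    stop("`membrane_area_px` must be a single count >= 1")
  if (length(pha_areas_px) && any(pha_areas_px < 0))
    stop("granule areas must be >= 0")
  min(1, sum(pha_areas_px^1.5) / membrane_area_px^1.5)
}

#' Volume fraction to mass fraction
#'
#' Converts a PHA volume fraction to a mass fraction using the PHA-to-biomass
#' density ratio `rho`. Under the default two-component mixture model
#' `w = rho*v / (rho*v + (1 - v))`, which is strictly increasing with
#' `w(0) = 0` and `w(1) = 1`.
#'
#' @param v Volume fraction in `[0, 1]` (vectorized).
#' @param params A [conversion_params()].
#' @return Mass fraction in `[0, 1]`.
#' @examples
#' volume_to_mass_fraction(0.5)  # 0.5495 / 1.0495
#' @export
volume_to_mass_fraction <- function(v, params = conversion_params()) {
  stopifnot(inherits(params, "conversion_params"))
  if (any(is.na(v)) || any(v < 0) || any(v > 1))
    stop("`v` must lie in [0, 1]")
  rho <- params$density_ratio
  if (params$mass_model == "mixture") rho * v / (rho * v + (1 - v))
  else pmin(1, rho * v)
}
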