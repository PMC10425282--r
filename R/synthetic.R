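#' Synthetic micrograph scene configuration
#'
#' Describes a field of non-overlapping coccoid cells, each carrying 0-2
#' polar PHA granules, rendered into three co-registered 8-bit fluorescence
#' channels (DNA, membrane, PHA) with Gaussian PSF blur and optional noise.
#' Images are 2-D equatorial projections; the ground truth additionally
#' records 3-D volume fractions from sphere volumes (`sum(r^3)/R^3`), so the
#' pipeline's sphere assumption can be judged against geometric truth.
#'
#' Defaults emulate a high-resource methanotrophic enrichment after a PHA
#' accumulation cycle at ~63x magnification: 50 cells of radius 20 +/- 2 px
#' in a 512 x 512 field, 40% of cells granule-bearing (mostly two granules,
#' at the poles), granule radius 8 px — giving a mean true PHA mass fraction
#' of about 12% (m/m) over granule-bearing cells — interiors at intensity
#' ~180 over background ~20.
#'
#' @param image_size `(rows, cols)` of the field.
#' @param n_cells Number of cells to place.
#' @param cell_radius_px,cell_radius_spread Cell radius drawn uniformly from
#'   `mean +/- spread` (px).
#' @param granules_per_cell Named probabilities for 0, 1 and 2 granules per
#'   cell (names `"0"`, `"1"`, `"2"`); must sum to 1.
#' @param granule_radius_px,granule_radius_spread Granule radius drawn
#'   uniformly from `mean +/- spread` (px); the largest granule must fit in
#'   the smallest cell.
#' @param channel_gains Named interior intensities for `DNA`, `MEMBRANE`,
#'   `PHA` (8-bit scale).
#' @param background_level Background intensity (8-bit scale).
#' @param psf_sigma_px Gaussian point-spread-function sigma in px; 0 disables
#'   blur.
#' @param noise_model `"none"`, `"gaussian"` (additive, sd `noise_sd`), or
#'   `"shot"` (Poisson with the pixel's blurred intensity as its mean).
#' @param noise_sd Standard deviation of Gaussian noise (intensity units).
#' @param min_gap_px Minimum edge-to-edge distance between cells (px); keeps
#'   blurred cells from merging into one connected component.
#' @param seed Integer RNG seed; identical config + seed gives identical
#'   scenes.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(512L, 512L), n_cells = 50L,
                         cell_radius_px = 20, cell_radius_spread = 2,
                         granules_per_cell = c("0" = 0.6, "1" = 0.1,
                                               "2" = 0.3),
                         granule_radius_px = 8, granule_radius_spread = 0,
                         channel_gains = c(DNA = 180, MEMBRANE = 180,
                                           PHA = 180),
                         background_level = 20, psf_sigma_px = 1.2,
                         noise_model = c("none", "gaussian", "shot"),
                         noise_sd = 5, min_gap_px = 6, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (length(image_size) != 2L || any(image_size < 1))
    stop("`image_size` must be (rows, cols) >= 1")
  if (n_cells < 0) stop("`n_cells` must be >= 0")
  if (abs(sum(granules_per_cell) - 1) > 1e-9 ||
      !identical(names(granules_per_cell), c("0", "1", "2")))
    stop("`granules_per_cell` must be probabilities named '0','1','2' summing to 1")
  rmin <- cell_radius_px - cell_radius_spread
  gmax <- granule_radius_px + granule_radius_spread
  if (rmin < 1) stop("cell radius range must stay >= 1 px")
  if (gmax > rmin)
    stop("granules must fit inside cells: max granule radius (", gmax,
         ") exceeds min cell radius (", rmin, ")")
  if (!all(c("DNA", "MEMBRANE", "PHA") %in% names(channel_gains)))
    stop("`channel_gains` must name DNA, MEMBRANE and PHA")
  structure(list(image_size = as.integer(image_size),
                 n_cells = as.integer(n_cells),
                 cell_radius_px = cell_radius_px,
                 cell_radius_spread = cell_radius_spread,
                 granules_per_cell = granules_per_cell,
                 granule_radius_px = granule_radius_px,
                 granule_radius_spread = granule_radius_spread,
                 channel_gains = channel_gains,
                 background_level = background_level,
                 psf_sigma_px = psf_sigma_px,
                 noise_model = noise_model, noise_sd = noise_sd,
                 min_gap_px = min_gap_px, seed = as.integer(seed)),
            class = "scene_config")
}

# paint a disk into `mat` (and optionally a label into `lab`)
.paint_disk <- function(mat, cy, cx, r, value, lab = NULL, label = NULL) {
  nr <- nrow(mat); nc <- ncol(mat)
  r0 <- max(1L, floor(cy - r)); r1 <- min(nr, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(nc, ceiling(cx + r))
  rows <- r0:r1; cols <- c0:c1
  dy <- (rows - cy)^2
  dx <- (cols - cx)^2
  inside <- outer(dy, dx, `+`) <= r^2
  sub <- mat[rows, cols, drop = FALSE]
  sub[inside] <- pmax(sub[inside], value)
  mat[rows, cols] <- sub
  if (!is.null(lab)) {
    lsub <- lab[rows, cols, drop = FALSE]
    lsub[inside] <- label
    lab[rows, cols] <- lsub
    return(list(mat = mat, lab = lab))
  }
  mat
}

.gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  rad <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  lim <- min(dim(mat))
  if (rad > lim) rad <- lim - (1L - lim %% 2L)  # largest odd size that fits
  as.matrix(EBImage::gblur(mat, sigma = sigma, radius = rad))
}

#' Generate a synthetic three-channel micrograph with ground truth
#'
#' Places non-overlapping cells by rejection sampling, draws 0-2 polar
#' granules per cell (granule centres at `min(0.6 R, R - r)` from the cell
#' centre along a random axis, one per pole), renders whole-cell disks into
#' the DNA and membrane channels and granule disks into the PHA channel,
#' then applies Gaussian PSF blur followed by noise to each channel
#' independently.
#'
#' @param cfg A [scene_config()].
#' @return A list of class `synthetic_scene`:
#'   \describe{
#'     \item{dna, membrane, pha}{the three rendered [channel_image()]s.}
#'     \item{truth}{class `scene_truth`: `cells` (per-cell centre, radius,
#'       granule count, `true_area_fraction` = `sum(r^2)/R^2`,
#'       `true_volume_fraction` = `sum(r^3)/R^3`, `true_mass_fraction` via
#'       the density-ratio mixture model), `granules` (per-granule centre
#'       and radius), `cell_mask` and `granule_mask` label images, and the
#'       generating `config`.}
#'   }
#' @examples
#' sc <- generate_scene(scene_config(image_size = c(96, 96), n_cells = 2,
#'                                   seed = 7))
#' sc$truth$cells$n_granules
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, .generate_scene_impl(cfg))
}

.generate_scene_impl <- function(cfg) {
  nr <- cfg$image_size[1]; nc <- cfg$image_size[2]
  n <- cfg$n_cells

  radii <- if (n) runif(n, cfg$cell_radius_px - cfg$cell_radius_spread,
                        cfg$cell_radius_px + cfg$cell_radius_spread)
           else numeric()
  cy <- numeric(n); cx <- numeric(n)
  for (i in seq_len(n)) {
    margin <- radii[i] + 2
    if (2 * margin >= min(nr, nc))
      stop("infeasible packing: cell radius ", round(radii[i], 1),
           " px does not fit the field")
    ok <- FALSE
    for (try in seq_len(5000L)) {
      y <- runif(1, margin, nr - margin)
      x <- runif(1, margin, nc - margin)
      if (i == 1L || all(sqrt((cy[seq_len(i - 1)] - y)^2 +
                              (cx[seq_len(i - 1)] - x)^2) >=
                         radii[seq_len(i - 1)] + radii[i] + cfg$min_gap_px)) {
        cy[i] <- y; cx[i] <- x; ok <- TRUE; break
      }
    }
    if (!ok)
      stop("infeasible packing: could not place cell ", i, " of ", n,
           " after 5000 attempts")
  }

  ngran <- if (n) sample(0:2, n, replace = TRUE, prob = cfg$granules_per_cell)
           else integer()

  bg <- cfg$background_level
  dna_m <- matrix(bg, nr, nc)
  mem_m <- matrix(bg, nr, nc)
  pha_m <- matrix(bg, nr, nc)
  cell_mask <- matrix(0L, nr, nc)
  gran_mask <- matrix(0L, nr, nc)

  gr_list <- vector("list", n)
  gid <- 0L
  for (i in seq_len(n)) {
    res <- .paint_disk(dna_m, cy[i], cx[i], radii[i],
                       cfg$channel_gains[["DNA"]], cell_mask, i)
    dna_m <- res$mat; cell_mask <- res$lab
    mem_m <- .paint_disk(mem_m, cy[i], cx[i], radii[i],
                         cfg$channel_gains[["MEMBRANE"]])
    k <- ngran[i]
    if (k == 0L) { gr_list[[i]] <- NULL; next }
    rg <- runif(k, cfg$granule_radius_px - cfg$granule_radius_spread,
                cfg$granule_radius_px + cfg$granule_radius_spread)
    theta <- runif(1, 0, 2 * pi)
    poles <- if (k == 2L) c(1, -1) else sample(c(1, -1), 1L)
    gy <- numeric(k); gx <- numeric(k)
    for (g in seq_len(k)) {
      off <- min(0.6 * radii[i], radii[i] - rg[g])
      gy[g] <- cy[i] + poles[g] * off * sin(theta)
      gx[g] <- cx[i] + poles[g] * off * cos(theta)
      gid <- gid + 1L
      res <- .paint_disk(pha_m, gy[g], gx[g], rg[g],
                         cfg$channel_gains[["PHA"]], gran_mask, gid)
      pha_m <- res$mat; gran_mask <- res$lab
    }
    gr_list[[i]] <- data.frame(cell_id = i,
                               granule_id = gid - k + seq_len(k),
                               center_row = gy, center_col = gx,
                               radius_px = rg)
  }
  granules <- if (gid) do.call(rbind, gr_list)
              else data.frame(cell_id = integer(), granule_id = integer(),
                              center_row = numeric(), center_col = numeric(),
                              radius_px = numeric())

  render <- function(m) {
    m <- .gaussian_blur(m, cfg$psf_sigma_px)
    if (cfg$noise_model == "gaussian")
      m <- m + rnorm(length(m), 0, cfg$noise_sd)
    else if (cfg$noise_model == "shot")
      m <- matrix(rpois(length(m), pmax(m, 0)), nrow(m), ncol(m))
    matrix(as.integer(pmin(255, pmax(0, round(m)))), nrow(m), ncol(m))
  }

  taf <- tvf <- tmf <- numeric(n)
  for (i in seq_len(n)) {
    g <- granules[granules$cell_id == i, , drop = FALSE]
    taf[i] <- min(1, sum(g$radius_px^2) / radii[i]^2)
    tvf[i] <- min(1, sum(g$radius_px^3) / radii[i]^3)
  }
  tmf <- if (n) volume_to_mass_fraction(tvf) else numeric()

  truth <- structure(list(
    cells = data.frame(cell_id = seq_len(n), center_row = cy,
                       center_col = cx, radius_px = radii,
                       n_granules = ngran, true_area_fraction = taf,
                       true_volume_fraction = tvf, true_mass_fraction = tmf),
    granules = granules,
    cell_mask = cell_mask, granule_mask = gran_mask,
    config = cfg
  ), class = "scene_truth")

  structure(list(
    dna = channel_image(render(dna_m), role = "DNA"),
    membrane = channel_image(render(mem_m), role = "MEMBRANE"),
    pha = channel_image(render(pha_m), role = "PHA"),
    truth = truth
  ), class = "synthetic_scene")
}

#' Ground-truth sample summary of a synthetic scene
#'
#' Recomputes, from the truth records alone, the quantities the image
#' pipeline estimates: the percentage of cells carrying at least one granule
#' and the mean true mass fraction over granule-bearing cells.
#'
#' @param truth A `scene_truth` (from [generate_scene()]) or a list of them
#'   (pooled).
#' @return List: `n_cells`, `n_cells_with_granules`,
#'   `percent_cells_with_pha`, `mean_true_mass_fraction_pct` (`NA` with a
#'   warning when no cell bears granules).
#' @export
truth_summary <- function(truth) {
  if (inherits(truth, "scene_truth")) truth <- list(truth)
  if (!length(truth) || !all(vapply(truth, inherits, TRUE, "scene_truth")))
    stop("`truth` must be one or more scene_truth objects")
  cells <- do.call(rbind, lapply(truth, `[[`, "cells"))
  n <- nrow(cells)
  bearing <- cells$n_granules > 0L
  nb <- sum(bearing)
  if (nb == 0L && n > 0L)
    warning("no granule-bearing cells; mean true mass fraction undefined")
  list(
    n_cells = n,
    n_cells_with_granules = nb,
    percent_cells_with_pha = if (n) 100 * nb / n else NA_real_,
    mean_true_mass_fraction_pct =
      if (nb) 100 * mean(cells$true_mass_fraction[bearing]) else NA_real_
  )
}
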