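#' @rdname run_quantify
#' @param path YAML file path.
#' @export
read_quantify_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  chan <- c("dna", "membrane", "pha")
  per_channel <- function(node, build, default) {
    if (is.null(node)) return(stats::setNames(rep(list(default), 3L), chan))
    if (!any(chan %in% names(node)))  # one spec for all channels
      node <- stats::setNames(rep(list(node), 3L), chan)
    out <- lapply(chan, function(ch) {
      if (is.null(node[[ch]])) default else do.call(build, node[[ch]])
    })
    stats::setNames(out, chan)
  }
  conv <- if (is.null(y$conversion)) conversion_params()
          else do.call(conversion_params, y$conversion)
  quantify_config(
    bernsen = per_channel(y$bernsen, bernsen_params, bernsen_params()),
    filter = per_channel(y$filter, particle_filter,
                         particle_filter(min_area_px = 4)),
    conversion = conv
  )
}

#' @rdname run_simulate
#' @param path YAML file path with [scene_config()] fields.
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$granules_per_cell))
    y$granules_per_cell <- unlist(y$granules_per_cell)
  if (!is.null(y$channel_gains)) y$channel_gains <- unlist(y$channel_gains)
  if (!is.null(y$image_size)) y$image_size <- unlist(y$image_size)
  do.call(scene_config, y)
}

.write_provenance <- function(path, stage, seed, config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(list(
    package = "phaquant",
    version = as.character(packageVersion("phaquant")),
    stage = stage,
    seed = seed,
    config = strip(config)
  ), path)
  invisible(path)
}

#' Simulate a synthetic micrograph field and write its artifacts
#'
#' Generates a scene with [generate_scene()] and writes the three channel
#' TIFFs (`dna.tif`, `membrane.tif`, `pha.tif`), the truth tables
#' (`truth_cells.csv`, `truth_granules.csv`), the truth label masks
#' (`cell_mask.tif`, `granule_mask.tif`) and a provenance file
#' (`provenance.yaml`: package version, seed and full configuration — no
#' timestamps, so identical runs are byte-identical).
#'
#' @param config A [scene_config()] or path to a YAML file of its fields.
#' @param seed Optional integer overriding the config's seed.
#' @param out_dir Output directory (created if needed).
#' @return The `synthetic_scene`, invisibly.
#' @export
run_simulate <- function(config = scene_config(), seed = NULL, out_dir) {
  if (is.character(config)) config <- read_scene_config(config)
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- generate_scene(config)
  write_channel_tiff(sc$dna, file.path(out_dir, "dna.tif"))
  write_channel_tiff(sc$membrane, file.path(out_dir, "membrane.tif"))
  write_channel_tiff(sc$pha, file.path(out_dir, "pha.tif"))
  write.csv(sc$truth$cells, file.path(out_dir, "truth_cells.csv"),
            row.names = FALSE)
  write.csv(sc$truth$granules, file.path(out_dir, "truth_granules.csv"),
            row.names = FALSE)
  write_mask_tiff(sc$truth$cell_mask, file.path(out_dir, "cell_mask.tif"))
  write_mask_tiff(sc$truth$granule_mask,
                  file.path(out_dir, "granule_mask.tif"))
  .write_provenance(file.path(out_dir, "provenance.yaml"), "simulate",
                    config$seed, config)
  invisible(sc)
}

#' Quantify a three-channel field from TIFF files
#'
#' Reads the DNA, membrane and PHA channel TIFFs, runs [quantify_field()],
#' and writes `cells.csv` (one row per cell, fractions both dimensionless
#' and as percent), `fields.csv` (field-level counts), `summary.csv` (the
#' [summarize_sample()] statistics) and `provenance.yaml`. All inputs are
#' read and validated before any output is written.
#'
#' @param dna,membrane,pha Paths to single-channel grayscale TIFFs.
#' @param config A [quantify_config()] or path to a YAML file with optional
#'   `bernsen`, `filter` (global or per-channel `dna`/`membrane`/`pha`) and
#'   `conversion` blocks.
#' @param out_dir Output directory (created if needed).
#' @return The `field_result`, invisibly.
#' @export
run_quantify <- function(dna, membrane, pha, config = quantify_config(),
                         out_dir) {
  if (is.character(config)) config <- read_quantify_config(config)
  stopifnot(inherits(config, "quantify_config"))
  di <- read_channel_tiff(dna, "DNA")
  mi <- read_channel_tiff(membrane, "MEMBRANE")
  pi_ <- read_channel_tiff(pha, "PHA")
  fr <- quantify_field(di, mi, pi_, config)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cells <- fr$cells
  cells$area_pct <- 100 * cells$area_fraction
  cells$volume_pct <- 100 * cells$volume_fraction
  cells$mass_pct <- 100 * cells$mass_fraction
  write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  write.csv(as.data.frame(fr$counts), file.path(out_dir, "fields.csv"),
            row.names = FALSE)
  sm <- summarize_sample(list(fr))
  write.csv(data.frame(
    n_images = sm$n_images, dna_cell_count = sm$dna_cell_count,
    n_membrane_cells = sm$n_membrane_cells,
    n_cells_with_pha = sm$n_cells_with_pha,
    percent_cells_with_pha = sm$percent_cells_with_pha,
    mean_mass_fraction_pct = sm$mean_mass_fraction_pct,
    mean_mass_fraction_all_cells_pct = sm$mean_mass_fraction_all_cells_pct
  ), file.path(out_dir, "summary.csv"), row.names = FALSE)
  .write_provenance(file.path(out_dir, "provenance.yaml"), "quantify",
                    NA_integer_, config)
  invisible(fr)
}

#' Compute growth-cycle yields from a CSV time series
#'
#' Reads a growth-cycle CSV (columns `time_h`, `ch4_pct`, `nh4_mM`,
#' `cells_per_mL`), computes [growth_cycle_yields()] and writes them as a
#' one-row `yields.csv` plus `provenance.yaml` to `out_dir`.
#'
#' @param cycle_csv Path to the growth-cycle CSV.
#' @param config Optional path to a YAML file with bottle geometry keys
#'   (`liquid_volume_mL`, `headspace_volume_mL`, `temperature_K`,
#'   `pressure_atm`), or a named list of the same.
#' @param out_dir Output directory.
#' @return The `yield_result`, invisibly.
#' @export
run_yields <- function(cycle_csv, config = NULL, out_dir) {
  geom <- list()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    geom <- yaml::read_yaml(config)
  } else if (is.list(config)) geom <- config
  cyc <- do.call(read_growth_cycle, c(list(path = cycle_csv), geom))
  yr <- growth_cycle_yields(cyc)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(unclass(yr)), file.path(out_dir, "yields.csv"),
            row.names = FALSE)
  .write_provenance(file.path(out_dir, "provenance.yaml"), "yields",
                    NA_integer_, geom)
  invisible(yr)
}

#' End-to-end recovery check: simulate, quantify, compare to truth
#'
#' Generates a synthetic scene, quantifies it with the image pipeline, and
#' reports the recovered versus true percent-of-cells-with-PHA and mean
#' per-cell PHA mass fraction. Writes `recover.csv` when `out_dir` is given.
#'
#' @param scene_cfg A [scene_config()].
#' @param quant_cfg A [quantify_config()].
#' @param out_dir Optional output directory.
#' @return Data frame with one row: recovered and true statistics plus their
#'   differences.
#' @export
run_recover <- function(scene_cfg = scene_config(),
                        quant_cfg = quantify_config(), out_dir = NULL) {
  sc <- generate_scene(scene_cfg)
  fr <- quantify_field(sc$dna, sc$membrane, sc$pha, quant_cfg)
  sm <- summarize_sample(list(fr))
  ts <- truth_summary(sc$truth)
  out <- data.frame(
    seed = scene_cfg$seed,
    n_cells_truth = ts$n_cells,
    dna_cell_count = sm$dna_cell_count,
    percent_cells_with_pha_recovered = sm$percent_cells_with_pha,
    percent_cells_with_pha_truth = ts$percent_cells_with_pha,
    mean_mass_pct_recovered = sm$mean_mass_fraction_pct,
    mean_mass_pct_truth = ts$mean_true_mass_fraction_pct
  )
  out$percent_points_error <- out$percent_cells_with_pha_recovered -
    out$percent_cells_with_pha_truth
  out$mass_relative_error <- (out$mean_mass_pct_recovered -
    out$mean_mass_pct_truth) / out$mean_mass_pct_truth
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(out_dir, "recover.csv"), row.names = FALSE)
    .write_provenance(file.path(out_dir, "provenance.yaml"), "recover",
                      scene_cfg$seed, list(scene = scene_cfg,
                                           quantify = quant_cfg))
  }
  out
}
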