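#' Configuration for field quantification
#'
#' Bundles per-channel thresholding parameters, per-channel particle filters
#' and the fraction-conversion parameters used by [quantify_field()].
#'
#' Default particle filters assume the ~63x objective scale of the
#' synthetic generator (cells tens of pixels across): cell channels keep
#' components of at least 20 px, the granule channel at least 4 px, to
#' suppress single-pixel noise without discarding real objects.
#'
#' @param bernsen Named list of [bernsen_params()] for `dna`, `membrane`,
#'   `pha`; a single `bernsen_params` is recycled to all three channels.
#' @param filter Named list of [particle_filter()] for `dna`, `membrane`,
#'   `pha`; a single `particle_filter` is recycled likewise.
#' @param conversion A [conversion_params()].
#' @return An object of class `quantify_config`.
#' @export
quantify_config <- function(bernsen = bernsen_params(),
                            filter = list(
                              dna = particle_filter(min_area_px = 20),
                              membrane = particle_filter(min_area_px = 20),
                              pha = particle_filter(min_area_px = 4)),
                            conversion = conversion_params()) {
  chan <- c("dna", "membrane", "pha")
  if (inherits(bernsen, "bernsen_params"))
    bernsen <- stats::setNames(rep(list(bernsen), 3L), chan)
  if (inherits(filter, "particle_filter"))
    filter <- stats::setNames(rep(list(filter), 3L), chan)
  if (!all(chan %in% names(bernsen)))
    stop("`bernsen` must name dna, membrane and pha entries")
  if (!all(chan %in% names(filter)))
    stop("`filter` must name dna, membrane and pha entries")
  stopifnot(inherits(conversion, "conversion_params"))
  structure(list(bernsen = bernsen[chan], filter = filter[chan],
                 conversion = conversion),
            class = "quantify_config")
}

#' Count cells from the DNA channel
#'
#' Each surviving particle of the DNA (nucleic-acid stain) channel is counted
#' as one cell.
#'
#' @param dna_particles A [particle_set()] derived from the DNA channel.
#' @return Integer cell count.
#' @export
count_cells_dna <- function(dna_particles) {
  stopifnot(inherits(dna_particles, "particle_set"))
  nrow(dna_particles$particles)
}

#' Percentage of cells with detectable PHA
#'
#' The number of cells carrying at least one assigned PHA particle divided by
#' the DNA-channel cell count, as a percentage. The numerator comes from the
#' membrane channel and the denominator from the DNA channel (the membrane
#' stain does not mark all cells), so values above 100 are possible when the
#' channels disagree; they are flagged with a warning but not clipped.
#'
#' @param n_cells_with_pha Count of PHA-positive cells.
#' @param dna_cell_count DNA-channel cell count (>= 1).
#' @return Percentage (0-100, possibly above 100).
#' @examples
#' percent_cells_with_pha(38, 100)  # 38
#' @export
percent_cells_with_pha <- function(n_cells_with_pha, dna_cell_count) {
  if (length(dna_cell_count) != 1L || is.na(dna_cell_count) ||
      dna_cell_count < 1)
    stop("`dna_cell_count` must be >= 1")
  pct <- 100 * n_cells_with_pha / dna_cell_count
  if (pct > 100)
    warning("more PHA-positive membrane cells than DNA-counted cells (",
            round(pct, 1), "%); channels disagree")
  pct
}

#' Quantify PHA content of every cell in one field of view
#'
#' Runs the full single-field pipeline on three co-registered channels:
#' Bernsen thresholding of each channel, particle analysis, assignment of PHA
#' particles to membrane-defined cells by centroid containment/overlap, and
#' per-cell conversion of the PHA area fraction to volume and mass fractions.
#' Deterministic for fixed inputs and configuration.
#'
#' @param dna,membrane,pha [channel_image()] objects of identical dimensions
#'   with the corresponding roles.
#' @param config A [quantify_config()].
#' @return A list of class `field_result`:
#'   \describe{
#'     \item{cells}{data frame, one row per membrane-defined cell: `cell_label`,
#'       `membrane_area_px`, `n_pha_particles`, `pha_area_px`,
#'       `area_fraction`, `volume_fraction`, `mass_fraction`, `has_pha`.}
#'     \item{counts}{list: `dna_cell_count`, `membrane_cell_count`,
#'       `pha_particle_count`, `n_pha_unassigned`, `n_cells_with_pha`,
#'       `percent_cells_with_pha` (`NA` when no DNA cells).}
#'     \item{particles}{the three [particle_set()]s (`dna`, `membrane`,
#'       `pha`) for inspection or export.}
#'   }
#' @export
quantify_field <- function(dna, membrane, pha, config = quantify_config()) {
  stopifnot(inherits(dna, "channel_image"), inherits(membrane, "channel_image"),
            inherits(pha, "channel_image"), inherits(config, "quantify_config"))
  if (dna$role != "DNA" || membrane$role != "MEMBRANE" || pha$role != "PHA")
    stop("channel roles must be DNA, MEMBRANE, PHA in that order")
  d <- dim(dna$pixels)
  if (!identical(d, dim(membrane$pixels)) || !identical(d, dim(pha$pixels)))
    stop("channel dimensions differ; channels must be co-registered")

  ps <- list(
    dna = label_particles(bernsen_threshold(dna, config$bernsen$dna),
                          config$filter$dna),
    membrane = label_particles(bernsen_threshold(membrane,
                                                 config$bernsen$membrane),
                               config$filter$membrane),
    pha = label_particles(bernsen_threshold(pha, config$bernsen$pha),
                          config$filter$pha)
  )

  assign <- overlap_assign(ps$pha, ps$membrane)
  mem <- ps$membrane$particles
  phap <- ps$pha$particles
  n_cells <- nrow(mem)

  cells <- data.frame(
    cell_label = mem$label,
    membrane_area_px = mem$area_px,
    n_pha_particles = rep(0L, n_cells), pha_area_px = rep(0L, n_cells),
    area_fraction = rep(0, n_cells), volume_fraction = rep(0, n_cells),
    mass_fraction = rep(0, n_cells), has_pha = rep(FALSE, n_cells)
  )
  if (n_cells > 0L && nrow(assign) > 0L) {
    conv <- config$conversion
    for (i in seq_len(n_cells)) {
      gi <- assign$child_label[!is.na(assign$parent_label) &
                                 assign$parent_label == cells$cell_label[i]]
      if (!length(gi)) next
      areas <- phap$area_px[match(gi, phap$label)]
      cells$n_pha_particles[i] <- length(gi)
      cells$pha_area_px[i] <- sum(areas)
      cells$area_fraction[i] <-
        cell_area_fraction(cells$membrane_area_px[i], areas)
      cells$volume_fraction[i] <- if (conv$volume_model == "aggregate")
        area_to_volume_fraction(cells$area_fraction[i])
      else per_granule_volume_fraction(cells$membrane_area_px[i], areas)
      cells$mass_fraction[i] <-
        volume_to_mass_fraction(cells$volume_fraction[i], conv)
      cells$has_pha[i] <- TRUE
    }
  }

  dna_n <- count_cells_dna(ps$dna)
  n_with <- sum(cells$has_pha)
  counts <- list(
    dna_cell_count = dna_n,
    membrane_cell_count = n_cells,
    pha_particle_count = nrow(phap),
    n_pha_unassigned = sum(is.na(assign$parent_label)),
    n_cells_with_pha = n_with,
    percent_cells_with_pha =
      if (dna_n >= 1L) percent_cells_with_pha(n_with, dna_n) else NA_real_
  )
  structure(list(cells = cells, counts = counts, particles = ps),
            class = "field_result")
}

#' @export
print.field_result <- function(x, ...) {
  cat(sprintf(
    "<field_result> %d DNA cells, %d membrane cells, %d with PHA (%s%%)\n",
    x$counts$dna_cell_count, x$counts$membrane_cell_count,
    x$counts$n_cells_with_pha,
    ifelse(is.na(x$counts$percent_cells_with_pha), "NA",
           sprintf("%.1f", x$counts$percent_cells_with_pha))))
  invisible(x)
}

#' Pool per-field results into a sample summary
#'
#' Pools cells over all fields imaged for one sample. The
#' percent-of-cells-with-PHA statistic is computed from the pooled counts
#' (PHA-positive membrane cells over DNA-counted cells), and the mean
#' single-cell PHA mass fraction is reported over PHA-containing cells, with
#' an all-cells mean alongside for transparency.
#'
#' @param fields List of [quantify_field()] results (>= 1).
#' @return A list of class `sample_summary`: `n_images`, `dna_cell_count`,
#'   `n_membrane_cells`, `n_cells_with_pha`, `percent_cells_with_pha`,
#'   `per_cell_mass_fractions` (pooled, PHA-positive cells),
#'   `mean_mass_fraction_pct` (% m/m over PHA-positive cells),
#'   `mean_mass_fraction_all_cells_pct`.
#' @export
summarize_sample <- function(fields) {
  if (inherits(fields, "field_result")) fields <- list(fields)
  if (!length(fields) || !all(vapply(fields, inherits, TRUE, "field_result")))
    stop("`fields` must be a non-empty list of field results")
  dna_total <- sum(vapply(fields,
                          function(f) as.integer(f$counts$dna_cell_count),
                          0L))
  if (dna_total < 1L) stop("no DNA-counted cells pooled over fields")
  cells <- do.call(rbind, lapply(fields, `[[`, "cells"))
  n_with <- sum(cells$has_pha)
  wpos <- cells$mass_fraction[cells$has_pha]
  structure(list(
    n_images = length(fields),
    dna_cell_count = dna_total,
    n_membrane_cells = nrow(cells),
    n_cells_with_pha = n_with,
    percent_cells_with_pha = percent_cells_with_pha(n_with, dna_total),
    per_cell_mass_fractions = wpos,
    mean_mass_fraction_pct = if (n_with) 100 * mean(wpos) else NA_real_,
    mean_mass_fraction_all_cells_pct =
      if (nrow(cells)) 100 * mean(cells$mass_fraction) else NA_real_
  ), class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<sample_summary> %d image(s), %d DNA cells, %d/%d membrane cells with ",
    "PHA\n  percent cells with PHA: %.1f%%\n  mean PHA content ",
    "(PHA-positive cells): %s%% (m/m)\n"),
    x$n_images, x$dna_cell_count, x$n_cells_with_pha, x$n_membrane_cells,
    x$percent_cells_with_pha,
    ifelse(is.na(x$mean_mass_fraction_pct), "NA",
           sprintf("%.2f", x$mean_mass_fraction_pct))))
  invisible(x)
}
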