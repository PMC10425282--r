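#' Particle size/border filter
#'
#' Filter applied during particle analysis: connected components with pixel
#' area outside `[min_area_px, max_area_px]`, or touching the image border
#' when `exclude_border` is set, are dropped.
#'
#' @param min_area_px Minimum component area in pixels (>= 0).
#' @param max_area_px Maximum component area in pixels; `Inf` for unbounded.
#' @param exclude_border Drop components touching any image edge?
#' @return An object of class `particle_filter`.
#' @export
particle_filter <- function(min_area_px = 0L, max_area_px = Inf,
                            exclude_border = FALSE) {
  if (min_area_px < 0) stop("`min_area_px` must be >= 0")
  if (max_area_px < min_area_px) stop("`min_area_px` must be <= `max_area_px`")
  structure(list(min_area_px = min_area_px, max_area_px = max_area_px,
                 exclude_border = isTRUE(exclude_border)),
            class = "particle_filter")
}

#' Particle analysis: label and measure connected components
#'
#' Enumerates 8-connected components of the object pixels of a binary mask,
#' applies the size and border filter, and relabels surviving components
#' `1..n` in raster order (row by row) of their first pixel. Per particle the
#' pixel area, centroid, bounding box and a border-contact flag are recorded.
#'
#' @param mask A [binary_mask()] or logical matrix.
#' @param filt A [particle_filter()].
#' @return An object of class `particle_set`: a list with
#'   \describe{
#'     \item{particles}{data frame with columns `label`, `area_px`,
#'       `centroid_row`, `centroid_col`, `bbox_min_row`, `bbox_min_col`,
#'       `bbox_max_row`, `bbox_max_col`, `touches_border`.}
#'     \item{label_image}{integer matrix, 0 = background.}
#'     \item{dropped_area_px}{total object pixels removed by the filter, so
#'       that `sum(particles$area_px) + dropped_area_px` equals the object
#'       pixel count of the mask.}
#'     \item{provenance}{filter settings and source-mask provenance.}
#'   }
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:4, 2:4] <- TRUE; m[7, 7] <- TRUE
#' ps <- label_particles(m, particle_filter(min_area_px = 5))
#' ps$particles$area_px  # the 1-px speck is dropped
#' @export
label_particles <- function(mask, filt = particle_filter()) {
  if (inherits(mask, "binary_mask")) {
    prov <- mask$provenance
    mask <- mask$pixels
  } else prov <- list()
  stopifnot(is.matrix(mask), is.logical(mask))
  stopifnot(inherits(filt, "particle_filter"))

  lab <- label8_cpp(mask)
  nlab <- max(lab)
  empty <- data.frame(label = integer(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      bbox_min_row = integer(), bbox_min_col = integer(),
                      bbox_max_row = integer(), bbox_max_col = integer(),
                      touches_border = logical())
  if (nlab == 0L) {
    return(structure(list(particles = empty, label_image = lab,
                          dropped_area_px = 0L,
                          provenance = list(filter = unclass(filt),
                                            source = prov)),
                     class = "particle_set"))
  }

  idx <- which(lab > 0L)
  labs <- lab[idx]
  rc <- arrayInd(idx, dim(lab))
  f <- factor(labs, levels = seq_len(nlab))
  rows <- split(rc[, 1L], f)
  cols <- split(rc[, 2L], f)
  area <- tabulate(labs, nbins = nlab)
  stats <- data.frame(
    label = seq_len(nlab),
    area_px = area,
    centroid_row = vapply(rows, mean, 0),
    centroid_col = vapply(cols, mean, 0),
    bbox_min_row = vapply(rows, min, 0L),
    bbox_min_col = vapply(cols, min, 0L),
    bbox_max_row = vapply(rows, max, 0L),
    bbox_max_col = vapply(cols, max, 0L),
    row.names = NULL
  )
  stats$touches_border <- stats$bbox_min_row == 1L | stats$bbox_min_col == 1L |
    stats$bbox_max_row == nrow(mask) | stats$bbox_max_col == ncol(mask)

  keep <- stats$area_px >= filt$min_area_px & stats$area_px <= filt$max_area_px
  if (filt$exclude_border) keep <- keep & !stats$touches_border
  dropped <- sum(stats$area_px[!keep])

  kept <- stats[keep, , drop = FALSE]
  map <- integer(nlab)
  map[kept$label] <- seq_len(nrow(kept))
  kept$label <- seq_len(nrow(kept))
  rownames(kept) <- NULL
  newlab <- lab
  newlab[idx] <- map[labs]

  structure(list(particles = if (nrow(kept)) kept else empty,
                 label_image = newlab,
                 dropped_area_px = dropped,
                 provenance = list(filter = unclass(filt), source = prov)),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles, %d x %d px, %d object px dropped\n",
              nrow(x$particles), nrow(x$label_image), ncol(x$label_image),
              x$dropped_area_px))
  invisible(x)
}

#' Assign child particles to parent particles by containment/overlap
#'
#' Attributes each child particle (e.g. a PHA granule) to a parent particle
#' (e.g. a membrane-defined cell). A child is assigned to the parent whose
#' region contains the child's centroid (rounded to the nearest pixel); if
#' the centroid falls on parent background, to the parent with maximal pixel
#' overlap with the child's region; a child with zero overlap with every
#' parent is unassigned (`NA`). Ties are broken by the lowest parent label,
#' so the assignment is deterministic.
#'
#' @param children,parents [particle_set()] objects derived from images of
#'   identical dimensions.
#' @return Data frame with columns `child_label`, `parent_label` (`NA` when
#'   unassigned).
#' @export
overlap_assign <- function(children, parents) {
  stopifnot(inherits(children, "particle_set"),
            inherits(parents, "particle_set"))
  if (!identical(dim(children$label_image), dim(parents$label_image)))
    stop("children and parents derive from images of different dimensions")
  plab <- parents$label_image
  cl <- children$particles
  n <- nrow(cl)
  out <- data.frame(child_label = cl$label, parent_label = rep(NA_integer_, n))
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    r <- min(max(1L, as.integer(round(cl$centroid_row[i]))), nrow(plab))
    c <- min(max(1L, as.integer(round(cl$centroid_col[i]))), ncol(plab))
    hit <- plab[r, c]
    if (hit > 0L) {
      out$parent_label[i] <- hit
      next
    }
    overlap <- plab[children$label_image == cl$label[i]]
    overlap <- overlap[overlap > 0L]
    if (length(overlap)) {
      counts <- tabulate(overlap)
      out$parent_label[i] <- which.max(counts)  # ties -> lowest label
    }
  }
  out
}

#' Write a particle table to CSV
#'
#' @param ps A [particle_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_particles_csv <- function(ps, path) {
  stopifnot(inherits(ps, "particle_set"))
  write.csv(ps$particles, path, row.names = FALSE)
  invisible(path)
}
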