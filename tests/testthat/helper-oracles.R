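# Independent oracles used to validate the image operators, plus small
# fixture builders. These stay deliberately naive (per-pixel loops, queues)
# and share no code with the implementation.

# brute-force Bernsen: per-pixel scan of the clipped circular window
oracle_bernsen <- function(px, radius, contrast_threshold, low_contrast_cut) {
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      vals <- integer()
      for (rr in max(1, r - radius):min(nr, r + radius)) {
        dy <- rr - r
        w <- floor(sqrt(radius^2 - dy^2))
        cs <- max(1, c - w):min(nc, c + w)
        vals <- c(vals, px[rr, cs])
      }
      mx <- max(vals); mn <- min(vals)
      out[r, c] <- if (mx - mn < contrast_threshold)
        (mx + mn) >= 2 * low_contrast_cut
      else 2 * px[r, c] > (mx + mn)
    }
  }
  out
}

# queue-based flood fill, 8-connected, seeds scanned in raster order
oracle_flood_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!mask[r, c] || lab[r, c] != 0L) next
      nxt <- nxt + 1L
      queue <- list(c(r, c))
      lab[r, c] <- nxt
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          if (mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nxt
            queue[[length(queue) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# exhaustive pixel-overlap maximization between two label images
oracle_overlap <- function(child_lab, parent_lab) {
  labs <- sort(unique(child_lab[child_lab > 0L]))
  vapply(labs, function(l) {
    ov <- parent_lab[child_lab == l]
    ov <- ov[ov > 0L]
    if (!length(ov)) return(NA_integer_)
    counts <- tabulate(ov)
    which.max(counts)
  }, integer(1))
}

random_mask <- function(nr, nc, density = 0.2) {
  matrix(runif(nr * nc) < density, nr, nc)
}

make_img <- function(px, role = "PHA") {
  storage.mode(px) <- "integer"
  channel_image(px, role = role)
}

# small scene configuration that keeps unit tests fast
cfg_small <- function(n_cells = 8L, seed = 1L, ...) {
  scene_config(image_size = c(256L, 256L), n_cells = n_cells, seed = seed,
               ...)
}
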