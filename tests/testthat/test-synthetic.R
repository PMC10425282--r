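test_that("an empty scene renders background-only channels", {
  sc <- generate_scene(scene_config(image_size = c(64L, 64L), n_cells = 0L,
                                    psf_sigma_px = 0, seed = 1L))
  expect_true(all(sc$dna$pixels == 20L))
  expect_true(all(sc$pha$pixels == 20L))
  expect_equal(nrow(sc$truth$cells), 0L)
  expect_equal(nrow(sc$truth$granules), 0L)
})

test_that("identical seed and config reproduce identical pixel arrays", {
  cfg <- cfg_small(n_cells = 6L, seed = 123L, noise_model = "gaussian",
                   noise_sd = 3)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$dna$pixels, b$dna$pixels)
  expect_identical(a$membrane$pixels, b$membrane$pixels)
  expect_identical(a$pha$pixels, b$pha$pixels)
  expect_identical(a$truth$cells, b$truth$cells)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(generate_scene(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("rasterized masks of a known cell reproduce analytic areas", {
  cfg <- scene_config(image_size = c(128L, 128L), n_cells = 1L,
                      cell_radius_px = 20, cell_radius_spread = 0,
                      granules_per_cell = c("0" = 0, "1" = 0, "2" = 1),
                      granule_radius_px = 5, granule_radius_spread = 0,
                      psf_sigma_px = 0, noise_model = "none", seed = 2L)
  sc <- generate_scene(cfg)
  f_measured <- sum(sc$truth$granule_mask > 0L) / sum(sc$truth$cell_mask > 0L)
  # at granule radius 5 px, rasterization moves disk areas by a few percent
  expect_equal(f_measured, 2 * 25 / 400, tolerance = 0.05)
  # 3-D truth uses sphere volumes, not areas
  expect_equal(sc$truth$cells$true_volume_fraction, 2 * 5^3 / 20^3,
               tolerance = 1e-12)
})

test_that("granules always lie inside their cell", {
  for (seed in 1:5) {
    sc <- generate_scene(cfg_small(n_cells = 10L, seed = seed))
    tr <- sc$truth
    for (i in seq_len(nrow(tr$granules))) {
      g <- tr$granules[i, ]
      cell <- tr$cells[tr$cells$cell_id == g$cell_id, ]
      d <- sqrt((g$center_row - cell$center_row)^2 +
                (g$center_col - cell$center_col)^2)
      expect_lte(d + g$radius_px, cell$radius_px + 1e-9)
    }
  }
})

test_that("infeasible packing fails with a clear error", {
  cfg <- scene_config(image_size = c(100L, 100L), n_cells = 20L,
                      cell_radius_px = 20, cell_radius_spread = 0, seed = 1L)
  expect_error(generate_scene(cfg), "infeasible packing")
})

test_that("truth summaries equal an exhaustive recount of the records", {
  for (seed in 1:5) {
    sc <- generate_scene(cfg_small(n_cells = 12L, seed = 200L + seed))
    ts <- truth_summary(sc$truth)
    cells <- sc$truth$cells
    expect_equal(ts$n_cells, nrow(cells))
    expect_equal(ts$n_cells_with_granules, sum(cells$n_granules > 0))
    expect_equal(ts$percent_cells_with_pha,
                 100 * mean(cells$n_granules > 0))
    if (ts$n_cells_with_granules > 0)
      expect_equal(ts$mean_true_mass_fraction_pct,
                   100 * mean(cells$true_mass_fraction[cells$n_granules > 0]))
  }
})

test_that("a granule-free scene flags the undefined mean", {
  cfg <- cfg_small(n_cells = 4L, seed = 3L,
                   granules_per_cell = c("0" = 1, "1" = 0, "2" = 0))
  sc <- generate_scene(cfg)
  expect_warning(ts <- truth_summary(sc$truth), "undefined")
  expect_equal(ts$percent_cells_with_pha, 0)
  expect_true(is.na(ts$mean_true_mass_fraction_pct))
})

test_that("detection accuracy does not improve when noise is added", {
  acc <- function(noise_sd) {
    errs <- vapply(1:3, function(s) {
      cfg <- cfg_small(n_cells = 10L, seed = 300L + s,
                       noise_model = if (noise_sd > 0) "gaussian" else "none",
                       noise_sd = noise_sd)
      sc <- generate_scene(cfg)
      fr <- quantify_field(sc$dna, sc$membrane, sc$pha)
      sm <- summarize_sample(list(fr))
      ts <- truth_summary(sc$truth)
      abs(sm$percent_cells_with_pha - ts$percent_cells_with_pha)
    }, 0)
    mean(errs)
  }
  # sd 12 overwhelms the default contrast threshold and must not beat sd 0
  expect_lte(acc(0), acc(12))
})

test_that("scene config validation rejects impossible geometries", {
  expect_error(scene_config(granule_radius_px = 25), "fit inside")
  expect_error(scene_config(granules_per_cell = c("0" = 0.5, "1" = 0.2,
                                                  "2" = 0.2)), "summing to 1")
})
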