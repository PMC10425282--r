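test_that("all-zero channels give zero cells and zero particles", {
  z <- matrix(0L, 64, 64)
  fr <- quantify_field(channel_image(z, "DNA"), channel_image(z, "MEMBRANE"),
                       channel_image(z, "PHA"))
  expect_equal(fr$counts$dna_cell_count, 0L)
  expect_equal(fr$counts$membrane_cell_count, 0L)
  expect_equal(fr$counts$pha_particle_count, 0L)
  expect_equal(nrow(fr$cells), 0L)
  expect_true(is.na(fr$counts$percent_cells_with_pha))
})

test_that("channel size mismatch and role confusion are errors", {
  a <- channel_image(matrix(0L, 8, 8), "DNA")
  b <- channel_image(matrix(0L, 8, 8), "MEMBRANE")
  p9 <- channel_image(matrix(0L, 9, 9), "PHA")
  expect_error(quantify_field(a, b, p9), "co-registered")
  p8 <- channel_image(matrix(0L, 8, 8), "DNA")
  expect_error(quantify_field(a, b, p8), "roles")
})

test_that("a single synthetic cell with known granule load is recovered", {
  # two granules of radius R*sqrt(0.125) in a cell of radius 20:
  # analytic area fraction 2*0.125 = 0.25, aggregate volume 0.25^1.5 = 0.125
  cfg <- scene_config(image_size = c(128L, 128L), n_cells = 1L,
                      cell_radius_px = 20, cell_radius_spread = 0,
                      granules_per_cell = c("0" = 0, "1" = 0, "2" = 1),
                      granule_radius_px = 20 * sqrt(0.125),
                      granule_radius_spread = 0,
                      psf_sigma_px = 0, noise_model = "none", seed = 9L)
  sc <- generate_scene(cfg)
  fr <- quantify_field(sc$dna, sc$membrane, sc$pha)
  expect_equal(nrow(fr$cells), 1L)
  expect_equal(fr$cells$n_pha_particles, 2L)
  expect_equal(fr$cells$area_fraction, 0.25, tolerance = 0.02)
  expect_equal(fr$cells$volume_fraction, 0.125, tolerance = 0.03)
})

test_that("DNA cell counts on noiseless non-touching scenes are exact", {
  for (seed in 1:3) {
    k <- c(5L, 9L, 12L)[seed]
    sc <- generate_scene(cfg_small(n_cells = k, seed = seed,
                                   psf_sigma_px = 0, noise_model = "none"))
    fr <- quantify_field(sc$dna, sc$membrane, sc$pha)
    expect_equal(fr$counts$dna_cell_count, k)
    expect_equal(fr$counts$membrane_cell_count, k)
    # per-cell PHA flags match the generator's truth exactly
    truth_bearing <- sc$truth$cells$n_granules > 0L
    expect_equal(sum(fr$cells$has_pha), sum(truth_bearing))
  }
})

test_that("percent of cells with PHA uses the DNA denominator", {
  expect_equal(percent_cells_with_pha(38, 100), 38)
  expect_equal(percent_cells_with_pha(0, 100), 0)
  expect_error(percent_cells_with_pha(5, 0), ">= 1")
  expect_warning(pct <- percent_cells_with_pha(12, 10), "disagree")
  expect_equal(pct, 120)
})

test_that("sample summaries pool cells over fields", {
  mk <- function(n_with, n_dna) {
    cells <- data.frame(cell_label = seq_len(n_dna),
                        membrane_area_px = 100L, n_pha_particles = 0L,
                        pha_area_px = 0L, area_fraction = 0,
                        volume_fraction = 0, mass_fraction = 0,
                        has_pha = FALSE)
    if (n_with > 0) {
      cells$has_pha[seq_len(n_with)] <- TRUE
      cells$mass_fraction[seq_len(n_with)] <- 0.1
    }
    structure(list(cells = cells,
                   counts = list(dna_cell_count = n_dna,
                                 membrane_cell_count = n_dna,
                                 pha_particle_count = n_with,
                                 n_pha_unassigned = 0L,
                                 n_cells_with_pha = n_with,
                                 percent_cells_with_pha = 100 * n_with / n_dna),
                   particles = NULL),
              class = "field_result")
  }
  one <- summarize_sample(list(mk(38, 100)))
  expect_equal(one$percent_cells_with_pha, 38)
  two <- summarize_sample(list(mk(10, 50), mk(30, 50)))
  expect_equal(two$percent_cells_with_pha, 40)
  expect_equal(two$n_images, 2L)
  expect_equal(two$mean_mass_fraction_pct, 10)
  expect_error(summarize_sample(list()), "non-empty")
})

test_that("pooled summaries of noiseless multi-field samples match truth", {
  scenes <- lapply(1:4, function(s)
    generate_scene(cfg_small(n_cells = 10L, seed = 100L + s,
                             psf_sigma_px = 0, noise_model = "none")))
  fields <- lapply(scenes, function(sc)
    quantify_field(sc$dna, sc$membrane, sc$pha))
  sm <- summarize_sample(fields)
  ts <- truth_summary(lapply(scenes, `[[`, "truth"))
  expect_equal(sm$dna_cell_count, ts$n_cells)
  expect_equal(sm$n_cells_with_pha, ts$n_cells_with_granules)
  expect_equal(sm$percent_cells_with_pha, ts$percent_cells_with_pha)
})

test_that("quantification is deterministic for fixed inputs", {
  sc <- generate_scene(cfg_small(n_cells = 6L, seed = 77L))
  f1 <- quantify_field(sc$dna, sc$membrane, sc$pha)
  f2 <- quantify_field(sc$dna, sc$membrane, sc$pha)
  expect_identical(f1$cells, f2$cells)
  expect_identical(f1$counts, f2$counts)
})
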