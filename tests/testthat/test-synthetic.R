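# Synthetic imaging: scene validation, placement, rendering, ground truth.

test_that("scene_spec validates its invariants", {
  expect_error(scene_spec(seed = 1, wpb_length_um = c(5, 1)), "min <= max")
  expect_error(scene_spec(seed = 1, pixel_size_um = 0), "> 0")
  expect_error(scene_spec(seed = 1, nucleus_count = -1), ">= 0")
  expect_error(scene_spec(nucleus_count = 1), "seed")
  sp <- scene_spec(seed = 1)
  expect_identical(sp$n_slices, 23L)
  expect_equal(sp$z_step_um, 0.3)
  expect_equal(sp$wpb_length_um, c(1, 5))
  expect_equal(sp$wpb_width_um, c(0.1, 0.3))
})

test_that("an empty noiseless scene renders uniform background", {
  sp <- scene_spec(field_width_px = 64, field_height_px = 48, n_slices = 4,
                   noise_sd = 0, background_level = 0.2, seed = 3)
  f <- render_field(sp)
  expect_true(all(f$image$nuclei_channel == 0.2))
  expect_true(all(f$image$vwf_channel == 0.2))
  expect_equal(dim(f$image$vwf_channel), c(48, 64, 4))
})

test_that("ground-truth inventory matches requested counts and stays in bounds", {
  sp <- scene_spec(field_width_px = 256, field_height_px = 256, n_slices = 5,
                   nucleus_count = 7, wpb_count = 30, immature_count = 4,
                   seed = 11)
  f <- render_field(sp)
  expect_equal(nrow(f$truth$nuclei), 7)
  expect_equal(nrow(f$truth$wpbs), 30)
  expect_equal(nrow(f$truth$immature), 4)
  for (df in f$truth[c("nuclei", "wpbs", "immature")]) {
    expect_true(all(df$y_px > -0.5 & df$y_px < 255.5))
    expect_true(all(df$x_px > -0.5 & df$x_px < 255.5))
  }
  # sampled morphology respects the configured ranges (in um)
  expect_true(all(f$truth$wpbs$length_px * sp$pixel_size_um >= 1 - 1e-9))
  expect_true(all(f$truth$wpbs$length_px * sp$pixel_size_um <= 5 + 1e-9))
  expect_true(all(f$truth$wpbs$width_px * sp$pixel_size_um <= 0.3 + 1e-9))
})

test_that("rendering is bit-identical for a fixed seed", {
  sp <- scene_spec(field_width_px = 128, field_height_px = 128, n_slices = 3,
                   pixel_size_um = 0.25, nucleus_count = 3, wpb_count = 10,
                   immature_count = 2, seed = 99)
  f1 <- render_field(sp)
  f2 <- render_field(sp)
  expect_identical(f1$image$nuclei_channel, f2$image$nuclei_channel)
  expect_identical(f1$image$vwf_channel, f2$image$vwf_channel)
  expect_identical(f1$truth$wpbs, f2$truth$wpbs)
})

test_that("over-dense scenes are rejected with a placement error", {
  sp <- scene_spec(field_width_px = 64, field_height_px = 64,
                   pixel_size_um = 0.11, nucleus_count = 40, seed = 5)
  expect_error(render_field(sp), "cannot place")
  sp2 <- scene_spec(field_width_px = 96, field_height_px = 96,
                    pixel_size_um = 0.11, wpb_count = 200, n_slices = 3,
                    seed = 5)
  expect_error(render_field(sp2), "placement capacity")
})

test_that("blur-free footprints match analytic areas to discretization error", {
  px <- 0.11
  # one capsule rod: 4 x 0.3 um
  sp <- noiseless_scene(field_width_px = 128, field_height_px = 128,
                        n_slices = 1, wpb_count = 1,
                        wpb_length_um = c(4, 4), wpb_width_um = c(0.3, 0.3),
                        seed = 21)
  f <- render_field(sp)
  a_px <- sum(f$image$vwf_channel[, , 1] > 0)
  l <- 4 / px; w <- 0.3 / px
  a_true <- (l - w) * w + pi * (w / 2)^2
  p_true <- 2 * (l - w) + pi * w
  expect_lt(abs(a_px - a_true), p_true)   # within one pixel-perimeter
  # one ellipse nucleus
  sp2 <- noiseless_scene(field_width_px = 256, field_height_px = 256,
                         n_slices = 1, nucleus_count = 1,
                         nucleus_radius_um = c(5, 5), seed = 22)
  f2 <- render_field(sp2)
  a2 <- sum(f2$image$nuclei_channel[, , 1] > 0)
  r <- 5 / px
  expect_lt(abs(a2 - pi * r^2), 2 * pi * r)
})

test_that("a labeling oracle recovers counts exactly from noiseless renders", {
  for (seed in c(2, 13, 77)) {
    # rod widths at least ~2 px so blur-free footprints cannot fragment
    sp <- noiseless_scene(field_width_px = 384, field_height_px = 384,
                          n_slices = 5, nucleus_count = 5, wpb_count = 25,
                          wpb_width_um = c(0.25, 0.3),
                          immature_count = 6, seed = seed)
    f <- render_field(sp)
    expect_equal(oracle_count(f$image$nuclei_channel), 5)
    expect_equal(oracle_count(f$image$vwf_channel), 25 + 6)
  }
})

test_that("placed VWF objects respect the minimum separation", {
  sp <- noiseless_scene(field_width_px = 256, field_height_px = 256,
                        n_slices = 1, wpb_count = 40, seed = 8)
  f <- render_field(sp)
  w <- f$truth$wpbs
  u <- cbind(sin(w$orientation_rad), cos(w$orientation_rad))
  half <- pmax(w$length_px / 2 - w$width_px / 2, 0)
  A <- cbind(w$y_px, w$x_px) - half * u
  B <- cbind(w$y_px, w$x_px) + half * u
  margin_px <- sp$min_separation_um / sp$pixel_size_um
  for (i in seq_len(nrow(w) - 1)) {
    j <- (i + 1):nrow(w)
    d <- wpbquant:::min_dist_segment_to_segments(A[i, ], B[i, ],
                                      A[j, , drop = FALSE],
                                      B[j, , drop = FALSE])
    expect_true(all(d >= (w$width_px[i] + w$width_px[j]) / 2 + margin_px - 1e-9))
  }
})

test_that("simulate_growth_counts reproduces exact doublings and is seeded", {
  s <- simulate_growth_counts(100, 24, c(0, 24, 48))
  expect_equal(s$counts, c(100, 200, 400))
  # independently computed: 30000 * 2^(92/33)
  s2 <- simulate_growth_counts(30000, 33, c(4, 96))
  expect_equal(s2$counts[2], 207184.086, tolerance = 1e-6)
  p1 <- simulate_growth_counts(500, 30, c(0, 24, 48), noise = "poisson",
                               seed = 42)
  p2 <- simulate_growth_counts(500, 30, c(0, 24, 48), noise = "poisson",
                               seed = 42)
  expect_identical(p1$counts, p2$counts)
  expect_error(simulate_growth_counts(100, 24, numeric(0)), "non-empty")
  expect_error(simulate_growth_counts(100, 24, c(0, 10), noise = "poisson"),
               "seed")
})

test_that("growth simulator satisfies the exact ratio law without noise", {
  for (dt in c(10, 26, 33, 100)) {
    s <- simulate_growth_counts(1234, dt, c(4, 24, 48, 72, 96))
    r <- s$counts[-1] / s$counts[-5]
    expect_equal(r, 2^(diff(s$times_hr) / dt), tolerance = 1e-12)
  }
})

test_that("simulate_experiment has the right replication structure", {
  tiny <- list(field_width_px = 96L, field_height_px = 96L,
               pixel_size_um = 0.25, n_slices = 2L, noise_sd = 0,
               nucleus_radius_um = c(3, 4))
  des <- experiment_design("constant_density", "HUVEC",
                           slides_per_condition = 5, n_experiments = 1,
                           carrying_capacity_cells = 2,
                           wpb_per_cell_curve = wpb_curve("constant",
                                                          value = 1),
                           immature_fraction = 0, scene = tiny, seed = 31)
  sim <- simulate_experiment(des, field_fun = function(img, truth) NULL)
  expect_equal(nrow(sim$fields), 4 * 5 * 9)   # 4 time points x 5 slides x 9
  expect_equal(as.integer(table(sim$fields$condition_id)), rep(45L, 4))
  # determinism of the generated inventory
  sim2 <- simulate_experiment(des, field_fun = function(img, truth) NULL)
  expect_identical(sim$fields, sim2$fields)
})

test_that("a constant WPB-per-cell curve yields that pooled truth ratio", {
  tiny <- list(field_width_px = 256L, field_height_px = 256L,
               pixel_size_um = 0.25, n_slices = 3L, noise_sd = 0)
  des <- suppressWarnings(experiment_design(
    "constant_time", "HUVEC", seeding_densities = 30000,
    slides_per_condition = 2, n_experiments = 1,
    carrying_capacity_cells = 8,
    wpb_per_cell_curve = wpb_curve("constant", value = 10),
    immature_fraction = 0, scene = tiny, seed = 17))
  sim <- simulate_experiment(des, field_fun = function(img, truth) NULL)
  ratio <- sum(sim$fields$n_wpb_true) / sum(sim$fields$n_nuclei_true)
  expect_equal(ratio, 10, tolerance = 0.1)    # Poisson sampling noise
})

test_that("experiment designs enforce their method constraints", {
  expect_error(experiment_design("constant_density",
                                 seeding_densities = c(1e4, 3e4), seed = 1),
               "single seeding density")
  expect_error(experiment_design("constant_time",
                                 time_points_hr = c(48, 96), seed = 1),
               "single time point")
  expect_warning(experiment_design("constant_density",
                                   slides_per_condition = 2, seed = 1),
                 "5 slides")
  d <- experiment_design("constant_time", "ECFC", seed = 1)
  expect_equal(d$seeding_densities, c(5000, 10000, 30000))
  expect_equal(d$time_points_hr, 96)
  expect_equal(d$growth_doubling_time_hr, 26)
})
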