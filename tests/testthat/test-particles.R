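# Particle labeling, shape measurement and filtering.

test_that("disjoint components are counted per connectivity", {
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:4] <- TRUE
  m[8:10, 8:10] <- TRUE
  expect_equal(n_particles(label_particles(m)), 2)
  # diagonal touch: one object under 8-connectivity, two under 4
  d <- matrix(FALSE, 6, 6)
  d[2, 2] <- TRUE
  d[3, 3] <- TRUE
  expect_equal(n_particles(label_particles(d, connectivity = 8)), 1)
  expect_equal(n_particles(label_particles(d, connectivity = 4)), 2)
  expect_equal(n_particles(label_particles(matrix(FALSE, 5, 5))), 0)
})

test_that("shape descriptors match closed forms within estimator tolerance", {
  px <- 0.11
  # large digitized disc: circularity near 1
  dp <- label_particles(disc_mask(20), px)$particles
  expect_gt(dp$circularity, 0.85)
  expect_lte(dp$circularity, 1)
  expect_equal(dp$area_um2, sum(disc_mask(20)) * px^2)
  # square of side s: continuous circularity pi/4; chain estimate within 10%
  sq <- label_particles(rect_mask(50, 50), px)$particles
  expect_equal(sq$circularity, pi / 4, tolerance = 0.1)
  # 5 x 0.3 um rectangular rod (45 x 3 px at 0.11 um/px): circularity
  # approx 4*pi*1.5/10.6^2 = 0.168 from direct evaluation
  rod <- label_particles(rect_mask(3, 45), px)$particles
  expect_equal(rod$circularity, 0.168, tolerance = 0.25)
  expect_lt(rod$circularity, 0.3)
  # centroid is the pixel-mean in 0-based coordinates
  m <- matrix(FALSE, 7, 9); m[3:4, 5:7] <- TRUE
  p <- label_particles(m)$particles
  expect_equal(p$centroid_y, 2.5)
  expect_equal(p$centroid_x, 5)
})

test_that("rendered discs are rounder than rods of comparable area", {
  px <- 0.11
  for (r in c(3, 5, 8)) {
    disc <- label_particles(disc_mask(r), px)$particles
    # rod with the same pixel area at a 3 px width, elongated enough that
    # the digitization does not round it up to a blob
    len <- max(round(disc$area_um2 / px^2 / 3), 10)
    rod <- label_particles(rect_mask(3, len), px)$particles
    expect_gt(disc$circularity, rod$circularity)
  }
})

test_that("filter_particles is a subset, idempotent, and selects by shape", {
  m <- matrix(FALSE, 40, 80)
  m[5:25, 5:25][disc_mask(10, 21)] <- TRUE      # disc, high circularity
  m[18:20, 30:74] <- TRUE                       # 3 x 45 px rod
  ps <- label_particles(m, 0.11)
  expect_equal(n_particles(ps), 2)
  # full-range filter is the identity
  expect_equal(filter_particles(ps)$particles, ps$particles)
  # circularity cut keeps only the rod
  rods <- filter_particles(ps, circ_max = 0.8)
  expect_equal(n_particles(rods), 1)
  expect_lt(rods$particles$circularity, 0.8)
  # idempotence and subset property
  again <- filter_particles(rods, circ_max = 0.8)
  expect_identical(again$particles, rods$particles)
  expect_true(all(rods$particles$label %in% ps$particles$label))
  # empty input -> empty output
  e <- label_particles(matrix(FALSE, 4, 4))
  expect_equal(n_particles(filter_particles(e, circ_max = 0.5)), 0)
  expect_error(filter_particles(ps, circ_min = 0.9, circ_max = 0.2), "min <= max")
})

test_that("count_field recovers a clean synthetic scene and is deterministic", {
  sp <- scene_spec(field_width_px = 384, field_height_px = 384, n_slices = 7,
                   nucleus_count = 7, wpb_count = 30, immature_count = 10,
                   noise_sd = 0.05, seed = 41)
  f <- render_field(sp)
  r1 <- count_field(f$image)
  expect_equal(r1$counts$nuclei_count, 7)
  expect_equal(r1$counts$wpb_count, 30)   # immature discs filtered out
  r2 <- count_field(f$image)
  expect_identical(r1$counts, r2$counts)
  # empty scene counts (0, 0)
  e <- render_field(scene_spec(field_width_px = 64, field_height_px = 64,
                               n_slices = 2, seed = 1))
  ec <- count_field(e$image)
  expect_equal(ec$counts$nuclei_count, 0)
  expect_equal(ec$counts$wpb_count, 0)
})

test_that("count_field reports the failing stage on malformed input", {
  f <- field_image(array(0, c(8, 8, 1)), array(0, c(8, 8, 1)),
                   pixel_size_um = 0.11, z_step_um = 0.3)
  f$nuclei_channel <- array("a", c(8, 8, 1))   # corrupt after construction
  expect_error(count_field(f), "\\[")
})

test_that("per-slice counting sums slice counts", {
  # two bright blobs on different slices, none overlapping in z
  nuc <- array(0, c(40, 40, 2))
  vwf <- array(0, c(40, 40, 2))
  vwf[5:7, 5:20, 1] <- 1
  vwf[25:27, 10:30, 2] <- 1
  nuc[10:25, 10:25, 1] <- 1
  f <- field_image(nuc, vwf, pixel_size_um = 0.5, z_step_um = 0.3)
  pp <- pipeline_params(projection = "per_slice")
  res <- count_field(f, pp)
  expect_equal(res$counts$wpb_count, 2)
  expect_equal(res$counts$nuclei_count, 1)
  expect_true("slice" %in% names(res$wpb$particles))
})
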