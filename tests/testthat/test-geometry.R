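# Scaffold generation, porosity measurement, chamber construction.

test_that("porosity measurement counts void fractions exactly", {
  lab <- array(FL, c(4, 4, 4))
  expect_equal(measure_porosity(voxel_domain(lab, 1e-4)), 1)
  lab_s <- array(SC, c(4, 4, 4))
  expect_equal(measure_porosity(lab_s), 0)
  # 3-D checkerboard is half void by construction
  idx <- expand.grid(i = 1:4, j = 1:4, k = 1:4)
  chk <- array(ifelse((idx$i + idx$j + idx$k) %% 2 == 0, FL, SC),
               c(4, 4, 4))
  expect_equal(measure_porosity(chk), 0.5)
  expect_error(measure_porosity(array(integer(0), c(0, 0, 0))), "empty")
})

test_that("a single subtracted sphere recovers its analytic volume", {
  # one r = 1 mm sphere centred in a 10 mm cube: porosity = (4/3) pi r^3 / V
  h <- 5e-5
  n <- round(10e-3 / h)
  cc <- (seq_len(n) - 0.5) * h - 5e-3
  d2 <- outer(outer(cc^2, cc^2, "+"), cc^2, "+")
  lab <- array(SC, c(n, n, n))
  lab[d2 <= (1e-3)^2] <- FL
  expect_equal(measure_porosity(lab), 4 / 3 * pi * 1e-3^3 / 1e-6,
               tolerance = 2e-3)
})

test_that("sphere-subtraction scaffold hits the target porosity", {
  spec <- scaffold_spec(target_porosity = 0.525, seed = 1L,
                        spacing = 0.175e-3)
  blk <- generate_sphere_subtracted_scaffold(spec)
  expect_lt(abs(blk$meta$porosity - 0.525), 0.005)
  expect_equal(blk$shape, round(c(10e-3, 10e-3, 3e-3) / 0.175e-3))
  # zero target gives the untouched solid block
  solid <- generate_sphere_subtracted_scaffold(
    scaffold_spec(target_porosity = 0, spacing = 0.175e-3))
  expect_equal(measure_porosity(solid), 0)
})

test_that("sphere scaffolds are reproducible for a fixed seed", {
  spec <- scaffold_spec(seed = 42L, spacing = 0.175e-3)
  b1 <- generate_sphere_subtracted_scaffold(spec)
  b2 <- generate_sphere_subtracted_scaffold(spec)
  expect_identical(b1$labels, b2$labels)
  b3 <- generate_sphere_subtracted_scaffold(
    scaffold_spec(seed = 43L, spacing = 0.175e-3))
  expect_false(identical(b1$labels, b3$labels))
})

test_that("porosity tuning converges across targets and seeds", {
  for (target in c(0.3, 0.5, 0.7)) {
    for (seed in 1:5) {
      blk <- generate_sphere_subtracted_scaffold(
        scaffold_spec(target_porosity = target, seed = seed,
                      spacing = 0.175e-3))
      expect_lt(abs(blk$meta$porosity - target), 0.005)
    }
  }
})

test_that("strut lattice realizes the closed-form width/pitch porosity", {
  # solid fraction of an orthogonal two-direction grid: 2a - a^2, a = w/s,
  # so a = 1 - sqrt(porosity)
  expect_equal(1 - sqrt(0.5), 0.2929, tolerance = 1e-4)
  blk <- generate_strut_scaffold(
    scaffold_spec(variant = "strut_lattice", target_porosity = 0.5))
  expect_lt(abs(blk$meta$porosity - 0.5), 0.005)
  expect_lt(abs(measure_porosity(blk) - 0.5), 0.005)
})

test_that("strut lattice degenerate widths behave", {
  spec <- scaffold_spec(variant = "strut_lattice", target_porosity = 0.5)
  empty <- generate_strut_scaffold(spec, strut_width = 0)
  expect_equal(measure_porosity(empty), 1)
  expect_error(generate_strut_scaffold(spec, strut_width = 1e-3),
               "pitch")
})

test_that("quarter chamber voxelization matches the nominal fill volume", {
  ch <- chamber_spec()  # 8 cm, 110 mL, quarter
  dom <- build_chamber_domain(ch, NULL, resolution = 2e-3)
  expect_lt(abs(dom$meta$occupied_volume - 27.5e-6) / 27.5e-6, 0.03)
  # every voxel carries exactly one known label
  expect_true(all(dom$labels %in% VOXEL_LABELS))
  expect_gte(sum(dom$labels == VOXEL_LABELS[["inlet"]]), 1)
  expect_gte(sum(dom$labels == VOXEL_LABELS[["outlet"]]), 1)
})

test_that("full-cylinder fluid volume matches pi r^2 h", {
  ch <- chamber_spec(quarter = FALSE, n_scaffolds = 0L)
  dom <- build_chamber_domain(ch, NULL, resolution = 2e-3)
  expect_lt(abs(dom$meta$occupied_volume - 110e-6) / 110e-6, 0.03)
})

test_that("quarter-domain fluid volume is a quarter of the full domain's", {
  chq <- chamber_spec()
  chf <- chamber_spec(quarter = FALSE)
  dq <- build_chamber_domain(chq, NULL, resolution = 2e-3)
  df <- build_chamber_domain(chf, NULL, resolution = 2e-3)
  expect_lt(abs(4 * dq$meta$fluid_volume - df$meta$fluid_volume) /
              df$meta$fluid_volume, 0.01)
})

test_that("scaffolds protruding beyond the chamber are rejected", {
  ch <- chamber_spec(n_scaffolds = 12L)
  blk <- generate_strut_scaffold(
    scaffold_spec(variant = "strut_lattice", target_porosity = 0.5))
  bad <- list(list(center = c(0.039, 0.01, 0.009), angle = pi / 4,
                   dims = c(10e-3, 10e-3, 3e-3)))
  expect_error(build_chamber_domain(ch, list(blk), placement = bad),
               "protrudes")
})

test_that("scaffold embedding labels cells inside the placement boxes", {
  ch <- chamber_spec(n_scaffolds = 12L)
  blk <- generate_strut_scaffold(
    scaffold_spec(variant = "strut_lattice", target_porosity = 0.5))
  dom <- build_chamber_domain(ch, list(blk), resolution = 2e-3)
  expect_equal(length(dom$meta$scaffold_boxes), 3L)  # 12 / 4 in a quadrant
  expect_gt(sum(dom$labels == SC), 0)
  expect_gt(dom$meta$scaffold_area_resolved, 0)
})
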