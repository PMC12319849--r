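test_that("simulation is deterministic for identical spec and seed", {
  spec <- phantom_spec(c(6, 5, 16), regions = list(
    region("box", mu_s = 6, birefringence = 3e-4, axis_deg = 40)))
  v1 <- simulate_volume(spec, noise_sd = 0.02, seed = 11)
  v2 <- simulate_volume(spec, noise_sd = 0.02, seed = 11)
  expect_identical(v1$ascan$ch1, v2$ascan$ch1)
  expect_identical(v1$ascan$ch2, v2$ascan$ch2)
  v3 <- simulate_volume(spec, noise_sd = 0.02, seed = 12)
  expect_false(identical(v1$ascan$ch1, v3$ascan$ch1))
})

test_that("zero birefringence gives no cross-polarized signal and zero retardance", {
  a <- simulate_ascan(rep(4, 30), rep(0, 30), rep(0, 30))
  expect_true(all(Mod(a$ch1) < 1e-15))
  expect_true(all(compute_retardance(a) == 0))
})

test_that("a volume column equals the per-line simulator (noiseless)", {
  spec <- phantom_spec(c(4, 3, 20), regions = list(
    region("box", mu_s = 6, birefringence = 3e-4, axis_deg = 77)))
  v <- simulate_volume(spec)
  one <- simulate_ascan(v$truth$mu_s[2, 3, ], v$truth$birefringence[2, 3, ],
                        v$truth$theta[2, 3, ], spec = spec)
  expect_equal(v$ascan$ch1[2, 3, ], one$ch1, tolerance = 1e-12)
  expect_equal(v$ascan$ch2[2, 3, ], one$ch2, tolerance = 1e-12)
})

test_that("input validation rejects bad profiles and regions", {
  expect_error(simulate_ascan(rep(1, 5), rep(0, 4), rep(0, 5)), "length")
  expect_error(simulate_ascan(rep(-1, 5), rep(0, 5), rep(0, 5)), "non-negative")
  expect_error(region("box", mu_s = -1), "mu_s")
  expect_error(region("box", axis_deg = 180), "axis_deg")
  expect_error(phantom_spec(c(0, 4, 4)), "grid_shape")
})

test_that("empty region list yields background-only ground truth and recovery", {
  spec <- phantom_spec(c(3, 3, 400), background_mu_s = 2, axial_pixel_um = 5)
  v <- simulate_volume(spec)
  expect_true(all(v$truth$mu_s == 2))
  rec <- reconstruct_volume(v$ascan)
  expect_lt(max(abs(rec$mu_s[1, 1, 1:200] / 2 - 1)), 0.05)
})

test_that("abutting boxes give a piecewise-constant axis map with a straight boundary", {
  spec <- phantom_spec(c(10, 10, 4), regions = list(
    region("box", x = c(1, 5), mu_s = 5, birefringence = 2e-4, axis_deg = 0),
    region("box", x = c(6, 10), mu_s = 5, birefringence = 2e-4, axis_deg = 90)))
  tr <- phantom_truth(spec)
  expect_true(all(tr$theta[, 1:5, ] == 0))
  expect_true(all(tr$theta[, 6:10, ] == 90))
})

test_that("reflectivity decays monotonically in a homogeneous medium", {
  a <- simulate_ascan(rep(8, 50), rep(0, 50), rep(0, 50))
  r <- compute_reflectivity(a)
  expect_true(all(diff(r[-1]) <= 1e-15))
})

test_that("through-plane inclination reduces apparent birefringence", {
  flat <- uniform_ascan_recon(30)$retardance
  steep <- simulate_ascan(rep(4, 40), rep(5e-4, 40), rep(30, 40),
                          through_plane_deg = 60)
  expect_true(all(compute_retardance(steep) <= flat + 1e-9))
  expect_equal(compute_retardance(steep)[40],
               closed_form_retardance(40 * 4.2, 5e-4 * cos(pi / 3)^2),
               tolerance = 1e-9)
})

test_that("tile offsets follow the rounded step rule with edge clamping", {
  expect_identical(tile_offsets(100, 100, 0), 0L)
  expect_identical(tile_offsets(700, 350, 0.2), c(0L, 280L, 350L))
  expect_equal(diff(tile_offsets(700, 350, 0.2))[1], 280)
  expect_error(tile_offsets(50, 100, 0.2), "larger")
  expect_error(tile_offsets(100, 50, 1), "overlap_frac")
  # coverage property across assorted geometries
  for (case in list(c(97, 30), c(128, 50), c(350, 350), c(200, 64))) {
    offs <- tile_offsets(case[1], case[2], 0.2)
    covered <- rep(FALSE, case[1])
    for (o in offs) covered[(o + 1):(o + case[2])] <- TRUE
    expect_true(all(covered))
  }
})

test_that("tiled acquisition covers the grid and matches the full simulation", {
  spec <- phantom_spec(c(50, 50, 8), regions = list(
    region("box", mu_s = 5, birefringence = 2e-4, axis_deg = 10)))
  acq <- simulate_tiled_acquisition(spec, tile_px = 30, overlap_frac = 0.2)
  full <- simulate_volume(spec)
  t1 <- acq$tiles[[1]]
  expect_equal(as.numeric(t1$offset), c(0, 0))
  expect_equal(t1$ascan$ch1, full$ascan$ch1[1:30, 1:30, ], tolerance = 1e-15)
  covered <- matrix(FALSE, 50, 50)
  for (t in acq$tiles) {
    covered[t$offset[2] + 1:30, t$offset[1] + 1:30] <- TRUE
  }
  expect_true(all(covered))
})

test_that("dMRI stand-in: background is isotropic, bundles anisotropic, crossings mixed", {
  bg <- phantom_spec(c(60, 60, 6), lateral_pixel_um = 30)
  dm0 <- simulate_dmri_maps(phantom_truth(bg), bg, grid_spacing_mm = 0.8)
  expect_true(all(dm0$fa < 1e-9))
  expect_false(any(dm0$valid))

  single <- phantom_spec(c(60, 60, 6), lateral_pixel_um = 30, regions = list(
    region("box", mu_s = 8, birefringence = 4e-4, axis_deg = 0)))
  dm1 <- simulate_dmri_maps(phantom_truth(single), single, grid_spacing_mm = 0.8)
  v <- dm1$principal_dir[1, 1, ]
  expect_lt(abs(v[3]), 1e-9)
  expect_lt(min(abs(c(atan2(v[2], v[1]), atan2(-v[2], -v[1])))), 1e-9)

  # mixed-orientation voxel: FA strictly below the single-bundle value,
  # checked against a hand-built mixture-tensor eigendecomposition
  crossing <- phantom_spec(c(60, 60, 6), lateral_pixel_um = 30, regions = list(
    region("box", z = c(1, 3), mu_s = 8, birefringence = 4e-4, axis_deg = 0),
    region("box", z = c(4, 6), mu_s = 8, birefringence = 4e-4, axis_deg = 90)))
  dm2 <- simulate_dmri_maps(phantom_truth(crossing), crossing,
                            grid_spacing_mm = 0.8)
  expect_lt(dm2$fa[1, 1], dm1$fa[1, 1])
  ad <- 1.2e-3; rd <- 0.3e-3
  Tmix <- (diag(c(ad, rd, rd)) + diag(c(rd, ad, rd))) / 2
  lam <- eigen(Tmix, symmetric = TRUE)$values
  fa_oracle <- sqrt(3 / 2) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  expect_equal(dm2$fa[1, 1], fa_oracle, tolerance = 1e-9)

  expect_error(simulate_dmri_maps(phantom_truth(bg), bg,
                                  grid_spacing_mm = 1e-6), "spacing")
})
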