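test_that("Dice coefficient covers identities, disjoint masks and half overlap", {
  a <- matrix(FALSE, 10, 20); a[, 1:10] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- !a
  expect_equal(dice(a, b), 0)
  c50 <- matrix(FALSE, 10, 20); c50[, 6:15] <- TRUE   # |A|=|B|=100, 50 shared
  expect_equal(dice(a, c50), 0.5)
  expect_equal(dice(a, c50), dice(c50, a))
  empty <- matrix(FALSE, 10, 20)
  expect_equal(dice(empty, empty), 1)
  expect_error(dice(a, matrix(TRUE, 5, 5)), "shape")
})

test_that("polar decomposition isolates the rotation", {
  ang <- 0.3
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  expect_equal(polar_rotation(R), R, tolerance = 1e-12)
  expect_equal(polar_rotation(diag(c(2, 0.5))), diag(2), tolerance = 1e-12)
  A <- R %*% diag(c(1.3, 0.8))
  expect_equal(polar_rotation(A), R, tolerance = 1e-12)
})

test_that("affine application and inversion round-trip points", {
  tf <- affine_transform(matrix(c(1.1, 0.2, -0.1, 0.9), 2, 2), c(3, -2))
  p <- cbind(runif(10, 0, 50), runif(10, 0, 50))
  back <- apply_affine(invert_affine(tf), apply_affine(tf, p))
  expect_equal(back, p, tolerance = 1e-10)
  expect_error(affine_transform(matrix(0, 2, 2)), "invertible")
})

test_that("resampling: identity, integer shifts, and smooth round trips", {
  m <- smooth_blob_map(64)
  ident <- affine_transform()
  expect_equal(resample_map(m, ident), m, tolerance = 1e-12)
  sh <- affine_transform(diag(2), c(3, 2))
  r <- resample_map(m, sh, interpolation = "nearest")
  expect_equal(r[2 + 1:10, 3 + 1:10], m[1:10, 1:10])
  expect_true(all(is.nan(r[1:2, ])))
  tf <- affine_transform(matrix(c(cos(0.1), sin(0.1), -sin(0.1), cos(0.1)),
                                2, 2), c(1.5, -0.5))
  fwd <- resample_map(m, tf)
  back <- resample_map(fwd, invert_affine(tf))
  ok <- is.finite(back) & is.finite(m)
  expect_gt(mean(ok), 0.7)
  expect_lt(max(abs(back[ok] - m[ok])), 0.05 * diff(range(m)))
})

test_that("self-registration returns the identity transform", {
  m <- smooth_blob_map(64)
  tf <- register_affine(m, -m, levels = 2)
  rot <- atan2(tf$rotational_component[2, 1], tf$rotational_component[1, 1])
  expect_lt(abs(rot) * 180 / pi, 1e-3)
  ctr <- apply_affine(tf, c(32, 32))
  expect_lt(sqrt(sum((ctr - c(32, 32))^2)), 1e-3)
})

test_that("registration recovers a known rotation + translation", {
  fixed <- smooth_blob_map(128)
  ang <- 7 * pi / 180
  L <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  tf_true <- affine_transform(L, c(3, -2) + c(64, 64) - as.numeric(L %*% c(64, 64)))
  moving <- -resample_map(fixed, invert_affine(tf_true))
  moving[!is.finite(moving)] <- 0
  tf <- register_affine(fixed, moving, levels = 3)
  rot <- atan2(tf$rotational_component[2, 1], tf$rotational_component[1, 1])
  expect_lt(abs(rot * 180 / pi - 7), 0.5)
  for (p in list(c(64, 64), c(30, 40), c(90, 100))) {
    err <- sqrt(sum((apply_affine(tf, p) - apply_affine(tf_true, p))^2))
    expect_lt(err, 0.5)
  }
  # WM-mask agreement after alignment
  wm_fixed <- make_masks(fixed, "otsu")
  wm_moving <- resample_map(wm_fixed * 1, invert_affine(tf_true),
                            interpolation = "nearest")
  wm_moving[!is.finite(wm_moving)] <- 0
  aligned <- resample_map(wm_moving, tf, interpolation = "nearest")
  expect_gte(dice(aligned == 1, wm_fixed), 0.95)
})

test_that("registration rejects blank or constant inputs", {
  m <- smooth_blob_map(32)
  expect_error(register_affine(m, matrix(0, 32, 32)), "non-constant")
  expect_error(register_affine(matrix(1, 32, 32), m), "non-constant")
})

test_that("vector reorientation projects in-plane axial angles", {
  ident <- affine_transform()
  v <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0) / sqrt(2), c(-1, 0, 0))
  out <- reorient_and_project(v, ident)
  expect_equal(out$angle_deg[1], 0)
  expect_equal(out$angle_deg[2], 90)
  expect_false(out$valid[3])
  expect_true(is.nan(out$angle_deg[3]))
  expect_equal(out$angle_deg[4], 45)
  expect_equal(out$angle_deg[5], 0)    # axial: -x is the same axis as +x
  # applying the rotational component turns in-plane vectors accordingly
  ang <- 0.4
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  tf <- affine_transform(R %*% diag(c(1.2, 0.7)), c(5, 5))
  out2 <- reorient_and_project(rbind(c(1, 0, 0)), tf)
  expect_equal(out2$angle_deg[1], ang * 180 / pi, tolerance = 1e-9)
})

test_that("reorientation is equivariant under a common rotation of vectors and plane", {
  set.seed(8)
  ang <- 0.6
  R3 <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  v <- matrix(rnorm(30), 10, 3)
  v <- v / sqrt(rowSums(v^2))
  base <- reorient_and_project(v, diag(3))
  rot <- reorient_and_project(v %*% t(R3), diag(3),
                              plane = rbind(R3[, 1], R3[, 2]))
  ok <- base$valid & rot$valid
  expect_true(any(ok))
  expect_lt(max(oracle_axial_dist(base$angle_deg[ok], rot$angle_deg[ok])), 1e-6)
})

test_that("Otsu masking splits a bimodal map at the valley", {
  set.seed(12)
  m <- matrix(c(rnorm(500, 10, 1), rnorm(500, 30, 1)), 25, 40)
  thr_oracle <- oracle_otsu(as.numeric(m))
  mask <- make_masks(m, "otsu", keep_largest = FALSE, fill_holes = FALSE)
  # agreement with the exhaustive oracle within one 256-level bin
  binw <- diff(range(m)) / 256
  implied <- max(m[!mask & is.finite(m)])
  expect_lt(abs(implied - thr_oracle), max(2 * binw, 0.5))
  expect_true(all(mask == (m > implied)))
  expect_error(make_masks(matrix(5, 10, 10), "otsu"), "degenerate")
  # idempotence: re-masking the masked map reproduces the mask
  m2 <- m; m2[!mask] <- min(m)
  mask2 <- make_masks(m2, "threshold", value = implied,
                      keep_largest = FALSE, fill_holes = FALSE)
  expect_equal(mask2, mask)
})
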