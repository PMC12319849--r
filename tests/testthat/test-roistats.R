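test_that("axial circular mean follows the angle-doubling oracle", {
  expect_equal(circ_mean_axial(c(10, 10)), 10)
  # 170 and 10 are axially symmetric about 0: doubled vectors at 340 and 20
  # average to argument 0
  expect_equal(circ_mean_axial(c(170, 10)), 0)
  d <- circ_mean_axial(c(0, 90))
  expect_true(is.nan(d))
  expect_true(isTRUE(attr(d, "degenerate")))
  expect_error(circ_mean_axial(numeric(0)), "finite")
  expect_error(circ_mean_axial(NaN), "finite")
  expect_equal(circ_mean_axial(c(10, 50), weights = c(1, 0)), 10)
})

test_that("axial circular mean is equivariant and relabel-invariant", {
  set.seed(13)
  for (i in 1:50) {
    a <- runif(sample(2:20, 1), 0, 60) # coherent cluster, non-degenerate
    m <- circ_mean_axial(a)
    shift <- runif(1, 0, 180)
    expect_equal(circ_mean_axial((a + shift) %% 180), (m + shift) %% 180,
                 tolerance = 1e-9)
    flip <- a
    k <- sample(length(a), ceiling(length(a) / 2))
    flip[k] <- (flip[k] + 180) %% 180
    expect_equal(circ_mean_axial(flip), m, tolerance = 1e-9)
  }
})

test_that("polar-space angular difference folds onto [0, 90]", {
  expect_equal(angular_difference(178, 1), 3)
  expect_equal(angular_difference(1, 178), 3)
  expect_equal(angular_difference(77, 77), 0)
  expect_equal(angular_difference(0, 90), 90)
  expect_true(is.nan(angular_difference(NaN, 10)))
  # exhaustive sweep on the 1-degree grid: symmetry, bounds, 180-invariance
  g <- expand.grid(a = 0:179, b = 0:179)
  d <- angular_difference(g$a, g$b)
  expect_true(all(d >= 0 & d <= 90))
  expect_equal(d, angular_difference(g$b, g$a))
  expect_equal(d, angular_difference(g$a + 180, g$b))
  expect_equal(d, angular_difference(g$a, g$b + 180))
  expect_equal(d, oracle_axial_dist(g$a, g$b))
})

test_that("angular difference satisfies the half-circle triangle inequality", {
  set.seed(14)
  a <- runif(2000, 0, 180); b <- runif(2000, 0, 180); c <- runif(2000, 0, 180)
  lhs <- angular_difference(a, c)
  rhs <- angular_difference(a, b) + angular_difference(b, c)
  expect_true(all(lhs <= rhs + 1e-9))
})

test_that("pearson matches the covariance formula and validates input", {
  x <- c(1, 2, 3); y <- c(1, 2, 2)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), r_hand)
  expect_equal(pearson(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson(1:10, -(1:10)), -1)
  expect_equal(pearson(c(x, NaN), c(y, 5)), r_hand)  # pairwise deletion
  expect_error(pearson(1:2, 1:2), "3")
  expect_error(pearson(c(1, 1, 1), 1:3), "constant")
  expect_error(pearson(1:3, 1:4), "length")
})

test_that("ROI placement filters the lattice by white-matter fraction", {
  full <- matrix(TRUE, 60, 60)
  r <- place_rois(full, roi_size_um = 200, pixel_um = 10)  # 20 px boxes
  expect_equal(nrow(r), 9)
  expect_error(place_rois(matrix(FALSE, 60, 60), 200, 10), "fraction")
  half <- matrix(FALSE, 60, 60); half[1:30, ] <- TRUE
  r2 <- place_rois(half, 200, 10, min_wm_frac = 0.8)
  expect_true(all(r2$y0 < 20))
  # requested count: exactly n distinct ROIs
  big <- matrix(TRUE, 300, 300)
  r3 <- place_rois(big, 200, 10, n_rois = 120)
  expect_equal(nrow(r3), 120)
  expect_equal(nrow(unique(r3[, c("x0", "y0")])), 120)
})

test_that("ROI tables aggregate maps and drop empty ROIs", {
  m <- matrix(2, 40, 40)
  ps <- parameter_map_stack(m, m * 10, matrix(30, 40, 40), 10)
  dmri <- list(adc = m * 1e-4, fa = m * 0.2, theta = matrix(150, 40, 40))
  rois <- place_rois(matrix(TRUE, 40, 40), 200, 10)
  tab <- extract_roi_table(ps, dmri, rois)
  expect_equal(unique(tab$mean_mu_s), 2)
  expect_equal(unique(tab$mean_retardance), 20)
  expect_equal(unique(tab$circ_mean_theta_psoct), 30)
  expect_equal(unique(tab$circ_mean_theta_dmri), 150)
  expect_equal(unique(tab$fa), 0.4)
  # an all-NaN ROI is dropped with a warning
  mu2 <- m; mu2[1:20, 1:20] <- NaN
  ps2 <- parameter_map_stack(mu2, m, matrix(30, 40, 40), 10)
  expect_warning(tab2 <- extract_roi_table(ps2, dmri, rois), "dropped")
  expect_equal(nrow(tab2), nrow(rois) - 1)
  expect_error(extract_roi_table(ps, list(adc = matrix(0, 3, 3),
                                          fa = matrix(0, 3, 3),
                                          theta = matrix(0, 3, 3)), rois),
               "grid")
})

test_that("two-bundle phantom ROIs recover each bundle's axis within bin width", {
  spec <- demo_phantom_spec(nx = 90, ny = 90, nz = 24, lateral_pixel_um = 30,
                            axes_deg = c(40, 140))
  sim <- simulate_volume(spec, noise_sd = 0, seed = 3)
  maps <- enface_stack(reconstruct_volume(sim$ascan))
  wm <- apply(sim$truth$birefringence > 0, c(1, 2), any)
  rois <- place_rois(wm, roi_size_um = 450, pixel_um = 30, min_wm_frac = 0.9)
  dmri <- list(adc = maps$mu_s_map * 0, fa = maps$mu_s_map * 0,
               theta = maps$orientation_map)
  tab <- extract_roi_table(maps, dmri, rois)
  truth_axis <- ifelse(tab$center_y < 45, 40, 140)
  expect_true(all(oracle_axial_dist(tab$circ_mean_theta_psoct, truth_axis)
                  <= 2.5))
})

test_that("white-matter summaries report mean and configurable deviation", {
  m <- matrix(5, 10, 10)
  expect_equal(wm_summary(m, matrix(TRUE, 10, 10)), c(mean = 5, sd = 0))
  two <- matrix(c(1, 3), 1, 2)
  expect_equal(wm_summary(two, matrix(TRUE, 1, 2)), c(mean = 2, sd = 1))
  expect_equal(wm_summary(two, matrix(TRUE, 1, 2), sd_type = "sample"),
               c(mean = 2, sd = sqrt(2)))
  withnan <- matrix(c(1, 3, NaN, 100), 2, 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(wm_summary(withnan, mask)[["mean"]], 2)
  expect_error(wm_summary(m, matrix(FALSE, 10, 10)), "empty")
})

test_that("polar histograms conserve counts", {
  expect_equal(unname(polar_histogram(rep(0, 12), bin_deg = 10)),
               c(12, rep(0, 8)))
  even <- rep(seq(5, 85, by = 10), each = 3)
  expect_true(all(polar_histogram(even, 10) == 3))
  set.seed(15)
  d <- runif(137, 0, 90)
  expect_equal(sum(polar_histogram(d, 15)), 137)
  f <- tempfile(fileext = ".png")
  polar_histogram(d, 15, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_error(polar_histogram(d, 7), "bin_deg")
  expect_error(polar_histogram(c(10, 95), 10), "90")
})
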