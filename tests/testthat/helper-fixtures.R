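# Fixtures built in code: phantoms, smooth maps and independent oracles.

# closed-form double-pass retardance (degrees) for a uniform retarder,
# folded the way the arctan estimator folds it: into [0, 90]
closed_form_retardance <- function(z_um, dn, wavelength_um = 1.3) {
  x <- (2 * (2 * pi / wavelength_um) * dn * z_um) * 180 / pi
  x <- x %% 360
  x <- ifelse(x > 180, 360 - x, x)
  ifelse(x > 90, 180 - x, x)
}

# independent axial-distance oracle (degrees)
oracle_axial_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# brute-force wrap of an angle into [0, 360) by repeated shifting
oracle_wrap360 <- function(x) {
  while (x < 0) x <- x + 360
  while (x >= 360) x <- x - 360
  x
}

# counting oracle for the histogram-peak orientation estimator
oracle_hist_peak <- function(samples, bin_deg = 5) {
  samples <- samples[is.finite(samples)]
  if (!length(samples)) return(NaN)
  nb <- 180 / bin_deg
  counts <- integer(nb)
  for (s in samples) {
    k <- floor((s %% 180) / bin_deg) + 1
    counts[k] <- counts[k] + 1
  }
  best <- which(counts == max(counts))[1]   # tie -> lowest bin
  (best - 1) * bin_deg + bin_deg / 2
}

# exhaustive 256-bin Otsu threshold oracle (between-class variance)
oracle_otsu <- function(v, nbins = 256) {
  rng <- range(v)
  b <- pmin(floor((v - rng[1]) / diff(rng) * nbins), nbins - 1)
  h <- tabulate(b + 1, nbins = nbins)
  p <- h / sum(h)
  best <- -Inf; best_t <- 0
  mu_tot <- sum((seq_len(nbins) - 1) * p)
  w0 <- 0; mu0 <- 0
  for (t in seq_len(nbins - 1)) {
    w0 <- w0 + p[t]; mu0 <- mu0 + (t - 1) * p[t]
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    m0 <- mu0 / w0; m1 <- (mu_tot - mu0) / w1
    v_b <- w0 * w1 * (m0 - m1)^2
    if (v_b > best) { best <- v_b; best_t <- t }
  }
  rng[1] + best_t / nbins * diff(rng)
}

# smooth multi-blob map used as a registration fixture
smooth_blob_map <- function(n = 128) {
  g <- function(cx, cy, s, a) {
    x <- outer(rep(1, n), seq_len(n)); y <- outer(seq_len(n), rep(1, n))
    a * exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
  }
  g(40, 40, 15, 2) + g(90, 70, 20, 3) + g(60, 100, 10, 1.5) +
    g(100, 30, 12, 2.5)
}

# concentric tangential orientation field about the image center
circle_field <- function(n = 160, r_in = 30, r_out = 70) {
  cx <- (n - 1) / 2; cy <- (n - 1) / 2
  x <- outer(rep(1, n), 0:(n - 1)); y <- outer(0:(n - 1), rep(1, n))
  rx <- x - cx; ry <- y - cy
  theta <- (atan2(rx, -ry) * 180 / pi) %% 180
  r <- sqrt(rx^2 + ry^2)
  orientation_field(theta, r > r_in & r < r_out)
}

# small uniform-axis phantom A-line + its reconstruction
uniform_ascan_recon <- function(theta_deg, dn = 5e-4, mu_s = 4, nz = 40,
                                axial_pixel_um = 4.2, noise_sd = 0) {
  a <- simulate_ascan(rep(mu_s, nz), rep(dn, nz), rep(theta_deg, nz),
                      axial_pixel_um = axial_pixel_um, noise_sd = noise_sd,
                      seed = 42)
  list(ascan = a,
       retardance = compute_retardance(a),
       theta = compute_axis(a),
       z_um = seq_len(nz) * axial_pixel_um)
}
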