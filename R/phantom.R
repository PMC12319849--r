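#' Define a birefringent fiber phantom
#'
#' A phantom is a voxel grid holding, per voxel, a scattering coefficient
#' (mm^-1), a birefringence (refractive-index difference, dimensionless), an
#' in-plane fiber axis (degrees, axial) and a through-plane inclination.
#' Regions are painted onto a uniform background in list order (later regions
#' overwrite earlier ones). The phantom is the ground truth against which all
#' reconstruction, tractography and registration stages are tested.
#'
#' @param grid_shape integer triple `c(nx, ny, nz)` in pixels.
#' @param lateral_pixel_um lateral pixel size (default 10, the instrument's
#'   lateral resolution).
#' @param axial_pixel_um axial pixel size in tissue (default 4.2).
#' @param wavelength_um center wavelength of the source (default 1.3).
#' @param regions list of [region()] objects.
#' @param background_mu_s scattering coefficient of uncovered voxels, mm^-1.
#'   Background is non-birefringent.
#' @return object of class `phantom_spec`.
#' @seealso [region()], [simulate_volume()], [simulate_dmri_maps()]
#' @export
phantom_spec <- function(grid_shape,
                         lateral_pixel_um = 10,
                         axial_pixel_um = 4.2,
                         wavelength_um = 1.3,
                         regions = list(),
                         background_mu_s = 0.5) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be three integers >= 1", call. = FALSE)
  stopifnot_scalar_num(lateral_pixel_um, "lateral_pixel_um", min = 1e-12)
  stopifnot_scalar_num(axial_pixel_um, "axial_pixel_um", min = 1e-12)
  stopifnot_scalar_num(wavelength_um, "wavelength_um", min = 1e-12)
  stopifnot_scalar_num(background_mu_s, "background_mu_s", min = 0)
  for (r in regions)
    if (!inherits(r, "phantom_region")) stop("regions must be region() objects", call. = FALSE)
  structure(list(grid_shape = grid_shape,
                 lateral_pixel_um = lateral_pixel_um,
                 axial_pixel_um = axial_pixel_um,
                 wavelength_um = wavelength_um,
                 regions = regions,
                 background_mu_s = background_mu_s),
            class = "phantom_spec")
}

#' Define a phantom region
#'
#' Geometry is either an axis-aligned box (`x`, `y`, `z` 1-based inclusive
#' voxel ranges; `NULL` means full extent) or an oriented cylinder (`point` +
#' `direction` + `radius`, voxel coordinates).
#'
#' @param geometry `"box"` or `"cylinder"`.
#' @param x,y,z integer ranges `c(lo, hi)` for boxes.
#' @param point,direction,radius cylinder axis point, direction 3-vector and
#'   radius in voxels.
#' @param mu_s scattering coefficient, mm^-1 (>= 0).
#' @param birefringence refractive-index difference Delta-n (>= 0).
#' @param axis_deg in-plane fiber axis, degrees in `[0, 180)`.
#' @param through_plane_deg inclination from the imaging plane in
#'   `[-90, 90]`; apparent birefringence scales as `cos^2` of it.
#' @return object of class `phantom_region`.
#' @export
region <- function(geometry = c("box", "cylinder"),
                   x = NULL, y = NULL, z = NULL,
                   point = NULL, direction = NULL, radius = NULL,
                   mu_s = 1, birefringence = 0, axis_deg = 0,
                   through_plane_deg = 0) {
  geometry <- match.arg(geometry)
  if (mu_s < 0) stop("mu_s must be >= 0", call. = FALSE)
  if (birefringence < 0) stop("birefringence must be >= 0", call. = FALSE)
  if (axis_deg < 0 || axis_deg >= 180)
    stop("axis_deg must lie in [0, 180)", call. = FALSE)
  if (abs(through_plane_deg) > 90)
    stop("through_plane_deg must lie in [-90, 90]", call. = FALSE)
  if (geometry == "cylinder") {
    if (is.null(point) || is.null(direction) || is.null(radius))
      stop("cylinder needs point, direction and radius", call. = FALSE)
    direction <- direction / sqrt(sum(direction^2))
  }
  structure(list(geometry = geometry, x = x, y = y, z = z,
                 point = point, direction = direction, radius = radius,
                 mu_s = mu_s, birefringence = birefringence,
                 axis_deg = axis_deg, through_plane_deg = through_plane_deg),
            class = "phantom_region")
}

#' Rasterize a phantom into ground-truth voxel maps
#'
#' @param spec a [phantom_spec()].
#' @return list of arrays `[ny, nx, nz]`: `mu_s`, `birefringence`, `theta`
#'   (degrees, NaN where non-birefringent) and `inclination` (degrees).
#' @export
phantom_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  mu_s <- array(spec$background_mu_s, c(ny, nx, nz))
  dn <- array(0, c(ny, nx, nz))
  theta <- array(NaN, c(ny, nx, nz))
  incl <- array(0, c(ny, nx, nz))
  if (length(spec$regions) == 0L)
    return(list(mu_s = mu_s, birefringence = dn, theta = theta, inclination = incl))
  ix <- array(rep(seq_len(nx), each = ny), c(ny, nx, nz))
  iy <- array(rep(seq_len(ny), times = nx), c(ny, nx, nz))
  iz <- array(rep(seq_len(nz), each = ny * nx), c(ny, nx, nz))
  for (r in spec$regions) {
    if (r$geometry == "box") {
      xr <- r$x %||% c(1L, nx); yr <- r$y %||% c(1L, ny); zr <- r$z %||% c(1L, nz)
      inside <- ix >= xr[1] & ix <= xr[2] & iy >= yr[1] & iy <= yr[2] &
        iz >= zr[1] & iz <= zr[2]
    } else {
      dx <- ix - r$point[1]; dy <- iy - r$point[2]; dz <- iz - r$point[3]
      proj <- dx * r$direction[1] + dy * r$direction[2] + dz * r$direction[3]
      d2 <- dx^2 + dy^2 + dz^2 - proj^2
      inside <- d2 <= r$radius^2
    }
    mu_s[inside] <- r$mu_s
    dn[inside] <- r$birefringence
    theta[inside] <- if (r$birefringence > 0) r$axis_deg else NaN
    incl[inside] <- r$through_plane_deg
  }
  list(mu_s = mu_s, birefringence = dn, theta = theta, inclination = incl)
}

# Detection model shared by the per-line and volume simulators.
# Cumulative single-pass Jones product J(z) = L_z ... L_1 with per-pixel
# layer L = R(theta) diag(e^{i d}, e^{-i d}) R(-theta); round trip M = J^T J;
# incident right-circular light; detected channels
#   ch2 = <RCP| M |RCP>  (co-polarized)
#   ch1 = -i <LCP| M |RCP>  (cross-polarized, quarter-wave bias)
# so that a uniform retarder gives ch1 = sin(delta_dp) e^{i 2 theta} and
# ch2 = cos(delta_dp), with delta_dp = 2 (2 pi / lambda) Delta-n z the
# cumulative double-pass retardation.
.jones_channels <- function(mu_s, dn_eff, theta_rad, wavelength_um,
                            axial_pixel_um, beta) {
  nz <- length(mu_s)
  delta_mm <- axial_pixel_um / 1000
  amp <- sqrt(beta * mu_s) * exp(-cumsum(mu_s) * delta_mm)
  dk <- (2 * pi / wavelength_um) * dn_eff * axial_pixel_um
  ep <- exp(1i * dk); em <- Conj(ep)
  c2 <- cos(theta_rad)^2; s2 <- sin(theta_rad)^2
  cs <- cos(theta_rad) * sin(theta_rad)
  # per-pixel layer entries (R diag R^T)
  L11 <- ep * c2 + em * s2
  L22 <- ep * s2 + em * c2
  L12 <- (ep - em) * cs
  J11 <- 1 + 0i; J12 <- 0i; J21 <- 0i; J22 <- 1 + 0i
  ch1 <- complex(nz); ch2 <- complex(nz)
  for (k in seq_len(nz)) {
    n11 <- L11[k] * J11 + L12[k] * J21
    n12 <- L11[k] * J12 + L12[k] * J22
    n21 <- L12[k] * J11 + L22[k] * J21
    n22 <- L12[k] * J12 + L22[k] * J22
    J11 <- n11; J12 <- n12; J21 <- n21; J22 <- n22
    # M = t(J) %*% J (symmetric)
    M11 <- J11 * J11 + J21 * J21
    M12 <- J11 * J12 + J21 * J22
    M22 <- J12 * J12 + J22 * J22
    # E_out = M %*% rcp, rcp = (1, i)/sqrt(2)
    e1 <- (M11 + 1i * M12) / sqrt(2)
    e2 <- (M12 + 1i * M22) / sqrt(2)
    ch1[k] <- -1i * (e1 + 1i * e2) / sqrt(2)   # -i <LCP|E>
    ch2[k] <- (e1 - 1i * e2) / sqrt(2)         #    <RCP|E>
  }
  list(ch1 = ch1 * amp, ch2 = ch2 * amp)
}

# noise draw order contract: per A-line, channel 1 first, then channel 2;
# within a channel the real parts for all depths, then the imaginary parts.
.draw_line_noise <- function(nz, noise_sd) {
  n1 <- complex(real = stats::rnorm(nz, 0, noise_sd),
                imaginary = stats::rnorm(nz, 0, noise_sd))
  n2 <- complex(real = stats::rnorm(nz, 0, noise_sd),
                imaginary = stats::rnorm(nz, 0, noise_sd))
  list(n1, n2)
}

#' Simulate one dual-channel complex A-line
#'
#' Forward model: single backscatter with amplitude
#' `A(z) = sqrt(beta * mu_s(z)) * exp(-sum_{j<=z} mu_s(j) * Delta)`, a
#' cumulative Jones product over per-pixel linear retarders, round trip by
#' transpose product, circular input polarization, and additive circular
#' complex Gaussian channel noise. For a uniform-axis medium the detected
#' channels satisfy `arctan(A1/A2) = delta_dp` (wrapped cumulative
#' double-pass retardation, `2 * (2 pi / lambda) * Delta-n * z`) and
#' `(phi1 - phi2)/2 = theta`.
#'
#' @param mu_s,birefringence,axis_deg per-depth-pixel profiles (equal length);
#'   `axis_deg` entries may be NaN where birefringence is zero.
#' @param through_plane_deg per-pixel inclination (scalar recycled); scales
#'   apparent birefringence by `cos^2`.
#' @param spec optional [phantom_spec()] supplying wavelength and pixel sizes.
#' @param wavelength_um,axial_pixel_um used when `spec` is NULL.
#' @param beta backscatter fraction (fixed constant of the forward model).
#' @param noise_sd amplitude standard deviation of the complex channel noise.
#' @param seed integer; set for reproducible noise (ignored when NULL).
#' @return list with complex vectors `ch1`, `ch2` and `axial_pixel_um`.
#' @export
simulate_ascan <- function(mu_s, birefringence, axis_deg,
                           through_plane_deg = 0, spec = NULL,
                           wavelength_um = 1.3, axial_pixel_um = 4.2,
                           beta = 0.01, noise_sd = 0, seed = NULL) {
  if (!is.null(spec)) {
    wavelength_um <- spec$wavelength_um
    axial_pixel_um <- spec$axial_pixel_um
  }
  nz <- length(mu_s)
  through_plane_deg <- rep_len(through_plane_deg, nz)
  if (length(birefringence) != nz || length(axis_deg) != nz)
    stop("mu_s, birefringence and axis_deg must share length", call. = FALSE)
  if (any(mu_s < 0) || any(birefringence < 0))
    stop("mu_s and birefringence must be non-negative", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  th <- ifelse(is.finite(axis_deg), axis_deg, 0)
  dn_eff <- birefringence * cos(deg2rad(through_plane_deg))^2
  ch <- .jones_channels(mu_s, dn_eff, deg2rad(th), wavelength_um,
                        axial_pixel_um, beta)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    nz_noise <- .draw_line_noise(nz, noise_sd)
    ch$ch1 <- ch$ch1 + nz_noise[[1]]
    ch$ch2 <- ch$ch2 + nz_noise[[2]]
  }
  list(ch1 = ch$ch1, ch2 = ch$ch2, axial_pixel_um = axial_pixel_um)
}

#' Simulate a full dual-channel PSOCT volume with ground truth
#'
#' Applies the A-line forward model to every lateral pixel of the phantom.
#' The physics is evaluated vectorized across columns; noise is drawn from a
#' single stream, A-line by A-line in column-major map order (rows fastest),
#' channel 1 before channel 2 within each line.
#'
#' @inheritParams simulate_ascan
#' @param spec a [phantom_spec()].
#' @return list with `ascan` (class `oct_ascan`: complex arrays `ch1`, `ch2`
#'   of dim `[ny, nx, nz]`, plus pixel metadata), `truth` (see
#'   [phantom_truth()]) and `spec`.
#' @export
simulate_volume <- function(spec, noise_sd = 0, seed = 1, beta = 0.01) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- phantom_truth(spec)
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  delta_mm <- spec$axial_pixel_um / 1000
  mu <- truth$mu_s
  dn_eff <- truth$birefringence * cos(deg2rad(truth$inclination))^2
  th <- deg2rad(ifelse(is.finite(truth$theta), truth$theta, 0))
  # amplitude with cumulative attenuation along z
  cum <- mu
  for (k in seq_len(nz)) if (k > 1) cum[, , k] <- cum[, , k - 1] + mu[, , k]
  amp <- sqrt(beta * mu) * exp(-cum * delta_mm)
  dk <- (2 * pi / spec$wavelength_um) * dn_eff * spec$axial_pixel_um
  ep <- exp(1i * dk)
  c2 <- cos(th)^2; s2 <- sin(th)^2; cs <- cos(th) * sin(th)
  L11 <- ep * c2 + Conj(ep) * s2
  L22 <- ep * s2 + Conj(ep) * c2
  L12 <- (ep - Conj(ep)) * cs
  dim0 <- c(ny, nx)
  J11 <- array(1 + 0i, dim0); J12 <- array(0i, dim0)
  J21 <- array(0i, dim0); J22 <- array(1 + 0i, dim0)
  ch1 <- array(0i, c(ny, nx, nz)); ch2 <- array(0i, c(ny, nx, nz))
  for (k in seq_len(nz)) {
    n11 <- L11[, , k] * J11 + L12[, , k] * J21
    n12 <- L11[, , k] * J12 + L12[, , k] * J22
    n21 <- L12[, , k] * J11 + L22[, , k] * J21
    n22 <- L12[, , k] * J12 + L22[, , k] * J22
    J11 <- n11; J12 <- n12; J21 <- n21; J22 <- n22
    M11 <- J11 * J11 + J21 * J21
    M12 <- J11 * J12 + J21 * J22
    M22 <- J12 * J12 + J22 * J22
    e1 <- (M11 + 1i * M12) / sqrt(2)
    e2 <- (M12 + 1i * M22) / sqrt(2)
    ch1[, , k] <- (-1i * (e1 + 1i * e2) / sqrt(2)) * amp[, , k]
    ch2[, , k] <- ((e1 - 1i * e2) / sqrt(2)) * amp[, , k]
  }
  if (noise_sd > 0) {
    set.seed(seed)
    for (j in seq_len(nx)) for (i in seq_len(ny)) {
      nn <- .draw_line_noise(nz, noise_sd)
      ch1[i, j, ] <- ch1[i, j, ] + nn[[1]]
      ch2[i, j, ] <- ch2[i, j, ] + nn[[2]]
    }
  }
  ascan <- structure(list(ch1 = ch1, ch2 = ch2,
                          axial_pixel_um = spec$axial_pixel_um,
                          lateral_pixel_um = spec$lateral_pixel_um,
                          metadata = list(noise_sd = noise_sd, seed = seed,
                                          beta = beta)),
                     class = "oct_ascan")
  list(ascan = ascan, truth = truth, spec = spec)
}

#' Nominal tile offsets for an overlapped tile scan
#'
#' Step between adjacent tiles is `round(tile_px * (1 - overlap_frac))`; the
#' last tile is clamped to the grid edge so the union of tiles always covers
#' the full extent.
#'
#' @param extent_px lateral extent in pixels.
#' @param tile_px tile size in pixels.
#' @param overlap_frac fractional overlap in `[0, 1)` (0.2 for the
#'   instrument's tile scans).
#' @return integer vector of 0-based offsets.
#' @export
tile_offsets <- function(extent_px, tile_px, overlap_frac = 0.2) {
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must lie in [0, 1)", call. = FALSE)
  if (tile_px > extent_px)
    stop("tile larger than grid extent", call. = FALSE)
  step <- max(1L, as.integer(round(tile_px * (1 - overlap_frac))))
  offs <- seq.int(0L, max(0L, extent_px - tile_px), by = step)
  if (offs[length(offs)] + tile_px < extent_px)
    offs <- c(offs, extent_px - tile_px)
  as.integer(offs)
}

#' Simulate a tiled acquisition
#'
#' Simulates the whole phantom once, then cuts overlapping tiles at the
#' nominal offsets of [tile_offsets()], mirroring blockface tile scanning
#' with 20% overlap.
#'
#' @inheritParams simulate_volume
#' @param tile_px lateral tile size in pixels (applied to both axes).
#' @param overlap_frac fractional overlap between adjacent tiles.
#' @return list with `tiles` (each `list(ascan, offset)`, offset 0-based
#'   `c(x, y)`), `truth`, `spec`, `overlap_frac`.
#' @export
simulate_tiled_acquisition <- function(spec, tile_px, overlap_frac = 0.2,
                                       noise_sd = 0, seed = 1, beta = 0.01) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]
  full <- simulate_volume(spec, noise_sd = noise_sd, seed = seed, beta = beta)
  offx <- tile_offsets(nx, tile_px, overlap_frac)
  offy <- tile_offsets(ny, tile_px, overlap_frac)
  tiles <- list()
  for (oy in offy) for (ox in offx) {
    rows <- (oy + 1):(oy + tile_px)
    cols <- (ox + 1):(ox + tile_px)
    tile <- structure(list(ch1 = full$ascan$ch1[rows, cols, , drop = FALSE],
                           ch2 = full$ascan$ch2[rows, cols, , drop = FALSE],
                           axial_pixel_um = spec$axial_pixel_um,
                           lateral_pixel_um = spec$lateral_pixel_um,
                           metadata = full$ascan$metadata),
                      class = "oct_ascan")
    tiles[[length(tiles) + 1L]] <- list(ascan = tile, offset = c(ox, oy))
  }
  list(tiles = tiles, truth = full$truth, spec = spec,
       overlap_frac = overlap_frac)
}

#' Generate matched coarse-grid dMRI-style maps from a phantom
#'
#' Stands in for an ex vivo diffusion scan of the same specimen: each coarse
#' voxel's tensor is the mixture of prolate single-fiber tensors (aligned to
#' the local 3D fiber axis) and isotropic background tensors over the fine
#' voxels it covers. ADC is the mean diffusivity, FA the standard tensor
#' fractional anisotropy, and the principal direction the leading
#' eigenvector. Mixed-orientation voxels therefore show reduced FA, exactly
#' as crossing fibers do in tensor-model diffusion imaging.
#'
#' @param truth ground-truth maps from [phantom_truth()]/[simulate_volume()].
#' @param spec the originating [phantom_spec()].
#' @param grid_spacing_mm coarse (scanner-like) grid spacing, default 0.8.
#' @param axial_diffusivity,radial_diffusivity prolate tensor eigenvalues for
#'   a fiber population, mm^2/s; radial falls as myelination restricts
#'   cross-fiber diffusion.
#' @param background_diffusivity isotropic background diffusivity, mm^2/s.
#' @param fa_valid_min principal directions of voxels with FA below this are
#'   flagged invalid.
#' @return object of class `dmri_maps`: `adc`, `fa` (matrices on the coarse
#'   grid), `principal_dir` (`[ny, nx, 3]`), `valid`, `grid_spacing_mm`.
#' @export
simulate_dmri_maps <- function(truth, spec, grid_spacing_mm = 0.8,
                               axial_diffusivity = 1.2e-3,
                               radial_diffusivity = 0.3e-3,
                               background_diffusivity = 0.8e-3,
                               fa_valid_min = 0.1) {
  fine_mm <- spec$lateral_pixel_um / 1000
  if (grid_spacing_mm < fine_mm)
    stop("coarse spacing smaller than fine pixel size", call. = FALSE)
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]
  ratio <- grid_spacing_mm / fine_mm
  nxc <- max(1L, as.integer(floor(nx / ratio)))
  nyc <- max(1L, as.integer(floor(ny / ratio)))
  adc <- matrix(NaN, nyc, nxc); fa <- matrix(NaN, nyc, nxc)
  pdir <- array(NaN, c(nyc, nxc, 3)); valid <- matrix(FALSE, nyc, nxc)
  fib <- truth$birefringence > 0
  thr <- deg2rad(ifelse(is.finite(truth$theta), truth$theta, 0))
  inc <- deg2rad(truth$inclination)
  ux <- cos(thr) * cos(inc); uy <- sin(thr) * cos(inc); uz <- sin(inc)
  ad <- axial_diffusivity; rd <- radial_diffusivity
  for (jc in seq_len(nxc)) for (ic in seq_len(nyc)) {
    cols <- (floor((jc - 1) * ratio) + 1):min(nx, ceiling(jc * ratio))
    rows <- (floor((ic - 1) * ratio) + 1):min(ny, ceiling(ic * ratio))
    f <- fib[rows, cols, , drop = FALSE]
    n_tot <- length(f); n_fib <- sum(f)
    Tm <- diag(3) * background_diffusivity * (n_tot - n_fib)
    if (n_fib > 0) {
      vx <- ux[rows, cols, , drop = FALSE][f]
      vy <- uy[rows, cols, , drop = FALSE][f]
      vz <- uz[rows, cols, , drop = FALSE][f]
      S <- matrix(c(sum(vx * vx), sum(vx * vy), sum(vx * vz),
                    sum(vx * vy), sum(vy * vy), sum(vy * vz),
                    sum(vx * vz), sum(vy * vz), sum(vz * vz)), 3, 3)
      Tm <- Tm + rd * n_fib * diag(3) + (ad - rd) * S
    }
    Tm <- Tm / n_tot
    ev <- eigen(Tm, symmetric = TRUE)
    lam <- ev$values
    adc[ic, jc] <- mean(lam)
    fa[ic, jc] <- sqrt(3 / 2) * sqrt(sum((lam - mean(lam))^2)) /
      sqrt(sum(lam^2))
    pdir[ic, jc, ] <- ev$vectors[, 1]
    valid[ic, jc] <- fa[ic, jc] >= fa_valid_min
  }
  pdir[is.na(pdir)] <- NaN
  structure(list(adc = adc, fa = fa, principal_dir = pdir, valid = valid,
                 grid_spacing_mm = grid_spacing_mm),
            class = "dmri_maps")
}
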