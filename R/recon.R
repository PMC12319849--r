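#' Reconstruct complex depth profiles from spectral fringes
#'
#' Removes the DC component (per-spectrum mean subtraction) and returns the
#' positive-frequency half of the inverse discrete Fourier transform, which
#' converts interference-related spectral oscillations into complex depth
#' profiles `A(z) exp(i phi(z))` for each polarization channel.
#'
#' @param ch1,ch2 real spectra: vectors, or matrices with one spectrum per
#'   column.
#' @param axial_pixel_um axial pixel size to attach to the output.
#' @return list with complex `ch1`, `ch2` of depth length
#'   `floor(n_spectral / 2)` (same column layout as the input) and
#'   `axial_pixel_um`.
#' @seealso [synthesize_fringes()] for the forward direction used in tests.
#' @export
fourier_reconstruct <- function(ch1, ch2, axial_pixel_um = 4.2) {
  v1 <- is.null(dim(ch1)); v2 <- is.null(dim(ch2))
  m1 <- if (v1) matrix(ch1, ncol = 1) else ch1
  m2 <- if (v2) matrix(ch2, ncol = 1) else ch2
  if (nrow(m1) != nrow(m2) || ncol(m1) != ncol(m2))
    stop("channel spectra must share dimensions", call. = FALSE)
  n <- nrow(m1)
  if (n < 2) stop("spectra must have length >= 2", call. = FALSE)
  half <- floor(n / 2)
  ifft_half <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    d <- stats::mvfft(m, inverse = TRUE) / n
    d[seq_len(half), , drop = FALSE]
  }
  d1 <- ifft_half(m1); d2 <- ifft_half(m2)
  if (v1) { d1 <- d1[, 1]; d2 <- d2[, 1] }
  list(ch1 = d1, ch2 = d2, axial_pixel_um = axial_pixel_um)
}

#' Synthesize real spectral fringes from a complex depth profile
#'
#' Inverse of [fourier_reconstruct()]: places the profile at positive
#' frequencies (with its Hermitian mirror) so that DC removal plus the
#' inverse DFT recovers the profile exactly. Used to validate the
#' reconstruction against a forward/inverse DFT round trip.
#'
#' @param profile complex depth profile (vector or matrix, one per column),
#'   occupying depth pixels `1 .. m`; requires `m < n_spectral / 2`.
#' @param n_spectral length of the output spectrum.
#' @return real spectrum (vector or matrix).
#' @export
synthesize_fringes <- function(profile, n_spectral) {
  vec <- is.null(dim(profile))
  p <- if (vec) matrix(profile, ncol = 1) else profile
  m <- nrow(p)
  if (m >= floor(n_spectral / 2))
    stop("profile too long for the requested spectrum", call. = FALSE)
  full <- matrix(0i, n_spectral, ncol(p))
  full[seq_len(m), ] <- p                      # bins 0..m-1 (depth pixel z at bin z-1)
  idx <- n_spectral - seq_len(m - 1) + 1       # Hermitian mirror of bins 1..m-1
  full[idx, ] <- Conj(p[2:m, , drop = FALSE])
  s <- Re(stats::mvfft(full))
  if (vec) s[, 1] else s
}

.ascan_arrays <- function(ascan) {
  if (!is.list(ascan) || is.null(ascan$ch1) || is.null(ascan$ch2))
    stop("ascan must contain ch1 and ch2", call. = FALSE)
  if (!identical(dim(ascan$ch1) %||% length(ascan$ch1),
                 dim(ascan$ch2) %||% length(ascan$ch2)))
    stop("channels must share shape", call. = FALSE)
  ascan
}

#' Reflectivity from dual-channel amplitudes
#'
#' `R(z) = A1(z)^2 + A2(z)^2`, the polarization-independent backscattered
#' intensity (proportionality constant fixed at 1).
#'
#' @param ascan dual-channel complex profile/volume (`ch1`, `ch2`).
#' @return numeric array of the same shape.
#' @export
compute_reflectivity <- function(ascan) {
  ascan <- .ascan_arrays(ascan)
  Mod(ascan$ch1)^2 + Mod(ascan$ch2)^2
}

#' Retardance from dual-channel amplitudes
#'
#' `delta(z) = arctan(A1(z) / A2(z))` in degrees, bounded to `[0, 90]`;
#' `A2 = 0, A1 > 0` gives 90 and a fully dark pixel gives NaN.
#'
#' @inheritParams compute_reflectivity
#' @return retardance in degrees, same shape as the input channels.
#' @export
compute_retardance <- function(ascan) {
  ascan <- .ascan_arrays(ascan)
  a1 <- Mod(ascan$ch1); a2 <- Mod(ascan$ch2)
  out <- rad2deg(atan2(a1, a2))
  out[a1 == 0 & a2 == 0] <- NaN
  out
}

#' Optic-axis orientation from the channel phase difference
#'
#' `theta(z) = (phi1(z) - phi2(z)) / 2`: the phase difference is wrapped into
#' `[0, 360)` degrees and halved, landing in the axial range `[0, 180)`.
#' Pixels whose cross-polarized amplitude is at or below `snr_floor` carry no
#' orientation information and return NaN.
#'
#' @inheritParams compute_reflectivity
#' @param snr_floor amplitude floor on `|ch1|` below which the axis is
#'   undefined (default 0: only exactly dark pixels are masked).
#' @return axis orientation in degrees `[0, 180)`, NaN where undefined.
#' @export
compute_axis <- function(ascan, snr_floor = 0) {
  ascan <- .ascan_arrays(ascan)
  dphi <- rad2deg(Arg(ascan$ch1) - Arg(ascan$ch2))
  out <- wrap_deg(dphi, 360) / 2
  out[Mod(ascan$ch1) <= snr_floor] <- NaN
  out
}

#' Depth-resolved scattering coefficient (tail-sum estimator)
#'
#' Implements `mu_s(z) = I(z) / (2 * Delta * sum_{j = z+1..d} I(j))` on the
#' linear reflectivity signal, the depth-resolved attenuation estimator of
#' Vermeer and colleagues. In the near-infrared, attenuation in tissue is
#' scattering-dominated, so the estimate is reported as a scattering
#' coefficient. The finite tail sum is used exactly as printed: the last
#' pixel (empty tail) and any zero tail give NaN. The estimator is unbiased
#' only while the remaining signal is fully captured, so a growing positive
#' bias toward the tail is expected; `tail_drop` optionally removes the last
#' pixels from the output for that reason.
#'
#' @param intensity non-negative reflectivity signal: vector, or array with
#'   depth as the last dimension.
#' @param delta_mm axial pixel size in mm.
#' @param tail_drop number of trailing depth pixels to set NaN (default 0).
#' @return `mu_s` in mm^-1, same shape as `intensity`.
#' @export
compute_scattering_profile <- function(intensity, delta_mm, tail_drop = 0) {
  if (any(intensity < 0, na.rm = TRUE))
    stop("intensity must be non-negative", call. = FALSE)
  stopifnot_scalar_num(delta_mm, "delta_mm", min = 1e-12)
  dm <- dim(intensity)
  if (is.null(dm)) {
    d <- length(intensity)
    if (d < 2) stop("need at least 2 depth pixels", call. = FALSE)
    tail <- rev(cumsum(rev(intensity)))          # sum_{j >= z}
    tail <- c(tail[-1], 0)                       # sum_{j > z}
    mu <- intensity / (2 * delta_mm * tail)
    mu[tail <= 0] <- NaN
    mu[d] <- NaN
    if (tail_drop > 0) mu[(d - tail_drop + 1):d] <- NaN
    mu
  } else {
    nz <- dm[length(dm)]
    flat <- matrix(intensity, ncol = nz)
    tail <- t(apply(flat, 1, function(r) rev(cumsum(rev(r)))))
    tail <- cbind(tail[, -1, drop = FALSE], 0)
    mu <- flat / (2 * delta_mm * tail)
    mu[tail <= 0] <- NaN
    mu[, nz] <- NaN
    if (tail_drop > 0) mu[, (nz - tail_drop + 1):nz] <- NaN
    array(mu, dm)
  }
}

#' Reconstruct all optical-property volumes from a dual-channel volume
#'
#' Applies reflectivity, retardance, axis-orientation and scattering-
#' coefficient estimation per voxel/A-line and records the axial pixel size
#' and depth.
#'
#' @param ascan an `oct_ascan` (see [simulate_volume()]) or any list with
#'   complex `ch1`, `ch2` and `axial_pixel_um`.
#' @param snr_floor passed to [compute_axis()].
#' @param tail_drop passed to [compute_scattering_profile()].
#' @return object of class `oct_recon`: arrays `reflectivity`, `retardance`,
#'   `theta`, `mu_s`, plus `axial_pixel_um`, `lateral_pixel_um`, `depth_px`.
#' @export
reconstruct_volume <- function(ascan, snr_floor = 0, tail_drop = 0) {
  ascan <- .ascan_arrays(ascan)
  delta_um <- ascan$axial_pixel_um %||% 4.2
  refl <- compute_reflectivity(ascan)
  dm <- dim(refl) %||% length(refl)
  nz <- dm[length(dm)]
  structure(list(
    reflectivity = refl,
    retardance = compute_retardance(ascan),
    theta = compute_axis(ascan, snr_floor = snr_floor),
    mu_s = compute_scattering_profile(refl, delta_um / 1000,
                                      tail_drop = tail_drop),
    axial_pixel_um = delta_um,
    lateral_pixel_um = ascan$lateral_pixel_um %||% NA_real_,
    depth_px = nz), class = "oct_recon")
}
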