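#' Affine transform between image grids
#'
#' Maps moving-grid coordinates to fixed-grid coordinates:
#' `x_fixed = matrix %*% x_moving + translation`, with 0-based pixel-center
#' coordinates ordered `(x, y)`. The rotational component — the orthogonal
#' factor of the polar decomposition of the linear part — is stored
#' alongside; it is what gets applied to diffusion orientation vectors.
#'
#' @param matrix 2x2 invertible linear part.
#' @param translation length-2 offset `(x, y)` in fixed-grid pixels.
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(2), translation = c(0, 0)) {
  stopifnot(all(dim(matrix) == c(2, 2)), length(translation) == 2)
  if (!all(is.finite(matrix)) || abs(det(matrix)) < 1e-12 ||
      kappa(matrix) > 1e8)
    stop("linear part must be invertible and well-conditioned", call. = FALSE)
  structure(list(matrix = matrix, translation = as.numeric(translation),
                 rotational_component = polar_rotation(matrix)),
            class = "affine_transform")
}

#' Rotation factor of the polar decomposition
#'
#' Decomposes `A = R P` with `R` orthogonal (det +1) and `P` symmetric
#' positive definite; for a pure rotation it returns the rotation itself,
#' and for pure anisotropic scaling the identity.
#'
#' @param A square matrix.
#' @return orthogonal matrix with determinant +1.
#' @export
polar_rotation <- function(A) {
  s <- svd(A)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u; u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

#' Apply / invert affine transforms
#'
#' @param tf an [affine_transform()].
#' @param points matrix with columns `x, y` (moving-grid coordinates).
#' @return transformed points / the inverse transform.
#' @export
apply_affine <- function(tf, points) {
  stopifnot(inherits(tf, "affine_transform"))
  p <- matrix(points, ncol = 2)
  t(tf$matrix %*% t(p)) + rep(tf$translation, each = nrow(p))
}

#' @rdname apply_affine
#' @export
invert_affine <- function(tf) {
  Ai <- solve(tf$matrix)
  affine_transform(Ai, as.numeric(-Ai %*% tf$translation))
}

#' Resample a map through an affine transform
#'
#' Pull-back resampling onto the fixed grid: each fixed-grid pixel is mapped
#' through the inverse transform into the moving map and sampled there.
#' Out-of-domain pixels become NaN. Binary masks should use `"nearest"`.
#'
#' @param map moving-grid matrix.
#' @param tf [affine_transform()] mapping moving to fixed coordinates.
#' @param target_dim `c(nrow, ncol)` of the fixed grid (default: same as
#'   `map`).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return matrix on the fixed grid.
#' @export
resample_map <- function(map, tf, target_dim = dim(map),
                         interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  Ai <- solve(tf$matrix)
  nr <- target_dim[1]; nc <- target_dim[2]
  gx <- rep(seq_len(nc) - 1, each = nr)
  gy <- rep(seq_len(nr) - 1, times = nc)
  sx <- Ai[1, 1] * (gx - tf$translation[1]) + Ai[1, 2] * (gy - tf$translation[2])
  sy <- Ai[2, 1] * (gx - tf$translation[1]) + Ai[2, 2] * (gy - tf$translation[2])
  .sample_grid(map, sx, sy, nr, nc, interpolation)
}

.sample_grid <- function(map, sx, sy, nr, nc, interpolation) {
  mr <- nrow(map); mc <- ncol(map)
  out <- rep(NaN, nr * nc)
  if (interpolation == "nearest") {
    j <- round(sx) + 1; i <- round(sy) + 1
    ok <- i >= 1 & i <= mr & j >= 1 & j <= mc
    out[ok] <- map[cbind(i[ok], j[ok])]
  } else {
    j0 <- floor(sx); i0 <- floor(sy)
    fx <- sx - j0; fy <- sy - i0
    ok <- i0 >= 0 & i0 <= mr - 2 & j0 >= 0 & j0 <= mc - 2
    # edge pixels: clamp exact-boundary samples
    edge <- (i0 == mr - 1 & fy == 0) | (j0 == mc - 1 & fx == 0)
    ok2 <- (i0 >= 0 & j0 >= 0 & i0 <= mr - 1 & j0 <= mc - 1) & edge
    idx <- which(ok)
    if (length(idx)) {
      i1 <- i0[idx] + 1; j1 <- j0[idx] + 1
      v00 <- map[cbind(i1, j1)];     v01 <- map[cbind(i1, j1 + 1)]
      v10 <- map[cbind(i1 + 1, j1)]; v11 <- map[cbind(i1 + 1, j1 + 1)]
      out[idx] <- (1 - fy[idx]) * ((1 - fx[idx]) * v00 + fx[idx] * v01) +
        fy[idx] * ((1 - fx[idx]) * v10 + fx[idx] * v11)
    }
    idx2 <- which(ok2 & !ok)
    if (length(idx2))
      out[idx2] <- map[cbind(pmin(i0[idx2] + 1, mr), pmin(j0[idx2] + 1, mc))]
  }
  matrix(out, nr, nc)
}

#' Dice overlap coefficient between binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Two empty masks agree trivially and
#' return 1 (documented convention, avoids NaN on degenerate fixtures).
#'
#' @param mask_a,mask_b logical matrices on a common grid.
#' @return value in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks must share shape", call. = FALSE)
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  a[is.na(a)] <- FALSE; b[is.na(b)] <- FALSE   # NaN pixels count as background
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# block-mean downsample by integer factor (NaN-ignoring)
.block_reduce <- function(m, f) {
  nr <- floor(nrow(m) / f) * f; nc <- floor(ncol(m) / f) * f
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  arr <- array(m, c(f, nr / f, f, nc / f))
  s <- apply(arr, c(2, 4), function(v) mean(v[is.finite(v)]))
  s[!is.finite(s)] <- NaN
  s
}

.ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 16) return(-1)
  a <- a[ok]; b <- b[ok]
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(-1)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb) * length(a) / (length(a) - 1)
}

#' Intensity-driven affine registration of dMRI-style to PSOCT maps
#'
#' Registers a moving map (typically ADC) to a fixed map (typically the
#' scattering coefficient, the pair with the best gray/white contrast) by
#' maximizing normalized cross-correlation over affine parameters, coarse to
#' fine over an image pyramid. Because ADC and scattering contrast are
#' anti-correlated in white matter, the moving map is negated before
#' matching (`negate_moving`). Initialization: center-of-mass alignment and
#' the pixel-size ratio as isotropic scale. The returned transform maps
#' moving coordinates to fixed coordinates.
#'
#' @param fixed,moving matrices with more than one distinct finite value.
#' @param levels number of pyramid levels (default 3).
#' @param fixed_px_um,moving_px_um pixel sizes, used for the scale
#'   initialization.
#' @param negate_moving negate moving intensities before matching.
#' @param max_rotation_deg bound on the rotation search (box constraint).
#' @return an [affine_transform()] with attribute `ncc` (final correlation).
#' @export
register_affine <- function(fixed, moving, levels = 3,
                            fixed_px_um = 1, moving_px_um = 1,
                            negate_moving = TRUE, max_rotation_deg = 30) {
  for (m in list(fixed, moving)) {
    mf <- m[is.finite(m)]
    if (!length(mf) || length(unique(mf)) < 2)
      stop("registration needs non-constant input maps", call. = FALSE)
  }
  if (anyNA(fixed) || anyNA(moving)) {
    fixed[!is.finite(fixed)] <- NaN; moving[!is.finite(moving)] <- NaN
  }
  zsc <- function(m) {
    v <- m[is.finite(m)]
    (m - mean(v)) / stats::sd(v)
  }
  fz <- zsc(fixed)
  mz <- zsc(if (negate_moving) -moving else moving)
  scale0 <- moving_px_um / fixed_px_um
  com <- function(m) {
    w <- m - min(m[is.finite(m)]); w[!is.finite(w)] <- 0
    if (sum(w) == 0) w[] <- 1
    c(sum(w * rep(seq_len(ncol(m)) - 1, each = nrow(m))),
      sum(w * rep(seq_len(nrow(m)) - 1, times = ncol(m)))) / sum(w)
  }
  cf <- com(fz); cm <- com(mz)
  # parameters: angle, log sx, log sy, shear, tx, ty  (center-based)
  par <- c(0, log(scale0), log(scale0), 0, cf[1] - cm[1] * scale0,
           cf[2] - cm[2] * scale0)
  # pyramid
  facs <- 2^((levels - 1):0)
  for (f in facs) {
    ff <- if (f > 1) .block_reduce(fz, f) else fz
    mf <- if (f > 1) .block_reduce(mz, f) else mz
    nr <- nrow(ff); nc <- ncol(ff)
    gx <- rep(seq_len(nc) - 1, each = nr)
    gy <- rep(seq_len(nr) - 1, times = nc)
    obj <- function(p) {
      ang <- p[1]
      if (abs(ang) > deg2rad(max_rotation_deg)) return(1e6)
      L <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2) %*%
        matrix(c(exp(p[2]), 0, p[4], exp(p[3])), 2, 2)
      Ai <- solve(L)
      tx <- p[5] / f; ty <- p[6] / f
      sx <- Ai[1, 1] * (gx - tx) + Ai[1, 2] * (gy - ty)
      sy <- Ai[2, 1] * (gx - tx) + Ai[2, 2] * (gy - ty)
      samp <- .sample_grid(mf, sx, sy, nr, nc, "linear")
      -.ncc(samp, ff)
    }
    p0 <- par; p0[5:6] <- par[5:6]   # translations stored at full resolution
    opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = if (f == facs[1]) 600 else 300,
                                       reltol = 1e-10))
    par <- opt$par
  }
  ang <- par[1]
  L <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2) %*%
    matrix(c(exp(par[2]), 0, par[4], exp(par[3])), 2, 2)
  tf <- affine_transform(L, par[5:6])
  attr(tf, "ncc") <- -opt$value
  tf
}

#' Reorient diffusion vectors and extract in-plane axial angles
#'
#' Applies the rotational component of the registration transform to the
#' dMRI principal-direction vectors, projects them onto the imaging plane,
#' and reports the in-plane axial angle. Vectors whose in-plane projection
#' is shorter than `min_inplane` are through-plane fibers whose 2D angle is
#' meaningless; they are flagged invalid.
#'
#' @param vectors unit 3-vectors: `n x 3` matrix or `[ny, nx, 3]` array.
#' @param tf an [affine_transform()] (its `rotational_component` is used),
#'   or a 2x2/3x3 rotation matrix.
#' @param plane 2x3 matrix whose rows are the in-plane basis vectors
#'   (default: the x/y image axes).
#' @param min_inplane validity threshold on the projected magnitude.
#' @param valid optional logical input-validity flags.
#' @return list with `angle_deg` (degrees `[0, 180)`, NaN where invalid) and
#'   `valid`, shaped like the input grid.
#' @export
reorient_and_project <- function(vectors, tf, plane = rbind(c(1, 0, 0),
                                                            c(0, 1, 0)),
                                 min_inplane = 0.1, valid = NULL) {
  if (inherits(tf, "affine_transform")) tf <- tf$rotational_component
  R3 <- if (all(dim(tf) == c(2, 2))) rbind(cbind(tf, 0), c(0, 0, 1)) else tf
  dm <- dim(vectors)
  grid <- length(dm) == 3
  V <- if (grid) matrix(vectors, ncol = 3) else matrix(vectors, ncol = 3)
  Vr <- V %*% t(R3)
  px <- Vr %*% plane[1, ]; py <- Vr %*% plane[2, ]
  mag <- sqrt(px^2 + py^2)
  ang <- wrap_deg(rad2deg(atan2(py, px)))
  ok <- is.finite(mag) & mag >= min_inplane
  if (!is.null(valid)) ok <- ok & as.logical(valid)
  ang[!ok] <- NaN
  if (grid) {
    list(angle_deg = matrix(ang, dm[1], dm[2]),
         valid = matrix(ok, dm[1], dm[2]))
  } else {
    list(angle_deg = as.numeric(ang), valid = as.logical(ok))
  }
}

#' Tissue / white-matter masks from a parameter map
#'
#' Foreground by Otsu's threshold (or a fixed value), optional retention of
#' the largest connected component and hole filling — the recipe used to
#' build tissue and white-matter masks for Dice evaluation of the
#' registration. Invert the map (or use `higher = FALSE`) for quantities
#' where the structure of interest is dark, such as ADC in white matter.
#'
#' @param map numeric matrix, finite on its support.
#' @param method `"otsu"` or `"threshold"`.
#' @param value threshold for `method = "threshold"`.
#' @param higher keep pixels above (TRUE) or below the threshold.
#' @param keep_largest retain only the largest connected component.
#' @param fill_holes fill enclosed holes.
#' @return logical matrix.
#' @export
make_masks <- function(map, method = c("otsu", "threshold"), value = NULL,
                       higher = TRUE, keep_largest = TRUE,
                       fill_holes = TRUE) {
  method <- match.arg(method)
  m <- map; m[!is.finite(m)] <- NA
  v <- m[is.finite(m)]
  if (!length(v) || diff(range(v)) <= 0)
    stop("degenerate map: no contrast to threshold", call. = FALSE)
  thr <- if (method == "otsu") {
    norm <- (m - min(v)) / diff(range(v)); norm[is.na(norm)] <- 0
    min(v) + diff(range(v)) * EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  } else {
    if (is.null(value)) stop("value required for method = 'threshold'", call. = FALSE)
    value
  }
  mask <- if (higher) !is.na(m) & m > thr else !is.na(m) & m < thr
  if (keep_largest && any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    sizes <- tabulate(as.integer(lab)[as.integer(lab) > 0])
    mask <- matrix(as.integer(lab) == which.max(sizes), nrow(mask), ncol(mask))
  }
  if (fill_holes && any(mask))
    mask <- matrix(as.logical(EBImage::fillHull(EBImage::Image(mask * 1))),
                   nrow(mask), ncol(mask))
  mask
}
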