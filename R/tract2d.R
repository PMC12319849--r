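#' White-matter mask from a retardance map
#'
#' Thresholds the retardance en-face map (white matter is birefringent, gray
#' matter and background are not) and cleans the result morphologically:
#' connected components smaller than `min_size` pixels are removed and holes
#' up to `hole_size` pixels are filled. When `threshold` is NULL it is chosen
#' by Otsu's method on the retardance histogram.
#'
#' @param retardance_map 2D retardance map in degrees.
#' @param threshold retardance threshold in degrees, or NULL for Otsu.
#' @param min_size,hole_size morphological cleanup sizes in pixels.
#' @return logical matrix.
#' @export
build_mask_from_retardance <- function(retardance_map, threshold = NULL,
                                       min_size = 50, hole_size = 50) {
  m <- retardance_map
  m[!is.finite(m)] <- 0
  if (is.null(threshold)) {
    rng <- range(m)
    if (diff(rng) <= 0) stop("constant retardance map: supply a threshold",
                             call. = FALSE)
    norm <- (m - rng[1]) / diff(rng)
    threshold <- rng[1] + diff(rng) *
      EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- m > threshold
  } else {
    if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
    mask <- m >= threshold
  }
  .clean_mask(mask, min_size, hole_size)
}

.clean_mask <- function(mask, min_size, hole_size) {
  mode(mask) <- "logical"
  if (!any(mask) || all(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  sizes <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  keep <- which(sizes >= min_size)
  mask <- matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask))
  if (any(!mask) && hole_size > 0) {
    holes <- EBImage::bwlabel(EBImage::Image((!mask) * 1))
    hs <- tabulate(as.integer(holes)[as.integer(holes) > 0])
    filled <- matrix(as.logical(EBImage::fillHull(EBImage::Image(mask * 1))),
                     nrow(mask), ncol(mask))
    small_holes <- which(hs <= hole_size)
    fill_px <- matrix(as.integer(holes) %in% small_holes,
                      nrow(mask), ncol(mask)) & filled
    mask <- mask | fill_px
  }
  mask
}

#' Axial orientation field for tractography
#'
#' @param theta 2D map of axial angles, degrees `[0, 180)` or NaN.
#' @param mask logical trackable-region map; forced FALSE where theta is NaN.
#' @param pixel_um lateral pixel size.
#' @return object of class `orientation_field`.
#' @export
orientation_field <- function(theta, mask = NULL, pixel_um = 10) {
  mask <- mask %||% is.finite(theta)
  if (!identical(dim(mask), dim(theta)))
    stop("mask and theta must share shape", call. = FALSE)
  mask <- mask & is.finite(theta)
  structure(list(theta = theta, mask = mask, pixel_um = pixel_um),
            class = "orientation_field")
}

#' Regular seed grid inside a mask
#'
#' @param mask logical matrix.
#' @param spacing_px grid spacing in pixels (>= 1).
#' @return matrix with columns `x`, `y` (0-based pixel-center coordinates).
#' @export
seed_grid <- function(mask, spacing_px = 5) {
  if (spacing_px < 1) stop("spacing_px must be >= 1", call. = FALSE)
  ys <- seq(1, nrow(mask), by = spacing_px)
  xs <- seq(1, ncol(mask), by = spacing_px)
  pts <- expand.grid(x = xs, y = ys)
  keep <- mask[cbind(pts$y, pts$x)]
  out <- as.matrix(pts[keep, c("x", "y"), drop = FALSE]) - 1
  rownames(out) <- NULL
  out
}

# nearest-pixel (FACT) or doubled-angle bilinear orientation lookup;
# returns degrees or NaN. Coordinates are 0-based pixel centers.
.field_theta <- function(field, x, y, interp) {
  nr <- nrow(field$theta); nc <- ncol(field$theta)
  if (interp == "nearest") {
    j <- round(x) + 1; i <- round(y) + 1
    if (i < 1 || i > nr || j < 1 || j > nc) return(NaN)
    if (!field$mask[i, j]) return(NaN)
    return(field$theta[i, j])
  }
  j0 <- floor(x); i0 <- floor(y)
  fx <- x - j0; fy <- y - i0
  acc <- c(0, 0); wtot <- 0
  for (dij in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
    i <- i0 + dij[1] + 1; j <- j0 + dij[2] + 1
    if (i < 1 || i > nr || j < 1 || j > nc) next
    if (!field$mask[i, j]) next
    w <- (if (dij[1] == 0) 1 - fy else fy) * (if (dij[2] == 0) 1 - fx else fx)
    a2 <- deg2rad(2 * field$theta[i, j])
    acc <- acc + w * c(cos(a2), sin(a2))
    wtot <- wtot + w
  }
  if (wtot <= 0 || sum(acc^2) < 1e-20) return(NaN)
  wrap_deg(wrap_deg(rad2deg(atan2(acc[2], acc[1])), 360) / 2)
}

# one half-track from `pos` with initial direction sign `dir0`
.track_half <- function(field, pos, dir0, step_px, max_angle_deg,
                        max_len_px, interp) {
  pts <- matrix(pos, ncol = 2)
  d <- dir0
  prev_theta <- .field_theta(field, pos[1], pos[2], "nearest")
  len <- 0
  repeat {
    th <- .field_theta(field, pos[1], pos[2], interp)
    if (!is.finite(th)) break
    th_pix <- .field_theta(field, pos[1], pos[2], "nearest")
    if (is.finite(prev_theta) && is.finite(th_pix) &&
        axial_difference_deg(th_pix, prev_theta) > max_angle_deg) break
    prev_theta <- th_pix
    v <- c(cos(deg2rad(th)), sin(deg2rad(th)))
    if (sum(v * d) < 0) v <- -v
    pos <- pos + step_px * v
    d <- v
    if (pos[1] < 0 || pos[2] < 0 ||
        pos[1] > ncol(field$theta) - 1 || pos[2] > nrow(field$theta) - 1) break
    if (!is.finite(.field_theta(field, pos[1], pos[2], "nearest"))) {
      pts <- rbind(pts, pos); len <- len + step_px
      break
    }
    pts <- rbind(pts, pos)
    len <- len + step_px
    if (len >= max_len_px) break
  }
  pts
}

# internal axial distance in degrees (scalar)
axial_difference_deg <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

#' FACT-style streamline tractography on a 2D axial orientation field
#'
#' From each seed, tracks bidirectionally with Euler steps of `step_px`:
#' the local direction is the unit vector of the (by default
#' nearest-neighbor) pixel orientation, with its sign chosen to continue the
#' previous step — axial data has no intrinsic sign, so the first step
#' spawns both signs, one per half-track. Tracking terminates on leaving the
#' mask or image bounds, on an axial angle change between consecutive pixel
#' orientations exceeding `max_angle_deg`, on NaN orientation, or at
#' `max_len_px` arc length. Half-tracks are merged; streamlines shorter than
#' `min_len_px` are discarded.
#'
#' @param field an [orientation_field()].
#' @param seeds matrix with columns `x`, `y` (0-based), e.g. [seed_grid()].
#' @param step_px Euler step in pixels, in `(0, 1]` (default 0.5).
#' @param max_angle_deg maximum axial angle change between consecutive
#'   pixels before termination (default 45).
#' @param min_len_px,max_len_px streamline length bounds in pixels.
#' @param interp `"nearest"` (FACT) or `"bilinear"` (doubled-angle
#'   interpolated directions, more accurate on smooth fields).
#' @return list of streamlines; each is a matrix of `x, y` points with
#'   attribute `length_px`.
#' @export
track <- function(field, seeds, step_px = 0.5, max_angle_deg = 45,
                  min_len_px = 10, max_len_px = 1e4,
                  interp = c("nearest", "bilinear")) {
  stopifnot(inherits(field, "orientation_field"))
  interp <- match.arg(interp)
  if (step_px <= 0 || step_px > 1) stop("step_px must be in (0, 1]", call. = FALSE)
  if (max_angle_deg <= 0 || max_angle_deg > 90)
    stop("max_angle_deg must be in (0, 90]", call. = FALSE)
  out <- list()
  for (s in seq_len(nrow(seeds))) {
    pos <- as.numeric(seeds[s, 1:2])
    th0 <- .field_theta(field, pos[1], pos[2], "nearest")
    if (!is.finite(th0)) {
      warning(sprintf("seed %d outside mask: skipped", s), call. = FALSE)
      next
    }
    v0 <- c(cos(deg2rad(th0)), sin(deg2rad(th0)))
    half_a <- .track_half(field, pos, v0, step_px, max_angle_deg,
                          max_len_px / 2, interp)
    half_b <- .track_half(field, pos, -v0, step_px, max_angle_deg,
                          max_len_px / 2, interp)
    pts <- rbind(half_b[rev(seq_len(nrow(half_b))), , drop = FALSE],
                 half_a[-1, , drop = FALSE])
    if (nrow(pts) < 2) next
    len <- sum(sqrt(rowSums(diff(pts)^2)))
    if (len < min_len_px) next
    dimnames(pts) <- list(NULL, c("x", "y"))
    attr(pts, "length_px") <- len
    out[[length(out) + 1L]] <- pts
  }
  out
}
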