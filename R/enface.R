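#' Bundle co-located en-face parameter maps
#'
#' @param mu_s_map,retardance_map,orientation_map 2D maps sharing shape;
#'   orientation in degrees `[0, 180)` or NaN.
#' @param pixel_um lateral pixel size.
#' @param masks optional named list of logical maps (e.g. `tissue`, `wm`).
#' @return object of class `parameter_map_stack`.
#' @export
parameter_map_stack <- function(mu_s_map, retardance_map, orientation_map,
                                pixel_um, masks = list()) {
  dims <- dim(mu_s_map)
  for (m in c(list(retardance_map, orientation_map), unname(masks)))
    if (!identical(dim(m), dims)) stop("all maps must share shape", call. = FALSE)
  bad <- orientation_map[is.finite(orientation_map)]
  if (length(bad) && (any(bad < 0) || any(bad >= 180)))
    stop("orientation_map values must lie in [0, 180)", call. = FALSE)
  structure(list(mu_s_map = mu_s_map, retardance_map = retardance_map,
                 orientation_map = orientation_map, pixel_um = pixel_um,
                 masks = masks),
            class = "parameter_map_stack")
}

.depth_slab <- function(volume, depth_range) {
  dm <- dim(volume)
  nz <- dm[3]
  depth_range <- depth_range %||% c(1L, nz)
  if (length(depth_range) != 2L || depth_range[1] < 1 ||
      depth_range[2] > nz || depth_range[1] > depth_range[2])
    stop("depth_range must be a non-empty interval within the volume depth",
         call. = FALSE)
  volume[, , depth_range[1]:depth_range[2], drop = FALSE]
}

#' En-face mean of a scalar volume
#'
#' Collapses a reconstructed per-voxel quantity to a 2D map by the
#' NaN-ignoring arithmetic mean over a depth range (the slice thickness);
#' all-NaN columns give NaN.
#'
#' @param volume numeric array `[ny, nx, nz]`.
#' @param depth_range `c(first, last)` depth pixels (1-based, inclusive);
#'   NULL for full depth.
#' @return matrix `[ny, nx]`.
#' @export
enface_mean <- function(volume, depth_range = NULL) {
  slab <- .depth_slab(volume, depth_range)
  n <- apply(!is.na(slab), c(1, 2), sum)
  s <- apply(slab, c(1, 2), function(v) sum(v, na.rm = TRUE))
  out <- s / n
  out[n == 0] <- NaN
  out
}

#' En-face orientation by histogram peak
#'
#' Per lateral pixel, bins the valid axial orientations over the depth range
#' into `180 / bin_deg` intervals `[0, bin), [bin, 2*bin), ...` and returns
#' the center of the fullest bin (ties broken toward the lowest bin). The
#' output is therefore bin-quantized by construction: centers are
#' `bin_deg/2 + k * bin_deg`.
#'
#' @param theta_volume axial orientations, degrees `[0, 180)` or NaN,
#'   `[ny, nx, nz]`.
#' @inheritParams enface_mean
#' @param bin_deg histogram bin width in degrees; must divide 180
#'   (default 5).
#' @return matrix of bin-center orientations, NaN where no valid samples.
#' @export
enface_orientation <- function(theta_volume, depth_range = NULL, bin_deg = 5) {
  if (180 %% bin_deg != 0)
    stop("bin_deg must divide 180", call. = FALSE)
  slab <- .depth_slab(theta_volume, depth_range)
  nb <- as.integer(180 / bin_deg)
  apply(slab, c(1, 2), function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NaN)
    b <- pmin(floor(wrap_deg(v) / bin_deg), nb - 1L)
    counts <- tabulate(b + 1L, nbins = nb)
    (which.max(counts) - 1L) * bin_deg + bin_deg / 2
  })
}

#' Bundle tiles and nominal offsets for stitching
#'
#' @param tiles list of [parameter_map_stack()] objects.
#' @param offsets list (or matrix rows) of 0-based `c(x, y)` pixel offsets.
#' @param overlap_frac nominal fractional overlap used for blend ramps.
#' @return object of class `tile_layout`.
#' @export
tile_layout <- function(tiles, offsets, overlap_frac = 0.2) {
  if (!length(tiles)) stop("empty layout", call. = FALSE)
  if (length(tiles) != length(offsets))
    stop("one offset per tile required", call. = FALSE)
  px <- vapply(tiles, function(t) t$pixel_um, numeric(1))
  if (any(abs(px - px[1]) > 1e-9))
    stop("inconsistent pixel sizes across tiles", call. = FALSE)
  offsets <- lapply(offsets, function(o) {
    if (any(o < 0)) stop("offsets must be non-negative", call. = FALSE)
    as.numeric(o)
  })
  structure(list(tiles = tiles, offsets = offsets,
                 overlap_frac = overlap_frac), class = "tile_layout")
}

# per-tile feathering weight: ramps linearly over the overlap width from the
# tile border inward; strictly positive everywhere so a solely-covered pixel
# normalizes to weight 1.
.tile_weight <- function(nr, nc, overlap_w) {
  di <- pmin(seq_len(nr), rev(seq_len(nr)))
  dj <- pmin(seq_len(nc), rev(seq_len(nc)))
  wi <- pmin(di / max(overlap_w, 1), 1)
  wj <- pmin(dj / max(overlap_w, 1), 1)
  outer(wi, wj, pmin)
}

#' Stitch overlapping tiles into a mosaic
#'
#' Scalar maps are fused by linear blending: per-pixel tile weights ramp
#' linearly from the tile edge to 1 at a distance of the overlap width and
#' are normalized to sum to 1 over the tiles covering each mosaic pixel.
#' Orientation maps are blended axially: angles are doubled onto unit
#' vectors, averaged with the same weights, and the resultant argument is
#' halved back into `[0, 180)` — naive averaging would corrupt angles across
#' the 0/180 seam. Nominal offsets are trusted (blockface acquisition has
#' exact stage coordinates); `refine = TRUE` refines each tile's offset by
#' integer phase correlation against the running mosaic within `±5` px.
#'
#' @param layout a [tile_layout()].
#' @param refine logical; refine nominal offsets by phase correlation.
#' @return a [parameter_map_stack()] mosaic.
#' @export
stitch <- function(layout, refine = FALSE) {
  stopifnot(inherits(layout, "tile_layout"))
  tiles <- layout$tiles; offsets <- layout$offsets
  nr <- nrow(tiles[[1]]$mu_s_map); nc <- ncol(tiles[[1]]$mu_s_map)
  overlap_w <- max(1, round(layout$overlap_frac * min(nr, nc)))
  if (refine && length(tiles) > 1)
    offsets <- .refine_offsets(tiles, offsets)
  W <- max(vapply(offsets, `[`, numeric(1), 1)) + nc
  H <- max(vapply(offsets, `[`, numeric(1), 2)) + nr
  acc_w <- matrix(0, H, W)
  acc_mu <- matrix(0, H, W); acc_ret <- matrix(0, H, W)
  acc_cx <- matrix(0, H, W); acc_cy <- matrix(0, H, W)
  acc_wth <- matrix(0, H, W)
  for (k in seq_along(tiles)) {
    t <- tiles[[k]]; o <- offsets[[k]]
    rows <- (o[2] + 1):(o[2] + nr); cols <- (o[1] + 1):(o[1] + nc)
    w <- .tile_weight(nr, nc, overlap_w)
    wm <- w; wm[!is.finite(t$mu_s_map)] <- 0
    acc_mu[rows, cols] <- acc_mu[rows, cols] +
      ifelse(is.finite(t$mu_s_map), t$mu_s_map, 0) * wm
    wr <- w; wr[!is.finite(t$retardance_map)] <- 0
    acc_ret[rows, cols] <- acc_ret[rows, cols] +
      ifelse(is.finite(t$retardance_map), t$retardance_map, 0) * wr
    acc_w[rows, cols] <- acc_w[rows, cols] + wm
    th2 <- deg2rad(2 * t$orientation_map)
    wth <- w; wth[!is.finite(th2)] <- 0
    acc_cx[rows, cols] <- acc_cx[rows, cols] +
      ifelse(is.finite(th2), cos(th2), 0) * wth
    acc_cy[rows, cols] <- acc_cy[rows, cols] +
      ifelse(is.finite(th2), sin(th2), 0) * wth
    acc_wth[rows, cols] <- acc_wth[rows, cols] + wth
  }
  mu <- acc_mu / acc_w; ret <- acc_ret / acc_w
  mu[acc_w == 0] <- NaN; ret[acc_w == 0] <- NaN
  th <- wrap_deg(wrap_deg(rad2deg(atan2(acc_cy, acc_cx)), 360) / 2)
  th[acc_wth == 0 | (acc_cx^2 + acc_cy^2) < 1e-18] <- NaN
  parameter_map_stack(mu, ret, th, tiles[[1]]$pixel_um)
}

# integer phase-correlation refinement of nominal offsets (first tile fixed)
.refine_offsets <- function(tiles, offsets, search_px = 5) {
  ref <- tiles[[1]]$mu_s_map
  out <- offsets
  for (k in seq_along(tiles)[-1]) {
    best <- offsets[[k]]; best_cc <- -Inf
    for (dx in -search_px:search_px) for (dy in -search_px:search_px) {
      o <- offsets[[k]] + c(dx, dy)
      if (any(o < 0)) next
      cc <- .overlap_ncc(ref, offsets[[1]], tiles[[k]]$mu_s_map, o)
      if (is.finite(cc) && cc > best_cc) { best_cc <- cc; best <- o }
    }
    out[[k]] <- best
  }
  out
}

.overlap_ncc <- function(a, oa, b, ob) {
  ra <- oa[2] + seq_len(nrow(a)); ca <- oa[1] + seq_len(ncol(a))
  rb <- ob[2] + seq_len(nrow(b)); cb <- ob[1] + seq_len(ncol(b))
  rr <- intersect(ra, rb); cc <- intersect(ca, cb)
  if (length(rr) < 4 || length(cc) < 4) return(NA_real_)
  va <- a[rr - oa[2], cc - oa[1]]; vb <- b[rr - ob[2], cc - ob[1]]
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 8) return(NA_real_)
  suppressWarnings(stats::cor(va[ok], vb[ok]))
}

#' Stack serial sections into a volume
#'
#' Ordered concatenation of en-face section maps along a third axis; the
#' blockface geometry needs no inter-slice registration. Slice thickness
#' (typically 100-150 um) is recorded as metadata.
#'
#' @param sections ordered list of [parameter_map_stack()] objects sharing
#'   shape and pixel size.
#' @param slice_thickness_um physical thickness removed between sections.
#' @return list of 3D arrays (`mu_s`, `retardance`, `orientation`) plus
#'   `pixel_um` and `slice_thickness_um`; class `section_volume`.
#' @export
stack_sections <- function(sections, slice_thickness_um = 150) {
  if (!length(sections)) stop("no sections", call. = FALSE)
  dims <- dim(sections[[1]]$mu_s_map)
  for (s in sections)
    if (!identical(dim(s$mu_s_map), dims))
      stop("sections must share shape", call. = FALSE)
  pick <- function(field) {
    out <- array(NA_real_, c(dims, length(sections)))
    for (k in seq_along(sections)) out[, , k] <- sections[[k]][[field]]
    out
  }
  structure(list(mu_s = pick("mu_s_map"),
                 retardance = pick("retardance_map"),
                 orientation = pick("orientation_map"),
                 pixel_um = sections[[1]]$pixel_um,
                 slice_thickness_um = slice_thickness_um),
            class = "section_volume")
}

#' En-face parameter stack from a reconstructed volume
#'
#' Convenience wrapper: NaN-ignoring depth means for the scattering
#' coefficient and retardance, histogram-peak collapse for the orientation.
#'
#' @param recon an `oct_recon` from [reconstruct_volume()].
#' @inheritParams enface_orientation
#' @return a [parameter_map_stack()].
#' @export
enface_stack <- function(recon, depth_range = NULL, bin_deg = 5) {
  stopifnot(inherits(recon, "oct_recon"))
  parameter_map_stack(
    enface_mean(recon$mu_s, depth_range),
    enface_mean(recon$retardance, depth_range),
    enface_orientation(recon$theta, depth_range, bin_deg),
    recon$lateral_pixel_um)
}
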