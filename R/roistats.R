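#' Place square ROIs in the white matter
#'
#' Candidate boxes sit on a regular non-overlapping lattice over the map;
#' boxes whose white-matter fraction reaches `min_wm_frac` survive. If more
#' than `n_rois` survive, the list is thinned deterministically with an even
#' stride over the candidate sequence (replacing by-hand ROI selection with
#' a reproducible rule; `seed` only breaks exact stride ties).
#'
#' @param wm_mask logical white-matter mask.
#' @param roi_size_um ROI edge length, default 900 (0.9 mm).
#' @param pixel_um lateral pixel size of the mask.
#' @param n_rois requested number of ROIs, or NULL for all survivors.
#' @param min_wm_frac minimum white-matter fraction per box (default 0.8).
#' @param seed optional integer for tie-breaking.
#' @return data.frame with `roi_id`, `x0`, `y0` (0-based top-left), `size_px`,
#'   `wm_frac`.
#' @export
place_rois <- function(wm_mask, roi_size_um = 900, pixel_um = 10,
                       n_rois = NULL, min_wm_frac = 0.8, seed = NULL) {
  size_px <- max(1L, as.integer(round(roi_size_um / pixel_um)))
  nr <- nrow(wm_mask); nc <- ncol(wm_mask)
  if (size_px > nr || size_px > nc)
    stop("ROI larger than the map", call. = FALSE)
  ys <- seq(1L, nr - size_px + 1L, by = size_px)
  xs <- seq(1L, nc - size_px + 1L, by = size_px)
  cand <- expand.grid(y = ys, x = xs)
  frac <- mapply(function(y, x)
    mean(wm_mask[y:(y + size_px - 1L), x:(x + size_px - 1L)]),
    cand$y, cand$x)
  keep <- which(frac >= min_wm_frac)
  if (!length(keep))
    stop("no ROI candidate reaches the white-matter fraction", call. = FALSE)
  if (!is.null(n_rois) && length(keep) > n_rois) {
    idx <- unique(round(seq(1, length(keep), length.out = n_rois)))
    if (length(idx) < n_rois) {
      pool <- setdiff(seq_along(keep), idx)
      if (!is.null(seed)) set.seed(seed)
      extra <- pool[seq_len(n_rois - length(idx))]
      idx <- sort(c(idx, extra))
    }
    keep <- keep[idx]
  }
  data.frame(roi_id = seq_along(keep),
             x0 = cand$x[keep] - 1L, y0 = cand$y[keep] - 1L,
             size_px = size_px, wm_frac = frac[keep])
}

#' Circular mean of axial (180-degree periodic) angles
#'
#' Angles are doubled, the (optionally weighted) mean resultant vector is
#' computed, and its argument halved back into `[0, 180)`. A resultant
#' length below 1e-9 (e.g. two orthogonal axes in balance) has no meaningful
#' mean and returns NaN with attribute `degenerate = TRUE`.
#'
#' @param angles degrees in `[0, 180)`; NaN entries are dropped.
#' @param weights optional non-negative weights.
#' @return mean axial angle in degrees, or NaN.
#' @export
circ_mean_axial <- function(angles, weights = NULL) {
  w <- weights %||% rep(1, length(angles))
  ok <- is.finite(angles) & is.finite(w)
  angles <- angles[ok]; w <- w[ok]
  if (!length(angles)) stop("no finite angles", call. = FALSE)
  a2 <- deg2rad(2 * angles)
  cx <- sum(w * cos(a2)) / sum(w)
  cy <- sum(w * sin(a2)) / sum(w)
  if (sqrt(cx^2 + cy^2) < 1e-9)
    return(structure(NaN, degenerate = TRUE))
  wrap_deg(wrap_deg(rad2deg(atan2(cy, cx)), 360) / 2)
}

#' Axial angular difference in polar space
#'
#' Difference between two axial angles on the half-circle: `|a - b|` modulo
#' 180, folded to at most 90 degrees — so 178 vs 1 differ by 3 degrees, not
#' 177.
#'
#' @param a,b angles in degrees (vectors recycle); NaN propagates.
#' @return difference in degrees, `[0, 90]`.
#' @export
angular_difference <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Pearson correlation with pairwise NaN removal
#'
#' Validated front end to the product-moment correlation: pairs with a
#' missing member are dropped; fewer than 3 complete pairs or a constant
#' vector is an error rather than NA.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input has no defined correlation", call. = FALSE)
  stats::cor(x, y)
}

#' ROI-level comparison table between PSOCT and dMRI maps
#'
#' For each ROI: NaN-ignoring means of the scattering coefficient,
#' retardance, ADC and FA, plus axial circular means of the PSOCT
#' orientation and of the reoriented in-plane dMRI orientation. All inputs
#' must already live on the common PSOCT grid (dMRI maps resampled, vectors
#' reoriented first). ROIs with no valid pixel are dropped with a warning.
#'
#' @param psoct a [parameter_map_stack()].
#' @param dmri list with matrices `adc`, `fa`, `theta` on the PSOCT grid.
#' @param rois data.frame from [place_rois()].
#' @return data.frame (one row per retained ROI) with columns `roi_id`,
#'   `center_x`, `center_y`, `mean_mu_s`, `mean_retardance`,
#'   `circ_mean_theta_psoct`, `mean_adc`, `fa`, `circ_mean_theta_dmri`,
#'   `n_valid_px`.
#' @export
extract_roi_table <- function(psoct, dmri, rois) {
  stopifnot(inherits(psoct, "parameter_map_stack"))
  dims <- dim(psoct$mu_s_map)
  for (nm in c("adc", "fa", "theta"))
    if (!identical(dim(dmri[[nm]]), dims))
      stop("dmri maps must be on the PSOCT grid", call. = FALSE)
  nanmean <- function(v) { v <- v[is.finite(v)]; if (length(v)) mean(v) else NaN }
  circ_or_nan <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NaN)
    as.numeric(circ_mean_axial(v))
  }
  rows <- lapply(seq_len(nrow(rois)), function(k) {
    r <- rois[k, ]
    ri <- (r$y0 + 1):(r$y0 + r$size_px)
    ci <- (r$x0 + 1):(r$x0 + r$size_px)
    sub <- function(m) m[ri, ci]
    n_valid <- sum(is.finite(sub(psoct$mu_s_map)))
    data.frame(roi_id = r$roi_id,
               center_x = r$x0 + r$size_px / 2,
               center_y = r$y0 + r$size_px / 2,
               mean_mu_s = nanmean(sub(psoct$mu_s_map)),
               mean_retardance = nanmean(sub(psoct$retardance_map)),
               circ_mean_theta_psoct = circ_or_nan(sub(psoct$orientation_map)),
               mean_adc = nanmean(sub(dmri$adc)),
               fa = nanmean(sub(dmri$fa)),
               circ_mean_theta_dmri = circ_or_nan(sub(dmri$theta)),
               n_valid_px = n_valid)
  })
  out <- do.call(rbind, rows)
  drop <- out$n_valid_px == 0
  if (any(drop)) {
    warning(sprintf("%d ROI(s) with no valid pixels dropped", sum(drop)),
            call. = FALSE)
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Whole-white-matter summary of a parameter map
#'
#' NaN-ignoring mean and standard deviation over masked pixels, the numbers
#' behind per-sample bar plots of scattering coefficient and retardance.
#'
#' @param map numeric matrix.
#' @param wm_mask logical mask (nonempty).
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return named numeric vector `c(mean, sd)`.
#' @export
wm_summary <- function(map, wm_mask, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!any(wm_mask)) stop("empty mask", call. = FALSE)
  v <- map[wm_mask]
  v <- v[is.finite(v)]
  c(mean = mean(v), sd = .sd_by(v, sd_type))
}

#' Polar histogram of axial angular differences
#'
#' Bins differences in `[0, 90]` degrees (values of exactly 90 fall in the
#' last bin) and optionally draws a polar plot to a PNG file.
#'
#' @param differences degrees in `[0, 90]`.
#' @param bin_deg bin width; must divide 90.
#' @param file optional PNG path for the polar plot.
#' @return named integer vector of per-bin counts (names are bin centers).
#' @export
polar_histogram <- function(differences, bin_deg = 10, file = NULL) {
  if (90 %% bin_deg != 0) stop("bin_deg must divide 90", call. = FALSE)
  d <- differences[is.finite(differences)]
  if (any(d < 0 | d > 90)) stop("differences must lie in [0, 90]", call. = FALSE)
  nb <- as.integer(90 / bin_deg)
  b <- pmin(floor(d / bin_deg), nb - 1L)
  counts <- tabulate(b + 1L, nbins = nb)
  names(counts) <- bin_deg / 2 + bin_deg * (seq_len(nb) - 1)
  if (!is.null(file)) {
    grDevices::png(file, width = 480, height = 480)
    on.exit(grDevices::dev.off())
    ang <- deg2rad(as.numeric(names(counts)))
    r <- counts / max(counts, 1)
    graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-0.1, 1.1), asp = 1,
                   axes = FALSE, xlab = "", ylab = "",
                   main = "PSOCT vs dMRI angular difference")
    for (k in seq_along(ang)) {
      a0 <- deg2rad(bin_deg * (k - 1)); a1 <- deg2rad(bin_deg * k)
      aa <- seq(a0, a1, length.out = 10)
      graphics::polygon(c(0, r[k] * cos(aa)), c(0, r[k] * sin(aa)),
                        col = "steelblue", border = "white")
    }
    graphics::segments(0, 0, cos(seq(0, pi / 2, by = pi / 6)),
                       sin(seq(0, pi / 2, by = pi / 6)), col = "gray70")
  }
  counts
}
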