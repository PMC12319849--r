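#' Write / read a 2D map or volume with pixel-size metadata
#'
#' TIFF output is 32-bit float (multi-page for volumes) with a JSON sidecar
#' (`<path>.json`) recording pixel sizes, units and the orientation-wrapping
#' convention; NIfTI output stores pixel sizes in the pixdim fields (mm).
#'
#' @param map numeric matrix or 3D array.
#' @param path output path (`.tif`/`.tiff` or `.nii`/`.nii.gz`).
#' @param pixel_um lateral pixel size.
#' @param slice_um through-plane spacing for volumes.
#' @param meta extra metadata recorded in the sidecar (TIFF only).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, pixel_um = 10, slice_um = pixel_um,
                      meta = list()) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    pages <- if (length(dim(map)) == 3)
      lapply(seq_len(dim(map)[3]), function(k) map[, , k])
    else list(map)
    tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
    sidecar <- c(list(pixel_um = pixel_um, slice_um = slice_um,
                      dim = dim(map) %||% length(map),
                      orientation_convention = "degrees in [0,180), NaN invalid"),
                 meta)
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (ext == "nii") {
    im <- RNifti::asNifti(map)
    nd <- length(dim(map) %||% 1)
    RNifti::pixdim(im) <- c(pixel_um / 1000, pixel_um / 1000,
                            slice_um / 1000)[seq_len(nd)]
    RNifti::writeNifti(im, path)
  } else stop("unsupported format: ", ext, call. = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    map <- if (length(pages) == 1) pages[[1]] else {
      arr <- array(NA_real_, c(dim(pages[[1]]), length(pages)))
      for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
      arr
    }
    side <- paste0(path, ".json")
    meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
            else list()
    list(map = map, pixel_um = meta$pixel_um %||% NA_real_, meta = meta)
  } else if (ext == "nii") {
    im <- RNifti::readNifti(path)
    pd <- as.numeric(RNifti::pixdim(im))
    list(map = array(as.numeric(im), dim(im)), pixel_um = pd[1] * 1000,
         meta = list(pixdim_mm = pd))
  } else stop("unsupported format: ", ext, call. = FALSE)
}

#' Write an HSV-encoded orientation preview image
#'
#' Hue encodes the axial angle (hue = theta / 180, i.e. the color wheel
#' covers 2 theta), brightness encodes an optional weight map (typically
#' retardance), and invalid pixels are black.
#'
#' @param orientation_map axial angles in degrees `[0, 180)`, NaN invalid.
#' @param path output PNG path.
#' @param weight optional map scaled to [0, 1] for brightness (NULL: full).
#' @return `path`, invisibly.
#' @export
write_orientation_png <- function(orientation_map, path, weight = NULL) {
  h <- wrap_deg(orientation_map) / 180
  v <- if (is.null(weight)) matrix(1, nrow(h), ncol(h)) else {
    w <- weight; rng <- range(w[is.finite(w)])
    if (diff(rng) > 0) (w - rng[1]) / diff(rng) else w * 0 + 1
  }
  ok <- is.finite(h) & is.finite(v)
  rgb <- array(0, c(nrow(h), ncol(h), 3))
  col <- grDevices::col2rgb(grDevices::hsv(h[ok], 1, pmin(pmax(v[ok], 0), 1))) / 255
  for (k in 1:3) {
    plane <- matrix(0, nrow(h), ncol(h))
    plane[ok] <- col[k, ]
    rgb[, , k] <- plane
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Write / read streamlines as newline-delimited JSON
#'
#' One streamline per line: an object with `points` (list of `[x, y]` pixel
#' coordinates) and `length_px`.
#'
#' @param streamlines list of point matrices from [track()].
#' @param path output `.ndjson` path.
#' @return `path` invisibly / the streamline list.
#' @export
write_streamlines <- function(streamlines, path) {
  lines <- vapply(streamlines, function(s) {
    jsonlite::toJSON(list(points = unname(apply(s, 1, c, simplify = FALSE)),
                          length_px = attr(s, "length_px")),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_streamlines
#' @export
read_streamlines <- function(path) {
  lapply(readLines(path), function(l) {
    o <- jsonlite::fromJSON(l)
    pts <- if (is.matrix(o$points)) o$points
           else matrix(unlist(o$points), ncol = 2, byrow = TRUE)
    dimnames(pts) <- list(NULL, c("x", "y"))
    attr(pts, "length_px") <- o$length_px
    pts
  })
}

#' Serialize / load an affine transform as JSON
#'
#' Row-vector convention and 0-based pixel-center coordinates, as used
#' throughout the package.
#'
#' @param tf an [affine_transform()].
#' @param path JSON path.
#' @param meta optional fixed/moving grid metadata.
#' @return `path` invisibly / the transform.
#' @export
write_affine <- function(tf, path, meta = list()) {
  stopifnot(inherits(tf, "affine_transform"))
  jsonlite::write_json(c(list(matrix = tf$matrix, translation = tf$translation,
                              rotational_component = tf$rotational_component,
                              convention = "x_fixed = matrix %*% x_moving + translation; 0-based pixel centers (x, y)"),
                         meta),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(matrix(unlist(o$matrix), 2, 2), as.numeric(o$translation))
}

#' Read a phantom description from YAML or JSON
#'
#' Schema: top-level `grid_shape` (3 integers), optional `lateral_pixel_um`,
#' `axial_pixel_um`, `wavelength_um`, `background_mu_s`, and `regions`, a
#' list of objects with `geometry` (`box`/`cylinder`), geometry fields
#' (`x`, `y`, `z` ranges or `point`/`direction`/`radius`), `mu_s`,
#' `birefringence`, `axis_deg`, `through_plane_deg`.
#'
#' @param path `.yaml`/`.yml`/`.json` file.
#' @return a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("grid_shape", "lateral_pixel_um", "axial_pixel_um",
               "wavelength_um", "background_mu_s", "regions")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown phantom config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  regions <- lapply(cfg$regions %||% list(), function(r) {
    do.call(region, r)
  })
  phantom_spec(grid_shape = unlist(cfg$grid_shape),
               lateral_pixel_um = cfg$lateral_pixel_um %||% 10,
               axial_pixel_um = cfg$axial_pixel_um %||% 4.2,
               wavelength_um = cfg$wavelength_um %||% 1.3,
               regions = regions,
               background_mu_s = cfg$background_mu_s %||% 0.5)
}
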