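#' Demonstration fiber phantom
#'
#' A coronal-section-like phantom: two broad myelinated bands with distinct
#' in-plane axes on a weakly scattering background, the minimal geometry
#' that exercises reconstruction, masking, tractography, registration and
#' ROI statistics. Defaults emulate a 6 x 6 mm section sampled at 30 um
#' laterally and 4.2 um axially.
#'
#' @param nx,ny,nz grid size in pixels.
#' @param lateral_pixel_um,axial_pixel_um pixel sizes.
#' @param mu_s_wm white-matter scattering coefficient, mm^-1.
#' @param dn_wm white-matter birefringence.
#' @param mu_s_bg background (gray-matter-like) scattering coefficient.
#' @param axes_deg in-plane axes of the two bands.
#' @return a [phantom_spec()].
#' @export
demo_phantom_spec <- function(nx = 200, ny = 200, nz = 40,
                              lateral_pixel_um = 30, axial_pixel_um = 4.2,
                              mu_s_wm = 8, dn_wm = 4e-4, mu_s_bg = 0.8,
                              axes_deg = c(30, 150)) {
  phantom_spec(
    grid_shape = c(nx, ny, nz),
    lateral_pixel_um = lateral_pixel_um,
    axial_pixel_um = axial_pixel_um,
    background_mu_s = mu_s_bg,
    regions = list(
      region("box", y = c(round(ny * 0.08), round(ny * 0.47)),
             mu_s = mu_s_wm, birefringence = dn_wm, axis_deg = axes_deg[1]),
      region("box", y = c(round(ny * 0.60), round(ny * 0.93)),
             mu_s = mu_s_wm, birefringence = dn_wm, axis_deg = axes_deg[2])))
}

#' Study conditions for the developmental age series
#'
#' Five synthetic "specimens" spanning the first years of life: white-matter
#' scattering coefficient rising roughly tenfold with myelin maturation,
#' birefringence rising with it, and diffusion radial diffusivity falling as
#' myelin restricts cross-fiber water movement (so ADC decreases while FA
#' increases).
#'
#' @return data.frame with one row per age: `age_months`, `mu_s_wm`,
#'   `dn_wm`, `radial_diffusivity`.
#' @export
age_series_conditions <- function() {
  data.frame(age_months = c(3, 6, 15, 50, 54),
             mu_s_wm = c(1.2, 2.0, 4.0, 8.0, 10.0),
             dn_wm = c(1.0e-4, 1.8e-4, 3.0e-4, 4.5e-4, 5.0e-4),
             radial_diffusivity = c(6.5e-4, 6.0e-4, 5.0e-4, 3.8e-4, 3.3e-4))
}

# deterministic polynomial rolling hash over the serialized object,
# for provenance config fingerprints (not cryptographic)
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.default_config <- function() {
  list(phantom = NULL, noise_sd = 0.005, seed = 1,
       tile = list(tile_px = 120, overlap_frac = 0.2),
       recon = list(tail_drop = 4, snr_floor = 0),
       enface = list(bin_deg = 5, depth_range = NULL),
       tract = list(threshold = NULL, step_px = 0.5, seed_spacing_px = 10,
                    min_len_px = 10, max_len_px = 1e4),
       coreg = list(levels = 3, grid_spacing_mm = 0.8),
       roi = list(roi_size_um = 900, n_rois = 24, min_wm_frac = 0.8),
       out_dir = NULL)
}

#' Read a strict pipeline configuration
#'
#' YAML or JSON; unknown keys (at the top level or inside a section) are
#' rejected with an error naming the key — silent misconfiguration is the
#' dominant pipeline failure mode. Omitted keys take package defaults.
#'
#' @param path config file, or NULL for the defaults.
#' @return validated config list.
#' @export
read_config <- function(path = NULL) {
  def <- .default_config()
  if (is.null(path)) return(def)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in c("tile", "recon", "enface", "tract", "coreg", "roi")) {
    if (!is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
      if (length(bad))
        stop(sprintf("unknown config key(s) in '%s': %s", sec,
                     paste(bad, collapse = ", ")), call. = FALSE)
      def[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
    }
  }
  for (k in c("phantom", "noise_sd", "seed", "out_dir"))
    if (!is.null(cfg[[k]])) def[[k]] <- cfg[[k]]
  def
}

#' Run the full synthetic PSOCT / dMRI analysis pipeline
#'
#' Chains every stage on one phantom: tiled dual-channel simulation,
#' per-tile reconstruction and en-face collapse, mosaic stitching, tissue
#' and white-matter masking, orientation-field tractography, matched
#' dMRI-style map generation, affine co-registration and vector
#' reorientation, ROI extraction and PSOCT-dMRI statistics. Fully
#' deterministic for a fixed `seed`. When `out_dir` is set, maps,
#' streamlines, the transform, the ROI table (CSV), a statistics report and
#' a provenance record (config hash, seed, package version, stage timings)
#' are written there.
#'
#' @param config list from [read_config()] (NULL for defaults).
#' @param seed overrides the config seed when given.
#' @return list with `mosaic` (parameter maps), `masks`, `streamlines`,
#'   `dmri`, `transform`, `roi_table`, `stats` and `provenance`.
#' @export
run_pipeline <- function(config = NULL, seed = NULL) {
  cfg <- config %||% .default_config()
  if (!is.null(seed)) cfg$seed <- seed
  spec <- cfg$phantom %||% demo_phantom_spec()
  if (is.character(spec)) spec <- read_phantom_spec(spec)
  timings <- c()
  tic <- function() Sys.time()
  lap <- function(t0, nm) {
    timings[nm] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  t0 <- tic()
  acq <- simulate_tiled_acquisition(spec, tile_px = cfg$tile$tile_px,
                                    overlap_frac = cfg$tile$overlap_frac,
                                    noise_sd = cfg$noise_sd, seed = cfg$seed)
  lap(t0, "simulate")

  t0 <- tic()
  tiles <- lapply(acq$tiles, function(t) {
    rec <- reconstruct_volume(t$ascan, snr_floor = cfg$recon$snr_floor,
                              tail_drop = cfg$recon$tail_drop)
    enface_stack(rec, depth_range = cfg$enface$depth_range,
                 bin_deg = cfg$enface$bin_deg)
  })
  lap(t0, "reconstruct")

  t0 <- tic()
  layout <- tile_layout(tiles, lapply(acq$tiles, `[[`, "offset"),
                        overlap_frac = acq$overlap_frac)
  mosaic <- stitch(layout)
  lap(t0, "stitch")

  t0 <- tic()
  tissue <- make_masks(mosaic$mu_s_map, method = "otsu", keep_largest = FALSE)
  wm <- build_mask_from_retardance(mosaic$retardance_map,
                                   threshold = cfg$tract$threshold)
  mosaic$masks <- list(tissue = tissue, wm = wm)
  lap(t0, "mask")

  t0 <- tic()
  field <- orientation_field(mosaic$orientation_map, wm, mosaic$pixel_um)
  seeds <- seed_grid(wm, cfg$tract$seed_spacing_px)
  streamlines <- track(field, seeds, step_px = cfg$tract$step_px,
                       min_len_px = cfg$tract$min_len_px,
                       max_len_px = cfg$tract$max_len_px)
  lap(t0, "track")

  t0 <- tic()
  dmri <- simulate_dmri_maps(acq$truth, spec,
                             grid_spacing_mm = cfg$coreg$grid_spacing_mm)
  tf <- register_affine(mosaic$mu_s_map, dmri$adc, levels = cfg$coreg$levels,
                        fixed_px_um = spec$lateral_pixel_um,
                        moving_px_um = dmri$grid_spacing_mm * 1000)
  target <- dim(mosaic$mu_s_map)
  adc_r <- resample_map(dmri$adc, tf, target)
  fa_r <- resample_map(dmri$fa, tf, target)
  reo <- reorient_and_project(dmri$principal_dir, tf, valid = dmri$valid)
  theta_r <- resample_map(reo$angle_deg, tf, target, interpolation = "nearest")
  lap(t0, "register")

  t0 <- tic()
  rois <- place_rois(wm, roi_size_um = cfg$roi$roi_size_um,
                     pixel_um = mosaic$pixel_um, n_rois = cfg$roi$n_rois,
                     min_wm_frac = cfg$roi$min_wm_frac, seed = cfg$seed)
  roi_table <- extract_roi_table(mosaic,
                                 list(adc = adc_r, fa = fa_r, theta = theta_r),
                                 rois)
  ang_diff <- angular_difference(roi_table$circ_mean_theta_psoct,
                                 roi_table$circ_mean_theta_dmri)
  stats <- list(
    wm_mu_s = wm_summary(mosaic$mu_s_map, wm),
    wm_retardance = wm_summary(mosaic$retardance_map, wm),
    dice_tissue = dice(tissue, is.finite(adc_r)),
    dice_wm = dice(wm, is.finite(fa_r) & fa_r > 0.2),
    median_angular_difference = stats::median(ang_diff, na.rm = TRUE),
    n_streamlines = length(streamlines),
    n_rois = nrow(roi_table))
  lap(t0, "roistats")

  prov <- list(config_hash = .config_hash(cfg), seed = cfg$seed,
               package_version = as.character(utils::packageVersion("psoctr")),
               timings_s = as.list(timings))
  out <- list(mosaic = mosaic, masks = mosaic$masks,
              streamlines = streamlines, dmri = dmri, transform = tf,
              roi_table = roi_table, angular_differences = ang_diff,
              stats = stats, provenance = prov)
  if (!is.null(cfg$out_dir)) .write_pipeline_artifacts(out, cfg)
  out
}

.write_pipeline_artifacts <- function(res, cfg) {
  d <- cfg$out_dir
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  px <- res$mosaic$pixel_um
  write_map(res$mosaic$mu_s_map, file.path(d, "mu_s.tif"), px)
  write_map(res$mosaic$retardance_map, file.path(d, "retardance.tif"), px)
  write_map(res$mosaic$orientation_map, file.path(d, "orientation.tif"), px)
  write_map(res$masks$wm * 1, file.path(d, "wm_mask.tif"), px)
  write_orientation_png(res$mosaic$orientation_map,
                        file.path(d, "orientation_preview.png"),
                        weight = res$mosaic$retardance_map)
  write_streamlines(res$streamlines, file.path(d, "streamlines.ndjson"))
  write_affine(res$transform, file.path(d, "transform.json"))
  utils::write.csv(res$roi_table, file.path(d, "roi_table.csv"),
                   row.names = FALSE)
  polar_histogram(res$angular_differences[is.finite(res$angular_differences)],
                  bin_deg = 10, file = file.path(d, "angular_difference.png"))
  jsonlite::write_json(res$stats, file.path(d, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$provenance, file.path(d, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(d)
}

#' Simulate and analyze the developmental age series
#'
#' One phantom per row of [age_series_conditions()], each run through
#' simulation, reconstruction, en-face collapse, white-matter masking,
#' dMRI-map generation and ROI extraction on its own seed stream. ROI tables
#' are pooled for cross-age correlation, the desk-scale analogue of
#' correlating optical and diffusion parameters across specimens of
#' different ages.
#'
#' @param conditions data.frame like [age_series_conditions()].
#' @param seed base seed; age k uses `seed + k`.
#' @param noise_sd channel noise amplitude.
#' @param n_rois ROIs per age.
#' @param nx,ny,nz,lateral_pixel_um phantom geometry shared across ages.
#' @return list with `pooled` (data.frame of ROI rows + age), `per_age`
#'   tables and `correlations` (`r_mu_s_adc`, `r_retardance_fa`,
#'   `r_mu_s_fa`, `r_retardance_adc`).
#' @export
simulate_age_series <- function(conditions = age_series_conditions(),
                                seed = 1, noise_sd = 0.005, n_rois = 24,
                                nx = 200, ny = 200, nz = 40,
                                lateral_pixel_um = 30) {
  per_age <- list()
  for (k in seq_len(nrow(conditions))) {
    cond <- conditions[k, ]
    spec <- demo_phantom_spec(nx = nx, ny = ny, nz = nz,
                              lateral_pixel_um = lateral_pixel_um,
                              mu_s_wm = cond$mu_s_wm, dn_wm = cond$dn_wm)
    sim <- simulate_volume(spec, noise_sd = noise_sd, seed = seed + k)
    rec <- reconstruct_volume(sim$ascan, tail_drop = 4)
    maps <- enface_stack(rec)
    wm_true <- apply(sim$truth$birefringence > 0, c(1, 2), any)
    dmri <- simulate_dmri_maps(sim$truth, spec,
                               radial_diffusivity = cond$radial_diffusivity)
    ratio <- dmri$grid_spacing_mm * 1000 / lateral_pixel_um
    tf <- affine_transform(diag(2) * ratio, c((ratio - 1) / 2, (ratio - 1) / 2))
    target <- dim(maps$mu_s_map)
    reo <- reorient_and_project(dmri$principal_dir, tf, valid = dmri$valid)
    dmri_maps <- list(adc = resample_map(dmri$adc, tf, target),
                      fa = resample_map(dmri$fa, tf, target),
                      theta = resample_map(reo$angle_deg, tf, target,
                                           interpolation = "nearest"))
    rois <- place_rois(wm_true, roi_size_um = 900,
                       pixel_um = lateral_pixel_um, n_rois = n_rois,
                       min_wm_frac = 0.8, seed = seed + k)
    tab <- extract_roi_table(maps, dmri_maps, rois)
    tab$age_months <- cond$age_months
    per_age[[k]] <- tab
  }
  pooled <- do.call(rbind, per_age)
  correlations <- list(
    r_mu_s_adc = pearson(pooled$mean_mu_s, pooled$mean_adc),
    r_retardance_fa = pearson(pooled$mean_retardance, pooled$fa),
    r_mu_s_fa = pearson(pooled$mean_mu_s, pooled$fa),
    r_retardance_adc = pearson(pooled$mean_retardance, pooled$mean_adc))
  list(pooled = pooled, per_age = per_age, correlations = correlations)
}
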