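#' Parameters for a synthetic is-PLA acquisition
#'
#' Builds the parameter set describing one automated acquisition: the xy
#' field grid, z sampling, the three fluorescence channels (DAPI for DNA,
#' FITC for alpha-tubulin, TRITC for PLA amplification products), the cell
#' population, and the camera noise model. Defaults emulate a 40x widefield
#' acquisition of HeLa cultures: an asynchronous culture has a small mitotic
#' fraction, while a mitosis-enriched (synchronized and released) culture is
#' dominated by mitotic figures. The importazole (IPZ) condition reduces the
#' expected per-cell PLA puncta count by `ipz_puncta_fold_reduction` without
#' changing puncta placement.
#'
#' All intensity scales are in arbitrary camera units on a 16-bit range; the
#' simulator makes no claim of photometric realism, only of the contrasts the
#' downstream segmentation relies on (mitotic chromosome masses brighter and
#' less round than interphase nuclei; spindles bright and compact in the
#' tubulin channel).
#'
#' @param field_grid_count Number of xy fields in the acquisition grid.
#' @param z_planes Number of z planes per field.
#' @param image_size_px Integer pair, image width and height in pixels.
#' @param pixel_size_um Pixel size in micrometres.
#' @param cells_per_field Integer range (length 2): cells drawn uniformly
#'   per field.
#' @param mitotic_fraction Probability that a cell is mitotic. Around
#'   0.05-0.08 for an asynchronous culture; >= 0.5 for a mitosis-enriched one.
#' @param condition `"CTR"` (untreated) or `"IPZ"` (importazole-treated).
#' @param ipz_puncta_fold_reduction Expected fold reduction of per-cell
#'   puncta counts under IPZ; must be >= 1.
#' @param noise List with elements `photon` (logical; Poisson shot noise),
#'   `read_sd` (Gaussian read-noise standard deviation, a.u.) and
#'   `background` (named per-channel background level, a.u.).
#' @param intensity List of intensity scales (a.u.) and puncta rates; see
#'   the default for the full set of fields.
#' @param geometry List of object geometry parameters in pixels.
#' @param rng_seed Integer seed controlling every random draw.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(field_grid_count = 60L,
                         z_planes = 10L,
                         image_size_px = c(256L, 256L),
                         pixel_size_um = 0.325,
                         cells_per_field = c(4L, 8L),
                         mitotic_fraction = 0.06,
                         condition = c("CTR", "IPZ"),
                         ipz_puncta_fold_reduction = 4,
                         noise = list(photon = TRUE, read_sd = 10,
                                      background = c(DAPI = 600, FITC = 500, TRITC = 200)),
                         intensity = list(
                           interphase_dapi_peak_meanlog = log(8000), interphase_dapi_peak_sdlog = 0.12,
                           mitotic_dapi_peak_meanlog = log(20000), mitotic_dapi_peak_sdlog = 0.12,
                           spindle_fitc_peak_meanlog = log(15000), spindle_fitc_peak_sdlog = 0.15,
                           interphase_fitc_haze_frac = 0.08,
                           puncta_meanlog = log(1e5), puncta_sdlog = 0.35,
                           puncta_rate_mitotic = 12, puncta_rate_interphase = 3),
                         geometry = list(
                           nucleus_radius_px_mean = 21, nucleus_radius_px_sd = 2.5,
                           nucleus_axis_ratio = c(0.85, 1.0),
                           chromosome_radius_px_mean = 14, chromosome_radius_px_sd = 2,
                           chromosome_axis_ratio = c(0.35, 0.55),
                           chromosome_lobes = c(2L, 4L),
                           spindle_radius_px_mean = 26, spindle_radius_px_sd = 3,
                           spindle_axis_ratio = c(0.45, 0.6),
                           min_separation_px = 8),
                         rng_seed = 1L) {
  condition <- match.arg(condition)
  p <- list(field_grid_count = as.integer(field_grid_count),
            z_planes = as.integer(z_planes),
            channels = c("DAPI", "FITC", "TRITC"),
            image_size_px = as.integer(image_size_px),
            pixel_size_um = pixel_size_um,
            cells_per_field = as.integer(cells_per_field),
            mitotic_fraction = mitotic_fraction,
            condition = condition,
            ipz_puncta_fold_reduction = ipz_puncta_fold_reduction,
            noise = noise, intensity = intensity, geometry = geometry,
            rng_seed = as.integer(rng_seed))
  validate_scene_params(p)
  class(p) <- "scene_params"
  p
}

validate_scene_params <- function(p) {
  stopifnot(p$field_grid_count >= 1L, p$z_planes >= 1L,
            length(p$channels) == 3L,
            length(p$image_size_px) == 2L, all(p$image_size_px >= 16L),
            p$pixel_size_um > 0,
            length(p$cells_per_field) == 2L, all(p$cells_per_field >= 0L),
            p$cells_per_field[1] <= p$cells_per_field[2],
            p$mitotic_fraction >= 0, p$mitotic_fraction <= 1,
            p$condition %in% c("CTR", "IPZ"),
            p$ipz_puncta_fold_reduction >= 1,
            is.numeric(p$noise$read_sd), p$noise$read_sd >= 0,
            length(p$noise$background) == 3L, all(p$noise$background >= 0))
  invisible(p)
}

#' Modify a scene parameter set
#'
#' Convenience wrapper: replaces top-level fields of an existing
#' `scene_params` object and re-validates.
#'
#' @param params A `scene_params` object.
#' @param ... Named top-level fields to replace.
#' @return The modified `scene_params` object.
#' @export
update_scene_params <- function(params, ...) {
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(params)) stop("unknown scene parameter: ", nm)
    params[[nm]] <- dots[[nm]]
  }
  if (!is.null(dots$field_grid_count)) params$field_grid_count <- as.integer(params$field_grid_count)
  if (!is.null(dots$z_planes)) params$z_planes <- as.integer(params$z_planes)
  if (!is.null(dots$cells_per_field)) params$cells_per_field <- as.integer(params$cells_per_field)
  if (!is.null(dots$rng_seed)) params$rng_seed <- as.integer(params$rng_seed)
  validate_scene_params(params)
  params
}
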