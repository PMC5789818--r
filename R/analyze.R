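#' Default configuration for the is-PLA imaging analysis
#'
#' Bundles the projection, background-subtraction, segmentation,
#' classification and measurement settings used by [analyze_stack()].
#' Intensity thresholds default to Otsu's method per channel; the size and
#' circularity ranges and the mitotic classifier cutoffs were calibrated
#' once against the synthetic-scene generator and are stored here as the
#' package defaults. All values can be overridden.
#'
#' @param background List: `method`, plus method parameters of
#'   [subtract_background()].
#' @param dapi [segmentation_params()] for DAPI objects (nuclei and
#'   chromosome masses segmented together, then classified).
#' @param spindle [segmentation_params()] for tubulin spindles.
#' @param classifier [classifier_params()].
#' @param pla_selection Mask selection for the PLA readout, see
#'   [measure_pla()].
#' @param measure_on `"subtracted"` (default) or `"raw"`: whether PLA sum
#'   intensities are taken on the background-subtracted or raw projection.
#' @return A list of class `imaging_config`.
#' @export
imaging_config <- function(background = list(method = "percentile", p = 50),
                           dapi = segmentation_params("DAPI", threshold = "otsu",
                                                      min_area_px = 150,
                                                      max_area_px = 20000),
                           spindle = segmentation_params("FITC", threshold = "otsu",
                                                         min_area_px = 150,
                                                         max_area_px = 20000,
                                                         min_circularity = 0.3),
                           classifier = classifier_params(),
                           pla_selection = "union",
                           measure_on = c("subtracted", "raw")) {
  measure_on <- match.arg(measure_on)
  structure(list(background = background, dapi = dapi, spindle = spindle,
                 classifier = classifier, pla_selection = pla_selection,
                 measure_on = measure_on),
            class = "imaging_config")
}

#' Analyze one field of an acquisition
#'
#' Projects the field (maximum intensity over z), subtracts background,
#' segments DAPI objects and spindles, classifies interphase versus mitotic
#' cells, and measures per-cell PLA sum intensities. Mitotic cells are
#' measured on the configured selection (default: union of chromosome and
#' linked-spindle masks); interphase cells on their nuclear mask.
#'
#' @param stack An `image_stack`.
#' @param field Field index.
#' @param config An [imaging_config()].
#' @return List with `records` (per-cell data frame including
#'   `pla_sum_intensity` and `field`), `cell_set`, and the projections.
#' @export
analyze_field <- function(stack, field, config = imaging_config()) {
  proj <- max_intensity_projection(stack, field)
  bgargs <- config$background
  sub <- do.call(subtract_background, c(list(img = proj), bgargs))
  dapi_mask <- segment_category(sub, config$dapi, "dapi")
  spindle_mask <- segment_category(sub, config$spindle, "spindle")
  cs <- classify_cells(dapi_mask, spindle_mask, params = config$classifier)
  pla_img <- if (config$measure_on == "subtracted") sub else proj
  if (nrow(cs$cells)) {
    mit <- cs$cells$cell_id[cs$cells$class == "mitotic"]
    intp <- cs$cells$cell_id[cs$cells$class == "interphase"]
    parts <- list()
    if (length(mit)) {
      parts[[1]] <- measure_pla(pla_img, cs, config$pla_selection, cell_ids = mit)
    }
    if (length(intp)) {
      parts[[length(parts) + 1L]] <- measure_pla(pla_img, cs, "nucleus",
                                                 cell_ids = intp)
    }
    records <- do.call(rbind, parts)
    records <- records[order(records$cell_id), , drop = FALSE]
  } else {
    records <- cs$cells
    records$pla_sum_intensity <- numeric(0)
  }
  records$field <- rep(field, nrow(records))
  rownames(records) <- NULL
  list(records = records, cell_set = cs, projection = proj, subtracted = sub)
}

#' Analyze every field of an acquisition
#'
#' Runs [analyze_field()] over all fields and concatenates the per-cell
#' records, renumbering `cell_id` to be unique across the acquisition. The
#' result is independent of field processing order.
#'
#' @param stack An `image_stack`.
#' @param config An [imaging_config()].
#' @param fields Field indices to analyze (default all).
#' @return Data frame of per-cell records.
#' @export
analyze_stack <- function(stack, config = imaging_config(),
                          fields = seq_len(n_fields(stack))) {
  recs <- lapply(fields, function(f) analyze_field(stack, f, config)$records)
  out <- do.call(rbind, recs)
  if (nrow(out)) out$cell_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write per-cell records as a tab-separated table
#'
#' @param records Data frame from [analyze_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
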