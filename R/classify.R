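#' Classifier parameters for interphase vs mitotic DAPI objects
#'
#' A DAPI object is called mitotic when its peak intensity exceeds
#' `mitotic_peak_min` *and* its circularity is below `mitotic_circ_max`
#' (condensed chromosome masses are brighter and less round than interphase
#' nuclei), or when it overlaps a phospho-histone-H3-positive mask. The
#' defaults were calibrated once against the synthetic-scene generator's
#' intensity scales and are expressed in background-subtracted a.u. The
#' circularity ceiling is deliberately permissive: under the
#' corrected-chain perimeter estimator, digitised round nuclei measure at
#' (or clamp to) 1 while defocus smoothing can raise lobed chromosome
#' masses to ~0.99, so the ceiling mainly excludes ideal disks and the
#' intensity floor carries most of the discrimination.
#'
#' @param mitotic_peak_min Peak-intensity floor for the mitotic call (a.u.).
#' @param mitotic_circ_max Circularity ceiling for the mitotic call.
#' @param link_dist_factor A spindle is linkable to a chromosome mass if
#'   their centroid distance is at most this factor times the mean spindle
#'   major-axis length.
#' @return A list of class `classifier_params`.
#' @export
classifier_params <- function(mitotic_peak_min = 13000,
                              mitotic_circ_max = 0.98,
                              link_dist_factor = 1.5) {
  structure(list(mitotic_peak_min = mitotic_peak_min,
                 mitotic_circ_max = mitotic_circ_max,
                 link_dist_factor = link_dist_factor),
            class = "classifier_params")
}

#' Classify DAPI objects into interphase and mitotic cells
#'
#' Applies the intensity/circularity rule of [classifier_params()] (with an
#' optional pH3 override) to every object of a DAPI segmentation mask, then
#' links each mitotic object to at most one spindle by greedy one-to-one
#' assignment on centroid distance, restricted to pairs closer than
#' `link_dist_factor` times the mean spindle major axis. Distance ties are
#' broken deterministically towards the lowest spindle label.
#'
#' @param dapi_mask `labeled_mask` of DAPI objects (nuclei + chromosome
#'   masses).
#' @param spindle_mask Optional `labeled_mask` of spindles (FITC/tubulin).
#' @param ph3_mask Optional `labeled_mask` of pH3-positive figures; any DAPI
#'   object overlapping it is called mitotic regardless of the
#'   intensity/circularity rule.
#' @param params A [classifier_params()] object.
#' @return A `cell_set`: list with `cells` (one row per cell: `cell_id`,
#'   `class`, `dapi_label`, `spindle_label`, centroid, shape and intensity
#'   features), `unlinked_spindles` (labels), and the input masks.
#' @export
classify_cells <- function(dapi_mask, spindle_mask = NULL, ph3_mask = NULL,
                           params = classifier_params()) {
  f <- dapi_mask$features
  n <- nrow(f)
  mitotic <- logical(n)
  if (n) {
    mitotic <- f$peak_intensity > params$mitotic_peak_min &
      f$circularity < params$mitotic_circ_max
    if (!is.null(ph3_mask)) {
      for (i in seq_len(n)) {
        sel <- dapi_mask$labels == f$label[i]
        if (any(ph3_mask$labels[sel] > 0L)) mitotic[i] <- TRUE
      }
    }
  }
  cells <- data.frame(cell_id = seq_len(n),
                      class = ifelse(mitotic, "mitotic", "interphase"),
                      dapi_label = f$label, spindle_label = NA_integer_,
                      cx = f$cx, cy = f$cy,
                      area = f$area, circularity = f$circularity,
                      mean_dapi = f$mean_intensity, peak_dapi = f$peak_intensity)

  unlinked <- integer(0)
  if (!is.null(spindle_mask) && nrow(spindle_mask$features)) {
    sf <- spindle_mask$features
    link_max <- params$link_dist_factor * mean(sf$major_axis)
    mit_idx <- which(cells$class == "mitotic")
    if (length(mit_idx)) {
      pairs <- expand.grid(ci = mit_idx, si = seq_len(nrow(sf)))
      pairs$dist <- sqrt((cells$cx[pairs$ci] - sf$cx[pairs$si])^2 +
                         (cells$cy[pairs$ci] - sf$cy[pairs$si])^2)
      pairs <- pairs[pairs$dist <= link_max, , drop = FALSE]
      pairs <- pairs[order(pairs$dist, sf$label[pairs$si], cells$cell_id[pairs$ci]), ,
                     drop = FALSE]
      taken_c <- logical(nrow(cells)); taken_s <- logical(nrow(sf))
      for (k in seq_len(nrow(pairs))) {
        ci <- pairs$ci[k]; si <- pairs$si[k]
        if (!taken_c[ci] && !taken_s[si]) {
          cells$spindle_label[ci] <- sf$label[si]
          taken_c[ci] <- TRUE; taken_s[si] <- TRUE
        }
      }
      unlinked <- sf$label[!taken_s]
    } else {
      unlinked <- sf$label
    }
  }
  structure(list(cells = cells, unlinked_spindles = unlinked,
                 dapi_mask = dapi_mask, spindle_mask = spindle_mask,
                 params = params),
            class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  cat("cell_set:", nrow(x$cells), "cells (",
      sum(x$cells$class == "mitotic"), "mitotic,",
      sum(!is.na(x$cells$spindle_label)), "with linked spindle );",
      length(x$unlinked_spindles), "unlinked spindles\n")
  invisible(x)
}
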