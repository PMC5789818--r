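#' Evaluate cell detections against the simulator's ground truth
#'
#' Matches detected cell records to ground-truth cells by the
#' centroid-in-mask rule: a detection is eligible for a truth cell when its
#' centroid falls inside the truth object's analytic shape (the nucleus for
#' an interphase cell, the chromosome mass for a mitotic one). Eligible
#' pairs are assigned one-to-one greedily by centroid distance, per field.
#' Coverage is `100 * matched / truth_count` and precision (the complement
#' of the false-positive fraction among detections) is
#' `100 * matched / detection_count`.
#'
#' @param records Data frame of detections with columns `field`, `class`,
#'   `cx`, `cy` (e.g. from [analyze_stack()]).
#' @param scene The `ground_truth_scene` the stack was rendered from.
#' @return An `evaluation_result`: coverage and precision (with across-field
#'   standard deviations), per-class matched/missed/spurious counts, and the
#'   fraction of matched detections whose interphase/mitotic call agrees
#'   with the truth.
#' @export
evaluate_segmentation <- function(records, scene) {
  truth_cells <- scene$cells
  ## the truth mask of a cell: its DAPI object (nucleus or chromosome mass)
  truth_obj <- scene$objects[scene$objects$channel == "DAPI", , drop = FALSE]
  truth_obj <- truth_obj[match(truth_cells$cell_id, truth_obj$cell_id), , drop = FALSE]

  per_field <- lapply(sort(unique(c(records$field, truth_cells$field))), function(fld) {
    det <- records[records$field == fld, , drop = FALSE]
    tr <- truth_cells[truth_cells$field == fld, , drop = FALSE]
    to <- truth_obj[truth_obj$field == fld, , drop = FALSE]
    n_det <- nrow(det); n_tr <- nrow(tr)
    if (n_det == 0L || n_tr == 0L) {
      return(data.frame(field = fld, truth = n_tr, detections = n_det,
                        matched = 0L, class_agree = 0L))
    }
    pairs <- expand.grid(di = seq_len(n_det), ti = seq_len(n_tr))
    inside <- mapply(function(di, ti) {
      truth_object_contains(scene, to$object_id[ti], det$cx[di], det$cy[di])
    }, pairs$di, pairs$ti)
    pairs <- pairs[inside, , drop = FALSE]
    pairs$dist <- sqrt((det$cx[pairs$di] - tr$cx[pairs$ti])^2 +
                       (det$cy[pairs$di] - tr$cy[pairs$ti])^2)
    pairs <- pairs[order(pairs$dist, pairs$ti, pairs$di), , drop = FALSE]
    used_d <- logical(n_det); used_t <- logical(n_tr)
    matched <- 0L; agree <- 0L
    for (k in seq_len(nrow(pairs))) {
      di <- pairs$di[k]; ti <- pairs$ti[k]
      if (!used_d[di] && !used_t[ti]) {
        used_d[di] <- used_t[ti] <- TRUE
        matched <- matched + 1L
        if (det$class[di] == tr$class[ti]) agree <- agree + 1L
      }
    }
    data.frame(field = fld, truth = n_tr, detections = n_det,
               matched = matched, class_agree = agree)
  })
  pf <- do.call(rbind, per_field)
  total_truth <- sum(pf$truth); total_det <- sum(pf$detections)
  matched <- sum(pf$matched)
  cov_f <- with(pf[pf$truth > 0, , drop = FALSE], 100 * matched / truth)
  prec_f <- with(pf[pf$detections > 0, , drop = FALSE], 100 * matched / detections)
  structure(list(
    coverage_pct = if (total_truth) 100 * matched / total_truth else NA_real_,
    coverage_sd = stats::sd(cov_f),
    precision_pct = if (total_det) 100 * matched / total_det else NA_real_,
    precision_sd = stats::sd(prec_f),
    matched = matched, missed = total_truth - matched,
    spurious = total_det - matched,
    truth_count = total_truth, detection_count = total_det,
    class_agreement_pct = if (matched) 100 * sum(pf$class_agree) / matched else NA_real_,
    per_field = pf),
    class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation: coverage %.1f%% (sd %.1f), precision %.1f%% (sd %.1f);\n",
              x$coverage_pct, x$coverage_sd, x$precision_pct, x$precision_sd))
  cat(sprintf("  matched %d / truth %d, spurious %d; class agreement %.1f%%\n",
              x$matched, x$truth_count, x$spurious, x$class_agreement_pct))
  invisible(x)
}
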