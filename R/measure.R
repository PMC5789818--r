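#' Per-cell PLA sum intensity within segmentation masks
#'
#' Sums the PLA (TRITC) channel over the pixels of the requested mask
#' selection for each cell: `"nucleus"` (interphase nuclear mask),
#' `"chromosomes"` (mitotic chromosome mask), `"spindle"` (linked spindle
#' mask), or `"union"` (all masks belonging to the cell: nucleus for
#' interphase, chromosomes plus linked spindle for mitotic — the default
#' mitotic readout). Requesting a selection a cell's class cannot provide
#' (e.g. a spindle for an interphase cell) is an error. The measurement is
#' additive over disjoint masks and monotone under mask inclusion.
#'
#' @param pla_img A `projected_image` (or plain matrix) carrying the PLA
#'   channel; if a `projected_image`, its `"TRITC"` channel is used.
#' @param cell_set A `cell_set` from [classify_cells()].
#' @param selection `"union"`, `"nucleus"`, `"chromosomes"` or `"spindle"`.
#' @param cell_ids Cells to measure (default: all in the set).
#' @return The `cell_set$cells` data frame restricted to `cell_ids`, with a
#'   `pla_sum_intensity` column appended.
#' @export
measure_pla <- function(pla_img, cell_set, selection = c("union", "nucleus",
                                                         "chromosomes", "spindle"),
                        cell_ids = NULL) {
  selection <- match.arg(selection)
  m <- if (inherits(pla_img, "projected_image")) {
    channel_matrix(pla_img, "TRITC")
  } else pla_img
  cells <- cell_set$cells
  if (is.null(cell_ids)) cell_ids <- cells$cell_id
  rows <- cells[match(cell_ids, cells$cell_id), , drop = FALSE]
  if (anyNA(rows$cell_id)) stop("unknown cell_id requested")
  dapi <- cell_set$dapi_mask$labels
  spin <- if (!is.null(cell_set$spindle_mask)) cell_set$spindle_mask$labels
  sums <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    cls <- rows$class[i]
    sel <- switch(selection,
      nucleus = {
        if (cls != "interphase") stop("selection 'nucleus' is not defined for a ",
                                      cls, " cell (cell_id ", rows$cell_id[i], ")")
        dapi == rows$dapi_label[i]
      },
      chromosomes = {
        if (cls != "mitotic") stop("selection 'chromosomes' is not defined for a ",
                                   cls, " cell (cell_id ", rows$cell_id[i], ")")
        dapi == rows$dapi_label[i]
      },
      spindle = {
        if (cls != "mitotic" || is.na(rows$spindle_label[i])) {
          stop("selection 'spindle' is not available for cell_id ",
               rows$cell_id[i], " (class ", cls, ", no linked spindle mask)")
        }
        spin == rows$spindle_label[i]
      },
      union = {
        s <- dapi == rows$dapi_label[i]
        if (cls == "mitotic" && !is.na(rows$spindle_label[i]) && !is.null(spin)) {
          s <- s | (spin == rows$spindle_label[i])
        }
        s
      })
    sums[i] <- sum(m[sel])
  }
  rows$pla_sum_intensity <- sums
  rownames(rows) <- NULL
  rows
}
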