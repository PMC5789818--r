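#' Per-category segmentation parameters
#'
#' Each segmented category (interphase nuclei, mitotic chromosome masses,
#' spindles) is defined by a channel, an intensity threshold and admissible
#' area and circularity ranges. `threshold = "otsu"` picks the threshold
#' automatically by Otsu's method on the channel histogram; a numeric value
#' is used as an absolute cutoff in a.u.
#'
#' @param channel Channel name the category is segmented on.
#' @param threshold `"otsu"` or a numeric intensity cutoff (a.u.).
#' @param min_area_px,max_area_px Admissible object area range (px^2).
#' @param min_circularity,max_circularity Admissible circularity range.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(channel, threshold = "otsu",
                                min_area_px = 1, max_area_px = Inf,
                                min_circularity = 0, max_circularity = 1) {
  stopifnot(min_area_px >= 1, max_area_px >= min_area_px,
            min_circularity >= 0, max_circularity >= min_circularity,
            max_circularity <= 1)
  structure(list(channel = channel, threshold = threshold,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 min_circularity = min_circularity,
                 max_circularity = max_circularity),
            class = "segmentation_params")
}

## Otsu threshold on a matrix of 16-bit counts
otsu_threshold <- function(m) {
  EBImage::otsu(EBImage::Image(m / 65535), range = c(0, 1), levels = 256L) * 65535
}

#' Segment one object category from a projected image
#'
#' Thresholds the category's channel, labels 8-connected components, and
#' retains components whose area and circularity (`4*pi*A/P^2` with the
#' contour-chain perimeter of [mask_perimeter()]) fall within the
#' configured ranges. An empty result is valid.
#'
#' @param img A `projected_image` (normally background-subtracted).
#' @param params A [segmentation_params()] object.
#' @param category Category name stored with the mask.
#' @return A `labeled_mask`: list with `labels` (integer matrix, 0 =
#'   background), `category`, `features` (per-label area, circularity,
#'   centroid, mean/peak source intensity) and the threshold used.
#' @export
segment_category <- function(img, params, category) {
  m <- channel_matrix(img, params$channel)
  thr <- if (identical(params$threshold, "otsu")) otsu_threshold(m) else params$threshold
  bw <- m > thr
  lab <- label_components_8(bw)
  feats <- label_features(lab, m)
  keep <- feats$area >= params$min_area_px & feats$area <= params$max_area_px &
    feats$circularity >= params$min_circularity &
    feats$circularity <= params$max_circularity
  feats <- feats[keep, , drop = FALSE]
  ## relabel survivors 1..n, preserving raster order
  new_lab <- matrix(0L, nrow(lab), ncol(lab))
  if (nrow(feats)) {
    for (i in seq_len(nrow(feats))) new_lab[lab == feats$label[i]] <- i
    feats$label <- seq_len(nrow(feats))
  }
  rownames(feats) <- NULL
  structure(list(labels = new_lab, category = category, features = feats,
                 threshold = thr, params = params),
            class = "labeled_mask")
}

## 8-connected component labelling: 4-connected pass first, then diagonal
## adjacencies merged by union-find over the (few) label pairs
label_components_8 <- function(bw) {
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(bw != 0)))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

## per-label area, circularity, centroid and intensity statistics
label_features <- function(lab, intensity = NULL) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) {
    return(data.frame(label = integer(), area = numeric(),
                      circularity = numeric(), cx = numeric(), cy = numeric(),
                      major_axis = numeric(),
                      mean_intensity = numeric(), peak_intensity = numeric()))
  }
  res <- lapply(ids, function(id) {
    sel <- lab == id
    idx <- which(sel, arr.ind = TRUE)
    ## full major-axis length from the principal second moment (4 sigma,
    ## exact for a filled ellipse)
    major <- if (nrow(idx) > 1L) {
      ev <- eigen(stats::cov(idx), symmetric = TRUE, only.values = TRUE)$values
      4 * sqrt(max(ev[1], 0))
    } else 1
    data.frame(label = id, area = nrow(idx),
               circularity = mask_circularity(sel),
               cx = mean(idx[, 1]), cy = mean(idx[, 2]),
               major_axis = major,
               mean_intensity = if (is.null(intensity)) NA_real_ else mean(intensity[sel]),
               peak_intensity = if (is.null(intensity)) NA_real_ else max(intensity[sel]))
  })
  do.call(rbind, res)
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat("labeled_mask [", x$category, "]:", nrow(x$features),
      "objects, threshold", round(x$threshold, 1), "a.u.\n")
  invisible(x)
}

#' Save / reload a labeled mask as 16-bit label TIFF
#'
#' Labels are stored as 16-bit gray values (label / 65535), so up to 65535
#' objects round-trip exactly; reloading and re-measuring reproduces
#' identical features.
#'
#' @param mask A `labeled_mask`.
#' @param path Output TIFF path.
#' @param category Category to attach on reload.
#' @param intensity Optional intensity matrix to recompute features against.
#' @return `path` invisibly (`write_mask`); a `labeled_mask` (`read_mask`).
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(t(mask$labels) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, category = "unknown", intensity = NULL) {
  lab <- round(t(tiff::readTIFF(path)) * 65535)
  storage.mode(lab) <- "integer"
  structure(list(labels = lab, category = category,
                 features = label_features(lab, intensity),
                 threshold = NA_real_, params = NULL),
            class = "labeled_mask")
}
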