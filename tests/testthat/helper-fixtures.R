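## Shared fixtures: small, fast synthetic scenes and hand-built images.

## a small acquisition for unit tests: one field, modest image, full z
tiny_scene_params <- function(fields = 1L, mitotic_fraction = 0.5,
                              cells = c(2L, 4L), size = 192L, z = 6L,
                              condition = "CTR", seed = 1L, ...) {
  scene_params(field_grid_count = fields, z_planes = z,
               image_size_px = c(size, size), cells_per_field = cells,
               mitotic_fraction = mitotic_fraction, condition = condition,
               rng_seed = seed, ...)
}

noise_free <- function() {
  list(photon = FALSE, read_sd = 0, background = c(DAPI = 0, FITC = 0, TRITC = 0))
}

## build a projected_image from per-channel matrices (DAPI, FITC, TRITC)
make_projected <- function(dapi, fitc = NULL, tritc = NULL) {
  if (is.null(fitc)) fitc <- matrix(0, nrow(dapi), ncol(dapi))
  if (is.null(tritc)) tritc <- matrix(0, nrow(dapi), ncol(dapi))
  arr <- array(0, c(nrow(dapi), ncol(dapi), 3))
  arr[, , 1] <- dapi; arr[, , 2] <- fitc; arr[, , 3] <- tritc
  structure(list(data = arr, channels = c("DAPI", "FITC", "TRITC"),
                 field = 1L, pixel_size_um = 0.325),
            class = "projected_image")
}

## rasterised disk / axis-aligned bar masks
disk_mask <- function(n, cx, cy, r) {
  x <- row(matrix(0, n, n)); y <- col(matrix(0, n, n))
  (x - cx)^2 + (y - cy)^2 <= r^2
}

bar_mask <- function(n, cx, cy, w, h) {
  x <- row(matrix(0, n, n)); y <- col(matrix(0, n, n))
  abs(x - cx) <= w / 2 & abs(y - cy) <= h / 2
}
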