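#' Multi-field, multi-channel z-stack container
#'
#' An `image_stack` holds the rendered (or loaded) acquisition as a 5-D
#' numeric array with dimensions `(x, y, channel, z, field)`, together with
#' channel names and the pixel size. Values are 16-bit camera counts stored
#' as numerics in `[0, 65535]`.
#'
#' @param data 5-D array `(x, y, channel, z, field)`.
#' @param channels Character vector of channel names.
#' @param pixel_size_um Pixel size in micrometres.
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, channels, pixel_size_um) {
  stopifnot(length(dim(data)) == 5L, dim(data)[3] == length(channels))
  structure(list(data = data, channels = channels,
                 pixel_size_um = pixel_size_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d fields x %d z x %d channels (%s), %dx%d px, %.3f um/px\n",
              d[5], d[4], d[3], paste(x$channels, collapse = "/"),
              d[1], d[2], x$pixel_size_um))
  invisible(x)
}

#' Number of fields / z planes in a stack
#' @param stack An `image_stack`.
#' @return Integer count.
#' @export
n_fields <- function(stack) dim(stack$data)[5]

#' @rdname n_fields
#' @export
n_z <- function(stack) dim(stack$data)[4]

## Stamp a diffraction-limited spot: a 2-D Gaussian whose pixel values are
## exact integrals of the normalised Gaussian over pixel squares (via pnorm
## differences), so the stamped flux equals `flux` up to window truncation.
stamp_gaussian <- function(img, x0, y0, sigma, flux) {
  if (flux <= 0) return(img)
  W <- nrow(img); H <- ncol(img)
  r <- ceiling(6 * sigma + 2)
  xs <- max(1L, floor(x0 - r)):min(W, ceiling(x0 + r))
  ys <- max(1L, floor(y0 - r)):min(H, ceiling(y0 + r))
  if (!length(xs) || !length(ys)) return(img)
  px <- stats::pnorm(xs + 0.5, x0, sigma) - stats::pnorm(xs - 0.5, x0, sigma)
  py <- stats::pnorm(ys + 0.5, y0, sigma) - stats::pnorm(ys - 0.5, y0, sigma)
  img[xs, ys] <- img[xs, ys] + flux * outer(px, py)
  img
}

## defocus model: in-focus lateral sigma plus a linear growth with |dz|
## (planes); puncta flux is spread over planes with Gaussian axial weights
## normalised over the acquired range, so total stack flux is conserved.
.render_const <- list(area_sigma0 = 1.0, area_defocus = 1.2,
                      spot_sigma0 = 1.3, spot_defocus = 0.8,
                      spot_axial_sd = 1.2)

#' Render an acquisition stack from a ground-truth scene
#'
#' Rasterises the scene into a `(fields, z, channels, y, x)` stack: DAPI and
#' tubulin objects are drawn as flat-topped shapes at their in-focus plane
#' and Gaussian-blurred with a defocus kernel growing linearly with distance
#' from focus; PLA puncta are diffraction-limited Gaussian spots whose flux
#' is distributed across z with Gaussian axial weights (total rendered flux
#' equals the punctum's integrated intensity in the noise-free limit).
#' Photon (Poisson) noise, Gaussian read noise and per-channel background
#' are then applied and the result is quantised to 16-bit counts. Rendering
#' is deterministic given the scene and its seed.
#'
#' @param scene A `ground_truth_scene`.
#' @param params The [scene_params()] used to build the scene.
#' @return An `image_stack`.
#' @export
render_acquisition <- function(scene, params) {
  validate_scene_params(params)
  W <- params$image_size_px[1]; H <- params$image_size_px[2]
  nz <- params$z_planes; nf <- params$field_grid_count
  zmid <- (nz + 1) / 2
  rc <- .render_const
  ## rendering noise stream decoupled from the scene's draws
  set.seed((scene$seed %% 1000003L) * 2011L + 7L)

  arr <- array(0, dim = c(W, H, 3L, nz, nf))
  bg <- params$noise$background
  haze_peak <- params$intensity$interphase_fitc_haze_frac *
    exp(params$intensity$spindle_fitc_peak_meanlog)

  for (field in seq_len(nf)) {
    base <- list(DAPI = matrix(0, W, H), FITC = matrix(0, W, H))
    objs <- scene$objects[scene$objects$field == field, , drop = FALSE]
    for (i in seq_len(nrow(objs))) {
      shp <- scene$shapes[[objs$object_id[i]]]
      r <- shape_rasterize(shp)
      xs <- r$x0 + seq_len(nrow(r$mask)) - 1L
      ys <- r$y0 + seq_len(ncol(r$mask)) - 1L
      keep_x <- xs >= 1L & xs <= W; keep_y <- ys >= 1L & ys <= H
      ch <- objs$channel[i]
      base[[ch]][xs[keep_x], ys[keep_y]] <-
        base[[ch]][xs[keep_x], ys[keep_y]] +
        objs$peak_intensity[i] * r$mask[keep_x, keep_y]
      ## faint cytoskeletal tubulin haze over interphase cells
      if (objs$class[i] == "interphase_nucleus") {
        e <- shp$parts[[1]]
        hz <- list(type = "ellipse",
                   parts = list(list(cx = e$cx, cy = e$cy, a = 1.8 * e$a,
                                     b = 1.8 * e$b, theta = e$theta)))
        rh <- shape_rasterize(hz)
        xs <- rh$x0 + seq_len(nrow(rh$mask)) - 1L
        ys <- rh$y0 + seq_len(ncol(rh$mask)) - 1L
        keep_x <- xs >= 1L & xs <= W; keep_y <- ys >= 1L & ys <= H
        base$FITC[xs[keep_x], ys[keep_y]] <-
          base$FITC[xs[keep_x], ys[keep_y]] + haze_peak * rh$mask[keep_x, keep_y]
      }
    }
    pts <- scene$puncta[scene$puncta$field == field, , drop = FALSE]
    for (z in seq_len(nz)) {
      dz <- abs(z - zmid)
      sig <- rc$area_sigma0 + rc$area_defocus * dz
      for (ci in 1:2) {
        b <- base[[params$channels[ci]]]
        plane <- if (all(b == 0)) b else
          as.matrix(EBImage::gblur(EBImage::Image(b), sigma = sig))
        arr[, , ci, z, field] <- plane
      }
    }
    ## PLA puncta in the TRITC channel
    if (nrow(pts)) {
      zw <- outer(pts$z, seq_len(nz),
                  function(z0, z) exp(-((z - z0)^2) / (2 * rc$spot_axial_sd^2)))
      zw <- zw / rowSums(zw)
      for (i in seq_len(nrow(pts))) {
        for (z in seq_len(nz)) {
          w <- zw[i, z]
          if (w < 1e-6) next
          sig <- rc$spot_sigma0 + rc$spot_defocus * abs(z - pts$z[i])
          arr[, , 3L, z, field] <- stamp_gaussian(
            arr[, , 3L, z, field], pts$x[i], pts$y[i], sig,
            w * pts$integrated_intensity[i])
        }
      }
    }
    ## camera model: background + shot noise + read noise, 16-bit quantised.
    ## Quantisation belongs to the camera: with all noise sources disabled
    ## the ideal (continuous) image is returned, so rendered puncta flux is
    ## conserved exactly in the noise-free limit.
    noisy <- isTRUE(params$noise$photon) || params$noise$read_sd > 0
    for (ci in 1:3) {
      for (z in seq_len(nz)) {
        sig <- arr[, , ci, z, field] + bg[ci]
        if (isTRUE(params$noise$photon)) {
          sig <- matrix(stats::rpois(length(sig), lambda = sig), W, H)
        }
        if (params$noise$read_sd > 0) {
          sig <- sig + stats::rnorm(length(sig), 0, params$noise$read_sd)
        }
        if (noisy) sig <- round(sig)
        arr[, , ci, z, field] <- pmin(65535, pmax(0, sig))
      }
    }
  }
  image_stack(arr, params$channels, params$pixel_size_um)
}

#' Write / read an acquisition stack as multi-page TIFF
#'
#' Planes are written in field -> z -> channel order as 16-bit grayscale
#' pages; stack geometry, channel names and pixel size go to a JSON sidecar
#' (`<path>.json`) so the stack can be reloaded without external metadata.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return `path` invisibly (`write_stack`); an `image_stack` (`read_stack`).
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  planes <- vector("list", d[5] * d[4] * d[3])
  k <- 0L
  for (f in seq_len(d[5])) for (z in seq_len(d[4])) for (ci in seq_len(d[3])) {
    k <- k + 1L
    planes[[k]] <- t(stack$data[, , ci, z, f]) / 65535
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, compression = "none")
  meta <- list(fields = d[5], z_planes = d[4], channels = stack$channels,
               width = d[1], height = d[2],
               pixel_size_um = stack$pixel_size_um,
               plane_order = "field,z,channel")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(meta$width, meta$height, length(meta$channels), meta$z_planes, meta$fields)
  arr <- array(0, dim = d)
  k <- 0L
  for (f in seq_len(d[5])) for (z in seq_len(d[4])) for (ci in seq_len(d[3])) {
    k <- k + 1L
    arr[, , ci, z, f] <- round(t(pages[[k]]) * 65535)
  }
  image_stack(arr, meta$channels, meta$pixel_size_um)
}
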