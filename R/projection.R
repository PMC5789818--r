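#' Maximum intensity projection of one field
#'
#' Collapses the z dimension of one acquisition field by taking, per pixel
#' and per channel, the maximum over all z planes. Projecting a single-plane
#' stack is the identity.
#'
#' @param stack An `image_stack`.
#' @param field Field index (1-based).
#' @return A `projected_image`: list with `data` (array `(x, y, channel)`),
#'   `channels`, `field` and `pixel_size_um`.
#' @export
max_intensity_projection <- function(stack, field) {
  d <- dim(stack$data)
  if (field < 1L || field > d[5]) stop("field index out of range: ", field)
  if (d[4] < 1L) stop("stack has an empty z axis")
  proj <- array(0, dim = d[1:3])
  for (ci in seq_len(d[3])) {
    m <- stack$data[, , ci, 1L, field]
    if (d[4] > 1L) for (z in 2:d[4]) m <- pmax(m, stack$data[, , ci, z, field])
    proj[, , ci] <- m
  }
  structure(list(data = proj, channels = stack$channels, field = field,
                 pixel_size_um = stack$pixel_size_um),
            class = "projected_image")
}

#' Extract one channel of a projected image
#' @param img A `projected_image`.
#' @param channel Channel name or index.
#' @return Numeric matrix `(x, y)`.
#' @export
channel_matrix <- function(img, channel) {
  ci <- if (is.character(channel)) match(channel, img$channels) else channel
  if (is.na(ci) || ci < 1L || ci > length(img$channels)) {
    stop("unknown channel: ", channel)
  }
  img$data[, , ci]
}

#' Background subtraction on a projected image
#'
#' Three estimators of the (per-channel) background are supported:
#' `constant` subtracts a fixed value; `percentile` subtracts the given
#' percentile of the channel (the median, p = 50, is robust when objects
#' cover a minority of the field); `rolling_ball` subtracts a local
#' background estimated by grayscale morphological opening with a disc
#' structuring element of the given radius. Output is clamped at 0.
#'
#' @param img A `projected_image`.
#' @param method One of `"constant"`, `"percentile"`, `"rolling_ball"`.
#' @param value Constant to subtract (constant method).
#' @param p Percentile in `[0, 100]` (percentile method).
#' @param radius Structuring-element radius in px (rolling_ball method).
#' @return A `projected_image` with non-negative values.
#' @export
subtract_background <- function(img, method = c("percentile", "constant", "rolling_ball"),
                                value = 0, p = 50, radius = 25) {
  if (!is.character(method) || !all(method %in% c("percentile", "constant", "rolling_ball"))) {
    stop("unknown background-subtraction method: ", paste(method, collapse = ", "))
  }
  method <- match.arg(method)
  out <- img
  for (ci in seq_along(img$channels)) {
    m <- img$data[, , ci]
    bgm <- switch(method,
      constant = value,
      percentile = as.numeric(stats::quantile(m, probs = p / 100, names = FALSE)),
      rolling_ball = {
        brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
        as.matrix(EBImage::opening(EBImage::Image(m / 65535), brush)) * 65535
      })
    out$data[, , ci] <- pmax(0, m - bgm)
  }
  out
}
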