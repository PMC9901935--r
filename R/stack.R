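#' Multichannel 3D image stack
#'
#' Container for confocal-style image data. Intensities are stored as a
#' numeric 4D array indexed `[channel, z, y, x]`; physical voxel sizes are in
#' micrometres. Pixel index `i` (1-based) along an axis maps to the physical
#' coordinate of the pixel centre, `(i - 0.5) * voxel_size`.
#'
#' @param data numeric array. Accepted shapes: `(channel, z, y, x)`,
#'   `(z, y, x)` (single channel) or `(y, x)` (single channel, single slice).
#' @param voxel_size numeric length-3 vector `c(x = , y = , z = )` in µm;
#'   all entries must be positive.
#' @param channels character vector of channel labels, one per channel.
#' @param bit_depth nominal bit depth of the acquisition (8 or 16); stored
#'   for provenance, intensities themselves are kept numeric.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_size, channels = NULL, bit_depth = 16L) {
  if (!is.array(data) && !is.matrix(data)) stop("`data` must be an array")
  d <- dim(data)
  if (length(d) == 2L) dim(data) <- c(1L, 1L, d)
  if (length(dim(data)) == 3L) dim(data) <- c(1L, dim(data))
  if (length(dim(data)) != 4L) stop("`data` must have 2, 3 or 4 dimensions")
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("intensities must be finite and non-negative")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 positive numbers (x, y, z) in µm")
  }
  names(voxel_size) <- c("x", "y", "z")
  nc <- dim(data)[1L]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (length(channels) != nc) stop("one channel label per channel required")
  structure(
    list(data = data, voxel_size = voxel_size,
         channels = as.character(channels), bit_depth = as.integer(bit_depth)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d channel(s) [%s], %d slice(s), %d x %d px\n",
              d[1], paste(x$channels, collapse = ", "), d[2], d[4], d[3]))
  cat(sprintf("voxel size: %.4g x %.4g x %.4g µm\n",
              x$voxel_size["x"], x$voxel_size["y"], x$voxel_size["z"]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    ci <- as.integer(channel)
    if (ci < 1L || ci > length(stack$channels)) stop("channel index out of range")
    return(ci)
  }
  ci <- match(channel, stack$channels)
  if (is.na(ci)) {
    stop(sprintf("unknown channel '%s' (have: %s)", channel,
                 paste(stack$channels, collapse = ", ")))
  }
  ci
}

#' Extract one channel of a stack as a (z, y, x) array
#'
#' @param stack an [image_stack()].
#' @param channel channel label or index.
#' @return numeric 3D array `(z, y, x)`.
#' @export
stack_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  ci <- channel_index(stack, channel)
  d <- dim(stack$data)
  array(stack$data[ci, , , ], dim = d[2:4])
}

#' Maximum intensity projection
#'
#' Collapses a channel of a z-stack along z: `out[y, x] = max_z in[z, y, x]`,
#' the standard first step of the density and recombination measurements.
#'
#' @inheritParams stack_channel
#' @return numeric matrix `(y, x)`.
#' @export
max_project <- function(stack, channel = 1L) {
  vol <- stack_channel(stack, channel)
  apply(vol, c(2L, 3L), max)
}

#' Convert an image to 8-bit with a linear display range
#'
#' Mirrors ImageJ's "8-bit" conversion: intensities are linearly mapped so
#' that `display_min` -> 0 and `display_max` -> 255, clipped to that range and
#' rounded half-to-even (R's `round()`), giving platform-stable integers.
#'
#' @param image numeric matrix or array.
#' @param display_min,display_max display range bounds; `display_max` must
#'   exceed `display_min` and both must be finite.
#' @return integer array of the same shape with values in 0..255.
#' @export
convert_8bit <- function(image, display_min = min(image), display_max = max(image)) {
  if (!is.numeric(display_min) || !is.numeric(display_max) ||
      !is.finite(display_min) || !is.finite(display_max)) {
    stop("display bounds must be finite numbers")
  }
  if (display_max <= display_min) stop("`display_max` must exceed `display_min`")
  scaled <- (image - display_min) * (255 / (display_max - display_min))
  scaled[scaled < 0] <- 0
  scaled[scaled > 255] <- 255
  out <- round(scaled)
  storage.mode(out) <- "integer"
  out
}

#' Write a stack as multi-page TIFF with a YAML voxel-size sidecar
#'
#' One file per channel (`<prefix>_<channel>.tif`), 16-bit, plus
#' `<prefix>.yaml` recording voxel sizes (µm), channel labels and bit depth.
#'
#' @param stack an [image_stack()].
#' @param prefix output path prefix (directory must exist).
#' @return invisibly, the paths written.
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  scale <- max(stack$data, 1e-12)
  paths <- character(0)
  for (ci in seq_len(d[1])) {
    vol <- stack_channel(stack, ci)
    pages <- lapply(seq_len(d[2]), function(z) vol[z, , ] / scale)
    p <- sprintf("%s_%s.tif", prefix, stack$channels[ci])
    tiff::writeTIFF(pages, p, bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  meta <- list(
    voxel_size_um = as.list(stack$voxel_size),
    channels = as.list(stack$channels),
    bit_depth = stack$bit_depth,
    intensity_scale = scale
  )
  yp <- paste0(prefix, ".yaml")
  yaml::write_yaml(meta, yp)
  invisible(c(paths, yp))
}

#' Read a stack written by [write_stack()]
#'
#' @param prefix the path prefix used when writing.
#' @return an [image_stack()].
#' @export
read_stack <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  channels <- unlist(meta$channels)
  vols <- lapply(channels, function(ch) {
    pages <- tiff::readTIFF(sprintf("%s_%s.tif", prefix, ch), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, dim = c(length(pages), dim(pages[[1]])))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    arr * meta$intensity_scale
  })
  data <- array(0, dim = c(length(vols), dim(vols[[1]])))
  for (ci in seq_along(vols)) data[ci, , , ] <- vols[[ci]]
  image_stack(data, unlist(meta$voxel_size_um), channels,
              bit_depth = meta$bit_depth)
}
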