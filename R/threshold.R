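#' Binary mask with provenance
#'
#' @param mask logical matrix or 3D array.
#' @param pixel_size numeric, µm per pixel along each axis (length 2 for 2D
#'   masks, 3 for 3D; recycled from length 1).
#' @param source description of the source channel.
#' @param method thresholding method that produced the mask, if any.
#' @param level threshold level, if any.
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(mask, pixel_size = 1, source = NA_character_,
                        method = NA_character_, level = NA_real_) {
  if (!is.logical(mask)) stop("`mask` must be logical")
  nd <- length(dim(mask))
  if (is.null(dim(mask)) || !(nd %in% c(2L, 3L))) stop("`mask` must be 2D or 3D")
  pixel_size <- as.numeric(pixel_size)
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, nd)
  if (length(pixel_size) != nd || any(pixel_size <= 0)) {
    stop("`pixel_size` must be positive, one value per mask dimension")
  }
  structure(list(mask = mask, pixel_size = pixel_size, source = source,
                 method = method, level = level),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %s px, %.3g%% foreground (method=%s, level=%s)\n",
              paste(dim(x$mask), collapse = " x "),
              100 * mean(x$mask), x$method, format(x$level)))
  invisible(x)
}

image_histogram <- function(image) {
  v <- as.integer(round(as.numeric(image)))
  if (any(v < 0L | v > 255L)) stop("expected an 8-bit image (values 0..255)")
  tabulate(v + 1L, nbins = 256L)
}

#' Huang fuzzy-entropy threshold of a 256-level histogram
#'
#' For each candidate level t the image is split at t; a pixel of grey value g
#' gets fuzzy membership `mu = 1 / (1 + |g - m| / C)` in its own class, where
#' `m` is the mean grey value of the class the pixel falls in and
#' `C = g_max - g_min` is the observed dynamic range. The threshold is the t
#' minimising the Shannon entropy of the memberships,
#' `S(t) = -sum_g h(g) * (mu ln mu + (1 - mu) ln(1 - mu))`.
#' Ties are broken towards the lowest level.
#'
#' @param counts integer vector of 256 histogram counts (levels 0..255).
#' @return the threshold level t (foreground = values strictly above t).
#' @keywords internal
huang_threshold_histogram <- function(counts) {
  stopifnot(length(counts) == 256L)
  levels_present <- which(counts > 0L) - 1L
  if (length(levels_present) < 2L) {
    stop("histogram is degenerate (fewer than two occupied grey levels)")
  }
  g <- 0:255
  h <- as.numeric(counts)
  gmin <- min(levels_present); gmax <- max(levels_present)
  C <- gmax - gmin
  csum <- cumsum(h)
  cwsum <- cumsum(h * g)
  n <- csum[256L]
  wtot <- cwsum[256L]
  ent <- function(mu) {
    # x ln x with 0 ln 0 = 0; memberships are in [0.5, 1]
    term <- function(x) ifelse(x > 0, x * log(x), 0)
    term(mu) + term(1 - mu)
  }
  best_t <- NA_integer_; best_s <- Inf
  for (t in gmin:(gmax - 1L)) {
    n0 <- csum[t + 1L]
    if (n0 == 0 || n0 == n) next
    m0 <- cwsum[t + 1L] / n0
    m1 <- (wtot - cwsum[t + 1L]) / (n - n0)
    mclass <- ifelse(g <= t, m0, m1)
    mu <- 1 / (1 + abs(g - mclass) / C)
    s <- -sum(h * ent(mu))
    if (s < best_s - 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

#' Otsu threshold of a 256-level histogram
#'
#' Exhaustive scan over all 256 candidate levels for the t maximising the
#' between-class variance `w0 w1 (m0 - m1)^2`. Ties go to the lowest level.
#'
#' @inheritParams huang_threshold_histogram
#' @return the threshold level t (foreground = values strictly above t).
#' @keywords internal
otsu_threshold_histogram <- function(counts) {
  stopifnot(length(counts) == 256L)
  if (sum(counts > 0L) < 2L) {
    stop("histogram is degenerate (fewer than two occupied grey levels)")
  }
  g <- 0:255
  h <- as.numeric(counts)
  n <- sum(h)
  csum <- cumsum(h)
  cwsum <- cumsum(h * g)
  wtot <- cwsum[256L]
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    n0 <- csum[t + 1L]
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    m0 <- cwsum[t + 1L] / n0
    m1 <- (wtot - cwsum[t + 1L]) / n1
    v <- (n0 / n) * (n1 / n) * (m0 - m1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

#' Automatic global threshold (Huang or Otsu)
#'
#' Reimplements the ImageJ-style automatic thresholds used for the particle
#' (density) and percent-area (recombination) measurements. Non-8-bit input
#' is first binned to 256 levels over its observed range. The mask keeps
#' pixels strictly above the returned level.
#'
#' @param image numeric matrix (2D) or array (3D).
#' @param method `"huang"` or `"otsu"`.
#' @param pixel_size µm per pixel, passed to [binary_mask()].
#' @return a list with `level` (on the original intensity scale), `level_8bit`
#'   (0..255 bin index) and `mask` (a [binary_mask()]).
#' @export
global_threshold <- function(image, method = c("otsu", "huang"), pixel_size = 1) {
  method <- match.arg(method)
  if (length(image) == 0L) stop("empty image")
  rng <- range(image)
  if (!all(is.finite(rng))) stop("image contains non-finite values")
  if (rng[1] == rng[2]) stop("constant image: threshold undefined")
  already_8bit <- is.integer(image) ||
    (all(image == floor(image)) && rng[1] >= 0 && rng[2] <= 255)
  if (already_8bit) {
    img8 <- image
    to_native <- function(t) t
  } else {
    img8 <- convert_8bit(image, rng[1], rng[2])
    to_native <- function(t) rng[1] + (t + 0.5) * (rng[2] - rng[1]) / 255
  }
  counts <- image_histogram(img8)
  t8 <- switch(method,
               huang = huang_threshold_histogram(counts),
               otsu  = otsu_threshold_histogram(counts))
  mask <- img8 > t8
  dim(mask) <- dim(image)
  list(level = to_native(t8), level_8bit = t8,
       mask = binary_mask(mask, pixel_size = pixel_size,
                          method = method, level = to_native(t8)))
}

#' Percent area of a binary mask
#'
#' The ImageJ "%Area" measurement: `100 * foreground pixels / total pixels`.
#'
#' @param mask a [binary_mask()] or logical array.
#' @return percentage in `[0, 100]`.
#' @export
percent_area <- function(mask) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  if (!is.logical(m) || length(m) == 0L) stop("`mask` must be a non-empty logical array")
  100 * sum(m) / length(m)
}
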