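#' Cell density per unit area
#'
#' Standardised density measure: `count / area`, reported per 10^4 µm².
#' For scales with multiple lobes, one density is measured at the centre of
#' each lobe and the per-lobe densities are averaged ([scale_density()]).
#' For tiled low-magnification acquisitions, counts and areas are pooled
#' before dividing ([pooled_density()]).
#'
#' @param count cell count (or vector of counts).
#' @param area_um2 measured area(s) in µm²; must be positive.
#' @param per_um2 reporting unit (default 1e4 µm²).
#' @return density in cells per `per_um2` µm².
#' @export
region_density <- function(count, area_um2, per_um2 = 1e4) {
  if (any(area_um2 <= 0)) stop("`area_um2` must be positive")
  count / area_um2 * per_um2
}

#' @rdname region_density
#' @param lobe_densities per-lobe densities of one scale.
#' @export
scale_density <- function(lobe_densities) {
  if (length(lobe_densities) == 0) stop("no lobe measurements")
  mean(lobe_densities)
}

#' @rdname region_density
#' @param counts,areas_um2 per-tile counts and areas to pool.
#' @export
pooled_density <- function(counts, areas_um2, per_um2 = 1e4) {
  region_density(sum(counts), sum(areas_um2), per_um2)
}

#' Align scale outlines at the posterior-margin midpoint
#'
#' Each scale is translated so that the anchor — the midpoint of the
#' dorsal-most and ventral-most vertices of its posterior margin — maps to
#' the origin. Translation only: pairwise distances are preserved, so
#' shapes are compared without rotation or scaling. Coordinates follow
#' x = anterior to posterior, y = ventral to dorsal, in µm.
#'
#' @param outlines data frame `scale_id`, `vertex_index`, `x_um`, `y_um`,
#'   `is_posterior_margin` (as from [generate_scale_field()]).
#' @param points optional data frame `scale_id`, `x_um`, `y_um` of cell
#'   positions to carry through the same per-scale translation.
#' @return list with `outlines`, `points` (translated copies) and `anchors`
#'   (data frame `scale_id`, `x_um`, `y_um` of the original anchors).
#' @export
align_scales <- function(outlines, points = NULL) {
  need <- c("scale_id", "x_um", "y_um", "is_posterior_margin")
  if (!all(need %in% names(outlines))) {
    stop("`outlines` needs columns scale_id, x_um, y_um, is_posterior_margin")
  }
  ids <- unique(outlines$scale_id)
  anchors <- lapply(ids, function(s) {
    o <- outlines[outlines$scale_id == s, ]
    pm <- o[o$is_posterior_margin, ]
    if (nrow(pm) == 0) {
      stop(sprintf("scale %s has no posterior-margin annotation", s))
    }
    dorsal <- pm[which.max(pm$y_um), ]
    ventral <- pm[which.min(pm$y_um), ]
    data.frame(scale_id = s,
               x_um = (dorsal$x_um + ventral$x_um) / 2,
               y_um = (dorsal$y_um + ventral$y_um) / 2)
  })
  anchors <- do.call(rbind, anchors)
  shift <- function(df) {
    m <- match(df$scale_id, anchors$scale_id)
    if (anyNA(m)) stop("points reference a scale with no outline")
    df$x_um <- df$x_um - anchors$x_um[m]
    df$y_um <- df$y_um - anchors$y_um[m]
    df
  }
  list(outlines = shift(outlines),
       points = if (!is.null(points)) shift(points) else NULL,
       anchors = anchors)
}

#' Scott's bandwidth for 2D kernel density estimation
#'
#' Per-axis Gaussian kernel sd: `sd(x) * n^(-1/6)`.
#'
#' @param x numeric vector.
#' @return bandwidth (kernel sd).
#' @export
scott_bandwidth <- function(x) {
  stats::sd(x) * length(x)^(-1 / 6)
}

#' 2D kernel density estimate of cell positions
#'
#' Gaussian KDE on a regular grid (via [MASS::kde2d()]), with Scott's-rule
#' bandwidths by default and grid limits padded by four bandwidths so the
#' density integrates to ~1 over the grid. The trapezoidal integral is
#' returned for QC.
#'
#' @param x,y point coordinates (µm), at least 2 points.
#' @param bandwidth kernel sd, length 1 or 2 (x, y); `NULL` = Scott's rule.
#' @param n grid points per axis.
#' @param lims optional `c(xmin, xmax, ymin, ymax)`.
#' @return list `x`, `y` (grid axes), `z` (density matrix, x by y),
#'   `bandwidth`, `integral`.
#' @export
position_density <- function(x, y, bandwidth = NULL, n = 101, lims = NULL) {
  if (length(x) < 2 || length(y) != length(x)) stop("need >= 2 paired points")
  if (is.null(bandwidth)) {
    bandwidth <- c(scott_bandwidth(x), scott_bandwidth(y))
  }
  bandwidth <- rep(as.numeric(bandwidth), length.out = 2)
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 0)) {
    stop("degenerate bandwidth; points may be identical")
  }
  if (is.null(lims)) {
    lims <- c(range(x) + c(-4, 4) * bandwidth[1],
              range(y) + c(-4, 4) * bandwidth[2])
  }
  # kde2d's `h` is 4x the Gaussian kernel sd
  kd <- MASS::kde2d(x, y, h = 4 * bandwidth, n = n, lims = lims)
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  zi <- kd$z
  wx <- rep(1, length(kd$x)); wx[c(1, length(wx))] <- 0.5
  wy <- rep(1, length(kd$y)); wy[c(1, length(wy))] <- 0.5
  integral <- sum((wx %o% wy) * zi) * dx * dy
  list(x = kd$x, y = kd$y, z = kd$z, bandwidth = bandwidth, integral = integral)
}

#' Histogram of cell positions along a rectangle axis
#'
#' Counts points falling inside an axis-aligned rectangle, binned along the
#' chosen axis into `n_bins` equal half-open bins `[lo, hi)`: a point on an
#' interior bin edge is counted in the right-hand bin, and points exactly on
#' the rectangle's far edge are excluded (the half-open convention applied
#' throughout).
#'
#' @param x,y point coordinates (µm).
#' @param rect `c(xmin, xmax, ymin, ymax)` with positive extent.
#' @param n_bins number of bins (>= 1).
#' @param axis `"x"` (anterior-posterior, default) or `"y"`.
#' @return list with `counts`, `breaks` and `mids`.
#' @export
segment_histogram <- function(x, y, rect, n_bins = 20, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (n_bins < 1) stop("`n_bins` must be at least 1")
  rect <- as.numeric(rect)
  if (rect[2] <= rect[1] || rect[4] <= rect[3]) {
    stop("rectangle must have positive extent")
  }
  inside <- x >= rect[1] & x < rect[2] & y >= rect[3] & y < rect[4]
  v <- if (axis == "x") x[inside] else y[inside]
  lo <- if (axis == "x") rect[1] else rect[3]
  hi <- if (axis == "x") rect[2] else rect[4]
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  idx <- pmin(floor((v - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  list(counts = counts, breaks = breaks, mids = (breaks[-1] + breaks[-(n_bins + 1)]) / 2)
}
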