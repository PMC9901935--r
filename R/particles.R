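#' Label connected components of a binary array
#'
#' ImageJ-default connectivity: 8-connectivity in 2D, 26-connectivity in 3D.
#' Implemented as vectorised minimum-label propagation: every foreground
#' pixel starts with a unique label and repeatedly takes the minimum label
#' over its neighbourhood until a fixed point, then labels are compacted to
#' 1..n in order of first (column-major) occurrence.
#'
#' @param mask logical matrix or 3D array.
#' @return integer array of the same shape; 0 = background.
#' @export
label_components <- function(mask) {
  if (!is.logical(mask)) stop("`mask` must be logical")
  d <- dim(mask)
  nd <- length(d)
  if (!(nd %in% c(2L, 3L))) stop("`mask` must be 2D or 3D")
  if (nd == 2L) { d <- c(d, 1L); dim(mask) <- d }
  full_out <- array(0L, dim = d)
  if (any(mask)) {
    # crop to the foreground bounding box; propagation cost scales with it
    w <- which(mask, arr.ind = TRUE)
    lo <- pmax(apply(w, 2, min), 1L)
    hi <- pmin(apply(w, 2, max), d)
    sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    full_out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- label_core(sub)
  }
  out <- full_out
  ids <- unique(out[out > 0])
  out[out > 0] <- match(out[out > 0], ids)
  dim(out) <- if (nd == 2L) d[1:2] else d
  storage.mode(out) <- "integer"
  out
}

label_core <- function(mask) {
  d <- dim(mask)
  # pad with background so neighbour shifts never wrap
  pd <- d + 2L
  lab <- array(0, dim = pd)
  core <- list(2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L))
  init <- array(0, dim = d)
  init[mask] <- seq_len(sum(mask))
  lab[core[[1]], core[[2]], core[[3]]] <- init
  shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = if (dim(mask)[3] > 1) -1:1 else 0)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0 & shifts$dz == 0), ]
  fg <- lab > 0
  repeat {
    new <- lab
    for (k in seq_len(nrow(shifts))) {
      s <- shifts[k, ]
      nb <- lab[core[[1]] + s$dx, core[[2]] + s$dy, core[[3]] + s$dz]
      nbp <- array(0, dim = pd)
      nbp[core[[1]], core[[2]], core[[3]]] <- nb
      take <- fg & nbp > 0 & nbp < new
      new[take] <- nbp[take]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab[core[[1]], core[[2]], core[[3]]]
}

#' Maximum Feret diameter of a point set
#'
#' Largest pairwise Euclidean distance between the supplied coordinates plus
#' one pixel diameter worth of extent: for raster blobs the coordinates are
#' voxel centres, so the caliper extent of a blob along its longest chord is
#' the centre-to-centre distance plus one voxel. `pts` are physical (µm)
#' coordinates of voxel centres; `pad` is the voxel diagonal contribution
#' (pass 0 for pure point sets).
#'
#' @param pts numeric matrix, one row per point.
#' @param pad added to the maximum centre-to-centre distance (µm).
#' @return numeric scalar.
#' @keywords internal
max_feret <- function(pts, pad = 0) {
  n <- nrow(pts)
  if (n == 1L) return(pad)
  if (n > 400L) {
    # reduce to the coordinate-wise extreme shell to bound the pairwise cost
    keep <- unique(unlist(lapply(seq_len(ncol(pts)), function(j) {
      r <- range(pts[, j])
      which(pts[, j] %in% r)
    })))
    if (length(keep) > 1L && length(keep) < n) {
      hull <- pts[keep, , drop = FALSE]
      # pairwise distances over hull candidates plus full set vs hull
      dmax <- max(as.matrix(stats::dist(hull)))
      for (j in seq_len(nrow(hull))) {
        dd <- sqrt(rowSums((pts - matrix(hull[j, ], n, ncol(pts), byrow = TRUE))^2))
        dmax <- max(dmax, dd)
      }
      return(dmax + pad)
    }
  }
  max(stats::dist(pts)) + pad
}

#' Particle analysis of a 2D binary mask
#'
#' Reimplements the ImageJ "Analyze particles" measurement: 8-connected
#' components of the mask whose physical area falls in `[min_area, max_area]`,
#' with centroids and maximum Feret diameters in µm. Pixel `(row, col)` has
#' its centre at `x = (col - 0.5) * px`, `y = (row - 0.5) * py`.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param min_area,max_area area filters in µm².
#' @param pixel_size µm per pixel (x, y); overrides the mask's own value if
#'   given.
#' @return data.frame: `label`, `area_um2`, `x_um`, `y_um`, bounding box in
#'   pixels (`bbox_x0`, `bbox_x1`, `bbox_y0`, `bbox_y1`) and `feret_um`.
#' @export
analyze_particles <- function(mask, min_area = 0, max_area = Inf, pixel_size = NULL) {
  if (inherits(mask, "binary_mask")) {
    if (is.null(pixel_size)) pixel_size <- mask$pixel_size
    mask <- mask$mask
  }
  if (is.null(pixel_size)) pixel_size <- 1
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2L)
  if (!is.logical(mask) || length(dim(mask)) != 2L) stop("`mask` must be a 2D logical matrix")
  if (min_area > max_area) stop("`min_area` must not exceed `max_area`")
  px <- pixel_size[1]; py <- pixel_size[2]
  pxarea <- px * py
  empty <- data.frame(label = integer(0), area_um2 = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      bbox_x0 = integer(0), bbox_x1 = integer(0),
                      bbox_y0 = integer(0), bbox_y1 = integer(0),
                      feret_um = numeric(0))
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  rows <- split(seq_along(labs), labs)
  out <- lapply(seq_along(rows), function(k) {
    ii <- rows[[k]]
    r <- idx[ii, 1L]; cc <- idx[ii, 2L]
    area <- length(ii) * pxarea
    pts <- cbind((cc - 0.5) * px, (r - 0.5) * py)
    data.frame(label = k, area_um2 = area,
               x_um = mean(pts[, 1]), y_um = mean(pts[, 2]),
               bbox_x0 = min(cc), bbox_x1 = max(cc),
               bbox_y0 = min(r), bbox_y1 = max(r),
               feret_um = max_feret(pts, pad = (px + py) / 2))
  })
  out <- do.call(rbind, out)
  out <- out[out$area_um2 >= min_area & out$area_um2 <= max_area, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out$label <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
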