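#' Detect nuclei in a 3D stack
#'
#' 3D blob detection for the nuclear-reporter channel: the channel is
#' auto-thresholded (Otsu by default), 26-connected components above a
#' minimum volume are taken as nuclei, and each is summarised by its
#' intensity-weighted centroid (physical µm), its maximum nuclear diameter
#' (3D maximum Feret diameter of the thresholded voxel set, µm) and its mean
#' intensity in every channel of the stack.
#'
#' @param stack an [image_stack()].
#' @param channel nuclear channel label or index.
#' @param threshold_method `"otsu"` or `"huang"`.
#' @param min_volume_um3 components smaller than this are discarded
#'   (default 10 µm³, well below any real nucleus).
#' @param threshold_level optional fixed threshold on the native intensity
#'   scale, bypassing the automatic method.
#' @return a `cell_table` data.frame: `cell_id`, `x_um`, `y_um`, `z_um`,
#'   `diameter_um`, `volume_um3`, `n_voxels`, plus one `mean_<channel>`
#'   column per channel. A `qc` attribute lists possible merged nuclei
#'   (volume > 1.8x the median detected volume).
#' @export
detect_cells_3d <- function(stack, channel = 1L,
                            threshold_method = c("otsu", "huang"),
                            min_volume_um3 = 10,
                            threshold_level = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  threshold_method <- match.arg(threshold_method)
  vol <- stack_channel(stack, channel)
  vs <- stack$voxel_size  # c(x, y, z); vol is (z, y, x)
  voxvol <- prod(vs)
  empty <- cell_table_skeleton(stack$channels)
  if (max(vol) == min(vol)) {
    attr(empty, "qc") <- list(note = "constant channel, nothing detected")
    return(empty)
  }
  if (is.null(threshold_level)) {
    thr <- global_threshold(vol, method = threshold_method)
    mask <- thr$mask$mask
    level <- thr$level
  } else {
    mask <- vol > threshold_level
    level <- threshold_level
  }
  lab <- label_components(mask)
  nlab <- max(lab)
  if (nlab == 0L) {
    attr(empty, "qc") <- list(note = "no components above threshold")
    return(empty)
  }
  idx <- which(lab > 0, arr.ind = TRUE)  # columns: z, y, x (array dim order)
  labs <- lab[lab > 0]
  ints <- vol[lab > 0]
  groups <- split(seq_along(labs), labs)
  sizes <- lengths(groups)
  keep <- which(sizes * voxvol >= min_volume_um3)
  rows <- lapply(keep, function(g) {
    ii <- groups[[g]]
    zz <- idx[ii, 1L]; yy <- idx[ii, 2L]; xx <- idx[ii, 3L]
    w <- ints[ii]; w <- w / sum(w)
    pts <- cbind((xx - 0.5) * unname(vs["x"]),
                 (yy - 0.5) * unname(vs["y"]),
                 (zz - 0.5) * unname(vs["z"]))
    means <- vapply(seq_along(stack$channels), function(ci) {
      chv <- stack$data[ci, , , ]
      dim(chv) <- dim(stack$data)[2:4]
      mean(chv[cbind(zz, yy, xx)])
    }, numeric(1))
    stats::setNames(
      c(sum(w * pts[, 1]), sum(w * pts[, 2]), sum(w * pts[, 3]),
        unname(max_feret(pts, pad = (vs[["x"]] + vs[["y"]]) / 2)),
        length(ii) * voxvol, length(ii), means),
      c("x_um", "y_um", "z_um", "diameter_um", "volume_um3", "n_voxels",
        paste0("mean_", stack$channels)))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(cell_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("cell_table", "data.frame")
  medvol <- stats::median(out$volume_um3)
  merged <- out$cell_id[out$volume_um3 > 1.8 * medvol]
  attr(out, "qc") <- list(threshold_level = level,
                          n_components = nlab,
                          n_kept = nrow(out),
                          merged_candidates = merged)
  out
}

cell_table_skeleton <- function(channels) {
  out <- data.frame(cell_id = integer(0), x_um = numeric(0), y_um = numeric(0),
                    z_um = numeric(0), diameter_um = numeric(0),
                    volume_um3 = numeric(0), n_voxels = numeric(0))
  for (ch in channels) out[[paste0("mean_", ch)]] <- numeric(0)
  class(out) <- c("cell_table", "data.frame")
  out
}
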