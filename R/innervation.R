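#' Scoring sphere for a cell
#'
#' The innervation scoring volume: a sphere centred on the cell centroid
#' whose diameter is 10% larger than the maximum nuclear diameter (so
#' radius = 0.55 x diameter by default). The enlargement factor is
#' configurable via `enlargement`.
#'
#' @param x_um,y_um,z_um centroid coordinates (µm).
#' @param diameter_um maximum nuclear diameter (µm), must be positive.
#' @param cell_id optional id.
#' @param enlargement sphere diameter as a multiple of the nuclear diameter
#'   (default 1.1).
#' @return list with `cell_id`, `center` (µm, length 3) and `radius_um`.
#' @export
scoring_sphere <- function(x_um, y_um, z_um, diameter_um, cell_id = NA_integer_,
                           enlargement = 1.1) {
  if (!is.finite(diameter_um) || diameter_um <= 0) {
    stop("`diameter_um` must be positive")
  }
  list(cell_id = cell_id,
       center = c(x = x_um, y = y_um, z = z_um),
       radius_um = enlargement * diameter_um / 2)
}

#' Score innervation of cells against an axon mask
#'
#' A cell is scored innervated if at least one foreground voxel of the axon
#' mask has its centre at Euclidean physical distance at most the scoring
#' sphere radius from the cell centroid. Distances are computed in µm with
#' per-axis voxel scaling, so anisotropic stacks are handled correctly.
#' Cells whose centroid falls outside the mask extent are excluded with a
#' warning and reported via the `excluded` attribute.
#'
#' @param cells data frame with columns `x_um`, `y_um`, `z_um`,
#'   `diameter_um` and optionally `cell_id` (e.g. from [detect_cells_3d()]
#'   or a generator truth table).
#' @param axon_mask logical `(z, y, x)` array, or a [binary_mask()].
#' @param voxel_um voxel sizes `c(x, y, z)` in µm (taken from the
#'   `binary_mask` if available).
#' @param enlargement scoring-sphere enlargement factor (default 1.1).
#' @return the `cells` data frame with logical column `innervated_scored`
#'   and numeric column `radius_um` appended (excluded cells dropped; the
#'   name avoids clobbering a generator's truth column `innervated`);
#'   attribute `excluded` holds the ids of out-of-bounds cells.
#' @export
score_innervation <- function(cells, axon_mask, voxel_um = NULL, enlargement = 1.1) {
  if (inherits(axon_mask, "binary_mask")) {
    if (is.null(voxel_um)) voxel_um <- axon_mask$pixel_size
    axon_mask <- axon_mask$mask
  }
  if (is.null(voxel_um)) stop("`voxel_um` required")
  if (!is.logical(axon_mask) || length(dim(axon_mask)) != 3L) {
    stop("`axon_mask` must be a 3D logical array (z, y, x)")
  }
  voxel_um <- stats::setNames(as.numeric(voxel_um), c("x", "y", "z"))
  d <- dim(axon_mask)
  ext <- c(x = d[3] * voxel_um[["x"]], y = d[2] * voxel_um[["y"]],
           z = d[1] * voxel_um[["z"]])
  if (is.null(cells$cell_id)) cells$cell_id <- seq_len(nrow(cells))
  oob <- cells$x_um < 0 | cells$x_um > ext["x"] |
    cells$y_um < 0 | cells$y_um > ext["y"] |
    cells$z_um < 0 | cells$z_um > ext["z"]
  if (any(oob)) {
    warning(sprintf("%d cell(s) outside the mask extent were excluded: %s",
                    sum(oob), paste(cells$cell_id[oob], collapse = ", ")))
  }
  excluded <- cells$cell_id[oob]
  cells <- cells[!oob, , drop = FALSE]
  n <- nrow(cells)
  radius <- enlargement * cells$diameter_um / 2
  flag <- logical(n)
  for (i in seq_len(n)) {
    r <- radius[i]
    ctr <- c(cells$x_um[i], cells$y_um[i], cells$z_um[i])
    # candidate voxel index ranges covering the sphere, per axis
    xr <- index_window(ctr[1], r, voxel_um[["x"]], d[3])
    yr <- index_window(ctr[2], r, voxel_um[["y"]], d[2])
    zr <- index_window(ctr[3], r, voxel_um[["z"]], d[1])
    if (!length(xr) || !length(yr) || !length(zr)) next
    sub <- axon_mask[zr, yr, xr, drop = FALSE]
    if (!any(sub)) next
    w <- which(sub, arr.ind = TRUE)
    dx <- (xr[w[, 3]] - 0.5) * voxel_um[["x"]] - ctr[1]
    dy <- (yr[w[, 2]] - 0.5) * voxel_um[["y"]] - ctr[2]
    dz <- (zr[w[, 1]] - 0.5) * voxel_um[["z"]] - ctr[3]
    flag[i] <- any(dx^2 + dy^2 + dz^2 <= r^2)
  }
  cells$innervated_scored <- flag
  cells$radius_um <- radius
  attr(cells, "excluded") <- excluded
  cells
}

index_window <- function(center, radius, vox, lim) {
  lo <- max(1L, floor((center - radius) / vox))
  hi <- min(lim, ceiling((center + radius) / vox) + 1L)
  if (lo > hi) integer(0) else lo:hi
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k successes, `n` trials.
#' @param n trials.
#' @param conf confidence level (default 0.95).
#' @return named numeric `c(lower, upper)` on the proportion scale.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n < 1) stop("`n` must be at least 1")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Clopper-Pearson exact confidence interval
#'
#' @inheritParams wilson_ci
#' @return named numeric `c(lower, upper)` on the proportion scale.
#' @export
clopper_pearson_ci <- function(k, n, conf = 0.95) {
  ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
  c(lower = ci[1], upper = ci[2])
}

#' Summarise innervation frequency with a confidence interval
#'
#' Frequency = 100 k / n with a 95% Wilson score interval by default
#' (Clopper-Pearson available via `ci_method`). When a `group` vector is
#' given (e.g. scale id), a per-group frequency is also returned, matching
#' the convention of plotting one dot per scale.
#'
#' @param flags logical vector of per-cell innervation calls.
#' @param label condition/marker label.
#' @param group optional grouping vector (same length as `flags`).
#' @param conf confidence level.
#' @param ci_method `"wilson"` or `"clopper-pearson"`.
#' @return list with `label`, `k`, `n`, `frequency_pct`, `ci_pct`
#'   (lower/upper, percent) and optionally `per_group` (data frame).
#' @export
innervation_summary <- function(flags, label = NA_character_, group = NULL,
                                conf = 0.95,
                                ci_method = c("wilson", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  if (length(flags) == 0) stop("no cells to summarise")
  if (anyNA(flags)) stop("`flags` must not contain NA")
  k <- sum(flags); n <- length(flags)
  ci <- switch(ci_method,
               wilson = wilson_ci(k, n, conf),
               `clopper-pearson` = clopper_pearson_ci(k, n, conf))
  out <- list(label = label, k = k, n = n,
              frequency_pct = 100 * k / n,
              ci_pct = 100 * ci)
  if (!is.null(group)) {
    sp <- split(flags, group)
    out$per_group <- data.frame(
      group = names(sp),
      k = vapply(sp, sum, numeric(1)),
      n = lengths(sp),
      frequency_pct = 100 * vapply(sp, mean, numeric(1)),
      row.names = NULL
    )
  }
  out
}
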