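#' Classify cells as photoconverted or new
#'
#' Labels a cell "converted" (pre-existing at the photoconversion pulse) if
#' its converted-channel intensity fraction,
#' `converted / (converted + native)`, exceeds a threshold. If no threshold
#' is given, the Otsu split of the observed ratio distribution (binned to
#' 256 levels) is used. Cells with zero intensity in both channels cannot be
#' classified and are reported separately.
#'
#' @param cells data frame with columns `native_intensity` and
#'   `converted_intensity`.
#' @param ratio_threshold fraction in (0, 1), or `NULL` for the Otsu default.
#' @return `cells` with logical column `converted_call` appended
#'   (NA for unclassifiable cells); attributes `ratio_threshold` and
#'   `unclassifiable` (row indices).
#' @export
classify_photoconverted <- function(cells, ratio_threshold = NULL) {
  need <- c("native_intensity", "converted_intensity")
  if (!all(need %in% names(cells))) {
    stop("`cells` needs columns native_intensity and converted_intensity")
  }
  tot <- cells$native_intensity + cells$converted_intensity
  bad <- tot <= 0
  ratio <- ifelse(bad, NA_real_, cells$converted_intensity / tot)
  if (is.null(ratio_threshold)) {
    r <- ratio[!bad]
    if (length(unique(round(r * 255))) < 2L) {
      stop("ratio distribution is degenerate; supply `ratio_threshold`")
    }
    t8 <- otsu_threshold_histogram(tabulate(round(r * 255) + 1L, nbins = 256L))
    ratio_threshold <- (t8 + 0.5) / 255
  }
  cells$converted_call <- ratio > ratio_threshold
  if (any(bad)) {
    warning(sprintf("%d cell(s) with zero intensity in both channels are unclassifiable",
                    sum(bad)))
  }
  attr(cells, "ratio_threshold") <- ratio_threshold
  attr(cells, "unclassifiable") <- which(bad)
  cells
}

#' Pulse-chase turnover accounting
#'
#' From per-timepoint counts of converted and new (non-converted) cells,
#' computes the published pulse-chase summaries: percent converted cells
#' remaining relative to day 0, percent total cells relative to day 0,
#' per-interval loss fractions `1 - converted(t[k+1]) / converted(t[k])`,
#' per-interval additions (increments of the new-cell count), and the
#' half-life from a log-linear decay fit through the origin
#' (`remaining = exp(-lambda t)`, `t_half = ln 2 / lambda`). A constant
#' converted count gives an undefined (infinite) half-life, reported as `NA`
#' with `half_life_finite = FALSE`.
#'
#' @param counts data frame with columns `t_days`, `converted`, `new`
#'   (counts at each timepoint; `t_days` strictly increasing, first row at
#'   day 0).
#' @return object of class `turnover_series`: the input plus derived columns
#'   `total`, `remaining_pct`, `total_pct`, and components `loss_per_interval`,
#'   `addition_per_interval`, `lambda_per_day`, `half_life_days`,
#'   `half_life_finite`.
#' @export
turnover_stats <- function(counts) {
  need <- c("t_days", "converted", "new")
  if (!all(need %in% names(counts))) {
    stop("`counts` needs columns t_days, converted, new")
  }
  if (nrow(counts) < 2) stop("need at least two timepoints")
  if (is.unsorted(counts$t_days, strictly = TRUE)) {
    stop("`t_days` must be strictly increasing")
  }
  if (counts$t_days[1] != 0) stop("the series must start at day 0")
  if (any(counts$converted < 0) || any(counts$new < 0)) stop("counts must be non-negative")
  if (counts$converted[1] == 0) {
    stop("no converted cells at day 0: remaining percentage undefined")
  }
  counts$total <- counts$converted + counts$new
  counts$remaining_pct <- 100 * counts$converted / counts$converted[1]
  counts$total_pct <- 100 * counts$total / counts$total[1]
  k <- nrow(counts)
  loss <- 1 - counts$converted[-1] / counts$converted[-k]
  addition <- diff(counts$new)
  rem <- counts$converted / counts$converted[1]
  t <- counts$t_days
  pos <- t > 0 & rem > 0
  if (any(pos)) {
    lambda <- -sum(t[pos] * log(rem[pos])) / sum(t[pos]^2)
  } else {
    lambda <- Inf  # everything lost immediately
  }
  finite <- is.finite(lambda) && lambda > 0
  structure(list(
    counts = counts,
    loss_per_interval = loss,
    addition_per_interval = addition,
    lambda_per_day = lambda,
    half_life_days = if (finite) log(2) / lambda else NA_real_,
    half_life_finite = finite
  ), class = "turnover_series")
}

#' @export
print.turnover_series <- function(x, ...) {
  cat("Photoconversion pulse-chase series\n")
  print(x$counts, row.names = FALSE)
  cat(sprintf("mean loss per interval: %.1f%%\n", 100 * mean(x$loss_per_interval)))
  cat(sprintf("half-life: %s days\n",
              if (x$half_life_finite) sprintf("%.1f", x$half_life_days) else "undefined"))
  invisible(x)
}

#' Recombination efficiency of a lineage-reporter projection
#'
#' The percent area of the Huang-thresholded maximum projection of the
#' lineage-reporter channel, taken as the local recombination efficiency.
#' Near-blank fields (dynamic range below `floor_range` of the maximum
#' intensity, or constant) are reported as 0% with a QC flag rather than
#' thresholding pure noise.
#'
#' @param image 2D numeric matrix (a maximum projection).
#' @param floor_range minimum dynamic range, as a fraction of the maximum
#'   intensity, for thresholding to be attempted (default 0.05).
#' @return numeric percentage with attribute `qc` (`"ok"` or `"blank"`).
#' @export
recombination_efficiency <- function(image, floor_range = 0.05) {
  if (length(dim(image)) != 2L) stop("`image` must be a 2D matrix")
  rng <- range(image)
  if (diff(rng) <= floor_range * max(abs(rng), 1e-12)) {
    return(structure(0, qc = "blank"))
  }
  thr <- global_threshold(image, method = "huang")
  structure(percent_area(thr$mask), qc = "ok")
}

#' Paired comparison of lineage labelling vs recombination efficiency
#'
#' Wilcoxon signed-rank test (two-sided) of the per-scale percentage of
#' Merkel cells expressing the lineage reporter against the per-scale local
#' recombination efficiency. Exact distribution is used for n <= 25
#' zero-excluded pairs (no ties), the normal approximation with continuity
#' correction otherwise (as in [stats::wilcox.test()]). If every pair is
#' tied the test is degenerate: p = 1 by convention, with a warning.
#'
#' @param mc_pct per-scale percent of MCs expressing the reporter.
#' @param recomb_pct per-scale local recombination efficiency (percent).
#' @return list with `statistic` (V), `p_value`, `n_pairs`, `median_mc`,
#'   `median_recomb` and `differences`.
#' @export
paired_label_comparison <- function(mc_pct, recomb_pct) {
  if (length(mc_pct) != length(recomb_pct)) stop("inputs must be paired")
  ok <- stats::complete.cases(mc_pct, recomb_pct)
  mc_pct <- mc_pct[ok]; recomb_pct <- recomb_pct[ok]
  if (length(mc_pct) < 2) stop("need at least two complete pairs")
  d <- mc_pct - recomb_pct
  if (all(d == 0)) {
    warning("all paired differences are zero; degenerate test, p = 1")
    return(list(statistic = NA_real_, p_value = 1, n_pairs = length(d),
                median_mc = stats::median(mc_pct),
                median_recomb = stats::median(recomb_pct),
                differences = d))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(mc_pct, recomb_pct, paired = TRUE,
                       exact = sum(d != 0) <= 25, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_pairs = length(d),
       median_mc = stats::median(mc_pct),
       median_recomb = stats::median(recomb_pct),
       differences = d)
}

#' Nearest-neighbour matching of cells across two timepoints
#'
#' Optional per-cell fate table: greedily matches each cell at the later
#' timepoint to the nearest unmatched cell at the earlier timepoint within a
#' distance gate (default 5 µm), in order of increasing distance.
#'
#' @param cells_a,cells_b data frames with `x_um`, `y_um`, `z_um` (and
#'   optionally `cell_id`).
#' @param gate_um maximum match distance (µm).
#' @return data frame `id_a`, `id_b`, `distance_um`; unmatched cells of
#'   either table are listed with `NA` on the other side.
#' @export
match_cells <- function(cells_a, cells_b, gate_um = 5) {
  ida <- if (is.null(cells_a$cell_id)) seq_len(nrow(cells_a)) else cells_a$cell_id
  idb <- if (is.null(cells_b$cell_id)) seq_len(nrow(cells_b)) else cells_b$cell_id
  za <- if (is.null(cells_a$z_um)) 0 else cells_a$z_um
  zb <- if (is.null(cells_b$z_um)) 0 else cells_b$z_um
  na <- nrow(cells_a); nb <- nrow(cells_b)
  if (na == 0 || nb == 0) {
    return(data.frame(id_a = c(ida, rep(NA, nb)),
                      id_b = c(rep(NA, na), idb),
                      distance_um = NA_real_))
  }
  dm <- outer(cells_a$x_um, cells_b$x_um, `-`)^2 +
    outer(cells_a$y_um, cells_b$y_um, `-`)^2 + outer(za, zb, `-`)^2
  dm <- sqrt(dm)
  pairs <- which(dm <= gate_um, arr.ind = TRUE)
  ord <- order(dm[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_a <- logical(na); used_b <- logical(nb)
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(id_a = ida[i], id_b = idb[j],
                                            distance_um = dm[i, j])
    }
  }
  matched <- if (length(out)) do.call(rbind, out) else
    data.frame(id_a = integer(0), id_b = integer(0), distance_um = numeric(0))
  rbind(matched,
        data.frame(id_a = ida[!used_a], id_b = rep(NA, sum(!used_a)),
                   distance_um = rep(NA_real_, sum(!used_a))),
        data.frame(id_a = rep(NA, sum(!used_b)), id_b = idb[!used_b],
                   distance_um = rep(NA_real_, sum(!used_b))))
}
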