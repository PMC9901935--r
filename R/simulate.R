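#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so generators are deterministic under a
#' given seed without disturbing the caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specification for a synthetic skin stack
#'
#' Defines the geometry, content and noise of a simulated two-channel
#' (nuclear reporter + axon reporter) confocal stack of the scale epidermis.
#' The default lateral pixel size, `sqrt(67055) / 500` (about 0.518 µm/px),
#' mirrors a 500 x 500 px field of view covering 67,055 µm²; the default
#' z-step of 1 µm over 30 slices is a conventional confocal sampling of the
#' epidermal slab.
#'
#' @param field_um field size in µm, `c(x, y, z)`.
#' @param voxel_um voxel size in µm, `c(x = lateral, y = lateral, z = step)`.
#' @param n_cells number of Merkel-cell nuclei to place.
#' @param diameter_um_range range of maximum nuclear diameters (µm).
#' @param p_inn probability that a cell is innervated (truth flag).
#' @param p_converted probability that a cell carries photoconverted reporter.
#' @param p_lineage probability that a cell carries the lineage label.
#' @param n_axons number of background axon random walks.
#' @param axon_step_um persistent-walk step length (µm).
#' @param varicosity_rate per-step probability of a varicosity.
#' @param background,signal background and peak signal intensity levels.
#' @param noise_sd additive Gaussian noise sigma.
#' @param poisson_noise logical, add Poisson shot noise.
#' @param allow_overlap allow nuclei (and scoring spheres) to overlap. When
#'   `FALSE` (default) centroids are placed so that scoring spheres are
#'   pairwise disjoint, which makes the innervation ground truth exact.
#' @param sphere_enlargement scoring-sphere enlargement factor used when
#'   constructing the innervation ground truth (default 1.1).
#' @param seed integer seed.
#' @return a `sim_stack_spec` list.
#' @export
sim_stack_spec <- function(field_um = c(x = 259, y = 259, z = 30),
                           voxel_um = c(x = sqrt(67055) / 500,
                                        y = sqrt(67055) / 500, z = 1),
                           n_cells = 50,
                           diameter_um_range = c(5, 8),
                           p_inn = 0.9,
                           p_converted = 0,
                           p_lineage = 0,
                           n_axons = 8,
                           axon_step_um = 2,
                           varicosity_rate = 0.15,
                           background = 100,
                           signal = 1000,
                           noise_sd = 20,
                           poisson_noise = FALSE,
                           allow_overlap = FALSE,
                           sphere_enlargement = 1.1,
                           seed = 1L) {
  field_um <- stats::setNames(as.numeric(field_um), c("x", "y", "z"))
  voxel_um <- stats::setNames(as.numeric(voxel_um), c("x", "y", "z"))
  if (any(voxel_um <= 0) || any(field_um <= 0)) stop("field and voxel sizes must be positive")
  if (p_inn < 0 || p_inn > 1) stop("`p_inn` must be in [0, 1]")
  if (p_converted < 0 || p_converted > 1) stop("`p_converted` must be in [0, 1]")
  if (p_lineage < 0 || p_lineage > 1) stop("`p_lineage` must be in [0, 1]")
  if (n_cells < 0) stop("`n_cells` must be non-negative")
  if (diameter_um_range[1] <= 2 * voxel_um["x"]) {
    stop("nucleus diameters must exceed twice the lateral voxel size")
  }
  if (n_cells > 0 && p_inn > 0 && n_axons == 0) {
    stop("innervation requested (p_inn > 0) but `n_axons` is zero")
  }
  structure(as.list(environment()), class = "sim_stack_spec")
}

# pack cell centroids so that scoring spheres are pairwise disjoint and lie
# fully inside the field; errors out if the field cannot hold them
place_cells <- function(spec) {
  n <- spec$n_cells
  if (n == 0) {
    return(data.frame(cell_id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), diameter_um = numeric(0)))
  }
  d <- stats::runif(n, spec$diameter_um_range[1], spec$diameter_um_range[2])
  r <- spec$sphere_enlargement * d / 2
  xs <- ys <- zs <- numeric(n)
  attempts <- 0L
  max_attempts <- 500L * n
  placed <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf("cannot pack %d non-overlapping nuclei into the field", n))
    }
    i <- placed + 1L
    cand <- c(stats::runif(1, r[i], spec$field_um["x"] - r[i]),
              stats::runif(1, r[i], spec$field_um["y"] - r[i]),
              stats::runif(1, min(r[i], spec$field_um["z"] / 2),
                           max(spec$field_um["z"] - r[i], spec$field_um["z"] / 2)))
    ok <- TRUE
    if (!spec$allow_overlap && placed > 0L) {
      dd <- sqrt((xs[1:placed] - cand[1])^2 + (ys[1:placed] - cand[2])^2 +
                   (zs[1:placed] - cand[3])^2)
      # one extra lateral voxel of clearance keeps rasterised spheres disjoint
      ok <- all(dd > r[1:placed] + r[i] + spec$voxel_um["x"])
    }
    if (ok) {
      xs[i] <- cand[1]; ys[i] <- cand[2]; zs[i] <- cand[3]
      placed <- i
    }
  }
  data.frame(cell_id = seq_len(n), x_um = xs, y_um = ys, z_um = zs, diameter_um = d)
}

# mark voxels whose centres lie within `radius_vox` voxels of sampled points
# (points in µm); returns the updated logical array (z, y, x)
rasterize_points <- function(mask, pts, voxel_um) {
  if (nrow(pts) == 0) return(mask)
  d <- dim(mask)
  ix <- pmin(pmax(ceiling(pts[, 1] / voxel_um["x"]), 1L), d[3])
  iy <- pmin(pmax(ceiling(pts[, 2] / voxel_um["y"]), 1L), d[2])
  iz <- pmin(pmax(ceiling(pts[, 3] / voxel_um["z"]), 1L), d[1])
  offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0),
                c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (k in seq_len(nrow(offs))) {
    jx <- ix + offs[k, 1]; jy <- iy + offs[k, 2]; jz <- iz + offs[k, 3]
    keep <- jx >= 1 & jx <= d[3] & jy >= 1 & jy <= d[2] & jz >= 1 & jz <= d[1]
    if (any(keep)) {
      mask[cbind(jz[keep], jy[keep], jx[keep])] <- TRUE
    }
  }
  mask
}

# sample points densely along a polyline (rows = vertices, µm)
sample_polyline <- function(verts, spacing) {
  if (nrow(verts) < 2) return(verts)
  out <- list()
  for (i in seq_len(nrow(verts) - 1)) {
    a <- verts[i, ]; b <- verts[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / spacing) + 1L))
    out[[i]] <- cbind(a[1] + ts * (b[1] - a[1]),
                      a[2] + ts * (b[2] - a[2]),
                      a[3] + ts * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

# persistent 3D random walk constrained to the field
axon_walk <- function(spec, n_steps) {
  f <- spec$field_um
  pos <- c(stats::runif(1, 0, f["x"]), stats::runif(1, 0, f["y"]),
           stats::runif(1, f["z"] * 0.2, f["z"] * 0.8))
  dir <- stats::rnorm(3) * c(1, 1, 0.2)  # axons run mostly laterally
  dir <- dir / sqrt(sum(dir^2))
  verts <- matrix(0, n_steps + 1, 3)
  verts[1, ] <- pos
  for (s in seq_len(n_steps)) {
    dir <- dir + stats::rnorm(3, sd = 0.35) * c(1, 1, 0.2)
    dir <- dir / sqrt(sum(dir^2))
    pos <- pos + dir * spec$axon_step_um
    # reflect at the field boundary
    for (ax in 1:3) {
      if (pos[ax] < 0) { pos[ax] <- -pos[ax]; dir[ax] <- -dir[ax] }
      if (pos[ax] > f[ax]) { pos[ax] <- 2 * f[ax] - pos[ax]; dir[ax] <- -dir[ax] }
    }
    verts[s + 1, ] <- pos
  }
  verts
}

#' Generate a synthetic skin stack with ground truth
#'
#' Renders a two-channel stack (`"nuclear"`, `"axon"`): ellipsoidal nuclei as
#' anisotropic Gaussian blobs (sigma = diameter / 4, truncated at 2 sigma) at
#' ground-truth centroids, and filamentous axons as persistent random walks
#' rasterised into 1-voxel-radius tubes with spherical varicosities.
#' Innervation is enforced constructively: every truth-innervated cell gets
#' an axon branch ending in a varicosity inside its scoring sphere, and all
#' axon voxels are carved out of the scoring spheres of non-innervated cells,
#' so the truth flags are exact by construction.
#'
#' @param spec a [sim_stack_spec()].
#' @param render if `FALSE`, skip rendering the intensity channels (the
#'   returned `stack` is `NULL`); the ground truth and axon mask are
#'   identical to a rendered run with the same seed. Useful for large
#'   geometry-only simulations.
#' @return list with elements `stack` (an [image_stack()]), `truth` (data
#'   frame: `cell_id`, `x_um`, `y_um`, `z_um`, `diameter_um`, `innervated`,
#'   `converted`, `lineage`), `axon_mask` (logical `(z, y, x)` array, the
#'   noiseless rasterised axons) and `axons` (list of polyline vertex
#'   matrices).
#' @export
generate_skin_stack <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "sim_stack_spec"))
  local_seed(spec$seed, {
    vx <- spec$voxel_um
    dims <- c(z = max(1L, round(spec$field_um["z"] / vx["z"])),
              y = max(1L, round(spec$field_um["y"] / vx["y"])),
              x = max(1L, round(spec$field_um["x"] / vx["x"])))
    cells <- place_cells(spec)
    n <- nrow(cells)
    cells$innervated <- if (n) stats::runif(n) < spec$p_inn else logical(0)
    cells$converted <- if (n) stats::runif(n) < spec$p_converted else logical(0)
    cells$lineage <- if (n) stats::runif(n) < spec$p_lineage else logical(0)
    radius <- spec$sphere_enlargement * cells$diameter_um / 2

    # --- axon channel: background walks + constructive innervation ---
    axons <- list()
    pts_acc <- list()
    n_steps <- ceiling(1.5 * max(spec$field_um[c("x", "y")]) / spec$axon_step_um)
    if (spec$n_axons > 0) {
      for (a in seq_len(spec$n_axons)) {
        verts <- axon_walk(spec, n_steps)
        axons[[a]] <- verts
        pts_acc[[length(pts_acc) + 1L]] <- sample_polyline(verts, spacing = min(vx) / 2)
        vari <- verts[stats::runif(nrow(verts)) < spec$varicosity_rate, , drop = FALSE]
        if (nrow(vari) > 0) {
          # a varicosity is a ~1 µm bead: stamp a small jittered cloud
          cloud <- vari[rep(seq_len(nrow(vari)), each = 6L), , drop = FALSE] +
            matrix(stats::rnorm(6L * nrow(vari) * 3, sd = 0.5), ncol = 3)
          pts_acc[[length(pts_acc) + 1L]] <- rbind(vari, cloud)
        }
      }
    }
    if (n > 0 && any(cells$innervated)) {
      for (i in which(cells$innervated)) {
        ctr <- c(cells$x_um[i], cells$y_um[i], cells$z_um[i])
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        inner <- ctr + u * (0.4 * radius[i])       # point inside the sphere
        outer <- ctr + u * (radius[i] + 4)          # approach from outside
        pts_acc[[length(pts_acc) + 1L]] <-
          sample_polyline(rbind(outer, inner), spacing = min(vx) / 2)
        axons[[length(axons) + 1L]] <- rbind(outer, inner)
      }
    }
    axon_mask <- array(FALSE, dim = unname(dims))
    if (length(pts_acc)) {
      axon_mask <- rasterize_points(axon_mask, do.call(rbind, pts_acc), vx)
    }
    if (n > 0 && any(!cells$innervated)) {
      # carve every axon voxel out of non-innervated scoring spheres
      w <- which(axon_mask, arr.ind = TRUE)
      if (nrow(w) > 0) {
        cx <- (w[, 3] - 0.5) * vx["x"]
        cy <- (w[, 2] - 0.5) * vx["y"]
        cz <- (w[, 1] - 0.5) * vx["z"]
        drop <- rep(FALSE, nrow(w))
        for (i in which(!cells$innervated)) {
          dd2 <- (cx - cells$x_um[i])^2 + (cy - cells$y_um[i])^2 + (cz - cells$z_um[i])^2
          drop <- drop | dd2 <= radius[i]^2
        }
        if (any(drop)) axon_mask[w[drop, , drop = FALSE]] <- FALSE
      }
    }

    if (!render) {
      return(list(stack = NULL, truth = cells, axon_mask = axon_mask,
                  axons = axons))
    }

    # --- nuclear channel: truncated anisotropic Gaussian blobs ---
    nuc <- array(0, dim = unname(dims))
    if (n > 0) {
      for (i in seq_len(n)) {
        sig <- cells$diameter_um[i] / 4
        ext <- 2 * sig  # truncate at 2 sigma
        rng <- function(center, vox, lim) {
          lo <- max(1L, floor((center - ext) / vox))
          hi <- min(lim, ceiling((center + ext) / vox))
          lo:hi
        }
        px <- rng(cells$x_um[i], vx["x"], dims["x"])
        py <- rng(cells$y_um[i], vx["y"], dims["y"])
        pz <- rng(cells$z_um[i], vx["z"], dims["z"])
        gx <- exp(-((px - 0.5) * vx["x"] - cells$x_um[i])^2 / (2 * sig^2))
        gy <- exp(-((py - 0.5) * vx["y"] - cells$y_um[i])^2 / (2 * sig^2))
        gz <- exp(-((pz - 0.5) * vx["z"] - cells$z_um[i])^2 / (2 * sig^2))
        blob <- outer(gz, outer(gy, gx))  # (z, y, x) patch
        r2 <- outer(((pz - 0.5) * vx["z"] - cells$z_um[i])^2,
                    outer(((py - 0.5) * vx["y"] - cells$y_um[i])^2,
                          ((px - 0.5) * vx["x"] - cells$x_um[i])^2, `+`), `+`)
        blob[r2 > ext^2] <- 0
        nuc[pz, py, px] <- pmax(nuc[pz, py, px], spec$signal * blob)
      }
    }

    data <- array(0, dim = c(2L, unname(dims)))
    data[1, , , ] <- nuc + spec$background
    data[2, , , ] <- axon_mask * spec$signal + spec$background
    if (spec$noise_sd > 0) {
      data <- data + stats::rnorm(length(data), sd = spec$noise_sd)
    }
    if (spec$poisson_noise) {
      data <- array(stats::rpois(length(data), lambda = pmax(data, 0)), dim = dim(data))
    }
    data[data < 0] <- 0
    stack <- image_stack(data, vx, channels = c("nuclear", "axon"))
    list(stack = stack, truth = cells, axon_mask = axon_mask, axons = axons)
  })
}

#' Specification for a photoconversion pulse-chase simulation
#'
#' Emulates the pulse-chase design: a region is photoconverted at day 0
#' (`n0` converted cells, no new cells), then every interval each surviving
#' converted cell is lost with probability `p_loss` and `Poisson(lambda_add)`
#' new, non-converted cells are added. The defaults mirror the published
#' experiment: ~15% of converted cells lost per 7-day interval, with
#' additions balancing losses so the total stays nearly constant.
#'
#' @param n0 converted cells at day 0.
#' @param p_loss per-interval loss probability of a converted cell.
#' @param lambda_add expected new cells per interval.
#' @param interval_days interval length in days (default 7).
#' @param n_timepoints number of timepoints including day 0 (default 5, i.e.
#'   0–28 days).
#' @param ratio_mean_converted,ratio_mean_new class means of the
#'   converted-channel intensity fraction for converted and new cells.
#' @param ratio_sd within-class sd of the intensity fraction.
#' @param seed integer seed.
#' @return a `turnover_sim_spec` list.
#' @export
turnover_sim_spec <- function(n0 = 60, p_loss = 0.15, lambda_add = 9,
                              interval_days = 7, n_timepoints = 5,
                              ratio_mean_converted = 0.8, ratio_mean_new = 0.05,
                              ratio_sd = 0.05, seed = 1L) {
  if (p_loss < 0 || p_loss > 1) stop("`p_loss` must be in [0, 1]")
  if (lambda_add < 0) stop("`lambda_add` must be non-negative")
  if (n0 < 0) stop("`n0` must be non-negative")
  if (n_timepoints < 1) stop("need at least one timepoint")
  structure(as.list(environment()), class = "turnover_sim_spec")
}

#' Generate a photoconversion time series with ground truth
#'
#' @param spec a [turnover_sim_spec()].
#' @param counts_only if `TRUE`, skip the per-cell intensity snapshots
#'   (`snapshots` is `NULL`); counts are identical to a full run with the
#'   same seed.
#' @return list with `snapshots` (one data frame per timepoint: `cell_id`,
#'   `converted` truth flag, `native_intensity`, `converted_intensity`) and
#'   `counts` (data frame `t_days`, `converted`, `new`, `total`).
#' @export
generate_photoconversion_series <- function(spec, counts_only = FALSE) {
  stopifnot(inherits(spec, "turnover_sim_spec"))
  local_seed(spec$seed, {
    snapshots <- vector("list", spec$n_timepoints)
    counts <- data.frame(t_days = (seq_len(spec$n_timepoints) - 1) * spec$interval_days,
                         converted = NA_integer_, new = NA_integer_,
                         total = NA_integer_)
    # phase 1: population dynamics (counts are independent of the intensity
    # draws, so `counts_only` runs reproduce the same counts)
    next_id <- spec$n0 + 1L
    conv_ids <- seq_len(spec$n0)
    new_ids <- integer(0)
    ids_at <- vector("list", spec$n_timepoints)
    flag_at <- vector("list", spec$n_timepoints)
    for (k in seq_len(spec$n_timepoints)) {
      if (k > 1) {
        survive <- stats::runif(length(conv_ids)) >= spec$p_loss
        conv_ids <- conv_ids[survive]
        added <- stats::rpois(1, spec$lambda_add)
        if (added > 0) {
          new_ids <- c(new_ids, seq.int(next_id, next_id + added - 1L))
          next_id <- next_id + added
        }
      }
      counts$converted[k] <- length(conv_ids)
      counts$new[k] <- length(new_ids)
      counts$total[k] <- length(conv_ids) + length(new_ids)
      ids_at[[k]] <- c(conv_ids, new_ids)
      flag_at[[k]] <- c(rep(TRUE, length(conv_ids)), rep(FALSE, length(new_ids)))
    }
    if (counts_only) return(list(snapshots = NULL, counts = counts))
    # phase 2: per-cell two-channel intensities
    total_int <- 1000
    for (k in seq_len(spec$n_timepoints)) {
      ids <- ids_at[[k]]; flag <- flag_at[[k]]
      ratio <- stats::rnorm(length(ids),
                            mean = ifelse(flag, spec$ratio_mean_converted,
                                          spec$ratio_mean_new),
                            sd = spec$ratio_sd)
      ratio <- pmin(pmax(ratio, 0), 1)
      snapshots[[k]] <- data.frame(
        cell_id = ids,
        converted = flag,
        native_intensity = (1 - ratio) * total_int,
        converted_intensity = ratio * total_int
      )
    }
    list(snapshots = snapshots, counts = counts)
  })
}

#' Specification for a density-vs-standard-length cohort simulation
#'
#' Per-fish trunk Merkel-cell densities following a bilinear (one-breakpoint)
#' mean with optional genotype main effect and genotype x SL interaction and
#' Gaussian residual noise. The default breakpoint of 8.27 mm SL and design
#' size n = 52 fish mirror the published developmental cohort; slopes are
#' near-flat below the breakpoint and steep above it, matching the onset of
#' squamation.
#'
#' @param n_per_genotype fish per genotype (length 1 or 2).
#' @param genotypes genotype labels; the first is the reference.
#' @param sl_range_mm standard length range (mm), sampled uniformly.
#' @param b0 density intercept at SL = 0 (cells per 10^4 µm²).
#' @param s1,s2 slopes below / above the breakpoint (cells per 10^4 µm² per mm).
#' @param psi_mm breakpoint (mm SL); must lie inside `sl_range_mm`.
#' @param genotype_effect additive genotype main effect (second genotype).
#' @param interaction_effect genotype x SL interaction slope (second genotype).
#' @param sigma residual standard deviation; >= 0.
#' @param seed integer seed.
#' @return a `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n_per_genotype = 52, genotypes = "sibling",
                            sl_range_mm = c(6, 16),
                            b0 = 0.3, s1 = 0.05, s2 = 1.5, psi_mm = 8.27,
                            genotype_effect = 0, interaction_effect = 0,
                            sigma = 0.4, seed = 1L) {
  if (diff(range(sl_range_mm)) <= 0) stop("`sl_range_mm` must be a nonempty range")
  if (psi_mm <= sl_range_mm[1] || psi_mm >= sl_range_mm[2]) {
    stop("`psi_mm` must lie strictly inside `sl_range_mm`")
  }
  if (sigma < 0) stop("`sigma` must be non-negative")
  if (length(n_per_genotype) == 1L) {
    n_per_genotype <- rep(n_per_genotype, length(genotypes))
  }
  if (length(n_per_genotype) != length(genotypes)) {
    stop("`n_per_genotype` must match `genotypes`")
  }
  structure(as.list(environment()), class = "cohort_sim_spec")
}

#' Bilinear mean density at given standard lengths
#'
#' `mu(SL) = b0 + s1 * SL + (s2 - s1) * (SL - psi)+`, i.e. a continuous
#' one-breakpoint piecewise-linear function.
#'
#' @param sl standard lengths (mm).
#' @param spec a [cohort_sim_spec()].
#' @param genotype_index 1 for the reference genotype, 2 for the second.
#' @return numeric vector of mean densities.
#' @export
cohort_mean_density <- function(sl, spec, genotype_index = 1L) {
  mu <- spec$b0 + spec$s1 * sl + (spec$s2 - spec$s1) * pmax(sl - spec$psi_mm, 0)
  if (genotype_index > 1L) {
    mu <- mu + spec$genotype_effect + spec$interaction_effect * sl
  }
  mu
}

#' Generate a per-fish cohort table
#'
#' @param spec a [cohort_sim_spec()].
#' @return data frame: `fish_id`, `sl_mm`, `genotype`, `density`
#'   (cells per 10^4 µm²), `true_mean`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  local_seed(spec$seed, {
    rows <- list()
    fid <- 0L
    for (g in seq_along(spec$genotypes)) {
      n <- spec$n_per_genotype[g]
      sl <- stats::runif(n, spec$sl_range_mm[1], spec$sl_range_mm[2])
      mu <- cohort_mean_density(sl, spec, genotype_index = g)
      dens <- mu + stats::rnorm(n, sd = spec$sigma)
      rows[[g]] <- data.frame(fish_id = fid + seq_len(n), sl_mm = sl,
                              genotype = spec$genotypes[g],
                              density = dens, true_mean = mu)
      fid <- fid + n
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate scale outlines with Merkel-cell point sets
#'
#' Each scale is a closed polygon shaped like a zebrafish scale: a rounded
#' disc whose anterior (left) edge carries `n_lobes` lobes, with the
#' posterior (right) arc flagged as the posterior margin. Points are sampled
#' inside the polygon by rejection under a configurable spatial intensity.
#'
#' @param n_scales number of scales (>= 1).
#' @param points_per_scale Merkel cells per scale.
#' @param radius_um nominal scale radius (µm).
#' @param n_lobes lobes on the anterior margin (0 = smooth).
#' @param lobe_depth relative radial amplitude of the lobes.
#' @param n_vertices vertices in each outline polygon.
#' @param intensity optional `function(x, y)` giving a relative sampling
#'   intensity (need not be normalised); `NULL` = uniform.
#' @param jitter_um sd of per-scale random translation of the outline centre,
#'   emulating placement variability across fish.
#' @param seed integer seed.
#' @return list with `outlines` (data frame `scale_id`, `vertex_index`,
#'   `x_um`, `y_um`, `is_posterior_margin`) and `points` (data frame
#'   `scale_id`, `x_um`, `y_um`).
#' @export
generate_scale_field <- function(n_scales = 1, points_per_scale = 30,
                                 radius_um = 150, n_lobes = 2,
                                 lobe_depth = 0.15, n_vertices = 72,
                                 intensity = NULL, jitter_um = 20, seed = 1L) {
  if (n_scales < 1) stop("`n_scales` must be at least 1")
  local_seed(seed, {
    outlines <- list(); points <- list()
    for (s in seq_len(n_scales)) {
      ctr <- stats::rnorm(2, sd = jitter_um)
      th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
      r <- rep(radius_um, n_vertices)
      scale_stretch <- stats::runif(1, 0.9, 1.1)
      # anterior lobes: radial modulation on the left half (|theta| > pi/2)
      anterior <- cos(th) < 0
      if (n_lobes > 0) {
        r[anterior] <- r[anterior] *
          (1 + lobe_depth * abs(sin(n_lobes * th[anterior] / 2 + pi / 2)))
      }
      x <- ctr[1] + r * cos(th) * scale_stretch
      y <- ctr[2] + r * sin(th)
      if (0.5 * (abs(polygon_area(x, y))) <= 0) stop("degenerate scale outline")
      # posterior margin: the arc with |theta| <= pi/4 around theta = 0
      post <- cos(th) > cos(pi / 4)
      outlines[[s]] <- data.frame(scale_id = s, vertex_index = seq_len(n_vertices),
                                  x_um = x, y_um = y, is_posterior_margin = post)
      pts <- sample_in_polygon(x, y, points_per_scale, intensity)
      if (nrow(pts)) {
        points[[s]] <- data.frame(scale_id = s, x_um = pts[, 1], y_um = pts[, 2])
      }
    }
    list(outlines = do.call(rbind, outlines),
         points = if (length(points)) do.call(rbind, points) else
           data.frame(scale_id = integer(0), x_um = numeric(0), y_um = numeric(0)))
  })
}

# signed area (shoelace); > 0 for counter-clockwise vertex order
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param px,py point coordinates (vectors).
#' @param vx,vy polygon vertices (closed implicitly).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    if (any(cross)) {
      xint <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      flip <- cross & (px < xint)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

# rejection-sample points inside a polygon under a relative intensity
sample_in_polygon <- function(vx, vy, n, intensity = NULL) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  bx <- range(vx); by <- range(vy)
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  guard <- 0L
  # upper bound of the intensity over the bounding box, for rejection
  imax <- if (is.null(intensity)) 1 else {
    gx <- seq(bx[1], bx[2], length.out = 40)
    gy <- seq(by[1], by[2], length.out = 40)
    max(outer(gx, gy, intensity)) * 1.05
  }
  while (got < n) {
    guard <- guard + 1L
    if (guard > 10000L) stop("rejection sampling failed; check the intensity function")
    m <- 4L * (n - got) + 16L
    cx <- stats::runif(m, bx[1], bx[2])
    cy <- stats::runif(m, by[1], by[2])
    ok <- point_in_polygon(cx, cy, vx, vy)
    if (!is.null(intensity)) {
      ok <- ok & stats::runif(m) < intensity(cx, cy) / imax
    }
    take <- which(ok)
    if (length(take)) {
      take <- take[seq_len(min(length(take), n - got))]
      out[got + seq_along(take), ] <- cbind(cx[take], cy[take])
      got <- got + length(take)
    }
  }
  out
}

#' Generate a mosaic lineage-label field
#'
#' Emulates a maximum projection of the lineage-reporter (DsRed) channel in a
#' mosaically recombined epidermis: the field is tiled into keratinocyte-
#' sized patches, each labelled with probability `coverage`; labelled patches
#' are bright, the rest background. With zero noise the Huang percent-area
#' measurement recovers `coverage` directly.
#'
#' @param coverage fraction of cells carrying the label, in [0, 1].
#' @param field_px field side length in pixels.
#' @param cell_px linear patch (keratinocyte) size in pixels.
#' @param background,signal intensity levels.
#' @param noise_sd additive Gaussian noise sigma.
#' @param seed integer seed.
#' @return list with `image` (matrix) and `true_coverage` (realised labelled
#'   fraction of patches).
#' @export
generate_mosaic_field <- function(coverage = 0.3, field_px = 256, cell_px = 16,
                                  background = 10, signal = 200, noise_sd = 0,
                                  seed = 1L) {
  if (coverage < 0 || coverage > 1) stop("`coverage` must be in [0, 1]")
  local_seed(seed, {
    nc <- ceiling(field_px / cell_px)
    lab <- matrix(stats::runif(nc * nc) < coverage, nc, nc)
    img <- matrix(background, field_px, field_px)
    idx <- cbind(as.vector(pmin(((row(img) - 1) %/% cell_px) + 1, nc)),
                 as.vector(pmin(((col(img) - 1) %/% cell_px) + 1, nc)))
    img[as.vector(lab[idx])] <- signal
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), sd = noise_sd)
    img[img < 0] <- 0
    list(image = img, true_coverage = mean(lab))
  })
}
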