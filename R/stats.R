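#' Ordinary least squares fit with CI band
#'
#' Simple linear regression `y ~ x` with the summaries reported alongside
#' the published scatterplots: slope, intercept, R², the regression
#' F-statistic on (1, n-2) df with its p-value, and a pointwise 95%
#' confidence band for the mean response.
#'
#' @param x,y numeric vectors (>= 3 points, `x` not constant).
#' @param conf confidence level for the band.
#' @param band_at x values at which to evaluate the CI band (default: sorted
#'   unique `x`).
#' @return list: `slope`, `intercept`, `r_squared`, `f_statistic`, `df`,
#'   `p_value`, `sigma`, `band` (data frame `x`, `fit`, `lower`, `upper`),
#'   and the underlying `lm` fit.
#' @export
linear_fit <- function(x, y, conf = 0.95, band_at = NULL) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("`x` is constant: singular design")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  if (is.null(band_at)) band_at <- sort(unique(x))
  pr <- stats::predict(fit, newdata = data.frame(x = band_at),
                       interval = "confidence", level = conf)
  fstat <- unname(sm$fstatistic)
  list(slope = unname(stats::coef(fit))[2],
       intercept = unname(stats::coef(fit))[1],
       r_squared = sm$r.squared,
       f_statistic = fstat[1],
       df = c(fstat[2], fstat[3]),
       p_value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
       sigma = sm$sigma,
       band = data.frame(x = band_at, fit = pr[, "fit"],
                         lower = pr[, "lwr"], upper = pr[, "upr"]),
       fit = fit)
}

# design matrix for the working model of the breakpoint iteration:
# y ~ x + (x - psi)+ + gap indicator
seg_design <- function(x, psi) {
  cbind(1, x, pmax(x - psi, 0), -as.numeric(x > psi))
}

#' One-breakpoint segmented (piecewise-linear) regression
#'
#' Iterative breakpoint estimation in the style of the `segmented` approach
#' used for the density-vs-standard-length analysis: starting from an
#' initial breakpoint, repeatedly fit the working model
#' `y ~ x + (x - psi)+ + V` (V the gap indicator `-1{x > psi}`) and update
#' `psi <- psi + gamma / beta`, where `gamma` is the gap coefficient and
#' `beta` the slope-change coefficient, until `|delta psi| < tol`. The
#' update is run from a grid of starting values (interior deciles of `x` by
#' default) and the solution with the lowest residual sum of squares wins
#' (exact ties: lowest psi). If no slope change is identifiable the result
#' falls back to plain OLS with `identifiable = FALSE`.
#'
#' Per-segment R² and F are from separate OLS fits restricted to each side
#' of the breakpoint.
#'
#' @param x,y numeric vectors (>= 6 points spanning a nondegenerate range).
#' @param init optional vector of starting breakpoints.
#' @param tol convergence tolerance on the breakpoint update.
#' @param max_iter maximum iterations per start.
#' @return object of class `segmented_fit`: `psi`, `intercept`, `slope1`,
#'   `slope2`, `rss`, `converged`, `iterations`, `identifiable`,
#'   `segment1`/`segment2` (per-side [linear_fit()] summaries or `NULL` if a
#'   side has < 3 points), and `ols` (the no-breakpoint fallback summary).
#' @export
segmented_fit <- function(x, y, init = NULL, tol = 1e-6, max_iter = 100L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 6) stop("need at least 6 points")
  if (diff(range(x)) <= 0) stop("`x` range is degenerate")
  xs <- sort(unique(x))
  # psi must keep at least two distinct x on each side to identify slopes
  lo <- xs[2]; hi <- xs[length(xs) - 1]
  prof_rss <- function(psi) {
    f <- stats::lm.fit(cbind(1, x, pmax(x - psi, 0)), y)
    sum(f$residuals^2)
  }
  if (is.null(init)) {
    # the profile RSS is piecewise smooth with kinks at the observed x, so
    # every local basin contains an inter-observation midpoint: start the
    # descent once per interval (capped by profile screening for large n)
    mids <- (xs[-1] + xs[-length(xs)]) / 2
    mids <- mids[mids >= lo & mids <= hi]
    if (length(mids) > 60) {
      mids <- mids[order(vapply(mids, prof_rss, numeric(1)))[1:60]]
    }
    init <- unique(c(stats::quantile(x, probs = seq(0.1, 0.9, by = 0.1),
                                     names = FALSE), mids))
  }
  run_from <- function(psi) {
    conv <- FALSE; it <- 0L
    rss_cur <- prof_rss(psi)
    while (it < max_iter) {
      it <- it + 1L
      X <- seg_design(x, psi)
      fit <- stats::lm.fit(X, y)
      beta <- fit$coefficients[3]
      gamma <- fit$coefficients[4]
      if (!is.finite(beta) || abs(beta) < 1e-10) return(NULL)
      step <- gamma / beta
      if (!is.finite(step)) return(NULL)
      # step halving: accept the update only if the profile RSS improves
      h <- 1
      repeat {
        psi_new <- min(max(psi + h * step, lo), hi)
        rss_new <- prof_rss(psi_new)
        if (rss_new <= rss_cur + 1e-12 || h < 1 / 1024) break
        h <- h / 2
      }
      if (rss_new > rss_cur + 1e-12) { conv <- TRUE; break }  # local minimum
      if (abs(psi_new - psi) < tol) { psi <- psi_new; rss_cur <- rss_new
        conv <- TRUE; break }
      psi <- psi_new; rss_cur <- rss_new
    }
    # final fit without the gap term: the constrained (continuous) model
    Xf <- cbind(1, x, pmax(x - psi, 0))
    ff <- stats::lm.fit(Xf, y)
    list(psi = psi, coef = ff$coefficients, rss = sum(ff$residuals^2),
         converged = conv, iterations = it)
  }
  cands <- Filter(Negate(is.null), lapply(init, run_from))
  # the profile minimum can also sit exactly at an observed x (a kink of the
  # piecewise-smooth profile), where the iterative update has no fixed
  # point: evaluate those candidates directly
  kinks <- xs[xs >= lo & xs <= hi]
  for (kp in kinks) {
    ff <- stats::lm.fit(cbind(1, x, pmax(x - kp, 0)), y)
    cands[[length(cands) + 1L]] <- list(psi = kp, coef = ff$coefficients,
                                        rss = sum(ff$residuals^2),
                                        converged = TRUE, iterations = 0L)
  }
  ols_fit <- linear_fit(x, y)
  if (length(cands) == 0) {
    return(structure(list(psi = NA_real_, intercept = ols_fit$intercept,
                          slope1 = ols_fit$slope, slope2 = ols_fit$slope,
                          rss = sum(stats::residuals(ols_fit$fit)^2),
                          converged = TRUE, iterations = 0L,
                          identifiable = FALSE, segment1 = NULL,
                          segment2 = NULL, ols = ols_fit),
                     class = "segmented_fit"))
  }
  rss <- vapply(cands, `[[`, numeric(1), "rss")
  psis <- vapply(cands, `[[`, numeric(1), "psi")
  best <- order(rss, psis)[1]
  b <- cands[[best]]
  # a breakpoint glued to the boundary of the admissible range, or a slope
  # change indistinguishable from zero, means no real breakpoint
  slope_change <- b$coef[3]
  se_y <- stats::sd(y)
  identifiable <- abs(slope_change) > 1e-8 * max(1, se_y / max(diff(range(x)), 1e-12))
  seg_sub <- function(side) {
    xi <- if (side == 1) x[x <= b$psi] else x[x > b$psi]
    yi <- if (side == 1) y[x <= b$psi] else y[x > b$psi]
    if (length(xi) >= 3 && stats::sd(xi) > 0) linear_fit(xi, yi) else NULL
  }
  structure(list(psi = unname(b$psi),
                 intercept = unname(b$coef[1]),
                 slope1 = unname(b$coef[2]),
                 slope2 = unname(b$coef[2] + b$coef[3]),
                 rss = b$rss,
                 converged = b$converged,
                 iterations = b$iterations,
                 identifiable = identifiable,
                 segment1 = seg_sub(1), segment2 = seg_sub(2),
                 ols = ols_fit),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("segmented_fit: no identifiable breakpoint; OLS fallback\n")
    cat(sprintf("  slope %.4g, intercept %.4g, R² %.3f\n",
                x$ols$slope, x$ols$intercept, x$ols$r_squared))
  } else {
    cat(sprintf("segmented_fit: breakpoint = %.4g\n", x$psi))
    cat(sprintf("  slope below %.4g, slope above %.4g (converged: %s, %d iter)\n",
                x$slope1, x$slope2, x$converged, x$iterations))
    for (s in 1:2) {
      seg <- if (s == 1) x$segment1 else x$segment2
      if (!is.null(seg)) {
        cat(sprintf("  segment %d: R² = %.3f, F = %.3g, p = %.3g\n",
                    s, seg$r_squared, seg$f_statistic, seg$p_value))
      }
    }
  }
  invisible(x)
}

#' Dense grid-search breakpoint estimator
#'
#' Independent reference estimator: evaluates the continuous one-breakpoint
#' model's residual sum of squares on a dense grid of candidate breakpoints
#' and returns the minimiser. Used to validate [segmented_fit()].
#'
#' @param x,y numeric vectors.
#' @param grid candidate breakpoints (default: 2000 points spanning the
#'   interior of the x range).
#' @return list `psi`, `rss`.
#' @export
segmented_grid_search <- function(x, y, grid = NULL) {
  xs <- sort(unique(x))
  if (is.null(grid)) {
    grid <- seq(xs[2], xs[length(xs) - 1], length.out = 2000)
  }
  rss <- vapply(grid, function(psi) {
    f <- stats::lm.fit(cbind(1, x, pmax(x - psi, 0)), y)
    sum(f$residuals^2)
  }, numeric(1))
  i <- which.min(rss)
  list(psi = grid[i], rss = rss[i])
}

#' Johnson-Neyman region of significance for a genotype x SL interaction
#'
#' Fits `y = b0 + b1 SL + b2 G + b3 SL G` (G a 0/1 genotype indicator) and
#' finds where the genotype difference `delta(SL) = b2 + b3 SL` is
#' significant at level `alpha` (two-sided, df = n - 4): the boundaries are
#' the real roots of `delta(SL)^2 = t_crit^2 Var(delta(SL))`, a quadratic in
#' SL. The significant sub-range(s) of the observed SL range are reported.
#'
#' @param sl standard lengths (mm).
#' @param genotype 0/1 indicator, factor or two-level character vector
#'   (first level = reference).
#' @param y response (density).
#' @param alpha significance level (default 0.05).
#' @return object of class `jn_result`: `coefficients`, `vcov`, `t_crit`,
#'   `df`, `boundaries` (numeric, possibly empty), `significant` (data frame
#'   of intervals `lo`, `hi` within the observed range), and `direction`.
#' @export
johnson_neyman <- function(sl, genotype, y, alpha = 0.05) {
  if (!is.numeric(genotype)) {
    genotype <- as.integer(factor(genotype)) - 1L
  }
  if (!all(genotype %in% c(0, 1))) stop("`genotype` must have exactly two levels")
  if (length(unique(genotype)) < 2) stop("both genotypes must be present")
  ok <- stats::complete.cases(sl, genotype, y)
  sl <- sl[ok]; genotype <- genotype[ok]; y <- y[ok]
  n <- length(y)
  fit <- stats::lm(y ~ sl * genotype)
  if (any(is.na(stats::coef(fit)))) stop("singular design")
  V <- stats::vcov(fit)
  b <- stats::coef(fit)
  bG <- b[["genotype"]]; bI <- b[["sl:genotype"]]
  vG <- V["genotype", "genotype"]
  vI <- V["sl:genotype", "sl:genotype"]
  vGI <- V["genotype", "sl:genotype"]
  df <- n - 4
  tc2 <- stats::qt(1 - alpha / 2, df)^2
  # (bG + bI s)^2 - tc2 (vG + 2 s vGI + s^2 vI) = 0
  A <- bI^2 - tc2 * vI
  B <- 2 * bG * bI - 2 * tc2 * vGI
  C <- bG^2 - tc2 * vG
  disc <- B^2 - 4 * A * C
  roots <- numeric(0)
  if (abs(A) < 1e-300) {
    if (abs(B) > 0) roots <- -C / B
  } else if (disc >= 0) {
    roots <- sort(((-B) + c(-1, 1) * sqrt(disc)) / (2 * A))
  }
  rng <- range(sl)
  tval <- function(s) (bG + bI * s) / sqrt(vG + 2 * s * vGI + s^2 * vI)
  # determine significant sub-intervals of the observed range
  edges <- sort(unique(c(rng, roots[roots > rng[1] & roots < rng[2]])))
  sig <- list()
  for (i in seq_len(length(edges) - 1)) {
    mid <- (edges[i] + edges[i + 1]) / 2
    if (tval(mid)^2 >= tc2) {
      sig[[length(sig) + 1L]] <- data.frame(lo = edges[i], hi = edges[i + 1])
    }
  }
  sig <- if (length(sig)) do.call(rbind, sig) else
    data.frame(lo = numeric(0), hi = numeric(0))
  # merge adjacent intervals
  if (nrow(sig) > 1) {
    keep <- list(sig[1, ])
    for (i in 2:nrow(sig)) {
      last <- keep[[length(keep)]]
      if (abs(sig$lo[i] - last$hi) < 1e-9) {
        keep[[length(keep)]]$hi <- sig$hi[i]
      } else keep[[length(keep) + 1L]] <- sig[i, ]
    }
    sig <- do.call(rbind, keep)
  }
  direction <- if (nrow(sig) == 0) "nowhere"
  else if (nrow(sig) == 1 && sig$lo[1] <= rng[1] + 1e-9 && sig$hi[1] >= rng[2] - 1e-9) "everywhere"
  else if (nrow(sig) == 1 && sig$hi[1] >= rng[2] - 1e-9) "above"
  else if (nrow(sig) == 1 && sig$lo[1] <= rng[1] + 1e-9) "below"
  else "between"
  structure(list(coefficients = b, vcov = V, t_crit = sqrt(tc2), df = df,
                 boundaries = roots[roots > rng[1] & roots < rng[2]],
                 significant = sig, direction = direction,
                 sl_range = rng, fit = fit),
            class = "jn_result")
}

#' @export
print.jn_result <- function(x, ...) {
  cat(sprintf("Johnson-Neyman: genotype difference significant %s", x$direction))
  if (length(x$boundaries)) {
    cat(sprintf(" (boundary at %s mm SL)",
                paste(sprintf("%.2f", x$boundaries), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' `F = MS_between / MS_within`; pairwise adjusted p-values from the
#' studentized range distribution at df = N - k, with the Tukey-Kramer
#' standard error for unbalanced groups (base R's `aov` + `TukeyHSD`).
#'
#' @param values numeric response.
#' @param groups grouping factor (>= 2 levels, each with >= 2 observations).
#' @return list: `f_statistic`, `df`, `p_value`, `tukey` (data frame
#'   `comparison`, `diff`, `lwr`, `upr`, `p_adj`), and the `aov` fit.
#' @export
oneway_anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 observations")
  fit <- stats::aov(values ~ groups)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(f_statistic = sm[["F value"]][1],
       df = c(sm[["Df"]][1], sm[["Df"]][2]),
       p_value = sm[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"],
                          row.names = NULL),
       fit = fit)
}

#' Rank test: Mann-Whitney (unpaired) or Wilcoxon signed-rank (paired)
#'
#' Unpaired: Mann-Whitney U with the exact distribution when feasible
#' (min(n) <= 8 guaranteed exact in the absence of ties) and the
#' tie-corrected normal approximation otherwise. Paired: Wilcoxon
#' signed-rank, exact for <= 25 nonzero pairs without ties. Two-sided.
#'
#' @param a,b numeric samples (`paired = TRUE` requires equal lengths).
#' @param paired logical.
#' @return list `statistic` (U or V), `p_value`, `method`.
#' @export
rank_test <- function(a, b, paired = FALSE) {
  if (length(a) == 0 || length(b) == 0) stop("empty input")
  if (paired && length(a) != length(b)) stop("paired mode requires equal lengths")
  if (paired && all(a - b == 0)) {
    warning("all paired differences are zero; degenerate test, p = 1")
    return(list(statistic = NA_real_, p_value = 1,
                method = "Wilcoxon signed rank (degenerate)"))
  }
  exact <- if (paired) sum(a - b != 0) <= 25 else min(length(a), length(b)) <= 8
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, paired = paired, exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = min(ht$p.value, 1),
       method = ht$method)
}

#' Boxplot summary following the plotting convention used throughout
#'
#' Median, first/third quartile hinges and whiskers extending no further
#' than 1.5 x IQR from the hinges; values beyond the whiskers are outliers.
#'
#' @param x numeric vector.
#' @return list `median`, `hinges` (lower, upper), `whiskers`
#'   (lower, upper), `outliers`.
#' @export
boxplot_summary <- function(x) {
  x <- x[is.finite(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  wl <- min(x[x >= q[1] - 1.5 * iqr])
  wu <- max(x[x <= q[3] + 1.5 * iqr])
  list(median = q[2], hinges = c(lower = q[1], upper = q[3]),
       whiskers = c(lower = wl, upper = wu),
       outliers = x[x < wl | x > wu])
}
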