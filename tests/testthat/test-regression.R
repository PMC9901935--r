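test_that("OLS summaries match the normal equations", {
  x <- c(1, 2, 3, 4); y <- 2 * x + 1
  f <- suppressWarnings(linear_fit(x, y))  # perfect fit warns harmlessly
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  set.seed(71)
  x <- runif(40, 0, 10); y <- 1.5 + 0.8 * x + rnorm(40)
  f2 <- linear_fit(x, y)
  # independent closed-form solution
  sxx <- sum((x - mean(x))^2)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  Fst <- (sum((y - mean(y))^2) - sum(res^2)) / (sum(res^2) / (40 - 2))
  expect_equal(f2$slope, b1, tolerance = 1e-12)
  expect_equal(f2$intercept, b0, tolerance = 1e-12)
  expect_equal(f2$r_squared, r2, tolerance = 1e-12)
  expect_equal(f2$f_statistic, Fst, tolerance = 1e-10)
  # CI band brackets the fitted line
  expect_true(all(f2$band$lower <= f2$band$fit & f2$band$fit <= f2$band$upper))
  # y unrelated to x: R² near zero
  y0 <- rnorm(200)
  expect_lt(linear_fit(runif(200), y0)$r_squared, 0.05)
  expect_error(linear_fit(rep(1, 5), rnorm(5)), "constant")
})

test_that("segmented fit recovers a noise-free breakpoint exactly", {
  set.seed(5)
  x <- sort(runif(60, 6, 16))
  psi <- 8.27
  y <- 0.3 + 0.1 * x + (3.0 - 0.1) * pmax(x - psi, 0)
  f <- suppressWarnings(segmented_fit(x, y))
  expect_true(f$identifiable)
  expect_lt(abs(f$psi - psi), 0.01)
  expect_equal(f$slope1, 0.1, tolerance = 1e-6)
  expect_equal(f$slope2, 3.0, tolerance = 1e-6)
  expect_equal(f$segment1$r_squared, 1, tolerance = 1e-9)
  expect_equal(f$segment2$r_squared, 1, tolerance = 1e-9)
})

test_that("a single straight line yields the OLS fallback", {
  set.seed(6)
  x <- sort(runif(30, 0, 10))
  y <- 2 + 0.5 * x
  f <- suppressWarnings(segmented_fit(x, y))
  expect_false(f$identifiable)
  expect_equal(f$ols$slope, 0.5, tolerance = 1e-9)
  expect_error(segmented_fit(1:4, 1:4), "at least 6")
})

test_that("iterative breakpoint equals the dense grid-search minimiser", {
  diffs <- vapply(1:40, function(s) {
    cs <- cohort_sim_spec(seed = 2000 + s)
    co <- generate_cohort(cs)
    f <- segmented_fit(co$sl_mm, co$density)
    g <- segmented_grid_search(co$sl_mm, co$density)
    abs(f$psi - g$psi)
  }, numeric(1))
  expect_lt(max(diffs), 0.05)
})

test_that("breakpoint recovery at the published design size", {
  # n = 52 fish, true breakpoint 8.27 mm, default per-fish density scatter
  psis <- vapply(1:60, function(s) {
    cs <- cohort_sim_spec(seed = 3000 + s)
    co <- generate_cohort(cs)
    segmented_fit(co$sl_mm, co$density)$psi
  }, numeric(1))
  expect_lt(median(abs(psis - 8.27)), 0.3)
})

test_that("Johnson-Neyman handles the degenerate direction cases", {
  set.seed(81)
  sl <- runif(60, 7, 19)
  g <- rep(0:1, each = 30)
  # large main effect, no interaction: significant everywhere
  y1 <- 1 + 0.5 * sl + 8 * g + rnorm(60, sd = 0.5)
  jn1 <- johnson_neyman(sl, g, y1)
  expect_equal(jn1$direction, "everywhere")
  # identical groups: significant nowhere
  y2 <- 1 + 0.5 * sl + rnorm(60, sd = 0.5)
  jn2 <- johnson_neyman(sl, g, y2)
  expect_equal(jn2$direction, "nowhere")
  expect_error(johnson_neyman(sl, rep(0, 60), y2), "both genotypes")
})

test_that("Johnson-Neyman boundaries equal a dense grid scan", {
  for (s in 1:25) {
    set.seed(5000 + s)
    n <- 40
    sl <- runif(n, 7, 19)
    g <- rep(0:1, each = n / 2)
    y <- 1 + 0.6 * sl + rnorm(1, 0, 2) * g + rnorm(1, 0, 0.4) * sl * g +
      rnorm(n, sd = 1.5)
    jn <- johnson_neyman(sl, g, y)
    grid <- oracle_jn_grid(sl, g, y)
    res <- diff(grid$grid[1:2])
    # significant set from the analytic intervals, evaluated on the grid
    insig <- rep(FALSE, length(grid$grid))
    if (nrow(jn$significant)) {
      for (i in seq_len(nrow(jn$significant))) {
        insig <- insig | (grid$grid >= jn$significant$lo[i] - res &
                            grid$grid <= jn$significant$hi[i] + res)
      }
    }
    mismatch <- mean(insig != grid$sig)
    expect_lt(mismatch, 0.002)  # agreement up to grid resolution
  }
})

test_that("one-way ANOVA matches hand computation and the t-test identity", {
  # all groups identical in mean with internal spread: F = 0
  v <- rep(c(1, 2, 3), 3)
  g <- rep(letters[1:3], each = 3)
  expect_equal(oneway_anova_tukey(v, g)$f_statistic, 0)

  # two groups: F equals the square of the pooled t statistic
  set.seed(91)
  a <- rnorm(12); b <- rnorm(15, 0.8)
  an <- oneway_anova_tukey(c(a, b), rep(c("a", "b"), c(12, 15)))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(an$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p_value, tt$p.value, tolerance = 1e-10)

  # 3 x 4 fixed table: hand SS decomposition
  tab <- list(g1 = c(10, 12, 11, 13), g2 = c(14, 15, 13, 16), g3 = c(9, 8, 10, 9))
  vals <- unlist(tab); grp <- rep(names(tab), each = 4)
  gm <- mean(vals)
  ssb <- sum(vapply(tab, function(v) 4 * (mean(v) - gm)^2, numeric(1)))
  ssw <- sum(vapply(tab, function(v) sum((v - mean(v))^2), numeric(1)))
  f_hand <- (ssb / 2) / (ssw / 9)
  an2 <- oneway_anova_tukey(vals, grp)
  expect_equal(an2$f_statistic, f_hand, tolerance = 1e-12)
  expect_equal(an2$df, c(2, 9))
  # Tukey HSD: adjusted p from the studentized range distribution
  ms_w <- ssw / 9
  q12 <- abs(mean(tab$g1) - mean(tab$g2)) / sqrt(ms_w / 4)
  p12 <- stats::ptukey(q12, 3, 9, lower.tail = FALSE)
  got <- an2$tukey$p_adj[an2$tukey$comparison == "g2-g1"]
  expect_equal(got, p12, tolerance = 1e-10)
  expect_error(oneway_anova_tukey(1:5, c("a", "a", "a", "a", "b")),
               "at least 2 observations")
})

test_that("rank tests match exhaustive enumeration on small samples", {
  # complete separation at n = m = 3: U = 0, exact two-sided p = 0.1
  rt <- rank_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(rt$statistic, 0)
  expect_equal(rt$p_value, 0.1, tolerance = 1e-12)
  # enumeration oracle: all C(6,3) assignments of ranks
  combs <- combn(6, 3)
  us <- apply(combs, 2, function(idx) sum(idx) - 6)  # rank sum - n(n+1)/2
  p_en <- mean(us <= 0) * 2
  expect_equal(rt$p_value, p_en, tolerance = 1e-12)
  # identical samples: maximal p
  expect_equal(rank_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1, tolerance = 1e-9)
  # paired mode delegates to the signed-rank machinery
  rp <- rank_test(2 * (1:6), 1:6, paired = TRUE)
  expect_equal(rp$statistic, 21)
  expect_error(rank_test(numeric(0), 1), "empty")
  expect_error(rank_test(1:3, 1:4, paired = TRUE), "equal lengths")
})

test_that("Mann-Whitney test has nominal type-I error", {
  set.seed(77)
  rej <- mean(replicate(2000, {
    rank_test(rnorm(15), rnorm(15))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("boxplot summaries follow the 1.5 IQR whisker convention", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 100)
  bs <- boxplot_summary(x)
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  expect_equal(unname(bs$hinges), q[c(1, 3)])
  expect_equal(bs$median, q[2])
  # whiskers reach the most extreme point within 1.5 IQR of the hinges
  expect_equal(unname(bs$whiskers), c(min(x[x >= q[1] - 1.5 * iqr]),
                                      max(x[x <= q[3] + 1.5 * iqr])))
  expect_equal(bs$outliers, 100)
})
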