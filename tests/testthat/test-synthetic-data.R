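test_that("stack generator is deterministic and validates its spec", {
  sp <- sim_stack_spec(field_um = c(60, 60, 16), n_cells = 8, seed = 9)
  a <- generate_skin_stack(sp)
  b <- generate_skin_stack(sp)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth, b$truth)
  expect_identical(a$axon_mask, b$axon_mask)
  # default lateral pixel size derives from the 500 px / 67,055 µm² field
  expect_equal(sim_stack_spec()$voxel_um[["x"]], sqrt(67055) / 500, tolerance = 1e-12)
  expect_equal(sim_stack_spec()$voxel_um[["x"]], 0.518, tolerance = 1e-3)
  expect_error(sim_stack_spec(p_inn = 1.2), "p_inn")
  expect_error(sim_stack_spec(diameter_um_range = c(0.5, 1)), "diameter")
  expect_error(sim_stack_spec(n_axons = 0, p_inn = 0.5), "n_axons")
  expect_error(sim_stack_spec(voxel_um = c(0, 1, 1)), "positive")
})

test_that("edge-case stacks behave as specified", {
  # empty field: pure background noise, empty truth
  sp0 <- sim_stack_spec(field_um = c(30, 30, 8), n_cells = 0, p_inn = 0,
                        n_axons = 0, seed = 3)
  s0 <- generate_skin_stack(sp0)
  expect_equal(nrow(s0$truth), 0)
  expect_false(any(s0$axon_mask))
  # probability-1 innervation: every truth flag set
  sp1 <- sim_stack_spec(field_um = c(100, 100, 20), n_cells = 50, p_inn = 1,
                        seed = 1)
  s1 <- generate_skin_stack(sp1, render = FALSE)
  expect_true(all(s1$truth$innervated))
  expect_equal(nrow(s1$truth), 50)
  # infeasible packing is reported, not silently truncated
  spx <- sim_stack_spec(field_um = c(20, 20, 10), n_cells = 200, seed = 1)
  expect_error(generate_skin_stack(spx, render = FALSE), "pack")
})

test_that("scoring the generated geometry reproduces the truth flags exactly", {
  for (s in 1:6) {
    sp <- sim_stack_spec(field_um = c(90, 90, 20), n_cells = 25,
                         p_inn = c(0.2, 0.5, 0.8)[s %% 3 + 1], seed = 200 + s)
    sim <- generate_skin_stack(sp, render = FALSE)
    sc <- score_innervation(sim$truth, sim$axon_mask, voxel_um = c(sp$voxel_um))
    expect_identical(sc$innervated_scored, sim$truth$innervated)
  }
})

test_that("generated innervation fraction is calibrated to p_inn", {
  p <- 0.7
  fr <- vapply(1:60, function(s) {
    sp <- sim_stack_spec(field_um = c(100, 100, 24), n_cells = 40, p_inn = p,
                         seed = 500 + s)
    mean(generate_skin_stack(sp, render = FALSE)$truth$innervated)
  }, numeric(1))
  se <- sqrt(p * (1 - p) / (40 * 60))
  expect_lt(abs(mean(fr) - p), 3 * se)
})

test_that("photoconversion series conserves counts and obeys edge cases", {
  # no dynamics: every timepoint identical to t0
  s0 <- generate_photoconversion_series(
    turnover_sim_spec(n0 = 30, p_loss = 0, lambda_add = 0, seed = 2))
  expect_true(all(s0$counts$converted == 30 & s0$counts$new == 0))
  # certain loss: zero converted cells at every t > 0
  s1 <- generate_photoconversion_series(
    turnover_sim_spec(n0 = 30, p_loss = 1, lambda_add = 3, seed = 2))
  expect_equal(s1$counts$converted[-1], rep(0L, 4))
  # conservation at every timepoint, and snapshots match counts
  s2 <- generate_photoconversion_series(turnover_sim_spec(seed = 8))
  expect_equal(s2$counts$converted + s2$counts$new, s2$counts$total)
  for (k in seq_along(s2$snapshots)) {
    expect_equal(sum(s2$snapshots[[k]]$converted), s2$counts$converted[k])
    expect_equal(nrow(s2$snapshots[[k]]), s2$counts$total[k])
  }
  # counts-only runs reproduce the same counts
  s2b <- generate_photoconversion_series(turnover_sim_spec(seed = 8),
                                         counts_only = TRUE)
  expect_identical(s2$counts, s2b$counts)
  expect_error(turnover_sim_spec(p_loss = 1.4), "p_loss")
})

test_that("converted survival is calibrated to the binomial expectation", {
  # n0 = 10000, 4 intervals, many seeds: remaining fraction ~ 0.85^k
  n_seeds <- 200
  rem <- sapply(1:n_seeds, function(s) {
    sp <- turnover_sim_spec(n0 = 10000, p_loss = 0.15, lambda_add = 0,
                            n_timepoints = 5, seed = s)
    generate_photoconversion_series(sp, counts_only = TRUE)$counts$converted / 10000
  })
  for (k in 1:4) {
    expected <- 0.85^k
    se <- sd(rem[k + 1, ]) / sqrt(n_seeds)
    expect_lt(abs(mean(rem[k + 1, ]) - expected), 3 * se + 1e-12)
  }
})

test_that("cohort generator reproduces the bilinear mean exactly at sigma = 0", {
  cs <- cohort_sim_spec(n_per_genotype = 30, sigma = 0, seed = 4)
  co <- generate_cohort(cs)
  expect_equal(co$density, cohort_mean_density(co$sl_mm, cs))
  expect_equal(co$density, co$true_mean)
  # parallel lines when the interaction coefficient is zero
  cs2 <- cohort_sim_spec(genotypes = c("a", "b"), n_per_genotype = 10,
                         genotype_effect = 2.5, interaction_effect = 0,
                         sigma = 0, seed = 4)
  co2 <- generate_cohort(cs2)
  d <- co2$true_mean[co2$genotype == "b"] -
    cohort_mean_density(co2$sl_mm[co2$genotype == "b"], cs2, genotype_index = 1)
  expect_equal(d, rep(2.5, 10))
  expect_error(cohort_sim_spec(psi_mm = 20), "psi")
  expect_error(cohort_sim_spec(sigma = -1), "sigma")
})

test_that("scale fields contain their points and mark the posterior margin", {
  sf <- generate_scale_field(n_scales = 1, points_per_scale = 1000,
                             n_lobes = 0, jitter_um = 0, seed = 12)
  o <- sf$outlines
  inside <- point_in_polygon(sf$points$x_um, sf$points$y_um, o$x_um, o$y_um)
  expect_true(all(inside))
  expect_true(any(o$is_posterior_margin))
  # posterior-margin vertices sit on the posterior (positive x) side
  expect_true(all(o$x_um[o$is_posterior_margin] > 0))
  expect_error(generate_scale_field(n_scales = 0), "n_scales")
})

test_that("spatially biased sampling respects a 3:1 intensity ratio", {
  # ray strip: |y| < 50; interray: elsewhere. Expected point ratio equals
  # 3 * (ray area) / (interray area); estimate areas by MC integration.
  intensity <- function(x, y) ifelse(abs(y) < 50, 3, 1)
  n_seeds <- 100
  frac <- vapply(1:n_seeds, function(s) {
    sf <- generate_scale_field(n_scales = 1, points_per_scale = 200,
                               n_lobes = 0, jitter_um = 0,
                               intensity = intensity, seed = s)
    mean(abs(sf$points$y_um) < 50)
  }, numeric(1))
  one <- generate_scale_field(1, 0, n_lobes = 0, jitter_um = 0, seed = 1)
  o <- one$outlines
  set.seed(77)
  gx <- runif(2e5, min(o$x_um), max(o$x_um))
  gy <- runif(2e5, min(o$y_um), max(o$y_um))
  ins <- point_in_polygon(gx, gy, o$x_um, o$y_um)
  a_ray <- mean(ins & abs(gy) < 50)
  a_int <- mean(ins & abs(gy) >= 50)
  p_exp <- 3 * a_ray / (3 * a_ray + a_int)
  se <- sd(frac) / sqrt(n_seeds)
  expect_lt(abs(mean(frac) - p_exp), 3 * se + 0.01)
})

test_that("mosaic fields reproduce the requested label coverage", {
  mz <- generate_mosaic_field(coverage = 0.3, seed = 7)
  expect_equal(percent_area(mz$image > 100), 100 * mz$true_coverage)
  full <- generate_mosaic_field(coverage = 1, seed = 7)
  expect_equal(mean(full$image > 100), 1)
})

test_that("stack round-trips through TIFF + YAML sidecar", {
  sp <- sim_stack_spec(field_um = c(30, 30, 6), n_cells = 3, seed = 5,
                       noise_sd = 0)
  sim <- generate_skin_stack(sp)
  td <- withr::local_tempdir()
  prefix <- file.path(td, "stack")
  write_stack(sim$stack, prefix)
  back <- read_stack(prefix)
  expect_equal(back$channels, sim$stack$channels)
  expect_equal(back$voxel_size, sim$stack$voxel_size)
  # 16-bit quantisation: relative error bounded by 1/65535 of the max
  expect_lt(max(abs(back$data - sim$stack$data)), max(sim$stack$data) / 65535 + 1e-9)
})
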