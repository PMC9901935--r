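test_that("max projection equals a per-pixel loop over z", {
  set.seed(11)
  arr <- array(runif(8 * 8 * 8), dim = c(1, 8, 8, 8))
  st <- image_stack(arr, c(1, 1, 1), channels = "nuc")
  proj <- max_project(st, "nuc")
  manual <- matrix(0, 8, 8)
  for (y in 1:8) for (x in 1:8) manual[y, x] <- max(arr[1, , y, x])
  expect_equal(proj, manual)

  # single slice: identity; single bright voxel: projects to its (y, x)
  one <- array(runif(16), dim = c(1, 4, 4))
  st1 <- image_stack(one, c(1, 1, 1))
  expect_equal(max_project(st1, 1), matrix(one[1, , ], 4, 4))
  spark <- array(0, dim = c(5, 6, 7)); spark[3, 4, 2] <- 9
  stk <- image_stack(spark, c(1, 1, 1))
  pr <- max_project(stk, 1)
  expect_equal(which(pr == 9, arr.ind = TRUE)[1, ], c(row = 4, col = 2))
  expect_error(max_project(st, "missing"), "unknown channel")
})

test_that("8-bit conversion is a clipped linear rescale with banker's rounding", {
  img <- matrix(0:255, 16, 16)
  expect_equal(convert_8bit(img, 0, 255), img, ignore_attr = TRUE)
  ramp <- matrix(c(0, 32768, 65535, seq(0, 65535, length.out = 253)), 16, 16)
  out <- convert_8bit(ramp, 0, 65535)
  expect_equal(out[2], round(32768 * 255 / 65535))
  expect_equal(out[1], 0L)
  expect_equal(out[3], 255L)
  expect_true(all(out >= 0 & out <= 255))
  # clipping below / above the display range
  expect_equal(unique(as.vector(convert_8bit(matrix(-5, 2, 2), 0, 10))), 0L)
  expect_equal(unique(as.vector(convert_8bit(matrix(99, 2, 2), 0, 10))), 255L)
  expect_error(convert_8bit(img, 5, 5), "exceed")
  expect_error(convert_8bit(img, 0, Inf), "finite")
})

test_that("Huang fuzzy entropy matches a hand evaluation on a 3-level histogram", {
  counts <- integer(256)
  counts[0 + 1] <- 4; counts[128 + 1] <- 2; counts[255 + 1] <- 4
  # hand evaluation of S(t) for every candidate t, per the formula
  hand <- oracle_huang(counts)
  expect_equal(mcskin:::huang_threshold_histogram(counts), hand)
  # perfectly bimodal histogram: both methods cut between the modes
  bim <- integer(256); bim[10 + 1] <- 50; bim[200 + 1] <- 50
  th <- mcskin:::huang_threshold_histogram(bim)
  to <- mcskin:::otsu_threshold_histogram(bim)
  expect_true(th >= 10 && th < 200)
  expect_true(to >= 10 && to < 200)
})

test_that("Huang and Otsu equal independent brute-force scans on random histograms", {
  set.seed(201)
  for (i in 1:50) {
    counts <- integer(256)
    k <- sample(3:40, 1)
    lv <- sample(0:255, k)
    counts[lv + 1] <- rpois(k, 30) + 1L
    expect_identical(mcskin:::huang_threshold_histogram(counts), oracle_huang(counts))
    expect_identical(mcskin:::otsu_threshold_histogram(counts), oracle_otsu(counts))
  }
})

test_that("Otsu threshold of a bimodal image agrees with EBImage", {
  skip_if_not_installed("EBImage")
  set.seed(77)
  v <- pmin(pmax(round(c(rnorm(2000, 80, 12), rnorm(1500, 180, 15))), 0L), 255L)
  img <- matrix(as.integer(v), 50, 70)
  ours <- global_threshold(img, "otsu")
  eb <- EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1), levels = 256)
  # EBImage reports a bin-midpoint; allow the one-bin convention offset
  expect_lt(abs(ours$level_8bit / 255 - eb), 2.5 / 255)
  expect_true(all((img > ours$level_8bit) == ours$mask$mask))
})

test_that("thresholds shift with a constant intensity offset", {
  set.seed(31)
  img <- matrix(sample(20:120, 400, replace = TRUE), 20, 20)
  for (m in c("huang", "otsu")) {
    t0 <- global_threshold(img, m)$level_8bit
    t1 <- global_threshold(img + 40L, m)$level_8bit
    expect_equal(t1, t0 + 40L)
  }
  expect_error(global_threshold(matrix(7, 4, 4)), "constant")
})

test_that("percent area counts foreground pixels", {
  expect_equal(percent_area(matrix(FALSE, 5, 5)), 0)
  expect_equal(percent_area(matrix(TRUE, 5, 5)), 100)
  m <- matrix(FALSE, 10, 10); m[1:5, 1:5] <- TRUE
  expect_equal(percent_area(m), 25)
  # monotone non-increasing in the threshold level
  set.seed(5)
  img <- matrix(sample(0:255, 900, TRUE), 30, 30)
  pa <- sapply(c(10, 60, 120, 200), function(t) percent_area(img > t))
  expect_true(all(diff(pa) <= 0))
})

test_that("particle analysis matches geometry and a flood-fill oracle", {
  # two separated 5x5 squares
  m <- matrix(FALSE, 20, 20); m[2:6, 2:6] <- TRUE; m[10:14, 12:16] <- TRUE
  pt <- analyze_particles(m, pixel_size = 0.5)
  expect_equal(nrow(pt), 2)
  expect_equal(pt$area_um2, rep(25 * 0.5^2, 2))
  expect_equal(nrow(analyze_particles(matrix(FALSE, 4, 4))), 0)
  expect_error(analyze_particles(m, min_area = 5, max_area = 1), "exceed")

  set.seed(99)
  for (i in 1:50) {
    mk <- matrix(runif(32 * 32) < 0.35, 32, 32)
    lab <- label_components(mk)
    ref <- oracle_label_2d(mk)
    # same partition (labels may be permuted): compare co-labelling
    expect_equal(max(lab), max(ref))
    expect_true(all(tapply(ref[mk], lab[mk], function(v) length(unique(v))) == 1))
    tab <- analyze_particles(mk, pixel_size = 1)
    ref_sizes <- sort(as.integer(table(ref[ref > 0])))
    expect_equal(sort(tab$area_um2), as.numeric(ref_sizes))
    # centroids match the oracle's per-component means
    ref_cent <- t(sapply(seq_len(max(ref)), function(l) {
      w <- which(ref == l, arr.ind = TRUE)
      c(x = mean(w[, 2] - 0.5), y = mean(w[, 1] - 0.5))
    }))
    ord1 <- order(tab$x_um, tab$y_um)
    ord2 <- order(ref_cent[, "x"], ref_cent[, "y"])
    expect_equal(tab$x_um[ord1], ref_cent[ord2, "x"], ignore_attr = TRUE)
    expect_equal(tab$y_um[ord1], ref_cent[ord2, "y"], ignore_attr = TRUE)
  }
})

test_that("particle count is invariant under translation and rotation", {
  set.seed(13)
  m <- matrix(runif(30 * 30) < 0.3, 30, 30)
  n0 <- nrow(analyze_particles(m))
  shifted <- matrix(FALSE, 40, 40); shifted[6:35, 9:38] <- m
  expect_equal(nrow(analyze_particles(shifted)), n0)
  rotated <- t(m[nrow(m):1, ])  # 90 degrees
  expect_equal(nrow(analyze_particles(rotated)), n0)
})

test_that("area filters select particles by physical size", {
  m <- matrix(FALSE, 30, 30)
  m[2:3, 2:3] <- TRUE           # 4 px
  m[10:17, 10:17] <- TRUE       # 64 px
  px <- 0.5                      # areas: 1 and 16 µm²
  expect_equal(nrow(analyze_particles(m, pixel_size = px)), 2)
  expect_equal(analyze_particles(m, min_area = 2, pixel_size = px)$area_um2, 16)
  expect_equal(analyze_particles(m, max_area = 2, pixel_size = px)$area_um2, 1)
})

test_that("3D detection recovers an isolated noise-free nucleus", {
  # one 8 µm sphere rendered directly (not via the generator)
  vx <- c(0.5, 0.5, 1)
  dims <- c(z = 24, y = 48, x = 48)
  ctr <- c(x = 12, y = 12, z = 12)
  arr <- array(0, dim = unname(dims))
  for (z in 1:dims["z"]) for (y in 1:dims["y"]) {
    xs <- (1:dims["x"] - 0.5) * vx[1]
    d2 <- (xs - ctr["x"])^2 + ((y - 0.5) * vx[2] - ctr["y"])^2 +
      ((z - 0.5) * vx[3] - ctr["z"])^2
    arr[z, y, ] <- ifelse(d2 <= 16, 1000, 0)
  }
  st <- image_stack(arr + 10, vx, channels = "nuclear")
  ct <- detect_cells_3d(st, "nuclear")
  expect_equal(nrow(ct), 1)
  expect_lt(abs(ct$x_um - ctr["x"]), 0.5 * vx[1] + 1e-9)
  expect_lt(abs(ct$y_um - ctr["y"]), 0.5 * vx[2] + 1e-9)
  expect_lt(abs(ct$z_um - ctr["z"]), 0.5 * vx[3] + 1e-9)
  expect_lt(abs(ct$diameter_um - 8), vx[1] + 1e-9)
})

test_that("3D detection matches generator truth on rendered stacks", {
  hits <- 0; truths <- 0; dets <- 0
  for (s in 1:5) {
    fx <- standard_fixture(seed = 100 + s)
    cells <- detect_cells_3d(fx$sim$stack, "nuclear")
    m <- match_cells(fx$sim$truth, cells, gate_um = 2)
    hits <- hits + sum(!is.na(m$id_a) & !is.na(m$id_b))
    truths <- truths + nrow(fx$sim$truth)
    dets <- dets + nrow(cells)
  }
  expect_gte(hits / truths, 0.98)  # recall
  expect_gte(hits / dets, 0.98)    # precision
})

test_that("overlapping nuclei merge into fewer detections and are QC-flagged", {
  vx <- c(0.5, 0.5, 1)
  arr <- array(0, dim = c(16, 40, 40))
  render_ball <- function(arr, ctr, r) {
    for (z in 1:16) for (y in 1:40) {
      xs <- (1:40 - 0.5) * 0.5
      d2 <- (xs - ctr[1])^2 + ((y - 0.5) * 0.5 - ctr[2])^2 + ((z - 0.5) - ctr[3])^2
      arr[z, y, ] <- pmax(arr[z, y, ], ifelse(d2 <= r^2, 800, 0))
    }
    arr
  }
  arr <- render_ball(arr, c(8, 8, 8), 3)
  arr <- render_ball(arr, c(12, 8, 8), 3)    # overlaps the first
  arr <- render_ball(arr, c(16, 16, 8), 1.5) # small, separate
  st <- image_stack(arr + 5, vx, channels = "nuclear")
  ct <- detect_cells_3d(st, "nuclear")
  expect_equal(nrow(ct), 2)  # merged pair counts once
  expect_true(length(attr(ct, "qc")$merged_candidates) >= 1)
})
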