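# Independent reference implementations used as oracles. These deliberately
# use the most literal, brute-force formulation available and share no code
# with the package internals.

# Huang fuzzy-entropy threshold: literal per-level evaluation of
# S(t) = -sum_g h(g) [mu ln mu + (1-mu) ln(1-mu)], mu = 1/(1+|g-m|/C)
oracle_huang <- function(counts) {
  g <- 0:255
  occupied <- which(counts > 0) - 1
  C <- max(occupied) - min(occupied)
  best_t <- NA_integer_
  best_s <- Inf
  for (t in min(occupied):(max(occupied) - 1)) {
    lo <- g <= t
    n0 <- sum(counts[lo]); n1 <- sum(counts[!lo])
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[lo] * g[lo]) / n0
    m1 <- sum(counts[!lo] * g[!lo]) / n1
    s <- 0
    for (gv in g) {
      if (counts[gv + 1] == 0) next
      m <- if (gv <= t) m0 else m1
      mu <- 1 / (1 + abs(gv - m) / C)
      e <- 0
      if (mu > 0 && mu < 1) e <- -(mu * log(mu) + (1 - mu) * log(1 - mu))
      s <- s + counts[gv + 1] * e
    }
    if (s < best_s - 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# Otsu: literal between-class variance scan
oracle_otsu <- function(counts) {
  g <- 0:255
  n <- sum(counts)
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:254) {
    lo <- g <= t
    w0 <- sum(counts[lo]) / n; w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[lo] * g[lo]) / sum(counts[lo])
    m1 <- sum(counts[!lo] * g[!lo]) / sum(counts[!lo])
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# flood-fill (explicit stack) connected-component labelling, 8-connectivity
oracle_label_2d <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      todo <- list(c(i, j))
      lab[i, j] <- cur
      while (length(todo)) {
        p <- todo[[length(todo)]]
        todo[[length(todo)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            todo[[length(todo) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# exhaustive all-voxel innervation scan: for every cell, test every true
# voxel centre against the sphere
oracle_innervation <- function(cells, mask, voxel_um, enlargement = 1.1) {
  w <- which(mask, arr.ind = TRUE)  # (z, y, x)
  cx <- (w[, 3] - 0.5) * voxel_um[1]
  cy <- (w[, 2] - 0.5) * voxel_um[2]
  cz <- (w[, 1] - 0.5) * voxel_um[3]
  vapply(seq_len(nrow(cells)), function(i) {
    r <- enlargement * cells$diameter_um[i] / 2
    any((cx - cells$x_um[i])^2 + (cy - cells$y_um[i])^2 +
          (cz - cells$z_um[i])^2 <= r^2)
  }, logical(1))
}

# closed-form Wilson score interval
oracle_wilson <- function(k, n, z = qnorm(0.975)) {
  p <- k / n
  c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n),
    (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n))
}

# Johnson-Neyman by brute force: test the genotype contrast on a dense grid
oracle_jn_grid <- function(sl, genotype, y, alpha = 0.05, n_grid = 1e4) {
  g <- as.integer(factor(genotype)) - 1L
  fit <- lm(y ~ sl * g)
  V <- vcov(fit); b <- coef(fit)
  tc <- qt(1 - alpha / 2, length(y) - 4)
  grid <- seq(min(sl), max(sl), length.out = n_grid)
  tval <- (b[["g"]] + b[["sl:g"]] * grid) /
    sqrt(V["g", "g"] + 2 * grid * V["g", "sl:g"] + grid^2 * V["sl:g", "sl:g"])
  sig <- abs(tval) >= tc
  list(grid = grid, sig = sig)
}

# standard fixture used across tests: a small rendered stack
standard_fixture <- function(seed = 42, n_cells = 50, p_inn = 0.6) {
  sp <- sim_stack_spec(field_um = c(120, 120, 24), n_cells = n_cells,
                       p_inn = p_inn, noise_sd = 15, seed = seed)
  list(spec = sp, sim = generate_skin_stack(sp))
}
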