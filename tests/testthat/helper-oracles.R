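# Test helpers: independent oracles and small generators. These deliberately
# avoid the package's complex-arithmetic code paths.

# random landmark configuration
rand_shape <- function(p = 26, spread = 100) {
  matrix(stats::rnorm(2 * p, 0, spread), p, 2)
}

# apply a rigid (or similarity) transform to a p x 2 configuration
apply_similarity <- function(cfg, theta = 0, scale = 1, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  sweep(cfg %*% t(R) * scale, 2, shift, "+")
}

# brute-force Procrustes distance: grid over the rotation angle plus
# golden-section refinement, all in real arithmetic
proc_dist_grid <- function(a, b, n_grid = 720) {
  ctr <- function(m) sweep(m, 2, colMeans(m))
  a <- ctr(a); b <- ctr(b)
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  f <- function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    sqrt(sum((a %*% t(R) - b)^2))
  }
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)
  vals <- vapply(grid, f, 0)
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  stats::optimize(f, c(lo, hi), tol = 1e-14)$objective
}

# permutation one-way ANOVA p-value (F statistic, label shuffling)
perm_anova_p <- function(y, g, B = 2000) {
  fstat <- function(yy) {
    m <- tapply(yy, g, mean); n <- tapply(yy, g, length)
    gm <- mean(yy)
    ssb <- sum(n * (m - gm)^2); ssw <- sum((yy - m[g])^2)
    k <- length(m)
    (ssb / (k - 1)) / (ssw / (length(yy) - k))
  }
  obs <- fstat(y)
  cnt <- sum(vapply(seq_len(B), function(i) fstat(sample(y)) >= obs, NA))
  (cnt + 1) / (B + 1)
}

# permutation oracle for Tukey-type familywise pairwise p-values: the
# permutation distribution of the maximum studentized-range statistic
perm_tukey_p <- function(y, g, B = 4000) {
  g <- factor(g)
  k <- nlevels(g)
  qstat <- function(yy) {
    m <- tapply(yy, g, mean); n <- tapply(yy, g, length)
    mse <- sum((yy - m[g])^2) / (length(yy) - k)
    cmb <- utils::combn(k, 2)
    q <- abs(m[cmb[1, ]] - m[cmb[2, ]]) /
      sqrt(mse / 2 * (1 / n[cmb[1, ]] + 1 / n[cmb[2, ]]))
    q
  }
  obs <- qstat(y)
  maxq <- vapply(seq_len(B), function(i) max(qstat(sample(y))), 0)
  p <- vapply(obs, function(q) (sum(maxq >= q) + 1) / (B + 1), 0)
  cmb <- utils::combn(levels(g), 2)
  stats::setNames(p, paste(cmb[2, ], cmb[1, ], sep = "-"))
}

# standard three-group simulated dataset used across shape tests
sim_three_groups <- function(n = 12, seed = 42, effect = 1) {
  simulate_dataset(data.frame(label = c("WT", "Het", "Mut"),
                              n = rep(n, 3),
                              preset = c("none", "none", "mutant"),
                              effect_scale = c(0, 0, effect)),
                   seed = seed)
}
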