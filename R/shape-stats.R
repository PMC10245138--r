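# flatten aligned coords to an n x 2p real matrix (x1..xp then y1..yp)
aligned_matrix <- function(al) {
  p <- dim(al$coords)[1]
  cbind(t(al$coords[, 1, ]), t(al$coords[, 2, ]))
}

#' Shape principal component analysis
#'
#' Covariance-matrix PCA of the Procrustes coordinates. Eigenvectors are
#' per-landmark displacement fields; for 2D Procrustes-superimposed,
#' tangent-projected data the four similarity degrees of freedom (two
#' translations, scale, rotation) carry exactly zero variance, so at most
#' `2p - 4` eigenvalues are non-trivial.
#'
#' @param al an `ff_aligned` (or the symmetric component via
#'   [symmetric_shapes()]).
#' @return `ff_shape_pca`: eigenvalues, variance fractions, `scores`
#'   (specimens x components), `loadings` (2p x components) and
#'   `displacements` (p x 2 x components displacement fields), plus the
#'   consensus.
#' @export
shape_pca <- function(al) {
  X <- aligned_matrix(al)
  n <- nrow(X)
  if (n < 3) stop("shape PCA needs at least 3 specimens")
  p <- dim(al$coords)[1]
  Xc <- sweep(X, 2, colMeans(X))
  eg <- eigen(stats::cov(Xc), symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  V <- eg$vectors
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  disp <- array(NA_real_, c(p, 2, ncol(V)))
  disp[, 1, ] <- V[seq_len(p), ]
  disp[, 2, ] <- V[p + seq_len(p), ]
  structure(list(eigenvalues = lam, variance_explained = lam / sum(lam),
                 scores = Xc %*% V, loadings = V, displacements = disp,
                 consensus = al$consensus, schema = al$schema,
                 meta = al$meta),
            class = "ff_shape_pca")
}

#' @export
print.ff_shape_pca <- function(x, ...) {
  k <- min(4, length(x$eigenvalues))
  cat(sprintf("Shape PCA: first %d PCs explain %s of shape variance\n", k,
              paste(sprintf("%.0f%%", 100 * x$variance_explained[1:k]),
                    collapse = " + ")))
  invisible(x)
}

# project aligned shapes onto the PCs spanning the covariance rank
# (eigenvalue > tol * largest); guards the within-group covariance
# inversions in CVA/DFA against the similarity-induced null directions
reduce_shape_space <- function(al, groups = NULL, tol = 1e-10) {
  X <- aligned_matrix(al)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  eg <- eigen(stats::cov(Xc), symmetric = TRUE)
  r <- sum(eg$values > tol * eg$values[1])
  if (!is.null(groups)) {
    g <- factor(groups)
    r_max <- nrow(X) - nlevels(g)
    if (r_max < 1)
      stop("too few specimens for a within-group covariance; add specimens")
    r <- min(r, r_max)
  }
  V <- eg$vectors[, seq_len(r), drop = FALSE]
  list(Y = Xc %*% V, V = V, center = ctr, rank = r)
}

pooled_within_cov <- function(Y, g) {
  lv <- levels(g)
  n <- nrow(Y)
  W <- matrix(0, ncol(Y), ncol(Y))
  for (l in lv) {
    Yl <- Y[g == l, , drop = FALSE]
    W <- W + crossprod(sweep(Yl, 2, colMeans(Yl)))
  }
  W / (n - length(lv))
}

#' Canonical variate analysis of aligned shapes
#'
#' CVA on the Procrustes shape space: shapes are first projected onto the
#' principal components spanning the covariance rank, canonical axes are
#' the eigenvectors of the within-group/between-group covariance
#' eigenproblem, and group differences are summarized by pairwise
#' Mahalanobis distances (between group means, in the pooled within-group
#' metric) and Procrustes distances (between group mean shapes).
#' Permutation p-values shuffle group labels within each pair of groups;
#' p-values use the `(b + 1)/(n_perm + 1)` estimator and are never zero.
#'
#' @param al an `ff_aligned`.
#' @param groups group label per specimen (defaults to the `group` metadata
#'   column).
#' @param n_perm permutation rounds (default 10000).
#' @param seed RNG seed, mandatory for reproducibility.
#' @return `ff_cva`: canonical `axes` (reduced-space), `scores`
#'   (specimens x canonical variates), `cv_eigenvalues`, `mahalanobis`,
#'   `procrustes` (distance matrices) and the matching permutation p-value
#'   matrices, `n_perm`, `seed`.
#' @export
cva <- function(al, groups = al$meta$group, n_perm = 10000, seed = 1) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("CVA needs at least 2 groups")
  if (any(table(g) < 3)) stop("every group needs at least 3 specimens")
  set.seed(seed)
  red <- reduce_shape_space(al, groups = g)
  Y <- red$Y
  W <- pooled_within_cov(Y, g)
  Wchol <- tryCatch(chol(W), error = function(e)
    stop("singular within-group covariance; add specimens per group"))
  Whalf_inv <- backsolve(Wchol, diag(ncol(Y)))
  means <- t(vapply(levels(g), function(l)
    colMeans(Y[g == l, , drop = FALSE]), numeric(ncol(Y))))
  grand <- colMeans(Y)
  ng <- as.vector(table(g))
  B <- crossprod(sweep(means, 2, grand) * sqrt(ng)) / (nlevels(g) - 1)
  M <- t(Whalf_inv) %*% B %*% Whalf_inv
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  n_cv <- min(nlevels(g) - 1, ncol(Y))
  axes <- Whalf_inv %*% eg$vectors[, seq_len(n_cv), drop = FALSE]
  scores <- sweep(Y, 2, grand) %*% axes
  colnames(scores) <- paste0("CV", seq_len(n_cv))

  lv <- levels(g)
  k <- length(lv)
  maha <- proc <- p_maha <- p_proc <- matrix(0, k, k, dimnames = list(lv, lv))
  Winv <- chol2inv(Wchol)
  mean_shapes <- lapply(lv, function(l) mean_shape(al, g == l))
  names(mean_shapes) <- lv
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    da <- means[a, ] - means[b, ]
    maha[a, b] <- maha[b, a] <- sqrt(drop(t(da) %*% Winv %*% da))
    proc[a, b] <- proc[b, a] <-
      procrustes_distance(mean_shapes[[a]], mean_shapes[[b]])
    pp <- cva_pair_permute(al, Y, g, lv[a], lv[b], n_perm)
    p_maha[a, b] <- p_maha[b, a] <- (sum(pp$maha >= maha[a, b]) + 1) / (n_perm + 1)
    p_proc[a, b] <- p_proc[b, a] <- (sum(pp$proc >= proc[a, b]) + 1) / (n_perm + 1)
  }
  structure(list(axes = axes, scores = scores,
                 cv_eigenvalues = pmax(eg$values[seq_len(n_cv)], 0),
                 mahalanobis = maha, procrustes = proc,
                 p_mahalanobis = p_maha, p_procrustes = p_proc,
                 mean_shapes = mean_shapes, groups = lv, rank = red$rank,
                 n_perm = n_perm, seed = seed, meta = al$meta),
            class = "ff_cva")
}

# permutation distribution for one pair of groups: labels are shuffled
# among the specimens of the pair, the pooled within-group covariance is
# recomputed with the permuted labels, and both distance statistics are
# re-evaluated
cva_pair_permute <- function(al, Y, g, la, lb, n_perm) {
  idx <- which(g %in% c(la, lb))
  na <- sum(g == la)
  Z <- coords_to_cpx(al$coords)
  maha <- proc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    gp <- g
    gp[idx] <- sample(gp[idx])
    Wp <- pooled_within_cov(Y, gp)
    ch <- tryCatch(chol(Wp), error = function(e) NULL)
    ma <- colMeans(Y[gp == la, , drop = FALSE])
    mb <- colMeans(Y[gp == lb, , drop = FALSE])
    d <- ma - mb
    maha[b] <- if (is.null(ch)) Inf else
      sqrt(drop(crossprod(backsolve(ch, d, transpose = TRUE))))
    za <- colMeans(Z[gp == la, , drop = FALSE])
    zb <- colMeans(Z[gp == lb, , drop = FALSE])
    proc[b] <- cpx_proc_dist(za, zb)
  }
  list(maha = maha, proc = proc)
}

cpx_proc_dist <- function(z, w) {
  z <- z - mean(z); w <- w - mean(w)
  z <- z / sqrt(sum(Mod(z)^2)); w <- w / sqrt(sum(Mod(w)^2))
  sqrt(max(0, 2 - 2 * Mod(sum(z * Conj(w)))))
}

#' @export
print.ff_cva <- function(x, ...) {
  cat(sprintf("CVA: %d groups, %d canonical variates, shape-space rank %d\n",
              length(x$groups), ncol(x$scores), x$rank))
  cat("Pairwise Mahalanobis distances (p, permutation):\n")
  for (a in seq_along(x$groups)[-length(x$groups)])
    for (b in (a + 1):length(x$groups))
      cat(sprintf("  %s vs %s: D = %.3f (P = %.4g); Procrustes d = %.4f (P = %.4g)\n",
                  x$groups[a], x$groups[b], x$mahalanobis[a, b],
                  x$p_mahalanobis[a, b], x$procrustes[a, b],
                  x$p_procrustes[a, b]))
  invisible(x)
}

#' Two-group discriminant function analysis of aligned shapes
#'
#' DFA on the reduced Procrustes shape space: the discriminant axis is the
#' within-group-whitened mean difference, specimens are scored along it,
#' and the mean-shape difference is tested by a permutation test on the
#' Procrustes distance between group means (labels shuffled, `(b+1)/(n+1)`
#' p-value estimator: with `n_perm = 10000` the smallest reportable p is
#' `1/10001`). Optionally a leave-one-out classification table is computed.
#'
#' @param al an `ff_aligned`.
#' @param groups two-level group label per specimen (default `group`
#'   metadata column); alternatively pass `group_a`/`group_b` to select two
#'   levels of a multi-level label.
#' @param group_a,group_b optional level names selecting the two groups.
#' @param n_perm permutation rounds.
#' @param seed RNG seed.
#' @param loo compute the leave-one-out classification table.
#' @return `ff_dfa`: `procrustes_distance` between the group mean shapes,
#'   permutation `p_value`, per-specimen discriminant `scores`, the
#'   discriminant `axis` as a p x 2 landmark displacement field, the two
#'   `mean_shapes` (the wireframe pair), and optionally `loo` (confusion
#'   matrix).
#' @export
dfa <- function(al, groups = al$meta$group, group_a = NULL, group_b = NULL,
                n_perm = 10000, seed = 1, loo = FALSE) {
  g <- factor(groups)
  if (!is.null(group_a) || !is.null(group_b)) {
    if (is.null(group_a) || is.null(group_b))
      stop("give both group_a and group_b")
    if (!all(c(group_a, group_b) %in% levels(g)))
      stop("group(s) not present: ",
           paste(setdiff(c(group_a, group_b), levels(g)), collapse = ", "))
    keep <- g %in% c(group_a, group_b)
    al <- structure(list(coords = al$coords[, , keep, drop = FALSE],
                         centroid_sizes = al$centroid_sizes[keep],
                         consensus = al$consensus, tangent = al$tangent,
                         principal_axes = al$principal_axes,
                         iterations = al$iterations,
                         final_change = al$final_change, schema = al$schema,
                         meta = al$meta[keep, , drop = FALSE],
                         units = al$units),
                    class = "ff_aligned")
    g <- factor(as.character(g[keep]), levels = c(group_a, group_b))
  }
  if (nlevels(g) != 2) stop("DFA compares exactly two groups, got ",
                            nlevels(g))
  if (any(table(g) < 3)) stop("every group needs at least 3 specimens")
  set.seed(seed)
  red <- reduce_shape_space(al, groups = g)
  Y <- red$Y
  W <- pooled_within_cov(Y, g)
  Wchol <- tryCatch(chol(W), error = function(e)
    stop("singular within-group covariance; add specimens per group"))
  lv <- levels(g)
  m1 <- colMeans(Y[g == lv[1], , drop = FALSE])
  m2 <- colMeans(Y[g == lv[2], , drop = FALSE])
  w <- drop(chol2inv(Wchol) %*% (m2 - m1))
  scores <- drop(sweep(Y, 2, (m1 + m2) / 2) %*% w)
  ms1 <- mean_shape(al, g == lv[1])
  ms2 <- mean_shape(al, g == lv[2])
  d_obs <- procrustes_distance(ms1, ms2)
  # vectorized permutation of the Procrustes distance between group means
  Z <- coords_to_cpx(al$coords)
  n <- nrow(Z); n1 <- sum(g == lv[1])
  perm_idx <- vapply(seq_len(n_perm), function(i) sample.int(n, n1),
                     integer(n1))
  Ind <- matrix(0, n_perm, n)
  Ind[cbind(rep(seq_len(n_perm), each = n1), as.vector(perm_idx))] <- 1
  M1 <- (Ind %*% Z) / n1
  M2 <- ((1 - Ind) %*% Z) / (n - n1)
  M1 <- M1 - rowMeans(M1)
  M2 <- M2 - rowMeans(M2)
  M1 <- M1 / sqrt(rowSums(Mod(M1)^2))
  M2 <- M2 / sqrt(rowSums(Mod(M2)^2))
  ip <- Mod(rowSums(M1 * Conj(M2)))
  d_perm <- sqrt(pmax(0, 2 - 2 * ip))
  p_val <- (sum(d_perm >= d_obs) + 1) / (n_perm + 1)
  # discriminant axis as a landmark displacement field
  axis_full <- drop(red$V %*% w)
  p <- dim(al$coords)[1]
  axis_disp <- cbind(x = axis_full[seq_len(p)], y = axis_full[p + seq_len(p)])
  loo_tab <- NULL
  if (loo) {
    pred <- character(n)
    for (i in seq_len(n)) {
      gi <- g[-i]
      Yi <- Y[-i, , drop = FALSE]
      Wi <- pooled_within_cov(Yi, droplevels(gi))
      chi <- tryCatch(chol(Wi), error = function(e) NULL)
      if (is.null(chi)) { pred[i] <- NA_character_; next }
      mi1 <- colMeans(Yi[gi == lv[1], , drop = FALSE])
      mi2 <- colMeans(Yi[gi == lv[2], , drop = FALSE])
      wi <- drop(chol2inv(chi) %*% (mi2 - mi1))
      sc <- drop((Y[i, ] - (mi1 + mi2) / 2) %*% wi)
      pred[i] <- if (sc > 0) lv[2] else lv[1]
    }
    loo_tab <- table(truth = g, predicted = factor(pred, levels = lv))
  }
  structure(list(groups = lv, procrustes_distance = d_obs, p_value = p_val,
                 scores = stats::setNames(scores, al$meta$specimen_id),
                 group = g, axis = axis_disp,
                 mean_shapes = stats::setNames(list(ms1, ms2), lv),
                 rank = red$rank, n_perm = n_perm, seed = seed,
                 loo = loo_tab),
            class = "ff_dfa")
}

#' @export
print.ff_dfa <- function(x, ...) {
  cat(sprintf("DFA %s vs %s: Procrustes distance = %.4f, P %s (%d permutations)\n",
              x$groups[1], x$groups[2], x$procrustes_distance,
              if (x$p_value <= 1 / (x$n_perm + 1))
                sprintf("< %.4g", 1 / x$n_perm) else
                sprintf("= %.4g", x$p_value),
              x$n_perm))
  if (!is.null(x$loo)) {
    cat("Leave-one-out classification:\n")
    print(x$loo)
  }
  invisible(x)
}
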