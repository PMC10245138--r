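#' Principal component analysis of a feature table or matrix
#'
#' Exact eigendecomposition of the covariance (`scale = "raw"`) or
#' correlation (`scale = "zscore"`) matrix of the features. Component signs
#' are fixed deterministically: the largest-magnitude element of each
#' loading vector is made positive, so scores and loadings are reproducible
#' across runs and platforms.
#'
#' @param x an `ff_features` table or a numeric specimens x features matrix.
#' @param scale `"raw"` (covariance) or `"zscore"` (correlation; features
#'   standardized to mean 0, sd 1).
#' @return `ff_pca`: list with `loadings` (features x components, orthonormal
#'   columns), `eigenvalues` (non-increasing), `variance_explained` (sums to
#'   1), `scores` (specimens x components, zero mean per component), `scale`,
#'   `center`/`sdev` records and `rotation = "none"`.
#' @export
ff_pca <- function(x, scale = c("raw", "zscore")) {
  scale <- match.arg(scale)
  X <- if (inherits(x, "ff_features")) feature_matrix(x) else as.matrix(x)
  if (nrow(X) < 3) stop("PCA needs at least 3 specimens")
  if (anyNA(X)) stop("PCA input contains missing values")
  ctr <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  if (scale == "zscore") {
    const <- colnames(X)[sdev == 0]
    if (length(const) > 0)
      stop("constant feature(s) cannot be z-scored: ",
           paste(const, collapse = ", "))
    Xs <- sweep(sweep(X, 2, ctr), 2, sdev, "/")
  } else {
    Xs <- sweep(X, 2, ctr)
  }
  S <- stats::cov(Xs)
  eg <- eigen(S, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  V <- eg$vectors
  # deterministic sign: largest-|.| element of each loading vector positive
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(ncol(V))))
  scores <- Xs %*% V
  structure(list(loadings = V, eigenvalues = lam,
                 variance_explained = lam / sum(lam),
                 scores = scores, scale = scale, center = ctr, sdev = sdev,
                 rotation = "none"),
            class = "ff_pca")
}

#' @export
print.ff_pca <- function(x, ...) {
  k <- min(6, length(x$eigenvalues))
  cat(sprintf("PCA (%s%s): %d components; variance explained (first %d): %s\n",
              x$scale,
              if (x$rotation != "none") paste0(", ", x$rotation) else "",
              length(x$eigenvalues), k,
              paste(sprintf("%.1f%%", 100 * x$variance_explained[1:k]),
                    collapse = " ")))
  invisible(x)
}

#' Kaiser component retention
#'
#' Retains the contiguous leading components passing the Kaiser rule:
#' eigenvalue greater than 1 for correlation-matrix (`zscore`) PCA,
#' eigenvalue at least the mean eigenvalue for covariance-matrix (`raw`)
#' PCA (ties at the mean retained).
#'
#' @param pr an `ff_pca`.
#' @return integer vector of retained component indices (1..k).
#' @export
kaiser_retain <- function(pr) {
  lam <- pr$eigenvalues
  keep <- if (pr$scale == "zscore") {
    lam > 1
  } else {
    lam >= mean(lam) * (1 - 1e-12)
  }
  k <- if (any(keep)) max(which(cumsum(!keep) == 0)) else 0L
  seq_len(k)
}

#' Varimax rotation of retained components
#'
#' Orthogonally rotates the first `k` loading columns towards simple
#' structure (varimax criterion, Kaiser row-normalization), recomputing the
#' scores for the rotated components. Communalities (row sums of squared
#' loadings over the rotated block) and the block's total variance are
#' conserved.
#'
#' @param pr an `ff_pca`.
#' @param k number of leading components to rotate (>= 2); defaults to the
#'   Kaiser retention count.
#' @return an `ff_pca` with `loadings`, `scores`, `eigenvalues` (sum of
#'   squared loadings x original eigenvalue structure) replaced for the
#'   rotated block and `rotation = "varimax"`.
#' @export
varimax_rotate <- function(pr, k = length(kaiser_retain(pr))) {
  if (k < 2) stop("varimax rotation needs at least 2 components (k = ", k, ")")
  L <- pr$loadings[, seq_len(k), drop = FALSE]
  vm <- stats::varimax(L, normalize = TRUE)
  R <- as.matrix(vm$rotmat)
  # variance carried by each rotated component: diag(R' Lambda R)
  lamk <- pr$eigenvalues[seq_len(k)]
  newvar <- diag(t(R) %*% (lamk * R))
  ord <- order(newvar, decreasing = TRUE)
  R <- R[, ord, drop = FALSE]
  rot <- L %*% R
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; R[, j] <- -R[, j] }
  }
  colnames(rot) <- paste0("RC", seq_len(k))
  out <- pr
  out$loadings <- rot
  out$eigenvalues <- newvar[ord]
  out$variance_explained <- out$eigenvalues / sum(pr$eigenvalues)
  out$scores <- pr$scores[, seq_len(k), drop = FALSE] %*% R
  colnames(out$scores) <- colnames(rot)
  out$rotation <- "varimax"
  out$rotmat <- R
  out
}

#' Logistic classification on PC scores
#'
#' Fits a logistic regression of a two-level group factor on selected PC
#' scores. For a single component the decision threshold (score at which the
#' predicted probability crosses 0.5) is reported. Perfect separation is
#' detected and handled by refitting with a small ridge penalty; the result
#' is flagged `separation = TRUE` and no Wald p-value is reported for it.
#'
#' @param pr an `ff_pca`.
#' @param groups factor (or coercible) with exactly two levels, one value
#'   per specimen; the second level is modelled as the "positive" class.
#' @param components integer vector of component indices to use (default 1).
#' @return `ff_pc_classifier`: coefficients, per-specimen fitted
#'   probabilities and predicted classes, training accuracy, Wald `p_value`
#'   of the score coefficient (single component, unpenalized fit only), and
#'   `threshold` (single component only).
#' @export
fit_pc_classifier <- function(pr, groups, components = 1L) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("classifier needs exactly 2 groups, got ",
                            nlevels(g))
  if (any(table(g) < 3)) stop("each group needs at least 3 specimens")
  S <- pr$scores[, components, drop = FALSE]
  if (nrow(S) != length(g)) stop("groups length does not match specimens")
  y <- as.integer(g) - 1L
  df <- data.frame(y = y, S)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- stats::coef(fit)
  pval <- NA_real_
  if (!sep && length(components) == 1L) {
    pval <- summary(fit)$coefficients[2, "Pr(>|z|)"]
  }
  if (sep) {
    coefs <- ridge_logistic(cbind(1, S), y, lambda = 1e-2)
    prob <- stats::plogis(cbind(1, S) %*% coefs)[, 1]
  } else {
    prob <- stats::fitted(fit)
  }
  thr <- if (length(components) == 1L && coefs[2] != 0)
    unname(-coefs[1] / coefs[2]) else NA_real_
  pred <- levels(g)[1L + (prob > 0.5)]
  structure(list(coefficients = coefs, levels = levels(g),
                 components = components, probabilities = prob,
                 predicted = pred, accuracy = mean(pred == as.character(g)),
                 p_value = pval, threshold = thr, separation = sep),
            class = "ff_pc_classifier")
}

#' @export
print.ff_pc_classifier <- function(x, ...) {
  cat(sprintf("PC-score logistic classifier (%s vs %s) on component(s) %s\n",
              x$levels[1], x$levels[2],
              paste(x$components, collapse = ",")))
  cat(sprintf("  training accuracy %.1f%%%s", 100 * x$accuracy,
              if (x$separation) " [separation: ridge-penalized fit]" else ""))
  if (!is.na(x$threshold))
    cat(sprintf("; decision threshold at score %.3f", x$threshold))
  if (!is.na(x$p_value)) cat(sprintf("; coefficient P = %.3g", x$p_value))
  cat("\n")
  invisible(x)
}

# ridge-penalized logistic regression by Newton iterations (no penalty on
# the intercept); used only as the separation fallback
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
  for (it in seq_len(maxit)) {
    eta <- X %*% beta
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X * as.vector(w), X) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.vector(beta)
}
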