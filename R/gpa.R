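# Internal complex-number representation of 2D landmark configurations.
# A configuration (p x 2) maps to a complex p-vector z = x + iy; rotation by
# theta is multiplication by exp(i*theta), so optimal rotation-only
# superimposition has the closed form z * Conj(s)/|s| with s = sum(z*Conj(c)).
# Reflections are unreachable by construction.

coords_to_cpx <- function(coords) {
  # p x 2 x n array -> n x p complex matrix
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  t(coords[, 1, ] + 1i * coords[, 2, ])
}

cpx_to_coords <- function(Z) {
  # n x p complex matrix -> p x 2 x n array
  n <- nrow(Z); p <- ncol(Z)
  out <- array(NA_real_, c(p, 2, n), dimnames = list(NULL, c("x", "y"), NULL))
  for (i in seq_len(n)) {
    out[, 1, i] <- Re(Z[i, ])
    out[, 2, i] <- Im(Z[i, ])
  }
  out
}

cpx_center <- function(Z) Z - rowMeans(Z)

cpx_size <- function(Z) sqrt(rowSums(Mod(Z)^2))

# align each row of Z to consensus c by the optimal rotation
cpx_rotate_to <- function(Z, cons) {
  s <- Z %*% Conj(cons)            # n x 1 inner products
  phase <- Conj(s) / Mod(s)
  Z * as.vector(phase)
}

#' Generalized Procrustes analysis
#'
#' Full generalized Procrustes superimposition: each configuration is
#' centred, scaled to unit centroid size, and iteratively rotated to the
#' running consensus until the consensus changes by less than `tol`
#' (default 1e-10) or `max_iter` iterations. The final consensus is
#' optionally aligned to its principal axes (rotating all specimens with
#' it), and configurations are optionally projected orthogonally into the
#' tangent space at the consensus. Superimposition optimizes over rotations
#' only; reflections are never applied.
#'
#' @param ds an [ff_dataset()] with at least 2 specimens.
#' @param tangent project into tangent space at the consensus (default
#'   `TRUE`).
#' @param principal_axes align the consensus to its principal axes
#'   (default `TRUE`).
#' @param tol consensus convergence tolerance.
#' @param max_iter iteration cap.
#' @return `ff_aligned`: list with `coords` (p x 2 x n Procrustes
#'   coordinates), `centroid_sizes` (original units), `consensus` (p x 2
#'   mean shape), `tangent`, `iterations`, `final_change`, plus the schema
#'   and metadata of the input.
#' @export
gpa <- function(ds, tangent = TRUE, principal_axes = TRUE, tol = 1e-10,
                max_iter = 100) {
  n <- n_specimens(ds)
  if (n < 2) stop("GPA needs at least 2 specimens")
  Z <- coords_to_cpx(ds$coords)
  Zc <- cpx_center(Z)
  cs <- cpx_size(Zc)
  # degenerate configurations: all landmarks collinear (or coincident)
  for (i in seq_len(n)) {
    zi <- Zc[i, ] / cs[i]
    if (Mod(sum(zi^2)) > 1 - 1e-12 || cs[i] == 0)
      stop("degenerate (collinear) configuration for specimen '",
           ds$meta$specimen_id[i], "'")
  }
  Zu <- Zc / cs
  cons <- Zu[1, ]
  cons <- cons / sqrt(sum(Mod(cons)^2))
  change <- Inf; it <- 0L
  while (change > tol && it < max_iter) {
    it <- it + 1L
    Za <- cpx_rotate_to(Zu, cons)
    new_cons <- colMeans(Za)
    new_cons <- new_cons - mean(new_cons)
    new_cons <- new_cons / sqrt(sum(Mod(new_cons)^2))
    # keep consensus phase continuous between iterations
    s <- sum(new_cons * Conj(cons))
    new_cons <- new_cons * Conj(s) / Mod(s)
    change <- sqrt(sum(Mod(new_cons - cons)^2))
    cons <- new_cons
    Zu <- Za
  }
  Za <- cpx_rotate_to(Zu, cons)
  if (principal_axes) {
    rot <- principal_axis_phase(cons)
    cons <- cons * rot
    Za <- Za * rot
  }
  if (tangent) {
    sc <- Re(Za %*% Conj(cons))  # cos(rho_i), real after rotation alignment
    Za <- Za + (1 - as.vector(sc)) %o% cons
  }
  structure(list(coords = cpx_to_coords(Za), centroid_sizes = cs,
                 consensus = cbind(x = Re(cons), y = Im(cons)),
                 tangent = tangent, principal_axes = principal_axes,
                 iterations = it, final_change = change,
                 schema = ds$schema, meta = ds$meta, units = ds$units),
            class = "ff_aligned")
}

# rotation (unit complex) taking the consensus onto its principal axes,
# with a deterministic 180-degree disambiguation: after rotation the
# landmark farthest from the centroid has positive x
principal_axis_phase <- function(cons) {
  m2 <- sum(cons^2)   # (Sxx - Syy) + 2i Sxy of the centred consensus
  phi <- 0.5 * Arg(m2)
  rot <- exp(-1i * phi)
  far <- which.max(Mod(cons))
  if (Re(cons[far] * rot) < 0) rot <- -rot
  rot
}

#' @export
print.ff_aligned <- function(x, ...) {
  cat(sprintf(paste0("Procrustes-aligned shapes: %d specimens x %d landmarks",
                     " (%d iterations, final change %.2e%s)\n"),
              dim(x$coords)[3], dim(x$coords)[1], x$iterations,
              x$final_change,
              if (x$tangent) ", tangent-projected" else ""))
  invisible(x)
}

#' Mean shape of (a subset of) aligned specimens
#' @param al an `ff_aligned`.
#' @param idx optional specimen subset.
#' @return p x 2 matrix.
#' @export
mean_shape <- function(al, idx = NULL) {
  co <- if (is.null(idx)) al$coords else al$coords[, , idx, drop = FALSE]
  apply(co, c(1, 2), mean)
}

#' Procrustes distance between two configurations
#'
#' Both configurations are centred and scaled to unit centroid size; the
#' distance is the square root of the summed squared coordinate differences
#' after the optimal rotation-only superimposition. It is symmetric and zero
#' exactly when the shapes differ only by a similarity transform.
#'
#' @param shape1,shape2 p x 2 coordinate matrices with equal `p`.
#' @export
procrustes_distance <- function(shape1, shape2) {
  shape1 <- as.matrix(shape1); shape2 <- as.matrix(shape2)
  if (!all(dim(shape1) == dim(shape2)))
    stop("landmark count mismatch: ", nrow(shape1), " vs ", nrow(shape2))
  z <- shape1[, 1] + 1i * shape1[, 2]
  w <- shape2[, 1] + 1i * shape2[, 2]
  z <- z - mean(z); w <- w - mean(w)
  z <- z / sqrt(sum(Mod(z)^2)); w <- w / sqrt(sum(Mod(w)^2))
  sqrt(max(0, 2 - 2 * Mod(sum(z * Conj(w)))))
}

#' Export Procrustes coordinates as a plain-text table
#'
#' Writes one row per specimen (`specimen_id`, `x1 y1 ... xP yP`,
#' tab-separated), the interchange layout accepted by common morphometrics
#' software.
#'
#' @param al an `ff_aligned`.
#' @param path output file.
#' @export
export_procrustes <- function(al, path) {
  p <- dim(al$coords)[1]
  m <- matrix(NA_real_, dim(al$coords)[3], 2 * p)
  m[, seq(1, 2 * p, 2)] <- t(al$coords[, 1, ])
  m[, seq(2, 2 * p, 2)] <- t(al$coords[, 2, ])
  df <- data.frame(specimen_id = al$meta$specimen_id, m)
  names(df)[-1] <- paste0(rep(c("x", "y"), p), rep(seq_len(p), each = 2))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
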