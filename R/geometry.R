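#' Euclidean distance between two points
#'
#' @param p,q numeric length-2 points.
#' @return non-negative distance `sqrt((xp - xq)^2 + (yp - yq)^2)`.
#' @export
lm_distance <- function(p, q) {
  sqrt(sum((p - q)^2))
}

#' Interior angle at a vertex, in degrees
#'
#' The angle at vertex `B` between rays `BA` and `BC`, computed via the law
#' of cosines with the cosine argument clamped to `[-1, 1]`; range 0-180
#' degrees.
#'
#' @param A,B,C numeric length-2 points; `B` is the vertex.
#' @param names optional landmark names used in error messages.
#' @export
lm_angle <- function(A, B, C, names = NULL) {
  if (all(A == B) || all(C == B)) {
    lab <- if (is.null(names)) "A/B/C" else paste(names, collapse = "/")
    stop("degenerate angle: vertex coincides with a ray endpoint (", lab, ")")
  }
  a <- lm_distance(B, C)   # side opposite A
  c_ <- lm_distance(A, B)  # side opposite C
  b <- lm_distance(A, C)   # side opposite B (spans the angle at B)
  cosb <- (a^2 + c_^2 - b^2) / (2 * a * c_)
  cosb <- min(1, max(-1, cosb))
  acos(cosb) * 180 / pi
}

#' Polygon area (shoelace formula)
#'
#' Absolute area of the polygon traversed in vertex order; orientation
#' independent, zero for collinear input. For three points this is the
#' classical triangle-area determinant formula.
#'
#' @param points numeric matrix with one `(x, y)` row per vertex, at least 3.
#' @export
polygon_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("polygon_area needs at least 3 points")
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}
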