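#' Wireframe of landmark-connecting edges
#'
#' @param reference p x 2 reference shape (drawn light).
#' @param target p x 2 target shape (drawn dark), superimposed onto the
#'   reference by the optimal similarity transform before drawing.
#' @param edges two-column matrix of landmark index pairs; defaults to the
#'   edge set shipped with the package (face outline, mouth polygon, eye,
#'   olfactory and neuromast connectors).
#' @param schema schema the edges refer to.
#' @return object of class `ff_wireframe`.
#' @export
wireframe <- function(reference, target = reference, edges = NULL,
                      schema = default_schema()) {
  if (is.null(edges)) edges <- default_wireframe_edges()
  edges <- as.matrix(edges)
  if (nrow(edges) == 0) stop("empty wireframe edge list")
  if (any(edges < 1 | edges > schema$n))
    stop("wireframe edges reference landmarks outside 1..", schema$n)
  stopifnot(nrow(reference) == schema$n, nrow(target) == schema$n)
  structure(list(reference = as.matrix(reference),
                 target = as.matrix(target), edges = edges, schema = schema),
            class = "ff_wireframe")
}

#' Default wireframe edge set
#' @return two-column integer matrix of landmark index pairs.
#' @export
default_wireframe_edges <- function() {
  y <- yaml::read_yaml(system.file("extdata", "wireframe_default.yaml",
                                   package = "fishface", mustWork = TRUE))
  do.call(rbind, lapply(y$edges, as.integer))
}

#' Render a wireframe overlay to SVG or PNG
#'
#' Draws the reference wireframe in light grey and the target (after
#' optimal superimposition onto the reference) in dark colour. The y axis
#' is flipped so the rendered face is upright regardless of the
#' image-coordinate convention (y increasing downward).
#'
#' @param wf an [wireframe()] object.
#' @param out output file; extension `.svg` or `.png` selects the device.
#'   `NULL` draws on the active device.
#' @param magnify factor applied to the target's deviation from the
#'   reference (1 = true scale).
#' @return invisibly, a list with the plotted `reference` and `target`
#'   coordinates (superimposed, y-flipped) for programmatic inspection.
#' @export
render_wireframe <- function(wf, out = NULL, magnify = 1) {
  ref <- wf$reference
  tgt <- superimpose_onto(wf$target, ref)
  if (magnify != 1) tgt <- ref + magnify * (tgt - ref)
  refp <- cbind(ref[, 1], -ref[, 2])
  tgtp <- cbind(tgt[, 1], -tgt[, 2])
  if (!is.null(out)) {
    ext <- tolower(tools::file_ext(out))
    switch(ext,
           svg = grDevices::svg(out, width = 6, height = 6),
           png = grDevices::png(out, width = 900, height = 900, res = 150),
           stop("unsupported wireframe output format: .", ext))
    on.exit(grDevices::dev.off())
  }
  rng <- apply(rbind(refp, tgtp), 2, range)
  graphics::plot(NA, xlim = rng[, 1], ylim = rng[, 2], asp = 1,
                 xlab = "", ylab = "", axes = FALSE,
                 main = "wireframe overlay")
  graphics::segments(refp[wf$edges[, 1], 1], refp[wf$edges[, 1], 2],
                     refp[wf$edges[, 2], 1], refp[wf$edges[, 2], 2],
                     col = "grey70", lwd = 2)
  graphics::segments(tgtp[wf$edges[, 1], 1], tgtp[wf$edges[, 1], 2],
                     tgtp[wf$edges[, 2], 1], tgtp[wf$edges[, 2], 2],
                     col = "grey10", lwd = 2)
  invisible(list(reference = refp, target = tgtp, edges = wf$edges))
}

# optimal similarity superimposition of shape onto ref (translation, scale,
# rotation; no reflection)
superimpose_onto <- function(shape, ref) {
  z <- shape[, 1] + 1i * shape[, 2]
  w <- ref[, 1] + 1i * ref[, 2]
  mz <- mean(z); mw <- mean(w)
  z <- z - mz
  wc <- w - mw
  s <- sum(Conj(z) * wc) / sum(Mod(z)^2)   # complex scale+rotation
  z2 <- z * s + mw
  cbind(x = Re(z2), y = Im(z2))
}
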