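#' Default synthetic face template
#'
#' A bilaterally symmetric 26-landmark face-like configuration, about 300
#' units wide, with the eight mouth landmarks on a convex ellipse. Ships
#' with named deformation presets (per-landmark displacement fields, zero
#' net translation, bilaterally symmetric):
#' `mouth_elongation` (vertical opening/elongation of the oral cavity),
#' `face_narrowing` (lateral landmarks drawn towards the midline),
#' `stage_3to4` (face narrowing plus isotropic mouth enlargement, emulating
#' the largest developmental transition) and `mutant` (mouth elongation
#' plus face narrowing, emulating a severe craniofacial mutant).
#'
#' @return `ff_template`: list with `name`, `schema`, `mean_coords`
#'   (26 x 2) and `presets` (named list of 26 x 2 displacement fields).
#' @export
default_template <- function() {
  schema <- default_schema()
  cx <- 256; cy <- 256
  lm <- function(dx, dy) c(cx + dx, cy + dy)
  co <- rbind(
    lm(0, -150),                        # 1  glabella
    lm(-110, -120), lm(110, -120),      # 2/3  frontotemporale
    lm(-40, -95),  lm(40, -95),         # 4/5  olfactory placodes
    lm(-55, -60),  lm(55, -60),         # 6/7  eye medial canthi
    lm(-105, -55), lm(105, -55),        # 8/9  eye lateral canthi
    lm(-150, -20), lm(150, -20),        # 10/11 zygia
    lm(-125, -90), lm(125, -90),        # 12/13 neuromasts superior
    lm(-135, 60),  lm(135, 60),         # 14/15 neuromasts inferior
    lm(0, 0),                           # 16 labiale superius
    lm(-35, 4),   lm(35, 4),            # 17/18 crista philtri
    lm(-70, 30),  lm(70, 30),           # 19/20 chelion
    lm(-50, 51),  lm(50, 51),           # 21/22 oral laterals
    lm(0, 60),                          # 23 labiale inferius
    lm(-90, 95),  lm(90, 95),           # 24/25 gonion
    lm(0, 135)                          # 26 gnathion
  )
  colnames(co) <- c("x", "y")
  mouth <- schema$mouth_indices
  mc <- colMeans(co[mouth, ])
  zero_sum <- function(f) sweep(f, 2, colMeans(f))
  f_mouth <- matrix(0, schema$n, 2)
  # open/elongate the mouth vertically, slightly narrowed
  f_mouth[mouth, 2] <- (co[mouth, 2] - mc[2]) * 0.45
  f_mouth[mouth, 1] <- -(co[mouth, 1] - mc[1]) * 0.10
  f_mouth <- zero_sum(f_mouth)
  f_narrow <- matrix(0, schema$n, 2)
  lateral <- setdiff(seq_len(schema$n), mouth)
  f_narrow[lateral, 1] <- -(co[lateral, 1] - cx) * 0.12
  f_narrow <- zero_sum(f_narrow)
  f_stage <- matrix(0, schema$n, 2)
  f_stage[mouth, ] <- sweep(co[mouth, ], 2, mc) * 0.15
  f_stage[lateral, 1] <- -(co[lateral, 1] - cx) * 0.08
  f_stage <- zero_sum(f_stage)
  presets <- list(mouth_elongation = f_mouth, face_narrowing = f_narrow,
                  stage_3to4 = f_stage, mutant = zero_sum(f_mouth + f_narrow))
  structure(list(name = "default", schema = schema, mean_coords = co,
                 presets = presets),
            class = "ff_template")
}

#' @export
print.ff_template <- function(x, ...) {
  cat(sprintf("Synthetic face template '%s': %d landmarks, presets: %s\n",
              x$name, nrow(x$mean_coords),
              paste(names(x$presets), collapse = ", ")))
  invisible(x)
}

#' Simulate a landmark dataset
#'
#' Generates specimens as: template mean + `effect_scale` x group preset
#' field + bilaterally symmetric individual variation + fluctuating
#' asymmetry noise (+ an optional explicit directional-asymmetry field),
#' then a random similarity pose (rotation, scale, translation), then
#' isotropic digitization noise per landmark. Fully reproducible from the
#' seed; a ground-truth record (true group mean shapes and the true
#' Procrustes distances between them) is attached as attribute
#' `"ground_truth"`.
#'
#' Defaults emulate a typical imaging study design: group sizes around 30,
#' digitization error of 2 units on a face about 300 units wide, individual
#' shape variation of 3 units, mounting-induced pose jitter of up to 10
#' degrees rotation, 10% scale and 20 units translation.
#'
#' @param groups data frame with columns `label`, `n`, and optionally
#'   `preset` (name in `template$presets`, or `"none"`) and `effect_scale`.
#' @param template an [default_template()]-like object.
#' @param digitization_sd isotropic landmark digitization noise sd (units).
#' @param individual_sd sd of the symmetric individual variation (units).
#' @param asymmetry_sd sd of fluctuating-asymmetry noise (units).
#' @param pose list with `rotation_deg`, `scale`, `translation` half-ranges;
#'   set to `NULL` to disable pose jitter.
#' @param directional_asymmetry optional p x 2 displacement field added
#'   as-is (not mirrored) to every specimen, injecting directional
#'   asymmetry.
#' @param stage_dpf optional per-group stage annotation (recycled).
#' @param seed RNG seed (mandatory).
#' @return an [ff_dataset()] with `group` metadata and a `ground_truth`
#'   attribute.
#' @export
simulate_dataset <- function(groups, template = default_template(),
                             digitization_sd = 2, individual_sd = 3,
                             asymmetry_sd = 1,
                             pose = list(rotation_deg = 10, scale = 0.1,
                                         translation = 20),
                             directional_asymmetry = NULL,
                             stage_dpf = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory for simulation")
  stopifnot(is.data.frame(groups), all(c("label", "n") %in% names(groups)))
  if (is.null(groups$preset)) groups$preset <- "none"
  if (is.null(groups$effect_scale)) groups$effect_scale <- 1
  if (any(groups$n < 1)) stop("every group needs n >= 1")
  stopifnot(digitization_sd >= 0, individual_sd >= 0, asymmetry_sd >= 0)
  bad <- setdiff(setdiff(groups$preset, "none"), names(template$presets))
  if (length(bad) > 0)
    stop("unknown preset(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  schema <- template$schema
  p <- schema$n
  pairs <- schema$pairs
  mid <- schema$midline
  true_means <- list()
  coords_list <- list(); meta_list <- list()
  for (gi in seq_len(nrow(groups))) {
    lab <- groups$label[gi]
    eff <- if (groups$preset[gi] == "none") matrix(0, p, 2) else
      groups$effect_scale[gi] * template$presets[[groups$preset[gi]]]
    mu <- template$mean_coords + eff
    true_means[[lab]] <- mu
    for (k in seq_len(groups$n[gi])) {
      cfg <- mu
      if (individual_sd > 0) {
        dl <- matrix(stats::rnorm(nrow(pairs) * 2, 0, individual_sd),
                     nrow(pairs), 2)
        cfg[pairs[, 1], ] <- cfg[pairs[, 1], ] + dl
        cfg[pairs[, 2], 1] <- cfg[pairs[, 2], 1] - dl[, 1]
        cfg[pairs[, 2], 2] <- cfg[pairs[, 2], 2] + dl[, 2]
        cfg[mid, 2] <- cfg[mid, 2] + stats::rnorm(length(mid), 0, individual_sd)
      }
      if (asymmetry_sd > 0)
        cfg <- cfg + matrix(stats::rnorm(p * 2, 0, asymmetry_sd), p, 2)
      if (!is.null(directional_asymmetry))
        cfg <- cfg + directional_asymmetry
      if (!is.null(pose)) {
        th <- stats::runif(1, -pose$rotation_deg, pose$rotation_deg) * pi / 180
        sc <- 1 + stats::runif(1, -pose$scale, pose$scale)
        tr <- stats::runif(2, -pose$translation, pose$translation)
        ctr <- colMeans(cfg)
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
        cfg <- sweep(sweep(cfg, 2, ctr) %*% t(R) * sc, 2, ctr + tr, "+")
      }
      if (digitization_sd > 0)
        cfg <- cfg + matrix(stats::rnorm(p * 2, 0, digitization_sd), p, 2)
      coords_list[[length(coords_list) + 1L]] <- cfg
      meta_list[[length(meta_list) + 1L]] <-
        data.frame(specimen_id = sprintf("%s_%03d", lab, k), group = lab)
    }
  }
  n <- length(coords_list)
  coords <- array(NA_real_, c(p, 2, n))
  for (i in seq_len(n)) coords[, , i] <- coords_list[[i]]
  meta <- do.call(rbind, meta_list)
  if (!is.null(stage_dpf))
    meta$stage_dpf <- rep(rep(stage_dpf, length.out = nrow(groups)),
                          groups$n)
  lv <- groups$label
  k <- length(lv)
  true_proc <- matrix(0, k, k, dimnames = list(lv, lv))
  for (a in seq_len(k)) for (b in seq_len(k))
    if (a != b) true_proc[a, b] <-
      procrustes_distance(true_means[[lv[a]]], true_means[[lv[b]]])
  ds <- ff_dataset(coords, schema = schema, meta = meta,
                   provenance = sprintf("simulate_dataset(seed=%d)", seed))
  attr(ds, "ground_truth") <- list(mean_shapes = true_means,
                                   procrustes = true_proc,
                                   groups = groups, seed = seed)
  ds
}

#' Simulate a latent-factor feature table
#'
#' Generates a specimens x features matrix from a small number of
#' orthogonal latent factors with simple structure (each feature loads on
#' exactly one factor; factor 1 carries about a third of the features, the
#' rest split evenly) plus unit Gaussian noise, the structure assumed by
#' Kaiser-retention analyses of standardized measurement data. A group
#' label can displace one group along factor 1 by `delta` factor-sd, giving
#' a known Bayes classification accuracy `pnorm(delta / 2)`.
#'
#' @param n_per_group specimens per group (two groups, `"A"` and `"B"`).
#' @param n_features number of features (default 39).
#' @param n_factors number of latent factors (default 6).
#' @param loading factor loading magnitude (default 3; noise sd is 1).
#' @param delta displacement of group B along factor 1, in factor sd.
#' @param seed RNG seed.
#' @return an `ff_features` table with `group` metadata; attribute
#'   `"ground_truth"` records `delta`, the Bayes accuracy and the factor
#'   assignment of each feature.
#' @export
simulate_feature_factors <- function(n_per_group = 60, n_features = 39,
                                     n_factors = 6, loading = 3, delta = 0,
                                     seed) {
  if (missing(seed)) stop("a seed is mandatory for simulation")
  set.seed(seed)
  n <- 2 * n_per_group
  g <- rep(c("A", "B"), each = n_per_group)
  # factor 1 carries about a third of the features (as the mouth cluster
  # carries about a third of the landmarks) so the leading component is a
  # clean estimate of it; remaining features split evenly over the others
  m1 <- max(n_features %/% n_factors + n_features %% n_factors,
            round(0.36 * n_features))
  m_other <- (n_features - m1) %/% (n_factors - 1L)
  m1 <- n_features - m_other * (n_factors - 1L)
  assign <- rep(seq_len(n_factors), times = c(m1, rep(m_other, n_factors - 1L)))
  F <- matrix(stats::rnorm(n * n_factors), n, n_factors)
  F[g == "B", 1] <- F[g == "B", 1] + delta
  L <- matrix(0, n_features, n_factors)
  L[cbind(seq_len(n_features), assign)] <- loading
  X <- F %*% t(L) + matrix(stats::rnorm(n * n_features), n, n_features)
  colnames(X) <- sprintf("feature_%02d", seq_len(n_features))
  out <- cbind(data.frame(specimen_id = sprintf("spec_%03d", seq_len(n)),
                          group = g), as.data.frame(X))
  out <- structure(out, feature_names = colnames(X),
                   units = rep("unitless", n_features),
                   class = c("ff_features", "data.frame"))
  attr(out, "ground_truth") <- list(delta = delta,
                                    bayes_accuracy = stats::pnorm(delta / 2),
                                    factor_of_feature = assign, seed = seed)
  out
}

#' Write the canned fixture suite
#'
#' Emits the small deterministic fixtures used across the test suite: a
#' clean three-group dataset in TPS, wide-CSV and long-CSV form; a dataset
#' with one specimen's chelion pair swapped; a 26-row and a 27-row point
#' list; a null two-group dataset and a mutant-effect two-group dataset
#' (wide CSV); plus `manifest.json` recording seeds and parameters. All
#' content is synthetic, generated from [default_template()].
#'
#' @param outdir writable output directory (created if absent).
#' @param seed base RNG seed.
#' @return invisibly, a character vector of the written file paths.
#' @export
write_fixture_suite <- function(outdir, seed = 20230601) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) stop("output directory not writable: ",
                                        outdir)
  paths <- character()
  emit <- function(fn) { paths <<- c(paths, fn); fn }
  clean <- simulate_dataset(
    data.frame(label = c("WT", "Het", "Mut"), n = c(5, 5, 5),
               preset = c("none", "none", "mutant"),
               effect_scale = c(0, 0, 1)),
    seed = seed)
  write_tps(clean, emit(file.path(outdir, "clean.tps")))
  write_csv_dataset(clean, emit(file.path(outdir, "clean_wide.csv")), "wide")
  write_csv_dataset(clean, emit(file.path(outdir, "clean_long.csv")), "long")
  swapped <- clean
  tmp <- swapped$coords[19, , 2]
  swapped$coords[19, , 2] <- swapped$coords[20, , 2]
  swapped$coords[20, , 2] <- tmp
  write_csv_dataset(swapped, emit(file.path(outdir, "swapped_pair_wide.csv")),
                    "wide")
  tpl <- default_template()
  pts26 <- cbind(seq_len(26), tpl$mean_coords)
  utils::write.table(pts26, emit(file.path(outdir, "points_26.txt")),
                     row.names = FALSE, col.names = FALSE)
  pts27 <- rbind(pts26, c(27, 256, 500))
  utils::write.table(pts27, emit(file.path(outdir, "points_27.txt")),
                     row.names = FALSE, col.names = FALSE)
  null2 <- simulate_dataset(
    data.frame(label = c("g1", "g2"), n = c(10, 10)), seed = seed + 1)
  write_csv_dataset(null2, emit(file.path(outdir, "null_two_group.csv")),
                    "wide")
  eff2 <- simulate_dataset(
    data.frame(label = c("WT", "Mut"), n = c(10, 10),
               preset = c("none", "mutant"), effect_scale = c(0, 1)),
    seed = seed + 2)
  write_csv_dataset(eff2, emit(file.path(outdir, "effect_two_group.csv")),
                    "wide")
  manifest <- list(seed = seed,
                   files = basename(paths),
                   generator = "fishface::write_fixture_suite",
                   parameters = list(clean = list(n = c(5, 5, 5), seed = seed),
                                     null_two_group = list(n = c(10, 10),
                                                           seed = seed + 1),
                                     effect_two_group = list(n = c(10, 10),
                                                             seed = seed + 2)))
  jsonlite::write_json(manifest,
                       emit(file.path(outdir, "manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
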