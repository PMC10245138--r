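#' Compute the catalog measurements for every specimen
#'
#' Evaluates each catalog feature (distances, angles, polygon areas, then
#' composites over earlier features) on every specimen. The computation is a
#' pure function of the dataset and catalog: column order equals catalog
#' order and repeated calls return identical tables.
#'
#' @param ds an [ff_dataset()].
#' @param catalog an [feature_catalog()]; default [default_catalog()].
#' @return a `ff_features` object: data frame with `specimen_id`, any
#'   metadata columns, and one numeric column per feature; attributes
#'   `feature_names` and `units`.
#' @export
compute_features <- function(ds, catalog = default_catalog(ds$schema)) {
  if (catalog$schema$n != ds$schema$n)
    stop("catalog schema (", catalog$schema$n,
         " landmarks) does not match dataset schema (", ds$schema$n, ")")
  n <- n_specimens(ds)
  vals <- matrix(NA_real_, n, length(catalog$features),
                 dimnames = list(NULL, catalog$names))
  for (i in seq_len(n)) {
    cf <- ds$coords[, , i]
    for (k in seq_along(catalog$features)) {
      f <- catalog$features[[k]]
      vals[i, k] <- switch(f$kind,
        distance = lm_distance(cf[f$landmarks[[1]], ], cf[f$landmarks[[2]], ]),
        angle = lm_angle(cf[f$landmarks[[1]], ], cf[f$landmarks[[2]], ],
                         cf[f$landmarks[[3]], ],
                         names = ds$schema$landmarks$name[unlist(f$landmarks)]),
        polygon_area = polygon_area(cf[unlist(f$landmarks), , drop = FALSE]),
        composite = {
          x <- vals[i, unlist(f$inputs)]
          switch(f$op, sum = sum(x), mean = mean(x),
                 difference = abs(x[1] - x[2]))
        })
    }
  }
  out <- cbind(ds$meta, as.data.frame(vals))
  structure(out, feature_names = catalog$names, units = catalog$units,
            class = c("ff_features", "data.frame"))
}

#' @export
print.ff_features <- function(x, ...) {
  cat(sprintf("Feature table: %d specimens x %d features\n", nrow(x),
              length(attr(x, "feature_names"))))
  NextMethod()
}

#' Extract the numeric feature matrix from a feature table
#' @param ft an `ff_features` table.
#' @return specimens x features numeric matrix.
#' @export
feature_matrix <- function(ft) {
  as.matrix(ft[, attr(ft, "feature_names"), drop = FALSE])
}

#' Per-feature group comparison (one-way ANOVA + Tukey HSD)
#'
#' For each feature, runs a classical fixed-effects one-way ANOVA across the
#' groups, Tukey's HSD post hoc pairwise comparisons, and flags features
#' significant at the Bonferroni-corrected level `alpha / n_features`
#' (0.05/39 rounds to 0.00128, the conventional display; the comparison is
#' done at full precision).
#'
#' @param ft an `ff_features` table.
#' @param group_col metadata column holding the group label.
#' @param alpha familywise level before Bonferroni correction.
#' @return `ff_group_comparison`: list with `table` (per-feature data frame:
#'   group means/sd, F, p, Bonferroni flag), `tukey` (named list of pairwise
#'   p-value matrices per feature), `alpha_bonferroni`, `groups`.
#' @export
compare_groups <- function(ft, group_col = "group", alpha = 0.05) {
  if (!group_col %in% names(ft))
    stop("no metadata column '", group_col, "' in the feature table")
  g <- factor(ft[[group_col]])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  small <- names(which(table(g) < 2))
  if (length(small) > 0)
    stop("group(s) with fewer than 2 specimens: ",
         paste(small, collapse = ", "))
  fn <- attr(ft, "feature_names")
  alpha_bonf <- alpha / length(fn)
  X <- feature_matrix(ft)
  rows <- list(); tukey <- list()
  for (nm in fn) {
    y <- X[, nm]
    if (stats::var(y) == 0) {
      # identical values in every group: no evidence of difference
      fstat <- 0; pval <- 1
      tk <- matrix(1, nlevels(g) * (nlevels(g) - 1) / 2, 1,
                   dimnames = list(pair_labels(levels(g)), "p adj"))
    } else {
      fit <- stats::aov(y ~ g)
      an <- summary(fit)[[1]]
      fstat <- an[["F value"]][1]
      pval <- an[["Pr(>F)"]][1]
      tk <- stats::TukeyHSD(fit)$g[, "p adj", drop = FALSE]
    }
    means <- tapply(y, g, mean)
    sds <- tapply(y, g, stats::sd)
    row <- data.frame(feature = nm, F = fstat, p = pval,
                      significant = pval < alpha_bonf)
    for (lv in levels(g)) {
      row[[paste0("mean_", lv)]] <- means[[lv]]
      row[[paste0("sd_", lv)]] <- sds[[lv]]
    }
    rows[[nm]] <- row
    tukey[[nm]] <- tk
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, tukey = tukey,
                 alpha = alpha, alpha_bonferroni = alpha_bonf,
                 alpha_bonferroni_display = round(alpha_bonf, 5),
                 groups = levels(g)),
            class = "ff_group_comparison")
}

pair_labels <- function(lv) {
  cmb <- utils::combn(lv, 2)
  paste(cmb[2, ], cmb[1, ], sep = "-")
}

#' @export
print.ff_group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison over %d features, groups: %s\n",
              nrow(x$table), paste(x$groups, collapse = ", ")))
  cat(sprintf("Bonferroni-corrected threshold: P < %.5f (%d significant)\n",
              x$alpha_bonferroni_display, sum(x$table$significant)))
  invisible(x)
}

#' Write a group comparison to CSV
#' @param gc an `ff_group_comparison`.
#' @param path output CSV.
#' @export
write_group_comparison <- function(gc, path) {
  tk <- do.call(rbind, lapply(names(gc$tukey), function(nm) {
    m <- gc$tukey[[nm]]
    stats::setNames(as.data.frame(t(m[, 1])), paste0("tukey_", rownames(m)))
  }))
  utils::write.csv(cbind(gc$table, tk), path, row.names = FALSE)
  invisible(path)
}

#' Brain (or any) length-to-width ratio
#'
#' Dimensionless per-specimen ratio of two landmark distances, e.g. the
#' telencephalon length-to-width axis.
#'
#' @param ds an [ff_dataset()].
#' @param length_indices,width_indices length-2 landmark index vectors.
#' @return numeric vector named by specimen id.
#' @export
brain_length_width_ratio <- function(ds, length_indices, width_indices) {
  stopifnot(length(length_indices) == 2L, length(width_indices) == 2L)
  idx <- c(length_indices, width_indices)
  if (any(idx < 1L | idx > ds$schema$n))
    stop("landmark indices outside 1..", ds$schema$n)
  n <- n_specimens(ds)
  out <- vapply(seq_len(n), function(i) {
    len <- lm_distance(ds$coords[length_indices[1], , i],
                       ds$coords[length_indices[2], , i])
    wid <- lm_distance(ds$coords[width_indices[1], , i],
                       ds$coords[width_indices[2], , i])
    if (wid == 0)
      stop("zero width distance for specimen '", ds$meta$specimen_id[i], "'")
    len / wid
  }, 0)
  stats::setNames(out, ds$meta$specimen_id)
}
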