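#' Run the full analysis pipeline
#'
#' Orchestrates the two-track workflow on a landmark dataset: feature-based
#' analysis (catalog measurements, group comparison, feature-space PCA) and
#' shape-based analysis (Procrustes superimposition, optional object
#' symmetry, shape PCA, CVA, DFA with wireframe output). Every run writes a
#' machine-readable provenance record (`provenance.json`: configuration,
#' seed, package version) beside the results; identical configuration and
#' seed give identical numeric outputs.
#'
#' @param ds an [ff_dataset()], or a path to a dataset file (with `format`).
#' @param out_dir output directory (created if needed).
#' @param stages character vector among `"features"`, `"compare"`, `"pca"`,
#'   `"gpa"`, `"symmetry"`, `"cva"`, `"dfa"`.
#' @param format input format when `ds` is a path: `"tps"`, `"wide"`,
#'   `"long"`, `"pointpicker"`.
#' @param catalog feature catalog (default [default_catalog()]).
#' @param group_col metadata column with the group labels.
#' @param alpha familywise alpha for the group comparison.
#' @param scale PCA scaling, `"raw"` or `"zscore"`.
#' @param use_symmetric run shape statistics on the symmetric component.
#' @param n_perm permutation rounds for CVA/DFA.
#' @param seed RNG seed used by every stochastic stage.
#' @return invisibly, a named list of the computed result objects.
#' @export
run_pipeline <- function(ds, out_dir,
                         stages = c("features", "compare", "pca", "gpa",
                                    "symmetry", "cva", "dfa"),
                         format = NULL, catalog = NULL,
                         group_col = "group", alpha = 0.05,
                         scale = "zscore", use_symmetric = TRUE,
                         n_perm = 1000, seed = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(ds)) {
    if (is.null(format)) stop("give format= when ds is a path")
    ds <- switch(format,
                 tps = read_tps(ds),
                 wide = read_csv_dataset(ds, "wide"),
                 long = read_csv_dataset(ds, "long"),
                 pointpicker = read_pointpicker(ds),
                 stop("unknown input format '", format, "'"))
  }
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(catalog)) catalog <- default_catalog(ds$schema)
  results <- list()
  t0 <- Sys.time()
  log_stage <- function(name, expr) {
    tic <- Sys.time()
    val <- force(expr)
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(Sys.time() - tic, units = "secs")))
    val
  }
  has_groups <- group_col %in% names(ds$meta) &&
    length(unique(ds$meta[[group_col]])) >= 2

  if ("features" %in% stages) {
    ft <- log_stage("features", compute_features(ds, catalog))
    utils::write.csv(ft, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    results$features <- ft
  }
  if ("compare" %in% stages) {
    if (!"features" %in% stages) stop("stage 'compare' needs 'features'")
    if (!has_groups) stop("stage 'compare' needs a '", group_col,
                          "' metadata column with >= 2 groups")
    gc <- log_stage("compare",
                    compare_groups(results$features, group_col, alpha))
    write_group_comparison(gc, file.path(out_dir, "comparison.csv"))
    results$comparison <- gc
  }
  if ("pca" %in% stages) {
    if (!"features" %in% stages) stop("stage 'pca' needs 'features'")
    pr <- log_stage("pca", ff_pca(results$features, scale = scale))
    keep <- kaiser_retain(pr)
    utils::write.csv(data.frame(specimen_id = results$features$specimen_id,
                                pr$scores),
                     file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
    utils::write.csv(data.frame(feature = rownames(pr$loadings),
                                pr$loadings),
                     file.path(out_dir, "pca_loadings.csv"),
                     row.names = FALSE)
    results$pca <- pr
    results$kaiser <- keep
    if (has_groups) {
      grDevices::svg(file.path(out_dir, "pca_scores.svg"), 6, 6)
      plot_scores(pr$scores, ds$meta[[group_col]])
      grDevices::dev.off()
    }
  }
  al <- NULL
  if (any(c("gpa", "symmetry", "cva", "dfa") %in% stages)) {
    al <- log_stage("gpa", gpa(ds))
    export_procrustes(al, file.path(out_dir, "procrustes_coords.tsv"))
    results$gpa <- al
  }
  shapes_for_stats <- al
  if ("symmetry" %in% stages) {
    sdec <- log_stage("symmetry", symmetry_decompose(ds))
    results$symmetry <- sdec
    if (use_symmetric) shapes_for_stats <- symmetric_shapes(sdec)
  }
  if (any(c("cva", "dfa") %in% stages)) {
    if (!has_groups) stop("shape group statistics need a '", group_col,
                          "' metadata column with >= 2 groups")
    g <- ds$meta[[group_col]]
    spc <- log_stage("shape_pca", shape_pca(shapes_for_stats))
    results$shape_pca <- spc
    if ("cva" %in% stages && length(unique(g)) >= 2) {
      cv <- log_stage("cva", cva(shapes_for_stats, g, n_perm = n_perm,
                                 seed = seed))
      results$cva <- cv
      utils::write.csv(as.data.frame(cv$mahalanobis),
                       file.path(out_dir, "cva_mahalanobis.csv"))
      utils::write.csv(as.data.frame(cv$procrustes),
                       file.path(out_dir, "cva_procrustes.csv"))
    }
    if ("dfa" %in% stages) {
      lv <- unique(as.character(g))
      pairs <- utils::combn(lv, 2)
      dfa_rows <- list()
      for (j in seq_len(ncol(pairs))) {
        dd <- log_stage(paste0("dfa:", pairs[1, j], "-", pairs[2, j]),
                        dfa(shapes_for_stats, g, group_a = pairs[1, j],
                            group_b = pairs[2, j], n_perm = n_perm,
                            seed = seed))
        dfa_rows[[j]] <- data.frame(group_a = pairs[1, j],
                                    group_b = pairs[2, j],
                                    procrustes_distance = dd$procrustes_distance,
                                    p_value = dd$p_value)
        wf <- wireframe(dd$mean_shapes[[1]], dd$mean_shapes[[2]],
                        schema = ds$schema)
        render_wireframe(wf, file.path(out_dir,
                                       sprintf("wireframe_%s_vs_%s.svg",
                                               pairs[1, j], pairs[2, j])))
        results$dfa[[paste(pairs[, j], collapse = "_vs_")]] <- dd
      }
      dfa_tab <- do.call(rbind, dfa_rows)
      # familywise correction over the pairwise comparisons
      dfa_tab$significant_bonferroni <-
        dfa_tab$p_value < alpha / nrow(dfa_tab)
      utils::write.csv(dfa_tab, file.path(out_dir, "dfa.csv"),
                       row.names = FALSE)
      results$dfa_table <- dfa_tab
    }
  }
  prov <- list(package = "fishface",
               version = as.character(utils::packageVersion("fishface")),
               seed = seed, n_perm = n_perm, stages = stages,
               group_col = group_col, alpha = alpha, scale = scale,
               use_symmetric = use_symmetric,
               n_specimens = n_specimens(ds),
               provenance = ds$provenance,
               elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

# PC1 x PC2 score plot coloured by group
plot_scores <- function(scores, groups, main = "PC scores") {
  g <- factor(groups)
  cols <- grDevices::hcl.colors(max(3, nlevels(g)), "Dark 3")[as.integer(g)]
  graphics::plot(scores[, 1], scores[, 2], col = cols, pch = 19,
                 xlab = colnames(scores)[1], ylab = colnames(scores)[2],
                 main = main)
  graphics::legend("topright", legend = levels(g), col =
                     grDevices::hcl.colors(max(3, nlevels(g)),
                                           "Dark 3")[seq_len(nlevels(g))],
                   pch = 19, bty = "n")
}
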