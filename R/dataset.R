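#' Landmark dataset container
#'
#' A dataset holds the landmark configurations of a set of specimens that
#' share one schema and one coordinate unit. Coordinates are stored in the
#' geomorph convention: a `p x 2 x n` array (landmarks x xy x specimens),
#' rows in schema index order.
#'
#' @param coords `p x 2 x n` numeric array, or a `p x 2` matrix for a single
#'   specimen.
#' @param schema an [landmark_schema()] object; defaults to [default_schema()].
#' @param meta data frame with one row per specimen; must contain
#'   `specimen_id`, may contain `stage_dpf`, `group` and other columns.
#' @param units `"pixel"` or `"micrometer"`.
#' @param pixel_size optional micrometres per pixel.
#' @param provenance free-text record of source files.
#' @return object of class `ff_dataset`.
#' @export
ff_dataset <- function(coords, schema = default_schema(), meta = NULL,
                       units = "pixel", pixel_size = NULL,
                       provenance = "in-memory") {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 2L)
  if (dim(coords)[1] != schema$n)
    stop("coords has ", dim(coords)[1], " landmarks; schema defines ", schema$n)
  if (!all(is.finite(coords))) stop("all landmark coordinates must be finite")
  n <- dim(coords)[3]
  if (is.null(meta)) {
    meta <- data.frame(specimen_id = sprintf("spec_%03d", seq_len(n)))
  }
  stopifnot(is.data.frame(meta), nrow(meta) == n,
            "specimen_id" %in% names(meta))
  meta$specimen_id <- as.character(meta$specimen_id)
  units <- match.arg(units, c("pixel", "micrometer"))
  dimnames(coords) <- list(NULL, c("x", "y"), meta$specimen_id)
  structure(list(coords = coords, schema = schema, meta = meta,
                 units = units, pixel_size = pixel_size,
                 provenance = provenance),
            class = "ff_dataset")
}

#' @export
print.ff_dataset <- function(x, ...) {
  cat(sprintf("Landmark dataset: %d specimens x %d landmarks [%s]\n",
              n_specimens(x), x$schema$n, x$units))
  if (!is.null(x$meta$group))
    cat("  groups:", paste(names(table(x$meta$group)), table(x$meta$group),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of specimens in a dataset
#' @param ds an `ff_dataset`.
#' @export
n_specimens <- function(ds) dim(ds$coords)[3]

#' Subset a dataset by specimen
#' @param ds an `ff_dataset`.
#' @param idx integer, logical or character (specimen id) index.
#' @export
subset_specimens <- function(ds, idx) {
  if (is.character(idx)) idx <- match(idx, ds$meta$specimen_id)
  ff_dataset(ds$coords[, , idx, drop = FALSE], schema = ds$schema,
             meta = ds$meta[idx, , drop = FALSE], units = ds$units,
             pixel_size = ds$pixel_size, provenance = ds$provenance)
}

#' Combine datasets sharing a schema and units
#' @param ... `ff_dataset` objects.
#' @export
bind_datasets <- function(...) {
  dss <- list(...)
  stopifnot(length(dss) >= 1L)
  units <- unique(vapply(dss, `[[`, "", "units"))
  if (length(units) != 1L)
    stop("cannot combine datasets with mixed units: ",
         paste(units, collapse = ", "))
  ns <- vapply(dss, function(d) d$schema$n, 0L)
  if (length(unique(ns)) != 1L) stop("datasets use different schemas")
  coords <- do.call(abind3, lapply(dss, `[[`, "coords"))
  cols <- Reduce(union, lapply(dss, function(d) names(d$meta)))
  meta <- do.call(rbind, lapply(dss, function(d) {
    m <- d$meta
    for (cl in setdiff(cols, names(m))) m[[cl]] <- NA
    m[, cols, drop = FALSE]
  }))
  ff_dataset(coords, schema = dss[[1]]$schema, meta = meta, units = units,
             provenance = paste(vapply(dss, `[[`, "", "provenance"),
                                collapse = "; "))
}

#' Validate a landmark dataset
#'
#' Reporting-only checks: duplicated specimen ids; per-landmark coordinate
#' outliers (distance from the per-landmark dataset median, after centering
#' each specimen, exceeding `k` times the MAD of those distances); and
#' left/right label swaps, detected per bilateral pair from the sign of the
#' signed area of the (left, top-midline, right) triangle relative to the
#' dataset majority for that pair.
#'
#' @param ds an `ff_dataset`.
#' @param k MAD multiplier for the outlier rule (default 6).
#' @return data frame of findings with columns `type`, `specimen_id`,
#'   `landmark`, `message`; zero rows when the dataset is clean. The input
#'   is never modified.
#' @export
validate_dataset <- function(ds, k = 6) {
  findings <- list()
  add <- function(type, specimen_id, landmark, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      type = type, specimen_id = specimen_id,
      landmark = if (is.null(landmark)) NA_integer_ else as.integer(landmark),
      message = message)
  }
  dup <- ds$meta$specimen_id[duplicated(ds$meta$specimen_id)]
  for (id in unique(dup))
    add("duplicate_id", id, NULL, paste0("specimen id '", id, "' occurs ",
        sum(ds$meta$specimen_id == id), " times"))

  n <- n_specimens(ds); p <- ds$schema$n
  centred <- ds$coords
  for (i in seq_len(n))
    centred[, , i] <- sweep(centred[, , i], 2, colMeans(centred[, , i]))
  if (n >= 4L) {
    med <- apply(centred, c(1, 2), stats::median)
    dist_to_med <- sqrt(apply((centred - c(med))^2, c(1, 3), sum))
    for (j in seq_len(p)) {
      m <- stats::mad(dist_to_med[j, ], center = 0)
      if (m <= 0) next
      out <- which(dist_to_med[j, ] > k * m)
      for (i in out)
        add("outlier", ds$meta$specimen_id[i], j,
            sprintf("landmark %d is %.1f MADs from the dataset median", j,
                    dist_to_med[j, i] / m))
    }
  }

  # pair swap detection via signed area of (left, top midline, right)
  if (nrow(ds$schema$pairs) > 0L && length(ds$schema$midline) > 0L && n >= 3L) {
    top <- ds$schema$midline[1]
    for (pr in seq_len(nrow(ds$schema$pairs))) {
      l <- ds$schema$pairs[pr, 1]; r <- ds$schema$pairs[pr, 2]
      sa <- vapply(seq_len(n), function(i) {
        a <- ds$coords[l, , i]; b <- ds$coords[top, , i]; cc <- ds$coords[r, , i]
        (b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])
      }, 0)
      s <- sign(sa)
      maj <- sign(sum(s))
      if (maj == 0) next
      for (i in which(s == -maj & s != 0))
        add("pair_swap", ds$meta$specimen_id[i], l,
            sprintf("landmarks %d/%d (%s / %s) appear side-swapped", l, r,
                    ds$schema$landmarks$name[l], ds$schema$landmarks$name[r]))
    }
  }

  if (length(findings) == 0L)
    return(data.frame(type = character(), specimen_id = character(),
                      landmark = integer(), message = character()))
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}

# bind 3d arrays along the third margin
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])[1:2]
  n <- sum(vapply(arrs, function(a) dim(a)[3], 0L))
  out <- array(NA_real_, c(d, n))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[3]
    out[, , at + seq_len(k)] <- a
    at <- at + k
  }
  out
}
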