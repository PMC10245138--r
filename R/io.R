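#' Read an ImageJ Point Picker export
#'
#' Reads a whitespace/tab-delimited point list, one landmark per row in
#' schema numerical order. Column handling is positional: 2 columns are
#' `(x, y)`; 3 columns are `(index, x, y)`; 4 or more columns are
#' `(index, x, y, ...)` with trailing columns (slice etc.) ignored.
#'
#' @param path point list file.
#' @param specimen_id id to assign to the specimen.
#' @param schema landmark schema (default [default_schema()]).
#' @param allow_extra if `TRUE`, files with more rows than landmarks keep the
#'   first `schema$n` rows instead of erroring.
#' @param units coordinate units, `"pixel"` by default.
#' @return an [ff_dataset()] with one specimen whose row order equals the
#'   file row order.
#' @export
read_pointpicker <- function(path, specimen_id = basename(path),
                             schema = default_schema(), allow_extra = FALSE,
                             units = "pixel") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  # drop a non-numeric header line if present
  first_tok <- function(s) strsplit(trimws(s), "\\s+")[[1]][1]
  if (length(lines) > 0 && is.na(suppressWarnings(as.numeric(first_tok(lines[1])))))
    lines <- lines[-1]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[\\s,]+", perl = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(tok))
    if (anyNA(num))
      stop("non-numeric cell in '", path, "' at line ", i, ": '", lines[i], "'")
    if (length(num) < 2L)
      stop("line ", i, " of '", path, "' has fewer than 2 columns")
    rows[[i]] <- if (length(num) == 2L) num else num[2:3]
  }
  m <- do.call(rbind, rows)
  p <- schema$n
  if (is.null(m) || nrow(m) < p)
    stop("expected ", p, " landmarks, found ", if (is.null(m)) 0L else nrow(m),
         " in '", path, "'")
  if (nrow(m) > p) {
    if (!allow_extra)
      stop("expected ", p, " landmarks, found ", nrow(m), " in '", path,
           "' (use allow_extra = TRUE to keep the first ", p, ")")
    m <- m[seq_len(p), , drop = FALSE]
  }
  ff_dataset(array(m, c(p, 2, 1)), schema = schema,
             meta = data.frame(specimen_id = specimen_id),
             units = units, provenance = path)
}

#' Read / write landmark datasets as CSV
#'
#' Two dialects are supported. `wide`: one row per specimen with columns
#' `specimen_id`, `x1,y1,...,xP,yP` plus any metadata columns. `long`: one
#' row per landmark with columns `specimen_id`, `landmark`, `x`, `y` plus
#' metadata columns (constant within specimen). Round-trips through
#' [write_csv_dataset()] are lossless: coordinates are written with full
#' precision.
#'
#' @param path CSV file.
#' @param dialect `"wide"` or `"long"`.
#' @param schema landmark schema.
#' @param units coordinate units.
#' @return an [ff_dataset()].
#' @export
read_csv_dataset <- function(path, dialect = c("wide", "long"),
                             schema = default_schema(), units = "pixel") {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  p <- schema$n
  if (dialect == "wide") {
    cn <- c(paste0("x", seq_len(p)), paste0("y", seq_len(p)))
    missing <- setdiff(cn, names(df))
    if (length(missing) > 0)
      stop("wide CSV '", path, "' lacks coordinate columns: ",
           paste(utils::head(missing, 6), collapse = ", "))
    if (!"specimen_id" %in% names(df))
      df$specimen_id <- sprintf("spec_%03d", seq_len(nrow(df)))
    bad <- which(!stats::complete.cases(df[, cn]))
    if (length(bad) > 0)
      stop("specimen(s) with missing landmark coordinates: ",
           paste(df$specimen_id[bad], collapse = ", "))
    n <- nrow(df)
    coords <- array(NA_real_, c(p, 2, n))
    for (i in seq_len(n)) {
      coords[, 1, i] <- as.numeric(df[i, paste0("x", seq_len(p))])
      coords[, 2, i] <- as.numeric(df[i, paste0("y", seq_len(p))])
    }
    meta <- df[, setdiff(names(df), cn), drop = FALSE]
  } else {
    need <- c("specimen_id", "landmark", "x", "y")
    if (!all(need %in% names(df)))
      stop("long CSV '", path, "' needs columns ", paste(need, collapse = ", "))
    ids <- unique(df$specimen_id)
    n <- length(ids)
    coords <- array(NA_real_, c(p, 2, n))
    extra <- setdiff(names(df), need)
    meta <- data.frame(specimen_id = ids, stringsAsFactors = FALSE)
    for (cl in extra) meta[[cl]] <- NA
    for (i in seq_len(n)) {
      sub <- df[df$specimen_id == ids[i], , drop = FALSE]
      got <- as.integer(sub$landmark)
      miss <- setdiff(seq_len(p), got)
      if (length(miss) > 0)
        stop("specimen '", ids[i], "' is missing landmark(s) ",
             paste(miss, collapse = ", "))
      coords[got, 1, i] <- sub$x
      coords[got, 2, i] <- sub$y
      for (cl in extra) meta[i, cl] <- sub[[cl]][1]
    }
  }
  if ("stage_dpf" %in% names(meta)) meta$stage_dpf <- as.numeric(meta$stage_dpf)
  ff_dataset(coords, schema = schema, meta = meta, units = units,
             provenance = path)
}

#' @rdname read_csv_dataset
#' @param ds dataset to write.
#' @export
write_csv_dataset <- function(ds, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  p <- ds$schema$n
  n <- n_specimens(ds)
  if (dialect == "wide") {
    out <- ds$meta
    for (j in seq_len(p)) out[[paste0("x", j)]] <- ds$coords[j, 1, ]
    for (j in seq_len(p)) out[[paste0("y", j)]] <- ds$coords[j, 2, ]
  } else {
    out <- do.call(rbind, lapply(seq_len(n), function(i) {
      d <- data.frame(specimen_id = ds$meta$specimen_id[i],
                      landmark = seq_len(p),
                      x = ds$coords[, 1, i], y = ds$coords[, 2, i])
      for (cl in setdiff(names(ds$meta), "specimen_id"))
        d[[cl]] <- ds$meta[i, cl]
      d
    }))
  }
  # full double precision so wide/long round-trips are bit-identical
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write TPS landmark files
#'
#' TPS is the interchange dialect of landmark morphometrics. Records start
#' with `LM=<count>`, followed by one `x y` line per landmark, then optional
#' `ID=`, `IMAGE=` and `SCALE=` keys. When `apply_scale = TRUE` and a record
#' carries `SCALE=`, coordinates are multiplied by the scale factor and the
#' dataset units are set to micrometres.
#'
#' @param path TPS file.
#' @param schema landmark schema; the `LM=` count must match.
#' @param apply_scale multiply coordinates by any `SCALE=` key.
#' @return an [ff_dataset()].
#' @export
read_tps <- function(path, schema = default_schema(), apply_scale = FALSE) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0) stop("no LM= records in '", path, "'")
  p <- schema$n
  specs <- list(); ids <- character(); scales <- numeric()
  bounds <- c(starts, length(lines) + 1L)
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:(bounds[k + 1L] - 1L)]
    lm <- as.integer(sub("^LM\\s*=\\s*", "", block[1], ignore.case = TRUE))
    if (lm != p)
      stop("TPS record ", k, " declares LM=", lm, " but the schema has ",
           p, " landmarks")
    coord_lines <- block[1L + seq_len(lm)]
    m <- t(vapply(coord_lines, function(s) {
      v <- suppressWarnings(as.numeric(strsplit(s, "\\s+")[[1]]))
      if (length(v) < 2 || anyNA(v[1:2]))
        stop("bad coordinate line in TPS record ", k, ": '", s, "'")
      v[1:2]
    }, c(0, 0)))
    rest <- block[-seq_len(lm + 1L)]
    id <- sub("^(ID|IMAGE)\\s*=\\s*", "",
              grep("^(ID|IMAGE)\\s*=", rest, ignore.case = TRUE, value = TRUE),
              ignore.case = TRUE)
    sc <- sub("^SCALE\\s*=\\s*", "",
              grep("^SCALE\\s*=", rest, ignore.case = TRUE, value = TRUE),
              ignore.case = TRUE)
    ids[k] <- if (length(id) > 0) id[1] else sprintf("spec_%03d", k)
    scales[k] <- if (length(sc) > 0) as.numeric(sc[1]) else NA_real_
    specs[[k]] <- m
  }
  coords <- array(NA_real_, c(p, 2, length(specs)))
  for (k in seq_along(specs)) coords[, , k] <- specs[[k]]
  units <- "pixel"
  if (apply_scale && any(!is.na(scales))) {
    for (k in which(!is.na(scales))) coords[, , k] <- coords[, , k] * scales[k]
    units <- "micrometer"
  }
  ff_dataset(coords, schema = schema,
             meta = data.frame(specimen_id = ids), units = units,
             provenance = path)
}

#' @rdname read_tps
#' @param ds dataset to write.
#' @param scale optional `SCALE=` value written into every record.
#' @export
write_tps <- function(ds, path, scale = NULL) {
  p <- ds$schema$n
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(n_specimens(ds))) {
    writeLines(sprintf("LM=%d", p), con)
    writeLines(sprintf("%.10g %.10g", ds$coords[, 1, i], ds$coords[, 2, i]), con)
    writeLines(sprintf("ID=%s", ds$meta$specimen_id[i]), con)
    if (!is.null(scale)) writeLines(sprintf("SCALE=%.10g", scale), con)
  }
  invisible(path)
}
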