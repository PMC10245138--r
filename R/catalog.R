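#' Feature catalog
#'
#' A catalog is the declarative definition of the automated facial
#' measurements: each entry is a distance (2 landmarks), an angle
#' (3 landmarks, vertex listed second), a polygon area (>= 3 landmarks) or a
#' composite (`sum`, `mean` or absolute `difference` of previously defined
#' features). The default catalog has 39 entries.
#'
#' @param features list of feature definitions (each a list with `name`,
#'   `kind`, and `landmarks` or `op`+`inputs`).
#' @param schema schema the landmark indices are validated against.
#' @param name,version catalog identification.
#' @return object of class `ff_catalog`.
#' @export
feature_catalog <- function(features, schema = default_schema(),
                            name = "custom", version = "0") {
  nms <- vapply(features, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate feature names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  seen <- character()
  for (f in features) {
    kind <- f$kind
    if (!kind %in% c("distance", "angle", "polygon_area", "composite"))
      stop("feature '", f$name, "': unknown kind '", kind, "'")
    if (kind == "composite") {
      if (!f$op %in% c("sum", "mean", "difference"))
        stop("feature '", f$name, "': unknown composite op '", f$op, "'")
      bad <- setdiff(unlist(f$inputs), seen)
      if (length(bad) > 0)
        stop("composite '", f$name, "' references undefined feature(s): ",
             paste(bad, collapse = ", "))
      if (f$op == "difference" && length(f$inputs) != 2L)
        stop("composite '", f$name, "': difference takes exactly 2 inputs")
    } else {
      idx <- as.integer(unlist(f$landmarks))
      if (any(idx < 1L | idx > schema$n))
        stop("feature '", f$name, "' references landmark(s) outside 1..",
             schema$n, ": ", paste(idx[idx < 1L | idx > schema$n], collapse = ", "))
      need <- switch(kind, distance = 2L, angle = 3L, polygon_area = NA)
      if (kind == "polygon_area") {
        if (length(idx) < 3L)
          stop("polygon feature '", f$name, "' needs >= 3 landmarks")
      } else if (length(idx) != need) {
        stop("feature '", f$name, "' (", kind, ") needs exactly ", need,
             " landmarks, got ", length(idx))
      }
    }
    seen <- c(seen, f$name)
  }
  units <- vapply(features, feature_units_one, "", nms = nms, features = features)
  structure(list(features = features, names = nms, units = units,
                 schema = schema, name = name, version = version),
            class = "ff_catalog")
}

feature_units_one <- function(f, nms, features) {
  switch(f$kind,
    distance = "length",
    angle = "degrees",
    polygon_area = "length2",
    composite = {
      iu <- unique(vapply(f$inputs, function(nm)
        feature_units_one(features[[match(nm, nms)]], nms, features), ""))
      if (length(iu) == 1L) iu else "mixed"
    })
}

#' Read a feature catalog from YAML
#' @param path YAML catalog file.
#' @param schema schema to validate against.
#' @export
read_catalog <- function(path, schema = default_schema()) {
  y <- yaml::read_yaml(path)
  feature_catalog(y$features, schema = schema,
                  name = if (is.null(y$name)) "custom" else y$name,
                  version = if (is.null(y$version)) "0" else y$version)
}

#' The default 39-measurement catalog
#' @param schema schema to validate against (default [default_schema()]).
#' @export
default_catalog <- function(schema = default_schema()) {
  read_catalog(system.file("extdata", "catalog_default.yaml",
                           package = "fishface", mustWork = TRUE),
               schema = schema)
}

#' @export
print.ff_catalog <- function(x, ...) {
  kinds <- table(vapply(x$features, `[[`, "", "kind"))
  cat(sprintf("Feature catalog '%s' v%s: %d features (%s)\n", x$name,
              x$version, length(x$features),
              paste(names(kinds), kinds, sep = "=", collapse = ", ")))
  invisible(x)
}
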