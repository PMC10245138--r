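#' Landmark schema
#'
#' A landmark schema is the named, ordered, sided definition of the landmark
#' set: each landmark has an index, a name, a side (`"midline"`, `"left"` or
#' `"right"`) and, for sided landmarks, the index of its contralateral
#' partner. The default schema has 26 landmarks: 4 midline points and 11
#' bilateral pairs, with 8 of the 26 on the mouth.
#'
#' @param landmarks data frame with columns `index`, `name`, `side` and
#'   `pair` (`NA` for midline landmarks).
#' @param name schema name.
#' @param mouth_indices optional integer vector of mouth landmark indices.
#' @return object of class `ff_schema` with elements `landmarks` (data
#'   frame), `n`, `midline` (integer vector), `pairs` (two-column integer
#'   matrix, left index first) and `mouth_indices`.
#' @export
landmark_schema <- function(landmarks, name = "custom", mouth_indices = integer()) {
  stopifnot(is.data.frame(landmarks),
            all(c("index", "name", "side") %in% names(landmarks)))
  if (is.null(landmarks$pair)) landmarks$pair <- NA_integer_
  landmarks$index <- as.integer(landmarks$index)
  landmarks$pair <- as.integer(landmarks$pair)
  n <- nrow(landmarks)
  if (!identical(sort(landmarks$index), seq_len(n)))
    stop("landmark indices must cover 1..", n, " exactly once")
  landmarks <- landmarks[order(landmarks$index), , drop = FALSE]
  rownames(landmarks) <- NULL
  if (!all(landmarks$side %in% c("midline", "left", "right")))
    stop("side must be one of 'midline', 'left', 'right'")
  mid <- landmarks$index[landmarks$side == "midline"]
  sided <- landmarks$side != "midline"
  if (any(sided & is.na(landmarks$pair)))
    stop("sided landmarks must declare a pair index")
  if (any(!sided & !is.na(landmarks$pair)))
    stop("midline landmarks must not declare a pair index")
  # pair relation must be a symmetric involution between opposite sides
  for (i in landmarks$index[sided]) {
    j <- landmarks$pair[i]
    if (is.na(j) || j < 1L || j > n || j == i)
      stop("invalid pair index for landmark ", i)
    if (!identical(landmarks$pair[j], i))
      stop("pair relation is not symmetric for landmarks ", i, " and ", j)
    if (landmarks$side[i] == landmarks$side[j])
      stop("landmarks ", i, " and ", j, " pair within the same side")
  }
  left <- landmarks$index[landmarks$side == "left"]
  pairs <- cbind(left = left, right = landmarks$pair[left])
  if (2L * nrow(pairs) + length(mid) != n)
    stop("pairs and midline landmarks do not partition the schema")
  structure(list(landmarks = landmarks, n = n, midline = mid,
                 pairs = pairs, mouth_indices = as.integer(mouth_indices),
                 name = name),
            class = "ff_schema")
}

#' Read a landmark schema from a YAML file
#'
#' @param path YAML file with a `landmarks` list (keys `index`, `name`,
#'   `side`, `pair`) and optional `name` and `mouth_indices` keys.
#' @return an [landmark_schema()] object.
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  lm <- do.call(rbind, lapply(y$landmarks, function(l) {
    data.frame(index = as.integer(l$index), name = l$name, side = l$side,
               pair = if (is.null(l$pair)) NA_integer_ else as.integer(l$pair))
  }))
  landmark_schema(lm, name = if (is.null(y$name)) "custom" else y$name,
                  mouth_indices = as.integer(unlist(y$mouth_indices)))
}

#' The default 26-landmark rostral-view schema
#'
#' @return the schema shipped with the package: 26 landmarks, 4 midline and
#'   11 left/right pairs (glabella, frontotemporale, olfactory placodes,
#'   eye canthi, zygia, neuromasts, and the mouth landmarks labiale
#'   superius/inferius, crista philtri, chelion, oral laterals, plus gonion
#'   and gnathion).
#' @export
default_schema <- function() {
  read_schema(system.file("extdata", "schema_default.yaml",
                          package = "fishface", mustWork = TRUE))
}

#' @export
print.ff_schema <- function(x, ...) {
  cat(sprintf("Landmark schema '%s': %d landmarks (%d midline, %d pairs)\n",
              x$name, x$n, length(x$midline), nrow(x$pairs)))
  invisible(x)
}

# permutation that swaps left/right labels (identity on midline landmarks)
schema_relabel_perm <- function(schema) {
  perm <- seq_len(schema$n)
  perm[schema$pairs[, "left"]] <- schema$pairs[, "right"]
  perm[schema$pairs[, "right"]] <- schema$pairs[, "left"]
  perm
}
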