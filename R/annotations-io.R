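#' Build an annotation set
#'
#' Region annotations live in 40x-level pixel coordinates (0-based,
#' origin top-left). Each region is a simple polygon carrying one class
#' label; regions of the same class may overlap.
#'
#' @param scan_id Scan identifier.
#' @param labels Character vector of class codes, one per region.
#' @param rings List of polygon rings (2-column x,y matrices; an
#'   explicit closing vertex is allowed and dropped).
#' @return Tibble with columns `scan_id`, `region_id`, `label`,
#'   `geometry` (list-column of normalized open rings).
#' @examples
#' sq <- rbind(c(0, 0), c(256, 0), c(256, 256), c(0, 256))
#' annotation_set("s1", "R4", list(sq))
#' @export
annotation_set <- function(scan_id, labels, rings) {
  stopifnot(length(labels) == length(rings))
  severity_rank(labels) # validates codes
  rings <- lapply(rings, normalize_ring)
  simple <- vapply(rings, is_simple_ring, logical(1))
  if (any(!simple)) {
    stop("self-intersecting polygon(s) at region ",
         paste(which(!simple), collapse = ", "))
  }
  tibble::tibble(
    scan_id = scan_id,
    region_id = seq_along(rings),
    label = as.character(labels),
    geometry = rings
  )
}

#' Read or write region annotations as GeoJSON
#'
#' Annotations are exchanged as a GeoJSON FeatureCollection of Polygon
#' features, each with a `label` property holding a valid class code.
#' Coordinates are interpreted as 40x-level pixels. Features with an
#' unknown label, non-Polygon geometry, or interior rings (holes) are
#' rejected with the offending feature index.
#'
#' @param path File path.
#' @param scan_id Scan identifier; defaults to the top-level `scan_id`
#'   member if present, else the file name without extension.
#' @return `read_annotations()` returns an [annotation_set()] tibble.
#' @export
read_annotations <- function(path, scan_id = NULL) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  if (is.null(scan_id)) {
    scan_id <- gj$scan_id %||% sub("\\.[^.]*$", "", basename(path))
  }
  feats <- gj$features %||% list()
  labels <- character(0)
  rings <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- f$geometry
    if (is.null(geom$type) || geom$type != "Polygon") {
      stop("feature ", i, ": geometry type is not Polygon")
    }
    if (length(geom$coordinates) != 1) {
      stop("feature ", i, ": interior rings (holes) are not supported")
    }
    lab <- f$properties$label
    if (is.null(lab) || !lab %in% class_labels()) {
      stop("feature ", i, ": unknown class label ",
           if (is.null(lab)) "<missing>" else paste0("'", lab, "'"))
    }
    ring <- do.call(rbind, lapply(geom$coordinates[[1]], function(p) {
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))
    }))
    labels <- c(labels, lab)
    rings <- c(rings, list(ring))
  }
  annotation_set(scan_id, labels, rings)
}

#' @rdname read_annotations
#' @param annotations An [annotation_set()] tibble.
#' @return `write_annotations()` invisibly returns `path`.
#' @export
write_annotations <- function(annotations, path) {
  feats <- purrr::map2(annotations$geometry, annotations$label, function(ring, lab) {
    closed <- rbind(ring, ring[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(label = lab),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(closed)),
                                  function(i) closed[i, ]))
      )
    )
  })
  gj <- list(type = "FeatureCollection",
             scan_id = annotations$scan_id[1] %||% "scan",
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

manifest_partitions <- c("train", "validation", "test")

validate_manifest <- function(manifest) {
  need <- c("scan_id", "magnification", "x", "y", "label", "partition")
  missing <- setdiff(need, names(manifest))
  if (length(missing)) stop("manifest lacks column(s): ",
                            paste(missing, collapse = ", "))
  if (!all(manifest$magnification %in% c(40, 20, 10, 5))) {
    stop("magnification must be one of 40, 20, 10, 5")
  }
  if (any(manifest$x %% 128 != 0 | manifest$y %% 128 != 0)) {
    stop("patch coordinates must lie on the stride-128 lattice")
  }
  severity_rank(manifest$label) # validates non-NA codes
  if (!all(manifest$partition %in% manifest_partitions)) {
    stop("partition must be one of ",
         paste(manifest_partitions, collapse = ", "))
  }
  key <- paste(manifest$scan_id, manifest$magnification, manifest$x,
               manifest$y)
  if (anyDuplicated(key)) stop("duplicate (scan_id, magnification, x, y) rows")
  parts <- dplyr::distinct(manifest, .data$scan_id, .data$partition)
  if (anyDuplicated(parts$scan_id)) {
    stop("a scan_id appears in more than one partition")
  }
  invisible(manifest)
}

#' Read or write a patch manifest
#'
#' A patch manifest lists every extracted patch: scan, magnification,
#' top-left (x, y) on the stride-128 lattice at that magnification, the
#' assigned class label (empty when unlabeled), and the scan's
#' partition. Partitions are disjoint at the scan level.
#'
#' @param manifest Tibble with columns `scan_id`, `magnification`, `x`,
#'   `y`, `label` (`NA` = unlabeled), `partition`.
#' @param path CSV file path.
#' @return `read_manifest()` returns the manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_csv(
    manifest[, c("scan_id", "magnification", "x", "y", "label", "partition")],
    path, na = "")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, col_types = readr::cols(
    scan_id = readr::col_character(),
    magnification = readr::col_double(),
    x = readr::col_double(),
    y = readr::col_double(),
    label = readr::col_character(),
    partition = readr::col_character()
  ), na = "")
  validate_manifest(m)
  m
}

#' Read or write a probability map
#'
#' Maps are stored in a plain-text CSV format: `#`-prefixed header
#' lines carry `scan_id`, `magnification` and the class order, followed
#' by one row per grid cell (`row,col,valid`, then one probability
#' column per class). On read, vectors whose sum deviates from 1 by
#' more than `1e-4` are renormalized with a warning; a file without the
#' class-order header is rejected.
#'
#' @param map A [prob_map()].
#' @param path CSV file path.
#' @return `read_probability_map()` returns a [prob_map()].
#' @export
write_probability_map <- function(map, path) {
  stopifnot(inherits(map, "prob_map"))
  d <- dim(map$grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# prob_map v1",
    paste0("# scan_id: ", map$scan_id),
    paste0("# magnification: ", map$magnification),
    paste0("# classes: ", paste(map$classes, collapse = ","))
  ), con)
  flat <- matrix(aperm(map$grid, c(3, 1, 2)), nrow = d[1] * d[2],
                 ncol = d[3], byrow = TRUE)
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df <- cbind(idx, valid = as.vector(map$valid), flat)
  names(df) <- c("row", "col", "valid", map$classes)
  writeLines(paste(names(df), collapse = ","), con)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_probability_map
#' @export
read_probability_map <- function(path) {
  header <- readLines(path, n = 10)
  header <- header[startsWith(header, "#")]
  meta <- function(key) {
    line <- grep(paste0("^# ", key, ": "), header, value = TRUE)
    if (length(line) == 0) return(NULL)
    sub(paste0("^# ", key, ": "), "", line[1])
  }
  classes <- meta("classes")
  if (is.null(classes)) stop("probability-map file lacks a class-order header")
  classes <- strsplit(classes, ",")[[1]]
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("row", "col", "valid", classes) %in% names(df)))
  h <- max(df$row); w <- max(df$col)
  grid <- array(NA_real_, dim = c(h, w, length(classes)))
  valid <- matrix(NA, h, w)
  valid[cbind(df$row, df$col)] <- as.logical(df$valid)
  probs <- as.matrix(df[, classes, drop = FALSE])
  sums <- rowSums(probs)
  off <- as.logical(valid[cbind(df$row, df$col)]) & abs(sums - 1) > 1e-4
  if (any(off)) {
    warning(sum(off), " probability vector(s) deviated from sum 1 by >1e-4; ",
            "renormalized")
    probs[off, ] <- probs[off, , drop = FALSE] / sums[off]
  }
  for (k in seq_along(classes)) {
    grid[cbind(df$row, df$col, k)] <- probs[, k]
  }
  prob_map(grid, classes, valid,
           scan_id = meta("scan_id") %||% "scan",
           magnification = as.numeric(meta("magnification") %||% 40),
           tol = 1e-4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
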