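#' Rescale a probability map to a coarser grid
#'
#' Probability maps produced at a higher magnification cover the same
#' scan region with a denser grid; they are brought to a common
#' dimensionality by block-averaging the probability vectors over each
#' `r x r` block (which keeps them on the simplex and commutes with map
#' averaging). The validity mask is the logical OR over each block. The
#' ratio between source and target shape must be an integer per axis.
#'
#' @param map A [prob_map()].
#' @param target_shape `c(rows, cols)` of the target grid.
#' @return A [prob_map()] of the target shape.
#' @export
rescale_map <- function(map, target_shape) {
  stopifnot(inherits(map, "prob_map"), length(target_shape) == 2)
  d <- dim(map$grid)
  r <- d[1:2] / target_shape
  if (any(r != round(r)) || any(r < 1)) {
    stop("source shape ", d[1], "x", d[2],
         " is not an integer multiple of target ", target_shape[1], "x",
         target_shape[2])
  }
  gr <- (seq_len(d[1]) - 1) %/% r[1]
  gc <- (seq_len(d[2]) - 1) %/% r[2]
  out <- array(NA_real_, dim = c(target_shape, d[3]))
  for (k in seq_len(d[3])) {
    out[, , k] <- t(rowsum(t(rowsum(map$grid[, , k], gr)), gc)) / (r[1] * r[2])
  }
  valid <- t(rowsum(t(rowsum(map$valid * 1, gr)), gc)) > 0
  prob_map(out, map$classes, valid, map$scan_id, map$magnification)
}

#' Average probability maps on a common grid
#'
#' Elementwise arithmetic mean of the members' probability vectors;
#' the validity mask is the logical OR.
#'
#' @param maps List of [prob_map()]s with identical shapes and class
#'   lists.
#' @return A [prob_map()].
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 1, all(vapply(maps, inherits, logical(1), "prob_map")))
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!identical(dim(m$grid), dim(ref$grid))) stop("map shape mismatch")
    if (!identical(m$classes, ref$classes)) stop("map class-list mismatch")
  }
  grid <- Reduce(`+`, lapply(maps, `[[`, "grid")) / length(maps)
  valid <- Reduce(`|`, lapply(maps, `[[`, "valid"))
  prob_map(grid, ref$classes, valid, ref$scan_id, ref$magnification)
}

#' Merge classes of a probability map into groups
#'
#' Group probabilities are the sums of their member-class
#' probabilities; the grouping must partition the class list.
#'
#' @param map A [prob_map()].
#' @param grouping Named list of character vectors, e.g.
#'   [binary_grouping()].
#' @return A [prob_map()] over the group names.
#' @export
merge_class_groups <- function(map, grouping) {
  stopifnot(inherits(map, "prob_map"))
  members <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(members) || !setequal(members, map$classes)) {
    stop("grouping must partition the class list")
  }
  d <- dim(map$grid)
  out <- array(0, dim = c(d[1], d[2], length(grouping)))
  for (g in seq_along(grouping)) {
    idx <- match(grouping[[g]], map$classes)
    out[, , g] <- apply(map$grid[, , idx, drop = FALSE], c(1, 2), sum)
  }
  prob_map(out, names(grouping), map$valid, map$scan_id, map$magnification)
}

#' Binarize a probability map into a cancer/non-cancer call per cell
#'
#' By default a cell is called cancerous when its argmax class is
#' cancerous under the chosen setting; alternatively a threshold on the
#' summed cancer-class probability can be used.
#'
#' @param map A [prob_map()].
#' @param setting `"S1"` or `"S2"` (which grades count as cancerous);
#'   for maps already merged to `NC`/`C` classes the setting is
#'   ignored.
#' @param prob_threshold If non-`NULL`, call cancer when the summed
#'   cancer probability is at or above this value instead of by argmax.
#' @return Logical matrix (`NA` on invalid cells).
#' @export
binarize_map <- function(map, setting = "S1", prob_threshold = NULL) {
  stopifnot(inherits(map, "prob_map"))
  cancer <- if (setequal(map$classes, c("NC", "C"))) "C" else {
    map$classes[is_cancerous(map$classes, setting)]
  }
  if (is.null(prob_threshold)) {
    am <- argmax_map(map)
    out <- matrix(am %in% cancer, nrow(am), ncol(am))
  } else {
    idx <- match(cancer, map$classes)
    pc <- apply(map$grid[, , idx, drop = FALSE], c(1, 2), sum)
    out <- pc >= prob_threshold
  }
  out[!map$valid] <- NA
  out
}

#' Median filtering of a binary prediction map
#'
#' Each cell is replaced by the median of its `k x k` neighborhood,
#' eliminating isolated outliers that do not form larger clusters.
#' Borders are handled by reflection padding; cells marked invalid are
#' excluded from every neighborhood (and left unchanged themselves).
#' A tie (possible only when invalid cells shrink a neighborhood to an
#' even count) keeps the cell's own value.
#'
#' @param binary_map Logical (or 0/1) matrix; `NA` entries are treated
#'   as invalid.
#' @param k Odd kernel size.
#' @param valid Optional logical matrix of valid cells.
#' @return Logical matrix of the same shape.
#' @export
median_filter_map <- function(binary_map, k = 3, valid = NULL) {
  if (k %% 2 == 0) stop("kernel size k must be odd")
  m <- matrix(as.logical(binary_map), nrow(binary_map), ncol(binary_map))
  if (is.null(valid)) valid <- !is.na(m)
  h <- nrow(m); w <- ncol(m)
  r <- (k - 1) / 2
  reflect <- function(i, n) {
    # reflection without edge repetition: ... 3 2 | 1 2 3 ... n | n-1 n-2
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  out <- m
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!valid[i, j]) next
      ri <- reflect(i + (-r:r), h)
      rj <- reflect(j + (-r:r), w)
      nb_v <- valid[ri, rj, drop = FALSE]
      nb <- m[ri, rj, drop = FALSE][nb_v]
      if (length(nb) == 0) next
      pos <- sum(nb)
      out[i, j] <- if (pos * 2 == length(nb)) m[i, j] else pos * 2 > length(nb)
    }
  }
  out[!valid] <- NA
  out
}

#' Specify a map ensemble
#'
#' @param members Tibble (or data frame) with columns `model` and
#'   `magnification`, one row per ensemble member. All members must
#'   share a class list; the target grid is the grid of the
#'   lowest-magnification member.
#' @param median_filter `"none"`, `"after"` (binarize the ensemble map,
#'   then filter) or `"before"` (binarize and filter each member's
#'   rescaled map, then combine by majority vote).
#' @param k Median-filter kernel size.
#' @param setting Binarization setting for the median-filter stage.
#' @return A list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(members, median_filter = c("none", "after", "before"),
                          k = 3, setting = "S1") {
  members <- tibble::as_tibble(members)
  stopifnot(nrow(members) >= 1,
            all(c("model", "magnification") %in% names(members)))
  structure(list(members = members, median_filter = match.arg(median_filter),
                 k = k, setting = setting),
            class = "ensemble_spec")
}

member_id <- function(model, magnification) {
  paste0(model, "@", magnification, "x")
}

#' Run a map ensemble
#'
#' Rescales every member map to the grid of the lowest-magnification
#' member and averages them. When member grid shapes are not exact
#' integer multiples of the target (patch grids at the scan border),
#' trailing rows/columns are trimmed before pooling. With
#' `median_filter != "none"` the result additionally carries a
#' median-filtered binary cancer map in `$binary`.
#'
#' @param spec An [ensemble_spec()].
#' @param maps Named list of [prob_map()]s; names are
#'   `"<model>@<magnification>x"`.
#' @return The ensembled [prob_map()] (element `binary` added when
#'   median filtering is requested).
#' @export
run_ensemble <- function(spec, maps) {
  stopifnot(inherits(spec, "ensemble_spec"))
  ids <- member_id(spec$members$model, spec$members$magnification)
  missing <- setdiff(ids, names(maps))
  if (length(missing)) stop("missing member map(s): ",
                            paste(missing, collapse = ", "))
  maps <- maps[ids]
  target_id <- ids[which.min(spec$members$magnification)]
  target_shape <- dim(maps[[target_id]]$grid)[1:2]
  crop <- function(map, shape) {
    r <- (dim(map$grid)[1:2]) %/% shape
    keep1 <- seq_len(shape[1] * r[1]); keep2 <- seq_len(shape[2] * r[2])
    map$grid <- map$grid[keep1, keep2, , drop = FALSE]
    map$valid <- map$valid[keep1, keep2, drop = FALSE]
    map
  }
  rescaled <- lapply(maps, function(m) {
    if (identical(dim(m$grid)[1:2], target_shape)) return(m)
    rescale_map(crop(m, target_shape), target_shape)
  })
  ens <- average_maps(rescaled)
  ens$magnification <- min(spec$members$magnification)
  if (spec$median_filter == "after") {
    ens$binary <- median_filter_map(binarize_map(ens, spec$setting),
                                    spec$k, ens$valid)
  } else if (spec$median_filter == "before") {
    bins <- lapply(rescaled, function(m) {
      median_filter_map(binarize_map(m, spec$setting), spec$k, m$valid)
    })
    votes <- Reduce(`+`, lapply(bins, function(b) ifelse(is.na(b), 0, b)))
    n_ok <- Reduce(`+`, lapply(bins, function(b) (!is.na(b)) * 1))
    ens$binary <- votes * 2 > n_ok
    ens$binary[n_ok == 0] <- NA
  }
  ens
}
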