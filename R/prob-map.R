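#' Per-scan probability maps
#'
#' A probability map holds, for every cell of a scan's patch grid at one
#' magnification, a vector of class probabilities, plus a logical mask
#' marking cells that overlap valid tissue. Cells outside valid tissue
#' carry a uniform vector by convention and are ignored by downstream
#' statistics.
#'
#' @param grid Numeric array `H x W x C` of probabilities.
#' @param classes Character vector of length `C`, the class order.
#' @param valid Logical `H x W` matrix; defaults to all `TRUE`.
#' @param scan_id,magnification Identification metadata.
#' @param tol Tolerance for the row-sum check on valid cells.
#' @return An object of class `prob_map`.
#' @examples
#' g <- array(rep(c(0.25, 0.75), each = 4), dim = c(2, 2, 2))
#' m <- prob_map(g, classes = c("NC", "C"), scan_id = "s1", magnification = 40)
#' tidy(m)
#' @export
prob_map <- function(grid, classes, valid = NULL, scan_id = "scan",
                     magnification = 40, tol = 1e-6) {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  stopifnot(length(classes) == dim(grid)[3], !anyDuplicated(classes))
  if (is.null(valid)) valid <- matrix(TRUE, dim(grid)[1], dim(grid)[2])
  stopifnot(is.logical(valid), all(dim(valid) == dim(grid)[1:2]))
  sums <- apply(grid, c(1, 2), sum)
  bad <- valid & (abs(sums - 1) > tol | apply(grid, c(1, 2), min) < -tol)
  if (any(bad)) {
    stop("probability vectors on ", sum(bad),
         " valid cell(s) are not normalized within ", tol)
  }
  structure(
    list(grid = grid, classes = as.character(classes), valid = valid,
         scan_id = scan_id, magnification = magnification),
    class = "prob_map"
  )
}

#' @export
print.prob_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<prob_map> scan %s @ %sx: %d x %d grid, %d classes (%s), %d/%d valid cells\n",
    x$scan_id, x$magnification, d[1], d[2], d[3],
    paste(x$classes, collapse = ","), sum(x$valid), d[1] * d[2]))
  invisible(x)
}

#' Tidy a probability map into a long tibble
#'
#' @param x A [prob_map()].
#' @param ... Unused.
#' @return Tibble with columns `row`, `col`, `valid`, `class`, `prob`
#'   (rows/cols are 1-based grid indices).
#' @exportS3Method generics::tidy
tidy.prob_map <- function(x, ...) {
  d <- dim(x$grid)
  tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]),
                     class = x$classes) |>
    dplyr::mutate(
      valid = x$valid[cbind(.data$row, .data$col)],
      prob = x$grid[cbind(.data$row, .data$col, match(.data$class, x$classes))]
    ) |>
    dplyr::select("row", "col", "valid", "class", "prob")
}

#' Argmax label per grid cell
#'
#' @param map A [prob_map()].
#' @return Character matrix of per-cell argmax classes (`NA` on invalid
#'   cells). Ties resolve to the earlier class in the class order.
#' @export
argmax_map <- function(map) {
  stopifnot(inherits(map, "prob_map"))
  d <- dim(map$grid)
  flat <- matrix(map$grid, d[1] * d[2], d[3])
  lab <- map$classes[max.col(flat, ties.method = "first")]
  out <- matrix(lab, d[1], d[2])
  out[!map$valid] <- NA
  out
}

#' Heatmap of a probability map
#'
#' Plots the per-cell probability of one class, or the argmax label when
#' `class = NULL`. Invalid cells are blank.
#'
#' @param object A [prob_map()].
#' @param class Class code to display, or `NULL` for the argmax label.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.prob_map <- function(object, class = NULL, ...) {
  td <- tidy(object)
  if (is.null(class)) {
    am <- argmax_map(object)
    df <- td |>
      dplyr::distinct(.data$row, .data$col, .data$valid) |>
      dplyr::mutate(label = am[cbind(.data$row, .data$col)]) |>
      dplyr::filter(.data$valid)
    ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$label)) +
      ggplot2::geom_tile() +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() +
      ggplot2::labs(x = NULL, y = NULL, fill = "class",
                    title = sprintf("%s @ %sx", object$scan_id,
                                    object$magnification))
  } else {
    stopifnot(class %in% object$classes)
    df <- dplyr::filter(td, .data$class == !!class, .data$valid)
    ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$prob)) +
      ggplot2::geom_tile() +
      ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
      ggplot2::coord_fixed() +
      ggplot2::labs(x = NULL, y = NULL, fill = paste0("P(", class, ")"),
                    title = sprintf("%s @ %sx", object$scan_id,
                                    object$magnification))
  }
}

uniform_fill <- function(map) {
  d <- dim(map$grid)
  g <- map$grid
  for (k in seq_len(d[3])) {
    slice <- g[, , k]
    slice[!map$valid] <- 1 / d[3]
    g[, , k] <- slice
  }
  map$grid <- g
  map
}
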