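#' Build the patch grid for a scan level
#'
#' Patches of `patch_size` pixels are taken on a regular lattice with
#' the given stride; positions whose patch would extend past the scan
#' are dropped (no padding). Coordinates are 0-based, at the patch's own
#' magnification level.
#'
#' @param dims `c(width, height)` of the level in pixels.
#' @param magnification Level the grid belongs to.
#' @param patch_size Patch side in pixels.
#' @param stride Lattice stride in pixels.
#' @return Tibble with columns `magnification`, `x`, `y` in row-major
#'   order, plus attributes `grid_rows`/`grid_cols`. A scan smaller than
#'   one patch yields an empty grid with a warning.
#' @examples
#' build_patch_grid(c(512, 512))
#' @export
build_patch_grid <- function(dims, magnification = 40, patch_size = 256,
                             stride = 128) {
  w <- dims[1]; h <- dims[2]
  xs <- seq(0, by = stride, length.out = max(0, (w - patch_size) %/% stride + 1))
  ys <- seq(0, by = stride, length.out = max(0, (h - patch_size) %/% stride + 1))
  if (w < patch_size || h < patch_size) {
    warning("scan level (", w, "x", h, ") smaller than one patch; empty grid")
    xs <- numeric(0); ys <- numeric(0)
  }
  grid <- tidyr::expand_grid(y = ys, x = xs) |>
    dplyr::mutate(magnification = magnification, .before = 1)
  attr(grid, "grid_rows") <- length(ys)
  attr(grid, "grid_cols") <- length(xs)
  grid
}

#' Per-class coverage of a patch by annotations
#'
#' The fraction of the patch area covered by the union of each class's
#' regions, computed by exact polygon geometry (not rasterization).
#' Overlapping regions of one class are not double counted; fractions of
#' different classes can sum above 1 only when regions of different
#' classes overlap.
#'
#' @param rect Numeric `c(x, y, size)`: top-left corner and side of the
#'   patch, in 40x-level coordinates.
#' @param annotations An [annotation_set()] tibble.
#' @return Named numeric vector of fractions in `[0, 1]`, one entry per
#'   class present in the annotation set.
#' @export
class_coverage <- function(rect, annotations) {
  stopifnot(length(rect) == 3, rect[3] > 0)
  box <- c(rect[1], rect[2], rect[1] + rect[3], rect[2] + rect[3])
  area <- rect[3]^2
  labs <- unique(annotations$label)
  cov <- vapply(labs, function(lab) {
    rings <- annotations$geometry[annotations$label == lab]
    union_area_in_rect(rings, box) / area
  }, numeric(1))
  names(cov) <- labs
  cov
}

#' Assign a label to a 40x patch from its coverage map
#'
#' A label is assigned iff exactly one class covers the patch with a
#' ratio at or above the threshold; if no class, or two or more
#' (overlapping) classes, reach it, the patch stays unlabeled.
#'
#' @param coverage Named numeric vector from [class_coverage()].
#' @param threshold Minimum overlap ratio (inclusive).
#' @return A class code, or `NA_character_`.
#' @examples
#' assign_label_40x(c(N = 0.8))
#' assign_label_40x(c(N = 0.5, R3 = 0.4))
#' @export
assign_label_40x <- function(coverage, threshold = 0.75) {
  hit <- names(coverage)[coverage >= threshold]
  if (length(hit) == 1) hit else NA_character_
}

#' Merge 40x sub-patch labels into a lower-magnification label
#'
#' The most severe of the labeled sub-patches wins (e.g. sub-labels
#' `N, R3, R3, R4` merge to `R4`); sub-patches without a label are
#' ignored, and a patch whose sub-patches are all unlabeled stays
#' unlabeled. Valid list lengths are 4 (20x), 16 (10x) and 64 (5x).
#'
#' @param labels Character vector of class codes with `NA` for
#'   unlabeled sub-patches.
#' @return A class code or `NA_character_`.
#' @examples
#' merge_sublabels(c("N", "R3", "R3", "R4"))
#' @export
merge_sublabels <- function(labels) {
  if (!length(labels) %in% c(4, 16, 64)) {
    stop("sub-label list must have length 4, 16 or 64, got ", length(labels))
  }
  ranks <- severity_rank(labels)
  if (all(is.na(ranks))) return(NA_character_)
  class_labels()[max(ranks, na.rm = TRUE)]
}

#' Number of 40x sub-patches per patch at a magnification
#'
#' @param magnification One of 40, 20, 10, 5.
#' @return 1, 4, 16 or 64.
#' @export
subdivision_count <- function(magnification) {
  stopifnot(magnification %in% c(40, 20, 10, 5))
  as.integer((40 / magnification)^2)
}

#' Label one patch at any magnification
#'
#' At 40x the patch is labeled directly from its annotation coverage.
#' At lower magnifications its physical footprint at the 40x level (a
#' `256 * 40 / m` pixel square) is tiled by 4, 16 or 64 non-overlapping
#' 256-pixel 40x sub-patches; each is labeled by the 40x rule and the
#' most severe labeled value is merged upward.
#'
#' @param x,y Patch top-left, 0-based, at the patch's own level.
#' @param magnification One of 40, 20, 10, 5.
#' @param annotations An [annotation_set()] tibble (40x coordinates).
#' @param patch_size Patch side at the patch's own level.
#' @param threshold Overlap threshold for the 40x rule.
#' @return A class code or `NA_character_`.
#' @export
label_patch <- function(x, y, magnification, annotations, patch_size = 256,
                        threshold = 0.75) {
  stopifnot(magnification %in% c(40, 20, 10, 5))
  s <- 40 / magnification
  if (magnification == 40) {
    return(assign_label_40x(
      class_coverage(c(x, y, patch_size), annotations), threshold))
  }
  n <- 40 / magnification # sub-patches per side
  x0 <- x * s; y0 <- y * s
  offs <- (seq_len(n) - 1) * patch_size
  sub <- tidyr::expand_grid(dy = offs, dx = offs)
  labs <- purrr::map2_chr(sub$dx, sub$dy, function(dx, dy) {
    assign_label_40x(
      class_coverage(c(x0 + dx, y0 + dy, patch_size), annotations), threshold)
  })
  merge_sublabels(labs)
}

#' Label every patch of a grid
#'
#' @param grid Tibble from [build_patch_grid()] (columns
#'   `magnification`, `x`, `y`).
#' @param annotations An [annotation_set()] tibble.
#' @param patch_size,threshold Passed to [label_patch()].
#' @return The grid with a `label` column added.
#' @export
label_patches <- function(grid, annotations, patch_size = 256,
                          threshold = 0.75) {
  grid |>
    dplyr::mutate(label = purrr::pmap_chr(
      list(.data$x, .data$y, .data$magnification),
      function(x, y, m) label_patch(x, y, m, annotations, patch_size, threshold)
    ))
}

#' Extract a labeled patch dataset from annotated scans
#'
#' Builds the stride-128 patch grid at every requested magnification of
#' every scan, labels each patch by the hierarchical rule, optionally
#' crops and writes the patch images as PNG, and returns the combined
#' patch manifest. Magnifications absent from a pyramid are skipped
#' with a warning.
#'
#' @param scans List of [scan_pyramid()] objects.
#' @param annotations Named list of [annotation_set()] tibbles, keyed by
#'   scan id.
#' @param partitions Tibble with columns `scan_id`, `partition`
#'   (train/validation/test); every scan must be assigned.
#' @param out_dir Directory for patch images, or `NULL` to skip writing.
#' @param magnifications Levels to extract.
#' @param patch_size,stride,threshold Grid and labeling parameters.
#' @return The patch manifest tibble (see [write_manifest()]).
#' @export
extract_dataset <- function(scans, annotations, partitions, out_dir = NULL,
                            magnifications = c(40, 20, 10, 5),
                            patch_size = 256, stride = 128, threshold = 0.75) {
  ids <- vapply(scans, function(s) s$scan_id, character(1))
  missing <- setdiff(ids, partitions$scan_id)
  if (length(missing)) stop("no partition assigned for scan(s): ",
                            paste(missing, collapse = ", "))
  rows <- purrr::map(scans, function(scan) {
    ann <- annotations[[scan$scan_id]]
    if (is.null(ann)) stop("no annotations for scan ", scan$scan_id)
    part <- partitions$partition[match(scan$scan_id, partitions$scan_id)]
    purrr::map(magnifications, function(m) {
      dims <- scan_dims(scan, m)
      if (is.null(dims)) {
        warning("scan ", scan$scan_id, ": level ", m, "x absent; skipped")
        return(NULL)
      }
      grid <- build_patch_grid(dims, m, patch_size, stride) |>
        label_patches(ann, patch_size, threshold) |>
        dplyr::mutate(scan_id = scan$scan_id, partition = part, .before = 1)
      if (!is.null(out_dir)) {
        pdir <- file.path(out_dir, scan$scan_id, paste0(m, "x"))
        dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
        purrr::pwalk(list(grid$x, grid$y), function(x, y) {
          png::writePNG(crop_patch(scan, m, x, y, patch_size),
                        file.path(pdir, paste0(x, "_", y, ".png")))
        })
      }
      grid
    }) |> purrr::compact() |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  manifest <- rows[, c("scan_id", "magnification", "x", "y", "label",
                       "partition")]
  validate_manifest(manifest)
  manifest
}
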