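#' Scan pyramids
#'
#' A scan is stored as an image pyramid with levels at 40x, 20x, 10x and
#' 5x magnification; level `m` has dimensions `ceiling(dim40 * m / 40)`.
#' Images are numeric `H x W x 3` arrays in `[0, 1]` (top-left origin;
#' pixel (x, y) in 0-based scan coordinates is `img[y + 1, x + 1, ]`).
#' A pyramid may omit levels, but dimensions of the levels present must
#' be mutually consistent.
#'
#' @param scan_id Scan identifier.
#' @param levels Named list mapping `"40"`, `"20"`, `"10"`, `"5"` to
#'   image arrays.
#' @return An object of class `scan_pyramid`.
#' @export
scan_pyramid <- function(scan_id, levels) {
  stopifnot(length(levels) >= 1, all(names(levels) %in% c("40", "20", "10", "5")))
  levels <- lapply(levels, function(img) {
    if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
    stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
    img
  })
  mags <- as.numeric(names(levels))
  ref <- levels[[as.character(max(mags))]]
  ref_dim40 <- dim(ref)[1:2] * 40 / max(mags)
  for (m in mags) {
    got <- dim(levels[[as.character(m)]])[1:2]
    want <- ceiling(ref_dim40 * m / 40)
    if (any(abs(got - want) > 1)) {
      stop("level ", m, "x dimensions ", paste(got, collapse = "x"),
           " inconsistent with pyramid (expected ~",
           paste(want, collapse = "x"), ")")
    }
  }
  structure(list(scan_id = scan_id, levels = levels), class = "scan_pyramid")
}

#' @export
print.scan_pyramid <- function(x, ...) {
  cat("<scan_pyramid>", x$scan_id, "\n")
  for (m in names(x$levels)) {
    d <- dim(x$levels[[m]])
    cat(sprintf("  %3sx: %d x %d px\n", m, d[2], d[1]))
  }
  invisible(x)
}

#' Level dimensions of a pyramid
#' @param scan A [scan_pyramid()].
#' @param magnification Level to query.
#' @return `c(width, height)` in pixels, or `NULL` if the level is absent.
#' @export
scan_dims <- function(scan, magnification) {
  img <- scan$levels[[as.character(magnification)]]
  if (is.null(img)) return(NULL)
  c(dim(img)[2], dim(img)[1])
}

#' Read or write a scan pyramid as one PNG per level
#'
#' Levels are stored as `40.png`, `20.png`, `10.png`, `5.png` inside a
#' directory named after the scan.
#'
#' @param dir Directory holding (or to hold) the level images.
#' @param scan_id Scan identifier; defaults to the directory name.
#' @return A [scan_pyramid()] / invisibly the directory.
#' @export
read_scan_pyramid <- function(dir, scan_id = basename(dir)) {
  files <- file.path(dir, paste0(c(40, 20, 10, 5), ".png"))
  present <- file.exists(files)
  if (!any(present)) stop("no pyramid level images found in ", dir)
  levels <- lapply(files[present], png::readPNG)
  levels <- lapply(levels, function(img) {
    if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
    img
  })
  names(levels) <- as.character(c(40, 20, 10, 5))[present]
  scan_pyramid(scan_id, levels)
}

#' @rdname read_scan_pyramid
#' @param scan A [scan_pyramid()].
#' @export
write_scan_pyramid <- function(scan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(scan$levels)) {
    png::writePNG(scan$levels[[m]], file.path(dir, paste0(m, ".png")))
  }
  invisible(dir)
}

#' Crop one patch from a pyramid level
#'
#' @param scan A [scan_pyramid()].
#' @param magnification Level.
#' @param x,y Top-left corner in 0-based level coordinates.
#' @param patch_size Patch side in pixels.
#' @return `patch_size x patch_size x 3` array.
#' @export
crop_patch <- function(scan, magnification, x, y, patch_size = 256) {
  img <- scan$levels[[as.character(magnification)]]
  if (is.null(img)) stop("magnification ", magnification, "x absent from pyramid")
  d <- dim(img)
  stopifnot(x >= 0, y >= 0, x + patch_size <= d[2], y + patch_size <= d[1])
  img[(y + 1):(y + patch_size), (x + 1):(x + patch_size), , drop = FALSE]
}
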