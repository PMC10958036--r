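#' Configuration for synthetic annotated scans
#'
#' The generator emulates the structure of an annotated prostate WSI at
#' desk scale: rectangular class-textured regions laid without overlap
#' over a white (glass) background at 40x base resolution, with lower
#' pyramid levels rendered by block-averaging. Class textures are
#' separable by mean color on purpose, so the small reference
#' classifier can learn them; photorealism is a non-goal. The default
#' class distribution follows the published annotation-class frequencies
#' (restricted to the non-background classes), and region sizes are in
#' the range of typical annotated lesions at this scale.
#'
#' @param dims `c(width, height)` at 40x, each at least 256.
#' @param n_regions Number of regions to place.
#' @param size_range Side-length range of a region in 40x pixels
#'   (snapped to multiples of 8 so the 1/8-resolution truth mask is
#'   exact).
#' @param class_probs Named probabilities over the region classes.
#' @param textures Named list of base RGB means per class.
#' @param noise_sd Gaussian texture noise standard deviation.
#' @param background Background gray level (glass).
#' @return A list of class `synth_scan_config`.
#' @export
synth_scan_config <- function(
    dims = c(1024, 1024), n_regions = 8, size_range = c(128, 384),
    class_probs = c(T = 0.255, N = 0.378, A = 0.089, R1 = 0.0075,
                    R2 = 0.0075, R3 = 0.065, R4 = 0.165, R5 = 0.033),
    textures = list(
      T = c(0.92, 0.80, 0.85), N = c(0.85, 0.55, 0.70),
      A = c(0.60, 0.70, 0.60), R1 = c(0.75, 0.45, 0.65),
      R2 = c(0.65, 0.38, 0.60), R3 = c(0.55, 0.30, 0.55),
      R4 = c(0.45, 0.22, 0.50), R5 = c(0.35, 0.15, 0.45)),
    noise_sd = 0.02, background = 0.97) {
  stopifnot(all(dims >= 256), n_regions >= 1,
            abs(sum(class_probs) - 1) < 1e-6,
            all(names(class_probs) %in% names(textures)))
  structure(list(dims = dims, n_regions = n_regions, size_range = size_range,
                 class_probs = class_probs, textures = textures,
                 noise_sd = noise_sd, background = background),
            class = "synth_scan_config")
}

#' Generate one synthetic annotated scan
#'
#' Places non-overlapping rectangular regions, fills each with its
#' class texture, renders the 20x/10x/5x levels by block-averaging,
#' and returns the pyramid together with the matching annotations and
#' the ground-truth tissue mask at 1/8 resolution. Region placement
#' retries a bounded number of times; if space runs out, fewer regions
#' are placed with a warning. The same seed reproduces the output
#' exactly.
#'
#' @param config A [synth_scan_config()].
#' @param seed Mandatory integer seed.
#' @param scan_id Scan identifier.
#' @param render Set `FALSE` to skip image synthesis (returns `scan =
#'   NULL`) when only annotations and masks are needed.
#' @return List with elements `scan` ([scan_pyramid()]), `annotations`
#'   ([annotation_set()]), `truth_mask` (`tissue_mask`, method
#'   `"truth"`), `regions` (tibble of placed rectangles).
#' @export
generate_scan <- function(config, seed, scan_id = "synthetic_scan",
                          render = TRUE) {
  stopifnot(inherits(config, "synth_scan_config"), !missing(seed))
  set.seed(seed)
  w <- config$dims[1]; h <- config$dims[2]
  snap_size <- function(v) pmax(8, round(v / 8) * 8)
  snap_pos <- function(v) pmax(0, round(v / 8) * 8)
  placed <- list()
  overlaps <- function(r, others) {
    any(vapply(others, function(o) {
      r[1] < o[1] + o[3] && o[1] < r[1] + r[3] &&
        r[2] < o[2] + o[4] && o[2] < r[2] + r[4]
    }, logical(1)))
  }
  labels <- sample(names(config$class_probs), config$n_regions, replace = TRUE,
                   prob = config$class_probs)
  kept_labels <- character(0)
  for (i in seq_len(config$n_regions)) {
    ok <- FALSE
    for (try in 1:30) {
      rw <- snap_size(stats::runif(1, config$size_range[1], config$size_range[2]))
      rh <- snap_size(stats::runif(1, config$size_range[1], config$size_range[2]))
      if (rw > w || rh > h) next
      rx <- snap_pos(stats::runif(1, 0, w - rw))
      ry <- snap_pos(stats::runif(1, 0, h - rh))
      if (rx + rw > w || ry + rh > h) next
      rect <- c(rx, ry, rw, rh)
      if (!overlaps(rect, placed)) {
        placed <- c(placed, list(rect)); kept_labels <- c(kept_labels, labels[i])
        ok <- TRUE; break
      }
    }
    if (!ok) {
      warning("could not place region ", i, " without overlap; placed ",
              length(placed), " of ", config$n_regions)
      break
    }
  }
  scan <- NULL
  if (render) {
    img <- array(config$background, dim = c(h, w, 3)) +
      array(stats::rnorm(h * w * 3, sd = config$noise_sd / 2), dim = c(h, w, 3))
    for (i in seq_along(placed)) {
      r <- placed[[i]]
      base <- config$textures[[kept_labels[i]]]
      rows <- (r[2] + 1):(r[2] + r[4]); cols <- (r[1] + 1):(r[1] + r[3])
      for (ch in 1:3) {
        img[rows, cols, ch] <- base[ch] +
          stats::rnorm(length(rows) * length(cols), sd = config$noise_sd)
      }
    }
    img <- pmin(pmax(img, 0), 1)
    scan <- scan_pyramid(scan_id, list(
      "40" = img,
      "20" = downsample_scan(img, 2),
      "10" = downsample_scan(img, 4),
      "5" = downsample_scan(img, 8)))
  }
  rings <- lapply(placed, function(r) {
    rbind(c(r[1], r[2]), c(r[1] + r[3], r[2]),
          c(r[1] + r[3], r[2] + r[4]), c(r[1], r[2] + r[4]))
  })
  ann <- annotation_set(scan_id, kept_labels, rings)
  truth <- matrix(FALSE, ceiling(h / 8), ceiling(w / 8))
  for (r in placed) {
    truth[(r[2] / 8 + 1):((r[2] + r[4]) / 8), (r[1] / 8 + 1):((r[1] + r[3]) / 8)] <- TRUE
  }
  list(scan = scan, annotations = ann,
       truth_mask = new_tissue_mask(truth, scan_id, "truth"),
       regions = tibble::tibble(
         label = kept_labels,
         x = vapply(placed, `[`, numeric(1), 1),
         y = vapply(placed, `[`, numeric(1), 2),
         width = vapply(placed, `[`, numeric(1), 3),
         height = vapply(placed, `[`, numeric(1), 4)))
}

#' Generate a synthetic probability map with known truth
#'
#' Grows one contiguous cancerous blob occupying the requested fraction
#' of valid cells; every cell draws its probability vector from a
#' Dirichlet distribution concentrated on its true class
#' (`alpha = sharpness` on the true class, `1/K` elsewhere), so larger
#' `sharpness` means cleaner maps and in the limit the argmax map
#' equals the truth exactly.
#'
#' @param grid_shape `c(rows, cols)` of the patch grid.
#' @param cancer_fraction Fraction of valid cells made cancerous, in
#'   `[0, 1]`.
#' @param sharpness Dirichlet concentration on the true class.
#' @param seed Mandatory integer seed.
#' @param classes Class list of the map.
#' @param cancer_classes,normal_classes Classes truth cells are drawn
#'   from inside/outside the blob.
#' @param scan_id,magnification Metadata for the map.
#' @return A [prob_map()] with the truth label matrix in
#'   `attr(, "truth")`.
#' @export
generate_probability_map <- function(grid_shape, cancer_fraction,
                                     sharpness = 5, seed,
                                     classes = class_labels(),
                                     cancer_classes = c("R3", "R4", "R5"),
                                     normal_classes = c("T", "N"),
                                     scan_id = "synthetic_scan",
                                     magnification = 40) {
  stopifnot(cancer_fraction >= 0, cancer_fraction <= 1, !missing(seed))
  set.seed(seed)
  h <- grid_shape[1]; w <- grid_shape[2]
  truth <- matrix(sample(normal_classes, h * w, replace = TRUE), h, w)
  n_cancer <- round(cancer_fraction * h * w)
  if (n_cancer > 0) {
    # grow a 4-connected blob from a random seed cell
    start <- c(sample(h, 1), sample(w, 1))
    blob <- matrix(FALSE, h, w)
    frontier <- list(start)
    taken <- 0
    while (taken < n_cancer && length(frontier) > 0) {
      pick <- sample(length(frontier), 1)
      cell <- frontier[[pick]]
      frontier <- frontier[-pick]
      if (blob[cell[1], cell[2]]) next
      blob[cell[1], cell[2]] <- TRUE
      taken <- taken + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        nb <- cell + d
        if (nb[1] >= 1 && nb[1] <= h && nb[2] >= 1 && nb[2] <= w &&
            !blob[nb[1], nb[2]]) {
          frontier <- c(frontier, list(nb))
        }
      }
    }
    truth[blob] <- sample(cancer_classes, sum(blob), replace = TRUE)
  }
  k <- length(classes)
  grid <- array(NA_real_, dim = c(h, w, k))
  alpha_base <- 1 / k
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      alpha <- rep(alpha_base, k)
      alpha[match(truth[i, j], classes)] <- sharpness
      g <- stats::rgamma(k, shape = alpha)
      grid[i, j, ] <- g / sum(g)
    }
  }
  out <- prob_map(grid, classes, scan_id = scan_id,
                  magnification = magnification)
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic diagnosis cohort
#'
#' Samples per-scan truths and cancerous-tissue percentages from two
#' log-normal distributions, emulating the bimodal structure of real
#' screening cohorts: non-cancerous scans concentrate near zero while
#' cancerous scans spread over tens of percent, with an ambiguous
#' overlap between. Defaults follow the reported cohort: prevalence
#' 2090/4675, non-cancerous mass below ~2% and cancerous mass above
#' ~5%.
#'
#' @param n_scans Number of scans.
#' @param seed Mandatory integer seed.
#' @param prevalence Probability a scan is cancerous.
#' @param nc_meanlog,nc_sdlog Log-normal parameters of `p_c` for
#'   non-cancerous scans.
#' @param c_meanlog,c_sdlog Parameters for cancerous scans.
#' @return Tibble with columns `scan_id`, `truth`, `p_c` (percent,
#'   clamped to `[0, 100]`).
#' @export
generate_cohort <- function(n_scans = 200, seed, prevalence = 2090 / 4675,
                            nc_meanlog = log(0.6), nc_sdlog = 1.0,
                            c_meanlog = log(15), c_sdlog = 1.0) {
  stopifnot(!missing(seed))
  set.seed(seed)
  truth <- ifelse(stats::runif(n_scans) < prevalence, "C", "NC")
  p_c <- ifelse(truth == "C",
                stats::rlnorm(n_scans, c_meanlog, c_sdlog),
                stats::rlnorm(n_scans, nc_meanlog, nc_sdlog))
  tibble::tibble(scan_id = sprintf("synth_%04d", seq_len(n_scans)),
                 truth = truth, p_c = pmin(pmax(p_c, 0), 100))
}
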