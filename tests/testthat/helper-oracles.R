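# Independent oracles and small fixture builders used across the suite.

rect_ring <- function(x, y, w, h) {
  rbind(c(x, y), c(x + w, y), c(x + w, y + h), c(x, y + h))
}

# star-shaped simple polygon around a random center; vertices at strictly
# increasing angles (min gap) guarantee simplicity
rand_simple_poly <- function(xmax = 512, ymax = 512, rmin = 30, rmax = 180) {
  n <- sample(3:8, 1)
  cx <- runif(1, 0, xmax); cy <- runif(1, 0, ymax)
  r <- runif(n, rmin, rmax)
  repeat {
    th <- sort(runif(n, 0, 2 * pi))
    gaps <- diff(c(th, th[1] + 2 * pi))
    # every edge stays inside its own convex (< pi) angular wedge
    if (min(gaps) > 0.1 && max(gaps) < 3) break
  }
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# pixel-rasterization coverage oracle: fraction of pixel centers inside
# the union of the rings, within the patch rect (x, y, size)
raster_coverage <- function(rings, rect, res = 1) {
  xs <- rect[1] + seq(res / 2, rect[3], by = res)
  ys <- rect[2] + seq(res / 2, rect[3], by = res)
  inside <- matrix(FALSE, length(ys), length(xs))
  point_in_poly <- function(ring, px, py) {
    n <- nrow(ring)
    x1 <- ring[, 1]; y1 <- ring[, 2]
    x2 <- ring[c(2:n, 1), 1]; y2 <- ring[c(2:n, 1), 2]
    vapply(seq_along(px), function(i) {
      hit <- (y1 <= py[i]) != (y2 <= py[i])
      if (!any(hit)) return(FALSE)
      xc <- x1[hit] + (py[i] - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit])
      sum(xc < px[i]) %% 2 == 1
    }, logical(1))
  }
  grid <- expand.grid(px = xs, py = ys)
  for (ring in rings) {
    inside <- inside | matrix(point_in_poly(ring, grid$px, grid$py),
                              length(ys), length(xs), byrow = TRUE)
  }
  mean(inside)
}

# raster-based patch labeling pipeline (independent of the exact-geometry
# path): rasterized coverage -> threshold rule -> most-severe merge
raster_label_patch <- function(x, y, magnification, annotations,
                               patch_size = 256, threshold = 0.75, res = 2) {
  s <- 40 / magnification
  n <- s
  x0 <- x * s; y0 <- y * s
  offs <- (seq_len(n) - 1) * patch_size
  labs <- c()
  for (dy in offs) for (dx in offs) {
    cov <- vapply(unique(annotations$label), function(lab) {
      raster_coverage(annotations$geometry[annotations$label == lab],
                      c(x0 + dx, y0 + dy, patch_size), res = res)
    }, numeric(1))
    hit <- names(cov)[cov >= threshold]
    labs <- c(labs, if (length(hit) == 1) hit else NA_character_)
  }
  ranks <- match(labs, class_labels())
  if (all(is.na(ranks))) NA_character_ else class_labels()[max(ranks, na.rm = TRUE)]
}

# mid-rank Pearson correlation, written from the definition
midrank_pearson <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(a) sum(v < a) + (sum(v == a) + 1) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# random normalized probability grid (flat Dirichlet)
rand_prob_grid <- function(h, w, k) {
  g <- array(rgamma(h * w * k, shape = 1), dim = c(h, w, k))
  s <- apply(g, c(1, 2), sum)
  g / array(rep(s, k), dim = c(h, w, k))
}

# brute-force median filter oracle: same reflection/exclusion contract,
# but computed cell by cell from first principles
brute_median_filter <- function(m, k, valid = NULL) {
  if (is.null(valid)) valid <- !is.na(m)
  h <- nrow(m); w <- ncol(m); r <- (k - 1) / 2
  refl <- function(i, n) {
    if (i < 1) return(2 - i)
    if (i > n) return(2 * n - i)
    i
  }
  out <- m
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!valid[i, j]) { out[i, j] <- NA; next }
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      ii <- refl(i + di, h); jj <- refl(j + dj, w)
      if (valid[ii, jj]) vals <- c(vals, m[ii, jj])
    }
    if (length(vals) == 0) next
    out[i, j] <- if (sum(vals) * 2 == length(vals)) m[i, j] else
      sum(vals) * 2 > length(vals)
  }
  out
}

# tiny two-class annotated scan used in several tests
demo_scan <- function(seed = 1, dims = c(512, 512)) {
  cfg <- synth_scan_config(
    dims = dims, n_regions = 3, size_range = c(96, 192),
    class_probs = c(N = 0.5, R4 = 0.5))
  generate_scan(cfg, seed = seed, scan_id = paste0("demo_", seed))
}

mask_iou <- function(a, b) sum(a & b) / sum(a | b)
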