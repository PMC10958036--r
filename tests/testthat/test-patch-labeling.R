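test_that("patch grids enumerate stride-128 positions that fit the scan", {
  g <- build_patch_grid(c(512, 512))
  expect_equal(nrow(g), 9)
  expect_setequal(unique(g$x), c(0, 128, 256))
  expect_setequal(unique(g$y), c(0, 128, 256))
  # row-major: y varies slowest
  expect_equal(g$y, rep(c(0, 128, 256), each = 3))

  expect_equal(nrow(build_patch_grid(c(256, 256))), 1)
  expect_equal(nrow(build_patch_grid(c(500, 500))), 4) # partial patches dropped
  expect_warning(g0 <- build_patch_grid(c(200, 300)), "smaller than one patch")
  expect_equal(nrow(g0), 0)
})

test_that("class coverage is exact on analytic cases", {
  ann <- annotation_set("s", c("R3", "N"), list(
    rect_ring(0, 0, 512, 512),        # R3 everywhere
    rect_ring(1024, 0, 128, 256)))    # N covers left half of patch at x=1024
  cov <- class_coverage(c(128, 128, 256), ann)
  expect_equal(unname(cov["R3"]), 1.0)
  cov2 <- class_coverage(c(1024, 0, 256), ann)
  expect_equal(unname(cov2["N"]), 0.5)
  # degenerate (zero-area) polygon contributes nothing
  flat <- rbind(c(0, 0), c(100, 0), c(200, 0))
  ann3 <- annotation_set("s", "A", list(flat))
  expect_equal(unname(class_coverage(c(0, 0, 256), ann3)["A"]), 0)
})

test_that("overlapping same-class regions are not double counted", {
  ann <- annotation_set("s", c("N", "N"), list(
    rect_ring(0, 0, 192, 256), rect_ring(64, 0, 192, 256)))
  expect_equal(unname(class_coverage(c(0, 0, 256), ann)["N"]), 1.0)
})

test_that("exact coverage agrees with the pixel-rasterization oracle", {
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(2:5, 1)
    ann <- annotation_set("s", sample(class_labels(), n, TRUE),
                          replicate(n, rand_simple_poly(), simplify = FALSE))
    rect <- c(sample(0:256, 1), sample(0:256, 1), 256)
    exact <- class_coverage(rect, ann)
    for (lab in names(exact)) {
      oracle <- raster_coverage(ann$geometry[ann$label == lab], rect, res = 1)
      expect_lt(abs(exact[[lab]] - oracle), 0.01)
    }
  }
})

test_that("the 40x rule assigns a label only for a unique class above 0.75", {
  expect_equal(assign_label_40x(c(N = 0.80)), "N")
  expect_equal(assign_label_40x(c(R4 = 0.75)), "R4") # boundary inclusive
  expect_true(is.na(assign_label_40x(c(N = 0.5, R3 = 0.4))))
  expect_true(is.na(assign_label_40x(c(N = 0.80, R3 = 0.80)))) # contradictory
  expect_true(is.na(assign_label_40x(c(N = 0.7499))))
})

test_that("sub-label merging takes the most severe label", {
  expect_equal(merge_sublabels(c("N", "R3", "R3", "R4")), "R4")
  expect_equal(merge_sublabels(rep("N", 4)), "N")
  expect_true(is.na(merge_sublabels(rep(NA_character_, 4))))
  expect_equal(merge_sublabels(c("T", "A", NA, NA)), "A")
  expect_equal(merge_sublabels(c(rep(NA_character_, 63), "R2")), "R2")
  expect_error(merge_sublabels(c("N", "N")), "length 4, 16 or 64")
  # commutative and idempotent (max over a total order)
  set.seed(5)
  labs <- sample(c(class_labels(), NA), 16, TRUE)
  expect_equal(merge_sublabels(labs), merge_sublabels(sample(labs)))
  expect_equal(merge_sublabels(rep(merge_sublabels(labs), 4)),
               merge_sublabels(labs))
})

test_that("hierarchical labeling subdivides 4/16/64 and merges severity", {
  expect_equal(subdivision_count(40), 1)
  expect_equal(subdivision_count(20), 4)
  expect_equal(subdivision_count(10), 16)
  expect_equal(subdivision_count(5), 64)

  # a 20x patch fully inside one R5 region
  ann <- annotation_set("s", "R5", list(rect_ring(0, 0, 512, 512)))
  expect_equal(label_patch(0, 0, 20, ann), "R5")

  # one labeled sub-patch suffices at 5x: a single 256px R4 square inside
  # an otherwise empty 2048px footprint
  ann2 <- annotation_set("s", "R4", list(rect_ring(512, 768, 256, 256)))
  expect_equal(label_patch(0, 0, 5, ann2), "R4")
  # and the same footprint with nothing annotated stays unlabeled
  ann3 <- annotation_set("s", "R4", list(rect_ring(4096, 4096, 256, 256)))
  expect_true(is.na(label_patch(0, 0, 5, ann3)))
})

test_that("hierarchical labels match the rasterization-oracle pipeline", {
  set.seed(31)
  for (rep in 1:4) {
    n <- sample(2:5, 1)
    ann <- annotation_set(
      "s", sample(c("N", "A", "R2", "R4"), n, TRUE),
      replicate(n, rand_simple_poly(512, 512, 60, 220), simplify = FALSE))
    for (m in c(40, 20)) {
      g <- build_patch_grid(c(512, 512) * m / 40, m)
      pick <- g[sample(nrow(g), min(3, nrow(g))), ]
      for (i in seq_len(nrow(pick))) {
        got <- label_patch(pick$x[i], pick$y[i], m, ann)
        want <- raster_label_patch(pick$x[i], pick$y[i], m, ann, res = 1)
        expect_equal(got, want)
      }
    }
  }
})

test_that("a cancerous region on unannotated tissue never lowers severity", {
  # note: a cancerous region *overlapping* an annotated one can unlabel a
  # patch (two classes above the 0.75 threshold are contradictory), so
  # monotonicity holds only for additions disjoint from existing regions
  ann <- annotation_set("s", c("N", "T", "R3"), list(
    rect_ring(0, 0, 256, 256), rect_ring(0, 256, 256, 256),
    rect_ring(128, 0, 96, 384)))
  g <- label_patches(build_patch_grid(c(512, 512)), ann)
  ann2 <- dplyr::bind_rows(
    ann, annotation_set("s", "R5", list(rect_ring(256, 0, 256, 512))))
  g2 <- label_patches(build_patch_grid(c(512, 512)), ann2)
  r1 <- severity_rank(g$label); r2 <- severity_rank(g2$label)
  expect_true(all(is.na(r1) | (!is.na(r2) & r2 >= r1)))
})

test_that("lower-magnification labels dominate their labeled sub-patches", {
  # deterministic layout guaranteeing labeled patches at both levels
  ann <- annotation_set("p", c("R4", "N"), list(
    rect_ring(0, 0, 512, 512), rect_ring(512, 0, 256, 768)))
  g40 <- label_patches(build_patch_grid(c(768, 768), 40), ann)
  g20 <- label_patches(build_patch_grid(c(384, 384), 20), ann)
  expect_true(any(!is.na(g20$label)))
  checked <- 0
  for (i in seq_len(nrow(g20))) {
    x0 <- g20$x[i] * 2; y0 <- g20$y[i] * 2
    subs <- g40[g40$x %in% c(x0, x0 + 256) & g40$y %in% c(y0, y0 + 256), ]
    # note: stride-128 40x grid patches are not the merge sub-patches, but any
    # aligned 40x patch inside the 20x footprint must not exceed its severity
    sub_rank <- suppressWarnings(max(severity_rank(subs$label), na.rm = TRUE))
    if (is.finite(sub_rank) && !is.na(g20$label[i])) {
      checked <- checked + 1
      expect_gte(severity_rank(g20$label[i]), sub_rank)
    }
  }
  expect_gte(checked, 1)
})

test_that("extract_dataset writes a self-consistent manifest and patches", {
  s <- demo_scan(seed = 3)
  out <- withr::local_tempdir()
  # the 10x and 5x levels of a 512px scan are smaller than one patch
  suppressWarnings(manifest <- extract_dataset(
    list(s$scan), setNames(list(s$annotations), s$scan$scan_id),
    tibble::tibble(scan_id = s$scan$scan_id, partition = "train"),
    out_dir = out, magnifications = c(40, 20, 10, 5)))
  expect_equal(sum(manifest$magnification == 40), 9)
  expect_equal(sum(manifest$magnification == 20), 1)
  expect_equal(sum(manifest$magnification == 5), 0)
  # labels match an independent recomputation
  for (i in sample(nrow(manifest), 5)) {
    expect_equal(manifest$label[i],
                 label_patch(manifest$x[i], manifest$y[i],
                             manifest$magnification[i], s$annotations))
  }
  # patch images exist and have the right size
  p <- file.path(out, s$scan$scan_id, "40x", "128_128.png")
  expect_true(file.exists(p))
  expect_equal(dim(png::readPNG(p))[1:2], c(256, 256))
  # a missing partition is an error
  expect_error(extract_dataset(
    list(s$scan), setNames(list(s$annotations), s$scan$scan_id),
    tibble::tibble(scan_id = "other", partition = "train")),
    "no partition")
})
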