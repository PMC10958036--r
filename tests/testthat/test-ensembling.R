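test_that("rescaling block-averages probability vectors exactly", {
  # constant map stays constant at any scale
  g <- array(rep(c(0.3, 0.7), each = 16), dim = c(4, 4, 2))
  m <- prob_map(g, c("NC", "C"))
  r <- rescale_map(m, c(2, 2))
  expect_equal(r$grid, array(rep(c(0.3, 0.7), each = 4), dim = c(2, 2, 2)))

  # 2x2 block of (1,0),(1,0),(0,1),(0,1) -> (0.5, 0.5)
  g2 <- array(0, dim = c(2, 2, 2))
  g2[1, , 1] <- 1; g2[2, , 2] <- 1
  r2 <- rescale_map(prob_map(g2, c("NC", "C")), c(1, 1))
  expect_equal(as.vector(r2$grid), c(0.5, 0.5))

  expect_error(rescale_map(m, c(3, 2)), "integer multiple")
})

test_that("rescaling matches a brute-force per-block mean", {
  set.seed(61)
  g <- rand_prob_grid(8, 12, 5)
  valid <- matrix(runif(96) > 0.3, 8, 12)
  m <- prob_map(g, paste0("c", 1:5), valid)
  r <- rescale_map(m, c(2, 3))
  for (i in 1:2) for (j in 1:3) {
    rows <- ((i - 1) * 4 + 1):(i * 4); cols <- ((j - 1) * 4 + 1):(j * 4)
    for (k in 1:5) {
      expect_lt(abs(r$grid[i, j, k] - mean(g[rows, cols, k])), 1e-9)
    }
    expect_equal(r$valid[i, j], any(valid[rows, cols]))
  }
})

test_that("map averaging is elementwise and identity on duplicates", {
  set.seed(62)
  m1 <- prob_map(rand_prob_grid(3, 3, 4), paste0("c", 1:4))
  expect_equal(average_maps(list(m1, m1))$grid, m1$grid)
  g2 <- array(c(0.2, 0.4, 0.8, 0.6), dim = c(1, 1, 2))
  ma <- prob_map(array(c(0.2, 0.8), dim = c(1, 1, 2)), c("a", "b"))
  mb <- prob_map(array(c(0.4, 0.6), dim = c(1, 1, 2)), c("a", "b"))
  expect_equal(as.vector(average_maps(list(ma, mb))$grid), c(0.3, 0.7))
  expect_error(average_maps(list(m1, ma)), "shape mismatch")
})

test_that("rescale, average and group-merge preserve normalization", {
  set.seed(63)
  maps <- lapply(1:4, function(i) prob_map(rand_prob_grid(4, 4, 9),
                                           class_labels()))
  avg <- average_maps(maps)
  expect_lt(max(abs(apply(avg$grid, c(1, 2), sum) - 1)), 1e-9)
  res <- rescale_map(avg, c(2, 2))
  expect_lt(max(abs(apply(res$grid, c(1, 2), sum) - 1)), 1e-9)
  mer <- merge_class_groups(res, binary_grouping("S1"))
  expect_lt(max(abs(apply(mer$grid, c(1, 2), sum) - 1)), 1e-9)
})

test_that("class-group merging sums probabilities over a partition", {
  set.seed(64)
  m <- prob_map(rand_prob_grid(3, 3, 9), class_labels())
  g <- merge_class_groups(m, binary_grouping("S1"))
  expect_equal(g$classes, c("NC", "C"))
  cancer_idx <- match(paste0("R", 1:5), m$classes)
  expect_equal(g$grid[, , 2],
               apply(m$grid[, , cancer_idx], c(1, 2), sum))
  # singleton groups are the identity
  singles <- setNames(as.list(class_labels()), class_labels())
  expect_equal(merge_class_groups(m, singles)$grid, m$grid)
  expect_error(merge_class_groups(m, list(a = "BG", b = "T")), "partition")
})

test_that("median filtering removes isolated outliers and fixes constants", {
  bm <- matrix(FALSE, 7, 7); bm[4, 4] <- TRUE
  expect_false(any(median_filter_map(bm, 3)))
  expect_true(all(median_filter_map(matrix(TRUE, 5, 5), 3)))
  expect_error(median_filter_map(bm, 4), "odd")
})

test_that("median filtering equals the brute-force neighborhood oracle", {
  set.seed(65)
  for (rep in 1:5) {
    m <- matrix(runif(256) > 0.5, 16, 16)
    valid <- matrix(runif(256) > 0.15, 16, 16)
    got <- median_filter_map(m, 3, valid)
    want <- brute_median_filter(m, 3, valid)
    expect_identical(got, want)
  }
  # k = 5 as well
  m <- matrix(runif(144) > 0.5, 12, 12)
  expect_identical(median_filter_map(m, 5), brute_median_filter(m, 5))
})

test_that("repeated median filtering converges to a fixed point", {
  # one application is not idempotent in general (thin structures keep
  # eroding), but iteration reaches a fixed point quickly
  set.seed(66)
  for (rep in 1:6) {
    m <- matrix(runif(100) > 0.5, 10, 10)
    for (i in 1:12) {
      nxt <- median_filter_map(m, 3)
      if (identical(nxt, m)) break
      m <- nxt
    }
    expect_identical(median_filter_map(m, 3), m)
  }
})

test_that("median filtering commutes with complement and is monotone", {
  set.seed(67)
  for (rep in 1:5) {
    m <- matrix(runif(100) > 0.5, 10, 10)
    expect_identical(median_filter_map(!m, 3), !median_filter_map(m, 3))
    m2 <- m | (matrix(runif(100), 10, 10) > 0.7) # m2 >= m elementwise
    expect_true(all(median_filter_map(m, 3) <= median_filter_map(m2, 3)))
  }
})

test_that("ensembles rescale to the coarsest member and average", {
  set.seed(67)
  fine <- prob_map(rand_prob_grid(4, 4, 2), c("NC", "C"),
                   scan_id = "s", magnification = 40)
  coarse <- prob_map(rand_prob_grid(2, 2, 2), c("NC", "C"),
                     scan_id = "s", magnification = 20)
  spec <- ensemble_spec(tibble::tibble(model = c("vgg", "vgg"),
                                       magnification = c(40, 20)))
  ens <- run_ensemble(spec, list("vgg@40x" = fine, "vgg@20x" = coarse))
  # hand-computed: rescale fine by 2x2 mean, then average with coarse
  hand <- (rescale_map(fine, c(2, 2))$grid + coarse$grid) / 2
  expect_equal(ens$grid, hand)
  expect_equal(dim(ens$grid)[1:2], c(2, 2))
  expect_equal(ens$magnification, 20)

  # single member is rescale only; identical members give the member
  s1 <- ensemble_spec(tibble::tibble(model = "m", magnification = 40))
  expect_equal(run_ensemble(s1, list("m@40x" = fine))$grid, fine$grid)
  s2 <- ensemble_spec(tibble::tibble(model = c("a", "b"),
                                     magnification = c(20, 20)))
  expect_equal(run_ensemble(s2, list("a@20x" = coarse, "b@20x" = coarse))$grid,
               coarse$grid)
  expect_error(run_ensemble(s2, list("a@20x" = coarse)), "b@20x")
})

test_that("non-multiple member grids are trimmed before pooling", {
  set.seed(68)
  fine <- prob_map(rand_prob_grid(5, 5, 2), c("NC", "C"), magnification = 40)
  coarse <- prob_map(rand_prob_grid(2, 2, 2), c("NC", "C"), magnification = 20)
  spec <- ensemble_spec(tibble::tibble(model = "m", magnification = c(40, 20)))
  ens <- run_ensemble(spec, list("m@40x" = fine, "m@20x" = coarse))
  trimmed <- fine$grid[1:4, 1:4, , drop = FALSE]
  hand <- (rescale_map(prob_map(trimmed, c("NC", "C"),
                                fine$valid[1:4, 1:4]), c(2, 2))$grid +
             coarse$grid) / 2
  expect_equal(ens$grid, hand)
})

test_that("median filtering integrates with ensembling in both orders", {
  set.seed(69)
  m1 <- prob_map(rand_prob_grid(6, 6, 2), c("NC", "C"), magnification = 40)
  m2 <- prob_map(rand_prob_grid(6, 6, 2), c("NC", "C"), magnification = 40)
  maps <- list("a@40x" = m1, "b@40x" = m2)
  members <- tibble::tibble(model = c("a", "b"), magnification = 40)
  after <- run_ensemble(ensemble_spec(members, median_filter = "after"), maps)
  expect_equal(after$binary,
               median_filter_map(binarize_map(average_maps(list(m1, m2))), 3))
  before <- run_ensemble(ensemble_spec(members, median_filter = "before"), maps)
  expect_type(before$binary, "logical")
  expect_equal(dim(before$binary), c(6, 6))
})
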