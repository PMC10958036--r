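test_that("evaluation preprocessing takes the central crop deterministically", {
  img <- array(0, dim = c(256, 256, 3))
  img[17:240, 17:240, ] <- 1 # mark the central 224x224 block
  out <- preprocess_patch(img, "eval", "vit")
  # every output pixel comes from the marked block
  expect_equal(dim(out), c(224, 224, 3))
  for (ch in 1:3) {
    expect_equal(out[, , ch],
                 matrix((1 - slidediag:::imagenet_mean_01[ch]) /
                          slidediag:::imagenet_sd_01[ch],
                        224, 224))
  }
  expect_error(preprocess_patch(array(0, dim = c(255, 256, 3))), "256 x 256")
})

test_that("family normalizations zero out their reference colors", {
  img <- array(rep(c(123.680, 116.779, 103.939) / 255, each = 256 * 256),
               dim = c(256, 256, 3))
  out <- preprocess_patch(img, "eval", "cnn")
  expect_lt(max(abs(out)), 1e-10)

  img2 <- array(0, dim = c(256, 256, 3))
  img2[, , 1] <- 0.485
  out2 <- preprocess_patch(img2, "eval", "vit")
  expect_lt(max(abs(out2[, , 1])), 1e-10)
})

test_that("train-mode preprocessing is seed-reproducible and augments", {
  img <- array(runif(256 * 256 * 3), dim = c(256, 256, 3))
  set.seed(99); a <- preprocess_patch(img, "train", "cnn")
  set.seed(99); b <- preprocess_patch(img, "train", "cnn")
  expect_identical(a, b)
  set.seed(100); c2 <- preprocess_patch(img, "train", "cnn")
  expect_false(identical(a, c2))
})

make_training_set <- function(n_per_class, classes = c("N", "R4"),
                              textures = list(N = c(0.85, 0.55, 0.70),
                                              R4 = c(0.45, 0.22, 0.50))) {
  labels <- rep(classes, each = n_per_class)
  images <- lapply(labels, function(lab) {
    base <- textures[[lab]]
    img <- array(rep(base, each = 256 * 256), dim = c(256, 256, 3)) +
      array(rnorm(256 * 256 * 3, sd = 0.03), dim = c(256, 256, 3))
    pmin(pmax(img, 0), 1)
  })
  manifest <- tibble::tibble(
    scan_id = "train", magnification = 40,
    x = (seq_along(labels) - 1) * 128, y = 0,
    label = labels, partition = "train")
  list(manifest = manifest, images = images)
}

test_that("the reference backbone separates color classes on holdout data", {
  set.seed(55)
  tr <- make_training_set(40)
  te <- make_training_set(25)
  suppressMessages(cfg <- train_config(epochs = 8, lr = 0.5, batch_size = 16, seed = 4))
  clf <- train_classifier(tr$manifest, tr$images, cfg)
  expect_equal(clf$classes, c("N", "R4")) # canonical severity order
  p <- predict_proba(clf, te$images)
  expect_equal(colnames(p), c("N", "R4"))
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  pred <- clf$classes[max.col(p)]
  acc <- mean(pred == te$manifest$label)
  expect_gte(acc, 0.95)
  # history is one row per epoch with decreasing-ish loss
  expect_equal(nrow(tidy(clf)), 8)
  expect_lt(tidy(clf)$loss[8], tidy(clf)$loss[1])
  expect_equal(glance(clf)$n_classes, 2)
})

test_that("training is seed-deterministic and validates classes", {
  set.seed(56)
  tr <- make_training_set(10)
  suppressMessages(cfg <- train_config(epochs = 2, lr = 0.5, seed = 7))
  c1 <- train_classifier(tr$manifest, tr$images, cfg)
  c2 <- train_classifier(tr$manifest, tr$images, cfg)
  expect_identical(c1$history, c2$history)
  expect_identical(c1$state$W, c2$state$W)
  expect_error(
    train_classifier(tr$manifest, tr$images, cfg, classes = c("N", "R4", "R5")),
    "no training instances: R5")
})

test_that("probability maps cover the grid and respect the tissue mask", {
  set.seed(57)
  s <- demo_scan(seed = 21)
  tr <- make_training_set(30)
  suppressMessages(cfg <- train_config(epochs = 6, lr = 0.5, batch_size = 16, seed = 8))
  clf <- train_classifier(tr$manifest, tr$images, cfg)
  mask <- otsu_tissue_mask(downsample_scan(s$scan$levels[["40"]], 8),
                           s$scan$scan_id)
  pm <- predict_probability_map(s$scan, 40, clf, mask)
  expect_s3_class(pm, "prob_map")
  expect_equal(dim(pm$grid)[1:2], c(3, 3))
  sums <- apply(pm$grid, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_error(predict_probability_map(s$scan, 80, clf), "absent")

  # an all-background scan yields no valid cells
  blank <- scan_pyramid("blank", list("40" = array(1, dim = c(512, 512, 3))))
  suppressWarnings(bmask <- otsu_tissue_mask(
    downsample_scan(blank$levels[["40"]], 8), "blank"))
  pmb <- predict_probability_map(blank, 40, clf, bmask)
  expect_false(any(pmb$valid))
  expect_true(all(abs(pmb$grid - 0.5) < 1e-12))
})

test_that("argmax maps recover the layout of a separable cancer block", {
  set.seed(58)
  # deterministic layout: a 256px R4 block at (256, 256) inside an N field
  textures <- list(N = c(0.85, 0.55, 0.70), R4 = c(0.45, 0.22, 0.50))
  img <- array(rep(textures$N, each = 768 * 768), dim = c(768, 768, 3))
  img[257:512, 257:512, ] <- array(rep(textures$R4, each = 256 * 256),
                                   dim = c(256, 256, 3))
  img <- pmin(pmax(img + array(rnorm(768 * 768 * 3, sd = 0.03),
                               dim = c(768, 768, 3)), 0), 1)
  ann <- annotation_set("block", c("R4", rep("N", 4)), list(
    rect_ring(256, 256, 256, 256),
    rect_ring(0, 0, 768, 256), rect_ring(0, 512, 768, 256),
    rect_ring(0, 256, 256, 256), rect_ring(512, 256, 256, 256)))
  s <- list(scan = scan_pyramid("block", list("40" = img)),
            annotations = ann)
  tr <- make_training_set(30)
  suppressMessages(tcfg <- train_config(epochs = 6, lr = 0.5, batch_size = 16, seed = 9))
  clf <- train_classifier(tr$manifest, tr$images, tcfg)
  pm <- predict_probability_map(s$scan, 40, clf,
                                otsu_tissue_mask(
                                  downsample_scan(s$scan$levels[["40"]], 8)))
  am <- argmax_map(pm)
  # truth at patch level from the hierarchical labeling rule
  truth <- label_patches(build_patch_grid(c(768, 768), 40), s$annotations)
  labeled <- !is.na(truth$label) & pm$valid[cbind(
    truth$y / 128 + 1, truth$x / 128 + 1)]
  pred_cancer <- am[cbind(truth$y / 128 + 1, truth$x / 128 + 1)] == "R4"
  true_cancer <- truth$label == "R4"
  iou <- sum(pred_cancer[labeled] & true_cancer[labeled]) /
    max(1, sum(pred_cancer[labeled] | true_cancer[labeled]))
  expect_gte(iou, 0.8)
})
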