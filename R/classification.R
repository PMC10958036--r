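imagenet_mean_255 <- c(123.680, 116.779, 103.939)
imagenet_mean_01 <- c(0.485, 0.456, 0.406)
imagenet_sd_01 <- c(0.229, 0.224, 0.225)

#' Preprocess a 256x256 patch for classification
#'
#' Training mode crops a random 224x224 window, applies a random
#' horizontal flip and a rotation by a random multiple of 90 degrees
#' (draws come from R's RNG, so a fixed seed reproduces the output
#' bit-exactly). Evaluation mode takes the central 224x224 crop at
#' offset (16, 16) deterministically. The `cnn` family then rescales to
#' 0--255 and subtracts the ImageNet channel mean (123.680, 116.779,
#' 103.939); the `vit` family stays on the 0--1 scale and normalizes by
#' the ImageNet mean (0.485, 0.456, 0.406) and standard deviation
#' (0.229, 0.224, 0.225).
#'
#' @param image `256 x 256 x 3` array in `[0, 1]`.
#' @param mode `"train"` or `"eval"`.
#' @param family `"cnn"` or `"vit"`.
#' @return `224 x 224 x 3` numeric array.
#' @export
preprocess_patch <- function(image, mode = c("eval", "train"),
                             family = c("cnn", "vit")) {
  mode <- match.arg(mode)
  family <- match.arg(family)
  d <- dim(image)
  if (length(d) != 3 || d[1] != 256 || d[2] != 256 || d[3] != 3) {
    stop("input patch must be 256 x 256 x 3")
  }
  if (mode == "train") {
    ox <- sample(0:32, 1)
    oy <- sample(0:32, 1)
    crop <- image[(oy + 1):(oy + 224), (ox + 1):(ox + 224), , drop = FALSE]
    if (sample(c(TRUE, FALSE), 1)) crop <- crop[, 224:1, , drop = FALSE]
    k <- sample(0:3, 1)
    for (i in seq_len(k)) { # 90 degrees counter-clockwise
      crop <- aperm(crop, c(2, 1, 3))[224:1, , , drop = FALSE]
    }
  } else {
    crop <- image[17:240, 17:240, , drop = FALSE]
  }
  out <- crop
  for (ch in 1:3) {
    out[, , ch] <- if (family == "cnn") {
      crop[, , ch] * 255 - imagenet_mean_255[ch]
    } else {
      (crop[, , ch] - imagenet_mean_01[ch]) / imagenet_sd_01[ch]
    }
  }
  out
}

#' Training configuration for patch classifiers
#'
#' Defaults: 50 epochs of SGD at learning rate 1e-4, decayed by a
#' factor of 0.1 every 20 epochs, batch size 32, weight decay 5e-4.
#' Deviating values are allowed and reported with a message.
#'
#' @param epochs,lr,lr_decay,lr_decay_every,batch_size,weight_decay
#'   Schedule parameters.
#' @param seed Seed for initialization, shuffling and augmentation.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 50, lr = 1e-4, lr_decay = 0.1,
                         lr_decay_every = 20, batch_size = 32,
                         weight_decay = 5e-4, seed = 1) {
  cfg <- list(epochs = epochs, lr = lr, lr_decay = lr_decay,
              lr_decay_every = lr_decay_every, batch_size = batch_size,
              weight_decay = weight_decay, seed = seed)
  defaults <- list(epochs = 50, lr = 1e-4, lr_decay = 0.1,
                   lr_decay_every = 20, batch_size = 32, weight_decay = 5e-4)
  diff <- names(Filter(isTRUE, Map(function(k) !identical(cfg[[k]], defaults[[k]]),
                                   names(defaults))))
  if (length(diff)) {
    message("train_config deviates from defaults: ", paste(diff, collapse = ", "))
  }
  structure(cfg, class = "train_config")
}

#' Reference patch-classification backbone
#'
#' A deliberately small backbone used for tests and examples: softmax
#' (multinomial logistic) regression on per-channel mean-color
#' features, trained by minibatch SGD. Any backbone exposing the same
#' three functions (`init`, `step`, `predict`) can be plugged into
#' [train_classifier()]; deep architectures are configuration, not
#' code, of this package.
#'
#' @return A list of class `patch_backbone` with functions
#'   `init(n_classes)`, `step(state, x, y, lr, weight_decay)` and
#'   `predict(state, x)`, where `x` is a list of preprocessed
#'   `224 x 224 x 3` arrays.
#' @export
reference_backbone <- function() {
  featurize <- function(x) {
    t(vapply(x, function(img) c(
      mean(img[, , 1]), mean(img[, , 2]), mean(img[, , 3])) / 100,
      numeric(3)))
  }
  structure(list(
    name = "mean-color softmax",
    init = function(n_classes) {
      list(W = matrix(stats::rnorm(4 * n_classes, sd = 0.01), 4, n_classes))
    },
    step = function(state, x, y, lr, weight_decay) {
      f <- cbind(1, featurize(x))
      z <- f %*% state$W
      z <- z - apply(z, 1, max)
      p <- exp(z) / rowSums(exp(z))
      n <- nrow(f)
      yhot <- matrix(0, n, ncol(state$W))
      yhot[cbind(seq_len(n), y)] <- 1
      loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
      grad <- crossprod(f, p - yhot) / n + weight_decay * state$W
      state$W <- state$W - lr * grad
      list(state = state, loss = loss)
    },
    predict = function(state, x) {
      f <- cbind(1, featurize(x))
      z <- f %*% state$W
      z <- z - apply(z, 1, max)
      exp(z) / rowSums(exp(z))
    }
  ), class = "patch_backbone")
}

#' Train a patch classifier
#'
#' Trains a pluggable backbone on the labeled rows of a patch manifest.
#' Each epoch re-augments every patch in training mode (random crop,
#' flip, rotation), shuffles, and runs minibatch updates with the
#' configured learning-rate schedule. All randomness is governed by
#' `config$seed`, so two runs with the same seed produce identical
#' per-epoch losses.
#'
#' @param manifest Patch manifest tibble; only rows with a label are
#'   used.
#' @param images List of `256 x 256 x 3` arrays aligned with the rows
#'   of `manifest`.
#' @param config A [train_config()].
#' @param backbone A backbone, e.g. [reference_backbone()].
#' @param family Preprocessing family (`"cnn"` or `"vit"`).
#' @param classes Class order for `predict_proba`; defaults to the
#'   labels present, in canonical severity order. A requested class
#'   with no training rows is an error.
#' @return An object of class `patch_classifier`.
#' @export
train_classifier <- function(manifest, images, config = train_config(),
                             backbone = reference_backbone(),
                             family = c("cnn", "vit"), classes = NULL) {
  family <- match.arg(family)
  stopifnot(nrow(manifest) == length(images))
  keep <- !is.na(manifest$label)
  labels <- manifest$label[keep]
  images <- images[keep]
  if (length(labels) == 0) stop("manifest contains no labeled rows")
  if (is.null(classes)) {
    classes <- class_labels()[class_labels() %in% unique(labels)]
  }
  counts <- table(factor(labels, levels = classes))
  if (any(counts == 0)) {
    stop("class with no training instances: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  }
  if (!all(labels %in% classes)) stop("labels outside the class list")
  y <- match(labels, classes)
  set.seed(config$seed)
  state <- backbone$init(length(classes))
  history <- vector("list", config$epochs)
  lr <- config$lr
  for (epoch in seq_len(config$epochs)) {
    if (epoch > 1 && (epoch - 1) %% config$lr_decay_every == 0) {
      lr <- lr * config$lr_decay
    }
    aug <- lapply(images, preprocess_patch, mode = "train", family = family)
    ord <- sample(length(aug))
    losses <- c()
    for (start in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
      res <- backbone$step(state, aug[idx], y[idx], lr, config$weight_decay)
      state <- res$state
      losses <- c(losses, res$loss)
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                       loss = mean(losses))
  }
  structure(list(backbone = backbone, state = state, classes = classes,
                 family = family, config = config,
                 history = purrr::list_rbind(history)),
            class = "patch_classifier")
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat(sprintf("<patch_classifier> %s, %d classes (%s), %d epoch(s)\n",
              x$backbone$name, length(x$classes),
              paste(x$classes, collapse = ","), nrow(x$history)))
  invisible(x)
}

#' Class probabilities for patches
#'
#' @param classifier A [train_classifier()] result.
#' @param images List of `256 x 256 x 3` arrays.
#' @return Matrix `n x K` of probabilities, columns in
#'   `classifier$classes` order.
#' @export
predict_proba <- function(classifier, images) {
  stopifnot(inherits(classifier, "patch_classifier"))
  x <- lapply(images, preprocess_patch, mode = "eval",
              family = classifier$family)
  p <- classifier$backbone$predict(classifier$state, x)
  colnames(p) <- classifier$classes
  p
}

#' @exportS3Method generics::tidy
tidy.patch_classifier <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.patch_classifier <- function(x, ...) {
  tibble::tibble(backbone = x$backbone$name, n_classes = length(x$classes),
                 epochs = nrow(x$history),
                 final_loss = utils::tail(x$history$loss, 1))
}

#' Probability map of a scan at one magnification
#'
#' Classifies the central 224x224 crop of every 256-pixel grid patch
#' overlapping valid tissue and assembles the per-class probabilities
#' into a [prob_map()] aligned with the patch grid. Cells outside valid
#' tissue are marked invalid and carry a uniform vector.
#'
#' @param scan A [scan_pyramid()].
#' @param magnification Level to classify (must be present).
#' @param classifier A [train_classifier()] result.
#' @param tissue_mask A `tissue_mask`, or `NULL` to treat all cells as
#'   valid.
#' @param patch_size,stride Grid parameters.
#' @param min_tissue Passed to [mask_to_grid()].
#' @return A [prob_map()].
#' @export
predict_probability_map <- function(scan, magnification, classifier,
                                    tissue_mask = NULL, patch_size = 256,
                                    stride = 128, min_tissue = 0.5) {
  dims <- scan_dims(scan, magnification)
  if (is.null(dims)) stop("magnification ", magnification,
                          "x absent from pyramid")
  grid <- build_patch_grid(dims, magnification, patch_size, stride)
  nr <- attr(grid, "grid_rows"); nc <- attr(grid, "grid_cols")
  valid <- if (is.null(tissue_mask)) rep(TRUE, nrow(grid)) else {
    mask_to_grid(tissue_mask, grid, patch_size, min_tissue)
  }
  k <- length(classifier$classes)
  probs <- matrix(1 / k, nrow(grid), k)
  if (any(valid)) {
    imgs <- purrr::map2(grid$x[valid], grid$y[valid], function(x, y) {
      crop_patch(scan, magnification, x, y, patch_size)
    })
    probs[valid, ] <- predict_proba(classifier, imgs)
  }
  # grid is row-major (y outer), so fill the H x W grid by row
  grid_arr <- array(NA_real_, dim = c(nr, nc, k))
  for (j in seq_len(k)) {
    grid_arr[, , j] <- matrix(probs[, j], nr, nc, byrow = TRUE)
  }
  prob_map(grid_arr, classifier$classes,
           valid = matrix(valid, nr, nc, byrow = TRUE),
           scan_id = scan$scan_id, magnification = magnification)
}
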