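#' Block-average downsampling of a scan image
#'
#' Each output pixel is the mean of a `factor x factor` block of input
#' pixels; partial blocks at the right/bottom edge average the pixels
#' they actually contain. Output dimensions are `ceiling(dim / factor)`.
#'
#' @param image Numeric `H x W x 3` array (or `H x W` matrix) in `[0, 1]`.
#' @param factor Integer downsampling factor.
#' @return Array (or matrix) of the downsampled image.
#' @export
downsample_scan <- function(image, factor = 8) {
  stopifnot(factor >= 1, factor == round(factor))
  block_mean <- function(m) {
    gr <- (seq_len(nrow(m)) - 1) %/% factor
    gc <- (seq_len(ncol(m)) - 1) %/% factor
    s <- rowsum(t(rowsum(m, gr)), gc)
    n <- tabulate(gr + 1) %o% tabulate(gc + 1)
    t(s) / n
  }
  if (length(dim(image)) == 2) return(block_mean(image))
  out <- lapply(seq_len(dim(image)[3]), function(k) block_mean(image[, , k]))
  array(unlist(out), dim = c(dim(out[[1]]), length(out)))
}

new_tissue_mask <- function(mask, scan_id, method, factor = 8) {
  structure(list(mask = mask, scan_id = scan_id, method = method,
                 factor = factor),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> scan %s (%s): %d x %d, %.1f%% tissue\n",
              x$scan_id, x$method, nrow(x$mask), ncol(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Tissue fraction of a mask
#' @param mask A `tissue_mask`.
#' @return Fraction of mask pixels marked tissue.
#' @export
tissue_fraction <- function(mask) mean(mask$mask)

# top threshold of an exhaustive 3-level Otsu split of a 256-bin histogram
multiotsu_top_threshold <- function(gray, nbins = 256) {
  h <- tabulate(pmin(pmax(floor(gray * nbins) + 1, 1), nbins), nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  cw <- c(0, cumsum(p))
  cm <- c(0, cumsum(p * mids))
  t1 <- rep(1:(nbins - 2), times = (nbins - 2):1)
  t2 <- unlist(lapply(1:(nbins - 2), function(a) (a + 1):(nbins - 1)))
  w1 <- cw[t1 + 1];            m1 <- cm[t1 + 1]
  w2 <- cw[t2 + 1] - cw[t1 + 1]; m2 <- cm[t2 + 1] - cm[t1 + 1]
  w3 <- 1 - cw[t2 + 1];        m3 <- cm[nbins + 1] - cm[t2 + 1]
  v <- ifelse(w1 > 0, m1^2 / w1, 0) + ifelse(w2 > 0, m2^2 / w2, 0) +
    ifelse(w3 > 0, m3^2 / w3, 0)
  t2[which.max(v)] / nbins
}

#' Otsu valid-tissue segmentation
#'
#' Segments stained tissue from the bright glass background on a
#' downsampled scan image: grayscale conversion, an Otsu threshold,
#' tissue on the darker side (H&E tissue is darker than the
#' background), then a morphological closing with a 3x3 box element to
#' fill pinholes. Because a scan carrying several stain intensities has
#' a multi-modal gray histogram, the default uses a 3-level Otsu split
#' and keeps the threshold adjacent to the bright background mode
#' (`levels = 3`); on a bimodal histogram this coincides with the
#' classic 2-level threshold, which `levels = 2` forces.
#'
#' @param image Downsampled RGB image (see [downsample_scan()]).
#' @param scan_id Scan identifier carried on the mask.
#' @param factor Downsampling factor the image was produced with.
#' @param levels 2 (classic Otsu) or 3 (multi-level, default).
#' @return A `tissue_mask` (binary matrix at the downsampled
#'   resolution, method `"otsu"`). A constant image yields an
#'   all-background mask with a warning.
#' @export
otsu_tissue_mask <- function(image, scan_id = "scan", factor = 8, levels = 3) {
  stopifnot(levels %in% c(2, 3))
  gray <- if (length(dim(image)) == 3) {
    (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  } else image
  if (stats::sd(gray) == 0) {
    warning("constant image; returning all-background mask")
    return(new_tissue_mask(matrix(FALSE, nrow(gray), ncol(gray)),
                           scan_id, "otsu", factor))
  }
  thr <- if (levels == 2) EBImage::otsu(gray, range = c(0, 1)) else {
    multiotsu_top_threshold(gray)
  }
  mask <- gray < thr
  closed <- EBImage::closing(EBImage::Image(mask * 1),
                             EBImage::makeBrush(3, shape = "box"))
  new_tissue_mask(EBImage::imageData(closed) > 0.5, scan_id, "otsu", factor)
}

#' Project a tissue mask onto a patch grid
#'
#' A patch is treated as valid tissue iff at least `min_tissue` of its
#' footprint, measured in mask pixels at the mask's resolution, is
#' tissue.
#'
#' @param mask A `tissue_mask` at 1/`factor` of 40x resolution.
#' @param grid Tibble from [build_patch_grid()].
#' @param patch_size Patch side at the grid's own magnification.
#' @param min_tissue Minimum tissue fraction of the footprint.
#' @return Logical vector, one entry per grid row.
#' @export
mask_to_grid <- function(mask, grid, patch_size = 256, min_tissue = 0.5) {
  stopifnot(inherits(mask, "tissue_mask"))
  m <- mask$mask
  vapply(seq_len(nrow(grid)), function(i) {
    s <- 40 / grid$magnification[i]
    x0 <- grid$x[i] * s / mask$factor
    y0 <- grid$y[i] * s / mask$factor
    sz <- patch_size * s / mask$factor
    rows <- max(1, floor(y0) + 1):min(nrow(m), ceiling(y0 + sz))
    cols <- max(1, floor(x0) + 1):min(ncol(m), ceiling(x0 + sz))
    mean(m[rows, cols]) >= min_tissue
  }, logical(1))
}

# ---- small fully convolutional network (VDSR-style) -------------------

#' Configuration for the tissue-segmentation FCN
#'
#' Defaults follow the reference architecture: 10 convolutional layers
#' of 64 3x3 filters (plus a 1-channel sigmoid head), trained for 600
#' epochs with Adam at learning rate 1e-4 and weight decay 1e-4.
#' Deviating values are allowed and reported with a message.
#'
#' @param n_layers,n_filters Architecture size.
#' @param epochs,lr,weight_decay Training schedule.
#' @param seed Seed for weight initialization and shuffling.
#' @return A list of class `fcn_config`.
#' @export
fcn_config <- function(n_layers = 10, n_filters = 64, epochs = 600,
                       lr = 1e-4, weight_decay = 1e-4, seed = 1) {
  cfg <- list(n_layers = n_layers, n_filters = n_filters, epochs = epochs,
              lr = lr, weight_decay = weight_decay, seed = seed)
  defaults <- fcn_defaults
  diff <- names(Filter(isTRUE, Map(function(k) !identical(cfg[[k]], defaults[[k]]),
                                   names(defaults))))
  if (length(diff)) {
    message("fcn_config deviates from defaults: ", paste(diff, collapse = ", "))
  }
  structure(cfg, class = "fcn_config")
}

fcn_defaults <- list(n_layers = 10, n_filters = 64, epochs = 600,
                     lr = 1e-4, weight_decay = 1e-4)

# im2col for 3x3 same-padding convolution: H*W x (9*C) matrix.
im2col3 <- function(a) {
  d <- dim(a); h <- d[1]; w <- d[2]; ch <- d[3]
  pad <- array(0, dim = c(h + 2, w + 2, ch))
  pad[2:(h + 1), 2:(w + 1), ] <- a
  cols <- matrix(0, h * w, 9 * ch)
  k <- 0
  for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1
    block <- pad[dy + seq_len(h), dx + seq_len(w), , drop = FALSE]
    cols[, ((k - 1) * ch + 1):(k * ch)] <- matrix(block, h * w, ch)
  }
  cols
}

# adjoint of im2col3: scatter-add HW x 9C back to H x W x C.
col2im3 <- function(cols, h, w, ch) {
  pad <- array(0, dim = c(h + 2, w + 2, ch))
  k <- 0
  for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1
    block <- array(cols[, ((k - 1) * ch + 1):(k * ch)], dim = c(h, w, ch))
    pad[dy + seq_len(h), dx + seq_len(w), ] <-
      pad[dy + seq_len(h), dx + seq_len(w), , drop = FALSE] + block
  }
  pad[2:(h + 1), 2:(w + 1), , drop = FALSE]
}

fcn_init <- function(config) {
  set.seed(config$seed)
  chans <- c(3, rep(config$n_filters, config$n_layers), 1)
  lapply(seq_len(length(chans) - 1), function(l) {
    fan_in <- 9 * chans[l]
    list(W = matrix(stats::rnorm(fan_in * chans[l + 1], sd = sqrt(2 / fan_in)),
                    fan_in, chans[l + 1]),
         b = rep(0, chans[l + 1]))
  })
}

fcn_forward <- function(params, x, keep = FALSE) {
  acts <- list(x)
  a <- x
  nl <- length(params)
  for (l in seq_len(nl)) {
    m <- im2col3(a)
    z <- sweep(m %*% params[[l]]$W, 2, params[[l]]$b, "+")
    a <- if (l < nl) pmax(z, 0) else 1 / (1 + exp(-z))
    a <- array(a, dim = c(dim(x)[1], dim(x)[2], ncol(z)))
    if (keep) acts[[l + 1]] <- a
  }
  if (keep) acts else a
}

#' Train the tissue-segmentation FCN
#'
#' Per-pixel binary cross-entropy on image patches with matching binary
#' masks, optimized with Adam.
#'
#' @param patches List of `21 x 21 x 3` arrays (any size works; all
#'   patches in one call must share dimensions).
#' @param masks List of binary matrices of the same spatial size.
#' @param config An [fcn_config()].
#' @return A list of class `fcn_model` with fields `params`, `config`,
#'   `history` (per-epoch mean loss).
#' @export
train_fcn <- function(patches, masks, config = fcn_config()) {
  stopifnot(length(patches) == length(masks), length(patches) > 0)
  params <- fcn_init(config)
  mstate <- lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                            mb = p$b * 0, vb = p$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  history <- numeric(config$epochs)
  nl <- length(params)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(patches))
    losses <- numeric(length(ord))
    for (ii in seq_along(ord)) {
      x <- patches[[ord[ii]]]
      ytrue <- masks[[ord[ii]]]
      h <- dim(x)[1]; w <- dim(x)[2]
      acts <- fcn_forward(params, x, keep = TRUE)
      p <- acts[[nl + 1]][, , 1]
      p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
      losses[ii] <- -mean(ytrue * log(p) + (1 - ytrue) * log(1 - p))
      # backward: dL/dz for sigmoid + BCE
      dz <- matrix((p - ytrue) / (h * w), h * w, 1)
      for (l in nl:1) {
        a_in <- acts[[l]]
        m <- im2col3(a_in)
        dW <- crossprod(m, dz)
        db <- colSums(dz)
        dm <- dz %*% t(params[[l]]$W)
        da <- col2im3(dm, h, w, dim(a_in)[3])
        if (l > 1) {
          relu_grad <- (acts[[l]] > 0) * 1
          # note: acts[[l]] is the *output* of layer l-1 (ReLU), input to l
          dz <- matrix(da * relu_grad, h * w, dim(a_in)[3])
        }
        st <- mstate[[l]]
        gW <- dW + config$weight_decay * params[[l]]$W
        st$mW <- b1 * st$mW + (1 - b1) * gW
        st$vW <- b2 * st$vW + (1 - b2) * gW^2
        st$mb <- b1 * st$mb + (1 - b1) * db
        st$vb <- b2 * st$vb + (1 - b2) * db^2
        mstate[[l]] <- st
        tcorr <- step + 1
        params[[l]]$W <- params[[l]]$W -
          config$lr * (st$mW / (1 - b1^tcorr)) /
          (sqrt(st$vW / (1 - b2^tcorr)) + eps)
        params[[l]]$b <- params[[l]]$b -
          config$lr * (st$mb / (1 - b1^tcorr)) /
          (sqrt(st$vb / (1 - b2^tcorr)) + eps)
      }
      step <- step + 1
    }
    history[epoch] <- mean(losses)
  }
  structure(list(params = params, config = config, history = history),
            class = "fcn_model")
}

#' FCN valid-tissue segmentation
#'
#' Runs the fully convolutional network over a downsampled scan image
#' and thresholds the per-pixel tissue probability at 0.5.
#'
#' @param image Downsampled RGB image.
#' @param model An `fcn_model` from [train_fcn()] (an untrained model
#'   from [fcn_init_model()] still yields a correctly shaped mask).
#' @param scan_id,factor Metadata carried on the mask.
#' @return A `tissue_mask` with method `"fcn"`.
#' @export
fcn_tissue_mask <- function(image, model, scan_id = "scan", factor = 8) {
  if (length(dim(image)) == 2) {
    image <- array(rep(image, 3), dim = c(dim(image), 3))
  }
  p <- fcn_forward(model$params, image)[, , 1]
  new_tissue_mask(p >= 0.5, scan_id, "fcn", factor)
}

#' @rdname fcn_tissue_mask
#' @param config An [fcn_config()].
#' @return `fcn_init_model()` returns an untrained `fcn_model`.
#' @export
fcn_init_model <- function(config = fcn_config()) {
  structure(list(params = fcn_init(config), config = config,
                 history = numeric(0)),
            class = "fcn_model")
}
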