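#' Configure the encoder-decoder segmenter
#'
#' The model maps a 3-channel patch to a per-pixel foreground logit map of
#' the same spatial size through a U-Net-style topology: `depth` encoder
#' levels of two 3x3 convolutions + ReLU followed by 2x2 max-pooling, a
#' bottleneck, and a mirrored decoder with nearest-neighbour upsampling and
#' skip connections from matching encoder levels. Named presets fix the
#' loss/optimizer combination:
#' `unet1` = BCE-with-logits + SGD, `unet2` = Dice+BCE + Adam,
#' `unet3` = Dice + Adam, `unet4` (alias `mp_net`) = Dice + SGD.
#'
#' @param preset Optional preset name (`"unet1"`..`"unet4"`, `"mp_net"`).
#' @param depth Encoder levels (default 4; patch side must be divisible by
#'   `2^depth`).
#' @param base_width Channels at the first level (default 16; 64 is the
#'   full-scale setting).
#' @param loss `"bce_logits"`, `"dice"` or `"dice_bce"`.
#' @param optimizer `"sgd"` (momentum 0.9) or `"adam"`.
#' @param lr Learning rate (default 1e-2 for SGD, 1e-3 for Adam).
#' @param momentum SGD momentum.
#' @param batch_size Mini-batch size N.
#' @param epochs Training epochs.
#' @param patch_size Training/inference window side (px).
#' @param seed Integer seed for initialization and batching.
#' @return A `model_config` list.
#' @export
model_config <- function(preset = NULL, depth = 4L, base_width = 16L,
                         loss = c("dice", "bce_logits", "dice_bce"),
                         optimizer = c("sgd", "adam"), lr = NULL,
                         momentum = 0.9, batch_size = 8L, epochs = 10L,
                         patch_size = 256L, seed = 1L) {
  if (!is.null(preset)) {
    combo <- switch(preset,
      unet1 = list(loss = "bce_logits", optimizer = "sgd"),
      unet2 = list(loss = "dice_bce", optimizer = "adam"),
      unet3 = list(loss = "dice", optimizer = "adam"),
      unet4 = ,
      mp_net = list(loss = "dice", optimizer = "sgd"),
      stopf("unknown preset '%s'", preset)
    )
    loss <- combo$loss; optimizer <- combo$optimizer
  } else {
    loss <- match.arg(loss); optimizer <- match.arg(optimizer)
  }
  if (is.null(lr)) lr <- if (optimizer == "sgd") 1e-2 else 1e-3
  stopifnot(depth >= 1, base_width >= 1, lr > 0, batch_size >= 1, epochs >= 1)
  structure(list(preset = preset, depth = as.integer(depth),
                 base_width = as.integer(base_width), loss = loss,
                 optimizer = optimizer, lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patch_size = as.integer(patch_size), seed = as.integer(seed)),
            class = "model_config")
}

#' Build (initialize) a segmentation model
#'
#' Seeded He-normal initialization; two builds with the same config are
#' parameter-identical. An optional weights file (a checkpoint written by
#' [save_checkpoint()]) can be loaded instead of random initialization.
#'
#' @param config A [model_config()].
#' @param weights_file Optional checkpoint path to initialize from.
#' @return A `segnet_model` (list: config, params).
#' @export
build_model <- function(config, weights_file = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (config$patch_size %% 2^config$depth != 0) {
    stopf("patch_size %d is not divisible by 2^depth = %d",
          config$patch_size, 2^config$depth)
  }
  if (!is.null(weights_file)) {
    ckpt <- readRDS(weights_file)
    return(structure(list(config = config, params = ckpt$params),
                     class = "segnet_model"))
  }
  params <- with_seed(config$seed,
                      init_params(config$depth, config$base_width))
  structure(list(config = config, params = params), class = "segnet_model")
}

#' @export
print.segnet_model <- function(x, ...) {
  cat(sprintf("<segnet_model> depth %d, width %d, %s + %s, %d parameters\n",
              x$config$depth, x$config$base_width, x$config$loss,
              x$config$optimizer, n_parameters(x$params)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file serialized parameters; a JSON config sidecar
#' (`<path>.json`) is written alongside when jsonlite is available.
#'
#' @param model A `segnet_model`.
#' @param path Checkpoint file path.
#' @return `path` (save) / a `segnet_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$params), path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  cfg <- ckpt$config
  class(cfg) <- "model_config"
  structure(list(config = cfg, params = ckpt$params), class = "segnet_model")
}

# ---- losses --------------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * t) + s) / (sum(p) + sum(t) + s)` with smoothing
#' `s = 1`; lies in `[0, 1]` and is ~0 for a perfect binary prediction.
#'
#' @param prob Probability map (values in `[0, 1]`).
#' @param target Binary target of the same shape.
#' @param smooth Smoothing constant `s`.
#' @return Scalar loss.
#' @export
dice_loss <- function(prob, target, smooth = 1) {
  if (!all(dim(prob) == dim(target))) stopf("prob/target shapes differ")
  1 - (2 * sum(prob * target) + smooth) / (sum(prob) + sum(target) + smooth)
}

#' Binary cross-entropy from logits
#'
#' Numerically stable mean BCE:
#' `mean(max(z, 0) - z * t + log(1 + exp(-|z|)))`.
#'
#' @param logits Logit map.
#' @param target Binary target of the same shape.
#' @return Scalar loss.
#' @export
bce_logits_loss <- function(logits, target) {
  if (!all(dim(logits) == dim(target))) stopf("logits/target shapes differ")
  mean(pmax(logits, 0) - logits * target + log1p(exp(-abs(logits))))
}

#' @rdname bce_logits_loss
#' @param prob Probability map for the Dice term.
#' @export
dice_bce_loss <- function(logits, prob, target) {
  dice_loss(prob, target) + bce_logits_loss(logits, target)
}

# batch loss + gradient wrt logits; z, t are [h,w,1,n]
batch_loss <- function(kind, z, t, smooth = 1) {
  n <- dim(z)[4]
  p <- sigmoid(z)
  dL <- array(0, dim(z))
  loss <- 0
  if (kind %in% c("dice", "dice_bce")) {
    for (l in seq_len(n)) {
      pl <- p[, , , l]; tl <- t[, , , l]
      num <- 2 * sum(pl * tl) + smooth
      den <- sum(pl) + sum(tl) + smooth
      loss <- loss + (1 - num / den) / n
      dLdp <- -(2 * tl * den - num) / den^2 / n
      dL[, , , l] <- dL[, , , l] + dLdp * pl * (1 - pl)
    }
  }
  if (kind %in% c("bce_logits", "dice_bce")) {
    loss <- loss + mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
    dL <- dL + (p - t) / length(z)
  }
  list(loss = loss, dlogits = dL)
}

# ---- training ------------------------------------------------------------

patches_to_tensor <- function(patches, channels) {
  n <- length(patches)
  d <- dim(patches[[1]])
  x <- array(0, c(d[1], d[2], channels, n))
  for (l in seq_len(n)) {
    p <- patches[[l]]
    if (channels == 1L) x[, , 1L, l] <- p else x[, , , l] <- p
  }
  x
}

#' Train the segmenter on image/mask patches
#'
#' Seeded mini-batch optimization of the configured loss; per-epoch training
#' loss, validation loss and validation IoU are recorded, and the parameters
#' from the best validation-loss epoch are returned (training loss decides
#' when no validation set is given). Fully deterministic given
#' `config$seed`.
#'
#' @param model A `segnet_model` from [build_model()].
#' @param image_patches List of `size x size x 3` patches (8-bit values;
#'   internally scaled to `[0, 1]`).
#' @param mask_patches Paired list of `size x size` binary masks.
#' @param val_image_patches,val_mask_patches Optional validation pairs.
#' @param verbose Print per-epoch losses.
#' @return The trained `segnet_model`, with a `history` data.frame field
#'   (epoch, train_loss, val_loss, val_iou) and `best_epoch`.
#' @export
train <- function(model, image_patches, mask_patches,
                  val_image_patches = NULL, val_mask_patches = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(model, "segnet_model"))
  if (length(image_patches) < 1L) stopf("empty training set")
  if (length(image_patches) != length(mask_patches)) {
    stopf("image/mask patch counts differ")
  }
  cfg <- model$config
  x <- patches_to_tensor(image_patches, 3L) / 255
  y <- patches_to_tensor(mask_patches, 1L)
  has_val <- !is.null(val_image_patches) && length(val_image_patches) > 0
  if (has_val) {
    xv <- patches_to_tensor(val_image_patches, 3L) / 255
    yv <- patches_to_tensor(val_mask_patches, 1L)
  }
  params <- model$params
  step <- make_optimizer(cfg$optimizer, params, cfg$lr, cfg$momentum)
  n <- dim(x)[4]
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_iou = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_batches <- 0L
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        xb <- x[, , , idx, drop = FALSE]
        yb <- y[, , , idx, drop = FALSE]
        fw <- net_forward(params, xb, cfg$depth, keep_cache = TRUE)
        bl <- batch_loss(cfg$loss, fw$logits, yb)
        grads <- net_backward(params, fw$cache, bl$dlogits, cfg$depth)
        params <- step(params, grads)
        ep_loss <- ep_loss + bl$loss
        n_batches <- n_batches + 1L
      }
      ep_loss <- ep_loss / n_batches
      if (has_val) {
        vz <- net_forward(params, xv, cfg$depth)$logits
        vl <- batch_loss(cfg$loss, vz, yv)$loss
        vp <- (sigmoid(vz) > 0.5) * 1
        inter <- sum(vp * yv); uni <- sum(pmax(vp, yv))
        viou <- if (uni > 0) inter / uni else 1
      } else {
        vl <- NA_real_; viou <- NA_real_
      }
      sel_loss <- if (has_val) vl else ep_loss
      if (sel_loss < best$loss) best <- list(loss = sel_loss, params = params,
                                             epoch = ep)
      history[ep, ] <- list(ep, ep_loss, vl, viou)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f  val IoU %.4f",
                        ep, ep_loss, vl, viou))
      }
    }
  })
  structure(list(config = cfg, params = best$params, history = history,
                 best_epoch = best$epoch, final_params = params),
            class = "segnet_model")
}

# ---- prediction ----------------------------------------------------------

predict_prob_patches <- function(model, patches, batch_size = 8L) {
  cfg <- model$config
  n <- length(patches)
  out <- vector("list", n)
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    xb <- patches_to_tensor(patches[idx], 3L) / 255
    z <- net_forward(model$params, xb, cfg$depth)$logits
    p <- sigmoid(z)
    for (j in seq_along(idx)) out[[idx[j]]] <- p[, , 1L, j]
  }
  out
}

#' Predict an MP mask for a full image
#'
#' Splits the image into `patch_size` windows, predicts per-patch foreground
#' probabilities, merges them back (overlaps averaged) and binarizes at the
#' probability threshold (strictly greater than).
#'
#' @param model A trained `segnet_model`.
#' @param image An [mp_image()].
#' @param threshold Probability threshold (default 0.5).
#' @param stride Window stride (default `patch_size`, i.e. non-overlapping).
#' @return List with `prob` (probability matrix) and `mask` ([mp_mask()]).
#' @export
predict_mask <- function(model, image, threshold = 0.5, stride = NULL) {
  stopifnot(inherits(model, "segnet_model"), inherits(image, "mp_image"))
  size <- model$config$patch_size
  if (is.null(stride)) stride <- size
  ex <- extract_patches(image$pixels, size = size, stride = stride)
  probs <- predict_prob_patches(model, ex$patches,
                                batch_size = model$config$batch_size)
  prob <- merge_patches(ex$grid, probs)
  list(prob = prob, mask = binarize_prob(prob, threshold))
}

binarize_prob <- function(prob, threshold) mp_mask((prob > threshold) * 1L)

#' Photometric test-time augmentations
#'
#' Standard 8-bit photometric transforms with clipping to `[0, 255]`:
#' additive brightness, contrast about mid-gray, and HSV shifts (hue in
#' degrees, saturation/value as additive fractions of 1).
#'
#' @param image An [mp_image()].
#' @param delta Brightness offset in intensity units.
#' @param factor Contrast factor (1 = identity).
#' @param dh,ds,dv Hue shift (degrees), saturation and value offsets.
#' @return An [mp_image()].
#' @export
adjust_brightness <- function(image, delta) {
  px <- pmin(pmax(image$pixels + delta, 0), 255)
  mp_image(px, scale = image$scale, id = image$id)
}

#' @rdname adjust_brightness
#' @export
adjust_contrast <- function(image, factor) {
  px <- pmin(pmax(round((image$pixels - 128) * factor + 128), 0), 255)
  mp_image(px, scale = image$scale, id = image$id)
}

#' @rdname adjust_brightness
#' @export
shift_hsv <- function(image, dh = 0, ds = 0, dv = 0) {
  px <- image$pixels
  d <- dim(px)
  flat <- matrix(as.numeric(px), prod(d[1:2]), 3L)
  hsv <- grDevices::rgb2hsv(t(flat), maxColorValue = 255)
  hsv[1, ] <- (hsv[1, ] + dh / 360) %% 1
  hsv[2, ] <- pmax(0, pmin(1, hsv[2, ] + ds))
  hsv[3, ] <- pmax(0, pmin(1, hsv[3, ] + dv))
  rgb <- grDevices::col2rgb(grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ]))
  out <- array(0L, d)
  out[, , 1] <- matrix(rgb[1, ], d[1], d[2])
  out[, , 2] <- matrix(rgb[2, ], d[1], d[2])
  out[, , 3] <- matrix(rgb[3, ], d[1], d[2])
  mp_image(out, scale = image$scale, id = image$id)
}

#' Default test-time augmentation set
#'
#' Brightness +/-25, contrast 0.8 / 1.2 and hue +/-10 degrees; each entry is
#' a function `mp_image -> mp_image`.
#'
#' @return Named list of augmentation functions.
#' @export
default_tta <- function() {
  list(
    bright_up   = function(im) adjust_brightness(im, 25),
    bright_down = function(im) adjust_brightness(im, -25),
    contrast_up   = function(im) adjust_contrast(im, 1.2),
    contrast_down = function(im) adjust_contrast(im, 0.8),
    hue_plus  = function(im) shift_hsv(im, dh = 10),
    hue_minus = function(im) shift_hsv(im, dh = -10)
  )
}

#' Predict with test-time augmentation
#'
#' Predicts on the original image and on each photometrically augmented
#' copy (augmentations are label-preserving, so probability maps align
#' without inverse warping), averages the probability maps pixel-wise, and
#' binarizes the average.
#'
#' @inheritParams predict_mask
#' @param augmentations List of functions `mp_image -> mp_image`
#'   (default [default_tta()]); an empty list reduces to [predict_mask()].
#' @return List with `prob` and `mask`.
#' @export
tta_predict <- function(model, image, augmentations = default_tta(),
                        threshold = 0.5, stride = NULL) {
  base <- predict_mask(model, image, threshold, stride)
  if (length(augmentations) == 0L) return(base)
  acc <- base$prob
  for (aug in augmentations) {
    acc <- acc + predict_mask(model, aug(image), threshold, stride)$prob
  }
  prob <- acc / (length(augmentations) + 1L)
  list(prob = prob, mask = binarize_prob(prob, threshold))
}

#' Cross-validated training and evaluation
#'
#' For each of the four fine-tuning runs, fold `CVF(5 - k)` is held out for
#' validation, the remaining three folds are trained on, and the fixed test
#' split is evaluated; the grand mean of each metric is the arithmetic mean
#' of the four per-fold test means.
#'
#' @param images,masks Named lists (by image id) of [mp_image()]s and masks.
#' @param folds Fold assignment data.frame from [assign_folds()].
#' @param config A [model_config()].
#' @param patch_filter `"drop_empty"` applies [filter_empty_patches()] to
#'   training patches; `"none"` keeps all.
#' @return List with `fold_models`, `fold_means` (4-row data.frame) and
#'   `grand_mean`.
#' @export
cross_validate <- function(images, masks, folds, config,
                           patch_filter = c("drop_empty", "none")) {
  patch_filter <- match.arg(patch_filter)
  need <- c("test", paste0("CVF", 1:4))
  if (!all(need %in% folds$split)) {
    stopf("fold assignment must contain test and CVF1..CVF4")
  }
  size <- config$patch_size
  get_patches <- function(ids) {
    ip <- list(); mp <- list()
    for (id in ids) {
      exi <- extract_patches(images[[id]]$pixels, size = size)
      exm <- extract_patches(as_mask_matrix(masks[[id]]), size = size)
      ip <- c(ip, exi$patches); mp <- c(mp, exm$patches)
    }
    if (patch_filter == "drop_empty") {
      f <- filter_empty_patches(ip, mp)
      list(ip = f$image_patches, mp = f$mask_patches)
    } else list(ip = ip, mp = mp)
  }
  test_ids <- folds$id[folds$split == "test"]
  fold_models <- list()
  fold_rows <- list()
  for (k in 1:4) {
    val_fold <- paste0("CVF", 5L - k)
    train_ids <- folds$id[!folds$split %in% c("test", val_fold)]
    val_ids <- folds$id[folds$split == val_fold]
    tr <- get_patches(train_ids)
    va <- get_patches(val_ids)
    cfg_k <- config
    cfg_k$seed <- config$seed + k
    mdl <- train(build_model(cfg_k), tr$ip, tr$mp, va$ip, va$mp)
    fold_models[[k]] <- mdl
    rows <- do.call(rbind, lapply(test_ids, function(id) {
      pr <- predict_mask(mdl, images[[id]])
      seg_metrics(confusion(pr$mask, masks[[id]]))
    }))
    fold_rows[[k]] <- colMeans(rows[c("balanced_accuracy", "recall",
                                      "precision", "f1", "iou")])
  }
  fold_means <- data.frame(fold = paste0("run", 1:4),
                           do.call(rbind, fold_rows), row.names = NULL)
  grand <- as.data.frame(as.list(colMeans(fold_means[, -1])))
  list(fold_models = fold_models, fold_means = fold_means,
       grand_mean = grand)
}
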