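tiny_cfg <- function(...) {
  model_config(depth = 1L, base_width = 2L, patch_size = 8L, epochs = 2L,
               batch_size = 2L, seed = 11L, ...)
}

test_that("the model maps patches to logit maps of the same spatial size", {
  cfg <- model_config(depth = 1L, base_width = 4L, patch_size = 64L, seed = 1L)
  mdl <- build_model(cfg)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  z <- mpquant:::net_forward(mdl$params, x, 1)$logits
  expect_equal(dim(z), c(64, 64, 1, 2))
  expect_error(mpquant:::net_forward(mdl$params,
                                     array(0, c(30, 30, 3, 1)), 2),
               "divisible")
  expect_error(build_model(model_config(depth = 3L, patch_size = 30L)),
               "divisible")
})

test_that("initialization is seed-deterministic and width-monotone", {
  a <- build_model(tiny_cfg()); b <- build_model(tiny_cfg())
  expect_identical(a$params, b$params)
  wide <- build_model(model_config(depth = 1L, base_width = 4L,
                                   patch_size = 8L, seed = 11L))
  expect_gt(mpquant:::n_parameters(wide$params),
            mpquant:::n_parameters(a$params))
})

test_that("losses honour their closed forms", {
  t <- array(rbinom(64, 1, 0.4), c(8, 8))
  expect_lt(dice_loss(t, t), 1 / (2 * sum(t) + 1) + 1e-12)
  # disjoint equal-area prediction
  a <- array(0, c(8, 8)); a[1:2, ] <- 1
  b <- array(0, c(8, 8)); b[5:6, ] <- 1
  expect_equal(dice_loss(a, b), 1 - 1 / (32 + 1))
  # half-overlap, equal area: loss 0.5 in the large-area limit
  big <- 200
  p <- c(rep(1, big), rep(0, big)); q <- c(rep(0, big / 2), rep(1, big),
                                           rep(0, big / 2))
  expect_equal(dice_loss(array(p, c(2 * big, 1)), array(q, c(2 * big, 1))),
               0.5, tolerance = 0.01)

  z <- array(0, c(4, 4)); t0 <- array(0, c(4, 4))
  expect_equal(bce_logits_loss(z, t0), log(2))
  expect_lt(bce_logits_loss(array(100, c(4, 4)), array(1, c(4, 4))), 1e-10)
  # stable formulation equals the naive formula at moderate logits
  set.seed(77)
  zl <- array(rnorm(64, 0, 3), c(8, 8)); tt <- array(rbinom(64, 1, 0.5), c(8, 8))
  pr <- 1 / (1 + exp(-zl))
  naive <- -mean(tt * log(pr) + (1 - tt) * log(1 - pr))
  expect_equal(bce_logits_loss(zl, tt), naive, tolerance = 1e-6)
  expect_equal(dice_bce_loss(zl, pr, tt),
               dice_loss(pr, tt) + bce_logits_loss(zl, tt))
  expect_error(dice_loss(array(0, c(2, 2)), array(0, c(3, 3))), "shape")
})

test_that("analytic gradients match central differences", {
  cfg <- model_config(depth = 1L, base_width = 2L, loss = "dice_bce",
                      patch_size = 8L, seed = 7L)
  P <- build_model(cfg)$params
  set.seed(70)
  # move biases off zero: with zero biases many pre-activations sit exactly
  # on the ReLU kink where the subgradient and finite differences disagree
  for (nm in names(P)) P[[nm]]$b <- rnorm(length(P[[nm]]$b), 0, 0.05)
  x <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
  fw <- mpquant:::net_forward(P, x, 1, keep_cache = TRUE)
  bl <- mpquant:::batch_loss("dice_bce", fw$logits, y)
  gr <- mpquant:::net_backward(P, fw$cache, bl$dlogits, 1)
  lossfun <- function(params) {
    z <- mpquant:::net_forward(params, x, 1)$logits
    mpquant:::batch_loss("dice_bce", z, y)$loss
  }
  eps <- 1e-5
  for (nm in names(P)) for (fld in c("W", "b")) {
    arr <- P[[nm]][[fld]]
    for (i in sample(length(arr), min(3, length(arr)))) {
      p2 <- P; p2[[nm]][[fld]][i] <- p2[[nm]][[fld]][i] + eps
      p3 <- P; p3[[nm]][[fld]][i] <- p3[[nm]][[fld]][i] - eps
      num <- (lossfun(p2) - lossfun(p3)) / (2 * eps)
      expect_equal(gr[[nm]][[fld]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic and can overfit one scene", {
  sc <- generate_scene(sample_scene_spec(c(32, 32), 1, archetypes = "particle",
                                         seed = 83))
  exi <- extract_patches(sc$image$pixels, size = 32)
  exm <- extract_patches(unclass(sc$mask), size = 32)
  cfg <- model_config(depth = 2L, base_width = 8L, loss = "dice_bce",
                      optimizer = "adam", patch_size = 32L, epochs = 80L,
                      batch_size = 1L, seed = 5L)
  m1 <- train(build_model(cfg), exi$patches, exm$patches)
  m2 <- train(build_model(cfg), exi$patches, exm$patches)
  expect_identical(m1$history, m2$history)
  expect_lt(tail(m1$history$train_loss, 1), 0.05)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  pr <- predict_mask(m1, sc$image)
  expect_gt(seg_metrics(confusion(pr$mask, sc$mask))$iou, 0.9)
  expect_error(train(build_model(cfg), list(), list()), "empty")
})

test_that("prediction handles thresholds, shapes and constant models", {
  cfg <- tiny_cfg()
  mdl <- build_model(cfg)
  # zero every parameter: logits identically 0 -> p = 0.5 -> empty mask
  for (nm in names(mdl$params)) {
    mdl$params[[nm]]$W[] <- 0; mdl$params[[nm]]$b[] <- 0
  }
  img <- mp_image(array(sample(0:255, 20 * 12 * 3, TRUE), c(20, 12, 3)))
  pr <- predict_mask(mdl, img)
  expect_equal(dim(pr$prob), c(20, 12))
  expect_true(all(pr$prob == 0.5))
  expect_equal(sum(pr$mask), 0L) # strict > 0.5
  expect_equal(dim(pr$mask), dim(unclass(pr$mask)))
})

test_that("checkpoints roundtrip through disk", {
  td <- withr::local_tempdir()
  mdl <- build_model(tiny_cfg())
  save_checkpoint(mdl, file.path(td, "m.ckpt"))
  back <- load_checkpoint(file.path(td, "m.ckpt"))
  expect_identical(back$params, mdl$params)
  expect_equal(back$config$depth, mdl$config$depth)
  hooked <- build_model(tiny_cfg(), weights_file = file.path(td, "m.ckpt"))
  expect_identical(hooked$params, mdl$params)
})

test_that("photometric augmentations behave as documented", {
  img <- mp_image(array(sample(0:255, 10 * 10 * 3, TRUE), c(10, 10, 3)))
  expect_identical(adjust_brightness(img, 0)$pixels, img$pixels)
  expect_identical(adjust_contrast(img, 1)$pixels, img$pixels)
  expect_identical(shift_hsv(img, 0, 0, 0)$pixels, img$pixels)
  clipped <- adjust_brightness(mp_image(array(240L, c(2, 2, 3))), 25)
  expect_true(all(clipped$pixels == 255L))
  wrapped <- shift_hsv(img, dh = 360)
  expect_true(max(abs(wrapped$pixels - img$pixels)) <= 1)
})

test_that("test-time augmentation averages stay bracketed", {
  sc <- generate_scene(sample_scene_spec(c(48, 48), 1, seed = 89,
                                         archetypes = "particle"))
  cfg <- tiny_cfg()
  mdl <- build_model(cfg)
  base <- predict_mask(mdl, sc$image)
  ident <- tta_predict(mdl, sc$image,
                       augmentations = list(function(x) x, function(x) x))
  expect_equal(ident$prob, base$prob)
  expect_equal(tta_predict(mdl, sc$image, augmentations = list())$prob,
               base$prob)
  augs <- default_tta()
  individual <- c(list(base$prob),
                  lapply(augs, function(a)
                    predict_mask(mdl, a(sc$image))$prob))
  tta <- tta_predict(mdl, sc$image)
  lo <- Reduce(pmin, individual); hi <- Reduce(pmax, individual)
  expect_true(all(tta$prob >= lo - 1e-12 & tta$prob <= hi + 1e-12))
  expect_true(all(tta$prob >= 0 & tta$prob <= 1))
  expect_equal(dim(tta$prob), dim(base$prob))
})

test_that("cross-validation averages fold means into the grand mean", {
  set.seed(97)
  ids <- sprintf("im%02d", 1:10)
  scenes <- lapply(1:10, function(s) generate_scene(
    sample_scene_spec(c(16, 16), 1, archetypes = "particle", seed = 100 + s,
                      size_range = c(5, 7))))
  images <- setNames(lapply(scenes, `[[`, "image"), ids)
  masks <- setNames(lapply(scenes, `[[`, "mask"), ids)
  folds <- assign_folds(vapply(masks, sum, 0L), ids = ids)
  cfg <- model_config(depth = 1L, base_width = 2L, loss = "dice_bce",
                      optimizer = "adam", patch_size = 16L, epochs = 2L,
                      batch_size = 4L, seed = 3L)
  cv <- cross_validate(images, masks, folds, cfg)
  expect_equal(nrow(cv$fold_means), 4L)
  expect_equal(cv$grand_mean$iou, mean(cv$fold_means$iou))
  expect_equal(cv$grand_mean$f1, mean(cv$fold_means$f1))
  expect_error(cross_validate(images, masks, folds[folds$split != "CVF2", ],
                              cfg), "CVF")
})
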