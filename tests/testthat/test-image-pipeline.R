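# Bilinear face normalization and the CNN training paths.

test_that("bilinear resize matches the closed-form oracle on random crops", {
  set.seed(11)
  for (rep in 1:20) {
    H <- sample(2:9, 1); W <- sample(2:9, 1)
    oh <- sample(1:12, 1); ow <- sample(1:12, 1)
    img <- array(runif(H * W * 3), c(H, W, 3))
    expect_equal(bilinear_resize(img, oh, ow),
                 bilinear_resize_oracle(img, oh, ow), tolerance = 1e-12)
  }
})

test_that("upsampling the 2x2 checker crop places 50 at the center", {
  img <- array(c(0, 100, 100, 0), c(2, 2, 1))
  up <- bilinear_resize(img, 3, 3)
  expect_equal(up[2, 2, 1], 50)
  expect_equal(up[1, 1, 1], 0)      # corners preserved (corner-aligned)
  expect_equal(up[3, 3, 1], 0)
  expect_equal(up[1, 3, 1], 100)
})

test_that("normalize_face crops, clamps out-of-bounds boxes and is idempotent", {
  set.seed(3)
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  # identity: N equal to crop size returns the crop unchanged
  f <- normalize_face(img, list(x = 5, y = 7, w = 16, h = 16), N = 16)
  expect_equal(unclass(f), img[7:22, 5:20, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # box past the right edge is clipped then resized
  f2 <- normalize_face(img, list(x = 30, y = 1, w = 13, h = 20), N = 12)
  expect_equal(attr(f2, "box")[["w"]], 11)
  expect_equal(dim(f2), c(12L, 12L, 3L))
  # fully outside
  expect_error(normalize_face(img, list(x = 45, y = 1, w = 5, h = 5), N = 8),
               "geometry error")
  expect_error(normalize_face(img, list(x = 1, y = 1, w = 5, h = 5), N = 4),
               "argument error")
  # idempotence at fixed N with the full-frame box
  once <- normalize_face(img, list(x = 1, y = 1, w = 40, h = 40), N = 24)
  twice <- normalize_face(unclass(once), list(x = 1, y = 1, w = 24, h = 24),
                          N = 24)
  expect_equal(unclass(twice), unclass(once), tolerance = 1 / 255,
               ignore_attr = TRUE)
})

test_that("a small CNN learns separable 2-class faces to >0.9 held-out accuracy", {
  cfg <- synth_config(L = 2L, n_per_class = 100L, difficulty = 1.0, seed = 1L)
  d <- gen_faces(cfg)
  sp <- stratified_split(d$labels, 0.5, seed = 1)
  m <- train_image_model(build_cnn_small(2), d$images[sp$train],
                         d$labels[sp$train], epochs = 30, batch_size = 16,
                         seed = 1)
  sc <- score_images(m, d$images[sp$test])
  acc <- mean(max.col(sc) - 1L == d$labels[sp$test])
  expect_gt(acc, 0.9)
  # training loss trends downward
  h <- m$history
  expect_lt(mean(tail(h$loss, 5)), mean(head(h$loss, 5)))
})

test_that("an untrained model scores near-uniformly and at chance", {
  cfg <- tiny_cfg(L = 3L, seed = 5)
  d <- gen_faces(cfg)
  m <- train_image_model(build_cnn_small(3), d$images, d$labels, epochs = 0,
                         seed = 2)
  sc <- score_images(m, d$images)
  expect_equal(unname(rowSums(sc)), rep(1, nrow(sc)), tolerance = 1e-5)
  expect_lt(mean(abs(sc - 1 / 3)), 0.25)  # near-uniform rows on average
})

test_that("scoring is deterministic, row-normalized and order-equivariant", {
  cfg <- tiny_cfg(L = 2L, seed = 9)
  d <- gen_faces(cfg)
  m <- train_image_model(build_cnn_small(2), d$images, d$labels, epochs = 2,
                         seed = 3)
  sc1 <- score_images(m, d$images)
  expect_equal(unname(rowSums(sc1)), rep(1, nrow(sc1)), tolerance = 1e-5)
  # duplicated inputs give identical rows
  sc_dup <- score_images(m, d$images[c(1, 1, 2)])
  expect_equal(unname(unclass(sc_dup)[1, ]), unname(unclass(sc_dup)[2, ]))
  # permuting inputs permutes rows identically
  perm <- rev(seq_along(d$images))
  sc2 <- score_images(m, d$images[perm])
  expect_equal(unname(unclass(sc2)), unname(unclass(sc1)[perm, ]),
               tolerance = 1e-12)
  # mismatched input shape is a configuration error
  expect_error(score_images(m, list(array(0, c(16, 16, 3)))),
               "configuration error")
})

test_that("training refuses a single-class set and mismatched shapes", {
  cfg <- tiny_cfg(L = 2L, seed = 4)
  d <- gen_faces(cfg)
  one_class <- d$labels == 0
  expect_error(train_image_model(build_cnn_small(2), d$images[one_class],
                                 d$labels[one_class], epochs = 1),
               "single class")
  expect_error(train_image_model(build_cnn_small(2, input_size = 16L),
                                 d$images, d$labels, epochs = 1),
               "configuration error")
})

test_that("progressive-resolution training transfers weights and validates input", {
  cfg <- tiny_cfg(L = 2L, seed = 7)
  d <- gen_faces(cfg)
  expect_error(scheme1_progressive_train(
    function(s) build_cnn_small(2, input_size = s), d$images, d$labels,
    resolutions = c(32, 16)), "argument error")
  m <- scheme1_progressive_train(
    function(s) build_cnn_small(2, input_size = s), d$images, d$labels,
    resolutions = c(16, 24, 32), epochs_per_stage = 2, seed = 1)
  expect_equal(nrow(m$stage_log), 3)
  # conv weights are resolution-independent, so every stage after the first
  # transfers all conv/bn layers (and the head when the flatten length holds)
  expect_gte(min(m$stage_log$transferred[-1]), 8)
  # degenerate single-resolution schedule equals plain training
  m1 <- scheme1_progressive_train(
    function(s) build_cnn_small(2, input_size = s), d$images, d$labels,
    resolutions = 32, epochs_per_stage = 2, seed = 1)
  plain <- train_image_model(build_cnn_small(2), d$images, d$labels,
                             epochs = 2, seed = 1)
  X <- painsense:::stack_images(d$images)
  expect_equal(nn_predict(m1, X), nn_predict(plain, X), tolerance = 1e-12)
})

test_that("frozen layers are bit-exact unchanged after fine-tuning", {
  cfg <- tiny_cfg(L = 2L, seed = 8)
  d <- gen_faces(cfg)
  base <- train_image_model(build_cnn_small(2), d$images, d$labels,
                            epochs = 2, seed = 1)
  tuned <- scheme2_transfer_train(build_cnn_small(2), d$images, d$labels,
                                  mode = "warm_start", init_model = base,
                                  freeze = "^block", epochs = 2, seed = 2)
  conv_layers <- grep("^block", names(tuned$params), value = TRUE)
  for (nm in conv_layers)
    expect_identical(tuned$params[[nm]], base$params[[nm]])
  expect_true(all(grepl("^block", tuned$frozen_layers)))
  # the trainable head did move
  expect_false(identical(tuned$params[["fc1"]], base$params[["fc1"]]))
  # freezing everything makes training a no-op on the warm-started weights
  frozen_all <- scheme2_transfer_train(build_cnn_small(2), d$images, d$labels,
                                       mode = "warm_start", init_model = base,
                                       freeze = ".", epochs = 2, seed = 3)
  expect_identical(frozen_all$params, base$params)
  expect_error(scheme2_transfer_train(build_cnn_small(2), d$images, d$labels,
                                      freeze = "no_such_layer", epochs = 1),
               "configuration error")
  expect_error(scheme2_transfer_train(build_cnn_small(2), d$images, d$labels,
                                      mode = "warm_start", epochs = 1),
               "configuration error")
})

test_that("training under a fixed seed reproduces identical models", {
  cfg <- tiny_cfg(L = 2L, seed = 12)
  d <- gen_faces(cfg)
  m1 <- train_image_model(build_cnn_small(2), d$images, d$labels, epochs = 3,
                          seed = 42)
  m2 <- train_image_model(build_cnn_small(2), d$images, d$labels, epochs = 3,
                          seed = 42)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("warm-starting from a related task reaches the target in fewer epochs", {
  arch <- build_cnn_small(2)
  epochs_to <- function(h, thr = 0.9) {
    i <- which(h$acc >= thr)
    if (length(i)) i[1] else nrow(h) + 1L
  }
  warm_e <- scratch_e <- integer(0)
  for (seed in 1:3) {
    pre <- gen_faces(synth_config(L = 2L, n_per_class = 25L, difficulty = 1.0,
                                  seed = seed + 50L))
    base <- train_image_model(arch, pre$images, pre$labels, epochs = 6,
                              seed = seed)
    d <- gen_faces(synth_config(L = 2L, n_per_class = 25L, difficulty = 0.7,
                                seed = seed))
    warm <- scheme2_transfer_train(arch, d$images, d$labels,
                                   mode = "warm_start", init_model = base,
                                   epochs = 10, seed = seed)
    scratch <- scheme2_transfer_train(arch, d$images, d$labels,
                                      mode = "from_scratch", epochs = 10,
                                      seed = seed)
    warm_e <- c(warm_e, epochs_to(warm$history))
    scratch_e <- c(scratch_e, epochs_to(scratch$history))
  }
  expect_lt(median(warm_e), median(scratch_e))
})
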