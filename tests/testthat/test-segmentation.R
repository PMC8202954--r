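# U-Net construction, training contracts, overlap-tile stitching, and the
# Dice / object-F1 evaluation metrics.

test_that("U-Net outputs match input size with sigmoid-range values", {
  cfg <- seg_config(64L, n_classes = 2L, depth = 3L, base_filters = 4L)
  m <- build_unet(cfg, seed = 1)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  p <- predict_tiles(m, x)
  expect_equal(dim(p), c(64L, 64L, 2L, 2L))
  expect_true(all(p > 0 & p < 1))
  expect_error(seg_config(100L, depth = 3L), "divisible")
})

test_that("parameter counts are deterministic and analytic", {
  cfg <- seg_config(128L, n_classes = 1L, depth = 3L, base_filters = 8L)
  m1 <- build_unet(cfg, seed = 1)
  m2 <- build_unet(cfg, seed = 2)
  count <- function(m) cryptflow:::n_params(m$params)
  expect_equal(count(m1), count(m2))
  # sum of conv shapes: encoder, bottleneck, decoder (up + 2 convs), 1x1 out
  f <- 8L * 2L^(0:2); fb <- 8L * 2L^3
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout
  expected <- conv_n(3, 3, f[1]) + conv_n(3, f[1], f[1]) +
    conv_n(3, f[1], f[2]) + conv_n(3, f[2], f[2]) +
    conv_n(3, f[2], f[3]) + conv_n(3, f[3], f[3]) +
    conv_n(3, f[3], fb) + conv_n(3, fb, fb) +
    conv_n(3, fb, f[3]) + conv_n(3, 2 * f[3], f[3]) + conv_n(3, f[3], f[3]) +
    conv_n(3, f[3], f[2]) + conv_n(3, 2 * f[2], f[2]) + conv_n(3, f[2], f[2]) +
    conv_n(3, f[2], f[1]) + conv_n(3, 2 * f[1], f[1]) + conv_n(3, f[1], f[1]) +
    conv_n(1, f[1], 1L)
  expect_equal(count(m1), expected)
})

test_that("training splits 80/20 and keeps augmented tiles out of validation", {
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  tiles <- lapply(1:100, function(i)
    list(image = img, mask = array(round(runif(32 * 32)), c(32, 32, 1)),
         spec = list(slide_id = "s"), augmented = FALSE,
         tile_id = paste0("t", i)))
  m <- build_unet(seg_config(32L, 1L, depth = 2L, base_filters = 2L), seed = 0)
  fit <- train_seg(m, tiles, split_seed = 1, epochs = 1L, batch_size = 20L)
  expect_length(fit$split$train, 80L)
  expect_length(fit$split$val, 20L)
  # augmented children of validation tiles are excluded from training
  aug <- lapply(tiles[1:10], function(t) {
    t$augmented <- TRUE; t$source_id <- t$tile_id
    t$tile_id <- paste0(t$tile_id, "_aug"); t
  })
  fit2 <- train_seg(m, c(tiles, aug), split_seed = 1, epochs = 1L,
                    batch_size = 20L)
  val_ids <- vapply(tiles[fit2$split$val], function(t) t$tile_id, character(1))
  train_src <- vapply(c(tiles, aug)[fit2$split$train], function(t)
    if (is.null(t$source_id)) "" else t$source_id, character(1))
  expect_length(intersect(train_src, val_ids), 0L)
  expect_error(train_seg(m, tiles[1:5]), "at least 10")
})

test_that("overlap-tile stitching equals direct application of a per-pixel model", {
  set.seed(2)
  surrogates <- list(
    function(im) array(im[, , 2], c(dim(im)[1:2], 1)),
    function(im) array(im[, , 1] / (1 + im[, , 3]), c(dim(im)[1:2], 1)))
  sizes <- list(c(480, 480), c(960, 960), c(500, 731), c(130, 97),
                c(1000, 250))
  for (fun in surrogates) for (sz in sizes) {
    img <- array(runif(prod(sz) * 3), c(sz, 3))
    pm <- predict_slide(fun, img, tile = 512L, center = 480L)
    expect_identical(pm$prob[, , 1], fun(img)[, , 1])
  }
  # tile counts follow the ceiling grid
  img <- array(runif(480 * 480 * 3), c(480, 480, 3))
  expect_equal(predict_slide(surrogates[[1]], img, tile = 512L,
                             center = 480L)$n_tiles, 1L)
  img <- array(runif(960 * 960 * 3), c(960, 960, 3))
  expect_equal(predict_slide(surrogates[[1]], img, tile = 512L,
                             center = 480L)$n_tiles, 4L)
})

test_that("dice handles identity, disjoint, partial and empty masks", {
  a <- matrix(FALSE, 10, 10); a[1:5, 1:5] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- matrix(FALSE, 10, 10); b[6:10, 6:10] <- TRUE
  expect_equal(dice(a, b), 0)
  # |a| = |b| = 100, |intersection| = 50
  a2 <- matrix(FALSE, 20, 20); a2[1:10, 1:10] <- TRUE
  b2 <- matrix(FALSE, 20, 20); b2[1:10, 6:15] <- TRUE
  expect_equal(dice(a2, b2), 0.5)
  expect_equal(dice(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 1)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(a, matrix(FALSE, 5, 5)), "shape")
})

test_that("object F1 follows greedy IoU matching and label permutation invariance", {
  truth <- matrix(0L, 20, 20)
  truth[2:8, 2:8] <- 1L
  truth[12:18, 12:18] <- 2L
  expect_equal(object_f1(truth, truth)$f1, 1)
  expect_equal(object_f1(matrix(0L, 20, 20), truth)$f1, 0)
  # one prediction matching one of two truths: P = 1, R = 0.5, F1 = 2/3
  pred <- matrix(0L, 20, 20); pred[2:8, 2:8] <- 1L
  r <- object_f1(pred, truth)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f1, 2 / 3)
  # permuting instance labels changes nothing
  perm <- truth; perm[truth == 1L] <- 2L; perm[truth == 2L] <- 1L
  expect_equal(object_f1(perm, truth)$f1, 1)
  # below-threshold overlap is not a match
  off <- matrix(0L, 20, 20); off[6:12, 6:12] <- 1L
  expect_equal(object_f1(off, truth)$f1, 0)
})

test_that("short training on fixtures converges with mostly decreasing loss", {
  fit <- fx_seg_fit()
  h <- fit$model$history
  expect_gt(tail(h$val_dice, 1), 0.8)
  lagged <- h$train_loss[seq_len(nrow(h) - 3)] -
    h$train_loss[seq_len(nrow(h) - 3) + 3]
  expect_lte(sum(lagged < 0), 1)  # allow one violation
  expect_gt(tail(h$val_accuracy, 1), 0.9)
})
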