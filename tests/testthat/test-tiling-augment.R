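# Randomized sliding-window tiling and image/mask-synchronous augmentation.

test_that("degenerate window/stride ranges tile the image exactly", {
  img <- array(runif(512 * 512 * 3), c(512, 512, 3))
  sl <- list(image = img, gland_mask = matrix(FALSE, 512, 512),
             metadata = list(slide_id = "s"))
  t1 <- generate_tiles(sl, seed = 1, win_range = c(512L, 512L),
                       stride_range = c(512L, 512L), out_size = 512L)
  expect_length(t1, 1L)
  expect_equal(t1[[1]]$image, img)

  img2 <- array(runif(1024 * 1024 * 3), c(1024, 1024, 3))
  sl2 <- list(image = img2, gland_mask = matrix(FALSE, 1024, 1024),
              metadata = list(slide_id = "s"))
  t2 <- generate_tiles(sl2, seed = 1, win_range = c(512L, 512L),
                       stride_range = c(512L, 512L), out_size = 512L)
  expect_length(t2, 4L)  # ceiling((1024-512)/512)+1 = 2 positions per axis
  origins <- t(vapply(t2, function(t) c(t$spec$origin_row, t$spec$origin_col),
                      numeric(2)))
  expect_setequal(paste(origins[, 1], origins[, 2]),
                  c("0 0", "0 512", "512 0", "512 512"))
  # tiles reproduce the image subwindows exactly
  expect_equal(t2[[1]]$image, img2[1:512, 1:512, ])
})

test_that("default ranges on a large fixture hit the tile target", {
  img <- array(runif(3000 * 3000), c(3000, 3000, 1))
  img <- array(rep(img, 3), c(3000, 3000, 3))
  sl <- list(image = img, gland_mask = matrix(FALSE, 3000, 3000),
             metadata = list(slide_id = "big"))
  tl <- generate_tiles(sl, seed = 4, n_target = 100L)
  expect_gte(length(tl), 80L)
  expect_lte(length(tl), 120L)
  expect_true(all(vapply(tl, function(t)
    all(dim(t$image) == c(512L, 512L, 3L)), logical(1))))
  # windows and strides within the documented ranges
  wh <- vapply(tl, function(t) t$spec$window_h, numeric(1))
  expect_true(all(wh >= 256 & wh <= 768))
  # reproducible for a fixed seed
  tl2 <- generate_tiles(sl, seed = 4, n_target = 100L)
  expect_identical(lapply(tl, `[[`, "spec"), lapply(tl2, `[[`, "spec"))
})

test_that("too-small images fall back to a single resized tile", {
  img <- array(runif(200 * 200 * 3), c(200, 200, 3))
  sl <- list(image = img, gland_mask = matrix(FALSE, 200, 200),
             metadata = list(slide_id = "small"))
  expect_warning(tl <- generate_tiles(sl, seed = 1), "smaller")
  expect_length(tl, 1L)
  expect_equal(dim(tl[[1]]$image), c(512L, 512L, 3L))
})

test_that("identity-pinned augmentation returns the input unchanged", {
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  msk <- array((matrix(runif(128 * 128), 128) > 0.5) * 1, c(128, 128, 1))
  tile <- list(image = img, mask = msk, spec = list(slide_id = "s"),
               augmented = FALSE, tile_id = "t1")
  a <- augment(tile, seed = 5, crop_range = c(128, 128),
               aspect_range = c(1, 1), sigma_range = c(0, 0),
               angle_range = c(0, 0))
  expect_equal(a$image, img)
  expect_equal(a$mask, msk)
  expect_true(a$augmented)
  expect_equal(a$source_id, "t1")
})

test_that("a marked pixel lands at the same place in image and mask", {
  mk_tile <- function(r, c) {
    img <- array(0, c(128, 128, 3)); msk <- array(0, c(128, 128, 1))
    img[r, c, ] <- 1; msk[r, c, 1] <- 1
    list(image = img, mask = msk, spec = list(slide_id = "s"),
         augmented = FALSE, tile_id = "t1")
  }
  # closed-form 90-degree check
  t0 <- mk_tile(30L, 50L)
  a <- augment(t0, seed = 1, crop_range = c(128, 128), aspect_range = c(1, 1),
               sigma_range = c(0, 0), angle_range = c(90, 90))
  wi <- which(a$image[, , 1] == max(a$image[, , 1]), arr.ind = TRUE)
  wm <- which(a$mask[, , 1] == 1, arr.ind = TRUE)
  expect_equal(as.integer(wi), as.integer(wm))
  expect_equal(max(a$image[, , 1]), 1)
  # property: over many random crops/rotations the marker (when retained)
  # sits on a bright image pixel, and the mask stays binary
  hits <- 0L
  for (s in 1:50) {
    t1 <- mk_tile(64L, 64L)  # center marker survives most crops
    a <- augment(t1, seed = s, sigma_range = c(0, 0))
    expect_true(all(a$mask %in% c(0, 1)))
    mi <- which(a$mask[, , 1] == 1)
    if (length(mi) > 0) {
      hits <- hits + 1L
      # two chained bilinear resamplings can dilute the unit marker to
      # ~0.25 * 0.25 of its intensity at worst
      expect_gt(max(a$image[, , 1][mi]), 0.05)
    }
  }
  expect_gt(hits, 25L)
})

test_that("dataset expansion yields factor * N tiles, reproducibly", {
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  tiles <- lapply(1:10, function(i)
    list(image = img, mask = array(1, c(96, 96, 1)),
         spec = list(slide_id = "s"), augmented = FALSE,
         tile_id = paste0("t", i)))
  ex <- expand_dataset(tiles, factor = 5L, seed = 3, sigma_range = c(0, 1))
  expect_length(ex, 50L)
  expect_equal(sum(vapply(ex, function(t) t$augmented, logical(1))), 40L)
  expect_identical(expand_dataset(tiles, factor = 1L, seed = 3), tiles)
  ex2 <- expand_dataset(tiles, factor = 5L, seed = 3, sigma_range = c(0, 1))
  expect_equal(ex[[37]]$image, ex2[[37]]$image)
})
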