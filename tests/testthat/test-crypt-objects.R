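# Instance extraction, central/peripheral partitioning (against a
# brute-force distance-transform oracle), and patch-stack sampling.

disc_mask <- function(H, W, cy, cx, r) {
  outer(seq_len(H), seq_len(W), function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}

test_that("instance extraction thresholds, filters and orders by area", {
  m <- disc_mask(60, 60, 15, 15, 8) | disc_mask(60, 60, 45, 45, 12)
  inst <- extract_instances(m * 1, min_area = 10L)
  expect_length(inst, 2L)
  expect_gt(inst[[1]]$area, inst[[2]]$area)  # ordered by descending area
  expect_equal(inst[[1]]$label, 1L)
  # min_area discards a small disc: radius 3.5 disc has ~38 < 50 pixels
  sm <- disc_mask(30, 30, 15, 15, 3.5)
  expect_lt(sum(sm), 50)
  expect_length(extract_instances(sm * 1, min_area = 50L), 0L)
  expect_length(extract_instances(matrix(0, 10, 10)), 0L)
  expect_error(extract_instances(m * 1, threshold = 1.5), "threshold")
})

test_that("centroid, area and orientation agree with planted ellipses", {
  s <- fx_clean_slide("normal")
  inst <- extract_instances(s$gland_mask * 1, min_area = 10L)
  # match instances to planted crypts by centroid
  planted <- s$centers
  for (ins in inst) {
    d <- sqrt(rowSums(sweep(planted, 2, ins$centroid)^2))
    k <- which.min(d)
    expect_lt(d[k], 2)  # centroid within 2 px of the planted center
    expect_equal(ins$area, s$areas[k])
    # orientation within 15 degrees (folded) for clearly elongated crypts
    ad <- abs(ins$orientation - s$orientations[k]) %% 180
    ad <- min(ad, 180 - ad)
    if (ins$area > 400) expect_lt(ad, 20)
  }
})

test_that("partition agrees with a brute-force distance oracle on random blobs", {
  set.seed(9)
  for (rep in 1:20) {
    m <- matrix(FALSE, 40, 40)
    cx <- runif(1, 14, 26); cy <- runif(1, 14, 26); rad <- runif(1, 6, 13)
    m <- disc_mask(40, 40, cy, cx, rad)
    # random bites out of the disc make irregular blobs
    m <- m & !disc_mask(40, 40, runif(1, 10, 30), runif(1, 10, 30),
                        runif(1, 2, 5))
    if (!any(m)) next
    inst <- structure(list(label = 1L, mask = m, bbox = c(1L, 1L, 40L, 40L),
                           centroid = c(cy, cx), area = sum(m),
                           orientation = 0),
                      class = "crypt_instance")
    depth <- sample(2:6, 1)
    pr <- partition_regions(inst, border_depth = depth)
    # oracle: Euclidean distance to nearest background (frame counts)
    bg <- which(!m, arr.ind = TRUE)
    fg <- which(m, arr.ind = TRUE)
    dmin <- apply(fg, 1, function(p) min(
      sqrt(min((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2)),
      p[1], 41 - p[1], p[2], 41 - p[2]))
    oracle <- m & FALSE
    oracle[fg[dmin > depth, , drop = FALSE]] <- TRUE
    expect_identical(pr$central, oracle)
    # partition identity
    expect_identical(pr$central | pr$peripheral, m)
    expect_false(any(pr$central & pr$peripheral))
  }
})

test_that("thin objects are flagged and fall back to peripheral sampling", {
  bar <- matrix(FALSE, 20, 20); bar[9:10, 2:19] <- TRUE
  inst <- structure(list(label = 1L, mask = bar, bbox = c(1L, 1L, 20L, 20L),
                         centroid = c(9.5, 10.5), area = sum(bar),
                         orientation = 0),
                    class = "crypt_instance")
  pr <- partition_regions(inst, border_depth = 5)
  expect_true(pr$thin)
  expect_false(any(pr$central))
  expect_identical(pr$peripheral, bar)
  img <- array(runif(20 * 20 * 3), c(20, 20, 3))
  st <- sample_patches(inst, img, seed = 1, patch_size = 8L)
  expect_true(st$thin)
  expect_length(st$central_idx, 0L)
  expect_equal(dim(st$tensor), c(8L, 8L, 72L))
})

test_that("patch stacks have the contracted shape, centers and determinism", {
  s <- fx_clean_slide("normal")
  inst <- extract_instances(s$gland_mask * 1, min_area = 10L)
  ins <- inst[[1]]
  st <- sample_patches(ins, s$image, seed = 7)
  expect_equal(dim(st$tensor), c(24L, 24L, 72L))
  expect_equal(nrow(st$centers), 24L)
  reg <- partition_regions(ins)
  off <- ins$bbox[1:2] - 1L
  loc <- sweep(st$centers, 2, off)
  for (i in st$central_idx) expect_true(reg$central[loc[i, 1], loc[i, 2]])
  for (i in setdiff(seq_len(24), st$central_idx))
    expect_true(reg$peripheral[loc[i, 1], loc[i, 2]])
  # all centers inside the instance mask
  expect_true(all(ins$mask[loc]))
  expect_identical(sample_patches(ins, s$image, seed = 7), st)
  expect_false(identical(sample_patches(ins, s$image, seed = 8)$centers,
                         st$centers))
  # patch values are genuine image crops (checked away from borders)
  c1 <- st$centers[1, ]
  rs <- c1[1] - 13 + 1:24; cs <- c1[2] - 13 + 1:24
  if (all(rs >= 1 & rs <= dim(s$image)[1]) &&
      all(cs >= 1 & cs <= dim(s$image)[2]))
    expect_equal(st$tensor[, , 1:3], s$image[rs, cs, ])
})

test_that("cohort stack builder attaches slide metadata", {
  s <- fx_clean_slide("dss")
  st <- crypt_stacks(s, seed = 1, min_area = 10L)
  expect_gt(length(st), 0L)
  expect_true(all(vapply(st, function(x) x$group == "dss", logical(1))))
  expect_true(all(vapply(st, function(x) x$slide_id == s$metadata$slide_id,
                         logical(1))))
})
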