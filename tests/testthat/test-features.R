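# Masked GLCM against brute-force pair enumeration, hand-computed Haralick
# values, entropy and Canny measures, and crypt/slide morphometrics.

test_that("masked GLCM equals brute-force pair enumeration", {
  set.seed(1)
  off <- cryptflow:::glcm_offsets(1L, c(0, 45, 90, 135))
  for (r in 1:20) {
    gray <- matrix(sample(0:7, 256, TRUE), 16, 16)
    mask <- matrix(runif(256) > 0.3, 16, 16)
    if (!any(mask)) next
    P1 <- masked_glcm(gray, mask, levels = 8L)$P
    P2 <- brute_glcm(gray, mask, 8L, off)
    expect_equal(P1, P2, tolerance = 1e-12)
  }
})

test_that("all-true mask reproduces the whole-image GLCM", {
  set.seed(2)
  gray <- matrix(sample(0:15, 400, TRUE), 20, 20)
  full <- matrix(TRUE, 20, 20)
  off <- cryptflow:::glcm_offsets(1L, c(0, 45, 90, 135))
  expect_equal(masked_glcm(gray, full, levels = 16L)$P,
               brute_glcm(gray, full, 16L, off), tolerance = 1e-12)
})

test_that("checkerboard and constant GLCMs give hand-computed features", {
  g <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  P <- masked_glcm(g, matrix(TRUE, 2, 2), levels = 2L, distances = 1L,
                   angles = 0)
  expect_equal(P$P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  f <- glcm_features(P)
  expect_equal(f$glcm_contrast, 1)
  expect_equal(f$glcm_dissimilarity, 1)
  expect_equal(f$glcm_homogeneity, 0.5)
  expect_equal(f$glcm_ASM, 0.5)
  expect_equal(f$glcm_energy, sqrt(0.5))
  expect_equal(f$glcm_correlation, -1)
  expect_equal(f$glcm_entropy, log(2))
  # constant region: single-entry degenerate distribution
  fc <- glcm_features(masked_glcm(matrix(3L, 4, 4), matrix(TRUE, 4, 4),
                                  levels = 8L))
  expect_equal(fc$glcm_contrast, 0)
  expect_equal(fc$glcm_dissimilarity, 0)
  expect_equal(fc$glcm_homogeneity, 1)
  expect_equal(fc$glcm_ASM, 1)
  expect_equal(fc$glcm_energy, 1)
  expect_equal(fc$glcm_entropy, 0)
  expect_equal(fc$glcm_correlation, 1)
  expect_error(glcm_features(matrix(1, 2, 2)), "not normalized")
  expect_error(masked_glcm(g, matrix(FALSE, 2, 2)), "empty")
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_error(masked_glcm(matrix(0L, 5, 5), single, levels = 2L),
               "degenerate")
})

test_that("first-order entropy matches closed forms", {
  expect_equal(first_order_entropy(matrix(0.5, 5, 5), matrix(TRUE, 5, 5)), 0)
  two <- matrix(rep(c(0.2, 0.7), each = 8), 4, 4)
  expect_equal(first_order_entropy(two, matrix(TRUE, 4, 4)), 1)
  u <- matrix((0:255) / 256, 16, 16)
  expect_equal(first_order_entropy(u, matrix(TRUE, 16, 16), bins = 256L), 8)
  expect_error(first_order_entropy(u, matrix(FALSE, 16, 16)), "empty")
})

test_that("canny density is 0 on flat images, in [0,1], and counts masked edges", {
  flat <- matrix(0.5, 40, 40)
  expect_equal(canny_density(flat, matrix(TRUE, 40, 40)), 0)
  set.seed(3)
  for (r in 1:20) {
    img <- matrix(runif(40 * 40), 40, 40)
    mask <- matrix(runif(40 * 40) > 0.4, 40, 40)
    if (!any(mask)) next
    d <- canny_density(img, mask)
    expect_gte(d, 0); expect_lte(d, 1)
  }
  # a sharp vertical step: masked density equals the direct masked count
  step <- cbind(matrix(0, 40, 20), matrix(1, 40, 20))
  mask <- matrix(FALSE, 40, 40); mask[11:30, 11:30] <- TRUE
  e <- canny_edges(step)
  expect_equal(canny_density(step, mask), sum(e & mask) / sum(mask))
  expect_gt(canny_density(step, mask), 0)  # the edge crosses the mask
})

test_that("nearest-neighbour morphometrics use 3-4-5 distances and folded angles", {
  i1 <- synthetic_instance(1L, c(0, 0), 10)
  i2 <- synthetic_instance(2L, c(3, 4), 170)
  m <- morphometrics(list(i1, i2), matrix(TRUE, 2, 2), matrix(TRUE, 2, 2))
  expect_equal(m$crypts$nn_distance, c(5, 5))
  expect_equal(m$crypts$nn_angle_diff, c(20, 20))  # min(|160|, 180-160)
  i3 <- synthetic_instance(3L, c(0, 1), 10)
  m2 <- morphometrics(list(i1, i3), matrix(TRUE, 2, 2), matrix(TRUE, 2, 2))
  expect_equal(m2$crypts$nn_angle_diff, c(0, 0))
  # single crypt: nearest-neighbour features are missing
  m1 <- morphometrics(list(i1), matrix(TRUE, 2, 2), matrix(TRUE, 2, 2))
  expect_true(is.na(m1$crypts$nn_distance))
  # empty mucosa: ratio undefined with a warning
  expect_warning(
    m0 <- morphometrics(list(i1, i2), matrix(TRUE, 2, 2),
                        matrix(FALSE, 2, 2)),
    "mucosa")
  expect_true(is.na(m0$slide$gland_mucosa_ratio))
  # planted areas give the exact ratio
  g <- matrix(FALSE, 30, 30); g[1:10, 1:10] <- TRUE        # 100 px
  mu <- matrix(FALSE, 30, 30); mu[1:20, 1:20] <- TRUE      # 400 px
  m3 <- morphometrics(list(i1, i2), g, mu)
  expect_equal(m3$slide$gland_mucosa_ratio, 0.25)
})

test_that("feature ranges hold across many fixture crypts", {
  ft <- fx_feature_table()
  cr <- ft$crypts
  expect_gt(nrow(cr), 200L)
  expect_true(all(cr$glcm_homogeneity > 0 & cr$glcm_homogeneity <= 1))
  expect_true(all(cr$glcm_ASM > 0 & cr$glcm_ASM <= 1))
  expect_equal(cr$glcm_energy, sqrt(cr$glcm_ASM))
  expect_true(all(cr$glcm_correlation >= -1 & cr$glcm_correlation <= 1))
  expect_true(all(cr$glcm_contrast >= 0))
  expect_true(all(cr$glcm_entropy >= 0))
  expect_true(all(cr$entropy_bits >= 0))
  expect_true(all(cr$canny_density >= 0 & cr$canny_density <= 1))
  ok <- !is.na(cr$nn_angle_diff)
  expect_true(all(cr$nn_angle_diff[ok] >= 0 & cr$nn_angle_diff[ok] <= 90))
  expect_true(all(cr$orientation >= 0 & cr$orientation < 180))
})

test_that("slide-level aggregation and score joining behave", {
  ft <- fx_feature_table()
  sl <- ft$slides
  # slide means reproduce the mean of the crypt rows
  sid <- sl$slide_id[which.max(sl$n_crypts)]
  expect_equal(sl$glcm_contrast[sl$slide_id == sid],
               mean(ft$crypts$glcm_contrast[ft$crypts$slide_id == sid]))
  expect_equal(sl$gland_mucosa_ratio, sl$gland_area / sl$mucosa_area)
  # joining pathologist scores, with a warning for unknown ids
  sc <- data.frame(slide_id = c(sl$slide_id[1], "nonexistent"),
                   epithelium_score = c(2, 9), inflammation_score = c(1, 9))
  s1 <- fx_cohort()[1]
  expect_warning(ft2 <- featurize_cohort(s1, scores = sc), "unknown")
  expect_true("epithelium_score" %in% names(ft2$slides))
})

test_that("masked GLCM contrast orders the archetypes as built", {
  sl <- fx_feature_table()$slides
  mg <- tapply(sl$glcm_contrast, sl$group, mean, na.rm = TRUE)
  expect_gt(mg[["normal"]], mg[["treated"]])
  expect_gt(mg[["treated"]], mg[["dss"]])
})

test_that("masked entropy separates groups more than whole-slide entropy", {
  sl <- fx_feature_table()$slides
  d <- function(f) {
    x <- sl[[f]][sl$group == "normal"]; y <- sl[[f]][sl$group == "dss"]
    (mean(x) - mean(y)) / sqrt((stats::var(x) + stats::var(y)) / 2)
  }
  expect_gt(d("entropy_masked"), d("entropy_slide"))
})
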