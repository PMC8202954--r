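# Masked texture and morphometric features per crypt and per slide:
# first-order entropy, gray-level co-occurrence (Haralick) statistics
# restricted to a mask, Canny edge density, nearest-neighbour geometry and
# the gland/mucosa area ratio.

#' ITU-R 601 luma of an RGB array
#' @param img `[H, W, 3]` array with values in `[0, 1]`, or an `[H, W]`
#'   matrix returned unchanged.
#' @return grayscale matrix in `[0, 1]`.
#' @export
to_gray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Uniform quantization of a [0,1] grayscale image to integer levels
#' @param gray matrix in `[0, 1]`.
#' @param levels number of gray levels G.
#' @return integer matrix with values `0 .. G-1`.
#' @export
quantize_gray <- function(gray, levels = 32L) {
  q <- floor(gray * levels)
  q[q >= levels] <- levels - 1L
  q[q < 0L] <- 0L
  matrix(as.integer(q), nrow(gray), ncol(gray))
}

# Offsets (drow, dcol) for a distance/angle pair, skimage convention:
# 0 deg = horizontal right, angles counterclockwise.
glcm_offsets <- function(distances, angles) {
  off <- NULL
  for (d in distances) for (a in angles) {
    rad <- a * pi / 180
    off <- rbind(off, c(round(-d * sin(rad)), round(d * cos(rad))))
  }
  off
}

#' Masked gray-level co-occurrence matrix
#'
#' Counts pairs of pixels at the given offsets where BOTH pixels lie inside
#' the mask, accumulates over all offsets, symmetrizes (adds the transpose)
#' and normalizes to sum 1.
#'
#' @param gray integer matrix of levels `0 .. levels-1` (see
#'   [quantize_gray()]), or a numeric `[0,1]` matrix which is quantized.
#' @param mask logical matrix (nonempty).
#' @param levels number of gray levels G.
#' @param distances offset distances in pixels.
#' @param angles offset angles in degrees.
#' @return a `glcm_matrix`: list with `P` (G x G, symmetric, sums to 1),
#'   `levels`, `distances`, `angles`, `n_pairs`.
#' @export
masked_glcm <- function(gray, mask, levels = 32L, distances = 1L,
                        angles = c(0, 45, 90, 135)) {
  if (!is.integer(gray)) gray <- quantize_gray(gray, levels)
  if (!any(mask)) stop("mask is empty")
  off <- glcm_offsets(distances, angles)
  C <- glcm_pair_counts(gray, mask, as.integer(levels),
                        as.integer(off[, 1]), as.integer(off[, 2]))
  n_pairs <- sum(C)
  if (n_pairs == 0)
    stop("degenerate mask: no co-occurring pixel pairs at these offsets")
  P <- C + t(C)
  P <- P / sum(P)
  structure(list(P = P, levels = as.integer(levels), distances = distances,
                 angles = angles, n_pairs = n_pairs),
            class = "glcm_matrix")
}

#' Haralick features of a GLCM
#'
#' contrast `= sum (i-j)^2 P`, dissimilarity `= sum |i-j| P`, homogeneity
#' `= sum P / (1 + (i-j)^2)`, ASM `= sum P^2`, energy `= sqrt(ASM)`,
#' entropy `= -sum P ln P` (natural log; `0 ln 0 := 0`), correlation
#' `= sum (i - mu_i)(j - mu_j) P / (sigma_i sigma_j)`, defined as 1 for a
#' zero-variance matrix (the continuity limit of identical pixels).
#'
#' @param glcm a `glcm_matrix` (or a bare normalized symmetric matrix).
#' @return named list of the seven features, prefixed `glcm_`.
#' @export
glcm_features <- function(glcm) {
  P <- if (inherits(glcm, "glcm_matrix")) glcm$P else glcm
  if (abs(sum(P) - 1) > 1e-6) stop("GLCM is not normalized")
  if (any(P < 0)) stop("GLCM has negative entries")
  G <- nrow(P)
  i <- matrix(seq_len(G) - 1, G, G)
  j <- t(i)
  dif <- i - j
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  var_i <- sum((i - mu_i)^2 * P); var_j <- sum((j - mu_j)^2 * P)
  sd_ij <- sqrt(var_i * var_j)
  pos <- P > 0
  list(
    glcm_contrast = sum(dif^2 * P),
    glcm_dissimilarity = sum(abs(dif) * P),
    glcm_homogeneity = sum(P / (1 + dif^2)),
    glcm_ASM = sum(P^2),
    glcm_energy = sqrt(sum(P^2)),
    glcm_entropy = -sum(P[pos] * log(P[pos])),
    glcm_correlation = if (sd_ij == 0) 1
      else sum((i - mu_i) * (j - mu_j) * P) / sd_ij
  )
}

#' First-order Shannon entropy of a masked region
#'
#' Entropy in bits (log2) of the intensity histogram restricted to the mask.
#'
#' @param gray numeric `[0,1]` matrix (or integer levels).
#' @param mask logical matrix (nonempty).
#' @param bins number of histogram bins.
#' @return entropy in bits, `>= 0`.
#' @export
first_order_entropy <- function(gray, mask, bins = 256L) {
  if (!any(mask)) stop("mask is empty")
  v <- gray[mask]
  if (!is.integer(v)) {
    v <- floor(v * bins)
    v[v >= bins] <- bins - 1L
  }
  p <- tabulate(v + 1L, bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# ---- Canny edge detection ---------------------------------------------------

# Separable Gaussian blur with replicated borders; works for images smaller
# than the kernel (unlike FFT-based filters).
gaussian_blur_matrix <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (t in -r:r)
    out <- out + k[t + r + 1] * m[pmin(pmax(seq_len(H) + t, 1L), H), ]
  m2 <- matrix(0, H, W)
  for (t in -r:r)
    m2 <- m2 + k[t + r + 1] * out[, pmin(pmax(seq_len(W) + t, 1L), W)]
  m2
}

# Sobel gradients with replicated borders.
sobel_gradients <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  shift <- function(dr, dc) {
    r <- pmin(pmax(seq_len(H) + dr, 1L), H)
    c <- pmin(pmax(seq_len(W) + dc, 1L), W)
    gray[r, c]
  }
  gx <- (shift(-1, 1) + 2 * shift(0, 1) + shift(1, 1)) -
    (shift(-1, -1) + 2 * shift(0, -1) + shift(1, -1))
  gy <- (shift(1, -1) + 2 * shift(1, 0) + shift(1, 1)) -
    (shift(-1, -1) + 2 * shift(-1, 0) + shift(-1, 1))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Canny edge map
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis thresholding (weak edges are
#' kept only in 8-connected components containing a strong edge).
#'
#' @param gray numeric `[0,1]` matrix.
#' @param sigma Gaussian smoothing sigma in pixels.
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude.
#' @return logical edge matrix.
#' @export
canny_edges <- function(gray, sigma = 1.4, low = 0.1, high = 0.2) {
  if (sigma > 0) gray <- gaussian_blur_matrix(gray, sigma)
  g <- sobel_gradients(gray)
  H <- nrow(gray); W <- ncol(gray)
  mag <- g$mag
  if (max(mag) == 0) return(matrix(FALSE, H, W))
  ang <- atan2(g$gy, g$gx) * 180 / pi
  ang <- ang %% 180
  sector <- ifelse(ang < 22.5 | ang >= 157.5, 0L,
                   ifelse(ang < 67.5, 1L, ifelse(ang < 112.5, 2L, 3L)))
  shift <- function(m, dr, dc) {
    out <- matrix(0, H, W)
    rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
    ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  # neighbour offsets along the gradient direction per sector
  n1 <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  keep <- matrix(FALSE, H, W)
  for (s in 0:3) {
    d <- n1[[s + 1]]
    a <- shift(mag, d[1], d[2])
    b <- shift(mag, -d[1], -d[2])
    keep <- keep | (sector == s & mag >= a & mag >= b)
  }
  nms <- mag * keep
  strong <- nms >= high * max(mag)
  weak <- nms >= low * max(mag)
  if (!any(strong)) return(matrix(FALSE, H, W))
  lab <- cc_label8(matrix(as.integer(weak), H, W))
  good <- unique(lab[strong])
  lab > 0 & matrix(lab %in% good, H, W)
}

#' Canny edge density within a mask
#'
#' Fraction of mask pixels flagged as Canny edges (edges detected on the
#' whole image, counted inside the mask).
#'
#' @inheritParams canny_edges
#' @param mask logical matrix (nonempty).
#' @return fraction in `[0, 1]`.
#' @export
canny_density <- function(gray, mask, sigma = 1.4, low = 0.1, high = 0.2) {
  if (!any(mask)) stop("mask is empty")
  e <- canny_edges(gray, sigma = sigma, low = low, high = high)
  sum(e & mask) / sum(mask)
}

# ---- morphometrics ----------------------------------------------------------

# Fold an orientation difference into [0, 90] degrees.
fold_angle <- function(delta) {
  d <- abs(delta) %% 180
  pmin(d, 180 - d)
}

#' Nearest-neighbour and area morphometrics
#'
#' Per crypt: Euclidean centroid distance to the nearest other crypt and the
#' absolute difference of the two major-axis orientations folded into
#' `[0, 90]` degrees (missing when fewer than 2 crypts). Per slide: crypt
#' count, gland and mucosa areas and their ratio (undefined and flagged when
#' the mucosa mask is empty).
#'
#' @param instances list of `crypt_instance`s.
#' @param gland_mask,mucosa_mask logical matrices.
#' @return list with `crypts` data.frame (label, nn_distance, nn_angle_diff,
#'   nn_label) and `slide` list (n_crypts, gland_area, mucosa_area,
#'   gland_mucosa_ratio).
#' @export
morphometrics <- function(instances, gland_mask, mucosa_mask) {
  n <- length(instances)
  if (n >= 2) {
    cen <- t(vapply(instances, function(i) i$centroid, numeric(2)))
    ori <- vapply(instances, function(i) i$orientation, numeric(1))
    D <- as.matrix(stats::dist(cen))
    diag(D) <- Inf
    nn <- apply(D, 1, which.min)
    crypts <- data.frame(
      label = vapply(instances, function(i) i$label, integer(1)),
      nn_distance = D[cbind(seq_len(n), nn)],
      nn_angle_diff = fold_angle(ori - ori[nn]),
      nn_label = vapply(instances, function(i) i$label, integer(1))[nn])
  } else {
    crypts <- data.frame(
      label = vapply(instances, function(i) i$label, integer(1)),
      nn_distance = rep(NA_real_, n), nn_angle_diff = rep(NA_real_, n),
      nn_label = rep(NA_integer_, n))
  }
  ga <- sum(gland_mask); ma <- sum(mucosa_mask)
  slide <- list(n_crypts = n, gland_area = ga, mucosa_area = ma,
                gland_mucosa_ratio = if (ma > 0) ga / ma else NA_real_)
  if (ma == 0) warning("mucosa mask empty; gland/mucosa ratio undefined")
  list(crypts = crypts, slide = slide)
}

# ---- cohort featurization ---------------------------------------------------

# All texture/morphometric features of one crypt instance on one slide.
crypt_feature_row <- function(instance, image, glcm_levels = 32L,
                              glcm_distances = 1L,
                              glcm_angles = c(0, 45, 90, 135)) {
  bb <- instance$bbox
  sub <- image[bb[1]:bb[3], bb[2]:bb[4], , drop = FALSE]
  gray <- to_gray(sub)
  feats <- tryCatch(
    glcm_features(masked_glcm(gray, instance$mask, levels = glcm_levels,
                              distances = glcm_distances,
                              angles = glcm_angles)),
    error = function(e) stats::setNames(
      as.list(rep(NA_real_, 7)),
      c("glcm_contrast", "glcm_dissimilarity", "glcm_homogeneity",
        "glcm_ASM", "glcm_energy", "glcm_entropy", "glcm_correlation")))
  cbind(data.frame(label = instance$label, area = instance$area,
                   orientation = instance$orientation,
                   centroid_row = instance$centroid[1],
                   centroid_col = instance$centroid[2]),
        as.data.frame(feats),
        data.frame(entropy_bits = first_order_entropy(gray, instance$mask),
                   canny_density = canny_density(gray, instance$mask)))
}

#' Crypt- and slide-level feature tables for a cohort
#'
#' For every slide: extracts (or reuses) crypt instances, computes per-crypt
#' texture and morphometric features, and aggregates slide-level records
#' (crypt count, gland/mucosa areas and ratio, unweighted means of the
#' per-crypt features, plus whole-slide and masked first-order entropy).
#' Optional pathologist scores (CSV columns `slide_id`, `epithelium_score`,
#' `inflammation_score`) are joined on `slide_id`; unknown ids produce a
#' warning and an outer join.
#'
#' @param slides list of `rendered_slide`s (or lists with `image`,
#'   `gland_mask`, `mucosa_mask`, `metadata`).
#' @param instances_list optional list (parallel to `slides`) of instance
#'   lists; by default instances are extracted from each slide's gland mask.
#' @param scores optional data.frame (or CSV path) of pathologist scores.
#' @param threshold,min_area passed to [extract_instances()].
#' @param ... GLCM parameters passed to the per-crypt featurizer.
#' @return a `feature_table`: list with `crypts` and `slides` data.frames.
#' @export
featurize_cohort <- function(slides, instances_list = NULL, scores = NULL,
                             threshold = 0.5, min_area = 30L, ...) {
  crypt_rows <- list()
  slide_rows <- list()
  for (k in seq_along(slides)) {
    sl <- slides[[k]]
    meta <- sl$metadata
    inst <- if (!is.null(instances_list)) instances_list[[k]]
      else extract_instances(sl$gland_mask * 1, threshold = threshold,
                             min_area = min_area)
    mor <- morphometrics(inst, sl$gland_mask, sl$mucosa_mask)
    gray <- to_gray(sl$image)
    if (length(inst) > 0) {
      cf <- do.call(rbind, lapply(inst, crypt_feature_row, image = sl$image,
                                  ...))
      cf <- merge(cf, mor$crypts, by = "label", sort = TRUE)
      cf <- cbind(data.frame(slide_id = meta$slide_id,
                             animal_id = meta$animal_id,
                             group = meta$group), cf)
      crypt_rows[[length(crypt_rows) + 1L]] <- cf
      num <- cf[, !(names(cf) %in% c("slide_id", "animal_id", "group",
                                     "label", "nn_label", "centroid_row",
                                     "centroid_col")), drop = FALSE]
      means <- as.list(colMeans(num, na.rm = TRUE))
    } else {
      means <- NULL
    }
    srow <- data.frame(slide_id = meta$slide_id, animal_id = meta$animal_id,
                       group = meta$group, n_crypts = mor$slide$n_crypts,
                       gland_area = mor$slide$gland_area,
                       mucosa_area = mor$slide$mucosa_area,
                       gland_mucosa_ratio = mor$slide$gland_mucosa_ratio,
                       entropy_slide = first_order_entropy(
                         gray, matrix(TRUE, nrow(gray), ncol(gray))),
                       entropy_masked = if (any(sl$gland_mask))
                         first_order_entropy(gray, sl$gland_mask)
                       else NA_real_)
    if (!is.null(means)) srow <- cbind(srow, as.data.frame(means))
    slide_rows[[length(slide_rows) + 1L]] <- srow
  }
  crypts <- if (length(crypt_rows)) do.call(rbind, crypt_rows) else NULL
  cols <- unique(unlist(lapply(slide_rows, names)))
  slide_tab <- do.call(rbind, lapply(slide_rows, function(r) {
    miss <- setdiff(cols, names(r))
    for (m in miss) r[[m]] <- NA_real_
    r[cols]
  }))
  if (!is.null(scores)) {
    if (is.character(scores)) scores <- utils::read.csv(scores)
    unknown <- setdiff(scores$slide_id, slide_tab$slide_id)
    if (length(unknown))
      warning("score table has unknown slide_ids: ",
              paste(unknown, collapse = ", "))
    slide_tab <- merge(slide_tab, scores, by = "slide_id", all = TRUE)
  }
  rownames(slide_tab) <- NULL
  if (!is.null(crypts)) rownames(crypts) <- NULL
  structure(list(crypts = crypts, slides = slide_tab),
            class = "feature_table")
}

#' Write a feature table as tidy CSVs
#' @param ft a `feature_table`.
#' @param dir output directory.
#' @return invisibly `NULL`.
#' @export
write_features <- function(ft, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(ft$crypts))
    utils::write.csv(ft$crypts, file.path(dir, "crypt_features.csv"),
                     row.names = FALSE)
  utils::write.csv(ft$slides, file.path(dir, "slide_features.csv"),
                   row.names = FALSE)
  invisible(NULL)
}
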