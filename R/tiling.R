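# Training-tile generation by randomized sliding windows (window side
# 256-768 px, stride 256-512 px at full scale, resized to the network input
# size) and spatial/blur augmentation applied identically to image and mask.

# ---- resampling primitives --------------------------------------------------

# Bilinear resize of [H,W,C] (or matrix) to Ho x Wo; exact identity when the
# size is unchanged. Pixel-center (align_corners = FALSE) convention.
bilinear_resize <- function(img, Ho, Wo) {
  d <- dim(img)
  is_mat <- length(d) == 2L
  if (is_mat) { img <- array(img, c(d, 1L)); d <- dim(img) }
  H <- d[1]; W <- d[2]; C <- d[3]
  sr <- pmin(pmax((seq_len(Ho) - 0.5) * H / Ho + 0.5, 1), H)
  sc <- pmin(pmax((seq_len(Wo) - 0.5) * W / Wo + 0.5, 1), W)
  r0 <- floor(sr); r1 <- pmin(r0 + 1, H); wr <- sr - r0
  c0 <- floor(sc); c1 <- pmin(c0 + 1, W); wc <- sc - c0
  out <- array(0, c(Ho, Wo, C))
  Wr <- matrix(wr, Ho, Wo); Wc <- matrix(wc, Ho, Wo, byrow = TRUE)
  for (ch in seq_len(C)) {
    p <- img[, , ch]
    out[, , ch] <- (1 - Wr) * (1 - Wc) * p[r0, c0] + Wr * (1 - Wc) * p[r1, c0] +
      (1 - Wr) * Wc * p[r0, c1] + Wr * Wc * p[r1, c1]
  }
  if (is_mat) out[, , 1] else out
}

# Nearest-neighbour resize (for masks; keeps values binary).
nearest_resize <- function(img, Ho, Wo) {
  d <- dim(img)
  is_mat <- length(d) == 2L
  if (is_mat) img <- array(img, c(d, 1L))
  y <- nn_resize_nearest(as_batch(img * 1), as.integer(Ho), as.integer(Wo))
  out <- array(y, dim(y)[1:3])
  if (is_mat) out[, , 1] else out
}

# Rotate about the image center by `angle` degrees (backward mapping).
# interp: bilinear (image) or nearest (mask). fill: reflect or zero.
rotate_about_center <- function(img, angle, interp = c("bilinear", "nearest"),
                                fill = c("reflect", "zero")) {
  interp <- match.arg(interp); fill <- match.arg(fill)
  d <- dim(img)
  is_mat <- length(d) == 2L
  if (is_mat) { img <- array(img, c(d, 1L)); d <- dim(img) }
  H <- d[1]; W <- d[2]; C <- d[3]
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  xs <- cos(th) * xx + sin(th) * yy + cx
  ys <- -sin(th) * xx + cos(th) * yy + cy
  out <- array(0, c(H, W, C))
  if (interp == "nearest") {
    ri <- round(ys); ci <- round(xs)
    inside <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    if (fill == "reflect") {
      ri <- matrix(reflect_index(as.integer(ri), H), H, W)
      ci <- matrix(reflect_index(as.integer(ci), W), H, W)
      inside[] <- TRUE
    } else {
      ri[!inside] <- 1L; ci[!inside] <- 1L
    }
    idx <- cbind(as.vector(ri), as.vector(ci))
    for (ch in seq_len(C)) {
      v <- img[, , ch][idx]
      v[!as.vector(inside)] <- 0
      out[, , ch] <- matrix(v, H, W)
    }
  } else {
    r0 <- floor(ys); c0 <- floor(xs)
    wr <- ys - r0; wc <- xs - c0
    gi <- function(r, c) { # gather with fill policy
      if (fill == "reflect") {
        r <- matrix(reflect_index(as.integer(r), H), H, W)
        c <- matrix(reflect_index(as.integer(c), W), H, W)
        list(idx = cbind(as.vector(r), as.vector(c)), valid = TRUE)
      } else {
        ok <- r >= 1 & r <= H & c >= 1 & c <= W
        r[!ok] <- 1L; c[!ok] <- 1L
        list(idx = cbind(as.vector(r), as.vector(c)), valid = as.vector(ok))
      }
    }
    g00 <- gi(r0, c0); g10 <- gi(r0 + 1, c0)
    g01 <- gi(r0, c0 + 1); g11 <- gi(r0 + 1, c0 + 1)
    for (ch in seq_len(C)) {
      p <- img[, , ch]
      v <- function(g) {
        x <- p[g$idx]
        if (!isTRUE(g$valid)) x[!g$valid] <- 0
        x
      }
      res <- (1 - as.vector(wr)) * (1 - as.vector(wc)) * v(g00) +
        as.vector(wr) * (1 - as.vector(wc)) * v(g10) +
        (1 - as.vector(wr)) * as.vector(wc) * v(g01) +
        as.vector(wr) * as.vector(wc) * v(g11)
      out[, , ch] <- matrix(res, H, W)
    }
  }
  if (is_mat) out[, , 1] else out
}

# ---- tile generation --------------------------------------------------------

# Uniform integer in [lo, hi]; length-1 safe (unlike sample(lo:hi, 1)).
sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  as.integer(sample.int(hi - lo + 1L, 1L) + lo - 1L)
}

# Build the [H,W,nc] training mask for a slide-like object.
slide_mask_array <- function(slide, n_classes) {
  m1 <- slide$gland_mask * 1
  if (n_classes == 1L) return(array(m1, c(dim(m1), 1L)))
  m2 <- slide$mucosa_mask * 1
  array(c(m1, m2), c(dim(m1), 2L))
}

#' Generate training tiles by randomized sliding windows
#'
#' Scans the slide with windows of per-step random side in `win_range` and
#' random stride in `stride_range`; windows near the border are clamped
#' inside the image. Each window (image + mask) is resized to
#' `out_size x out_size`. Randomized scan passes repeat until about
#' `n_target` tiles exist; when both ranges are degenerate the scan is
#' deterministic and a single pass is performed.
#'
#' @param slide a `rendered_slide`, or any list with `image`, `gland_mask`
#'   (and `mucosa_mask` when `n_classes = 2`) and optionally
#'   `metadata$slide_id`.
#' @param seed integer seed.
#' @param n_target approximate number of tiles to produce.
#' @param win_range window side range in pixels (full scale: 256-768).
#' @param stride_range stride range in pixels (full scale: 256-512).
#' @param out_size output tile side (network input size).
#' @param n_classes 1 (gland) or 2 (gland + mucosa) mask channels.
#' @return list of `training_tile` objects: `image` (`[S,S,3]`), binary
#'   `mask` (`[S,S,nc]`), `spec` (0-based origin, window size, slide id),
#'   `augmented = FALSE`, `tile_id`.
#' @export
generate_tiles <- function(slide, seed = 0L, n_target = 100L,
                           win_range = c(256L, 768L),
                           stride_range = c(256L, 512L),
                           out_size = 512L, n_classes = 1L) {
  img <- slide$image
  H <- dim(img)[1]; W <- dim(img)[2]
  sid <- if (!is.null(slide$metadata$slide_id)) slide$metadata$slide_id else "slide"
  msk <- slide_mask_array(slide, n_classes)
  make_tile <- function(r0, c0, wh, ww, k) {
    sub <- img[r0:(r0 + wh - 1), c0:(c0 + ww - 1), , drop = FALSE]
    subm <- msk[r0:(r0 + wh - 1), c0:(c0 + ww - 1), , drop = FALSE]
    list(image = bilinear_resize(sub, out_size, out_size),
         mask = nearest_resize(subm, out_size, out_size),
         spec = list(origin_row = r0 - 1L, origin_col = c0 - 1L,
                     window_h = wh, window_w = ww, slide_id = sid),
         augmented = FALSE, source_id = NULL,
         tile_id = sprintf("%s_t%04d", sid, k))
  }
  if (min(H, W) < win_range[1]) {
    warning("image smaller than minimum window; returning one whole-image tile")
    return(list(make_tile(1L, 1L, H, W, 1L)))
  }
  degenerate <- win_range[1] == win_range[2] &&
    stride_range[1] == stride_range[2]
  with_seed(seed, {
    tiles <- list()
    k <- 0L
    for (pass in seq_len(1000L)) {
      r <- 1L
      repeat {
        hit_bottom <- FALSE
        c <- 1L
        repeat {
          wh <- sample_range(win_range[1], win_range[2])
          ww <- sample_range(win_range[1], win_range[2])
          wh <- min(wh, H); ww <- min(ww, W)
          r0 <- max(1L, min(r, H - wh + 1L))
          c0 <- max(1L, min(c, W - ww + 1L))
          k <- k + 1L
          tiles[[k]] <- make_tile(r0, c0, wh, ww, k)
          if (!degenerate && k >= n_target) return(tiles)
          hit_bottom <- hit_bottom || (r0 + wh - 1L >= H)
          if (c0 + ww - 1L >= W) break
          c <- c + sample_range(stride_range[1], stride_range[2])
        }
        if (r + wh - 1L >= H) break
        r <- r + sample_range(stride_range[1], stride_range[2])
      }
      if (degenerate) return(tiles)
    }
    tiles
  })
}

#' Augment one training tile
#'
#' Composition of random-resized crop (crop side in `crop_range` with random
#' aspect ratio, then resize back to the tile side), Gaussian blur with
#' random sigma (image only), and rotation by a random angle. The mask
#' receives the identical spatial transforms with nearest-neighbour
#' interpolation and no blur; rotation fills exposed image corners by
#' reflection and mask corners with 0. Pin all three ranges to degenerate
#' identity values to recover the input exactly.
#'
#' @param tile a `training_tile`.
#' @param seed integer seed.
#' @param crop_range crop side range in pixels; default `[side/2, side]`
#'   (the full-scale 256-768 range clamped to a 512 tile).
#' @param aspect_range crop aspect-ratio range.
#' @param sigma_range Gaussian blur sigma range in pixels.
#' @param angle_range rotation angle range in degrees.
#' @return the augmented `training_tile` (`augmented = TRUE`, `source_id`
#'   set to the input's `tile_id`).
#' @export
augment <- function(tile, seed = 0L, crop_range = NULL,
                    aspect_range = c(3 / 4, 4 / 3),
                    sigma_range = c(0, 2), angle_range = c(0, 360)) {
  side <- dim(tile$image)[1]
  if (is.null(crop_range)) crop_range <- c(side %/% 2L, side)
  crop_range <- pmin(crop_range, side)
  with_seed(seed, {
    img <- tile$image
    msk <- tile$mask
    s <- stats::runif(1, crop_range[1], crop_range[2])
    ar <- stats::runif(1, aspect_range[1], aspect_range[2])
    ch <- max(1L, min(side, as.integer(round(s * sqrt(ar)))))
    cw <- max(1L, min(side, as.integer(round(s / sqrt(ar)))))
    r0 <- if (ch < side) sample.int(side - ch + 1L, 1L) else 1L
    c0 <- if (cw < side) sample.int(side - cw + 1L, 1L) else 1L
    if (ch < side || cw < side) {
      img <- bilinear_resize(img[r0:(r0 + ch - 1), c0:(c0 + cw - 1), ,
                                 drop = FALSE], side, side)
      msk <- nearest_resize(msk[r0:(r0 + ch - 1), c0:(c0 + cw - 1), ,
                                drop = FALSE], side, side)
    }
    sigma <- stats::runif(1, sigma_range[1], sigma_range[2])
    if (sigma > 1e-3) {
      img <- array(EBImage::imageData(EBImage::gblur(img, sigma = sigma)),
                   dim(img))
    }
    angle <- stats::runif(1, angle_range[1], angle_range[2])
    if (abs(angle %% 360) > 1e-9) {
      img <- rotate_about_center(img, angle, "bilinear", "reflect")
      msk <- rotate_about_center(msk, angle, "nearest", "zero")
    }
    msk <- (msk > 0.5) * 1
    out <- tile
    out$image <- img
    out$mask <- msk
    out$augmented <- TRUE
    out$source_id <- tile$tile_id
    out$tile_id <- sprintf("%s_aug%d", tile$tile_id, seed)
    out
  })
}

#' Expand a tile set with augmented copies
#'
#' Returns the originals plus `(factor - 1)` augmented copies of each, the
#' standard 5N expansion at the default factor.
#'
#' @param tiles list of `training_tile`s.
#' @param factor total expansion factor (>= 1).
#' @param seed integer seed; per-copy seeds are derived deterministically.
#' @param ... passed to [augment()].
#' @return list of `factor * length(tiles)` tiles.
#' @export
expand_dataset <- function(tiles, factor = 5L, seed = 0L, ...) {
  stopifnot(factor >= 1L)
  out <- tiles
  for (k in seq_len(factor - 1L)) {
    for (i in seq_along(tiles)) {
      s <- derive_seed(seed, sprintf("aug_%d_%d", k, i))
      out[[length(out) + 1L]] <- augment(tiles[[i]], seed = s, ...)
    }
  }
  out
}

#' Persist tiles as paired PNGs with a manifest CSV
#' @param tiles list of `training_tile`s.
#' @param dir output directory.
#' @return invisibly, the manifest data.frame.
#' @export
write_tiles <- function(tiles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(tiles, function(t) {
    png::writePNG(t$image, file.path(dir, paste0(t$tile_id, "_img.png")))
    m <- t$mask
    if (dim(m)[3] == 2L) m <- array(c(m[, , 1], m[, , 2], m[, , 2] * 0),
                                    c(dim(m)[1:2], 3L))
    else m <- m[, , 1]
    png::writePNG(m, file.path(dir, paste0(t$tile_id, "_mask.png")))
    data.frame(tile_id = t$tile_id, slide_id = t$spec$slide_id,
               origin_row = t$spec$origin_row, origin_col = t$spec$origin_col,
               window_h = t$spec$window_h, window_w = t$spec$window_w,
               augmented = t$augmented)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "tiles.csv"), row.names = FALSE)
  invisible(manifest)
}
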