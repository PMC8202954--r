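# Supervised gland/mucosa segmentation: a U-Net encoder-decoder trained on
# 512x512 (or reduced-size) tiles, applied at slide scale with the
# overlap-tile strategy (predict on padded tiles, keep each tile's center).

#' U-Net configuration
#'
#' @param input_size tile side in pixels fed to the network; must be divisible
#'   by `2^depth`. The slide-scale configuration uses 512; the reduced CPU
#'   configuration uses 128.
#' @param n_classes number of independent sigmoid output channels (1 = gland
#'   only, 2 = gland + mucosa).
#' @param depth number of pooling levels in the encoder.
#' @param base_filters filters at the first level; doubled at each level.
#' @param center side of the central crop kept when stitching overlap tiles;
#'   defaults to `input_size * 15/16` (480 for 512-tiles, 120 for 128-tiles).
#' @return a `seg_config` list.
#' @export
seg_config <- function(input_size = 128L, n_classes = 1L, depth = 3L,
                       base_filters = 8L, center = NULL) {
  input_size <- as.integer(input_size)
  if (input_size %% (2L^depth) != 0L)
    stop("input_size must be divisible by 2^depth")
  if (is.null(center)) center <- as.integer(round(input_size * 15 / 16))
  if (center > input_size || center < 1L) stop("invalid center size")
  structure(list(input_size = input_size, n_classes = as.integer(n_classes),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 center = as.integer(center)),
            class = "seg_config")
}

#' Build an untrained U-Net
#'
#' Encoder: `depth` levels of (conv3x3, ReLU) x2 + 2x2 max pool, filters
#' doubling per level; a two-conv bottleneck; decoder: nearest-neighbour
#' upsampling + conv, skip concatenation, (conv3x3, ReLU) x2; final 1x1 conv
#' with one sigmoid unit per class.
#'
#' @param config a [seg_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `unet` holding parameters and config.
#' @export
build_unet <- function(config, seed = 0L) {
  stopifnot(inherits(config, "seg_config"))
  d <- config$depth
  f <- config$base_filters * 2L^(seq_len(d) - 1L)
  fb <- config$base_filters * 2L^d
  with_seed(seed, {
    params <- list(enc = list(), bott = NULL, dec = list(), out = NULL)
    cin <- 3L
    for (i in seq_len(d)) {
      params$enc[[i]] <- list(conv1 = conv_init(3, 3, cin, f[i]),
                              conv2 = conv_init(3, 3, f[i], f[i]))
      cin <- f[i]
    }
    params$bott <- list(conv1 = conv_init(3, 3, f[d], fb),
                        conv2 = conv_init(3, 3, fb, fb))
    cab <- fb
    for (i in rev(seq_len(d))) {
      params$dec[[i]] <- list(up = conv_init(3, 3, cab, f[i]),
                              conv1 = conv_init(3, 3, 2L * f[i], f[i]),
                              conv2 = conv_init(3, 3, f[i], f[i]))
      cab <- f[i]
    }
    params$out <- conv_init(1, 1, f[1], config$n_classes)
    structure(list(params = params, config = config, trained = FALSE,
                   history = NULL),
              class = "unet")
  })
}

# Forward pass on a batch [H,W,3,N]; returns logits and (optionally) the
# cache of intermediate activations needed for backprop.
unet_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  d <- model$config$depth
  cache <- list(enc = vector("list", d), dec = vector("list", d))
  a <- x
  skips <- vector("list", d)
  for (i in seq_len(d)) {
    z1 <- conv_fwd(a, p$enc[[i]]$conv1); a1 <- relu_fwd(z1)
    z2 <- conv_fwd(a1, p$enc[[i]]$conv2); a2 <- relu_fwd(z2)
    mp <- nn_maxpool_forward(a2)
    if (keep_cache)
      cache$enc[[i]] <- list(x = a, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
                             argmax = mp$argmax)
    skips[[i]] <- a2
    a <- mp$y
  }
  zb1 <- conv_fwd(a, p$bott$conv1); ab1 <- relu_fwd(zb1)
  zb2 <- conv_fwd(ab1, p$bott$conv2); ab2 <- relu_fwd(zb2)
  if (keep_cache) cache$bott <- list(x = a, z1 = zb1, a1 = ab1, z2 = zb2)
  a <- ab2
  for (i in rev(seq_len(d))) {
    sk <- skips[[i]]
    up <- nn_resize_nearest(a, dim(sk)[1], dim(sk)[2])
    zu <- conv_fwd(up, p$dec[[i]]$up); au <- relu_fwd(zu)
    cc <- cat_channels(au, sk)
    z1 <- conv_fwd(cc, p$dec[[i]]$conv1); a1 <- relu_fwd(z1)
    z2 <- conv_fwd(a1, p$dec[[i]]$conv2); a2 <- relu_fwd(z2)
    if (keep_cache)
      cache$dec[[i]] <- list(xin = a, up = up, zu = zu, au = au, cc = cc,
                             z1 = z1, a1 = a1, z2 = z2)
    a <- a2
  }
  logits <- conv_fwd(a, p$out, pad = 0L)
  if (keep_cache) cache$pre_out <- a
  list(logits = logits, cache = if (keep_cache) cache else NULL)
}

# Backward pass; returns the gradient tree matching model$params.
unet_backward <- function(model, cache, dlogits) {
  p <- model$params
  d <- model$config$depth
  g <- list(enc = vector("list", d), bott = NULL, dec = vector("list", d),
            out = NULL)
  bo <- conv_bwd(cache$pre_out, p$out, dlogits, pad = 0L)
  g$out <- list(w = bo$dw, b = bo$db)
  da <- bo$dx
  dskips <- vector("list", d)
  for (i in seq_len(d)) { # decoder blocks, from the last applied (i=1) upward
    cd <- cache$dec[[i]]
    dz2 <- relu_bwd(cd$z2, da)
    b2 <- conv_bwd(cd$a1, p$dec[[i]]$conv2, dz2)
    dz1 <- relu_bwd(cd$z1, b2$dx)
    b1 <- conv_bwd(cd$cc, p$dec[[i]]$conv1, dz1)
    cu <- dim(cd$au)[3]
    dau <- b1$dx[, , seq_len(cu), , drop = FALSE]
    dsk <- b1$dx[, , cu + seq_len(dim(cd$cc)[3] - cu), , drop = FALSE]
    dzu <- relu_bwd(cd$zu, dau)
    bu <- conv_bwd(cd$up, p$dec[[i]]$up, dzu)
    dxin <- nn_resize_nearest_backward(bu$dx, dim(cd$xin)[1], dim(cd$xin)[2])
    g$dec[[i]] <- list(up = list(w = bu$dw, b = bu$db),
                       conv1 = list(w = b1$dw, b = b1$db),
                       conv2 = list(w = b2$dw, b = b2$db))
    dskips[[i]] <- dsk
    da <- dxin
  }
  cb <- cache$bott
  dz2 <- relu_bwd(cb$z2, da)
  b2 <- conv_bwd(cb$a1, p$bott$conv2, dz2)
  dz1 <- relu_bwd(cb$z1, b2$dx)
  b1 <- conv_bwd(cb$x, p$bott$conv1, dz1)
  g$bott <- list(conv1 = list(w = b1$dw, b = b1$db),
                 conv2 = list(w = b2$dw, b = b2$db))
  da <- b1$dx
  for (i in rev(seq_len(d))) {
    ce <- cache$enc[[i]]
    da2 <- nn_maxpool_backward(da, ce$argmax, dim(ce$a2)[1], dim(ce$a2)[2])
    da2 <- da2 + dskips[[i]]
    dz2 <- relu_bwd(ce$z2, da2)
    b2 <- conv_bwd(ce$a1, p$enc[[i]]$conv2, dz2)
    dz1 <- relu_bwd(ce$z1, b2$dx)
    b1 <- conv_bwd(ce$x, p$enc[[i]]$conv1, dz1)
    g$enc[[i]] <- list(conv1 = list(w = b1$dw, b = b1$db),
                       conv2 = list(w = b2$dw, b = b2$db))
    da <- b1$dx
  }
  g
}

# Convert model$params leaves (w/b pairs) to match adam trees transparently:
# params already ARE the tree; adam walks any nested list of arrays.

#' Train a U-Net on training tiles
#'
#' Original (unaugmented) tiles are split 80/20 into training and validation
#' at the tile level; augmented tiles join the training set only, and any
#' augmented copy of a validation tile is excluded. The loss is pixelwise
#' binary cross-entropy; history records per-epoch training loss, validation
#' Dice and validation pixel accuracy.
#'
#' @param model an untrained or previously trained [build_unet()] model.
#' @param tiles list of `training_tile` objects (see [generate_tiles()]).
#' @param split_seed seed for the 80/20 split and batch shuffling.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param val_frac validation fraction of the original tiles.
#' @param pos_weight weight of foreground pixels in the cross-entropy;
#'   values above 1 guard against collapse to the all-background optimum
#'   when glands cover a small image fraction.
#' @return the trained model with a `history` data.frame attached.
#' @export
train_seg <- function(model, tiles, split_seed = 0L, epochs = 10L, lr = 1e-3,
                      batch_size = 4L, val_frac = 0.2, pos_weight = 3) {
  stopifnot(inherits(model, "unet"))
  if (length(tiles) < 10L) stop("need at least 10 tiles")
  aug <- vapply(tiles, function(t) isTRUE(t$augmented), logical(1))
  orig_idx <- which(!aug)
  if (length(orig_idx) == 0L) stop("no original tiles to validate on")
  nval <- max(1L, round(val_frac * length(orig_idx)))
  val_idx <- with_seed(derive_seed(split_seed, "split"),
                       sample(orig_idx, nval))
  val_ids <- vapply(tiles[val_idx], function(t) t$tile_id, character(1))
  train_idx <- setdiff(seq_along(tiles), val_idx)
  src <- vapply(tiles[train_idx],
                function(t) if (is.null(t$source_id)) "" else t$source_id,
                character(1))
  train_idx <- train_idx[!(src %in% val_ids)]
  if (length(train_idx) == 0L) stop("empty training split")

  nc <- model$config$n_classes
  get_xy <- function(i) {
    t <- tiles[[i]]
    m <- t$mask
    if (length(dim(m)) == 2L) m <- array(m, c(dim(m), 1L))
    if (dim(m)[3] < nc) stop("tile mask has fewer channels than n_classes")
    list(x = t$image, y = m[, , seq_len(nc), drop = FALSE])
  }

  vx <- stack_batch(lapply(val_idx, function(i) get_xy(i)$x))
  vy <- stack_batch(lapply(val_idx, function(i) get_xy(i)$y))

  state <- adam_init(model$params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_dice = numeric(),
                     val_accuracy = numeric())
  rng_seed <- derive_seed(split_seed, "epochs")
  for (ep in seq_len(epochs)) {
    ord <- with_seed(rng_seed + ep, sample(train_idx))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    tl <- 0
    for (bi in batches) {
      xs <- stack_batch(lapply(bi, function(i) get_xy(i)$x))
      ys <- stack_batch(lapply(bi, function(i) get_xy(i)$y))
      fw <- unet_forward(model, xs, keep_cache = TRUE)
      lo <- bce_with_logits(fw$logits, ys, pos_weight = pos_weight)
      tl <- tl + lo$loss * length(bi)
      grads <- unet_backward(model, fw$cache, lo$dz)
      upd <- adam_step(model$params, grads, state, lr = lr)
      model$params <- upd$params
      state <- upd$state
    }
    vf <- unet_forward(model, vx)
    vl <- bce_with_logits(vf$logits, vy)$loss
    vp <- sigmoid(vf$logits)
    vdice <- dice(vp[, , 1, , drop = FALSE] >= 0.5,
                  vy[, , 1, , drop = FALSE] >= 0.5)
    vacc <- mean((vp >= 0.5) == (vy >= 0.5))
    hist <- rbind(hist, data.frame(epoch = ep,
                                   train_loss = tl / length(train_idx),
                                   val_loss = vl, val_dice = vdice,
                                   val_accuracy = vacc))
  }
  model$trained <- TRUE
  model$history <- hist
  model$split <- list(train = sort(train_idx), val = sort(val_idx))
  model
}

#' Predict class probabilities for one tile batch
#' @param model trained `unet`.
#' @param x batch array `[H, W, 3, N]`.
#' @return probability array `[H, W, n_classes, N]`.
#' @export
predict_tiles <- function(model, x) {
  sigmoid(unet_forward(model, x)$logits)
}

# Mirror (reflect, no edge duplication) index into 1..n for arbitrary i.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  as.integer(ifelse(j < n, j + 1L, p - j + 1L))
}

# Reflect-pad an [H,W,C] array (or matrix) on all four sides.
pad_reflect <- function(img, top, bottom, left, right) {
  d <- dim(img)
  is_mat <- length(d) == 2L
  if (is_mat) img <- array(img, c(d, 1L))
  d <- dim(img)
  ri <- reflect_index(seq(1L - top, d[1] + bottom), d[1])
  ci <- reflect_index(seq(1L - left, d[2] + right), d[2])
  out <- img[ri, ci, , drop = FALSE]
  if (is_mat) out <- out[, , 1]
  out
}

#' Slide-scale prediction with the overlap-tile strategy
#'
#' The image is reflect-padded so that `tile`-sized windows on a `center`
#' stride grid cover it, the model is applied per window, and only the
#' central `center x center` area of each output is kept, so every output
#' pixel is predicted exactly once with full spatial context.
#'
#' @param model a trained `unet`, or a plain function `image -> [H,W,k]`
#'   array (used as a per-pixel surrogate in equivalence tests).
#' @param image RGB array `[H, W, 3]`, values in `[0, 1]`.
#' @param tile,center window and kept-center sides; default from the model
#'   config (512/480 at full scale, 128/120 reduced).
#' @return a `probability_mask`: list with `prob` array `[H, W, k]` and the
#'   stitching parameters.
#' @export
predict_slide <- function(model, image, tile = NULL, center = NULL) {
  if (inherits(model, "unet")) {
    if (is.null(tile)) tile <- model$config$input_size
    if (is.null(center)) center <- model$config$center
    fun <- function(im) {
      r <- predict_tiles(model, as_batch(im))
      array(r, dim(r)[1:3])
    }
  } else {
    stopifnot(is.function(model))
    if (is.null(tile) || is.null(center))
      stop("tile and center must be given for a surrogate model")
    fun <- function(im) {
      r <- model(im)
      if (length(dim(r)) == 2L) r <- array(r, c(dim(r), 1L))
      r
    }
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  m <- (tile - center) %/% 2L
  nr <- ceiling(H / center); ncl <- ceiling(W / center)
  padded <- pad_reflect(image, m, nr * center - H + (tile - center - m),
                        m, ncl * center - W + (tile - center - m))
  nclasses <- dim(fun(array(padded[seq_len(tile), seq_len(tile), ],
                            c(tile, tile, 3))))[3]
  out <- array(0, c(nr * center, ncl * center, nclasses))
  for (i in seq_len(nr)) {
    for (j in seq_len(ncl)) {
      r0 <- (i - 1L) * center; c0 <- (j - 1L) * center
      win <- array(padded[r0 + seq_len(tile), c0 + seq_len(tile), ],
                   c(tile, tile, 3))
      pr <- fun(win)
      out[r0 + seq_len(center), c0 + seq_len(center), ] <-
        pr[m + seq_len(center), m + seq_len(center), , drop = FALSE]
    }
  }
  structure(list(prob = out[seq_len(H), seq_len(W), , drop = FALSE],
                 tile = tile, center = center, n_tiles = nr * ncl),
            class = "probability_mask")
}

#' Dice coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b logical (or 0/1) arrays of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("dice: shape mismatch")
  a <- as.logical(a); b <- as.logical(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Object-level F1 by greedy IoU matching
#'
#' Predicted and ground-truth instances are matched one-to-one in order of
#' decreasing IoU; pairs with IoU at or above `iou_threshold` count as true
#' positives (the GlaS-style criterion).
#'
#' @param pred,truth integer label matrices (0 = background).
#' @param iou_threshold minimum IoU for a match.
#' @return list with `precision`, `recall`, `f1`, `n_pred`, `n_truth`.
#' @export
object_f1 <- function(pred, truth, iou_threshold = 0.5) {
  if (!identical(dim(pred), dim(truth))) stop("object_f1: shape mismatch")
  np <- max(pred); nt <- max(truth)
  if (np == 0 || nt == 0) {
    tp <- 0L
  } else {
    both <- pred > 0 & truth > 0
    inter <- table(factor(pred[both], levels = seq_len(np)),
                   factor(truth[both], levels = seq_len(nt)))
    ap <- tabulate(pred[pred > 0], np)
    at <- tabulate(truth[truth > 0], nt)
    inter <- unclass(inter)
    iou <- inter / (outer(ap, at, "+") - inter)
    ord <- order(iou, decreasing = TRUE)
    usedp <- logical(np); usedt <- logical(nt); tp <- 0L
    for (k in ord) {
      if (iou[k] < iou_threshold) break
      i <- (k - 1) %% np + 1; j <- (k - 1) %/% np + 1
      if (!usedp[i] && !usedt[j]) {
        usedp[i] <- TRUE; usedt[j] <- TRUE; tp <- tp + 1L
      }
    }
  }
  precision <- if (np > 0) tp / np else 0
  recall <- if (nt > 0) tp / nt else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_pred = np, n_truth = nt)
}
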