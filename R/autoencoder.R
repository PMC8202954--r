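# Unsupervised latent representation of crypts: a dual-stream convolutional
# autoencoder over the central/peripheral patch stacks. Each stream encodes
# its 36-channel sub-stack with four stride-2 convolutions (filters
# 96, 64, 32, 24), the 2x2x24 bottlenecks are flattened and concatenated as
# the latent code, and mirrored decoders (24, 32, 64, 96) reconstruct the
# input under a pixelwise binary cross-entropy loss.

#' Autoencoder configuration
#'
#' @param encoder_filters filters of the four stride-2 encoder stages.
#' @param dual_stream if `TRUE` (default) the central and peripheral
#'   sub-stacks are encoded by two parallel branches whose bottlenecks are
#'   concatenated; if `FALSE` a single branch takes all 72 channels.
#' @param input_size patch side (24).
#' @param in_channels total stack channels (72 = 3 RGB x 24 patches).
#' @return an `ae_config` list; the decoder schedule is always the reverse
#'   of the encoder schedule.
#' @export
ae_config <- function(encoder_filters = c(96L, 64L, 32L, 24L),
                      dual_stream = TRUE, input_size = 24L,
                      in_channels = 72L) {
  if (length(encoder_filters) != 4L) stop("need 4 encoder stages")
  structure(list(encoder_filters = as.integer(encoder_filters),
                 decoder_filters = rev(as.integer(encoder_filters)),
                 n_downsamples = 4L, dual_stream = isTRUE(dual_stream),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels)),
            class = "ae_config")
}

# Spatial sizes along the encoder (ceil halving): 24, 12, 6, 3, 2.
ae_sizes <- function(input_size) {
  s <- input_size
  out <- s
  for (i in 1:4) { s <- ceiling(s / 2); out <- c(out, s) }
  as.integer(out)
}

#' Build an untrained convolutional autoencoder
#'
#' @param config an [ae_config()]; a decoder schedule that is not the
#'   reverse of the encoder schedule is rejected by construction.
#' @param seed integer seed for weight initialization.
#' @return an object of class `crypt_ae`.
#' @export
build_autoencoder <- function(config, seed = 0L) {
  stopifnot(inherits(config, "ae_config"))
  if (!identical(config$decoder_filters, rev(config$encoder_filters)))
    stop("decoder filter schedule must be the reverse of the encoder's")
  nb <- if (config$dual_stream) 2L else 1L
  cb <- config$in_channels %/% nb
  ef <- config$encoder_filters; df <- config$decoder_filters
  with_seed(seed, {
    branches <- lapply(seq_len(nb), function(b) {
      cin <- cb
      enc <- list()
      for (j in 1:4) { enc[[j]] <- conv_init(3, 3, cin, ef[j]); cin <- ef[j] }
      dec <- list()
      for (j in 1:4) { dec[[j]] <- conv_init(3, 3, cin, df[j]); cin <- df[j] }
      list(enc = enc, dec = dec, out = conv_init(3, 3, cin, cb))
    })
    structure(list(params = branches, config = config, trained = FALSE,
                   history = NULL, branch_channels = cb),
              class = "crypt_ae")
  })
}

# Forward one branch on [S,S,cb,N]; returns logits, bottleneck, cache.
ae_branch_forward <- function(bp, x, keep_cache = FALSE) {
  sizes <- ae_sizes(dim(x)[1])
  cache <- list(enc = vector("list", 4), dec = vector("list", 4))
  a <- x
  for (j in 1:4) {
    z <- conv_fwd(a, bp$enc[[j]], stride = 2L, pad = 1L)
    if (keep_cache) cache$enc[[j]] <- list(x = a, z = z)
    a <- relu_fwd(z)
  }
  bottleneck <- a
  for (j in 1:4) {
    up <- nn_resize_nearest(a, sizes[5 - j], sizes[5 - j])
    z <- conv_fwd(up, bp$dec[[j]], stride = 1L, pad = 1L)
    if (keep_cache) cache$dec[[j]] <- list(xin = a, up = up, z = z)
    a <- relu_fwd(z)
  }
  logits <- conv_fwd(a, bp$out, stride = 1L, pad = 1L)
  if (keep_cache) cache$pre_out <- a
  list(logits = logits, bottleneck = bottleneck,
       cache = if (keep_cache) cache else NULL)
}

ae_branch_backward <- function(bp, cache, dlogits) {
  g <- list(enc = vector("list", 4), dec = vector("list", 4), out = NULL)
  bo <- conv_bwd(cache$pre_out, bp$out, dlogits, stride = 1L, pad = 1L)
  g$out <- list(w = bo$dw, b = bo$db)
  da <- bo$dx
  for (j in 4:1) {
    cd <- cache$dec[[j]]
    dz <- relu_bwd(cd$z, da)
    bb <- conv_bwd(cd$up, bp$dec[[j]], dz, stride = 1L, pad = 1L)
    da <- nn_resize_nearest_backward(bb$dx, dim(cd$xin)[1], dim(cd$xin)[2])
    g$dec[[j]] <- list(w = bb$dw, b = bb$db)
  }
  for (j in 4:1) {
    ce <- cache$enc[[j]]
    dz <- relu_bwd(ce$z, da)
    bb <- conv_bwd(ce$x, bp$enc[[j]], dz, stride = 2L, pad = 1L)
    da <- bb$dx
    g$enc[[j]] <- list(w = bb$dw, b = bb$db)
  }
  g
}

# Split a stack batch [S,S,72,N] into per-branch inputs.
ae_branch_inputs <- function(model, x) {
  if (!model$config$dual_stream) return(list(x))
  cb <- model$branch_channels
  list(x[, , seq_len(cb), , drop = FALSE],
       x[, , cb + seq_len(cb), , drop = FALSE])
}

#' Train the autoencoder on patch stacks
#'
#' Pixel/channel-wise binary cross-entropy of the sigmoid reconstruction
#' against the input stack (RGB already in `[0, 1]`), Adam optimizer.
#'
#' @param model a [build_autoencoder()] model.
#' @param stacks list of `patch_stack`s (at least 20).
#' @param epochs training epochs.
#' @param seed shuffling seed.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @return the trained model with `history` (per-epoch mean loss).
#' @export
train_ae <- function(model, stacks, epochs = 10L, seed = 0L, lr = 1e-3,
                     batch_size = 8L) {
  stopifnot(inherits(model, "crypt_ae"))
  if (length(stacks) < 20L) stop("need at least 20 stacks")
  state <- adam_init(model$params)
  losses <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, paste0("ep", ep)),
                     sample(seq_along(stacks)))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    tot <- 0
    for (bi in batches) {
      x <- stack_batch(lapply(stacks[bi], function(s) s$tensor))
      xs <- ae_branch_inputs(model, x)
      grads <- vector("list", length(xs))
      loss <- 0
      for (b in seq_along(xs)) {
        fw <- ae_branch_forward(model$params[[b]], xs[[b]], keep_cache = TRUE)
        lo <- bce_with_logits(fw$logits, xs[[b]])
        loss <- loss + lo$loss
        grads[[b]] <- ae_branch_backward(model$params[[b]], fw$cache, lo$dz)
      }
      tot <- tot + loss / length(xs) * length(bi)
      upd <- adam_step(model$params, grads, state, lr = lr)
      model$params <- upd$params
      state <- upd$state
    }
    losses <- c(losses, tot / length(stacks))
  }
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_len(epochs), loss = losses)
  model
}

#' Reconstruct patch stacks (sigmoid output)
#' @param model a trained `crypt_ae`.
#' @param stack one `patch_stack` (or a bare tensor).
#' @return reconstruction array with the input's shape, values in `(0, 1)`.
#' @export
reconstruct <- function(model, stack) {
  x <- if (inherits(stack, "patch_stack")) stack$tensor else stack
  xs <- ae_branch_inputs(model, as_batch(x))
  rec <- lapply(seq_along(xs), function(b)
    sigmoid(ae_branch_forward(model$params[[b]], xs[[b]])$logits))
  out <- if (length(rec) == 1L) rec[[1]] else cat_channels(rec[[1]], rec[[2]])
  array(out, dim(x))
}

#' Mean reconstruction BCE of a model on a stack set
#' @param model a `crypt_ae` (trained or not).
#' @param stacks list of `patch_stack`s.
#' @return scalar mean binary cross-entropy.
#' @export
reconstruction_loss <- function(model, stacks) {
  x <- stack_batch(lapply(stacks, function(s) s$tensor))
  xs <- ae_branch_inputs(model, x)
  mean(vapply(seq_along(xs), function(b) {
    fw <- ae_branch_forward(model$params[[b]], xs[[b]])
    bce_with_logits(fw$logits, xs[[b]])$loss
  }, numeric(1)))
}

#' Encode patch stacks into latent codes
#'
#' Deterministic bottleneck activations, flattened (96 dims per branch at
#' the default configuration) and concatenated across branches; stack
#' metadata (crypt label, slide, group) is carried through.
#'
#' @param model a trained `crypt_ae`.
#' @param stacks list of `patch_stack`s.
#' @return a `latent_codes` object: list with `codes` matrix (N x D) and
#'   `meta` data.frame (crypt_label, slide_id, animal_id, group).
#' @export
encode <- function(model, stacks) {
  stopifnot(inherits(model, "crypt_ae"))
  if (!isTRUE(model$trained)) stop("model is not trained")
  x <- stack_batch(lapply(stacks, function(s) s$tensor))
  xs <- ae_branch_inputs(model, x)
  mats <- lapply(seq_along(xs), function(b) {
    bt <- ae_branch_forward(model$params[[b]], xs[[b]])$bottleneck
    n <- dim(bt)[4]
    t(matrix(bt, ncol = n))
  })
  codes <- do.call(cbind, mats)
  meta <- data.frame(
    crypt_label = vapply(stacks, function(s) as.integer(s$label), integer(1)),
    slide_id = vapply(stacks, function(s)
      if (is.null(s$slide_id)) NA_character_ else s$slide_id, character(1)),
    animal_id = vapply(stacks, function(s)
      if (is.null(s$animal_id)) NA_character_ else s$animal_id, character(1)),
    group = vapply(stacks, function(s)
      if (is.null(s$group)) NA_character_ else s$group, character(1)),
    stringsAsFactors = FALSE)
  structure(list(codes = codes, meta = meta), class = "latent_codes")
}

#' 2D t-SNE embedding of latent codes
#'
#' Exact (non-approximate) t-SNE with perplexity calibration by binary
#' search, early exaggeration, momentum gradient descent and PCA
#' initialization; deterministic for a fixed seed.
#'
#' @param codes a `latent_codes` object or a numeric matrix (rows = crypts).
#' @param perplexity t-SNE perplexity; requires at least `3 * perplexity`
#'   points.
#' @param seed integer seed.
#' @param max_iter gradient-descent iterations.
#' @return an `embedding_map`: data.frame with `x`, `y` and any metadata
#'   columns of the input.
#' @export
embed_tsne <- function(codes, perplexity = 30, seed = 0L, max_iter = 500L) {
  meta <- NULL
  if (inherits(codes, "latent_codes")) {
    meta <- codes$meta
    codes <- codes$codes
  }
  if (nrow(codes) < 3 * perplexity)
    stop("need at least 3 * perplexity points")
  y <- tsne_exact(codes, perplexity = perplexity, seed = seed,
                  max_iter = max_iter)
  out <- data.frame(x = y[, 1], y = y[, 2])
  if (!is.null(meta)) out <- cbind(out, meta)
  class(out) <- c("embedding_map", class(out))
  out
}

#' Post-hoc k-means zoning of latent codes
#'
#' Exploratory grouping of the latent space into k zones. The zones are a
#' post-hoc reading aid, not an algorithmic output of the embedding.
#'
#' @param codes a `latent_codes` object or matrix.
#' @param k number of zones.
#' @param seed integer seed.
#' @return integer vector of zone assignments.
#' @export
latent_zones <- function(codes, k = 4L, seed = 0L) {
  m <- if (inherits(codes, "latent_codes")) codes$codes else codes
  with_seed(seed, stats::kmeans(m, centers = k, nstart = 5)$cluster)
}

#' Export latent codes and embedding as CSV
#' @param codes a `latent_codes` object.
#' @param emb an `embedding_map` (optional).
#' @param dir output directory.
#' @return invisibly `NULL`.
#' @export
write_embedding <- function(codes, emb = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- cbind(codes$meta, as.data.frame(codes$codes))
  utils::write.csv(df, file.path(dir, "latent_codes.csv"), row.names = FALSE)
  if (!is.null(emb))
    utils::write.csv(as.data.frame(emb), file.path(dir, "embedding.csv"),
                     row.names = FALSE)
  invisible(NULL)
}
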