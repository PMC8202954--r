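# Shared fixtures, built once per test run and cached. All seeds are fixed
# so every test sees identical data.

.fx_cache <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# One noise-free slide per archetype (exact ground truth).
fx_clean_slide <- function(group = "normal") {
  fx_get(paste0("clean_", group), function() {
    p <- archetype_params(group)
    p$noise_sd <- 0
    render_slide(p, 384, 384, seed = 42, slide_id = paste0("clean_", group))
  })
}

# The 3 x 6 animals x 2 slides cohort used for the treatment-effect checks.
fx_cohort <- function() {
  fx_get("cohort", function()
    render_cohort(n_animals_per_group = 6L, slides_per_animal = 2L,
                  seed = 11, height = 384L, width = 384L))
}

fx_feature_table <- function() {
  fx_get("feature_table", function() featurize_cohort(fx_cohort()))
}

# 150 patch stacks per archetype for the latent-space checks.
fx_stacks <- function(per_group = 150L) {
  fx_get("stacks", function() {
    groups <- c("normal", "dss", "treated")
    stacks <- list()
    for (g in groups) {
      n <- 0L; k <- 0L
      while (n < per_group && k < 200L) {
        k <- k + 1L
        s <- render_slide(archetype_params(g), 384, 384,
                          seed = 1000L * match(g, groups) + k,
                          slide_id = paste0(g, "_", k))
        for (x in crypt_stacks(s, seed = k, min_area = 30L)) {
          if (n < per_group) {
            n <- n + 1L
            stacks[[length(stacks) + 1L]] <- x
          }
        }
      }
    }
    stacks
  })
}

# Trained autoencoder + codes on the stack fixture.
fx_ae_fit <- function() {
  fx_get("ae_fit", function() {
    stacks <- fx_stacks()
    ae <- build_autoencoder(ae_config(), seed = 0)
    untrained_loss <- reconstruction_loss(ae, stacks)
    ae <- train_ae(ae, stacks, epochs = 6L, seed = 1)
    list(model = ae, codes = encode(ae, stacks),
         untrained_loss = untrained_loss)
  })
}

# Reduced U-Net trained on fixture tiles, plus a held-out slide.
fx_seg_fit <- function() {
  fx_get("seg_fit", function() {
    groups <- c("normal", "dss", "treated")
    slides <- list()
    for (g in groups) for (k in 1:2)
      slides[[paste0(g, k)]] <- render_slide(
        archetype_params(g), 384, 384,
        seed = k * 10 + match(g, groups), slide_id = paste0(g, k))
    held <- render_slide(archetype_params("treated"), 384, 384, seed = 99,
                         slide_id = "held")
    tiles <- list()
    for (i in seq_along(slides))
      tiles <- c(tiles, generate_tiles(slides[[i]], seed = i, n_target = 8L,
                                       win_range = c(96L, 192L),
                                       stride_range = c(64L, 96L),
                                       out_size = 128L, n_classes = 1L))
    model <- build_unet(seg_config(128L, n_classes = 1L, depth = 3L,
                                   base_filters = 8L), seed = 0)
    model <- train_seg(model, tiles, split_seed = 1, epochs = 10L, lr = 1e-3,
                       batch_size = 4L)
    list(model = model, held = held, tiles = tiles)
  })
}

# Brute-force masked GLCM by pair enumeration (independent oracle).
brute_glcm <- function(gray, mask, G, offsets) {
  P <- matrix(0, G, G)
  H <- nrow(gray); W <- ncol(gray)
  for (o in seq_len(nrow(offsets))) for (i in seq_len(H)) for (j in seq_len(W)) {
    ni <- i + offsets[o, 1]; nj <- j + offsets[o, 2]
    if (ni >= 1 && ni <= H && nj >= 1 && nj <= W && mask[i, j] && mask[ni, nj])
      P[gray[i, j] + 1, gray[ni, nj] + 1] <- P[gray[i, j] + 1, gray[ni, nj] + 1] + 1
  }
  P <- P + t(P)
  P / sum(P)
}

# Mean fraction of same-group labels among the k nearest neighbours.
knn_purity <- function(X, g, k = 10L) {
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  mean(vapply(seq_len(nrow(D)), function(i)
    mean(g[order(D[i, ])[seq_len(k)]] == g[i]), numeric(1)))
}

# Build a crypt_instance directly from a centroid/orientation (for
# morphometrics unit tests).
synthetic_instance <- function(label, centroid, orientation, area = 1L) {
  structure(list(label = as.integer(label), mask = matrix(TRUE, 1, 1),
                 bbox = c(1L, 1L, 1L, 1L), centroid = centroid,
                 area = as.integer(area), orientation = orientation),
            class = "crypt_instance")
}
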