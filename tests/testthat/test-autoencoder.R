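# Dual-stream convolutional autoencoder: architecture contracts, training
# behaviour and the deterministic latent encoding, plus the exact t-SNE.

test_that("configuration enforces the mirrored filter schedule", {
  cfg <- ae_config()
  expect_identical(cfg$decoder_filters, rev(cfg$encoder_filters))
  expect_equal(cfg$encoder_filters, c(96L, 64L, 32L, 24L))
  bad <- cfg
  bad$decoder_filters <- c(1L, 2L, 3L, 4L)
  expect_error(build_autoencoder(bad), "reverse")
  expect_error(ae_config(c(8L, 4L)), "4 encoder stages")
})

test_that("reconstruction shape, range and bottleneck arithmetic", {
  cfg <- ae_config(c(12L, 10L, 8L, 6L))  # small but same geometry
  m <- build_autoencoder(cfg, seed = 1)
  x <- array(runif(24 * 24 * 72), c(24, 24, 72))
  rec <- reconstruct(m, x)
  expect_equal(dim(rec), dim(x))
  expect_true(all(rec > 0 & rec < 1))
  # spatial sizes halve with ceiling: 24 -> 12 -> 6 -> 3 -> 2
  expect_equal(cryptflow:::ae_sizes(24L), c(24L, 12L, 6L, 3L, 2L))
  # flattened bottleneck: 2 x 2 x last_filters per branch
  m$trained <- TRUE
  st <- list(structure(list(tensor = x, label = 1L, seed = 0L),
                       class = "patch_stack"))
  codes <- encode(m, st)
  expect_equal(ncol(codes$codes), 2L * 2L * 2L * 6L)  # two branches
  # full-scale schedule: 2 x 2 x 24 = 96 per branch
  mp <- build_autoencoder(ae_config(), seed = 1)
  mp$trained <- TRUE
  expect_equal(ncol(encode(mp, st)$codes), 192L)
})

test_that("encoding is deterministic, metadata-preserving and decoder-independent", {
  cfg <- ae_config(c(8L, 6L, 5L, 4L))
  m <- build_autoencoder(cfg, seed = 2)
  m$trained <- TRUE
  set.seed(5)
  mk <- function(g) structure(list(tensor = array(runif(24 * 24 * 72),
                                                  c(24, 24, 72)),
                                   label = 1L, seed = 0L, group = g),
                              class = "patch_stack")
  stacks <- list(mk("a"), mk("b"), mk("a"))
  stacks[[3]]$tensor <- stacks[[1]]$tensor  # identical input
  co <- encode(m, stacks)
  expect_equal(nrow(co$codes), 3L)
  expect_equal(co$codes[1, ], co$codes[3, ])
  expect_equal(co$meta$group, c("a", "b", "a"))
  # perturbing decoder weights must not change the encoding
  m2 <- m
  m2$params[[1]]$dec[[2]]$w <- m2$params[[1]]$dec[[2]]$w + 1
  m2$params[[2]]$out$w <- m2$params[[2]]$out$w * 0
  expect_equal(encode(m2, stacks)$codes, co$codes)
  m$trained <- FALSE
  expect_error(encode(m, stacks), "not trained")
})

test_that("training reduces loss; constant stacks converge to the constant", {
  set.seed(6)
  mk <- function() structure(list(tensor = array(runif(24 * 24 * 72),
                                                 c(24, 24, 72)),
                                  label = 1L, seed = 0L),
                             class = "patch_stack")
  stacks <- replicate(24, mk(), simplify = FALSE)
  cfg <- ae_config(c(8L, 6L, 5L, 4L))
  m0 <- build_autoencoder(cfg, seed = 3)
  m <- train_ae(m0, stacks, epochs = 5L, seed = 1)
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
  expect_error(train_ae(m0, stacks[1:5]), "at least 20")
  # constant-colour stacks: BCE is minimized at p = target
  const <- lapply(1:24, function(i)
    structure(list(tensor = array(0.25, c(24, 24, 72)), label = i, seed = 0L),
              class = "patch_stack"))
  mc <- train_ae(build_autoencoder(cfg, seed = 4), const, epochs = 30L,
                 seed = 2, lr = 3e-3)
  rec <- reconstruct(mc, const[[1]])
  expect_lt(mean(abs(rec - 0.25)), 0.05)
  # deterministic retraining reproduces the loss trace
  m2 <- train_ae(m0, stacks, epochs = 5L, seed = 1)
  expect_equal(m$history$loss, m2$history$loss)
})

test_that("trained model beats its untrained initialization on held-out stacks", {
  fit <- fx_ae_fit()
  stacks <- fx_stacks()
  expect_lt(reconstruction_loss(fit$model, stacks), fit$untrained_loss)
})

test_that("t-SNE returns one deterministic 2D point per input", {
  set.seed(8)
  X <- rbind(matrix(rnorm(60 * 5), 60, 5),
             matrix(rnorm(60 * 5, mean = 6), 60, 5))
  co <- structure(list(codes = X,
                       meta = data.frame(crypt_label = seq_len(120),
                                         slide_id = "s", animal_id = "a",
                                         group = rep(c("g1", "g2"),
                                                     each = 60))),
                  class = "latent_codes")
  emb <- embed_tsne(co, perplexity = 10, seed = 1, max_iter = 300L)
  expect_equal(nrow(emb), 120L)
  expect_true(all(c("x", "y", "group") %in% names(emb)))
  emb2 <- embed_tsne(co, perplexity = 10, seed = 1, max_iter = 300L)
  expect_equal(emb$x, emb2$x)
  # two well-separated blobs stay separated in the embedding
  expect_gt(knn_purity(cbind(emb$x, emb$y), emb$group, k = 10L), 0.9)
  expect_error(embed_tsne(co, perplexity = 50), "perplexity")
})
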