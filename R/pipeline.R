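# Orchestration of the full workflow: fixtures -> tiles -> segmentation
# training -> slide prediction -> crypt instances & patch stacks ->
# autoencoder embedding -> features -> cohort statistics, with per-stage
# seeds, a content-hash manifest for skip-on-rerun, and a run log.

#' Demo-scale run configuration
#'
#' All stochastic stages have explicit seeds derived from one master seed;
#' the configuration round-trips losslessly through JSON.
#'
#' @param out_dir run directory.
#' @param seed master seed.
#' @param n_animals,slides_per_animal,slide_size fixture cohort shape.
#' @param seg_epochs,ae_epochs training lengths.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 0L, n_animals = 2L,
                       slides_per_animal = 1L, slide_size = 256L,
                       seg_epochs = 4L, ae_epochs = 4L) {
  structure(list(
    out_dir = out_dir,
    seeds = list(fixtures = derive_seed(seed, "fixtures"),
                 tiling = derive_seed(seed, "tiling"),
                 training = derive_seed(seed, "training"),
                 ae = derive_seed(seed, "ae"),
                 tsne = derive_seed(seed, "tsne")),
    fixtures = list(n_animals = n_animals,
                    slides_per_animal = slides_per_animal,
                    height = slide_size, width = slide_size,
                    jitter_sd = 0.08),
    tiling = list(n_target = 8L, win_range = c(96L, 192L),
                  stride_range = c(64L, 96L), out_size = 128L,
                  n_classes = 2L, augment_factor = 2L),
    seg = list(input_size = 128L, n_classes = 2L, depth = 3L,
               base_filters = 8L, epochs = seg_epochs, lr = 1e-3,
               batch_size = 4L, threshold = 0.5, min_area = 30L),
    ae = list(encoder_filters = c(32L, 24L, 16L, 12L), dual_stream = TRUE,
              epochs = ae_epochs, lr = 1e-3, batch_size = 8L),
    tsne = list(perplexity = 12, max_iter = 250L),
    glcm = list(levels = 32L, distances = 1L, angles = c(0, 45, 90, 135)),
    stats = list(features = c("gland_mucosa_ratio", "glcm_contrast",
                              "glcm_dissimilarity", "glcm_homogeneity",
                              "glcm_ASM", "entropy_masked", "entropy_slide",
                              "nn_distance", "n_crypts"))),
    class = "run_config")
}

run_log <- function(config, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 paste0(..., collapse = ""))
  cat(msg, "\n", file = file.path(config$out_dir, "run_log.txt"),
      append = TRUE)
  message(msg)
}

# Hash an R object by serializing it to JSON and md5-summing the file.
hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the full workflow
#'
#' Executes all stages in order. Each stage's inputs (its configuration,
#' seeds, and the md5 sums of the upstream stage's artifact) are hashed into
#' a manifest; a stage whose hash matches and whose artifacts still exist
#' unchanged is skipped, so a second identical run performs no
#' recomputation and deleting one stage's outputs reruns only that stage
#' and its dependents.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  mf_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(mf_path))
    jsonlite::read_json(mf_path, simplifyVector = TRUE) else list()
  cache <- file.path(out, "cache")
  dir.create(cache, showWarnings = FALSE)

  stage <- function(name, dep_hashes, runner) {
    h <- hash_obj(list(cfg = config[[name]], seeds = config$seeds,
                       deps = dep_hashes))
    rec <- manifest[[name]]
    rds <- file.path(cache, paste0(name, ".rds"))
    ok <- !is.null(rec) && identical(rec$hash, h) &&
      all(file.exists(rec$files)) &&
      identical(unname(tools::md5sum(rec$files)), unname(unlist(rec$md5)))
    if (ok) {
      run_log(config, "stage ", name, ": up to date, skipped")
      return(list(obj = readRDS(rds), md5 = rec$md5))
    }
    run_log(config, "stage ", name, ": running")
    res <- runner()
    saveRDS(res$obj, rds)
    files <- c(rds, res$files)
    rec <- list(hash = h, files = files, md5 = unname(tools::md5sum(files)))
    manifest[[name]] <<- rec
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE), mf_path)
    list(obj = res$obj, md5 = rec$md5)
  }

  fx <- stage("fixtures", NULL, function() {
    slides <- render_cohort(config$fixtures$n_animals,
                            config$fixtures$slides_per_animal,
                            seed = config$seeds$fixtures,
                            height = config$fixtures$height,
                            width = config$fixtures$width,
                            jitter_sd = config$fixtures$jitter_sd)
    mfst <- write_fixtures(slides, file.path(out, "fixtures"))
    list(obj = slides, files = file.path(out, "fixtures", "slides.csv"),
         manifest = mfst)
  })
  slides <- fx$obj

  tl <- stage("tiling", fx$md5, function() {
    tc <- config$tiling
    tiles <- list()
    for (s in slides) {
      tt <- generate_tiles(s, seed = derive_seed(config$seeds$tiling,
                                                 s$metadata$slide_id),
                           n_target = tc$n_target, win_range = tc$win_range,
                           stride_range = tc$stride_range,
                           out_size = tc$out_size, n_classes = tc$n_classes)
      tiles <- c(tiles, tt)
    }
    tiles <- expand_dataset(tiles, factor = tc$augment_factor,
                            seed = config$seeds$tiling)
    mfst <- write_tiles(tiles, file.path(out, "tiles"))
    list(obj = tiles, files = file.path(out, "tiles", "tiles.csv"))
  })

  sg <- stage("seg", tl$md5, function() {
    sc <- config$seg
    cfg <- seg_config(sc$input_size, sc$n_classes, sc$depth, sc$base_filters)
    model <- build_unet(cfg, seed = config$seeds$training)
    model <- train_seg(model, tl$obj, split_seed = config$seeds$training,
                       epochs = sc$epochs, lr = sc$lr,
                       batch_size = sc$batch_size)
    dir.create(file.path(out, "model"), showWarnings = FALSE)
    hfile <- file.path(out, "model", "history.csv")
    utils::write.csv(model$history, hfile, row.names = FALSE)
    writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE),
               file.path(out, "model", "config.json"))
    list(obj = model, files = c(hfile, file.path(out, "model", "config.json")))
  })

  pr <- stage("predict", sg$md5, function() {
    dir.create(file.path(out, "masks"), showWarnings = FALSE)
    masks <- lapply(slides, function(s) predict_slide(sg$obj, s$image))
    files <- character(0)
    for (k in seq_along(slides)) {
      f <- file.path(out, "masks",
                     paste0(slides[[k]]$metadata$slide_id, "_prob.tiff"))
      tiff::writeTIFF(masks[[k]]$prob[, , 1], f, bits.per.sample = 32L)
      files <- c(files, f)
    }
    list(obj = masks, files = files)
  })

  cr <- stage("crypts", pr$md5, function() {
    sc <- config$seg
    insts <- list(); stacks <- list()
    dir.create(file.path(out, "crypts"), showWarnings = FALSE)
    for (k in seq_along(slides)) {
      s <- slides[[k]]
      inst <- extract_instances(pr$obj[[k]], threshold = sc$threshold,
                                min_area = sc$min_area)
      write_instances(inst, file.path(out, "crypts"), s$metadata$slide_id)
      insts[[k]] <- inst
      st <- lapply(inst, function(ins) {
        ps <- sample_patches(ins, s$image,
                             seed = derive_seed(config$seeds$ae,
                                                paste0(s$metadata$slide_id,
                                                       ins$label)))
        ps$slide_id <- s$metadata$slide_id
        ps$animal_id <- s$metadata$animal_id
        ps$group <- s$metadata$group
        ps
      })
      stacks <- c(stacks, st)
    }
    list(obj = list(instances = insts, stacks = stacks),
         files = list.files(file.path(out, "crypts"), full.names = TRUE))
  })

  em <- stage("embed", cr$md5, function() {
    ac <- config$ae
    if (length(cr$obj$stacks) < 20L) {
      run_log(config, "embed: fewer than 20 crypts segmented; skipping")
      dir.create(file.path(out, "embedding"), showWarnings = FALSE)
      f <- file.path(out, "embedding", "latent_codes.csv")
      utils::write.csv(data.frame(), f, row.names = FALSE)
      return(list(obj = NULL, files = f))
    }
    cfg <- ae_config(ac$encoder_filters, dual_stream = ac$dual_stream)
    model <- build_autoencoder(cfg, seed = config$seeds$ae)
    model <- train_ae(model, cr$obj$stacks, epochs = ac$epochs,
                      seed = config$seeds$ae, lr = ac$lr,
                      batch_size = ac$batch_size)
    codes <- encode(model, cr$obj$stacks)
    emb <- NULL
    if (nrow(codes$codes) >= 3 * config$tsne$perplexity)
      emb <- embed_tsne(codes, perplexity = config$tsne$perplexity,
                        seed = config$seeds$tsne,
                        max_iter = config$tsne$max_iter)
    write_embedding(codes, emb, file.path(out, "embedding"))
    if (!is.null(emb)) {
      grDevices::png(file.path(out, "embedding", "tsne.png"),
                     width = 800, height = 700)
      grp <- factor(emb$group)
      graphics::plot(emb$x, emb$y, col = as.integer(grp), pch = 19,
                     xlab = "t-SNE 1", ylab = "t-SNE 2",
                     main = "Latent crypt morphology map")
      graphics::legend("topright", legend = levels(grp),
                       col = seq_along(levels(grp)), pch = 19)
      grDevices::dev.off()
    }
    list(obj = list(model_history = model$history, codes = codes, emb = emb),
         files = file.path(out, "embedding", "latent_codes.csv"))
  })

  ft <- stage("features", cr$md5, function() {
    tab <- featurize_cohort(slides, instances_list = cr$obj$instances,
                            glcm_levels = config$glcm$levels,
                            glcm_distances = config$glcm$distances,
                            glcm_angles = config$glcm$angles)
    write_features(tab, file.path(out, "features"))
    list(obj = tab, files = file.path(out, "features", "slide_features.csv"))
  })

  st <- stage("stats", ft$md5, function() {
    feats <- intersect(config$stats$features, names(ft$obj$slides))
    sl <- ft$obj$slides
    cmp <- group_comparisons(sl, feats)
    an <- aggregate_features(sl, "animal")
    pca <- pca_features(an, feats, png = file.path(out, "pca.png"))
    cl <- tryCatch(cluster_heatmap(an, feats,
                                   png = file.path(out, "heatmap.png")),
                   error = function(e) NULL)
    write_stats(file.path(out, "stats"), comparisons = cmp, pca = pca,
                clust = cl)
    list(obj = list(comparisons = cmp, pca = pca, clust = cl),
         files = file.path(out, "stats", "group_comparisons.csv"))
  })

  run_log(config, "run complete")
  invisible(manifest)
}
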