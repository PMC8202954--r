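# Synthetic H&E-like colonic mucosa with exact ground truth. Crypts are
# rendered as elliptical epithelial rings around a mottled lumen, embedded in
# a stromal mucosa band; three archetypes emulate the naive / DSS-colitis /
# treated continuum (crypt density, atrophy, goblet-texture loss).

#' Archetype parameters for synthetic mucosa
#'
#' Returns the rendering parameters of one study-condition archetype.
#' Densities and speckle (goblet) fractions are strictly ordered
#' `normal > treated > dss`, mirroring crypt loss under colitis and partial
#' recovery under treatment; radii shrink in the colitis archetype
#' (atrophy). The palette approximates H&E (purple epithelium, pale pink
#' lumen, pink stroma); the exact RGB values are package constants.
#'
#' @param name one of `"normal"`, `"dss"`, `"treated"`.
#' @return an `archetype_params` list.
#' @export
archetype_params <- function(name = c("normal", "dss", "treated")) {
  name <- match.arg(name)
  base <- list(
    normal  = list(crypt_density = 70, radius_mean = 18, radius_sd = 3,
                   ring_thickness = 5, goblet_speckle_density = 0.35),
    treated = list(crypt_density = 45, radius_mean = 15, radius_sd = 2.5,
                   ring_thickness = 4.5, goblet_speckle_density = 0.18),
    dss     = list(crypt_density = 20, radius_mean = 10, radius_sd = 2,
                   ring_thickness = 3.5, goblet_speckle_density = 0.04)
  )[[name]]
  structure(c(list(name = name), base,
              list(stain_palette = list(
                     epithelium = c(0.45, 0.30, 0.65),
                     lumen = c(0.95, 0.88, 0.92),
                     goblet = c(0.35, 0.22, 0.52),
                     stroma = c(0.92, 0.65, 0.73),
                     background = c(0.97, 0.96, 0.97)),
                   noise_sd = 4 / 255)),
            class = "archetype_params")
}

# Pixels of an ellipse (center cr/cc, semi-axes a >= b, orientation theta
# degrees) as a logical matrix over the full H x W frame.
ellipse_mask <- function(H, W, cr, cc, a, b, theta_deg) {
  th <- theta_deg * pi / 180
  r0 <- max(1L, floor(cr - a)); r1 <- min(H, ceiling(cr + a))
  c0 <- max(1L, floor(cc - a)); c1 <- min(W, ceiling(cc + a))
  if (r0 > r1 || c0 > c1) return(matrix(FALSE, H, W))
  rows <- r0:r1; cols <- c0:c1
  y <- outer(rows - cr, rep(1, length(cols)))
  x <- outer(rep(1, length(rows)), cols - cc)
  # major axis along direction theta in (col, row) coordinates
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  sub <- (u / a)^2 + (v / b)^2 <= 1
  m <- matrix(FALSE, H, W)
  m[rows, cols] <- sub
  m
}

#' Render one synthetic mucosa slide
#'
#' Deterministic for a fixed seed. Crypts are non-overlapping ellipses
#' (axis ratio in `[1, 2]`, uniform orientation) with an epithelial ring and
#' a lumen mottled at the archetype's goblet speckle density; stroma fills
#' the mucosa band; Gaussian pixel noise is added after compositing. If a
#' crypt cannot be placed after 100 rejection-sampling retries the slide is
#' returned with fewer crypts and the actual count in the metadata.
#'
#' @param params an [archetype_params()] list.
#' @param height,width image size in pixels (at least 128).
#' @param seed integer seed.
#' @param slide_id,animal_id identifiers stored in the metadata.
#' @return a `rendered_slide`: list with `image` (`[H,W,3]`, values 0-1),
#'   logical `gland_mask` and `mucosa_mask`, integer `instance_labels`
#'   (0 = background, labels `1..n` with no gaps), per-crypt ground truth
#'   (`centers`, `orientations`, `areas`) and `metadata`.
#' @export
render_slide <- function(params, height = 384L, width = 384L, seed = 0L,
                         slide_id = "slide1", animal_id = "animal1") {
  stopifnot(inherits(params, "archetype_params"))
  if (height < 128L || width < 128L) stop("height and width must be >= 128")
  H <- as.integer(height); W <- as.integer(width)
  with_seed(seed, {
    # wavy mucosa band occupying ~80% of the image height
    cols <- seq_len(W)
    top <- 0.06 * H + 0.02 * H * sin(2 * pi * cols / W * 2 + stats::runif(1, 0, 2 * pi))
    bot <- 0.94 * H + 0.02 * H * sin(2 * pi * cols / W * 3 + stats::runif(1, 0, 2 * pi))
    rowm <- matrix(seq_len(H), H, W)
    mucosa <- sweep(rowm, 2, top, ">=") & sweep(rowm, 2, bot, "<=")

    n_target <- round(params$crypt_density * H * W / 1e6)
    occupied <- matrix(FALSE, H, W)
    labels <- matrix(0L, H, W)
    pal <- params$stain_palette
    img <- array(rep(pal$background, each = H * W), c(H, W, 3))
    for (ch in 1:3) {
      pl <- img[, , ch]; pl[mucosa] <- pal$stroma[ch]; img[, , ch] <- pl
    }

    margin <- 3 # minimum separation so instances stay unambiguous
    centers <- NULL; orientations <- NULL; areas <- integer(0)
    n_placed <- 0L
    for (k in seq_len(n_target)) {
      placed <- FALSE
      for (try in seq_len(100L)) {
        b <- max(3, stats::rnorm(1, params$radius_mean, params$radius_sd))
        q <- stats::runif(1, 1, 2)      # major/minor axis ratio
        a <- b * q
        th <- stats::runif(1, 0, 180)
        cr <- stats::runif(1, a + 2, H - a - 2)
        cc <- stats::runif(1, a + 2, W - a - 2)
        ccol <- as.integer(round(cc))
        if (cr - a < top[ccol] || cr + a > bot[ccol]) next
        grown <- ellipse_mask(H, W, cr, cc, a + margin, b + margin, th)
        if (any(grown & occupied)) next
        crypt <- ellipse_mask(H, W, cr, cc, a, b, th)
        if (!any(crypt)) next
        occupied <- occupied | grown
        n_placed <- n_placed + 1L
        labels[crypt] <- n_placed
        inner <- ellipse_mask(H, W, cr, cc,
                              max(a - params$ring_thickness, 1),
                              max(b - params$ring_thickness, 1), th)
        ring <- crypt & !inner
        lum <- crypt & inner
        for (ch in 1:3) {
          pl <- img[, , ch]
          pl[ring] <- pal$epithelium[ch]
          pl[lum] <- pal$lumen[ch]
          img[, , ch] <- pl
        }
        lum_idx <- which(lum)
        nspeck <- round(params$goblet_speckle_density * length(lum_idx))
        if (nspeck > 0) {
          sp <- sample(lum_idx, nspeck)
          for (ch in 1:3) {
            pl <- img[, , ch]; pl[sp] <- pal$goblet[ch]; img[, , ch] <- pl
          }
        }
        centers <- rbind(centers, c(cr, cc))
        orientations <- c(orientations, th)
        areas <- c(areas, sum(crypt))
        placed <- TRUE
        break
      }
      if (!placed) next
    }
    gland <- labels > 0L
    mucosa <- mucosa | gland # glands are part of the mucosa by definition
    if (params$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, params$noise_sd), dim(img))
      img[img < 0] <- 0; img[img > 1] <- 1
    }
    structure(list(image = img, gland_mask = gland, mucosa_mask = mucosa,
                   instance_labels = labels,
                   centers = centers, orientations = orientations,
                   areas = areas,
                   metadata = list(slide_id = slide_id, animal_id = animal_id,
                                   group = params$name, n_crypts = n_placed,
                                   requested_crypts = n_target, seed = seed)),
              class = "rendered_slide")
  })
}

#' Render a hierarchical cohort of synthetic slides
#'
#' Three groups (normal, dss, treated) with `n_animals_per_group` animals and
#' `slides_per_animal` slides each. Per-animal multiplicative jitter on
#' density, radius and speckle density makes the animal a random-effect
#' level; `jitter_sd = 0` gives every slide of a group identical parameters.
#'
#' @param n_animals_per_group,slides_per_animal counts (>= 1).
#' @param seed integer master seed.
#' @param height,width slide size in pixels.
#' @param jitter_sd sd of the per-animal log-normal parameter jitter.
#' @param groups archetype names to include.
#' @return list of `rendered_slide` objects.
#' @export
render_cohort <- function(n_animals_per_group = 2L, slides_per_animal = 2L,
                          seed = 0L, height = 384L, width = 384L,
                          jitter_sd = 0.08,
                          groups = c("normal", "dss", "treated")) {
  stopifnot(n_animals_per_group >= 1L, slides_per_animal >= 1L)
  slides <- list()
  for (g in groups) {
    for (a in seq_len(n_animals_per_group)) {
      animal_id <- sprintf("%s_a%02d", g, a)
      aseed <- derive_seed(seed, animal_id)
      par <- archetype_params(g)
      if (jitter_sd > 0) {
        jit <- with_seed(aseed, exp(stats::rnorm(3, 0, jitter_sd)))
        par$crypt_density <- par$crypt_density * jit[1]
        par$radius_mean <- par$radius_mean * jit[2]
        par$goblet_speckle_density <-
          min(1, par$goblet_speckle_density * jit[3])
      }
      for (s in seq_len(slides_per_animal)) {
        slide_id <- sprintf("%s_s%02d", animal_id, s)
        slides[[slide_id]] <- render_slide(
          par, height, width, seed = derive_seed(aseed, slide_id),
          slide_id = slide_id, animal_id = animal_id)
      }
    }
  }
  slides
}

#' Write a rendered slide (and ground truth) to disk
#'
#' Image as PNG, gland/mucosa masks as 8-bit PNG (0/255), instance labels as
#' 16-bit single-channel TIFF.
#'
#' @param slide a `rendered_slide`.
#' @param dir output directory (created if missing).
#' @return invisibly, a one-row data.frame of metadata (the manifest row).
#' @export
write_slide <- function(slide, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- slide$metadata$slide_id
  png::writePNG(slide$image, file.path(dir, paste0(id, "_img.png")))
  png::writePNG(slide$gland_mask * 1, file.path(dir, paste0(id, "_gland.png")))
  png::writePNG(slide$mucosa_mask * 1,
                file.path(dir, paste0(id, "_mucosa.png")))
  tiff::writeTIFF(slide$instance_labels / 65535,
                  file.path(dir, paste0(id, "_labels.tiff")),
                  bits.per.sample = 16L)
  invisible(data.frame(slide_id = id, animal_id = slide$metadata$animal_id,
                       group = slide$metadata$group,
                       n_crypts = slide$metadata$n_crypts,
                       seed = slide$metadata$seed))
}

#' Write a whole cohort plus its metadata manifest
#' @param slides list of `rendered_slide`s (e.g. from [render_cohort()]).
#' @param dir output directory.
#' @return invisibly, the manifest data.frame (also written as
#'   `slides.csv` in `dir`).
#' @export
write_fixtures <- function(slides, dir) {
  manifest <- do.call(rbind, lapply(slides, write_slide, dir = dir))
  utils::write.csv(manifest, file.path(dir, "slides.csv"), row.names = FALSE)
  invisible(manifest)
}
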