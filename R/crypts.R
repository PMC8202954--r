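# From probability masks to crypt instances (8-connected components with
# area filtering, centroid and moment orientation) and to the 24x24x72
# central/peripheral patch stacks that feed the autoencoder.

#' Extract crypt instances from a probability mask
#'
#' Thresholds the map, labels 8-connected components, discards components
#' below `min_area`, and relabels survivors `1..n` by decreasing area.
#'
#' @param prob a `probability_mask` (first channel used), or a plain numeric
#'   matrix of per-pixel probabilities, or a logical mask.
#' @param threshold binarization threshold in (0, 1).
#' @param min_area minimum component area in pixels.
#' @return list of `crypt_instance` objects (fields `label`, `mask` cropped
#'   to the bounding box, `bbox` = `c(r0, c0, r1, c1)` 1-based inclusive,
#'   `centroid` (row, col), `area`, `orientation` degrees in [0, 180)), with
#'   the full relabelled matrix in `attr(, "labels")`.
#' @export
extract_instances <- function(prob, threshold = 0.5, min_area = 30L) {
  if (inherits(prob, "probability_mask")) prob <- prob$prob[, , 1]
  if (is.logical(prob)) prob <- prob * 1
  if (length(dim(prob)) == 3L) prob <- prob[, , 1]
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  bin <- matrix(as.integer(prob >= threshold), nrow(prob), ncol(prob))
  lab <- cc_label8(bin)
  n <- max(lab)
  out_labels <- matrix(0L, nrow(lab), ncol(lab))
  instances <- list()
  if (n > 0) {
    areas <- tabulate(lab[lab > 0], n)
    keep <- which(areas >= min_area)
    keep <- keep[order(areas[keep], decreasing = TRUE)]
    for (i in seq_along(keep)) {
      old <- keep[i]
      idx <- which(lab == old, arr.ind = TRUE)
      out_labels[idx] <- i
      r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
      c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
      m <- matrix(FALSE, r1 - r0 + 1, c1 - c0 + 1)
      m[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- TRUE
      instances[[i]] <- structure(
        list(label = i, mask = m, bbox = c(r0, c0, r1, c1),
             centroid = c(mean(idx[, 1]), mean(idx[, 2])),
             area = areas[old],
             orientation = mask_orientation(idx[, 1], idx[, 2])),
        class = "crypt_instance")
    }
  }
  attr(instances, "labels") <- out_labels
  instances
}

# Major-axis orientation (degrees in [0, 180)) from second central moments,
# measured from the column (x) axis with rows as y.
mask_orientation <- function(rows, cols) {
  x <- cols - mean(cols); y <- rows - mean(rows)
  mu20 <- mean(x * x); mu02 <- mean(y * y); mu11 <- mean(x * y)
  th <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  th %% 180
}

#' Split a crypt mask into central region and peripheral border
#'
#' The central region is the set of mask pixels whose Euclidean distance to
#' the background exceeds `border_depth` (equivalently, the erosion of the
#' mask by that depth); the peripheral border is the rest, so the two
#' partition the mask. A mask too thin to have a central region is returned
#' with `thin = TRUE`.
#'
#' @param instance a `crypt_instance` (or any logical mask).
#' @param border_depth band depth in pixels (>= 1); default scales with the
#'   crypt's equivalent radius, `max(2, 0.25 * sqrt(area / pi))`.
#' @return list `central`, `peripheral` (logical, same shape as the instance
#'   mask), `thin` flag.
#' @export
partition_regions <- function(instance, border_depth = NULL) {
  m <- if (inherits(instance, "crypt_instance")) instance$mask else instance
  if (is.null(border_depth)) border_depth <- max(2, 0.25 * sqrt(sum(m) / pi))
  if (border_depth < 1) stop("border_depth must be >= 1")
  # pad so the bounding-box edge counts as background
  pm <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
  pm[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m * 1
  d <- EBImage::imageData(EBImage::distmap(pm))
  d <- d[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)]
  central <- d > border_depth
  peripheral <- m & !central
  list(central = central, peripheral = peripheral, thin = !any(central))
}

#' Sample the 24x24x72 patch stack of one crypt
#'
#' Draws `n_per_region` patch centers uniformly with replacement from the
#' central region and the peripheral border of the instance, crops
#' `patch_size`-sided RGB patches from the slide image (reflect-padded at
#' image borders), and stacks them channelwise, central patches first:
#' `3 * 2 * n_per_region` channels (72 at the defaults). For thin objects
#' all `2 * n_per_region` patches come from the peripheral border.
#'
#' @param instance a `crypt_instance` (bbox coordinates refer to `image`).
#' @param image RGB array `[H, W, 3]`.
#' @param seed integer seed.
#' @param n_per_region patches per region (default 12).
#' @param patch_size patch side in pixels (default 24).
#' @param border_depth passed to [partition_regions()].
#' @return a `patch_stack`: list with `tensor`
#'   (`[patch_size, patch_size, 6 * n_per_region]`), `centers` (full-image
#'   row/col), `central_idx`, `label`, `seed`, `thin`.
#' @export
sample_patches <- function(instance, image, seed = 0L, n_per_region = 12L,
                           patch_size = 24L, border_depth = NULL) {
  stopifnot(inherits(instance, "crypt_instance"))
  if (sum(instance$mask) == 0) stop("instance mask is empty")
  reg <- partition_regions(instance, border_depth)
  off <- instance$bbox[1:2] - 1L
  cen_px <- which(reg$central, arr.ind = TRUE)
  per_px <- which(reg$peripheral, arr.ind = TRUE)
  n_tot <- 2L * n_per_region
  with_seed(seed, {
    if (reg$thin) {
      pick <- per_px[sample.int(nrow(per_px), n_tot, replace = TRUE), ,
                     drop = FALSE]
      central_idx <- integer(0)
    } else {
      pc <- cen_px[sample.int(nrow(cen_px), n_per_region, replace = TRUE), ,
                   drop = FALSE]
      pp <- per_px[sample.int(nrow(per_px), n_per_region, replace = TRUE), ,
                   drop = FALSE]
      pick <- rbind(pc, pp)
      central_idx <- seq_len(n_per_region)
    }
    centers <- sweep(pick, 2, off, "+")
    half <- patch_size %/% 2L
    H <- dim(image)[1]; W <- dim(image)[2]
    tensor <- array(0, c(patch_size, patch_size, 3L * n_tot))
    for (i in seq_len(n_tot)) {
      rs <- reflect_index(centers[i, 1] - half + seq_len(patch_size) - 1L, H)
      cs <- reflect_index(centers[i, 2] - half + seq_len(patch_size) - 1L, W)
      tensor[, , 3L * (i - 1L) + 1:3] <- image[rs, cs, , drop = FALSE]
    }
    structure(list(tensor = tensor, centers = centers,
                   central_idx = central_idx, label = instance$label,
                   seed = seed, thin = reg$thin),
              class = "patch_stack")
  })
}

#' Patch stacks for every crypt of a slide
#'
#' Convenience wrapper: extracts instances from the slide's gland mask (or a
#' supplied probability mask), samples a patch stack per crypt, and attaches
#' slide/animal/group metadata for downstream embedding.
#'
#' @param slide a `rendered_slide` (or list with `image` and metadata).
#' @param prob probability mask; defaults to the slide's ground-truth
#'   `gland_mask`.
#' @param seed integer seed.
#' @param min_area,threshold passed to [extract_instances()].
#' @param ... passed to [sample_patches()].
#' @return list of `patch_stack`s with `slide_id`, `animal_id`, `group` set.
#' @export
crypt_stacks <- function(slide, prob = NULL, seed = 0L, threshold = 0.5,
                         min_area = 30L, ...) {
  if (is.null(prob)) prob <- slide$gland_mask * 1
  inst <- extract_instances(prob, threshold = threshold, min_area = min_area)
  lapply(inst, function(ins) {
    st <- sample_patches(ins, slide$image,
                         seed = derive_seed(seed, ins$label), ...)
    st$slide_id <- slide$metadata$slide_id
    st$animal_id <- slide$metadata$animal_id
    st$group <- slide$metadata$group
    st
  })
}

#' Export crypt instances of one slide
#'
#' 16-bit label TIFF plus a CSV of per-instance geometry.
#'
#' @param instances result of [extract_instances()].
#' @param dir output directory.
#' @param slide_id identifier used in file names.
#' @return invisibly, the instance data.frame.
#' @export
write_instances <- function(instances, dir, slide_id = "slide") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lab <- attr(instances, "labels")
  tiff::writeTIFF(lab / 65535, file.path(dir, paste0(slide_id, "_labels.tiff")),
                  bits.per.sample = 16L)
  df <- do.call(rbind, lapply(instances, function(i)
    data.frame(label = i$label, centroid_row = i$centroid[1],
               centroid_col = i$centroid[2], area = i$area,
               orientation = i$orientation)))
  if (is.null(df)) df <- data.frame(label = integer(), centroid_row = numeric(),
                                    centroid_col = numeric(), area = integer(),
                                    orientation = numeric())
  utils::write.csv(df, file.path(dir, paste0(slide_id, "_instances.csv")),
                   row.names = FALSE)
  invisible(df)
}
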