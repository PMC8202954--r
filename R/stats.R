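# Slide- and animal-level statistics: Welch two-sample comparisons, Pearson
# feature-score correlations, PCA and z-scored hierarchical clustering, as
# used for treatment-effect readouts.

#' Aggregate a feature table to slide or animal level
#'
#' Unweighted mean of every numeric column within the unit (slide or
#' animal); one row per unit, group labels carried through.
#'
#' @param table data.frame with `slide_id`, `animal_id`, `group` columns
#'   (e.g. `feature_table$crypts` or `$slides`).
#' @param level `"slide"` or `"animal"`.
#' @return aggregated data.frame.
#' @export
aggregate_features <- function(table, level = c("slide", "animal")) {
  level <- match.arg(level)
  id <- if (level == "slide") "slide_id" else "animal_id"
  if (!id %in% names(table)) stop("missing column: ", id)
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  num <- setdiff(num, c("label", "nn_label"))
  groups <- unique(table[, c(id, "group"), drop = FALSE])
  agg <- stats::aggregate(table[num], by = list(unit = table[[id]]),
                          FUN = mean, na.rm = TRUE)
  names(agg)[1] <- id
  out <- merge(groups, agg, by = id, sort = TRUE)
  rownames(out) <- NULL
  out
}

#' Welch two-sample t-test (unequal variances)
#'
#' Unpaired two-sided t-test with the Welch-Satterthwaite degrees of
#' freedom, as used for all group comparisons.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @param feature,groups labels recorded in the result.
#' @return a `group_comparison` data.frame row: feature, groups, means,
#'   `t`, `df`, two-sided `p`.
#' @export
welch_t <- function(a, b, feature = NA_character_, groups = c("a", "b")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  data.frame(feature = feature, group_a = groups[1], group_b = groups[2],
             mean_a = mean(a), mean_b = mean(b),
             t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors (n >= 3, nonzero variances).
#' @param pair label recorded in the result.
#' @return a `correlation_result` data.frame row: pair, `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y, pair = NA_character_) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ht <- stats::cor.test(x, y, method = "pearson")
  data.frame(pair = pair, r = unname(ht$estimate), p = ht$p.value,
             n = length(x))
}

#' All pairwise Welch comparisons of features across groups
#'
#' @param table aggregated table with a `group` column.
#' @param features character vector of feature columns.
#' @param adjust if `TRUE`, append Benjamini-Hochberg adjusted p-values
#'   (off by default; raw p-values are the primary output).
#' @return data.frame of [welch_t()] rows for every feature x group pair.
#' @export
group_comparisons <- function(table, features, adjust = FALSE) {
  gs <- unique(table$group)
  rows <- list()
  for (f in features) {
    for (i in seq_along(gs)) for (j in seq_along(gs)) {
      if (i >= j) next
      row <- tryCatch(
        welch_t(table[[f]][table$group == gs[i]],
                table[[f]][table$group == gs[j]],
                feature = f, groups = c(gs[i], gs[j])),
        error = function(e) NULL) # too few non-missing values: skip pair
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

# Drop constant features with a warning; returns the kept feature names.
drop_constant <- function(table, features) {
  sds <- vapply(features, function(f) stats::sd(table[[f]], na.rm = TRUE),
                numeric(1))
  bad <- features[is.na(sds) | sds == 0]
  if (length(bad))
    warning("dropping constant feature(s): ", paste(bad, collapse = ", "))
  setdiff(features, bad)
}

#' PCA of standardized features
#'
#' Column-standardizes the selected features (constant features dropped with
#' a warning), computes principal components, and returns scores and
#' explained-variance ratios (sorted descending, summing to 1).
#'
#' @param table data.frame of units x features (with optional `group`).
#' @param features character vector of feature columns.
#' @param png optional path for a PC1/PC2 scatter PNG colored by group.
#' @return list with `scores`, `ratios`, `loadings`, `features`.
#' @export
pca_features <- function(table, features, png = NULL) {
  if (length(features) < 2) stop("need at least 2 features")
  if (nrow(table) < 3) stop("need at least 3 units")
  features <- drop_constant(table, features)
  X <- as.matrix(table[, features, drop = FALSE])
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ratios <- pc$sdev^2 / sum(pc$sdev^2)
  if (!is.null(png)) {
    grDevices::png(png, width = 800, height = 700)
    grp <- if ("group" %in% names(table)) factor(table$group[keep])
      else factor(rep("unit", nrow(X)))
    graphics::plot(pc$x[, 1], pc$x[, 2], col = as.integer(grp), pch = 19,
                   xlab = sprintf("PC1 (%.1f%%)", 100 * ratios[1]),
                   ylab = sprintf("PC2 (%.1f%%)", 100 * ratios[2]),
                   main = "PCA of crypt image features")
    graphics::legend("topright", legend = levels(grp), col = seq_along(levels(grp)),
                     pch = 19)
    grDevices::dev.off()
  }
  list(scores = pc$x, ratios = ratios, loadings = pc$rotation,
       features = features)
}

#' Z-scored hierarchical clustering with heatmap
#'
#' Per-feature z-scores, Euclidean distances, average-linkage hierarchical
#' clustering; returns the linkage, leaf order and the z-scored matrix, and
#' optionally draws the clustered heatmap to PNG.
#'
#' @param table data.frame of units x features.
#' @param features character vector of feature columns.
#' @param png optional output PNG path.
#' @param labels optional row labels (defaults to `animal_id` or `slide_id`
#'   when present).
#' @return list with `hc` (hclust), `order`, `z` (z-scored matrix),
#'   `features`.
#' @export
cluster_heatmap <- function(table, features, png = NULL, labels = NULL) {
  if (nrow(table) < 3) stop("need at least 3 units")
  features <- drop_constant(table, features)
  X <- as.matrix(table[, features, drop = FALSE])
  if (is.null(labels)) {
    labels <- if ("animal_id" %in% names(table)) table$animal_id
      else if ("slide_id" %in% names(table)) table$slide_id
      else as.character(seq_len(nrow(table)))
  }
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  Z <- scale(X)
  rownames(Z) <- labels
  hc <- stats::hclust(stats::dist(Z, method = "euclidean"),
                      method = "average")
  if (!is.null(png)) {
    grDevices::png(png, width = 900, height = 700)
    stats::heatmap(Z, Rowv = stats::as.dendrogram(hc), Colv = NA,
                   scale = "none", margins = c(10, 8),
                   col = grDevices::hcl.colors(64, "RdBu", rev = TRUE))
    grDevices::dev.off()
  }
  list(hc = hc, order = hc$order, z = Z, features = features,
       keep = which(keep))
}

#' Purity of one group at a k-cluster cut
#'
#' Cuts the dendrogram at `k` clusters and reports, for the cluster that
#' contains the most units of `group`, the fraction of its members that
#' belong to `group`.
#'
#' @param clust result of [cluster_heatmap()].
#' @param groups group label per unit of the ORIGINAL table; rows dropped for
#'   missing values are handled via `clust$keep`.
#' @param group the group of interest.
#' @param k number of clusters at the cut.
#' @return purity in `(0, 1]`.
#' @export
cluster_purity <- function(clust, groups, group, k = 3L) {
  if (!is.null(clust$keep) && length(groups) != length(clust$hc$order))
    groups <- groups[clust$keep]
  ct <- stats::cutree(clust$hc, k = k)
  tab <- table(ct, groups)
  cl <- which.max(tab[, group])
  tab[cl, group] / sum(tab[cl, ])
}

#' Write the cohort statistics bundle
#'
#' `group_comparisons.csv`, `correlations.csv`, `pca_scores.csv`,
#' `linkage.csv` plus PCA and heatmap PNGs.
#'
#' @param dir output directory.
#' @param comparisons,correlations data.frames (optional).
#' @param pca result of [pca_features()] (optional).
#' @param clust result of [cluster_heatmap()] (optional).
#' @return invisibly `NULL`.
#' @export
write_stats <- function(dir, comparisons = NULL, correlations = NULL,
                        pca = NULL, clust = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(comparisons))
    utils::write.csv(comparisons, file.path(dir, "group_comparisons.csv"),
                     row.names = FALSE)
  if (!is.null(correlations))
    utils::write.csv(correlations, file.path(dir, "correlations.csv"),
                     row.names = FALSE)
  if (!is.null(pca))
    utils::write.csv(data.frame(pca$scores,
                                ratio = c(pca$ratios,
                                          rep(NA, nrow(pca$scores) -
                                                length(pca$ratios)))[
                                                  seq_len(nrow(pca$scores))]),
                     file.path(dir, "pca_scores.csv"), row.names = FALSE)
  if (!is.null(clust))
    utils::write.csv(data.frame(clust$hc$merge, height = clust$hc$height),
                     file.path(dir, "linkage.csv"), row.names = FALSE)
  invisible(NULL)
}
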