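#' Ward hierarchical clustering of the normalized feature matrix
#'
#' Agglomerative clustering under Ward's minimum-variance criterion with
#' Euclidean distances (the `ward.D2` dialect: merge heights are on the
#' distance scale, `sqrt(2 * delta-SS)`). Ties are resolved
#' deterministically by the underlying implementation (lowest pair index).
#'
#' @param x numeric matrix (patients x features) or a `normalized_matrix`.
#' @return object of class `ward_tree`: the `hclust` fit plus the data
#'   matrix.
#' @export
ward_linkage <- function(x) {
  if (inherits(x, "normalized_matrix")) x <- x$x
  x <- as.matrix(x)
  stop_if(nrow(x) < 2, "need at least two rows")
  stop_if(any(!is.finite(x)), "matrix contains non-finite entries")
  hc <- stats::hclust(dist(x), method = "ward.D2")
  structure(list(hclust = hc, data = x), class = "ward_tree")
}

#' Cut a Ward tree into k clusters
#' @param tree a `ward_tree`.
#' @param k number of clusters, 1..n.
#' @return integer cluster labels.
#' @export
cut_ward <- function(tree, k) {
  stopifnot(inherits(tree, "ward_tree"))
  n <- nrow(tree$data)
  stop_if(k < 1 || k > n, sprintf("k must be in [1, %d]", n))
  cutree(tree$hclust, k = k)
}

#' Cluster-validity indices for a given partition
#'
#' Average silhouette width (singletons score 0) and the Dunn index
#' (minimum single-linkage inter-cluster distance over the maximum
#' intra-cluster diameter), both under Euclidean distance.
#'
#' @param x data matrix.
#' @param labels integer cluster labels, k >= 2.
#' @param d optional precomputed `dist` object.
#' @return list: `k`, `avg_silhouette`, `dunn`, `sizes`.
#' @export
validity_indices <- function(x, labels, d = NULL) {
  if (inherits(x, "normalized_matrix")) x <- x$x
  k <- length(unique(labels))
  stop_if(k < 2, "validity indices need k >= 2")
  if (is.null(d)) d <- dist(x)
  sil <- cluster::silhouette(labels, d)
  list(k = k,
       avg_silhouette = mean(sil[, "sil_width"]),
       dunn = dunn_index(d, labels),
       sizes = as.integer(table(labels)))
}

#' Dunn index
#' @param d a `dist` object.
#' @param labels integer cluster labels.
#' @return minimum inter-cluster distance / maximum cluster diameter.
#' @export
dunn_index <- function(d, labels) {
  dm <- as.matrix(d)
  same <- outer(labels, labels, `==`)
  diag(same) <- NA
  max_diam <- max(dm[same & !is.na(same)])
  min_inter <- min(dm[!same & !is.na(same)])
  min_inter / max_diam
}

#' Select the dendrogram cut level
#'
#' Scans cut levels, computes the average silhouette width and the Dunn
#' index at each, and picks the level maximizing the rank-sum of the two
#' indices (a composite, since the study blended the quantitative indices
#' with heatmap inspection); ties go to the smaller k. A `force_k`
#' override reproduces a human choice.
#'
#' @param tree a `ward_tree`.
#' @param x data matrix used for the distances (defaults to the tree's
#'   data).
#' @param k_range candidate cluster counts (default 2:20).
#' @param force_k optional fixed choice; the metrics table is still
#'   emitted.
#' @return list: `k` (chosen), `metrics` (data frame over `k_range`).
#' @export
select_k <- function(tree, x = NULL, k_range = 2:20, force_k = NULL) {
  stopifnot(inherits(tree, "ward_tree"))
  if (is.null(x)) x <- tree$data
  if (inherits(x, "normalized_matrix")) x <- x$x
  n <- nrow(x)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  stop_if(length(k_range) == 0, "empty k range")
  d <- dist(x)
  rows <- lapply(k_range, function(k) {
    vi <- validity_indices(x, cut_ward(tree, k), d)
    data.frame(k = k, avg_silhouette = vi$avg_silhouette, dunn = vi$dunn)
  })
  metrics <- do.call(rbind, rows)
  metrics$rank_sum <- rank(metrics$avg_silhouette) + rank(metrics$dunn)
  chosen <- if (!is.null(force_k)) force_k
            else metrics$k[which.max(metrics$rank_sum)]
  list(k = chosen, metrics = metrics)
}

#' Renumber subgroups by ascending mean age
#'
#' The study convention: subgroup 1 is the youngest on average. Ties are
#' broken by the original label.
#'
#' @param labels integer cluster labels.
#' @param ages numeric ages, one per patient.
#' @return list of class `subgroup_assignment`: `labels` (renumbered),
#'   `mean_age` (per new label), `mapping` (old -> new).
#' @export
renumber_by_age <- function(labels, ages) {
  stop_if(length(labels) != length(ages) || anyNA(ages), "every patient needs an age")
  means <- tapply(ages, labels, mean)
  ord <- order(means, names(means))
  mapping <- setNames(seq_along(ord), names(means)[ord])
  new_labels <- unname(mapping[as.character(labels)])
  structure(list(labels = new_labels,
                 mean_age = setNames(as.numeric(means[ord]), seq_along(ord)),
                 mapping = mapping),
            class = "subgroup_assignment")
}

#' Voxelwise WMH frequency maps per subgroup
#'
#' The likelihood of WMH presence per voxel within each subgroup: the
#' voxelwise mean of the binary WMH masks of its members. Masks must share
#' one grid (no spatial normalization is attempted); on a grid mismatch the
#' map is skipped with a warning.
#'
#' @param masks list of binary 3D arrays, one per patient.
#' @param labels subgroup labels, one per patient.
#' @return named list of numeric arrays (frequency between 0 and 1) or `NULL`
#'   when skipped.
#' @export
wmh_frequency_maps <- function(masks, labels) {
  stop_if(length(masks) != length(labels), "one mask per patient required")
  dims <- lapply(masks, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1) {
    warning("masks are on differing grids; frequency maps skipped")
    return(NULL)
  }
  out <- list()
  for (g in sort(unique(labels))) {
    sel <- which(labels == g)
    acc <- array(0, dim(masks[[sel[1]]]))
    for (i in sel) acc <- acc + (masks[[i]] != 0)
    out[[as.character(g)]] <- acc / length(sel)
  }
  out
}

#' Heatmap matrix and rendering of the clustering result
#'
#' Reorders the normalized matrix rows into dendrogram leaf order (the
#' heatmap convention: one row per patient, one column per feature,
#' diverging palette centred at 0) and optionally renders the dendrogram
#' and heatmap to files.
#'
#' @param tree a `ward_tree`.
#' @param assignment a `subgroup_assignment`.
#' @param nm a `normalized_matrix` (or plain matrix).
#' @param dir optional output directory; when given, writes
#'   `dendrogram.pdf`, `heatmap.png` and `heatmap_matrix.tsv`.
#' @return list: `order` (leaf order), `heatmap` (reordered matrix),
#'   `row_subgroup` (subgroup per heatmap row).
#' @export
render_outputs <- function(tree, assignment, nm, dir = NULL) {
  stopifnot(inherits(tree, "ward_tree"), inherits(assignment, "subgroup_assignment"))
  x <- if (inherits(nm, "normalized_matrix")) nm$x else as.matrix(nm)
  ord <- tree$hclust$order
  hm <- x[ord, , drop = FALSE]
  row_sub <- assignment$labels[ord]
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    grDevices::pdf(file.path(dir, "dendrogram.pdf"), width = 9, height = 5)
    plot(tree$hclust, labels = FALSE, hang = -1, main = "Ward dendrogram",
         xlab = "", sub = "")
    grDevices::dev.off()
    write.table(data.frame(subgroup = row_sub, hm),
                file.path(dir, "heatmap_matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      lim <- max(abs(hm), na.rm = TRUE)
      grDevices::png(file.path(dir, "heatmap.png"), width = 1200, height = 1400)
      hm_named <- hm
      rownames(hm_named) <- as.character(seq_len(nrow(hm)))
      pheatmap::pheatmap(hm_named, cluster_rows = FALSE, cluster_cols = FALSE,
                         show_rownames = FALSE,
                         breaks = seq(-lim, lim, length.out = 101),
                         annotation_row = data.frame(
                           subgroup = factor(row_sub),
                           row.names = rownames(hm_named)))
      grDevices::dev.off()
    }
  }
  list(order = ord, heatmap = hm, row_subgroup = row_sub)
}
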