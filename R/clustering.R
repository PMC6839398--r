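#' Hierarchical Ward clustering of shape features
#'
#' Agglomerative clustering with Ward's method on Euclidean distances, cut
#' at `k` clusters. Features may be raw angle profiles (seed-free,
#' recommended for reproducible composition statistics) or a t-SNE
#' embedding from [embed_profiles()] (the visual-clustering route); the
#' feature space used is recorded in the result. When `k` is `NULL` it is
#' chosen to maximize the mean silhouette width over `k_range`, replacing
#' the by-eye dendrogram cut with an explicit rule.
#'
#' @param features numeric matrix (cells x features), a list of
#'   `angle_profile`s, or a 2-column embedding.
#' @param k number of clusters, or `NULL` to select by silhouette.
#' @param method linkage method for [stats::hclust()] ("ward.D2" is Ward
#'   on Euclidean distances).
#' @param k_range candidate k values for silhouette selection.
#' @param ids optional cell identifiers.
#' @return a `cluster_assignment`: list with `labels` (integer 1..k, named
#'   by id), `k`, `method`, `feature_space`, `hclust` (the tree).
#' @export
cluster_profiles <- function(features, k = NULL, method = "ward.D2",
                             k_range = 2:8, ids = NULL) {
  x <- profiles_to_matrix(features)
  n <- nrow(x)
  if (!is.null(k) && (k < 2 || k > n)) stop("k must be in [2, n]")
  d <- dist(x)
  if (max(d) < .Machine$double.eps * 100)
    stop("degenerate feature set: all profiles identical")
  hc <- hclust(d, method = method)
  feature_space <- if (ncol(x) == 2) "embedding" else "profile"
  if (is.null(k)) {
    k_range <- k_range[k_range < n]
    sil <- vapply(k_range, function(kk) {
      mean(cluster::silhouette(cutree(hc, kk), d)[, 3])
    }, numeric(1))
    k <- k_range[which.max(sil)]
  }
  labels <- cutree(hc, k)
  if (!is.null(ids)) names(labels) <- ids
  structure(list(labels = labels, k = as.integer(k), method = method,
                 feature_space = feature_space, hclust = hc),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d (%s linkage, %s space): sizes %s\n",
              x$k, x$method, x$feature_space,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Sex-chromosome composition of shape clusters
#'
#' For every cluster: X and Y counts, X proportion with its standard error
#' of proportion, and a one-sample Z-test of the X proportion against 0.5
#' with Holm correction across clusters. Cells with missing labels are
#' excluded from the proportion and counted separately.
#'
#' @param assignment a `cluster_assignment` (or an integer label vector).
#' @param sex character vector of "X"/"Y" (NA allowed), one per cell.
#' @param alpha flag threshold on Holm-adjusted p.
#' @return data.frame: cluster, n, n_x, n_y, n_unknown, p_x, se, z, p,
#'   p_adjusted, flag.
#' @export
cluster_sex_composition <- function(assignment, sex, alpha = 0.05) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else assignment
  stopifnot(length(labels) == length(sex))
  rows <- lapply(sort(unique(labels)), function(cl) {
    s <- sex[labels == cl]
    nx <- sum(s == "X", na.rm = TRUE)
    ny <- sum(s == "Y", na.rm = TRUE)
    if (nx + ny == 0) stop("cluster ", cl, " has no labelled cells")
    zt <- one_sample_ztest(nx, nx + ny, 0.5)
    data.frame(cluster = cl, n = length(s), n_x = nx, n_y = ny,
               n_unknown = sum(is.na(s)), p_x = nx / (nx + ny),
               se = se_proportion(nx, nx + ny), z = zt$z, p = zt$p)
  })
  tab <- do.call(rbind, rows)
  hb <- holm_bonferroni(tab$p, alpha = alpha)
  tab$p_adjusted <- hb$p_adjusted
  tab$flag <- hb$reject
  tab
}

#' Rank clusters by deviation from a reference consensus
#'
#' Computes, for each cluster of a population, the mean squared vertex
#' distance between the cluster's (unit-scaled, aligned) consensus and a
#' reference consensus (typically wild type). Used to identify the most
#' "normal" and the most deviant shape clusters.
#'
#' @param outlines list of `outline`s for the clustered cells.
#' @param labels cluster labels, one per outline.
#' @param reference_outlines list of `outline`s defining the reference
#'   (e.g. a wild-type population).
#' @param n_points common vertex count.
#' @return data.frame: cluster, distance (ascending = most normal first).
#' @export
rank_clusters_by_reference <- function(outlines, labels, reference_outlines,
                                       n_points = 200) {
  ref_rs <- lapply(reference_outlines, smooth_resample, n_points = n_points)
  ref <- consensus_shape(align_outlines(ref_rs, scale_mode = "unit-scaled"))
  refv <- as_vertices(ref$mean_outline)
  cls <- sort(unique(labels))
  dists <- vapply(cls, function(cl) {
    rs <- lapply(outlines[labels == cl], smooth_resample, n_points = n_points)
    cs <- consensus_shape(align_outlines(rs, scale_mode = "unit-scaled"))
    v <- rotate_to(as_vertices(cs$mean_outline), refv)
    mean(rowSums((v - refv)^2))
  }, numeric(1))
  data.frame(cluster = cls, distance = dists)[order(dists), ]
}
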