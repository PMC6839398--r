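#' Landmark-then-Procrustes alignment of outlines
#'
#' Aligns a set of outlines that share a vertex count: each is re-indexed so
#' its hook apex becomes vertex 1 (fixing point correspondence with a
#' biologically meaningful landmark), translated to centroid origin,
#' optionally scaled to unit centroid size, then rigidly rotated to the
#' running mean shape by a rotation-only Kabsch fit. Reflections are never
#' applied. The rotate-to-mean pass is iterated until the mean shape moves
#' by less than `tol` times the mean radius.
#'
#' @param outlines list of `outline`s, all with the same vertex count.
#' @param apexes integer vector of apex vertex indices (1-based); by
#'   default located per outline via [detect_hook_apex()] on a profile of
#'   the same resolution as the outline.
#' @param scale_mode "size-preserving" keeps each outline's scale;
#'   "unit-scaled" divides by centroid size.
#' @param tol convergence tolerance on mean movement, relative to mean radius.
#' @param max_iter iteration cap for the Procrustes pass.
#' @return list of aligned vertex matrices (class `aligned_outlines`).
#' @export
align_outlines <- function(outlines, apexes = NULL,
                           scale_mode = c("size-preserving", "unit-scaled"),
                           tol = 1e-6, max_iter = 100) {
  scale_mode <- match.arg(scale_mode)
  if (!length(outlines)) stop("no outlines to align")
  np <- vapply(outlines, function(o) nrow(as_vertices(o)), integer(1))
  if (length(unique(np)) != 1)
    stop("all outlines must share the same vertex count; got ",
         paste(unique(np), collapse = ", "))
  n <- np[1]
  if (is.null(apexes)) {
    apexes <- vapply(outlines, function(o) {
      pr <- detect_hook_apex(angle_profile(o, n_index = 100))
      # profile index (0-based, percent) -> nearest vertex index
      round(pr$apex / 100 * n) %% n + 1L
    }, numeric(1))
  }
  mats <- lapply(seq_along(outlines), function(i) {
    v <- rotate_start(as_vertices(outlines[[i]]), as.integer(apexes[i]))
    v <- sweep(v, 2, colMeans(v))
    if (scale_mode == "unit-scaled") v <- v / sqrt(mean(rowSums(v^2)))
    v
  })
  mean_shape <- Reduce(`+`, mats) / length(mats)
  mean_radius <- sqrt(mean(rowSums(mean_shape^2)))
  if (mean_radius == 0) mean_radius <- 1
  for (it in seq_len(max_iter)) {
    mats <- lapply(mats, rotate_to, target = mean_shape)
    new_mean <- Reduce(`+`, mats) / length(mats)
    move <- sqrt(mean(rowSums((new_mean - mean_shape)^2)))
    mean_shape <- new_mean
    if (move < tol * mean_radius) break
  }
  structure(mats, class = "aligned_outlines")
}

# Rotation-only (no reflection) Kabsch fit of v onto target.
rotate_to <- function(v, target) {
  h <- crossprod(v, target)  # 2x2
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  v %*% t(r)
}

#' Consensus shape of an aligned outline set
#'
#' Vertexwise mean polygon with a per-vertex radial interquartile-range
#' envelope describing shape variability around the consensus.
#'
#' @param aligned an `aligned_outlines` set (or list of equal-size vertex
#'   matrices already aligned).
#' @return a `consensus_shape`: list with `mean_outline` (`outline`),
#'   `envelope` (per-vertex radial IQR), `n_cells`.
#' @export
consensus_shape <- function(aligned) {
  if (!length(aligned)) stop("empty aligned set")
  mats <- lapply(aligned, as_vertices)
  mean_shape <- Reduce(`+`, mats) / length(mats)
  radii <- vapply(mats, function(m) sqrt(rowSums(m^2)), numeric(nrow(mean_shape)))
  radii <- matrix(radii, nrow = nrow(mean_shape))
  env <- apply(radii, 1, function(r) diff(quantile(r, c(0.25, 0.75))))
  structure(list(mean_outline = outline(mean_shape), envelope = as.numeric(env),
                 n_cells = length(mats)), class = "consensus_shape")
}

#' @export
print.consensus_shape <- function(x, ...) {
  cat(sprintf("<consensus_shape> of %d cells, area %.2f um^2, median radial IQR %.3f um\n",
              x$n_cells, polygon_area(x$mean_outline), median(x$envelope)))
  invisible(x)
}

#' Build per-group consensus shapes from a population
#'
#' Convenience wrapper: resamples all outlines of a population to a common
#' vertex count, splits by a grouping vector (e.g. genotype or cluster
#' label), aligns each group and returns its consensus.
#'
#' @param outlines list of `outline`s.
#' @param groups vector of group labels, one per outline.
#' @param n_points common vertex count for alignment.
#' @param scale_mode passed to [align_outlines()].
#' @return named list of `consensus_shape` objects.
#' @export
group_consensus <- function(outlines, groups, n_points = 200,
                            scale_mode = "size-preserving") {
  stopifnot(length(outlines) == length(groups))
  res <- lapply(split(seq_along(outlines), groups), function(ix) {
    rs <- lapply(outlines[ix], smooth_resample, n_points = n_points)
    consensus_shape(align_outlines(rs, scale_mode = scale_mode))
  })
  res
}
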