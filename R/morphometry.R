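#' Sliding-window interior-angle profile of an outline
#'
#' Measures, at `n_index` equally spaced perimeter positions, the interior
#' angle of the triangle (A, p, B) where A and B lie half a window before
#' and after p along the perimeter. Convex regions give angles below 180
#' degrees, concave (reflex) regions above; a circle gives the closed form
#' 180 - 180 * window_fraction everywhere. Index i of the profile sits at
#' i percent of the perimeter counterclockwise from the first vertex (or
#' from the hook apex once anchored with [detect_hook_apex()]).
#'
#' The outline is densely resampled to a multiple of `n_index` so window
#' endpoints fall exactly on vertices; the profile is invariant to
#' translation, rotation and uniform scaling, and to the stored orientation
#' of the outline (orientation is canonicalized to counterclockwise).
#'
#' @param x an `outline`.
#' @param window_fraction window length as a fraction of the perimeter,
#'   in (0, 0.5).
#' @param n_index number of profile positions (default 100, i.e. percent).
#' @param oversample dense-resampling factor per index position.
#' @return an `angle_profile`: list with `angles` (degrees, length
#'   `n_index`), `window_fraction`, `anchored` (logical), `apex` (set by
#'   [detect_hook_apex()]).
#' @export
angle_profile <- function(x, window_fraction = 0.05, n_index = 100,
                          oversample = 20) {
  if (window_fraction <= 0 || window_fraction >= 0.5)
    stop("window_fraction must be in (0, 0.5): the window may not wrap past the antipode")
  m <- n_index * oversample
  off <- round(window_fraction / 2 * m)
  if (off < 1) stop("window_fraction too small for this resolution")
  v <- as_vertices(smooth_resample(x, n_points = m))
  idx <- seq(1L, m, by = oversample)  # the n_index measurement positions
  p <- v[idx, , drop = FALSE]
  a <- v[((idx - 1L - off) %% m) + 1L, , drop = FALSE]  # before p
  b <- v[((idx - 1L + off) %% m) + 1L, , drop = FALSE]  # after p
  u1 <- a - p; u2 <- b - p
  n1 <- sqrt(rowSums(u1^2)); n2 <- sqrt(rowSums(u2^2))
  cosang <- pmin(pmax(rowSums(u1 * u2) / (n1 * n2), -1), 1)
  ang <- acos(cosang) * 180 / pi
  # side test: traversal A -> p -> B; left turn (positive cross) = convex
  crossz <- (p[, 1] - a[, 1]) * (b[, 2] - p[, 2]) -
            (p[, 2] - a[, 2]) * (b[, 1] - p[, 1])
  ang <- ifelse(crossz < 0, 360 - ang, ang)
  structure(list(angles = ang, window_fraction = window_fraction,
                 n_index = n_index, anchored = FALSE, apex = NA_integer_),
            class = "angle_profile")
}

#' @export
print.angle_profile <- function(x, ...) {
  cat(sprintf("<angle_profile> %d indices, window %.3f, min %.1f deg%s\n",
              x$n_index, x$window_fraction, min(x$angles),
              if (isTRUE(x$anchored)) " (anchored at hook apex)" else ""))
  invisible(x)
}

#' Locate the hook apex and anchor the profile there
#'
#' The hook apex is the sharpest point of the falciform head: the global
#' minimum of the interior-angle profile. Ties are broken by the earliest
#' position in traversal order. The returned profile is rotated so the apex
#' becomes index 0. A near-constant profile (range below `min_range`
#' degrees, e.g. a circle) carries no landmark and is an error.
#'
#' @param x an `angle_profile`, or an `outline` (profiled with defaults).
#' @param min_range minimum profile range (degrees) for a usable landmark.
#' @param ... passed to [angle_profile()] when `x` is an outline.
#' @return the anchored `angle_profile`; element `apex` holds the 0-based
#'   raw index of the apex before rotation.
#' @export
detect_hook_apex <- function(x, min_range = 5, ...) {
  prof <- if (inherits(x, "angle_profile")) x else angle_profile(x, ...)
  rng <- max(prof$angles) - min(prof$angles)
  if (rng < min_range)
    stop("no landmark: angle profile is near-constant (range ",
         sprintf("%.2f", rng), " deg)")
  i <- which.min(prof$angles)  # which.min takes the earliest tie
  prof$apex <- i - 1L
  prof$angles <- prof$angles[c(i:length(prof$angles), seq_len(i - 1L))]
  prof$anchored <- TRUE
  prof
}

#' Standard morphometric parameters of a nucleus outline
#'
#' Area by the shoelace formula; perimeter by arc length; length as the
#' maximum caliper (Feret) diameter; width as the extent perpendicular to
#' the length axis; circularity = 4 * pi * area / perimeter^2 (1 for a
#' circle); regularity = area / (pi * length * width / 4), the ratio of the
#' area to that of the bounding ellipse on the same axes (1 for an
#' ellipse); and the minimum of the interior-angle profile. Circularity and
#' regularity are size-independent; the linear measures and area are not.
#'
#' @param x an `outline` (must be simple; checked).
#' @param window_fraction,n_index passed to [angle_profile()] for min_angle.
#' @return a one-row data.frame: area, perimeter, length, width, min_angle,
#'   circularity, regularity.
#' @export
morph_stats <- function(x, window_fraction = 0.05, n_index = 100) {
  v <- as_vertices(x)
  if (!is_simple_polygon(v)) stop("outline is self-intersecting")
  area <- polygon_area(v)
  per <- polygon_perimeter(v)
  hull <- v[chull(v), , drop = FALSE]
  dm <- as.matrix(dist(hull))
  ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  axis <- hull[ij[2], ] - hull[ij[1], ]
  len <- sqrt(sum(axis^2))
  perp <- c(-axis[2], axis[1]) / len
  proj <- as.numeric(v %*% perp)
  wid <- diff(range(proj))
  prof <- angle_profile(x, window_fraction = window_fraction, n_index = n_index)
  data.frame(area = area, perimeter = per, length = len, width = wid,
             min_angle = min(prof$angles),
             circularity = 4 * pi * area / per^2,
             regularity = area / (pi * len * wid / 4))
}

#' Morphometry table for a synthetic population
#'
#' Computes [morph_stats()] plus the measured acrosome curvature proxy
#' (180 minus the mean interior angle over the dorsal quarter of the
#' profile) for every cell of a `nucleus_population`.
#'
#' @param pop a `nucleus_population`.
#' @param window_fraction,n_index profile settings.
#' @return data.frame: id, genotype, sex, then the morphometric columns.
#' @export
population_morphometry <- function(pop, window_fraction = 0.05, n_index = 100) {
  stopifnot(inherits(pop, "nucleus_population"))
  stats_list <- lapply(pop$outlines, function(o) {
    st <- morph_stats(o, window_fraction = window_fraction, n_index = n_index)
    pr <- detect_hook_apex(angle_profile(o, window_fraction = window_fraction,
                                         n_index = n_index))
    # dorsal quarter: indices just past the apex, where the acrosomal
    # concavity of the generator lives
    dorsal <- pr$angles[seq(floor(n_index * 0.05) + 1, ceiling(n_index * 0.3))]
    st$dorsal_curvature <- 180 - mean(dorsal)
    st
  })
  cbind(pop$cells[, c("id", "genotype", "sex")], do.call(rbind, stats_list))
}

#' Anchored angle-profile matrix for a set of outlines
#'
#' Computes the apex-anchored angle profile of every outline and stacks
#' them as a matrix (one row per cell), the feature matrix used for
#' embedding and clustering.
#'
#' @param outlines list of `outline`s, or a `nucleus_population`.
#' @param window_fraction,n_index profile settings.
#' @return numeric matrix, cells by `n_index`.
#' @export
profile_matrix <- function(outlines, window_fraction = 0.05, n_index = 100) {
  if (inherits(outlines, "nucleus_population")) outlines <- outlines$outlines
  t(vapply(outlines, function(o) {
    detect_hook_apex(angle_profile(o, window_fraction = window_fraction,
                                   n_index = n_index))$angles
  }, numeric(n_index)))
}

#' Compare X- and Y-bearing cells parameter by parameter
#'
#' Wilcoxon rank-sum test of X versus Y cells for each requested parameter,
#' within each genotype, with Bonferroni correction across parameters
#' (within genotype) and a significance flag at adjusted p < 0.01 — the
#' convention used for sperm morphometry comparisons.
#'
#' @param measurements data.frame with columns genotype, sex, and the
#'   parameter columns (e.g. from [population_morphometry()]).
#' @param parameters character vector of parameter column names; default is
#'   every numeric column.
#' @param alpha flag threshold on the Bonferroni-adjusted p-value.
#' @return tidy data.frame: genotype, parameter, n_x, n_y, median_x,
#'   median_y, statistic, p, p_adjusted, flag.
#' @export
compare_xy <- function(measurements, parameters = NULL, alpha = 0.01) {
  stopifnot(all(c("genotype", "sex") %in% names(measurements)))
  if (is.null(parameters)) {
    num <- vapply(measurements, is.numeric, logical(1))
    parameters <- setdiff(names(measurements)[num], c("genotype", "sex"))
  }
  out <- list()
  for (gt in unique(measurements$genotype)) {
    sub <- measurements[measurements$genotype == gt, ]
    if (!all(c("X", "Y") %in% sub$sex))
      stop("genotype ", gt, ": both sex labels must be present")
    rows <- lapply(parameters, function(p) {
      xs <- sub[[p]][sub$sex == "X"]
      ys <- sub[[p]][sub$sex == "Y"]
      wt <- wilcoxon_ranksum(xs, ys)
      data.frame(genotype = gt, parameter = p, n_x = length(xs),
                 n_y = length(ys), median_x = median(xs), median_y = median(ys),
                 statistic = wt$statistic, p = wt$p,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$p_adjusted <- pmin(tab$p * length(parameters), 1)
    tab$flag <- tab$p_adjusted < alpha
    out[[gt]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
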