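#' Shape parameters for a parametric falciform sperm-head outline
#'
#' The generator models the hook-shaped (falciform) mouse sperm nucleus as a
#' star-shaped radial perturbation of an ellipse: an elliptical body, a
#' narrow radial spike forming the apical hook, a dorsal concavity whose
#' depth sets the acrosomal curvature, and a width modulation at the caudal
#' base. Each knob maps to one of the morphological effects reported for
#' Yq-deficient sperm (hook shortening, increased acrosomal curvature, area
#' reduction, base-width change) so effects can be planted independently.
#'
#' @param body_length,body_width nuclear body axes, micrometres.
#' @param hook_length radial extent of the apical hook beyond the body, um.
#' @param acrosome_curvature dimensionless >= 0; depth of the dorsal
#'   concavity (sharper curvature of the acrosomal edge as it increases).
#' @param base_width caudal base width, um.
#' @param area_scale dimensionless > 0 multiplier on cross-sectional area.
#' @return a `shape_params` list.
#' @export
shape_params <- function(body_length = 8, body_width = 4.2, hook_length = 3,
                         acrosome_curvature = 0.5, base_width = 4,
                         area_scale = 1) {
  p <- list(body_length = body_length, body_width = body_width,
            hook_length = hook_length, acrosome_curvature = acrosome_curvature,
            base_width = base_width, area_scale = area_scale)
  for (nm in c("body_length", "body_width", "base_width")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0)
      stop(sprintf("invalid shape parameter: %s must be a positive length", nm))
  }
  if (p$hook_length < 0) stop("invalid shape parameter: hook_length must be >= 0")
  if (p$acrosome_curvature < 0)
    stop("invalid shape parameter: acrosome_curvature must be >= 0")
  if (p$area_scale <= 0) stop("invalid shape parameter: area_scale must be > 0")
  structure(p, class = "shape_params")
}

#' Names of the six shape parameters
#' @return character vector of parameter names in canonical order.
#' @export
shape_param_names <- function() {
  c("body_length", "body_width", "hook_length", "acrosome_curvature",
    "base_width", "area_scale")
}

# shortest signed angular difference
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Generate one synthetic sperm-nucleus outline
#'
#' Produces a simple, closed, counterclockwise polygon whose sharpest point
#' (global minimum of the sliding-window interior-angle profile) sits at the
#' hook apex. A small seeded low-order Fourier perturbation of the radius
#' gives cell-to-cell texture without breaking star-shapedness, so the
#' polygon is simple by construction. The same parameters and seed always
#' return the identical vertex list.
#'
#' @param params a [shape_params()] object.
#' @param seed integer seed for the radial perturbation; `NULL` for none.
#' @param n_vertices number of polygon vertices (>= 200).
#' @param jitter_sd amplitude of the radial Fourier perturbation relative
#'   to the body half-width.
#' @return an `outline`; attribute `apex_index` marks the planted hook-tip
#'   vertex, attribute `params` carries the generating parameters.
#' @export
generate_shape <- function(params = shape_params(), seed = NULL,
                           n_vertices = 400, jitter_sd = 0.004) {
  if (!inherits(params, "shape_params")) params <- do.call(shape_params, as.list(params))
  if (n_vertices < 200) stop("n_vertices must be >= 200")
  a <- params$body_length / 2
  b <- params$body_width / 2
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  # elliptical body radius
  r <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  # caudal base width modulation (around th = pi)
  base_ratio <- params$base_width / params$body_width
  r <- r * (1 + (base_ratio - 1) * exp(-0.5 * (ang_diff(th, pi) / 0.7)^2))
  # apical hook: narrow radial spike at th = 0, much sharper than any
  # acrosomal concavity so the apex is always the global profile minimum.
  # The spike width scales with its length (self-similar tip), so hook
  # length varies the hook's extent, not the sharpness of its apex.
  sigma_h <- 0.04 + 0.08 * params$hook_length / 3
  r <- r + params$hook_length * exp(-0.5 * (ang_diff(th, 0) / sigma_h)^2)
  # dorsal acrosomal concavity between hook and mid-body: a broad, gentle
  # flattening of the dorsal edge (narrow notches are dominated by angle
  # noise; the biological effect is a smooth change of edge curvature)
  dip <- params$acrosome_curvature * 0.45 * b *
    exp(-0.5 * (ang_diff(th, 1.3) / 0.8)^2)
  # soft floor: deep dips saturate smoothly instead of clipping, so there
  # is no discrete shape regime at extreme curvature
  floor_r <- 0.15 * b; tsc <- 0.1 * b
  r <- floor_r + tsc * log1p(exp((r - dip - floor_r) / tsc))
  if (!is.null(seed) && jitter_sd > 0) {
    per <- with_seed(seed, {
      amp <- rnorm(5, 0, jitter_sd * b)
      ph <- runif(5, 0, 2 * pi)
      rowSums(sapply(1:5, function(k) amp[k] * cos((k + 1) * th + ph[k])))
    })
    r <- pmax(r + per, 0.1 * b)
  }
  r <- r * sqrt(params$area_scale)
  v <- cbind(r * cos(th), r * sin(th))
  out <- outline(v)
  attr(out, "apex_index") <- 1L
  attr(out, "params") <- params
  out
}

#' Population specification for the synthetic generator
#'
#' Describes one genotype cohort. Per-cell parameters are drawn as
#' independent Gaussians around the wild-type baseline shifted by
#' `genotype_effect` for every cell and additionally by `sex_effect` for
#' Y-bearing cells only (wild type ignores `sex_effect`, so X and Y cells
#' are exchangeable there). Latent X/Y labels are Bernoulli(0.5), matching
#' the equal production of X- and Y-bearing sperm by normal meiosis.
#'
#' Default effect sizes for the mutant genotypes are calibrated so that the
#' full profile-clustering pipeline recovers X-enrichment of normal-shaped
#' clusters in the high-50s percent range; they are a tuning target for the
#' pipeline, not measured biology.
#'
#' @param genotype one of "WT", "YQDEL", "SHSLY".
#' @param n_cells number of cells (> 0).
#' @param sex_effect named numeric: additive shift applied to Y-bearing
#'   cells only (same names as [shape_params()]).
#' @param genotype_effect named numeric: additive shift applied to all cells.
#' @param noise_sd named numeric: within-population SD per parameter.
#' @param seed integer seed.
#' @param base_params baseline [shape_params()] (wild-type means).
#' @return a `population_spec` list.
#' @export
population_spec <- function(genotype = c("WT", "YQDEL", "SHSLY"), n_cells = 500,
                            sex_effect = NULL, genotype_effect = NULL,
                            noise_sd = NULL, seed = 1,
                            base_params = shape_params()) {
  genotype <- match.arg(genotype)
  if (!is.numeric(n_cells) || n_cells <= 0) stop("n_cells must be > 0")
  zero <- setNames(numeric(6), shape_param_names())
  def_noise <- c(body_length = 0.35, body_width = 0.2, hook_length = 0.15,
                 acrosome_curvature = 0.35, base_width = 0.25, area_scale = 0.06)
  def_gt <- switch(genotype,
    WT = zero,
    YQDEL = c(body_length = -0.35, body_width = -0.12, hook_length = -0.25,
              acrosome_curvature = 0.6, base_width = -0.25, area_scale = -0.10),
    SHSLY = c(body_length = -0.6, body_width = -0.2, hook_length = -0.4,
              acrosome_curvature = 0.95, base_width = -0.4, area_scale = -0.15))
  def_sex <- switch(genotype,
    WT = zero,
    YQDEL = c(body_length = -0.07, body_width = -0.02, hook_length = -0.04,
              acrosome_curvature = 0.11, base_width = -0.055, area_scale = -0.015),
    SHSLY = c(body_length = -0.1, body_width = -0.03, hook_length = -0.06,
              acrosome_curvature = 0.155, base_width = -0.08, area_scale = -0.02))
  fill <- function(x, def) {
    out <- def
    if (!is.null(x)) {
      bad <- setdiff(names(x), shape_param_names())
      if (length(bad)) stop("unknown shape parameter(s): ", paste(bad, collapse = ", "))
      out[names(x)] <- x
    }
    out[shape_param_names()]
  }
  structure(list(genotype = genotype, n_cells = as.integer(n_cells),
                 sex_effect = fill(sex_effect, def_sex),
                 genotype_effect = fill(genotype_effect, def_gt),
                 noise_sd = fill(noise_sd, def_noise),
                 seed = seed, base_params = base_params),
            class = "population_spec")
}

#' Generate a population of nucleus records
#'
#' Draws per-cell shape parameters per the specification, generates each
#' outline, and returns a `nucleus_population`: a parameter table plus the
#' outlines. Wild-type populations ignore `sex_effect`, so X- and Y-labelled
#' cells are identically distributed there.
#'
#' @param spec a [population_spec()].
#' @param make_outlines generate the outlines (default); `FALSE` returns
#'   only the parameter table, for parameter-level simulations.
#' @return a `nucleus_population` list with `cells` (data.frame: id,
#'   genotype, sex, true parameters) and `outlines` (list of `outline`).
#' @export
generate_population <- function(spec, make_outlines = TRUE) {
  if (!inherits(spec, "population_spec")) stop("spec must be a population_spec")
  n <- spec$n_cells
  pn <- shape_param_names()
  base <- unlist(spec$base_params[pn])
  with_seed(spec$seed, {
    sex <- ifelse(runif(n) < 0.5, "X", "Y")
    par_mat <- matrix(rep(base, each = n), n, 6, dimnames = list(NULL, pn))
    par_mat <- par_mat + matrix(rep(spec$genotype_effect, each = n), n, 6)
    if (spec$genotype != "WT") {
      isy <- sex == "Y"
      par_mat[isy, ] <- par_mat[isy, , drop = FALSE] +
        matrix(rep(spec$sex_effect, each = sum(isy)), sum(isy), 6)
    }
    par_mat <- par_mat + matrix(rnorm(n * 6), n, 6) %*% diag(spec$noise_sd)
    colnames(par_mat) <- pn
    # keep parameters physically valid
    par_mat[, "body_length"] <- pmax(par_mat[, "body_length"], 2)
    par_mat[, "body_width"] <- pmax(par_mat[, "body_width"], 1.5)
    par_mat[, "hook_length"] <- pmax(par_mat[, "hook_length"], 0)
    par_mat[, "acrosome_curvature"] <- pmax(par_mat[, "acrosome_curvature"], 0)
    par_mat[, "base_width"] <- pmax(par_mat[, "base_width"], 1.5)
    par_mat[, "area_scale"] <- pmax(par_mat[, "area_scale"], 0.3)
    cell_seeds <- sample.int(2147483646L, n)
    outlines <- if (make_outlines) lapply(seq_len(n), function(i) {
      generate_shape(do.call(shape_params, as.list(par_mat[i, ])),
                     seed = cell_seeds[i])
    }) else NULL
    cells <- data.frame(id = sprintf("%s_%04d", spec$genotype, seq_len(n)),
                        genotype = spec$genotype, sex = sex,
                        as.data.frame(par_mat), stringsAsFactors = FALSE)
    structure(list(cells = cells, outlines = outlines, spec = spec),
              class = "nucleus_population")
  })
}

#' @export
print.nucleus_population <- function(x, ...) {
  cat(sprintf("<nucleus_population> %s: %d cells (%d X, %d Y)\n",
              x$spec$genotype, nrow(x$cells), sum(x$cells$sex == "X"),
              sum(x$cells$sex == "Y")))
  invisible(x)
}

#' Rasterize an outline to a noisy grayscale image
#'
#' Renders a filled polygon on a pixel grid (pixel centres at
#' (i - 1/2, j - 1/2) * pixel_size, j increasing upward), applies Gaussian
#' blur, then additive Gaussian noise — emulating a DAPI-stained nucleus on
#' a dark background. Intensities are clamped to [0, 1]; the same inputs
#' and seed give a bit-identical image.
#'
#' @param x an `outline`.
#' @param pixel_size micrometres per pixel.
#' @param blur_sd Gaussian blur SD in pixels.
#' @param noise_sd additive noise SD on the [0, 1] intensity scale.
#' @param background,foreground background and nucleus intensities in [0, 1].
#' @param dims optional c(nx, ny) canvas in pixels; default fits the outline
#'   with a 15% margin. An outline exceeding the canvas is an error.
#' @param origin optional c(x, y) um of the pixel grid origin; default
#'   places the outline centrally.
#' @param seed integer seed for the noise.
#' @return a `gray_image`: numeric matrix (nx by ny, `[x, y]` indexing) in
#'   [0, 1] with attributes `pixel_size` and `origin`.
#' @export
rasterize <- function(x, pixel_size = 0.1, blur_sd = 1, noise_sd = 0.02,
                      background = 0.1, foreground = 0.85, dims = NULL,
                      origin = NULL, seed = NULL) {
  v <- as_vertices(x)
  if (nrow(v) < 3) stop("blank or degenerate outline")
  rng <- apply(v, 2, range)
  span <- rng[2, ] - rng[1, ]
  if (is.null(dims)) {
    margin <- 0.15 * max(span)
    dims <- ceiling((span + 2 * margin) / pixel_size)
    origin <- rng[1, ] - margin
  } else if (is.null(origin)) {
    origin <- rng[1, ] - (dims * pixel_size - span) / 2
  }
  dims <- as.integer(dims)
  # reject outlines that stick out of the canvas
  vv <- sweep(v, 2, origin)
  if (any(vv < 0) || any(vv[, 1] > dims[1] * pixel_size) ||
      any(vv[, 2] > dims[2] * pixel_size))
    stop("outline exceeds the image canvas")
  cx <- (seq_len(dims[1]) - 0.5) * pixel_size
  cy <- (seq_len(dims[2]) - 0.5) * pixel_size
  gx <- rep(cx, times = dims[2])
  gy <- rep(cy, each = dims[1])
  inside <- pracma::inpolygon(gx, gy, vv[, 1], vv[, 2], boundary = TRUE)
  img <- matrix(ifelse(inside, foreground, background), dims[1], dims[2])
  if (blur_sd > 0) {
    w <- 2L * ceiling(3 * blur_sd) + 1L
    br <- EBImage::makeBrush(w, shape = "gaussian", sigma = blur_sd)
    img <- EBImage::filter2(img, br, boundary = "replicate")
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(rnorm(length(img), 0, noise_sd),
                                        nrow(img), ncol(img)))
  }
  img <- pmin(pmax(img, 0), 1)
  gray_image(img, pixel_size = pixel_size, origin = origin)
}

#' Grayscale image container
#'
#' A plain numeric matrix in `[x, y]` indexing with intensities in [0, 1],
#' plus the physical pixel size. y increases upward (mathematical frame).
#'
#' @param pixels numeric matrix.
#' @param pixel_size micrometres per pixel.
#' @param origin physical coordinate of the (0, 0) pixel corner, um.
#' @return a `gray_image`.
#' @export
gray_image <- function(pixels, pixel_size = 0.1, origin = c(0, 0)) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(pixels) == 0) stop("empty image")
  structure(pixels, pixel_size = pixel_size, origin = origin,
            class = c("gray_image", class(pixels)))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.3g um/px\n", nrow(x), ncol(x),
              attr(x, "pixel_size")))
  invisible(x)
}

#' Swim-up experiment specification and count generator
#'
#' Simulates X/Y FISH scoring of swim-up motility fractions: for each male,
#' live/killed state, and fraction 1..n_fractions (increasing motility), the
#' X-bearing count is Binomial(cells, p) with logit(p) linear in the
#' fraction index. Killed (freeze/thaw) sperm are the negative control and
#' use slope zero regardless of genotype. Per-male intercepts get a small
#' Gaussian wobble so males are replicates, not clones.
#'
#' @param n_males males per genotype.
#' @param genotypes character vector of genotype names.
#' @param n_fractions fractions per run (default 6).
#' @param cells_per_fraction cells scored per slide (default 400).
#' @param logit_intercept baseline log-odds of an X-bearing cell.
#' @param logit_slope_per_fraction named numeric, one slope per genotype
#'   (log-odds change per fraction step for live sperm).
#' @param male_sd SD of the per-male intercept wobble.
#' @param states which states to simulate.
#' @param seed integer seed.
#' @return `generate_swimup_counts` returns a data.frame with columns
#'   male_id, genotype, state, fraction, x_count, y_count.
#' @export
swimup_spec <- function(n_males = 10, genotypes = c("WT", "YQDEL"),
                        n_fractions = 6, cells_per_fraction = 400,
                        logit_intercept = 0,
                        logit_slope_per_fraction = c(WT = 0, YQDEL = 0.15),
                        male_sd = 0.05, states = c("live", "killed"),
                        seed = 1) {
  if (n_males <= 0 || n_fractions <= 0 || cells_per_fraction <= 0)
    stop("n_males, n_fractions and cells_per_fraction must be > 0")
  missing_gt <- setdiff(genotypes, names(logit_slope_per_fraction))
  if (length(missing_gt))
    stop("no slope given for genotype(s): ", paste(missing_gt, collapse = ", "))
  structure(list(n_males = as.integer(n_males), genotypes = genotypes,
                 n_fractions = as.integer(n_fractions),
                 cells_per_fraction = as.integer(cells_per_fraction),
                 logit_intercept = logit_intercept,
                 logit_slope_per_fraction = logit_slope_per_fraction,
                 male_sd = male_sd, states = states, seed = seed),
            class = "swimup_spec")
}

#' @rdname swimup_spec
#' @param spec a `swimup_spec`.
#' @export
generate_swimup_counts <- function(spec = swimup_spec()) {
  if (!inherits(spec, "swimup_spec")) stop("spec must be a swimup_spec")
  with_seed(spec$seed, {
    rows <- list()
    for (gt in spec$genotypes) {
      slope <- spec$logit_slope_per_fraction[[gt]]
      for (m in seq_len(spec$n_males)) {
        male_int <- spec$logit_intercept + rnorm(1, 0, spec$male_sd)
        for (st in spec$states) {
          sl <- if (st == "killed") 0 else slope
          # centre the trend on the mid fraction so the pooled proportion
          # stays near the intercept whatever the slope
          eta <- male_int + sl * (seq_len(spec$n_fractions) -
                                    (spec$n_fractions + 1) / 2)
          p <- plogis(eta)
          xk <- rbinom(spec$n_fractions, spec$cells_per_fraction, p)
          rows[[length(rows) + 1]] <- data.frame(
            male_id = sprintf("%s_m%02d", gt, m), genotype = gt, state = st,
            fraction = seq_len(spec$n_fractions), x_count = xk,
            y_count = spec$cells_per_fraction - xk, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate midpiece-length samples for two swim-up fractions
#'
#' Gaussian lengths for the best-swimming (top) and poorest-swimming
#' (bottom) fractions, with the top mean exceeding the bottom mean by
#' `shift` in expectation — emulating MitoTracker midpiece measurements.
#'
#' @param n_top,n_bottom sample sizes (> 0).
#' @param shift mean difference top minus bottom, um.
#' @param mean_bottom bottom-fraction mean midpiece length, um.
#' @param sd within-group SD, um.
#' @param seed integer seed.
#' @return list with numeric vectors `top` and `bottom`.
#' @export
generate_midpiece_lengths <- function(n_top, n_bottom, shift = 0,
                                      mean_bottom = 21, sd = 0.8, seed = 1) {
  if (n_top <= 0 || n_bottom <= 0) stop("n_top and n_bottom must be > 0")
  with_seed(seed, list(top = rnorm(n_top, mean_bottom + shift, sd),
                       bottom = rnorm(n_bottom, mean_bottom, sd)))
}
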