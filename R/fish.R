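#' A captured image with stage coordinates
#'
#' One micrograph of a nucleus together with the recorded motorized-stage
#' position, slide identity and capture phase (pre-FISH morphology image or
#' post-FISH sex-typed image). Stage coordinates allow re-identification of
#' the same physical cell across the two imaging rounds.
#'
#' @param image a `gray_image` (or numeric matrix).
#' @param stage_xy numeric length-2 stage coordinates, micrometres.
#' @param slide_id slide identifier.
#' @param phase "pre" or "post".
#' @param id image identifier.
#' @return a `captured_image`.
#' @export
captured_image <- function(image, stage_xy, slide_id = "slide1",
                           phase = c("pre", "post"), id = NULL) {
  phase <- match.arg(phase)
  if (length(stage_xy) != 2 || any(!is.finite(stage_xy)))
    stop("stage_xy must be two finite coordinates")
  structure(list(image = image, stage_xy = as.numeric(stage_xy),
                 slide_id = slide_id, phase = phase, id = id),
            class = "captured_image")
}

#' Candidate pre/post pairs within a stage-coordinate radius
#'
#' All cross-phase pairs whose recorded stage positions lie within
#' `radius` micrometres, sorted by coordinate distance. Pairing across
#' different slides is an error (stage coordinates are only comparable
#' within one slide).
#'
#' @param pre,post lists of `captured_image` (phases "pre" and "post").
#' @param radius pairing radius, micrometres.
#' @return data.frame: pre_id, post_id, distance.
#' @export
pair_by_coordinates <- function(pre, post, radius) {
  slides <- unique(c(vapply(pre, `[[`, "", "slide_id"),
                     vapply(post, `[[`, "", "slide_id")))
  if (length(slides) > 1)
    stop("mixed slides: coordinate pairing requires a single slide_id, got ",
         paste(slides, collapse = ", "))
  pre_xy <- t(vapply(pre, `[[`, numeric(2), "stage_xy"))
  post_xy <- t(vapply(post, `[[`, numeric(2), "stage_xy"))
  pre_id <- vapply(seq_along(pre), function(i)
    if (is.null(pre[[i]]$id)) sprintf("pre_%03d", i) else as.character(pre[[i]]$id), "")
  post_id <- vapply(seq_along(post), function(i)
    if (is.null(post[[i]]$id)) sprintf("post_%03d", i) else as.character(post[[i]]$id), "")
  g <- expand.grid(i = seq_along(pre), j = seq_along(post))
  d <- sqrt((pre_xy[g$i, 1] - post_xy[g$j, 1])^2 +
            (pre_xy[g$i, 2] - post_xy[g$j, 2])^2)
  keep <- d <= radius
  out <- data.frame(pre_id = pre_id[g$i[keep]], post_id = post_id[g$j[keep]],
                    distance = d[keep], stringsAsFactors = FALSE)
  out[order(out$distance, out$pre_id, out$post_id), , drop = FALSE]
}

#' Structural similarity (SSIM) between two images
#'
#' Standard SSIM with an 11x11 Gaussian window (sigma 1.5) and stability
#' constants C1 = (K1 L)^2, C2 = (K2 L)^2, averaged over `levels` dyadic
#' downscalings (each level blurs and decimates by two). Identical images
#' score 1; the score is symmetric and, within the tolerance set by the
#' constants, invariant to a common affine intensity rescale.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @param levels number of dyadic scales to average over.
#' @param dynamic_range intensity range L of the data (1 for [0, 1] images).
#' @param window_size,window_sigma Gaussian window parameters, pixels.
#' @return scalar similarity in [-1, 1].
#' @export
ssim_score <- function(a, b, levels = 3, dynamic_range = 1,
                       window_size = 11, window_sigma = 1.5) {
  a <- unclass(as.matrix(a)); b <- unclass(as.matrix(b))
  attributes(a) <- list(dim = dim(a)); attributes(b) <- list(dim = dim(b))
  if (!all(dim(a) == dim(b)))
    stop("dimension mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  scores <- numeric(levels)
  for (lev in seq_len(levels)) {
    if (min(dim(a)) < window_size) {
      scores <- scores[seq_len(lev - 1)]
      break
    }
    scores[lev] <- ssim_single(a, b, dynamic_range, window_size, window_sigma)
    if (lev < levels) {
      a <- downsample2(a); b <- downsample2(b)
    }
  }
  if (!length(scores)) stop("images smaller than the SSIM window")
  mean(scores)
}

ssim_single <- function(a, b, L, wsize, wsigma) {
  w <- EBImage::makeBrush(wsize, shape = "gaussian", sigma = wsigma)
  f <- function(m) EBImage::filter2(m, w, boundary = "replicate")
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  mu_a <- f(a); mu_b <- f(b)
  va <- f(a * a) - mu_a^2
  vb <- f(b * b) - mu_b^2
  vab <- f(a * b) - mu_a * mu_b
  smap <- ((2 * mu_a * mu_b + c1) * (2 * vab + c2)) /
          ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(smap)
}

downsample2 <- function(m) {
  br <- EBImage::makeBrush(5, shape = "gaussian", sigma = 1)
  m <- EBImage::filter2(m, br, boundary = "replicate")
  m[seq(1, nrow(m), by = 2), seq(1, ncol(m), by = 2), drop = FALSE]
}

# Pad or crop image b's matrix to the dimensions of a, centred, filling
# with the median border intensity of b.
match_dims <- function(m, dims) {
  if (all(dim(m) == dims)) return(m)
  fill <- median(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
  out <- matrix(fill, dims[1], dims[2])
  sx <- min(nrow(m), dims[1]); sy <- min(ncol(m), dims[2])
  ox_m <- (nrow(m) - sx) %/% 2; oy_m <- (ncol(m) - sy) %/% 2
  ox_o <- (dims[1] - sx) %/% 2; oy_o <- (dims[2] - sy) %/% 2
  out[ox_o + seq_len(sx), oy_o + seq_len(sy)] <-
    m[ox_m + seq_len(sx), oy_m + seq_len(sy)]
  out
}

#' Score candidate pairs and assign one-to-one matches
#'
#' `score_candidates` computes the SSIM between the images of every
#' candidate pair (padding/cropping the post image to the pre image's
#' canvas). `assign_matches` then greedily accepts pairs in order of
#' descending similarity — ties broken by lowest pre id, then post id —
#' skipping any pair whose pre or post image is already matched, and
#' rejecting pairs below `min_similarity`. The accepted set is one-to-one
#' by construction.
#'
#' @param candidates data.frame from [pair_by_coordinates()]; for
#'   `assign_matches` it must carry a `similarity` column.
#' @param pre,post lists of `captured_image` (ids must match candidates).
#' @param levels passed to [ssim_score()].
#' @param scales candidate shrink factors applied to the post image before
#'   scoring; the best score over scales is kept. FISH swelling dilates the
#'   nucleus by roughly 10%, and SSIM is sensitive to that misregistration,
#'   so undoing the scale change before comparing is part of the matcher.
#' @param min_similarity acceptance threshold.
#' @return `score_candidates`: candidates with a `similarity` column.
#'   `assign_matches`: data.frame pre_id, post_id, distance, similarity,
#'   accepted (only accepted rows returned).
#' @export
score_candidates <- function(candidates, pre, post, levels = 3,
                             scales = c(0.85, 0.9, 0.95, 1)) {
  pre_ids <- vapply(seq_along(pre), function(i)
    if (is.null(pre[[i]]$id)) sprintf("pre_%03d", i) else as.character(pre[[i]]$id), "")
  post_ids <- vapply(seq_along(post), function(i)
    if (is.null(post[[i]]$id)) sprintf("post_%03d", i) else as.character(post[[i]]$id), "")
  candidates$similarity <- vapply(seq_len(nrow(candidates)), function(r) {
    ia <- as.matrix(unclass(pre[[match(candidates$pre_id[r], pre_ids)]]$image))
    ib <- as.matrix(unclass(post[[match(candidates$post_id[r], post_ids)]]$image))
    attributes(ia) <- list(dim = dim(ia)); attributes(ib) <- list(dim = dim(ib))
    max(vapply(scales, function(s) {
      ibs <- if (s == 1) ib else
        EBImage::resize(ib, w = max(round(nrow(ib) * s), 8),
                        h = max(round(ncol(ib) * s), 8))
      ssim_score(ia, match_dims(ibs, dim(ia)), levels = levels)
    }, numeric(1)))
  }, numeric(1))
  candidates
}

#' @rdname score_candidates
#' @export
assign_matches <- function(candidates, min_similarity = 0.5) {
  if (!"similarity" %in% names(candidates))
    stop("candidates must be scored first (see score_candidates)")
  ord <- order(-candidates$similarity, candidates$pre_id, candidates$post_id)
  cand <- candidates[ord, , drop = FALSE]
  used_pre <- character(0); used_post <- character(0)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (cand$similarity[r] < min_similarity) next
    if (cand$pre_id[r] %in% used_pre || cand$post_id[r] %in% used_post) next
    keep[r] <- TRUE
    used_pre <- c(used_pre, cand$pre_id[r])
    used_post <- c(used_post, cand$post_id[r])
  }
  res <- cand[keep, , drop = FALSE]
  res$accepted <- rep(TRUE, nrow(res))
  rownames(res) <- NULL
  res
}

#' Emulate the FISH swelling distortion on an image
#'
#' The chromatin swelling required for FISH probe penetration distorts the
#' detailed head morphology between the two imaging rounds. The fixture
#' model is an isotropic ~10% dilation (image upscaling about the centre)
#' followed by Gaussian blur and fresh noise.
#'
#' @param image a `gray_image` or matrix.
#' @param dilation linear scale factor (1.1 = 10% swelling).
#' @param blur_sd Gaussian blur SD, pixels.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed for the noise.
#' @return matrix of the same dimensions.
#' @export
fish_distort <- function(image, dilation = 1.1, blur_sd = 1.5,
                         noise_sd = 0.02, seed = NULL) {
  m <- as.matrix(unclass(image))
  attributes(m) <- list(dim = dim(m))
  big <- EBImage::resize(m, w = round(nrow(m) * dilation),
                         h = round(ncol(m) * dilation))
  out <- match_dims(big, dim(m))
  if (blur_sd > 0) {
    br <- EBImage::makeBrush(2L * ceiling(3 * blur_sd) + 1L, "gaussian",
                             sigma = blur_sd)
    out <- EBImage::filter2(out, br, boundary = "replicate")
  }
  if (noise_sd > 0)
    out <- out + with_seed(seed, matrix(rnorm(length(out), 0, noise_sd),
                                        nrow(out), ncol(out)))
  pmin(pmax(out, 0), 1)
}
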