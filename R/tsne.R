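# Exact-gradient t-SNE (Student-t stochastic neighbour embedding).
#
# Direct implementation of the standard algorithm: Gaussian input
# affinities with per-point bandwidths calibrated to a target perplexity by
# bisection, symmetrized and normalized; 2D Student-t output kernel;
# gradient descent with momentum (0.5 then 0.8), adaptive per-dimension
# gains, and early exaggeration of the input affinities for the first 250
# iterations. O(n^2) memory and time per iteration, which is ample at the
# dataset sizes used for angle-profile work.

tsne_affinities <- function(x, perplexity, tol = 1e-5, max_tries = 50) {
  n <- nrow(x)
  ss <- rowSums(x^2)
  d2 <- outer(ss, ss, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf
  logu <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; bmin <- -Inf; bmax <- Inf
    di <- d2[i, ]
    for (tr in seq_len(max_tries)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0; pi_ <- w }
      else {
        pi_ <- w / sw
        h <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
      }
      hdiff <- h - logu
      if (abs(hdiff) < tol) break
      if (hdiff > 0) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else           { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    p[i, ] <- pi_
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, .Machine$double.xmin)
}

tsne_embed <- function(x, perplexity = 30, max_iter = 1000, seed = NULL,
                       eta = 200, momentum = 0.5, final_momentum = 0.8,
                       mom_switch = 250, exaggeration = 12, stop_lying = 250) {
  n <- nrow(x)
  p <- tsne_affinities(x, perplexity)
  p_ex <- p * exaggeration
  y <- with_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (iter in seq_len(max_iter)) {
    pp <- if (iter <= stop_lying) p_ex else p
    ss <- rowSums(y^2)
    num <- 1 / (1 + outer(ss, ss, "+") - 2 * tcrossprod(y))
    diag(num) <- 0
    q <- pmax(num / sum(num), .Machine$double.xmin)
    l <- (pp - q) * num
    grad <- 4 * (diag(rowSums(l)) - l) %*% y
    mom <- if (iter <= mom_switch) momentum else final_momentum
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- mom * inc - eta * gains * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  y
}

#' Embed angle profiles in two dimensions with t-SNE
#'
#' Runs t-SNE (exact gradient, Student-t output kernel) on a matrix of
#' angle profiles. With the same inputs and seed the embedding is
#' bit-identical. The defaults (perplexity 100, 1000 iterations) match the
#' settings used for sperm angle-profile work; at least `3 * perplexity`
#' profiles are required for the perplexity calibration to be meaningful.
#'
#' @param profiles list of `angle_profile`s, or a numeric matrix with one
#'   profile per row.
#' @param perplexity target perplexity of the input affinities.
#' @param max_iter gradient-descent iterations.
#' @param seed integer seed for the embedding initialization.
#' @return numeric matrix (n x 2) of embedding coordinates.
#' @export
embed_profiles <- function(profiles, perplexity = 100, max_iter = 1000,
                           seed = 1) {
  x <- profiles_to_matrix(profiles)
  if (nrow(x) < 3 * perplexity)
    stop("too few profiles for perplexity ", perplexity,
         ": need at least ", ceiling(3 * perplexity))
  tsne_embed(x, perplexity = perplexity, max_iter = max_iter, seed = seed)
}

profiles_to_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  if (inherits(profiles, "angle_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    if (inherits(p, "angle_profile")) p$angles else as.numeric(p)
  }))
}
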