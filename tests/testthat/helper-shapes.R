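# Analytic shape fixtures used across the suite.

circle_outline <- function(r = 1, n = 500, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  outline(cbind(centre[1] + r * cos(th), centre[2] + r * sin(th)))
}

ellipse_outline <- function(a = 2, b = 1, n = 500) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  outline(cbind(a * cos(th), b * sin(th)))
}

square_outline <- function(s = 1) {
  outline(rbind(c(0, 0), c(s, 0), c(s, s), c(0, s)))
}

# square with many vertices along each edge so profile windows fall on edges
dense_square <- function(s = 4, per_edge = 100) {
  t <- seq(0, s, length.out = per_edge + 1)[-(per_edge + 1)]
  outline(rbind(cbind(t, 0), cbind(s, t), cbind(s - t, s), cbind(0, s - t)))
}

rotate_verts <- function(v, angle) {
  v %*% matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
}

outline_verts <- function(o) o$vertices

# exhaustive two-tailed binomial p-value (minimum-likelihood definition)
binom_p_enum <- function(k, n, p0) {
  pr <- dbinom(0:n, n, p0)
  sum(pr[pr <= pr[k + 1] * (1 + 1e-9)])
}

# exhaustive two-tailed rank-sum p-value for small tie-free samples
wilcox_p_enum <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool); m <- length(a)
  robs <- sum(rank(pool)[seq_len(m)])
  combs <- utils::combn(n, m)
  rks <- rank(pool)
  stat <- apply(combs, 2, function(ix) sum(rks[ix]))
  centre <- m * (n + 1) / 2
  mean(abs(stat - centre) >= abs(robs - centre) - 1e-9)
}
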