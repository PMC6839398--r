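#' Beta regression of swim-up X proportions
#'
#' Maximum-likelihood beta regression with a logit link for the mean and a
#' common precision phi: y_i ~ Beta(mu_i phi, (1 - mu_i) phi) with
#' logit(mu_i) = x_i' beta. This is the model used to explain the X
#' proportion of swim-up fractions as an interaction of strain (genotype),
#' live/dead state, and segment (fraction index). The fraction index enters
#' as a numeric trend by default — the published fraction profiles are
#' monotone — with a categorical option.
#'
#' Proportions are computed as x_count / (x_count + y_count); rows on the
#' boundary (0 or 1) are shrunk by the standard (y (n - 1) + 1/2) / n
#' transform, since the beta likelihood is undefined at the boundary.
#' Optimization is BFGS on (beta, log phi) with analytic gradients; the
#' penalized objective is monitored so the reported log-likelihood is the
#' best value reached, and non-convergence is an error carrying the last
#' state.
#'
#' @param table swim-up count data.frame: male_id, genotype, state,
#'   fraction, x_count, y_count (see [generate_swimup_counts()]).
#' @param formula mean-model formula in terms of table columns; the
#'   response is ignored (the X proportion is always used). Default is the
#'   full genotype x state x fraction interaction.
#' @param segment_numeric treat fraction as numeric trend (default) or
#'   factor.
#' @return a `betareg_fit`: coefficients (logit scale), phi, loglik,
#'   fitted, df (number of free parameters), converged, model frame info.
#' @export
betareg_fit <- function(table,
                        formula = ~ genotype * state * fraction,
                        segment_numeric = TRUE) {
  req <- c("fraction", "x_count", "y_count")
  if (!all(req %in% names(table)))
    stop("table must have columns ", paste(req, collapse = ", "))
  tab <- as.data.frame(table)
  ntot <- tab$x_count + tab$y_count
  if (any(ntot <= 0)) stop("every row needs x_count + y_count > 0")
  y <- tab$x_count / ntot
  bound <- y <= 0 | y >= 1
  y[bound] <- (y[bound] * (ntot[bound] - 1) + 0.5) / ntot[bound]
  if (!segment_numeric) tab$fraction <- factor(tab$fraction)
  for (cc in intersect(c("genotype", "state", "male_id"), names(tab)))
    tab[[cc]] <- factor(tab[[cc]])
  X <- model.matrix(formula, data = tab)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  fit <- betareg_ml(y, X)
  fit$call_formula <- formula
  fit$segment_numeric <- segment_numeric
  fit
}

# Core ML fit: y in (0,1), X full-rank design. Parameters c(beta, log phi).
betareg_ml <- function(y, X, maxit = 500) {
  k <- ncol(X)
  logy <- log(y); log1y <- log1p(-y)
  nll <- function(par) {
    eta <- drop(X %*% par[1:k])
    mu <- plogis(eta)
    phi <- exp(par[k + 1])
    a <- mu * phi; b <- (1 - mu) * phi
    -sum(lgamma(phi) - lgamma(a) - lgamma(b) + (a - 1) * logy + (b - 1) * log1y)
  }
  gr <- function(par) {
    eta <- drop(X %*% par[1:k])
    mu <- plogis(eta)
    phi <- exp(par[k + 1])
    a <- mu * phi; b <- (1 - mu) * phi
    ystar <- logy - log1y
    mustar <- digamma(a) - digamma(b)
    dbeta_ <- -phi * drop(crossprod(X, (ystar - mustar) * mu * (1 - mu)))
    dphi <- -sum(digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(b) +
                   mu * logy + (1 - mu) * log1y) * phi
    c(dbeta_, dphi)
  }
  # starting values: least squares on the logit scale
  zs <- qlogis(y)
  b0 <- qr.coef(qr(X), zs)
  b0[is.na(b0)] <- 0
  mu0 <- plogis(drop(X %*% b0))
  r <- zs - drop(X %*% b0)
  v <- max(var(r), 1e-4)
  phi0 <- max(mean(1 / (v * mu0 * (1 - mu0))) - 1, 2)
  opt <- optim(c(b0, log(phi0)), nll, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  if (opt$convergence != 0) {
    e <- simpleError(paste0("beta regression did not converge (code ",
                            opt$convergence, ")"))
    e$last_state <- opt
    stop(e)
  }
  eta <- drop(X %*% opt$par[1:k])
  hess <- optimHess(opt$par, nll, gr)
  vc <- tryCatch(solve(hess), error = function(e) matrix(NA, k + 1, k + 1))
  structure(list(coefficients = setNames(opt$par[1:k], colnames(X)),
                 phi = exp(opt$par[k + 1]),
                 loglik = -opt$value,
                 fitted = plogis(eta),
                 se = sqrt(pmax(diag(vc)[1:k], 0)),
                 vcov = vc,
                 df = k + 1L,
                 n = length(y),
                 converged = TRUE),
            class = "betareg_fit")
}

#' @export
print.betareg_fit <- function(x, ...) {
  cat(sprintf("<betareg_fit> %d obs, %d parameters, logLik %.3f, phi %.2f\n",
              x$n, x$df, x$loglik, x$phi))
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @importFrom stats optimHess
NULL

#' Likelihood-ratio test of nested beta regressions
#'
#' chi2 = 2 (logLik_full - logLik_reduced) on df equal to the difference in
#' free parameter counts, with the upper-tail chi-square p-value. A reduced
#' model fitting better than the full model beyond numerical tolerance
#' signals an optimization failure and is an error.
#'
#' @param full,reduced `betareg_fit` objects, reduced nested in full.
#' @param tol tolerance for a negative chi-square before erroring.
#' @return list: chi2, df, p.
#' @export
likelihood_ratio_test <- function(full, reduced, tol = 1e-6) {
  if (!inherits(full, "betareg_fit") || !inherits(reduced, "betareg_fit"))
    stop("both arguments must be betareg_fit objects")
  df <- full$df - reduced$df
  if (df < 0) stop("the first argument must be the larger (full) model")
  chi2 <- 2 * (full$loglik - reduced$loglik)
  if (chi2 < -tol)
    stop("full model has lower likelihood than reduced model: optimization failure")
  chi2 <- max(chi2, 0)
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Full statistical analysis of a swim-up experiment
#'
#' Reproduces the swim-up analysis suite: per-genotype, per-fraction
#' one-sample Z-tests of the live X proportion against 0.5 (Holm-corrected
#' within genotype); per-fraction two-sample Z-tests between two genotypes
#' (Holm-corrected); and a beta-regression likelihood-ratio test of whether
#' genotype modulates the fraction trend (full model with genotype
#' interactions versus a reduced model without genotype terms), on live
#' rows only for the trend contrast plus the killed-state control retained
#' in the full interaction model.
#'
#' @param table swim-up counts (see [generate_swimup_counts()]).
#' @param genotypes the two genotypes to contrast (default the first two
#'   present, reference first).
#' @param alpha flag threshold after Holm correction.
#' @return list: per_fraction (Z-tests vs 0.5), genotype_contrast
#'   (two-sample Z-tests), lrt (chi2, df, p), fits (full and reduced).
#' @export
swimup_analysis <- function(table, genotypes = NULL, alpha = 0.05) {
  tab <- as.data.frame(table)
  if (is.null(genotypes)) genotypes <- head(unique(tab$genotype), 2)
  live <- tab[tab$state == "live" & tab$genotype %in% genotypes, ]
  # pooled per-fraction counts, one-sample Z vs 0.5
  per <- do.call(rbind, lapply(genotypes, function(gt) {
    sub <- live[live$genotype == gt, ]
    agg_x <- tapply(sub$x_count, sub$fraction, sum)
    agg_n <- tapply(sub$x_count + sub$y_count, sub$fraction, sum)
    zz <- mapply(function(k, n) one_sample_ztest(k, n, 0.5),
                 agg_x, agg_n, SIMPLIFY = FALSE)
    data.frame(genotype = gt, fraction = as.integer(names(agg_x)),
               x = as.integer(agg_x), n = as.integer(agg_n),
               p_x = agg_x / agg_n,
               se = se_proportion(as.integer(agg_x), as.integer(agg_n)),
               z = vapply(zz, `[[`, 0, "z"), p = vapply(zz, `[[`, 0, "p"))
  }))
  per$p_adjusted <- NA_real_; per$flag <- NA
  for (gt in genotypes) {
    sel <- per$genotype == gt
    hb <- holm_bonferroni(per$p[sel], alpha)
    per$p_adjusted[sel] <- hb$p_adjusted
    per$flag[sel] <- hb$reject
  }
  # two-sample contrast per fraction
  g1 <- per[per$genotype == genotypes[1], ]
  g2 <- per[per$genotype == genotypes[2], ]
  fr <- intersect(g1$fraction, g2$fraction)
  tz <- lapply(fr, function(f) {
    two_proportion_ztest(g2$x[g2$fraction == f], g2$n[g2$fraction == f],
                         g1$x[g1$fraction == f], g1$n[g1$fraction == f])
  })
  contrast <- data.frame(fraction = fr,
                         diff = vapply(tz, `[[`, 0, "estimate"),
                         z = vapply(tz, `[[`, 0, "z"),
                         p = vapply(tz, `[[`, 0, "p"))
  hb <- holm_bonferroni(contrast$p, alpha)
  contrast$p_adjusted <- hb$p_adjusted
  contrast$flag <- hb$reject
  # beta regression: does genotype modulate the trend?
  sub <- tab[tab$genotype %in% genotypes, ]
  full <- betareg_fit(sub, ~ genotype * state * fraction)
  reduced <- betareg_fit(sub, ~ state * fraction)
  lrt <- likelihood_ratio_test(full, reduced)
  list(per_fraction = per, genotype_contrast = contrast, lrt = lrt,
       fits = list(full = full, reduced = reduced))
}
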