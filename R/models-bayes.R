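#' Prior specification for the Bayesian LASSO
#'
#' Defaults follow the usual weakly-informative guidance: residual
#' scaled-inverse-chi-square with `df_e = 5` and scale chosen so its prior
#' mode equals half the phenotypic variance; the Gamma prior on `lambda^2`
#' is centered on the value at which the markers are expected to explain
#' `R2` of the phenotypic variance (`lambda^2 = 2 (1 - R2) / R2 *
#' sum_j mean(z_ij^2)` under the double-exponential marginal), with shape
#' 1.1 so the prior is diffuse. Every element can be overridden, and
#' `fix_lambda2` freezes the shrinkage instead of sampling it.
#'
#' @param y,Z phenotypes and (centered) marker matrix used for the
#'   data-driven defaults.
#' @param df_e,S_e residual prior degrees of freedom and scale.
#' @param r,delta Gamma shape and rate for `lambda^2`.
#' @param R2 expected marker R-squared behind the default `lambda^2`.
#' @param fix_lambda2 optional fixed value for `lambda^2` (not sampled).
#' @return list of class `bl_priors`.
#' @export
bl_priors <- function(y, Z, df_e = 5, S_e = NULL, r = NULL, delta = NULL,
                      R2 = 0.5, fix_lambda2 = NULL) {
  stopifnot(df_e > 0)
  vy <- var(y)
  if (is.null(S_e)) S_e <- 0.5 * vy * (df_e + 2)
  msx <- sum(colMeans(Z^2))
  lambda2_hat <- if (!is.null(fix_lambda2)) fix_lambda2 else
    2 * (1 - R2) / R2 * msx
  if (is.null(r)) r <- 1.1
  if (is.null(delta)) delta <- r / lambda2_hat
  stopifnot(S_e > 0, r > 0, delta > 0)
  structure(list(df_e = df_e, S_e = S_e, r = r, delta = delta,
                 lambda2_init = lambda2_hat,
                 fix_lambda2 = !is.null(fix_lambda2)),
            class = "bl_priors")
}

#' Bayesian LASSO regression on markers (Gibbs sampler)
#'
#' Marker effects carry the double-exponential (LASSO) prior through the
#' scale-mixture hierarchy `a_j | tau_j^2 ~ N(0, tau_j^2 sigma2_e)`,
#' `tau_j^2 ~ Exp(lambda^2)`, `lambda^2 ~ Gamma(r, delta)`, with a
#' scaled-inverse-chi-square prior on `sigma2_e`. Sampling uses the
#' conjugate conditionals of the Park-Casella construction (coordinate-wise
#' marker updates, inverse-Gaussian `1/tau^2`), single-threaded and seeded,
#' so chains are bit-reproducible. Defaults: 20,000 iterations, 2,000
#' burn-in, thinning 100 (180 retained samples).
#'
#' @param y phenotype vector.
#' @param Z centered marker matrix (see [center_markers()]).
#' @param priors a [bl_priors()]; data-driven defaults when omitted.
#' @param chain,burnin,thin chain settings.
#' @param seed RNG seed.
#' @param Z_new optional marker rows for unphenotyped individuals, predicted
#'   from the posterior-mean marker effects.
#' @return a `model_fit` with posterior-mean `marker_effects`, GEBVs and
#'   sampler diagnostics (`n_retained`, `lambda2`, posterior `sigma2_e`
#'   draws).
#' @export
fit_bayesian_lasso <- function(y, Z, priors = NULL, chain = 20000,
                               burnin = 2000, thin = 100, seed = 1L,
                               Z_new = NULL) {
  stopifnot(burnin < chain, thin >= 1)
  if (is.null(priors)) priors <- bl_priors(y, Z)
  set.seed(seed)
  res <- .bl_gibbs_cpp(y, Z, as.integer(chain), as.integer(burnin),
                       as.integer(thin), priors$df_e, priors$S_e,
                       priors$r, priors$delta, priors$lambda2_init,
                       priors$fix_lambda2)
  a <- drop(res$a); names(a) <- colnames(Z)
  gebv <- drop(res$gebv)
  names(gebv) <- if (!is.null(names(y))) names(y) else rownames(Z)
  if (!is.null(Z_new)) {
    gn <- drop(Z_new %*% a); names(gn) <- rownames(Z_new)
    gebv <- c(gebv, gn)
  }
  vc <- structure(list(sigma2_g = NA_real_, sigma2_e = res$sigma2_e,
                       h2_ratio = NA_real_), class = "varcomp")
  new_model_fit("bl", beta = c(intercept = res$beta), gebv = gebv, vc = vc,
                marker_effects = a,
                diagnostics = list(n_retained = res$n_retained,
                                   lambda2 = res$lambda2,
                                   tau2 = drop(res$tau2),
                                   s2e_draws = res$s2e_draws,
                                   acceptance = 1))
}

#' Gaussian kernel set for RKHS regression
#'
#' Squared-Euclidean genetic distances on the raw 0/1/2 coding,
#' `d_ij = sum_k (x_ik - x_jk)^2`, the median off-diagonal distance
#' `d_bar`, and the multi-kernel bandwidth rule `h = (2 / (5 d_bar),
#' 2 / d_bar, 10 / d_bar)` giving kernels `K_ij = exp(-h d_ij)`.
#'
#' @param genotypes complete dosage matrix.
#' @param h optional explicit bandwidths overriding the rule.
#' @return list of class `kernel_set`: `d` (distance matrix), `d_bar`, `h`,
#'   `kernels` (list of matrices).
#' @export
kernel_set <- function(genotypes, h = NULL) {
  d <- as.matrix(dist(genotypes))^2
  d_bar <- median(d[upper.tri(d)])
  if (d_bar == 0) stop("median genetic distance is zero (duplicate-only panel)")
  if (is.null(h)) h <- c(2 / (5 * d_bar), 2 / d_bar, 2 * 5 / d_bar)
  kernels <- lapply(h, function(hh) exp(-hh * d))
  structure(list(d = d, d_bar = d_bar, h = h, kernels = kernels),
            class = "kernel_set")
}

#' RKHS regression with Gaussian multi-kernel averaging (Gibbs sampler)
#'
#' `y = 1 beta + sum_k u_k + e` with `u_k ~ N(0, K_k sigma2_gk)` over the
#' kernel set of [kernel_set()], scaled-inverse-chi-square priors on each
#' `sigma2_gk` and on `sigma2_e`. Each kernel's effects are updated in its
#' eigenbasis (where the conditional posterior is diagonal); unphenotyped
#' individuals are handled by data augmentation, so kernels are built on
#' all genotyped individuals and the validation set receives GEBVs.
#' Defaults: 20,000 iterations, 2,000 burn-in, thinning 100.
#'
#' @param y named phenotype vector (a subset of `rownames(genotypes)`).
#' @param genotypes complete dosage matrix over every individual to fit or
#'   predict.
#' @param h optional explicit bandwidths (e.g. a single small bandwidth for
#'   a one-kernel model).
#' @param df_g,S_g,df_e,S_e prior hyperparameters; scales default to modes
#'   at half the phenotypic variance (split equally across kernels).
#' @param chain,burnin,thin,seed chain settings.
#' @return a `model_fit`; GEBV = posterior mean of the summed kernel
#'   effects, diagnostics include per-kernel variances and `n_retained`.
#' @export
fit_rkhs <- function(y, genotypes, h = NULL, df_g = 5, S_g = NULL,
                     df_e = 5, S_e = NULL, chain = 20000, burnin = 2000,
                     thin = 100, seed = 1L) {
  stopifnot(burnin < chain, thin >= 1)
  if (anyNA(genotypes)) stop("genotypes must be complete for RKHS")
  set.seed(seed)
  ids <- rownames(genotypes)
  if (is.null(names(y))) {
    if (length(y) != nrow(genotypes)) stop("unnamed y must match genotypes")
    names(y) <- ids
  }
  obs <- match(names(y), ids)
  if (anyNA(obs)) stop("phenotyped ids missing from genotypes")
  ks <- kernel_set(genotypes, h = h)
  nk <- length(ks$kernels)
  n <- nrow(genotypes)
  vy <- var(y)
  if (is.null(S_e)) S_e <- 0.5 * vy * (df_e + 2)
  if (is.null(S_g)) S_g <- 0.5 * vy * (df_g + 2) / nk
  eig <- lapply(ks$kernels, function(K) eigen(K, symmetric = TRUE))
  Gam <- lapply(eig, `[[`, "vectors")
  lam <- lapply(eig, function(e) pmax(e$values, 0))
  keep_ev <- lapply(lam, function(l) l > 1e-10 * max(l))

  yfull <- rep(mean(y), n); yfull[obs] <- y
  miss <- setdiff(seq_len(n), obs)
  beta <- mean(y)
  u <- replicate(nk, rep(0, n), simplify = FALSE)
  s2g <- rep(vy / (2 * nk), nk)
  s2e <- vy / 2
  usum_mean <- rep(0, n); kept <- 0
  s2g_sum <- rep(0, nk); s2e_sum <- 0; beta_sum <- 0
  s2e_draws <- numeric(0)

  total_u <- function() Reduce(`+`, u)
  for (it in seq_len(chain)) {
    utot <- total_u()
    # augment unobserved phenotypes
    if (length(miss) > 0)
      yfull[miss] <- beta + utot[miss] + rnorm(length(miss), 0, sqrt(s2e))
    # intercept
    r0 <- yfull - utot
    beta <- rnorm(1, mean(r0), sqrt(s2e / n))
    # kernel effects in their eigenbases
    for (k in seq_len(nk)) {
      r <- yfull - beta - (utot - u[[k]])
      rs <- crossprod(Gam[[k]], r)
      ok <- keep_ev[[k]]
      prec <- 1 / s2e + 1 / (lam[[k]][ok] * s2g[k])
      mu <- (rs[ok] / s2e) / prec
      v <- rep(0, n)
      v[ok] <- mu + rnorm(sum(ok), 0, sqrt(1 / prec))
      unew <- drop(Gam[[k]] %*% v)
      utot <- utot - u[[k]] + unew
      u[[k]] <- unew
      ss <- sum(v[ok]^2 / lam[[k]][ok])
      s2g[k] <- (S_g + ss) / rchisq(1, df_g + sum(ok))
    }
    e <- yfull - beta - utot
    s2e <- (S_e + sum(e^2)) / rchisq(1, df_e + n)
    if (it > burnin && (it - burnin) %% thin == 0) {
      kept <- kept + 1
      usum_mean <- usum_mean + utot
      s2g_sum <- s2g_sum + s2g
      s2e_sum <- s2e_sum + s2e
      beta_sum <- beta_sum + beta
      s2e_draws <- c(s2e_draws, s2e)
    }
  }
  gebv <- usum_mean / kept
  names(gebv) <- ids
  vc <- structure(list(sigma2_g = sum(s2g_sum) / kept,
                       sigma2_e = s2e_sum / kept,
                       h2_ratio = NA_real_), class = "varcomp")
  new_model_fit("rkhs", beta = c(intercept = beta_sum / kept), gebv = gebv,
                vc = vc,
                diagnostics = list(n_retained = kept,
                                   sigma2_g_kernels = s2g_sum / kept,
                                   h = ks$h, d_bar = ks$d_bar,
                                   s2e_draws = s2e_draws,
                                   acceptance = 1))
}
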