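#' REML variance components for a single-random-effect model
#'
#' Model `y = X beta + g + e`, `g ~ N(0, K sigma2_g)`, `e ~ N(0, I sigma2_e)`.
#' The likelihood is profiled on the heritability-like ratio
#' `h = sigma2_g / (sigma2_g + sigma2_e)` after rotating the data into the
#' eigenbasis of `K`, and maximized by 1-D bounded search (tolerance 1e-8),
#' so the estimate is deterministic. Standard errors come from a numeric
#' observed-information matrix in `(sigma2_g, sigma2_e)`.
#'
#' @param y response vector (individuals with phenotypes).
#' @param K symmetric PSD relationship matrix over the same individuals
#'   (pedigree A, genomic G or a kernel).
#' @param X fixed-effect design; default an intercept column.
#' @param eig optional precomputed `eigen(K, symmetric = TRUE)` to reuse
#'   across traits sharing one K.
#' @return object of class `varcomp`: `sigma2_g`, `sigma2_e`, `h2_ratio`
#'   (= g / (g + e)), `loglik` (restricted), `se_sigma2_g`, plus the inputs'
#'   dimensions.
#' @export
reml_variance_components <- function(y, K, X = NULL, eig = NULL) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (is.null(eig)) eig <- eigen(unclass(K), symmetric = TRUE)
  d <- eig$values
  if (min(d) < -1e-6 * max(abs(d)))
    stop("K is not positive semi-definite")
  d <- pmax(d, 0)
  U <- eig$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  q <- ncol(X)

  neg_restricted_ll <- function(h) {
    w <- h * d + (1 - h)
    if (any(w <= 0)) return(1e10)
    XtWX <- crossprod(Xs / w, Xs)
    XtWy <- crossprod(Xs / w, ys)
    bhat <- solve(XtWX, XtWy)
    r <- ys - Xs %*% bhat
    rss <- sum(r^2 / w)
    phi <- rss / (n - q)
    0.5 * ((n - q) * log(phi) + sum(log(w)) +
             determinant(XtWX, logarithm = TRUE)$modulus + (n - q))
  }
  opt <- optimize(neg_restricted_ll, interval = c(1e-8, 1 - 1e-8),
                  tol = 1e-8)
  h <- opt$minimum
  w <- h * d + (1 - h)
  XtWX <- crossprod(Xs / w, Xs)
  bhat <- solve(XtWX, crossprod(Xs / w, ys))
  rss <- sum((ys - Xs %*% bhat)^2 / w)
  phi <- rss / (n - q)
  s2g <- h * phi
  s2e <- (1 - h) * phi

  # numeric observed information in (s2g, s2e) for delta-method SEs
  se_s2g <- tryCatch({
    eps <- pmax(abs(c(s2g, s2e)), 1e-3) * 1e-3
    f <- function(th) {
      ww <- th[1] * d + th[2]
      if (any(ww <= 0)) return(1e10)
      XtWX2 <- crossprod(Xs / ww, Xs)
      b2 <- solve(XtWX2, crossprod(Xs / ww, ys))
      r2 <- ys - Xs %*% b2
      0.5 * (sum(log(ww)) + sum(r2^2 / ww) +
               determinant(XtWX2, logarithm = TRUE)$modulus)
    }
    H <- matrix(0, 2, 2)
    th0 <- c(s2g, s2e)
    for (a in 1:2) for (b in 1:2) {
      ea <- eb <- c(0, 0); ea[a] <- eps[a]; eb[b] <- eps[b]
      H[a, b] <- (f(th0 + ea + eb) - f(th0 + ea - eb) -
                    f(th0 - ea + eb) + f(th0 - ea - eb)) /
        (4 * eps[a] * eps[b])
    }
    v <- solve(H)[1, 1]
    if (!is.finite(v) || v <= 0) NA_real_ else sqrt(v)
  }, error = function(e) NA_real_)

  structure(list(sigma2_g = s2g, sigma2_e = s2e,
                 h2_ratio = s2g / (s2g + s2e),
                 loglik = -opt$objective, se_sigma2_g = se_s2g,
                 n = n, beta = drop(bhat)),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("REML variance components: sigma2_g = %.4g, sigma2_e = %.4g (ratio h2 = %.3f)\n",
              x$sigma2_g, x$sigma2_e, x$h2_ratio))
  invisible(x)
}

#' Narrow-sense heritability from variance components
#'
#' `h2 = sigma2_additive / sigma2_y` with `sigma2_y` the phenotypic variance
#' of the sample, the pedigree-based (`h2_a`, K = A) or genomic (`h2_g`,
#' K = G) estimator depending on which relationship matrix produced the
#' variance components. The standard error is delta-method:
#' `se(sigma2_g) / sigma2_y`.
#'
#' @param vc a `varcomp` from [reml_variance_components()].
#' @param y the phenotype vector the components were estimated from.
#' @return list with `h2`, `se`, `sigma2_g`, `sigma2_y`.
#' @export
heritability <- function(vc, y) {
  s2y <- var(y)
  if (s2y <= 0) stop("phenotypic variance must be positive")
  list(h2 = vc$sigma2_g / s2y,
       se = if (is.na(vc$se_sigma2_g)) NA_real_ else vc$se_sigma2_g / s2y,
       sigma2_g = vc$sigma2_g, sigma2_y = s2y)
}
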