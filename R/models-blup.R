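new_model_fit <- function(method, beta, gebv, vc = NULL,
                          marker_effects = NULL, diagnostics = NULL) {
  structure(list(method = method, beta = beta, gebv = gebv, vc = vc,
                 marker_effects = marker_effects,
                 diagnostics = diagnostics),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d GEBVs, intercept %.4g\n",
              toupper(x$method), length(x$gebv), x$beta[1]))
  if (!is.null(x$vc))
    cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g\n",
                x$vc$sigma2_g, x$vc$sigma2_e))
  invisible(x)
}

#' BLUP with a relationship matrix (ABLUP with K = A, GBLUP with K = G)
#'
#' Solves the single-random-effect mixed-model equations
#' `[X'X, X'Z; Z'X, Z'Z + K^{-1} lambda]` with `lambda = sigma2_e /
#' sigma2_a`, through the equivalent variance-model form
#' `beta = (X'V^{-1}X)^{-1} X'V^{-1} y`,
#' `a = sigma2_a K Z' V^{-1} (y - X beta)` with
#' `V = Z K Z' sigma2_a + I sigma2_e`. The two are identical whenever `K`
#' is invertible, and the variance form stays defined for the
#' rank-deficient G that arises when allele frequencies are estimated from
#' the same sample. Individuals in `K` without phenotypes (e.g. a
#' validation set) receive GEBVs through their relationships.
#'
#' @param y named phenotype vector (names must appear in `rownames(K)`);
#'   individuals of `K` not named in `y` are treated as unphenotyped.
#' @param K relationship matrix over all individuals to predict.
#' @param vc optional `varcomp`; REML-estimated on the phenotyped subset of
#'   `K` when omitted.
#' @param method label stored in the fit (`"gblup"` or `"ablup"`).
#' @return a `model_fit` with GEBVs for every individual in `K`.
#' @export
fit_blup <- function(y, K, vc = NULL, method = "gblup") {
  ids <- rownames(K)
  if (is.null(names(y))) {
    if (length(y) != nrow(K)) stop("unnamed y must match dim(K)")
    names(y) <- ids
  }
  if (!all(names(y) %in% ids)) stop("phenotyped ids missing from K")
  obs <- match(names(y), ids)
  Kuu <- unclass(K)[obs, obs, drop = FALSE]
  if (is.null(vc))
    vc <- reml_variance_components(y, Kuu)
  s2a <- vc$sigma2_g; s2e <- vc$sigma2_e
  n <- length(y)
  V <- Kuu * s2a + diag(s2e, n)
  Vinv_y <- solve(V, y)
  Vinv_1 <- solve(V, rep(1, n))
  beta <- sum(Vinv_y) / sum(Vinv_1)
  r <- solve(V, y - beta)
  gebv <- drop(s2a * unclass(K)[, obs, drop = FALSE] %*% r)
  names(gebv) <- ids
  new_model_fit(method, beta = c(intercept = beta), gebv = gebv, vc = vc)
}

#' Ridge-regression BLUP on marker covariates
#'
#' Solves the marker-effect mixed-model equations
#' `[n, 1'Z; Z'1, Z'Z + I lambda] [beta; a] = [1'y; Z'y]` with
#' `lambda = sigma2_e / sigma2_m`. When `lambda` is not supplied it is
#' obtained by REML on the observationally equivalent model with
#' `K = Z Z'`, whose variance component is the per-marker variance itself.
#' GEBVs are `g_i = Z_i' a`. Zero-variance marker columns are dropped with
#' a warning.
#'
#' @param y phenotype vector.
#' @param Z marker matrix for the phenotyped individuals, centered
#'   consistently with [g_matrix()] (dosages minus `2 p_j`).
#' @param lambda optional shrinkage ratio; `vc` optional `varcomp` giving
#'   `lambda = sigma2_e / sigma2_g`.
#' @param Z_new optional marker rows for unphenotyped individuals to
#'   predict.
#' @return a `model_fit` with `marker_effects`; GEBVs for the training rows
#'   followed by any `Z_new` rows.
#' @export
fit_rrblup <- function(y, Z, lambda = NULL, vc = NULL, Z_new = NULL) {
  zv <- apply(Z, 2, var)
  if (any(zv == 0)) {
    warning(sprintf("dropping %d zero-variance marker columns", sum(zv == 0)))
    Z <- Z[, zv > 0, drop = FALSE]
    if (!is.null(Z_new)) Z_new <- Z_new[, zv > 0, drop = FALSE]
  }
  n <- length(y); p <- ncol(Z)
  if (is.null(lambda)) {
    if (is.null(vc)) vc <- reml_variance_components(y, tcrossprod(Z))
    lambda <- vc$sigma2_e / vc$sigma2_g
  }
  # mixed-model equations with an explicit intercept block
  C <- rbind(cbind(n, t(colSums(Z))),
             cbind(colSums(Z), crossprod(Z) + diag(lambda, p)))
  rhs <- c(sum(y), crossprod(Z, y))
  sol <- solve(C, rhs)
  beta <- sol[1]
  a <- sol[-1]
  names(a) <- colnames(Z)
  gebv_tr <- drop(Z %*% a)
  names(gebv_tr) <- if (!is.null(names(y))) names(y) else rownames(Z)
  gebv <- gebv_tr
  if (!is.null(Z_new)) {
    gn <- drop(Z_new %*% a)
    names(gn) <- rownames(Z_new)
    gebv <- c(gebv, gn)
  }
  new_model_fit("rrblup", beta = c(intercept = beta), gebv = gebv, vc = vc,
                marker_effects = a,
                diagnostics = list(lambda = lambda))
}

#' Center a dosage matrix for marker-based models
#'
#' Subtracts `2 p_j` per column (equivalently, codes -1/0/1 and subtracts
#' `2 (p_j - 0.5)`), matching the centering inside [g_matrix()] so that
#' GBLUP and rrBLUP operate on the same scale.
#'
#' @param genotypes 0/1/2 matrix.
#' @param p allele frequencies; sample frequencies when omitted.
#' @export
center_markers <- function(genotypes, p = NULL) {
  if (is.null(p)) p <- colMeans(genotypes) / 2
  sweep(genotypes, 2, 2 * p)
}

#' Adjust raw phenotypes for site, age and block effects
#'
#' Fits the mixed model `Y = X beta + Z u + W b + e` with fixed overall
#' mean, site and age, a random block-within-site term and a random
#' additive term with pedigree covariance A, by REML over the two variance
#' ratios (additive and block, relative to residual). The adjusted
#' phenotype subtracts the estimated fixed effects and block BLUPs but
#' keeps the additive effect and residual:
#' `y_adj = y - X beta_hat - W b_hat`.
#'
#' @param pheno data frame with `id`, `site`, `block`, `age` and the trait.
#' @param trait name of the raw trait column.
#' @param pedigree pedigree data frame (for the additive covariance);
#'   individuals absent from it are treated as founders.
#' @param site_specific_residual logical; one round of iterated weighted
#'   fitting with per-site residual variances (homogeneous default).
#' @return named vector of adjusted phenotypes, with the fitted components
#'   in attributes (`beta`, `block_blup`, `varcomp`).
#' @export
adjust_phenotypes <- function(pheno, trait, pedigree = NULL,
                              site_specific_residual = FALSE) {
  y <- pheno[[trait]]
  n <- length(y)
  has_site <- length(unique(pheno$site)) > 1
  has_age <- length(unique(pheno$age)) > 1
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (has_site)
    X <- cbind(X, model.matrix(~ factor(pheno$site))[, -1, drop = FALSE])
  if (has_age) X <- cbind(X, age = pheno$age - mean(pheno$age))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  blocks <- factor(pheno$block)
  has_block <- nlevels(blocks) > 1
  W <- if (has_block) model.matrix(~ blocks - 1) else NULL
  A <- if (!is.null(pedigree)) {
    Afull <- a_matrix(pedigree)
    idx <- match(pheno$id, rownames(Afull))
    if (anyNA(idx)) stop("phenotyped ids missing from pedigree")
    unclass(Afull)[idx, idx]
  } else diag(n)

  WWt <- if (has_block) tcrossprod(W) else NULL
  neg_ll <- function(logg) {
    ga <- exp(logg[1])
    gb <- if (has_block) exp(logg[2]) else 0
    V <- ga * A + diag(n)
    if (has_block) V <- V + gb * WWt
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtViX <- crossprod(X, Vi_X)
    b <- solve(XtViX, crossprod(Vi_X, y))
    r <- y - X %*% b
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    rss <- sum(r * Vi_r)
    s2e <- rss / (n - ncol(X))
    0.5 * ((n - ncol(X)) * log(s2e) + 2 * sum(log(diag(ch))) +
             determinant(XtViX, logarithm = TRUE)$modulus)
  }
  init <- if (has_block) c(0, 0) else 0
  opt <- optim(init, neg_ll, method = if (has_block) "Nelder-Mead" else "Brent",
               lower = if (!has_block) -10 else -Inf,
               upper = if (!has_block) 10 else Inf,
               control = list(reltol = 1e-9, maxit = 500))
  ga <- exp(opt$par[1]); gb <- if (has_block) exp(opt$par[2]) else 0
  weights <- rep(1, n)
  for (pass in seq_len(1 + site_specific_residual)) {
    V <- ga * A + diag(weights)
    if (has_block) V <- V + gb * WWt
    Vi_X <- solve(V, X)
    b <- solve(crossprod(X, Vi_X), crossprod(Vi_X, y))
    r <- drop(y - X %*% b)
    Vi_r <- solve(V, r)
    bblup <- if (has_block) gb * crossprod(W, Vi_r) else NULL
    if (site_specific_residual && pass == 1 && has_site) {
      res <- r - if (has_block) drop(W %*% bblup) else 0
      sv <- tapply(res, pheno$site, var)
      weights <- as.numeric(sv[as.character(pheno$site)] / mean(sv))
    }
  }
  adj <- drop(y - X %*% b - if (has_block) drop(W %*% bblup) else 0)
  names(adj) <- pheno$id
  attr(adj, "beta") <- drop(b)
  attr(adj, "block_blup") <- if (has_block) drop(bblup) else NULL
  attr(adj, "varcomp") <- c(gamma_additive = ga, gamma_block = gb)
  adj
}
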