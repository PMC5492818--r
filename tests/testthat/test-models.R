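test_that("phenotype adjustment recovers injected effects and degenerates cleanly", {
  # no site/age/block variation: adjusted = raw - grand mean
  ph0 <- tibble::tibble(id = paste0("i", 1:50), site = 1, block = "1_1",
                        age = 3, y = rnorm(50, 10))
  adj0 <- adjust_phenotypes(ph0, "y")
  expect_equal(unname(adj0), ph0$y - mean(ph0$y), tolerance = 1e-6,
               ignore_attr = TRUE)

  pop <- pop_h2_recovery()
  sub <- pop$phenotypes[1:500, ]
  adj <- adjust_phenotypes(sub, "raw_wood")
  # the +0.5 sd site-2 offset is recovered by the site fixed effect
  sy <- sqrt(var(pop$genetic_values[, "wood"]) / 0.35)
  site_hat <- attr(adj, "beta")[2]
  # the contrast SE under residual sd ~ sy at n = 500 is ~0.09 sy
  expect_lt(abs(site_hat - 0.5 * sy) / sy, 0.15)
  expect_lt(var(adj), var(sub$raw_wood))
  expect_gt(cor(adj, sub$adjtrue_wood), 0.95)

  # aliased fixed effects are reported by name
  bad <- ph0
  bad$site <- rep(1:2, each = 25)
  bad$age <- ifelse(bad$site == 1, 3, 6)
  expect_error(adjust_phenotypes(bad, "y"), "aliased")
})

test_that("REML is calibrated under the null, recovers h2, and is scale-equivariant", {
  pop <- pop_h2_recovery()
  G <- g_matrix(pop$genotypes)
  set.seed(10)
  # pure noise: essentially no genetic variance attributed
  y0 <- rnorm(500)
  K0 <- unclass(G)[1:500, 1:500]
  vc0 <- reml_variance_components(y0, K0)
  expect_lt(vc0$sigma2_g / var(y0), 0.05)

  # y simulated through K at h2 = 0.4
  eig <- eigen(K0, symmetric = TRUE)
  L <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)))
  g <- drop(L %*% rnorm(500))
  g <- g / sd(g) * sqrt(0.4)
  y1 <- g + rnorm(500, 0, sqrt(0.6))
  vc1 <- reml_variance_components(y1, K0, eig = eig)
  expect_lt(abs(heritability(vc1, y1)$h2 - 0.4), 0.1)

  # doubling y multiplies both components by 4, leaving the ratio alone
  vc2 <- reml_variance_components(2 * y1, K0, eig = eig)
  expect_equal(vc2$sigma2_g / vc1$sigma2_g, 4, tolerance = 1e-3)
  expect_equal(vc2$sigma2_e / vc1$sigma2_e, 4, tolerance = 1e-3)
  expect_equal(vc2$h2_ratio, vc1$h2_ratio, tolerance = 1e-4)
})

test_that("heritability is the printed variance ratio and is affine-invariant", {
  y <- rnorm(200)
  vc <- structure(list(sigma2_g = 0.35 * var(y), sigma2_e = NA,
                       se_sigma2_g = NA_real_), class = "varcomp")
  expect_equal(heritability(vc, y)$h2, 0.35)

  pop <- pop_homogeneous()
  K <- unclass(g_matrix(pop$genotypes))[1:300, 1:300]
  y1 <- adjusted_trait(pop)[1:300]
  h1 <- heritability(reml_variance_components(y1, K), y1)$h2
  h2_ <- heritability(reml_variance_components(3 * y1 + 7, K), 3 * y1 + 7)$h2
  expect_equal(h1, h2_, tolerance = 1e-4)
})

test_that("BLUP solves the mixed-model equations exactly on a toy system", {
  ped <- tibble::tibble(id = c("p1", "p2", "o1", "o2", "o3"),
                        sire = c(NA, NA, "p1", "p1", "p1"),
                        dam = c(NA, NA, "p2", "p2", NA),
                        generation = c("G0", "G0", "G1", "G1", "G1"))
  A <- a_matrix(ped)
  set.seed(2)
  y <- rnorm(5, 10)
  names(y) <- ped$id
  lambda <- 1.7
  vc <- structure(list(sigma2_g = 1 / lambda, sigma2_e = 1),
                  class = "varcomp")
  fit <- fit_blup(y, A, vc = vc)
  oracle <- mme_dense_solve(unname(y), unclass(A), lambda)
  expect_lt(abs(fit$beta - oracle$beta), 1e-8)
  expect_lt(max(abs(fit$gebv - oracle$a)), 1e-8)

  # infinite shrinkage: GEBVs -> 0, intercept -> sample mean
  vc_inf <- structure(list(sigma2_g = 1e-10, sigma2_e = 1),
                      class = "varcomp")
  fit_inf <- fit_blup(y, A, vc = vc_inf)
  expect_lt(max(abs(fit_inf$gebv)), 1e-6)
  expect_equal(unname(fit_inf$beta), mean(y), tolerance = 1e-6)

  # translation equivariance: only the intercept shifts
  fit_shift <- fit_blup(y + 5, A, vc = vc)
  expect_equal(fit_shift$gebv, fit$gebv, tolerance = 1e-9)
  expect_equal(unname(fit_shift$beta - fit$beta), 5, tolerance = 1e-9)
})

test_that("rrBLUP matches closed forms and shrinks monotonically", {
  set.seed(3)
  # lambda = 0 with n > p: ordinary least squares
  n <- 60; p <- 5
  Z <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  fit0 <- fit_rrblup(y, Z, lambda = 1e-10)
  ols <- coef(lm(y ~ Z))
  expect_equal(unname(fit0$marker_effects), unname(ols[-1]),
               tolerance = 1e-5)

  # single centered marker: a = z'y / (z'z + lambda)
  z <- matrix(rnorm(30), 30, 1)
  z <- z - mean(z)
  y1 <- rnorm(30); y1 <- y1 - mean(y1)
  f1 <- fit_rrblup(y1, z, lambda = 2.5)
  expect_equal(unname(f1$marker_effects),
               sum(z * y1) / (sum(z^2) + 2.5), tolerance = 1e-8)

  norms <- vapply(c(0.1, 1, 10, 100), function(l)
    sqrt(sum(fit_rrblup(y, Z, lambda = l)$marker_effects^2)), numeric(1))
  expect_true(all(diff(norms) < 0))

  Zz <- cbind(Z, 0)
  expect_warning(fit_rrblup(y, Zz, lambda = 1), "zero-variance")
})

test_that("GBLUP and rrBLUP give identical GEBVs at matched shrinkage", {
  pop <- pop_structured()
  M <- pop$genotypes[1:200, 1:500]
  y <- adjusted_trait(pop)[1:200]
  p <- colMeans(M) / 2
  cdenom <- 2 * sum(p * (1 - p))
  G <- g_matrix(M, p = p)
  Z <- center_markers(M, p = p)
  vc <- reml_variance_components(y, G)
  fg <- fit_blup(y, G, vc = vc)
  fr <- suppressWarnings(
    fit_rrblup(y, Z, lambda = vc$sigma2_e / (vc$sigma2_g / cdenom)))
  expect_lt(max(abs(fg$gebv - fr$gebv[names(fg$gebv)])), 1e-6)
})

test_that("Bayesian LASSO sampler bookkeeping and reproducibility hold", {
  set.seed(5)
  n <- 120; p <- 200
  Z <- center_markers(matrix(rbinom(n * p, 2, 0.4), n, p))
  a <- rnorm(p, 0, 0.08)
  y <- drop(Z %*% a) + rnorm(n)
  f1 <- fit_bayesian_lasso(y, Z, chain = 3000, burnin = 500, thin = 25,
                           seed = 9)
  expect_equal(f1$diagnostics$n_retained, (3000 - 500) / 25)
  f2 <- fit_bayesian_lasso(y, Z, chain = 3000, burnin = 500, thin = 25,
                           seed = 9)
  expect_identical(f1$gebv, f2$gebv)
  f3 <- fit_bayesian_lasso(y, Z, chain = 3000, burnin = 500, thin = 25,
                           seed = 10)
  expect_gt(cor(f1$gebv, f3$gebv), 0.95)
  expect_error(fit_bayesian_lasso(y, Z, chain = 100, burnin = 200), "burnin")
})

test_that("BL posterior residual variance covers the simulation truth at n = 500", {
  set.seed(6)
  n <- 500; p <- 300
  Z <- center_markers(matrix(rbinom(n * p, 2, 0.35), n, p))
  a <- rnorm(p, 0, 0.05)
  s2e_true <- 1.44
  y <- drop(Z %*% a) + rnorm(n, 0, sqrt(s2e_true))
  f <- fit_bayesian_lasso(y, Z, chain = 4000, burnin = 1000, thin = 15,
                          seed = 4)
  draws <- f$diagnostics$s2e_draws
  expect_lt(abs(mean(draws) - s2e_true), 2 * sd(draws))
})

test_that("kernel set follows the printed bandwidth rule and kernel limits", {
  g <- matrix(rbinom(40 * 60, 2, 0.5), 40, 60)
  ks <- kernel_set(g)
  d <- as.matrix(dist(g))^2
  dbar <- median(d[upper.tri(d)])
  expect_equal(ks$d_bar, dbar)
  expect_equal(ks$h, c(2 / (5 * dbar), 2 / dbar, 10 / dbar))
  expect_true(ks$h[1] < ks$h[2] && ks$h[2] < ks$h[3])
  for (K in ks$kernels) {
    expect_equal(unname(diag(K)), rep(1, 40))  # d = 0 => K = 1
    expect_true(all(K > 0 & K <= 1))
  }
  dup <- matrix(1, 5, 10)
  expect_error(kernel_set(dup), "duplicate")
})

test_that("single-kernel RKHS with a tiny bandwidth approaches the GBLUP ranking", {
  pop <- pop_structured()
  M <- pop$genotypes[1:300, 1:400]
  y <- adjusted_trait(pop)[1:300]
  fg <- fit_blup(y, g_matrix(M))
  d <- as.matrix(dist(M))^2
  dbar <- median(d[upper.tri(d)])
  rk <- fit_rkhs(y, M, h = 0.01 / dbar, chain = 4000, burnin = 1000,
                 thin = 15, seed = 3)
  expect_equal(rk$diagnostics$n_retained, (4000 - 1000) / 15)
  expect_gt(cor(rk$gebv, fg$gebv, method = "spearman"), 0.95)
})

test_that("RKHS posterior residual variance covers the simulation truth", {
  pop <- pop_homogeneous()
  M <- pop$genotypes[1:300, 1:300]
  set.seed(8)
  # simulate from the multi-kernel model itself, sigma2_e = 1
  ks <- kernel_set(M)
  g <- rep(0, 300)
  for (K in ks$kernels) {
    e <- eigen(K, symmetric = TRUE)
    g <- g + drop(e$vectors %*% (sqrt(pmax(e$values, 0)) *
                                   rnorm(300, 0, sqrt(0.2))))
  }
  s2e_true <- 1
  y <- g + rnorm(300, 0, 1)
  names(y) <- rownames(M)
  f <- fit_rkhs(y, M, chain = 3000, burnin = 800, thin = 10, seed = 5)
  draws <- f$diagnostics$s2e_draws
  expect_lt(abs(mean(draws) - s2e_true), 2 * sd(draws))
})
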