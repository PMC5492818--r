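test_that("HWE exact test matches known values and the enumeration oracle", {
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  set.seed(42)
  for (i in 1:30) {
    n <- sample(5:200, 1)
    counts <- as.vector(rmultinom(1, n, runif(3, 0.05, 1)))
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                 hwe_enum_oracle(counts[1], counts[2], counts[3]),
                 tolerance = 1e-12)
  }
})

test_that("HWE p-value shrinks monotonically with heterozygote deficit", {
  # fixed allele counts (60 A, 140 a in n = 100), decreasing heterozygotes
  p <- vapply(c(40, 30, 20, 10, 0), function(h) {
    aa <- (60 - h) / 2; bb <- (140 - h) / 2
    hwe_exact_test(aa, h, bb)
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("sample QC applies the strict 70% call-rate rule", {
  set.seed(1)
  g <- matrix(rbinom(10 * 200, 2, 0.4), 10, 200)
  rownames(g) <- paste0("s", 1:10)
  rates <- seq(0.55, 1, length.out = 10)
  for (i in 1:10) {
    nmiss <- round((1 - rates[i]) * 200)
    if (nmiss > 0) g[i, sample(200, nmiss)] <- NA
  }
  res <- qc_samples(g, call_rate_min = 0.70)
  expected_keep <- which(rowMeans(!is.na(g)) >= 0.70)  # brute-force recount
  expect_identical(rownames(res$genotypes), paste0("s", expected_keep))
  expect_equal(res$report$n_samples_removed, 10 - length(expected_keep))

  full <- matrix(rbinom(50, 2, 0.5), 5, 10)
  expect_identical(qc_samples(full)$genotypes, full)
  allbad <- matrix(NA_integer_, 3, 10)
  expect_error(qc_samples(allbad), "every sample")
})

test_that("SNP QC removes monomorphic, low-MAF and HWE-failing SNPs with reconciled counts", {
  set.seed(2)
  n <- 100
  good <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
  mono <- matrix(0L, n, 1)
  rare <- matrix(c(rep(1L, 1), rep(0L, n - 1)), n, 1)   # MAF 0.005
  hwe_perfect <- matrix(c(rep(0L, 25), rep(1L, 50), rep(2L, 25)), n, 1)
  hwe_bad <- matrix(c(rep(0L, 50), rep(2L, 50)), n, 1)
  lowcall <- matrix(c(rep(NA_integer_, 40), rbinom(60, 2, 0.5)), n, 1)
  g <- cbind(good, mono, rare, hwe_perfect, hwe_bad, lowcall)
  res <- qc_snps(g)
  rep_ <- res$report
  expect_equal(rep_$n_snps_removed_callrate, 1)
  expect_equal(rep_$n_snps_removed_maf_mono, 2)
  expect_equal(rep_$n_snps_removed_hwe, 1)
  expect_equal(rep_$n_snps_in - rep_$n_snps_out,
               rep_$n_snps_removed_callrate + rep_$n_snps_removed_maf_mono +
                 rep_$n_snps_removed_hwe)
  expect_true(all(c(1:5, 8) %in% res$keep))  # perfect-HWE SNP retained
  # idempotence
  res2 <- qc_snps(res$genotypes)
  expect_equal(ncol(res2$genotypes), ncol(res$genotypes))
  expect_equal(res2$report$n_snps_removed_callrate +
                 res2$report$n_snps_removed_maf_mono +
                 res2$report$n_snps_removed_hwe, 0)
})

test_that("modal imputation fills the mode, never alters calls, and scores >= 0.7", {
  col <- matrix(c(0L, 0L, 2L, NA), 4, 1)
  expect_equal(impute_simple(col)[4, 1], 0L)
  g <- matrix(rbinom(40, 2, 0.5), 8, 5)
  expect_identical(impute_simple(g), g)
  expect_error(impute_simple(matrix(NA_integer_, 3, 1)), "entirely missing")

  pop <- pop_homogeneous()
  masked <- apply_missingness(pop$genotypes, 0.1, seed = 8)
  imp <- impute_simple(masked)
  mask <- attr(masked, "mask")
  acc <- mean(imp[mask] == attr(masked, "truth"))
  expect_gte(acc, 0.7)
  untouched <- setdiff(seq_along(imp), mask)
  expect_identical(imp[untouched], pop$genotypes[untouched])
})

test_that("ld_r2 is the squared Pearson correlation with affine invariance", {
  a <- c(0, 1, 2, 0, 1, 2, 1)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, 2 - a), 1)
  b <- c(0, 1, 1, 1, 2, 0, 2)
  expect_equal(ld_r2(a, b), cor(a, b)^2)
  expect_error(ld_r2(a, rep(1, 7)), "monomorphic")
})

test_that("LD pruning obeys the threshold, tie rule and chunking invariance", {
  set.seed(3)
  base <- matrix(rbinom(200 * 12, 2, 0.5), 200, 12)
  # duplicated SNP: exactly the earlier copy is retained
  dup <- cbind(base[, 1], base)
  kept <- ld_prune(dup, r2_max = 0.2, window = ncol(dup))
  expect_true(1 %in% kept)
  expect_false(2 %in% kept)
  # after pruning, no retained pair within a window exceeds the threshold
  pop <- pop_structured()
  g <- pop$genotypes[, 1:200]
  kept2 <- ld_prune(g, r2_max = 0.2, window = 50, step = 5)
  v2 <- apply(g, 2, var)
  for (s in seq(1, 151, by = 10)) {
    win <- intersect(kept2, s:(s + 49))
    win <- win[v2[win] > 0]
    if (length(win) >= 2) {
      r2 <- cor(g[, win])^2
      expect_lte(max(r2[upper.tri(r2)]), 0.2 + 1e-12)
    }
  }
  # independent SNPs survive untouched
  indep <- matrix(rbinom(500 * 8, 2, 0.5), 500, 8)
  expect_identical(ld_prune(indep, window = 8), 1:8)
  # chunking invariance when the window spans everything
  expect_identical(ld_prune(g[, 1:80], window = 80, step = 5),
                   ld_prune(g[, 1:80], window = 80, step = 40))
})

test_that("LD-decay fitting recovers the decay rate and handles flat data", {
  set.seed(4)
  n <- 80
  d <- runif(400, 100, 50000)
  r2 <- expected_r2_hillweir(0.001 * d, n) + rnorm(400, 0, 0.01)
  fit <- fit_ld_decay(r2, d, n)
  expect_lt(abs(fit$C_per_bp - 0.001) / 0.001, 0.2)
  expect_true(all(diff(fit$predict(seq(0, 1e5, length.out = 50))) < 0))

  flat <- fit_ld_decay(rep(0.6, 50), runif(50, 1, 1e5), n)
  expect_equal(flat$C_per_bp, 0)
  expect_error(fit_ld_decay(rep(0.5, 5), 1:5, 50), "at least 10")
  expect_error(fit_ld_decay(c(rep(0.5, 10), NA), 1:11, 50), "non-finite")
})

test_that("faster genic copying decay lowers genic LD relative to intergenic", {
  cfg <- sim_config(n_parents_A = 60, n_parents_B = 2, n_families = 1,
                    n_chrom = 3, snps_per_chrom = 500, fst = 0,
                    ld_rho = 0.95, ld_rho_genic = 0.5, seed = 61)
  f <- simulate_founder_haplotypes(cfg)
  g <- f$A[seq(1, 120, 2), ] + f$A[seq(2, 120, 2), ]
  v <- apply(g, 2, var)
  reg <- f$snp_map$region
  adj <- function(cls) {
    idx <- which(reg[-length(reg)] == cls & reg[-1] == cls &
                   v[-length(v)] > 0 & v[-1] > 0 &
                   diff(f$snp_map$chrom) == 0)
    mean(vapply(idx, function(j) cor(g[, j], g[, j + 1])^2, numeric(1)))
  }
  expect_gt(adj("intergenic"), adj("CDS"))
})
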