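test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(fst = -0.1), "fst")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(h2_targets = c(a = 1)), "h2_targets")
  expect_error(sim_config(h2_targets = c(a = 0)), "h2_targets")
  expect_error(sim_config(family_size_range = c(1, 14)), "family_size_range")
  expect_error(sim_config(pedigree_error_rate = 1.2), "pedigree_error_rate")
})

test_that("identical config and seed give a bit-identical population", {
  cfg <- sim_config(n_parents_A = 10, n_parents_B = 10, n_families = 20,
                    family_size_range = c(2, 3), n_chrom = 2,
                    snps_per_chrom = 100, fst = 0.2,
                    h2_targets = c(t = 0.3), n_qtl = 20,
                    pedigree_error_rate = 0.2, missing_rate = 0.05,
                    seed = 77)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$phenotypes, p2$phenotypes)
  expect_identical(p1$recorded_pedigree, p2$recorded_pedigree)
  expect_identical(attr(p1$genotypes_missing, "mask"),
                   attr(p2$genotypes_missing, "mask"))
})

test_that("founder divergence matches the target Fst (Weir-Cockerham)", {
  cfg0 <- sim_config(n_parents_A = 60, n_parents_B = 60, n_families = 10,
                     n_chrom = 4, snps_per_chrom = 500, fst = 0, seed = 5)
  f0 <- simulate_founder_haplotypes(cfg0)
  gA <- f0$A[seq(1, nrow(f0$A), 2), ] + f0$A[seq(2, nrow(f0$A), 2), ]
  gB <- f0$B[seq(1, nrow(f0$B), 2), ] + f0$B[seq(2, nrow(f0$B), 2), ]
  expect_lt(abs(wc_fst(gA, gB)), 0.02)

  cfg3 <- sim_config(n_parents_A = 80, n_parents_B = 80, n_families = 10,
                     n_chrom = 5, snps_per_chrom = 1000, fst = 0.3, seed = 6)
  f3 <- simulate_founder_haplotypes(cfg3)
  gA <- f3$A[seq(1, nrow(f3$A), 2), ] + f3$A[seq(2, nrow(f3$A), 2), ]
  gB <- f3$B[seq(1, nrow(f3$B), 2), ] + f3$B[seq(2, nrow(f3$B), 2), ]
  expect_lt(abs(wc_fst(gA, gB) - 0.3), 0.05)

  f3b <- simulate_founder_haplotypes(cfg3)
  expect_identical(f3$A, f3b$A)
})

test_that("zero map length transmits unrecombined parental haplotypes", {
  cfg <- sim_config(n_parents_A = 4, n_parents_B = 4, n_families = 4,
                    n_chrom = 3, snps_per_chrom = 50, chrom_length_cM = 0,
                    fst = 0.2, seed = 9)
  f <- simulate_founder_haplotypes(cfg)
  set.seed(1)
  for (r in 1:10) {
    gam <- gshybrid:::make_gamete(f$A[1, ], f$A[2, ], f$snp_map, 0)
    for (ch in unique(f$snp_map$chrom)) {
      idx <- f$snp_map$chrom == ch
      expect_true(identical(gam[idx], f$A[1, ][idx]) ||
                    identical(gam[idx], f$A[2, ][idx]))
    }
  }
})

test_that("interspecific cross of fixed alternate alleles is fully heterozygous", {
  cfg <- sim_config(n_parents_A = 4, n_parents_B = 4, n_families = 6,
                    n_chrom = 2, snps_per_chrom = 40, fst = 0.2, seed = 2)
  f <- simulate_founder_haplotypes(cfg)
  f$A[, ] <- 1L  # species A fixed for the minor allele
  f$B[, ] <- 0L  # species B fixed for the other
  pop <- mate_diallel(f, cfg)
  g1 <- pop$true_pedigree$id[pop$true_pedigree$generation == "G1"]
  expect_true(all(pop$genotypes[g1, ] == 1L))
})

test_that("realized genomic relationships match pedigree expectations in a homogeneous base", {
  pop <- pop_homogeneous()
  G <- g_matrix(pop$genotypes)
  smry <- summarize_relationships(G, pop$true_pedigree)
  expect_gte(smry$n_pairs[smry$class == "full_sib"], 40)
  expect_lt(abs(smry$mean[smry$class == "full_sib"] - 0.5), 0.05)
  expect_true(smry$mean[smry$class == "half_sib"] > 0.2 &&
                smry$mean[smry$class == "half_sib"] < 0.3)
  expect_lt(abs(smry$mean[smry$class == "unrelated"]), 0.05)
  # unrelated founder pairs within one species
  ped <- pop$true_pedigree
  a_ids <- ped$id[ped$species == "A"]
  offd <- unclass(G)[a_ids, a_ids][upper.tri(diag(length(a_ids)))]
  expect_lt(abs(mean(offd)), 0.05)
})

test_that("pedigree-error injection hits the requested rate and only sires", {
  pop <- pop_pederr()
  rec0 <- inject_pedigree_errors(pop$true_pedigree, 0, seed = 1)
  expect_identical(rec0$sire, pop$true_pedigree$sire)
  rec <- inject_pedigree_errors(pop$true_pedigree, 0.3, seed = 11)
  g1 <- pop$true_pedigree$generation == "G1"
  frac <- mean(rec$sire[g1] != pop$true_pedigree$sire[g1])
  expect_lt(abs(frac - 0.3), 0.05)
  expect_identical(rec$dam, pop$true_pedigree$dam)
  # altered sires stay within the sire species
  sires <- pop$true_pedigree$id[pop$true_pedigree$species == "A"]
  expect_true(all(rec$sire[g1] %in% sires))
})

test_that("phenotype simulation hits heritability targets and the h2 -> 1 limit", {
  pop <- pop_h2_recovery()
  ratio <- var(pop$genetic_values[, "wood"]) /
    var(pop$phenotypes$adjtrue_wood)
  expect_lt(abs(ratio - 0.35), 0.05)

  cfg_hi <- sim_config(n_parents_A = 10, n_parents_B = 10, n_families = 30,
                       family_size_range = c(3, 4), n_chrom = 2,
                       snps_per_chrom = 150, fst = 0.1,
                       h2_targets = c(t = 0.999), env_effects = FALSE,
                       seed = 21)
  pop_hi <- simulate_population(cfg_hi)
  expect_gt(cor(pop_hi$phenotypes$raw_t, pop_hi$genetic_values[, "t"]), 0.99)
  # no environmental terms: raw phenotype equals the adjusted truth
  expect_equal(pop_hi$phenotypes$raw_t, pop_hi$phenotypes$adjtrue_t)
})

test_that("region annotation partitions SNPs at configurable proportions", {
  expect_true(all(annotate_snp_regions(1:1000, gene_fraction = 0) ==
                    "intergenic"))
  pos <- sample.int(4e7, 20000)
  reg <- annotate_snp_regions(pos)
  expect_equal(length(reg), 20000)
  expect_setequal(unique(reg), c("CDS", "genic", "intergenic"))
  frac <- table(reg) / length(reg)
  # defaults emulate the 28.5% / 73.6% / 26.4% CDS / genic / intergenic split
  expect_lt(abs(frac[["CDS"]] - 0.285), 0.05)
  expect_lt(abs(frac[["CDS"]] + frac[["genic"]] - 0.736), 0.05)
  expect_lt(abs(frac[["intergenic"]] - 0.264), 0.05)
})

test_that("missingness masking is counted and bookkept", {
  g <- matrix(rbinom(300 * 2000, 2, 0.3), 300, 2000)
  expect_identical(apply_missingness(g, 0, seed = 1)[, ], g[, ])
  m <- apply_missingness(g, 0.1, seed = 3)
  expect_lt(abs(mean(is.na(m)) - 0.1), 0.01)
  mask <- attr(m, "mask")
  expect_identical(g[mask], as.integer(attr(m, "truth")))
  expect_true(all(is.na(m[mask])))
})

test_that("hybrids fall between the parental species along PC1", {
  pop <- pop_structured()
  pc <- pca_structure(pop$genotypes)
  sp <- pop$true_pedigree$species
  mA <- mean(pc$scores[sp == "A", 1]); mB <- mean(pc$scores[sp == "B", 1])
  hyb <- pc$scores[sp == "hybrid", 1]
  expect_true(all(hyb > min(mA, mB) & hyb < max(mA, mB)))
})

test_that("adjacent-SNP LD increases with the copying persistence", {
  adj_r2 <- function(rho) {
    cfg <- sim_config(n_parents_A = 100, n_parents_B = 2, n_families = 1,
                      n_chrom = 2, snps_per_chrom = 500, fst = 0,
                      ld_rho = rho, seed = 31)
    f <- simulate_founder_haplotypes(cfg)
    g <- f$A[seq(1, 200, 2), ] + f$A[seq(2, 200, 2), ]
    p <- colMeans(g) / 2
    maf <- pmin(p, 1 - p)
    r2 <- vapply(seq_len(ncol(g) - 1), function(j) {
      if (maf[j] < 0.1 || maf[j + 1] < 0.1) return(NA_real_)
      cor(g[, j], g[, j + 1])^2
    }, numeric(1))
    mean(r2, na.rm = TRUE)
  }
  r <- vapply(c(0, 0.5, 0.95), adj_r2, numeric(1))
  expect_true(r[1] < r[2] && r[2] < r[3])
})
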