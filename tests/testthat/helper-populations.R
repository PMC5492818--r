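# Shared simulated populations, built once per test run. Sizes are desk
# scale; seeds fixed so every test sees identical data.

.pop_cache <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
  if (!exists(key, envir = .pop_cache))
    assign(key, builder(), envir = .pop_cache)
  get(key, envir = .pop_cache)
}

# homogeneous base (no species divergence): the regime where the classical
# relationship expectations (0.5 / 0.25 / 0) and h2 calibration hold
pop_homogeneous <- function() .cached("hom", function() {
  simulate_population(sim_config(
    n_parents_A = 40, n_parents_B = 40, n_families = 100,
    family_size_range = c(2, 3), n_chrom = 5, snps_per_chrom = 400,
    fst = 0, ld_rho = 0.95, h2_targets = c(wood = 0.35), n_qtl = 100,
    pedigree_error_rate = 0, missing_rate = 0, seed = 101))
})

# two diverged species + F1 hybrids: the study-like structure
pop_structured <- function() .cached("struct", function() {
  simulate_population(sim_config(
    n_parents_A = 24, n_parents_B = 24, n_families = 70,
    family_size_range = c(4, 6), n_chrom = 5, snps_per_chrom = 400,
    fst = 0.3, ld_rho = 0.95, h2_targets = c(wood = 0.35), n_qtl = 100,
    pedigree_error_rate = 0, missing_rate = 0, seed = 202))
})

# large homogeneous cohort for heritability recovery (~1000 G1, 2000 SNPs)
pop_h2_recovery <- function() .cached("h2big", function() {
  simulate_population(sim_config(
    n_parents_A = 45, n_parents_B = 45, n_families = 170,
    family_size_range = c(5, 7), n_chrom = 5, snps_per_chrom = 400,
    fst = 0, ld_rho = 0.95, h2_targets = c(wood = 0.35), n_qtl = 100,
    pedigree_error_rate = 0, missing_rate = 0, seed = 303))
})

# mid-size structured population for the pedigree-error mechanism
pop_pederr <- function() .cached("pederr", function() {
  simulate_population(sim_config(
    n_parents_A = 30, n_parents_B = 30, n_families = 120,
    family_size_range = c(3, 5), n_chrom = 5, snps_per_chrom = 400,
    fst = 0.3, ld_rho = 0.95, h2_targets = c(wood = 0.35), n_qtl = 100,
    pedigree_error_rate = 0, missing_rate = 0, seed = 404))
})

# structured population with a dense panel for SNP-subset experiments
pop_snp_panel <- function() .cached("snp", function() {
  simulate_population(sim_config(
    n_parents_A = 24, n_parents_B = 24, n_families = 70,
    family_size_range = c(4, 6), n_chrom = 5, snps_per_chrom = 2000,
    fst = 0.3, ld_rho = 0.95, h2_targets = c(wood = 0.35), n_qtl = 100,
    pedigree_error_rate = 0, missing_rate = 0, seed = 505))
})

adjusted_trait <- function(pop, trait = "wood") {
  y <- pop$phenotypes[[paste0("adjtrue_", trait)]]
  names(y) <- pop$phenotypes$id
  y
}

# minimal adjusted Rand index for cluster-label comparison
rand_adjusted <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  stot <- choose(sum(tab), 2)
  exp_ <- si * sj / stot
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
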