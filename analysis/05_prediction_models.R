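#!/usr/bin/env Rscript
# Step 5 — genomic prediction: methods, CV composition, training-set size.
#
# Predictive ability (Pearson r between adjusted phenotypes and GEBVs in
# the validation set). Two experiments:
#  (a) the five engines (ABLUP on the recorded pedigree, GBLUP, rrBLUP,
#      Bayesian LASSO, RKHS) at CV1 / 4:1 on a 1000-SNP random panel
#      (enough markers to sit on the PA plateau at this scale, and light
#      enough for the samplers), 5 replicates;
#  (b) GBLUP and ABLUP across the four CV compositions and five TS:VS
#      ratios on all SNPs, 10 replicates.
# Bayesian chains are shortened to 3000/500/10 here; the full-length
# defaults (20000/2000/100) remain available through the chain arguments.

library(gshybrid)

cfg <- read_sim_config("results/population/config.txt")
pop <- simulate_population(cfg)
pop$genotypes <- impute_simple(pop$genotypes_missing)
y <- adjust_phenotypes(pop$phenotypes, "raw_density",
                       pop$recorded_pedigree)
clusters <- kmeans_clusters(pop$genotypes, seed = cfg$seed)

cat("five methods at CV1, ratio 4:1, 1000-SNP panel...\n")
panel <- snp_subsets(pop$snp_info, counts = 1000, seed = cfg$seed)
tbl_m <- run_grid(pop, y,
                  methods = c("ablup", "gblup", "rrblup", "bl", "rkhs"),
                  scenarios = "CV1", ratios = 4, snp_sets = panel,
                  n_replicates = 5, seed = cfg$seed + 1,
                  chain = 3000, burnin = 500, thin = 10)
write_table_tsv(tbl_m, "results/pa_methods.tsv")
print(summarize_pa(tbl_m, by = "method"), n = Inf)

cat("\nGBLUP vs ABLUP across CV compositions and TS:VS ratios...\n")
tbl_c <- run_grid(pop, y, methods = c("gblup", "ablup"),
                  scenarios = c("CV1", "CV2", "CV3", "CV4"),
                  ratios = c(1, 2, 3, 4, 9), n_replicates = 10,
                  seed = cfg$seed + 2, clusters = clusters)
write_table_tsv(tbl_c, "results/pa_compositions_sizes.tsv")
print(summarize_pa(tbl_c, by = c("method", "scenario")), n = Inf)
print(summarize_pa(tbl_c[tbl_c$scenario == "CV1", ],
                   by = c("method", "ratio")), n = Inf)

cat("\nparents-only training vs size-matched random control...\n")
ped <- pop$recorded_pedigree
n0 <- sum(ped$generation == "G0")
G <- g_matrix(pop$genotypes)
set.seed(cfg$seed + 3)
seeds <- sample.int(1e7, 10)
po <- t(vapply(seeds, function(s) {
  s1 <- make_split("parents_only", 1, ped, seed = s)
  f1 <- fit_blup(y[s1$training], G)
  s2 <- make_split("CV1", 1, ped, seed = s, sizes = c(n0, n0))
  f2 <- fit_blup(y[s2$training], G)
  c(parents_only = predictive_ability(y[s1$validation],
                                      f1$gebv[s1$validation]),
    random_matched = predictive_ability(y[s2$validation],
                                        f2$gebv[s2$validation]))
}, numeric(2)))
write_table_tsv(as.data.frame(po), "results/pa_parents_only.tsv")
cat(sprintf("mean PA parents-only %.3f vs size-matched random %.3f\n",
            mean(po[, 1]), mean(po[, 2])))
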