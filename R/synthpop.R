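#' Configuration for a simulated two-species hybrid breeding population
#'
#' Bundles every parameter of the synthetic population generator. Defaults
#' mirror the design of a two-generation Eucalyptus-type hybrid breeding
#' program: two diverged parental species (90 + 78 surviving parents) crossed
#' in an incomplete diallel into ~338 full-sib F1 families of 1-13 offspring,
#' genotyped at ~41k SNPs on 11 chromosomes.
#'
#' @param n_parents_A,n_parents_B number of founder parents per species.
#'   Species A parents act as sires, species B parents as dams.
#' @param n_families number of full-sib families (distinct sire x dam pairs).
#' @param family_size_range integer length-2; offspring per family drawn
#'   uniformly from this range (default 1-13).
#' @param n_chrom,snps_per_chrom genome layout.
#' @param chrom_length_cM genetic map length per chromosome (cM).
#' @param chrom_length_bp physical chromosome length; SNP bp positions are
#'   uniform on `[1, chrom_length_bp]` and genetic positions proportional.
#' @param fst target divergence between the two species in `[0, 1)`;
#'   per-SNP species allele frequencies follow a Balding-Nichols model
#'   around shared ancestral frequencies.
#' @param ld_rho adjacent-marker haplotype-copying persistence in `[0, 1)`;
#'   founder haplotypes are built by a first-order Markov copying process
#'   over a panel of template haplotypes, so adjacent-SNP LD grows with
#'   `ld_rho`.
#' @param ld_rho_genic optional separate persistence for SNPs in genic
#'   regions (CDS + genic); lower values give faster LD decay in genes.
#' @param n_templates template haplotypes per species for the copying process.
#' @param h2_targets named numeric vector of narrow-sense heritabilities in
#'   (0,1), one trait each.
#' @param n_qtl QTLs per trait, sampled among the simulated SNPs.
#' @param pedigree_error_rate fraction of G1 records whose recorded sire is
#'   replaced by a different random male of the same species (pollen
#'   contamination / mislabelling model).
#' @param missing_rate i.i.d. genotype missingness applied to the final
#'   matrix.
#' @param gene_fraction,cds_fraction fraction of the genome covered by genic
#'   regions (gene body + 2 kb flanks) and the CDS share of the genic span.
#'   Defaults reproduce a 28.5/73.6/26.4% CDS/genic/intergenic SNP split.
#' @param env_effects logical; add fixed site/age offsets and random
#'   block-within-site effects to raw phenotypes.
#' @param seed integer master seed; identical configs + seed give
#'   bit-identical populations.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_parents_A = 90L, n_parents_B = 78L,
                       n_families = 338L, family_size_range = c(1L, 13L),
                       n_chrom = 11L, snps_per_chrom = 3755L,
                       chrom_length_cM = 100, chrom_length_bp = 4e7,
                       fst = 0.3, ld_rho = 0.95, ld_rho_genic = NULL,
                       n_templates = 100L,
                       h2_targets = c(trait1 = 0.35), n_qtl = 100L,
                       pedigree_error_rate = 0.3, missing_rate = 0.1,
                       gene_fraction = 0.736, cds_fraction = 0.388,
                       env_effects = TRUE, seed = 1L) {
  stopifnot(n_parents_A >= 2, n_parents_B >= 2, n_families >= 1,
            length(family_size_range) == 2,
            n_chrom >= 1, snps_per_chrom >= 1, chrom_length_cM >= 0)
  if (!is.numeric(fst) || fst < 0 || fst >= 1)
    stop("`fst` must be in [0, 1)")
  if (!is.numeric(ld_rho) || ld_rho < 0 || ld_rho >= 1)
    stop("`ld_rho` must be in [0, 1)")
  if (!is.null(ld_rho_genic) && (ld_rho_genic < 0 || ld_rho_genic >= 1))
    stop("`ld_rho_genic` must be in [0, 1)")
  if (any(family_size_range < 1) || any(family_size_range > 13))
    stop("`family_size_range` must lie within [1, 13]")
  if (family_size_range[1] > family_size_range[2])
    stop("`family_size_range` must be non-decreasing")
  if (any(h2_targets <= 0) || any(h2_targets >= 1))
    stop("all `h2_targets` must be in (0, 1)")
  if (pedigree_error_rate < 0 || pedigree_error_rate > 1)
    stop("`pedigree_error_rate` must be in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1)
    stop("`missing_rate` must be in [0, 1]")
  if (gene_fraction < 0 || gene_fraction > 1 ||
      cds_fraction < 0 || cds_fraction > 1)
    stop("`gene_fraction` and `cds_fraction` must be in [0, 1]")
  if (is.null(names(h2_targets)))
    names(h2_targets) <- paste0("trait", seq_along(h2_targets))
  cfg <- list(
    n_parents_A = as.integer(n_parents_A),
    n_parents_B = as.integer(n_parents_B),
    n_families = as.integer(n_families),
    family_size_range = as.integer(family_size_range),
    n_chrom = as.integer(n_chrom),
    snps_per_chrom = as.integer(snps_per_chrom),
    chrom_length_cM = chrom_length_cM,
    chrom_length_bp = chrom_length_bp,
    fst = fst, ld_rho = ld_rho, ld_rho_genic = ld_rho_genic,
    n_templates = as.integer(n_templates),
    h2_targets = h2_targets, n_qtl = as.integer(n_qtl),
    pedigree_error_rate = pedigree_error_rate,
    missing_rate = missing_rate,
    gene_fraction = gene_fraction, cds_fraction = cds_fraction,
    env_effects = isTRUE(env_effects),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' SNP map for a configured genome
#'
#' Uniform random bp positions per chromosome (sorted), genetic positions
#' proportional to physical ones, plus region annotation.
#' @keywords internal
make_snp_map <- function(config) {
  p_chr <- config$snps_per_chrom
  maps <- lapply(seq_len(config$n_chrom), function(ch) {
    pos <- sort(sample.int(config$chrom_length_bp, p_chr))
    tibble::tibble(
      chrom = ch,
      pos_bp = pos,
      pos_cM = pos / config$chrom_length_bp * config$chrom_length_cM)
  })
  map <- do.call(rbind, maps)
  map$region <- annotate_snp_regions(map$pos_bp,
                                     gene_fraction = config$gene_fraction,
                                     cds_fraction = config$cds_fraction)
  map$id <- sprintf("snp_%d_%d", map$chrom, map$pos_bp)
  map
}

#' Annotate SNPs as CDS, genic (non-CDS) or intergenic
#'
#' Synthetic gene models tile each chromosome with a fixed period: a gene
#' body flanked by 2 kb counts as genic, a central block of the gene body as
#' CDS, the rest of the period as intergenic. Labels partition the SNPs:
#' `"CDS"`, `"genic"` (genic but non-CDS) and `"intergenic"`; the genic
#' *region* in the biological sense is CDS plus genic.
#'
#' @param snp_pos_bp integer vector of physical positions.
#' @param gene_fraction fraction of the period covered by the genic span;
#'   0 makes every SNP intergenic.
#' @param cds_fraction CDS share of the genic span.
#' @param gene_length,flank gene-body and flank lengths in bp.
#' @return character vector in `{"CDS","genic","intergenic"}`.
#' @export
annotate_snp_regions <- function(snp_pos_bp, gene_fraction = 0.736,
                                 cds_fraction = 0.388,
                                 gene_length = 8000, flank = 2000) {
  if (gene_fraction <= 0)
    return(rep("intergenic", length(snp_pos_bp)))
  genic_span <- gene_length + 2 * flank
  period <- genic_span / gene_fraction
  cds_len <- cds_fraction * genic_span
  offset <- (snp_pos_bp - 1) %% period
  # genic span sits at the start of each period; CDS centred in the gene body
  cds_start <- flank + (gene_length - cds_len) / 2
  region <- rep("intergenic", length(snp_pos_bp))
  region[offset < genic_span] <- "genic"
  region[offset >= cds_start & offset < cds_start + cds_len] <- "CDS"
  region
}

#' Simulate founder haplotypes for the two parental species
#'
#' Per-SNP ancestral allele frequencies are uniform on (0.05, 0.95); species
#' frequencies deviate from them under a Balding-Nichols model with the
#' configured Fst. Haplotypes are then assembled by first-order Markov
#' copying over a species-specific panel of template haplotypes: at each SNP
#' the copied template is kept with probability `ld_rho` (or
#' `ld_rho_genic` at genic/CDS SNPs) and redrawn otherwise, which induces
#' adjacent-marker LD that decays geometrically with marker distance.
#' Chains restart at chromosome boundaries.
#'
#' @param config a [sim_config()].
#' @param snp_map optional precomputed SNP map (from the internal map
#'   builder); built from `config` if omitted.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return list with per-species haplotype matrices (`2*n_parents` rows x
#'   SNP columns, 0/1), the SNP map and the per-species allele frequencies.
#' @export
simulate_founder_haplotypes <- function(config, snp_map = NULL,
                                        seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  if (is.null(snp_map)) snp_map <- make_snp_map(config)
  p <- nrow(snp_map)
  # U-shaped ancestral spectrum (neutral-like, chip-realistic: mean MAF ~0.15)
  p0 <- 0.02 + 0.96 * rbeta(p, 0.3, 0.3)
  if (config$fst == 0) {
    pA <- pB <- p0
  } else {
    shape <- (1 - config$fst) / config$fst
    pA <- rbeta(p, p0 * shape, (1 - p0) * shape)
    pB <- rbeta(p, p0 * shape, (1 - p0) * shape)
  }
  rho <- rep(config$ld_rho, p)
  if (!is.null(config$ld_rho_genic))
    rho[snp_map$region != "intergenic"] <- config$ld_rho_genic
  new_chrom <- c(TRUE, diff(snp_map$chrom) != 0)
  hap_panel <- function(freq, n_hap) {
    K <- config$n_templates
    templates <- matrix(rbinom(K * p, 1L, rep(freq, each = K)), nrow = K)
    haps <- matrix(0L, nrow = n_hap, ncol = p)
    for (h in seq_len(n_hap)) {
      switch_ <- runif(p) >= rho
      switch_[new_chrom] <- TRUE
      seg <- cumsum(switch_)
      tmpl <- sample.int(K, max(seg), replace = TRUE)[seg]
      haps[h, ] <- templates[cbind(tmpl, seq_len(p))]
    }
    haps
  }
  list(
    A = hap_panel(pA, 2L * config$n_parents_A),
    B = hap_panel(pB, 2L * config$n_parents_B),
    snp_map = snp_map,
    freq_A = pA, freq_B = pB)
}

# one meiosis: recombine the two haplotypes of a parent into a gamete,
# crossovers Poisson on the genetic map (Haldane, no interference)
make_gamete <- function(hap1, hap2, snp_map, chrom_length_cM) {
  p <- length(hap1)
  out <- integer(p)
  for (ch in unique(snp_map$chrom)) {
    idx <- which(snp_map$chrom == ch)
    n_xo <- rpois(1, chrom_length_cM / 100)
    start <- sample.int(2L, 1L)
    if (n_xo == 0L || chrom_length_cM == 0) {
      out[idx] <- if (start == 1L) hap1[idx] else hap2[idx]
    } else {
      bp <- sort(runif(n_xo, 0, chrom_length_cM))
      seg <- findInterval(snp_map$pos_cM[idx], bp)
      use1 <- (seg + start) %% 2L == 1L
      out[idx] <- ifelse(use1, hap1[idx], hap2[idx])
    }
  }
  out
}

#' Mate the two founder panels in an incomplete diallel
#'
#' Draws `n_families` distinct sire (species A) x dam (species B) pairs,
#' family sizes uniform over `family_size_range`, and forms each offspring
#' genotype from one recombinant gamete per parent (crossovers Poisson on
#' the genetic map; Haldane map function, no interference).
#'
#' @param founders output of [simulate_founder_haplotypes()].
#' @param config the same [sim_config()].
#' @param seed RNG seed; defaults to `config$seed + 1` so founder and mating
#'   randomness are decoupled but jointly reproducible.
#' @return list with the combined 0/1/2 genotype matrix (founders + G1,
#'   individuals x SNPs, rownames = ids), the true pedigree tibble
#'   (id, sire, dam, generation, species) and the SNP map.
#' @export
mate_diallel <- function(founders, config, seed = config$seed + 1L) {
  set.seed(seed)
  snp_map <- founders$snp_map
  nA <- config$n_parents_A; nB <- config$n_parents_B
  if (config$n_families > nA * nB)
    stop("n_families exceeds the number of possible sire x dam pairs")
  ids_A <- sprintf("A%03d", seq_len(nA))
  ids_B <- sprintf("B%03d", seq_len(nB))
  pair_idx <- sample.int(nA * nB, config$n_families)
  sire_of <- ((pair_idx - 1L) %% nA) + 1L
  dam_of <- ((pair_idx - 1L) %/% nA) + 1L
  fam_sizes <- sample(seq(config$family_size_range[1],
                          config$family_size_range[2]),
                      config$n_families, replace = TRUE)
  n_off <- sum(fam_sizes)
  p <- nrow(snp_map)

  geno_A <- founders$A[seq(1, 2 * nA, 2), , drop = FALSE] +
    founders$A[seq(2, 2 * nA, 2), , drop = FALSE]
  geno_B <- founders$B[seq(1, 2 * nB, 2), , drop = FALSE] +
    founders$B[seq(2, 2 * nB, 2), , drop = FALSE]

  off <- matrix(0L, nrow = n_off, ncol = p)
  off_ids <- sprintf("H%04d", seq_len(n_off))
  off_sire <- character(n_off); off_dam <- character(n_off)
  k <- 0L
  for (f in seq_len(config$n_families)) {
    s <- sire_of[f]; d <- dam_of[f]
    hs1 <- founders$A[2 * s - 1L, ]; hs2 <- founders$A[2 * s, ]
    hd1 <- founders$B[2 * d - 1L, ]; hd2 <- founders$B[2 * d, ]
    for (o in seq_len(fam_sizes[f])) {
      k <- k + 1L
      off[k, ] <- make_gamete(hs1, hs2, snp_map, config$chrom_length_cM) +
        make_gamete(hd1, hd2, snp_map, config$chrom_length_cM)
      off_sire[k] <- ids_A[s]; off_dam[k] <- ids_B[d]
    }
  }
  genotypes <- rbind(geno_A, geno_B, off)
  rownames(genotypes) <- c(ids_A, ids_B, off_ids)
  colnames(genotypes) <- snp_map$id
  pedigree <- tibble::tibble(
    id = c(ids_A, ids_B, off_ids),
    sire = c(rep(NA_character_, nA + nB), off_sire),
    dam = c(rep(NA_character_, nA + nB), off_dam),
    generation = c(rep("G0", nA + nB), rep("G1", n_off)),
    species = c(rep("A", nA), rep("B", nB), rep("hybrid", n_off)))
  list(genotypes = genotypes, true_pedigree = pedigree, snp_map = snp_map)
}

#' Inject pedigree-recording errors
#'
#' For a Bernoulli(`rate`) subset of G1 records the recorded sire is replaced
#' by a different random G0 male of the same species, emulating pollen
#' contamination; with `mode = "mislabel"` the whole record (sire and dam)
#' is replaced by a different random pair. The true pedigree is untouched.
#'
#' @param true_pedigree pedigree tibble from [mate_diallel()].
#' @param rate error fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @param mode `"sire"` (default) or `"mislabel"`.
#' @return recorded pedigree tibble with a logical `altered` column.
#' @export
inject_pedigree_errors <- function(true_pedigree, rate, seed = 1L,
                                   mode = c("sire", "mislabel")) {
  mode <- match.arg(mode)
  stopifnot(rate >= 0, rate <= 1)
  set.seed(seed)
  ped <- true_pedigree
  g1 <- which(ped$generation == "G1")
  sires <- unique(ped$sire[g1]); sires <- sires[!is.na(sires)]
  all_sires <- ped$id[ped$species == "A" & ped$generation == "G0"]
  all_dams <- ped$id[ped$species == "B" & ped$generation == "G0"]
  hit <- g1[runif(length(g1)) < rate]
  altered <- rep(FALSE, nrow(ped))
  for (i in hit) {
    others <- setdiff(all_sires, ped$sire[i])
    if (length(others) == 0) next
    ped$sire[i] <- sample(others, 1L)
    if (mode == "mislabel") {
      od <- setdiff(all_dams, ped$dam[i])
      if (length(od) > 0) ped$dam[i] <- sample(od, 1L)
    }
    altered[i] <- TRUE
  }
  ped$altered <- altered
  ped
}

#' Simulate additive phenotypes at target heritabilities
#'
#' Per trait, `n_qtl` QTLs are sampled among the SNPs, additive effects drawn
#' standard normal, and environmental noise scaled so that the realized
#' additive variance over total variance equals the target narrow-sense
#' heritability. When `env_effects` is on, fixed site and age offsets and
#' random block-within-site effects (magnitudes proportional to the
#' phenotypic SD) are added on top, for exercising phenotype adjustment.
#'
#' @param genotypes 0/1/2 matrix, individuals x SNPs (no missing).
#' @param config a [sim_config()]; uses `h2_targets`, `n_qtl`, `env_effects`.
#' @param seed RNG seed.
#' @return list: `phenotypes` tibble (id, site, block, age, one raw + one
#'   adjusted-truth column per trait), `qtl_effects` (per-trait tibbles of
#'   SNP index and effect), `genetic_values` matrix (individuals x traits).
#' @export
simulate_phenotypes <- function(genotypes, config, seed = config$seed + 2L) {
  if (any(config$h2_targets <= 0) || any(config$h2_targets >= 1))
    stop("heritability targets must be in (0, 1)")
  if (config$n_qtl > ncol(genotypes))
    stop("n_qtl exceeds the number of SNPs")
  set.seed(seed)
  n <- nrow(genotypes)
  ids <- rownames(genotypes)
  site <- sample(1:2, n, replace = TRUE)
  block <- sample(1:8, n, replace = TRUE)
  age <- sample(c(3, 6), n, replace = TRUE)
  tbl <- tibble::tibble(id = ids, site = site,
                        block = paste0(site, "_", block), age = age)
  qtl_effects <- list()
  gmat <- matrix(NA_real_, n, length(config$h2_targets),
                 dimnames = list(ids, names(config$h2_targets)))
  for (tr in names(config$h2_targets)) {
    h2 <- config$h2_targets[[tr]]
    qtl <- sample.int(ncol(genotypes), config$n_qtl)
    beta <- rnorm(config$n_qtl)
    g <- drop(genotypes[, qtl, drop = FALSE] %*% beta)
    vg <- var(g)
    if (vg <= 0) stop("realized additive variance is zero; add QTLs or diversity")
    e <- rnorm(n, 0, sqrt(vg * (1 - h2) / h2))
    y_adj <- g + e          # what perfect adjustment would recover
    sy <- sqrt(vg / h2)
    if (config$env_effects) {
      site_off <- c(0, 0.5 * sy)[site]
      age_off <- 0.15 * sy * (age - mean(age))
      blk <- rnorm(16, 0, 0.3 * sy)
      names(blk) <- paste0(rep(1:2, each = 8), "_", rep(1:8, 2))
      raw <- y_adj + site_off + age_off + blk[tbl$block]
    } else {
      raw <- y_adj
    }
    tbl[[paste0("raw_", tr)]] <- unname(raw)
    tbl[[paste0("adjtrue_", tr)]] <- unname(y_adj)
    gmat[, tr] <- g
    qtl_effects[[tr]] <- tibble::tibble(snp = qtl, effect = beta)
  }
  list(phenotypes = tbl, qtl_effects = qtl_effects, genetic_values = gmat)
}

#' Mask genotypes missing at random
#'
#' Sets entries to `NA` i.i.d. at the given rate and records the masked
#' positions and their true values so imputation accuracy can be scored.
#'
#' @param genotypes 0/1/2 matrix.
#' @param rate missing fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return the masked matrix with attributes `mask` (integer positions into
#'   the matrix) and `truth` (the masked true genotypes).
#' @export
apply_missingness <- function(genotypes, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  set.seed(seed)
  out <- genotypes
  if (rate > 0) {
    mask <- which(runif(length(out)) < rate)
    truth <- out[mask]
    out[mask] <- NA_integer_
  } else {
    mask <- integer(0); truth <- integer(0)
  }
  attr(out, "mask") <- mask
  attr(out, "truth") <- truth
  out
}

#' Simulate a complete two-species hybrid breeding population
#'
#' Orchestrates the generator end to end: SNP map + region annotation,
#' founder haplotypes, incomplete-diallel mating, phenotypes, pedigree-error
#' injection and genotype missingness, all deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_population`: list with `genotypes` (complete
#'   matrix), `genotypes_missing` (masked copy, if `missing_rate > 0`),
#'   `snp_info`, `true_pedigree`, `recorded_pedigree`, `phenotypes`,
#'   `qtl_effects`, `genetic_values`, `founder_freqs` and the `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  founders <- simulate_founder_haplotypes(config)
  pop <- mate_diallel(founders, config)
  phen <- simulate_phenotypes(pop$genotypes, config)
  recorded <- if (config$pedigree_error_rate > 0)
    inject_pedigree_errors(pop$true_pedigree, config$pedigree_error_rate,
                           seed = config$seed + 3L)
  else cbind(pop$true_pedigree, altered = FALSE)
  miss <- if (config$missing_rate > 0)
    apply_missingness(pop$genotypes, config$missing_rate,
                      seed = config$seed + 4L)
  else NULL
  structure(list(
    genotypes = pop$genotypes,
    genotypes_missing = miss,
    snp_info = pop$snp_map,
    true_pedigree = pop$true_pedigree,
    recorded_pedigree = tibble::as_tibble(recorded),
    phenotypes = phen$phenotypes,
    qtl_effects = phen$qtl_effects,
    genetic_values = phen$genetic_values,
    founder_freqs = list(A = founders$freq_A, B = founders$freq_B),
    config = config), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  ped <- x$true_pedigree
  cat("Simulated hybrid breeding population\n",
      sprintf("  %d individuals (%d G0, %d G1), %d SNPs on %d chromosomes\n",
              nrow(x$genotypes), sum(ped$generation == "G0"),
              sum(ped$generation == "G1"), ncol(x$genotypes),
              x$config$n_chrom),
      sprintf("  traits: %s (target h2: %s)\n",
              paste(names(x$config$h2_targets), collapse = ", "),
              paste(x$config$h2_targets, collapse = ", ")), sep = "")
  invisible(x)
}
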