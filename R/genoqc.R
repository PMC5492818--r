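#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test: given the allele counts, sums the
#' probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count. Computed with log-factorials
#' so it is stable to large samples.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, not all zero).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  # heterozygote counts share the parity of the minor-allele count
  n_minor <- min(nA, na)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(nAa | n, nA) = log[ n! / (nAA! nAa! naa!) * 2^nAa * nA! na! / (2n)! ]
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- (na - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

call_rates <- function(genotypes, margin) {
  ok <- !is.na(genotypes)
  if (margin == 1) rowMeans(ok) else colMeans(ok)
}

# method-of-moments inbreeding estimate per sample: 1 - observed het /
# expected het, expectation from sample allele frequencies
inbreeding_mom <- function(genotypes) {
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  poly <- which(p > 0 & p < 1 & !is.na(p))
  if (length(poly) == 0) return(rep(0, nrow(genotypes)))
  g <- genotypes[, poly, drop = FALSE]
  eh <- matrix(2 * p[poly] * (1 - p[poly]), nrow(g), length(poly), byrow = TRUE)
  eh[is.na(g)] <- NA
  1 - rowSums(g == 1, na.rm = TRUE) / rowSums(eh, na.rm = TRUE)
}

#' Sample-level quality control
#'
#' Removes samples with call rate strictly below `call_rate_min` or a
#' method-of-moments inbreeding coefficient strictly above
#' `inbreeding_max`; survivor order is preserved.
#'
#' @param genotypes individuals x SNPs 0/1/2/NA matrix.
#' @param call_rate_min minimum fraction of called genotypes (default 0.70).
#' @param inbreeding_max maximum inbreeding estimate (default 1; values
#'   above one indicate genotyping artifacts).
#' @return list: `genotypes` (filtered) and `report` (class `qc_report`).
#' @export
qc_samples <- function(genotypes, call_rate_min = 0.70, inbreeding_max = 1) {
  stopifnot(nrow(genotypes) > 0)
  cr <- call_rates(genotypes, 1)
  f <- inbreeding_mom(genotypes)
  drop_ <- cr < call_rate_min | f > inbreeding_max
  if (all(drop_)) stop("sample QC removed every sample")
  report <- structure(list(
    n_samples_in = nrow(genotypes),
    n_samples_removed = sum(drop_),
    thresholds = list(call_rate_min = call_rate_min,
                      inbreeding_max = inbreeding_max)),
    class = "qc_report")
  list(genotypes = genotypes[!drop_, , drop = FALSE], report = report)
}

#' SNP-level quality control
#'
#' Removes SNPs in three sequential steps: call rate < `call_rate_min`,
#' then monomorphism or minor allele frequency < `maf_min`, then exact
#' Hardy-Weinberg p-value < `hwe_p_min` (all strict inequalities). The
#' report itemizes the count removed at each step; counts reconcile exactly
#' with the change in dimensions.
#'
#' @param genotypes individuals x SNPs 0/1/2/NA matrix (sample QC applied).
#' @param call_rate_min,maf_min,hwe_p_min thresholds (defaults 0.70, 0.01,
#'   1e-6).
#' @return list: `genotypes`, `keep` (retained column indices into the
#'   input) and `report` (class `qc_report`).
#' @export
qc_snps <- function(genotypes, call_rate_min = 0.70, maf_min = 0.01,
                    hwe_p_min = 1e-6) {
  p <- ncol(genotypes)
  keep <- seq_len(p)
  cr <- call_rates(genotypes, 2)
  fail_cr <- cr < call_rate_min
  keep <- keep[!fail_cr]
  g <- genotypes[, keep, drop = FALSE]
  freq <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  fail_maf <- is.na(maf) | maf < maf_min | freq == 0 | freq == 1
  keep <- keep[!fail_maf]
  g <- genotypes[, keep, drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]
    hwe_exact_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                   sum(x == 2, na.rm = TRUE))
  }, numeric(1))
  fail_hwe <- hwe_p < hwe_p_min
  keep <- keep[!fail_hwe]
  report <- structure(list(
    n_snps_in = p,
    n_snps_removed_callrate = sum(fail_cr),
    n_snps_removed_maf_mono = sum(fail_maf),
    n_snps_removed_hwe = sum(fail_hwe),
    n_snps_out = length(keep),
    thresholds = list(call_rate_min = call_rate_min, maf_min = maf_min,
                      hwe_p_min = hwe_p_min)),
    class = "qc_report")
  list(genotypes = genotypes[, keep, drop = FALSE], keep = keep,
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  for (nm in setdiff(names(x), "thresholds"))
    cat(sprintf("  %s: %s\n", nm, x[[nm]]))
  cat("  thresholds:",
      paste(names(x$thresholds), unlist(x$thresholds), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Modal-genotype imputation
#'
#' Replaces missing entries with the per-SNP modal genotype (ties broken
#' toward the lower dosage); non-missing entries are never altered. A
#' deliberately simple baseline; haplotype-based imputation is out of scope.
#'
#' @param genotypes 0/1/2/NA matrix.
#' @return completed matrix.
#' @export
impute_simple <- function(genotypes) {
  out <- genotypes
  for (j in seq_len(ncol(out))) {
    x <- out[, j]
    nas <- is.na(x)
    if (!any(nas)) next
    if (all(nas)) stop(sprintf("SNP column %d is entirely missing", j))
    counts <- tabulate(x[!nas] + 1L, nbins = 3L)
    out[nas, j] <- which.max(counts) - 1L  # which.max takes the first tie
  }
  out
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of genotype dosages.
#' @param a,b dosage vectors without missing values.
#' @export
ld_r2 <- function(a, b) {
  if (anyNA(a) || anyNA(b)) stop("missing genotypes; impute first")
  if (var(a) == 0 || var(b) == 0)
    stop("r2 undefined for a monomorphic SNP")
  cor(a, b)^2
}

#' Greedy windowed LD pruning
#'
#' Within each sliding window of `window` SNPs (stepped by `step`), while
#' any retained pair has r-squared above `r2_max`, the later SNP of the
#' worst (highest-r2) pair is dropped; ties resolve to the first such pair,
#' making the procedure deterministic. With `chrom` supplied, windows do not
#' cross chromosome boundaries.
#'
#' @param genotypes complete dosage matrix, SNPs in map order.
#' @param r2_max retention threshold (default 0.2).
#' @param window,step window size and slide in SNPs (defaults 50 / 5).
#' @param chrom optional chromosome id per SNP.
#' @return sorted integer indices of the retained SNPs.
#' @export
ld_prune <- function(genotypes, r2_max = 0.2, window = 50, step = 5,
                     chrom = NULL) {
  p <- ncol(genotypes)
  keep <- rep(TRUE, p)
  groups <- if (is.null(chrom)) list(seq_len(p)) else
    split(seq_len(p), chrom)
  for (idx in groups) {
    starts <- unique(c(seq(1, max(1, length(idx) - window + 1), by = step)))
    for (s in starts) {
      win <- idx[s:min(s + window - 1, length(idx))]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2) break
        v <- apply(genotypes[, act, drop = FALSE], 2, var)
        act <- act[v > 0]
        if (length(act) < 2) break
        r2 <- cor(genotypes[, act, drop = FALSE])^2
        r2[lower.tri(r2, diag = TRUE)] <- 0
        worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        if (r2[worst[1], worst[2]] <= r2_max) break
        keep[act[max(worst)]] <- FALSE  # drop the later SNP of the pair
      }
    }
  }
  which(keep)
}

#' Drift-recombination expectation of r-squared (Hill-Weir)
#'
#' Expected r-squared at population-scaled recombination `C`, with the
#' finite-sample correction for `n` sampled individuals, as used for
#' nonlinear LD-decay regressions on distance.
#'
#' @param C population recombination parameter (rho times distance).
#' @param n sample size.
#' @export
expected_r2_hillweir <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the LD-decay curve over physical distance
#'
#' Least-squares fit of the Hill-Weir expectation with `C = rho * distance`,
#' over a single non-negative decay-rate parameter `rho` (per bp), by 1-D
#' golden-section search on a log grid. All-flat data collapses to the
#' `C -> 0` boundary.
#'
#' @param r2_values observed r-squared per SNP pair.
#' @param distances_bp pairwise physical distances.
#' @param n_samples sample size behind the r-squared estimates.
#' @return object of class `ld_decay_fit`: list with `C_per_bp`, `n`, `rss`
#'   and a `predict(distance)` closure.
#' @export
fit_ld_decay <- function(r2_values, distances_bp, n_samples) {
  if (length(r2_values) < 10) stop("need at least 10 SNP pairs")
  if (!all(is.finite(r2_values)) || !all(is.finite(distances_bp)))
    stop("non-finite r2 or distance values")
  rss_of <- function(log10rho) {
    rho <- 10^log10rho
    sum((r2_values - expected_r2_hillweir(rho * distances_bp, n_samples))^2)
  }
  opt <- optimize(rss_of, interval = c(-14, 0), tol = 1e-10)
  rho <- 10^opt$minimum
  # boundary check: essentially-flat fits report the C -> 0 limit
  if (rss_of(-14) <= opt$objective + 1e-12) rho <- 0
  structure(list(
    C_per_bp = rho, n = n_samples,
    rss = if (rho == 0) rss_of(-14) else opt$objective,
    predict = function(d) expected_r2_hillweir(rho * d, n_samples)),
    class = "ld_decay_fit")
}
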