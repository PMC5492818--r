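---
title: "Models and simulation design in gshybrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and simulation design in gshybrid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`gshybrid` evaluates genomic prediction in a two-generation interspecific
hybrid breeding population: parents of two diverged species (G0) crossed in
an incomplete diallel, producing F1 full-sib families (G1). The package
covers the full workflow — synthetic population generation, genotype QC,
relationship matrices, five prediction engines, heritability estimation,
and relatedness-aware cross-validation — with the `analysis/` scripts as the
narrative drivers.

# The prediction model

All engines fit variants of the linear mixed model

$$\mathbf{y} = \mathbf{1}\beta + \mathbf{Z}\mathbf{a} + \mathbf{e},$$

where $\mathbf{y}$ holds adjusted phenotypes and $\mathbf{a}$ is either a
vector of individual breeding values with covariance proportional to a
relationship matrix (ABLUP: pedigree $\mathbf{A}$; GBLUP: genomic
$\mathbf{G}$; RKHS: Gaussian kernels $\mathbf{K}_h$), or a vector of marker
effects (rrBLUP: i.i.d. normal; Bayesian LASSO: double-exponential through
the exponential scale mixture). The genomic relationship matrix follows
VanRaden,

$$\mathbf{G} = \frac{(\mathbf{M}-\mathbf{P})(\mathbf{M}-\mathbf{P})^\top}
{2\sum_j p_j(1-p_j)},$$

with $\mathbf{M}$ the minor-allele dosage matrix and the $j$-th column of
$\mathbf{P}$ equal to $2p_j$. Note a coding subtlety: stating the centering
as $2(p_j-0.5)$ presumes a $-1/0/1$ coding; both parameterizations are
algebraically identical and `g_matrix()` accepts the 0/1/2 coding directly.
Allele frequencies default to the sample but can be supplied, so a single
$\mathbf{G}$ computed on the full panel serves training and validation
subsets — the convention used throughout the cross-validation grid.

`fit_blup()` solves the mixed-model equations through the equivalent
variance-model form ($\hat\beta$ by GLS against
$\mathbf{V} = \mathbf{ZKZ}^\top\sigma_a^2 + \mathbf{I}\sigma_e^2$, then
$\hat{\mathbf{a}} = \sigma_a^2\mathbf{KZ}^\top\mathbf{V}^{-1}
(\mathbf{y}-\mathbf{1}\hat\beta)$). The two formulations coincide whenever
$\mathbf{K}$ is invertible; the variance form additionally handles the
rank-deficient $\mathbf{G}$ that arises when allele frequencies are
estimated from the same sample, without a diagonal blend that would perturb
the GBLUP–rrBLUP equivalence (which the test suite asserts to
$10^{-6}$). rrBLUP's shrinkage is $\lambda = \sigma_e^2/\sigma_m^2$; the
equivalence mapping is $\sigma_g^2 = 2\sum_j p_j(1-p_j)\,\sigma_m^2$.

## Variance components and heritability

`reml_variance_components()` profiles the restricted likelihood on the
ratio $h = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ after rotating into the
eigenbasis of $\mathbf{K}$, maximized by bounded 1-D search (tolerance
1e-8) — deterministic, with no general mixed-model machinery. Heritability
follows the ratio definitions $h_a^2=\sigma_a^2/\sigma_y^2$ (pedigree) and
$h_g^2=\sigma_g^2/\sigma_y^2$ (genomic), with $\sigma_y^2$ the sample
phenotypic variance and a delta-method standard error from a numeric
observed-information matrix.

A caveat established by the test suite: in the two-species F1 cohort the
VanRaden $\mathbf{G}$ referenced to pooled allele frequencies has a mean
diagonal around 0.8 (interspecific hybrids carry excess heterozygosity
relative to the pooled-sample Hardy–Weinberg expectation), which inflates
$h_g^2$ by roughly the reciprocal factor. Calibration of the estimator is
therefore demonstrated in a homogeneous cohort (`fst = 0`), where the
recovery bias at true $h^2 \in \{0.10, 0.35\}$ is below 0.05 over 20
replicates of an $n \approx 1000$, 2000-SNP cohort. In the structured
regime the package instead demonstrates the *comparative* result that
matters for breeding practice: with 30% wrong recorded sires,
$\hat h_a^2$ (recorded pedigree) falls below $\hat h_g^2$ in $\ge$ 18/20
replicates, and the mean realized genomic relationship of recorded
full-sib pairs drops well below the 0.5 pedigree expectation.

## Bayesian LASSO

The hierarchy is the Park–Casella construction:
$a_j \mid \tau_j^2, \sigma_e^2 \sim N(0, \tau_j^2\sigma_e^2)$,
$\tau_j^2 \sim \mathrm{Exp}$, $\lambda^2 \sim \Gamma(r,\delta)$,
$\sigma_e^2 \sim \chi^{-2}(df_e, S_e)$, sampled by conjugate Gibbs updates
(coordinate-wise marker effects in compiled code, inverse-Gaussian
$1/\tau_j^2$). Defaults follow the usual weakly-informative guidance:
$df_e = 5$ with $S_e$ placing the prior mode of $\sigma_e^2$ at half the
phenotypic variance, and the $\lambda^2$ prior centered where markers are
expected to explain $R^2 = 0.5$ of the variance
($\lambda^2 = 2\frac{1-R^2}{R^2}\sum_j \overline{z_{ij}^2}$), shape 1.1.
Chain defaults are 20,000 iterations, 2,000 burn-in, thinning 100
(180 retained samples); all chains are single-threaded and seeded, so runs
are bit-reproducible.

The "ridge limit" of the Bayesian LASSO is a weak-shrinkage property: with
$\lambda^2$ fixed at the default and shrinkage matched through the
posterior-mean $\tau^2$ ($\lambda_{\mathrm{ridge}} = 1/\overline{\tau^2}$),
GEBVs agree with rrBLUP within 10% relative L2. Agreement *degrades* as the
fixed $\lambda^2$ grows, because strong double-exponential shrinkage is
precisely where the posterior departs most from a Gaussian-prior solution;
the package documents (and tests) the regime where the limit actually
holds.

## RKHS

Distances are the raw squared-Euclidean dosage distances
$d_{ij}=\sum_k (x_{ik}-x_{jk})^2$ — deliberately unstandardized, matching
the printed definition — with $\bar d$ the median off-diagonal distance and
the three-kernel rule $h = (2/(5\bar d),\; 2/\bar d,\; 10/\bar d)$,
$K_{ij} = \exp(-h\,d_{ij})$. Kernel-effect updates are performed in each
kernel's eigenbasis, where the conditional posterior is diagonal;
unphenotyped individuals are handled by data augmentation, so validation
sets receive GEBVs from the same run. Scaled-inverse-chi-square priors put
the genetic prior mode at half the phenotypic variance split equally
across kernels. A single-kernel model with a tiny bandwidth reproduces the
GBLUP ranking (Spearman > 0.95), the expected linear-kernel limit.

## Phenotype adjustment

`adjust_phenotypes()` fits
$\mathbf{Y} = \mathbf{X}\boldsymbol\beta + \mathbf{Z}\mathbf{u} +
\mathbf{W}\mathbf{b} + \mathbf{e}$ with fixed overall mean, site and age,
random block-within-site, and a random additive term with pedigree
covariance $\mathbf{A}$, by REML over the two variance ratios. Adjusted
phenotypes subtract the fixed effects and block BLUPs but retain the
additive component and residual. Heterogeneous per-site residual variance
is available through one round of iterated weighted fitting
(`site_specific_residual = TRUE`); the homogeneous default is used at desk
scale where per-site variances are weakly identified.

# The synthetic population generator

The generator emulates the data structure the analysis assumes, not any
particular dataset:

* **Species divergence** — per-SNP ancestral frequencies from a U-shaped
  spectrum ($0.02 + 0.96\,\mathrm{Beta}(0.3, 0.3)$, mean MAF ~0.15, the
  shape typical of post-QC SNP chips; a uniform spectrum would make even
  the modal-imputation baseline of 0.7 unattainable), with species
  frequencies drawn from a Balding–Nichols model at the configured
  $F_{st}$. The default $F_{st}=0.3$ reflects a species pair separated by
  millions of years; the Weir–Cockerham estimate on simulated founders
  recovers the target within ±0.05.
* **Linkage disequilibrium** — founder haplotypes are built by first-order
  Markov copying over 100 species-specific template haplotypes
  (persistence `ld_rho = 0.95` per adjacent SNP, chains restarting at
  chromosome boundaries). This is deliberately simpler than coalescent
  simulation: it runs at desk scale and produces monotone LD decay with a
  controllable rate, including optionally faster decay in genic regions
  (`ld_rho_genic`). It does *not* reproduce deep multi-generation
  recombination histories, so cross-species LD phase at short range is
  independent rather than partially correlated.
* **Mating** — an incomplete diallel samples distinct sire×dam pairs
  (species A × species B); gametes recombine with Poisson crossovers on
  the genetic map (Haldane, no interference — the standard choice absent
  any stated alternative); family sizes are uniform on 1–13 by default.
* **Traits** — per trait, `n_qtl` QTLs are sampled uniformly among the
  SNPs, effects are standard normal, and Gaussian noise is scaled so the
  realized additive/total variance ratio equals the target $h^2$ (defaults
  span the 0.05–0.5 regime of growth and wood traits). Site (+0.5 SD),
  age (0.15 SD per year) and block (0.3 SD) effects are added for the
  adjustment machinery. Architecture is purely additive; dominance,
  epistasis and genotype-by-environment interaction are out of scope.
* **Pedigree errors** — a Bernoulli subset of G1 records has the recorded
  sire replaced by another male of the same species (pollen-contamination
  model; full mislabelling is a toggle). The generator keeps the true and
  recorded pedigrees side by side so the error consequences are measurable.
* **Missingness** — i.i.d. masking with bookkeeping of the masked truth,
  so imputation can be scored.

Everything is deterministic given the config seed; `analysis/01` writes
the config as key:value text and every later step re-derives the identical
population from it.

## What passing tests do and do not show

The synthetic data reproduce the *structural* features the methods rely on
(family relatedness, species divergence, LD decay, heritability scaling,
pedigree-error dilution), so green tests certify the estimators and the
experiment machinery. They do not certify behavior on real data with
non-additive architecture, genotyping artifacts beyond i.i.d. missingness,
or deep LD histories. One documented consequence: with additive QTL on the
genotyped panel and phase fully preserved across a single meiosis, training
on pure-species parents predicts F1 hybrids *better* than a size-matched
random training set (over half the F1 genetic variance is parent-average
at these family sizes), whereas the empirical expectation for real
populations is the opposite; reproducing that failure requires mechanisms
this generator intentionally excludes (age-dependent genetic correlations
below one, non-additive hybrid effects, ungenotyped causal loci with
species-discordant phase).

# Cross-validation designs

Individuals are clustered by k-means on the top 20 principal components
(clustering 40k raw dimensions is noise-dominated; a raw-matrix mode
exists), with $k = \mathrm{round}(n/6.14)$ mirroring 182 clusters over
1117 individuals. The four compositions: CV1 random; CV2 all G0 parents in
training, validation purely G1; CV3 cluster-atomic assignment (the design
goal of *minimizing* training–validation relatedness is implemented by
sending whole clusters to one side or the other); CV4 proportional
within-cluster splits (*maximizing* relatedness: every validation
individual keeps same-cluster relatives in training). `parents_only` plus
the CV1 `sizes` override reproduce the pure-parents-to-hybrid side
experiment with its size-matched random control. Validation-set sizes use
`round(n/(ratio+1))` with cluster-atomicity resolved to the closest
achievable size; no attempt is made to match any specific printed size
pairs, which follow no single rounding rule.

Replicate seeds derive deterministically from the master seed; splits are
asserted disjoint every replicate; variance components are re-estimated per
replicate by default (a config flag could fix them, but re-estimation is
the safer default when training sets change composition).

# Numerical choices and degenerate inputs

* Exact conditional test for HWE (enumeration via log-factorials), robust
  at the rare-genotype counts where a $10^{-6}$ threshold operates; strict
  inequalities for all QC thresholds ("less than 70%"). Applied to the
  pooled sample, as a PLINK-style workflow implies, although Wahlund
  effects are expected under structure.
* LD pruning is greedy within 50-SNP windows stepped by 5 (conventional
  defaults; only the $r^2 < 0.2$ threshold is externally fixed), dropping
  the later SNP of the worst pair — deterministic, ties to the first pair.
* LD decay is least-squares over the Hill–Weir drift–recombination
  expectation with sample-size correction, one non-negative rate parameter
  fitted on a log grid by golden-section search; flat inputs collapse to
  the $C \to 0$ boundary.
* Monomorphic SNPs contribute zero to both numerator and denominator of
  $\mathbf{G}$; an all-monomorphic panel is an error, as are all-missing
  SNP columns in imputation, duplicate-only panels in `kernel_set()`
  ($\bar d = 0$), and pedigree cycles in `a_matrix()`.
* Problem sizes in the tests and the acceptance script: populations of
  ~330–1100 individuals, 2000–10,000 SNPs, 20 replicates per direction
  check — the scale at which every direction the package asserts is
  statistically stable while a full run stays in the minutes range.

# Known limitations

Additive-only traits; two generations (no grandparental links, so the
"unrelated" class is simply "no shared recorded parent"); single-trait
models; no phasing or haplotype imputation (the modal imputer is a
deliberate baseline); founder LD from template copying rather than
demographic history; heterogeneous residual variances only via one-step
reweighting. The PCA standardization choice (center-only vs standardized)
is exposed because the convention in comparable analyses is unstated.
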