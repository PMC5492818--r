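#' Genotype-based k-means clusters for relatedness-aware splits
#'
#' k-means on the leading principal components of the genotype matrix
#' (k-means on tens of thousands of raw SNP dimensions is noise-dominated;
#' a raw-matrix mode is available). The default `k = round(n / 6.14)`
#' reproduces the cluster granularity of 182 clusters over 1117
#' individuals.
#'
#' @param genotypes complete dosage matrix.
#' @param k number of clusters; `NULL` for the default rule.
#' @param seed RNG seed (k-means starts are seeded).
#' @param n_pc leading PCs to cluster on; `use_pcs = FALSE` clusters the
#'   raw matrix.
#' @return named integer vector of cluster labels.
#' @export
kmeans_clusters <- function(genotypes, k = NULL, seed = 1L, n_pc = 20,
                            use_pcs = TRUE) {
  n <- nrow(genotypes)
  if (is.null(k)) k <- max(2L, round(n / 6.14))
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k cannot exceed the number of individuals")
  if (k == n)  # exact solution: every individual its own cluster
    return(structure(seq_len(n), names = rownames(genotypes)))
  set.seed(seed)
  X <- if (use_pcs && n > 2) {
    pc <- pca_structure(genotypes, n_pc = min(n_pc, n - 1))
    pc$scores
  } else genotypes
  km <- kmeans(X, centers = k, nstart = 10, iter.max = 100)
  structure(km$cluster, names = rownames(genotypes))
}

parse_ratio <- function(ts_ratio) {
  if (is.character(ts_ratio)) {
    parts <- as.numeric(strsplit(ts_ratio, ":", fixed = TRUE)[[1]])
    ts_ratio <- parts[1] / parts[2]
  }
  stopifnot(is.numeric(ts_ratio), ts_ratio > 0)
  ts_ratio
}

#' Build one training/validation split
#'
#' Scenarios over a two-generation population (G0 parents, G1 progeny):
#' * `CV1` — random assignment at the target ratio;
#' * `CV2` — every G0 parent in the training set, topped up with random G1;
#'   validation is exclusively the remaining G1;
#' * `CV3` — clusters are atomic: each whole cluster goes to the training
#'   or validation side (greedy fill to the target size), minimizing
#'   relatedness between the sets;
#' * `CV4` — every cluster is split proportionally between the two sets, so
#'   each validation individual has same-cluster relatives in training
#'   (maximum relatedness);
#' * `parents_only` — training is all G0, validation an equal-sized random
#'   G1 draw (the pure-species-to-hybrid side experiment).
#'
#' Under cluster atomicity exact sizes can be infeasible; the closest
#' achievable sizes are used and reported.
#'
#' @param scenario one of `"CV1"`, `"CV2"`, `"CV3"`, `"CV4"`,
#'   `"parents_only"`.
#' @param ts_ratio training:validation ratio, numeric (`9`) or string
#'   (`"9:1"`).
#' @param pedigree pedigree with `id` and `generation` columns defining the
#'   population.
#' @param clusters named cluster labels (required for CV3/CV4).
#' @param seed RNG seed; `replicate` an index stored for provenance.
#' @param sizes optional `c(n_training, n_validation)` overriding the
#'   ratio for CV1 with a random *disjoint* (not exhaustive) draw — the
#'   size-matched control for the `parents_only` scenario.
#' @return object of class `cv_scheme`: `training`, `validation` id
#'   vectors plus the request metadata.
#' @export
make_split <- function(scenario = c("CV1", "CV2", "CV3", "CV4",
                                    "parents_only"),
                       ts_ratio = 4, pedigree, clusters = NULL, seed = 1L,
                       replicate = 1L, sizes = NULL) {
  scenario <- match.arg(scenario)
  ratio <- parse_ratio(ts_ratio)
  ids <- pedigree$id
  gen <- pedigree$generation
  n <- length(ids)
  if (!is.null(sizes)) {
    if (scenario != "CV1") stop("`sizes` is only supported for CV1")
    stopifnot(sum(sizes) <= n)
    set.seed(seed)
    pick <- sample(ids, sum(sizes))
    return(structure(list(scenario = "CV1", ts_ratio = sizes[1] / sizes[2],
                          training = pick[seq_len(sizes[1])],
                          validation = pick[sizes[1] + seq_len(sizes[2])],
                          replicate = as.integer(replicate),
                          seed = as.integer(seed),
                          n_training = sizes[1], n_validation = sizes[2]),
                     class = "cv_scheme"))
  }
  vs_target <- round(n / (ratio + 1))
  if (vs_target < 1 || vs_target >= n)
    stop("ratio leaves an empty training or validation set")
  set.seed(seed)
  g0 <- ids[gen == "G0"]; g1 <- ids[gen == "G1"]
  if (scenario %in% c("CV3", "CV4")) {
    if (is.null(clusters)) stop(scenario, " requires cluster labels")
    if (!all(ids %in% names(clusters)))
      stop("cluster labels missing for some individuals")
    cl <- clusters[ids]
  }
  vs <- switch(scenario,
    CV1 = sample(ids, vs_target),
    CV2 = {
      ts_target <- n - vs_target
      if (ts_target < length(g0))
        stop("training target smaller than the number of G0 parents")
      ts_fill <- sample(g1, ts_target - length(g0))
      setdiff(g1, ts_fill)
    },
    CV3 = {
      groups <- split(ids, cl)
      ord <- sample(length(groups))
      vs_ <- character(0)
      for (gi in ord) {
        if (length(vs_) >= vs_target) break
        cand <- c(vs_, groups[[gi]])
        # keep the closer of overshooting vs stopping short
        if (abs(length(cand) - vs_target) <= abs(length(vs_) - vs_target))
          vs_ <- cand
      }
      vs_
    },
    CV4 = {
      frac <- vs_target / n
      unlist(lapply(split(ids, cl), function(members) {
        m <- length(members)
        if (m < 2) return(character(0))  # singletons stay in training
        n_vs <- min(m - 1, round(frac * m))
        if (n_vs < 1) return(character(0))
        sample(members, n_vs)
      }), use.names = FALSE)
    },
    parents_only = sample(g1, min(length(g0), length(g1))))
  ts <- if (scenario == "parents_only") g0 else setdiff(ids, vs)
  structure(list(scenario = scenario, ts_ratio = ratio,
                 training = ts, validation = vs,
                 replicate = as.integer(replicate), seed = as.integer(seed),
                 n_training = length(ts), n_validation = length(vs)),
            class = "cv_scheme")
}

#' @export
print.cv_scheme <- function(x, ...) {
  cat(sprintf("%s split (ratio %.2f:1): %d training / %d validation\n",
              x$scenario, x$ts_ratio, x$n_training, x$n_validation))
  invisible(x)
}

#' Predictive ability
#'
#' Pearson correlation between the adjusted phenotypes and the GEBVs of the
#' validation set.
#'
#' @param y_vs adjusted phenotypes; `gebv_vs` matching GEBVs.
#' @export
predictive_ability <- function(y_vs, gebv_vs) {
  if (length(y_vs) != length(gebv_vs)) stop("length mismatch")
  if (length(y_vs) < 3) stop("need at least 3 validation individuals")
  if (var(y_vs) == 0 || var(gebv_vs) == 0)
    stop("predictive ability undefined: zero variance")
  cor(y_vs, gebv_vs)
}

#' SNP subsets by count or genomic region
#'
#' Random subsets without replacement at each requested count, and/or region
#' subsets from the SNP annotation: `cds` (CDS class only), `genic` (CDS
#' plus genic), `intergenic`, `all`.
#'
#' @param snp_info SNP table with a `region` column.
#' @param counts integer vector of subset sizes.
#' @param regions character vector of region subset names.
#' @param seed RNG seed.
#' @return named list of sorted SNP index vectors.
#' @export
snp_subsets <- function(snp_info, counts = NULL, regions = NULL, seed = 1L) {
  p <- nrow(snp_info)
  set.seed(seed)
  out <- list()
  for (ct in counts) {
    if (ct > p) stop(sprintf("requested %d SNPs but only %d available", ct, p))
    out[[paste0("n", ct)]] <- sort(sample.int(p, ct))
  }
  for (rg in regions) {
    idx <- switch(rg,
      cds = which(snp_info$region == "CDS"),
      genic = which(snp_info$region %in% c("CDS", "genic")),
      intergenic = which(snp_info$region == "intergenic"),
      all = seq_len(p),
      stop("unknown region subset: ", rg))
    out[[rg]] <- idx
  }
  out
}

fit_one <- function(method, y_ts, pop, split, G = NULL, A = NULL,
                    Zc = NULL, genotypes = NULL, chain = 3000,
                    burnin = 500, thin = 10, seed = 1L) {
  vs <- split$validation
  switch(method,
    gblup = fit_blup(y_ts, G, method = "gblup")$gebv[vs],
    ablup = fit_blup(y_ts, A, method = "ablup")$gebv[vs],
    rrblup = fit_rrblup(y_ts, Zc[names(y_ts), , drop = FALSE],
                        Z_new = Zc[vs, , drop = FALSE])$gebv[vs],
    bl = fit_bayesian_lasso(y_ts, Zc[names(y_ts), , drop = FALSE],
                            chain = chain, burnin = burnin, thin = thin,
                            seed = seed,
                            Z_new = Zc[vs, , drop = FALSE])$gebv[vs],
    rkhs = fit_rkhs(y_ts, genotypes, chain = chain, burnin = burnin,
                    thin = thin, seed = seed)$gebv[vs],
    stop("unknown method: ", method))
}

#' Predictive-ability grid over methods, scenarios, sizes and SNP sets
#'
#' For every cell (method x scenario x ratio x SNP set) and replicate:
#' build the split, fit the model on the training set (variance components
#' re-estimated per replicate), predict the validation set and record the
#' predictive ability. Replicate seeds derive deterministically from the
#' master seed; model failures are recorded per row, not fatal.
#'
#' @param population a `sim_population` (QC'd/imputed genotypes assumed).
#' @param y named vector of adjusted phenotypes over the population.
#' @param methods subset of `c("gblup","ablup","rrblup","bl","rkhs")`.
#' @param scenarios CV scenario names; `ratios` TS:VS ratios.
#' @param snp_sets optional named list of SNP index vectors (from
#'   [snp_subsets()]); default all SNPs.
#' @param n_replicates replicates per cell (the study design used 200;
#'   desk-scale analyses use 10-20).
#' @param seed master seed.
#' @param clusters optional precomputed cluster labels (computed once when
#'   any CV3/CV4 scenario is requested).
#' @param chain,burnin,thin chain settings passed to the samplers.
#' @return tibble of PA rows with full provenance columns.
#' @export
run_grid <- function(population, y, methods = "gblup", scenarios = "CV1",
                     ratios = 4, snp_sets = NULL, n_replicates = 10,
                     seed = 1L, clusters = NULL, chain = 3000,
                     burnin = 500, thin = 10) {
  ped <- population$recorded_pedigree
  geno <- population$genotypes
  if (is.null(snp_sets)) snp_sets <- list(all = seq_len(ncol(geno)))
  needs_cluster <- any(scenarios %in% c("CV3", "CV4"))
  if (needs_cluster && is.null(clusters))
    clusters <- kmeans_clusters(geno, seed = seed)
  A <- if ("ablup" %in% methods) a_matrix(ped) else NULL
  grid <- expand.grid(snp_set = names(snp_sets), ratio = ratios,
                      scenario = scenarios, method = methods,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  seed_tbl <- matrix(sample.int(.Machine$integer.max - 1,
                                nrow(grid) * n_replicates),
                     nrow = nrow(grid))
  rows <- list()
  for (ci in seq_len(nrow(grid))) {
    cell <- grid[ci, ]
    idx <- snp_sets[[cell$snp_set]]
    sub <- geno[, idx, drop = FALSE]
    pfreq <- colMeans(sub) / 2
    G <- if (any(c("gblup") %in% cell$method)) g_matrix(sub, p = pfreq)
    Zc <- if (cell$method %in% c("rrblup", "bl"))
      center_markers(sub, p = pfreq) else NULL
    for (rep_ in seq_len(n_replicates)) {
      rs <- seed_tbl[ci, rep_]
      row <- tibble::tibble(method = cell$method, scenario = cell$scenario,
                            ratio = cell$ratio, snp_set = cell$snp_set,
                            n_snps = length(idx), replicate = rep_,
                            seed = rs, n_training = NA_integer_,
                            n_validation = NA_integer_, pa = NA_real_,
                            error = NA_character_)
      res <- tryCatch({
        split <- make_split(cell$scenario, cell$ratio, ped,
                            clusters = clusters, seed = rs,
                            replicate = rep_)
        stopifnot(length(intersect(split$training, split$validation)) == 0)
        y_ts <- y[split$training]
        gebv_vs <- fit_one(cell$method, y_ts, population, split, G = G,
                           A = A, Zc = Zc, genotypes = sub, chain = chain,
                           burnin = burnin, thin = thin, seed = rs)
        list(pa = predictive_ability(y[split$validation],
                                     gebv_vs[split$validation]),
             split = split)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$error <- conditionMessage(res)
      } else {
        row$pa <- res$pa
        row$n_training <- res$split$n_training
        row$n_validation <- res$split$n_validation
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Summaries of a predictive-ability table
#'
#' Grouped means and standard deviations (SD reported as missing for
#' single-replicate groups; empty groups are dropped with a warning
#' upstream by the grid itself).
#'
#' @param pa_tbl output of [run_grid()].
#' @param by grouping columns.
#' @return tibble of group, n, mean_pa, sd_pa.
#' @export
summarize_pa <- function(pa_tbl, by = c("method", "scenario", "ratio",
                                        "snp_set")) {
  dt <- data.table::as.data.table(pa_tbl[!is.na(pa_tbl$pa), ])
  out <- dt[, list(n = .N, mean_pa = mean(pa),
                   sd_pa = if (.N > 1) sd(pa) else NA_real_),
            by = by]
  tibble::as_tibble(out)
}

#' Replicate-matched paired PA differences between two levels of a factor
#'
#' @param pa_tbl output of [run_grid()].
#' @param factor_col column to contrast; `level_a,level_b` its two levels.
#' @return tibble of per-replicate differences `pa_a - pa_b` (rows matched
#'   on every other provenance column).
#' @export
pa_paired_diff <- function(pa_tbl, factor_col, level_a, level_b) {
  keys <- setdiff(c("method", "scenario", "ratio", "snp_set", "replicate"),
                  factor_col)
  a <- pa_tbl[pa_tbl[[factor_col]] == level_a, ]
  b <- pa_tbl[pa_tbl[[factor_col]] == level_b, ]
  m <- merge(as.data.frame(a), as.data.frame(b), by = keys,
             suffixes = c("_a", "_b"))
  tibble::tibble(m[keys], diff = m$pa_a - m$pa_b)
}
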