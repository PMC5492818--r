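new_relmat <- function(values, kind, ids) {
  dimnames(values) <- list(ids, ids)
  attr(values, "kind") <- kind
  class(values) <- c("relmat", class(values))
  values
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("%s relationship matrix, %d individuals\n",
              attr(x, "kind"), nrow(x)))
  cat(sprintf("  diagonal mean %.3f, off-diagonal mean %.3f\n",
              mean(diag(x)), mean(x[upper.tri(x)])))
  invisible(x)
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Additive relationship matrix A from a pedigree by the tabular method:
#' individuals are sorted so parents precede offspring, founders (unknown
#' parents) are unrelated and non-inbred, and
#' `a_ij = (a_{j,sire} + a_{j,dam}) / 2`, `a_ii = 1 + a_{sire,dam} / 2`.
#'
#' @param pedigree data frame with columns `id`, `sire`, `dam`; `NA` (or an
#'   id absent from the table) marks an unknown parent.
#' @return a `relmat` of kind `"pedigree_A"`.
#' @export
a_matrix <- function(pedigree) {
  ped <- as.data.frame(pedigree)
  ids <- ped$id
  if (anyDuplicated(ids)) stop("duplicated ids in pedigree")
  n <- length(ids)
  sire <- match(ped$sire, ids)
  dam <- match(ped$dam, ids)
  # topological order (Kahn): parents before offspring
  order_ <- integer(0)
  placed <- rep(FALSE, n)
  remaining <- seq_len(n)
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(i) {
      (is.na(sire[i]) || placed[sire[i]]) &&
        (is.na(dam[i]) || placed[dam[i]])
    }, logical(1))]
    if (length(ready) == 0)
      stop("pedigree contains a cycle (an individual is its own ancestor)")
    placed[ready] <- TRUE
    order_ <- c(order_, ready)
    remaining <- setdiff(remaining, ready)
  }
  A <- matrix(0, n, n)
  for (i in order_) {
    s <- sire[i]; d <- dam[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    for (j in order_) {
      if (j == i) break
      aij <- 0
      if (!is.na(s)) aij <- aij + 0.5 * A[j, s]
      if (!is.na(d)) aij <- aij + 0.5 * A[j, d]
      A[i, j] <- A[j, i] <- aij
    }
  }
  new_relmat(A, "pedigree_A", ids)
}

#' VanRaden genomic relationship matrix
#'
#' `G = (M - P)(M - P)' / (2 * sum_j p_j (1 - p_j))` where `M` holds minor
#' allele counts 0/1/2 and the `j`-th column of `P` is `2 p_j`
#' (equivalently, a -1/0/1 coding centered by `2(p_j - 0.5)`; the two are
#' algebraically identical). Monomorphic SNPs contribute zero to both
#' numerator and denominator.
#'
#' @param genotypes complete 0/1/2 matrix, individuals x SNPs.
#' @param p optional allele frequencies; computed from the sample when
#'   omitted. Supplying frequencies from the full genotyped panel lets a
#'   single G serve training and validation subsets.
#' @return a `relmat` of kind `"genomic_G"`.
#' @export
g_matrix <- function(genotypes, p = NULL) {
  if (anyNA(genotypes)) stop("missing genotypes; impute before g_matrix")
  if (is.null(p)) p <- colMeans(genotypes) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic: zero denominator")
  W <- sweep(genotypes, 2, 2 * p)
  G <- tcrossprod(W) / denom
  new_relmat(G, "genomic_G", rownames(genotypes))
}

classify_pairs <- function(pedigree) {
  ped <- as.data.frame(pedigree)
  off <- ped[ped$generation != "G0", , drop = FALSE]
  n <- nrow(off)
  if (n < 2) stop("need at least two non-founder individuals")
  pairs <- utils::combn(n, 2)
  s1 <- off$sire[pairs[1, ]]; s2 <- off$sire[pairs[2, ]]
  d1 <- off$dam[pairs[1, ]]; d2 <- off$dam[pairs[2, ]]
  same_s <- !is.na(s1) & !is.na(s2) & s1 == s2
  same_d <- !is.na(d1) & !is.na(d2) & d1 == d2
  cls <- ifelse(same_s & same_d, "full_sib",
                ifelse(same_s | same_d, "half_sib", "unrelated"))
  tibble::tibble(id1 = off$id[pairs[1, ]], id2 = off$id[pairs[2, ]],
                 class = cls)
}

#' Relationship summaries by family type
#'
#' Classifies every pair of non-founder (G1) individuals from the recorded
#' pedigree as full-sib (same sire and dam), half-sib (exactly one shared
#' parent) or unrelated (no shared parent), and summarizes the relationship
#' matrix entries per class.
#'
#' @param relmat a `relmat` covering at least the pedigree's G1 ids.
#' @param pedigree pedigree data frame with `generation` labels.
#' @return tibble with class, pair count, min, mean, max.
#' @export
summarize_relationships <- function(relmat, pedigree) {
  pairs <- classify_pairs(pedigree)
  ids <- rownames(relmat)
  if (!all(pairs$id1 %in% ids) || !all(pairs$id2 %in% ids))
    stop("pedigree ids missing from the relationship matrix")
  vals <- relmat[cbind(match(pairs$id1, ids), match(pairs$id2, ids))]
  classes <- c("full_sib", "half_sib", "unrelated")
  out <- lapply(classes, function(cl) {
    v <- vals[pairs$class == cl]
    if (length(v) == 0)
      c(n_pairs = 0, min = NA_real_, mean = NA_real_, max = NA_real_)
    else c(n_pairs = length(v), min = min(v), mean = mean(v), max = max(v))
  })
  res <- tibble::as_tibble(do.call(rbind, out))
  res$class <- classes
  res[, c("class", "n_pairs", "min", "mean", "max")]
}

#' PCA of population structure
#'
#' Principal components of the (column-centered, optionally standardized)
#' genotype matrix. Variance-explained fractions are relative to the total
#' genotypic variance, so they sum to at most one.
#'
#' @param genotypes complete dosage matrix.
#' @param scale. standardize SNP columns (default `FALSE`).
#' @param n_pc number of components to return (default 10).
#' @return list: `scores` (individuals x PCs), `var_explained`, `sdev`.
#' @export
pca_structure <- function(genotypes, scale. = FALSE, n_pc = 10) {
  if (nrow(genotypes) < 2) stop("need at least 2 samples for PCA")
  v <- apply(genotypes, 2, var)
  keep <- v > 0
  pr <- prcomp(genotypes[, keep, drop = FALSE], center = TRUE,
               scale. = scale.)
  total <- if (scale.) sum(keep) else sum(v[keep])
  n_pc <- min(n_pc, ncol(pr$x))
  list(scores = pr$x[, seq_len(n_pc), drop = FALSE],
       var_explained = pr$sdev[seq_len(n_pc)]^2 / total,
       sdev = pr$sdev)
}
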