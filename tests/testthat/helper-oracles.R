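# Independent oracles used by the tests. These deliberately re-derive
# quantities through different routes than the package implementation.

# Weir-Cockerham theta (Fst) for two populations from dosage matrices.
wc_fst <- function(geno1, geno2) {
  n1 <- nrow(geno1); n2 <- nrow(geno2); r <- 2
  p1 <- colMeans(geno1) / 2; p2 <- colMeans(geno2) / 2
  h1 <- colMeans(geno1 == 1); h2 <- colMeans(geno2 == 1)
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  keep <- is.finite(a + b + cc) & (a + b + cc) != 0
  sum(a[keep]) / sum((a + b + cc)[keep])
}

# Gene-dropping estimate of the additive relationship matrix: founders get
# unique allele labels, alleles drop through the pedigree, relationship is
# twice the probability that random alleles from two individuals are IBD.
gene_drop_relationship <- function(pedigree, n_drops = 2e5, seed = 99) {
  set.seed(seed)
  ped <- as.data.frame(pedigree)
  n <- nrow(ped)
  sire <- match(ped$sire, ped$id)
  dam <- match(ped$dam, ped$id)
  al1 <- matrix(0L, n, n_drops)
  al2 <- matrix(0L, n, n_drops)
  lab <- 0L
  # assumes parents precede offspring in the table (true for the generator)
  for (i in seq_len(n)) {
    if (is.na(sire[i])) {
      al1[i, ] <- lab + 1L; lab <- lab + 1L
    } else {
      pick <- runif(n_drops) < 0.5
      al1[i, ] <- ifelse(pick, al1[sire[i], ], al2[sire[i], ])
    }
    if (is.na(dam[i])) {
      al2[i, ] <- lab + 1L; lab <- lab + 1L
    } else {
      pick <- runif(n_drops) < 0.5
      al2[i, ] <- ifelse(pick, al1[dam[i], ], al2[dam[i], ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    kin <- mean((al1[i, ] == al1[j, ]) + (al1[i, ] == al2[j, ]) +
                  (al2[i, ] == al1[j, ]) + (al2[i, ] == al2[j, ])) / 4
    A[i, j] <- A[j, i] <- 2 * kin
  }
  # a_ii = 1 + F, with F = P(the two alleles of i are IBD)
  for (i in seq_len(n))
    A[i, i] <- 1 + mean(al1[i, ] == al2[i, ])
  A
}

# Exact HWE p-value by full enumeration with the Wigginton recurrence
# P(het + 2) / P(het) = 4 aa bb / ((het + 2)(het + 1)).
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  n_minor <- min(nA, 2 * n - nA)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  pr <- numeric(length(hets))
  pr[1] <- 1
  for (k in seq_along(hets)[-1]) {
    h_prev <- hets[k - 1]
    aa_prev <- (nA - h_prev) / 2
    bb_prev <- (2 * n - nA - h_prev) / 2
    pr[k] <- pr[k - 1] * 4 * aa_prev * bb_prev /
      ((h_prev + 2) * (h_prev + 1))
  }
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Dense solve of the single-trait mixed-model equations
# [X'X, X'Z; Z'X, Z'Z + Kinv * lambda] [b; a] = [X'y; Z'y]
mme_dense_solve <- function(y, K, lambda) {
  n <- length(y)
  X <- matrix(1, n, 1)
  Kinv <- solve(K)
  C <- rbind(cbind(crossprod(X), t(X)),
             cbind(X, diag(n) + Kinv * lambda))
  sol <- solve(C, c(crossprod(X, y), y))
  list(beta = sol[1], a = sol[-1])
}
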