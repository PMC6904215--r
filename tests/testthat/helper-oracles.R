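# Independent oracles used across the suite. These deliberately use
# naive/brute-force formulations distinct from the package's
# implementations.

# Recursive kinship coefficient (Karigl): phi(i, i) = 0.5 (no
# inbreeding), phi(i, j) = 0.5 * (phi(f_i, j) + phi(m_i, j)) recursing
# on the later-generation individual. MZ twins are first collapsed onto
# one genome. Returns 2 * phi (additive relationship).
oracle_kinship <- function(pedigree) {
  ped <- pedigree
  genome <- ped$id
  if (!is.null(ped$twin_group)) {
    for (tg in unique(stats::na.omit(ped$twin_group))) {
      mem <- ped$id[!is.na(ped$twin_group) & ped$twin_group == tg]
      genome[ped$id %in% mem] <- mem[1]
    }
  }
  uids <- unique(genome)
  fa <- ped$father[match(uids, ped$id)]
  mo <- ped$mother[match(uids, ped$id)]
  gen <- stats::setNames(rep(0L, length(uids)), uids)
  repeat {
    g2 <- gen
    for (i in seq_along(uids)) {
      pg <- c(if (!is.na(fa[i])) gen[fa[i]], if (!is.na(mo[i])) gen[mo[i]])
      if (length(pg)) g2[i] <- max(pg) + 1L
    }
    if (identical(g2, gen)) break
    gen <- g2
  }
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    if (a == b) return(0.5)
    if (gen[a] < gen[b]) { tmp <- a; a <- b; b <- tmp }
    if (gen[a] == 0) return(0)  # two distinct founders
    i <- match(a, uids)
    0.5 * (phi(fa[i], b) + phi(mo[i], b))
  }
  n <- length(ped$id)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i))
    K[i, j] <- K[j, i] <- 2 * phi(genome[i], genome[j])
  diag(K) <- 1
  K
}

# Dense-Sigma GLS with re-profiled residual scale: the brute-force
# counterpart of the package's rotated weighted least squares.
oracle_gls <- function(y, g, K, lambda, covariates = NULL) {
  n <- length(y)
  Sigma <- lambda * K + diag(n)
  Si <- solve(Sigma)
  X <- cbind(1, covariates, g)
  A <- t(X) %*% Si %*% X
  beta <- solve(A, t(X) %*% Si %*% y)
  r <- y - X %*% beta
  s2 <- drop(t(r) %*% Si %*% r) / (n - ncol(X))
  se <- sqrt(s2 * diag(solve(A)))
  p <- ncol(X)
  z <- beta[p] / se[p]
  c(beta = unname(beta[p]), se = unname(se[p]),
    p = unname(2 * stats::pnorm(-abs(z))))
}

# Sorted-BH with fixed denominator: p_(i) * n / i, cumulative minimum
# from the largest, capped at 1, mapped back to input order.
oracle_bh <- function(p, n_total) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * n_total / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Full multinomial log-likelihood-difference HWE statistic:
# 2 * [ sum O log(O/n) - sum O log(E/n) ] with E from the MLE allele
# frequency under HWE.
oracle_hwe_stat <- function(counts) {
  n <- sum(counts)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  probs <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  ll_sat <- sum(ifelse(counts > 0, counts * log(counts / n), 0))
  ll_hwe <- sum(ifelse(counts > 0, counts * log(probs), 0))
  2 * (ll_sat - ll_hwe)
}

# Brute-force Mann-Whitney U for group a (pairwise comparison count).
oracle_rank_sum_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# O(m^2) configuration-enumeration colocalization oracle.
oracle_coloc <- function(l1, l2, p1, p2, p12) {
  m <- length(l1)
  w0 <- 1
  w1 <- sum(p1 * exp(l1))
  w2 <- sum(p2 * exp(l2))
  w3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m))
    if (i != j) w3 <- w3 + p1 * p2 * exp(l1[i] + l2[j])
  w4 <- sum(p12 * exp(l1 + l2))
  w <- c(H0 = w0, H1 = w1, H2 = w2, H3 = w3, H4 = w4)
  w / sum(w)
}

# Shared fixture: one moderate cohort reused by several test files.
cohort_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ped <- simulate_pedigree(n_families = 15, family_size_range = c(2, 6),
                               n_twin_pairs = 5, n_unrelated = 60,
                               seed = 42)
      sim <- simulate_hla_haplotypes(ped$pedigree, n_genes = 8,
                                     alleles_per_gene = 10,
                                     n_linked_snps = 60, seed = 43)
      cov <- simulate_coverage(sim$diplotypes, genome_mean_cov = 50,
                               noise_cv = 0, seed = 44)
      calls <- call_hla_table(cov)
      cache <<- list(ped = ped, sim = sim, coverage = cov, calls = calls)
    }
    cache
  }
})
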