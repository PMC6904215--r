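test_that("the five calling rules reproduce the worked profiles", {
  gm <- 50  # threshold t = 10
  # rule 1: nothing passes
  expect_equal(call_hla_genotype(c(a = 4, b = 3), gm),
               c(NA_character_, NA_character_))
  # rule 2: single allele at >= 2t is homozygous (non-strict boundary)
  expect_equal(call_hla_genotype(c(a = 30), gm), c("a", "a"))
  expect_equal(call_hla_genotype(c(a = 20), gm), c("a", "a"))
  # rule 3: single allele below 2t leaves the partner Undetermined
  expect_equal(call_hla_genotype(c(a = 15), gm), c("a", NA))
  # rule 4: top > 2 x second is homozygous (strict boundary)
  expect_equal(call_hla_genotype(c(a = 40, b = 15), gm), c("a", "a"))
  expect_equal(call_hla_genotype(c(a = 30, b = 15), gm), c("a", "b"))
  # rule 5: heterozygous top two
  expect_equal(call_hla_genotype(c(a = 25, b = 15), gm), c("a", "b"))
  expect_equal(call_hla_genotype(c(b = 25, a = 15, c = 11), gm),
               c("a", "b"))
  expect_error(call_hla_genotype(c(a = 10), 0), "genome_mean_coverage")
})

test_that("calls are scale-invariant and independent of allele order", {
  set.seed(10)
  for (i in 1:50) {
    k <- sample(1:6, 1)
    d <- stats::setNames(stats::runif(k, 0, 60),
                         sample(letters, k))
    gm <- stats::runif(1, 20, 80)
    base <- call_hla_genotype(d, gm)
    for (c_ in c(0.01, 3, 117)) {
      expect_identical(call_hla_genotype(c_ * d, c_ * gm), base)
    }
    perm <- sample(k)
    expect_identical(call_hla_genotype(d[perm], gm), base)
  }
  # exact depth ties break lexicographically by allele code
  expect_equal(call_hla_genotype(c(z = 25, b = 25, q = 25), 50),
               c("b", "q"))
  expect_equal(call_hla_genotype(c(z = 25, a = 49.9), 50), c("a", "z"))
})

test_that("resolution truncation keeps leading fields and errors when short", {
  expect_equal(truncate_resolution("A*01:02:03:04", 4), "A*01:02")
  expect_equal(truncate_resolution("A*01:02:03:04", 2), "A*01")
  expect_equal(truncate_resolution("A*01:02:03:04", 8), "A*01:02:03:04")
  expect_equal(truncate_resolution("A*01:01", 4), "A*01:01")
  expect_error(truncate_resolution("A*01:01", 8), "resolution")
  expect_equal(truncate_resolution(c("B*05:01", NA), 2), c("B*05", NA))
})

test_that("recall counts fully determined genotypes only", {
  calls <- data.frame(sample = sprintf("s%02d", 1:10), gene = "G",
                      allele1 = "a", allele2 = "b",
                      stringsAsFactors = FALSE)
  expect_equal(unname(recall_rate(calls)), 1)
  calls$allele2[3] <- NA
  expect_equal(unname(recall_rate(calls)), 0.9)
  expect_error(recall_rate(calls, gene = "missing"), "unknown gene")
})

test_that("pair concordance matches the worked fractions and exclusion rule", {
  mk <- function(n, g = "G") data.frame(
    sample = c(sprintf("a%02d", 1:n), sprintf("b%02d", 1:n)),
    gene = g, allele1 = "x", allele2 = "y", stringsAsFactors = FALSE)
  calls <- mk(10)
  pairs <- data.frame(a = sprintf("a%02d", 1:10), b = sprintf("b%02d", 1:10))
  expect_equal(unname(pair_concordance(calls, pairs)), 1)
  # one mismatching pair among ten
  calls$allele2[calls$sample == "b01"] <- "z"
  expect_equal(unname(pair_concordance(calls, pairs)), 0.9)
  # an Undetermined slot removes the pair from the denominator
  calls$allele2[calls$sample == "b02"] <- NA
  expect_equal(unname(pair_concordance(calls, pairs)), 8 / 9)
  # all pairs uninformative -> NA
  calls$allele1 <- NA
  expect_true(is.na(pair_concordance(calls, pairs)))
})

test_that("Mendelian concordance enumerates allele assignments", {
  mk_calls <- function(f, m, c) data.frame(
    sample = c("F", "M", "C"), gene = "G",
    allele1 = c(f[1], m[1], c[1]), allele2 = c(f[2], m[2], c[2]),
    stringsAsFactors = FALSE)
  trio <- data.frame(father = "F", mother = "M", child = "C")
  expect_equal(unname(mendelian_concordance(
    mk_calls(c("a", "b"), c("c", "d"), c("a", "c")), trio)), 1)
  expect_equal(unname(mendelian_concordance(
    mk_calls(c("a", "b"), c("c", "d"), c("a", "a")), trio)), 0)
  # needs the swapped assignment to be tried
  expect_equal(unname(mendelian_concordance(
    mk_calls(c("a", "b"), c("a", "c"), c("a", "a")), trio)), 1)
  # Undetermined slot excludes the trio
  expect_true(is.na(mendelian_concordance(
    mk_calls(c("a", NA), c("c", "d"), c("a", "c")), trio)))
})

test_that("HWE LRT matches hand and oracle computations", {
  h <- hwe_lrt(c(25, 50, 25))
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)
  expect_false(h$flagged)
  h2 <- hwe_lrt(c(50, 0, 50))
  expect_equal(h2$statistic, 200 * log(2), tolerance = 1e-12)
  expect_lt(h2$p_value, 1e-6)
  expect_true(h2$flagged)
  expect_error(hwe_lrt(c(-1, 5, 5)))
  # equals the full multinomial log-likelihood difference on random triples
  set.seed(31)
  for (i in 1:100) {
    cnt <- stats::rmultinom(1, size = sample(20:300, 1),
                            prob = stats::runif(3, 0.05, 1))[, 1]
    if (2 * cnt[1] + cnt[2] == 0 || 2 * cnt[3] + cnt[2] == 0) next
    expect_equal(hwe_lrt(cnt)$statistic, oracle_hwe_stat(cnt),
                 tolerance = 1e-10)
  }
})

test_that("injected genotype errors lower twin concordance proportionally", {
  set.seed(55)
  n_pairs <- 120
  eps <- 0.1
  calls <- data.frame(
    sample = c(sprintf("a%03d", 1:n_pairs), sprintf("b%03d", 1:n_pairs)),
    gene = "G", allele1 = "x", allele2 = "y", stringsAsFactors = FALSE)
  flip <- stats::runif(n_pairs) < eps
  calls$allele2[n_pairs + which(flip)] <- "zz"
  pairs <- data.frame(a = sprintf("a%03d", 1:n_pairs),
                      b = sprintf("b%03d", 1:n_pairs))
  conc <- unname(pair_concordance(calls, pairs))
  tol <- 3 * sqrt(eps * (1 - eps) / n_pairs)
  expect_lt(abs((1 - conc) - eps), tol)
})

test_that("carrier frequencies and the reference correlation are exact", {
  calls <- data.frame(
    sample = sprintf("s%03d", 1:100), gene = "G",
    allele1 = c(rep("a", 50), rep("b", 50)),
    allele2 = c(rep("a", 20), rep("c", 80)),
    stringsAsFactors = FALSE)
  ref <- c(a = 0.5, b = 0.5, c = 0.8)
  cmp <- compare_frequencies(calls, ref)
  f <- cmp$frequencies
  expect_equal(f$cohort_freq[f$allele == "a"], 0.5)
  expect_equal(f$cohort_freq[f$allele == "b"], 0.5)
  expect_equal(f$cohort_freq[f$allele == "c"], 0.8)
  expect_equal(cmp$r, 1)
  # r equals the covariance-formula Pearson on a constructed 5-allele table
  calls5 <- data.frame(
    sample = rep(sprintf("s%02d", 1:20), each = 1), gene = "G",
    allele1 = rep(c("a", "b", "c", "d", "e"), 4),
    allele2 = rep(c("a", "b", "c", "d", "e"), c(8, 2, 4, 4, 2)),
    stringsAsFactors = FALSE)
  ref5 <- c(a = 0.41, b = 0.13, c = 0.22, d = 0.2, e = 0.11)
  cmp5 <- compare_frequencies(calls5, ref5)
  x <- cmp5$frequencies$reference_freq
  y <- cmp5$frequencies$cohort_freq
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cmp5$r, r_oracle, tolerance = 1e-12)
  expect_error(compare_frequencies(calls, c(zzz = 0.1)), "shared")
})

test_that("HWE screen under equilibrium rarely flags at the 1e-6 threshold", {
  set.seed(91)
  n <- 275
  flags <- replicate(400, {
    p <- stats::runif(1, 0.1, 0.9)
    g <- stats::rbinom(n, 2, p)
    hwe_lrt(c(sum(g == 2), sum(g == 1), sum(g == 0)))$flagged
  })
  expect_equal(mean(flags), 0, tolerance = 0.005)
})
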