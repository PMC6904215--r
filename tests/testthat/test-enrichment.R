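test_that("decile assignment partitions pairs into near-equal bins", {
  tab <- data.frame(feature = "g", predictor = sprintf("v%03d", 1:100),
                    beta = stats::rnorm(100), stringsAsFactors = FALSE)
  d <- effect_size_deciles(tab)
  expect_equal(unname(table(d$decile)), rep(10L, 10), ignore_attr = TRUE)
  expect_equal(d$decile[which.max(abs(d$beta))], 10L)
  expect_equal(d$decile[which.min(abs(d$beta))], 1L)
  # every pair in exactly one bin, sizes differ by <= 1 for any n
  t2 <- tab[1:37, ]
  d2 <- effect_size_deciles(t2)
  expect_equal(sum(table(d2$decile)), 37)
  expect_lte(diff(range(table(d2$decile))), 1)
  expect_error(effect_size_deciles(tab[1:9, ]), ">= 10")
})

test_that("tied effect sizes are assigned by a stable brute-force order", {
  set.seed(3)
  tab <- data.frame(feature = "g", predictor = sprintf("v%02d", 30:1),
                    beta = sample(c(0.1, 0.2, 0.3), 30, replace = TRUE),
                    stringsAsFactors = FALSE)
  d <- effect_size_deciles(tab)
  ord <- order(abs(tab$beta), tab$predictor, tab$feature, method = "radix")
  want <- integer(30)
  want[ord] <- ceiling(seq_len(30) * 10 / 30)
  expect_equal(d$decile, want)
})

test_that("enrichment matrix normalization identities hold", {
  # uniform counts in a state -> all-zero column
  dec <- data.frame(feature = "g",
                    predictor = sprintf("v%03d", 1:200),
                    beta = 1, decile = rep(1:10, each = 20),
                    stringsAsFactors = FALSE)
  states <- stats::setNames(rep(c("1_TssA", "15_Quies"), 100),
                            dec$predictor)
  M <- enrichment_matrix(dec, states, pseudo = 0)
  expect_equal(unname(M[, "1_TssA"]), rep(0, 10))
  # one bin at 2x the column average is exactly 1.0
  st2 <- stats::setNames(rep("7_Enh", 200), dec$predictor)
  dec2 <- dec
  dec2$decile <- rep(c(1, 1, 2:9), 20)  # bin 1 holds 2x the average
  M2 <- enrichment_matrix(dec2, st2, pseudo = 0)
  # bin 1 count 40, bins 2-9 count 20, bin 10 count 0 -> mean 20
  expect_equal(M2["1", "7_Enh"], 1)
  # column mean of 2^value is 1 by construction (pseudo = 0 path)
  set.seed(19)
  dec3 <- dec
  dec3$decile <- sample(1:10, 200, replace = TRUE)
  st3 <- stats::setNames(sample(roadmap_states()[1:5], 200, TRUE),
                         dec$predictor)
  M3 <- enrichment_matrix(dec3, st3, pseudo = 1)
  expect_equal(unname(colMeans(2^M3)), rep(1, ncol(M3)), tolerance = 1e-12)
  # invariance to scaling all counts in a column by a constant:
  # duplicating every pair of a state leaves its column unchanged
  dup <- rbind(dec3, transform(dec3, predictor = paste0(dec3$predictor, "b")))
  stdup <- stats::setNames(rep(st3, 2), dup$predictor)
  M4 <- enrichment_matrix(dup, stdup, pseudo = 0)
  M5 <- enrichment_matrix(dec3, st3, pseudo = 0)
  expect_equal(M4, M5, tolerance = 1e-12)
})

test_that("variant annotation respects half-open BED intervals", {
  bed <- data.frame(chrom = "6", start = c(100, 200), end = c(200, 300),
                    state = c("1_TssA", "4_Tx"), stringsAsFactors = FALSE)
  v <- data.frame(chrom = "6", pos = c(100, 101, 200, 201, 300, 301, 50),
                  id = sprintf("x%d", 1:7), stringsAsFactors = FALSE)
  st <- annotate_variants(v, bed)
  # pos is 1-based: pos 101 -> 0-based 100 -> first interval
  expect_equal(unname(st[c("x2", "x3")]), c("1_TssA", "1_TssA"))
  expect_equal(unname(st["x4"]), "4_Tx")
  expect_equal(unname(st["x5"]), "4_Tx")  # 0-based 299 < 300
  expect_equal(unname(st[c("x6", "x7")]), rep("unannotated", 2))
  expect_equal(unname(st["x1"]), "unannotated")  # 0-based 99 < start
})

test_that("large-effect QTLs planted in TSS intervals enrich bin 10 only", {
  set.seed(29)
  bed <- simulate_chromatin_states(mean_width = 5000, seed = 5)
  v <- data.frame(chrom = "6",
                  pos = sample(seq(29650000, 33100000), 400),
                  id = sprintf("v%03d", 1:400), stringsAsFactors = FALSE)
  st <- annotate_variants(v, bed)
  beta <- abs(stats::rnorm(400, 0, 0.2))
  # give TSS variants systematically larger effects
  tss <- st[v$id] == "1_TssA"
  beta[tss] <- beta[tss] + 2
  tab <- data.frame(feature = "g", predictor = v$id, beta = beta,
                    stringsAsFactors = FALSE)
  M <- enrichment_matrix(effect_size_deciles(tab), st)
  expect_gt(M["10", "1_TssA"], 0)
  expect_lte(M["1", "1_TssA"], 0)
})

test_that("AIF group comparison is exact for small groups and tie-robust", {
  r <- aif_comparison(c(0.9, 0.9, 0.9), c(0.5, 0.5, 0.5))
  expect_equal(r$U, 9)
  expect_equal(r$p_value, 0.1)  # 2 of the 20 C(6,3) splits are as extreme
  expect_equal(r$method, "exact")
  ident <- aif_comparison(c(0.6, 0.7, 0.8), c(0.6, 0.7, 0.8))
  expect_gt(ident$p_value, 0.99)
  expect_warning(sk <- aif_comparison(0.5, c(0.6, 0.7)), "skipped")
  expect_true(is.na(sk$p_value))
  # U agrees with the pairwise-count oracle (incl. ties)
  set.seed(37)
  for (i in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    a <- round(stats::runif(n1, 0.5, 1), 2)
    b <- round(stats::runif(n2, 0.5, 1), 2)
    expect_equal(aif_comparison(a, b)$U, oracle_rank_sum_u(a, b))
  }
  # continuity-corrected normal approximation tracks exact enumeration
  # within 0.02 at the combined n = 12 switch point (tie-free data)
  for (i in 1:30) {
    a <- stats::runif(6, 0.5, 1); b <- stats::runif(6, 0.5, 1)
    ex <- aif_comparison(a, b)
    no <- aif_comparison(a, b, exact_max = 0)
    expect_lt(abs(no$p_value - ex$p_value), 0.02)
  }
})

test_that("heterozygous-eQTL AIF shifts are detected at realistic sizes", {
  hits <- vapply(1:20, function(s) {
    set.seed(600 + s)
    het <- 0.5 + 0.5 * stats::rbeta(100, 2.8, 5)   # mean ~0.68
    hom <- 0.5 + 0.5 * stats::rbeta(100, 1.9, 6)   # mean ~0.62
    aif_comparison(het, hom)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("coexpression beta equals the normal-equations oracle", {
  set.seed(43)
  n <- 60
  X <- cbind(stats::rnorm(n), stats::rbinom(n, 1, 0.5))
  ej <- stats::rnorm(n)
  ei <- 0.8 * ej + X %*% c(0.3, -0.2) + stats::rnorm(n, 0, 0.5)
  b <- coexpression_beta(ei, ej, X)
  D <- cbind(1, ej, X)
  oracle <- solve(t(D) %*% D, t(D) %*% ei)[2]
  expect_equal(b, oracle, tolerance = 1e-10)
  # identity and null behavior
  expect_equal(coexpression_beta(ej, ej), 1, tolerance = 1e-12)
  ind <- replicate(50, {
    x <- stats::rnorm(40); y <- stats::rnorm(40)
    coexpression_beta(x, y)
  })
  expect_lt(abs(mean(ind)), 3 / sqrt(50 * 40))
  # collinearity gives NA
  expect_true(is.na(coexpression_beta(ei, ej, cbind(ej))))
  # matrix version has unit diagonal
  Y <- rbind(a = ei[1:20], b = ej[1:20])
  B <- coexpression_matrix(Y)
  expect_equal(unname(diag(B)), c(1, 1))
})
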