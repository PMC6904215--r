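test_that("local Bonferroni and genome-wide BH follow the worked arithmetic", {
  # nominal p = 1 stays capped at 1
  a1 <- data.frame(feature = "g1", predictor = "v1", beta = 0.1, se = 1,
                   p = 1, stringsAsFactors = FALSE)
  h1 <- hierarchical_correction(a1)
  expect_equal(h1$results$p_local, 1)
  # single gene, lead p = 1e-11, m = 45245 -> local 4.5245e-7;
  # BH rank 1 of n = 20595 -> 9.318e-3 < 0.05 -> eGene
  a2 <- data.frame(feature = "g1", predictor = c("v1", "v2"),
                   beta = c(1, 0), se = 1, p = c(1e-11, 0.5),
                   stringsAsFactors = FALSE)
  h2 <- hierarchical_correction(a2, m_local = 45245)
  expect_equal(h2$leads$p_local, 1e-11 * 45245, tolerance = 1e-12)
  expect_equal(h2$leads$p_bh, 1e-11 * 45245 * 20595, tolerance = 1e-9)
  expect_equal(h2$egenes, "g1")
  expect_equal(h2$leads$predictor, "v1")
})

test_that("eGene calls and QTL sets match an independent BH reimplementation", {
  set.seed(17)
  for (rep in 1:5) {
    tab <- expand.grid(feature = sprintf("g%d", 1:5),
                       predictor = sprintf("v%02d", 1:20),
                       stringsAsFactors = FALSE)
    tab$beta <- stats::rnorm(100)
    tab$se <- 1
    tab$p <- 10^stats::runif(100, -9, 0)
    h <- hierarchical_correction(tab, n_genomewide = 20595,
                                 bh_alpha = 0.05, local_alpha = 0.1)
    # oracle: per-feature Bonferroni, sorted BH on leads, local-0.1 QTLs
    sp <- split(seq_len(100), tab$feature)
    lead_p <- vapply(sp, function(ix) min(pmin(1, tab$p[ix] * 20)),
                     numeric(1))
    adj <- oracle_bh(lead_p, 20595)
    egenes <- names(lead_p)[adj < 0.05]
    expect_setequal(h$egenes, egenes)
    for (f in egenes) {
      ix <- sp[[f]]
      want <- tab$predictor[ix][pmin(1, tab$p[ix] * 20) < 0.1]
      expect_setequal(h$qtls$predictor[h$qtls$feature == f], want)
    }
  }
  # reference sorted-BH semantics on random p-vectors
  for (rep in 1:200) {
    p <- stats::runif(sample(3:40, 1))
    n_tot <- length(p) + sample(0:500, 1)
    expect_equal(stats::p.adjust(p, "BH", n = n_tot),
                 oracle_bh(p, n_tot), tolerance = 1e-12)
  }
})

test_that("lead ties break by genomic position then identifier", {
  tab <- data.frame(feature = "g", predictor = c("vB", "vA", "vC"),
                    beta = 1, se = 1, p = c(1e-5, 1e-5, 1e-5),
                    stringsAsFactors = FALSE)
  pos <- c(vB = 500, vA = 100, vC = 100)
  h <- hierarchical_correction(tab, positions = pos)
  expect_equal(h$leads$predictor, "vA")  # smallest pos, then id
  h2 <- hierarchical_correction(tab)
  expect_equal(h2$leads$predictor, "vA")  # lexicographic fallback
})

test_that("variant filtering applies the three cohort filters", {
  # toy VCF with known call-rate / MAF / HWE properties
  n <- 60
  samples <- sprintf("s%02d", seq_len(n))
  geno <- rbind(
    pass1 = stats::rbinom(n, 2, 0.3),
    lowcall = c(rep(NA, 4), stats::rbinom(n - 4, 2, 0.3)),   # 93% call
    boundary_call = c(rep(NA, 3), stats::rbinom(n - 3, 2, 0.3)),  # 95%
    rare = c(1, rep(0, n - 1)),                              # MAF 0.008
    common_boundary = c(rep(1, 2), rep(0, n - 2)),           # MAF ~0.017
    hwe_bad = rep(c(2, 0), n / 2),                           # no hets
    mono = rep(0, n))
  set.seed(23)
  geno["pass1", ] <- stats::rbinom(n, 2, 0.4)
  variants <- data.frame(chrom = "6", pos = 1:7 * 100,
                         id = rownames(geno), ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  colnames(geno) <- samples
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(geno, variants, path)
  fv <- filter_variants(path, unrelated = samples)
  expect_true("pass1" %in% rownames(fv$dosage))
  expect_true("boundary_call" %in% rownames(fv$dosage))  # >= 95% kept
  expect_true("common_boundary" %in% rownames(fv$dosage))
  expect_false("lowcall" %in% rownames(fv$dosage))
  expect_false("rare" %in% rownames(fv$dosage))
  expect_false("hwe_bad" %in% rownames(fv$dosage))
  expect_false("mono" %in% rownames(fv$dosage))
  # dosages survive the round trip
  expect_equal(fv$dosage["pass1", ], geno["pass1", ],
               ignore_attr = TRUE)
  # surviving count equals hand enumeration
  expect_equal(nrow(fv$dosage), 3)
})

test_that("multi-allelic records decompose into biallelic rows", {
  n <- 20
  samples <- sprintf("s%02d", 1:n)
  gt <- c(rep("0/1", 5), rep("0/2", 5), rep("1/2", 2), rep("0/0", 8))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", samples),
                   collapse = "\t"),
             paste(c("6", "100", "multi", "A", "G,T", ".", "PASS", ".",
                     "GT", gt), collapse = "\t"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, path)
  fv <- filter_variants(path, min_call_rate = 0, min_maf = 0,
                        hwe_alpha = 0)
  expect_equal(fv$stats$id, c("multi_G", "multi_T"))
  d <- fv$dosage
  expect_equal(sum(d["multi_G", ]), 5 + 2)   # alt-1 copies
  expect_equal(sum(d["multi_T", ]), 5 + 2)   # alt-2 copies
})

test_that("HLA dosage coding follows the 0 / 0.5 / 1 convention", {
  expect_equal(encode_hla_dosage(c("a", "b"), "a"), 0.5)
  expect_equal(encode_hla_dosage(c("a", "a"), "a"), 1)
  expect_equal(encode_hla_dosage(c("b", "c"), "a"), 0)
  expect_true(is.na(encode_hla_dosage(c("b", NA), "a")))
  expect_equal(encode_hla_dosage(c("a", NA), "a"), 0.5)
  # matrix construction agrees with the scalar encoder
  calls <- data.frame(sample = c("s1", "s2", "s3", "s4"), gene = "G",
                      allele1 = c("a", "a", "b", "b"),
                      allele2 = c("a", "b", "c", NA),
                      stringsAsFactors = FALSE)
  D <- hla_dosage_matrix(calls, min_freq = 0)
  expect_equal(unname(D["a", ]), c(1, 0.5, 0, NA))
  expect_equal(unname(D["b", ]), c(0, 0.5, 0.5, 0.5))
  expect_equal(attr(D, "gene")[["a"]], "G")
})

test_that("HLA-type scan separates self-associations and counts all tests", {
  fx <- cohort_fixture()
  K <- fx$ped$kinship
  calls <- fx$calls
  D <- hla_dosage_matrix(calls, samples = rownames(K), min_freq = 0.01)
  genes <- unique(calls$gene)
  feats <- c(genes[1:3], "nonhla1", "nonhla2")
  # plant the effect on a common type so the scan is well powered
  cand <- rownames(D)[attr(D, "gene")[rownames(D)] == genes[1]]
  focal <- cand[which.max(attr(D, "freq")[cand])]
  ex <- simulate_expression(feats, fx$sim$diplotypes, fx$sim$snp_geno, K,
                            effects = data.frame(feature = "nonhla1",
                                                 predictor = focal,
                                                 beta = 1.5),
                            sigma_g = 0.2, sigma_e = 0.5, seed = 31)
  sc <- scan_hla_types(ex$expression, D, K,
                       hwe_flags = rownames(D)[2])
  expect_equal(sc$n_tests, nrow(ex$expression) * nrow(D))
  # self rows are exactly the cognate-gene combinations
  tg <- attr(D, "gene")
  expect_true(all(sc$self$feature == tg[sc$self$predictor]))
  expect_false(any(sc$associations$feature ==
                     tg[sc$associations$predictor]))
  expect_equal(nrow(sc$self) + nrow(sc$associations), sc$n_tests)
  # planted cross-gene HLA-type effect is recovered
  expect_true("nonhla1" %in% sc$egenes)
  hit <- sc$associations[sc$associations$feature == "nonhla1" &
                           sc$associations$predictor == focal, ]
  expect_true(hit$significant)
  expect_true(all(sc$associations$hwe_flagged[
    sc$associations$predictor == rownames(D)[2]]))
})

test_that("conditioning on the causal variant removes the association signal", {
  set.seed(41)
  ped <- simulate_pedigree(10, c(2, 5), 2, 120, seed = 51)
  K <- ped$kinship
  sim <- simulate_hla_haplotypes(ped$pedigree, n_genes = 4,
                                 alleles_per_gene = 8,
                                 n_linked_snps = 40, seed = 52)
  af <- rowMeans(sim$snp_geno) / 2
  causal <- rownames(sim$snp_geno)[which.min(abs(af - 0.5))]
  ex <- simulate_expression("gA", snp_geno = sim$snp_geno, kinship = K,
                            effects = data.frame(feature = "gA",
                                                 predictor = causal,
                                                 beta = 1),
                            sigma_g = 0.2, sigma_e = 0.6, seed = 53)
  prim <- hierarchical_correction(
    lmm_scan(ex$expression, sim$snp_geno, K),
    positions = stats::setNames(sim$variants$pos, sim$variants$id))
  expect_true("gA" %in% prim$egenes)
  cond <- conditional_scan(ex$expression, sim$snp_geno, K,
                           leads = list(gA = causal))
  # conditioning predictor is excluded from the scan
  expect_true(is.na(cond$results$p[cond$results$predictor == causal]))
  # no remaining predictor reaches the local QTL threshold
  expect_equal(nrow(cond$qtls), 0)
})
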