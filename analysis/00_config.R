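# Shared configuration for the analysis drivers. Each numbered script
# sources this file and rebuilds the cohort deterministically from the
# seed, so no binary state is carried between scripts.
suppressPackageStartupMessages(library(mhcqtl))

cohort_seed <- 1L
results_dir <- "results"

build_cohort <- function(seed = cohort_seed) {
  ped <- simulate_pedigree(n_families = 56, family_size_range = c(2, 14),
                           n_twin_pairs = 25, n_unrelated = 377,
                           seed = seed)
  sim <- simulate_hla_haplotypes(ped$pedigree, n_genes = 30,
                                 alleles_per_gene = 15,
                                 n_linked_snps = 300, seed = seed + 1)
  cov <- simulate_coverage(sim$diplotypes, genome_mean_cov = 50,
                           noise_cv = 0.15, dropout_rate = 0.02,
                           seed = seed + 2)
  list(ped = ped, sim = sim, coverage = cov)
}

# expression cohort: the subset with RNA-seq, with planted cis effects
build_expression <- function(cohort, seed = cohort_seed) {
  K <- cohort$ped$kinship
  G <- cohort$sim$snp_geno
  af <- rowMeans(G) / 2
  common <- rownames(G)[af > 0.2 & af < 0.8]
  set.seed(seed + 50)
  # 146 expressed genes: the 30 HLA genes plus 116 other MHC genes
  hla <- dimnames(cohort$sim$diplotypes)[[2]]
  genes <- c(hla, sprintf("gene%03d", seq_len(146 - length(hla))))
  # planted truth: 8 SNP eQTLs on non-HLA genes and 4 HLA-type effects
  dip <- cohort$sim$diplotypes
  type_freq <- table(c(dip[, , 1], dip[, , 2])) / (2 * nrow(dip))
  common_types <- names(type_freq)[type_freq > 0.15 & type_freq < 0.6]
  effects <- rbind(
    data.frame(feature = genes[31:38], predictor = sample(common, 8),
               beta = round(stats::runif(8, 0.5, 1.1), 2)),
    data.frame(feature = c(genes[39:41], hla[2]),
               predictor = sample(common_types, 4),
               beta = round(stats::runif(4, 0.7, 1.1), 2)))
  ex <- simulate_expression(genes, cohort$sim$diplotypes, G, K,
                            effects = effects, sigma_g = 0.3,
                            sigma_e = 0.7, seed = seed + 51)
  list(expression = ex$expression, aif = ex$aif, effects = effects)
}
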