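# mhcqtl

Regulatory analysis of the human MHC region (chr6p21.3) for cohorts with
family structure: HLA genotype calling from per-allele sequencing
coverage, HLA type-specific expression, kinship-aware eQTL mapping for
single variants and multi-allelic HLA-type dosages, chromatin-state
enrichment, allelic-imbalance association, and eQTL–GWAS colocalization.
It is written for statistical geneticists who need the whole chain —
from coverage profiles to colocalization posteriors — as tested,
composable R functions, together with a synthetic cohort generator so
every stage can be validated against known ground truth without access
to protected genotype data.

## The methods at the core

**HLA calling.** For each gene, alleles with mean coverage
≥ 20% of the genome-wide mean (threshold *t*) are considered and the
genotype is decided by five rules: nothing passes → no call; one allele
with depth ≥ 2*t* → homozygous; one allele below 2*t* → heterozygous
with an Undetermined partner; top allele > 2 × second → homozygous;
otherwise the top two alleles. Validation: recall, MZ-twin and
Mendelian concordance, per-allele Hardy-Weinberg LRT
(2 Σ O ln(O/E), 1 df, carrier collapse), carrier-frequency comparison
with a reference panel.

**Kinship LMM.** y = α + gβ + u + ε with u ~ N(0, σ²_g K); REML on the
eigenbasis of K, then GLS per predictor with the variance ratio fixed
(P3D) and the residual scale re-profiled, so K = I reduces exactly to
OLS. Hierarchical correction: gene-level Bonferroni → lead; BH across
genes with denominator 20,595; eQTLs at locally adjusted p < 0.1 within
eGenes; conditional scans add accumulated leads as covariates.
HLA types are coded 0 / 0.5 / 1 and all gene × type combinations are
BH-corrected in one batch (146 × 283 = 41,318 tests at the study
configuration).

**Colocalization.** Wakefield log ABF per variant
(½ log V/(V+W) + ½ z² W/(V+W), W = 0.15²), five-hypothesis posteriors
(H0–H4) with priors p1 = p2 = 1e-4, p12 = 1e-5, H3 via the log-space
sum-minus-shared identity. Posteriors sum to 1 within 1e-9.

## Worked example

```r
library(mhcqtl)

ped <- simulate_pedigree(n_families = 20, family_size_range = c(2, 6),
                         n_twin_pairs = 5, n_unrelated = 300, seed = 7)
sim <- simulate_hla_haplotypes(ped$pedigree, n_genes = 30,
                               alleles_per_gene = 15,
                               n_linked_snps = 300, seed = 8)
cov <- simulate_coverage(sim$diplotypes, genome_mean_cov = 50,
                         noise_cv = 0, seed = 9)
calls <- call_hla_table(cov)
mean(recall_rate(calls))                     # 1
truth_concordance(calls, sim$diplotypes)     # 1

K <- ped$kinship
D <- top_hla_types(hla_dosage_matrix(calls, samples = rownames(K),
                                     min_freq = 0.01), 283)
focal <- rownames(D)[which.min(abs(attr(D, "freq") - 0.3))]
ex <- simulate_expression(sprintf("gene%03d", 1:146), sim$diplotypes,
                          sim$snp_geno, K,
                          effects = data.frame(feature = "gene001",
                                               predictor = focal,
                                               beta = 1.2),
                          seed = 10)
sc <- scan_hla_types(ex$expression, D, K)
sc$n_tests                                   # 41318
"gene001" %in% sc$egenes                     # TRUE
a <- sc$associations
signif(a[a$feature == "gene001" & a$predictor == focal,
         c("beta", "p", "p_bh")], 3)
#   beta        p     p_bh
#   1.29 1.21e-13 4.98e-09
```

On a noise-free cohort of 358 individuals the caller recovers every
genotype (recall and truth concordance both print `1`). The HLA-type
scan enumerates exactly 41,318 tests (146 expressed genes × 283 common
types), which is also its Benjamini-Hochberg denominator; the gene with
the planted HLA-type effect (true β = 1.2 on the 0/0.5/1 dosage of a
frequency-0.30 type) is recovered as an eGene with an estimated effect
of 1.29 and a BH-adjusted p of 5.0e-9.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on the synthetic
cohort and write plain-text tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | cohort (56 families, 25 MZ twin pairs, 377 unrelated), coverage TSV, VCF, truth |
| `02_hla_typing_qc.R` | genotype calls; recall, twin/Mendelian concordance, HWE screen, frequency comparison |
| `03_allele_expression.R` | per-allele TPMs, gene reconstruction, expressed-gene filter, allele-vs-rest tests |
| `04_eqtl_scan.R` | variant filters, single-variant LMM scan, 3-step correction, conditional 1–2 |
| `05_hla_type_eqtl.R` | HLA-type dosage scan, self-associations, conditional stages |
| `06_regulatory_context.R` | effect-size-decile × chromatin-state enrichment, AIF tests, coexpression betas |
| `07_colocalization.R` | eQTL–GWAS posteriors on shared- and distinct-causal loci |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_cohort.R`.

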