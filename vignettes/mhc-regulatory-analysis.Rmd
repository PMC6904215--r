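---
title: "Methods: HLA typing and kinship-aware eQTL mapping in the MHC region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HLA typing and kinship-aware eQTL mapping in the MHC region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

The major histocompatibility complex (MHC) on chromosome 6p21.3 is the
most polymorphic region of the human genome: HLA genes carry hundreds of
alleles, linkage disequilibrium (LD) extends over megabases, and both
coding and regulatory variation are dense. `mhcqtl` implements a complete
regulatory analysis of this region as composable R functions plus a set
of narrative drivers under `analysis/`:

1. HLA genotype calling from per-allele sequencing coverage, with
   validation metrics (recall, twin / Mendelian / paired-sample
   concordance, per-allele Hardy-Weinberg tests, reference frequency
   comparison);
2. HLA type-specific and gene-level expression quantification;
3. a kinship-aware linear mixed model (LMM) association engine for
   biallelic variants and multi-allelic HLA-type dosages, with
   hierarchical multiple-testing correction and conditional scans;
4. chromatin-state enrichment of eQTL effect-size deciles, allelic
   imbalance association, and pairwise coexpression;
5. five-hypothesis colocalization of eQTL and GWAS signals from summary
   statistics.

Because the cohorts such analyses run on are access-controlled, the
package ships a synthetic cohort generator that reproduces the
*statistical structure* the methods assume. Every stage is therefore
testable against known ground truth, offline.

# The synthetic cohort

`simulate_pedigree()` builds nuclear families plus unrelated singletons.
Defaults mirror the study design the pipeline targets: 56 families of
2–14 members including 25 monozygotic (MZ) twin pairs, plus 377
unrelated individuals. Family sizes are drawn with probability
proportional to $2^{-s}$, so small families dominate, as in volunteer
cohorts. The kinship matrix is the additive relationship matrix from the
pedigree (tabular method): self = 1, parent–offspring = full siblings =
0.5, and MZ twins are collapsed onto one genome so their entry is 1. No
inbreeding is modeled, so the diagonal is exactly 1; the matrix is
validated against an independent recursive kinship-coefficient oracle in
the tests.

`simulate_hla_haplotypes()` draws per-gene allele frequencies from a
symmetric Dirichlet (concentration 0.5 by default), which yields the
realistic mixture of a few common and many rare alleles. A founder
haplotype carries one allele per HLA gene; children inherit whole
haplotypes with no within-region recombination by default (a
per-meiosis crossover probability is available), emulating the region's
strong LD. Each SNP is assigned to a gene and carries its alternate
allele exactly when the haplotype's allele at that gene falls in a
fixed random subset — SNPs therefore tag HLA types deterministically,
giving the LD structure on which the conditional scans and the
haplotype-power comparison depend. This is a structural emulation, not
a population-genetic simulation: there is no mutation, drift, or
fine-scale recombination map, so tests passing here show correctness of
the analysis machinery, not calibration on real MHC data.

`simulate_coverage()` emulates the per-allele mean-depth table produced
by read-assignment tools. Carried alleles receive depth centred on the
genome-wide mean (homozygous) or half of it (each heterozygous allele)
with multiplicative lognormal noise; the default coefficient of
variation 0.15 is a stated assumption, as the upstream tool's noise is
not characterized anywhere we could calibrate against. Non-carried
alleles get background coverage, exponential with mean 5% of the genome
mean and truncated just below the 20% calling threshold so background
alone can never produce a call — this is what makes the noise-free
recovery guarantee exact on every seed. Dropout is modeled at the
sample × gene level: with the configured probability, the locus's reads
collapse to background and the caller produces a no-call (both allele
slots Undetermined). We chose locus-level rather than per-allele
dropout deliberately: under the five calling rules a lone surviving
heterozygous allele (depth ≈ 0.5 × genome mean ≥ 2 × threshold) is
always called homozygous, so per-allele dropout would produce silent
miscalls rather than Undetermined slots, and the slot rate would not
track the dropout parameter.

`simulate_expression()` generates
$y = X_c\gamma + \sum_k g_k\beta_k + u + \varepsilon$ with
$u \sim N(0, \sigma_g^2 K)$ and $\varepsilon \sim N(0, \sigma_e^2 I)$,
where predictors may be SNP dosages (0/1/2) or HLA-type dosages
(0/0.5/1). Defaults $\sigma_g^2 = 0.3$, $\sigma_e^2 = 0.7$ put 30% of
variance on the polygenic kinship component, a typical heritability for
expression traits. Allelic imbalance fractions (AIF) are drawn directly
from Beta distributions rescaled to [0.5, 1] — Beta(2.5, 5) for samples
heterozygous at the causal predictor (mean ≈ 0.67), Beta(1.5, 6)
otherwise (mean ≈ 0.60) — rather than simulated at read level, since
read-level allele-specific estimation is outside the package's scope.

`simulate_gwas()` re-draws an independent cohort from the stored founder
haplotype structure, generates a quantitative trait with a configurable
single-variant heritability, and returns marginal per-variant summary
statistics, so colocalization can be exercised with known shared or
distinct causal variants.

# HLA genotype calling

With threshold $t = 0.2 \times$ genome-wide mean coverage, and
considering only alleles with mean depth ≥ t:

1. no allele passes → no call;
2. one allele passes with depth ≥ 2t → homozygous;
3. one allele passes with depth < 2t → heterozygous with the partner
   Undetermined;
4. two or more pass, top depth > 2 × second → homozygous for the top;
5. otherwise → heterozygous for the top two.

Two boundary readings are deliberate and documented: rule 2 is
non-strict ("two or more times") and rule 4 strict ("more than twice").
Exact depth ties are broken by depth descending then allele code
ascending, so calls are deterministic and independent of input order;
the whole procedure is scale-invariant in (depths, genome mean).

Validation metrics follow the usual definitions: recall is the fraction
of samples with both alleles determined; pair (twin / paired-sample) and
Mendelian concordance exclude, per gene, any pair or trio containing an
Undetermined slot. We scope the exclusion per gene rather than per
individual so one failed locus does not void a sample's other 29 genes.
Trios are non-overlapping (each individual used once, greedy selection).

The Hardy-Weinberg test collapses each allele of a multi-allelic locus
to "focal vs pooled others" and computes the multinomial likelihood
ratio statistic $2\sum O \ln(O/E)$ against expectations from the MLE
allele frequency, with 1 df. A full multi-allelic exact test is
intentionally avoided: with hundreds of alleles per locus it is
computationally heavy, and selection in the MHC violates its
assumptions anyway, so the per-allele collapse with a stringent
$10^{-6}$ flag threshold is used and flagged types are carried through
the HLA-type scan rather than removed. The test is run on an unrelated
subset: one individual per family, chosen as the lexicographically
smallest id for determinism.

# Expression quantification

For heterozygous genotypes the TPM quantified against each haplotype's
cDNA is the allele's expression; for homozygous genotypes one cDNA
absorbs both copies, so the gene TPM is divided by two per copy.
Gene-level expression is the sum of the two allele TPMs, making the two
operations exact inverses. Expressed genes are those with TPM ≥ 2 in at
least 10 samples (both boundaries non-strict).

Each HLA allele with at least two carriers is tested against all other
alleles of its cognate gene on quantile-normalized expression. The
default test is Mann-Whitney; a Welch t-test is available via
`method =` because the two are used interchangeably in this literature
and we surface the choice rather than hide it. BH correction is applied
across all (gene, allele) tests in one batch, with significance at
adjusted p < 0.05.

# The mixed-model association engine

Expression is quantile-normalized per gene (rank-based inverse normal,
$\Phi^{-1}((r - 0.5)/n)$, average ranks for ties) and covariates —
sex, age, batch, technical metrics, expression principal components
(standing in for latent-factor methods) and genotype principal
components — are regressed out *before* the kinship model
(pre-residualization). The LMM is
$y = \alpha + g\beta + u + \varepsilon$, $u \sim N(0, \sigma_g^2 K)$.
Variance components are estimated once per feature by REML on the null
model, via the eigendecomposition of $K$ and a one-dimensional search
over the variance ratio $\lambda = \sigma_g^2/\sigma_e^2$ on the log
scale (interval $e^{\pm 18}$, with endpoint checks). Each association
then runs generalized least squares with $\Sigma \propto \lambda K + I$
fixed and the residual scale re-profiled per model — the standard
"population parameters previously determined" approximation, orders of
magnitude faster than per-variant refitting and asymptotically
equivalent. Re-profiling the scale has a useful exact property: with
$K = I$ the results coincide with OLS to machine precision, which the
tests assert. Wald p-values use the standard normal reference by
default (`df_test = "t"` switches to a t reference). Missing dosages
are mean-imputed per variant; monomorphic or conditioning-collinear
predictors are reported untested rather than dropped silently.

Variant filters before the scan: call rate ≥ 95%, minor allele
frequency ≥ 1% (computed on non-missing calls), and HWE p ≥ $10^{-6}$
on the unrelated subset, with multi-allelic records decomposed into one
biallelic row per alternate allele first.

## Hierarchical correction and conditional scans

Step 1 adjusts nominal p-values per gene by Bonferroni with the number
of local tests (by default the number of predictors actually tested;
a fixed factor can be supplied to replicate a published denominator),
and the smallest adjusted p defines the lead, with ties broken by
genomic position then predictor id. Step 2 BH-corrects the lead
p-values across genes with a fixed denominator equal to the genome-wide
expressed-gene count (20,595 by default) — deliberately conservative,
since only the region's genes are actually scanned; genes below 0.05
are eGenes. Step 3 reports, for each eGene, every predictor with
locally adjusted p < 0.1 as an eQTL. Conditional stages add the
accumulated lead dosages as fixed covariates (the leads themselves are
excluded from the scan) and reapply the same correction: conditional 1
conditions on the primary lead, conditional 2 on the primary and
conditional-1 leads, and so on.

## HLA-type dosage scan

Each eight-digit type is coded 0 / 0.5 / 1 (absent / heterozygous /
homozygous); under this coding the mean dosage equals the allele
frequency, and types with frequency ≥ 1% are kept. Every
(expressed gene × common type) combination is tested and BH-corrected
in a single batch whose denominator is the full combination count — at
the study configuration of 146 genes × 283 types, exactly 41,318 tests.
Self-associations (a type against its own gene's expression) are
computed and reported separately but excluded from the cross-gene
results, and HWE-flagged types are flagged, not removed. Because an
eight-digit type is a haplotype of many regulatory variants, its dosage
concentrates signal that single SNPs tag only partially; the acceptance
suite verifies on synthetic loci that the type scan detects eGenes at
least as often as the best single-SNP scan when the signal is split
across tagging SNPs.

# Regulatory context

All tested gene–variant pairs are ranked by absolute effect size (the
sign convention is our documented choice) with ties broken by predictor
id, and split into 10 equal-count bins. For each chromatin annotation
set, pairs are counted per (decile, state) cell; each state column gets
a pseudo-count (default 1, to keep the log finite on empty cells), is
divided by its mean across deciles and log2-transformed, so values are
enrichments centred on zero and the identity
$\mathrm{mean}(2^{\mathrm{column}}) = 1$ holds exactly on the
pseudo-count-free path. Variants map to states by single base position
against half-open BED intervals; positions outside all intervals pool
into an "unannotated" category excluded from the 10 × 15 matrix.

AIF comparisons (heterozygous vs homozygous carriers of an eQTL) use
the Mann-Whitney U with exact enumeration over all
$\binom{n_1+n_2}{n_1}$ assignments for combined n ≤ 12 (valid under
ties) and a tie-corrected, continuity-corrected normal approximation
above. Coexpression between two genes is the coefficient of $e_j$ in
the least-squares fit $e_i \sim e_j + \text{covariates}$.

# Colocalization

Per-variant evidence is the Wakefield approximate Bayes factor,
$\log \mathrm{ABF} = \tfrac12\log\frac{V}{V+W} +
\tfrac12 z^2\frac{W}{V+W}$ with $V = \mathrm{se}^2$, $z = \beta/\mathrm{se}$,
and prior effect variance $W = 0.15^2$ for quantitative traits. Under
the single-causal-variant-per-trait assumption the five hypothesis
weights are assembled from per-variant log ABFs and priors
($p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, the cited method's published
defaults; the analysed study states none): H0 no association, H1/H2 one
trait only, H3 both traits with distinct causal variants, H4 a shared
causal variant. H3 uses the identity
$\sum_{i \ne j} = \sum_i \sum_j - \sum_{i=j}$ computed in log space
(log-sum-exp and log-diff-exp), with the explicit $O(m^2)$ pair
enumeration retained as the test oracle. Posteriors sum to one within
$10^{-9}$; pairs with PP(H4) above 0.2 and 0.8 are flagged. Variants
are matched by identifier; strand/allele flipping is out of scope
because the synthetic data are internally consistent.

# Numerical choices and degenerate inputs

* Kinship eigenvalues are clamped at zero; matrices with eigenvalues
  below $-10^{-6}$ (relative) are rejected as non-PSD.
* With $K = I$ (or any scalar multiple) the variance components are not
  separately identifiable; the engine still returns correct
  associations because only the ratio enters the GLS weights.
* `quantile_normalize()` on a constant vector warns and returns zeros;
  fewer than 3 non-missing values is an error.
* Rank-deficient covariate designs error naming the collinear columns.
* Empty conditioning sets reproduce the primary scan exactly.
* All generators funnel randomness through a single integer seed and
  regenerate byte-identically.

# Problem sizes used in tests and drivers

The test and acceptance configurations are chosen to exercise the
study-scale worked counts while staying desk-sized: typing runs at
~500–560 samples × 30 genes; the HLA-type scan at 146 genes × 283 types
(41,318 tests); LMM calibration at n = 300 with 2,000 null replicates;
parameter recovery and conditional-lead recovery over 50 seeds;
colocalization loci over 20 seeds per scenario; the global-null eGene
rate over 10–20 seeds of 100–200 genes × 300–500 variants.

# Known limitations

* The generator's SNP–HLA tagging is deterministic, so SNP–type LD is
  stronger and cleaner than in real MHC data; power comparisons are
  qualitative analogues, not effect-size forecasts.
* Coverage noise parameters are assumptions, not calibrated to any
  read-assignment tool's empirical error profile.
* AIF values are simulated at the summary level; no read-level
  allele-specific machinery is included.
* The LMM uses the P3D approximation by default; per-variant REML
  refitting is available (`vc = NULL` per call) but not used by the
  drivers.
* Colocalization assumes one causal variant per trait and a
  quantitative GWAS trait on the same effect scale.
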