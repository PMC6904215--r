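#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 56 families (2-14 members) with 25
# MZ twin pairs plus 377 unrelated individuals; 30 multi-allelic HLA
# genes in complete within-region linkage with 300 tagging SNPs; and
# per-allele coverage profiles at 50x mean depth with 15% multiplicative
# noise and 2% locus dropout. Writes the plain-text cohort tables that
# the later drivers and any external tool can consume.
source("analysis/00_config.R")

out <- file.path(results_dir, "cohort")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
co <- build_cohort()
fam_sizes <- table(co$ped$pedigree$family)
cat("cohort:", nrow(co$ped$pedigree), "individuals —",
    sum(fam_sizes > 1), "families,",
    sum(!is.na(co$ped$pedigree$twin_group)) / 2, "MZ twin pairs,",
    sum(fam_sizes == 1), "unrelated\n")

write.table(co$ped$pedigree, file.path(out, "pedigree.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(co$coverage, file.path(out, "coverage.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_vcf(co$sim$snp_geno, co$sim$variants, file.path(out, "snps.vcf"))
dip <- co$sim$diplotypes
truth <- data.frame(sample = rep(rownames(dip), times = 2 * ncol(dip)),
                    gene = rep(rep(colnames(dip), each = nrow(dip)), 2),
                    copy = rep(1:2, each = nrow(dip) * ncol(dip)),
                    allele = c(dip[, , 1], dip[, , 2]))
write.table(truth, file.path(out, "true_diplotypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
km <- co$ped$kinship
write.table(data.frame(id = rownames(km), km, check.names = FALSE),
            file.path(out, "kinship.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote", out, "\n")
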