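#' HLA type-specific expression from haplotype-level TPM
#'
#' For a heterozygous genotype, the TPM quantified against each
#' haplotype's cDNA is taken directly as that allele's expression. For a
#' homozygous genotype only one cDNA is quantified, so the gene TPM is
#' divided by two to give the per-copy expression. Genotypes with an
#' Undetermined slot are skipped with a warning.
#'
#' @param genotype Character length 2 (allele1, allele2; NA =
#'   Undetermined).
#' @param tpm For heterozygotes, numeric length 2 in genotype order
#'   (per-haplotype TPM); for homozygotes, the gene-level TPM (length 1)
#'   or two haplotype TPMs that are summed first.
#' @return data.frame: allele, copy (1/2), tpm; NULL if skipped.
#' @export
allele_specific_tpm <- function(genotype, tpm) {
  stopifnot(all(tpm >= 0))
  if (anyNA(genotype)) {
    warning("Undetermined genotype skipped")
    return(NULL)
  }
  if (genotype[1] == genotype[2]) {
    half <- sum(tpm) / 2
    return(data.frame(allele = genotype, copy = 1:2, tpm = rep(half, 2),
                      stringsAsFactors = FALSE))
  }
  stopifnot(length(tpm) == 2)
  data.frame(allele = genotype, copy = 1:2, tpm = as.numeric(tpm),
             stringsAsFactors = FALSE)
}

#' Gene-level expression from per-allele TPMs
#'
#' Sums the two per-allele TPMs for each sample x gene. Missing allele
#' records propagate as NA.
#'
#' @param allele_tpms data.frame: sample, gene, allele, tpm (two rows per
#'   sample x gene).
#' @return data.frame: sample, gene, tpm.
#' @export
gene_level_expression <- function(allele_tpms) {
  key <- interaction(allele_tpms$sample, allele_tpms$gene, drop = TRUE,
                     sep = "\r")
  sp <- split(allele_tpms$tpm, key)
  ids <- strsplit(names(sp), "\r", fixed = TRUE)
  data.frame(sample = vapply(ids, `[`, "", 1L),
             gene = vapply(ids, `[`, "", 2L),
             tpm = vapply(sp, function(x)
               if (length(x) == 2) sum(x) else NA_real_, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expressed-gene filter
#'
#' Retains genes with TPM >= `min_tpm` in at least `min_samples` samples
#' (both boundaries non-strict).
#'
#' @param tpm_matrix Genes x samples numeric matrix.
#' @param min_tpm TPM threshold (default 2).
#' @param min_samples Minimum number of samples at or above it
#'   (default 10).
#' @return Character vector of retained gene ids.
#' @export
expressed_gene_filter <- function(tpm_matrix, min_tpm = 2,
                                  min_samples = 10L) {
  stopifnot(nrow(tpm_matrix) > 0)
  keep <- rowSums(tpm_matrix >= min_tpm, na.rm = TRUE) >= min_samples
  rownames(tpm_matrix)[keep]
}

#' Test each HLA allele's expression against all other alleles
#'
#' For every allele of every HLA gene with at least `min_carriers`
#' carriers and two non-carriers, compares the (quantile-normalized)
#' expression of the cognate gene between carriers and non-carriers.
#' Nominal p-values come from a two-sided Mann-Whitney U test by default
#' (Welch t-test available); Benjamini-Hochberg correction is applied
#' across all tested alleles of all genes in one batch. Samples with an
#' Undetermined genotype at a gene are excluded from both groups.
#'
#' @param expression Genes x samples matrix of quantile-normalized
#'   expression (see [quantile_normalize()]).
#' @param calls Genotype calls data.frame (sample, gene, allele1,
#'   allele2).
#' @param method "mann-whitney" (default) or "t-test".
#' @param min_carriers Minimum carriers for an allele to be tested
#'   (default 2).
#' @param alpha Significance threshold on the BH-adjusted p (default
#'   0.05).
#' @return data.frame: gene, allele, n_carriers, statistic, p_nominal,
#'   p_adjusted, significant.
#' @export
allele_vs_rest_test <- function(expression, calls,
                                method = c("mann-whitney", "t-test"),
                                min_carriers = 2L, alpha = 0.05) {
  method <- match.arg(method)
  out <- list()
  for (g in intersect(unique(calls$gene), rownames(expression))) {
    cg <- calls[calls$gene == g & !is.na(calls$allele1) &
                  !is.na(calls$allele2), , drop = FALSE]
    cg <- cg[cg$sample %in% colnames(expression), , drop = FALSE]
    if (nrow(cg) == 0) next
    y <- expression[g, cg$sample]
    for (a in sort(unique(c(cg$allele1, cg$allele2)))) {
      carrier <- cg$allele1 == a | cg$allele2 == a
      if (sum(carrier) < min_carriers || sum(!carrier) < 2) next
      if (method == "mann-whitney") {
        wt <- suppressWarnings(stats::wilcox.test(y[carrier], y[!carrier],
                                                  exact = FALSE,
                                                  correct = FALSE))
      } else {
        wt <- stats::t.test(y[carrier], y[!carrier])
      }
      out[[length(out) + 1L]] <- data.frame(
        gene = g, allele = a, n_carriers = sum(carrier),
        statistic = unname(wt$statistic), p_nominal = wt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(gene = character(0), allele = character(0),
                      n_carriers = integer(0), statistic = numeric(0),
                      p_nominal = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0)))
  res <- do.call(rbind, out)
  res$p_adjusted <- stats::p.adjust(res$p_nominal, method = "BH")
  res$significant <- res$p_adjusted < alpha
  res
}
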