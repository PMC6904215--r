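#' Encode an HLA genotype as a focal-allele dosage
#'
#' Dosage coding for HLA-type association: 0 = does not harbor the focal
#' allele, 0.5 = heterozygous for it, 1 = homozygous. A genotype with an
#' Undetermined slot and no observed focal copy is missing (NA); with one
#' observed focal copy it codes 0.5.
#'
#' @param genotype Character length 2 (NA = Undetermined slot).
#' @param focal_allele Allele code.
#' @return Dosage in \{0, 0.5, 1\} or NA.
#' @export
encode_hla_dosage <- function(genotype, focal_allele) {
  copies <- sum(genotype == focal_allele, na.rm = TRUE)
  if (copies == 0 && anyNA(genotype)) return(NA_real_)
  copies / 2
}

#' HLA-type dosage matrix for a cohort
#'
#' Builds the types x samples dosage matrix from genotype calls and
#' filters types by population allele frequency (mean dosage over
#' non-missing samples, which equals the allele frequency under the
#' 0/0.5/1 coding).
#'
#' @param calls Genotype calls data.frame (sample, gene, allele1,
#'   allele2).
#' @param samples Sample ids defining the column order (default: unique
#'   samples in `calls`).
#' @param min_freq Minimum allele frequency (non-strict, default 0.01);
#'   set to 0 to keep every type.
#' @return Matrix types x samples with a `gene` attribute mapping each
#'   type (row) to its cognate gene.
#' @export
hla_dosage_matrix <- function(calls, samples = NULL, min_freq = 0.01) {
  if (is.null(samples)) samples <- sort(unique(calls$sample))
  types <- unique(data.frame(gene = c(calls$gene, calls$gene),
                             allele = c(calls$allele1, calls$allele2),
                             stringsAsFactors = FALSE))
  types <- types[!is.na(types$allele), , drop = FALSE]
  types <- types[order(types$gene, types$allele, method = "radix"), ,
                 drop = FALSE]
  key <- paste(calls$sample, calls$gene, sep = "\r")
  D <- matrix(NA_real_, nrow(types), length(samples),
              dimnames = list(types$allele, samples))
  for (r in seq_len(nrow(types))) {
    ix <- match(paste(samples, types$gene[r], sep = "\r"), key)
    a1 <- calls$allele1[ix]; a2 <- calls$allele2[ix]
    copies <- (ifelse(is.na(a1), FALSE, a1 == types$allele[r])) +
              (ifelse(is.na(a2), FALSE, a2 == types$allele[r]))
    dos <- copies / 2
    dos[copies == 0 & (is.na(a1) | is.na(a2))] <- NA
    D[r, ] <- dos
  }
  freq <- rowMeans(D, na.rm = TRUE)
  keep <- !is.na(freq) & freq >= min_freq
  D <- D[keep, , drop = FALSE]
  attr(D, "gene") <- stats::setNames(types$gene[keep], types$allele[keep])
  attr(D, "freq") <- freq[keep]
  D
}

#' Subset an HLA dosage matrix to its most common types
#'
#' Keeps the `n` types with the highest allele frequency (ties broken by
#' type code), preserving the `gene` and `freq` attributes. Used to fix
#' the scanned type count of a cohort configuration.
#'
#' @param dosages Matrix from [hla_dosage_matrix()].
#' @param n Number of types to keep.
#' @return Subset dosage matrix with attributes.
#' @export
top_hla_types <- function(dosages, n) {
  freq <- attr(dosages, "freq")
  stopifnot(!is.null(freq), n <= nrow(dosages))
  keep <- order(-freq, rownames(dosages), method = "radix")[seq_len(n)]
  out <- dosages[keep, , drop = FALSE]
  attr(out, "gene") <- attr(dosages, "gene")[rownames(out)]
  attr(out, "freq") <- freq[keep]
  out
}

#' HLA-type eQTL scan
#'
#' Tests every (expressed gene x common HLA type) combination with the
#' kinship mixed model. The Benjamini-Hochberg correction is applied in
#' one batch whose denominator is the full number of combinations
#' (genes x types), which is also reported as `n_tests`.
#' Self-associations -- an HLA type tested against the expression of its
#' own gene -- are computed and reported separately, and excluded from
#' the cross-gene result set. HWE-flagged types are carried through with
#' a flag, not removed.
#'
#' @param Y Expressed genes x samples matrix (covariate-adjusted,
#'   normalized).
#' @param dosages Types x samples matrix from [hla_dosage_matrix()]
#'   (must carry the `gene` attribute).
#' @param K Kinship matrix or [kinship_eigen()] object.
#' @param conditioning NULL, matrix, or named list feature -> matrix of
#'   conditioning dosage rows (e.g. SNP lead eQTLs for conditional
#'   stages).
#' @param bh_alpha Significance threshold on the BH-adjusted p (default
#'   0.05).
#' @param hwe_flags Optional character vector of HWE-flagged type codes.
#' @param stage Stage label.
#' @return List: `associations` (cross-gene results with p_bh,
#'   significant, hwe_flagged), `self` (self-association rows), `egenes`
#'   (features with >= 1 significant cross-gene association), `n_tests`.
#' @export
scan_hla_types <- function(Y, dosages, K, conditioning = NULL,
                           bh_alpha = 0.05, hwe_flags = character(0),
                           stage = "primary") {
  type_gene <- attr(dosages, "gene")
  if (is.null(type_gene))
    stop("dosages must carry a 'gene' attribute (see hla_dosage_matrix)",
         call. = FALSE)
  n_tests <- nrow(Y) * nrow(dosages)
  if (n_tests == 0)
    return(list(associations = NULL, self = NULL, egenes = character(0),
                n_tests = 0L))
  assoc <- lmm_scan(Y, dosages, K, conditioning = conditioning)
  assoc$p_bh <- stats::p.adjust(assoc$p, method = "BH",
                                n = max(n_tests, sum(!is.na(assoc$p))))
  assoc$significant <- !is.na(assoc$p_bh) & assoc$p_bh < bh_alpha
  assoc$hwe_flagged <- assoc$predictor %in% hwe_flags
  assoc$stage <- stage
  self <- assoc$feature == type_gene[assoc$predictor]
  self[is.na(self)] <- FALSE
  cross <- assoc[!self, , drop = FALSE]
  list(associations = cross, self = assoc[self, , drop = FALSE],
       egenes = sort(unique(cross$feature[cross$significant])),
       n_tests = as.integer(n_tests))
}
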