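#' Write biallelic genotypes to a VCF v4.2 file
#'
#' Minimal plain-text writer for simulated genotypes (GT field only).
#'
#' @param geno Variants x samples dosage matrix (0/1/2, NA = missing).
#' @param variants data.frame: chrom, pos, id, ref, alt (rows aligned
#'   with `geno`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, variants, path) {
  stopifnot(nrow(geno) == nrow(variants))
  gt <- matrix("./.", nrow(geno), ncol(geno))
  gt[!is.na(geno) & geno == 0] <- "0/0"
  gt[!is.na(geno) & geno == 1] <- "0/1"
  gt[!is.na(geno) & geno == 2] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", colnames(geno)),
                    collapse = "\t"))
  body <- vapply(seq_len(nrow(geno)), function(i)
    paste(c(variants$chrom[i], variants$pos[i], variants$id[i],
            variants$ref[i], variants$alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and filter variants from a VCF
#'
#' Parses a VCF (via vcfR), decomposes multi-allelic records into one
#' biallelic row per alternate allele, and applies the three cohort
#' filters: call rate >= `min_call_rate`, minor allele frequency >=
#' `min_maf`, and Hardy-Weinberg equilibrium (carrier-collapse LRT
#' p >= `hwe_alpha`) evaluated on an unrelated subset.
#'
#' @param vcf Path to a VCF file or a `vcfR` object.
#' @param min_call_rate Minimum fraction of non-missing genotypes
#'   (default 0.95).
#' @param min_maf Minimum minor allele frequency on non-missing calls
#'   (default 0.01).
#' @param hwe_alpha HWE rejection threshold (default 1e-6).
#' @param unrelated Character vector of sample ids for the HWE test
#'   (default: all samples).
#' @return List: `dosage` (passing variants x samples, NA = missing),
#'   `variants` (info for passing rows), `stats` (per decomposed row:
#'   call_rate, maf, hwe_p, pass).
#' @export
filter_variants <- function(vcf, min_call_rate = 0.95, min_maf = 0.01,
                            hwe_alpha = 1e-6, unrelated = NULL) {
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  if (is.null(unrelated)) unrelated <- samples
  unrel_ix <- match(intersect(unrelated, samples), samples)
  if (length(unrel_ix) == 0) stop("empty unrelated subset", call. = FALSE)

  rows <- list(); info <- list()
  for (i in seq_len(nrow(gt))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    al <- strsplit(gsub("|", "/", gt[i, ], fixed = TRUE), "/", fixed = TRUE)
    for (k in seq_along(alts)) {
      dos <- vapply(al, function(a) {
        if (length(a) == 0 || any(a == ".") || anyNA(a)) return(NA_real_)
        sum(a == as.character(k))
      }, numeric(1))
      id <- fix[i, "ID"]
      if (length(alts) > 1) id <- paste0(id, "_", alts[k])
      rows[[length(rows) + 1L]] <- dos
      info[[length(info) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        id = id, ref = fix[i, "REF"], alt = alts[k],
        stringsAsFactors = FALSE)
    }
  }
  dosage <- do.call(rbind, rows)
  colnames(dosage) <- samples
  info <- do.call(rbind, info)
  rownames(dosage) <- info$id

  call_rate <- rowMeans(!is.na(dosage))
  af <- rowMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe_p <- apply(dosage[, unrel_ix, drop = FALSE], 1L, function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NA_real_)
    hwe_lrt(c(sum(d == 2), sum(d == 1), sum(d == 0)))$p_value
  })
  pass <- call_rate >= min_call_rate & maf >= min_maf &
    (!is.na(hwe_p) & hwe_p >= hwe_alpha)
  stats <- data.frame(id = info$id, call_rate = call_rate, maf = maf,
                      hwe_p = hwe_p, pass = pass, row.names = NULL,
                      stringsAsFactors = FALSE)
  list(dosage = dosage[pass, , drop = FALSE],
       variants = info[pass, , drop = FALSE], stats = stats)
}
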