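#' Simulate multi-allelic HLA haplotypes and tagging SNPs
#'
#' Founder haplotypes carry one allele per HLA gene, drawn from gene-wise
#' allele frequencies (symmetric Dirichlet), plus a binary SNP haplotype
#' that is a deterministic function of the HLA alleles: each SNP is
#' assigned to one gene and carries the alternate allele whenever the
#' haplotype's allele at that gene belongs to a fixed random subset of the
#' gene's alleles. SNPs are therefore in strong LD with HLA types, as in
#' the MHC. Children inherit one whole haplotype from each parent; by
#' default no recombination occurs within the region, and MZ twins share
#' both haplotypes.
#'
#' @param pedigree data.frame from [simulate_pedigree()].
#' @param n_genes Number of HLA genes.
#' @param alleles_per_gene Number of distinct eight-digit alleles per gene.
#' @param freq_concentration Symmetric Dirichlet concentration for founder
#'   allele frequencies (0.5 gives a realistic common/rare mix).
#' @param n_linked_snps Number of biallelic SNPs tagging HLA alleles.
#' @param recomb_prob Per-meiosis probability of a single crossover at a
#'   random gene boundary (default 0: complete linkage).
#' @param seed Integer seed.
#' @return List: `diplotypes` (3-d array individuals x genes x 2 of allele
#'   codes), `haplotypes` (individuals x genes x 2 allele indices),
#'   `snp_geno` (variants x individuals dosage 0/1/2), `snp_hap`
#'   (variants x 2*individuals phased 0/1), `variants` (data.frame chrom,
#'   pos, id, ref, alt, gene, tagged alleles), `genes` (data.frame gene,
#'   tss, pos), `truth` (allele frequencies, tagging scheme, seed).
#' @export
simulate_hla_haplotypes <- function(pedigree, n_genes = 30L,
                                    alleles_per_gene = 15L,
                                    freq_concentration = 0.5,
                                    n_linked_snps = 300L,
                                    recomb_prob = 0,
                                    seed = 1L) {
  stopifnot(alleles_per_gene >= 2, n_genes >= 1, freq_concentration > 0,
            recomb_prob >= 0, recomb_prob <= 1)
  set.seed(seed)
  ids <- pedigree$id
  n <- length(ids)
  genes <- sprintf("HLA-S%02d", seq_len(n_genes))
  # gene TSS positions spread over the ~3.4 Mb region (chr6 MHC +/- 1Mb)
  region <- c(29640168L, 33115544L)
  gene_pos <- round(seq(region[1] + 5e4, region[2] - 5e4,
                        length.out = n_genes))
  allele_codes <- vapply(seq_len(n_genes), function(g)
    sprintf("%s*%02d:01:01:%02d", genes[g], seq_len(alleles_per_gene),
            seq_len(alleles_per_gene)),
    character(alleles_per_gene))  # alleles_per_gene x n_genes
  # founder allele frequencies: symmetric Dirichlet via normalized gammas
  freqs <- matrix(0, alleles_per_gene, n_genes,
                  dimnames = list(NULL, genes))
  for (g in seq_len(n_genes)) {
    x <- stats::rgamma(alleles_per_gene, shape = freq_concentration)
    freqs[, g] <- x / sum(x)
  }
  # SNP tagging scheme: SNP j belongs to gene gene_of[j]; alt allele iff
  # haplotype's allele index at that gene is in tagset[[j]]
  gene_of <- rep_len(seq_len(n_genes), n_linked_snps)
  tagset <- lapply(seq_len(n_linked_snps), function(j) {
    k <- sample(seq_len(alleles_per_gene - 1L), 1L)
    sort(sample(seq_len(alleles_per_gene), k))
  })
  snp_pos <- sort(sample(seq(region[1], region[2]), n_linked_snps))

  # haplotypes: n x n_genes x 2 allele indices, filled founders-first
  hap <- array(NA_integer_, dim = c(n, n_genes, 2L),
               dimnames = list(ids, genes, NULL))
  ord <- order(!is.na(pedigree$father))  # founders first (stable)
  draw_founder_hap <- function() {
    vapply(seq_len(n_genes), function(g)
      sample.int(alleles_per_gene, 1L, prob = freqs[, g]), integer(1))
  }
  meiosis <- function(h2) {
    # h2: n_genes x 2 parental haplotypes; transmit one, rare crossover
    pick <- sample(1:2, 1L)
    h <- h2[, pick]
    if (recomb_prob > 0 && stats::runif(1) < recomb_prob && n_genes > 1) {
      bp <- sample.int(n_genes - 1L, 1L)
      h <- c(h2[seq_len(bp), pick], h2[(bp + 1L):n_genes, 3L - pick])
    }
    h
  }
  done_twin <- character(0)
  for (i in ord) {
    fa <- pedigree$father[i]; mo <- pedigree$mother[i]
    tg <- pedigree$twin_group[i]
    if (!is.na(tg) && tg %in% done_twin) {
      co <- which(pedigree$twin_group == tg &
                  !is.na(pedigree$twin_group))[1]
      hap[i, , ] <- hap[co, , ]
      next
    }
    if (is.na(fa) && is.na(mo)) {
      hap[i, , 1L] <- draw_founder_hap()
      hap[i, , 2L] <- draw_founder_hap()
    } else {
      hap[i, , 1L] <- if (!is.na(fa)) meiosis(hap[fa, , ]) else draw_founder_hap()
      hap[i, , 2L] <- if (!is.na(mo)) meiosis(hap[mo, , ]) else draw_founder_hap()
    }
    if (!is.na(tg)) done_twin <- c(done_twin, tg)
  }

  diplo <- array(NA_character_, dim = dim(hap), dimnames = dimnames(hap))
  for (g in seq_len(n_genes)) {
    diplo[, g, 1L] <- allele_codes[hap[, g, 1L], g]
    diplo[, g, 2L] <- allele_codes[hap[, g, 2L], g]
  }

  # phased SNP haplotypes from the tagging scheme
  snp_hap <- matrix(0L, n_linked_snps, 2L * n)
  for (j in seq_len(n_linked_snps)) {
    g <- gene_of[j]
    snp_hap[j, seq(1L, 2L * n, by = 2L)] <- as.integer(hap[, g, 1L] %in% tagset[[j]])
    snp_hap[j, seq(2L, 2L * n, by = 2L)] <- as.integer(hap[, g, 2L] %in% tagset[[j]])
  }
  snp_geno <- snp_hap[, seq(1L, 2L * n, by = 2L), drop = FALSE] +
              snp_hap[, seq(2L, 2L * n, by = 2L), drop = FALSE]
  colnames(snp_geno) <- ids
  variants <- data.frame(chrom = "6", pos = snp_pos,
                         id = sprintf("var%05d", seq_len(n_linked_snps)),
                         ref = "A", alt = "G",
                         gene = genes[gene_of],
                         stringsAsFactors = FALSE)
  rownames(snp_geno) <- variants$id
  list(diplotypes = diplo, haplotypes = hap, snp_geno = snp_geno,
       snp_hap = snp_hap, variants = variants,
       genes = data.frame(gene = genes, tss = gene_pos,
                          stringsAsFactors = FALSE),
       truth = list(allele_freqs = freqs, allele_codes = allele_codes,
                    tagset = tagset, gene_of_snp = gene_of, seed = seed))
}
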