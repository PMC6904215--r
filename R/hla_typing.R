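#' Call an HLA genotype from a per-allele coverage profile
#'
#' Applies five decision rules to the alleles of one gene in one sample.
#' With threshold t = 0.2 x genome-wide mean coverage, and considering
#' only alleles with mean coverage >= t:
#' \enumerate{
#'   \item no allele passes: no call (both slots Undetermined);
#'   \item one allele passes with depth >= 2t: homozygous for it;
#'   \item one allele passes with depth < 2t: heterozygous with the second
#'     allele Undetermined;
#'   \item two or more pass and the top depth is more than twice the
#'     second: homozygous for the top allele;
#'   \item otherwise: heterozygous for the top two alleles.
#' }
#' Rule 2 is non-strict (>=) and rule 4 strict (>), read literally from
#' the procedure's wording. Equal depths are broken by depth descending
#' then allele code ascending, so calls are independent of input order.
#' Undetermined slots are returned as `NA`.
#'
#' @param depths Named numeric vector: allele code -> mean depth.
#' @param genome_mean_coverage Genome-wide mean depth (> 0).
#' @return Character vector length 2 (canonical sorted order, NA last).
#' @export
call_hla_genotype <- function(depths, genome_mean_coverage) {
  if (!is.numeric(genome_mean_coverage) || genome_mean_coverage <= 0)
    stop("genome_mean_coverage must be > 0", call. = FALSE)
  stopifnot(all(depths >= 0))
  t <- 0.2 * genome_mean_coverage
  pass <- depths[depths >= t]
  if (length(pass) == 0L) return(c(NA_character_, NA_character_))
  ord <- order(-pass, names(pass), method = "radix")
  pass <- pass[ord]
  if (length(pass) == 1L) {
    if (pass[1] >= 2 * t) return(rep(names(pass)[1], 2L))
    return(c(names(pass)[1], NA_character_))
  }
  if (pass[1] > 2 * pass[2]) return(rep(names(pass)[1], 2L))
  canonical_genotype(names(pass)[1:2])
}

canonical_genotype <- function(pair) {
  if (all(is.na(pair))) return(c(NA_character_, NA_character_))
  sort(pair, na.last = TRUE)
}

#' Call genotypes for a whole coverage table
#'
#' @param coverage data.frame from [simulate_coverage()] or read from TSV
#'   (columns sample, gene, allele, mean_coverage, genome_mean_coverage).
#' @return data.frame: sample, gene, allele1, allele2 (NA = Undetermined).
#' @export
call_hla_table <- function(coverage) {
  stopifnot(all(c("sample", "gene", "allele", "mean_coverage",
                  "genome_mean_coverage") %in% names(coverage)))
  key <- paste(coverage$sample, coverage$gene, sep = "\r")
  sp <- split(seq_len(nrow(coverage)), key)
  gt <- vapply(sp, function(ix) {
    d <- coverage$mean_coverage[ix]
    names(d) <- coverage$allele[ix]
    call_hla_genotype(d, coverage$genome_mean_coverage[ix[1]])
  }, character(2))
  ids <- strsplit(names(sp), "\r", fixed = TRUE)
  out <- data.frame(sample = vapply(ids, `[`, "", 1L),
                    gene = vapply(ids, `[`, "", 2L),
                    allele1 = gt[1, ], allele2 = gt[2, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$sample, out$gene, method = "radix"), , drop = FALSE]
}

#' Truncate an HLA allele code to lower field resolution
#'
#' Eight-digit codes carry four colon-separated fields
#' (e.g. `A*01:01:01:01`); truncation keeps the first `digits / 2` fields.
#'
#' @param allele Character vector of allele codes (`GENE*f1:f2[:f3[:f4]]`).
#' @param digits Target resolution: 2, 4, 6 or 8.
#' @return Truncated allele codes.
#' @export
truncate_resolution <- function(allele, digits) {
  stopifnot(digits %in% c(2, 4, 6, 8))
  k <- digits / 2
  vapply(allele, function(a) {
    if (is.na(a)) return(NA_character_)
    star <- regexpr("*", a, fixed = TRUE)
    if (star < 0) stop("malformed allele code: ", a, call. = FALSE)
    fields <- strsplit(substring(a, star + 1L), ":", fixed = TRUE)[[1]]
    if (length(fields) < k)
      stop("allele ", a, " has no ", digits, "-digit resolution",
           call. = FALSE)
    paste0(substring(a, 1L, star), paste(fields[seq_len(k)], collapse = ":"))
  }, character(1), USE.NAMES = FALSE)
}

#' Typing recall per gene
#'
#' Fraction of samples with a fully determined genotype (no Undetermined
#' slot) at a gene.
#'
#' @param calls data.frame from [call_hla_table()].
#' @param gene Gene id (default: all genes in the table).
#' @return Named numeric vector of recall per gene.
#' @export
recall_rate <- function(calls, gene = NULL) {
  if (!is.null(gene)) {
    if (!all(gene %in% calls$gene)) stop("unknown gene", call. = FALSE)
    calls <- calls[calls$gene %in% gene, , drop = FALSE]
  }
  ok <- !is.na(calls$allele1) & !is.na(calls$allele2)
  r <- tapply(ok, calls$gene, mean)[unique(calls$gene)]
  stats::setNames(as.numeric(r), names(r))
}

#' Genotype concordance between paired samples
#'
#' Per gene, the fraction of pairs whose unordered genotypes match
#' exactly. Pairs with any Undetermined slot at a gene are excluded from
#' that gene's denominator; a gene with no informative pair is NA.
#'
#' @param calls data.frame of genotype calls covering both pair members.
#' @param pairs data.frame with columns a, b (sample ids).
#' @return Named numeric vector: concordance per gene.
#' @export
pair_concordance <- function(calls, pairs) {
  genes <- unique(calls$gene)
  key <- paste(calls$sample, calls$gene, sep = "\r")
  a1 <- calls$allele1; a2 <- calls$allele2
  vapply(genes, function(g) {
    ia <- match(paste(pairs$a, g, sep = "\r"), key)
    ib <- match(paste(pairs$b, g, sep = "\r"), key)
    ga1 <- a1[ia]; ga2 <- a2[ia]; gb1 <- a1[ib]; gb2 <- a2[ib]
    inf <- !is.na(ga1) & !is.na(ga2) & !is.na(gb1) & !is.na(gb2)
    if (!any(inf)) return(NA_real_)
    mean(ga1[inf] == gb1[inf] & ga2[inf] == gb2[inf])
  }, numeric(1))
}

#' Mendelian inheritance concordance across trios
#'
#' A trio is concordant at a gene iff the child's two alleles can be
#' assigned so that one is carried by the father and the other by the
#' mother. Trios with any Undetermined slot at that gene are excluded
#' from that gene's denominator.
#'
#' @param calls data.frame of genotype calls.
#' @param trios data.frame with columns father, mother, child
#'   (non-overlapping: each individual used once).
#' @return Named numeric vector: concordance per gene.
#' @export
mendelian_concordance <- function(calls, trios) {
  genes <- unique(calls$gene)
  key <- paste(calls$sample, calls$gene, sep = "\r")
  vapply(genes, function(g) {
    gi <- function(ids) {
      ix <- match(paste(ids, g, sep = "\r"), key)
      cbind(calls$allele1[ix], calls$allele2[ix])
    }
    Fg <- gi(trios$father); Mg <- gi(trios$mother); Cg <- gi(trios$child)
    inf <- stats::complete.cases(Fg) & stats::complete.cases(Mg) &
           stats::complete.cases(Cg)
    if (!any(inf)) return(NA_real_)
    conc <- vapply(which(inf), function(i) {
      c1 <- Cg[i, 1]; c2 <- Cg[i, 2]
      (c1 %in% Fg[i, ] && c2 %in% Mg[i, ]) ||
        (c2 %in% Fg[i, ] && c1 %in% Mg[i, ])
    }, logical(1))
    mean(conc)
  }, numeric(1))
}

#' Extract non-overlapping trios from a pedigree
#'
#' Greedy selection of (father, mother, child) triples in which each
#' individual appears at most once across all trios.
#'
#' @param pedigree data.frame with columns id, father, mother.
#' @return data.frame: father, mother, child.
#' @export
extract_trios <- function(pedigree) {
  used <- character(0)
  rows <- list()
  kids <- pedigree[!is.na(pedigree$father) & !is.na(pedigree$mother), ,
                   drop = FALSE]
  for (i in seq_len(nrow(kids))) {
    trio <- c(kids$father[i], kids$mother[i], kids$id[i])
    if (!any(trio %in% used)) {
      used <- c(used, trio)
      rows[[length(rows) + 1L]] <- data.frame(
        father = trio[1], mother = trio[2], child = trio[3],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(father = character(0), mother = character(0),
                      child = character(0)))
  do.call(rbind, rows)
}

#' Per-allele Hardy-Weinberg likelihood ratio test
#'
#' Each allele of a multi-allelic locus is tested independently by
#' collapsing the locus to "focal allele vs pooled others". With observed
#' genotype counts (homozygous carrier, heterozygous carrier,
#' non-carrier) and allele frequency estimate
#' p = (2 n_hom + n_het) / (2n), the statistic is the multinomial LRT
#' 2 * sum O * ln(O / E) against Hardy-Weinberg expectations
#' E = n * (p^2, 2pq, q^2), referred to chi-square with 1 df. Zero cells
#' contribute 0.
#'
#' @param counts Numeric length 3: (n_hom_carrier, n_het_carrier,
#'   n_noncarrier).
#' @param flag_alpha Flag threshold on the p-value (default 1e-6).
#' @return List: counts, p_hat, statistic, p_value, flagged.
#' @export
hwe_lrt <- function(counts, flag_alpha = 1e-6) {
  stopifnot(length(counts) == 3, all(counts >= 0), sum(counts) > 0)
  n <- sum(counts)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  E <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  terms <- ifelse(counts > 0, counts * log(counts / E), 0)
  stat <- 2 * sum(terms)
  pv <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(counts = unname(counts), p_hat = unname(p), statistic = unname(stat),
       p_value = unname(pv), flagged = pv < flag_alpha)
}

#' HWE screen of every HLA allele in a cohort
#'
#' Runs [hwe_lrt()] for each allele of each gene on an unrelated subset
#' of fully-called samples.
#'
#' @param calls Genotype calls data.frame.
#' @param samples Optional character vector restricting to an unrelated
#'   subset (see [unrelated_subset()]).
#' @param flag_alpha Flag threshold (default 1e-6).
#' @return data.frame: gene, allele, n_hom, n_het, n_noncarrier,
#'   statistic, p_value, flagged.
#' @export
hwe_screen <- function(calls, samples = NULL, flag_alpha = 1e-6) {
  if (!is.null(samples)) calls <- calls[calls$sample %in% samples, ,
                                        drop = FALSE]
  calls <- calls[!is.na(calls$allele1) & !is.na(calls$allele2), ,
                 drop = FALSE]
  out <- list()
  for (g in unique(calls$gene)) {
    cg <- calls[calls$gene == g, , drop = FALSE]
    for (a in sort(unique(c(cg$allele1, cg$allele2)))) {
      copies <- (cg$allele1 == a) + (cg$allele2 == a)
      cnt <- c(sum(copies == 2), sum(copies == 1), sum(copies == 0))
      h <- hwe_lrt(cnt, flag_alpha)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, allele = a, n_hom = cnt[1], n_het = cnt[2],
        n_noncarrier = cnt[3], statistic = h$statistic,
        p_value = h$p_value, flagged = h$flagged,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Compare cohort HLA carrier frequencies with a reference panel
#'
#' Carrier frequency = individuals carrying at least one copy / total
#' individuals (fully-called at the gene). Pearson r is the correlation
#' from a linear fit over alleles shared with the reference.
#'
#' @param calls Genotype calls data.frame.
#' @param reference_freqs Named numeric vector: allele -> reference
#'   carrier frequency.
#' @return List: `frequencies` (data.frame allele, cohort_freq,
#'   reference_freq) and `r` (Pearson correlation over shared alleles).
#' @export
compare_frequencies <- function(calls, reference_freqs) {
  calls <- calls[!is.na(calls$allele1) & !is.na(calls$allele2), ,
                 drop = FALSE]
  tab <- list()
  for (g in unique(calls$gene)) {
    cg <- calls[calls$gene == g, , drop = FALSE]
    n <- nrow(cg)
    for (a in sort(unique(c(cg$allele1, cg$allele2)))) {
      carrier <- cg$allele1 == a | cg$allele2 == a
      tab[[length(tab) + 1L]] <- data.frame(
        allele = a, cohort_freq = sum(carrier) / n,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, tab)
  tab$reference_freq <- reference_freqs[tab$allele]
  shared <- tab[!is.na(tab$reference_freq), , drop = FALSE]
  if (nrow(shared) < 2)
    stop("fewer than 2 alleles shared with the reference", call. = FALSE)
  r <- stats::cor(shared$cohort_freq, shared$reference_freq)
  list(frequencies = tab, r = unname(r))
}

#' Undetermined allele-slot rate
#'
#' Fraction of allele slots (2 per sample x gene) that are Undetermined;
#' a no-call counts as two Undetermined slots.
#'
#' @param calls Genotype calls data.frame.
#' @return Scalar fraction.
#' @export
undetermined_slot_rate <- function(calls) {
  mean(c(is.na(calls$allele1), is.na(calls$allele2)))
}

#' Genotype concordance with simulated truth
#'
#' @param calls Genotype calls data.frame.
#' @param diplotypes Truth array from [simulate_hla_haplotypes()].
#' @param exclude_undetermined Drop calls with any Undetermined slot from
#'   the denominator (default FALSE: they count as discordant).
#' @return Fraction of sample x gene genotypes identical to truth.
#' @export
truth_concordance <- function(calls, diplotypes,
                              exclude_undetermined = FALSE) {
  si <- match(calls$sample, dimnames(diplotypes)[[1]])
  gi <- match(calls$gene, dimnames(diplotypes)[[2]])
  t1 <- diplotypes[cbind(si, gi, 1L)]
  t2 <- diplotypes[cbind(si, gi, 2L)]
  tr <- t(apply(cbind(t1, t2), 1L, sort))
  if (exclude_undetermined) {
    keep <- !is.na(calls$allele1) & !is.na(calls$allele2)
    calls <- calls[keep, , drop = FALSE]; tr <- tr[keep, , drop = FALSE]
  }
  mean(!is.na(calls$allele1) & !is.na(calls$allele2) &
         calls$allele1 == tr[, 1] & calls$allele2 == tr[, 2])
}
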