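#' Simulate per-allele coverage profiles
#'
#' Emulates the per-allele mean read depth table produced by abundance
#' estimation over an HLA allele database. Each carried allele receives
#' depth centred on genome_mean_cov (homozygous) or genome_mean_cov / 2
#' (each heterozygous allele) with multiplicative lognormal noise of the
#' stated coefficient of variation. Non-carried alleles receive low
#' background coverage: exponential with mean 5% of the genome mean,
#' truncated just below the 20% calling threshold so background alone can
#' never create a call. With probability `dropout_rate` a sample's read
#' extraction fails at a locus: every allele at that sample x gene falls
#' to background, producing a no-call downstream (both allele slots
#' Undetermined).
#'
#' @param diplotypes individuals x genes x 2 array of allele codes
#'   (from [simulate_hla_haplotypes()]).
#' @param genome_mean_cov Genome-wide mean depth (> 0).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal depth noise (0 = deterministic depths).
#' @param dropout_rate Per sample x gene probability of locus dropout.
#' @param n_background Number of non-carried alleles per locus receiving
#'   background coverage rows.
#' @param seed Integer seed.
#' @return data.frame: sample, gene, allele, mean_coverage,
#'   genome_mean_coverage.
#' @export
simulate_coverage <- function(diplotypes, genome_mean_cov = 50,
                              noise_cv = 0.15, dropout_rate = 0,
                              n_background = 3L, seed = 1L) {
  stopifnot(genome_mean_cov > 0, noise_cv >= 0,
            dropout_rate >= 0, dropout_rate <= 1)
  set.seed(seed)
  ids <- dimnames(diplotypes)[[1]]
  genes <- dimnames(diplotypes)[[2]]
  thr <- 0.2 * genome_mean_cov
  sdlog <- sqrt(log(1 + noise_cv^2))
  noisy <- function(mu, k) {
    if (noise_cv == 0) rep(mu, k)
    else mu * stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  background <- function(k) pmin(stats::rexp(k, rate = 1 / (0.05 * genome_mean_cov)),
                                 0.95 * thr)
  o_sample <- o_gene <- o_allele <- vector("list",
                                           length(ids) * length(genes))
  o_cov <- o_sample
  z <- 0L
  for (g in seq_along(genes)) {
    gene_alleles <- unique(as.vector(diplotypes[, g, ]))
    for (i in seq_along(ids)) {
      a1 <- diplotypes[i, g, 1L]; a2 <- diplotypes[i, g, 2L]
      hom <- identical(a1, a2)
      carried <- if (hom) a1 else c(a1, a2)
      others <- setdiff(gene_alleles, carried)
      nb <- min(n_background, length(others))
      bg_alleles <- if (nb > 0) sample(others, nb) else character(0)
      dropped <- dropout_rate > 0 && stats::runif(1) < dropout_rate
      cov_carried <- if (dropped) background(length(carried))
                     else if (hom) noisy(genome_mean_cov, 1L)
                     else noisy(genome_mean_cov / 2, 2L)
      z <- z + 1L
      o_sample[[z]] <- rep(ids[i], length(carried) + nb)
      o_gene[[z]] <- rep(genes[g], length(carried) + nb)
      o_allele[[z]] <- c(carried, bg_alleles)
      o_cov[[z]] <- c(cov_carried, background(nb))
    }
  }
  data.frame(sample = unlist(o_sample), gene = unlist(o_gene),
             allele = unlist(o_allele), mean_coverage = unlist(o_cov),
             genome_mean_coverage = genome_mean_cov,
             stringsAsFactors = FALSE)
}
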