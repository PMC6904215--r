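#' Simulate expression with planted cis effects and a kinship component
#'
#' Generates y = Xc gamma + sum(g beta_true) + u + e per feature, with
#' u ~ MVN(0, sigma_g^2 K) and e ~ N(0, sigma_e^2 I). Predictors named in
#' `effects` may be SNP ids (rows of `snp_geno`, dosage 0/1/2) or HLA
#' allele codes (dosage 0/0.5/1 derived from the true diplotypes). Also
#' emits an allelic-imbalance fraction (AIF) table for the features with
#' planted effects: AIF is drawn from a Beta rescaled to [0.5, 1],
#' shifted upward for samples heterozygous at the causal predictor.
#'
#' @param features Character vector of feature (gene) names.
#' @param diplotypes Individuals x genes x 2 allele-code array (may be
#'   NULL if no HLA-type effects are planted).
#' @param snp_geno Variants x individuals dosage matrix (may be NULL).
#' @param kinship Kinship matrix (samples in simulation order).
#' @param effects data.frame(feature, predictor, beta); empty for a
#'   global null.
#' @param sigma_g Genetic (kinship) variance component.
#' @param sigma_e Residual variance component.
#' @param covariates Optional samples x q design whose effects
#'   (gamma ~ N(0, 0.25)) are added.
#' @param aif_beta_het,aif_beta_hom Beta shape pairs for the AIF draw in
#'   eQTL-heterozygous and other samples.
#' @param seed Integer seed.
#' @return List: `expression` (features x samples), `aif` (data.frame
#'   sample, feature, aif, eqtl_het), `truth` (effects, gamma,
#'   variance components, seed).
#' @export
simulate_expression <- function(features, diplotypes = NULL,
                                snp_geno = NULL, kinship,
                                effects = NULL, sigma_g = 0.3,
                                sigma_e = 0.7, covariates = NULL,
                                aif_beta_het = c(2.5, 5),
                                aif_beta_hom = c(1.5, 6), seed = 1L) {
  stopifnot(sigma_g >= 0, sigma_e >= 0)
  set.seed(seed)
  ids <- rownames(kinship)
  n <- length(ids)
  predictor_dosage <- function(pr) {
    if (!is.null(snp_geno) && pr %in% rownames(snp_geno))
      return(snp_geno[pr, ids])
    if (!is.null(diplotypes)) {
      gn <- sub("\\*.*$", "", pr)
      if (gn %in% dimnames(diplotypes)[[2]]) {
        return(((diplotypes[ids, gn, 1] == pr) +
                  (diplotypes[ids, gn, 2] == pr)) / 2)
      }
    }
    stop("effect refers to unknown predictor: ", pr, call. = FALSE)
  }
  if (!is.null(effects) && nrow(effects) > 0 &&
      !all(effects$feature %in% features))
    stop("effect refers to unknown feature", call. = FALSE)
  L <- if (sigma_g > 0) chol(sigma_g * kinship + 1e-8 * diag(n)) else NULL
  gamma <- if (is.null(covariates)) NULL
           else stats::rnorm(ncol(covariates), 0, 0.5)
  Y <- matrix(0, length(features), n, dimnames = list(features, ids))
  for (f in seq_along(features)) {
    y <- stats::rnorm(n, 0, sqrt(sigma_e))
    if (!is.null(L)) y <- y + drop(crossprod(L, stats::rnorm(n)))
    if (!is.null(covariates)) y <- y + drop(covariates %*% gamma)
    Y[f, ] <- y
  }
  het <- matrix(FALSE, length(features), n,
                dimnames = list(features, ids))
  if (!is.null(effects) && nrow(effects) > 0) {
    for (r in seq_len(nrow(effects))) {
      g <- predictor_dosage(effects$predictor[r])
      Y[effects$feature[r], ] <- Y[effects$feature[r], ] +
        effects$beta[r] * g
      mx <- max(g, na.rm = TRUE)
      het[effects$feature[r], ] <- het[effects$feature[r], ] |
        (!is.na(g) & g > 0 & g < mx)
    }
  }
  aif <- NULL
  if (!is.null(effects) && nrow(effects) > 0) {
    af <- unique(effects$feature)
    aif <- do.call(rbind, lapply(af, function(f) {
      hz <- het[f, ]
      v <- numeric(n)
      v[hz] <- 0.5 + 0.5 * stats::rbeta(sum(hz), aif_beta_het[1],
                                        aif_beta_het[2])
      v[!hz] <- 0.5 + 0.5 * stats::rbeta(sum(!hz), aif_beta_hom[1],
                                         aif_beta_hom[2])
      data.frame(sample = ids, feature = f, aif = v, eqtl_het = hz,
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }
  list(expression = Y, aif = aif,
       truth = list(effects = effects, gamma = gamma, sigma_g = sigma_g,
                    sigma_e = sigma_e, seed = seed))
}

# founder SNP haplotypes regenerated from a stored tagging scheme
draw_founder_snp_haps <- function(truth, n_hap) {
  freqs <- truth$allele_freqs
  n_genes <- ncol(freqs)
  gene_hap <- vapply(seq_len(n_genes), function(g)
    sample.int(nrow(freqs), n_hap, replace = TRUE, prob = freqs[, g]),
    integer(n_hap))
  m <- length(truth$tagset)
  H <- matrix(0L, m, n_hap)
  for (j in seq_len(m))
    H[j, ] <- as.integer(gene_hap[, truth$gene_of_snp[j]] %in%
                           truth$tagset[[j]])
  H
}

#' Simulate GWAS summary statistics on an independent cohort
#'
#' Draws `n_gwas` unrelated individuals from the same founder haplotype
#' structure (allele frequencies and SNP tagging scheme) as an existing
#' simulation, generates a quantitative trait with SNP heritability
#' `h2_snp` attributed to one causal variant (shared with the eQTL locus
#' or an independent one), and returns marginal per-variant summary
#' statistics.
#'
#' @param sim Output of [simulate_hla_haplotypes()] (its `truth` and
#'   `variants` are used).
#' @param shared_causal,independent_causal At most one: variant id (row
#'   of `sim$snp_geno`) that is causal for the trait. Both NULL gives a
#'   null trait.
#' @param n_gwas GWAS cohort size.
#' @param h2_snp Variance fraction explained by the causal variant.
#' @param seed Integer seed.
#' @return data.frame: variant, beta, se, n.
#' @export
simulate_gwas <- function(sim, shared_causal = NULL,
                          independent_causal = NULL, n_gwas = 5000L,
                          h2_snp = 0, seed = 1L) {
  if (!is.null(shared_causal) && !is.null(independent_causal))
    stop("at most one of shared_causal / independent_causal",
         call. = FALSE)
  stopifnot(n_gwas > 0, h2_snp >= 0, h2_snp < 1)
  set.seed(seed)
  H1 <- draw_founder_snp_haps(sim$truth, n_gwas)
  H2 <- draw_founder_snp_haps(sim$truth, n_gwas)
  G <- H1 + H2
  rownames(G) <- sim$variants$id
  causal <- c(shared_causal, independent_causal)
  y <- stats::rnorm(n_gwas)
  if (length(causal) == 1 && h2_snp > 0) {
    g <- G[causal, ]
    vg <- stats::var(g)
    if (vg == 0) stop("causal variant is monomorphic in the GWAS cohort",
                      call. = FALSE)
    b <- sqrt(h2_snp / ((1 - h2_snp) * vg))
    y <- y + b * g
  }
  Gc <- G - rowMeans(G)
  yc <- y - mean(y)
  sxx <- rowSums(Gc^2)
  beta <- as.vector(Gc %*% yc) / sxx
  rss <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(rss / (n_gwas - 2) / sxx)
  mono <- sxx == 0
  beta[mono] <- NA; se[mono] <- NA
  data.frame(variant = sim$variants$id, beta = beta, se = se,
             n = n_gwas, row.names = NULL, stringsAsFactors = FALSE)
}
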