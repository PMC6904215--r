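#' Wakefield log approximate Bayes factor
#'
#' For a single variant with estimated effect `beta`, standard error
#' `se` (V = se^2) and prior effect variance `W`, the log ABF is
#' 0.5 log(V / (V + W)) + 0.5 z^2 W / (V + W) with z = beta / se.
#' W = 0 gives log ABF = 0 (no prior mass on an effect).
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s) (> 0).
#' @param W Prior effect variance (default 0.15^2, quantitative traits).
#' @return Log approximate Bayes factor(s).
#' @export
wakefield_labf <- function(beta, se, W = 0.15^2) {
  if (any(se <= 0, na.rm = TRUE)) stop("se must be > 0", call. = FALSE)
  stopifnot(W >= 0)
  V <- se^2
  z2 <- (beta / se)^2
  0.5 * log(V / (V + W)) + 0.5 * z2 * W / (V + W)
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b
logdiffexp <- function(a, b) {
  if (b > a + 1e-12) stop("logdiffexp: negative difference", call. = FALSE)
  if (!is.finite(a)) return(-Inf)
  d <- 1 - exp(b - a)
  if (d <= 0) return(-Inf)
  a + log(d)
}

#' Five-hypothesis colocalization from summary statistics
#'
#' Assembles per-variant Wakefield log ABFs for two traits and computes
#' posterior probabilities for the five single-causal-variant
#' hypotheses: H0 no association in either trait; H1 association only in
#' trait 1; H2 only in trait 2; H3 both traits, different causal
#' variants; H4 both traits, one shared causal variant. H3 is computed
#' in log space via the identity sum-over-distinct-pairs =
#' sum1 * sum2 - sum12. The five posteriors sum to one.
#'
#' @param stats1,stats2 data.frames with columns variant (or id), beta,
#'   se; intersected on variant id.
#' @param p1,p2 Prior probability a variant is causal for trait 1 / 2
#'   (default 1e-4).
#' @param p12 Prior probability a variant is causal for both (default
#'   1e-5).
#' @param W Prior effect variance for the ABFs (default 0.15^2).
#' @return List: pp (named numeric H0..H4, sums to 1), n_variants,
#'   flags pp_h4_gt_0.2 / pp_h4_gt_0.8.
#' @export
coloc_ppa <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      W = 0.15^2) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1)
  idcol <- function(d) if ("variant" %in% names(d)) d$variant else d$id
  v1 <- idcol(stats1); v2 <- idcol(stats2)
  keep1 <- !is.na(stats1$beta) & !is.na(stats1$se)
  keep2 <- !is.na(stats2$beta) & !is.na(stats2$se)
  shared <- intersect(v1[keep1], v2[keep2])
  if (length(shared) < 2) {
    warning("fewer than 2 shared variants; colocalization skipped")
    return(NULL)
  }
  i1 <- match(shared, v1); i2 <- match(shared, v2)
  l1 <- wakefield_labf(stats1$beta[i1], stats1$se[i1], W)
  l2 <- wakefield_labf(stats2$beta[i2], stats2$se[i2], W)
  s1 <- logsumexp(l1)          # log sum_i ABF1_i
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)    # log sum_i ABF1_i ABF2_i
  lh <- c(H0 = 0,
          H1 = log(p1) + s1,
          H2 = log(p2) + s2,
          H3 = log(p1) + log(p2) + logdiffexp(s1 + s2, s12),
          H4 = log(p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  list(pp = pp, n_variants = length(shared),
       pp_h4_gt_0.2 = unname(pp["H4"] > 0.2),
       pp_h4_gt_0.8 = unname(pp["H4"] > 0.8))
}
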