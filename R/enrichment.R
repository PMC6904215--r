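#' Assign chromatin states to variant positions
#'
#' Maps each variant's single base position onto half-open 0-based BED
#' intervals (non-overlapping within an annotation set). Positions
#' outside every interval are labeled "unannotated".
#'
#' @param variants data.frame with chrom, pos (1-based), id.
#' @param bed data.frame with chrom, start, end, state (BED
#'   half-open).
#' @return Named character vector: variant id -> state.
#' @export
annotate_variants <- function(variants, bed) {
  out <- stats::setNames(rep("unannotated", nrow(variants)), variants$id)
  for (ch in unique(variants$chrom)) {
    b <- bed[bed$chrom == ch, , drop = FALSE]
    if (nrow(b) == 0) next
    b <- b[order(b$start), , drop = FALSE]
    vi <- which(variants$chrom == ch)
    p0 <- variants$pos[vi] - 1L  # 0-based position
    ix <- findInterval(p0, b$start)
    hit <- ix > 0 & p0 < b$end[pmax(ix, 1L)]
    out[vi[hit]] <- b$state[ix[hit]]
  }
  out
}

#' Effect-size decile assignment
#'
#' Ranks all tested (feature, predictor) pairs by absolute effect size
#' (ties broken by predictor id, then feature) and splits them into 10
#' equal-count bins; bin 10 holds the largest effects. Bin sizes differ
#' by at most 1.
#'
#' @param assoc data.frame with feature, predictor, beta (untested NA
#'   rows are dropped).
#' @return `assoc` (tested rows) with a `decile` column.
#' @export
effect_size_deciles <- function(assoc) {
  assoc <- assoc[!is.na(assoc$beta), , drop = FALSE]
  n <- nrow(assoc)
  if (n < 10) stop("need >= 10 tested pairs", call. = FALSE)
  ord <- order(abs(assoc$beta), assoc$predictor, assoc$feature,
               method = "radix")
  dec <- integer(n)
  dec[ord] <- ceiling(seq_len(n) * 10 / n)
  assoc$decile <- dec
  assoc
}

#' Effect-size-decile by chromatin-state enrichment matrix
#'
#' Counts pairs in each (decile, state) cell, adds a pseudo-count,
#' divides each state column by its mean across deciles, and
#' log2-transforms, yielding enrichments centered around zero. The
#' "unannotated" state is excluded from the matrix.
#'
#' @param deciles Output of [effect_size_deciles()].
#' @param states Named character vector variant id -> state (from
#'   [annotate_variants()]).
#' @param pseudo Pseudo-count added to each cell (default 1; 0
#'   reproduces the bare normalization identity when no cell is empty).
#' @return 10 x n_states matrix of log2 enrichments.
#' @export
enrichment_matrix <- function(deciles, states, pseudo = 1) {
  st <- states[deciles$predictor]
  keep <- !is.na(st) & st != "unannotated"
  tab <- table(factor(deciles$decile[keep], levels = 1:10),
               factor(st[keep]))
  M <- matrix(as.numeric(tab), nrow = 10,
              dimnames = list(1:10, colnames(tab))) + pseudo
  M <- sweep(M, 2, colMeans(M), "/")
  log2(M)
}

#' Mann-Whitney comparison of two allelic-imbalance groups
#'
#' U statistic for `group_a` with a two-sided p-value: exact enumeration
#' over all assignments when the combined sample size is <= 12 (valid
#' under ties), tie-corrected normal approximation otherwise.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each, AIF or any
#'   ordinal score).
#' @param exact_max Combined size at or below which enumeration is used
#'   (default 12).
#' @return List: U, p_value, method.
#' @export
aif_comparison <- function(group_a, group_b, exact_max = 12L) {
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 2 || n2 < 2) {
    warning("group with < 2 values; comparison skipped")
    return(list(U = NA_real_, p_value = NA_real_, method = "skipped"))
  }
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    Us <- apply(combos, 2, function(ix)
      sum(r[ix]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p_value = p, method = "exact"))
  }
  N <- n1 + n2
  ties <- table(pooled)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- max(abs(U - mu) - 0.5, 0) / sqrt(sig2)  # continuity-corrected
  list(U = U, p_value = 2 * stats::pnorm(-z), method = "normal")
}

#' Pairwise coexpression coefficient
#'
#' Coefficient of e_j from the least-squares fit
#' e_i ~ e_j + covariates (intercept included); the beta is the
#' coexpression measure.
#'
#' @param e_i,e_j Expression vectors (aligned samples).
#' @param design Optional samples x q covariate matrix.
#' @return Scalar beta (NA on collinearity).
#' @export
coexpression_beta <- function(e_i, e_j, design = NULL) {
  X <- cbind(1, e_j, design)
  fit <- stats::lm.fit(X, e_i)
  if (fit$rank < ncol(X)) return(NA_real_)
  unname(fit$coefficients[2])
}

#' Full coexpression beta matrix
#'
#' @param Y Genes x samples expression matrix.
#' @param design Optional covariate matrix.
#' @return Genes x genes matrix of coexpression betas (diagonal 1).
#' @export
coexpression_matrix <- function(Y, design = NULL) {
  g <- rownames(Y)
  B <- matrix(NA_real_, nrow(Y), nrow(Y), dimnames = list(g, g))
  for (i in seq_along(g)) for (j in seq_along(g))
    B[i, j] <- if (i == j) 1 else coexpression_beta(Y[i, ], Y[j, ], design)
  B
}
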