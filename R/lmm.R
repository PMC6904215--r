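#' Rank-based inverse normal transform
#'
#' Maps a vector to normal scores Phi^-1((rank - 0.5) / n), with average
#' ranks for ties; monotone in the input and invariant to permutation of
#' samples. All-identical input returns zeros with a warning.
#'
#' @param x Numeric vector (>= 3 non-missing values).
#' @return Numeric vector of normal scores (NA preserved).
#' @export
quantile_normalize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 3) stop("need >= 3 non-missing values", call. = FALSE)
  if (stats::var(x[ok]) == 0) {
    warning("all values identical; returning zeros")
    x[ok] <- 0
    return(x)
  }
  n <- sum(ok)
  x[ok] <- stats::qnorm((rank(x[ok], ties.method = "average") - 0.5) / n)
  x
}

#' Regress covariates out of an expression vector
#'
#' Least-squares residual of y on the covariate design (intercept always
#' included). Residuals are orthogonal to every covariate column.
#'
#' @param y Numeric vector.
#' @param design Numeric matrix samples x covariates (may be NULL for
#'   centering only).
#' @return Residual vector.
#' @export
adjust_covariates <- function(y, design = NULL) {
  X <- cbind(`(intercept)` = rep(1, length(y)), design)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  qr.resid(qr_x, y)
}

#' Eigendecomposition of a kinship matrix
#'
#' Validates symmetry and positive semi-definiteness (tolerating ridge
#' 1e-6 below zero) and returns the spectral decomposition reused by
#' every mixed-model fit.
#'
#' @param K Symmetric kinship matrix.
#' @return List: `U` (eigenvectors), `d` (eigenvalues, clamped at 0),
#'   `ids` (dimnames).
#' @export
kinship_eigen <- function(K) {
  if (!isSymmetric(unname(K), tol = 1e-8))
    stop("kinship matrix must be symmetric", call. = FALSE)
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values), 1))
    stop("kinship matrix is not positive semi-definite", call. = FALSE)
  list(U = e$vectors, d = pmax(e$values, 0), ids = rownames(K))
}

is_kinship_eigen <- function(x) is.list(x) && all(c("U", "d") %in% names(x))

# Restricted log-likelihood (up to a constant) at variance ratio
# lambda = sigma_g^2 / sigma_e^2, on rotated data.
reml_ll <- function(log_lambda, yt, Xt, d) {
  lambda <- exp(log_lambda)
  w <- 1 / (lambda * d + 1)
  Xw <- Xt * w
  A <- crossprod(Xw, Xt)
  beta <- solve(A, crossprod(Xw, yt))
  r <- yt - Xt %*% beta
  n <- length(yt); p <- ncol(Xt)
  s2 <- sum(w * r^2) / (n - p)
  -0.5 * ((n - p) * log(s2) + sum(log(lambda * d + 1)) +
            determinant(A, logarithm = TRUE)$modulus[1])
}

#' REML variance components of the kinship null model
#'
#' Fits y = X b + u + e with u ~ N(0, sigma_g^2 K) and
#' e ~ N(0, sigma_e^2 I) by a one-dimensional REML search over the
#' variance ratio on the eigenbasis of K (X defaults to the intercept).
#' With K = I the two components are not separately identifiable; the
#' total variance is still estimated correctly and association results
#' reduce to ordinary least squares.
#'
#' @param y Numeric response (typically covariate-adjusted normalized
#'   expression).
#' @param K Kinship matrix or a [kinship_eigen()] object.
#' @param X Optional fixed-effect design (samples x p); intercept added.
#' @return List: sigma_g, sigma_e, h2, lambda.
#' @export
fit_null_lmm <- function(y, K, X = NULL) {
  eig <- if (is_kinship_eigen(K)) K else kinship_eigen(K)
  stopifnot(length(y) == length(eig$d))
  Xf <- cbind(rep(1, length(y)), X)
  yt <- drop(crossprod(eig$U, y))
  Xt <- crossprod(eig$U, Xf)
  opt <- stats::optimize(reml_ll, interval = c(-18, 18), yt = yt, Xt = Xt,
                         d = eig$d, maximum = TRUE, tol = 1e-6)
  # guard against boundary optima
  cand <- rbind(c(opt$maximum, opt$objective),
                c(-18, reml_ll(-18, yt, Xt, eig$d)),
                c(18, reml_ll(18, yt, Xt, eig$d)))
  best <- cand[which.max(cand[, 2]), 1]
  lambda <- exp(best)
  if (best <= -17.9) lambda <- 0
  w <- 1 / (lambda * eig$d + 1)
  Xw <- Xt * w
  beta <- solve(crossprod(Xw, Xt), crossprod(Xw, yt))
  r <- yt - Xt %*% beta
  s2 <- sum(w * r^2) / (length(y) - ncol(Xt))
  sigma_e <- s2
  sigma_g <- lambda * s2
  list(sigma_g = sigma_g, sigma_e = sigma_e,
       h2 = if (sigma_g + sigma_e > 0) sigma_g / (sigma_g + sigma_e) else 0,
       lambda = lambda)
}

# Weighted (rotated) association of yt on Xt whose LAST column is the
# predictor. Residual scale is re-profiled per model so that with K = I
# results coincide with ordinary least squares.
wls_assoc <- function(yt, Xt, w, df_test = c("normal", "t")) {
  df_test <- match.arg(df_test)
  n <- length(yt); p <- ncol(Xt)
  Xw <- Xt * w
  A <- crossprod(Xw, Xt)
  Ai <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ai)) return(c(beta = NA, se = NA, p = NA))
  beta <- Ai %*% crossprod(Xw, yt)
  r <- yt - Xt %*% beta
  s2 <- sum(w * r^2) / (n - p)
  se <- sqrt(s2 * diag(Ai))
  z <- beta[p] / se[p]
  pv <- if (df_test == "normal") 2 * stats::pnorm(-abs(z))
        else 2 * stats::pt(-abs(z), df = n - p)
  c(beta = unname(beta[p]), se = unname(se[p]), p = unname(pv))
}

#' Kinship-aware single-predictor association
#'
#' Generalized least squares of y on (intercept, covariates, g) under
#' Sigma = sigma_g^2 K + sigma_e^2 I, with the variance ratio taken from
#' a previously fitted null model (population parameters previously
#' determined) and the residual scale re-profiled per model. Two-sided
#' Wald p-value against the standard normal by default.
#'
#' @param y Response vector.
#' @param g Predictor dosage vector (missing values mean-imputed).
#' @param K Kinship matrix or [kinship_eigen()] object.
#' @param vc Variance components from [fit_null_lmm()] (fitted on the fly
#'   if NULL).
#' @param covariates Optional samples x q matrix of fixed covariates
#'   (e.g. conditioning dosages).
#' @param df_test "normal" (default) or "t" reference for the Wald test.
#' @return Named numeric: beta, se, p (NA if g is monomorphic).
#' @export
lmm_association <- function(y, g, K, vc = NULL, covariates = NULL,
                            df_test = "normal") {
  eig <- if (is_kinship_eigen(K)) K else kinship_eigen(K)
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  if (stats::var(g) == 0) return(c(beta = NA, se = NA, p = NA))
  if (is.null(vc)) vc <- fit_null_lmm(y, eig, X = covariates)
  w <- 1 / (vc$lambda * eig$d + 1)
  X <- cbind(rep(1, length(y)), covariates, g)
  wls_assoc(drop(crossprod(eig$U, y)), crossprod(eig$U, X), w, df_test)
}

#' Mixed-model association scan over features and predictors
#'
#' Runs [lmm_association()] for every feature (row of `Y`) against every
#' predictor (row of `G`), reusing one eigendecomposition and one null
#' variance-component fit per feature. Conditioning dosages (global
#' matrix or per-feature list) enter the fixed effects and the null
#' model; conditioning predictors themselves, and predictors collinear
#' with the conditioning set, are reported untested (NA).
#'
#' @param Y Features x samples matrix (covariate-adjusted, normalized).
#' @param G Predictors x samples dosage matrix.
#' @param K Kinship matrix or [kinship_eigen()] object.
#' @param conditioning NULL, a predictors x samples matrix applied to all
#'   features, or a named list (feature -> matrix of conditioning rows).
#' @param exclude Named list (feature -> predictor ids) of predictors to
#'   skip, in addition to conditioning predictors named in rownames.
#' @param df_test Wald reference, "normal" or "t".
#' @return data.frame: feature, predictor, beta, se, p.
#' @export
lmm_scan <- function(Y, G, K, conditioning = NULL, exclude = NULL,
                     df_test = "normal") {
  eig <- if (is_kinship_eigen(K)) K else kinship_eigen(K)
  n <- ncol(Y)
  stopifnot(ncol(G) == n, length(eig$d) == n)
  G <- as.matrix(G)
  # mean-impute missing dosages once
  if (anyNA(G)) {
    for (j in which(rowSums(is.na(G)) > 0)) {
      m <- mean(G[j, ], na.rm = TRUE)
      G[j, is.na(G[j, ])] <- m
    }
  }
  Gt <- tcrossprod(G, t(eig$U))          # G %*% U, rows rotated
  ones_t <- drop(crossprod(eig$U, rep(1, n)))
  feats <- rownames(Y); preds <- rownames(G)
  res <- vector("list", length(feats))
  for (f in seq_along(feats)) {
    cond <- conditioning
    if (is.list(cond) && !is.null(names(cond))) cond <- cond[[feats[f]]]
    cond <- if (is.null(cond)) NULL else as.matrix(cond)
    if (!is.null(cond) && nrow(cond) == 0) cond <- NULL
    skip <- character(0)
    if (!is.null(cond)) skip <- rownames(cond)
    if (!is.null(exclude)) skip <- c(skip, exclude[[feats[f]]])
    y <- Y[f, ]
    Xcov <- if (is.null(cond)) NULL else t(cond)
    vc <- fit_null_lmm(y, eig, X = Xcov)
    w <- 1 / (vc$lambda * eig$d + 1)
    yt <- drop(crossprod(eig$U, y))
    Ct <- if (is.null(cond)) NULL else crossprod(eig$U, t(cond))
    # collinearity of predictors with the conditioning set
    resid_space <- function(gv) {
      if (is.null(cond)) return(stats::var(gv) > 0)
      r <- stats::lm.fit(cbind(1, t(cond)), gv)$residuals
      mean(r^2) > 1e-10 * max(stats::var(gv), 1e-12)
    }
    out <- matrix(NA_real_, length(preds), 3,
                  dimnames = list(preds, c("beta", "se", "p")))
    for (j in seq_along(preds)) {
      if (preds[j] %in% skip) next
      gv <- G[j, ]
      if (stats::var(gv) == 0 || !resid_space(gv)) next
      Xt <- cbind(ones_t, Ct, Gt[j, ])
      out[j, ] <- wls_assoc(yt, Xt, w, df_test)
    }
    res[[f]] <- data.frame(feature = feats[f], predictor = preds,
                           beta = out[, 1], se = out[, 2], p = out[, 3],
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Three-step hierarchical multiple-testing correction
#'
#' Step 1: per feature, nominal p-values are Bonferroni-adjusted for the
#' number of local tests (`m_local`, defaulting to the number of
#' predictors actually tested for that feature); the predictor with the
#' smallest adjusted p is the lead (ties broken by genomic position,
#' then predictor id). Step 2: lead adjusted p-values are BH-corrected
#' across features with a fixed denominator `n_genomewide`
#' (the genome-wide expressed-gene count); features below `bh_alpha` are
#' eGenes. Step 3: for each eGene, every predictor with locally adjusted
#' p < `local_alpha` is reported as a QTL.
#'
#' @param assoc data.frame from [lmm_scan()] (feature, predictor, beta,
#'   se, p).
#' @param positions Optional named vector predictor -> genomic position
#'   for lead tie-breaking.
#' @param m_local Fixed local Bonferroni factor (NULL = per-feature count
#'   of tested predictors).
#' @param n_genomewide BH denominator across features (default 20595).
#' @param bh_alpha eGene threshold on the BH-adjusted lead p (default
#'   0.05).
#' @param local_alpha QTL threshold on the locally adjusted p within
#'   eGenes (default 0.1).
#' @param stage Stage label stored on the results (e.g. "primary",
#'   "conditional1").
#' @return List: `results` (assoc + p_local, lead, stage), `leads`
#'   (per-feature lead with p_bh), `egenes` (character), `qtls`
#'   (significant rows for eGenes).
#' @export
hierarchical_correction <- function(assoc, positions = NULL,
                                    m_local = NULL, n_genomewide = 20595,
                                    bh_alpha = 0.05, local_alpha = 0.1,
                                    stage = "primary") {
  if (nrow(assoc) == 0)
    return(list(results = assoc, leads = assoc[0, ], egenes = character(0),
                qtls = assoc[0, ]))
  assoc$p_local <- NA_real_
  assoc$lead <- FALSE
  for (f in unique(assoc$feature)) {
    ix <- which(assoc$feature == f)
    tested <- ix[!is.na(assoc$p[ix])]
    if (length(tested) == 0) next
    m <- if (is.null(m_local)) length(tested) else m_local
    assoc$p_local[tested] <- pmin(1, assoc$p[tested] * m)
    pos <- if (is.null(positions)) rep(0, length(tested))
           else positions[assoc$predictor[tested]]
    lead <- tested[order(assoc$p_local[tested], pos,
                         assoc$predictor[tested], method = "radix")[1]]
    assoc$lead[lead] <- TRUE
  }
  assoc$stage <- stage
  leads <- assoc[assoc$lead, , drop = FALSE]
  leads$p_bh <- stats::p.adjust(leads$p_local, method = "BH",
                                n = max(n_genomewide, nrow(leads)))
  egenes <- leads$feature[!is.na(leads$p_bh) & leads$p_bh < bh_alpha]
  qtls <- assoc[assoc$feature %in% egenes & !is.na(assoc$p_local) &
                  assoc$p_local < local_alpha, , drop = FALSE]
  list(results = assoc, leads = leads, egenes = egenes, qtls = qtls)
}

#' Conditional association scan
#'
#' Re-runs the scan for the given features with the accumulated lead
#' dosages as fixed covariates (the conditioning predictors themselves
#' are excluded), then applies the same hierarchical correction.
#'
#' @param Y,G,K As in [lmm_scan()].
#' @param leads Named list feature -> character vector of conditioning
#'   predictor ids (rows of `G`), e.g. the lead eQTL(s) from previous
#'   stages.
#' @param stage Stage label (e.g. "conditional1").
#' @param ... Passed to [hierarchical_correction()].
#' @return As [hierarchical_correction()].
#' @export
conditional_scan <- function(Y, G, K, leads, stage = "conditional1", ...) {
  feats <- intersect(rownames(Y), names(leads))
  cond <- lapply(leads[feats], function(ids)
    G[ids, , drop = FALSE])
  out <- lmm_scan(Y[feats, , drop = FALSE], G, K, conditioning = cond)
  hierarchical_correction(out, stage = stage, ...)
}
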