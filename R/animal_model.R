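#' Precompute the eigendecomposition of a relatedness matrix
#'
#' The animal-model likelihood for any trait measured on the same plants can
#' be profiled after a single eigendecomposition of the relatedness matrix,
#' which rotates the model to independent observations. Do this once per
#' study and pass the result to [fit_lmm()] for every gene.
#'
#' @param K symmetric positive semi-definite relatedness matrix.
#' @return object of class `kinship_eigen` with `values`, `vectors`, `n`.
#' @export
eigen_kinship <- function(K) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (anyNA(K)) stop("relatedness matrix contains missing entries")
  e <- eigen(K, symmetric = TRUE)
  e$values[e$values < 0] <- 0
  structure(list(values = e$values, vectors = e$vectors, n = nrow(K)),
            class = "kinship_eigen")
}

#' Fit the animal model by maximum likelihood
#'
#' Fits `y = X b + g + e` with `g ~ N(0, Vg K)` and `e ~ N(0, Ve I)` by full
#' maximum likelihood (not REML). After rotating by the eigenvectors of `K`
#' the covariance is diagonal in the mixing proportion `s = Vg / (Vg + Ve)`,
#' so the profile likelihood is maximised by a one-dimensional search with
#' generalized-least-squares fixed effects at each `s`. Standard errors come
#' from the GLS information matrix at the optimum. A boundary solution
#' `Vg = 0` is reported as such, never hidden.
#'
#' @param y phenotype vector.
#' @param X fixed-effect design matrix (with intercept).
#' @param K a relatedness matrix or a [eigen_kinship()] object.
#' @return object of class `lmm_fit`: `Vg`, `Ve`, `loglik`, `beta`, `se`,
#'   `s` (variance ratio), `boundary`, `n`, `df_fixed`.
#' @export
fit_lmm <- function(y, X, K) {
  if (!inherits(K, "kinship_eigen")) K <- eigen_kinship(unclass(K))
  n <- length(y)
  stopifnot(nrow(X) == n, K$n == n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed-effect design is singular; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  U <- K$vectors; d <- K$values
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  prof <- function(s) {
    w <- s * d + (1 - s)            # eigenvalues of s*K + (1-s)*I
    sw <- 1 / sqrt(w)
    fit <- stats::lm.fit(Xs * sw, ys * sw)
    rss <- sum(fit$residuals^2)
    vp <- rss / n                   # ML profile estimate of Vg + Ve scale
    ll <- -0.5 * (n * log(2 * pi) + n * log(vp) + sum(log(w)) + n)
    list(ll = ll, vp = vp, fit = fit, w = w)
  }
  opt <- stats::optimize(function(s) -prof(s)$ll, c(0, 1 - 1e-8),
                         tol = 1e-9)
  s_hat <- opt$minimum
  # guard the boundary: optimize() cannot return exactly 0
  cand <- prof(s_hat)
  at0 <- prof(0)
  if (at0$ll >= cand$ll) { s_hat <- 0; cand <- at0 }
  vp <- cand$vp
  Vg <- s_hat * vp; Ve <- (1 - s_hat) * vp
  beta <- cand$fit$coefficients
  XtWX <- crossprod(Xs / sqrt(cand$w))
  covb <- vp * solve(XtWX)
  se <- sqrt(diag(covb))
  names(beta) <- names(se) <- colnames(X)
  structure(list(Vg = Vg, Ve = Ve, loglik = cand$ll, beta = beta, se = se,
                 cov_beta = covb, s = s_hat, boundary = s_hat == 0,
                 n = n, df_fixed = ncol(X)),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Animal model ML fit (n = %d): Vg = %.4f, Ve = %.4f, logLik = %.3f%s\n",
              x$n, x$Vg, x$Ve, x$loglik,
              if (x$boundary) " [Vg at boundary 0]" else ""))
  invisible(x)
}

#' Per-family additive dose design columns
#'
#' Builds one column per alternative line z holding the dose (0/1/2) of the
#' line-z allele for plants of family z and zero elsewhere. Reference-line
#' parental plants (family 0) carry dose 0 everywhere; alternative parental
#' plants enter their own family block at dose 2.
#'
#' @param dose alternative-allele dose per plant at the locus.
#' @param family family label per plant (0 = reference parentals).
#' @param n_lines number of founder lines.
#' @param reference_line reference line index.
#' @return matrix with columns `a_line<z>`.
#' @export
family_dose_design <- function(dose, family, n_lines, reference_line = 1) {
  alt <- setdiff(seq_len(n_lines), reference_line)
  X <- sapply(alt, function(z) ifelse(family == z, dose, 0))
  colnames(X) <- paste0("a_line", alt)
  X
}

#' Per-family dominance (heterozygote indicator) design columns
#'
#' @inheritParams family_dose_design
#' @return matrix with columns `d_line<z>`.
#' @export
family_het_design <- function(dose, family, n_lines, reference_line = 1) {
  alt <- setdiff(seq_len(n_lines), reference_line)
  X <- sapply(alt, function(z) as.numeric(family == z & dose == 1L))
  colnames(X) <- paste0("d_line", alt)
  X
}

#' Cis eQTL tests for one gene
#'
#' Fits the nested model sequence: Model 0 (cohort fixed effects, genetic
#' random effect over the relatedness matrix), Model 1 (adds one additive cis
#' effect per family: the phenotype is incremented by `a_z` for heterozygotes
#' and `2 a_z` for line-z homozygotes), Model 2 (adds one dominance deviation
#' per family). Each step adds one parameter per family, so the
#' likelihood-ratio statistics `LRT1 = 2 (LL1 - LL0)` (cis additive) and
#' `LRT2 = 2 (LL2 - LL1)` (cis dominance) are referred to chi-square with as
#' many df as segregating families (9 for the full design). The genetic
#' variance under Model 1 is the trans component `Vg_trans` (cis effects are
#' absorbed into fixed effects); Model 0's Vg covers cis plus trans, and the
#' two locus-variance estimators Vg(r2) and Vg(a) are reported.
#'
#' Plants with unknown cis genotype are dropped for this gene (with a
#' per-gene eigendecomposition of the corresponding relatedness submatrix); a
#' gene with no segregating family is flagged untestable.
#'
#' @param y phenotype vector (standardized expression).
#' @param dose cis-locus alternative-allele dose per plant (`NA` unknown).
#' @param family family label per plant (0 = reference parentals).
#' @param cohort factor of growth cohorts.
#' @param K relatedness matrix (needed when genotypes are missing) or
#'   [eigen_kinship()] object for the complete-data fast path.
#' @param n_lines,reference_line founder panel dimensions.
#' @return list of class `gene_result`: fits for models 0/1/2, `LRT1`,
#'   `LRT2`, `p1`, `p2`, `df`, `a_hat`, `d_hat`, `se_a`, `se_d`, `Vg_cis_r2`,
#'   `Vg_cis_a`, `Vg_trans`, `Ve`, `n_used`, `untestable`.
#' @export
cis_tests <- function(y, dose, family, cohort, K, n_lines = 10,
                      reference_line = 1) {
  keep <- !is.na(dose) & !is.na(y)
  if (!all(keep)) {
    if (inherits(K, "kinship_eigen"))
      stop("missing genotypes require the full relatedness matrix, not its eigendecomposition")
    K <- unclass(K)[keep, keep]
    y <- y[keep]; dose <- dose[keep]
    family <- family[keep]; cohort <- droplevels(factor(cohort[keep]))
  }
  seg <- tapply(dose, family, function(d) length(unique(d)) > 1L)
  seg_fams <- names(seg)[which(seg)]
  if (!length(seg_fams))
    return(structure(list(untestable = TRUE), class = "gene_result"))
  Keig <- if (inherits(K, "kinship_eigen")) K else eigen_kinship(K)
  X0 <- stats::model.matrix(~cohort, data.frame(cohort = cohort))
  Xa <- family_dose_design(dose, family, n_lines, reference_line)
  Xd <- family_het_design(dose, family, n_lines, reference_line)
  # keep only estimable columns (families present with variation)
  keep_a <- apply(Xa, 2, function(v) stats::var(v) > 0)
  keep_d <- apply(Xd, 2, function(v) stats::var(v) > 0)
  fit0 <- fit_lmm(y, X0, Keig)
  fit1 <- fit_lmm(y, cbind(X0, Xa[, keep_a, drop = FALSE]), Keig)
  fit2 <- fit_lmm(y, cbind(X0, Xa[, keep_a, drop = FALSE],
                           Xd[, keep_d, drop = FALSE]), Keig)
  lrt1 <- max(2 * (fit1$loglik - fit0$loglik), 0)
  lrt2 <- max(2 * (fit2$loglik - fit1$loglik), 0)
  df1 <- sum(keep_a); df2 <- sum(keep_d)
  acols <- colnames(Xa)[keep_a]; dcols <- colnames(Xd)[keep_d]
  a_hat <- fit1$beta[acols]; se_a <- fit1$se[acols]
  d_hat <- fit2$beta[dcols]; se_d <- fit2$se[dcols]
  vgc_a <- if (length(a_hat) >= 2) vg_a(a_hat, se_a) else NA_real_
  structure(list(
    untestable = FALSE, fit0 = fit0, fit1 = fit1, fit2 = fit2,
    LRT1 = lrt1, LRT2 = lrt2, df = c(df1 = df1, df2 = df2),
    p1 = chisq_p(lrt1, df1), p2 = chisq_p(lrt2, df2),
    a_hat = a_hat, se_a = se_a, d_hat = d_hat, se_d = se_d,
    Vg_cis_r2 = vg_r2(fit0, fit1), Vg_cis_a = vgc_a,
    Vg_trans = fit1$Vg, Ve = fit1$Ve, n_used = fit0$n),
    class = "gene_result")
}

# chi-square upper-tail p computed on the log scale to survive LRT > 300
chisq_p <- function(stat, df) {
  if (df == 0) return(NA_real_)
  exp(stats::pchisq(stat, df, lower.tail = FALSE, log.p = TRUE))
}

#' Locus variance by model contrast, Vg(r2)
#'
#' Subtracts the genetic variance under Model 1 (trans only; the cis effect
#' sits in the fixed effects) from the genetic variance under Model 0 (cis +
#' trans). The difference estimates the cis contribution and may be negative
#' by sampling error; it is reported signed.
#'
#' @param fit0,fit1 nested [fit_lmm()] fits of the same trait.
#' @return numeric estimate (may be negative).
#' @export
vg_r2 <- function(fit0, fit1) {
  stopifnot(inherits(fit0, "lmm_fit"), inherits(fit1, "lmm_fit"),
            fit0$n == fit1$n)
  fit0$Vg - fit1$Vg
}

#' Locus variance from the dispersion of family effects, Vg(a)
#'
#' `Vg(a) = 2 (s_a^2 - mean(se_a^2))`: twice the sample variance (n-1
#' denominator) among the per-family additive-effect estimates minus the
#' variance contributed by estimation error. The family estimates come from
#' disjoint families and can be treated as unrelated. The result may be
#' negative when noise dominates and is reported signed.
#'
#' @param a_estimates per-family additive-effect estimates.
#' @param a_standard_errors their standard errors.
#' @return numeric estimate (may be negative).
#' @export
vg_a <- function(a_estimates, a_standard_errors) {
  ok <- is.finite(a_estimates) & is.finite(a_standard_errors)
  if (sum(ok) < 2) stop("need at least two finite effect estimates")
  2 * (stats::var(a_estimates[ok]) - mean(a_standard_errors[ok]^2))
}

#' Over/underdominance test for one family
#'
#' Compares Model 2 (dominance deviation free in every family) to the model
#' in which family z is constrained to complete dominance of either allele
#' (`d_z = +a_z` or `d_z = -a_z`, i.e. the heterozygote equals one of the
#' homozygotes). Each constraint removes one parameter, giving a 1-df LRT per
#' sign; over/underdominance is supported only when the unconstrained fit
#' beats *both* constraints. A family with a near-zero additive effect makes
#' the constraint degenerate and is flagged.
#'
#' @inheritParams cis_tests
#' @param z the family (alternative line index) to test.
#' @param a_tol additive effects below this absolute value flag the result.
#' @return list: `LRT_plus`, `LRT_minus` (vs `d = +a` and `d = -a`), `LRT`
#'   (the minimum, the reportable statistic), `p` (chi-square 1 df),
#'   `degenerate`.
#' @export
overdominance_test <- function(y, dose, family, cohort, K, z,
                               n_lines = 10, reference_line = 1,
                               a_tol = 1e-3) {
  keep <- !is.na(dose) & !is.na(y)
  y <- y[keep]; dose <- dose[keep]
  family <- family[keep]; cohort <- factor(cohort[keep])
  Keig <- if (inherits(K, "kinship_eigen") && all(keep)) K
          else eigen_kinship(unclass(K)[keep, keep])
  if (length(unique(dose[family == z])) < 2L)
    stop("family ", z, " does not segregate at this locus")
  X0 <- stats::model.matrix(~cohort, data.frame(cohort = cohort))
  Xa <- family_dose_design(dose, family, n_lines, reference_line)
  Xd <- family_het_design(dose, family, n_lines, reference_line)
  keep_a <- apply(Xa, 2, function(v) stats::var(v) > 0)
  keep_d <- apply(Xd, 2, function(v) stats::var(v) > 0)
  X2 <- cbind(X0, Xa[, keep_a, drop = FALSE], Xd[, keep_d, drop = FALSE])
  fit2 <- fit_lmm(y, X2, Keig)
  az <- paste0("a_line", z); dz <- paste0("d_line", z)
  constrained <- function(sign) {
    # d_z = sign * a_z merges the family's two columns into dose + sign*het
    Xc_a <- Xa; Xc_a[, az] <- Xa[, az] + sign * Xd[, dz]
    Xd_rest <- Xd[, setdiff(colnames(Xd)[keep_d], dz), drop = FALSE]
    fit_lmm(y, cbind(X0, Xc_a[, keep_a, drop = FALSE], Xd_rest), Keig)
  }
  lrt_p <- max(2 * (fit2$loglik - constrained(+1)$loglik), 0)
  lrt_m <- max(2 * (fit2$loglik - constrained(-1)$loglik), 0)
  lrt <- min(lrt_p, lrt_m)
  list(LRT_plus = lrt_p, LRT_minus = lrt_m, LRT = lrt,
       p = chisq_p(lrt, 1),
       degenerate = abs(fit2$beta[az]) < a_tol)
}

#' Haseman-Elston regression estimate of genetic variance
#'
#' Least-squares estimation of the genetic variance carried by a relatedness
#' matrix (genome-wide, or locus-specific for a single QTL). Two classic
#' forms are available. The `"difference"` form (default) regresses the
#' squared pair differences `(y_i - y_j)^2` on `R_ii + R_jj` and `R_ij`
#' jointly; since `E[(y_i - y_j)^2] = Vg (R_ii + R_jj) - 2 Vg R_ij + 2 Ve`,
#' the `R_ij` coefficient divided by -2 estimates Vg, and any shift shared by
#' both plants cancels exactly. The `"product"` form regresses the
#' off-diagonal cross-products `y_i y_j` of the centred phenotype on `R_ij`
#' (slope = Vg); it is simpler but leaks the estimated mean into the
#' products, which biases it when the genetic signal is strong relative to
#' the sample. Cheap but markedly noisier than the likelihood estimators.
#'
#' @param y phenotype vector (fixed effects already removed).
#' @param K relatedness matrix (inbreeding-aware diagonal allowed).
#' @param form `"difference"` (default) or `"product"`.
#' @return the Vg estimate.
#' @export
he_regression <- function(y, K, form = c("difference", "product")) {
  form <- match.arg(form)
  K <- unclass(K)
  n <- length(y)
  stopifnot(nrow(K) == n)
  lo <- lower.tri(K)
  rij <- K[lo]
  if (stats::var(rij) == 0) stop("relatedness has no variation across pairs")
  if (form == "product") {
    yc <- y - mean(y)
    cp <- tcrossprod(yc)[lo]
    return(stats::cov(cp, rij) / stats::var(rij))
  }
  sq <- outer(y, y, function(a, b) (a - b)^2)[lo]
  rii <- outer(diag(K), diag(K), "+")[lo]
  X <- cbind(1, rii, rij)
  cf <- stats::lm.fit(X, sq)$coefficients
  unname(-cf[3] / 2)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper around
#' `p.adjust(method = "fdr")`.
#'
#' @param pvalues vector of p-values in `[0, 1]` (`NA` allowed).
#' @return q-values, monotone in the sorted p-values.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "fdr")
}
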