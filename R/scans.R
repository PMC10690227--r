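#' Single-marker regression of expression on genotype
#'
#' Least-squares fit of the phenotype on the allele dose (0/1/2) and a
#' heterozygote indicator plus covariates, as used in the Cross-specific
#' per-family analysis. Returns the additive and dominance effect estimates
#' with standard errors and the model-vs-null F statistic. Optional
#' observation weights (e.g. precision weights from an external
#' normalisation) are honoured.
#'
#' @param y phenotype vector for one family.
#' @param dose marker dose per plant (0/1/2).
#' @param covariates optional design matrix of nuisance fixed effects
#'   (cohort); an intercept is always included.
#' @param weights optional non-negative observation weights.
#' @return list `a`, `d`, `se_a`, `se_d`, `F`, `p`, `df`, `skipped` (TRUE
#'   for a monomorphic marker).
#' @export
marker_regression <- function(y, dose, covariates = NULL, weights = NULL) {
  keep <- !is.na(dose) & !is.na(y)
  y <- y[keep]; dose <- dose[keep]
  X0 <- cbind(`(Intercept)` = rep(1, length(y)),
              if (!is.null(covariates)) covariates[keep, , drop = FALSE])
  if (length(unique(dose)) < 2L)
    return(list(a = NA_real_, d = NA_real_, se_a = NA_real_, se_d = NA_real_,
                F = NA_real_, p = NA_real_, df = c(0, 0), skipped = TRUE))
  het <- as.numeric(dose == 1L)
  X1 <- cbind(X0, a = dose)
  if (stats::var(het) > 0) X1 <- cbind(X1, d = het)
  w <- if (is.null(weights)) rep(1, length(y)) else weights[keep]
  f0 <- stats::lm.wfit(X0, y, w)
  f1 <- stats::lm.wfit(X1, y, w)
  rss0 <- sum(w * f0$residuals^2); rss1 <- sum(w * f1$residuals^2)
  df1 <- f1$rank - f0$rank; df2 <- length(y) - f1$rank
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  sigma2 <- rss1 / df2
  XtX <- chol2inv(chol(crossprod(sqrt(w) * X1)))
  se <- sqrt(diag(XtX) * sigma2)
  names(se) <- colnames(X1)
  list(a = unname(f1$coefficients["a"]),
       d = unname(if ("d" %in% colnames(X1)) f1$coefficients["d"] else NA_real_),
       se_a = unname(se["a"]),
       se_d = unname(if ("d" %in% names(se)) se["d"] else NA_real_),
       F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), skipped = FALSE)
}

#' Scan all markers for one gene within a family
#'
#' @param y phenotype vector for the family's plants.
#' @param dose_matrix plants x markers dose matrix for the family.
#' @param covariates,weights passed to [marker_regression()].
#' @return data frame with one row per marker: `marker`, `a`, `d`, `se_a`,
#'   `se_d`, `F`, `p`.
#' @export
scan_gene <- function(y, dose_matrix, covariates = NULL, weights = NULL) {
  res <- lapply(seq_len(ncol(dose_matrix)), function(m)
    marker_regression(y, dose_matrix[, m], covariates, weights))
  data.frame(marker = colnames(dose_matrix),
             a = vapply(res, `[[`, numeric(1), "a"),
             d = vapply(res, `[[`, numeric(1), "d"),
             se_a = vapply(res, `[[`, numeric(1), "se_a"),
             se_d = vapply(res, `[[`, numeric(1), "se_d"),
             F = vapply(res, `[[`, numeric(1), "F"),
             p = vapply(res, `[[`, numeric(1), "p"))
}

#' Gene-specific permutation p-values for a marker scan
#'
#' Builds the null distribution of the genomewide maximum F statistic by
#' shuffling the phenotype over plants (within strata, by default, to respect
#' the design) and assigns each marker
#' `p = (1 + #(null max >= observed)) / (n_perm + 1)`.
#'
#' @inheritParams scan_gene
#' @param n_perm number of permutations (>= 100 recommended; fewer warns).
#' @param rng_seed integer seed.
#' @param strata optional factor; shuffling is confined within its levels.
#' @return list `observed` (scan data frame), `perm_p` (per-marker
#'   genomewide-adjusted p), `null_max` (the permutation distribution).
#' @export
permutation_pvalue <- function(y, dose_matrix, covariates = NULL,
                               n_perm = 1000, rng_seed = 1, strata = NULL,
                               weights = NULL) {
  if (n_perm < 100)
    warning("fewer than 100 permutations gives a coarse p-value")
  obs <- scan_gene(y, dose_matrix, covariates, weights)
  set.seed(rng_seed)
  idx <- seq_along(y)
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- if (is.null(strata)) sample(idx) else {
      out <- idx
      for (lev in levels(factor(strata))) {
        sel <- which(strata == lev)
        out[sel] <- sel[sample(length(sel))]
      }
      out
    }
    ps <- scan_gene(y[perm], dose_matrix, covariates, weights)
    null_max[b] <- max(ps$F, na.rm = TRUE)
  }
  perm_p <- vapply(obs$F, function(f)
    if (is.na(f)) NA_real_ else (1 + sum(null_max >= f)) / (n_perm + 1),
    numeric(1))
  list(observed = obs, perm_p = perm_p, null_max = null_max)
}

#' Cluster significant trans eQTLs into loci
#'
#' Single-linkage chaining of significant trans hits within a cM window,
#' separately per family and chromosome: consecutive (sorted) hits closer
#' than `window` join one locus. A locus affecting at least
#' `hotspot_min_genes` distinct genes is flagged as a hotspot. The reported
#' position is the mean cM of member hits (optionally weighted).
#'
#' @param hits data frame with columns `family`, `chrom`, `cM`, `gene` and
#'   optionally `weight` (e.g. a LOD score for position weighting).
#' @param window chaining distance in cM (default 2).
#' @param hotspot_min_genes hotspot threshold on distinct affected genes.
#' @return data frame with one row per locus: `family`, `chrom`, `cM_mean`,
#'   `cM_min`, `cM_max`, `n_hits`, `n_genes`, `hotspot`, `members`
#'   (list-column of hit row indices).
#' @export
cluster_trans <- function(hits, window = 2, hotspot_min_genes = 30) {
  if (anyNA(hits$cM)) {
    warning(sum(is.na(hits$cM)), " hit(s) without a cM position excluded")
    hits <- hits[!is.na(hits$cM), , drop = FALSE]
  }
  out <- list()
  for (fam in unique(hits$family)) for (ch in unique(hits$chrom)) {
    sel <- which(hits$family == fam & hits$chrom == ch)
    if (!length(sel)) next
    sel <- sel[order(hits$cM[sel])]
    pos <- hits$cM[sel]
    new_cluster <- c(TRUE, diff(pos) > window)
    cl <- cumsum(new_cluster)
    for (k in unique(cl)) {
      rows <- sel[cl == k]
      w <- if (!is.null(hits$weight)) hits$weight[rows] else rep(1, length(rows))
      out[[length(out) + 1L]] <- data.frame(
        family = fam, chrom = ch,
        cM_mean = sum(hits$cM[rows] * w) / sum(w),
        cM_min = min(hits$cM[rows]), cM_max = max(hits$cM[rows]),
        n_hits = length(rows), n_genes = length(unique(hits$gene[rows])),
        hotspot = length(unique(hits$gene[rows])) >= hotspot_min_genes)
      out[[length(out)]]$members <- I(list(rows))
    }
  }
  do.call(rbind, out)
}

#' Principal components of the standardized transcriptome
#'
#' Standard PCA of the plants x genes phenotype matrix (already unit-variance
#' per gene). Score variances equal the eigenvalues, which sum to the number
#' of genes; component signs follow the convention that the largest-absolute
#' loading is positive.
#'
#' @param phenotype plants x genes standardized expression matrix (no
#'   missing values).
#' @param n_pc number of components to retain (default all).
#' @return list of class `pc_traits`: `scores` (plants x PC), `loadings`
#'   (genes x PC), `eigenvalues`, `var_explained`.
#' @export
pca_transcriptome <- function(phenotype, n_pc = NULL) {
  if (anyNA(phenotype)) stop("phenotype matrix contains missing values")
  if (any(apply(phenotype, 2, stats::var) == 0))
    stop("constant gene column; standardize first")
  pc <- stats::prcomp(phenotype, center = TRUE, scale. = FALSE)
  k <- if (is.null(n_pc)) ncol(pc$rotation) else min(n_pc, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    v <- load[which.max(abs(load[, j])), j]
    if (v < 0) -1 else 1
  }, numeric(1))
  load <- sweep(load, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  ev <- pc$sdev^2
  structure(list(scores = scores, loadings = load,
                 eigenvalues = ev,
                 var_explained = ev / sum(ev)),
            class = "pc_traits")
}

#' Genome scan for QTLs on a principal-component score
#'
#' Treats a PC score as a quantitative trait: fits the null animal model
#' (heritability of the score), then adds a candidate QTL at every
#' `step`-th gene position along each chromosome with the same per-family
#' additive (Model 1) and dominance (Model 2) fixed-effect structure as the
#' cis tests. The best position per chromosome (highest Model 2 likelihood)
#' is retained; `LRT_total = LRT_additive + LRT_dominance` by construction,
#' and a pcQTL is declared when the total test beats `p_threshold`.
#'
#' @param score PC score vector over plants.
#' @param gene_dose plants x positions dose matrix (interpolated genotypes).
#' @param gene_pos data frame `chrom`, `cM` per position column.
#' @param family,cohort design vectors.
#' @param K relatedness or [eigen_kinship()]; positions with missing dose
#'   fall back to a per-position submatrix decomposition.
#' @param step test every `step`-th position (default 2, every other gene).
#' @param p_threshold significance threshold on the total test.
#' @param n_lines,reference_line founder panel dimensions.
#' @return list of class `pcqtl_scan`: `fit0`, `by_chrom` (data frame with
#'   the best position per chromosome: `chrom`, `position`, `cM`,
#'   `LRT_additive`, `LRT_dominance`, `LRT_total`, `df`, p-values,
#'   `significant`), `all` (every tested position).
#' @export
pc_qtl_scan <- function(score, gene_dose, gene_pos, family, cohort, K,
                        step = 2, p_threshold = 1e-5, n_lines = 10,
                        reference_line = 1) {
  have_matrix <- !inherits(K, "kinship_eigen")
  Keig <- if (have_matrix) eigen_kinship(unclass(K)) else K
  X0 <- stats::model.matrix(~cohort, data.frame(cohort = factor(cohort)))
  fit0 <- fit_lmm(score, X0, Keig)
  rows <- list()
  for (j in seq(1, ncol(gene_dose), by = step)) {
    dose <- gene_dose[, j]
    if (anyNA(dose)) {
      if (!have_matrix) next  # cannot drop plants without the full matrix
      keep <- !is.na(dose)
      Ke <- eigen_kinship(unclass(K)[keep, keep])
      ct <- cis_tests(score[keep], dose[keep], family[keep],
                      factor(cohort[keep]), Ke, n_lines, reference_line)
      f0 <- if (isTRUE(ct$untestable)) NULL else ct$fit0
    } else {
      ct <- cis_tests(score, dose, family, cohort, Keig, n_lines,
                      reference_line)
      f0 <- fit0
    }
    if (isTRUE(ct$untestable)) next
    lrt_a <- max(2 * (ct$fit1$loglik - f0$loglik), 0)
    lrt_d <- max(2 * (ct$fit2$loglik - ct$fit1$loglik), 0)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = gene_pos$chrom[j], position = colnames(gene_dose)[j],
      cM = gene_pos$cM[j], LRT_additive = lrt_a, LRT_dominance = lrt_d,
      LRT_total = lrt_a + lrt_d,
      df_additive = unname(ct$df["df1"]), df_dominance = unname(ct$df["df2"]))
  }
  all <- do.call(rbind, rows)
  all$p_additive <- mapply(chisq_p, all$LRT_additive, all$df_additive)
  all$p_dominance <- mapply(chisq_p, all$LRT_dominance, all$df_dominance)
  all$p_total <- mapply(chisq_p, all$LRT_total,
                        all$df_additive + all$df_dominance)
  best <- do.call(rbind, lapply(split(all, all$chrom), function(d)
    d[which.max(d$LRT_total), , drop = FALSE]))
  best$significant <- best$p_total < p_threshold
  structure(list(fit0 = fit0, by_chrom = best, all = all),
            class = "pcqtl_scan")
}
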