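#' Counts-per-million matrix
#'
#' @param counts plants x genes matrix of raw counts.
#' @param lib_sizes per-plant library sizes; defaults to row sums of the full
#'   count matrix.
#' @return plants x genes CPM matrix.
#' @export
cpm <- function(counts, lib_sizes = rowSums(counts)) {
  if (any(lib_sizes <= 0)) {
    bad <- rownames(counts)[lib_sizes <= 0]
    stop("zero library size for plant(s): ", paste(bad, collapse = ", "))
  }
  counts / lib_sizes * 1e6
}

#' Filter lowly expressed genes on mean CPM
#'
#' Genes whose mean counts-per-million across plants falls below the
#' threshold are not analysed; expression of such genes is dominated by
#' sampling noise at realistic depths.
#'
#' @inheritParams cpm
#' @param threshold minimum mean CPM (default 0.5).
#' @return logical vector over genes (TRUE = retained).
#' @export
cpm_filter <- function(counts, threshold = 0.5, lib_sizes = rowSums(counts)) {
  colMeans(cpm(counts, lib_sizes)) >= threshold
}

#' Box-Cox transform of one gene's expression values
#'
#' Selects the power `lambda` maximising the Box-Cox profile log-likelihood
#' on a grid (via `MASS::boxcox` of an intercept-only model) and applies
#' `(y^lambda - 1)/lambda` (natural log at `lambda = 0`).
#'
#' @param values positive values (CPM plus offset).
#' @param lambda_grid grid searched for the profile maximum.
#' @return list `lambda`, `transformed`.
#' @export
boxcox_gene <- function(values, lambda_grid = seq(-2, 2, by = 0.05)) {
  if (any(values <= 0)) stop("Box-Cox requires positive values; add an offset")
  if (stats::var(values) == 0) stop("constant input has no variance to transform")
  bc <- MASS::boxcox(values ~ 1, lambda = lambda_grid, plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  transformed <- if (abs(lambda) < 1e-12) log(values)
                 else (values^lambda - 1) / lambda
  list(lambda = lambda, transformed = transformed)
}

#' Standardize a vector to mean zero, unit variance
#'
#' Uses the population (n-denominator) variance so that downstream
#' variance-component estimates partition a total of exactly one.
#'
#' @param values numeric vector.
#' @return standardized vector.
#' @export
standardize <- function(values) {
  n <- length(values)
  v <- stats::var(values) * (n - 1) / n
  if (!is.finite(v) || v == 0) stop("zero variance; cannot standardize")
  (values - mean(values)) / sqrt(v)
}

#' Prepare the Combined-analysis phenotype matrix
#'
#' The full preparation pipeline: CPM filter, CPM with an offset for zero
#' counts, per-gene Box-Cox transform, and unit-variance standardization.
#' The per-gene transform record (`lambda`, offset) is returned so any
#' phenotype value can be traced back to a raw count.
#'
#' @param counts plants x genes raw count matrix.
#' @param lib_sizes per-plant library sizes (default row sums).
#' @param cpm_threshold minimum mean CPM for a gene to be analysed.
#' @param offset added to CPM before Box-Cox so zero counts are transformable.
#' @param lambda_grid passed to [boxcox_gene()].
#' @return list of class `expression_prep`: `phenotype` (plants x retained
#'   genes, each column mean 0 variance 1), `retained` (logical over input
#'   genes), `transforms` (data frame gene, lambda, offset), `lib_sizes`.
#' @export
prepare_expression <- function(counts, lib_sizes = rowSums(counts),
                               cpm_threshold = 0.5, offset = 0.5,
                               lambda_grid = seq(-2, 2, by = 0.05)) {
  retained <- cpm_filter(counts, cpm_threshold, lib_sizes)
  cp <- cpm(counts[, retained, drop = FALSE], lib_sizes)
  G <- ncol(cp)
  pheno <- matrix(NA_real_, nrow(cp), G, dimnames = dimnames(cp))
  lambda <- numeric(G)
  for (g in seq_len(G)) {
    bc <- boxcox_gene(cp[, g] + offset, lambda_grid)
    pheno[, g] <- standardize(bc$transformed)
    lambda[g] <- bc$lambda
  }
  structure(list(phenotype = pheno, retained = retained,
                 transforms = data.frame(gene = colnames(cp), lambda = lambda,
                                         offset = offset),
                 lib_sizes = lib_sizes),
            class = "expression_prep")
}
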