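#' Genetic and environmental covariance of a gene pair
#'
#' Applies the null animal model (Model 0) to each trait and to their raw sum
#' `Z = y1 + y2`; since `Var(Z) = Var(y1) + Var(y2) + 2 Cov(y1, y2)` holds
#' separately for the genetic and environmental components, the covariances
#' are `C_G = (VgZ - Vg1 - Vg2) / 2` and `C_E = (VeZ - Ve1 - Ve2) / 2`. The
#' sum is deliberately *not* restandardized: the identity needs the variance
#' of the raw sum.
#'
#' @param y1,y2 standardized phenotypes on the same plants.
#' @param K relatedness matrix or [eigen_kinship()] object.
#' @param X fixed-effect design (default intercept only; pass the cohort
#'   design used for the single-trait fits).
#' @return list of class `pair_covariance`: `C_G`, `C_E`, `CG2`, `CE2`, and
#'   the three underlying fits.
#' @export
pair_covariance <- function(y1, y2, K, X = NULL) {
  if (length(y1) != length(y2))
    stop("'y1' and 'y2' must be measured on the same plants")
  Keig <- if (inherits(K, "kinship_eigen")) K else eigen_kinship(unclass(K))
  if (is.null(X)) X <- matrix(1, length(y1), 1, dimnames = list(NULL, "(Intercept)"))
  f1 <- fit_lmm(y1, X, Keig)
  f2 <- fit_lmm(y2, X, Keig)
  fz <- fit_lmm(y1 + y2, X, Keig)
  cg <- (fz$Vg - f1$Vg - f2$Vg) / 2
  ce <- (fz$Ve - f1$Ve - f2$Ve) / 2
  structure(list(C_G = cg, C_E = ce, CG2 = cg^2, CE2 = ce^2,
                 fit1 = f1, fit2 = f2, fitZ = fz),
            class = "pair_covariance")
}

#' Random background gene pairs
#'
#' Pairs each gene with `k` distinct other genes uniformly at random, removes
#' self-pairs and duplicates (unordered), reproducing the construction of a
#' genomewide background set for covariance contrasts.
#'
#' @param genes character vector of gene ids.
#' @param k partners per gene.
#' @param rng_seed integer seed.
#' @return data frame `gene1`, `gene2` with `gene1 < gene2`, no duplicates.
#' @export
random_pairs <- function(genes, k = 10, rng_seed = 1) {
  n <- length(genes)
  if (k >= n) stop("'k' must be smaller than the number of genes")
  set.seed(rng_seed)
  g1 <- rep(genes, each = k)
  g2 <- unlist(lapply(seq_len(n), function(i) sample(genes[-i], k)))
  a <- pmin(g1, g2); b <- pmax(g1, g2)
  keep <- !duplicated(paste(a, b))
  data.frame(gene1 = a[keep], gene2 = b[keep], stringsAsFactors = FALSE)
}

#' Covariance of every pair in a list
#'
#' @param pairs data frame `gene1`, `gene2`.
#' @param phenotype plants x genes standardized matrix.
#' @inheritParams pair_covariance
#' @return `pairs` with columns `C_G`, `C_E`, `CG2`, `CE2` appended.
#' @export
pair_covariances <- function(pairs, phenotype, K, X = NULL) {
  Keig <- if (inherits(K, "kinship_eigen")) K else eigen_kinship(unclass(K))
  res <- t(vapply(seq_len(nrow(pairs)), function(i) {
    pc <- pair_covariance(phenotype[, pairs$gene1[i]],
                          phenotype[, pairs$gene2[i]], Keig, X)
    c(pc$C_G, pc$C_E)
  }, numeric(2)))
  pairs$C_G <- res[, 1]; pairs$C_E <- res[, 2]
  pairs$CG2 <- pairs$C_G^2; pairs$CE2 <- pairs$C_E^2
  pairs
}

#' Contrast squared covariances between pair classes
#'
#' Compares the mean squared genetic (and environmental) covariance of a
#' focal pair set - typically pairs of genes affected by the same trans eQTL
#' - against a background set, with an unequal-variance (Welch) t test on
#' the squared covariances.
#'
#' @param background,shared data frames with `CG2` and `CE2` columns, e.g.
#'   from [pair_covariances()].
#' @return data frame with one row per statistic (`CG2`, `CE2`): class
#'   means, standard errors, the mean ratio, Welch t and p (one-sided,
#'   shared > background).
#' @export
trans_pair_contrast <- function(background, shared) {
  if (!nrow(background) || !nrow(shared)) stop("both pair sets must be non-empty")
  one <- function(col) {
    b <- background[[col]]; s <- shared[[col]]
    tt <- stats::t.test(s, b, alternative = "greater")
    data.frame(statistic = col,
               mean_background = mean(b), se_background = stats::sd(b) / sqrt(length(b)),
               mean_shared = mean(s), se_shared = stats::sd(s) / sqrt(length(s)),
               ratio = mean(s) / mean(b),
               t = unname(tt$statistic), p = tt$p.value)
  }
  rbind(one("CG2"), one("CE2"))
}
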