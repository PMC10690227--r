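#' Enumerate allelic-series configurations
#'
#' The founder-line additive effects (the reference anchored at zero plus one
#' estimate per alternative line) are ranked, and every way of cutting the
#' ranking at one or more of the `n_lines - 1` gaps defines a configuration:
#' contiguous rank bins are functional alleles. All non-empty split sets are
#' returned, `2^(n_lines - 1) - 1` configurations (511 for ten lines),
#' covering two up to `n_lines` alleles.
#'
#' @param n_lines number of founder lines (>= 2).
#' @return list of integer vectors, each the set of cut gap indices (gap k
#'   separates rank k from rank k+1).
#' @export
enumerate_configs <- function(n_lines = 10) {
  if (!is.numeric(n_lines) || n_lines < 2)
    stop("'n_lines' must be at least 2")
  gaps <- n_lines - 1L
  out <- vector("list", 2^gaps - 1L)
  for (code in seq_len(2^gaps - 1L))
    out[[code]] <- which(bitwAnd(code, bitwShiftL(1L, 0:(gaps - 1L))) != 0L)
  out
}

# bin membership (1-based, in rank order) for each of n ranked lines
config_bins <- function(splits, n_lines) {
  findInterval(seq_len(n_lines) - 1L, splits) + 1L
}

#' Fit one allelic-series configuration for a gene
#'
#' Refits the additive cis model with founder lines in the same rank bin
#' sharing a single additive-effect parameter; the bin containing the
#' reference line is anchored at zero. With every line in its own bin the fit
#' equals the unconstrained Model 1; with all lines merged with the reference
#' it collapses to Model 0.
#'
#' @param splits integer vector of cut gaps (possibly empty for the
#'   single-allele null), as produced by [enumerate_configs()].
#' @param rank_order founder line indices in effect rank order (length
#'   `n_lines`), reference included.
#' @param y,dose,family,cohort,K as in [cis_tests()].
#' @param n_lines,reference_line founder panel dimensions.
#' @return list `loglik`, `fit`, `bins` (line index -> bin), `k` (allele
#'   count).
#' @export
fit_config <- function(splits, rank_order, y, dose, family, cohort, K,
                       n_lines = 10, reference_line = 1) {
  stopifnot(length(rank_order) == n_lines)
  bins_by_rank <- config_bins(splits, n_lines)
  bins <- integer(n_lines)
  bins[rank_order] <- bins_by_rank
  if (length(unique(bins_by_rank)) != length(splits) + 1L)
    stop("configuration contains an empty bin")
  Keig <- if (inherits(K, "kinship_eigen")) K else eigen_kinship(unclass(K))
  X0 <- stats::model.matrix(~cohort, data.frame(cohort = factor(cohort)))
  Xa <- family_dose_design(dose, family, n_lines, reference_line)
  ref_bin <- bins[reference_line]
  Xc <- NULL
  for (b in setdiff(sort(unique(bins)), ref_bin)) {
    lines_b <- setdiff(which(bins == b), reference_line)
    col <- rowSums(Xa[, paste0("a_line", lines_b), drop = FALSE])
    Xc <- cbind(Xc, col)
  }
  if (!is.null(Xc)) {
    colnames(Xc) <- paste0("allele", setdiff(sort(unique(bins)), ref_bin))
    keep <- apply(Xc, 2, function(v) stats::var(v) > 0)
    Xc <- Xc[, keep, drop = FALSE]
    if (ncol(Xc) == 0L) Xc <- NULL
  }
  fit <- fit_lmm(y, cbind(X0, Xc), Keig)
  list(loglik = fit$loglik, fit = fit, bins = bins,
       k = length(unique(bins)))
}

#' Select the allelic series for a gene by stepwise likelihood
#'
#' Ranks the per-family additive-effect estimates (reference at zero), finds
#' for each allele count k the best configuration by exhaustive search over
#' rank splits, and increases k stepwise from 2, accepting an extra allele
#' only while twice the likelihood gain exceeds `threshold` (3.84, the 5%
#' chi-square point with 1 df). Optionally a 1-vs-2-allele comparison with
#' the same rule can collapse a no-signal gene to a single allele.
#'
#' @inheritParams fit_config
#' @param a_hat named per-family additive estimates (`a_line<z>`) from the
#'   unconstrained Model 1 fit; computed internally when `NULL`.
#' @param threshold acceptance threshold on twice the likelihood difference.
#' @param allow_k1 if `TRUE`, also compare the best 2-allele fit against the
#'   single-allele (Model 0) fit and return k = 1 when the split is not
#'   supported.
#' @return list of class `allele_series`: `k`, `bins` (line -> allele class),
#'   `effects` (per-allele estimates, reference class at 0), `H`
#'   (heterozygosity of the line counts), `loglik_path`, `rank_order`.
#' @export
select_series <- function(y, dose, family, cohort, K, a_hat = NULL,
                          n_lines = 10, reference_line = 1,
                          threshold = 3.84, allow_k1 = FALSE) {
  Keig <- if (inherits(K, "kinship_eigen")) K else eigen_kinship(unclass(K))
  if (is.null(a_hat)) {
    ct <- cis_tests(y, dose, family, cohort, Keig, n_lines, reference_line)
    if (isTRUE(ct$untestable)) stop("gene is untestable: no segregating family")
    a_hat <- ct$a_hat
  }
  effects <- rep(0, n_lines)
  z <- as.integer(sub("a_line", "", names(a_hat)))
  effects[z] <- a_hat
  # ties broken by founder line index for determinism
  rank_order <- order(effects, seq_len(n_lines))
  gaps <- n_lines - 1L
  best_at_k <- function(k) {
    cuts <- utils::combn(gaps, k - 1L, simplify = FALSE)
    fits <- lapply(cuts, fit_config, rank_order = rank_order, y = y,
                   dose = dose, family = family, cohort = cohort, K = Keig,
                   n_lines = n_lines, reference_line = reference_line)
    fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  }
  ll_path <- numeric(0)
  best <- best_at_k(2L)
  ll_path["2"] <- best$loglik
  k <- 2L
  while (k < n_lines) {
    cand <- best_at_k(k + 1L)
    ll_path[as.character(k + 1L)] <- cand$loglik
    if (2 * (cand$loglik - best$loglik) > threshold) {
      best <- cand; k <- k + 1L
    } else break
  }
  if (allow_k1 && k == 2L) {
    fit1a <- fit_config(integer(0), rank_order, y, dose, family, cohort,
                        Keig, n_lines, reference_line)
    ll_path <- c("1" = fit1a$loglik, ll_path)
    if (2 * (best$loglik - fit1a$loglik) <= threshold) {
      best <- fit1a; k <- 1L
    }
  }
  counts <- table(best$bins)
  eff <- rep(0, k)
  fb <- best$fit$beta
  got <- grep("^allele", names(fb), value = TRUE)
  eff[as.integer(sub("allele", "", got))] <- fb[got]
  # report effects relative to the reference allele class
  names(eff) <- paste0("allele", seq_len(k))
  structure(list(k = k, bins = best$bins, effects = eff,
                 H = heterozygosity(as.integer(counts)),
                 loglik_path = ll_path, rank_order = rank_order),
            class = "allele_series")
}

#' Heterozygosity of an allele-count configuration
#'
#' `H = 1 - sum(q_i^2)` with `q_i` the frequency of allele class i among the
#' founder lines. With ten lines H ranges from 0 (one allele) to 0.9 (ten
#' singleton alleles); the maximum with two alleles is 0.5.
#'
#' @param line_allele_counts integer counts of lines per allele class.
#' @return H in `[0, 1)`.
#' @export
heterozygosity <- function(line_allele_counts) {
  total <- sum(line_allele_counts)
  if (total <= 0) stop("allele counts must sum to a positive total")
  q <- line_allele_counts / total
  1 - sum(q^2)
}
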