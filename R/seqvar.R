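#' Per-window nucleotide diversity and indel statistic
#'
#' From whole-genome-alignment summaries of one window (a gene body or its
#' 1 kb upstream/downstream flank) between two founder genomes: nucleotide
#' diversity `pi` is the fraction of aligned positions that differ, and the
#' indel statistic `U = (total bp - aligned bp) / total bp` measures how much
#' of the window fails to align. Perfectly colinear sequences give `U = 0`;
#' U rises toward 1 as indels and unalignable sequence accumulate. With no
#' aligned positions `pi` is undefined (`NA`) and `U = 1`.
#'
#' @param total_bp window length (> 0).
#' @param aligned_bp aligned positions (`<= total_bp`).
#' @param mismatch_bp mismatching aligned positions (`<= aligned_bp`).
#' @return data frame with columns `pi` and `U` (vectorized over inputs).
#' @export
window_stats <- function(total_bp, aligned_bp, mismatch_bp) {
  if (any(total_bp <= 0)) stop("'total_bp' must be positive")
  if (any(aligned_bp < 0) || any(aligned_bp > total_bp))
    stop("'aligned_bp' must lie in [0, total_bp]")
  if (any(mismatch_bp < 0) || any(mismatch_bp > aligned_bp))
    stop("'mismatch_bp' must lie in [0, aligned_bp]")
  data.frame(pi = ifelse(aligned_bp > 0, mismatch_bp / aligned_bp, NA_real_),
             U = (total_bp - aligned_bp) / total_bp)
}

#' Aggregate line-pair window statistics per gene
#'
#' The alignment summaries come per gene, window and alternative line (each
#' line aligned against the reference); the per-gene predictor is the mean
#' over the line comparisons.
#'
#' @param summaries data frame with columns `gene`, `window` (one of
#'   `upstream_1kb`, `genic`, `downstream_1kb`), `line`, `total_bp`,
#'   `aligned_bp`, `mismatch_bp`.
#' @return data frame with one row per gene and six predictor columns
#'   `pi_<window>`, `U_<window>`.
#' @export
aggregate_window_stats <- function(summaries) {
  st <- window_stats(summaries$total_bp, summaries$aligned_bp,
                     summaries$mismatch_bp)
  summaries$pi <- st$pi; summaries$U <- st$U
  genes <- unique(summaries$gene)
  wins <- c("upstream_1kb", "genic", "downstream_1kb")
  out <- data.frame(gene = genes)
  for (w in wins) {
    sel <- summaries$window == w
    out[[paste0("pi_", w)]] <-
      tapply(summaries$pi[sel], summaries$gene[sel], mean, na.rm = TRUE)[genes]
    out[[paste0("U_", w)]] <-
      tapply(summaries$U[sel], summaries$gene[sel], mean)[genes]
  }
  out
}

#' Regress cis-eQTL significance on sequence-variation predictors
#'
#' Standardizes each predictor (mean 0, variance 1 across genes) and fits an
#' ordinary multiple linear regression of the cis additive likelihood-ratio
#' statistic (optionally `log1p`-transformed, since the LRT is heavy-tailed)
#' on all of them jointly.
#'
#' @param lrt per-gene cis LRT values.
#' @param predictors data frame/matrix of per-gene predictors (typically the
#'   six `pi`/`U` columns of [aggregate_window_stats()]).
#' @param log_response transform the response with `log1p`.
#' @return list `coefficients` (the `summary.lm` coefficient table on
#'   standardized predictors), `model` (the `lm` fit), `condition_number`.
#' @export
predict_cis_significance <- function(lrt, predictors, log_response = FALSE) {
  Z <- scale(as.matrix(predictors))
  if (nrow(Z) < 10 * ncol(Z))
    warning("fewer than 10 genes per predictor; estimates will be unstable")
  kappa_z <- kappa(crossprod(Z) / (nrow(Z) - 1), exact = TRUE)
  if (kappa_z > 1e6)
    warning("predictors are nearly collinear (condition number ",
            signif(kappa_z, 3), ")")
  y <- if (log_response) log1p(lrt) else lrt
  fit <- stats::lm(y ~ Z)
  tab <- summary(fit)$coefficients
  rownames(tab) <- sub("^Z", "", rownames(tab))
  list(coefficients = tab, model = fit, condition_number = kappa_z)
}

#' Synthetic alignment summaries for a simulated study
#'
#' Generates per-gene, per-window, per-line alignment summary tables whose
#' sequence variation is loosely coupled to the generating cis architecture
#' (genes with larger cis effects receive more genic mismatches and more
#' upstream unaligned sequence), so the downstream regression has signal to
#' find. Synthetic stand-in for whole-genome-alignment output.
#'
#' @param arch an `f2_architecture`.
#' @param coupling strength of the variation/effect coupling (0 = none).
#' @param rng_seed integer seed.
#' @return data frame in the format of [aggregate_window_stats()] input.
#' @export
simulate_window_summaries <- function(arch, coupling = 1, rng_seed = 1) {
  set.seed(rng_seed)
  genes <- arch$genes
  alt <- setdiff(seq_len(arch$panel$n_lines), arch$panel$reference_line)
  cis_size <- sqrt(rowMeans(arch$cis_a[, alt, drop = FALSE]^2))
  wins <- c("upstream_1kb", "genic", "downstream_1kb")
  out <- expand.grid(gene = genes, window = wins, line = alt,
                     stringsAsFactors = FALSE)
  g <- match(out$gene, genes)
  total <- ifelse(out$window == "genic", 2000L, 1000L)
  # baseline pi ~ 2%, U ~ 10%; coupling inflates genic pi and upstream U
  pi_mu <- 0.02 * exp(coupling * ifelse(out$window == "genic",
                                        cis_size[g], 0))
  u_mu <- 0.10 * exp(coupling * ifelse(out$window == "upstream_1kb",
                                       cis_size[g], 0))
  u_mu <- pmin(u_mu, 0.8)
  aligned <- rbinom(nrow(out), total, 1 - u_mu)
  mism <- rbinom(nrow(out), aligned, pmin(pi_mu, 0.5))
  out$total_bp <- total; out$aligned_bp <- aligned; out$mismatch_bp <- mism
  out
}
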