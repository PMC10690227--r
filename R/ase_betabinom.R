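#' Beta-binomial log-likelihood of allele-specific counts
#'
#' Treats the alternative-allele read counts of cis-heterozygous plants as
#' beta-binomial: the per-plant alternative-read fraction is Beta(alpha,
#' beta) and reads are binomial given it. The beta-binomial accommodates the
#' overdispersion of real ASE data relative to a plain binomial.
#'
#' @param ref_count,alt_count per-plant reads from the reference and the
#'   alternative parental allele.
#' @param alpha,beta beta shape parameters (> 0).
#' @return total log-likelihood over plants.
#' @export
bb_loglik <- function(ref_count, alt_count, alpha, beta) {
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0)
    stop("'alpha' and 'beta' must be positive")
  n <- ref_count + alt_count
  sum(lchoose(n, alt_count) +
        lbeta(alt_count + alpha, ref_count + beta) - lbeta(alpha, beta))
}

#' Naive allele-specific expression fraction
#'
#' The unweighted mean of per-plant alternative-allele read fractions
#' `A / (R + A)` across heterozygous plants; usually very close to the
#' beta-binomial ML mean.
#'
#' @inheritParams bb_loglik
#' @return mean alternative fraction.
#' @export
naive_fraction <- function(ref_count, alt_count) {
  total <- ref_count + alt_count
  keep <- total > 0
  if (!any(keep)) stop("no plants with reads")
  mean(alt_count[keep] / total[keep])
}

#' Beta-binomial test of allele-specific expression
#'
#' Fits, by maximum likelihood, a null beta-binomial with `alpha = beta`
#' (balanced allelic expression on average; one free parameter) and an
#' alternative with `alpha != beta` (either parental allele may be
#' over-represented; two free parameters), and compares them by a 1-df
#' likelihood-ratio test. The alternative model is optimised over
#' `(logit mu, log theta)` with `mu = alpha/(alpha+beta)` the mean
#' alternative fraction and `theta = alpha + beta` the precision.
#'
#' @inheritParams bb_loglik
#' @param min_plants minimum informative plants (total reads > 0).
#' @param theta_max upper bound on the precision (near-binomial limit).
#' @return list of class `ase_fit`: `alpha`, `beta`, `mu` (ML mean
#'   fraction), `theta`, `LL_null`, `LL_alt`, `LRT`, `p`, `naive`,
#'   `n_plants`, `boundary` (all reads from one allele).
#' @export
ase_test <- function(ref_count, alt_count, min_plants = 2,
                     theta_max = 1e6) {
  keep <- (ref_count + alt_count) > 0
  ref_count <- ref_count[keep]; alt_count <- alt_count[keep]
  if (length(ref_count) < min_plants)
    stop("need at least ", min_plants, " plants with reads")
  boundary <- sum(ref_count) == 0 || sum(alt_count) == 0
  nll_alt <- function(par) {
    mu <- stats::plogis(par[1]); th <- exp(par[2])
    -bb_loglik(ref_count, alt_count, mu * th, (1 - mu) * th)
  }
  nll_null <- function(lth) {
    th <- exp(lth)
    -bb_loglik(ref_count, alt_count, th / 2, th / 2)
  }
  on_null <- stats::optimize(nll_null, c(log(1e-3), log(theta_max)))
  start <- c(stats::qlogis(min(max(naive_fraction(ref_count, alt_count),
                                   0.02), 0.98)),
             on_null$minimum)
  on_alt <- stats::optim(start, nll_alt, method = "L-BFGS-B",
                         lower = c(stats::qlogis(1e-6), log(1e-3)),
                         upper = c(stats::qlogis(1 - 1e-6), log(theta_max)))
  ll_null <- -on_null$objective
  ll_alt <- max(-on_alt$value, ll_null)  # alternative nests the null
  mu <- stats::plogis(on_alt$par[1]); th <- exp(on_alt$par[2])
  lrt <- 2 * (ll_alt - ll_null)
  structure(list(alpha = mu * th, beta = (1 - mu) * th, mu = mu, theta = th,
                 LL_null = ll_null, LL_alt = ll_alt, LRT = lrt,
                 p = chisq_p(lrt, 1),
                 naive = naive_fraction(ref_count, alt_count),
                 n_plants = length(ref_count), boundary = boundary),
            class = "ase_fit")
}

#' @export
print.ase_fit <- function(x, ...) {
  cat(sprintf("Beta-binomial ASE fit: n = %d plants, mu = %.3f (naive %.3f), LRT = %.2f, p = %.3g%s\n",
              x$n_plants, x$mu, x$naive, x$LRT, x$p,
              if (x$boundary) " [boundary: one allele only]" else ""))
  invisible(x)
}
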