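#' Make putative genotype calls from allele-specific read counts
#'
#' Within one F2 family only two founder haplotypes segregate, so the read
#' counts to each parental allele support a three-state call: RR (reference
#' homozygote), RA (heterozygote), AA (alternative homozygote). Calls are
#' error prone at low coverage and where allele-specific expression makes
#' heterozygotes resemble the high-expressing homozygote; they are therefore
#' treated downstream as the emitted states of an HMM, not as truth.
#'
#' @param ref_count,alt_count non-negative integer vectors (or matrices) of
#'   reads assigned to the reference and alternative parental allele.
#' @param min_total minimum total reads for a call; below it the call is
#'   missing.
#' @param tau_hom homozygote threshold on the alternative-allele read
#'   fraction: `<= tau_hom` calls RR, `>= 1 - tau_hom` calls AA, otherwise
#'   RA.
#' @return integer vector/matrix of calls: 1 = RR, 2 = RA, 3 = AA, `NA` =
#'   missing.
#' @export
call_putative <- function(ref_count, alt_count, min_total = 2,
                          tau_hom = 0.15) {
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  total <- ref_count + alt_count
  frac <- ifelse(total > 0, alt_count / total, NA_real_)
  call <- ifelse(frac <= tau_hom, 1L, ifelse(frac >= 1 - tau_hom, 3L, 2L))
  call[total < min_total] <- NA_integer_
  if (is.matrix(ref_count))
    call <- matrix(call, nrow(ref_count), dimnames = dimnames(ref_count))
  call
}

#' F2 genotype transition matrix between adjacent loci
#'
#' Each F2 genotype is transmitted through two independent gametes of the
#' selfed F1, each recombining between two adjacent loci with probability
#' `r`. The resulting 3x3 Markov transition matrix over (RR, RA, AA) is
#' doubly stochastic and leaves the 1:2:1 F2 distribution invariant.
#'
#' @param r recombination fraction in `[0, 0.5]`.
#' @return 3x3 matrix of transition probabilities, rows = current state.
#' @export
f2_transition_matrix <- function(r) {
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r > 0.5)
    stop("'r' must be a recombination fraction in [0, 0.5]")
  s <- 1 - r
  matrix(c(s^2,       2 * r * s,   r^2,
           r * s,     s^2 + r^2,   r * s,
           r^2,       2 * r * s,   s^2),
         3, 3, byrow = TRUE,
         dimnames = list(c("RR", "RA", "AA"), c("RR", "RA", "AA")))
}

# emission probability matrix for one marker: rows true state, cols observed
.emission <- function(eps) {
  matrix(c(1 - eps, eps / 2, eps / 2,
           eps / 2, 1 - eps, eps / 2,
           eps / 2, eps / 2, 1 - eps),
         3, 3, byrow = TRUE)
}

# per-plant emission likelihoods at one marker: n x 3, missing rows = 1
.emission_lik <- function(obs, eps) {
  n <- length(obs)
  E <- matrix(1, n, 3)
  ok <- !is.na(obs)
  if (any(ok)) {
    Em <- .emission(eps)
    E[ok, ] <- t(Em)[obs[ok], , drop = FALSE]  # row o of t(Em) = P(o | s = 1..3)
  }
  E
}

#' Fit the F2 genotyping HMM for one chromosome of one family
#'
#' Hidden states are the true genotypes (RR, RA, AA) at each ordered marker;
#' observations are the putative calls. The model has a genotyping error rate
#' per marker (emission: the true state is observed with probability
#' `1 - eps_m`, each wrong state with `eps_m / 2`; missing calls are emitted
#' with state-independent probability and drop out of the likelihood) and a
#' recombination fraction per adjacent-marker interval (transmission:
#' [f2_transition_matrix()]). The initial distribution is the F2 segregation
#' (1/4, 1/2, 1/4). Parameters are estimated by expectation-maximisation over
#' the forward-backward statistics summed over plants, with closed-form
#' M-steps: `eps_m` from the expected mismatch fraction and `r_k` from the
#' expected number of recombinant gametes (each genotype transition is two
#' gamete transmissions).
#'
#' @param calls integer matrix (plants x ordered markers) of putative calls
#'   (1/2/3, `NA` missing).
#' @param eps0,r0 initial error rate and recombination fraction.
#' @param fix_eps optional fixed per-marker error rate (skips the eps
#'   M-step); recycled over markers.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return an object of class `hmm_fit`: `eps` (per marker), `r` (per
#'   interval), `loglik`, `posterior` (plants x markers x 3 array),
#'   `decoded` (max-posterior calls), `max_posterior`, `converged`,
#'   `n_iter`.
#' @export
fit_hmm <- function(calls, eps0 = 0.05, r0 = 0.05, fix_eps = NULL,
                    max_iter = 200, tol = 1e-4) {
  stopifnot(is.matrix(calls), ncol(calls) >= 2)
  if (!any(!is.na(calls))) stop("no non-missing calls")
  n <- nrow(calls); M <- ncol(calls)
  eps <- if (!is.null(fix_eps)) rep_len(fix_eps, M) else rep(eps0, M)
  r <- rep(r0, M - 1L)
  init <- c(0.25, 0.5, 0.25)
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  alpha <- beta <- vector("list", M)
  repeat {
    it <- it + 1L
    Elik <- lapply(seq_len(M), function(m) .emission_lik(calls[, m], eps[m]))
    Tm <- lapply(r, f2_transition_matrix)
    # forward with per-plant scaling
    logc <- matrix(0, n, M)
    a <- sweep(Elik[[1]], 2, init, "*")
    sc <- rowSums(a); logc[, 1] <- log(sc); a <- a / sc
    alpha[[1]] <- a
    for (m in 2:M) {
      a <- (a %*% Tm[[m - 1L]]) * Elik[[m]]
      sc <- rowSums(a); logc[, m] <- log(sc); a <- a / sc
      alpha[[m]] <- a
    }
    ll <- sum(logc)
    # backward (scaled)
    b <- matrix(1, n, 3); beta[[M]] <- b
    for (m in (M - 1L):1L) {
      b <- (b * Elik[[m + 1L]]) %*% t(Tm[[m]])
      b <- b / exp(logc[, m + 1L])
      beta[[m]] <- b
    }
    # E-step statistics and M-step
    gamma_sum_mis <- numeric(M); gamma_sum_obs <- numeric(M)
    new_eps <- eps
    for (m in seq_len(M)) {
      g <- alpha[[m]] * beta[[m]]
      g <- g / rowSums(g)
      ok <- !is.na(calls[, m])
      if (any(ok)) {
        obs <- calls[ok, m]
        match_w <- g[cbind(which(ok), obs)]
        gamma_sum_obs[m] <- sum(ok)
        gamma_sum_mis[m] <- sum(ok) - sum(match_w)
      }
      if (is.null(fix_eps) && gamma_sum_obs[m] > 0)
        new_eps[m] <- min(max(gamma_sum_mis[m] / gamma_sum_obs[m], 0), 0.49)
    }
    new_r <- r
    for (k in seq_len(M - 1L)) {
      # expected transition counts xi (3x3) summed over plants
      A <- alpha[[k]]; B <- beta[[k + 1L]] * Elik[[k + 1L]] /
        exp(logc[, k + 1L])
      X <- t(A) %*% B * Tm[[k]]
      X <- X / sum(X) * n
      rr <- r[k]
      e_ra_ra <- 2 * rr^2 / ((1 - rr)^2 + rr^2)  # expected recombinant gametes in RA->RA
      rec <- X[1, 2] + X[2, 1] + X[2, 3] + X[3, 2] +
        2 * (X[1, 3] + X[3, 1]) + X[2, 2] * e_ra_ra
      new_r[k] <- min(max(rec / (2 * sum(X)), 1e-9), 0.5)
    }
    if (abs(ll - ll_old) < tol) { converged <- TRUE }
    if (converged || it >= max_iter) {
      eps_final <- eps; r_final <- r
      break
    }
    eps <- new_eps; r <- new_r; ll_old <- ll
  }
  post <- array(NA_real_, c(n, M, 3),
                dimnames = list(rownames(calls), colnames(calls),
                                c("RR", "RA", "AA")))
  for (m in seq_len(M)) {
    g <- alpha[[m]] * beta[[m]]
    post[, m, ] <- g / rowSums(g)
  }
  maxp <- apply(post, c(1, 2), max)
  decoded <- apply(post, c(1, 2), which.max)
  structure(list(eps = eps_final, r = r_final, loglik = ll,
                 posterior = post, decoded = decoded, max_posterior = maxp,
                 converged = converged, n_iter = it),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("F2 genotyping HMM fit:", ncol(x$decoded), "markers,",
      nrow(x$decoded), "plants\n")
  cat(sprintf("logLik %.3f after %d EM iterations (%s)\n", x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("mean error rate %.4f; map length %.1f cM\n",
              mean(x$eps), sum(haldane_cM(x$r))))
  invisible(x)
}

#' Forward-algorithm log-likelihood of a call matrix
#'
#' Evaluates the HMM likelihood at given parameters without fitting; used for
#' diagnostics and for checking the fitted optimum.
#'
#' @inheritParams fit_hmm
#' @param eps per-marker error rates (recycled).
#' @param r per-interval recombination fractions.
#' @return total log-likelihood summed over plants.
#' @export
hmm_loglik <- function(calls, eps, r) {
  M <- ncol(calls)
  eps <- rep_len(eps, M)
  stopifnot(length(r) == M - 1L)
  a <- sweep(.emission_lik(calls[, 1], eps[1]), 2, c(0.25, 0.5, 0.25), "*")
  sc <- rowSums(a); ll <- sum(log(sc)); a <- a / sc
  for (m in 2:M) {
    a <- (a %*% f2_transition_matrix(r[m - 1L])) * .emission_lik(calls[, m], eps[m])
    sc <- rowSums(a); ll <- ll + sum(log(sc)); a <- a / sc
  }
  ll
}

#' Haldane map distance from a recombination fraction
#'
#' Inverse Haldane map function `d = -50 * ln(1 - 2r)` cM; `r = 0.5` is
#' capped at `cap` with a warning.
#'
#' @param r recombination fraction(s) in `[0, 0.5]`.
#' @param cap distance assigned where `r` is at (or numerically beyond) 0.5.
#' @return distances in cM.
#' @export
haldane_cM <- function(r, cap = 200) {
  stopifnot(all(r >= 0), all(r <= 0.5))
  d <- -50 * log(1 - 2 * r)
  if (any(!is.finite(d) | d > cap)) {
    warning("recombination fraction at 0.5; distance capped at ", cap, " cM")
    d[!is.finite(d) | d > cap] <- cap
  }
  d
}

#' Extract the genetic map from a fitted HMM
#'
#' Converts the fitted adjacent recombination fractions to cM via the inverse
#' Haldane function and accumulates positions from zero at the first marker.
#'
#' @param fit an `hmm_fit`, or a numeric vector of recombination fractions.
#' @param marker_ids optional marker names.
#' @param cap passed to [haldane_cM()].
#' @return data frame `marker`, `cM`, plus attribute `length_cM`.
#' @export
extract_map <- function(fit, marker_ids = NULL, cap = 200) {
  r <- if (inherits(fit, "hmm_fit")) fit$r else fit
  pos <- c(0, cumsum(haldane_cM(r, cap)))
  if (is.null(marker_ids) && inherits(fit, "hmm_fit"))
    marker_ids <- colnames(fit$decoded)
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_along(pos))
  out <- data.frame(marker = marker_ids, cM = pos)
  attr(out, "length_cM") <- pos[length(pos)]
  out
}

#' Interpolate genotypes at non-marker loci
#'
#' A gene flanked by two markers with the same decoded genotype inherits that
#' genotype; when the flanks disagree (a recombination event lies in the
#' interval) the gene is scored as unknown. Genes outside the flanked range
#' take the nearest marker's genotype; genes on a chromosome without markers
#' are unknown for all plants.
#'
#' @param marker_genotypes integer matrix (plants x markers) of decoded calls.
#' @param marker_pos data frame with `chrom` and `cM` for each marker column.
#' @param gene_pos data frame with `chrom` and `cM` for each target locus.
#' @return integer matrix (plants x genes) with `NA` for unknown.
#' @export
interpolate_genotypes <- function(marker_genotypes, marker_pos, gene_pos) {
  stopifnot(ncol(marker_genotypes) == nrow(marker_pos))
  n <- nrow(marker_genotypes)
  out <- matrix(NA_integer_, n, nrow(gene_pos),
                dimnames = list(rownames(marker_genotypes),
                                rownames(gene_pos)))
  for (ch in unique(gene_pos$chrom)) {
    gsel <- which(gene_pos$chrom == ch)
    msel <- which(marker_pos$chrom == ch)
    if (!length(msel)) next
    ord <- msel[order(marker_pos$cM[msel])]
    mpos <- marker_pos$cM[ord]
    for (gi in gsel) {
      x <- gene_pos$cM[gi]
      k <- findInterval(x, mpos)
      if (k == 0L) {
        out[, gi] <- marker_genotypes[, ord[1L]]
      } else if (mpos[k] == x) {
        out[, gi] <- marker_genotypes[, ord[k]]   # gene at a marker position
      } else if (k >= length(ord)) {
        out[, gi] <- marker_genotypes[, ord[length(ord)]]
      } else {
        left <- marker_genotypes[, ord[k]]
        right <- marker_genotypes[, ord[k + 1L]]
        same <- !is.na(left) & !is.na(right) & left == right
        out[same, gi] <- left[same]
      }
    }
  }
  out
}

#' Line-of-origin relatedness matrix
#'
#' Relatedness is twice the coefficient of coancestry, averaged over loci.
#' With founder lines assumed mutually unrelated and fully inbred, the
#' coancestry of two plants at one locus is a quarter of the number of
#' founder-line matches among the four cross-pairs of their alleles. A plant
#' of family z with alternative-allele dose d carries `2 - d` reference
#' alleles and `d` line-z alleles, so the whole computation reduces to two
#' matrix products. Values run from 0 (no shared founders) to 2 (fully
#' inbred identical genotypes).
#'
#' @param dose integer matrix (plants x loci) of alternative-allele doses,
#'   `NA` allowed.
#' @param family integer vector of family labels per plant (0 = plants of the
#'   reference line itself).
#' @param psd_repair if `TRUE`, adds the smallest ridge (at most
#'   `1e-6 * mean(diag)`) needed to make the marker-averaged matrix positive
#'   semi-definite, which marker averaging can leave slightly indefinite.
#' @return symmetric `n x n` matrix of class `relatedness` with the ridge (if
#'   any) recorded in attribute `ridge`; a plant pair with no jointly
#'   non-missing loci gets `NA`.
#' @export
relatedness <- function(dose, family, psd_repair = TRUE) {
  stopifnot(nrow(dose) == length(family))
  D <- dose
  obs <- !is.na(D)
  D[!obs] <- 0L
  Rm <- 2 - D
  Rm[!obs] <- 0L
  same_fam <- outer(family, family, "==") & family != 0L
  # reference-allele matches always count; alternative-allele matches only
  # count within the same family (different families carry different lines)
  cross <- Rm %*% t(Rm) + (D %*% t(D)) * same_fam
  # families share the alternative line with themselves; reference-line
  # parental plants (family 0) share reference alleles only, already counted
  nshared <- obs %*% t(obs)
  R <- cross / (2 * nshared)
  R[nshared == 0] <- NA_real_
  ridge <- 0
  if (psd_repair && !anyNA(R)) {
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < 0) {
      ridge <- -ev + 1e-10
      if (ridge > 1e-6 * mean(diag(R)))
        warning("relatedness matrix needed a ridge of ", signif(ridge, 3),
                " to become positive semi-definite")
      R <- R + diag(ridge, nrow(R))
    }
  }
  structure(R, class = c("relatedness", "matrix"), ridge = ridge)
}

#' Genotype a whole family from marker counts
#'
#' Convenience pipeline for one family: putative calls from allele-specific
#' marker counts, per-chromosome HMM fits, genetic map extraction, and
#' interpolation to gene positions. Markers whose fitted error rate exceeds
#' `max_eps` are flagged and excluded from interpolation.
#'
#' @param ref_count,alt_count plants x markers count matrices.
#' @param marker_pos data frame with `chrom`, `cM` per marker column.
#' @param gene_pos optional data frame with `chrom`, `cM` per gene for
#'   interpolation.
#' @param min_total,tau_hom see [call_putative()].
#' @param max_eps error-rate threshold above which a marker is excluded.
#' @param ... passed to [fit_hmm()].
#' @return list with `fits` (per chromosome), `decoded`, `max_posterior`,
#'   `map` (per-chromosome data frames), `eps`, `flagged_markers`, and
#'   `gene_genotypes` when `gene_pos` is given.
#' @export
genotype_family <- function(ref_count, alt_count, marker_pos,
                            gene_pos = NULL, min_total = 2, tau_hom = 0.15,
                            max_eps = 0.3, ...) {
  calls <- call_putative(ref_count, alt_count, min_total, tau_hom)
  chroms <- unique(marker_pos$chrom)
  fits <- list(); maps <- list()
  decoded <- matrix(NA_integer_, nrow(calls), ncol(calls),
                    dimnames = dimnames(calls))
  maxp <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  eps <- numeric(ncol(calls))
  for (ch in chroms) {
    sel <- which(marker_pos$chrom == ch)
    sel <- sel[order(marker_pos$cM[sel])]
    fit <- fit_hmm(calls[, sel, drop = FALSE], ...)
    fits[[as.character(ch)]] <- fit
    decoded[, sel] <- fit$decoded
    maxp[, sel] <- fit$max_posterior
    eps[sel] <- fit$eps
    maps[[as.character(ch)]] <- extract_map(fit)
  }
  flagged <- which(eps > max_eps)
  out <- list(fits = fits, decoded = decoded, max_posterior = maxp,
              map = maps, eps = eps, flagged_markers = flagged)
  if (!is.null(gene_pos)) {
    keep <- setdiff(seq_len(ncol(decoded)), flagged)
    out$gene_genotypes <- interpolate_genotypes(
      decoded[, keep, drop = FALSE], marker_pos[keep, , drop = FALSE],
      gene_pos)
  }
  out
}
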