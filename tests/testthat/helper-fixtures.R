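# Shared fixtures, built lazily and cached for the whole test run.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# compact two-chromosome study with a known cis architecture
fx_study <- function() fixture("study", function() {
  panel <- founder_panel(n_lines = 10, n_chrom = 2, chrom_length_cM = 90,
                         n_markers = 60, n_genes = 20)
  arch <- random_cis_architecture(panel, sigma_alpha = 0.5, Ve = 1,
                                  rng_seed = 5)
  simulate_study(panel, arch, n_per_family = 30, n_parental = 2, rng_seed = 2)
})

fx_K <- function() fixture("K", function() {
  st <- fx_study()
  relatedness(st$dose[, st$loci$type == "marker"], st$design$family)
})

fx_Keig <- function() fixture("Keig", function() eigen_kinship(fx_K()))

# genotype framework with a study-realistic 10-chromosome genome, used for
# estimator benchmarking and null calibration
fx_bench_truth <- function() fixture("bench_truth", function() {
  panel <- founder_panel(n_lines = 10, n_chrom = 10, chrom_length_cM = 90,
                         n_markers = 400, n_genes = 10)
  simulate_truth(panel, n_per_family = 25, n_parental = 2, rng_seed = 2)
})

fx_bench_K <- function() fixture("bench_K", function() {
  tr <- fx_bench_truth()
  relatedness(tr$dose[, tr$loci$type == "marker"], tr$design$family)
})

fx_bench_Keig <- function() fixture("bench_Keig",
                                    function() eigen_kinship(fx_bench_K()))

# larger families on the same genome, for recovery checks whose estimators
# need within-family relatedness information
fx_big_truth <- function() fixture("big_truth", function() {
  panel <- founder_panel(n_lines = 10, n_chrom = 10, chrom_length_cM = 90,
                         n_markers = 400, n_genes = 10)
  simulate_truth(panel, n_per_family = 60, n_parental = 2, rng_seed = 2)
})

fx_big_K <- function() fixture("big_K", function() {
  tr <- fx_big_truth()
  relatedness(tr$dose[, tr$loci$type == "marker"], tr$design$family)
})

fx_big_Keig <- function() fixture("big_Keig",
                                  function() eigen_kinship(fx_big_K()))

# dense multivariate-normal log-likelihood of the animal model, evaluated
# directly from the covariance matrix (independent oracle for fit_lmm)
dense_lmm_loglik <- function(y, X, K, beta, Vg, Ve) {
  n <- length(y)
  V <- Vg * unclass(K) + Ve * diag(n)
  r <- y - X %*% beta
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(V)$modulus +
                       crossprod(r, solve(V, r))))
}

# brute-force HMM likelihood: explicit sum over all 3^M hidden paths
brute_force_hmm_loglik <- function(calls, eps, r) {
  M <- ncol(calls)
  eps <- rep_len(eps, M)
  emis <- function(obs, s, e) {
    if (is.na(obs)) 1 else if (obs == s) 1 - e else e / 2
  }
  init <- c(0.25, 0.5, 0.25)
  Tm <- lapply(r, f2_transition_matrix)
  total <- 0
  paths <- as.matrix(expand.grid(rep(list(1:3), M)))
  for (i in seq_len(nrow(calls))) {
    lik <- 0
    for (p in seq_len(nrow(paths))) {
      s <- paths[p, ]
      w <- init[s[1]] * emis(calls[i, 1], s[1], eps[1])
      for (m in 2:M)
        w <- w * Tm[[m - 1]][s[m - 1], s[m]] * emis(calls[i, m], s[m], eps[m])
      lik <- lik + w
    }
    total <- total + log(lik)
  }
  total
}

# draw a phenotype with genetic covariance Vg*K plus iid noise
draw_polygenic <- function(n, Vg, Ve, chol_K) {
  sqrt(Vg) * drop(crossprod(chol_K, stats::rnorm(n))) +
    stats::rnorm(n, 0, sqrt(Ve))
}
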