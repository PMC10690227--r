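test_that("putative calls follow the fraction thresholds and coverage floor", {
  expect_identical(call_putative(10, 0, min_total = 2), 1L)
  expect_identical(call_putative(5, 5, min_total = 2), 2L)
  expect_identical(call_putative(0, 10, min_total = 2), 3L)
  expect_identical(call_putative(1, 0, min_total = 2), NA_integer_)
  expect_identical(call_putative(0, 0, min_total = 2), NA_integer_)
  # tau boundary: 15% alternative reads still calls RR
  expect_identical(call_putative(85, 15, min_total = 2), 1L)
  expect_identical(call_putative(84, 16, min_total = 2), 2L)
  expect_error(call_putative(-1, 3), "non-negative")
  # matrix input keeps shape
  m <- call_putative(matrix(c(9, 0, 5, 1), 2), matrix(c(0, 9, 5, 0), 2))
  expect_identical(dim(m), c(2L, 2L))
})

test_that("F2 transition matrix matches brute-force gamete transmission", {
  expect_equal(f2_transition_matrix(0), diag(3), ignore_attr = TRUE)
  T5 <- f2_transition_matrix(0.5)
  for (i in 1:3) expect_equal(unname(T5[i, ]), c(0.25, 0.5, 0.25))
  expect_error(f2_transition_matrix(0.7), "0.5")

  # brute force: each genotype is an (ordered) pair of gametes, each gamete
  # recombines independently with probability r
  brute <- function(r) {
    M <- matrix(0, 3, 3)
    for (g1 in 0:1) for (g2 in 0:1) for (x1 in 0:1) for (x2 in 0:1) {
      p <- 0.25 * (r^x1 * (1 - r)^(1 - x1)) * (r^x2 * (1 - r)^(1 - x2))
      from <- g1 + g2
      to <- ((g1 + x1) %% 2) + ((g2 + x2) %% 2)
      M[from + 1, to + 1] <- M[from + 1, to + 1] + p
    }
    M / rowSums(M)
  }
  for (r in c(0.1, 0.25, 0.4)) {
    expect_equal(unname(f2_transition_matrix(r)), brute(r), tolerance = 1e-12)
    expect_equal(rowSums(f2_transition_matrix(r)), c(RR = 1, RA = 1, AA = 1))
  }
  expect_equal(unname(f2_transition_matrix(0.1)[1, ]), c(0.81, 0.18, 0.01))
})

test_that("forward likelihood equals brute-force path summation", {
  set.seed(11)
  calls <- matrix(sample(c(1:3, NA), 8, replace = TRUE), 2, 4)
  calls[1, 1] <- 1L  # ensure at least one observation
  eps <- c(0.02, 0.1, 0.05, 0.3)
  r <- c(0.05, 0.2, 0.45)
  expect_equal(hmm_loglik(calls, eps, r),
               brute_force_hmm_loglik(calls, eps, r), tolerance = 1e-9)
})

test_that("HMM recovers generating parameters from synthetic families", {
  panel <- founder_panel(n_lines = 2, n_chrom = 1, chrom_length_cM = 90,
                         n_markers = 120, n_genes = 0)
  truth <- simulate_f2_family(panel, 2, 120, rng_seed = 31) + 1L
  attr(truth, "alt_line") <- NULL

  # error-free calls: eps ~ 0 and decoding near-perfect (an isolated
  # single-marker double recombinant may legitimately be smoothed away)
  fit <- fit_hmm(truth)
  expect_true(fit$converged)
  expect_lt(mean(fit$eps), 0.005)
  expect_gte(mean(fit$decoded == truth), 0.999)
  # posterior triples sum to one
  expect_equal(apply(fit$posterior, c(1, 2), sum),
               matrix(1, nrow(truth), ncol(truth)), ignore_attr = TRUE,
               tolerance = 1e-9)

  # with injected miscalls the error rate is recovered
  noisy <- inject_miscalls(truth, 0.05, rng_seed = 32)
  fit2 <- fit_hmm(noisy)
  expect_lt(abs(mean(fit2$eps) - 0.05), 0.015)
  expect_gt(mean(fit2$decoded == truth), 0.99)

  # single plant, two markers, calls (RR, RR), eps fixed 0: posterior RR = 1
  one <- fit_hmm(matrix(c(1L, 1L), 1, 2), fix_eps = 0)
  expect_equal(unname(one$posterior[1, , "RR"]), c(1, 1), tolerance = 1e-12)
})

test_that("map extraction inverts the Haldane function and round-trips", {
  expect_equal(attr(extract_map(c(0, 0, 0)), "length_cM"), 0)
  r10 <- (1 - exp(-0.2)) / 2
  expect_equal(haldane_cM(r10), 10, tolerance = 1e-10)
  expect_warning(d <- haldane_cM(0.5, cap = 150), "capped")
  expect_equal(d, 150)

  # simulate -> fit -> extract recovers the generating map within 10%
  panel <- founder_panel(n_lines = 2, n_chrom = 1, chrom_length_cM = 90,
                         n_markers = 100, n_genes = 0)
  truth <- simulate_f2_family(panel, 2, 400, rng_seed = 33) + 1L
  fit <- fit_hmm(inject_miscalls(truth, 0.02, rng_seed = 34))
  expect_equal(attr(extract_map(fit), "length_cM"), 90, tolerance = 0.10)
})

test_that("genotype interpolation applies the flanking-marker rule", {
  mg <- rbind(c(2L, 2L, 1L, 3L),
              c(1L, 1L, 1L, 1L))
  marker_pos <- data.frame(chrom = c(1, 1, 1, 2), cM = c(0, 10, 20, 5))
  gene_pos <- data.frame(chrom = c(1, 1, 1, 1, 2, 3),
                         cM = c(5, 15, 25, 10, 2, 1))
  out <- interpolate_genotypes(mg, marker_pos, gene_pos)
  # equal flanks inherit the genotype; unequal flanks are unknown
  expect_identical(unname(out[1, 1]), 2L)          # between equal RA..RA
  expect_identical(unname(out[1, 2]), NA_integer_) # flank mismatch
  expect_identical(unname(out[1, 3]), 1L)          # beyond last marker: nearest
  expect_identical(unname(out[1, 4]), 2L)          # exactly at marker 2
  expect_identical(unname(out[1, 5]), 3L)          # chromosome 2 single marker
  expect_identical(unname(out[1, 6]), NA_integer_) # chromosome without markers
  expect_true(all(out[2, 1:5] == 1L))
})

test_that("relatedness matches the line-of-origin coancestry expectations", {
  st <- fx_study()
  K <- fx_K()
  expect_true(isSymmetric(unclass(K)))
  expect_true(all(K >= -1e-8 & K <= 2 + 1e-8))

  design <- st$design
  par_ref <- which(design$generation == "P" & design$family == 0)
  par_alt2 <- which(design$generation == "P" & design$family == 2)
  par_alt3 <- which(design$generation == "P" & design$family == 3)
  # identical fully inbred plants: R = 2
  expect_equal(K[par_ref[1], par_ref[2]], 2, tolerance = 1e-6)
  expect_equal(K[par_alt2[1], par_alt2[2]], 2, tolerance = 1e-6)
  # plants of two different founder lines: R = 0
  expect_equal(K[par_alt2[1], par_alt3[1]], 0, tolerance = 1e-6)
  # F2s of different families: mean R ~ 0.5 (share only the reference parent)
  f2_2 <- which(design$generation == "F2" & design$family == 2)
  f2_3 <- which(design$generation == "F2" & design$family == 3)
  expect_equal(mean(K[f2_2, f2_3]), 0.5, tolerance = 0.05)
  # F2s within a family: mean R ~ 1
  expect_equal(mean(K[f2_2, f2_2][lower.tri(K[f2_2, f2_2])]), 1,
               tolerance = 0.07)
  # PSD after repair
  expect_gte(min(eigen(unclass(K), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
})

test_that("whole-family genotyping pipeline decodes to high accuracy", {
  st <- fx_study()
  fam2 <- st$design$family == 2 & st$design$generation == "F2"
  loci <- st$loci
  mk <- loci$type == "marker"
  gt <- genotype_family(st$marker_ref[fam2, ], st$marker_alt[fam2, ],
                        loci[mk, ], loci[!mk, ])
  truth <- st$dose[fam2, mk] + 1L
  expect_gt(mean(gt$decoded == truth), 0.98)
  # interpolated gene genotypes match the simulated truth where known
  gtruth <- st$dose[fam2, !mk] + 1L
  known <- !is.na(gt$gene_genotypes)
  expect_gt(mean(gt$gene_genotypes[known] == gtruth[known]), 0.98)
})
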