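test_that("meiosis crossover counts and positions follow the no-interference model", {
  expect_error(simulate_meiosis(-1), "non-negative")

  # zero-length map never recombines
  xo <- simulate_meiosis(0, n_gametes = 50, rng_seed = 1)
  expect_true(all(lengths(xo) == 0))

  # Poisson moments at 100 cM: mean and variance both ~1 per gamete
  xo <- simulate_meiosis(100, n_gametes = 8000, rng_seed = 42)
  k <- lengths(xo)
  expect_equal(mean(k), 1, tolerance = 0.05)
  expect_equal(var(k), 1, tolerance = 0.08)
  # positions uniform on the map
  pos <- unlist(xo)
  expect_true(all(pos >= 0 & pos <= 100))
  expect_equal(mean(pos), 50, tolerance = 2.5)
})

test_that("F2 families segregate 1:2:1 and recombine per the Haldane map", {
  panel <- founder_panel(n_lines = 3, n_chrom = 1, chrom_length_cM = 90,
                         n_markers = 2, n_genes = 0)
  expect_error(simulate_f2_family(panel, alt_line = 1, n_plants = 5),
               "reference")
  expect_error(simulate_f2_family(panel, alt_line = 2, n_plants = 0),
               "positive")

  dose <- simulate_f2_family(panel, 2, 4000, rng_seed = 7)
  # Mendelian segregation at a single locus
  frq <- table(factor(dose[, 1], levels = 0:2)) / nrow(dose)
  expect_equal(unname(as.vector(frq)), c(0.25, 0.5, 0.25), tolerance = 0.12)

  # markers 90 cM apart: realized recombination matches the Haldane fraction
  # r = (1 - exp(-2 * 0.9)) / 2 ~ 0.4174. Among plants homozygous at both
  # markers, a discordant pair requires both gametes recombinant, so the
  # discordance fraction estimates r^2 / (r^2 + (1 - r)^2).
  r_expected <- (1 - exp(-2 * 0.9)) / 2
  hom <- dose[, 1] != 1L & dose[, 2] != 1L
  rec_hom <- mean(dose[hom, 1] != dose[hom, 2])
  expect_lt(abs(rec_hom - r_expected^2 / (r_expected^2 + (1 - r_expected)^2)),
            0.05)

  # complete linkage: zero-length chromosome keeps loci identical
  panel0 <- founder_panel(n_lines = 3, n_chrom = 1, chrom_length_cM = 0,
                          n_markers = 2, n_genes = 0)
  dose0 <- simulate_f2_family(panel0, 2, 300, rng_seed = 8)
  expect_true(all(dose0[, 1] == dose0[, 2]))
})

test_that("simulated studies respect design invariants and are reproducible", {
  st <- fx_study()
  expect_true(all(st$dose %in% 0:2))
  # parental plants homozygous at every locus
  par_ref <- st$design$generation == "P" & st$design$family == 0
  par_alt <- st$design$generation == "P" & st$design$family > 0
  expect_true(all(st$dose[par_ref, ] == 0L))
  expect_true(all(st$dose[par_alt, ] == 2L))
  expect_true(all(st$gene_ref >= 0) && all(st$gene_alt >= 0))
  # homozygotes emit reads only from their own allele
  g <- st$loci$id[st$loci$type == "gene"][1]
  expect_true(all(st$gene_alt[st$dose[, g] == 0L, g] == 0L))
  expect_true(all(st$gene_ref[st$dose[, g] == 2L, g] == 0L))

  # bit-reproducible under the same seed
  st2 <- simulate_study(st$panel, st$arch, n_per_family = 30, n_parental = 2,
                        rng_seed = 2)
  expect_identical(st$dose, st2$dose)
  expect_identical(st$gene_alt, st2$gene_alt)

  # architecture validation
  expect_error(architecture(st$panel, Ve = -1), "non-negative")
  expect_error(
    architecture(st$panel,
                 trans = data.frame(locus = "nope", gene = g, a = 1, d = 0)),
    "unknown locus")
})

test_that("ASE coupling over-represents the high allele in heterozygote reads", {
  panel <- founder_panel(n_lines = 10, n_chrom = 1, chrom_length_cM = 50,
                         n_markers = 10, n_genes = 5)
  a <- matrix(0.8, 5, 10)  # every alternative allele increases expression
  arch <- architecture(panel, cis_a = a, ase_coupling = TRUE,
                       ase_strength = 1)
  st <- simulate_study(panel, arch, n_per_family = 40, n_parental = 0,
                       rng_seed = 3)
  g <- st$loci$id[st$loci$type == "gene"][3]
  het <- st$dose[, g] == 1L
  tot <- st$gene_ref[het, g] + st$gene_alt[het, g]
  frac <- st$gene_alt[het, g][tot > 0] / tot[tot > 0]
  expect_gt(mean(frac), 0.55)
})

test_that("miscall injection corrupts calls at the requested rate", {
  calls <- matrix(rep(1:3, length.out = 6000), 60, 100)
  out <- inject_miscalls(calls, 0.1, rng_seed = 4)
  expect_lt(abs(mean(out != calls) - 0.1), 0.015)
  expect_true(all(out %in% 1:3))
  expect_identical(inject_miscalls(calls, 0), calls)
  expect_error(inject_miscalls(calls, 1.5), "rate")
})

test_that("estimator benchmark validates inputs", {
  tr <- fx_bench_truth()
  expect_error(estimator_benchmark(tr, list(a = list(sigma_alpha = 0)),
                                   n_reps = 1), "at least 2")
  expect_error(estimator_benchmark(tr, list(a = list(sigma_alpha = 0)),
                                   n_reps = 2, estimators = "ridge"),
               "unknown estimator")
})
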