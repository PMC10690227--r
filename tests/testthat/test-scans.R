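test_that("marker regression solves the toy least-squares problem exactly", {
  # 6-plant table: doses 0,0,1,1,2,2 and y = 1,1,2,2,3,3 -> a = 1, d = 0
  mr <- marker_regression(c(1, 1, 2, 2, 3, 3), c(0, 0, 1, 1, 2, 2))
  expect_equal(mr$a, 1, tolerance = 1e-12)
  expect_equal(mr$d, 0, tolerance = 1e-12)
  expect_false(mr$skipped)

  # additive phenotype: dominance estimate stays near zero
  set.seed(81)
  dose <- sample(0:2, 200, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  y <- 0.5 * dose + rnorm(200, 0, 0.2)
  mr2 <- marker_regression(y, dose)
  expect_lt(abs(mr2$a - 0.5), 0.06)
  expect_lt(abs(mr2$d), 0.1)

  # monomorphic marker is skipped, not fitted
  expect_true(marker_regression(y, rep(1, 200))$skipped)
})

test_that("effect estimates recover the generating a and d", {
  set.seed(82)
  dose <- sample(0:2, 300, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  y <- 0.5 * dose + 0.25 * (dose == 1) + rnorm(300)
  mr <- marker_regression(y, dose)
  expect_lt(abs(mr$a - 0.5), 3.5 * mr$se_a)
  expect_lt(abs(mr$d - 0.25), 3.5 * mr$se_d)
})

test_that("permutation p-values are calibrated, reproducible and floor at 1/(B+1)", {
  st <- fx_study()
  fam2 <- st$design$family == 2 & st$design$generation == "F2"
  mk_chr1 <- st$loci$id[st$loci$type == "marker" & st$loci$chrom == 1]
  doses <- st$dose[fam2, mk_chr1[seq(1, length(mk_chr1), by = 2)]]
  set.seed(83)
  y_null <- rnorm(sum(fam2))
  expect_warning(permutation_pvalue(y_null, doses, n_perm = 50, rng_seed = 1),
                 "100 permutations")
  p1 <- permutation_pvalue(y_null, doses, n_perm = 150, rng_seed = 9)
  p2 <- permutation_pvalue(y_null, doses, n_perm = 150, rng_seed = 9)
  expect_identical(p1$perm_p, p2$perm_p)
  expect_true(all(p1$perm_p > 0 & p1$perm_p <= 1))
  # null phenotype: the best marker's genomewide p should not be extreme
  expect_gt(min(p1$perm_p), 1 / 151)

  # strong QTL at a scanned marker reaches the permutation floor
  y_qtl <- st$dose[fam2, mk_chr1[7]] * 1.5 + rnorm(sum(fam2), 0, 0.5)
  pq <- permutation_pvalue(y_qtl, doses, n_perm = 150, rng_seed = 10)
  expect_equal(min(pq$perm_p), 1 / 151)
})

test_that("trans hits chain into loci within the clustering window", {
  hits <- data.frame(family = 2, chrom = 1, cM = c(1.0, 2.5), gene = c("a", "b"))
  expect_equal(nrow(cluster_trans(hits)), 1)
  hits2 <- data.frame(family = 2, chrom = 1, cM = c(1.0, 3.5), gene = c("a", "b"))
  expect_equal(nrow(cluster_trans(hits2)), 2)

  # chaining: consecutive gaps under the window merge transitively
  hits3 <- data.frame(family = 2, chrom = 1, cM = c(0, 1.9, 3.8, 9),
                      gene = letters[1:4])
  cl3 <- cluster_trans(hits3)
  expect_equal(cl3$n_hits, c(3, 1))

  # input order does not matter
  shuffle <- hits3[c(3, 1, 4, 2), ]
  expect_equal(cluster_trans(shuffle)$n_hits, cl3$n_hits)

  # families and chromosomes are clustered separately
  hits4 <- data.frame(family = c(2, 3), chrom = 1, cM = c(1, 1.5),
                      gene = c("a", "b"))
  expect_equal(nrow(cluster_trans(hits4)), 2)

  # hotspot flag requires 30 distinct affected genes
  hits5 <- data.frame(family = 2, chrom = 1, cM = runif(35, 0, 1),
                      gene = sprintf("g%02d", 1:35))
  expect_true(cluster_trans(hits5)$hotspot)
  expect_false(cluster_trans(hits5[1:29, ])$hotspot)
  expect_warning(cluster_trans(rbind(hits5, data.frame(family = 2, chrom = 1,
                                                       cM = NA, gene = "x"))),
                 "without a cM position")
})

test_that("transcriptome PCA preserves trace, orthogonality and reconstruction", {
  st <- fx_study()
  ph <- apply(st$phenotype, 2, standardize)
  pcs <- pca_transcriptome(ph)
  G <- ncol(ph)
  expect_equal(sum(pcs$eigenvalues), G * nrow(ph) / (nrow(ph) - 1),
               tolerance = 0.05)
  # score columns are uncorrelated
  cc <- cor(pcs$scores[, 1:5])
  expect_equal(cc, diag(5), ignore_attr = TRUE, tolerance = 1e-9)
  expect_true(all(diff(pcs$var_explained) <= 1e-12))
  # loadings x scores reconstruct the centred matrix
  recon <- pcs$scores %*% t(pcs$loadings)
  expect_equal(recon, scale(ph, scale = FALSE), ignore_attr = TRUE,
               tolerance = 1e-6)
  # rank-1 input: first component carries everything
  u <- rnorm(50); v <- rnorm(8)
  pcs1 <- pca_transcriptome(outer(u, v))
  expect_gt(pcs1$var_explained[1], 0.999)
  expect_error(pca_transcriptome(cbind(const = rep(1, 50), x = rnorm(50))),
               "constant")
})

test_that("pcQTL scan decomposes the total LRT into additive and dominance parts", {
  st <- fx_study()
  Keig <- fx_Keig()
  genes <- st$loci$id[st$loci$type == "gene"]
  gd <- st$dose[, genes]
  gp <- st$loci[match(genes, st$loci$id), ]
  set.seed(84)
  score <- rnorm(nrow(gd))
  sc <- pc_qtl_scan(score, gd, gp, st$design$family, st$design$cohort, Keig,
                    step = 4)
  expect_equal(sc$all$LRT_total, sc$all$LRT_additive + sc$all$LRT_dominance,
               tolerance = 1e-9)
  expect_equal(sort(unique(sc$by_chrom$chrom)), c(1, 2))
  # pure-noise score should not clear the pcQTL threshold
  expect_false(any(sc$by_chrom$significant))
})
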