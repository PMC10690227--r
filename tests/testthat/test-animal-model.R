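test_that("eigen-rotated likelihood equals the dense multivariate-normal density", {
  st <- fx_study()
  K <- fx_K()
  set.seed(41)
  sub <- sample(nrow(K), 120)
  Ksub <- unclass(K)[sub, sub]
  Keig <- eigen_kinship(Ksub)
  chol_K <- chol(Ksub + diag(1e-8, 120))
  X <- cbind(1, rnorm(120))
  for (rep in 1:4) {
    y <- drop(X %*% c(1, 0.5)) + draw_polygenic(120, 0.5, 0.5, chol_K)
    fit <- fit_lmm(y, X, Keig)
    expect_equal(fit$loglik,
                 dense_lmm_loglik(y, X, Ksub, fit$beta, fit$Vg, fit$Ve),
                 tolerance = 1e-6)
  }
})

test_that("iid phenotypes collapse to the ordinary Gaussian fit", {
  Keig <- fx_Keig()
  n <- Keig$n
  set.seed(42)
  y <- rnorm(n)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_lmm(y, X, Keig)
  expect_equal(fit$Vg, 0, tolerance = 1e-3)
  # ML Gaussian log-likelihood of the intercept-only model
  s2 <- mean((y - mean(y))^2)
  ll0 <- -n / 2 * (log(2 * pi * s2) + 1)
  expect_equal(fit$loglik, ll0, tolerance = 1e-4)
})

test_that("singular designs fail loudly with the collinear column named", {
  Keig <- fx_Keig()
  n <- Keig$n
  X <- cbind(`(Intercept)` = 1, dup1 = rep(1, n))
  expect_error(fit_lmm(rnorm(n), X, Keig), "dup1")
})

test_that("heritability is recovered on average across simulated traits", {
  K <- fx_bench_K()
  Keig <- fx_bench_Keig()
  n <- Keig$n
  chol_K <- chol(unclass(K) + diag(1e-8, n))
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  set.seed(43)
  h2 <- replicate(60, {
    y <- draw_polygenic(n, 0.5, 0.75, chol_K)  # Vg/(Vg + Ve * ) on K scale
    fit <- fit_lmm(y, X, Keig)
    fit$Vg / (fit$Vg + fit$Ve)
  })
  # generating ratio s = 0.5/(0.5 + 0.75) = 0.4
  expect_lt(abs(mean(h2) - 0.4), 3 * sd(h2) / sqrt(60) + 0.02)
})

test_that("cis tests separate additive and dominance signal", {
  st <- fx_study()
  Keig <- fx_Keig()
  design <- st$design
  fam <- design$family
  set.seed(44)
  a_line <- c(0, rnorm(9, 0, 0.6))

  g <- st$loci$id[st$loci$type == "gene"][5]
  dose <- st$dose[, g]
  a_pl <- ifelse(fam == 0, 0, a_line[pmax(fam, 1)])

  # pure additive effect: LRT1 large, LRT2 near its chi-square null mean
  y_add <- a_pl * dose + rnorm(length(dose), 0, 1)
  ct <- cis_tests(y_add, dose, fam, design$cohort, Keig)
  expect_false(ct$untestable)
  expect_gt(ct$LRT1, 40)
  expect_lt(ct$LRT2, qchisq(0.999, 9))
  expect_equal(unname(ct$df), c(9, 9))

  # complete dominance (d = a): dominance estimates track the generating
  # additive effects one-for-one (regressed on the generating values to
  # avoid errors-in-variables attenuation)
  y_dom <- a_pl * dose + a_pl * (dose == 1) + rnorm(length(dose), 0, 0.3)
  ct2 <- cis_tests(y_dom, dose, fam, design$cohort, Keig)
  ratio <- sum(ct2$d_hat * a_line[2:10]) / sum(a_line[2:10]^2)
  expect_lt(abs(ratio - 1), 0.15)
  expect_gt(ct2$LRT2, qchisq(0.999, 9))

  # unknown genotypes are dropped; missing data requires the full matrix
  dose_na <- dose; dose_na[1:10] <- NA
  expect_error(cis_tests(y_add, dose_na, fam, design$cohort, Keig),
               "full relatedness")
  ct3 <- cis_tests(y_add, dose_na, fam, design$cohort, fx_K())
  expect_equal(ct3$n_used, length(dose) - 10)

  # non-segregating gene flagged untestable
  ct4 <- cis_tests(y_add, rep(0L, length(dose)), fam, design$cohort, Keig)
  expect_true(ct4$untestable)
})

test_that("model nesting holds: LL0 <= LL1 <= LL2 on random traits", {
  st <- fx_study()
  Keig <- fx_Keig()
  set.seed(45)
  for (g in sample(st$loci$id[st$loci$type == "gene"], 4)) {
    y <- standardize(st$phenotype[, g])
    ct <- cis_tests(y, st$dose[, g], st$design$family, st$design$cohort, Keig)
    expect_gte(ct$fit1$loglik, ct$fit0$loglik - 1e-6)
    expect_gte(ct$fit2$loglik, ct$fit1$loglik - 1e-6)
  }
})

test_that("locus-variance estimators compute their defining formulas", {
  # identical nested fits: contrast is zero
  st <- fx_study(); Keig <- fx_Keig()
  y <- standardize(st$phenotype[, 1])
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_lmm(y, X, Keig)
  expect_equal(vg_r2(f, f), 0)

  # worked dispersion example: a = (+0.5 x5, -0.5 x4), se^2 = 0.01
  a <- c(rep(0.5, 5), rep(-0.5, 4))
  expect_equal(vg_a(a, rep(0.1, 9)), 2 * (var(a) - 0.01))
  expect_equal(vg_a(a, rep(0.1, 9)), 0.535556, tolerance = 1e-6)
  # all equal, no error: zero
  expect_equal(vg_a(rep(0.3, 9), rep(0, 9)), 0)
  # noise-dominated: negative value reported, not clipped
  expect_equal(vg_a(rep(0, 9), rep(sqrt(0.05), 9)), -0.1)
  expect_error(vg_a(c(1, NA, NA, NA, NA, NA, NA, NA, NA), rep(0.1, 9)),
               "two finite")
})

test_that("Haseman-Elston regression matches closed-form least squares", {
  # pure noise: slope near zero on average
  K <- fx_K()
  set.seed(46)
  e0 <- replicate(20, he_regression(rnorm(nrow(K)), K))
  expect_lt(abs(mean(e0)), 3 * sd(e0) / sqrt(20) + 0.01)
  expect_error(he_regression(rnorm(3), diag(1, 3)), "no variation")

  # 5-plant toy: product form equals the hand-computed OLS slope
  Ktoy <- matrix(0.2, 5, 5); diag(Ktoy) <- 1
  Ktoy[1, 2] <- Ktoy[2, 1] <- 1.2
  Ktoy[3, 4] <- Ktoy[4, 3] <- 0.6
  y <- c(1.2, 0.8, -0.5, -0.9, 0.1)
  lo <- lower.tri(Ktoy)
  yc <- y - mean(y)
  cp <- tcrossprod(yc)[lo]; x <- Ktoy[lo]
  slope_hand <- sum((cp - mean(cp)) * (x - mean(x))) / sum((x - mean(x))^2)
  expect_equal(he_regression(y, Ktoy, form = "product"), slope_hand,
               tolerance = 1e-12)

  # difference form recovers a generating Vg of 0.4 on average
  chol_K <- chol(unclass(K) + diag(1e-8, nrow(K)))
  est <- replicate(40, he_regression(draw_polygenic(nrow(K), 0.4, 1, chol_K), K))
  expect_lt(abs(mean(est) - 0.4), 3 * sd(est) / sqrt(40) + 0.02)
})

test_that("over/underdominance test behaves under its generating models", {
  st <- fx_study()
  Keig <- fx_Keig()
  fam <- st$design$family
  g <- st$loci$id[st$loci$type == "gene"][8]
  dose <- st$dose[, g]
  set.seed(47)
  a_line <- c(0, rnorm(9, 0, 0.5)); a_line[2] <- 0.8
  a_pl <- ifelse(fam == 0, 0, a_line[pmax(fam, 1)])

  # complete dominance d = +a in every family: constraint fits, LRT_plus ~ 0
  y_cd <- a_pl * dose + a_pl * (dose == 1) + rnorm(length(dose), 0, 0.3)
  od <- overdominance_test(y_cd, dose, fam, st$design$cohort, Keig, z = 2)
  expect_lt(od$LRT_plus, qchisq(0.99, 1))
  expect_false(od$degenerate)

  # overdominant family 2 (d = 2a): unconstrained beats both constraints
  d_pl <- ifelse(fam == 2, 2 * a_line[2], 0)
  y_od <- a_pl * dose + d_pl * (dose == 1) + rnorm(length(dose), 0, 0.3)
  od2 <- overdominance_test(y_od, dose, fam, st$design$cohort, Keig, z = 2)
  expect_gt(od2$LRT, qchisq(0.95, 1))

  # additive gene action: partial dominance, not overdominance, and the
  # reportable statistic stays at the chi-square scale
  y_ad <- a_pl * dose + rnorm(length(dose), 0, 0.3)
  od3 <- overdominance_test(y_ad, dose, fam, st$design$cohort, Keig, z = 2)
  expect_gt(od3$LRT_plus, qchisq(0.95, 1))  # rejects complete dominance
  expect_gt(od3$LRT_minus, qchisq(0.95, 1))
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})
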