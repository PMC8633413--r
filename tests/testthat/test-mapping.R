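test_that("the null fit recovers simulation truth and the scan bookkeeping holds", {
  fx <- small_sim()
  ctl <- mapping_control(subtests = FALSE)
  null <- fit_null(fx$pheno, ctl)
  # psi was rescaled for heritability; phi and rho are untouched by scaling
  expect_lt(abs(null$psi[["phi_H"]] - 0.9), 0.1)
  expect_lt(abs(null$psi[["rho"]] - 0.5), 0.2)
  # pooled growth parameters near the class-average truth
  expect_lt(abs(null$theta[["K_H"]] - 25) / 25, 0.1)
  expect_lt(abs(null$theta[["K_D"]] - 30) / 30, 0.1)
})

test_that("the marker scan yields non-negative LRTs, monotone FDR, and detects the causal marker", {
  fx <- small_sim()
  ctl <- mapping_control(subtests = FALSE)
  scan <- lrt_scan(fx$pheno, fx$geno, ctl)
  r <- scan$results
  expect_true(all(r$lrt >= 0))
  expect_equal(r$df, 6 * (ifelse(r$segregation == "testcross", 2, 3) - 1))
  # BH adjustment is monotone in the raw p-values
  ord <- order(r$p_value)
  expect_true(all(diff(r$p_fdr[ord]) >= -1e-12))
  expect_true(all(r$p_fdr >= r$p_value - 1e-12))
  # the causal marker (H2 = 0.2 here) tops the scan
  expect_equal(r$marker_id[which.min(r$p_value)],
               fx$geno$info$marker_id[fx$cfg$causal_index])
  expect_true(r$significant[which.min(r$p_value)])
  # determinism: identical inputs give identical results
  scan2 <- lrt_scan(fx$pheno, fx$geno, ctl)
  expect_identical(scan$results, scan2$results)
})

test_that("class handling: sizes add up, small classes drop, monomorphic markers error", {
  fx <- small_sim()
  null <- fit_null(fx$pheno, mapping_control())
  codes <- fx$geno$codes[2, ]
  codes[1:4] <- NA
  f <- fit_alternative(fx$pheno, codes, null)
  expect_equal(sum(f$n_by_class), sum(!is.na(codes)))
  expect_equal(f$dropped, 4)
  # a class below the minimum size is dropped with a warning
  codes2 <- rep(0L, length(codes))
  codes2[1] <- 1L
  codes2[2:3] <- 2L
  expect_warning(f2 <- fit_alternative(fx$pheno, codes2, null), "dropping")
  expect_equal(length(f2$classes), 2)
  # monomorphic marker: degenerate
  expect_error(suppressWarnings(
    fit_alternative(fx$pheno, rep(0L, length(codes)), null)), "degenerate")
})

test_that("an empty marker list yields an empty scan", {
  fx <- small_sim()
  g0 <- fx$geno
  g0$codes <- g0$codes[0, , drop = FALSE]
  g0$info <- g0$info[0, ]
  scan <- lrt_scan(fx$pheno, g0, mapping_control(subtests = FALSE))
  expect_equal(nrow(scan$results), 0)
})

test_that("raw p-values are approximately uniform under the global null", {
  cfg <- sim_config(n = 100, p = 200, H2 = 0, seed = 23)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  scan <- lrt_scan(ph, g, mapping_control(subtests = FALSE))
  ks <- suppressWarnings(ks.test(scan$results$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("sub-hypothesis tests separate interaction effects from independent ones", {
  # marker affecting only the interaction coefficients
  cfg <- sim_config(n = 200, p = 2, H2 = 0.3, seed = 31)
  g <- simulate_genotypes(cfg)
  g$info$segregation[1] <- "testcross"
  g$codes[1, ] <- rep(0:1, length.out = 200)
  th0 <- unclass(default_cri_params())
  th1 <- th0; th1[["beta_HfromD"]] <- -0.016; th1[["beta_DfromH"]] <- 0.012
  th2 <- th0; th2[["beta_HfromD"]] <- -0.004; th2[["beta_DfromH"]] <- 0.000
  times <- cfg$times; T <- length(times)
  M <- vapply(list(th1, th2), function(th) {
    tr <- integrate_cri(as_cri_params(th), cfg$init, times, step = 0.05)
    c(tr$H, tr$D)
  }, numeric(2 * T))
  set.seed(31)
  E <- simulate_sad1(200, T, sad_params(0.9, 0.9, 0.35, 0.42, 0.5))
  Y <- t(M)[g$codes[1, ] + 1, ] + E
  ph <- cri_pheno(Y[, 1:T], Y[, T + 1:T], times)
  ctl <- mapping_control(subtests = FALSE)
  null <- fit_null(ph, ctl)
  alt <- fit_alternative(ph, g$codes[1, ], null, ctl)
  st <- subhypothesis_tests(ph, g$codes[1, ], alt, null, ctl)
  # nesting: constrained log-likelihoods cannot exceed the unconstrained one
  expect_lte(st$loglik_independent_constrained, st$loglik_alternative + 1e-6)
  expect_lte(st$loglik_interaction_constrained, st$loglik_alternative + 1e-6)
  # the interaction test fires, the independent test does not
  expect_lt(st$interaction[["p"]], 0.001)
  expect_gt(st$independent[["p"]], 0.01)
})

test_that("genetic effect curves match direct enumeration and are label-invariant", {
  th1 <- cri_params(0.5, 22, -0.01, 0.4, 27, 0.006)
  th2 <- cri_params(0.5, 28, -0.01, 0.4, 33, 0.006)
  init <- c(H = 0.8, D = 0.7)
  times <- 1:14
  ec <- genetic_effect_curves(list(th1, th2), c(0.5, 0.5), times, init)
  # two equally weighted classes: g(t) = |mu1(t) - mu2(t)| / 2
  m1 <- integrate_cri(th1, init, times)
  m2 <- integrate_cri(th2, init, times)
  expect_equal(ec$g1, abs(m1$H - m2$H) / 2)
  expect_equal(ec$g2, abs(m1$D - m2$D) / 2)
  expect_true(all(ec$g1 >= 0) && all(ec$g2 >= 0))
  # brute-force weighted-SD oracle on a random 3-class instance
  set.seed(5)
  ths <- lapply(1:3, function(i)
    cri_params(runif(1, .3, .7), runif(1, 18, 30), runif(1, -.015, .015),
               runif(1, .3, .6), runif(1, 22, 36), runif(1, -.01, .01)))
  w <- c(0.25, 0.5, 0.25)
  ec3 <- genetic_effect_curves(ths, w, times, init)
  M <- vapply(ths, function(th) integrate_cri(th, init, times)$H, numeric(14))
  orac <- sapply(seq_len(14), function(t) {
    mbar <- sum(w * M[t, ])
    sqrt(sum(w * (M[t, ] - mbar)^2))
  })
  expect_equal(ec3$g1, orac)
  # invariance to genotype-class relabeling
  ec3r <- genetic_effect_curves(ths[c(3, 1, 2)], w[c(3, 1, 2)], times, init)
  expect_equal(ec3$g1, ec3r$g1)
  expect_equal(ec3$dynamic_correlation, ec3r$dynamic_correlation)
  # correlation undefined at the shared initial state, bounded elsewhere
  dc <- ec3$dynamic_correlation
  expect_true(all(is.na(dc) | abs(dc) <= 1 + 1e-12))
  expect_true(all(is.finite(dc[-1])))
  # identical parameter sets give identically zero curves
  ec0 <- genetic_effect_curves(list(th1, th1), c(0.5, 0.5), times, init)
  expect_equal(ec0$g1, rep(0, 14))
})

test_that("the permutation null produces valid genome-wide p-values", {
  cfg <- sim_config(n = 40, p = 4, H2 = 0.3, seed = 13)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  set.seed(13)
  scan <- lrt_scan(ph, g, mapping_control(subtests = FALSE,
                                          null_method = "permutation",
                                          n_perm = 5))
  expect_true("p_genomewide" %in% names(scan$results))
  expect_true(all(scan$results$p_genomewide >= 0 &
                    scan$results$p_genomewide <= 1))
  # the strong causal marker beats every label permutation
  causal <- scan$results$marker_id == "snp0001"
  expect_equal(scan$results$p_genomewide[causal], 0)
})

test_that("effect_curves() extracts one curve per scanned marker with QTL flags", {
  fx <- small_sim()
  scan <- lrt_scan(fx$pheno, fx$geno, mapping_control(subtests = FALSE))
  ec <- effect_curves(scan)
  expect_equal(nrow(ec$g1), nrow(scan$results))
  expect_equal(ec$qtl, scan$results$significant)
  expect_true(all(ec$g1 >= 0) && all(ec$g2 >= 0))
})
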