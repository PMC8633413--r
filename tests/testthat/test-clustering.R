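test_that("the Legendre basis satisfies its defining identities", {
  b <- lop_basis(c(-1, 0.5, 1), 2)
  expect_equal(b$basis[, 1], rep(1, 3))          # P0 = 1
  expect_equal(b$basis[c(1, 3), 2], c(-1, 1))    # P1 at the interval ends
  expect_equal(b$basis[2, 3], (3 * 0.25 - 1) / 2)  # P2(0.5) = -0.125
  # orthogonality under dense-grid quadrature on [-1, 1]
  dense <- seq(-1, 1, length.out = 4001)
  V <- legendre_matrix(dense, 5)$val
  G <- crossprod(V) * (2 / 4000)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)), 1e-3)
  expect_warning(lop_basis(1:3, 3), "interpolation")
  expect_error(lop_basis(c(2, 2), 1), "distinct")
})

test_that("a single-component mixture degenerates to the GLS mean curve", {
  cs <- simulate_effect_curve_sets(1, 60, separation = 0, seed = 4)
  fit <- em_fit(cs, 1)
  expect_equal(fit$omega, 1)
  expect_true(all(fit$posterior == 1))
  # model mean equals the GLS projection of the sample mean curve
  Y <- cbind(cs$g1, cs$g2)
  T <- length(cs$times)
  B <- lop_basis(cs$times, fit$order)$basis
  X <- rbind(cbind(B, matrix(0, T, fit$order + 1)),
             cbind(matrix(0, T, fit$order + 1), B))
  S <- sad1_covariance(fit$psi_g, T)
  Qi <- solve(S)
  gls <- X %*% solve(t(X) %*% Qi %*% X, t(X) %*% Qi %*% colMeans(Y))
  expect_equal(as.vector(fit$u), as.vector(gls), tolerance = 1e-6)
})

test_that("EM recovers well-separated clusters exactly and increases the likelihood monotonically", {
  cs <- simulate_effect_curve_sets(2, 100, separation = 10, seed = 6)
  fit <- em_fit(cs, 2, cluster_control(restarts = 2))
  expect_equal(ari(fit$assignment, cs$labels), 1)
  expect_true(all(diff(fit$trace) >= -1e-8))
  # posterior rows sum to one; weights match posterior column means
  expect_equal(rowSums(fit$posterior), rep(1, 200), tolerance = 1e-12)
  expect_equal(fit$omega, colMeans(fit$posterior), tolerance = 1e-6)
})

test_that("restart seeds change labels at most by permutation", {
  cs <- simulate_effect_curve_sets(3, 60, separation = 8, seed = 8)
  f1 <- em_fit(cs, 3, cluster_control(restarts = 1, seed = 1))
  f2 <- em_fit(cs, 3, cluster_control(restarts = 1, seed = 99))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
  expect_equal(ari(f1$assignment, f2$assignment), 1)
})

test_that("information criteria select the true number of modules", {
  for (sd in c(13, 29)) {
    cs <- simulate_effect_curve_sets(3, 80, separation = 6, seed = sd)
    sel <- select_num_modules(cs, 1:5,
                              control = cluster_control(restarts = 2))
    expect_equal(sel$L, 3)
    tr <- attr(sel, "criterion_trace")
    expect_equal(nrow(tr), 5)  # one criterion value per candidate L
  }
  # degenerate single-shape data: L = 1 wins
  cs1 <- simulate_effect_curve_sets(2, 50, separation = 0, seed = 17)
  sel1 <- select_num_modules(cs1, 1:3,
                             control = cluster_control(restarts = 2))
  expect_equal(sel1$L, 1)
})

test_that("module means recombine and the module tree partitions markers", {
  cs <- simulate_effect_curve_sets(3, 50, separation = 8, seed = 21)
  fit <- em_fit(cs, 3, cluster_control(restarts = 2))
  mm <- module_mean_curves(fit, cs)
  # module of identical curves: empirical mean equals the member mean
  Y <- cbind(cs$g1, cs$g2)
  for (l in 1:3) {
    rows <- fit$assignment == l
    expect_equal(mm[l, ], colMeans(Y[rows, , drop = FALSE]))
  }
  # weighted recombination of module means reproduces the grand mean
  w <- tabulate(fit$assignment, 3) / length(fit$assignment)
  expect_equal(as.vector(t(mm) %*% w), colMeans(Y))
  # tree: subclustering children partition the parent's member set
  tree <- module_tree(fit, cs)
  expect_equal(sort(unname(unlist(lapply(tree$nodes, function(n)
    if (is.null(n$parent)) n$members else character(0))))), sort(cs$ids))
  tree2 <- subcluster(tree, "M1", 1:2,
                      control = cluster_control(restarts = 2))
  kids <- tree2$nodes[["M1"]]$children
  expect_true(all(grepl("^SM[0-9]+/M1$", kids)))
  got <- sort(unname(unlist(lapply(tree2$nodes[kids], `[[`, "members"))))
  expect_equal(got, sort(tree2$nodes[["M1"]]$members))
  # a node too small to split is left alone with a warning
  tiny <- tree2
  tiny$nodes[["M2"]]$members <- tiny$nodes[["M2"]]$members[1]
  expect_warning(subcluster(tiny, "M2", 2:3), "too small")
})
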