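test_that("Legendre smoothing reproduces polynomials and their derivatives", {
  times <- 1:14
  y <- 2 + 0.5 * times - 0.03 * times^2
  sm <- smooth_and_interpolate(y, times, order = 2)
  expect_lt(max(abs(sm$dense_values -
                      (2 + 0.5 * sm$dense_times - 0.03 * sm$dense_times^2))),
            1e-10)
  # constant curve: zero derivative
  smc <- smooth_and_interpolate(rep(3, 14), times, order = 3)
  expect_lt(max(abs(smc$dense_deriv)), 1e-10)
  # analytic derivative matches central finite differences
  y2 <- exp(-0.2 * times) * sin(times / 3)
  sm2 <- smooth_and_interpolate(y2, times, order = 6, n_dense = 400,
                                tol = 0.5)
  fd <- diff(sm2$dense_values) / diff(sm2$dense_times)
  mid <- (sm2$dense_deriv[-1] + sm2$dense_deriv[-400]) / 2
  expect_lt(max(abs(fd - mid)), 1e-3)
  expect_error(smooth_and_interpolate(1:3, 1:3, order = 3), "order")
})

test_that("selection recovers a planted proportional regulator among decoys", {
  # focal rate of change = baseline trend + 2 x one candidate's curve
  # (node2, itself a regulated node so its shape is distinctive);
  # 20 decoy candidates of independent shape
  sys <- simulate_planted_network(22, data.frame(source = c(1, 2),
                                                 target = c(2, 22),
                                                 strength = c(0.5, 2)),
                                  noise_sd = 0.003, seed = 7)
  ctl <- network_control(seed = 7)
  sm <- lapply(sys$curves, function(v)
    smooth_and_interpolate(v, sys$times, order = ctl$order_smooth, tol = 1))
  spec <- select_regulators(sm[["node22"]], sm[paste0("node", 1:21)], ctl)
  expect_equal(spec$support, "node2")
  expect_gt(spec$coefficients[["node2"]], 0)
  expect_equal(unname(spec$coefficients[["node2"]]), 2, tolerance = 0.1)
  # in-degree cap of zero forces an empty support
  ctl0 <- network_control(max_in_degree = 0)
  expect_length(select_regulators(sm[["node22"]], sm[paste0("node", 1:21)],
                                  ctl0)$support, 0)
  # no candidates at all
  expect_length(select_regulators(sm[["node22"]], list(), ctl)$support, 0)
})

test_that("the ODE decomposition recovers a planted dependent term and conserves the derivative", {
  sys <- simulate_planted_network(2, data.frame(source = 1, target = 2,
                                                strength = 0.5),
                                  noise_sd = 0.002, seed = 11)
  ctl <- network_control(seed = 11)
  sm <- lapply(sys$curves, function(v)
    smooth_and_interpolate(v, sys$times, order = ctl$order_smooth, tol = 1))
  spec <- select_regulators(sm[["node2"]], sm["node1"], ctl)
  expect_equal(spec$support, "node1")
  dec <- fit_ode_decomposition(sm[["node2"]], spec, sm["node1"], ctl)
  # dependent component matches 0.5 x regulator curve
  planted <- 0.5 * sm[["node1"]]$dense_values
  expect_lt(sqrt(mean((dec$dependent_deriv[, "node1"] - planted)^2)) /
              mean(abs(planted)), 0.05)
  # conservation: components sum to the smoothed derivative exactly
  total <- dec$independent_deriv + rowSums(dec$dependent_deriv)
  expect_lt(max(abs(total - sm[["node2"]]$dense_deriv)) /
              max(abs(sm[["node2"]]$dense_deriv)), 1e-6)
  # RK4 reconstruction follows the smoothed focal curve
  expect_lt(dec$reconstruction_rmse,
            0.02 * diff(range(sm[["node2"]]$dense_values)))
  # no regulators: the independent component is the smoothed derivative
  dec0 <- fit_ode_decomposition(sm[["node2"]], structure(list(
    coefficients = numeric(0), support = character(0)),
    class = "regression_spec"), list(), ctl)
  expect_equal(dec0$independent_deriv, sm[["node2"]]$dense_deriv)
  # edge weight and sign
  ed <- edge_from_decomposition(dec, "node2")
  expect_equal(ed$sign, "activation")
  expect_equal(ed$weight, mean(abs(dec$dependent_deriv[, "node1"])))
  # flipping the coupling sign flips the edge, preserving the weight
  sys2 <- simulate_planted_network(2, data.frame(source = 1, target = 2,
                                                 strength = -0.5),
                                   noise_sd = 0.002, seed = 11)
  sm2 <- lapply(sys2$curves, function(v)
    smooth_and_interpolate(v, sys2$times, order = ctl$order_smooth, tol = 1))
  spec2 <- select_regulators(sm2[["node2"]], sm2["node1"], ctl)
  dec2 <- fit_ode_decomposition(sm2[["node2"]], spec2, sm2["node1"], ctl)
  ed2 <- edge_from_decomposition(dec2, "node2")
  expect_equal(ed2$sign, "inhibition")
  expect_equal(ed2$weight, ed$weight, tolerance = 0.05)
})

test_that("a constructed three-node chain is recovered exactly with correct signs", {
  sys <- simulate_planted_network(3, data.frame(source = c(1, 2),
                                                target = c(2, 3),
                                                strength = c(0.45, 0.45)),
                                  noise_sd = 0.005, seed = 5)
  net <- suppressWarnings(
    build_layer_network(sys$curves, sys$times, trait = "height",
                        layer = "local", control = network_control(seed = 5)))
  got <- sort(paste(net$edges$source, net$edges$target, sep = ">"))
  expect_equal(got, c("node1>node2", "node2>node3"))
  expect_true(all(net$edges$sign == "activation"))
  # degree bookkeeping: handshake identity
  dd <- degree_distribution(net)
  expect_equal(dd$degrees$out_degree, c(1L, 1L, 0L))
  expect_equal(dd$degrees$in_degree, c(0L, 1L, 1L))
  expect_equal(sum(dd$degrees$out_degree), nrow(net$edges))
  # node deconstruction conserves the node curve
  rep3 <- deconstruct_node_effect(net, "node3")
  net_curve <- rep3$value[rep3$component == "net"]
  parts <- rep3$value[rep3$component == "independent"]
  for (s in unique(sub("^dependent:", "",
                       grep("^dependent:", rep3$component, value = TRUE))))
    parts <- parts + rep3$value[rep3$component == paste0("dependent:", s)]
  expect_lt(max(abs(net_curve - parts)) / diff(range(net_curve)), 0.05)
})

test_that("mutually independent curves yield (nearly) empty networks, deterministically", {
  indeg <- numeric(5)
  for (s in 1:5) {
    cs <- simulate_effect_curve_sets(6, 1, separation = 5, seed = 200 + s)
    cm <- cs$g1
    rownames(cm) <- paste0("n", 1:6)
    net <- suppressWarnings(
      build_layer_network(cm, cs$times, control = network_control(seed = s,
                                                                  smooth_tol = 1)))
    indeg[s] <- nrow(net$edges) / 6
  }
  expect_lte(mean(indeg), 1)
  # determinism: identical inputs and seed give identical edge lists
  sys <- simulate_planted_network(4, data.frame(source = 1, target = 2,
                                                strength = 0.4), seed = 3)
  n1 <- suppressWarnings(build_layer_network(sys$curves, sys$times,
                                             control = network_control(seed = 7)))
  n2 <- suppressWarnings(build_layer_network(sys$curves, sys$times,
                                             control = network_control(seed = 7)))
  expect_identical(n1$edges, n2$edges)
})

test_that("the independent variant can reuse the overall support", {
  sys <- simulate_planted_network(3, data.frame(source = c(1, 2),
                                                target = c(2, 3),
                                                strength = c(0.45, 0.45)),
                                  noise_sd = 0.005, seed = 5)
  overall <- suppressWarnings(
    build_layer_network(sys$curves, sys$times,
                        control = network_control(seed = 5)))
  ctl <- network_control(seed = 5, reuse_support = TRUE)
  indep <- suppressWarnings(
    build_layer_network(sys$curves, sys$times, variant = "independent",
                        control = ctl, reuse_from = overall))
  expect_equal(indep$variant, "independent")
  for (nd in indep$nodes$id)
    expect_equal(indep$decompositions[[nd]]$support,
                 overall$decompositions[[nd]]$support)
})

test_that("networks export to igraph and edge-list files", {
  sys <- simulate_planted_network(3, data.frame(source = c(1, 2),
                                                target = c(2, 3),
                                                strength = c(0.5, -0.5)),
                                  noise_sd = 0.005, seed = 13)
  net <- suppressWarnings(
    build_layer_network(sys$curves, sys$times,
                        control = network_control(seed = 13)))
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  f <- tempfile(fileext = ".csv")
  gml <- tempfile(fileext = ".graphml")
  write_network(net, f, graphml = gml)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(net$edges))
  expect_true(file.exists(gml))
})
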