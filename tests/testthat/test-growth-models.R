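test_that("CRI right-hand side matches direct substitution and its equilibria", {
  # uncoupled equilibrium at the asymptotes
  th <- cri_params(1, 10, 0, 1, 7, 0)
  expect_equal(unname(cri_rhs(c(H = 10, D = 7), th)), c(0, 0))
  # logistic term alone
  expect_equal(cri_rhs(c(H = 5, D = 3), th)[["dH"]], 2.5)
  # coupling term adds alpha * beta * H * D
  th2 <- cri_params(1, 10, 0.1, 1, 7, 0)
  expect_equal(cri_rhs(c(H = 5, D = 2), th2)[["dH"]], 2.5 + 1.0)
  expect_error(cri_rhs(c(H = NaN, D = 1), th), "non-finite")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(cri_params(-1, 10, 0, 1, 7, 0), "positive")
  expect_error(cri_params(1, 0, 0, 1, 7, 0), "positive")
  expect_silent(cri_params(1, 10, -5, 1, 7, 5))
  expect_error(sad_params(0.5, 0.5, -1, 1, 0), "positive")
  expect_error(sad_params(0.5, 0.5, 1, 1, 1.2), "rho")
  expect_warning(sad_params(1.5, 0.5, 1, 1, 0), "phi")
})

test_that("RK4 integration matches the closed-form logistic limit", {
  th <- cri_params(0.5, 10, 0, 0.4, 8, 0)
  tr <- integrate_cri(th, c(H = 1, D = 0.5), seq(1, 14))
  expect_lt(max(abs(tr$H - logistic_closed(1:14, 0.5, 10, 1, 1))), 1e-6)
  expect_lt(max(abs(tr$D - logistic_closed(1:14, 0.4, 8, 0.5, 1))), 1e-6)
  # single-time grid returns the initial state
  tr0 <- integrate_cri(th, c(H = 2, D = 3), times = 5)
  expect_equal(unlist(tr0[1, ]), c(time = 5, H = 2, D = 3))
})

test_that("RK4 agrees with a fine-step forward-Euler oracle and converges at 4th order", {
  th <- cri_params(0.6, 2, 0.15, 0.5, 1.5, -0.1)
  init <- c(H = 0.3, D = 0.2)
  times <- c(0, 0.5, 1)
  orac <- euler_oracle(th, init, times, h = 1e-5)
  tr <- integrate_cri(th, init, times, step = 0.01)
  expect_lt(max(abs(cbind(tr$H, tr$D) - orac)), 1e-5)
  # halving a coarse step shrinks the deviation from the oracle by >= 8x
  dev_h <- max(abs(cbind(integrate_cri(th, init, times, step = 0.5)$H,
                         integrate_cri(th, init, times, step = 0.5)$D) - orac))
  dev_h2 <- max(abs(cbind(integrate_cri(th, init, times, step = 0.25)$H,
                          integrate_cri(th, init, times, step = 0.25)$D) - orac))
  expect_gte(dev_h / dev_h2, 8)
})

test_that("growth decomposition conserves the full derivative and tracks coupling signs", {
  set.seed(1)
  for (rep in 1:10) {
    th <- cri_params(runif(1, 0.2, 0.8), runif(1, 10, 30),
                     runif(1, -0.02, 0.02), runif(1, 0.2, 0.6),
                     runif(1, 10, 30), runif(1, -0.02, 0.02))
    tr <- integrate_cri(th, c(H = 0.8, D = 0.7), 1:14)
    d <- decompose_growth(th, tr)
    rhs <- t(vapply(seq_len(nrow(tr)),
                    function(i) cri_rhs(c(H = tr$H[i], D = tr$D[i]), th),
                    numeric(2)))
    expect_equal(d$independent_H + d$interactive_H, rhs[, 1])
    expect_equal(d$independent_D + d$interactive_D, rhs[, 2])
    expect_true(all(sign(d$interactive_H) ==
                      sign(th[["beta_HfromD"]]) |
                      d$interactive_H == 0))
  }
  # zero coupling: interactive components identically zero
  tr <- integrate_cri(theta_uncoupled, c(H = 1, D = 1), 1:10)
  d <- decompose_growth(theta_uncoupled, tr)
  expect_true(all(d$interactive_H == 0) && all(d$interactive_D == 0))
})

test_that("trajectories saturate monotonically under non-negative coupling", {
  set.seed(2)
  for (rep in 1:5) {
    th <- cri_params(runif(1, 0.2, 0.8), runif(1, 10, 30),
                     runif(1, 0, 0.01), runif(1, 0.2, 0.6),
                     runif(1, 10, 30), runif(1, 0, 0.01))
    tr <- integrate_cri(th, c(H = 0.5, D = 0.5), 1:14)
    expect_true(all(diff(tr$H) >= -1e-10))
    expect_true(all(diff(tr$D) >= -1e-10))
  }
})

test_that("strategy classification is total over all sign combinations", {
  expect_equal(classify_strategy(0, 0), "neutral")
  expect_equal(classify_strategy(0.1, 0), "cooperative")
  expect_equal(classify_strategy(-0.2, 0.3), "antagonistic")
  # the 1e-8 zero tolerance absorbs floating-point dust
  expect_equal(classify_strategy(1e-12, -1e-15), "neutral")
})

test_that("the CRI fit recovers its own parameters from noise-free data", {
  tr <- integrate_cri(theta_default, c(H = 0.8, D = 0.7), 1:14)
  fit <- fit_cri(tr$H, tr$D, tr$time)
  expect_lt(max(abs(coef(fit) - unclass(theta_default)) /
                  abs(unclass(theta_default))), 0.01)
  expect_gte(fit$r_squared[["overall"]], 0.999)
  expect_equal(fit$strategy, "antagonistic")
  # methods behave
  expect_equal(unname(coef(fit)), as.numeric(fit$params))
  expect_equal(nrow(predict(fit, times = c(2, 5, 9))), 3)
  expect_length(residuals(fit), 28)
})

test_that("on uncoupled logistic data the CRI fit finds negligible interaction and nests the logistic", {
  tr <- integrate_cri(theta_uncoupled, c(H = 1, D = 0.6), 1:14)
  fit <- fit_cri(tr$H, tr$D, tr$time)
  expect_lt(abs(coef(fit)[["beta_HfromD"]]), 1e-4)
  expect_lt(abs(coef(fit)[["beta_DfromH"]]), 1e-4)
  expect_equal(classify_strategy(coef(fit)[["beta_HfromD"]],
                                 coef(fit)[["beta_DfromH"]], tol = 1e-4),
               "neutral")
  # nesting against the uncoupled model itself: the CRI least-squares fit
  # cannot do worse than the best pair of fixed-init logistic curves, which
  # is the beta = 0 submodel (checked on noisy data so the scale is stable)
  set.seed(8)
  yH <- tr$H * exp(rnorm(14, 0, 0.02))
  yD <- tr$D * exp(rnorm(14, 0, 0.02))
  fitn <- fit_cri(yH, yD, tr$time)
  nested_sse <- function(y) {
    obj <- function(p) sum((logistic_closed(tr$time, exp(p[1]), exp(p[2]),
                                            y[1], 1) - y)^2)
    optim(c(log(0.5), log(1.05 * max(y))), obj,
          control = list(maxit = 2000, reltol = 1e-12))$value
  }
  expect_lte(fitn$sse, nested_sse(yH) + nested_sse(yD) + 1e-6)
})

test_that("classical growth fits recover known parameters and flag degenerate input", {
  times <- 1:14
  y <- 22 * exp(-3 * exp(-0.35 * times))
  g <- fit_classical("gompertz", y, times)
  expect_lt(max(abs(g$params - c(22, 3, 0.35)) / c(22, 3, 0.35)), 1e-4)
  expect_gte(g$r_squared, 0.99999)
  yk <- 30 * exp(-4 * times^(-1.2))
  k <- fit_classical("korf", yk, times)
  expect_lt(max(abs(k$params - c(30, 4, 1.2)) / c(30, 4, 1.2)), 1e-4)
  d <- fit_classical("gompertz", rep(5, 14), times)
  expect_true(d$degenerate)
  expect_equal(unname(d$params["a"]), 5)
  expect_error(fit_classical("weibull", y, times), "supported")
})

test_that("the CRI fit outperforms classical single-trait fits on coupled data", {
  tr <- integrate_cri(theta_default, c(H = 0.8, D = 0.7), 1:14)
  fit <- fit_cri(tr$H, tr$D, tr$time)
  for (m in c("gompertz", "korf", "richards", "logistic")) {
    cl_H <- fit_classical(m, tr$H, tr$time)
    expect_gte(fit$r_squared[["height"]], cl_H$r_squared - 1e-6)
  }
})
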