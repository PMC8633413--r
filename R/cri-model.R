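#' Right-hand side of the CRI growth system
#'
#' Evaluates the derivatives (dH/dt, dD/dt) of the coupled regulatory
#' interaction system at a given state. Each derivative is the sum of an
#' independent (self-regulated logistic) component and an interactive
#' component proportional to the product of the two traits.
#'
#' @param state numeric vector with elements `H` and `D` (non-negative trait
#'   values); an optional `t` element is ignored (the system is autonomous).
#' @param params a [cri_params()] object.
#' @return Named numeric vector `c(dH, dD)`.
#' @export
cri_rhs <- function(state, params) {
  params <- as_cri_params(params)
  H <- state[["H"]]; D <- state[["D"]]
  if (!is.finite(H) || !is.finite(D))
    stop("non-finite trait state", call. = FALSE)
  c(dH = params[["alpha_H"]] * (1 - H / params[["K_H"]]) * H +
      params[["alpha_H"]] * params[["beta_HfromD"]] * H * D,
    dD = params[["alpha_D"]] * (1 - D / params[["K_D"]]) * D +
      params[["alpha_D"]] * params[["beta_DfromH"]] * D * H)
}

#' Integrate the CRI system with fixed-step RK4
#'
#' Classic fourth-order Runge-Kutta with a fixed internal step, evaluated at
#' the requested observation times. The trajectory starts exactly at the
#' initial state.
#'
#' @param params a [cri_params()] object.
#' @param init numeric vector with elements `H` and `D`: state at `times[1]`.
#' @param times strictly increasing numeric vector of evaluation times.
#' @param step internal RK4 step (years); the last sub-step of each interval
#'   is shortened to land exactly on the requested time.
#' @return A data frame with columns `time`, `H`, `D` of class
#'   `cri_trajectory`.
#' @export
integrate_cri <- function(params, init, times, step = 0.01) {
  params <- as_cri_params(params)
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  H0 <- init[["H"]]; D0 <- init[["D"]]
  if (!is.finite(H0) || !is.finite(D0) || H0 < 0 || D0 < 0)
    stop("initial state must be finite and non-negative", call. = FALSE)
  m <- cri_rk4_cpp(as.numeric(params), H0, D0, as.numeric(times), step)
  structure(data.frame(time = times, H = m[, 1], D = m[, 2]),
            class = c("cri_trajectory", "data.frame"),
            params = params, step = step)
}

#' Decompose a CRI trajectory into independent and interactive growth
#'
#' Evaluates, along a coupled trajectory, the self-regulated derivative
#' components and the interaction-driven derivative components of each trait,
#' together with their running (trapezoid) integrals. At every time point the
#' independent and interactive derivative components sum exactly to the full
#' right-hand side of the system.
#'
#' @param params the [cri_params()] the trajectory was integrated under.
#' @param trajectory a `cri_trajectory` from [integrate_cri()], or any data
#'   frame with columns `time`, `H`, `D`.
#' @return A list of class `cri_decomposition` with derivative components
#'   (`independent_H`, `interactive_H`, `independent_D`, `interactive_D`) and
#'   the matching cumulative curves (`cum_*`).
#' @export
decompose_growth <- function(params, trajectory) {
  params <- as_cri_params(params)
  if (!all(c("time", "H", "D") %in% names(trajectory)))
    stop("trajectory must have columns time, H, D", call. = FALSE)
  t <- trajectory$time; H <- trajectory$H; D <- trajectory$D
  if (length(t) != length(H) || length(t) != length(D))
    stop("trajectory columns have mismatched lengths", call. = FALSE)
  ind_H <- params[["alpha_H"]] * (1 - H / params[["K_H"]]) * H
  int_H <- params[["alpha_H"]] * params[["beta_HfromD"]] * H * D
  ind_D <- params[["alpha_D"]] * (1 - D / params[["K_D"]]) * D
  int_D <- params[["alpha_D"]] * params[["beta_DfromH"]] * D * H
  structure(list(times = t,
                 independent_H = ind_H, interactive_H = int_H,
                 independent_D = ind_D, interactive_D = int_D,
                 cum_independent_H = cumtrapz(t, ind_H),
                 cum_interactive_H = cumtrapz(t, int_H),
                 cum_independent_D = cumtrapz(t, ind_D),
                 cum_interactive_D = cumtrapz(t, int_D)),
            class = "cri_decomposition")
}

# running trapezoid integral, 0 at the first point
cumtrapz <- function(t, y) {
  n <- length(t)
  if (n == 1L) return(0)
  c(0, cumsum(0.5 * diff(t) * (y[-n] + y[-1])))
}

#' Classify the trait-interaction strategy
#'
#' Maps the signs of the two interaction coefficients to the strategy set:
#' both (numerically) zero is `neutral`; at least one positive and none
#' negative is `cooperative` (one trait promotes the other without being
#' hindered); any negative coefficient is `antagonistic` (at least one trait's
#' growth is inhibited by the other).
#'
#' @param beta_HfromD,beta_DfromH interaction coefficients.
#' @param tol absolute threshold below which a coefficient is treated as zero;
#'   exact zeros never arise in floating point estimates.
#' @return One of `"neutral"`, `"cooperative"`, `"antagonistic"`.
#' @export
classify_strategy <- function(beta_HfromD, beta_DfromH, tol = 1e-8) {
  if (!is.finite(beta_HfromD) || !is.finite(beta_DfromH))
    stop("interaction coefficients must be finite", call. = FALSE)
  b1 <- if (abs(beta_HfromD) < tol) 0 else sign(beta_HfromD)
  b2 <- if (abs(beta_DfromH) < tol) 0 else sign(beta_DfromH)
  if (b1 < 0 || b2 < 0) return("antagonistic")
  if (b1 > 0 || b2 > 0) return("cooperative")
  "neutral"
}

# method-of-moments starting values for the CRI fit: asymptote a bit above the
# observed maximum, rate from the early log-slope, no interaction
moment_start <- function(y, times) {
  K <- 1.05 * max(y)
  i <- seq_len(min(4L, length(y)))
  sl <- stats::coef(stats::lm(log(pmax(y[i], 1e-8)) ~ times[i]))[2]
  alpha <- max(min(sl, 3), 0.05)
  c(alpha = unname(alpha), K = K)
}

# optimizer scale: (log aH, log KH, bHD, log aD, log KD, bDH)
theta_to_opt <- function(theta) {
  c(log(theta[1]), log(theta[2]), theta[3], log(theta[4]), log(theta[5]),
    theta[6])
}
opt_to_theta <- function(par) {
  c(exp(par[1]), exp(par[2]), par[3], exp(par[4]), exp(par[5]), par[6])
}

#' Fit the CRI system to observed height and diameter trajectories
#'
#' Nonlinear least squares on the RK4 solution of the CRI system, minimised by
#' the Nelder-Mead simplex with multiple restarts from a perturbed
#' method-of-moments grid. The initial state is fixed at the first
#' observations, keeping six free parameters.
#'
#' @param height,diameter numeric vectors of observed trait values.
#' @param times observation times (strictly increasing, length >= 6).
#' @param init_params optional [cri_params()] starting point added to the
#'   restart set.
#' @param control a [cri_control()] list.
#' @return An object of class `cri_fit` with elements `params`
#'   ([cri_params()]), `fitted` (data frame), `residuals`, `r_squared`
#'   (overall and per trait), `sse`, `logLik`, `AIC`, `BIC`, `strategy`, and
#'   `convergence`.
#' @examples
#' th <- cri_params(0.5, 20, -0.01, 0.4, 25, 0.005)
#' tr <- integrate_cri(th, c(H = 1, D = 1), 1:14)
#' fit <- fit_cri(tr$H, tr$D, tr$time)
#' coef(fit)
#' @export
fit_cri <- function(height, diameter, times, init_params = NULL,
                    control = cri_control()) {
  T <- length(times)
  if (T < 6L) stop("need at least 6 time points (six free parameters)",
                   call. = FALSE)
  if (length(height) != T || length(diameter) != T)
    stop("trait vectors must match times in length", call. = FALSE)
  if (any(height <= 0) || any(diameter <= 0))
    stop("trajectories must be positive", call. = FALSE)

  obs <- c(height, diameter)
  Q <- diag(2 * T)
  s2 <- sum(obs^2)
  H0 <- height[1]; D0 <- diameter[1]
  obj <- function(par) {
    cri_negq_cpp(opt_to_theta(par), H0, D0, times, control$step, Q, obs, s2, 1)
  }

  mh <- moment_start(height, times)
  md <- moment_start(diameter, times)
  base <- c(mh["alpha"], mh["K"], 0, md["alpha"], md["K"], 0)
  starts <- list(base)
  if (!is.null(init_params)) starts <- c(starts, list(as.numeric(as_cri_params(init_params))))
  # log-spaced perturbations of rate and asymptote, small +/- interaction seeds
  fac <- exp(seq(-0.7, 0.7, length.out = 4))
  k <- 1L
  while (length(starts) < control$n_starts) {
    f <- fac[(k - 1L) %% length(fac) + 1L]
    bseed <- c(0, 0.2 / md["K"], -0.2 / md["K"])[(k - 1L) %/% length(fac) %% 3 + 1L]
    starts <- c(starts, list(c(base[1] * f, base[2] * f^0.3, bseed,
                               base[4] / f, base[5] * f^-0.3, -bseed)))
    k <- k + 1L
  }

  best <- NULL
  for (s in starts[seq_len(control$n_starts)]) {
    o <- try(stats::optim(theta_to_opt(s), obj, method = "Nelder-Mead",
                          control = list(maxit = control$maxit,
                                         reltol = control$reltol)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("CRI fit failed from every start", call. = FALSE)
  # polish the winner
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = control$maxit,
                                      reltol = control$reltol))

  theta <- as_cri_params(opt_to_theta(best$par))
  traj <- integrate_cri(theta, c(H = H0, D = D0), times, step = control$step)
  res_H <- traj$H - height
  res_D <- traj$D - diameter
  sse <- sum(res_H^2) + sum(res_D^2)
  r2 <- function(res, y) 1 - sum(res^2) / sum((y - mean(y))^2)
  n_obs <- 2 * T
  sigma2 <- sse / n_obs
  ll <- -n_obs / 2 * (log(2 * pi * sigma2) + 1)
  k_par <- 7  # six growth parameters + residual variance
  structure(list(params = theta,
                 fitted = traj,
                 residuals = c(height = res_H, diameter = res_D),
                 r_squared = c(overall = 1 - sse /
                                 sum((obs - mean(obs))^2),
                               height = r2(res_H, height),
                               diameter = r2(res_D, diameter)),
                 sse = sse,
                 logLik = ll, AIC = -2 * ll + 2 * k_par,
                 BIC = -2 * ll + k_par * log(n_obs),
                 strategy = classify_strategy(theta[["beta_HfromD"]],
                                              theta[["beta_DfromH"]],
                                              control$beta_tol),
                 init = c(H = H0, D = D0), times = times,
                 data = list(height = height, diameter = diameter),
                 convergence = best$convergence, control = control),
            class = "cri_fit")
}

#' @export
print.cri_fit <- function(x, digits = 4, ...) {
  cat("CRI growth fit (", length(x$times), " time points)\n", sep = "")
  print(round(unclass(x$params), digits))
  cat("interaction strategy:", x$strategy, "\n")
  cat(sprintf("R^2: overall %.4f (height %.4f, diameter %.4f)\n",
              x$r_squared["overall"], x$r_squared["height"],
              x$r_squared["diameter"]))
  cat(sprintf("AIC %.2f  BIC %.2f\n", x$AIC, x$BIC))
  invisible(x)
}

#' @export
coef.cri_fit <- function(object, ...) unclass(object$params)

#' @export
logLik.cri_fit <- function(object, ...) {
  structure(object$logLik, df = 7, class = "logLik")
}

#' @export
residuals.cri_fit <- function(object, ...) object$residuals

#' @export
fitted.cri_fit <- function(object, ...) object$fitted

#' @export
predict.cri_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted)
  integrate_cri(object$params, object$init, times,
                step = object$control$step)
}

#' @export
summary.cri_fit <- function(object, ...) {
  dec <- decompose_growth(object$params, object$fitted)
  out <- list(fit = object, decomposition = dec)
  class(out) <- "summary.cri_fit"
  out
}

#' @export
print.summary.cri_fit <- function(x, ...) {
  print(x$fit)
  d <- x$decomposition
  n <- length(d$times)
  cat(sprintf("cumulative growth at t = %g: height %.2f (independent %.2f, interactive %.2f)\n",
              d$times[n], d$cum_independent_H[n] + d$cum_interactive_H[n],
              d$cum_independent_H[n], d$cum_interactive_H[n]))
  cat(sprintf("                         diameter %.2f (independent %.2f, interactive %.2f)\n",
              d$cum_independent_D[n] + d$cum_interactive_D[n],
              d$cum_independent_D[n], d$cum_interactive_D[n]))
  invisible(x)
}

#' @export
plot.cri_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$times, x$data$height, xlab = "time", ylab = "height",
                 main = "height", ...)
  graphics::lines(x$fitted$time, x$fitted$H, col = 2)
  graphics::plot(x$times, x$data$diameter, xlab = "time", ylab = "diameter",
                 main = "diameter", ...)
  graphics::lines(x$fitted$time, x$fitted$D, col = 4)
  invisible(x)
}

classical_models <- list(
  gompertz = list(
    f = function(t, p) p[1] * exp(-p[2] * exp(-p[3] * t)),
    npar = 3, lower_pos = c(TRUE, TRUE, TRUE)),
  korf = list(
    f = function(t, p) p[1] * exp(-p[2] * t^(-p[3])),
    npar = 3, lower_pos = c(TRUE, TRUE, TRUE)),
  richards = list(
    # 4-parameter form y = a (1 - b exp(-c t))^(1/(1-m)), m != 1
    f = function(t, p) {
      base <- 1 - p[2] * exp(-p[3] * t)
      if (any(base <= 0) || abs(1 - p[4]) < 1e-6) return(rep(NA_real_, length(t)))
      p[1] * base^(1 / (1 - p[4]))
    },
    npar = 4, lower_pos = c(TRUE, TRUE, TRUE, FALSE)),
  logistic = list(
    f = function(t, p) p[1] / (1 + p[2] * exp(-p[3] * t)),
    npar = 3, lower_pos = c(TRUE, TRUE, TRUE))
)

#' Fit a classical single-trait growth equation
#'
#' Least-squares fits of the Gompertz (`a exp(-b exp(-c t))`), Korf
#' (`a exp(-b t^-c)`), Richards (`a (1 - b exp(-c t))^(1/(1-m))`) or logistic
#' (`a / (1 + b exp(-c t))`) curve, for accuracy/complexity comparison against
#' the CRI system.
#'
#' @param model_name one of `"gompertz"`, `"korf"`, `"richards"`,
#'   `"logistic"`.
#' @param y observed trait values.
#' @param times observation times.
#' @param n_starts simplex restarts.
#' @return An object of class `classical_fit` with `params`, `r_squared`,
#'   `residuals`, `AIC`, `BIC`, and a `degenerate` flag (set for constant
#'   input, where the asymptote equals the constant and the rate is 0).
#' @export
fit_classical <- function(model_name, y, times, n_starts = 8) {
  if (!model_name %in% names(classical_models))
    stop("unsupported model '", model_name, "'; supported: ",
         paste(names(classical_models), collapse = ", "), call. = FALSE)
  spec <- classical_models[[model_name]]
  T <- length(times)
  if (length(y) != T) stop("y and times must match in length", call. = FALSE)

  if (stats::sd(y) < 1e-12 * max(abs(y), 1)) {
    p <- c(a = mean(y), b = 0, c = 0, m = 0.5)[seq_len(spec$npar)]
    return(structure(list(model_name = model_name, params = p,
                          r_squared = NA_real_, residuals = rep(0, T),
                          fitted = rep(mean(y), T), sse = 0,
                          AIC = NA_real_, BIC = NA_real_, degenerate = TRUE),
                     class = "classical_fit"))
  }

  to_opt <- function(p) ifelse(spec$lower_pos, log(p), p)
  to_nat <- function(q) ifelse(spec$lower_pos, exp(q), q)
  obj <- function(q) {
    yy <- spec$f(times, to_nat(q))
    if (anyNA(yy) || any(!is.finite(yy))) return(1e12)
    sum((yy - y)^2)
  }
  K <- 1.05 * max(y)
  base <- switch(model_name,
    gompertz = c(K, max(log(K / max(y[1], 1e-8)), 0.1), 0.3),
    korf = c(1.2 * K, 3, 1),
    richards = c(K, 0.9, 0.3, 0.5),
    logistic = c(K, max(K / max(y[1], 1e-8) - 1, 0.1), 0.3))
  fac <- exp(seq(-0.6, 0.6, length.out = n_starts))
  best <- NULL
  for (i in seq_len(n_starts)) {
    st <- base * c(1, fac[i], fac[n_starts + 1 - i], 1)[seq_len(spec$npar)]
    o <- try(stats::optim(to_opt(st), obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("classical fit failed for ", model_name, call. = FALSE)
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 4000, reltol = 1e-13))
  p <- to_nat(best$par)
  names(p) <- c("a", "b", "c", "m")[seq_len(spec$npar)]
  fit <- spec$f(times, p)
  res <- fit - y
  sse <- sum(res^2)
  sigma2 <- sse / T
  ll <- -T / 2 * (log(2 * pi * max(sigma2, 1e-300)) + 1)
  k_par <- spec$npar + 1
  structure(list(model_name = model_name, params = p,
                 r_squared = 1 - sse / sum((y - mean(y))^2),
                 residuals = res, fitted = fit, sse = sse, logLik = ll,
                 AIC = -2 * ll + 2 * k_par, BIC = -2 * ll + k_par * log(T),
                 degenerate = FALSE),
            class = "classical_fit")
}

#' @export
print.classical_fit <- function(x, digits = 4, ...) {
  cat(x$model_name, "growth fit\n")
  print(round(x$params, digits))
  if (isTRUE(x$degenerate)) cat("degenerate fit (constant input)\n")
  else cat(sprintf("R^2 %.4f  AIC %.2f  BIC %.2f\n", x$r_squared, x$AIC, x$BIC))
  invisible(x)
}
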