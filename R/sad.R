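#' SAD(1) longitudinal covariance matrix
#'
#' Closed-form covariance of the stacked vector (trait 1 at times 1..T, then
#' trait 2 at times 1..T) under the bivariate first-order structured
#' antedependence process `y_r(t) = phi_r y_r(t-1) + eps_r(t)`, `y_r(0) = 0`,
#' with innovation standard deviations `nu_r` and contemporaneous innovation
#' correlation `rho`. For `s <= t`,
#' \deqn{Cov(y_r(s), y_r(t)) = \nu_r^2 \phi_r^{t-s} (1-\phi_r^{2s})/(1-\phi_r^2)}
#' \deqn{Cov(y_1(s), y_2(t)) = \rho \nu_1 \nu_2 \phi_2^{t-s}
#'   (1-(\phi_1\phi_2)^s)/(1-\phi_1\phi_2)}
#' with the `phi -> 1` limits taken by continuity.
#'
#' @param psi a [sad_params()] object.
#' @param T number of time points (>= 2).
#' @return A symmetric positive-definite `2T x 2T` matrix.
#' @export
sad1_covariance <- function(psi, T) {
  psi <- as_sad_params(psi)
  if (T < 2) stop("T must be at least 2", call. = FALSE)
  phi1 <- psi[["phi_H"]]; phi2 <- psi[["phi_D"]]
  nu1 <- psi[["nu_H"]]; nu2 <- psi[["nu_D"]]; rho <- psi[["rho"]]

  # geometric partial sum sum_{u=0}^{s-1} q^u with the q -> 1 limit
  gsum <- function(q, s) if (abs(1 - q) < 1e-12) s else (1 - q^s) / (1 - q)

  own_block <- function(phi, nu) {
    lag <- abs(outer(1:T, 1:T, "-"))
    smin <- outer(1:T, 1:T, pmin)
    nu^2 * phi^lag * matrix(gsum(phi^2, smin), T, T)
  }
  # cross block C[s, t] = Cov(y1(s), y2(t))
  smin <- outer(1:T, 1:T, pmin)
  lag <- outer(1:T, 1:T, "-")  # s - t
  phi_pow <- ifelse(lag <= 0, phi2^(-lag), phi1^lag)
  C <- rho * nu1 * nu2 * phi_pow * matrix(gsum(phi1 * phi2, smin), T, T)

  rbind(cbind(own_block(phi1, nu1), C),
        cbind(t(C), own_block(phi2, nu2)))
}

# cholesky of the SAD(1) covariance; error names psi if not PD
sad1_chol <- function(psi, T) {
  S <- sad1_covariance(psi, T)
  U <- try(chol(S), silent = TRUE)
  if (inherits(U, "try-error"))
    stop("SAD(1) covariance not positive definite for psi = (",
         paste(signif(unclass(as_sad_params(psi)), 4), collapse = ", "), ")",
         call. = FALSE)
  U
}

#' Log-likelihood of bivariate longitudinal trajectories
#'
#' Sum over individuals of the log density of a 2T-dimensional normal with a
#' shared mean curve and SAD(1) covariance, computed via the Cholesky
#' factorization.
#'
#' @param Y numeric matrix, one row per individual, columns = trait 1 at
#'   times 1..T then trait 2 at times 1..T.
#' @param mu mean vector of length 2T (stacked the same way).
#' @param psi a [sad_params()] object, or a pre-computed covariance matrix.
#' @return The log-likelihood (scalar).
#' @export
bivariate_loglik <- function(Y, mu, psi) {
  Y <- as.matrix(Y)
  m <- ncol(Y)
  if (length(mu) != m) stop("mean vector length must match data columns",
                            call. = FALSE)
  if (is.matrix(psi)) {
    U <- try(chol(psi), silent = TRUE)
    if (inherits(U, "try-error"))
      stop("covariance matrix not positive definite", call. = FALSE)
  } else {
    U <- sad1_chol(psi, m %/% 2L)
  }
  loglik_chol(Y, mu, U)
}

# loglik given upper Cholesky factor of Sigma
loglik_chol <- function(Y, mu, U) {
  n <- nrow(Y); m <- ncol(Y)
  R <- sweep(Y, 2L, mu)
  V <- backsolve(U, t(R), transpose = TRUE)
  quad <- sum(V * V)
  logdet <- 2 * sum(log(diag(U)))
  -0.5 * (n * m * log(2 * pi) + n * logdet + quad)
}

#' Simulate bivariate SAD(1) residual paths
#'
#' Draws `n` independent realizations of the bivariate SAD(1) process over
#' `T` time points, returned as an `n x 2T` matrix (trait 1 columns first).
#'
#' @param n number of paths.
#' @param T number of time points.
#' @param psi a [sad_params()] object.
#' @return `n x 2T` numeric matrix.
#' @export
simulate_sad1 <- function(n, T, psi) {
  psi <- as_sad_params(psi)
  phi1 <- psi[["phi_H"]]; phi2 <- psi[["phi_D"]]
  nu1 <- psi[["nu_H"]]; nu2 <- psi[["nu_D"]]; rho <- psi[["rho"]]
  E1 <- matrix(0, n, T); E2 <- matrix(0, n, T)
  prev1 <- numeric(n); prev2 <- numeric(n)
  a <- sqrt(1 - rho^2)
  for (t in seq_len(T)) {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    prev1 <- phi1 * prev1 + nu1 * z1
    prev2 <- phi2 * prev2 + nu2 * (rho * z1 + a * z2)
    E1[, t] <- prev1
    E2[, t] <- prev2
  }
  cbind(E1, E2)
}
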