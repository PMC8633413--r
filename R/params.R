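#' Coupled regulatory interaction (CRI) parameters
#'
#' Container for the six parameters of the CRI growth system
#' \deqn{dH/dt = \alpha_H (1 - H/K_H) H + \alpha_H \beta_{H \leftarrow D} H D}
#' \deqn{dD/dt = \alpha_D (1 - D/K_D) D + \alpha_D \beta_{D \leftarrow H} D H}
#' Each trait's growth rate splits into a self-regulated logistic part and an
#' interaction part driven by the co-existing trait. The interaction
#' coefficients `beta_HfromD` and `beta_DfromH` may take either sign: positive
#' values mean the companion trait promotes growth, negative values mean it
#' inhibits growth.
#'
#' @param alpha_H,alpha_D intrinsic growth rates (1/year), must be positive.
#' @param K_H,K_D asymptotic trait values (trait units), must be positive.
#' @param beta_HfromD dependence of height growth on diameter (per diameter
#'   unit); unrestricted in sign.
#' @param beta_DfromH dependence of diameter growth on height (per height
#'   unit); unrestricted in sign.
#' @return An object of class `cri_params` (named numeric vector of length 6).
#' @examples
#' cri_params(0.5, 25, -0.01, 0.4, 30, 0.006)
#' @export
cri_params <- function(alpha_H, K_H, beta_HfromD, alpha_D, K_D, beta_DfromH) {
  p <- c(alpha_H = alpha_H, K_H = K_H, beta_HfromD = beta_HfromD,
         alpha_D = alpha_D, K_D = K_D, beta_DfromH = beta_DfromH)
  validate_cri_params(p)
  structure(p, class = "cri_params")
}

validate_cri_params <- function(p) {
  if (length(p) != 6L || anyNA(p) || !all(is.finite(p)))
    stop("CRI parameters must be 6 finite numbers", call. = FALSE)
  if (p[["alpha_H"]] <= 0 || p[["alpha_D"]] <= 0)
    stop("growth rates alpha_H, alpha_D must be positive", call. = FALSE)
  if (p[["K_H"]] <= 0 || p[["K_D"]] <= 0)
    stop("asymptotes K_H, K_D must be positive", call. = FALSE)
  invisible(p)
}

#' @export
print.cri_params <- function(x, digits = 4, ...) {
  cat("CRI growth parameters:\n")
  print(round(unclass(x), digits))
  cat("interaction strategy:", classify_strategy(x[["beta_HfromD"]],
                                                 x[["beta_DfromH"]]), "\n")
  invisible(x)
}

as_cri_params <- function(x) {
  if (inherits(x, "cri_params")) return(x)
  x <- unlist(x)
  nm <- c("alpha_H", "K_H", "beta_HfromD", "alpha_D", "K_D", "beta_DfromH")
  if (!is.null(names(x)) && all(nm %in% names(x))) x <- x[nm]
  names(x) <- nm
  validate_cri_params(x)
  structure(x, class = "cri_params")
}

#' SAD(1) covariance parameters
#'
#' Parameters of the bivariate first-order structured antedependence model for
#' longitudinal residuals: each trait's residual at time t is `phi` times its
#' residual at t - 1 plus an innovation; innovations of the two traits at the
#' same time have standard deviations `nu_H`, `nu_D` and correlation `rho`.
#'
#' @param phi_H,phi_D antedependence coefficients (unitless). Values with
#'   `|phi| >= 1` are allowed but produce variance growing without bound and
#'   trigger a warning.
#' @param nu_H,nu_D innovation standard deviations (trait units), positive.
#' @param rho innovation cross-correlation, `|rho| < 1`.
#' @return An object of class `sad_params` (named numeric vector of length 5).
#' @export
sad_params <- function(phi_H, phi_D, nu_H, nu_D, rho) {
  p <- c(phi_H = phi_H, phi_D = phi_D, nu_H = nu_H, nu_D = nu_D, rho = rho)
  validate_sad_params(p)
  structure(p, class = "sad_params")
}

validate_sad_params <- function(p) {
  if (length(p) != 5L || anyNA(p) || !all(is.finite(p)))
    stop("SAD(1) parameters must be 5 finite numbers", call. = FALSE)
  if (p[["nu_H"]] <= 0 || p[["nu_D"]] <= 0)
    stop("innovation standard deviations nu_H, nu_D must be positive",
         call. = FALSE)
  if (abs(p[["rho"]]) >= 1)
    stop("innovation cross-correlation rho must satisfy |rho| < 1",
         call. = FALSE)
  if (abs(p[["phi_H"]]) >= 1 || abs(p[["phi_D"]]) >= 1)
    warning("|phi| >= 1: residual variance grows without bound over time")
  invisible(p)
}

as_sad_params <- function(x) {
  if (inherits(x, "sad_params")) return(x)
  x <- unlist(x)
  nm <- c("phi_H", "phi_D", "nu_H", "nu_D", "rho")
  if (!is.null(names(x)) && all(nm %in% names(x))) x <- x[nm]
  names(x) <- nm
  validate_sad_params(x)
  structure(x, class = "sad_params")
}

#' @export
print.sad_params <- function(x, digits = 4, ...) {
  cat("SAD(1) covariance parameters:\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Control settings for CRI trajectory fitting
#'
#' @param step internal RK4 step in years.
#' @param n_starts number of simplex restarts from the perturbed
#'   method-of-moments grid (the likelihood surface of coupled ODE fits is
#'   multimodal).
#' @param maxit,reltol passed to [stats::optim()] (Nelder-Mead).
#' @param beta_tol absolute threshold below which an interaction coefficient is
#'   treated as zero when classifying the interaction strategy.
#' @return A named list of class `cri_control`.
#' @export
cri_control <- function(step = 0.01, n_starts = 10, maxit = 1000,
                        reltol = 1e-10, beta_tol = 1e-8) {
  structure(list(step = step, n_starts = n_starts, maxit = maxit,
                 reltol = reltol, beta_tol = beta_tol),
            class = "cri_control")
}
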