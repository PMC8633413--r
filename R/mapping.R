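#' Bivariate longitudinal phenotype container
#'
#' Holds height and diameter measurements for `n` individuals on a shared
#' (balanced) time grid.
#'
#' @param height,diameter `n x T` numeric matrices, one row per individual.
#' @param times observation times (length `T`, strictly increasing).
#' @param ids optional individual identifiers.
#' @return An object of class `cri_pheno`.
#' @export
cri_pheno <- function(height, diameter, times, ids = NULL) {
  height <- as.matrix(height); diameter <- as.matrix(diameter)
  T <- length(times)
  if (ncol(height) != T || ncol(diameter) != T)
    stop("trait matrices must have one column per time point", call. = FALSE)
  if (nrow(height) != nrow(diameter))
    stop("trait matrices must have the same number of individuals",
         call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(height)))
  structure(list(height = height, diameter = diameter, times = times,
                 ids = as.character(ids)),
            class = "cri_pheno")
}

#' @export
print.cri_pheno <- function(x, ...) {
  cat("bivariate longitudinal phenotypes:", nrow(x$height), "individuals,",
      length(x$times), "time points\n")
  invisible(x)
}

#' Control settings for the marker scan
#'
#' @param alpha genome-wide significance level; the per-marker threshold is
#'   Bonferroni-corrected across the markers scanned.
#' @param step internal RK4 step (years) for mean curves inside the
#'   likelihood. Coarser than the [integrate_cri()] default: at 0.05 yr the
#'   RK4 solution error is orders of magnitude below phenotypic noise.
#' @param maxit,reltol Nelder-Mead settings for each genotype-class fit.
#' @param profile_rounds outer iterations alternating growth-parameter and
#'   covariance-parameter updates in the null fit.
#' @param subtests run the two sub-hypothesis tests (independent-parameter
#'   equality and interaction-parameter equality) on significant markers.
#' @param null_method `"chisq"` for the chi-square reference of the LRT, or
#'   `"permutation"` for a genotype-relabelling null of the genome-wide
#'   maximum LRT.
#' @param n_perm permutation replicates when `null_method = "permutation"`.
#' @param refit_psi re-estimate the SAD(1) parameters under each marker's
#'   alternative model instead of reusing the null estimate.
#' @param freq_mode genotype-class frequencies used in effect curves:
#'   observed `n_j / n` or Mendelian expectations.
#' @param min_class genotype classes with fewer individuals are dropped
#'   (with a warning) before fitting.
#' @return A named list of class `mapping_control`.
#' @export
mapping_control <- function(alpha = 0.05, step = 0.05, maxit = 500,
                            reltol = 1e-9, profile_rounds = 3,
                            subtests = TRUE,
                            null_method = c("chisq", "permutation"),
                            n_perm = 100, refit_psi = FALSE,
                            freq_mode = c("observed", "expected"),
                            min_class = 2) {
  structure(list(alpha = alpha, step = step, maxit = maxit, reltol = reltol,
                 profile_rounds = profile_rounds, subtests = subtests,
                 null_method = match.arg(null_method), n_perm = n_perm,
                 refit_psi = refit_psi, freq_mode = match.arg(freq_mode),
                 min_class = min_class),
            class = "mapping_control")
}

# stacked data matrix (height columns then diameter columns)
pheno_matrix <- function(pheno) cbind(pheno$height, pheno$diameter)

# single-class growth-parameter fit by Nelder-Mead on the compiled objective
theta_fit <- function(Y, times, H0, D0, Q, start_theta, step, maxit, reltol) {
  s1 <- colSums(Y)
  s2 <- sum((Y %*% Q) * Y)
  n <- nrow(Y)
  obj <- function(par)
    cri_negq_cpp(opt_to_theta(par), H0, D0, times, step, Q, s1, s2, n)
  o <- stats::optim(theta_to_opt(start_theta), obj, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = reltol))
  list(theta = opt_to_theta(o$par), negq = o$value,
       convergence = o$convergence)
}

# moment estimator of SAD(1) parameters from residual matrices (n x T each)
psi_moments <- function(R1, R2) {
  T <- ncol(R1)
  ph <- function(R) {
    num <- sum(vapply(2:T, function(t) stats::cov(R[, t], R[, t - 1]), 0))
    den <- sum(vapply(2:T, function(t) stats::var(R[, t - 1]), 0))
    max(min(num / max(den, 1e-12), 0.995), -0.995)
  }
  phi1 <- ph(R1); phi2 <- ph(R2)
  innov <- function(R, phi) cbind(R[, 1], R[, -1] - phi * R[, -T])
  I1 <- innov(R1, phi1); I2 <- innov(R2, phi2)
  nu1 <- sqrt(max(mean(I1^2), 1e-12))
  nu2 <- sqrt(max(mean(I2^2), 1e-12))
  rho <- max(min(stats::cor(as.vector(I1), as.vector(I2)), 0.99), -0.99)
  sad_params(phi1, phi2, nu1, nu2, rho)
}

psi_to_opt <- function(psi)
  c(psi[[1]], psi[[2]], log(psi[[3]]), log(psi[[4]]), atanh(psi[[5]]))
opt_to_psi <- function(par) {
  p <- c(phi_H = par[1], phi_D = par[2], nu_H = exp(par[3]),
         nu_D = exp(par[4]), rho = tanh(par[5]))
  structure(p, class = "sad_params")
}

# maximise the Gaussian loglik over psi with the residual scatter S fixed;
# returns psi and the achieved loglik
psi_fit <- function(S, n, T, psi_start, maxit = 400) {
  m <- 2 * T
  obj <- function(par) {
    psi <- opt_to_psi(par)
    if (abs(psi[["phi_H"]]) > 5 || abs(psi[["phi_D"]]) > 5) return(1e12)
    Sg <- sad1_covariance(psi, T)
    U <- try(chol(Sg), silent = TRUE)
    if (inherits(U, "try-error")) return(1e12)
    0.5 * (n * m * log(2 * pi) + n * 2 * sum(log(diag(U))) +
             sum(chol2inv(U) * S))
  }
  o <- stats::optim(psi_to_opt(psi_start), obj, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-9))
  list(psi = opt_to_psi(o$par), loglik = -o$value)
}

#' Fit the null (pooled) growth model
#'
#' Maximises the joint bivariate longitudinal likelihood over one shared set
#' of CRI growth parameters and the SAD(1) covariance parameters, alternating
#' Nelder-Mead updates of the growth parameters (with RK4-generated mean
#' curves) and of the covariance parameters. The initial state is fixed at the
#' mean first observation.
#'
#' @param pheno a [cri_pheno()] object with at least 2 individuals.
#' @param control a [mapping_control()] list.
#' @return A list of class `cri_null_fit` with `theta` ([cri_params()]),
#'   `psi` ([sad_params()]), `loglik`, the fitted mean curve `mu`, and cached
#'   covariance factors.
#' @export
fit_null <- function(pheno, control = mapping_control()) {
  Y <- pheno_matrix(pheno)
  n <- nrow(Y); T <- length(pheno$times)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  times <- pheno$times
  # initial states are fixed at the mean first observation; trait states are
  # non-negative by definition, so noisy negative means are floored
  H0 <- max(mean(pheno$height[, 1]), 0.01 * max(pheno$height))
  D0 <- max(mean(pheno$diameter[, 1]), 0.01 * max(pheno$diameter))

  mh <- moment_start(colMeans(pheno$height), times)
  md <- moment_start(colMeans(pheno$diameter), times)
  theta <- c(mh["alpha"], mh["K"], 0, md["alpha"], md["K"], 0)
  Q <- diag(2 * T)
  fit <- theta_fit(Y, times, H0, D0, Q, theta, control$step,
                   control$maxit, control$reltol)
  theta <- fit$theta

  mu <- mu_curve(theta, H0, D0, times, control$step)
  R <- sweep(Y, 2L, mu)
  psi <- psi_moments(R[, 1:T, drop = FALSE], R[, T + 1:T, drop = FALSE])

  loglik <- -Inf
  for (r in seq_len(control$profile_rounds)) {
    U <- sad1_chol(psi, T)
    Q <- chol2inv(U)
    fit <- theta_fit(Y, times, H0, D0, Q, theta, control$step,
                     control$maxit, control$reltol)
    theta <- fit$theta
    mu <- mu_curve(theta, H0, D0, times, control$step)
    R <- sweep(Y, 2L, mu)
    pf <- psi_fit(crossprod(R), n, T, psi)
    psi <- pf$psi
    if (abs(pf$loglik - loglik) < 1e-6 * abs(pf$loglik)) {
      loglik <- pf$loglik
      break
    }
    loglik <- pf$loglik
  }
  U <- sad1_chol(psi, T)
  structure(list(theta = as_cri_params(theta), psi = psi, loglik = loglik,
                 mu = mu, init = c(H = H0, D = D0), times = times, n = n,
                 chol = U, Q = chol2inv(U),
                 logdet = 2 * sum(log(diag(U))),
                 convergence = fit$convergence),
            class = "cri_null_fit")
}

mu_curve <- function(theta, H0, D0, times, step) {
  m <- cri_rk4_cpp(as.numeric(theta), H0, D0, as.numeric(times), step)
  c(m[, 1], m[, 2])
}

# loglik of rows Y around theta-implied mean given cached factors
loglik_theta <- function(Y, theta, null, step) {
  mu <- mu_curve(theta, null$init[["H"]], null$init[["D"]], null$times, step)
  loglik_chol(Y, mu, null$chol)
}

#' Fit genotype-specific growth parameters at one marker
#'
#' Maximises the grouped likelihood with one CRI parameter set per genotype
#' class and a shared SAD(1) covariance. Because genotypes are observed, the
#' likelihood factorises over classes and each class is fitted independently.
#'
#' @param pheno a [cri_pheno()] object.
#' @param codes integer genotype codes per individual (NA allowed; those
#'   individuals are dropped for this marker).
#' @param null a `cri_null_fit` whose SAD(1) estimate is shared.
#' @param control a [mapping_control()] list.
#' @return A list of class `cri_marker_fit`: `theta_by_genotype`, `loglik`
#'   (alternative), `loglik_null` (null parameters evaluated on the same
#'   individuals), `n_by_class`, `classes`, `dropped`.
#' @export
fit_alternative <- function(pheno, codes, null, control = mapping_control()) {
  Y <- pheno_matrix(pheno)
  keep <- !is.na(codes)
  classes <- sort(unique(codes[keep]))
  sizes <- vapply(classes, function(g) sum(codes[keep] == g), 0L)
  small <- classes[sizes < control$min_class]
  if (length(small)) {
    warning("dropping genotype class(es) with fewer than ", control$min_class,
            " individuals: ", paste(small, collapse = ", "))
    keep <- keep & !(codes %in% small)
    classes <- setdiff(classes, small)
    sizes <- vapply(classes, function(g) sum(codes[keep] == g), 0L)
  }
  if (length(classes) < 2)
    stop("degenerate marker: fewer than two usable genotype classes",
         call. = FALSE)
  T <- length(pheno$times)
  psi <- null$psi
  Q <- null$Q
  ll <- 0
  thetas <- vector("list", length(classes))
  names(thetas) <- as.character(classes)
  for (i in seq_along(classes)) {
    rows <- which(keep & codes == classes[i])
    Yj <- Y[rows, , drop = FALSE]
    f <- theta_fit(Yj, pheno$times, null$init[["H"]], null$init[["D"]], Q,
                   as.numeric(null$theta), control$step, control$maxit,
                   control$reltol)
    thetas[[i]] <- as_cri_params(f$theta)
    ll <- ll + (-0.5 * length(rows) * 2 * T * log(2 * pi)
                - 0.5 * length(rows) * null$logdet - f$negq)
  }
  if (isTRUE(control$refit_psi)) {
    R <- NULL
    for (i in seq_along(classes)) {
      rows <- which(keep & codes == classes[i])
      mu <- mu_curve(as.numeric(thetas[[i]]), null$init[["H"]],
                     null$init[["D"]], pheno$times, control$step)
      R <- rbind(R, sweep(Y[rows, , drop = FALSE], 2L, mu))
    }
    pf <- psi_fit(crossprod(R), nrow(R), T, psi)
    psi <- pf$psi
    ll <- pf$loglik
  }
  ll_null <- loglik_chol(Y[keep, , drop = FALSE], null$mu, null$chol)
  structure(list(theta_by_genotype = thetas, loglik = ll,
                 loglik_null = ll_null, psi = psi,
                 n_by_class = stats::setNames(sizes, classes),
                 classes = classes, dropped = sum(!keep)),
            class = "cri_marker_fit")
}

#' Likelihood-ratio scan over markers
#'
#' For every marker, compares genotype-specific CRI parameter sets against the
#' pooled null by a likelihood-ratio test under the shared SAD(1) covariance.
#' P-values come from the chi-square reference with `6 (J - 1)` degrees of
#' freedom (or from a genotype-permutation null of the genome-wide maximum
#' LRT); Benjamini-Hochberg FDR is reported across markers and significance is
#' declared at the Bonferroni-corrected genome-wide level.
#'
#' @param pheno a [cri_pheno()] object.
#' @param geno a `cri_geno` object (see [read_genotypes()] /
#'   [simulate_genotypes()]).
#' @param control a [mapping_control()] list.
#' @return An object of class `cri_scan`: a results data frame (one row per
#'   marker: `marker_id`, `lrt`, `df`, `p_value`, `p_fdr`, `significant`,
#'   sub-test columns) with the null fit, per-marker genotype parameter sets
#'   and class frequencies attached as attributes.
#' @export
lrt_scan <- function(pheno, geno, control = mapping_control()) {
  stopifnot(inherits(pheno, "cri_pheno"))
  n <- nrow(pheno$height)
  if (ncol(geno$codes) != n)
    stop("genotype and phenotype individual counts differ", call. = FALSE)
  null <- fit_null(pheno, control)
  p <- nrow(geno$codes)
  if (p == 0L) {
    return(structure(list(results = empty_scan_results(), null = null,
                          fits = list(), control = control),
                     class = "cri_scan"))
  }
  fits <- vector("list", p)
  lrt <- df <- rep(NA_real_, p)
  failed <- rep(FALSE, p)
  for (k in seq_len(p)) {
    f <- try(fit_alternative(pheno, geno$codes[k, ], null, control),
             silent = TRUE)
    if (inherits(f, "try-error")) {
      failed[k] <- TRUE
      next
    }
    fits[[k]] <- f
    lrt[k] <- max(2 * (f$loglik - f$loglik_null), 0)
    df[k] <- 6 * (length(f$classes) - 1)
  }
  p_value <- stats::pchisq(lrt, df, lower.tail = FALSE)
  threshold <- control$alpha / p
  if (control$null_method == "permutation") {
    maxlrt <- permutation_max_lrt(pheno, geno, null, control)
    p_gw <- vapply(lrt, function(l) mean(maxlrt >= l), 0)
    significant <- !is.na(lrt) & p_gw <= control$alpha
  } else {
    p_gw <- NULL
    significant <- !is.na(p_value) & p_value < threshold
  }
  res <- data.frame(marker_id = geno$info$marker_id,
                    chromosome = geno$info$chromosome,
                    position = geno$info$position,
                    segregation = geno$info$segregation,
                    lrt = lrt, df = df, p_value = p_value,
                    p_fdr = stats::p.adjust(p_value, "BH"),
                    significant = significant, failed = failed,
                    stringsAsFactors = FALSE)
  if (!is.null(p_gw)) res$p_genomewide <- p_gw
  res$lrt_independent <- res$p_independent <- NA_real_
  res$lrt_interaction <- res$p_interaction <- NA_real_
  if (isTRUE(control$subtests)) {
    for (k in which(res$significant)) {
      st <- subhypothesis_tests(pheno, geno$codes[k, ], fits[[k]], null,
                                control)
      res$lrt_independent[k] <- st$independent["lrt"]
      res$p_independent[k] <- st$independent["p"]
      res$lrt_interaction[k] <- st$interaction["lrt"]
      res$p_interaction[k] <- st$interaction["p"]
    }
  }
  ord <- order(res$chromosome, res$position)
  structure(list(results = res[ord, ], null = null, fits = fits[ord],
                 threshold = threshold, control = control,
                 times = pheno$times, n = n),
            class = "cri_scan")
}

empty_scan_results <- function() {
  data.frame(marker_id = character(), chromosome = character(),
             position = numeric(), segregation = character(),
             lrt = numeric(), df = numeric(), p_value = numeric(),
             p_fdr = numeric(), significant = logical(), failed = logical())
}

# genome-wide maximum LRT under genotype-label permutation
permutation_max_lrt <- function(pheno, geno, null, control) {
  p <- nrow(geno$codes)
  vapply(seq_len(control$n_perm), function(b) {
    perm <- sample.int(ncol(geno$codes))
    mx <- 0
    for (k in seq_len(p)) {
      f <- try(fit_alternative(pheno, geno$codes[k, perm], null, control),
               silent = TRUE)
      if (!inherits(f, "try-error"))
        mx <- max(mx, 2 * (f$loglik - f$loglik_null))
    }
    mx
  }, 0)
}

#' @export
print.cri_scan <- function(x, ...) {
  r <- x$results
  cat("CRI system-mapping scan:", nrow(r), "markers,", x$n, "individuals\n")
  cat("significant markers:", sum(r$significant, na.rm = TRUE),
      sprintf("(genome-wide alpha = %g, Bonferroni)\n", x$control$alpha))
  invisible(x)
}

#' @export
summary.cri_scan <- function(object, ...) {
  r <- object$results
  cat("CRI system-mapping scan\n")
  cat(sprintf("  markers: %d (%d failed)\n", nrow(r), sum(r$failed)))
  cat(sprintf("  individuals: %d, time points: %d\n", object$n,
              length(object$times)))
  cat(sprintf("  null strategy: %s\n",
              classify_strategy(object$null$theta[["beta_HfromD"]],
                                object$null$theta[["beta_DfromH"]])))
  sig <- r[which(r$significant), ]
  cat(sprintf("  significant markers: %d\n", nrow(sig)))
  if (nrow(sig)) print(utils::head(sig[order(sig$p_value), ], 10))
  invisible(object)
}

#' @export
plot.cri_scan <- function(x, ...) {
  r <- x$results
  lp <- -log10(pmax(r$p_fdr, 1e-300))
  graphics::plot(seq_along(lp), lp, pch = 16, cex = 0.6,
                 col = ifelse(r$significant, 2, 1),
                 xlab = "marker index", ylab = "-log10 FDR-adjusted p", ...)
  graphics::abline(h = -log10(x$control$alpha), lty = 2)
  invisible(x)
}

#' Sub-hypothesis tests at a significant marker
#'
#' Tests whether a marker affects the independent growth parameters
#' (`alpha_H, K_H, alpha_D, K_D` constrained equal across genotype classes,
#' interaction coefficients free) and the interaction parameters
#' (`beta_HfromD, beta_DfromH` constrained equal, the rest free), each by a
#' likelihood-ratio test against the unconstrained per-genotype fit with
#' `4 (J - 1)` and `2 (J - 1)` degrees of freedom respectively.
#'
#' @param pheno a [cri_pheno()] object.
#' @param codes genotype codes at the marker.
#' @param altfit the `cri_marker_fit` from [fit_alternative()].
#' @param null the `cri_null_fit`.
#' @param control a [mapping_control()] list.
#' @return List with elements `independent` and `interaction`, each
#'   `c(lrt =, df =, p =)`, plus the constrained log-likelihoods.
#' @export
subhypothesis_tests <- function(pheno, codes, altfit, null,
                                control = mapping_control()) {
  Y <- pheno_matrix(pheno)
  T <- length(pheno$times)
  classes <- altfit$classes
  J <- length(classes)
  rows <- lapply(classes, function(g) which(!is.na(codes) & codes == g))
  stats_j <- lapply(rows, function(rr) {
    Yj <- Y[rr, , drop = FALSE]
    list(s1 = colSums(Yj), s2 = sum((Yj %*% null$Q) * Yj), n = length(rr))
  })
  negq_theta <- function(theta, st)
    cri_negq_cpp(theta, null$init[["H"]], null$init[["D"]], pheno$times,
                 control$step, null$Q, st$s1, st$s2, st$n)
  n_tot <- sum(vapply(stats_j, `[[`, 0, "n"))
  const <- -0.5 * n_tot * 2 * T * log(2 * pi) - 0.5 * n_tot * null$logdet

  fit_constrained <- function(par_to_thetas, start) {
    obj <- function(par) {
      th <- par_to_thetas(par)
      sum(vapply(seq_len(J), function(j) negq_theta(th[[j]], stats_j[[j]]),
                 0))
    }
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = control$maxit * 2,
                                     reltol = control$reltol))
    const - o$value
  }

  # re-polish the per-class fits so the unconstrained likelihood dominates
  # the constrained ones even when a single simplex pass under-converged
  th_j <- lapply(altfit$theta_by_genotype, as.numeric)
  ll_alt <- altfit$loglik
  for (pass in 1:2) {
    ll_new <- const
    for (j in seq_len(J)) {
      o <- stats::optim(theta_to_opt(th_j[[j]]),
                        function(par) negq_theta(opt_to_theta(par),
                                                 stats_j[[j]]),
                        method = "Nelder-Mead",
                        control = list(maxit = control$maxit,
                                       reltol = control$reltol))
      th_j[[j]] <- opt_to_theta(o$par)
      ll_new <- ll_new - o$value
    }
    ll_alt <- max(ll_alt, ll_new)
  }
  # shared independent parameters, class-specific interaction coefficients
  ind_mean <- rowMeans(vapply(th_j, function(t) t[c(1, 2, 4, 5)], numeric(4)))
  startA <- c(log(ind_mean), unlist(lapply(th_j, function(t) t[c(3, 6)])))
  llA <- fit_constrained(function(par) {
    lapply(seq_len(J), function(j)
      c(exp(par[1]), exp(par[2]), par[4 + 2 * j - 1],
        exp(par[3]), exp(par[4]), par[4 + 2 * j]))
  }, startA)
  # shared interaction coefficients, class-specific independent parameters
  beta_mean <- rowMeans(vapply(th_j, function(t) t[c(3, 6)], numeric(2)))
  startB <- c(beta_mean, unlist(lapply(th_j, function(t) log(t[c(1, 2, 4, 5)]))))
  llB <- fit_constrained(function(par) {
    lapply(seq_len(J), function(j) {
      q <- par[2 + 4 * (j - 1) + 1:4]
      c(exp(q[1]), exp(q[2]), par[1], exp(q[3]), exp(q[4]), par[2])
    })
  }, startB)

  lrt_ind <- max(2 * (ll_alt - llA), 0)
  lrt_int <- max(2 * (ll_alt - llB), 0)
  list(independent = c(lrt = lrt_ind, df = 4 * (J - 1),
                       p = stats::pchisq(lrt_ind, 4 * (J - 1),
                                         lower.tail = FALSE)),
       interaction = c(lrt = lrt_int, df = 2 * (J - 1),
                       p = stats::pchisq(lrt_int, 2 * (J - 1),
                                         lower.tail = FALSE)),
       loglik_independent_constrained = llA,
       loglik_interaction_constrained = llB,
       loglik_alternative = ll_alt)
}

#' Genetic-effect curves at a marker
#'
#' The genetic effect of a marker on each trait at time t is the weighted
#' standard deviation across genotype classes of the class mean trajectories,
#' \deqn{g(t) = \sqrt{\sum_j w_j (\mu_j(t) - \bar\mu(t))^2}.}
#' Independent-effect variants replace the coupled trajectories with the
#' cumulative independent growth components from [decompose_growth()]. The
#' dynamic genetic correlation at time t is the w-weighted Pearson correlation
#' of the genotype deviations between the two traits.
#'
#' @param theta_by_genotype list of [cri_params()], one per genotype class.
#' @param freqs class frequencies (summing to 1).
#' @param times evaluation times.
#' @param init initial state `c(H =, D =)` shared across classes.
#' @param step RK4 step.
#' @return A list of class `effect_curve_pair` with `g1`, `g2`,
#'   `independent_g1`, `independent_g2` (all non-negative) and
#'   `dynamic_correlation`.
#' @export
genetic_effect_curves <- function(theta_by_genotype, freqs, times, init,
                                  step = 0.01) {
  J <- length(theta_by_genotype)
  if (abs(sum(freqs) - 1) > 1e-8)
    stop("class frequencies must sum to 1", call. = FALSE)
  T <- length(times)
  if (J < 2) {
    warning("single genotype class: zero effect curves")
    z <- rep(0, T)
    return(structure(list(times = times, g1 = z, g2 = z, independent_g1 = z,
                          independent_g2 = z,
                          dynamic_correlation = rep(NA_real_, T)),
                     class = "effect_curve_pair"))
  }
  M1 <- M2 <- I1 <- I2 <- matrix(0, J, T)
  for (j in seq_len(J)) {
    tr <- integrate_cri(theta_by_genotype[[j]], init, times, step)
    M1[j, ] <- tr$H; M2[j, ] <- tr$D
    d <- decompose_growth(theta_by_genotype[[j]], tr)
    I1[j, ] <- init[["H"]] + d$cum_independent_H
    I2[j, ] <- init[["D"]] + d$cum_independent_D
  }
  wsd <- function(M) {
    mbar <- colSums(M * freqs)
    sqrt(pmax(colSums(freqs * sweep(M, 2L, mbar)^2), 0))
  }
  dev <- function(M) sweep(M, 2L, colSums(M * freqs))
  d1 <- dev(M1); d2 <- dev(M2)
  num <- colSums(freqs * d1 * d2)
  den <- sqrt(colSums(freqs * d1^2) * colSums(freqs * d2^2))
  structure(list(times = times, g1 = wsd(M1), g2 = wsd(M2),
                 independent_g1 = wsd(I1), independent_g2 = wsd(I2),
                 dynamic_correlation = ifelse(den > 0, num / den, NA_real_)),
            class = "effect_curve_pair")
}

#' Per-marker effect curves from a scan
#'
#' Computes the bivariate genetic-effect curve of every successfully fitted
#' marker in a [lrt_scan()] result.
#'
#' @param scan a `cri_scan` object.
#' @param step RK4 step for the class mean trajectories.
#' @return An object of class `effect_curve_set`: list with `times`, `g1` and
#'   `g2` (`p x T` matrices), `independent_g1`, `independent_g2`, `ids`, and
#'   the per-marker `qtl` significance flags.
#' @export
effect_curves <- function(scan, step = 0.05) {
  stopifnot(inherits(scan, "cri_scan"))
  ok <- which(!scan$results$failed)
  T <- length(scan$times)
  ctl <- scan$control
  g1 <- g2 <- i1 <- i2 <- matrix(NA_real_, length(ok), T)
  for (i in seq_along(ok)) {
    f <- scan$fits[[ok[i]]]
    freqs <- if (ctl$freq_mode == "expected")
      mendelian_freqs(length(f$classes))
    else f$n_by_class / sum(f$n_by_class)
    ec <- genetic_effect_curves(f$theta_by_genotype, freqs, scan$times,
                                scan$null$init, step)
    g1[i, ] <- ec$g1; g2[i, ] <- ec$g2
    i1[i, ] <- ec$independent_g1; i2[i, ] <- ec$independent_g2
  }
  structure(list(times = scan$times, g1 = g1, g2 = g2,
                 independent_g1 = i1, independent_g2 = i2,
                 ids = scan$results$marker_id[ok],
                 qtl = scan$results$significant[ok]),
            class = "effect_curve_set")
}

mendelian_freqs <- function(J) {
  if (J == 2) c(0.5, 0.5)
  else if (J == 3) c(0.25, 0.5, 0.25)
  else rep(1 / J, J)
}

#' @export
print.effect_curve_set <- function(x, ...) {
  cat("genetic-effect curves:", nrow(x$g1), "markers,", length(x$times),
      "time points (", sum(x$qtl), "QTL-flagged )\n")
  invisible(x)
}
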