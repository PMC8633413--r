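#' Default CRI parameters for the simulator
#'
#' A poplar-like parameter set: height saturating near 19 m and diameter near
#' 28 cm by year 14, with the antagonistic strategy reported for stem growth
#' (diameter inhibits height growth, height promotes diameter growth).
#'
#' @return A [cri_params()] object.
#' @export
default_cri_params <- function() {
  cri_params(alpha_H = 0.55, K_H = 25, beta_HfromD = -0.010,
             alpha_D = 0.40, K_D = 30, beta_DfromH = 0.006)
}

#' Default SAD(1) parameters for the simulator
#'
#' Strong antedependence (`phi = 0.9`) so residual variance accumulates over
#' the growth period, and moderately correlated innovations between the two
#' stem traits. Innovation scales are rescaled at simulation time to hit the
#' requested heritability.
#'
#' @return A [sad_params()] object.
#' @export
default_sad_params <- function() {
  sad_params(phi_H = 0.9, phi_D = 0.9, nu_H = 1, nu_D = 1.2, rho = 0.5)
}

#' Simulation configuration
#'
#' Defines one study condition for the full-sib simulator: a mapping
#' population of `n` individuals scored at `p` unlinked markers, one causal
#' marker whose genotype classes follow CRI parameter sets with shifted
#' asymptotes, and SAD(1) residual noise rescaled to a target heritability
#' (the proportion of genetic variance in phenotypic variance, averaged over
#' time points and traits).
#'
#' @param n individuals (>= 4).
#' @param p markers (>= 1).
#' @param prop_testcross proportion of markers segregating 1:1 (testcross,
#'   2 genotype classes); the rest segregate 1:2:1 (intercross, 3 classes).
#' @param causal_index index of the causal marker (its genotype determines
#'   each individual's growth parameters when `H2 > 0`).
#' @param effect_size fractional shift of the asymptotes `K_H`, `K_D`
#'   between extreme genotype classes.
#' @param H2 target heritability, `0 <= H2 < 1`; `H2 = 0` simulates the
#'   global null (all individuals share `theta0`).
#' @param theta0 baseline [cri_params()].
#' @param psi template [sad_params()]; innovation scales are rescaled to
#'   achieve `H2`.
#' @param times observation grid (annual by default).
#' @param init initial state `c(H =, D =)` at `times[1]`.
#' @param step RK4 step for mean curves.
#' @param seed master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 66, p = 100, prop_testcross = 0.6,
                       causal_index = 1, effect_size = 0.10, H2 = 0.05,
                       theta0 = default_cri_params(),
                       psi = default_sad_params(), times = 1:14,
                       init = c(H = 0.8, D = 0.7), step = 0.05, seed = 1) {
  if (H2 < 0 || H2 >= 1) stop("H2 must satisfy 0 <= H2 < 1", call. = FALSE)
  if (n < 4) stop("need at least 4 individuals", call. = FALSE)
  if (p < 1) stop("need at least 1 marker", call. = FALSE)
  if (causal_index < 1 || causal_index > p)
    stop("causal_index out of range", call. = FALSE)
  structure(list(n = n, p = p, prop_testcross = prop_testcross,
                 causal_index = causal_index, effect_size = effect_size,
                 H2 = H2, theta0 = as_cri_params(theta0),
                 psi = as_sad_params(psi), times = times, init = init,
                 step = step, seed = seed),
            class = "sim_config")
}

#' Simulate full-sib marker genotypes
#'
#' Testcross markers (one parent heterozygous) segregate 1:1 over two
#' genotype classes; intercross markers (both parents heterozygous, phases
#' collapsed) segregate 1:2:1 over three classes. Markers are drawn
#' independently (no linkage).
#'
#' @param config a [sim_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return An object of class `cri_geno`: list with `info` (marker metadata
#'   data frame) and `codes` (`p x n` integer matrix).
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  set.seed(seed)
  p <- config$p; n <- config$n
  segregation <- ifelse(stats::runif(p) < config$prop_testcross,
                        "testcross", "intercross")
  codes <- matrix(NA_integer_, p, n)
  for (k in seq_len(p)) {
    codes[k, ] <- if (segregation[k] == "testcross")
      sample(0:1, n, replace = TRUE)
    else sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  }
  info <- data.frame(marker_id = sprintf("snp%04d", seq_len(p)),
                     chromosome = "1", position = seq_len(p),
                     segregation = segregation, stringsAsFactors = FALSE)
  structure(list(info = info, codes = codes,
                 ids = paste0("ind", seq_len(n))),
            class = "cri_geno")
}

#' @export
print.cri_geno <- function(x, ...) {
  cat("marker genotypes:", nrow(x$codes), "markers x", ncol(x$codes),
      "individuals (", sum(x$info$segregation == "testcross"), "testcross,",
      sum(x$info$segregation == "intercross"), "intercross )\n")
  invisible(x)
}

# per-genotype-class CRI parameter sets at the causal marker: asymptotes
# K_H, K_D shifted by -e, (0,) +e across classes
causal_class_params <- function(config, J) {
  e <- config$effect_size
  shifts <- if (J == 2) c(-e, e) else seq(-e, e, length.out = J)
  lapply(shifts, function(s) {
    th <- unclass(config$theta0)
    th[["K_H"]] <- th[["K_H"]] * (1 + s)
    th[["K_D"]] <- th[["K_D"]] * (1 + s)
    as_cri_params(th)
  })
}

#' Simulate bivariate longitudinal phenotypes
#'
#' Each individual's mean curve is the RK4 solution of the CRI system under
#' the parameter set of its causal-marker genotype class; residuals follow the
#' bivariate SAD(1) process. Innovation scales are rescaled so that, averaged
#' over time points and traits, the genetic variance fraction equals the
#' requested heritability. With `H2 = 0` all individuals share the baseline
#' parameters and the template noise is used as given.
#'
#' @param geno a `cri_geno` from [simulate_genotypes()].
#' @param config the matching [sim_config()].
#' @param seed optional seed overriding `config$seed` (offset internally from
#'   the genotype draw).
#' @return A [cri_pheno()] with attributes `psi_used` (rescaled
#'   [sad_params()]), `theta_by_class`, `causal_classes` and `H2`.
#' @export
simulate_phenotypes <- function(geno, config, seed = config$seed + 1L) {
  set.seed(seed)
  n <- config$n; times <- config$times; T <- length(times)
  psi <- config$psi
  if (config$H2 > 0) {
    if (config$effect_size == 0)
      stop("H2 > 0 requires genotype-specific parameters (effect_size > 0)",
           call. = FALSE)
    codes <- geno$codes[config$causal_index, ]
    seg <- geno$info$segregation[config$causal_index]
    J <- if (seg == "testcross") 2L else 3L
    thetas <- causal_class_params(config, J)
    w <- mendelian_freqs(J)
    M <- vapply(thetas, function(th)
      mu_curve(as.numeric(th), config$init[["H"]], config$init[["D"]],
               times, config$step), numeric(2 * T))  # 2T x J
    mbar <- as.vector(M %*% w)
    vg <- mean(colSums(w * t(M - mbar)^2))
    ve <- mean(sad1_variance_profile(psi, T))
    scale2 <- vg * (1 - config$H2) / (config$H2 * ve)
    psi <- sad_params(psi[["phi_H"]], psi[["phi_D"]],
                      psi[["nu_H"]] * sqrt(scale2),
                      psi[["nu_D"]] * sqrt(scale2), psi[["rho"]])
    mu_i <- t(M)[codes + 1L, , drop = FALSE]  # n x 2T
  } else {
    thetas <- list(config$theta0)
    codes <- rep(0L, n)
    mu_i <- matrix(mu_curve(as.numeric(config$theta0), config$init[["H"]],
                            config$init[["D"]], times, config$step),
                   n, 2 * T, byrow = TRUE)
  }
  E <- simulate_sad1(n, T, psi)
  Y <- mu_i + E
  ph <- cri_pheno(Y[, 1:T, drop = FALSE], Y[, T + 1:T, drop = FALSE], times,
                  ids = geno$ids)
  attr(ph, "psi_used") <- psi
  attr(ph, "theta_by_class") <- thetas
  attr(ph, "causal_classes") <- codes
  attr(ph, "H2") <- config$H2
  ph
}

# marginal residual variance profile over times and traits (2T values)
sad1_variance_profile <- function(psi, T) {
  v <- function(phi, nu) {
    s <- seq_len(T)
    if (abs(1 - phi^2) < 1e-12) nu^2 * s else nu^2 * (1 - phi^(2 * s)) / (1 - phi^2)
  }
  c(v(psi[["phi_H"]], psi[["nu_H"]]), v(psi[["phi_D"]], psi[["nu_D"]]))
}

# deterministic replicate seeds below 2^31
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + index * 104729) %% 2147483629 + 1)
}

#' ROC curve and trapezoid AUC from scores and labels
#'
#' Sweeps the decision threshold over the observed score range and returns
#' the (FPR, TPR) points and their trapezoid area.
#'
#' @param scores numeric scores (larger = more evidence for positive).
#' @param labels logical/0-1 vector, TRUE for positives.
#' @return List with `fpr`, `tpr` (monotone non-decreasing) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels), any(!labels))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(s) mean(scores[labels] >= s), 0)
  fpr <- vapply(thr, function(s) mean(scores[!labels] >= s), 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Power, false-positive-rate and ROC study
#'
#' Runs the marker scan on repeated simulated datasets over a grid of sample
#' sizes and heritabilities. Power is the proportion of replicates in which
#' the causal marker is declared significant at the genome-wide threshold;
#' the FPR is the fraction of null-marker tests declared significant; ROC
#' curves rank causal against null markers by their LRT statistic across
#' thresholds, with trapezoid AUC.
#'
#' @param conditions data frame with columns `n` and `H2`.
#' @param replicates replicates per condition.
#' @param config baseline [sim_config()] (its `n`, `H2` and `seed` are
#'   overridden per condition/replicate).
#' @param control [mapping_control()] for the scans; sub-hypothesis tests are
#'   disabled inside the study.
#' @return An object of class `cri_power_study`: `table` (per-condition
#'   power, FPR, AUC), `roc` (per-condition ROC points), `replicates`,
#'   `seeds`.
#' @export
run_power_study <- function(conditions, replicates = 50,
                            config = sim_config(),
                            control = mapping_control()) {
  stopifnot(replicates >= 1, all(c("n", "H2") %in% names(conditions)))
  control$subtests <- FALSE
  tab <- conditions
  tab$power <- tab$fpr <- tab$auc <- NA_real_
  tab$n_reps <- 0L
  roc <- vector("list", nrow(conditions))
  all_seeds <- list()
  idx <- 0L
  for (ci in seq_len(nrow(conditions))) {
    hits <- 0L; fp <- 0L; fp_den <- 0L; used <- 0L
    scores <- numeric(0); labels <- logical(0)
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      sd <- derive_seed(config$seed, idx)
      cfg <- config
      cfg$n <- conditions$n[ci]; cfg$H2 <- conditions$H2[ci]; cfg$seed <- sd
      res <- try({
        g <- simulate_genotypes(cfg)
        ph <- simulate_phenotypes(g, cfg)
        lrt_scan(ph, g, control)
      }, silent = TRUE)
      if (inherits(res, "try-error")) next
      used <- used + 1L
      all_seeds[[idx]] <- sd
      rr <- res$results
      causal <- rr$marker_id == g$info$marker_id[cfg$causal_index]
      if (cfg$H2 > 0) {
        hits <- hits + as.integer(rr$significant[causal])
        fp <- fp + sum(rr$significant[!causal], na.rm = TRUE)
        fp_den <- fp_den + sum(!causal & !rr$failed)
        scores <- c(scores, rr$lrt)
        labels <- c(labels, causal)
      } else {
        fp <- fp + sum(rr$significant, na.rm = TRUE)
        fp_den <- fp_den + sum(!rr$failed)
      }
    }
    tab$n_reps[ci] <- used
    tab$fpr[ci] <- fp / max(fp_den, 1L)
    if (conditions$H2[ci] > 0) {
      tab$power[ci] <- hits / max(used, 1L)
      rc <- roc_curve(scores, labels)
      roc[[ci]] <- rc
      tab$auc[ci] <- rc$auc
    }
  }
  structure(list(table = tab, roc = roc, replicates = replicates,
                 seeds = unlist(all_seeds), config = config),
            class = "cri_power_study")
}

#' @export
print.cri_power_study <- function(x, digits = 3, ...) {
  cat("CRI mapping power study (", x$replicates, "replicates/condition )\n")
  print(cbind(x$table[c("n", "H2", "n_reps")],
              round(x$table[c("power", "fpr", "auc")], digits)))
  invisible(x)
}

#' Simulate clustered genetic-effect curve sets
#'
#' Cluster mean curves are random low-order Legendre expansions whose minimum
#' pairwise distance is scaled to the requested multiple of the innovation
#' standard deviation; member curves add bivariate SAD(1) noise around their
#' cluster mean. With `separation = 0` all clusters share one mean.
#'
#' @param L_true number of clusters.
#' @param members curves per cluster.
#' @param separation minimum pairwise RMS distance between cluster means, in
#'   units of the innovation sd.
#' @param psi [sad_params()] for the member noise.
#' @param times observation grid.
#' @param order polynomial order of the mean curves.
#' @param seed random seed.
#' @return List of class `effect_curve_set` with `g1`, `g2`
#'   (`(L_true * members) x T`), plus `labels` (true cluster of each curve)
#'   and `means` (`L_true x 2T`).
#' @export
simulate_effect_curve_sets <- function(L_true, members, separation,
                                       psi = default_sad_params(),
                                       times = 1:14, order = 3, seed = 1) {
  stopifnot(L_true >= 1, members >= 1)
  set.seed(seed)
  psi <- as_sad_params(psi)
  T <- length(times)
  B <- lop_basis(times, order)$basis
  nu_ref <- sqrt(mean(c(psi[["nu_H"]]^2, psi[["nu_D"]]^2)))
  U <- t(vapply(seq_len(L_true), function(l) {
    c(B %*% stats::rnorm(order + 1, 0, 2), B %*% stats::rnorm(order + 1, 0, 2))
  }, numeric(2 * T)))
  if (L_true > 1) {
    center <- colMeans(U)
    dev <- sweep(U, 2L, center)
    dmin <- min(stats::dist(U) / sqrt(2 * T))
    fac <- if (separation == 0) 0 else separation * nu_ref / max(dmin, 1e-12)
    U <- sweep(dev * fac, 2L, center, "+")
  }
  labels <- rep(seq_len(L_true), each = members)
  E <- simulate_sad1(L_true * members, T, psi)
  G <- U[labels, , drop = FALSE] + E
  structure(list(times = times, g1 = G[, 1:T, drop = FALSE],
                 g2 = G[, T + 1:T, drop = FALSE],
                 independent_g1 = NULL, independent_g2 = NULL,
                 ids = paste0("curve", seq_len(nrow(G))),
                 qtl = rep(FALSE, nrow(G)), labels = labels, means = U),
            class = "effect_curve_set")
}

#' Simulate a planted regulatory curve system
#'
#' Builds `n_nodes` effect curves that follow the network ODE exactly: each
#' node's rate of change is a low-order baseline trend plus planted
#' couplings proportional to its regulators' curves,
#' \deqn{dy_l/dt = trend_l(t) + \sum \theta_{l \leftarrow l'} y_{l'}(t),}
#' then adds observation noise at the sampled time points. Source nodes (no
#' incoming edge) get random positive quartic Legendre curves so that every
#' regulator carries shape information beyond the baseline trend. Used to
#' test network support recovery.
#'
#' @param n_nodes number of nodes.
#' @param edges data frame with columns `source`, `target` (node indices) and
#'   `strength` (signed coupling coefficients).
#' @param times observation grid.
#' @param noise_sd sd of iid observation noise added to the sampled curves.
#' @param seed random seed.
#' @return List with `curves` (named list of numeric vectors over `times`),
#'   `edges` (the planted truth, named node ids), `times`.
#' @export
simulate_planted_network <- function(n_nodes, edges, times = 1:14,
                                     noise_sd = 0.01, seed = 1) {
  set.seed(seed)
  T <- length(times)
  dense <- seq(times[1], times[T], length.out = 400)
  rand_curve <- function(order) {
    B <- legendre_matrix(2 * (dense - dense[1]) / diff(range(dense)) - 1,
                         order)$val
    # flat coefficient scale, with a guaranteed top-order component:
    # regulators must carry shape information beyond the baseline trend for
    # their influence to be attributable
    cf <- stats::rnorm(order + 1, 0, 0.4)
    cf[order + 1] <- sample(c(-1, 1), 1) * stats::runif(1, 0.3, 0.7)
    v <- as.vector(B %*% cf)
    v - min(v) + 0.3
  }
  ord <- topo_order(n_nodes, edges)
  vals <- vector("list", n_nodes)
  for (i in ord) {
    inc <- edges[edges$target == i, , drop = FALSE]
    # every node gets a distinct quartic baseline (its derivative, a cubic,
    # lies inside the fitted trend block); couplings add the running
    # integral of each regulator's curve
    y <- rand_curve(4)
    if (nrow(inc))
      for (j in seq_len(nrow(inc)))
        y <- y + inc$strength[j] * cumtrapz(dense, vals[[inc$source[j]]])
    vals[[i]] <- y
  }
  curves <- lapply(seq_len(n_nodes), function(i) {
    y <- stats::approx(dense, vals[[i]], xout = times)$y
    y + stats::rnorm(T, 0, noise_sd)
  })
  names(curves) <- paste0("node", seq_len(n_nodes))
  edges_out <- data.frame(source = paste0("node", edges$source),
                          target = paste0("node", edges$target),
                          strength = edges$strength,
                          stringsAsFactors = FALSE)
  list(curves = curves, edges = edges_out, times = times)
}

# topological order; planted graphs must be acyclic
topo_order <- function(n_nodes, edges) {
  indeg <- tabulate(edges$target, n_nodes)
  ord <- integer(0)
  ready <- which(indeg == 0)
  edges_left <- edges
  while (length(ready)) {
    i <- ready[1]; ready <- ready[-1]; ord <- c(ord, i)
    out <- edges_left$source == i
    for (tgt in edges_left$target[out]) {
      indeg[tgt] <- indeg[tgt] - 1L
      if (indeg[tgt] == 0L) ready <- c(ready, tgt)
    }
    edges_left <- edges_left[!out, , drop = FALSE]
  }
  if (length(ord) < n_nodes) stop("planted network must be acyclic",
                                  call. = FALSE)
  ord
}
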