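#' Legendre orthogonal polynomial basis
#'
#' Evaluates Legendre polynomials P_0..P_order at the observation times
#' mapped affinely onto \[-1, 1\]. Column 0 is identically 1 and the columns
#' are orthogonal under the continuous inner product on \[-1, 1\].
#'
#' @param times observation times (>= 2 distinct values).
#' @param order polynomial order `r >= 0`. Orders at or above the number of
#'   time points put the fit in the interpolation regime and trigger a
#'   warning.
#' @return A list of class `lop_basis` with `order`, `times`, the affine
#'   `time_map` (t_min, t_max), `basis` (`T x (order+1)`) and `deriv`
#'   (derivatives with respect to t).
#' @export
lop_basis <- function(times, order) {
  if (order < 0) stop("order must be >= 0", call. = FALSE)
  if (length(unique(times)) < 2) stop("need at least 2 distinct times",
                                      call. = FALSE)
  if (order >= length(times))
    warning("polynomial order >= number of time points: interpolation regime")
  tmin <- min(times); tmax <- max(times)
  x <- 2 * (times - tmin) / (tmax - tmin) - 1
  P <- legendre_matrix(x, order)
  structure(list(order = order, times = times,
                 time_map = c(t_min = tmin, t_max = tmax),
                 basis = P$val, deriv = P$deriv * (2 / (tmax - tmin))),
            class = "lop_basis")
}

# Legendre values and x-derivatives by the three-term recurrence
legendre_matrix <- function(x, order) {
  n <- length(x)
  V <- matrix(0, n, order + 1)
  D <- matrix(0, n, order + 1)
  V[, 1] <- 1
  if (order >= 1) {
    V[, 2] <- x
    D[, 2] <- 1
  }
  if (order >= 2) {
    for (m in 1:(order - 1)) {
      V[, m + 2] <- ((2 * m + 1) * x * V[, m + 1] - m * V[, m]) / (m + 1)
      D[, m + 2] <- (2 * m + 1) * V[, m + 1] + D[, m]
    }
  }
  list(val = V, deriv = D)
}

#' Control settings for curve-mixture fitting
#'
#' @param order Legendre polynomial order of the module mean curves (per
#'   trait).
#' @param tol EM stops when the log-likelihood improves by less than this.
#' @param max_iter maximum EM iterations.
#' @param restarts independent EM runs (seeded k-means initializations);
#'   the best likelihood is kept.
#' @param kmeans_nstart `nstart` for the k-means initializer.
#' @param seed base seed; restart r uses `seed + r - 1`.
#' @return A named list of class `cluster_control`.
#' @export
cluster_control <- function(order = 4, tol = 1e-6, max_iter = 500,
                            restarts = 5, kmeans_nstart = 5, seed = 1) {
  structure(list(order = order, tol = tol, max_iter = max_iter,
                 restarts = restarts, kmeans_nstart = kmeans_nstart,
                 seed = seed),
            class = "cluster_control")
}

curve_matrix <- function(curves) {
  if (inherits(curves, "effect_curve_set"))
    return(cbind(curves$g1, curves$g2))
  as.matrix(curves)
}

curve_times <- function(curves) {
  if (inherits(curves, "effect_curve_set")) return(curves$times)
  tm <- attr(curves, "times")
  if (is.null(tm)) stop("curve matrix needs a 'times' attribute",
                        call. = FALSE)
  tm
}

curve_ids <- function(curves, p) {
  if (inherits(curves, "effect_curve_set") && !is.null(curves$ids))
    return(curves$ids)
  if (!is.null(rownames(curves))) return(rownames(curves))
  paste0("snp", seq_len(p))
}

#' EM mixture clustering of bivariate effect curves
#'
#' Fits an `L`-component Gaussian mixture to per-marker bivariate
#' genetic-effect curves. Component mean curves are Legendre orthogonal
#' polynomial expansions (both traits), the shared within-module covariance
#' is SAD(1), and the model is fitted by EM: posterior update, exact weight
#' and generalized-least-squares mean updates, and a simplex update of the
#' covariance parameters. Initialization is seeded k-means with restarts.
#'
#' @param curves an `effect_curve_set` (see [effect_curves()],
#'   [simulate_effect_curve_sets()]) or a `p x 2T` matrix with a `times`
#'   attribute.
#' @param L number of modules (`p >= L`).
#' @param control a [cluster_control()] list.
#' @return An object of class `curve_mixture`: mixture weights `omega`,
#'   coefficient matrix `Phi` (`L x 2(order+1)`), mean curves `u`
#'   (`L x 2T`), covariance parameters `psi_g`, posterior matrix `posterior`
#'   (`p x L`, rows summing to 1), `assignment` (MAP, ties to the lowest
#'   index), `loglik`, `AIC`, `BIC`, `trace` and re-seeding log.
#' @export
em_fit <- function(curves, L, control = cluster_control()) {
  Y <- curve_matrix(curves)
  times <- curve_times(curves)
  p <- nrow(Y); T <- length(times)
  if (p < L) stop("need at least as many curves as modules", call. = FALSE)
  best <- NULL
  for (r in seq_len(if (L == 1) 1 else control$restarts)) {
    fit <- try(em_fit_once(Y, times, L, control, control$seed + r - 1L),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("all EM restarts failed", call. = FALSE)
  best$ids <- curve_ids(curves, p)
  best
}

em_fit_once <- function(Y, times, L, control, seed) {
  p <- nrow(Y); T <- length(times); m <- 2 * T
  r <- control$order
  B <- lop_basis(times, r)$basis
  X <- rbind(cbind(B, matrix(0, T, r + 1)), cbind(matrix(0, T, r + 1), B))
  set.seed(seed)
  if (L == 1) {
    Om <- matrix(1, p, 1)
  } else {
    km <- stats::kmeans(Y, centers = L, nstart = control$kmeans_nstart,
                        iter.max = 50)
    Om <- matrix(0, p, L)
    Om[cbind(seq_len(p), km$cluster)] <- 1
  }
  psi <- NULL
  ll_old <- -Inf
  trace <- numeric(0)
  reseeded <- integer(0)
  for (it in seq_len(control$max_iter)) {
    # --- M step ---
    wsum <- colSums(Om)
    omega <- wsum / p
    gbar <- t(Om) %*% Y / pmax(wsum, 1e-300)     # L x m weighted means
    if (is.null(psi)) {
      R0 <- Y - gbar[max.col(Om, "first"), , drop = FALSE]
      psi <- psi_moments(R0[, 1:T, drop = FALSE], R0[, T + 1:T, drop = FALSE])
    }
    U <- sad1_chol(psi, T)
    Qi <- chol2inv(U)
    A <- solve(t(X) %*% Qi %*% X, t(X) %*% Qi)   # GLS projector
    Phi <- gbar %*% t(A)                          # L x 2(r+1)
    u <- Phi %*% t(X)                             # L x m
    M <- matrix(0, m, m)
    for (l in seq_len(L)) {
      Rl <- sweep(Y, 2L, u[l, ])
      M <- M + crossprod(Rl * sqrt(Om[, l]))
    }
    pf <- psi_fit(M, p, T, psi, maxit = 80)
    psi <- pf$psi
    U <- sad1_chol(psi, T)
    logdet <- 2 * sum(log(diag(U)))
    # --- E step ---
    logf <- matrix(0, p, L)
    for (l in seq_len(L)) {
      V <- backsolve(U, t(sweep(Y, 2L, u[l, ])), transpose = TRUE)
      logf[, l] <- -0.5 * (m * log(2 * pi) + logdet + colSums(V^2))
    }
    lw <- sweep(logf, 2L, log(pmax(omega, 1e-300)), "+")
    mx <- apply(lw, 1, max)
    ll <- sum(mx + log(rowSums(exp(lw - mx))))
    Om <- exp(lw - mx) / rowSums(exp(lw - mx))
    # re-seed modules that lost all weight
    low <- which(colSums(Om) / p < 1 / (10 * p))
    if (length(low)) {
      worst <- order(mx + log(rowSums(exp(lw - mx))))[seq_along(low)]
      for (i in seq_along(low)) {
        Om[worst[i], ] <- 0
        Om[worst[i], low[i]] <- 1
      }
      reseeded <- c(reseeded, it)
    }
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < control$tol && ll >= ll_old - 1e-8)
      break
    ll_old <- ll
  }
  n_free <- (L - 1) + L * ncol(X) + 5
  structure(list(L = L, omega = omega, Phi = Phi, u = u, psi_g = psi,
                 posterior = Om, assignment = max.col(Om, "first"),
                 loglik = ll, n_free = n_free,
                 AIC = -2 * ll + 2 * n_free,
                 BIC = -2 * ll + n_free * log(p),
                 order = r, times = times, basis = B, trace = trace,
                 reseeded = reseeded, seed = seed),
            class = "curve_mixture")
}

#' @export
print.curve_mixture <- function(x, digits = 3, ...) {
  cat("curve mixture:", x$L, "modules,", nrow(x$posterior), "curves\n")
  cat("weights:", paste(round(x$omega, digits), collapse = " "), "\n")
  cat(sprintf("loglik %.2f  AIC %.2f  BIC %.2f (%d EM iterations)\n",
              x$loglik, x$AIC, x$BIC, length(x$trace)))
  invisible(x)
}

#' @export
logLik.curve_mixture <- function(object, ...) {
  structure(object$loglik, df = object$n_free, class = "logLik")
}

#' @export
plot.curve_mixture <- function(x, ...) {
  T <- length(x$times)
  graphics::matplot(x$times, t(x$u[, 1:T, drop = FALSE]), type = "l", lty = 1,
                    xlab = "time", ylab = "genetic effect",
                    main = "module mean curves (height solid, diameter dashed)",
                    ...)
  graphics::matlines(x$times, t(x$u[, T + 1:T, drop = FALSE]), lty = 2)
  invisible(x)
}

#' Select the number of modules by AIC or BIC
#'
#' Fits the curve mixture for each candidate number of modules (each with its
#' own deterministic seed) and returns the fit minimizing the chosen
#' criterion, with the full criterion trace attached.
#'
#' @param curves as in [em_fit()].
#' @param L_range candidate module counts.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @param control a [cluster_control()] list.
#' @return The best `curve_mixture`, with attribute `criterion_trace` (data
#'   frame of L, loglik, AIC, BIC).
#' @export
select_num_modules <- function(curves, L_range, criterion = c("BIC", "AIC"),
                               control = cluster_control()) {
  criterion <- match.arg(criterion)
  if (!length(L_range)) stop("L_range must be non-empty", call. = FALSE)
  fits <- vector("list", length(L_range))
  errs <- character(0)
  for (i in seq_along(L_range)) {
    ctl <- control
    ctl$seed <- control$seed + 1000L * L_range[i]
    fits[[i]] <- try(em_fit(curves, L_range[i], ctl), silent = TRUE)
    if (inherits(fits[[i]], "try-error"))
      errs <- c(errs, paste0("L=", L_range[i], ": ",
                             attr(fits[[i]], "condition")$message))
  }
  ok <- !vapply(fits, inherits, TRUE, "try-error")
  if (!any(ok)) stop("all mixture fits failed: ",
                     paste(errs, collapse = "; "), call. = FALSE)
  tr <- data.frame(L = L_range[ok],
                   loglik = vapply(fits[ok], `[[`, 0, "loglik"),
                   AIC = vapply(fits[ok], `[[`, 0, "AIC"),
                   BIC = vapply(fits[ok], `[[`, 0, "BIC"))
  best <- fits[ok][[which.min(tr[[criterion]])]]
  attr(best, "criterion_trace") <- tr
  attr(best, "criterion") <- criterion
  best
}

#' Module mean curves
#'
#' Returns each module's bivariate mean effect curve, either as the empirical
#' mean of the member curves (MAP assignment; the default) or as the
#' model-based Legendre expansion.
#'
#' @param fit a `curve_mixture`.
#' @param curves the curves the model was fitted to (required for the
#'   empirical type).
#' @param type `"empirical"` or `"model"`.
#' @return `L x 2T` matrix of mean curves.
#' @export
module_mean_curves <- function(fit, curves = NULL,
                               type = c("empirical", "model")) {
  type <- match.arg(type)
  if (type == "model") return(fit$u)
  if (is.null(curves)) stop("empirical means need the member curves",
                            call. = FALSE)
  Y <- curve_matrix(curves)
  out <- matrix(NA_real_, fit$L, ncol(Y))
  for (l in seq_len(fit$L)) {
    rows <- which(fit$assignment == l)
    if (length(rows))
      out[l, ] <- colMeans(Y[rows, , drop = FALSE])
  }
  out
}

#' Build a module tree from a fitted mixture
#'
#' Creates the top layer of the nested module hierarchy (modules ->
#' submodules -> markers): one node per mixture component, labeled `M<l>`,
#' holding its member ids and empirical mean curves.
#'
#' @param fit a `curve_mixture`.
#' @param curves the clustered curves.
#' @return An object of class `module_tree`.
#' @export
module_tree <- function(fit, curves) {
  Y <- curve_matrix(curves)
  ids <- fit$ids
  means <- module_mean_curves(fit, curves)
  nodes <- list()
  for (l in seq_len(fit$L)) {
    lab <- paste0("M", l)
    nodes[[lab]] <- list(label = lab, parent = NULL, children = character(0),
                         members = ids[fit$assignment == l],
                         mean = means[l, ])
  }
  structure(list(nodes = nodes, times = fit$times,
                 curves = structure(Y, times = fit$times),
                 ids = ids),
            class = "module_tree")
}

#' @export
print.module_tree <- function(x, ...) {
  roots <- names(x$nodes)[vapply(x$nodes, function(n) is.null(n$parent), TRUE)]
  cat("module tree:", length(roots), "top-level modules,",
      length(x$nodes) - length(roots), "submodule nodes,",
      length(x$ids), "markers\n")
  invisible(x)
}

#' Subcluster a module-tree node
#'
#' Recursively applies mixture-size selection and EM clustering to the member
#' curves of one node, adding child nodes labeled `SM<i>/<parent>`. The
#' children partition the parent's member set. Nodes with fewer members than
#' twice the smallest candidate L are left untouched with a warning.
#'
#' @param tree a [module_tree()].
#' @param node label of the node to split.
#' @param L_range candidate submodule counts.
#' @param control a [cluster_control()] list.
#' @param criterion `"BIC"` or `"AIC"`.
#' @return The updated `module_tree` (the sub-fit is attached to the node).
#' @export
subcluster <- function(tree, node, L_range, control = cluster_control(),
                       criterion = "BIC") {
  nd <- tree$nodes[[node]]
  if (is.null(nd)) stop("unknown node '", node, "'", call. = FALSE)
  rows <- match(nd$members, tree$ids)
  if (length(rows) < 2 * min(L_range)) {
    warning("node ", node, " too small to subcluster; skipped")
    return(tree)
  }
  sub <- structure(tree$curves[rows, , drop = FALSE], times = tree$times)
  rownames(sub) <- nd$members
  fit <- select_num_modules(sub, L_range, criterion = criterion,
                            control = control)
  means <- module_mean_curves(fit, sub)
  for (l in seq_len(fit$L)) {
    lab <- paste0("SM", l, "/", node)
    tree$nodes[[lab]] <- list(label = lab, parent = node,
                              children = character(0),
                              members = nd$members[fit$assignment == l],
                              mean = means[l, ])
    tree$nodes[[node]]$children <- c(tree$nodes[[node]]$children, lab)
  }
  tree$nodes[[node]]$subfit <- fit
  tree
}
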