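#' Control settings for epistatic-network reconstruction
#'
#' @param order_smooth Legendre order used to smooth node effect curves.
#' @param order_ode Legendre order of the independent (time-trend) term in
#'   the ODE decomposition.
#' @param n_dense dense interpolation grid size; interpolation lets the
#'   number of nodes exceed the number of observed time points.
#' @param selector support selection: `"ztest"` (noise-calibrated
#'   forward/backward test after LASSO screening, default), `"cv"`
#'   (cross-validated LASSO penalty) or `"bic"` (BIC along the path).
#' @param z_crit z-score a candidate regulator must exceed (against the
#'   closed-form noise level of the smoothed derivative) to enter the
#'   support.
#' @param screen_size candidate sets larger than this are first screened to
#'   the top-scoring subset.
#' @param lambda_rule CV rule, `"lambda.1se"` (sparser, default) or
#'   `"lambda.min"`.
#' @param nfolds CV folds (contiguous blocks).
#' @param max_in_degree cap on regulators retained per node (network
#'   sparsity).
#' @param weight_floor edges with weight below this are dropped.
#' @param smooth_tol smoothing is flagged when the fit RMSE exceeds this
#'   fraction of the curve range.
#' @param cond_limit design condition number above which the decomposition
#'   falls back to ridge.
#' @param reuse_support reuse the overall-variant regulator support for the
#'   independent variant instead of re-running selection.
#' @param seed seed for CV fold assignment (determinism).
#' @return A named list of class `network_control`.
#' @export
network_control <- function(order_smooth = 7, order_ode = 3, n_dense = 100,
                            selector = c("ztest", "cv", "bic"),
                            z_crit = 4, screen_size = 12,
                            lambda_rule = c("lambda.1se", "lambda.min"),
                            nfolds = 5, max_in_degree = 8,
                            weight_floor = 1e-8, smooth_tol = 0.02,
                            cond_limit = 1e10, reuse_support = FALSE,
                            seed = 1) {
  structure(list(order_smooth = order_smooth, order_ode = order_ode,
                 n_dense = n_dense, selector = match.arg(selector),
                 z_crit = z_crit, screen_size = screen_size,
                 lambda_rule = match.arg(lambda_rule), nfolds = nfolds,
                 max_in_degree = max_in_degree, weight_floor = weight_floor,
                 smooth_tol = smooth_tol, cond_limit = cond_limit,
                 reuse_support = reuse_support, seed = seed),
            class = "network_control")
}

#' Smooth an effect curve and interpolate onto a dense grid
#'
#' Least-squares Legendre polynomial fit of the observed curve, evaluated
#' with its analytic derivative on a dense grid spanning the observation
#' window.
#'
#' @param values observed curve values.
#' @param times observation times (>= 3).
#' @param order polynomial order (must be below the number of points).
#' @param n_dense dense grid size.
#' @param tol warn when fit RMSE exceeds this fraction of the curve range.
#' @return An object of class `smoothed_curve` with `coef`, `dense_times`,
#'   `dense_values`, `dense_deriv`, `rmse` and the raw data.
#' @export
smooth_and_interpolate <- function(values, times, order = 4, n_dense = 100,
                                   tol = 0.02) {
  T <- length(times)
  if (T < 3) stop("need at least 3 observed times", call. = FALSE)
  if (order >= T)
    stop("order must be below the number of points (would interpolate noise exactly)",
         call. = FALSE)
  bas <- lop_basis(times, order)
  cf <- stats::lsfit(bas$basis, values, intercept = FALSE)$coefficients
  dense <- seq(times[1], times[T], length.out = n_dense)
  bd <- lop_basis_at(dense, bas)
  fit <- as.vector(bas$basis %*% cf)
  rng <- diff(range(values))
  rmse <- sqrt(mean((fit - values)^2))
  if (rng > 0 && rmse > tol * rng)
    warning(sprintf("smoothing RMSE %.3g exceeds %g%% of curve range",
                    rmse, 100 * tol))
  structure(list(coef = cf, times = times, values = values,
                 order = order, dense_times = dense,
                 dense_values = as.vector(bd$basis %*% cf),
                 dense_deriv = as.vector(bd$deriv %*% cf),
                 rmse = rmse, range = rng),
            class = "smoothed_curve")
}

# evaluate an existing basis (same time map) at new times
lop_basis_at <- function(new_times, bas) {
  tmin <- bas$time_map[["t_min"]]; tmax <- bas$time_map[["t_max"]]
  x <- 2 * (new_times - tmin) / (tmax - tmin) - 1
  P <- legendre_matrix(x, bas$order)
  list(basis = P$val, deriv = P$deriv * (2 / (tmax - tmin)))
}

#' Select regulators of a focal curve
#'
#' Regresses the focal node's smoothed rate of change (the quantity the
#' network ODE models) on candidate node curves at the observed time points,
#' alongside an unpenalized low-order time-trend block absorbing the focal
#' node's own baseline dynamics. When candidates are many, they are first
#' screened to a tractable set by marginal score. The support is chosen by a
#' noise-calibrated forward/backward test: the smoothing operator makes the
#' derivative's noise covariance available in closed form
#' (`Cov = sigma^2 D (B'B)^{-1} D'` with `sigma^2` estimated from the
#' smoothing residual), so each candidate's fit gain has an exact z-score
#' under the no-edge null, and only candidates exceeding `z_crit` enter.
#' Sparsity is additionally capped at `max_in_degree`.
#'
#' Alternative selectors keep the whole decision on the LASSO path:
#' `"cv"` (cross-validated penalty, contiguous folds) and `"bic"`.
#'
#' @param focal a `smoothed_curve`.
#' @param candidates named list of `smoothed_curve`s (the focal node must
#'   not be among them).
#' @param control a [network_control()] list.
#' @return A list of class `regression_spec` with `coefficients` (named,
#'   support only, OLS scale), `support`, `trend_coef` (time-trend block),
#'   `residuals` (at the observed times).
#' @export
select_regulators <- function(focal, candidates, control = network_control()) {
  times <- focal$times
  T <- length(times)
  bas <- suppressWarnings(lop_basis(times, focal$order))
  yk <- as.vector(bas$deriv %*% focal$coef)
  Bt <- trend_block(times, control$order_ode)
  empty <- function() {
    cf <- stats::lsfit(Bt, yk, intercept = FALSE)$coefficients
    structure(list(coefficients = numeric(0), support = character(0),
                   trend_coef = cf,
                   residuals = yk - as.vector(Bt %*% cf)),
              class = "regression_spec")
  }
  if (!length(candidates) || control$max_in_degree == 0) return(empty())
  X <- vapply(candidates, `[[`, numeric(T), "values")
  keep <- apply(X, 2, function(v) stats::sd(v) > 1e-12)
  if (!any(keep) || stats::sd(yk) < 1e-12) return(empty())
  Xc <- X[, keep, drop = FALSE]

  # noise scale of the derivative estimate, from the smoothing residual
  p_bas <- ncol(bas$basis)
  sig2 <- max(T * focal$rmse^2 / max(T - p_bas, 1), 1e-12)
  K <- bas$deriv %*% solve(crossprod(bas$basis)) %*% t(bas$deriv)

  ztest <- function(sup, nm) {
    Xcur <- cbind(Bt, Xc[, sup, drop = FALSE])
    Mres <- function(v) stats::lm.fit(Xcur, v)$residuals
    xt <- Mres(Xc[, nm])
    if (stats::sd(xt) < 1e-10) return(c(0, 0))
    yt <- Mres(yk)
    den <- sqrt(max(sig2 * as.numeric(t(xt) %*% K %*% xt), 1e-300))
    c(abs(sum(xt * yt)) / den, sum(xt * yt)^2 / sum(xt^2))
  }

  if (control$selector %in% c("cv", "bic")) {
    co <- lasso_path_support(Bt, Xc, yk, control)
  } else {
    # very large candidate sets are first screened by the marginal z-score
    if (ncol(Xc) > control$screen_size) {
      z0 <- vapply(colnames(Xc), function(nm) ztest(character(0), nm)[1], 0)
      Xc <- Xc[, order(z0, decreasing = TRUE)[seq_len(control$screen_size)],
               drop = FALSE]
    }
    sup <- character(0)
    repeat {
      cand <- setdiff(colnames(Xc), sup)
      if (!length(cand) || length(sup) >= control$max_in_degree) break
      zs <- vapply(cand, function(nm) ztest(sup, nm), numeric(2))
      zs[!is.finite(zs)] <- 0
      ok <- zs[1, ] >= control$z_crit
      if (!any(ok)) break
      sup <- c(sup, cand[ok][which.max(zs[2, ok])])
    }
    repeat {
      if (!length(sup)) break
      zs <- vapply(sup, function(nm) ztest(setdiff(sup, nm), nm)[1], 0)
      if (min(zs) >= control$z_crit) break
      sup <- setdiff(sup, sup[which.min(zs)])
    }
    co <- stats::setNames(rep(0, length(sup)), sup)
  }
  if (!length(co)) return(empty())
  cf <- stats::lsfit(cbind(Bt, Xc[, names(co), drop = FALSE]), yk,
                     intercept = FALSE)$coefficients
  trend <- cf[seq_len(ncol(Bt))]
  co <- stats::setNames(cf[-seq_len(ncol(Bt))], names(co))
  eta <- as.vector(Xc[, names(co), drop = FALSE] %*% co)
  structure(list(coefficients = co, support = names(co),
                 trend_coef = trend,
                 residuals = yk - as.vector(Bt %*% trend) - eta),
            class = "regression_spec")
}

# support straight from the LASSO path: penalty by blocked CV or BIC
lasso_path_support <- function(Bt, Xc, yk, control) {
  if (ncol(Xc) < 2) {
    cf <- stats::lsfit(cbind(Bt, Xc), yk, intercept = FALSE)$coefficients
    co <- cf[ncol(Bt) + 1L]
    r2 <- 1 - sum((yk - cbind(Bt, Xc) %*% cf)^2) /
      max(sum(stats::lm.fit(Bt, yk)$residuals^2), 1e-300)
    return(if (r2 > 0.5) stats::setNames(co, colnames(Xc)) else numeric(0))
  }
  XX <- cbind(Bt, Xc)
  pf <- c(rep(0, ncol(Bt)), rep(1, ncol(Xc)))
  set.seed(control$seed)
  if (control$selector == "cv") {
    foldid <- rep(seq_len(control$nfolds),
                  each = ceiling(length(yk) / control$nfolds))[seq_along(yk)]
    cvf <- suppressWarnings(glmnet::cv.glmnet(XX, yk, foldid = foldid,
                                              penalty.factor = pf,
                                              standardize = TRUE))
    b <- stats::coef(cvf, s = control$lambda_rule)
  } else {
    gf <- suppressWarnings(glmnet::glmnet(XX, yk, penalty.factor = pf,
                                          standardize = TRUE))
    pred <- stats::predict(gf, XX)
    n <- length(yk)
    rss <- colSums((pred - yk)^2)
    bic <- n * log(pmax(rss, 1e-300) / n) + gf$df * log(n)
    b <- stats::coef(gf, s = gf$lambda[which.min(bic)])
  }
  co <- as.matrix(b)[-seq_len(ncol(Bt) + 1L), 1]
  co <- co[co != 0]
  if (length(co) > control$max_in_degree)
    co <- co[order(abs(co), decreasing = TRUE)][seq_len(control$max_in_degree)]
  co
}

# refit the regression with the support taken from another network's
# decomposition of the same node (no re-selection)
reuse_spec <- function(focal, net, node, sm, control) {
  dec <- net$decompositions[[node]]
  sup <- if (is.null(dec)) character(0) else intersect(dec$support, names(sm))
  bas <- suppressWarnings(lop_basis(focal$times, focal$order))
  yk <- as.vector(bas$deriv %*% focal$coef)
  Bt <- trend_block(focal$times, control$order_ode)
  X <- if (length(sup))
    cbind(Bt, vapply(sm[sup], `[[`, numeric(length(yk)), "values"))
  else Bt
  cf <- stats::lsfit(X, yk, intercept = FALSE)$coefficients
  co <- stats::setNames(cf[-seq_len(ncol(Bt))], sup)
  structure(list(coefficients = co, support = sup,
                 trend_coef = cf[seq_len(ncol(Bt))],
                 residuals = yk - as.vector(X %*% cf)),
            class = "regression_spec")
}

# unpenalized Legendre time-trend block (intercept + P1..Pm of mapped time)
trend_block <- function(tt, order) {
  x <- 2 * (tt - tt[1]) / (tt[length(tt)] - tt[1]) - 1
  legendre_matrix(x, order)$val
}

#' ODE decomposition of a node effect curve
#'
#' Decomposes the focal node's rate of change into an independent term (a
#' low-order Legendre expansion over the growth period plus whatever the
#' regulators do not explain) and one dependent term per selected regulator
#' (a single coefficient times the regulator's effect curve, the way the
#' growth system itself couples traits), fitted by least squares against the
#' smoothed derivative on the dense grid. The independent component absorbs
#' the least-squares residual, so the components sum exactly to the smoothed
#' derivative at every grid point; the focal curve is reconstructed from its
#' first observed value by RK4 over the decomposed derivative.
#'
#' @param focal a `smoothed_curve`.
#' @param spec a `regression_spec` from [select_regulators()].
#' @param regulators named list of `smoothed_curve`s covering
#'   `spec$support`.
#' @param control a [network_control()] list.
#' @return An object of class `ode_decomposition`: per-term coefficients
#'   (`theta_independent` for the trend block, `theta_by_regulator`),
#'   derivative components on the dense grid (`independent_deriv`,
#'   `dependent_deriv` matrix), the matching cumulative effect curves, the
#'   RK4 `reconstruction` and its RMSE, and a `ridged` flag.
#' @export
fit_ode_decomposition <- function(focal, spec, regulators = list(),
                                  control = network_control()) {
  dense_t <- focal$dense_times
  nd <- length(dense_t)
  y <- focal$dense_deriv
  sup <- spec$support
  if (!all(sup %in% names(regulators)))
    stop("regulators must cover the selected support", call. = FALSE)
  Bt <- trend_block(dense_t, control$order_ode)
  R <- if (length(sup))
    vapply(regulators[sup], `[[`, numeric(nd), "dense_values")
  else matrix(0, nd, 0)
  Xd <- cbind(Bt, R)
  ridged <- FALSE
  if (kappa(Xd, exact = FALSE) > control$cond_limit) {
    ridged <- TRUE
    lam <- 1e-6 * mean(colSums(Xd^2))
    cf <- as.vector(solve(crossprod(Xd) + lam * diag(ncol(Xd)),
                          crossprod(Xd, y)))
  } else {
    cf <- as.vector(stats::lsfit(Xd, y, intercept = FALSE)$coefficients)
  }
  theta <- cf[ncol(Bt) + seq_along(sup)]
  dep <- matrix(0, nd, length(sup), dimnames = list(NULL, sup))
  for (i in seq_along(sup)) dep[, i] <- theta[i] * R[, i]
  # the independent term absorbs the fit residual: conservation is exact
  ind <- y - if (length(sup)) rowSums(dep) else 0
  total <- ind + if (length(sup)) rowSums(dep) else 0
  recon <- rk4_curve(dense_t, total, focal$dense_values[1])
  structure(list(node = NULL, support = sup,
                 theta_independent = cf[seq_len(ncol(Bt))],
                 theta_by_regulator = stats::setNames(as.list(theta), sup),
                 dense_times = dense_t,
                 independent_deriv = ind, dependent_deriv = dep,
                 cum_independent = cumtrapz(dense_t, ind),
                 cum_dependent = if (length(sup))
                   apply(dep, 2, function(v) cumtrapz(dense_t, v))
                 else dep,
                 net_curve = focal$dense_values,
                 reconstruction = recon,
                 reconstruction_rmse = sqrt(mean((recon -
                                                    focal$dense_values)^2)),
                 ridged = ridged),
            class = "ode_decomposition")
}

# RK4 integration of a tabulated derivative (linear interpolation between
# grid points) from a given initial value
rk4_curve <- function(tt, deriv, y0) {
  f <- stats::approxfun(tt, deriv, rule = 2)
  n <- length(tt)
  out <- numeric(n)
  out[1] <- y0
  for (i in 2:n) {
    h <- tt[i] - tt[i - 1]
    t0 <- tt[i - 1]; y <- out[i - 1]
    k1 <- f(t0); k2 <- f(t0 + h / 2); k3 <- k2; k4 <- f(t0 + h)
    out[i] <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out
}

#' Directed edges implied by an ODE decomposition
#'
#' Each retained regulator contributes one directed edge into the focal
#' node. The edge weight is the time-average of the absolute dependent-effect
#' derivative; the sign (activation / inhibition) is the sign of the
#' time-averaged dependent derivative.
#'
#' @param dec an `ode_decomposition`.
#' @param focal_id id of the focal node.
#' @param floor edges with weight below this are dropped.
#' @return Data frame with columns `source`, `target`, `sign`
#'   (`"activation"` / `"inhibition"`), `weight`.
#' @export
edge_from_decomposition <- function(dec, focal_id, floor = 1e-8) {
  if (!length(dec$support))
    return(data.frame(source = character(0), target = character(0),
                      sign = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE))
  avg <- colMeans(dec$dependent_deriv)
  w <- colMeans(abs(dec$dependent_deriv))
  keep <- w >= floor
  data.frame(source = dec$support[keep],
             target = rep(focal_id, sum(keep)),
             sign = ifelse(avg[keep] >= 0, "activation", "inhibition"),
             weight = unname(w[keep]), stringsAsFactors = FALSE)
}

#' Reconstruct one layer of the epistatic network
#'
#' For every node (module, submodule or marker effect curve) in turn: smooth
#' and interpolate, select regulators among all other nodes by LASSO, fit the
#' ODE decomposition, and derive signed weighted edges. One network is built
#' per trait and variant.
#'
#' @param curves named list of numeric vectors (one effect curve per node,
#'   all on `times`), or a matrix with rownames.
#' @param times observation times.
#' @param trait `"height"` or `"diameter"` (annotation).
#' @param variant `"overall"` or `"independent"` (annotation; pass the
#'   matching curves).
#' @param layer one of `"metagalactic"`, `"intergalactic"`, `"local"` —
#'   the module, submodule and marker layers.
#' @param qtl_flags optional named logical vector marking QTL-containing
#'   nodes.
#' @param control a [network_control()] list.
#' @param reuse_from optional `epistatic_network` whose per-node regulator
#'   support is reused instead of re-running selection (honoured when
#'   `control$reuse_support` is TRUE; typically the overall-variant network
#'   when building the independent variant).
#' @return An object of class `epistatic_network`: `nodes` data frame
#'   (`id`, `qtl`, `failed`), `edges` data frame (`source`, `target`,
#'   `sign`, `weight`), the per-node `decompositions`, and annotations.
#' @export
build_layer_network <- function(curves, times,
                                trait = c("height", "diameter"),
                                variant = c("overall", "independent"),
                                layer = c("metagalactic", "intergalactic",
                                          "local"),
                                qtl_flags = NULL,
                                control = network_control(),
                                reuse_from = NULL) {
  trait <- match.arg(trait); variant <- match.arg(variant)
  layer <- match.arg(layer)
  if (is.matrix(curves))
    curves <- stats::setNames(lapply(seq_len(nrow(curves)),
                                     function(i) curves[i, ]),
                              rownames(curves))
  if (length(curves) < 2) stop("need at least 2 nodes", call. = FALSE)
  ids <- names(curves)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("curves must be named", call. = FALSE)
  sm <- lapply(curves, function(v)
    smooth_and_interpolate(v, times, order = control$order_smooth,
                           n_dense = control$n_dense,
                           tol = control$smooth_tol))
  edges <- list()
  decs <- vector("list", length(ids))
  names(decs) <- ids
  failed <- logical(length(ids))
  for (i in seq_along(ids)) {
    res <- try({
      spec <- if (isTRUE(control$reuse_support) && !is.null(reuse_from)) {
        reuse_spec(sm[[i]], reuse_from, ids[i], sm, control)
      } else {
        select_regulators(sm[[i]], sm[-i], control)
      }
      dec <- fit_ode_decomposition(sm[[i]], spec, sm[spec$support], control)
      dec$node <- ids[i]
      decs[[i]] <- dec
      edges[[i]] <- edge_from_decomposition(dec, ids[i],
                                            floor = control$weight_floor)
    }, silent = TRUE)
    if (inherits(res, "try-error")) failed[i] <- TRUE
  }
  ed <- do.call(rbind, edges[!vapply(edges, is.null, TRUE)])
  if (is.null(ed))
    ed <- data.frame(source = character(0), target = character(0),
                     sign = character(0), weight = numeric(0))
  qtl <- if (is.null(qtl_flags)) rep(FALSE, length(ids))
    else as.logical(qtl_flags[ids])
  structure(list(nodes = data.frame(id = ids, qtl = qtl, failed = failed,
                                    stringsAsFactors = FALSE),
                 edges = ed, decompositions = decs, trait = trait,
                 variant = variant, layer = layer, times = times,
                 smoothed = sm, control = control),
            class = "epistatic_network")
}

#' @export
print.epistatic_network <- function(x, ...) {
  cat(sprintf("%s %s network (%s variant): %d nodes, %d edges\n",
              x$layer, x$trait, x$variant, nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    pos <- mean(x$edges$sign == "activation")
    cat(sprintf("activation edges: %.1f%%; inhibition: %.1f%%\n",
                100 * pos, 100 * (1 - pos)))
  }
  invisible(x)
}

#' @export
summary.epistatic_network <- function(object, ...) {
  print(object)
  dd <- degree_distribution(object)
  cat("out-degree range:", paste(range(dd$degrees$out_degree), collapse = "-"),
      " in-degree range:", paste(range(dd$degrees$in_degree), collapse = "-"),
      "\n")
  invisible(object)
}

#' Convert an epistatic network to an igraph graph
#'
#' @param net an `epistatic_network`.
#' @return An [igraph::graph_from_data_frame()] directed graph with `sign`
#'   and `weight` edge attributes and `qtl` vertex attribute.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}

#' @export
plot.epistatic_network <- function(x, ...) {
  g <- as_igraph(x)
  ecol <- ifelse(igraph::E(g)$sign == "activation", "blue", "red")
  vcol <- ifelse(igraph::V(g)$qtl, "green", "grey80")
  igraph::plot.igraph(g, edge.color = ecol, vertex.color = vcol,
                      edge.width = 0.5 + 3 * igraph::E(g)$weight /
                        max(igraph::E(g)$weight, 1e-12),
                      ...)
  invisible(x)
}

#' Out- and in-degree distributions
#'
#' @param net an `epistatic_network`.
#' @return List with `degrees` (per-node out/in counts) and `histogram`
#'   (count tables of each).
#' @export
degree_distribution <- function(net) {
  ids <- net$nodes$id
  out_deg <- table(factor(net$edges$source, levels = ids))
  in_deg <- table(factor(net$edges$target, levels = ids))
  deg <- data.frame(id = ids, out_degree = as.integer(out_deg),
                    in_degree = as.integer(in_deg),
                    stringsAsFactors = FALSE)
  list(degrees = deg,
       histogram = list(out_degree = table(deg$out_degree),
                        in_degree = table(deg$in_degree)))
}

#' Deconstruct a node's effect curve into components
#'
#' Reports, on the dense grid, the node's net effect curve, its independent
#' component and each incoming dependent component (cumulative effect
#' curves anchored at the node's first value), in long format suitable for
#' component plots.
#'
#' @param net an `epistatic_network`.
#' @param node node id.
#' @return Data frame with columns `time`, `component`, `value`.
#' @export
deconstruct_node_effect <- function(net, node) {
  dec <- net$decompositions[[node]]
  if (is.null(dec)) stop("no decomposition for node '", node, "'",
                         call. = FALSE)
  y0 <- dec$net_curve[1]
  tt <- dec$dense_times
  out <- data.frame(time = tt, component = "net", value = dec$net_curve,
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(time = tt, component = "independent",
                               value = y0 + dec$cum_independent,
                               stringsAsFactors = FALSE))
  for (s in dec$support)
    out <- rbind(out, data.frame(time = tt,
                                 component = paste0("dependent:", s),
                                 value = dec$cum_dependent[, s],
                                 stringsAsFactors = FALSE))
  out
}
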