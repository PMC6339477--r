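#' Gauss-Hermite nodes and weights
#'
#' Golub-Welsch construction: eigen-decomposition of the symmetric
#' tridiagonal Jacobi matrix of the (physicists') Hermite recurrence, with
#' weights from the squared first eigenvector components. Exact for
#' polynomial integrands against exp(-x^2) up to degree 2n - 1.
#'
#' @param n Number of nodes.
#' @return List with `nodes` and `weights`.
#' @keywords internal
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1, ord]^2)
}

#' Fit a binomial random-intercept GLMM by adaptive Gauss-Hermite ML
#'
#' Models a binary behavioural response (1 = search, 0 = travel) on
#' covariates with a Gaussian random intercept per group (bird identity),
#' maximising the exact marginal likelihood
#' \deqn{\prod_i \int \prod_j \mathrm{Bern}(y_{ij} \mid
#'   \mathrm{logit}^{-1}(x_{ij}'\beta + \alpha_i))\,
#'   \varphi(\alpha_i; 0, \sigma_\alpha^2)\, d\alpha_i}
#' by quasi-Newton optimisation over \eqn{(\beta, \log\sigma_\alpha)}, with
#' the per-group integrals evaluated by adaptive Gauss-Hermite quadrature
#' (1 node = Laplace approximation). Standard errors come from the inverse
#' observed information at the optimum; Wald Z and two-sided normal
#' p-values are reported, together with marginal and conditional
#' \eqn{R^2} (see [nakagawa_r2()]).
#'
#' @param data Data frame with the response, covariate and group columns;
#'   rows with any missing value among them are dropped (count messaged).
#' @param response Name of the 0/1 response column (default `"y"`).
#' @param covariates Character vector of fixed-effect column names (an
#'   intercept is always included). May be empty for an intercept-only fit.
#' @param group Name of the grouping column (default `"individual_id"`).
#' @param quadrature_nodes Number of Gauss-Hermite nodes (default 25).
#' @param sigma_fixed Optional non-negative value at which to fix
#'   \eqn{\sigma_\alpha} instead of estimating it; `0` gives a plain
#'   logistic regression.
#' @return An object of class `glmm_fit`; see [tidy.glmm_fit()] and
#'   [glance.glmm_fit()] for tabular summaries.
#' @export
fit_binomial_glmm <- function(data, response = "y",
                              covariates = c("sst_rank", "turbidity_rank",
                                             "chla_rank"),
                              group = "individual_id",
                              quadrature_nodes = 25,
                              sigma_fixed = NULL) {
  stopifnot(quadrature_nodes >= 1)
  cols <- c(response, covariates, group)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0)
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))

  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " row(s) with missing values dropped before fitting")
  d <- data[keep, , drop = FALSE]

  y <- as.numeric(d[[response]])
  if (!all(y %in% c(0, 1))) stop("response must be 0/1")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(d[, covariates, drop = FALSE]))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  g <- as.integer(factor(d[[group]])) - 1L
  ngroups <- max(g) + 1L
  if (ngroups < 2 && is.null(sigma_fixed))
    warning("fewer than 2 groups; random-intercept variance is not ",
            "meaningfully estimable", call. = FALSE)

  gh <- gauss_hermite(quadrature_nodes)
  p <- ncol(X)
  estimate_sigma <- is.null(sigma_fixed)

  nll <- function(par) {
    sigma <- if (estimate_sigma) exp(par[p + 1]) else sigma_fixed
    -glmm_marginal_loglik_cpp(par[1:p], sigma, X, y, g, ngroups,
                              gh$nodes, gh$weights)
  }

  # warm start from an unpenalised logistic fit
  start_glm <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())$coefficients)
  par0 <- if (estimate_sigma) c(start_glm, log(0.5)) else start_glm

  # fine finite-difference steps: the default 1e-3 is too coarse for the
  # curvature of this likelihood and can strand BFGS off the optimum
  ctrl <- list(maxit = 500, reltol = 1e-12, ndeps = rep(1e-5, length(par0)))
  opt <- stats::optim(par0, nll, method = "BFGS", control = ctrl)
  # restarting BFGS resets its curvature approximation and escapes stalls
  for (k in 1:3) {
    opt2 <- stats::optim(opt$par, nll, method = "BFGS", control = ctrl)
    improved <- opt$value - opt2$value
    if (opt2$value <= opt$value) opt <- opt2
    if (improved < 1e-8) break
  }
  converged <- opt$convergence == 0

  beta <- opt$par[1:p]
  names(beta) <- colnames(X)
  sigma <- if (estimate_sigma) exp(opt$par[p + 1]) else sigma_fixed
  boundary <- estimate_sigma && sigma < 1e-3

  # observed information; at a sigma ~ 0 boundary the log-sigma direction is
  # degenerate, so fall back to the fixed-effect block with sigma held fixed
  se <- rep(NA_real_, p)
  ndeps <- function(k) list(ndeps = rep(1e-4, k))
  if (boundary) {
    h <- stats::optimHess(beta, function(b) -glmm_marginal_loglik_cpp(
      b, 0, X, y, g, ngroups, gh$nodes, gh$weights), control = ndeps(p))
    vc <- try(solve(h), silent = TRUE)
    if (!inherits(vc, "try-error") && all(diag(vc) > 0)) se <- sqrt(diag(vc))
    else warning("singular information matrix; SEs unavailable", call. = FALSE)
    warning("random-intercept variance estimate at the zero boundary",
            call. = FALSE)
  } else {
    h <- stats::optimHess(opt$par, nll, control = ndeps(length(opt$par)))
    vc <- try(solve(h), silent = TRUE)
    if (inherits(vc, "try-error") || any(diag(vc)[1:p] <= 0)) {
      # an unusable information matrix usually means a stalled optimiser:
      # rescue with a derivative-free pass before giving up on SEs
      nm <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
      opt2 <- stats::optim(nm$par, nll, method = "BFGS", control = ctrl)
      if (opt2$value <= opt$value) {
        opt <- opt2
        beta <- opt$par[1:p]
        names(beta) <- colnames(X)
        sigma <- if (estimate_sigma) exp(opt$par[p + 1]) else sigma_fixed
      }
      h <- stats::optimHess(opt$par, nll, control = ndeps(length(opt$par)))
      vc <- try(solve(h), silent = TRUE)
    }
    if (!inherits(vc, "try-error") && all(diag(vc)[1:p] > 0))
      se <- sqrt(diag(vc)[1:p])
    else warning("singular information matrix; SEs unavailable", call. = FALSE)
  }

  z <- beta / se
  fit <- structure(list(
    beta = beta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    sigma2_alpha = unname(sigma^2), loglik = unname(-opt$value),
    converged = converged, boundary = boundary,
    nobs = length(y), ngroups = ngroups,
    n_dropped = n_dropped,
    quadrature_nodes = quadrature_nodes,
    covariates = covariates, response = response, group = group,
    X = X, y = y, group_index = g
  ), class = "glmm_fit")
  r2 <- nakagawa_r2(fit)
  fit$r2_marginal <- r2[["r2_marginal"]]
  fit$r2_conditional <- r2[["r2_conditional"]]
  if (!converged)
    warning("optimiser did not converge within the iteration budget",
            call. = FALSE)
  fit
}

#' Marginal and conditional R-squared of a logit-link GLMM
#'
#' Variance-partition goodness of fit: with \eqn{\sigma_f^2} the variance
#' of the fixed-effect linear predictor across observations,
#' \eqn{\sigma_\alpha^2} the random-intercept variance and \eqn{\pi^2/3}
#' the logistic distribution-specific variance,
#' \deqn{R^2_m = \sigma_f^2 / (\sigma_f^2 + \sigma_\alpha^2 + \pi^2/3),
#'  \quad R^2_c = (\sigma_f^2 + \sigma_\alpha^2) /
#'   (\sigma_f^2 + \sigma_\alpha^2 + \pi^2/3).}
#'
#' @param fit A [fit_binomial_glmm()] object, or `NULL` when supplying the
#'   components directly.
#' @param sigma2_fixed,sigma2_alpha Optional variance components overriding
#'   those of `fit` (useful for closed-form checks).
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
nakagawa_r2 <- function(fit = NULL, sigma2_fixed = NULL, sigma2_alpha = NULL) {
  if (is.null(sigma2_fixed)) {
    stopifnot(inherits(fit, "glmm_fit"))
    sigma2_fixed <- stats::var(as.vector(fit$X %*% fit$beta))
  }
  if (is.null(sigma2_alpha)) sigma2_alpha <- fit$sigma2_alpha
  denom <- sigma2_fixed + sigma2_alpha + pi^2 / 3
  c(r2_marginal = sigma2_fixed / denom,
    r2_conditional = (sigma2_fixed + sigma2_alpha) / denom)
}

#' Population-level predicted probability of search behaviour
#'
#' Inverse-logit of the fixed-effect linear predictor (random effect at 0).
#'
#' @param fit A [fit_binomial_glmm()] object.
#' @param newdata Data frame with the fit's covariate columns. Ranked
#'   covariates outside `[0, 20]` trigger a warning but are still used.
#' @return Numeric vector of probabilities.
#' @export
predict_search_probability <- function(fit, newdata) {
  stopifnot(inherits(fit, "glmm_fit"))
  X <- cbind(1, as.matrix(newdata[, fit$covariates, drop = FALSE]))
  ranky <- grepl("_rank$", fit$covariates)
  if (any(ranky)) {
    rv <- as.matrix(newdata[, fit$covariates[ranky], drop = FALSE])
    if (any(rv < 0 | rv > 20, na.rm = TRUE))
      warning("rank covariate outside [0, 20]", call. = FALSE)
  }
  stats::plogis(as.vector(X %*% fit$beta))
}

#' Partial-effect curve of one covariate
#'
#' Predicted search probability over a grid of one covariate with the
#' others held at a reference value (default mid-rank 10), with a 95%
#' pointwise Wald band on the link scale.
#'
#' @param fit A [fit_binomial_glmm()] object.
#' @param variable Covariate name to vary.
#' @param at Reference value for the remaining covariates (default 10).
#' @param grid Grid of values (default 0 to 20).
#' @return Tibble with `value`, `prob`, `lower`, `upper`.
#' @export
partial_effect <- function(fit, variable, at = 10,
                           grid = seq(0, 20, length.out = 101)) {
  stopifnot(variable %in% fit$covariates)
  nd <- as.data.frame(matrix(at, nrow = length(grid),
                             ncol = length(fit$covariates)))
  names(nd) <- fit$covariates
  nd[[variable]] <- grid
  X <- cbind(1, as.matrix(nd))
  eta <- as.vector(X %*% fit$beta)
  # delta-method band needs the fixed-effect covariance; rebuild from SEs is
  # insufficient, so recompute the observed information over beta only
  gh <- gauss_hermite(fit$quadrature_nodes)
  h <- stats::optimHess(fit$beta, function(b) -glmm_marginal_loglik_cpp(
    b, sqrt(fit$sigma2_alpha), fit$X, fit$y, fit$group_index, fit$ngroups,
    gh$nodes, gh$weights), control = list(ndeps = rep(1e-4, length(fit$beta))))
  vc <- try(solve(h), silent = TRUE)
  se_eta <- if (inherits(vc, "try-error")) rep(NA_real_, length(eta))
    else sqrt(rowSums((X %*% vc) * X))
  tibble::tibble(value = grid, prob = stats::plogis(eta),
                 lower = stats::plogis(eta - 1.96 * se_eta),
                 upper = stats::plogis(eta + 1.96 * se_eta))
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Binomial random-intercept GLMM (adaptive Gauss-Hermite,",
      x$quadrature_nodes, "nodes)\n")
  cat(x$nobs, "observations,", x$ngroups, "groups; logLik",
      format(x$loglik, digits = 6), "\n\n")
  tab <- data.frame(Estimate = round(x$beta, 3), SE = round(x$se, 3),
                    Z = round(x$z, 2),
                    `P-value` = format.pval(x$p, digits = 2, eps = 1e-3),
                    check.names = FALSE)
  print(tab)
  cat("\nRandom intercept variance:", format(x$sigma2_alpha, digits = 4),
      "\nR2 cond./marg.:", paste0(round(x$r2_conditional, 2), "/",
                                  round(x$r2_marginal, 2)), "\n")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' Coefficient table of a GLMM fit
#'
#' @param x A `glmm_fit` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy glmm_fit
#' @export
tidy.glmm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                 std.error = unname(x$se), statistic = unname(x$z),
                 p.value = unname(x$p))
}

#' One-row model summary of a GLMM fit
#'
#' @param x A `glmm_fit` object.
#' @param ... Unused.
#' @return One-row tibble with variance components, R-squareds, log
#'   likelihood and fit metadata.
#' @method glance glmm_fit
#' @export
glance.glmm_fit <- function(x, ...) {
  tibble::tibble(sigma2_alpha = x$sigma2_alpha,
                 r2_marginal = x$r2_marginal,
                 r2_conditional = x$r2_conditional,
                 logLik = x$loglik, nobs = x$nobs, ngroups = x$ngroups,
                 converged = x$converged)
}

#' JSON summary of a GLMM fit
#'
#' @param fit A `glmm_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    coefficients = as.list(fit$beta), se = as.list(stats::setNames(fit$se, names(fit$beta))),
    z = as.list(stats::setNames(fit$z, names(fit$beta))),
    p = as.list(stats::setNames(fit$p, names(fit$beta))),
    sigma2_alpha = fit$sigma2_alpha, loglik = fit$loglik,
    r2_marginal = fit$r2_marginal, r2_conditional = fit$r2_conditional,
    converged = fit$converged, nobs = fit$nobs, ngroups = fit$ngroups
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
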