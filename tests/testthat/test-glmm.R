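# Simulate a random-intercept logistic data set with known parameters.
sim_glmm_data <- function(ngroups = 15, nper = 200,
                          beta = c(-2.247, 0.065, -0.050, -0.002),
                          sigma = 1) {
  g <- rep(seq_len(ngroups), each = nper)
  X <- cbind(1, matrix(runif(ngroups * nper * 3, 0, 20), ncol = 3))
  alpha <- rnorm(ngroups, 0, sigma)
  y <- rbinom(length(g), 1, plogis(as.vector(X %*% beta) + alpha[g]))
  data.frame(y = y, sst_rank = X[, 2], turbidity_rank = X[, 3],
             chla_rank = X[, 4], individual_id = g)
}

test_that("Gauss-Hermite rule integrates polynomials exactly", {
  gh <- fptforage:::gauss_hermite(7)
  # moments of exp(-x^2): odd vanish, even = gamma((k+1)/2)
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes), 0, tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2, tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^8), 105 / 16 * sqrt(pi),
               tolerance = 1e-10)
})

test_that("sigma fixed at zero reproduces the IRLS logistic oracle", {
  set.seed(51)
  d <- sim_glmm_data(sigma = 0, nper = 100)
  fit <- fit_binomial_glmm(d, sigma_fixed = 0)
  oracle <- glm(y ~ sst_rank + turbidity_rank + chla_rank, data = d,
                family = binomial())
  expect_lt(max(abs(fit$beta - coef(oracle))), 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(oracle)))),
               tolerance = 1e-3)
})

test_that("estimates agree with an independent adaptive-quadrature fitter", {
  skip_if_not_installed("lme4")
  set.seed(52)
  d <- sim_glmm_data(nper = 150)
  fit <- fit_binomial_glmm(d)
  ref <- lme4::glmer(y ~ sst_rank + turbidity_rank + chla_rank +
                       (1 | individual_id), data = d, family = binomial,
                     nAGQ = 25)
  expect_lt(max(abs(fit$beta - lme4::fixef(ref))), 1e-4)
  expect_equal(fit$sigma2_alpha, unname(unlist(lme4::VarCorr(ref))),
               tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(vcov(ref))))),
               tolerance = 1e-3)
})

test_that("Laplace (1 node) and 25-node fits agree on a well-behaved set", {
  set.seed(53)
  d <- sim_glmm_data(nper = 150)
  f1 <- fit_binomial_glmm(d, quadrature_nodes = 1)
  f25 <- fit_binomial_glmm(d, quadrature_nodes = 25)
  expect_lt(abs(f1$loglik - f25$loglik), 0.5)
  expect_lt(max(abs(f1$beta - f25$beta)), 0.02)
})

test_that("marginal log-likelihood beats the null fit and has zero score", {
  set.seed(54)
  d <- sim_glmm_data(nper = 120)
  fit <- fit_binomial_glmm(d)
  null_fit <- suppressWarnings(
    fit_binomial_glmm(d, covariates = character(0)))
  expect_gte(fit$loglik, null_fit$loglik)

  gh <- fptforage:::gauss_hermite(25)
  Xm <- fit$X
  ll <- function(par) fptforage:::glmm_marginal_loglik_cpp(
    par[1:4], exp(par[5]), Xm, fit$y, fit$group_index, fit$ngroups,
    gh$nodes, gh$weights)
  par_hat <- c(fit$beta, log(sqrt(fit$sigma2_alpha)))
  eps <- 1e-5
  grad <- vapply(seq_along(par_hat), function(j) {
    e <- rep(0, length(par_hat)); e[j] <- eps
    (ll(par_hat + e) - ll(par_hat - e)) / (2 * eps)
  }, numeric(1))
  # score per observation near zero at the optimum
  expect_lt(max(abs(grad)) / fit$nobs, 1e-5)
})

test_that("estimator precision improves with the number of groups", {
  set.seed(55)
  rmse <- function(ngroups, reps = 8) {
    errs <- replicate(reps, {
      d <- sim_glmm_data(ngroups = ngroups, nper = 60,
                         beta = c(-1, 0.08, -0.05, 0), sigma = 1)
      f <- suppressWarnings(fit_binomial_glmm(d))
      f$beta[["sst_rank"]] - 0.08
    })
    sqrt(mean(errs^2))
  }
  expect_lt(rmse(60), rmse(15) * 1.2)  # loose 1/sqrt(groups) trend check
})

test_that("Nakagawa variance-partition R2 follows the closed form", {
  r2 <- nakagawa_r2(sigma2_fixed = 1, sigma2_alpha = 2)
  expect_equal(r2[["r2_marginal"]], 1 / (3 + pi^2 / 3), tolerance = 1e-9)
  expect_equal(r2[["r2_conditional"]], 3 / (3 + pi^2 / 3), tolerance = 1e-9)
  expect_equal(r2[["r2_marginal"]], 0.1590, tolerance = 1e-3)
  expect_equal(r2[["r2_conditional"]], 0.4770, tolerance = 1e-3)

  # no fixed-effect variance -> marginal 0; no random variance -> collapse
  expect_equal(nakagawa_r2(sigma2_fixed = 0,
                           sigma2_alpha = 1.3)[["r2_marginal"]], 0)
  r2c <- nakagawa_r2(sigma2_fixed = 0.7, sigma2_alpha = 0)
  expect_equal(r2c[["r2_marginal"]], r2c[["r2_conditional"]])

  set.seed(56)
  d <- sim_glmm_data(nper = 80)
  fit <- fit_binomial_glmm(d)
  expect_true(fit$r2_marginal >= 0 && fit$r2_marginal <= fit$r2_conditional)
  expect_lte(fit$r2_conditional, 1)
})

test_that("population-level predictions invert the link", {
  set.seed(57)
  d <- sim_glmm_data(nper = 80)
  fit <- fit_binomial_glmm(d)
  fit$beta <- c(-2.247, 0.065, -0.050, -0.002)  # reference coefficients
  nd <- data.frame(sst_rank = 0, turbidity_rank = 0, chla_rank = 0)
  expect_equal(predict_search_probability(fit, nd), plogis(-2.247),
               tolerance = 1e-9)
  expect_equal(round(predict_search_probability(fit, nd), 4), 0.0956)

  grid <- data.frame(sst_rank = seq(0, 20, 1), turbidity_rank = 10,
                     chla_rank = 10)
  p <- predict_search_probability(fit, grid)
  expect_true(all(diff(p) > 0))  # increasing when beta_sst > 0

  fit$beta <- c(0, 0, 0, 0)
  expect_equal(predict_search_probability(fit, grid), rep(0.5, 21))
  fit$beta <- c(-2.247, 0.065, -0.050, -0.002)
  expect_warning(predict_search_probability(
    fit, data.frame(sst_rank = 25, turbidity_rank = 10, chla_rank = 10)),
    "outside")
})

test_that("fit surface: validation, missing rows, tidiers", {
  set.seed(58)
  d <- sim_glmm_data(nper = 60)
  d$sst_rank[1:5] <- NA
  expect_message(fit <- fit_binomial_glmm(d), "5 row")
  expect_equal(fit$nobs, nrow(d) - 5)

  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "sst_rank", "turbidity_rank",
                          "chla_rank"))
  expect_true(all(td$std.error > 0))
  expect_true(all(td$p.value >= 0 & td$p.value <= 1))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)

  d2 <- d
  d2$dup <- d2$sst_rank
  expect_error(fit_binomial_glmm(d2, covariates = c("sst_rank", "dup")),
               "rank deficient")
  expect_error(fit_binomial_glmm(d, response = "nope"), "lacks column")
  d3 <- d
  d3$y <- d3$y + 1
  expect_error(fit_binomial_glmm(d3), "0/1")
})

test_that("partial effects hold other covariates at the reference rank", {
  set.seed(59)
  d <- sim_glmm_data(nper = 100)
  fit <- fit_binomial_glmm(d)
  pe <- partial_effect(fit, "sst_rank", at = 10)
  expect_equal(nrow(pe), 101)
  mid <- predict_search_probability(
    fit, data.frame(sst_rank = pe$value, turbidity_rank = 10, chla_rank = 10))
  expect_equal(pe$prob, mid)
  expect_true(all(pe$lower <= pe$prob & pe$prob <= pe$upper))
})
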