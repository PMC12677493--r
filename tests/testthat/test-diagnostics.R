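test_that("R-hat is near one for well-mixed chains and detects
           separation", {
  set.seed(417)
  x <- rnorm(10000)
  ch <- cbind(x, x) # identical chains
  expect_lt(abs(rhat(ch) - 1), 0.001)
  iid <- matrix(rnorm(20000), ncol = 2)
  expect_lt(abs(rhat(iid) - 1), 0.01)
  # two chains offset by 5 SDs: between-chain variance dominates
  sep <- cbind(rnorm(1000), rnorm(1000) + 5)
  expect_gt(rhat(sep), 1.1)
  expect_error(rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
})

test_that("R-hat matches an independently coded split formula", {
  set.seed(418)
  for (r in 1:10) {
    # AR(1) chains with different persistence
    mk <- function(rho) {
      x <- numeric(500)
      for (i in 2:500) x[i] <- rho * x[i - 1] + rnorm(1)
      x
    }
    ch <- cbind(mk(0.3), mk(0.6), mk(0.1))
    expect_equal(rhat(ch), oracle_rhat(ch), tolerance = 1e-10)
  }
})

test_that("ESS recovers the independent and AR(1) closed forms", {
  set.seed(419)
  iid <- matrix(rnorm(10000), ncol = 2)
  e <- ess(iid)
  expect_equal(e$bulk, 10000, tolerance = 0.15)
  expect_false(e$constant)
  # AR(1), rho = 0.9: ESS ~ n (1 - rho) / (1 + rho)
  rho <- 0.9
  mk <- function(n) {
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sqrt(1 / (1 - rho^2)))
    for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1)
    x
  }
  ch <- cbind(mk(20000), mk(20000))
  expect_equal(ess(ch)$bulk, 40000 * (1 - rho) / (1 + rho),
               tolerance = 0.25)
  # constant chains: defined as zero with a flag, no exception
  cc <- ess(matrix(2, 100, 2))
  expect_equal(cc$bulk, 0)
  expect_equal(cc$tail, 0)
  expect_true(cc$constant)
})

test_that("WAIC matches pencil-and-paper on a 2x2 matrix", {
  ll <- matrix(c(-1, -1.5, -2, -2.5), 2) # draws x observations
  res <- waic(ll)
  lppd <- log((exp(-1) + exp(-1.5)) / 2) + log((exp(-2) + exp(-2.5)) / 2)
  p <- var(c(-1, -1.5)) + var(c(-2, -2.5))
  expect_equal(res$waic, -2 * (lppd - p), tolerance = 1e-12)
  expect_equal(res$p_waic, p, tolerance = 1e-12)
  # zero-variance columns: p_waic = 0 and waic = -2 sum(ll)
  ll0 <- matrix(rep(c(-1.3, -0.7), each = 5), 5)
  res0 <- waic(ll0)
  expect_identical(res0$p_waic, 0)
  expect_identical(res0$waic, -2 * (-1.3 - 0.7))
  expect_error(waic(matrix(c(1, NA), 1)), "non-finite")
})

test_that("PSIS-LOO equals WAIC exactly for zero-variance log-likelihood
           and flags injected outliers", {
  ll0 <- matrix(rep(c(-1.3, -0.7, -2.2), each = 150), 150)
  expect_identical(loo(ll0)$looic, waic(ll0)$waic)
  # a well-specified logistic simulation keeps all pareto k below 0.7
  # and looic close to waic
  set.seed(420)
  n <- 1000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * x))
  ml <- glm(y ~ x, binomial)
  V <- vcov(ml)
  draws <- MASS::mvrnorm(800, coef(ml), V)
  eta <- cbind(1, x) %*% t(draws) # n x draws
  ll <- t(y * eta - log(1 + exp(eta))) # draws x n
  l <- loo(ll)
  w <- waic(ll)
  expect_true(all(l$pareto_k < 0.7))
  expect_lt(abs(w$waic - l$looic), 2)
  # inject one wildly misfit observation: its k is the maximum
  ll_out <- ll
  ll_out[, 17] <- ll_out[, 17] * (1 + 3 * abs(rnorm(nrow(ll))))
  l2 <- loo(ll_out)
  expect_equal(which.max(l2$pareto_k), 17L)
  expect_error(loo(ll[1:50, ]), ">= 100")
})

test_that("the diagnostics report flags nonconverged parameters and high
           pareto k", {
  cfg <- synthetic_config("refined", n = 600)
  gen <- generate_dataset(cfg, 33)
  dr <- fit(build_model(refined_spec()), gen$data,
            mcmc_config(chains = 2, iter = 500, warmup = 250, seed = 9))
  rep <- diagnostics_report(dr, gen$data)
  expect_true(all(c("rhat", "ess_bulk", "ess_tail") %in%
                    names(rep$parameters)))
  expect_equal(nrow(rep$parameters), dim(dr$draws)[3])
  expect_true(is.finite(rep$waic))
  expect_gte(rep$looic, rep$waic - 10)
  expect_length(rep$pareto_k, 600)
})

test_that("identical sensitivity cells give identical summaries and the
           refinement rule drops zero-covered mediators", {
  cfg <- synthetic_config("refined", n = 500)
  gen <- generate_dataset(cfg, 44)
  spec <- refined_spec()
  mc <- mcmc_config(chains = 2, iter = 400, warmup = 200, seed = 11)
  sens <- sensitivity_run(list(a = spec, b = spec),
                          list(default = prior_config()),
                          gen$data, mc, information_criteria = FALSE)
  cells <- sens$cells
  expect_equal(cells$direct[cells$spec == "a"],
               cells$direct[cells$spec == "b"])
  expect_equal(cells$proportion_mediated[cells$spec == "a"],
               cells$proportion_mediated[cells$spec == "b"])
  # refinement: a mediator whose indirect HDI covers zero is dropped
  sch <- k_mediator_schema(2)
  spec2 <- model_spec(sch, mediators = c("M1", "M2"),
                      controls = character(0))
  set.seed(421)
  dm <- cbind(bX = rnorm(300, 0.2, 0.02),
              gamma_M1 = rnorm(300, 1, 0.05), b_M1 = rnorm(300, 1, 0.05),
              gamma_M2 = rnorm(300, 0, 0.5), b_M2 = rnorm(300, 0, 0.5))
  ref <- refine_spec(decompose(dm, spec2), spec2)
  expect_equal(ref$mediators, "M1")
})

test_that("prior choice washes out at strong-signal sample sizes", {
  cfg <- synthetic_config("refined", n = 4000)
  gen <- generate_dataset(cfg, 55)
  spec <- refined_spec()
  mc <- mcmc_config(chains = 2, iter = 1000, warmup = 500, seed = 13)
  sens <- sensitivity_run(list(refined = spec),
                          list(default = prior_config(),
                               diffuse = prior_config("diffuse")),
                          gen$data, mc, information_criteria = FALSE)
  expect_true(all(sens$cells$status == "ok"))
  # mediation path means shift by less than 0.1 on the logit scale
  expect_null(sens$flags)
})

test_that("model comparison prefers the specification that generated the
           data", {
  # data generated without pain/smoking paths: the refined system should
  # win on LOOIC in a clear majority of replicates
  wins <- 0L
  nrep <- 10
  for (r in seq_len(nrep)) {
    cfg <- synthetic_config("refined", n = 1500)
    gen <- generate_dataset(cfg, 600 + r)
    mc <- mcmc_config(chains = 2, iter = 600, warmup = 300, seed = r)
    looics <- vapply(list(refined_spec(), comprehensive_spec()),
                     function(sp) {
                       dr <- fit(build_model(sp), gen$data, mc)
                       loo(pointwise_loglik(dr, gen$data))$looic
                     }, numeric(1))
    if (looics[1] < looics[2]) wins <- wins + 1L
  }
  expect_gte(wins / nrep, 0.8)
})
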