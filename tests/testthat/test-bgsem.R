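test_that("model specification validates bindings", {
  sch <- toy_schema()
  expect_error(model_spec(sch, mediators = c("Mb", "Qx")), "Qx")
  expect_error(model_spec(sch, mediators = c("Mb", "C")),
               "not declared as mediator")
  spec <- model_spec(sch)
  expect_equal(spec$mediators, c("Mb", "Mo"))
  expect_equal(spec$exposure, "X")
})

test_that("prior presets carry the documented families and scales", {
  p <- prior_config()
  expect_equal(p$coefficient$family, "cauchy")
  expect_equal(p$coefficient$scale, 2.5)
  expect_equal(p$intercept, list(family = "student_t", df = 3,
                                 location = 0, scale = 2.5))
  d <- prior_config("diffuse")
  expect_equal(d$coefficient$family, "flat")
  expect_equal(d$intercept$df, 1)
  expect_equal(d$intercept$scale, 1000)
  expect_error(prior_config(coefficient = list(family = "normal",
                                               scale = -1)), "scale")
})

test_that("the joint weighted log-density matches longhand computation", {
  sch <- toy_schema()
  d <- toy_dataset(25, seed = 3)
  spec <- model_spec(sch)
  model <- build_model(spec, prior_config())
  pars <- c(alpha_Y = -1.1, bX = 0.4, b_Mb = 0.6, b_Mo = -0.3, b_C = 0.2,
            alpha_Mb = -0.5, gamma_Mb = 0.7,
            "alpha_Mo[1]" = -0.8, "alpha_Mo[2]" = 0.9, gamma_Mo = -0.6)
  rec <- d$records
  w <- d$weight
  # outcome block
  Xy <- cbind(1, rec$X, rec$Mb, rec$Mo, rec$C)
  ll <- oracle_logistic_ll(pars[1:5], Xy, rec$Y, w)
  # binary mediator block
  ll <- ll + oracle_logistic_ll(pars[c("alpha_Mb", "gamma_Mb")],
                                cbind(1, rec$X), rec$Mb, w)
  # ordinal mediator block (latent-shift cumulative logit)
  sig <- function(x) 1 / (1 + exp(-x))
  for (i in seq_len(nrow(rec))) {
    eta <- pars["gamma_Mo"] * rec$X[i]
    cum <- c(0, sig(pars["alpha_Mo[1]"] - eta),
             sig(pars["alpha_Mo[2]"] - eta), 1)
    ll <- ll + w[i] * log(cum[rec$Mo[i] + 2] - cum[rec$Mo[i] + 1])
  }
  expect_equal(model_log_density(model, d, pars, include_prior = FALSE),
               unname(ll), tolerance = 1e-12)
  # priors: Cauchy(0, 2.5) on coefficients, Student-t(3, 0, 2.5) elsewhere
  lp_cauchy <- function(x) -log(1 + (x / 2.5)^2)
  lp_t <- function(x) -2 * log(1 + (x / 2.5)^2 / 3)
  lp <- sum(lp_cauchy(pars[c("bX", "b_Mb", "b_Mo", "b_C", "gamma_Mb",
                             "gamma_Mo")])) +
    sum(lp_t(pars[c("alpha_Y", "alpha_Mb", "alpha_Mo[1]", "alpha_Mo[2]")]))
  expect_equal(model_log_density(model, d, pars),
               unname(ll + lp), tolerance = 1e-10)
  expect_error(model_log_density(model, d, pars[-2]), "bX")
})

test_that("unit weights reduce the pseudo-likelihood to the plain
           likelihood", {
  sch <- toy_schema()
  d <- toy_dataset(30, seed = 4, weights = rep(1, 30))
  model <- build_model(model_spec(sch))
  pars <- c(alpha_Y = 0.2, bX = -0.4, b_Mb = 0.1, b_Mo = 0.3, b_C = -0.2,
            alpha_Mb = 0.4, gamma_Mb = -0.7,
            "alpha_Mo[1]" = -1, "alpha_Mo[2]" = 1, gamma_Mo = 0.5)
  rec <- d$records
  unweighted <- oracle_logistic_ll(pars[1:5],
                                   cbind(1, rec$X, rec$Mb, rec$Mo, rec$C),
                                   rec$Y, rep(1, 30)) +
    oracle_logistic_ll(pars[6:7], cbind(1, rec$X), rec$Mb, rep(1, 30))
  sig <- function(x) 1 / (1 + exp(-x))
  for (i in 1:30) {
    eta <- pars["gamma_Mo"] * rec$X[i]
    cum <- c(0, sig(pars["alpha_Mo[1]"] - eta),
             sig(pars["alpha_Mo[2]"] - eta), 1)
    unweighted <- unweighted + log(cum[rec$Mo[i] + 2] - cum[rec$Mo[i] + 1])
  }
  expect_equal(model_log_density(model, d, pars, include_prior = FALSE),
               unname(unweighted), tolerance = 1e-12)
})

test_that("sampler gradients agree with numerical differentiation", {
  sch <- toy_schema()
  d <- toy_dataset(40, seed = 6)
  spec <- model_spec(sch)
  model <- build_model(spec)
  set.seed(411)
  for (plan in bgsem:::submodel_plan(spec)) {
    X <- bgsem:::submodel_design(spec, plan, d$records)
    y <- as.integer(d$records[[plan$response]])
    pr <- bgsem:::plan_priors(plan, model$priors)
    q <- rnorm(length(plan$params), 0, 0.4)
    fam <- ifelse(plan$family == "binary", 0L, 1L)
    res <- bgsem:::cpp_logpost(fam, X, y, d$weight, plan$ncat, pr$type,
                               pr$df, pr$loc, pr$scale, q, TRUE)
    num <- vapply(seq_along(q), function(j) {
      h <- 1e-6
      qp <- q; qp[j] <- qp[j] + h
      qm <- q; qm[j] <- qm[j] - h
      (bgsem:::cpp_logpost(fam, X, y, d$weight, plan$ncat, pr$type, pr$df,
                           pr$loc, pr$scale, qp, TRUE)$lp -
         bgsem:::cpp_logpost(fam, X, y, d$weight, plan$ncat, pr$type,
                             pr$df, pr$loc, pr$scale, qm, TRUE)$lp) /
        (2 * h)
    }, numeric(1))
    expect_equal(as.vector(res$grad), num, tolerance = 1e-5)
  }
})

test_that("a zero-mediator system is a weighted logistic regression and
           the posterior matches the ML oracle", {
  sch <- schema(
    variable_spec("X", "exposure", "binary", c("No", "Yes")),
    variable_spec("Y", "outcome", "binary", c("No", "Yes")),
    variable_spec("C", "control", "binary", c("A", "B")))
  set.seed(409)
  n <- 2000
  x <- rbinom(n, 1, 0.4)
  cc <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.8 + 0.9 * x - 0.5 * cc))
  d <- bgsem_dataset(data.frame(X = x, Y = y, C = cc), rep(1, n), sch)
  spec <- model_spec(sch, mediators = character(0))
  model <- build_model(spec, prior_config("diffuse"))
  dr <- fit(model, d, mcmc_config(chains = 2, iter = 1200, warmup = 600,
                                  seed = 2))
  s <- summary(dr)
  ml <- glm(y ~ x + cc, binomial)
  for (pair in list(c("alpha_Y", "(Intercept)"), c("bX", "x"),
                    c("b_C", "cc"))) {
    post <- s[s$parameter == pair[1], ]
    expect_lt(abs(post$mean - coef(ml)[pair[2]]), 3 * post$sd)
  }
  # pointwise log-likelihood equals the logistic log-likelihood matrix
  ll <- pointwise_loglik(dr, d)
  dm <- as_draws_matrix(dr)
  i <- c(1, 7)
  for (dd in c(1, 500)) {
    eta <- cbind(1, x[i], cc[i]) %*% dm[dd, c("alpha_Y", "bX", "b_C")]
    expect_equal(ll[dd, i],
                 as.vector(y[i] * eta - log(1 + exp(eta))),
                 tolerance = 1e-10)
  }
})

test_that("fitting is deterministic and weight-scale invariant", {
  sch <- toy_schema()
  d1 <- toy_dataset(120, seed = 10, weights = rep(2, 120))
  d2 <- toy_dataset(120, seed = 10, weights = rep(1, 120))
  model <- build_model(model_spec(sch))
  mc <- mcmc_config(chains = 2, iter = 400, warmup = 200, seed = 5)
  dr1 <- fit(model, d1, mc)
  dr2 <- fit(model, d1, mc)
  expect_identical(dr1$draws, dr2$draws)
  # all-equal weights normalize to exactly 1: same draws as unit weights
  dr3 <- fit(model, d2, mc)
  expect_identical(dr1$draws, dr3$draws)
})

test_that("ordinal threshold draws are increasing in every retained draw", {
  cfg <- synthetic_config("refined", n = 800)
  gen <- generate_dataset(cfg, 14)
  dr <- fit(build_model(refined_spec()), gen$data,
            mcmc_config(chains = 2, iter = 500, warmup = 250, seed = 3))
  dm <- as_draws_matrix(dr)
  for (m in c("health_status", "adl", "chronic_disease")) {
    th <- dm[, grep(paste0("^alpha_", m, "\\["), colnames(dm)),
             drop = FALSE]
    expect_true(all(apply(th, 1, function(r) all(diff(r) > 0))))
  }
})

test_that("prior-only sampling reproduces the prior's quartiles", {
  sch <- toy_schema()
  d <- bgsem_dataset(toy_dataset(5)$records[0, ], numeric(0), sch)
  model <- build_model(model_spec(sch))
  dr <- fit(model, d, mcmc_config(chains = 2, iter = 5100, warmup = 100,
                                  seed = 4))
  g <- as_draws_matrix(dr)[, "gamma_Mb"]
  expect_length(g, 10000)
  # Cauchy(0, 2.5): median 0, quartiles at +/- 2.5, IQR 5
  expect_lt(abs(median(g)), 0.15)
  expect_equal(unname(diff(quantile(g, c(0.25, 0.75)))), 5,
               tolerance = 0.15)
})

test_that("pointwise log-likelihood is invariant to pre-normalization
           weight rescaling", {
  sch <- toy_schema()
  set.seed(410)
  w <- rlnorm(80, 0, 0.4)
  d1 <- toy_dataset(80, seed = 15, weights = w)
  d2 <- toy_dataset(80, seed = 15, weights = 2 * w)
  model <- build_model(model_spec(sch))
  mc <- mcmc_config(chains = 2, iter = 300, warmup = 150, seed = 6)
  dr <- fit(model, d1, mc)
  expect_equal(pointwise_loglik(dr, d1), pointwise_loglik(dr, d2),
               tolerance = 1e-12)
})

test_that("fit refuses incomplete data and bad configurations", {
  d <- toy_dataset(30)
  d$records$Mb[2] <- NA
  expect_error(fit(build_model(model_spec(toy_schema())), d,
                   mcmc_config(chains = 2, iter = 200, warmup = 100)),
               "missing values")
  expect_error(mcmc_config(chains = 0), "chains")
  expect_error(mcmc_config(iter = 100, warmup = 100), "warmup")
})
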