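test_that("cumulative-logit probabilities match the logistic-CDF oracle", {
  # sigma(x) = 1/(1+exp(-x)); category masses from adjacent CDF differences
  p <- cumulative_logit_probs(0, c(-1, 1))
  sig <- function(x) 1 / (1 + exp(-x))
  expect_equal(round(p, 4), c(0.2689, 0.4621, 0.2689))
  expect_equal(p, c(sig(-1), sig(1) - sig(-1), 1 - sig(1)),
               tolerance = 1e-12)
  expect_error(cumulative_logit_probs(0, c(1, 1)), "increasing")
})

test_that("cumulative-logit probabilities sum to one and respect limits", {
  set.seed(403)
  for (r in 1:50) {
    K <- sample(3:6, 1)
    th <- sort(rnorm(K - 1, 0, 2))
    if (any(diff(th) == 0)) next
    eta <- rnorm(1, 0, 3)
    p <- cumulative_logit_probs(eta, th)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
  }
  # mass concentrates on the top category as eta grows
  expect_gt(cumulative_logit_probs(30, c(-1, 1))[3], 1 - 1e-10)
  # symmetric thresholds at eta = 0 give a symmetric vector
  p <- cumulative_logit_probs(0, c(-2, -0.5, 0.5, 2))
  expect_equal(p, rev(p), tolerance = 1e-12)
})

test_that("binary generation is the two-category cumulative-logit case", {
  # Bernoulli-logit P(M=1) = sigma(a + g x) equals the top category of a
  # 2-category cumulative logit with threshold -a and slope g
  for (x in 0:1) for (a in c(-1.2, 0.3)) for (g in c(-0.5, 0.9)) {
    expect_equal(plogis(a + g * x),
                 cumulative_logit_probs(g * x, -a)[2], tolerance = 1e-12)
  }
})

test_that("generation is reproducible and matches configured prevalences", {
  cfg <- synthetic_config("refined", n = 50000)
  g1 <- generate_dataset(cfg, 99)
  g2 <- generate_dataset(cfg, 99)
  expect_identical(g1$data$records, g2$data$records)
  expect_identical(g1$data$weight, g2$data$weight)
  g3 <- generate_dataset(cfg, 100)
  expect_false(identical(g1$data$records, g3$data$records))

  rec <- g1$data$records
  expect_equal(mean(rec$depressive_symptoms), 0.3824, tolerance = 0.01)
  expect_equal(mean(rec$inpatient), 0.1922, tolerance = 0.015)
  expect_equal(mean(rec$health_status == 0), 0.2879, tolerance = 0.015)
  expect_equal(mean(g1$data$weight), 1, tolerance = 1e-12)
})

test_that("large-sample ML estimates recover the generative slopes", {
  cfg <- synthetic_config("refined", n = 100000)
  gen <- generate_dataset(cfg, 5)
  rec <- gen$data$records
  truth <- setNames(gen$truth$value, gen$truth$term)
  # one binary mediator by the IRLS oracle
  g <- glm(alcohol_use ~ depressive_symptoms, binomial, rec)
  se <- summary(g)$coefficients["depressive_symptoms", 2]
  expect_lt(abs(coef(g)["depressive_symptoms"] -
                  truth["gamma_alcohol_use"]), 2 * se)
  # outcome equation slopes within 3 SE
  g2 <- glm(inpatient ~ depressive_symptoms + alcohol_use + disability +
              health_status + satisfaction_health + adl + chronic_disease +
              health_insurance + physical_examination + work_status + age +
              gender, binomial, rec)
  cf <- summary(g2)$coefficients
  for (pair in list(c("depressive_symptoms", "bX"),
                    c("health_status", "b_health_status"),
                    c("chronic_disease", "b_chronic_disease"),
                    c("health_insurance", "b_health_insurance"))) {
    expect_lt(abs(cf[pair[1], 1] - truth[pair[2]]), 3 * cf[pair[1], 2])
  }
})

test_that("MAR injection hits the configured marginal rate", {
  cfg <- synthetic_config("refined", n = 20000)
  gen <- generate_dataset(cfg, 12)
  # rate zero leaves the data untouched
  inj0 <- inject_missingness(gen$data,
                             list(list(target = "adl", rate = 0,
                                       driver = "age", b = 0.5)), 3)
  expect_identical(inj0$data$records, gen$data$records)
  # 10% holes land within binomial tolerance at n = 20,000
  inj <- inject_missingness(gen$data,
                            list(list(target = "adl", rate = 0.10,
                                      driver = "age", b = 0.6)), 3)
  frac <- mean(is.na(inj$data$records$adl))
  expect_gte(frac, 0.09)
  expect_lte(frac, 0.11)
  # missingness depends on the driver (MAR, not MCAR)
  rate_by_age <- tapply(is.na(inj$data$records$adl),
                        gen$data$records$age, mean)
  expect_gt(rate_by_age[["2"]], rate_by_age[["0"]])
  # ground truth is the untouched input
  expect_identical(inj$ground_truth$records, gen$data$records)
  # exposure/outcome are protected targets
  expect_error(inject_missingness(gen$data,
                                  list(list(target = "inpatient",
                                            rate = 0.1, driver = "age",
                                            b = 0)), 3),
               "excluded, not imputed")
})

test_that("generative truths carry fit-compatible parameter names", {
  cfg <- synthetic_config("refined", n = 10)
  tt <- true_param_table(cfg)
  expect_true(all(c("bX", "alpha_Y", "gamma_health_status",
                    "b_chronic_disease", "alpha_adl[3]") %in% tt$term))
  # calibrated thresholds are strictly increasing
  th <- tt$value[grep("^alpha_adl\\[", tt$term)]
  expect_true(all(diff(th) > 0))
})
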