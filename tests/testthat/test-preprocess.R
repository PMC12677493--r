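test_that("Little's test degrees of freedom follow the pattern formula", {
  # 3 variables; patterns: complete (p_j = 3) and missing-one (p_j = 2)
  # df = (3 + 2) - 3 = 2
  set.seed(404)
  d <- data.frame(a = rnorm(300), b = rnorm(300), c = rnorm(300))
  d$c[1:60] <- NA
  res <- littles_mcar_test(d)
  expect_equal(res$df, 2L)
  expect_equal(res$n_patterns, 2L)
  expect_gte(res$p, 0)
  expect_lte(res$p, 1)
  # add a third pattern missing two variables: df = (3+2+1) - 3 = 3
  d2 <- d
  d2$a[61:100] <- NA
  d2$b[61:100] <- NA
  expect_equal(littles_mcar_test(d2)$df, 3L)
})

test_that("Little's test degenerates gracefully on complete data", {
  d <- data.frame(a = rnorm(50), b = rnorm(50))
  res <- littles_mcar_test(d)
  expect_true(res$complete)
  expect_equal(res$statistic, 0)
  expect_equal(res$df, 0L)
  expect_equal(res$p, 1)
})

test_that("Little's statistic is invariant to reordering and affine
           recoding", {
  set.seed(405)
  n <- 600
  d <- data.frame(a = rbinom(n, 1, 0.4), b = sample(0:2, n, TRUE),
                  c = rbinom(n, 1, 0.6), e = sample(0:3, n, TRUE))
  d$b[sample(n, 80)] <- NA
  d$e[sample(n, 50)] <- NA
  base <- littles_mcar_test(d)$statistic
  perm <- littles_mcar_test(d[, c("e", "c", "a", "b")])$statistic
  expect_equal(perm, base, tolerance = 1e-6)
  aff <- d
  aff$b <- 5 * aff$b - 2
  aff$a <- -3 * aff$a + 7
  expect_equal(littles_mcar_test(aff)$statistic, base, tolerance = 1e-4)
})

test_that("missingness report tallies counts and patterns consistently", {
  d <- toy_dataset(80)
  d$records$Mo[1:8] <- NA
  d$records$Mb[5:10] <- NA
  rep <- missingness_report(d)
  expect_equal(sum(rep$patterns$n), 80)
  expect_equal(rep$variables$n_missing[rep$variables$variable == "Mo"], 8)
  expect_false(rep$complete)
})

test_that("chained imputation preserves observed cells and the contract", {
  cfg <- synthetic_config("refined", n = 1500,
                          missing = default_missing_config(0.08))
  gen <- generate_dataset(cfg, 21)
  inj <- inject_missingness(gen$data, cfg$missing, 21)
  imp <- mice_impute(inj$data, m = 5, maxit = 3, seed = 8)
  expect_length(imp$completed, 5)
  mask <- missing_mask(inj$data)
  for (k in 1:5) {
    rec <- imp$completed[[k]]$records
    expect_false(anyNA(rec))
    # observed cells bitwise identical to the input
    expect_identical(as.matrix(rec)[!mask],
                     as.matrix(inj$data$records)[!mask])
  }
  # deterministic given the seed, and copies differ from each other
  imp2 <- mice_impute(inj$data, m = 5, maxit = 3, seed = 8)
  expect_identical(imp$completed[[2]]$records, imp2$completed[[2]]$records)
  expect_false(identical(imp$completed[[1]]$records,
                         imp$completed[[2]]$records))
})

test_that("imputation handles the degenerate and pathological cases", {
  d <- toy_dataset(50)
  imp <- mice_impute(d, m = 3, maxit = 2, seed = 1)
  expect_length(imp$completed, 3)
  expect_identical(imp$completed[[1]]$records, d$records)
  expect_identical(imp$completed[[3]]$records, d$records)
  expect_equal(nrow(imputation_diagnostics(imp, d)), 0)
  d$records$Mb[1:48] <- NA
  expect_error(mice_impute(d, m = 2, maxit = 1, seed = 1), ">95%")
})

test_that("observed-vs-imputed comparison table is well formed", {
  cfg <- synthetic_config("refined", n = 2000,
                          missing = list(list(target = "health_status",
                                              rate = 0.1, driver = "age",
                                              b = 0)))
  gen <- generate_dataset(cfg, 31)
  inj <- inject_missingness(gen$data, cfg$missing, 31)
  imp <- mice_impute(inj$data, m = 3, maxit = 3, seed = 2)
  tab <- imputation_diagnostics(imp, inj$data)
  expect_setequal(unique(tab$variable), "health_status")
  expect_equal(sum(tab$freq_observed), 1, tolerance = 1e-12)
  expect_equal(sum(tab$freq_imputed), 1, tolerance = 1e-12)
  expect_true(all(tab$abs_difference >= 0 & tab$abs_difference <= 1))
  expect_error(imputation_diagnostics(imp, toy_dataset(10)),
               "schema mismatch")
})

test_that("aGVIF is near one for independent predictors and flags exact
           collinearity", {
  set.seed(406)
  n <- 5000
  X <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.3),
             c = rbinom(n, 1, 0.7))
  res <- agvif(X)
  expect_true(all(abs(res$agvif - 1) < 0.05))
  Xdup <- cbind(X, a2 = X[, "a"])
  expect_error(agvif(Xdup), "rank deficient")
})

test_that("a 1-df term's aGVIF equals sqrt(VIF) from the
           regress-on-rest oracle", {
  set.seed(407)
  n <- 800
  z <- rnorm(n)
  X <- cbind(a = z + rnorm(n), b = z + rnorm(n), c = rnorm(n))
  res <- agvif(X)
  # classical VIF oracle: 1 / (1 - R^2) regressing each column on the rest
  for (j in colnames(X)) {
    fit <- lm(X[, j] ~ X[, setdiff(colnames(X), j)])
    vif_j <- 1 / (1 - summary(fit)$r.squared)
    expect_equal(res$agvif[res$term == j], sqrt(vif_j), tolerance = 1e-8)
  }
  # cross-check against car::vif on the same design
  df <- as.data.frame(X)
  df$y <- rnorm(n)
  vifs <- car::vif(lm(y ~ a + b + c, df))
  expect_equal(res$gvif, unname(vifs[res$term]), tolerance = 1e-8)
})

test_that("aGVIF is invariant to the reference-category choice", {
  set.seed(408)
  n <- 2000
  f <- sample(0:2, n, TRUE, prob = c(0.5, 0.3, 0.2))
  other <- rbinom(n, 1, plogis(0.5 * (f == 2)))
  ref0 <- cbind(f1 = as.numeric(f == 1), f2 = as.numeric(f == 2),
                other = other)
  ref2 <- cbind(f0 = as.numeric(f == 0), f1 = as.numeric(f == 1),
                other = other)
  a0 <- agvif(ref0, groups = list(f = c("f1", "f2"), other = "other"))
  a2 <- agvif(ref2, groups = list(f = c("f0", "f1"), other = "other"))
  expect_equal(a0$agvif, a2$agvif, tolerance = 1e-10)
})
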