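test_that("HDI matches order-statistics oracles", {
  set.seed(412)
  u <- runif(100000)
  h <- hdi(u, 0.95)
  expect_equal(h[2] - h[1], 0.95, tolerance = 0.011)
  z <- rnorm(100000)
  hz <- hdi(z, 0.95)
  # symmetric density: HDI coincides with the central interval
  expect_equal(hz[1], -1.96, tolerance = 0.03)
  expect_equal(hz[2], 1.96, tolerance = 0.03)
  expect_equal(hdi(rep(3.5, 10)), c(3.5, 3.5))
  expect_error(hdi(1), "at least 2")
  expect_error(hdi(c(1, 2), mass = 1.2), "mass")
})

test_that("HDI is never longer than the equal-tail interval", {
  set.seed(413)
  for (r in 1:20) {
    x <- rlnorm(5000, 0, sample(c(0.3, 1, 2), 1))
    h <- hdi(x, 0.9)
    q <- quantile(x, c(0.05, 0.95))
    expect_lte(h[2] - h[1], unname(q[2] - q[1]) + 1e-12)
  }
})

test_that("degenerate draws reproduce the printed product arithmetic", {
  sch <- k_mediator_schema(1)
  spec <- model_spec(sch, mediators = "M1", controls = character(0))
  dm <- cbind(bX = rep(0.16, 200), gamma_M1 = -1.33, b_M1 = -0.68)
  dec <- decompose(dm, spec)
  expect_equal(mean(dec$draws$indirect[, "M1"]), 0.9044, tolerance = 1e-12)
  tab <- summarize_paths(dec)
  expect_equal(tab$value[tab$variable == "M1"], "0.90(0.90, 0.90)")
})

test_that("decomposition matches a brute-force per-draw loop", {
  sch <- k_mediator_schema(5)
  meds <- paste0("M", 1:5)
  spec <- model_spec(sch, mediators = meds, controls = character(0))
  set.seed(414)
  D <- 400
  dm <- cbind(bX = rnorm(D, 0.2, 0.1),
              matrix(rnorm(D * 5, 0, 0.5), D,
                     dimnames = list(NULL, paste0("gamma_", meds))),
              matrix(rnorm(D * 5, 0, 0.5), D,
                     dimnames = list(NULL, paste0("b_", meds))))
  dec <- decompose(dm, spec)
  # independent loop oracle
  ind <- matrix(NA_real_, D, 5)
  tot <- numeric(D)
  for (d in seq_len(D)) {
    for (k in 1:5)
      ind[d, k] <- dm[d, paste0("gamma_M", k)] * dm[d, paste0("b_M", k)]
    tot[d] <- dm[d, "bX"] + sum(ind[d, ])
  }
  expect_equal(unname(dec$draws$indirect), ind, tolerance = 1e-12)
  expect_equal(dec$draws$total, tot, tolerance = 1e-12)
  expect_equal(mean(dec$draws$total_indirect),
               sum(colMeans(dec$draws$indirect)), tolerance = 1e-12)
  # additivity holds exactly per draw
  expect_lt(max(abs(dec$draws$total - dec$draws$direct -
                      rowSums(dec$draws$indirect))), 1e-12)
})

test_that("decomposition is invariant to mediator ordering and collapses
           when mediator paths vanish", {
  sch <- k_mediator_schema(3)
  meds <- paste0("M", 1:3)
  set.seed(415)
  D <- 300
  dm <- cbind(bX = rnorm(D),
              matrix(rnorm(D * 6), D,
                     dimnames = list(NULL, c(paste0("gamma_", meds),
                                             paste0("b_", meds)))))
  d1 <- decompose(dm, model_spec(sch, mediators = meds,
                                 controls = character(0)))
  d2 <- decompose(dm, model_spec(sch, mediators = rev(meds),
                                 controls = character(0)))
  expect_equal(d1$draws$total, d2$draws$total, tolerance = 1e-12)
  expect_equal(d1$summary[d1$summary$variable == "M2", ],
               d2$summary[d2$summary$variable == "M2", ],
               tolerance = 1e-12, ignore_attr = TRUE)
  # all-zero mediator draws: total equals direct exactly
  dm0 <- dm
  dm0[, paste0("b_", meds)] <- 0
  d0 <- decompose(dm0, model_spec(sch, mediators = meds,
                                  controls = character(0)))
  expect_identical(d0$draws$total, d0$draws$direct)
  expect_error(decompose(dm[, 1:3], model_spec(sch, mediators = meds,
                                               controls = character(0))),
               "missing parameter")
})

test_that("proportion mediated reproduces the published arithmetic", {
  expect_equal(round_half_up(proportion_mediated(2.32, 0.16)), 93.55)
  expect_equal(round_half_up(proportion_mediated(2.43, 0.17)), 93.46)
  expect_equal(proportion_mediated(0, 0.5), 0)
  expect_error(proportion_mediated(0.3, -0.3), "zero")
  # inconsistent mediation is reported unclamped
  expect_lt(proportion_mediated(-0.5, 1), 0)
  expect_gt(proportion_mediated(2, -0.5), 100)
})

test_that("path reports have the published table shape and rounding", {
  expect_equal(round_half_up(0.9044), 0.90)
  expect_equal(round_half_up(0.565), 0.57)
  expect_equal(round_half_up(-0.565), -0.57)
  expect_equal(round_half_up(0.5644), 0.56)
  sch <- k_mediator_schema(1)
  spec <- model_spec(sch, mediators = "M1", controls = character(0))
  set.seed(416)
  dm <- cbind(bX = rnorm(300, 0.2, 0.05), gamma_M1 = rnorm(300, 1, 0.1),
              b_M1 = rnorm(300, 0.5, 0.1))
  dec <- decompose(dm, spec)
  tab <- summarize_paths(dec)
  expect_true(all(c("M1", "total_indirect", "direct") %in% tab$variable))
  expect_match(tab$x_m[tab$variable == "M1"],
               "^-?\\d+\\.\\d{2}\\(-?\\d+\\.\\d{2}, -?\\d+\\.\\d{2}\\)$")
  edges <- path_edges(dec)
  expect_equal(nrow(edges), 3) # X->M1, M1->Y, X->Y
  expect_true(all(edges$style %in% c("solid", "dashed")))
})
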