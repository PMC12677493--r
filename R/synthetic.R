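# Synthetic Andersen-structured cohorts generated from the structural
# equations themselves: controls from fixed marginals, exposure ~
# Bernoulli(prevalence), each mediator from its Bernoulli-logit or
# cumulative-logit equation given the exposure, the outcome from a
# Bernoulli-logit on exposure + mediators + controls, lognormal survey
# weights normalized to mean 1, and optional MAR missingness.

#' Cumulative-logit category probabilities
#'
#' Latent-shift parameterization: with logistic CDF \eqn{\sigma}, the
#' probability of category \eqn{c} (1-based) is
#' \eqn{\sigma(\alpha_c - \eta) - \sigma(\alpha_{c-1} - \eta)} with
#' \eqn{\alpha_0 = -\infty} and \eqn{\alpha_m = +\infty}. Larger `eta`
#' shifts mass toward higher categories.
#'
#' @param eta linear predictor (scalar or vector).
#' @param thresholds strictly increasing numeric vector of length m-1.
#' @return for scalar `eta` a probability vector of length m; for vector
#'   `eta` a matrix (length(eta) x m). Rows sum to 1.
#' @export
cumulative_logit_probs <- function(eta, thresholds) {
  if (length(thresholds) < 1 || any(diff(thresholds) <= 0) ||
      any(!is.finite(thresholds)))
    stop("thresholds must be finite and strictly increasing", call. = FALSE)
  hi <- c(thresholds, Inf)
  lo <- c(-Inf, thresholds)
  p <- vapply(seq_along(hi), function(c)
    plogis(hi[c] - eta) - plogis(lo[c] - eta), numeric(length(eta)))
  if (length(eta) == 1) as.numeric(p) else p
}

# Table-2-style marginal category probabilities used as generator defaults.
default_marginals <- function() {
  m <- list(
    depressive_symptoms = c(0.6176, 0.3824),
    inpatient = c(0.8078, 0.1922),
    pain = c(0.6150, 0.3850),
    smoking = c(0.7193, 0.2807),
    alcohol_use = c(0.7196, 0.2804),
    disability = c(0.5721, 0.4279),
    health_status = c(0.2879, 0.4954, 0.2167),
    satisfaction_health = c(0.2654, 0.4696, 0.2650),
    adl = c(0.6099, 0.0939, 0.1163, 0.1799),
    chronic_disease = c(0.1407, 0.2169, 0.6424),
    gender = c(0.4835, 0.5165),
    age = c(0.6482, 0.2915, 0.0603),
    marital_status = c(0.1799, 0.8201),
    ethnicity = c(0.0674, 0.9326),
    residence = c(0.2678, 0.7322),
    religious_belief = c(0.8957, 0.1043),
    work_status = c(0.4436, 0.5564),
    education = c(0.2567, 0.4644, 0.2366, 0.0423),
    pension = c(0.0825, 0.9174),
    satisfaction_healthcare = c(0.1679, 0.4195, 0.4125),
    physical_examination = c(0.4310, 0.5690),
    health_insurance = c(0.0251, 0.9749)
  )
  lapply(m, function(p) p / sum(p))
}

# Path coefficients of the two model specifications (posterior means of the
# refined and comprehensive fits), used as generative truths.
study_path_means <- function(model = c("refined", "comprehensive")) {
  model <- match.arg(model)
  if (model == "refined") {
    list(
      direct = 0.16,
      mediators = list(
        alcohol_use = list(gamma = -0.48, beta = -0.41),
        disability = list(gamma = 0.70, beta = 0.13),
        health_status = list(gamma = -1.33, beta = -0.67),
        satisfaction_health = list(gamma = -1.33, beta = -0.28),
        adl = list(gamma = 0.99, beta = 0.19),
        chronic_disease = list(gamma = 0.80, beta = 0.74)
      ),
      controls = c(health_insurance = 1.28, physical_examination = 0.34,
                   work_status = -0.36, age = 0.37, gender = 0.28)
    )
  } else {
    list(
      direct = 0.17,
      mediators = list(
        pain = list(gamma = -1.18, beta = -0.07),
        alcohol_use = list(gamma = -0.47, beta = -0.37),
        disability = list(gamma = 0.70, beta = 0.14),
        smoking = list(gamma = -0.08, beta = -0.45),
        health_status = list(gamma = -1.33, beta = -0.68),
        satisfaction_health = list(gamma = -1.33, beta = -0.27),
        adl = list(gamma = 0.99, beta = 0.22),
        chronic_disease = list(gamma = 0.80, beta = 0.71)
      ),
      controls = c(health_insurance = 1.22, physical_examination = 0.32,
                   marital_status = -0.04, work_status = -0.30,
                   residence = -0.14, satisfaction_healthcare = 0.02,
                   age = 0.35, gender = 0.45, ethnicity = 0.02,
                   pension = 0.10, education = -0.10,
                   religious_belief = -0.12)
    )
  }
}

# Calibrate a binary mediator's intercept so the marginal prevalence matches
# the target given exposure prevalence px: (1-px) s(a) + px s(a + g) = p.
calibrate_binary_intercept <- function(target, gamma, px) {
  f <- function(a) (1 - px) * plogis(a) + px * plogis(a + gamma) - target
  uniroot(f, c(-30, 30), tol = 1e-12)$root
}

# Calibrate ordinal thresholds so marginal cumulative probabilities match:
# (1-px) s(a_c) + px s(a_c - g) = cum_p_c for each c.
calibrate_thresholds <- function(marginal, gamma, px) {
  cum <- cumsum(marginal)[-length(marginal)]
  vapply(cum, function(p) {
    f <- function(a) (1 - px) * plogis(a) + px * plogis(a - gamma) - p
    uniroot(f, c(-30, 30), tol = 1e-12)$root
  }, numeric(1))
}

#' Default MAR missingness configuration
#'
#' Three need-factor mediators lose cells at modest rates, driven by the
#' age category (older subjects more likely to have holes), giving a
#' missing-at-random but not completely-at-random pattern.
#'
#' @param rate marginal missingness rate per target variable.
#' @return list of per-target configs (`target`, `rate`, `driver`, `b`).
#' @export
default_missing_config <- function(rate = 0.05) {
  lapply(c("health_status", "chronic_disease", "satisfaction_health"),
         function(v) list(target = v, rate = rate, driver = "age", b = 0.4))
}

#' Build a synthetic-cohort configuration
#'
#' Defaults emulate the study conditions: exposure prevalence 38.24%,
#' control marginals matching the participant-characteristics table, path
#' coefficients equal to the printed posterior means of the chosen model
#' specification, mediator intercepts/thresholds and the outcome intercept
#' calibrated so marginal prevalences match the same table (outcome
#' prevalence 19.22%), lognormal(0, 0.5) survey weights normalized to mean
#' 1, and age-driven MAR missingness on three need mediators.
#'
#' @param model `"refined"` (6 mediators, 5 controls) or `"comprehensive"`
#'   (8 mediators, 12 controls).
#' @param n subject count.
#' @param exposure_prevalence probability of the exposure.
#' @param path_means generative truths: list with `direct`, `mediators`
#'   (per-mediator `gamma`, `beta`) and `controls` (named coefficient
#'   vector); defaults to the printed posterior means of `model`.
#' @param marginals named list of per-variable category probabilities.
#' @param weight_model list(`dist` = "lognormal", `meanlog`, `sdlog`).
#' @param missing list of MAR configs as in [default_missing_config()], or
#'   `NULL` for complete data.
#' @param calib_n Monte Carlo size used once to calibrate the outcome
#'   intercept (fixed internal stream; not affected by generation seeds).
#' @return object of class `bgsem_synth_config` with calibrated
#'   `true_params`.
#' @export
synthetic_config <- function(model = c("refined", "comprehensive"),
                             n = 7777,
                             exposure_prevalence = 0.3824,
                             path_means = NULL,
                             marginals = default_marginals(),
                             weight_model = list(dist = "lognormal",
                                                 meanlog = 0, sdlog = 0.5),
                             missing = default_missing_config(),
                             calib_n = 200000) {
  model <- match.arg(model)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  px <- exposure_prevalence
  if (!(px > 0 && px < 1))
    stop("exposure_prevalence must be in (0,1)", call. = FALSE)
  pm <- path_means %||% study_path_means(model)
  sch <- charls_schema()
  for (p in marginals) {
    if (any(p <= 0) || abs(sum(p) - 1) > 1e-8)
      stop("marginal probabilities must be positive and sum to 1",
           call. = FALSE)
  }
  meds <- names(pm$mediators)
  ctrls <- names(pm$controls)
  stopifnot(all(meds %in% mediator_names(sch)),
            all(ctrls %in% control_names(sch)))
  # calibrate mediator intercepts / thresholds against marginals
  true_params <- list(direct = pm$direct, mediators = list(),
                      controls = pm$controls)
  for (m in meds) {
    g <- pm$mediators[[m]]$gamma
    b <- pm$mediators[[m]]$beta
    if (sch[[m]]$family == "binary") {
      a <- calibrate_binary_intercept(marginals[[m]][2], g, px)
      true_params$mediators[[m]] <-
        list(family = "binary", gamma = g, beta = b, alpha = a)
    } else {
      th <- calibrate_thresholds(marginals[[m]], g, px)
      true_params$mediators[[m]] <-
        list(family = "ordinal", gamma = g, beta = b, thresholds = th)
    }
  }
  cfg <- structure(
    list(model = model, n = as.integer(n), exposure_prevalence = px,
         true_params = true_params, marginals = marginals,
         weight_model = weight_model, missing = missing,
         schema = sch),
    class = "bgsem_synth_config")
  # outcome intercept: match the marginal outcome prevalence by Monte Carlo
  # over the structural system (fixed internal calibration stream)
  target_y <- marginals$inpatient[2]
  lin <- draw_structural(cfg, calib_n, seed = 171717L)$linpred
  cfg$true_params$alpha_Y <-
    uniroot(function(a) mean(plogis(a + lin)) - target_y,
            c(-30, 30), tol = 1e-10)$root
  cfg
}

#' @export
print.bgsem_synth_config <- function(x, ...) {
  cat("<bgsem_synth_config> model=", x$model, " n=", x$n,
      " exposure_prev=", x$exposure_prevalence, "\n", sep = "")
  invisible(x)
}

# Draw exposure, mediators and controls (no outcome) plus the outcome
# linear predictor without intercept. Each random source gets its own
# substream so adding a variable never perturbs earlier ones.
draw_structural <- function(cfg, n, seed) {
  tp <- cfg$true_params
  meds <- names(tp$mediators)
  ctrls <- names(tp$controls)
  seeds <- derive_seeds(seed, 2L + length(meds) + length(ctrls))
  si <- 0L
  nxt <- function() { si <<- si + 1L; seeds[si] }
  X <- with_seed(nxt(), rbinom(n, 1L, cfg$exposure_prevalence))
  lin <- tp$direct * X
  M <- list()
  for (m in meds) {
    p <- tp$mediators[[m]]
    M[[m]] <- with_seed(nxt(), {
      if (p$family == "binary") {
        rbinom(n, 1L, plogis(p$alpha + p$gamma * X))
      } else {
        # cumulative-logit latent shift: P(M <= c | X) = s(alpha_c - g X)
        cum <- vapply(p$thresholds, function(a) plogis(a - p$gamma * X),
                      numeric(n))
        u <- runif(n)
        as.integer(rowSums(u > cum))
      }
    })
    lin <- lin + p$beta * M[[m]]
  }
  C <- list()
  for (cv in ctrls) {
    pr <- cfg$marginals[[cv]]
    C[[cv]] <- with_seed(nxt(),
      as.integer(sample.int(length(pr), n, replace = TRUE, prob = pr) - 1L))
    lin <- lin + tp$controls[[cv]] * C[[cv]]
  }
  list(X = as.integer(X), M = M, C = C, linpred = lin)
}

#' Generate a synthetic cohort
#'
#' Draws a complete dataset from the configured structural equations. Fully
#' reproducible: the same `(config, seed)` yields byte-identical output.
#' Variables outside the configured specification (e.g. pain/smoking under
#' the refined model) are still generated — independently from their
#' marginals — so the full schema is always populated.
#'
#' @param config a `bgsem_synth_config`.
#' @param seed integer seed.
#' @return list with `data` (complete `bgsem_dataset`), `truth`
#'   (data.frame of term/value generative parameters) and `config`.
#' @export
generate_dataset <- function(config, seed) {
  stopifnot(inherits(config, "bgsem_synth_config"))
  n <- config$n
  sch <- config$schema
  seeds <- derive_seeds(seed, 4L, salt = 1L)
  s <- draw_structural(config, n, seed = seeds[1])
  Y <- with_seed(seeds[2],
    rbinom(n, 1L, plogis(config$true_params$alpha_Y + s$linpred)))
  w <- with_seed(seeds[3], rlnorm(n, config$weight_model$meanlog,
                                  config$weight_model$sdlog))
  # fill schema variables outside the model spec from their marginals
  rec <- data.frame(row.names = seq_len(n))
  extra_vars <- setdiff(names(sch), c(exposure_name(sch), outcome_name(sch),
                                      names(s$M), names(s$C)))
  extra <- with_seed(seeds[4], lapply(extra_vars, function(v) {
    pr <- config$marginals[[v]]
    as.integer(sample.int(length(pr), n, replace = TRUE, prob = pr) - 1L)
  }))
  names(extra) <- extra_vars
  cols <- c(setNames(list(s$X), exposure_name(sch)),
            setNames(list(Y), outcome_name(sch)), s$M, s$C, extra)
  for (v in names(sch)) rec[[v]] <- cols[[v]]
  data <- bgsem_dataset(rec, w, sch)
  list(data = data, truth = true_param_table(config), config = config)
}

#' Generative truths as a term/value table
#'
#' Terms are named exactly as the fitted parameters (`bX`, `b_<mediator>`,
#' `b_<control>`, `gamma_<mediator>`, `alpha_<...>`), so recovery checks
#' can join truth to posterior summaries by name.
#'
#' @param config a `bgsem_synth_config`.
#' @return data.frame with columns `term`, `value`.
#' @export
true_param_table <- function(config) {
  tp <- config$true_params
  terms <- c(alpha_Y = tp$alpha_Y, bX = tp$direct)
  for (m in names(tp$mediators)) {
    p <- tp$mediators[[m]]
    terms[paste0("b_", m)] <- p$beta
    terms[paste0("gamma_", m)] <- p$gamma
    if (p$family == "binary") {
      terms[paste0("alpha_", m)] <- p$alpha
    } else {
      terms[paste0("alpha_", m, "[", seq_along(p$thresholds), "]")] <-
        p$thresholds
    }
  }
  for (cv in names(tp$controls))
    terms[paste0("b_", cv)] <- tp$controls[[cv]]
  data.frame(term = names(terms), value = unname(terms),
             stringsAsFactors = FALSE)
}

#' Inject missing-at-random holes
#'
#' Each target cell is set missing with probability
#' \eqn{\sigma(a + b \cdot driver)}, with `a` calibrated by root finding on
#' the realized driver codes so the marginal missing rate equals the
#' configured rate in expectation. Drivers must be fully observed; the
#' exposure and outcome may not be targets (the study excluded such rows
#' rather than imputing them) unless `allow_key` is set.
#'
#' @param data complete `bgsem_dataset`.
#' @param config list of per-target configs (`target`, `rate`, `driver`,
#'   `b`), e.g. [default_missing_config()].
#' @param seed integer seed.
#' @param allow_key permit holes in exposure/outcome (default `FALSE`).
#' @return list with `data` (holes injected) and `ground_truth` (the
#'   untouched input).
#' @export
inject_missingness <- function(data, config, seed, allow_key = FALSE) {
  stopifnot(inherits(data, "bgsem_dataset"))
  sch <- data$schema
  out <- data
  if (length(config) == 0) return(list(data = out, ground_truth = data))
  seeds <- derive_seeds(seed, length(config), salt = 2L)
  for (i in seq_along(config)) {
    mc <- config[[i]]
    v <- mc$target
    if (!v %in% names(sch)) stop("unknown target '", v, "'", call. = FALSE)
    if (!allow_key && v %in% c(exposure_name(sch), outcome_name(sch)))
      stop("missingness target '", v, "' is the exposure/outcome; such ",
           "rows are excluded, not imputed", call. = FALSE)
    if (mc$rate < 0 || mc$rate >= 1)
      stop("missing rate must be in [0,1)", call. = FALSE)
    if (mc$rate == 0) next
    d <- data$records[[mc$driver]]
    if (anyNA(d))
      stop("driver '", mc$driver, "' must be fully observed", call. = FALSE)
    b <- mc$b %||% 0
    a <- uniroot(function(a) mean(plogis(a + b * d)) - mc$rate,
                 c(-40, 40), tol = 1e-12)$root
    hole <- with_seed(seeds[i],
                      runif(length(d)) < plogis(a + b * d))
    out$records[[v]][hole] <- NA_integer_
  }
  list(data = out, ground_truth = data)
}
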