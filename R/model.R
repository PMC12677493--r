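# Structural system: one Bernoulli-logit outcome equation plus one
# sub-model per mediator (Bernoulli-logit for binary mediators,
# cumulative-logit with ordered thresholds for ordinal ones). Mediator
# equations contain only the exposure. The joint posterior factorizes over
# sub-models because no parameter is shared.

#' Specify the structural mediation system
#'
#' @param sch a `bgsem_schema`.
#' @param mediators character vector of mediator names (must have role
#'   `"mediator"` in the schema); each gets its own sub-model and a
#'   coefficient in the outcome equation.
#' @param controls character vector of control names entering the outcome
#'   equation.
#' @param control_coding `"score"` (one coefficient per control, linear
#'   0-based integer scores — the coding that yields a single printed
#'   coefficient per multi-level control) or `"dummy"` (full dummy
#'   expansion, first level reference). Ordinal mediators always enter the
#'   outcome equation as linear integer scores.
#' @return object of class `bgsem_model_spec`.
#' @export
model_spec <- function(sch, mediators = mediator_names(sch),
                       controls = control_names(sch),
                       control_coding = c("score", "dummy")) {
  stopifnot(inherits(sch, "bgsem_schema"))
  control_coding <- match.arg(control_coding)
  unknown <- setdiff(c(mediators, controls), names(sch))
  if (length(unknown))
    stop("unbound variable(s) in model spec: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  bad_m <- mediators[vapply(mediators, function(v) sch[[v]]$role,
                            character(1)) != "mediator"]
  if (length(bad_m))
    stop("not declared as mediator in schema: ",
         paste(bad_m, collapse = ", "), call. = FALSE)
  bad_c <- controls[vapply(controls, function(v) sch[[v]]$role,
                           character(1)) != "control"]
  if (length(bad_c))
    stop("not declared as control in schema: ",
         paste(bad_c, collapse = ", "), call. = FALSE)
  if (length(intersect(mediators, controls)))
    stop("a variable cannot be both mediator and control", call. = FALSE)
  structure(list(schema = sch, exposure = exposure_name(sch),
                 outcome = outcome_name(sch),
                 mediators = mediators, controls = controls,
                 control_coding = control_coding),
            class = "bgsem_model_spec")
}

#' @export
print.bgsem_model_spec <- function(x, ...) {
  cat("<bgsem_model_spec> ", x$exposure, " -> ", x$outcome, "\n",
      "  mediators: ", paste(x$mediators, collapse = ", "), "\n",
      "  controls:  ", paste(x$controls, collapse = ", "),
      " (", x$control_coding, " coding)\n", sep = "")
  invisible(x)
}

#' The two study specifications
#'
#' `comprehensive_spec()` includes all eight mediators and twelve controls;
#' `refined_spec()` keeps the six mediators and five controls retained
#' after posterior screening (alcohol use, disability, health status,
#' satisfaction with health, ADL, chronic disease; health insurance,
#' physical examination, work status, age, gender).
#'
#' @param sch schema, default [charls_schema()].
#' @return a `bgsem_model_spec`.
#' @export
refined_spec <- function(sch = charls_schema()) {
  model_spec(sch,
             mediators = c("alcohol_use", "disability", "health_status",
                           "satisfaction_health", "adl", "chronic_disease"),
             controls = c("health_insurance", "physical_examination",
                          "work_status", "age", "gender"))
}

#' @rdname refined_spec
#' @export
comprehensive_spec <- function(sch = charls_schema()) {
  model_spec(sch)
}

#' Prior configuration
#'
#' Presets: `"default"` places Cauchy(0, 2.5) on all regression
#' coefficients and Student-t(3, 0, 2.5) on intercepts and ordinal
#' thresholds; `"diffuse"` (the sensitivity setting) places flat priors on
#' coefficients (bounded at +/-1000 so the posterior stays proper) and
#' highly diffuse Student-t(1, 0, 1000) on intercepts and thresholds.
#'
#' @param preset `"default"` or `"diffuse"`.
#' @param coefficient,intercept optional overrides: lists with `family`
#'   (`"cauchy"`, `"student_t"`, `"normal"`, `"flat"`), `df`, `location`,
#'   `scale`.
#' @return object of class `bgsem_prior_config`.
#' @export
prior_config <- function(preset = c("default", "diffuse"),
                         coefficient = NULL, intercept = NULL) {
  preset <- match.arg(preset)
  if (preset == "default") {
    coefficient <- coefficient %||%
      list(family = "cauchy", df = NA_real_, location = 0, scale = 2.5)
    intercept <- intercept %||%
      list(family = "student_t", df = 3, location = 0, scale = 2.5)
  } else {
    coefficient <- coefficient %||%
      list(family = "flat", df = NA_real_, location = 0, scale = 1)
    intercept <- intercept %||%
      list(family = "student_t", df = 1, location = 0, scale = 1000)
  }
  for (p in list(coefficient, intercept)) {
    if (!p$family %in% c("cauchy", "student_t", "normal", "flat"))
      stop("unknown prior family '", p$family, "'", call. = FALSE)
    if (p$family != "flat" && (!is.finite(p$scale) || p$scale <= 0))
      stop("prior scale must be > 0", call. = FALSE)
    if (p$family == "student_t" && (!is.finite(p$df) || p$df <= 0))
      stop("student_t prior needs df > 0", call. = FALSE)
  }
  structure(list(preset = preset, coefficient = coefficient,
                 intercept = intercept),
            class = "bgsem_prior_config")
}

prior_code <- function(family) {
  c(cauchy = 0L, student_t = 1L, normal = 2L, flat = 3L)[[family]]
}

# log prior density (unnormalized, matching the sampler's internal form)
prior_logdens <- function(x, p) {
  z <- (x - p$location) / p$scale
  switch(p$family,
         cauchy = -log(1 + z^2),
         student_t = -0.5 * (p$df + 1) * log(1 + z^2 / p$df),
         normal = -0.5 * z^2,
         flat = ifelse(abs(x) > 1000, -Inf, 0))
}

#' MCMC configuration
#'
#' The study-scale default mirrors the original computational settings
#' (4 chains, 10,000 iterations each including 5,000 warmup);
#' `profile = "test"` is the documented desk-scale setting (2 chains,
#' 1,500 iterations including 750 warmup) used throughout the package's
#' simulation studies.
#'
#' @param chains number of chains (>= 1).
#' @param iter total iterations per chain (including warmup).
#' @param warmup warmup iterations per chain (< iter).
#' @param seed integer seed; all chain and sub-model streams derive from
#'   it deterministically.
#' @param target_accept dual-averaging acceptance target.
#' @param max_leapfrog leapfrog steps are drawn uniformly from
#'   1..max_leapfrog each iteration.
#' @param profile shortcut: `"paper"` or `"test"` fills chains/iter/warmup.
#' @return object of class `bgsem_mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, iter = 10000, warmup = 5000, seed = 1,
                        target_accept = 0.9, max_leapfrog = 32,
                        profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("paper", "test"))
    if (profile == "test") { chains <- 2; iter <- 1500; warmup <- 750 }
    else { chains <- 4; iter <- 10000; warmup <- 5000 }
  }
  if (chains < 1) stop("chains must be >= 1", call. = FALSE)
  if (warmup >= iter) stop("warmup must be < iter", call. = FALSE)
  if (!(target_accept > 0 && target_accept < 1))
    stop("target_accept must be in (0,1)", call. = FALSE)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 target_accept = target_accept,
                 max_leapfrog = as.integer(max_leapfrog)),
            class = "bgsem_mcmc_config")
}

#' Assemble a fit-ready model object
#'
#' Binds a structural specification to a prior configuration. The joint
#' log-density is the sum of the sub-models' weighted (pseudo-likelihood)
#' log-likelihoods plus the log-priors; each observation's contribution is
#' multiplied by its normalized survey weight in every sub-model.
#'
#' @param spec a `bgsem_model_spec`.
#' @param priors a `bgsem_prior_config` (default preset).
#' @return object of class `bgsem_model`.
#' @export
build_model <- function(spec, priors = prior_config()) {
  stopifnot(inherits(spec, "bgsem_model_spec"),
            inherits(priors, "bgsem_prior_config"))
  structure(list(spec = spec, priors = priors), class = "bgsem_model")
}

#' @export
print.bgsem_model <- function(x, ...) {
  cat("<bgsem_model> priors=", x$priors$preset, "\n", sep = "")
  print(x$spec)
  invisible(x)
}

# ---- sub-model plumbing ------------------------------------------------

# Describe every sub-model of a spec: family, response, design columns,
# parameter names, prior class per parameter ("intercept" or "coefficient").
submodel_plan <- function(spec) {
  sch <- spec$schema
  plans <- list()
  # outcome equation
  cols <- c("alpha_Y", "bX")
  for (m in spec$mediators) cols <- c(cols, paste0("b_", m))
  if (spec$control_coding == "score") {
    for (cv in spec$controls) cols <- c(cols, paste0("b_", cv))
  } else {
    for (cv in spec$controls) {
      lev <- sch[[cv]]$levels
      cols <- c(cols, paste0("b_", cv, "_", make.names(lev[-1])))
    }
  }
  plans[["Y"]] <- list(name = "Y", family = "binary", ncat = 2L,
                       response = spec$outcome, params = cols,
                       prior_class = c("intercept",
                                       rep("coefficient", length(cols) - 1)))
  for (m in spec$mediators) {
    if (sch[[m]]$family == "binary") {
      plans[[m]] <- list(name = m, family = "binary", ncat = 2L,
                         response = m,
                         params = c(paste0("alpha_", m), paste0("gamma_", m)),
                         prior_class = c("intercept", "coefficient"))
    } else {
      K <- n_levels(sch, m)
      plans[[m]] <- list(name = m, family = "ordinal", ncat = K,
                         response = m,
                         params = c(paste0("alpha_", m, "[", 1:(K - 1), "]"),
                                    paste0("gamma_", m)),
                         prior_class = c(rep("intercept", K - 1),
                                         "coefficient"))
    }
  }
  plans
}

# Design matrix of one sub-model (response excluded). Outcome: intercept +
# exposure + mediator scores + control scores/dummies. Mediators: exposure
# column only (no intercept column for the ordinal family — thresholds act
# as intercepts).
submodel_design <- function(spec, plan, records) {
  sch <- spec$schema
  n <- nrow(records)
  if (plan$name == "Y") {
    cols <- list(alpha_Y = rep(1, n), bX = records[[spec$exposure]])
    for (m in spec$mediators) cols[[paste0("b_", m)]] <- records[[m]]
    if (spec$control_coding == "score") {
      for (cv in spec$controls) cols[[paste0("b_", cv)]] <- records[[cv]]
    } else {
      for (cv in spec$controls) {
        lev <- sch[[cv]]$levels
        for (l in seq_along(lev)[-1])
          cols[[paste0("b_", cv, "_", make.names(lev[l]))]] <-
            as.numeric(records[[cv]] == (l - 1))
      }
    }
    X <- do.call(cbind, cols)
  } else if (plan$family == "binary") {
    X <- cbind(1, records[[spec$exposure]])
  } else {
    X <- cbind(records[[spec$exposure]])
  }
  storage.mode(X) <- "double"
  X
}

# prior vectors for a plan under a prior config
plan_priors <- function(plan, priors) {
  pr <- lapply(plan$prior_class, function(cl)
    if (cl == "intercept") priors$intercept else priors$coefficient)
  list(type = vapply(pr, function(p) prior_code(p$family), integer(1)),
       df = vapply(pr, function(p)
         ifelse(is.na(p$df %||% NA_real_), 1, p$df), numeric(1)),
       loc = vapply(pr, function(p) p$location %||% 0, numeric(1)),
       scale = vapply(pr, function(p) p$scale %||% 1, numeric(1)))
}

#' Joint weighted log-density of the structural system
#'
#' Evaluates the model's joint log-density (sum over sub-models of the
#' weighted log-likelihood, plus unnormalized log-priors) at a named
#' parameter vector. This is the same density the sampler explores (up to
#' the ordered-threshold change of variables) and is exposed for
#' verification against hand computation.
#'
#' @param model a `bgsem_model`.
#' @param data a complete `bgsem_dataset`.
#' @param params named numeric vector covering every model parameter
#'   (naming as in [true_param_table()]).
#' @param include_prior add the log-prior terms (default `TRUE`).
#' @return scalar log-density.
#' @export
model_log_density <- function(model, data, params, include_prior = TRUE) {
  stopifnot(inherits(model, "bgsem_model"), inherits(data, "bgsem_dataset"))
  plans <- submodel_plan(model$spec)
  lp <- 0
  for (plan in plans) {
    miss <- setdiff(plan$params, names(params))
    if (length(miss))
      stop("missing parameter(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    th <- unname(params[plan$params])
    X <- submodel_design(model$spec, plan, data$records)
    y <- as.integer(data$records[[plan$response]])
    if (anyNA(y) || anyNA(X))
      stop("sub-model '", plan$name, "': data contain missing values; ",
           "impute first", call. = FALSE)
    lp <- lp + cpp_submodel_loglik(
      ifelse(plan$family == "binary", 0L, 1L), X, y, data$weight,
      plan$ncat, th)
    if (include_prior) {
      pr <- lapply(plan$prior_class, function(cl)
        if (cl == "intercept") model$priors$intercept
        else model$priors$coefficient)
      lp <- lp + sum(mapply(function(x, p) prior_logdens(x, p), th, pr))
    }
  }
  lp
}
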