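#' Fit the weighted Bayesian generalized SEM by MCMC
#'
#' Samples every sub-model's posterior with Hamiltonian Monte Carlo
#' (jittered-length leapfrog trajectories, dual-averaging step-size
#' adaptation, diagonal metric learned during warmup). Because the joint
#' posterior factorizes across sub-models, sampling them independently is
#' exact. Identical `(model, data, mcmc)` input yields identical draws.
#'
#' With a zero-row dataset the posterior equals the prior, and draws are
#' taken i.i.d. from the prior directly (ordinal thresholds as the order
#' statistics of the threshold prior).
#'
#' @param model a `bgsem_model` from [build_model()].
#' @param data a complete `bgsem_dataset` (impute first if needed).
#' @param mcmc a `bgsem_mcmc_config`.
#' @return object of class `bgsem_draws`: post-warmup draws array
#'   `(iteration, chain, parameter)` on the natural scale, plus sampler
#'   reports per sub-model/chain. A warning (stored in `$warnings`) is
#'   recorded when any chain's divergence fraction exceeds 10%.
#' @export
fit <- function(model, data, mcmc = mcmc_config(profile = "test")) {
  stopifnot(inherits(model, "bgsem_model"), inherits(data, "bgsem_dataset"),
            inherits(mcmc, "bgsem_mcmc_config"))
  spec <- model$spec
  plans <- submodel_plan(spec)
  n <- nrow(data$records)
  keep <- mcmc$iter - mcmc$warmup
  all_params <- unlist(lapply(plans, `[[`, "params"), use.names = FALSE)
  draws <- array(NA_real_, c(keep, mcmc$chains, length(all_params)),
                 dimnames = list(NULL, NULL, all_params))
  seeds <- derive_seeds(mcmc$seed, length(plans) * mcmc$chains, salt = 3L)
  reports <- list()
  warnings <- character()
  si <- 0L
  for (plan in plans) {
    fam <- ifelse(plan$family == "binary", 0L, 1L)
    pr <- plan_priors(plan, model$priors)
    if (n == 0) {
      for (ch in seq_len(mcmc$chains)) {
        si <- si + 1L
        draws[, ch, plan$params] <-
          with_seed(seeds[si], prior_draws(plan, model$priors, keep))
      }
      next
    }
    X <- submodel_design(spec, plan, data$records)
    y <- as.integer(data$records[[plan$response]])
    if (anyNA(y) || anyNA(X))
      stop("sub-model '", plan$name, "': data contain missing values; ",
           "run imputation first", call. = FALSE)
    w <- data$weight
    # mediator sub-models depend on the data only through a handful of
    # (design row, response) cells; aggregating their weights is an exact
    # sufficient-statistic reduction of the weighted likelihood
    cs <- collapse_rows(X, y, w)
    if (!is.null(cs)) { X <- cs$X; y <- cs$y; w <- cs$w }
    # sample on the weighted-mean-centered design: an exact
    # reparameterization that decorrelates intercepts/thresholds from the
    # slopes (intercept priors act on the centered scale); draws are
    # mapped back to the natural scale afterwards
    ctr <- center_design(X, fam, w)
    init <- submodel_init(plan, ctr$X, y, w)
    for (ch in seq_len(mcmc$chains)) {
      si <- si + 1L
      init_ch <- init + with_seed(seeds[si],
                                  runif(length(init), -0.05, 0.05))
      res <- cpp_hmc(fam, ctr$X, y, w, plan$ncat,
                     pr$type, pr$df, pr$loc, pr$scale, init_ch,
                     mcmc$iter, mcmc$warmup, mcmc$target_accept,
                     mcmc$max_leapfrog, as.integer(seeds[si] %% 2^31))
      draws[, ch, plan$params] <- uncenter_draws(res$draws, fam,
                                                 plan$ncat, ctr$mu)
      div_frac <- res$divergent / mcmc$iter
      if (div_frac > 0.10)
        warnings <- c(warnings, sprintf(
          "sub-model '%s' chain %d: %.1f%% divergent transitions",
          plan$name, ch, 100 * div_frac))
      reports[[length(reports) + 1L]] <-
        data.frame(submodel = plan$name, chain = ch,
                   accept_rate = res$accept_rate,
                   divergent = res$divergent, step_size = res$step_size)
    }
  }
  structure(list(draws = draws, model = model, mcmc = mcmc,
                 submodels = plans,
                 sampler_report = if (length(reports))
                   do.call(rbind, reports) else NULL,
                 warnings = warnings),
            class = "bgsem_draws")
}

# deterministic, data-informed initial values on the sampling scale
submodel_init <- function(plan, X, y, w) {
  if (plan$family == "binary") {
    p0 <- min(max(weighted.mean(y, w), 0.02), 0.98)
    c(qlogis(p0), rep(0, ncol(X) - 1))
  } else {
    K <- plan$ncat
    cum <- cumsum(vapply(0:(K - 2), function(c)
      weighted.mean(y <= c, w), numeric(1)))
    cum <- pmin(pmax(cum, 0.01), 0.99)
    alpha <- qlogis(cum)
    alpha <- cummax(alpha + seq_along(alpha) * 1e-6) # enforce increasing
    theta <- c(alpha[1], if (K > 2) log(pmax(diff(alpha), 1e-4)))
    c(theta, rep(0, ncol(X)))
  }
}

#' @importFrom stats weighted.mean
prior_draws <- function(plan, priors, ndraw) {
  draw1 <- function(p, m) {
    switch(p$family,
           cauchy = rcauchy(m, p$location, p$scale),
           student_t = p$location + p$scale * rt(m, p$df),
           normal = rnorm(m, p$location, p$scale),
           flat = runif(m, -1000, 1000))
  }
  out <- matrix(NA_real_, ndraw, length(plan$params))
  ints <- which(plan$prior_class == "intercept")
  coefs <- which(plan$prior_class == "coefficient")
  if (plan$family == "ordinal") {
    # thresholds: ordered draws from the intercept prior
    th <- matrix(draw1(priors$intercept, ndraw * length(ints)), ndraw)
    out[, ints] <- t(apply(th, 1, sort))
  } else {
    for (j in ints) out[, j] <- draw1(priors$intercept, ndraw)
  }
  for (j in coefs) out[, j] <- draw1(priors$coefficient, ndraw)
  out
}

#' @export
print.bgsem_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("<bgsem_draws> ", d[1], " iterations x ", d[2], " chains x ", d[3],
      " parameters\n", sep = "")
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Flatten draws to a matrix
#'
#' @param draws a `bgsem_draws`.
#' @return matrix (chains stacked, iterations within chain) x parameters.
#' @export
as_draws_matrix <- function(draws) {
  stopifnot(inherits(draws, "bgsem_draws"))
  d <- dim(draws$draws)
  out <- do.call(rbind, lapply(seq_len(d[2]), function(ch)
    draws$draws[, ch, , drop = TRUE]))
  dim(out) <- c(d[1] * d[2], d[3])
  colnames(out) <- dimnames(draws$draws)[[3]]
  out
}

#' Long-format draws table
#'
#' Columnar representation (chain, iteration, parameter, value) for CSV
#' persistence and external plotting.
#'
#' @param draws a `bgsem_draws`.
#' @return data.frame in long format.
#' @export
draws_long <- function(draws) {
  stopifnot(inherits(draws, "bgsem_draws"))
  d <- dim(draws$draws)
  pn <- dimnames(draws$draws)[[3]]
  data.frame(
    chain = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    iteration = rep(rep(seq_len(d[1]), times = d[2]), times = d[3]),
    parameter = rep(pn, each = d[1] * d[2]),
    value = as.vector(draws$draws))
}

#' Posterior summary table
#'
#' @param object a `bgsem_draws`.
#' @param prob HDI mass (default 0.95).
#' @param ... unused.
#' @return data.frame: parameter, mean, sd, hdi bounds, split R-hat,
#'   bulk and tail ESS.
#' @export
summary.bgsem_draws <- function(object, prob = 0.95, ...) {
  pn <- dimnames(object$draws)[[3]]
  multi <- dim(object$draws)[2] >= 2
  rows <- lapply(pn, function(p) {
    ch <- object$draws[, , p, drop = TRUE]
    if (is.null(dim(ch))) ch <- matrix(ch, ncol = 1)
    x <- as.vector(ch)
    h <- hdi(x, prob)
    e <- if (multi) ess(ch) else list(bulk = NA_real_, tail = NA_real_)
    data.frame(parameter = p, mean = mean(x), sd = sd(x),
               hdi_low = h[1], hdi_high = h[2],
               rhat = if (multi) rhat(ch) else NA_real_,
               ess_bulk = e$bulk, ess_tail = e$tail)
  })
  do.call(rbind, rows)
}

#' Pointwise weighted log-likelihood matrix
#'
#' Per observation, the sum of its weighted log-likelihood contributions
#' across all sub-models, evaluated at every post-warmup draw — the input
#' to [waic()] and [loo()]. Weights are the dataset's normalized weights,
#' exactly as used in the fit, so rescaling all raw weights by a common
#' factor leaves the matrix unchanged.
#'
#' @param draws a `bgsem_draws`.
#' @param data the complete `bgsem_dataset` the model was fitted to.
#' @return matrix (total draws x observations).
#' @export
pointwise_loglik <- function(draws, data) {
  stopifnot(inherits(draws, "bgsem_draws"), inherits(data, "bgsem_dataset"))
  dm <- as_draws_matrix(draws)
  n <- nrow(data$records)
  total <- matrix(0, nrow(dm), n)
  for (plan in draws$submodels) {
    if (!all(plan$params %in% colnames(dm)))
      stop("draws are missing parameters for sub-model '", plan$name, "'",
           call. = FALSE)
    X <- submodel_design(draws$model$spec, plan, data$records)
    y <- as.integer(data$records[[plan$response]])
    if (length(y) != n || anyNA(y) || anyNA(X))
      stop("data shape/missingness mismatch for sub-model '", plan$name,
           "'", call. = FALSE)
    total <- total + cpp_pointwise_loglik(
      ifelse(plan$family == "binary", 0L, 1L), X, y, data$weight,
      plan$ncat, dm[, plan$params, drop = FALSE])
  }
  total
}

# Exact aggregation of a weighted likelihood over duplicated
# (design row, response) combinations; NULL when the design is too rich
# to benefit.
collapse_rows <- function(X, y, w, max_groups = 64) {
  if (nrow(X) <= max_groups || ncol(X) > 4) return(NULL)
  key <- do.call(paste, c(as.data.frame(X), list(y), sep = "\r"))
  uk <- unique(key)
  if (length(uk) > max_groups) return(NULL)
  first <- match(uk, key)
  idx <- match(key, uk)
  list(X = X[first, , drop = FALSE], y = y[first],
       w = as.numeric(rowsum(w, idx)))
}

# center non-intercept design columns at their weighted means (family 0:
# first column is the intercept; family 1: all columns are slopes)
center_design <- function(X, fam, w) {
  slope_cols <- if (fam == 0L) seq_len(ncol(X))[-1] else seq_len(ncol(X))
  mu <- rep(0, ncol(X))
  if (length(slope_cols)) {
    mu[slope_cols] <- apply(X[, slope_cols, drop = FALSE], 2,
                            weighted.mean, w = w)
    X[, slope_cols] <- sweep(X[, slope_cols, drop = FALSE], 2,
                             mu[slope_cols])
  }
  list(X = X, mu = mu)
}

# map centered-scale draws back to the natural parameterization
uncenter_draws <- function(draws, fam, ncat, mu) {
  if (fam == 0L) {
    shift <- draws[, -1, drop = FALSE] %*% mu[-1]
    draws[, 1] <- draws[, 1] - shift
  } else {
    T <- ncat - 1L
    Q <- ncol(draws) - T
    shift <- draws[, T + seq_len(Q), drop = FALSE] %*% mu
    for (c in seq_len(T)) draws[, c] <- draws[, c] + shift
  }
  draws
}
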