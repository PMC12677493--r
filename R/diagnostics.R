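# Convergence and fit diagnostics: rank-normalized split R-hat, bulk/tail
# effective sample size, WAIC, and Pareto-smoothed importance-sampling
# leave-one-out cross-validation. Implemented from the standard published
# formulas; information criteria are reported on the deviance scale
# (-2 * elpd).

split_chains <- function(ch) {
  ch <- as.matrix(ch)
  n <- nrow(ch)
  h <- floor(n / 2)
  cbind(ch[1:h, , drop = FALSE], ch[(n - h + 1):n, , drop = FALSE])
}

rank_normalize <- function(ch) {
  ch <- as.matrix(ch)
  r <- matrix(rank(ch, ties.method = "average"), nrow(ch))
  qnorm((r - 3 / 8) / (length(ch) + 1 / 4))
}

# classic potential-scale-reduction on a (iter x chain) matrix
rhat_basic <- function(ch) {
  n <- nrow(ch)
  m <- ncol(ch)
  mu <- colMeans(ch)
  W <- mean(apply(ch, 2, var))
  B <- n * var(mu)
  if (W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split R-hat
#'
#' Each chain is split in half, draws are rank-normalized jointly, and the
#' potential scale reduction factor is computed. Values near 1.00 indicate
#' convergence; above 1.01 is flagged downstream. With `folded = TRUE`
#' the maximum of the bulk statistic and the folded (tail-sensitive)
#' statistic on absolute deviations from the median is returned instead.
#'
#' @param chains matrix of draws, one column per chain (at least 2 chains
#'   with at least 4 draws each).
#' @param folded also compute the folded variant and report the maximum.
#' @return scalar R-hat.
#' @export
rhat <- function(chains, folded = FALSE) {
  chains <- as.matrix(chains)
  if (ncol(chains) < 2)
    stop("rhat requires >= 2 chains", call. = FALSE)
  if (nrow(chains) < 4)
    stop("rhat requires >= 4 draws per chain", call. = FALSE)
  sp <- split_chains(chains)
  bulk <- rhat_basic(rank_normalize(sp))
  if (!folded) return(bulk)
  max(bulk, rhat_basic(rank_normalize(abs(sp - median(sp)))))
}

# biased autocovariance sequence (lags 0..n-1) via zero-padded FFT
autocovariance <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  npad <- 2^ceiling(log2(2 * n))
  f <- fft(c(x, rep(0, npad - n)))
  Re(fft(f * Conj(f), inverse = TRUE))[1:n] / npad / n
}

# autocorrelation-based ESS of split (possibly transformed) chains, using
# Geyer's initial positive and initial monotone sequences
ess_basic <- function(ch) {
  n <- nrow(ch)
  m <- ncol(ch)
  if (n < 4) return(NA_real_)
  acov <- vapply(seq_len(m), function(j) autocovariance(ch[, j]),
                 numeric(n))
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n +
    (if (m > 1) var(colMeans(ch)) else 0)
  if (var_plus < .Machine$double.eps) return(0)
  rho <- rep(0, n)
  rho[1] <- 1
  rho[2] <- 1 - (mean_var - mean(acov[2, ])) / var_plus
  rho_even <- rho[1]
  rho_odd <- rho[2]
  t <- 0
  while (t < n - 4 && (rho_even + rho_odd) > 0) {
    t <- t + 2
    rho_even <- 1 - (mean_var - mean(acov[t + 1, ])) / var_plus
    rho_odd <- 1 - (mean_var - mean(acov[t + 2, ])) / var_plus
    if (rho_even + rho_odd >= 0) {
      rho[t + 1] <- rho_even
      rho[t + 2] <- rho_odd
    }
  }
  max_t <- max(t, 2)
  # enforce monotone decrease of paired sums
  t <- 0
  while (t <= max_t - 4) {
    t <- t + 2
    if (rho[t + 1] + rho[t + 2] > rho[t - 1] + rho[t]) {
      rho[t + 1] <- (rho[t - 1] + rho[t]) / 2
      rho[t + 2] <- rho[t + 1]
    }
  }
  total <- n * m
  tau <- -1 + 2 * sum(rho[1:max_t]) + rho[max_t + 1]
  tau <- max(tau, 1 / log10(total))
  total / tau
}

#' Bulk and tail effective sample size
#'
#' Bulk ESS is the autocorrelation-based ESS of the rank-normalized split
#' chains; tail ESS is the minimum ESS of the 5% and 95% quantile
#' indicator functions. A constant chain is reported as 0 with the
#' `constant` flag rather than an error.
#'
#' @param chains matrix of draws, one column per chain.
#' @return list with `bulk`, `tail`, `constant`.
#' @export
ess <- function(chains) {
  chains <- as.matrix(chains)
  if (ncol(chains) < 2)
    stop("ess requires >= 2 chains", call. = FALSE)
  if (nrow(chains) < 4)
    stop("ess requires >= 4 draws per chain", call. = FALSE)
  if (sd(chains) < .Machine$double.eps)
    return(list(bulk = 0, tail = 0, constant = TRUE))
  sp <- split_chains(chains)
  bulk <- ess_basic(rank_normalize(sp))
  tail_one <- function(q) {
    ind <- (sp <= quantile(sp, q)) * 1
    dim(ind) <- dim(sp)
    if (sd(ind) < .Machine$double.eps) return(0)
    ess_basic(ind)
  }
  list(bulk = bulk, tail = min(tail_one(0.05), tail_one(0.95)),
       constant = FALSE)
}

#' Widely applicable information criterion
#'
#' `lppd = sum_i log mean_d exp(ll[d,i])` (log-sum-exp stabilized),
#' `p_waic = sum_i var_d(ll[d,i])`, `waic = -2 (lppd - p_waic)`.
#'
#' @param loglik matrix of pointwise log-likelihood values
#'   (draws x observations), e.g. from [pointwise_loglik()].
#' @return list with `waic`, `p_waic`, `lppd`.
#' @export
waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (any(!is.finite(loglik)))
    stop("waic: non-finite log-likelihood entries", call. = FALSE)
  lppd_i <- apply(loglik, 2, log_mean_exp)
  p_i <- apply(loglik, 2, var)
  list(waic = -2 * (sum(lppd_i) - sum(p_i)), p_waic = sum(p_i),
       lppd = sum(lppd_i))
}

# Generalized Pareto fit to exceedances (Zhang & Stephens 2009 profile
# posterior mean), with the usual weakly-informative shrinkage of k.
gpdfit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  jhalf <- seq_len(m) - 0.5
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / jhalf)) / (prior_bs * xstar)
  # profile likelihood in the Zhang-Stephens parameterization
  # (their shape is the negative of the usual xi)
  zs_k <- function(bi) -mean(log1p(-bi * x))
  l <- vapply(b, function(bi) {
    k <- zs_k(bi)
    n * (log(bi / k) + k - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l - l[j])), numeric(1))
  b_hat <- sum(b * w)
  xi <- -zs_k(b_hat)
  sigma <- -xi / b_hat
  # shrink the shape toward 0.5 with 10 pseudo-observations
  xi <- (n * xi + 10 * 0.5) / (n + 10)
  list(k = xi, sigma = sigma)
}

# GPD quantile, shape xi (k), scale sigma, location 0
qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(k * (-log1p(-p))) / k
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Per observation, raw importance weights are `exp(-ll)`; the largest 20%
#' of weights are replaced by quantiles of a generalized Pareto
#' distribution fitted to them, truncated at the raw maximum, and the
#' LOO expected log predictive density is computed with the smoothed
#' weights. `looic = -2 * elpd_loo`. The tail shape `k` diagnoses
#' influential observations (flagged above 0.7). Zero-variance columns are
#' left unsmoothed, making `looic` equal WAIC exactly in that degenerate
#' case.
#'
#' @param loglik matrix (draws x observations), >= 100 draws.
#' @return list with `looic`, `elpd_loo`, `pareto_k` (per observation).
#' @export
loo <- function(loglik) {
  loglik <- as.matrix(loglik)
  S <- nrow(loglik)
  if (S < 100)
    stop("loo requires >= 100 draws", call. = FALSE)
  if (any(!is.finite(loglik)))
    stop("loo: non-finite log-likelihood entries", call. = FALSE)
  n <- ncol(loglik)
  elpd <- numeric(n)
  k <- numeric(n)
  M <- ceiling(0.2 * S)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    lw <- -ll
    lw <- lw - max(lw)
    if (sd(lw) < .Machine$double.eps) {
      # uniform weights: elpd reduces to log mean exp(ll) exactly
      elpd[i] <- log_mean_exp(ll)
      k[i] <- -Inf
      next
    }
    ord <- order(lw)
    tail_ids <- ord[(S - M + 1):S]
    cutoff <- lw[ord[S - M]]
    exceed <- exp(lw[tail_ids]) - exp(cutoff)
    if (all(exceed <= 0)) {
      k[i] <- -Inf
    } else {
      fitk <- gpdfit(exceed[exceed > 0])
      k[i] <- fitk$k
      smoothed <- log(exp(cutoff) +
                        qgpd((rank(lw[tail_ids],
                                   ties.method = "first") - 0.5) / M,
                             fitk$k, fitk$sigma))
      lw[tail_ids] <- pmin(smoothed, 0) # truncate at raw max (= 0)
    }
    elpd[i] <- log_sum_exp(lw + ll) - log_sum_exp(lw)
  }
  list(looic = -2 * sum(elpd), elpd_loo = sum(elpd), pareto_k = k)
}

#' Convergence-and-fit report
#'
#' Per-parameter split R-hat and bulk/tail ESS, model-level WAIC and
#' PSIS-LOO, and the standard flags (R-hat > 1.01; Pareto k > 0.7).
#'
#' @param draws a `bgsem_draws`.
#' @param data the fitted dataset (for the pointwise log-likelihood);
#'   set `NULL` to skip the information criteria.
#' @return object of class `bgsem_diagnostics`: `parameters` table,
#'   `waic`, `p_waic`, `looic`, `pareto_k`, `flags`.
#' @export
diagnostics_report <- function(draws, data = NULL) {
  stopifnot(inherits(draws, "bgsem_draws"))
  pn <- dimnames(draws$draws)[[3]]
  par_tab <- do.call(rbind, lapply(pn, function(p) {
    ch <- draws$draws[, , p, drop = TRUE]
    if (is.null(dim(ch))) ch <- matrix(ch, ncol = 1)
    e <- ess(ch)
    data.frame(parameter = p,
               rhat = if (ncol(ch) >= 2) rhat(ch) else NA_real_,
               ess_bulk = e$bulk, ess_tail = e$tail)
  }))
  out <- list(parameters = par_tab, waic = NA_real_, p_waic = NA_real_,
              looic = NA_real_, pareto_k = NULL)
  if (!is.null(data)) {
    ll <- pointwise_loglik(draws, data)
    w <- waic(ll)
    l <- loo(ll)
    out$waic <- w$waic
    out$p_waic <- w$p_waic
    out$looic <- l$looic
    out$pareto_k <- l$pareto_k
  }
  out$flags <- list(
    rhat_above_1.01 = par_tab$parameter[!is.na(par_tab$rhat) &
                                          par_tab$rhat > 1.01],
    pareto_k_above_0.7 = if (!is.null(out$pareto_k))
      which(out$pareto_k > 0.7) else integer(0))
  class(out) <- "bgsem_diagnostics"
  out
}

#' @export
print.bgsem_diagnostics <- function(x, ...) {
  cat("<bgsem_diagnostics> max rhat = ",
      sprintf("%.4f", max(x$parameters$rhat, na.rm = TRUE)),
      "; waic = ", sprintf("%.2f", x$waic),
      "; looic = ", sprintf("%.2f", x$looic), "\n", sep = "")
  if (length(x$flags$rhat_above_1.01))
    cat("  rhat > 1.01: ", paste(x$flags$rhat_above_1.01, collapse = ", "),
        "\n")
  invisible(x)
}

#' Automated refinement of a model specification
#'
#' Drops every mediator whose indirect-association 95% HDI covers zero in
#' a fitted decomposition. This is a mechanical stand-in for the original
#' judgment-guided screening (which examined the individual path HDIs and
#' effect sizes as well); the two agree on clear-cut cases.
#'
#' @param decomp a `bgsem_decomposition` from the comprehensive fit.
#' @param spec the comprehensive `bgsem_model_spec`.
#' @param controls optional control subset for the refined spec (defaults
#'   to the spec's controls, unchanged).
#' @return a new `bgsem_model_spec`.
#' @export
refine_spec <- function(decomp, spec, controls = spec$controls) {
  stopifnot(inherits(decomp, "bgsem_decomposition"),
            inherits(spec, "bgsem_model_spec"))
  s <- decomp$summary
  med <- s[s$role == "mediator", ]
  keep <- med$variable[med$value_lo > 0 | med$value_hi < 0]
  if (length(keep) == 0)
    stop("no mediator has an indirect HDI excluding zero; refusing to ",
         "build an empty mediation model", call. = FALSE)
  model_spec(spec$schema, mediators = keep, controls = controls,
             control_coding = spec$control_coding)
}

#' Prior and specification sensitivity runner
#'
#' Fits every (specification x prior preset) cell with the same seed and
#' data, and tabulates the decomposition summaries, convergence ranges and
#' information criteria side by side; absolute differences in path means
#' across priors (within each specification) are flagged when they exceed
#' `flag_threshold` on the log-odds scale. A cell that fails to fit is
#' marked failed and the run continues.
#'
#' @param specs named list of `bgsem_model_spec` objects (e.g.
#'   comprehensive / refined).
#' @param priors named list of `bgsem_prior_config` objects (e.g.
#'   default / diffuse).
#' @param data complete `bgsem_dataset`.
#' @param mcmc a `bgsem_mcmc_config` (same seed reused for every cell).
#' @param flag_threshold log-odds difference that triggers a flag.
#' @param information_criteria compute WAIC/LOOIC per cell (slower).
#' @return object of class `bgsem_sensitivity`: `cells` table and
#'   `flags` table.
#' @export
sensitivity_run <- function(specs, priors, data, mcmc,
                            flag_threshold = 0.1,
                            information_criteria = TRUE) {
  cells <- list()
  path_means <- list()
  for (sn in names(specs)) for (pn in names(priors)) {
    key <- paste(sn, pn, sep = ".")
    res <- tryCatch({
      mod <- build_model(specs[[sn]], priors[[pn]])
      dr <- fit(mod, data, mcmc)
      dec <- decompose(dr)
      diag <- diagnostics_report(dr, if (information_criteria) data)
      path_means[[key]] <- setNames(
        c(dec$summary$value_mean[dec$summary$role == "mediator"],
          dec$summary$value_mean[dec$summary$role == "direct"]),
        c(dec$mediators, "direct"))
      data.frame(spec = sn, prior = pn, status = "ok",
                 direct = mean(dec$draws$direct),
                 total_indirect = mean(dec$draws$total_indirect),
                 proportion_mediated = dec$proportion_mediated,
                 rhat_max = max(diag$parameters$rhat, na.rm = TRUE),
                 waic = diag$waic, looic = diag$looic,
                 n_divergent = if (is.null(dr$sampler_report)) 0
                   else sum(dr$sampler_report$divergent))
    }, error = function(e)
      data.frame(spec = sn, prior = pn, status = paste("failed:",
                                                       conditionMessage(e)),
                 direct = NA, total_indirect = NA,
                 proportion_mediated = NA, rhat_max = NA, waic = NA,
                 looic = NA, n_divergent = NA))
    cells[[key]] <- res
  }
  cells <- do.call(rbind, cells)
  # flag prior-driven shifts within each spec
  flags <- list()
  for (sn in names(specs)) {
    keys <- paste(sn, names(priors), sep = ".")
    keys <- keys[keys %in% names(path_means)]
    if (length(keys) < 2) next
    ref <- path_means[[keys[1]]]
    for (k in keys[-1]) {
      common <- intersect(names(ref), names(path_means[[k]]))
      d <- abs(ref[common] - path_means[[k]][common])
      if (any(d > flag_threshold))
        flags[[paste(sn, k)]] <- data.frame(
          spec = sn, comparison = paste(keys[1], "vs", k),
          path = common[d > flag_threshold],
          abs_difference = unname(d[d > flag_threshold]))
    }
  }
  structure(list(cells = cells,
                 flags = if (length(flags)) do.call(rbind, flags)
                 else NULL),
            class = "bgsem_sensitivity")
}

#' @export
print.bgsem_sensitivity <- function(x, ...) {
  print(x$cells, row.names = FALSE)
  if (!is.null(x$flags)) {
    cat("prior-sensitivity flags:\n")
    print(x$flags, row.names = FALSE)
  } else cat("no prior-sensitivity flags\n")
  invisible(x)
}
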