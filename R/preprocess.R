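# Missing-data assessment and handling: missingness patterns and Little's
# MCAR test (EM under a multivariate-normal working model on the numeric
# codes — an approximation for categorical data, but the standard one),
# chained-equation multiple imputation with Bayesian parameter draws, and
# the adjusted-GVIF collinearity screen.

#' Missingness report
#'
#' Per-variable missing counts/percents, the distinct missingness
#' patterns with frequencies, and Little's MCAR test.
#'
#' @param data a `bgsem_dataset`.
#' @return object of class `bgsem_missingness_report` with fields
#'   `variables`, `patterns`, `mcar_statistic`, `mcar_df`, `mcar_p`,
#'   `complete` (flag: no incomplete patterns).
#' @export
missingness_report <- function(data) {
  stopifnot(inherits(data, "bgsem_dataset"))
  M <- missing_mask(data)
  vars <- data.frame(variable = colnames(M),
                     n_missing = colSums(M),
                     pct_missing = 100 * colMeans(M), row.names = NULL)
  pat_key <- apply(M, 1, function(r) paste(as.integer(r), collapse = ""))
  pat_tab <- as.data.frame(table(pattern = pat_key),
                           stringsAsFactors = FALSE)
  names(pat_tab)[2] <- "n"
  mcar <- littles_mcar_test(data)
  structure(list(variables = vars, patterns = pat_tab,
                 mcar_statistic = mcar$statistic, mcar_df = mcar$df,
                 mcar_p = mcar$p, complete = mcar$complete),
            class = "bgsem_missingness_report")
}

#' @export
print.bgsem_missingness_report <- function(x, ...) {
  cat("<bgsem_missingness_report> ", nrow(x$patterns),
      " missingness patterns\n", sep = "")
  cat(sprintf("  Little's MCAR test: chi2 = %.2f, df = %d, p = %.4g\n",
              x$mcar_statistic, x$mcar_df, x$mcar_p))
  invisible(x)
}

#' Little's MCAR test
#'
#' Tests whether the data are missing completely at random by comparing
#' the observed-variable means of each missingness pattern against the EM
#' estimates of the grand mean and covariance under a multivariate-normal
#' working model on the numeric codes:
#' \eqn{d^2 = \sum_j n_j (\bar y_j - \hat\mu_j)' \hat\Sigma_j^{-1}
#' (\bar y_j - \hat\mu_j)}, referred to a chi-square with
#' \eqn{df = \sum_j p_j - p} (observed variables per pattern minus total
#' variables). EM runs to a 1e-6 observed-data log-likelihood tolerance
#' (max 500 iterations) with a 1e-8 ridge on the covariance.
#'
#' Treating coded categories as numeric under normality is an
#' approximation; pattern means are asymptotically normal under MCAR
#' regardless, so the test keeps its asymptotic level.
#'
#' Complete data return `(statistic = 0, df = 0, p = 1)` with
#' `complete = TRUE` rather than an error.
#'
#' @param data a `bgsem_dataset` (or plain numeric data.frame/matrix with
#'   `NA`s).
#' @param tol,max_iter,ridge EM controls.
#' @return list with `statistic`, `df`, `p`, `complete`, `n_patterns`.
#' @export
littles_mcar_test <- function(data, tol = 1e-6, max_iter = 500,
                              ridge = 1e-8) {
  Y <- if (inherits(data, "bgsem_dataset"))
    as.matrix(data$records) else as.matrix(data)
  storage.mode(Y) <- "double"
  # drop all-missing rows and constant/all-missing columns
  Y <- Y[rowSums(!is.na(Y)) > 0, , drop = FALSE]
  n <- nrow(Y)
  p <- ncol(Y)
  obs <- !is.na(Y)
  if (all(obs)) {
    return(list(statistic = 0, df = 0L, p = 1, complete = TRUE,
                n_patterns = 1L))
  }
  em <- em_norm(Y, tol = tol, max_iter = max_iter, ridge = ridge)
  mu <- em$mu
  Sigma <- em$Sigma
  key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  d2 <- 0
  df <- 0L
  for (k in unique(key)) {
    rows <- which(key == k)
    oj <- obs[rows[1], ]
    pj <- sum(oj)
    if (pj == 0) next
    ybar <- colMeans(Y[rows, oj, drop = FALSE])
    diff <- ybar - mu[oj]
    Sj <- Sigma[oj, oj, drop = FALSE]
    d2 <- d2 + length(rows) *
      drop(crossprod(diff, solve(Sj, diff)))
    df <- df + pj
  }
  df <- df - p
  list(statistic = d2, df = as.integer(df),
       p = pchisq(d2, df, lower.tail = FALSE), complete = FALSE,
       n_patterns = length(unique(key)))
}

# EM for multivariate normal with missing values (grouped by pattern);
# returns ML mean and covariance
em_norm <- function(Y, tol = 1e-6, max_iter = 500, ridge = 1e-8) {
  n <- nrow(Y)
  p <- ncol(Y)
  obs <- !is.na(Y)
  # start from available-case moments
  mu <- colMeans(Y, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  Sigma <- diag(apply(Y, 2, function(c) {
    v <- var(c, na.rm = TRUE)
    if (!is.finite(v) || v < 1e-6) 1 else v
  }), p)
  key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), key)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    S1 <- numeric(p)
    S2 <- matrix(0, p, p)
    ll <- 0
    for (rows in groups) {
      oj <- obs[rows[1], ]
      mj <- !oj
      Yo <- Y[rows, oj, drop = FALSE]
      nj <- length(rows)
      if (!any(mj)) {
        S1 <- S1 + colSums(Y[rows, , drop = FALSE])
        S2 <- S2 + crossprod(Y[rows, , drop = FALSE])
      } else if (!any(oj)) {
        next
      } else {
        Soo <- Sigma[oj, oj, drop = FALSE]
        Smo <- Sigma[mj, oj, drop = FALSE]
        Smm <- Sigma[mj, mj, drop = FALSE]
        B <- Smo %*% solve(Soo)                    # regression coefs
        resid <- sweep(Yo, 2, mu[oj])              # nj x pj
        Em <- sweep(resid %*% t(B), 2, mu[mj], "+") # conditional means
        Cm <- Smm - B %*% t(Smo)                   # conditional cov
        Z <- matrix(0, nj, p)
        Z[, oj] <- Yo
        Z[, mj] <- Em
        S1 <- S1 + colSums(Z)
        S2 <- S2 + crossprod(Z)
        S2[mj, mj] <- S2[mj, mj] + nj * Cm
      }
      # observed-data log-likelihood contribution
      Soo <- Sigma[oj, oj, drop = FALSE]
      cs <- chol(Soo)
      resid <- sweep(Y[rows, oj, drop = FALSE], 2, mu[oj])
      q <- rowSums((resid %*% chol2inv(cs)) * resid)
      ll <- ll - 0.5 * nj * (2 * sum(log(diag(cs))) +
                               sum(oj) * log(2 * pi)) - 0.5 * sum(q)
    }
    mu <- S1 / n
    Sigma <- S2 / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2 + diag(ridge, p)
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma, iterations = it, loglik = ll)
}

# ---- MICE --------------------------------------------------------------

#' Multiple imputation by chained equations
#'
#' Visits incomplete variables in schema order for `maxit` sweeps; each
#' binary variable is imputed from a logistic regression on all other
#' analysis variables with coefficients drawn from their approximate
#' posterior (Bayesian logistic draws), and each ordinal variable from a
#' proportional-odds model with drawn coefficients. Produces `m`
#' independently completed copies; observed cells are never altered, and
#' the result is deterministic given `seed`.
#'
#' @param data a `bgsem_dataset` with missing cells.
#' @param m number of completed copies.
#' @param maxit chained-equation sweeps per copy.
#' @param seed integer seed.
#' @param predictors optional character vector restricting the predictor
#'   set (default: all other schema variables).
#' @return object of class `bgsem_imputation`: `completed` (list of m
#'   complete `bgsem_dataset`s), `chain_means` (per copy x iteration x
#'   variable, for convergence inspection), `config`.
#' @export
mice_impute <- function(data, m = 5, maxit = 10, seed = 1,
                        predictors = NULL) {
  stopifnot(inherits(data, "bgsem_dataset"), m >= 1, maxit >= 1)
  sch <- data$schema
  rec0 <- data$records
  miss <- lapply(rec0, function(x) which(is.na(x)))
  targets <- names(sch)[vapply(miss, length, integer(1)) > 0]
  over <- targets[vapply(targets, function(v)
    mean(is.na(rec0[[v]])), numeric(1)) > 0.95]
  if (length(over))
    stop("variable(s) ", paste(over, collapse = ", "), " are >95% ",
         "missing; exclude them instead of imputing", call. = FALSE)
  if (length(targets) == 0) {
    completed <- replicate(m, data, simplify = FALSE)
    return(structure(list(completed = completed, chain_means = NULL,
                          config = list(m = m, maxit = maxit, seed = seed)),
                     class = "bgsem_imputation"))
  }
  seeds <- derive_seeds(seed, m, salt = 4L)
  chain_means <- array(
    NA_real_, c(m, maxit, length(targets)),
    dimnames = list(NULL, NULL, targets))
  completed <- vector("list", m)
  for (copy in seq_len(m)) {
    completed[[copy]] <- with_seed(seeds[copy], {
      rec <- rec0
      # initialize holes by sampling observed values
      for (v in targets) {
        obs_vals <- rec0[[v]][!is.na(rec0[[v]])]
        rec[[v]][miss[[v]]] <- sample(obs_vals, length(miss[[v]]),
                                      replace = TRUE)
      }
      for (it in seq_len(maxit)) {
        for (v in targets) {
          pred <- predictors %||% setdiff(names(sch), v)
          rec[[v]][miss[[v]]] <- impute_one(
            rec, v, pred, miss[[v]], sch)
          chain_means[copy, it, v] <- mean(rec[[v]][miss[[v]]])
        }
      }
      bgsem_dataset(rec, data$weight, sch, normalize = FALSE)
    })
  }
  structure(list(completed = completed, chain_means = chain_means,
                 config = list(m = m, maxit = maxit, seed = seed)),
            class = "bgsem_imputation")
}

#' @export
print.bgsem_imputation <- function(x, ...) {
  cat("<bgsem_imputation> m = ", length(x$completed), " completed copies\n",
      sep = "")
  invisible(x)
}

# draw imputations for the missing cells of one variable, conditional on
# the current completed values of the predictors
impute_one <- function(rec, v, predictors, idx, sch) {
  Xf <- as.matrix(as.data.frame(rec[predictors]))
  storage.mode(Xf) <- "double"
  # drop constant predictors to keep the working fits full rank
  keep <- apply(Xf, 2, function(c) length(unique(c[-idx])) > 1)
  Xf <- Xf[, keep, drop = FALSE]
  y <- rec[[v]]
  K <- n_levels(sch, v)
  fit_rows <- setdiff(seq_along(y), idx)
  if (ncol(Xf) == 0 || length(fit_rows) < 5 * (ncol(Xf) + K)) {
    # too little information: draw from the observed distribution
    return(sample(y[fit_rows], length(idx), replace = TRUE))
  }
  if (K == 2) {
    g <- tryCatch(
      suppressWarnings(glm.fit(cbind(1, Xf[fit_rows, , drop = FALSE]),
                               y[fit_rows], family = binomial())),
      error = function(e) NULL)
    if (is.null(g) || !g$converged)
      return(sample(y[fit_rows], length(idx), replace = TRUE))
    beta_hat <- g$coefficients
    XtWX <- crossprod(cbind(1, Xf[fit_rows, , drop = FALSE]) *
                        sqrt(g$weights))
    V <- tryCatch(chol2inv(chol(XtWX + diag(1e-8, ncol(XtWX)))),
                  error = function(e) NULL)
    if (is.null(V))
      return(sample(y[fit_rows], length(idx), replace = TRUE))
    beta <- beta_hat + drop(rnorm(length(beta_hat)) %*% chol(V))
    pr <- plogis(drop(cbind(1, Xf[idx, , drop = FALSE]) %*% beta))
    as.integer(rbinom(length(idx), 1L, pr))
  } else {
    yf <- factor(y[fit_rows], levels = 0:(K - 1), ordered = TRUE)
    dat <- data.frame(.y = yf, Xf[fit_rows, , drop = FALSE])
    po <- tryCatch(
      suppressWarnings(MASS::polr(.y ~ ., data = dat, Hess = TRUE)),
      error = function(e) NULL)
    if (is.null(po))
      return(sample(y[fit_rows], length(idx), replace = TRUE))
    th_hat <- c(po$coefficients, po$zeta)
    V <- tryCatch(solve(po$Hessian), error = function(e) NULL)
    if (is.null(V))
      return(sample(y[fit_rows], length(idx), replace = TRUE))
    th <- th_hat + drop(rnorm(length(th_hat)) %*%
                          chol((V + t(V)) / 2 + diag(1e-10, nrow(V))))
    nb <- length(po$coefficients)
    beta <- th[seq_len(nb)]
    zeta <- sort(th[nb + seq_len(K - 1)])
    eta <- drop(Xf[idx, , drop = FALSE] %*% beta)
    cum <- vapply(zeta, function(z) plogis(z - eta), numeric(length(idx)))
    if (length(idx) == 1) cum <- matrix(cum, nrow = 1)
    u <- runif(length(idx))
    as.integer(rowSums(u > cum))
  }
}

#' Observed-versus-imputed comparison table
#'
#' For every imputed variable, the category frequencies among observed
#' cells and among imputed cells (pooled over the m copies), with the
#' absolute difference — a tabular form of the usual distributional
#' imputation check.
#'
#' @param result a `bgsem_imputation`.
#' @param original the `bgsem_dataset` that was imputed.
#' @return data.frame: variable, level, freq_observed, freq_imputed,
#'   abs_difference. Empty (0 rows) when nothing was imputed.
#' @export
imputation_diagnostics <- function(result, original) {
  stopifnot(inherits(result, "bgsem_imputation"),
            inherits(original, "bgsem_dataset"))
  sch <- original$schema
  if (!identical(names(sch), names(result$completed[[1]]$schema)))
    stop("schema mismatch between imputation result and original",
         call. = FALSE)
  out <- list()
  for (v in names(sch)) {
    idx <- which(is.na(original$records[[v]]))
    if (length(idx) == 0) next
    K <- n_levels(sch, v)
    obs_vals <- original$records[[v]][-idx]
    imp_vals <- unlist(lapply(result$completed, function(d)
      d$records[[v]][idx]))
    fo <- tabulate(obs_vals + 1L, K) / max(length(obs_vals), 1L)
    fi <- tabulate(imp_vals + 1L, K) / max(length(imp_vals), 1L)
    out[[v]] <- data.frame(variable = v, level = sch[[v]]$levels,
                           freq_observed = fo, freq_imputed = fi,
                           abs_difference = abs(fo - fi))
  }
  if (length(out) == 0)
    return(data.frame(variable = character(), level = character(),
                      freq_observed = numeric(), freq_imputed = numeric(),
                      abs_difference = numeric()))
  do.call(rbind, c(out, make.row.names = FALSE))
}

# ---- collinearity ------------------------------------------------------

#' Adjusted generalized variance inflation factors
#'
#' For each term, `GVIF = det(R11) * det(R22) / det(R)` on the correlation
#' matrix of the centered dummy-coded design (R11: the term's columns,
#' R22: all other columns), and `aGVIF = GVIF^(1/(2 df))` with df the
#' term's dummy-column count — comparable across terms of different
#' dimension, and equal to sqrt(VIF) for a 1-df term. The result is
#' invariant to each term's reference-category choice.
#'
#' @param data a complete `bgsem_dataset` (or data.frame of numeric
#'   codes).
#' @param terms variables to screen (default: all exposure/mediator/
#'   control variables of the schema).
#' @param dummy_code expand multi-level terms to dummies (default `TRUE`;
#'   `FALSE` uses one linear-score column per term).
#' @param groups for a plain design matrix: named list mapping each term
#'   to its column names (defaults to one term per column).
#' @return data.frame: term, df, gvif, agvif.
#' @export
agvif <- function(data, terms = NULL, dummy_code = TRUE, groups = NULL) {
  if (inherits(data, "bgsem_dataset")) {
    sch <- data$schema
    terms <- terms %||% setdiff(names(sch), outcome_name(sch))
    rec <- data$records
    if (anyNA(rec[terms]))
      stop("agvif requires complete data for the screened terms",
           call. = FALSE)
    cols <- list()
    groups <- list()
    for (v in terms) {
      K <- n_levels(sch, v)
      if (dummy_code && K > 2) {
        nm <- paste0(v, "_", seq_len(K - 1))
        for (l in seq_len(K - 1))
          cols[[nm[l]]] <- as.numeric(rec[[v]] == l)
        groups[[v]] <- nm
      } else {
        cols[[v]] <- as.numeric(rec[[v]])
        groups[[v]] <- v
      }
    }
    X <- do.call(cbind, cols)
  } else {
    X <- as.matrix(data)
    if (is.null(groups)) {
      terms <- terms %||% colnames(X)
      groups <- as.list(setNames(terms, terms))
    }
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  sds <- apply(X, 2, sd)
  if (any(sds < .Machine$double.eps))
    stop("constant column(s): ",
         paste(colnames(X)[sds < .Machine$double.eps], collapse = ", "),
         call. = FALSE)
  R <- cor(X)
  detR <- det(R)
  if (detR < 1e-12) {
    # identify an offending term by leave-one-term-out determinants
    for (v in names(groups)) {
      others <- setdiff(colnames(X), groups[[v]])
      if (length(others) && det(R[others, others, drop = FALSE]) > 1e-12 &&
          detR < 1e-12)
        stop("design is (near-)rank deficient; term '", v,
             "' is collinear with the others", call. = FALSE)
    }
    stop("design is (near-)rank deficient", call. = FALSE)
  }
  rows <- lapply(names(groups), function(v) {
    g <- groups[[v]]
    others <- setdiff(colnames(X), g)
    g11 <- det(R[g, g, drop = FALSE])
    g22 <- if (length(others))
      det(R[others, others, drop = FALSE]) else 1
    gvif <- g11 * g22 / detR
    data.frame(term = v, df = length(g), gvif = gvif,
               agvif = gvif^(1 / (2 * length(g))))
  })
  do.call(rbind, rows)
}
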