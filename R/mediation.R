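# Posterior product-of-coefficients decomposition on the log-odds scale:
# per draw, indirect_k = gamma_k * beta_k, total indirect = sum_k,
# total = direct + total indirect; summaries are posterior means with 95%
# highest density intervals.

#' Highest density interval
#'
#' The shortest contiguous interval over the sorted samples containing
#' `ceiling(mass * n)` points.
#'
#' @param samples numeric vector (>= 2 finite values).
#' @param mass interval mass in (0, 1), default 0.95.
#' @return numeric `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2)
    stop("hdi needs at least 2 finite samples", call. = FALSE)
  if (!(mass > 0 && mass < 1))
    stop("mass must be in (0, 1)", call. = FALSE)
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Decompose the exposure-outcome association over posterior draws
#'
#' For each mediator k the indirect association is the per-draw product of
#' the exposure-to-mediator slope (`gamma_k`) and the mediator-to-outcome
#' coefficient (`b_k`), on the log-odds scale. The direct association is
#' the exposure coefficient of the outcome equation; per draw,
#' total = direct + sum of indirects exactly.
#'
#' @param draws a `bgsem_draws` (or a plain named draw matrix).
#' @param spec the `bgsem_model_spec` (taken from `draws` if omitted).
#' @param mass HDI mass, default 0.95.
#' @return object of class `bgsem_decomposition` with per-draw vectors
#'   (`direct`, `total_indirect`, `total`, per-mediator `indirect`), a
#'   summary table, and both proportion-mediated variants.
#' @export
decompose <- function(draws, spec = NULL, mass = 0.95) {
  if (inherits(draws, "bgsem_draws")) {
    spec <- spec %||% draws$model$spec
    dm <- as_draws_matrix(draws)
  } else {
    dm <- as.matrix(draws)
    if (is.null(spec)) stop("spec required with a plain draw matrix",
                            call. = FALSE)
  }
  meds <- spec$mediators
  need <- c("bX", paste0("gamma_", meds), paste0("b_", meds))
  miss <- setdiff(need, colnames(dm))
  if (length(miss))
    stop("missing parameter(s) in draws: ", paste(miss, collapse = ", "),
         call. = FALSE)
  direct <- dm[, "bX"]
  a <- dm[, paste0("gamma_", meds), drop = FALSE]
  b <- dm[, paste0("b_", meds), drop = FALSE]
  ind <- a * b
  colnames(ind) <- meds
  total_indirect <- rowSums(ind)
  total <- direct + total_indirect
  summ <- function(x) c(mean = mean(x), hdi(x, mass))
  rows <- rbind(
    t(vapply(meds, function(m)
      c(summ(a[, paste0("gamma_", m)]), summ(b[, paste0("b_", m)]),
        summ(ind[, m])), numeric(9))),
    total_indirect = c(rep(NA_real_, 6), summ(total_indirect)),
    direct = c(rep(NA_real_, 6), summ(direct)),
    total = c(rep(NA_real_, 6), summ(total)))
  colnames(rows) <- c("xm_mean", "xm_lo", "xm_hi", "my_mean", "my_lo",
                      "my_hi", "value_mean", "value_lo", "value_hi")
  summary_tab <- data.frame(
    variable = rownames(rows),
    role = c(rep("mediator", length(meds)), "total_indirect", "direct",
             "total"),
    rows, row.names = NULL)
  structure(list(
    mediators = meds,
    draws = list(direct = direct, indirect = ind,
                 total_indirect = total_indirect, total = total),
    summary = summary_tab, mass = mass,
    proportion_mediated = proportion_mediated(mean(total_indirect),
                                              mean(direct)),
    proportion_mediated_draws = {
      r <- 100 * total_indirect / total
      c(mean = mean(r), hdi(r, mass))
    }),
    class = "bgsem_decomposition")
}

#' @export
print.bgsem_decomposition <- function(x, ...) {
  cat("<bgsem_decomposition> ", length(x$mediators), " mediators; ",
      "proportion mediated (ratio of posterior means) = ",
      sprintf("%.2f%%", x$proportion_mediated), "\n", sep = "")
  invisible(x)
}

#' Proportion of the total association that is mediated
#'
#' Computed from posterior-mean path estimates:
#' `100 * total_indirect / (total_indirect + direct)` — the ratio of
#' reported means, not the mean of per-draw ratios (which is unstable when
#' the total is near zero; that variant is exposed separately as
#' `proportion_mediated_draws` on the decomposition object). The value may
#' exceed 100% or be negative under inconsistent mediation; it is not
#' clamped.
#'
#' @param total_indirect_mean posterior mean of the total indirect
#'   association.
#' @param direct_mean posterior mean of the direct association.
#' @return percentage (scalar).
#' @export
proportion_mediated <- function(total_indirect_mean, direct_mean) {
  tot <- total_indirect_mean + direct_mean
  if (tot == 0)
    stop("total association is zero; proportion undefined", call. = FALSE)
  100 * total_indirect_mean / tot
}

#' Path-table report
#'
#' One row per mediator (exposure-to-mediator, mediator-to-outcome and
#' indirect columns, each "mean (lo, hi)" at half-up 2 decimals), followed
#' by total-indirect and direct rows — the published path-table layout.
#'
#' @param decomp a `bgsem_decomposition`.
#' @return data.frame of formatted strings.
#' @export
summarize_paths <- function(decomp) {
  stopifnot(inherits(decomp, "bgsem_decomposition"))
  s <- decomp$summary
  fmt <- function(m, lo, hi)
    ifelse(is.na(m), "-", sprintf("%.2f(%.2f, %.2f)", round_half_up(m),
                                  round_half_up(lo), round_half_up(hi)))
  data.frame(
    variable = s$variable,
    x_m = fmt(s$xm_mean, s$xm_lo, s$xm_hi),
    m_y = fmt(s$my_mean, s$my_lo, s$my_hi),
    value = fmt(s$value_mean, s$value_lo, s$value_hi),
    role = s$role)
}

#' Path-diagram edge list
#'
#' Edges (source, target, mean, hdi bounds) for external graphing; an edge
#' is `solid` when its 95% HDI excludes zero, `dashed` otherwise.
#'
#' @param decomp a `bgsem_decomposition`.
#' @param exposure,outcome node labels.
#' @return data.frame edge list.
#' @export
path_edges <- function(decomp, exposure = "X", outcome = "Y") {
  s <- decomp$summary
  med <- s[s$role == "mediator", ]
  style <- function(lo, hi) ifelse(lo > 0 | hi < 0, "solid", "dashed")
  rbind(
    data.frame(source = exposure, target = med$variable,
               mean = med$xm_mean, hdi_low = med$xm_lo, hdi_high = med$xm_hi,
               style = style(med$xm_lo, med$xm_hi)),
    data.frame(source = med$variable, target = outcome,
               mean = med$my_mean, hdi_low = med$my_lo, hdi_high = med$my_hi,
               style = style(med$my_lo, med$my_hi)),
    {
      d <- s[s$role == "direct", ]
      data.frame(source = exposure, target = outcome, mean = d$value_mean,
                 hdi_low = d$value_lo, hdi_high = d$value_hi,
                 style = style(d$value_lo, d$value_hi))
    })
}
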