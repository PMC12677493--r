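# Shared fixtures and independent oracles used across the suite.

# minimal schema: binary exposure/outcome, one binary and one ordinal
# mediator, one binary control
toy_schema <- function() {
  schema(
    variable_spec("X", "exposure", "binary", c("No", "Yes")),
    variable_spec("Y", "outcome", "binary", c("No", "Yes")),
    variable_spec("Mb", "mediator", "binary", c("No", "Yes"), "need"),
    variable_spec("Mo", "mediator", "ordinal", c("Low", "Mid", "High"),
                  "need"),
    variable_spec("C", "control", "binary", c("A", "B"), "predisposing")
  )
}

toy_dataset <- function(n = 60, seed = 11, weights = NULL,
                        sch = toy_schema()) {
  set.seed(seed)
  rec <- data.frame(
    X = rbinom(n, 1, 0.4),
    Y = rbinom(n, 1, 0.3),
    Mb = rbinom(n, 1, 0.5),
    Mo = sample(0:2, n, replace = TRUE),
    C = rbinom(n, 1, 0.5))
  bgsem_dataset(rec, weights %||% rlnorm(n, 0, 0.3), sch)
}

# schema with an arbitrary number of binary mediators (for decomposition
# oracles)
k_mediator_schema <- function(k) {
  vars <- c(
    list(variable_spec("X", "exposure", "binary", c("No", "Yes")),
         variable_spec("Y", "outcome", "binary", c("No", "Yes"))),
    lapply(seq_len(k), function(i)
      variable_spec(paste0("M", i), "mediator", "binary", c("No", "Yes"))))
  schema(vars)
}

# weighted logistic log-likelihood written out longhand (test-side oracle)
oracle_logistic_ll <- function(beta, X, y, w) {
  eta <- as.vector(X %*% beta)
  sum(w * (y * eta - log(1 + exp(eta))))
}

# independently coded rank-normalized split R-hat (formula oracle)
oracle_rhat <- function(chains) {
  half <- floor(nrow(chains) / 2)
  sp <- cbind(chains[seq_len(half), , drop = FALSE],
              chains[(nrow(chains) - half + 1):nrow(chains), ,
                     drop = FALSE])
  zfun <- function(m) {
    z <- qnorm((rank(m, ties.method = "average") - 0.375) /
                 (length(m) + 0.25))
    matrix(z, nrow(m))
  }
  base <- function(m) {
    nn <- nrow(m)
    W <- mean(apply(m, 2, var))
    B <- nn * var(colMeans(m))
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  }
  base(zfun(sp))
}

expect_no_na <- function(x) expect_false(anyNA(x))
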