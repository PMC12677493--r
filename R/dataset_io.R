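#' Construct a coded dataset
#'
#' A dataset bundles the integer-coded subject records (0-based codes in
#' each variable's declared level order, `NA` for missing cells), one
#' strictly positive survey weight per row (normalized to mean 1), and the
#' schema the codes refer to.
#'
#' @param records data.frame of integer codes, one column per schema
#'   variable, `NA` marking missing cells.
#' @param weight positive numeric vector, one entry per row; normalized to
#'   mean 1 on construction.
#' @param sch a `bgsem_schema`.
#' @param normalize logical; divide weights by their mean (default `TRUE`).
#' @return an object of class `bgsem_dataset`.
#' @export
bgsem_dataset <- function(records, weight = NULL, sch, normalize = TRUE) {
  stopifnot(inherits(sch, "bgsem_schema"))
  records <- as.data.frame(records)
  miss_col <- setdiff(names(sch), names(records))
  if (length(miss_col))
    stop("records missing required column(s): ",
         paste(miss_col, collapse = ", "), call. = FALSE)
  records <- records[names(sch)]
  for (v in names(sch)) {
    x <- records[[v]]
    k <- n_levels(sch, v)
    bad <- which(!is.na(x) & (x < 0 | x >= k | x != floor(x)))
    if (length(bad))
      stop("variable '", v, "' row ", bad[1], ": code ", x[bad[1]],
           " outside 0..", k - 1L, call. = FALSE)
    records[[v]] <- as.integer(x)
  }
  if (is.null(weight)) weight <- rep(1, nrow(records))
  if (length(weight) != nrow(records))
    stop("weight length (", length(weight), ") != row count (",
         nrow(records), ")", call. = FALSE)
  if (nrow(records) > 0) {
    if (any(!is.finite(weight)) || any(weight <= 0))
      stop("weights must be strictly positive and finite", call. = FALSE)
    if (normalize) weight <- normalize_weights(weight)
  }
  structure(list(records = records, weight = as.numeric(weight),
                 schema = sch),
            class = "bgsem_dataset")
}

#' @export
print.bgsem_dataset <- function(x, ...) {
  cat("<bgsem_dataset> ", nrow(x$records), " subjects x ",
      ncol(x$records), " variables; ",
      sum(is.na(x$records)), " missing cells\n", sep = "")
  invisible(x)
}

#' @export
dim.bgsem_dataset <- function(x) dim(x$records)

#' Missingness mask of a dataset
#'
#' @param data a `bgsem_dataset`.
#' @return logical matrix, `TRUE` where a cell is missing.
#' @export
missing_mask <- function(data) {
  stopifnot(inherits(data, "bgsem_dataset"))
  as.matrix(is.na(data$records))
}

#' Normalize survey weights to mean one
#'
#' Divides each weight by the sample mean so that the normalized weights
#' average exactly 1 (sum = n) while relative ratios are preserved; the
#' effective sample size stays on the subject scale. Idempotent.
#'
#' @param weights strictly positive numeric vector.
#' @return numeric vector with mean 1.
#' @export
normalize_weights <- function(weights) {
  if (length(weights) < 1)
    stop("normalize_weights: empty weight vector", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("normalize_weights: weights must be strictly positive and finite",
         call. = FALSE)
  weights / mean(weights)
}

# CSV dialect -----------------------------------------------------------------
# UTF-8, header row, comma delimiter; cells are level labels; missing cells
# are the empty string or "NA". An optional ".weight" column carries the
# survey weight (default 1).

#' Read a labelled CSV into a coded dataset
#'
#' Cells must be level labels from the schema (or empty/"NA" for missing);
#' they are mapped to 0-based integer codes in declared level order. A
#' `.weight` column, if present, supplies survey weights (normalized to
#' mean 1 on load).
#'
#' @param path CSV file path.
#' @param sch a `bgsem_schema`.
#' @return a `bgsem_dataset`.
#' @export
load_dataset <- function(path, sch) {
  stopifnot(inherits(sch, "bgsem_schema"))
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  na.strings = c("", "NA"), fileEncoding = "UTF-8")
  miss_col <- setdiff(names(sch), names(raw))
  if (length(miss_col))
    stop("file '", path, "' missing required column(s): ",
         paste(miss_col, collapse = ", "), call. = FALSE)
  codes <- as.data.frame(lapply(names(sch), function(v) {
    x <- raw[[v]]
    code <- match(x, sch[[v]]$levels) - 1L
    bad <- which(!is.na(x) & is.na(code))
    if (length(bad))
      stop("variable '", v, "' row ", bad[1], ": unknown label '",
           x[bad[1]], "'", call. = FALSE)
    code
  }), col.names = names(sch))
  if (nrow(raw) == 0) codes <- codes[0, , drop = FALSE]
  w <- if (".weight" %in% names(raw)) as.numeric(raw[[".weight"]]) else NULL
  bgsem_dataset(codes, w, sch)
}

#' Write a coded dataset back to the labelled CSV dialect
#'
#' Inverse of [load_dataset()]: codes become level labels, missing cells
#' become empty strings, and the (normalized) weights are stored in a
#' `.weight` column so that a write/load round trip is the identity.
#'
#' @param data a `bgsem_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "bgsem_dataset"))
  sch <- data$schema
  lab <- as.data.frame(lapply(names(sch), function(v) {
    x <- data$records[[v]]
    ifelse(is.na(x), "", sch[[v]]$levels[x + 1L])
  }), col.names = names(sch))
  lab$.weight <- data$weight
  write.csv(lab, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
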