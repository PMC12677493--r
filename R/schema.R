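#' Declare a study variable
#'
#' A variable specification records everything the pipeline needs to know
#' about one column of a subject-level table: its role in the structural
#' system (exposure, mediator, control or outcome), its distributional
#' family (binary or ordinal), its ordered level labels, and the Andersen
#' behavioral-model domain it belongs to (predisposing, enabling or need).
#'
#' Integer codes are 0-based in the declared level order; the first level
#' is the reference category.
#'
#' @param name variable name (syntactic identifier).
#' @param role one of `"exposure"`, `"mediator"`, `"control"`, `"outcome"`.
#' @param family one of `"binary"`, `"ordinal"`.
#' @param levels character vector of ordered category labels; binary
#'   variables must have exactly 2, ordinal variables at least 3.
#' @param andersen_domain one of `"predisposing"`, `"enabling"`, `"need"`,
#'   `"none"`.
#' @return an object of class `bgsem_variable`.
#' @export
variable_spec <- function(name, role, family, levels,
                          andersen_domain = "none") {
  role <- match.arg(role, c("exposure", "mediator", "control", "outcome"))
  family <- match.arg(family, c("binary", "ordinal"))
  andersen_domain <- match.arg(andersen_domain,
                               c("predisposing", "enabling", "need", "none"))
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("'name' must be a single non-empty string", call. = FALSE)
  levels <- as.character(levels)
  if (anyDuplicated(levels))
    stop("duplicate levels for variable '", name, "'", call. = FALSE)
  if (family == "binary" && length(levels) != 2)
    stop("binary variable '", name, "' must have exactly 2 levels",
         call. = FALSE)
  if (family == "ordinal" && length(levels) < 3)
    stop("ordinal variable '", name, "' must have >= 3 ordered levels",
         call. = FALSE)
  structure(list(name = name, role = role, family = family,
                 levels = levels, andersen_domain = andersen_domain),
            class = "bgsem_variable")
}

#' Assemble a variable schema
#'
#' @param ... `bgsem_variable` objects (or a single list of them).
#' @return an object of class `bgsem_schema`: a named list of variable
#'   specifications with exactly one exposure and one outcome.
#' @export
schema <- function(...) {
  vars <- list(...)
  if (length(vars) == 1 && is.list(vars[[1]]) &&
      !inherits(vars[[1]], "bgsem_variable"))
    vars <- vars[[1]]
  if (!all(vapply(vars, inherits, logical(1), "bgsem_variable")))
    stop("all arguments must be variable_spec() objects", call. = FALSE)
  nms <- vapply(vars, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate variable names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  roles <- vapply(vars, `[[`, character(1), "role")
  if (sum(roles == "exposure") != 1)
    stop("schema must contain exactly one exposure variable", call. = FALSE)
  if (sum(roles == "outcome") != 1)
    stop("schema must contain exactly one outcome variable", call. = FALSE)
  names(vars) <- nms
  structure(vars, class = "bgsem_schema")
}

#' @export
print.bgsem_schema <- function(x, ...) {
  cat("<bgsem_schema> ", length(x), " variables\n", sep = "")
  for (v in x)
    cat(sprintf("  %-28s %-8s %-7s [%s] %s\n", v$name, v$role, v$family,
                paste(v$levels, collapse = "/"), v$andersen_domain))
  invisible(x)
}

schema_names_by_role <- function(sch, role) {
  nms <- unname(vapply(sch, `[[`, character(1), "name"))
  nms[vapply(sch, `[[`, character(1), "role") == role]
}

exposure_name <- function(sch) schema_names_by_role(sch, "exposure")
outcome_name <- function(sch) schema_names_by_role(sch, "outcome")
mediator_names <- function(sch) schema_names_by_role(sch, "mediator")
control_names <- function(sch) schema_names_by_role(sch, "control")

n_levels <- function(sch, name) length(sch[[name]]$levels)

#' The CHARLS-style Andersen schema
#'
#' Builds the default 22-variable schema used throughout the package:
#' depressive symptoms (binary exposure, CES-D-10 cutoff coding), inpatient
#' healthcare utilization (binary outcome), eight behavioral/need mediators
#' and twelve socio-demographic controls, each with its Andersen domain and
#' ordered level labels.
#'
#' @return a `bgsem_schema`.
#' @export
charls_schema <- function() {
  schema(
    variable_spec("depressive_symptoms", "exposure", "binary", c("No", "Yes")),
    variable_spec("inpatient", "outcome", "binary", c("No", "Yes")),
    # mediators
    variable_spec("pain", "mediator", "binary", c("No", "Yes"), "need"),
    variable_spec("smoking", "mediator", "binary", c("No", "Yes"),
                  "predisposing"),
    variable_spec("alcohol_use", "mediator", "binary", c("No", "Yes"),
                  "predisposing"),
    variable_spec("disability", "mediator", "binary", c("No", "Yes"), "need"),
    variable_spec("health_status", "mediator", "ordinal",
                  c("Poor", "Neutral", "Good"), "need"),
    variable_spec("satisfaction_health", "mediator", "ordinal",
                  c("Dissatisfied", "Neutral", "Satisfied"), "need"),
    variable_spec("adl", "mediator", "ordinal",
                  c("No limitation", "Mildly limited", "Moderately limited",
                    "Severely limited"), "need"),
    variable_spec("chronic_disease", "mediator", "ordinal",
                  c("None", "Single", "Multiple"), "need"),
    # controls
    variable_spec("gender", "control", "binary", c("Female", "Male"),
                  "predisposing"),
    variable_spec("age", "control", "ordinal", c("60-69", "70-79", ">=80"),
                  "predisposing"),
    variable_spec("marital_status", "control", "binary", c("No", "Yes"),
                  "predisposing"),
    variable_spec("ethnicity", "control", "binary", c("Non-Han", "Han"),
                  "predisposing"),
    variable_spec("residence", "control", "binary", c("Urban", "Rural"),
                  "predisposing"),
    variable_spec("religious_belief", "control", "binary", c("No", "Yes"),
                  "predisposing"),
    variable_spec("work_status", "control", "binary", c("No", "Yes"),
                  "predisposing"),
    variable_spec("education", "control", "ordinal",
                  c("Illiterate", "Primary", "Secondary", "Higher"),
                  "enabling"),
    variable_spec("pension", "control", "binary", c("No", "Yes"), "enabling"),
    variable_spec("satisfaction_healthcare", "control", "ordinal",
                  c("Dissatisfied", "Neutral", "Satisfied"), "enabling"),
    variable_spec("physical_examination", "control", "binary", c("No", "Yes"),
                  "enabling"),
    variable_spec("health_insurance", "control", "binary", c("No", "Yes"),
                  "enabling")
  )
}

#' Read / write a schema as YAML
#'
#' The YAML layout is a list of maps with keys `name`, `role`, `family`,
#' `levels`, `andersen_domain`.
#'
#' @param path file path.
#' @return `read_schema()` returns a `bgsem_schema`; `write_schema()`
#'   returns `path` invisibly.
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.list(y) || length(y) == 0)
    stop("schema YAML must be a non-empty list of variable maps",
         call. = FALSE)
  vars <- lapply(y, function(v) {
    need <- c("name", "role", "family", "levels")
    miss <- setdiff(need, names(v))
    if (length(miss))
      stop("schema YAML entry missing key(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    variable_spec(v$name, v$role, v$family, unlist(v$levels),
                  v$andersen_domain %||% "none")
  })
  schema(vars)
}

#' @rdname read_schema
#' @param sch a `bgsem_schema`.
#' @export
write_schema <- function(sch, path) {
  stopifnot(inherits(sch, "bgsem_schema"))
  y <- lapply(unname(sch), function(v)
    list(name = v$name, role = v$role, family = v$family,
         levels = as.list(v$levels), andersen_domain = v$andersen_domain))
  yaml::write_yaml(y, path)
  invisible(path)
}

# exposure scoring ------------------------------------------------------------

#' Score the CES-D-10 depression scale
#'
#' Sums ten items each rated 0-3 (total range 0-30) and applies the
#' conventional symptom cutoff: a total of 10 or more marks the presence
#' of depressive symptoms.
#'
#' @param items integer vector of exactly 10 item scores, each in 0-3.
#' @return list with `total` (0-30) and `symptomatic` (0/1).
#' @export
score_cesd <- function(items) {
  if (length(items) != 10)
    stop("score_cesd: expected 10 items, got ", length(items), call. = FALSE)
  if (anyNA(items))
    stop("score_cesd: missing item at index ",
         which(is.na(items))[1], call. = FALSE)
  bad <- which(items != as.integer(items) | items < 0 | items > 3)
  if (length(bad))
    stop("score_cesd: item ", bad[1], " (value ", items[bad[1]],
         ") outside 0-3", call. = FALSE)
  total <- as.integer(sum(items))
  list(total = total, symptomatic = as.integer(total >= 10))
}

#' Bin a raw age in years into the study's age categories
#'
#' Half-open intervals [60, 70), [70, 80), [80, Inf) map to the labels
#' `"60-69"`, `"70-79"`, `">=80"`.
#'
#' @param age numeric vector of ages in years (all >= 60).
#' @return integer codes 0/1/2 in the age level order.
#' @export
bin_age <- function(age) {
  if (any(age < 60, na.rm = TRUE))
    stop("bin_age: ages below 60 are outside the study population",
         call. = FALSE)
  code <- ifelse(age < 70, 0L, ifelse(age < 80, 1L, 2L))
  as.integer(code)
}
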