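# Config-driven orchestration of the full analysis: simulate -> impute ->
# fit -> decompose -> diagnose -> report. Each stage writes its artifacts
# and a manifest (inputs, outputs, seed, runtime, package version) under
# the output directory; numeric results live only in files, logging goes
# to stderr.

canonical_stages <- c("simulate", "impute", "fit", "decompose", "diagnose",
                      "report")

#' Read and validate a run configuration
#'
#' @param path YAML file path, or a list already in config shape.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("run config must be a mapping", call. = FALSE)
  cfg$out_dir <- cfg$out_dir %||% "results"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$model <- match.arg(cfg$model %||% "refined",
                         c("refined", "comprehensive"))
  cfg$profile <- match.arg(cfg$profile %||% "test", c("test", "paper"))
  cfg$n <- as.integer(cfg$n %||% 4000L)
  cfg$stages <- cfg$stages %||% canonical_stages
  unknown <- setdiff(cfg$stages, canonical_stages)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg$stages <- canonical_stages[canonical_stages %in% cfg$stages]
  cfg$missing_rate <- cfg$missing_rate %||% 0.05
  cfg$m_imputations <- as.integer(cfg$m_imputations %||% 5L)
  cfg$maxit <- as.integer(cfg$maxit %||% 10L)
  cfg$prior_preset <- cfg$prior_preset %||% "default"
  cfg
}

pipeline_log <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

write_manifest <- function(out_dir, stage, inputs, outputs, seed, t0,
                           status = "ok") {
  yaml::write_yaml(
    list(stage = stage, status = status, inputs = as.list(inputs),
         outputs = as.list(outputs), seed = seed,
         runtime_sec = round(as.numeric(Sys.time()) - t0, 2),
         package_version = as.character(utils::packageVersion("bgsem"))),
    file.path(out_dir, paste0("manifest_", stage, ".yaml")))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order. Later stages read the
#' artifacts written by earlier ones, so any suffix of the pipeline can be
#' re-run against an existing output directory; re-running with the same
#' config reproduces all numeric outputs.
#'
#' @param config a YAML path or config list; see [read_run_config()].
#'   Keys: `out_dir`, `seed`, `model` (refined/comprehensive), `profile`
#'   (test/paper), `n`, `stages`, `missing_rate`, `m_imputations`,
#'   `maxit`, `prior_preset`, optional `mcmc` overrides (chains, iter,
#'   warmup).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  sch <- charls_schema()
  spec <- if (cfg$model == "refined") refined_spec(sch)
          else comprehensive_spec(sch)
  mc_args <- cfg$mcmc %||% list()
  mcmc <- mcmc_config(
    chains = mc_args$chains %||% if (cfg$profile == "test") 2 else 4,
    iter = mc_args$iter %||% if (cfg$profile == "test") 1500 else 10000,
    warmup = mc_args$warmup %||% if (cfg$profile == "test") 750 else 5000,
    seed = cfg$seed)
  state <- list()
  pth <- function(...) file.path(cfg$out_dir, ...)

  run_stage <- function(stage, inputs, outputs, fun) {
    t0 <- as.numeric(Sys.time())
    pipeline_log("stage ", stage, " started")
    ok <- tryCatch({ fun(); TRUE }, error = function(e) e)
    if (!isTRUE(ok)) {
      write_manifest(cfg$out_dir, stage, inputs, outputs, cfg$seed, t0,
                     status = paste("failed:", conditionMessage(ok)))
      stop("stage '", stage, "' failed: ", conditionMessage(ok),
           call. = FALSE)
    }
    write_manifest(cfg$out_dir, stage, inputs, outputs, cfg$seed, t0)
    pipeline_log("stage ", stage, " done")
  }

  stage_funs <- list(
    simulate = function() {
      syn_cfg <- synthetic_config(cfg$model, n = cfg$n,
                                  missing = default_missing_config(
                                    cfg$missing_rate))
      gen <- generate_dataset(syn_cfg, cfg$seed)
      inj <- inject_missingness(gen$data, syn_cfg$missing, cfg$seed)
      write_dataset(inj$data, pth("dataset.csv"))
      write_dataset(inj$ground_truth, pth("ground_truth.csv"))
      write.csv(gen$truth, pth("truth.csv"), row.names = FALSE)
      state$data <<- inj$data
    },
    impute = function() {
      data <- state$data %||% load_dataset(pth("dataset.csv"), sch)
      rep <- missingness_report(data)
      mr <- rep$variables
      mr$mcar_statistic <- rep$mcar_statistic
      mr$mcar_df <- rep$mcar_df
      mr$mcar_p <- rep$mcar_p
      write.csv(mr, pth("missingness_report.csv"), row.names = FALSE)
      imp <- mice_impute(data, m = cfg$m_imputations, maxit = cfg$maxit,
                         seed = cfg$seed)
      for (k in seq_along(imp$completed))
        write_dataset(imp$completed[[k]],
                      pth(sprintf("completed_%d.csv", k)))
      write.csv(imputation_diagnostics(imp, data),
                pth("imputation_diagnostics.csv"), row.names = FALSE)
      write.csv(agvif(imp$completed[[1]]), pth("agvif.csv"),
                row.names = FALSE)
      state$completed <<- imp$completed
    },
    fit = function() {
      data <- if (!is.null(state$completed)) state$completed[[1]]
        else if (file.exists(pth("completed_1.csv")))
          load_dataset(pth("completed_1.csv"), sch)
        else load_dataset(pth("dataset.csv"), sch)
      model <- build_model(spec, prior_config(cfg$prior_preset))
      dr <- fit(model, data, mcmc)
      write.csv(draws_long(dr), pth("draws.csv"), row.names = FALSE)
      state$fit_data <<- data
      state$draws <<- dr
    },
    decompose = function() {
      dr <- state$draws %||%
        stop("fit artifacts not in memory; run the fit stage in the same ",
             "call")
      dec <- decompose(dr)
      write.csv(summarize_paths(dec), pth("paths.csv"), row.names = FALSE)
      write.csv(dec$summary, pth("decomposition.csv"), row.names = FALSE)
      write.csv(path_edges(dec, exposure = spec$exposure,
                           outcome = spec$outcome),
                pth("path_edges.csv"), row.names = FALSE)
      state$decomposition <<- dec
    },
    diagnose = function() {
      dr <- state$draws %||%
        stop("fit artifacts not in memory; run the fit stage in the same ",
             "call")
      diag <- diagnostics_report(dr, state$fit_data)
      write.csv(diag$parameters, pth("diagnostics_parameters.csv"),
                row.names = FALSE)
      write.csv(data.frame(waic = diag$waic, p_waic = diag$p_waic,
                           looic = diag$looic,
                           max_pareto_k = max(diag$pareto_k)),
                pth("diagnostics_model.csv"), row.names = FALSE)
      state$diagnostics <<- diag
    },
    report = function() {
      vr <- verify_paper_arithmetic(path_table("refined"))
      vc <- verify_paper_arithmetic(path_table("comprehensive"))
      write.csv(vr, pth("verification_refined.csv"), row.names = FALSE)
      write.csv(vc, pth("verification_comprehensive.csv"),
                row.names = FALSE)
      pm <- data.frame(
        model = c("refined", "comprehensive"),
        proportion_mediated = c(
          vr$computed[grepl("proportion", vr$check)],
          vc$computed[grepl("proportion", vc$check)]))
      if (!is.null(state$decomposition))
        pm <- rbind(pm, data.frame(
          model = paste0("synthetic_", cfg$model),
          proportion_mediated = round_half_up(
            state$decomposition$proportion_mediated)))
      write.csv(pm, pth("proportion_mediated.csv"), row.names = FALSE)
      state$verification <<- list(refined = vr, comprehensive = vc)
    })
  stage_io <- list(
    simulate = list(character(),
                    c("dataset.csv", "ground_truth.csv", "truth.csv")),
    impute = list("dataset.csv",
                  c("missingness_report.csv", "agvif.csv",
                    "imputation_diagnostics.csv")),
    fit = list("completed_1.csv", "draws.csv"),
    decompose = list("draws.csv",
                     c("paths.csv", "path_edges.csv",
                       "decomposition.csv")),
    diagnose = list("draws.csv",
                    c("diagnostics_parameters.csv",
                      "diagnostics_model.csv")),
    report = list(character(),
                  c("verification_refined.csv",
                    "verification_comprehensive.csv",
                    "proportion_mediated.csv")))
  for (stage in cfg$stages)
    run_stage(stage, stage_io[[stage]][[1]], stage_io[[stage]][[2]],
              stage_funs[[stage]])
  invisible(state)
}
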