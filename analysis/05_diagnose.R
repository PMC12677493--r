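#!/usr/bin/env Rscript
# Convergence and fit evaluation (split R-hat, bulk/tail ESS, WAIC,
# PSIS-LOO with Pareto k) plus the prior/specification sensitivity run:
# refined vs comprehensive specification under default and diffuse priors.

source("analysis/00_config.R")

data <- load_dataset(out_path("completed_1.csv"), charls_schema())
model <- build_model(refined_spec(), prior_config())
draws <- fit(model, data, MCMC)

diag <- diagnostics_report(draws, data)
write.csv(diag$parameters, out_path("convergence.csv"), row.names = FALSE)
write.csv(data.frame(waic = diag$waic, p_waic = diag$p_waic,
                     looic = diag$looic,
                     max_pareto_k = max(diag$pareto_k)),
          out_path("fit_criteria.csv"), row.names = FALSE)
cat(sprintf("WAIC %.2f, LOOIC %.2f, max Pareto k %.3f\n",
            diag$waic, diag$looic, max(diag$pareto_k)))
cat(sprintf("parameters with R-hat > 1.01: %d; Pareto k > 0.7: %d\n",
            length(diag$flags$rhat_above_1.01),
            length(diag$flags$pareto_k_above_0.7)))

sens <- sensitivity_run(
  specs = list(refined = refined_spec(),
               comprehensive = comprehensive_spec()),
  priors = list(default = prior_config(),
                diffuse = prior_config("diffuse")),
  data = data, mcmc = MCMC)
write.csv(sens$cells, out_path("sensitivity_cells.csv"), row.names = FALSE)
if (!is.null(sens$flags))
  write.csv(sens$flags, out_path("sensitivity_flags.csv"),
            row.names = FALSE)
print(sens)
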