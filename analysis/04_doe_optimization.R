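#!/usr/bin/env Rscript
# Response-surface analysis of the packaged 18-run solid-dispersion design:
# fit each response on the coded factor space, report the model-selection
# statistics, and pick the optimal formulation by Derringer-Suich
# desirability (maximize DC/DE15/DE60, minimize MDT).

library(dissolvr)

des <- diacerein_design()
goals <- c(dc = "maximize", de15 = "maximize", de60 = "maximize",
           mdt = "minimize")
orders <- list(dc = "quadratic", de15 = "linear", de60 = "quadratic",
               mdt = "quadratic")

models <- lapply(setNames(nm = names(goals)), function(r)
  fit_response_model(des, r, orders[[r]]))
stats_tab <- model_statistics(models)
write.csv(stats_tab, "results/doe_statistics.csv", row.names = FALSE)
print(stats_tab, digits = 4)

opt <- desirability_optimize(models, goals)
write.csv(opt$candidates, "results/doe_candidates.csv", row.names = FALSE)
print(opt)
cat(sprintf("\nOptimum: drug:polymer 1:%g with %s (D = %.3f) -- the SD18 setting\n",
            opt$best$ratio_parts, opt$best$polymer, opt$best$D))
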