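#!/usr/bin/env Rscript
# Compare the group-effect model against the pooled model by DIC, probe
# covariate models, and run the posterior predictive check with
# loess-smoothed group profiles. Run analysis/01_simulate_cohort.R first.

library(amclear)

seed <- 20180314L
ds <- read_cohort("results/cohort")
dir.create("results/model_selection", showWarnings = FALSE, recursive = TRUE)

fits <- list(
  group = fit_hierarchical_model(
    build_design(ds, kinetic_model_spec()),
    mcmc = mcmc_config(seed = seed)),
  pooled = fit_hierarchical_model(
    build_design(ds, kinetic_model_spec(group_effect = FALSE)),
    mcmc = mcmc_config(seed = seed)),
  group_age = fit_hierarchical_model(
    build_design(ds, kinetic_model_spec(covariates = "age")),
    mcmc = mcmc_config(seed = seed)))

cmp <- compare_models(fits)
write.csv(cmp$table, "results/model_selection/comparison.csv",
          row.names = FALSE)
print(cmp$table, digits = 5)
d <- cmp$deltas
cat(sprintf("delta DIC (pooled - group): %.2f\n",
            d$delta_dic[d$model_a == "pooled" & d$model_b == "group"]))

# age effects should straddle zero (no covariate effect was simulated)
age_ci <- apply(fits$group_age$draws[, c("beta_age_r", "beta_age_k")], 2,
                quantile, c(0.025, 0.975))
cat("age-effect 95% CrIs (R0, k):",
    sprintf("(%.3f, %.3f)", age_ci[1, ], age_ci[2, ]), "\n")

ppc <- posterior_predictive_check(fits$group, n_replicates = 200,
                                  seed = seed)
jsonlite::write_json(
  list(coverage = ppc$coverage, per_group = as.list(ppc$per_group),
       n_replicates = ppc$n_replicates, span = ppc$span),
  "results/model_selection/ppc.json", auto_unbox = TRUE, digits = NA)
cat(sprintf("PPC: observed smooth inside 95%% envelope at %.0f%% of grid points\n",
            100 * ppc$coverage))

# observed-vs-envelope profiles per group
png("results/model_selection/ppc_profiles.png", width = 1200, height = 420)
op <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
for (grp in unique(ppc$profiles$group)) {
  p <- ppc$profiles[ppc$profiles$group == grp, ]
  plot(p$t, p$observed, type = "n", ylim = range(p[, c("lower", "upper", "observed")]),
       xlab = "days since time origin", ylab = "median AM BC (um^2)",
       main = grp)
  polygon(c(p$t, rev(p$t)), c(p$lower, rev(p$upper)),
          col = "#9ecae180", border = NA)
  lines(p$t, p$observed, col = "red", lwd = 2)
}
par(op); dev.off()
cat("wrote results/model_selection\n")
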