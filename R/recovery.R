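#' Parameter-recovery and model-comparison simulation study
#'
#' Replicates the panel design end to end: for each replicate a synthetic
#' cohort is generated at the configured group-level ground truth, the
#' group-effect and pooled hierarchical decay models are fitted, and the
#' study records (i) the posterior mean, SD and 95% credible interval of each
#' group's R0 and k together with whether the interval covers the truth, and
#' (ii) the DIC of both models.
#'
#' @param n_replicates Number of simulated cohorts.
#' @param seed Master seed; each replicate derives its own generator and
#'   sampler seeds from it.
#' @param config Cohort generator configuration (its `group_params` are the
#'   ground truth).
#' @param spec Model spec for the group-effect model; the pooled model is the
#'   same spec with `group_effect = FALSE`.
#' @param mcmc MCMC settings applied to every fit (the per-fit seed is
#'   derived from `seed` and the replicate index).
#' @param fit_pooled Also fit the pooled model for DIC comparison.
#' @return List of class `amclear_recovery`: `estimates` (one row per
#'   replicate x group x parameter: estimate, sd, CrI, truth, covered),
#'   `dic` (one row per replicate: group/pooled DIC and their difference),
#'   `truth`, `n_replicates`.
#' @export
recovery_study <- function(n_replicates = 20L, seed = 1L,
                           config = cohort_config(),
                           spec = kinetic_model_spec(),
                           mcmc = mcmc_config(n_iter = 4000L),
                           fit_pooled = TRUE) {
  truth <- config$group_params
  est <- list(); dic <- list()
  for (r in seq_len(n_replicates)) {
    rs <- as.integer((as.numeric(seed) * 1009 + r) %% 2147483647)
    ds <- generate_cohort(config, seed = rs)
    mc <- mcmc; mc$seed <- rs
    des_g <- build_design(ds, spec)
    fit_g <- fit_hierarchical_model(des_g, mcmc = mc)
    # convergence is recorded per replicate below rather than warned per fit
    g <- suppressWarnings(summarize_groups(fit_g))
    g <- merge(g, truth[, c("group", "R0", "k")], by = "group")
    est[[r]] <- data.frame(
      replicate = r,
      group = rep(g$group, 2),
      parameter = rep(c("R0", "k"), each = nrow(g)),
      truth = c(g$R0, g$k),
      estimate = c(g$r0_mean, g$k_mean),
      post_sd = c(g$r0_sd, g$k_sd),
      lower = c(g$r0_lower, g$k_lower),
      upper = c(g$r0_upper, g$k_upper),
      stringsAsFactors = FALSE)
    est[[r]]$covered <- est[[r]]$lower <= est[[r]]$truth &
      est[[r]]$truth <= est[[r]]$upper
    est[[r]]$converged <- fit_g$converged
    if (fit_pooled) {
      spec_p <- spec; spec_p$group_effect <- FALSE
      des_p <- build_design(ds, spec_p)
      fit_p <- fit_hierarchical_model(des_p, mcmc = mc)
      cmp <- compare_models(list(group = fit_g, pooled = fit_p))
      dic[[r]] <- data.frame(
        replicate = r,
        dic_group = cmp$table$dic[cmp$table$model == "group"],
        dic_pooled = cmp$table$dic[cmp$table$model == "pooled"],
        group_wins = cmp$table$model[1] == "group",
        converged_group = fit_g$converged,
        converged_pooled = fit_p$converged)
    }
  }
  structure(list(estimates = do.call(rbind, est),
                 dic = if (fit_pooled) do.call(rbind, dic),
                 truth = truth, n_replicates = n_replicates),
            class = "amclear_recovery")
}

#' Summarise a recovery study per group-level parameter
#'
#' For each group x parameter: mean bias of the posterior mean across
#' replicates, the average posterior SD, the bias-to-SD ratio, and the
#' fraction of replicates whose 95% credible interval covers the truth.
#'
#' @param study An `amclear_recovery`.
#' @return Data frame, one row per group x parameter.
#' @export
summarize_recovery <- function(study) {
  e <- study$estimates
  key <- interaction(e$group, e$parameter, drop = TRUE)
  out <- lapply(split(e, key), function(d) {
    data.frame(group = d$group[1], parameter = d$parameter[1],
               truth = d$truth[1],
               mean_estimate = mean(d$estimate),
               bias = mean(d$estimate) - d$truth[1],
               mean_post_sd = mean(d$post_sd),
               bias_over_sd = abs(mean(d$estimate) - d$truth[1]) /
                 mean(d$post_sd),
               coverage = mean(d$covered),
               n = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$parameter, out$group), ]
}
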