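test_that("design assigns time origins and anchors residents at T1", {
  # full attendance so the first observation is the first scheduled visit
  ds <- generate_cohort(cohort_config(seed = 2, induction_success = 1,
                                      dropout_hazard = 0))
  des <- build_design(ds, kinetic_model_spec())

  # residents: origin at first visit, anchored, T1 row consumed by the anchor
  be_ids <- ds$subjects$subject_id[ds$subjects$group == "BE"]
  expect_true(all(des$subjects$anchored[des$subjects$group == "BE"]))
  expect_false(any(des$subjects$anchored[des$subjects$group != "BE"]))
  for (id in intersect(be_ids, des$subjects$subject_id)) {
    raw <- ds$observations[ds$observations$subject_id == id, ]
    kept <- des$obs[des$obs$subject_id == id, ]
    expect_equal(nrow(kept), nrow(raw) - 1L)
    anchor <- des$subjects$log_r0_anchor[des$subjects$subject_id == id]
    expect_equal(anchor, log(raw$median_bc_um2[which.min(raw$t_days)]))
    expect_true(all(kept$t > 0))
  }

  # newcomers: first observation at the arrival latency, R0 refers to day 0
  lmic <- des$obs[des$obs$group == "LMIC", ]
  first_t <- tapply(lmic$t, lmic$subject_id, min)
  lat <- ds$subjects$latency_days[match(names(first_t),
                                        ds$subjects$subject_id)]
  expect_equal(as.numeric(first_t), as.numeric(lat))

  # under "estimated", nothing is anchored and no rows are consumed
  des2 <- build_design(ds, kinetic_model_spec(resident_r0_rule = "estimated"))
  expect_false(any(des2$subjects$anchored))
  expect_equal(nrow(des2$obs), nrow(ds$observations))
})

test_that("subjects without valid slides are dropped with a logged reason", {
  ds <- generate_cohort(cohort_config(seed = 4))
  victim <- ds$subjects$subject_id[1]
  ds$observations <- ds$observations[ds$observations$subject_id != victim, ]
  des <- build_design(ds, kinetic_model_spec())
  expect_true(victim %in% des$dropped$subject_id)
  expect_equal(des$dropped$reason[des$dropped$subject_id == victim],
               "no valid slides")
  expect_false(victim %in% des$subjects$subject_id)
})

test_that("zero outcomes are offset with a warning", {
  ds <- generate_cohort(cohort_config(seed = 5))
  ds$observations$median_bc_um2[3] <- 0
  ds$observations$p90_bc_um2[3] <- max(ds$observations$p90_bc_um2[3], 0)
  expect_warning(des <- build_design(ds, kinetic_model_spec()),
                 "offsetting")
  expect_true(all(des$obs$y > 0))
})

test_that("reduced-model posterior matches dense grid integration", {
  # one subject, two free parameters (log R0, k), known noise scale: the
  # MCMC posterior must agree with brute-force quadrature of the
  # unnormalised posterior on a fine grid
  set.seed(99)
  t_obs <- seq(0, 294, by = 42)
  sigma <- 0.3
  y <- exp(log(0.9 * exp(-0.012 * t_obs)) + rnorm(length(t_obs), 0, sigma))
  ds <- list(
    subjects = data.frame(subject_id = "S1", group = "LMIC",
                          latency_days = 0L, stringsAsFactors = FALSE),
    observations = data.frame(subject_id = "S1",
                              visit_index = seq_along(t_obs),
                              t_days = t_obs, median_bc_um2 = y,
                              p90_bc_um2 = y, n_cells = 25L,
                              stringsAsFactors = FALSE))
  spec <- kinetic_model_spec(
    group_effect = FALSE, resident_r0_rule = "estimated",
    priors = list(sigma_y_fixed = sigma, sigma_r_fixed = 0,
                  sigma_k_fixed = 0, logR0_loc = 0, logR0_scale = 2,
                  k_loc = 0, k_scale = 0.05))
  fit <- fit_hierarchical_model(build_design(ds, spec),
                                mcmc = mcmc_config(n_chains = 4,
                                                   n_iter = 4000, seed = 12))

  # independent oracle: 2D grid quadrature
  lr0_grid <- seq(log(0.9) - 1, log(0.9) + 1, length.out = 400)
  k_grid <- seq(-0.02, 0.05, length.out = 400)
  ly <- log(y)
  logpost <- outer(lr0_grid, k_grid, function(lr0, k) {
    ll <- 0
    for (j in seq_along(t_obs)) {
      ll <- ll + dnorm(ly[j], lr0 - k * t_obs[j], sigma, log = TRUE)
    }
    ll + dnorm(lr0, 0, 2, log = TRUE) + dnorm(k, 0, 0.05, log = TRUE)
  })
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  lr0_mean <- sum(rowSums(w) * lr0_grid)
  k_mean <- sum(colSums(w) * k_grid)
  lr0_sd <- sqrt(sum(rowSums(w) * (lr0_grid - lr0_mean)^2))
  k_sd <- sqrt(sum(colSums(w) * (k_grid - k_mean)^2))

  mc <- fit$draws
  expect_lt(abs(mean(mc[, "logR0g[1]"]) - lr0_mean), 0.1 * lr0_sd)
  expect_lt(abs(mean(mc[, "kg[1]"]) - k_mean), 0.1 * k_sd)
  expect_lt(abs(sd(mc[, "logR0g[1]"]) - lr0_sd), 0.1 * lr0_sd)
  expect_lt(abs(sd(mc[, "kg[1]"]) - k_sd), 0.1 * k_sd)
  # central interval endpoints from the grid CDF
  cdf_k <- cumsum(colSums(w))
  k_q <- approx(cdf_k, k_grid, c(0.025, 0.975), ties = "ordered")$y
  expect_lt(max(abs(unname(quantile(mc[, "kg[1]"], c(0.025, 0.975))) - k_q)),
            0.15 * k_sd)
})

test_that("near-noiseless single-group data recover truth tightly", {
  cfg <- noiseless_config(R0 = 1.0, k = 0.01, n = 4L, n_visits = 8L)
  ds <- generate_cohort(cfg)
  spec <- kinetic_model_spec(
    group_effect = FALSE, resident_r0_rule = "estimated",
    priors = list(sigma_y_fixed = 0.02, sigma_r_fixed = 0,
                  sigma_k_fixed = 0))
  fit <- fit_hierarchical_model(build_design(ds, spec),
                                mcmc = quick_mcmc(3))
  r0_hat <- mean(exp(fit$draws[, "logR0g[1]"]))
  k_hat <- mean(fit$draws[, "kg[1]"])
  expect_lt(abs(r0_hat - 1.0), 0.01)
  expect_lt(abs(k_hat - 0.01), 1e-4)
  # credible interval width shrinks with the noise scale
  expect_lt(diff(quantile(fit$draws[, "kg[1]"], c(0.025, 0.975))), 5e-4)
})

test_that("a flat series yields a k interval containing zero", {
  cfg <- cohort_config(
    group_params = data.frame(group = "LMIC", n = 8L, R0 = 0.5, k = 0,
                              latency_min = 1L, latency_max = 19L),
    sigma_k = 0, seed = 21)
  ds <- generate_cohort(cfg)
  fit <- fit_hierarchical_model(
    build_design(ds, kinetic_model_spec(group_effect = FALSE)),
    mcmc = quick_mcmc(4))
  kq <- quantile(fit$draws[, "kg[1]"], c(0.025, 0.975))
  expect_lt(kq[1], 0)
  expect_gt(kq[2], 0)
})

test_that("growth (negative k) is estimated with the right sign", {
  cfg <- cohort_config(
    group_params = data.frame(group = "HIC", n = 12L, R0 = 0.26, k = -0.004,
                              latency_min = 2L, latency_max = 23L),
    sigma_k = 0.001, seed = 22)
  ds <- generate_cohort(cfg)
  fit <- fit_hierarchical_model(
    build_design(ds, kinetic_model_spec(group_effect = FALSE)),
    mcmc = quick_mcmc(5))
  expect_lt(mean(fit$draws[, "kg[1]"]), 0)
  g <- suppressWarnings(summarize_groups(fit))
  expect_identical(g$half_life_days, Inf)
  expect_gt(g$pr_k_nonpos, 0.5)
})

test_that("fits are reproducible for identical data, spec and seed", {
  ds <- generate_cohort(cohort_config(seed = 6))
  des <- build_design(ds, kinetic_model_spec())
  mc <- mcmc_config(n_chains = 2, n_adapt = 200, n_burnin = 100,
                    n_iter = 200, seed = 77)
  f1 <- fit_hierarchical_model(des, mcmc = mc)
  f2 <- fit_hierarchical_model(des, mcmc = mc)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_hierarchical_model(des, mcmc = mcmc_config(
    n_chains = 2, n_adapt = 200, n_burnin = 100, n_iter = 200, seed = 78))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("group summaries expose posterior mean, SD, CrI and half-life", {
  ds <- generate_cohort(cohort_config(seed = 8))
  fit <- fit_hierarchical_model(build_design(ds, kinetic_model_spec()),
                                mcmc = quick_mcmc(9))
  g <- suppressWarnings(summarize_groups(fit))
  expect_setequal(g$group, c("LMIC", "HIC", "BE"))
  expect_true(all(g$r0_lower < g$r0_mean & g$r0_mean < g$r0_upper))
  expect_true(all(g$k_lower <= g$k_upper))
  lmic <- g[g$group == "LMIC", ]
  # half-life CrI is the monotone transform of the k CrI
  expect_equal(lmic$half_life_lower, log(2) / lmic$k_upper)
  expect_equal(lmic$half_life_upper, log(2) / lmic$k_lower)
  expect_equal(lmic$half_life_days, log(2) / lmic$k_mean)
})

test_that("model and MCMC settings load from YAML", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.yaml")
  writeLines(c("model:",
               "  group_effect: false",
               "  outcome: p90",
               "  covariates: [age]",
               "  priors:",
               "    k_scale: 0.1",
               "mcmc:",
               "  n_chains: 2",
               "  n_iter: 500",
               "  seed: 9"), path)
  cfg <- read_model_config(path)
  expect_false(cfg$spec$group_effect)
  expect_equal(cfg$spec$outcome, "p90")
  expect_equal(cfg$spec$covariates, "age")
  expect_equal(cfg$spec$priors$k_scale, 0.1)
  expect_equal(cfg$spec$priors$logR0_scale, 2) # untouched default
  expect_equal(cfg$mcmc$n_chains, 2L)
  expect_equal(cfg$mcmc$seed, 9L)
})

test_that("fit outputs serialize to summary, draws and metadata", {
  ds <- generate_cohort(cohort_config(seed = 10))
  fit <- fit_hierarchical_model(build_design(ds, kinetic_model_spec()),
                                mcmc = mcmc_config(n_chains = 2,
                                                   n_adapt = 200,
                                                   n_burnin = 100,
                                                   n_iter = 200, seed = 1))
  dir <- withr::local_tempdir()
  write_fit(fit, dir)
  summ <- read.csv(file.path(dir, "posterior_summary.csv"))
  expect_true(all(c("parameter", "mean", "sd", "q2.5", "q97.5",
                    "rhat", "ess") %in% names(summ)))
  meta <- jsonlite::read_json(file.path(dir, "fit_meta.json"))
  expect_equal(meta$fingerprint, fit$fingerprint)
})
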