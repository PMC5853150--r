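#' Specification of the hierarchical decay model
#'
#' Describes one candidate model for the panel of slide summaries: whether
#' group-level kinetics are shared or per-group, which subject/visit
#' covariates enter, the observation noise model, how resident subjects'
#' initial values are handled, which outcome is modelled, and the prior
#' scales.
#'
#' The model is a Bayesian hierarchical single-exponential decay: observation
#' j of subject i has expected value \eqn{R_{0i} e^{-k_i t_{ij}}} with
#' multiplicative log-normal noise; subject-level \eqn{\log R_{0i}} and
#' \eqn{k_i} are drawn around group-level means. Under
#' `resident_r0_rule = "fixed_to_T1"` the subject-level \eqn{\log R_{0i}} of
#' residents is fixed to their first (T1) observation, which then informs the
#' group mean through the hierarchy instead of entering the observation
#' likelihood.
#'
#' @param group_effect If `TRUE`, separate R0 and k per group; if `FALSE`, a
#'   single shared pair (the pooled model).
#' @param covariates Character subset of `c("sex", "age", "season")`. Sex and
#'   age act additively on the subject-level log R0 and k means; season (a
#'   4-level meteorological factor of the visit date) acts on the observation
#'   log-mean.
#' @param noise_model `"lognormal_on_value"` (default) or `"normal_on_log"`.
#'   The two give the same posterior; they differ in the deviance scale used
#'   for DIC (with vs without the log-normal Jacobian), so only fits sharing a
#'   noise model are comparable.
#' @param resident_r0_rule `"fixed_to_T1"` (default) or `"estimated"`.
#' @param outcome `"median"` or `"p90"` slide summary.
#' @param priors Named list overriding any of the default prior settings:
#'   `logR0_loc`, `logR0_scale` (normal prior on group log R0),
#'   `k_loc`, `k_scale` (normal prior on group k), `sigma_y_scale`,
#'   `sigma_r_scale`, `sigma_k_scale` (half-normal SD priors), `beta_scale`
#'   (normal prior on covariate effects), and the degenerate options
#'   `sigma_y_fixed`, `sigma_r_fixed`, `sigma_k_fixed` (fix a scale to a
#'   known value; fixing a hierarchy scale to 0 pins subject parameters to
#'   the group mean — the reduced model used for oracle checks).
#' @return A list of class `amclear_model_spec`.
#' @export
kinetic_model_spec <- function(group_effect = TRUE,
                               covariates = character(),
                               noise_model = c("lognormal_on_value",
                                               "normal_on_log"),
                               resident_r0_rule = c("fixed_to_T1",
                                                    "estimated"),
                               outcome = c("median", "p90"),
                               priors = list()) {
  noise_model <- match.arg(noise_model)
  resident_r0_rule <- match.arg(resident_r0_rule)
  outcome <- match.arg(outcome)
  covariates <- unique(covariates)
  if (!all(covariates %in% c("sex", "age", "season"))) {
    stop("covariates must be a subset of sex, age, season", call. = FALSE)
  }
  pr <- list(logR0_loc = 0, logR0_scale = 2,
             k_loc = 0, k_scale = 0.05,
             sigma_y_scale = 1, sigma_r_scale = 1, sigma_k_scale = 0.01,
             beta_scale = 1,
             sigma_y_fixed = NULL, sigma_r_fixed = NULL,
             sigma_k_fixed = NULL)
  unknown <- setdiff(names(priors), names(pr))
  if (length(unknown)) stop("unknown prior settings: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  pr[names(priors)] <- priors
  structure(list(group_effect = isTRUE(group_effect),
                 covariates = covariates,
                 noise_model = noise_model,
                 resident_r0_rule = resident_r0_rule,
                 outcome = outcome,
                 priors = pr),
            class = "amclear_model_spec")
}

#' Read a model spec and MCMC settings from a YAML file
#'
#' The file may contain a `model` block (arguments of
#' [kinetic_model_spec()], with `priors` as a nested map) and an `mcmc`
#' block (arguments of [mcmc_config()]).
#'
#' @param path YAML file path.
#' @return List with elements `spec` and `mcmc`.
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  spec <- do.call(kinetic_model_spec, as.list(raw$model))
  mcmc <- do.call(mcmc_config, as.list(raw$mcmc))
  list(spec = spec, mcmc = mcmc)
}

#' MCMC settings
#'
#' @param n_chains Number of chains (each gets its own RNG stream derived
#'   from `seed`).
#' @param n_adapt Adaptation iterations.
#' @param n_burnin Burn-in iterations discarded after adaptation.
#' @param n_iter Kept iterations per chain.
#' @param thin Thinning interval.
#' @param seed Integer seed controlling all chains.
#' @return A list of class `amclear_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_adapt = 500L, n_burnin = 1000L,
                        n_iter = 5000L, thin = 1L, seed = 1L) {
  structure(list(n_chains = as.integer(n_chains),
                 n_adapt = as.integer(n_adapt),
                 n_burnin = as.integer(n_burnin),
                 n_iter = as.integer(n_iter),
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "amclear_mcmc_config")
}

#' Build the model-ready observation table from a cohort dataset
#'
#' Assigns each subject's time origin (arrival day for newcomers, first visit
#' for residents), selects the outcome column, anchors resident initial
#' values to the T1 observation when the model spec asks for it, encodes
#' covariates, and drops subjects without usable slides (with a logged
#' reason). Outcome values of exactly 0 are offset by half the smallest
#' non-zero outcome (log-normal support excludes 0) with a warning.
#'
#' @param dataset An `amclear_cohort` (or any list with `subjects` and
#'   `observations` data frames in the same schema).
#' @param spec A [kinetic_model_spec()].
#' @return A list of class `amclear_design`: `obs` (likelihood rows:
#'   `subject_id`, `subj`, `group`, `grp`, `t`, `y`, covariate columns),
#'   `subjects` (per-subject: `subject_id`, `grp`, `anchored`,
#'   `log_r0_anchor`), `groups` (level names), `dropped` (subject ids and
#'   reasons), and the spec.
#' @export
build_design <- function(dataset, spec = kinetic_model_spec()) {
  obs <- dataset$observations
  sub <- dataset$subjects
  stopifnot(is.data.frame(obs), is.data.frame(sub))
  outcome_col <- if (spec$outcome == "median") "median_bc_um2" else
    "p90_bc_um2"
  obs <- obs[!is.na(obs[[outcome_col]]), , drop = FALSE]
  if ("n_cells" %in% names(obs)) {
    obs <- obs[obs$n_cells >= 25L | is.na(obs$n_cells), , drop = FALSE]
  }

  have <- intersect(sub$subject_id, unique(obs$subject_id))
  gone <- setdiff(sub$subject_id, have)
  dropped <- data.frame(subject_id = gone,
                        reason = rep("no valid slides", length(gone)),
                        stringsAsFactors = FALSE)
  sub <- sub[sub$subject_id %in% have, , drop = FALSE]
  obs <- obs[obs$subject_id %in% have, , drop = FALSE]
  if (!nrow(obs)) stop("no usable observations", call. = FALSE)

  groups <- if (spec$group_effect) {
    gl <- unique(sub$group)
    gl[order(match(gl, c("LMIC", "HIC", "BE")))]
  } else "all"
  sub$grp <- if (spec$group_effect) match(sub$group, groups) else 1L

  y <- obs[[outcome_col]]
  if (any(y == 0)) {
    off <- min(y[y > 0]) / 2
    warning("offsetting ", sum(y == 0), " zero outcome(s) by ", signif(off, 3),
            " (half the smallest nonzero value)", call. = FALSE)
    y[y == 0] <- off
  }
  obs$y <- y
  obs <- obs[order(match(obs$subject_id, sub$subject_id), obs$t_days), ,
             drop = FALSE]
  obs$subj <- match(obs$subject_id, sub$subject_id)
  obs$grp <- sub$grp[obs$subj]
  obs$group <- sub$group[obs$subj]

  # resident anchoring: the first (earliest) observation of each resident is
  # consumed as the subject's fixed log R0 and removed from the likelihood
  sub$anchored <- FALSE
  sub$log_r0_anchor <- NA_real_
  if (spec$resident_r0_rule == "fixed_to_T1" && "group" %in% names(sub)) {
    drop_rows <- integer(0)
    for (i in which(sub$group == "BE")) {
      rows <- which(obs$subj == i)
      first <- rows[which.min(obs$t_days[rows])]
      sub$anchored[i] <- TRUE
      sub$log_r0_anchor[i] <- log(obs$y[first])
      # shift so the anchor sits at the subject's time origin
      obs$t_days[rows] <- obs$t_days[rows] - obs$t_days[first]
      drop_rows <- c(drop_rows, first)
    }
    if (length(drop_rows)) obs <- obs[-drop_rows, , drop = FALSE]
  }

  des_obs <- data.frame(subject_id = obs$subject_id, subj = obs$subj,
                        group = obs$group, grp = obs$grp,
                        t = obs$t_days, y = obs$y,
                        stringsAsFactors = FALSE)
  if ("season" %in% spec$covariates) {
    if (!"season" %in% names(obs)) {
      # derive a 4-level season from the visit day within a nominal year
      doy <- (obs$t_days %% 365.25)
      des_obs$season <- 1L + ((doy %/% 91.3125) %% 4L)
    } else des_obs$season <- as.integer(factor(obs$season))
  }
  if ("sex" %in% spec$covariates) {
    sub$x_sex <- as.numeric(factor(sub$sex)) - 1
  }
  if ("age" %in% spec$covariates) {
    sub$x_age <- as.numeric(scale(sub$age_years))
  }

  structure(list(obs = des_obs,
                 subjects = sub[, intersect(c("subject_id", "group", "grp",
                                              "anchored", "log_r0_anchor",
                                              "x_sex", "x_age"), names(sub)),
                                drop = FALSE],
                 groups = groups, dropped = dropped, spec = spec),
            class = "amclear_design")
}

# short fingerprint identifying the data a design was built from, used to
# refuse DIC comparisons across different data
design_fingerprint <- function(design) {
  o <- design$obs
  sprintf("n%d_s%d_y%.6e_t%.6e_%s_%s",
          nrow(o), nrow(design$subjects), sum(o$y), sum(o$t),
          design$spec$outcome, design$spec$noise_model)
}

# assemble the JAGS model string for a design + spec
build_jags_model <- function(design) {
  spec <- design$spec
  pr <- spec$priors
  covs <- spec$covariates
  sub_terms_r <- character(0)
  sub_terms_k <- character(0)
  if ("sex" %in% covs) {
    sub_terms_r <- c(sub_terms_r, "beta_sex_r * x_sex[s]")
    sub_terms_k <- c(sub_terms_k, "beta_sex_k * x_sex[s]")
  }
  if ("age" %in% covs) {
    sub_terms_r <- c(sub_terms_r, "beta_age_r * x_age[s]")
    sub_terms_k <- c(sub_terms_k, "beta_age_k * x_age[s]")
  }
  mu_r <- paste(c("logR0g[grp[s]]", sub_terms_r), collapse = " + ")
  mu_k <- paste(c("kg[grp[s]]", sub_terms_k), collapse = " + ")
  seas <- if ("season" %in% covs) " + seas_eff[season[i]]" else ""

  lik <- paste0(
    "  for (i in 1:N) {\n",
    "    logmu[i] <- logR0s[subj[i]] - ks[subj[i]] * t[i]", seas, "\n",
    "    y[i] ~ dlnorm(logmu[i], tau_y)\n",
    "  }\n")

  # hierarchy scales are per group under the group-effect model: the
  # resident anchor adds measurement noise to that group's subject-level
  # values, so dispersions are not exchangeable across groups.
  # Latent subject effects are non-centred (z-scores scaled by the group
  # sigma) for sampler mixing; anchored residents stay centred because
  # their values are observed hierarchy nodes.
  fixed_r <- !is.null(pr$sigma_r_fixed) && pr$sigma_r_fixed == 0
  fixed_k <- !is.null(pr$sigma_k_fixed) && pr$sigma_k_fixed == 0
  n_anch <- sum(design$subjects$anchored)
  n_est <- sum(!design$subjects$anchored)

  hier <- paste0("  for (s in 1:S) {\n",
                 "    muR[s] <- ", mu_r, "\n",
                 "    muK[s] <- ", mu_k, "\n",
                 "  }\n")
  if (fixed_r) {
    hier <- paste0(hier, "  for (s in 1:S) { logR0s[s] <- muR[s] }\n")
  } else {
    if (n_est > 0) {
      hier <- paste0(hier,
        "  for (e in 1:n_est) {\n",
        "    zr[e] ~ dnorm(0, 1)\n",
        "    logR0s[est_idx[e]] <- muR[est_idx[e]] +",
        " sigma_r[grp[est_idx[e]]] * zr[e]\n",
        "  }\n")
    }
    if (n_anch > 0) {
      hier <- paste0(hier,
        "  for (a in 1:n_anch) {\n",
        "    logR0anch[a] ~ dnorm(muR[anch_idx[a]],",
        " tau_r[grp[anch_idx[a]]])\n",
        "    logR0s[anch_idx[a]] <- logR0anch[a]\n",
        "  }\n")
    }
  }
  if (fixed_k) {
    hier <- paste0(hier, "  for (s in 1:S) { ks[s] <- muK[s] }\n")
  } else {
    hier <- paste0(hier,
      "  for (s in 1:S) {\n",
      "    zk[s] ~ dnorm(0, 1)\n",
      "    ks[s] <- muK[s] + sigma_k[grp[s]] * zk[s]\n",
      "  }\n")
  }

  grp <- paste0(
    "  for (g in 1:G) {\n",
    "    logR0g[g] ~ dnorm(", pr$logR0_loc, ", ",
    1 / pr$logR0_scale^2, ")\n",
    "    kg[g] ~ dnorm(", pr$k_loc, ", ", 1 / pr$k_scale^2, ")\n",
    "    R0g[g] <- exp(logR0g[g])\n",
    "  }\n")

  sigma_y_block <- if (!is.null(pr$sigma_y_fixed)) {
    paste0("  sigma_y <- ", pr$sigma_y_fixed, "\n",
           "  tau_y <- ", 1 / pr$sigma_y_fixed^2, "\n")
  } else {
    paste0("  sigma_y ~ dnorm(0, ", 1 / pr$sigma_y_scale^2, ") T(0,)\n",
           "  tau_y <- pow(sigma_y, -2)\n")
  }
  group_scale_block <- function(name, fixed, scale) {
    tau <- paste0("tau_", sub("sigma_", "", name))
    if (!is.null(fixed)) {
      if (fixed == 0) return("")  # handled structurally above
      paste0("  for (g in 1:G) {\n",
             "    ", name, "[g] <- ", fixed, "\n",
             "    ", tau, "[g] <- ", 1 / fixed^2, "\n  }\n")
    } else {
      paste0("  for (g in 1:G) {\n",
             "    ", name, "[g] ~ dnorm(0, ", 1 / scale^2, ") T(0,)\n",
             "    ", tau, "[g] <- pow(", name, "[g], -2)\n  }\n")
    }
  }
  scales <- paste0(
    sigma_y_block,
    group_scale_block("sigma_r", pr$sigma_r_fixed, pr$sigma_r_scale),
    group_scale_block("sigma_k", pr$sigma_k_fixed, pr$sigma_k_scale))

  betas <- character(0)
  bprec <- 1 / pr$beta_scale^2
  if ("sex" %in% covs) betas <- c(betas,
    paste0("  beta_sex_r ~ dnorm(0, ", bprec, ")\n",
           "  beta_sex_k ~ dnorm(0, ", bprec, ")\n"))
  if ("age" %in% covs) betas <- c(betas,
    paste0("  beta_age_r ~ dnorm(0, ", bprec, ")\n",
           "  beta_age_k ~ dnorm(0, ", bprec, ")\n"))
  if ("season" %in% covs) betas <- c(betas,
    paste0("  seas_eff[1] <- 0\n",
           "  for (q in 2:4) { seas_eff[q] ~ dnorm(0, ", bprec, ") }\n"))

  paste0("model {\n", lik, hier, grp, scales,
         paste(betas, collapse = ""), "}\n")
}

#' Fit the Bayesian hierarchical single-exponential decay model
#'
#' Runs MCMC (Gibbs/Metropolis via JAGS) on the model described by the
#' design's [kinetic_model_spec()]: group-level initial quantity R0 (um^2)
#' and decay constant k (1/day, unconstrained in sign), subject-level
#' deviations, and a log-normal observation noise scale. Anchored residents'
#' log R0 values enter as observed hierarchy nodes. The observation-level
#' deviance is evaluated in R for every kept draw (the basis for DIC).
#'
#' Convergence is assessed by split-chain potential scale reduction
#' (threshold 1.05) and effective sample size (threshold 400) on every
#' reported parameter; a failing fit is returned but carries
#' `converged = FALSE` and downstream summaries warn.
#'
#' @param design An [build_design()] result (or a cohort dataset, which is
#'   passed through `build_design` with `spec`).
#' @param spec Model spec, only used when `design` is a cohort dataset.
#' @param mcmc An [mcmc_config()].
#' @return A list of class `amclear_fit`: `draws` (combined draw matrix),
#'   `mcmc_list` (coda object), `summary` (per-parameter mean, sd, q2.5,
#'   q97.5, rhat, ess), `deviance` (per-draw vector), `dev_at_mean`,
#'   `converged`, `design`, `spec`, `mcmc`, `fingerprint`.
#' @export
fit_hierarchical_model <- function(design, spec = kinetic_model_spec(),
                                   mcmc = mcmc_config()) {
  if (inherits(design, "amclear_cohort") ||
      (!inherits(design, "amclear_design") && !is.null(design$observations))) {
    design <- build_design(design, spec)
  }
  spec <- design$spec
  o <- design$obs
  s <- design$subjects
  if (nrow(o) < 2L) stop("need at least 2 observations", call. = FALSE)

  G <- if (spec$group_effect) length(design$groups) else 1L
  dat <- list(N = nrow(o), S = nrow(s), G = G,
              y = o$y, t = o$t, subj = o$subj, grp = s$grp)
  pr <- spec$priors
  fixed_r <- !is.null(pr$sigma_r_fixed) && pr$sigma_r_fixed == 0
  fixed_k <- !is.null(pr$sigma_k_fixed) && pr$sigma_k_fixed == 0
  if (fixed_r && any(s$anchored)) {
    stop("sigma_r_fixed = 0 (degenerate hierarchy) is incompatible with ",
         "anchored residents; use resident_r0_rule = 'estimated'",
         call. = FALSE)
  }
  if (!fixed_r) {
    est <- which(!s$anchored)
    anch <- which(s$anchored)
    if (length(est)) {
      dat$n_est <- length(est)
      dat$est_idx <- as.array(est)
    }
    if (length(anch)) {
      dat$n_anch <- length(anch)
      dat$anch_idx <- as.array(anch)
      dat$logR0anch <- as.array(s$log_r0_anchor[anch])
    }
  }
  if ("sex" %in% spec$covariates) dat$x_sex <- s$x_sex
  if ("age" %in% spec$covariates) dat$x_age <- s$x_age
  if ("season" %in% spec$covariates) dat$season <- o$season

  model_str <- build_jags_model(design)
  inits <- lapply(seq_len(mcmc$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((as.numeric(mcmc$seed) * 97 + ch) %%
                                  2147483646) + 1L)
  })
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          inits = inits, n.chains = mcmc$n_chains,
                          n.adapt = mcmc$n_adapt, quiet = TRUE)
  if (mcmc$n_burnin > 0) {
    stats::update(jm, n.iter = mcmc$n_burnin, progress.bar = "none")
  }
  monitors <- c("logR0g", "kg", "R0g", "logR0s", "ks", "sigma_y")
  if (is.null(pr$sigma_r_fixed)) monitors <- c(monitors, "sigma_r")
  if (is.null(pr$sigma_k_fixed)) monitors <- c(monitors, "sigma_k")
  if ("sex" %in% spec$covariates) {
    monitors <- c(monitors, "beta_sex_r", "beta_sex_k")
  }
  if ("age" %in% spec$covariates) {
    monitors <- c(monitors, "beta_age_r", "beta_age_k")
  }
  if ("season" %in% spec$covariates) monitors <- c(monitors, "seas_eff")
  ml <- rjags::coda.samples(jm, variable.names = monitors,
                            n.iter = mcmc$n_iter * mcmc$thin,
                            thin = mcmc$thin, progress.bar = "none")
  # coda drops the [1] index on length-one vectors; restore it so indexing
  # is uniform downstream
  fix_names <- function(nm) {
    vec_vars <- c("logR0g", "kg", "R0g", "logR0s", "ks", "sigma_r", "sigma_k")
    ifelse(nm %in% vec_vars, paste0(nm, "[1]"), nm)
  }
  for (ch in seq_along(ml)) {
    colnames(ml[[ch]]) <- fix_names(colnames(ml[[ch]]))
  }
  draws <- do.call(rbind, lapply(ml, as.matrix))

  # deviance of the observation likelihood per draw
  dev <- observation_deviance(draws, design)
  theta_hat <- colMeans(draws)
  dev_hat <- observation_deviance(rbind(theta_hat), design)

  # diagnostics on reported (group-level + scale + covariate) parameters
  report <- grep("^(logR0g|kg|R0g|sigma_|beta_|seas_eff)", colnames(draws),
                 value = TRUE)
  report <- report[apply(draws[, report, drop = FALSE], 2,
                         function(v) stats::var(v) > 0)]
  rhat <- vapply(report, function(p) {
    split_rhat(lapply(ml, function(ch) as.numeric(ch[, p])))
  }, numeric(1))
  ess <- vapply(report, function(p) {
    sum(vapply(ml, function(ch) {
      as.numeric(coda::effectiveSize(ch[, p]))
    }, numeric(1)))
  }, numeric(1))

  qs <- t(apply(draws, 2, stats::quantile, c(0.025, 0.975), names = FALSE))
  summ <- data.frame(parameter = colnames(draws),
                     mean = colMeans(draws),
                     sd = apply(draws, 2, stats::sd),
                     q2.5 = qs[, 1], q97.5 = qs[, 2],
                     rhat = rhat[match(colnames(draws), report)],
                     ess = ess[match(colnames(draws), report)],
                     row.names = NULL, stringsAsFactors = FALSE)
  converged <- all(rhat < 1.05) && all(ess > 400)

  structure(list(draws = draws, mcmc_list = ml, summary = summ,
                 deviance = dev, dev_at_mean = dev_hat,
                 converged = converged,
                 design = design, spec = spec, mcmc = mcmc,
                 fingerprint = design_fingerprint(design)),
            class = "amclear_fit")
}

# deviance of the observation likelihood at each draw (rows of `draws`);
# constants included, so absolute values match the declared noise model
observation_deviance <- function(draws, design) {
  o <- design$obs
  n_draw <- nrow(draws)
  logmu <- posterior_logmu(draws, design)
  sigma <- if ("sigma_y" %in% colnames(draws)) draws[, "sigma_y"] else
    design$spec$priors$sigma_y_fixed
  ly <- matrix(log(o$y), n_draw, nrow(o), byrow = TRUE)
  ll <- stats::dnorm(ly, logmu, sigma, log = TRUE)
  if (design$spec$noise_model == "lognormal_on_value") ll <- ll - ly # Jacobian
  -2 * rowSums(ll)
}

# split-chain potential scale reduction factor; chains is a list of equal
# length numeric vectors
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Group-level kinetic summaries with clearance half-lives
#'
#' Extracts per-group posterior summaries of R0 (um^2) and k (1/day) from a
#' fit and derives the clearance half-life ln(2)/k. The half-life point
#' estimate uses the posterior mean of k; its credible interval is the
#' monotone transform of the k interval (ln 2 / upper, ln 2 / lower). When a
#' group's k interval reaches 0 or below, the half-life upper bound is `Inf`
#' and the posterior mass of k at or below 0 is reported.
#'
#' @param fit An `amclear_fit`.
#' @return Data frame, one row per group: R0/k posterior mean, sd, 95%
#'   credible bounds, `half_life_days`, `half_life_lower`,
#'   `half_life_upper`, `pr_k_nonpos`.
#' @export
summarize_groups <- function(fit) {
  stopifnot(inherits(fit, "amclear_fit"))
  if (!fit$converged) {
    warning("fit did not pass convergence thresholds; summaries may be ",
            "unreliable", call. = FALSE)
  }
  groups <- fit$design$groups
  out <- lapply(seq_along(groups), function(g) {
    r0 <- exp(fit$draws[, paste0("logR0g[", g, "]")])
    k <- fit$draws[, paste0("kg[", g, "]")]
    kq <- stats::quantile(k, c(0.025, 0.975), names = FALSE)
    hl <- half_life_interval(kq[1], kq[2])
    data.frame(group = groups[g],
               r0_mean = mean(r0), r0_sd = stats::sd(r0),
               r0_lower = stats::quantile(r0, 0.025, names = FALSE),
               r0_upper = stats::quantile(r0, 0.975, names = FALSE),
               k_mean = mean(k), k_sd = stats::sd(k),
               k_lower = kq[1], k_upper = kq[2],
               half_life_days = half_life(mean(k)),
               half_life_lower = hl[["lower"]],
               half_life_upper = hl[["upper"]],
               pr_k_nonpos = mean(k <= 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a fit's outputs to a directory
#'
#' Posterior summary CSV, draws CSV and a metadata JSON (spec, MCMC
#' settings, fingerprint, convergence flag).
#'
#' @param fit An `amclear_fit`.
#' @param dir Output directory, created if missing.
#' @return Invisibly, `dir`.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$summary, file.path(dir, "posterior_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fit$draws), file.path(dir, "draws.csv"),
                   row.names = FALSE)
  meta <- list(spec = unclass(fit$spec), mcmc = unclass(fit$mcmc),
               fingerprint = fit$fingerprint, converged = fit$converged,
               groups = fit$design$groups)
  meta$spec$priors <- Filter(Negate(is.null), meta$spec$priors)
  jsonlite::write_json(meta, file.path(dir, "fit_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
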