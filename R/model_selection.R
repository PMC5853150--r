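#' Deviance Information Criterion of a fit
#'
#' Computes the DIC components from the per-draw observation deviance:
#' \eqn{\bar D} (mean posterior deviance), \eqn{D(\hat\theta)} (deviance at
#' the posterior mean of each parameter on its sampling scale),
#' \eqn{p_D = \bar D - D(\hat\theta)} and
#' \eqn{DIC = \bar D + p_D = D(\hat\theta) + 2 p_D}. With a continuous
#' likelihood the deviance — and hence the DIC — can be negative; only
#' differences between models fitted to the same data are meaningful.
#'
#' @param fit An `amclear_fit`.
#' @return List with `dic`, `d_bar`, `d_hat`, `p_d`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "amclear_fit"))
  if (is.null(fit$deviance) || !length(fit$deviance)) {
    stop("fit carries no deviance trace", call. = FALSE)
  }
  d_bar <- mean(fit$deviance)
  d_hat <- fit$dev_at_mean
  p_d <- d_bar - d_hat
  list(dic = d_bar + p_d, d_bar = d_bar, d_hat = d_hat, p_d = p_d)
}

#' Compare fitted models by DIC
#'
#' Tabulates DIC components for a named list of fits on identical data and
#' reports all pairwise DIC differences. No winner is declared beyond the
#' lower-DIC ordering: DIC differences are read as relative evidence only.
#'
#' @param fits Named list of `amclear_fit` objects sharing one data
#'   fingerprint (same observations, outcome and noise model).
#' @return List of class `amclear_comparison`: `table` (one row per model,
#'   sorted by DIC) and `deltas` (data frame `model_a`, `model_b`,
#'   `delta_dic` = DIC_a - DIC_b for all ordered pairs).
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  fps <- vapply(fits, function(f) f$fingerprint, character(1))
  if (length(unique(fps)) > 1L) {
    stop("fits were made on differing data (fingerprints: ",
         paste(unique(fps), collapse = " vs "), "); comparison refused",
         call. = FALSE)
  }
  comps <- lapply(fits, compute_dic)
  tab <- data.frame(model = names(fits),
                    dic = vapply(comps, `[[`, numeric(1), "dic"),
                    d_bar = vapply(comps, `[[`, numeric(1), "d_bar"),
                    d_hat = vapply(comps, `[[`, numeric(1), "d_hat"),
                    p_d = vapply(comps, `[[`, numeric(1), "p_d"),
                    converged = vapply(fits, `[[`, logical(1), "converged"),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$dic), , drop = FALSE]
  deltas <- if (nrow(tab) > 1L) {
    pairs <- expand.grid(model_a = tab$model, model_b = tab$model,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$model_a != pairs$model_b, , drop = FALSE]
    pairs$delta_dic <- tab$dic[match(pairs$model_a, tab$model)] -
      tab$dic[match(pairs$model_b, tab$model)]
    rownames(pairs) <- NULL
    pairs
  } else {
    data.frame(model_a = character(0), model_b = character(0),
               delta_dic = numeric(0))
  }
  structure(list(table = tab, deltas = deltas), class = "amclear_comparison")
}

#' DIC difference between two values
#'
#' Convenience for the printed-arithmetic form `DIC_a - DIC_b`; e.g. the
#' pooled-vs-group pair (-43.6, -202.91) gives 159.31.
#'
#' @param dic_a,dic_b DIC values.
#' @return `dic_a - dic_b`.
#' @export
delta_dic <- function(dic_a, dic_b) dic_a - dic_b

#' Posterior predictive check with loess-smoothed group profiles
#'
#' Draws replicate datasets from the posterior predictive distribution at the
#' observed design points, smooths the observed and each replicate's
#' per-group time profile with local linear regression (tricube weights,
#' `stats::loess`), and reports the central 95% replicate envelope on a time
#' grid together with the fraction of grid points at which the observed
#' smooth lies inside the envelope.
#'
#' @param fit An `amclear_fit`.
#' @param n_replicates Number of posterior predictive replicates (draws are
#'   taken evenly spaced through the chain); fewer than 50 triggers a
#'   warning.
#' @param seed Seed for the predictive noise.
#' @param span Loess span (fraction of points in each local fit).
#' @param grid_n Grid points per group.
#' @return List of class `amclear_ppc`: `profiles` (per group and grid
#'   point: observed smooth, envelope `lower`/`upper`, `inside`),
#'   `coverage` (overall fraction of grid points inside), `per_group`
#'   coverage, `n_replicates`, `span`.
#' @export
posterior_predictive_check <- function(fit, n_replicates = 200L, seed = 1L,
                                       span = 0.75, grid_n = 40L) {
  stopifnot(inherits(fit, "amclear_fit"))
  if (n_replicates < 50L) {
    warning("fewer than 50 posterior predictive replicates; envelope ",
            "quantiles will be noisy", call. = FALSE)
  }
  o <- fit$design$obs
  set.seed(seed)
  idx <- unique(round(seq(1, nrow(fit$draws), length.out = n_replicates)))
  logmu <- posterior_logmu(fit$draws[idx, , drop = FALSE], fit$design)
  sigma <- if ("sigma_y" %in% colnames(fit$draws)) {
    fit$draws[idx, "sigma_y"]
  } else rep(fit$spec$priors$sigma_y_fixed, length(idx))

  smooth_one <- function(t, y, grid) {
    if (length(unique(t)) < 4L) return(rep(mean(y), length(grid)))
    fitl <- suppressWarnings(
      stats::loess(y ~ t, span = span, degree = 1,
                   family = "gaussian",
                   control = stats::loess.control(surface = "direct")))
    as.numeric(stats::predict(fitl, data.frame(t = grid)))
  }

  groups <- unique(o$group)
  profiles <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    rows <- which(o$group == groups[gi])
    tg <- o$t[rows]
    grid <- seq(min(tg), max(tg), length.out = grid_n)
    obs_smooth <- smooth_one(tg, o$y[rows], grid)
    rep_smooth <- matrix(NA_real_, length(idx), grid_n)
    for (r in seq_along(idx)) {
      yrep <- stats::rlnorm(length(rows), logmu[r, rows], sigma[r])
      rep_smooth[r, ] <- smooth_one(tg, yrep, grid)
    }
    env <- apply(rep_smooth, 2, stats::quantile, c(0.025, 0.975),
                 names = FALSE)
    profiles[[gi]] <- data.frame(group = groups[gi], t = grid,
                                 observed = obs_smooth,
                                 lower = env[1, ], upper = env[2, ],
                                 inside = obs_smooth >= env[1, ] &
                                   obs_smooth <= env[2, ],
                                 stringsAsFactors = FALSE)
  }
  profiles <- do.call(rbind, profiles)
  per_group <- tapply(profiles$inside, profiles$group, mean)
  structure(list(profiles = profiles,
                 coverage = mean(profiles$inside),
                 per_group = per_group,
                 n_replicates = length(idx), span = span),
            class = "amclear_ppc")
}

# posterior log-mean of every observation for the given draws
posterior_logmu <- function(draws, design) {
  o <- design$obs
  s <- design$subjects
  n_draw <- nrow(draws)
  S <- nrow(s)
  cols_lr <- paste0("logR0s[", seq_len(S), "]")
  LR0 <- if (any(cols_lr %in% colnames(draws))) {
    m <- matrix(NA_real_, n_draw, S)
    found <- cols_lr %in% colnames(draws)
    m[, found] <- draws[, cols_lr[found], drop = FALSE]
    for (j in which(s$anchored)) {
      if (all(is.na(m[, j]))) m[, j] <- s$log_r0_anchor[j]
    }
    m
  } else draws[, paste0("logR0g[", s$grp, "]"), drop = FALSE]
  cols_k <- paste0("ks[", seq_len(S), "]")
  KS <- if (any(cols_k %in% colnames(draws))) {
    draws[, cols_k, drop = FALSE]
  } else draws[, paste0("kg[", s$grp, "]"), drop = FALSE]
  # note: subject-level draws already include any sex/age covariate terms
  # (they are built from the covariate-adjusted subject means in the model);
  # only the observation-level season effect is added here
  logmu <- LR0[, o$subj, drop = FALSE] -
    KS[, o$subj, drop = FALSE] * rep(o$t, each = n_draw)
  if ("season" %in% design$spec$covariates) {
    seff <- matrix(0, n_draw, 4)
    for (q in 2:4) {
      cn <- paste0("seas_eff[", q, "]")
      if (cn %in% colnames(draws)) seff[, q] <- draws[, cn]
    }
    logmu <- logmu + seff[, o$season, drop = FALSE]
  }
  logmu
}
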