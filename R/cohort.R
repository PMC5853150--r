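#' Configuration for the synthetic panel cohort generator
#'
#' Builds the parameter list consumed by [generate_cohort()]. Defaults emulate
#' the longitudinal panel design the kinetics model was developed for: three
#' exposure groups of 15 healthy young subjects each — newcomers from highly
#' polluted cities in low- and middle-income countries (LMIC), newcomers from
#' high-income countries (HIC), and long-term Belgian residents (BE) — each
#' followed over 8 visits about 6 weeks apart, with sputum induction succeeding
#' on 85% of visits and 25 macrophages measured per successful slide.
#'
#' Group-level ground-truth kinetics default to the fitted median AM BC values
#' (LMIC R0 = 1.122 um^2, k = 0.013/day; HIC 0.387, 0.002; BE 0.275, -0.001).
#' Newcomer latency between arrival and the first visit is drawn uniformly on
#' the observed ranges (LMIC 1-19 days, HIC 2-23 days); residents have zero
#' latency by definition.
#'
#' @param group_params Data frame with one row per group and columns `group`,
#'   `n`, `R0` (um^2), `k` (1/day), `latency_min`, `latency_max` (days).
#' @param sigma_log_r0 Subject-level SD of log R0 around the group mean.
#' @param sigma_k Subject-level SD of k around the group mean (1/day).
#' @param sigma_obs Slide-level lognormal noise SD (log scale) multiplying the
#'   subject's decay curve on each visit.
#' @param sigma_cell Per-cell lognormal SD (log scale) of carbon area around
#'   the slide-level value; controls how far the 90th percentile sits above
#'   the median.
#' @param cells_per_slide Macrophages measured per successful slide.
#' @param n_visits Scheduled visits per subject.
#' @param visit_interval_days Days between consecutive visits.
#' @param visit_jitter_days Uniform jitter (+/- days) on each visit date.
#' @param induction_success Probability a visit yields an adequate sputum
#'   sample.
#' @param dropout_hazard Per-visit probability of monotone dropout, applied
#'   from the fifth visit on so every subject attends at least 4 visits.
#' @param zero_mass Point mass at exactly 0 for per-cell areas (cells without
#'   visible inclusions).
#' @param keep_cells Keep the per-cell area table in the returned dataset.
#' @param seed Integer seed recorded in the config and used by
#'   [generate_cohort()].
#' @return A list of class `amclear_cohort_config`.
#' @export
cohort_config <- function(group_params = default_group_params(),
                          sigma_log_r0 = 0.3,
                          sigma_k = 0.002,
                          sigma_obs = 0.25,
                          sigma_cell = 1.3,
                          cells_per_slide = 25L,
                          n_visits = 8L,
                          visit_interval_days = 42,
                          visit_jitter_days = 0,
                          induction_success = 0.85,
                          dropout_hazard = 0.02,
                          zero_mass = 0,
                          keep_cells = FALSE,
                          seed = 1L) {
  need <- c("group", "n", "R0", "k", "latency_min", "latency_max")
  if (!all(need %in% names(group_params))) {
    stop("group_params must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  scales <- c(sigma_log_r0 = sigma_log_r0, sigma_k = sigma_k,
              sigma_obs = sigma_obs, sigma_cell = sigma_cell)
  if (any(scales < 0)) stop("dispersion scales must be >= 0", call. = FALSE)
  if (any(group_params$R0 <= 0)) stop("group R0 must be > 0", call. = FALSE)
  if (induction_success <= 0 || induction_success > 1) {
    stop("induction_success must be in (0, 1]", call. = FALSE)
  }
  if (dropout_hazard < 0 || dropout_hazard >= 1) {
    stop("dropout_hazard must be in [0, 1)", call. = FALSE)
  }
  if (zero_mass < 0 || zero_mass >= 1) {
    stop("zero_mass must be in [0, 1)", call. = FALSE)
  }
  if (cells_per_slide < 1) stop("cells_per_slide must be >= 1", call. = FALSE)
  cfg <- list(group_params = group_params,
              sigma_log_r0 = sigma_log_r0, sigma_k = sigma_k,
              sigma_obs = sigma_obs, sigma_cell = sigma_cell,
              cells_per_slide = as.integer(cells_per_slide),
              n_visits = as.integer(n_visits),
              visit_interval_days = visit_interval_days,
              visit_jitter_days = visit_jitter_days,
              induction_success = induction_success,
              dropout_hazard = dropout_hazard,
              zero_mass = zero_mass,
              keep_cells = isTRUE(keep_cells),
              seed = as.integer(seed))
  class(cfg) <- "amclear_cohort_config"
  cfg
}

#' Default group-level ground truth for the cohort generator
#'
#' Median AM BC kinetics per exposure group: initial quantity `R0` (um^2),
#' decay constant `k` (1/day) and the range of newcomer latency (days between
#' arrival and first visit).
#'
#' @return Data frame with one row per group (LMIC, HIC, BE).
#' @export
default_group_params <- function() {
  data.frame(
    group = c("LMIC", "HIC", "BE"),
    n = c(15L, 15L, 15L),
    R0 = c(1.122, 0.387, 0.275),
    k = c(0.013, 0.002, -0.001),
    latency_min = c(1L, 2L, 0L),
    latency_max = c(19L, 23L, 0L),
    stringsAsFactors = FALSE
  )
}

# subgroup labels mirroring the secondary analyses: 7/8 native/foreign-born
# residents, 11/4 moderately/low-exposed HIC newcomers
.assign_subgroups <- function(group, n) {
  if (group == "BE") {
    n_native <- round(n * 7 / 15)
    c(rep("BEnative", n_native), rep("BEforeign", n - n_native))
  } else if (group == "HIC") {
    n_mod <- round(n * 11 / 15)
    c(rep("HICmoderate", n_mod), rep("HIClow", n - n_mod))
  } else {
    rep("none", n)
  }
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates a panel dataset with the statistical structure the decay model
#' assumes: subject-level kinetic parameters drawn around group means
#' (log-normal for R0, normal for k), visit times on a fixed grid offset by
#' newcomer latency, Bernoulli induction success per visit, optional monotone
#' dropout, and right-skewed (log-normal) per-cell carbon areas whose
#' population median follows the subject's decay curve. Slide summaries record
#' the sample median and 90th percentile of the per-cell areas.
#'
#' Time origin: newcomers (LMIC, HIC) have t = 0 on the arrival day, so their
#' first visit falls at `latency_days`; residents (BE) have t = 0 at the first
#' visit.
#'
#' @param config A [cohort_config()] list.
#' @param seed Overrides `config$seed` if given.
#' @return A list of class `amclear_cohort` with elements `subjects`,
#'   `observations`, optionally `cells`, and `provenance` (config, seed, and
#'   attended-visit count used to audit the induction success rate).
#' @examples
#' ds <- generate_cohort(cohort_config(seed = 7))
#' head(ds$observations)
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  if (!inherits(config, "amclear_cohort_config")) {
    stop("config must come from cohort_config()", call. = FALSE)
  }
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  gp <- config$group_params

  subjects <- do.call(rbind, lapply(seq_len(nrow(gp)), function(g) {
    n <- gp$n[g]
    grp <- gp$group[g]
    latency <- if (grp == "BE") rep(0L, n) else {
      as.integer(round(stats::runif(n, gp$latency_min[g] - 0.5,
                                    gp$latency_max[g] + 0.5)))
    }
    latency <- pmin(pmax(latency, gp$latency_min[g]), gp$latency_max[g])
    data.frame(
      subject_id = sprintf("%s%02d", grp, seq_len(n)),
      group = grp,
      subgroup = .assign_subgroups(grp, n),
      sex = sample(c("F", "M"), n, replace = TRUE),
      age_years = round(stats::rnorm(n, mean = 26.5, sd = 4.5), 1),
      latency_days = latency,
      prior_pm10 = signif(exp(stats::rnorm(
        n, mean = log(if (grp == "LMIC") 100 else 23), sd = 0.3)), 3),
      true_r0 = exp(stats::rnorm(n, log(gp$R0[g]), config$sigma_log_r0)),
      true_k = stats::rnorm(n, gp$k[g], config$sigma_k),
      stringsAsFactors = FALSE
    )
  }))
  subjects$age_years <- pmax(subjects$age_years, 18)
  rownames(subjects) <- NULL

  obs_list <- vector("list", nrow(subjects))
  cell_list <- if (config$keep_cells) vector("list", nrow(subjects)) else NULL
  n_attended_total <- 0L
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    # monotone dropout: at-risk from visit 5 so everyone attends >= 4 visits
    n_att <- config$n_visits
    if (config$dropout_hazard > 0 && config$n_visits > 4L) {
      for (v in 5L:config$n_visits) {
        if (stats::runif(1) < config$dropout_hazard) { n_att <- v - 1L; break }
      }
    }
    n_attended_total <- n_attended_total + n_att
    visits <- seq_len(n_att)
    t_days <- s$latency_days + (visits - 1L) * config$visit_interval_days
    if (config$visit_jitter_days > 0) {
      jit <- stats::runif(n_att, -config$visit_jitter_days,
                          config$visit_jitter_days)
      jit[1] <- max(jit[1], -s$latency_days) # keep t >= 0
      t_days <- t_days + jit
      t_days <- cummax(t_days) + (seq_len(n_att) - 1L) * 1e-9
    }
    success <- stats::runif(n_att) < config$induction_success
    if (!any(success)) next
    ok <- which(success)
    mu <- s$true_r0 * exp(-s$true_k * t_days[ok]) *
      exp(stats::rnorm(length(ok), 0, config$sigma_obs))
    rows <- lapply(seq_along(ok), function(j) {
      areas <- exp(stats::rnorm(config$cells_per_slide, log(mu[j]),
                                config$sigma_cell))
      if (config$zero_mass > 0) {
        areas[stats::runif(config$cells_per_slide) < config$zero_mass] <- 0
      }
      qs <- stats::quantile(areas, c(0.5, 0.9), type = 7, names = FALSE)
      list(obs = data.frame(subject_id = s$subject_id,
                            visit_index = ok[j],
                            t_days = t_days[ok[j]],
                            median_bc_um2 = qs[1],
                            p90_bc_um2 = qs[2],
                            n_cells = config$cells_per_slide,
                            stringsAsFactors = FALSE),
           cells = if (config$keep_cells) {
             data.frame(subject_id = s$subject_id, visit_index = ok[j],
                        cell_id = seq_along(areas), bc_area_um2 = areas,
                        stringsAsFactors = FALSE)
           })
    })
    obs_list[[i]] <- do.call(rbind, lapply(rows, `[[`, "obs"))
    if (config$keep_cells) {
      cell_list[[i]] <- do.call(rbind, lapply(rows, `[[`, "cells"))
    }
  }

  observations <- do.call(rbind, obs_list)
  rownames(observations) <- NULL
  ds <- list(subjects = subjects,
             observations = observations,
             provenance = list(config = config, seed = seed,
                               n_visits_attended = n_attended_total))
  if (config$keep_cells) {
    ds$cells <- do.call(rbind, cell_list)
    rownames(ds$cells) <- NULL
  }
  class(ds) <- "amclear_cohort"
  validate_cohort(ds)
  ds
}

#' Check the structural invariants of a cohort dataset
#'
#' Verifies referential integrity between observations and subjects, ordered
#' per-subject visit times, the p90 >= median constraint, attended-visit
#' bounds, and the latency/group consistency rule (zero latency iff resident).
#' Called internally by [generate_cohort()]; exported so externally assembled
#' datasets can be validated too.
#'
#' @param ds An `amclear_cohort` list.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_cohort <- function(ds) {
  sub <- ds$subjects; obs <- ds$observations
  if (!all(obs$subject_id %in% sub$subject_id)) {
    stop("observation references unknown subject", call. = FALSE)
  }
  res <- sub$latency_days == 0
  if (!all(res == (sub$group == "BE"))) {
    stop("latency_days must be 0 exactly for BE residents", call. = FALSE)
  }
  if (!is.null(sub$subgroup)) {
    ok_sub <- list(BE = c("BEnative", "BEforeign"),
                   HIC = c("HICmoderate", "HIClow"),
                   LMIC = "none")
    bad <- mapply(function(g, sg) !sg %in% ok_sub[[g]],
                  sub$group, sub$subgroup)
    if (any(bad)) stop("subgroup inconsistent with group", call. = FALSE)
  }
  if (any(obs$p90_bc_um2 < obs$median_bc_um2 - 1e-12)) {
    stop("p90 below median", call. = FALSE)
  }
  bad_t <- vapply(split(obs$t_days, obs$subject_id),
                  function(t) any(diff(t) <= 0) && length(t) > 1, logical(1))
  if (any(bad_t)) stop("t_days not strictly increasing", call. = FALSE)
  n_per <- table(obs$subject_id)
  if (any(n_per > ds$provenance$config$n_visits)) {
    stop("more observations than scheduled visits", call. = FALSE)
  }
  invisible(TRUE)
}

#' Intra-individual coefficient of variation
#'
#' Percent coefficient of variation (100 x sample SD / mean) of one subject's
#' repeated slide summaries, the quantity used to describe within-person
#' stability of the biomarker in residents with constant exposure.
#'
#' @param series Numeric vector of at least two finite positive values.
#' @return CV in percent.
#' @examples
#' intra_individual_cv(c(1, 3)) # 70.71
#' @export
intra_individual_cv <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 2L || any(!is.finite(series))) {
    stop("need >= 2 finite values", call. = FALSE)
  }
  m <- mean(series)
  if (m == 0) stop("mean is zero; CV undefined", call. = FALSE)
  100 * stats::sd(series) / m
}

#' Write a cohort dataset to a directory
#'
#' Serializes `subjects.csv`, `observations.csv` (and `cells.csv` when kept)
#' plus a `config.yaml` provenance record.
#'
#' @param ds An `amclear_cohort`.
#' @param dir Output directory, created if missing.
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ds$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$observations, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  if (!is.null(ds$cells)) {
    utils::write.csv(ds$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  }
  cfg <- ds$provenance$config
  cfg$group_params <- as.list(cfg$group_params)
  yaml::write_yaml(list(seed = ds$provenance$seed,
                        n_visits_attended = ds$provenance$n_visits_attended,
                        config = unclass(cfg)),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort dataset written by [write_cohort()]
#'
#' @param dir Directory containing `subjects.csv` and `observations.csv`.
#' @return An `amclear_cohort` list.
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  observations <- utils::read.csv(file.path(dir, "observations.csv"),
                                  stringsAsFactors = FALSE)
  prov <- list()
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) {
    raw <- yaml::read_yaml(cfg_path)
    cfg <- raw$config
    cfg$group_params <- as.data.frame(cfg$group_params,
                                      stringsAsFactors = FALSE)
    class(cfg) <- "amclear_cohort_config"
    prov <- list(config = cfg, seed = raw$seed,
                 n_visits_attended = raw$n_visits_attended)
  }
  ds <- list(subjects = subjects, observations = observations,
             provenance = prov)
  class(ds) <- "amclear_cohort"
  ds
}
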