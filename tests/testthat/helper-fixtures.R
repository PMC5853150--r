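# shared fixtures built in code

# small noiseless single-group config: every slide median sits exactly on the
# decay curve
noiseless_config <- function(R0 = 1.0, k = 0.01, n = 4L, group = "LMIC",
                             n_visits = 6L, seed = 1L) {
  cohort_config(
    group_params = data.frame(group = group, n = n, R0 = R0, k = k,
                              latency_min = if (group == "BE") 0L else 1L,
                              latency_max = if (group == "BE") 0L else 1L,
                              stringsAsFactors = FALSE),
    sigma_log_r0 = 0, sigma_k = 0, sigma_obs = 0, sigma_cell = 0,
    induction_success = 1, dropout_hazard = 0, n_visits = n_visits,
    seed = seed)
}

# brute-force discrete disk pixel count: the enumeration oracle for the
# image pipeline, independent of generate_synthetic_image internals
enumerate_disk_pixels <- function(cx, cy, r, width, height) {
  n <- 0L
  for (x in seq_len(width)) {
    for (y in seq_len(height)) {
      if ((x - cx)^2 + (y - cy)^2 <= r^2) n <- n + 1L
    }
  }
  n
}

# fast MCMC settings for unit tests (acceptance uses the defaults)
quick_mcmc <- function(seed = 1L) {
  mcmc_config(n_chains = 2L, n_adapt = 300L, n_burnin = 300L,
              n_iter = 800L, seed = seed)
}
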