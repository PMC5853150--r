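#' Bland-Altman analysis of two quantification methods
#'
#' Mean difference and limits of agreement between paired per-cell carbon
#' areas measured by two methods (e.g. 2D confocal images vs
#' maximum-intensity projections of 3D z-stacks). On the log scale the
#' differences are `log(b) - log(a)` (natural logarithm), so the limits are
#' invariant to a common multiplicative rescaling of both methods. Limits of
#' agreement are mean +/- 2 SD of the differences.
#'
#' @param area_a,area_b Paired non-negative measurements (same cells, same
#'   order).
#' @param log_scale Analyse natural-log differences (default `TRUE`).
#' @param zero_offset Offset added to both methods before taking logs when
#'   zeros are present; `NULL` (default) means zeros are an error under
#'   `log_scale`.
#' @return List of class `amclear_bland_altman`: `n`, `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `log_scale`, and the per-pair `means` and
#'   `diffs` for plotting.
#' @examples
#' bland_altman(c(1, 2, 4), c(2, 4, 8))$mean_diff # ln 2
#' @export
bland_altman <- function(area_a, area_b, log_scale = TRUE,
                         zero_offset = NULL) {
  if (length(area_a) != length(area_b)) {
    stop("methods must be paired (equal length)", call. = FALSE)
  }
  keep <- is.finite(area_a) & is.finite(area_b)
  a <- area_a[keep]; b <- area_b[keep]
  if (length(a) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (any(a < 0) || any(b < 0)) stop("areas must be non-negative",
                                     call. = FALSE)
  if (log_scale) {
    if (any(a == 0) || any(b == 0)) {
      if (is.null(zero_offset)) {
        stop("zeros present: supply zero_offset for the log scale",
             call. = FALSE)
      }
      a <- a + zero_offset; b <- b + zero_offset
    }
    a <- log(a); b <- log(b)
  }
  d <- b - a
  m <- mean(d); s <- stats::sd(d)
  structure(list(n = length(d), mean_diff = m, sd_diff = s,
                 loa_lower = m - 2 * s, loa_upper = m + 2 * s,
                 log_scale = log_scale,
                 means = (a + b) / 2, diffs = d),
            class = "amclear_bland_altman")
}

#' Spearman rank correlation with a 95% confidence interval
#'
#' Rank correlation with midranks for ties. The default confidence interval
#' applies the Fisher z-transform to the rank correlation with variance
#' 1/(n-3) — an approximation, labelled as such in the result; a
#' nonparametric bootstrap over pairs is available as an alternative.
#'
#' @param area_a,area_b Paired measurements.
#' @param ci_method `"fisher"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples when `ci_method = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @return List: `r`, `ci_lower`, `ci_upper`, `n`, `ci_method`.
#' @examples
#' spearman_with_ci(1:5, c(1, 3, 2, 4, 5))$r # 0.9
#' @export
spearman_with_ci <- function(area_a, area_b,
                             ci_method = c("fisher", "bootstrap"),
                             n_boot = 2000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  if (length(area_a) != length(area_b)) {
    stop("methods must be paired (equal length)", call. = FALSE)
  }
  keep <- is.finite(area_a) & is.finite(area_b)
  a <- area_a[keep]; b <- area_b[keep]
  n <- length(a)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant measurements: rank correlation undefined", call. = FALSE)
  }
  r <- stats::cor(a, b, method = "spearman")
  if (ci_method == "fisher") {
    z <- atanh(r)
    hw <- 1.96 / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  } else {
    set.seed(seed)
    rs <- replicate(n_boot, {
      i <- sample.int(n, replace = TRUE)
      if (stats::sd(a[i]) == 0 || stats::sd(b[i]) == 0) NA_real_ else
        stats::cor(a[i], b[i], method = "spearman")
    })
    ci <- stats::quantile(rs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  list(r = r, ci_lower = ci[1], ci_upper = ci[2], n = n,
       ci_method = ci_method)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement, computed
#' from the two-way ANOVA mean squares over targets (cells) and raters
#' (methods):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with `n` targets and `k = 2` methods. The form identifier is always part
#' of the result so the choice is auditable.
#'
#' @param area_a,area_b Paired measurements.
#' @return List: `icc`, `form` (`"ICC(2,1)"` with a plain-words label),
#'   `n`, and the mean squares `ms_rows`, `ms_cols`, `ms_error`.
#' @examples
#' icc_agreement(1:10, 1:10)$icc # 1
#' @export
icc_agreement <- function(area_a, area_b) {
  if (length(area_a) != length(area_b)) {
    stop("methods must be paired (equal length)", call. = FALSE)
  }
  keep <- is.finite(area_a) & is.finite(area_b)
  a <- area_a[keep]; b <- area_b[keep]
  n <- length(a)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  k <- 2
  x <- cbind(a, b)
  grand <- mean(x)
  if (all(x == grand)) stop("zero total variance: ICC undefined",
                            call. = FALSE)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_error <- ss_error / ((n - 1) * (k - 1))
  icc <- (ms_rows - ms_error) /
    (ms_rows + (k - 1) * ms_error + k * (ms_cols - ms_error) / n)
  list(icc = icc,
       form = "ICC(2,1): two-way random effects, absolute agreement, single measurement",
       n = n, ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_error)
}

#' Full method-agreement report
#'
#' Bundles the Bland-Altman analysis (log scale), Spearman correlation with
#' confidence interval, and ICC(2,1) for a table of paired per-cell areas.
#'
#' @param pairs Data frame with columns `area_a` and `area_b` (and optionally
#'   `cell_id`).
#' @param log_scale Log-scale Bland-Altman (default `TRUE`).
#' @param zero_offset Passed to [bland_altman()].
#' @param ci_method Passed to [spearman_with_ci()].
#' @return List of class `amclear_agreement`: `n`, `bland_altman`,
#'   `spearman`, `icc`.
#' @export
agreement_report <- function(pairs, log_scale = TRUE, zero_offset = NULL,
                             ci_method = "fisher") {
  stopifnot(all(c("area_a", "area_b") %in% names(pairs)))
  ba <- bland_altman(pairs$area_a, pairs$area_b, log_scale = log_scale,
                     zero_offset = zero_offset)
  sp <- spearman_with_ci(pairs$area_a, pairs$area_b, ci_method = ci_method)
  ic <- icc_agreement(pairs$area_a, pairs$area_b)
  structure(list(n = ba$n, bland_altman = ba, spearman = sp, icc = ic),
            class = "amclear_agreement")
}

#' Write an agreement report as JSON
#'
#' @param report An `amclear_agreement`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_agreement <- function(report, path) {
  out <- list(n = report$n,
              bland_altman = report$bland_altman[
                c("mean_diff", "sd_diff", "loa_lower", "loa_upper",
                  "log_scale")],
              spearman = report$spearman,
              icc = report$icc[c("icc", "form", "n")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
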