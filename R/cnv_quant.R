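#' Copy-number call container
#'
#' @param estimate Point estimate of the diploid copy number of the unit.
#' @param ci Length-2 numeric 95% confidence interval (may contain NA).
#' @param method Character label of the estimator.
#' @return Object of class `copy_number_call` with `estimate`, `call`
#'   (nearest integer, half away from zero), `ci_low`, `ci_high`, `method`.
#' @keywords internal
copy_number_call <- function(estimate, ci = c(NA_real_, NA_real_), method = "") {
  stopifnot(is.finite(estimate), estimate > 0)
  structure(list(estimate = estimate,
                 call = as.integer(round_half_away(estimate)),
                 ci_low = ci[1], ci_high = ci[2], method = method),
            class = "copy_number_call")
}

#' @exportS3Method base::print
print.copy_number_call <- function(x, ...) {
  cat(sprintf("Copy-number call (%s): %.3f -> %d copies", x$method,
              x$estimate, x$call))
  if (is.finite(x$ci_low))
    cat(sprintf("  [95%% CI %.3f-%.3f]", x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}

# windows of a track fully contained in a set of intervals (same chrom)
windows_in_intervals <- function(track, intervals) {
  if (is.numeric(intervals) && length(intervals) == 2)
    intervals <- data.frame(chrom = track$chrom[1], start = intervals[1],
                            end = intervals[2])
  hit <- rep(FALSE, nrow(track))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (track$chrom == intervals$chrom[i] &
                    track$start >= intervals$start[i] &
                    track$end <= intervals$end[i])
  }
  hit
}

#' Estimate diploid copy number from a coverage track
#'
#' Mean window depth inside the CNV interval is normalised to the mean over
#' a user-supplied baseline interval set (a neighbouring CNV-free region
#' standing in for the genome average), and scaled so that equal depths
#' give two copies:
#' `estimate = 2 * mean(depth in CNV) / mean(depth in baseline)`.
#'
#' @param track A `coverage_track` data frame (`chrom`, `start`, `end`,
#'   `mean_depth`; 0-based half-open windows), e.g. from
#'   [simulate_coverage_track()] or [read_coverage_tsv()].
#' @param cnv_interval Interval containing the duplicated unit: a data
#'   frame (`chrom`, `start`, `end`) or numeric `c(start, end)`. Defaults
#'   to the track's own `cnv_interval` attribute when present.
#' @param baseline_intervals Interval set for the baseline mean; must not
#'   intersect the CNV interval. Defaults to the track attribute.
#' @return A `copy_number_call`. The 95% CI propagates the sampling
#'   variance of the two window means on the log-ratio scale.
#' @export
estimate_copy_number_from_coverage <- function(track, cnv_interval = NULL,
                                               baseline_intervals = NULL) {
  if (is.null(cnv_interval)) cnv_interval <- attr(track, "cnv_interval")
  if (is.null(baseline_intervals))
    baseline_intervals <- attr(track, "baseline_intervals")
  if (is.null(cnv_interval) || is.null(baseline_intervals))
    stop("cnv_interval and baseline_intervals are required")
  in_cnv <- windows_in_intervals(track, cnv_interval)
  in_base <- windows_in_intervals(track, baseline_intervals)
  in_base <- in_base & !in_cnv
  if (!any(in_cnv)) stop("no coverage windows inside the CNV interval")
  if (!any(in_base)) stop("no coverage windows inside the baseline intervals")
  mu_c <- mean(track$mean_depth[in_cnv])
  mu_b <- mean(track$mean_depth[in_base])
  if (mu_b <= 0) stop("baseline depth is zero; cannot normalise")
  est <- 2 * mu_c / mu_b
  # delta-method CI on the log ratio of the two window means
  n_c <- sum(in_cnv); n_b <- sum(in_base)
  v_c <- stats::var(track$mean_depth[in_cnv]) / n_c
  v_b <- stats::var(track$mean_depth[in_base]) / n_b
  se_log <- sqrt(ifelse(is.na(v_c), 0, v_c) / mu_c^2 +
                   ifelse(is.na(v_b), 0, v_b) / mu_b^2)
  ci <- est * exp(c(-1, 1) * 1.96 * se_log)
  copy_number_call(est, ci, method = "coverage")
}

#' Estimate diploid copy number from a droplet digital PCR assay
#'
#' Positive-droplet fractions are Poisson-corrected to per-droplet molecule
#' concentrations, `lambda = -log(1 - positive/total)`, and the diploid
#' copy number is twice the target/reference concentration ratio. The 95%
#' CI propagates the binomial standard errors of the two positive fractions
#' through the log transform (delta method).
#'
#' @param assay A [droplet_assay()].
#' @return A `copy_number_call`.
#' @export
ddpcr_copy_number <- function(assay) {
  stopifnot(inherits(assay, "droplet_assay"))
  check_channel <- function(pos, tot, name) {
    if (pos == 0) stop(sprintf("%s channel is empty (no positive droplets)", name))
    if (pos == tot) stop(sprintf("%s channel is saturated (all droplets positive)", name))
  }
  check_channel(assay$target_positive, assay$target_total, "target")
  check_channel(assay$reference_positive, assay$reference_total, "reference")

  p_t <- assay$target_positive / assay$target_total
  p_r <- assay$reference_positive / assay$reference_total
  lam_t <- -log(1 - p_t)
  lam_r <- -log(1 - p_r)
  est <- 2 * lam_t / lam_r
  # se(lambda) = se(p) / (1 - p); combine on the log-ratio scale
  se_t <- sqrt(p_t * (1 - p_t) / assay$target_total) / (1 - p_t)
  se_r <- sqrt(p_r * (1 - p_r) / assay$reference_total) / (1 - p_r)
  se_log <- sqrt((se_t / lam_t)^2 + (se_r / lam_r)^2)
  ci <- est * exp(c(-1, 1) * 1.96 * se_log)
  copy_number_call(est, ci, method = "ddPCR")
}
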