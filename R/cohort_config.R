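#' Synthetic cohort configuration
#'
#' Collects and validates every knob of the synthetic-cohort generator. The
#' defaults describe the cohort the analysis targets: 31 subjects of whom 12
#' are seizure-free after surgery, a 114-region bilateral parcellation sampled
#' at 600 Hz, hub-structured within-hemisphere covariance with weaker
#' inter-hemispheric coupling, a planted link between hub removal and
#' seizure-free outcome, and a planted positive association between overall
#' connectivity and log10 epilepsy duration.
#'
#' The signal model for region i is
#' `x_i(t) = lambda_i g_H(i)(t) + mu c(t) + sigma eps_i(t)` with independent
#' unit-variance white Gaussian factors (one per hemisphere plus one global)
#' and noise, where `lambda_i = scale * loading_hub` for hub regions and
#' `scale * loading_base` otherwise, `mu = scale * loading_global`,
#' `sigma = noise_sd`, and `scale = 1 + duration_slope * log10(duration_years)`.
#'
#' @param n_subjects Cohort size.
#' @param n_seizure_free Number of subjects with outcome `ILAE1` (seizure-free).
#' @param n_regions Even region count (split equally across hemispheres).
#' @param fs Sampling rate in Hz.
#' @param record_minutes Simulated recording length per subject, minutes.
#' @param n_hubs_per_hemisphere Hub regions planted in each hemisphere.
#' @param loading_hub,loading_base Hemisphere-factor loadings for hub and
#'   non-hub regions (unitless, >= 0).
#' @param loading_global Global-factor loading shared by all regions; this is
#'   the only source of inter-hemispheric correlation.
#' @param noise_sd Standard deviation of the per-region white noise.
#' @param hub_hit_fraction_good,hub_hit_fraction_poor Probability that each
#'   hub of the resected hemisphere falls inside the resection, for
#'   seizure-free (`ILAE1`) and not-seizure-free (`ILAE_gt1`) subjects.
#' @param resection_size Number of regions removed (all in one hemisphere).
#' @param duration_range_years Length-2 vector `(min, max)`, min > 0;
#'   durations are sampled log-uniformly so log10 duration is uniform.
#' @param duration_slope Loading-scale increment per log10(year); plants a
#'   monotone positive association between mean connectivity and duration.
#' @param seed Master seed; all per-subject substreams derive from it.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 31,
                          n_seizure_free = 12,
                          n_regions = 114,
                          fs = 600,
                          record_minutes = 1,
                          n_hubs_per_hemisphere = 4,
                          loading_hub = 0.9,
                          loading_base = 0.4,
                          loading_global = 0.2,
                          noise_sd = 1,
                          hub_hit_fraction_good = 0.9,
                          hub_hit_fraction_poor = 0.1,
                          resection_size = 8,
                          duration_range_years = c(1, 40),
                          duration_slope = 0.05,
                          seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_seizure_free = as.integer(n_seizure_free),
    n_regions = as.integer(n_regions),
    fs = fs,
    record_minutes = record_minutes,
    n_hubs_per_hemisphere = as.integer(n_hubs_per_hemisphere),
    loading_hub = loading_hub,
    loading_base = loading_base,
    loading_global = loading_global,
    noise_sd = noise_sd,
    hub_hit_fraction_good = hub_hit_fraction_good,
    hub_hit_fraction_poor = hub_hit_fraction_poor,
    resection_size = as.integer(resection_size),
    duration_range_years = as.numeric(duration_range_years),
    duration_slope = duration_slope,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1L, cfg$n_seizure_free >= 0L,
            cfg$n_seizure_free <= cfg$n_subjects,
            cfg$fs > 0, cfg$record_minutes > 0,
            cfg$n_hubs_per_hemisphere >= 1L)
  if (cfg$n_regions < 4L || cfg$n_regions %% 2L != 0L)
    stop("n_regions must be even and >= 4")
  half <- cfg$n_regions %/% 2L
  if (cfg$n_hubs_per_hemisphere > half)
    stop("n_hubs_per_hemisphere exceeds hemisphere size")
  if (cfg$resection_size < 1L || cfg$resection_size > half)
    stop("resection_size must be in [1, regions per hemisphere]")
  if (any(c(cfg$loading_hub, cfg$loading_base, cfg$loading_global) < 0))
    stop("factor loadings must be >= 0")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (!(cfg$hub_hit_fraction_poor >= 0 &&
        cfg$hub_hit_fraction_poor <= cfg$hub_hit_fraction_good &&
        cfg$hub_hit_fraction_good <= 1))
    stop("need 0 <= hub_hit_fraction_poor <= hub_hit_fraction_good <= 1")
  if (length(cfg$duration_range_years) != 2L ||
      cfg$duration_range_years[1] <= 0 ||
      diff(cfg$duration_range_years) < 0)
    stop("duration_range_years must be (min > 0, max >= min)")
  invisible(cfg)
}
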