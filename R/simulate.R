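#' Simulate one subject's ROI time series
#'
#' Draws a `n_regions x n_samples` matrix from the hub-structured factor
#' model described in [cohort_config()]: each region loads on its hemisphere's
#' latent factor (hub regions more strongly), on one weak global factor shared
#' across hemispheres, and carries independent white noise. The loading scale
#' grows with log10 epilepsy duration, planting the duration-connectivity
#' association.
#'
#' The generator owns a dedicated Mersenne-Twister stream keyed by `seed`;
#' repeated calls with identical arguments return identical matrices and the
#' R session's RNG state is untouched.
#'
#' @param atlas A `region_atlas`.
#' @param config A `cohort_config`.
#' @param hub_ids Integer region ids to treat as hubs (may span both
#'   hemispheres).
#' @param duration_years Epilepsy duration (> 0), within the configured range.
#' @param seed Integer stream seed.
#' @param n_samples Number of samples; defaults to
#'   `round(record_minutes * 60 * fs)`.
#' @return Matrix (regions x samples) with rownames = region ids.
#' @export
simulate_subject_timeseries <- function(atlas, config, hub_ids,
                                        duration_years, seed,
                                        n_samples = NULL) {
  validate_atlas(atlas)
  validate_cohort_config(config)
  if (!all(hub_ids %in% atlas$region_id))
    stop("hub_ids outside atlas: ", paste(setdiff(hub_ids, atlas$region_id), collapse = ", "))
  if (length(duration_years) != 1L || !is.finite(duration_years) ||
      duration_years <= 0)
    stop("duration_years must be a single positive number")
  if (is.null(n_samples))
    n_samples <- round(config$record_minutes * 60 * config$fs)
  scale <- 1 + config$duration_slope * log10(duration_years)
  lam <- ifelse(atlas$region_id %in% hub_ids,
                config$loading_hub, config$loading_base) * scale
  hemi <- ifelse(atlas$hemisphere == "L", 0L, 1L)
  X <- .sim_factor_ts(as.integer(n_samples), lam, hemi,
                      config$loading_global * scale, config$noise_sd,
                      as.numeric(seed))
  rownames(X) <- atlas$region_id
  X
}

#' Closed-form population correlation matrix of the factor model
#'
#' The exact Pearson correlation implied by the generative model, used as the
#' analytic oracle against which simulated connectivity converges:
#' within hemisphere `cov(i,j) = lambda_i lambda_j + mu^2`, across hemispheres
#' `cov(i,j) = mu^2`, and `var(i) = lambda_i^2 + mu^2 + sigma^2`.
#'
#' @inheritParams simulate_subject_timeseries
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
population_fc <- function(atlas, config, hub_ids, duration_years) {
  validate_atlas(atlas)
  scale <- 1 + config$duration_slope * log10(duration_years)
  lam <- ifelse(atlas$region_id %in% hub_ids,
                config$loading_hub, config$loading_base) * scale
  mu <- config$loading_global * scale
  same <- outer(atlas$hemisphere, atlas$hemisphere, "==")
  cov <- outer(lam, lam) * same + mu^2
  v <- lam^2 + mu^2 + config$noise_sd^2
  rho <- cov / sqrt(outer(v, v))
  diag(rho) <- 1
  dimnames(rho) <- list(atlas$region_id, atlas$region_id)
  rho
}

#' Plant a resection over one hemisphere
#'
#' Selects `resection_size` regions, all within the hemisphere that contains
#' `hub_ids`. Each hub is included independently with probability
#' `hub_hit_fraction_good` (outcome `ILAE1`) or `hub_hit_fraction_poor`
#' (outcome `ILAE_gt1`); the remainder of the resection is filled with
#' uniformly sampled non-hub regions of the same hemisphere. This creates the
#' planted coupling between hub removal and seizure-free outcome that the
#' downstream group analysis is meant to recover.
#'
#' @param atlas A `region_atlas`.
#' @param hub_ids Hub region ids, all in one hemisphere (the hemisphere to be
#'   resected).
#' @param outcome `"ILAE1"` or `"ILAE_gt1"`.
#' @param config A `cohort_config`.
#' @param seed Integer seed.
#' @return Integer vector of removed region ids.
#' @export
plant_resection <- function(atlas, hub_ids, outcome, config, seed) {
  validate_atlas(atlas)
  outcome <- match.arg(outcome, c("ILAE1", "ILAE_gt1"))
  if (!all(hub_ids %in% atlas$region_id)) stop("hub_ids outside atlas")
  hemis <- unique(atlas$hemisphere[match(hub_ids, atlas$region_id)])
  if (length(hemis) != 1L)
    stop("hub_ids must lie within a single hemisphere")
  hemi_ids <- atlas$region_id[atlas$hemisphere == hemis]
  if (config$resection_size > length(hemi_ids))
    stop("resection_size exceeds hemisphere size")
  p <- if (outcome == "ILAE1") config$hub_hit_fraction_good else config$hub_hit_fraction_poor
  with_seed(seed, {
    hit <- hub_ids[runif(length(hub_ids)) < p]
    if (length(hit) > config$resection_size)
      hit <- sample(hit, config$resection_size)
    pool <- setdiff(hemi_ids, hub_ids)
    n_fill <- config$resection_size - length(hit)
    fill <- if (n_fill > 0L) sample(pool, n_fill) else integer(0)
    sort(as.integer(c(hit, fill)))
  })
}

# Per-subject random draws shared by sample_cohort() and cohort_truth();
# one with_seed block so both see identical cohorts for a given config.
.cohort_draws <- function(config, atlas) {
  n <- config$n_subjects
  half_ids <- hemisphere_index(atlas)
  with_seed(config$seed, {
    list(
      duration = 10^runif(n, log10(config$duration_range_years[1]),
                          log10(config$duration_range_years[2])),
      affected = sample(c("L", "R"), n, replace = TRUE),
      hubsL = replicate(n, sample(atlas$region_id[half_ids$L],
                                  config$n_hubs_per_hemisphere), simplify = FALSE),
      hubsR = replicate(n, sample(atlas$region_id[half_ids$R],
                                  config$n_hubs_per_hemisphere), simplify = FALSE),
      seed_ts = sample.int(.Machine$integer.max - 1L, n),
      seed_res = sample.int(.Machine$integer.max - 1L, n)
    )
  })
}

#' Ground-truth table of a synthetic cohort, without simulating signals
#'
#' Reproduces exactly the per-subject draws that [sample_cohort()] would make
#' for `config` (durations, outcomes, hub placements) and the closed-form
#' population mean connectivity, skipping the expensive time-series
#' generation. Useful as the analytic reference in recovery tests.
#'
#' @param config A `cohort_config`.
#' @return data.frame with columns `subject_id`, `outcome`, `duration_years`,
#'   `affected_hemisphere`, `planted_mean_fc`.
#' @export
cohort_truth <- function(config) {
  validate_cohort_config(config)
  atlas <- build_atlas(config$n_regions)
  n <- config$n_subjects
  draws <- .cohort_draws(config, atlas)
  outcome <- rep(c("ILAE1", "ILAE_gt1"),
                 c(config$n_seizure_free, n - config$n_seizure_free))
  planted <- vapply(seq_len(n), function(i) {
    pop <- population_fc(atlas, config, c(draws$hubsL[[i]], draws$hubsR[[i]]),
                         draws$duration[i])
    mean(pop[upper.tri(pop)])
  }, numeric(1))
  data.frame(subject_id = sprintf("sub-%03d", seq_len(n)),
             outcome = outcome,
             duration_years = draws$duration,
             affected_hemisphere = draws$affected,
             planted_mean_fc = planted,
             stringsAsFactors = FALSE)
}

#' Sample a full synthetic cohort
#'
#' Generates `n_subjects` subject records: time series, resection, outcome
#' (`n_seizure_free` subjects are `ILAE1`), log-uniform epilepsy duration, and
#' a ground-truth block (hub ids, resected hemisphere, population mean
#' connectivity) for recovery tests. Fully reproducible from `config$seed`;
#' each subject draws from an independent derived substream.
#'
#' @param config A `cohort_config`.
#' @return A `hubdrs_cohort`: list with elements `atlas`, `config`, and
#'   `subjects` (list of subject records; see Details).
#' @details Each subject record is a list with fields `subject_id`,
#'   `timeseries` (regions x samples), `fs`, `removed_regions`, `outcome`,
#'   `duration_years` and `truth` (`hub_region_ids`, `affected_hemisphere`,
#'   `planted_mean_fc`).
#' @export
sample_cohort <- function(config) {
  validate_cohort_config(config)
  atlas <- build_atlas(config$n_regions)
  n <- config$n_subjects
  draws <- .cohort_draws(config, atlas)
  outcome <- rep(c("ILAE1", "ILAE_gt1"),
                 c(config$n_seizure_free, n - config$n_seizure_free))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    hubs <- c(draws$hubsL[[i]], draws$hubsR[[i]])
    hubs_aff <- if (draws$affected[i] == "L") draws$hubsL[[i]] else draws$hubsR[[i]]
    ts <- simulate_subject_timeseries(atlas, config, hubs,
                                      draws$duration[i], draws$seed_ts[i])
    removed <- plant_resection(atlas, hubs_aff, outcome[i], config,
                               draws$seed_res[i])
    pop <- population_fc(atlas, config, hubs, draws$duration[i])
    subjects[[i]] <- list(
      subject_id = sprintf("sub-%03d", i),
      timeseries = ts,
      fs = config$fs,
      removed_regions = removed,
      outcome = outcome[i],
      duration_years = draws$duration[i],
      truth = list(
        hub_region_ids = sort(hubs),
        affected_hemisphere = draws$affected[i],
        planted_mean_fc = mean(pop[upper.tri(pop)])
      )
    )
  }
  structure(list(atlas = atlas, config = config, subjects = subjects),
            class = "hubdrs_cohort")
}

#' @export
print.hubdrs_cohort <- function(x, ...) {
  cat(sprintf("hubdrs synthetic cohort: %d subjects (%d ILAE1), %d regions, %g min at %g Hz\n",
              length(x$subjects),
              sum(vapply(x$subjects, function(s) s$outcome == "ILAE1", logical(1))),
              nrow(x$atlas), x$config$record_minutes, x$config$fs))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One directory per cohort: `atlas.tsv`, per-subject `sub-XXX_ts.csv`
#' (regions x samples, no header) and `sub-XXX_meta.json`, plus a
#' `cohort_manifest.json` recording the configuration.
#'
#' @param cohort A `hubdrs_cohort`.
#' @param dir Output directory (created if missing).
#' @param write_timeseries Write the (large) per-subject CSV matrices;
#'   metadata is always written.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_timeseries = TRUE) {
  stopifnot(inherits(cohort, "hubdrs_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  for (s in cohort$subjects) {
    if (write_timeseries)
      data.table::fwrite(data.table::as.data.table(s$timeseries),
                         file.path(dir, paste0(s$subject_id, "_ts.csv")),
                         col.names = FALSE)
    meta <- list(fs = s$fs, outcome = s$outcome,
                 duration_years = s$duration_years,
                 removed_regions = s$removed_regions, truth = s$truth)
    jsonlite::write_json(meta, file.path(dir, paste0(s$subject_id, "_meta.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(package = "hubdrs",
                   n_subjects = length(cohort$subjects),
                   config = unclass(cohort$config))
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a time-series CSV (regions x samples, no header)
#'
#' @param path CSV path as written by [write_cohort()].
#' @return Numeric matrix, regions in file (= atlas) order.
#' @export
read_timeseries_csv <- function(path) {
  as.matrix(data.table::fread(path, header = FALSE))
}
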