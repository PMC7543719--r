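#' Per-subject, per-segment D_RS and mean connectivity table
#'
#' Runs the connectivity + D_RS chain over every subject of a cohort: select
#' epochs (or take the whole recording as one segment), build the epoch-mean
#' sliding-window correlation network, record its mean connectivity (full
#' matrix), mask inter-hemispheric connections, compute intra-hemispheric
#' node strength, and score D_RS against the subject's resection.
#'
#' @param cohort A `hubdrs_cohort` from [sample_cohort()], or a
#'   `cohort_config`, in which case subjects are generated one at a time and
#'   discarded after analysis (identical results to materializing the cohort
#'   first, but with per-subject rather than per-cohort memory).
#' @param window_seconds,overlap_fraction Sliding-window parameters
#'   (defaults 2 s, 50%).
#' @param n_epochs,epoch_seconds,min_gap_seconds Epoch selection; with the
#'   default `epoch_seconds = NULL` the entire recording is analyzed as a
#'   single segment.
#' @param spared_scope Passed to [drs_statistic()].
#' @param seed Seed for epoch placement (per-subject substreams derived).
#' @return data.frame with one row per subject-segment: `subject_id`,
#'   `segment`, `drs`, `mean_fc`, `outcome`, `duration_years`.
#' @export
cohort_drs_table <- function(cohort,
                             window_seconds = 2, overlap_fraction = 0.5,
                             n_epochs = 3, epoch_seconds = NULL,
                             min_gap_seconds = 300,
                             spared_scope = "both",
                             seed = 1L) {
  streamed <- inherits(cohort, "cohort_config")
  if (streamed) {
    config <- cohort
    validate_cohort_config(config)
    atlas <- build_atlas(config$n_regions)
    draws <- .cohort_draws(config, atlas)
    n <- config$n_subjects
    outcomes <- rep(c("ILAE1", "ILAE_gt1"),
                    c(config$n_seizure_free, n - config$n_seizure_free))
  } else {
    atlas <- cohort$atlas
    validate_atlas(atlas)
    n <- length(cohort$subjects)
  }
  epoch_seeds <- derive_seeds(seed, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (streamed) {
      hubs <- c(draws$hubsL[[i]], draws$hubsR[[i]])
      hubs_aff <- if (draws$affected[i] == "L") draws$hubsL[[i]] else draws$hubsR[[i]]
      s <- list(
        subject_id = sprintf("sub-%03d", i),
        timeseries = simulate_subject_timeseries(atlas, config, hubs,
                                                 draws$duration[i],
                                                 draws$seed_ts[i]),
        fs = config$fs,
        removed_regions = plant_resection(atlas, hubs_aff, outcomes[i],
                                          config, draws$seed_res[i]),
        outcome = outcomes[i],
        duration_years = draws$duration[i]
      )
    } else {
      s <- cohort$subjects[[i]]
    }
    spec <- window_spec(window_seconds, overlap_fraction, fs = s$fs)
    epochs <- if (is.null(epoch_seconds)) {
      data.frame(start = 1L, end = ncol(s$timeseries) + 1L)
    } else {
      select_epochs(ncol(s$timeseries), s$fs, n_epochs, epoch_seconds,
                    min_gap_seconds, seed = epoch_seeds[i])
    }
    labels <- label_from_list(s$removed_regions, atlas)
    seg_rows <- vector("list", nrow(epochs))
    for (e in seq_len(nrow(epochs))) {
      fc <- epoch_mean_fc(s$timeseries, spec,
                          c(epochs$start[e], epochs$end[e]))
      mfc <- mean_fc(fc)
      strength <- intra_hemispheric_strength(fc, atlas)
      d <- drs_statistic(strength, labels, atlas, spared_scope,
                         subject_id = s$subject_id, epoch_index = e)
      seg_rows[[e]] <- data.frame(
        subject_id = s$subject_id, segment = e, drs = d$drs, mean_fc = mfc,
        outcome = s$outcome, duration_years = s$duration_years,
        stringsAsFactors = FALSE
      )
    }
    rows[[i]] <- do.call(rbind, seg_rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-level statistics from a cohort table
#'
#' Per segment: outcome AUC with logit confidence interval and one-tailed
#' rank-sum p ([group_outcome_test()]) and the robust duration regression
#' ([fit_duration_robust()]). Across segments (when more than one is
#' present): the random-intercept mixed model ([fit_duration_lme()]).
#' Per-segment p-values are reported uncorrected.
#'
#' @param tab data.frame from [cohort_drs_table()].
#' @param level Confidence level for AUC intervals.
#' @return List with `segments` (named per-segment sublists: `outcome` and
#'   `duration`), and `lme` (or `NULL` for a single segment).
#' @export
group_stats <- function(tab, level = 0.95) {
  req <- c("subject_id", "segment", "drs", "mean_fc", "outcome", "duration_years")
  if (!all(req %in% names(tab))) stop("tab is missing required columns")
  segs <- sort(unique(tab$segment))
  per_seg <- lapply(segs, function(sg) {
    d <- tab[tab$segment == sg, ]
    list(outcome = group_outcome_test(d$drs, d$outcome, level),
         duration = fit_duration_robust(d))
  })
  names(per_seg) <- paste0("segment_", segs)
  lme <- if (length(segs) >= 2L) fit_duration_lme(tab) else NULL
  list(segments = per_seg, lme = lme)
}

#' End-to-end pipeline configuration
#'
#' @param cohort A [cohort_config()].
#' @param window_seconds,overlap_fraction Sliding-window parameters.
#' @param n_epochs,epoch_seconds,min_gap_seconds Epoch selection (see
#'   [cohort_drs_table()]).
#' @param spared_scope `"both"` or `"ipsilateral"`.
#' @param ci_level Confidence level.
#' @param seed Pipeline seed (epoch placement).
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(),
                       window_seconds = 2, overlap_fraction = 0.5,
                       n_epochs = 3, epoch_seconds = NULL,
                       min_gap_seconds = 300,
                       spared_scope = "both", ci_level = 0.95,
                       seed = 1L) {
  structure(list(cohort = cohort, window_seconds = window_seconds,
                 overlap_fraction = overlap_fraction, n_epochs = n_epochs,
                 epoch_seconds = epoch_seconds,
                 min_gap_seconds = min_gap_seconds,
                 spared_scope = spared_scope, ci_level = ci_level,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Flatten group_stats into plain lists for JSON serialization.
.stats_to_json_list <- function(stats) {
  seg <- lapply(stats$segments, function(s) {
    o <- s$outcome; d <- s$duration
    list(auc = o$auc, ci_low = o$ci_low, ci_high = o$ci_high,
         level = o$level, n1 = o$n1, n2 = o$n2,
         p_one_tailed = o$p_one_tailed, p_method = o$p_method,
         duration = list(slope = d$slope, intercept = d$intercept,
                         adjusted_r2 = d$adjusted_r2, lrt_p = d$lrt_p,
                         model_kind = d$model_kind))
  })
  lme <- if (!is.null(stats$lme)) {
    l <- stats$lme
    list(slope = l$slope, intercept = l$intercept, se_slope = l$se_slope,
         segment_var = l$segment_var, lrt_p = l$lrt_p,
         model_kind = l$model_kind)
  }
  list(segments = seg, lme = lme)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' simulate -> connectivity -> resection labels -> D_RS -> group statistics.
#' Writes `cohort_table.tsv`, `group_stats.json`, per-subject D_RS JSON files
#' under `drs/`, and a `manifest.json` recording the full configuration.
#' Identical configuration + seed reproduces byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param output_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @return Invisibly, a list with `table` (the cohort data.frame), `stats`
#'   (from [group_stats()]) and `output_dir`.
#' @export
run_pipeline <- function(config = run_config(), output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  tab <- cohort_drs_table(config$cohort,
                          window_seconds = config$window_seconds,
                          overlap_fraction = config$overlap_fraction,
                          n_epochs = config$n_epochs,
                          epoch_seconds = config$epoch_seconds,
                          min_gap_seconds = config$min_gap_seconds,
                          spared_scope = config$spared_scope,
                          seed = config$seed)
  stats <- group_stats(tab, level = config$ci_level)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tab, file.path(output_dir, "cohort_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(.stats_to_json_list(stats),
                         file.path(output_dir, "group_stats.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    drs_dir <- file.path(output_dir, "drs")
    dir.create(drs_dir, showWarnings = FALSE)
    for (sid in unique(tab$subject_id)) {
      d <- tab[tab$subject_id == sid, ]
      jsonlite::write_json(
        list(subject_id = sid,
             segments = d$segment, drs = d$drs, mean_fc = d$mean_fc,
             outcome = d$outcome[1], duration_years = d$duration_years[1]),
        file.path(drs_dir, paste0(sid, "_drs.json")),
        auto_unbox = TRUE, digits = NA)
    }
    cfg <- config
    cfg$cohort <- unclass(cfg$cohort)
    jsonlite::write_json(list(package = "hubdrs", config = unclass(cfg)),
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(table = tab, stats = stats, output_dir = output_dir))
}
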