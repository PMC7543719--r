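test_that("simulator is deterministic given its seed and ignores R's RNG state", {
  atlas <- build_atlas(8)
  cfg <- cohort_config(n_subjects = 2, n_seizure_free = 1, n_regions = 8,
                       n_hubs_per_hemisphere = 2, resection_size = 2)
  set.seed(1)
  a <- simulate_subject_timeseries(atlas, cfg, hub_ids = c(1, 5),
                                   duration_years = 5, seed = 42,
                                   n_samples = 500)
  set.seed(999)
  b <- simulate_subject_timeseries(atlas, cfg, hub_ids = c(1, 5),
                                   duration_years = 5, seed = 42,
                                   n_samples = 500)
  expect_identical(a, b)
  d <- simulate_subject_timeseries(atlas, cfg, hub_ids = c(1, 5),
                                   duration_years = 5, seed = 43,
                                   n_samples = 500)
  expect_false(identical(a, d))
  expect_equal(dim(a), c(8L, 500L))
})

test_that("default sample length is record_minutes * 60 * fs", {
  atlas <- build_atlas(4)
  cfg <- cohort_config(n_subjects = 1, n_seizure_free = 1, n_regions = 4,
                       n_hubs_per_hemisphere = 1, resection_size = 1,
                       record_minutes = 10 / 60, fs = 600)
  x <- simulate_subject_timeseries(atlas, cfg, hub_ids = 1,
                                   duration_years = 2, seed = 1)
  expect_equal(ncol(x), 6000L)
})

test_that("zero loadings give independent channels", {
  atlas <- build_atlas(6)
  cfg <- cohort_config(n_subjects = 1, n_seizure_free = 1, n_regions = 6,
                       n_hubs_per_hemisphere = 1, resection_size = 1,
                       loading_hub = 0, loading_base = 0, loading_global = 0,
                       noise_sd = 1)
  x <- simulate_subject_timeseries(atlas, cfg, hub_ids = 1,
                                   duration_years = 5, seed = 7,
                                   n_samples = 36000)
  r <- cor(t(x))
  expect_true(all(abs(r[upper.tri(r)]) < 0.05))
})

test_that("sample correlation matches the closed-form factor-model value", {
  # two non-hub regions of one hemisphere: rho = lam^2 / (lam^2 + sigma^2)
  lam <- 0.6; s <- 0.8
  atlas <- build_atlas(4)
  cfg <- cohort_config(n_subjects = 1, n_seizure_free = 1, n_regions = 4,
                       n_hubs_per_hemisphere = 1, resection_size = 1,
                       loading_hub = 0.9, loading_base = lam,
                       loading_global = 0, noise_sd = s, duration_slope = 0)
  Tn <- 36000
  x <- simulate_subject_timeseries(atlas, cfg, hub_ids = 3,
                                   duration_years = 5, seed = 11,
                                   n_samples = Tn)
  rho <- lam^2 / (lam^2 + s^2)
  tol <- 3 * (1 - rho^2) / sqrt(Tn)
  expect_equal(cor(x[1, ], x[2, ]), rho, tolerance = tol / rho)
  # and the analytic matrix agrees entry-wise with covariance algebra
  pop <- population_fc(atlas, cfg, hub_ids = 3, duration_years = 5)
  expect_equal(unname(pop[1, 2]), rho, tolerance = 1e-12)
  expect_equal(unname(pop[1, 3]), 0, tolerance = 1e-12)  # mu = 0: hemispheres decouple
})

test_that("empirical connectivity converges to the analytic correlation at 120 s", {
  atlas <- build_atlas(8)
  cfg <- cohort_config(n_subjects = 1, n_seizure_free = 1, n_regions = 8,
                       n_hubs_per_hemisphere = 2, resection_size = 2)
  hubs <- c(1, 2, 5, 6)
  x <- simulate_subject_timeseries(atlas, cfg, hubs, duration_years = 5,
                                   seed = 3, n_samples = 120 * 600)
  emp <- cor(t(x))
  pop <- population_fc(atlas, cfg, hubs, duration_years = 5)
  expect_lt(max(abs(emp - pop)), 0.05)
})

test_that("hubs have strictly larger population intra-hemispheric strength", {
  atlas <- build_atlas(20)
  cfg <- cohort_config(n_subjects = 1, n_seizure_free = 1, n_regions = 20,
                       n_hubs_per_hemisphere = 2, resection_size = 3)
  hubs <- c(1, 2, 11, 12)
  pop <- population_fc(atlas, cfg, hubs, duration_years = 5)
  strength <- intra_hemispheric_strength(pop, atlas)
  is_hub <- atlas$region_id %in% hubs
  expect_gt(min(strength[is_hub]), max(strength[!is_hub]))
})

test_that("simulator rejects invalid durations and unknown hubs", {
  atlas <- build_atlas(4)
  cfg <- cohort_config(n_subjects = 1, n_seizure_free = 1, n_regions = 4,
                       n_hubs_per_hemisphere = 1, resection_size = 1)
  expect_error(simulate_subject_timeseries(atlas, cfg, 1, -2, seed = 1),
               "positive")
  expect_error(simulate_subject_timeseries(atlas, cfg, 99, 5, seed = 1),
               "outside atlas")
})

test_that("plant_resection honors forced hits, forced misses and hemisphere bounds", {
  atlas <- build_atlas(114)
  cfg <- cohort_config(hub_hit_fraction_good = 1, hub_hit_fraction_poor = 0,
                       resection_size = 4)
  hubs <- c(3, 10, 21, 40)  # all left hemisphere
  expect_equal(plant_resection(atlas, hubs, "ILAE1", cfg, seed = 1),
               sort(hubs))
  miss <- plant_resection(atlas, hubs, "ILAE_gt1", cfg, seed = 1)
  expect_length(intersect(miss, hubs), 0)
  expect_length(miss, 4)
  expect_true(all(atlas$hemisphere[match(miss, atlas$region_id)] == "L"))

  tiny <- build_atlas(6)
  cfg_big <- cohort_config(n_regions = 114, resection_size = 20)
  expect_error(plant_resection(tiny, c(1, 2), "ILAE1", cfg_big, seed = 1),
               "exceeds hemisphere")
  expect_error(plant_resection(atlas, c(1, 60), "ILAE1", cfg, seed = 1),
               "single hemisphere")
})

test_that("expected hub capture matches the binomial mean over 200 seeds", {
  atlas <- build_atlas(114)
  cfg <- cohort_config(hub_hit_fraction_good = 0.75, resection_size = 8)
  hubs <- c(5, 17, 30, 50)
  hits <- vapply(1:200, function(s) {
    length(intersect(plant_resection(atlas, hubs, "ILAE1", cfg, seed = s), hubs))
  }, numeric(1))
  expect_gte(mean(hits), 2.6)  # binomial mean 3 with Monte-Carlo slack
  expect_lte(mean(hits), 3.4)
})

test_that("sample_cohort produces the configured outcome split and valid resections", {
  cfg <- small_cohort_config(seed = 21)
  co <- sample_cohort(cfg)
  outcomes <- vapply(co$subjects, `[[`, character(1), "outcome")
  expect_equal(sum(outcomes == "ILAE1"), 12L)
  expect_equal(sum(outcomes == "ILAE_gt1"), 19L)
  for (s in co$subjects) {
    expect_gt(length(s$removed_regions), 0)
    h <- unique(co$atlas$hemisphere[match(s$removed_regions, co$atlas$region_id)])
    expect_length(h, 1)           # unilateral resection
    expect_identical(h, s$truth$affected_hemisphere)
    expect_true(all(s$removed_regions %in% co$atlas$region_id))
    expect_gt(s$duration_years, 0)
    expect_true(s$duration_years >= cfg$duration_range_years[1] &&
                  s$duration_years <= cfg$duration_range_years[2])
    expect_true(is.finite(s$truth$planted_mean_fc))
  }
})

test_that("sample_cohort is reproducible and a 1-subject cohort works", {
  cfg <- cohort_config(n_subjects = 3, n_seizure_free = 1, n_regions = 8,
                       n_hubs_per_hemisphere = 2, resection_size = 2,
                       record_minutes = 1 / 60, seed = 5)
  c1 <- sample_cohort(cfg)
  c2 <- sample_cohort(cfg)
  expect_identical(c1$subjects[[2]]$timeseries, c2$subjects[[2]]$timeseries)
  expect_identical(c1$subjects[[3]]$removed_regions,
                   c2$subjects[[3]]$removed_regions)
  expect_identical(vapply(c1$subjects, `[[`, numeric(1), "duration_years"),
                   vapply(c2$subjects, `[[`, numeric(1), "duration_years"))

  single <- sample_cohort(cohort_config(n_subjects = 1, n_seizure_free = 1,
                                        n_regions = 6, n_hubs_per_hemisphere = 1,
                                        resection_size = 2,
                                        record_minutes = 1 / 60, seed = 2))
  expect_equal(single$subjects[[1]]$outcome, "ILAE1")
})

test_that("cohort round-trips through the on-disk layout", {
  cfg <- cohort_config(n_subjects = 2, n_seizure_free = 1, n_regions = 6,
                       n_hubs_per_hemisphere = 1, resection_size = 2,
                       record_minutes = 1 / 60, seed = 9)
  co <- sample_cohort(cfg)
  dir <- tempfile("cohort")
  on.exit(unlink(dir, recursive = TRUE))
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "atlas.tsv")))
  expect_true(file.exists(file.path(dir, "cohort_manifest.json")))
  ts <- read_timeseries_csv(file.path(dir, "sub-001_ts.csv"))
  expect_equal(unname(ts), unname(co$subjects[[1]]$timeseries),
               tolerance = 1e-12)
  meta <- jsonlite::read_json(file.path(dir, "sub-001_meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$outcome, co$subjects[[1]]$outcome)
  expect_equal(sort(meta$removed_regions), sort(co$subjects[[1]]$removed_regions))
})

test_that("cohort_truth mirrors sample_cohort without simulating signals", {
  cfg <- cohort_config(n_subjects = 5, n_seizure_free = 2, n_regions = 8,
                       n_hubs_per_hemisphere = 2, resection_size = 2,
                       record_minutes = 1 / 60, seed = 31)
  co <- sample_cohort(cfg)
  tr <- cohort_truth(cfg)
  expect_equal(tr$duration_years,
               vapply(co$subjects, `[[`, numeric(1), "duration_years"))
  expect_equal(tr$outcome, vapply(co$subjects, `[[`, character(1), "outcome"))
  expect_equal(tr$planted_mean_fc,
               vapply(co$subjects, function(s) s$truth$planted_mean_fc,
                      numeric(1)))
  expect_equal(tr$affected_hemisphere,
               vapply(co$subjects, function(s) s$truth$affected_hemisphere,
                      character(1)))
})
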