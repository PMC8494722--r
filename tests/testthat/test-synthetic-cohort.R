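# Synthetic cohort generator: baseline distributions, trajectory and
# observation models, event-time sampling, calibration, visit grids.

test_that("generate_baseline draws the configured cohort", {
  cfg <- cohort_config(n_subjects = 263, seed = 1)
  subj <- generate_baseline(cfg)
  expect_equal(nrow(subj), 263)
  expect_true(all(subj$censor_time <= cfg$max_followup + 1e-12))

  expect_equal(nrow(generate_baseline(cohort_config(n_subjects = 0))), 0)

  big <- generate_baseline(cohort_config(n_subjects = 10000, seed = 2))
  expect_equal(mean(big$sex), 0.72, tolerance = 0.015)
  expect_equal(mean(big$age), 67, tolerance = 0.0075)   # +- 0.5 years
  expect_equal(sd(big$age), 13, tolerance = 0.04)       # +- 0.5 years
  expect_true(all(big$age >= 18 & big$age <= 100))
  ## random effects follow N(0, D)
  expect_equal(sd(big$b0), cfg$d_sd[1], tolerance = 0.05)
  expect_equal(sd(big$b1), cfg$d_sd[2], tolerance = 0.05)
})

test_that("baseline generation rejects invalid distribution parameters", {
  expect_error(cohort_config(n_subjects = -1), "n_subjects")
  expect_error(cohort_config(sigma = -0.1), "sigma")
  expect_error(cohort_config(d_cor = 2), "positive semi-definite")
  expect_error(cohort_config(h0 = c(0.1, -0.2)), "h0")
  expect_error(generate_baseline(
    cohort_config(covariates = list(age_sd = -1))), "covariates")
  expect_error(cohort_config(covariates = list(nonsense = 1)), "unknown")
})

test_that("true trajectories are linear on the log scale and positive", {
  cfg <- cohort_config(beta0 = log(100), beta1 = 0, beta_cov = numeric(0))
  flat <- list(eta_long = 0, b0 = 0, b1 = 0)
  expect_equal(true_trajectory(flat, c(0, 1, 2.5), cfg), rep(log(100), 3))

  riser <- list(eta_long = 0, b0 = 0, b1 = 0.1)
  expect_equal(true_trajectory(riser, 2, cfg) - true_trajectory(riser, 0, cfg),
               0.2)
  expect_true(all(exp(true_trajectory(riser, seq(0, 3, 0.25), cfg)) > 0))
})

test_that("biomarker observation noise is reproducible and correctly scaled", {
  cfg <- cohort_config(seed = 9, sigma = 0, beta_cov = numeric(0))
  sub <- list(subject_id = "S0001", eta_long = 0, b0 = 0.2, b1 = -0.05)
  rec <- observe_biomarker(sub, c(0, 0.5), cfg)
  expect_equal(rec$log_value, true_trajectory(sub, c(0, 0.5), cfg))
  expect_equal(rec$value, exp(rec$log_value))

  cfg$sigma <- 0.15
  t_many <- seq(0, 999.9, by = 0.1) # 10,000 distinct observation times
  noise <- observe_biomarker(sub, t_many, cfg)$log_value -
    true_trajectory(sub, t_many, cfg)
  expect_equal(var(noise), cfg$sigma^2, tolerance = 0.05)

  again <- observe_biomarker(sub, c(0, 0.5), cfg)
  expect_identical(observe_biomarker(sub, c(0, 0.5), cfg), again)
})

test_that("event-time sampler agrees with the closed exponential form when alpha = 0", {
  cfg <- cohort_config(n_subjects = 10000, seed = 21, alpha = 0,
                       beta_cov = numeric(0), gamma = numeric(0),
                       h0 = rep(0.1, 5), t_max_search = 200)
  subj <- generate_baseline(cfg)
  tt <- sample_event_time(subj, cfg)
  expect_true(all(is.finite(tt)))
  expect_equal(mean(tt), 10, tolerance = 0.03)          # 10 +- 0.3 yr
  expect_equal(mean(tt <= 1), 1 - exp(-0.1), tolerance = 0.10)
  ks <- suppressWarnings(stats::ks.test(tt, "pexp", rate = 0.1))
  expect_gt(ks$p.value, 0.01)
})

test_that("higher random intercepts shorten event times when alpha > 0", {
  cfg <- cohort_config(n_subjects = 4000, seed = 22, alpha = 1.5,
                       beta_cov = numeric(0), gamma = numeric(0),
                       h0 = rep(0.05, 5), t_max_search = 400)
  subj <- generate_baseline(cfg)
  lo <- subj; lo$b0 <- -0.3
  hi <- subj; hi$b0 <- 0.3
  E <- withr::with_seed(5, rexp(nrow(subj)))
  t_lo <- sample_event_time(lo, cfg, E = E)
  t_hi <- sample_event_time(hi, cfg, E = E)
  expect_true(all(t_hi <= t_lo + 1e-9))
  grid <- c(2, 5, 10, 20)
  ecdf_lo <- vapply(grid, function(g) mean(t_lo <= g), numeric(1))
  ecdf_hi <- vapply(grid, function(g) mean(t_hi <= g), numeric(1))
  expect_true(all(ecdf_hi >= ecdf_lo))
})

test_that("event-rate calibration hits its target and scales proportionally", {
  cfg <- original_design_config(seed = 31)
  cal <- calibrate_event_rate(cfg, n_mc = 20000L)
  s1 <- attr(cal, "calibration_scalar")

  check <- cal
  check$n_subjects <- 20000L
  check$seed <- 987L
  subj <- generate_baseline(check)
  events <- sample_event_time(subj, check) <= subj$censor_time
  expect_equal(mean(events), 0.266, tolerance = 0.04)   # 26.6% +- ~1%

  expect_error(calibrate_event_rate(cohort_config(target_event_rate = 0)),
               "target_event_rate")

  doubled <- cfg
  doubled$h0 <- cfg$h0 * 2
  s2 <- attr(calibrate_event_rate(doubled, n_mc = 20000L),
             "calibration_scalar")
  expect_equal(s2, s1 / 2, tolerance = 1e-6)
})

test_that("visit grids truncate at censoring and strictly before events", {
  expect_equal(persched:::visit_grid(Inf, 2.5, 0.25),
               seq(0, 2.5, by = 0.25))                     # 11 visits
  expect_length(persched:::visit_grid(Inf, 3.0, 0.25), 13) # full 3-yr grid
  expect_equal(persched:::visit_grid(0.1, 2.5, 0.25), 0)   # baseline only
  expect_equal(persched:::visit_grid(0.5, 3, 0.25), c(0, 0.25)) # strict <
})

test_that("cohorts are bit-reproducible under a fixed seed and round-trip CSV", {
  cfg <- calibrate_event_rate(test_config(seed = 41, n_subjects = 30),
                              n_mc = 2000L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$longitudinal, c2$longitudinal)
  expect_identical(c1$subjects, c2$subjects)

  expect_true(all(c1$longitudinal$time <=
                    c1$survival$observed_time[match(c1$longitudinal$subject_id,
                                                    c1$survival$subject_id)] + 1e-9))
  expect_equal(c1$survival$observed_time,
               pmin(c1$subjects$true_event_time, c1$subjects$censor_time))

  dir <- withr::local_tempdir()
  write_cohort(c1, dir)
  back <- read_cohort(dir)
  expect_equal(back$longitudinal$log_value, c1$longitudinal$log_value,
               tolerance = 1e-12)
  expect_equal(back$survival$event, c1$survival$event)
  expect_error(read_cohort(file.path(dir, "nope")), "missing")
})

test_that("the original 2.5-year design reproduces the printed cohort summaries", {
  cfg <- calibrate_event_rate(original_design_config(seed = 51), n_mc = 8000L)
  big <- cfg; big$n_subjects <- 4000L; big$seed <- 52L
  subj <- generate_baseline(big)
  tev <- sample_event_time(subj, big)
  fu <- pmin(tev, subj$censor_time)
  counts <- vapply(seq_along(tev), function(i) {
    length(persched:::visit_grid(tev[i], subj$censor_time[i], 0.25))
  }, numeric(1))
  expect_equal(median(counts), 9)
  expect_gte(qtl(counts, 0.25), 5)
  expect_lte(qtl(counts, 0.75), 11)
  expect_equal(median(fu), 2.2, tolerance = 0.05)
})
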