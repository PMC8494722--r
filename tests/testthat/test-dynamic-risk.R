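# Dynamic prediction: closed-form checks in the biomarker-independent
# case, monotonicity and threshold consistency, posterior random effects,
# and the expected information gain.

test_that("conditional risk matches the closed form when the biomarker is uninformative", {
  ff <- flat_fit(h = 0.1)
  ctrl <- risk_control(n_b = 100, method = "laplace", seed = 3)
  t <- 0.5
  expect_equal(cumulative_risk(ff$fit, ff$data, NULL, t, t, control = ctrl), 0)
  expect_equal(cumulative_risk(ff$fit, ff$data, NULL, t, t + 1, control = ctrl),
               1 - exp(-0.1), tolerance = 5e-4)      # 0.0952 to 3 decimals
  expect_equal(cumulative_risk(ff$fit, ff$data, NULL, t, t + 0.25, control = ctrl),
               1 - exp(-0.1 * 0.25), tolerance = 5e-4)
  expect_error(cumulative_risk(ff$fit, ff$data, NULL, t, t - 0.1, control = ctrl),
               "u must be >= t")

  thr <- find_threshold_time(ff$fit, ff$data, NULL, t, kappa = 0.075,
                             horizon = 3, control = ctrl)
  expect_equal(thr$t_threshold - t, -log(0.925) / 0.1, tolerance = 2e-3)

  thr1 <- find_threshold_time(ff$fit, ff$data, NULL, t, kappa = 1,
                              horizon = 3, control = ctrl)
  expect_true(thr1$beyond_horizon)
  expect_identical(thr1$t_threshold, Inf)
})

test_that("risk curves are monotone, bounded, and consistent with the threshold time", {
  cc <- shared_cohort()
  fit <- shared_truth_fit()
  ctrl <- risk_control(n_b = 300, method = "laplace", seed = 9)
  for (i in c(2, 7, 19)) {
    sid <- cc$cohort$subjects$subject_id[i]
    sdat <- cc$cohort$longitudinal[cc$cohort$longitudinal$subject_id == sid &
                                     cc$cohort$longitudinal$time <= 0.5, ]
    if (nrow(sdat) < 3) next
    sub <- cc$cohort$subjects[i, ]
    draws <- posterior_random_effects(fit, sdat, sub, 0.5, ctrl)
    grid <- seq(0.5, 3, length.out = 21)
    pi_u <- cumulative_risk(fit, sdat, sub, 0.5, grid, draws = draws)
    expect_true(all(diff(pi_u) >= -1e-12))
    expect_true(all(pi_u >= 0 & pi_u <= 1))

    thr <- find_threshold_time(fit, sdat, sub, 0.5, kappa = 0.075,
                               horizon = 3, draws = draws)
    if (!thr$beyond_horizon) {
      pi_thr <- cumulative_risk(fit, sdat, sub, 0.5, thr$t_threshold,
                                draws = draws)
      expect_equal(pi_thr, 0.075, tolerance = 2e-3)
    }
  }
})

test_that("conditional risk at true parameters matches brute-force event simulation", {
  cc <- shared_cohort()
  fit <- shared_truth_fit()
  i <- which(cc$cohort$subjects$true_event_time > 1.2)[1]
  sub <- cc$cohort$subjects[i, ]
  sid <- sub$subject_id
  sdat <- cc$cohort$longitudinal[cc$cohort$longitudinal$subject_id == sid &
                                   cc$cohort$longitudinal$time <= 0.5, ]
  t <- 0.5; u <- 1.5
  draws <- fixed_b_draws(fit, sdat, sub, t, c(sub$b0, sub$b1))
  pi_fit <- cumulative_risk(fit, sdat, sub, t, u, draws = draws)

  ## brute force: simulate event times from the generative hazard for this
  ## subject's exact latent state, estimate P(T <= u | T > t)
  n_mc <- 40000L
  rep_sub <- sub[rep(1, n_mc), ]
  cfg <- cc$config
  E <- withr::with_seed(404, rexp(n_mc))
  tt_mc <- sample_event_time(rep_sub, cfg, E = E)
  keep <- tt_mc > t
  pi_mc <- mean(tt_mc[keep] <= u)
  expect_equal(pi_fit, pi_mc, tolerance = 0.01)
})

test_that("posterior random effects concentrate in the noiseless limit", {
  long <- data.frame(subject_id = "A", time = 0, log_value = 5.1,
                     value = exp(5.1))
  surv <- data.frame(subject_id = "A", observed_time = 0.5, event = 0L)
  spec <- jm_spec(long_covariates = character(0),
                  surv_covariates = character(0),
                  random = "intercept", n_hazard_pieces = 2L, fast = TRUE)
  params <- list(beta = c(4.6, 0), sigma = 1e-7, D = matrix(0.25),
                 h0 = c(0.05, 0.05), gamma = numeric(0), alpha = 0)
  fit <- as_jm_fit(params, long, surv, NULL, spec, breaks = c(0, 1.5, 3))
  draws <- posterior_random_effects(fit, long, NULL, 0,
                                    risk_control(n_b = 50, method = "laplace",
                                                 seed = 2))
  expect_equal(mean(draws$b[, 1]), 5.1 - 4.6, tolerance = 1e-5)
  expect_lt(sd(draws$b[, 1]), 1e-5)
  expect_error(posterior_random_effects(fit, long[0, ], NULL, 0),
               "at least one measurement")
})

test_that("posterior random effects track the latent truth across subjects", {
  cc <- shared_cohort()
  fit <- shared_truth_fit()
  subjects <- head(cc$cohort$subjects, 120)
  ctrl <- risk_control(n_b = 60, method = "laplace", seed = 11)
  est <- t(vapply(seq_len(nrow(subjects)), function(i) {
    sid <- subjects$subject_id[i]
    sdat <- cc$cohort$longitudinal[cc$cohort$longitudinal$subject_id == sid, ]
    sdat <- sdat[sdat$time <= 0.75, ]
    if (!nrow(sdat)) return(c(NA_real_, NA_real_))
    dr <- posterior_random_effects(fit, sdat, subjects[i, ],
                                   max(sdat$time), ctrl)
    colMeans(dr$b)
  }, numeric(2)))
  ok <- complete.cases(est)
  expect_gt(cor(est[ok, 1], subjects$b0[ok]), 0.7)
})

test_that("independence-MH and Laplace posteriors agree on well-identified subjects", {
  cc <- shared_cohort()
  fit <- shared_truth_fit()
  sid <- cc$cohort$subjects$subject_id[3]
  sdat <- cc$cohort$longitudinal[cc$cohort$longitudinal$subject_id == sid, ]
  sub <- cc$cohort$subjects[3, ]
  t <- max(sdat$time)
  la <- posterior_random_effects(fit, sdat, sub, t,
                                 risk_control(n_b = 500, method = "laplace",
                                              seed = 21))
  mh <- posterior_random_effects(fit, sdat, sub, t,
                                 risk_control(n_b = 500, method = "mh",
                                              seed = 22))
  expect_equal(mean(mh$b[, 1]), mean(la$b[, 1]), tolerance = 0.05)
  expect_equal(sd(mh$b[, 1]), sd(la$b[, 1]), tolerance = 0.5)
})

test_that("more measurements shrink the random-effect posterior on average", {
  cc <- shared_cohort()
  fit <- shared_truth_fit()
  ctrl <- risk_control(n_b = 150, method = "laplace", seed = 31)
  ids <- head(cc$cohort$subjects$subject_id[
    cc$cohort$subjects$true_event_time > 2], 25)
  sds <- vapply(ids, function(sid) {
    sdat <- cc$cohort$longitudinal[cc$cohort$longitudinal$subject_id == sid, ]
    few <- posterior_random_effects(fit, sdat[sdat$time <= 0.5, ],
                                    cc$cohort$subjects[cc$cohort$subjects$subject_id == sid, ],
                                    0.5, ctrl)
    many <- posterior_random_effects(fit, sdat[sdat$time <= 1.75, ],
                                     cc$cohort$subjects[cc$cohort$subjects$subject_id == sid, ],
                                     1.75, ctrl)
    c(sd(few$b[, 2]), sd(many$b[, 2]))
  }, numeric(2))
  expect_lt(mean(sds[2, ]), mean(sds[1, ]))
})

test_that("expected information gain is non-negative and vanishes for an uninformative biomarker", {
  ff <- flat_fit(h = 0.1)
  ctrl <- risk_control(n_b = 200, method = "laplace", outer_draws = 100,
                       seed = 41)
  draws <- posterior_random_effects(ff$fit, ff$data, NULL, 0.5, ctrl)
  for (u in c(0.8, 1.5, 2.5)) {
    ig <- expected_info_gain(ff$fit, ff$data, NULL, 0.5, u, horizon = 3,
                             draws = draws, control = ctrl)
    expect_gte(ig$ekl, 0)
    expect_lte(ig$ekl, 2 * max(ig$mc_se, 1e-12)) # zero within MC error
  }
})

test_that("information gain is positive under association and respects grid refinement", {
  cc <- shared_cohort()
  fit <- shared_truth_fit()
  sid <- cc$cohort$subjects$subject_id[5]
  sdat <- cc$cohort$longitudinal[cc$cohort$longitudinal$subject_id == sid &
                                   cc$cohort$longitudinal$time <= 0.5, ]
  sub <- cc$cohort$subjects[5, ]
  base <- risk_control(n_b = 400, method = "laplace", outer_draws = 400,
                       seed = 51)
  draws <- posterior_random_effects(fit, sdat, sub, 0.5, base)
  ig1 <- expected_info_gain(fit, sdat, sub, 0.5, 1.25, draws = draws,
                            control = base)
  expect_gt(ig1$ekl, 0)
  fine <- base
  fine$density_grid <- 2L * base$density_grid
  ig2 <- expected_info_gain(fit, sdat, sub, 0.5, 1.25, draws = draws,
                            control = fine)
  expect_equal(ig2$ekl, ig1$ekl, tolerance = 0.05)
})

test_that("a noisier assay yields less expected information on average", {
  cc <- shared_cohort()
  quiet <- true_params(cc$config)
  noisy <- quiet
  noisy$sigma <- quiet$sigma * 6
  igs <- vapply(list(quiet, noisy), function(p) {
    fit <- as_jm_fit(p, cc$cohort$longitudinal, cc$cohort$survival,
                     cc$cohort$subjects, test_spec(),
                     breaks = seq(0, 3, length.out = 4))
    ctrl <- risk_control(n_b = 300, method = "laplace", outer_draws = 200,
                         seed = 61)
    mean(vapply(c(3, 5, 8), function(i) {
      sid <- cc$cohort$subjects$subject_id[i]
      sdat <- cc$cohort$longitudinal[cc$cohort$longitudinal$subject_id == sid &
                                       cc$cohort$longitudinal$time <= 0.5, ]
      expected_info_gain(fit, sdat, cc$cohort$subjects[i, ], 0.5, 1.5,
                         control = ctrl)$ekl
    }, numeric(1)))
  }, numeric(1))
  expect_lt(igs[2], igs[1])
})

test_that("risk profiles export tidily and plot without error", {
  ff <- flat_fit()
  ctrl <- risk_control(n_b = 100, method = "laplace", seed = 71)
  rp <- risk_profile(ff$fit, ff$data, NULL, 0.5, horizon = 3, control = ctrl)
  expect_s3_class(rp, "risk_profile")
  expect_true(all(rp$lower <= rp$risk + 1e-12 & rp$risk <= rp$upper + 1e-12))
  expect_equal(rp$risk[1], 0)
  pdf(NULL)
  expect_silent(plot(rp))
  dev.off()
})
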