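# Joint model: likelihood cross-checks against independent oracles,
# input validation, the HR transform, and single-cohort estimation.

test_that("joint log-likelihood matches brute-force grid integration on a toy dataset", {
  toy <- toy_data()
  spec <- jm_spec(long_covariates = character(0),
                  surv_covariates = character(0),
                  n_hazard_pieces = 2L, gh_nodes = 15L, quad_nodes = 15L)
  ll_pkg <- joint_loglik(toy$params, toy$long, toy$surv, NULL, spec,
                         toy$breaks)
  ll_brute <- 0
  for (id in c("A", "B", "C")) {
    sel <- toy$long$subject_id == id
    i <- match(id, toy$surv$subject_id)
    ll_brute <- ll_brute +
      brute_loglik_subject(toy$long$log_value[sel], toy$long$time[sel],
                           toy$surv$observed_time[i], toy$surv$event[i],
                           toy$params, toy$breaks)
  }
  expect_equal(ll_pkg, ll_brute, tolerance = 1e-4)
})

test_that("doubling the hazard quadrature nodes leaves the log-likelihood unchanged", {
  toy <- toy_data()
  ll <- vapply(c(15L, 30L), function(nq) {
    spec <- jm_spec(long_covariates = character(0),
                    surv_covariates = character(0),
                    n_hazard_pieces = 2L, gh_nodes = 9L, quad_nodes = nq)
    joint_loglik(toy$params, toy$long, toy$surv, NULL, spec, toy$breaks)
  }, numeric(1))
  expect_lt(abs(ll[1] - ll[2]), 1e-4)
})

test_that("the degenerate longitudinal-only case reproduces an independent mixed model", {
  skip_if_not_installed("lme4")
  cfg <- cohort_config(n_subjects = 120, seed = 61, alpha = 0,
                       beta_cov = c(age10 = 0.04, sex = 0.15),
                       gamma = numeric(0), h0 = rep(1e-4, 5))
  coh <- generate_cohort(cfg)
  long <- coh$longitudinal
  surv <- coh$survival
  surv$event <- 0L # all censored: survival factor does not involve alpha

  W <- covariate_design(coh$subjects, c("age10", "sex"))
  df <- data.frame(y = long$log_value, tt = long$time,
                   id = long$subject_id,
                   W[match(long$subject_id, coh$subjects$subject_id), ])
  lmm <- lme4::lmer(y ~ tt + age10 + sex + (tt | id), data = df, REML = FALSE)
  vc <- lme4::VarCorr(lmm)$id

  ## joint likelihood at the mixed model's own estimates, with a vanishing
  ## hazard, equals the mixed model's maximized likelihood
  params <- list(beta = unname(lme4::fixef(lmm)), sigma = stats::sigma(lmm),
                 D = matrix(as.numeric(vc), 2) + diag(1e-10, 2),
                 h0 = rep(1e-12, 3), gamma = numeric(0), alpha = 0)
  spec <- jm_spec(long_covariates = c("age10", "sex"),
                  surv_covariates = character(0),
                  n_hazard_pieces = 3L, gh_nodes = 11L, quad_nodes = 7L)
  ll_joint <- joint_loglik(params, long, surv, coh$subjects, spec,
                           breaks = seq(0, 3, length.out = 4))
  expect_equal(ll_joint, as.numeric(stats::logLik(lmm)), tolerance = 1e-4)

  ## and the joint fit of the same data recovers the same longitudinal
  ## estimates (weak priors, hazard decoupled)
  fit <- fit_joint_model(long, surv, coh$subjects, spec)
  expect_equal(unname(fit$pars$beta), unname(lme4::fixef(lmm)),
               tolerance = 2e-3)
  expect_equal(fit$pars$sigma, stats::sigma(lmm), tolerance = 2e-3)
  expect_equal(sqrt(diag(fit$pars$D)), sqrt(diag(matrix(as.numeric(vc), 2))),
               tolerance = 0.02)
})

test_that("the HR per 20% change transform is the closed form and monotone", {
  expect_equal(hazard_ratio_per_20pct(0), 1)
  expect_equal(hazard_ratio_per_20pct(1), 1.2)
  expect_equal(hazard_ratio_per_20pct(-0.5), exp(-0.5 * log(1.2)))
  a <- seq(-3, 3, by = 0.25)
  hr <- hazard_ratio_per_20pct(a)
  expect_true(all(diff(hr) > 0))
  expect_true(all((hr > 1) == (a > 0)))

  ff <- flat_fit()
  h <- hazard_ratio_per_20pct(ff$fit)
  expect_s3_class(h, "jm_hr")
  expect_equal(h$hr, 1) # alpha = 0
})

test_that("input validation reports orphans, late measurements and bad values", {
  cc <- shared_cohort()
  clean <- validate_inputs(cc$cohort$longitudinal, cc$cohort$survival)
  expect_equal(nrow(clean), 0)

  long <- cc$cohort$longitudinal
  surv <- cc$cohort$survival
  late <- long
  late$time[1] <- surv$observed_time[match(late$subject_id[1],
                                           surv$subject_id)] + 0.5
  rep1 <- validate_inputs(late, surv)
  expect_equal(sum(rep1$finding == "measurement_after_observed_time" &
                     rep1$fatal), 1)

  zero <- long
  zero$value[2] <- 0
  rep2 <- validate_inputs(zero, surv)
  expect_true(any(rep2$finding == "non_positive_value" & rep2$fatal))

  dup <- rbind(long, long[1, ])
  expect_true(any(validate_inputs(dup, surv)$finding == "duplicated_measurement"))

  orphan <- long
  orphan$subject_id[1] <- "GHOST"
  expect_true(any(validate_inputs(orphan, surv)$finding ==
                    "orphan_longitudinal_subject"))
  expect_error(fit_joint_model(orphan, surv, cc$cohort$subjects, test_spec()),
               "GHOST")
})

test_that("a single-cohort fit recovers the generative parameters", {
  cc <- shared_cohort()
  fit <- shared_fit()
  expect_true(fit$converged)
  sm <- summary(fit)$table
  pick <- function(nm) sm[sm$parameter == nm, ]

  b1 <- pick("beta.time")
  expect_true(b1$lower <= cc$config$beta1 && cc$config$beta1 <= b1$upper)
  sg <- pick("log_sigma") # natural scale in the summary table
  expect_true(sg$lower <= cc$config$sigma && cc$config$sigma <= sg$upper)
  al <- pick("alpha")
  expect_true(al$lower <= cc$config$alpha && cc$config$alpha <= al$upper)
  expect_gt(al$estimate, 0)

  hr <- hazard_ratio_per_20pct(fit)
  expect_gt(hr$hr, 1)
  expect_true(hr$lower < 1.2^cc$config$alpha && 1.2^cc$config$alpha < hr$upper)
})

test_that("fit JSON round-trips and supports dynamic prediction", {
  fit <- shared_fit()
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- read_fit_json(path)
  expect_equal(back$theta, fit$theta, tolerance = 1e-12)
  expect_equal(back$breaks, fit$breaks)
  expect_equal(back$pars$alpha, fit$pars$alpha)

  cc <- shared_cohort()
  sid <- cc$cohort$subjects$subject_id[1]
  sdat <- cc$cohort$longitudinal[cc$cohort$longitudinal$subject_id == sid &
                                   cc$cohort$longitudinal$time <= 0.5, ]
  sub <- cc$cohort$subjects[1, ]
  ctrl <- risk_control(n_b = 100, method = "laplace", seed = 1)
  r1 <- cumulative_risk(fit, sdat, sub, 0.5, 1.5, control = ctrl)
  r2 <- cumulative_risk(back, sdat, sub, 0.5, 1.5, control = ctrl)
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("MCMC mode runs and reports convergence diagnostics", {
  cfg <- calibrate_event_rate(test_config(seed = 71, n_subjects = 60),
                              n_mc = 2000L)
  coh <- generate_cohort(cfg)
  spec <- test_spec(method = "mcmc", chains = 2L, iter = 150L, burn = 50L)
  fit <- withr::with_seed(7, suppressWarnings(
    fit_joint_model(coh$longitudinal, coh$survival, coh$subjects, spec)))
  expect_false(is.null(fit$draws))
  expect_equal(nrow(fit$draws), 300)
  expect_length(fit$diagnostics$rhat, length(fit$theta))
  expect_length(fit$diagnostics$ess, length(fit$theta))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  ## short chains are allowed to be flagged, but never silently
  expect_type(fit$converged, "logical")
})
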