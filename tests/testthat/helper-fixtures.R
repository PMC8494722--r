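# Shared fixtures and independent oracles. Heavy objects are cached per
# session so several test files can reuse them.

.fx <- new.env(parent = emptyenv())

## Reduced-dimension spec used throughout the tests: two baseline
## covariates, three hazard pieces, fast quadrature.
test_spec <- function(...) {
  jm_spec(long_covariates = c("age10", "sex"),
          surv_covariates = c("age10", "sex"),
          n_hazard_pieces = 3L, fast = TRUE, ...)
}

## Matching generator configuration (covariate effects restricted to the
## same columns so the fitted model is correctly specified).
test_config <- function(seed = 101L, n_subjects = 263L, ...) {
  cohort_config(n_subjects = n_subjects, seed = seed,
                beta_cov = c(age10 = 0.04, sex = 0.15),
                gamma = c(age10 = 0.30, sex = 0.20), ...)
}

## True generative parameters expressed on the fitter's scale (flat hazard
## equal to the calibrated pieces, which are constant by construction).
true_params <- function(cfg, n_pieces = 3L) {
  list(beta = c(cfg$beta0, cfg$beta1, unname(cfg$beta_cov)),
       sigma = cfg$sigma, D = cfg$D,
       h0 = rep(cfg$h0[1], n_pieces),
       gamma = unname(cfg$gamma), alpha = cfg$alpha)
}

## One calibrated cohort shared across test files.
shared_cohort <- function() {
  if (is.null(.fx$cohort)) {
    cfg <- calibrate_event_rate(test_config(), n_mc = 4000L)
    .fx$config <- cfg
    .fx$cohort <- generate_cohort(cfg)
  }
  list(config = .fx$config, cohort = .fx$cohort)
}

## One MAP fit of the shared cohort.
shared_fit <- function() {
  if (is.null(.fx$fit)) {
    cc <- shared_cohort()
    .fx$fit <- fit_joint_model(cc$cohort$longitudinal, cc$cohort$survival,
                               cc$cohort$subjects, test_spec())
  }
  .fx$fit
}

## Fit object fixed at the true generative parameters of the shared cohort
## (equal-width hazard breaks matching the generator).
shared_truth_fit <- function() {
  if (is.null(.fx$truth_fit)) {
    cc <- shared_cohort()
    .fx$truth_fit <- as_jm_fit(true_params(cc$config),
                               cc$cohort$longitudinal, cc$cohort$survival,
                               cc$cohort$subjects, test_spec(),
                               breaks = seq(0, 3, length.out = 4L))
  }
  .fx$truth_fit
}

## A biomarker-independent reference fit: alpha = 0, no covariates,
## constant hazard `h`. Admits closed-form conditional risks.
flat_fit <- function(h = 0.1) {
  long <- data.frame(subject_id = c("A", "A", "A", "B"),
                     time = c(0, 0.25, 0.5, 0),
                     log_value = c(4.6, 4.65, 4.55, 4.5))
  long$value <- exp(long$log_value)
  surv <- data.frame(subject_id = c("A", "B"),
                     observed_time = c(1, 2), event = c(0L, 1L))
  spec <- jm_spec(long_covariates = character(0),
                  surv_covariates = character(0),
                  n_hazard_pieces = 2L, fast = TRUE)
  params <- list(beta = c(4.6, 0), sigma = 0.1,
                 D = matrix(c(0.09, 0, 0, 0.01), 2),
                 h0 = c(h, h), gamma = numeric(0), alpha = 0)
  list(fit = as_jm_fit(params, long, surv, NULL, spec, breaks = c(0, 1.5, 3)),
       data = long[long$subject_id == "A", ],
       params = params)
}

## Independent brute-force joint log-likelihood for a single subject:
## tensor Simpson rule over the random effects; cumulative hazard by fine
## trapezoid WITHIN each hazard piece (the integrand jumps at the piece
## boundaries, so each segment is integrated separately).
brute_loglik_subject <- function(y, tt, Tobs, delta, params, breaks,
                                 nb = 201L, ns = 401L, half = 6) {
  stopifnot(nb %% 2 == 1)
  h0fun <- function(s) params$h0[pmax(pmin(findInterval(s, breaks,
                                                        left.open = TRUE),
                                           length(params$h0)), 1L)]
  K <- length(params$h0)
  segs <- lapply(seq_len(K), function(p) {
    lo <- breaks[p]
    hi <- if (p < K) min(breaks[p + 1], Tobs) else Tobs
    if (hi <= lo) return(NULL)
    list(h0 = params$h0[p], sg = seq(lo, hi, length.out = ns))
  })
  segs <- Filter(Negate(is.null), segs)
  cumhaz <- function(b0, b1) {
    sum(vapply(segs, function(sg) {
      f <- sg$h0 * exp(params$alpha *
                         (params$beta[1] + params$beta[2] * sg$sg +
                            b0 + b1 * sg$sg))
      sum((f[-1] + f[-length(f)]) / 2 * diff(sg$sg))
    }, numeric(1)))
  }
  sdb <- sqrt(diag(params$D))
  b0g <- seq(-half * sdb[1], half * sdb[1], length.out = nb)
  b1g <- seq(-half * sdb[2], half * sdb[2], length.out = nb)
  simpson_w <- function(g) {
    w <- rep(c(2, 4), length.out = length(g)); w[1] <- w[length(g)] <- 1
    w * diff(g[1:2]) / 3
  }
  w0 <- simpson_w(b0g); w1 <- simpson_w(b1g)
  Dinv <- solve(params$D)
  ldD <- determinant(params$D, logarithm = TRUE)$modulus[1]
  tot <- 0
  for (i in seq_along(b0g)) {
    b0 <- b0g[i]
    lf <- vapply(b1g, function(b1) {
      m <- params$beta[1] + params$beta[2] * tt + b0 + b1 * tt
      lon <- -sum((y - m)^2) / (2 * params$sigma^2) -
        length(y) * log(params$sigma * sqrt(2 * pi))
      mT <- params$beta[1] + params$beta[2] * Tobs + b0 + b1 * Tobs
      ev <- delta * (log(h0fun(Tobs)) + params$alpha * mT) - cumhaz(b0, b1)
      pr <- -0.5 * (Dinv[1, 1] * b0^2 + 2 * Dinv[1, 2] * b0 * b1 +
                      Dinv[2, 2] * b1^2) - log(2 * pi) - 0.5 * ldD
      lon + ev + pr
    }, numeric(1))
    tot <- tot + w0[i] * sum(w1 * exp(lf))
  }
  log(tot)
}

## Shared 3-subject toy dataset for likelihood cross-checks.
toy_data <- function() {
  long <- data.frame(
    subject_id = rep(c("A", "B", "C"), times = c(3, 2, 4)),
    time = c(0, 0.25, 0.5, 0, 0.5, 0, 0.25, 0.5, 0.75),
    log_value = c(4.5, 4.6, 4.4, 4.9, 5.1, 4.2, 4.25, 4.35, 4.5)
  )
  long$value <- exp(long$log_value)
  surv <- data.frame(subject_id = c("A", "B", "C"),
                     observed_time = c(0.8, 0.6, 1.2),
                     event = c(1L, 0L, 1L))
  params <- list(beta = c(4.5, 0.1), sigma = 0.12,
                 D = matrix(c(0.09, 0.01, 0.01, 0.04), 2),
                 h0 = c(0.2, 0.3), gamma = numeric(0), alpha = 0.8)
  list(long = long, surv = surv, params = params, breaks = c(0, 0.5, 1.2))
}

## Hand-built risk_draws object at fixed parameters and a single known b.
fixed_b_draws <- function(fit, data, covariates, t, b) {
  ctx <- persched:::pred_context(fit, data, covariates, t)
  bmat <- matrix(b, 1, 2)
  H <- persched:::cumhaz_pred(fit$pars, ctx, bmat, t, fit$breaks,
                              fit$spec$quad_nodes)
  structure(list(ctx = ctx, pars_list = list(fit$pars), b = bmat,
                 theta_idx = 1L, St = exp(-drop(H)), t = t,
                 control = risk_control(n_b = 1L), breaks = fit$breaks,
                 nq = fit$spec$quad_nodes),
            class = "risk_draws")
}
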