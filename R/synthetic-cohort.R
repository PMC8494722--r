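#' @name synthetic-cohort
#' @title Synthetic chronic-heart-failure cohort with known ground truth
#'
#' @description The generator emulates a prospective CHF cohort with
#' trimonthly biomarker sampling and a composite cardiac endpoint. Every
#' latent quantity (random effects, true event time) is retained so that
#' downstream model fitting and scheduling can be evaluated against truth;
#' the truth table is never visible to the scheduler.
NULL

## Names of the centred covariate design columns available to beta_cov/gamma.
design_columns <- function() {
  c("age10", "sex", "diabetes", "afib", "nyha_c", "diuretics", "sbp10", "egfr10")
}

#' Centred covariate design matrix for the generative model
#'
#' Continuous covariates are centred at typical cohort values and scaled to
#' clinically interpretable units: `age10` = (age - 67)/10, `sbp10` =
#' (systolic BP - 122)/10, `egfr10` = (baseline eGFR - 58)/10, `nyha_c` =
#' NYHA class - 2. Binary covariates enter as 0/1.
#'
#' @param subjects subjects data frame (see [generate_baseline()]).
#' @param cols subset of [design_columns()] to return.
#' @return numeric matrix with one row per subject.
#' @export
covariate_design <- function(subjects, cols = design_columns()) {
  full <- cbind(
    age10 = (subjects$age - 67) / 10,
    sex = subjects$sex,
    diabetes = subjects$diabetes,
    afib = subjects$atrial_fibrillation,
    nyha_c = subjects$nyha_class - 2,
    diuretics = subjects$diuretics,
    sbp10 = (subjects$systolic_bp - 122) / 10,
    egfr10 = (subjects$baseline_egfr - 58) / 10
  )
  full[, cols, drop = FALSE]
}

clamp <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

#' Draw baseline subjects
#'
#' Draws `n_subjects` subjects: baseline covariates from the configured
#' independent marginal distributions, random effects from N(0, D), entry
#' times (if staggered entry is configured) and the resulting censoring
#' times. Event times are not drawn here; see [sample_event_time()] and
#' [generate_cohort()].
#'
#' @param config a [cohort_config()].
#' @return data frame with one row per subject: identifiers, covariates,
#'   latent random effects `b0`, `b1`, linear predictors `eta_long`
#'   (`beta_cov' w`) and `eta_surv` (`gamma' w`), `entry_time` and
#'   `censor_time`.
#' @export
generate_baseline <- function(config) {
  validate_cohort_config(config)
  n <- config$n_subjects
  cv <- config$covariates
  if (cv$age_sd < 0 || cv$sbp_sd < 0 || cv$egfr_sd < 0 ||
      any(cv$nyha_probs < 0) || abs(sum(cv$nyha_probs) - 1) > 1e-8) {
    stop_config("covariates", "invalid distribution parameters")
  }
  subjects <- withr::with_seed(mix_seed(config$seed, "baseline"), {
    df <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = clamp(rnorm(n, cv$age_mean, cv$age_sd), cv$bounds$age),
      sex = rbinom(n, 1, cv$sex_p),
      diabetes = rbinom(n, 1, cv$diabetes_p),
      atrial_fibrillation = rbinom(n, 1, cv$afib_p),
      nyha_class = sample.int(4L, n, replace = TRUE, prob = cv$nyha_probs),
      diuretics = rbinom(n, 1, cv$diuretics_p),
      systolic_bp = clamp(rnorm(n, cv$sbp_mean, cv$sbp_sd), cv$bounds$systolic_bp),
      baseline_egfr = clamp(rnorm(n, cv$egfr_mean, cv$egfr_sd),
                            cv$bounds$baseline_egfr),
      stringsAsFactors = FALSE
    )
    b <- MASS::mvrnorm(max(n, 2), mu = c(0, 0), Sigma = config$D)[seq_len(n), , drop = FALSE]
    df$b0 <- b[, 1]
    df$b1 <- b[, 2]
    df$entry_time <- if (config$recruitment_years > 0) {
      runif(n, 0, config$recruitment_years)
    } else rep(0, n)
    censor <- pmin(config$max_followup, config$study_years - df$entry_time)
    if (config$dropout_rate > 0) {
      censor <- pmin(censor, rexp(n, config$dropout_rate))
    }
    df$censor_time <- censor
    df
  })
  if (n > 0) {
    w_long <- covariate_design(subjects, names(config$beta_cov))
    w_surv <- covariate_design(subjects, names(config$gamma))
    subjects$eta_long <- if (length(config$beta_cov)) {
      drop(w_long %*% config$beta_cov)
    } else rep(0, n)
    subjects$eta_surv <- if (length(config$gamma)) {
      drop(w_surv %*% config$gamma)
    } else rep(0, n)
  } else {
    subjects$eta_long <- numeric(0)
    subjects$eta_surv <- numeric(0)
  }
  subjects
}

#' True (noise-free) log-scale biomarker trajectory
#'
#' `m_i(t) = beta0 + beta1 t + beta_cov' w_i + b_i0 + b_i1 t`, deterministic
#' given the subject's latent random effects.
#'
#' @param subject one-row subjects data frame (or list with `eta_long`,
#'   `b0`, `b1`).
#' @param t vector of times (years, >= 0).
#' @param config the generating [cohort_config()].
#' @return numeric vector of log-scale levels.
#' @export
true_trajectory <- function(subject, t, config) {
  stopifnot(all(t >= 0))
  config$beta0 + config$beta1 * t + subject$eta_long +
    subject$b0 + subject$b1 * t
}

#' Observe a noisy biomarker measurement
#'
#' Adds N(0, sigma^2) assay/biological noise on the log scale. The noise
#' stream is seeded per (subject, time) from the master seed, so
#' re-requesting the same measurement reproduces the same value — the
#' scheduler can ask for a measurement at any time and the underlying
#' "reality" stays fixed.
#'
#' @inheritParams true_trajectory
#' @return data frame with columns `subject_id`, `time`, `biomarker`,
#'   `value`, `log_value` (one row per element of `t`).
#' @export
observe_biomarker <- function(subject, t, config) {
  stopifnot(all(t >= 0))
  m <- true_trajectory(subject, t, config)
  eps <- hash_normal(config$seed, "obs", subject$subject_id, t)
  log_value <- m + config$sigma * eps
  data.frame(
    subject_id = subject$subject_id,
    time = t,
    biomarker = config$biomarker_name,
    value = exp(log_value),
    log_value = log_value,
    stringsAsFactors = FALSE
  )
}

## Piecewise-constant baseline-hazard breakpoints (equal width on
## [0, max_followup]); the last piece extends beyond the cap.
hazard_breaks <- function(config) {
  seq(0, config$max_followup, length.out = length(config$h0) + 1L)
}

## Cumulative generative hazard H_i(t_i) for each subject at its own time,
## by Gauss-Legendre quadrature within hazard pieces.
## subjects: data frame rows aligned with t. Returns numeric vector.
cumhaz_true <- function(subjects, t, config) {
  n <- nrow(subjects)
  if (n == 0L) return(numeric(0))
  stopifnot(length(t) == n)
  breaks <- hazard_breaks(config)
  K <- length(config$h0)
  rule <- gl_nodes(config$quad_nodes)
  ## hazard: h0(s) * exp(eta_surv + alpha * m_i(s))
  ##       = h0(s) * exp(A_i + B_i s),
  A <- subjects$eta_surv + config$alpha *
    (config$beta0 + subjects$eta_long + subjects$b0)
  B <- config$alpha * (config$beta1 + subjects$b1)
  H <- numeric(n)
  for (p in seq_len(K)) {
    lo <- breaks[p]
    hi <- if (p < K) pmin(breaks[p + 1], t) else t
    act <- which(t > lo)
    if (!length(act)) next
    sc <- gl_rescale(rule, rep(lo, length(act)), hi[act])
    f <- config$h0[p] * exp(A[act] + B[act] * sc$x) # len(act) x m
    H[act] <- H[act] + rowSums(sc$w * f)
  }
  if (any(!is.finite(H))) {
    bad <- subjects$subject_id[!is.finite(H)]
    stop(sprintf("non-finite hazard while generating event times for subject(s): %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  H
}

#' Sample true event times from the generative hazard
#'
#' Draws E ~ Exponential(1) per subject and solves the cumulative-hazard
#' equation H_i(T) = E by bisection on `[0, t_max_search]` (cumulative
#' hazard by Gauss-Legendre quadrature within hazard pieces). Subjects whose
#' cumulative hazard never reaches E within the search horizon get `Inf`
#' (no event).
#'
#' @param subjects subjects data frame from [generate_baseline()].
#' @param config the generating [cohort_config()].
#' @param E optional vector of unit-exponential draws (for testing);
#'   drawn from the `"event"` substream of the master seed when `NULL`.
#' @return numeric vector of event times (years; `Inf` = none in horizon).
#' @export
sample_event_time <- function(subjects, config, E = NULL) {
  n <- nrow(subjects)
  if (n == 0L) return(numeric(0))
  if (is.null(E)) {
    E <- withr::with_seed(mix_seed(config$seed, "event"), rexp(n))
  }
  tmax <- config$t_max_search
  Hmax <- cumhaz_true(subjects, rep(tmax, n), config)
  out <- rep(Inf, n)
  solve_idx <- which(Hmax >= E)
  if (length(solve_idx)) {
    lo <- rep(0, length(solve_idx))
    hi <- rep(tmax, length(solve_idx))
    sub <- subjects[solve_idx, , drop = FALSE]
    for (it in seq_len(64L)) {
      mid <- (lo + hi) / 2
      Hm <- cumhaz_true(sub, mid, config)
      below <- Hm < E[solve_idx]
      lo[below] <- mid[below]
      hi[!below] <- mid[!below]
      if (max(hi - lo) < 1e-9) break
    }
    out[solve_idx] <- (lo + hi) / 2
  }
  out
}

#' Calibrate the baseline hazard to a target event proportion
#'
#' Rescales the baseline-hazard pieces `h0` by a scalar `s` so that the
#' Monte-Carlo expected endpoint proportion under the config's censoring
#' scheme equals `target_event_rate`. Under common random numbers the event
#' indicator is `s * H_i(C_i) >= E_i`, so the proportion is a step function
#' of `s` whose exact root is the target-quantile of the ratios
#' `E_i / H_i(C_i)`; the calibration inverts that quantile directly (a fixed
#' inner seed makes it deterministic).
#'
#' @param config a [cohort_config()].
#' @param n_mc Monte-Carlo cohort size used for the calibration objective.
#' @return the config with `h0` rescaled (attribute `"calibration_scalar"`
#'   records the factor).
#' @export
calibrate_event_rate <- function(config, n_mc = 20000L) {
  validate_cohort_config(config)
  target <- config$target_event_rate
  if (target <= 0 || target >= 1) {
    stop_config("target_event_rate", "calibration requires a rate in (0, 1)")
  }
  big <- config
  big$n_subjects <- as.integer(n_mc)
  big$seed <- mix_seed(config$seed, "calibrate")
  subjects <- generate_baseline(big)
  E <- withr::with_seed(mix_seed(big$seed, "event"), rexp(n_mc))
  H1 <- cumhaz_true(subjects, subjects$censor_time, big)
  r <- E / H1
  s <- unname(quantile(r, target, type = 1))
  if (!is.finite(s) || s < 1e-6 || s > 1e6) {
    stop(sprintf("calibration error: required hazard scalar %.3g outside [1e-6, 1e6]", s),
         call. = FALSE)
  }
  config$h0 <- config$h0 * s
  attr(config, "calibration_scalar") <- s
  config
}

#' Generate a full synthetic cohort
#'
#' Draws baseline subjects, true event times, the trimonthly visit grid
#' truncated at `min(true event, censoring)` (strictly before the event;
#' the censoring visit itself is kept), and noisy biomarker measurements at
#' every visit. Bit-reproducible given the config's seed.
#'
#' @param config a (typically calibrated) [cohort_config()].
#' @return object of class `chf_cohort`: list with data frames
#'   `longitudinal` (subject_id, time, biomarker, value, log_value),
#'   `survival` (subject_id, observed_time, event), and `subjects`
#'   (covariates plus latent truth), plus the `config`.
#' @export
generate_cohort <- function(config) {
  subjects <- generate_baseline(config)
  subjects$true_event_time <- sample_event_time(subjects, config)
  subjects$observed_time <- pmin(subjects$true_event_time, subjects$censor_time)
  subjects$event <- as.integer(subjects$true_event_time <= subjects$censor_time)
  long <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    visits <- visit_grid(subjects$true_event_time[i], subjects$censor_time[i],
                         config$visit_interval)
    long[[i]] <- observe_biomarker(subjects[i, ], visits, config)
  }
  structure(list(
    longitudinal = do.call(rbind, long) %||%
      data.frame(subject_id = character(), time = numeric(),
                 biomarker = character(), value = numeric(),
                 log_value = numeric()),
    survival = data.frame(subject_id = subjects$subject_id,
                          observed_time = subjects$observed_time,
                          event = subjects$event,
                          stringsAsFactors = FALSE),
    subjects = subjects,
    config = config
  ), class = "chf_cohort")
}

## Scheduled visit times: multiples of the interval up to the censoring time
## (inclusive, with tolerance) and strictly before the event time.
visit_grid <- function(event_time, censor_time, interval) {
  end <- min(event_time, censor_time)
  k <- floor(censor_time / interval + 1e-9)
  t <- seq(0, by = interval, length.out = k + 1L)
  t[t < event_time - 1e-12 & t <= censor_time + 1e-9]
}

#' @export
print.chf_cohort <- function(x, ...) {
  n <- nrow(x$subjects)
  cat(sprintf("Synthetic CHF cohort: %d subjects, %d %s measurements\n",
              n, nrow(x$longitudinal), x$config$biomarker_name))
  if (n) {
    cat(sprintf("  events: %d (%.1f%%); median follow-up %.2f yr; median %d samples/subject\n",
                sum(x$survival$event), 100 * mean(x$survival$event),
                median(x$survival$observed_time),
                as.integer(median(table(x$longitudinal$subject_id)))))
  }
  invisible(x)
}

#' Write / read a cohort as plain-text CSV
#'
#' Three files in `dir`: `longitudinal.csv` (subject_id, time_years,
#' biomarker, value), `survival.csv` (subject_id, observed_time_years,
#' event) and `truth.csv` (covariates and latent fields; clearly labelled
#' and never read by the scheduler). UTF-8, "." decimal, header rows.
#'
#' @param cohort a `chf_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir` (write) or a `chf_cohort` without config (read), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "chf_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- cohort$longitudinal
  write.csv(data.frame(subject_id = long$subject_id,
                       time_years = long$time,
                       biomarker = long$biomarker,
                       value = long$value),
            file.path(dir, "longitudinal.csv"), row.names = FALSE)
  write.csv(data.frame(subject_id = cohort$survival$subject_id,
                       observed_time_years = cohort$survival$observed_time,
                       event = cohort$survival$event),
            file.path(dir, "survival.csv"), row.names = FALSE)
  write.csv(cohort$subjects, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  long_path <- file.path(dir, "longitudinal.csv")
  surv_path <- file.path(dir, "survival.csv")
  for (p in c(long_path, surv_path)) {
    if (!file.exists(p)) stop(sprintf("missing cohort file '%s'", p), call. = FALSE)
  }
  long_raw <- read.csv(long_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_years", "biomarker", "value")
  missing_cols <- setdiff(need, names(long_raw))
  if (length(missing_cols)) {
    stop(sprintf("longitudinal.csv lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  surv_raw <- read.csv(surv_path, stringsAsFactors = FALSE)
  need_s <- c("subject_id", "observed_time_years", "event")
  missing_s <- setdiff(need_s, names(surv_raw))
  if (length(missing_s)) {
    stop(sprintf("survival.csv lacks column(s): %s",
                 paste(missing_s, collapse = ", ")), call. = FALSE)
  }
  truth_path <- file.path(dir, "truth.csv")
  structure(list(
    longitudinal = data.frame(subject_id = long_raw$subject_id,
                              time = long_raw$time_years,
                              biomarker = long_raw$biomarker,
                              value = long_raw$value,
                              log_value = log(long_raw$value),
                              stringsAsFactors = FALSE),
    survival = data.frame(subject_id = surv_raw$subject_id,
                          observed_time = surv_raw$observed_time_years,
                          event = surv_raw$event,
                          stringsAsFactors = FALSE),
    subjects = if (file.exists(truth_path)) {
      read.csv(truth_path, stringsAsFactors = FALSE)
    } else NULL,
    config = NULL
  ), class = "chf_cohort")
}
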