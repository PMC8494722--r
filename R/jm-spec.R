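#' Specification of the joint model
#'
#' Defines the longitudinal submodel (fixed intercept + slope + baseline
#' covariates; random intercept or intercept + slope), the relative-risk
#' survival submodel (piecewise-constant baseline hazard on event-time
#' quantile knots, covariate coefficients, current-value association), and
#' the estimation settings.
#'
#' @param long_covariates,surv_covariates covariate design columns (see
#'   [covariate_design()]) entering the longitudinal and survival submodels.
#'   The defaults follow the clinical adjustment set: age, sex, diabetes,
#'   atrial fibrillation, NYHA class, diuretics and systolic blood pressure;
#'   set `tubular = TRUE` to add baseline eGFR (used when modelling tubular
#'   markers).
#' @param tubular add `egfr10` to both adjustment sets.
#' @param random `"intercept+slope"` (default) or `"intercept"`.
#' @param n_hazard_pieces number of baseline-hazard pieces (knots at
#'   event-time quantiles).
#' @param association only `"current-value"` is implemented; `"slope"` and
#'   `"area"` are recognised but unimplemented stubs.
#' @param quad_nodes Gauss-Legendre nodes per hazard piece for cumulative
#'   hazards (doubling them should leave the log-likelihood essentially
#'   unchanged).
#' @param gh_nodes adaptive Gauss-Hermite nodes per random-effect dimension.
#' @param method `"map"` (posterior mode + Laplace covariance; the fast
#'   reference mode) or `"mcmc"` (random-walk Metropolis started at the MAP).
#' @param chains,iter,burn MCMC settings (used when `method = "mcmc"`;
#'   `iter` counts post-burn-in draws per chain).
#' @param prior_sd SD of the weakly informative normal prior applied to every
#'   unconstrained-transformed parameter.
#' @param fast shrink quadrature sizes (`gh_nodes = 5`, `quad_nodes = 7`) for
#'   speed; intended for simulation experiments and tests.
#' @return object of class `jm_spec`.
#' @export
jm_spec <- function(long_covariates = c("age10", "sex", "diabetes", "afib",
                                        "nyha_c", "diuretics", "sbp10"),
                    surv_covariates = long_covariates,
                    tubular = FALSE,
                    random = c("intercept+slope", "intercept"),
                    n_hazard_pieces = 5L,
                    association = c("current-value", "slope", "area"),
                    quad_nodes = 15L,
                    gh_nodes = 7L,
                    method = c("map", "mcmc"),
                    chains = 2L, iter = 1000L, burn = 250L,
                    prior_sd = 10,
                    fast = FALSE) {
  association <- match.arg(association)
  if (association != "current-value") {
    stop("only the 'current-value' association is implemented", call. = FALSE)
  }
  if (tubular) {
    long_covariates <- union(long_covariates, "egfr10")
    surv_covariates <- union(surv_covariates, "egfr10")
  }
  if (fast) {
    gh_nodes <- 5L
    quad_nodes <- 7L
  }
  if (n_hazard_pieces < 1L) stop("n_hazard_pieces must be >= 1", call. = FALSE)
  if (iter <= 0L || burn < 0L) stop("need iter > 0 and burn >= 0", call. = FALSE)
  bad <- setdiff(c(long_covariates, surv_covariates), design_columns())
  if (length(bad)) {
    stop(sprintf("unknown covariate design columns: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(
    long_covariates = long_covariates,
    surv_covariates = surv_covariates,
    random = match.arg(random),
    n_hazard_pieces = as.integer(n_hazard_pieces),
    association = association,
    quad_nodes = as.integer(quad_nodes),
    gh_nodes = as.integer(gh_nodes),
    method = match.arg(method),
    chains = as.integer(chains), iter = as.integer(iter), burn = as.integer(burn),
    prior_sd = prior_sd,
    fast = fast
  ), class = "jm_spec")
}

#' @export
print.jm_spec <- function(x, ...) {
  cat("Joint model specification\n")
  cat(sprintf("  longitudinal: log(value) ~ 1 + time + %s; random: %s\n",
              paste(x$long_covariates, collapse = " + "), x$random))
  cat(sprintf("  survival: %d hazard pieces; covariates %s; association: %s\n",
              x$n_hazard_pieces, paste(x$surv_covariates, collapse = " + "),
              x$association))
  cat(sprintf("  estimation: %s (GH %d^d, GL %d/piece)\n",
              x$method, x$gh_nodes, x$quad_nodes))
  invisible(x)
}

#' Validate longitudinal/survival inputs before fitting
#'
#' Report-only check for the data contract of [fit_joint_model()]: subjects
#' present in one table but not the other, measurements recorded after the
#' observed survival time, non-positive biomarker values (log undefined),
#' duplicated (subject, time) rows, and survival subjects with no
#' measurement at all.
#'
#' @param longitudinal data frame with `subject_id`, `time`, `value` (or
#'   `log_value`).
#' @param survival data frame with `subject_id`, `observed_time`, `event`.
#' @return object of class `jm_validation`: a data frame of findings with
#'   columns `finding`, `subject_id`, `detail`, `fatal` (zero rows = clean).
#' @export
validate_inputs <- function(longitudinal, survival) {
  findings <- list()
  add <- function(finding, ids, detail, fatal) {
    if (length(ids)) {
      findings[[length(findings) + 1L]] <<- data.frame(
        finding = finding, subject_id = as.character(ids),
        detail = detail, fatal = fatal, stringsAsFactors = FALSE)
    }
  }
  orphan_long <- setdiff(unique(longitudinal$subject_id), survival$subject_id)
  add("orphan_longitudinal_subject", orphan_long,
      "measurements without a survival record", TRUE)
  no_meas <- setdiff(survival$subject_id, unique(longitudinal$subject_id))
  add("subject_without_measurements", no_meas,
      "survival record but zero measurements", TRUE)
  obs_time <- survival$observed_time[match(longitudinal$subject_id,
                                           survival$subject_id)]
  late <- longitudinal$subject_id[!is.na(obs_time) &
                                    longitudinal$time > obs_time + 1e-9]
  add("measurement_after_observed_time", unique(late),
      "measurement time exceeds observed survival time", TRUE)
  if (!is.null(longitudinal$value)) {
    nonpos <- longitudinal$subject_id[longitudinal$value <= 0]
    add("non_positive_value", unique(nonpos),
        "value <= 0: log transform undefined", TRUE)
  }
  dup <- duplicated(longitudinal[, c("subject_id", "time")])
  add("duplicated_measurement", unique(longitudinal$subject_id[dup]),
      "duplicated (subject, time) row", TRUE)
  out <- if (length(findings)) do.call(rbind, findings) else {
    data.frame(finding = character(), subject_id = character(),
               detail = character(), fatal = logical(),
               stringsAsFactors = FALSE)
  }
  structure(out, class = c("jm_validation", "data.frame"))
}

#' @export
print.jm_validation <- function(x, ...) {
  if (!nrow(x)) {
    cat("Input validation: clean (no findings)\n")
  } else {
    cat(sprintf("Input validation: %d finding(s), %d fatal\n",
                nrow(x), sum(x$fatal)))
    print.data.frame(x)
  }
  invisible(x)
}
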