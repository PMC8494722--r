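# Screening strategies on subjects with known ground truth: personalized
# (risk-threshold + maximum expected information gain + stopping rule) and
# fixed trimonthly, both with a three-measurement run-in.

#' Screening schedule policy
#'
#' @param kind `"personalized"` or `"fixed"`.
#' @param kappa cumulative-risk stopping threshold (default 0.075: scheduling
#'   stops — flagging a high-risk interval — when the risk within the
#'   clinical window exceeds 7.5%).
#' @param delta clinical window in years (default 0.25 = 3 months).
#' @param run_in number of initial trimonthly measurements taken before any
#'   personalized decision (default 3: t = 0, 0.25, 0.5).
#' @param fixed_interval fixed-arm visit spacing in years (default 0.25).
#' @param grid_size candidate times for the information-gain search
#'   (default 16, equally spaced).
#' @param min_spacing smallest allowed gap to the next measurement (default
#'   half a month).
#' @param candidate_offsets optional fixed offsets (years after the current
#'   visit) overriding the information-gain candidate grid; used for
#'   degenerate policies in equivalence checks.
#' @return list of class `schedule_policy`.
#' @export
schedule_policy <- function(kind = c("personalized", "fixed"),
                            kappa = 0.075, delta = 0.25, run_in = 3L,
                            fixed_interval = 0.25, grid_size = 16L,
                            min_spacing = 1 / 24,
                            candidate_offsets = NULL) {
  kind <- match.arg(kind)
  stopifnot(kappa > 0, kappa <= 1, delta > 0, run_in >= 1, grid_size >= 2,
            fixed_interval > 0, min_spacing > 0)
  structure(list(kind = kind, kappa = kappa, delta = delta,
                 run_in = as.integer(run_in),
                 fixed_interval = fixed_interval,
                 grid_size = as.integer(grid_size),
                 min_spacing = min_spacing,
                 candidate_offsets = candidate_offsets),
            class = "schedule_policy")
}

#' Decide the next action at a screening visit
#'
#' Implements the personalized decision rule. If the cumulative risk within
#' the clinical window, `pi(t + delta | t)`, reaches `kappa`, scheduling
#' stops (high-risk interval flagged, intervention at `t`). Otherwise the
#' risk-threshold time `t_threshold` is located and the expected
#' information gain is evaluated on an equally spaced candidate grid over
#' `[t + min_spacing, t_threshold]`; the next measurement is placed at the
#' candidate with maximal expected gain (earliest time on ties).
#'
#' @param fit a `jm_fit`.
#' @param data subject measurements up to `t`.
#' @param covariates subject one-row covariate table.
#' @param t current visit time (years); subject must be event-free here.
#' @param policy a [schedule_policy()].
#' @param horizon administrative end of follow-up (years).
#' @param control a [risk_control()].
#' @return list of class `schedule_action`: `action` (`"stop"`,
#'   `"measure"`, or `"none"` past the horizon), `t`, `risk_window`,
#'   `t_threshold`, `u_next`, `ekl` (data frame of the candidate curve).
#' @export
next_action <- function(fit, data, covariates = NULL, t, policy,
                        horizon = 3, control = risk_control()) {
  if (t >= horizon - 1e-9) {
    return(structure(list(action = "none", t = t, risk_window = NA_real_,
                          t_threshold = NA_real_, u_next = NA_real_,
                          ekl = NULL), class = "schedule_action"))
  }
  draws <- posterior_random_effects(fit, data, covariates, t, control)
  risk_window <- cumulative_risk(fit, data, covariates, t,
                                 u = min(t + policy$delta, horizon),
                                 draws = draws)
  if (risk_window >= policy$kappa) {
    return(structure(list(action = "stop", t = t, risk_window = risk_window,
                          t_threshold = t, u_next = NA_real_, ekl = NULL),
                     class = "schedule_action"))
  }
  thr <- find_threshold_time(fit, data, covariates, t, kappa = policy$kappa,
                             horizon = horizon, draws = draws)
  t_thr <- if (thr$beyond_horizon) horizon else thr$t_threshold
  cand <- if (!is.null(policy$candidate_offsets)) {
    pmin(t + policy$candidate_offsets, horizon)
  } else {
    lo <- t + policy$min_spacing
    hi <- max(t_thr, lo + 1e-6)
    seq(lo, hi, length.out = policy$grid_size)
  }
  cand <- unique(pmin(pmax(cand, t + 1e-9), horizon))
  if (length(cand) == 1L) {
    ekl_df <- data.frame(u = cand, ekl = NA_real_, mc_se = NA_real_)
    u_star <- cand
  } else {
    ig <- lapply(cand, function(u) {
      expected_info_gain(fit, data, covariates, t, u, horizon = horizon,
                         draws = draws, control = control)
    })
    ekl_df <- data.frame(u = cand,
                         ekl = vapply(ig, `[[`, numeric(1), "ekl"),
                         mc_se = vapply(ig, `[[`, numeric(1), "mc_se"))
    best <- max(ekl_df$ekl)
    u_star <- min(ekl_df$u[ekl_df$ekl >= best - 1e-12]) # earliest tie-break
  }
  structure(list(action = "measure", t = t, risk_window = risk_window,
                 t_threshold = t_thr, u_next = u_star, ekl = ekl_df),
            class = "schedule_action")
}

new_outcome <- function(subject_id, strategy, times, followup, stopped,
                        intervention, true_event, horizon,
                        pre_run_in = FALSE) {
  structure(list(subject_id = subject_id, strategy = strategy,
                 measurement_times = times,
                 n_measurements = length(times),
                 followup_used = followup,
                 stopped_for_intervention = stopped,
                 intervention_time = intervention,
                 true_event_time = true_event,
                 event_within_horizon = is.finite(true_event) &&
                   true_event <= horizon,
                 pre_run_in_event = pre_run_in),
            class = "schedule_outcome")
}

#' @export
print.schedule_outcome <- function(x, ...) {
  cat(sprintf("%s schedule for %s: %d measurements over %.2f yr%s\n",
              x$strategy, x$subject_id, x$n_measurements, x$followup_used,
              if (x$stopped_for_intervention) {
                sprintf("; stopped for intervention at %.2f yr", x$intervention_time)
              } else ""))
  invisible(x)
}

run_in_times <- function(policy) {
  seq(0, by = policy$fixed_interval, length.out = policy$run_in)
}

## Measurements actually observable for a subject: strictly before the true
## event and not after the horizon.
observable <- function(times, true_event, horizon) {
  times[times < true_event - 1e-12 & times <= horizon + 1e-9]
}

#' Run the personalized strategy for one subject with known truth
#'
#' Starts from the trimonthly run-in, then iterates [next_action()]: each
#' scheduled measurement is drawn from the subject's true trajectory via
#' [observe_biomarker()], the risk profile is updated, and the loop ends at
#' a stop (high-risk flag), the true event (which occurs before the next
#' scheduled measurement), or the horizon. The subject's true event time is
#' never visible to the decision rule — only the measurements are.
#'
#' @param fit a `jm_fit` (fitted on data that excludes this subject's
#'   future, or at fixed parameters).
#' @param subject one-row subjects data frame with truth (from
#'   [generate_baseline()] + event time).
#' @param config the generating [cohort_config()] (provides the
#'   measurement-generating truth).
#' @param policy a [schedule_policy()] with `kind = "personalized"`.
#' @param horizon administrative end of follow-up in years.
#' @param control a [risk_control()].
#' @return a `schedule_outcome`; subjects whose event precedes the end of
#'   the run-in are flagged (`pre_run_in_event = TRUE`) and excluded from
#'   comparisons.
#' @export
run_personalized <- function(fit, subject, config, policy = schedule_policy(),
                             horizon = 3, control = risk_control()) {
  true_event <- subject$true_event_time
  run_t <- run_in_times(policy)
  t_runin_end <- max(run_t)
  if (true_event <= t_runin_end) {
    times <- observable(run_t, true_event, horizon)
    return(new_outcome(subject$subject_id, "personalized", times,
                       min(true_event, horizon), FALSE, NA_real_, true_event,
                       horizon, pre_run_in = TRUE))
  }
  times <- run_t
  data <- observe_biomarker(subject, times, config)
  t <- t_runin_end
  stopped <- FALSE; intervention <- NA_real_; followup <- horizon
  decisions <- list()
  guard <- ceiling((horizon - t_runin_end) / policy$min_spacing) + 2L
  for (step in seq_len(guard)) {
    ctrl <- control
    ctrl$seed <- mix_seed(config$seed, "sched", subject$subject_id, t)
    act <- next_action(fit, data, subject, t, policy, horizon, ctrl)
    decisions[[length(decisions) + 1L]] <- data.frame(
      subject_id = subject$subject_id, visit_time = t,
      risk_window = act$risk_window, t_threshold = act$t_threshold,
      action = act$action, u_next = act$u_next,
      ekl_at_next = if (!is.null(act$ekl) && is.finite(act$u_next)) {
        act$ekl$ekl[match(act$u_next, act$ekl$u)]
      } else NA_real_,
      stringsAsFactors = FALSE)
    if (act$action == "none") { followup <- horizon; break }
    if (act$action == "stop") {
      stopped <- TRUE; intervention <- t; followup <- t; break
    }
    u <- act$u_next
    if (u >= true_event - 1e-12) { followup <- min(true_event, horizon); break }
    if (u > horizon + 1e-9) { followup <- horizon; break }
    times <- c(times, u)
    data <- rbind(data, observe_biomarker(subject, u, config))
    t <- u
    if (t >= horizon - 1e-9) { followup <- horizon; break }
  }
  out <- new_outcome(subject$subject_id, "personalized", times, followup,
                     stopped, intervention, true_event, horizon)
  out$decisions <- do.call(rbind, decisions)
  out
}

#' Write the personalized-arm decision log as JSON lines
#'
#' One JSON object per scheduling decision: visit time, risk within the
#' clinical window, threshold time, action, the chosen next measurement
#' time and its expected information gain.
#'
#' @param study a `schedule_study`.
#' @param path output file (`.jsonl`).
#' @return `path`, invisibly.
#' @export
write_decision_log <- function(study, path) {
  stopifnot(inherits(study, "schedule_study"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (o in study$outcomes$personalized) {
    if (is.null(o$decisions)) next
    for (i in seq_len(nrow(o$decisions))) {
      writeLines(jsonlite::toJSON(as.list(o$decisions[i, ]),
                                  auto_unbox = TRUE, digits = NA, na = "null"),
                 con)
    }
  }
  invisible(path)
}

#' Run the fixed trimonthly strategy for one subject with known truth
#'
#' Measurements at every multiple of the fixed interval until the event or
#' the horizon. For comparability of high-risk identification, the same
#' stopping rule as the personalized arm (risk within the clinical window
#' at least `kappa`) is evaluated at every post-run-in visit.
#'
#' @inheritParams run_personalized
#' @return a `schedule_outcome`.
#' @export
run_fixed <- function(fit, subject, config, policy = schedule_policy("fixed"),
                      horizon = 3, control = risk_control()) {
  true_event <- subject$true_event_time
  run_t <- run_in_times(policy)
  t_runin_end <- max(run_t)
  if (true_event <= t_runin_end) {
    times <- observable(run_t, true_event, horizon)
    return(new_outcome(subject$subject_id, "fixed", times,
                       min(true_event, horizon), FALSE, NA_real_, true_event,
                       horizon, pre_run_in = TRUE))
  }
  all_visits <- seq(0, horizon + 1e-9, by = policy$fixed_interval)
  visits <- observable(all_visits, true_event, horizon)
  times <- run_t
  data <- observe_biomarker(subject, times, config)
  stopped <- FALSE; intervention <- NA_real_
  followup <- min(true_event, horizon)
  for (t in visits[visits >= t_runin_end - 1e-9]) {
    if (t > t_runin_end + 1e-9) {
      times <- c(times, t)
      data <- rbind(data, observe_biomarker(subject, t, config))
    }
    ctrl <- control
    ctrl$seed <- mix_seed(config$seed, "schedfix", subject$subject_id, t)
    draws <- posterior_random_effects(fit, data, subject, t, ctrl)
    risk_window <- cumulative_risk(fit, data, subject, t,
                                   u = min(t + policy$delta, horizon),
                                   draws = draws)
    if (risk_window >= policy$kappa) {
      stopped <- TRUE; intervention <- t; followup <- t; break
    }
  }
  new_outcome(subject$subject_id, "fixed", times, followup,
              stopped, intervention, true_event, horizon)
}

#' High-risk interval offset in months
#'
#' Estimated intervention time minus the true event time, in months;
#' negative values mean the high-risk flag preceded the event (timely
#' identification). `NA` when the strategy never stopped or the subject has
#' no event.
#'
#' @param outcome a `schedule_outcome`.
#' @return months (numeric) or `NA`.
#' @export
high_risk_offset <- function(outcome) {
  if (!isTRUE(outcome$stopped_for_intervention)) return(NA_real_)
  if (!is.finite(outcome$true_event_time)) return(NA_real_)
  (outcome$intervention_time - outcome$true_event_time) * 12
}

#' Measurements per year of follow-up used
#'
#' @param outcome a `schedule_outcome`.
#' @return `n_measurements / followup_used` (rate per year).
#' @export
measurements_per_year <- function(outcome) {
  if (!is.finite(outcome$followup_used) || outcome$followup_used <= 0) {
    stop("zero follow-up: measurements per year undefined", call. = FALSE)
  }
  outcome$n_measurements / outcome$followup_used
}

#' Run both strategies over a cohort of subjects with truth
#'
#' Convenience wrapper executing [run_personalized()] and [run_fixed()]
#' for every subject and collecting per-subject outcome rows plus a
#' decision log.
#'
#' @param fit a `jm_fit`.
#' @param subjects subjects data frame with truth (must include
#'   `true_event_time`).
#' @param config the generating [cohort_config()].
#' @param policy a [schedule_policy()] (the fixed arm reuses its `kappa`,
#'   `delta` and `run_in`).
#' @param horizon end of follow-up (years).
#' @param control a [risk_control()].
#' @param verbose print one line per subject.
#' @return list of class `schedule_study` with data frames `personalized`
#'   and `fixed` (columns subject_id, n_measurements, followup_used,
#'   rate_per_year, stopped, intervention_time, true_event_time,
#'   high_risk_offset_months, pre_run_in_event) and the outcome objects.
#' @export
run_schedule_study <- function(fit, subjects, config,
                               policy = schedule_policy(), horizon = 3,
                               control = risk_control(), verbose = FALSE) {
  fixed_policy <- policy
  fixed_policy$kind <- "fixed"
  out_p <- vector("list", nrow(subjects))
  out_f <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    out_p[[i]] <- run_personalized(fit, s, config, policy, horizon, control)
    out_f[[i]] <- run_fixed(fit, s, config, fixed_policy, horizon, control)
    if (verbose) {
      cat(sprintf("%s: personalized %d, fixed %d measurements\n",
                  s$subject_id, out_p[[i]]$n_measurements,
                  out_f[[i]]$n_measurements))
    }
  }
  structure(list(personalized = outcomes_frame(out_p),
                 fixed = outcomes_frame(out_f),
                 outcomes = list(personalized = out_p, fixed = out_f),
                 policy = policy, horizon = horizon),
            class = "schedule_study")
}

outcomes_frame <- function(outs) {
  data.frame(
    subject_id = vapply(outs, `[[`, character(1), "subject_id"),
    strategy = vapply(outs, `[[`, character(1), "strategy"),
    n_measurements = vapply(outs, `[[`, numeric(1), "n_measurements"),
    followup_used = vapply(outs, `[[`, numeric(1), "followup_used"),
    rate_per_year = vapply(outs, function(o) {
      if (o$followup_used > 0) o$n_measurements / o$followup_used else NA_real_
    }, numeric(1)),
    stopped = vapply(outs, `[[`, logical(1), "stopped_for_intervention"),
    intervention_time = vapply(outs, `[[`, numeric(1), "intervention_time"),
    true_event_time = vapply(outs, `[[`, numeric(1), "true_event_time"),
    event_within_horizon = vapply(outs, `[[`, logical(1), "event_within_horizon"),
    high_risk_offset_months = vapply(outs, high_risk_offset, numeric(1)),
    pre_run_in_event = vapply(outs, `[[`, logical(1), "pre_run_in_event"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.schedule_study <- function(x, ...) {
  keep <- !x$personalized$pre_run_in_event
  cat(sprintf("Schedule study: %d subjects (%d pre-run-in events excluded)\n",
              nrow(x$personalized), sum(!keep)))
  cat(sprintf("  personalized: median %s measurements; fixed: median %s\n",
              fmt_med_iqr(x$personalized$n_measurements[keep], 0),
              fmt_med_iqr(x$fixed$n_measurements[keep], 0)))
  invisible(x)
}
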