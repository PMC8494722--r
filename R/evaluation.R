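# Aggregation of schedule outcomes into the headline comparison:
# measurement counts, measurements saved per year (paired per subject),
# and high-risk-interval offsets per strategy.

#' Compare personalized and fixed schedule outcomes
#'
#' Pairs the two outcome sets by subject (error if they do not cover the
#' same subjects), drops subjects whose event preceded the run-in (both
#' arms are identical there), and summarises: median and interquartile
#' range of measurement counts and rates per strategy, the paired
#' per-subject difference of rates ("measurements saved per year"), and
#' the high-risk-offset distribution among subjects with a true event.
#' Quantiles use linear interpolation.
#'
#' @param personalized,fixed outcome data frames (from
#'   [run_schedule_study()]'s `$personalized` / `$fixed`, or equivalent) or
#'   a `schedule_study`.
#' @param biomarker label carried into the summary.
#' @return object of class `comparison_summary`.
#' @export
compare_schedules <- function(personalized, fixed = NULL,
                              biomarker = "biomarker") {
  if (inherits(personalized, "schedule_study")) {
    fixed <- personalized$fixed
    personalized <- personalized$personalized
  }
  unpaired <- c(setdiff(personalized$subject_id, fixed$subject_id),
                setdiff(fixed$subject_id, personalized$subject_id))
  if (length(unpaired)) {
    stop(paste("unpaired subjects:", paste(unique(unpaired), collapse = ", ")),
         call. = FALSE)
  }
  fixed <- fixed[match(personalized$subject_id, fixed$subject_id), ,
                 drop = FALSE]
  keep <- !(personalized$pre_run_in_event %||% FALSE) &
    !(fixed$pre_run_in_event %||% FALSE)
  p <- personalized[keep, , drop = FALSE]
  f <- fixed[keep, , drop = FALSE]
  saved <- f$rate_per_year - p$rate_per_year
  ev <- if (!is.null(p$event_within_horizon)) p$event_within_horizon else {
    is.finite(p$true_event_time)
  }
  q3 <- function(x) if (length(x)) qtl(x, c(0.25, 0.5, 0.75)) else rep(NA_real_, 3)
  structure(list(
    biomarker = biomarker,
    n_subjects = nrow(p),
    n_events = sum(ev),
    n_excluded_pre_run_in = sum(!keep),
    strategies = list(
      personalized = list(
        n_measurements = q3(p$n_measurements),
        rate_per_year = q3(p$rate_per_year),
        n_interventions = sum(p$stopped),
        offset_months = q3(p$high_risk_offset_months[ev & p$stopped]),
        n_flagged_events = sum(ev & p$stopped)
      ),
      fixed = list(
        n_measurements = q3(f$n_measurements),
        rate_per_year = q3(f$rate_per_year),
        n_interventions = sum(f$stopped),
        offset_months = q3(f$high_risk_offset_months[ev & f$stopped]),
        n_flagged_events = sum(ev & f$stopped)
      )
    ),
    saved_per_year = q3(saved),
    paired_saved = saved
  ), class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  render_report(x)
  invisible(x)
}

#' Render a comparison summary
#'
#' Prints a per-biomarker table in the median (p25-p75) reporting style and
#' returns the machine-readable list; with `json` a path, writes the
#' summary as JSON (round-trippable via [read_comparison_json()]).
#'
#' @param summary a `comparison_summary`.
#' @param json optional path for a JSON copy.
#' @param quiet suppress the printed table.
#' @return the summary, invisibly.
#' @export
render_report <- function(summary, json = NULL, quiet = FALSE) {
  stopifnot(inherits(summary, "comparison_summary"))
  if (!quiet) {
    if (summary$n_subjects == 0) {
      cat("Schedule comparison: no subjects\n")
    } else {
      fmt3 <- function(q, d = 1) sprintf("%.*f (%.*f-%.*f)", d, q[2], d, q[1], d, q[3])
      cat(sprintf("Schedule comparison - %s (n = %d, events = %d)\n",
                  summary$biomarker, summary$n_subjects, summary$n_events))
      for (nm in c("personalized", "fixed")) {
        s <- summary$strategies[[nm]]
        cat(sprintf("  %-12s measurements %s; per year %s; interventions %d\n",
                    nm, fmt3(s$n_measurements, 0), fmt3(s$rate_per_year),
                    s$n_interventions))
        if (s$n_flagged_events > 0) {
          cat(sprintf("  %-12s high-risk offset (months, %d flagged events) %s\n",
                      "", s$n_flagged_events, fmt3(s$offset_months)))
        }
      }
      cat(sprintf("  saved per year (fixed - personalized): %s\n",
                  fmt3(summary$saved_per_year)))
    }
  }
  if (!is.null(json)) write_comparison_json(summary, json)
  invisible(summary)
}

#' Write / read a comparison summary as JSON
#'
#' @param summary a `comparison_summary`.
#' @param path JSON file.
#' @return `path` / a `comparison_summary` equal to the serialized one.
#' @export
write_comparison_json <- function(summary, path) {
  x <- unclass(summary)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_comparison_json
#' @export
read_comparison_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(x$strategies)) {
    for (f in c("n_measurements", "rate_per_year", "offset_months")) {
      x$strategies[[nm]][[f]] <- as.numeric(x$strategies[[nm]][[f]])
    }
  }
  x$saved_per_year <- as.numeric(x$saved_per_year)
  x$paired_saved <- as.numeric(x$paired_saved)
  structure(x, class = "comparison_summary")
}

#' Write per-subject schedule outcomes as CSV
#'
#' One row per subject and strategy.
#'
#' @param study a `schedule_study`.
#' @param path CSV file.
#' @return `path`, invisibly.
#' @export
write_outcomes_csv <- function(study, path) {
  stopifnot(inherits(study, "schedule_study"))
  write.csv(rbind(study$personalized, study$fixed), path, row.names = FALSE)
  invisible(path)
}

#' Box-plot style comparison figure
#'
#' Side-by-side distributions of measurements per year under the two
#' strategies and of high-risk offsets (months) where available.
#'
#' @param summary a `comparison_summary` built with the raw study, or a
#'   `schedule_study`.
#' @param study the `schedule_study` holding per-subject rows.
#' @return invisibly, `NULL`.
#' @export
plot_comparison <- function(summary, study) {
  keep <- !study$personalized$pre_run_in_event
  graphics::par(mfrow = c(1, 2))
  graphics::boxplot(
    list(personalized = study$personalized$rate_per_year[keep],
         fixed = study$fixed$rate_per_year[keep]),
    ylab = "measurements per year", main = summary$biomarker)
  off <- list(personalized = stats::na.omit(study$personalized$high_risk_offset_months),
              fixed = stats::na.omit(study$fixed$high_risk_offset_months))
  if (any(lengths(off) > 0)) {
    graphics::boxplot(off, ylab = "high-risk offset (months)",
                      main = "timeliness")
    graphics::abline(h = 0, lty = 2)
  }
  invisible(NULL)
}
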