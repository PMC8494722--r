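# persched

Personalized scheduling of biomarker measurements in chronic heart failure
(CHF), evaluated by simulation against the conventional fixed trimonthly
scheme.

## The problem

Kidney biomarkers (creatinine, cystatin C, eGFR, KIM-1, NAG) are measured
serially in CHF patients because their individual temporal evolution
predicts adverse cardiac outcomes — but everyone is measured on the same
fixed grid. A measurement taken when a patient's prognosis is certain adds
cost without information; a measurement delayed too long can miss the start
of a high-risk interval before a composite cardiac endpoint (cardiac death,
transplantation, LVAD implantation or heart-failure hospitalization). Since
no real cohort contains a personalized-scheduling arm, the comparison must
be simulated: generate a cohort with known ground truth that mimics a
prospective CHF study (263 patients, trimonthly sampling, endpoint in
26.6% of patients), fit a joint model, and replay both strategies on the
same simulated patients.

`persched` implements the full pipeline:

1. **Synthetic cohort** — log-scale linear mixed biomarker trajectories
   `m_i(t) = β₀ + β₁t + β'ᵥwᵢ + b_{i0} + b_{i1}t`, `b_i ~ N(0, D)`, with a
   relative-risk hazard `h_i(t) = h₀(t)·exp(γ'wᵢ + α·m_i(t))` (piecewise
   constant `h₀`, calibrated to the target endpoint proportion). Everything
   is reproducible from one master seed.
2. **Joint model** — marginal likelihood via adaptive Gauss–Hermite
   integration over the random effects; MAP + Laplace (default) or
   random-walk Metropolis with split-R̂/ESS diagnostics. The association is
   summarised as the hazard ratio per 20% biomarker change, `HR = 1.2^α`.
3. **Dynamic prediction** — conditional cumulative risk
   `π(u|t) = 1 − E[S(u|b,θ)/S(t|b,θ)]` given the measurements up to `t`,
   the 7.5%-risk threshold time, and the expected Kullback–Leibler
   information gain of a hypothetical future measurement.
4. **Scheduling** — the personalized policy stops (flags a high-risk
   interval) when the 3-month risk exceeds 7.5%, otherwise measures next at
   the information-gain maximiser in `(t, t_threshold]`; the fixed policy
   measures trimonthly with the same stopping rule. Both share a
   3-measurement run-in.
5. **Evaluation** — paired per-subject comparison: measurements per year
   saved, and the high-risk-interval offset (intervention time minus true
   event time, months).

## Worked example

```r
library(persched)

## 1. a calibrated synthetic cohort at the clinical design
##    (generator restricted to the same covariates the demo model adjusts for)
cfg <- original_design_config(seed = 42,
                              beta_cov = c(age10 = 0.04, sex = 0.15),
                              gamma = c(age10 = 0.30, sex = 0.20))
cfg <- calibrate_event_rate(cfg)
cohort <- generate_cohort(cfg)
cohort
#> Synthetic CHF cohort: 263 subjects, 2211 creatinine measurements
#>   events: 68 (25.9%); median follow-up 2.15 yr; median 9 samples/subject

## 2. fit the joint model (fast mode)
spec <- jm_spec(long_covariates = c("age10", "sex"),
                surv_covariates = c("age10", "sex"),
                n_hazard_pieces = 3, fast = TRUE)
fit <- fit_joint_model(cohort$longitudinal, cohort$survival,
                       cohort$subjects, spec)
hazard_ratio_per_20pct(fit)
#> HR per 20% biomarker change: 1.238 (95% CI 1.094-1.401)

## 3. compare scheduling strategies on simulated subjects (3-year design)
cfg3 <- cfg; cfg3$max_followup <- 3; cfg3$study_years <- 3
cfg3$recruitment_years <- 0
cohort3 <- generate_cohort(cfg3)
study <- run_schedule_study(fit, head(cohort3$subjects, 40), cfg3,
                            schedule_policy(), horizon = 3,
                            control = risk_control(n_b = 150,
                                                   method = "laplace",
                                                   outer_draws = 40))
compare_schedules(study, biomarker = "creatinine")
#> Schedule comparison - creatinine (n = 39, events = 14)
#>   personalized measurements 7 (5-10); per year 3.0 (2.5-3.7); interventions 6
#>                high-risk offset (months, 2 flagged events) -16.6 (-21.0--12.3)
#>   fixed        measurements 13 (9-13); per year 4.3 (4.3-4.3); interventions 6
#>                high-risk offset (months, 2 flagged events) -14.5 (-19.9--9.1)
#>   saved per year (fixed - personalized): 1.3 (0.7-1.7)
```

The cohort reproduces the clinical calibration (about a quarter of subjects
reach the endpoint, median 9 trimonthly samples per patient). In the
scheduling comparison the personalized arm flags the same number of
high-risk intervals with comparable timeliness (negative offsets = the flag
preceded the event) while using roughly half the measurements — a median of
about 1–2 measurements per year saved, the qualitative headline this
simulation design reproduces. The fitted hazard ratio on this single seed
sits below the generative value of 1.2^2 = 1.44; across replicate cohorts
the estimator is close to unbiased (see the parameter-recovery test).

The numbers shown are the output of this exact code (seed 42); a different
seed changes them within Monte-Carlo variation.

A thin command-line wrapper around the same functions is installed at
`inst/cli/persched.R` (`simulate` / `fit` / `schedule` subcommands).

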