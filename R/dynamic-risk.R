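# Subject-specific dynamic prediction from a fitted joint model:
# posterior random effects given accumulated measurements and event-free
# survival, conditional cumulative-risk curves, the risk-threshold time,
# and the expected Kullback-Leibler information gain of a future
# measurement.

#' Monte-Carlo settings for dynamic prediction
#'
#' @param n_b random-effect draws in total (default 400).
#' @param n_theta parameter-uncertainty draws (0 = parameters fixed at the
#'   point estimate; random-effect draws are then all taken under it).
#' @param method `"mh"` (independence Metropolis-Hastings with a Laplace
#'   proposal; the reference sampler) or `"laplace"` (draws from the
#'   Laplace normal approximation; the fast mode).
#' @param horizon prediction horizon in years from enrollment (default 3).
#' @param density_grid number of event-time cells used to discretize the
#'   event-time distribution for information-gain computations.
#' @param ekl_span years beyond the candidate time covered by the
#'   event-time cells (the fitted hazard extends its last piece); the
#'   remaining far-tail mass enters as a single survivor cell. The default
#'   `NULL` chooses the span per subject and visit so that the cells cover
#'   at least ~80% of the event-time mass (a geometric search over spans
#'   up to 192 years).
#' @param outer_draws hypothetical-measurement draws for the expected
#'   information gain.
#' @param seed optional seed making the draw set reproducible.
#' @return list of class `risk_control`.
#' @export
risk_control <- function(n_b = 400L, n_theta = 0L,
                         method = c("mh", "laplace"),
                         horizon = 3, density_grid = 25L,
                         ekl_span = NULL, outer_draws = 100L, seed = NULL) {
  structure(list(n_b = as.integer(n_b), n_theta = as.integer(n_theta),
                 method = match.arg(method), horizon = horizon,
                 density_grid = as.integer(density_grid),
                 ekl_span = ekl_span,
                 outer_draws = as.integer(outer_draws), seed = seed),
            class = "risk_control")
}

## Per-subject prediction context: covariate contractions and measurement
## history up to the conditioning time.
pred_context <- function(fit, data, covariates, t) {
  spec <- fit$spec
  keep <- data$time <= t + 1e-9
  data <- data[keep, , drop = FALSE]
  if (!nrow(data)) {
    stop("dynamic prediction requires at least one measurement at or before t",
         call. = FALSE)
  }
  y <- if (!is.null(data$log_value)) data$log_value else log(data$value)
  wl <- if (length(spec$long_covariates)) {
    drop(covariate_design(covariates, spec$long_covariates))
  } else numeric(0)
  ws <- if (length(spec$surv_covariates)) {
    drop(covariate_design(covariates, spec$surv_covariates))
  } else numeric(0)
  list(y = y, tt = data$time, t = t,
       wl = wl, ws = ws,
       subject_id = as.character(data$subject_id[1]))
}

## Fixed-effect mean of the log trajectory at times `times` under pars.
mu_of <- function(pars, ctx, times) {
  pars$beta[1] + pars$beta[2] * times +
    if (length(ctx$wl)) sum(ctx$wl * pars$beta[-(1:2)]) else 0
}

## Gauss-Legendre node set for cumulative hazards up to each time in
## `times` on the fit's hazard pieces (last piece extends beyond its break).
pred_nodes <- function(times, breaks, h0, nq = 7L) {
  K <- length(h0)
  rule <- gl_nodes(nq)
  lapply(times, function(u) {
    tn <- wn <- numeric(0)
    for (p in seq_len(K)) {
      lo <- breaks[p]
      hi <- if (p < K) min(breaks[p + 1], u) else u
      if (u <= lo || hi <= lo) next
      sc <- gl_rescale(rule, lo, hi)
      tn <- c(tn, as.vector(sc$x))
      wn <- c(wn, as.vector(sc$w) * h0[p])
    }
    list(t = tn, w = wn)
  })
}

## Cumulative hazard matrix: draws (rows of b) x times. b is S x 2 (second
## column zero for intercept-only models).
cumhaz_pred <- function(pars, ctx, b, times, breaks, nq = 7L) {
  S <- nrow(b)
  nodes <- pred_nodes(times, breaks, pars$h0, nq)
  gws <- if (length(ctx$ws)) sum(ctx$ws * pars$gamma) else 0
  H <- matrix(0, S, length(times))
  eb0 <- pars$alpha * b[, 1]
  ab1 <- pars$alpha * b[, 2]
  for (m in seq_along(times)) {
    nd <- nodes[[m]]
    if (!length(nd$t)) next
    base <- nd$w * exp(gws + pars$alpha * mu_of(pars, ctx, nd$t))
    E <- exp(outer(ab1, nd$t) + eb0)
    H[, m] <- drop(E %*% base)
  }
  H
}

## log posterior density (unnormalized) of b given measurements up to t and
## survival to t; b is S x 2.
logpost_b <- function(pars, ctx, b, breaks, nq = 7L) {
  S <- nrow(b)
  mu <- mu_of(pars, ctx, ctx$tt)
  r <- outer(b[, 1], rep(1, length(ctx$y))) +
    outer(b[, 2], ctx$tt) # S x J deviations
  resid2 <- rowSums((matrix(ctx$y - mu, S, length(ctx$y), byrow = TRUE) - r)^2)
  lon <- -resid2 / (2 * pars$sigma^2)
  H <- drop(cumhaz_pred(pars, ctx, b, ctx$t, breaks, nq))
  Dinv <- pars$Dinv
  pr <- if (ncol(b) == 2 && nrow(Dinv) == 2) {
    -0.5 * (Dinv[1, 1] * b[, 1]^2 + 2 * Dinv[1, 2] * b[, 1] * b[, 2] +
              Dinv[2, 2] * b[, 2]^2)
  } else {
    -0.5 * Dinv[1, 1] * b[, 1]^2
  }
  lon - H + pr
}

## Laplace approximation of p(b | data to t, T > t): mode + covariance.
laplace_b <- function(pars, ctx, breaks, nq = 7L) {
  d <- if (nrow(pars$Dinv) == 2) 2L else 1L
  b <- rep(0, 2)
  mu <- mu_of(pars, ctx, ctx$tt)
  S11 <- length(ctx$y); S1t <- sum(ctx$tt); Stt <- sum(ctx$tt^2)
  u1 <- sum(ctx$y - mu); ut <- sum((ctx$y - mu) * ctx$tt)
  Dinv <- if (d == 2) pars$Dinv else {
    m <- matrix(0, 2, 2); m[1, 1] <- pars$Dinv[1, 1]; m[2, 2] <- 1e8; m
  }
  nd <- pred_nodes(ctx$t, breaks, pars$h0, nq)[[1]]
  gws <- if (length(ctx$ws)) sum(ctx$ws * pars$gamma) else 0
  base <- nd$w * exp(gws + pars$alpha * mu_of(pars, ctx, nd$t))
  f_old <- -Inf
  for (it in seq_len(50L)) {
    cb <- base * exp(pars$alpha * (b[1] + b[2] * nd$t))
    C0 <- sum(cb); C1 <- sum(cb * nd$t); C2 <- sum(cb * nd$t^2)
    g <- c((u1 - S11 * b[1] - S1t * b[2]) / pars$sigma^2 - pars$alpha * C0,
           (ut - S1t * b[1] - Stt * b[2]) / pars$sigma^2 - pars$alpha * C1) -
      drop(Dinv %*% b)
    Hm <- matrix(c(S11 / pars$sigma^2 + pars$alpha^2 * C0 + Dinv[1, 1],
                   S1t / pars$sigma^2 + pars$alpha^2 * C1 + Dinv[1, 2],
                   S1t / pars$sigma^2 + pars$alpha^2 * C1 + Dinv[1, 2],
                   Stt / pars$sigma^2 + pars$alpha^2 * C2 + Dinv[2, 2]), 2, 2)
    if (d == 1) { g[2] <- 0; Hm[1, 2] <- Hm[2, 1] <- 0; Hm[2, 2] <- 1e8 }
    db <- solve(Hm, g)
    if (max(abs(g[seq_len(d)])) < 1e-10) break
    b <- b + db
  }
  Sigma <- solve(Hm)
  if (d == 1) Sigma[2, 2] <- 0
  list(mode = b, Sigma = Sigma, d = d)
}

#' Posterior draws of a subject's random effects
#'
#' Draws from `p(b | measurements up to t, T > t, theta)`. Parameters are
#' fixed at the fit's point estimate (`n_theta = 0`) or drawn from the
#' fit's posterior; within each parameter draw the random effects are
#' sampled by independence Metropolis-Hastings with a Laplace proposal
#' (method `"mh"`), or directly from the Laplace approximation (method
#' `"laplace"`, the fast mode).
#'
#' @param fit a `jm_fit`.
#' @param data the subject's longitudinal rows (only those with
#'   `time <= t` are used; at least one is required).
#' @param covariates the subject's one-row baseline covariate table.
#' @param t conditioning time (years); the subject is assumed event-free
#'   at `t`.
#' @param control a [risk_control()].
#' @return object of class `risk_draws`: joint draws of parameters and
#'   random effects with their survival-to-`t` values, shared by
#'   [cumulative_risk()], [find_threshold_time()] and
#'   [expected_info_gain()] so that risk curves are monotone in the
#'   horizon.
#' @export
posterior_random_effects <- function(fit, data, covariates = NULL, t,
                                     control = risk_control()) {
  ctx <- pred_context(fit, data, covariates, t)
  run <- function() {
    pars_list <- param_draws(fit, control$n_theta)
    n_each <- max(1L, ceiling(control$n_b / length(pars_list)))
    b_all <- NULL; th_idx <- integer(0)
    for (s in seq_along(pars_list)) {
      pars <- pars_list[[s]]
      la <- laplace_b(pars, ctx, fit$breaks, fit$spec$quad_nodes)
      bs <- draw_b(pars, ctx, la, n_each, control$method, fit$breaks,
                   fit$spec$quad_nodes)
      b_all <- rbind(b_all, bs)
      th_idx <- c(th_idx, rep.int(s, nrow(bs)))
    }
    list(pars_list = pars_list, b = b_all, theta_idx = th_idx)
  }
  dr <- if (is.null(control$seed)) run() else withr::with_seed(control$seed, run())
  ## survival to t per draw (denominator of all conditional risks)
  St <- numeric(nrow(dr$b))
  for (s in seq_along(dr$pars_list)) {
    rows <- which(dr$theta_idx == s)
    H <- cumhaz_pred(dr$pars_list[[s]], ctx, dr$b[rows, , drop = FALSE],
                     t, fit$breaks, fit$spec$quad_nodes)
    St[rows] <- exp(-drop(H))
  }
  structure(list(ctx = ctx, pars_list = dr$pars_list, b = dr$b,
                 theta_idx = dr$theta_idx, St = St, t = t,
                 control = control, breaks = fit$breaks,
                 nq = fit$spec$quad_nodes),
            class = "risk_draws")
}

draw_b <- function(pars, ctx, la, n, method, breaks, nq) {
  d <- la$d
  Sig <- la$Sigma[seq_len(d), seq_len(d), drop = FALSE]
  prop <- function(n) {
    z <- matrix(rnorm(n * d), n, d) %*% chol(Sig * 1.2)
    cbind(z[, 1] + la$mode[1],
          if (d == 2) z[, 2] + la$mode[2] else rep(0, n))
  }
  if (method == "laplace") return(prop(n))
  ## independence MH with the (inflated) Laplace proposal
  cand <- prop(n)
  lp_target <- logpost_b(pars, ctx, cand, breaks, nq)
  dv <- sweep(cand[, seq_len(d), drop = FALSE], 2, la$mode[seq_len(d)])
  Sinv <- solve(Sig * 1.2)
  lp_prop <- -0.5 * rowSums((dv %*% Sinv) * dv)
  lw <- lp_target - lp_prop
  out <- matrix(0, n, 2)
  cur <- which.max(lw)
  for (i in seq_len(n)) {
    if (log(runif(1)) < lw[i] - lw[cur]) cur <- i
    out[i, ] <- cand[cur, ]
  }
  out
}

#' Conditional cumulative risk
#'
#' `pi(u | t)`: probability of the endpoint by horizon `u` given survival
#' to `t`, the measurements up to `t` and the covariates, averaged over the
#' posterior draws of parameters and random effects:
#' `E[1 - S(u | b, theta) / S(t | b, theta)]`.
#'
#' @inheritParams posterior_random_effects
#' @param u horizon (scalar or vector), `u >= t`.
#' @param draws optionally, a `risk_draws` object (from
#'   [posterior_random_effects()]) to reuse; computed fresh otherwise.
#' @return numeric vector of risks (one per `u`).
#' @export
cumulative_risk <- function(fit, data, covariates = NULL, t, u,
                            draws = NULL, control = risk_control()) {
  if (any(u < t - 1e-12)) stop("u must be >= t", call. = FALSE)
  if (is.null(draws)) {
    draws <- posterior_random_effects(fit, data, covariates, t, control)
  }
  colMeans(1 - surv_ratio(draws, u))
}

## S(u | b, theta) / S(t | b, theta) for every draw: draws x length(u).
surv_ratio <- function(draws, u) {
  out <- matrix(0, nrow(draws$b), length(u))
  for (s in seq_along(draws$pars_list)) {
    rows <- which(draws$theta_idx == s)
    H <- cumhaz_pred(draws$pars_list[[s]], draws$ctx,
                     draws$b[rows, , drop = FALSE], u, draws$breaks, draws$nq)
    out[rows, ] <- exp(-H) / draws$St[rows]
  }
  pmin(out, 1)
}

#' Time at which the conditional cumulative risk reaches a threshold
#'
#' Finds the smallest `u` with `pi(u | t) = kappa` by bisection on a fixed
#' common set of posterior draws (so the risk curve is monotone in `u`).
#' Returns `t_threshold = Inf` when even the horizon risk stays below
#' `kappa`.
#'
#' @inheritParams cumulative_risk
#' @param kappa risk threshold in (0, 1) (default 0.075).
#' @param horizon latest admissible time (years from enrollment).
#' @param tol bisection tolerance in years.
#' @return list of class `threshold_result`: `t_threshold`, `kappa`,
#'   `horizon`, `risk_at_horizon`, `beyond_horizon`.
#' @export
find_threshold_time <- function(fit, data, covariates = NULL, t,
                                kappa = 0.075, horizon = 3,
                                draws = NULL, control = risk_control(),
                                tol = 1e-3) {
  stopifnot(kappa > 0, kappa <= 1)
  if (is.null(draws)) {
    draws <- posterior_random_effects(fit, data, covariates, t, control)
  }
  risk_h <- mean(1 - surv_ratio(draws, horizon))
  if (risk_h < kappa) {
    return(structure(list(t_threshold = Inf, kappa = kappa, horizon = horizon,
                          risk_at_horizon = risk_h, beyond_horizon = TRUE),
                     class = "threshold_result"))
  }
  lo <- t; hi <- horizon
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (mean(1 - surv_ratio(draws, mid)) < kappa) lo <- mid else hi <- mid
  }
  structure(list(t_threshold = (lo + hi) / 2, kappa = kappa, horizon = horizon,
                 risk_at_horizon = risk_h, beyond_horizon = FALSE),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$beyond_horizon) {
    cat(sprintf("risk threshold %.1f%% not reached by horizon %.2f yr (risk there %.3f)\n",
                100 * x$kappa, x$horizon, x$risk_at_horizon))
  } else {
    cat(sprintf("cumulative risk reaches %.1f%% at t = %.3f yr\n",
                100 * x$kappa, x$t_threshold))
  }
  invisible(x)
}

#' Expected Kullback-Leibler information gain of a measurement at `u`
#'
#' How much a hypothetical biomarker measurement at time `u` is expected to
#' change the subject's event-time distribution. The event-time
#' distribution given survival to `u` is discretized into cells on
#' `[u, horizon]` plus a beyond-horizon survivor atom; for each
#' hypothetical measurement `y(u)` drawn from its posterior predictive the
#' random-effect draws are importance-reweighted and the discrete KL
#' divergence KL(updated || current) is computed. The reported value is
#' the average over hypothetical measurements (in nats) with its
#' Monte-Carlo standard error.
#'
#' @inheritParams cumulative_risk
#' @param u candidate measurement time, `t < u <= horizon`.
#' @param horizon end of the prediction window (years from enrollment).
#' @return list of class `info_gain`: `u`, `ekl`, `mc_se`, `n_outer`.
#' @export
expected_info_gain <- function(fit, data, covariates = NULL, t, u,
                               horizon = 3, draws = NULL,
                               control = risk_control()) {
  stopifnot(u > t, u <= horizon + 1e-9)
  if (is.null(draws)) {
    draws <- posterior_random_effects(fit, data, covariates, t, control)
  }
  ## Discretized event-time distribution given T > u on the model's own
  ## support: cells over (u, u + span] (the fitted hazard extends its
  ## last piece) plus one far-tail survivor cell, so the distribution is
  ## proper and no renormalization fudge is needed.
  span <- control$ekl_span
  if (is.null(span)) {
    ## adapt the span to the subject's own risk scale: smallest
    ## power-of-two span capturing >= 80% of the conditional mass
    ladder <- pmax(horizon - u, 3) * 2^(0:6)
    Sl <- surv_ratio(draws, u + ladder)
    Su0 <- drop(surv_ratio(draws, u))
    mass <- 1 - colMeans(Sl / Su0)
    hit <- which(mass >= 0.8)
    span <- if (length(hit)) ladder[hit[1]] else ladder[length(ladder)]
  }
  grid <- seq(u, u + span, length.out = control$density_grid + 1L)
  Smat <- surv_ratio(draws, grid)          # S(g)/S(t) per draw
  Su <- Smat[, 1]
  w0 <- Su / sum(Su)                       # recondition draws on T > u
  cell <- cbind(Smat[, -ncol(Smat), drop = FALSE] -
                  Smat[, -1, drop = FALSE],
                Smat[, ncol(Smat)]) / Su   # cells + far tail, per draw
  cell <- pmax(cell, 0)
  p0 <- drop(crossprod(cell, w0))
  ## a dominant far-tail cell is legitimate (a low-risk subject whose
  ## event-time distribution is largely defective under the fitted model);
  ## warn only when the within-span cells carry essentially no mass, where
  ## the KL update is numerically meaningless
  if (sum(p0[-length(p0)]) < 1e-6) {
    warning("event-time mass within the density grid is numerically negligible; information gain unreliable",
            call. = FALSE)
  }
  ## hypothetical measurements from the posterior predictive at u
  mu_draw <- numeric(nrow(draws$b))
  sd_draw <- numeric(nrow(draws$b))
  for (s in seq_along(draws$pars_list)) {
    rows <- which(draws$theta_idx == s)
    pars <- draws$pars_list[[s]]
    mu_draw[rows] <- mu_of(pars, draws$ctx, u) + draws$b[rows, 1] +
      draws$b[rows, 2] * u
    sd_draw[rows] <- pars$sigma
  }
  R <- control$outer_draws
  run <- function() {
    idx <- sample.int(length(w0), R, replace = TRUE, prob = w0)
    y_hyp <- rnorm(R, mu_draw[idx], sd_draw[idx])
    kl <- numeric(R)
    for (r in seq_len(R)) {
      lw <- log(w0) + dnorm(y_hyp[r], mu_draw, sd_draw, log = TRUE)
      w1 <- exp(lw - max(lw)); w1 <- w1 / sum(w1)
      p1 <- drop(crossprod(cell, w1))
      ok <- p1 > 0 & p0 > 0
      ## guard rounding: the discrete KL divergence is non-negative
      kl[r] <- max(0, sum(p1[ok] * (log(p1[ok]) - log(p0[ok]))))
    }
    kl
  }
  kl <- if (is.null(control$seed)) run() else {
    withr::with_seed(mix_seed(control$seed, "ekl", u), run())
  }
  structure(list(u = u, ekl = mean(kl), mc_se = sd(kl) / sqrt(R),
                 n_outer = R), class = "info_gain")
}

#' @export
print.info_gain <- function(x, ...) {
  cat(sprintf("expected KL information gain at u = %.3f: %.5f nats (MC se %.5f)\n",
              x$u, x$ekl, x$mc_se))
  invisible(x)
}

#' Conditional risk profile over a horizon grid
#'
#' @inheritParams cumulative_risk
#' @param grid horizon times (default 40 points from `t` to `horizon`).
#' @param horizon end of the grid when `grid` is not given.
#' @param band central posterior band level for the per-draw conditional
#'   risks.
#' @return data frame of class `risk_profile`: `subject_id`, `t`, `u`,
#'   `risk`, `lower`, `upper`.
#' @export
risk_profile <- function(fit, data, covariates = NULL, t, grid = NULL,
                         horizon = 3, draws = NULL,
                         control = risk_control(), band = 0.95) {
  if (is.null(draws)) {
    draws <- posterior_random_effects(fit, data, covariates, t, control)
  }
  grid <- grid %||% seq(t, horizon, length.out = 41L)
  risk_mat <- 1 - surv_ratio(draws, grid)
  a <- (1 - band) / 2
  out <- data.frame(
    subject_id = draws$ctx$subject_id,
    t = t, u = grid,
    risk = colMeans(risk_mat),
    lower = apply(risk_mat, 2, qtl, p = a),
    upper = apply(risk_mat, 2, qtl, p = 1 - a)
  )
  class(out) <- c("risk_profile", "data.frame")
  out
}

#' @export
plot.risk_profile <- function(x, kappa = 0.075, ...) {
  graphics::plot(x$u, 100 * x$risk, type = "l", lwd = 2, col = "steelblue",
                 xlab = "time since enrollment (years)",
                 ylab = "cumulative risk of the endpoint (%)",
                 ylim = c(0, max(100 * x$upper, 10)), ...)
  graphics::polygon(c(x$u, rev(x$u)), 100 * c(x$lower, rev(x$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
  graphics::abline(h = 100 * kappa, lty = 2)
  invisible(x)
}
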