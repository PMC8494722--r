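#' Fit the joint model for a longitudinal biomarker and the endpoint
#'
#' Maximizes the weakly-penalized marginal joint likelihood (normal
#' longitudinal submodel given subject random effects, relative-risk
#' survival submodel with piecewise-constant baseline hazard and
#' current-value association, random effects integrated out by adaptive
#' Gauss-Hermite quadrature). The default `"map"` method returns the
#' posterior mode with a Laplace (normal) approximation of parameter
#' uncertainty; `"mcmc"` runs random-walk Metropolis chains started at the
#' mode, with split-Rhat and effective-sample-size diagnostics.
#'
#' Starting values come from a linear mixed model
#' ([nlme::lme()]) for the longitudinal part and a Cox model
#' ([survival::coxph()]) with the last observed biomarker value for the
#' survival part; piecewise event rates initialize the baseline hazard.
#'
#' @param longitudinal data frame with `subject_id`, `time` (years) and
#'   `value` (> 0) or `log_value`.
#' @param survival data frame with `subject_id`, `observed_time`, `event`.
#' @param covariates baseline table with one row per subject (raw columns
#'   `age`, `sex`, ... as produced by [generate_baseline()]); may be `NULL`
#'   when the spec uses no covariates.
#' @param spec a [jm_spec()].
#' @param breaks optional fixed baseline-hazard breakpoints.
#' @param init optional named parameter vector (transformed scale) to start
#'   from.
#' @param verbose print optimizer progress.
#' @return object of class `jm_fit`; see [summary.jm_fit()],
#'   [hazard_ratio_per_20pct()], and the dynamic-prediction functions.
#' @export
fit_joint_model <- function(longitudinal, survival, covariates = NULL,
                            spec = jm_spec(), breaks = NULL, init = NULL,
                            verbose = FALSE) {
  dat <- jm_prepare(longitudinal, survival, covariates, spec, breaks)
  th0 <- init %||% init_theta(dat)
  mode_env <- new.env(parent = emptyenv())
  prior_sd <- spec$prior_sd
  negpost <- function(th) {
    pars <- try(unpack_theta(th, dat), silent = TRUE)
    if (inherits(pars, "try-error")) return(1e10)
    ll <- try(marginal_loglik(pars, dat, mode_env), silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
    -(ll + sum(dnorm(th, 0, prior_sd, log = TRUE)))
  }
  opt <- optim(th0, negpost, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10,
                              trace = if (verbose) 1 else 0))
  theta <- stats::setNames(opt$par, theta_names(dat))
  H <- optimHess(theta, negpost)
  vc <- laplace_vcov(H)
  diagnostics <- list(
    optim_convergence = opt$convergence,
    hessian_pd = vc$pd,
    n_subjects = dat$n, n_obs = length(dat$y),
    message = opt$message %||% ""
  )
  converged <- opt$convergence == 0 && vc$pd
  if (!converged) {
    warning("joint model fit flagged as non-converged; inspect $diagnostics",
            call. = FALSE)
  }
  fit <- structure(list(
    spec = spec, theta = theta, pars = unpack_theta(theta, dat),
    vcov = vc$vcov, breaks = dat$breaks,
    theta_names = theta_names(dat),
    logpost = -opt$value,
    loglik = marginal_loglik(unpack_theta(theta, dat), dat, mode_env),
    method = spec$method, draws = NULL,
    diagnostics = diagnostics, converged = converged,
    dat = dat
  ), class = "jm_fit")
  if (spec$method == "mcmc") {
    fit <- run_mcmc(fit, negpost)
  }
  fit
}

laplace_vcov <- function(H) {
  vc <- try(solve(H), silent = TRUE)
  pd <- !inherits(vc, "try-error") && all(diag(vc) > 0)
  if (!pd) {
    ev <- eigen(H, symmetric = TRUE)
    lam <- pmax(ev$values, 1e-8)
    vc <- ev$vectors %*% diag(1 / lam, length(lam)) %*% t(ev$vectors)
    pd <- FALSE
  }
  vc <- (vc + t(vc)) / 2
  list(vcov = vc, pd = pd)
}

init_theta <- function(dat) {
  df <- data.frame(y = dat$y, tt = dat$t, sub = dat$gi)
  Wl <- dat$X[, -(1:2), drop = FALSE]
  beta <- NULL; sigma <- NULL; D <- NULL
  lf <- if (ncol(Wl)) {
    df <- cbind(df, Wl)
    stats::as.formula(paste("y ~ tt +", paste(colnames(Wl), collapse = "+")))
  } else y ~ tt
  lmm <- try(nlme::lme(lf, random = if (dat$d == 2) ~tt | sub else ~1 | sub,
                       data = df, method = "ML",
                       control = nlme::lmeControl(returnObject = TRUE)),
             silent = TRUE)
  if (!inherits(lmm, "try-error")) {
    beta <- unname(nlme::fixef(lmm))
    sigma <- lmm$sigma
    vcm <- try(as.matrix(nlme::getVarCov(lmm)), silent = TRUE)
    if (!inherits(vcm, "try-error") && all(is.finite(vcm))) D <- unname(vcm)
  }
  if (is.null(beta)) {
    lmf <- stats::lm(lf, data = df)
    beta <- unname(stats::coef(lmf))
    sigma <- summary(lmf)$sigma
  }
  if (is.null(beta) || anyNA(beta)) {
    if (is.null(beta)) beta <- rep(0, dat$p)
    beta[!is.finite(beta)] <- 0
  }
  if (is.null(sigma) || !is.finite(sigma) || sigma <= 0) sigma <- 0.2
  if (is.null(D)) {
    D <- if (dat$d == 2) diag(c(0.09, 0.01)) else matrix(0.09)
  }
  ## project the initial covariance back to positive definite if needed
  ei <- eigen((D + t(D)) / 2, symmetric = TRUE)
  D <- ei$vectors %*% diag(pmax(ei$values, 1e-4), dat$d) %*% t(ei$vectors)
  D <- D + diag(1e-4, dat$d)
  ## survival side: Cox model with last observed log value
  last_idx <- vapply(seq_len(dat$n), function(i) {
    w <- which(dat$obs_sub == i); w[which.max(dat$t[w])]
  }, integer(1))
  lv <- dat$y[last_idx]
  cx_df <- data.frame(T = dat$Tobs, d = dat$delta, lv = lv)
  gamma <- rep(0, dat$q); alpha <- 0
  cf <- if (dat$q) {
    cx_df <- cbind(cx_df, dat$W_surv)
    stats::as.formula(paste("survival::Surv(T, d) ~ lv +",
                            paste(colnames(dat$W_surv), collapse = "+")))
  } else survival::Surv(T, d) ~ lv
  cx <- try(survival::coxph(cf, data = cx_df), silent = TRUE)
  if (!inherits(cx, "try-error")) {
    co <- stats::coef(cx)
    if (is.finite(co["lv"])) alpha <- unname(co["lv"])
    if (dat$q) {
      g <- co[colnames(dat$W_surv)]
      gamma <- ifelse(is.finite(g), unname(g), 0)
    }
  }
  ## piecewise event rates deflated by the average linear predictor
  lp <- (if (dat$q) drop(dat$W_surv %*% gamma) else 0) + alpha * lv
  h0 <- vapply(seq_len(dat$K), function(p) {
    lo <- dat$breaks[p]; hi <- dat$breaks[p + 1]
    if (p == dat$K) hi <- max(hi, max(dat$Tobs))
    ev <- sum(dat$delta == 1 & dat$Tobs > lo & dat$Tobs <= hi)
    pt <- sum(pmax(pmin(dat$Tobs, hi) - lo, 0))
    max(ev, 0.5) / max(pt, 1e-8)
  }, numeric(1))
  h0 <- h0 * exp(-mean(lp))
  pack_theta(list(beta = beta, sigma = max(sigma, 1e-3), D = D, h0 = h0,
                  gamma = gamma, alpha = alpha), dat)
}

## ---- Random-walk Metropolis over theta --------------------------------

run_mcmc <- function(fit, negpost) {
  spec <- fit$spec
  p <- length(fit$theta)
  prop_chol <- try(chol((2.38^2 / p) * fit$vcov), silent = TRUE)
  if (inherits(prop_chol, "try-error")) {
    prop_chol <- diag(sqrt(diag(fit$vcov)) * 2.38 / sqrt(p), p)
  }
  total <- spec$iter + spec$burn
  draws <- vector("list", spec$chains)
  accept <- numeric(spec$chains)
  for (ch in seq_len(spec$chains)) {
    chain <- matrix(NA_real_, total, p)
    th <- fit$theta + if (ch > 1) drop(rnorm(p) %*% prop_chol) else 0
    lp <- -negpost(th)
    for (it in seq_len(total)) {
      cand <- th + drop(rnorm(p) %*% prop_chol)
      lp_c <- -negpost(cand)
      if (is.finite(lp_c) && log(runif(1)) < lp_c - lp) {
        th <- cand; lp <- lp_c; accept[ch] <- accept[ch] + 1
      }
      chain[it, ] <- th
    }
    draws[[ch]] <- chain[-seq_len(spec$burn), , drop = FALSE]
  }
  all_draws <- do.call(rbind, draws)
  colnames(all_draws) <- fit$theta_names
  rh <- split_rhat(draws)
  ess <- vapply(seq_len(p), function(j) {
    ess_chains(lapply(draws, function(m) m[, j]))
  }, numeric(1))
  fit$draws <- all_draws
  fit$diagnostics$rhat <- stats::setNames(rh, fit$theta_names)
  fit$diagnostics$ess <- stats::setNames(ess, fit$theta_names)
  fit$diagnostics$accept_rate <- accept / total
  fit$converged <- fit$converged && all(rh < 1.05) && all(ess > 100)
  if (!all(rh < 1.05) || !all(ess > 100)) {
    warning("MCMC diagnostics below threshold (split-Rhat >= 1.05 or ESS <= 100); fit flagged",
            call. = FALSE)
  }
  fit
}

## split-Rhat per parameter over a list of chain matrices
split_rhat <- function(chains) {
  p <- ncol(chains[[1]])
  vapply(seq_len(p), function(j) {
    halves <- unlist(lapply(chains, function(m) {
      x <- m[, j]; h <- floor(length(x) / 2)
      list(x[seq_len(h)], x[h + seq_len(h)])
    }), recursive = FALSE)
    mns <- vapply(halves, mean, numeric(1))
    vrs <- vapply(halves, var, numeric(1))
    nh <- length(halves[[1]])
    W <- mean(vrs); B <- nh * var(mns)
    if (W <= 0) return(1)
    sqrt(((nh - 1) / nh * W + B / nh) / W)
  }, numeric(1))
}

ess_chains <- function(xs) {
  sum(vapply(xs, function(x) {
    n <- length(x)
    if (var(x) == 0) return(n)
    rho <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
    s <- 0
    for (k in seq(1, length(rho) - 1, by = 2)) {
      pair <- rho[k] + rho[k + 1]
      if (!is.finite(pair) || pair < 0) break
      s <- s + pair
    }
    n / (1 + 2 * s)
  }, numeric(1)))
}

## ---- draws / summaries -------------------------------------------------

## Parameter draws for dynamic prediction: list of unpacked parameter sets.
## n = 0 returns the point estimate only.
param_draws <- function(fit, n = 0L, seed = NULL) {
  dat_stub <- list(p = fit$dat$p %||% sum(startsWith(fit$theta_names, "beta.")),
                   d = if (any(fit$theta_names == "chol.22")) 2L else 1L,
                   K = sum(startsWith(fit$theta_names, "log_h0.")),
                   q = sum(startsWith(fit$theta_names, "gamma.")))
  if (n <= 0L) return(list(fit$pars))
  ths <- if (!is.null(fit$draws)) {
    idx <- if (is.null(seed)) sample.int(nrow(fit$draws), n, replace = TRUE) else {
      withr::with_seed(seed, sample.int(nrow(fit$draws), n, replace = TRUE))
    }
    fit$draws[idx, , drop = FALSE]
  } else {
    draw <- function() MASS::mvrnorm(n, fit$theta, fit$vcov)
    m <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    matrix(m, nrow = n)
  }
  lapply(seq_len(n), function(i) unpack_theta(ths[i, ], dat_stub))
}

#' Hazard ratio per 20% biomarker change
#'
#' With the biomarker modelled on the natural-log scale, a 20% increase in
#' level shifts the current-value term by `log(1.2)`, so the hazard ratio is
#' `1.2^alpha`; the interval comes from the corresponding quantiles of
#' alpha's posterior (MCMC draws, or the Laplace normal approximation).
#'
#' @param fit a `jm_fit` (or a bare numeric alpha, for which only the point
#'   transform is returned).
#' @param level interval coverage (default 0.95).
#' @return list with `hr`, `lower`, `upper`, `alpha`, `level` (class
#'   `jm_hr`), or a numeric vector when `fit` is numeric.
#' @export
hazard_ratio_per_20pct <- function(fit, level = 0.95) {
  if (is.numeric(fit)) return(1.2^fit)
  stopifnot(inherits(fit, "jm_fit"))
  a_idx <- which(fit$theta_names == "alpha")
  alpha <- fit$theta[[a_idx]]
  zq <- c((1 - level) / 2, 1 - (1 - level) / 2)
  a_ci <- if (!is.null(fit$draws)) {
    qtl(fit$draws[, a_idx], zq)
  } else {
    alpha + qnorm(zq) * sqrt(fit$vcov[a_idx, a_idx])
  }
  structure(list(hr = 1.2^alpha, lower = 1.2^a_ci[1], upper = 1.2^a_ci[2],
                 alpha = alpha, level = level), class = "jm_hr")
}

#' @export
print.jm_hr <- function(x, ...) {
  cat(sprintf("HR per 20%% biomarker change: %.3f (%.0f%% CI %.3f-%.3f)\n",
              x$hr, 100 * x$level, x$lower, x$upper))
  invisible(x)
}

#' Build a `jm_fit` at fixed (e.g. true generative) parameter values
#'
#' Useful for simulation experiments that need dynamic predictions under
#' known parameters: the resulting object behaves like a converged fit with
#' degenerate (zero) parameter uncertainty.
#'
#' @inheritParams joint_loglik
#' @return a `jm_fit`.
#' @export
as_jm_fit <- function(params, longitudinal, survival, covariates = NULL,
                      spec = jm_spec(), breaks = NULL) {
  dat <- jm_prepare(longitudinal, survival, covariates, spec, breaks)
  theta <- pack_theta(params, dat)
  structure(list(
    spec = spec, theta = theta, pars = unpack_theta(theta, dat),
    vcov = matrix(0, length(theta), length(theta)),
    breaks = dat$breaks, theta_names = theta_names(dat),
    logpost = NA_real_, loglik = NA_real_,
    method = "fixed", draws = NULL,
    diagnostics = list(fixed_parameters = TRUE), converged = TRUE,
    dat = dat
  ), class = "jm_fit")
}

#' @export
print.jm_fit <- function(x, ...) {
  cat(sprintf("Joint model fit (%s)%s\n", x$method,
              if (x$converged) "" else "  ** flagged: not converged **"))
  cat(sprintf("  subjects: %s, observations: %s, hazard pieces: %d\n",
              x$diagnostics$n_subjects %||% "?",
              x$diagnostics$n_obs %||% "?", length(x$pars$h0)))
  cat(sprintf("  sigma = %.4f, alpha = %.3f", x$pars$sigma, x$pars$alpha))
  cat(sprintf("  (HR per 20%% change %.3f)\n", 1.2^x$pars$alpha))
  invisible(x)
}

#' Summary of a joint model fit
#'
#' @param object a `jm_fit`.
#' @param level interval coverage.
#' @param ... unused.
#' @return a `summary.jm_fit` with a coefficient table (estimate, SE on the
#'   working scale, interval) and the HR per 20% change.
#' @export
summary.jm_fit <- function(object, level = 0.95, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  zq <- qnorm(1 - (1 - level) / 2)
  est <- object$theta
  lower <- est - zq * se
  upper <- est + zq * se
  natural <- function(nm, v) {
    if (startsWith(nm, "log_") || nm %in% c("chol.11", "chol.22")) exp(v) else v
  }
  tab <- data.frame(
    parameter = object$theta_names,
    estimate = vapply(seq_along(est), function(i) natural(object$theta_names[i], est[i]), numeric(1)),
    lower = vapply(seq_along(est), function(i) natural(object$theta_names[i], lower[i]), numeric(1)),
    upper = vapply(seq_along(est), function(i) natural(object$theta_names[i], upper[i]), numeric(1)),
    row.names = NULL
  )
  structure(list(table = tab, hr = hazard_ratio_per_20pct(object, level),
                 diagnostics = object$diagnostics, converged = object$converged,
                 level = level),
            class = "summary.jm_fit")
}

#' @export
print.summary.jm_fit <- function(x, ...) {
  cat("Joint model parameter estimates",
      sprintf("(%.0f%% intervals, natural scale for sd/hazard terms)\n", 100 * x$level))
  print(x$table, digits = 4)
  print(x$hr)
  if (!x$converged) cat("** fit flagged as non-converged **\n")
  invisible(x)
}

#' @export
coef.jm_fit <- function(object, ...) object$theta

#' @export
vcov.jm_fit <- function(object, ...) object$vcov

#' @export
logLik.jm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

## ---- JSON serialization ------------------------------------------------

#' Write / read a fit as JSON
#'
#' Serializes point estimates, the Laplace covariance, hazard breakpoints,
#' the spec, diagnostics and the HR-per-20%-change summary (schema
#' `persched-fit/1`). MCMC draws are not serialized.
#'
#' @param fit a `jm_fit`.
#' @param path JSON file.
#' @return `path` / a `jm_fit` (without internal data; usable for dynamic
#'   prediction).
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "jm_fit"))
  hr <- hazard_ratio_per_20pct(fit)
  payload <- list(
    schema = "persched-fit/1",
    theta = as.list(stats::setNames(as.numeric(fit$theta), fit$theta_names)),
    vcov = fit$vcov,
    breaks = fit$breaks,
    spec = unclass(fit$spec),
    diagnostics = fit$diagnostics,
    converged = fit$converged,
    hr_per_20pct = list(hr = hr$hr, lower = hr$lower, upper = hr$upper),
    loglik = fit$loglik
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "persched-fit/1")) {
    stop("unrecognised fit JSON schema", call. = FALSE)
  }
  spec <- do.call(jm_spec, x$spec[setdiff(names(x$spec),
                                          c("association")) ])
  theta <- unlist(x$theta)
  nms <- names(theta)
  dat_stub <- list(p = sum(startsWith(nms, "beta.")),
                   d = if (any(nms == "chol.22")) 2L else 1L,
                   K = sum(startsWith(nms, "log_h0.")),
                   q = sum(startsWith(nms, "gamma.")))
  structure(list(
    spec = spec, theta = theta, pars = unpack_theta(theta, dat_stub),
    vcov = matrix(as.numeric(x$vcov), length(theta), length(theta)),
    breaks = as.numeric(x$breaks), theta_names = nms,
    logpost = NA_real_, loglik = x$loglik,
    method = spec$method, draws = NULL,
    diagnostics = x$diagnostics, converged = isTRUE(x$converged),
    dat = NULL
  ), class = "jm_fit")
}
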