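# Joint-likelihood engine.
#
# Marginal log-likelihood of the joint model: for each subject the product of
# the longitudinal normal likelihood given random effects b, the
# relative-risk survival likelihood with hazard h0(t) exp(gamma'w + alpha
# m(t)), and the N(0, D) random-effects density, integrated over b by
# adaptive Gauss-Hermite quadrature centred at the per-subject posterior
# mode (found by damped Newton; the integrand is log-concave in b).
# Cumulative hazards use Gauss-Legendre quadrature within hazard pieces.

## Assemble the internal data representation used by the likelihood.
jm_prepare <- function(longitudinal, survival, covariates, spec,
                       breaks = NULL) {
  rep_v <- validate_inputs(longitudinal, survival)
  if (any(rep_v$fatal)) {
    stop(paste0("fatal data problems; offending subjects: ",
                paste(unique(rep_v$subject_id[rep_v$fatal]), collapse = ", ")),
         call. = FALSE)
  }
  ids <- as.character(survival$subject_id)
  n <- length(ids)
  if (is.null(longitudinal$log_value)) {
    longitudinal$log_value <- log(longitudinal$value)
  }
  if (any(!is.finite(longitudinal$log_value))) {
    stop("non-finite log biomarker values", call. = FALSE)
  }
  obs_sub <- match(as.character(longitudinal$subject_id), ids)
  y <- longitudinal$log_value
  tt <- longitudinal$time
  ncov <- union(spec$long_covariates, spec$surv_covariates)
  if (length(ncov)) {
    if (is.null(covariates)) {
      stop("spec includes covariates but no covariate table was given",
           call. = FALSE)
    }
    crow <- match(ids, as.character(covariates$subject_id))
    if (anyNA(crow)) {
      stop(paste("missing covariate rows for subjects:",
                 paste(ids[is.na(crow)], collapse = ", ")), call. = FALSE)
    }
    covariates <- covariates[crow, , drop = FALSE]
  }
  W_long <- if (length(spec$long_covariates)) {
    covariate_design(covariates, spec$long_covariates)
  } else matrix(0, n, 0)
  W_surv <- if (length(spec$surv_covariates)) {
    covariate_design(covariates, spec$surv_covariates)
  } else matrix(0, n, 0)
  Tobs <- survival$observed_time
  delta <- survival$event
  d <- if (spec$random == "intercept+slope") 2L else 1L
  X <- cbind(`(Intercept)` = 1, time = tt, W_long[obs_sub, , drop = FALSE])
  gi <- factor(obs_sub, levels = seq_len(n))
  S11 <- as.vector(rowsum(rep(1, length(y)), gi))
  S1t <- as.vector(rowsum(tt, gi))
  Stt <- as.vector(rowsum(tt^2, gi))
  K <- spec$n_hazard_pieces
  if (is.null(breaks)) {
    ev <- Tobs[delta == 1]
    src <- if (length(ev) >= K) ev else Tobs
    interior <- unique(qtl(src, seq_len(K - 1) / K))
    breaks <- c(0, interior, max(Tobs))
    breaks <- sort(unique(breaks))
  }
  K <- length(breaks) - 1L
  ## flattened Gauss-Legendre nodes, subject x overlapping hazard piece
  rule <- gl_nodes(spec$quad_nodes)
  node_t <- node_logw <- numeric(0)
  node_sub <- node_piece <- integer(0)
  for (p in seq_len(K)) {
    lo <- breaks[p]
    hi <- if (p < K) pmin(breaks[p + 1], Tobs) else Tobs
    act <- which(Tobs > lo & hi > lo)
    if (!length(act)) next
    sc <- gl_rescale(rule, rep(lo, length(act)), hi[act])
    node_t <- c(node_t, as.vector(t(sc$x)))
    node_logw <- c(node_logw, log(as.vector(t(sc$w))))
    node_sub <- c(node_sub, rep(act, each = length(rule$x)))
    node_piece <- c(node_piece, rep.int(p, length(act) * length(rule$x)))
  }
  ord <- order(node_sub)
  node_t <- node_t[ord]; node_logw <- node_logw[ord]
  node_sub <- node_sub[ord]; node_piece <- node_piece[ord]
  Xn <- cbind(1, node_t, W_long[node_sub, , drop = FALSE])
  XT <- cbind(1, Tobs, W_long)
  list(ids = ids, n = n, y = y, t = tt, obs_sub = obs_sub, gi = gi,
       X = X, Xn = Xn, XT = XT, W_surv = W_surv,
       Tobs = Tobs, delta = delta, d = d,
       S11 = S11, S1t = S1t, Stt = Stt,
       breaks = breaks, K = K,
       node_t = node_t, node_logw = node_logw,
       node_sub = node_sub, node_piece = node_piece,
       p = ncol(X), q = ncol(W_surv), spec = spec)
}

## ---- parameter vector <-> parameter list ------------------------------

theta_names <- function(dat) {
  c(paste0("beta.", colnames(dat$X)),
    "log_sigma",
    if (dat$d == 2) c("chol.11", "chol.21", "chol.22") else "chol.11",
    paste0("log_h0.", seq_len(dat$K)),
    if (dat$q) paste0("gamma.", colnames(dat$W_surv)),
    "alpha")
}

pack_theta <- function(pars, dat) {
  Dm <- as.matrix(pars$D)
  if (dat$d == 2) {
    L <- t(chol(Dm + diag(1e-12, 2)))
    cD <- c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
  } else {
    cD <- log(sqrt(Dm[1, 1]))
  }
  th <- c(pars$beta, log(pars$sigma), cD, log(pars$h0),
          if (dat$q) pars$gamma, pars$alpha)
  stats::setNames(th, theta_names(dat))
}

unpack_theta <- function(theta, dat) {
  p <- dat$p; d <- dat$d; K <- dat$K; q <- dat$q
  i <- 0L
  beta <- theta[i + seq_len(p)]; i <- i + p
  sigma <- exp(theta[i + 1L]); i <- i + 1L
  if (d == 2) {
    L <- matrix(c(exp(theta[i + 1L]), theta[i + 2L], 0, exp(theta[i + 3L])), 2, 2)
    i <- i + 3L
    D <- L %*% t(L)
  } else {
    L <- matrix(exp(theta[i + 1L])); i <- i + 1L
    D <- L^2
  }
  h0 <- exp(theta[i + seq_len(K)]); i <- i + K
  gamma <- if (q) theta[i + seq_len(q)] else numeric(0); i <- i + q
  alpha <- theta[i + 1L]
  Dinv <- solve(D)
  list(beta = unname(beta), sigma = unname(sigma), D = unname(D),
       Dinv = Dinv, h0 = unname(h0), log_h0 = log(unname(h0)),
       gamma = unname(gamma), alpha = unname(alpha),
       logdetD = determinant(D, logarithm = TRUE)$modulus[1])
}

## ---- per-theta caches --------------------------------------------------

theta_cache <- function(pars, dat) {
  r0 <- dat$y - drop(dat$X %*% pars$beta)
  gi <- dat$gi
  u1 <- as.vector(rowsum(r0, gi))
  ut <- if (dat$d == 2) as.vector(rowsum(r0 * dat$t, gi)) else NULL
  ssr0 <- as.vector(rowsum(r0^2, gi))
  gw <- if (dat$q) drop(dat$W_surv %*% pars$gamma) else rep(0, dat$n)
  xnb <- drop(dat$Xn %*% pars$beta)
  xtb <- drop(dat$XT %*% pars$beta)
  ## node-level constant part of log hazard contribution
  qnode <- dat$node_logw + pars$log_h0[dat$node_piece] +
    gw[dat$node_sub] + pars$alpha * xnb
  list(r0 = r0, u1 = u1, ut = ut, ssr0 = ssr0, gw = gw,
       xnb = xnb, xtb = xtb, qnode = qnode)
}

## Sum node values by subject; every subject has >= 1 node.
node_sum <- function(x, dat) {
  as.vector(rowsum(x, dat$node_sub, reorder = TRUE))
}

## Per-subject log integrand at random-effect values (b0, b1 vectors).
logf_b <- function(b0, b1, pars, dat, ca, parts = FALSE) {
  if (is.null(b1)) b1 <- rep(0, dat$n)
  ssr <- ca$ssr0 - 2 * (b0 * ca$u1 + if (dat$d == 2) b1 * (ca$ut) else 0) +
    b0^2 * dat$S11 + 2 * b0 * b1 * dat$S1t + b1^2 * dat$Stt
  lon <- -ssr / (2 * pars$sigma^2) - dat$S11 * log(pars$sigma) -
    dat$S11 * log(2 * pi) / 2
  cn <- exp(ca$qnode + pars$alpha * (b0[dat$node_sub] + b1[dat$node_sub] * dat$node_t))
  H <- node_sum(cn, dat)
  logh_T <- pars$log_h0[piece_of(dat$Tobs, dat$breaks)] + ca$gw +
    pars$alpha * (ca$xtb + b0 + b1 * dat$Tobs)
  ev <- dat$delta * logh_T - H
  pr <- if (dat$d == 2) {
    -0.5 * (pars$Dinv[1, 1] * b0^2 + 2 * pars$Dinv[1, 2] * b0 * b1 +
              pars$Dinv[2, 2] * b1^2) - log(2 * pi) - 0.5 * pars$logdetD
  } else {
    -0.5 * pars$Dinv[1, 1] * b0^2 - 0.5 * log(2 * pi) - 0.5 * pars$logdetD
  }
  out <- lon + ev + pr
  if (parts) list(total = out, cn = cn) else out
}

piece_of <- function(t, breaks) {
  K <- length(breaks) - 1L
  pmax(pmin(findInterval(t, breaks, left.open = TRUE), K), 1L)
}

## Damped Newton search for the per-subject posterior modes of b.
## Returns modes and the (negative-definite) Hessian components there.
newton_modes <- function(pars, dat, ca, b_init = NULL) {
  n <- dat$n; d <- dat$d
  b0 <- if (!is.null(b_init)) b_init[, 1] else rep(0, n)
  b1 <- if (d == 2) {
    if (!is.null(b_init) && ncol(b_init) >= 2) b_init[, 2] else rep(0, n)
  } else NULL
  f <- logf_b(b0, b1, pars, dat, ca)
  for (it in seq_len(40L)) {
    cn <- exp(ca$qnode + pars$alpha *
                (b0[dat$node_sub] + if (d == 2) b1[dat$node_sub] * dat$node_t else 0))
    C0 <- node_sum(cn, dat)
    zr1 <- ca$u1 - dat$S11 * b0 - if (d == 2) dat$S1t * b1 else 0
    g1 <- zr1 / pars$sigma^2 + dat$delta * pars$alpha - pars$alpha * C0 -
      (pars$Dinv[1, 1] * b0 + if (d == 2) pars$Dinv[1, 2] * b1 else 0)
    h11 <- -dat$S11 / pars$sigma^2 - pars$alpha^2 * C0 - pars$Dinv[1, 1]
    if (d == 2) {
      C1 <- node_sum(cn * dat$node_t, dat)
      C2 <- node_sum(cn * dat$node_t^2, dat)
      zrt <- ca$ut - dat$S1t * b0 - dat$Stt * b1
      g2 <- zrt / pars$sigma^2 + dat$delta * pars$alpha * dat$Tobs -
        pars$alpha * C1 - (pars$Dinv[1, 2] * b0 + pars$Dinv[2, 2] * b1)
      h12 <- -dat$S1t / pars$sigma^2 - pars$alpha^2 * C1 - pars$Dinv[1, 2]
      h22 <- -dat$Stt / pars$sigma^2 - pars$alpha^2 * C2 - pars$Dinv[2, 2]
      det <- h11 * h22 - h12^2
      db0 <- -( h22 * g1 - h12 * g2) / det
      db1 <- -(-h12 * g1 + h11 * g2) / det
    } else {
      db0 <- -g1 / h11
      db1 <- NULL
    }
    gmax <- max(abs(g1), if (d == 2) abs(g2) else 0)
    if (gmax < 1e-8) break
    step <- 1
    repeat {
      nb0 <- b0 + step * db0
      nb1 <- if (d == 2) b1 + step * db1 else NULL
      fn <- logf_b(nb0, nb1, pars, dat, ca)
      if (all(fn >= f - 1e-12) || step < 1 / 64) break
      step <- step / 2
    }
    b0 <- nb0; b1 <- nb1; f <- fn
  }
  ## final Hessian at the mode
  cn <- exp(ca$qnode + pars$alpha *
              (b0[dat$node_sub] + if (d == 2) b1[dat$node_sub] * dat$node_t else 0))
  C0 <- node_sum(cn, dat)
  h11 <- -dat$S11 / pars$sigma^2 - pars$alpha^2 * C0 - pars$Dinv[1, 1]
  if (d == 2) {
    C1 <- node_sum(cn * dat$node_t, dat)
    C2 <- node_sum(cn * dat$node_t^2, dat)
    h12 <- -dat$S1t / pars$sigma^2 - pars$alpha^2 * C1 - pars$Dinv[1, 2]
    h22 <- -dat$Stt / pars$sigma^2 - pars$alpha^2 * C2 - pars$Dinv[2, 2]
    list(b0 = b0, b1 = b1, h11 = h11, h12 = h12, h22 = h22)
  } else {
    list(b0 = b0, b1 = NULL, h11 = h11)
  }
}

## Marginal log-likelihood (sum over subjects) at unpacked parameters.
## mode_env caches posterior modes between calls for warm starts.
marginal_loglik <- function(pars, dat, mode_env = NULL) {
  ca <- theta_cache(pars, dat)
  b_init <- if (!is.null(mode_env) && !is.null(mode_env$b)) mode_env$b else NULL
  md <- newton_modes(pars, dat, ca, b_init)
  if (!is.null(mode_env)) {
    mode_env$b <- cbind(md$b0, if (dat$d == 2) md$b1)
  }
  gh <- gh_nodes(dat$spec$gh_nodes)
  if (dat$d == 2) {
    m11 <- -md$h11; m12 <- -md$h12; m22 <- -md$h22
    l11 <- sqrt(m11); l21 <- m12 / l11; l22 <- sqrt(pmax(m22 - l21^2, 1e-12))
    a11 <- 1 / l11; a12 <- -l21 / (l11 * l22); a22 <- 1 / l22
    U <- expand.grid(u1 = gh$x, u2 = gh$x)
    Wg <- as.vector(outer(gh$w, gh$w))
    sg <- U$u1^2 + U$u2^2
    G <- nrow(U)
    M <- matrix(0, dat$n, G)
    for (g in seq_len(G)) {
      b0g <- md$b0 + sqrt(2) * (a11 * U$u1[g] + a12 * U$u2[g])
      b1g <- md$b1 + sqrt(2) * (a22 * U$u2[g])
      M[, g] <- logf_b(b0g, b1g, pars, dat, ca) + sg[g] + log(Wg[g])
    }
    li <- logsumexp(M) + log(2) - log(l11 * l22)
  } else {
    l11 <- sqrt(-md$h11)
    G <- length(gh$x)
    M <- matrix(0, dat$n, G)
    for (g in seq_len(G)) {
      b0g <- md$b0 + sqrt(2) * gh$x[g] / l11
      M[, g] <- logf_b(b0g, NULL, pars, dat, ca) + gh$x[g]^2 + log(gh$w[g])
    }
    li <- logsumexp(M) + 0.5 * log(2) - log(l11)
  }
  sum(li)
}

#' Joint log-likelihood at fixed parameter values
#'
#' Evaluates the marginal joint log-likelihood (longitudinal + survival,
#' random effects integrated out by adaptive Gauss-Hermite quadrature) at
#' user-supplied parameter values — useful for likelihood cross-checks and
#' for building reference fits at known (e.g. true generative) parameters.
#'
#' @param params named list with `beta` (length = 2 + number of longitudinal
#'   covariates: intercept, time slope, covariate effects), `sigma`, `D`
#'   (d x d), `h0` (one value per hazard piece), `gamma`, `alpha`.
#' @param longitudinal,survival data frames as in [fit_joint_model()].
#' @param covariates baseline covariate table (one row per subject).
#' @param spec a [jm_spec()].
#' @param breaks optional baseline-hazard breakpoints (length
#'   `length(h0) + 1`); defaults to event-time quantile knots.
#' @return scalar log-likelihood.
#' @export
joint_loglik <- function(params, longitudinal, survival, covariates = NULL,
                         spec = jm_spec(), breaks = NULL) {
  dat <- jm_prepare(longitudinal, survival, covariates, spec, breaks)
  if (length(params$h0) != dat$K) {
    stop(sprintf("h0 has %d pieces but the hazard grid has %d",
                 length(params$h0), dat$K), call. = FALSE)
  }
  pars <- unpack_theta(pack_theta(params, dat), dat)
  marginal_loglik(pars, dat)
}
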