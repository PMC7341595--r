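# Exact GP inference for the SM-LMC model: marginal likelihood, analytic
# gradients, MAP fitting by alternating closed-form scale updates with scaled
# conjugate gradients, and posterior prediction.

# Cholesky with escalating relative jitter (1e-8 * mean diag, x10 per retry,
# ceiling 1e-2) before raising a numerical error carrying the attempts.
chol_jitter <- function(K) {
  U <- tryCatch(chol(K), error = function(e) NULL)
  if (!is.null(U)) return(list(U = U, jitter = 0))
  md <- mean(diag(K))
  jit <- .medgp_jitter0
  tried <- numeric(0)
  while (jit <= .medgp_jitter_max) {
    tried <- c(tried, jit)
    U <- tryCatch(chol(K + diag(jit * md, nrow(K))), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, jitter = jit))
    jit <- jit * 10
  }
  abort(paste0("Cholesky factorization failed; attempted relative jitters: ",
               paste(signif(tried, 3), collapse = ", ")),
        class = "medgp_numerical_error")
}

# Group-sum a T x T matrix into a D x D matrix by covariate index on both axes.
group_sum_dd <- function(W, d_idx, D) {
  G1 <- rowsum(W, group = d_idx, reorder = TRUE)            # |d| x T
  G2 <- rowsum(t(G1), group = d_idx, reorder = TRUE)        # |d| x |d|
  present <- sort(unique(d_idx))
  G <- matrix(0, D, D)
  G[present, present] <- t(G2)
  G
}

# --- parameter packing -------------------------------------------------------

# The optimizer works on an unconstrained vector: log(mu), log(v), raw A
# entries, log(lambda), log(sigma^2). Entries that are structurally fixed
# (mu = 0 squared-exponential kernels, frozen A entries, lambda or noise held)
# are masked out and always read back from the base model.
pack_model <- function(model, fit_noise = TRUE, freeze_A = NULL,
                       fit_mu = NULL) {
  Q <- model_Q(model); D <- model_D(model); R <- model_R(model)
  n_a <- Q * D * R
  layout <- list(
    lmu = seq_len(Q),
    lv = Q + seq_len(Q),
    a = 2 * Q + seq_len(n_a),
    llam = 2 * Q + n_a + seq_len(Q * D),
    ls2 = 2 * Q + n_a + Q * D + seq_len(D)
  )
  par <- numeric(2 * Q + n_a + Q * D + D)
  free <- logical(length(par))
  mus <- vapply(model$basis, `[[`, numeric(1), "mu")
  vs <- vapply(model$basis, `[[`, numeric(1), "v")
  if (is.null(fit_mu)) fit_mu <- mus > 0
  par[layout$lmu] <- ifelse(mus > 0, log(pmax(mus, 1e-300)), 0)
  free[layout$lmu] <- fit_mu & mus > 0
  par[layout$lv] <- ifelse(vs > 0, log(pmax(vs, 1e-300)), 0)
  free[layout$lv] <- vs > 0
  a_all <- unlist(lapply(model$weights, function(w) as.numeric(w$A)))
  par[layout$a] <- a_all
  if (is.null(freeze_A)) {
    free[layout$a] <- TRUE
  } else {
    free[layout$a] <- !unlist(freeze_A)
  }
  lam_all <- unlist(lapply(model$weights, `[[`, "lambda"))
  par[layout$llam] <- ifelse(lam_all > 0, log(pmax(lam_all, 1e-300)), 0)
  free[layout$llam] <- lam_all > 0
  par[layout$ls2] <- log(model$noise_var)
  free[layout$ls2] <- isTRUE(fit_noise)
  list(par = par, free = free, layout = layout, base = model,
       Q = Q, D = D, R = R)
}

unpack_model <- function(skel, par) {
  Q <- skel$Q; D <- skel$D; R <- skel$R
  m <- skel$base
  lay <- skel$layout
  # cap log-scale entries so rejected optimizer trial steps cannot overflow
  # exp(); values this large are never accepted
  idx_log <- c(lay$lmu, lay$lv, lay$llam, lay$ls2)
  par[idx_log] <- pmin(par[idx_log], 50)
  for (q in seq_len(Q)) {
    if (skel$free[lay$lmu[q]]) m$basis[[q]]$mu <- exp(par[lay$lmu[q]])
    if (skel$free[lay$lv[q]]) m$basis[[q]]$v <- exp(par[lay$lv[q]])
    a_idx <- lay$a[((q - 1) * D * R) + seq_len(D * R)]
    A <- matrix(par[a_idx], D, R)
    Abase <- skel$base$weights[[q]]$A
    fr <- matrix(skel$free[a_idx], D, R)
    A[!fr] <- Abase[!fr]
    m$weights[[q]]$A <- A
    l_idx <- lay$llam[((q - 1) * D) + seq_len(D)]
    lam <- exp(par[l_idx])
    lam[!skel$free[l_idx]] <- skel$base$weights[[q]]$lambda[!skel$free[l_idx]]
    m$weights[[q]]$lambda <- lam
  }
  s2 <- exp(par[lay$ls2])
  s2[!skel$free[lay$ls2]] <- skel$base$noise_var[!skel$free[lay$ls2]]
  m$noise_var <- s2
  m
}

# --- objective and gradient --------------------------------------------------

#' Build objective/gradient closures for a flattened data set
#'
#' Advanced interface used by the fitting loop, the online updater and the
#' gradient-check tests. Returns the negative log posterior (for
#' minimization) and its analytic gradient over the free entries of the
#' packed parameter vector.
#'
#' @param x,y,d_idx Flattened observation times, values (already on the
#'   model's internal scale) and covariate indices.
#' @param skel A packing skeleton from the internal `pack_model()`.
#' @param prior_state,prior_cfg Shrinkage prior state and configuration, or
#'   `NULL` to use the marginal likelihood alone.
#' @return List with `fn(par_free)`, `gr(par_free)`, and `value_parts(par_free)`
#'   (named log-marginal and log-prior components).
#' @keywords internal
#' @export
make_objective <- function(x, y, d_idx, skel, prior_state = NULL,
                           prior_cfg = NULL) {
  D <- skel$D; Q <- skel$Q; R <- skel$R
  lay <- skel$layout
  use_prior <- !is.null(prior_state) && !is.null(prior_cfg)

  cache <- new.env(parent = emptyenv())
  cache$key <- NULL

  compute <- function(par_free) {
    key <- paste(format(par_free, digits = 17), collapse = ",")
    if (identical(cache$key, key)) return(cache$res)
    par <- skel$par
    par[skel$free] <- par_free
    model <- unpack_model(skel, par)
    mp <- model_parts(model)
    bad <- !all(is.finite(c(mp$mu, mp$v, unlist(mp$A), mp$lambda, mp$s2)))
    res_cpp <- if (bad) list(ok = FALSE) else
      .smlmc_ll_grad(x, y, as.integer(d_idx), mp$mu, mp$v, mp$A,
                     mp$lambda, mp$s2, D, TRUE)
    if (!isTRUE(res_cpp$ok)) {
      # infeasible trial point (overflowed parameters or a Gram matrix the
      # jitter ladder cannot factor): report -Inf so the line search rejects
      # the step rather than killing the fit
      res <- list(value = -Inf, grad = rep(0, sum(skel$free)),
                  ll = -Inf, lp = 0)
      cache$key <- key
      cache$res <- res
      return(res)
    }
    ll <- res_cpp$ll
    g <- numeric(length(par))
    for (q in seq_len(Q)) {
      g[lay$a[((q - 1) * D * R) + seq_len(D * R)]] <-
        as.numeric(res_cpp$dA[[q]])
      g[lay$llam[((q - 1) * D) + seq_len(D)]] <-
        res_cpp$dlam[, q] * model$weights[[q]]$lambda
      g[lay$lv[q]] <- res_cpp$dv[q] * model$basis[[q]]$v
      if (skel$free[lay$lmu[q]]) {
        g[lay$lmu[q]] <- res_cpp$dmu[q] * model$basis[[q]]$mu
      }
    }
    g[lay$ls2] <- res_cpp$ds2 * model$noise_var
    lp <- 0
    if (use_prior) {
      lp <- log_prior(model, prior_state, prior_cfg)
      for (q in seq_len(Q)) {
        psi <- pmax(prior_state$psi[[q]], .psi_floor)
        ga <- -model$weights[[q]]$A / psi
        idx <- lay$a[((q - 1) * D * R) + seq_len(D * R)]
        g[idx] <- g[idx] + as.numeric(ga)
        lidx <- lay$llam[((q - 1) * D) + seq_len(D)]
        g[lidx] <- g[lidx] -
          model$weights[[q]]$lambda / prior_cfg$beta_lambda
      }
    }
    res <- list(value = ll + lp, grad = g[skel$free], ll = ll, lp = lp)
    cache$key <- key
    cache$res <- res
    res
  }

  list(
    fn = function(p) -compute(p)$value,
    gr = function(p) -compute(p)$grad,
    value_parts = function(p) {
      r <- compute(p)
      c(log_marginal = r$ll, log_prior = r$lp)
    }
  )
}

# standardization helpers: statistics computed per covariate on the model's
# covariate ordering; sd floor avoids division by zero for constant series
standardize_stats <- function(flat, D) {
  center <- numeric(D); scale <- rep(1, D)
  for (d in seq_len(D)) {
    yv <- flat$y[flat$d == d]
    if (length(yv) > 0) center[d] <- mean(yv)
    if (length(yv) > 1) {
      s <- sd(yv)
      if (is.finite(s) && s > 1e-12) scale[d] <- s
    }
  }
  list(center = center, scale = scale)
}

apply_standardize <- function(y, d_idx, center, scale) {
  (y - center[d_idx]) / scale[d_idx]
}

# split a model into the flat containers the compiled core consumes
model_parts <- function(model) {
  list(
    mu = vapply(model$basis, `[[`, numeric(1), "mu"),
    v = vapply(model$basis, `[[`, numeric(1), "v"),
    A = lapply(model$weights, `[[`, "A"),
    lambda = do.call(cbind, lapply(model$weights, `[[`, "lambda")),
    s2 = model$noise_var
  )
}

# --- public operations -------------------------------------------------------

#' Exact GP log marginal likelihood of one patient under a model
#'
#' \deqn{\log p(y) = -\tfrac12 y^\top (K+\Sigma)^{-1} y
#'   - \tfrac12 \log|K+\Sigma| - \tfrac{T}{2}\log 2\pi,}
#' with `K` the block SM-LMC Gram matrix on the flattened observations,
#' `Sigma` the diagonal of per-covariate noise variances and a zero mean
#' function. If the model carries standardization statistics the values are
#' standardized first (the kernel lives on that scale).
#'
#' @param model A [medgp_model()].
#' @param patient A single-patient `medgp_cohort` with >= 1 observation.
#' @return Scalar log marginal likelihood.
#' @export
log_marginal <- function(model, patient) {
  flat <- flatten_vectors(patient, model$covariate_names)
  if (length(flat$x) < 1) abort("patient has no observations")
  y <- flat$y
  if (!is.null(model$center)) {
    y <- apply_standardize(y, flat$d, model$center, model$scale)
  }
  mp <- model_parts(model)
  res <- .smlmc_ll_grad(flat$x, y, as.integer(flat$d), mp$mu, mp$v, mp$A,
                        mp$lambda, mp$s2, model_D(model), FALSE)
  if (!isTRUE(res$ok)) {
    abort("Cholesky factorization failed after jitter escalation",
          class = "medgp_numerical_error")
  }
  res$ll
}

#' Fitting configuration
#'
#' Defaults follow the reference protocol: at most 30 outer iterations of the
#' two-block loop with convergence when the objective changes by less than
#' 0.005; 1000 random restarts drawing length scales uniformly in 6-72 h and
#' periods in 24-72 h; `A` entries initialized uniformly in (-1.5, 1.5).
#'
#' @param Q Number of basis kernels.
#' @param R Rank of each coregionalization factor.
#' @param max_iters Maximum outer iterations (>= 1).
#' @param tol Convergence threshold on the change in the objective.
#' @param n_init Number of random initialization candidates.
#' @param ls_range_h,period_range_h,a_init_range Initialization ranges
#'   (hours, hours, unitless).
#' @param lambda_init_range Range for initial diagonal weights.
#' @param noise_init Initial noise variance on the standardized scale.
#' @param seed Integer seed controlling initialization.
#' @param use_sparse_prior Apply the hierarchical shrinkage prior?
#' @param eta Global shrinkage hyperparameter of the prior.
#' @param beta_lambda Laplace scale for the diagonal weights.
#' @param standardize Standardize each covariate before fitting (inverted at
#'   prediction)?
#' @param scg_maxit Inner scaled-conjugate-gradient iterations per outer
#'   cycle.
#' @param fix_mu_zero Freeze all frequencies at zero (squared-exponential
#'   behaviour; used by the SE baseline).
#' @param n_starts Number of top-ranked initialization candidates to start
#'   the optimization from; each runs `triage_iters` outer cycles, the one
#'   with the best objective continues to `max_iters`. Multi-start guards
#'   against period-aliasing local optima.
#' @param triage_iters Outer cycles per start before triage.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(Q = 5, R = 2, max_iters = 30, tol = 0.005,
                       n_init = 1000, ls_range_h = c(6, 72),
                       period_range_h = c(24, 72),
                       a_init_range = c(-1.5, 1.5),
                       lambda_init_range = c(0.01, 0.3),
                       noise_init = 0.1, seed = 1,
                       use_sparse_prior = TRUE, eta = 0.1,
                       beta_lambda = 0.01, standardize = TRUE,
                       scg_maxit = 100, fix_mu_zero = FALSE,
                       n_starts = 1, triage_iters = 2) {
  if (max_iters < 1) abort("max_iters must be >= 1",
                           class = "medgp_validation_error")
  if (tol <= 0) abort("tol must be > 0", class = "medgp_validation_error")
  for (rg in list(ls_range_h, period_range_h, a_init_range,
                  lambda_init_range)) {
    if (length(rg) != 2 || rg[1] > rg[2]) {
      abort("ranges must be ordered pairs", class = "medgp_validation_error")
    }
  }
  structure(list(
    Q = Q, R = R, max_iters = as.integer(max_iters), tol = tol,
    n_init = as.integer(n_init), ls_range_h = ls_range_h,
    period_range_h = period_range_h, a_init_range = a_init_range,
    lambda_init_range = lambda_init_range, noise_init = noise_init,
    seed = as.integer(seed), use_sparse_prior = isTRUE(use_sparse_prior),
    eta = eta, beta_lambda = beta_lambda, standardize = isTRUE(standardize),
    scg_maxit = as.integer(scg_maxit), fix_mu_zero = isTRUE(fix_mu_zero),
    n_starts = as.integer(n_starts), triage_iters = as.integer(triage_iters)
  ), class = "fit_config")
}

# run expr with a local RNG stream derived from seed; the caller's RNG state
# is left untouched
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

draw_candidate <- function(cfg, D) {
  basis <- vector("list", cfg$Q)
  weights <- vector("list", cfg$Q)
  for (q in seq_len(cfg$Q)) {
    l <- runif(1, cfg$ls_range_h[1], cfg$ls_range_h[2])
    p <- runif(1, cfg$period_range_h[1], cfg$period_range_h[2])
    mu <- if (cfg$fix_mu_zero) 0 else period_to_mu(p)
    basis[[q]] <- sm_kernel(mu, lengthscale_to_v(l))
    A <- matrix(runif(D * cfg$R, cfg$a_init_range[1], cfg$a_init_range[2]),
                D, cfg$R)
    lam <- runif(D, cfg$lambda_init_range[1], cfg$lambda_init_range[2])
    weights[[q]] <- coreg_weights(A, lam)
  }
  list(basis = basis, weights = weights)
}

#' Random-restart initialization
#'
#' Draws `n_init` candidate parameter sets (length scale uniform in
#' `ls_range_h`, period uniform in `period_range_h`, `A` entries uniform in
#' `a_init_range`), scores each by the exact log marginal likelihood on the
#' patient, and returns the highest-scoring candidate (first index wins
#' ties). Deterministic given `cfg$seed`.
#'
#' @param patient A single-patient `medgp_cohort`.
#' @param cfg A [fit_config()].
#' @return A [medgp_model()] with standardization statistics attached when
#'   `cfg$standardize` is set.
#' @export
init_random <- function(patient, cfg, top_m = 1L) {
  covs <- attr(patient, "covariates")
  D <- length(covs)
  flat <- flatten_vectors(patient, covs)
  stats <- if (cfg$standardize) standardize_stats(flat, D) else
    list(center = NULL, scale = NULL)
  with_local_seed(cfg$seed, {
    top <- vector("list", top_m)
    top_ll <- rep(-Inf, top_m)
    for (i in seq_len(cfg$n_init)) {
      cand <- draw_candidate(cfg, D)
      m <- medgp_model(cand$basis, cand$weights,
                       noise_var = rep(cfg$noise_init, D),
                       covariate_names = covs,
                       center = stats$center, scale = stats$scale)
      ll <- tryCatch(log_marginal(m, patient), error = function(e) -Inf)
      if (is.finite(ll) && ll > min(top_ll)) {
        j <- which.min(top_ll)
        top[[j]] <- m
        top_ll[j] <- ll
      }
    }
    keep <- is.finite(top_ll)
    if (!any(keep)) abort("all initialization candidates failed",
                          class = "medgp_numerical_error")
    top <- top[keep][order(top_ll[keep], decreasing = TRUE)]
    if (top_m == 1L) top[[1]] else top
  })
}

#' Fit a patient-specific SM-LMC model by MAP
#'
#' Alternates (1) closed-form MAP updates of the latent shrinkage scales
#' ([map_update_scales()]) with (2) scaled-conjugate-gradient maximization of
#' the log posterior over the kernel parameters (frequencies, spectral
#' variances, `A` entries, diagonal weights, noise variances), until the
#' objective changes by less than `cfg$tol` or `cfg$max_iters` outer cycles.
#'
#' @param patient A single-patient `medgp_cohort`.
#' @param cfg A [fit_config()].
#' @param model0 Optional starting model; defaults to [init_random()].
#' @return A list of class `medgp_fit` with fields `model`, `prior_state`,
#'   `trace` (objective per outer iteration), `converged`, `n_iters`,
#'   `log_marginal`.
#' @export
fit_patient <- function(patient, cfg, model0 = NULL) {
  covs <- attr(patient, "covariates")
  flat <- flatten_vectors(patient, covs)
  if (length(flat$x) < 1) abort("patient has no observations")
  starts <- if (!is.null(model0)) list(model0) else
    if (cfg$n_starts > 1L) init_random(patient, cfg, top_m = cfg$n_starts)
    else list(init_random(patient, cfg))
  if (length(starts) > 1L) {
    # triage: a short burn-in from each candidate, continue only the best
    burns <- lapply(starts, function(m0) {
      run_fit_loop(patient, flat, cfg, m0, n_iters = cfg$triage_iters)
    })
    objs <- vapply(burns, function(b) tail(b$trace, 1), numeric(1))
    best <- burns[[which.max(objs)]]
    fit <- run_fit_loop(patient, flat, cfg, best$model,
                        n_iters = cfg$max_iters, state = best$state,
                        trace0 = best$trace)
  } else {
    fit <- run_fit_loop(patient, flat, cfg, starts[[1]],
                        n_iters = cfg$max_iters)
  }
  model <- fit$model
  # noise floor: 1e-6 of the per-covariate sample variance (standardized
  # scale has unit variance)
  model$noise_var <- pmax(model$noise_var, 1e-6)
  structure(list(
    model = model, prior_state = fit$state, trace = fit$trace,
    converged = fit$converged, n_iters = length(fit$trace),
    log_marginal = log_marginal(model, patient),
    patient_id = patient$patient_id[1]
  ), class = "medgp_fit")
}

# the two-block alternating loop; resumable (state/trace carried over)
run_fit_loop <- function(patient, flat, cfg, model0, n_iters,
                         state = NULL, trace0 = numeric(0)) {
  y <- flat$y
  if (!is.null(model0$center)) {
    y <- apply_standardize(y, flat$d, model0$center, model0$scale)
  }
  pcfg <- prior_config(eta = cfg$eta, beta_lambda = cfg$beta_lambda)
  if (is.null(state)) state <- init_prior_state(model0)
  skel <- pack_model(model0, fit_noise = TRUE,
                     fit_mu = if (cfg$fix_mu_zero) rep(FALSE, model_Q(model0)))
  par <- skel$par
  model <- model0
  trace <- trace0
  converged <- FALSE
  prev <- if (length(trace0) > 0) tail(trace0, 1) else NA_real_
  for (it in seq_len(n_iters)) {
    if (cfg$use_sparse_prior) {
      state <- map_update_scales(model, state, pcfg)
    }
    obj <- make_objective(flat$x, y, flat$d, skel,
                          prior_state = if (cfg$use_sparse_prior) state,
                          prior_cfg = if (cfg$use_sparse_prior) pcfg)
    res <- scg_min(par[skel$free], obj$fn, obj$gr, maxit = cfg$scg_maxit)
    par[skel$free] <- res$par
    skel$par <- par
    model <- unpack_model(skel, par)
    qval <- -res$value
    trace <- c(trace, qval)
    if (!is.finite(qval)) {
      abort("non-finite objective during fitting",
            class = "medgp_numerical_error")
    }
    if (!is.na(prev) && abs(qval - prev) < cfg$tol) {
      converged <- TRUE
      break
    }
    prev <- qval
  }
  list(model = model, state = state, trace = trace, converged = converged)
}

#' @export
print.medgp_fit <- function(x, ...) {
  cat(sprintf(
    "<medgp_fit> patient %s: %d outer iterations, %sconverged, logML %.2f\n",
    x$patient_id, x$n_iters, if (x$converged) "" else "NOT ", x$log_marginal))
  print(x$model)
  invisible(x)
}

#' @method tidy medgp_fit
#' @export
tidy.medgp_fit <- function(x, ...) tidy(x$model, ...)

#' @method glance medgp_fit
#' @export
glance.medgp_fit <- function(x, ...) {
  tibble::tibble(
    log_marginal = x$log_marginal,
    objective = tail(x$trace, 1),
    n_iters = x$n_iters,
    converged = x$converged,
    Q = model_Q(x$model), D = model_D(x$model), R = model_R(x$model)
  )
}

#' Posterior predictive mean and variance at query points
#'
#' Standard Gaussian process conditional under the joint SM-LMC kernel. With
#' an empty history the prior is returned: mean zero (in standardized units)
#' and variance `sum_q b_q,(d,d) + sigma_d^2`. Predictive variances include
#' the observation noise, so 95% intervals are intervals for observations.
#'
#' @param object A [medgp_model()].
#' @param history A single-patient `medgp_cohort` of conditioning
#'   observations (may be empty or `NULL`).
#' @param query A data frame with columns `time_hours` and `covariate`.
#' @param ... Unused.
#' @return A tibble `time_hours, covariate, pred_mean, pred_var`.
#' @export
predict.medgp_model <- function(object, history = NULL, query, ...) {
  model <- object
  covs <- model$covariate_names
  qd <- match(query$covariate, covs)
  if (anyNA(qd)) abort("query covariate outside the model's ordering")
  qx <- as.numeric(query$time_hours)
  prior_var_d <- vapply(seq_along(covs), function(d) {
    sum(vapply(model$weights, function(w) build_B(w)[d, d], numeric(1)))
  }, numeric(1))
  center <- if (is.null(model$center)) rep(0, length(covs)) else model$center
  scale <- if (is.null(model$scale)) rep(1, length(covs)) else model$scale
  n_hist <- if (is.null(history)) 0L else nrow(history)
  if (n_hist == 0L) {
    mean_s <- rep(0, length(qx))
    var_s <- prior_var_d[qd] + model$noise_var[qd]
  } else {
    flat <- flatten_vectors(history, covs)
    yh <- apply_standardize(flat$y, flat$d, center, scale)
    K <- gram(model, flat$x, flat$d)
    diag(K) <- diag(K) + model$noise_var[flat$d]
    ch <- chol_jitter(K)
    U <- ch$U
    alpha <- backsolve(U, forwardsolve(t(U), yh))
    Kqh <- gram(model, qx, qd, flat$x, flat$d)
    mean_s <- as.numeric(Kqh %*% alpha)
    Vh <- forwardsolve(t(U), t(Kqh))
    var_s <- prior_var_d[qd] - colSums(Vh^2) + model$noise_var[qd]
    var_s <- pmax(var_s, 1e-12)
  }
  tibble::tibble(
    time_hours = qx,
    covariate = covs[qd],
    pred_mean = mean_s * scale[qd] + center[qd],
    pred_var = var_s * scale[qd]^2
  )
}

#' Full MAP objective (log posterior) of a model/state pair on a patient
#'
#' `log_marginal()` plus [log_prior()]; the prior term is zero when
#' `cfg$use_sparse_prior` is off.
#'
#' @param model A [medgp_model()].
#' @param prior_state A prior state (ignored when the prior is off).
#' @param cfg A [fit_config()].
#' @param patient A single-patient `medgp_cohort`.
#' @return Scalar objective value.
#' @export
map_objective <- function(model, prior_state, cfg, patient) {
  ll <- log_marginal(model, patient)
  if (!cfg$use_sparse_prior) return(ll)
  pcfg <- prior_config(eta = cfg$eta, beta_lambda = cfg$beta_lambda)
  ll + log_prior(model, prior_state, pcfg)
}
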