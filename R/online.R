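# Patient-specific sequential prediction: initialize from the population
# prior, predict each incoming observation from strictly-prior-or-concurrent
# data, then adapt hyperparameters with momentum gradient steps over a
# sliding window, preserving empirical zeros in the A matrices.

#' Online updating configuration
#'
#' Defaults follow the reference protocol: momentum 0.9, learning rate 1e-5,
#' a trailing 72-hour window for the update gradient, and freezing of `A`
#' entries whose magnitude in the empirical prior is at most 1e-3.
#'
#' @param momentum Momentum coefficient in \[0, 1).
#' @param learning_rate Gradient ascent step size (> 0).
#' @param window_h Trailing window (hours) of observations used for the
#'   update gradient.
#' @param freeze_threshold `A` entries with prior magnitude at or below this
#'   stay exactly zero.
#' @param update Perform momentum updates at all?
#' @return A list of class `online_config`.
#' @export
online_config <- function(momentum = 0.9, learning_rate = 1e-5,
                          window_h = 72, freeze_threshold = 1e-3,
                          update = TRUE) {
  if (momentum < 0 || momentum >= 1) abort("momentum must be in [0, 1)")
  if (learning_rate < 0) abort("learning_rate must be >= 0")
  if (window_h <= 0) abort("window_h must be > 0")
  structure(list(momentum = momentum, learning_rate = learning_rate,
                 window_h = window_h, freeze_threshold = freeze_threshold,
                 update = isTRUE(update)), class = "online_config")
}

#' One momentum step on a parameter vector (ascent)
#'
#' `velocity <- momentum * velocity + learning_rate * grad`;
#' the returned `delta` equals the new velocity.
#'
#' @param grad Gradient of the log posterior w.r.t. the parameters.
#' @param velocity Current velocity (same shape).
#' @param cfg An [online_config()].
#' @return List with `delta` (to add to the parameters) and `velocity`.
#' @export
momentum_step <- function(grad, velocity, cfg) {
  if (length(grad) != length(velocity)) abort("shape mismatch in momentum_step")
  if (any(!is.finite(grad))) {
    return(list(delta = rep(0, length(velocity)), velocity = velocity,
                skipped = TRUE))
  }
  velocity <- cfg$momentum * velocity + cfg$learning_rate * grad
  list(delta = velocity, velocity = velocity, skipped = FALSE)
}

#' Sequential online prediction (and adaptation) for one patient
#'
#' Observations are processed in time order. Each observation is predicted
#' from all observations strictly earlier in time plus same-time observations
#' of *other* covariates (same-covariate simultaneous observations are
#' excluded), so no future information is used. After each prediction, if
#' updating is on, one momentum step is taken on all non-frozen
#' hyperparameters using the gradient of the log marginal likelihood
#' restricted to observations within the trailing `window_h` hours. `A`
#' entries whose magnitude in the prior is at or below `freeze_threshold`
#' stay exactly zero.
#'
#' @param patient A single-patient `medgp_cohort`.
#' @param prior A `medgp_prior` or `medgp_model` used as the starting model;
#'   its standardization statistics (population-derived) are applied.
#' @param cfg An [online_config()].
#' @return A tibble of class `medgp_trace` with one row per observation:
#'   `time_hours, covariate, observed, pred_mean, pred_var, in_95ci`. The
#'   final adapted model is attached as attribute `"model"`.
#' @export
run_online <- function(patient, prior, cfg = online_config()) {
  covs <- prior$covariate_names
  flat <- flatten_vectors(patient, covs)
  n <- length(flat$x)
  ord <- order(flat$x, flat$d)
  ev <- list(x = flat$x[ord], y = flat$y[ord], d = flat$d[ord])
  center <- if (is.null(prior$center)) rep(0, length(covs)) else prior$center
  scale <- if (is.null(prior$scale)) rep(1, length(covs)) else prior$scale
  ys <- apply_standardize(ev$y, ev$d, center, scale)

  freeze <- lapply(prior$weights, function(w) abs(w$A) <= cfg$freeze_threshold)
  model <- prior
  class(model) <- "medgp_model"
  # frozen entries are pinned to exact zero for the whole pass
  for (q in seq_along(model$weights)) {
    model$weights[[q]]$A[freeze[[q]]] <- 0
  }
  skel <- pack_model(model, fit_noise = TRUE, freeze_A = freeze)
  par <- skel$par
  velocity <- rep(0, sum(skel$free))
  do_update <- cfg$update && cfg$learning_rate > 0

  rec_mean <- numeric(n); rec_var <- numeric(n)
  for (e in seq_len(n)) {
    t_e <- ev$x[e]
    cond <- which(ev$x < t_e | (ev$x == t_e & ev$d != ev$d[e]))
    if (length(cond) == 0) {
      pr <- predict(model, history = NULL,
                    query = tibble::tibble(time_hours = t_e,
                                           covariate = covs[ev$d[e]]))
    } else {
      hist <- tibble::tibble(
        patient_id = "online", covariate = covs[ev$d[cond]],
        time_hours = ev$x[cond], value = ev$y[cond]
      )
      hist <- as_cohort(hist, covariates = covs)
      pr <- predict(model, history = hist,
                    query = tibble::tibble(time_hours = t_e,
                                           covariate = covs[ev$d[e]]))
    }
    rec_mean[e] <- pr$pred_mean
    rec_var[e] <- pr$pred_var
    if (do_update) {
      win <- which(ev$x > t_e - cfg$window_h & ev$x <= t_e)
      step_ok <- tryCatch({
        obj <- make_objective(ev$x[win], ys[win], ev$d[win], skel)
        g_ascent <- -obj$gr(par[skel$free])
        st <- momentum_step(g_ascent, velocity, cfg)
        if (!st$skipped) {
          par[skel$free] <- par[skel$free] + st$delta
          velocity <- st$velocity
          skel$par <- par
          model <- unpack_model(skel, par)
        }
        TRUE
      }, error = function(e2) FALSE)
      if (!step_ok) {
        warn(sprintf("online update skipped at t = %.2f h (numerical failure)",
                     t_e))
      }
    }
  }
  sd_e <- sqrt(rec_var)
  trace <- tibble::tibble(
    time_hours = ev$x,
    covariate = covs[ev$d],
    observed = ev$y,
    pred_mean = rec_mean,
    pred_var = rec_var,
    in_95ci = abs(ev$y - rec_mean) <= 1.96 * sd_e
  )
  attr(trace, "model") <- model
  class(trace) <- c("medgp_trace", class(tibble::tibble()))
  trace
}
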