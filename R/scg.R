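# Scaled conjugate gradient minimizer (Moller 1993). Second-order step sizes
# are estimated from a one-sided finite difference of the gradient along the
# search direction with a Levenberg-Marquardt style scale, so no line search
# function evaluations are needed. Steps are accepted only when they decrease
# the objective, which makes the outer fitting trace monotone by construction.
#
# fn: function(par) -> objective value (to minimize)
# gr: function(par) -> gradient vector
# Returns list(par, value, n_iter, converged).
scg_min <- function(par, fn, gr, maxit = 200L, tol_f = 1e-8, tol_x = 1e-8) {
  sigma0 <- 1e-4
  n <- length(par)
  x <- par
  fnow <- fn(x)
  if (!is.finite(fnow)) abort("non-finite objective at SCG start",
                              class = "medgp_numerical_error")
  gradnew <- gr(x)
  gradold <- gradnew
  d <- -gradnew
  success <- TRUE
  nsuccess <- 0L
  beta <- 1e-6
  betamin <- 1e-15; betamax <- 1e100
  fold <- fnow
  theta <- 0; kappa <- 0; mu <- 0
  for (j in seq_len(maxit)) {
    if (success) {
      mu <- sum(d * gradnew)
      if (mu >= 0) {
        d <- -gradnew
        mu <- sum(d * gradnew)
      }
      kappa <- sum(d * d)
      if (kappa < .Machine$double.eps) {
        return(list(par = x, value = fnow, n_iter = j, converged = TRUE))
      }
      sigma <- sigma0 / sqrt(kappa)
      gplus <- gr(x + sigma * d)
      theta <- sum(d * (gplus - gradnew)) / sigma
    }
    delta <- theta + beta * kappa
    if (!is.finite(delta) || delta <= 0) {
      delta <- beta * kappa
      beta <- beta - theta / kappa
    }
    alpha <- -mu / delta
    xnew <- x + alpha * d
    fnew <- fn(xnew)
    Delta <- if (is.finite(fnew)) 2 * (fnew - fold) / (alpha * mu) else -1
    if (is.finite(fnew) && Delta >= 0) {
      success <- TRUE
      nsuccess <- nsuccess + 1L
      x <- xnew
      fnow <- fnew
    } else {
      success <- FALSE
      fnow <- fold
    }
    if (success) {
      if (max(abs(alpha * d)) < tol_x && abs(fnew - fold) < tol_f) {
        return(list(par = x, value = fnow, n_iter = j, converged = TRUE))
      }
      fold <- fnew
      gradold <- gradnew
      gradnew <- gr(x)
      if (sum(gradnew^2) == 0) {
        return(list(par = x, value = fnow, n_iter = j, converged = TRUE))
      }
    }
    if (Delta < 0.25) beta <- min(4 * beta, betamax)
    if (Delta > 0.75) beta <- max(beta / 2, betamin)
    if (nsuccess == n) {
      d <- -gradnew
      nsuccess <- 0L
    } else if (success) {
      gam <- (sum(gradold * gradold) - sum(gradnew * gradold)) / mu
      d <- gam * d - gradnew
    }
  }
  list(par = x, value = fnow, n_iter = maxit, converged = FALSE)
}
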