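#' Configuration of the structured shrinkage prior
#'
#' The entries of each coregionalization factor `A_q` carry a four-level
#' hierarchical gamma prior that recapitulates two layers of the horseshoe:
#' \deqn{\tau_{q,(r)} \sim \mathrm{Ga}(\xi, \eta),\;
#'       \phi_{q,(r)} \sim \mathrm{Ga}(\gamma, \tau_{q,(r)}),\;
#'       \delta_{q,(d,r)} \sim \mathrm{Ga}(\beta, \phi_{q,(r)}),}
#' \deqn{\psi_{q,(d,r)} \sim \mathrm{Ga}(\alpha, \delta_{q,(d,r)}),\;
#'       a_{q,(d,r)} \sim \mathcal{N}(0, \psi_{q,(d,r)}),}
#' where every gamma is shape/rate and each level's value acts as the rate of
#' the level below, so a large global \eqn{\tau} shrinks the whole chain.
#' \eqn{\phi, \tau} give column-wise shrinkage (pruning latent functions);
#' \eqn{\psi, \delta} give element-wise shrinkage. The diagonal weights
#' \eqn{\lambda_{q,(d)}} are constrained non-negative and carry a Laplace
#' prior on their magnitude, i.e. an exponential with scale `beta_lambda` on
#' the half-line.
#'
#' @param alpha,beta,gamma,xi Gamma shape hyperparameters (default 0.5 each,
#'   the horseshoe-equivalent setting).
#' @param eta Global shrinkage rate; typically chosen over 0.01/0.1/1.0 by
#'   cross-validation.
#' @param beta_lambda Laplace scale for the diagonal weights (default 0.01).
#' @return A list of class `prior_config`.
#' @export
prior_config <- function(alpha = 0.5, beta = 0.5, gamma = 0.5, xi = 0.5,
                         eta = 0.1, beta_lambda = 0.01) {
  vals <- c(alpha, beta, gamma, xi, eta, beta_lambda)
  if (any(vals <= 0)) abort("all prior hyperparameters must be > 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, xi = xi,
                 eta = eta, beta_lambda = beta_lambda),
            class = "prior_config")
}

# floor used for the local variances psi; keeps the Gaussian factor finite
# when an A entry has been driven to (numerical) zero
.psi_floor <- 1e-6

#' Initialize the latent scale state of the shrinkage prior
#'
#' All local and column scales start at 1, mirroring an uninformative warm
#' start; shapes follow the paired model's `A_q` matrices.
#'
#' @param model A [medgp_model()].
#' @return A list of class `prior_state` with per-kernel fields `psi`,
#'   `delta` (D x R matrices) and `phi`, `tau` (length-R vectors).
#' @export
init_prior_state <- function(model) {
  D <- model_D(model); R <- model_R(model)
  structure(list(
    psi = replicate(model_Q(model), matrix(1, D, R), simplify = FALSE),
    delta = replicate(model_Q(model), matrix(1, D, R), simplify = FALSE),
    phi = replicate(model_Q(model), rep(1, R), simplify = FALSE),
    tau = replicate(model_Q(model), rep(1, R), simplify = FALSE)
  ), class = "prior_state")
}

check_prior_state <- function(state) {
  pos <- function(x) all(unlist(x) > 0)
  if (!pos(state$psi) || !pos(state$delta) || !pos(state$phi) || !pos(state$tau)) {
    abort("prior state scales must be strictly positive",
          class = "medgp_validation_error")
  }
  invisible(state)
}

#' Log-density contribution of the shrinkage prior
#'
#' Sums the log-densities of every factor of the prior product: Gaussian
#' `a | psi`, the gamma chain `psi | alpha, delta`, `delta | beta, phi`,
#' `phi | gamma, tau`, `tau | xi, eta`, and the exponential (half-line
#' Laplace) prior on each `lambda`. The priors on the kernel parameters
#' `mu_q`, `v_q` are flat and contribute zero.
#'
#' @param model A [medgp_model()].
#' @param state A [init_prior_state()] state with matching shapes.
#' @param cfg A [prior_config()].
#' @return The scalar log prior density (up to the flat-prior constant).
#' @export
log_prior <- function(model, state, cfg) {
  check_prior_state(state)
  lp <- 0
  for (q in seq_len(model_Q(model))) {
    A <- model$weights[[q]]$A
    psi <- pmax(state$psi[[q]], .psi_floor)
    lp <- lp + sum(dnorm(A, 0, sqrt(psi), log = TRUE))
    lp <- lp + sum(dgamma(state$psi[[q]], shape = cfg$alpha,
                          rate = state$delta[[q]], log = TRUE))
    lp <- lp + sum(dgamma(state$delta[[q]], shape = cfg$beta,
                          rate = rep(state$phi[[q]], each = nrow(A)), log = TRUE))
    lp <- lp + sum(dgamma(state$phi[[q]], shape = cfg$gamma,
                          rate = state$tau[[q]], log = TRUE))
    lp <- lp + sum(dgamma(state$tau[[q]], shape = cfg$xi,
                          rate = cfg$eta, log = TRUE))
    lam <- model$weights[[q]]$lambda
    lp <- lp + sum(-lam / cfg$beta_lambda - log(cfg$beta_lambda))
  }
  lp
}

# Mode of a Gamma(shape, rate) when it exists and is positive, else the mean
# ("or mean when the mode does not exist"). Vectorized over rate.
gamma_mode_or_mean <- function(shape, rate) {
  n <- max(length(shape), length(rate))
  shape <- rep_len(shape, n)
  rate <- rep_len(rate, n)
  ifelse(shape > 1, (shape - 1) / rate, shape / rate)
}

# Mode of the generalized inverse Gaussian conditional
#   p(psi) \propto psi^{p-1} exp(-(a psi + b/psi)/2),
# which is ((p-1) + sqrt((p-1)^2 + a b)) / a.
gig_mode <- function(p, a, b) {
  ((p - 1) + sqrt((p - 1)^2 + a * b)) / a
}

#' Closed-form MAP updates of the latent shrinkage scales
#'
#' One Gauss-Seidel sweep over the conjugate chain: each scale is set to the
#' mode of its full conditional given the current `A` entries and the other
#' scales, falling back to the conditional mean when the mode is undefined or
#' non-positive. The conditionals are
#' \itemize{
#'   \item `psi | a, delta`: generalized inverse Gaussian with order
#'     `alpha - 1/2`, rate `2 delta` and inverse-rate `a^2`;
#'   \item `delta | psi, phi`: Gamma(`alpha + beta`, `psi + phi`);
#'   \item `phi | delta, tau`: Gamma(`D beta + gamma`, `sum_d delta + tau`);
#'   \item `tau | phi, eta`: Gamma(`gamma + xi`, `phi + eta`).
#' }
#'
#' @param model A [medgp_model()] supplying the current `A` entries.
#' @param state Current [init_prior_state()] state.
#' @param cfg A [prior_config()].
#' @return A new `prior_state`.
#' @export
map_update_scales <- function(model, state, cfg) {
  check_prior_state(state)
  D <- model_D(model)
  for (q in seq_len(model_Q(model))) {
    A <- model$weights[[q]]$A
    a2 <- A^2
    p_gig <- cfg$alpha - 0.5
    psi <- matrix(NA_real_, nrow(A), ncol(A))
    has_mass <- a2 > 0
    psi[has_mass] <- gig_mode(p_gig, 2 * state$delta[[q]][has_mass],
                              a2[has_mass])
    if (any(!has_mass)) {
      # a = 0: the conditional degenerates to Gamma(alpha - 1/2, delta)
      psi[!has_mass] <- gamma_mode_or_mean(p_gig, state$delta[[q]][!has_mass])
    }
    psi <- pmax(psi, .psi_floor)
    delta <- matrix(gamma_mode_or_mean(cfg$alpha + cfg$beta,
                                       psi + rep(state$phi[[q]], each = D)),
                    D, ncol(A))
    phi <- gamma_mode_or_mean(cfg$beta * D + cfg$gamma,
                              colSums(delta) + state$tau[[q]])
    tau <- gamma_mode_or_mean(cfg$gamma + cfg$xi, phi + cfg$eta)
    state$psi[[q]] <- psi
    state$delta[[q]] <- delta
    state$phi[[q]] <- phi
    state$tau[[q]] <- tau
  }
  state
}

#' Draw from the generative shrinkage chain
#'
#' Samples `a` values through the four-level gamma hierarchy; used to study
#' the marginal shrinkage profile (heavy tails, concentration at zero).
#'
#' @param n Number of draws.
#' @param cfg A [prior_config()].
#' @return Numeric vector of `a` draws.
#' @export
r_shrinkage_marginal <- function(n, cfg) {
  tau <- stats::rgamma(n, shape = cfg$xi, rate = cfg$eta)
  phi <- stats::rgamma(n, shape = cfg$gamma, rate = tau)
  delta <- stats::rgamma(n, shape = cfg$beta, rate = phi)
  psi <- stats::rgamma(n, shape = cfg$alpha, rate = delta)
  rnorm(n, 0, sqrt(psi))
}
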