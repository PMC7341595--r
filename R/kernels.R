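#' Spectral mixture basis kernel
#'
#' A stationary basis kernel over time distances,
#' \deqn{\kappa_q(\rho) = \exp(-2\pi^2\rho^2 v_q)\,\cos(2\pi\rho\mu_q),}
#' with \eqn{\rho = |t - t'|} in hours. The frequency \eqn{\mu_q} (cycles per
#' hour) sets the characteristic period \eqn{1/\mu_q}; the spectral variance
#' \eqn{v_q} sets the characteristic length scale \eqn{1/(2\pi\sqrt{v_q})}.
#' With \eqn{\mu_q = 0} the kernel reduces to a squared-exponential; the
#' mixture weights live in the coregionalization matrices, so
#' \eqn{\kappa_q(0) = 1} exactly.
#'
#' @param mu Frequency in cycles per hour (>= 0).
#' @param v Spectral variance in 1/hour^2 (>= 0).
#' @return A list of class `sm_kernel` with fields `mu`, `v`.
#' @seealso [sm_eval()], [period_to_mu()], [lengthscale_to_v()]
#' @export
sm_kernel <- function(mu, v) {
  stopifnot(is.numeric(mu), is.numeric(v), length(mu) == 1, length(v) == 1)
  if (mu < 0 || v < 0) abort("sm_kernel requires mu >= 0 and v >= 0")
  structure(list(mu = as.numeric(mu), v = as.numeric(v)), class = "sm_kernel")
}

#' Evaluate a spectral mixture basis kernel at time distances
#'
#' @param rho Non-negative time distances |t - t'| in hours (vectorized).
#' @param kernel An [sm_kernel()].
#' @return Kernel values in \[-1, 1\].
#' @export
sm_eval <- function(rho, kernel) {
  if (any(rho < 0)) {
    abort("sm_eval expects absolute time distances (rho >= 0)",
          class = "medgp_validation_error")
  }
  exp(-2 * pi^2 * rho^2 * kernel$v) * cos(2 * pi * rho * kernel$mu)
}

#' Conversions between natural kernel quantities and (mu, v)
#'
#' The single source of truth for the period/frequency and
#' length-scale/spectral-variance conversions used by initialization and
#' reporting: `v = 1 / (2 pi l)^2` and `mu = 1 / p`.
#'
#' @param p Period in hours.
#' @param l Length scale in hours.
#' @param mu Frequency in cycles/hour.
#' @param v Spectral variance in 1/hour^2.
#' @return The converted quantity.
#' @name sm-conversions
NULL

#' @rdname sm-conversions
#' @export
period_to_mu <- function(p) 1 / p

#' @rdname sm-conversions
#' @export
mu_to_period <- function(mu) 1 / mu

#' @rdname sm-conversions
#' @export
lengthscale_to_v <- function(l) 1 / (2 * pi * l)^2

#' @rdname sm-conversions
#' @export
v_to_lengthscale <- function(v) 1 / (2 * pi * sqrt(v))

#' Coregionalization weights for one basis kernel
#'
#' Holds the low-rank factor `A` (D x R) and the non-negative diagonal
#' augmentation `lambda` (length D) that parameterize the cross-covariate
#' weight matrix `B = A A' + diag(lambda)`, guaranteed symmetric positive
#' semi-definite (strictly positive definite when all lambda > 0).
#'
#' @param A Numeric D x R matrix.
#' @param lambda Non-negative numeric vector of length D.
#' @return A list of class `coreg_weights`.
#' @export
coreg_weights <- function(A, lambda) {
  A <- as.matrix(A)
  if (length(lambda) != nrow(A)) {
    abort("lambda must have one entry per covariate (row of A)")
  }
  if (any(lambda < 0)) abort("lambda entries must be non-negative")
  structure(list(A = A, lambda = as.numeric(lambda)), class = "coreg_weights")
}

#' Build the cross-covariate weight matrix B = A A' + diag(lambda)
#'
#' @param w A [coreg_weights()].
#' @return A symmetric positive semi-definite D x D matrix whose smallest
#'   eigenvalue is at least `min(lambda)` (up to numerical tolerance).
#' @export
build_B <- function(w) {
  B <- tcrossprod(w$A)
  diag(B) <- diag(B) + w$lambda
  B
}

#' Construct a multi-output SM-LMC model
#'
#' The full model for one patient (or a population prior): `Q` spectral
#' mixture basis kernels, per-kernel coregionalization weights, and
#' per-covariate residual noise variances. The joint kernel between
#' observation `(d, t)` and `(d', t')` is
#' \deqn{\kappa((d,t),(d',t')) = \sum_q b_{q,(d,d')}\,\kappa_q(|t-t'|).}
#'
#' @param basis List of `Q` [sm_kernel()] objects.
#' @param weights List of `Q` [coreg_weights()] objects sharing D.
#' @param noise_var Positive length-D vector of residual variances.
#' @param covariate_names Ordered character vector of length D.
#' @param center,scale Optional per-covariate standardization statistics
#'   (length-D); the scale on which the model's kernel operates.
#' @return A list of class `medgp_model`.
#' @export
medgp_model <- function(basis, weights, noise_var, covariate_names,
                        center = NULL, scale = NULL) {
  Q <- length(basis)
  if (length(weights) != Q) abort("basis and weights must have equal length Q")
  D <- length(covariate_names)
  for (w in weights) {
    if (nrow(w$A) != D) abort("weights dimension D must match covariate_names")
  }
  if (length(noise_var) != D || any(noise_var <= 0)) {
    abort("noise_var must be a positive length-D vector")
  }
  structure(list(
    basis = basis, weights = weights,
    noise_var = as.numeric(noise_var),
    covariate_names = as.character(covariate_names),
    center = center, scale = scale
  ), class = "medgp_model")
}

model_Q <- function(model) length(model$basis)
model_D <- function(model) length(model$covariate_names)
model_R <- function(model) if (model_Q(model) > 0) ncol(model$weights[[1]]$A) else 0L

#' @export
print.medgp_model <- function(x, ...) {
  cat(sprintf("<medgp_model> Q = %d basis kernels, D = %d covariates, R = %d\n",
              model_Q(x), model_D(x), model_R(x)))
  for (q in seq_len(model_Q(x))) {
    k <- x$basis[[q]]
    per <- if (k$mu > 0) sprintf("%.1f h", 1 / k$mu) else "none (SE)"
    ls <- if (k$v > 0) sprintf("%.1f h", v_to_lengthscale(k$v)) else "Inf"
    cat(sprintf("  kernel %d: period %s, length scale %s\n", q, per, ls))
  }
  invisible(x)
}

#' Gram matrix of the block-structured SM-LMC kernel
#'
#' Computes the covariance between flattened observation sets, each given as
#' times plus covariate indices. When `x2`/`d2` are omitted the result is the
#' symmetric PSD Gram matrix of `(x, d_idx)` (without observation noise).
#'
#' @param model A [medgp_model()].
#' @param x Numeric vector of observation times (hours).
#' @param d_idx Integer vector of covariate indices in 1..D, same length as
#'   `x`.
#' @param x2,d2 Optional second set; defaults to the first.
#' @return A `length(x)` by `length(x2)` covariance matrix.
#' @export
gram <- function(model, x, d_idx, x2 = NULL, d2 = NULL) {
  if (length(x) != length(d_idx)) abort("x and d_idx lengths differ")
  D <- model_D(model)
  if (length(d_idx) && (min(d_idx) < 1 || max(d_idx) > D)) {
    abort("cov_index out of range 1..D", class = "medgp_validation_error")
  }
  if (is.null(x2)) { x2 <- x; d2 <- d_idx }
  if (length(x2) != length(d2)) abort("x2 and d2 lengths differ")
  if (length(d2) && (min(d2) < 1 || max(d2) > D)) {
    abort("cov_index out of range 1..D", class = "medgp_validation_error")
  }
  rho <- abs(outer(x, x2, "-"))
  K <- matrix(0, length(x), length(x2))
  for (q in seq_len(model_Q(model))) {
    Bq <- build_B(model$weights[[q]])
    K <- K + Bq[cbind(rep(d_idx, length(d2)), rep(d2, each = length(d_idx)))] *
      sm_eval(rho, model$basis[[q]])
  }
  K
}

#' Count model hyperparameters
#'
#' Each basis kernel contributes its frequency and spectral variance plus the
#' D x R weight-matrix entries and the D diagonal weights; optionally the D
#' per-covariate noise variances are counted too. For the full configuration
#' Q = 5, D = 24, R = 8 with noise this totals 1114.
#'
#' @param Q Number of basis kernels (>= 1).
#' @param D Number of covariates (>= 1).
#' @param R Rank of each coregionalization factor (>= 1).
#' @param include_noise Count the D noise variances as well?
#' @return Integer count `Q (2 + D R + D)` plus `D` if `include_noise`.
#' @export
count_hyperparameters <- function(Q, D, R, include_noise = FALSE) {
  if (Q < 1 || D < 1 || R < 1) {
    abort("Q, D and R must all be >= 1", class = "medgp_validation_error")
  }
  n <- Q * (2 + D * R + D)
  if (isTRUE(include_noise)) n <- n + D
  as.integer(n)
}

#' Serialize a model (or population prior) to JSON
#'
#' Round-trip stable for the 17-significant-digit decimal representation.
#'
#' @param model A `medgp_model` or `medgp_prior`.
#' @param path Output path for the JSON document.
#' @return `path`, invisibly.
#' @export
write_medgp_model <- function(model, path) {
  doc <- list(
    Q = model_Q(model), D = model_D(model), R = model_R(model),
    covariate_names = model$covariate_names,
    kernels = lapply(seq_len(model_Q(model)), function(q) {
      list(mu = model$basis[[q]]$mu, v = model$basis[[q]]$v,
           A = as.numeric(t(model$weights[[q]]$A)),  # row-major
           lambda = model$weights[[q]]$lambda)
    }),
    noise_var = model$noise_var
  )
  if (!is.null(model$center)) doc$center <- model$center
  if (!is.null(model$scale)) doc$scale <- model$scale
  if (!is.null(model$coverage)) doc$coverage <- model$coverage
  if (!is.null(model$Q_prime)) doc$Q_prime <- model$Q_prime
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a model (or population prior) from JSON
#'
#' @param path Path to a JSON document written by [write_medgp_model()].
#' @return A `medgp_model` (with prior fields restored when present).
#' @export
read_medgp_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  D <- doc$D; R <- doc$R
  kernels <- doc$kernels
  if (is.data.frame(kernels)) {
    kernels <- lapply(seq_len(nrow(kernels)), function(i) {
      list(mu = kernels$mu[i], v = kernels$v[i],
           A = kernels$A[[i]], lambda = kernels$lambda[[i]])
    })
  }
  basis <- lapply(kernels, function(k) sm_kernel(k$mu, k$v))
  weights <- lapply(kernels, function(k) {
    coreg_weights(matrix(as.numeric(k$A), nrow = D, ncol = R, byrow = TRUE),
                  as.numeric(k$lambda))
  })
  m <- medgp_model(basis, weights, as.numeric(doc$noise_var),
                   as.character(doc$covariate_names),
                   center = if (!is.null(doc$center)) as.numeric(doc$center),
                   scale = if (!is.null(doc$scale)) as.numeric(doc$scale))
  if (!is.null(doc$coverage)) {
    m$coverage <- as.numeric(doc$coverage)
    m$Q_prime <- as.integer(doc$Q_prime)
    class(m) <- c("medgp_prior", class(m))
  }
  m
}

#' @method tidy medgp_model
#' @export
tidy.medgp_model <- function(x, ...) {
  purrr::map_dfr(seq_len(model_Q(x)), function(q) {
    k <- x$basis[[q]]
    B <- build_B(x$weights[[q]])
    tibble::tibble(
      kernel = q, mu = k$mu, v = k$v,
      period_h = ifelse(k$mu > 0, 1 / k$mu, Inf),
      lengthscale_h = ifelse(k$v > 0, v_to_lengthscale(k$v), Inf),
      b_trace = sum(diag(B)),
      b_max = max(abs(B)),
      sparsity = mean(abs(B) <= .medgp_near_zero)
    )
  })
}

#' @method glance medgp_model
#' @export
glance.medgp_model <- function(x, ...) {
  tibble::tibble(
    Q = model_Q(x), D = model_D(x), R = model_R(x),
    n_hyperparameters = count_hyperparameters(
      model_Q(x), model_D(x), model_R(x), include_noise = TRUE)
  )
}
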