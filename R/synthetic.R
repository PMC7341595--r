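# Seeded generator of EHR-like cohorts drawn from a known SM-LMC model:
# per-covariate jittered-gap renewal sampling (vitals every few hours, labs
# roughly daily, unaligned across covariates and patients), exact joint
# latent draws, per-covariate Gaussian noise.

#' Canned generating models for synthetic scenarios
#'
#' \describe{
#'   \item{`"two_correlated"`}{Two lab covariates (a PT/INR-like pair) sharing
#'     one long-term rank-1 kernel plus a weaker shared circadian kernel.}
#'   \item{`"vitals_labs"`}{Five covariates: two vitals carrying a 24-hour
#'     periodic kernel, and a strongly correlated lab triple (an
#'     Hct/Hgb/RBC-like block) on a long-term (> 3 day) smooth kernel.}
#'   \item{`"independent"`}{Diagonal coregionalization (no cross-covariate
#'     structure); a negative control.}
#' }
#'
#' @param scenario Scenario name.
#' @return A [medgp_model()] usable as a generating truth.
#' @export
default_truth <- function(scenario = c("two_correlated", "vitals_labs",
                                       "independent")) {
  scenario <- match.arg(scenario)
  z2 <- c(0, 0)
  switch(scenario,
    two_correlated = medgp_model(
      basis = list(
        sm_kernel(0, lengthscale_to_v(100)),        # long-term trend
        sm_kernel(1 / 24, lengthscale_to_v(36))     # circadian
      ),
      weights = list(
        coreg_weights(cbind(c(0.9, 0.9), z2), c(0.02, 0.02)),  # rank-1 shared
        coreg_weights(cbind(c(0.55, 0.5), z2), c(0.01, 0.01))
      ),
      noise_var = c(0.04, 0.04),
      covariate_names = c("pt", "inr")
    ),
    vitals_labs = medgp_model(
      basis = list(
        sm_kernel(0, lengthscale_to_v(80)),         # > 3 day smooth
        sm_kernel(1 / 24, lengthscale_to_v(48))     # circadian, vitals block
      ),
      weights = list(
        coreg_weights(cbind(c(0, 0, 0.9, 0.85, 0.8), rep(0, 5)),
                      c(0.02, 0.02, 0.04, 0.04, 0.04)),
        coreg_weights(cbind(c(0.8, 0.7, 0, 0, 0), rep(0, 5)),
                      c(0.02, 0.02, 0.01, 0.01, 0.01))
      ),
      noise_var = c(0.06, 0.06, 0.04, 0.04, 0.04),
      covariate_names = c("hr", "resp", "hct", "hgb", "rbc")
    ),
    independent = medgp_model(
      basis = list(
        sm_kernel(0, lengthscale_to_v(60)),
        sm_kernel(1 / 24, lengthscale_to_v(36))
      ),
      weights = list(
        coreg_weights(cbind(z2, z2), c(0.7, 0.7)),
        coreg_weights(cbind(z2, z2), c(0.3, 0.3))
      ),
      noise_var = c(0.05, 0.05),
      covariate_names = c("lab1", "lab2")
    )
  )
}

# default per-covariate mean inter-observation gaps (hours): vitals every
# 4 h, labs roughly daily
default_gaps <- function(covariate_names) {
  vitals <- c("hr", "resp", "sbp", "temp")
  setNames(ifelse(covariate_names %in% vitals, 4, 24), covariate_names)
}

#' Simulation configuration
#'
#' @param n_patients Number of patients.
#' @param truth Generating [medgp_model()] (e.g. [default_truth()]).
#' @param stay_range_h Length-of-stay range (hours), drawn uniformly.
#' @param gaps Named per-covariate mean inter-observation gaps (hours);
#'   defaults to 3.5 h for vitals-like names and 24 h otherwise.
#' @param gap_jitter Multiplicative jitter range applied to each gap.
#' @param seed Integer seed; cohorts are bit-identical under equal seeds.
#' @param max_obs Per-patient cap on total observations (exact joint draws
#'   use a dense Cholesky).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients, truth, stay_range_h = c(96, 240),
                       gaps = NULL, gap_jitter = c(0.5, 1.5), seed = 1,
                       max_obs = 1500) {
  if (length(stay_range_h) != 2 || stay_range_h[1] > stay_range_h[2]) {
    abort("stay_range_h must be an ordered pair",
          class = "medgp_validation_error")
  }
  if (is.null(gaps)) gaps <- default_gaps(truth$covariate_names)
  if (any(gaps <= 0)) abort("gaps must be positive",
                            class = "medgp_validation_error")
  structure(list(n_patients = as.integer(n_patients), truth = truth,
                 stay_range_h = stay_range_h, gaps = gaps,
                 gap_jitter = gap_jitter, seed = as.integer(seed),
                 max_obs = as.integer(max_obs)),
            class = "sim_config")
}

#' Simulate a cohort from a known SM-LMC model
#'
#' For each patient: draw a length of stay uniformly in `stay_range_h`; draw
#' per-covariate observation times by a jittered-gap renewal process
#' (unaligned across covariates and patients); draw the joint latent function
#' at all flattened times exactly from the zero-mean GP with the truth
#' kernel; add per-covariate Gaussian noise. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `cohort` (a `medgp_cohort`) and `truth` (the
#'   generating model plus per-patient latent records for recovery tests).
#' @export
simulate_cohort <- function(cfg) {
  truth <- cfg$truth
  covs <- truth$covariate_names
  # validate the generating kernel is usable before drawing anything
  probe <- gram(truth, c(0, 1), c(1L, 1L))
  if (any(!is.finite(probe))) {
    abort("degenerate truth kernel", class = "medgp_validation_error")
  }
  with_local_seed(cfg$seed, {
    rows <- list(); latents <- list()
    for (i in seq_len(cfg$n_patients)) {
      stay <- runif(1, cfg$stay_range_h[1], cfg$stay_range_h[2])
      xs <- list()
      for (cv in covs) {
        gap <- cfg$gaps[[cv]]
        t_cur <- gap * runif(1, cfg$gap_jitter[1], cfg$gap_jitter[2])
        ts <- numeric(0)
        while (t_cur <= stay) {
          ts <- c(ts, t_cur)
          t_cur <- t_cur + gap * runif(1, cfg$gap_jitter[1], cfg$gap_jitter[2])
        }
        xs[[cv]] <- ts
      }
      x <- unlist(xs, use.names = FALSE)
      d <- rep(seq_along(covs), lengths(xs))
      if (length(x) > cfg$max_obs) {
        keep <- sort(sample.int(length(x), cfg$max_obs))
        x <- x[keep]; d <- d[keep]
      }
      if (length(x) == 0) next
      K <- gram(truth, x, d)
      ch <- chol_jitter(K + diag(1e-10 * max(mean(diag(K)), 1), length(x)))
      f <- as.numeric(t(ch$U) %*% rnorm(length(x)))
      y <- f + rnorm(length(x), 0, sqrt(truth$noise_var[d]))
      pid <- sprintf("sim%03d", i)
      rows[[i]] <- tibble::tibble(
        patient_id = pid, covariate = covs[d], time_hours = x, value = y
      )
      latents[[pid]] <- tibble::tibble(
        time_hours = x, covariate = covs[d], latent = f
      )
    }
    empty <- tibble::tibble(patient_id = character(), covariate = character(),
                            time_hours = numeric(), value = numeric())
    cohort <- as_cohort(dplyr::bind_rows(c(list(empty), rows)),
                        covariates = covs)
    list(cohort = cohort,
         truth = list(model = truth, latents = latents, config = cfg))
  })
}
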