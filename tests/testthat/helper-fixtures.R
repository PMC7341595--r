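# Shared fixture builders: small random cohorts/models generated in code.

# a random valid model with positive-definite weights
random_model <- function(Q = 2, D = 2, R = 2, seed = 1,
                         covs = paste0("c", seq_len(D))) {
  withr::with_seed(seed, {
    basis <- lapply(seq_len(Q), function(q) {
      sm_kernel(mu = runif(1, 1 / 72, 1 / 24),
                v = lengthscale_to_v(runif(1, 6, 72)))
    })
    weights <- lapply(seq_len(Q), function(q) {
      coreg_weights(matrix(runif(D * R, -1, 1), D, R),
                    runif(D, 0.05, 0.3))
    })
    medgp_model(basis, weights, noise_var = runif(D, 0.05, 0.2),
                covariate_names = covs)
  })
}

# a random flattened data set (times, values, covariate indices)
random_flat <- function(Tn = 20, D = 2, seed = 1, t_max = 100) {
  withr::with_seed(seed, {
    list(x = sort(runif(Tn, 0, t_max)),
         y = rnorm(Tn),
         d = sample.int(D, Tn, replace = TRUE))
  })
}

flat_to_patient <- function(flat, covs, id = "p1") {
  as_cohort(tibble::tibble(
    patient_id = id, covariate = covs[flat$d],
    time_hours = flat$x, value = flat$y
  ), covariates = covs)
}

# random small cohort tibble (not necessarily GP-distributed)
random_cohort <- function(n_patients = 3, D = 2, seed = 1) {
  covs <- paste0("c", seq_len(D))
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_patients), function(i) {
      n <- sample(3:8, 1)
      tibble::tibble(
        patient_id = sprintf("p%02d", i),
        covariate = sample(covs, n, replace = TRUE),
        time_hours = round(runif(n, 0, 120), 3),
        value = rnorm(n)
      )
    })
    as_cohort(dplyr::bind_rows(rows), covariates = covs)
  })
}

# independent dense log MVN density (solve + determinant, no Cholesky path)
dense_mvn_logpdf <- function(y, K) {
  as.numeric(-0.5 * t(y) %*% solve(K, y) -
               0.5 * determinant(K, logarithm = TRUE)$modulus -
               0.5 * length(y) * log(2 * pi))
}
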