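test_that("featurize evaluates the kernel at hourly lags over 72 h", {
  k <- sm_kernel(1 / 24, 0)
  f <- featurize(k)
  expect_length(f, 72)
  expect_equal(f[c(24, 48, 72)], c(1, 1, 1))
  expect_true(all(f >= -1 & f <= 1))
  # rapid decay: sub-hour length scale kills every lag
  f2 <- featurize(sm_kernel(0, lengthscale_to_v(0.15)))
  expect_true(all(abs(f2) < 1e-6))
  expect_length(featurize(k, include_lag0 = TRUE), 73)
  f3 <- featurize(random_model(Q = 1, seed = 9)$basis[[1]])
  expect_length(f3, 72)
})

test_that("clustering separates planted kernel families exactly", {
  # two families: 2 h vs 120 h length scales, 50 kernels each, small jitter
  kernels <- withr::with_seed(5, {
    c(lapply(1:50, function(i) sm_kernel(0, lengthscale_to_v(2 * runif(1, 0.9, 1.1)))),
      lapply(1:50, function(i) sm_kernel(0, lengthscale_to_v(120 * runif(1, 0.9, 1.1)))))
  })
  feats <- do.call(rbind, lapply(kernels, featurize))
  cl <- cluster_kernels(feats, Q_max = 5, seed = 3)
  expect_identical(cl$Q_prime, 2L)
  truth_lab <- rep(1:2, each = 50)
  # adjusted Rand index = 1 <=> the 2-way partition matches exactly
  tab <- table(cl$assignments, truth_lab)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  # determinism under the seed
  cl2 <- cluster_kernels(feats, Q_max = 5, seed = 3)
  expect_identical(cl$assignments, cl2$assignments)
})

test_that("identical features collapse to a single cluster", {
  feats <- matrix(rep(featurize(sm_kernel(0, lengthscale_to_v(24))), 8),
                  nrow = 8, byrow = TRUE)
  cl <- cluster_kernels(feats, Q_max = 4, seed = 1)
  expect_identical(cl$Q_prime, 1L)
})

test_that("mclust agrees with the package GMM on a low-dimensional case", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  X <- withr::with_seed(11, rbind(
    matrix(rnorm(60, mean = 0, sd = 0.3), ncol = 2),
    matrix(rnorm(60, mean = 5, sd = 0.3), ncol = 2)
  ))
  cl <- cluster_kernels(X, Q_max = 4, seed = 2)
  mc <- mclust::Mclust(X, G = 1:4, verbose = FALSE)
  expect_identical(cl$Q_prime, 2L)
  expect_equal(mc$G, 2)
  tab <- table(cl$assignments, mc$classification)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("kde_weighted_mean is robust to a planted outlier", {
  xs <- c(rep(1, 10) + withr::with_seed(2, rnorm(10, 0, 0.01)), 10)
  agg <- kde_weighted_mean(xs)
  expect_lt(abs(agg - 1), abs(mean(xs) - 1))
  expect_equal(kde_weighted_mean(5), 5)
  expect_equal(kde_weighted_mean(rep(2, 4)), 2)
})

test_that("aggregate_cluster reproduces identical members and refactors PSD", {
  k <- sm_kernel(1 / 30, lengthscale_to_v(40))
  w <- coreg_weights(matrix(c(1, 0.8, 0.2, -0.1), 2, 2), c(0.1, 0.2))
  members <- lapply(1:5, function(i) list(kernel = k, weights = w,
                                          patient_id = paste0("p", i)))
  agg <- aggregate_cluster(members, D = 2, R = 2)
  expect_equal(agg$kernel$mu, k$mu, tolerance = 1e-12)
  expect_equal(agg$kernel$v, k$v, tolerance = 1e-12)
  expect_equal(build_B(agg$weights), build_B(w), tolerance = 1e-8)
  # random PSD members: aggregated reconstruction stays PSD; and when the
  # members share a column space (rank(B_agg) <= R) it is near-exact
  for (seed in 1:3) {
    A0 <- withr::with_seed(seed + 30, matrix(rnorm(6), 3, 2))
    ms <- withr::with_seed(seed, lapply(1:8, function(i) {
      list(kernel = sm_kernel(runif(1, 0.01, 0.05),
                              lengthscale_to_v(runif(1, 20, 40))),
           weights = coreg_weights(A0 %*% diag(runif(2, 0.5, 1.5)),
                                   rep(0, 3)),
           patient_id = paste0("p", i))
    }))
    agg <- aggregate_cluster(ms, D = 3, R = 2)
    B <- build_B(agg$weights)
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) >= -1e-10)
    B_direct <- matrix(0, 3, 3)
    Bs <- lapply(ms, function(m) build_B(m$weights))
    for (i in 1:3) for (j in 1:3) {
      B_direct[i, j] <- kde_weighted_mean(vapply(Bs, function(b) b[i, j],
                                                 numeric(1)))
    }
    expect_lt(norm(B - (B_direct + t(B_direct)) / 2, "F") /
                norm(B_direct, "F"), 0.05)
  }
})

test_that("multiple kernels from one patient are summed before aggregation", {
  k <- sm_kernel(0, lengthscale_to_v(30))
  w1 <- coreg_weights(matrix(c(1, 0), 2, 1), c(0, 0))
  w2 <- coreg_weights(matrix(c(0, 1), 2, 1), c(0, 0))
  # patient A contributes both kernels; patient B contributes their sum
  wB <- coreg_weights(matrix(0, 2, 1), c(1, 1))
  members <- list(
    list(kernel = k, weights = w1, patient_id = "A"),
    list(kernel = k, weights = w2, patient_id = "A"),
    list(kernel = k, weights = wB, patient_id = "B")
  )
  agg <- aggregate_cluster(members, D = 2, R = 1)
  # both patients' summed B equal diag(1, 1), so the aggregate must too
  expect_equal(build_B(agg$weights), diag(2), tolerance = 1e-8)
})

test_that("build_population_prior recovers a shared truth and coverage", {
  truth <- default_truth("two_correlated")
  # many patients, each carrying the same two kernels: idempotence up to
  # cluster ordering
  fits <- lapply(1:6, function(i) {
    m <- truth
    m$center <- c(0, 0); m$scale <- c(1, 1)
    structure(list(model = m, patient_id = paste0("p", i)),
              class = "medgp_fit")
  })
  prior <- build_population_prior(fits, seed = 4)
  expect_s3_class(prior, "medgp_prior")
  expect_identical(prior$Q_prime, 2L)
  expect_equal(prior$coverage, c(1, 1))
  periods <- vapply(prior$basis, function(k) ifelse(k$mu > 0, 1 / k$mu, Inf),
                    numeric(1))
  expect_true(any(abs(periods - 24) < 1))
  Bs_truth <- lapply(truth$weights, build_B)
  Bs_prior <- lapply(prior$weights, build_B)
  err <- vapply(Bs_prior, function(B) {
    min(vapply(Bs_truth, function(Bt) norm(B - Bt, "F"), numeric(1)))
  }, numeric(1))
  expect_true(all(err < 1e-6))
  # clusters ordered by descending length scale
  vs <- vapply(prior$basis, `[[`, numeric(1), "v")
  expect_true(all(diff(vs) >= 0))
})

test_that("near-zero kernels are excluded and can empty the pool", {
  dead <- medgp_model(
    list(sm_kernel(0, lengthscale_to_v(20))),
    list(coreg_weights(matrix(1e-4, 2, 1), c(0, 0))),
    noise_var = c(0.1, 0.1), covariate_names = c("a", "b")
  )
  expect_error(build_population_prior(list(dead, dead), seed = 1),
               regexp = "near-zero")
  live <- medgp_model(
    list(sm_kernel(0, lengthscale_to_v(20))),
    list(coreg_weights(matrix(0.5, 2, 1), c(0.1, 0.1))),
    noise_var = c(0.1, 0.1), covariate_names = c("a", "b")
  )
  pr <- build_population_prior(list(live, dead), seed = 1)
  expect_identical(pr$Q_prime, 1L)
  expect_equal(pr$coverage, 0.5)
})

test_that("end-to-end population recovery from fitted synthetic patients", {
  truth <- default_truth("two_correlated")
  sim <- simulate_cohort(sim_config(8, truth, stay_range_h = c(200, 260),
                                    gaps = c(pt = 4, inr = 4), seed = 77))
  pats <- cohort_split(sim$cohort)
  fits <- lapply(seq_along(pats), function(i) {
    cfg <- fit_config(Q = 2, R = 2, n_init = 100, max_iters = 12,
                      scg_maxit = 50, seed = 30 + i)
    fit_patient(pats[[i]], cfg)
  })
  prior <- build_population_prior(fits, seed = 5)
  expect_identical(prior$Q_prime, 2L)
  periods <- vapply(prior$basis, function(k) ifelse(k$mu > 0, 1 / k$mu, Inf),
                    numeric(1))
  # the circadian cluster lands within 10% of the generating 24 h period
  expect_lt(min(abs(periods - 24) / 24), 0.10)
})

test_that("kde_grid_argmax picks the density peak on a log grid", {
  xs <- c(rep(2, 15) * withr::with_seed(8, runif(15, 0.95, 1.05)), 40, 50)
  pick <- kde_grid_argmax(xs)
  expect_lt(abs(pick - 2), 0.5)
  expect_equal(kde_grid_argmax(7), 7)
})
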