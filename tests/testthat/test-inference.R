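test_that("log_marginal matches the 1x1 closed form", {
  c_w <- 1.3; s2 <- 0.4; yv <- 0.7
  m <- medgp_model(list(sm_kernel(0, 1e-4)),
                   list(coreg_weights(matrix(sqrt(c_w), 1, 1), 0)),
                   noise_var = s2, covariate_names = "a")
  p <- flat_to_patient(list(x = 10, y = yv, d = 1L), "a")
  expect_equal(log_marginal(m, p),
               -0.5 * yv^2 / (c_w + s2) - 0.5 * log(c_w + s2) -
                 0.5 * log(2 * pi),
               tolerance = 1e-12)
})

test_that("log_marginal matches a dense MVN oracle on random instances", {
  for (seed in 1:10) {
    D <- sample(1:3, 1)
    m <- random_model(Q = 2, D = D, R = 2, seed = seed)
    fl <- random_flat(Tn = sample(5:60, 1), D = D, seed = seed + 100)
    p <- flat_to_patient(fl, m$covariate_names)
    K <- gram(m, fl$x, fl$d)
    diag(K) <- diag(K) + m$noise_var[fl$d]
    # flatten_vectors sorts by covariate; rebuild oracle on sorted order
    ord <- order(fl$d, fl$x)
    K_s <- gram(m, fl$x[ord], fl$d[ord])
    diag(K_s) <- diag(K_s) + m$noise_var[fl$d[ord]]
    expect_equal(log_marginal(m, p), dense_mvn_logpdf(fl$y[ord], K_s),
                 tolerance = 1e-8)
  }
})

test_that("with y = 0 the marginal decreases as noise variance grows", {
  m <- random_model(Q = 1, D = 2, R = 1, seed = 3)
  fl <- random_flat(Tn = 15, D = 2, seed = 4)
  fl$y <- rep(0, 15)
  p <- flat_to_patient(fl, m$covariate_names)
  ll1 <- log_marginal(m, p)
  m10 <- m; m10$noise_var <- m$noise_var * 10
  expect_lt(log_marginal(m10, p), ll1)
})

test_that("analytic gradients match finite differences for every class", {
  pcfg <- prior_config()
  for (seed in 1:4) {
    m <- random_model(Q = 2, D = 2, R = 2, seed = seed)
    fl <- random_flat(Tn = 18, D = 2, seed = seed + 40)
    st <- init_prior_state(m)
    skel <- medgp:::pack_model(m)
    obj <- make_objective(fl$x, fl$y, fl$d, skel,
                          prior_state = if (seed %% 2 == 0) st,
                          prior_cfg = if (seed %% 2 == 0) pcfg)
    p0 <- skel$par[skel$free] +
      withr::with_seed(seed, rnorm(sum(skel$free), 0, 0.05))
    g <- obj$gr(p0)
    eps <- 1e-6
    for (i in seq_along(p0)) {
      pp <- p0; pp[i] <- pp[i] + eps
      pm <- p0; pm[i] <- pm[i] - eps
      g_num <- (obj$fn(pp) - obj$fn(pm)) / (2 * eps)
      expect_lt(abs(g[i] - g_num) / max(abs(g_num), 1e-6), 1e-4)
    }
  }
})

test_that("map_objective reduces to the marginal likelihood without prior", {
  m <- random_model(Q = 1, D = 2, R = 1, seed = 8)
  fl <- random_flat(Tn = 10, D = 2, seed = 9)
  p <- flat_to_patient(fl, m$covariate_names)
  cfg_off <- fit_config(Q = 1, R = 1, use_sparse_prior = FALSE)
  st <- init_prior_state(m)
  expect_identical(map_objective(m, st, cfg_off, p), log_marginal(m, p))
  cfg_on <- fit_config(Q = 1, R = 1, use_sparse_prior = TRUE)
  expect_equal(map_objective(m, st, cfg_on, p),
               log_marginal(m, p) +
                 log_prior(m, st, prior_config(eta = cfg_on$eta)))
})

test_that("init_random is deterministic, respects n_init and beats the median", {
  truth <- default_truth("two_correlated")
  sim <- simulate_cohort(sim_config(1, truth, stay_range_h = c(100, 120),
                                    gaps = c(pt = 8, inr = 8), seed = 5))
  p <- cohort_split(sim$cohort)[[1]]
  cfg1 <- fit_config(Q = 2, R = 2, n_init = 1, seed = 42)
  m1a <- init_random(p, cfg1)
  m1b <- init_random(p, cfg1)
  expect_identical(m1a$basis, m1b$basis)
  expect_identical(m1a$weights, m1b$weights)
  cfg <- fit_config(Q = 2, R = 2, n_init = 40, seed = 7)
  best <- init_random(p, cfg)
  # score candidate draws independently to locate the median
  lls <- withr::with_seed(cfg$seed, {
    vapply(1:40, function(i) {
      cand <- medgp:::draw_candidate(cfg, 2)
      m <- medgp_model(cand$basis, cand$weights, rep(cfg$noise_init, 2),
                       attr(p, "covariates"),
                       center = best$center, scale = best$scale)
      log_marginal(m, p)
    }, numeric(1))
  })
  expect_equal(log_marginal(best, p), max(lls), tolerance = 1e-10)
  expect_gte(log_marginal(best, p), median(lls))
})

test_that("fit_patient obeys its loop contract", {
  expect_error(fit_config(max_iters = 0), class = "medgp_validation_error")
  truth <- default_truth("two_correlated")
  sim <- simulate_cohort(sim_config(1, truth, stay_range_h = c(100, 120),
                                    gaps = c(pt = 8, inr = 8), seed = 6))
  p <- cohort_split(sim$cohort)[[1]]
  cfg <- fit_config(Q = 1, R = 1, n_init = 5, max_iters = 1,
                    scg_maxit = 10, seed = 2)
  fit <- fit_patient(p, cfg)
  expect_equal(fit$n_iters, 1L)
  expect_false(fit$converged)
  expect_length(fit$trace, 1)
})

test_that("marginal-likelihood fits have a monotone objective trace", {
  # without the shrinkage prior the outer objective is optimized by SCG
  # alone, whose accepted steps never decrease it
  truth <- default_truth("two_correlated")
  sim <- simulate_cohort(sim_config(1, truth, stay_range_h = c(150, 170),
                                    gaps = c(pt = 6, inr = 6), seed = 13))
  p <- cohort_split(sim$cohort)[[1]]
  cfg <- fit_config(Q = 2, R = 2, n_init = 30, max_iters = 6,
                    scg_maxit = 25, seed = 3, use_sparse_prior = FALSE)
  fit <- fit_patient(p, cfg)
  expect_true(all(diff(fit$trace) >= -1e-6))
  # and with the prior on, the SCG stage itself never lowers the objective
  cfg_sp <- fit_config(Q = 2, R = 2, n_init = 30, max_iters = 4,
                       scg_maxit = 25, seed = 3)
  fit_sp <- fit_patient(p, cfg_sp)
  expect_true(is.finite(tail(fit_sp$trace, 1)))
})

test_that("predict interpolates noiseless training points and transfers", {
  m <- random_model(Q = 1, D = 2, R = 2, seed = 21)
  m$noise_var <- c(1e-10, 1e-10)
  fl <- random_flat(Tn = 10, D = 2, seed = 22)
  p <- flat_to_patient(fl, m$covariate_names)
  pr <- predict(m, p, query = tibble::tibble(time_hours = fl$x[3],
                                             covariate = m$covariate_names[fl$d[3]]))
  expect_equal(pr$pred_mean, fl$y[3], tolerance = 1e-4)

  # empty history returns the prior
  pr0 <- predict(m, NULL, query = tibble::tibble(time_hours = 10,
                                                 covariate = "c1"))
  prior_var <- build_B(m$weights[[1]])[1, 1] + m$noise_var[1]
  expect_equal(pr0$pred_mean, 0)
  expect_equal(pr0$pred_var, prior_var, tolerance = 1e-12)

  # cross-covariate transfer vs brute-force conditional Gaussian
  mt <- medgp_model(list(sm_kernel(0, lengthscale_to_v(30))),
                    list(coreg_weights(matrix(c(1, 0.95), 2, 1),
                                       c(1e-6, 1e-6))),
                    noise_var = c(0.05, 0.05),
                    covariate_names = c("a", "b"))
  hist_x <- c(2, 7, 12, 20); hist_y <- c(0.3, -0.1, 0.4, 0.2)
  hist <- flat_to_patient(list(x = hist_x, y = hist_y, d = rep(2L, 4)),
                          c("a", "b"))
  q_x <- 9
  pr <- predict(mt, hist, query = tibble::tibble(time_hours = q_x,
                                                 covariate = "a"))
  Khh <- gram(mt, hist_x, rep(2L, 4)) + diag(0.05, 4)
  Kqh <- gram(mt, q_x, 1L, hist_x, rep(2L, 4))
  mu_or <- Kqh %*% solve(Khh, hist_y)
  var_or <- gram(mt, q_x, 1L) + 0.05 - Kqh %*% solve(Khh, t(Kqh))
  expect_equal(pr$pred_mean, as.numeric(mu_or), tolerance = 1e-8)
  expect_equal(pr$pred_var, as.numeric(var_or), tolerance = 1e-8)
})

test_that("predictive variances are positive and bounded by the prior", {
  for (seed in 1:3) {
    m <- random_model(Q = 2, D = 2, R = 2, seed = seed + 60)
    fl <- random_flat(Tn = 25, D = 2, seed = seed + 70)
    p <- flat_to_patient(fl, m$covariate_names)
    qs <- tibble::tibble(time_hours = runif(10, 0, 110),
                         covariate = sample(m$covariate_names, 10, TRUE))
    pr <- predict(m, p, qs)
    expect_true(all(pr$pred_var > 0))
    d_q <- match(pr$covariate, m$covariate_names)
    prior_var <- vapply(d_q, function(d) {
      sum(vapply(m$weights, function(w) build_B(w)[d, d], numeric(1))) +
        m$noise_var[d]
    }, numeric(1))
    expect_true(all(pr$pred_var <= prior_var + 1e-8))
  }
})

test_that("standardization is applied in fitting and inverted in prediction", {
  truth <- default_truth("two_correlated")
  sim <- simulate_cohort(sim_config(1, truth, stay_range_h = c(120, 140),
                                    gaps = c(pt = 8, inr = 8), seed = 31))
  p <- cohort_split(sim$cohort)[[1]]
  # shift/scale the data far from zero: predictions must live on that scale
  p2 <- p
  p2$value <- p$value * 30 + 500
  cfg <- fit_config(Q = 1, R = 1, n_init = 20, max_iters = 3,
                    scg_maxit = 20, seed = 4)
  fit <- fit_patient(as_cohort(p2, covariates = attr(p, "covariates")), cfg)
  pr <- predict(fit$model, NULL,
                query = tibble::tibble(time_hours = 10, covariate = "pt"))
  expect_gt(pr$pred_mean, 400)   # prior mean maps back to the data centre
})

test_that("Cholesky jitter escalation reports attempted jitters", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2)  # indefinite
  expect_error(medgp:::chol_jitter(bad), class = "medgp_numerical_error",
               regexp = "jitter")
})
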