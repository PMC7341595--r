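mk_trace <- function(obs, pred, cov = "a", var = NULL, t = seq_along(obs),
                     pid = NULL) {
  tr <- tibble::tibble(
    time_hours = t, covariate = cov, observed = obs, pred_mean = pred,
    pred_var = if (is.null(var)) NA_real_ else var,
    in_95ci = NA
  )
  if (!is.null(pid)) tr$patient_id <- pid
  tr
}

test_that("mae and coverage95 match hand arithmetic", {
  tr <- mk_trace(c(1, 3), c(2, 2))
  expect_equal(mae(tr), 1.0)
  expect_equal(mae(mk_trace(c(5, 5), c(5, 5))), 0)
  tr4 <- mk_trace(c(0, 0, 0, 10), c(0, 0, 0, 0), var = rep(1, 4))
  expect_equal(coverage95(tr4), 75)
  expect_equal(coverage95(mk_trace(c(0), c(0), var = 1)), 100)
  expect_true(is.na(mae(tr, covariate = "zz")))
  expect_true(is.na(coverage95(mk_trace(c(1), c(1)))))  # no variance
  # random recomputation oracle
  obs <- withr::with_seed(1, rnorm(50)); pr <- withr::with_seed(2, rnorm(50))
  expect_equal(mae(mk_trace(obs, pr)), mean(abs(obs - pr)))
})

test_that("naive one-lag predicts the previous value and skips the first", {
  p <- as_cohort(tibble::tibble(
    patient_id = "p1", covariate = "a",
    time_hours = c(1, 2, 3), value = c(1, 2, 4)
  ))
  tr <- naive_one_lag(p)
  expect_equal(tr$pred_mean, c(1, 2))
  expect_equal(tr$observed, c(2, 4))
  expect_equal(mae(tr), 1.5)
  expect_true(all(is.na(tr$pred_var)))
  # constant series is predicted perfectly
  pc <- as_cohort(tibble::tibble(patient_id = "p", covariate = "a",
                                 time_hours = 1:5, value = rep(7, 5)))
  expect_equal(mae(naive_one_lag(pc)), 0)
  # < 2 observations: empty trace
  p1 <- as_cohort(tibble::tibble(patient_id = "p", covariate = "a",
                                 time_hours = 1, value = 3))
  expect_equal(nrow(naive_one_lag(p1)), 0)
  # shift-by-one oracle on a random series
  vals <- withr::with_seed(9, rnorm(20))
  pr <- as_cohort(tibble::tibble(patient_id = "p", covariate = "a",
                                 time_hours = 1:20, value = vals))
  expect_equal(naive_one_lag(pr)$pred_mean, vals[-20])
})

test_that("compare computes improvement, pairing and Bonferroni flags", {
  obs <- withr::with_seed(4, rnorm(100))
  base_err <- withr::with_seed(5, abs(rnorm(100, 0, 0.5)) + 0.2)
  tr_base <- mk_trace(obs, obs + base_err)
  tr_meth <- mk_trace(obs, obs + base_err / 2)  # planted uniform 50% cut
  rep <- compare(tr_meth, tr_base, alpha = 0.05)
  expect_equal(rep$improvement_pct, 50, tolerance = 1e-10)
  expect_lt(rep$p_value, 0.05)
  expect_true(rep$significant)
  # identical traces: zero improvement, non-significant
  rep0 <- compare(tr_base, tr_base)
  expect_equal(rep0$improvement_pct, 0)
  expect_false(rep0$significant)
  # threshold arithmetic: 4.17e-4 at 24 covariates, 0.005 at 2
  expect_equal(signif(bonferroni_threshold(0.01, 24), 3), 4.17e-4)
  expect_equal(bonferroni_threshold(0.01, 2), 0.005)
  # mismatched observed values raise an alignment error
  tr_bad <- tr_base; tr_bad$observed <- tr_bad$observed + 1
  expect_error(compare(tr_meth, tr_bad), class = "medgp_alignment_error")
  expect_error(compare(tr_meth, mk_trace(1:3, 1:3, cov = "zz")),
               class = "medgp_alignment_error")
})

test_that("compare aligns events by patient, covariate and time", {
  obs <- c(1, 2, 3, 4)
  a <- mk_trace(obs, obs + 1, pid = c("p1", "p1", "p2", "p2"))
  # same events, shuffled rows
  b <- mk_trace(obs, obs + 0.5, pid = c("p1", "p1", "p2", "p2"))[c(3, 1, 4, 2), ]
  rep <- compare(a, b)
  expect_equal(rep$n_events, 4L)
  expect_equal(rep$mae_method, 1)
  expect_equal(rep$mae_baseline, 0.5)
})

test_that("univariate SE/SM baselines follow the online protocol at D = 1", {
  truth1 <- medgp_model(list(sm_kernel(0, lengthscale_to_v(40))),
                        list(coreg_weights(matrix(0.9, 1, 1), 0.05)),
                        noise_var = 0.05, covariate_names = "x")
  sim <- simulate_cohort(sim_config(1, truth1, stay_range_h = c(160, 180),
                                    gaps = c(x = 4), seed = 21))
  p <- cohort_split(sim$cohort)[[1]]
  cfg <- fit_config(Q = 1, R = 1, n_init = 40, max_iters = 6,
                    scg_maxit = 30, seed = 3)
  tr_se <- univariate_gp_baseline(p, "x", "SE", cfg)
  expect_equal(nrow(tr_se), nrow(p))
  # SE means the frequency stayed at zero
  m_se <- attr(tr_se, "model")
  expect_identical(m_se$basis[[1]]$mu, 0)
  # deterministic under the seed
  tr_se2 <- univariate_gp_baseline(p, "x", "SE", cfg)
  expect_equal(tr_se$pred_mean, tr_se2$pred_mean, tolerance = 1e-12)
  # equivalence at D = 1: full model on the same single covariate
  fit <- fit_patient(as_cohort(p, covariates = "x"), cfg)
  tr_full <- run_online(p, fit$model, online_config(update = FALSE))
  sm_cfg <- cfg
  tr_sm <- univariate_gp_baseline(p, "x", "SM", sm_cfg)
  expect_lt(abs(mae(tr_sm) - mae(tr_full)) / mae(tr_full), 0.05)
})

test_that("SE underperforms SM on strongly periodic series", {
  truth_per <- medgp_model(list(sm_kernel(1 / 24, lengthscale_to_v(72))),
                           list(coreg_weights(matrix(0.95, 1, 1), 0.02)),
                           noise_var = 0.02, covariate_names = "x")
  wins <- 0
  for (s in 1:4) {
    sim <- simulate_cohort(sim_config(1, truth_per,
                                      stay_range_h = c(150, 170),
                                      gaps = c(x = 5), seed = 300 + s))
    p <- cohort_split(sim$cohort)[[1]]
    cfg <- fit_config(Q = 1, R = 1, n_init = 40, max_iters = 5,
                      scg_maxit = 30, seed = s)
    m_se <- mae(univariate_gp_baseline(p, "x", "SE", cfg))
    m_sm <- mae(univariate_gp_baseline(p, "x", "SM", cfg))
    if (m_sm < m_se) wins <- wins + 1
  }
  expect_gte(wins, 3)
})

test_that("crossvalidate partitions patients deterministically", {
  truth <- default_truth("two_correlated")
  sim <- simulate_cohort(sim_config(6, truth, stay_range_h = c(90, 110),
                                    gaps = c(pt = 8, inr = 8), seed = 41))
  cfg <- fit_config(Q = 1, R = 1, n_init = 10, max_iters = 2,
                    scg_maxit = 15, seed = 2)
  cv <- crossvalidate(sim$cohort, cfg, online_config(update = FALSE),
                      k = 3, seed = 11)
  expect_equal(sort(table(cv$folds$fold)), sort(table(rep(1:3, 2))),
               ignore_attr = TRUE)
  expect_setequal(cv$folds$patient_id, unique(sim$cohort$patient_id))
  cv2 <- crossvalidate(sim$cohort, cfg, online_config(update = FALSE),
                       k = 3, seed = 11)
  expect_identical(cv$folds, cv2$folds)
  expect_s3_class(cv$report$naive, "medgp_eval")
  # every patient is predicted exactly once
  expect_setequal(unique(cv$traces$medgp$patient_id), cv$folds$patient_id)
  expect_error(crossvalidate(sim$cohort, cfg, k = 7, seed = 1),
               class = "medgp_validation_error")
})

test_that("the best-of-SE/SM baseline picks the lower-MAE kernel per covariate", {
  se <- dplyr::bind_rows(mk_trace(c(1, 2), c(1, 2), cov = "a"),
                         mk_trace(c(1, 2), c(3, 4), cov = "b"))
  sm <- dplyr::bind_rows(mk_trace(c(1, 2), c(2, 3), cov = "a"),
                         mk_trace(c(1, 2), c(1, 2), cov = "b"))
  best <- select_best_baseline(se, sm)
  expect_equal(attr(best, "chosen"), c(a = "SE", b = "SM"))
  expect_equal(mae(best, "a"), 0)
  expect_equal(mae(best, "b"), 0)
})
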