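# Evaluation harness: MAE, 95% coverage, naive and univariate GP baselines,
# paired significance testing with Bonferroni correction, patient-level
# cross-validation.

#' Mean absolute error of a prediction trace
#'
#' @param trace A trace tibble with columns `covariate`, `observed`,
#'   `pred_mean` (e.g. from [run_online()]).
#' @param covariate Optional covariate name; default pools all records.
#' @return Scalar MAE, or `NA` if no records.
#' @export
mae <- function(trace, covariate = NULL) {
  if (!is.null(covariate)) trace <- trace[trace$covariate == covariate, ]
  if (nrow(trace) == 0) return(NA_real_)
  mean(abs(trace$observed - trace$pred_mean))
}

#' Empirical 95% coverage of a prediction trace, in percent
#'
#' The percentage of observations within `pred_mean +/- 1.96 sqrt(pred_var)`.
#'
#' @inheritParams mae
#' @return Coverage in \[0, 100\], or `NA` if no records or no predictive
#'   variance (e.g. the naive baseline).
#' @export
coverage95 <- function(trace, covariate = NULL) {
  if (!is.null(covariate)) trace <- trace[trace$covariate == covariate, ]
  if (nrow(trace) == 0 || all(is.na(trace$pred_var))) return(NA_real_)
  inside <- abs(trace$observed - trace$pred_mean) <=
    1.96 * sqrt(trace$pred_var)
  100 * mean(inside, na.rm = TRUE)
}

#' Per-covariate metrics of a trace
#'
#' @param trace A trace tibble.
#' @return Tibble with `covariate`, `n`, `mae`, `coverage95`.
#' @export
trace_metrics <- function(trace) {
  trace |>
    dplyr::group_by(.data$covariate) |>
    dplyr::summarise(
      n = dplyr::n(),
      mae = mean(abs(.data$observed - .data$pred_mean)),
      coverage95 = if (all(is.na(.data$pred_var))) NA_real_ else
        100 * mean(abs(.data$observed - .data$pred_mean) <=
                     1.96 * sqrt(.data$pred_var)),
      .groups = "drop"
    )
}

#' Naive one-lag baseline
#'
#' Predicts each observation by the previous observed value of the same
#' covariate; the first observation of each covariate is skipped. The
#' baseline has no predictive distribution, so `pred_var` is `NA` and
#' coverage is not applicable.
#'
#' @param patient A single-patient `medgp_cohort`.
#' @param covariate Optional covariate name(s); default all.
#' @return A trace tibble (`time_hours, covariate, observed, pred_mean,
#'   pred_var, in_95ci`).
#' @export
naive_one_lag <- function(patient, covariate = NULL) {
  covs <- attr(patient, "covariates")
  if (is.null(covariate)) covariate <- covs
  out <- lapply(covariate, function(cv) {
    rows <- patient[patient$covariate == cv, ]
    rows <- rows[order(rows$time_hours), ]
    if (nrow(rows) < 2) return(NULL)
    tibble::tibble(
      time_hours = rows$time_hours[-1],
      covariate = cv,
      observed = rows$value[-1],
      pred_mean = rows$value[-nrow(rows)],
      pred_var = NA_real_,
      in_95ci = NA
    )
  })
  tr <- dplyr::bind_rows(out)
  class(tr) <- c("medgp_trace", class(tibble::tibble()))
  tr
}

#' Independent univariate GP baseline
#'
#' Runs the same online protocol as [run_online()] on a single covariate in
#' isolation (D = 1, no cross-covariate conditioning). The SE variant is the
#' spectral mixture kernel with the frequency fixed at zero; the SM variant
#' uses Q = 1.
#'
#' @param patient A single-patient `medgp_cohort`.
#' @param covariate The covariate to model.
#' @param kernel_type `"SE"` or `"SM"`.
#' @param cfg A [fit_config()]; Q and R are forced to 1.
#' @param prior Optional univariate `medgp_model` to use as the online prior
#'   (e.g. aggregated from training patients); when `NULL` the model is
#'   fitted on the patient's own series first.
#' @param online_cfg An [online_config()]; defaults to no updating.
#' @return A trace tibble for that covariate.
#' @export
univariate_gp_baseline <- function(patient, covariate,
                                   kernel_type = c("SM", "SE"),
                                   cfg = fit_config(Q = 1, R = 1),
                                   prior = NULL,
                                   online_cfg = online_config(update = FALSE)) {
  kernel_type <- match.arg(kernel_type)
  sub <- as_cohort(patient[patient$covariate == covariate, ],
                   covariates = covariate)
  cfg$Q <- 1L; cfg$R <- 1L
  cfg$fix_mu_zero <- kernel_type == "SE"
  if (is.null(prior)) {
    fit <- fit_patient(sub, cfg)
    prior <- fit$model
  }
  run_online(sub, prior, online_cfg)
}

# build an alignment key per prediction event; duplicates within a key are
# disambiguated by arrival order
event_keys <- function(tr) {
  pid <- if ("patient_id" %in% names(tr)) tr$patient_id else "p"
  key <- paste(pid, tr$covariate, sprintf("%.9g", tr$time_hours),
               sep = "|")
  occ <- stats::ave(seq_along(key), key, FUN = seq_along)
  paste(key, occ, sep = "#")
}

#' Compare a method's trace against a baseline
#'
#' Aligns prediction events by (patient, covariate, time), computes
#' per-covariate MAE for both methods, the percent MAE improvement
#' `100 (MAE_base - MAE_method) / MAE_base` (positive = method better), a
#' two-sided paired t-test on per-event absolute errors, and a significance
#' flag at the Bonferroni-corrected threshold `alpha / n_covariates`.
#'
#' @param method_trace,baseline_trace Trace tibbles covering the same
#'   held-out observations (an optional `patient_id` column is honoured).
#'   Events present in only one trace are dropped from the comparison;
#'   matched events whose observed values disagree raise an alignment error.
#' @param alpha Family-wise error rate before correction (default 0.01,
#'   giving the 4.17e-4 threshold at 24 covariates and 0.005 at 2).
#' @param n_covariates Number of jointly modelled covariates used in the
#'   Bonferroni divisor; defaults to the number of covariates present.
#' @return A tibble of class `medgp_eval` with one row per covariate.
#' @export
compare <- function(method_trace, baseline_trace, alpha = 0.01,
                    n_covariates = NULL) {
  m <- tibble::as_tibble(method_trace)
  b <- tibble::as_tibble(baseline_trace)
  m$.key <- event_keys(m)
  b$.key <- event_keys(b)
  common <- intersect(m$.key, b$.key)
  if (length(common) == 0) {
    abort("no common prediction events between method and baseline",
          class = "medgp_alignment_error")
  }
  m <- m[match(common, m$.key), ]
  b <- b[match(common, b$.key), ]
  bad <- which(abs(m$observed - b$observed) > 1e-9)
  if (length(bad) > 0) {
    abort(paste0("observed values disagree for matched events: ",
                 paste(head(m$.key[bad], 5), collapse = "; ")),
          class = "medgp_alignment_error")
  }
  if (is.null(n_covariates)) n_covariates <- length(unique(m$covariate))
  threshold <- alpha / n_covariates
  err_m <- abs(m$observed - m$pred_mean)
  err_b <- abs(b$observed - b$pred_mean)
  out <- lapply(unique(m$covariate), function(cv) {
    i <- m$covariate == cv
    mae_m <- mean(err_m[i]); mae_b <- mean(err_b[i])
    p <- tryCatch(t.test(err_m[i], err_b[i], paired = TRUE)$p.value,
                  error = function(e) NA_real_)
    tibble::tibble(
      covariate = cv, n_events = sum(i),
      mae_method = mae_m, mae_baseline = mae_b,
      improvement_pct = 100 * (mae_b - mae_m) / mae_b,
      coverage_method = coverage95(m[i, ]),
      coverage_baseline = coverage95(b[i, ]),
      p_value = p,
      significant = !is.na(p) & p < threshold
    )
  })
  res <- dplyr::bind_rows(out)
  attr(res, "alpha") <- alpha
  attr(res, "threshold") <- threshold
  class(res) <- c("medgp_eval", class(tibble::tibble()))
  res
}

#' Patient-level k-fold cross-validation of the full pipeline
#'
#' Partitions patients into `k` folds by a seeded shuffle. Each patient is
#' fitted once ([fit_patient()] with a per-patient derived seed); for each
#' fold a population prior is built from the training patients' fits and the
#' held-out patients are predicted online. Reports per-covariate comparisons
#' against the requested baselines.
#'
#' @param cohort A `medgp_cohort` with at least `k` patients.
#' @param fit_cfg A [fit_config()].
#' @param online_cfg An [online_config()].
#' @param k Number of folds.
#' @param seed Integer seed for fold assignment and clustering.
#' @param baselines Character subset of `c("naive", "unigp")`.
#' @param Q_max Passed to [build_population_prior()].
#' @return A list of class `medgp_cv`: `report` (named list of `medgp_eval`
#'   per baseline), `traces` (named list of bound trace tibbles per method),
#'   `folds` (tibble patient_id/fold), `fits`.
#' @export
crossvalidate <- function(cohort, fit_cfg, online_cfg = online_config(),
                          k = 10, seed = 1, baselines = "naive",
                          Q_max = NULL) {
  patients <- cohort_split(cohort)
  n <- length(patients)
  if (k > n) abort("k exceeds the number of patients",
                   class = "medgp_validation_error")
  folds <- with_local_seed(seed, {
    sample(rep_len(seq_len(k), n))
  })
  fold_tbl <- tibble::tibble(patient_id = names(patients), fold = folds)
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- fit_cfg
    cfg_i$seed <- fit_cfg$seed + i
    fits[[i]] <- fit_patient(patients[[i]], cfg_i)
  }
  names(fits) <- names(patients)
  medgp_traces <- list(); naive_traces <- list(); unigp_traces <- list()
  for (f in seq_len(k)) {
    train <- which(folds != f); test <- which(folds == f)
    prior <- build_population_prior(fits[train], Q_max = Q_max, seed = seed)
    for (i in test) {
      tr <- run_online(patients[[i]], prior, online_cfg)
      tr$patient_id <- names(patients)[i]
      medgp_traces[[length(medgp_traces) + 1]] <- tr
      if ("naive" %in% baselines) {
        nb <- naive_one_lag(patients[[i]])
        if (nrow(nb) > 0) {
          nb$patient_id <- names(patients)[i]
          naive_traces[[length(naive_traces) + 1]] <- nb
        }
      }
      if ("unigp" %in% baselines) {
        covs <- attr(cohort, "covariates")
        for (cv in covs) {
          ucfg <- fit_cfg
          ucfg$seed <- fit_cfg$seed + i
          ut <- tryCatch(
            univariate_gp_baseline(patients[[i]], cv, "SM", ucfg),
            error = function(e) NULL)
          if (!is.null(ut) && nrow(ut) > 0) {
            ut$patient_id <- names(patients)[i]
            unigp_traces[[length(unigp_traces) + 1]] <- ut
          }
        }
      }
    }
  }
  traces <- list(medgp = dplyr::bind_rows(medgp_traces))
  report <- list()
  if ("naive" %in% baselines) {
    traces$naive <- dplyr::bind_rows(naive_traces)
    report$naive <- compare(traces$medgp, traces$naive)
  }
  if ("unigp" %in% baselines) {
    traces$unigp <- dplyr::bind_rows(unigp_traces)
    report$unigp <- compare(traces$medgp, traces$unigp)
  }
  structure(list(report = report, traces = traces, folds = fold_tbl,
                 fits = fits), class = "medgp_cv")
}

#' Combine SE and SM univariate baselines by per-covariate best MAE
#'
#' The "independent GP (best)" reference: for each covariate, keep the
#' trace of whichever univariate kernel (squared exponential or spectral
#' mixture) achieved the lower MAE.
#'
#' @param trace_se,trace_sm Trace tibbles from [univariate_gp_baseline()]
#'   covering the same covariates.
#' @return A combined trace tibble with attribute `"chosen"` naming the
#'   kernel per covariate.
#' @export
select_best_baseline <- function(trace_se, trace_sm) {
  covs <- union(unique(trace_se$covariate), unique(trace_sm$covariate))
  parts <- list(); chosen <- character(0)
  for (cv in covs) {
    m_se <- mae(trace_se, cv); m_sm <- mae(trace_sm, cv)
    use_sm <- is.na(m_se) || (!is.na(m_sm) && m_sm <= m_se)
    src <- if (use_sm) trace_sm else trace_se
    parts[[cv]] <- src[src$covariate == cv, ]
    chosen[cv] <- if (use_sm) "SM" else "SE"
  }
  out <- dplyr::bind_rows(parts)
  attr(out, "chosen") <- chosen
  class(out) <- c("medgp_trace", class(tibble::tibble()))
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise rate (default 0.01).
#' @param n_covariates Number of jointly modelled covariates.
#' @return `alpha / n_covariates` (e.g. 0.01/24 = 4.17e-4; 0.01/2 = 0.005).
#' @export
bonferroni_threshold <- function(alpha = 0.01, n_covariates) {
  alpha / n_covariates
}
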