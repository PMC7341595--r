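# Population-level empirical prior: featurize fitted basis kernels, cluster
# with a BIC-selected Gaussian mixture, aggregate hyperparameters per cluster
# by KDE-density-weighted means, refactor aggregated B matrices via SVD.

#' Temporal features of a basis kernel
#'
#' Evaluates the kernel at hourly lags within a 72-hour window (lags 1..72 by
#' default; lag 0 is identically 1 and carries no information, but can be
#' included).
#'
#' @param kernel An [sm_kernel()].
#' @param include_lag0 Include lag 0 (giving a 73-vector)?
#' @return Numeric feature vector with entries in \[-1, 1\].
#' @export
featurize <- function(kernel, include_lag0 = FALSE) {
  lags <- if (include_lag0) 0:72 else 1:72
  sm_eval(lags, kernel)
}

# EM for a Gaussian mixture in which every component has its own (diagonal)
# covariance matrix, k-means-seeded restarts. Diagonal (rather than
# unconstrained) component covariances keep the BIC parameter count
# proportionate to the feature dimension, which full covariances would swamp
# for cohort-scale numbers of fitted kernels. The per-dimension variance
# floor `reg` (0.01, i.e. 0.1 in kernel-correlation units) sets the
# resolution below which two kernel shapes count as the same cluster;
# within-cluster spread at that scale is absorbed by the KDE aggregation.
gmm_em <- function(X, k, n_restarts = 10, max_iter = 2000, reg = 1e-2,
                   tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  if (k > nrow(unique(X))) return(NULL)
  run_one <- function() {
    if (k == 1) {
      z <- rep(1L, n)
    } else {
      km <- suppressWarnings(kmeans(X, centers = k, nstart = 1,
                                    iter.max = 50))
      z <- km$cluster
    }
    resp <- matrix(0, n, k)
    resp[cbind(seq_len(n), z)] <- 1
    ll_old <- -Inf; ll <- -Inf
    for (iter in seq_len(max_iter)) {
      nk <- pmax(colSums(resp), 1e-10)
      wk <- nk / n
      mus <- crossprod(resp, X) / nk
      comp_ll <- matrix(NA_real_, n, k)
      for (j in seq_len(k)) {
        Xc <- sweep(X, 2, mus[j, ])
        vars <- colSums(Xc^2 * resp[, j]) / nk[j] + reg
        comp_ll[, j] <- -0.5 * colSums(t(Xc^2) / vars) -
          0.5 * sum(log(vars)) - 0.5 * p * log(2 * pi) + log(wk[j])
      }
      mx <- apply(comp_ll, 1, max)
      ll <- sum(mx + log(rowSums(exp(comp_ll - mx))))
      resp <- exp(comp_ll - mx)
      resp <- resp / rowSums(resp)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
      ll_old <- ll
    }
    list(loglik = ll, resp = resp, weights = wk, means = mus)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- run_one()
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  best
}

#' Cluster kernel features with a BIC-selected Gaussian mixture
#'
#' Fits mixtures for k = 1..`Q_max`, each component with its own diagonal
#' covariance matrix (10 k-means-seeded restarts each, up to 2000 EM
#' iterations, variance floor 0.01), selects the k minimizing BIC,
#' and returns hard assignments by maximum responsibility. k values exceeding
#' the number of features are skipped.
#'
#' @param features Matrix with one kernel feature vector per row (see
#'   [featurize()]), or a list of such vectors.
#' @param Q_max Largest cluster count to consider.
#' @param seed Integer seed (restarts are seeded deterministically).
#' @return List with `assignments` (integer vector), `Q_prime`, and `bic`
#'   (tibble of k and BIC).
#' @export
cluster_kernels <- function(features, Q_max, seed = 1) {
  if (is.list(features)) features <- do.call(rbind, features)
  n <- nrow(features); p <- ncol(features)
  if (n < 1) abort("need at least one kernel feature")
  with_local_seed(seed, {
    rows <- list(); fits <- list()
    for (k in seq_len(Q_max)) {
      if (k > n) next
      fit <- gmm_em(features, k)
      if (is.null(fit)) next
      n_par <- (k - 1) + k * p + k * p
      bic <- -2 * fit$loglik + n_par * log(n)
      rows[[length(rows) + 1]] <- tibble::tibble(k = k, bic = bic)
      fits[[as.character(k)]] <- fit
    }
    if (length(fits) == 0) abort("no feasible cluster count",
                                 class = "medgp_numerical_error")
    bic_tbl <- dplyr::bind_rows(rows)
    k_best <- bic_tbl$k[which.min(bic_tbl$bic)]
    fit <- fits[[as.character(k_best)]]
    assignments <- max.col(fit$resp, ties.method = "first")
    list(assignments = as.integer(assignments), Q_prime = as.integer(k_best),
         bic = bic_tbl)
  })
}

#' Density-weighted mean via a Gaussian KDE with Silverman's bandwidth
#'
#' The aggregate of member values `x_i` is `sum(w_i x_i) / sum(w_i)` with
#' `w_i` the kernel density estimate evaluated at `x_i` (bandwidth by
#' Silverman's rule of thumb). Degenerates to the arithmetic mean when all
#' values coincide or only one member exists.
#'
#' @param xs Numeric member values.
#' @return Scalar aggregate.
#' @export
kde_weighted_mean <- function(xs) {
  xs <- as.numeric(xs)
  if (length(xs) == 1) return(xs)
  bw <- tryCatch(bw.nrd0(xs), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) return(mean(xs))
  w <- vapply(xs, function(xi) sum(dnorm(xi - xs, 0, bw)), numeric(1))
  sum(w * xs) / sum(w)
}

# Refactor a symmetric aggregated B into A (top-R scaled eigenvectors of the
# eigenvalue-floored matrix) and a non-negative diagonal residual lambda that
# preserves the diagonal of B.
refactor_B <- function(B, R) {
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  r_use <- min(R, length(vals))
  A <- eg$vectors[, seq_len(r_use), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(r_use)]), r_use)
  if (r_use < R) A <- cbind(A, matrix(0, nrow(B), R - r_use))
  lambda <- pmax(diag(B) - rowSums(A^2), 0)
  coreg_weights(A, lambda)
}

#' Aggregate one cluster of fitted kernels into a population kernel
#'
#' Scalar hyperparameters (`mu`, `v`, each entry of `B`) are aggregated by
#' [kde_weighted_mean()] across members. When a patient contributes several
#' kernels to the cluster their `B` matrices are summed first (the kernel is
#' additive). The aggregated `B` is symmetrized, eigenvalue-floored at zero
#' and refactored into `A` (top-R scaled eigenvectors) plus a non-negative
#' diagonal `lambda` preserving the diagonal.
#'
#' @param members List of members, each a list with `kernel` ([sm_kernel()]),
#'   `weights` ([coreg_weights()]) and `patient_id`.
#' @param D,R Covariate count and factor rank of the output.
#' @return List with `kernel` and `weights`.
#' @export
aggregate_cluster <- function(members, D, R) {
  if (length(members) == 0) abort("empty cluster")
  if (length(members) == 1) {
    return(list(kernel = members[[1]]$kernel, weights = members[[1]]$weights))
  }
  # Kernel-shape parameters use the KDE density argmax rather than the
  # density-weighted mean: kernel shape is strongly non-linear in (mu, v)
  # (period aliasing makes member frequencies multi-lumped), and the mean of
  # two good kernels can be a bad kernel. The argmax picks the dominant
  # lump. Weight-matrix entries, which enter the kernel linearly, keep the
  # density-weighted mean.
  mu_agg <- kde_argmax(vapply(members, function(m) m$kernel$mu, numeric(1)))
  v_agg <- kde_argmax(vapply(members, function(m) m$kernel$v, numeric(1)))
  pids <- vapply(members, function(m) as.character(m$patient_id),
                 character(1))
  B_by_patient <- lapply(unique(pids), function(pid) {
    Bs <- lapply(members[pids == pid], function(m) build_B(m$weights))
    Reduce(`+`, Bs)
  })
  B_agg <- matrix(0, D, D)
  for (i in seq_len(D)) for (j in i:D) {
    val <- kde_weighted_mean(vapply(B_by_patient, function(B) B[i, j],
                                    numeric(1)))
    B_agg[i, j] <- val; B_agg[j, i] <- val
  }
  list(kernel = sm_kernel(max(mu_agg, 0), max(v_agg, 0)),
       weights = refactor_B(B_agg, R))
}

#' Build the population-level empirical prior from per-patient fits
#'
#' Featurizes every fitted basis kernel whose `B` matrix is not all-near-zero
#' (all entries <= 1e-3 dropped), clusters the features
#' ([cluster_kernels()]), aggregates each cluster ([aggregate_cluster()]),
#' averages noise variances and standardization statistics across patients,
#' and computes per-cluster patient coverage (fraction of patients with a
#' non-zero `B` in that cluster). Clusters are ordered by descending length
#' scale.
#'
#' @param fits List of `medgp_fit` objects (or bare `medgp_model`s) sharing
#'   the covariate ordering.
#' @param Q_max Largest cluster count for BIC selection; defaults to the
#'   models' Q.
#' @param seed Integer seed for clustering.
#' @param drop_threshold Near-zero threshold for excluding dead kernels.
#' @param include_lag0 Passed to [featurize()].
#' @return A `medgp_prior` (a [medgp_model()] with `coverage` and `Q_prime`).
#' @export
build_population_prior <- function(fits, Q_max = NULL, seed = 1,
                                   drop_threshold = .medgp_near_zero,
                                   include_lag0 = FALSE) {
  models <- lapply(fits, function(f) if (inherits(f, "medgp_fit")) f$model else f)
  if (length(models) < 1) abort("need at least one fitted model")
  covs <- models[[1]]$covariate_names
  D <- length(covs); R <- model_R(models[[1]])
  pids <- vapply(seq_along(models), function(i) {
    f <- fits[[i]]
    if (inherits(f, "medgp_fit") && !is.null(f$patient_id)) f$patient_id
    else paste0("model", i)
  }, character(1))
  members <- list()
  for (i in seq_along(models)) {
    m <- models[[i]]
    for (q in seq_len(model_Q(m))) {
      B <- build_B(m$weights[[q]])
      if (max(abs(B)) <= drop_threshold) next
      members[[length(members) + 1]] <- list(
        kernel = m$basis[[q]], weights = m$weights[[q]],
        patient_id = pids[i])
    }
  }
  if (length(members) == 0) {
    abort(paste0("no kernels left after near-zero filtering; ",
                 "lower drop_threshold or disable filtering"))
  }
  feats <- do.call(rbind, lapply(members, function(m)
    featurize(m$kernel, include_lag0 = include_lag0)))
  Q_all <- max(vapply(models, model_Q, integer(1)))
  if (is.null(Q_max)) Q_max <- Q_all
  cl <- cluster_kernels(feats, Q_max = Q_max, seed = seed)
  agg <- lapply(seq_len(cl$Q_prime), function(k) {
    aggregate_cluster(members[cl$assignments == k], D, R)
  })
  coverage <- vapply(seq_len(cl$Q_prime), function(k) {
    length(unique(vapply(members[cl$assignments == k],
                         function(m) m$patient_id, character(1)))) /
      length(unique(pids))
  }, numeric(1))
  # stable reporting order: descending length scale (ascending v)
  ord <- order(vapply(agg, function(a) a$kernel$v, numeric(1)))
  agg <- agg[ord]; coverage <- coverage[ord]
  noise <- rowMeans(vapply(models, `[[`, numeric(D), "noise_var"))
  centers <- lapply(models, `[[`, "center")
  scales <- lapply(models, `[[`, "scale")
  center <- if (all(!vapply(centers, is.null, logical(1)))) {
    rowMeans(do.call(cbind, centers))
  }
  scale <- if (all(!vapply(scales, is.null, logical(1)))) {
    rowMeans(do.call(cbind, scales))
  }
  prior <- medgp_model(
    basis = lapply(agg, `[[`, "kernel"),
    weights = lapply(agg, `[[`, "weights"),
    noise_var = noise, covariate_names = covs,
    center = center, scale = scale
  )
  prior$coverage <- coverage
  prior$Q_prime <- cl$Q_prime
  class(prior) <- c("medgp_prior", class(prior))
  prior
}

#' @export
print.medgp_prior <- function(x, ...) {
  cat(sprintf("<medgp_prior> Q' = %d population kernels\n", x$Q_prime))
  for (q in seq_len(model_Q(x))) {
    k <- x$basis[[q]]
    per <- if (k$mu > 0) sprintf("%.1f h", 1 / k$mu) else "none (SE)"
    ls <- if (k$v > 0) sprintf("%.1f h", v_to_lengthscale(k$v)) else "Inf"
    cat(sprintf("  cluster %d: period %s, length scale %s, coverage %.2f\n",
                q, per, ls, x$coverage[q]))
  }
  invisible(x)
}

# Linear-grid KDE argmax over arbitrary (possibly zero) member values; used
# for the kernel-shape parameters where lumps of period aliases make the
# weighted mean unrepresentative.
kde_argmax <- function(xs, n_grid = 256) {
  xs <- as.numeric(xs)
  if (length(xs) == 1 || diff(range(xs)) == 0) return(xs[1])
  bw <- tryCatch(bw.nrd0(xs), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) return(mean(xs))
  grid <- seq(min(xs), max(xs), length.out = n_grid)
  dens <- vapply(grid, function(g) sum(dnorm(g - xs, 0, bw)), numeric(1))
  grid[which.max(dens)]
}

#' Grid-based KDE aggregation for univariate GP hyperparameters
#'
#' For univariate (single-covariate) GP baselines, density-weighted means are
#' unstable, so each hyperparameter is aggregated by evaluating its Gaussian
#' KDE on a log-spaced grid (32 points spanning the observed member range)
#' and taking the argmax.
#'
#' @param xs Positive member values of one hyperparameter.
#' @param n_grid Grid resolution.
#' @return The grid point with the highest KDE density.
#' @export
kde_grid_argmax <- function(xs, n_grid = 32) {
  xs <- as.numeric(xs)
  xs <- xs[xs > 0]
  if (length(xs) == 0) abort("no positive values to aggregate")
  if (length(xs) == 1 || diff(range(xs)) == 0) return(xs[1])
  bw <- bw.nrd0(xs)
  if (!is.finite(bw) || bw <= 0) return(mean(xs))
  grid <- exp(seq(log(min(xs)), log(max(xs)), length.out = n_grid))
  dens <- vapply(grid, function(g) sum(dnorm(g - xs, 0, bw)), numeric(1))
  grid[which.max(dens)]
}
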