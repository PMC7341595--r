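# ggplot2 views of models, online traces and evaluation reports.

#' @method autoplot medgp_model
#' @export
autoplot.medgp_model <- function(object, window_h = 72, ...) {
  lags <- seq(0, window_h, by = 0.5)
  df <- purrr::map_dfr(seq_len(model_Q(object)), function(q) {
    tibble::tibble(
      kernel = sprintf("kernel %d", q),
      lag_h = lags,
      value = sm_eval(lags, object$basis[[q]])
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_h, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~kernel) +
    ggplot2::labs(x = "lag (hours)", y = expression(kappa[q](rho)),
                  title = "Basis kernels") +
    ggplot2::theme_minimal()
}

#' @method autoplot medgp_prior
#' @export
autoplot.medgp_prior <- function(object, ...) {
  p <- autoplot.medgp_model(object, ...)
  p + ggplot2::labs(title = sprintf("Population kernels (Q' = %d)",
                                    object$Q_prime))
}

#' Heatmap of a coregionalization weight matrix B_q
#'
#' @param model A [medgp_model()].
#' @param q Basis kernel index.
#' @return A ggplot object.
#' @export
plot_coreg <- function(model, q = 1) {
  B <- build_B(model$weights[[q]])
  covs <- model$covariate_names
  df <- tidyr::expand_grid(row = covs, col = covs)
  df$value <- as.numeric(B[cbind(match(df$row, covs), match(df$col, covs))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("B[%d] cross-covariate weights", q)) +
    ggplot2::theme_minimal()
}

#' @method autoplot medgp_trace
#' @export
autoplot.medgp_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$lo <- df$pred_mean - 1.96 * sqrt(df$pred_var)
  df$hi <- df$pred_mean + 1.96 * sqrt(df$pred_var)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_hours)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred_mean),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.7) +
    ggplot2::facet_wrap(~covariate, scales = "free_y") +
    ggplot2::labs(x = "hours since admission", y = "value",
                  title = "Online predictions (95% band) vs observations") +
    ggplot2::theme_minimal()
}

#' @method autoplot medgp_eval
#' @export
autoplot.medgp_eval <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- ifelse(df$significant, "*", "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$covariate,
                                   y = .data$improvement_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "MAE improvement (%)",
                  title = "Improvement over baseline (* = significant)") +
    ggplot2::theme_minimal()
}
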