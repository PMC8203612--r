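# broom-style accessors and ggplot2 autoplot methods for the fitted objects
# and result types

#' @export
tidy.stage1_model <- function(x, ...) x$log

#' @export
glance.stage1_model <- function(x, ...) {
  tibble::tibble(backbone = x$config$backbone, feature_dim = x$feature_dim,
                 epochs = nrow(x$log), best_epoch = x$best_epoch,
                 tune_roc_auc = x$log$tune_roc_auc[x$best_epoch],
                 tune_pr_auc = x$log$tune_pr_auc[x$best_epoch])
}

#' @export
tidy.stage2_model <- function(x, ...) x$log

#' @export
glance.stage2_model <- function(x, ...) {
  tibble::tibble(trunk_width = x$config$trunk_width,
                 n_blocks = x$config$n_blocks,
                 epochs = nrow(x$log), best_epoch = x$best_epoch,
                 tune_kappa_quad = x$log$tune_kappa_quad[x$best_epoch])
}

#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(weighting = x$weighting, estimate = x$estimate,
                 ci_low = x$ci_low, ci_high = x$ci_high, n = x$n)
}

#' @export
tidy.grading_eval <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(statistic = "accuracy", estimate = x$accuracy$estimate,
                   ci_low = x$accuracy$ci_low, ci_high = x$accuracy$ci_high),
    tibble::tibble(statistic = "kappa", estimate = x$kappa$estimate,
                   ci_low = x$kappa$ci_low, ci_high = x$kappa$ci_high),
    tibble::tibble(statistic = "kappa_quad", estimate = x$kappa_quad$estimate,
                   ci_low = x$kappa_quad$ci_low, ci_high = x$kappa_quad$ci_high))
}

#' @export
glance.grading_eval <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy$estimate,
                 kappa = x$kappa$estimate, kappa_quad = x$kappa_quad$estimate)
}

#' @export
tidy.ratio_series_result <- function(x, ...) x$summary

#' @export
tidy.embedding_result <- function(x, ...) x$points

#' Plot a training log
#'
#' @param object A `stage1_model` or `stage2_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stage1_model <- function(object, ...) {
  object$log |>
    tidyr::pivot_longer(c("train_loss", "tune_roc_auc", "tune_pr_auc"),
                        names_to = "metric") |>
    ggplot2::ggplot(ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = "Stage-1 MIL training",
                  subtitle = "dotted line: selected checkpoint")
}

#' @rdname autoplot.stage1_model
#' @export
autoplot.stage2_model <- function(object, ...) {
  object$log |>
    tidyr::pivot_longer(c("train_loss", "tune_accuracy", "tune_kappa_quad"),
                        names_to = "metric") |>
    ggplot2::ggplot(ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = "Stage-2 grader training",
                  subtitle = "dotted line: selected checkpoint")
}

#' Plot the t-SNE embedding of pattern features
#'
#' @param object An `embedding_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.embedding_result <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$x, .data$y, color = .data$pattern)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_point(data = object$centroids, size = 5) +
    ggplot2::labs(title = "Stage-1 feature embedding (t-SNE)",
                  subtitle = sprintf("mean silhouette %.3f", object$silhouette))
}

#' Plot a ratio-concatenation series
#'
#' @param object A `ratio_series_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ratio_series_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(1 - .data$ratio, .data$mean,
                               color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                                          ymax = pmin(1, .data$mean + .data$sd)),
                             size = 0.3) +
    ggplot2::labs(x = "fraction of pattern-4 slide",
                  y = "mean class probability",
                  title = "Proportion sensitivity of the grader")
}

#' Plot a feature map channel summary
#'
#' Shows the per-position L2 norm of the feature vectors — a quick look at
#' where tissue signal sits on the canvas.
#'
#' @param object A `feature_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feature_map <- function(object, ...) {
  nrm <- sqrt(apply(object$values^2, c(1, 2), sum))
  df <- tidyr::expand_grid(row = seq_len(nrow(nrm)), col = seq_len(ncol(nrm)))
  df$norm <- as.numeric(nrm[cbind(df$row, df$col)])
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$norm)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Feature-map magnitude", x = NULL, y = NULL)
}
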