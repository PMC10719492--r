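#' Regression metrics for packing-angle predictions
#'
#' The standard metric set for one prediction run:
#' \describe{
#'   \item{pearson_r}{sample correlation of actual and predicted;}
#'   \item{mean_error}{mean absolute error, degrees;}
#'   \item{rmse}{root-mean-squared error, degrees;}
#'   \item{relrmse}{RMSE divided by the root-mean-square of the actual
#'     angles (dimensionless), so an error is judged relative to the
#'     magnitude of the angles themselves;}
#'   \item{slope, intercept}{ordinary least squares of predicted regressed
#'     on actual -- 1 and 0 for a perfect predictor.}
#' }
#'
#' @param actual,predicted Equal-length finite numeric vectors (degrees).
#' @return A one-row tibble of class `pa_eval` with columns `n`,
#'   `pearson_r`, `mean_error`, `rmse`, `relrmse`, `slope`, `intercept`.
#' @examples
#' regression_metrics(c(-44, -46), c(-45, -45))
#' @export
regression_metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    abort("actual and predicted must have equal length")
  }
  if (length(actual) == 0) abort("Empty prediction set")
  stopifnot(all(is.finite(actual)), all(is.finite(predicted)))
  n <- length(actual)
  err <- predicted - actual
  rmse <- sqrt(mean(err^2))
  if (n >= 2 && sd(actual) > 0 && sd(predicted) > 0) {
    r <- stats::cor(actual, predicted)
  } else {
    r <- NA_real_
  }
  if (n >= 2 && sd(actual) > 0) {
    fit <- coef(lm(predicted ~ actual))
    intercept <- unname(fit[1]); slope <- unname(fit[2])
  } else {
    slope <- NA_real_; intercept <- NA_real_
  }
  out <- tibble(
    n = n, pearson_r = r, mean_error = mean(abs(err)), rmse = rmse,
    relrmse = rmse / sqrt(mean(actual^2)),
    slope = slope, intercept = intercept
  )
  class(out) <- c("pa_eval", class(out))
  out
}

#' Classification metrics for the angle-class gatekeeper
#'
#' Builds the 3 x 3 confusion matrix in fixed class order (`min_outlier`,
#' `normal`, `max_outlier`) and computes accuracy and the multiclass
#' Matthews correlation coefficient (Gorodkin's generalization). A
#' degenerate margin (e.g. a single observed class) makes the MCC
#' undefined; it is reported as 0 with a warning.
#'
#' @param actual,predicted Factors (or values coercible via
#'   [classify_angle()] levels) of equal nonzero length.
#' @return A list of class `pa_class_eval` with `accuracy`, `mcc` and
#'   `confusion` (3 x 3 count matrix, rows = actual).
#' @export
classification_metrics <- function(actual, predicted) {
  lv <- angle_class_levels()
  actual <- factor(actual, levels = lv)
  predicted <- factor(predicted, levels = lv)
  if (length(actual) != length(predicted)) {
    abort("actual and predicted must have equal length")
  }
  if (length(actual) == 0) abort("Empty prediction set")
  confusion <- table(actual = actual, predicted = predicted)
  structure(
    list(accuracy = sum(diag(confusion)) / sum(confusion),
         mcc = multiclass_mcc(confusion),
         confusion = unclass(confusion)),
    class = "pa_class_eval"
  )
}

#' Multiclass Matthews correlation coefficient
#'
#' Gorodkin's K-category generalization, computed from a confusion matrix
#' with actual classes in rows and predicted classes in columns. Returns 0
#' (with a warning) when a marginal total makes the denominator zero.
#'
#' @param confusion Square count matrix.
#' @return MCC in \[-1, 1\].
#' @export
multiclass_mcc <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  s <- sum(confusion)
  c_trace <- sum(diag(confusion))
  t_k <- rowSums(confusion)   # actual counts
  p_k <- colSums(confusion)   # predicted counts
  denom <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (denom == 0) {
    warn("MCC undefined (degenerate class margin); returning 0")
    return(0)
  }
  (c_trace * s - sum(t_k * p_k)) / denom
}

#' @export
print.pa_class_eval <- function(x, ...) {
  cat(sprintf("accuracy %.3f, MCC %.3f\n", x$accuracy, x$mcc))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a prediction table
#'
#' Data-frame-first wrapper around [regression_metrics()] that keeps the
#' predictions with the metrics so the result can be plotted
#' ([autoplot.pa_predictions()]) or rendered to files ([render_report()]).
#'
#' @param data Data frame of predictions.
#' @param actual,predicted Column names (default `"angle_deg"`,
#'   `".pred"`).
#' @param method Label for report rows.
#' @return An object of class `pa_predictions`: the metrics row plus the
#'   prediction data.
#' @export
evaluate_predictions <- function(data, actual = "angle_deg",
                                 predicted = ".pred", method = "model") {
  metrics <- regression_metrics(data[[actual]], data[[predicted]])
  structure(
    list(method = method, metrics = metrics,
         data = tibble(actual = data[[actual]],
                       predicted = data[[predicted]])),
    class = "pa_predictions"
  )
}

#' @export
print.pa_predictions <- function(x, ...) {
  cat(sprintf("<pa_predictions %s> n = %d\n", x$method, x$metrics$n))
  print(as_tibble(x$metrics))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.pa_eval <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), cols = -"n",
                      names_to = "metric", values_to = "value")
}

#' Tidiers for evaluation and model objects
#'
#' `tidy()` returns long-format metrics (or, for a boosted regressor,
#' per-feature gain importance); `glance()` returns a one-row summary.
#'
#' @param x A `pa_eval`, `pa_predictions`, `cv_result` or `pa_model`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
#' @export
tidy.pa_predictions <- function(x, ...) tidy.pa_eval(x$metrics)

#' @rdname tidiers
#' @export
glance.pa_predictions <- function(x, ...) {
  dplyr::bind_cols(tibble(method = x$method), as_tibble(x$metrics))
}

#' @rdname tidiers
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(folds = x$folds, repeats = x$repeats, seed = x$seed),
    as_tibble(x$pooled))
}

#' @rdname tidiers
#' @export
tidy.cv_result <- function(x, ...) as_tibble(x$fold_metrics)

#' @rdname tidiers
#' @export
glance.pa_model <- function(x, ...) {
  tibble(kind = x$kind, schema = x$schema$name,
         n_features = x$schema$length, n_train = x$n_train,
         target_min = x$target_range[1], target_max = x$target_range[2])
}

#' @rdname tidiers
#' @export
tidy.pa_model <- function(x, ...) {
  if (x$kind != "gbr") {
    abort("tidy() feature importance is available for kind 'gbr' only")
  }
  as_tibble(xgboost::xgb.importance(model = x$fit))
}

#' Render an evaluation report to files
#'
#' Writes a one-row metrics TSV (`<prefix>_metrics.tsv`, columns `method`,
#' `n`, `pearson_r`, `mean_error`, `rmse`, `relrmse`, `slope`,
#' `intercept`) and the three standard diagnostic panels as PNG files:
#' predicted-vs-actual scatter with the identity line
#' (`<prefix>_scatter.png`), the error histogram (`<prefix>_errors.png`)
#' and squared error against actual angle (`<prefix>_sqerror.png`).
#'
#' @param x A `pa_predictions` from [evaluate_predictions()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (defaults to the method label).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(x, dir, prefix = NULL) {
  stopifnot(inherits(x, "pa_predictions"))
  prefix <- prefix %||% x$method
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, paste0(prefix, c("_metrics.tsv", "_scatter.png",
                                           "_errors.png", "_sqerror.png")))
  readr::write_tsv(glance.pa_predictions(x), files[1])
  plots <- list(autoplot(x, "scatter"), autoplot(x, "errors"),
                autoplot(x, "sqerror"))
  for (i in 1:3) {
    ggplot2::ggsave(files[i + 1], plots[[i]], width = 5, height = 4,
                    dpi = 150)
  }
  invisible(files)
}

#' Diagnostic plots for a prediction set
#'
#' The three panels used throughout reporting: (a) predicted vs actual
#' with the identity line, (b) the distribution of prediction errors,
#' (c) squared error for each actual angle.
#'
#' @param object A `pa_predictions` from [evaluate_predictions()].
#' @param which `"scatter"`, `"errors"` or `"sqerror"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pa_predictions <- function(object,
                                    which = c("scatter", "errors",
                                              "sqerror"), ...) {
  which <- match.arg(which)
  d <- object$data
  if (which == "scatter") {
    return(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$actual,
                                      y = .data$predicted)) +
        ggplot2::geom_abline(slope = 1, intercept = 0,
                             linetype = "dashed", colour = "grey50") +
        ggplot2::geom_point(alpha = 0.5, size = 0.9) +
        ggplot2::labs(x = "Actual packing angle (deg)",
                      y = "Predicted packing angle (deg)",
                      title = object$method) +
        ggplot2::theme_minimal()
    )
  }
  if (which == "errors") {
    return(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted - .data$actual)) +
        ggplot2::geom_histogram(bins = 30, fill = "grey35") +
        ggplot2::labs(x = "Prediction error (deg)", y = "Count",
                      title = object$method) +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$actual,
                                  y = (.data$predicted - .data$actual)^2)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::labs(x = "Actual packing angle (deg)",
                  y = "Squared error (deg^2)", title = object$method) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pa_predictions
#' @export
autoplot.cv_result <- function(object, which = c("scatter", "errors",
                                                 "sqerror"), ...) {
  ev <- evaluate_predictions(object$predictions,
                             method = sprintf("%d-fold CV", object$folds))
  autoplot.pa_predictions(ev, which = which)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
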