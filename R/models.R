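#' Gradient-boosting hyperparameter configurations
#'
#' `gbr_config()` holds the regression hyperparameters; the shipped
#' defaults are the grid-search-selected values used for all four feature
#' schemas. `gbc_config()` holds the three-class gatekeeper classifier's
#' hyperparameters.
#'
#' Gradient boosting is fitted with the xgboost library (exact
#' deterministic single-thread histogram trees): `learning_rate` is the
#' shrinkage per tree, `max_depth` the tree depth, `min_samples_leaf` the
#' minimum samples per leaf (for squared-error loss this is xgboost's
#' `min_child_weight`, since each sample has unit hessian), and
#' `n_estimators` the number of trees. `alpha` only affects the huber and
#' quantile losses; it is recorded but inert under the default
#' squared-error loss (the loss used for the published hyperparameters is
#' ambiguous, so all three readings are runnable via `loss`).
#' `warm_start` in the classifier config is likewise recorded but has no
#' effect on the fitted ensemble.
#'
#' @param alpha Quantile/huber parameter (default 0.01).
#' @param learning_rate Shrinkage (default 0.1).
#' @param max_depth Tree depth (default 2).
#' @param min_samples_leaf Minimum samples per leaf (default 10).
#' @param n_estimators Number of boosting rounds (default 50000).
#' @param random_state Integer seed (default 100).
#' @param loss One of `"squared_error"`, `"huber"`, `"quantile"`.
#' @param warm_start Logical, recorded only (default `TRUE`).
#' @return A list of class `gbr_config` / `gbc_config`.
#' @export
gbr_config <- function(alpha = 0.01, learning_rate = 0.1, max_depth = 2,
                       min_samples_leaf = 10, n_estimators = 50000,
                       random_state = 100,
                       loss = c("squared_error", "huber", "quantile")) {
  structure(
    list(alpha = alpha, learning_rate = learning_rate,
         max_depth = max_depth, min_samples_leaf = min_samples_leaf,
         n_estimators = n_estimators, random_state = random_state,
         loss = match.arg(loss)),
    class = "gbr_config"
  )
}

#' @rdname gbr_config
#' @export
gbc_config <- function(learning_rate = 0.1, max_depth = 2,
                       min_samples_leaf = 10, n_estimators = 50000,
                       random_state = 100, warm_start = TRUE) {
  structure(
    list(learning_rate = learning_rate, max_depth = max_depth,
         min_samples_leaf = min_samples_leaf, n_estimators = n_estimators,
         random_state = random_state, warm_start = warm_start),
    class = "gbc_config"
  )
}

xgb_reg_params <- function(config) {
  objective <- switch(config$loss,
    squared_error = list(objective = "reg:squarederror"),
    huber = list(objective = "reg:pseudohubererror",
                 huber_slope = config$alpha),
    quantile = list(objective = "reg:quantileerror",
                    quantile_alpha = config$alpha))
  c(objective,
    list(eta = config$learning_rate,
         max_depth = config$max_depth,
         min_child_weight = config$min_samples_leaf,
         tree_method = "hist", nthread = 1,
         seed = config$random_state))
}

# resolve newdata (matrix / record tibble / fv_structure / sequence path)
# to the model's feature matrix
model_matrix <- function(newdata, schema) {
  if (is.matrix(newdata)) {
    if (ncol(newdata) != schema$length) {
      abort(sprintf("Feature matrix has %d columns; schema %s needs %d",
                    ncol(newdata), schema$name, schema$length))
    }
    return(newdata)
  }
  if (is.data.frame(newdata) && "residues" %in% names(newdata)) {
    return(features_from_records(newdata, schema))
  }
  matrix(featurize(newdata, schema), nrow = 1)
}

new_pa_model <- function(kind, schema, config, fit, y, n) {
  structure(
    list(kind = kind, schema = schema, config = config, fit = fit,
         target_range = range(y), n_train = n,
         trained = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    class = c(paste0("pa_", kind), "pa_model")
  )
}

#' Train a gradient-boosted packing-angle regressor
#'
#' Fits a gradient-boosted regression ensemble on angle records (or a raw
#' feature matrix) under one feature schema. Training is deterministic for
#' a fixed config and input order.
#'
#' @param data Angle-record tibble (with `residues`, loop lengths and the
#'   target column), or a numeric feature matrix matching the schema.
#' @param schema A [feature_schema] or its name.
#' @param config A [gbr_config()].
#' @param angle Target angles in degrees when `data` is a matrix;
#'   otherwise taken from `angle_col`.
#' @param angle_col Name of the target column (default `"angle_deg"`).
#' @return A `pa_model` bundle (kind `"gbr"`); use [predict()] on it.
#' @export
train_gbr <- function(data, schema = "gbr4", config = gbr_config(),
                      angle = NULL, angle_col = "angle_deg") {
  schema <- as_schema(schema)
  x <- model_matrix(data, schema)
  y <- angle %||% data[[angle_col]]
  stopifnot(length(y) == nrow(x), all(is.finite(y)))
  if (nrow(x) < 2 * config$min_samples_leaf) {
    abort(sprintf("Too few samples (%d) for min_samples_leaf = %d",
                  nrow(x), config$min_samples_leaf))
  }
  booster <- xgboost::xgb.train(
    params = xgb_reg_params(config),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
    nrounds = config$n_estimators, verbose = 0)
  new_pa_model("gbr", schema, config, booster, y, nrow(x))
}

#' Classify a packing angle as normal or outlier
#'
#' Observed packing angles are essentially normally distributed with
#' poorly populated tails; about 94% of structures fall between -40 and
#' -50 degrees. That range (inclusive on both ends) is the `normal` class;
#' anything above it is a `max_outlier` and anything below a
#' `min_outlier`.
#'
#' @param angle_deg Numeric vector of angles in degrees.
#' @return Factor with levels `min_outlier`, `normal`, `max_outlier`.
#' @examples
#' classify_angle(c(-45, -39.9, -50.1))
#' @export
classify_angle <- function(angle_deg) {
  stopifnot(all(is.finite(angle_deg)))
  factor(
    ifelse(angle_deg < -50, "min_outlier",
           ifelse(angle_deg > -40, "max_outlier", "normal")),
    levels = angle_class_levels()
  )
}

#' @rdname classify_angle
#' @export
angle_class_levels <- function() c("min_outlier", "normal", "max_outlier")

#' Train the classifier-gated packing-angle predictor
#'
#' Two-stage predictor: a gradient-boosted three-class 'gatekeeper'
#' classifier assigns each example to `min_outlier` / `normal` /
#' `max_outlier` (see [classify_angle()]), and three class-specific
#' gradient-boosted regressors -- each trained only on its class's
#' records, with the same regression hyperparameters -- produce the angle.
#' At prediction time each example is routed to exactly the regressor of
#' its predicted class.
#'
#' @inheritParams train_gbr
#' @param gbc A [gbc_config()] for the gatekeeper.
#' @param gbr A [gbr_config()] for the three class regressors.
#' @return A `pa_model` bundle (kind `"gated"`).
#' @export
train_gated <- function(data, schema = "gbr4", gbc = gbc_config(),
                        gbr = gbr_config(), angle = NULL,
                        angle_col = "angle_deg") {
  schema <- as_schema(schema)
  x <- model_matrix(data, schema)
  y <- angle %||% data[[angle_col]]
  stopifnot(length(y) == nrow(x))
  cls <- classify_angle(y)
  counts <- table(cls)
  need <- 2 * gbr$min_samples_leaf
  if (any(counts < need)) {
    abort(sprintf(
      "Class(es) too small for gating (%s; need >= %d each): widen the data or disable gating",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
      need))
  }
  gate <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = 3,
                  eta = gbc$learning_rate, max_depth = gbc$max_depth,
                  min_child_weight = gbc$min_samples_leaf,
                  tree_method = "hist", nthread = 1,
                  seed = gbc$random_state),
    data = xgboost::xgb.DMatrix(
      x, label = as.integer(cls) - 1L, nthread = 1),
    nrounds = gbc$n_estimators, verbose = 0)
  regressors <- lapply(angle_class_levels(), function(lv) {
    keep <- cls == lv
    booster <- xgboost::xgb.train(
      params = xgb_reg_params(gbr),
      data = xgboost::xgb.DMatrix(x[keep, , drop = FALSE],
                                  label = y[keep], nthread = 1),
      nrounds = gbr$n_estimators, verbose = 0)
    list(booster = booster, range = range(y[keep]))
  })
  names(regressors) <- angle_class_levels()
  fit <- list(gate = gate, regressors = regressors, gbc = gbc)
  new_pa_model("gated", schema, gbr, fit, y, nrow(x))
}

#' Train the multi-layer-perceptron baseline
#'
#' A single-hidden-layer feed-forward regressor used as a neural-network
#' comparison point: rectified-linear hidden units, one linear output, L2
#' weight penalty, Glorot-uniform initialization controlled by `seed`, and
#' L-BFGS optimization of the penalized least-squares loss on the raw
#' (unstandardized) features. Non-convergence within `max_iter` iterations
#' produces a warning, not an error.
#'
#' @inheritParams train_gbr
#' @param hidden Hidden-layer width (default 15).
#' @param max_iter Maximum optimizer iterations (default 1200).
#' @param alpha L2 penalty strength (default 0.0001).
#' @param seed Integer seed for the weight initialization.
#' @return A `pa_model` bundle (kind `"mlp"`).
#' @export
train_mlp <- function(data, schema = "gbr4", hidden = 15L,
                      max_iter = 1200L, alpha = 1e-4, seed = 100,
                      angle = NULL, angle_col = "angle_deg") {
  schema <- as_schema(schema)
  x <- model_matrix(data, schema)
  y <- angle %||% data[[angle_col]]
  stopifnot(length(y) == nrow(x), all(is.finite(y)))
  p <- ncol(x); h <- as.integer(hidden); n <- nrow(x)

  unpack <- function(par) {
    list(W1 = matrix(par[seq_len(p * h)], p, h),
         b1 = par[p * h + seq_len(h)],
         W2 = par[p * h + h + seq_len(h)],
         b2 = par[p * h + 2 * h + 1])
  }
  fwd <- function(w, x) {
    a <- sweep(x %*% w$W1, 2, w$b1, "+")
    z <- pmax(a, 0)
    list(a = a, z = z, yhat = drop(z %*% w$W2) + w$b2)
  }
  loss <- function(par) {
    w <- unpack(par)
    f <- fwd(w, x)
    mean((f$yhat - y)^2) / 2 +
      alpha / (2 * n) * (sum(w$W1^2) + sum(w$W2^2))
  }
  grad <- function(par) {
    w <- unpack(par)
    f <- fwd(w, x)
    d_out <- (f$yhat - y) / n                     # n-vector
    gW2 <- drop(crossprod(f$z, d_out)) + alpha / n * w$W2
    gb2 <- sum(d_out)
    d_hid <- (d_out %o% w$W2) * (f$a > 0)         # n x h
    gW1 <- crossprod(x, d_hid) + alpha / n * w$W1
    gb1 <- colSums(d_hid)
    c(as.vector(gW1), gb1, gW2, gb2)
  }

  init <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    lim1 <- sqrt(6 / (p + h))
    lim2 <- sqrt(6 / (h + 1))
    c(runif(p * h, -lim1, lim1), rep(0, h),
      runif(h, -lim2, lim2), 0)
  })
  opt <- optim(init, fn = loss, gr = grad, method = "L-BFGS-B",
               control = list(maxit = max_iter))
  if (opt$convergence != 0) {
    warn(sprintf("MLP optimizer did not converge within %d iterations (%s)",
                 max_iter, opt$message %||% ""))
  }
  fit <- c(unpack(opt$par),
           list(hidden = h, alpha = alpha, max_iter = max_iter,
                seed = seed, final_loss = opt$value,
                converged = opt$convergence == 0))
  new_pa_model("mlp", schema, fit[c("hidden", "alpha", "max_iter", "seed")],
               fit, y, n)
}

#' Predict packing angles from a fitted model bundle
#'
#' @param object A `pa_model` from [train_gbr()], [train_gated()] or
#'   [train_mlp()].
#' @param newdata Angle-record tibble, feature matrix, [fv_structure],
#'   numbered-sequence tibble or file path; must match the bundle's
#'   schema.
#' @param type For gated bundles: `"angle"` (default) returns the angles,
#'   `"class"` the gatekeeper classes, `"both"` a tibble with `.pred` and
#'   `.class`. Ignored for other kinds.
#' @param ... Unused.
#' @return Numeric vector of angles in degrees (or per `type`).
#' @export
predict.pa_model <- function(object, newdata,
                             type = c("angle", "class", "both"), ...) {
  type <- match.arg(type)
  x <- model_matrix(newdata, object$schema)
  if (object$kind == "gbr") {
    return(predict(object$fit, xgboost::xgb.DMatrix(x, nthread = 1)))
  }
  if (object$kind == "mlp") {
    w <- object$fit
    return(drop(pmax(sweep(x %*% w$W1, 2, w$b1, "+"), 0) %*% w$W2) + w$b2)
  }
  # gated: route each example through the regressor of its predicted class
  prob <- predict(object$fit$gate, xgboost::xgb.DMatrix(x, nthread = 1))
  cls <- factor(angle_class_levels()[max.col(prob, ties.method = "first")],
                levels = angle_class_levels())
  if (type == "class") return(cls)
  pred <- numeric(nrow(x))
  for (lv in angle_class_levels()) {
    pick <- cls == lv
    if (any(pick)) {
      pred[pick] <- predict(
        object$fit$regressors[[lv]]$booster,
        xgboost::xgb.DMatrix(x[pick, , drop = FALSE], nthread = 1))
    }
  }
  if (type == "both") return(tibble(.pred = pred, .class = cls))
  pred
}

#' @export
print.pa_model <- function(x, ...) {
  cat(sprintf("<pa_model %s> schema %s (%d features), %d training samples\n",
              x$kind, x$schema$name, x$schema$length, x$n_train))
  invisible(x)
}

#' Save / load a model bundle
#'
#' Bundles are serialized with their feature schema and configuration;
#' `load_model()` refuses a bundle whose schema disagrees with the one
#' requested, which protects against predicting with mismatched feature
#' layouts.
#'
#' @param object A `pa_model`.
#' @param path File path.
#' @param schema Optional schema (or name) the loaded bundle must match.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   bundle.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "pa_model"))
  ser <- object
  if (object$kind == "gbr") {
    ser$fit <- xgboost::xgb.save.raw(object$fit)
  } else if (object$kind == "gated") {
    ser$fit$gate <- xgboost::xgb.save.raw(object$fit$gate)
    ser$fit$regressors <- lapply(object$fit$regressors, function(r) {
      r$booster <- xgboost::xgb.save.raw(r$booster)
      r
    })
  }
  saveRDS(ser, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path, schema = NULL) {
  object <- readRDS(path)
  stopifnot(inherits(object, "pa_model"))
  if (!is.null(schema)) {
    schema <- as_schema(schema)
    if (!identical(schema$name, object$schema$name)) {
      abort(sprintf("Bundle was trained with schema %s, not %s",
                    object$schema$name, schema$name))
    }
  }
  if (object$kind == "gbr") {
    object$fit <- xgboost::xgb.load.raw(object$fit)
  } else if (object$kind == "gated") {
    object$fit$gate <- xgboost::xgb.load.raw(object$fit$gate)
    object$fit$regressors <- lapply(object$fit$regressors, function(r) {
      r$booster <- xgboost::xgb.load.raw(r$booster)
      r
    })
  }
  object
}

#' Repeated K-fold cross-validation of the boosted regressor
#'
#' Partitions the records into `folds` folds (`repeats` independent
#' repartitions); in each round the model is retrained on the other folds
#' and predicts the held-out fold, so every record is predicted exactly
#' once per repeat by a model not trained on it. Metrics are computed on
#' the pooled out-of-fold predictions and per fold.
#'
#' @param records Angle-record tibble.
#' @param schema A [feature_schema] or its name.
#' @param config A [gbr_config()].
#' @param folds Number of folds (default 10).
#' @param repeats Number of repartitions (default 1).
#' @param seed Integer seed for the fold assignment.
#' @return A list of class `cv_result`: `pooled` ([regression_metrics()]
#'   row), `fold_metrics` (one row per fold and repeat), `predictions`
#'   (tibble of `id`, `rep`, `fold`, `angle_deg`, `.pred`).
#' @export
cross_validate <- function(records, schema = "gbr4", config = gbr_config(),
                           folds = 10, repeats = 1, seed = 100) {
  if (folds < 2) abort("folds must be >= 2")
  n <- nrow(records)
  if (n < folds) abort("Need at least as many records as folds")
  schema <- as_schema(schema)
  x <- features_from_records(records, schema)
  y <- records$angle_deg

  assignments <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    lapply(seq_len(repeats), function(r) sample(rep(seq_len(folds),
                                                    length.out = n)))
  })

  preds <- list()
  fold_rows <- list()
  for (r in seq_len(repeats)) {
    fold_of <- assignments[[r]]
    pred_r <- numeric(n)
    for (k in seq_len(folds)) {
      hold <- fold_of == k
      model <- train_gbr(x[!hold, , drop = FALSE], schema, config,
                         angle = y[!hold])
      pred_r[hold] <- predict(model, x[hold, , drop = FALSE])
      fold_rows[[length(fold_rows) + 1L]] <- dplyr::bind_cols(
        tibble(rep = r, fold = k),
        regression_metrics(y[hold], pred_r[hold]))
    }
    preds[[r]] <- tibble(id = records$id, rep = r, fold = fold_of,
                         angle_deg = y, .pred = pred_r)
  }
  predictions <- dplyr::bind_rows(preds)
  structure(
    list(pooled = regression_metrics(predictions$angle_deg,
                                     predictions$.pred),
         fold_metrics = dplyr::bind_rows(fold_rows),
         predictions = predictions,
         folds = folds, repeats = repeats, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold x %d repeat(s), %d records\n",
              x$folds, x$repeats, nrow(x$predictions) / x$repeats))
  print(x$pooled)
  invisible(x)
}
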