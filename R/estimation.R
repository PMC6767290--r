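#' Specify a regression model for volume or fill-ratio estimation
#'
#' Epsilon-insensitive support vector regression with a linear or Gaussian
#' kernel, or a single-factor ordinary least squares benchmark. The Gaussian
#' kernel is `k(u, v) = exp(-||u - v||^2 / kernel_scale^2)`, evaluated on
#' z-score standardized features; the named kernels fix the scale at 5.7
#' (medium) or 23 (coarse). Unless overridden, the box constraint and
#' epsilon tube follow the `iqr(y)/1.349` and `iqr(y)/13.49` defaults of the
#' regression toolbox convention under which those kernel scales were
#' established.
#'
#' @param target `"volume"` or `"fill_ratio"`; which label column the model
#'   predicts (`mass_g` or `fill_ratio_pre`).
#' @param model `"svm"` or `"lr"` (single-factor linear regression).
#' @param kernel For SVM: `"linear"`, `"medium"` or `"coarse"` Gaussian.
#' @param kernel_scale Gaussian kernel scale; defaults to 5.7 / 23 for the
#'   named kernels, ignored for the linear kernel.
#' @param box_constraint SVM cost parameter; `NULL` = `iqr(y)/1.349`.
#' @param epsilon_tube SVR insensitivity width; `NULL` = `iqr(y)/13.49`.
#' @param lr_feature For `model = "lr"`: the single feature to regress on
#'   (`"sip_duration"`, `"integral_theta"` or `"max_theta"`).
#' @param scope Feature scope the spec was extracted at (`"macro"` or
#'   `"sip"`); carried as metadata.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(target = c("volume", "fill_ratio"),
                       model = c("svm", "lr"),
                       kernel = c("medium", "coarse", "linear"),
                       kernel_scale = NULL,
                       box_constraint = NULL,
                       epsilon_tube = NULL,
                       lr_feature = NULL,
                       scope = "macro") {
  target <- match.arg(target)
  model <- match.arg(model)
  kernel <- match.arg(kernel)
  if (is.null(kernel_scale)) {
    kernel_scale <- switch(kernel, medium = 5.7, coarse = 23, linear = NA_real_)
  }
  if (!is.na(kernel_scale) && kernel_scale <= 0) {
    abort("kernel_scale must be positive", class = "sipsense_validation_error")
  }
  if (model == "lr" && is.null(lr_feature)) {
    abort("model = 'lr' requires lr_feature", class = "sipsense_validation_error")
  }
  structure(list(target = target, model = model, kernel = kernel,
                 kernel_scale = kernel_scale, box_constraint = box_constraint,
                 epsilon_tube = epsilon_tube, lr_feature = lr_feature,
                 scope = scope),
            class = "model_spec")
}

#' Fit a regression model to a feature matrix
#'
#' Features are z-score standardized with parameters learned from the
#' training rows only (stored on the model and reapplied at prediction
#' time); zero-variance features are dropped with a warning. Predictions are
#' returned in label units.
#'
#' @param spec A [model_spec()].
#' @param X Data frame of numeric features (one row per drink).
#' @param y Numeric labels matching the rows of `X`.
#' @return Object of class `sip_model` with the fitted regressor and
#'   standardization parameters.
#' @export
fit <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) {
    abort("rows of X must match length of y", class = "sipsense_validation_error")
  }
  if (nrow(X) < 2) {
    abort("at least 2 training rows required", class = "sipsense_validation_error")
  }
  if (anyNA(X) || anyNA(y)) {
    abort("missing values in training data", class = "sipsense_validation_error")
  }

  if (spec$model == "lr") {
    f <- spec$lr_feature
    if (!f %in% names(X)) {
      abort(paste0("lr_feature not in X: ", f), class = "sipsense_validation_error")
    }
    x1 <- X[[f]]
    if (var(x1) == 0) {
      abort("zero-variance benchmark feature", class = "sipsense_validation_error")
    }
    fitted <- lm(y ~ x1, data = data.frame(x1 = x1, y = y))
    return(structure(list(spec = spec, fit = fitted, features = f,
                          center = NULL, scale = NULL,
                          fr_source = attr(X, "fr_source")),
                     class = "sip_model"))
  }

  mu <- vapply(X, mean, numeric(1))
  sdev <- vapply(X, sd, numeric(1))
  keep <- sdev > 0
  if (!all(keep)) {
    warn(paste0("dropping zero-variance feature(s): ",
                paste(names(X)[!keep], collapse = ", ")))
  }
  Xs <- scale(as.matrix(X[, keep, drop = FALSE]),
              center = mu[keep], scale = sdev[keep])
  cost <- spec$box_constraint %||% (IQR(y) / 1.349)
  eps <- spec$epsilon_tube %||% (IQR(y) / 13.49)
  if (cost <= 0) cost <- 1      # degenerate iqr(y) = 0
  if (eps <= 0) eps <- 1e-3
  svm_args <- list(x = Xs, y = y, type = "eps-regression",
                   cost = cost, epsilon = eps, scale = FALSE)
  if (spec$kernel == "linear") {
    svm_args$kernel <- "linear"
  } else {
    svm_args$kernel <- "radial"
    svm_args$gamma <- 1 / spec$kernel_scale^2
  }
  fitted <- do.call(e1071::svm, svm_args)
  structure(list(spec = spec, fit = fitted, features = names(X)[keep],
                 center = mu[keep], scale = sdev[keep],
                 fr_source = attr(X, "fr_source")),
            class = "sip_model")
}

#' @export
predict.sip_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (object$spec$model == "lr") {
    return(unname(predict(object$fit,
                          newdata = data.frame(x1 = newdata[[object$features]]))))
  }
  Xs <- scale(as.matrix(newdata[, object$features, drop = FALSE]),
              center = object$center, scale = object$scale)
  unname(predict(object$fit, Xs))
}

#' @export
print.sip_model <- function(x, ...) {
  cat(sprintf("<sip_model> %s %s%s, target %s, %d feature(s)\n",
              x$spec$model,
              if (x$spec$model == "svm") x$spec$kernel else x$spec$lr_feature,
              if (x$spec$model == "svm" && x$spec$kernel != "linear")
                sprintf(" (scale %.3g)", x$spec$kernel_scale) else "",
              x$spec$target, length(x$features)))
  invisible(x)
}

#' @export
tidy.sip_model <- function(x, ...) {
  if (x$spec$model == "lr") {
    co <- coef(x$fit)
    return(tibble(term = c("(Intercept)", x$features),
                  estimate = unname(co)))
  }
  tibble(term = x$features,
         center = unname(x$center),
         scale = unname(x$scale))
}

#' @export
glance.sip_model <- function(x, ...) {
  tibble(model = x$spec$model,
         kernel = if (x$spec$model == "svm") x$spec$kernel else NA_character_,
         kernel_scale = x$spec$kernel_scale,
         target = x$spec$target,
         n_features = length(x$features),
         n_sv = if (x$spec$model == "svm") x$fit$tot.nSV else NA_integer_,
         fr_source = x$fr_source %||% NA_character_)
}

#' Fit a single-factor linear regression benchmark
#'
#' Convenience wrapper for the ordinary least squares benchmarks
#' (`y = b0 + b1 * f`).
#'
#' @param feature One of `"sip_duration"`, `"integral_theta"`, `"max_theta"`.
#' @param X Data frame containing the feature column.
#' @param y Labels.
#' @param target Label kind, carried as metadata.
#' @return A `sip_model`.
#' @export
fit_lr_single <- function(feature, X, y, target = "volume") {
  fit(model_spec(target = target, model = "lr", lr_feature = feature), X, y)
}

#' Append the fill ratio to a feature matrix
#'
#' The appended column is standardized together with the other features at
#' fit time; its provenance (`truth` vs `estimate`) is recorded on the
#' matrix and copied into the fitted model.
#'
#' @param X Feature data frame.
#' @param fr Fill-ratio values, one per row of `X`.
#' @param source `"truth"` or `"estimate"`.
#' @return `X` with an extra `fill_ratio` column and attribute `fr_source`.
#' @export
append_fill_ratio_feature <- function(X, fr, source = c("truth", "estimate")) {
  source <- match.arg(source)
  if (length(fr) != nrow(X)) {
    abort("fr length must equal rows of X", class = "sipsense_validation_error")
  }
  X <- as_tibble(X)
  X$fill_ratio <- fr
  attr(X, "fr_source") <- source
  X
}

#' Select the training rows closest in fill ratio to a query
#'
#' Returns the indices of the `k` training rows whose fill-ratio labels are
#' closest (absolute difference) to the query estimate; ties break by
#' original row order.
#'
#' @param train_fr Fill-ratio labels of the training rows.
#' @param query_fr Scalar fill-ratio estimate for the test drink.
#' @param k Number of neighbours (default 150).
#' @return Integer indices into `train_fr`.
#' @export
condition_training_set <- function(train_fr, query_fr, k = 150L) {
  if (k > length(train_fr)) {
    abort(sprintf("k = %d exceeds training size %d", k, length(train_fr)),
          class = "sipsense_validation_error")
  }
  ord <- order(abs(train_fr - query_fr))  # radix sort: stable in ties
  sort(ord[seq_len(k)])
}

target_column <- function(target) {
  switch(target, volume = "mass_g", fill_ratio = "fill_ratio_pre")
}

#' Evaluate a model under leave-one-trial-out validation
#'
#' One fold per trial: fold `k` trains on every other trial (features
#' standardized within the training fold) and predicts every drink of trial
#' `k`. Deterministic given the data and spec.
#'
#' @param data Tibble joining per-drink features and labels; must contain
#'   `trial_id`, `drink_index`, the feature columns and the target column
#'   (`mass_g` or `fill_ratio_pre`).
#' @param spec A [model_spec()].
#' @param feature_cols Feature columns to use; default the 33 IS features
#'   (plus `fill_ratio` if present). Ignored for `model = "lr"`.
#' @param multi_target `"none"`, `"partition"` (restrict each test drink's
#'   training set to the `k_nearest` rows nearest in fill ratio) or
#'   `"append"` (append the fill ratio as a feature).
#' @param fr_values Per-row fill ratios used by the multi-target strategies
#'   (the training side always uses the ground-truth labels; `fr_values`
#'   supplies the query/appended value per drink — pass label fill ratios
#'   for `source = "truth"`, or model estimates).
#' @param fr_source `"truth"` or `"estimate"`; provenance tag for `fr_values`.
#' @param k_nearest Neighbourhood size for the partition strategy.
#' @return Tibble of class `loto_result`: one row per drink with `trial_id`,
#'   `drink_index`, `truth`, `pred`, plus per-fold bookkeeping (`n_train`).
#'   Attribute `folds` keeps the per-fold audit trail: standardization
#'   parameters, training size and the trials trained on.
#' @export
loto_evaluate <- function(data, spec, feature_cols = NULL,
                          multi_target = c("none", "partition", "append"),
                          fr_values = NULL,
                          fr_source = c("truth", "estimate"),
                          k_nearest = 150L) {
  multi_target <- match.arg(multi_target)
  fr_source <- match.arg(fr_source)
  ycol <- target_column(spec$target)
  stopifnot(ycol %in% names(data), "trial_id" %in% names(data))
  trials <- unique(data$trial_id)
  if (length(trials) < 2) {
    abort("LOTO needs at least 2 trials", class = "sipsense_validation_error")
  }
  if (is.null(feature_cols)) {
    feature_cols <- intersect(c(is_feature_names(),
                                if (multi_target == "append") "fill_ratio"),
                              names(data))
    if (spec$model == "lr") feature_cols <- spec$lr_feature
  }
  if (multi_target != "none") {
    if (is.null(fr_values)) {
      if (fr_source == "truth") fr_values <- data$fill_ratio_pre
      else abort("fr_values must be supplied for fr_source = 'estimate'",
                 class = "sipsense_validation_error")
    }
    stopifnot(length(fr_values) == nrow(data))
  }

  fold_meta <- list()
  res <- purrr::map_dfr(trials, function(tr) {
    test_i <- which(data$trial_id == tr)
    train_i <- which(data$trial_id != tr)
    Xtr <- data[train_i, feature_cols, drop = FALSE]
    ytr <- data[[ycol]][train_i]
    Xte <- data[test_i, feature_cols, drop = FALSE]

    if (multi_target == "append") {
      # training side uses the ground-truth fill-ratio labels; the test side
      # uses fr_values (truth or an upstream estimate)
      Xtr <- append_fill_ratio_feature(Xtr, data$fill_ratio_pre[train_i],
                                       source = fr_source)
      Xte <- append_fill_ratio_feature(Xte, fr_values[test_i],
                                       source = fr_source)
      m <- fit(spec, Xtr, ytr)
      preds <- predict(m, Xte)
      fold_meta[[tr]] <<- list(center = m$center, scale = m$scale,
                               n_train = length(train_i),
                               train_trials = unique(data$trial_id[train_i]))
    } else if (multi_target == "partition") {
      preds <- vapply(seq_along(test_i), function(j) {
        sel <- condition_training_set(data$fill_ratio_pre[train_i],
                                      fr_values[test_i[j]], k = k_nearest)
        m <- fit(spec, Xtr[sel, , drop = FALSE], ytr[sel])
        predict(m, Xte[j, , drop = FALSE])
      }, numeric(1))
      fold_meta[[tr]] <<- list(n_train = k_nearest,
                               train_trials = unique(data$trial_id[train_i]))
    } else {
      m <- fit(spec, Xtr, ytr)
      preds <- predict(m, Xte)
      fold_meta[[tr]] <<- list(center = m$center, scale = m$scale,
                               n_train = length(train_i),
                               train_trials = unique(data$trial_id[train_i]))
    }
    tibble(trial_id = tr,
           drink_index = data$drink_index[test_i],
           truth = data[[ycol]][test_i],
           pred = as.numeric(preds),
           n_train = fold_meta[[tr]]$n_train)
  })
  structure(res, folds = fold_meta, spec = spec,
            class = c("loto_result", class(res)))
}
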