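#' Map a phenological stage to its calibration phase
#'
#' CNC is estimated by two stage-specific models: one calibrated on
#' vegetative data (tillering + jointing), one on reproductive data
#' (heading + filling) -- the physiological shift after heading is the
#' principal change in N dynamics.
#'
#' @param stage Stage label(s).
#' @return `"vegetative"` or `"reproductive"` per element.
#' @export
stage_phase <- function(stage) {
  map <- c(tillering = "vegetative", jointing = "vegetative",
           heading = "reproductive", filling = "reproductive")
  out <- unname(map[stage])
  if (anyNA(out)) gy_stop(paste("unknown stage:", paste(stage[is.na(out)], collapse = ", ")),
                          "input_error")
  out
}

default_rf_hyper <- function() {
  list(trees = 50L, max_depth = 6L, min_leaf = 3L, mtry = "sqrt", seed = 42L)
}

fit_rf <- function(x, y, hyper) {
  mtry <- if (identical(hyper$mtry, "sqrt")) max(1L, floor(sqrt(ncol(x)))) else as.integer(hyper$mtry)
  ranger::ranger(
    x = x, y = y,
    num.trees = hyper$trees, mtry = mtry,
    min.node.size = hyper$min_leaf, max.depth = hyper$max_depth,
    seed = hyper$seed, num.threads = 1
  )
}

check_features <- function(rows, features, what) {
  missing <- setdiff(features, names(rows))
  if (length(missing) > 0) {
    gy_stop(paste0(what, " missing feature column(s): ", paste(missing, collapse = ", ")),
            "schema_error")
  }
}

#' Fit a stage-phase random-forest CNC estimator
#'
#' Random-forest regression of field-measured CNC on the five plot-mean
#' vegetation indices, one model per phase. Hyperparameters default to the
#' common compact setting (50 trees, max depth 6, min leaf 3, sqrt(p)
#' feature subsampling, seed 42) and are overridable. Features are matched
#' by name, never by position.
#'
#' @param train Data frame with the five VI columns (`NDVI`, `NDRE`, `EVI`,
#'   `GNDVI`, `SAVI`), a `cnc` target column, and optionally a `stage`
#'   column (checked against `phase`).
#' @param phase `"vegetative"` or `"reproductive"`.
#' @param hyper Hyperparameter list, see `default_rf_hyper` entries `trees`,
#'   `max_depth`, `min_leaf`, `mtry`, `seed`.
#' @return Object of class `cnc_estimator` with the fitted forest, feature
#'   order, target range, training R-squared (1 - SSE/SST) and metadata.
#' @export
fit_cnc <- function(train, phase = c("vegetative", "reproductive"),
                    hyper = default_rf_hyper()) {
  phase <- match.arg(phase)
  check_features(train, c(vi_names(), "cnc"), "CNC training data")
  if ("stage" %in% names(train)) {
    ph <- stage_phase(train$stage)
    if (any(ph != phase)) {
      gy_stop(sprintf("training rows from the %s phase passed to the %s model",
                      paste(unique(ph[ph != phase]), collapse = "/"), phase),
              "input_error")
    }
  }
  if (nrow(train) < 10) {
    gy_stop(sprintf("need >= 10 training rows, got %d", nrow(train)), "input_error")
  }
  x <- train[, vi_names(), drop = FALSE]
  y <- train$cnc
  if (any(!is.finite(as.matrix(x))) || any(!is.finite(y))) {
    gy_stop("non-finite values in CNC training data", "input_error")
  }
  forest <- fit_rf(x, y, hyper)
  pred <- stats::predict(forest, data = x, num.threads = 1)$predictions
  sst <- sum((y - mean(y))^2)
  structure(
    list(forest = forest, phase = phase, features = vi_names(),
         hyper = hyper, target_range = range(y),
         train_r2 = if (sst > 0) 1 - sum((y - pred)^2) / sst else NA_real_,
         n_train = nrow(train), version = "grassyield-cnc-1"),
    class = "cnc_estimator"
  )
}

#' @export
print.cnc_estimator <- function(x, ...) {
  cat(sprintf("CNC random-forest estimator (%s phase): %d trees, n = %d, train R2 = %.3f\n",
              x$phase, x$hyper$trees, x$n_train, x$train_r2))
  invisible(x)
}

#' Predict CNC from plot-mean vegetation indices
#'
#' Features are matched by column name (any column order); a missing
#' feature raises a schema error. Forest-mean predictions are bounded by
#' the training-target range.
#'
#' @param est A [fit_cnc()] estimator.
#' @param rows Data frame carrying the five VI columns.
#' @return Numeric vector of CNC predictions (%).
#' @export
predict_cnc <- function(est, rows) {
  stopifnot(inherits(est, "cnc_estimator"))
  check_features(rows, est$features, "prediction data")
  stats::predict(est$forest, data = rows[, est$features, drop = FALSE],
                 num.threads = 1)$predictions
}

#' Fit both phase models and predict with stage routing
#'
#' `fit_cnc_models()` fits the vegetative and reproductive estimators from a
#' stage-labelled training table; `predict_cnc_by_stage()` routes each row
#' to its phase's estimator (heading/filling rows are scored by the
#' reproductive model).
#'
#' @param train Stage-labelled training table (columns as in [fit_cnc()]
#'   plus `stage`).
#' @param hyper Shared hyperparameters.
#' @return `fit_cnc_models`: named list with `vegetative` and
#'   `reproductive` estimators.
#' @export
fit_cnc_models <- function(train, hyper = default_rf_hyper()) {
  check_features(train, c(vi_names(), "cnc", "stage"), "CNC training data")
  ph <- stage_phase(train$stage)
  list(
    vegetative = fit_cnc(train[ph == "vegetative", , drop = FALSE], "vegetative", hyper),
    reproductive = fit_cnc(train[ph == "reproductive", , drop = FALSE], "reproductive", hyper)
  )
}

#' @rdname fit_cnc_models
#' @param models List from [fit_cnc_models()].
#' @param rows Stage-labelled rows to score.
#' @export
predict_cnc_by_stage <- function(models, rows) {
  check_features(rows, c(vi_names(), "stage"), "prediction data")
  ph <- stage_phase(rows$stage)
  out <- numeric(nrow(rows))
  for (p in unique(ph)) {
    out[ph == p] <- predict_cnc(models[[p]], rows[ph == p, , drop = FALSE])
  }
  out
}

#' Persist / restore a CNC estimator
#'
#' Versioned on-disk model artifact embedding the hyperparameters and
#' feature order; `load_cnc_model()` refuses artifacts whose version or
#' feature schema does not match.
#'
#' @param est A `cnc_estimator`.
#' @param path Artifact path (RDS).
#' @export
save_cnc_model <- function(est, path) {
  stopifnot(inherits(est, "cnc_estimator"))
  saveRDS(est, path)
  invisible(path)
}

#' @rdname save_cnc_model
#' @export
load_cnc_model <- function(path) {
  if (!file.exists(path)) gy_stop(paste("no such model artifact:", path), "format_error")
  est <- readRDS(path)
  if (!inherits(est, "cnc_estimator") || !identical(est$version, "grassyield-cnc-1") ||
      !identical(est$features, vi_names())) {
    gy_stop("model artifact schema/version mismatch; refusing to predict", "schema_error")
  }
  est
}
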