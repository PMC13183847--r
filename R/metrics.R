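#' Agreement metrics for an observed/predicted series
#'
#' Computes the four agreement statistics used throughout the package, all
#' with the population (1/n) variance convention:
#' \describe{
#'   \item{r2}{`1 - SSE/SST` -- identical in form to the Nash-Sutcliffe
#'     efficiency and, on validation data, deliberately different from the
#'     squared Pearson correlation (reported separately as `r2_pearson`).}
#'   \item{nrmse}{`RMSE / mean(obs) * 100` (percent).}
#'   \item{nse}{Nash-Sutcliffe efficiency; computed independently and
#'     asserted identical to `r2` on every report.}
#'   \item{ccc}{Lin's concordance correlation coefficient
#'     `2 r s_y s_yhat / (s_y^2 + s_yhat^2 + (mean(y) - mean(yhat))^2)`,
#'     penalizing both imprecision and bias.}
#' }
#'
#' @param obs,pred Equal-length numeric vectors (length >= 2, finite).
#' @param tag Optional dataset tag (e.g. `"calibration"`).
#' @param year_scope,stage_scope Optional scope labels carried in the report.
#' @return Object of class `metrics_report`.
#' @export
agreement_metrics <- function(obs, pred, tag = NULL, year_scope = NULL, stage_scope = NULL) {
  if (length(obs) != length(pred)) gy_stop("obs and pred lengths differ", "input_error")
  n <- length(obs)
  if (n < 2) gy_stop("need at least 2 paired values", "input_error")
  if (any(!is.finite(obs)) || any(!is.finite(pred))) {
    gy_stop("non-finite values in paired series", "input_error")
  }
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) gy_stop("observed series is constant: R2/NSE/CCC undefined", "undefined_metric")
  sse <- sum((obs - pred)^2)
  r2 <- 1 - sse / sst
  nse <- 1 - mean((obs - pred)^2) / mean((obs - mean(obs))^2)
  stopifnot(isTRUE(all.equal(r2, nse)))  # the two printed formulas are one identity
  if (mean(obs) == 0) gy_stop("mean(obs) = 0: NRMSE undefined", "undefined_metric")
  nrmse <- sqrt(mean((obs - pred)^2)) / mean(obs) * 100
  s2y <- mean((obs - mean(obs))^2)
  s2p <- mean((pred - mean(pred))^2)
  r <- if (s2p > 0) stats::cor(obs, pred) else 0
  ccc <- 2 * r * sqrt(s2y) * sqrt(s2p) / (s2y + s2p + (mean(obs) - mean(pred))^2)
  structure(
    list(r2 = r2, nrmse = nrmse, nse = nse, ccc = ccc, r2_pearson = r^2,
         n = n, tag = tag, year_scope = year_scope, stage_scope = stage_scope),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  hdr <- paste(c(x$tag, x$year_scope, x$stage_scope), collapse = " / ")
  if (nzchar(hdr)) cat(hdr, ": ", sep = "")
  cat(sprintf("R2 = %.3f, NRMSE = %.1f%%, NSE = %.3f, CCC = %.3f (n = %d)\n",
              x$r2, x$nrmse, x$nse, x$ccc, x$n))
  invisible(x)
}

#' Cross-year split protocol
#'
#' @param train_years,test_years Disjoint, non-empty year vectors.
#' @return Object of class `split_protocol`.
#' @export
split_protocol <- function(train_years, test_years) {
  if (length(train_years) == 0 || length(test_years) == 0) {
    gy_stop("training and validation year sets must be non-empty", "protocol_error")
  }
  if (length(intersect(train_years, test_years)) > 0) {
    gy_stop("training and validation years overlap", "protocol_error")
  }
  structure(list(train_years = train_years, test_years = test_years),
            class = "split_protocol")
}

#' Cross-year calibration/validation of the trait-based and direct models
#'
#' The held-out-season protocol: on the training years only, fit (i) the
#' stage-phase CNC random forests on field CNC vs UAV vegetation indices,
#' and the trait-based quadratic yield model on stage-pooled UAV plant
#' height + RF-estimated CNC; and (ii) the direct random-forest baseline on
#' stage-pooled vegetation indices + plant height. Both models are then
#' evaluated on the held-out years. Per-stage validation reports feed each
#' stage's traits separately through the calibrated models.
#'
#' @param protocol A [split_protocol()].
#' @param data Stage-wise table with columns `year`, `plot_id`, `stage`,
#'   the five VI columns, `ph_cm` (UAV height, cm), `cnc` (field-measured
#'   CNC, used for CNC-model training), `seed_yield`.
#' @param form Yield-model form for the trait-based branch.
#' @param per_stage Also compute per-stage validation reports?
#' @param hyper Random-forest hyperparameters shared by both RF stages.
#' @return List of class `cross_year_result`: `trait` and `direct`, each
#'   with `calibration` and `validation` [agreement_metrics()] reports
#'   (plus `per_stage` lists), the fitted objects, and the pooled
#'   calibration/validation tables.
#' @export
cross_year_validate <- function(protocol, data, form = "expanded",
                                per_stage = TRUE, hyper = default_rf_hyper()) {
  stopifnot(inherits(protocol, "split_protocol"))
  need <- c("year", "plot_id", "stage", vi_names(), "ph_cm", "cnc", "seed_yield")
  check_features(data, need, "cross-year data")
  yrs <- c(protocol$train_years, protocol$test_years)
  if (!all(yrs %in% data$year)) {
    gy_stop("data does not span all protocol years", "protocol_error")
  }
  train_rows <- data[data$year %in% protocol$train_years, , drop = FALSE]
  test_rows <- data[data$year %in% protocol$test_years, , drop = FALSE]

  # trait branch: RF CNC estimation, then the constrained quadratic
  cnc_models <- fit_cnc_models(train_rows, hyper = hyper)
  data$cnc_uav <- predict_cnc_by_stage(cnc_models, data)
  pooled <- pool_traits(data, trait_cols = c("ph_cm", "cnc_uav", "seed_yield", vi_names()))
  pooled_train <- pooled[pooled$year %in% protocol$train_years, , drop = FALSE]
  pooled_test <- pooled[pooled$year %in% protocol$test_years, , drop = FALSE]

  trait_fit <- fit_yield_model(
    data.frame(P = pooled_train$ph_cm, C = pooled_train$cnc_uav,
               yield = pooled_train$seed_yield),
    form = form
  )
  trait_cal <- agreement_metrics(
    pooled_train$seed_yield,
    predict_yield(trait_fit, data.frame(P = pooled_train$ph_cm, C = pooled_train$cnc_uav)),
    tag = "calibration", year_scope = paste(protocol$train_years, collapse = "+"))
  trait_val <- agreement_metrics(
    pooled_test$seed_yield,
    predict_yield(trait_fit, data.frame(P = pooled_test$ph_cm, C = pooled_test$cnc_uav)),
    tag = "validation", year_scope = paste(protocol$test_years, collapse = "+"))

  direct_fit <- fit_direct_model(pooled_train, hyper = hyper)
  direct_cal <- agreement_metrics(pooled_train$seed_yield,
                                  predict_direct(direct_fit, pooled_train),
                                  tag = "calibration",
                                  year_scope = paste(protocol$train_years, collapse = "+"))
  direct_val <- agreement_metrics(pooled_test$seed_yield,
                                  predict_direct(direct_fit, pooled_test),
                                  tag = "validation",
                                  year_scope = paste(protocol$test_years, collapse = "+"))

  stage_reports <- function(score) {
    if (!per_stage) return(NULL)
    out <- list()
    test_aug <- data[data$year %in% protocol$test_years, , drop = FALSE]
    for (s in unique(test_aug$stage)) {
      rows <- test_aug[test_aug$stage == s, , drop = FALSE]
      out[[s]] <- agreement_metrics(rows$seed_yield, score(rows),
                                    tag = "validation", stage_scope = s,
                                    year_scope = paste(protocol$test_years, collapse = "+"))
    }
    out
  }
  trait_stage <- stage_reports(function(rows) {
    predict_yield(trait_fit, data.frame(P = rows$ph_cm, C = rows$cnc_uav))
  })
  direct_stage <- stage_reports(function(rows) predict_direct(direct_fit, rows))

  structure(
    list(
      trait = list(calibration = trait_cal, validation = trait_val,
                   per_stage = trait_stage, fit = trait_fit, cnc_models = cnc_models),
      direct = list(calibration = direct_cal, validation = direct_val,
                    per_stage = direct_stage, fit = direct_fit),
      pooled_train = pooled_train, pooled_test = pooled_test,
      protocol = protocol
    ),
    class = "cross_year_result"
  )
}

#' @export
print.cross_year_result <- function(x, ...) {
  cat("Cross-year protocol: train",
      paste(x$protocol$train_years, collapse = "+"), "-> validate",
      paste(x$protocol$test_years, collapse = "+"), "\n")
  cat("  trait model:  "); print(x$trait$validation)
  cat("  direct model: "); print(x$direct$validation)
  invisible(x)
}
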