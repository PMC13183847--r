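#' Coupled source-sink yield model parameters
#'
#' The multiplicative source-sink response
#' `Y = (delta1 C + delta2 C^2) * (gamma1 P + gamma2 P^2) + a`, where `C` is
#' canopy N concentration (% dry mass, the source module), `P` plant height
#' (cm, the sink module) and `a` the baseline yield (kg/ha). The coefficient
#' pairs are only identified up to a common rescaling (k on the deltas,
#' 1/k on the gammas); [normalize_coupled()] fixes `gamma1 = 1`.
#'
#' @param d1,d2 Source (CNC) linear and quadratic coefficients.
#' @param g1,g2 Sink (PH) linear and quadratic coefficients.
#' @param a Intercept (kg/ha).
#' @return Object of class `coupled_params`.
#' @export
coupled_params <- function(d1, d2, g1, g2, a) {
  v <- c(d1 = d1, d2 = d2, g1 = g1, g2 = g2, a = a)
  if (any(!is.finite(v))) gy_stop("coupled parameters must be finite", "input_error")
  structure(as.list(v), class = "coupled_params")
}

#' Expanded quadratic yield model parameters
#'
#' The expanded polynomial form
#' `Y = b_p P + b_p2 P^2 + b_c C + b_c2 C^2 + b_pc P C + a` with a single
#' height-by-nitrogen interaction term. This is the form under which
#' coefficient tables and contribution rates are reported, and the default
#' form for fitting.
#'
#' @param b_p,b_p2 Plant-height linear/quadratic coefficients.
#' @param b_c,b_c2 CNC linear/quadratic coefficients.
#' @param b_pc Interaction coefficient.
#' @param a Intercept (kg/ha).
#' @return Object of class `expanded_params`.
#' @export
expanded_params <- function(b_p, b_p2, b_c, b_c2, b_pc, a) {
  v <- c(b_p = b_p, b_p2 = b_p2, b_c = b_c, b_c2 = b_c2, b_pc = b_pc, a = a)
  if (any(!is.finite(v))) gy_stop("expanded parameters must be finite", "input_error")
  structure(as.list(v), class = "expanded_params")
}

#' Evaluate the coupled source-sink model
#'
#' @param params A [coupled_params()] object.
#' @param P Plant height (cm), vectorized.
#' @param C Canopy N concentration (%), vectorized.
#' @return Predicted seed yield (kg/ha).
#' @export
predict_coupled <- function(params, P, C) {
  stopifnot(inherits(params, "coupled_params"))
  (params$d1 * C + params$d2 * C^2) * (params$g1 * P + params$g2 * P^2) + params$a
}

#' Evaluate the expanded quadratic model
#'
#' @param params An [expanded_params()] object.
#' @inheritParams predict_coupled
#' @return Predicted seed yield (kg/ha).
#' @export
predict_expanded <- function(params, P, C) {
  stopifnot(inherits(params, "expanded_params"))
  params$b_p * P + params$b_p2 * P^2 + params$b_c * C + params$b_c2 * C^2 +
    params$b_pc * P * C + params$a
}

#' Remove the coupled model's scale ambiguity
#'
#' Rescales `(d1, d2)` by `g1` and `(g1, g2)` by `1/g1` so that `g1 = 1`,
#' leaving every prediction unchanged. Requires `g1 != 0`.
#'
#' @param params A [coupled_params()] object.
#' @return Normalized [coupled_params()].
#' @export
normalize_coupled <- function(params) {
  stopifnot(inherits(params, "coupled_params"))
  k <- params$g1
  if (k == 0) gy_stop("cannot normalize: gamma1 = 0", "identifiability_error")
  coupled_params(params$d1 * k, params$d2 * k, 1, params$g2 / k, params$a)
}

#' Identifiable products of a coupled parameter set
#'
#' The four cross products `delta_i * gamma_j` (plus the intercept) are
#' invariant under the coupled model's scale ambiguity; recovery tests
#' compare these, not the raw coefficient pairs.
#'
#' @param params A [coupled_params()] object.
#' @return Named numeric vector `d1g1`, `d1g2`, `d2g1`, `d2g2`, `a`.
#' @export
coupled_products <- function(params) {
  with(params, c(d1g1 = d1 * g1, d1g2 = d1 * g2, d2g1 = d2 * g1, d2g2 = d2 * g2, a = a))
}

# Accept (P, C, yield) under either the modeling or the tabular names.
yield_frame <- function(data) {
  p <- if ("P" %in% names(data)) data$P else if ("ph" %in% names(data)) data$ph else data$ph_cm
  c_ <- if ("C" %in% names(data)) data$C else data$cnc
  y <- if ("yield" %in% names(data)) data$yield else data$seed_yield
  if (is.null(p) || is.null(c_) || is.null(y)) {
    gy_stop("need P (or ph/ph_cm), C (or cnc) and yield (or seed_yield) columns", "schema_error")
  }
  data.frame(P = p, C = c_, yield = y)
}

#' Build the yield calibration table from stage-wise traits
#'
#' Joins the stage-wise trait table to the per-plot final yields under one
#' of two conventions: `pool = "mean"` (default) averages the stages into a
#' single plot-level trait pair, one calibration row per plot -- the same
#' predictor convention used by the yield generator; `pool = "stack"` keeps
#' one row per stage, each paired with the plot's final yield (the
#' stage-stacked alternative).
#'
#' @param traits Stage-wise trait rows (`year`, `plot_id`, `stage`, PH and
#'   CNC columns). UAV tables may carry `ph_cm`/`cnc`; field tables `ph`.
#' @param yields Per-plot yield records (`year`, `plot_id`, `seed_yield`).
#' @param pool `"mean"` or `"stack"`.
#' @return Data frame with `year`, `plot_id`, (`n_rate`, `block` if
#'   present), `P`, `C`, `yield`.
#' @export
calibration_table <- function(traits, yields, pool = c("mean", "stack")) {
  pool <- match.arg(pool)
  ph_col <- intersect(c("ph", "ph_cm"), names(traits))[1]
  if (is.na(ph_col) || !"cnc" %in% names(traits)) {
    gy_stop("traits need a plant-height (ph or ph_cm) and a cnc column", "schema_error")
  }
  tt <- traits
  tt$P <- tt[[ph_col]]; tt$C <- tt$cnc
  if (pool == "mean") {
    tt <- pool_traits(tt, trait_cols = c("P", "C"))
  }
  m <- merge(tt, yields[, c("year", "plot_id", "seed_yield")], by = c("year", "plot_id"))
  m$yield <- m$seed_yield
  keep <- intersect(c("year", "plot_id", "block", "n_rate", "stage", "P", "C", "yield"),
                    names(m))
  m[order(m$year, m$plot_id), keep, drop = FALSE]
}

#' Fit the yield response model
#'
#' Least-squares calibration of the yield response surface on plot-level
#' trait pairs. The expanded form is fitted by ordinary least squares on
#' the five regressors plus intercept; the coupled (multiplicative) form by
#' Levenberg-Marquardt nonlinear least squares under the `gamma1 = 1`
#' normalization, initialized from an OLS fit of the four separable product
#' terms and restarted from seeded jitters if it fails to converge.
#'
#' @param data Rows with columns `P`, `C`, `yield` (aliases `ph`/`ph_cm`,
#'   `cnc`, `seed_yield` accepted), e.g. from [calibration_table()].
#' @param form `"expanded"` (default) or `"coupled"`.
#' @return Object of class `yield_fit`: `params` ([expanded_params()] or
#'   normalized [coupled_params()]), `form`, and `fit` (training R-squared
#'   as 1 - SSE/SST, NRMSE %, n, residual SD).
#' @export
fit_yield_model <- function(data, form = c("expanded", "coupled")) {
  form <- match.arg(form)
  d <- yield_frame(data)
  if (any(!is.finite(as.matrix(d)))) gy_stop("non-finite values in calibration data", "input_error")
  if (nrow(d) < 10) gy_stop(sprintf("need >= 10 calibration rows, got %d", nrow(d)), "input_error")
  if (stats::sd(d$P) == 0 || stats::sd(d$C) == 0) {
    gy_stop("no variation in P or C: surface not identifiable", "identifiability_error")
  }
  if (form == "expanded") {
    fit <- stats::lm(yield ~ P + I(P^2) + C + I(C^2) + I(P * C), data = d)
    if (fit$rank < 6) {
      gy_stop("rank-deficient design: expanded surface not identifiable", "identifiability_error")
    }
    cf <- stats::coef(fit)
    params <- expanded_params(b_p = cf[["P"]], b_p2 = cf[["I(P^2)"]],
                              b_c = cf[["C"]], b_c2 = cf[["I(C^2)"]],
                              b_pc = cf[["I(P * C)"]], a = cf[["(Intercept)"]])
    pred <- unname(stats::fitted(fit))
  } else {
    params <- fit_coupled_nls(d)
    pred <- predict_coupled(params, d$P, d$C)
  }
  res <- d$yield - pred
  sst <- sum((d$yield - mean(d$yield))^2)
  structure(
    list(params = params, form = form,
         fit = list(r2 = 1 - sum(res^2) / sst,
                    nrmse = sqrt(mean(res^2)) / mean(d$yield) * 100,
                    n = nrow(d), sigma = stats::sd(res))),
    class = "yield_fit"
  )
}

# Coupled fit: Y = (d1 C + d2 C^2)(P + g2 P^2) + a with gamma1 fixed at 1.
fit_coupled_nls <- function(d) {
  # OLS on the four product regressors gives the separable starting point
  ols <- stats::lm(yield ~ I(C * P) + I(C * P^2) + I(C^2 * P) + I(C^2 * P^2), data = d)
  cf <- stats::coef(ols)
  d1_0 <- cf[["I(C * P)"]]; d2_0 <- cf[["I(C^2 * P)"]]
  g2_cands <- c(cf[["I(C * P^2)"]] / d1_0, cf[["I(C^2 * P^2)"]] / d2_0)
  g2_0 <- mean(g2_cands[is.finite(g2_cands)])
  if (!is.finite(g2_0)) g2_0 <- 0
  starts <- list(c(d1 = d1_0, d2 = d2_0, g2 = g2_0, a = cf[["(Intercept)"]]))
  jitters <- with_seed(1402, lapply(1:5, function(i) {
    s <- starts[[1]]
    s * stats::runif(4, 0.5, 1.5) + c(0, 0, 0, stats::rnorm(1, 0, abs(s[["a"]]) * 0.1 + 1))
  }))
  last_err <- NULL
  for (s in c(starts, jitters)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        yield ~ (d1 * C + d2 * C^2) * (P + g2 * P^2) + a,
        data = d, start = as.list(s),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
    if (!inherits(fit, "error")) {
      cf <- stats::coef(fit)
      return(coupled_params(d1 = cf[["d1"]], d2 = cf[["d2"]], g1 = 1,
                            g2 = cf[["g2"]], a = cf[["a"]]))
    }
    last_err <- fit
  }
  gy_stop(paste("coupled fit failed to converge from all starts:",
                conditionMessage(last_err)), "fit_failure")
}

#' Predict from a fitted yield model
#'
#' @param fit A [fit_yield_model()] object.
#' @param data Rows with `P` and `C` (aliases accepted).
#' @return Predicted yields (kg/ha).
#' @export
predict_yield <- function(fit, data) {
  stopifnot(inherits(fit, "yield_fit"))
  nm <- names(data)
  p <- if ("P" %in% nm) data$P else if ("ph" %in% nm) data$ph else data$ph_cm
  c_ <- if ("C" %in% nm) data$C else data$cnc
  if (is.null(p) || is.null(c_)) gy_stop("need P and C columns to predict", "schema_error")
  if (fit$form == "expanded") predict_expanded(fit$params, p, c_)
  else predict_coupled(fit$params, p, c_)
}

# Explained sum of squares of the OLS fit of y on an (optional) subset of
# the five surface regressors. Used by the grouped-LMG decomposition.
subset_ssr <- function(X, y, cols) {
  if (length(cols) == 0) return(0)
  fit <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
  sst <- sum((y - mean(y))^2)
  sse <- sum(fit$residuals^2)
  sst - sse
}

#' Grouped hierarchical (LMG) contribution partitioning
#'
#' Decomposes the variance explained by the fitted expanded surface over
#' the three term groups -- plant height `{P, P^2}`, nitrogen `{C, C^2}`
#' and the interaction `{P C}` -- by averaging the sequential
#' explained-sum-of-squares increments over all group orderings (the
#' grouped LMG / Shapley decomposition). Shares are normalized to sum to
#' 100%; the interaction's effect direction is reported from the sign of
#' the fitted `b_pc`.
#'
#' @param fit A [fit_yield_model()] fit of form `"expanded"`.
#' @param data The training rows the surface was fitted on.
#' @param method Method tag; only `"lmg-grouped"` is implemented.
#' @return Object of class `contribution_report`: `share_ph`, `share_cnc`,
#'   `share_interaction` (percent, summing to 100), `interaction_sign`,
#'   `method`.
#' @export
contribution_rates <- function(fit, data, method = "lmg-grouped") {
  stopifnot(inherits(fit, "yield_fit"))
  if (fit$form != "expanded") {
    gy_stop("contribution partitioning is defined for the expanded form", "input_error")
  }
  if (!identical(method, "lmg-grouped")) {
    gy_stop(paste("unknown contribution method:", method), "input_error")
  }
  d <- yield_frame(data)
  X <- cbind(P = d$P, P2 = d$P^2, C = d$C, C2 = d$C^2, PC = d$P * d$C)
  groups <- list(ph = c("P", "P2"), cnc = c("C", "C2"), interaction = "PC")
  m <- length(groups)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  names(subsets) <- names(groups)
  ssr_cache <- apply(subsets, 1, function(incl) {
    subset_ssr(X, d$yield, unlist(groups[incl], use.names = FALSE))
  })
  key <- function(incl) sum(2^(which(incl) - 1)) + 1
  # Shapley value over the 3 groups from the 8 cached subset SSRs
  shap <- vapply(seq_len(m), function(g) {
    others <- setdiff(seq_len(m), g)
    total <- 0
    for (r in 0:length(others)) {
      combos <- if (r == 0) list(integer(0)) else
        utils::combn(others, r, simplify = FALSE)
      w <- factorial(r) * factorial(m - r - 1) / factorial(m)
      for (s in combos) {
        incl_s <- seq_len(m) %in% s
        incl_sg <- seq_len(m) %in% c(s, g)
        total <- total + w * (ssr_cache[key(incl_sg)] - ssr_cache[key(incl_s)])
      }
    }
    total
  }, 0)
  tot <- sum(shap)
  shares <- if (tot > 0) 100 * shap / tot else rep(100 / m, m)
  stopifnot(abs(sum(shares) - 100) < 0.1)
  structure(
    list(share_ph = shares[1], share_cnc = shares[2], share_interaction = shares[3],
         interaction_sign = sign(fit$params$b_pc), method = method),
    class = "contribution_report"
  )
}

#' @export
print.contribution_report <- function(x, ...) {
  cat(sprintf("Contribution shares (%s): PH %.1f%%, CNC %.1f%%, PHxCNC %.1f%% (interaction %s)\n",
              x$method, x$share_ph, x$share_cnc, x$share_interaction,
              if (x$interaction_sign < 0) "negative" else if (x$interaction_sign > 0) "positive" else "zero"))
  invisible(x)
}

#' Yield response surface and stationary-point report
#'
#' Evaluates the fitted surface on a (P, C) grid and characterizes its
#' stationary point in closed form: for the expanded form the solution of
#' the 2x2 gradient system with Hessian eigenvalue classification
#' (maximum / minimum / saddle); for the coupled form the interior critical
#' point `(-gamma1 / 2 gamma2, -delta1 / 2 delta2)`. Also reports, per C
#' slice, the grid P maximizing yield.
#'
#' @param params [expanded_params()] or [coupled_params()].
#' @param p_grid,c_grid Grid vectors for P (cm) and C (%).
#' @return List: `surface` (matrix, P rows x C columns), `p_grid`, `c_grid`,
#'   `stationary` (list `P`, `C`, `value`, `class`; NULL if none), and
#'   `slice_argmax` (data frame `C`, `P_opt`, `value`).
#' @export
response_surface <- function(params,
                             p_grid = seq(1, 40, length.out = 101),
                             c_grid = seq(0.1, 3, length.out = 101)) {
  predict_fun <- if (inherits(params, "expanded_params")) predict_expanded else predict_coupled
  surface <- outer(p_grid, c_grid, function(p, c) predict_fun(params, p, c))
  stationary <- NULL
  if (inherits(params, "expanded_params")) {
    H <- matrix(c(2 * params$b_p2, params$b_pc, params$b_pc, 2 * params$b_c2), 2, 2)
    if (abs(det(H)) > 1e-12) {
      sol <- solve(H, -c(params$b_p, params$b_c))
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      cls <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum" else "saddle"
      stationary <- list(P = sol[1], C = sol[2],
                         value = predict_expanded(params, sol[1], sol[2]), class = cls)
    }
  } else {
    if (params$g2 != 0 && params$d2 != 0) {
      p0 <- -params$g1 / (2 * params$g2)
      c0 <- -params$d1 / (2 * params$d2)
      yn <- params$d1 * c0 + params$d2 * c0^2
      yp <- params$g1 * p0 + params$g2 * p0^2
      ev <- c(2 * params$g2 * yn, 2 * params$d2 * yp)
      cls <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum" else "saddle"
      stationary <- list(P = p0, C = c0,
                         value = predict_coupled(params, p0, c0), class = cls)
    }
  }
  idx <- apply(surface, 2, which.max)
  slice_argmax <- data.frame(C = c_grid, P_opt = p_grid[idx],
                             value = surface[cbind(idx, seq_along(c_grid))])
  list(surface = surface, p_grid = p_grid, c_grid = c_grid,
       stationary = stationary, slice_argmax = slice_argmax)
}

#' Direct spectral yield baseline (random forest on VIs + PH)
#'
#' The conventional direct model: a random forest mapping the five plot-mean
#' vegetation indices plus UAV plant height straight to seed yield, with the
#' same compact hyperparameters as the CNC estimator.
#'
#' @param data Rows with `NDVI`, `NDRE`, `EVI`, `GNDVI`, `SAVI`, `ph_cm`
#'   and a `seed_yield` (or `yield`) target.
#' @param hyper Hyperparameter list (see [fit_cnc()]).
#' @return Object of class `direct_model`.
#' @export
fit_direct_model <- function(data, hyper = default_rf_hyper()) {
  features <- c(vi_names(), "ph_cm")
  check_features(data, features, "direct-model training data")
  y <- if ("seed_yield" %in% names(data)) data$seed_yield else data$yield
  if (is.null(y)) gy_stop("direct-model training data needs a yield column", "schema_error")
  if (nrow(data) < 10) gy_stop("need >= 10 training rows", "input_error")
  forest <- fit_rf(data[, features, drop = FALSE], y, hyper)
  structure(list(forest = forest, features = features, hyper = hyper,
                 target_range = range(y), n_train = nrow(data)),
            class = "direct_model")
}

#' @rdname fit_direct_model
#' @param model A fitted `direct_model`.
#' @param rows Rows carrying the six feature columns.
#' @return `predict_direct`: numeric vector of yield predictions (kg/ha).
#' @export
predict_direct <- function(model, rows) {
  stopifnot(inherits(model, "direct_model"))
  check_features(rows, model$features, "prediction data")
  stats::predict(model$forest, data = rows[, model$features, drop = FALSE],
                 num.threads = 1)$predictions
}

#' Per-pixel yield map from trait rasters
#'
#' Evaluates the trait-based yield model on aligned plant-height and CNC
#' rasters over the vegetation mask; non-vegetation pixels are missing in
#' the output. Heights are supplied in metres (raster convention) and
#' converted to cm (model convention) internally.
#'
#' @param params [expanded_params()] or [coupled_params()] (or a
#'   [fit_yield_model()] object, whose params are used).
#' @param ph_raster Plant-height [gy_raster()] in metres.
#' @param cnc_raster CNC [gy_raster()] (%), per pixel or constant per plot.
#' @param mask A `veg_mask` (or logical matrix).
#' @return A [gy_raster()] of predicted yield (kg/ha).
#' @export
predict_yield_map <- function(params, ph_raster, cnc_raster, mask) {
  if (inherits(params, "yield_fit")) params <- params$params
  if (!grids_equal(ph_raster, cnc_raster)) {
    gy_stop("PH and CNC rasters are not aligned", "alignment_error")
  }
  m <- if (inherits(mask, "veg_mask")) mask$mask else mask
  if (!identical(dim(m), dim(ph_raster$values))) {
    gy_stop("mask shape does not match the trait rasters", "alignment_error")
  }
  predict_fun <- if (inherits(params, "expanded_params")) predict_expanded else predict_coupled
  out <- matrix(NA_real_, nrow(m), ncol(m))
  sel <- which(m)
  out[sel] <- predict_fun(params, 100 * ph_raster$values[sel], cnc_raster$values[sel])
  gy_raster(out, px = ph_raster$px, xmin = ph_raster$xmin,
            ymin = ph_raster$ymin, crs = ph_raster$crs)
}
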