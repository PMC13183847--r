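#' One-way ANOVA with Fisher's protected LSD letter groups
#'
#' Protected procedure: the one-way ANOVA F test gates the pairwise
#' comparisons. If the F test is not significant at `alpha`, all groups
#' share a single letter; otherwise every pair is compared by the LSD
#' t test on the pooled error mean square, and compact letter groups are
#' assigned (insert-and-absorb algorithm, groups ordered by decreasing
#' mean, so "a" marks the highest-yielding group).
#'
#' @param y Response values (e.g. plot seed yields).
#' @param group Treatment labels (coerced to factor; >= 2 levels, each with
#'   >= 2 replicates).
#' @param alpha Significance level for both the F gate and the pairwise
#'   comparisons.
#' @return Data frame `group`, `n`, `mean`, `letters` (ordered by
#'   decreasing mean), with attributes `f_pvalue`, `mse`, `df_error`,
#'   `alpha`.
#' @export
anova_lsd <- function(y, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2) gy_stop("need at least 2 treatment groups", "input_error")
  cnt <- table(group)
  if (any(cnt < 2)) {
    gy_stop(paste("group(s) with < 2 replicates:",
                  paste(names(cnt)[cnt < 2], collapse = ", ")), "input_error")
  }
  if (any(!is.finite(y))) gy_stop("non-finite response values", "input_error")
  fit <- stats::aov(y ~ group)
  tab <- summary(fit)[[1]]
  pval <- tab[["Pr(>F)"]][1]
  mse <- tab[["Mean Sq"]][2]
  dfe <- tab[["Df"]][2]

  means <- tapply(y, group, mean)
  ord <- order(means, decreasing = TRUE)
  lev <- levels(group)[ord]
  mns <- as.numeric(means[ord])
  ns <- as.integer(cnt[ord])
  k <- length(lev)

  if (pval >= alpha || !is.finite(pval)) {
    letters <- rep("a", k)
  } else {
    # significance matrix in mean-descending order
    sig <- matrix(FALSE, k, k)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
        tstat <- abs(mns[i] - mns[j]) / se
        sig[i, j] <- sig[j, i] <- 2 * stats::pt(tstat, dfe, lower.tail = FALSE) < alpha
      }
    }
    letters <- compact_letters(sig)
  }
  out <- data.frame(group = lev, n = ns, mean = mns, letters = letters,
                    stringsAsFactors = FALSE)
  attr(out, "f_pvalue") <- pval
  attr(out, "mse") <- mse
  attr(out, "df_error") <- dfe
  attr(out, "alpha") <- alpha
  out
}

# Insert-and-absorb compact letter display. `sig` is a symmetric logical
# matrix (TRUE = the pair differs) with rows/cols in display order.
compact_letters <- function(sig) {
  k <- nrow(sig)
  cols <- list(rep(TRUE, k))  # start with one letter containing everyone
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          # split the offending column into two, dropping one member each
          c1 <- col; c1[j] <- FALSE
          c2 <- col; c2[i] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1]] <- c2
        }
      }
      # absorb columns that are subsets of another
      drop <- rep(FALSE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && !drop[a] && !drop[b] && all(cols[[a]] <= cols[[b]])) drop[a] <- TRUE
        }
      }
      cols <- cols[!drop]
    }
  }
  # order letters by first member so "a" is the top mean
  first <- vapply(cols, function(cl) which(cl)[1], 0L)
  cols <- cols[order(first)]
  vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, `[`, TRUE, i))], collapse = "")
  }, "")
}

#' Collect a pipeline run into a report
#'
#' Assembles the artifacts of a complete run -- design, fitted parameters,
#' contribution shares, calibration/validation metric tables, LSD letters
#' and optional map file paths -- into a deterministic human-readable
#' Markdown summary plus a machine-readable JSON results file.
#'
#' @param run Named list with components `design` ([make_design()]),
#'   `fit` ([fit_yield_model()]), `contributions` ([contribution_rates()]),
#'   `metrics` (a [cross_year_validate()] result), and optionally
#'   `lsd` ([anova_lsd()]) and `map_paths` (character).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of `report.md` and `results.json`.
#' @export
run_report <- function(run, dir) {
  need <- c("design", "fit", "contributions", "metrics")
  missing <- setdiff(need, names(run))
  if (length(missing) > 0) {
    gy_stop(paste("run is missing artifact(s):", paste(missing, collapse = ", ")),
            "incomplete_input")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  met <- function(m) sprintf("R2 = %.4f, NRMSE = %.2f%%, NSE = %.4f, CCC = %.4f (n = %d)",
                             m$r2, m$nrmse, m$nse, m$ccc, m$n)
  par_line <- paste(vapply(names(run$fit$params), function(nm) {
    sprintf("%s = %.6g", nm, run$fit$params[[nm]])
  }, ""), collapse = ", ")
  lines <- c(
    "# Seed-yield trait model run report", "",
    sprintf("Design: %d year(s) x %d N rates x %d blocks (%d plots)",
            length(run$design$years), length(run$design$n_rates),
            run$design$n_blocks, nrow(run$design$plots)),
    sprintf("N rates (kg/ha): %s", paste(run$design$n_rates, collapse = ", ")), "",
    sprintf("## Fitted %s yield model", run$fit$form),
    par_line,
    sprintf("Calibration fit: R2 = %.4f, NRMSE = %.2f%% (n = %d)",
            run$fit$fit$r2, run$fit$fit$nrmse, run$fit$fit$n), "",
    "## Contribution shares (grouped LMG)",
    sprintf("PH %.1f%% | CNC %.1f%% | PH x CNC %.1f%% (interaction sign %+d)",
            run$contributions$share_ph, run$contributions$share_cnc,
            run$contributions$share_interaction, run$contributions$interaction_sign), "",
    "## Cross-year metrics",
    paste("Trait model, calibration: ", met(run$metrics$trait$calibration)),
    paste("Trait model, validation:  ", met(run$metrics$trait$validation)),
    paste("Direct model, calibration:", met(run$metrics$direct$calibration)),
    paste("Direct model, validation: ", met(run$metrics$direct$validation))
  )
  if (!is.null(run$lsd)) {
    lines <- c(lines, "", "## Treatment separation (protected LSD)",
               sprintf("%-8s n=%d  mean=%.1f  %s", run$lsd$group, run$lsd$n,
                       run$lsd$mean, run$lsd$letters))
  }
  if (!is.null(run$map_paths)) {
    lines <- c(lines, "", "## Yield maps", run$map_paths)
  }
  md <- file.path(dir, "report.md")
  writeLines(lines, md)
  js <- file.path(dir, "results.json")
  payload <- list(
    design = list(years = run$design$years, n_rates = run$design$n_rates,
                  n_blocks = run$design$n_blocks),
    params = run$fit$params[],
    form = run$fit$form,
    contributions = list(share_ph = run$contributions$share_ph,
                         share_cnc = run$contributions$share_cnc,
                         share_interaction = run$contributions$share_interaction),
    metrics = list(
      trait = list(calibration = unclass(run$metrics$trait$calibration)[c("r2", "nrmse", "nse", "ccc", "n")],
                   validation = unclass(run$metrics$trait$validation)[c("r2", "nrmse", "nse", "ccc", "n")]),
      direct = list(calibration = unclass(run$metrics$direct$calibration)[c("r2", "nrmse", "nse", "ccc", "n")],
                    validation = unclass(run$metrics$direct$validation)[c("r2", "nrmse", "nse", "ccc", "n")])
    ),
    lsd = if (!is.null(run$lsd)) run$lsd else NULL,
    map_paths = run$map_paths
  )
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(report = md, results = js))
}
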