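#' Phenological stage labels
#'
#' The four flight/sampling stages, in developmental order. Tillering and
#' jointing form the vegetative phase, heading and filling the reproductive
#' phase (see [stage_phase()]).
#'
#' @return Character vector of the four ordered stage labels.
#' @export
stage_labels <- function() c("tillering", "jointing", "heading", "filling")

#' Build a randomized complete block N-rate trial design
#'
#' Lays out a randomized complete block design (RCBD): within each year and
#' block, every nitrogen rate occurs exactly once, in a seeded random order.
#' The default trial geometry mirrors a seven-rate, three-block turfgrass
#' seed-production experiment (21 plots per year).
#'
#' @param years Integer vector of year labels (e.g. `2022:2024`).
#' @param n_rates Numeric vector of distinct N application rates (kg N/ha).
#' @param n_blocks Number of complete blocks (replicates) per year.
#' @param seed Integer seed controlling the within-block randomization.
#' @return An object of class `field_design`: a list with `years`, `n_rates`,
#'   `n_blocks`, `stages`, and a `plots` data frame with columns `year`,
#'   `plot_id`, `block`, `n_rate`.
#' @examples
#' d <- make_design(2022:2024, c(0, 60, 90, 120, 150, 180, 210), 3, seed = 1)
#' nrow(d$plots)  # 63
#' @export
make_design <- function(years = 2022:2024,
                        n_rates = c(0, 60, 90, 120, 150, 180, 210),
                        n_blocks = 3,
                        seed = 1) {
  if (length(n_rates) == 0) gy_stop("n_rates must be non-empty", "invalid_design")
  if (anyDuplicated(n_rates)) gy_stop("n_rates must be distinct", "invalid_design")
  if (length(years) == 0 || anyDuplicated(years)) {
    gy_stop("years must be non-empty and distinct", "invalid_design")
  }
  if (n_blocks < 1) gy_stop("n_blocks must be >= 1", "invalid_design")

  plots <- with_seed(seed, {
    do.call(rbind, lapply(years, function(yr) {
      do.call(rbind, lapply(seq_len(n_blocks), function(b) {
        rates <- n_rates[sample.int(length(n_rates))]
        data.frame(
          year = yr,
          plot_id = sprintf("B%d-%02d", b, seq_along(rates)),
          block = b,
          n_rate = rates,
          stringsAsFactors = FALSE
        )
      }))
    }))
  })
  rownames(plots) <- NULL
  structure(
    list(years = years, n_rates = sort(n_rates), n_blocks = n_blocks,
         stages = stage_labels(), plots = plots, seed = seed),
    class = "field_design"
  )
}

#' @export
print.field_design <- function(x, ...) {
  cat("RCBD field design:", length(x$years), "year(s) x",
      length(x$n_rates), "N rates x", x$n_blocks, "blocks =",
      nrow(x$plots), "plots\n")
  cat("  years:", paste(x$years, collapse = ", "), "\n")
  cat("  N rates (kg/ha):", paste(x$n_rates, collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth parameters for the synthetic field trial
#'
#' Bundles the trait-trajectory and yield-generation parameters used by
#' [simulate_traits()] and [simulate_yield()]. Plant height follows a
#' saturating (Michaelis-Menten) response to N scaled by a stage asymptote;
#' canopy N concentration follows a saturating N response damped by a
#' multiplicative stage-decline factor, so expected PH rises and expected CNC
#' falls over the season while both increase with N. Year effects are
#' multiplicative gains per year; block effects are seeded multiplicative
#' gains per (year, block) representing field heterogeneity in an RCBD.
#'
#' Defaults emulate a low-canopy turfgrass seed crop: PH asymptotes of
#' 8/14/22/26 cm across stages, CNC between roughly 0.5 and 1.8 percent dry
#' mass, and a yield surface with an interior optimum (near PH 14 cm and
#' CNC 1.1 percent) whose decline past the optimum is driven largely by the
#' negative height-by-nitrogen interaction, so the highest N rates overshoot
#' it (the over-fertilization penalty). Plot-level microsite gains represent
#' within-treatment field heterogeneity beyond the block effects; plant
#' height varies more plot-to-plot than tissue N, hence the asymmetric
#' defaults.
#'
#' @param ph_asym Named stage vector of PH asymptotes (cm).
#' @param ph_n_half Half-saturation N rate for PH (kg N/ha).
#' @param ph_n_floor Fraction of the asymptote reached at N = 0.
#' @param ph_year_gain Multiplicative PH year effects, matched to design
#'   years by position.
#' @param ph_block_sd SD of log-normal per-(year, block) PH gains.
#' @param ph_plot_sd SD of log-normal per-(year, plot) PH microsite gains.
#' @param ph_noise_sd Observation noise SD for PH (cm).
#' @param cnc_base Baseline CNC (%) at N = 0 before stage decline.
#' @param cnc_n_max Maximum additional CNC (%) at saturating N.
#' @param cnc_n_half Half-saturation N rate for CNC (kg N/ha).
#' @param cnc_stage_decline Named stage vector of multiplicative decline
#'   factors (1 at tillering, decreasing).
#' @param cnc_year_gain,cnc_block_sd,cnc_plot_sd,cnc_noise_sd CNC analogues
#'   of the PH year/block/plot/noise parameters (noise in % dry mass).
#' @param yield [expanded_params()] used generatively for plot seed yield.
#' @param yield_noise_frac Yield noise SD as a fraction of the mean
#'   model-implied yield.
#' @param seed Default seed carried with the parameter set.
#' @return Object of class `truth_params`.
#' @export
truth_params <- function(ph_asym = c(tillering = 8, jointing = 14, heading = 22, filling = 26),
                         ph_n_half = 90,
                         ph_n_floor = 0.4,
                         ph_year_gain = c(1.00, 0.92, 1.06),
                         ph_block_sd = 0.08,
                         ph_plot_sd = 0.15,
                         ph_noise_sd = 1,
                         cnc_base = 0.6,
                         cnc_n_max = 1.6,
                         cnc_n_half = 80,
                         cnc_stage_decline = c(tillering = 1, jointing = 0.9, heading = 0.75, filling = 0.6),
                         cnc_year_gain = c(1.00, 1.05, 0.94),
                         cnc_block_sd = 0.08,
                         cnc_plot_sd = 0.08,
                         cnc_noise_sd = 0.05,
                         yield = expanded_params(b_p = 193, b_p2 = -6, b_c = 1740,
                                                 b_c2 = -450, b_pc = -60, a = -1350),
                         yield_noise_frac = 0.05,
                         seed = 1) {
  sds <- c(ph_block_sd, ph_plot_sd, ph_noise_sd, cnc_block_sd, cnc_plot_sd,
           cnc_noise_sd, yield_noise_frac)
  if (any(sds < 0)) gy_stop("noise sds must be >= 0", "invalid_design")
  stopifnot(all(stage_labels() %in% names(ph_asym)),
            all(stage_labels() %in% names(cnc_stage_decline)))
  structure(
    list(ph_asym = ph_asym, ph_n_half = ph_n_half, ph_n_floor = ph_n_floor,
         ph_year_gain = ph_year_gain, ph_block_sd = ph_block_sd,
         ph_plot_sd = ph_plot_sd, ph_noise_sd = ph_noise_sd,
         cnc_base = cnc_base, cnc_n_max = cnc_n_max, cnc_n_half = cnc_n_half,
         cnc_stage_decline = cnc_stage_decline, cnc_year_gain = cnc_year_gain,
         cnc_block_sd = cnc_block_sd, cnc_plot_sd = cnc_plot_sd,
         cnc_noise_sd = cnc_noise_sd,
         yield = yield, yield_noise_frac = yield_noise_frac, seed = seed),
    class = "truth_params"
  )
}

year_gain <- function(gains, years, year) {
  i <- match(year, years)
  g <- rep_len(gains, length(years))
  g[i]
}

#' Closed-form expected plant height
#'
#' The noise- and block-free expectation of simulated PH, used as the
#' independent oracle for generator tests.
#'
#' @param truth A [truth_params()] object.
#' @param stage Stage label(s).
#' @param n_rate N rate(s) (kg N/ha).
#' @param year,years Year label and the design's year vector (for the year
#'   gain); defaults give a gain of the first year.
#' @return Expected PH in cm.
#' @export
expected_ph <- function(truth, stage, n_rate, year = NULL, years = NULL) {
  g <- if (is.null(year)) 1 else year_gain(truth$ph_year_gain, years, year)
  sat <- truth$ph_n_floor + (1 - truth$ph_n_floor) * n_rate / (n_rate + truth$ph_n_half)
  unname(truth$ph_asym[stage] * sat * g)
}

#' Closed-form expected canopy N concentration
#'
#' @inheritParams expected_ph
#' @return Expected CNC in percent dry mass.
#' @export
expected_cnc <- function(truth, stage, n_rate, year = NULL, years = NULL) {
  g <- if (is.null(year)) 1 else year_gain(truth$cnc_year_gain, years, year)
  level <- truth$cnc_base + truth$cnc_n_max * n_rate / (n_rate + truth$cnc_n_half)
  unname(level * truth$cnc_stage_decline[stage] * g)
}

block_gains <- function(design, sd) {
  key <- unique(design$plots[, c("year", "block")])
  key$gain <- exp(stats::rnorm(nrow(key), 0, sd))
  key
}

#' Simulate stage-wise trait observations for a field design
#'
#' Draws one (PH, CNC) observation per (year, plot, stage): the closed-form
#' expectations of [expected_ph()] / [expected_cnc()], scaled by the seeded
#' per-(year, block) gains, plus independent Gaussian observation noise.
#' Values are clamped to physically admissible ranges (PH in (0, 60] cm,
#' CNC in (0, 5] %).
#'
#' @param design A [make_design()] object.
#' @param truth A [truth_params()] object.
#' @param seed Integer seed (defaults to `truth$seed`).
#' @return Data frame with columns `year`, `plot_id`, `block`, `n_rate`,
#'   `stage`, `ph` (cm), `cnc` (%), `provenance` (`"field"`).
#' @export
simulate_traits <- function(design, truth = truth_params(), seed = truth$seed) {
  stopifnot(inherits(design, "field_design"), inherits(truth, "truth_params"))
  with_seed(seed, {
    gph <- block_gains(design, truth$ph_block_sd)
    gcn <- block_gains(design, truth$cnc_block_sd)
    pkey <- design$plots[, c("year", "plot_id")]
    pkey$gain_ph_plot <- exp(stats::rnorm(nrow(pkey), 0, truth$ph_plot_sd))
    pkey$gain_cnc_plot <- exp(stats::rnorm(nrow(pkey), 0, truth$cnc_plot_sd))
    rows <- merge(design$plots,
                  data.frame(stage = design$stages, stringsAsFactors = FALSE))
    # fixed ordering so the noise draws are reproducible
    rows <- rows[order(rows$year, rows$block, rows$plot_id,
                       match(rows$stage, design$stages)), ]
    rows$gain_ph <- gph$gain[match(paste(rows$year, rows$block),
                                   paste(gph$year, gph$block))]
    rows$gain_cnc <- gcn$gain[match(paste(rows$year, rows$block),
                                    paste(gcn$year, gcn$block))]
    ip <- match(paste(rows$year, rows$plot_id), paste(pkey$year, pkey$plot_id))
    rows$gain_ph <- rows$gain_ph * pkey$gain_ph_plot[ip]
    rows$gain_cnc <- rows$gain_cnc * pkey$gain_cnc_plot[ip]
    n <- nrow(rows)
    eph <- expected_ph(truth, rows$stage, rows$n_rate) *
      vapply(rows$year, function(y) year_gain(truth$ph_year_gain, design$years, y), 0)
    ecn <- expected_cnc(truth, rows$stage, rows$n_rate) *
      vapply(rows$year, function(y) year_gain(truth$cnc_year_gain, design$years, y), 0)
    rows$ph <- clamp(eph * rows$gain_ph + stats::rnorm(n, 0, truth$ph_noise_sd), 0.01, 60)
    rows$cnc <- clamp(ecn * rows$gain_cnc + stats::rnorm(n, 0, truth$cnc_noise_sd), 0.01, 5)
    rows$provenance <- "field"
    rows$gain_ph <- rows$gain_cnc <- NULL
    rownames(rows) <- NULL
    rows
  })
}

#' Pool stage-wise traits to one row per plot
#'
#' Averages the four stage observations of each (year, plot) into a single
#' plot-level trait pair -- the predictor convention used both by the yield
#' generator and by the default model calibration. Any vegetation-index
#' columns present are pooled the same way.
#'
#' @param traits Data frame of stage-wise rows (from [simulate_traits()] or
#'   the imagery pipeline).
#' @param trait_cols Columns to average; defaults to every numeric column
#'   except design metadata.
#' @return One row per (year, plot) with pooled trait means.
#' @export
pool_traits <- function(traits, trait_cols = NULL) {
  meta <- c("year", "plot_id", "block", "n_rate")
  if (is.null(trait_cols)) {
    num <- vapply(traits, is.numeric, TRUE)
    trait_cols <- setdiff(names(traits)[num], meta)
  }
  agg <- stats::aggregate(traits[trait_cols],
                          by = traits[c("year", "plot_id")], FUN = mean)
  keep <- intersect(meta, names(traits))
  first <- traits[!duplicated(traits[c("year", "plot_id")]), keep, drop = FALSE]
  out <- merge(first, agg, by = c("year", "plot_id"))
  out[order(out$year, out$plot_id), , drop = FALSE]
}

#' Simulate final plot seed yield from a known response surface
#'
#' Evaluates the ground-truth expanded quadratic yield model on each plot's
#' stage-pooled (mean over stages) observed trait pair, adds Gaussian noise
#' with SD equal to `yield_noise_frac` times the mean model yield, and floors
#' at zero. With zero noise the returned yields equal the model evaluation
#' exactly, so the generator and the fitted model share one predictor
#' convention (round-trip identity).
#'
#' @inheritParams simulate_traits
#' @param traits Stage-wise trait table covering every (year, plot, stage).
#' @return Data frame with `year`, `plot_id`, `block`, `n_rate`,
#'   `seed_yield` (kg/ha).
#' @export
simulate_yield <- function(design, traits, truth = truth_params(), seed = truth$seed) {
  stopifnot(inherits(design, "field_design"))
  need <- merge(design$plots[, c("year", "plot_id")],
                data.frame(stage = design$stages))
  have <- paste(traits$year, traits$plot_id, traits$stage)
  missing <- setdiff(paste(need$year, need$plot_id, need$stage), have)
  if (length(missing) > 0) {
    gy_stop(sprintf("traits missing for %d (year, plot, stage) cells, e.g. %s",
                    length(missing), missing[1]), "incomplete_input")
  }
  pooled <- pool_traits(traits, trait_cols = c("ph", "cnc"))
  mu <- predict_expanded(truth$yield, pooled$ph, pooled$cnc)
  sdy <- truth$yield_noise_frac * mean(mu)
  y <- with_seed(seed, mu + stats::rnorm(length(mu), 0, sdy))
  out <- pooled[, intersect(c("year", "plot_id", "block", "n_rate"), names(pooled))]
  out$seed_yield <- pmax(y, 0)
  rownames(out) <- NULL
  out
}

#' Write / read the tabular field artifacts
#'
#' Plain-CSV serialization of the design plot table, trait observations and
#' yield records, with the documented column names preserved.
#'
#' @param x Data frame (or `field_design`, whose `plots` table is written).
#' @param path Output CSV path.
#' @return `write_field_csv` returns `path` invisibly; `read_field_csv`
#'   returns a data frame.
#' @export
write_field_csv <- function(x, path) {
  if (inherits(x, "field_design")) x <- x$plots
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  if (!file.exists(path)) gy_stop(paste("no such file:", path), "format_error")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize truth/configuration parameters as YAML
#'
#' Flat key-value (YAML) persistence of a [truth_params()] set, including the
#' yield generator coefficients and the seed.
#'
#' @param truth A [truth_params()] object.
#' @param path YAML file path.
#' @export
write_truth_params <- function(truth, path) {
  stopifnot(inherits(truth, "truth_params"))
  lst <- unclass(truth)
  lst$yield <- unclass(lst$yield)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_truth_params
#' @export
read_truth_params <- function(path) {
  if (!file.exists(path)) gy_stop(paste("no such file:", path), "format_error")
  lst <- yaml::read_yaml(path)
  lst$yield <- do.call(expanded_params, lst$yield)
  # restore stage names dropped by YAML scalarization
  for (f in c("ph_asym", "cnc_stage_decline")) {
    v <- unlist(lst[[f]])
    if (is.null(names(v)) || !all(stage_labels() %in% names(v))) names(v) <- stage_labels()
    lst[[f]] <- v
  }
  do.call(truth_params, lst)
}
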