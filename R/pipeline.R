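#' Simulate a complete multi-year UAV trial
#'
#' End-to-end study generator: builds the RCBD design, simulates field
#' trait observations and plot yields from the ground truth, then renders
#' one synthetic scene per (year, stage) and runs the full imagery-trait
#' pipeline (Otsu masking, DSM - DEM heights, VI extraction) on it. The
#' returned UAV table pairs the imagery-derived plot traits with the
#' field-measured CNC and final yields, which is exactly the input the
#' cross-year protocol consumes.
#'
#' Scene rendering uses per-plot canopy cover from [cover_fraction()] and
#' per-year multiplicative band gains to emulate between-season radiometric
#' differences.
#'
#' @param design A [make_design()] object.
#' @param truth A [truth_params()] object.
#' @param seed Master seed; per-scene seeds are derived from it.
#' @param pixel_size Scene pixel size (m). The default 0.25 m keeps full
#'   trials fast; single scenes can be rendered at the native 0.03 m GSD
#'   via [scene_spec()] directly.
#' @param plot_size,gap Plot geometry passed to [plot_layout()] (m).
#' @param band_gains_by_year List (or single vector) of 5-band gain vectors,
#'   matched to design years by position. Default: 1.00, 0.95, 1.10 applied
#'   uniformly to all bands of years 1..3.
#' @param refl_noise_sd,height_noise_sd Sensor noise passed to [scene_spec()].
#' @param render If `FALSE`, skip imagery and return field tables only.
#' @return List of class `gy_trial`: `design`, `truth`, `traits` (field),
#'   `yields`, `uav` (imagery-derived stage-wise plot table with field
#'   `cnc` and `seed_yield` attached), `layouts` (per-year plot polygons).
#' @export
simulate_trial <- function(design = make_design(),
                           truth = truth_params(),
                           seed = 1,
                           pixel_size = 0.25,
                           plot_size = 4, gap = 1,
                           band_gains_by_year = NULL,
                           refl_noise_sd = 0.004,
                           height_noise_sd = 0.005,
                           render = TRUE) {
  traits <- simulate_traits(design, truth, seed = seed)
  yields <- simulate_yield(design, traits, truth, seed = seed + 1)
  if (is.null(band_gains_by_year)) {
    band_gains_by_year <- lapply(rep_len(c(1.00, 0.95, 1.10), length(design$years)),
                                 function(g) rep(g, 5))
  }
  if (!is.list(band_gains_by_year)) band_gains_by_year <- list(band_gains_by_year)
  band_gains_by_year <- rep_len(band_gains_by_year, length(design$years))

  layouts <- lapply(design$years, plot_layout, design = design,
                    plot_size = plot_size, gap = gap)
  names(layouts) <- as.character(design$years)
  uav <- NULL
  if (render) {
    rows <- list()
    for (yi in seq_along(design$years)) {
      yr <- design$years[yi]
      lay <- layouts[[yi]]
      for (si in seq_along(design$stages)) {
        st <- design$stages[si]
        tr <- traits[traits$year == yr & traits$stage == st, , drop = FALSE]
        tr <- tr[match(lay$plot_id, tr$plot_id), ]
        plots <- lay
        plots$cover <- cover_fraction(st, plots$n_rate)
        plots$ph_m <- tr$ph / 100
        plots$cnc <- tr$cnc
        spec <- scene_spec(plots, pixel_size = pixel_size,
                           band_gains = band_gains_by_year[[yi]],
                           refl_noise_sd = refl_noise_sd,
                           height_noise_sd = height_noise_sd,
                           seed = seed + 1000 * yi + si)
        scene <- render_scene(spec)
        ex <- extract_plot_traits(scene$stack, scene$heights, lay, stage = st)
        ex$year <- yr
        ex$cnc <- tr$cnc        # field-measured CNC (Kjeldahl analogue)
        rows[[length(rows) + 1]] <- ex
      }
    }
    uav <- do.call(rbind, rows)
    uav <- merge(uav, yields[, c("year", "plot_id", "seed_yield")],
                 by = c("year", "plot_id"))
    uav <- uav[order(uav$year, match(uav$stage, design$stages), uav$plot_id), ]
    rownames(uav) <- NULL
  }
  structure(list(design = design, truth = truth, traits = traits,
                 yields = yields, uav = uav, layouts = layouts, seed = seed),
            class = "gy_trial")
}

#' @export
print.gy_trial <- function(x, ...) {
  cat("Synthetic UAV trial:", nrow(x$design$plots), "plots,",
      nrow(x$traits), "trait observations",
      if (!is.null(x$uav)) paste0("(", nrow(x$uav), " UAV rows)"), "\n")
  invisible(x)
}
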