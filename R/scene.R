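#' Band order of the multispectral stack
#'
#' @return `c("B", "G", "R", "RE", "NIR")` -- blue, green, red, red edge,
#'   near infrared.
#' @export
band_names <- function() c("B", "G", "R", "RE", "NIR")

#' Default endmember reflectance spectra
#'
#' Plausible five-band surface-reflectance spectra for bright bare soil and
#' for grass canopies at the low- and high-nitrogen ends of the simulated
#' range. The vegetation spectrum of a plot is a linear mix of the two grass
#' endmembers indexed by its CNC (see [scene_spec()]): increasing CNC raises
#' NIR, lowers red/red-edge reflectance, so NDVI-family indices and NDRE
#' increase monotonically with CNC.
#'
#' @return Named list `soil`, `veg_low`, `veg_high` (each a 5-vector in
#'   band order) and `cnc_range`, the CNC interval (% dry mass) mapped onto
#'   the endmember mix.
#' @export
default_spectra <- function() {
  list(
    soil = c(B = 0.10, G = 0.14, R = 0.18, RE = 0.22, NIR = 0.26),
    veg_low = c(B = 0.04, G = 0.09, R = 0.07, RE = 0.18, NIR = 0.38),
    veg_high = c(B = 0.03, G = 0.07, R = 0.04, RE = 0.16, NIR = 0.52),
    cnc_range = c(0.2, 3.0)
  )
}

# Linear endmember mix for a vector of plot CNC values -> matrix [plots x 5].
veg_spectrum <- function(cnc, spectra = default_spectra()) {
  w <- clamp((cnc - spectra$cnc_range[1]) / diff(spectra$cnc_range), 0, 1)
  outer(1 - w, spectra$veg_low) + outer(w, spectra$veg_high)
}

#' Rectangular plot layout for a design year
#'
#' Arranges the year's plots on a regular grid (blocks as rows, plots within
#' block as columns), returning one world-coordinate rectangle per plot.
#'
#' @param design A [make_design()] object.
#' @param year Year to lay out.
#' @param plot_size Plot side length (m).
#' @param gap Alley width between plots and around the field margin (m).
#' @return Data frame `year`, `plot_id`, `block`, `n_rate` with a list column
#'   `poly` of closed 2-column vertex matrices.
#' @export
plot_layout <- function(design, year, plot_size = 4, gap = 1) {
  p <- design$plots[design$plots$year == year, , drop = FALSE]
  if (nrow(p) == 0) gy_stop(paste("year", year, "not in design"), "invalid_design")
  p <- p[order(p$block, p$plot_id), ]
  p$col <- stats::ave(seq_len(nrow(p)), p$block, FUN = seq_along)
  step <- plot_size + gap
  p$poly <- lapply(seq_len(nrow(p)), function(i) {
    x0 <- gap + (p$col[i] - 1) * step
    y0 <- gap + (p$block[i] - 1) * step
    cbind(x = c(x0, x0 + plot_size, x0 + plot_size, x0, x0),
          y = c(y0, y0, y0 + plot_size, y0 + plot_size, y0))
  })
  p$col <- NULL
  rownames(p) <- NULL
  p
}

#' Canopy cover fraction model
#'
#' Ground-cover fraction used when rendering scenes: increases with stage
#' (canopy closure over the season) and with N rate (denser canopies under
#' fertilization), clamped to `[0.05, 0.98]`.
#'
#' @param stage Stage label(s).
#' @param n_rate N rate(s), kg N/ha.
#' @return Cover fraction in `[0, 1]`.
#' @export
cover_fraction <- function(stage, n_rate) {
  base <- c(tillering = 0.45, jointing = 0.60, heading = 0.75, filling = 0.85)
  clamp(unname(base[stage]) * (0.75 + 0.5 * n_rate / (n_rate + 90)), 0.05, 0.98)
}

#' Specification of a synthetic UAV scene
#'
#' Collects everything [render_scene()] needs: the plot polygons with their
#' true per-plot traits and cover, the spectral model, grid geometry, year
#' band gains and sensor noise levels.
#'
#' @param plots Data frame with columns `plot_id`, `poly` (list of vertex
#'   matrices), `cover` (fraction in `[0, 1]`), `ph_m` (true plant height,
#'   m) and `cnc` (%); e.g. built from [plot_layout()] plus a trait table.
#' @param pixel_size Pixel size (m); default 0.03 (multispectral-like GSD).
#' @param margin Soil margin rendered around the plot extent (m).
#' @param spectra Endmember set, see [default_spectra()].
#' @param band_gains Five multiplicative year-effect gains (one per band;
#'   a scalar is recycled).
#' @param refl_noise_sd Additive reflectance sensor noise SD.
#' @param height_noise_sd Per-pixel DSM noise SD (m).
#' @param dem_base,dem_slope Planar bare-ground elevation model:
#'   `dem = dem_base + dem_slope[1] * x + dem_slope[2] * y`.
#' @param crs CRS tag carried on all rasters.
#' @param seed Seed for vegetation-pixel placement and sensor noise.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(plots, pixel_size = 0.03, margin = 1,
                       spectra = default_spectra(),
                       band_gains = rep(1, 5),
                       refl_noise_sd = 0.004, height_noise_sd = 0.005,
                       dem_base = 100, dem_slope = c(0.002, 0.001),
                       crs = "local-metric", seed = 1) {
  stopifnot(all(c("plot_id", "poly", "cover", "ph_m", "cnc") %in% names(plots)))
  band_gains <- rep_len(band_gains, 5)
  if (pixel_size <= 0) gy_stop("pixel size must be > 0", "geometry_error")
  if (any(band_gains <= 0)) gy_stop("band gains must be > 0", "geometry_error")
  if (any(plots$cover < 0 | plots$cover > 1)) {
    gy_stop("cover fractions must lie in [0, 1]", "geometry_error")
  }
  refl <- c(spectra$soil, spectra$veg_low, spectra$veg_high)
  if (any(refl < 0 | refl > 1)) gy_stop("reflectance spectra must lie in [0, 1]", "geometry_error")
  structure(list(plots = plots, pixel_size = pixel_size, margin = margin,
                 spectra = spectra, band_gains = band_gains,
                 refl_noise_sd = refl_noise_sd, height_noise_sd = height_noise_sd,
                 dem_base = dem_base, dem_slope = dem_slope, crs = crs, seed = seed),
            class = "scene_spec")
}

#' Render a synthetic five-band reflectance and DSM/DEM scene
#'
#' Builds the grid covering all plot polygons (plus margin), draws vegetation
#' pixels inside each plot at exactly `round(cover * n_pixels)` seeded
#' positions, assigns the CNC-indexed vegetation spectrum there and the soil
#' spectrum elsewhere, multiplies all bands by the year band gains, and adds
#' truncated Gaussian sensor noise. The DSM equals the planar DEM plus the
#' plot's true height on vegetation pixels (plus height noise); on soil the
#' DSM equals the DEM exactly.
#'
#' @param spec A [scene_spec()].
#' @param grid Optional [gy_raster()] template defining the grid; polygons
#'   must fall inside its extent (geometry error otherwise).
#' @param seed Seed override (defaults to `spec$seed`).
#' @return List of class `gy_scene` with `stack` (`refl_stack`: named list
#'   of five band [gy_raster()]s), `heights` (list `dsm`, `dem`), `layout`
#'   (logical vegetation matrix) and `cover` (data frame of realized per-plot
#'   cover fractions).
#' @export
render_scene <- function(spec, grid = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  px <- spec$pixel_size
  allxy <- do.call(rbind, lapply(spec$plots$poly, function(p) as.matrix(p)[, 1:2]))
  if (is.null(grid)) {
    xmin <- 0; ymin <- 0
    xmax <- max(allxy[, 1]) + spec$margin
    ymax <- max(allxy[, 2]) + spec$margin
    nc <- ceiling(xmax / px); nr <- ceiling(ymax / px)
    grid <- gy_raster(matrix(0, nr, nc), px = px, xmin = xmin, ymin = ymin, crs = spec$crs)
  } else {
    px <- grid$px
    xmax <- grid$xmin + ncol(grid$values) * px
    ymax <- grid$ymin + nrow(grid$values) * px
    if (any(allxy[, 1] < grid$xmin) || any(allxy[, 1] > xmax) ||
        any(allxy[, 2] < grid$ymin) || any(allxy[, 2] > ymax)) {
      gy_stop("plot polygon falls outside the scene grid", "geometry_error")
    }
  }
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  ctr <- pixel_centers(grid)
  dem <- spec$dem_base + spec$dem_slope[1] * ctr$x + spec$dem_slope[2] * ctr$y

  veg <- matrix(FALSE, nr, nc)
  bands <- lapply(spec$spectra$soil, function(v) matrix(v, nr, nc))
  names(bands) <- band_names()
  ph <- matrix(0, nr, nc)
  vspec <- veg_spectrum(spec$plots$cnc, spec$spectra)
  cover_out <- data.frame(plot_id = spec$plots$plot_id,
                          cover_target = spec$plots$cover,
                          cover_realized = NA_real_, n_pixels = NA_integer_)

  out <- with_seed(seed, {
    for (i in seq_len(nrow(spec$plots))) {
      inp <- which(pixels_in_polygon(grid, spec$plots$poly[[i]]))
      if (length(inp) == 0) {
        gy_stop(paste("plot", spec$plots$plot_id[i], "covers no pixel centers"),
                "geometry_error")
      }
      k <- round(spec$plots$cover[i] * length(inp))
      sel <- if (k > 0) sample(inp, k) else integer(0)
      veg[sel] <- TRUE
      ph[sel] <- spec$plots$ph_m[i]
      for (b in seq_along(bands)) bands[[b]][sel] <- vspec[i, b]
      cover_out$cover_realized[i] <- k / length(inp)
      cover_out$n_pixels[i] <- length(inp)
    }
    for (b in seq_along(bands)) {
      v <- bands[[b]] * spec$band_gains[b]
      if (spec$refl_noise_sd > 0) v <- v + matrix(stats::rnorm(nr * nc, 0, spec$refl_noise_sd), nr, nc)
      bands[[b]] <- clamp(v, 0, 1)
    }
    dsm <- dem + ph
    if (spec$height_noise_sd > 0) {
      dsm[veg] <- dsm[veg] + stats::rnorm(sum(veg), 0, spec$height_noise_sd)
    }
    list(bands = bands, dsm = dsm)
  })

  mk <- function(m) gy_raster(m, px = px, xmin = grid$xmin, ymin = grid$ymin, crs = spec$crs)
  stack <- structure(lapply(out$bands, mk), class = "refl_stack")
  heights <- structure(list(dsm = mk(out$dsm), dem = mk(dem)), class = "height_pair")
  structure(list(stack = stack, heights = heights, layout = veg, cover = cover_out),
            class = "gy_scene")
}

#' Assemble a reflectance stack from band rasters
#'
#' @param ... Five [gy_raster()]s named B, G, R, RE, NIR (or a single named
#'   list). All bands must share the grid and contain no negative values.
#' @return Object of class `refl_stack`.
#' @export
refl_stack <- function(...) {
  bands <- list(...)
  if (length(bands) == 1 && is.list(bands[[1]]) && !inherits(bands[[1]], "gy_raster")) {
    bands <- bands[[1]]
  }
  if (!setequal(names(bands), band_names())) {
    gy_stop("reflectance stack needs exactly the bands B, G, R, RE, NIR", "format_error")
  }
  bands <- bands[band_names()]
  for (b in bands) {
    if (!grids_equal(b, bands[[1]])) gy_stop("band grids are not co-registered", "alignment_error")
    if (any(b$values < 0, na.rm = TRUE)) gy_stop("negative reflectance", "format_error")
  }
  structure(bands, class = "refl_stack")
}

#' Assemble a DSM/DEM pair
#'
#' @param dsm,dem Surface and bare-ground elevation [gy_raster()]s (m) on a
#'   common grid.
#' @return Object of class `height_pair`.
#' @export
height_pair <- function(dsm, dem) {
  if (!grids_equal(dsm, dem)) {
    gy_stop("DSM and DEM grids differ (shape, georeferencing or CRS)", "alignment_error")
  }
  structure(list(dsm = dsm, dem = dem), class = "height_pair")
}

scene_files <- function() c(band_names(), "dsm", "dem")

#' Write / read a scene as ASCII grids plus a JSON sidecar
#'
#' One ESRI ASCII grid per band (`B.asc` ... `NIR.asc`) and for the DSM and
#' DEM, plus `scene.json` recording the CRS tag, band order and grid
#' metadata. The round trip is lossless (bitwise-equal arrays, identical
#' georeferencing and CRS).
#'
#' @param stack A `refl_stack`.
#' @param heights A `height_pair`.
#' @param dir Scene directory (created if needed).
#' @return `write_scene` returns `dir` invisibly; `read_scene` a list with
#'   `stack` and `heights`.
#' @export
write_scene <- function(stack, heights, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in band_names()) write_asc(stack[[b]], file.path(dir, paste0(b, ".asc")))
  write_asc(heights$dsm, file.path(dir, "dsm.asc"))
  write_asc(heights$dem, file.path(dir, "dem.asc"))
  meta <- c(grid_meta(stack[[1]]), list(band_order = band_names()))
  jsonlite::write_json(meta, file.path(dir, "scene.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  meta_path <- file.path(dir, "scene.json")
  if (!file.exists(meta_path)) gy_stop(paste("missing scene sidecar:", meta_path), "format_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  crs <- meta$crs %||% "local-metric"
  paths <- file.path(dir, paste0(scene_files(), ".asc"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    gy_stop(paste("missing raster file(s):", paste(basename(missing), collapse = ", ")),
            "format_error")
  }
  rasters <- lapply(paths, read_asc, crs = crs)
  names(rasters) <- scene_files()
  stack <- refl_stack(rasters[band_names()])
  heights <- height_pair(rasters$dsm, rasters$dem)
  list(stack = stack, heights = heights)
}

#' Write / read plot polygons as GeoJSON
#'
#' Standard GeoJSON FeatureCollection of Polygon features with `plot_id`,
#' `year`, `block` and `n_rate` properties.
#'
#' @param plots Layout data frame (see [plot_layout()]).
#' @param path GeoJSON file path.
#' @return `write_plots_geojson` returns `path` invisibly;
#'   `read_plots_geojson` a layout-style data frame.
#' @export
write_plots_geojson <- function(plots, path) {
  props <- intersect(c("plot_id", "year", "block", "n_rate"), names(plots))
  features <- lapply(seq_len(nrow(plots)), function(i) {
    ring <- as.matrix(plots$poly[[i]])[, 1:2, drop = FALSE]
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    list(
      type = "Feature",
      properties = as.list(plots[i, props, drop = FALSE]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(j) unname(ring[j, ]))))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plots_geojson
#' @export
read_plots_geojson <- function(path) {
  if (!file.exists(path)) gy_stop(paste("no such file:", path), "format_error")
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    gy_stop(paste("not a GeoJSON FeatureCollection:", path), "format_error")
  }
  rows <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    colnames(m) <- c("x", "y")
    c(f$properties, list(poly = m))
  })
  props <- names(rows[[1]])[names(rows[[1]]) != "poly"]
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r[props], stringsAsFactors = FALSE)
  }))
  out$poly <- lapply(rows, `[[`, "poly")
  out
}
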