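#' Supported vegetation index names
#'
#' The closed index set computed from the five-band stack. `"GDVI"` is
#' accepted by [compute_vi()] as an alias of `"GNDVI"` (the two names are
#' used interchangeably for the green NDVI in the literature).
#'
#' @return `c("NDVI", "NDRE", "EVI", "GNDVI", "SAVI")`.
#' @export
vi_names <- function() c("NDVI", "NDRE", "EVI", "GNDVI", "SAVI")

#' Compute a vegetation index raster
#'
#' Element-wise application of the standard formulas:
#' \describe{
#'   \item{NDVI}{(NIR - R) / (NIR + R)}
#'   \item{NDRE}{(NIR - RE) / (NIR + RE)}
#'   \item{EVI}{2.5 (NIR - R) / (NIR + 6 R - 7.5 B + 1)}
#'   \item{GNDVI}{(NIR - G) / (NIR + G)}
#'   \item{SAVI}{1.5 (NIR - R) / (NIR + R + 0.5)}
#' }
#' Pixels whose denominator magnitude falls below the guard (1e-6 for EVI,
#' 1e-12 otherwise) are flagged missing (`NA`), never infinite.
#'
#' @param stack A `refl_stack`.
#' @param which Index name (case-insensitive; `"GDVI"` = `"GNDVI"`).
#' @return A [gy_raster()] of index values.
#' @export
compute_vi <- function(stack, which) {
  nm <- toupper(which)
  if (nm == "GDVI") nm <- "GNDVI"
  if (!nm %in% vi_names()) {
    gy_stop(paste0("unsupported vegetation index '", which, "'"), "unsupported_index")
  }
  B <- stack$B$values; G <- stack$G$values; R <- stack$R$values
  RE <- stack$RE$values; NIR <- stack$NIR$values
  res <- switch(nm,
    NDVI = ratio_vi(NIR - R, NIR + R),
    NDRE = ratio_vi(NIR - RE, NIR + RE),
    GNDVI = ratio_vi(NIR - G, NIR + G),
    SAVI = ratio_vi(1.5 * (NIR - R), NIR + R + 0.5),
    EVI = ratio_vi(2.5 * (NIR - R), NIR + 6 * R - 7.5 * B + 1, guard = 1e-6)
  )
  g <- stack$NIR
  gy_raster(res, px = g$px, xmin = g$xmin, ymin = g$ymin, crs = g$crs)
}

ratio_vi <- function(num, den, guard = 1e-12) {
  out <- num / den
  out[abs(den) < guard] <- NA_real_
  out
}

#' Otsu's histogram threshold
#'
#' Bins the finite values (clipped to `[-1, 1]`) into a 256-bin histogram
#' and returns the bin edge maximizing the between-class variance
#' `w0 w1 (mu0 - mu1)^2`. Ties break toward the lower threshold.
#'
#' @param values Numeric vector (e.g. NDVI values); needs at least two
#'   distinct finite values.
#' @param bins Number of histogram bins.
#' @return The threshold (scalar), with attributes `bins` and
#'   `between_class_variance`.
#' @export
otsu_threshold <- function(values, bins = 256) {
  v <- values[is.finite(values)]
  v <- clamp(v, -1, 1)
  if (length(unique(v)) < 2) {
    gy_stop("degenerate histogram: fewer than 2 distinct finite values", "degenerate_histogram")
  }
  edges <- seq(min(v), max(v), length.out = bins + 1)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), nbins = bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[bins]
  # between-class variance for a cut after bin k (k = 1 .. bins - 1)
  k <- seq_len(bins - 1)
  w0k <- w0[k]; w1k <- 1 - w0k
  num <- (mu_t * w0k - mu0[k])^2
  sb <- ifelse(w0k > 0 & w1k > 0, num / (w0k * w1k), -Inf)
  best <- which.max(sb)  # which.max returns the first (lowest) maximizer
  structure(edges[best + 1], bins = bins, between_class_variance = sb[best])
}

#' Vegetation mask from NDVI thresholding
#'
#' Computes NDVI and classifies vegetation as `NDVI > threshold`, using
#' Otsu's method by default or a caller-supplied manual threshold. `NA`
#' NDVI pixels are classified as background.
#'
#' @param stack A `refl_stack`.
#' @param method `"otsu-ndvi"` (the only automatic method).
#' @param threshold Optional manual threshold overriding Otsu.
#' @return Object of class `veg_mask`: list with the logical `mask` matrix,
#'   the `threshold` used and a `method` tag.
#' @export
vegetation_mask <- function(stack, method = "otsu-ndvi", threshold = NULL) {
  ndvi <- compute_vi(stack, "NDVI")$values
  if (is.null(threshold)) {
    if (!identical(method, "otsu-ndvi")) {
      gy_stop(paste("unknown masking method:", method), "unsupported_index")
    }
    threshold <- tryCatch(as.numeric(otsu_threshold(ndvi)), condition = function(c) {
      if (inherits(c, "gy_degenerate_histogram")) {
        gy_stop(paste("NDVI histogram is degenerate (single value);",
                      "pass a manual `threshold=` to classify this scene"),
                "degenerate_histogram")
      }
      stop(c)
    })
    used <- "otsu-ndvi"
  } else {
    used <- "manual"
  }
  mask <- !is.na(ndvi) & ndvi > threshold
  structure(list(mask = mask, threshold = as.numeric(threshold), method = used),
            class = "veg_mask")
}

#' Per-pixel plant height from DSM - DEM differencing
#'
#' Subtracts the bare-ground DEM from the canopy DSM. If the two grids
#' differ, the DSM is first bilinearly resampled onto the DEM grid.
#' Negative differences (noise dips below the bare-ground reference) are
#' clipped to zero.
#'
#' @param heights A `height_pair`.
#' @return A [gy_raster()] of canopy height in metres.
#' @export
plant_height <- function(heights) {
  dsm <- heights$dsm; dem <- heights$dem
  if (!grids_equal(dsm, dem)) {
    if (!identical(dsm$crs, dem$crs)) {
      gy_stop("DSM and DEM CRS tags differ; cannot align", "alignment_error")
    }
    dsm <- resample_bilinear(dsm, dem)
    if (!grids_equal(dsm, dem)) gy_stop("DSM/DEM grids remain misaligned", "alignment_error")
  }
  gy_raster(pmax(dsm$values - dem$values, 0),
            px = dem$px, xmin = dem$xmin, ymin = dem$ymin, crs = dem$crs)
}

#' Plot-level trait summary over vegetation pixels
#'
#' Aggregates one plot: mean plant height (converted to cm, the field-ruler
#' unit) and the mean of each vegetation index, both over vegetation pixels
#' whose centers fall inside the plot polygon, plus the vegetation pixel
#' count and cover fraction.
#'
#' @param stack A `refl_stack`.
#' @param heights A `height_pair` (or a precomputed [plant_height()] raster).
#' @param mask A `veg_mask`.
#' @param polygon Two-column vertex matrix of the plot boundary.
#' @param stage Stage label recorded in the summary.
#' @param plot_id Plot identifier recorded in the summary.
#' @param vis Vegetation indices to summarize.
#' @return One-row data frame: `plot_id`, `stage`, `ph_cm`, one column per
#'   VI, `n_veg`, `cover`.
#' @export
summarize_plot <- function(stack, heights, mask, polygon, stage,
                           plot_id = NA_character_, vis = vi_names()) {
  ph <- if (inherits(heights, "gy_raster")) heights else plant_height(heights)
  if (!grids_equal(ph, stack$NIR)) {
    gy_stop("height and reflectance grids are not aligned", "alignment_error")
  }
  inp <- pixels_in_polygon(ph, polygon)
  if (!any(inp)) gy_stop(paste("plot", plot_id, "does not intersect the grid"), "geometry_error")
  veg <- inp & mask$mask
  nveg <- sum(veg)
  if (nveg == 0) gy_stop(paste("no vegetation pixels in plot", plot_id), "empty_plot")
  out <- data.frame(plot_id = plot_id, stage = stage,
                    ph_cm = 100 * mean(ph$values[veg], na.rm = TRUE),
                    stringsAsFactors = FALSE)
  for (v in vis) out[[v]] <- mean(compute_vi(stack, v)$values[veg], na.rm = TRUE)
  out$n_veg <- nveg
  out$cover <- nveg / sum(inp)
  out
}

#' Extract plot-level traits from a rendered or loaded scene
#'
#' Full imagery-trait pipeline for one acquisition: NDVI + Otsu vegetation
#' mask (or manual threshold), DSM - DEM plant height, and per-plot
#' aggregation over vegetation pixels.
#'
#' @param stack A `refl_stack`.
#' @param heights A `height_pair`.
#' @param plots Layout data frame with `plot_id` and `poly` columns (extra
#'   metadata columns such as `block` and `n_rate` are carried through).
#' @param stage Stage label for all summaries.
#' @param threshold Optional manual NDVI threshold (otherwise Otsu).
#' @param vis Vegetation indices to extract.
#' @return Data frame with one row per plot; attribute `threshold` records
#'   the NDVI cut used.
#' @export
extract_plot_traits <- function(stack, heights, plots, stage,
                                threshold = NULL, vis = vi_names()) {
  mask <- vegetation_mask(stack, threshold = threshold)
  ph <- plant_height(heights)
  vi_rasters <- lapply(vis, function(v) compute_vi(stack, v)$values)
  names(vi_rasters) <- vis
  rows <- lapply(seq_len(nrow(plots)), function(i) {
    inp <- pixels_in_polygon(ph, plots$poly[[i]])
    if (!any(inp)) {
      gy_stop(paste("plot", plots$plot_id[i], "does not intersect the grid"), "geometry_error")
    }
    veg <- inp & mask$mask
    if (sum(veg) == 0) {
      gy_stop(paste("no vegetation pixels in plot", plots$plot_id[i]), "empty_plot")
    }
    out <- data.frame(plot_id = plots$plot_id[i], stage = stage,
                      ph_cm = 100 * mean(ph$values[veg], na.rm = TRUE),
                      stringsAsFactors = FALSE)
    for (v in vis) out[[v]] <- mean(vi_rasters[[v]][veg], na.rm = TRUE)
    out$n_veg <- sum(veg)
    out$cover <- sum(veg) / sum(inp)
    out
  })
  res <- do.call(rbind, rows)
  extra <- setdiff(names(plots), c("poly", names(res)))
  for (e in extra) res[[e]] <- plots[[e]]
  attr(res, "threshold") <- mask$threshold
  res
}
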