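#' Lightweight georeferenced single-band raster
#'
#' A north-up, row-major grid: row 1 is the northernmost row, pixel centers
#' follow the pixel-center convention (`x = xmin + (col - 0.5) * px`,
#' `y = ymin + (nrow - row + 0.5) * px`). Values are stored as a plain
#' numeric matrix; georeferencing is the lower-left corner, pixel size (m)
#' and a CRS tag.
#'
#' @param values Numeric matrix (rows x cols).
#' @param px Pixel size in metres (> 0).
#' @param xmin,ymin World coordinates of the lower-left grid corner.
#' @param crs CRS tag (free-form string; carried through I/O unchanged).
#' @return Object of class `gy_raster`.
#' @export
gy_raster <- function(values, px, xmin = 0, ymin = 0, crs = "local-metric") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (!is.finite(px) || px <= 0) gy_stop("pixel size must be > 0", "format_error")
  structure(list(values = values, px = px, xmin = xmin, ymin = ymin, crs = crs),
            class = "gy_raster")
}

#' @export
print.gy_raster <- function(x, ...) {
  cat(sprintf("gy_raster: %d x %d px, %.4g m/px, origin (%.4g, %.4g), crs '%s'\n",
              nrow(x$values), ncol(x$values), x$px, x$xmin, x$ymin, x$crs))
  invisible(x)
}

#' @export
as.matrix.gy_raster <- function(x, ...) x$values

grid_meta <- function(r) list(nrow = nrow(r$values), ncol = ncol(r$values),
                              px = r$px, xmin = r$xmin, ymin = r$ymin, crs = r$crs)

grids_equal <- function(a, b, tol = 1e-9) {
  ga <- grid_meta(a); gb <- grid_meta(b)
  ga$nrow == gb$nrow && ga$ncol == gb$ncol &&
    abs(ga$px - gb$px) < tol && abs(ga$xmin - gb$xmin) < tol &&
    abs(ga$ymin - gb$ymin) < tol && identical(ga$crs, gb$crs)
}

#' Pixel-center world coordinates of a raster
#'
#' @param r A [gy_raster()].
#' @return List with matrices `x` and `y` of pixel-center coordinates.
#' @export
pixel_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  xs <- r$xmin + (seq_len(nc) - 0.5) * r$px
  ys <- r$ymin + (nr - seq_len(nr) + 0.5) * r$px
  list(x = matrix(xs, nr, nc, byrow = TRUE), y = matrix(ys, nr, nc))
}

#' Even-odd (ray casting) point-in-polygon test
#'
#' Vectorized over points; the polygon is a two-column matrix of vertices
#' (closed or open ring). Points exactly on an edge may fall on either side;
#' plot polygons in this package are laid out with gaps so plot membership
#' is never edge-ambiguous.
#'
#' @param x,y Point coordinates (equal-length vectors).
#' @param poly Two-column numeric matrix of polygon vertices.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n >= 2 && all(poly[1, ] == poly[n, ])) { poly <- poly[-n, , drop = FALSE]; n <- n - 1 }
  if (n < 3) gy_stop("polygon needs at least 3 vertices", "geometry_error")
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Logical matrix of pixels whose centers fall inside `poly`.
pixels_in_polygon <- function(r, poly) {
  ctr <- pixel_centers(r)
  m <- point_in_polygon(as.vector(ctr$x), as.vector(ctr$y), poly)
  matrix(m, nrow(r$values), ncol(r$values))
}

#' Bilinearly resample a raster onto another grid
#'
#' Standard bilinear interpolation at the target grid's pixel centers;
#' target pixels falling outside the source extent take the nearest edge
#' value. Used to re-project a DSM onto the DEM grid when their grids differ.
#'
#' @param src Source [gy_raster()].
#' @param target Raster whose grid defines the output.
#' @return A [gy_raster()] on the target grid.
#' @export
resample_bilinear <- function(src, target) {
  ctr <- pixel_centers(target)
  nr <- nrow(src$values); nc <- ncol(src$values)
  # fractional source pixel indices of target centers
  fc <- (as.vector(ctr$x) - src$xmin) / src$px + 0.5
  fr <- nr - (as.vector(ctr$y) - src$ymin) / src$px + 0.5
  fc <- clamp(fc, 1, nc); fr <- clamp(fr, 1, nr)
  c0 <- clamp(floor(fc), 1, nc - 1); r0 <- clamp(floor(fr), 1, nr - 1)
  wc <- fc - c0; wr <- fr - r0
  v <- src$values
  out <- (1 - wr) * ((1 - wc) * v[cbind(r0, c0)] + wc * v[cbind(r0, c0 + 1)]) +
    wr * ((1 - wc) * v[cbind(r0 + 1, c0)] + wc * v[cbind(r0 + 1, c0 + 1)])
  gy_raster(matrix(out, nrow(target$values), ncol(target$values)),
            px = target$px, xmin = target$xmin, ymin = target$ymin, crs = target$crs)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Text-based standard geospatial raster format (readable by GDAL/QGIS).
#' Values are written with 17 significant digits so a write-read round trip
#' reproduces IEEE doubles bit-for-bit. `NA` maps to the NODATA value.
#' The CRS tag is not part of the `.asc` format; scene I/O stores it in a
#' JSON sidecar (see [write_scene()]).
#'
#' @param r A [gy_raster()].
#' @param path Output `.asc` path.
#' @param crs CRS tag to attach on read.
#' @return `write_asc` returns `path` invisibly; `read_asc` a [gy_raster()].
#' @export
write_asc <- function(r, path) {
  stopifnot(inherits(r, "gy_raster"))
  v <- r$values
  hdr <- c(
    sprintf("NCOLS %d", ncol(v)),
    sprintf("NROWS %d", nrow(v)),
    sprintf("XLLCORNER %.17g", r$xmin),
    sprintf("YLLCORNER %.17g", r$ymin),
    sprintf("CELLSIZE %.17g", r$px),
    "NODATA_VALUE -9999"
  )
  body <- apply(v, 1, function(row) {
    row[is.na(row)] <- -9999
    paste(sprintf("%.17g", row), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path, crs = "local-metric") {
  if (!file.exists(path)) gy_stop(paste("missing raster file:", path), "format_error")
  lines <- readLines(path)
  if (length(lines) < 7) gy_stop(paste("malformed ASCII grid:", path), "format_error")
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- toupper(vapply(hdr, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(vapply(hdr, `[`, "", 2)))
  names(vals) <- keys
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE", "NODATA_VALUE")
  if (!all(need %in% keys) || anyNA(vals[need])) {
    gy_stop(paste("malformed ASCII grid header:", path), "format_error")
  }
  nc <- as.integer(vals["NCOLS"]); nr <- as.integer(vals["NROWS"])
  nums <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(nums) != nr * nc) {
    gy_stop(sprintf("ASCII grid %s has %d values, expected %d", path, length(nums), nr * nc),
            "format_error")
  }
  m <- matrix(nums, nr, nc, byrow = TRUE)
  m[m == vals["NODATA_VALUE"]] <- NA_real_
  gy_raster(m, px = vals[["CELLSIZE"]], xmin = vals[["XLLCORNER"]],
            ymin = vals[["YLLCORNER"]], crs = crs)
}
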