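test_that("vegetation indices match their printed formulas at hand values", {
  st <- const_stack(B = 0.05, G = 0.08, R = 0.1, RE = 0.2, NIR = 0.5)
  expect_equal(compute_vi(st, "NDVI")$values[1, 1], 0.4 / 0.6)
  st2 <- const_stack(R = 0.1, NIR = 0.5, B = 0.05)
  expect_equal(compute_vi(const_stack(NIR = 0.4, R = 0.1, B = 0.05), "SAVI")$values[1, 1],
               1.5 * 0.3 / (0.4 + 0.1 + 0.5))
  expect_equal(compute_vi(const_stack(NIR = 0.4, R = 0.1, B = 0.05), "EVI")$values[1, 1],
               2.5 * 0.3 / (0.4 + 0.6 - 0.375 + 1))
  # symmetry zeros
  expect_equal(compute_vi(const_stack(NIR = 0.3, R = 0.3), "NDVI")$values[1, 1], 0)
  expect_equal(compute_vi(const_stack(NIR = 0.2, RE = 0.2), "NDRE")$values[1, 1], 0)
  expect_equal(compute_vi(const_stack(NIR = 0.25, G = 0.25), "GNDVI")$values[1, 1], 0)
})

test_that("GDVI is accepted as the GNDVI alias and unknown indices error", {
  st <- const_stack()
  expect_identical(compute_vi(st, "GDVI")$values, compute_vi(st, "GNDVI")$values)
  expect_error(compute_vi(st, "MSAVI"), class = "gy_unsupported_index")
})

test_that("all five indices equal the scalar-loop oracle on random pixels", {
  st <- random_stack(2000, seed = 42)
  for (v in vi_names()) {
    got <- compute_vi(st, v)$values
    want <- vi_oracle(st, v)
    expect_identical(is.na(got), is.na(want))
    expect_lt(max(abs(got - want), na.rm = TRUE), 1e-12)
  }
})

test_that("near-zero EVI denominators are flagged missing, not infinite", {
  # choose bands so NIR + 6R - 7.5B + 1 = 0
  st <- const_stack(B = 0.2, R = 0.05, NIR = 0.2)  # 0.2 + 0.3 - 1.5 + 1 = 0
  v <- compute_vi(st, "EVI")$values
  expect_true(all(is.na(v)))
})

test_that("Otsu equals the exhaustive between-class-variance maximizer", {
  x <- c(rep(0.1, 50), rep(0.8, 50))
  thr <- otsu_threshold(x)
  expect_gt(thr, 0.1); expect_lt(thr, 0.8)
  expect_identical(sum(x > thr), 50L)
  expect_equal(as.numeric(thr), otsu_oracle(x))
  set.seed(99)
  x2 <- c(rnorm(1e4, 0.15, 0.03), rnorm(1e4, 0.70, 0.05))
  thr2 <- as.numeric(otsu_threshold(x2))
  # the variance curve plateaus across the empty inter-cluster gap and the
  # tie-break takes its lower edge: the cut lies in the gap between modes
  expect_gt(thr2, 0.15 + 3 * 0.03); expect_lt(thr2, 0.70 - 3 * 0.05)
  expect_equal(thr2, otsu_oracle(x2))
  # classification against the generating mixture is essentially perfect
  truth_cls <- rep(c(FALSE, TRUE), each = 1e4)
  expect_gt(mean((x2 > thr2) == truth_cls), 0.999)
  expect_error(otsu_threshold(rep(0.4, 100)), class = "gy_degenerate_histogram")
})

test_that("vegetation mask matches the rendered layout and manual cuts", {
  s <- small_scene(seed = 12, noiseless = TRUE)
  mask <- vegetation_mask(s$scene$stack)
  expect_identical(mask$mask, s$scene$layout)
  nd <- compute_vi(s$scene$stack, "NDVI")$values
  m5 <- vegetation_mask(s$scene$stack, threshold = 0.5)
  expect_identical(m5$mask, !is.na(nd) & nd > 0.5)
  expect_identical(m5$method, "manual")
  # raising the threshold never adds vegetation pixels
  m6 <- vegetation_mask(s$scene$stack, threshold = 0.6)
  expect_true(all(m5$mask | !m6$mask))
  # all-vegetation constant scene: degenerate histogram with guidance
  err <- tryCatch(vegetation_mask(const_stack(nr = 10, nc = 10)), condition = identity)
  expect_s3_class(err, "gy_degenerate_histogram")
  expect_match(conditionMessage(err), "threshold")
})

test_that("plant height differencing clips negatives and flags misalignment", {
  dem <- gy_raster(matrix(100, 4, 4), px = 1)
  up <- gy_raster(matrix(100.2, 4, 4), px = 1)
  expect_equal(plant_height(height_pair(up, dem))$values, matrix(0.2, 4, 4),
               tolerance = 1e-12)
  expect_true(all(plant_height(height_pair(dem, dem))$values == 0))
  dip <- gy_raster(matrix(99.99, 4, 4), px = 1)
  expect_true(all(plant_height(height_pair(dip, dem))$values == 0))
  other <- gy_raster(matrix(100, 4, 4), px = 1, crs = "EPSG:32650")
  expect_error(height_pair(dem, other), class = "gy_alignment_error")
})

test_that("a coarser DSM is resampled onto the DEM grid before differencing", {
  dem <- gy_raster(matrix(50, 8, 8), px = 0.5)
  dsm_coarse <- gy_raster(matrix(50.3, 4, 4), px = 1)
  ph <- plant_height(structure(list(dsm = dsm_coarse, dem = dem), class = "height_pair"))
  expect_equal(dim(ph$values), c(8, 8))
  expect_equal(unique(as.vector(ph$values)), 0.3, tolerance = 1e-12)
})

test_that("plot summaries equal a brute-force pixel loop", {
  s <- small_scene(seed = 13)
  mask <- vegetation_mask(s$scene$stack)
  ph <- plant_height(s$scene$heights)
  poly <- s$plots$poly[[2]]
  got <- summarize_plot(s$scene$stack, s$scene$heights, mask, poly, "heading",
                        plot_id = s$plots$plot_id[2])
  # oracle: iterate pixels, test centers, accumulate
  ctr <- pixel_centers(ph)
  vi_mats <- lapply(vi_names(), function(v) compute_vi(s$scene$stack, v)$values)
  names(vi_mats) <- vi_names()
  n_in <- 0; n_veg <- 0; ph_sum <- 0
  vi_sum <- setNames(numeric(5), vi_names()); vi_n <- setNames(numeric(5), vi_names())
  for (i in seq_len(nrow(ph$values))) for (j in seq_len(ncol(ph$values))) {
    if (!point_in_polygon(ctr$x[i, j], ctr$y[i, j], poly)) next
    n_in <- n_in + 1
    if (!mask$mask[i, j]) next
    n_veg <- n_veg + 1
    ph_sum <- ph_sum + ph$values[i, j]
    for (v in vi_names()) {
      val <- vi_mats[[v]][i, j]
      if (!is.na(val)) { vi_sum[v] <- vi_sum[v] + val; vi_n[v] <- vi_n[v] + 1 }
    }
  }
  expect_equal(got$ph_cm, 100 * ph_sum / n_veg, tolerance = 1e-12)
  expect_equal(got$n_veg, n_veg)
  expect_equal(got$cover, n_veg / n_in, tolerance = 1e-12)
  for (v in vi_names()) expect_equal(got[[v]], vi_sum[[v]] / vi_n[[v]], tolerance = 1e-12)
})

test_that("masked means exclude soil and empty plots error", {
  # half vegetation at 0.3 m, half soil: plot mean must be 30 cm
  dem <- gy_raster(matrix(10, 6, 6), px = 1)
  dsm_m <- matrix(10, 6, 6); dsm_m[, 1:3] <- 10.3
  hp <- height_pair(gy_raster(dsm_m, px = 1), dem)
  mask <- structure(list(mask = matrix(rep(c(TRUE, FALSE), each = 18), 6, 6),
                         threshold = 0.5, method = "manual"), class = "veg_mask")
  st <- const_stack(nr = 6, nc = 6)
  poly <- cbind(c(0, 6, 6, 0), c(0, 0, 6, 6))
  got <- summarize_plot(st, hp, mask, poly, "heading", plot_id = "p")
  expect_equal(got$ph_cm, 30)
  expect_equal(got$cover, 0.5)
  empty <- structure(list(mask = matrix(FALSE, 6, 6), threshold = 0.5, method = "manual"),
                     class = "veg_mask")
  expect_error(summarize_plot(st, hp, empty, poly, "heading"), class = "gy_empty_plot")
})

test_that("noiseless end-to-end extraction recovers PH and cover exactly", {
  s <- small_scene(seed = 14, noiseless = TRUE)
  ex <- extract_plot_traits(s$scene$stack, s$scene$heights, s$layout, "heading")
  ex <- ex[match(s$plots$plot_id, ex$plot_id), ]
  expect_equal(ex$ph_cm, 100 * s$plots$ph_m, tolerance = 1e-10)
  expect_equal(ex$cover, s$scene$cover$cover_realized, tolerance = 1e-12)
})
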