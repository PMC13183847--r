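# Shared in-code fixtures. Everything is generated, nothing is stored.

# A uniform 5-band stack with constant reflectance per band.
const_stack <- function(B = 0.05, G = 0.08, R = 0.1, RE = 0.2, NIR = 0.5,
                        nr = 4, nc = 5, px = 1) {
  mk <- function(v) gy_raster(matrix(v, nr, nc), px = px)
  refl_stack(list(B = mk(B), G = mk(G), R = mk(R), RE = mk(RE), NIR = mk(NIR)))
}

# Random reflectance stack for oracle comparisons.
random_stack <- function(n, seed = 1) {
  set.seed(seed)
  mk <- function() gy_raster(matrix(runif(n), 1, n), px = 1)
  refl_stack(list(B = mk(), G = mk(), R = mk(), RE = mk(), NIR = mk()))
}

# Scalar-loop VI oracle, independent of the vectorized implementation.
vi_oracle <- function(stack, which) {
  nr <- nrow(stack$B$values); nc <- ncol(stack$B$values)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    b <- stack$B$values[i, j]; g <- stack$G$values[i, j]
    r <- stack$R$values[i, j]; re <- stack$RE$values[i, j]
    nir <- stack$NIR$values[i, j]
    val <- switch(which,
      NDVI = { den <- nir + r; if (abs(den) < 1e-12) NA else (nir - r) / den },
      NDRE = { den <- nir + re; if (abs(den) < 1e-12) NA else (nir - re) / den },
      GNDVI = { den <- nir + g; if (abs(den) < 1e-12) NA else (nir - g) / den },
      SAVI = { den <- nir + r + 0.5; if (abs(den) < 1e-12) NA else 1.5 * (nir - r) / den },
      EVI = { den <- nir + 6 * r - 7.5 * b + 1; if (abs(den) < 1e-6) NA else 2.5 * (nir - r) / den }
    )
    out[i, j] <- val
  }
  out
}

# Exhaustive Otsu oracle: naive double loop over the identical histogram.
otsu_oracle <- function(values, bins = 256) {
  v <- values[is.finite(values)]
  v <- pmin(pmax(v, -1), 1)
  edges <- seq(min(v), max(v), length.out = bins + 1)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), nbins = bins)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  best_k <- NA; best_sb <- -Inf
  for (k in 1:(bins - 1)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts[(k + 1):bins])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):bins] * mids[(k + 1):bins]) / n1
    w0 <- n0 / (n0 + n1); w1 <- 1 - w0
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best_sb + 1e-15) { best_sb <- sb; best_k <- k }
  }
  edges[best_k + 1]
}

# A small one-year scene: design, traits, rendered scene + layout table.
small_scene <- function(seed = 1, noiseless = FALSE, n_rates = c(0, 90, 210),
                        n_blocks = 2, pixel_size = 0.25, cover = NULL,
                        band_gains = rep(1, 5)) {
  design <- make_design(years = 2022, n_rates = n_rates, n_blocks = n_blocks,
                        seed = seed)
  truth <- truth_params()
  if (noiseless) {
    truth <- truth_params(ph_block_sd = 0, ph_plot_sd = 0, ph_noise_sd = 0,
                          cnc_block_sd = 0, cnc_plot_sd = 0, cnc_noise_sd = 0,
                          yield_noise_frac = 0)
  }
  traits <- simulate_traits(design, truth, seed = seed)
  lay <- plot_layout(design, 2022)
  tr <- traits[traits$stage == "heading", ]
  tr <- tr[match(lay$plot_id, tr$plot_id), ]
  plots <- lay
  plots$cover <- if (is.null(cover)) cover_fraction("heading", plots$n_rate) else cover
  plots$ph_m <- tr$ph / 100
  plots$cnc <- tr$cnc
  spec <- scene_spec(plots, pixel_size = pixel_size, band_gains = band_gains,
                     refl_noise_sd = if (noiseless) 0 else 0.004,
                     height_noise_sd = if (noiseless) 0 else 0.005,
                     seed = seed + 7)
  scene <- render_scene(spec)
  list(design = design, truth = truth, traits = traits, layout = lay,
       plots = plots, spec = spec, scene = scene)
}

# Well-spread (P, C) grid rows for exact-recovery fits.
grid_rows <- function(p = seq(4, 30, length.out = 7), c = seq(0.3, 2.2, length.out = 6)) {
  expand.grid(P = p, C = c)
}
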