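test_that("coupled model evaluation matches its multiplicative structure", {
  p <- coupled_params(d1 = 1, d2 = 0, g1 = 1, g2 = 0, a = 0)
  expect_equal(predict_coupled(p, P = 10, C = 1), 10)
  p2 <- coupled_params(d1 = 2, d2 = -0.5, g1 = 1, g2 = 0.1, a = 7)
  expect_equal(predict_coupled(p2, P = 0, C = 1.3), 7)  # sink factor vanishes
  # term-by-term scalar expansion oracle on random parameters/traits
  set.seed(21)
  for (i in 1:20) {
    pr <- coupled_params(rnorm(1), rnorm(1), rnorm(1), rnorm(1), rnorm(1))
    P <- runif(1, 1, 30); C <- runif(1, 0.1, 3)
    hand <- pr$d1 * pr$g1 * C * P + pr$d1 * pr$g2 * C * P^2 +
      pr$d2 * pr$g1 * C^2 * P + pr$d2 * pr$g2 * C^2 * P^2 + pr$a
    expect_equal(predict_coupled(pr, P, C), hand, tolerance = 1e-12)
  }
})

test_that("expanded model evaluation matches finite differences and identities", {
  p0 <- expanded_params(0, 0, 0, 0, 0, a = 7)
  expect_equal(predict_expanded(p0, 12, 1.1), 7)
  t4 <- expanded_params(b_p = 135.90, b_p2 = -0.15, b_c = 7269.50,
                        b_c2 = -1710.00, b_pc = -83.80, a = 0)
  P <- 18; C <- 1.0; eps <- 1e-6
  slope <- (predict_expanded(t4, P, C + eps) - predict_expanded(t4, P, C - eps)) / (2 * eps)
  expect_equal(slope, t4$b_c + 2 * t4$b_c2 * C + t4$b_pc * P, tolerance = 1e-4)
  # a coupled model with no cross terms equals the matching expanded model
  cp <- coupled_params(d1 = 3, d2 = 0, g1 = 1, g2 = 0, a = 5)
  ep <- expanded_params(b_p = 0, b_p2 = 0, b_c = 0, b_c2 = 0, b_pc = 3, a = 5)
  g <- grid_rows()
  expect_equal(predict_coupled(cp, g$P, g$C), predict_expanded(ep, g$P, g$C),
               tolerance = 1e-12)
})

test_that("coupled predictions are invariant to the delta/gamma rescaling", {
  pr <- coupled_params(d1 = 2, d2 = -0.6, g1 = 4, g2 = -0.12, a = 300)
  k <- 3.7
  scaled <- coupled_params(pr$d1 * k, pr$d2 * k, pr$g1 / k, pr$g2 / k, pr$a)
  g <- grid_rows()
  expect_equal(predict_coupled(pr, g$P, g$C), predict_coupled(scaled, g$P, g$C),
               tolerance = 1e-9)
  norm <- normalize_coupled(pr)
  expect_equal(norm$g1, 1)
  expect_equal(predict_coupled(norm, g$P, g$C), predict_coupled(pr, g$P, g$C),
               tolerance = 1e-9)
  expect_equal(coupled_products(norm), coupled_products(pr), tolerance = 1e-12)
})

test_that("noiseless expanded data refits exactly and matches normal equations", {
  truth <- expanded_params(b_p = 193, b_p2 = -6, b_c = 1740, b_c2 = -450,
                           b_pc = -60, a = -1350)
  d <- grid_rows()
  d$yield <- predict_expanded(truth, d$P, d$C)
  fit <- fit_yield_model(d, form = "expanded")
  for (nm in names(truth)) {
    expect_lt(abs((fit$params[[nm]] - truth[[nm]]) / truth[[nm]]), 1e-6)
  }
  expect_equal(fit$fit$r2, 1, tolerance = 1e-9)
  # brute-force normal-equations oracle on a noisy instance
  set.seed(31)
  d$yield <- d$yield + rnorm(nrow(d), 0, 25)
  fit2 <- fit_yield_model(d, form = "expanded")
  X <- cbind(1, d$P, d$P^2, d$C, d$C^2, d$P * d$C)
  beta <- solve(t(X) %*% X, t(X) %*% d$yield)
  got <- unlist(fit2$params)[c("a", "b_p", "b_p2", "b_c", "b_c2", "b_pc")]
  expect_equal(unname(got), as.vector(beta), tolerance = 1e-10)
})

test_that("noiseless coupled data recovers the identifiable products", {
  truth <- coupled_params(d1 = 40, d2 = -18, g1 = 2.2, g2 = -0.05, a = 250)
  d <- grid_rows()
  d$yield <- predict_coupled(truth, d$P, d$C)
  fit <- fit_yield_model(d, form = "coupled")
  got <- coupled_products(fit$params)
  want <- coupled_products(truth)
  for (nm in names(want)) {
    expect_lt(abs((got[[nm]] - want[[nm]]) / want[[nm]]), 1e-6)
  }
  expect_equal(fit$params$g1, 1)  # normalization applied
})

test_that("degenerate calibration inputs raise identifiability errors", {
  d <- grid_rows()
  d$yield <- 100 + d$P
  flat <- d; flat$C <- 1
  expect_error(fit_yield_model(flat), class = "gy_identifiability_error")
  expect_error(fit_yield_model(d[1:5, ]), class = "gy_input_error")
})

test_that("contribution shares behave as a grouped Shapley decomposition", {
  # CNC-only truth on a centered balanced factorial: every P-group regressor
  # is sample-orthogonal to the response, so CNC must carry 100% exactly
  truth_c <- expanded_params(b_p = 0, b_p2 = 0, b_c = 900, b_c2 = -300, b_pc = 0, a = 100)
  d <- expand.grid(P = c(-5, 0, 5), C = c(0.5, 1.0, 1.5))
  d <- d[rep(seq_len(nrow(d)), 5), ]
  d$yield <- predict_expanded(truth_c, d$P, d$C)
  fit <- fit_yield_model(d)
  rep_c <- contribution_rates(fit, d)
  expect_equal(rep_c$share_cnc, 100, tolerance = 1e-6)
  expect_equal(rep_c$share_ph, 0, tolerance = 1e-6)
  expect_equal(rep_c$share_interaction, 0, tolerance = 1e-6)
  expect_equal(rep_c$share_ph + rep_c$share_cnc + rep_c$share_interaction, 100,
               tolerance = 0.1)
})

test_that("grouped LMG equals the brute-force all-orderings average", {
  set.seed(42)
  n <- 80
  d <- data.frame(P = runif(n, 5, 30), C = runif(n, 0.3, 2.2))
  d$yield <- 200 + 8 * d$P - 0.2 * d$P^2 + 300 * d$C - 90 * d$C^2 -
    4 * d$P * d$C + rnorm(n, 0, 20)
  fit <- fit_yield_model(d)
  got <- contribution_rates(fit, d)
  # oracle: sequential SSR increments averaged over all 6 group orderings
  groups <- list(ph = c("P", "P2"), cnc = c("C", "C2"), int = "PC")
  X <- data.frame(P = d$P, P2 = d$P^2, C = d$C, C2 = d$C^2, PC = d$P * d$C)
  ssr <- function(cols) {
    if (length(cols) == 0) return(0)
    f <- lm(d$yield ~ ., data = X[, cols, drop = FALSE])
    sum((fitted(f) - mean(d$yield))^2)
  }
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  incr <- matrix(0, 6, 3)
  for (pi in seq_along(perms)) {
    ord <- perms[[pi]]
    prev <- character(0)
    for (gi in seq_along(ord)) {
      cols <- c(prev, groups[[ord[gi]]])
      incr[pi, ord[gi]] <- ssr(cols) - ssr(prev)
      prev <- cols
    }
  }
  avg <- colMeans(incr)
  shares <- 100 * avg / sum(avg)
  expect_equal(c(got$share_ph, got$share_cnc, got$share_interaction), shares,
               tolerance = 1e-8)
  expect_equal(got$interaction_sign, sign(fit$params$b_pc))
})

test_that("orthogonal equal-variance groups split contributions evenly", {
  # centered full factorial: linear P and C effects with equal variance,
  # no interaction signal; the analytic shares are 50/50/0
  d <- expand.grid(P = c(-1, 0, 1), C = c(-1, 0, 1))
  d <- d[rep(seq_len(nrow(d)), 4), ]
  d$yield <- 5 * d$P + 5 * d$C + 100
  fit <- fit_yield_model(d)
  got <- contribution_rates(fit, d)
  expect_equal(got$share_ph, 50, tolerance = 1e-6)
  expect_equal(got$share_cnc, 50, tolerance = 1e-6)
  expect_equal(got$share_interaction, 0, tolerance = 1e-6)
})

test_that("response surface reports the closed-form stationary maximum", {
  p <- expanded_params(b_p = 20, b_p2 = -1, b_c = 300, b_c2 = -150, b_pc = 0, a = 50)
  rs <- response_surface(p)
  expect_equal(rs$stationary$P, -p$b_p / (2 * p$b_p2), tolerance = 1e-10)
  expect_equal(rs$stationary$C, -p$b_c / (2 * p$b_c2), tolerance = 1e-10)
  expect_equal(rs$stationary$class, "maximum")
  # grid argmax equals a dense brute-force scan
  fine <- response_surface(p, p_grid = seq(1, 40, length.out = 400),
                           c_grid = seq(0.1, 3, length.out = 400))
  dense <- which(fine$surface == max(fine$surface), arr.ind = TRUE)
  expect_equal(fine$p_grid[dense[1]], rs$stationary$P, tolerance = 0.1)
  expect_equal(fine$c_grid[dense[2]], rs$stationary$C, tolerance = 0.01)
  # per-slice argmax curve matches a direct scan at a probe slice
  probe_c <- fine$c_grid[200]
  vals <- predict_expanded(p, fine$p_grid, probe_c)
  expect_equal(fine$slice_argmax$P_opt[200], fine$p_grid[which.max(vals)])
})

test_that("the reported coefficient-table surface yields a finite stationary report", {
  t4 <- expanded_params(b_p = 135.90, b_p2 = -0.15, b_c = 7269.50,
                        b_c2 = -1710.00, b_pc = -83.80, a = 0)
  rs <- response_surface(t4)
  expect_true(is.finite(rs$stationary$P) && is.finite(rs$stationary$C))
  expect_true(rs$stationary$class %in% c("maximum", "minimum", "saddle"))
  # coupled-form stationary point in closed form
  cp <- coupled_params(d1 = 40, d2 = -20, g1 = 2, g2 = -0.08, a = 100)
  rc <- response_surface(cp)
  expect_equal(rc$stationary$P, -cp$g1 / (2 * cp$g2), tolerance = 1e-12)
  expect_equal(rc$stationary$C, -cp$d1 / (2 * cp$d2), tolerance = 1e-12)
  expect_equal(rc$stationary$class, "maximum")
})

test_that("direct RF baseline is seeded-deterministic and range-bounded", {
  trial <- simulate_trial(make_design(years = 2022, seed = 51), seed = 51)
  pooled <- pool_traits(trial$uav, c("ph_cm", "seed_yield", vi_names()))
  m1 <- fit_direct_model(pooled)
  m2 <- fit_direct_model(pooled)
  expect_identical(predict_direct(m1, pooled), predict_direct(m2, pooled))
  set.seed(52)
  wild <- pooled
  for (v in c(vi_names(), "ph_cm")) wild[[v]] <- wild[[v]] * runif(nrow(wild), 0.2, 3)
  p <- predict_direct(m1, wild)
  expect_true(all(p >= min(pooled$seed_yield) - 1e-9))
  expect_true(all(p <= max(pooled$seed_yield) + 1e-9))
  expect_error(fit_direct_model(pooled[, setdiff(names(pooled), "EVI")]),
               class = "gy_schema_error")
})

test_that("yield maps evaluate per pixel over the mask only", {
  p <- expanded_params(b_p = 10, b_p2 = -0.2, b_c = 200, b_c2 = -60, b_pc = -3, a = 50)
  set.seed(53)
  ph <- gy_raster(matrix(runif(24, 0.05, 0.3), 4, 6), px = 1)
  cnc <- gy_raster(matrix(runif(24, 0.5, 2), 4, 6), px = 1)
  mask <- matrix(runif(24) > 0.3, 4, 6)
  ym <- predict_yield_map(p, ph, cnc, mask)
  for (i in 1:4) for (j in 1:6) {
    if (mask[i, j]) {
      expect_equal(ym$values[i, j],
                   predict_expanded(p, 100 * ph$values[i, j], cnc$values[i, j]),
                   tolerance = 1e-12)
    } else {
      expect_true(is.na(ym$values[i, j]))
    }
  }
  # constant-trait plot: constant in-plot yield equal to the point prediction
  phc <- gy_raster(matrix(0.15, 4, 6), px = 1)
  cncc <- gy_raster(matrix(1.2, 4, 6), px = 1)
  ymc <- predict_yield_map(p, phc, cncc, matrix(TRUE, 4, 6))
  expect_equal(unique(as.vector(ymc$values)), predict_expanded(p, 15, 1.2))
  misaligned <- gy_raster(matrix(1, 4, 6), px = 2)
  expect_error(predict_yield_map(p, ph, misaligned, mask), class = "gy_alignment_error")
})

test_that("calibration can also stack stages when requested", {
  d <- make_design(years = 2022, n_rates = c(0, 90, 210), n_blocks = 2, seed = 54)
  truth <- truth_params()
  tr <- simulate_traits(d, truth, seed = 1)
  y <- simulate_yield(d, tr, truth, seed = 2)
  stacked <- calibration_table(tr, y, pool = "stack")
  pooledt <- calibration_table(tr, y, pool = "mean")
  expect_equal(nrow(stacked), nrow(tr))
  expect_equal(nrow(pooledt), nrow(y))
  expect_true(all(c("P", "C", "yield") %in% names(stacked)))
})
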