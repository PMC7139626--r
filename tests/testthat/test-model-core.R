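# deterministic core: rhs, fixed points, stability, labels, scales

test_that("transcription equilibrium and absorbing unmodified state", {
  p <- epi_params()
  Tstar <- p$k_tr * p$F_TF / p$lambda  # g(0,0) = 1
  f <- epi_rhs(c(0, 0, 0, Tstar), p)
  expect_equal(unname(f[4]), 0)
  # all writer and methylation rates off -> origin is absorbing
  p0 <- epi_params(k_m = 0, D_novo_0 = 0, k_tr = 0)
  expect_equal(unname(epi_rhs(c(0, 0, 0, 0), p0)), rep(0, 4))
  expect_error(epi_rhs(c(NA, 0, 0, 0), p), "finite")
})

test_that("profile A supports five stable and eight unstable fixed points", {
  fp <- find_fixed_points(epi_params())
  expect_equal(sum(fp$stable), 5)
  expect_equal(sum(!fp$stable), 8)
  expect_setequal(fp$label[fp$stable], c("a", "b", "c", "d", "e"))
  expect_true(all(fp$residual < 1e-8))
})

test_that("stability flags agree with a recomputed Jacobian spectrum", {
  p <- epi_params()
  fp <- find_fixed_points(p)
  for (i in seq_len(nrow(fp))) {
    ev <- eigen(epi_jacobian(as.numeric(fp[i, c("m4", "m27", "mcpg", "T")]),
                             p), only.values = TRUE)$values
    expect_equal(fp$stable[i], max(Re(ev)) < -1e-9)
  }
})

test_that("state labels follow the mark thresholds and methylation split", {
  p <- epi_params()
  mx <- p$m4_max
  expect_equal(classify_state(c(0.9 * mx, 0.9 * mx, 0.05, 0), p), "b")
  expect_equal(classify_state(c(0.01, 0.01, 0.95, 0), p), "e")
  expect_equal(classify_state(c(0.01, 0.9 * mx, 0.05, 0), p), "a")
  expect_equal(classify_state(c(0.9 * mx, 0.01, 0.05, 0), p), "c")
  expect_equal(classify_state(c(0.01, 0.01, 0.05, 0), p), "d")
})

test_that("methylation sub-map is bistable at reference (lattice oracle)", {
  p <- epi_params()
  # brute-force oracle: iterate the per-cycle map from every lattice point
  lattice <- seq(0, 1, length.out = 500)
  ends <- vapply(lattice, function(m) {
    for (i in 1:2000) m <- mcpg_cycle_update(m, 0, p)
    m
  }, numeric(1))
  basins <- unique(round(ends, 4))
  expect_length(basins, 2)  # exactly two attracting levels
  fp <- mcpg_fixed_points(p, m4 = 0)
  expect_equal(sum(fp$stable), 2)
  expect_equal(sum(!fp$stable), 1)
  expect_equal(sort(basins), sort(fp$mcpg[fp$stable]), tolerance = 1e-3)
  # the unstable root separates the two basins
  thr <- mcpg_threshold(p)
  expect_true(all(ends[lattice < thr - 1e-3] < 0.5))
  expect_true(all(ends[lattice > thr + 1e-3] > 0.5))
})

test_that("trajectories stay inside the state simplex", {
  p <- epi_params()
  set.seed(5)
  for (i in 1:6) {
    m4 <- runif(1, 0, 0.9); m27 <- runif(1, 0, 1 - m4)
    x <- c(m4, m27, runif(1), runif(1, 0, 2))
    for (s in 1:4000) {
      x <- x + 0.01 * .epi_rhs(x, p)
      }
    expect_true(x[1] >= -1e-9 && x[2] >= -1e-9)
    expect_true(x[1] + x[2] <= 1 + 1e-9)
    expect_true(x[3] >= -1e-9 && x[3] <= 1 + 1e-9)
    expect_true(x[4] >= -1e-9)
  }
})

test_that("equilibrium responses are monotone in their drivers", {
  p <- epi_params()
  # equilibrium T of the bivalent state is non-decreasing in F_TF
  bT <- vapply(c(0.9, 1.0, 1.1), function(F) {
    fp <- find_fixed_points(epi_params(F_TF = F))
    fp$T[fp$stable & fp$label == "b"][1]
  }, numeric(1))
  expect_true(all(diff(bT) >= -1e-9))
  # bivalent m4 is non-increasing in D_novo_0
  bm <- vapply(c(0.05, 0.1, 0.15), function(D) {
    fp <- find_fixed_points(epi_params(D_novo_0 = D))
    fp$m4[fp$stable & fp$label == "b"][1]
  }, numeric(1))
  expect_true(all(diff(bm) <= 1e-9))
  # increasing accessibility phi weakly increases bivalent m4
  bphi <- vapply(c(1.0, 1.05, 1.1), function(ph) {
    fp <- find_fixed_points(epi_params(phi = ph))
    fp$m4[fp$stable & fp$label == "b"][1]
  }, numeric(1))
  expect_true(all(diff(bphi) >= -1e-9))
  # lowering methylation increases both writer binding probabilities
  pr_hi <- binding_probs(0.3, 0.3, 0.3, 0.05, p)
  pr_lo <- binding_probs(0.3, 0.3, 0.05, 0.05, p)
  expect_gt(pr_lo$P4, pr_hi$P4)
  expect_gt(pr_lo$P27, pr_hi$P27)
})

test_that("bifurcation scan brackets the methylation-bistable region", {
  p <- epi_params()
  bif <- scan_bifurcation(p, "D_novo_0", seq(0.02, 0.3, by = 0.02))
  expect_true(bif$D_novo_C0 < bif$D_novo_C1)
  # oracle: thresholds from the one-dimensional sub-map on a lattice
  has_high <- function(D) {
    fp <- mcpg_fixed_points(p, m4 = 0, D_novo = D)
    any(fp$stable & fp$mcpg > 0.5)
  }
  has_low <- function(D) {
    fp <- mcpg_fixed_points(p, m4 = 0, D_novo = D)
    any(fp$stable & fp$mcpg <= 0.5)
  }
  grid <- seq(0.02, 0.3, by = 0.02)
  c0 <- max(grid[!vapply(grid, has_high, logical(1))])
  c1 <- min(grid[!vapply(grid, has_low, logical(1))])
  expect_equal(bif$D_novo_C0, c0, tolerance = 0.021)
  expect_equal(bif$D_novo_C1, c1, tolerance = 0.021)
  # reference rate sits inside the bistable region
  expect_true(bif$D_novo_C0 < 0.1 && 0.1 < bif$D_novo_C1)
  expect_error(scan_bifurcation(p, "D_novo_0", 0.1), "length")
})

test_that("non-linear plotting scale has the documented fixed values", {
  expect_equal(nonlinear_scale(0.5, 1), 0.4)
  expect_equal(nonlinear_scale(1 / 11, 1), 0.35)
  expect_equal(nonlinear_scale(10 / 11, 1), 0.45)
  # symmetric about m_max/2 for any m_max
  expect_equal(nonlinear_scale(0.2 * 0.75, 0.75) - 0.4,
               0.4 - nonlinear_scale(0.8 * 0.75, 0.75))
  expect_error(nonlinear_scale(0.5, -1), "m_max")
})

test_that("YAML profile round-trips to the built-in defaults", {
  f <- system.file("extdata", "profile_A.yaml", package = "epiprotect")
  p <- epi_params_from_yaml(f)
  q <- epi_params()
  expect_identical(unclass(p), unclass(q))
})
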