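# stochastic population simulator: single-cell steps, division, ensembles

test_that("single-cell step respects limits and degenerate rates", {
  p <- epi_params()
  cell <- new_cell_state(p, m4 = 0.3, m27 = 0.3, mcpg = 0.1, T_ = 0.1)
  expect_error(step_cell(cell, p, dt = p$tau / 10), "dt")
  frozen <- epi_params(k_m = 0, k_d = 0, k_tr = 0, lambda = 0)
  set.seed(1)
  after <- step_cell(cell, frozen, dt = 0.01)
  expect_equal(after$nucleosomes, cell$nucleosomes)
  expect_equal(after$T, cell$T, tolerance = 1e-12)
  expect_error(new_cell_state(p, m4 = 0.8, m27 = 0.5), "capacity")
})

test_that("per-nucleosome gain frequency matches k_m * P4 * dt (binomial MC)", {
  p <- epi_params()
  dt <- p$tau / 100
  cell <- new_cell_state(p, m4 = 0, m27 = 0, mcpg = 0.05, T_ = 1)
  pr <- binding_probs(0, 0, 0.05, 1, p)
  p_gain <- p$k_m * (pr$P4 + pr$P27 - pr$P4 * p$k_m * dt * pr$P27) * dt
  p4_marg <- p$k_m * pr$P4 * dt  # marginal prob. a U nucleosome gains K4
  set.seed(42)
  n_rep <- 10000
  gains <- replicate(n_rep, {
    after <- step_cell(cell, p, dt)
    sum(after$nucleosomes == "K4")
  })
  n_trials <- n_rep * p$N_nuc
  phat <- sum(gains) / n_trials
  se <- sqrt(p4_marg * (1 - p4_marg) / n_trials)
  expect_lt(abs(phat - p4_marg), 3 * se + p4_marg^2) # tie-break correction << p
})

test_that("division dilutes marks binomially and updates methylation once", {
  p <- epi_params()
  cell <- new_cell_state(p, m4 = 0, m27 = 1, mcpg = 0.2, T_ = 0)
  cell$phase <- p$tau
  set.seed(7)
  kept <- replicate(4000, {
    d <- divide_cell(cell, p)
    sum(d$nucleosomes == "K27")
  })
  # chi-square against Binomial(N_nuc, 1/2)
  obs <- tabulate(kept + 1, nbins = p$N_nuc + 1)
  expc <- dbinom(0:p$N_nuc, p$N_nuc, 0.5) * length(kept)
  keep <- expc > 1
  chi <- sum((obs[keep] - expc[keep])^2 / expc[keep])
  pval <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
  # deterministic per-cycle methylation map applied exactly once, with
  # the mother's (unmodified-H3K4) state entering the de novo term
  d <- divide_cell(cell, p)
  expect_equal(d$mcpg, mcpg_cycle_update(0.2, 0, p))
  expect_equal(d$phase, 0)
  # unmodified mother -> daughter identical in marks
  bare <- new_cell_state(p, mcpg = 0.1)
  bare$phase <- p$tau
  expect_equal(sum(divide_cell(bare, p)$nucleosomes != "U"), 0)
  expect_error(divide_cell(new_cell_state(p), p), "cycle")
})

test_that("population runs are reproducible and conserve bookkeeping", {
  p <- epi_params()
  r1 <- simulate_population(p, n_cells = 50, t_total = 12, t_equil = 6,
                            seed = 3)
  r2 <- simulate_population(p, n_cells = 50, t_total = 12, t_equil = 6,
                            seed = 3)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$histogram$counts, r2$histogram$counts)
  r3 <- simulate_population(p, n_cells = 50, t_total = 12, t_equil = 6,
                            seed = 4)
  expect_false(identical(r1$summary$mean, r3$summary$mean))
  # histogram weight equals number of (cell, time) observations
  expect_equal(sum(r1$histogram$counts), r1$summary$n_obs)
  expect_equal(sum(r1$summary$occupancy), 1)
})

test_that("noise-free population initialised at a stable fixed point stays put", {
  p <- epi_params(k_m = 0, k_d = 0)
  # with modification noise and division off, only T and mcpg evolve
  fp <- find_fixed_points(epi_params())
  st <- fp[fp$stable & fp$label == "a", ]
  r <- simulate_population(p, n_cells = 20, t_total = 10, t_equil = 2,
                           init = c(st$m4, st$m27, st$mcpg, st$T),
                           seed = 1, divide = FALSE)
  # nucleosome counts are frozen; T relaxes to its equilibrium for the
  # rounded nucleosome state and stays there
  expect_lt(r$summary$sd[["m4"]], 1e-12)
  expect_lt(r$summary$sd[["m27"]], 1e-12)
})

test_that("high methylation state is not reached from low-methylation attractors", {
  p <- epi_params()
  r <- simulate_population(p, n_cells = 150, t_total = 60, t_equil = 20,
                           init = "attractors", seed = 12)
  expect_lt(r$summary$occupancy[["e"]], 0.005)
  expect_lt(r$summary$mean[["mcpg"]], 0.2)
})

test_that("deterministic CpG update keeps low-branch cells on the low branch", {
  p <- epi_params()
  thr <- mcpg_threshold(p)
  m <- 0.9 * thr
  for (i in 1:500) m <- mcpg_cycle_update(m, 0, p)
  expect_lt(m, thr)
})

test_that("basin map labels fixed points and respects attractor geometry", {
  p <- epi_params()
  fp <- find_fixed_points(p)
  st <- fp[fp$stable & fp$label != "e", ]
  bm <- basin_map(p, n_grid = 9, mcpg0 = 0.09)
  # each stable fixed point's own grid-neighbourhood maps to itself
  for (i in seq_len(nrow(st))) {
    d <- sqrt((bm$m4 - st$m4[i])^2 + (bm$m27 - st$m27[i])^2)
    expect_equal(bm$label[which.min(d)], st$label[i])
  }
  expect_true(all(bm$label %in% c(fp$label, "none")))
})
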