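# DNA-repair simulation and hyper-methylation statistics

test_that("protocol validation enforces the physical constraints", {
  p <- epi_params()
  expect_error(repair_protocol(repair_freq = 1.5), "repair_freq")
  expect_error(check_protocol(repair_protocol(duration = 2), p), "tau")
  expect_error(check_protocol(repair_protocol(D_repair = 0.05), p),
               "exceed")
})

test_that("without repair hits no cell hyper-methylates", {
  p <- epi_params()
  out <- simulate_repair(p, repair_protocol(onset_time = 5, repair_freq = 0,
                                            horizon = 40),
                         n_cells = 30, seed = 2)
  expect_equal(sum(out$hyper), 0)
  final_mc <- out$final$mc
  expect_true(all(final_mc < out$mcpg_C))
})

test_that("a single isolated hit is healed within a few cell cycles", {
  p <- epi_params()
  # deterministic trace of the per-cycle map: one elevated cycle, then
  # relaxation under baseline
  mc <- mcpg_fixed_points(p, m4 = 0)$mcpg[1]  # low fixed point
  mc0 <- mc
  mc <- mcpg_cycle_update(mc, 0, p, D_novo = 0.3)  # the repair cycle
  expect_gt(mc, mc0)
  cycles <- 0
  while (abs(mc - mc0) > 0.01 * mc0 && cycles < 50) {
    mc <- mcpg_cycle_update(mc, 0, p)
    cycles <- cycles + 1
  }
  expect_lt(cycles, 10)
})

test_that("relaxation after a de novo rate change is exponential", {
  p <- epi_params()
  mc0 <- mcpg_fixed_points(p, m4 = 0)$mcpg[1]
  # continuous-time trace: perturb upward, integrate dmcpg_dt back down
  mc <- mc0 + 0.1
  dt <- 0.02
  trace <- vapply(1:150, function(i) {
    mc <<- mc + dt * dmcpg_dt(mc, 0, p)
    mc
  }, numeric(1))
  dev <- (trace - mc0)[20:120]  # asymptotic tail, past the curved entry
  fit <- stats::lm(log(dev) ~ seq_along(dev))
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("repair raises methylation and hyper-methylation is absorbing", {
  p <- epi_params()
  prot <- repair_protocol(onset_time = 10, repair_freq = 0.25,
                          D_repair = 0.3, horizon = 250)
  out <- simulate_repair(p, prot, n_cells = 60, seed = 5)
  expect_gt(sum(out$hyper), 0)
  expect_true(all(out$n_repairs_before_hyper[out$hyper] >= 1))
  # absorbing: once above the threshold at a baseline cycle, a cell's
  # methylation never returns below it
  for (j in which(out$hyper)) {
    traj <- out$mcpg_traj[, j]
    k <- which(traj > out$mcpg_C)[1]
    expect_true(all(traj[k:length(traj)] > out$mcpg_C, na.rm = TRUE))
  }
  # seeded determinism
  out2 <- simulate_repair(p, prot, n_cells = 60, seed = 5)
  expect_identical(out$hyper, out2$hyper)
  expect_identical(out$mcpg_traj, out2$mcpg_traj)
})

test_that("hyper-methylation probability is monotone in the protocol drivers", {
  p <- epi_params()
  base <- function(freq, D_rep, horizon = 150) {
    out <- simulate_repair(p, repair_protocol(onset_time = 5,
      repair_freq = freq, D_repair = D_rep, horizon = horizon),
      n_cells = 60, seed = 9)
    mean(out$hyper)
  }
  p_lo <- base(0.1, 0.3)
  p_hi_freq <- base(0.3, 0.3)
  expect_gte(p_hi_freq, p_lo)
  p_hi_rate <- base(0.1, 0.4)
  expect_gte(p_hi_rate, p_lo)
})

test_that("baseline below the bistable region cannot hyper-methylate", {
  p <- epi_params(D_novo_0 = 0.05)  # below D_novo_C0
  # elevated rate kept below D_novo_C1 so the low state never destabilises
  prot <- repair_protocol(onset_time = 5, repair_freq = 0.5,
                          D_repair = 0.15, horizon = 120)
  out <- simulate_repair(p, prot, n_cells = 40, seed = 3)
  expect_equal(sum(out$hyper), 0)
})

test_that("permanent supercritical forcing hyper-methylates every cell", {
  p <- epi_params()
  prot <- repair_protocol(onset_time = 5, repair_freq = 1,
                          D_repair = 0.35, horizon = 300)
  out <- simulate_repair(p, prot, n_cells = 30, seed = 4)
  expect_equal(mean(out$hyper), 1)
})

test_that("repairs-before-hyper comparison and its degenerate case", {
  p <- epi_params()
  prot <- repair_protocol(onset_time = 5, repair_freq = 0.3,
                          D_repair = 0.32, horizon = 220)
  lo <- simulate_repair(epi_params(D_novo_0 = 0.08), prot,
                        n_cells = 60, seed = 21)
  hi <- simulate_repair(p, prot, n_cells = 60, seed = 21)
  cmp <- repairs_before_hyper(lo, hi)
  if (cmp$defined) {
    expect_true(is.finite(cmp$ks$p_value))
    expect_true(cmp$ks$D >= 0 && cmp$ks$D <= 1)
  }
  none <- simulate_repair(p, repair_protocol(onset_time = 5,
    repair_freq = 0, horizon = 30), n_cells = 10, seed = 1)
  undef <- repairs_before_hyper(none, hi)
  expect_false(undef$defined)
  expect_null(undef$ks)
})
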