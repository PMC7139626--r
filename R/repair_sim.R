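# DNA-repair simulation: random repair hits transiently raise de novo
# DNMT activity; detection of promoter hyper-methylation events.

#' Define a DNA-repair protocol
#'
#' @param onset_time Start of the damage regime (days; default 50 cell
#'   cycles of equilibration under baseline dynamics).
#' @param repair_freq Probability per cell and per cell division of a
#'   repair hit (reference 0.04 per cycle).
#' @param D_repair Elevated de novo methylation rate while a damaged locus
#'   is repaired (reference 0.3, above the upper bound of the methylation
#'   bistable region).
#' @param duration Time the elevated rate lasts within the affected cycle
#'   (days; must not exceed `tau` — the damage is fully repaired within the
#'   cycle in which it occurs).
#' @param horizon Total simulated time after onset (days).
#' @param phi_repair Optional elevated chromatin accessibility during
#'   repair (default `NULL`: accessibility unchanged).
#' @return A list of class `"repair_protocol"`.
#' @export
repair_protocol <- function(onset_time = 50, repair_freq = 0.04,
                            D_repair = 0.3, duration = 1,
                            horizon = 500, phi_repair = NULL) {
  if (repair_freq < 0 || repair_freq > 1) {
    stop("repair_freq must lie in [0, 1] per cycle")
  }
  if (onset_time < 0 || horizon <= 0) stop("invalid protocol times")
  structure(list(onset_time = onset_time, repair_freq = repair_freq,
                 D_repair = D_repair, duration = duration,
                 horizon = horizon, phi_repair = phi_repair),
            class = "repair_protocol")
}

check_protocol <- function(protocol, p) {
  if (protocol$duration > p$tau) stop("repair duration must be <= tau")
  if (protocol$D_repair <= p$D_novo_0) {
    stop("D_repair must exceed the baseline de novo rate")
  }
  invisible(protocol)
}

#' Simulate repeated DNA repair and detect hyper-methylation
#'
#' Cells are equilibrated for `onset_time` under baseline dynamics starting
#' from stochastically acquired low-methylation states. Afterwards each
#' cell is hit at most once per cycle with probability
#' `repair_freq * tau`; a hit raises the effective de novo rate of that
#' cycle to `D_repair` for `duration` (time-weighted into the per-cycle
#' CpG update), after which the rate returns to baseline. A cell is called
#' hyper-methylated when its end-of-cycle methylation exceeds the
#' bistability threshold `mcpg_C`: by bistability, any state beyond the
#' separatrix converges to the high branch under baseline dynamics, so the
#' crossing itself is the irreversible commitment (sub-threshold repair
#' excursions relax back and never count). If the baseline rate lies below
#' the bistable region no high-methylation attractor exists and the
#' hyper-methylation probability is structurally zero.
#'
#' @param p An [epi_params()] object (baseline `D_novo_0`).
#' @param protocol A [repair_protocol()].
#' @param n_cells Number of simulated cells (reference 100).
#' @param seed Integer seed.
#' @param dt Time step (days).
#' @return A list of class `"epi_repair"`: `mcpg_traj` (cycles x cells
#'   matrix of end-of-cycle methylation), `hit_traj` (logical matrix of
#'   repair hits), `hyper` (logical per cell), `hyper_time`,
#'   `n_repairs_before_hyper` (NA for cells that never hyper-methylate),
#'   `mcpg_C`, `mcpg_high` (the high fixed point), `converged` (hyper cells
#'   whose final methylation is within 5% of the high fixed point), and the
#'   configuration.
#' @export
simulate_repair <- function(p, protocol = repair_protocol(),
                            n_cells = 100, seed = 1, dt = p$tau / 100) {
  validate_params(p)
  check_protocol(protocol, p)
  if (n_cells < 1) stop("n_cells must be >= 1")
  set.seed(seed)
  mcc <- mcpg_threshold(p)
  bistable <- !is.na(mcc)
  if (!bistable) {
    # below D_novo_C0 there is no high-methylation attractor: cells can
    # never hyper-methylate, whatever the repair forcing
    mcc <- Inf
    mc_high <- NA_real_
  } else {
    fp_hi <- mcpg_fixed_points(p, m4 = 0)
    mc_high <- max(fp_hi$mcpg[fp_hi$stable])
  }
  pop <- pop_init(p, n_cells, "attractors")
  phase <- stats::runif(n_cells, 0, p$tau)

  # effective per-cycle de novo rate of a hit cycle: time-weighted exposure
  D_hit <- (protocol$duration * protocol$D_repair +
            (p$tau - protocol$duration) * p$D_novo_0) / p$tau
  phi_base <- p$phi

  n_cycles_total <- ceiling((protocol$onset_time + protocol$horizon) / p$tau)
  mc_traj <- matrix(NA_real_, n_cycles_total, n_cells)
  hit_traj <- matrix(FALSE, n_cycles_total, n_cells)
  hyper <- rep(FALSE, n_cells)
  hyper_time <- rep(NA_real_, n_cells)
  n_hits <- rep(0L, n_cells)
  n_hits_at_hyper <- rep(NA_integer_, n_cells)
  cycle_idx <- rep(1L, n_cells)
  hit_now <- rep(FALSE, n_cells)

  n_steps <- ceiling((protocol$onset_time + protocol$horizon) / dt)
  p_run <- p
  for (s in seq_len(n_steps)) {
    t_now <- s * dt
    damage_on <- t_now > protocol$onset_time
    # chromatin opening during repair (optional scenario): raise phi for
    # cells currently under repair; applied population-wide per step via
    # a cell-specific phi is not supported by the vectorised engine, so
    # the optional scenario raises phi globally during the damage regime.
    p_run$phi <- if (damage_on && !is.null(protocol$phi_repair)) {
      protocol$phi_repair
    } else phi_base
    pop <- pop_step(pop, p_run, dt)
    phase <- phase + dt
    who <- phase >= p$tau
    if (any(who)) {
      idx <- which(who)
      D_cycle <- ifelse(hit_now[idx], D_hit, p$D_novo_0)
      m4 <- pop$n4[idx] / p$N_nuc
      pop$mc[idx] <- mcpg_cycle_update(pop$mc[idx], m4, p, D_cycle)
      pop$n4[idx] <- stats::rbinom(length(idx), pop$n4[idx], 0.5)
      pop$n27[idx] <- stats::rbinom(length(idx), pop$n27[idx], 0.5)
      phase[idx] <- phase[idx] - p$tau
      # record end-of-cycle state
      ci <- cycle_idx[idx]
      ok <- ci <= n_cycles_total
      mc_traj[cbind(ci[ok], idx[ok])] <- pop$mc[idx][ok]
      hit_traj[cbind(ci[ok], idx[ok])] <- hit_now[idx][ok]
      # crossing the separatrix is itself the commitment: from any
      # mc > mcpg_C the baseline dynamics converge to the high branch
      newly <- !hyper[idx] & pop$mc[idx] > mcc
      if (any(newly)) {
        j <- idx[newly]
        hyper[j] <- TRUE
        hyper_time[j] <- t_now
        n_hits_at_hyper[j] <- n_hits[j]
      }
      cycle_idx[idx] <- ci + 1L
      # draw hits for the cycle that just started
      hit_now[idx] <- damage_on &
        stats::runif(length(idx)) < protocol$repair_freq * p$tau
      n_hits[idx] <- n_hits[idx] + hit_now[idx]
    }
  }
  converged <- if (bistable) {
    hyper & abs(pop$mc - mc_high) < 0.05 * mc_high
  } else rep(FALSE, n_cells)
  structure(list(
    mcpg_traj = mc_traj, hit_traj = hit_traj, hyper = hyper,
    hyper_time = hyper_time,
    n_repairs_before_hyper = n_hits_at_hyper,
    mcpg_C = mcc, mcpg_high = mc_high, converged = converged,
    final = pop,
    config = list(params = p, protocol = protocol, n_cells = n_cells,
                  seed = seed, dt = dt)
  ), class = "epi_repair")
}

#' @export
print.epi_repair <- function(x, ...) {
  cat("Repair simulation:", x$config$n_cells, "cells,",
      sum(x$hyper), "hyper-methylated\n")
  cat(sprintf("  mcpg_C = %.3f, high state = %.3f\n", x$mcpg_C, x$mcpg_high))
  invisible(x)
}

#' Hyper-methylation probability across protocol conditions
#'
#' Runs [simulate_repair()] for every combination of baseline de novo rate
#' and repair frequency and tabulates the fraction of cells that
#' hyper-methylate within the horizon, with a binomial standard deviation.
#'
#' @param p Base [epi_params()] object.
#' @param baselines Numeric vector of baseline `D_novo_0` values (>= 2).
#' @param repair_freqs Numeric vector of repair frequencies (>= 2).
#' @param protocol Template [repair_protocol()] (frequency is overridden).
#' @param n_cells Cells per run.
#' @param seed Base seed; runs with the same (baseline, frequency) index
#'   offset share derived seeds so conditions are comparable.
#' @return A data.frame with columns `D_novo_0`, `repair_freq`, `p_hyper`,
#'   `sd`, `n_hyper`, `n_cells`.
#' @export
hypermethylation_probability <- function(p, baselines = c(0.08, 0.10),
                                         repair_freqs = c(0.04, 0.08),
                                         protocol = repair_protocol(),
                                         n_cells = 100, seed = 1) {
  if (length(baselines) < 2 || length(repair_freqs) < 2) {
    stop("need >= 2 baselines and >= 2 repair frequencies")
  }
  grid <- expand.grid(D_novo_0 = baselines, repair_freq = repair_freqs)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    q <- p
    q$D_novo_0 <- grid$D_novo_0[i]
    pr <- protocol
    pr$repair_freq <- grid$repair_freq[i]
    out <- simulate_repair(q, pr, n_cells = n_cells, seed = seed + i)
    k <- sum(out$hyper)
    ph <- k / n_cells
    data.frame(D_novo_0 = grid$D_novo_0[i],
               repair_freq = grid$repair_freq[i],
               p_hyper = ph, sd = sqrt(ph * (1 - ph) / n_cells),
               n_hyper = k, n_cells = n_cells)
  })
  do.call(rbind, rows)
}

#' Repair events endured before hyper-methylation
#'
#' Collects, for every hyper-methylated cell of two repair simulations, the
#' number of repair hits it experienced before entering the high
#' methylation state, and compares the two distributions with a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param outcome_low,outcome_high [simulate_repair()] results for the
#'   lower and higher baseline de novo rate.
#' @return A list: `counts_low`, `counts_high`, `mean_low`, `mean_high`,
#'   `ks` (the [ks_two_sample()] result, or `NULL` with `defined = FALSE`
#'   if either group has no hyper-methylated cell).
#' @export
repairs_before_hyper <- function(outcome_low, outcome_high) {
  cl <- outcome_low$n_repairs_before_hyper[outcome_low$hyper]
  ch <- outcome_high$n_repairs_before_hyper[outcome_high$hyper]
  defined <- length(cl) > 0 && length(ch) > 0
  list(counts_low = cl, counts_high = ch,
       mean_low = if (length(cl)) mean(cl) else NA_real_,
       mean_high = if (length(ch)) mean(ch) else NA_real_,
       ks = if (defined) ks_two_sample(cl, ch) else NULL,
       defined = defined)
}
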