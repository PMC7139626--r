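# Stochastic single-cell population simulator: nucleosome-level
# (de-)modification, cell division with histone dilution, deterministic
# per-cycle CpG updates.

#' Create a single-cell promoter state
#'
#' The unit of the stochastic simulator: an array of `N_nuc` promoter
#' nucleosomes each carrying `"U"` (unmodified), `"K4"` (H3K4me3) or
#' `"K27"` (H3K27me3), plus the continuous methylation fraction `mcpg`,
#' transcription level `T`, and cell-cycle phase (time since division).
#'
#' @param p An [epi_params()] object (supplies `N_nuc`).
#' @param m4,m27 Initial modification fractions (rounded to nucleosome
#'   counts).
#' @param mcpg,T_ Initial methylation fraction and transcription level.
#' @param phase Time since the last division, in days (`0 <= phase < tau`).
#' @return A list of class `"cell_state"` with elements `nucleosomes`,
#'   `mcpg`, `T`, `phase`.
#' @export
new_cell_state <- function(p, m4 = 0, m27 = 0, mcpg = 0, T_ = 0, phase = 0) {
  N <- p$N_nuc
  n4 <- round(m4 * N); n27 <- round(m27 * N)
  if (n4 + n27 > N) stop("m4 + m27 exceeds nucleosome capacity")
  if (mcpg < 0 || mcpg > 1 || T_ < 0) stop("invalid mcpg or T")
  if (phase < 0 || phase >= p$tau) stop("phase must lie in [0, tau)")
  nuc <- rep(c("K4", "K27", "U"), c(n4, n27, N - n4 - n27))
  structure(list(nucleosomes = nuc, mcpg = mcpg, T = T_, phase = phase),
            class = "cell_state")
}

cell_fractions <- function(cell) {
  N <- length(cell$nucleosomes)
  c(m4 = sum(cell$nucleosomes == "K4") / N,
    m27 = sum(cell$nucleosomes == "K27") / N)
}

#' Advance one cell by one time step
#'
#' Stochastic nucleosome update: each unmodified nucleosome gains H3K4me3
#' (H3K27me3) with probability `k_m * P4 * dt` (`k_m * P27 * dt`), where the
#' binding probabilities are evaluated at the cell's current mean state;
#' each modified nucleosome loses its mark with probability `k_d * dt`.
#' When both gain events fire on the same nucleosome, one mark is chosen
#' with probability proportional to `P4 : P27`. Transcription is integrated
#' by explicit Euler; `mcpg` is left unchanged within the cycle (it is
#' updated deterministically at division, see [divide_cell()]).
#'
#' @param cell A [new_cell_state()] object.
#' @param p An [epi_params()] object.
#' @param dt Time step in days (must satisfy `dt <= tau/50` and keep all
#'   per-step probabilities below 1).
#' @return The updated cell.
#' @export
step_cell <- function(cell, p, dt) {
  if (dt > p$tau / 50) stop("dt too large (must be <= tau/50)")
  fr <- cell_fractions(cell)
  pr <- binding_probs(fr["m4"], fr["m27"], cell$mcpg, cell$T, p)
  p4 <- p$k_m * pr$P4 * dt
  p27 <- p$k_m * pr$P27 * dt
  pl <- p$k_d * dt
  if (p4 > 1 || p27 > 1 || pl > 1) stop("per-step probability exceeds 1; reduce dt")
  nuc <- cell$nucleosomes
  isU <- nuc == "U"
  if (any(isU)) {
    nU <- sum(isU)
    g4 <- stats::runif(nU) < p4
    g27 <- stats::runif(nU) < p27
    both <- g4 & g27
    if (any(both)) {
      pick4 <- stats::runif(sum(both)) < pr$P4 / (pr$P4 + pr$P27)
      g4[both] <- pick4
      g27[both] <- !pick4
    }
    new <- rep("U", nU)
    new[g4] <- "K4"
    new[g27 & !g4] <- "K27"
    nuc[isU] <- new
  }
  isM <- nuc != "U"
  if (any(isM)) {
    lose <- stats::runif(sum(isM)) < pl
    nuc[isM][lose] <- "U"
  }
  g <- (1 + p$a_T * fr["m4"]) / (1 + p$b_T * fr["m27"])
  cell$T <- max(0, cell$T + dt * (p$k_tr * p$F_TF * g - p$lambda * cell$T))
  cell$nucleosomes <- nuc
  cell$phase <- cell$phase + dt
  cell
}

#' Deterministic per-cycle CpG methylation update
#'
#' The replication-tied methylation map applied once per cell division:
#' de novo gain `D_novo * phi * (1 - m4) * (1 - mcpg)` and maintenance
#' failure `(1 - p_maint(mcpg)) * mcpg` accumulated over one cycle `tau`.
#' Its fixed points coincide with the roots of [dmcpg_dt()]. Individual-CpG
#' fluctuations are deliberately suppressed: without this, rare runs of
#' maintenance failures would let single cells random-walk across the
#' methylation separatrix.
#'
#' @param mcpg,m4 Current state (vectorised over cells).
#' @param p An [epi_params()] object.
#' @param D_novo Effective de novo rate for this cycle.
#' @return Updated methylation fraction, clipped to \[0, 1\].
#' @export
mcpg_cycle_update <- function(mcpg, m4, p, D_novo = p$D_novo_0) {
  pmin(1, pmax(0, mcpg + p$tau * dmcpg_dt(mcpg, m4, p, D_novo)))
}

#' Divide a cell with histone dilution
#'
#' Each modified nucleosome of the mother is retained by the tracked
#' daughter with probability 1/2 and otherwise replaced by a newly
#' synthesised unmodified one; `mcpg` is updated once by the deterministic
#' per-cycle methylation map; the cycle phase is reset to 0.
#'
#' @param cell A [new_cell_state()] object with `phase >= tau`.
#' @param p An [epi_params()] object.
#' @return The daughter cell.
#' @export
divide_cell <- function(cell, p) {
  if (cell$phase < p$tau) stop("cell has not completed its cycle")
  fr <- cell_fractions(cell)
  nuc <- cell$nucleosomes
  isM <- nuc != "U"
  keep <- stats::runif(sum(isM)) < 0.5
  nuc[isM][!keep] <- "U"
  cell$nucleosomes <- nuc
  cell$mcpg <- mcpg_cycle_update(cell$mcpg, fr[["m4"]], p)
  cell$phase <- 0
  cell
}

# --- vectorised population engine -------------------------------------
# Cells are exchangeable at the nucleosome level, so the population is
# advanced on sufficient statistics (counts n4, n27 per cell); the update
# probabilities are identical to step_cell/divide_cell.

pop_init <- function(p, n_cells, init) {
  N <- p$N_nuc
  if (is.character(init) && identical(init, "attractors")) {
    fp <- find_fixed_points(p)
    st <- fp[fp$stable & fp$label %in% c("a", "b", "c", "d"), ]
    if (nrow(st) == 0) stop("no stable low-methylation attractor found")
    idx <- rep_len(seq_len(nrow(st)), n_cells)
    list(n4 = round(st$m4[idx] * N), n27 = round(st$m27[idx] * N),
         mc = st$mcpg[idx], T = st$T[idx])
  } else if (is.numeric(init) && length(init) == 4) {
    list(n4 = rep(round(init[1] * N), n_cells),
         n27 = rep(round(init[2] * N), n_cells),
         mc = rep(init[3], n_cells), T = rep(init[4], n_cells))
  } else stop("init must be \"attractors\" or a numeric state (m4, m27, mcpg, T)")
}

# one vectorised step over all cells; returns modified pop list
pop_step <- function(pop, p, dt) {
  N <- p$N_nuc
  m4 <- pop$n4 / N; m27 <- pop$n27 / N
  pr <- binding_probs(m4, m27, pop$mc, pop$T, p)
  p4 <- p$k_m * pr$P4 * dt
  p27 <- p$k_m * pr$P27 * dt
  if (any(p4 > 1) || any(p27 > 1) || p$k_d * dt > 1) {
    stop("per-step probability exceeds 1; reduce dt")
  }
  nU <- N - pop$n4 - pop$n27
  # marginal per-nucleosome gain probabilities with P4:P27 tie-break
  both <- p4 * p27
  w4 <- ifelse(pr$P4 + pr$P27 > 0, pr$P4 / (pr$P4 + pr$P27), 0.5)
  q4 <- p4 * (1 - p27) + both * w4
  q27 <- p27 * (1 - p4) + both * (1 - w4)
  g4 <- stats::rbinom(length(nU), nU, q4)
  rest <- ifelse(q4 < 1, pmin(1, q27 / (1 - q4)), 0)
  g27 <- stats::rbinom(length(nU), nU - g4, rest)
  l4 <- stats::rbinom(length(nU), pop$n4, p$k_d * dt)
  l27 <- stats::rbinom(length(nU), pop$n27, p$k_d * dt)
  pop$n4 <- pop$n4 + g4 - l4
  pop$n27 <- pop$n27 + g27 - l27
  g <- (1 + p$a_T * m4) / (1 + p$b_T * m27)
  pop$T <- pmax(0, pop$T + dt * (p$k_tr * p$F_TF * g - p$lambda * pop$T))
  pop
}

# vectorised division of the flagged cells
pop_divide <- function(pop, p, who) {
  if (!any(who)) return(pop)
  m4 <- pop$n4 / p$N_nuc
  pop$mc[who] <- mcpg_cycle_update(pop$mc[who], m4[who], p)
  pop$n4[who] <- stats::rbinom(sum(who), pop$n4[who], 0.5)
  pop$n27[who] <- stats::rbinom(sum(who), pop$n27[who], 0.5)
  pop
}

#' Simulate a population of promoters to quasi-steady state
#'
#' Advances `n_cells` independent promoters with stochastic nucleosome
#' (de-)modification, Euler-integrated transcription, fixed cycle length
#' `tau` with uniformly staggered initial phases, binomial histone dilution
#' at division and a deterministic per-cycle CpG update. After an
#' equilibration period the state is sampled at regular intervals and
#' accumulated into an occupancy histogram over `(m4, m27)` and summary
#' statistics.
#'
#' @param p An [epi_params()] object.
#' @param n_cells Number of cells (the reference protocol uses 5000).
#' @param t_total Total simulated time (days).
#' @param t_equil Equilibration time discarded before averaging (days).
#' @param init `"attractors"` (cells distributed equally over the stable
#'   low-methylation fixed points a–d) or a numeric `c(m4, m27, mcpg, T)`.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param dt Time step (days).
#' @param sample_every Sampling interval for the averaging window (days).
#' @param n_bins Number of histogram bins per axis.
#' @param trajectories If `TRUE`, record population-mean time series.
#' @param divide If `FALSE`, suppress cell division (no histone dilution
#'   and no per-cycle CpG update); used to isolate the modification noise.
#' @return A list of class `"epi_population"`: `summary` (means and SDs of
#'   m4, m27, mcpg, T over cells and window, plus per-label occupation
#'   frequencies), `histogram` (bin edges and counts), `trajectories`
#'   (optional data.frame of population means over time), and the call
#'   configuration.
#' @export
simulate_population <- function(p, n_cells = 5000, t_total = 100,
                                t_equil = 50, init = "attractors",
                                seed = 1, dt = p$tau / 100,
                                sample_every = p$tau / 2,
                                n_bins = 21, trajectories = FALSE,
                                divide = TRUE) {
  validate_params(p)
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (t_total <= t_equil) stop("t_total must exceed t_equil")
  set.seed(seed)
  pop <- pop_init(p, n_cells, init)
  phase <- stats::runif(n_cells, 0, p$tau)
  mcc <- mcpg_threshold(p)
  if (is.na(mcc)) mcc <- 0.5
  n_steps <- ceiling(t_total / dt)
  sample_stride <- max(1L, round(sample_every / dt))
  equil_step <- ceiling(t_equil / dt)
  edges <- seq(0, 1, length.out = n_bins + 1)
  H <- matrix(0, n_bins, n_bins)
  sums <- c(m4 = 0, m27 = 0, mcpg = 0, T = 0)
  sq <- sums
  occ <- c(a = 0, b = 0, c = 0, d = 0, e = 0)
  n_obs <- 0
  traj <- if (trajectories) vector("list", n_steps %/% sample_stride + 1)
  ti <- 0
  theta4 <- 0.5 * p$m4_max; theta27 <- 0.5 * p$m27_max
  for (s in seq_len(n_steps)) {
    pop <- pop_step(pop, p, dt)
    phase <- phase + dt
    who <- phase >= p$tau
    if (any(who)) {
      if (divide) pop <- pop_divide(pop, p, who)
      phase[who] <- phase[who] - p$tau
    }
    if (s %% sample_stride == 0) {
      m4 <- pop$n4 / p$N_nuc; m27 <- pop$n27 / p$N_nuc
      if (trajectories) {
        ti <- ti + 1
        traj[[ti]] <- data.frame(t = s * dt, m4 = mean(m4),
                                 m27 = mean(m27), mcpg = mean(pop$mc),
                                 T = mean(pop$T))
      }
      if (s > equil_step) {
        v <- cbind(m4, m27, pop$mc, pop$T)
        sums <- sums + colSums(v)
        sq <- sq + colSums(v^2)
        n_obs <- n_obs + n_cells
        i4 <- pmin(n_bins, findInterval(m4, edges, rightmost.closed = TRUE))
        i27 <- pmin(n_bins, findInterval(m27, edges, rightmost.closed = TRUE))
        tab <- table(factor(i4, levels = 1:n_bins),
                     factor(i27, levels = 1:n_bins))
        H <- H + as.matrix(tab)
        hi4 <- m4 >= theta4; hi27 <- m27 >= theta27
        occ["b"] <- occ["b"] + sum(hi4 & hi27)
        occ["a"] <- occ["a"] + sum(!hi4 & hi27)
        occ["c"] <- occ["c"] + sum(hi4 & !hi27)
        occ["d"] <- occ["d"] + sum(!hi4 & !hi27 & pop$mc < mcc)
        occ["e"] <- occ["e"] + sum(!hi4 & !hi27 & pop$mc >= mcc)
      }
    }
  }
  mean_v <- sums / n_obs
  sd_v <- sqrt(pmax(0, sq / n_obs - mean_v^2))
  names(mean_v) <- names(sd_v) <- c("m4", "m27", "mcpg", "T")
  out <- list(
    summary = list(mean = mean_v, sd = sd_v, occupancy = occ / n_obs,
                   n_obs = n_obs),
    histogram = list(edges = edges, counts = H, total = sum(H)),
    trajectories = if (trajectories) do.call(rbind, traj[seq_len(ti)]),
    config = list(n_cells = n_cells, t_total = t_total, t_equil = t_equil,
                  init = init, seed = seed, dt = dt,
                  sample_every = sample_every, params = p)
  )
  class(out) <- "epi_population"
  out
}

#' @export
print.epi_population <- function(x, ...) {
  cat("Quasi-steady-state population summary (", x$config$n_cells,
      " cells, window ", x$config$t_total - x$config$t_equil, " days)\n",
      sep = "")
  m <- rbind(mean = x$summary$mean, sd = x$summary$sd)
  print(round(m, 4))
  cat("occupancy:", paste(names(x$summary$occupancy),
      round(x$summary$occupancy, 3), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Sweep the de novo methylation rate for several HMT binding energies
#'
#' Runs [simulate_population()] for every combination of `eps_BS` and
#' `D_novo_0` and tabulates the population means and SDs: the in-silico
#' analogue of lowering de novo DNMT activity for G1-like (`eps_BS = 5.5`)
#' versus G2-like (`eps_BS = 5.0`) model genes.
#'
#' @param p Base [epi_params()] object.
#' @param eps_BS_values Numeric vector of binding energies.
#' @param D_novo_values Numeric vector of de novo rates.
#' @param seed Base seed; each run derives its own sub-seed.
#' @param ... Passed to [simulate_population()] (e.g. `n_cells`,
#'   `t_total`, `t_equil`).
#' @return A data.frame with one row per (eps_BS, D_novo_0) combination:
#'   means and SDs of m4, m27, mcpg, T.
#' @export
dnovo_sweep <- function(p, eps_BS_values = c(5.0, 5.2, 5.5),
                        D_novo_values = seq(0, 0.1, by = 0.01),
                        seed = 1, ...) {
  grid <- expand.grid(eps_BS = eps_BS_values, D_novo_0 = D_novo_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    q <- p
    q$eps_BS <- grid$eps_BS[i]
    q$D_novo_0 <- grid$D_novo_0[i]
    run <- simulate_population(q, seed = seed + i, ...)
    data.frame(eps_BS = grid$eps_BS[i], D_novo_0 = grid$D_novo_0[i],
               m4 = run$summary$mean[["m4"]], m4_sd = run$summary$sd[["m4"]],
               m27 = run$summary$mean[["m27"]], m27_sd = run$summary$sd[["m27"]],
               mcpg = run$summary$mean[["mcpg"]], mcpg_sd = run$summary$sd[["mcpg"]],
               T = run$summary$mean[["T"]], T_sd = run$summary$sd[["T"]])
  })
  do.call(rbind, rows)
}

#' Locate the H3K4me3 recruitment threshold in a de novo sweep
#'
#' The largest scanned de novo rate at which the population mean H3K4me3
#' level exceeds its value at the reference rate (the maximum of the
#' grid) by more than `delta`. By default the detector is self-scaling:
#' `delta` is half the curve's own full response amplitude (its maximal
#' increase over the reference), floored at `noise_floor` so that a flat
#' curve is never called recruiting.
#'
#' @param sweep A single-eps_BS slice of a [dnovo_sweep()] table.
#' @param delta Minimal mean-m4 increase that counts as recruitment;
#'   `NULL` for the self-scaling default.
#' @param noise_floor Smallest increase distinguishable from Monte-Carlo
#'   noise at the packaged run sizes.
#' @return The threshold rate, or `NA` if no recruitment is observed.
#' @export
recruitment_threshold <- function(sweep, delta = NULL, noise_floor = 0.02) {
  sweep <- sweep[order(sweep$D_novo_0), ]
  ref <- sweep$m4[nrow(sweep)]
  amp <- max(sweep$m4) - ref
  if (is.null(delta)) delta <- max(amp / 2, noise_floor)
  if (amp <= noise_floor) return(NA_real_)
  rec <- sweep$D_novo_0[sweep$m4 - ref > delta]
  if (length(rec) == 0) NA_real_ else max(rec)
}

#' Map basins of attraction in the histone phase plane
#'
#' Noise-free relaxation of the deterministic model from a grid of initial
#' `(m4, m27)` states at fixed initial methylation and transcription; each
#' grid point is labelled with the fixed point it converges to.
#'
#' @param p An [epi_params()] object.
#' @param n_grid Grid resolution per axis.
#' @param mcpg0,T0 Initial methylation and transcription for every start.
#' @param t_max Integration horizon (days).
#' @return A data.frame with columns `m4`, `m27`, `label` (attractor label
#'   or `"none"` if unconverged).
#' @export
basin_map <- function(p, n_grid = 21, mcpg0 = 0.1, T0 = NULL, t_max = 400) {
  fp <- find_fixed_points(p)
  st <- fp[fp$stable, ]
  axis <- seq(0, 1, length.out = n_grid)
  grid <- expand.grid(m4 = axis, m27 = axis)
  grid <- grid[grid$m4 + grid$m27 <= 1, ]
  lab <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    T_init <- if (is.null(T0)) {
      p$k_tr * p$F_TF * (1 + p$a_T * grid$m4[i]) /
        (1 + p$b_T * grid$m27[i]) / p$lambda
    } else T0
    x <- c(grid$m4[i], grid$m27[i], mcpg0, T_init)
    x <- relax_to_attractor(x, p, t_max)
    d <- sqrt((st$m4 - x[1])^2 + (st$m27 - x[2])^2 + (st$mcpg - x[3])^2)
    lab[i] <- if (length(d) && min(d) < 0.05 &&
                  max(abs(.epi_rhs(x, p))) < 1e-6) {
      st$label[which.min(d)]
    } else "none"
  }
  cbind(grid, label = lab)
}

# adaptive forward integration of the deterministic flow
relax_to_attractor <- function(x, p, t_max = 400, dt = 0.02) {
  n <- ceiling(t_max / dt)
  for (i in seq_len(n)) {
    f <- .epi_rhs(x, p)
    if (max(abs(f)) < 1e-10) break
    x <- x + dt * f
    x[1] <- min(max(x[1], 0), 1)
    x[2] <- min(max(x[2], 0), 1 - x[1])
    x[3] <- min(max(x[3], 0), 1)
    x[4] <- max(x[4], 0)
  }
  x
}
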