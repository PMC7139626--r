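# Deterministic mean-field core: self-consistent equations, fixed points,
# stability, state labels, bifurcation scans.

#' HMT binding probabilities
#'
#' Saturating (logistic) binding probabilities of the H3K4me3 and H3K27me3
#' writer complexes as functions of the promoter state. Both writer
#' complexes bind the un-methylated promoter CpGs with base energy
#' `eps_BS * (1 - mcpg) * phi`, amplified cooperatively by nucleosomes
#' already carrying their own mark (factor `1 + eps_c * m_k`, the
#' reader-writer feedback); transcription stabilises the H3K4me3 writer
#' (`+ eps_T * T`) and destabilises the H3K27me3 writer (`- eps_x * T`);
#' promoter-bound transcription factors additionally recruit the H3K4me3
#' writer directly (`+ eps_F * (F_TF - 1)`, zero at reference activation).
#' Because the cooperative term multiplies the DNA-binding energy, neither
#' mark can sustain itself on a fully methylated promoter: on the high
#' DNA-methylation branch only the unmodified state survives.
#'
#' @param m4,m27,mcpg,T_ State components (vectorised).
#' @param p An [epi_params()] object.
#' @return A list with components `P4` and `P27`.
#' @export
binding_probs <- function(m4, m27, mcpg, T_, p) {
  e_dna <- p$eps_BS * (1 - mcpg) * p$phi
  E4  <- e_dna * (1 + p$eps_c4 * m4) + p$eps_T * T_ +
    p$eps_F * (p$F_TF - 1)
  E27 <- e_dna * (1 + p$eps_c27 * m27) - p$eps_x * T_
  list(P4  = stats::plogis(E4  - p$eps0 - p$d0_4),
       P27 = stats::plogis(E27 - p$eps0))
}

#' Maintenance methylation efficiency
#'
#' Probability that a methylated CpG is maintained through replication;
#' increases cooperatively with the promoter methylation level, which makes
#' the DNA-methylation subsystem bistable.
#'
#' @param mcpg Methylation fraction in \[0, 1\] (vectorised).
#' @param p An [epi_params()] object.
#' @return Maintenance probability in \[0, 1\].
#' @export
p_maint <- function(mcpg, p) {
  mh <- mcpg^p$h_maint
  p$p0 + (1 - p$p0) * mh / (mh + p$K_maint^p$h_maint)
}

#' Net DNA methylation rate
#'
#' Continuous-time flux of the promoter methylation fraction: de novo
#' methylation at rate `D_novo_0 * phi`, antagonised by H3K4me3
#' (`* (1 - m4)`), acting on un-methylated CpGs, minus maintenance failure
#' at replication, `(1 - p_maint(mcpg)) * mcpg / tau`.
#'
#' @param mcpg,m4 State components (vectorised).
#' @param p An [epi_params()] object.
#' @param D_novo Optional override of the effective de novo rate (used by
#'   the repair simulator); defaults to `p$D_novo_0`.
#' @return dm_CpG/dt.
#' @export
dmcpg_dt <- function(mcpg, m4, p, D_novo = p$D_novo_0) {
  D_novo * p$phi * (1 - m4) * (1 - mcpg) -
    (1 - p_maint(mcpg, p)) * mcpg / p$tau
}

#' Right-hand side of the self-consistent model equations
#'
#' Rates of change of the promoter state `(m4, m27, mcpg, T)`:
#' \deqn{dm_4/dt = k_m P_4 (1 - m_4 - m_{27}) - k_d m_4}
#' \deqn{dm_{27}/dt = k_m P_{27} (1 - m_4 - m_{27}) - k_d m_{27}}
#' \deqn{dm_{CpG}/dt = D_{novo} \phi (1 - m_4)(1 - m_{CpG}) -
#'   (1 - p_{maint}(m_{CpG})) m_{CpG}/\tau}
#' \deqn{dT/dt = k_{tr} F_{TF} (1 + a_T m_4)/(1 + b_T m_{27}) - \lambda T}
#'
#' @param state Numeric vector `c(m4, m27, mcpg, T)`.
#' @param p An [epi_params()] object.
#' @return Numeric vector of the four time derivatives.
#' @export
#' @examples
#' p <- epi_params()
#' epi_rhs(c(0.1, 0.8, 0.1, 0.05), p)
epi_rhs <- function(state, p) {
  if (length(state) != 4 || !all(is.finite(state))) {
    stop("state must be a finite numeric vector (m4, m27, mcpg, T)")
  }
  .epi_rhs(state, p)
}

# unchecked hot-path version used inside solvers/integrators
.epi_rhs <- function(state, p) {
  m4 <- state[1]; m27 <- state[2]; mc <- state[3]; T_ <- state[4]
  pr <- binding_probs(m4, m27, mc, T_, p)
  u  <- 1 - m4 - m27
  c(m4  = p$k_m * pr$P4  * u - p$k_d * m4,
    m27 = p$k_m * pr$P27 * u - p$k_d * m27,
    mcpg = dmcpg_dt(mc, m4, p),
    T   = p$k_tr * p$F_TF * (1 + p$a_T * m4) / (1 + p$b_T * m27) -
          p$lambda * T_)
}

# finite-difference Jacobian of epi_rhs (central differences)
epi_jacobian <- function(state, p, eps = 1e-6) {
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    hi <- lo <- state
    hi[j] <- hi[j] + eps
    lo[j] <- lo[j] - eps
    J[, j] <- (epi_rhs(hi, p) - epi_rhs(lo, p)) / (2 * eps)
  }
  J
}

# analytic Jacobian of epi_rhs (used inside the Newton solver; the
# stability flag in find_fixed_points is recomputed by finite differences)
epi_jacobian_analytic <- function(state, p) {
  m4 <- state[1]; m27 <- state[2]; mc <- state[3]; T_ <- state[4]
  pr <- binding_probs(m4, m27, mc, T_, p)
  P4 <- pr$P4; P27 <- pr$P27
  d4 <- P4 * (1 - P4); d27 <- P27 * (1 - P27)
  u <- 1 - m4 - m27
  ebs <- p$eps_BS * p$phi
  e_dna <- ebs * (1 - mc)
  J <- matrix(0, 4, 4)
  J[1, ] <- c(p$k_m * (d4 * e_dna * p$eps_c4 * u - P4) - p$k_d,
              -p$k_m * P4,
              -p$k_m * u * d4 * ebs * (1 + p$eps_c4 * m4),
              p$k_m * u * d4 * p$eps_T)
  J[2, ] <- c(-p$k_m * P27,
              p$k_m * (d27 * e_dna * p$eps_c27 * u - P27) - p$k_d,
              -p$k_m * u * d27 * ebs * (1 + p$eps_c27 * m27),
              -p$k_m * u * d27 * p$eps_x)
  mh <- abs(mc)^p$h_maint
  Kh <- p$K_maint^p$h_maint
  pm <- p$p0 + (1 - p$p0) * mh / (mh + Kh)
  dpm <- (1 - p$p0) * p$h_maint * abs(mc)^(p$h_maint - 1) * Kh / (mh + Kh)^2
  J[3, ] <- c(-p$D_novo_0 * p$phi * (1 - mc), 0,
              -p$D_novo_0 * p$phi * (1 - m4) -
                ((1 - pm) - dpm * mc) / p$tau, 0)
  gden <- 1 + p$b_T * m27
  J[4, ] <- c(p$k_tr * p$F_TF * p$a_T / gden,
              -p$k_tr * p$F_TF * (1 + p$a_T * m4) * p$b_T / gden^2,
              0, -p$lambda)
  J
}

# damped Newton iteration for roots of epi_rhs; returns state or NULL
newton_root <- function(start, p, tol = 1e-11, maxit = 200) {
  x <- start
  for (i in seq_len(maxit)) {
    f <- .epi_rhs(x, p)
    if (max(abs(f)) < tol) return(x)
    J <- epi_jacobian_analytic(x, p)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      xn <- x - lam * step
      # keep the iterate inside a slightly padded domain
      if (all(is.finite(xn)) &&
          xn[1] > -0.2 && xn[2] > -0.2 && xn[1] + xn[2] < 1.2 &&
          xn[3] > -0.2 && xn[3] < 1.2 && xn[4] > -2) {
        fn <- .epi_rhs(xn, p)
        if (max(abs(fn)) < max(abs(f)) || lam < 1e-4) break
      }
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
    x <- xn
  }
  if (max(abs(.epi_rhs(x, p))) < tol) x else NULL
}

#' Classify a regulatory state
#'
#' Assigns one of the five regulatory-state labels: `"a"` (H3K27me3),
#' `"b"` (bivalent), `"c"` (H3K4me3), `"d"` (unmodified, low DNA
#' methylation), `"e"` (unmodified, high DNA methylation). A mark counts as
#' "high" above `theta * m_max` (default half-maximal, matching the model's
#' reading that `m4 < 0.5` is below reliable experimental detection).
#'
#' @param state Numeric vector `c(m4, m27, mcpg, T)`.
#' @param p An [epi_params()] object.
#' @param theta Fraction of `m_max` above which a mark counts as present.
#' @param mcpg_c Methylation threshold separating the low and high DNA
#'   methylation branches; default [mcpg_threshold()].
#' @return A single character label in `c("a","b","c","d","e")`.
#' @export
classify_state <- function(state, p, theta = 0.5, mcpg_c = mcpg_threshold(p)) {
  hi4  <- state[1] >= theta * p$m4_max
  hi27 <- state[2] >= theta * p$m27_max
  if (hi4 && hi27) return("b")
  if (hi27) return("a")
  if (hi4) return("c")
  if (state[3] < mcpg_c) "d" else "e"
}

#' Fixed points of the DNA-methylation sub-map
#'
#' Roots of `dmcpg_dt` at frozen histone state `m4`, found by sign scanning
#' on a fine lattice plus bisection. Under the reference parameters the
#' sub-map is bistable: a low and a high methylation state separated by an
#' unstable threshold.
#'
#' @param p An [epi_params()] object.
#' @param m4 Frozen H3K4me3 level entering the de novo term.
#' @param D_novo Effective de novo rate (default `p$D_novo_0`).
#' @param n Lattice resolution.
#' @return A data.frame with columns `mcpg` and `stable`.
#' @export
mcpg_fixed_points <- function(p, m4 = 0, D_novo = p$D_novo_0, n = 2000) {
  grid <- seq(0, 1, length.out = n + 1)
  f <- dmcpg_dt(grid, m4, p, D_novo)
  roots <- numeric(0)
  if (abs(f[1]) < 1e-14) roots <- c(roots, grid[1])
  for (i in seq_len(n)) {
    if (f[i] == 0 && grid[i] > 0) next # captured as a crossing endpoint below
    if (sign(f[i]) * sign(f[i + 1]) < 0) {
      r <- stats::uniroot(function(m) dmcpg_dt(m, m4, p, D_novo),
                          c(grid[i], grid[i + 1]), tol = 1e-12)$root
      roots <- c(roots, r)
    }
  }
  if (abs(f[n + 1]) < 1e-14) roots <- c(roots, grid[n + 1])
  roots <- sort(unique(round(roots, 10)))
  eps <- 1e-6
  stable <- vapply(roots, function(r) {
    lo <- dmcpg_dt(max(r - eps, 0), m4, p, D_novo)
    hi <- dmcpg_dt(min(r + eps, 1), m4, p, D_novo)
    lo >= 0 && hi <= 0
  }, logical(1))
  data.frame(mcpg = roots, stable = stable)
}

#' Separatrix of the DNA-methylation sub-map
#'
#' The unstable fixed point of the methylation sub-map at `m4 = 0` and the
#' reference de novo rate: promoters with `mcpg` above this threshold are
#' attracted to the high-methylation branch, below it to the low branch.
#'
#' @param p An [epi_params()] object.
#' @param D_novo Effective de novo rate (default `p$D_novo_0`).
#' @return The threshold methylation level, or `NA` if the sub-map is not
#'   bistable at these parameters.
#' @export
mcpg_threshold <- function(p, D_novo = p$D_novo_0) {
  fp <- mcpg_fixed_points(p, m4 = 0, D_novo = D_novo)
  un <- fp$mcpg[!fp$stable & fp$mcpg > 1e-9 & fp$mcpg < 1 - 1e-9]
  if (length(un) == 0) return(NA_real_)
  un[1]
}

#' Find all fixed points of the model
#'
#' Multi-start damped-Newton root search of the self-consistent equations
#' over a grid of initial states covering the histone simplex, both
#' DNA-methylation branches, and low/high transcription. Converged roots are
#' deduplicated, classified stable/unstable via the eigenvalues of a
#' finite-difference Jacobian, labelled with [classify_state()], and sorted
#' by `m4`, then `m27`.
#'
#' @param p An [epi_params()] object.
#' @param n_grid Number of grid points per histone axis.
#' @param dedup_tol Max-norm tolerance below which two roots are considered
#'   identical.
#' @return A data.frame of class `"epi_fixed_points"` with columns `label`,
#'   `stable`, `m4`, `m27`, `mcpg`, `T`, `residual`.
#' @export
#' @examples
#' fp <- find_fixed_points(epi_params())
#' table(fp$stable)
find_fixed_points <- function(p, n_grid = 9, dedup_tol = 1e-4) {
  validate_params(p)
  T_max <- 2 * p$k_tr * max(p$F_TF, 1) * (1 + p$a_T) / p$lambda
  # non-uniform grid: extra resolution near the axes, where nucleation
  # saddles sit close to the unmodified edge of the simplex
  m_grid <- unique(sort(c(0.003, 0.02, 0.05, 0.09, 0.15,
                          seq(0.02, 0.98, length.out = n_grid))))
  starts <- expand.grid(m4 = m_grid, m27 = m_grid,
                        mcpg = c(0.05, 0.5, 0.95), T = c(0, T_max))
  starts <- starts[starts$m4 + starts$m27 <= 1, ]
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    r <- newton_root(as.numeric(starts[i, ]), p)
    if (is.null(r)) next
    # discard spurious roots outside the physical domain
    if (r[1] < -1e-8 || r[2] < -1e-8 || r[1] + r[2] > 1 + 1e-8 ||
        r[3] < -1e-8 || r[3] > 1 + 1e-8 || r[4] < -1e-8) next
    dup <- FALSE
    for (q in roots) if (max(abs(q - r)) < dedup_tol) { dup <- TRUE; break }
    if (!dup) roots[[length(roots) + 1]] <- r
  }
  if (length(roots) == 0) {
    warning("no fixed point converged from any start")
    out <- data.frame(label = character(0), stable = logical(0),
                      m4 = numeric(0), m27 = numeric(0), mcpg = numeric(0),
                      T = numeric(0), residual = numeric(0))
    class(out) <- c("epi_fixed_points", class(out))
    return(out)
  }
  mcc <- mcpg_threshold(p)
  if (is.na(mcc)) mcc <- 0.5
  rows <- lapply(roots, function(r) {
    ev <- eigen(epi_jacobian(r, p), only.values = TRUE)$values
    data.frame(label = classify_state(r, p, mcpg_c = mcc),
               stable = max(Re(ev)) < -1e-9,
               m4 = r[1], m27 = r[2], mcpg = r[3], T = r[4],
               residual = max(abs(epi_rhs(r, p))))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$m4, out$m27), ]
  rownames(out) <- NULL
  class(out) <- c("epi_fixed_points", class(out))
  out
}

#' Bifurcation scan over a model parameter
#'
#' Runs [find_fixed_points()] on a grid of values of one parameter and
#' assembles the solution branches. For `param = "D_novo_0"` the scan also
#' reports the bounds of the DNA-methylation bistable region:
#' `D_novo_C0` (largest grid value below which no high-methylation stable
#' state exists), `D_novo_C1` (smallest grid value above which no
#' low-methylation stable state exists), and the separating threshold
#' `mcpg_C` at the reference de novo rate.
#'
#' @param p An [epi_params()] object (the scanned parameter is overridden).
#' @param param One of `"D_novo_0"`, `"eps_BS"`, `"F_TF"`, `"phi"`.
#' @param values Monotone numeric grid (length >= 2).
#' @param mcpg_split Methylation level separating "low" from "high"
#'   branches when tallying (default 0.5).
#' @return A list of class `"epi_bifurcation"`: `branches` (data.frame with
#'   a `value` column bound to the fixed-point table), and for D-novo scans
#'   `D_novo_C0`, `D_novo_C1`, `mcpg_C`.
#' @export
scan_bifurcation <- function(p, param = "D_novo_0", values,
                             mcpg_split = 0.5) {
  param <- match.arg(param, c("D_novo_0", "eps_BS", "F_TF", "phi"))
  if (length(values) < 2) stop("parameter grid must have length >= 2")
  if (is.unsorted(values) && is.unsorted(rev(values))) {
    stop("parameter grid must be monotone")
  }
  branches <- lapply(values, function(v) {
    q <- p
    q[[param]] <- v
    fp <- find_fixed_points(q)
    if (nrow(fp)) cbind(value = v, fp) else NULL
  })
  branches <- do.call(rbind, branches)
  out <- list(param = param, branches = branches)
  if (param == "D_novo_0") {
    # bistability bounds of the methylation sub-map at unmodified histone
    # state (m4 = 0): histone-rich states keep a low branch far beyond
    # D_novo_C1 because H3K4me3 suppresses the de novo flux
    vs <- sort(values)
    sub <- lapply(vs, function(v) mcpg_fixed_points(p, m4 = 0, D_novo = v))
    has_high <- vapply(sub, function(f)
      any(f$stable & f$mcpg > mcpg_split), logical(1))
    has_low <- vapply(sub, function(f)
      any(f$stable & f$mcpg <= mcpg_split), logical(1))
    out$D_novo_C0 <- if (any(!has_high)) max(vs[!has_high]) else NA_real_
    out$D_novo_C1 <- if (any(!has_low)) min(vs[!has_low]) else NA_real_
    out$mcpg_C <- mcpg_threshold(p)
  }
  class(out) <- "epi_bifurcation"
  out
}

#' Non-linear plotting scale for modification levels
#'
#' Maps a modification fraction `m` to the plot coordinate
#' `0.4 - 0.05 log10((m_max - m)/m)`, which spreads out the near-0 and
#' near-saturation regions of the phase plane. Values at or outside
#' `(0, m_max)` are clipped to `m_max * 1e-6` / `m_max * (1 - 1e-6)` before
#' the transform.
#'
#' @param m Modification fraction(s).
#' @param m_max Maximal modification fraction (> 0).
#' @return Transformed coordinate(s).
#' @export
#' @examples
#' nonlinear_scale(0.5)          # 0.4
#' nonlinear_scale(c(1, 10) / 11) # 0.35, 0.45
nonlinear_scale <- function(m, m_max = 1) {
  if (m_max <= 0) stop("m_max must be > 0")
  m <- pmin(pmax(m, m_max * 1e-6), m_max * (1 - 1e-6))
  0.4 - 0.05 * log10((m_max - m) / m)
}
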