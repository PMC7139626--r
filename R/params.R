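#' Model parameters for the epigenetic regulation model
#'
#' Constructs the full parameter set of the promoter model: coupled dynamics
#' of the fractions of H3K4me3- and H3K27me3-modified promoter nucleosomes
#' (`m4`, `m27`), the fraction of methylated promoter CpGs (`mcpg`) and the
#' transcription level (`T`). The packaged profile `"A"` is the calibrated
#' reference set used throughout: at `F_TF = 1`, `eps_BS = 5.0`,
#' `D_novo_0 = 0.1` it supports five locally stable regulatory states
#' (H3K27me3-only, bivalent, H3K4me3-only, and two unmodified states with
#' low/high DNA methylation) beside eight unstable solutions.
#'
#' All rates are per day; the cell cycle time `tau` is 1 day. Energies
#' (`eps_BS`, `eps0`, `eps_c`, `eps_T`, `eps_x`) are in units of kT.
#'
#' @param profile Character; currently only `"A"`.
#' @param ... Named overrides of individual parameters, e.g. `F_TF = 1.4`,
#'   `eps_BS = 5.5`, `D_novo_0 = 0.05`, `phi = 1.2`.
#'
#' @return A list of class `"epi_params"` with components:
#' \describe{
#'   \item{F_TF}{transcription-factor regulation factor (reference 1.0).}
#'   \item{eps_BS}{interaction energy between CpG-binding HMTs and the
#'     un-methylated promoter (5.0 for the reference/G2-like gene, 5.5 for
#'     the G1-like gene).}
#'   \item{D_novo_0}{maximum de novo DNA methylation rate per cell cycle.}
#'   \item{phi}{chromatin accessibility scalar (default 1).}
#'   \item{tau}{cell cycle time in days.}
#'   \item{eps0}{binding threshold energy of the HMT writer complexes;
#'     the H3K4me3 writer threshold carries an additional offset `d0_4`.}
#'   \item{eps_c4, eps_c27}{cooperativity of the two writers (bound writer
#'     stabilised by already modified nucleosomes of its own mark). The
#'     H3K27me3 writer is strongly mark-cooperative; the H3K4me3 writer
#'     relies more on its transcription coupling.}
#'   \item{eps_T, eps_x}{transcription coupling: T stabilises the H3K4me3
#'     writer and destabilises the H3K27me3 writer.}
#'   \item{eps_F}{direct recruitment of the H3K4me3 writer by the gene's
#'     transcription factors, relative to the reference activation
#'     (`eps_F * (F_TF - 1)`).}
#'   \item{k_m, k_d}{nucleosome modification / demodification rates.}
#'   \item{k_tr, lambda}{transcript synthesis and decay rates.}
#'   \item{a_T, b_T}{activation by m4 and repression by m27 in the
#'     transcription gain `g(m4, m27) = (1 + a_T m4)/(1 + b_T m27)`.}
#'   \item{p0, h_maint, K_maint}{maintenance methylation efficiency
#'     `p_maint(m) = p0 + (1 - p0) m^h/(m^h + K^h)`; the cooperative
#'     increase with `mcpg` produces DNA-methylation bistability.}
#'   \item{m4_max, m27_max}{maximal modification fractions.}
#'   \item{N_nuc}{number of promoter nucleosomes in the stochastic
#'     simulator.}
#' }
#' @export
#' @examples
#' p <- epi_params()
#' g1 <- epi_params(eps_BS = 5.5)
epi_params <- function(profile = "A", ...) {
  if (!identical(profile, "A")) {
    stop("unknown parameter profile: ", profile)
  }
  p <- list(
    # external regulation / scenario knobs
    F_TF     = 1.0,
    eps_BS   = 5.0,
    D_novo_0 = 0.1,
    phi      = 1.0,
    tau      = 1.0,
    # HMT binding energetics (calibrated, frozen)
    eps0     = 15.0,
    d0_4     = -0.5,
    eps_c4   = 10.0,
    eps_c27  = 20.0,
    eps_T    = 1.0,
    eps_x    = 1.0,
    eps_F    = 12.0,
    # nucleosome (de-)modification rates
    k_m      = 3.0,
    k_d      = 1.0,
    # transcription
    k_tr     = 0.088,
    lambda   = 4.0,
    a_T      = 90.0,
    b_T      = 36.0,
    # maintenance methylation
    p0       = 0.0,
    h_maint  = 4.0,
    K_maint  = 0.3,
    # bounds / discretisation
    m4_max   = 0.75,
    m27_max  = 0.75,
    N_nuc    = 20L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  class(p) <- "epi_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  rates <- c("D_novo_0", "k_m", "k_d", "k_tr", "lambda", "tau", "F_TF")
  for (nm in rates) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      stop("parameter ", nm, " must be a finite non-negative number")
    }
  }
  if (p$eps_BS <= 0) stop("eps_BS must be > 0")
  if (p$phi <= 0) stop("phi must be > 0")
  if (p$D_novo_0 > 1) stop("D_novo_0 must lie in [0, 1]")
  if (p$p0 < 0 || p$p0 >= 1) stop("p0 must lie in [0, 1)")
  if (p$N_nuc < 1) stop("N_nuc must be >= 1")
  invisible(p)
}

#' @export
print.epi_params <- function(x, ...) {
  cat("Epigenetic model parameters (profile A",
      if (x$eps_BS != 5.0 || x$D_novo_0 != 0.1 || x$F_TF != 1.0)
        ", modified" else "", ")\n", sep = "")
  cat(sprintf("  F_TF = %.3g, eps_BS = %.3g, D_novo_0 = %.3g, phi = %.3g\n",
              x$F_TF, x$eps_BS, x$D_novo_0, x$phi))
  cat(sprintf("  writers: eps0 = %.3g, eps_c27 = %.3g, eps_T = %.3g, eps_x = %.3g, k_m = %.3g, k_d = %.3g\n",
              x$eps0, x$eps_c27, x$eps_T, x$eps_x, x$k_m, x$k_d))
  cat(sprintf("  transcription: k_tr = %.3g, lambda = %.3g, a_T = %.3g, b_T = %.3g\n",
              x$k_tr, x$lambda, x$a_T, x$b_T))
  cat(sprintf("  methylation: p0 = %.3g, h = %.3g, K = %.3g; N_nuc = %d\n",
              x$p0, x$h_maint, x$K_maint, x$N_nuc))
  invisible(x)
}

#' Load model parameters from a YAML profile file
#'
#' Reads a parameter profile such as the packaged
#' `system.file("extdata", "profile_A.yaml", package = "epiprotect")` and
#' returns a validated [epi_params()] object. Fields in the file override
#' the built-in defaults; a `profile` field selects the base profile.
#'
#' @param path Path to a YAML file of parameter values.
#' @return An `epi_params` object.
#' @export
epi_params_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  profile <- if (!is.null(vals$profile)) vals$profile else "A"
  vals$profile <- NULL
  vals$N_nuc <- as.integer(vals$N_nuc)
  do.call(epi_params, c(list(profile = profile), vals))
}
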