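# Promoter CpG characterisation: CpG/GpC dinucleotide ratio, HCG/ICG/LCG
# promoter classes, and gene-set comparisons.

#' CpG/GpC dinucleotide ratio of a sequence
#'
#' Counts overlapping `CG` and `GC` dinucleotides (dinucleotides containing
#' `N` are skipped) and returns their ratio. This normalises the CpG count
#' by base composition: because GpC is not a methylation target it is not
#' depleted, so the ratio measures how much CpG depletion a promoter has
#' escaped.
#'
#' @param sequence A character string or `Biostrings::DNAString` over
#'   A, C, G, T, N.
#' @return The ratio `count(CG) / count(GC)`, or `NA` (with attribute
#'   `undefined = TRUE`) if the sequence contains no GpC.
#' @export
#' @examples
#' cpg_gpc_fraction("GCGC")  # one CG, two GC -> 0.5
cpg_gpc_fraction <- function(sequence) {
  s <- Biostrings::DNAString(as.character(sequence))
  n_cg <- Biostrings::countPattern("CG", s)
  n_gc <- Biostrings::countPattern("GC", s)
  if (n_gc == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  n_cg / n_gc
}

# per-window counts via cumulative sums over the character vector
window_stats <- function(chars, window) {
  L <- length(chars)
  isC <- chars == "C"; isG <- chars == "G"; isN <- chars == "N"
  d1 <- chars[-L]; d2 <- chars[-1]
  isCG <- d1 == "C" & d2 == "G"
  isValid <- d1 != "N" & d2 != "N"
  cum <- function(x) c(0, cumsum(x))
  cC <- cum(isC); cG <- cum(isG); cN <- cum(isN)
  cCG <- cum(isCG & isValid)
  starts <- seq_len(max(1L, L - window + 1L))
  ends <- pmin(starts + window - 1L, L)
  # cum is 1-shifted: bases in window [s, e] -> cum[e + 1] - cum[s];
  # dinucleotides start at s .. e-1 -> cumCG[e] - cumCG[s]
  nC <- cC[ends + 1] - cC[starts]
  nG <- cG[ends + 1] - cG[starts]
  nN <- cN[ends + 1] - cN[starts]
  nCG <- cCG[ends] - cCG[starts]
  len <- (ends - starts + 1) - nN
  data.frame(start = starts, gc = (nC + nG) / pmax(1, len),
             oe = ifelse(nC * nG > 0, nCG * len / (nC * nG), 0))
}

#' Classify a promoter as HCG, ICG or LCG
#'
#' Sliding-window CpG-density classification: a promoter is `HCG` (high
#' CpG) if any window of `window` bases has GC content at least `gc_high`
#' and CpG observed/expected ratio at least `oe_high`; `LCG` (low CpG) if
#' no window reaches `oe_low`; otherwise `ICG` (intermediate). The CpG
#' observed/expected ratio of a window is `#CG * L / (#C * #G)`.
#'
#' @param sequence A character string or `Biostrings::DNAString`.
#' @param window Window size in bases (default 500); sequences shorter
#'   than the window are evaluated full-length with a warning.
#' @param gc_high,oe_high,oe_low Class thresholds.
#' @return `"HCG"`, `"ICG"` or `"LCG"`.
#' @export
classify_promoter <- function(sequence, window = 500, gc_high = 0.55,
                              oe_high = 0.75, oe_low = 0.48) {
  chars <- strsplit(toupper(as.character(sequence)), "")[[1]]
  if (length(chars) < 2) stop("sequence too short")
  if (length(chars) < window) {
    warning("sequence shorter than window; evaluating full sequence")
    window <- length(chars)
  }
  w <- window_stats(chars, window)
  if (any(w$gc >= gc_high & w$oe >= oe_high)) return("HCG")
  if (all(w$oe < oe_low)) return("LCG")
  "ICG"
}

#' Profile a set of promoter sequences
#'
#' @param sequences A named character vector or `Biostrings::DNAStringSet`;
#'   names are gene ids.
#' @param window Classification window (see [classify_promoter()]).
#' @return A data.frame with one row per promoter: `gene_id`, `length`,
#'   `n_cpg`, `n_gpc`, `ratio` (CpG/GpC), `gc`, `class`.
#' @export
profile_promoters <- function(sequences, window = 500) {
  seqs <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(seqs))) stop("sequences must be named by gene id")
  n_cg <- Biostrings::vcountPattern("CG", seqs)
  n_gc <- Biostrings::vcountPattern("GC", seqs)
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  len <- Biostrings::width(seqs)
  cls <- vapply(seq_along(seqs), function(i)
    classify_promoter(seqs[[i]], window = window), character(1))
  data.frame(gene_id = names(seqs), length = len,
             n_cpg = n_cg, n_gpc = n_gc,
             ratio = ifelse(n_gc > 0, n_cg / n_gc, NA_real_),
             gc = (freq[, "C"] + freq[, "G"]) / pmax(1, rowSums(freq[, 1:4, drop = FALSE])),
             class = cls)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()] (two-sided): exact p-value for
#' small samples without ties, asymptotic otherwise. Shared by the
#' promoter comparison and the repair-count comparison.
#'
#' @param x,y Numeric samples (non-empty).
#' @return A list with elements `D` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided"))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Promoter-class and CpG-ratio report for gene sets
#'
#' Computes per-set HCG/ICG/LCG class fractions and compares the CpG/GpC
#' ratio distributions of the G1 and G2 sets with a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param profiles Output of [profile_promoters()].
#' @param sets A [derive_gene_sets()] result (or any list with `G0`, `G1`,
#'   `G2` character vectors).
#' @return A list: `class_fractions` (data.frame set x class), `ks`
#'   ([ks_two_sample()] of G1 vs G2 ratios, `NULL` if either set is empty,
#'   with `defined` flag), `ratio_means` per set.
#' @export
setwise_report <- function(profiles, sets) {
  use <- list(G0 = sets$G0, G1 = sets$G1, G2 = sets$G2)
  unknown <- setdiff(unique(unlist(use)), profiles$gene_id)
  if (length(unknown)) {
    warning("gene ids without promoter profile: ",
            paste(utils::head(unknown, 10), collapse = ", "))
  }
  frac <- do.call(rbind, lapply(names(use), function(nm) {
    pr <- profiles[profiles$gene_id %in% use[[nm]], ]
    n <- nrow(pr)
    data.frame(set = nm, n = n,
               HCG = if (n) mean(pr$class == "HCG") else NA_real_,
               ICG = if (n) mean(pr$class == "ICG") else NA_real_,
               LCG = if (n) mean(pr$class == "LCG") else NA_real_)
  }))
  r1 <- profiles$ratio[profiles$gene_id %in% use$G1 & !is.na(profiles$ratio)]
  r2 <- profiles$ratio[profiles$gene_id %in% use$G2 & !is.na(profiles$ratio)]
  defined <- length(r1) > 0 && length(r2) > 0
  list(class_fractions = frac,
       ratio_means = c(G1 = if (length(r1)) mean(r1) else NA_real_,
                       G2 = if (length(r2)) mean(r2) else NA_real_),
       ks = if (defined) ks_two_sample(r1, r2) else NULL,
       defined = defined)
}
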