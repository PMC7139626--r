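# Synthetic genomic fixtures: gene annotations, per-mark/per-condition peak
# files with planted G1/G2 structure, and promoter sequences with
# controlled CpG/GpC statistics.

#' Specification for a synthetic genomic fixture
#'
#' Defaults echo the experimental scale being emulated: 319 planted
#' G1-like genes (H3K27me3-only
#' genes that recruit H3K4me3 in all three stress conditions), 557 planted
#' G2-like genes (never recruit H3K4me3), promoters of the G1-like set
#' drawn with a stochastically higher CpG/GpC ratio.
#'
#' @param n_genes Total number of genes.
#' @param n_G1,n_G2 Planted set sizes.
#' @param promoter_length Length of each promoter sequence (bases).
#' @param ratio_G1,ratio_G2,ratio_bg Target mean CpG/GpC ratios for
#'   G1-like, G2-like and background promoters.
#' @param ratio_sd Lognormal spread of per-promoter target ratios.
#' @param gc_G1,gc_G2,gc_bg Target GC contents.
#' @param noise Per-condition probability that a background gene's
#'   quadruplet flips one random bit.
#' @param p_0010 Probability that a background gene is an H3K27me3-only
#'   (`"0010"`) gene in the untreated wild type.
#' @param seed Integer seed.
#' @return A list of class `"synth_spec"`.
#' @export
synth_spec <- function(n_genes = 2000, n_G1 = 319, n_G2 = 557,
                       promoter_length = 4000,
                       ratio_G1 = 0.90, ratio_G2 = 0.55, ratio_bg = 0.70,
                       ratio_sd = 0.15,
                       gc_G1 = 0.58, gc_G2 = 0.48, gc_bg = 0.50,
                       noise = 0, p_0010 = 0.3, seed = 1) {
  if (n_G1 + n_G2 > n_genes) stop("planted sets exceed n_genes")
  if (noise < 0 || noise > 1) stop("noise must lie in [0, 1]")
  if (min(ratio_G1, ratio_G2, ratio_bg) <= 0) stop("ratios must be > 0")
  structure(as.list(environment()), class = "synth_spec")
}

#' First-order Markov promoter sequence with target CpG/GpC statistics
#'
#' Samples a DNA sequence from a first-order Markov chain whose stationary
#' dinucleotide frequencies hit a target GC content and CpG/GpC dinucleotide
#' ratio. The chain is built from independent base draws with the C-to-G
#' transition reweighted; the factor is solved so that the stationary
#' frequencies give exactly the requested ratio.
#'
#' @param length Sequence length (bases).
#' @param ratio Target CpG/GpC ratio (> 0).
#' @param gc Target GC content in (0, 1).
#' @return A character string of A/C/G/T.
#' @export
generate_promoter_sequence <- function(length, ratio = 0.8, gc = 0.5) {
  if (gc <= 0) {
    # degenerate AT-only sequence; CpG/GpC undefined
    return(paste(sample(c("A", "T"), length, replace = TRUE), collapse = ""))
  }
  if (gc >= 1 || ratio <= 0) stop("need 0 < gc < 1 and ratio > 0")
  markov_batch(length, ratio, gc)
}

# transition matrix achieving a target CpG/GpC ratio at given GC content
markov_matrix <- function(ratio, gc) {
  base <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  trans_for <- function(beta) {
    P <- rbind(A = base, C = base, G = base, T = base)
    colnames(P) <- names(base)
    P["C", "G"] <- base[["G"]] * beta
    P["C", ] <- P["C", ] / sum(P["C", ])
    P
  }
  achieved <- function(beta) {
    P <- trans_for(beta)
    ev <- eigen(t(P))
    pi <- Re(ev$vectors[, which.max(Re(ev$values))])
    pi <- pi / sum(pi)
    names(pi) <- colnames(P)
    (pi[["C"]] * P["C", "G"]) / (pi[["G"]] * P["G", "C"])
  }
  sol <- tryCatch(
    stats::uniroot(function(b) achieved(b) - ratio, c(1e-6, 60), tol = 1e-9),
    error = function(e) NULL)
  if (is.null(sol)) {
    stop(sprintf("target ratio %.3g infeasible at GC %.3g (achievable up to %.3g)",
                 ratio, gc, achieved(60)))
  }
  trans_for(sol$root)
}

# sample many sequences at once: one vectorised pass over positions
markov_batch <- function(length, ratios, gcs) {
  n <- base::length(ratios)
  cums <- array(0, c(n, 4, 4))
  starts <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    P <- markov_matrix(ratios[i], gcs[i])
    cums[i, , ] <- t(apply(P, 1, cumsum))
    starts[i, ] <- cumsum(c((1 - gcs[i]) / 2, gcs[i] / 2, gcs[i] / 2,
                            (1 - gcs[i]) / 2))
  }
  out <- matrix(1L, n, length)
  u <- stats::runif(n)
  cur <- 1L + (u > starts[, 1]) + (u > starts[, 2]) + (u > starts[, 3])
  out[, 1] <- cur
  rows <- seq_len(n)
  for (j in 2:length) {
    u <- stats::runif(n)
    c1 <- cums[cbind(rows, cur, 1L)]
    c2 <- cums[cbind(rows, cur, 2L)]
    c3 <- cums[cbind(rows, cur, 3L)]
    cur <- 1L + (u > c1) + (u > c2) + (u > c3)
    out[, j] <- cur
  }
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) paste(bases[out[i, ]], collapse = ""),
         character(1))
}

QUADS <- apply(expand.grid(rep(list(0:1), 4))[, 4:1], 1, paste, collapse = "")

flip_random_bit <- function(quad) {
  i <- sample.int(4, 1)
  bit <- substr(quad, i, i)
  substr(quad, i, i) <- if (bit == "0") "1" else "0"
  quad
}

#' Generate a complete synthetic peak/annotation/sequence fixture
#'
#' Writes, under `out_dir`: a BED6 gene annotation on one synthetic
#' chromosome, 16 peak BED files (4 histone marks x 4 conditions) realising
#' planted G1-like (`0010 -> 1010` under all three stress conditions) and
#' G2-like (`0010`, never H3K4me3) genes plus randomised background genes,
#' a promoter FASTA whose CpG/GpC ratios are stochastically higher for the
#' G1-like set, a ground-truth table, and a YAML manifest consumable by the
#' classification stage.
#'
#' Geometry: genes are spaced every 10 kb with alternating strand; promoter
#' marks get 1 kb peaks centred on the TSS, H3K36me3 peaks span a mock gene
#' body downstream of the TSS.
#'
#' @param spec A [synth_spec()].
#' @param out_dir Output directory (created; must not exist unless
#'   `force = TRUE`).
#' @param force Overwrite an existing directory.
#' @return Invisibly, a list with the manifest path, the ground-truth
#'   data.frame and the file map.
#' @export
generate_fixture <- function(spec, out_dir, force = FALSE) {
  stopifnot(inherits(spec, "synth_spec"))
  if (dir.exists(out_dir) && !force &&
      length(list.files(out_dir)) > 0) {
    stop("output directory exists; use force = TRUE")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  n <- spec$n_genes
  spacing <- 10000L
  tss <- seq(5000L, by = spacing, length.out = n)
  strand <- rep(c("+", "-"), length.out = n)
  ids <- sprintf("gene%04d", seq_len(n))
  chrom <- "chrS"
  chrom_len <- max(tss) + spacing

  membership <- rep("bg", n)
  planted <- sample.int(n, spec$n_G1 + spec$n_G2)
  membership[planted[seq_len(spec$n_G1)]] <- "G1"
  membership[planted[seq_len(spec$n_G2) + spec$n_G1]] <- "G2"

  # intended quadruplets per condition
  states <- matrix("0000", n, 4, dimnames = list(ids, CONDITIONS))
  bg <- membership == "bg"
  n_bg <- sum(bg)
  bg_wt <- ifelse(stats::runif(n_bg) < spec$p_0010, "0010",
                  sample(setdiff(QUADS, "0010"), n_bg, replace = TRUE))
  states[bg, "WT"] <- bg_wt
  # background (0010) genes recruit H3K4me3 in a random proper subset of
  # the stress conditions (1 or 2 of 3), so they belong to neither G1
  # (which requires all three) nor G2 (which requires none)
  n_rec <- ifelse(bg_wt == "0010", 1L + (stats::runif(n_bg) < 0.5), 0L)
  rec_conds <- lapply(n_rec, function(k)
    if (k > 0) sample(STRESS_CONDITIONS, k) else character(0))
  for (cond in STRESS_CONDITIONS) {
    st <- bg_wt
    recruits <- vapply(rec_conds, function(x) cond %in% x, logical(1))
    substr(st[recruits], 1, 1) <- "1"
    flip <- stats::runif(n_bg) < spec$noise
    st[flip] <- vapply(st[flip], flip_random_bit, character(1))
    states[bg, cond] <- st
  }
  states[membership == "G1", "WT"] <- "0010"
  states[membership == "G1", STRESS_CONDITIONS] <- "1010"
  states[membership == "G2", ] <- "0010"

  # gene annotation (BED6, 0-based half-open; TSS at interval start for +,
  # end-1 for -)
  body_len <- 3000L
  gene_start <- ifelse(strand == "+", tss, tss - body_len)
  gene_end <- ifelse(strand == "+", tss + body_len, tss + 1L)
  genes_bed <- data.frame(chrom = chrom, start = gene_start,
                          end = gene_end, name = ids, score = 0,
                          strand = strand)
  gene_file <- file.path(out_dir, "genes.bed")
  utils::write.table(genes_bed, gene_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # peak files per mark x condition
  peak_files <- list()
  for (cond in CONDITIONS) {
    peak_files[[cond]] <- list()
    for (mi in seq_along(MARKS)) {
      mark <- MARKS[mi]
      has <- substr(states[, cond], mi, mi) == "1"
      if (mark == "H3K36me3") {
        p_start <- ifelse(strand == "+", tss + 500L, tss - 500L - body_len)
        p_end <- p_start + body_len
      } else {
        p_start <- tss - 500L
        p_end <- tss + 500L
      }
      df <- data.frame(chrom = chrom, start = p_start[has],
                       end = p_end[has],
                       name = sprintf("%s_%s_pk%d", mark, cond,
                                      seq_len(sum(has))),
                       score = 100, strand = ".")
      f <- file.path(out_dir, sprintf("%s_%s.bed", mark, cond))
      utils::write.table(df, f, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      peak_files[[cond]][[mark]] <- f
    }
  }

  # promoter sequences
  ratio_mean <- c(G1 = spec$ratio_G1, G2 = spec$ratio_G2, bg = spec$ratio_bg)
  gc_mean <- c(G1 = spec$gc_G1, G2 = spec$gc_G2, bg = spec$gc_bg)
  ratios <- ratio_mean[membership] *
    exp(stats::rnorm(n, 0, spec$ratio_sd))
  gcs <- pmin(0.75, pmax(0.3,
    gc_mean[membership] + stats::rnorm(n, 0, 0.03)))
  seqs <- markov_batch(spec$promoter_length, ratios, gcs)
  fasta_file <- file.path(out_dir, "promoters.fa")
  writeLines(paste0(">", ids, "\n",
                    vapply(seqs, function(s)
                      paste(substring(s, seq(1, nchar(s), 80),
                            pmin(nchar(s), seq(80, nchar(s) + 79, 80))),
                            collapse = "\n"), character(1))),
             fasta_file)

  truth <- data.frame(gene_id = rep(ids, each = 4),
                      condition = rep(CONDITIONS, n),
                      quadruplet = as.vector(t(states)),
                      set = rep(membership, each = 4),
                      target_ratio = rep(ratios, each = 4))
  truth_file <- file.path(out_dir, "ground_truth.tsv")
  utils::write.table(truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    genome = list(chrom = chrom, length = chrom_len),
    genes = basename(gene_file),
    promoters = basename(fasta_file),
    ground_truth = basename(truth_file),
    conditions = lapply(stats::setNames(nm = CONDITIONS), function(cond)
      lapply(stats::setNames(nm = MARKS), function(mark)
        basename(peak_files[[cond]][[mark]]))),
    spec = unclass(spec))
  manifest_file <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_file)
  invisible(list(manifest = manifest_file, truth = truth,
                 genes = gene_file, peaks = peak_files,
                 promoters = fasta_file))
}

#' Load the peak file map from a fixture manifest
#'
#' @param manifest_file Path to a `manifest.yaml` written by
#'   [generate_fixture()].
#' @return A list with `genes` (GRanges), `peaks` (nested condition/mark
#'   list of GRanges), `promoters` (DNAStringSet), `truth` (data.frame).
#' @export
read_fixture <- function(manifest_file) {
  m <- yaml::read_yaml(manifest_file)
  dir <- dirname(manifest_file)
  peaks <- lapply(m$conditions, function(cond)
    lapply(cond, function(f) rtracklayer::import(file.path(dir, f))))
  list(genes = read_genes(file.path(dir, m$genes)),
       peaks = peaks,
       promoters = Biostrings::readDNAStringSet(file.path(dir, m$promoters)),
       truth = utils::read.delim(file.path(dir, m$ground_truth),
                                 colClasses = c(quadruplet = "character")))
}
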