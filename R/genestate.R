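# Histone-state quadruplet classification of genes from peak intervals and
# derivation of the G1/G2 gene sets.

MARKS <- c("H3K4me3", "H3K9me3", "H3K27me3", "H3K36me3")
CONDITIONS <- c("WT", "WT_rad", "KO", "KO_rad")
STRESS_CONDITIONS <- c("WT_rad", "KO", "KO_rad")

#' Read a gene annotation into a GRanges object
#'
#' Accepts a BED6 or GFF3 file; gene identifiers are taken from the BED
#' name column or the GFF `ID`/`Name`/`gene_id` attribute. When a gene id
#' occurs on several rows (multiple annotated transcription starts) the
#' 5'-most start per gene is kept.
#'
#' @param path BED6 or GFF3 file path.
#' @return A `GRanges` with a `gene_id` metadata column.
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path)
  ids <- if (!is.null(gr$name)) gr$name
         else if (!is.null(gr$ID)) gr$ID
         else if (!is.null(gr$gene_id)) gr$gene_id
         else if (!is.null(gr$Name)) gr$Name
         else stop("no gene identifier column found in ", path)
  gr$gene_id <- as.character(ids)
  # 5'-most TSS per gene id
  tss <- GenomicRanges::resize(gr, width = 1, fix = "start")
  ord <- order(gr$gene_id,
               ifelse(as.character(BiocGenerics::strand(gr)) == "-",
                      -BiocGenerics::start(tss), BiocGenerics::start(tss)))
  gr <- gr[ord]
  gr[!duplicated(gr$gene_id)]
}

#' Promoter windows around transcription start sites
#'
#' Strand-oriented half-open windows `[TSS - up, TSS + down)` in 0-based
#' coordinates (the returned `GRanges` uses the usual 1-based closed
#' convention internally).
#'
#' @param genes A `GRanges` with a `gene_id` column (see [read_genes()]).
#' @param up,down Bases upstream/downstream of the TSS.
#' @return A `GRanges` of promoter windows.
#' @export
promoter_windows <- function(genes, up = 2000, down = 2000) {
  GenomicRanges::trim(GenomicRanges::promoters(
    GenomicRanges::resize(genes, width = 1, fix = "start"),
    upstream = up, downstream = down))
}

#' Assign 0/1 histone-state quadruplets to genes
#'
#' For each gene and condition, a mark's bit is 1 iff at least `min_overlap`
#' bases of any peak of that mark overlap the promoter window. The
#' quadruplet is ordered (H3K4me3, H3K9me3, H3K27me3, H3K36me3).
#'
#' @param genes A `GRanges` with `gene_id` (see [read_genes()]).
#' @param peaks A nested list `peaks[[condition]][[mark]]` of `GRanges` (or
#'   BED file paths) for the four marks in the four conditions.
#' @param up,down Promoter window extent around the TSS.
#' @param min_overlap Minimum overlap in bases (default 1).
#' @return A data.frame with columns `gene_id`, `condition`, `quadruplet`,
#'   ordered by gene then condition.
#' @export
assign_quadruplets <- function(genes, peaks, up = 2000, down = 2000,
                               min_overlap = 1) {
  prom <- promoter_windows(genes, up, down)
  conditions <- names(peaks)
  out <- list()
  for (cond in conditions) {
    bits <- matrix(0L, length(prom), length(MARKS),
                   dimnames = list(NULL, MARKS))
    for (mark in MARKS) {
      pk <- peaks[[cond]][[mark]]
      if (is.null(pk)) stop("missing peaks for ", mark, " in ", cond)
      if (is.character(pk)) pk <- rtracklayer::import(pk)
      shared <- intersect(GenomeInfoDb::seqlevels(pk),
                          GenomeInfoDb::seqlevels(prom))
      if (length(shared) == 0 && length(pk) > 0) {
        warning("no shared chromosomes between genes and ", mark,
                " peaks in ", cond)
      }
      hits <- GenomicRanges::findOverlaps(prom, pk,
                                          minoverlap = min_overlap)
      bits[unique(S4Vectors::queryHits(hits)), mark] <- 1L
    }
    out[[cond]] <- data.frame(
      gene_id = prom$gene_id, condition = cond,
      quadruplet = apply(bits, 1, paste, collapse = ""))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, match(res$condition, CONDITIONS)), ]
  rownames(res) <- NULL
  res
}

#' Derive the G0/G1/G2 gene sets from quadruplet states
#'
#' `G0` is the set of genes exclusively H3K27me3-modified (`"0010"`) in the
#' untreated wild type. `G1` comprises the G0 genes that switch to the
#' bivalent promoter state `"1010"` in all three stress conditions
#' (irradiated wild type, Msh2-deficient, irradiated Msh2-deficient);
#' `G2` the G0 genes that never recruit H3K4me3 under stress (H3K4me3 bit 0
#' in all three; `strict = TRUE` additionally requires the full state to
#' stay `"0010"`).
#'
#' @param states Output of [assign_quadruplets()] covering all four
#'   conditions for every gene.
#' @param strict Use the strict G2 definition (state `"0010"` in all
#'   conditions) instead of constraining only the H3K4me3 bit.
#' @return A list of class `"gene_sets"`: character vectors `G0`, `G1`,
#'   `G2`, and `transitions`, a table of WT-state x stress-state counts
#'   over the three stress conditions.
#' @export
derive_gene_sets <- function(states, strict = FALSE) {
  if (nrow(states) == 0) {
    return(structure(list(G0 = character(0), G1 = character(0),
                          G2 = character(0),
                          transitions = table(character(0), character(0))),
                     class = "gene_sets"))
  }
  wide <- stats::reshape(states, idvar = "gene_id", timevar = "condition",
                         direction = "wide")
  names(wide) <- sub("^quadruplet\\.", "", names(wide))
  missing <- CONDITIONS[!CONDITIONS %in% names(wide)]
  if (length(missing)) stop("missing condition(s): ",
                            paste(missing, collapse = ", "))
  incomplete <- apply(is.na(wide[, CONDITIONS]), 1, any)
  if (any(incomplete)) {
    stop("genes lacking a state in some condition: ",
         paste(utils::head(wide$gene_id[incomplete], 10), collapse = ", "))
  }
  g0 <- wide$WT == "0010"
  stress <- as.matrix(wide[, STRESS_CONDITIONS])
  all_1010 <- rowSums(stress == "1010") == 3
  k4_bit <- matrix(substr(stress, 1, 1), nrow(stress))
  never_k4 <- rowSums(k4_bit == "0") == 3
  g2_rule <- if (strict) rowSums(stress == "0010") == 3 else never_k4
  transitions <- table(WT = rep(wide$WT, 3), stress = as.vector(stress))
  structure(list(G0 = wide$gene_id[g0],
                 G1 = wide$gene_id[g0 & all_1010],
                 G2 = wide$gene_id[g0 & g2_rule],
                 transitions = transitions),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("Gene sets: G0 =", length(x$G0), "| G1 =", length(x$G1),
      "| G2 =", length(x$G2), "\n")
  invisible(x)
}
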