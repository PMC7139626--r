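# shared helpers: tiny in-memory genomic objects built in code

# tss is 0-based (like BED); the GRanges uses 1-based closed coordinates
make_genes <- function(tss = c(1000L, 5000L, 9000L),
                       strand = c("+", "-", "+"),
                       ids = sprintf("g%d", seq_along(tss)),
                       chrom = "chr1") {
  GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = ifelse(strand == "+", tss + 1L, tss - 499L),
                     width = 501L),
    strand = strand, gene_id = ids)
}

peak_gr <- function(starts, ends, chrom = "chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts + 1L, ends))
}

# peaks list with every mark empty except those given
make_peaks <- function(per_condition, chrom = "chr1") {
  empty <- GenomicRanges::GRanges()
  lapply(per_condition, function(marks) {
    out <- list(H3K4me3 = empty, H3K9me3 = empty,
                H3K27me3 = empty, H3K36me3 = empty)
    for (nm in names(marks)) out[[nm]] <- marks[[nm]]
    out
  })
}

# brute-force quadruplet oracle: O(genes x peaks) interval scan on
# 0-based half-open promoter windows
oracle_quadruplets <- function(genes, peaks, up = 2000, down = 2000) {
  tss0 <- ifelse(as.character(BiocGenerics::strand(genes)) == "+",
                 BiocGenerics::start(genes) - 1L,
                 BiocGenerics::end(genes) - 1L)
  lo <- ifelse(as.character(BiocGenerics::strand(genes)) == "+",
               tss0 - up, tss0 - down + 1L)
  hi <- lo + up + down  # [lo, hi) half-open
  rows <- list()
  for (cond in names(peaks)) {
    quad <- character(length(genes))
    for (i in seq_along(genes)) {
      bits <- vapply(MARKS, function(mark) {
        pk <- peaks[[cond]][[mark]]
        if (length(pk) == 0) return(0L)
        ps <- BiocGenerics::start(pk) - 1L
        pe <- BiocGenerics::end(pk)
        any(pmin(hi[i], pe) - pmax(lo[i], ps) >= 1) * 1L
      }, integer(1))
      quad[i] <- paste(bits, collapse = "")
    }
    rows[[cond]] <- data.frame(gene_id = genes$gene_id, condition = cond,
                               quadruplet = quad)
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$gene_id, match(res$condition, CONDITIONS)), ]
  rownames(res) <- NULL
  res
}
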