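# quadruplet assignment and G1/G2 set derivation

test_that("quadruplet bits follow peak overlap with the promoter window", {
  genes <- make_genes(tss = c(10000L, 30000L, 50000L),
                      strand = c("+", "+", "-"))
  k27 <- peak_gr(c(9500L, 29500L, 49500L), c(10500L, 30500L, 50500L))
  base <- make_peaks(list(
    WT = list(H3K27me3 = k27),
    WT_rad = list(H3K27me3 = k27),
    KO = list(H3K27me3 = k27),
    KO_rad = list(H3K27me3 = k27)))
  st <- assign_quadruplets(genes, base)
  expect_equal(nrow(st), 12)
  expect_true(all(st$quadruplet == "0010"))

  # no peaks at all -> 0000
  none <- make_peaks(list(WT = list(), WT_rad = list(), KO = list(),
                          KO_rad = list()))
  st0 <- assign_quadruplets(genes, none)
  expect_true(all(st0$quadruplet == "0000"))
})

test_that("half-open boundary: a peak ending exactly at window start is no overlap", {
  genes <- make_genes(tss = 10000L, strand = "+", ids = "g1")
  # promoter window is [8000, 12000) in 0-based half-open coordinates
  just_out <- peak_gr(7900L, 8000L)   # ends at 8000 exclusive
  just_in  <- peak_gr(7900L, 8001L)   # one base inside
  mk <- function(pk) make_peaks(list(WT = list(H3K4me3 = pk),
    WT_rad = list(), KO = list(), KO_rad = list()))
  st_out <- assign_quadruplets(genes, mk(just_out))
  st_in <- assign_quadruplets(genes, mk(just_in))
  expect_equal(st_out$quadruplet[st_out$condition == "WT"], "0000")
  expect_equal(st_in$quadruplet[st_in$condition == "WT"], "1000")
})

test_that("overlap engine matches a brute-force scan on random intervals", {
  set.seed(42)
  genes <- make_genes(tss = sort(sample(5000:95000, 30)) ,
                      strand = sample(c("+", "-"), 30, replace = TRUE),
                      ids = sprintf("g%02d", 1:30))
  rand_peaks <- function(n) {
    s <- sample(0:100000, n)
    peak_gr(s, s + sample(200:3000, n, replace = TRUE))
  }
  peaks <- lapply(stats::setNames(nm = CONDITIONS), function(cond)
    lapply(stats::setNames(nm = MARKS), function(mark) rand_peaks(15)))
  got <- assign_quadruplets(genes, peaks)
  want <- oracle_quadruplets(genes, peaks)
  expect_equal(got, want)
})

test_that("peak row order does not affect quadruplets", {
  set.seed(9)
  genes <- make_genes(tss = c(10000L, 20000L, 30000L))
  pk <- peak_gr(c(9800L, 19800L, 29800L), c(10200L, 20200L, 30200L))
  mk <- function(p) make_peaks(list(WT = list(H3K9me3 = p), WT_rad = list(),
                                    KO = list(), KO_rad = list()))
  st1 <- assign_quadruplets(genes, mk(pk))
  st2 <- assign_quadruplets(genes, mk(rev(pk)))
  expect_equal(st1, st2)
})

test_that("gene set derivation implements the G1/G2 state rules", {
  quads <- function(wt, s1, s2, s3) c(WT = wt, WT_rad = s1, KO = s2,
                                      KO_rad = s3)
  tab <- rbind(
    g_g1  = quads("0010", "1010", "1010", "1010"),  # G1: all three switch
    g_2of3 = quads("0010", "1010", "1010", "0010"), # only 2 of 3
    g_g2  = quads("0010", "0010", "0011", "0010"),  # never H3K4me3
    g_non = quads("0110", "1010", "1010", "1010"),  # not 0010 in WT
    g_k4  = quads("0010", "1010", "1110", "1011"))  # K4 everywhere, not 1010
  states <- data.frame(
    gene_id = rep(rownames(tab), each = 4),
    condition = rep(CONDITIONS, nrow(tab)),
    quadruplet = as.vector(t(tab)))
  gs <- derive_gene_sets(states)
  expect_setequal(gs$G0, c("g_g1", "g_2of3", "g_g2", "g_k4"))
  expect_equal(gs$G1, "g_g1")
  expect_setequal(gs$G2, "g_g2")
  expect_false("g_2of3" %in% c(gs$G1, gs$G2))
  # strict mode drops genes that gained other marks
  gs_strict <- derive_gene_sets(states, strict = TRUE)
  expect_equal(gs_strict$G2, character(0))
  # invariants
  expect_length(intersect(gs$G1, gs$G2), 0)
  expect_true(all(c(gs$G1, gs$G2) %in% gs$G0))
})

test_that("incomplete conditions raise an informative error; empty input works", {
  states <- data.frame(gene_id = "g1", condition = "WT",
                       quadruplet = "0010")
  expect_error(derive_gene_sets(states), "missing condition")
  empty <- derive_gene_sets(data.frame(gene_id = character(0),
                                       condition = character(0),
                                       quadruplet = character(0)))
  expect_length(empty$G1, 0)
  expect_length(empty$G2, 0)
})
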