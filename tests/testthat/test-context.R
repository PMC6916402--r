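test_that("classifyContext follows the two-downstream-base rule", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGA", chr2 = "ACAGT",
                                  chr3 = "ACTTG", chr4 = "TTCGT"))
  expect_equal(classifyContext(g, "chr1", 2, "+"), "CpG")
  expect_equal(classifyContext(g, "chr2", 2, "+"), "CHG")
  expect_equal(classifyContext(g, "chr3", 2, "+"), "CHH")
  # reverse-strand C at the forward G of TTCGT reads 5'-CG: CpG
  expect_equal(classifyContext(g, "chr4", 4, "-"), "CpG")
  expect_error(classifyContext(g, "chr1", 1, "+"), "not a cytosine")
})

test_that("enumerateCytosines emits each strand's cytosine exactly once", {
  g <- Biostrings::DNAStringSet(c(chr1 = "CG"))
  s <- enumerateCytosines(g)
  expect_equal(length(s), 2L)
  expect_equal(as.character(GenomicRanges::strand(s)), c("+", "-"))
  expect_equal(S4Vectors::mcols(s)$context, c("CpG", "CpG"))

  expect_equal(length(enumerateCytosines(
    Biostrings::DNAStringSet(c(chr1 = "AAA")))), 0L)

  # CNG: forward C has N in triplet; reverse C (the G) runs into N then edge
  s2 <- enumerateCytosines(Biostrings::DNAStringSet(c(chr1 = "CNG")))
  expect_equal(length(s2), 2L)
  expect_equal(unique(S4Vectors::mcols(s2)$context), "boundary")
})

test_that("context labels partition all cytosines on random sequences", {
  set.seed(42)
  for (i in 1:5) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 500, replace = TRUE,
                        prob = c(.24, .24, .24, .24, .04)), collapse = "")
    g <- Biostrings::DNAStringSet(c(chr1 = seq))
    s <- enumerateCytosines(g)
    v <- strsplit(seq, "")[[1]]
    expect_equal(length(s), sum(v == "C") + sum(v == "G"))
    expect_equal(anyDuplicated(paste(GenomicRanges::start(s),
                                     GenomicRanges::strand(s))), 0L)
    expect_true(all(S4Vectors::mcols(s)$context %in%
                    c("CpG", "CHG", "CHH", "boundary")))
  }
  # strand symmetry on a sequence equal to its own reverse complement
  pal <- "ACGCGT"
  s <- enumerateCytosines(Biostrings::DNAStringSet(c(chr1 = pal)))
  ctx <- S4Vectors::mcols(s)$context
  std <- as.character(GenomicRanges::strand(s))
  expect_equal(sum(ctx == "CpG" & std == "+"), sum(ctx == "CpG" & std == "-"))
})

test_that("windowComposition computes O/E and footprint ratios", {
  g <- Biostrings::DNAStringSet(c(chr1 = "CGCG"))
  w <- windowComposition(g, window = 4L)
  expect_equal(S4Vectors::mcols(w)$cpg_oe, 2 * 4 / (2 * 2))
  expect_equal(S4Vectors::mcols(w)$cg_ratio, 1)

  w2 <- windowComposition(Biostrings::DNAStringSet(c(chr1 = "ATAT")),
                          window = 4L)
  expect_equal(S4Vectors::mcols(w2)$cg_ratio, 0)
  expect_true(is.na(S4Vectors::mcols(w2)$cpg_oe))

  w3 <- windowComposition(Biostrings::DNAStringSet(c(chr1 = "ACGTACGT")),
                          window = 8L)
  expect_equal(S4Vectors::mcols(w3)$cpg_ratio, 4 / 8)

  # tiling without double counting; last partial window flagged
  g4 <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 7), collapse = "")))
  w4 <- windowComposition(g4, window = 10L)
  expect_equal(sum(GenomicRanges::width(w4)), 28L)
  expect_equal(S4Vectors::mcols(w4)$partial, c(FALSE, FALSE, TRUE))
  # all footprint ratios stay in [0, 1] even on repetitive sequence
  g5 <- Biostrings::DNAStringSet(c(chr1 = strrep("C", 50)))
  w5 <- windowComposition(g5, window = 50L)
  rat <- S4Vectors::mcols(w5)
  expect_true(all(c(rat$cpg_ratio, rat$chg_ratio, rat$chh_ratio) >= 0))
  expect_true(all(c(rat$cpg_ratio, rat$chg_ratio, rat$chh_ratio) <= 1))
})

test_that("detectCgi finds CG-rich islands and respects min_len", {
  cg300 <- strrep("CG", 150)
  polyA <- strrep("A", 2000)
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(polyA, cg300, polyA)))
  cgi <- detectCgi(g)
  expect_equal(length(cgi), 1L)
  expect_true(GenomicRanges::start(cgi) <= 2001 + 1 &&
              GenomicRanges::end(cgi) >= 2300 - 1)
  expect_true(all(GenomicRanges::width(cgi) >= 200))

  expect_equal(length(detectCgi(Biostrings::DNAStringSet(
    c(chr1 = strrep("A", 10000))))), 0L)

  g150 <- Biostrings::DNAStringSet(
    c(chr1 = paste0(polyA, strrep("CG", 75), polyA)))
  expect_equal(length(detectCgi(g150)), 0L)

  # output sorted and non-overlapping
  g2 <- Biostrings::DNAStringSet(c(chr1 = paste0(polyA, cg300, polyA,
                                                 cg300, polyA)))
  cgi2 <- detectCgi(g2)
  expect_equal(length(cgi2), 2L)
  expect_true(all(GenomicRanges::start(cgi2)[-1] >
                  GenomicRanges::end(cgi2)[-length(cgi2)]))
})

test_that("correlateWindowStat reports r, drops undefined, flags zero variance", {
  w <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 11, 21, 31), width = 10),
    cpg_oe = c(1, 2, 3, 4), partial = FALSE)
  r1 <- correlateWindowStat(w, "cpg_oe", c(1, 2, 3, 4))
  expect_equal(r1$r, 1)
  r2 <- correlateWindowStat(w, "cpg_oe", -c(1, 2, 3, 4))
  expect_equal(r2$r, -1)
  r3 <- correlateWindowStat(w, "cpg_oe", rep(5, 4))
  expect_true(r3$flagged)
  expect_true(is.na(r3$r))

  # seeded simulation: MLgf decreasing in cpg_oe plus noise
  set.seed(99)
  oe <- runif(100, 0.2, 1.5)
  ml <- 0.05 - 0.02 * oe + rnorm(100, 0, 0.004)
  ws <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, by = 10, length.out = 100), width = 10),
    cpg_oe = oe, partial = FALSE)
  rs <- correlateWindowStat(ws, "cpg_oe", ml)
  expect_lt(rs$r, 0)
  expect_lt(rs$p, 0.05)
})
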