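test_that("exactTest2x2 matches enumeration and fisher.test", {
  expect_equal(as.numeric(exactTest2x2(5, 5, 5, 5)), 1)
  # frozen from the enumeration oracle, margins (10,10 | 10,10)
  expect_equal(as.numeric(exactTest2x2(10, 0, 0, 10)),
               oracleFisher2x2(10, 0, 0, 10), tolerance = 1e-12)
  expect_lt(abs(as.numeric(exactTest2x2(10, 0, 0, 10)) - 1.082509e-05),
            1e-10)
  expect_equal(as.numeric(exactTest2x2(0, 20, 10, 10)),
               oracleFisher2x2(0, 20, 10, 10), tolerance = 1e-12)

  # symmetry under simultaneous row and column swap
  set.seed(5)
  m1 <- rpois(50, 4); u1 <- rpois(50, 6)
  m2 <- rpois(50, 2); u2 <- rpois(50, 8)
  expect_equal(as.numeric(exactTest2x2(m1, u1, m2, u2)),
               as.numeric(exactTest2x2(u2, m2, u1, m1)))

  # agreement with the stats implementation on random tables
  for (i in 1:25) {
    t4 <- rpois(4, 8)
    ours <- as.numeric(exactTest2x2(t4[1], t4[2], t4[3], t4[4]))
    ref <- stats::fisher.test(matrix(t4, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-7)
  }

  # degenerate margins: p = 1 and flagged
  p <- exactTest2x2(c(0, 3), c(0, 2), c(0, 4), c(5, 1))
  expect_equal(as.numeric(p)[1], 1)
  expect_true(attr(p, "degenerate")[1])
  expect_false(attr(p, "degenerate")[2])
})

test_that("bhFdr performs the step-up adjustment", {
  expect_equal(bhFdr(0.05), 0.05)
  expect_equal(bhFdr(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bhFdr(c(0.04, 0.01)), c(0.04, 0.02))  # order preserved
  set.seed(8)
  p <- runif(100)
  q <- bhFdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_equal(q, p.adjust(p, "BH"))
})

test_that("callDms applies p and fold thresholds with direction", {
  tab <- data.frame(chrom = "chr1", pos = c(10, 20, 30),
                    strand = "+", context = "CpG")
  meth <- cbind(A_1 = c(12L, 5L, 0L), B_1 = c(0L, 5L, 0L))
  unmeth <- cbind(A_1 = c(0L, 5L, 12L), B_1 = c(12L, 5L, 12L))
  ms <- msFromTable(tab, meth, unmeth, stages = c("A", "B"))
  dms <- callDms(ms, "A", "B")
  mc <- S4Vectors::mcols(dms)
  expect_true(mc$called[1])
  expect_equal(mc$direction[1], "hyper-in-group1")
  expect_equal(mc$p[1], oracleFisher2x2(12, 0, 0, 12), tolerance = 1e-12)
  expect_false(mc$called[2])   # identical counts are never called
  expect_false(mc$called[3])
  expect_true(all(mc$q >= mc$p))
})

test_that("callDmrs emits non-overlapping windows meeting all criteria", {
  set.seed(31)
  cfg <- simConfig(genome_length = 2e5, n_chrom = 1, n_genes = 10,
                   n_te = 5, n_lncrna = 3, n_circrna = 2, n_trna = 2,
                   n_cgi = 2, n_dmr = 4, stages = c("A", "B"),
                   stage_scale = c(A = 1, B = 1), n_coupled = 0,
                   coupled_stage = "B", medip_stage = "B",
                   do_medip = FALSE, do_expression = FALSE)
  st <- simulateStudy(cfg, seed = 31)
  dmrs <- callDmrs(st$methylome, "A", "B", st$genome)
  expect_gt(length(dmrs), 0)
  mc <- S4Vectors::mcols(dmrs)
  expect_true(all(abs(mc$area_stat) >= 40))
  expect_true(all(mc$pooled_fold > 6))
  expect_true(all(mc$pooled_p < 0.05))
  expect_true(all(mc$n_sites >= 3))
  srt <- GenomicRanges::sort(dmrs, ignore.strand = TRUE)
  if (length(srt) > 1)
    expect_true(all(GenomicRanges::start(srt)[-1] >
                    GenomicRanges::end(srt)[-length(srt)]))

  # antisymmetry under group exchange: same regions, flipped direction
  swapped <- callDmrs(st$methylome, "B", "A", st$genome)
  expect_equal(GenomicRanges::start(dmrs), GenomicRanges::start(swapped))
  expect_equal(S4Vectors::mcols(dmrs)$area_stat,
               -S4Vectors::mcols(swapped)$area_stat)
  expect_true(all(S4Vectors::mcols(dmrs)$direction !=
                  S4Vectors::mcols(swapped)$direction))
})

test_that("callDmps derives strand-aware clipped promoters", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 3000)))
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(5001, 5001, 501), c(8000, 8000, 800)),
    strand = c("+", "-", "+"),
    elementClass = "gene", elementId = c("gp", "gm", "edge"))
  tab <- data.frame(chrom = "chr1", pos = c(3500, 9000), strand = "+",
                    context = "CpG")
  meth <- cbind(A_1 = c(5L, 5L), B_1 = c(5L, 5L))
  ms <- msFromTable(tab, meth, meth, stages = c("A", "B"))
  dmp <- callDmps(ms, genes, "A", "B", g)
  expect_equal(GenomicRanges::start(dmp)[1], 3001L)  # [3001,5000] upstream
  expect_equal(GenomicRanges::end(dmp)[1], 5000L)
  expect_equal(GenomicRanges::start(dmp)[2], 8001L)  # downstream of minus gene
  expect_equal(GenomicRanges::end(dmp)[2], 10000L)
  expect_equal(GenomicRanges::start(dmp)[3], 1L)     # clipped at the edge
  expect_equal(GenomicRanges::end(dmp)[3], 500L)
  expect_true(S4Vectors::mcols(dmp)$clipped[3])
  expect_false(any(S4Vectors::mcols(dmp)$called))
})

test_that("classifyHyper maps direction to the hypermethylated stage", {
  d <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 100), width = 50),
    direction = c("hyper-in-group1", "hyper-in-group2"))
  S4Vectors::metadata(d)$groups <- c("SP", "MG")
  h <- classifyHyper(list(sp_mg = d))
  expect_equal(S4Vectors::mcols(h)$hyper_stage, c("SP", "MG"))
  expect_equal(S4Vectors::mcols(h)$hypo_stage, c("MG", "SP"))
  # swapping groups flips the labels
  d2 <- d
  S4Vectors::mcols(d2)$direction <- rev(S4Vectors::mcols(d)$direction)
  S4Vectors::metadata(d2)$groups <- c("MG", "SP")
  h2 <- classifyHyper(list(x = d2))
  expect_equal(S4Vectors::mcols(h2)$hyper_stage, c("SP", "MG"))
})

test_that("overlapElements reports exact overlap widths", {
  dmr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  el <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 400),
    elementClass = "exon", elementId = "e1")
  ov <- overlapElements(dmr, el)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$overlap_bp, 50L)

  far <- GenomicRanges::shift(el, 1000)
  expect_equal(nrow(overlapElements(dmr, far)), 0L)

  set.seed(12)
  a <- GenomicRanges::GRanges(sample(c("chr1", "chr2"), 60, TRUE),
    IRanges::IRanges(sample(1e4, 60), width = sample(50:500, 60, TRUE)))
  b <- GenomicRanges::GRanges(sample(c("chr1", "chr2"), 60, TRUE),
    IRanges::IRanges(sample(1e4, 60), width = sample(50:500, 60, TRUE)),
    elementClass = "TE", elementId = paste0("t", 1:60))
  ours <- overlapElements(a, b)
  brute <- bruteOverlap(a, b)
  expect_equal(nrow(ours), nrow(brute))
  o1 <- ours[order(ours$dmr_id, ours$element_id), ]
  b1 <- brute[order(paste0("dmr", brute$i), paste0("t", brute$j)), ]
  expect_equal(o1$overlap_bp, b1$overlap_bp)
})
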