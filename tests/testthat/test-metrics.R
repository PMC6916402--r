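test_that("siteML is the methylated-read fraction", {
  expect_identical(siteML(3, 1), 0.75)
  expect_identical(siteML(0, 5), 0)
  expect_identical(siteML(4, 0), 1)
  expect_true(is.na(siteML(0, 0)))
  expect_error(siteML(-1, 2))
})

test_that("estimateConversion measures the lambda nonconversion rate", {
  gr <- GenomicRanges::GRanges("lambda",
    IRanges::IRanges(1:100, width = 1), strand = "+",
    meth = c(rep(1L, 5), rep(0L, 95)), unmeth = rep(100L, 100) - c(rep(1L, 5), rep(0L, 95)),
    context = "CHH")
  est <- estimateConversion(gr)
  expect_equal(est$nonconversion, 5 / 10000)
  expect_equal(est$conversion, 1 - 5 / 10000)
  expect_equal(est$n_lambda_reads, 10000)

  gr0 <- gr
  S4Vectors::mcols(gr0)$meth <- 0L
  S4Vectors::mcols(gr0)$unmeth <- 100L
  expect_equal(estimateConversion(gr0)$conversion, 1)

  expect_error(estimateConversion(gr[as.character(
    GenomicRanges::seqnames(gr)) != "lambda"]))

  # binomial sampling oracle: planted failure 4e-4 over 50000 reads
  set.seed(17)
  n_sites <- 500L; cov <- 100L
  meth <- rbinom(n_sites, cov, 4e-4)
  grs <- GenomicRanges::GRanges("lambda",
    IRanges::IRanges(seq_len(n_sites), width = 1), strand = "+",
    meth = meth, unmeth = cov - meth, context = "CHH")
  est2 <- estimateConversion(grs)
  se <- sqrt(4e-4 * (1 - 4e-4) / (n_sites * cov))
  expect_lt(abs(est2$nonconversion - 4e-4), 3 * se)
})

test_that("callMC enforces coverage, evidence and the binomial guard", {
  r1 <- callMC(4, 0, nonconversion = 5e-4)
  expect_true(r1$is_mC)
  expect_equal(r1$ml, 1)

  r2 <- callMC(2, 1, nonconversion = 5e-4)   # coverage 3 < 4
  expect_false(r2$is_mC)

  r3 <- callMC(0, 10, nonconversion = 5e-4)
  expect_false(r3$is_mC)
  expect_equal(r3$ml, 0)

  # binomial guard: 1 methylated read in very deep coverage is explicable
  # by conversion failure alone
  r4 <- callMC(1, 1999, nonconversion = 5e-4)
  expect_false(r4$is_mC)

  # alternative reading of the four-read rule: methylated reads >= 4
  r5 <- callMC(3, 1, nonconversion = 5e-4, rule = "meth")
  expect_false(r5$is_mC)
  expect_true(callMC(4, 26, nonconversion = 5e-4, rule = "meth")$is_mC)
})

test_that("filterHetSites removes exactly the confounded intersection", {
  sites <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100, 100, 200), width = 1),
    strand = c("+", "-", "+"), ml = c(0.5, 0.5, 0.5), is_mC = TRUE)
  v <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100, 201), width = 1),
    ref = c("C", "A"), alt = c("T", "G"))
  out <- filterHetSites(sites, v)
  # + strand C at 100 removed (C>T); - strand site at 100 kept (not G>A);
  # site at 200 kept (variant at 201 and not C>T anyway)
  expect_equal(length(out), 2L)
  expect_equal(S4Vectors::metadata(out)$het_removed_fraction, 1 / 3)
  expect_equal(length(filterHetSites(out, v)), 2L)  # idempotent
  expect_equal(length(filterHetSites(sites, v[0])), 3L)  # identity

  vga <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, width = 1),
                                ref = "G", alt = "A")
  expect_equal(as.character(GenomicRanges::strand(
    filterHetSites(sites, vga))), c("+", "+"))
})

test_that("fragmentML divides summed site levels by fragment C+G", {
  g <- Biostrings::DNAStringSet(c(chr1 = "CCGG"))
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2, width = 1),
    strand = "+", context = "CpG", coverage = 10L, ml = 0.5, is_mC = TRUE)
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 4))
  fm <- fragmentML(sites, iv, g)
  expect_equal(S4Vectors::mcols(fm)$mlgf, 0.5 / 4)
  expect_equal(S4Vectors::mcols(fm)$n_mC, 1L)

  # no mC -> 0, still defined
  fm0 <- fragmentML(sites[0], iv, g)
  expect_equal(S4Vectors::mcols(fm0)$mlgf, 0)
  expect_false(S4Vectors::mcols(fm0)$is_methylated_element)

  # both strands of one CpG fully methylated attain the upper bound
  g2 <- Biostrings::DNAStringSet(c(chr1 = "CG"))
  s2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 2), width = 1),
    strand = c("+", "-"), context = "CpG", coverage = 10L, ml = 1,
    is_mC = TRUE)
  fm2 <- fragmentML(s2, GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2)), g2)
  expect_equal(S4Vectors::mcols(fm2)$mlgf, 1)

  # zero C+G fragment flagged undefined, not zero
  gN <- Biostrings::DNAStringSet(c(chr1 = "AATTAA"))
  fmN <- fragmentML(s2[0], GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 6)), gN)
  expect_true(is.na(S4Vectors::mcols(fmN)$mlgf))
  expect_true(S4Vectors::mcols(fmN)$cg_undefined)
})

test_that("mlwg is additive over chromosomes and scale-invariant", {
  g <- Biostrings::DNAStringSet(c(chr1 = "CGCGAT", chr2 = "ACGTACGT",
                                  lambda = "CGCG"))
  sites <- GenomicRanges::GRanges(c("chr1", "chr2"),
    IRanges::IRanges(c(1, 2), width = 1), strand = "+",
    context = c("CpG", "CpG"), coverage = c(10L, 20L), ml = c(0.5, 0.25),
    is_mC = TRUE)
  cg1 <- 4; cg2 <- 4  # lambda excluded from the denominator
  expect_equal(mlwg(sites, g), (0.5 + 0.25) / (cg1 + cg2))
  # additivity: C+G-weighted per-chromosome combination equals global
  m1 <- mlwg(sites[1], g[c("chr1", "lambda")])
  m2 <- mlwg(sites[2], g[c("chr2", "lambda")])
  expect_equal((m1 * cg1 + m2 * cg2) / (cg1 + cg2), mlwg(sites, g))
  expect_equal(mlwg(sites[0], g), 0)

  # doubling every site's coverage at equal proportions leaves MLwg fixed
  sites2 <- sites
  S4Vectors::mcols(sites2)$coverage <- S4Vectors::mcols(sites)$coverage * 2L
  expect_equal(mlwg(sites2, g), mlwg(sites, g))
})

test_that("componentSummary pools within class and self-normalizes", {
  g <- Biostrings::DNAStringSet(c(chr1 = "CGCGCGCGCGCGAT"))
  # two elements of one class with unequal C+G, only the first methylated
  el <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 5), c(4, 12)),
    elementClass = "TE", elementId = c("te1", "te2"))
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 3), width = 1),
    strand = "+", context = "CpG", coverage = 10L, ml = c(0.6, 0.2),
    is_mC = TRUE)
  mlwg_v <- mlwg(sites, g)
  cs <- componentSummary(sites, el, g, mlwg_v)
  te <- cs[cs$element_class == "TE", ]
  # pooled: (0.6 + 0.2) / (4 + 8), NOT the mean of per-element MLgf
  expect_equal(te$mlgc, 0.8 / 12)
  expect_false(isTRUE(all.equal(te$mlgc, mean(c(0.8 / 4, 0)))))
  expect_equal(te$pct_methylated_elements, 0.5)
  expect_equal(cs$nmlgc[cs$element_class == "GENOME"], 1)
  expect_equal(te$nmlgc, te$mlgc / mlwg_v)
  # class level at twice the genome level normalizes to 2
  expect_equal(componentSummary(sites, el, g, te$mlgc / 2)$nmlgc[1], 2)
})

test_that("contextFractions recovers the mC context mix", {
  ctx <- rep(c("CpG", "CHG", "CHH"), c(24, 19, 57))
  sites <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq_along(ctx), width = 1), strand = "+",
    context = ctx, ml = 0.5, is_mC = TRUE)
  expect_equal(contextFractions(sites),
               c(CpG = 0.24, CHG = 0.19, CHH = 0.57))
  s1 <- sites[S4Vectors::mcols(sites)$context == "CpG"]
  expect_equal(unname(contextFractions(s1)), c(1, 0, 0))
})
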