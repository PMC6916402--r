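# compact config shared by the generator tests
.tinyCfg <- function(...) {
  simConfig(genome_length = 1.2e5, n_chrom = 2, n_genes = 12, n_te = 6,
            n_lncrna = 4, n_circrna = 3, n_trna = 3, n_cgi = 3,
            n_dmr = 4, n_coupled = 4, lambda_length = 10000L,
            do_medip = FALSE, do_expression = TRUE, ...)
}

test_that("simulateGenome is deterministic and respects its spec", {
  set.seed(1); g1 <- simulateGenome(.tinyCfg())
  set.seed(1); g2 <- simulateGenome(.tinyCfg())
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(as.data.frame(g1$elements), as.data.frame(g2$elements))

  # realized GC within 1% of the configured content on a large sequence
  set.seed(2)
  gg <- simulateGenome(simConfig(genome_length = 1e6, n_chrom = 1,
                                 n_genes = 5, n_te = 2, n_lncrna = 2,
                                 n_circrna = 2, n_trna = 2, n_cgi = 0))
  gc <- sum(Biostrings::letterFrequency(gg$genome[["chr1"]], c("C", "G"))) /
    1e6
  expect_lt(abs(gc - 0.5), 0.01)

  # requested genes present with a consistent exon/intron partition
  mc <- S4Vectors::mcols(g1$elements)
  genes <- g1$elements[mc$elementClass == "gene"]
  expect_equal(length(genes), 12L)
  for (gid in S4Vectors::mcols(genes)$elementId[1:4]) {
    parts <- g1$elements[!is.na(mc$geneId) & mc$geneId == gid &
                         mc$elementClass %in% c("exon", "intron")]
    gene <- genes[S4Vectors::mcols(genes)$elementId == gid]
    expect_equal(sum(GenomicRanges::width(parts)),
                 GenomicRanges::width(gene))
    srt <- GenomicRanges::sort(parts, ignore.strand = TRUE)
    cls <- as.character(S4Vectors::mcols(srt)$elementClass)
    expect_equal(cls[1], "exon")
    expect_equal(cls[length(cls)], "exon")
    expect_true(all(cls[-1] != cls[-length(cls)]))  # strictly alternating
  }
  # same-class elements never overlap
  for (cls in c("gene", "TE", "lncRNA")) {
    el <- g1$elements[mc$elementClass == cls]
    expect_equal(length(GenomicRanges::reduce(el, ignore.strand = TRUE,
                                              min.gapwidth = 0L)),
                 length(el))
  }
  expect_true("lambda" %in% names(g1$genome))
})

test_that("simulateMethylomes plants the configured landscape", {
  # null config: only conversion-failure noise survives the binomial guard
  # the binomial guard is a level-0.05 test, so the false-call fraction
  # under pure conversion failure is bounded by alpha
  cfg0 <- .tinyCfg(base_rates = c(CpG = 0, CHG = 0, CHH = 0), n_dmr = 0,
                   n_coupled = 0)
  st0 <- simulateStudy(cfg0, seed = 4)
  called <- callMethylation(st0$methylome, stage = "SP")
  expect_lt(mean(S4Vectors::mcols(called)$is_mC), 0.05)
  # a stricter alpha tightens the guard accordingly
  strict <- callMethylation(st0$methylome, stage = "SP", alpha = 1e-4)
  expect_lt(mean(S4Vectors::mcols(strict)$is_mC), 1e-3)

  # gametophyte rates exceed the sporophyte's in the default scaling
  st <- simulateStudy(.tinyCfg(), seed = 5)
  conv <- estimateConversion(st$methylome)
  ml_sp <- mlwg(callMethylation(st$methylome, stage = "SP",
                                nonconversion = conv$nonconversion),
                st$genome)
  ml_mg <- mlwg(callMethylation(st$methylome, stage = "MG",
                                nonconversion = conv$nonconversion),
                st$genome)
  expect_gt(ml_mg, ml_sp)

  # truth is sufficient to locate every planted DMR
  expect_equal(length(st$truth$dmrs), 4L)
  expect_true(all(GenomicRanges::width(st$truth$dmrs) == 1000L))
  expect_true(all(S4Vectors::mcols(st$truth$dmrs)$target_stage %in%
                  c("SP", "FG", "MG")))

  # CHH-dominant context mix among called mCs
  cf <- contextFractions(callMethylation(st$methylome, stage = "MG",
                                         nonconversion = conv$nonconversion))
  expect_gt(cf["CHH"], cf["CpG"])
  expect_gt(cf["CHH"], cf["CHG"])
})

test_that("injectHeterozygosity draws variants at the configured rate", {
  set.seed(9)
  g <- simulateGenome(.tinyCfg())$genome
  expect_equal(length(injectHeterozygosity(g, .tinyCfg(het_rate = 0))), 0L)

  set.seed(10)
  v <- injectHeterozygosity(g, .tinyCfg())
  L <- sum(Biostrings::width(g)) - 10000  # lambda excluded
  se <- sqrt(L * 0.0014)
  expect_lt(abs(length(v) - L * 0.0014), 3 * se)
  mc <- S4Vectors::mcols(v)
  expect_true(all(mc$ref != mc$alt))
  expect_true(all(mc$confounding ==
                  ((mc$ref == "C" & mc$alt == "T") |
                   (mc$ref == "G" & mc$alt == "A"))))
})

test_that("confounding variants create false mC calls the filter removes", {
  cfg <- .tinyCfg(base_rates = c(CpG = 0, CHG = 0, CHH = 0), n_dmr = 0,
                  n_coupled = 0, het_rate = 0.005, het_ct_fraction = 1)
  st <- simulateStudy(cfg, seed = 12)
  ms <- st$methylome
  # emulate the bisulfite read-through of a heterozygous C>T site: half of
  # the reads at a confounded cytosine keep reporting C (look methylated)
  conf <- st$variants[S4Vectors::mcols(st$variants)$confounding]
  rr <- SummarizedExperiment::rowRanges(ms)
  std <- as.character(GenomicRanges::strand(rr))
  hit <- (IRanges::overlapsAny(rr, conf[S4Vectors::mcols(conf)$ref == "C"],
                               ignore.strand = TRUE) & std == "+") |
         (IRanges::overlapsAny(rr, conf[S4Vectors::mcols(conf)$ref == "G"],
                               ignore.strand = TRUE) & std == "-")
  m <- methReads(ms); u <- unmethReads(ms)
  m[hit, ] <- as.integer(round((m[hit, ] + u[hit, ]) / 2))
  u[hit, ] <- pmax(u[hit, ] - m[hit, ], 0L)
  ms2 <- MethylomeSet(rr, m, u, SummarizedExperiment::colData(ms))
  called <- callMethylation(ms2, stage = "SP")
  hit_called <- hit[as.character(GenomicRanges::seqnames(rr)) != "lambda"]
  n_conf_before <- sum(S4Vectors::mcols(called)$is_mC & hit_called)
  expect_gt(n_conf_before, 50)  # confounded sites look methylated
  filt <- filterHetSites(called, st$variants)
  # after filtering no confounded site remains (exact intersection removed)
  fstd <- as.character(GenomicRanges::strand(filt))
  left <- (IRanges::overlapsAny(filt, conf[S4Vectors::mcols(conf)$ref == "C"],
                                ignore.strand = TRUE) & fstd == "+") |
          (IRanges::overlapsAny(filt, conf[S4Vectors::mcols(conf)$ref == "G"],
                                ignore.strand = TRUE) & fstd == "-")
  expect_equal(sum(left), 0L)
})

test_that("written study files pass the package's own readers", {
  st <- simulateStudy(.tinyCfg(do_medip = TRUE, medip_smooth = 101L),
                      seed = 20)
  dir <- file.path(tempdir(), "studyio")
  expect_no_warning(writeStudy(st, dir))
  g <- readGenome(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(st$genome))
  rep1 <- readCytosineReport(file.path(dir, "SP_1.cx.tsv"), "SP_1")
  expect_equal(length(rep1), nrow(st$methylome))
  expect_identical(S4Vectors::mcols(rep1)$meth,
                   unname(methReads(st$methylome)[, "SP_1"]))
  genes <- readElements(file.path(dir, "elements_gene.bed"), "gene", g)
  mcold <- S4Vectors::mcols(st$elements)
  expect_equal(length(genes), sum(mcold$elementClass == "gene"))
  bg <- readBedGraph(file.path(dir, "medip_ip.bedGraph"))
  dt <- asDepthTrack(bg, setNames(Biostrings::width(st$genome),
                                  names(st$genome)))
  expect_identical(as.numeric(depthRle(dt)$chr1),
                   as.numeric(depthRle(st$medip$ip)$chr1))
  v <- readVariants(file.path(dir, "variants.vcf"))
  expect_equal(length(v), length(st$variants))
  ex <- readExpressionCounts(file.path(dir, "expression_counts.tsv"))
  expect_equal(ex$counts, st$expression$counts)
  unlink(dir, recursive = TRUE)
})

test_that("MethylomeSet and DepthTrack enforce their invariants", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:3, width = 1),
    strand = "+", context = c("CpG", "CHH", "CHG"))
  ms <- MethylomeSet(gr, cbind(s1 = 1:3), cbind(s1 = 0:2),
    S4Vectors::DataFrame(sample_id = "s1", stage = "SP"))
  expect_equal(unname(totalReads(ms)[, 1]), c(1L, 3L, 5L))
  expect_error(MethylomeSet(gr, cbind(s1 = c(-1L, 1L, 1L)),
    cbind(s1 = 0:2),
    S4Vectors::DataFrame(sample_id = "s1", stage = "SP")),
    "non-negative")
  badctx <- gr
  S4Vectors::mcols(badctx)$context <- "weird"
  expect_error(MethylomeSet(badctx, cbind(s1 = 1:3), cbind(s1 = 0:2),
    S4Vectors::DataFrame(sample_id = "s1", stage = "SP")), "context")

  pooled <- poolByStage(MethylomeSet(gr,
    cbind(a_1 = 1:3, a_2 = 1:3, b_1 = 0:2),
    cbind(a_1 = 1:3, a_2 = 1:3, b_1 = 0:2),
    S4Vectors::DataFrame(sample_id = c("a_1", "a_2", "b_1"),
                         stage = c("A", "A", "B"))))
  expect_equal(ncol(pooled), 2L)
  expect_equal(unname(methReads(pooled)[, "A"]), c(2L, 4L, 6L))

  expect_error(DepthTrack(IRanges::RleList(chr1 = S4Vectors::Rle(-1))),
               "non-negative")
})
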