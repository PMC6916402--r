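#' Two-sided exact test on a 2x2 methylation count table
#'
#' Fisher's exact test for one cytosine site (or pooled region): rows are
#' the two sample groups, columns methylated/unmethylated read counts. The
#' two-sided p-value sums all hypergeometric table probabilities not
#' exceeding the observed table's probability. Fully vectorized over
#' sites; support enumeration is linear in the methylated-read margin, so
#' genome-scale site sets in a sparsely methylated genome are cheap.
#' Degenerate margins (an empty row or column) yield p = 1 by convention,
#' flagged in the `"degenerate"` attribute.
#'
#' @param m1,u1 methylated/unmethylated counts in group 1 (vectorized).
#' @param m2,u2 counts in group 2.
#' @return numeric vector of two-sided p-values with attribute
#'   `degenerate`.
#' @export
exactTest2x2 <- function(m1, u1, m2, u2) {
  stopifnot(all(c(m1, u1, m2, u2) >= 0))
  n <- length(m1)
  stopifnot(length(u1) == n, length(m2) == n, length(u2) == n)
  n1 <- m1 + u1; n2 <- m2 + u2; m <- m1 + m2; N <- n1 + n2
  p <- rep(1, n)
  ok <- n1 > 0 & n2 > 0 & m > 0 & m < N
  if (any(ok)) {
    w <- which(ok)
    lo <- pmax(0, m[w] - n2[w]); hi <- pmin(m[w], n1[w])
    len <- hi - lo + 1L
    idx <- rep(w, len)
    k <- sequence(len, from = lo, by = 1L)
    d <- dhyper(k, n1[idx], n2[idx], m[idx])
    dobs <- dhyper(m1[w], n1[w], n2[w], m[w])
    incl <- d <= dobs[match(idx, w)] * (1 + 1e-7)
    s <- rowsum(d * incl, group = idx)
    p[as.integer(rownames(s))] <- pmin(s[, 1], 1)
  }
  attr(p, "degenerate") <- !ok
  p
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment (wraps [stats::p.adjust()]); order-preserving and
#' never below the raw p-value.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return q-values, same order as `p`.
#' @export
bhFdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

# pooled per-group count vectors from a MethylomeSet; groups are stage
# labels or column indices; lambda rows droped via sites mask
.groupCounts <- function(x, group) {
  cols <- if (is.character(group) && all(group %in% sampleStage(x)))
    which(sampleStage(x) %in% group) else group
  if (!length(cols)) stop("no libraries matched group specification")
  list(m = rowSums(methReads(x)[, cols, drop = FALSE]),
       u = rowSums(unmethReads(x)[, cols, drop = FALSE]))
}

#' Call differentially methylated sites (DMSs)
#'
#' Per-site two-group comparison with replicates pooled by count summation
#' (three replicates per group in the study design). Sites covered by at
#' least `min_reads` in both groups are tested with [exactTest2x2()];
#' candidate DMSs satisfy `p < p_max` and a methylation-level fold-change
#' above `fold_min` in either direction, computed with pseudocount `eps` on
#' both levels: `fold = (ml1 + eps) / (ml2 + eps)`. BH q-values over all
#' tested sites are reported alongside.
#'
#' @param x a [MethylomeSet].
#' @param group1,group2 stage labels (replicates pooled) or column indices.
#' @param min_reads per-group coverage requirement (default 4).
#' @param p_max raw p-value threshold (default 0.05).
#' @param fold_min minimal fold-change (default 2).
#' @param eps fold-change pseudocount (default 0.001).
#' @param lambda_chrom spike-in record dropped before testing.
#' @return `GRanges` of tested sites with `ml1`, `ml2`, `p`, `q`, `fold`
#'   (>= 1, direction given separately), `direction`, `called`.
#' @export
callDms <- function(x, group1, group2, min_reads = 4L, p_max = 0.05,
                    fold_min = 2, eps = 0.001, lambda_chrom = "lambda") {
  g1 <- .groupCounts(x, group1); g2 <- .groupCounts(x, group2)
  gr <- SummarizedExperiment::rowRanges(x)
  keep <- as.character(GenomicRanges::seqnames(gr)) != lambda_chrom &
    (g1$m + g1$u) >= min_reads & (g2$m + g2$u) >= min_reads
  gr <- gr[keep]
  m1 <- g1$m[keep]; u1 <- g1$u[keep]
  m2 <- g2$m[keep]; u2 <- g2$u[keep]
  p <- exactTest2x2(m1, u1, m2, u2)
  ml1 <- m1 / (m1 + u1); ml2 <- m2 / (m2 + u2)
  fold_raw <- (ml1 + eps) / (ml2 + eps)
  fold <- pmax(fold_raw, 1 / fold_raw)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    context = siteContext(x)[keep],
    ml1 = ml1, ml2 = ml2, p = as.numeric(p), q = bhFdr(as.numeric(p)),
    fold = fold,
    direction = ifelse(ml1 >= ml2, "hyper-in-group1", "hyper-in-group2"),
    called = as.numeric(p) < p_max & fold > fold_min)
  S4Vectors::metadata(gr)$groups <- c(.groupLabel(group1),
                                      .groupLabel(group2))
  gr
}

.groupLabel <- function(g) paste(as.character(g), collapse = "+")

# per-interval differential statistics on precomputed site vectors
# sites: list(pos sorted, m1,u1,m2,u2, ml1, ml2, s) for ONE chromosome;
# cg_cum: .cum0 of C/G indicator of the chromosome
.regionStats <- function(starts, ends, sites, cg_cum, eps) {
  cs <- function(v) .cum0(v)
  i1 <- findInterval(starts - 1L, sites$pos) + 1L
  i2 <- findInterval(ends, sites$pos)
  rng <- function(c0) c0[i2 + 1L] - c0[i1]
  n_sites <- i2 - i1 + 1L
  n_sites[n_sites < 0] <- 0L
  csS <- cs(sites$s); csm1 <- cs(sites$m1); csu1 <- cs(sites$u1)
  csm2 <- cs(sites$m2); csu2 <- cs(sites$u2)
  csml1 <- cs(sites$ml1); csml2 <- cs(sites$ml2)
  cg <- cg_cum[pmin(ends, length(cg_cum) - 1L) + 1L] - cg_cum[starts]
  mlgf1 <- ifelse(cg > 0, rng(csml1) / cg, NA_real_)
  mlgf2 <- ifelse(cg > 0, rng(csml2) / cg, NA_real_)
  fold_raw <- (mlgf1 + eps) / (mlgf2 + eps)
  list(area_stat = rng(csS), n_sites = n_sites,
       m1 = rng(csm1), u1 = rng(csu1), m2 = rng(csm2), u2 = rng(csu2),
       mlgf1 = mlgf1, mlgf2 = mlgf2,
       fold = pmax(fold_raw, 1 / fold_raw),
       direction = ifelse(mlgf1 >= mlgf2, "hyper-in-group1",
                          "hyper-in-group2"))
}

#' Call differentially methylated regions (DMRs)
#'
#' Sliding-window scan (default 1000-bp windows advanced by 100 bp). Every
#' window is scored with an areaStat-style statistic combining per-site
#' p-values and the direction of the methylation difference:
#' `areaStat = sum over covered sites of sign(ml1 - ml2) * (-log10 p_site)`
#' with per-site p from [exactTest2x2()] on pooled counts. A window is a
#' DMR when, conjointly, `|areaStat| >= areastat_min` (default 40), the
#' window methylation-level fold-change exceeds `fold_min` (default 6,
#' pseudocount `eps`), and the exact test on window-pooled counts gives
#' `p < p_max`. To keep DMRs non-overlapping the scan is greedy: after a
#' window is emitted, scanning resumes downstream of its end. Windows with
#' fewer than `min_sites` contributing sites are skipped.
#'
#' @inheritParams callDms
#' @param genome `DNAStringSet` (window C+G denominators for the fold).
#' @param window,step window and step length in bp.
#' @param areastat_min minimal `|areaStat|`.
#' @param fold_min minimal window fold-change (default 6).
#' @param min_sites minimal covered sites per window (stability guard).
#' @return `GRanges` of non-overlapping DMRs with `area_stat`, `pooled_p`,
#'   `pooled_fold`, `mlgf1`, `mlgf2`, `direction`, `n_sites`.
#' @export
callDmrs <- function(x, group1, group2, genome, window = 1000L,
                     step = 100L, areastat_min = 40, fold_min = 6,
                     p_max = 0.05, min_reads = 4L, min_sites = 3L,
                     eps = 0.001, lambda_chrom = "lambda") {
  prep <- .diffSitePrep(x, group1, group2, min_reads, lambda_chrom)
  out <- list()
  for (ch in names(prep$by_chrom)) {
    sites <- prep$by_chrom[[ch]]
    if (!length(sites$pos)) next
    L <- length(genome[[ch]])
    cg_cum <- .cum0(.charvec(genome, ch) %in% c("C", "G"))
    starts <- seq.int(1L, max(1L, L - step + 1L), by = step)
    ends <- pmin(starts + window - 1L, L)
    st <- .regionStats(starts, ends, sites, cg_cum, eps)
    cand <- which(st$n_sites >= min_sites &
                  abs(st$area_stat) >= areastat_min &
                  st$fold > fold_min)
    if (!length(cand)) next
    pp <- exactTest2x2(st$m1[cand], st$u1[cand], st$m2[cand], st$u2[cand])
    qual <- cand[as.numeric(pp) < p_max]
    ppk <- as.numeric(pp)[as.numeric(pp) < p_max]
    if (!length(qual)) next
    # greedy left-to-right emit-and-jump: resume downstream of each DMR
    cur_end <- 0L
    emit <- logical(length(qual))
    for (j in seq_along(qual)) {
      if (starts[qual[j]] > cur_end) {
        emit[j] <- TRUE
        cur_end <- ends[qual[j]]
      }
    }
    k <- qual[emit]
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(starts[k], ends[k]),
      area_stat = st$area_stat[k], pooled_p = ppk[emit],
      pooled_fold = st$fold[k], mlgf1 = st$mlgf1[k], mlgf2 = st$mlgf2[k],
      direction = st$direction[k], n_sites = st$n_sites[k])
    out[[ch]] <- gr
  }
  res <- if (length(out)) suppressWarnings(do.call(c, unname(out)))
         else GenomicRanges::GRanges()
  S4Vectors::metadata(res)$groups <- c(.groupLabel(group1),
                                       .groupLabel(group2))
  res
}

# shared site preparation for region-level tests: pooled counts, coverage
# filter, per-site p and signed -log10 p, split by chromosome
.diffSitePrep <- function(x, group1, group2, min_reads, lambda_chrom) {
  g1 <- .groupCounts(x, group1); g2 <- .groupCounts(x, group2)
  gr <- SummarizedExperiment::rowRanges(x)
  keep <- as.character(GenomicRanges::seqnames(gr)) != lambda_chrom &
    (g1$m + g1$u) >= min_reads & (g2$m + g2$u) >= min_reads
  gr <- gr[keep]
  m1 <- g1$m[keep]; u1 <- g1$u[keep]
  m2 <- g2$m[keep]; u2 <- g2$u[keep]
  p <- as.numeric(exactTest2x2(m1, u1, m2, u2))
  p <- pmax(p, .Machine$double.xmin)
  ml1 <- m1 / (m1 + u1); ml2 <- m2 / (m2 + u2)
  s <- sign(ml1 - ml2) * (-log10(p))
  sn <- as.character(GenomicRanges::seqnames(gr))
  pos <- GenomicRanges::start(gr)
  by_chrom <- lapply(split(seq_along(gr), sn), function(i) {
    o <- i[order(pos[i])]
    list(pos = pos[o], m1 = m1[o], u1 = u1[o], m2 = m2[o], u2 = u2[o],
         ml1 = ml1[o], ml2 = ml2[o], s = s[o])
  })
  list(by_chrom = by_chrom)
}

#' Call differentially methylated promoters (DMPs)
#'
#' Applies the DMR criteria (areaStat, fold-change, pooled exact test) to
#' the fixed 2000-bp region upstream of each gene's transcript start,
#' strand-aware and clipped at chromosome edges (clipped promoters are
#' flagged). No sliding is involved.
#'
#' @inheritParams callDmrs
#' @param genes `GRanges` of genes with strand and `elementId`.
#' @param upstream promoter length in bp (default 2000).
#' @return `GRanges` of promoters with the DMR statistics, `gene_id`,
#'   `clipped`, and `called`.
#' @export
callDmps <- function(x, genes, group1, group2, genome, upstream = 2000L,
                     areastat_min = 40, fold_min = 6, p_max = 0.05,
                     min_reads = 4L, min_sites = 3L, eps = 0.001,
                     lambda_chrom = "lambda") {
  prom <- GenomicRanges::promoters(genes, upstream = upstream,
                                   downstream = 0L)
  chrlen <- Biostrings::width(genome)[
    match(as.character(GenomicRanges::seqnames(prom)), names(genome))]
  clipped <- GenomicRanges::start(prom) < 1L |
    GenomicRanges::end(prom) > chrlen
  prom <- GenomicRanges::GRanges(GenomicRanges::seqnames(prom),
    IRanges::IRanges(pmax(GenomicRanges::start(prom), 1L),
                     pmin(GenomicRanges::end(prom), chrlen)),
    strand = GenomicRanges::strand(prom))
  prep <- .diffSitePrep(x, group1, group2, min_reads, lambda_chrom)
  n <- length(prom)
  res <- data.frame(area_stat = numeric(n), pooled_p = rep(1, n),
                    pooled_fold = numeric(n), mlgf1 = numeric(n),
                    mlgf2 = numeric(n), direction = character(n),
                    n_sites = integer(n))
  sn <- as.character(GenomicRanges::seqnames(prom))
  for (ch in unique(sn)) {
    i <- which(sn == ch)
    sites <- prep$by_chrom[[ch]]
    if (is.null(sites)) next
    cg_cum <- .cum0(.charvec(genome, ch) %in% c("C", "G"))
    st <- .regionStats(GenomicRanges::start(prom)[i],
                       GenomicRanges::end(prom)[i], sites, cg_cum, eps)
    res$area_stat[i] <- st$area_stat
    res$n_sites[i] <- st$n_sites
    res$pooled_fold[i] <- st$fold
    res$mlgf1[i] <- st$mlgf1; res$mlgf2[i] <- st$mlgf2
    res$direction[i] <- st$direction
    res$pooled_p[i] <- as.numeric(
      exactTest2x2(st$m1, st$u1, st$m2, st$u2))
  }
  out <- prom
  called <- res$n_sites >= min_sites & abs(res$area_stat) >= areastat_min &
    res$pooled_fold > fold_min & res$pooled_p < p_max
  called[is.na(called)] <- FALSE
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = S4Vectors::mcols(genes)$elementId, res,
    clipped = clipped, called = called)
  out
}

#' Classify DMRs as stage-specific hyper/hypomethylation
#'
#' Given pairwise DMR calls labelled with their two group names, each DMR
#' is hypermethylated in the group on the higher-methylation side of its
#' comparison. Swapping the groups of a comparison flips every direction.
#'
#' @param dmr_list named list of `GRanges` from [callDmrs()] (each carries
#'   its group labels in `metadata(x)$groups`).
#' @return single `GRanges` with `hyper_stage` and `hypo_stage` columns.
#' @export
classifyHyper <- function(dmr_list) {
  pieces <- lapply(dmr_list, function(d) {
    if (!length(d)) return(NULL)
    gl <- S4Vectors::metadata(d)$groups
    hyper <- ifelse(S4Vectors::mcols(d)$direction == "hyper-in-group1",
                    gl[1], gl[2])
    S4Vectors::mcols(d)$hyper_stage <- hyper
    S4Vectors::mcols(d)$hypo_stage <- ifelse(hyper == gl[1], gl[2], gl[1])
    d
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, unname(pieces)))
}

#' Overlap DMRs with annotated elements
#'
#' Emits every (DMR, element) pair sharing at least one bp, with the exact
#' overlap width.
#'
#' @param dmrs `GRanges` of DMRs.
#' @param elements `GRanges` with `elementClass`/`elementId`.
#' @return `data.frame` with `dmr_id`, `element_id`, `element_class`,
#'   `overlap_bp`.
#' @export
overlapElements <- function(dmrs, elements) {
  hits <- GenomicRanges::findOverlaps(dmrs, elements, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(dmr_id = character(), element_id = character(),
                      element_class = character(), overlap_bp = integer()))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    dmrs[qi], elements[si], ignore.strand = TRUE))
  dmr_id <- if (!is.null(names(dmrs))) names(dmrs)[qi]
            else paste0("dmr", qi)
  data.frame(dmr_id = dmr_id,
             element_id = as.character(S4Vectors::mcols(elements)$elementId[si]),
             element_class = as.character(S4Vectors::mcols(elements)$elementClass[si]),
             overlap_bp = ov)
}
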