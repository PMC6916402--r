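#' Site methylation level (MLmc)
#'
#' The methylation level of one cytosine is the number of methylated
#' (unconverted) reads over the total reads mapped to the site:
#' `ml = meth / (meth + unmeth)`. Uncovered sites are undefined (`NA`)
#' and excluded upstream.
#'
#' @param meth,unmeth non-negative read counts (vectorized).
#' @return numeric vector in `[0, 1]`, `NA` at zero coverage.
#' @export
siteML <- function(meth, unmeth) {
  stopifnot(all(meth >= 0, na.rm = TRUE), all(unmeth >= 0, na.rm = TRUE))
  cov <- meth + unmeth
  ifelse(cov > 0, meth / cov, NA_real_)
}

#' Estimate the bisulfite conversion rate from the lambda spike-in
#'
#' The unmethylated lambda phage genome is co-treated with the sample, so
#' any methylated call on lambda reflects conversion failure. The
#' nonconversion rate is the fraction of lambda cytosine reads sequenced as
#' cytosine: `sum(meth) / sum(meth + unmeth)` over all lambda sites, and
#' the conversion rate is its complement.
#'
#' @param x a [MethylomeSet] containing lambda sites, or a `GRanges` from
#'   [readCytosineReport()].
#' @param lambda_chrom name of the spike-in record.
#' @param sample optional sample id (default: pool all libraries).
#' @return list with `nonconversion`, `conversion`, `n_sites`, `n_reads`.
#' @export
estimateConversion <- function(x, lambda_chrom = "lambda", sample = NULL) {
  if (is(x, "MethylomeSet")) {
    keep <- as.character(GenomicRanges::seqnames(
      SummarizedExperiment::rowRanges(x))) == lambda_chrom
    if (!any(keep)) stop("no '", lambda_chrom, "' sites present")
    m <- methReads(x)[keep, , drop = FALSE]
    u <- unmethReads(x)[keep, , drop = FALSE]
    if (!is.null(sample)) {
      m <- m[, sample, drop = FALSE]; u <- u[, sample, drop = FALSE]
    }
    meth <- sum(m); tot <- sum(m) + sum(u); n_sites <- sum(keep)
  } else {
    keep <- as.character(GenomicRanges::seqnames(x)) == lambda_chrom
    if (!any(keep)) stop("no '", lambda_chrom, "' sites present")
    mc <- S4Vectors::mcols(x[keep])
    meth <- sum(mc$meth); tot <- sum(mc$meth) + sum(mc$unmeth)
    n_sites <- sum(keep)
  }
  if (tot == 0) stop("lambda spike-in has zero coverage")
  nc <- meth / tot
  list(nonconversion = nc, conversion = 1 - nc,
       n_lambda_sites = n_sites, n_lambda_reads = tot)
}

#' Call methylated cytosines
#'
#' A site is called methylated (`is_mC`) when (i) its total coverage reaches
#' `min_reads` (default four reads), (ii) at least one methylated read is
#' observed, and (iii) a one-sided binomial test rejects the hypothesis that
#' all methylated reads are conversion failures:
#' `P(X >= meth | n = coverage, p = nonconversion) < alpha`. The binomial
#' guard matters in this very low global-methylation regime, where a few
#' conversion failures can mimic methylation. `ml` is reported for every
#' covered site regardless of the call. Set `rule = "meth"` to require
#' `min_reads` methylated reads instead of total reads.
#'
#' @param meth,unmeth read-count vectors (replicates already pooled).
#' @param nonconversion lambda nonconversion rate from
#'   [estimateConversion()].
#' @param min_reads coverage threshold (default 4).
#' @param alpha binomial test level (default 0.05).
#' @param rule `"total"` (default): `min_reads` applies to total coverage;
#'   `"meth"`: to methylated reads.
#' @return `data.frame` with `coverage`, `ml`, `is_mC`.
#' @export
callMC <- function(meth, unmeth, nonconversion, min_reads = 4L,
                   alpha = 0.05, rule = c("total", "meth")) {
  rule <- match.arg(rule)
  cov <- meth + unmeth
  ml <- siteML(meth, unmeth)
  ptail <- pbinom(pmax(meth - 1, 0), cov, nonconversion, lower.tail = FALSE)
  thr_ok <- if (rule == "total") cov >= min_reads else meth >= min_reads
  is_mC <- thr_ok & meth >= 1 & ptail < alpha
  data.frame(coverage = cov, ml = ml, is_mC = is_mC)
}

#' Call methylation over a MethylomeSet
#'
#' Pools the replicate libraries of one stage by summing counts per site,
#' then applies [callMC()]. Lambda spike-in sites are dropped from the
#' result (they only inform the conversion rate).
#'
#' @param x a [MethylomeSet].
#' @param stage stage label whose replicates are pooled; `NULL` pools all
#'   libraries.
#' @param nonconversion lambda nonconversion rate; by default estimated
#'   from the pooled libraries' own lambda sites.
#' @param lambda_chrom spike-in record name.
#' @inheritParams callMC
#' @return `GRanges` of sites with `context`, `coverage`, `ml`, `is_mC`.
#' @export
callMethylation <- function(x, stage = NULL, nonconversion = NULL,
                            lambda_chrom = "lambda", min_reads = 4L,
                            alpha = 0.05, rule = c("total", "meth")) {
  rule <- match.arg(rule)
  cols <- if (is.null(stage)) seq_len(ncol(x)) else
    which(sampleStage(x) == stage)
  if (!length(cols)) stop("no libraries for stage ", stage)
  m <- rowSums(methReads(x)[, cols, drop = FALSE])
  u <- rowSums(unmethReads(x)[, cols, drop = FALSE])
  if (is.null(nonconversion)) {
    keep <- as.character(GenomicRanges::seqnames(
      SummarizedExperiment::rowRanges(x))) == lambda_chrom
    if (!any(keep)) stop("supply 'nonconversion' when no spike-in is present")
    nonconversion <- sum(m[keep]) / sum(m[keep] + u[keep])
  }
  gr <- SummarizedExperiment::rowRanges(x)
  cl <- callMC(m, u, nonconversion, min_reads, alpha, rule)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    context = siteContext(x), coverage = cl$coverage, ml = cl$ml,
    is_mC = cl$is_mC)
  drop <- as.character(GenomicRanges::seqnames(gr)) == lambda_chrom
  gr <- gr[!drop]
  S4Vectors::metadata(gr)$nonconversion <- nonconversion
  S4Vectors::metadata(gr)$min_reads <- min_reads
  S4Vectors::metadata(gr)$alpha <- alpha
  gr
}

#' Remove cytosine sites confounded by C-T / G-A polymorphisms
#'
#' A heterozygous C>T variant under a forward-strand cytosine (or G>A under
#' a reverse-strand cytosine) is read by bisulfite sequencing exactly like
#' an unmethylated (or spuriously methylated) cytosine, so such sites are
#' excluded. Removal is the exact intersection with the variant set and is
#' idempotent; the removed fraction is recorded in
#' `metadata(x)$het_removed_fraction`.
#'
#' @param sites called sites (`GRanges` from [callMethylation()]).
#' @param variants `GRanges` with `ref`/`alt` from [readVariants()].
#' @return filtered `GRanges`.
#' @export
filterHetSites <- function(sites, variants) {
  if (length(variants) == 0L) {
    S4Vectors::metadata(sites)$het_removed_fraction <- 0
    return(sites)
  }
  mc <- S4Vectors::mcols(variants)
  ct <- variants[mc$ref == "C" & mc$alt == "T"]
  ga <- variants[mc$ref == "G" & mc$alt == "A"]
  std <- as.character(GenomicRanges::strand(sites))
  hit_ct <- IRanges::overlapsAny(sites, ct, ignore.strand = TRUE) &
    std == "+"
  hit_ga <- IRanges::overlapsAny(sites, ga, ignore.strand = TRUE) &
    std == "-"
  drop <- hit_ct | hit_ga
  out <- sites[!drop]
  S4Vectors::metadata(out)$het_removed_fraction <-
    if (length(sites)) sum(drop) / length(sites) else 0
  out
}

# C+G letter counts of arbitrary intervals, N-masked bases excluded
.intervalCG <- function(genome, intervals) {
  sn <- as.character(GenomicRanges::seqnames(intervals))
  out <- integer(length(intervals))
  for (ch in unique(sn)) {
    i <- which(sn == ch)
    v <- Biostrings::Views(genome[[ch]],
      IRanges::IRanges(GenomicRanges::start(intervals)[i],
                       GenomicRanges::end(intervals)[i]))
    out[i] <- rowSums(Biostrings::letterFrequency(v, c("C", "G")))
  }
  out
}

#' Fragment methylation level (MLgf)
#'
#' The methylation level of a genomic fragment is the sum of the site
#' methylation levels of all called mCs inside the fragment (both strands)
#' divided by the fragment's C+G nucleotide count:
#' `MLgf = sum(MLmc of mCs) / (C+G of fragment)`. Fragments whose C+G count
#' is zero (N-rich intervals) are undefined (`NA`) and flagged, never
#' treated as zero.
#'
#' @param sites called sites from [callMethylation()].
#' @param intervals `GRanges` of fragments.
#' @param genome `DNAStringSet`.
#' @return the `intervals` with metadata columns `mlgf`, `n_mC`,
#'   `cg_count`, `is_methylated_element`, `cg_undefined`.
#' @export
fragmentML <- function(sites, intervals, genome) {
  cg <- .intervalCG(genome, intervals)
  mC <- sites[S4Vectors::mcols(sites)$is_mC %in% TRUE]
  hits <- GenomicRanges::findOverlaps(mC, intervals, ignore.strand = TRUE)
  mlsum <- numeric(length(intervals))
  nmc <- integer(length(intervals))
  if (length(hits)) {
    agg <- rowsum(cbind(S4Vectors::mcols(mC)$ml[S4Vectors::queryHits(hits)],
                        1),
                  group = S4Vectors::subjectHits(hits))
    idx <- as.integer(rownames(agg))
    mlsum[idx] <- agg[, 1]
    nmc[idx] <- agg[, 2]
  }
  out <- intervals
  S4Vectors::mcols(out)$mlgf <- ifelse(cg > 0, mlsum / cg, NA_real_)
  S4Vectors::mcols(out)$n_mC <- nmc
  S4Vectors::mcols(out)$cg_count <- cg
  S4Vectors::mcols(out)$is_methylated_element <- nmc >= 1L
  S4Vectors::mcols(out)$cg_undefined <- cg == 0L
  out
}

#' Whole-genome methylation level (MLwg)
#'
#' The genome-wide analogue of [fragmentML()]: the sum of site methylation
#' levels over all called mCs (optionally restricted to one context)
#' divided by the total C+G count of the genome (spike-in excluded).
#'
#' @param sites called sites from [callMethylation()].
#' @param genome `DNAStringSet`.
#' @param context optional `"CpG"`, `"CHG"` or `"CHH"` restriction.
#' @param exclude chromosomes excluded from the denominator.
#' @return a single methylation level.
#' @export
mlwg <- function(sites, genome, context = NULL, exclude = "lambda") {
  mc <- S4Vectors::mcols(sites)
  sel <- mc$is_mC %in% TRUE
  if (!is.null(context)) sel <- sel & mc$context == context
  sum(mc$ml[sel]) / .cgCount(genome, exclude)
}

#' Per-class methylation summary (MLgc, NMLgc)
#'
#' For each element class, the class methylation level pools numerators and
#' denominators across all elements of the class (it is *not* the mean of
#' per-element MLgf): `MLgc = sum(MLmc of mCs in class) / sum(C+G of
#' class)`. MLgc is then normalized by the whole-genome level to give
#' `NMLgc = MLgc / MLwg`, so the GENOME class has NMLgc exactly 1. The
#' fraction of elements containing at least one mC is reported per class.
#'
#' @param sites called sites from [callMethylation()].
#' @param elements `GRanges` with `elementClass` metadata.
#' @param genome `DNAStringSet`.
#' @param mlwg_value whole-genome level; computed via [mlwg()] if missing.
#' @param exclude chromosomes excluded from the GENOME class.
#' @return `data.frame` with one row per class plus a GENOME row: `mlgc`,
#'   `nmlgc`, `n_elements`, `pct_methylated_elements`.
#' @export
componentSummary <- function(sites, elements, genome, mlwg_value = NULL,
                             exclude = "lambda") {
  if (is.null(mlwg_value)) mlwg_value <- mlwg(sites, genome, exclude = exclude)
  stopifnot(mlwg_value > 0)
  fm <- fragmentML(sites, elements, genome)
  mc <- S4Vectors::mcols(fm)
  cls <- as.character(mc$elementClass)
  rows <- lapply(unique(cls), function(cl) {
    i <- cls == cl & !mc$cg_undefined
    if (sum(mc$cg_count[i]) == 0) stop("class ", cl, " has zero C+G")
    mlgc <- sum(mc$mlgf[i] * mc$cg_count[i]) / sum(mc$cg_count[i])
    data.frame(element_class = cl, mlgc = mlgc, nmlgc = mlgc / mlwg_value,
               n_elements = sum(cls == cl),
               pct_methylated_elements = mean(mc$is_methylated_element[cls == cl]))
  })
  genome_row <- data.frame(element_class = "GENOME", mlgc = mlwg_value,
                           nmlgc = 1, n_elements = 1L,
                           pct_methylated_elements = NA_real_)
  out <- rbind(do.call(rbind, rows), genome_row)
  rownames(out) <- NULL
  out
}

#' Context composition of methylated cytosines
#'
#' Fractions of called mCs falling in CpG, CHG and CHH context (summing to
#' one). In the kelp methylome the mix is CHH-dominated.
#'
#' @param sites called sites from [callMethylation()].
#' @return named numeric vector `c(CpG=, CHG=, CHH=)`.
#' @export
contextFractions <- function(sites) {
  mc <- S4Vectors::mcols(sites)
  ctx <- mc$context[mc$is_mC %in% TRUE]
  if (!length(ctx)) stop("no methylated cytosines")
  tab <- table(factor(ctx, levels = c("CpG", "CHG", "CHH")))
  setNames(as.numeric(tab) / sum(tab), names(tab))
}
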