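#' MethylomeSet: per-cytosine bisulfite counts across samples
#'
#' An S4 container for single-base methylome data, extending
#' [SummarizedExperiment::RangedSummarizedExperiment]. Rows are individual
#' cytosine sites (width-1 `GRanges` on the strand carrying the C, with a
#' `context` metadata column in \{CpG, CHG, CHH, boundary\}); columns are
#' sequencing libraries. Two integer assays are required: `meth` (reads
#' supporting methylation, i.e. unconverted C) and `unmeth` (converted
#' reads). `colData` carries at least `sample_id` and `stage` (life-cycle
#' stage; replicates of a stage share the `stage` value).
#'
#' Cytosines on the reverse strand are represented at the genomic position
#' of the forward-strand G with strand `-`; symmetric CpG sites are never
#' merged across strands.
#'
#' @param sites `GRanges` of cytosine sites with a `context` metadata column.
#' @param meth,unmeth integer matrices, sites x samples.
#' @param colData `DataFrame` (or data.frame) with columns `sample_id` and
#'   `stage`, one row per sample.
#'
#' @return A `MethylomeSet`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(2, 5), width = 1),
#'   strand = "+", context = c("CpG", "CHH"))
#' ms <- MethylomeSet(gr, meth = cbind(s1 = c(3L, 0L)),
#'   unmeth = cbind(s1 = c(1L, 8L)),
#'   colData = S4Vectors::DataFrame(sample_id = "s1", stage = "SP"))
#' methReads(ms)
#' @export
MethylomeSet <- function(sites, meth, unmeth, colData) {
  meth <- as.matrix(meth)
  unmeth <- as.matrix(unmeth)
  storage.mode(meth) <- "integer"
  storage.mode(unmeth) <- "integer"
  colData <- S4Vectors::DataFrame(colData)
  if (is.null(rownames(colData)) || all(rownames(colData) == as.character(seq_len(nrow(colData)))))
    rownames(colData) <- colData$sample_id
  colnames(meth) <- colnames(unmeth) <- rownames(colData)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = meth, unmeth = unmeth),
    rowRanges = sites, colData = colData)
  new("MethylomeSet", se)
}

#' @rdname MethylomeSet
#' @export
setClass("MethylomeSet", contains = "RangedSummarizedExperiment")

setValidity("MethylomeSet", function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("meth", "unmeth") %in% an))
    msg <- c(msg, "assays 'meth' and 'unmeth' are required")
  else {
    m <- SummarizedExperiment::assay(object, "meth")
    u <- SummarizedExperiment::assay(object, "unmeth")
    if (any(m < 0, na.rm = TRUE) || any(u < 0, na.rm = TRUE))
      msg <- c(msg, "read counts must be non-negative")
  }
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr)) {
    if (!all(GenomicRanges::width(rr) == 1L))
      msg <- c(msg, "cytosine sites must have width 1")
    ctx <- S4Vectors::mcols(rr)$context
    if (is.null(ctx))
      msg <- c(msg, "rowRanges must carry a 'context' column")
    else if (!all(as.character(ctx) %in% c("CpG", "CHG", "CHH", "boundary")))
      msg <- c(msg, "context must be one of CpG, CHG, CHH, boundary")
    if (any(as.character(GenomicRanges::strand(rr)) == "*"))
      msg <- c(msg, "site strand must be + or -")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample_id", "stage") %in% colnames(cd)))
    msg <- c(msg, "colData must carry 'sample_id' and 'stage'")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn MethylomeSet matrix of methylated-read counts.
#' @param x a `MethylomeSet`.
#' @export
setMethod("methReads", "MethylomeSet", function(x)
  SummarizedExperiment::assay(x, "meth"))

#' @describeIn MethylomeSet matrix of unmethylated-read counts.
#' @export
setMethod("unmethReads", "MethylomeSet", function(x)
  SummarizedExperiment::assay(x, "unmeth"))

#' @describeIn MethylomeSet matrix of per-site coverage (meth + unmeth).
#' @export
setMethod("totalReads", "MethylomeSet", function(x)
  methReads(x) + unmethReads(x))

#' @describeIn MethylomeSet per-site context labels (character).
#' @export
setMethod("siteContext", "MethylomeSet", function(x)
  as.character(S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$context))

#' @describeIn MethylomeSet per-sample stage labels (character).
#' @export
setMethod("sampleStage", "MethylomeSet", function(x)
  as.character(SummarizedExperiment::colData(x)$stage))

#' @describeIn MethylomeSet pool replicate libraries by summing counts per
#'   site, one column per stage (the pooling used for all ML statistics).
#' @param stages optional subset of stages to keep, in the given order.
#' @export
setMethod("poolByStage", "MethylomeSet", function(x, stages = NULL) {
  st <- sampleStage(x)
  if (is.null(stages)) stages <- unique(st)
  stopifnot(all(stages %in% st))
  m <- methReads(x); u <- unmethReads(x)
  pm <- vapply(stages, function(s) rowSums(m[, st == s, drop = FALSE]),
               numeric(nrow(x)))
  pu <- vapply(stages, function(s) rowSums(u[, st == s, drop = FALSE]),
               numeric(nrow(x)))
  MethylomeSet(SummarizedExperiment::rowRanges(x), pm, pu,
    S4Vectors::DataFrame(sample_id = stages, stage = stages))
})

setMethod("show", "MethylomeSet", function(object) {
  cat("MethylomeSet with", nrow(object), "cytosine sites and",
      ncol(object), "libraries\n")
  ctx <- siteContext(object)
  if (length(ctx))
    cat("contexts:", paste(sprintf("%s=%d", names(table(ctx)), table(ctx)),
                           collapse = " "), "\n")
  cat("stages:", paste(unique(sampleStage(object)), collapse = ", "), "\n")
  callNextMethod()
})

#' DepthTrack: per-base read depth of one sequencing library
#'
#' A light S4 wrapper pairing a per-chromosome run-length encoded depth
#' vector (`RleList`) with the library size (total mapped reads) used for
#' reads-per-million scaling. Depths are non-negative; a normalized or
#' background-subtracted track has `librarySize = NA`.
#'
#' @param cov named `RleList` (or coercible) of per-base depths.
#' @param librarySize total mapped reads of the library; `NA` for derived
#'   (already normalized) tracks.
#' @return A `DepthTrack`.
#' @examples
#' dt <- DepthTrack(IRanges::RleList(chr1 = S4Vectors::Rle(c(0, 2, 2, 1))),
#'   librarySize = 1e6)
#' librarySize(dt)
#' @export
DepthTrack <- function(cov, librarySize = NA_real_) {
  if (!is(cov, "RleList")) cov <- methods::as(cov, "RleList")
  new("DepthTrack", cov = cov, librarySize = as.numeric(librarySize))
}

#' @rdname DepthTrack
#' @export
setClass("DepthTrack",
  representation(cov = "RleList", librarySize = "numeric"))

setValidity("DepthTrack", function(object) {
  msg <- NULL
  if (length(object@librarySize) != 1L)
    msg <- c(msg, "librarySize must be a single number")
  else if (!is.na(object@librarySize) && object@librarySize < 0)
    msg <- c(msg, "librarySize must be non-negative")
  if (any(vapply(object@cov, function(r) any(S4Vectors::runValue(r) < 0),
                 logical(1))))
    msg <- c(msg, "depths must be non-negative")
  if (is.null(names(object@cov)) && length(object@cov))
    msg <- c(msg, "coverage RleList must be named by chromosome")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn DepthTrack the underlying per-chromosome depth `RleList`.
#' @param x a `DepthTrack`.
#' @export
setMethod("depthRle", "DepthTrack", function(x) x@cov)

#' @describeIn DepthTrack total mapped reads (`NA` for normalized tracks).
#' @export
setMethod("librarySize", "DepthTrack", function(x) x@librarySize)

setMethod("show", "DepthTrack", function(object) {
  cat("DepthTrack over", length(object@cov), "chromosomes (",
      sum(as.numeric(vapply(object@cov, length, numeric(1)))), "bp )\n")
  cat("library size:", object@librarySize, "\n")
})
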