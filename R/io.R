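#' Read a reference genome from FASTA
#'
#' Loads a (multi-)FASTA genome, upper-cases all sequence, and masks every
#' non-A/C/G/T letter (IUPAC ambiguity codes and anything else) to `N`.
#' Masked bases are excluded from all downstream C/G denominators, which
#' keeps methylation-level denominators deterministic.
#'
#' @param path path to a FASTA file. A lambda spike-in, when present, is an
#'   extra record (conventionally named `"lambda"`).
#' @return A [Biostrings::DNAStringSet] with unique names.
#' @export
readGenome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA: ", path)
  # FASTA descriptions may carry comments after the identifier
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm))
    stop("duplicate record names in ", path)
  s <- toupper(as.character(x))
  s <- gsub("[^ACGTN]", "N", s)   # mask every ambiguity letter
  out <- Biostrings::DNAStringSet(s)
  names(out) <- nm
  out
}

#' Read a per-cytosine methylation report
#'
#' Parses the tab-separated per-cytosine layout produced by bisulfite
#' methylation extractors (one row per reference cytosine):
#' `chrom, pos (1-based), strand, count_methylated, count_unmethylated,
#' context, trinucleotide`. Rows with zero coverage are retained. Reverse
#' strand cytosines are reported at the forward-strand G position with
#' strand `-`.
#'
#' @param path path to the report (no header line).
#' @param sample_id identifier attached to every record.
#' @return A `GRanges` of width-1 sites with metadata columns `meth`,
#'   `unmeth`, `context`, `trinucleotide`, `sample_id`.
#' @export
readCytosineReport <- function(path, sample_id) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 3, 6, 7)))
  if (ncol(dt) != 7L)
    stop("expected 7 tab-separated columns in ", path, ", found ", ncol(dt))
  names(dt) <- c("chrom", "pos", "strand", "meth", "unmeth", "context",
                 "trinucleotide")
  bad <- which(!(dt$strand %in% c("+", "-")) |
               is.na(dt$pos) | dt$pos < 1 |
               is.na(dt$meth) | dt$meth < 0 |
               is.na(dt$unmeth) | dt$unmeth < 0)
  if (length(bad))
    stop("malformed cytosine report row at line ", bad[1], " of ", path)
  gr <- GenomicRanges::GRanges(dt$chrom,
    IRanges::IRanges(dt$pos, width = 1L), strand = dt$strand,
    meth = as.integer(dt$meth), unmeth = as.integer(dt$unmeth),
    context = dt$context, trinucleotide = dt$trinucleotide,
    sample_id = sample_id)
  gr
}

#' Write a per-cytosine methylation report
#'
#' Inverse of [readCytosineReport()]; one file per library.
#'
#' @param sites `GRanges` with `meth`, `unmeth`, `context` (and optionally
#'   `trinucleotide`) metadata columns.
#' @param path output path.
#' @export
writeCytosineReport <- function(sites, path) {
  mc <- S4Vectors::mcols(sites)
  tri <- if (!is.null(mc$trinucleotide)) mc$trinucleotide else "."
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    pos = GenomicRanges::start(sites),
    strand = as.character(GenomicRanges::strand(sites)),
    meth = mc$meth, unmeth = mc$unmeth,
    context = as.character(mc$context), trinucleotide = tri)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Assemble a MethylomeSet from per-sample cytosine reports
#'
#' All reports must cover the identical, identically ordered site set
#' (the layout produced by a genome-wide extractor or by
#' [writeStudy()]).
#'
#' @param paths named character vector of report paths; names are sample ids.
#' @param stages character vector of stage labels, parallel to `paths`.
#' @return A [MethylomeSet].
#' @export
methylomeFromReports <- function(paths, stages) {
  .stopifnot_named(paths, "report paths")
  grs <- lapply(names(paths), function(s) readCytosineReport(paths[[s]], s))
  key <- function(g) paste(GenomicRanges::seqnames(g),
                           GenomicRanges::start(g),
                           GenomicRanges::strand(g))
  k1 <- key(grs[[1]])
  for (g in grs[-1])
    if (!identical(key(g), k1))
      stop("cytosine reports do not cover an identical site set")
  sites <- grs[[1]]
  meth <- vapply(grs, function(g) S4Vectors::mcols(g)$meth,
                 integer(length(sites)))
  unmeth <- vapply(grs, function(g) S4Vectors::mcols(g)$unmeth,
                   integer(length(sites)))
  S4Vectors::mcols(sites) <- S4Vectors::DataFrame(
    context = S4Vectors::mcols(grs[[1]])$context)
  MethylomeSet(sites, meth, unmeth,
    S4Vectors::DataFrame(sample_id = names(paths), stage = stages))
}

#' Read element annotations from BED or GFF3
#'
#' The dialect is auto-detected from the file extension: `.bed` (0-based
#' half-open) or `.gff`/`.gff3` (1-based inclusive). Intervals are
#' normalized to the 1-based closed `GRanges` convention used throughout
#' the package; strand is preserved.
#'
#' @param path annotation file.
#' @param element_class class label attached to all intervals (e.g. `exon`,
#'   `intron`, `TE`, `lncRNA`, `circRNA`, `tRNA`, `CGI`). For GFF3 input the
#'   default is the feature `type` column.
#' @param genome optional `DNAStringSet`; when supplied, intervals on
#'   unknown chromosomes or beyond chromosome ends raise an error.
#' @return `GRanges` with `elementClass` and `elementId` metadata columns.
#' @export
readElements <- function(path, element_class = NULL, genome = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
      error = function(e) stop("malformed BED (", conditionMessage(e), ")"))
    if (any(GenomicRanges::width(gr) < 1L))
      stop("BED interval with end <= start in ", path)
    id <- if (!is.null(S4Vectors::mcols(gr)$name)) S4Vectors::mcols(gr)$name
          else paste0("el", seq_along(gr))
    cls <- if (is.null(element_class)) "element" else element_class
  } else if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "GFF3")
    mc <- S4Vectors::mcols(gr)
    id <- if (!is.null(mc$ID)) mc$ID else paste0("el", seq_along(gr))
    cls <- if (is.null(element_class)) as.character(mc$type) else element_class
  } else stop("unrecognized annotation extension: ", ext)
  if (!is.null(genome)) {
    sn <- as.character(GenomicRanges::seqnames(gr))
    if (!all(sn %in% names(genome)))
      stop("annotation refers to unknown chromosome(s): ",
           paste(setdiff(unique(sn), names(genome)), collapse = ", "))
    if (any(GenomicRanges::end(gr) > Biostrings::width(genome)[match(sn, names(genome))]))
      stop("annotation interval beyond chromosome end")
  }
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
    IRanges::ranges(gr), strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(elementClass = cls,
                                                elementId = id)
  out
}

#' Write element annotations to BED6
#'
#' @param elements `GRanges` with `elementId` metadata (used as the BED name).
#' @param path output `.bed` path.
#' @export
writeElements <- function(elements, path) {
  gr <- GenomicRanges::sort(elements, ignore.strand = TRUE)
  strand_chr <- as.character(GenomicRanges::strand(gr))
  strand_chr[strand_chr == "*"] <- "."
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = S4Vectors::mcols(gr)$elementId,
    score = 0L,
    strand = strand_chr)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a value track as bedGraph
#'
#' Intervals are sorted, overlap-checked, and adjacent intervals with equal
#' values are merged before writing; the result round-trips through
#' [readBedGraph()].
#'
#' @param x a `GRanges` with a numeric `score` column, or a `DepthTrack`.
#' @param path output `.bedGraph` path.
#' @export
writeBedGraph <- function(x, path) {
  if (is(x, "DepthTrack")) {
    rl <- depthRle(x)
    gr <- methods::as(rl, "GRanges")
    names(S4Vectors::mcols(gr)) <- "score"
  } else gr <- x
  if (is.null(S4Vectors::mcols(gr)$score))
    stop("bedGraph export requires a 'score' column")
  gr <- GenomicRanges::sort(GenomicRanges::granges(gr, use.mcols = TRUE),
                            ignore.strand = TRUE)
  if (length(gr) > 1) {
    same <- as.character(GenomicRanges::seqnames(gr))[-1] ==
            as.character(GenomicRanges::seqnames(gr))[-length(gr)]
    if (any(same & GenomicRanges::start(gr)[-1] <=
                   GenomicRanges::end(gr)[-length(gr)]))
      stop("overlapping intervals cannot be written as bedGraph")
  }
  con <- file(path, "w")
  writeLines("track type=bedGraph", con)
  close(con)
  if (length(gr)) {
    chrom <- as.character(GenomicRanges::seqnames(gr))
    start0 <- GenomicRanges::start(gr) - 1L
    end0 <- GenomicRanges::end(gr)
    val <- S4Vectors::mcols(gr)$score
    # merge adjacent runs of equal value
    n <- length(val)
    first <- c(TRUE, !(chrom[-1] == chrom[-n] & start0[-1] == end0[-n] &
                       val[-1] == val[-n]))
    run <- cumsum(first)
    last <- c(first[-1], TRUE)
    dt <- data.table::data.table(
      chrom = chrom[first], start = start0[first], end = end0[last],
      value = vapply(val[first], function(v) format(v, digits = 15),
                     character(1)))
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                       append = TRUE)
  }
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path `.bedGraph` file.
#' @return `GRanges` with a `score` column (1-based closed intervals).
#' @export
readBedGraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomicRanges::granges(gr, use.mcols = TRUE)
}

#' Convert an interval value track to a per-base DepthTrack
#'
#' @param gr `GRanges` with `score`.
#' @param seqlengths named chromosome lengths.
#' @param librarySize total mapped reads (NA for derived tracks).
#' @return A [DepthTrack].
#' @export
asDepthTrack <- function(gr, seqlengths, librarySize = NA_real_) {
  GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
  GenomeInfoDb::seqlengths(gr) <- seqlengths
  cov <- GenomicRanges::coverage(gr, weight = "score")
  DepthTrack(cov, librarySize)
}

#' Read heterozygous sites from VCF
#'
#' Only `CHROM`, `POS`, `REF`, `ALT` are consumed; multi-nucleotide alleles
#' are dropped (the polymorphic-site filter operates on SNVs).
#'
#' @param path uncompressed VCF (v4.x).
#' @return `GRanges` with `ref` and `alt` metadata columns.
#' @export
readVariants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- nchar(ref) == 1L & nchar(alt) == 1L
  GenomicRanges::GRanges(fix[keep, "CHROM"],
    IRanges::IRanges(as.integer(fix[keep, "POS"]), width = 1L),
    ref = ref[keep], alt = alt[keep])
}

#' Write heterozygous sites as a minimal VCF
#'
#' @param variants `GRanges` with `ref`/`alt`.
#' @param path output `.vcf` path.
#' @export
writeVariants <- function(variants, path) {
  variants <- GenomicRanges::sort(variants, ignore.strand = TRUE)
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  close(con)
  if (length(variants)) {
    dt <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(variants)),
      pos = GenomicRanges::start(variants), id = ".",
      ref = S4Vectors::mcols(variants)$ref,
      alt = S4Vectors::mcols(variants)$alt,
      qual = ".", filter = "PASS", info = ".")
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                       append = TRUE)
  }
  invisible(path)
}

#' Read a gene expression count table
#'
#' Layout: `gene_id`, `length_bp`, then one raw count column per library;
#' leading `#` comment lines are ignored.
#'
#' @param path TSV file.
#' @return list with `counts` (matrix genes x samples), `gene_length`
#'   (named), `samples`.
#' @export
readExpressionCounts <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          skip = "gene_id\t")
  counts <- as.matrix(dt[, -(1:2)])
  rownames(counts) <- dt$gene_id
  list(counts = counts,
       gene_length = setNames(dt$length_bp, dt$gene_id),
       samples = colnames(counts))
}

#' Write a gene expression count table
#'
#' @param counts matrix genes x samples.
#' @param gene_length named lengths (bp).
#' @param path output TSV.
#' @export
writeExpressionCounts <- function(counts, gene_length, path) {
  dt <- data.table::data.table(gene_id = rownames(counts),
    length_bp = as.integer(gene_length[rownames(counts)]))
  dt <- cbind(dt, data.table::as.data.table(counts))
  writeLines("# gene expression raw counts", path)
  data.table::fwrite(dt, path, sep = "\t", col.names = TRUE, append = TRUE)
  invisible(path)
}
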