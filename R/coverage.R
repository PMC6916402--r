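#' Normalize MeDIP depth against the input library
#'
#' Scales immunoprecipitation and input depths to reads-per-million of
#' their library sizes (removing library-size differences between
#' samples), subtracts the input background per position, and clips the
#' enrichment at zero (depths are non-negative signals):
#' `value = max(0, ip/ip_lib - input/input_lib) * 1e6`.
#'
#' @param ip,input [DepthTrack] objects on the same genome.
#' @return a [DepthTrack] in RPM units with `librarySize = NA`.
#' @export
normalizeDepth <- function(ip, input) {
  if (is.na(librarySize(ip)) || is.na(librarySize(input)) ||
      librarySize(ip) <= 0 || librarySize(input) <= 0)
    stop("both tracks need a positive library size")
  stopifnot(identical(names(depthRle(ip)), names(depthRle(input))))
  rl <- depthRle(ip) / librarySize(ip) -
        depthRle(input) / librarySize(input)
  rl <- methods::as(lapply(rl, function(r) {
    S4Vectors::runValue(r) <- pmax(S4Vectors::runValue(r), 0) * 1e6
    r
  }), "RleList")
  DepthTrack(rl, NA_real_)
}

#' Absolute and normalized read depth per element class (ARD/NARD)
#'
#' For each class of genomic components the absolute read depth is
#' `ARD = ARC x read_len / class_length`, where ARC (absolute read counts)
#' is recovered from the depth track as the depth integral over the class
#' divided by the read length (exact for non-clipped reads), and
#' `class_length` is the reduced (non-redundant) total bp of the class.
#' Each ARD is then normalized by the genome-wide ARD:
#' `NARD = ARD_class / ARD_genome`, so the GENOME row is exactly 1.
#'
#' @param depth a [DepthTrack] (raw or normalized).
#' @param elements `GRanges` with `elementClass` (and `elementId`).
#' @param read_len read-length constant of the ARD formula (default 150).
#' @param by `"class"` (default) or `"element"` for per-element records
#'   (used for the MeDIP/WGBS consistency check).
#' @return `data.frame` with `class`, `arc`, `class_length`, `ard`,
#'   `nard`; the GENOME row is always included.
#' @export
computeArd <- function(depth, elements, read_len = 150, by = c("class",
                       "element")) {
  by <- match.arg(by)
  stopifnot(length(elements) > 0)
  rl <- depthRle(depth)
  glen <- sum(as.numeric(vapply(rl, length, numeric(1))))
  garc <- sum(vapply(rl, function(r) sum(as.numeric(r)), numeric(1))) /
    read_len
  gard <- garc * read_len / glen
  key <- if (by == "class") as.character(S4Vectors::mcols(elements)$elementClass)
         else as.character(S4Vectors::mcols(elements)$elementId)
  rows <- lapply(unique(key), function(k) {
    el <- GenomicRanges::reduce(elements[key == k], ignore.strand = TRUE)
    len <- sum(GenomicRanges::width(el))
    if (len == 0) stop("class ", k, " has zero length")
    sn <- as.character(GenomicRanges::seqnames(el))
    integral <- 0
    for (ch in unique(sn)) {
      i <- which(sn == ch)
      v <- IRanges::Views(rl[[ch]],
        IRanges::IRanges(GenomicRanges::start(el)[i],
                         pmin(GenomicRanges::end(el)[i],
                              length(rl[[ch]]))))
      integral <- integral + sum(as.numeric(sum(v)))
    }
    arc <- integral / read_len
    data.frame(class = k, arc = arc, class_length = len,
               ard = arc * read_len / len,
               nard = (arc * read_len / len) / gard)
  })
  out <- rbind(data.frame(class = "GENOME", arc = garc, class_length = glen,
                          ard = gard, nard = 1),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

# bin index (1..nbins) for 0-based offsets within an element of length len
.binIndex <- function(offsets, len, nbins) {
  pmin(floor(nbins * offsets / len), nbins - 1L) + 1L
}

# numeric per-position values of an Rle over [start, end], positions
# outside [1, len] give NA
.rleSlice <- function(r, start, end) {
  L <- length(r)
  out <- rep(NA_real_, end - start + 1L)
  a <- max(1L, start); b <- min(L, end)
  if (a <= b)
    out[(a - start + 1L):(b - start + 1L)] <-
      as.numeric(S4Vectors::window(r, a, b))
  out
}

#' Metaplot profile over genomic elements
#'
#' Averages a per-base ratio statistic over elements after mapping each
#' element (and, depending on the scheme, its 2-kb flanks) onto a fixed
#' number of bins. Three binning schemes are supported:
#' \describe{
#'   \item{`element20`}{each element divided into 20 equal bins (20 bins).}
#'   \item{`flank100`}{2-kb flanks in 20 fixed 100-bp bins each side plus
#'     20 proportional bins across the element (60 bins).}
#'   \item{`gene40`}{2-kb flanks in 20 fixed 100-bp bins each side plus 40
#'     proportional windows across the gene (80 bins).}
#' }
#' Positions are assigned to proportional bins by
#' `floor(nbins * offset / length)`; reverse-strand elements are flipped so
#' every profile reads 5' to 3'. Within one element a bin's value is
#' `sum(numerator) / sum(denominator)`; bins are then averaged across
#' elements with equal element weight. For a fragment-methylation profile
#' use the tracks from [mlTrack()] and [cgTrack()]; for a depth profile
#' pass the depth as `numerator` and `denominator = NULL` (per-bp mean).
#' Elements shorter than the number of proportional bins are skipped and
#' tallied.
#'
#' @param numerator `RleList` (or [DepthTrack]) of per-base numerator
#'   values.
#' @param denominator `RleList` of per-base denominator values, or `NULL`
#'   for a plain per-bp mean.
#' @param elements `GRanges` (strand used for orientation).
#' @param scheme one of `"element20"`, `"flank100"`, `"gene40"`.
#' @param flank flank width in bp for the flanked schemes (default 2000).
#' @return `data.frame` with `bin`, `zone` (upstream/body/downstream),
#'   `value`, `n` (elements contributing); attribute `n_skipped`.
#' @export
metaplot <- function(numerator, denominator = NULL, elements,
                     scheme = c("element20", "flank100", "gene40"),
                     flank = 2000L) {
  scheme <- match.arg(scheme)
  if (is(numerator, "DepthTrack")) numerator <- depthRle(numerator)
  body_bins <- switch(scheme, element20 = 20L, flank100 = 20L, gene40 = 40L)
  flank_bins <- if (scheme == "element20") 0L else 20L
  flank_bin_w <- if (flank_bins) flank %/% flank_bins else 0L
  nb <- body_bins + 2L * flank_bins
  acc <- matrix(0, nrow = nb, ncol = 2)  # value sum, element count
  n_skipped <- 0L
  sn <- as.character(GenomicRanges::seqnames(elements))
  st <- GenomicRanges::start(elements)
  en <- GenomicRanges::end(elements)
  strnd <- as.character(GenomicRanges::strand(elements))
  for (i in seq_along(elements)) {
    len <- en[i] - st[i] + 1L
    if (len < body_bins) { n_skipped <- n_skipped + 1L; next }
    ch <- sn[i]
    a <- st[i] - flank_bins * flank_bin_w
    b <- en[i] + flank_bins * flank_bin_w
    num <- .rleSlice(numerator[[ch]], a, b)
    den <- if (is.null(denominator)) rep(1, b - a + 1L)
           else .rleSlice(denominator[[ch]], a, b)
    npos <- b - a + 1L
    off <- seq_len(npos) - 1L
    fl <- flank_bins * flank_bin_w
    zone <- ifelse(off < fl, 1L, ifelse(off < fl + len, 2L, 3L))
    bin <- integer(npos)
    bin[zone == 1L] <- off[zone == 1L] %/% flank_bin_w + 1L
    bin[zone == 2L] <- flank_bins +
      .binIndex(off[zone == 2L] - fl, len, body_bins)
    if (any(zone == 3L))
      bin[zone == 3L] <- flank_bins + body_bins +
        (off[zone == 3L] - fl - len) %/% flank_bin_w + 1L
    if (strnd[i] == "-") bin <- nb + 1L - bin
    ok <- !is.na(num) & !is.na(den)
    nsum <- rowsum(num[ok], bin[ok])
    dsum <- rowsum(den[ok], bin[ok])
    idx <- as.integer(rownames(nsum))
    val <- ifelse(dsum[, 1] > 0, nsum[, 1] / dsum[, 1], NA)
    good <- !is.na(val)
    acc[idx[good], 1] <- acc[idx[good], 1] + val[good]
    acc[idx[good], 2] <- acc[idx[good], 2] + 1
  }
  zone_lab <- c(rep("upstream", flank_bins), rep("body", body_bins),
                rep("downstream", flank_bins))
  out <- data.frame(bin = seq_len(nb), zone = zone_lab,
                    value = ifelse(acc[, 2] > 0, acc[, 1] / acc[, 2], NA),
                    n = acc[, 2])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Per-base methylation-level track from called sites
#'
#' An `RleList` holding, at every cytosine position called methylated, the
#' site methylation level (both strands collapse onto genomic position;
#' a position carrying mCs on both strands holds the sum of their levels,
#' matching the MLgf numerator). All other positions are zero.
#'
#' @param sites called sites from [callMethylation()].
#' @param genome `DNAStringSet`.
#' @param exclude chromosomes to skip.
#' @return named `RleList`.
#' @export
mlTrack <- function(sites, genome, exclude = "lambda") {
  chroms <- setdiff(names(genome), exclude)
  mC <- sites[S4Vectors::mcols(sites)$is_mC %in% TRUE]
  sn <- as.character(GenomicRanges::seqnames(mC))
  rl <- lapply(chroms, function(ch) {
    L <- length(genome[[ch]])
    v <- numeric(L)
    i <- which(sn == ch)
    if (length(i)) {
      agg <- rowsum(S4Vectors::mcols(mC)$ml[i],
                    GenomicRanges::start(mC)[i])
      v[as.integer(rownames(agg))] <- agg[, 1]
    }
    S4Vectors::Rle(v)
  })
  names(rl) <- chroms
  methods::as(rl, "RleList")
}

#' Per-base C+G indicator track (MLgf denominator)
#'
#' @param genome `DNAStringSet`.
#' @param exclude chromosomes to skip.
#' @return named `RleList` of 0/1 indicators.
#' @export
cgTrack <- function(genome, exclude = "lambda") {
  chroms <- setdiff(names(genome), exclude)
  rl <- lapply(chroms, function(ch)
    S4Vectors::Rle(as.numeric(.charvec(genome, ch) %in% c("C", "G"))))
  names(rl) <- chroms
  methods::as(rl, "RleList")
}

#' Consistency between MeDIP enrichment and WGBS methylation
#'
#' Pearson correlation between per-element normalized read depth (NARD,
#' from [computeArd()] with `by = "element"`) and per-element fragment
#' methylation (MLgf), the cross-platform agreement check between the
#' antibody-based and bisulfite-based assays.
#'
#' @param nard numeric per-element NARD.
#' @param mlgf numeric per-element MLgf, parallel to `nard`.
#' @return list with `r`, `p`, `n`, `flagged`.
#' @export
consistencyMedipWgbs <- function(nard, mlgf) {
  stopifnot(length(nard) == length(mlgf))
  .safeCor(nard, mlgf, min_n = 10L)
}
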