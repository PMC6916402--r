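#' Classify the sequence context of cytosines
#'
#' Assigns each cytosine its methylation context from the two bases
#' immediately downstream on its own strand: `CpG` when the next base is G,
#' `CHG` when the triplet is C-H-G, `CHH` when it is C-H-H (H = A, C or T),
#' and `boundary` when the needed downstream bases run off the chromosome
#' end or are masked to N. A CpG call needs only one downstream base.
#'
#' @param genome `DNAStringSet` from [readGenome()].
#' @param chrom,pos,strand parallel vectors; `pos` is the 1-based position
#'   of the cytosine (for `-` strand sites, the forward-strand G position).
#' @return character vector of context labels.
#' @export
classifyContext <- function(genome, chrom, pos, strand) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(strand) == n)
  out <- character(n)
  for (ch in unique(chrom)) {
    s <- .charvec(genome, ch)
    i <- which(chrom == ch)
    p <- pos[i]; st <- strand[i]
    ix <- function(v, i) {
      r <- rep(NA_character_, length(i))
      ok <- i >= 1L & i <= length(v)
      r[ok] <- v[i[ok]]
      r
    }
    base <- ifelse(st == "+", ix(s, p), .complement(ix(s, p)))
    if (any(base != "C", na.rm = TRUE) || anyNA(base))
      stop("position is not a cytosine on the given strand (first offender: ",
           ch, ":", p[which(is.na(base) | base != "C")[1]], ")")
    nxt1 <- ifelse(st == "+", ix(s, p + 1L), .complement(ix(s, p - 1L)))
    nxt2 <- ifelse(st == "+", ix(s, p + 2L), .complement(ix(s, p - 2L)))
    out[i] <- .contextFromNeighbors(nxt1, nxt2)
  }
  out
}

# context from the two downstream bases (NA = off the end)
.contextFromNeighbors <- function(nxt1, nxt2) {
  isH1 <- nxt1 %in% c("A", "C", "T")
  isH2 <- nxt2 %in% c("A", "C", "T")
  ifelse(is.na(nxt1) | nxt1 == "N", "boundary",
  ifelse(nxt1 == "G", "CpG",
  ifelse(is.na(nxt2) | nxt2 == "N", "boundary",
  ifelse(isH1 & nxt2 == "G", "CHG",
  ifelse(isH1 & isH2, "CHH", "boundary")))))
}

#' Enumerate all cytosine sites of a genome
#'
#' Emits every C on the forward strand and every G on the forward strand
#' (a reverse-strand cytosine, strand `-`) exactly once, with its context.
#' Together the non-boundary labels partition all cytosines into
#' CpG/CHG/CHH.
#'
#' @param genome `DNAStringSet`.
#' @param chroms chromosomes to enumerate (default all).
#' @return `GRanges` of width-1 sites, sorted by chromosome and position,
#'   with a `context` metadata column.
#' @export
enumerateCytosines <- function(genome, chroms = names(genome)) {
  pieces <- lapply(chroms, function(ch) {
    s <- .charvec(genome, ch)
    L <- length(s)
    pad <- function(v) c(v, NA, NA)
    fwd <- which(s == "C")
    rev <- which(s == "G")
    # forward: downstream = p+1, p+2
    sp <- pad(s)
    ctx_f <- .contextFromNeighbors(sp[fwd + 1L], sp[fwd + 2L])
    # reverse: downstream = complement(p-1), complement(p-2)
    sp2 <- c(NA, NA, s)
    ctx_r <- .contextFromNeighbors(.complement(sp2[rev + 1L]),
                                   .complement(sp2[rev]))
    pos <- c(fwd, rev)
    std <- rep(c("+", "-"), c(length(fwd), length(rev)))
    ctx <- c(ctx_f, ctx_r)
    o <- order(pos, std)
    GenomicRanges::GRanges(rep(ch, length(pos)),
                           IRanges::IRanges(pos[o], width = 1L),
                           strand = std[o], context = ctx[o])
  })
  gr <- suppressWarnings(do.call(c, pieces))
  GenomeInfoDb::seqlevels(gr) <- chroms
  GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)[
    match(chroms, names(genome))]
  gr
}

#' Sequence-composition statistics in tiling windows
#'
#' Tiles each chromosome with fixed windows (default 10 kb, non-overlapping)
#' and reports, per window: the CpG observed/expected ratio
#' `(N_CpG x L) / (N_C x N_G)`, the (C+G)/length ratio, and the fraction of
#' window nucleotides covered by CpG dinucleotides, CHG triplets and CHH
#' triplets (pattern footprints on either strand, each nucleotide counted
#' once), plus the fraction covered by CpG islands when a CGI set is given.
#' `cpg_oe` is `NA` (undefined, not zero) when the window lacks C or G.
#' Chromosome-final partial windows are emitted and flagged `partial`.
#'
#' @param genome `DNAStringSet`.
#' @param cgi optional `GRanges` of CpG islands.
#' @param window,step window and step size in bp (defaults 10000, equal:
#'   non-overlapping tiling).
#' @param exclude chromosomes to skip (default the lambda spike-in).
#' @return `GRanges` of windows with composition metadata columns.
#' @export
windowComposition <- function(genome, cgi = NULL, window = 10000L,
                              step = window, exclude = "lambda") {
  stopifnot(window >= step)
  chroms <- setdiff(names(genome), exclude)
  pieces <- lapply(chroms, function(ch) {
    s <- .charvec(genome, ch)
    L <- length(s)
    isC <- s == "C"; isG <- s == "G"
    isH <- s %in% c("A", "C", "T")          # H on forward strand
    isD <- s %in% c("A", "G", "T")          # complement-of-H on forward
    n <- L
    at <- function(v, off) c(v[-seq_len(off)], rep(FALSE, off))
    # pattern start indicators
    cpg <- isC & at(isG, 1L)                                  # CG
    chg_f <- isC & at(isH, 1L) & at(isG, 2L)                  # + strand CHG
    chh_f <- isC & at(isH, 1L) & at(isH, 2L)                  # + strand CHH
    chg_r <- isC & at(isD, 1L) & at(isG, 2L)                  # - strand CHG
    chh_r <- isD & at(isD, 1L) & at(isG, 2L)                  # - strand CHH
    footprint <- function(starts_list, width) {
      cov <- logical(n)
      for (st in starts_list) {
        idx <- which(st)
        for (k in 0:(width - 1L)) cov[idx + k] <- TRUE
      }
      cov[seq_len(n)]
    }
    cov_cpg <- footprint(list(cpg), 2L)
    cov_chg <- footprint(list(chg_f, chg_r), 3L)
    cov_chh <- footprint(list(chh_f, chh_r), 3L)
    cov_cgi <- logical(n)
    if (!is.null(cgi)) {
      ci <- cgi[as.character(GenomicRanges::seqnames(cgi)) == ch]
      for (j in seq_along(ci)) {
        a <- max(1L, GenomicRanges::start(ci)[j])
        b <- min(n, GenomicRanges::end(ci)[j])
        if (a <= b) cov_cgi[a:b] <- TRUE
      }
    }
    csC <- .cum0(isC); csG <- .cum0(isG); csCpG <- .cum0(cpg)
    csFcpg <- .cum0(cov_cpg); csFchg <- .cum0(cov_chg)
    csFchh <- .cum0(cov_chh); csFcgi <- .cum0(cov_cgi)
    starts <- seq.int(1L, L, by = step)
    ends <- pmin(starts + window - 1L, L)
    keep <- starts <= L
    starts <- starts[keep]; ends <- ends[keep]
    wl <- ends - starts + 1
    rng <- function(cs) cs[ends + 1L] - cs[starts]
    nC <- rng(csC); nG <- rng(csG); nCpG <- rng(csCpG)
    oe <- ifelse(nC > 0 & nG > 0, nCpG * wl / (nC * nG), NA_real_)
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts, ends),
      cpg_oe = oe,
      cg_ratio = (nC + nG) / wl,
      cpg_ratio = rng(csFcpg) / wl,
      chg_ratio = rng(csFchg) / wl,
      chh_ratio = rng(csFchh) / wl,
      cgi_ratio = rng(csFcgi) / wl,
      partial = wl < window)
  })
  suppressWarnings(do.call(c, pieces))
}

#' Detect CpG islands
#'
#' Classic sliding-window CGI detection (Gardiner-Garden & Frommer style
#' defaults): every `min_len`-bp window advanced by 1 bp that satisfies
#' GC fraction >= `min_gc` and CpG observed/expected >= `min_oe` is kept,
#' overlapping qualifying windows are merged into maximal islands, and a
#' merged island is retained only if it satisfies the GC and O/E criteria
#' as a whole (a short CpG-dense patch whose qualifying windows lean on
#' flanking sequence is thereby rejected).
#'
#' @param genome `DNAStringSet`.
#' @param min_len minimal island (and scan window) length, bp.
#' @param min_gc minimal GC fraction.
#' @param min_oe minimal CpG O/E ratio.
#' @param exclude chromosomes to skip.
#' @return sorted non-overlapping `GRanges` with `elementClass = "CGI"`.
#' @export
detectCgi <- function(genome, min_len = 200L, min_gc = 0.5, min_oe = 0.6,
                      exclude = "lambda") {
  stopifnot(min_len > 0, min_gc > 0, min_oe > 0)
  chroms <- setdiff(names(genome), exclude)
  pieces <- lapply(chroms, function(ch) {
    s <- .charvec(genome, ch)
    L <- length(s)
    if (L < min_len) return(GenomicRanges::GRanges())
    isC <- s == "C"; isG <- s == "G"
    cpg <- isC & c(isG[-1], FALSE)
    csC <- .cum0(isC); csG <- .cum0(isG); csCpG <- .cum0(cpg)
    starts <- seq_len(L - min_len + 1L)
    ends <- starts + min_len - 1L
    nC <- csC[ends + 1L] - csC[starts]
    nG <- csG[ends + 1L] - csG[starts]
    nCpG <- csCpG[ends + 1L] - csCpG[starts]
    gc_ok <- (nC + nG) / min_len >= min_gc
    oe_ok <- nC > 0 & nG > 0 & nCpG * min_len / (nC * nG) >= min_oe
    q <- which(gc_ok & oe_ok)
    if (!length(q)) return(GenomicRanges::GRanges())
    isl <- IRanges::reduce(IRanges::IRanges(q, width = min_len))
    # island-level check: the merged region must itself qualify
    ia <- IRanges::start(isl); ib <- IRanges::end(isl)
    inC <- csC[ib + 1L] - csC[ia]
    inG <- csG[ib + 1L] - csG[ia]
    inCpG <- csCpG[ib + 1L] - csCpG[ia]
    iw <- IRanges::width(isl)
    keep <- (inC + inG) / iw >= min_gc & inC > 0 & inG > 0 &
      inCpG * iw / (inC * inG) >= min_oe
    isl <- isl[keep]
    if (!length(isl)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(rep(ch, length(isl)), isl)
  })
  gr <- suppressWarnings(do.call(c, pieces))
  if (length(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      elementClass = "CGI", elementId = paste0("CGI", seq_along(gr)))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Correlate a window composition statistic with window methylation
#'
#' Pearson correlation between one sequence-composition statistic of
#' [windowComposition()] windows (e.g. `cpg_oe` or `chh_ratio`) and the
#' per-window fragment methylation level, dropping windows with undefined
#' values pairwise. Partial chromosome-final windows are excluded by
#' default (unequal-length bias).
#'
#' @param windows `GRanges` from [windowComposition()].
#' @param stat name of the composition column to use.
#' @param mlgf numeric vector of per-window MLgf, parallel to `windows`.
#' @param use_partial include flagged partial windows?
#' @return list with `r`, `p`, `n`, `flagged` (zero-variance guard).
#' @export
correlateWindowStat <- function(windows, stat, mlgf, use_partial = FALSE) {
  x <- S4Vectors::mcols(windows)[[stat]]
  stopifnot(length(x) == length(mlgf))
  if (!use_partial) {
    keep <- !S4Vectors::mcols(windows)$partial
    x <- x[keep]; mlgf <- mlgf[keep]
  }
  .safeCor(x, mlgf)
}
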