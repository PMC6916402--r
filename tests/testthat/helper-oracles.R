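# Independent oracles used across tests. These deliberately use naive,
# easily-audited algorithms and never share code with the implementation.

# two-sided Fisher p by full hypergeometric enumeration over the table
# support (scalar)
oracleFisher2x2 <- function(m1, u1, m2, u2) {
  n1 <- m1 + u1; n2 <- m2 + u2; m <- m1 + m2
  if (n1 == 0 || n2 == 0 || m == 0 || m == n1 + n2) return(1)
  ks <- max(0, m - n2):min(m, n1)
  probs <- vapply(ks, function(k)
    choose(n1, k) * choose(n2, m - k) / choose(n1 + n2, m), numeric(1))
  pobs <- probs[ks == m1]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# O(n^2) interval overlap: every pair is examined explicitly (outer loop
# over the first set, arithmetic against all of the second)
bruteOverlap <- function(a, b) {
  sa <- as.character(GenomicRanges::seqnames(a))
  sb <- as.character(GenomicRanges::seqnames(b))
  a1 <- GenomicRanges::start(a); a2 <- GenomicRanges::end(a)
  b1 <- GenomicRanges::start(b); b2 <- GenomicRanges::end(b)
  rows <- vector("list", length(a))
  for (i in seq_along(a)) {
    lo <- pmax(a1[i], b1)
    hi <- pmin(a2[i], b2)
    j <- which(sb == sa[i] & hi >= lo)
    if (length(j))
      rows[[i]] <- data.frame(i = i, j = j,
                              overlap_bp = (hi - lo + 1L)[j])
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(data.frame(i = integer(), j = integer(),
                                       overlap_bp = integer()))
  do.call(rbind, rows)
}

# Pearson r from the raw covariance formula (oracle for correlation ops)
oraclePearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# build a MethylomeSet from a compact site table (helper, not an oracle)
msFromTable <- function(tab, meth, unmeth, stages) {
  gr <- GenomicRanges::GRanges(tab$chrom,
    IRanges::IRanges(tab$pos, width = 1L), strand = tab$strand,
    context = tab$context)
  MethylomeSet(gr, meth, unmeth,
    S4Vectors::DataFrame(sample_id = colnames(meth), stage = stages))
}
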