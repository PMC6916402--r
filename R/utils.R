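# internal helpers shared across modules

# character vector of one chromosome sequence (uppercase)
.charvec <- function(genome, chrom) {
  strsplit(as.character(genome[[chrom]]), "", fixed = TRUE)[[1]]
}

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

# Pearson correlation with pairwise NA removal and a zero-variance flag.
# Returns list(r, p, n, flagged); flagged tests report r = NA.
.safeCor <- function(x, y, min_n = 3L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_n)
    return(list(r = NA_real_, p = NA_real_, n = length(x), flagged = TRUE))
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), flagged = TRUE))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       flagged = FALSE)
}

# C+G letter count of a whole genome or per chromosome
.cgCount <- function(genome, exclude = "lambda") {
  keep <- setdiff(names(genome), exclude)
  lf <- Biostrings::letterFrequency(genome[keep], letters = c("C", "G"))
  sum(lf)
}

# per-chromosome cumulative indicator sums, prepended with 0 so that
# sum over [a,b] (1-based inclusive) = cs[b+1] - cs[a]
.cum0 <- function(x) c(0, cumsum(x))

.stopifnot_named <- function(x, what) {
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop(what, " must have unique names", call. = FALSE)
  invisible(x)
}
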