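#' Reads per kilobase per million mapped reads (RPKM)
#'
#' `rpkm = count x 1e9 / (gene_length_bp x total_mapped_reads)`.
#'
#' @param count raw read count(s).
#' @param gene_len_bp gene length in bp (> 0).
#' @param total_mapped total mapped reads of the library (> 0).
#' @return numeric RPKM, vectorized.
#' @export
rpkm <- function(count, gene_len_bp, total_mapped) {
  if (any(gene_len_bp <= 0)) stop("gene length must be positive")
  if (any(total_mapped <= 0)) stop("total mapped reads must be positive")
  count * 1e9 / (gene_len_bp * total_mapped)
}

#' Expression quantile classes (high / medium / low / none)
#'
#' Genes with mean RPKM at or below `none_threshold` form the `none`
#' class; the remaining (expressed) genes are split into tertiles of mean
#' RPKM -- `low`, `medium`, `high` -- with class sizes differing by at most
#' one and ties broken stably by input order.
#'
#' @param mean_rpkm numeric mean RPKM per gene.
#' @param ids gene identifiers (tie-break order).
#' @param none_threshold RPKM at or below which a gene is unexpressed
#'   (default 0.1).
#' @return factor with levels `none`, `low`, `medium`, `high`, parallel to
#'   `mean_rpkm`.
#' @export
expressionClasses <- function(mean_rpkm, ids = seq_along(mean_rpkm),
                              none_threshold = 0.1) {
  n <- length(mean_rpkm)
  out <- rep("none", n)
  expressed <- which(mean_rpkm > none_threshold)
  if (length(expressed) >= 3) {
    o <- expressed[order(mean_rpkm[expressed])]   # stable for ties
    k <- length(o)
    sizes <- diff(round(seq(0, k, length.out = 4)))
    lab <- rep(c("low", "medium", "high"), sizes)
    out[o] <- lab
  } else if (length(expressed) > 0) {
    out[expressed] <- "low"
  }
  factor(out, levels = c("none", "low", "medium", "high"))
}

#' Pairwise-stage methylation/expression gene selection
#'
#' For each gene, unequal-variance (Welch) t-tests compare the replicate
#' MLgf values and the replicate expression values (on `log(RPKM + 1)` by
#' default) between two stages. A gene is selected when both tests give
#' `p < p_max` and the methylation difference opposes the expression
#' difference -- hypomethylated-and-more-expressed in one stage, or the
#' reverse. Genes with zero variance in both groups of either test are
#' excluded and flagged.
#'
#' @param ml_a,ml_b matrices (genes x replicates) of per-replicate MLgf
#'   for stages A and B (gene body or promoter region).
#' @param expr_a,expr_b matrices (genes x replicates) of per-replicate
#'   RPKM.
#' @param gene_ids gene identifiers.
#' @param p_max per-gene significance level (default 0.05).
#' @param log_expr test expression on `log(RPKM + 1)` (default TRUE).
#' @return `data.frame` with per-gene `p_ml`, `q_ml`, `p_expr`, `q_expr`,
#'   mean differences, `selected`, `category`
#'   (`hypo_high_in_A` / `hyper_low_in_A` / `ns`) and `flagged`.
#' @export
stagePairGenes <- function(ml_a, ml_b, expr_a, expr_b,
                           gene_ids = rownames(ml_a), p_max = 0.05,
                           log_expr = TRUE) {
  stopifnot(nrow(ml_a) == nrow(ml_b), nrow(ml_a) == nrow(expr_a),
            nrow(expr_a) == nrow(expr_b))
  if (log_expr) { expr_a <- log(expr_a + 1); expr_b <- log(expr_b + 1) }
  n <- nrow(ml_a)
  welch <- function(x, y) {
    if (sd(x) == 0 && sd(y) == 0) return(NA_real_)
    tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
  }
  p_ml <- vapply(seq_len(n), function(i) welch(ml_a[i, ], ml_b[i, ]),
                 numeric(1))
  p_expr <- vapply(seq_len(n), function(i) welch(expr_a[i, ], expr_b[i, ]),
                   numeric(1))
  d_ml <- rowMeans(ml_a) - rowMeans(ml_b)
  d_expr <- rowMeans(expr_a) - rowMeans(expr_b)
  flagged <- is.na(p_ml) | is.na(p_expr)
  sig <- !flagged & p_ml < p_max & p_expr < p_max
  opposed <- sign(d_ml) * sign(d_expr) < 0
  selected <- sig & opposed
  category <- rep("ns", n)
  category[selected & d_ml < 0] <- "hypo_high_in_A"
  category[selected & d_ml > 0] <- "hyper_low_in_A"
  data.frame(gene_id = if (is.null(gene_ids)) seq_len(n) else gene_ids,
             p_ml = p_ml, q_ml = bhFdr(ifelse(is.na(p_ml), 1, p_ml)),
             p_expr = p_expr,
             q_expr = bhFdr(ifelse(is.na(p_expr), 1, p_expr)),
             d_ml = d_ml, d_expr = d_expr,
             selected = selected, category = category, flagged = flagged)
}

#' Genome-wide methylation-expression correlation
#'
#' Pearson correlation between per-gene MLgf and `log(RPKM + 1)`; in
#' methylation-regulated genomes the association is negative.
#'
#' @param mlgf per-gene fragment methylation levels.
#' @param mean_rpkm per-gene mean RPKM.
#' @return list with `r`, `p`, `n`, `flagged`.
#' @export
mlExpressionCorrelation <- function(mlgf, mean_rpkm) {
  stopifnot(length(mlgf) == length(mean_rpkm))
  .safeCor(mlgf, log(mean_rpkm + 1), min_n = 10L)
}

#' Compact letter display for group comparisons
#'
#' Summarizes all pairwise unequal-variance t-tests (Holm-adjusted) among
#' groups as lowercase letters: groups that are not significantly
#' different share at least one letter (the insert-and-absorb
#' construction). Used to annotate per-stage distributions.
#'
#' @param values_by_group named list of numeric replicate vectors (>= 2
#'   groups, >= 2 replicates each).
#' @param alpha significance level after Holm adjustment (default 0.05).
#' @return named character vector of letter codes, ordered by decreasing
#'   group mean.
#' @export
groupLetters <- function(values_by_group, alpha = 0.05) {
  .stopifnot_named(values_by_group, "groups")
  k <- length(values_by_group)
  stopifnot(k >= 2, all(vapply(values_by_group, length, integer(1)) >= 2))
  nm <- names(values_by_group)
  pairs <- utils::combn(k, 2)
  pv <- apply(pairs, 2, function(ij) {
    x <- values_by_group[[ij[1]]]; y <- values_by_group[[ij[2]]]
    if (sd(x) == 0 && sd(y) == 0) return(1)
    tryCatch(t.test(x, y)$p.value, error = function(e) 1)
  })
  pv <- p.adjust(pv, method = "holm")
  diffmat <- matrix(FALSE, k, k)
  for (j in seq_len(ncol(pairs)))
    if (pv[j] < alpha) {
      diffmat[pairs[1, j], pairs[2, j]] <- TRUE
      diffmat[pairs[2, j], pairs[1, j]] <- TRUE
    }
  ord <- order(-vapply(values_by_group, mean, numeric(1)))
  # insert-and-absorb: columns are letter groups (sets of group indices)
  cols <- list(ord)
  for (j in seq_len(ncol(pairs))) {
    if (pv[j] >= alpha) next
    a <- pairs[1, j]; b <- pairs[2, j]
    repeat {
      viol <- which(vapply(cols, function(cc) a %in% cc && b %in% cc,
                           logical(1)))
      if (!length(viol)) break
      cc <- cols[[viol[1]]]
      cols[[viol[1]]] <- setdiff(cc, a)
      cols <- c(cols, list(setdiff(cc, b)))
      # absorb subsets
      keep <- rep(TRUE, length(cols))
      for (ii in seq_along(cols)) for (jj in seq_along(cols))
        if (ii != jj && keep[ii] && keep[jj] &&
            all(cols[[ii]] %in% cols[[jj]])) keep[ii] <- FALSE
      cols <- cols[keep]
    }
  }
  # order letter columns by the best-ranked member for stable output
  colrank <- vapply(cols, function(cc) min(match(cc, ord)), numeric(1))
  cols <- cols[order(colrank)]
  letters_out <- setNames(rep("", k), nm)
  for (ci in seq_along(cols))
    for (g in cols[[ci]])
      letters_out[g] <- paste0(letters_out[g], letters[ci])
  letters_out[ord]
}
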