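#' Score recovery of planted DMRs
#'
#' Matches called DMRs against the planted truth intervals: a planted DMR
#' counts as recovered when some call overlaps it reciprocally by at least
#' `min_frac` of both lengths and the call's hypermethylated side is the
#' planted target stage. A call with no overlap with any informative
#' planted region is a false call; the empirical FDR is the false-call
#' fraction.
#'
#' @param called `GRanges` from [callDmrs()] (with
#'   `metadata(called)$groups` naming the two compared stages).
#' @param planted truth `GRanges` (`target_stage` metadata); planted
#'   regions whose target stage is not among the compared groups are
#'   uninformative for this pair and are dropped.
#' @param min_frac reciprocal-overlap fraction (default 0.5).
#' @param also_true optional `GRanges` of additional genuinely
#'   differential regions (e.g. the bodies of methylation-coupled genes)
#'   that calls may legitimately hit; they extend the false-call reference
#'   but are not scored for recovery.
#' @return list with `n_planted`, `n_recovered`, `recovered` (logical per
#'   informative planted DMR), `n_called`, `n_false`, `fdr`.
#' @export
scoreDmrRecovery <- function(called, planted, min_frac = 0.5,
                             also_true = NULL) {
  groups <- S4Vectors::metadata(called)$groups
  informative <- planted[
    S4Vectors::mcols(planted)$target_stage %in% groups]
  hyper <- ifelse(S4Vectors::mcols(called)$direction == "hyper-in-group1",
                  groups[1], groups[2])
  rec <- logical(length(informative))
  if (length(called) && length(informative)) {
    hits <- GenomicRanges::findOverlaps(informative, called,
                                        ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      informative[qi], called[si], ignore.strand = TRUE))
    good <- ov >= min_frac * GenomicRanges::width(informative)[qi] &
      ov >= min_frac * GenomicRanges::width(called)[si] &
      hyper[si] == S4Vectors::mcols(informative)$target_stage[qi]
    rec[unique(qi[good])] <- TRUE
  }
  reference <- informative
  if (!is.null(also_true) && length(also_true))
    reference <- suppressWarnings(c(GenomicRanges::granges(informative),
                                    GenomicRanges::granges(also_true)))
  false_call <- if (length(called))
    !IRanges::overlapsAny(called, reference, ignore.strand = TRUE)
    else logical(0)
  list(n_planted = length(informative), n_recovered = sum(rec),
       recovered = rec, n_called = length(called),
       n_false = sum(false_call),
       fdr = if (length(called)) sum(false_call) / length(called) else 0)
}

#' Per-replicate fragment methylation of a gene set
#'
#' Calls methylation separately in every replicate library of the given
#' stages (shared lambda nonconversion rate) and returns one MLgf matrix
#' (genes x replicates) per stage, as used by [stagePairGenes()].
#'
#' @param x a [MethylomeSet].
#' @param regions `GRanges` of gene bodies or promoters, with `elementId`.
#' @param genome `DNAStringSet`.
#' @param stages stages to include (default all).
#' @return named list of MLgf matrices.
#' @export
replicateMlgf <- function(x, regions, genome, stages = unique(sampleStage(x))) {
  conv <- estimateConversion(x)
  out <- lapply(stages, function(st) {
    cols <- which(sampleStage(x) == st)
    m <- vapply(cols, function(j) {
      called <- callMethylation(x[, j], nonconversion = conv$nonconversion)
      S4Vectors::mcols(fragmentML(called, regions, genome))$mlgf
    }, numeric(length(regions)))
    rownames(m) <- S4Vectors::mcols(regions)$elementId
    m
  })
  names(out) <- stages
  out
}

#' Run the full analysis pipeline on a simulated study
#'
#' Simulates a study under `config` and `seed`, writes the study files,
#' runs every analysis stage of the package (conversion-rate estimation,
#' methylation calling with the heterozygosity filter, ML statistics and
#' component summaries, DMS/DMR calling between two stages with recovery
#' scoring against the planted truth, MeDIP normalization with ARD/NARD
#' and WGBS consistency, expression quantiles and methylation-expression
#' integration), writes the result tables, and returns the headline
#' numbers. Output is deterministic given `config` and `seed`.
#'
#' @param config from [simConfig()].
#' @param seed integer seed.
#' @param outdir output directory.
#' @param dmr_groups the two stages compared for DMS/DMR calling.
#' @return invisibly, a list of summary quantities (also written to
#'   `summary.json`).
#' @export
runPipeline <- function(config = simConfig(), seed = 1L, outdir,
                        dmr_groups = c("SP", "MG")) {
  study <- simulateStudy(config, seed)
  writeStudy(study, file.path(outdir, "sim"))
  resdir <- file.path(outdir, "results")
  dir.create(resdir, recursive = TRUE, showWarnings = FALSE)
  genome <- study$genome
  ms <- study$methylome
  stages <- config$stages
  conv <- estimateConversion(ms)

  # per-stage calls, het-filtered, ML statistics
  called <- lapply(stages, function(st) {
    cs <- callMethylation(ms, stage = st,
                          nonconversion = conv$nonconversion)
    filterHetSites(cs, study$variants)
  })
  names(called) <- stages
  mlwg_tab <- do.call(rbind, lapply(stages, function(st) {
    data.frame(stage = st,
      mlwg = mlwg(called[[st]], genome),
      mlwg_CpG = mlwg(called[[st]], genome, context = "CpG"),
      mlwg_CHG = mlwg(called[[st]], genome, context = "CHG"),
      mlwg_CHH = mlwg(called[[st]], genome, context = "CHH"))
  }))
  ctx_tab <- do.call(rbind, lapply(stages, function(st)
    data.frame(stage = st, t(contextFractions(called[[st]])))))
  data.table::fwrite(mlwg_tab, file.path(resdir, "mlwg.tsv"), sep = "\t")
  data.table::fwrite(ctx_tab, file.path(resdir, "context_fractions.tsv"),
                     sep = "\t")
  comp <- componentSummary(called[[stages[length(stages)]]],
                           study$elements, genome)
  data.table::fwrite(comp, file.path(resdir, "component_summary.tsv"),
                     sep = "\t")

  # differential methylation between the two focal stages
  dms <- callDms(ms, dmr_groups[1], dmr_groups[2])
  dmrs <- callDmrs(ms, dmr_groups[1], dmr_groups[2], genome)
  # coupled gene bodies are genuinely differential in the coupled stage;
  # calls on them are not false even though they are not interval DMRs
  coupled_gr <- NULL
  if (length(study$truth$coupled_genes) &&
      config$coupled_stage %in% dmr_groups) {
    mcel <- S4Vectors::mcols(study$elements)
    coupled_gr <- study$elements[mcel$elementClass == "gene" &
      mcel$elementId %in% study$truth$coupled_genes]
  }
  rec <- scoreDmrRecovery(dmrs, study$truth$dmrs, also_true = coupled_gr)
  ov <- overlapElements(dmrs, study$elements)
  dmr_df <- as.data.frame(dmrs)
  data.table::fwrite(dmr_df, file.path(resdir, "dmrs.tsv"), sep = "\t")
  data.table::fwrite(ov, file.path(resdir, "dmr_element_overlap.tsv"),
                     sep = "\t")

  out <- list(
    seed = seed,
    conversion_rate_pct = 100 * conv$conversion,
    nonconversion_rate = conv$nonconversion,
    mlwg = mlwg_tab,
    context_fractions = ctx_tab,
    nmlgc = setNames(comp$nmlgc, comp$element_class),
    n_dms_called = sum(S4Vectors::mcols(dms)$called),
    n_dmr_called = length(dmrs),
    dmr_recovered = rec$n_recovered, dmr_planted = rec$n_planted,
    dmr_fdr = rec$fdr)

  # MeDIP: normalization, NARD per class, WGBS consistency per element
  if (!is.null(study$medip)) {
    norm <- normalizeDepth(study$medip$ip, study$medip$input)
    medip_stage <- config$medip_stage
    body_cls <- c("gene", "exon", "intron", "TE", "lncRNA", "circRNA",
                  "tRNA", "TSSUP", "TESDOWN", "CGI")
    el <- study$elements[
      as.character(S4Vectors::mcols(study$elements)$elementClass) %in%
        body_cls]
    ard <- computeArd(norm, el, by = "class")
    data.table::fwrite(ard, file.path(resdir, "ard_nard.tsv"), sep = "\t")
    keep_cls <- c("gene", "TE", "lncRNA", "circRNA")
    elc <- el[as.character(S4Vectors::mcols(el)$elementClass) %in% keep_cls]
    per_el <- computeArd(norm, elc, by = "element")
    fm <- fragmentML(called[[medip_stage]], elc, genome)
    mlgf <- setNames(S4Vectors::mcols(fm)$mlgf,
                     S4Vectors::mcols(fm)$elementId)
    cons <- consistencyMedipWgbs(
      per_el$nard[match(names(mlgf), per_el$class)], mlgf)
    out$medip_nard_lncRNA <- ard$nard[ard$class == "lncRNA"]
    out$medip_wgbs_r <- cons$r
    out$medip_wgbs_p <- cons$p
  }

  # expression integration
  if (!is.null(study$expression)) {
    ex <- study$expression
    total <- colSums(ex$counts)
    rk <- sweep(ex$counts * 1e9, 2, total, "/") / ex$gene_length
    # within-stage comparison on the baseline (first) stage: expression
    # classes of a stage against that same stage's methylation
    base_stage <- stages[1]
    base_cols <- grep(paste0("^", base_stage, "_"), colnames(rk))
    mean_rpkm <- rowMeans(rk[, base_cols, drop = FALSE])
    classes <- expressionClasses(mean_rpkm, rownames(ex$counts))
    genes <- study$elements[
      S4Vectors::mcols(study$elements)$elementClass == "gene"]
    fm <- fragmentML(called[[base_stage]], genes, genome)
    gml <- setNames(S4Vectors::mcols(fm)$mlgf,
                    S4Vectors::mcols(fm)$elementId)[rownames(ex$counts)]
    corr <- mlExpressionCorrelation(gml, mean_rpkm)
    class_ml <- tapply(gml, classes, mean, na.rm = TRUE)
    cls_df <- data.frame(class = names(class_ml),
                         mean_mlgf = as.numeric(class_ml),
                         n = as.integer(table(classes)[names(class_ml)]))
    data.table::fwrite(cls_df,
                       file.path(resdir, "expression_class_mlgf.tsv"),
                       sep = "\t")
    out$expr_ml_r <- corr$r
    out$expr_ml_p <- corr$p
    out$class_mean_mlgf <- setNames(cls_df$mean_mlgf, cls_df$class)
  }

  jsonlite::write_json(out, file.path(resdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out)
}
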