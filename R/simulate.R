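#' Configuration for the synthetic three-stage methylome study
#'
#' Returns the default study configuration emulating a small kelp-like
#' methylome experiment: a 1-Mb genome in four chromosomes at GC 0.5 with
#' annotated genes (exon/intron structure), TEs, lncRNA/circRNA/tRNA gene
#' loci and CpG-island patches; three life-cycle stages (SP, FG, MG) with
#' three replicate libraries each; a CHH-dominated, very sparse
#' methylation landscape (sporophyte lowest, gametophytes 1.5-2x higher);
#' an unmethylated lambda spike-in; planted stage-specific DMRs; negative
#' methylation-expression coupling; MeDIP depth coupling; and heterozygous
#' sites at the genome-wide rate of about 0.14%, a fraction of which are
#' the bisulfite-confounding C>T / G>A class. Any field can be overridden
#' via `...`.
#'
#' @param ... named overrides of default fields.
#' @return a list of class `kelpmeth_config`.
#' @export
simConfig <- function(...) {
  cfg <- list(
    # genome
    genome_length = 1e6, n_chrom = 4L, gc_content = 0.5,
    lambda_length = 48502L,
    # annotation
    n_genes = 120L, n_te = 60L, n_lncrna = 30L, n_circrna = 20L,
    n_trna = 20L, n_cgi = 15L,
    # design
    stages = c("SP", "FG", "MG"), n_reps = 3L,
    # per-context methylation rates of the sporophyte; gametophytes scale up
    base_rates = c(CpG = 0.004, CHG = 0.003, CHH = 0.012),
    stage_scale = c(SP = 1, FG = 1.5, MG = 2),
    # element-class rate multipliers and intragenic shapes
    class_mult = c(exon = 0.6, intron = 1.3, TE = 1.5, lncRNA = 3,
                   circRNA = 2.5, tRNA = 0.4, CGI = 0.5),
    shape_amp_exon = -0.9,   # concave: centre below edges
    shape_amp_intron = 0.9,  # convex: centre above edges
    element_ml_sdlog = 0.5,  # per-element lognormal variability (mean 1)
    # methylation-expression coupling
    n_coupled = 50L, coupled_stage = "MG", coupled_ml_fold = 6,
    coupled_expr_fold = 4, silent_frac = 0.1,
    # planted DMRs
    n_dmr = 20L, dmr_len = 1000L, dmr_base_ml = 0.02, dmr_target_ml = 0.15,
    # sequencing
    coverage_mean = 30, coverage_dispersion = 10,
    conversion_failure = 5e-4,
    # MeDIP
    do_medip = TRUE, medip_stage = "MG", medip_base_depth = 5,
    medip_slope = 30, medip_smooth = 201L,
    # expression
    do_expression = TRUE, expr_intercept = 6, expr_slope = 5,
    expr_noise_sd = 0.5, expr_nb_size = 40,
    # heterozygosity
    het_rate = 0.0014, het_ct_fraction = 0.3)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(all(cfg$base_rates >= 0 & cfg$base_rates <= 1),
            cfg$dmr_target_ml <= 1, cfg$gc_content > 0, cfg$gc_content < 1)
  class(cfg) <- "kelpmeth_config"
  cfg
}

# random nucleotide string at a given GC content
.randSeq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# CpG-island-like patch: CG-rich dinucleotide sampling
.cgiSeq <- function(n) {
  di <- sample(c("CG", "GC", "CC", "GG", "CA", "TG", "AC", "GT"),
               ceiling(n / 2), replace = TRUE,
               prob = c(0.35, 0.15, 0.1, 0.1, 0.08, 0.08, 0.07, 0.07))
  substr(paste(di, collapse = ""), 1, n)
}

# place n elements of given lengths in [margin+1, L-margin] without overlap;
# returns integer starts in placement order
.packSlots <- function(L, lens, margin = 2500L, min_gap = 50L) {
  n <- length(lens)
  if (n == 0) return(integer())
  free <- L - 2 * margin - sum(lens) - (n + 1L) * min_gap
  if (free < 0) stop("infeasible packing: elements do not fit on chromosome")
  w <- runif(n + 1L)
  gaps <- min_gap + floor(free * w / sum(w))
  starts <- margin + cumsum(gaps)[seq_len(n)] +
    c(0L, cumsum(lens))[seq_len(n)] + 1L
  as.integer(starts)
}

#' Simulate the reference genome and its annotation
#'
#' Draws i.i.d. nucleotides at the configured GC content, plants CG-rich
#' CpG-island patches, appends the unmethylated lambda spike-in as an
#' extra record named `"lambda"`, and packs all requested elements
#' (genes with a consistent exon/intron partition, TEs, lncRNA/circRNA/
#' tRNA gene loci) without same-class overlap. TSSUP/TESDOWN elements are
#' derived as strand-aware 2-kb gene flanks.
#'
#' @param config from [simConfig()]. Uses the current RNG stream; seed at
#'   the caller (see [simulateStudy()]).
#' @return list with `genome` (`DNAStringSet` incl. lambda) and `elements`
#'   (`GRanges` with `elementClass`, `elementId`, `geneId`).
#' @export
simulateGenome <- function(config = simConfig()) {
  cl <- as.integer(config$genome_length / config$n_chrom)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  seqs <- vapply(chroms, function(ch) .randSeq(cl, config$gc_content),
                 character(1))
  # element specification table, randomly assigned to chromosomes
  srows <- function(class, lens)
    data.frame(class = rep(class, length(lens)), len = lens)
  spec <- rbind(
    srows("gene", sample(1500:4000, config$n_genes, replace = TRUE)),
    srows("TE", sample(500:2000, config$n_te, replace = TRUE)),
    srows("lncRNA", sample(600:2000, config$n_lncrna, replace = TRUE)),
    srows("circRNA", sample(400:1200, config$n_circrna, replace = TRUE)),
    srows("tRNA", sample(80:120, config$n_trna, replace = TRUE)),
    srows("CGI", sample(300:600, config$n_cgi, replace = TRUE)))
  spec$chrom <- sample(chroms, nrow(spec), replace = TRUE)
  spec <- spec[sample(nrow(spec)), , drop = FALSE]
  counters <- c(gene = 0L, TE = 0L, lncRNA = 0L, circRNA = 0L, tRNA = 0L,
                CGI = 0L)
  out <- list()
  for (ch in chroms) {
    sp <- spec[spec$chrom == ch, , drop = FALSE]
    starts <- .packSlots(cl, sp$len)
    for (i in seq_len(nrow(sp))) {
      counters[sp$class[i]] <- counters[sp$class[i]] + 1L
      id <- paste0(sp$class[i], counters[sp$class[i]])
      strand <- sample(c("+", "-"), 1)
      a <- starts[i]; b <- a + sp$len[i] - 1L
      if (sp$class[i] == "CGI") {
        substr(seqs[ch], a, b) <- .cgiSeq(sp$len[i])
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = a,
          end = b, strand = "*", class = "CGI", id = id, gene = NA)
      } else if (sp$class[i] == "gene") {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = a,
          end = b, strand = strand, class = "gene", id = id, gene = id)
        # exon/intron partition: k exons, k-1 introns, each >= 50 bp
        k <- sample(2:5, 1)
        nparts <- 2L * k - 1L
        w <- runif(nparts)
        part <- 50L + floor((sp$len[i] - 50L * nparts) * w / sum(w))
        part[nparts] <- sp$len[i] - sum(part[-nparts])
        bounds <- a + c(0L, cumsum(part))
        for (j in seq_len(nparts)) {
          pcls <- if (j %% 2 == 1) "exon" else "intron"
          out[[length(out) + 1L]] <- data.frame(chrom = ch,
            start = bounds[j], end = bounds[j + 1L] - 1L, strand = strand,
            class = pcls, id = paste0(id, "_", pcls, (j + 1L) %/% 2L),
            gene = id)
        }
      } else {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = a,
          end = b, strand = strand, class = sp$class[i], id = id,
          gene = NA)
      }
    }
  }
  tbl <- do.call(rbind, out)
  genome <- Biostrings::DNAStringSet(c(seqs,
    lambda = .randSeq(config$lambda_length, 0.5)))
  gr <- GenomicRanges::GRanges(tbl$chrom,
    IRanges::IRanges(tbl$start, tbl$end), strand = tbl$strand,
    elementClass = tbl$class, elementId = tbl$id, geneId = tbl$gene)
  # strand-aware 2-kb flanks of genes
  genes <- gr[S4Vectors::mcols(gr)$elementClass == "gene"]
  sl <- setNames(Biostrings::width(genome), names(genome))
  up <- GenomicRanges::trim(GenomicRanges::promoters(
    GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
      IRanges::ranges(genes), strand = GenomicRanges::strand(genes),
      seqlengths = sl[chroms]), upstream = 2000L, downstream = 0L))
  dn <- GenomicRanges::trim(GenomicRanges::flank(
    GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
      IRanges::ranges(genes), strand = GenomicRanges::strand(genes),
      seqlengths = sl[chroms]), width = 2000L, start = FALSE))
  S4Vectors::mcols(up) <- S4Vectors::DataFrame(elementClass = "TSSUP",
    elementId = paste0(S4Vectors::mcols(genes)$elementId, "_tssup"),
    geneId = S4Vectors::mcols(genes)$elementId)
  S4Vectors::mcols(dn) <- S4Vectors::DataFrame(elementClass = "TESDOWN",
    elementId = paste0(S4Vectors::mcols(genes)$elementId, "_tesdown"),
    geneId = S4Vectors::mcols(genes)$elementId)
  elements <- suppressWarnings(c(gr, up, dn))
  elements <- GenomicRanges::sort(elements, ignore.strand = TRUE)
  list(genome = genome, elements = elements)
}

# quadratic positional multiplier along an element, mean ~ 1:
# 1 + amp * ((1 - (2t-1)^2) - 2/3), t in [0,1]
.shapeMult <- function(t, amp) 1 + amp * ((1 - (2 * t - 1)^2) - 2 / 3)

#' Simulate the three-stage methylomes
#'
#' Assigns every cytosine a true methylation level: stage- and
#' context-specific base rate, times an element-class multiplier, times a
#' quadratic positional shape inside exons (concave) and introns
#' (convex), times a per-element lognormal factor (mosaic methylation);
#' the configured number of coupled genes is additionally hypermethylated
#' in the coupled stage. Planted DMR intervals override the level
#' (`dmr_base_ml` for all stages, `dmr_target_ml` for the assigned stage,
#' cycling through the stages). Per replicate, site coverage is negative
#' binomial and methylated reads are binomial at
#' `ml (1 - failure) + (1 - ml) failure`; lambda sites are fully
#' unmethylated, so their methylated reads are pure conversion failure.
#'
#' @param genome,elements from [simulateGenome()].
#' @param config from [simConfig()].
#' @return list with `methylome` (a [MethylomeSet] incl. lambda sites) and
#'   `truth` (planted parameters: per-site true ML per stage, DMR
#'   intervals, per-gene body ML, coupled genes, expected per-context
#'   MLwg).
#' @export
simulateMethylomes <- function(genome, elements, config = simConfig()) {
  chroms <- setdiff(names(genome), "lambda")
  sites <- enumerateCytosines(genome, chroms)
  ctx <- S4Vectors::mcols(sites)$context
  n <- length(sites)
  stages <- config$stages
  rates <- outer(config$stage_scale[stages], config$base_rates)
  # per-element factors (genes share one factor across their parts)
  mc <- S4Vectors::mcols(elements)
  ekey <- ifelse(is.na(mc$geneId), mc$elementId, mc$geneId)
  ukey <- unique(ekey)
  efac <- setNames(exp(rnorm(length(ukey), 0, config$element_ml_sdlog)) /
                     exp(config$element_ml_sdlog^2 / 2), ukey)
  # site-level multiplier from covering elements (exon/intron/TE/...)
  mult <- rep(1, n)
  modcls <- names(config$class_mult)
  for (cls in modcls) {
    el <- elements[mc$elementClass == cls]
    if (!length(el)) next
    hits <- GenomicRanges::findOverlaps(sites, el, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    m <- config$class_mult[[cls]] *
      efac[ifelse(is.na(S4Vectors::mcols(el)$geneId[si]),
                  S4Vectors::mcols(el)$elementId[si],
                  S4Vectors::mcols(el)$geneId[si])]
    amp <- switch(cls, exon = config$shape_amp_exon,
                  intron = config$shape_amp_intron, 0)
    if (amp != 0) {
      len <- GenomicRanges::width(el)[si]
      off <- GenomicRanges::start(sites)[qi] - GenomicRanges::start(el)[si]
      t <- ifelse(as.character(GenomicRanges::strand(el))[si] == "-",
                  (len - 1 - off) / pmax(len - 1, 1),
                  off / pmax(len - 1, 1))
      m <- m * pmax(.shapeMult(t, amp), 0.05)
    }
    mult[qi] <- m
  }
  site_ml <- vapply(stages, function(st)
    pmin(rates[st, ][match(ctx, colnames(rates))] * mult, 0.95, na.rm = FALSE),
    numeric(n))
  site_ml[is.na(site_ml)] <- 0   # boundary-context sites stay unmethylated
  # coupled genes: hypermethylated gene bodies in the coupled stage
  genes <- elements[mc$elementClass == "gene"]
  gids <- S4Vectors::mcols(genes)$elementId
  coupled <- character(0)
  if (config$n_coupled > 0 && length(genes)) {
    coupled <- sample(gids, min(config$n_coupled, length(gids)))
    gsel <- genes[gids %in% coupled]
    hit <- IRanges::overlapsAny(sites, gsel, ignore.strand = TRUE)
    site_ml[hit, config$coupled_stage] <-
      pmin(site_ml[hit, config$coupled_stage] * config$coupled_ml_fold, 0.95)
  }
  # planted DMRs in element-free gaps, stages assigned in rotation
  dmrs <- GenomicRanges::GRanges()
  if (config$n_dmr > 0) {
    sl <- setNames(Biostrings::width(genome), names(genome))[chroms]
    occupied <- GenomicRanges::reduce(
      GenomicRanges::GRanges(GenomicRanges::seqnames(elements),
        IRanges::ranges(elements) + 200L), ignore.strand = TRUE)
    all_gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(1L, sl))
    gaps <- GenomicRanges::setdiff(all_gr, occupied, ignore.strand = TRUE)
    gaps <- gaps[GenomicRanges::width(gaps) >= config$dmr_len + 200L]
    if (length(gaps) < config$n_dmr)
      stop("no room for planted DMRs: ", length(gaps),
           " usable gaps for ", config$n_dmr, " DMRs")
    # one DMR per gap keeps planted regions non-overlapping
    gi <- sample(seq_along(gaps), config$n_dmr)
    a <- GenomicRanges::start(gaps)[gi] +
      floor(runif(length(gi)) *
              (GenomicRanges::width(gaps)[gi] - config$dmr_len))
    dmrs <- GenomicRanges::GRanges(GenomicRanges::seqnames(gaps)[gi],
      IRanges::IRanges(a, width = config$dmr_len),
      target_stage = stages[(seq_along(gi) - 1L) %% length(stages) + 1L],
      base_ml = config$dmr_base_ml, target_ml = config$dmr_target_ml)
    hits <- GenomicRanges::findOverlaps(sites, dmrs, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    for (st in stages) {
      site_ml[qi, st] <- config$dmr_base_ml
      tsel <- S4Vectors::mcols(dmrs)$target_stage[si] == st
      site_ml[qi[tsel], st] <- config$dmr_target_ml
    }
  }
  # draw counts: stage-major replicate order
  f <- config$conversion_failure
  lam_sites <- enumerateCytosines(genome, "lambda")
  all_sites <- suppressWarnings(c(sites, lam_sites))
  nl <- length(lam_sites)
  sample_ids <- as.vector(t(outer(stages, seq_len(config$n_reps),
                                  function(s, r) paste0(s, "_", r))))
  meth <- matrix(0L, n + nl, length(sample_ids))
  unmeth <- matrix(0L, n + nl, length(sample_ids))
  col <- 0L
  for (st in stages) for (r in seq_len(config$n_reps)) {
    col <- col + 1L
    ml <- c(site_ml[, st], rep(0, nl))
    cov <- rnbinom(n + nl, size = config$coverage_dispersion,
                   mu = config$coverage_mean)
    p <- ml * (1 - f) + (1 - ml) * f
    meth[, col] <- rbinom(n + nl, cov, p)
    unmeth[, col] <- cov - meth[, col]
  }
  cd <- S4Vectors::DataFrame(sample_id = sample_ids,
    stage = rep(stages, each = config$n_reps))
  ms <- MethylomeSet(all_sites, meth, unmeth, cd)
  # truth record
  cg_total <- .cgCount(genome, exclude = "lambda")
  expected_mlwg <- vapply(c("CpG", "CHG", "CHH"), function(cc)
    colSums(site_ml[ctx == cc, , drop = FALSE]) / cg_total,
    numeric(length(stages)))
  if (is.null(dim(expected_mlwg)))
    expected_mlwg <- matrix(expected_mlwg, nrow = 1,
                            dimnames = list(stages,
                                            c("CpG", "CHG", "CHH")))
  gene_ml <- vapply(stages, function(st) {
    hits <- GenomicRanges::findOverlaps(sites, genes, ignore.strand = TRUE)
    v <- tapply(site_ml[S4Vectors::queryHits(hits), st],
                S4Vectors::subjectHits(hits), mean)
    out <- setNames(rep(NA_real_, length(genes)), gids)
    out[as.integer(names(v))] <- v
    out
  }, numeric(length(genes)))
  rownames(gene_ml) <- gids
  truth <- list(config = config, site_ml = site_ml, site_context = ctx,
                dmrs = dmrs, coupled_genes = coupled,
                element_factor = efac, gene_ml = gene_ml,
                expected_mlwg = expected_mlwg,
                conversion_failure = f, cg_total = cg_total)
  list(methylome = ms, truth = truth)
}

#' Simulate a MeDIP-seq depth pair (IP and input)
#'
#' Input depth is uniform Poisson; immunoprecipitation depth is Poisson
#' with a per-base rate enriched proportionally to the locally smoothed
#' true methylation density:
#' `rate = base x (1 + slope x smoothed_ml)`. Library sizes are recorded.
#'
#' @param genome `DNAStringSet`.
#' @param truth from [simulateMethylomes()] (supplies the true ML field of
#'   the assayed stage).
#' @param config from [simConfig()] (`medip_stage`, `medip_base_depth`,
#'   `medip_slope`, `medip_smooth`).
#' @return list with `ip` and `input` [DepthTrack]s.
#' @export
simulateMedip <- function(genome, truth, config = simConfig()) {
  chroms <- setdiff(names(genome), "lambda")
  sites <- enumerateCytosines(genome, chroms)
  mlst <- truth$site_ml[, config$medip_stage]
  sn <- as.character(GenomicRanges::seqnames(sites))
  ip <- list(); inp <- list()
  for (ch in chroms) {
    L <- length(genome[[ch]])
    v <- numeric(L)
    i <- which(sn == ch)
    agg <- rowsum(mlst[i], GenomicRanges::start(sites)[i])
    v[as.integer(rownames(agg))] <- agg[, 1]
    sm <- as.numeric(S4Vectors::runmean(S4Vectors::Rle(v),
                                        k = config$medip_smooth,
                                        endrule = "constant"))
    ip[[ch]] <- S4Vectors::Rle(rpois(L, config$medip_base_depth *
                                        (1 + config$medip_slope * sm)))
    inp[[ch]] <- S4Vectors::Rle(rpois(L, config$medip_base_depth))
  }
  ipt <- methods::as(ip, "RleList"); int <- methods::as(inp, "RleList")
  lib <- function(rl) sum(vapply(rl, function(r) sum(as.numeric(r)),
                                 numeric(1))) / 150
  list(ip = DepthTrack(ipt, lib(ipt)), input = DepthTrack(int, lib(int)))
}

#' Simulate the expression count table
#'
#' Per gene, the log mean expression decreases linearly with the gene's
#' within-stage methylation percentile plus lognormal gene noise (shared
#' across stages, so stage differences mirror methylation differences);
#' the configured fraction of most-methylated genes is silenced
#' (near-zero counts). Counts are negative binomial per replicate with a
#' gene-length factor.
#'
#' @param elements annotation from [simulateGenome()].
#' @param truth from [simulateMethylomes()] (per-gene true ML per stage).
#' @param config from [simConfig()].
#' @return list with `counts` (genes x samples), `gene_length`, `samples`,
#'   `silent_genes`.
#' @export
simulateExpression <- function(elements, truth, config = simConfig()) {
  mc <- S4Vectors::mcols(elements)
  genes <- elements[mc$elementClass == "gene"]
  gids <- S4Vectors::mcols(genes)$elementId
  len <- GenomicRanges::width(genes)
  stages <- config$stages
  ng <- length(genes)
  gnoise <- rnorm(ng, 0, config$expr_noise_sd)
  avg_ml <- rowMeans(truth$gene_ml)
  # silence the most-methylated genes, but never the coupled set (their
  # stage contrast is the planted signal)
  cand <- gids[!(gids %in% truth$coupled_genes)]
  cand <- cand[order(-avg_ml[match(cand, gids)])]
  silent <- cand[seq_len(min(length(cand), floor(config$silent_frac * ng)))]
  samples <- as.vector(t(outer(stages, seq_len(config$n_reps),
                               function(s, r) paste0(s, "_", r))))
  counts <- matrix(0L, ng, length(samples),
                   dimnames = list(gids, samples))
  for (st in stages) {
    pct <- (rank(truth$gene_ml[, st], ties.method = "first") - 0.5) / ng
    logmu <- config$expr_intercept - config$expr_slope * pct + gnoise
    mu <- exp(logmu) * len / 1000
    # planted repression of coupled genes in their hypermethylated stage
    if (st == config$coupled_stage)
      mu[gids %in% truth$coupled_genes] <-
        mu[gids %in% truth$coupled_genes] / config$coupled_expr_fold
    mu[gids %in% silent] <- 0.05
    for (r in seq_len(config$n_reps))
      counts[, paste0(st, "_", r)] <-
        rnbinom(ng, size = config$expr_nb_size, mu = mu)
  }
  list(counts = counts, gene_length = setNames(len, gids),
       samples = samples, silent_genes = silent)
}

#' Inject heterozygous sites
#'
#' Draws variant positions at the configured genome-wide heterozygosity
#' rate; the configured fraction is forced into the bisulfite-confounding
#' class (C>T under a forward cytosine, G>A under a reverse one), the rest
#' are random substitutions.
#'
#' @param genome `DNAStringSet`.
#' @param config from [simConfig()] (`het_rate`, `het_ct_fraction`).
#' @return `GRanges` with `ref`, `alt` and a `confounding` flag.
#' @export
injectHeterozygosity <- function(genome, config = simConfig()) {
  stopifnot(config$het_rate >= 0, config$het_rate <= 0.01)
  chroms <- setdiff(names(genome), "lambda")
  out <- list()
  for (ch in chroms) {
    s <- .charvec(genome, ch)
    pos <- which(runif(length(s)) < config$het_rate & s != "N")
    if (!length(pos)) next
    ref <- s[pos]
    alt <- character(length(pos))
    conf <- runif(length(pos)) < config$het_ct_fraction &
      ref %in% c("C", "G")
    alt[conf & ref == "C"] <- "T"
    alt[conf & ref == "G"] <- "A"
    todo <- which(!conf)
    alt[todo] <- vapply(ref[todo], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    out[[ch]] <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos, width = 1L),
      ref = ref, alt = alt,
      confounding = (ref == "C" & alt == "T") | (ref == "G" & alt == "A"))
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, unname(out)))
}

#' Simulate a complete synthetic study
#'
#' Runs all generators under one seeded RNG stream: genome and annotation,
#' three-stage methylomes with lambda spike-in and planted truth, MeDIP
#' depth pair, expression counts, heterozygous sites. Identical
#' `config` + `seed` give identical output.
#'
#' @param config from [simConfig()].
#' @param seed integer RNG seed.
#' @return list with `genome`, `elements`, `methylome`, `truth`, `medip`,
#'   `expression`, `variants`, `config`, `seed`.
#' @export
simulateStudy <- function(config = simConfig(), seed = 1L) {
  set.seed(seed)
  g <- simulateGenome(config)
  sim <- simulateMethylomes(g$genome, g$elements, config)
  medip <- if (isTRUE(config$do_medip))
    simulateMedip(g$genome, sim$truth, config) else NULL
  expr <- if (isTRUE(config$do_expression))
    simulateExpression(g$elements, sim$truth, config) else NULL
  variants <- injectHeterozygosity(g$genome, config)
  list(genome = g$genome, elements = g$elements,
       methylome = sim$methylome, truth = sim$truth, medip = medip,
       expression = expr, variants = variants, config = config,
       seed = seed)
}

#' Write a simulated study to disk
#'
#' Emits the study in the pipeline's exchange formats: genome FASTA,
#' one BED per element class, one per-cytosine report per library, MeDIP
#' bedGraph pair, expression count TSV, VCF of heterozygous sites, and a
#' JSON truth summary (planted rates, DMR table, coupled/silent genes,
#' expected per-context MLwg). All outputs are plain text and
#' deterministic given the study object.
#'
#' @param study from [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  fp <- function(x) file.path(dir, x)
  Biostrings::writeXStringSet(study$genome, fp("genome.fa"), width = 80L)
  files <- fp("genome.fa")
  mc <- S4Vectors::mcols(study$elements)
  for (cls in sort(unique(as.character(mc$elementClass)))) {
    f <- fp(paste0("elements_", cls, ".bed"))
    writeElements(study$elements[mc$elementClass == cls], f)
    files <- c(files, f)
  }
  ms <- study$methylome
  rr <- SummarizedExperiment::rowRanges(ms)
  for (j in seq_len(ncol(ms))) {
    sid <- SummarizedExperiment::colData(ms)$sample_id[j]
    gr <- rr
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      meth = methReads(ms)[, j], unmeth = unmethReads(ms)[, j],
      context = siteContext(ms))
    f <- fp(paste0(sid, ".cx.tsv"))
    writeCytosineReport(gr, f)
    files <- c(files, f)
  }
  if (!is.null(study$medip)) {
    writeBedGraph(study$medip$ip, fp("medip_ip.bedGraph"))
    writeBedGraph(study$medip$input, fp("medip_input.bedGraph"))
    files <- c(files, fp("medip_ip.bedGraph"), fp("medip_input.bedGraph"))
  }
  if (!is.null(study$expression)) {
    writeExpressionCounts(study$expression$counts,
                          study$expression$gene_length,
                          fp("expression_counts.tsv"))
    files <- c(files, fp("expression_counts.tsv"))
  }
  writeVariants(study$variants, fp("variants.vcf"))
  files <- c(files, fp("variants.vcf"))
  tr <- study$truth
  truth_json <- list(
    seed = study$seed,
    base_rates = as.list(tr$config$base_rates),
    stage_scale = as.list(tr$config$stage_scale),
    conversion_failure = tr$conversion_failure,
    expected_mlwg = cbind(data.frame(stage = rownames(tr$expected_mlwg)),
                          as.data.frame(tr$expected_mlwg)),
    dmrs = if (length(tr$dmrs)) data.frame(
      chrom = as.character(GenomicRanges::seqnames(tr$dmrs)),
      start = GenomicRanges::start(tr$dmrs),
      end = GenomicRanges::end(tr$dmrs),
      target_stage = S4Vectors::mcols(tr$dmrs)$target_stage,
      base_ml = S4Vectors::mcols(tr$dmrs)$base_ml,
      target_ml = S4Vectors::mcols(tr$dmrs)$target_ml) else list(),
    coupled_genes = tr$coupled_genes,
    silent_genes = if (!is.null(study$expression))
      study$expression$silent_genes else character(0),
    n_variants = length(study$variants),
    n_confounding_variants =
      sum(S4Vectors::mcols(study$variants)$confounding %in% TRUE),
    medip_library_sizes = if (!is.null(study$medip))
      c(ip = librarySize(study$medip$ip),
        input = librarySize(study$medip$input)) else NULL)
  jsonlite::write_json(truth_json, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, fp("truth.json"))
  invisible(files)
}
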