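---
title: "Quantifying a sparse brown-algal methylome: models and methods"
author: "kelpmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a sparse brown-algal methylome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The kelp *Saccharina japonica* methylates only about 1–2% of its genomic
cytosines, mostly in CHH context, and the level differs between the
diploid sporophyte (SP) and the haploid female and male gametophytes (FG,
MG). At such sparsity, an analysis lives or dies by its error model: a
handful of unconverted cytosines or heterozygous C>T sites can masquerade
as biology. `kelpmeth` implements the complete quantitative toolkit for
this regime — methylation-level statistics from per-cytosine bisulfite
counts, differential methylation between life-cycle stages, MeDIP-seq
depth normalization, metaplot profiling, sequence-composition windows,
and methylation–expression integration — together with a fully
deterministic synthetic-study generator so that every estimator can be
validated against planted truth without any external data.

# Methylation-level statistics

All statistics derive from the per-site level
$\mathrm{ML}_{mc} = \frac{\mathrm{reads}(mC)}{\mathrm{reads}(mC) + \mathrm{reads}(C)}$,
the fraction of reads carrying an unconverted cytosine at one reference
cytosine. Sites live on the strand carrying the C; symmetric CpG sites
are never destranded, because every formula operates per cytosine.

For a genomic fragment, the fragment level MLgf is the *sum* of site
levels of the methylated cytosines it contains divided by the fragment's
C+G nucleotide count — not a mean of site levels. The same construction
pooled over all elements of an annotation class gives the class level
MLgc, over the whole genome (spike-in excluded) the genome level MLwg,
and MLgc normalized by the intrasample MLwg gives NMLgc, which is exactly
1 for the genome itself. Pooling numerators and denominators across a
class (rather than averaging per-element MLgf) matters whenever element
lengths vary; `componentSummary()` implements the pooled form.

Fragments whose C+G count is zero (N-rich intervals) are undefined and
flagged, never silently zero. Ambiguous nucleotides are masked to N on
input and excluded from every C/G denominator, so denominators are
deterministic functions of the reference.

## Calling methylated cytosines

A site is called methylated when three conditions hold jointly:

1. total coverage of at least `min_reads = 4` reads;
2. at least one methylated read;
3. a one-sided binomial test rejects conversion failure as the sole
   explanation: $P(X \ge m \mid n = \mathrm{cov}, p = \hat f) < \alpha$
   with $\alpha = 0.05$.

The failure rate $\hat f$ is estimated from the unmethylated lambda
spike-in as the fraction of lambda cytosine positions sequenced as
cytosine (`estimateConversion()`); the conversion rate is its
complement. The four-read rule is read as *total* coverage; the
alternative reading (four methylated reads) is available via
`rule = "meth"`. Note that the guard is a level-$\alpha$ test: at
coverages up to roughly $\alpha/f$ reads, a single unconverted read is
already more evidence than failure alone explains, so under a fully
unmethylated null the call rate approaches $\alpha$, not zero; a
stricter $\alpha$ tightens this proportionally.

Replicates of a stage are pooled by summing counts per site for all ML
statistics; per-replicate MLgf vectors are retained (via
`replicateMlgf()`) for the replicate-level t-tests of the expression
integration.

## Heterozygosity filter

A heterozygous C>T variant under a forward-strand cytosine (or G>A under
a reverse-strand one) is indistinguishable from an (un)methylated
cytosine in bisulfite reads. `filterHetSites()` removes exactly the
intersection of called sites with that variant class, records the removed
fraction, and is idempotent.

# Differential methylation

Two stages are compared on replicate-pooled counts. Per site,
`exactTest2x2()` computes the two-sided Fisher exact p-value by summing
all hypergeometric table probabilities not exceeding the observed
table's. The implementation enumerates the support vectorized over sites
(support size is linear in the methylated-read margin, which is small in
this genome), and is verified in the test suite against both
`stats::fisher.test()` and an independent brute-force enumeration oracle
on every table with margins up to 12.

DMSs require raw $p < 0.05$ and a methylation-level fold-change above 2,
with Benjamini–Hochberg q-values reported alongside (the raw-p reading of
the threshold is used; q is available to the caller). Fold-changes use a
pseudocount $\varepsilon = 0.001$ on both levels so that comparisons
against zero stay finite and direction-stable.

DMRs use a 1000-bp window advanced in 100-bp steps. Each window is scored
with
$\mathrm{areaStat} = \sum_{\text{sites}} \operatorname{sign}(\Delta\mathrm{ML}) \cdot (-\log_{10} p_{\text{site}})$,
a score in the family used by sliding-window DMR callers such as swDMR
and DSS; the default threshold $|\mathrm{areaStat}| \ge 40$ is kept and
exposed as an argument. A window is emitted only when,
conjointly, the areaStat threshold, a window-level fold-change above 6
(on window methylation computed from the contributing sites over the
window's C+G count), and a pooled-count exact test $p < 0.05$ all hold —
the three criteria are enforced together rather than assuming one entails
the others. Scanning is greedy left-to-right: after a window is emitted
the scan resumes downstream of its end, so emitted DMRs never overlap.
Windows with fewer than three covered sites are skipped as a stability
guard. Promoter-level calls (DMPs) apply the same criteria to the fixed
2000-bp region upstream of each transcript start, strand-aware and
clipped at chromosome edges.

# Sequence composition and CpG islands

Composition tracks use non-overlapping 10-kb windows: CpG
observed/expected as $(N_{CpG} \cdot L)/(N_C \cdot N_G)$ (undefined, not
zero, when a window lacks C or G), the (C+G)/length ratio, and the
fraction of window nucleotides covered by CpG, CHG and CHH pattern
footprints on either strand. Footprints count *distinct* covered
nucleotides: counting 3 nt per overlapping instance could exceed the
window length on repetitive sequence, violating the requirement that all
ratios lie in [0, 1]. Chromosome-final partial windows are emitted,
flagged, and excluded from correlations by default.

CpG islands are detected with Gardiner-Garden–Frommer-style defaults
(window 200 bp, GC $\ge$ 0.5, O/E $\ge$ 0.6, step 1); CGI-prediction
tools differ in their exact criteria, so all three thresholds are
arguments, and a precomputed CGI BED can be supplied instead. Qualifying windows are merged, and a merged
island must satisfy the criteria as a whole — this rejects short dense
patches whose qualifying windows lean on flanking sequence.

# MeDIP depth and metaplots

MeDIP and input depths are scaled to reads-per-million of their library
sizes, the input background is subtracted per position, and enrichment is
clipped at zero (depths are non-negative signals and only enrichment is
interpreted). Per element class,
$\mathrm{ARD} = \mathrm{ARC} \times 150 / \text{class length}$ and
$\mathrm{NARD} = \mathrm{ARD}_{\text{class}}/\mathrm{ARD}_{\text{genome}}$.
The read-length constant defaults to 150; it is configurable, and it
cancels in NARD, which is the quantity interpreted downstream. ARC is recovered from a depth track as the depth integral divided
by the read length — exact for non-clipped reads and the natural
definition when the artifact consumes depth tracks rather than
alignments.

Metaplots map each element onto a fixed number of bins by
$\lfloor n_{\text{bins}} \cdot \text{offset}/\text{length} \rfloor$
(ties impossible by construction), flip reverse-strand elements so every
profile reads 5'→3', and average bins across elements with equal element
weight (the unweighted reading of the figure legends; site-count
weighting would let long elements dominate). Three schemes: 20 equal bins
per element; 2-kb flanks in 100-bp bins around 20 element bins; and 20
flank bins around 40 gene windows. Elements shorter than the bin count
are skipped and tallied. The MLgf profile uses a numerator track holding
site levels of called mCs and a C+G indicator denominator, so each bin's
value is the bin's MLgf.

# Expression integration

RPKM is $c \times 10^9 / (L \cdot N)$. The four expression classes
(high/medium/low/none) have no canonical cutoffs; they are defined
as: `none` when mean RPKM $\le 0.1$, the remaining genes
split into tertiles with stable tie-breaking and class sizes differing by
at most one. Genome-wide coupling is summarized by Pearson correlation of
MLgf against $\log(\mathrm{RPKM}+1)$; expression is tested on the log
scale to stabilize variance (raw scale available). Pairwise-stage
selection runs two Welch t-tests per gene on the three replicate values
(MLgf and log expression) and selects genes with both $p < 0.05$ and
opposed directions; hypomethylated-and-higher-expressed and the reverse
are reported separately, and within-stage class comparisons are made
against the same stage's methylation. For the lowercase-letter annotations of per-stage distributions,
Duncan's multiple range test — the traditional agronomy choice — is
replaced by pairwise Welch t-tests with Holm correction feeding a
standard compact-letter display: Duncan's procedure is under-specified
for n = 3 with unequal variances, and the letters only encode pairwise
significance.

# The synthetic study

The generator emulates a kelp life-cycle methylome experiment at desk
scale: a 1-Mb
genome in four chromosomes at GC 0.5 (the real genome is ~537 Mb), three
stages × three replicates, a 48,502-bp lambda spike-in, conversion
failure $5 \times 10^{-4}$ (conversion > 99.95%), negative-binomial
coverage with mean 30 (overdispersed, size 10, to exercise test
robustness), heterozygosity 0.14% with a configurable fraction of
bisulfite-confounding C>T/G>A variants, and sporophyte per-context rates
CpG 0.004 / CHG 0.003 / CHH 0.012 scaled ×1.5 (FG) and ×2 (MG) so the
gametophytes exceed the sporophyte. True site levels are modulated by
element-class multipliers (lncRNA/circRNA high, exons low, tRNA low),
quadratic positional shapes (introns convex, exons concave — treated as
qualitative, bin-order targets, not numeric ones), and a
mean-normalized per-element lognormal factor that produces the mosaic,
element-scale variation real methylomes show. Planted DMRs override the
level in intergenic 1-kb intervals (0.02 everywhere, 0.15 in the target
stage, stages assigned in rotation). Methylated read counts are binomial
at $ml(1-f) + (1-ml)f$; lambda sites use $ml = 0$, so their methylated
reads are a pure failure signal.

Expression depth is set so a typical gene receives on the order of a
hundred reads per replicate (`expr_intercept = 6`, negative-binomial size
40): shallower counts would make the three-replicate Welch tests powerless
for reasons unrelated to the method under test, and real RNA-seq gene
counts are of this order. Fifty coupled genes are hypermethylated
(×6) in the coupled stage and transcriptionally repressed there (×4, the
planted effect size); the most-methylated non-coupled genes are silenced
outright (`silent_frac = 0.1`) so the `none` expression class exists.
Coupled genes are excluded from silencing because their stage contrast
*is* the planted signal. MeDIP enrichment follows
$\mathrm{Poisson}\!\left(b\,(1 + s \cdot \widetilde{ml})\right)$ per
position, with $\widetilde{ml}$ the 201-bp running mean of true site
levels, against a uniform Poisson input.

What the generator does not emulate: read-level artifacts (mapping bias,
PCR duplicates, M-bias), linkage between neighbouring sites beyond the
planted element structure, sequence-driven coverage bias, and partial
methylation polymorphism between individuals. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
count-level model, not robustness to alignment artifacts.

# Numerical and testing choices

* Coordinates are GRanges-style 1-based closed everywhere inside the
  package; 0-based half-open and 1-based inclusive dialects exist only at
  the BED/GFF3/bedGraph/report boundaries, each converted at a single
  point and covered by round-trip tests.
* p-values are floored at the smallest positive double before
  $-\log_{10}$; degenerate 2×2 margins give $p = 1$, flagged.
* Zero-variance inputs to any correlation or t-test are flagged and
  excluded rather than propagating NaN.
* Type-I calibration of the DMS test is asserted on a null simulation at
  methylation level 0.5 and 100× coverage per replicate. This choice is
  deliberate: at kelp-like levels (~0.01–0.03) the discrete exact test is
  strongly conservative (measured size ≈ 0.013 at nominal 0.05), so a
  calibration band around the nominal level is only a meaningful check
  where the test's discreteness is mild (measured size ≈ 0.045 at the
  chosen design, established by a size analysis before the test was
  frozen). The sparse regime is instead covered by the null-DMR check on
  a 1-Mb kelp-like simulation, where conservatism is the safe direction.
* Problem sizes in the test suite — 1-Mb genomes for DMR recovery and
  determinism, 2.5 Mb / 500 genes for expression integration, 150–300 kb
  for the 20-seed shape and MeDIP-null sweeps — were chosen once as the
  smallest sizes at which the planted effects are comfortably above
  sampling noise for the stated acceptance margins.
* Empirical DMR FDR counts a call as false only when it overlaps neither
  a planted DMR interval nor (in the default study) a coupled-gene body,
  which is genuinely differential in the coupled stage.

# A worked session

```{r example}
library(kelpmeth)

study <- simulateStudy(simConfig(), seed = 7)
conv <- estimateConversion(study$methylome)
called <- callMethylation(study$methylome, stage = "MG",
                          nonconversion = conv$nonconversion)
called <- filterHetSites(called, study$variants)

mlwg(called, study$genome)                       # genome level
contextFractions(called)                         # CHH-dominated mix
componentSummary(called, study$elements, study$genome)

dmrs <- callDmrs(study$methylome, "SP", "MG", study$genome)
scoreDmrRecovery(dmrs, study$truth$dmrs)
```

# Limitations

The areaStat used here is one concretization; sliding-window callers
(swDMR, DSS) define related but not identical statistics, so the
threshold of 40 is meaningful relative to this definition. The exact test on pooled counts ignores
between-replicate overdispersion — a smoothed dispersion model in the
style of DSS is out of scope — so pooled p-values on real replicates are
anti-conservative when replicates disagree; the conjoint fold and
areaStat thresholds are the practical guard. CGI criteria, expression
class cutoffs, and the four-read rule reading are documented choices, all
exposed as arguments.
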