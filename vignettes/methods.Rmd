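---
title: "Methods: chromatin accessibility at H3K9me2 nucleation sites and CpG islands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin accessibility at H3K9me2 nucleation sites and CpG islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

faireCGI implements an integration analysis for paired-condition chromatin
accessibility data in hematopoietic stem and progenitor cells (HSPCs):
FAIRE-seq fragments from cells treated with a G9a/GLP methyltransferase
inhibitor (UNC0638, the "loss of H3K9me2" condition) and from DMSO-treated
controls, combined with H3K9me2 ChIP-seq peak calls ("nucleation sites"),
a CpG-island (CGI) annotation, and array-style DNA methylation beta
values. The scientific questions it addresses are:

1. Does chromatin accessibility at H3K9me2 nucleation sites change when
   the mark is lost, beyond what random genomic regions show?
2. Do nucleation sites have CGI-like base composition (elevated GC and
   CpG observed/expected ratio) even when they are not annotated CGIs?
3. How does the accessibility response stratify by promoter association,
   evolutionary CGI class, and DNA methylation state?

All coordinates are 0-based half-open (BED convention) and strand is
ignored throughout — FAIRE and H3K9me2 signals are unstranded. Overlap
always means at least one shared base pair; no minimum-fraction rule is
applied anywhere.

# Coverage and fold change

The counting unit is the sequenced **fragment** (the span between a read
pair's outermost mapped bases), not the read. A fragment contributes to
every window or region it overlaps by at least 1 bp. Windows truncated at
chromosome ends are dropped rather than shortened, so all windows of a
track have identical length and their counts are comparable. Signals are
normalized to fragments per million (library-size scaling); replicate
fragment files for one condition are pooled before analysis, and the
pooled library is what gets normalized.

The per-region fold change between treatment ($a$) and control ($b$) is

$$ FC = \frac{(c_a + \varepsilon)\,/\,N_a}{(c_b + \varepsilon)\,/\,N_b} $$

with raw counts $c$, library sizes $N$ and a pseudocount $\varepsilon$
(default 1 raw count). Applying $\varepsilon$ to raw counts *before*
normalization keeps its meaning independent of sequencing depth. The
pseudocount shrinks ratios toward 1; at the default synthetic depth
(roughly 13 control fragments per island) this biases a true 5-fold
effect down by about 5%, which is why recovery tests use a ±15% band
rather than asserting exact equality. Distributions and reports use
$\log_2 FC$ for symmetric treatment of gains and losses; ratios are kept
internally.

Because fold changes are per-million shares, a genome-wide *uniform*
accessibility change is unobservable: doubling everything doubles both
libraries and leaves every share unchanged (the usual compositional-data
caveat). `fold_changes()` and `resampling_null()` therefore expose
`normalize = FALSE` for raw-count ratios, the relevant scale when
libraries are externally calibrated.

# The resampling null and the rank-sum test

The background distribution of accessibility change is estimated two
ways, following the study design:

* **Random-region resampling**: draw $n$ regions of fixed length
  (defaults: 1,000 regions of 1 kb, 10,000 draws) uniformly over all
  valid placements — chromosomes weighted by the number of placements,
  `chrom_length - length + 1`, draws independent — and compute the fold
  change at each. Pooled values and per-draw medians are both retained,
  so the site-vs-random comparison can be run at the region level or the
  draw level.
* **Sliding-window background**: 1 kb windows at 50 bp increments across
  the genome; windows empty in both conditions are excluded (and
  counted).

Site fold changes are compared with the resampled background by a
two-sided Wilcoxon rank-sum test. The test is implemented in the package
with two paths:

* **Exact**: for $n_1 + n_2 \le 20$ without ties, full enumeration of all
  $\binom{n}{n_1}$ rank assignments.
* **Approximate**: a normal approximation with continuity correction and
  third/fourth-cumulant Edgeworth terms. The cumulants are computed
  exactly from the pooled midrank population under sampling without
  replacement, which makes the tie correction automatic and brings the
  worst-case two-sided error at $n_1 = n_2 = 8$ from about 0.011 (plain
  normal) to 0.0006.

p-values below representable double precision are labelled `<1e-300`
rather than printed as 0.

A calibration caveat worth stating: when site regions have systematically
*lower counts* than background regions (as depressed nucleation sites do
in the control condition), their fold-change distribution is more
dispersed even when its center is identical. The rank-sum test is
anticonservative under such variance inequality — in simulation, about
10% rejections at nominal 5% when sites are depressed 5-fold in both
conditions with no differential effect. The package's calibration test
therefore uses the fully exchangeable flat null (no depression, no
recovery), where the observed rejection rate is ~4.5% over 200
replicates. Interpreting a site-vs-random p-value on real data, one
should remember the test detects any distributional difference, not only
a location shift.

# Sequence composition and CGI-like detection

For a region of length $L$ with $L_{eff}$ non-N bases, $n_C$ cytosines,
$n_G$ guanines and $n_{CpG}$ CG dinucleotides:

$$ \mathrm{GC} = \frac{n_C + n_G}{L_{eff}}, \qquad
   \mathrm{CpG\ score} = \frac{n_{CpG} \cdot L_{eff}}{n_C \cdot n_G} $$

the classical observed/expected CpG ratio. N bases are excluded from both
numerator and denominator so assembly gaps cannot deflate GC content;
regions more than 50% N are rejected outright. Dinucleotides are counted
wherever both bases are non-N and inside the half-open region; pairs
spanning the region boundary are not counted, which is why the score of a
sequence and its reverse complement agree exactly (CG is its own reverse
complement). Soft-masked lowercase bases count as their base by default;
`mask_lowercase = TRUE` converts them to N. The score is defined as 0
when a region has no C or no G.

A region is **CGI-like** when GC ≥ 0.50, CpG score ≥ 0.60 and length ≥
200 bp — the classical Gardiner-Garden & Frommer thresholds, all
config-exposed. `scan_cgi_like()` tiles each chromosome (default 200 bp
windows, 50 bp step), classifies every window, and merges overlapping or
adjacent positive windows into maximal intervals. This scanner exists so
the synthetic pipeline can derive a CGI annotation from sequence alone;
it makes no attempt to reproduce any particular database's island list.

# Stratification

* **Promoter vs orphan**: a CGI is promoter-associated iff it overlaps
  any TSS point expanded by ±1,000 bp (config-exposed). Orphan CGIs are
  the inter-/intragenic remainder.
* **Methylation state**: the region score is the unweighted mean beta of
  probes inside the CGI (≥3 probes required, else `no_data`);
  methylated if mean beta > 0.75, unmethylated if < 0.25, otherwise
  indeterminate. Thresholds are strict inequalities, so boundary values
  fall into the indeterminate class.
* **Evolutionary class**: CGIs are labelled by pre-computed, mutually
  disjoint interval sets (low C→T deamination / rapid G-C gain / under
  selection). Re-deriving these classes from primate alignments is out of
  scope; overlapping class inputs are rejected as malformed. The
  stratified report drops the under-selection class by default, keeping
  the two interpretable classes in the comparison.

The stratified report computes per-CGI fold changes once and then, per
margin (methylation state, promoter status, evolutionary class), emits
n/median/quartiles and pairwise rank-sum p-values; strata with fewer than
2 regions are excluded from tests with a warning.

# The synthetic data generator

The generator produces a fully self-contained dataset — genome FASTA,
CGI/TSS/peak BEDs, probe table, fragment BEDs per condition, ground-truth
table — with the statistical structure the analysis assumes, so every
stage is testable without downloads. What it emulates, and how:

* **Sequence**: a first-order Markov chain (implemented in C++ for Mb
  scale) whose transition row out of C is solved numerically so the
  stationary sequence hits a target GC fraction and CpG observed/expected
  ratio. The background is CpG-depleted (GC 0.40, CpG score 0.25), as
  real genomes are; islands are embedded at GC 0.65, CpG score 0.8.
  Realized composition lands within ±0.01 of target at default island
  lengths; the recovery test asserts ±0.05.
* **Islands**: 300 islands of 500–1,500 bp on 2 × 2 Mb chromosomes,
  placed with enough mutual clearance that the altered-accessibility
  spans of neighbouring sites never merge. Half are promoter-associated
  (a 1 bp TSS at the island start), 30% are methylated.
* **Methylation probes**: every 100 bp inside islands; betas from a
  bimodal two-component Beta mixture (modes 0.1 and 0.9, concentration
  10), so probe-level distributions look like array data and region
  classification is nearly deterministic.
* **Peaks**: each island carries an H3K9me2 peak with probability 0.8
  (unmethylated) or 0.5 (methylated) — encoding the preferential
  nucleation at unmethylated, low-deamination CGIs — with widths uniform
  in 500–2,000 bp centered on the island; 40 additional CGI-like
  non-island sites carry peaks and respond like unmethylated sites.
* **Fragments**: placed by midpoint with a piecewise-constant rate:
  baseline 1 genome-wide, multiplied by a depression factor 0.2 over each
  nucleation site in the control, and additionally by a recovery factor
  in the treatment — $f_u = 5$ at unmethylated sites (full reversal,
  $0.2 \times 5 = 1$) and $f_m = 1.5$ at methylated sites (modest
  reversal). The constraint $f_u \ge f_m \ge 1$ encodes the direction of
  the methylation interaction. The altered-rate span is the island/peak
  union padded by one mean fragment length (150 bp), so that
  overlap-based counting over the island sees the configured ratio rather
  than an edge-diluted one. Because both libraries are sampled to a fixed
  size (2 × 10⁵ fragments), the treatment background rate is lowered
  slightly so total rate mass matches the control; without this
  mass balance the per-million fold change at sites would undershoot its
  configured value by the fraction of the library the recovered sites
  absorb. Fragment lengths are truncated-normal (mean 150, sd 30, min
  50 bp).

Everything is deterministic given the seed, to the byte, including the
written files.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: mappability and GC bias in sequencing,
replicate-level variability (libraries are born pooled), peak-calling
uncertainty (peaks are placed, not called), chromatin accessibility
structure unrelated to H3K9me2 (promoter peaks, enhancers), probe
annotation error, and any evolutionary signal in the sequence itself
(class labels are assigned, not evolved). Genome-scale printed quantities
from the motivating study (e.g. tens of thousands of peaks and islands,
or rank-sum p-values of order $10^{-250}$) depend on real genome-scale
data and are deliberately not reproduction targets at this toy scale.

# Numerical choices and problem sizes

* Default toy scale (2 chromosomes × 2 Mb, 300 islands, 2 × 10⁵
  fragments per condition) runs the full pipeline in under ten seconds,
  so the whole analysis is re-runnable from scratch in tests and scripts.
* The calibration study in the test suite uses 200 replicates of a
  single-chromosome 500 kb configuration with 2 × 10⁴ fragments, and the
  resampling null in scripts uses 100 draws of 1,000 regions — scaled
  down from the study protocol's 10,000 draws, whose pooled distribution
  at desk scale is indistinguishable from 100 draws for median-level
  summaries.
* Random-region sampling uses rejection against the exclusion set with a
  bounded attempt budget (default 1,000 × n) and reports the attempt
  count on failure, rather than looping forever on dense exclusions.
* Window tiling uses `floor((len - window)/step) + 1` windows per
  chromosome; chromosomes shorter than the window produce none (wiggle
  output emits no block for them).
* Ties in the rank-sum test take midranks; the exact path refuses ties
  and falls through to the Edgeworth approximation, whose tie correction
  is exact by construction.

# Known limitations

* The rank-sum comparison of site vs background fold changes is a test
  of distributional equality; with count-depth differences between the
  two region classes it will flag dispersion differences as significant
  (see above). A location-focused alternative (e.g. a bootstrap of
  medians) is out of scope here.
* Fold changes are compositional (per-million shares); absolute
  accessibility claims require external calibration, exposed only as the
  raw-count mode.
* BAM fragment extraction trusts the aligner's proper-pair flag and
  TLEN field and collapses duplicates by identical fragment coordinates;
  it does not re-pair reads itself.
* The CGI-like scanner merges at window resolution, so island boundaries
  are only step-accurate (±50 bp at defaults).
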