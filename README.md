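# faireCGI

Chromatin accessibility analysis at H3K9me2 nucleation sites and CpG
islands, for paired-condition FAIRE-seq experiments.

In committed hematopoietic stem and progenitor cells (HSPCs), the
G9a/GLP methyltransferases nucleate the repressive H3K9me2 mark at
punctate genomic sites with CpG-island-like base composition. Inhibiting
G9a/GLP (e.g. with UNC0638) removes the mark, and chromatin accessibility
at those sites — measured by FAIRE-seq — recovers, strongly at
unmethylated CGIs and only modestly at DNA-methylated ones. faireCGI is
an R package for this style of integration analysis: it takes fragment
files for a treatment and a control condition, H3K9me2 peak regions, a
CGI/TSS annotation and methylation probe betas, and quantifies where and
how much accessibility changes, against resampling and sliding-window
backgrounds.

## What it computes

For regions \(r\) with fragment counts \(c_a, c_b\) in libraries of size
\(N_a, N_b\), the package works with the pseudocounted, library-size
normalized fold change

```
FC(r) = ((c_a + eps) / N_a) / ((c_b + eps) / N_b)
```

and provides:

* **Interval toolkit** — BED I/O, half-open overlap arithmetic,
  random-region sampling weighted by valid placements
  (`read_bed`, `overlaps`, `overlap_fraction`, `sample_random_regions`).
* **Coverage** — fragment loading from BED or BAM (proper pairs,
  duplicates removed), sliding-window counting (10 bp wiggle tracks,
  1 kb / 50 bp genome backgrounds), per-region counts, fixedStep
  wiggle / bedGraph output (`load_fragments`, `count_in_windows`,
  `genome_background`, `write_track`).
* **Statistics** — per-region fold changes, a random-region resampling
  null (1,000 × 1 kb regions, 10,000 draws by default), a Wilcoxon
  rank-sum test with exact enumeration at small n and an
  Edgeworth-corrected normal approximation otherwise, and aggregate
  ("metaplot") profiles around region midpoints (`fold_changes`,
  `resampling_null`, `rank_sum_test`, `aggregate_profile`).
* **Sequence composition** — GC fraction and CpG observed/expected score,
  classical CGI thresholds (0.50 / 0.60 / 200 bp), and a sliding-window
  CGI-like scanner (`composition`, `classify_cgi_like`, `scan_cgi_like`).
* **Stratification** — peak/CGI overlap splitting, promoter vs orphan
  CGIs (TSS ± 1 kb), methylation state from probe betas (> 0.75
  methylated, < 0.25 unmethylated, strict), evolutionary class labels,
  and a stratified fold-change report with pairwise rank-sum tests
  (`split_by_overlap`, `classify_methylation`,
  `stratified_fold_change_report`).
* **Synthetic data** — a deterministic generator producing a toy genome
  with CGI-like islands, bimodal methylation, peaks biased to
  unmethylated islands, and paired fragment sets with configurable
  recovery factors `f_u >= f_m >= 1` (`synthetic_config`,
  `generate_dataset`, `write_dataset`, `truth_table`).

See `vignettes/methods.Rmd` for the model, parameter defaults and their
rationale, and known limitations.

## Worked example

Generate the default synthetic dataset and run the stratified analysis:

```r
library(faireCGI)

ds  <- generate_dataset(synthetic_config(seed = 42))
rec <- classify_methylation(ds$cgi, ds$probes)
rec <- assign_promoter_status(rec, ds$tss)
rec <- attach_evo_class(rec, split(ds$cgi, ds$cgi_labels$evo_class))

split_by_overlap(ds$peaks, ds$cgi)$fraction
#> [1] 0.8393574

stratified_fold_change_report(rec, ds$fragments$UNC0638, ds$fragments$DMSO)
#> stratified fold-change report
#>            margin         stratum   n     q1 median    q3
#> 1      meth_state      methylated 100 0.8731  1.120 1.378
#> 2      meth_state    unmethylated 200 3.1417  4.207 5.500
#> 3 promoter_status          orphan 167 1.0909  3.500 4.912
#> 4 promoter_status        promoter 133 1.0278  1.923 4.800
#> 5       evo_class         gc_gain 106 0.9519  1.221 1.571
#> 6       evo_class low_deamination 181 2.7778  4.176 5.500
#> pairwise rank-sum tests:
#>            margin  stratum_1       stratum_2 n_1 n_2 p_value
#> 1      meth_state methylated    unmethylated 100 200  0.0000
#> 2 promoter_status     orphan        promoter 167 133  0.3499
#> 3       evo_class    gc_gain low_deamination 106 181  0.0000
```

Reading the report: unmethylated CGIs respond strongly to loss of
H3K9me2 (median fold change 4.2, against a configured true effect of 5
shrunk slightly by the pseudocount), methylated CGIs barely move
(median 1.1 vs configured 1.5 over peaked and unpeaked islands
together), and the low-deamination evolutionary class — which is mostly
unmethylated — mirrors the methylation split. Promoter and orphan CGIs
behave alike. The site-vs-background comparison is equally clear-cut:

```r
fc  <- fold_changes(ds$peaks, ds$fragments$UNC0638, ds$fragments$DMSO)
nul <- resampling_null(ds$fragments$UNC0638, ds$fragments$DMSO, ds$genome,
                       n_regions = 1000, n_draws = 100, seed = 43)
rank_sum_test(fc$fold_change, nul$fold_changes)
#> Wilcoxon rank-sum test (normal_approximation): U = 2.34204e+07,
#>   n = (246, 100000), p = <1e-300
```

A command-line front end is installed as `exec/fairecgi` with
subcommands `simulate`, `foldchange`, `null`, `background`, `profile`
and `stratify`; run it with `Rscript <library>/faireCGI/exec/fairecgi`.

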