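test_that("peak/CGI partition is exact and reports the overlap fraction", {
  peaks <- interval_set(rep("chr1", 4), c(0, 100, 200, 300),
                        c(50, 150, 250, 350))
  cgis <- interval_set(c("chr1", "chr1"), c(40, 210), c(60, 220))
  sp <- split_by_overlap(peaks, cgis)
  expect_equal(sp$fraction, 0.5)
  expect_equal(nrow(sp$overlapping), 2)
  expect_equal(nrow(sp$non_overlapping), 2)
  expect_equal(nrow(sp$overlapping) + nrow(sp$non_overlapping), nrow(peaks))

  none <- split_by_overlap(peaks, cgis[0, ])
  expect_equal(none$fraction, 0)
  all_in <- split_by_overlap(peaks, peaks)
  expect_equal(all_in$fraction, 1)
})

test_that("promoter assignment expands TSS points by the flank", {
  cgi <- interval_set("chr1", 1000, 1500)
  tss_at <- function(p) interval_set("chr1", p, p + 1)
  expect_equal(assign_promoter_status(cgi, tss_at(1200),
                                      promoter_flank = 0)$promoter_status,
               "promoter")
  expect_equal(assign_promoter_status(cgi, tss_at(2400),
                                      promoter_flank = 1000)$promoter_status,
               "promoter")
  expect_equal(assign_promoter_status(cgi, tss_at(10000),
                                      promoter_flank = 1000)$promoter_status,
               "orphan")
})

test_that("methylation classification applies strict thresholds", {
  cgi <- interval_set("chr1", 0, 1000)
  pr <- function(beta) data.frame(chrom = "chr1",
                                  position = seq(100, by = 10,
                                                 length.out = length(beta)),
                                  beta = beta)
  st <- function(beta, ...)
    classify_methylation(cgi, pr(beta), min_probes = 1, ...)$meth_state
  expect_equal(st(c(0.9, 0.8, 0.85)), "methylated")
  expect_equal(st(c(0.1, 0.2)), "unmethylated")
  expect_equal(st(0.5), "indeterminate")
  # boundary values are indeterminate (strict > and <)
  expect_equal(st(c(0.75, 0.75)), "indeterminate")
  expect_equal(st(c(0.25, 0.25)), "indeterminate")
  rec <- classify_methylation(cgi, pr(c(0.9, 0.9)), min_probes = 3)
  expect_equal(rec$meth_state, "no_data")
  expect_equal(rec$n_probes, 2L)
})

test_that("raising the methylated threshold never adds methylated calls", {
  set.seed(81)
  cgis <- interval_set(rep("chr1", 50), (0:49) * 2000, (0:49) * 2000 + 800)
  probes <- data.frame(chrom = "chr1",
                       position = sort(sample(0:99999, 3000)),
                       beta = stats::runif(3000))
  n_meth <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(t)
    sum(classify_methylation(cgis, probes, t_meth = t,
                             min_probes = 1)$meth_state == "methylated"),
    0)
  expect_true(all(diff(n_meth) <= 0))
})

test_that("probe aggregation matches a point-in-interval scan", {
  set.seed(82)
  cgis <- random_intervals(100, max_pos = 50000, width = c(200, 2000))
  probes <- data.frame(
    chrom = sample(c("chr1", "chr2"), 2000, TRUE),
    position = sample(0:51999, 2000, TRUE),
    beta = stats::runif(2000))
  rec <- classify_methylation(cgis, probes, min_probes = 1)
  want <- bf_probe_stats(cgis, probes)
  expect_equal(rec$n_probes, as.integer(want[, "n"]))
  expect_equal(rec$mean_beta, unname(want[, "mean"]))
  # state recomputable from stored mean and thresholds
  expect_equal(rec$meth_state,
               faireCGI:::meth_state_from_beta(rec$mean_beta, rec$n_probes,
                                               min_probes = 1))
})

test_that("evolutionary class labels require disjoint class sets", {
  cgi <- interval_set(c("chr1", "chr1", "chr1"), c(0, 1000, 2000),
                      c(500, 1500, 2500))
  classes <- list(
    low_deamination = interval_set("chr1", 0, 600),
    gc_gain = interval_set("chr1", 1100, 1200))
  rec <- attach_evo_class(cgi, classes)
  expect_equal(rec$evo_class, c("low_deamination", "gc_gain", "unlabeled"))

  overlapping <- list(a = interval_set("chr1", 0, 600),
                      b = interval_set("chr1", 500, 700))
  expect_error(attach_evo_class(cgi, overlapping), "overlap")

  ambiguous <- list(a = interval_set("chr1", 0, 100),
                    b = interval_set("chr1", 400, 500))
  expect_error(attach_evo_class(cgi, ambiguous), "more than one")
})

test_that("stratified report recovers the generated methylation ordering", {
  cfg <- small_config(seed = 83, chrom_lengths = c(chrA = 1e6), n_cgi = 60,
                      frac_methylated = 0.5, p_peak_unmeth = 1,
                      p_peak_meth = 1, f_u = 4, f_m = 1.5)
  ds <- generate_dataset(cfg)
  rec <- classify_methylation(ds$cgi, ds$probes)
  rec <- assign_promoter_status(rec, ds$tss)
  rep <- stratified_fold_change_report(rec, ds$fragments$UNC0638,
                                       ds$fragments$DMSO)
  s <- rep$summaries[rep$summaries$margin == "meth_state", ]
  med <- stats::setNames(s$median, s$stratum)
  expect_gt(med[["unmethylated"]], med[["methylated"]])
  t <- rep$tests
  p <- t$p_value[t$margin == "meth_state" &
                   t$stratum_1 %in% c("methylated", "unmethylated") &
                   t$stratum_2 %in% c("methylated", "unmethylated")]
  expect_lt(p, 0.01)
})

test_that("equal effects across strata keep rank-sum tests calibrated", {
  rej <- 0; n_rep <- 100
  for (i in seq_len(n_rep)) {
    cfg <- small_config(seed = 8400 + i, chrom_lengths = c(chrA = 4e5),
                        n_cgi = 30, n_noncgi_peaks = 0,
                        frac_methylated = 0.5, p_peak_unmeth = 1,
                        p_peak_meth = 1, f_u = 2, f_m = 2,
                        library_size = c(UNC0638 = 2e4, DMSO = 2e4))
    ds <- generate_dataset(cfg)
    tr <- truth_table(ds)
    rec <- data.frame(
      chrom = tr$chrom, start = tr$start, end = tr$end, name = tr$name,
      promoter_status = tr$promoter_status, evo_class = tr$evo_class,
      meth_state = tr$meth_state, mean_beta = NA_real_, n_probes = 5L,
      stringsAsFactors = FALSE)
    rep <- stratified_fold_change_report(rec, ds$fragments$UNC0638,
                                         ds$fragments$DMSO,
                                         stratify_by = "meth_state")
    p <- rep$tests$p_value[rep$tests$stratum_1 %in%
                             c("methylated", "unmethylated") &
                             rep$tests$stratum_2 %in%
                             c("methylated", "unmethylated")]
    if (length(p) == 1 && p < 0.05) rej <- rej + 1
  }
  expect_lte(rej / n_rep, 0.10)
})

test_that("a single nonempty stratum yields summaries but no tests", {
  cfg <- small_config(seed = 85, n_cgi = 20, frac_methylated = 0,
                      n_noncgi_peaks = 0)
  ds <- generate_dataset(cfg)
  tr <- truth_table(ds)
  rec <- data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
                    name = tr$name, promoter_status = "unassigned",
                    evo_class = "unlabeled", meth_state = tr$meth_state,
                    mean_beta = NA_real_, n_probes = 5L,
                    stringsAsFactors = FALSE)
  rep <- stratified_fold_change_report(rec, ds$fragments$UNC0638,
                                       ds$fragments$DMSO,
                                       stratify_by = "meth_state")
  expect_true(is.null(rep$tests))
  expect_equal(rep$summaries$stratum, "unmethylated")
})
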