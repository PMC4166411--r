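test_that("fold changes combine counts, libraries and pseudocount correctly", {
  region <- interval_set("chr1", 0, 1000)
  mk <- function(n_in, n_out) {
    start <- c(seq(100, 100 + n_in - 1), seq(5000, 5000 + n_out - 1))
    fragment_set(interval_set(rep("chr1", n_in + n_out), start, start + 50))
  }
  # equal library sizes, counts 20 vs 10
  fc <- fold_changes(region, mk(20, 80), mk(10, 90), pseudocount = 0)
  expect_equal(fc$fold_change, 2.0)
  # library-size normalization: 10 of 200 vs 10 of 100
  fc2 <- fold_changes(region, mk(10, 190), mk(10, 90), pseudocount = 0)
  expect_equal(fc2$fold_change, 0.5)
  expect_equal(fc2$signal_a * 2, fc2$signal_b)
  # identical inputs
  fc3 <- fold_changes(region, mk(10, 90), mk(10, 90))
  expect_equal(fc3$fold_change, 1.0)
  # zero control count without pseudocount names the region
  r2 <- interval_set("chr1", 10000, 11000)
  expect_error(fold_changes(r2, mk(10, 90), mk(10, 90), pseudocount = 0),
               "chr1:10000-11000")
})

test_that("fold change is invariant to pooling order and monotone in counts", {
  set.seed(71)
  region <- interval_set("chr1", 1000, 2000)
  frag <- random_intervals(500, chroms = "chr1", max_pos = 9000)
  perm <- sample(nrow(frag))
  shuffled <- interval_set(frag$chrom[perm], frag$start[perm],
                           frag$end[perm])
  ctrl <- fragment_set(random_intervals(500, chroms = "chr1",
                                        max_pos = 9000))
  expect_equal(
    fold_changes(region, fragment_set(frag), ctrl)$fold_change,
    fold_changes(region, fragment_set(shuffled), ctrl)$fold_change)

  # move one outside fragment into the region: same library, higher count
  out_i <- which(frag$start > 3000)[1]
  moved <- frag
  moved$start[out_i] <- 1500; moved$end[out_i] <- 1600
  expect_gt(
    fold_changes(region, fragment_set(moved), ctrl)$fold_change,
    fold_changes(region, fragment_set(frag), ctrl)$fold_change)
})

test_that("rank-sum exact path reproduces enumeration", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$method, "exact")
  expect_equal(r$p.value, 0.1)  # 2/20 rank assignments as extreme
  expect_equal(r$statistic, 0)  # minimal U for x

  r2 <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$p.value, 1)

  d <- rank_sum_test(rep(2, 5), rep(2, 7))
  expect_true(d$degenerate)
  expect_equal(d$p.value, 1)

  # against an independent DP enumeration and wilcox.test
  set.seed(72)
  for (i in 1:20) {
    x <- sample(1000, 7); y <- sample(2000, 9) + 0.5
    p <- rank_sum_test(x, y)$p.value
    expect_equal(p, dp_ranksum_pvalue(x, y))
    expect_equal(p, stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("normal approximation stays within 0.01 of enumeration at n = 8 + 8", {
  set.seed(73)
  for (i in 1:100) {
    x <- stats::rnorm(8); y <- stats::rnorm(8, stats::runif(1, 0, 2))
    exact <- rank_sum_test(x, y)$p.value
    approx <- rank_sum_test(x, y, exact_limit = 0)$p.value
    expect_lt(abs(exact - approx), 0.01)
  }
})

test_that("strong separation yields vanishing p-values", {
  set.seed(74)
  x <- stats::rnorm(100, 1, 0.1)
  y <- stats::rnorm(100, 3, 0.1)
  r <- rank_sum_test(x, y)
  expect_lt(r$p.value, 1e-10)
  expect_equal(r$statistic, 0)  # complete separation
  big <- rank_sum_test(stats::rnorm(2000, 10, .1), stats::rnorm(2000, 0, .1))
  expect_equal(big$p.label, "<1e-300")
})

test_that("resampling null bookkeeping and degenerate case", {
  g <- genome_dict("chrA", 50000)
  set.seed(75)
  fr <- fragment_set(random_intervals(2000, chroms = "chrA",
                                      max_pos = 45000))
  nul <- resampling_null(fr, fr, g, n_regions = 3, region_length = 1000,
                         n_draws = 2, seed = 10)
  expect_length(nul$fold_changes, 6)
  expect_true(all(nul$fold_changes == 1))  # same library both sides
  nul2 <- resampling_null(fr, fr, g, n_regions = 5, n_draws = 3, seed = 10)
  expect_identical(nul2$fold_changes,
                   resampling_null(fr, fr, g, n_regions = 5, n_draws = 3,
                                   seed = 10)$fold_changes)
})

test_that("doubled fragments recover a 2x raw-count fold change", {
  g <- genome_dict("chrA", 100000)
  set.seed(76)
  b <- random_intervals(5000, chroms = "chrA", max_pos = 95000,
                        width = c(100, 200))
  a <- interval_set(rep(b$chrom, 2), rep(b$start, 2), rep(b$end, 2))
  nul <- resampling_null(fragment_set(a), fragment_set(b), g,
                         n_regions = 200, region_length = 1000,
                         n_draws = 10, seed = 11, normalize = FALSE)
  med <- stats::median(nul$fold_changes)
  expect_gt(med, 1.9); expect_lt(med, 2.1)
  # per-million normalization cancels a uniform global change
  nul2 <- resampling_null(fragment_set(a), fragment_set(b), g,
                          n_regions = 200, n_draws = 5, seed = 11)
  expect_equal(stats::median(nul2$fold_changes), 1, tolerance = 0.05)
})

test_that("genome background tiles windows and zeroes on identical input", {
  g <- genome_dict("chrA", 1100)
  fr <- fragment_set(interval_set("chrA", c(0, 300, 900), c(200, 700, 1100)))
  bg <- genome_background(fr, fr, g, window = 1000, step = 50)
  expect_equal(nrow(bg) + attr(bg, "n_excluded_empty"), 3)
  expect_true(all(bg$log2_fold_change == 0))
})

test_that("background change is confined to generated nucleation sites", {
  cfg <- synthetic_config(seed = 77, chrom_lengths = c(chrA = 1e6),
                          n_cgi = 30, n_noncgi_peaks = 0,
                          f_u = 3, f_m = 3, p_peak_unmeth = 1,
                          p_peak_meth = 1,
                          library_size = c(UNC0638 = 8e5, DMSO = 8e5))
  ds <- generate_dataset(cfg)
  bg <- genome_background(ds$fragments$UNC0638, ds$fragments$DMSO,
                          ds$genome, window = 1000, step = 50)
  wins <- interval_set(bg$chrom, bg$start, bg$end)
  tr <- truth_table(ds)
  # altered-rate span of each site: island/peak union plus the
  # fragment-length pad the generator applies
  pk <- ds$peaks[match(tr$name, ds$peaks$name), ]
  eff <- interval_set(tr$chrom,
                      pmax(0, pmin(tr$start, pk$start) - 150),
                      pmax(tr$end, pk$end) + 150)
  inside <- contained_any(wins, eff)
  pad <- interval_set(tr$chrom, pmax(0, tr$start - 3500), tr$end + 3500)
  near_site <- ov_any(wins, pad)
  expect_gt(stats::median(bg$log2_fold_change[inside]), 1)
  expect_lt(stats::median(abs(bg$log2_fold_change[!near_site])), 0.1)
})

test_that("aggregate profiles are flat for tiling coverage and symmetric", {
  g <- genome_dict("chrA", 20000)
  tile <- seq(0, 19950, by = 50)
  fr <- fragment_set(interval_set(rep("chrA", length(tile)), tile,
                                  tile + 50))
  regions <- interval_set(rep("chrA", 3), c(4000, 9000, 14000),
                          c(5000, 10000, 15000))
  prof <- aggregate_profile(regions, fr, g, flank = 1000, bin = 50)
  expect_equal(length(unique(prof$mean_signal)), 1)

  # symmetric placement around midpoints -> symmetric profile
  mids <- c(4500, 9500, 14500)
  fr2 <- fragment_set(interval_set(
    rep("chrA", 6), c(mids - 300, mids + 200), c(mids - 200, mids + 300)))
  prof2 <- aggregate_profile(regions, fr2, g, flank = 500, bin = 100)
  expect_equal(prof2$mean_signal, rev(prof2$mean_signal))
  expect_error(aggregate_profile(regions[0, ], fr, g), "empty")

  near_end <- interval_set("chrA", c(100, 9000), c(200, 10000))
  prof3 <- aggregate_profile(near_end, fr, g, flank = 1000, bin = 50)
  expect_equal(attr(prof3, "n_skipped"), 1)
})
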