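# Brute-force oracles, independent of the package's interval-tree /
# vectorised code paths, plus shared fixtures built in code.

bf_pair_overlaps <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 && s1 < e2 && s2 < e1
}

# fraction of query intervals overlapping >= 1 reference interval,
# all-pairs scan
bf_overlap_fraction <- function(query, reference) {
  hit <- vapply(seq_len(nrow(query)), function(i) {
    any(vapply(seq_len(nrow(reference)), function(j)
      bf_pair_overlaps(query$chrom[i], query$start[i], query$end[i],
                       reference$chrom[j], reference$start[j],
                       reference$end[j]), TRUE))
  }, TRUE)
  mean(hit)
}

# per-region fragment-overlap counts, all-pairs scan
bf_count_in_regions <- function(frag, regions) {
  vapply(seq_len(nrow(regions)), function(i)
    sum(vapply(seq_len(nrow(frag)), function(j)
      bf_pair_overlaps(regions$chrom[i], regions$start[i], regions$end[i],
                       frag$chrom[j], frag$start[j], frag$end[j]), TRUE)),
    0)
}

# per-window fragment counts for a single chromosome
bf_window_counts <- function(frag, chrom, chrom_len, window, step) {
  starts <- seq(0, chrom_len - window, by = step)
  vapply(starts, function(s)
    sum(frag$chrom == chrom & frag$start < s + window & frag$end > s), 0)
}

# probe-in-CGI assignment by point-in-interval scan
bf_probe_stats <- function(cgis, probes) {
  t(vapply(seq_len(nrow(cgis)), function(i) {
    inside <- probes$chrom == cgis$chrom[i] &
      probes$position >= cgis$start[i] & probes$position < cgis$end[i]
    c(n = sum(inside),
      mean = if (any(inside)) mean(probes$beta[inside]) else NA_real_)
  }, c(n = 0, mean = 0)))
}

# per-window CGI-like scan + merge, string arithmetic only
bf_scan_cgi_like <- function(seq_str, window, step, gc_min = 0.5,
                             score_min = 0.6, length_min = 200) {
  len <- nchar(seq_str)
  starts <- seq(0, len - window, by = step)
  pos <- logical(length(starts))
  for (k in seq_along(starts)) {
    w <- substr(seq_str, starts[k] + 1, starts[k] + window)
    b <- strsplit(w, "")[[1]]
    nC <- sum(b == "C"); nG <- sum(b == "G")
    nN <- sum(b == "N"); leff <- window - nN
    ncpg <- sum(b[-length(b)] == "C" & b[-1] == "G")
    gc <- if (leff > 0) (nC + nG) / leff else 0
    sc <- if (nC > 0 && nG > 0) ncpg * leff / (nC * nG) else 0
    pos[k] <- gc >= gc_min && sc >= score_min && window >= length_min
  }
  # merge overlapping/adjacent positive windows
  out <- NULL
  for (k in which(pos)) {
    s <- starts[k]; e <- s + window
    if (!is.null(out) && s <= out$end[nrow(out)])
      out$end[nrow(out)] <- max(out$end[nrow(out)], e)
    else out <- rbind(out, data.frame(start = s, end = e))
  }
  out
}

# exact rank-sum null distribution by subset-sum dynamic programming
# (different algorithm from the package's combn enumeration)
dp_ranksum_pvalue <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  W <- sum(rank(c(x, y))[seq_len(n1)])
  maxs <- sum((n - n1 + 1):n)
  ways <- matrix(0, nrow = n1 + 1, ncol = maxs + 1)
  ways[1, 1] <- 1
  for (r in 1:n) for (k in min(n1, r):1) {
    idx <- which(ways[k, ] > 0)
    ways[k + 1, idx + r] <- ways[k + 1, idx + r] + ways[k, idx]
  }
  dist <- ways[n1 + 1, ]
  total <- sum(dist)
  sums <- which(dist > 0) - 1
  p_le <- sum(dist[sums[sums <= W] + 1]) / total
  p_ge <- sum(dist[sums[sums >= W] + 1]) / total
  min(1, 2 * min(p_le, p_ge))
}

# vectorised any-overlap without the package's interval trees
ov_any <- function(query, ref) {
  hit <- logical(nrow(query))
  for (j in seq_len(nrow(ref)))
    hit <- hit | (query$chrom == ref$chrom[j] & query$start < ref$end[j] &
                    query$end > ref$start[j])
  hit
}

# is each query interval fully contained in some reference interval?
contained_any <- function(query, ref) {
  hit <- logical(nrow(query))
  for (j in seq_len(nrow(ref)))
    hit <- hit | (query$chrom == ref$chrom[j] &
                    query$start >= ref$start[j] & query$end <= ref$end[j])
  hit
}

# random interval fixture
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e4,
                             width = c(10, 300)) {
  chrom <- sample(chroms, n, replace = TRUE)
  w <- sample(width[1]:width[2], n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  interval_set(chrom, start, start + w)
}

# small, quick generator configuration for tests that need a full dataset
small_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, chrom_lengths = c(chrA = 6e5),
                   n_cgi = 40, n_noncgi_peaks = 5,
                   library_size = c(UNC0638 = 4e4, DMSO = 4e4))
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

# the default-scale dataset is expensive; build it once per test run
shared_env <- new.env()
default_dataset <- function() {
  if (is.null(shared_env$ds))
    shared_env$ds <- generate_dataset(synthetic_config(seed = 20140910))
  shared_env$ds
}
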