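#' Per-region fold change of normalized FAIRE signal between conditions
#'
#' Counts fragments per region in each condition, adds a raw-count
#' pseudocount, scales to fragments per million, and forms the
#' treatment/control ratio:
#' \deqn{FC = \frac{(c_a + \varepsilon)\,10^6 / N_a}
#'                 {(c_b + \varepsilon)\,10^6 / N_b}}
#' where \eqn{N_a, N_b} are library sizes. The pseudocount is applied to
#' raw counts before normalization so its meaning does not depend on
#' library depth; with `pseudocount = 0` a zero control count is an error
#' naming the region.
#'
#' @param regions a nonempty [interval_set()].
#' @param frags_a treatment [fragment_set()] (e.g. UNC0638).
#' @param frags_b control [fragment_set()] (e.g. DMSO).
#' @param pseudocount raw-count pseudocount \eqn{\varepsilon \ge 0}
#'   (default 1).
#' @param normalize divide by library size (default). With
#'   `normalize = FALSE` the ratio is formed from raw counts — the
#'   relevant scale when libraries are externally calibrated, since a
#'   genome-wide uniform accessibility change leaves per-million shares
#'   untouched.
#' @return Data frame with one row per region: coordinates, raw counts
#'   `count_a`/`count_b`, per-million signals `signal_a`/`signal_b`
#'   (without pseudocount), `fold_change` and `log2_fold_change` (with
#'   pseudocount).
#' @export
fold_changes <- function(regions, frags_a, frags_b, pseudocount = 1,
                         normalize = TRUE) {
  stopifnot(pseudocount >= 0)
  ca <- count_in_regions(frags_a, regions)
  cb <- count_in_regions(frags_b, regions)
  if (pseudocount == 0 && any(cb == 0)) {
    i <- which(cb == 0)[1]
    stop("zero control count with pseudocount = 0 at region ",
         regions$chrom[i], ":", regions$start[i], "-", regions$end[i])
  }
  la <- if (normalize) frags_a$library_size else 1
  lb <- if (normalize) frags_b$library_size else 1
  fc <- ((ca + pseudocount) / la) / ((cb + pseudocount) / lb)
  data.frame(chrom = regions$chrom, start = regions$start,
             end = regions$end,
             count_a = ca, count_b = cb,
             signal_a = ca * 1e6 / frags_a$library_size,
             signal_b = cb * 1e6 / frags_b$library_size,
             fold_change = fc, log2_fold_change = log2(fc),
             stringsAsFactors = FALSE)
}

#' Random-region resampling null for fold changes
#'
#' Repeatedly samples `n_regions` random regions of `region_length` bp
#' from the genome (`n_draws` times) and computes the treatment/control
#' fold change at each, giving the background distribution of
#' accessibility change against which fold changes at H3K9me2 nucleation
#' sites are compared. Defaults follow the published protocol: 1,000
#' regions of 1 kb drawn 10,000 times.
#'
#' @inheritParams fold_changes
#' @param genome a [genome_dict()].
#' @param n_regions regions per draw.
#' @param region_length region length in bp.
#' @param n_draws number of draws.
#' @param seed integer seed; the whole resampling is deterministic given
#'   the seed.
#' @param exclude optional [interval_set()] that sampled regions must
#'   avoid.
#' @inheritParams fold_changes
#' @return A list of class `resampling_null`: `fold_changes` (pooled,
#'   length `n_regions * n_draws`), `draw_medians` (length `n_draws`),
#'   and the parameters.
#' @export
resampling_null <- function(frags_a, frags_b, genome, n_regions = 1000,
                            region_length = 1000, n_draws = 10000,
                            seed = NULL, pseudocount = 1, exclude = NULL,
                            normalize = TRUE) {
  stopifnot(n_regions >= 1, n_draws >= 1)
  idx_a <- iranges_by_chrom(frags_a$fragments)
  idx_b <- iranges_by_chrom(frags_b$fragments)
  la <- if (normalize) frags_a$library_size else 1
  lb <- if (normalize) frags_b$library_size else 1
  with_seed(seed, {
    pooled <- vector("list", n_draws)
    med <- numeric(n_draws)
    for (d in seq_len(n_draws)) {
      regions <- sample_random_regions(genome, n_regions, region_length,
                                       seed = NULL, exclude = exclude)
      ca <- count_in_regions_indexed(idx_a, regions)
      cb <- count_in_regions_indexed(idx_b, regions)
      fc <- ((ca + pseudocount) / la) / ((cb + pseudocount) / lb)
      pooled[[d]] <- fc
      med[d] <- stats::median(fc)
    }
    structure(list(fold_changes = unlist(pooled), draw_medians = med,
                   n_regions = n_regions, n_draws = n_draws,
                   region_length = region_length, pseudocount = pseudocount,
                   seed = seed),
              class = "resampling_null")
  })
}

#' @export
print.resampling_null <- function(x, ...) {
  cat(sprintf(
    "resampling_null: %d draws x %d regions of %d bp; pooled median FC %.3f\n",
    x$n_draws, x$n_regions, x$region_length,
    stats::median(x$fold_changes)))
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test with midranks for ties. When
#' `n1 + n2 <= exact_limit` and there are no ties, the p-value is computed
#' by full enumeration of all rank assignments; otherwise a normal
#' approximation with continuity correction, tie-corrected variance and
#' third/fourth-cumulant Edgeworth terms (all computed exactly from the
#' pooled midrank population) is used. When every value in both samples
#' is identical the test is degenerate and p = 1.
#'
#' @param x,y numeric samples.
#' @param exact_limit maximum combined sample size for the exact
#'   enumeration path.
#' @return A list of class `rank_sum_test`: `statistic` (the Mann-Whitney
#'   U for `x`), `z` (NA on the exact path), `p.value`, `p.label`
#'   (`"<1e-300"` for p below representable precision), `n1`, `n2`,
#'   `method` (`"exact"` or `"normal_approximation"`) and `degenerate`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))
#' @export
rank_sum_test <- function(x, y, exact_limit = 20) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  all_v <- c(x, y)
  if (anyNA(all_v)) stop("NA values in rank_sum_test input")
  r <- rank(all_v)
  W <- sum(r[seq_len(n1)])                     # rank sum of x
  U <- W - n1 * (n1 + 1) / 2                   # Mann-Whitney U for x
  ties <- anyDuplicated(all_v) > 0
  degenerate <- length(unique(all_v)) == 1
  if (degenerate) {
    return(structure(list(statistic = U, z = 0, p.value = 1,
                          p.label = "1", n1 = n1, n2 = n2,
                          method = "degenerate", degenerate = TRUE),
                     class = "rank_sum_test"))
  }
  n <- n1 + n2
  if (!ties && n <= exact_limit) {
    # enumerate the null distribution of the rank sum of x over all
    # choose(n, n1) assignments of ranks
    sums <- colSums(matrix(utils::combn(n, n1), nrow = n1))
    p_le <- mean(sums <= W)
    p_ge <- mean(sums >= W)
    p <- min(1, 2 * min(p_le, p_ge))
    res <- list(statistic = U, z = NA_real_, p.value = p,
                method = "exact")
  } else {
    # Edgeworth-corrected normal approximation: exact mean, variance,
    # skewness and excess kurtosis of the rank sum under sampling n1
    # midranks without replacement from the pooled midrank population
    # (tie correction is implicit in the population moments), with
    # continuity correction.
    mom <- srswor_sum_moments(r, n1)
    if (mom$var <= 0) {
      res <- list(statistic = U, z = 0, p.value = 1, method = "degenerate")
    } else {
      Fhat <- function(w) {
        z <- (w - mom$mean) / sqrt(mom$var)
        ew <- stats::pnorm(z) - stats::dnorm(z) *
          (mom$g1 / 6 * (z^2 - 1) + mom$g2 / 24 * (z^3 - 3 * z))
        min(1, max(0, ew))
      }
      p_le <- Fhat(W + 0.5)
      p_ge <- 1 - Fhat(W - 0.5)
      z <- (W - mom$mean - sign(W - mom$mean) * 0.5) / sqrt(mom$var)
      res <- list(statistic = U, z = z,
                  p.value = min(1, 2 * min(p_le, p_ge)),
                  method = "normal_approximation")
    }
  }
  res$p.label <- if (res$p.value < 1e-300) "<1e-300"
                 else format(res$p.value, digits = 6)
  res$n1 <- n1; res$n2 <- n2
  res$degenerate <- FALSE
  structure(res, class = "rank_sum_test")
}

# Exact moments of the sum of m values sampled without replacement from
# population r: mean, variance, skewness g1 and excess kurtosis g2,
# from the population power sums.
srswor_sum_moments <- function(r, m) {
  N <- length(r)
  S1 <- sum(r); S2 <- sum(r^2); S3 <- sum(r^3); S4 <- sum(r^4)
  ff <- function(k) prod(m - 0:(k - 1)) / prod(N - 0:(k - 1))
  f1 <- ff(1); f2 <- ff(2); f3 <- ff(3); f4 <- ff(4)
  E1 <- f1 * S1
  E2 <- f1 * S2 + f2 * (S1^2 - S2)
  E3 <- f1 * S3 + 3 * f2 * (S1 * S2 - S3) +
    f3 * (S1^3 - 3 * S1 * S2 + 2 * S3)
  T3 <- S1^2 * S2 - S2^2 - 2 * S1 * S3 + 2 * S4
  T4 <- S1^4 - 6 * S1^2 * S2 + 3 * S2^2 + 8 * S1 * S3 - 6 * S4
  E4 <- f1 * S4 + f2 * (4 * (S1 * S3 - S4) + 3 * (S2^2 - S4)) +
    6 * f3 * T3 + f4 * T4
  v <- E2 - E1^2
  m3 <- E3 - 3 * E1 * E2 + 2 * E1^3
  m4 <- E4 - 4 * E1 * E3 + 6 * E1^2 * E2 - 3 * E1^4
  list(mean = E1, var = v,
       g1 = if (v > 0) m3 / v^1.5 else 0,
       g2 = if (v > 0) m4 / v^2 - 3 else 0)
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum test (%s): U = %g, n = (%d, %d), p = %s\n",
              x$method, x$statistic, x$n1, x$n2, x$p.label))
  invisible(x)
}

#' Genome-wide sliding-window background of accessibility change
#'
#' Tiles the genome with sliding windows (default 1 kb windows in 50 bp
#' increments), counts fragments per window in each condition and returns
#' the per-window log2 fold change (treatment/control, pseudocounted and
#' library-size normalized). Windows with zero fragments in both
#' conditions are excluded; their count is recorded in the
#' `n_excluded_empty` attribute.
#'
#' @inheritParams fold_changes
#' @param genome a [genome_dict()].
#' @param window window size in bp.
#' @param step increment in bp.
#' @return Data frame of retained windows: `chrom`, `start`, `end`,
#'   `count_a`, `count_b`, `log2_fold_change`.
#' @export
genome_background <- function(frags_a, frags_b, genome, window = 1000,
                              step = 50, pseudocount = 1) {
  ta <- count_in_windows(frags_a, window, step, genome)
  tb <- count_in_windows(frags_b, window, step, genome)
  out <- lapply(names(genome), function(chrom) {
    ca <- ta$values[[chrom]]; cb <- tb$values[[chrom]]
    if (length(ca) == 0) return(NULL)
    starts <- (seq_along(ca) - 1) * step
    data.frame(chrom = chrom, start = starts, end = starts + window,
               count_a = ca, count_b = cb, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  empty <- out$count_a == 0 & out$count_b == 0
  res <- out[!empty, , drop = FALSE]
  fc <- ((res$count_a + pseudocount) / frags_a$library_size) /
    ((res$count_b + pseudocount) / frags_b$library_size)
  res$log2_fold_change <- log2(fc)
  rownames(res) <- NULL
  attr(res, "n_excluded_empty") <- sum(empty)
  res
}

#' Aggregate signal profile around region midpoints
#'
#' For each region, lays bins of `bin` bp from `midpoint - flank` to
#' `midpoint + flank`, counts overlapping fragments per bin, normalizes to
#' fragments per million, and averages over regions — the aggregate
#' ("metaplot") FAIRE density around a region class. Regions whose
#' midpoint is closer than `flank` to a chromosome end are skipped; the
#' skipped count is recorded in the `n_skipped` attribute.
#'
#' @param regions a nonempty [interval_set()].
#' @param frags a [fragment_set()].
#' @param genome a [genome_dict()] bounding the flanks.
#' @param flank half-width of the profiled span in bp (multiple of `bin`).
#' @param bin bin width in bp.
#' @return Data frame with `bin_start`/`bin_end` (bp relative to the
#'   midpoint) and `mean_signal` (mean per-million fragment count);
#'   attributes `n_regions`, `n_skipped`, `condition`.
#' @export
aggregate_profile <- function(regions, frags, genome, flank = 5000,
                              bin = 50) {
  if (nrow(regions) == 0) stop("empty region set")
  stopifnot(flank %% bin == 0, flank >= bin)
  mid <- floor((regions$start + regions$end) / 2)
  lim <- unclass(genome)[regions$chrom]
  ok <- mid - flank >= 0 & mid + flank <= lim
  n_skipped <- sum(!ok)
  if (!any(ok)) stop("all regions closer than `flank` to a chromosome end")
  mid <- mid[ok]
  chrom <- regions$chrom[ok]
  offs <- seq(-flank, flank - bin, by = bin)
  nb <- length(offs)
  bin_chrom <- rep(chrom, each = nb)
  bin_start <- rep(mid, each = nb) + rep(offs, times = length(mid))
  bins <- interval_set(bin_chrom, bin_start, bin_start + bin)
  counts <- count_in_regions(frags, bins)
  m <- matrix(counts, nrow = nb)
  prof <- rowMeans(m) * 1e6 / frags$library_size
  out <- data.frame(bin_start = offs, bin_end = offs + bin,
                    mean_signal = prof)
  attr(out, "n_regions") <- length(mid)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "condition") <- frags$condition
  out
}
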