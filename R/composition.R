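#' Load chromosome sequences from FASTA
#'
#' Returns a named character vector of chromosome sequences over
#' `{A,C,G,T,N}`. Sequence handling is case-insensitive: soft-masked
#' (lowercase) bases are counted as their base by default, or converted to
#' `N` with `mask_lowercase = TRUE`.
#'
#' @param path FASTA file (multi-record).
#' @param mask_lowercase treat soft-masked bases as `N` instead of their
#'   base.
#' @param genome optional [genome_dict()]; sequence lengths must agree.
#' @return Named character vector (a sequence store).
#' @export
read_fasta <- function(path, mask_lowercase = FALSE, genome = NULL) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (mask_lowercase) seqs <- gsub("[acgtn]", "N", seqs)
  seqs <- toupper(seqs)
  if (!is.null(genome)) {
    common <- intersect(names(seqs), names(genome))
    if (any(nchar(seqs[common]) != unclass(genome)[common]))
      stop("FASTA sequence lengths disagree with the genome dictionary")
  }
  seqs
}

count_fixed <- function(x, pattern) {
  (nchar(x) - nchar(gsub(pattern, "", x, fixed = TRUE))) / nchar(pattern)
}

#' Sequence composition of genomic regions
#'
#' For each region, counts C, G and CpG (CG) dinucleotides and computes the
#' GC fraction and the CpG observed/expected score
#' \deqn{\mathrm{CpG\ score} = \frac{n_{CpG} \times L_{eff}}{n_C \times n_G}}
#' where \eqn{L_{eff}} is the region length excluding N bases. N bases are
#' excluded from both numerator and denominator so unsequenced gaps do not
#' deflate GC content; a region with more than `max_n_fraction` N is
#' rejected. Dinucleotides are counted at every position where both bases
#' are non-N and inside the (half-open) region; pairs spanning the region
#' end are not counted. The score is defined as 0 when a region has no C or
#' no G.
#'
#' @param seqs sequence store from [read_fasta()] (named character vector).
#' @param regions an [interval_set()].
#' @param max_n_fraction maximum tolerated fraction of N bases per region.
#' @return Data frame with one row per region: `chrom`, `start`, `end`,
#'   `L`, `L_eff`, `n_C`, `n_G`, `n_CpG`, `gc_fraction`, `cpg_score`.
#' @examples
#' seqs <- c(chr1 = "ACGTACGT")
#' composition(seqs, interval_set("chr1", 0, 4))
#' @export
composition <- function(seqs, regions, max_n_fraction = 0.5) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  unknown <- setdiff(unique(regions$chrom), names(seqs))
  if (length(unknown) > 0)
    stop("region chromosome(s) absent from sequence store: ",
         paste(unknown, collapse = ", "))
  if (nrow(regions) > 0) {
    lim <- nchar(seqs)[regions$chrom]
    if (any(regions$end > lim) || any(regions$start < 0))
      stop("region(s) outside sequence bounds")
  }
  sub <- substring(seqs[regions$chrom], regions$start + 1, regions$end)
  L <- regions$end - regions$start
  n_N <- count_fixed(sub, "N")
  L_eff <- L - n_N
  if (any(n_N > max_n_fraction * L))
    stop("region(s) with more than ", round(100 * max_n_fraction),
         "% N bases have no defined composition")
  n_C <- count_fixed(sub, "C")
  n_G <- count_fixed(sub, "G")
  n_CpG <- count_fixed(sub, "CG")
  gc <- ifelse(L_eff > 0, (n_C + n_G) / L_eff, 0)
  score <- ifelse(n_C > 0 & n_G > 0, n_CpG * L_eff / (n_C * n_G), 0)
  data.frame(chrom = regions$chrom, start = regions$start,
             end = regions$end, L = L, L_eff = L_eff, n_C = n_C,
             n_G = n_G, n_CpG = n_CpG, gc_fraction = gc,
             cpg_score = score, stringsAsFactors = FALSE)
}

#' Classify regions as CGI-like from their composition
#'
#' A region is CGI-like when it meets all three classical CpG-island
#' criteria: GC fraction at least `gc_min`, CpG observed/expected score at
#' least `score_min`, and length at least `length_min` bp. Defaults are the
#' Gardiner-Garden & Frommer thresholds (0.50 / 0.60 / 200 bp).
#'
#' @param profile data frame from [composition()].
#' @param gc_min minimum GC fraction.
#' @param score_min minimum CpG observed/expected score.
#' @param length_min minimum length in bp.
#' @return `profile` with a logical `is_cgi_like` column and the thresholds
#'   recorded as attributes.
#' @export
classify_cgi_like <- function(profile, gc_min = 0.5, score_min = 0.6,
                              length_min = 200) {
  profile$is_cgi_like <- profile$gc_fraction >= gc_min &
    profile$cpg_score >= score_min & profile$L >= length_min
  attr(profile, "thresholds") <- c(gc_min = gc_min, score_min = score_min,
                                   length_min = length_min)
  profile
}

#' Scan a genome for CGI-like regions
#'
#' Tiles each chromosome with windows of `window` bp at `step` bp
#' increments, classifies each window with [classify_cgi_like()], and
#' merges overlapping or adjacent positive windows into maximal intervals.
#' Windows where composition is undefined (mostly N) are negative.
#' Chromosomes shorter than the window are skipped with a warning.
#'
#' @inheritParams composition
#' @inheritParams classify_cgi_like
#' @param window window size in bp (must be at least `length_min`).
#' @param step increment in bp (at most `window`).
#' @return An [interval_set()] of merged CGI-like intervals.
#' @export
scan_cgi_like <- function(seqs, window = 200, step = 50, gc_min = 0.5,
                          score_min = 0.6, length_min = 200) {
  stopifnot(window >= length_min, step >= 1, step <= window)
  out_chrom <- character(0); out_start <- numeric(0); out_end <- numeric(0)
  for (chrom in names(seqs)) {
    len <- nchar(seqs[[chrom]])
    if (len < window) {
      warning("chromosome ", chrom, " shorter than window; skipped")
      next
    }
    starts <- seq(0, len - window, by = step)
    wins <- interval_set(rep(chrom, length(starts)), starts, starts + window)
    prof <- composition(seqs[chrom], wins, max_n_fraction = 1)
    prof$gc_fraction[prof$L_eff == 0] <- 0
    hit <- prof$gc_fraction >= gc_min & prof$cpg_score >= score_min &
      prof$L >= length_min
    if (!any(hit)) next
    merged <- IRanges::reduce(
      IRanges::IRanges(start = starts[hit] + 1, width = window))
    out_chrom <- c(out_chrom, rep(chrom, length(merged)))
    out_start <- c(out_start, IRanges::start(merged) - 1)
    out_end <- c(out_end, IRanges::end(merged))
  }
  interval_set(out_chrom, out_start, out_end, provenance = "cgi_like_scan")
}
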