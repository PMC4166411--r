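#' Genomic interval sets
#'
#' An `interval_set` is a data frame of half-open genomic intervals in the
#' BED coordinate convention: `start` is 0-based inclusive, `end` is
#' exclusive, so an interval covers bases `start .. end - 1` and must have
#' `end > start`. Columns are `chrom`, `start`, `end` and optional `name`
#' and `score`. A provenance tag (e.g. `"H3K9me2_peaks"`) records what the
#' set represents. Strand is ignored throughout: FAIRE and H3K9me2 signals
#' are unstranded.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors of 0-based half-open coordinates.
#' @param name optional character labels (NA allowed).
#' @param score optional numeric scores (NA allowed).
#' @param provenance single string tagging the set's origin.
#' @param genome optional [genome_dict()]; when supplied every interval must
#'   lie within its chromosome's bounds.
#' @return A data frame of class `interval_set`.
#' @examples
#' interval_set("chr1", c(0L, 500L), c(100L, 900L))
#' @export
interval_set <- function(chrom, start, end, name = NULL, score = NULL,
                         provenance = "", genome = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(start)
  if (length(chrom) == 1 && n > 1) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(end) == n)
  if (n > 0) {
    if (anyNA(start) || anyNA(end)) stop("interval coordinates contain NA")
    if (any(start < 0)) stop("interval start positions must be >= 0")
    bad <- which(end <= start)
    if (length(bad) > 0)
      stop("zero- or negative-length interval(s) at index ",
           paste(utils::head(bad, 5), collapse = ", "),
           " (end must exceed start)")
  }
  x <- data.frame(chrom = as.character(chrom), start = start, end = end,
                  stringsAsFactors = FALSE)
  x$name <- if (is.null(name)) rep(NA_character_, n) else as.character(name)
  x$score <- if (is.null(score)) rep(NA_real_, n) else as.numeric(score)
  class(x) <- c("interval_set", "data.frame")
  attr(x, "provenance") <- provenance
  if (!is.null(genome)) validate_against_genome(x, genome)
  x
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set of %d interval(s)", nrow(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat(sprintf(" [%s]", prov))
  cat("\n")
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Chromosome name/length dictionary
#'
#' Ordered mapping from chromosome name to length in bp. Bounds every
#' window-tiling and random-sampling operation in the package.
#'
#' @param names character vector of unique chromosome names.
#' @param lengths positive integer lengths in bp.
#' @return Named numeric vector of class `genome_dict`.
#' @examples
#' genome_dict(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_dict <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  stopifnot(length(names) == length(lengths))
  if (anyDuplicated(names)) stop("duplicate chromosome names in genome")
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  structure(stats::setNames(lengths, names), class = "genome_dict")
}

#' Read a genome dictionary from a two-column file
#'
#' Accepts two-column `chrom<TAB>length` text as well as the `.fai` index
#' dialect (length is taken from the second column; extra columns ignored).
#'
#' @param path file path.
#' @return A [genome_dict()].
#' @export
read_genome <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("genome file needs at least two columns: ", path)
  genome_dict(tab[[1]], tab[[2]])
}

validate_against_genome <- function(x, genome) {
  unknown <- setdiff(unique(x$chrom), names(genome))
  if (length(unknown) > 0)
    stop("chromosome(s) not in genome: ", paste(unknown, collapse = ", "))
  lim <- unclass(genome)[x$chrom]
  bad <- which(x$end > lim)
  if (length(bad) > 0)
    stop("interval(s) exceed chromosome bounds at index ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(x)
}

# interval_set -> per-chromosome IRanges (1-based closed <-> 0-based
# half-open: start+1 .. end). Used for all repeated overlap queries.
iranges_by_chrom <- function(x) {
  if (nrow(x) == 0) return(list())
  idx <- split(seq_len(nrow(x)), x$chrom)
  lapply(idx, function(i)
    IRanges::IRanges(start = x$start[i] + 1L, end = x$end[i], names = i))
}

#' Test whether two intervals overlap
#'
#' Two half-open intervals overlap iff they are on the same chromosome and
#' share at least 1 bp: `a$start < b$end && b$start < a$end`. This is the
#' primitive behind peak/CGI overlap statistics; no minimum-overlap
#' fraction is applied.
#'
#' @param a,b single-row [interval_set()]s (or lists with `chrom`, `start`,
#'   `end`).
#' @return `TRUE` or `FALSE`.
#' @examples
#' a <- interval_set("chr1", 0, 100)
#' b <- interval_set("chr1", 99, 200)
#' overlaps(a, b)
#' @export
overlaps <- function(a, b) {
  isTRUE(a$chrom[1] == b$chrom[1] &&
           a$start[1] < b$end[1] && b$start[1] < a$end[1])
}

# Vectorised: for each query interval, does it overlap any reference
# interval?
overlaps_any <- function(query, reference) {
  out <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(reference) == 0) return(out)
  qir <- iranges_by_chrom(query)
  rir <- iranges_by_chrom(reference)
  for (chrom in intersect(names(qir), names(rir))) {
    hit <- IRanges::overlapsAny(qir[[chrom]], rir[[chrom]])
    out[as.integer(names(qir[[chrom]]))] <- hit
  }
  out
}

#' Fraction of query intervals overlapping a reference set
#'
#' Each query interval is counted once regardless of how many reference
#' intervals it hits. This is the statistic behind "fraction of nucleation
#' sites overlapping CGIs".
#'
#' @param query,reference [interval_set()]s; `query` must be nonempty.
#' @return Proportion in `[0, 1]`.
#' @export
overlap_fraction <- function(query, reference) {
  if (nrow(query) == 0) stop("overlap fraction undefined for empty query set")
  mean(overlaps_any(query, reference))
}

#' Sample random fixed-length regions from a genome
#'
#' Draws `n` regions of exactly `length` bp, each fully inside a
#' chromosome. Chromosomes are chosen with probability proportional to the
#' number of valid placements (`chrom_length - length + 1`), and start
#' positions uniformly among them, so every valid placement in the genome
#' is equally likely. Draws are independent (two sampled regions may
#' overlap each other). When `exclude` is given, regions overlapping it are
#' rejected and redrawn.
#'
#' @param genome a [genome_dict()]; every chromosome must be at least
#'   `length` bp.
#' @param n number of regions.
#' @param length region length in bp.
#' @param seed integer seed for reproducibility, or `NULL` to use the
#'   current RNG stream.
#' @param exclude optional [interval_set()] that sampled regions must not
#'   overlap.
#' @param max_attempts cap on total draws before rejection sampling gives
#'   up (guards against exclusion sets covering almost all placements).
#' @return An [interval_set()] of `n` regions.
#' @examples
#' g <- genome_dict("chrA", 2000)
#' sample_random_regions(g, n = 5, length = 1000, seed = 7)
#' @export
sample_random_regions <- function(genome, n, length, seed = NULL,
                                  exclude = NULL, max_attempts = 1000 * n) {
  stopifnot(inherits(genome, "genome_dict"), n >= 1, length >= 1)
  lens <- unclass(genome)
  w <- lens - length + 1
  if (any(w < 1))
    stop("chromosome(s) shorter than the requested region length: ",
         paste(names(lens)[w < 1], collapse = ", "))
  with_seed(seed, {
    chrom <- character(0); start <- numeric(0)
    attempts <- 0; need <- n
    while (need > 0) {
      if (attempts >= max_attempts)
        stop("random-region sampling failed: exclusion set too dense (",
             attempts, " attempts for ", n, " regions)")
      batch <- min(need * 2, max_attempts - attempts)
      attempts <- attempts + batch
      ci <- sample.int(length(lens), batch, replace = TRUE, prob = w)
      st <- floor(stats::runif(batch) * w[ci])
      cand <- interval_set(names(lens)[ci], st, st + length)
      keep <- if (is.null(exclude) || nrow(exclude) == 0) rep(TRUE, batch)
              else !overlaps_any(cand, exclude)
      ok <- which(keep)[seq_len(min(need, sum(keep)))]
      chrom <- c(chrom, cand$chrom[ok]); start <- c(start, cand$start[ok])
      need <- n - length(chrom)
    }
    interval_set(chrom, start, start + length, provenance = "random_regions")
  })
}
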