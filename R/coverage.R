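#' Fragment sets
#'
#' A `fragment_set` holds one condition's sequenced paired-end fragments
#' (each the genomic span between a pair's outermost mapped bases) together
#' with the library size. The fragment, not the read, is the counting unit
#' for all coverage computation.
#'
#' @param fragments an [interval_set()] of fragments.
#' @param condition condition label, e.g. `"UNC0638"` or `"DMSO"`.
#' @return A list of class `fragment_set` with elements `condition`,
#'   `fragments` and `library_size`.
#' @export
fragment_set <- function(fragments, condition = "") {
  stopifnot(inherits(fragments, "interval_set"))
  structure(list(condition = condition, fragments = fragments,
                 library_size = nrow(fragments)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set '%s': %d fragments\n", x$condition,
              x$library_size))
  invisible(x)
}

#' Load sequenced fragments from BED or BAM
#'
#' BED input: each line is one fragment; multiple files are pooled
#' (replicate libraries combined), with per-file counts recorded in the
#' `per_file` attribute. BAM input: each properly paired, non-duplicate,
#' primary read pair yields one fragment spanning leftmost to rightmost
#' mapped base; pairs duplicated at identical (chrom, start, end) are
#' collapsed.
#'
#' @param paths one or more BED (or a single BAM) file paths.
#' @param genome [genome_dict()] for bounds validation.
#' @param condition condition label.
#' @return A [fragment_set()].
#' @export
load_fragments <- function(paths, genome = NULL, condition = "") {
  stopifnot(length(paths) >= 1)
  is_bam <- grepl("\\.bam$", paths, ignore.case = TRUE)
  parts <- lapply(seq_along(paths), function(i) {
    if (is_bam[i]) read_bam_fragments(paths[i], genome)
    else read_bed(paths[i], genome = genome)
  })
  counts <- vapply(parts, nrow, 0L)
  if (sum(counts) == 0) stop("no fragments found in input: ",
                             paste(paths, collapse = ", "))
  pooled <- interval_set(
    chrom = unlist(lapply(parts, `[[`, "chrom")),
    start = unlist(lapply(parts, `[[`, "start")),
    end = unlist(lapply(parts, `[[`, "end")),
    provenance = paste0("fragments:", condition))
  fs <- fragment_set(pooled, condition = condition)
  attr(fs, "per_file") <- stats::setNames(counts, paths)
  fs
}

read_bam_fragments <- function(path, genome = NULL) {
  flag <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE, isDuplicate = FALSE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "isize"))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  # keep the leftmost mate of each pair (positive TLEN): the fragment is
  # [pos - 1, pos - 1 + TLEN) in 0-based half-open coordinates.
  keep <- !is.na(b$pos) & !is.na(b$isize) & b$isize > 0
  if (!any(keep)) {
    any_flag <- Rsamtools::ScanBamParam(what = "flag")
    n_any <- length(Rsamtools::scanBam(path, param = any_flag)[[1]]$flag)
    if (n_any > 0)
      stop("no properly paired reads in ", path,
           "; supply fragment BED input instead")
    stop("empty BAM file: ", path)
  }
  chrom <- as.character(b$rname[keep])
  left <- b$pos[keep]
  width <- b$isize[keep]
  key <- paste(chrom, left, width)
  dup <- duplicated(key)
  interval_set(chrom[!dup], left[!dup] - 1, left[!dup] - 1 + width[!dup],
               provenance = basename(path), genome = genome)
}

# number of full windows of `window` bp at `step` bp increments on a
# chromosome: floor((len - window)/step) + 1; truncated windows dropped.
window_starts <- function(len, window, step) {
  if (len < window) return(numeric(0))
  seq(0, len - window, by = step)
}

#' Count fragments in sliding windows
#'
#' Tiles each chromosome with `window`-bp windows at `step`-bp increments
#' (windows truncated at chromosome ends are dropped so window length is
#' constant) and counts the fragments overlapping each window by at least
#' 1 bp. A fragment may increment many windows.
#'
#' @param frags a [fragment_set()].
#' @param window window size in bp.
#' @param step step in bp (`1 <= step <= window`).
#' @param genome a [genome_dict()].
#' @return A `coverage_track`: list with `window`, `step`, `normalized`,
#'   `library_size` and `values` (per-chromosome numeric vectors of window
#'   counts, window i covering `(i-1)*step .. (i-1)*step + window`).
#' @export
count_in_windows <- function(frags, window, step, genome) {
  stopifnot(inherits(frags, "fragment_set"), window >= 1, step >= 1,
            step <= window)
  fir <- iranges_by_chrom(frags$fragments)
  values <- lapply(stats::setNames(nm = names(genome)), function(chrom) {
    starts <- window_starts(unclass(genome)[[chrom]], window, step)
    if (length(starts) == 0) return(numeric(0))
    wins <- IRanges::IRanges(start = starts + 1, width = window)
    if (is.null(fir[[chrom]])) return(numeric(length(starts)))
    as.numeric(IRanges::countOverlaps(wins, fir[[chrom]]))
  })
  structure(list(window = window, step = step, normalized = FALSE,
                 library_size = frags$library_size, values = values),
            class = "coverage_track")
}

#' Count fragments overlapping each region
#'
#' Per-region fragment-overlap counts (at least 1 bp shared, half-open
#' convention), order-aligned with the input regions.
#'
#' @param frags a [fragment_set()].
#' @param regions a nonempty [interval_set()].
#' @return Numeric vector of counts, one per region.
#' @export
count_in_regions <- function(frags, regions) {
  stopifnot(inherits(frags, "fragment_set"))
  if (nrow(regions) == 0) stop("empty region set")
  count_in_regions_indexed(iranges_by_chrom(frags$fragments), regions)
}

# workhorse taking a prebuilt per-chromosome fragment index, so repeated
# resampling draws do not rebuild interval trees.
count_in_regions_indexed <- function(frag_index, regions) {
  out <- numeric(nrow(regions))
  qir <- iranges_by_chrom(regions)
  for (chrom in intersect(names(qir), names(frag_index))) {
    n <- IRanges::countOverlaps(qir[[chrom]], frag_index[[chrom]])
    out[as.integer(names(qir[[chrom]]))] <- n
  }
  out
}

#' Library-size normalization to fragments per million
#'
#' @param x a `coverage_track` or a numeric vector of counts.
#' @param library_size total fragment count of the library (taken from the
#'   track when omitted).
#' @return Same shape as `x`, scaled by `1e6 / library_size`.
#' @export
normalize_per_million <- function(x, library_size = NULL) {
  if (inherits(x, "coverage_track")) {
    library_size <- library_size %||% x$library_size
    if (is.null(library_size) || library_size <= 0)
      stop("library size must be positive")
    x$values <- lapply(x$values, function(v) v * 1e6 / library_size)
    x$normalized <- TRUE
    return(x)
  }
  if (is.null(library_size) || library_size <= 0)
    stop("library size must be positive")
  x * 1e6 / library_size
}

#' Write a coverage track as fixedStep wiggle or bedGraph
#'
#' FixedStep wiggle requires non-overlapping windows (`step == window`);
#' overlapping windows must be written as bedGraph. Chromosomes with no
#' windows emit no block. Values round-trip exactly through
#' [read_track()].
#'
#' @param track a `coverage_track` from [count_in_windows()].
#' @param path output file path.
#' @param format `"wiggle"` (fixedStep) or `"bedGraph"`.
#' @return Invisibly, `path`.
#' @export
write_track <- function(track, path, format = c("wiggle", "bedGraph")) {
  format <- match.arg(format)
  stopifnot(inherits(track, "coverage_track"))
  if (format == "wiggle" && track$step != track$window)
    stop("overlapping windows (step < window) cannot be written as ",
         "fixedStep wiggle; use format = 'bedGraph'")
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (length(v) == 0) next
    val <- format(v, trim = TRUE, digits = 15, scientific = FALSE)
    if (format == "wiggle") {
      writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                         chrom, track$step, track$window), con)
      writeLines(val, con)
    } else {
      starts <- (seq_along(v) - 1) * track$step
      writeLines(sprintf("%s\t%s\t%s\t%s", chrom, format_coord(starts),
                         format_coord(starts + track$window), val), con)
    }
  }
  invisible(path)
}

#' Read a coverage track written by [write_track()]
#'
#' @param path fixedStep wiggle or bedGraph file.
#' @param format track format.
#' @param window window size (required for bedGraph, where only interval
#'   bounds are stored; inferred from the header for wiggle).
#' @return A `coverage_track`.
#' @export
read_track <- function(path, format = c("wiggle", "bedGraph"),
                       window = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "wiggle") {
    hdr <- grep("^fixedStep", lines)
    if (length(hdr) == 0) stop("no fixedStep header in ", path)
    values <- list(); step <- NA; win <- NA
    bounds <- c(hdr, length(lines) + 1)
    for (i in seq_along(hdr)) {
      h <- lines[hdr[i]]
      chrom <- sub(".*chrom=(\\S+).*", "\\1", h)
      step <- as.integer(sub(".*step=(\\d+).*", "\\1", h))
      win <- as.integer(sub(".*span=(\\d+).*", "\\1", h))
      body <- lines[seq(hdr[i] + 1, bounds[i + 1] - 1)]
      values[[chrom]] <- as.numeric(body)
    }
    return(structure(list(window = win, step = step, normalized = NA,
                          library_size = NULL, values = values),
                     class = "coverage_track"))
  }
  f <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  chrom <- vapply(f, `[[`, "", 1)
  start <- as.numeric(vapply(f, `[[`, "", 2))
  end <- as.numeric(vapply(f, `[[`, "", 3))
  val <- as.numeric(vapply(f, `[[`, "", 4))
  win <- window %||% (end[1] - start[1])
  idx <- split(seq_along(chrom), chrom)
  step <- if (length(start) > 1 && length(idx[[1]]) > 1)
    start[idx[[1]][2]] - start[idx[[1]][1]] else win
  values <- lapply(idx, function(i) val[i][order(start[i])])
  structure(list(window = win, step = step, normalized = NA,
                 library_size = NULL, values = values),
            class = "coverage_track")
}
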