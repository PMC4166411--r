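#' Read a BED file into an interval set
#'
#' Parses BED3/BED6 (tab-separated, 0-based half-open). `track`, `browser`,
#' `#` comment and blank lines are skipped. Malformed lines (fewer than 3
#' fields, non-integer coordinates, `end <= start`) raise an error naming
#' the offending line; intervals exceeding chromosome bounds when a genome
#' is supplied are an error, never silently clipped.
#'
#' @param path BED file path.
#' @param genome optional [genome_dict()] used to validate chromosome names
#'   and bounds.
#' @param provenance provenance tag for the returned set (defaults to the
#'   file name).
#' @return An [interval_set()] in file order.
#' @export
read_bed <- function(path, genome = NULL, provenance = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(interval_set(character(0), numeric(0), numeric(0),
                        provenance = provenance, genome = genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED line ", lineno[which(nf < 3)[1]], " has fewer than 3 fields: ",
         path)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad) > 0)
    stop("non-integer coordinates on BED line ", lineno[bad[1]], ": ", path)
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0)
    stop("invalid interval (end <= start or start < 0) on BED line ",
         lineno[bad[1]], ": ", path)
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""),
                 NA_character_)
  name[name == "."] <- NA_character_
  score <- suppressWarnings(as.numeric(
    ifelse(nf >= 5, vapply(fields, function(f) f[min(5, length(f))], ""),
           NA_character_)))
  interval_set(chrom, start, end, name = name, score = score,
               provenance = provenance, genome = genome)
}

#' Write an interval set as BED
#'
#' Emits tab-separated 0-based half-open BED. Name and score columns are
#' written only when any value is present (`.`/`0` placeholders otherwise),
#' so that `read_bed(write_bed(x))` reproduces coordinates, names and
#' scores exactly. An empty set yields an empty file.
#'
#' @param x an [interval_set()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "interval_set"))
  if (nrow(x) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  cols <- list(x$chrom, format_coord(x$start), format_coord(x$end))
  has_name <- !all(is.na(x$name))
  has_score <- !all(is.na(x$score))
  if (has_name || has_score)
    cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name)))
  if (has_score)
    cols <- c(cols, list(ifelse(is.na(x$score), "0",
                                format(x$score, trim = TRUE, digits = 15,
                                       scientific = FALSE))))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_coord <- function(x) format(x, trim = TRUE, scientific = FALSE)
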