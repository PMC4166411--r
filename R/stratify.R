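#' Read a methylation probe table
#'
#' Tab-delimited `chrom`, `position` (0-based bp), `beta` (in \[0, 1\]),
#' with or without a header line.
#'
#' @param path file path.
#' @return Data frame with columns `chrom`, `position`, `beta`.
#' @export
read_probes <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("[A-Za-z]", strsplit(first, "\t")[[1]][2])
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE)
  tab <- stats::setNames(tab[, 1:3], c("chrom", "position", "beta"))
  if (any(tab$beta < 0 | tab$beta > 1))
    stop("beta values outside [0, 1] in ", path)
  if (any(tab$position < 0)) stop("negative probe positions in ", path)
  tab
}

#' Partition peaks by CGI overlap
#'
#' Splits a peak set into those overlapping (by at least 1 bp) any CGI and
#' those not, and reports the overlapping fraction — the "fraction of
#' nucleation sites overlapping CGIs" statistic.
#'
#' @param peaks a nonempty [interval_set()].
#' @param cgis an [interval_set()] (may be empty).
#' @return List with `overlapping`, `non_overlapping` (interval sets) and
#'   `fraction`.
#' @export
split_by_overlap <- function(peaks, cgis) {
  if (nrow(peaks) == 0) stop("empty peak set")
  hit <- overlaps_any(peaks, cgis)
  sub <- function(i, tag) {
    s <- peaks[i, , drop = FALSE]
    class(s) <- c("interval_set", "data.frame")
    attr(s, "provenance") <- tag
    rownames(s) <- NULL
    s
  }
  list(overlapping = sub(hit, "peaks_cgi_overlap"),
       non_overlapping = sub(!hit, "peaks_no_cgi_overlap"),
       fraction = mean(hit))
}

new_cgi_records <- function(cgis) {
  data.frame(chrom = cgis$chrom, start = cgis$start, end = cgis$end,
             name = if (all(is.na(cgis$name)))
               paste0("CGI_", seq_len(nrow(cgis))) else cgis$name,
             promoter_status = "unassigned",
             evo_class = "unlabeled",
             meth_state = "no_data",
             mean_beta = NA_real_, n_probes = 0L,
             stringsAsFactors = FALSE)
}

as_interval_set <- function(records, provenance = "CGI") {
  interval_set(records$chrom, records$start, records$end,
               name = records$name, provenance = provenance)
}

#' Label CGIs as promoter-associated or orphan
#'
#' A CGI is promoter-associated iff it overlaps any TSS point expanded by
#' `promoter_flank` bp on each side; otherwise it is an orphan CGI
#' (inter-/intragenic, not associated with an annotated start site).
#'
#' @param cgis an [interval_set()] of CGIs (or a CGI record table from
#'   another labelling step).
#' @param tss an [interval_set()] of TSS positions (1-bp points or gene
#'   starts).
#' @param promoter_flank expansion in bp around each TSS (default 1000).
#' @return CGI record data frame with `promoter_status` set to
#'   `"promoter"` or `"orphan"`.
#' @export
assign_promoter_status <- function(cgis, tss, promoter_flank = 1000) {
  records <- if (is.data.frame(cgis) && "promoter_status" %in% names(cgis))
    cgis else new_cgi_records(cgis)
  iv <- as_interval_set(records)
  expanded <- interval_set(tss$chrom, pmax(0, tss$start - promoter_flank),
                           tss$end + promoter_flank)
  records$promoter_status <-
    ifelse(overlaps_any(iv, expanded), "promoter", "orphan")
  records
}

#' Classify CGI methylation state from probe beta values
#'
#' Aggregates probes falling inside each CGI (unweighted mean beta) and
#' applies the strict thresholds: methylated when mean beta > `t_meth`,
#' unmethylated when mean beta < `t_unmeth`, otherwise indeterminate
#' (boundary values fall into indeterminate). CGIs with fewer than
#' `min_probes` probes get `no_data`.
#'
#' @inheritParams assign_promoter_status
#' @param probes probe data frame from [read_probes()].
#' @param t_meth methylated threshold (default 0.75).
#' @param t_unmeth unmethylated threshold (default 0.25).
#' @param min_probes minimum probe count per CGI (default 3).
#' @return CGI record data frame with `meth_state`, `mean_beta`,
#'   `n_probes` filled in.
#' @export
classify_methylation <- function(cgis, probes, t_meth = 0.75,
                                 t_unmeth = 0.25, min_probes = 3) {
  stopifnot(t_unmeth >= 0, t_meth <= 1, t_unmeth < t_meth)
  records <- if (is.data.frame(cgis) && "meth_state" %in% names(cgis))
    cgis else new_cgi_records(cgis)
  iv <- as_interval_set(records)
  cir <- iranges_by_chrom(iv)
  n <- integer(nrow(records)); s <- numeric(nrow(records))
  pidx <- split(seq_len(nrow(probes)), probes$chrom)
  for (chrom in intersect(names(cir), names(pidx))) {
    pi <- pidx[[chrom]]
    pir <- IRanges::IRanges(start = probes$position[pi] + 1L, width = 1L)
    hits <- IRanges::findOverlaps(cir[[chrom]], pir)
    ci <- as.integer(names(cir[[chrom]]))[S4Vectors::queryHits(hits)]
    beta <- probes$beta[pi][S4Vectors::subjectHits(hits)]
    agg_n <- tapply(beta, ci, length)
    agg_s <- tapply(beta, ci, sum)
    at <- as.integer(names(agg_n))
    n[at] <- n[at] + as.integer(agg_n)
    s[at] <- s[at] + as.numeric(agg_s)
  }
  records$n_probes <- n
  records$mean_beta <- ifelse(n > 0, s / n, NA_real_)
  records$meth_state <- meth_state_from_beta(records$mean_beta, n,
                                             t_meth, t_unmeth, min_probes)
  attr(records, "thresholds") <- c(t_meth = t_meth, t_unmeth = t_unmeth,
                                   min_probes = min_probes)
  records
}

meth_state_from_beta <- function(mean_beta, n_probes, t_meth = 0.75,
                                 t_unmeth = 0.25, min_probes = 3) {
  state <- rep("indeterminate", length(mean_beta))
  state[!is.na(mean_beta) & mean_beta > t_meth] <- "methylated"
  state[!is.na(mean_beta) & mean_beta < t_unmeth] <- "unmethylated"
  state[is.na(mean_beta) | n_probes < min_probes] <- "no_data"
  state
}

#' Attach evolutionary class labels to CGIs
#'
#' Labels each CGI by the unique pre-computed evolutionary class
#' (`low_deamination`: low C-to-T deamination, mostly unmethylated;
#' `gc_gain`: rapid G/C gain, mostly methylated; `under_selection`) whose
#' intervals it overlaps. Class interval sets must be mutually disjoint; a
#' CGI overlapping two classes indicates malformed input and is an error.
#'
#' @inheritParams assign_promoter_status
#' @param labeled_classes named list of [interval_set()]s, one per class.
#' @return CGI record data frame with `evo_class` set (or `"unlabeled"`).
#' @export
attach_evo_class <- function(cgis, labeled_classes) {
  stopifnot(is.list(labeled_classes), !is.null(names(labeled_classes)))
  cls <- names(labeled_classes)
  for (i in seq_along(cls)) for (j in seq_len(i - 1)) {
    a <- labeled_classes[[i]]; b <- labeled_classes[[j]]
    if (nrow(a) > 0 && nrow(b) > 0 && any(overlaps_any(a, b)))
      stop("evolutionary class interval sets overlap: ", cls[j], " vs ",
           cls[i])
  }
  records <- if (is.data.frame(cgis) && "evo_class" %in% names(cgis))
    cgis else new_cgi_records(cgis)
  iv <- as_interval_set(records)
  hit <- vapply(labeled_classes, function(s) overlaps_any(iv, s),
                logical(nrow(records)))
  hit <- matrix(hit, nrow = nrow(records))
  multi <- rowSums(hit) > 1
  if (any(multi))
    stop("CGI(s) overlapping more than one evolutionary class: ",
         paste(utils::head(records$name[multi], 5), collapse = ", "))
  records$evo_class <- "unlabeled"
  for (k in seq_along(cls)) records$evo_class[hit[, k]] <- cls[k]
  records
}

#' Stratified fold-change report
#'
#' Computes per-CGI fold changes (treatment/control) and summarizes them
#' within each stratum of the labelling margins (methylation state,
#' promoter status, evolutionary class), with pairwise rank-sum tests
#' between strata within each margin. Strata with fewer than `min_n`
#' regions are excluded from tests (with a warning). CGIs in classes named
#' in `drop_class` (by default those under selection, removed from the
#' evolutionary comparison for interpretability) are dropped from the
#' `evo_class` margin.
#'
#' @param records CGI record data frame carrying the labels.
#' @inheritParams fold_changes
#' @param stratify_by label columns to report margins for.
#' @param drop_class evolutionary classes to drop from the `evo_class`
#'   margin.
#' @param min_n minimum stratum size entering tests.
#' @return List of class `stratified_report`: `signals` (per-CGI fold
#'   changes with labels), `summaries` (per-stratum n/median/quartiles),
#'   `tests` (pairwise rank-sum p-values).
#' @export
stratified_fold_change_report <- function(records, frags_a, frags_b,
                                          pseudocount = 1,
                                          stratify_by = c("meth_state",
                                                          "promoter_status",
                                                          "evo_class"),
                                          drop_class = "under_selection",
                                          min_n = 2) {
  stopifnot(all(stratify_by %in% names(records)))
  iv <- as_interval_set(records)
  fc <- fold_changes(iv, frags_a, frags_b, pseudocount = pseudocount)
  signals <- cbind(records, fc[, c("count_a", "count_b", "signal_a",
                                   "signal_b", "fold_change",
                                   "log2_fold_change")])
  summaries <- list(); tests <- list()
  for (margin in stratify_by) {
    lab <- signals[[margin]]
    keep <- rep(TRUE, nrow(signals))
    if (margin == "evo_class" && length(drop_class) > 0)
      keep <- !(lab %in% drop_class)
    groups <- split(signals$fold_change[keep], lab[keep])
    groups <- groups[lengths(groups) > 0]
    if (length(groups) == 0) next
    q <- lapply(groups, stats::quantile, probs = c(0.25, 0.5, 0.75))
    summaries[[margin]] <- data.frame(
      margin = margin, stratum = names(groups),
      n = as.integer(lengths(groups)),
      q1 = vapply(q, `[[`, 0, 1), median = vapply(q, `[[`, 0, 2),
      q3 = vapply(q, `[[`, 0, 3),
      row.names = NULL, stringsAsFactors = FALSE)
    testable <- names(groups)[lengths(groups) >= min_n]
    if (length(testable) < length(groups))
      warning("stratum(s) with n < ", min_n, " excluded from tests in ",
              margin, " margin")
    if (length(testable) >= 2) {
      pairs <- utils::combn(testable, 2)
      tests[[margin]] <- data.frame(
        margin = margin, stratum_1 = pairs[1, ], stratum_2 = pairs[2, ],
        n_1 = lengths(groups)[pairs[1, ]], n_2 = lengths(groups)[pairs[2, ]],
        p_value = apply(pairs, 2, function(pr)
          rank_sum_test(groups[[pr[1]]], groups[[pr[2]]])$p.value),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  structure(list(signals = signals,
                 summaries = do.call(rbind, unname(summaries)),
                 tests = if (length(tests) > 0)
                   do.call(rbind, unname(tests)) else NULL),
            class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  cat("stratified fold-change report\n")
  if (!is.null(x$summaries)) print.data.frame(x$summaries, digits = 4)
  if (!is.null(x$tests)) {
    cat("pairwise rank-sum tests:\n")
    print.data.frame(x$tests, digits = 4)
  }
  invisible(x)
}
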