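#' Configuration for the synthetic epigenomics dataset
#'
#' Parameters of the generator that emulates the study design: a small
#' genome with embedded CGI-like islands of elevated GC and CpG
#' observed/expected ratio, TSS annotation for a promoter-associated
#' subset, bimodal methylation probe betas, H3K9me2 peaks placed
#' preferentially at unmethylated islands, and paired-condition FAIRE
#' fragment sets in which accessibility at peak sites is depressed in the
#' control and recovers under treatment by a factor `f_u` at unmethylated
#' sites and `f_m` at methylated sites (`f_u >= f_m >= 1`).
#'
#' @param seed integer RNG seed; generation is fully deterministic given
#'   the seed.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param background_freqs base frequencies (A, C, G, T) of the background
#'   sequence.
#' @param background_cpg_score CpG observed/expected target of the
#'   background (genomes are CpG-depleted).
#' @param n_cgi number of islands.
#' @param island_length_range island length range (bp).
#' @param island_gc,island_cpg_score island GC-fraction and CpG
#'   observed/expected targets.
#' @param frac_promoter fraction of islands given an adjacent TSS.
#' @param frac_methylated fraction of islands assigned the methylated
#'   state.
#' @param beta_modes means of the low/high methylation beta modes.
#' @param beta_concentration concentration of each beta mode
#'   (shape1 + shape2).
#' @param probe_spacing methylation probe spacing within islands (bp).
#' @param p_peak_unmeth,p_peak_meth probability that an
#'   unmethylated/methylated island carries an H3K9me2 peak.
#' @param n_noncgi_peaks number of peaks placed away from any island
#'   (CGI-like non-CGI nucleation sites; they respond like unmethylated
#'   sites).
#' @param peak_width_range peak width range (bp).
#' @param p_evo_unmeth,p_evo_meth probabilities of the evolutionary
#'   classes (low_deamination, gc_gain, under_selection) conditional on
#'   methylation state.
#' @param depression accessibility factor at peak sites in the control
#'   (relative to baseline 1).
#' @param f_u,f_m treatment recovery factors at unmethylated and
#'   methylated sites.
#' @param fragment_length_mean,fragment_length_sd,fragment_length_min
#'   fragment length distribution (truncated normal, bp).
#' @param library_size named vector of fragment counts per condition
#'   (treatment first).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                             background_freqs = c(A = 0.3, C = 0.2,
                                                  G = 0.2, T = 0.3),
                             background_cpg_score = 0.25,
                             n_cgi = 300,
                             island_length_range = c(500, 1500),
                             island_gc = 0.65,
                             island_cpg_score = 0.8,
                             frac_promoter = 0.5,
                             frac_methylated = 0.3,
                             beta_modes = c(low = 0.1, high = 0.9),
                             beta_concentration = 10,
                             probe_spacing = 100,
                             p_peak_unmeth = 0.8,
                             p_peak_meth = 0.5,
                             n_noncgi_peaks = 40,
                             peak_width_range = c(500, 2000),
                             p_evo_unmeth = c(low_deamination = 0.85,
                                              gc_gain = 0.10,
                                              under_selection = 0.05),
                             p_evo_meth = c(low_deamination = 0.10,
                                            gc_gain = 0.85,
                                            under_selection = 0.05),
                             depression = 0.2,
                             f_u = 5,
                             f_m = 1.5,
                             fragment_length_mean = 150,
                             fragment_length_sd = 30,
                             fragment_length_min = 50,
                             library_size = c(UNC0638 = 2e5, DMSO = 2e5)) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_config <- function(cfg) {
  probs <- c(cfg$frac_promoter, cfg$frac_methylated, cfg$p_peak_unmeth,
             cfg$p_peak_meth, cfg$background_freqs, cfg$p_evo_unmeth,
             cfg$p_evo_meth)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!(cfg$f_u >= cfg$f_m && cfg$f_m >= 1))
    stop("recovery factors must satisfy f_u >= f_m >= 1")
  if (cfg$depression <= 0 || cfg$depression > 1)
    stop("depression must lie in (0, 1]")
  if (any(c(cfg$n_cgi, cfg$library_size, cfg$chrom_lengths) <= 0) ||
      cfg$n_noncgi_peaks < 0)
    stop("counts and lengths must be positive")
  margin <- island_margin(cfg)
  need <- cfg$n_cgi * (max(cfg$island_length_range) + 2 * margin)
  if (need > 0.7 * sum(cfg$chrom_lengths))
    stop("unsatisfiable config: islands (plus spacing) exceed the genome")
  if (any(cfg$chrom_lengths < max(cfg$island_length_range) + 2 * margin))
    stop("unsatisfiable config: chromosome shorter than an island plus margin")
  invisible(cfg)
}

# clearance so that effect regions (peak/island union padded by one mean
# fragment length) of distinct sites never overlap.
island_margin <- function(cfg) {
  max(cfg$peak_width_range) / 2 + cfg$fragment_length_mean + 500
}

# Solve first-order Markov chain parameters (base frequencies and the
# transition row out of C) so the stationary sequence hits a target GC
# fraction and CpG observed/expected ratio.
solve_cpg_markov <- function(gc_target, cpg_target,
                             at_skew = c(0.5, 0.5)) {
  pC <- pG <- gc_target / 2
  for (iter in 1:40) {
    pA <- (1 - pC - pG) * at_skew[1]
    pT <- (1 - pC - pG) * at_skew[2]
    freqs <- c(pA, pC, pG, pT)
    score_of <- function(beta) {
      st <- markov_stationary(freqs, from_c_row(freqs, beta))
      beta / st[3] - cpg_target
    }
    hi <- min(0.999, 3 * pG)
    beta <- if (score_of(hi) < 0) hi else
      stats::uniroot(score_of, c(1e-6, hi), tol = 1e-10)$root
    st <- markov_stationary(freqs, from_c_row(freqs, beta))
    gc_real <- st[2] + st[3]
    if (abs(gc_real - gc_target) < 1e-6) break
    adj <- gc_target / gc_real
    pC <- min(0.49, pC * adj); pG <- min(0.49, pG * adj)
  }
  list(freqs = freqs, from_c = from_c_row(freqs, beta))
}

from_c_row <- function(freqs, beta) {
  pG <- freqs[3]
  row <- freqs * (1 - beta) / (1 - pG)
  row[3] <- beta
  row
}

markov_stationary <- function(freqs, from_c) {
  M <- matrix(rep(freqs, 4), nrow = 4, byrow = TRUE)
  M[2, ] <- from_c
  pi <- freqs
  for (i in 1:200) pi <- as.numeric(pi %*% M)
  pi / sum(pi)
}

BASE_CODES <- c(65L, 67L, 71L, 84L)  # A C G T

#' Generate a synthetic dataset
#'
#' Builds the complete toy dataset in memory: genome sequence, CGI
#' annotation with promoter/evolutionary/methylation labels, TSS, probe
#' table, H3K9me2 peaks and paired-condition fragment sets, plus a
#' ground-truth table for parameter-recovery tests. Fragments are placed
#' by a midpoint rate that is `baseline x depression` over each nucleation
#' site in the control and additionally `x f_u` (unmethylated) or `x f_m`
#' (methylated) in the treatment; the altered-rate span is the
#' island/peak union padded by one mean fragment length so that overlap
#' counting over the island sees the configured ratio. Exact library
#' sizes are achieved by sampling fragments to count. Fully deterministic
#' given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_dataset` with elements `genome`,
#'   `sequences`, `cgi`, `cgi_labels`, `tss`, `probes`, `peaks`,
#'   `fragments` (list of two [fragment_set()]s), `truth`, `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  genome <- genome_dict(names(cfg$chrom_lengths), cfg$chrom_lengths)
  with_seed(cfg$seed, {
    margin <- island_margin(cfg)
    gap <- 2 * margin

    ## island placement: mutually non-overlapping with clearance
    isl <- place_regions(cfg$chrom_lengths, cfg$n_cgi,
                         cfg$island_length_range, margin, gap)
    n_isl <- nrow(isl)

    ## labels
    meth <- ifelse(stats::runif(n_isl) < cfg$frac_methylated,
                   "methylated", "unmethylated")
    promoter <- ifelse(stats::runif(n_isl) < cfg$frac_promoter,
                       "promoter", "orphan")
    evo <- vapply(meth, function(m) {
      p <- if (m == "methylated") cfg$p_evo_meth else cfg$p_evo_unmeth
      sample(names(p), 1, prob = p)
    }, "")

    ## sequence
    bg <- solve_cpg_markov(sum(cfg$background_freqs[c("C", "G")]),
                           cfg$background_cpg_score,
                           at_skew = prop.table(
                             cfg$background_freqs[c("A", "T")]))
    isl_par <- solve_cpg_markov(cfg$island_gc, cfg$island_cpg_score)
    sequences <- character(0)
    for (chrom in names(genome)) {
      len <- unclass(genome)[[chrom]]
      codes <- markov_sequence(len, bg$freqs, bg$from_c)
      here <- which(isl$chrom == chrom)
      for (i in here) {
        w <- isl$end[i] - isl$start[i]
        codes[(isl$start[i] + 1):isl$end[i]] <-
          markov_sequence(w, isl_par$freqs, isl_par$from_c)
      }
      sequences[[chrom]] <- intToUtf8(BASE_CODES[codes])
    }

    ## TSS at promoter-island starts
    ptss <- which(promoter == "promoter")
    tss <- interval_set(isl$chrom[ptss], isl$start[ptss],
                        isl$start[ptss] + 1,
                        name = paste0("TSS_", seq_along(ptss)),
                        provenance = "TSS")

    ## methylation probes: bimodal betas by island state
    modes <- cfg$beta_modes; conc <- cfg$beta_concentration
    probes <- do.call(rbind, lapply(seq_len(n_isl), function(i) {
      pos <- seq(isl$start[i], isl$end[i] - 1, by = cfg$probe_spacing)
      mu <- if (meth[i] == "methylated") modes[["high"]] else modes[["low"]]
      data.frame(chrom = isl$chrom[i], position = pos,
                 beta = stats::rbeta(length(pos), mu * conc,
                                     (1 - mu) * conc),
                 stringsAsFactors = FALSE)
    }))

    ## H3K9me2 peaks: on islands by conditional probability, plus
    ## CGI-like non-CGI sites
    p_peak <- ifelse(meth == "methylated", cfg$p_peak_meth,
                     cfg$p_peak_unmeth)
    has_peak <- stats::runif(n_isl) < p_peak
    pw <- function(n) floor(stats::runif(n, cfg$peak_width_range[1],
                                         cfg$peak_width_range[2] + 1))
    mid <- floor((isl$start + isl$end) / 2)
    w <- pw(n_isl)
    pk_start <- pmax(0, mid - w %/% 2)
    pk_end <- pmin(unclass(genome)[isl$chrom], pk_start + w)
    site <- data.frame(
      chrom = isl$chrom, start = isl$start, end = isl$end,
      peak_start = pk_start, peak_end = pk_end,
      is_cgi = TRUE, promoter_status = promoter, evo_class = evo,
      meth_state = meth, has_peak = has_peak, stringsAsFactors = FALSE)
    if (cfg$n_noncgi_peaks > 0) {
      exclude_pad <- interval_set(isl$chrom, pmax(0, isl$start - gap),
                                  isl$end + gap)
      nc <- place_regions(cfg$chrom_lengths, cfg$n_noncgi_peaks,
                          cfg$peak_width_range, margin, gap,
                          exclude = exclude_pad)
      site <- rbind(site, data.frame(
        chrom = nc$chrom, start = nc$start, end = nc$end,
        peak_start = nc$start, peak_end = nc$end,
        is_cgi = FALSE, promoter_status = "unassigned",
        evo_class = "unlabeled", meth_state = "unmethylated",
        has_peak = TRUE, stringsAsFactors = FALSE))
    }
    site$name <- ifelse(site$is_cgi,
                        paste0("CGI_", cumsum(site$is_cgi)),
                        paste0("site_", seq_len(nrow(site))))
    f <- ifelse(site$meth_state == "methylated", cfg$f_m, cfg$f_u)
    site$true_ratio <- ifelse(site$has_peak, f, 1)

    ## fragment placement by midpoint rate over padded effect regions
    pad <- cfg$fragment_length_mean
    eff <- site[site$has_peak, , drop = FALSE]
    eff_start <- pmax(0, pmin(eff$start, eff$peak_start) - pad)
    eff_end <- pmin(unclass(genome)[eff$chrom],
                    pmax(eff$end, eff$peak_end) + pad)
    rate_treat <- cfg$depression * eff$true_ratio
    # With libraries sequenced to the same depth, extra fragments
    # recovered at nucleation sites must come out of the background:
    # lower the treatment background rate so total rate mass matches the
    # control and the per-million ratio at each site equals its
    # configured recovery factor exactly.
    eff_len <- eff_end - eff_start
    bg_len <- sum(cfg$chrom_lengths) - sum(eff_len)
    bg_treat <- 1 - cfg$depression *
      sum((eff$true_ratio - 1) * eff_len) / bg_len
    if (bg_treat <= 0)
      stop("unsatisfiable config: site recovery exceeds library capacity")
    frags <- list()
    for (cond in names(cfg$library_size)) {
      treatment <- cond == names(cfg$library_size)[1]
      frags[[cond]] <- sample_fragments(
        genome, eff$chrom, eff_start, eff_end,
        eff_rate = if (treatment) rate_treat
                   else rep(cfg$depression, nrow(eff)),
        bg_rate = if (treatment) bg_treat else 1,
        n = cfg$library_size[[cond]],
        len_mean = cfg$fragment_length_mean,
        len_sd = cfg$fragment_length_sd,
        len_min = cfg$fragment_length_min, condition = cond)
    }

    cgi_rows <- site$is_cgi
    truth <- data.frame(
      chrom = site$chrom, start = site$start, end = site$end,
      name = site$name, is_cgi = site$is_cgi,
      promoter_status = site$promoter_status,
      evo_class = site$evo_class, meth_state = site$meth_state,
      has_peak = site$has_peak, true_ratio = site$true_ratio,
      stringsAsFactors = FALSE)
    peaks <- interval_set(site$chrom[site$has_peak],
                          site$peak_start[site$has_peak],
                          site$peak_end[site$has_peak],
                          name = site$name[site$has_peak],
                          provenance = "H3K9me2_peaks")
    structure(list(
      genome = genome, sequences = sequences,
      cgi = interval_set(site$chrom[cgi_rows], site$start[cgi_rows],
                         site$end[cgi_rows], name = site$name[cgi_rows],
                         provenance = "CGI"),
      cgi_labels = truth[cgi_rows, c("name", "promoter_status",
                                     "evo_class", "meth_state")],
      tss = tss, probes = probes, peaks = peaks, fragments = frags,
      truth = truth, config = cfg), class = "synthetic_dataset")
  })
}

# place n mutually non-overlapping regions with `margin` clearance from
# chromosome ends and `gap` clearance from each other (and from
# `exclude`), lengths uniform in len_range. Chromosomes weighted by
# length.
place_regions <- function(chrom_lengths, n, len_range, margin, gap,
                          exclude = NULL, max_attempts = 200 * n) {
  placed <- interval_set(character(0), numeric(0), numeric(0))
  attempts <- 0
  while (nrow(placed) < n) {
    if (attempts >= max_attempts)
      stop("could not place ", n, " regions after ", attempts,
           " attempts; genome too crowded")
    attempts <- attempts + 1
    len <- floor(stats::runif(1, len_range[1], len_range[2] + 1))
    ci <- sample.int(length(chrom_lengths), 1, prob = chrom_lengths)
    chrom <- names(chrom_lengths)[ci]
    lo <- margin
    hi <- chrom_lengths[[ci]] - margin - len
    if (hi <= lo) next
    st <- floor(stats::runif(1, lo, hi))
    cand <- interval_set(chrom, max(0, st - gap), st + len + gap)
    if (nrow(placed) > 0 && any(overlaps_any(cand, placed))) next
    if (!is.null(exclude) && any(overlaps_any(cand, exclude))) next
    add <- interval_set(chrom, st, st + len)
    placed <- interval_set(c(placed$chrom, chrom), c(placed$start, st),
                           c(placed$end, st + len))
  }
  ord <- order(placed$chrom, placed$start)
  interval_set(placed$chrom[ord], placed$start[ord], placed$end[ord])
}

# draw exactly n fragments whose midpoints follow a piecewise-constant
# rate: 1 everywhere except the given effect regions.
sample_fragments <- function(genome, eff_chrom, eff_start, eff_end,
                             eff_rate, n, len_mean, len_sd, len_min,
                             condition, bg_rate = 1) {
  seg <- list()
  for (chrom in names(genome)) {
    len <- unclass(genome)[[chrom]]
    i <- which(eff_chrom == chrom)
    bp <- sort(unique(c(0, eff_start[i], eff_end[i], len)))
    st <- bp[-length(bp)]; en <- bp[-1]
    rate <- rep(bg_rate, length(st))
    for (k in seq_along(i)) {
      inside <- st >= eff_start[i[k]] & en <= eff_end[i[k]]
      rate[inside] <- eff_rate[i[k]]
    }
    seg[[chrom]] <- data.frame(chrom = chrom, start = st, end = en,
                               rate = rate, stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, seg)
  w <- seg$rate * (seg$end - seg$start)
  pick <- sample.int(nrow(seg), n, replace = TRUE, prob = w)
  mid <- seg$start[pick] +
    floor(stats::runif(n) * (seg$end[pick] - seg$start[pick]))
  flen <- round(stats::rnorm(n, len_mean, len_sd))
  flen <- pmin(pmax(flen, len_min), 2 * len_mean)
  start <- mid - flen %/% 2
  lim <- unclass(genome)[seg$chrom[pick]]
  start <- pmax(0, pmin(start, lim - flen))
  ord <- order(seg$chrom[pick], start)
  fragment_set(
    interval_set(seg$chrom[pick][ord], start[ord], (start + flen)[ord],
                 provenance = paste0("synthetic:", condition)),
    condition = condition)
}

#' Ground-truth table of a synthetic dataset
#'
#' Per-region truth (coordinates, CGI status, promoter status, methylation
#' state, peak presence, true treatment/control accessibility ratio)
#' enabling parameter-recovery tests. Regions without peaks have
#' `true_ratio` 1.
#'
#' @param dataset a `synthetic_dataset` from [generate_dataset()].
#' @return Data frame.
#' @export
truth_table <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dataset$truth
}

#' Write a synthetic dataset to standard files
#'
#' Writes FASTA genome, chromosome-size table, CGI/TSS/peak BEDs,
#' per-class evolutionary BEDs, the probe table, fragment BEDs per
#' condition, the ground-truth table and a JSON snapshot of the
#' configuration. Output is byte-identical across runs for the same
#' config.
#'
#' @param dataset a `synthetic_dataset`.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_dataset <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(dataset$sequences), p("genome.fa"))
  writeLines(paste(names(dataset$genome), format_coord(dataset$genome),
                   sep = "\t"), p("genome.txt"))
  write_bed(dataset$cgi, p("cgi.bed"))
  write_bed(dataset$tss, p("tss.bed"))
  write_bed(dataset$peaks, p("h3k9me2_peaks.bed"))
  lab <- dataset$cgi_labels
  for (cls in unique(lab$evo_class)) {
    rows <- which(lab$evo_class == cls)
    idx <- match(lab$name[rows], dataset$cgi$name)
    write_bed(interval_set(dataset$cgi$chrom[idx], dataset$cgi$start[idx],
                           dataset$cgi$end[idx],
                           name = dataset$cgi$name[idx]),
              p(paste0("class_", cls, ".bed")))
  }
  utils::write.table(dataset$probes, p("probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (cond in names(dataset$fragments))
    write_bed(dataset$fragments[[cond]]$fragments,
              p(paste0("fragments_", cond, ".bed")))
  utils::write.table(dataset$truth, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- list.files(outdir, full.names = TRUE)
  invisible(files)
}
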