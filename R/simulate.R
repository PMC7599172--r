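#' Simulation configuration
#'
#' Describes a synthetic Tn-seq study: a random genome with non-overlapping
#' ORFs, binary essentiality labels, and an insertion library whose per-base
#' intensity reflects the transposon's target-motif preference, an optional
#' donor-locus proximity bias, and suppression of insertions inside essential
#' ORFs (with a tolerated 5' fringe). Read counts per site are heavily
#' overdispersed and rare jackpot sites can be injected.
#'
#' @param seed Integer seed; identical config + seed gives identical output.
#' @param n_chromosomes Number of chromosomes. Default 1.
#' @param chrom_length Length of each chromosome (bp). Default 1e6.
#' @param gc_content Genome GC fraction. Default 0.38 (yeast-like).
#' @param n_orfs Number of ORFs. Default 500.
#' @param orf_length `c(min, max)` ORF length range (bp), sampled uniformly.
#'   Default `c(300, 3000)`.
#' @param essential_fraction Fraction of ORFs labeled essential. Default 0.2.
#' @param transposon `"acds_like"` (motif-free), `"hermes_like"` (TNNNNA
#'   preference) or `"pb_like"` (strict TTAA).
#' @param motif_weight Hermes-like on-motif intensity multiplier (>= 1).
#'   Default 10.
#' @param off_motif_rate PB-like off-motif relative intensity (0 = strictly
#'   motif-bound). Default 0.
#' @param donor `"plasmid"` (no positional bias) or `"chromosomal"`.
#' @param donor_chrom,donor_pos Donor locus for `donor = "chromosomal"`.
#' @param donor_bias,donor_lambda Proximity bias weight b and decay length
#'   lambda (bp): intensity factor `1 + b * exp(-distance/lambda)`. Defaults
#'   10 and 5e4.
#' @param n_insertions Target number of unique insertion sites. Default 1e5.
#' @param essential_suppression Intensity multiplier inside essential ORFs
#'   beyond the fringe. Default 0.02.
#' @param fringe_bp Tolerated 5' span of essential ORFs where suppression is
#'   not applied. Default 35.
#' @param read_mu,read_k Mean and dispersion of the negative-binomial read
#'   count per site. Defaults 100 and 0.5.
#' @param jackpot_rate Expected number of injected jackpot sites (Poisson).
#'   Default 1.
#' @param jackpot_range Multiplier range (log-uniform) applied to a jackpot
#'   site's read count. Default `c(1e3, 1e5)`.
#' @return A `tn_sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 1L, chrom_length = 1e6,
                       gc_content = 0.38, n_orfs = 500L,
                       orf_length = c(300L, 3000L), essential_fraction = 0.2,
                       transposon = c("acds_like", "hermes_like", "pb_like"),
                       motif_weight = 10, off_motif_rate = 0,
                       donor = c("plasmid", "chromosomal"),
                       donor_chrom = NULL, donor_pos = NULL,
                       donor_bias = 10, donor_lambda = 5e4,
                       n_insertions = 1e5, essential_suppression = 0.02,
                       fringe_bp = 35L, read_mu = 100, read_k = 0.5,
                       jackpot_rate = 1, jackpot_range = c(1e3, 1e5)) {
  transposon <- match.arg(transposon)
  donor <- match.arg(donor)
  stopifnot(gc_content >= 0, gc_content <= 1,
            essential_fraction >= 0, essential_fraction <= 1,
            essential_suppression >= 0, essential_suppression <= 1,
            donor_lambda > 0, motif_weight >= 1, off_motif_rate >= 0,
            length(orf_length) == 2L, orf_length[1] <= orf_length[2])
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length, gc_content = gc_content,
              n_orfs = as.integer(n_orfs), orf_length = as.integer(orf_length),
              essential_fraction = essential_fraction, transposon = transposon,
              motif_weight = motif_weight, off_motif_rate = off_motif_rate,
              donor = donor, donor_chrom = donor_chrom, donor_pos = donor_pos,
              donor_bias = donor_bias, donor_lambda = donor_lambda,
              n_insertions = n_insertions,
              essential_suppression = essential_suppression,
              fringe_bp = as.integer(fringe_bp), read_mu = read_mu,
              read_k = read_k, jackpot_rate = jackpot_rate,
              jackpot_range = jackpot_range)
  class(cfg) <- "tn_sim_config"
  cfg
}

sim_motif <- function(config) {
  switch(config$transposon,
         acds_like = NULL,
         hermes_like = target_motif("TNNNNA"),
         pb_like = target_motif("TTAA"))
}

#' Simulate a genome, ORF annotation and essentiality labels
#'
#' Chromosomes are i.i.d. bases at the configured GC content; ORFs are placed
#' uniformly without overlap (random strand) and labeled essential
#' independently at `essential_fraction`.
#'
#' @param config A `tn_sim_config`.
#' @return List with `genome` (`tn_genome`), `orfs` (ORF data.frame),
#'   `labels` (`tn_training`-shaped data.frame of true labels).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  base_p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
              G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
    paste(sample(names(base_p), config$chrom_length, replace = TRUE, prob = base_p),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", utils::as.roman(seq_len(config$n_chromosomes)))
  genome <- tn_genome(seqs)
  # uniform non-overlapping placement by rejection
  per_chrom <- diff(round(seq(0, config$n_orfs,
                              length.out = config$n_chromosomes + 1L)))
  rows <- list()
  id <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    placed_start <- integer(0); placed_end <- integer(0)
    tries <- 0L
    while (length(placed_start) < per_chrom[ci]) {
      tries <- tries + 1L
      if (tries > 200L * per_chrom[ci]) {
        stop("could not place ", per_chrom[ci], " non-overlapping ORFs on a ",
             config$chrom_length, " bp chromosome; reduce n_orfs")
      }
      len <- sample(config$orf_length[1]:config$orf_length[2], 1L)
      st <- sample.int(config$chrom_length - len + 1L, 1L) - 1L
      if (any(st < placed_end & st + len > placed_start)) next
      placed_start <- c(placed_start, st); placed_end <- c(placed_end, st + len)
      id <- id + 1L
      rows[[id]] <- data.frame(
        orf_id = sprintf("ORF%04d", id), chrom = names(seqs)[ci],
        start = st, end = st + len,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    }
  }
  orfs <- do.call(rbind, rows)
  orfs$length <- orfs$end - orfs$start
  orfs <- orfs[order(orfs$chrom, orfs$start), , drop = FALSE]
  rownames(orfs) <- NULL
  labels <- data.frame(
    orf_id = orfs$orf_id,
    label = ifelse(stats::runif(nrow(orfs)) < config$essential_fraction,
                   "essential", "non_essential"),
    stringsAsFactors = FALSE)
  list(genome = genome, orfs = orfs, labels = labels)
}

# per-base insertion intensity for one chromosome (numeric vector, 0-based
# position i stored at index i+1)
.chrom_intensity <- function(config, genome, orfs, labels, chrom, targets) {
  L <- chrom_lengths(genome)[[chrom]]
  w <- rep(1, L)
  if (config$transposon == "pb_like") {
    w <- rep(config$off_motif_rate, L)
  }
  if (!is.null(targets)) {
    p <- targets$positions[[chrom]]
    if (length(p) > 0L) {
      span_idx <- unique(as.integer(outer(p, seq_len(targets$motif$length) - 1L, "+"))) + 1L
      span_idx <- span_idx[span_idx >= 1L & span_idx <= L]
      w[span_idx] <- if (config$transposon == "pb_like") 1 else config$motif_weight
    }
  }
  if (config$donor == "chromosomal" && identical(config$donor_chrom, chrom)) {
    d <- abs(seq_len(L) - 1L - config$donor_pos)
    w <- w * (1 + config$donor_bias * exp(-d / config$donor_lambda))
  }
  lab <- stats::setNames(labels$label, labels$orf_id)
  for (i in which(orfs$chrom == chrom)) {
    if (lab[[orfs$orf_id[i]]] != "essential") next
    if (orfs$strand[i] == "+") {
      lo <- min(orfs$start[i] + config$fringe_bp, orfs$end[i]); hi <- orfs$end[i]
    } else {
      lo <- orfs$start[i]; hi <- max(orfs$end[i] - config$fringe_bp, orfs$start[i])
    }
    if (hi > lo) {
      idx <- (lo + 1L):hi
      w[idx] <- w[idx] * config$essential_suppression
    }
  }
  w
}

#' Simulate an insertion library
#'
#' Samples unique insertion sites from the per-base intensity implied by the
#' configuration (motif preference x donor-proximity bias x essential-ORF
#' suppression), draws an overdispersed read count per site, and injects
#' jackpot sites.
#'
#' @param genome,orfs,labels Output of [simulate_genome()] (or compatible).
#' @param config A `tn_sim_config`.
#' @return List with `library` (`tn_library`), `truth` (list: `labels`,
#'   `site_intensity` per sampled site, `jackpot_sites`), and `targets` (the
#'   `tn_targets` index used, or `NULL`).
#' @export
simulate_library <- function(genome, orfs, labels, config) {
  set.seed(config$seed + 1L)
  motif <- sim_motif(config)
  targets <- if (is.null(motif)) NULL else scan_target_sites(genome, motif)
  chroms <- names(genome$seq)
  intens <- lapply(chroms, function(chr)
    .chrom_intensity(config, genome, orfs, labels, chr, targets))
  names(intens) <- chroms
  capacity <- sum(vapply(intens, function(w) sum(w > 0), numeric(1)))
  if (config$n_insertions > capacity) {
    stop("requested ", config$n_insertions, " unique insertions but only ",
         capacity, " positions have non-zero intensity",
         if (config$transposon == "pb_like") " (TTAA motif capacity)" else "")
  }
  tot_w <- vapply(intens, sum, numeric(1))
  chosen <- lapply(chroms, function(chr) integer(0))
  names(chosen) <- chroms
  n_have <- 0L
  while (n_have < config$n_insertions) {
    need <- config$n_insertions - n_have
    batch <- max(1000L, ceiling(need * 1.5))
    per <- stats::rmultinom(1L, batch, tot_w)[, 1L]
    for (ci in seq_along(chroms)) {
      if (per[ci] == 0L) next
      draws <- sample.int(length(intens[[ci]]), per[ci], replace = TRUE,
                          prob = intens[[ci]])
      chosen[[ci]] <- unique(c(chosen[[ci]], draws))
    }
    n_have <- sum(lengths(chosen))
  }
  # trim overshoot deterministically (drop random excess, seeded)
  overshoot <- n_have - config$n_insertions
  if (overshoot > 0L) {
    all_idx <- unlist(lapply(seq_along(chroms), function(ci)
      paste0(ci, ":", chosen[[ci]])))
    drop <- sample(all_idx, overshoot)
    for (ci in seq_along(chroms)) {
      dd <- as.integer(sub("^\\d+:", "", drop[startsWith(drop, paste0(ci, ":"))]))
      chosen[[ci]] <- setdiff(chosen[[ci]], dd)
    }
  }
  sites <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    idx <- sort(chosen[[ci]])
    if (length(idx) == 0L) return(NULL)
    data.frame(chrom = chroms[ci], pos = idx - 1L,
               reads = pmax(1, stats::rnbinom(length(idx), size = config$read_k,
                                              mu = config$read_mu)),
               intensity = intens[[ci]][idx], stringsAsFactors = FALSE)
  }))
  n_jack <- stats::rpois(1L, config$jackpot_rate)
  jackpot_sites <- NULL
  if (n_jack > 0L && nrow(sites) > 0L) {
    j_idx <- sample.int(nrow(sites), min(n_jack, nrow(sites)))
    mult <- exp(stats::runif(length(j_idx), log(config$jackpot_range[1]),
                             log(config$jackpot_range[2])))
    sites$reads[j_idx] <- round(sites$reads[j_idx] * mult)
    jackpot_sites <- sites[j_idx, c("chrom", "pos", "reads")]
  }
  lib <- insertion_library(
    sites[, c("chrom", "pos", "reads")],
    metadata = list(species = "synthetic", transposon = config$transposon,
                    donor_locus = if (config$donor == "chromosomal") {
                      list(chrom = config$donor_chrom, pos = config$donor_pos)
                    } else "plasmid",
                    ploidy = "haploid", seed = config$seed))
  truth <- list(labels = labels,
                site_intensity = sites[, c("chrom", "pos", "intensity")],
                jackpot_sites = jackpot_sites)
  list(library = lib, truth = truth, targets = targets)
}

#' Emit tagged FASTQ reads for an insertion library
#'
#' Writes one FASTQ record per sequencing read: the transposon tag, then
#' `post_tag_offset` random filler bases, then the genomic sequence starting
#' at the insertion site (read strand randomized; a minus-strand read carries
#' the reverse complement of the genomic segment *ending* at the site, so
#' that trimming, mapping and junction calling collapse both orientations
#' back onto the exact site coordinate).
#'
#' @param lib A `tn_library`.
#' @param genome A `tn_genome`.
#' @param spec A `tn_trimspec` (its tag and offset are embedded in the reads).
#' @param path Output FASTQ path.
#' @param read_length Total read length. Default 75.
#' @param max_reads_per_site Cap on reads emitted per site (reads are emitted
#'   in proportion to, and at most, the site's read count). Default 50.
#' @param seed RNG seed for strand/filler randomization. Default 1.
#' @return Invisibly, the number of reads written.
#' @export
emit_reads <- function(lib, genome, spec, path, read_length = 75L,
                       max_reads_per_site = 50L, seed = 1L) {
  set.seed(seed)
  g_len <- read_length - nchar(spec$tag_sequence) - spec$post_tag_offset
  stopifnot(g_len >= 1L)
  lens <- chrom_lengths(genome)
  con <- file(path, "w")
  on.exit(close(con))
  n_out <- 0L
  for (i in seq_len(nrow(lib$sites))) {
    chr <- lib$sites$chrom[i]; pos <- lib$sites$pos[i]
    n_reads <- min(lib$sites$reads[i], max_reads_per_site)
    L <- lens[[chr]]
    for (r in seq_len(n_reads)) {
      minus_ok <- pos - g_len + 1L >= 0L
      plus_ok <- pos + g_len <= L
      strand <- if (minus_ok && plus_ok) {
        sample(c("+", "-"), 1L)
      } else if (plus_ok) "+" else if (minus_ok) "-" else next
      gseq <- if (strand == "+") {
        as.character(Biostrings::subseq(genome$seq[[chr]], pos + 1L, pos + g_len))
      } else {
        as.character(Biostrings::reverseComplement(
          Biostrings::subseq(genome$seq[[chr]], pos - g_len + 2L, pos + 1L)))
      }
      filler <- if (spec$post_tag_offset > 0L) {
        paste(sample(c("A", "C", "G", "T"), spec$post_tag_offset, replace = TRUE),
              collapse = "")
      } else ""
      seqq <- paste0(spec$tag_sequence, filler, gseq)
      n_out <- n_out + 1L
      writeLines(c(sprintf("@read%d %s:%d:%s", n_out, chr, pos, strand),
                   seqq, "+", strrep("I", nchar(seqq))), con)
    }
  }
  invisible(n_out)
}

#' Read sequences from FASTQ
#'
#' @param path FASTQ file.
#' @return Character vector of read sequences.
#' @export
read_fastq_sequences <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}
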