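#' Summarize an insertion library
#'
#' Computes the standard library-quality statistics used to compare
#' saturation-mutagenesis libraries: depth, reads-per-insertion dispersion,
#' jackpot indicators, per-gene insertion coverage, and (for motif-bound
#' transposons) target-sequence saturation.
#'
#' @param lib A `tn_library`.
#' @param orfs ORF data.frame.
#' @param target_index Optional `tn_targets`; when `NULL` (motif-free
#'   transposon) the target-derived fields are `NA`.
#' @return A one-row data.frame of class `tn_library_stats` with columns
#'   `unique_insertions`, `total_reads`, `mean_reads_per_insertion`,
#'   `sd_reads_per_insertion`, `max_reads_per_insertion`,
#'   `max_over_mean_ratio`, `n_sites_reads_gt_1e6`,
#'   `pct_targets_without_insertion`, `pct_insertions_at_targets`,
#'   `mean_insertions_per_gene`, `n_genes_zero_insertions`,
#'   `mean_targets_per_gene`, `n_genes_zero_targets`.
#' @details "An insertion at a target" means the site coordinate falls within
#'   the motif span `[p, p + motif length)` of at least one match; a target is
#'   "without insertion" when no site falls anywhere in its span.
#' @export
summarize_library <- function(lib, orfs, target_index = NULL) {
  stopifnot(inherits(lib, "tn_library"))
  if (lib$unique_insertions == 0L) stop("empty insertion library")
  r <- lib$sites$reads
  mean_r <- lib$total_reads / lib$unique_insertions
  per_gene <- insertions_in_intervals(lib, orfs$chrom, orfs$start, orfs$end)
  out <- data.frame(
    unique_insertions = lib$unique_insertions,
    total_reads = lib$total_reads,
    mean_reads_per_insertion = mean_r,
    sd_reads_per_insertion = if (length(r) > 1L) stats::sd(r) else 0,
    max_reads_per_insertion = max(r),
    max_over_mean_ratio = max(r) / mean_r,
    n_sites_reads_gt_1e6 = sum(r > 1e6),
    pct_targets_without_insertion = NA_real_,
    pct_insertions_at_targets = NA_real_,
    mean_insertions_per_gene = mean(per_gene$n_sites),
    n_genes_zero_insertions = sum(per_gene$n_sites == 0L),
    mean_targets_per_gene = NA_real_,
    n_genes_zero_targets = NA_integer_
  )
  if (!is.null(target_index)) {
    ov <- sites_vs_target_spans(lib, target_index)
    out$pct_targets_without_insertion <- 100 * ov$n_targets_without / ov$n_targets
    out$pct_insertions_at_targets <- 100 * ov$n_sites_at_targets / lib$unique_insertions
    tpg <- count_targets_per_orf(target_index, orfs)
    out$mean_targets_per_gene <- mean(tpg)
    out$n_genes_zero_targets <- sum(tpg == 0L)
  }
  class(out) <- c("tn_library_stats", "data.frame")
  out
}

# per-interval site/read counts; intervals 0-based half-open
insertions_in_intervals <- function(lib, chrom, start, end) {
  n_sites <- integer(length(chrom))
  n_reads <- numeric(length(chrom))
  for (chr in unique(chrom)) {
    sel <- which(chrom == chr)
    s <- lib$sites[lib$sites$chrom == chr, , drop = FALSE]
    if (nrow(s) == 0L) next
    ir_sites <- IRanges::IRanges(s$pos + 1L, width = 1L)
    ir_win <- IRanges::IRanges(start[sel] + 1L, end[sel])
    hits <- IRanges::findOverlaps(ir_win, ir_sites)
    qh <- S4Vectors::queryHits(hits)
    n_sites[sel] <- tabulate(qh, nbins = length(sel))
    rd <- tapply(s$reads[S4Vectors::subjectHits(hits)], factor(qh, levels = seq_along(sel)), sum)
    rd[is.na(rd)] <- 0
    n_reads[sel] <- as.numeric(rd)
  }
  data.frame(n_sites = n_sites, n_reads = n_reads)
}

# overlap bookkeeping between insertion sites and motif spans
sites_vs_target_spans <- function(lib, target_index) {
  len <- target_index$motif$length
  n_targets <- target_index$total_count
  n_without <- 0L
  at_target <- logical(lib$unique_insertions)
  for (chr in names(target_index$positions)) {
    p <- target_index$positions[[chr]]
    if (length(p) == 0L) next
    s_idx <- which(lib$sites$chrom == chr)
    spans <- IRanges::IRanges(p + 1L, width = len)
    if (length(s_idx) == 0L) {
      n_without <- n_without + length(p)
      next
    }
    sites <- IRanges::IRanges(lib$sites$pos[s_idx] + 1L, width = 1L)
    n_without <- n_without + sum(IRanges::countOverlaps(spans, sites) == 0L)
    at_target[s_idx] <- IRanges::countOverlaps(sites, spans) > 0L
  }
  list(n_targets = n_targets, n_targets_without = n_without,
       n_sites_at_targets = sum(at_target))
}

#' Detect jackpot insertion sites
#'
#' Jackpots are single sites carrying a disproportionate share of reads
#' (typically clones that transposed before induction). A site is flagged
#' when its read count is at least `fold` times the library's mean
#' reads-per-insertion.
#'
#' @param lib A `tn_library`.
#' @param fold Flagging threshold in multiples of the mean. Default 1000.
#' @return List with `jackpots` (flagged rows of the site table, with a
#'   `fold_over_mean` column), `n_sites_reads_gt_1e6`, and
#'   `mean_reads_per_insertion`.
#' @export
detect_jackpots <- function(lib, fold = 1000) {
  stopifnot(inherits(lib, "tn_library"))
  if (lib$unique_insertions == 0L) stop("empty insertion library")
  mean_r <- lib$total_reads / lib$unique_insertions
  hit <- lib$sites$reads >= fold * mean_r
  jack <- lib$sites[hit, , drop = FALSE]
  jack$fold_over_mean <- jack$reads / mean_r
  rownames(jack) <- NULL
  list(jackpots = jack,
       n_sites_reads_gt_1e6 = sum(lib$sites$reads > 1e6),
       mean_reads_per_insertion = mean_r)
}

#' Correlate library depth with classifier performance
#'
#' Pearson correlation (with two-sided p-values) of per-study AUC against the
#' number of unique insertion sites and against the total read count.
#'
#' @param unique_insertions Numeric vector of per-study unique insertion
#'   counts (any consistent unit).
#' @param total_reads Numeric vector of per-study total read counts.
#' @param auc Numeric vector of per-study AUCs.
#' @return List with `r_insertions`, `p_insertions`, `r_reads`, `p_reads`.
#' @export
correlate_depth_vs_auc <- function(unique_insertions, total_reads, auc) {
  n <- length(auc)
  if (n < 3L || length(unique_insertions) != n || length(total_reads) != n) {
    stop("need >= 3 paired studies")
  }
  ct_i <- stats::cor.test(unique_insertions, auc, method = "pearson")
  ct_r <- stats::cor.test(total_reads, auc, method = "pearson")
  list(r_insertions = unname(ct_i$estimate), p_insertions = ct_i$p.value,
       r_reads = unname(ct_r$estimate), p_reads = ct_r$p.value)
}

#' Metagene insertion profile around start codons
#'
#' Sums insertion sites at each strand-oriented offset relative to the start
#' codon over a gene subset (negative offsets are upstream), normalized per
#' gene and per million library insertions.
#'
#' @param lib A `tn_library`.
#' @param orfs ORF data.frame.
#' @param window Half-width W of the offset window `[-W, W]`. Default 1000.
#' @param subset Optional character vector of `orf_id`s (e.g. the essential
#'   or the non-essential genes); default all.
#' @return data.frame with columns `offset` and `value` (insertions per gene
#'   per 1e6 library insertions); all-zero for an empty subset.
#' @export
metagene_profile <- function(lib, orfs, window = 1000L, subset = NULL) {
  stopifnot(inherits(lib, "tn_library"))
  if (!is.null(subset)) orfs <- orfs[orfs$orf_id %in% subset, , drop = FALSE]
  offsets <- seq(-window, window)
  counts <- numeric(length(offsets))
  for (i in seq_len(nrow(orfs))) {
    s <- lib$sites[lib$sites$chrom == orfs$chrom[i], , drop = FALSE]
    if (nrow(s) == 0L) next
    off <- if (orfs$strand[i] == "+") {
      s$pos - orfs$start[i]
    } else {
      (orfs$end[i] - 1L) - s$pos   # last base of a minus-strand ORF is its start codon
    }
    off <- off[off >= -window & off <= window]
    if (length(off) > 0L) {
      tab <- tabulate(off + window + 1L, nbins = length(offsets))
      counts <- counts + tab
    }
  }
  norm <- if (nrow(orfs) > 0L && lib$unique_insertions > 0L) {
    counts / nrow(orfs) / lib$unique_insertions * 1e6
  } else {
    numeric(length(offsets))
  }
  data.frame(offset = offsets, value = norm)
}

#' Insertion load in the first coding bases of essential genes
#'
#' Mean number of insertion sites within the first `span` coding bases
#' (strand-oriented, from the start codon inward) of essential genes, divided
#' by the library's unique insertion count and multiplied by 1e6. A
#' depth-normalized measure of how tolerant essential-gene 5' ends are to
#' insertion (e.g. transposons carrying cryptic promoter activity score
#' higher). Independent of read counts by construction.
#'
#' @param lib A `tn_library`.
#' @param orfs ORF data.frame.
#' @param labels Named character vector or data.frame (`orf_id`, `label`)
#'   with labels in `{essential, non_essential}`.
#' @param span Coding span in bp. Default 100.
#' @return Single numeric value.
#' @export
upstream_coding_load <- function(lib, orfs, labels, span = 100L) {
  labels <- as_label_vector(labels)
  ess <- names(labels)[labels == "essential"]
  orfs <- orfs[orfs$orf_id %in% ess, , drop = FALSE]
  if (nrow(orfs) == 0L) stop("no essential genes in labels")
  plus <- orfs$strand == "+"
  start <- ifelse(plus, orfs$start, pmax(orfs$start, orfs$end - span))
  end <- ifelse(plus, pmin(orfs$end, orfs$start + span), orfs$end)
  n <- insertions_in_intervals(lib, orfs$chrom, start, end)$n_sites
  mean(n) / lib$unique_insertions * 1e6
}

as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    stats::setNames(as.character(labels$label), labels$orf_id)
  } else {
    labels
  }
}

#' Derive the printed summary-row statistics from raw library totals
#'
#' Reproduces the derived rows of a published library-summary table from its
#' raw rows, using the same reporting conventions: the mean reads-per-
#' insertion is rounded to an integer first and the max/mean ratio is then
#' computed from that rounded mean; percentages are reported to two decimals.
#'
#' @param total_reads Total read count.
#' @param unique_insertions Unique insertion-site count.
#' @param max_reads Read count at the deepest site.
#' @param targets_total Optional total number of target sequences.
#' @param targets_without_insertion Optional number of target sequences with
#'   no insertion.
#' @return List with `mean_reads_per_insertion` (rounded),
#'   `max_over_mean_ratio` (rounded), and `pct_targets_without_insertion`
#'   (2 dp; `NA` without target counts).
#' @export
derive_summary_stats <- function(total_reads, unique_insertions, max_reads,
                                 targets_total = NA, targets_without_insertion = NA) {
  mean_r <- round(total_reads / unique_insertions)
  list(
    mean_reads_per_insertion = mean_r,
    max_over_mean_ratio = round(max_reads / mean_r),
    pct_targets_without_insertion =
      round(100 * targets_without_insertion / targets_total, 2)
  )
}

#' Published summary statistics of six yeast transposon mutagenesis studies
#'
#' Returns the bundled per-study summary table for six published in vivo
#' transposon mutagenesis libraries (AcDs, Hermes and PiggyBac in
#' *C. albicans*, *S. cerevisiae* and *S. pombe*): raw totals (target
#' sequences, unique insertions, reads, deepest site) and the reported
#' classifier AUC. Units follow the published presentation: columns suffixed
#' `_1e3` are thousands, `_1e6` millions.
#'
#' @return data.frame, one row per study.
#' @export
study_summaries <- function() {
  path <- system.file("extdata", "study_summaries.csv", package = "tnverdict",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write library stats as TSV/JSON
#'
#' @param stats A `tn_library_stats` row (or plain data.frame of such rows).
#' @param path Output path; format chosen by extension (`.json` or TSV
#'   otherwise).
#' @export
write_library_stats <- function(stats, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(as.data.frame(stats)), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
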