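#' Built-in transposon target motifs
#'
#' Constructs a target-motif description. `PiggyBac` integrates almost
#' exclusively at TTAA; `Hermes` prefers the degenerate motif TNNNNA (N = any
#' base); `AcDs` has no strong target preference and is represented by a
#' `NULL` motif.
#'
#' @param name One of `"TTAA"`, `"TNNNNA"`, or a custom degenerate pattern
#'   over `{A,C,G,T,N}` (length >= 2).
#' @return A `tn_motif` object (list with `name`, `pattern`, `length`), or
#'   `NULL` for `name = "none"`.
#' @export
target_motif <- function(name) {
  if (is.null(name) || identical(tolower(name), "none")) return(NULL)
  pattern <- toupper(name)
  if (nchar(pattern) < 2L || grepl("[^ACGTN]", pattern)) {
    stop("motif pattern must be a string over {A,C,G,T,N} of length >= 2")
  }
  structure(list(name = pattern, pattern = pattern, length = nchar(pattern)),
            class = "tn_motif")
}

#' Scan a genome for transposon target sites
#'
#' Finds every (possibly overlapping) start position where the motif matches
#' the forward strand. Both built-in motifs (TTAA, TNNNNA) are
#' reverse-complement-palindromic pattern families, so a single-strand scan is
#' complete. An `N` in the genome never matches, even against a degenerate
#' pattern position.
#'
#' @param genome A `tn_genome`.
#' @param motif A `tn_motif` from [target_motif()].
#' @return A `tn_targets` object: list with `motif`, `positions` (named list
#'   of strictly increasing 0-based match start positions per chromosome) and
#'   `total_count`.
#' @export
scan_target_sites <- function(genome, motif) {
  stopifnot(inherits(genome, "tn_genome"), inherits(motif, "tn_motif"))
  pat <- Biostrings::DNAString(motif$pattern)
  degenerate <- grepl("N", motif$pattern, fixed = TRUE)
  positions <- lapply(seq_along(genome$seq), function(i) {
    subj <- genome$seq[[i]]
    m <- Biostrings::matchPattern(pat, subj, fixed = !degenerate)
    starts <- Biostrings::start(m)
    if (degenerate && length(starts) > 0L) {
      # N in the subject matches any degenerate position under fixed = FALSE;
      # drop windows containing N so genome ambiguity never counts as a site
      wins <- as.character(Biostrings::extractAt(
        subj, IRanges::IRanges(starts, width = motif$length)))
      starts <- starts[!grepl("N", wins, fixed = TRUE)]
    }
    as.integer(starts) - 1L  # 0-based
  })
  names(positions) <- names(genome$seq)
  structure(
    list(motif = motif, positions = positions,
         total_count = sum(lengths(positions))),
    class = "tn_targets"
  )
}

#' @export
print.tn_targets <- function(x, ...) {
  cat("tn_targets:", x$motif$pattern, "-", x$total_count, "site(s) on",
      length(x$positions), "chromosome(s)\n")
  invisible(x)
}

#' Count target sites per ORF
#'
#' A target is assigned to an ORF iff its match start position lies within
#' `[start, end)`; overlapping ORFs each count shared targets independently.
#'
#' @param index A `tn_targets` from [scan_target_sites()].
#' @param orfs ORF data.frame.
#' @return Named integer vector, `orf_id -> count`.
#' @export
count_targets_per_orf <- function(index, orfs) {
  stopifnot(inherits(index, "tn_targets"))
  counts <- integer(nrow(orfs))
  for (chr in unique(orfs$chrom)) {
    pos <- index$positions[[chr]]
    sel <- which(orfs$chrom == chr)
    if (is.null(pos) || length(pos) == 0L) next
    # strictly increasing positions: count in [start, end) via binary search
    counts[sel] <- findInterval(orfs$end[sel] - 1L, pos) -
      findInterval(orfs$start[sel] - 1L, pos)
  }
  stats::setNames(counts, orfs$orf_id)
}

#' Export target sites as BED
#'
#' Writes motif match spans in BED format (0-based half-open), one record per
#' match start.
#'
#' @param index A `tn_targets`.
#' @param path Output path.
#' @export
write_targets_bed <- function(index, path) {
  rows <- unlist(lapply(names(index$positions), function(chr) {
    p <- index$positions[[chr]]
    if (length(p) == 0L) return(character(0))
    sprintf("%s\t%d\t%d\t%s", chr, p, p + index$motif$length, index$motif$pattern)
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Export per-ORF target counts as TSV
#'
#' @param index A `tn_targets`.
#' @param orfs ORF data.frame.
#' @param path Output path.
#' @return The per-ORF count table, invisibly.
#' @export
write_targets_per_orf <- function(index, orfs, path) {
  n <- count_targets_per_orf(index, orfs)
  tab <- data.frame(orf_id = orfs$orf_id, n_targets = as.integer(n[orfs$orf_id]),
                    targets_per_kb = 1000 * as.integer(n[orfs$orf_id]) / orfs$length)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
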