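#' Freedom Index: largest insertion-free fraction of an ORF
#'
#' The length of the largest run of insertion-free bases within the ORF
#' (including the flanks from the ORF start to the first insertion and from
#' the last insertion to the ORF end), divided by the ORF length. 1 when the
#' ORF has no insertions; near 1 suggests an intolerant (essential) gene or
#' an essential domain.
#'
#' @param start,end ORF coordinates (0-based half-open).
#' @param positions Integer vector of insertion coordinates on the ORF's
#'   chromosome (0-based); positions outside `[start, end)` are ignored.
#' @return Fraction in `[0, 1]`.
#' @export
freedom_index <- function(start, end, positions) {
  L <- end - start
  p <- sort(positions[positions >= start & positions < end])
  if (length(p) == 0L) return(1)
  gaps <- c(p[1L] - start, diff(p) - 1L, end - p[length(p)] - 1L)
  max(gaps) / L
}

#' Neighborhood Index: ORF insertion density relative to its surroundings
#'
#' The ORF's insertion density divided by the insertion density of the window
#' extending `flank` bp on each side (clipped at chromosome ends; the window
#' includes the ORF itself). Normalizes for positional insertion biases such
#' as proximity to the donor locus or chromatin accessibility. When the
#' window contains no insertions at all the index is 0 and the ORF is flagged
#' as lacking local data.
#'
#' @param start,end ORF coordinates (0-based half-open).
#' @param positions Insertion coordinates on the ORF's chromosome (0-based).
#' @param chrom_length Chromosome length (bp), for window clipping.
#' @param flank Flank per side in bp. Default 10000.
#' @return List with `ni`, `n_orf`, `n_window`, `no_local_data`.
#' @export
neighborhood_index <- function(start, end, positions, chrom_length, flank = 10000L) {
  w_start <- max(0L, start - flank)
  w_end <- min(chrom_length, end + flank)
  n_orf <- sum(positions >= start & positions < end)
  n_win <- sum(positions >= w_start & positions < w_end)
  if (n_win == 0L) {
    return(list(ni = 0, n_orf = n_orf, n_window = 0L, no_local_data = TRUE))
  }
  ni <- (n_orf / (end - start)) / (n_win / (w_end - w_start))
  list(ni = ni, n_orf = n_orf, n_window = n_win, no_local_data = FALSE)
}

#' Insertions immediately upstream of the start codon
#'
#' Counts insertions in the strand-oriented window of `span` bp 5' of the
#' start codon (clipped at chromosome ends). An insertion exactly at the
#' start-codon base belongs to the ORF, not the upstream window.
#'
#' @param start,end ORF coordinates (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @param positions Insertion coordinates on the ORF's chromosome (0-based).
#' @param chrom_length Chromosome length (bp).
#' @param span Window span in bp. Default 100.
#' @return Integer count.
#' @export
upstream_insertions <- function(start, end, strand, positions, chrom_length,
                                span = 100L) {
  if (strand == "+") {
    lo <- max(0L, start - span); hi <- start            # [lo, hi)
  } else {
    lo <- end; hi <- min(chrom_length, end + span)      # [lo, hi)
  }
  sum(positions >= lo & positions < hi)
}

#' Compute the per-ORF predictor table
#'
#' Builds the eight per-ORF features feeding the essentiality classifier:
#' insertion count, read count, Neighborhood Index, Freedom Index, upstream
#' insertions, insertions per target sequence (motif-bound transposons only),
#' and length-normalized read and insertion counts.
#'
#' @param lib A `tn_library`.
#' @param orfs ORF data.frame.
#' @param genome A `tn_genome` (for chromosome lengths and validation).
#' @param target_counts Optional named integer vector from
#'   [count_targets_per_orf()]; enables the `insertions_per_target` feature.
#' @param flank NI flank per side (bp). Default 10000.
#' @param upstream_span Upstream window (bp). Default 100.
#' @return A data.frame of class `tn_features`, one row per ORF: identifiers
#'   and auxiliaries (`orf_id`, `chrom`, `length`, `n_targets`, `n_window`,
#'   flag columns `no_local_data`, `no_target`) plus the feature columns
#'   named by [feature_columns()]. ORFs with zero targets get
#'   `insertions_per_target = 0` and `no_target = TRUE`.
#' @export
compute_features <- function(lib, orfs, genome, target_counts = NULL,
                             flank = 10000L, upstream_span = 100L) {
  stopifnot(inherits(lib, "tn_library"), inherits(genome, "tn_genome"))
  lens <- chrom_lengths(genome)
  unknown <- setdiff(unique(orfs$chrom), names(lens))
  if (length(unknown) > 0L) {
    stop("ORF(s) on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  by_chrom <- split(lib$sites, lib$sites$chrom)
  n <- nrow(orfs)
  ins <- integer(n); reads <- numeric(n); ni <- numeric(n); fi <- numeric(n)
  up <- integer(n); n_win <- integer(n); no_local <- logical(n)
  for (i in seq_len(n)) {
    s <- by_chrom[[orfs$chrom[i]]]
    pos <- if (is.null(s)) integer(0) else s$pos
    in_orf <- pos >= orfs$start[i] & pos < orfs$end[i]
    ins[i] <- sum(in_orf)
    reads[i] <- if (is.null(s)) 0 else sum(s$reads[in_orf])
    nb <- neighborhood_index(orfs$start[i], orfs$end[i], pos,
                             lens[[orfs$chrom[i]]], flank)
    ni[i] <- nb$ni; n_win[i] <- nb$n_window; no_local[i] <- nb$no_local_data
    fi[i] <- freedom_index(orfs$start[i], orfs$end[i], pos)
    up[i] <- upstream_insertions(orfs$start[i], orfs$end[i], orfs$strand[i],
                                 pos, lens[[orfs$chrom[i]]], upstream_span)
  }
  out <- data.frame(
    orf_id = orfs$orf_id, chrom = orfs$chrom, length = orfs$length,
    insertions = ins, reads = reads,
    neighborhood_index = ni, freedom_index = fi,
    insertions_100_upstream = up,
    reads_per_length = reads / orfs$length,
    insertions_per_length = ins / orfs$length,
    n_window = n_win, no_local_data = no_local,
    stringsAsFactors = FALSE
  )
  if (!is.null(target_counts)) {
    nt <- as.integer(target_counts[orfs$orf_id])
    if (any(is.na(nt))) stop("target_counts missing for some ORFs")
    out$n_targets <- nt
    out$no_target <- nt == 0L
    out$insertions_per_target <- ifelse(nt == 0L, 0, ins / nt)
  }
  class(out) <- c("tn_features", "data.frame")
  out
}

#' Feature column names of a predictor table
#'
#' @param features A `tn_features` table (or any data.frame with the feature
#'   columns).
#' @return Character vector of feature column names in stable order; includes
#'   `insertions_per_target` only when present.
#' @export
feature_columns <- function(features) {
  base <- c("insertions", "reads", "neighborhood_index", "freedom_index",
            "insertions_100_upstream", "insertions_per_target",
            "reads_per_length", "insertions_per_length")
  intersect(base, names(features))
}

#' Write a predictor table with its column schema
#'
#' Writes the feature table as TSV and a sidecar JSON schema describing the
#' columns.
#'
#' @param features A `tn_features` table.
#' @param path TSV output path; the schema is written to `<path>.schema.json`.
#' @export
write_features <- function(features, path) {
  utils::write.table(as.data.frame(features), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  schema <- list(columns = names(features),
                 feature_columns = feature_columns(features),
                 coordinate_convention = "0-based half-open")
  jsonlite::write_json(schema, paste0(path, ".schema.json"), auto_unbox = TRUE)
  invisible(path)
}
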