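#' Transposon tag trimming specification
#'
#' Describes how the transposon-derived portion of a sequencing read is
#' located and removed before alignment, mirroring adapter-trimming with
#' `--discard-untrimmed`. Some chemistries (e.g. the *C. albicans* PiggyBac
#' protocol) skip a fixed number of bases between the tag and the first
#' genomic base; `post_tag_offset` expresses that dialect.
#'
#' @param tag_sequence Transposon tag (primer-side sequence) to search for.
#' @param min_overlap Minimum length of a partial tag match at the read start.
#' @param post_tag_offset Bases skipped after the tag end before the genomic
#'   portion begins. Default 0.
#' @param min_remaining_length Minimum genomic length retained. Default 2.
#' @param discard_untrimmed Reject reads with no qualifying tag match.
#'   Default `TRUE`.
#' @param max_mismatch Mismatches tolerated in a full tag match. Default: 1
#'   when the tag is >= 20 bp, else 0.
#' @return A `tn_trimspec` object.
#' @export
trim_spec <- function(tag_sequence, min_overlap = 3L, post_tag_offset = 0L,
                      min_remaining_length = 2L, discard_untrimmed = TRUE,
                      max_mismatch = NULL) {
  tag_sequence <- toupper(tag_sequence)
  stopifnot(min_overlap >= 1L, post_tag_offset >= 0L, nchar(tag_sequence) >= 1L)
  if (is.null(max_mismatch)) {
    max_mismatch <- if (nchar(tag_sequence) >= 20L) 1L else 0L
  }
  structure(
    list(tag_sequence = tag_sequence, min_overlap = as.integer(min_overlap),
         post_tag_offset = as.integer(post_tag_offset),
         min_remaining_length = as.integer(min_remaining_length),
         discard_untrimmed = isTRUE(discard_untrimmed),
         max_mismatch = as.integer(max_mismatch)),
    class = "tn_trimspec"
  )
}

# Locate the end (1-based, inclusive) of the tag match in one read, or NA.
# Full matches anywhere in the read are preferred; otherwise a suffix of the
# tag of length >= min_overlap may appear as the read prefix (tag truncated
# by the sequencing start, genome adjoining the read's 3' side).
.find_tag_end <- function(read, spec) {
  tag <- spec$tag_sequence
  m <- Biostrings::matchPattern(tag, Biostrings::DNAString(read),
                                max.mismatch = spec$max_mismatch)
  if (length(m) > 0L) {
    return(Biostrings::end(m)[1L])
  }
  # partial: tag suffix == read prefix
  max_part <- min(nchar(tag) - 1L, nchar(read))
  if (max_part >= spec$min_overlap) {
    for (len in seq(max_part, spec$min_overlap)) {
      if (substr(read, 1L, len) == substr(tag, nchar(tag) - len + 1L, nchar(tag))) {
        return(len)
      }
    }
  }
  NA_integer_
}

#' Trim the transposon tag from reads
#'
#' Locates the transposon tag in each read (full match anywhere, tolerating
#' `max_mismatch` mismatches, or a partial match of at least `min_overlap`
#' bases at the read start) and returns the genomic sub-read beginning
#' `post_tag_offset` bases after the tag end.
#'
#' @param reads Character vector of read sequences over `{A,C,G,T,N}`.
#' @param spec A `tn_trimspec` from [trim_spec()].
#' @return A list with `trimmed` (character, genomic portions of accepted
#'   reads), `status` (per-read: `"trimmed"`, `"no_tag"`, or `"too_short"`),
#'   and `counts` (tally of statuses). Reads without a tag are kept untrimmed
#'   when `discard_untrimmed = FALSE`.
#' @export
trim_transposon_tag <- function(reads, spec) {
  stopifnot(inherits(spec, "tn_trimspec"))
  reads <- toupper(reads)
  status <- character(length(reads))
  out <- character(length(reads))
  for (i in seq_along(reads)) {
    tag_end <- .find_tag_end(reads[i], spec)
    if (is.na(tag_end)) {
      if (spec$discard_untrimmed) {
        status[i] <- "no_tag"
        out[i] <- NA_character_
      } else {
        status[i] <- "trimmed"
        out[i] <- reads[i]
      }
      next
    }
    from <- tag_end + spec$post_tag_offset + 1L
    remaining <- if (from > nchar(reads[i])) "" else substr(reads[i], from, nchar(reads[i]))
    if (nchar(remaining) < spec$min_remaining_length) {
      status[i] <- "too_short"
      out[i] <- NA_character_
    } else {
      status[i] <- "trimmed"
      out[i] <- remaining
    }
  }
  list(trimmed = out[status == "trimmed"], status = status,
       counts = c(input = length(reads), trimmed = sum(status == "trimmed"),
                  no_tag = sum(status == "no_tag"),
                  too_short = sum(status == "too_short")))
}

#' Construct an insertion library
#'
#' The central object of the pipeline: the set of unique genomic insertion
#' sites with read counts. Site identity is the forward-strand junction
#' coordinate only; reads from either transposon end collapse onto the same
#' site.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `reads`.
#'   Rows sharing (chrom, pos) are collapsed by summing reads.
#' @param metadata Named list; recognised entries include `species`,
#'   `transposon`, `donor_locus`, `ploidy`.
#' @return A `tn_library` object with elements `sites` (sorted by
#'   (chrom, pos)), `metadata`, `total_reads`, `unique_insertions`.
#' @export
insertion_library <- function(sites, metadata = list()) {
  stopifnot(all(c("chrom", "pos", "reads") %in% names(sites)))
  if (nrow(sites) > 0L) {
    if (any(sites$reads < 1)) stop("read counts must be >= 1")
    agg <- stats::aggregate(reads ~ chrom + pos, data = sites, FUN = sum)
    agg <- agg[order(agg$chrom, agg$pos), , drop = FALSE]
    rownames(agg) <- NULL
    sites <- agg[, c("chrom", "pos", "reads")]
    sites$pos <- as.integer(sites$pos)
    sites$reads <- as.numeric(sites$reads)
  } else {
    sites <- data.frame(chrom = character(0), pos = integer(0), reads = numeric(0))
  }
  structure(
    list(sites = sites, metadata = metadata,
         total_reads = sum(sites$reads), unique_insertions = nrow(sites)),
    class = "tn_library"
  )
}

#' @export
print.tn_library <- function(x, ...) {
  cat("tn_library:", x$unique_insertions, "unique insertion site(s),",
      format(x$total_reads, big.mark = ","), "reads\n")
  if (!is.null(x$metadata$species)) {
    cat("  species:", x$metadata$species,
        " transposon:", x$metadata$transposon %||% "?", "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call insertion sites from aligned reads
#'
#' Applies the read-level filters (minimum mapping quality, first-aligned-base
#' reference match) and collapses surviving reads to unique junction
#' coordinates. A plus-strand read's junction is its leftmost aligned base; a
#' minus-strand read's junction is its rightmost aligned base. Both map to a
#' single forward-strand coordinate; strand is not part of site identity.
#'
#' @param aligned data.frame with columns `chrom`, `pos` (0-based leftmost
#'   aligned base), `strand`, `width` (aligned length), `mapq`, and
#'   `first_base_matches` (logical).
#' @param genome Optional `tn_genome` for chromosome validation.
#' @param mapq_min Minimum mapping quality retained. Default 20.
#' @param require_first_base_match Drop reads whose first aligned base
#'   mismatches the reference. Default `TRUE`.
#' @param metadata Passed to [insertion_library()].
#' @return A `tn_library`.
#' @export
call_insertions <- function(aligned, genome = NULL, mapq_min = 20,
                            require_first_base_match = TRUE, metadata = list()) {
  stopifnot(all(c("chrom", "pos", "strand", "width", "mapq") %in% names(aligned)))
  if (!is.null(genome)) {
    unknown <- setdiff(unique(aligned$chrom), names(genome$seq))
    if (length(unknown) > 0L) {
      stop("read(s) reference unknown chromosome(s): ", paste(unknown, collapse = ", "))
    }
  }
  keep <- aligned$mapq >= mapq_min
  if (require_first_base_match && "first_base_matches" %in% names(aligned)) {
    keep <- keep & aligned$first_base_matches
  }
  aligned <- aligned[keep, , drop = FALSE]
  if (nrow(aligned) == 0L) {
    return(insertion_library(data.frame(chrom = character(0), pos = integer(0),
                                        reads = numeric(0)), metadata))
  }
  junction <- ifelse(aligned$strand == "-", aligned$pos + aligned$width - 1L, aligned$pos)
  insertion_library(data.frame(chrom = aligned$chrom, pos = as.integer(junction),
                               reads = 1), metadata)
}

#' Merge insertion libraries
#'
#' Read counts are summed at identical coordinates; unique insertions are the
#' union of sites. Intended for combining replicate or haploid/diploid
#' libraries mapped to the same genome build.
#'
#' @param ... `tn_library` objects (or a single list of them).
#' @return A merged `tn_library`; `metadata$provenance` records the inputs'
#'   metadata.
#' @export
merge_libraries <- function(...) {
  libs <- list(...)
  if (length(libs) == 1L && !inherits(libs[[1]], "tn_library")) libs <- libs[[1]]
  stopifnot(length(libs) >= 1L, all(vapply(libs, inherits, logical(1), "tn_library")))
  species <- unique(unlist(lapply(libs, function(l) l$metadata$species)))
  if (length(species) > 1L) {
    stop("conflicting species metadata: ", paste(species, collapse = " vs "))
  }
  all_sites <- do.call(rbind, lapply(libs, function(l) l$sites))
  meta <- libs[[1]]$metadata
  meta$provenance <- lapply(libs, function(l) l$metadata)
  insertion_library(all_sites, meta)
}

#' Map sequences to a genome by exact matching
#'
#' A deliberately naive exact mapper for fixture-scale genomes: each sequence
#' is placed where it (or its reverse complement) matches exactly.
#' Uniquely-matching sequences receive MAPQ 42; multi-mapping sequences (e.g.
#' reads from duplicated regions) receive MAPQ 0 and are therefore removed by
#' the default [call_insertions()] filter, reproducing the mapping-driven loss
#' of signal in duplicated loci. Non-matching sequences are dropped.
#'
#' @param genome A `tn_genome` (intended for genomes up to ~10 Mb).
#' @param sequences Character vector of read sequences.
#' @return data.frame of aligned reads: `chrom`, `pos` (0-based leftmost
#'   forward-strand base), `strand`, `width`, `mapq`, `first_base_matches`.
#' @export
naive_exact_mapper <- function(genome, sequences) {
  stopifnot(inherits(genome, "tn_genome"))
  uniq <- unique(sequences)
  hit_tab <- lapply(uniq, function(s) {
    fwd <- Biostrings::DNAString(s)
    rev <- Biostrings::reverseComplement(fwd)
    hits <- list()
    for (chr in names(genome$seq)) {
      subj <- genome$seq[[chr]]
      for (st in c("+", "-")) {
        m <- Biostrings::matchPattern(if (st == "+") fwd else rev, subj, fixed = TRUE)
        if (length(m) > 0L) {
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = chr, pos = Biostrings::start(m) - 1L, strand = st,
            width = nchar(s), stringsAsFactors = FALSE)
        }
      }
    }
    if (length(hits) == 0L) return(NULL)
    hits <- do.call(rbind, hits)
    hits$mapq <- if (nrow(hits) == 1L) 42L else 0L
    hits[1L, , drop = FALSE]  # deterministic: first chromosome, leftmost, + first
  })
  names(hit_tab) <- uniq
  rows <- hit_tab[match(sequences, uniq)]
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) {
    return(data.frame(chrom = character(0), pos = integer(0), strand = character(0),
                      width = integer(0), mapq = integer(0),
                      first_base_matches = logical(0)))
  }
  out <- do.call(rbind, rows[keep])
  out$first_base_matches <- TRUE
  rownames(out) <- NULL
  out
}

#' Read an insertion map from TSV
#'
#' @param path TSV with columns `chrom`, `position` (0-based), `read_count`
#'   (header optional when exactly these three columns are present).
#' @param metadata Passed to [insertion_library()].
#' @return A `tn_library`.
#' @export
read_insertion_tsv <- function(path, metadata = list()) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("chrom", "pos", "reads")
  insertion_library(tab, metadata)
}

#' Write an insertion map to TSV
#'
#' @param lib A `tn_library`.
#' @param path Output path (columns: chrom, position (0-based), read_count).
#' @export
write_insertion_tsv <- function(lib, path) {
  tab <- lib$sites
  names(tab) <- c("chrom", "position", "read_count")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an insertion map as BedGraph
#'
#' One interval per site (half-open, width 1) with the read count as value;
#' suitable for genome-browser display.
#'
#' @param lib A `tn_library`.
#' @param path Output path.
#' @param track_name Track name header.
#' @export
write_insertion_bedgraph <- function(lib, path, track_name = "insertions") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  writeLines(sprintf("%s\t%d\t%d\t%g", lib$sites$chrom, lib$sites$pos,
                     lib$sites$pos + 1L, lib$sites$reads), con)
  invisible(path)
}

#' Read aligned reads from SAM/BAM
#'
#' Imports standard alignments (SAM is converted via [Rsamtools::asBam()]),
#' interpreting flag bit 0x10 as reverse strand and taking the aligned width
#' from the CIGAR reference span. When a genome is supplied, the
#' first-aligned-base reference match is computed by comparing the read's
#' first aligned base (strand-aware: last base of the read sequence for
#' reverse-strand alignments corresponds to the junction side handled by
#' [call_insertions()]; here the check is on the leftmost aligned base as
#' stored) to the reference; otherwise it defaults to `TRUE`.
#'
#' @param path SAM or BAM file.
#' @param genome Optional `tn_genome` for the first-base check.
#' @return data.frame suitable for [call_insertions()].
#' @export
read_alignments <- function(path, genome = NULL) {
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- if (is_sam) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else path
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "cigar", "mapq", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
  width <- GenomicAlignments_width(res$cigar)
  out <- data.frame(
    chrom = as.character(res$rname),
    pos = res$pos - 1L,   # SAM is 1-based
    strand = as.character(res$strand),
    width = width,
    mapq = res$mapq,
    stringsAsFactors = FALSE
  )
  if (!is.null(genome)) {
    first_ref <- vapply(seq_len(nrow(out)), function(i) {
      chr <- out$chrom[i]
      if (!chr %in% names(genome$seq)) return(NA_character_)
      as.character(Biostrings::subseq(genome$seq[[chr]], out$pos[i] + 1L, out$pos[i] + 1L))
    }, character(1))
    first_read <- substr(as.character(res$seq), 1L, 1L)
    out$first_base_matches <- !is.na(first_ref) & first_ref == first_read
  } else {
    out$first_base_matches <- TRUE
  }
  out
}

# reference span of a CIGAR string (M/D/N/=/X consume reference)
GenomicAlignments_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}
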