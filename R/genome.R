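#' Read a reference genome from FASTA
#'
#' Loads a (multi-record) FASTA file into a `tn_genome` object. Sequences are
#' uppercased; the fraction of soft-masked (lowercase) bases in the input is
#' retained per chromosome as `masked_fraction`.
#'
#' @param path Path to a FASTA file.
#' @return A `tn_genome` object: a list with elements `seq` (a named
#'   [Biostrings::DNAStringSet] of uppercase sequences), `masked_fraction`
#'   (named numeric, per chromosome), and `total_length` (bp).
#' @details Chromosome identifiers are taken as the first whitespace-delimited
#'   token of each FASTA header and must be unique. Only the alphabet
#'   `{A,C,G,T,N}` is permitted after uppercasing.
#' @export
read_genome <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    stop("empty FASTA file: ", path)
  }
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate chromosome id(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  chars <- as.character(raw)
  n_lower <- vapply(chars, function(s) {
    sum(strsplit(s, "")[[1]] %in% c("a", "c", "g", "t", "n"))
  }, numeric(1))
  up <- toupper(chars)
  bad <- vapply(up, function(s) any(!strsplit(s, "")[[1]] %in% c("A", "C", "G", "T", "N")),
                logical(1))
  if (any(bad)) {
    stop("non-ACGTN characters in sequence(s): ", paste(ids[bad], collapse = ", "))
  }
  if (any(nchar(up) == 0L)) {
    stop("empty sequence(s): ", paste(ids[nchar(up) == 0L], collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(up)
  names(seqs) <- ids
  tn_genome(seqs, masked_fraction = stats::setNames(n_lower / nchar(up), ids))
}

#' Construct a tn_genome from sequences
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector of
#'   uppercase DNA sequences.
#' @param masked_fraction Optional named numeric of per-chromosome soft-masked
#'   fractions (defaults to 0).
#' @return A `tn_genome` object.
#' @export
tn_genome <- function(seqs, masked_fraction = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  if (is.null(masked_fraction)) {
    masked_fraction <- stats::setNames(rep(0, length(seqs)), names(seqs))
  }
  structure(
    list(
      seq = seqs,
      masked_fraction = masked_fraction,
      total_length = sum(Biostrings::width(seqs))
    ),
    class = "tn_genome"
  )
}

#' @export
print.tn_genome <- function(x, ...) {
  cat("tn_genome:", length(x$seq), "chromosome(s),", x$total_length, "bp total\n")
  invisible(x)
}

#' Chromosome lengths of a genome
#'
#' @param genome A `tn_genome`.
#' @return Named integer vector of chromosome lengths (bp).
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "tn_genome"))
  stats::setNames(Biostrings::width(genome$seq), names(genome$seq))
}

#' Read ORF annotations from GFF3
#'
#' Parses a GFF3 file and returns one row per ORF with coordinates converted
#' from the 1-based inclusive GFF convention to the package-internal 0-based
#' half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Character vector of feature types (GFF column 3) to
#'   keep. Default `c("gene", "CDS")`.
#' @param id_attribute Attribute key holding the feature identifier. Default
#'   `"ID"`.
#' @param genome Optional `tn_genome`; when given, features on chromosomes
#'   absent from the genome are flagged in the `unknown_chrom` column.
#' @return A data.frame with columns `orf_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"` or `"-"`), `length`, and
#'   `unknown_chrom` (logical), sorted by (chrom, start). Records whose input
#'   start exceeds their end are rejected with a single warning reporting how
#'   many were dropped.
#' @export
read_orfs <- function(path, feature_types = c("gene", "CDS"), id_attribute = "ID",
                      genome = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ok_cols <- vapply(fields, length, integer(1)) >= 8L
  fields <- fields[ok_cols]
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  bad <- !is.na(starts) & !is.na(ends) & starts > ends
  if (any(bad)) {
    warning(sum(bad), " GFF record(s) with start > end rejected")
  }
  keep <- body[ok_cols][!bad]
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(c("##gff-version 3", keep), tmp)
  gr <- rtracklayer::import(tmp, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  ids <- as.character(S4Vectors::mcols(gr)[[id_attribute]])
  if (any(is.na(ids)) || any(!nzchar(ids))) {
    stop("feature(s) missing the '", id_attribute, "' attribute")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  orfs <- data.frame(
    orf_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    stringsAsFactors = FALSE
  )
  orfs$length <- orfs$end - orfs$start
  orfs$unknown_chrom <- if (is.null(genome)) FALSE else !(orfs$chrom %in% names(genome$seq))
  orfs <- orfs[order(orfs$chrom, orfs$start), , drop = FALSE]
  rownames(orfs) <- NULL
  validate_orfs(orfs, genome)
  orfs
}

#' Validate an ORF table
#'
#' Checks the internal ORF contract: unique ids, 0 <= start < end, and (when a
#' genome is supplied) end within the chromosome for known chromosomes.
#'
#' @param orfs ORF data.frame as returned by [read_orfs()].
#' @param genome Optional `tn_genome`.
#' @return The ORF table, invisibly.
#' @export
validate_orfs <- function(orfs, genome = NULL) {
  stopifnot(all(c("orf_id", "chrom", "start", "end", "strand") %in% names(orfs)))
  if (anyDuplicated(orfs$orf_id)) stop("duplicate orf_id values")
  if (any(orfs$start < 0) || any(orfs$start >= orfs$end)) {
    stop("invalid coordinates: require 0 <= start < end")
  }
  if (!all(orfs$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    known <- orfs$chrom %in% names(lens)
    if (any(known & orfs$end > lens[orfs$chrom])) {
      stop("ORF(s) extend beyond chromosome end")
    }
  }
  invisible(orfs)
}

#' Write ORFs back to GFF3
#'
#' Converts internal 0-based half-open coordinates back to the 1-based
#' inclusive GFF convention (the exact inverse of [read_orfs()]).
#'
#' @param orfs ORF data.frame.
#' @param path Output path.
#' @param feature_type Feature type for column 3. Default `"gene"`.
#' @param source Source tag for column 2.
#' @export
write_orfs_gff <- function(orfs, path, feature_type = "gene", source = "tnverdict") {
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                   orfs$chrom, source, feature_type,
                   orfs$start + 1L, orfs$end, orfs$strand, orfs$orf_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
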