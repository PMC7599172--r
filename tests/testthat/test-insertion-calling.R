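test_that("tag trimming removes the tag, honoring the post-tag offset", {
  spec0 <- trim_spec("TTGGTT", post_tag_offset = 0)
  expect_equal(trim_transposon_tag("TTGGTTACGTAC", spec0)$trimmed, "ACGTAC")

  spec3 <- trim_spec("TTGGTT", post_tag_offset = 3)
  expect_equal(trim_transposon_tag("TTGGTTACGTAC", spec3)$trimmed, "TAC")

  res <- trim_transposon_tag("ACGTACGT", spec0)
  expect_equal(length(res$trimmed), 0)
  expect_equal(res$status, "no_tag")
  expect_equal(unname(res$counts["no_tag"]), 1)

  # keep untrimmed reads when not discarding
  spec_keep <- trim_spec("TTGGTT", discard_untrimmed = FALSE)
  expect_equal(trim_transposon_tag("ACGTACGT", spec_keep)$trimmed, "ACGTACGT")
})

test_that("partial tag matches at the read start need min_overlap bases", {
  spec <- trim_spec("GATTACA", min_overlap = 4)
  # read begins with the last 4 tag bases
  expect_equal(trim_transposon_tag("TACAGGGCCC", spec)$trimmed, "GGGCCC")
  # only 3 matching bases: below the overlap floor
  expect_equal(trim_transposon_tag("ACAGGGCCC", spec)$status, "no_tag")
})

test_that("trimming rejects remnants shorter than the minimum and tolerates a
           mismatch in long tags", {
  spec <- trim_spec("TTGGTT", min_remaining_length = 2)
  expect_equal(trim_transposon_tag("ACGTTGGTTA", spec)$status, "too_short")

  long_tag <- strrep("TTGGAC", 4)  # 24 bp: one mismatch allowed
  read <- paste0(sub("^T", "A", long_tag), "CCCGGGAAA")
  expect_equal(trim_transposon_tag(read, trim_spec(long_tag))$trimmed,
               "CCCGGGAAA")
})

test_that("full internal tag matches satisfy the trimming length identity", {
  set.seed(11)
  tag <- "CATTGGAC"
  for (i in 1:50) {
    prefix <- random_seq(sample(0:10, 1))
    genomic <- random_seq(sample(5:40, 1))
    offset <- sample(0:4, 1)
    filler <- random_seq(offset)
    read <- paste0(prefix, tag, filler, genomic)
    spec <- trim_spec(tag, post_tag_offset = offset, min_overlap = 8)
    out <- trim_transposon_tag(read, spec)$trimmed
    expect_equal(nchar(prefix) + nchar(tag) + offset + nchar(out), nchar(read))
  }
})

test_that("insertion calling filters reads and collapses to forward-strand
           junctions", {
  aligned <- data.frame(
    chrom = "chrI", pos = c(150, 150, 150), strand = "+", width = 20,
    mapq = c(30, 30, 10), first_base_matches = TRUE)
  lib <- call_insertions(aligned)
  expect_equal(lib$sites$pos, 150)
  expect_equal(lib$sites$reads, 2)

  # minus-strand read whose rightmost base is 150 collapses with the plus read
  aligned2 <- data.frame(
    chrom = "chrI", pos = c(150, 131), strand = c("+", "-"), width = 20,
    mapq = 30, first_base_matches = TRUE)
  lib2 <- call_insertions(aligned2)
  expect_equal(nrow(lib2$sites), 1)
  expect_equal(lib2$sites$reads, 2)

  aligned3 <- data.frame(chrom = "chrI", pos = 10, strand = "+", width = 20,
                         mapq = 30, first_base_matches = FALSE)
  expect_equal(call_insertions(aligned3)$unique_insertions, 0)
})

test_that("insertion calling validates chromosomes and sorts its output", {
  g <- toy_genome(random_seq(500, seed = 3))
  bad <- data.frame(chrom = "chrX", pos = 10, strand = "+", width = 20,
                    mapq = 30, first_base_matches = TRUE)
  expect_error(call_insertions(bad, g), "unknown chromosome")

  set.seed(4)
  aligned <- data.frame(chrom = sample(c("a", "b"), 50, TRUE),
                        pos = sample(100, 50, TRUE), strand = "+", width = 20,
                        mapq = 30, first_base_matches = TRUE)
  lib <- call_insertions(aligned)
  expect_false(is.unsorted(order(lib$sites$chrom, lib$sites$pos)))
  # idempotent under re-collapse
  lib2 <- insertion_library(lib$sites)
  expect_equal(lib2$sites, lib$sites)
})

test_that("library merging sums counts, preserves totals, and commutes", {
  a <- toy_library(100, reads = 3)
  b <- insertion_library(data.frame(chrom = c("chrI", "chrII"), pos = c(100, 5),
                                    reads = c(2, 1)))
  m <- merge_libraries(a, b)
  expect_equal(m$sites$reads[m$sites$chrom == "chrI"], 5)
  expect_equal(m$sites$reads[m$sites$chrom == "chrII"], 1)
  expect_equal(m$total_reads, a$total_reads + b$total_reads)

  empty <- insertion_library(data.frame(chrom = character(0), pos = integer(0),
                                        reads = numeric(0)))
  expect_equal(merge_libraries(a, empty)$sites, a$sites)
  expect_equal(merge_libraries(a, b)$sites, merge_libraries(b, a)$sites)

  sc <- toy_library(1, metadata = list(species = "S_cerevisiae"))
  sp <- toy_library(1, metadata = list(species = "S_pombe"))
  expect_error(merge_libraries(sc, sp), "species")
})

test_that("the exact mapper assigns unique hits MAPQ 42 and multi-hits MAPQ 0", {
  set.seed(7)
  core <- random_seq(200)
  g <- toy_genome(paste0(core, substr(core, 1, 50)))  # 50-bp duplication
  uniq_read <- substr(core, 101, 120)
  dup_read <- substr(core, 10, 29)
  al <- naive_exact_mapper(g, c(uniq_read, dup_read))
  expect_equal(al$mapq, c(42, 0))
  expect_equal(al$pos[1], 100)

  # reverse-complement match: minus strand, forward-strand leftmost coordinate
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(uniq_read)))
  al_rc <- naive_exact_mapper(g, rc)
  expect_equal(al_rc$strand, "-")
  expect_equal(al_rc$pos, 100)

  expect_equal(nrow(naive_exact_mapper(g, "NNNNNNNNNN")), 0)
})

test_that("insertion maps round-trip through TSV and export to BedGraph", {
  lib <- insertion_library(data.frame(chrom = c("chrI", "chrI"), pos = c(5, 9),
                                      reads = c(2, 7)),
                           metadata = list(species = "synthetic"))
  p <- tempfile(fileext = ".tsv")
  write_insertion_tsv(lib, p)
  again <- read_insertion_tsv(p)
  expect_equal(again$sites, lib$sites)

  bg <- tempfile(fileext = ".bedgraph")
  write_insertion_bedgraph(lib, bg)
  expect_equal(readLines(bg)[2], "chrI\t5\t6\t2")
})

test_that("SAM alignments are imported with 0-based coordinates and strand", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrI\tLN:1000",
    "r1\t0\tchrI\t151\t42\t20M\t*\t0\t0\tACGTACGTACGTACGTACGT\t*",
    "r2\t16\tchrI\t132\t42\t20M\t*\t0\t0\tACGTACGTACGTACGTACGT\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTACGTACGTACGT\t*"), sam)
  al <- read_alignments(sam)
  expect_equal(nrow(al), 2)
  expect_equal(al$pos, c(150, 131))
  expect_equal(al$strand, c("+", "-"))
  expect_equal(al$width, c(20, 20))
  lib <- call_insertions(al, mapq_min = 20)
  expect_equal(lib$sites$pos, 150)  # both reads collapse onto one junction
  expect_equal(lib$sites$reads, 2)
})
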