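# Fixture builders shared across the test files. Everything is generated in
# code; no binary data.

write_temp_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  path
}

write_temp_gff <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

random_seq <- function(n, seed = NULL, letters = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# genome of a single chromosome
toy_genome <- function(seq, chrom = "chrI") {
  tn_genome(stats::setNames(c(seq), chrom))
}

toy_orfs <- function(start, end, strand = "+", chrom = "chrI",
                     orf_id = sprintf("g%02d", seq_along(start))) {
  data.frame(orf_id = orf_id, chrom = chrom, start = start, end = end,
             strand = strand, length = end - start, stringsAsFactors = FALSE)
}

toy_library <- function(pos, reads = 1, chrom = "chrI", metadata = list()) {
  insertion_library(data.frame(chrom = chrom, pos = pos, reads = reads),
                    metadata = metadata)
}

# sliding-window degenerate-motif oracle; N in the genome matches nothing
naive_motif_scan <- function(seq, pattern) {
  g <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  m <- length(p)
  hits <- integer(0)
  for (i in seq_len(length(g) - m + 1L)) {
    win <- g[i:(i + m - 1L)]
    ok <- all(win != "N" & (p == "N" | win == p))
    if (ok) hits <- c(hits, i - 1L)  # 0-based
  }
  hits
}

# brute-force Freedom Index: longest run of insertion-free bases / length
naive_fi <- function(start, end, positions) {
  hit <- logical(end - start)
  p <- positions[positions >= start & positions < end]
  hit[p - start + 1L] <- TRUE
  if (!any(hit)) return(1)
  runs <- rle(!hit)
  free <- runs$lengths[runs$values]
  if (length(free) == 0L) return(0)
  max(free) / (end - start)
}

# pairwise-ranking (Mann-Whitney) AUC estimator
rank_auc <- function(labels, scores) {
  sp <- scores[labels == "essential"]
  sn <- scores[labels == "non_essential"]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# a feature table + training set where the two classes are linearly separable
separable_study <- function(n_per_class = 30, seed = 1) {
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(2 * n_per_class))
  ess <- rep(c(TRUE, FALSE), each = n_per_class)
  feats <- data.frame(
    orf_id = ids, chrom = "chrI", length = 1000L,
    insertions = ifelse(ess, rpois(2 * n_per_class, 0.2), 20 + rpois(2 * n_per_class, 5)),
    reads = 0, neighborhood_index = ifelse(ess, 0.05, 1) + runif(2 * n_per_class, 0, 0.05),
    freedom_index = ifelse(ess, 0.95, 0.1) + runif(2 * n_per_class, 0, 0.04),
    insertions_100_upstream = rpois(2 * n_per_class, 1),
    reads_per_length = 0, insertions_per_length = 0,
    n_window = 100L, no_local_data = FALSE, stringsAsFactors = FALSE)
  feats$reads <- feats$insertions * 50
  feats$reads_per_length <- feats$reads / feats$length
  feats$insertions_per_length <- feats$insertions / feats$length
  class(feats) <- c("tn_features", "data.frame")
  training <- training_set(data.frame(
    orf_id = ids, label = ifelse(ess, "essential", "non_essential"),
    stringsAsFactors = FALSE))
  list(features = feats, training = training)
}

# small simulated study wrapped as a bundle (with importances)
sim_bundle <- function(seed, study_id = paste0("sim", seed), ...) {
  cfg <- sim_config(seed = seed, chrom_length = 2e5, n_orfs = 100,
                    n_insertions = 2e4, jackpot_rate = 0, ...)
  gen <- simulate_genome(cfg)
  sim <- simulate_library(gen$genome, gen$orfs, gen$labels, cfg)
  feats <- compute_features(sim$library, gen$orfs, gen$genome)
  tr <- training_set(gen$labels)
  fit <- fit_and_predict(feats, tr, 0.5)
  study_bundle(study_id, "synthetic", cfg$transposon, feats, tr,
               verdicts = fit$verdicts, importances = fit$importances)
}
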