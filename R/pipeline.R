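#' @keywords internal
write_manifest <- function(out_dir, step, config, seed, files) {
  digests <- tools::md5sum(files[file.exists(files)])
  manifest <- list(
    step = step,
    package_version = as.character(utils::packageVersion("tnverdict")),
    seed = seed,
    config = config,
    files = as.list(digests),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, paste0(step, ".manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Run the simulation stage
#'
#' Generates a synthetic study (genome FASTA, ORF GFF3, true-label CSV,
#' insertion-map TSV, optional tagged FASTQ) under `out_dir`, with a manifest
#' recording the configuration, seed and file digests.
#'
#' @param config A `tn_sim_config`.
#' @param out_dir Output directory (created if needed).
#' @param emit_fastq Also write tagged reads via [emit_reads()]. Default
#'   `FALSE`.
#' @param trimspec `tn_trimspec` used when `emit_fastq = TRUE`.
#' @return Invisibly, a list of the generated objects and file paths.
#' @export
run_simulation <- function(config, out_dir, emit_fastq = FALSE,
                           trimspec = trim_spec("TTGGTTACCGACC")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- simulate_genome(config)
  sim <- simulate_library(gen$genome, gen$orfs, gen$labels, config)
  paths <- list(
    fasta = file.path(out_dir, "genome.fa"),
    gff = file.path(out_dir, "orfs.gff3"),
    labels = file.path(out_dir, "labels.csv"),
    insertions = file.path(out_dir, "insertions.tsv")
  )
  Biostrings::writeXStringSet(gen$genome$seq, paths$fasta)
  write_orfs_gff(gen$orfs, paths$gff)
  utils::write.csv(gen$labels, paths$labels, row.names = FALSE, quote = FALSE)
  write_insertion_tsv(sim$library, paths$insertions)
  if (emit_fastq) {
    paths$fastq <- file.path(out_dir, "reads.fastq")
    emit_reads(sim$library, gen$genome, trimspec, paths$fastq,
               seed = config$seed + 2L)
  }
  write_manifest(out_dir, "simulate", unclass(config), config$seed,
                 unlist(paths))
  invisible(list(genome = gen$genome, orfs = gen$orfs, labels = gen$labels,
                 library = sim$library, truth = sim$truth,
                 targets = sim$targets, paths = paths))
}

#' Run the insertion-calling stage
#'
#' Trims the transposon tag from raw reads, maps the genomic portions with
#' the exact mapper, applies the read filters and writes the deduplicated
#' insertion map. Counts at every filtering step are logged in the manifest.
#'
#' @param fastq Path to tagged reads.
#' @param genome_fasta Path to the reference FASTA.
#' @param trimspec A `tn_trimspec`.
#' @param out_dir Output directory.
#' @param mapq_min,require_first_base_match Passed to [call_insertions()].
#' @return Invisibly, the called `tn_library` (also written to
#'   `insertions.tsv`).
#' @export
run_calling <- function(fastq, genome_fasta, trimspec, out_dir,
                        mapq_min = 20, require_first_base_match = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- read_genome(genome_fasta)
  reads <- read_fastq_sequences(fastq)
  trimmed <- trim_transposon_tag(reads, trimspec)
  aligned <- naive_exact_mapper(genome, trimmed$trimmed)
  lib <- call_insertions(aligned, genome, mapq_min = mapq_min,
                         require_first_base_match = require_first_base_match)
  path <- file.path(out_dir, "insertions.tsv")
  write_insertion_tsv(lib, path)
  write_manifest(out_dir, "call",
                 list(fastq = fastq, genome = genome_fasta,
                      trimspec = unclass(trimspec), mapq_min = mapq_min,
                      counts = c(as.list(trimmed$counts),
                                 mapped = nrow(aligned),
                                 passed_filters = lib$total_reads,
                                 sites = lib$unique_insertions)),
                 NA, path)
  invisible(lib)
}

#' Run the classification stage
#'
#' Computes features, curates ORFs, cross-validates the classifier, selects
#' the verdict threshold on pooled out-of-fold scores, fits the final model
#' and writes verdicts, importances and a JSON report.
#'
#' @param lib A `tn_library` (or path to an insertion TSV).
#' @param genome A `tn_genome` (or path to FASTA).
#' @param orfs ORF data.frame (or path to GFF3).
#' @param training A `tn_training` (or path to a labels CSV).
#' @param out_dir Output directory.
#' @param motif Optional motif name (`"TTAA"`, `"TNNNNA"`, `"none"`).
#' @param threshold_method `"youden"` (default) or `"euclidean"`.
#' @param k,n_trees,seed Classifier parameters (defaults 5, 200, 0).
#' @param curation Optional precomputed `tn_curation`; `NULL` runs
#'   [curate_orfs()] with defaults.
#' @return Invisibly, a list with `features`, `cv`, `threshold`, `fit`,
#'   `stats`, `curation`.
#' @export
run_classification <- function(lib, genome, orfs, training, out_dir,
                               motif = "none",
                               threshold_method = c("youden", "euclidean"),
                               k = 5L, n_trees = 200L, seed = 0L,
                               curation = NULL) {
  threshold_method <- match.arg(threshold_method)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.character(orfs)) orfs <- read_orfs(orfs, genome = genome)
  if (is.character(lib)) lib <- read_insertion_tsv(lib)
  if (is.character(training)) training <- read_training_csv(training)
  mot <- target_motif(motif)
  targets <- if (is.null(mot)) NULL else scan_target_sites(genome, mot)
  tc <- if (is.null(targets)) NULL else count_targets_per_orf(targets, orfs)
  features <- compute_features(lib, orfs, genome, target_counts = tc)
  if (is.null(curation)) curation <- curate_orfs(orfs, genome)
  training <- training_set(
    as.data.frame(training)[training$orf_id %in%
                              curation$orf_id[curation$kept], , drop = FALSE])
  cv <- cross_validate(features, training, k = k, n_trees = n_trees, seed = seed)
  thr <- roc_and_threshold(training$label, cv$oof_scores[training$orf_id],
                           method = threshold_method)
  fit <- fit_and_predict(features, training, thr$threshold, curation = curation,
                         n_trees = n_trees, seed = seed)
  stats <- summarize_library(lib, orfs, targets)
  paths <- list(verdicts = file.path(out_dir, "verdicts.csv"),
                importances = file.path(out_dir, "importances.tsv"),
                features = file.path(out_dir, "features.tsv"),
                report = file.path(out_dir, "report.json"))
  write_verdicts(fit, paths$verdicts)
  utils::write.table(data.frame(feature = names(fit$importances),
                                importance = fit$importances),
                     paths$importances, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_features(features, paths$features)
  report <- list(
    library_stats = as.list(as.data.frame(stats)),
    cv_auc_mean = cv$auc_mean, cv_auc_folds = cv$auc_folds,
    threshold = thr$threshold, threshold_method = threshold_method,
    youden_j = thr$j,
    n_essential_calls = sum(fit$verdicts$verdict == "essential"),
    n_excluded = sum(fit$verdicts$verdict == "excluded"),
    importances = as.list(fit$importances)
  )
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       na = "null")
  write_manifest(out_dir, "classify",
                 list(motif = motif, threshold_method = threshold_method,
                      k = k, n_trees = n_trees),
                 seed, unlist(paths))
  invisible(list(features = features, cv = cv, threshold = thr, fit = fit,
                 stats = stats, curation = curation))
}

#' Run the cross-study comparison stage
#'
#' Computes the all-pairs transfer-learning AUC matrix and (when importances
#' are present) the feature-importance correlation matrix.
#'
#' @param bundles List of `tn_bundle` objects.
#' @param out_dir Output directory.
#' @param train_fraction,seed,n_trees Passed to [transfer_matrix()].
#' @return Invisibly, list with `transfer` and `importance_cor` matrices.
#' @export
run_comparison <- function(bundles, out_dir, train_fraction = 0.8, seed = 0L,
                           n_trees = 200L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tm <- transfer_matrix(bundles, train_fraction, seed = seed, n_trees = n_trees)
  ic <- tryCatch(importance_correlation(bundles), error = function(e) NULL)
  utils::write.table(tm, file.path(out_dir, "transfer_auc.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  if (!is.null(ic)) {
    utils::write.table(ic, file.path(out_dir, "importance_correlation.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  write_manifest(out_dir, "compare",
                 list(train_fraction = train_fraction, n_trees = n_trees),
                 seed, file.path(out_dir, c("transfer_auc.tsv",
                                            "importance_correlation.tsv")))
  invisible(list(transfer = tm, importance_cor = ic))
}
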