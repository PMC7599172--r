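#' Build a training set from orthologs of two labeled species
#'
#' For a species without systematic deletion data, training labels are
#' transferred from two model species: a target gene is labeled essential iff
#' its orthologs in BOTH source species are essential, non-essential iff both
#' are non-essential; genes with conflicting or missing ortholog labels are
#' excluded. Ambiguous ortholog mappings (a target gene appearing in more
#' than one mapping row) are dropped and counted.
#'
#' @param labels_a,labels_b Named character vectors (or data.frames with
#'   `orf_id`, `label`) of `{essential, non_essential}` labels in the two
#'   source species.
#' @param ortholog_map data.frame with columns `source_id_a`, `source_id_b`,
#'   `target_id`.
#' @param target_orfs Character vector of valid target-species ORF ids.
#' @return A `tn_training` object: data.frame (`orf_id`, `label`,
#'   `provenance`) plus attributes `counts` (essential, non_essential,
#'   conflicting, unlabeled, ambiguous_dropped).
#' @export
build_ortholog_training_set <- function(labels_a, labels_b, ortholog_map,
                                        target_orfs) {
  labels_a <- as_label_vector(labels_a)
  labels_b <- as_label_vector(labels_b)
  stopifnot(all(c("source_id_a", "source_id_b", "target_id") %in% names(ortholog_map)))
  dup <- ortholog_map$target_id[duplicated(ortholog_map$target_id)]
  n_ambig <- length(unique(dup))
  map <- ortholog_map[!ortholog_map$target_id %in% dup, , drop = FALSE]
  map <- map[map$target_id %in% target_orfs, , drop = FALSE]
  la <- labels_a[map$source_id_a]
  lb <- labels_b[map$source_id_b]
  label <- rep(NA_character_, nrow(map))
  label[!is.na(la) & !is.na(lb) & la == "essential" & lb == "essential"] <- "essential"
  label[!is.na(la) & !is.na(lb) & la == "non_essential" & lb == "non_essential"] <- "non_essential"
  keep <- !is.na(label)
  if (!any(keep)) stop("no target genes received a consistent ortholog label")
  out <- data.frame(orf_id = map$target_id[keep], label = label[keep],
                    provenance = "ortholog_transfer", stringsAsFactors = FALSE)
  counts <- c(essential = sum(out$label == "essential"),
              non_essential = sum(out$label == "non_essential"),
              conflicting = sum(!keep & !is.na(la) & !is.na(lb)),
              unlabeled = sum(is.na(la) | is.na(lb)),
              ambiguous_dropped = n_ambig)
  training_set(out, counts = counts)
}

#' Construct a training set
#'
#' @param df data.frame with columns `orf_id`, `label` (and optionally
#'   `provenance`).
#' @param counts Optional named counts attached as an attribute.
#' @return A `tn_training` object.
#' @export
training_set <- function(df, counts = NULL) {
  stopifnot(all(c("orf_id", "label") %in% names(df)))
  if (anyDuplicated(df$orf_id)) stop("duplicate orf_id in training set")
  if (!all(df$label %in% c("essential", "non_essential"))) {
    stop("labels must be 'essential' or 'non_essential'")
  }
  if (!"provenance" %in% names(df)) df$provenance <- "native"
  rownames(df) <- NULL
  structure(df, class = c("tn_training", "data.frame"), counts = counts)
}

#' Read training labels from CSV
#'
#' @param path CSV with columns `orf_id`, `label`.
#' @return A `tn_training` object.
#' @export
read_training_csv <- function(path) {
  training_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Curate ORFs before classification
#'
#' Removes ORFs that cannot be assessed reliably, in order of precedence:
#' (1) duplicated/repeated regions, where short-read mapping quality filtering
#' erases insertions and genes are falsely predicted essential; (2) genes
#' shorter than `min_length` bp, whose low insertion probability inflates
#' false essential calls; (3) genes deleted from the assayed strains; (4)
#' user-listed dubious annotations. Duplication is detected as the fraction
#' of read-length k-mers of the ORF that occur more than once in the genome
#' (either strand) exceeding `dup_cutoff`.
#'
#' @param orfs ORF data.frame.
#' @param genome A `tn_genome`.
#' @param deleted_genes Character vector of ORF ids deleted in the strains.
#' @param exclusion_list Character vector of dubious ORF ids.
#' @param k K-mer length (read length). Default 75.
#' @param dup_cutoff Multi-mapping k-mer fraction above which an ORF is
#'   removed. Default 0.5.
#' @param min_length Minimum ORF length retained (bp). Default 300.
#' @param mappability Optional named numeric of precomputed multi-mapping
#'   k-mer fractions per ORF (skips the k-mer scan).
#' @return A `tn_curation` data.frame: `orf_id`, `kept`, `reason` (one of
#'   `duplicated_region`, `length_lt_300`, `deleted_in_strain`,
#'   `dubious_annotation`, `ok`).
#' @export
curate_orfs <- function(orfs, genome, deleted_genes = character(0),
                        exclusion_list = character(0), k = 75L,
                        dup_cutoff = 0.5, min_length = 300L,
                        mappability = NULL) {
  if (is.null(mappability)) {
    mappability <- orf_multimap_fraction(orfs, genome, k)
  }
  reason <- rep("ok", nrow(orfs))
  frac <- mappability[orfs$orf_id]
  frac[is.na(frac)] <- 0
  reason[frac > dup_cutoff] <- "duplicated_region"
  reason[reason == "ok" & orfs$length < min_length] <- "length_lt_300"
  reason[reason == "ok" & orfs$orf_id %in% deleted_genes] <- "deleted_in_strain"
  reason[reason == "ok" & orfs$orf_id %in% exclusion_list] <- "dubious_annotation"
  out <- data.frame(orf_id = orfs$orf_id, kept = reason == "ok", reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("tn_curation", "data.frame")
  out
}

#' Fraction of multi-mapping k-mers per ORF
#'
#' For each ORF, the fraction of its length-`k` subsequences that occur more
#' than once in the genome (forward or reverse strand). ORFs shorter than `k`
#' get 0 (they are handled by the length filter).
#'
#' @param orfs ORF data.frame.
#' @param genome A `tn_genome`.
#' @param k K-mer length. Default 75.
#' @return Named numeric vector per `orf_id`.
#' @export
orf_multimap_fraction <- function(orfs, genome, k = 75L) {
  res <- stats::setNames(numeric(nrow(orfs)), orfs$orf_id)
  eligible <- which(orfs$length >= k)
  if (length(eligible) == 0L) return(res)
  kmers <- lapply(eligible, function(i) {
    s <- genome$seq[[orfs$chrom[i]]]
    n_k <- orfs$length[i] - k + 1L
    starts <- orfs$start[i] + seq_len(n_k)  # 1-based starts
    as.character(Biostrings::extractAt(s, IRanges::IRanges(starts, width = k)))
  })
  flat <- unlist(kmers, use.names = FALSE)
  uniq <- unique(flat)
  pd <- Biostrings::PDict(uniq)
  counts <- rep(0L, length(uniq))
  for (chr in names(genome$seq)) {
    counts <- counts + Biostrings::countPDict(pd, genome$seq[[chr]]) +
      Biostrings::countPDict(pd, Biostrings::reverseComplement(genome$seq[[chr]]))
  }
  multi <- stats::setNames(counts > 1L, uniq)
  idx <- 1L
  for (j in seq_along(eligible)) {
    km <- kmers[[j]]
    res[orfs$orf_id[eligible[j]]] <- mean(multi[km])
  }
  res
}

#' Filter training genes whose insertion pattern contradicts their label
#'
#' A reproducible surrogate for visual screening of an ortholog-derived
#' training set: a gene labeled essential is removed when it shows clearly
#' non-essential insertion behaviour — Neighborhood Index at least `ni_min`,
#' Freedom Index at most `fi_max`, in a data-rich neighborhood (at least
#' `min_window_hits` insertions in the NI window). Non-essential labels are
#' never removed.
#'
#' @param training A `tn_training` object.
#' @param features A `tn_features` table (same library).
#' @param ni_min NI threshold; default the median NI of non-essential-labeled
#'   genes.
#' @param fi_max FI threshold. Default 0.25.
#' @param min_window_hits Minimum NI-window insertions. Default 20.
#' @return A `tn_training` with contradictory genes removed; attribute
#'   `removed` lists them.
#' @export
contradiction_filter <- function(training, features, ni_min = NULL,
                                 fi_max = 0.25, min_window_hits = 20L) {
  f <- as.data.frame(features)
  rownames(f) <- f$orf_id
  f <- f[training$orf_id, , drop = FALSE]
  if (is.null(ni_min)) {
    ni_min <- stats::median(f$neighborhood_index[training$label == "non_essential"])
  }
  fire <- training$label == "essential" &
    f$neighborhood_index >= ni_min &
    f$freedom_index <= fi_max &
    f$n_window >= min_window_hits
  removed <- training$orf_id[fire]
  out <- training_set(as.data.frame(training)[!fire, , drop = FALSE],
                      counts = attr(training, "counts"))
  attr(out, "removed") <- removed
  out
}

# feature matrix (rows = orf_ids) for model fitting
.feature_matrix <- function(features, orf_ids, cols = NULL) {
  f <- as.data.frame(features)
  rownames(f) <- f$orf_id
  if (is.null(cols)) cols <- feature_columns(features)
  missing <- setdiff(orf_ids, f$orf_id)
  if (length(missing) > 0L) {
    stop("features missing for ", length(missing), " ORF(s), e.g. ", missing[1L])
  }
  as.matrix(f[orf_ids, cols, drop = FALSE])
}

# one deterministic random-forest fit
.fit_rf <- function(x, y, n_trees, seed) {
  set.seed(seed)
  randomForest::randomForest(x = x, y = factor(y, levels = c("non_essential", "essential")),
                             ntree = n_trees)
}

.rf_prob <- function(model, x) {
  unname(stats::predict(model, x, type = "prob")[, "essential"])
}

# stratified fold assignment, deterministic given seed
.stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validate the essentiality classifier
#'
#' Stratified k-fold cross-validation of a Random Forest (default 200 trees)
#' on the labeled genes, producing an out-of-fold essentiality probability
#' for every training gene and per-fold AUCs. Deterministic given `seed`.
#'
#' @param features A `tn_features` table.
#' @param training A `tn_training` object (both classes present).
#' @param k Folds. Default 5.
#' @param n_trees Trees per forest. Default 200.
#' @param seed RNG seed. Default 0.
#' @param feature_cols Optional explicit feature column subset.
#' @return List with `oof_scores` (named, per training gene), `auc_folds`,
#'   `auc_mean`, and `folds` (assignment).
#' @export
cross_validate <- function(features, training, k = 5L, n_trees = 200L,
                           seed = 0L, feature_cols = NULL) {
  labels <- stats::setNames(training$label, training$orf_id)
  if (length(unique(labels)) < 2L) stop("training set contains a single class")
  if (min(table(labels)) < k) stop("fewer labeled genes than folds in one class")
  x <- .feature_matrix(features, names(labels), feature_cols)
  fold <- .stratified_folds(labels, k, seed)
  oof <- stats::setNames(rep(NA_real_, length(labels)), names(labels))
  auc_folds <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- .fit_rf(x[tr, , drop = FALSE], labels[tr], n_trees, seed + f)
    p <- .rf_prob(model, x[!tr, , drop = FALSE])
    oof[!tr] <- p
    auc_folds[f] <- roc_curve(labels[!tr], p)$auc
  }
  list(oof_scores = oof, auc_folds = auc_folds, auc_mean = mean(auc_folds),
       folds = stats::setNames(fold, names(labels)))
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a classification threshold (predict
#' essential when score >= threshold) and returns the resulting curve with
#' its trapezoidal AUC. The AUC equals the probability that a randomly chosen
#' essential gene is ranked above a randomly chosen non-essential one.
#'
#' @param labels Character vector in `{essential, non_essential}` (essential
#'   = positive class).
#' @param scores Numeric scores, higher = more essential.
#' @return A `tn_roc` object: data.frame (`threshold`, `fpr`, `tpr`) from
#'   (0,0) to (1,1), with attribute `auc`, accessible as `$auc`.
#' @export
roc_curve <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  pos <- labels == "essential"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  if (length(unique(scores)) < 2L) stop("constant scores give a degenerate ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  # trapezoidal integral over the sweep
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc), class = "tn_roc")
}

#' @export
print.tn_roc <- function(x, ...) {
  cat("tn_roc:", nrow(x$curve), "points, AUC =", format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Choose a verdict threshold on the ROC curve
#'
#' Two standard criteria: `"youden"` maximizes the vertical distance between
#' the curve and the chance diagonal (J = TPR - FPR); `"euclidean"` minimizes
#' the distance between the curve and the perfect-classifier corner (0, 1).
#' Ties are broken toward lower FPR.
#'
#' @param labels,scores As in [roc_curve()].
#' @param method `"youden"` (default) or `"euclidean"`.
#' @return List with `roc` (the `tn_roc`), `method`, `threshold`, `tpr`,
#'   `fpr`, `j` (Youden J at the optimum) and `distance` (Euclidean distance
#'   at the optimum).
#' @export
roc_and_threshold <- function(labels, scores, method = c("youden", "euclidean")) {
  method <- match.arg(method)
  roc <- roc_curve(labels, scores)
  cv <- roc$curve[is.finite(roc$curve$threshold), , drop = FALSE]
  crit <- if (method == "youden") {
    cv$tpr - cv$fpr
  } else {
    -sqrt((1 - cv$tpr)^2 + cv$fpr^2)
  }
  best <- which(crit == max(crit))
  best <- best[which.min(cv$fpr[best])]
  list(roc = roc, method = method, threshold = cv$threshold[best],
       tpr = cv$tpr[best], fpr = cv$fpr[best],
       j = cv$tpr[best] - cv$fpr[best],
       distance = sqrt((1 - cv$tpr[best])^2 + cv$fpr[best]^2))
}

#' Fit the final model and emit per-ORF verdicts
#'
#' Fits the Random Forest on the full training set and predicts an
#' essentiality probability for every ORF in the feature table. An ORF is
#' called essential when its probability reaches `threshold`; ORFs removed by
#' curation are carried as `excluded` with their curation reason regardless
#' of probability.
#'
#' @param features A `tn_features` table (all curated ORFs).
#' @param training A `tn_training` object.
#' @param threshold Probability threshold from [roc_and_threshold()].
#' @param curation Optional `tn_curation` from [curate_orfs()].
#' @param n_trees,seed Forest parameters. Defaults 200 and 0.
#' @param feature_cols Optional explicit feature column subset.
#' @return List with `verdicts` (data.frame `orf_id`, `probability`,
#'   `verdict`, `reason`), `importances` (named, impurity-based, normalized
#'   to sum 1), `model`, and `threshold`.
#' @export
fit_and_predict <- function(features, training, threshold, curation = NULL,
                            n_trees = 200L, seed = 0L, feature_cols = NULL) {
  labels <- stats::setNames(training$label, training$orf_id)
  if (is.null(feature_cols)) feature_cols <- feature_columns(features)
  x_train <- .feature_matrix(features, names(labels), feature_cols)
  model <- .fit_rf(x_train, labels, n_trees, seed)
  x_all <- .feature_matrix(features, features$orf_id, feature_cols)
  prob <- .rf_prob(model, x_all)
  verdict <- ifelse(prob >= threshold, "essential", "non_essential")
  reason <- rep("ok", nrow(features))
  if (!is.null(curation)) {
    cm <- match(features$orf_id, curation$orf_id)
    excl <- !is.na(cm) & !curation$kept[cm]
    verdict[excl] <- "excluded"
    reason[excl] <- curation$reason[cm[excl]]
  }
  imp <- randomForest::importance(model)[, 1L]
  importances <- imp / sum(imp)
  verdicts <- data.frame(orf_id = features$orf_id, probability = prob,
                         verdict = verdict, reason = reason,
                         stringsAsFactors = FALSE)
  list(verdicts = verdicts, importances = importances, model = model,
       threshold = threshold)
}

#' AUC as a function of a minimum target-count cutoff
#'
#' For motif-bound transposons, genes with few target sequences are hard to
#' classify. This sweep re-runs cross-validation on training subsets filtered
#' to genes with at least `cutoff` target sequences, for each cutoff.
#'
#' @param features A `tn_features` table containing `n_targets`.
#' @param training A `tn_training` object.
#' @param cutoffs Integer vector of minimum target counts. Default 0:10.
#' @param k,n_trees,seed Cross-validation parameters.
#' @return data.frame with `min_targets`, `auc`, `n_genes`; cutoffs leaving a
#'   single class are skipped with a warning.
#' @export
auc_vs_min_targets <- function(features, training, cutoffs = 0:10, k = 5L,
                               n_trees = 200L, seed = 0L) {
  if (!"n_targets" %in% names(features)) stop("feature table lacks n_targets")
  nt <- stats::setNames(features$n_targets, features$orf_id)
  rows <- lapply(cutoffs, function(cut) {
    keep <- training$orf_id[nt[training$orf_id] >= cut]
    sub <- as.data.frame(training)[training$orf_id %in% keep, , drop = FALSE]
    if (length(unique(sub$label)) < 2L || min(table(sub$label)) < k) {
      warning("cutoff ", cut, " leaves a degenerate training set; skipped")
      return(NULL)
    }
    cvr <- cross_validate(features, training_set(sub), k = k, n_trees = n_trees,
                          seed = seed)
    data.frame(min_targets = cut, auc = cvr$auc_mean, n_genes = nrow(sub))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Write verdicts to CSV
#'
#' @param fit Result of [fit_and_predict()] (or its `verdicts` data.frame).
#' @param path Output path.
#' @export
write_verdicts <- function(fit, path) {
  v <- if (is.data.frame(fit)) fit else fit$verdicts
  utils::write.csv(v, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
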