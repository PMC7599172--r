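#' Bundle one study's tables for cross-study analysis
#'
#' @param study_id Short study label (e.g. `"CaAcDs"`).
#' @param species Species label.
#' @param transposon Transposon label.
#' @param features A `tn_features` table.
#' @param training A `tn_training` object.
#' @param verdicts Optional verdict data.frame from [fit_and_predict()].
#' @param importances Optional named importance vector.
#' @return A `tn_bundle` object.
#' @export
study_bundle <- function(study_id, species, transposon, features, training,
                         verdicts = NULL, importances = NULL) {
  structure(
    list(study_id = study_id, species = species, transposon = transposon,
         features = features, training = training, verdicts = verdicts,
         importances = importances),
    class = "tn_bundle"
  )
}

# feature columns shared by name across bundles
shared_feature_columns <- function(...) {
  bundles <- list(...)
  if (length(bundles) == 1L && !inherits(bundles[[1]], "tn_bundle")) bundles <- bundles[[1]]
  Reduce(intersect, lapply(bundles, function(b) feature_columns(b$features)))
}

# stratified sample of a fraction of labeled genes, deterministic given seed
.stratified_sample <- function(labels, fraction, seed) {
  set.seed(seed)
  take <- unlist(lapply(unique(labels), function(cl) {
    idx <- names(labels)[labels == cl]
    sample(idx, max(1L, round(fraction * length(idx))))
  }))
  take
}

#' Transfer-learning AUC between two studies
#'
#' Fits a Random Forest on a stratified `train_fraction` sample of the
#' training study's labeled genes (features intersected by name across the
#' two studies) and evaluates the AUC on a stratified 20% sample of the test
#' study's labeled genes, excluding any gene used for training. With
#' `train_bundle == test_bundle` this is a within-study 80/20 holdout.
#'
#' @param train_bundle,test_bundle `tn_bundle` objects.
#' @param train_fraction Fraction of the training study's labels used for
#'   fitting. Default 0.8.
#' @param seed RNG seed.
#' @param n_trees Trees. Default 200.
#' @return List with `auc`, `n_train`, `n_test`, `features_used`.
#' @export
transfer_auc <- function(train_bundle, test_bundle, train_fraction = 0.8,
                         seed = 0L, n_trees = 200L) {
  cols <- shared_feature_columns(train_bundle, test_bundle)
  if (length(cols) == 0L) stop("no shared feature columns between studies")
  tr_labels <- stats::setNames(train_bundle$training$label, train_bundle$training$orf_id)
  te_labels <- stats::setNames(test_bundle$training$label, test_bundle$training$orf_id)
  tr_ids <- .stratified_sample(tr_labels, train_fraction, seed)
  te_pool <- te_labels[setdiff(names(te_labels), tr_ids)]
  if (length(unique(te_pool)) < 2L) stop("test pool lacks both classes")
  te_frac <- (1 - train_fraction) * length(te_labels) / length(te_pool)
  te_ids <- .stratified_sample(te_pool, min(1, te_frac), seed + 1L)
  x_tr <- .feature_matrix(train_bundle$features, tr_ids, cols)
  x_te <- .feature_matrix(test_bundle$features, te_ids, cols)
  model <- .fit_rf(x_tr, tr_labels[tr_ids], n_trees, seed)
  p <- .rf_prob(model, x_te)
  list(auc = roc_curve(te_labels[te_ids], p)$auc,
       n_train = length(tr_ids), n_test = length(te_ids), features_used = cols)
}

#' All-pairs transfer-learning AUC matrix
#'
#' @param bundles List of `tn_bundle` objects.
#' @param train_fraction,seed,n_trees As in [transfer_auc()].
#' @return Square matrix of AUCs (rows = training study, columns = test
#'   study); the diagonal holds within-study 80/20 holdout AUCs.
#' @export
transfer_matrix <- function(bundles, train_fraction = 0.8, seed = 0L,
                            n_trees = 200L) {
  ids <- vapply(bundles, function(b) b$study_id, character(1))
  m <- matrix(NA_real_, length(bundles), length(bundles), dimnames = list(ids, ids))
  for (i in seq_along(bundles)) {
    for (j in seq_along(bundles)) {
      m[i, j] <- transfer_auc(bundles[[i]], bundles[[j]], train_fraction,
                              seed = seed, n_trees = n_trees)$auc
    }
  }
  m
}

#' Feature-importance correlation across studies
#'
#' Pearson correlation of relative feature-importance vectors for every pair
#' of studies, over the feature schema shared by name.
#'
#' @param bundles List of `tn_bundle` objects carrying `importances`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
importance_correlation <- function(bundles) {
  cols <- Reduce(intersect, lapply(bundles, function(b) names(b$importances)))
  if (length(cols) < 3L) stop("fewer than 3 shared features; correlation unstable")
  ids <- vapply(bundles, function(b) b$study_id, character(1))
  vecs <- vapply(bundles, function(b) b$importances[cols], numeric(length(cols)))
  m <- stats::cor(vecs, method = "pearson")
  dimnames(m) <- list(ids, ids)
  m
}

.essential_set <- function(verdicts) {
  v <- if (is.data.frame(verdicts)) verdicts else verdicts$verdicts
  list(essential = v$orf_id[v$verdict == "essential"],
       universe = v$orf_id[v$verdict != "excluded"])
}

#' Three-way verdict agreement between two studies and a reference
#'
#' Partitions the common (non-excluded) ORF universe by essentiality in
#' study A, study B, and a reference label set, and reports the genes called
#' essential by both studies but non-essential in the reference (the
#' candidate false positives or reference errors).
#'
#' @param verdicts_a,verdicts_b Verdict tables (or [fit_and_predict()]
#'   results).
#' @param reference_labels Named label vector or data.frame (`orf_id`,
#'   `label`).
#' @return List with `counts` (2x2x2 table over A/B/reference essentiality),
#'   `both_not_reference` (character vector), and `universe_size`.
#' @export
verdict_agreement <- function(verdicts_a, verdicts_b, reference_labels) {
  a <- .essential_set(verdicts_a)
  b <- .essential_set(verdicts_b)
  ref <- as_label_vector(reference_labels)
  universe <- intersect(intersect(a$universe, b$universe), names(ref))
  if (length(universe) == 0L) stop("empty common ORF universe")
  fa <- factor(universe %in% a$essential, levels = c(FALSE, TRUE),
               labels = c("non_essential", "essential"))
  fb <- factor(universe %in% b$essential, levels = c(FALSE, TRUE),
               labels = c("non_essential", "essential"))
  fr <- factor(ref[universe] == "essential", levels = c(FALSE, TRUE),
               labels = c("non_essential", "essential"))
  counts <- table(A = fa, B = fb, reference = fr)
  both_not_ref <- universe[fa == "essential" & fb == "essential" &
                             fr == "non_essential"]
  list(counts = counts, both_not_reference = both_not_ref,
       universe_size = length(universe))
}

#' Compare essentiality verdicts between haploid and diploid libraries
#'
#' Partitions genes into essential-in-both (candidate haploinsufficient,
#' after curation), essential in the haploid only, essential in the diploid
#' only, and non-essential in both. Curation reasons are applied before the
#' candidate list is reported: a gene flagged as duplicated, dubious, deleted
#' or short is excluded from the candidates (but still counted in the raw
#' partition under `counts`).
#'
#' @param verdicts_haploid,verdicts_diploid Verdict tables (or
#'   [fit_and_predict()] results).
#' @param curation Optional `tn_curation`.
#' @return List with `counts` (named integer vector over the four
#'   categories), `categories` (per-gene data.frame), and
#'   `haploinsufficient_candidates` (essential-in-both surviving curation).
#' @export
ploidy_compare <- function(verdicts_haploid, verdicts_diploid, curation = NULL) {
  h <- .essential_set(verdicts_haploid)
  d <- .essential_set(verdicts_diploid)
  universe <- intersect(h$universe, d$universe)
  in_h <- universe %in% h$essential
  in_d <- universe %in% d$essential
  category <- ifelse(in_h & in_d, "essential_both",
                     ifelse(in_h, "essential_haploid_only",
                            ifelse(in_d, "essential_diploid_only",
                                   "non_essential_both")))
  cats <- data.frame(orf_id = universe, category = category,
                     stringsAsFactors = FALSE)
  candidates <- universe[category == "essential_both"]
  if (!is.null(curation)) {
    removed <- curation$orf_id[!curation$kept]
    candidates <- setdiff(candidates, removed)
  }
  counts <- table(factor(category, levels = c("essential_both",
                                              "essential_haploid_only",
                                              "essential_diploid_only",
                                              "non_essential_both")))
  list(counts = c(counts), categories = cats,
       haploinsufficient_candidates = candidates)
}
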