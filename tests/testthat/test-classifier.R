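test_that("ortholog training sets require agreement in both source species", {
  labels_a <- c(a = "essential", b = "essential", c = "essential",
                d = "non_essential", e = "non_essential")
  labels_b <- c(a = "essential", b = "essential", c = "non_essential",
                d = "non_essential", e = "essential")
  map <- data.frame(source_id_a = letters[1:5], source_id_b = letters[1:5],
                    target_id = paste0("t_", letters[1:5]))
  ts <- build_ortholog_training_set(labels_a, labels_b, map,
                                    paste0("t_", letters[1:5]))
  expect_setequal(ts$orf_id[ts$label == "essential"], c("t_a", "t_b"))
  expect_equal(ts$orf_id[ts$label == "non_essential"], "t_d")
  # conflicting orthologs (c, e) are excluded
  expect_false(any(c("t_c", "t_e") %in% ts$orf_id))
  expect_equal(unname(attr(ts, "counts")["conflicting"]), 2)

  # ambiguous target mappings are dropped with a count
  map2 <- rbind(map, data.frame(source_id_a = "a", source_id_b = "b",
                                target_id = "t_a"))
  ts2 <- build_ortholog_training_set(labels_a, labels_b, map2,
                                     paste0("t_", letters[1:5]))
  expect_false("t_a" %in% ts2$orf_id)
  expect_equal(unname(attr(ts2, "counts")["ambiguous_dropped"]), 1)

  expect_error(build_ortholog_training_set(labels_a, labels_b, map, "t_zz"),
               "no target genes")
})

test_that("curation removes short, deleted, dubious and duplicated ORFs in
           order of precedence", {
  set.seed(41)
  core <- random_seq(3000)
  # duplicate a 600-bp block to create an unmappable ORF
  g <- toy_genome(paste0(core, substr(core, 1001, 1600)))
  orfs <- toy_orfs(start = c(1050, 100, 2000, 2400),
                   end = c(1550, 350, 2350, 2800),
                   orf_id = c("dup", "short", "del", "dub"))
  rep <- curate_orfs(orfs, g, deleted_genes = "del", exclusion_list = "dub",
                     k = 30)
  expect_equal(rep$reason[match(c("dup", "short", "del", "dub"),
                                rep$orf_id)],
               c("duplicated_region", "length_lt_300", "deleted_in_strain",
                 "dubious_annotation"))
  expect_false(any(rep$kept[rep$reason != "ok"]))

  # the k-mer multiplicity fraction agrees with a direct string-count oracle
  mm <- orf_multimap_fraction(orfs[1, ], g, k = 30)
  gen_str <- as.character(g$seq[[1]])
  rc <- as.character(Biostrings::reverseComplement(g$seq[[1]]))
  km <- substring(gen_str, 1051:(1550 - 29), 1080:1550)
  n_occ <- vapply(km, function(s) {
    length(gregexpr(s, gen_str, fixed = TRUE)[[1]]) +
      sum(gregexpr(s, rc, fixed = TRUE)[[1]] > 0)
  }, numeric(1))
  expect_equal(unname(mm["dup"]), mean(n_occ > 1))

  # a unique ORF passes
  uniq <- curate_orfs(toy_orfs(100, 700, orf_id = "u"), g, k = 30)
  expect_true(uniq$kept)
})

test_that("the contradiction filter removes only data-rich essential-labeled
           genes with non-essential insertion patterns", {
  feats <- data.frame(
    orf_id = c("e_contradict", "e_nodata", "e_real", "n1", "n2"),
    neighborhood_index = c(1.2, 0.9, 0.02, 1.0, 0.8),
    freedom_index = c(0.10, 0.15, 0.97, 0.2, 0.3),
    n_window = c(100, 5, 80, 50, 60))
  tr <- training_set(data.frame(
    orf_id = feats$orf_id,
    label = c("essential", "essential", "essential", "non_essential",
              "non_essential")))
  out <- contradiction_filter(tr, feats)
  expect_equal(attr(out, "removed"), "e_contradict")
  # gene with no local data is kept despite its label
  expect_true("e_nodata" %in% out$orf_id)
  # non-essential labels are never removed
  expect_true(all(c("n1", "n2") %in% out$orf_id))
})

test_that("cross-validation separates separable data and is deterministic", {
  st <- separable_study()
  cv <- cross_validate(st$features, st$training, k = 5, n_trees = 100, seed = 0)
  expect_equal(cv$auc_mean, 1.0)
  expect_true(all(!is.na(cv$oof_scores)))

  cv2 <- cross_validate(st$features, st$training, k = 5, n_trees = 100, seed = 0)
  expect_identical(cv$oof_scores, cv2$oof_scores)

  one_class <- training_set(data.frame(orf_id = st$training$orf_id,
                                       label = "essential"))
  expect_error(cross_validate(st$features, one_class), "single class")
})

test_that("cross-validation of permuted labels gives chance-level AUC", {
  st <- separable_study(n_per_class = 20)
  set.seed(5)
  aucs <- replicate(30, {
    perm <- training_set(data.frame(orf_id = st$training$orf_id,
                                    label = sample(st$training$label)))
    cross_validate(st$features, perm, k = 5, n_trees = 60,
                   seed = sample.int(1e6, 1))$auc_mean
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("ROC/AUC agree with the pairwise-ranking estimator and pROC", {
  skip_if_not_installed("pROC")
  set.seed(6)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    labels <- sample(c("essential", "non_essential"), n, TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)  # ties on purpose
    if (length(unique(scores)) < 2) next
    r <- roc_curve(labels, scores)
    expect_equal(r$auc, rank_auc(labels, scores))
    p <- suppressMessages(pROC::roc(labels, scores, levels = c("non_essential",
                                                               "essential"),
                                    direction = "<"))
    expect_equal(r$auc, as.numeric(pROC::auc(p)))
  }
})

test_that("threshold selection maximizes Youden J with FPR tie-breaking", {
  # hand-built score set: optimum at threshold 0.8 with TPR 0.8, FPR 0.1
  labels <- c(rep("essential", 5), rep("non_essential", 10))
  scores <- c(0.9, 0.9, 0.85, 0.8, 0.15,
              0.82, rep(0.2, 9))
  th <- roc_and_threshold(labels, scores)
  brute <- sapply(unique(scores), function(t) {
    mean(scores[labels == "essential"] >= t) -
      mean(scores[labels == "non_essential"] >= t)
  })
  expect_equal(th$j, max(brute))
  expect_equal(th$threshold, 0.8)

  # Euclidean criterion is computed for the same curve
  th2 <- roc_and_threshold(labels, scores, method = "euclidean")
  expect_lte(th2$distance, sqrt((1 - th$tpr)^2 + th$fpr^2))

  # perfect classifier
  perf <- roc_and_threshold(c("essential", "essential", "non_essential"),
                            c(0.9, 0.8, 0.1))
  expect_equal(perf$roc$auc, 1.0)
  expect_equal(perf$j, 1.0)

  expect_error(roc_curve(labels, rep(0.5, 15)), "constant")
})

test_that("Youden optimum equals the brute-force sweep on random instances", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    labels <- c("essential", "non_essential",
                sample(c("essential", "non_essential"), n - 2, TRUE))
    scores <- round(runif(n), 1)
    if (length(unique(scores)) < 2) next
    th <- roc_and_threshold(labels, scores)
    brute <- max(sapply(unique(scores), function(t) {
      mean(scores[labels == "essential"] >= t) -
        mean(scores[labels == "non_essential"] >= t)
    }))
    expect_equal(th$j, brute)
  }
})

test_that("final fit emits verdicts, normalized importances and exclusions", {
  st <- separable_study()
  cur <- data.frame(orf_id = st$features$orf_id,
                    kept = st$features$orf_id != "g001",
                    reason = ifelse(st$features$orf_id == "g001",
                                    "duplicated_region", "ok"))
  fit <- fit_and_predict(st$features, st$training, threshold = 0.5,
                         curation = cur, n_trees = 100)
  expect_equal(sum(fit$importances), 1.0, tolerance = 1e-9)
  v <- fit$verdicts
  expect_equal(v$verdict[v$orf_id == "g001"], "excluded")
  expect_equal(v$reason[v$orf_id == "g001"], "duplicated_region")
  # separable training genes get verdicts consistent with their labels
  rest <- merge(v[v$verdict != "excluded", ], as.data.frame(st$training))
  expect_true(all(rest$verdict == rest$label))

  p <- tempfile(fileext = ".csv")
  write_verdicts(fit, p)
  expect_equal(nrow(utils::read.csv(p)), nrow(st$features))
})

test_that("the min-target sweep keeps the baseline and shrinks gene counts", {
  st <- separable_study()
  set.seed(8)
  st$features$n_targets <- rpois(nrow(st$features), 4)
  sw <- suppressWarnings(
    auc_vs_min_targets(st$features, st$training, cutoffs = 0:6, n_trees = 60))
  expect_equal(sw$min_targets[1], 0)
  expect_equal(sw$n_genes[1], nrow(st$training))
  expect_true(all(diff(sw$n_genes) <= 0))
})
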