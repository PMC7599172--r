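---
title: "Inferring gene essentiality from transposon mutagenesis libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene essentiality from transposon mutagenesis libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnverdict)
```

## The method

In vivo transposon mutagenesis saturates a genome with single-insertion
mutants: a heterologous transposon (AcDs, Hermes, or PiggyBac in yeasts) is
mobilized in a large cell population, each cell acquires at most one new
insertion, and deep sequencing of transposon–genome junctions reports where
insertions survived selection. Insertions inside a gene required for growth
remove that clone from the pool, so essential genes appear as insertion
deserts. Real libraries, however, are biased — transposons prefer target
motifs (TTAA for PiggyBac, TnnnnA for Hermes), reinsert near their donor
locus, and carry stochastic "jackpot" clones — so a per-gene decision rule
on raw counts is unreliable.

`tnverdict` treats essentiality as supervised binary classification. For
every ORF it computes eight predictors:

* `insertions`, `reads` — raw per-ORF counts;
* `neighborhood_index` (NI) — the ORF's insertion density divided by the
  density of the window extending 10 kb on each side (window includes the
  ORF). NI normalizes positional biases: donor proximity, chromatin
  accessibility. NI = 0 with an explicit flag when the window is empty;
* `freedom_index` (FI) — the longest insertion-free run of bases in the ORF
  divided by ORF length; FI = 1 for an untouched ORF, and near-1 values
  flag essential genes or essential domains;
* `insertions_100_upstream` — insertions in the 100 bp 5′ of the start codon
  (strand-oriented, half-open: the start-codon base belongs to the ORF);
* `insertions_per_target` — insertions per target motif in the ORF
  (motif-bound transposons only; 0 plus a `no_target` flag for motif-free
  ORFs);
* `reads_per_length`, `insertions_per_length` — length-normalized counts.

A Random Forest (200 trees, fixed seed 0) is trained on genes with known
essentiality, validated by stratified fivefold cross-validation, and scored
by AUC. The verdict threshold is chosen on the pooled out-of-fold
probabilities by the Youden criterion (maximum TPR − FPR over the ROC
sweep, ties broken toward lower FPR); the Euclidean distance-to-(0,1)
optimum is computed alongside as a sanity check. The final model is refit on
the full training set and applied to every curated ORF. Choosing the
threshold on pooled out-of-fold scores rather than refit scores avoids an
optimistically biased threshold; the bridge between cross-validated ROC and
full-model application is otherwise underdetermined.

## Upstream processing

Reads carry a transposon tag; `trim_transposon_tag()` locates it (full match
anywhere, one mismatch tolerated for tags of 20 bp or more, or a partial
match of at least `min_overlap` bases at the read start) and keeps the
genomic remainder, optionally skipping a fixed post-tag offset — the
3-bp-downstream dialect used by one PiggyBac chemistry. Alignment is
delegated: SAM/BAM input is read with standard flag conventions, or, at
fixture scale, `naive_exact_mapper()` places reads by exact (reverse-
complement-aware) matching, giving unique hits MAPQ 42 and multi-mapping
hits MAPQ 0. `call_insertions()` drops reads with MAPQ below 20 or a
first-base mismatch, then collapses junctions — leftmost aligned base of a
plus-strand read, rightmost of a minus-strand read — onto forward-strand
coordinates. Site identity deliberately ignores strand: published counts
treat a genomic position as one insertion regardless of which transposon end
was sequenced, and per-strand identity would double-count.

All internal coordinates are 0-based half-open; GFF3 (1-based inclusive) and
SAM (1-based) are converted only at the I/O boundary.

## Curation

Four reasons remove an ORF from classification, applied in order:
`duplicated_region` (the fraction of read-length k-mers — default k = 75 —
occurring more than once in the genome, either strand, exceeds 0.5; such
genes lose their reads to the MAPQ filter and masquerade as essential),
`length_lt_300` (short genes have too few insertion opportunities),
`deleted_in_strain`, and a user-supplied `dubious_annotation` list. A
rule-based contradiction filter stands in for the visual screening of
ortholog-derived labels: an essential-labeled gene is dropped when its NI is
at least the median NI of non-essential-labeled genes, its FI is at most
0.25, and its neighborhood holds at least 20 insertions — i.e. when a
data-rich region shows clearly non-essential behaviour. The thresholds are
exposed as arguments.

## Target motifs and library quality

`scan_target_sites()` counts every (possibly overlapping) forward-strand
match start of the motif; both built-in motifs are reverse-complement-
palindromic pattern families, so one strand suffices. `N` in the genome
never matches, so gapped assemblies do not inflate counts. A target belongs
to an ORF when its match start lies in `[start, end)`; a site "is at a
target" when its coordinate falls inside any motif span. These membership
rules are conventions — the simplest complete ones — and are applied
consistently in `summarize_library()`, which reproduces the standard
summary-table rows (reads per insertion, max/mean ratio, target saturation,
per-gene coverage). `derive_summary_stats()` follows the published reporting
convention in which the max/mean ratio is computed from the *rounded* mean.
`detect_jackpots()` flags sites with at least 1000-fold the mean
reads-per-insertion.

## The simulator

`simulate_genome()` and `simulate_library()` generate studies with the
statistical structure the classifier assumes, so recovery of known truth is
testable end to end. Per-base insertion intensity is the product of:

* a motif factor — 0 off-motif for PiggyBac-like (optionally a small
  `off_motif_rate`), weight 10 on TnnnnA spans for Hermes-like, flat for
  AcDs-like;
* a donor factor `1 + b·exp(−d/λ)` for chromosomal donors (defaults b = 10,
  λ = 50 kb), flat for plasmid donors;
* an essential-gene factor: intensity × ε (default 0.02) inside essential
  ORFs beyond a tolerated 5′ fringe of 35 bp — the empirical span over which
  essential genes tolerate insertions near their start codons.

Unique sites are drawn from this intensity until the target count is
reached; read counts are negative-binomial (μ = 100, dispersion k = 0.5,
floored at 1), chosen because published libraries show standard deviations
one to two orders of magnitude above the mean; jackpots are injected at a
Poisson rate (default 1 per library) by multiplying a random site's count by
a log-uniform factor between 10³ and 10⁵. The default study is 1 Mb, 500
non-overlapping ORFs of 300–3000 bp, 20% essential, 100,000 insertions,
GC 0.38 — a scaled-down yeast chromosome arm at realistic saturation.

What the simulator does **not** model: chromatin and replication-timing
bias, diploid allelic structure (heterozygous tolerance is emulated by
relaxing suppression per gene), biological off-motif PiggyBac integration,
and sequencing error. Passing recovery tests therefore demonstrate the
statistical machinery, not robustness to every real-data artifact.

## Numerical and design choices

* ε = 0.02 rather than 0 keeps essential ORFs imperfectly clean, so
  classification is non-trivial at the default depth.
* NI's window is 10 kb *per side* (the "surrounding 10 kb" is ambiguous);
  the flank is configurable.
* FI measures insertion-free *bases*: gaps between consecutive insertion
  coordinates minus one, plus both flanks. A fully saturated ORF has FI 0.
* Zero denominators (no targets, empty NI window) yield 0 with a flag
  column rather than `NA`, because the forest needs complete rows and the
  flag preserves the distinction.
* Metagene offsets are strand-symmetric: offset = pos − start on the plus
  strand and (end − 1) − pos on the minus strand, so the start codon maps
  to 0 on both strands and the first upstream base to −1.
* Determinism: every stochastic step (fold assignment, forest fits,
  stratified splits, the simulator) is seeded; identical configuration and
  seed give byte-identical outputs.
* Test and acceptance problem sizes: oracle properties run on 1000 random
  fixtures; recovery runs the default 1 Mb study at three seeds; the
  depth-degradation contrast uses 100k vs 5k insertions; the min-target
  sweep uses a PiggyBac-like study at GC 0.5 (sparse TTAA), 600 kb, 300
  ORFs, 2000 insertions, ε = 0.1, averaged over three seeds. These sizes
  were chosen so each experiment exercises the intended regime (saturated,
  depth-limited, target-limited) while remaining quick to run.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
gen <- simulate_genome(cfg)
sim <- simulate_library(gen$genome, gen$orfs, gen$labels, cfg)
feats <- compute_features(sim$library, gen$orfs, gen$genome)
training <- training_set(gen$labels)
cv <- cross_validate(feats, training)
th <- roc_and_threshold(training$label, cv$oof_scores[training$orf_id])
fit <- fit_and_predict(feats, training, th$threshold)
cv$auc_mean
th$threshold
```

The same flow is available from files via `run_simulation()`,
`run_calling()` and `run_classification()`, each of which writes a manifest
(configuration echo, seed, file digests) so any artifact is reproducible
from its manifest alone.

## Limitations

Cross-study transfer intersects feature schemas by name only; features with
matching names but study-specific scales (e.g. `reads`) transfer poorly, as
the cross-study analyses themselves show. The ortholog training-set
construction requires a curated ortholog map and drops ambiguous mappings
wholesale. The contradiction filter is a deliberately coarse surrogate for
expert visual inspection. Finally, essentiality is treated as binary even
though it is a quantitative, condition-dependent trait; probability outputs
are retained in the verdict table so users can revisit the dichotomy.
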