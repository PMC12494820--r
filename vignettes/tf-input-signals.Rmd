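---
title: "Predicting transcription factor input signals from paired transcriptomics and metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting transcription factor input signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfsignals)
```

## The problem

Most bacterial transcription factors (TFs) are allosteric sensors: a small
molecule binds the TF, changes its DNA-binding capacity, and thereby rewires
expression of the TF's target genes (its *regulon*). For the large majority
of TFs, even in model organisms, this input signal is unknown, because
identifying it traditionally requires one-at-a-time in vitro binding assays.

`tfsignals` implements a systematic computational screen for such signals.
The premise is simple: if a metabolite is the input signal of a TF, its
intracellular abundance should co-vary with the TF's *activity* — the
functional influence the TF exerts on its targets — across a diverse panel of
growth conditions. The pipeline therefore

1. infers per-condition TF activities from a gene expression matrix and a
   signed TF-to-gene regulatory network,
2. correlates those activities with metabolite abundances using a bootstrap
   Spearman scheme with an ROC-derived correlation threshold and a
   per-pair stability score, and
3. filters candidate TF–metabolite pairs by their distance in the metabolic
   network, keeping only metabolites that are direct substrates or products
   of reactions catalyzed by enzymes the TF regulates.

A synthetic-data generator with planted ground truth stands in for the
experimental datasets, so every stage is testable end to end.

## TF activity inference

A TF's expression level is a poor proxy for its activity (allosteric control
is post-translational), so activity is inferred from the collective behaviour
of the TF's direct targets. The implemented statistic is a transparent,
rank-based signed enrichment score in the spirit of analytic rank-based
enrichment analysis:

* The expression matrix is reduced to a *signature*: each gene is z-scored
  across conditions (`build_signature()`); constant genes become all-zero
  rows.
* Within each condition, signature values are rank-transformed across genes
  and mapped to standard-normal quantiles (`rank/(n+1)` normal scores).
* The raw activity of a TF in a condition is
  `sum(sign_g * ns_g) / sqrt(n)` over its regulon targets, where `sign_g`
  is the regulation mode (+1 activation, -1 repression) and `n` the number
  of targets used (`enrich_regulon()`). Flipping all signs negates the
  score, and any strictly monotone per-condition transform of the signature
  leaves it unchanged — the statistic sees only ranks.

Dual-mode edges (sign 0, from networks that annotate both activation and
repression for the same pair) have no defined direction and are excluded
from the sum; consequently they also do not count toward the minimum regulon
size of 3 targets required for a TF to be scored. This exclusion is a
package design choice — curated networks do not say per condition which
direction a dual edge takes.

Regulatory networks are incomplete and regulon sizes vary by two orders of
magnitude, which can bias a single global inference. `infer_activities()`
therefore scores each TF inside ten *subnetworks*, each containing the TF
plus 40 other TFs drawn at random without replacement, standardizes raw
scores across the subnetwork's member TFs within each condition, and reports
the median standardized score over subnetworks. The per-condition
standardization across member TFs is what makes the subsampling
consequential; without it, a per-TF statistic would be unaffected by the
subnetwork composition. Per-subnetwork scores are retained so the knockout
benchmark can report per-replicate accuracy. Whether draws are shared
between target TFs is not material to the estimator; each TF draws its own
subnetworks from one seeded generator.

Two diagnostics assess inferred activities:

* **Knockout benchmark** (`ko_direction_benchmark()`): in a condition where
  a TF's gene is deleted, the inferred activity should be lower than in the
  paired wild-type control. Reported per pair as a direction flag, the
  proportion of subnetwork replicates agreeing, and the rank percentile of
  the knockout condition among all conditions.
* **Dynamic chi-squared thresholds** (`dynamic_chi2_threshold()`): to filter
  out TFs whose activities are uninformative, a cutoff on any per-TF metric
  (e.g. maximum activity, activity range) is chosen by scanning all
  midpoints between consecutive sorted values and minimizing the chi-squared
  p-value of the 2x2 (above/below cutoff x correct/incorrect) table, among
  cutoffs where the above-cutoff group is enriched for correct TFs. Ties
  break toward the smaller cutoff so fewer TFs are discarded. The test is
  used without continuity correction; the reference cutoffs shipped with
  `apply_activity_filter()` (-0.752 on basal maximum activity, 0.166 on
  activity range) are values derived on one benchmark dataset and should be
  recomputed for new data.

## Metabolomics preprocessing

Flow-injection MS ion tables are processed in a fixed order
(`preprocess_ions()`):

1. `merge_replicates()` — technical duplicate injections are averaged.
2. `tic_normalize()` — each (condition, replicate) column is divided by its
   total ion count, making columns sum to 1.
3. `cv_filter()` — per ion and condition the coefficient of variation across
   biological replicates is computed; an ion reaching 15% CV in *any*
   condition is dropped entirely. Whole-profile removal is a package choice:
   the downstream correlation needs complete condition profiles, and
   partial removal would leave holes that must be imputed. Retained cells
   are collapsed to replicate means.
4. `annotate_ions()` — ions are matched to a compound reference by exact
   mass within 0.001 Da, assuming the [M-H]- adduct (expected m/z = neutral
   monoisotopic mass - 1.007276 Da; the adduct offset is configurable).
   Compounds with identical reference mass are indistinguishable by MS1 and
   collapse into a single matrix row keyed by the `;`-joined annotation set.
   Such a row later scores the *minimum* metabolic distance over its member
   compounds — the most favourable consistent reading of an ambiguous
   annotation, and the reason ambiguous sugar ions can inflate per-TF
   candidate counts.

`max_fold_change()` summarizes how much each metabolite moves across the
condition panel (max/min of condition means); a diverse panel — median fold
change well above 1 — is a precondition for the correlation screen to have
power.

## Correlation, threshold and stability

All statistics are computed on the full TF x metabolite grid, never a
preselected subset; with 173 TFs and 279 metabolites this is 48,267 pairs.

* `bootstrap_correlations()` draws, per bootstrap sample, 30 of the 40
  shared conditions *without replacement* and computes Spearman's rho for
  every pair over the subsample. Spearman (Pearson on average ranks) is
  used because an input-signal relationship need only be monotone, not
  linear, and rank correlation is insensitive to the unknown scaling of
  both activities and intensities. Subsampling conditions (rather than
  resampling with replacement) removes the influence of any single
  condition without duplicating observations in a rank statistic. The
  reported correlation score is the mean rho over the 1000 samples; a pair
  whose profile is constant within a subsample contributes no value for
  that sample (no imputation of ranks).
* `median_roc_threshold()` turns known TF–metabolite interactions into a
  decision threshold: per sample, an ROC curve over all measured pairs
  (positives = known pairs of the requested effect, negatives = everything
  else) yields the smallest correlation threshold with false positive rate
  at most 0.1; the final threshold is the *median of the per-sample
  thresholds*. A per-FPR-grid median TPR curve is also returned for
  reporting. Deriving the cutoff from per-sample thresholds rather than by
  inverting the median curve is a deliberate choice: it always yields a
  well-defined score cutoff even where the median curve is flat.
* `stability_scores()` reports, per pair, the proportion of the 1000
  samples in which rho *strictly exceeds* the threshold. The stability
  cutoff is then chosen by `select_stability_threshold()` as the observed
  stability value maximizing the fraction of retained pairs that are known
  interactions, with ties broken toward the larger (stricter) cutoff.
  Because the cutoff is itself an observed score, the cascade compares
  stability with `>=` so the pairs defining the cutoff are retained.

Activating interactions (abundance up, activity up) are the default
orientation; the inactivating branch is implemented (scores negated) but
reported separately, reflecting that negative correlations recover known
inactivating signals considerably less well.

## Metabolic distance and position

`build_graph()` converts a genome-scale metabolic model into an undirected
bipartite metabolite–reaction graph: only intracellular species are kept
(compartment suffixes are stripped), metabolites participating in more than
50 reactions are removed as hubs, and a configurable cofactor list (ATP,
NAD(P)(H), CoA, Pi, H2O, ... — the exact currency-metabolite set is a
package default, overridable) is removed globally. Both removals prevent
biologically meaningless two-step shortcuts through ubiquitous compounds. A
reaction is *regulated* by a TF when its gene association intersects the
TF's regulon.

`tf_metabolite_distance()` runs Dijkstra's algorithm with unit edge weights
(equivalently breadth-first search — hop counts are what "consecutive
reactions" means) ignoring reaction direction. Distance 0 means the
metabolite is a substrate or product of a regulated reaction; each further
linking reaction adds 1; absent metabolites, TFs without enzymatic targets,
and disconnected pairs score infinity.

For direct (distance-0) pairs, `classify_position()` uses the *stated*
reaction directions: a metabolite that is only a substrate of regulated
reactions sits *upstream* (feedforward sensing of a pathway input), only a
product *downstream* (end-product feedback), both *within* (pathway
intermediate); reversible regulated reactions count both roles. Distances
above 0 are never classified — the pipeline only reports positions for
final candidates, which require distance 0.

## The candidate cascade

`filter_candidates()` keeps pairs with mean correlation strictly above the
ROC threshold, stability at least the stability cutoff, and distance at most
the distance cutoff (default 0). TFs without any regulated enzyme are
excluded from the universe — distance cannot be evidenced for them. The
summary (`summarize_predictions()`) reports per-TF candidate counts,
position-class proportions, and known-signal recovery under two readings
(any candidate matches, or the top-correlated candidate matches), since
either convention is defensible.

All three filters are monotone: raising any cutoff can only shrink the
candidate list.

## The synthetic study and what it does (not) show

`generate_dataset()` plants a complete ground truth:

* **Activities**: i.i.d. standard normal per (TF, condition) — the simplest
  null that spans a wide activity range. In each of 8 knockout conditions
  the knocked-out TF's activity is forced to its row minimum minus 2, which
  guarantees the expected benchmark direction irrespective of scale. TF
  genes are carried as noise rows of the expression matrix so knockout
  metadata can reference them.
* **Expression**: signed sum of regulator activities per gene plus
  N(0, 0.1) noise; regulons of 8 targets with both signs present, disjoint
  whenever the gene pool allows (default 30 TFs x 8 targets over 300
  genes).
* **Metabolome**: a planted coupling of strength 1 gives
  `exp(strength * activity + eps)` with log-scale noise sd 0.1
  (inactivating couplings negate the activity). The exponential link keeps
  abundances positive, and because Spearman is invariant to monotone
  transforms the link cannot bias recovery; at zero noise the planted
  correlation is exactly +/-1. Ten couplings are planted by default; half
  are disclosed as "known" (driving the ROC and stability thresholds), half
  are left for the pipeline to discover.
* **Metabolic model**: per planted pair, a 1–3 reaction linear pathway whose
  regulated steps are catalyzed by the planted TF's targets, realizing the
  intended distance (0/1/2) and position (upstream/within/downstream);
  uncoupled metabolites enter through unregulated filler reactions; one hub
  metabolite participates in 51 reactions and a cofactor pair is attached
  to every pathway reaction, so the graph filters are exercised for real.
* **Ion table**: each metabolite becomes a [M-H]- ion of a distinct
  synthetic mass, observed in biological triplicate and technical duplicate
  with 2% multiplicative replicate noise.

One top-level seed drives all sub-generators through fixed offsets, so the
entire bundle — and the entire pipeline via `run_synthetic_study()` — is
byte-for-byte reproducible.

What passing on this bundle shows: the estimators are implemented correctly
(activities recover the planted truth with rank correlation above 0.9 at
noise 0.1; all planted direct couplings survive the cascade; the final list
is dominated by planted pairs). What it does not show: performance on real
data, where activities are condition-structured rather than i.i.d., regulons
overlap heavily, networks are wrong or incomplete, metabolite profiles are
mutually correlated along pathways, and annotation is ambiguous. The
generator deliberately omits these difficulties except for MS1 isobar
collapse and graph-shortcut hazards, which are modelled.

## Numerical choices and degenerate inputs

* Normal scores use `rank/(n+1)` with average ranks for ties, so scores are
  finite for any input.
* Subnetwork standardization with zero across-TF spread yields score 0;
  a single eligible TF skips standardization entirely (with a warning).
* Spearman over a constant profile is undefined and propagates as missing,
  never imputed; stability counts a missing sample as "not above
  threshold".
* The chi-squared scan skips tables with empty margins and returns `-Inf`
  (no filtering) when no cutoff enriches correct TFs.
* TSV serialization uses 17 significant digits, making write-then-read an
  exact identity for doubles; infinite distances are written as `inf`.
* All tie-breaks are fixed and documented: smaller cutoff for the
  chi-squared scan, larger cutoff for stability selection, arg-min member
  for isobaric distance sets.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
reference scale (30 TFs, 300 genes, 40 conditions, 60 metabolites, 1000
bootstrap samples) and the correlation stage additionally at full study
scale (173 TFs x 279 metabolites = 48,267 pairs, 1000 samples), sizes at
which the complete analysis takes well under a minute each on a single CPU.

## Limitations

* The enrichment statistic is a transparent rank-based stand-in for full
  VIPER: pleiotropy correction and interaction-confidence weighting are out
  of scope.
* No p-values or multiplicity control are attached to candidates; the
  screen is a ranked hypothesis generator, and its three scores are the
  only ranking.
* Currency-metabolite removal is global and list-based; per-reaction
  cofactor roles are not modelled.
* MS1 annotation cannot separate isobars; candidate lists for TFs whose
  regulons touch sugar metabolism will be inflated accordingly.
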