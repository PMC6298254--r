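---
title: "Spectral-count filtering and bait-prey network construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count filtering and bait-prey network construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baitprey)
```

## The problem

Bait-based interactomics screens (Virotrap, AP-MS and relatives) identify
hundreds to thousands of proteins per purification, most of which are not
interaction partners but shared background: abundant cellular proteins that
co-purify with any bait. `baitprey` implements a stringent, fully
deterministic filtering strategy for such screens that uses *control
purifications* — runs with baits unrelated to the pathway under study — as
an empirical background model, instead of probabilistic scoring
(SAINT/CompPASS-style models are deliberately out of scope).

The quantitative evidence unit throughout is the **spectral count**: the
number of peptide-to-spectrum matches (PSMs) assigned to a protein in one
LC-MS/MS run. The pipeline operates on raw counts; no normalisation (NSAF
or similar) is applied, because every decision rule is a threshold on small
integer counts where normalisation would only obscure the semantics.

## The procedure

Given a protein-by-experiment count matrix with experiment metadata (bait,
condition, replicate, role), the pipeline applies, in fixed order:

1. **PSM-level FDR** (upstream quality control, `compute_fdr()`): every
   spectrum keeps only its best-scoring match across the standard and
   reversed-database searches; the FDR is the number of decoy best-matches
   divided by all best-matches. A target-decoy score tie is resolved to the
   decoy, which can only overstate, never understate, the FDR. The FDR of
   an empty PSM set is defined as 0.
2. **Census** (`census()`): distinct proteins, and distinct (bait, prey)
   pairs where the prey has a nonzero count in at least one of its bait's
   runs. Bait self-identifications count as pairs at this stage; they are
   removed only at the lean-network step.
3. **Control filter** (`control_filter()`): any protein with a nonzero
   count in *any* control run — including a single-count identification —
   is removed globally, from every bait and condition. Removal is global
   rather than per-bait: a protein that co-purifies with an unrelated bait
   is background by definition, not an interactor of the remaining baits.
4. **Replicate summation** (`sum_replicates()`): counts are summed within
   each bait x condition replicate group; the summed count assigns the
   strength class — `one_hit` (1), `weak` (exactly 2), `strong` (>= 3).
5. **One-hit-wonder removal** (`drop_one_hit_wonders()`): a pair survives
   iff its summed count reaches 2 in at least one condition. For a
   surviving pair, a condition with sum 1 is *kept as presence evidence*
   but stays flagged `one_hit` and never confers weak/strong status. The
   alternative reading — pooling the two conditions' sums before
   thresholding — is available as `mode = "pooled"` for sensitivity
   analysis; we default to per-condition grouping because summation is
   defined per replicate group and the two conditions are distinct groups.
6. **Extensive network** (`build_extensive()`): one directed bait -> prey
   edge per surviving pair, carrying both conditions' strengths. Baits
   identified as preys of other baits stay single nodes with
   `is_bait = TRUE`.
7. **Dynamics** (`classify_dynamics()`): `appears` (TNF only),
   `disappears` (untreated only), `independent` (both). The three labels
   partition the edges by construction.
8. **Reference annotation** (`annotate_known()`): an edge is `known` when
   its unordered pair is in a curated reference set (e.g. a BioGRID
   subset); everything else is novel.
9. **Lean network** (`build_lean()`): a visualization-grade subgraph
   keeping (a) only edges strong in at least one condition, (b) no
   self-loops, and (c) only non-bait preys with degree >= 3 in the strong
   graph — *unless* the prey has at least one known edge, in which case it
   is rescued together with its strong edges. Bait nodes are exempt from
   the degree rule and retained while they keep an edge.

## Design choices that were genuinely open

* **Order of the lean rules.** We fix strong-filter -> self-loop removal ->
  degree computation -> degree-or-rescue retention. The published
  description of this family of workflows does not pin the order down, so
  `build_lean()` exposes `order = "degree_before_selfloop"` and
  `degree_scope = "extensive"` as reproduction switches. With the default
  data model the two order modes coincide: self-loops can only attach to
  bait nodes (every edge source is a bait), and baits are exempt from the
  degree rule — the switch exists for completeness and for data models
  where that invariant is relaxed.
* **"Strong" for lean inclusion** means strong in *at least one*
  condition, not in a fixed condition; a pair strongly supported only
  after stimulation is still a strong interaction.
* **One-hit presence evidence.** Whether a pair weak in one condition and
  one-hit in the other keeps the one-hit condition at all is unspecified in
  the workflow this package systematises; we keep it, flagged, because
  discarding it would silently change the dynamics label of the pair from
  `independent` to `appears`/`disappears` on the strength of a single PSM
  *absence* — the more conservative choice is to record presence.
* **FDR tie-break and empty-set convention** as described in step 1.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the filters
assume, so that the entire pipeline is testable without any deposited
data:

* **Design**: 12 baits x 2 conditions (untreated, TNF) x 3 biological
  replicates, plus 15 control experiments — the default panel mirrors the
  screen layout this pipeline targets.
* **Background**: `n_background = 150` contaminants, each detected in any
  given run with probability `background_detect_prob = 0.8`. With 15
  controls, the chance a background protein evades every control is
  `0.2^15` (~3e-11), which is what makes the control filter essentially
  exact; lowering the detection probability is the stress-test knob.
* **Planted interactors**: `interactors_per_bait = 10`, split
  50/25/25 between constitutive, TNF-induced and TNF-lost profiles.
  Condition-dependent interactors are *structural zeros* in their off
  condition, so dynamics labels have unambiguous ground truth; a
  `leaky_prob` mode places occasional off-condition single counts for
  stress tests.
* **Count law**: detected proteins draw `1 + NB(mu = count_mean - 1,
  size = count_dispersion)` with `count_mean = 6`, `count_dispersion = 2`
  — spectral counts are overdispersed relative to Poisson, and the +1
  shift keeps every detected protein at count >= 1 while preserving the
  mean. The abundance scale is a free simulator knob: no published
  distribution constrains it, and all pipeline decisions are threshold
  crossings, not distributional fits.
* **One-hit wonders**: a fraction `one_hit_rate = 0.1` of planted pairs is
  forced to a summed count of exactly 1 in each replicate group where the
  pair occurs, so the one-hit filter has planted true negatives.
* **Reference set**: `simulate_reference_set()` samples a stated fraction
  (default 0.5) of the planted pairs into an unordered-pair set plus
  optional never-planted decoy pairs, emulating the partial coverage of
  curated databases.
* Identifiers are synthetic accessions (`BAIT03`, `INT0042`, `BG0001`);
  no real gene names are fabricated.

What the generator does **not** emulate: peptide-level identification and
protein inference, correlated detection across runs (background proteins
are drawn independently per run), abundance-dependent detection, shared
interactors between baits (each planted prey belongs to one bait, so
degree->=3 retention in the lean network is exercised by the toy-graph
tests rather than the simulator), and real contaminant frequency profiles.
Passing the recovery tests therefore shows the *filter logic* is correct
under the assumed structure, not that the thresholds are optimal for any
particular real screen.

## Numerical and degenerate-input choices

* All counts are integers; no floating-point thresholds exist anywhere in
  the cascade, so results are exactly reproducible across platforms.
* An empty candidate list, an empty reference set, and preys absent from
  the reference are all legal and covered by tests; `control_filter()`
  refuses matrices without control columns instead of silently passing
  everything.
* Deterministic outputs: every simulation takes an explicit integer seed,
  and two runs with identical (config, seed) produce byte-identical
  files.

## Worked example

```{r example}
cfg <- synthetic_config(seed = 7)
d <- simulate_dataset(cfg)
ref <- simulate_reference_set(d$truth, coverage = 0.5, extra_pairs = 20,
                              seed = 7)
res <- run_pipeline(d$matrix, ref)
str(res$report, max.level = 2)
```

The report holds every checkpoint of the cascade: the pre-filter census,
the post-control census, the extensive network (with dynamics and
known/novel breakdowns) and the lean network (with rescued-edge and
self-loop counts). The test suite recomputes each checkpoint with
independent brute-force oracles on small matrices and toy graphs; the
problem sizes used there (matrices up to 6 proteins x 8 experiments,
graphs up to 10 nodes, 100-run recovery batches) were chosen so the full
property grid is exhaustive enough to be convincing while the whole suite
stays interactive.

## Limitations

* The control filter is binary: a protein seen once in one control is
  removed even if it is 50-fold enriched with a bait. This is the point of
  the stringent design, but it means abundant true interactors that also
  bind control baits are unrecoverable — quantitative enrichment scoring
  is explicitly not implemented.
* The lean network is a visualization aid, not an inference result; its
  degree and rescue rules discard low-degree novel preys by design.
* PSI-MITAB export targets version 2.5 with a minimal controlled
  vocabulary; pipeline-specific attributes travel in the confidence
  column, which round-trips through `read_mitab25()` but is not a
  registered CV term.
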