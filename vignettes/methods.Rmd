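---
title: "Methods: models, assumptions and design choices in ptenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, assumptions and design choices in ptenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptenet)
```

`ptenet` chains four analyses that are commonly applied to chronic
post-blast TBI proteomes: differential-expression calling from label-free
intensities, expression-constrained flux balance analysis (FBA),
multi-centrality ranking of a protein–protein interaction network, and
screening of chronic EEG for electrographic seizure candidates. This
vignette documents the statistical models behind each stage, the defaults
and why they were chosen, the numerical decisions, and what the synthetic
generators do and do not emulate.

## Differential protein expression

### Model and procedure

The unit of observation is a *run*: one LC–MS/MS injection of one animal's
sample. Intensities are strictly positive where a feature was detected and
absent otherwise — absence is informative (below detection), never zero.
The stage applies, in order:

1. **Total-intensity normalization.** Each run is rescaled so all runs
   share the same summed intensity (the mean of the input totals, so the
   table's overall scale is preserved). This assumes the vast majority of
   proteins are unchanged, the standard assumption behind total-ion
   normalization of label-free data.
2. **Peptide-to-protein rollup** by summation over a peptide→protein map;
   a protein is absent from a run only when all of its peptides are.
3. **Technical-replicate averaging** per animal, with the detection count
   per animal retained: an animal's abundance is the mean over the
   technical runs where the protein was seen, and the protein counts as
   detected for that animal if seen at least once.
4. **Group contrast.** The fold change is the ratio of group means of the
   animal-level abundances (experimental / control). The *t*-test is run
   on log2 abundances by default: intensities are approximately log-normal
   and the log transform stabilizes variance; the raw scale is available
   via `log_scale = FALSE` because the upstream convention of a given lab
   may differ. Welch's unequal-variance test is the default (no reason to
   assume equal group variances at n = 5); Student's pooled test is a
   config option. Proteins with fewer than two detected animals in either
   group are reported untested — a two-sample test is undefined there.
5. **Benjamini–Hochberg adjustment** across all tested proteins
   (`bh_adjust()`, a validating wrapper over the standard step-up
   implementation).

### DEP rule and sentinels

A tested protein is a DEP when all three hold:

* |log2 FC| ≥ log2(1.2) — the FC ≥ |1.2| rule read two-sided, so
  down-regulation at FC ≤ 1/1.2 qualifies symmetrically;
* adjusted *p* < 0.1 (strict);
* detected in ≥ 50% of the overexpressing group's technical runs. The
  familiar "5 of 10" instance corresponds to 5 animals × 2 technical runs;
  the fraction form generalizes to arbitrary designs.

Proteins absent from one entire group have no finite ratio; they carry the
conventional sentinel codes (100 = absent from control, 0.1 = absent from
experimental) in place of a fold change, no *p*-value, and are flagged as
DEPs in a separate, clearly marked stratum when they pass the presence
filter. They are never silently pooled with tested DEPs, because no error
control statement covers them. The two sentinel codes are mutually
exclusive by construction (a protein absent from both groups never appears
in the table).

Degenerate zero-variance groups (possible in noiseless synthetic data) are
resolved deterministically: identical group means give *p* = 1, distinct
means with zero variance give *p* = 0.

### Over-representation

`ora_enrichment()` is an exact one-sided hypergeometric test of a selected
protein list against annotation sets, BH-adjusted across sets. It is
deliberately database-agnostic: sets are plain named lists, so any GO/KEGG
export can be supplied as a TSV. No annotation databases ship with the
package.

## Expression-constrained flux balance analysis

### The LP and its solver

A `metabolic_model` holds reactions with sparse stoichiometries over
compartment-suffixed metabolites (`_c` cytosol, `_m` mitochondria, `_i`
inner mitochondrial membrane), flux bounds in mol hr⁻¹ gDW⁻¹, optional
gene–protein–reaction (GPR) rules, and exactly one objective reaction
(biomass maintenance). `fba()` maximizes the objective flux subject to
steady state (S·v = 0) and the bounds.

Numerical decisions:

* LP solving goes through `pracma::linprog` behind a small front-end that
  accepts ≤ / ≥ / = blocks. Infinite bounds are clamped to ±1000 flux
  units, so "unbounded" cannot occur by construction.
* Stoichiometric matrices of realistic models are row-rank-deficient
  (conserved moieties such as the cytochrome c or adenine pools). The
  front-end keeps a maximal independent subset of equality rows before
  solving; dropped rows are linear combinations of the kept ones with
  matching right-hand sides, so the feasible set is unchanged.
* FBA optima are degenerate. A secondary LP minimizes Σ|v| (split
  variables v = p − q) at the fixed primary optimum — the parsimonious
  convention — making reported flux vectors unique in practice and
  reproducible across solvers. The secondary solution is accepted only if
  it preserves the primary objective to 1e-8.
* Reported fluxes are rounded at 1e-12 to absorb solver-level floating
  point noise; the steady-state residual bound of 1e-8 is unaffected.
  Transient basis failures of the solver are retried before a
  non-converged status is reported; infeasibility is reported as a status
  with an empty flux table, never a fabricated vector.

### Linking fold changes to bounds

The perturbation anchors at the optimized solution v\*: for each reaction
regulated by at least one measured protein, with combined fold change *f*,

* v\* > 0: upper bound ← f·v\* (lower bound dropped to 0 if it would
  exceed the new upper bound);
* v\* < 0: lower bound ← f·v\*, mirrored;
* v\* = 0: bounds unchanged — a fold change scales an operating flux, and
  scaling zero is uninformative.

This is the minimal reading of "fold changes linked to the bounds of the
regulated reactions, anchored at the optimized solution", and it is
isolated in `apply_fold_change_constraints()` so alternative mappings can
be plugged in. Multiple proteins on one reaction combine through the GPR
rule: `and` → minimum (the scarcest complex member limits the complex),
`or` → maximum (isoenzymes substitute), and a rule-less protein list →
geometric mean (a symmetric, scale-balanced compromise). Proteins that map
to no reaction are ignored with a warning. The dysregulated condition is a
full re-optimization of the same biomass-maintenance objective under the
perturbed bounds — the disease state is presumed to still operate at its
(now reduced) capacity, which is what reported "dysregulated flux values"
imply.

Metabolite production under a solution is Σ max(0, coefficient × flux)
over reactions containing the metabolite; consumption is the negative
part. `production_change()` reports 100·(1 − dysregulated/optimized)
percent, both at full precision and truncated to an integer percent (the
truncation matches how such reductions are conventionally quoted, e.g. a
58.62% drop is reported as 58%). The change is undefined, and reported as
`NA`, when the optimized production is zero.

The toy generators provide hand-solvable ground truth: a linear chain
(optimum = uptake capacity), a two-branch join (optimum = sum of branch
capacities), and a miniature electron transport chain whose complex III-
and IV-like reactions both pump protons into `h_i` (optimum = 1.5 ×
capacity, from the 6 protons pumped and 4 consumed per ATP in the toy's
stoichiometry).

## Network centrality ranking

Edges with combined confidence strictly above 0.7 (the conventional
high-confidence STRING cutoff) form an undirected simple graph; duplicate
edges keep the maximum confidence, self-loops are dropped. STRING's
0–1000 integer scores are auto-detected and rescaled.

Five centralities are computed per connected component (the behavior of
the common desktop network tools for undirected graphs): degree,
betweenness normalized by (n−1)(n−2)/2, closeness (n−1)/Σd, eccentricity
(max geodesic distance), and stress — the raw count of shortest paths
through a node — which is implemented directly from all-pairs geodesic
path counts because no installed graph library provides it.

Two design points were genuinely open and are resolved as follows,
both configurable:

* **Normalization before weighting.** Counts (degree, stress) and
  fractions (betweenness, closeness) live on incomparable scales; mixing
  them raw would let whichever count is largest dominate the weighted sum
  arbitrarily. Each metric is therefore min–max normalized to [0, 1]
  across nodes before weighting. A metric that is constant across nodes
  normalizes to 1 for every node (hence a single-node network scores the
  full weight sum).
* **Eccentricity direction.** Eccentricity is a peripherality measure:
  high values mean far from everything. Since the other four metrics
  reward centrality, eccentricity is inverted before normalization
  (`invert_eccentricity = TRUE`) so a low-eccentricity node contributes
  positively.

The default weight vector (.28, .28, .20, .14, .10 for degree, stress,
betweenness, closeness, eccentricity) respects the published ordering —
degree and stress highest, then betweenness, closeness, eccentricity —
sums to 1 for interpretability, and is a configuration parameter, never a
constant inside the logic. Ties in the final score break lexicographically
by node id so rankings are reproducible. PageRank (damping 0.85, scores
summing to 1 over the whole graph) provides the comparison ordering, and
`select_targets()` applies the two-sided FC > |1.5| filter before taking
the top-10 of each list, reporting the union with provenance flags.

## EEG screening

The screen implements three criteria: duration ≥ 5 s, amplitude ≥ 3× the
background, and amplitude/frequency evolution. The background estimator is
the median of per-window RMS over non-overlapping 10-s windows — robust as
long as bursts occupy fewer than half the windows. The amplitude statistic
is the 1-s sliding-window RMS (the criterion's "amplitude" is not pinned
to peak, RMS or envelope anywhere authoritative; windowed RMS is the most
noise-stable choice and is configurable). Candidate regions above
threshold are merged across sub-second gaps. "Evolution of amplitude and
frequency" is operationalized as a significant monotone trend — Spearman
rank correlation, p < 0.05 — of either the per-second RMS or the
per-second dominant FFT frequency across the event. The original
workflow's custom detector plus manual expert proofreading cannot be
reproduced literally; this module is therefore documented as a screener
whose output is meant for expert review, and detection statistics on
synthetic traces say nothing about clinical sensitivity. Screening is
single-channel; a multi-channel AND-combiner can be layered on top by
intersecting per-channel event tables.

Detections are invariant to rescaling the whole trace (both the statistic
and the threshold scale linearly), and raising the amplitude threshold can
only remove events.

## What the synthetic generators emulate

* `simulate_abundance()` emulates the replicate hierarchy of the assumed
  study design: two groups × 5 animals × 2 technical runs. Log2
  intensities are baseline + group effect + biological noise + technical
  noise, with technical noise fixed at `noise_sd / 4` — technical
  replicates of one animal are substantially more similar than animals
  are. Missing values arise from uniform dropout and are encoded as
  absent rows, exercising the sentinel logic. Real LC–MS/MS data deviate
  in known ways that are deliberately not modeled: intensity-dependent
  dropout, shared/razor peptides, batch effects, heavy-tailed noise. The
  default `noise_sd = 0.2` (log2 scale) is chosen for testability — it
  yields realistic-looking ~15% CVs — since no intensity noise magnitude
  is published for the motivating dataset; recovery results on synthetic
  tables bound what the pipeline can do under its own assumptions, not
  performance on real data.
* `simulate_toy_model()` provides desk-scale stand-ins for a genome-scale
  reconstruction; they preserve the structural features the code must
  handle (bottlenecks, parallel routes, conserved moieties, a
  multi-producer proton pool, GPR rules with `and`) but none of the scale.
* `simulate_ppin()` plants hubs wired to ~80% of the network at
  confidence 0.75–1 over a sparse mixed-confidence background, so hub
  recovery is a sharp planted-truth question after the 0.7 filter. The
  preferential-attachment mode produces realistic degree heterogeneity
  without planted truth.
* `simulate_eeg()` adds oscillatory chirp bursts to Gaussian background
  noise. The burst envelope ramps from 0.8× to 1.2× of the nominal
  amplitude so amplitude evolves monotonically while the whole burst stays
  above the 3× detection threshold whenever the planted ratio is ≥ 4; the
  instantaneous frequency sweeps linearly (default 6→12 Hz). Real
  ictal EEG morphology (spikes, spike-wave complexes, post-ictal
  suppression) is not modeled.

All generators are pure functions of their arguments including the seed,
implemented under a local RNG state so they never disturb the caller's
stream.

## Problem sizes and statistical checks

The test suite and the acceptance script exercise the pipeline at sizes
chosen to make every check sharp yet quick to run: 500-protein tables with
25 planted effects over 100 simulations for DEP recovery; 100 random
graphs of up to 8 nodes for exhaustive-oracle centrality comparison (the
brute-force path enumeration is exponential, so 8 nodes is the practical
exhaustive regime); 40-node planted-hub networks over 100 seeds; 100
ten-minute synthetic EEG traces at 200 Hz. The 200 Hz rate is far below
typical acquisition rates (2 kHz) but comfortably above twice the highest
burst frequency simulated, so screening behavior is unaffected.

## Known limitations

* Genome-scale models are not parsed from SBML/JSON; the native TSV
  dialect covers the toy scale this package validates against. Published
  genome-scale flux values additionally depend on the exact deposited
  fold-change vector and model version, which the package does not ship.
* The DEP caller does no missing-value imputation and no shared-peptide
  apportioning.
* The EEG module screens; it does not classify spike morphology, detect
  post-ictal suppression, or fuse channels.
* The centrality weight vector is a convention respecting a published
  ordering, not fitted values; rankings under other weights respecting
  the same ordering can differ in the tail.
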