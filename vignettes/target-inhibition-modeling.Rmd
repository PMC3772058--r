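---
title: "Target inhibition modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target inhibition modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timnet)
```

This vignette documents the models implemented in `timnet`, their
assumptions, the tunable parameters, and the design decisions taken where
the methodology left genuine freedom. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The prediction problem

The data are a binary drug-by-target inhibition matrix `X` (rows: `n`
drugs, columns: `m` targets) and a vector `y` of single-drug efficacies
scaled to `[0, 1]` (`scale_efficacy()`: min maps to 0, max to 1; a panel of
constant efficacies is rejected as degenerate). The quantity of interest
is the efficacy of an arbitrary *target inhibition state* — the set of
targets a drug combination would jointly inhibit, modeled as the union of
the component drugs' target sets.

Two monotonicity assumptions connect states to efficacy: a superset of a
"successful" target set is successful, and a subset of an "unsuccessful"
one is unsuccessful. These are plausible for targeted signal-transduction
inhibitors screened over a short time scale in a genetically homogeneous
cell model (no drug-induced rewiring of survival pathways); they are *not*
plausible for broadly cytotoxic agents, and the model should not be fed
such compounds.

## From affinities to the binary matrix

* `inverse_scale_kd()` maps Kd (nM) to `s = 1 − log10(Kd)/log10(c_max)`,
  clipped to `[0, 1]`, with `c_max = 10000` nM the maximal assay
  concentration, so `s(1 nM) = 1` and `s(10000 nM) = 0`. The logarithmic
  form mirrors the free-energy scale of binding and makes the conventional
  global cutoff 0.9 correspond to low-nanomolar binding (Kd ≈ 2.5 nM).
  The transform is exposed rather than hard-wired; any monotone
  decreasing map can be substituted upstream.
* `binarize_global(threshold)` calls a target inhibited when
  `s ≥ threshold`. `binarize_drug_specific(fold = 50)` instead thresholds
  each drug at 50-fold its own minimal Kd, the convention for kinome
  panels where drugs differ widely in absolute potency. In both, ties
  count as inhibited — a fixed convention so that reruns and reimplementations
  agree at boundary values.
* Missing measurements are non-binding (Kd infinite, scaled 0). This is
  the only interpretation consistent with screening practice, where only
  plausible binders are measured.
* `filter_targets(min_drugs = 2)` removes targets inhibited by fewer than
  two drugs: a single-drug target carries no information for subset or
  superset inference.
* `collapse_identical_targets()` merges identically inhibited targets into
  a meta-target named `"A/B/C"`. The model cannot distinguish members of
  a meta-target; every downstream statement about a meta-target applies to
  the set, not to a chosen member. `expand_meta_targets()` inverts the
  collapse.

## The TIMMA rules

For a query state `T`, with profiles restricted to the selected set `S`:

1. **Identical-set rule.** If training drugs have profiles equal to `T`,
   the prediction is the mean of their efficacies. Equality takes
   precedence; the following rules see strictly proper subsets/supersets.
2. **Maximization rule (lower bound).** Among drugs with `T(k) ⊂ T`, let
   `k_max` have the highest efficacy. The bound is the mean of
   `y[k_max]` and the efficacies of other subset drugs whose profiles
   contain `T(k_max)` but have lower efficacy (evidence that the extra
   targets of those profiles do not help).
3. **Minimization rule (upper bound).** Symmetric: among drugs with
   `T(k) ⊃ T`, take the minimum-efficacy drug `k_min` and average in
   superset drugs whose profiles are contained in `T(k_min)` with higher
   efficacy.

The prediction is the mean of the two bounds when both exist. The
published description specifies averaging only "if both of these estimates
can be learned"; when exactly one bound exists we return that bound — the
natural reading, since a single bound is still the best available
estimate. With neither, the state is *non-identifiable* (`NA`).

The description of the bound updates does not say whether averaging is
cumulative or pairwise-iterative; we take a single arithmetic mean over
`{k_max} ∪ {qualifying drugs}` (likewise for `k_min`). A running pairwise
mean would weight drugs unequally by an arbitrary scan order, which
contradicts the order-invariance the rules otherwise have; ties in
`which.max`/`which.min` break to the lowest index.

States are held as integer bitmasks over `S`, so subset tests are single
`bitwAnd` comparisons; `|S|` is capped at 30 (R's 32-bit integer bit
operations). Selected sets in practice stay well below 20.

### Leave-one-out objective

`loo_error()` predicts each drug from the other `n − 1` and averages
`|ŷ − y|`. A non-identifiable LOO prediction contributes `|y − 0.5|` by
default: the error a maximally uninformative guess at the middle of the
efficacy scale would make. This choice is not fixed by the methodology;
`na_policy = "skip"` (drop the drug) and `"worst"` (charge 1) are
provided, and the same policy is applied to both predictors so
comparisons are like-for-like.

## The PKIM baseline

The PKIM rule is re-implemented from its published verbal description —
the efficacy accumulated from the subset profiles of the query, relative
to the loss of efficacy `1 − y` in its superset profiles — because the
original closed form is not available in our source material. We use

```
est(T) = clip01( mean{ y_k : T(k) ⊆ T } − mean{ 1 − y_k : T(k) ⊇ T } )
```

with non-strict families (a profile equal to `T` is in both), equal
weighting of the two families, and `NA` (non-determinable) when either
family is empty. Clipping to `[0, 1]` keeps the baseline on the efficacy
scale, as required for a fair absolute-error comparison; `clip = FALSE`
exposes the raw difference. Internal consistency is checked in the test
suite against an independently coded transcription of the same
description. This is a reconstruction, not a port of the original PKIM
code, and results attributed to PKIM here should be read with that caveat.

## Model selection

`sffs_select()` implements the four-step floating search: initialize at
the best single target; *Inclusion* adds the error-minimizing target and
exits when no addition strictly decreases the error; *Conditional
exclusion* removes the least harmful target, keeping the removal only if
the reduced set beats the best error previously achieved at that
cardinality; *Continuation* keeps shrinking while strictly improving on
historical bests, then returns to Inclusion. Decisions:

* "Decreases the error" is strict, with tolerance `1e-12`, and the
  historical-best comparison is strictly-better. Better-or-equal
  comparisons can cycle through tied sets; strictness guarantees
  termination (each accepted move strictly improves some `best[k]`), with
  a `max_moves` cap as a loud safety net.
* Ties among candidate targets break to the lowest column index, making
  runs deterministic; `selection_ci()` provides seeded random restarts
  (random single-target starting points, the natural reading of "random
  starting points") for an empirical spread of the attained objective.
* During Inclusion, candidate states are derived incrementally from the
  cached bitmasks of the current set (one added bit column) rather than
  rebuilt; tests assert every accepted move's error equals from-scratch
  recomputation.

`greedy_select()` is the strictly forward baseline (no exclusions);
`exhaustive_select()` enumerates all subsets of at most 20 candidates and
serves as the optimality oracle. `optimality_experiment()` evaluates all
three on random candidate draws under the TIMMA objective and reports
relative distances `(err − opt)/opt` (absolute when `opt = 0`); the
heuristics are compared with the optimum per draw but with each other
only in aggregate, as neither dominates the other instance-wise.

## Scores on the predicted efficacy matrix

`enumerate_efficacy_matrix()` evaluates every state over `S` (or the
at-most-pairwise states). The empty state is predicted by the same rules
(it is a subset of everything, so only the minimization rule can apply);
when non-identifiable its baseline defaults to 0 — no inhibition, no
predicted kill.

**Synergy.** The default null is Bliss independence on the efficacy
scale, `y_A + y_B − y_A·y_B`, equivalently a multiplicative model on
survival fractions; the pure product null `y_A·y_B` is available via
`null = "product"`. The two coincide exactly when either single efficacy
is 0, so data of that shape cannot distinguish them; the choice is
recorded in every output table (`attr(, "null")`). Drug-pair synergy
averages the cross target pairs of the two drugs, skipping same-node
pairs (a node cannot be combined with itself) and non-identifiable pairs.
siRNA synergies divide percentages by 100, apply the identical null, and
multiply back, so predicted (0–1) and measured (0–100) scores are never
mixed mid-calculation.

**Synthetic lethality.** Drugs are grouped by their joint (A, B)
inhibition state; three structures are fit by pooled group means —
parallel (`{11}` vs the rest), series (`{01,10,11}` vs `{00}`), and
singleton, taken as the better of the two single-target splits (the
alternative reading, "no target effect at all", would make the singleton
fit independent of A and B and never competitive, collapsing the score to
a series-vs-parallel contrast). The score is
`min(TSS_series, TSS_singleton)/TSS_parallel`, oriented so larger means
stronger synthetic lethality; a perfect AND pattern (parallel TSS 0)
returns the `Inf` sentinel, and when numerator and denominator are both 0
all structures fit perfectly and the score is 1 (no preference). The
anchor-anchor pair, whose three structures always coincide (score 1), is
the baseline for `rank_synthetic_lethal_partners()`; tied targets —
necessarily ones inhibited by the same drug set — share a rank.

**Networks.** Binarizing the efficacy matrix at threshold θ gives a
Boolean function of the inhibition state; non-identifiable states count
as not effective. Noisy predictions can make this function non-monotone,
which contradicts the model's own assumptions, so it is repaired by
monotone closure (a state is effective if any sub-state is), with the
number of repaired states reported and warned about. The minimal
effective sets (prime implicants) are extracted, and the pathway family
is their minimal-transversal dual: a state is effective iff it intersects
every pathway. This round trip is asserted exactly on every construction.
The threshold has no universal default; the case-study convention is the
scaled efficacy of a reference drug known to be active (e.g. 0.318 in one
breast-cancer analysis), and `run_full_pipeline()` falls back to the
midpoint of the training efficacy range.

## The synthetic-data generator

`simulate_dataset()` draws affinities and efficacies i.i.d. uniform on
`[0, 1]` for 100 drugs and 10 targets by default — deliberately the
hardest case, with no structure linking targets to efficacy and maximal
uncertainty about the interactions. It emulates the scale and marginals
of a kinome screen but none of its correlation structure: real binding
profiles are sparse and clustered by chemotype, and real efficacies do
depend on targets. Benchmarks on these data therefore measure the
robustness of the inference rules, not biological signal recovery;
passing them says nothing about any particular cancer screen.
`planted_network_dataset()` complements it with the opposite regime:
efficacy is exactly the indicator of blocking every planted pathway
(baseline near 0 otherwise, optional clipped Gaussian noise). With
`replicate_profiles = 2` every realized profile appears at least twice,
which guarantees that noise-free data determine the planted function
under leave-one-out evaluation — the premise of the recovery tests; with
fully random profiles a singleton state can make even the global optimum
strictly positive.

`threshold_sweep_compare()` runs the benchmark: per threshold and
replicate, binarize and compute both predictors' LOO errors on the full
target set. Model selection is *not* re-run per threshold — with an
80-point grid and 100 replicates that would be computationally
disproportionate, and using the full set keeps the two predictors
compared on identical inputs. "Accuracy" is `1 − mean LOO error` and
"improvement" is `100·(acc_TIMMA − acc_PKIM)/acc_PKIM`; both definitions
are printed in every report because they are conventions, not forced by
the data. The grand mean averages thresholds below 0.8, the promiscuous
regime where drugs retain on average more than two targets (at threshold
`t` a uniform affinity survives with probability `1 − t`, so the expected
targets per drug is `(1 − t)·m`). Above 0.9 profiles are nearly empty,
both predictors degenerate to the same non-informative behavior and the
comparison is vacuous.

Problem sizes used by the shipped checks: the acceptance script runs the
full 100-replicate, 80-threshold sweep; the test suite runs 50 replicates
of the same sweep, 1000 random oracle-equivalence instances (3–7 drugs,
2–4 targets), 100 selection-optimality instances, and desk-scale fixtures
elsewhere — sizes chosen so the whole suite completes in a few minutes
while keeping Monte-Carlo error well inside the asserted tolerances.

## siRNA screen processing

Replicate inhibition percentages are averaged per knockdown
(`qc_and_average()`); when two replicates disagree by more than 15
percentage points (absolute — treating it as relative would make the rule
vacuous at the low-inhibition end, where measurement noise dominates) and
exactly one sits on a plate edge, the edge well is dropped. Discordant
pairs with zero or two edge flags are kept whole with a warning — the
conservative choice that never silently discards data. Single-knockdown
values are normalized by averaging in the lower double-knockdown values
involving the same gene, never increasing a single
(`normalize_single_knockdown()`). `compare_predicted_measured()` averages
measured synergies within model node pairs, correlates them with the
predictions by Kendall's tau-b (`stats::cor.test`), and compares
High/Low predicted-efficacy groups with rank-sum tests; the High/Low
cutoff is the mean predicted pair efficacy computed from the data at
hand, not a hard-coded constant.

## Known limitations

* The set rules are blind to dose: a "1" in `X` is a fixed, drug-specific
  notion of engagement, and combination predictions inherit whatever the
  binarization threshold encodes.
* Non-identifiability grows with profile sparsity; at high thresholds
  most states carry no subset/superset evidence and predictions revert to
  the `na_policy`.
* Meta-targets bound the resolution: no statement can distinguish members
  of a node, including in the synthetic-lethality rankings.
* The PKIM baseline is a documented reconstruction from a verbal
  description (see above); absolute baseline numbers should be read with
  that caveat, though its qualitative behavior (non-determinable states,
  no identical-set rule, no single-bound fallback) follows the
  description exactly.
* Exhaustive search is capped at 20 candidates and full matrix
  enumeration at 20 targets; beyond that the floating search and the
  pairwise matrix mode are the supported paths.
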