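---
title: "Inferring signed gene regulatory networks with MIC screening and a fuzzy activator-repressor model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring signed gene regulatory networks with MIC screening and a fuzzy activator-repressor model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzygrn)
```

## The problem

Time-series expression experiments — the DREAM3/DREAM4 in-silico
challenges, or the *E. coli* SOS DNA-repair module — observe a handful of
short trajectories over tens of genes. The inference task is to recover the
directed, signed regulatory structure: which genes activate or repress
which targets. Exhaustive model-based approaches scale badly (for `n` genes
a classical fuzzy model scores `n (n-1) (n-2)` activator–repressor–target
triplets) and purely associational approaches recover many false edges and
no signs. `fuzzygrn` implements a two-stage hybrid:

1. **Screening.** For every target gene, candidate regulators are ranked by
   the lagged maximal information coefficient (MIC): the regulator's value
   at time *t* against the target's value at *t + 1*. Genes scoring at or
   above a threshold (per-target mean by default, or a fixed value) form
   the target's candidate set. This prunes the triplet search from
   `n (n-1) (n-2)` to `sum over targets of m (m-1)` for candidate-set
   sizes `m`.
2. **Fuzzy scoring.** Every ordered (activator, repressor) pair from the
   candidate set is asked to reproduce the target's trajectory through a
   Mamdani-style fuzzy rulebase. Pairs are ranked by a residual score and
   the best pairs emit signed edges: activator `+`, repressor `-`.

## Stage 1: the lagged MIC

For a sample `D` of `n` pairs, MIC is the maximum over axis-aligned grids
of the normalized mutual information

$$\mathrm{MIC}(D) = \max_{XY \le B(n)} \frac{I^*(D, X, Y)}{\log_2 \min(X, Y)},
\qquad B(n) = \lfloor n^{0.6} \rfloor,$$

where `X`, `Y` are the grid's column and row counts and `I*` the maximal
mutual information over placements of that shape. We use the conventional
non-strict bound `XY <= B(n)` (a strict variant is exposed as
`grid_strict`) and floor `B(n)` at 4 so the minimal 2x2 grid is always
admissible. Because lagged pairs are formed within each series and
concatenated across series, the matrix of all ordered gene pairs is
asymmetric by construction, and boundaries between independent experiments
are never straddled.

Placement search uses the ApproxMaxMI heuristic: equipartition one axis
(ties — identical expression values — are never split), partition the
other axis optimally by dynamic programming over value clumps (capped at
`C = 15` superclumps per column), and take the maximum over both
orientations. One refinement: when an axis has at most `min(B(n), 6)`
distinct values, all of its partitions are enumerated in place of the
single equipartition. This is cheap (at most `2^5` partitions), removes
the equipartition approximation exactly where it bites (heavily tied
axes), and makes the heuristic provably agree with the exhaustive
enumeration oracle on such samples — which the test suite exploits: the
package also ships `mic_bruteforce_oracle()`, an independent pure-R
enumeration of every admissible grid for `n <= 25`, and asserts that the
heuristic never exceeds it and meets it on tied axes.

Screening thresholds are inclusive (`>=`): with the per-target mean
threshold this guarantees at least one candidate on non-constant data.

## Stage 2: the fuzzy activator–repressor model

### Regulatory effect

Each regulator enters the rulebase not by its expression alone but by its
*regulatory effect*: regulatory relationship strength (its MIC score with
respect to the target) times its normalized expression, min-max normalized.
Min-max normalization is scale invariant, so normalizing a single
regulator's effect alone would cancel the MIC factor entirely. The package
therefore normalizes the activator's and repressor's raw effects **jointly
over the pair's pooled values** inside `score_pair()`: the stronger
regulator of a pair spans more of `[0, 1]`, the weaker is compressed
towards Low. The ablation `rrs = FALSE` reproduces the classical model, in
which the (dataset-normalized) expression levels enter directly; the two
modes coincide exactly when both regulators carry equal MIC scores.

### Fuzzification

Effects are fuzzified into Low/Medium/High by three uniform triangles with
vertices `(0, 0, 0.5)`, `(0, 0.5, 1)`, `(0.5, 1, 1)`. These vertices are
fixed by back-solving the method's single published worked example — an
effect of 0.4 must give Low 0.2, Medium 0.8, High 0 — and they are the
unique uniform triangular partition of unity consistent with it:

```{r}
input_membership(0.4)
```

The partition-of-unity property (memberships sum to 1 everywhere) matters
operationally: some rule always fires, so the defuzzification fallback is
provably unreachable under the defaults.

### Rulebase and aggregation

The 3x3 rule matrix maps (activator level, repressor level) to one of five
output levels VL, L, Med, H, VH:

```{r}
fuzzy_config()$rule_matrix
```

Only the anchor cell — activator High AND repressor Low gives Very High —
is fixed by the method's description; the rest is completed as the unique
monotone (non-decreasing in activator, non-increasing in repressor),
antisymmetric completion over five levels. The five output levels are
uniform triangles `VL (0, 0, 0.25)` through `VH (0.75, 1, 1)`; uniform
spacing is the standard construction where no exact layout is
prescribed. Both the memberships and the matrix are
config-overridable (`fuzzy_config()`, serializable with
`write_fuzzy_config()`; the shipped `inst/extdata/fuzzy-default.conf`
reproduces every default), so a different published matrix can be dropped
in without touching code. Rule firing is Mamdani min; each rule's output
triangle is clipped at its firing strength and rules are combined by
bounded sum, `min(1, sum of clipped memberships)`.

### Defuzzification

The aggregate is defuzzified by centroid over a discretized universe with
step 0.001 (midpoint-rule sums). The step was chosen so the discretization
error (about half a step) is far below expression noise; the antisymmetry
of the default configuration — swapping activator and repressor mirrors
the output around 0.5 — holds to within two steps and is asserted in the
tests. A zero aggregate would return 0.5 and be flagged, but cannot occur
under the defaults (see above).

### Residual score

For each series and each timepoint `t >= 2`, the pair's effects at `t - 1`
predict the target at `t`. With `P` predicted points pooled over series:

- `MSE = (1/P) * sum (Y_t - Yhat_t)^2`. The method's printed formula
  divides by the total timepoint count `T`, which is ill-defined when
  several independent series are stacked; any fixed positive denominator
  leaves the pair ranking unchanged, so the per-predicted-point form is
  used and documented here as a deliberate divergence.
- `variance` = population variance (divide by 9) of the nine per-rule
  firing **counts** — a rule counts as fired at a timepoint when its
  strength exceeds `firing_epsilon = 1e-9`; counts, not summed strengths,
  because evenness of rule usage is what is being measured. Variance taken
  across rules (not across time) is the reading consistent with "all rules
  evenly fired over all timepoints".
- `rs = MSE * variance`; low is good. Within a target, `rs` is min-max
  normalized to `nrs` (best pair 0, worst 1; all-equal gives all 0).

Selection keeps pairs with `nrs` at or below a threshold (default 0.05),
or the `k` lowest-`rs` pairs (`top_k`, the mode used for larger networks;
ties break by gene order for determinism). Kept pairs emit signed edges; a
gene appearing in both roles for one target is resolved to the role of its
lowest-rs kept pair, reflecting the one-role-per-context assumption.
`assemble_network()` unions per-target selections and resolves any
duplicate edge to the lower-rs occurrence.

## Evaluation

`confusion()` compares directed, unsigned edges over all `n (n-1)`
non-self ordered pairs (self-regulation is excluded throughout, matching
the benchmarks' convention); `network_metrics()` derives precision,
TPR/recall, FPR, specificity, F-score, SS_mean, MCC and structural
accuracy. SS_mean is not defined in the source literature; it is
implemented as the harmonic mean of sensitivity and specificity with
geometric and arithmetic variants selectable, and comparisons against
published SS_mean values should bear that choice in mind. When a signed
truth is available (the synthetic module), `signed_accuracy()` reports the
fraction of recovered true edges with the correct sign.
`combinatorial_reduction()` reports the screening stage's pruning
percentage, `100 (1 - sum m (m-1) / (n (n-1) (n-2)))`.

## The synthetic generator

`generate_network()` plants, per target, one activator and one repressor
(`density = 2`, the default study condition) drawn uniformly without
replacement. `simulate_expression()` draws initial values Uniform(0, 1)
and then iterates the *same* fuzzy rulebase as ground-truth dynamics:
each regulated gene's next value is the defuzzified rulebase output of its
parents' current values plus Gaussian noise (sd 0.02 by default), clipped
to `[0, 1]`; unregulated genes follow a mean-reverting walk (rate 0.2
towards 0.5, innovation sd 0.1 — enough variance to act as informative
drivers). Defaults mirror the DREAM4 10-gene layout: 10 genes, 5 series,
21 timepoints.

Reusing the inference rulebase as the generative law is deliberate: it
creates a well-posed recovery problem that isolates pipeline correctness
from model misspecification, and it makes a sharp self-consistency check
possible — with zero noise, scoring a planted pair against its own target
in the classical-effect mode reproduces the trajectory exactly (MSE is
zero to machine precision). Two consequences should temper interpretation:

- Simulated values are already on the normalized `[0, 1]` scale, so the
  generator returns datasets flagged `normalized = TRUE` (as DREAM
  normalized concentrations are) and the pipeline does not re-stretch
  them.
- Passing recovery tests on these data shows the pipeline recovers
  structure *when the model family matches the dynamics*. Real expression
  data (kinetic ODE dynamics, measurement noise structure, unobserved
  regulators, more than two regulators per gene) are not emulated; the
  `dynamics = "linear"` mode (`clip(w_a a - w_r r + b)` plus noise) is
  provided to probe mild misspecification, and performance on real DREAM
  downloads must be assessed with the documented workflow in the README,
  not inferred from these tests.

Under the default conditions (10 genes, density 2, 5 series of 21
timepoints, noise sd 0.02, mean-MIC screening, `nrs <= 0.05`, seeds 1-10)
the test suite requires mean F-score at least 0.5 and sign accuracy at
least 80% on recovered true edges; the observed values are well above
both bars.

## Numerical and design choices, in brief

- MIC: `alpha = 0.6`, `C = 15` (published MINE defaults), bound
  `XY <= max(floor(n^0.6), 4)`; ties kept in single clumps; exhaustive
  axis enumeration below 7 distinct values; C++ core, pure-R oracle.
- Thresholds compare inclusively (`>=` for MIC screening, `<=` for nrs).
- Defuzzification step 0.001; centroid by midpoint sums; no-fire fallback
  0.5 (unreachable under defaults).
- Degenerate inputs: constant genes normalize to all zeros with a warning;
  constant MIC inputs score 0 with a warning; candidate sets smaller than
  two yield a logged, non-fatal "no inferable regulators" outcome.
- Determinism: the pipeline has no unseeded randomness; selection ties
  break by input gene order; run logs record candidate sizes, thresholds,
  the reduction percentage and an MD5 hash of the exact fuzzy
  configuration.
- Problem sizes in the tests (10-gene networks, 5x21 series, 10 seeds;
  oracle samples at `n <= 20`) match the method's small-network study
  conditions while keeping the suite quick to run.

## Known limitations

- The off-anchor rulebase cells and the output-level layout are a
  reconstruction constrained by monotonicity, antisymmetry and the anchor
  rule; a differing original matrix would change numbers, which is why the
  configuration is serializable and overridable.
- SS_mean's formula is assumed (harmonic), not sourced.
- At most one activator and one repressor are modelled per prediction;
  multi-regulator logic beyond pair composition is out of scope.
- Self-regulation is deliberately not inferred or evaluated.
- MIC screening needs enough lagged samples per series pair; datasets with
  very few timepoints will screen poorly before the fuzzy stage ever runs.
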