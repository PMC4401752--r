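---
title: "Grammar inference for phosphosite prediction: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grammar inference for phosphosite prediction: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosgram)
```

## The model

phosgram predicts kinase-specific phosphorylation sites by learning a
probabilistic regular language over substrate windows. A *window* is the
`2·flank + 1` residues centered on a candidate serine or threonine, with
positions past a protein terminus padded by `X` ("any residue") so the
candidate always sits at the center. The modelling assumption is that the
substrate specificity of a kinase is carried by short-range sequence context
around the site, so that the set of substrate windows of one kinase forms a
(stochastic) regular language that can be inferred from positive examples
alone.

Training proceeds in two stages:

**Prefix tree acceptor.** The training windows are threaded into a trie-shaped
deterministic automaton with one state per distinct prefix. Each state `q_i`
carries the Alergia frequency estimates: `n_i` strings arriving, `f_i(a)`
strings leaving on symbol `a`, and `f_i(#)` strings terminating. Flow
conservation `n_i = f_i(#) + Σ_a f_i(a)` holds at every state and is asserted
throughout the test suite. States are numbered in *standard order*
(breadth-first, symbols alphabetical), which fixes the pair-scan order of both
Alergia and RPNI and makes serialized models reproducible.

**State merging.** Alergia folds statistically equivalent states. Two observed
frequencies are *different* when

> |f1/n1 − f2/n2| > sqrt(0.5 · ln(2/α)) · (1/√n1 + 1/√n2)

and two states are *compatible* when their termination frequencies, their
outgoing frequencies for every symbol, and (recursively) every pair of
same-symbol successors all pass the test. A missing successor participates as
a zero-count state, whose bound is unbounded, so it is compatible with
anything. The scan enumerates ordered pairs (`j` ascending from the second
state, `i` ascending below `j`), folds the first compatible pair, continues
with the next `j`, and repeats whole passes until none merges. Merging is
implemented as a union-find quotient with a determinization closure: blocks
forced together by a shared outgoing symbol are merged too, and all counts are
summed blockwise, so determinism and flow conservation are invariant under
every merge. On tree-shaped regions this is exactly the classic recursive
fold; unlike the literal recursion it stays well-defined when later passes
merge states inside already-cyclic regions.

The surviving counts give the deterministic stochastic automaton: transition
probabilities `P_ij(a) = f_i(a)/n_i`, final probabilities `P_if = f_i(#)/n_i`,
normalized per state (`P_if + Σ P_ij(a) = 1`, checked to 1e−9 on random
training sets). The probability of a window is the product of transition
probabilities along its unique path times the terminal final probability;
because the automaton is deterministic this path product coincides with the
general state-vector recursion, and the suite asserts that equivalence against
an independent implementation on random automata.

## Scoring, smoothing and localization

A model trained on positives only assigns probability zero to most unseen
windows. At scoring time every zero (or missing) transition and termination
probability that the path consults is therefore floored at a small
**smoothing** value, 0.01 by default. The stored parameters are *not*
renormalized: the floor is a lookup-time device, the normalization identity is
a property of the unsmoothed parameters, and 0.01 keeps its stated value. Once
a path leaves the automaton each remaining step contributes the floor, so a
7-mer with no matching prefix scores `0.01^8`. Classification compares the
*smoothed* probability against the decision threshold — with unsmoothed
scoring almost every non-training window would score exactly zero and the
threshold would be inert.

When a window contains several S/T residues, the phosphorylated one is
localized by the **emission probability** of each S/T along the window's state
path: the transition probability of that symbol from the state reached at its
position (the smoothing floor where the step is missing). The highest emission
wins; exact ties go to the leftmost candidate, a deterministic and reportable
rule.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `flank` | 3 | residues each side of the site; window width 7. Window width 7 is the best-performing operating width for this method; wider extractions (e.g. 21-mers, `flank = 10`) are the same operation, and `trim_window()` derives narrow windows from stored wide ones. Training and prediction must use the same flank. |
| `alpha` | 0.7 | Alergia confidence in (0, 1]. The bound *shrinks* as `alpha` grows: large values merge conservatively, small values generalize aggressively. |
| `smoothing` | 0.01 | scoring-time probability floor. |
| `threshold` | 0.008 | decision threshold on `p(w)` for calling a site. |
| `identity_threshold` | 0.6 | greedy redundancy filter: a window is kept iff its ungapped column identity to every previously kept window is ≤ 60%. Windows are equal-length and short, so column identity is a faithful stand-in for an alignment-based filter and needs no external program. |
| `train_fraction`, `neg_ratio` | 0.6, 10 | 60/40 positive split; test sets hold 10 negatives per positive, reflecting the real scarcity of phosphosites among S/T residues. |
| `min_count` | 0 | optional guard excluding low-count states from merge tests; 0 reproduces the pure algorithm. Short-window PTAs have many singleton states, so a positive guard is available for experimentation. |

## The evaluation layer

`compute_metrics()` derives precision, recall, accuracy, F-measure,
sensitivity and specificity from a confusion table; degenerate denominators
yield 0 with a `degenerate` flag rather than an error so resampling loops
never abort. `roc_points()` sweeps a threshold grid (default 0.001–0.010 in
steps of 0.0005, covering the region where the operating point 0.008 lives).
`cross_validate()` shuffles positives into k (default 10) folds, trains on
k−1 parts and tests on the held-out positives plus `neg_ratio` times as many
negatives, sampled without replacement *fresh per fold* with a fold-derived
seed; reusing negatives across folds is deliberately avoided so fold metrics
are exchangeable. `bootstrap_evaluate()` draws B resamples of the positive
set with replacement, each of the original size (the asymmetric bootstrap:
only positives are resampled, the negative pool is fixed), and runs the
seeded cross-validation once per resample — one metrics row per resample.
`paired_t_test()` is the classic one-sided paired t on accuracy differences
(alternative: the first method is better), df = n−1, rejection at 5%; the
degenerate zero-variance case returns t = 0, p = 0.5 for identical series
rather than erroring.

The RPNI and GA baselines produce plain accept/reject DFAs, so they carry no
score to sweep: they are excluded from ROC analysis and compared on accuracy
via `compare_gi()`, which runs all methods on identical repeated 60/40 splits
and reports the paired t-tests. The GA's hyperparameters (population 50, 100
generations, mutation 0.05 as "move one state to a random block",
single-point block-exchange crossover 0.8, elitism 1, fitness weights 1 and
10 on states and errors) are package choices: the DFA search spaces here are
small, and elitism makes the best-fitness trajectory monotone and therefore
testable.

## The synthetic generator

`motif_spec()` describes windows as an S/T center plus positional preferences:
each preferred offset takes a residue from its set with probability
`adherence`, otherwise from a background composition (uniform over the 20
amino acids by default — a table-driven background accepts realistic
compositions). Four presets loosely styled after familiar substrate
preferences (PKA-like basic at −3/−2, CK2-like acidic at +1/+3, MAPK-like P
at +1, PKC-like basic at −3/+2) serve as test fixtures, not biological
claims. Negatives are S/T-centered pure-background windows, emulating
non-phosphorylated S/T residues of substrate proteins.

What the generator does *not* emulate matters for interpreting green tests:
real substrate windows have correlated positions, family-internal
heterogeneity, shared homology between windows (the redundancy filter exists
precisely because of it), and non-uniform residue composition. Passing the
synthetic end-to-end gate (mean positive score above mean negative score,
correct center localization) therefore demonstrates that the inference
machinery recovers a planted positional signal — not that any particular
accuracy will be attained on curated phosphosite databases.

## Numerical and design choices

- **Recovery study conditions.** The parameter-recovery experiment samples
  2,000 strings per seed from a fixed 2-state generator (state 1:
  P(A→s2) = 0.4, P(B→s1) = 0.3, end 0.3; state 2: P(A→s1) = 0.2,
  P(B→s2) = 0.5, end 0.3) and requires the learned automaton to have exactly
  two states with all parameters within 0.05. It runs at `alpha = 0.05`: the
  Hoeffding tolerance shrinks like `sqrt(ln(2/α))` as `alpha` grows, and at
  the package default 0.7 the bound between two truly identical states with
  hundreds of observations is tighter than binomial sampling noise, so the
  machine fragments instead of collapsing. Choosing a small `alpha` for
  recovery-style experiments follows directly from the analytic form of the
  bound; the default 0.7 remains appropriate for conservative,
  structure-preserving merging on real windows.
- **Problem sizes.** The test experiments use 120–200 training windows,
  40–60 test positives with 10× negatives, B ≤ 10 bootstrap resamples with
  k ∈ {2, 3} folds, and 50-case property loops — sizes chosen so each
  experiment still has clear statistical resolution (binomial noise well
  under the asserted margins) while the whole suite runs in well under a
  minute of compute per file.
- **Degenerate inputs.** Empty training sets, out-of-alphabet symbols,
  S/T-free windows, infeasible class ratios, fold counts exceeding the
  positive set, and inconsistent RPNI samples all raise classed errors;
  metric degeneracies flag instead of erroring (see above).
- **Determinism.** Every stochastic routine takes an explicit seed and
  derives per-fold/per-resample seeds from it, so outputs are reproducible
  independently of execution order; RNG state of the caller is never
  disturbed (`withr::with_seed`).
- **Conservation under merging.** Blockwise count summation preserves flow
  conservation at every state and total termination counts (every training
  string terminates exactly once). The arrival count of the initial state
  grows if the root itself joins a merged block — arrivals through loops are
  then counted — which is the correct frequency semantics for the quotient's
  probability estimates.
- **Weak-motif comparisons.** When comparing models across motif strengths,
  the suite fixes the operating point at a constant specificity (the 95th
  percentile of negative scores) rather than a constant threshold, so the
  F-measure comparison is not confounded by the score scale changing with
  adherence.

## Limitations

- Only S/T-centered windows are modelled; Y/H phosphosites are out of scope.
- The automaton captures exact positional preferences; degenerate or
  gapped motifs dilute into many low-probability paths and are learned less
  efficiently than by profile models.
- Probabilities of fixed-width windows over a 21-symbol alphabet are small in
  absolute terms (a uniform 7-mer scores ~2·10⁻⁹); decision thresholds are
  meaningful relative to the learned score distribution, and the published
  operating point 0.008 presumes the heavily merged automata obtained on real
  kinase data.
- The baselines are the textbook algorithms (no blue-fringe/EDSM heuristics,
  no exact minimal-DFA search), as they serve as comparison points, not
  production classifiers.
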