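---
title: "From linguistic evidence to simulatable social models: methods behind socialfcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From linguistic evidence to simulatable social models: methods behind socialfcm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialfcm)
```

## The problem

Homelessness, like most complex social phenomena, is driven by factors —
addiction, family breakdown, education, income, housing cost — that interact
dynamically. Static regression-style summaries of any single link miss the
feedback structure. A fuzzy cognitive map (FCM) keeps the qualitative
character of the evidence while making the system simulatable: concepts are
nodes, causal claims are signed weighted edges, and the whole graph is
iterated as a discrete dynamical system.

`socialfcm` implements the full pipeline and ships one worked application:
a map of 14 concepts and 31 directed influences over the social
determinants of homelessness, each influence supported by three linguistic
statements from empirical studies.

## Grading linguistic evidence

Each statement ("significantly associated", "did not predict", ...) is
graded on a five-level ordinal scale VL < L < M < H < VH against a closed
word bank (`homelessness_lexicon()`). Lookups are exact-phrase after
case-folding; there is no stemming, because the bank is a curated record of
the phrases actually encountered, not a general NLP resource. Two phrases
in the published bank appear under two levels ("most effective",
"statistically significant"); the packaged transcription keeps both
listings, and the lexicon constructor resolves duplicates by an explicit
policy (default: first listing, scanning levels upward). `lookup_level()`
refuses unknown phrases rather than guessing.

## From levels to weights: the fuzzy inference system

The five levels are triangular fuzzy sets on the weight universe [0, 1]:

| level | (left, peak, right) |
|-------|---------------------|
| VL    | (0, 0, 0.25)        |
| L     | (0, 0.25, 0.5)      |
| M     | (0.25, 0.5, 0.75)   |
| H     | (0.5, 0.75, 1)      |
| VH    | (0.75, 1, 1)        |

Every point of the universe has positive membership somewhere and adjacent
levels cross at 0.5. Each edge's three statements become three Mamdani
rules whose antecedent ("the source concept is ON") is binary and fully
fired, so min-implication passes each consequent set through unchanged.
Aggregation is the pointwise maximum, sampled on a uniform grid (default
1001 points); defuzzification is the centroid, computed by the trapezoid
rule. The influence's sign is applied after defuzzification — the fuzzy
machinery only ever produces a magnitude in (0, 1).

This geometry is the unique symmetric five-level triangular partition
consistent with the exactly checkable worked values: three Low statements
defuzzify to 0.25, and the symmetric set {M, L, H} to exactly 0.5. For
rule sets touching the boundary shoulders the centroid differs by up to
about 0.02 from the values published for the original system (0.667 here
versus 0.648 for {M, H, VH}); the published system's exact shoulder
realization and universe discretization are not recoverable, so boundary
cases carry a ±0.02 calibration band. Grid refinement is immaterial at
this scale: doubling the grid moves no value by more than 1e-3.

### A property worth knowing: max-union centroids are not monotone

Raising one statement's level usually raises the defuzzified magnitude, and
always does when the levels involved stay within the interior set
{L, M, H}. It can, however, *lower* it when boundary shoulders are
involved: raising H to VH in {M, H, VH} folds the unique H hat into the VH
shoulder, the union loses its interior mass near 0.75, and the centroid
drops from 0.667 to 0.639. This is an intrinsic property of
maximum-aggregation with centroid defuzzification, confirmed here by
adaptive quadrature independent of the grid implementation — not a bug,
but worth remembering when reasoning about "stronger evidence ⇒ larger
weight". 19 of the 84 possible single-level raises over the 35 unordered
triples behave this way, all involving VL or VH.

## The dynamical engine

States update synchronously: the raw activation of concept *i* is
`Σ_{j≠i} A_j W_ji + m·A_i`, with `m ∈ {0, 1}` the self-memory setting, then
a threshold function is applied, then clamped concepts are overwritten.
Two thresholds are supported:

* **sign** — activations in {−1, 0, 1}. The state space is finite (at most
  3^N states), so the trajectory always revisits a state: an immediate
  repetition is a fixed point ("converged"), a longer one a limit cycle,
  reported with its period. The convergence tolerance ε is ignored.
* **tanh** — activations in (−1, 1). Iteration stops when no concept moves
  by more than ε (default 1e-5), or at `max_iter` (default 100).

The stored weight matrix's diagonal never enters the update sum; the
packaged six-concept heart-disease demonstration map stores its printed
diagonal of ones, but its printed trajectory is only consistent with the
self-term excluded and the driving concept clamped, which is exactly the
sign-mode default (`self_memory = 0` plus an explicit clamp). The tanh
case studies use `self_memory = 1` and no clamping, so activated concepts
can evolve. Both are settings, never hard-coded. "Four steps to converge"
counts produced state vectors including the initial one.

A practical note on tanh termination: concepts with no incoming edges decay
as `a ← tanh(a)`, which approaches 0 only algebraically, so runs containing
such concepts can hit `max_iter` before meeting ε even though the outcome
concept saturated long before. Classification therefore reads the final
outcome level, matching the plateau behaviour of the trajectories.

## Scenarios

A scenario activates a few concepts at levels in [0, 1] and never
pre-activates the outcome. The three packaged prototypical cases probe the
extremes and the middle: (1) addiction 0.65, family breakdown 0.57,
government assistance 0.46, mental illness 0.61; (2) addiction 0.30 against
education 1.0, income 0.72, social support 0.61, family breakdown 0.30;
(3) a mixed configuration (addiction 0.20, support 0.11, education 0.94,
family breakdown 0.51, income 1.0). The final homelessness level classifies
the outcome: ≥ 0.9 "likely", ≤ 0.1 "unlikely", otherwise "uncertain". The
0.9/0.1 cutoffs mirror the saturated-versus-near-zero separation of the
extreme cases and are configurable; they are a reporting convention, not a
fitted quantity. Under the defaults the final levels order Case 1 > Case 3
> Case 2, stably across ε ∈ [1e-6, 1e-4], and model exploration shows
addiction below 0.30 cannot overwhelm strong education and social support.

## Network analysis

* **Degree centrality**: sum of absolute incident weights, in plus out,
  self-loops excluded by default (the published single-edge rows are only
  consistent with their exclusion).
* **Closeness centrality**: edge lengths are inverse absolute weights
  (`1/|w|`; the weakest packaged edge, 0.25, gives the longest single-edge
  distance, 4). Shortest directed paths are computed on true infinities
  first — Big-M (default 100) is substituted only into the final sums, so
  the penalty can never appear inside a multi-hop path. With 14 concepts
  and a maximum edge distance of 4, no finite path exceeds 52, so 100 is
  safely "infinite"; raising it rescales values but provably preserves the
  ranking, which the tests assert at Big-M ∈ {100, 1000}. Raw closeness is
  of order 1e-3, so a ×10⁴ display scale is reported alongside.
* **Sensitivity sweeps**: one concept's initial value varies over
  0.1, ..., 1.0 while all others start at a common low baseline (0.01,
  outcome at 0) and the outcome is read after 3 tanh updates. The low
  baseline and short horizon keep the map away from saturation — at higher
  baselines or longer horizons every sweep flattens at +1 and discriminates
  nothing. Box-plot summaries (type-7 quartiles) compare concepts: a
  narrow box (addiction) marks a dominant influence, a wide one (cost of
  housing) a variable, weaker one.

Of the published centrality table only the low-degree rows (childhood
homelessness 1.25, income 1.3978, government assistance 1.3844, cost of
housing 0.4984, NGO 0.5) are arithmetically consistent with the published
edge list; the high-degree rows (e.g. education 5.4201, exceeding the
maximum attainable from its five incident edges) are not reproducible from
the printed edges and are excluded from quantitative checks, as is most of
the closeness column beyond the cost-of-housing computation and the
ranking-stability claim.

## Synthetic data

The generators (`random_map()`, `random_evidence()`, `random_scenario()`)
emulate the *structural* properties the analysis relies on — no self-edges,
weight magnitudes in [0.25, 1) as the five-level partition produces, mixed
signs, an optional outcome-only sink node mimicking homelessness — under a
single seeded stream per call that leaves the caller's RNG untouched. They
make every pipeline stage testable without external data, and power
property tests: centrality against brute-force oracles, sign-mode
termination within the 3^N bound, monotone sweeps on all-positive-path
maps. They do not attempt statistical realism of social indicators, so
passing tests demonstrate correctness of the machinery, not empirical
validity of any particular map.

## Numerical choices and limitations

* Centroid integration: trapezoid rule on a 1001-point grid; exact for the
  piecewise-linear memberships' areas, with O(h²) moment error ≪ 1e-4.
* Sign-mode cycle detection hashes exact state vectors; determinism is
  bit-for-bit, and identical inputs yield identical traces and CSV outputs.
* Degenerate inputs: empty knowledge bases give zero matrices; the all-zero
  state is a fixed point; single-concept maps make closeness degenerate and
  are flagged with a warning rather than a silent division by zero.
* Problem sizes in the test suite (maps up to 10 concepts for oracle
  comparisons, 50 random maps, sign-bound checks at N = 5–6) were chosen as
  the smallest sizes that exercise every code path with exhaustive or
  brute-force oracles still cheap to run.
* The packaged map treats homelessness purely as a sink; real feedback from
  homelessness onto its drivers is out of scope, as are learning edge
  weights from data, asynchronous update schemes, and alternative
  defuzzifiers.
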