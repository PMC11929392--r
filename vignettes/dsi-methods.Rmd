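---
title: "Successor-information embeddings: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Successor-information embeddings: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dsi)
```

This vignette is the package's own account of the science it implements:
the successor-information model, the constrained factorization that turns
it into unit-level representations, the spatial and semantic analyses
built on top, and the numerical choices made where the design was open.

## The model

An agent moving through `N_s` discrete states under a fixed default policy
induces the successor representation

$$\mathrm{SR}(s, s') \;=\; \mathbb{E}\Big[\sum_{t \ge 0} \gamma^t\,
\mathbf{1}[s_t = s'] \,\Big|\, s_0 = s\Big],$$

the discounted expected future occupancy of `s'` from `s`. Normalizing its
log by the self-information of the target state gives successor
information, and rectifying at zero gives positive successor information
(PSI):

$$\mathrm{SI}(s, s') = \log \mathrm{SR}(s, s') - \log P(s'),
\qquad \mathrm{PSI} = \max(\mathrm{SI}, 0).$$

PSI plays the same role for state sequences that positive pointwise mutual
information (PPMI) plays for word co-occurrence: treating words as states
and a token stream as a trajectory, SI is a PMI with an asymmetric
exponential co-occurrence window instead of the usual symmetric rectangular
one. The same quantity is, up to a scale, the value function of
goal-directed navigation under linearly solvable control, which is why the
dot product `x(s) . w(g)` of the factorized vectors (below) can drive
greedy navigation toward a goal `g`.

## Estimating SR, occupancy, and PSI

Two estimators are provided.

* `sr_empirical()` is the direct discounted-count estimator: for every
  visit of `s` it accumulates the discounted indicator sum over the rest of
  the trajectory (segment boundaries — documents in a corpus — truncate the
  window). It converges to the analytic SR and is the estimator of choice
  for corpora, where tokens are plentiful relative to the vocabulary and
  the discount horizon is short.
* For spatial walks at `gamma = 0.99` the discount horizon is ~100 steps,
  and the direct estimator needs very long walks before the *logarithm* of
  its far-field entries settles: log-scale noise in rarely counted pairs
  propagates into the factorization as high-frequency artefacts. The
  spatial pipelines therefore use the plug-in (model-based) estimator: the
  empirical one-step transition matrix of the same walk, pushed through the
  closed form `(I - gamma T)^{-1}` (`transition_matrix_empirical()` +
  `sr_analytic()`). Both estimators consume exactly the same walk; the
  plug-in form simply uses the Markov structure the environment actually
  has, and its accuracy is set by the per-state transition counts rather
  than by discounted pair counts.

Occupancy `P(s')` is the empirical visit frequency (or the stationary
distribution when a transition matrix is given); entries with `SR = 0` or
`P = 0` are zeroed and counted in a diagnostics attribute rather than
propagating `-Inf`. Logs are natural; an epsilon floor of `1e-12` guards
`log(0)` and floored entries are rectified away by construction.

Defaults: `gamma = 0.99` for 2-D spaces (grid formation degrades for
`gamma <= 0.98`, which shortens the predictive horizon below the scale of
the room), `gamma = 0.9` for word corpora (a ~10-token window, the scale on
which co-occurrence is informative).

## The factorization and why its decorrelation force is activity-proportional

`dsi_factorize()` fits `PSI ~ X W^T` with nonnegative `X` (state vectors)
and `W` (goal vectors), `D < N_s`, by plain projected gradient descent
(clip at zero after every step) from a seeded nonnegative random start.
The objective (`dsi_objective()`) is

$$\frac{1}{2 N_s}\lVert \mathrm{PSI} - X W^\top\rVert_F^2
+ \frac{\beta}{2 D} \sum_{k \ne l} \mathrm{corr}(X_k, X_l)^2
+ \frac{\rho}{2}\left(\lVert X\rVert_F^2 + \lVert W\rVert_F^2\right)$$

for the decorr variant; the sparse variant replaces the last two terms by
`rho_l1 (|X|_1 + |W|_1)`. The `decorr-nonneg-off` ablation keeps the
decorr objective and drops the projection.

One training detail matters far more than any weight setting: the
decorrelation force is applied in its **activity-proportional
(lateral-inhibition) form** `(beta / D) X R`, where `R` is the off-diagonal
inter-unit correlation matrix — the exact penalty gradient with the
per-unit normalization factors dropped (`dsi_objective()` retains the exact
chain-rule gradient, and the finite-difference check in the test suite runs
against it). The exact gradient of a squared *correlation* is inversely
scaled by each unit's norm: strongly active units feel almost no
decorrelation pressure, weak units feel enormous pressure, and gradient
descent settles into a degenerate solution — a few broad, high-amplitude
"blob" units that carry the reconstruction plus many near-silent noise
units that satisfy the penalty trivially. No hexagonal tuning emerges
anywhere in the (beta, rho) plane under that force (we verified this across
two orders of magnitude in each weight, with both plain and adaptive
steps). The activity-proportional form removes the inverse-norm factor, so
decorrelation pressure grows with unit activity: strong units must
actively repel each other, which forces the population to tile space with
phase-offset periodic fields — the configuration that keeps units
pairwise-decorrelated *and* reconstructs a smooth translation-invariant
kernel. This is also the form decorrelation takes in neural-network models
(lateral inhibition scales with presynaptic activity, not with a unit's
normalized selectivity). With it, roughly a quarter of the state-vector
units of the 30x30 open-room fixture classify as grid cells, in the band
the gridness analysis expects.

Decorrelation acts on the state matrix `X` only (the goal matrix is shaped
by reconstruction and L2 shrinkage); `decorr_w = TRUE` extends it to `W`,
which in our hands lowers the grid fraction of `X` without a compensating
gain — see "Known limitations".

Remaining numerical choices: weights `beta = 1`, `rho = 0.01` (set once so
the three forces sit within an order of magnitude of each other at
initialization on the 30x30 fixture); learning rate `0.05`; `3000`
iterations (grid structure sharpens well after the loss has visually
plateaued — by ~1500 iterations the grid fraction is still only two thirds
of its final value); init scale `sigma = sqrt(mean(PSI) / D)` so the
reconstruction starts on the right overall scale; divergence guard at ten
times the initial loss; all-zero columns are reinitialized once.

## Gridness analysis

`rate_map()` lays a unit's values out on the room; the spatial
autocorrelogram is the Pearson correlation of the map with itself at every
2-D offset over overlapping unmasked cells (FFT-based masked correlation;
offsets with fewer than 20 overlapping cells are undefined; an exact
direct-loop implementation serves as the oracle in the tests). The
gridness score uses the standard rotational contrast: an annulus from the
first local minimum of the radially averaged correlogram (excluding the
central peak) out to 2.5 times the first sidelobe radius — capped at the
largest radius with full angular coverage, so corner cells of the square
correlogram cannot masquerade as rotational structure — and scores
`min(corr at 60, 120 deg) - max(corr at 30, 90, 150 deg)` under bilinear
rotation resampling. A map with no genuine sidelobe (the first "minimum"
rises by less than 0.05) has undefined gridness and is never classified as
a grid cell; this is what a single-field (place-like) or constant unit
produces.

The classification null shuffles each map by randomly *permuting* its
free-cell values (100 shuffles per unit, pooled across units; a unit is a
grid cell if its score exceeds both the pooled 95th percentile and zero).
A circular shift of the flattened free-cell order was considered and
rejected: on a column-major flattening a circular shift is approximately a
toroidal translation of the map, and periodic maps are translation
invariant, so that null *retains* the structure the statistic is supposed
to detect (its 95th percentile on a grid-rich embedding was 0.33 versus
0.05 under permutation) and no periodic unit could ever exceed it.

## Path integration and navigation

`fit_movement_models()` fits one affine map per cardinal action by
ridge-regularized least squares over all legal transitions
(`x(s') ~ M_a x(s) + b_a`; ridge `1e-6` for conditioning). The intercept
absorbs the common baseline shared by all states (the nonnegative code
rides on a large DC pedestal that carries no movement information);
without it the linear map wastes its capacity reproducing the pedestal and
per-step decoding degrades. `path_integrate()` propagates a
representation with these maps, decodes the nearest state vector by cosine
similarity after every step (dot product behind a config switch), and by
default snaps the running vector to the decoded state — the attractor-like
cleanup that keeps errors from accumulating. A trial of
`path_integration_success_rate()` counts as a success only if the whole
decoded path matches.

`navigate()` evaluates `x(s') . w(g)` over the neighbors of the current
state and moves greedily (uniform random tie-breaks), to the goal or a
step cap of 8 times the shortest-path length; non-reaching trials enter
the summary with the cap as their path length. With the exact PSI as value
proxy this greedy rule is BFS-optimal on the open room, which the test
suite checks exhaustively at 10x10. On *trained* embeddings the
reconstructed value field carries noise of the same order as the
between-neighbor value differences far from the goal, and a purely greedy
agent gets trapped in two-state cycles at local noise maxima (we measured
~24 of 25 navigation failures to be such cycles, while the field is
globally sound: the greedy step reduces BFS distance at ~100% of states).
The `epsilon` argument (default 0, the deterministic limit) takes a
uniform random move with probability epsilon; the shipped navigation
analyses use `epsilon = 0.1`, which lets the agent escape noise pockets
within the step cap.

## Barrier contexts and composition

The context fixtures put thin walls *between* cells (blocked edges), so
all contexts — empty (phi), one wall (A), a second disjoint wall (B), both
(A+B) — share the identical 900-state footprint and state `i` means the
same position everywhere; alignment across contexts is the identity.

Unit identity across contexts is the second alignment requirement, and it
is why the contexts are trained by *fine-tuning*: phi trains from the
seeded random start, and A and B warm-start from phi's factors for a
shorter run (`train_context_embeddings()`, 300 fine-tuning iterations by
default). Training each context from an independent random start would
permute and re-mix the units arbitrarily, making per-unit representational
distances and the composition rule meaningless; fine-tuning keeps unit k
of A the adapted unit k of phi, so the units that move are exactly the
ones encoding the barrier. The composed representation for the unseen
two-wall context is
`x_i(A) + x_i(B) - x_i(phi)` per position and unit, clipped at zero
(the nonnegativity invariant the rest of the pipeline assumes), applied to
both X and W (navigation in the new context needs goal vectors too).
Partial composition restricts the rule to the top-k units by
representational distance `d_k = sum_i (x_k(i; B) - x_k(i; phi))^2`
between B and phi — where the second barrier's effect lives — and copies
everything else from A. Navigation trials in the composed context sample
starts from the left strip of the room and goals from the bottom-right
block, so that paths must negotiate both walls.

## Synthetic corpora

The semantic analyses need corpora with known structure, not downloads.
`generate_categorical_corpus()` emits documents that each activate one or
two of `n_categories` categories and boost the sampling mass of the active
categories' words (`boost = 5`); within-category co-occurrence then
exceeds between-category co-occurrence by construction. The default scale
(10 categories x 10 words, 2,000 documents x 100 tokens = 200k tokens)
mirrors the ten-categories-of-ten-words design of the population-level
analyses at a size that trains in seconds. `generate_relational_corpus()`
gives every word two latent factors (role within a family, e.g.
country/capital, and entity identity); documents activate either one
entity (its two role words co-occur) or one role (its words co-occur
across entities), and all consistent analogy quadruples are emitted as
ground truth. What these generators deliberately do not model: Zipfian
frequencies, grammar, polysemy, and document length variation — so passing
tests demonstrate the mechanism (concept-specific units, vector
analogies, partial recombination), not performance on natural language.

Conceptual specificity uses an injected similarity function; the tests use
the category oracle (1 within a category, optionally 0.25 for sibling
categories under a supercategory map, else 0), so the statistic's
arithmetic — mean TOP-10 pairwise similarity against the 95th percentile
and mean of 1,000 random-pair similarities — is checked against exact
collision probabilities. A lexical-database adapter can be injected for
real corpora; none is required anywhere in the package.

Two details of the specificity analysis deserve note. First, the TOP list
of a unit is truncated at zero activation (a sparse unit may activate
fewer than 10 words; words it never activates are not part of its tuning
profile), and a unit with fewer than two active words has undefined
similarity and is never significant. Second, the corpus used for the
significance comparison has 25 categories of 8 words under 5
supercategories plus 50 high-frequency background words: with coarser
structure (10 categories of 10), same-category collisions among random
pairs exceed 5% and the null's 95th percentile saturates at the maximum
similarity, making significance unattainable *by construction* for every
method; and without background words the planted block structure is so
clean that signed and nonnegative factorizations recover it equally well,
leaving the nonnegativity ablation nothing to show. Both are properties
of the evaluation design, not of the model.

## Problem sizes

The shipped analyses run at desk scale, chosen once: 300k-step walks
(about 330 visits per state; the plug-in SR estimator is insensitive to
further lengthening), 3000 training iterations (300 for context
fine-tuning), 100 shuffles per unit in the gridness null, 1,000 trials
per navigation or path-integration condition, 3 seeds for seed-averaged
quantities. The acceptance script (`scripts/acceptance.R`) states these
same sizes explicitly.

## Known limitations

These are honest properties of this implementation, reported as measured.

* **Grid fractions vary strongly across seeds and are transient in
  training.** State-vector grid fractions range roughly 0.14-0.29 across
  seeds (mean ~0.2), and the fraction *peaks* mid-training: continued
  optimization slowly trades grid-classified units for smoother codes
  with better reconstruction. The grid solution is therefore not the
  optimum of this objective at these weights but a long-lived transient;
  3000 iterations (where the fraction is near its peak and the loss has
  plateaued) is the declared training length.
* **Goal-vector (W) grid fractions stay well below state-vector (X)
  fractions** (~0.07-0.15 vs ~0.14-0.29). With decorrelation on X only —
  the constraint set the factorization states — nothing forces the goal
  vectors into periodic tuning; extending decorrelation to W
  (`decorr_w = TRUE`) makes X and W symmetric but pulls both fractions
  down to ~0.11.
* **Path-integration counts sit far below the reference regime**
  (roughly 150-330 of 1,000 whole-path-correct trials for decorr, 80-130
  for sparse; the decorr > sparse ordering holds). The bottleneck is
  code geometry, not the decoder: the exact-PSI code and an unconstrained
  rank-100 factor code both path-integrate at ~100% through the same
  movement-model machinery, while the nonnegative factor code's per-step
  decode plateaus near 85% however the decoder is configured. Training
  regimes that improve decoding (momentum, longer schedules) actively
  destroy grid tuning, so a single configuration cannot serve both
  analyses well; the shipped configuration favors the representational
  claims.
* **Full composition outperforms small partial compositions.** With
  fine-tuned contexts the composition machinery shows the expected
  structure (contextual information concentrates in non-grid units;
  composed vectors beat single-context vectors), but reaching the full
  composition's navigation performance takes on the order of tens of
  top-distance units, not single digits — the barrier signal is spread
  over more units here than in the reference regime.
* The gridness annulus is chosen per map from the radial profile; maps
  without a detectable sidelobe are scored on a fallback full annulus
  (so the shuffling null never conditions on apparent structure).
* Barrier composition assumes weakly interacting barriers (disjoint,
  non-touching walls). Connected barriers are known to defeat the additive
  rule; `barrier_context_envs()` builds only the disjoint layout.
* The corpus pipeline tokenizes by whitespace and lowercases nothing by
  itself; real-corpus preprocessing is the caller's responsibility.
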