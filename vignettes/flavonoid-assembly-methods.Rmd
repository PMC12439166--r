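---
title: "Methods: quantifying flavonoid supramolecular assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying flavonoid supramolecular assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavassembly)
```

flavassembly implements the quantitative pipeline used to study how dietary
flavonoids (quercetin and its glycosides isoquercitrin and quercitrin)
self-assemble into π-stacked supramolecular fibers and how that assembly
relates to broad, non-specific enzyme inhibition. This vignette is the
package's own account of the models, the tunable parameters, and the design
choices made where the methodology was genuinely open.

## 1. Dose–response fitting and IC50 categorisation

Percent inhibition $y$ is modelled as a four-parameter logistic in
$x = \log_{10}(\text{concentration in M})$:

$$ y(x) = b + \frac{t - b}{1 + 10^{\,h (x_0 - x)}} $$

with bottom $b$, top $t$, Hill slope $h$ and inflection $x_0$. Fitting is
bounded Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with all
replicate points entering the loss jointly — replicates are never averaged
first, preserving the error structure. The IC50 is **not** $10^{x_0}$: it is
the concentration where the fitted curve crosses 50% inhibition,

$$ x_{50} = x_0 - \frac{1}{h}\log_{10}\frac{t - 50}{50 - b}, $$

which exists only when $b < 50 < t$.

Each fit is assigned one of three categories, replacing manual curve review
with deterministic rules:

* **IN_RANGE** — the crossing lies at or below the top of the assayed range;
* **EXTRAPOLATED** — the curve rises clearly above baseline inside the range
  but crosses 50% only beyond it (the IC50 is the extrapolated crossing; if
  the fitted top never reaches 50% anywhere, the IC50 is reported as `Inf`);
* **BASELINE** — the fitted maximum response within the assayed range stays
  below the baseline threshold (default 25%), or the optimiser failed.

Parameter choices that matter:

* **Bounds** $b \in [-20, 30]$, $t \in [5, 120]$, $h \in [0.2, 5]$ (percent,
  percent, dimensionless). The *lower* bound on $t$ is deliberately below the
  25% baseline threshold. If the top is forced to at least 30%, a series that
  is pure readout noise must fit a ≥30% rise somewhere, and bounded least
  squares will park that rise inside the assayed range often enough to
  misclassify roughly a third of true-baseline series as extrapolated
  inhibitors. With $t \ge 5$ a no-signal series fits a near-flat curve and is
  classified BASELINE; on noisy synthetic screens per-pair category agreement
  with the generating truth is 99.5–100%.
* **Baseline threshold 25%** keeps weak partial inhibitors fittable while
  treating anything that never reaches a quarter of full inhibition within
  the range as no readout. It is an argument (`baseline_threshold`), not a
  constant.
* **Multi-start**: four preset starts (varying $h$ and $x_0$); the
  best-RMSE convergent fit wins. First-convergent selection was observed to
  accept a bad local optimum in roughly 1 in 400 noise-free curves.
* A 50% crossing *below* the bottom of the assayed range is reported
  IN_RANGE with the crossing concentration; under the screen design (lowest
  concentration 5 nM) this essentially never occurs.

## 2. Weighted Z-score efficacy ranking

For enzyme $i$, each successful readout is standardised on the log scale,
$z_i = (\log_{10} IC50_i - \bar X_i)/s_i$, where $\bar X_i$ and $s_i$ are the
mean and standard deviation of all successful $\log_{10} IC50$ values for
that enzyme. Compounds with no readout for an enzyme are imputed $z = 2$ —
two standard deviations worse than the panel mean — so unmeasurable, very
weak inhibitors still participate in the ranking. Per compound,

$$ \bar z = \frac{\sum_i w_i z_i}{n_{\text{panel}}}, \qquad
   w_i = \frac{N_i}{\sum_i N_i}, $$

with $N_i$ the number of successful readouts for enzyme $i$ and
$n_{\text{panel}}$ the panel size (7 in the study design). Compounds are
ranked ascending in $\bar z$: low scores mean potent, broad inhibition.

Decisions worth stating plainly:

* The division by $n_{\text{panel}}$ is applied *on top of* weights that
  already sum to one. It is implemented literally because that is how the
  ranking is defined; it is a rank-preserving constant rescaling of every
  score, so it changes no ordering.
* $s_i$ uses the sample ($n-1$) standard deviation; `sd_type = "population"`
  switches to the $n$ denominator.
* Extrapolated fits with a finite crossing count as successful readouts (and
  enter $\bar X_i$, $s_i$); this is what lets compounds with very high IC50s
  be ranked. `include_extrapolated = FALSE` restricts to in-range fits.
  Baseline fits, and extrapolated fits whose curve never reaches 50%
  (infinite IC50), are "no readout" and imputed.
* Imputation applies per compound × enzyme pair, not only to wholly missing
  compounds.
* Enzymes with fewer than two successful readouts define no scale; they are
  dropped from the panel with a warning rather than silently producing
  unstable z-scores.
* Repeatedly screened compounds are scored per repeat and the scores
  averaged; ties are broken lexicographically and flagged.

## 3. Radius of gyration and variance heterogeneity

Compactness is measured as the mass-weighted radius of gyration
$R_g = \sqrt{\sum_k m_k \lVert r_k - \bar r\rVert^2 / \sum_k m_k}$ per frame,
over a tag selection (mass weighting is the default, matching common
trajectory-analysis tooling; unit masses by flag). Which atoms enter the
selection for protein–flavonoid systems is a genuine open choice: the
package defaults to nothing (all atoms) and exposes `list(group = ...)`
filters so either protein-only or protein-plus-flavonoid series can be
produced; neither is asserted as canonical.

Structural heterogeneity between replicate simulations is tested with the
Levene family: the one-way ANOVA $F$ on absolute deviations from the group
center, on values pooled across duplicates within a condition over the
equilibrated window (inclusive bounds, times in ns; 200–400 ns in the study
design). `center = "mean"` is the default because that is Levene's test as
named; `center = "median"` gives the Brown–Forsythe variant, which common
scientific-Python tooling uses as its default — both are exposed so either
convention can be reproduced. The statistic is computed by `car::leveneTest`
behind the package interface; a hand-evaluated formula serves as the
independent oracle in the tests, and the test's empirical size at
$\alpha = 0.05$ is verified to sit in $[0.035, 0.065]$ on null simulations at
the pooled-window scale ($n = 400$ per group).

## 4. π-stacking contacts and assembly topology

A stacking contact between two aromatic rings requires three geometric
conditions simultaneously (defaults in parentheses):

* centroid–centroid distance ≤ `max_dist` (4.5 Å);
* interplanar angle ≤ `max_angle` (30°), computed between ring-plane normals
  (smallest principal axis of the ring atoms) and folded into [0°, 90°];
* lateral offset ≤ `max_offset` (2.0 Å), where the offset is the larger of
  the two parallel-displacement components — for each ring, the
  centroid–centroid vector minus its projection onto that ring's normal.

These are standard parallel π-stacking thresholds; all three are arguments.
Taking the *larger* of the two offsets makes the contact relation symmetric
and prevents a slipped pair from qualifying through the more permissive of
the two projections. T-shaped (edge-to-face) geometry is excluded by default
and available via `t_shaped = TRUE` with an angle window of [60°, 90°].
Hydrogen-bond edges are out of scope: branching is inferred purely from
stacking degree.

Ring-level contacts collapse to molecule-level edges; connected components
are classified exhaustively and mutually exclusively: **SINGLETON** (one
molecule), **SECONDARY** (any node of degree ≥ 3 — a branch point),
**CYCLIC** (a cycle with no branching), **PRIMARY** (a simple path — the
single linear stack that constitutes primary fiber structure).

The fiber generator builds ideal planar hexagonal rings (C–C radius 1.4 Å,
unit masses) because the detector tests geometry, not chemistry. Branch
sub-stacks grow at a 25° tilt from the main axis. At π-stacking distances an
interior junction is geometrically crowded: a branch ring close enough to
stack with its anchor is necessarily also within stacking geometry of the
anchor's next main-stack ring, so the constructed ground-truth adjacency
includes that junction edge. Component size and topology class — the
quantities the recovery tests assert — are invariant to it. A branch
anchored at the terminal ring simply extends the stack (a kinked path, still
PRIMARY); in a two-ring fiber a branch at ring 1 closes a triangle (CYCLIC).
The generator records the analytic adjacency implied by the construction and
classifies it combinatorially; the geometric detector must then reproduce
exactly that.

## 5. Weighted-ensemble engine and the variation-maximising resampler

The engine alternates propagation and resampling over an ensemble of
weighted walkers. Resampling maximises the REVO-style variation

$$ V = \sum_i \sum_j \left(\frac{d_{ij}}{d_0}\right)^{\alpha}, $$

with $d_{ij}$ the pairwise distance in the progress coordinate (the radius
of gyration by default; for scalar toy states the state itself), $d_0$ the
characteristic distance normalising the pairs, and $\alpha$ the distance
exponent. Novelty factors are fixed at 1. The greedy loop proposes cloning
the walker with the largest marginal contribution to $V$ together with
merging the closest eligible pair (distance ≤ `merge_dist`, combined weight
≤ `pmax`, disjoint from the clone); the merge survivor is drawn with
probability proportional to weight, and a proposal pair is accepted only if
it strictly increases $V$ (relative tolerance $10^{-9}$, so a degenerate
exponent $\alpha \to 0$, under which $V$ is flat, correctly results in no
resampling). Cloning splits a weight exactly in half; merging sums weights
exactly; the walker count is constant and total probability is conserved to
machine precision, with every weight kept in `[pmin, pmax]`. Defaults are
the study's resampler settings: 50 walkers, merge distance 0.25,
$d_0 = 0.1$, $\alpha = 4$, `pmax` 0.5, `pmin` $10^{-12}$.

Ancestry is recorded per cycle as a parent map, so any final walker traces
back through clones and merges to an initial walker, yielding the continuous
value/weight series of one lineage (`trace_lineage()`). Whether "total
simulation time" means per-walker or aggregate walker time is ambiguous in
general usage, so the result reports both when the propagator exposes a time
step.

The free-energy-like profile is $F_b = -\ln \hat p_b$ over bins of the
progress coordinate, with $\hat p$ the weight-normalised histogram of values
pooled over post-burn-in cycles (burn-in defaults to 20% of cycles; 50
uniform bins over the observed range, both configurable — pass explicit
edges for cross-run comparability). $F$ is defined only on occupied bins and
is unchanged by any rescaling of the weights.

Propagation is toy overdamped Langevin dynamics (Euler–Maruyama), vectorised
over walkers; the quartic double well $U(x) = B((x/a)^2 - 1)^2$ is the
standard test system. The engine does not wrap a molecular-dynamics code.

## 6. What the synthetic generators emulate — and what they do not

* `gen_inhibition_panel()` reproduces the screen design: 58 compounds × 7
  enzymes, 10 concentrations log-spaced over 5 nM–100 µM, two technical
  replicates, Gaussian readout noise on the percent scale (default sd 5%, a
  typical biochemical-assay scale), responses deliberately not clipped to
  [0, 100]. The default truth matrix reproduces the screen's reported
  category composition: 106/49/251 pairs (26.1/12.1/61.8%) in-range /
  above-range / absent. Above-range truths are drawn in 1.5–2.5 × 10⁻⁴ M, a
  window where a unit-slope curve still rises visibly above baseline within
  the assayed range, so the extrapolated category is identifiable. What it
  does not emulate: plate effects, heteroscedastic or correlated readout
  noise, compound-specific Hill slopes, or any real compound identities.
* `gen_collapse_trajectory()` emulates assembly as compaction: rigid
  molecules placed uniformly (minimum-separation rejection sampling, 10⁴
  retries, then an error) whose mean positions relax exponentially toward
  the centroid, with stationary Gaussian thermal jitter about that collapse
  path. Jitter is fluctuation about the path rather than an integrated
  random walk: a zero collapse rate then gives a genuinely trend-free
  compactness series, which is what "no assembly" must look like to the
  downstream variance analysis. Defaults (10 molecules, 3 nm box) start the
  ensemble near $R_g \approx 1.5$ nm, the typical pre-assembly initial
  compactness; the generator targets that qualitative property (assembly ⇒
  $R_g$ decreases), not any particular packing. No excluded volume during
  dynamics, no rotation of the rigid bodies, no solvent.
* `gen_ring_fiber()` and the double-well propagator are described above.

Consequently, passing tests demonstrate correctness of the *analysis* —
fitting, standardisation, statistics, geometry, resampling bookkeeping — on
data with the assumed statistical structure. They do not validate force
fields, sampling convergence of real molecular systems, or the biological
interpretation of assembly.

## 7. Numerical choices and problem sizes

Reproducibility: every generator seeds a private RNG stream from its spec
and documents the draw order, so outputs are bit-identical across calls and
releases; the caller's RNG state is never disturbed. Concentrations are
stored in molar and fitted on log₁₀ molar; trajectory coordinates are nm in
memory and Å in structure files (PDB convention); window bounds are
inclusive.

The test and acceptance workloads use desk-scale problem sizes chosen so the
statistical checks are sharp: 100 random 58×7 screens for oracle equivalence
of the ranking equations (agreement to 10⁻¹²), 100 seeded panels for IC50
recovery (max relative error ≤ 0.5% noise-free; median ≤ 20% at 5% noise),
1000 random configurations for the radius-of-gyration oracle (≤ 10⁻¹⁰
relative), 1000 null simulations at n = 400/group for the Levene size check,
a 50-walker × 1000-cycle double-well run for conservation (≤ 10⁻¹² at every
cycle), a 1500-cycle harmonic-well run for free-energy recovery (≤ 0.3 kT
over the central 80% of the mass, compared against the bin-integrated
Boltzmann reference so binning itself introduces no error), and 50 seeded
fiber constructions for exact assembly recovery.

## 8. Known limitations

* The fit categorisation is deterministic; a screen that was manually
  curated can differ from it near category boundaries.
* The resampler implements the published variation-maximisation scheme with
  novelty fixed at 1; runs driven by other novelty definitions will
  resample differently (weights and conservation behave identically).
* The assembly detector sees only π-stacking geometry; secondary structure
  stabilised chiefly by hydrogen bonding is invisible to it.
* The weighted-ensemble engine propagates toy dynamics only; its estimates
  carry the correlated-sampling noise of few-walker ensembles, visible as
  ±0.05-scale fluctuation in well occupancies at the default sizes.
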