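---
title: "Open-field behavioral phenotyping: models and methods"
author: "ethofield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-field behavioral phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethofield)
```

## The analysis problem

Markerless pose tracking reduces an hour of open-field video to two plain
records per mouse: a frame-wise *ethogram* — one of 13 movement labels per
frame (running, trotting, walking, right/left turning, stepping, rearing,
climbing, hunching, rising, sniffing, grooming, pausing) — and the back
keypoint's (x, y) trajectory in millimetres, center-origin. `ethofield`
implements everything downstream of those records for a three-genotype
(WT / HE / KO) by two-sex cohort design:

1. **Kinematic label correction** — rule-based vetoes such as "sniffing
   slower than 15 mm/s for more than 3 s is really pausing".
2. **Time budgets and temporal dynamics** — per-movement and per-cluster
   time fractions `T_i = M_i / M_Total` and bout frequencies, whole-session,
   per minute, and per 10-minute segment.
3. **Data-driven arena zoning** — a center/perimeter boundary located on
   the occupancy growth curve instead of the conventional "center = half
   the arena".
4. **Cluster transition networks** — empirical state and transition
   probabilities over 5 functional clusters, pruned at probability 0.05,
   with betweenness centrality identifying transitional hubs.
5. **Genotype discrimination** — leave-one-out linear discriminant
   classification from five behavioral feature sets, summarized as the mean
   diagonal of the row-normalized confusion matrix.

The 13 movements partition into 5 clusters — locomotion (running, trotting,
walking, both turnings, stepping), exploration (rearing, climbing, rising,
sniffing), forced posture (hunching), maintenance (grooming) and nap
(pausing) — and this partition is shipped as an immutable default
(`cluster_map()`); analyses accept an explicit override but never mutate it.

## Conventions

Frames are 0-based; bout intervals are half-open `[start, end)`; times are
seconds; coordinates are millimetres with the arena floor spanning
`[-200, 200]^2` (x rightward, y toward the far wall). The camera frame rate
is not fixed by the file format; 30 frames/s is the default and every file
carries its rate in a `# frame_rate=` comment line. "Frequency" is
standardized to bouts per minute throughout; whole-session bout counts are
exported alongside. A bout that straddles a time-bin boundary contributes
its frames to every bin it touches but its *count* only to the bin holding
its start frame.

## Kinematic correction

The back point's speed is computed on positions smoothed with a 0.33 s
centered moving average (window configurable; the edge frames use partial
windows). A rule relabels a bout only when its speed is *strictly* below
and its duration *strictly* above the thresholds, so a bout at exactly
15 mm/s or exactly 3 s is left alone. Rules are applied in one pass over
the original bout decomposition; adjacent same-label runs merge afterwards,
which makes the default rule set idempotent — reapplying it changes
nothing, a property the test suite asserts on randomized sessions.

## Data-driven zoning

For half-widths `a = 1, 2, ..., 200` mm the growth curve counts frames with
`max(|x|, |y|) <= a`; the annular density divides each increment by the
area of its square annulus. Thigmotactic mice pile occupancy into a band
near the walls, producing a density peak there. The boundary is placed at
the smallest `a`, scanned outward from the peak's left base along the
rising flank, where density first comes within 10% of the peak's
topographic prominence — equivalently, the start of the 90%-prominence
region. Two reconciliations the implementation makes explicit:

* **'a' is a half-width.** Reading the printed boundary (135 mm) as a full
  side length would make the "center" span only ±67.5 mm and the perimeter
  band 132 mm deep — implausible for thigmotaxis. As a half-width it leaves
  a ~65 mm wall band. The interpretation is configurable.
* **Prominence is computed on the density curve**, not the cumulative
  count, whose monotonicity admits no interior peak.
* A density maximum that sits at the first grid step is not a thigmotaxis
  peak and is not a candidate; a plateau running into the wall is a valid
  peak measured against its left side only (the back point physically
  cannot occupy the last millimetres, but clipped or coarse data can put a
  plateau there).

If the density is flat or monotone decreasing there is no peak and
`find_boundary()` refuses; callers fall back to the traditional division
(`a = 100` mm, center = half the arena length) or to the standardized
data-driven default `a = 135` mm. Peak finding on empirical density curves
is intrinsically noise-sensitive: per-animal curves from long stationary
bouts can carry shot-noise spikes in the small central annuli, so the
pipeline estimates the boundary on the cohort-pooled curve.

## Transition networks

Frames map to clusters; maximal runs merge into *events*. Because merged
events cannot repeat, the event-level transition matrix has a structurally
zero diagonal; self-transitions are therefore defined at the movement-bout
level within a cluster (walking → stepping is a locomotion self-loop).
Edges with probability below 0.05 are pruned from the displayed network —
the package reads the exclusion threshold as a probability cutoff, not a
significance test, since an isolated transition probability admits no
P-value; the threshold is exposed. Betweenness uses `-log(p)` edge lengths
(high-probability transitions are short) normalized by `(n-1)(n-2)`; an
unweighted variant is available since the weighting convention is not
canonical. Group graphs default to averaging per-animal estimates
(`pool = "animals"`), which weights animals equally; event pooling is
available and the two agree as session lengths equalize.

## Discrimination

Feature sets: `movements` (13 fractions + 13 bout frequencies),
`grooming` (2), `distance` (1), `position` (traditional center/perimeter
fractions, 2), `clusters` (10). Sexes are fitted separately. Features are
z-scored per column inside each training fold; the pooled within-class
covariance is shrunk toward `mean(diag(Sw)) * I` with the smallest weight
from a fixed ladder (0, 1e-4, ..., 1) that yields a well-conditioned
Cholesky factor — necessary in the 26-feature / ~15-per-class regime.
Class priors are the training proportions. Cross-validation is
leave-one-out by default (small n); stratified k-fold is available.
"Discrimination" is the mean of the row-normalized confusion diagonal
(mean per-class recall), which differs from overall accuracy under class
imbalance; both are reported. Note that leave-one-out null distributions
sit slightly *below* chance (removing the held-out animal shrinks its own
class's prior), a known small-sample property the tests account for.

## The synthetic cohort generator

No recordings accompany the study design this package targets, so
`simulate_cohort()` provides a fully specified stand-in with the cohort
layout males KO 20 / HE 15 / WT 19 and females KO 21 / HE 12 / WT 17
(104 animals; 60-minute sessions at 30 fps).

The ethogram is a **semi-Markov bout process**: a bout-to-bout transition
chain (13×13, zero diagonal) chooses the movement sequence and lognormal
laws (shape `sdlog = 0.6`, right-skewed as behavioral bout durations are)
choose dwell times. A semi-Markov process — rather than a frame-wise chain
— is essential because the analyses treat time fractions and bout
frequencies as separate readouts, and only explicit dwell laws let the two
vary independently. The closed-form stationary budget
(`stationary_budget()`: chain stationary weights × mean dwells,
renormalized) doubles as the oracle for convergence tests.

The trajectory is a **target-seeking random walk**: a spatial attractor is
drawn — in the wall band at Chebyshev radius 170 ± 12 mm with probability
`wall_affinity`, else uniformly in the central ±100 mm square — and
persists until the animal reaches it, travel proceeding at the current
movement's nominal speed (so pausing creeps and running closes distance),
reflecting at the walls. While dwelling, the attractor drifts slowly
(σ = 5 mm per bout) so residence mass spreads into a blob rather than a
point, and the deviation around it is AR(1) with innovation equal to the
per-frame step. "Stationary" movements carry a 4 mm/s nominal speed — the
back keypoint of a grooming or pausing mouse sways; a literal zero speed
(supported, and tested) freezes the point exactly, which concentrates
occupancy into single millimetre annuli no real tracker produces.

Group differences are *engineered orderings, not measured effect sizes*:
relative to same-sex WT, the HE and KO chains shift bout mass away from
walking / stepping / trotting / turning / climbing / rising / sniffing
toward pausing, grooming and hunching (KO beyond HE), lengthen grooming
and pausing dwells, scale the grooming↔pausing coupling (1 / 1.6 / 2.6)
before row renormalization, and raise wall affinity (0.74 / 0.82 / 0.90 —
center-time fractions land in the realistic 20–40% range and the pooled
density shows a clear wall peak near 165 mm). Sex effects are deliberately
mild (3% speed, 3% sniffing mass) and order-preserving, mirroring the
near-absence of sex differences in the target design. The engineered
separations are stronger than typical real data — most feature sets
classify nearly perfectly on defaults — so passing recovery tests
demonstrates that the estimators recover planted structure, not that real
genotypes are this separable.

Per-animal seeds derive from the design seed and animal id via a 32-bit
FNV-1a hash reduced mod 2^31−1, so any animal can be regenerated alone.

## Problem sizes in the test suite

Unit and property tests run on sessions of 10–600 s and cohorts of up to
36 animals. The recovery checks use 50,000 bouts (transition counting),
20,000 bouts (stationary budget), 5,000 events × 3 seeds (matrix
recovery), 20 replicate 30-animal cohorts of 10-minute sessions
(qualitative contrast recovery), and two full study-sized runs
(104 animals × 60 min × 30 fps) for byte-level reproducibility — chosen so
the whole suite completes in a few minutes on one CPU while keeping every
statistical tolerance comfortably non-marginal.

## Known limitations

* The trajectory model is a stand-in: it reproduces occupancy geometry and
  speed ordering, not rodent gait, wall-following curvature, or
  home-base behavior.
* Growth-curve boundary detection assumes a thigmotaxis peak; center-
  preferring animals (or pooled curves dominated by them) legitimately
  fail with "no occupancy peak".
* Corrections recompute speeds from the supplied back trajectory only; no
  other keypoints are modeled.
* The discrimination module fits plain LDA by design — no nonlinear
  classifiers or hyperparameter search — because the scientific claim it
  supports is about feature sets, not classifiers.
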