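---
title: "Gate-based cytometric fingerprinting: models, defaults, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gate-based cytometric fingerprinting: models, defaults, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cytofp` implements a gate-based analysis of microbial community flow
cytometry together with a generative model of such data. This vignette is
the package's own account of the science: what is modeled, which knobs
matter, which conventions were chosen where several were defensible, and
what the tests do and do not establish.

## 1. The measurement model

A community sample is measured as ~250,000 single-cell events on two
logarithmically scaled channels: DNA-stain fluorescence (DAPI; proportional
to DNA content) and forward scatter (FSC; related to cell size). Cells with
similar optical properties form clusters ("subcommunities") in this plane.
The analysis abstraction is an **event cloud**: an n × 2 matrix of
log-channel values, keyed by (treatment, replicate, day).

We place the channels on a log10 scale spanning four decades, [0, 4]. The
instrument convention behind logarithmically scaled dot plots varies by
vendor; four decades is the common default and keeps gate polygons simple.
Nothing downstream depends on the absolute scale — only gate geometry must
match the event scale.

## 2. Gating

A **gate template** is an ordered list of named convex polygons, fixed once
per study and applied identically to every sample, so that per-gate
abundances are comparable across samples and days. Conventions:

- **First-match assignment.** An event in several overlapping gates counts
  for the earliest gate in template order. This keeps gate counts an exact
  partition of the gated events (an invariant the tests check by integer
  conservation).
- **Inclusive boundary.** An event exactly on a polygon edge is inside (for
  the first gate that reaches it). With continuous data this is a
  measure-zero choice; it makes the rule total and deterministic.
- **Compositional denominator.** Abundances are percent of *gated* events;
  events outside every gate are reported separately (`ungated`). Rows then
  sum to 100 and Bray–Curtis is well defined. The alternative (percent of
  all events) would let ungated debris dilute every gate simultaneously.
- **Convex polygons only.** Curved or concave gates are out of scope; the
  containment test is a half-plane check per edge.

Templates are plain text (one `gate x y` vertex per line) and round-trip
exactly. Because manual gate geometry is usually not published, the package
also detects gates automatically: events are pooled across samples (equal
per-sample subsampling to a cap, default 5,000), a 2D Gaussian kernel
density (bandwidth 0.35 log units) is evaluated on a 128² grid, local
maxima above 2% of the global peak and at least 0.35 log units apart become
gates, and each gate polygon is the convex hull of the grid region above
10% of its peak height, split between nearby peaks by proximity. These
defaults resolve clusters whose centers are ≳0.5 log units apart — the
scale of visually distinct subcommunities on a 4-decade plot. Detection is
a convenience for self-contained synthetic studies; with real data a
manually curated template file is the primary path.

## 3. The generative model (what the simulator states)

The simulator emulates a replicated toxicant-exposure study:

| parameter | default | meaning |
|---|---|---|
| treatments | Neg, LAg10, EC50Ag10, EC50Ag30, Pos | negative control, low AgNP-10, EC50 AgNP-10, EC50 AgNP-30, AgNO3 positive control |
| replicates | 3 | independent cultures per treatment |
| sampling days | 0, 4, 7, 10, 14, 17, 21, 24 | 3–4 d intervals over 24 d; day 0 is the inoculum |
| events/sample | 250,000 | cells measured per dot plot |
| noise concentration | 200 | Dirichlet concentration of replicate composition noise |

Each subcommunity g is a bivariate Gaussian with center and covariance in
log-channel units, a **baseline abundance** b_g (percent at day 4, after
adaptation), and a **trajectory**: a linear slope k_g[t] in percent/day per
treatment. Realized abundances at day d ≥ 4 are
`b_g + k_g[t]·(d − 4)`, clipped at zero and renormalized to sum to 100;
events are then drawn as a multinomial mixture of the Gaussians. Linearity
from day 4 mirrors how trends are usually fit to such series; no attempt is
made to model saturating kinetics.

**Adaptation.** Day 0 abundances are `b_g − shift_g`, shared across
treatments (one inoculum), modeling the single large community
rearrangement between inoculum and the first post-transfer sampling as a
one-step shift. The default shift makes three inoculum-only subcommunities
(G1, G2, G13) collapse and the batch dominants (G8–G10) rise, so the first
interval carries the largest β and Bray–Curtis step — the qualitative
signature of adaptation.

**Replicate noise.** Each (treatment, replicate) draws ONE Dirichlet
perturbation of the baseline composition (concentration α·p, α = 200) and
keeps it for its whole time course. This models replicate cultures that
diverge in composition but follow the same dynamics — the spread one sees
between triplicate flasks. The choice of *replicate-constant* rather than
per-sample-day noise is deliberate and consequential: rank correlations of
abundance with time are scale-free, so i.i.d. per-day noise would give
every null gate a ~7% chance of |ρ| ≥ 0.4 at 21 pooled points regardless
of noise magnitude, swamping response detection with false positives that
real replicated designs do not show. Replicate-constant offsets instead cap
the null |ρ| near 0.33 (three separated rank bands). At α = 200 a 40%
gate has a replicate SD of ≈3.5%; larger spreads (the tens-of-percent
divergence late-stage disturbed cultures can show) are reachable by
lowering α.

**Determinism.** Every sample's event stream and every replicate's noise
draw get their own seed derived from the master seed and the sample key by
a stable string hash, so studies are reproducible event-for-event and
insensitive to generation order.

**What the generator does not emulate:** instrument drift and calibration
beads; debris and doublets; cluster shape change over time (clusters move
in abundance, not in position); spread that grows with abundance;
autocorrelated day-to-day noise. A green test on synthetic data therefore
establishes the correctness of the *computations* on well-clustered data,
not robustness to gating ambiguity on smeared real-world clouds.

## 4. Diversity metrics

- **Dominance threshold.** A gate is dominant when its abundance is
  *strictly* greater than τ. Both study conventions are defaults: τ = 2.9
  (cytometric dominance) and τ = 0.71 (matched to a sequencing OTU
  threshold). The threshold is applied to each replicate row; replicate
  mean ± SD are reported afterwards. (Applying it to replicate means
  instead is the other defensible reading; per-row keeps α defined for
  single replicates and is what the summaries average.)
- **α** is the count of dominant gates (Hill number of order zero over the
  dominance-filtered fingerprint). Lowering τ can only grow α — a property
  test, and visible end-to-end in the reports.
- **β** between two days is the number of gates unique to either day's
  dominant set. By default it is computed between *consecutive* sampling
  days within a replicate; comparison against a fixed reference day is
  available (`beta_mode = "reference"`) since "between sampling days" also
  admits that reading.
- **Bray–Curtis / NMDS.** Dissimilarity is Σ|x−y|/Σ(x+y) on the percent
  rows (vegan's implementation, cross-checked against a hand-rolled oracle
  in the tests). NMDS is Kruskal stress-1 with monotone regression
  (vegan::monoMDS), best of `restarts` (default 20) configurations — one
  metric-scaling start plus random starts — under a fixed seed. An
  all-zero dissimilarity matrix embeds at the origin with stress 0 by
  convention rather than erroring.
- **cybar table.** For fingerprint heatmaps each gate column is min–max
  scaled to [0,1] across samples; constant columns map to 0.5 (no
  information either way). The scaling is idempotent and never mutates the
  input table.

## 5. Response analysis

Per (treatment, gate), over the window 4–24 d (day 0 excluded as
pre-adaptation):

- **slope k**: OLS of abundance (percent) on day, replicates pooled as
  individual points (averaging per day first is available; pooling uses
  all information and its CI is conservative under replicate-constant
  offsets, since between-replicate variance inflates the residuals but the
  balanced design keeps the slope estimate unbiased).
- **Spearman ρ** of abundance against day, average ranks on ties; strong
  iff |ρ| ≥ 0.4 — the threshold is inclusive, so ρ = 0.39 is not strong.
  Zero-variance series yield an explicit `undefined` status, never a crash
  and never a strong flag.
- **markers**: positive = strong positive ρ and k > 0; negative = strong
  negative ρ, k < 0, and initial (first-window-day) replicate-mean
  abundance ≥ 1% — the floor keeps near-empty gates, whose only possible
  move is sideways noise, out of the negative marker list. Markers are
  reported per treatment; treatment specificity is for the reader to
  judge, not silently filtered.

Slopes are reported in raw percent/day by default. Slopes on the min–max
normalized (cybar) scale are available via `scale = "cybar"`; published k
values for such studies are often on an unstated normalized scale, so raw
and normalized slopes should never be compared numerically across sources.

**Compositional closure caveat.** Relative abundances are compositional:
if the slopes of the responding gates do not cancel, *every* other gate
acquires a small genuine relative trend of the opposite sign after
renormalization (closure). With a net inflow of +0.15 %/day, a 25% null
gate declines by ~0.04 %/day — real, and detectable once counting noise is
small. The acceptance suite documents the consequence: in a world with one
+0.9 and one −0.75 %/day responder, "exactly the two generative responders
are flagged" holds only ~half the time at high event counts, because the
pipeline *correctly* resolves the closure-induced declines whenever two
replicates' composition offsets happen to lie within the drift. That
assertion is kept in the suite as a known-red marker of this structural
fact; the attainable sub-claims (both true responders always found, no
flags under the null treatment, CI coverage of the implied slopes) pass.
When interpreting real data: a weak negative trend shared by many gates is
the signature of closure under a strong riser, not of independent decline.

## 6. Numerical conventions and edge cases

- Polygon validation normalizes vertex order to counter-clockwise and
  rejects non-convex or zero-area gates by cross-product sign.
- `apply_template` with zero gated events raises an explicit error rather
  than dividing by zero.
- Degenerate zero covariance collapses a cluster onto its center exactly
  (useful for oracle tests); any other non-positive-definite covariance is
  rejected.
- Realized abundances that clip to a zero total (all subcommunities driven
  extinct) abort with the sample key in the message.
- Fold changes against a zero reference return `Inf` with an explicit
  `"infinite"` status.
- FCS support is read-only (3.0/3.1, float/double/integer data, both byte
  orders), with channel selection by `$PnN` names; unknown channels error
  listing what is available. The package's own round-trip format is a
  delimited text table with the sample key in a header comment.

## 7. Known limitations

- Gates are convex and static; drifting clusters would need per-day
  templates, which would break abundance comparability.
- β counts membership turnover only; it is blind to abundance changes that
  do not cross the dominance threshold.
- No multiple-testing correction on ρ (deliberately, matching common
  practice for these fingerprint screens); with 34 gates × 5 treatments,
  expect a few |ρ| ≥ 0.4 flags under the null by chance when replicate
  structure is weak.
- The simulator's noise model (replicate-constant composition offsets +
  multinomial counting) is the simplest one consistent with replicated
  batch cultures; it understates day-to-day technical variability of real
  instruments.
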