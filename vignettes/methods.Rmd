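---
title: "Simulated live-imaging analysis of seeded tau aggregation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated live-imaging analysis of seeded tau aggregation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay this package models

Human iPSC-derived neurons expressing a TauRD-YFP biosensor (the tau
repeat domain with the P301L substitution fused to YFP) do not
aggregate spontaneously. When brain lysate containing misfolded,
seed-competent tau is added to the medium, the reporter is templated
into aggregates — first as small puncta in neurites, later as large
inclusions in the cell soma. A far-red vital dye labels live nuclei
dimly and lysed nuclei brightly, so cell death appears as a sudden
severalfold flash of the nuclear channel accompanied by nuclear
fragmentation. Imaging every 2 hours for 7 days (84 frames) yields, per
neuron, a censored event history: the time soma aggregation starts, the
time of death, or the time the cell leaves the field of view.

`tauseedr` implements the full analysis chain for such experiments —
punctum detection, single-cell tracking, survival statistics, and
aggregate-morphology classification — together with a ground-truthed
synthetic-microscopy generator, so that every stage can be tested
quantitatively without access to raw imaging data.

## The generative model

Event times are piecewise-constant-hazard (exponential) clocks; nothing
in the downstream statistics assumes this, but it gives closed forms for
every check.

* **Aggregation onset.** Hazard
  $h_{on} = h_0 \cdot m_{line} \cdot (d/10)^\gamma$, where $h_0$ is the
  control-line hazard at the 10 µg reference dose, $m_{line}$ applies to
  the mutant line only, $d$ is the lysate dose in µg and $\gamma$ the
  dose exponent. Control lysate and dose 0 never seed ($h_{on}=0$).
  Defaults $h_0 = 0.004\,/h$ and $m_{line} = 2.5$ put the 48-hour onset
  fractions near 0.17 (control) and 0.38 (mutant), the range reported
  for this class of experiment.
* **Death.** Baseline hazard $h_d = 0.002\,/h$ (about 28% baseline
  mortality over 7 d, typical of long-term neuronal culture), switching
  to $h_d \times 4$ at onset. A per-morphology multiplier (default 1)
  lets strain-dependent toxicity be simulated. The switch uses the
  memorylessness of the exponential: draw $e_1 \sim Exp(h_d)$; if
  $e_1 < t_{on}$ death is $e_1$, else $t_{on} + Exp(h_d m)$.
* **Field exit.** Independent hazard ($8\times10^{-4}\,/h$, ~12% over
  7 d); a cell that exits before dying disappears from all later frames
  and is right-censored.
* **Transient aggregation.** Each onset is transient with probability
  0.05; the aggregate then dissolves after an exponential dwell (mean
  30 h). This exercises the "Trans" branch of the class grammar.

Both the latent (untruncated) draws and the recorded (observable) event
times are kept in the truth table; distributional checks
(Kolmogorov–Smirnov against the configured exponentials) use the latent
values, pipeline validation uses the recorded ones.

## Rendering

Each cell is a static template — a soft-edged soma disc (radius 9 px,
diameter ≈ 12 µm at 0.65 µm/px) with 2–4 neurite segments at 30% of the soma's
diffuse brightness — stamped additively into each frame at its drifted
position. Drift is a common per-well stage-drift vector plus a small
per-cell motility jitter; making the jitter small (≤ 0.02 px/frame)
reflects the near-sessile behaviour of mature neurons and guarantees
somata placed ≥ 22 px apart never merge during a run. Neurite seed
puncta arrive as a Poisson process (rate per cell scaled by the same
dose response), are placed along neurites away from all somata, and move
with the field like the neurites that contain them.

Soma aggregates follow four archetypes: *Ordered* — one off-centre blob
whose width shrinks 2% per frame while its peak brightens (compaction);
*Disordered* — eight persistent cytoplasmic puncta; *Speckles* — five
puncta confined to the nucleus; *Other* — a lens-shaped (strongly
anisotropic) profile. Soma aggregates are rendered brighter than
neurite seeds (1.8× the punctum amplitude), reflecting that they
condense the soma's own reporter pool. No archetype exists for the
"Toxic" label; the generator accepts it as a category but assigns it
zero probability.

Death is rendered as the paper-described sequence: at the lysis frame
the nuclear dye jumps so that its background-subtracted mean over the
nucleus rises by exactly `death_flash_fold` (default 5) while the
nucleus fragments into three separated pieces; from the next frame the
cell body disperses to a faint residue and the bright fragmented
nucleus persists as a "dead-cell background nucleus". Gaussian read
noise (σ = 500 gray) is added last; photon (shot) noise,
photobleaching and focus drift are deliberately out of scope, so
passing tests demonstrate correctness of the analysis logic at a
realistic contrast-to-noise ratio, not robustness to every real-world
imaging artifact. Real images also contain overlapping cells, debris
and uneven illumination beyond the slow shading the median filter
removes; detection numbers on real data would be lower.

## Detection rules

Neurite seeds are connected components exceeding the **local
background** — a median filter, radius 15 px — by 10,000 gray levels,
with equivalent diameter $2\sqrt{A/\pi}$ between 0.1 and 4 µm. At
0.65 µm/px the 0.1 µm lower bound is sub-pixel, so the effective lower
bound is one pixel. Components above 4 µm are rejected and, dilated by
2 px, exclude whatever they touch. Because diffuse somata (~6,000 gray
over background) never cross the punctum threshold, the exclusion mask
is built at a lower soma-level threshold (2,500 gray); otherwise soma
aggregates — bright and smaller than 4 µm — would be counted as neurite
seeds, exactly the overcounting the exclusion is meant to prevent.

Soma-aggregate detection inside a tracked 70 × 70 px patch uses two
patch-local backgrounds: the patch median (camera background) to find
the soma's own footprint at the soma-level threshold, and the median of
that footprint as the reference the aggregate must exceed by the
punctum threshold. The second step is what makes the call specific: a
uniformly bright cell is its own background and never triggers, and
puncta not connected to the central soma (a neighbour's seeds drifting
through the patch) are never attributed to this cell. A frame is
positive when a component of ≥ 4 px survives these rules; the component
count, largest-component area fraction, nuclear-overlap fraction and
second-moment axis ratio are recorded for the morphology classifier.

The neurite-area surrogate thresholds the smoothed (σ = 0.8 px)
background-subtracted frame at 400 gray outside dilated soma cores,
closes the mask morphologically and drops components under 15 px. On
the simulator's cells this recovers the half-contrast footprint of the
rendered neurites to within ~10% while reporting essentially zero on
blank frames. It replaces trainable segmentation; it is a density
surrogate, not a morphological reconstruction. A wide background window
(radius 25 px) matters here: with the punctum-detection radius the
median near dense somata is inflated by the cells themselves and the
faint neurites vanish.

## Tracking and event calling

Somata are detected per frame at the soma-level threshold (≥ 50 px) and
linked by greedy nearest-neighbour assignment (max 20 px/frame, gaps up
to 2 frames bridged by interpolation, ties broken deterministically by
the lower incumbent track id). Tracks starting after the first frame
are excluded, mirroring selection of cells present at t0.

* **Death** is the first frame whose background-subtracted nuclear
  signal reaches 3× the rolling median of the preceding 5 frames. The
  window shrinks to 2 frames at the start of a track so early lysis
  remains callable; deaths in the first two frames have no baseline and
  are censored instead — an inherent limit shared by any
  change-detection rule. A floor (200 gray) guards near-zero medians.
  The readout disc (radius 7 px) is deliberately larger than the
  nucleus so the measured fold change is insensitive to the small
  centroid shift that an off-centre aggregate induces.
* **Onset** is the first run of ≥ 2 consecutive aggregate-positive
  frames; a later negative run of the same length marks the aggregate
  transient. An onset whose aggregate is rendered for fewer than 2
  frames (death within one frame of onset) leaves no scoreable
  evidence, for this rule and for a human scorer alike; the validator
  therefore scores recovery against *callable* onsets and reports such
  cells separately.
* **Censoring**: death takes precedence; otherwise a track ending early
  (gap timeout or field exit), a final position within 10 px of the
  border, or survival to the horizon censors the cell at that time.
* **Class labels** compose Initial+End+Survival state
  (`O`/`A` + `O`/`A` + `A`/`D`, e.g. `O+A+D`), with a transient flag —
  the automated equivalent of frame-by-frame manual scoring.

All event times live on the 2-h acquisition grid, so ties are heavy by
construction; the Cox fit uses the Efron tie correction by default
(Breslow available).

## Statistics

Kaplan–Meier estimation, the log-rank test and Cox regression wrap the
`survival` package (product-limit with Greenwood-based bands; `survdiff`;
`coxph`). A permutation log-rank option recomputes a vectorised version
of the same statistic under label permutation; tests verify the two
routes agree. Cumulative onset incidence is one minus the KM estimator
with onset as the event and death/censoring before onset censoring the
onset clock. The post-onset "survival clock" restarts each
aggregate-bearing cell's time at its onset and ignores left truncation,
matching the construction it reproduces; this is a simplification, and
the frequent end-of-experiment censoring it induces is visible in the
curves. Aggregate fractions at 48 h and 7 d count cells with onset at or
before the time point among cells still observable then, per replicate
well, compared across lines by Welch t tests. Seeding curves are
baseline-corrected by subtracting the overall mean of the no-lysate
counts (negative values retained so AUC stays unbiased), summarised by
trapezoidal AUC, and analysed by a two-way line × dose ANOVA with
Type II sums of squares (identical to I/III in the balanced simulated
designs) and by least-squares slopes in the 24–48 h window. Expression
correlations report Pearson r, r², and the adjusted R² of the matching
simple regression side by side, because published figures of this kind
are ambiguous about which of the three they print (adjusted R² can be
negative). No multiple-testing correction is applied, matching
per-comparison reporting conventions; a Holm adjustment is available to
users via `stats::p.adjust`.

## Morphology classification

Features are medians over the onset-to-death/end window (≥ 3
aggregate-positive frames, else Unclassifiable and excluded from all
statistics): punctum count, largest-component area fraction,
nuclear-overlap fraction, axis ratio of the largest component, and a
relative compaction slope (areas per hour / median area). The rules are
fixed: nuclear overlap > 0.5 → Speckles; else largest fraction > 0.6 →
Ordered, unless the axis ratio exceeds 2.2, which marks the lenticular
Other; else median count ≥ 5 → Disordered; else Other. The elongation
branch exists because a lens-shaped inclusion is a single dominant
component — without it nothing could ever be classified Other, and the
stated recovery target is unreachable for any mix containing that
archetype. Thresholds (0.5, 0.6, 5, 2.2) were frozen against the
archetype geometry before the recovery experiments were run. "Toxic" is
accepted in inputs for interoperability but never emitted. Residual
confusion concentrates between Ordered and Other, the two classes that
differ only in shape. Aggregate lifespan is reported as the observed
aggregate-bearing duration with the censoring status alongside; nothing
is imputed for aggregates still present at censoring.

## Problem sizes and numerical choices

The packaged experiments use one 256 × 256 px field per well (the
acquisition tiles several; tiling adds nothing to the analysis
contract), 60 cells per tracked well, 30 cells per 192 × 192 px seeding
well, and 84 frames. Replicate-level studies (type-I error, the
onset/post-onset dissociation) run on the generator's event sampler
directly — the stochastic layer the statistics consume — with a single
full image-pipeline run demonstrating the same result end to end;
rendering dozens of replicate fields would only re-measure the
detection layer already validated separately. Per-well RNG streams are
derived from one master seed, so any well can be regenerated alone and
identical configurations are bit-identical. Pixel coordinates are
1-based (x = column, y = row), R's native convention. Degenerate inputs
follow one rule throughout: impossible requests (no calibration, empty
groups, horizons beyond the data) are errors; legitimately degenerate
data (constant intensities, a class absent in one line) yield `NA`
statistics with a note rather than failures.

## Known limitations

Rendering is additive-Gaussian, not optics-faithful; no photobleaching,
shot noise, focus drift or cell division (cultures are post-mitotic).
The tracker is greedy, not globally optimal, and does not handle
overlapping somata (the generator avoids them; real data would need the
exclusion radii re-tuned). Morphology thresholds are tuned to the
archetypes; agreement with human raters on real imagery is unknowable
without real images. The post-onset clock ignores left truncation. The
uptake-by-compartment comparison operates on measured compartment
intensities and is exercised distributionally, not through rendered
label-channel images.
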