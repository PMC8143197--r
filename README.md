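# tauseedr

Simulated live-imaging analysis of seeded tau aggregation and neuronal
survival in human iPSC-derived neurons.

## The problem

Neurons expressing a TauRD-YFP biosensor (the tau repeat domain with
P301L, fused to YFP) aggregate only when exposed to seed-competent
misfolded tau — e.g. brain lysate from tauopathy-model mice. Two-channel
time-lapse imaging (reporter + a far-red vital nuclear dye, one frame
every 2 h for 7 d) then yields, per neuron, a censored event history:
when aggregation starts in the soma, when the cell dies (a sudden flash
and fragmentation of the nuclear dye at lysis), or when it leaves the
field of view. The questions such experiments answer are survival
questions: does aggregation raise the risk of death? do mutant lines
aggregate earlier, die faster after aggregating, or both? does the
morphologic "strain" of the aggregate matter?

`tauseedr` provides, for researchers building or validating such
pipelines:

* a **ground-truthed synthetic microscopy generator** — per-cell
  exponential clocks for aggregation onset (line- and dose-scaled),
  death (hazard switching at onset, optionally by morphology), and
  field exit; rendered somata, neurites, neurite seed puncta, four
  aggregate-morphology archetypes, the nuclear lysis flash with
  fragmentation, and Gaussian read noise;
* **detection**: local-background (median-filter) thresholding of
  neurite seed puncta with the 0.1–4 µm size band and a 10,000
  gray-level intensity rule, large-bright-area exclusion,
  soma-aggregate detection in tracked 70×70 px patches, and a
  neurite-area surrogate;
* **tracking**: greedy nearest-neighbour soma linking, death calls from
  the nuclear flash (fold over a rolling median), onset calls with
  persistence, censoring rules, and `Initial+End+Survival` class labels
  (e.g. `O+A+D`);
* **survival statistics**: Kaplan–Meier with Greenwood bands, log-rank
  (asymptotic and permutation), Cox proportional hazards with Efron
  ties, cumulative onset incidence, post-onset survival clocks,
  aggregate fractions at fixed times, seeding-curve AUC with a two-way
  line × dose ANOVA and early-window slopes, and expression
  correlations;
* **morphology classification** into Ordered / Disordered / Speckles /
  Other / Unclassifiable from patch descriptors, with per-line
  frequency and outcome comparisons.

The core survival model: each cell's death hazard is
`h_d` before aggregation onset and `h_d × m` after it; onset hazard is
`h_on = h_0 · m_line · (dose/10)^γ`. The central analysis pattern the
package reproduces is the dissociation between *earlier onset* and
*post-onset survival*: a line that only aggregates faster separates in
cumulative onset incidence but not on the post-onset survival clock.

## Worked example

```r
library(tauseedr)

cfg <- sim_config(line_label = "mutant", n_wells = 1,
                  n_cells_per_well = 60, rng_seed = 3)
sim <- simulate_well(cfg, 1)      # renders an 84-frame 2-channel stack
tc  <- track_cells(sim$stack)     # detect, link, call events, classify
table(tc$events$class_label)
#> O+A+A O+A+D O+O+A O+O+D
#>    19    17    14    10

truth <- simulate_experiment(cfg)$truth
v <- validate_against_truth(tc$events, truth)
round(c(onset = v$onset_within_1_frame, death = v$death_within_1_frame,
        status = v$status_agreement), 3)
#>  onset  death status
#>  1.000  1.000  0.983
```

Each label reads Initial+End+Survival: `O+A+D` is a neuron that started
without an aggregate, formed one, and died; 19 of 60 neurons here were
aggregate-bearing and alive at the 7-day horizon; onset and death calls
match the generator's ground truth to within one 2-hour frame, and
censored-versus-death status agrees for 98% of tracks.

The numbered scripts under `analysis/` run the full study:
`01_simulate_experiment.R` (conditions and ground truth),
`02_seeding_curves.R` (baseline-corrected neurite seed counts, AUC,
dose ANOVA, 24–48 h slopes), `03_single_cell_tracking.R` (event table +
truth validation), `04_survival_analysis.R` (early-aggregator KM
comparisons, cumulative onset, post-onset clock, Cox model, aggregate
fractions), `05_morphology.R` (strain classification and comparisons).
Tables land in `results/`.

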