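# ptclock

Locating the pyramidal tract (PT, corticospinal tract) relative to thalamic
and basal ganglia tumors, for neurosurgical planning research. Deep-seated
tumors displace the PT — the densely packed internal capsule can be pushed
but not encased — so the tract's position around the tumor follows the
tumor's own position. `ptclock` implements the full analysis chain that
turns diffusion-weighted MRI into that statement, and validates it end to
end on digital phantoms with analytic ground truth.

## What the package computes

1. **Tensor fit.** Per-voxel log-linear least squares on the
   Stejskal–Tanner model `S = S0 exp(-b gᵀ D g)`, with eigen-system, FA
   (`sqrt(3/2)·||λ − λ̄|| / ||λ||`) and ADC maps.
2. **Tensor-deflection tractography.** Streamline update
   `v' = normalize(0.2 v + 0.8 e₁)` with the clinical parameter set
   (FA ≥ 0.2, turn ≤ 30°/step, step = 1/3 voxel, length ≥ 50 mm) and a
   three-VOI selection protocol (seed corridor, precentral gyrus,
   cerebral peduncle with craniocaudal orientation).
3. **Operator-agreement gate.** Voxel-wise Cohen's kappa between two
   simulated operators' tracts; cases below κ = 0.7 are excluded.
4. **Three-line landmark geometry.** On the axial slice through the foramen
   of Monro (right-sided cases mirrored to the left): line 1 vertical
   through the anterior-limb vertex of the internal capsule, line 2
   horizontal through the foramen of Monro, line 3 horizontal through the
   junction of the middle and lateral thirds of the posterior limb.
5. **Eight-type tumor classification** from the three lines, and the frozen
   type → clock-sector prediction (12 = anterior, 3 = lateral, 6 =
   posterior, 9 = medial): T1→12, T2→6, T3A→9–12, T3B→6–9, T4A→12–3,
   T4B→3, T5→6–9, T6→3–6.
6. **Cohort summaries** (per-type shares, line-based aggregates,
   concordance rates) and a **phantom generator** emulating the acquisition
   (b = 1000 s/mm², 12 directions + b0, 1.9×1.9×3 mm voxels, five averages,
   Rician noise).

## Worked example

```r
library(ptclock)

# a type-4a phantom: posterior-medial tumor beyond line 3, SNR 25
case <- make_phantom_case(phantom_spec("T4A", seed = 42))
rec  <- run_case(case, case_id = "example_T4A", verbose = TRUE)
```

```
[example_T4A] fit          4.28s
[example_T4A] track        4.68s 57/80 streamlines
[example_T4A] gate         4.74s kappa = 0.990 (include)
[example_T4A] classify     4.75s type T4A

     case_id tumor_type observed_sector predicted_sector match     kappa included
 example_T4A        T4A            12-3             12-3  TRUE 0.9898806     TRUE
```

Reading: the two operators' tracts agree at κ = 0.99 (≥ 0.7, case
included); the tumor classifies as type 4a from the three-line geometry;
the tracked PT crosses the Monro slice between 12 and 3 o'clock relative to
the tumor — exactly the sector the type predicts, and the phantom's
analytic truth.

Feeding the published per-type counts through the cohort summary:

```r
summarize_cohort(c(T1 = 6, T2 = 6, T3A = 7, T3B = 5, T4A = 17, T4B = 6,
                   T5 = 3, T6 = 9))
```

gives n = 59 with shares 10.17 / 10.17 / 11.86 / 8.47 / 28.81 / 10.17 /
5.08 / 15.25 % and aggregates: 15 tumors (25.42 %) lateral of line 1,
18 (30.5 %) anterior of line 2, 24 (40.68 %) beyond line 3.

## Analysis scripts

Narrative drivers under `analysis/` write their tables to `results/`:

* `01_cohort_tables.R` — per-type shares and line-based aggregates from the
  published counts.
* `02_example_case.R` — one full case with all artifacts on disk (DWI,
  masks, TRK tract + JSON mirror, FA/ADC maps, report).
* `03_insilico_concordance.R` — 8 types × 5 seeds at SNR 25; per-type
  observed-vs-predicted sector concordance.
* `04_operator_agreement.R` — healthy-case kappa per type plus the
  constructed exclusion case (SNR 10, FA-damping shell).

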