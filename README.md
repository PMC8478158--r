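# cytoddr

Event-level analysis of mass-cytometry (CyTOF) DNA damage response (DDR)
time courses in peripheral-blood lymphocytes.

After ionizing radiation or UVC exposure, cells phosphorylate a cascade
of DDR proteins — γH2AX (S139), p-ATM (S1981), p-CHK2 (T68) and p53 —
whose induction kinetics differ sharply between lymphocyte lineages (NK
cells mount the strongest γH2AX response, B cells dominate p-CHK2, naive
T cells trade γH2AX for p-ATM/p53) and are essentially abolished in ATM
deficiency (ataxia telangiectasia). cytoddr implements the complete
computational side of such an experiment for analysts working with
pooled, palladium-barcoded CyTOF time courses:

* **FCS 3.0/3.1 IO** — reader ($DATATYPE F and I, both byte orders) and
  FCS 3.1 writer, with a panel model (channel ↔ metal ↔ marker ↔ role).
* **Preprocessing** — arcsinh transform (cofactor 5), iridium
  (Ir191/Ir193) singlet gating, cisplatin viability gating, thresholds
  estimated per file or overridden.
* **Debarcoding** — 20-key 3-of-6 Pd scheme, single-cell top-3
  separation deconvolution with doublet and low-confidence rejection.
* **Gating** — a declarative, hierarchical specification of 30
  T/NK/B populations (naive/CM/EM CD4 and CD8 T; CD56bright/dim × CD16 ×
  CD57 NK; naive/memory/switched/MZ-like/transitional/atypical B,
  plasmablasts, CD21^low CD38^low B), automated density-valley
  thresholds, and ki67/IdU cell-cycle classification (G0/G1/S plus the
  ki67−IdU+ arrested fraction).
* **Quantification** — per-population geometric MFI on the raw scale,
  per-donor fold induction `fold(t) = geoMFI(t) / geoMFI(untreated)`,
  survival composition tables (% of viable CD45+), and ki67-stratified
  kinetics.
* **Statistics** — two-way ANOVA with Tukey HSD pairwise comparisons
  (studentized range on the pooled MSE), Šídák adjustment, Student's t,
  and the `*/**/***/****` star code.
* **Synthetic experiments** — a seeded generator producing pooled
  barcoded events with ground-truth sidecars (subset-specific lognormal
  expression, pulse-shaped DDR kinetics `1 + A·(t/tp)·e^{1−t/tp}`,
  B-cell survival decay, AT profiles, dead-cell/doublet/barcode
  artifacts), so every stage is verifiable without any data download.

## Worked example

Simulate a two-donor experiment, run the pipeline, and inspect γH2AX
kinetics in the three main lineages:

```r
library(cytoddr)

cfg <- default_config_healthy(n_donors = 2, events_per_timepoint = 5000,
                              seed = 1)
sim <- simulate_experiment(cfg)
res <- analyze_experiment(sim)

subset(res$kinetics,
       population %in% c("CD3+ T", "CD56dim CD16+ NK", "CD19+CD20+ B") &
         marker == "gH2AX" & donor == "HD01")
```

```
 donor       population timepoint_h n_pos geo_mfi fold_induction
  HD01     CD19+CD20+ B           0   355    16.3          1.000
  HD01     CD19+CD20+ B           1   324    37.7          2.318
  HD01           CD3+ T           0  3390    16.3          1.000
  HD01           CD3+ T           1  3377    70.5          4.334
  HD01 CD56dim CD16+ NK           0   267    17.1          1.000
  HD01 CD56dim CD16+ NK           1   249   115.0          6.720
```

Each row is one (donor, population, marker, time point): `geo_mfi` is
the geometric mean of positive raw intensities, `fold_induction` the
ratio to the same donor's untreated sample — so γH2AX peaks at 1 h with
the lineage ordering NK (6.7×) > T (4.3×) > B (2.3×), and decays back to
baseline by 8–24 h. The survival table shows the B-cell composition
decline after irradiation:

```r
subset(res$survival, population == "CD19+CD20+ B" & donor == "HD01")
```

```
   population timepoint_h n_events pct_of_viable_CD45
 CD19+CD20+ B           0      369               7.84
 CD19+CD20+ B          24      187               4.01
```

`run_pipeline(cfg, "out/")` performs the same analysis and writes
`kinetics.csv`, `survival.csv`, `comparisons.csv` (Tukey comparisons
with stars), `thresholds.csv`, `yield.csv` and `run_report.json`.
A thin CLI wrapper ships in `inst/scripts/cytoddr`
(`cytoddr simulate --seed 1 --out sim/`,
`cytoddr run --config inst/extdata/demo_config.yaml --out out/`).

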