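# cipaddi — in silico TdP risk of two-drug combinations

Drug-induced torsade de pointes (TdP) is the proarrhythmia that the CiPA
(Comprehensive In-vitro Proarrhythmia Assay) paradigm screens for in
silico: measured ion-channel dose–response parameters are imposed on a
simulated human ventricular myocyte and the net charge

    qNet = ∫₀^2000ms (IKr + ICaL + INaL + Ito + IKs + IK1) dt   [uC/uF]

over one paced beat classifies a compound as low, intermediate or high
TdP risk. Patients rarely take one drug at a time, though. `cipaddi`
extends the assessment to **two-drug combinations**: each drug blocks up
to seven channels (Na, NaL, to, CaL, Kr/hERG, Ks, K1) by the Hill
fraction `E = 1 − [1 + (D/IC50)^n]^(−1)`, and the pair's combined block
per channel is either

* **allotopic** (independent sites): `E_AB = E_A + E_B − E_A·E_B`, or
* **syntopic** (shared site): `E_AB = (E_A + E_B − 2·E_A·E_B)/(1 − E_A·E_B)`.

The blocked O'Hara–Rudy endocardial myocyte (with CiPA-optimized
conductance scaling and hERG Markov gating) is paced at a 2000-ms cycle
length — 1000 drug-free beats to steady state, then 1000 drug beats —
and the beat with the steepest repolarization gradient among the last
250 yields APD90, CaD90 and qNet. Thresholds at 0.0652 and 0.0516 uC/uF
classify every (concentration pair × bootstrap sample) cell of a 0–4×cmax
combination map, the package's analogue of the assay's risk maps.

Intended users: safety-pharmacology and cardiac-electrophysiology
modellers who want a self-contained, scriptable implementation of the
combined-drug qNet assessment. Real per-drug bootstrap samples (the
public FDA CiPA CSVs) can be read in; a synthetic drug-sample generator
and a bundled synthetic three-drug panel make everything testable with
no downloads.

## Worked example

A reduced profile (100 control beats, 20 drug beats) keeps this example
to a few minutes on one CPU; the full protocol is `protocol_config()`.

```r
library(cipaddi)

pc <- protocol_profile("test")          # reduced, clearly-labelled profile
ctrl <- run_control(pc)
ctrl
#> <control_run> 100 beats (CL 2000 ms)
#>   qNet 0.0548 uC/uF, APD90 281.1 ms

## a potent selective hERG blocker vs a calcium-channel blocker
herg <- synthesize_population("hergA", cmax = 2,
                              nominal = list(Kr = c(ic50 = 1.2, h = 0.9)),
                              n_samples = 2, seed = 42)
cal  <- synthesize_population("calB", cmax = 120,
                              nominal = list(CaL = c(ic50 = 250, h = 1),
                                             Kr  = c(ic50 = 12000, h = 0.9)),
                              n_samples = 2, seed = 8)

## half-maximal hERG block prolongs the action potential and drains qNet
bm <- run_biomarkers(run_drug(ctrl, c(Kr = 0.5), pc))
round(bm$apd90, 1); round(bm$qnet, 4)
#> [1] 398.8
#> [1] 0.0316

## combination map over 0-2x cmax, allotopic interaction
map <- build_combination_map(herg, cal, "allotopic", ctrl, pc,
                             multiples = 0:2)
map$n_high
#>      multB
#> multA 0 1 2
#>     0 0 0 0
#>     1 2 2 2
#>     2 2 2 2
```

Reading the map: rows are the hERG blocker's concentration multiple.
Drug-free and hERG-free cells stay out of the high-risk class; at ≥1×
cmax the blocker pushes both bootstrap samples' qNet below the lower
threshold regardless of the partner's concentration — the monotone
high-risk shift expected of a pure hERG blocker. `plot(map)` renders the
three per-class panels shaded 0–100%.

The same machinery scales up: `tdp_metric_single()` labels each drug by
its mean qNet over 1–4×cmax, `cmd_panel()` enumerates all `n(n−1)/2`
pairs (66 for the 12 CiPA reference drugs, 25 concentration pairs each)
and tallies predicted classes per prior-risk pair, and
`read_drug_csv()` ingests FDA-style per-sample files
(`channel_map = c(hERG = "Kr")` translates foreign column tags).

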