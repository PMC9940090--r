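---
title: "Methods: in silico TdP risk of drug combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico TdP risk of drug combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cipaddi)
```

## The question the package answers

Block of cardiac ion channels — above all the hERG/IKr potassium channel —
can delay ventricular repolarization and trigger torsade de pointes (TdP).
The CiPA paradigm assesses this risk in silico: measured dose–response
parameters (IC50, Hill coefficient) for up to seven channels are imposed on
a simulated human ventricular myocyte, and the net charge `qNet` carried by
six currents over one paced beat classifies the drug as low, intermediate
or high TdP risk. `cipaddi` extends this single-drug assessment to
*two-drug combinations*: each drug's per-channel block is combined with a
pharmacodynamic interaction model, and the combined compound is classified
over a grid of concentration pairs and a population of bootstrap parameter
samples.

## The cell model

The myocyte is the O'Hara–Rudy undiseased human ventricular endocardial
cell: membrane potential obeys

    dVm/dt = -(Iion + Istim) / Cm,    Cm = 1 uF/cm^2,

with `Iion` the sum of 14 currents (INa, Ito, ICaL, ICaNa, ICaK, IKr, IKs,
IK1, INaCa, INaK, INab, ICab, IKb, IpCa), plus the full complement of
gating variables, CaMK signalling and intracellular Na/K/Ca pools of the
source model. Two CiPA-era modifications are built in:

* IKr uses the six-state hERG Markov gating model (closed, open and
  inactivated layers) rather than the original Hodgkin–Huxley gates; the
  original formulation remains available (`ikr = "hh"`).
* Five maximal conductances carry the CiPA rescaling optimized against APD
  rate-dependence data: `GNaL` ×2.661, `PCa` ×1.007, `GKr` ×1.013,
  `GKs` ×1.870, `GK1` ×1.698 (`cipa_scaling()`).

Drug binding kinetics on hERG are deliberately **not** modelled: drug
effects enter purely as conductance block (below), so IKr block is
instantaneous in concentration. The cell subtype, stimulus and solver are
not prescribed by the risk protocol itself; the package fixes them as
configuration with these defaults:

| choice | default | rationale |
|---|---|---|
| cell subtype | endocardial | the CiPA standard cell |
| stimulus | −80 uA/uF, 0.5 ms, at beat start | source-model convention |
| cycle length | 2000 ms | the TdP metric pacing rate |
| integrator | fixed step, Rush–Larsen gates | deterministic, reproducible |
| time step | 0.005 ms | explicit-scheme stability (see below) |
| trace sampling | 1 ms | biomarker interpolation handles sub-sample crossings |

## Drug block and the two interaction models

A drug at concentration `D` blocks channel `i` by the Hill fraction

    E = 1 - [1 + (D / IC50)^n]^(-1),

and the channel keeps conductance `g_i = g_control,i (1 - E)`. Channels
without measured parameters carry no block (`E = 0`), matching CiPA
practice. Block of `CaL` scales the shared L-type permeability, so ICaL,
ICaNa and ICaK are reduced together; fast (`Na`) and late (`NaL`) sodium
conductances are blocked independently.

Two single-drug fractions `E_A`, `E_B` on the same channel combine as

* **allotopic** (independent binding sites; Bliss-independence-like):
  `E_AB = E_A + E_B - E_A E_B` — the union probability of two independent
  blocking events;
* **syntopic** (competition for one site; Loewe-additivity-like):
  `E_AB = (E_A + E_B - 2 E_A E_B) / (1 - E_A E_B)`, continuously extended
  to 1 at the removable singularity `E_A = E_B = 1`.

For all inputs `max(E_A, E_B) <= syntopic <= allotopic <= 1`; both
combiners are commutative and monotone, and the package property-tests
these identities on dense grids. Concentrations are nM throughout; cmax
multiplication happens upstream of the combiners. A channel measured for
only one drug keeps that drug's single effect — the assay literature does
not prescribe this case, and the single-effect fallback is the natural
limit `E_other = 0` of both combiners.

## Pacing protocol and biomarkers

1. *Control:* the drug-free model is paced 1000 beats (CL 2000 ms) from
   the published initial conditions to its dynamic steady state.
2. *Drug:* from that steady state, the blocked model is paced 1000 beats;
   every concentration pair restarts from the same drug-free steady state
   (the protocol literature does not say otherwise; restarting makes cells
   independent and maps reproducible).
3. *Beat selection:* among the last 250 beats, the beat with the steepest
   repolarization gradient `dV/dt_repol` — the maximum slope between the
   30% and 90% repolarization crossings (or to the end of the beat when
   90% is never reached) — is selected: a positive value flags an early
   afterdepolarization, the cellular TdP precursor.
4. *Biomarkers* of the selected beat: `APD90` (peak Vm to the interpolated
   90%-repolarization crossing, amplitude-relative), `CaD90` (same on the
   calcium transient), and `qNet`, the trapezoidal integral of
   IKr + ICaL + INaL + Ito + IKs + IK1 over the full 2000 ms beat, in
   uC/uF.

Interpretation choices a reader should know: repolarization percentages
are measured against the beat's amplitude (peak minus beat minimum), the
standard CiPA reading of "90% of its value"; the AP peak is the absolute
Vm maximum of the beat (under EADs a local-maximum convention would
differ); beat-selection ties go to the latest beat, the closest to
limiting behaviour; a beat whose peak stays below −30 mV counts as no
elicited AP.

## Risk classification and combination maps

`qNet` above `threshold1 = 0.0652` uC/uF is low risk, between
`threshold2 = 0.0516` and `threshold1` intermediate, at or below
`threshold2` high. The thresholds are configuration constants from the
ordinal-regression calibration of the CiPA training set; a value exactly
on a threshold is assigned to the class enclosing it from below
(`q = threshold1` is intermediate), and non-finite qNet (failed run) is
"unclassifiable" rather than silently dropped.

A drug's *prior* label is the classification of its single-drug TdP
metric: the mean qNet over 1–4× cmax, per bootstrap sample. A
*combination map* for a drug pair classifies each sample's qNet at each
concentration pair (0–4× cmax each, 25 cells) directly — no 1–4×
averaging inside the map; the two conventions coexist in the assay and
the package keeps them separate deliberately. The 0× row/column reproduce
single-drug effects and the (0,0) cell the control. Risk-pair summaries
(`summarize_risk_pairs()`) tally predicted classes per unordered pair of
prior labels over all maps, *excluding* the 0× rows and columns: those
cells are single-drug effects, not combinations.

## The synthetic drug-sample generator

Real assessments read the public per-drug bootstrap samples (100 MCMC
draws of IC50 and Hill per channel). The MCMC fit itself is out of scope
here — the samples are inputs — so the package ships a generator that
emulates their statistical shape: IC50 log-normal around a nominal value
(log-sd `spread`, default 0.2, a well-constrained patch-clamp fit's
spread), Hill normal truncated positive (sd 0.1). The bundled three-drug
panel (`synthetic_panel()`) spans the qualitative profiles of the
reference drugs — a potent selective hERG blocker, a balanced
multichannel blocker, and a predominantly CaL blocker — with synthetic
cmax values; every file and name is labelled synthetic. What the
generator does *not* emulate: inter-channel correlation of the bootstrap
draws, heavy-tailed or multimodal posteriors, and the measured-drug
channel spectra. Tests passing on this panel therefore demonstrate the
machinery (protocol, combination algebra, classification, conservation
and symmetry properties), not agreement with any published drug-specific
result, which would require the external measured datasets and the full
66 × 25 × 100 design.

## Numerical choices

* **Time step.** The explicit scheme (Rush–Larsen for Hodgkin–Huxley
  gates, forward Euler for concentrations and Markov states) is unstable
  at the AP upstroke for dt = 0.01 ms; dt = 0.005 ms is stable and a
  halving study shows APD90 moves by well under 0.5 ms from dt = 0.005 to
  0.0025 ms. The step is configurable but 0.005 ms is the default
  everywhere, including the reduced test profiles.
* **Determinism.** Fixed step sequence, no adaptivity: identical inputs
  give bit-identical trajectories, which the suite asserts.
* **Crossings** are located by linear interpolation between 1-ms output
  samples; `dV/dt` is the centered difference on the output grid.
* **Steady state.** Pre-pacing runs the full 1000 beats by default. An
  optional early exit stops when the maximum relative end-of-beat state
  change drops below `ss_tol`. The documented steady-state band on qNet
  is 0.005 uC/uF: a 200-beat control differs from the 1000-beat value by
  about this much, and the band matches the solver-tolerance band
  (±0.004) attached to the reference control value.
* **Degenerate inputs.** Negative concentrations, inhibition fractions
  outside [0, 1], empty populations and malformed CSVs are rejected with
  messages before any compute; non-finite states and potentials outside
  (−150, 80) mV abort integration with a divergence signal carrying the
  failing beat and time, and protocols report such runs as failed rather
  than dropping them.

## Problem sizes used by the shipped checks

The test suite and acceptance script size their simulations for a single
CPU: the full 1000-beat control pacing is run once (it is the reference
quantity); property checks of protocols, maps and summaries use named
reduced profiles (100 control beats, 20–30 drug beats, trailing windows
of 5–8 beats, 2-sample populations, 0–2× grids). These profiles are
design choices exposed as `protocol_profile()` — a scaled run is labelled
as such in every output and is never silently substituted for the full
protocol.

## Known limitations

* Conductance block only: no dynamic hERG binding kinetics, so
  trapping-dependent differences between drugs are invisible.
* Pairs only; the combination algebra extends associatively to more
  drugs, but no protocol or map supports >2 drugs.
* Fixed cmax per drug: no pharmacokinetics, tissue localization or
  patient-specific exposure.
* Single endocardial cell: no transmural heterogeneity, fiber or organ
  level electrophysiology, and no mechanosensitive channels.
* The qNet thresholds are taken as constants; their derivation (ordinal
  regression over the training drugs) is not reimplemented.
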