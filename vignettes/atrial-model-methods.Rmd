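---
title: "Model and methods: the atriasim atrial electrophysiology toolchain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: the atriasim atrial electrophysiology toolchain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(atriasim)
```

## Scope

`atriasim` simulates human atrial electrophysiology at two scales: a single
atrial myocyte (a system of 23 ordinary differential equations) and
monodomain tissue (a reaction--diffusion equation on voxel grids). Around
the solvers it implements the standard analysis protocols of the
atrial-fibrillation (AF) modelling literature: action-potential duration
(APD) and restitution, effective refractory period (ERP), S1--S2
vulnerability-window scanning at tissue junctions, conduction-velocity
measurement and calibration, re-entry detection on rings, and
dominant-frequency mapping.

This vignette is the package's record of the modelling choices: the
equations, the free parameters and how they were fixed, the numerical
scheme, and the known limitations. It states no empirical result that the
test suite or the acceptance script does not itself compute.

## The myocyte model

The cell model is a Courtemanche--Ramirez--Nattel (CRN) family formulation
assembled from three published lineages, with every equation-level choice
listed here.

**Membrane currents.** I_Na uses Luo--Rudy kinetics exactly as in the CRN
model. I_CaL keeps the CRN activation gate `d` but replaces the single slow
voltage inactivation gate by the Nygren-lineage *fast + slow* pair
(`f_1`, tau about 10 ms at plateau; `f_2`, tau about 63 ms), plus a
Ca-dependent gate `f_Ca` that senses the peripheral (subsarcolemmal) Ca
with a half-saturation of 3 uM, scaled to the micromolar peripheral levels
of the compartmental Ca model. I_to and I_Kur use Nygren/Maleckar-style
first-power activation x inactivation kinetics; the sustained-current
activation midpoint sits at -15 mV so I_Kur carries plateau current in the
short remodelled APs. I_Kr uses CRN gating with a 1.5x slower activation
time constant; I_Ks uses CRN gating with a 2x slower activation time
constant, so it accumulates (and therefore repolarises) only during long
APs. I_K1 uses a steep inward rectification, `1/(1 + exp(0.09 (V + 82)))`,
of the Nygren family, confining it near the resting potential. The
NaK pump, Na-Ca exchanger, sarcolemmal Ca pump and background currents are
CRN formulations; the exchanger and pump sense peripheral Ca.

**Ca handling.** The four serial sarcoplasmic-reticulum (SR) compartments
of the spatial Koivumaki-lineage description are reduced to two well-mixed
pools (one SERCA uptake pool, one ryanodine-receptor release pool,
connected by a 180 ms transfer), and the cytosol is split into a
peripheral compartment (10% of cytosolic volume, carrying all sarcolemmal
Ca fluxes and the SR release flux, buffered by calmodulin plus a
sarcolemmal site class) and an interior compartment (troponin and
calmodulin buffering, SERCA uptake), exchanging with a 2 ms time constant.
Release keeps the CRN flux-triggered gating (`u`, `v`, `w`). This
reproduces the two-phase Ca-transient upstroke (the peripheral signal
peaks tens of milliseconds before the interior signal) while roughly
halving the state count of the four-compartment original.

**Stimulus bookkeeping.** Stimulus current is assigned to K+ so that
long pacing does not drift the ionic concentrations; the test suite checks
< 5% drift of Na_i and K_i over 100 beats. Extracellular concentrations
are fixed at CRN values (Na_o 140, K_o 5.4, Ca_o 1.8 mM).

**Units.** V in mV, time in ms, currents in pA/pF, concentrations in mM.
C_m = 100 pF converts nA stimulus amplitudes to pA/pF at the boundary.

### How the free parameters were fixed

The maximal conductances are not inherited from any single source model;
they were calibrated, once, against the published single-cell outputs of
the updated-CRN atrial model family: control APD90 of 242 ms at BCL
1000 ms with a resting potential near -80 mV and spike-and-dome
morphology, and the four documented AF-remodelling APD reductions (62, 60,
45, 49% for the AF-1..AF-4 transforms below). Control APD alone does not
identify the current balance -- many balances give 242 ms but respond very
differently to remodelling -- so the remodelling responses are part of the
calibration surface, and the corresponding test-suite checks are
consistency checks of that calibration rather than independent
predictions. The regional family (below) and the AF-4 left-atrial/
pulmonary-vein dispersion then follow from separate, per-region
calibrations.

A structural feature worth knowing: the model family is bistable between a
spike-and-dome AP (~200--300 ms) and a collapsed triangular AP
(~50--135 ms), with a forbidden duration band between them. Remodelled and
short-AP regional cells live on the collapsed branch; the printed
intermediate durations constrain which currents may carry the collapsed
branch (weak I_K1/I_Kr at -40..-70 mV, I_Kur dominant). The operating
point sits a safe margin from the branch-flip boundary (verified under
time-step halving, Rush--Larsen updates and beat-count changes).

## Regional cell models

Ten region labels are supported (RA base, CT, PM, RAA, AVR, AS, BB, LA,
LAA, PV). A regional variant is a set of multiplicative factors on maximal
conductances ([default_regional_table()]), produced by a deterministic
one-dimensional bisection per region ([calibrate_regional_table()])
against the published targets: absolute APD90 for RAA (230 ms), BB
(297 ms) and AS (152 ms); ratios to RAA for CT (1.21), PM (1.03), AVR
(0.71) and LA (0.86); and the 47 ms LA-PV difference for PV. LAA has no
published value; 190 ms (between LA and AVR) is the package's choice.

Which channels each region may scale follows the literature where the
base model permits it (PM, RAA scale I_CaL/I_to/I_Kur(/I_K1)), but two
deliberate deviations were needed because the calibrated base model's
control AP tail is carried by the delayed rectifiers: CT and BB reach
their prolonged APDs mainly by scaling I_Ks down (I_CaL/I_to scaling alone
saturates ~10 ms above control), and the short-AP regions AVR/AS/PV are
built on the collapsed branch via a deep I_CaL/I_Kur reduction with I_K1
tuned (their real counterparts are indeed short, triangular,
reduced-I_CaL phenotypes). The LA solution is degenerate (many
I_Kr/I_Ks/I_to mixes yield its control target); the shipped choice is the
I_Kr-dominant mix, selected so the LA-PV dispersion under the AF-4
transform matches its published 40 ms value. Under the AF-1/AF-2
transforms this model family collapses LA below PV, so the
"dispersion preserved under AF" property holds for AF-3/AF-4 only -- a
known limitation stated here and excluded from the stronger claims.

## AF remodelling scenarios

`af_scenario()` encodes six conditions as parameter transforms plus a
fractional reduction of the tissue diffusion coefficient:

| id | channel transforms | diffusion |
|----|---------------------|-----------|
| CONTROL | identity | 0% |
| AF0 | identity | -60% |
| AF1 | I_CaL -70% with 60% slower kinetics; I_to -70% with +16 mV inactivation shift; I_K1 +100% | -40% |
| AF2 | I_CaL -65%; I_to -65%; I_K1 +75% | -40% |
| AF3 | I_CaL -63%; I_to -66%; I_K1 +106%; I_Kur -49% | -40% |
| AF4 | I_CaL -70%; I_to -65%; I_K1 +100%; I_Kur -50%; I_Ks +100%; NCX +55%; SERCA +50%; RyR +300%; SR leak +25% | -40% |

Percentages apply multiplicatively to maximal conductances/flux scales;
only AF1 touches kinetics. The +16 mV shift is applied to the I_to
steady-state inactivation curve (depolarising), the reading most
consistent with the underlying voltage-clamp data; the time-constant
multiplier applies to both I_CaL activation and inactivation.

## Tissue model and numerics

The monodomain equation `dV/dt = div(D grad V) - I_ion/C_m` is discretised
with centred finite differences on voxel grids (0.33 mm default spacing)
and integrated with forward Euler at dt = 0.005 ms, the classical scheme
for this model family. Details:

* divergence-form diffusion with harmonic-mean face coefficients (correct
  flux continuity across region boundaries with differing D);
* no-flux boundaries by dropped boundary-face fluxes (equivalent to mirror
  ghost nodes); 1D rings are periodic;
* fibre anisotropy through `D = d_trans I + (d_long - d_trans) f f^T`
  with a 9:1 ratio; off-diagonal tensor terms are discretised with centred
  cross-differences where the full stencil lies inside the mask (the
  shipped geometries use axis-aligned fibres, for which they vanish
  exactly);
* the forward-Euler diffusion stability bound is checked before
  integration starts;
* per-cell gating may optionally use Rush--Larsen exponential updates
  (changes stability only; the convergence test guards agreement);
* the tissue inner loop evaluates the voltage-dependent rate functions
  from per-cell-type lookup tables (0.05 mV grid, linear interpolation);
  the single-cell path is fully analytic, and the two agree to the
  calibration tolerances.

`d_iso` was calibrated once so a control RA cable conducts at 0.7 m/s, and
`d_long` so a CT cable conducts at 1.3 m/s longitudinally
(`d_trans = d_long/9`); `calibrate_diffusion()` reproduces both.

**Known numerical limitation.** At 0.33 mm the scheme under-resolves the
~1 mm sodium upstroke: conduction runs ~6-7% below the continuum limit,
and halving dx changes CV by ~6%. Scaling laws in CV (the square-root
dependence on D) are therefore verified on 0.0825 mm cables, where the
dispersion error drops below 1%; at the standard spacing the 40%-reduced
CV comes out ~0.52 m/s rather than the continuum 0.54 m/s.

## Protocols

* **APD**: level-crossing at 90% repolarisation from the beat's peak
  toward the pre-stimulus diastolic potential, linearly interpolated;
  beats whose peak stays below 0 mV count as no-AP (NaN). Standard
  measurement: 10 beats of 2 nA / 2 ms stimuli, last beat measured.
* **Restitution**: steady-state (dynamic) pacing per BCL -- chosen because
  the rate dependence is conventionally displayed against BCL -- with an
  S1--S2 variant available; lost 1:1 capture marks a point missing rather
  than failing.
* **ERP**: ten S1 at 350 ms then a premature S2; the cellular criterion
  for a regenerative response is peak V > 0 mV and max dV/dt > 10 V/s, the
  tissue criterion is activation of a probe at least 5 mm beyond the
  3.3 mm stimulus-disc edge (-40 mV upstroke crossing). Bisection to 1 ms
  is exact because capture is monotone in the coupling interval; the sweep
  method verifies this.
* **Vulnerability windows**: S1--S2 at a two-region junction with the
  stimulus disc on the interface; each coupling interval is classified
  bilateral / unidirectional / blocked from the two probes, VW_CB is the
  maximal unidirectional interval, and re-entry follow-up builds VW_R
  (structurally a subset). For efficiency the ten-beat S1 conditioning is
  computed per cell type and imposed before a final in-tissue S1 beat, so
  electrotonic interaction shapes the repolarisation gradient the S2
  probes. Vulnerability is measured in isotropic tissue to separate
  electrical from structural effects.
* **Vulnerability factor**: `F_VWR = (ERP_1 - ERP_2) / WL_2` with
  `ERP_1 >= ERP_2` and `WL_2 = CV x ERP` in the shorter-ERP region. The
  ERP gap drives unidirectional block and the wavelength sets the minimum
  re-entrant path, so the ratio indexes the likelihood that a block
  matures into re-entry; any positive multiplicative constant would cancel
  under the reference normalisation, so the simple ratio is used. It is a
  single swappable function.
* **Dominant frequency**: plain periodogram (rectangular window, mean
  removal) of at least 2 s of signal; DF is the largest peak within
  0.1--20 Hz; secondary peaks not within +-5% of an integer multiple of
  the DF are reported as non-harmonic.

## Synthetic geometries

Cables, rings and two-region junction sheets stand in for anatomically
realistic atria: the junction sheet (default 30 x 30 mm, 91 x 91 nodes)
abuts two cell types across a straight interface with a 3.3 mm stimulus
disc on it and an optional 9:1 fibre bundle strip, emulating the
CT/PM-type and LA/PV-type junction experiments; rings support
unidirectional initiation via a transient conduction-block clamp and give
re-entry cycle lengths within a few percent of the kinematic ring-length /
CV prediction. `graded_junction()` replaces the stepwise interface with a
linear per-voxel parameter blend over a stated width; the test suite
checks that grading does not materially move the vulnerable window, the
property the stepwise assumption rests on. What these substrates do *not*
capture: realistic wall geometry and curvature, fibre disorganisation,
wall-thickness variation, and the 3D wave-breakup phenomenology of whole
atria -- so tissue-level results here are demonstrations of mechanism, not
anatomical predictions.

## Problem sizes used by the tests

The test suite and acceptance script run everything at the physiological
time step (0.005 ms) but on desk-scale substrates: 200-node cables for CV
and junction scans (66 mm), 300-node rings, small sheets for symmetry and
DF checks, 5-ms vulnerability-scan resolution, and re-entry persistence
thresholds of 0.5--1.5 s (scaled-down surrogates for the 4 s criterion,
reported as such by `detect_reentry()`).

## Limitations

* The AF-1/AF-2 LA-PV dispersion sign, the dx-convergence rate of CV, and
  the collapsed/plateau bistability are model-family artefacts discussed
  above.
* Intracellular ion accumulation effects on rate dependence (NaK-pump
  mediated) are outside scope, as is any structural remodelling beyond a
  uniform diffusion reduction.
* The SR load of the calibrated base model is low (sub-millimolar uptake
  pool), so absolute Ca-transient magnitudes are small; Ca-handling
  conclusions in the package are restricted to relative, between-scenario
  comparisons, which is how the tests use them.
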