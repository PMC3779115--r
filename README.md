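# atriasim

Multiscale simulation of human atrial electrophysiology and
atrial-fibrillation (AF) electrical remodelling, for computational
cardiologists and electrophysiology modellers.

AF remodels the atrial myocyte: L-type Ca current and transient-outward
current fall, inward-rectifier K current rises, and in some data sets the
ultra-rapid K current and the Ca-handling machinery change too, while
gap-junctional remodelling slows conduction. `atriasim` packages the
standard toolchain for studying how this remodelling creates an
arrhythmogenic substrate:

* an updated Courtemanche-family human atrial myocyte model (23 state
  variables: Luo-Rudy I_Na, fast+slow I_CaL voltage inactivation,
  Nygren/Maleckar-style I_to and I_Kur, steep-rectifier I_K1, and a
  two-compartment sarcoplasmic-reticulum Ca handling system with
  peripheral/interior cytosolic compartments);
* a calibrated family of regional cell variants (crista terminalis,
  pectinate muscle, appendages, septum, Bachmann's bundle, left atrium,
  pulmonary veins) expressed as conductance-scaling tables;
* five remodelling scenarios (`AF0`-`AF4`) applied as parameter
  transforms — e.g. `AF4`: I_CaL −70%, I_to −65%, I_K1 +100%, I_Kur −50%,
  I_Ks +100%, NCX +55%, SERCA +50%, RyR +300%, SR leak +25%, plus a 40%
  diffusion reduction;
* a monodomain reaction–diffusion solver (`dV/dt = ∇·(D∇V) − I_ion/C_m`,
  centred differences, forward Euler at 0.005 ms, harmonic-mean face
  coefficients, 9:1 fibre anisotropy) on synthetic cables, rings and
  two-region junction sheets;
* the analysis protocols: APD90 and restitution, effective refractory
  period (ERP), conduction-velocity measurement and calibration, S1–S2
  vulnerability-window scanning (unidirectional block VW_CB and re-entry
  VW_R, with the junction vulnerability factor
  `F_VWR = (ERP₁ − ERP₂)/WL₂`), re-entry detection, and dominant-frequency
  mapping in the 0.1–20 Hz band.

The science, every equation-level choice, and the calibration procedure
are documented in the methods vignette
(`vignettes/atrial-model-methods.Rmd`).

## Worked example

Pace the control right-atrial cell and an AF-remodelled counterpart, then
measure a cable conduction velocity:

```r
library(atriasim)

p_ctrl <- channel_params()
p_af4  <- apply_af(p_ctrl, "AF4")

apd_ctrl <- measure_apd(pace_cell(p_ctrl, bcl = 1000, n_beats = 10))
apd_af4  <- measure_apd(pace_cell(p_af4,  bcl = 1000, n_beats = 10))
cat(sprintf("APD90 control %.1f ms, AF-4 %.1f ms (%.0f%% reduction)\n",
            apd_ctrl, apd_af4, 100 * (1 - apd_af4 / apd_ctrl)))
#> APD90 control 243.7 ms, AF-4 118.7 ms (51% reduction)

cv <- measure_cv(make_cable(200), "CONTROL")
cat(sprintf("cable conduction velocity %.2f m/s\n", cv$cv))
#> cable conduction velocity 0.70 m/s
```

The control APD90 of ~244 ms and the ~51% AF-4 shortening are the model's
calibrated operating point; 0.70 m/s is the calibrated conduction-velocity
target of the isotropic right-atrial wall. A vulnerability scan on a
two-region junction cable:

```r
jc <- make_cable(200, region_layout = list(PM = 1:100, CT = 101:200))
scan_s1s2(jc, "CONTROL", ci_range = c(200, 300), ci_step = 5)
#> <vw_result> scenario CONTROL
#>   ERP CT = 255 ms, ERP PM = 225 ms, WL_2 = 157.4 mm
#>   VW_CB: [225, 250] ms
#>   VW_R:  empty
#>   F_VWR: 0.191
```

Premature beats in the 225–250 ms coupling window conduct into the
pectinate-muscle side but block toward the longer-APD crista terminalis —
the unidirectional block that seeds re-entry at real atrial junctions.

A command-line wrapper over the same functions is installed at
`inst/cli/atriasim` (subcommands `cell`, `params`, `cv`, `make-geom`,
`vw`, `run`, `calibrate`).

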