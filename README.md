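# idplink

Linking the monomer conformation of an intrinsically disordered protein
to its aggregation propensity.

Disease-associated single-point mutants of a disordered protein can
differ sharply in how fast they form amyloid fibrils and how readily
they phase-separate, while their monomer structures differ only subtly.
`idplink` implements the quantitative chain needed to test the
conformational hypothesis behind that observation: it measures monomer
expansion and interactions from scattering and ion-mobility data,
measures aggregation and phase behaviour from plate-reader data, and
correlates the two across conditions.

The stages, each exposed as package functions:

| stage | what it computes | core model |
|---|---|---|
| `saxs_reduce` | frame QC, averaging, buffer subtraction | chi-squared distance, 2-sigma single-pass rejection |
| `guinier_rg` | radius of gyration Rg | window-scanned Guinier histogram: all windows of `ln I` vs `q^2`, count-weighted average |
| `fit_mff` | Flory exponent nu | generalized Debye form factor `P(q)` via lower incomplete gamma; reduces exactly to the Debye function at nu = 1/2 |
| `fit_virial` | second virial coefficient A2 | `K c / I(0,c) = 1/Mw + 2 A2 c` on UV-paired SEC-SAXS forward intensities |
| `fit_sigmoid` | aggregation halftime | `s(t) = F / (1 + exp(-k (t - t_half)))` per replicate |
| `determine_csat` | LLPS saturation concentration | t-test ladder against a pooled 0-12 uM baseline, lowest `p < 0.05` |
| `ccs_pipeline` | reduced mobility, t0, CCS | `tA = t0 + L^2/(K dV)` step-field regression + Mason-Schamp |
| `regress` / `elbow_k` | cross-condition layer | OLS with recorded exclusions; k-means elbow (max second difference of WCSS) |

A synthetic-data module (`debye_profile`, `saw_ensemble` -- a
pivot-algorithm self-avoiding-walk sampler with compiled inner loops --
`scattering_from_ensemble`, `sec_saxs_series`, `tht_traces`,
`llps_plate`, `ims_arrival`) generates inputs with the exact
statistical structure each stage assumes, each with a ground-truth
sidecar, so the whole chain is testable offline.

## Worked example

Generate an ideal-chain scattering curve, recover Rg two ways, then run
a full synthetic step-field CCS measurement:

```r
library(idplink)

q <- seq(0.005, 1, length.out = 200)           # nm^-1
p <- debye_profile(rg_nm = 4, i0 = 1, q_grid = q)

guinier_rg(p)
#> <guinier_result> Rg = 3.929 +/- 0.040 nm (I0 = 0.9991, 630 windows)

fit_mff(p)
#> <flory_fit> nu = 0.500, Rg = 4.000 nm, I0 = 1 (red. chi2 3.6e-28)

inst <- ims_instrument(charge = 10, ion_mass_da = 20570)
sf <- ims_arrival(k0_cm2_vs = 1.0, t0_ms = 2.0,
                  voltages = c(400, 500, 600, 700, 800),
                  instrument = inst)
ccs_pipeline(sf)
#> <ccs_result> K0 = 1 cm2/V/s, t0 = 2 ms, CCS = 5369 A^2 (+/- 2.0%)
```

The Guinier histogram recovers the true Rg = 4 nm to 1.8% with a narrow
window distribution (the small deficit is the documented truncation bias
of Guinier windows on an ideal-chain curve); the form-factor fit returns the theta-solvent
exponent nu = 0.50 exactly on ideal-chain data; and the step-field
round trip reproduces the generating mobility and dead time, giving a
Mason-Schamp cross section of 5369 Angstrom^2 for this 20570 Da, 10+
ion in helium at 297 K.

## The analysis workflow

Numbered drivers under `analysis/` run a complete synthetic study and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # six conditions + all instrument data
Rscript analysis/02_conformation.R   # Guinier Rg + Flory nu per condition
Rscript analysis/03_virial.R         # A2 from the SEC-SAXS elution
Rscript analysis/04_kinetics_llps.R  # halftimes + Csat
Rscript analysis/05_ccs.R            # step-field CCS
Rscript analysis/06_correlate.R      # halftime-vs-Rg regression + elbow check
```

Each script states what it found; for example `03_virial.R` prints the
recovered `A2 = 4.6e-4 +/- 0.9e-4 cm^3 mol g^-2` against the generating
`5e-4` (repulsive, as constructed), and `04_kinetics_llps.R` reports the
24 uM turbidity onset and flags the non-aggregating reference condition
as "no aggregation observed". `run_pipeline()` performs the same
composition programmatically over any directory in these formats.

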