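# dscbezier

Bezier-constrained residue-function deconvolution and oxygen extraction
modelling for dynamic susceptibility contrast (DSC) MRI.

## What this is for

DSC-MRI tracks a gadolinium bolus through the brain with fast
T2\*-weighted imaging. Deconvolving the tissue concentration curve
$C_m(t)$ with the arterial input function $C_a(t)$ under the
tracer-kinetic model

$$k_H\,C_m(t) = \mathrm{CBF}\,\big[R(t) \otimes C_a(t-\delta)\big]$$

yields the tissue residue function $R(t)$ — the fraction of tracer still
in the voxel a time $t$ after arrival — plus the flow scale CBF and the
arterial bolus delay $\delta$. Standard SVD-style deconvolution returns
oscillating, partly negative $R(t)$; this package instead parameterises
$R(t)$ as a constrained cubic Bezier curve (control points
$(0,1)$, $(p_{1x},p_{1y})$, $(p_{2x},p_{2y})$, $(t_{end},0)$ under
ordering constraints), which guarantees $R(0)=1$, monotone decrease and
$R \ge 0$ by construction. From the fitted curve it computes, per voxel
and as whole-brain summaries:

* **MTT** $= \int R(t)\,dt$ (mean transit time),
* **CTH** $= \int (t-\mathrm{MTT})^2\,h(t)\,dt$ with
  $h = -dR/dt$ (capillary transit time heterogeneity),
* **$\delta$**, the arterial bolus delay (inversely related to arterial
  velocity),
* **AOEF** $= \int h(\tau)\,Q(\tau)\,d\tau$, an apparent oxygen
  extraction fraction index, where $Q(\tau)$ is the extraction along a
  single capillary of transit time $\tau$ from a three-compartment
  oxygen transport ODE
  ($dC/dx = -k\tau\,\alpha_H[P(C) - pO_2]$, Hill-equilibrium plasma
  tension $P$).

It also ships the paired-cohort statistics used to compare two
physiological states (normal breathing vs hyperventilation: paired t,
exact Wilcoxon signed-rank by full sign enumeration, Shapiro–Wilk,
Bonferroni gating, regressions against ETCO2), an eight-subject paired
reference table as a packaged fixture, and a synthetic phantom generator
(gamma-variate AIF, known residue functions, baseline-SNR-controlled
noise) so the entire pipeline is testable without any MRI data.

Intended users: perfusion MRI researchers who want physiologically
plausible residue functions and transit-time-based oxygenation indices,
and anyone needing a fully reproducible, self-contained DSC analysis
chain for method studies.

## Worked example

```r
library(dscbezier)

## paired cohort analysis of the packaged eight-subject table
tab <- cohort_table()
change_summaries(tab)[, c("parameter", "mean_n", "mean_h",
                          "pct_change_subject", "pct_change_of_means")]
#>   parameter  mean_n  mean_h pct_change_subject pct_change_of_means
#> 1       mtt  3.7550  4.9912              33.45               32.92
#> 2      aoef 22.5375 29.0000              29.58               28.67
#> 3       snr 34.4875 24.1750             -27.70              -29.90
#> 4     delta  0.4932  0.8051             128.84               63.23

paired_t_test(tab$mtt_n_s, tab$mtt_h_s)$p        # 0.0049
wilcoxon_signed_rank_exact(tab$delta_n_s, tab$delta_h_s)$p  # 0.0078125
```

Whole-brain MTT rises from 3.76 s to 4.99 s under hyperventilation (a
33% mean per-subject increase), AOEF rises ~30%, venous baseline SNR
falls ~28%, and the arterial delay lengthens by 63% in the ratio of
means — all significant at the Bonferroni-corrected level
$\alpha/4 = 0.0125$.

```r
## deconvolution of a synthetic voxel with known ground truth
acq <- acquisition_config()            # 46 frames @ 1.65 s, TE 54 ms
aif <- gamma_variate_aif(default_times <- (0:45) * 1.65)
truth <- linear_residue(3.8)           # MTT 3.8 s
tissue <- forward_model(truth, cbf = 0.012, delta = 0.5, aif, acq)
fit <- fit_voxel(tissue, aif, acq)
fit
#> Deconvolution fit: CBF = 0.012, delta = 0.500 s, MTT = 3.800 s, ...

## oxygen extraction index under the two blood-gas presets
aoef(linear_residue(3.8), condition_presets("normal_breathing"))   # 34.5
aoef(linear_residue(4.99), condition_presets("hyperventilation"))  # 38.8
```

The AOEF numbers are an index on a 0–100 scale whose absolute level
depends on the assumed arterial inlet oxygenation (documented defaults:
saturation 1.0, plasma pO2 250 mmHg under FiO2 = 0.5); ordering and
relative changes are the meaningful outputs.

The full voxel-wise pipeline (`run_pipeline()`) takes a 4D NIfTI volume,
a brain mask and an AIF series, and produces MTT/CTH/AOEF/delay/CBF/CBV
maps plus the whole-brain summary (delay averaged after scaled-MAD
outlier removal). `build_phantom()` generates matching synthetic inputs
with per-voxel ground truth. A thin command-line wrapper with `sim`,
`fit`, `summary`, `snr` and `cohort` subcommands is installed at
`inst/scripts/dscbezier-cli.R`.

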