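# cardiodti

Motion-compensated cardiac diffusion MRI at desk scale: gradient-moment-nulled
waveform design, physics-based simulation of diffusion-weighted signals from
moving synthetic phantoms, and diffusion-tensor / ADC reconstruction with the
region and group statistics used to detect myocardial injury.

## The problem

Diffusion encoding is exquisitely sensitive to motion: a conventional
Stejskal–Tanner gradient pair nulls only the zeroth gradient moment
m<sub>0</sub>, so the velocity and acceleration of the beating myocardium
accrue phase through the nonzero m<sub>1</sub> and m<sub>2</sub>, and the
spread of velocities within a voxel dephases the signal to nothing — the
heart disappears from the diffusion-weighted image. Nulling the moments
through second order (m<sub>0</sub> = m<sub>1</sub> = m<sub>2</sub> = 0,
"M012") makes the encoding invariant to rigid motion while keeping its
diffusion weighting, enabling quantitative cardiac diffusion tensor imaging
(DTI) in small animals. Myocardial injury (edema, infarction) then shows up
as an elevated apparent diffusion coefficient (ADC).

The package implements, for an audience of MR-physics and preclinical
imaging researchers:

* **Waveform design** under amplitude/slew limits (defaults 440 mT/m,
  3440 T/m/s): Stejskal–Tanner (M0), velocity-compensated (M01) and
  second-order motion-compensated (M012) designs built from
  finite-difference lobe patterns — e.g. effective amplitudes
  (1, −3, 3, −1)/3 for M012 — whose discrete moments
  m<sub>n</sub> = Σ G<sub>eff</sub>(t<sub>k</sub>) t<sub>k</sub><sup>n</sup> Δt
  cancel identically; b = ∫|q(t)|² dt is integrated numerically and matched
  to the target exactly by amplitude scaling.
* **Signal simulation**: S = S₀ exp(−b gᵀDg) per voxel, plus the bulk-motion
  phase γ(m₀r₀ + m₁v + ½m₂a)·g and Gaussian intravoxel dephasing
  exp(−½γ²m₁²σ<sub>v</sub>²), with seeded Rician noise.
* **Phantoms**: a six-vial PVP dilution series (ADC 1.37–2.21 ×10⁻³ mm²/s),
  a short-axis cardiac annulus with transmural fiber helix (+60° → −60°) and
  ring/sector injury regions, and seeded cohorts with between-subject
  variability.
* **Reconstruction**: voxel-wise log-linear least-squares tensor fit from
  ≥6 directions + b0, eigenvalues, ADC = trace/3 and FA maps, ROI
  statistics; NIfTI + FSL-style `.bval`/`.bvec` I/O.
* **Cardiac & group statistics**: Simpson-disk LV volumes and ejection
  fraction, hematocrit-corrected ECV from T1 panels, and Shapiro-Wilk-routed
  group comparison (Welch t / ANOVA / Mann-Whitney / Kruskal-Wallis with
  Bonferroni post-hocs).

## Worked example

Design the M012 encoding, image a chronic-infarction phantom at SNR 25, and
compare simulated control and injury cohorts:

```r
library(cardiodti)

wf <- design_motion_compensated(encoding_spec(b_target = 350, nulling_order = 2))
wf
#> <gradient_waveform> 1778 samples, dt = 10 us, duration = 17.780 ms
#>   peak |G| = 439.5 mT/m, refocus at sample 890
#>   b = 350 s/mm^2, m0 = 5.2e-23 T.s/m, m1 = -5.17e-22 T.s^2/m, m2 = -8.92e-24 T.s^3/m

inf <- infarct_experiment(infarct_md = 1.735e-3, remote_md = 1.484e-3,
                          snr = 25, seed = 1)
inf$roi[, c("region", "n_voxels", "mean", "sd")]
#>       region n_voxels     mean        sd
#> 1     cavity       96 2.979494 0.1754986
#> 2 myocardium      204 1.496966 0.1462399
#> 3     injury       68 1.710988 0.1690560

cohort_experiment(seed = 2)$comparison
#> <group_comparison>
#>   control      n =  5, mean = 1.52, sd = 0.09831
#>   injury       n = 23, mean = 1.803, sd = 0.2708
#>   t (Welch) test: statistic = -3.948, p = 0.0008789 (significant at 0.05)
```

The waveform's three moments sit at floating-point cancellation level
(~10⁻²² T·s/m) — the encoding is motion-invariant — and its integrated
b-value is exactly 350 s/mm². The infarct ROI recovers its generating ADC
(1.735 ×10⁻³ mm²/s) within noise, the remote wall recovers 1.484, and the
cohort comparison flags the injury group's ADC elevation. ADC values are
reported in 10⁻³ mm²/s throughout.

`motion_demo()` reproduces the qualitative hallmark of uncompensated cardiac
DWI: with a 10 mm/s intravoxel velocity spread the M0 encoding retains
~10⁻³⁹ of the myocardial magnitude (the heart is invisible) while M012
retains 100%.

## Command line

```sh
Rscript inst/cli/cardiodti.R design --b 350 --order 2 --gmax 0.44 --slew 3440 --out wf.csv
Rscript inst/cli/cardiodti.R simulate --phantom cardiac --snr 25 --seed 1 --out-dir out/
Rscript inst/cli/cardiodti.R reconstruct --in out/dwi --out-dir out/
Rscript inst/cli/cardiodti.R roistats --map out/adc.nii.gz --labels out/labels.nii.gz --out roi.csv
Rscript inst/cli/cardiodti.R run --config experiment.json --out-dir out/
```

`run` executes a canned experiment (`pvp`, `infarct`, `injury-cohort`,
`motion-demo`) from a JSON config and writes ROI CSVs, summary JSON, NIfTI
maps and a log file, fully seeded.

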