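# nprm: non-parametric residue mapping and multiple-injection kinetic analysis for dynamic PET

`nprm` is a simulation and analysis toolkit for voxel-level kinetic
mapping of dynamic positron emission tomography (PET) studies, with a
focus on a practical question in multi-tracer and repeat-injection
imaging: **how much is gained by pooling ("combining") the data from
several injections into one kinetic fit, instead of analysing each
injection separately?**

It is aimed at researchers in PET quantification and imaging statistics
who want a self-contained, fully synthetic environment in which the
combined-versus-separate question — and the behaviour of non-parametric
kinetic mapping in general — can be studied end to end: source
generation, tomographic (or deconvolution-type) scanning, Poisson count
sampling, reconstruction, voxel fitting and error meta-analysis.

## The model

Indicator-dilution theory writes a tissue time-activity curve as a
convolution of the arterial input function C_p with the tissue residue
R(t) — a non-negative, monotone non-increasing function whose value
R(0) is the tissue flow. The package represents residues
non-parametrically as piecewise-linear functions and maps kinetics via
the additive decomposition over the scan interval [0, T_E]

    R(t) = R_B(t) + R_D(t) + R_E(t)

into vascular (transit bounded by T_B, default 15 s), in-distribution
and extracted components, yielding

    V_B = ∫ R_B ,  V_D = ∫ R_D ,  K_D = R_D(0) ,  K_i = R_E(0) ,
    K_1 = K_D + K_i ,  extraction = K_i / K_1 ,  MTT = V_D / K_D + Δ .

Voxel fitting follows the NPRM (non-parametric residue mapping) scheme:
the image is segmented into clusters of approximately proportional time
courses; each segment mean is modelled as a delayed residue
convolution, an injection-site signal, or a distribution function
(monotone constraints imposed by non-negative least squares in a
cumulative parameterisation); cross-validation-guided backwards
elimination prunes the modelled curves plus per-injection AIF ("spike
residue") and integrated-AIF ("Patlak") supplements into a sub-TAC
basis X; and each voxel time course z is fit as z ≈ Xα with α ≥ 0, the
voxel residue being the corresponding non-negative combination of the
basis residues.

For a kinetic parameter estimated from J injections, Gaussian theory
gives the variance-pooling ratio

    MSE(combined) / MSE(separate_j) = σ_j^-2 / (σ_1^-2 + … + σ_J^-2) ≤ 1 ,

equal to 1/J for replicate designs — so percent improvement grows like
(J − 1). The simulators let you check this against full scanned,
reconstructed and refit studies: a 1-D Poisson deconvolution scanner
(kernel |ν|^-β, β = 1.35, with exact FBP-analogue inversion and
IRLS maximum-likelihood reconstruction) and a 2-D attenuated
parallel-beam Radon scanner (128×128 image, 183×181 sinogram, filtered
backprojection).

## A worked example

A repeat-water study with J = 2 injections at the reference dose:
simulate, reconstruct by FBP with a study-wide bandwidth selected on
the total-uptake image, fit every voxel combined and separately, and
summarise the weighted source error over replicates:

```r
library(nprm)
design <- make_study("repeat_h2o", dose = 1, ratio_or_J = 2,
                     N_R = 15, seed = 11)
cell <- run_mse_cell(design)
cell$summary
#> MSE_C = 2.005e-05 (SE 3.5e-07), MSE_S = 3.136e-05 (SE 4.6e-07),
#> improvement = 56.40% (SE 2.4)
```

`MSE_C` and `MSE_S` are the replicate means of the duration- and
intensity-weighted integrated squared error of the combined and
separate source estimates; the improvement (MSE_S/MSE_C − 1) × 100 is
the headline benefit of pooling, here ≈ 56% for two injections —
consistent with the theory's bound of up to 100% for J = 2 once
reconstruction bias is accounted for. Across J ∈ {2, 4, 6, 8}
(`run_repeat_h2o_experiment()`) the improvement is almost exactly
proportional to J − 1.

The dose economics come from the decay of reconstruction error with
dose τ:

```r
dm <- run_dose_mse_experiment(N_R = 100, seed = 1)
dm$gamma_tau
#> [1] 0.4402750
dose_equivalence(0.10, 0.42)
#> [1] 25.47408
```

so uptake MSE falls like τ^-0.44 in this configuration, and at an
exponent of 0.42 a 10% MSE improvement from combined analysis is worth
about a 25% dose increase.

## Package layout

- `R/frame-schedule.R`, `R/curves.R`, `R/residue.R`, `R/convolve.R` —
  acquisition schedules, sampled curves, piecewise-linear residues,
  decomposition/summaries, convolution and the two-compartment
  reference model.
- `R/nprm-segment.R`, `R/nprm-subtac.R`, `R/nprm-basis.R` — the NPRM
  pipeline (segmentation, sub-TAC modelling, basis selection, voxel
  fitting, kinetic mapping).
- `R/scanner1d.R`, `R/scanner2d.R` — the scanning simulators and
  reconstructions.
- `R/aif.R`, `R/phantom.R` — synthetic input functions, phantoms,
  source models and study designs.
- `R/evaluation.R`, `R/experiments.R` — combined/separate estimation,
  error assessment, MSE summaries, the theoretical ratio,
  meta-regressions, and the replicate experiment drivers.

The methods vignette (`vignettes/nprm-methods.Rmd`) documents the
modelling choices, defaults and limitations in detail.
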