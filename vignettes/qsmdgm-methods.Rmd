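---
title: "Methods: susceptibility mapping of deep grey matter and its statistical battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: susceptibility mapping of deep grey matter and its statistical battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`qsmdgm` implements, on fully synthetic data, the computational chain used to
study deep grey matter (DGM) magnetic susceptibility in multiple sclerosis:

1. dipole-physics phantoms and multi-echo complex GRE signal synthesis;
2. QSM reconstruction by multi-echo complex total field inversion (mTFI)
   with gradient-weighted total-variation (TV) regularization;
3. ROI metrics: CSF-referenced regional susceptibility means, head-size
   normalized volumes, lesion-filtered total lesion volume (TLV);
4. cohort simulation with configurable standardized effects;
5. the statistical battery: Spearman correlation matrix, per-region multiple
   regressions with standardized coefficients, variance-inflation screening,
   Freedman–Lane permutation p-values, and FDR correction grouped by outcome.

No real patient data are used anywhere; every stage is driven by the
package's own generators so that all downstream claims are testable against
known ground truth.

# Forward model

## Dipole physics

Susceptibility `chi` (ppm) induces a Lorentz-corrected field perturbation
given in k-space by `f = IFT(D * FT(chi))` with the unit dipole kernel

$$D(k) = \tfrac{1}{3} - \frac{(k \cdot \hat b_0)^2}{|k|^2}, \qquad D(0) = 0.$$

The `D(0) = 0` convention fixes the arbitrary constant: every forward field
has zero spatial mean, and any physical offset is deferred to the CSF
referencing step. The canonical validation is a uniform sphere, whose field
is zero inside and a pure dipole outside; on the default 64³ grid the
interior RMS is about 0.3% of the susceptibility difference and the
exterior matches the closed form to about 2% (RMS, relative to the local
dipole amplitude) in the shell two to three radii out. Beyond three radii
the periodic images of the FFT convolution dominate the comparison, which
is why the validation shell stops there.

## Signal model

Per voxel and echo,

$$S_j = m\, e^{-R_2^* TE_j}\, e^{i(\phi_0 + 2\pi \bar\gamma B_0 f_{ppm} 10^{-6} TE_j)} + \varepsilon_j,$$

with `gamma-bar = 42.577 MHz/T`, B0 = 3 T, and i.i.d. complex Gaussian noise
per echo and voxel. The default protocol has six monopolar echoes with
first TE 6 ms and spacing 6.4 ms, TR 41.75 ms, flip angle 20°. Noise is
white across echoes and voxels, an idealization of parallel-imaging
reconstructions whose noise is in reality spatially correlated; `noise_sigma`
is quoted as a fraction of the maximum magnitude, so `noise_sigma = 0.02`
corresponds to SNR 50 in the brightest tissue.

## Phantom geometry

The four DGM structures are ellipsoids — the simplest shapes with analytic
volumes, which makes voxelization testable — inside a spherical brain with a
CSF shell (susceptibility 0, low R2*) near the brain boundary, plus a few
small ellipsoidal lesions. Structure susceptibilities default to the mean
values reported for a large MS cohort (thalamus −0.008, caudate 0.042,
putamen 0.050, pallidum 0.099 ppm) with R2* increasing with iron content
(25–50 1/s). Axes are RAS-like with B0 along +z; this convention lives in
`grid_spec()` and nowhere else. What the phantom does *not* emulate:
realistic anatomy, partial-volume gradients, flow, or coil sensitivities —
so passing reconstruction tests demonstrates correctness of the inversion,
not clinical image quality.

# Reconstruction

## Objective

mTFI estimates susceptibility over the *whole field of view* directly from
the complex multi-echo data; background sources outside the brain are part
of the unknown rather than removed in a separate step. The committed
objective is a magnitude-weighted complex-exponential misfit summed over
echoes,

$$\sum_j \big\| m e^{-R_2^* TE_j}\big(e^{i\theta_j(\chi)} - e^{i\angle S_j}\big) |S_j|/\max|S| \big\|_2^2 + \lambda_{tv} \|M_G \nabla \chi\|_1,$$

with $\theta_j(\chi) = \phi_0 + 2\pi\bar\gamma B_0 (D*\chi) 10^{-6} TE_j$.
The per-axis binary edge masks $M_G$ exempt from the TV penalty the ~30%
strongest gradients of the echo-time-weighted magnitude
$W = \sum_j TE_j |S_j| / \sum_j TE_j$ (70th-percentile threshold within the
brain mask). Binary masks were chosen over continuous weights because their
behaviour is directly assertable (the zero fraction equals one minus the
percentile). A guard band of 1e-9 (relative) above the threshold keeps the
mask stable when many gradient values tie exactly, as they do on
piecewise-constant phantoms.

## Optimization

The problem is non-convex; it is solved by block-alternating updates:

* `m`, `R2*` — fitted once, by log-linear regression on the echo
  magnitudes. They enter the data term only as weights, so refitting them
  inside the loop would not change the minimizer over `chi` and would open a
  degenerate `m -> 0` path.
* `phi0` — closed-form per-voxel minimizer, recomputed every outer
  iteration.
* `chi` — one Gauss–Newton step per outer iteration, with the TV term
  handled by iteratively reweighted least squares (IRLS) and the linear
  system solved by preconditioned conjugate gradients (CG).

Three numerical choices matter and were fixed after profiling on the
default phantom:

1. **IRLS floor.** The objective smooths the TV term with
   `eps_tv = 1e-6` ppm, but the IRLS weights use a larger floor
   `eps_irls = 1e-4` ppm. With weights at `1/eps_tv`, flat regions
   contribute a ridge six orders of magnitude above the data term and the
   Gauss–Newton systems become so stiff that the iteration stalls at ~25%
   ROI underestimation. The floor conditions the *surrogate* only; descent
   is always measured on the `eps_tv` objective.
2. **k-space preconditioner.** CG iterations use the diagonal (in k-space)
   preconditioner $c_1 D(k)^2 + c_2 L(k) + \delta$, where $L$ is the
   discrete Laplacian symbol and $c_1, c_2$ track the mean data and TV
   weights. Without it the modes near the dipole null cone converge so
   slowly that ROI means stay ~25% low at any practical iteration count;
   with it the linear initializer alone recovers ROI means to a few
   percent.
3. **Monotone line search.** Every `chi` step is accepted only if the true
   (`eps_tv`) objective does not increase, with backtracking halving. The
   logged objective is therefore non-increasing by construction, which the
   tests assert on every run.

The initializer is a preconditioned total field inversion: the same TV
machinery applied to the linear problem
$\|w (f_{ppm} - D*\chi)\|_2^2 + \lambda \|M_G \nabla \chi\|_1$ over the full
FOV, with the substitution `chi = P y` where `P` is 1 inside the brain and
`preconditioner_scale = 30` outside, reflecting the orders-of-magnitude
stronger air/bone sources there. The per-voxel field `f` comes from a
magnitude-squared-weighted linear fit to temporally unwrapped echo phases
(greedy nearest-2π per voxel from echo 1; no spatial unwrapping — the
complex-domain data term makes residual wraps non-critical at these echo
times and field strengths).

## Regularization weights

`lambda_tv = 2e-5` (mTFI) and `lambda_tv_init = 1e-4` (initializer) were
chosen once by an L-curve-style sweep on the default noiseless 64³ phantom
and then frozen; they are not tuned per input. On that phantom the full
chain recovers every DGM ROI mean within 0.003 ppm noiselessly and within
0.008 ppm at SNR 50 (about 2.2 minutes per reconstruction at 64³ on one
CPU with default iteration counts: 5 initializer and 10 mTFI outer
iterations, 60 CG iterations each).

## Degenerate inputs and edge cases

Voxels with a zero echo magnitude are excluded from the fit mask and given
zero fidelity weight. An empty CSF mask produces an unreferenced map with
an explicit flag and warning rather than an error. A non-finite objective
aborts with the diagnostic log attached. Susceptibility is only determined
up to a constant; `csf_reference()` subtracts the CSF-mask mean, making ROI
values relative to CSF (exactly zero mean over the mask, by construction).

Reconstruction is deterministic: no stage draws random numbers, and
repeated runs are bit-identical. Invariance to a global receiver phase
offset holds to solver precision: with converged inner CG the
reconstruction changes by ~3e-6 ppm pointwise and ~3e-7 ppm in ROI means —
the residual reflects conditioning of the near-null dipole-cone modes at
double precision, not a modelling asymmetry.

# ROI metrics

Regional susceptibility is the arithmetic voxel mean over each label.
Volumes are corrected for head size as `raw / TIV * mean(TIV)`, which keeps
an intuitive mL scale. Lesions are filtered by 26-connected components
(matching the behaviour of common lesion tools; the choice is a convention)
with an inclusive 15 mm³ survival threshold — the volume of a 3 mm-diameter
sphere, the usual minimum reportable lesion. TLV is log-transformed with a
+0.01 mL offset so lesion-free subjects stay defined; the offset is
configuration, not measurement.

# Cohort simulation

## Construction

Covariates, regional susceptibilities, volumes and TIV are driven by a
12-dimensional Gaussian copula whose default correlation matrix encodes the
qualitative structure of MS cohorts: strong age–susceptibility correlations
in the basal ganglia (0.50–0.63), negative age–volume correlations,
moderate inter-regional correlations, mild same-region
susceptibility–volume coupling, and a TIV–sex association. The matrix is
eigenvalue-clipped to the nearest positive-definite correlation matrix and
the *realized* matrix is what the generator reports and tests compare
against. Marginals use the cohort means and standard deviations reported
for a large MS population (e.g. age 40 ± 11 years, 35.7% male, pallidum
0.099 ± 0.028 ppm). The joint distribution of a real cohort is not known
beyond such summaries, so all of this is configuration, not a fidelity
claim.

Baseline outcomes are built on the standardized (z) scale: the injected
standardized effects multiply the latent z-scores (sex enters as its 0/1
indicator), and the residual standard deviation is set from the analytic
signal variance so each outcome has unit latent variance — which is what
makes an injected coefficient directly comparable to the standardized
coefficient a refit recovers. If injected effects leave no residual
variance the generator refuses. Follow-up clinical outcomes are
`autocorrelation * baseline + injected longitudinal effects + noise`
(empirical variance calibration, floored so `autocorrelation = 1` stays
valid), with per-outcome availability fractions defaulting to the
differential follow-up rates of clinical scores (51% for EDSS down to 21%
for SDMT) and follow-up intervals uniform on 1–4.7 years. Clinical scores
are simulated as continuous Gaussians; the ordinal 0.5-step structure of
disability scales is deliberately not modelled, because the downstream
models treat outcomes as continuous responses.

## What injection means

The default effect map reproduces the pattern of reported cross-sectional
associations (caudate-EDSS 0.19, basal-ganglia effects on lesion volume,
dexterity and processing speed; volume effects on brain volume and
disability), and the default longitudinal map gives prognostic value to
thalamic and caudate volume but none to susceptibility. One subtlety: the
battery fits *per-region* models, so when effects are injected in several
correlated regions at once, a region's fitted coefficient includes
contributions from the omitted regions' effects (omitted-variable
arithmetic, about +0.06 for caudate-EDSS under the defaults). Recovery
checks therefore inject a single effect at a time; with the full default
map the per-region coefficients are expected to sit above their injected
values, which is a property of the model family, not a bias of the
estimator.

# Statistical battery

Model 3 of the analysis family enters a region's susceptibility and volume
together with age, sex and disease duration; the longitudinal version adds
the baseline outcome and the follow-up interval. Four regions by seven
baseline outcomes (five clinical scores, normalized brain volume, log TLV)
give 28 cross-sectional models; four regions by five clinical outcomes give
20 longitudinal models. Continuous variables are z-scored per model on its
complete cases; sex stays 0/1 (coefficients read as female-to-male
contrasts). Constant columns (for instance a degenerate follow-up interval)
are dropped from the design and flagged rather than crashing the battery.

Permutation inference uses the Freedman–Lane scheme: for each tested term,
residuals of the reduced model are permuted and added back to the
reduced-model fit, the full model is refit to each permuted response, and
the two-sided p-value is `(1 + #{|t*| >= |t|}) / (1 + B)`. This keeps
nuisance covariates' contributions intact under permutation and is
close-to-exact when residuals are exchangeable. The study default is
B = 10000; the test-suite and acceptance runs use B = 500 (p-value
granularity 1/501), a scaled-down setting chosen for iteration speed and
documented here as such. Calibration: under a pure-null cohort the
empirical rejection rate at the 5% level over 1000 replicates falls inside
the binomial band [0.036, 0.064].

FDR correction is Benjamini–Hochberg applied *within each group of models
sharing an outcome*, over the susceptibility and volume terms of the four
regional models (eight p-values per group); cross-sectional and
longitudinal families are corrected separately, and nuisance terms carry no
q-value. The Spearman matrix uses average ranks, pairwise-complete
observations, t-approximation p-values and BH across the upper triangle.
VIF screening (`1/(1 - R_k^2)`) reports perfect collinearity as infinite
with a flag so a screening loop can name the offender.

# Problem sizes and determinism

Default test-suite sizes were chosen so that each stage demonstrates its
property at the smallest size that exercises it: 32³ voxels at 2 mm for
reconstruction unit tests, 64³ at 1 mm for the physics and recovery
acceptance checks, cohorts of 150–771 subjects, 100–500 permutations
(10000 remains the analysis default). The latent-correlation convergence
check runs at n = 20000, where the sampling error of the empirical matrix
(~0.007 per entry) sits well below the ±0.03 assertion band; at n = 5000
the max-entry sampling error alone would straddle the band.

Every stochastic stage takes an explicit seed; the pipeline derives all
stage seeds from one global seed, and a full run is bit-reproducible from
it (asserted down to artifact file checksums). Reconstruction is
deterministic independent of seeds.

# Known limitations

* Ellipsoid phantoms have no partial-volume ramps; real DGM boundaries blur
  susceptibility contrast, so real-data ROI errors will exceed the phantom
  figures.
* The white-noise signal model ignores coil correlations and k-space
  undersampling artifacts.
* Greedy temporal unwrapping fails above ~78 Hz inter-echo offsets at the
  default spacing; strong background fields near air cavities can exceed
  this at 3 T, which the synthetic backgrounds do not.
* Clinical outcomes are continuous Gaussians; ordinal effects (floor and
  ceiling behaviour of disability scores) are absent.
* The exact objective of the reference mTFI implementation is not public;
  the magnitude-weighted complex misfit above is this package's committed
  definition, consistent with the cited nonlinear dipole-inversion family.
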