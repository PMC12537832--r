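# qsmdgm

Quantitative susceptibility mapping (QSM) of the deep grey matter (DGM) and
the statistics used to relate it to clinical severity in multiple sclerosis
— as a fully synthetic, fully testable R pipeline.

## The problem

Iron accumulation in the basal ganglia and myelin/iron loss in the thalamus
change tissue magnetic susceptibility χ (ppm), which QSM reconstructs from
the phase of multi-echo gradient-echo MRI. Cohort studies then ask whether
regional DGM susceptibility explains disability scores and MRI surrogates
(brain volume, lesion volume) beyond regional atrophy, age, sex and disease
duration — and whether baseline susceptibility predicts clinical outcomes
years later. Real cohorts of this kind are not publicly available, so this
package rebuilds the entire computational chain on synthetic data with known
ground truth: every stage can be validated against the truth that generated
its input.

The chain, and the science in each link:

1. **Phantoms** (`make_dgm_phantom`, `sphere_phantom`): ellipsoidal DGM
   structures with literature-level susceptibilities (thalamus −0.008 ppm …
   pallidum 0.099 ppm) inside a brain sphere with a CSF shell; forward
   dipole physics via the k-space kernel `D(k) = 1/3 − (k·b̂₀)²/|k|²`.
2. **Signal synthesis** (`synthesize_multiecho`): six-echo complex GRE
   signal `S_j = m e^{−R₂*TE_j} e^{i(φ₀ + 2πγ̄B₀ f·10⁻⁶ TE_j)}` plus complex
   Gaussian noise (TE₁ = 6 ms, ΔTE = 6.4 ms, 3 T).
3. **Reconstruction** (`mtfi_reconstruct`): multi-echo complex total field
   inversion — a whole-FOV non-convex inversion with magnitude-weighted
   complex-exponential data fidelity, edge-weighted total-variation
   regularization, total-field-inversion initialization, Gauss–Newton/IRLS
   optimization with preconditioned CG, and CSF referencing. No separate
   background-field removal step exists.
4. **ROI metrics** (`roi_mean`, `normalize_volume`, `lesion_filter_tlv`,
   `log_tlv`): regional means, TIV-normalized volumes, 26-connectivity
   lesion filtering at 15 mm³, log lesion volume.
5. **Cohort simulation** (`generate_cohort`): Gaussian-copula covariates and
   regional measures, outcomes built from configurable standardized effects,
   follow-up scores with baseline autocorrelation and per-outcome
   availability.
6. **Statistics** (`spearman_matrix`, `run_cross_sectional_battery`,
   `run_longitudinal_battery`): the 28-model cross-sectional and 20-model
   longitudinal regression batteries with standardized β, Freedman–Lane
   permutation p-values (10000 iterations by default), VIF screening and
   Benjamini–Hochberg FDR grouped by outcome.

## Worked example

```r
library(qsmdgm)

# phantom -> signal -> reconstruction, at unit-test scale (32^3, 2 mm)
ph  <- make_dgm_phantom(grid_spec(c(32, 32, 32), c(2, 2, 2)))
sig <- synthesize_multiecho(ph, acq_params(noise_sigma = 0), seed = 7)
map <- mtfi_reconstruct(sig, ph$brain_mask, ph$csf_mask,
                        recon_params(max_outer_iters = 8, cg_iters = 40))
summary(map, labels = ph$labels)
#> mTFI objective: 0.1116 0.07558 0.05984 0.05078 0.04461 0.03984 0.036 0.0327
#>   monotone descent: TRUE
#>   reference: csf
#>   ROI means (ppm):
#>    label1    label2    label3    label4
#> -0.007481  0.035960  0.045300  0.085380
```

The objective log decreases monotonically; the four ROI means recover the
ground-truth susceptibilities (−0.008, 0.042, 0.050, 0.099 ppm) at the
accuracy this coarse 2 mm grid allows — at the analysis scale (64³, 1 mm)
recovery is within 0.003 ppm noiselessly.

```r
# cohort -> batteries
tab <- generate_cohort(cohort_spec(n_subjects = 771, seed = 1))
bat <- run_cross_sectional_battery(tab, n_permutations = 500, seed = 1)
print(bat)
#> qsm_battery (cross_sectional): 28 models, 500 permutations per term
#> significant exposure terms (grouped FDR q < 0.05 ):
#>    region outcome   term    beta       p       q
#>  thalamus    edss volume -0.2360 0.00200 0.00266
#>   caudate    edss    qsm  0.2545 0.00200 0.00266
#>   caudate    edss volume -0.1235 0.00200 0.00266
#>   putamen    edss    qsm  0.1498 0.00200 0.00266
#>  ... (32 significant rows in total)
plot(bat)          # standardized-beta heatmap, FDR-masked
```

With the default effect map the battery flags the injected pattern: basal
ganglia susceptibility associates with disability, dexterity, processing
speed and lesion volume; volumes carry the larger effects. The printed
`beta` values are standardized coefficients (z-scored variables; sex kept
0/1), `p` the Freedman–Lane permutation p-value, and `q` its BH-corrected
value within the models sharing that outcome.

A command-line wrapper over the same functions is in `scripts/qsmdgm.R`
(subcommands `simulate-phantom`, `synthesize-signal`, `reconstruct`,
`extract-metrics`, `simulate-cohort`, `analyze-cross-sectional`,
`analyze-longitudinal`, `full-run`; every run writes a JSON manifest with
the config hash and seed).

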