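# sphsurv — rotation-invariant survival prediction from tumor shape

`sphsurv` predicts survival risk of cancer patients from segmented 3D tumor
volumes. It is written for imaging researchers who have a CT image plus a
binary tumor mask per subject (NIfTI) and right-censored follow-up records
(time `T`, event flag `E`), and who want an image-derived risk score that
does not depend on how the tumor is oriented in the scanner.

The pipeline:

1. **Spherical projections.** An enclosing sphere is centered at the tumor's
   center of mass; the tumor is mapped onto real-valued signals on the unit
   sphere: the **extended Gaussian image** (area-weighted distribution of
   outward surface normals), a **depth projection** (radial extent of the
   tumor along each ray from the centroid, mm), and an **intensity
   projection** (line integral of windowed HU along each ray).
2. **A spherical-harmonic convolutional network.** Spherical correlation
   lifts the maps onto the rotation group SO(3); a second correlation acts on
   SO(3); spherical pooling halves the bandwidth between layers; a
   rotation-invariant readout (integral + L2 norm per channel over the group)
   feeds a 40-feature dense layer and a linear scalar output
   *h<sub>θ</sub>(x)*.
3. **Proportional-hazards training.** The scalar output is the log-risk of
   λ(t|x) = λ₀(t)·exp(h<sub>θ</sub>(x)); the network minimizes the average
   negative log partial likelihood −(1/N<sub>E</sub>) Σ<sub>i:E=1</sub>
   [h<sub>i</sub> − log Σ<sub>T<sub>j</sub>≥T<sub>i</sub></sub>
   e<sup>h<sub>j</sub></sup>] (Breslow ties), so right-censored records are
   used without discarding or imputing them.
4. **Evaluation.** Harrell's concordance index, median-risk stratification,
   and Kaplan-Meier curves per risk group; event-stratified cross-validation
   and external-cohort evaluation with training-split-only normalization.

Everything — spherical harmonic transforms on the equiangular
Driscoll-Healy grid, Wigner-d recursions, spectral convolutions and their
hand-derived gradients, Adam training, survival statistics — runs in plain R
on one CPU. A phantom module generates star-shaped tumor solids with
textured interiors and simulated censored outcomes, so the whole pipeline is
testable against analytic ground truth without any patient data.

## Worked example

Simulate a 60-subject cohort whose risk is driven purely by tumor volume,
train the depth-map network, and evaluate on an independent 80-subject
cohort:

```r
library(sphsurv)

spec <- phantomCohortSpec(nSubjects = 60,
                          betaTrue = c(volume = 1.5, asphericity = 0),
                          seed = 7)
coh <- generateCohort(spec)
coh$cohort
#> SurvivalCohort: 60 subjects, 40 events ( 67 % )
#>   covariates: volume, asphericity

maps <- mapCohort(coh$subjects, "sphcnn1", bandwidth = 16)
fit <- trainRiskModel(maps, coh$cohort,
                      networkConfig(16, "sphcnn1", c1 = 4, c2 = 8),
                      seed = 1, epochs = 30, learningRate = 3e-3)
fit$model
#> RiskModel ( sphcnn1 ): bandwidths 16 -> 8 -> 4 , channels 1 -> 4 -> 8 -> dense 40 -> 1

ext <- generateCohort(phantomCohortSpec(nSubjects = 80,
                                        betaTrue = c(volume = 1.5, asphericity = 0),
                                        seed = 99))
ev <- evaluateExternal(fit$model, mapCohort(ext$subjects, "sphcnn1", 16),
                       ext$cohort)
round(ev$cIndex, 3)
#> [1] 0.796
round(concordanceIndex(riskScores(ext$cohort), ext$cohort), 3)
#> [1] 0.814
c(high = kmMedian(ev$kmHigh), low = kmMedian(ev$kmLow))
#>      high       low
#>  3.350777 34.171800
```

The trained model ranks the external cohort with concordance 0.796 against a
ceiling of 0.814 — the concordance of the *true* simulated log-risk, which
no predictor can beat in expectation — and the median-split risk groups
separate sharply: median survival 3.4 months in the high-risk group versus
34.2 in the low-risk group. Training takes under a minute on one CPU core.

## Command line

A thin wrapper over the same functions lives at `inst/cli/sphsurv.R`:

```sh
Rscript inst/cli/sphsurv.R phantom --n 50 --seed 7 --out phantoms/
Rscript inst/cli/sphsurv.R map --image a.nii.gz --mask a_mask.nii.gz \
        --bandwidth 16 --config sphcnn2 --out a.rds
Rscript inst/cli/sphsurv.R train --maps maps.rds --cohort cohort.csv \
        --config cfg.json --seed 1 --out model.rds
Rscript inst/cli/sphsurv.R cv | predict | evaluate ...
```

Every command takes `--seed`; identical seeds give bit-identical outputs.

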