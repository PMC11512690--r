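# alpsmt

Perivascular diffusivity (DTI-ALPS) and spherical-mean microstructure
mapping from multi-shell diffusion MRI, with the cohort statistics to
relate them to circadian time, sleep quality and cognition.

## The problem

The glymphatic system is a proposed brain waste-clearance pathway that
moves CSF along perivascular spaces. It cannot be observed directly in
humans without contrast agents, but at the level of the lateral-ventricle
body the perivascular spaces of the medullary veins run along the
left–right (x) axis — perpendicular both to projection fibres (head–foot,
z) and to association fibres (anterior–posterior, y). Diffusion tensor
imaging can therefore probe perivascular fluid mobility by comparing
diffusivity along x with diffusivity perpendicular to both fibre systems,
in ROIs where those fibres dominate:

```
ALPS = mean(Dx_proj, Dx_assoc) / mean(Dy_proj, Dz_assoc)
```

with an index of 1 meaning no preferential perivascular diffusion. The
index is computed per hemisphere and the two indices averaged.

Alongside it, the package fits the spherical-mean-technique (SMT)
two-compartment model. Per shell, averaging the signal over all gradient
directions removes fibre-orientation effects; the normalized shell mean
follows

```
e(b; v, λ) = v·c(bλ) + (1−v)·exp(−b(1−v)λ)·c(bvλ),
c(x) = sqrt(π/(4x))·erf(√x)
```

where `v` is the intra-neurite volume fraction (INVF), `λ` the intrinsic
diffusivity, and the extra-neurite transverse diffusivity is coupled by
the tortuosity relation `λ⊥ = (1−v)λ`. The extra-neurite mean diffusivity
is the derived map `exMD = λ(3−2v)/3`. A standard single-tensor fit on the
b = 1000 s/mm² shell supplies FA/MD and the tensor elements the ALPS index
reads.

The cohort layer provides circadian time (signed hours from usual
awakening to mid-scan), Pearson correlations, standardized-β linear
models (z-scored outcome and continuous predictors, so a simple-regression
β equals Pearson r), pooled t-tests, and Bonferroni control across the 34
Desikan–Killiany regions.

The package is aimed at neuroimaging researchers who want a tested,
self-validating reference implementation of this chain. Because suitable
cohort data are access-restricted, a synthetic-data module generates
multi-shell phantoms (tensor, stick+zeppelin, CSF compartments; Rician
noise) and cohort tables with configurable true standardized effects, so
every estimator is checked by parameter recovery.

## Worked example

Simulate a noisy phantom whose fibre slabs have a known perivascular
Dxx contribution, fit the tensor, and compute the ALPS index:

```r
library(alpsmt)

ps  <- defaultPhantomSpec(snr = 50, seed = 1, gridDim = c(12L, 12L, 8L))
ph  <- makePhantom(ps$spec)        # 3 shells x 90 directions + 18 b0
tf  <- fitTensor(ph$dwi)           # b=1000 shell + b0, OLS + WLS refit
res <- computeALPS(tf, ps$rois)
res
#> ALPSResult
#>   hemisphere     Dxproj    Dxassoc     Dyproj    Dzassoc projSize assocSize
#> 1       left 0.00079974 0.00080009 0.00039976 0.00040079   281.25    281.25
#> 2      right 0.00079851 0.00079911 0.00040065 0.00039943   281.25    281.25
#>    index
#> 1 1.9984
#> 2 1.9968
#> mean DTI-ALPS index: 1.99763
ps$expectedIndex                   # analytic value composed from the generator
#> [1] 2
```

The four columns are the ROI-averaged diffusivities (mm²/s): at SNR 50
the recovered index sits within 0.2% of the analytic value 2.0 composed
from the generating tensors (Dxx boosted by 0.4e-3 mm²/s in both fibre
slabs over a 0.4e-3 background).

Generate a synthetic cohort (n = 916) whose ALPS outcome carries true
standardized effects (circadian −0.07, white-matter volume −0.198, male
sex −0.101), and fit the main adjusted model:

```r
co  <- makeCohort(cohortSpec(n = 916, seed = 1))
fit <- standardizedLM("alps_index",
                      c("circadian_time", "wm_volume", "sex", "age",
                        "sbp", "bmi"), co$table)
fit$terms[, c("term", "beta", "se", "p")]
#>             term    beta     se        p
#> 1 circadian_time -0.1217 0.0320 1.51e-04
#> 2      wm_volume -0.2196 0.0320 1.20e-11
#> 3            sex -0.1364 0.0645 3.47e-02
#> 4            age -0.0484 0.0321 1.31e-01
#> 5            sbp -0.0255 0.0320 4.25e-01
#> 6            bmi  0.0430 0.0321 1.81e-01
```

Each β is a standardized coefficient; the injected effects are recovered
within their sampling error (SE ≈ 0.032 at this n) and the null
covariates stay null. `runPipeline(pipelineConfig(outDir))` chains the
whole flow — phantom → tensor → ALPS → SMT → regional aggregation →
cohort statistics — into one seeded, checksummed, byte-reproducible run,
and `reportRun(outDir)` tabulates every estimate against the recorded
ground truth. A thin command-line front end with the matching subcommands
lives at `inst/cli/alpsmt.R`.

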