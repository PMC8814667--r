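# mssm — multiscale structural surface mapping of the cerebral cortex

Cortical thinning is the classical structural MRI marker of Alzheimer's
disease, but neurodegeneration also erodes the *tissue contrast* between deep
gray matter and the adjacent white matter before the cortex measurably thins.
`mssm` implements multiscale structural surface mapping: at every cortical
vertex it samples the T1-weighted volume on intracortical surfaces at 20, 40,
60 and 80% depth and on white-matter surfaces 0.5 and 1 mm below the
gray/white border, forms the eight gray/white contrast ratios
$R(g,o) = I_{\mathrm{GM}}(g) / I_{\mathrm{WM}}(o)$, and combines them with
cortical thickness into a nine-feature map. Because each ratio compares
intensities millimetres apart, it is locally normalized against smooth
intensity nuisance fields. The feature maps are surface-smoothed (5 mm FWHM,
impulse-calibrated neighbour averaging), reduced to one component per vertex
by PLS1 regression against diagnosis ($w \propto X_c^\top y_c$, unit norm,
sign fixed to disease-positive), compared between groups with vertex-wise
pooled-variance t-tests, Cohen's d and Benjamini–Hochberg FDR, and fed to a
class-weighted ensemble classifier (top 3 of 9 families by 5-initialization
× 4-fold cross-validated AUROC, probability averaging) with ROC/PR
evaluation and threshold chosen to minimize FP + FN. A trained model can be
transferred, unchanged, to a second cohort (e.g. MCI converters vs
non-converters).

The package is aimed at methodologists who want to study this measurement
and classification procedure end to end without access to clinical MRI: a
synthetic cortical phantom generator (spherical ribbon geometry, piecewise
tissue intensities, multiplicative bias field, Gaussian noise, configurable
disease-like thinning and contrast-loss "signature" regions, synthetic
cognitive and volumetric scores) makes every stage testable against analytic
ground truth.

## Worked example

```r
library(mssm)

study <- run_study(seed = 1)   # full phantom study, ~1–2 minutes
study
#> mssm_study (seed 1): 80 subjects
#>   % significant vertices: MSSM 27.9 vs thickness 8.9
#>   mssm               AUROC 1.000
#>   ct                 AUROC 1.000
#>   hippocampus        AUROC 1.000
#>   noise              AUROC 0.516
#>   transfer           AUROC 0.997
study$extra
#> extra_region_analysis: 122 extra-region vertices
#>  control   pearson  spearman    p_pearson   p_spearman
#>     none 0.7014778 0.6693250 4.600867e-07 2.333131e-06
#>    x_all 0.6931355 0.6723427           NA           NA
#>    x_sig 0.6768930 0.6548190           NA           NA
```

Reading this: on a cohort of 40 affected and 40 control phantoms whose
contrast-loss region extends beyond the thinning region, the multiscale map
marks about three times as many vertices as significantly different
(FDR q = 0.05) as thickness alone — the qualitative signature of the method's
added sensitivity. Both vertex-wise classifiers separate the held-out test
subjects perfectly at this effect size, a pure-noise scalar stays at chance,
and the model transferred without refitting to a half-effect "MCI" cohort
sits between the two. The mean multiscale signal in the "extra" region
(significant for MSSM but not thickness) correlates with the FAQ-like
functional score within the affected group, and the correlation survives
partialling out mean cortical thickness — the extra region carries clinical
information thickness does not.

Individual stages are ordinary functions returning classed objects with
`print`/`summary`/`predict` methods: `make_cohort()`, `contrast_features()`,
`smooth_map()`, `fit_vertex_pls()`, `vertex_ttest()`, `mssm_train()`,
`mssm_evaluate()`, `transfer_predict()`. An on-disk pipeline with provenance
records is available through `run_pipeline()` and the thin CLI at
`inst/cli/mssm.R`:

```sh
Rscript inst/cli/mssm.R all --seed 1 --out mssm_out
```

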