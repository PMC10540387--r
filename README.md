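# stalknirs

Chemometric calibration of near-infrared (NIR) spectra against stalk
mechanical strength traits.

## What this solves, and for whom

Breeding cane crops for lodging and greensnap resistance requires
phenotyping two slow laboratory traits across hundreds of genotypes:
**rind penetrometer resistance** (RPR, N/mm² — peak force per unit area to
puncture the rind of a mature internode with a 1 mm² probe) and **breaking
force** (N — peak transverse force at which a young internode snaps). An
NIR spectrum of the same stalk tissue, measured in seconds over
~4,000–12,000 cm⁻¹, carries overtone/combination-band chemistry that
co-varies with these traits, so a multivariate calibration can replace most
of the lab work.

`stalknirs` is for plant phenotyping and chemometrics workers who need that
calibration pipeline as tested, scriptable R functions rather than
closed-source instrument software. It implements:

* spectra / reference-table I/O (wide CSV), window (wavenumber-range)
  selection;
* the ten standard pretreatments — COE, SSL, SNV, MMN, MSC, first and
  second Savitzky–Golay derivatives, and FD+SSL / FD+SNV / FD+MSC;
* PCA characterization and GH (Mahalanobis) spectral outlier screening;
* NIPALS PLS1 regression, segmented cross-validation, rank selection,
  pretreatment × window model search, external validation, RPD scoring,
  and global recalibration on the merged set;
* laboratory replicate reduction (trimmed-mean of 5 penetrometer
  positions), genotype summaries (mean, SD, SE, relative deviation), trait
  correlations;
* a synthetic spectra + reference generator reproducing the statistical
  structure of a real stalk-strength study, so every stage runs and is
  testable with no instrument data.

## The model in brief

With centered pretreated spectra $X$ and trait $y$, NIPALS PLS1 extracts
latent variables $t_a = X w_a$ with
$w_a = X^\top y/\lVert X^\top y\rVert$, loadings
$p_a = X^\top t_a/t_a^\top t_a$, $q_a = y^\top t_a/t_a^\top t_a$, deflating
$X$ after each component; the regression vector is
$\beta = W(P^\top W)^{-1}q$. Models are scored per stage by RMSE,
$R^2 = 1 - SS_{res}/SS_{tot}$, and $\mathrm{RPD} = \mathrm{SD}/\mathrm{RMSE}$
(calibration-set reference SD over stage RMSE; RPD > 2.5 is the
conventional screening threshold). The rank is the smallest whose RMSECV is
within 2% of the curve minimum. Full derivations, conventions and design
rationale are in `vignettes/nirs-calibration.Rmd`.

## Worked example

```r
library(stalknirs)

# a synthetic RPR study: 300 genotypes, absorbance spectra on a
# 4000-12000 cm^-1 grid with scatter artifacts and lab reference error
cfg <- generator_config(trait = "RPR", n_samples = 300, seed = 11)
gr  <- gen_reference(cfg)
sp  <- gen_spectra(gr$latent, cfg)

# spectral QC
pc <- fit_pca(sp, k = 10)
sum(pc$explained_variance_ratio)        # 0.999 of variance in 10 PCs
gh <- gh_distance(pc, sp, threshold = 3)
sum(gh$flag)                            # 1 spectrum flagged

# 4:1 split (range-containing), pretreatment search, external validation
split <- split_calibration_validation(gr$reference, ratio = 0.8, seed = 11)
cal_ref <- gr$reference[match(split$calibration, gr$reference$sample_id), ]
gs <- grid_search(sp[split$calibration], cal_ref,
                  candidate_pretreatments = c("NONE", "SNV", "MSC", "FD_SNV"),
                  max_rank = 12, n_segments = 10, seed = 11)
gs$leaderboard[, c("pretreatment", "rank", "RMSEC", "R2",
                   "RMSECV", "R2cv", "RPD_cv")]
```

```
  pretreatment rank RMSEC    R2 RMSECV  R2cv RPD_cv
1       FD_SNV    8 0.931 0.984   1.01 0.981   7.28
2          MSC    9 0.949 0.983   1.02 0.980   7.16
3          SNV    9 1.007 0.981   1.08 0.978   6.80
4         NONE   10 1.128 0.976   1.26 0.970   5.82
```

Scatter-corrective pretreatments clearly beat the raw spectra; the winner
(first derivative + SNV, 8 latent variables) cross-validates at RMSECV
1.01 N/mm² — essentially the study's reference measurement error (SD
0.94) — with R²cv 0.981 and RPD 7.3, i.e. a quantitative calibration.

```r
val_ref <- gr$reference[match(split$validation, gr$reference$sample_id), ]
ev <- external_validate(gs$models[[1]], sp[split$validation], val_ref)
c(RMSEP = ev$RMSEP, R2ev = ev$R2ev, RPD = ev$RPD)
#>  RMSEP   R2ev    RPD
#>  1.002  0.973   7.32
```

External performance matches the internal cross-validation — no
overfitting — and the model can be frozen with `save_model()` and applied
to new spectra files with `run_predict()`. The whole sequence, including
artifact files (model JSON, leaderboard CSV, report, predicted-vs-observed
table, run log), is available as one call through `pipeline_config()` +
`run_calibrate()`, or from a shell via the dispatcher in
`inst/cli/stalknirs.R` (subcommands `simulate`, `calibrate`, `validate`,
`predict`, `report`).

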