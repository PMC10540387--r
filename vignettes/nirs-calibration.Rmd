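---
title: "Calibrating NIR spectra against stalk mechanical strength: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating NIR spectra against stalk mechanical strength: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(stalknirs)
```

## The problem

Stalk lodging and greensnap are major sources of yield loss in tall cane
crops. Two laboratory traits quantify the underlying mechanical strength:
**rind penetrometer resistance** (RPR, N/mm²) — the peak force per unit area
needed to puncture the rind of a mature internode with a 1 mm² probe — and
**breaking force** (N), the peak transverse force at which a young internode
snaps. Both are slow to measure: each genotype needs several internode
punctures and six biological replicates. Near-infrared spectroscopy (NIRS)
offers a high-throughput surrogate: a reflectance/absorbance spectrum over
roughly 4,000–12,000 cm⁻¹ carries overtone and combination-band information
about the cell-wall chemistry that co-varies with mechanical strength, so a
multivariate calibration can predict the trait from the spectrum in seconds.

`stalknirs` implements the full calibration workflow: spectral pretreatment,
principal-component QC with GH (Mahalanobis) outlier screening, NIPALS
partial least squares (PLS1) regression, segmented internal
cross-validation with rank selection, a pretreatment-by-wavenumber-window
model search, external validation, RPD scoring, and global recalibration on
the merged set — plus the laboratory side (replicate reduction, genotype
summaries, trait correlations) and a synthetic data generator that makes
every stage testable at desk scale.

## The calibration model

Given pretreated spectra $X \in \mathbb{R}^{n\times p}$ and a reference
trait $y$, NIPALS PLS1 builds $A$ latent variables sequentially. With $X$
and $y$ column-centered, component $a$ computes

$$w_a = X^\top y / \lVert X^\top y\rVert,\qquad t_a = X w_a,\qquad
p_a = X^\top t_a / t_a^\top t_a,\qquad q_a = y^\top t_a / t_a^\top t_a,$$

then deflates $X \leftarrow X - t_a p_a^\top$ and
$y \leftarrow y - q_a t_a$. The regression vector in centered variable
space is $\beta = W (P^\top W)^{-1} q$. PLS1 is deterministic — there is no
random initialization — and the score vectors $t_a$ are mutually
orthogonal, which the test suite asserts. A zero-norm weight before
component $A$ means the requested rank exceeds the data rank and is an
error naming the failing component.

Model quality is reported per stage with the conventional statistic set:
RMSEC (calibration), RMSECV (internal cross-validation), RMSEP (external
validation), the corresponding $R^2 = 1 - SS_{res}/SS_{tot}$, and
$\mathrm{RPD} = \mathrm{SD}/\mathrm{RMSE}$. Models with RPD above 2.5 are
conventionally considered adequate ("fair") for screening applications;
values above 8–10 indicate quantitative accuracy.

Two conventions are deliberately declared rather than inherited, because
commercial chemometrics packages do not document theirs:

* **$R^2$** is always $1 - SS_{res}/SS_{tot}$ against the observed values
  of the stage being scored, so calibration, CV and external statistics are
  directly comparable.
* **RPD** always uses the calibration-set reference SD in the numerator and
  the stage RMSE in the denominator. For the cross-validation stage this
  reproduces published SD/RMSECV arithmetic exactly (e.g. SD 7.62 with
  RMSECV 0.74 gives RPD 10.30, and SD 6.08 with RMSECV 2.51 gives 2.42,
  both checked in the tests); vendor software sometimes applies a bias
  correction or the validation-set SD at other stages, and reported
  third-party external-stage RPDs frequently fit no simple formula at
  two-decimal precision, so the package states its convention and applies
  it uniformly.

## Pretreatment

Ten per-spectrum operators are provided, matching the standard scatter
correction menu: constant offset elimination (COE), straight-line
subtraction (SSL), standard normal variate (SNV), min–max normalization
(MMN), multiplicative scatter correction (MSC), Savitzky–Golay first and
second derivatives (FD, SED), and the combinations FD+SSL, FD+SNV, FD+MSC.
Combinations apply the derivative first, then the scatter step on the
derivative spectra, matching the conventional "FD + SNV" naming order.

Numerical contracts, each enforced by a property test:

* SNV output has mean 0 and sample SD 1 (n−1 denominator) per spectrum.
* MSC regresses each spectrum on a reference, then inverts the fitted
  affine map; it is invariant under $x \mapsto \alpha x + \beta$,
  $\alpha > 0$. The reference is the **calibration-set mean spectrum,
  frozen into the model** — prediction never re-estimates statistics from
  new data, and cross-validation refits the reference inside every fold so
  no information leaks into held-out segments.
* Savitzky–Golay derivatives use local polynomial regression
  (`signal::sgolayfilt`), scaled by the grid spacing (units per cm⁻¹);
  they are exact on polynomials up to the fitting order, and boundary
  points use the polynomial fit on the edge window so the variable count
  is preserved. Defaults are a 17-point window with polynomial order 2 —
  a typical vendor-style smoothing default, declared here because
  instrument software rarely documents its own — and both are
  configurable in `pretreatment()`.
* MMN scales each spectrum to exactly [0, 1]. Some vendor dialects scale
  to other ranges; after centering inside PLS the choice only changes a
  per-spectrum scalar.

## Spectral QC: PCA and the GH distance

`fit_pca()` operates on centered but unscaled spectra (all variables share
units), with a deterministic sign convention (the largest-magnitude loading
element is positive). The default depth is $k = 10$ components, the
customary depth for characterizing a NIR population, which on realistic
low-rank-plus-noise populations explains >99% of the spectral variance.

The GH ("global distance") statistic of a spectrum is its squared
Mahalanobis distance in the $k$-component score space divided by $k$, with
the score covariance estimated from the fitting set (n−1 denominator). Two
consequences anchor the tests: the mean GH over the fitting set is exactly
$(n-1)/k \cdot k/n = (n-1)/n$, and GH is invariant under orthogonal
rotations of the retained loadings. The flagging threshold defaults to
GH > 3, standard NIRS practice. Flagged spectra are **reported, never
silently removed**; removal is an explicit pipeline option
(`remove_outliers`), because how many spectra — if any — should be
discarded is a study-level decision.

A practical note on Mahalanobis screens that the design accounts for:
when outliers sit in the fitting set, they inflate the score covariance
along their own direction. A group forming a fraction $f$ of the data that
collapses onto a single direction can push its own GH down towards
$((1-f)/f + k - 1)/k$ — about 2.9 for $f = 0.05$, $k = 10$, i.e. *below* a
threshold of 3 no matter how gross the corruption. Detection therefore
depends on corrupted samples spreading over several directions. The
synthetic outlier injector (below) emulates heterogeneous defects for
exactly this reason, and the vignette states the ceiling so users screening
real data know that a coordinated, one-directional artifact class is better
caught by inspecting the score plots than by the GH flag alone.

## Cross-validation, rank selection and the model search

The calibration set is shuffled (seeded) and cut into `n_segments`
contiguous near-equal groups; each group is predicted by a model refit on
the others, including fold-local pretreatment statistics. The default is 10
segments — a common default in commercial NIRS software, declared here —
and `n_segments = n` gives leave-one-out, which the tests pin against a
brute-force refitting oracle exactly.

The rank (number of latent variables) is chosen from the RMSECV curve
computed in a single CV pass (each fold is fitted once at the maximum rank;
lower-rank predictions are read off the component sequence). Because the
curve is typically flat near its minimum, the default rule is parsimonious:
the smallest rank whose RMSECV is within 2% of the minimum. The plain
argmin is available (`parsimony = FALSE`).

`grid_search()` evaluates every pretreatment × window-set combination,
ranks by RMSECV (ties: higher R²cv, then lower rank), and returns the full
leaderboard with fitted models. `default_window_candidates()` implements
the default window scheme: the grid span cut into 10 equal blocks, with
every union of at most two non-adjacent block runs as a candidate (385
candidates), covering the one- and two-interval range selections common in
published calibrations. Exhaustive vendor-style region optimization is out
of scope. The worked examples and the test suite search a handful of
pretreatments over the full range — the package's desk-scale default — and
exercise the window enumeration separately.

`split_calibration_validation()` draws a seeded uniform 4:1 split, then
swaps the samples carrying the global minimum and maximum reference values
into the calibration set (exchanging with random non-extreme members to
preserve counts). Every validation prediction is then an interpolation.
`external_validate()` refuses any sample overlap with the calibration ids —
leakage is an error, not a warning. `global_recalibrate()` merges the two
sets and reruns rank selection and CV with the chosen pretreatment and
windows, the usual final step once external validation has passed.

## Laboratory reference processing

RPR is measured at five positions per internode; the internode value is the
mean of the three readings left after eliminating the maximum and the
minimum (exactly one instance of each under ties — the tie rule is declared,
since measurement protocols rarely state one). Six biological replicates
per genotype are summarized by their mean (the value fed to calibration,
matching genotype-level averaged spectra), sample SD, standard error
SD/√n, and **relative deviation, defined as the replicate coefficient of
variation SD/mean·100**. The CV definition is chosen because it is the one
consistent with how replicate-quality percentages are conventionally
reported alongside standard errors: a 6-replicate trait with SE ≈ 0.94 at a
mean of 42 has replicate SD ≈ 2.30 and hence a relative deviation near
5.5%, the magnitude quoted for penetrometer work, whereas SE/mean would
give ~2.2%.

## The synthetic data generator

Because raw calibration spectra are essentially never published alongside
trait tables, `stalknirs` ships a generator that reproduces the
*statistical structure* the analysis relies on, so the whole pipeline is
exercisable and testable without any download:

* **Reference traits** are truncated normal draws with the population
  parameters typical of each trait — RPR mean 42.0, SD 7.62, range
  22.8–79.7 N/mm²; breaking force mean 20.3, SD 6.08, range 6.6–32.8 N —
  plus an independent laboratory measurement error (SD 0.94 and 1.15
  respectively, the level implied by 6-replicate standard errors in the
  0.57–1.19 / 0.37–1.37 bands). The noiseless latent trait is returned
  alongside, so tests know the irreducible error floor exactly.
* **Spectra** are sums of Gaussian absorbance bands on a 4,000–12,000 cm⁻¹
  grid (1,038 points by default): five informative bands whose
  concentrations are affine in the standardized latent trait with
  alternating signs, eight independent interferent bands, then per-sample
  scatter (multiplicative slope SD 0.10, baseline offset SD 0.05, linear
  tilt SD 0.05) and additive noise (SD 0.002).
* The **band amplitudes are deliberately sized** (trait response 0.15 per
  latent SD against a baseline concentration of 1) so that per-spectrum
  intensity variation is dominated by scatter rather than chemistry. This
  is the regime scatter-corrective pretreatment exists for, and it is what
  makes the pretreatment comparison meaningful: with scatter SD raised to
  0.2, SNV beats no-pretreatment in RMSECV in essentially every seeded
  repetition, while at the cost of removing a genuine intensity degree of
  freedom. If instead the chemistry dominated amplitude variation, SNV
  normalization would *remove* signal — a real phenomenon practitioners
  should recognize, but not the study condition this generator emulates.
* **Replicates** expand each genotype into 6 biological replicates (and 5
  position peaks for RPR), with between-replicate SD 2.1 (RPR) / 2.82
  (breaking force) and position SD 2.0, sized so genotype standard errors
  land in the bands above.
* **Outliers** (`inject_outliers`) add a gross smooth artifact — offset,
  tilt, and quadratic bow, each of the requested amplitude with sign
  patterns cycled over all eight combinations — so a corrupted subset
  always spans three score directions and the GH masking ceiling described
  above does not apply. The recall property tests use amplitude 1.0
  absorbance, about 10× the generator's baseline nuisance variation.

What the generator does **not** emulate: real band assignments of cane
cell-wall chemistry, instrument line shape and detector noise spectra,
water-vapor interference, temperature drift, or nonlinear detector
saturation. Passing tests therefore demonstrate the *statistical
machinery* — not that any particular instrument will achieve a given RPD
on real stalks.

## Problem sizes and reproducibility

All randomness flows through integer seeds; identical configurations
produce byte-identical leaderboards. The test suite runs the full pipeline
(split → QC → pretreatment search → rank selection → CV → external
validation) at $n = 500$, $p = 1038$ over 20 seeds, and the
scatter-correction comparison at $n = 100$, $p = 200$ over 50 seeds —
sizes chosen so the whole suite completes in a few minutes on one core
while leaving the statistical margins wide. At these settings the pipeline
attains R²cv ≈ 0.98 and RPD ≈ 7 against an error-floor-limited maximum of
R² ≈ 0.985 (reference-error SD 0.94 on a trait SD of 7.6), external R²
within a few thousandths of the internal value, and GH recall of injected
outliers at or near 1.0.

## Known limitations

* NIPALS deflation accumulates rounding error at ranks near the data rank;
  the full-rank equivalence with ordinary least squares is tested to 1e−6
  on well-conditioned instances, and ill-conditioned requests fail loudly
  rather than silently.
* The GH screen inherits the masking ceiling of any non-robust Mahalanobis
  estimator (see above); a robust covariance option would be a natural
  extension.
* Window candidates are unions of at most two block runs; deeper region
  optimization (simulated annealing over intervals, as vendor tools offer)
  is out of scope.
* The package models one trait per calibration (PLS1); multi-response
  PLS2 is not implemented.
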