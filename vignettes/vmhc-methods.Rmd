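---
title: "Voxel-mirrored homotopic connectivity: model, pipeline and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-mirrored homotopic connectivity: model, pipeline and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measure

Voxel-mirrored homotopic connectivity (VMHC) quantifies interhemispheric
functional coupling in resting-state fMRI. For every gray-matter voxel, the
Pearson correlation is computed between the voxel's preprocessed BOLD time
series and that of its geometrically mirrored counterpart in the opposite
hemisphere, and Fisher z-transformed:

$$ z(v) \;=\; \operatorname{atanh}\, r\!\left(x_v,\; x_{m(v)}\right), $$

where $m(v)$ reflects the voxel across the midsagittal plane. Because the
correlation of a pair is a single number, statistics are computed once per
pair on a *unilateral* gray-matter mask (one hemisphere, midline plane
excluded — a midline voxel is its own mirror and would contribute a
degenerate $r = 1$) and reflected to the other hemisphere. Degenerate
correlations $|r| = 1$ are clipped to $1 - 10^{-7}$ before `atanh` so
downstream statistics stay finite.

Group analyses fit, at every unilateral-mask voxel, an ordinary
least-squares model of VMHC on an intercept, the group indicator
(patient = 1, so negative effects mean patients below controls), and
mean-centred covariates (age, gender 0/1, mean framewise displacement).
The group t statistic is mapped to a standard-normal Z through
$\Phi^{-1}$ of the one-tailed t probability, evaluated in log space so
large statistics remain finite and strictly monotone. Clinical association
maps are partial Pearson correlations within the patient group: VMHC and
the clinical score are both residualized on the covariates and correlated;
significance uses $t = r\sqrt{\mathrm{df}/(1-r^2)}$ with
$\mathrm{df} = n - 2 - n_{\mathrm{cov}}$.

## Preprocessing

The chain is fixed and logged: discard the first 10 volumes, smooth with a
6-mm-FWHM separable Gaussian (per-axis $\sigma =
\mathrm{FWHM}/(2\sqrt{2\ln 2})/\mathrm{voxel}$, kernel truncated at
$4\sigma$, zero-padding outside the grid), regress nuisance signals, and
band-pass filter 0.01–0.08 Hz. The nuisance design holds an intercept, the
six rigid-body motion parameters, a centred linear drift ramp, and mean
signals from the ventricular, white-matter and whole-brain masks obtained
by thresholding tissue probability maps at 0.7, 0.9 and 0.5 (strict `>`).
Tissue signals are extracted from the *smoothed* series (the alternative —
pre-smoothing extraction — differs negligibly for mask-mean signals; the
choice is logged). The band-pass is an ideal rectangular DFT-domain filter
that keeps coefficients with $|f| \in [0.01, 0.08]$ Hz inclusive and zeroes
everything else including the DC term; this is the convention of the
resting-state toolbox family this pipeline mirrors, has no phase
distortion, and makes the generator's recovery target exact (below).
Linear drift is a regressor inside the nuisance GLM rather than a separate
detrend pass.

Motion QC: framewise displacement is
$FD_t = \sum |\Delta t_i| + 50\,\mathrm{mm} \cdot \sum |\Delta r_i|$
(rotations converted to displacement on a 50-mm sphere, the standard
radius for this FD definition; $FD_1 = 0$), computed on the analyzed
(post-discard) volumes. A subject is excluded when FD exceeds 0.5 mm on
more than 35 volumes. A separate screen reports whether any translation
reaches 1 mm or any rotation 1 degree.

## Symmetric space

The study-specific symmetric template is the across-subject mean
gray-matter probability map averaged with its own left–right mirror. The
analysis mask is `template > 0.2`; the threshold is configurable because no
canonical value exists for this mask (0.2 is a common gray-matter
probability cut). The grid is forced to an odd left–right extent so a
midline plane exists; `mirror(i) = nx + 1 - i` (1-based) is an involution
with the midline column as fixed point. The left hemisphere (negative
world x) hosts the unilateral mask; by the mirror symmetry of the VMHC map
the choice of side cannot affect any statistic. Registration to the
template is identity resampling on the shared synthetic grid; real-data
nonlinear registration is outside this package's scope.

## Cluster-extent inference

Voxel-wise maps are thresholded two-tailed at $p = 0.01$ ($|Z| > 2.576$)
and corrected by cluster extent. The minimum cluster size is derived by
Monte-Carlo simulation in the AlphaSim style: each iteration fills the
unilateral mask's bounding box with unit Gaussian noise, smooths it with
the 6-mm kernel, restricts to the mask, re-standardizes to unit variance
within the mask (smoothing deflates variance, and the per-voxel p must
stay nominal), thresholds two-tailed, and records the maximum cluster size
over both signs; positive and negative clusters are never merged. The
threshold is the smallest $k$ whose exceedance fraction is at most
$\alpha = 0.05$. Smoothness is taken as the applied kernel's FWHM rather
than estimated from residuals, matching the stated simulation parameters.
Default connectivity is 6 (faces), configurable to 18 or 26; the
neighbourhood used by the original AlphaSim runs is not documented, so it
is exposed as configuration. Cluster tables report size in voxels and
mm³, the signed peak Z, and the peak's world coordinate with the midline
at x = 0 (MNI-style; reported sizes are integer multiples of the 27 mm³
voxel volume at the default 3-mm resolution).

The minimum cluster size often quoted for this design (810 mm³ — 30
voxels at 3-mm resolution) depends on the analysis mask's volume, which
differs between studies, so it is treated as reference output, never as a
calibration target.

A complementary structural check extracts per-subject mean gray-matter
values within each significant VMHC cluster and compares groups with the
same covariate-adjusted GLM, Bonferroni-corrected over clusters, to rule
out tissue-volume differences as the source of connectivity differences.
Age and gender are included as covariates for consistency with the other
analyses.

## Synthetic cohorts and what they do (not) emulate

Raw resting-state cohorts of this design are rarely shareable, so the
package ships a generator whose ground truth is exact. For a mirrored voxel pair
with target correlation $\rho$:

$$ x_L = \sqrt{\rho}\, s + \sqrt{1-\rho}\, e_L, \qquad
   x_R = \sqrt{\rho}\, s + \sqrt{1-\rho}\, e_R, $$

with $s, e_L, e_R$ independent unit-variance Gaussian processes built on
the exact passband DFT bins of the post-discard analysis window (random
Gaussian cosine/sine coefficients with a mild $1/\sqrt{k+2}$ spectral
tilt). The population correlation of the pair is exactly $\rho$, and —
because the processes live entirely inside the passband and on exact bins
— nuisance regression and the ideal band-pass leave it untouched, making
$\operatorname{atanh}\rho$ an exact recovery target. On top of this the
generator adds AR(1) noise whose analysis-window passband content is
projected out (so it exercises the filter without biasing the target), a
small random linear drift per voxel, and a constant offset. Spatial
smoothing preserves the engineered correlation in region interiors: a
symmetric kernel mixes pairs with pairs, so the smoothed correlation is a
kernel-weighted mean of the local $\rho$, exact wherever $\rho$ is locally
constant; validation therefore measures region means on box interiors
eroded by 2 voxels.

The anatomy is a symmetric ellipsoid: whole-brain, white-matter-core and
small ventricular probability maps, and a gray-matter shell carrying a
smooth, seeded, exactly mirror-symmetric perturbation per subject. Effect
regions are axis-aligned boxes on the left hemisphere (their mirror is
implied) so ground truth is exactly known, not anatomical atlas regions.
Demographics follow the study's table: 8/9 vs 9/8 male/female split at 17
per group, common age and education distributions, gamma-distributed
illness duration (patients), and group-specific Gaussian HDRS totals and
symptom factors truncated at plausible bounds. Clinical couplings lower a
patient's regional $\rho$ by `slope` per standard deviation of the score
(centred on the nominal patient mean, so couplings do not move group
means and clinical clusters stay disjoint from group-difference clusters,
matching the motivating study's structure); excursions outside $[0, 1)$
are clipped with a warning. Motion traces are mean-reverting random walks
(AR coefficient 0.95, so the per-step standard deviation equals the
configured value while positions stay bounded); the default step size of
0.042 mm with a log-normal (sd 0.4) per-subject scale was calibrated
analytically — FD is a sum of six half-normal steps — so that roughly 5%
of subjects exceed the FD exclusion rule and the QC path is exercised,
and the resulting mean FD (~0.22 mm) matches the levels reported for
cohorts like this one.

The generator does **not** emulate realistic anatomy, scanner artifacts,
physiological noise, slice-timing effects, or registration error. Passing
tests therefore demonstrate that the pipeline's estimator and inference
machinery are correct and calibrated under the stated statistical
structure — not that they are robust to every property of real data.

## Validation studies and problem sizes

Four recomputable studies (exported functions, also exercised by the test
suite and `scripts/acceptance.R`) back the package's claims. Their sizes
were chosen as the smallest designs that give the checks real statistical
teeth on a single CPU:

* **Parameter recovery** (`vmhc_recovery_study`): 10 subjects, 200
  analyzed frames, five disjoint 7×9×9 boxes at $\rho \in \{0, 0.2, 0.4,
  0.6, 0.8\}$ on a 41×49×41 grid (the smallest grid in which five such
  boxes fit inside the gray-matter shell with 2-voxel erosion margins).
  The regression of recovered region-mean z on $\operatorname{atanh}\rho$
  must have slope in $[0.95, 1.05]$, and the $\rho = 0$ region's mean |z|
  must stay below three theoretical standard errors. That standard error
  uses $2 B$ temporal degrees of freedom ($B$ retained passband bins, two
  real dof each, giving per-voxel Fisher-z sd $1/\sqrt{2B - 3}$) and a
  deliberately conservative one-voxel-per-resel count of independent
  voxels under 6-mm smoothing.
* **FWE calibration** (`fwe_calibration_study`): 1000 calibration plus
  1000 independent validation iterations on a 20³ mask at voxel
  $p = 0.01$, 6-mm FWHM; the validated family-wise positive rate must sit
  inside the 95% binomial interval around $\alpha = 0.05$. The integer
  size threshold makes the procedure conservative, which the interval
  tolerates.
* **Effect recovery** (`effect_recovery_study`): the default study
  conditions — 17 patients vs 17 controls, $\rho$ 0.6 → 0.3 in one
  region, one clinical coupling — on the default 25×31×25 grid. A
  corrected negative cluster must overlap the true region, and the group
  difference in interior region-mean VMHC has the analytic target
  $\operatorname{atanh} 0.6 - \operatorname{atanh} 0.3 = 0.3836$.
* **Null false positives** (`null_fp_study`): twenty independent no-effect
  cohorts (8 per group, 120 analyzed frames, 21×25×21 grid — scaled down
  so twenty full pipeline runs stay desk-sized) sharing one Monte-Carlo
  threshold (legitimate: the mask geometry is identical across runs). At
  most one run in twenty may show a corrected cluster. Note this event is
  itself stochastic: with the family-wise rate exactly at the nominal
  0.05 it holds with ~74% probability, and in practice more often because
  the integer threshold keeps the realized rate below nominal.

## Numerical and design choices

* Pooled-variance (Student) t rather than Welch for the two-sample
  comparisons: it reproduces the printed demographic-table p values
  (0.85, and 0.73 for the chi-squared) and is the convention of the
  toolbox family mirrored here. The 2×2 chi-squared uses no continuity
  correction for the same reason — with Yates' correction the 8/9 vs 9/8
  table gives chi² = 0, p = 1, not the printed 0.73.
* Covariates are mean-centred before fitting; this affects only the
  intercept. Constant covariates are rejected by an explicit rank check
  that names the collinear columns.
* Mean FD is a covariate in the group analysis; for the clinical maps the
  original description is ambiguous, so the default excludes it and a
  configuration flag (`fd_covariate_clinical`) includes it.
* The post-QC sample is used everywhere (a cohort's analyzed n may be
  smaller than its recruited n after FD exclusion).
* Voxels with zero-variance series inside the mask are set missing with a
  warning; group analyses use the complete-case intersection of defined
  voxels across subjects.
* Smoothing boundary handling is zero-padding, fixed and documented;
  kernel truncation at $4\sigma$ keeps the normalized kernel mass within
  ~$10^{-4}$ of complete.
* All randomness is seeded; a fixed configuration and seed reproduce every
  cohort, map and table bit-exactly. Per-subject and per-stage seeds are
  derived from the top-level seed with fixed offsets, so stages can be
  rerun independently.

## Known limitations

The mirror map assumes the functional data are already in a symmetric
space; real brains are not symmetric, and the upstream normalization that
the original workflow used (unified segmentation, nonlinear warps) is out
of scope here — gray-matter maps and aligned series are inputs. Cluster
inference relies on the simulated-smoothness assumption (applied kernel =
field smoothness), which is optimistic for real data where smoothness
varies spatially. The gray-matter ROI check consumes tissue maps as given
and performs no segmentation or modulation of its own.
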