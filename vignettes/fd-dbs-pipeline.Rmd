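---
title: "Boundary complexity, medication outcomes, and hypergraph classification: the fdbs methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary complexity, medication outcomes, and hypergraph classification: the fdbs methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fdbs` implements an analysis pipeline for a question in Parkinson's
disease (PD) neuroimaging: does the *boundary complexity* of cortical and
subcortical brain regions — quantified as a box-counting fractal dimension
(FD) on T1-weighted segmentations — carry information about how a
patient's medication burden changes after deep brain stimulation (DBS)?
The package covers the full chain: FD quantification from label volumes,
construction of the levodopa-equivalent daily dose (LEDD) outcome,
biomarker-validation statistics, penalized feature selection, nested-model
variance analysis, and a hypergraph neural network (HGNN) classifier.
Because patient MRI and medication records cannot ship with a package,
every stage is exercised end to end on deterministic phantoms and
synthetic cohorts with planted, known structure.

## Box-counting fractal dimension

For a binary voxel mask, the grid is partitioned into a non-overlapping
lattice of cubic boxes of edge `s` (anchored at the array corner; partial
boxes at the far edges are counted) and the number `N(s)` of boxes
containing at least one foreground voxel is recorded. The schedule starts
at the smallest grid dimension and halves (integer floor) down to 1 voxel.
FD is the ordinary least-squares slope of `log N` against `log(1/s)`
(natural logs; the slope is base-invariant).

Two modes are provided. The default, `boundary`, first reduces the mask to
its 6-neighbour boundary shell (a foreground voxel with at least one
face-neighbour outside the mask; array-edge voxels count as boundary),
matching the interest in surface complexity. `volume` counts all mask
voxels. Both modes are recorded in the output so results are never mixed
silently.

Numerical choices worth knowing:

* **Scaling window for closed surfaces.** A closed 2-D surface (e.g. the
  boundary shell of a cube) scales like the embedding volume at box sizes
  coarser than the enclosed cavity: `N(m) = m^3 - (m-2)^3` for the cube
  shell, so the first octaves contribute slope ≈ 3 and an all-scales fit
  is biased upward by roughly `log 6 / (octaves × log 2)` — about +0.5 at
  five octaves, shrinking only logarithmically with grid size. When a
  surface-like dimension is the target, the fit should be restricted to
  the fine-scale regime (the package's phantom checks use sizes 8 down
  to 1 on a 64³ cube, giving ≈ 2.11); the `sizes` argument makes this
  explicit. Exact fractals fitted on their natural lattice (the Menger
  sponge at sizes 27, 9, 3, 1) need no window: their points are exactly
  collinear.
* **Lattice anchoring and translation.** The box lattice is anchored at
  the array corner, which makes the estimate deterministic but means a
  *generic* translation of the object changes coarse-scale counts (the
  lattice does not move with the object). Translations that are a common
  multiple of all fitted box sizes leave every count — and therefore FD —
  exactly unchanged, and that exact invariance is what the test suite
  asserts. Practitioners wanting offset-free estimates average over
  lattice offsets; that refinement is out of scope here.
* **Anisotropic voxels.** Counting is done in voxel units. Spacing (e.g.
  0.5×0.5×1 mm acquisitions) is read from the NIfTI header, stored and
  reported, but does not enter the count; physically isotropic counting
  would require resampling, which belongs to preprocessing.

Registration and atlas warping are out of scope: the package consumes
label volumes already in subject space (NIfTI-1, via `RNifti`), with the
shipped AAL-90 naming as the default region table.

## The ΔLEDD outcome

Medication schedules (drug, dose per intake, intakes/day, visit offset in
months relative to surgery) are converted to levodopa-equivalent mg/day
with an *editable* factor table — the shipped CSV carries common
literature values but is configuration, not ground truth. Visits outside
±12 months are ignored. LEDDpre comes from the visit closest before
surgery (a surgery-day visit does not count as preoperative), LEDDpost
from the visit nearest 6 months after; at equal distance the earlier
visit wins, deterministically. The outcome is

&nbsp;&nbsp;&nbsp;&nbsp;ΔLEDD = 100% × (LEDDpre − LEDDpost) / LEDDpre,

stored in percent, positive when medication was reduced. The binary label
splits exactly at zero: ΔLEDD > 0 is `decrease` (the favourable class and
the positive class everywhere in the package), ΔLEDD ≤ 0 is
`no_decrease`. Unknown drugs are an error, never silently skipped;
subjects without a usable visit pair are excluded with a logged reason.

## Biomarker validation statistics

Case-control comparison uses two-sided Welch t-tests per region (Student's
available by flag; Welch is the robust default for multi-site groups),
Benjamini–Hochberg adjustment across the 90-region family, and pooled-SD
Cohen's d (no small-sample correction by default). Residual normality is
checked with the Anderson–Darling test plus QQ quantile pairs.
FD–severity associations are OLS models of the motor score (MDS-UPDRS
part III total, with the rigidity and postural-stability items 3.3 and
3.12 excluded, as appropriate for virtual exams) on regional FD with age
and sex as covariates, run per region and medication state (180 models
for 90 regions × OFF/ON) with BH adjustment over the whole family. Because
it is genuinely ambiguous whether a reported "R" is a standardized
coefficient or a partial correlation, the output carries both, labelled
`std_coef` and `partial_r`.

## Feature selection and variance analysis

Continuous features are standardized to mean 0 / SD 1 with statistics
fitted on training rows only and applied unchanged to validation and test
rows. Selection is L1-penalized logistic regression (the selector is
scored by classification AUC, which implies a classification loss; a
gaussian loss against the continuous outcome is available) over a
logarithmic grid of 25 shrinkage factors on [10⁻³, 1] (0.03 included),
scored by stratified 5-fold cross-validated AUC; ties go to the stronger
penalty (sparser model). Ridge (L2) refitting on the selected features
yields importance weights `|β| / max|β|` in (0, 1] — chosen so the most
important feature carries weight 1 when the weights become hyperedge
weights; sum-to-one normalization is available behind a flag.

The variance analysis compares two nested OLS models of ΔLEDD — clinical
features only (age, sex 0/1, DBS target STN = 1/GPi = 0, bilateral = 1,
percent OFF→ON motor improvement) versus clinical plus selected FD
regions — via

&nbsp;&nbsp;&nbsp;&nbsp;F = ((RSS₁ − RSS₂)/(df₁ − df₂)) / (RSS₂/df₂),

with df as *residual* degrees of freedom, i.e. the standard nested-model
F-statistic (cross-checked against `anova()` in the tests). A combined
design that adds no independent column is refused rather than reported as
F = 0.

## Hypergraphs and the HGNN classifier

Each selected feature builds one hypergraph over the subjects.
Categorical features (sex, target, hemispheres; any 0/1 encoding)
contribute one hyperedge per category — a partition of the nodes.
Continuous features contribute a k-uniform kNN hypergraph: node *i*'s
hyperedge is *i* plus its k−1 nearest neighbours by absolute difference on
that single standardized feature (distance ties break toward the lower
subject index). There are exactly n hyperedges of size k, and *i* always
belongs to its own hyperedge, so no node is isolated. Per-feature
hypergraphs are concatenated along the hyperedge axis, each hyperedge
inheriting its feature's ridge weight; provenance is retained. The
default k = 12 sits at the plateau of the k = 5..13 sweep that
`tune_k()` reproduces (validation-AUC argmax, ties to smaller k).

The classifier applies spectral hyperedge convolution,
`G = Dv^{-1/2} H W De^{-1} Hᵀ Dv^{-1/2}`, the degree-normalized
node→edge→node aggregation; `G` is provably invariant to global rescaling
of the edge weights and equivariant to node permutation (both asserted to
float tolerance in the tests). Two convolution layers (hidden width 16,
ReLU, dropout 0.3) end in a 2-class output trained with cross-entropy and
Adam (learning rate 0.01, weight decay 5×10⁻⁴, 400 epochs, full batch);
three independently initialized runs are trained and their predicted
probabilities averaged, a small init ensemble that stabilizes the
stochastic optimization.
Node features are the standardized selected columns themselves — the only
subject-level information available at inference. Hypergraphs span all
subjects (the usual transductive setting); labels of validation and test
nodes never enter the loss. There is no GPU dependency: at cohort scale
(n ≤ 500) the dense operator and full-batch backpropagation run in
seconds on one CPU, and all randomness (initialization, dropout) derives
from the config seed, so runs are bit-reproducible.

**Model selection.** Validation AUC is monitored every epoch. Selecting
the raw argmax over hundreds of epochs on a ~35-subject validation set is
badly max-biased — a single lucky epoch wins — so the kept checkpoint
maximizes a 9-epoch moving average of the validation curve, restricted to
epochs after the first quarter of training (the optimization transient).
Reported probabilities average the checkpoints within ±4 epochs of the
selected one, a small checkpoint ensemble that damps single-checkpoint
noise. Test metrics (threshold-free AUC with midrank ties; sensitivity
and specificity at probability 0.5, with the Youden-optimal point
reported alongside) are computed once, on test nodes only.

The outcome run trains two models — clinical features only, and clinical
plus selected FD ("the combined model is the clinical model plus the
selected FD features") — and reports the test AUC gap; the validation run
does the same for the PD-vs-HC contrast using the significant regions,
with ridge weights recomputed for that task.

## What the synthetic data emulates — and what it does not

`gen_fractal_phantom()` provides objects of exactly known dimension
(Menger sponge log 20/log 3, cube 3, shell 2, line 1);
`gen_blob_labelmap()` grows disjoint blobs around jittered lattice seeds
with a roughness parameter whose increase provably raises measured
boundary FD. `gen_case_control_fd()` draws per-region FD values
(Gaussian, means fixed per seed in the plausible 2.0–2.6 band, SD 0.1)
with a planted group difference of d = 1.2 in nine regions — seven
cortical (complexity higher in patients), putamen and pallidum
(lower) — mirroring the structure of a real case-control contrast at
n = 70 + 70.

`gen_cohort()` generates the DBS cohort: n = 231, age 65 ± 9, 33% female,
42% STN targets, 80% bilateral, OFF-state motor scores and a 53 ± 16%
levodopa response. The percent LEDD change is a target-dependent mixture
(STN mean +35, GPi mean +10, within-target SD 25), giving two divergent
medication trajectories, a between-target effect size near 1, and class
frequencies (≈ 90% of STN and ≈ 60% of GPi patients in the `decrease`
class) matching a realistic cohort. On top of the mixture, a planted
FD-borne component (22 percentage points per SD of the aggregated signal
over eight named regions) and a motor-responsiveness component (8 points
per SD) provide the
predictive structure; the residual SD is derived so the within-target
spread stays at 25 whatever is planted. The binary label is produced by
the LEDD module's rule, never re-implemented. The planted FD share was
set so the combined-versus-clinical contrast is *resolvable at desk
scale*: with a 35-subject test set the difference of two correlated AUCs
has a standard error near 0.07, so a population gap of roughly 0.12 — the
qualitative size of the real contrast — is the smallest that a 20-replicate
check can separate reliably. The corresponding planted variance fractions
are larger than real cohorts show; passing these checks demonstrates that
the pipeline recovers structure it should recover, not that real T1-w FD
carries this much signal.

The generators deliberately do not simulate raw T1-w intensities, scanner
or site effects, registration error, correlated FD covariance across
regions, or non-Gaussian tails — so the tests validate the machinery, not
the biology.

## Problem sizes and runtime

Test and acceptance runs use the cohort sizes the design targets
(n = 231 with a stratified 70/15/15 split; 70 + 70 for case-control;
20-replicate contrasts; 1000-replicate null calibrations for the F-test
and severity regressions; 200 for Anderson–Darling), with phantoms at
27³–96³. Everything runs single-threaded; the full suite completes in a few
minutes.

## Known limitations

* FD estimates at 4–7 octaves carry finite-scale bias (see the scaling
  window above); comparisons are meaningful within a fixed schedule, not
  across schedules.
* The HGNN is transductive; classifying a genuinely new subject requires
  rebuilding the hypergraph with that subject included.
* Validation-based model selection with ~35 validation subjects remains
  noisy even with smoothing; occasional replicates select a poor
  checkpoint, which is visible in the spread of the replicate contrasts.
* The LEDD factor table is configuration; site formularies differ, and no
  free-text medication parsing is attempted.
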