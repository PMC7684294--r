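---
title: "Signature expression, somatovisceral classification, and the synthetic cohort model"
author: "painsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature expression, somatovisceral classification, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painsig)
```

## The problem

Multivariate brain signatures — fixed, pre-published weight maps such as the
Neurologic Pain Signature (NPS) — summarize a subject's whole-brain contrast
map as a single scalar. Applied across multi-study cohorts they support three
kinds of questions: does a signature respond to a class of stimuli
(generalizability and sensitivity), can its score classify individual maps
(specificity), and do coarser network-level patterns distinguish stimulus
types that the signature treats alike (e.g. visceral versus somatic pain)?

`painsig` implements the full analysis stack for these questions: signature
expression scoring with effect-size statistics, single-interval and
forced-choice classification, binormal ROC models, a cross-validated
network-similarity logistic classifier, voxel-wise group GLMs with FDR and
minimum-statistic conjunction, and robust brain–behavior regression. Because
the original imaging data are not required to exercise any of this, the
package ships a synthetic multi-study cohort generator with the same
statistical structure, and the whole pipeline is validated against it.

## Signature expression

A subject's signature response is the dot product of the vectorized contrast
map $x$ with the signature weights $w$ over the analysis mask,

$$s_{\mathrm{dot}} = \sum_{v} x_v w_v, \qquad
  s_{\cos} = \frac{\sum_v x_v w_v}{\lVert x\rVert_2\,\lVert w\rVert_2},$$

with the cosine form the default because it damps scale differences between
studies and scanners. Voxel order is the ascending linear index (first axis
fastest), so scores are bit-for-bit reproducible. All cross-map computations
are restricted to the joint valid mask — voxels finite in every image — since
maps pooled from several studies rarely share coverage. No resampling is
implemented: inputs must already be on a common grid.

Per study, `study_signature_stats()` reports the mean response, a two-tailed
one-sample *t* test against zero, and the effect size $d_a$ (mean/SD of the
contrast scores). For contrast-versus-baseline designs the baseline
condition's score is identically zero — the contrast image already encodes
the difference — so $d_a$ reduces to mean/SD and the forced-choice accuracy
to the fraction of positive scores, with ties at exactly zero counted as
incorrect (the conservative choice).

The 95% confidence interval for $d_a$ uses the Hedges–Olkin normal-theory
variance for two independent groups with both group sizes set to the study
$N$:

$$\mathrm{var}(d) = \frac{n_1+n_2}{n_1 n_2} + \frac{d^2}{2(n_1+n_2)},
  \qquad d \pm 1.96\sqrt{\mathrm{var}(d)}.$$

Treating a within-subject contrast as two groups of size $N$ is a
convention, not an inevitability; it is the one this package fixes, and the
multiplier is the fixed normal quantile 1.96 rather than a *t* quantile.
`tests/testthat/test-acceptance.R` pins seven published (d, N, CI) triplets
to this formula at 3-decimal precision.

Spatial similarity between a map and a continuous reference is the Pearson
correlation of their voxel vectors; with a binary parcel mask it is reported
as a point-biserial correlation (numerically the same quantity). Group
inference on similarities is a one-sample *t* test on Fisher-z transformed
values, with means reported back on the *r* scale; $|r| = 1$ is rejected
rather than silently mapped to infinite *z*. Signatures are compared by a
one-way repeated-measures ANOVA on the z-scale similarity matrix
(df $= k-1,\ (k-1)(n-1)$) followed by paired *t* tests against the reference
signature with Bonferroni correction.

## Classification

**Single-interval (pain / no-pain).** One cutoff on the score axis, chosen
to maximize overall accuracy on the data at hand; ties are broken toward the
lowest such cutoff, and candidate cutoffs are midpoints between adjacent
distinct scores plus one sentinel below and above. All rates carry the
binomial standard error $\sqrt{p(1-p)/n}$; the balanced-accuracy SE combines
the class-wise SEs as $\tfrac12\sqrt{SE_{sens}^2+SE_{spec}^2}$.

**ROC.** The empirical AUROC is the Mann–Whitney statistic via midranks
(ties count ½). The binormal model fits a Gaussian per class without an
equal-variance constraint, $\mathrm{AUC} =
\Phi\!\big((\mu_1-\mu_0)/\sqrt{\sigma_1^2+\sigma_0^2}\big)$; under equal
variances this is $\Phi(d_a/\sqrt2)$, which the tests verify.

**Network classifier.** Each map is reduced to seven Fisher-z point-biserial
correlations with the atlas parcels, in fixed atlas order, and classified by
unregularized maximum-likelihood logistic regression (IRLS, deviance
tolerance 1e-8, at most 100 iterations; somatic coded 1). Separation —
diverging coefficients with fitted probabilities at 0/1 — is detected and
surfaced as a warning and a flag rather than silently regularized away,
because a penalized fit would change the estimand. Ten-fold cross-validation
is stratified by class with a mandatory seed; each subject is predicted by
the model not trained on their fold, the final model is the unweighted mean
of the fold coefficient vectors, and the CV report is computed at the
accuracy-maximizing probability threshold. The prospective decision
threshold stays at 0.5 unless the user overrides it, since the choice the
original analysis applied prospectively is not recoverable; both are stored.
When the fold count reaches the sample size the assignment degenerates to
leave-one-out (one subject per fold, seed-independent). Stability is
assessed by repeating the whole CV under independent fold randomizations and
summarizing the SD of classification error and the mean pairwise correlation
of coefficient vectors.

Generalization tests compare the proportion of a held-out study classified
somatic against a null proportion with an exact binomial test using the
doubled-smaller-tail convention, $p = \min(1, 2\min(P(X\le k), P(X\ge k)))$.
The default null proportion is 0.6249; its derivation in the original
analysis is unclear (it matches no obvious training quantity), so it is a
free parameter here. One published comparison (10/15 vs 0.6249, reported as
$P=0.97$) is not reproduced by this convention, which gives 0.965; the
minimum-likelihood convention gives 0.0625 for the 13/15 case and is
rejected because the doubled-tail convention reproduces the published 0.083.

## Voxel-wise group GLM

The second-level model is ordinary least squares per voxel: an intercept, a
modality regressor (somatic = 1), and study nuisance dummies constructed
within modality with one reference study per modality dropped — this coding
is a package choice (the source analyses do not state theirs) and keeps the
dummies orthogonal to the modality effect by construction. Contrast vectors
average per-study means so that "somatic", "visceral" and their combination
are interpretable regardless of study sizes. Voxel *p*-values are two-tailed
at $df = n - \mathrm{rank}(X)$.

FDR thresholding is Benjamini–Hochberg per contrast map (not pooled across
contrasts), with surviving voxels signed by their beta. The conjunction of
two thresholded maps keeps a voxel only when both are significant with the
same sign — the minimum-statistic conjunction read literally as the
intersection of separately thresholded maps; the alternative reading (FDR on
the voxel-wise minimum statistic itself) is deliberately not implemented,
as the intersection is the interpretation that matches "significant in
both". Differential maps are inclusively masked: a somatic-greater voxel is
reported only where the combined stimulation-versus-baseline map is itself
significantly activated (or deactivated, for the deactivation branch), so
the result reads "activation occurs and is stronger for X".

## Robust brain–behavior coupling

Ratings are regressed on signature responses with study covariates by IRLS
with Tukey's bisquare loss: tuning constant 4.685, scale re-estimated each
iteration as MAD/0.6745, coefficient tolerance 1e-8, at most 50 iterations —
the de-facto standard configuration of robust regression toolboxes in this
field; both loss and tuning are configurable since no single convention is
canonical. With `tuning = Inf` the fit reduces exactly to OLS (the tests pin
this). Coefficient covariance uses the standard M-estimator form
$\widehat\sigma^2 = \frac{\sum \psi(r_i)^2/(n-p)}{(\frac1n\sum\psi'(r_i))^2}$
on $(X'X)^{-1}$ without a small-sample correction factor; several
conventions exist and published SEs are not reproducible without knowing
which one was used, so this one is documented and validated against its own
oracle and against an independent IRLS implementation. The final weights are
reused for the weighted correlation: both variables are residualized against
the covariates by weighted least squares with the same weights, then
correlated with those weights; with equal weights and no covariates this is
ordinary Pearson correlation. Rest-condition ratings are defined as zero for
designs that collected none.

## The synthetic cohort generator

`simulate_cohort()` draws, per subject,

$$x_i = \mathrm{offset}_{study} + a_i\,W \;+\; \sum_k g_k(\mathrm{modality})\,
  \mathrm{parcel}_k \;+\; \varepsilon_i,$$

where $W$ is a planted unit-norm signature (parcel loadings plus a smoothed
random field), $g$ are modality-specific network loadings, and
$\varepsilon_i$ is Gaussian noise smoothed to FWHM 2 voxels — spatial
autocorrelation is required for the GLM and conjunction stages to behave
realistically. Smoothing uses separable circular convolution, which keeps
the filter exactly variance-preserving; that makes the SD of the noise
projection onto $W$ analytically computable
($\sigma_{score} = \sigma_\varepsilon \lVert G w\rVert_2 / \lVert g\rVert_2$,
with $G$ the kernel), so amplitudes can be planted on the true score scale:
$a_i \sim N(d_{true}\,\sigma_{tot}, \tau)$ with
$\sigma_{tot}^2 = \sigma_{score}^2 + \tau^2$, making the population effect
size of the dot score exactly $d_{true}$. Parameter-recovery tests confirm
the estimator is unbiased at this calibration.

Default study conditions mirror a seven-study somatovisceral cohort: four
visceral studies (gastric, two rectal, esophageal) and three somatic
(vulvar, two thermal) with $N$ = 15, 15, 29, 15, 30, 28, 33 and planted
per-study effect sizes 1.20–3.74, on a 12×12×12 grid with unit noise SD.
Between-subject amplitude SD equals the score-noise SD
(`amplitude_sd = 1`), so individual differences and scan noise contribute
equally to score variance. Ratings live on a 0–100 VAS-like scale:
$b\,a_i + N(0, 10)$ with $b$ set to 7 VAS points per amplitude SD, which
makes the expected rating–score correlation ≈ 0.4 — the realistic regime
for individually calibrated stimulation; baseline ratings are zero.

The atlas is a Voronoi parcellation of seven seed voxels, tiling the
*interior* of the grid (a one-voxel border is left out). The border
matters: if the parcels tiled every voxel their indicators would sum to one
everywhere, the seven Fisher-z features would be near-collinear, and the
multivariate logistic coefficients would be unidentified in practice — as
in the real setting, the networks must cover a proper subset of the
analysis mask. The modality loading vectors encode the somatovisceral
double dissociation (somatomotor and attention networks for somatic,
frontoparietal for visceral, default-mode deactivation for both, stronger
for somatic), with magnitude `gamma = 0.4` calibrated once so that the
best-separating network's feature separates the modalities by about 2
pooled SDs on the default grid. Under these defaults the population
discriminant coefficients reproduce the expected sign pattern
(+somatomotor, +dorsal/ventral attention, −frontoparietal, −default). At
the training size of 48 subjects the honest unregularized fit still flips
the sign of a weaker coefficient in roughly one replicate in ten under the
full seven-network mixture — a small-sample property of correlated
features, not a bug; the sign-recovery test therefore plants the pure
two-parcel double dissociation it asserts about.

What the generator does **not** emulate: anatomy, hemodynamics and
time-series structure (maps are drawn directly at the contrast level),
realistic spatial covariance beyond stationary Gaussian smoothing,
inter-study registration error and coverage differences (grids are shared
and complete unless the user plants missingness), and any mixture structure
in "ambiguous" stimulation types — in these simulations each study is
purely somatic or purely visceral. Passing tests therefore demonstrate
correctness of the estimators and error control under the assumed
statistical structure, not performance claims about real fMRI data.

## Two-stage pipeline

`run_pipeline()` chains the stages from one validated config: signature
scoring; stage 1, single-interval pain/no-pain classification of every map
(the default simulated cohort includes two no-pain control studies for
this); stage 2, the somatovisceral classifier trained with CV on the
designated training studies (defaults: the first rectal and second thermal
study) and applied prospectively to every map stage 1 classified as pain;
then the optional GLM/conjunction and brain–behavior stages. Every random
stage derives its seed from the master seed, outputs are plain text
(CSV/JSON/YAML) plus NIfTI maps, and a run is byte-reproducible from its
stored config — the tests pin this.

## Numerical choices and degenerate inputs

* Convergence: logistic IRLS 1e-8 on deviance (100 iterations); robust IRLS
  1e-8 relative coefficient change (50 iterations), non-convergence warns
  and returns the last iterate; exact fits short-circuit with unit weights.
* Tie-breaks: accuracy-maximizing cutoffs take the lowest maximizer;
  forced-choice ties count against the classifier; atlas distance ties go
  to the lowest parcel index.
* Degenerate inputs error loudly instead of returning NaN: zero-variance
  scores, zero-norm maps under cosine scaling, $|r|=1$ under Fisher-z,
  constant references, empty masks, rank-deficient designs, parcels that
  are empty or cover the whole mask, all-zero weights.
* Problem sizes in the test-suite simulations (8³–12³ grids, 10–100
  replicates) are chosen as the smallest at which the planted structure is
  comfortably identifiable; they are package choices, and all scale up by
  changing the config.

## Known limitations

Single fixed grid per analysis (no resampling); binary modalities only; no
penalized or hierarchical variants of the classifier or the rating model;
conjunction only in its intersection form; no cluster-extent inference or
anatomical labeling. Real weight maps and atlases load through the same
NIfTI interfaces as the synthetic stand-ins, but all inputs must be
pre-aligned.
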