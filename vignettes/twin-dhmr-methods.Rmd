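---
title: "Methods: paired DhMR discovery, validation and generalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired DhMR discovery, validation and generalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical model, the
choices that were genuinely open when it was designed, and what its tests
do and do not establish. It states no empirical result beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## The count model

All inference is on fragment counts. For region (or window) $r$ and
sample $s$ the model is negative binomial with log link:

$$y_{rs} \sim \mathrm{NB}(\mu_{rs},\ \alpha_r), \qquad
\log \mu_{rs} = \log f_s + \beta_{0r} + \gamma_{r,\mathrm{pair}(s)}
  + \delta_r\, \mathrm{case}(s) + \boldsymbol{x}_s^\top \boldsymbol{\eta}_r,$$

with variance $\mu + \alpha\mu^2$, library size factors $f_s$
(median-of-ratios over windows with all-positive counts, entering as
offsets), a fixed effect $\gamma$ per twin pair, the group effect
$\delta$ of interest, and optional covariates $\boldsymbol{x}$. The group
test is an analysis of deviance: the full and reduced (no group) models
are fitted by IRLS at a shared, fixed dispersion and the deviance
difference is referred to $\chi^2_1$.

**Why a pair fixed effect.** The matched design is the point of a
discordant-twin study: the pair factor absorbs everything co-twins share,
germline included. With 12 pairs x 2 samples the 12 pair means are
estimable, and offset shifts applied to both members of a pair provably
leave the group test unchanged (this is a unit test). A consequence of
exact matching: covariates constant within every pair — age, since
co-twins share a birth date — are collinear with the pair factor and are
dropped from both nested models automatically. Under a pair-factor
design with exactly matched ages, the age-adjusted model therefore
coincides with the leukocyte-adjusted one; the age term becomes active
when pairing is disabled (`include_pair_factor = FALSE`) or ages differ
within pairs.

**The three covariate models.** Model 1 fits no covariates beyond the
pair factor; model 2 adds the five leukocyte fractions (CD8+ T, CD4+ T,
NK, B cells, monocytes — granulocytes are the unit-sum remainder and are
omitted to avoid near-perfect collinearity); model 3 adds age. A region
is selected in phase 1 only when q <= 0.01 (Benjamini–Hochberg within
each model, across regions — not pooled across models) in *all three*
models with the *same sign* of the fitted group effect. Directional
consistency is judged on the fitted group coefficients because only they
respond to covariate adjustment; the package additionally reports the
observed effect $\log_2\!\big[(\bar{y}^{\mathrm{case}}/f + 0.5) /
(\bar{y}^{\mathrm{ctrl}}/f + 0.5)\big]$ (the 0.5 pseudocount guards
against zero means) as its primary `log2fc` column.

## Dispersion estimation

Per-region dispersion comes from a Pearson moment-matching estimator:
with $\hat\mu$ from the Poisson fit of the full design ($p$ columns, $n$
samples), $\hat\alpha$ solves

$$\sum_s \frac{(y_s - \hat\mu_s)^2}{\hat\mu_s + \alpha \hat\mu_s^2}
  = n - p - 1,$$

floored at $10^{-8}$ (under-dispersed regions degrade to Poisson). One
degree of freedom is reserved for the dispersion parameter itself;
without it the estimate is biased low at 24 samples and 13+ parameters,
which visibly inflates the deviance test (simple residual-moment
estimators produced a 5–6% null rate at p < 0.01 in calibration runs;
the df-reserved estimator restores uniform null p-values — this
calibration is itself an acceptance test). Within `discover_phase1()` and
`validate_phase2()` the per-region estimates are additionally *moderated*:
shrunk toward the cohort median with 20 prior degrees of freedom,

$$\alpha_r^{*} = \frac{d_0\,\tilde\alpha + d_r\,\hat\alpha_r}{d_0 + d_r},
\qquad d_0 = 20,$$

the same borrowing-strength logic as common/tagwise dispersion estimation
in standard count-based differential analysis. The moderated value is
shared by the full and reduced fits and across the three covariate models
of a region, so deviance differences isolate the group term and
cross-model selection compares like with like. `anodev_group_test()`
called standalone estimates its own per-region value.

## The three phases

* **Split.** MZ pairs are split at the pair level, 12 training + the
  rest validation (defaults match the study design of 19 MZ and 19 DZ
  pairs); DZ pairs are reserved for generalization. The split is uniform
  given the seed and never separates co-twins.
* **Phase 1** runs on training pairs only — region calling included, so
  the validation cohort stays untouched until phase 2.
* **Phase 2** re-tests each selected region on the validation pairs and
  keeps those with nominal p <= 0.01 (boundary inclusive) and a
  validation effect of the training sign. The default validation test is
  the *pair-matched model 1*, a deliberate deviation from re-running the
  fully adjusted model: with 7 pairs (14 samples) the model-3 design
  leaves one residual degree of freedom and essentially no power (in
  pilot runs, planted effects of |log2FC| 1.5–2.7 received p between
  0.013 and 0.08 and would have been discarded), while covariate
  robustness is already enforced by the phase-1 all-model rule. The
  fully adjusted validation remains available via `model = 3`.
  Dispersions are re-estimated on the validation cohort rather than
  carried over, since library depths and biological noise need not match
  the training cohort.
* **Phase 3** freezes the PCA fitted on all MZ pairs (configurable to
  training-only): the transform object stores the feature centering and
  scaling, the PCA centering, and the orthonormal loadings, and is
  applied verbatim — never refitted — to the DZ cohort.

## Features, PCA and dimension selection

Classifier features are per-region z-scores of
$\log_2(\text{normalized count} + 1)$; the log stabilizes the NB
variance and the z-score stops high-abundance regions from dominating
the covariance. The choice is frozen inside the transform so projection
cohorts use the fitting cohort's center and scale verbatim.
Zero-variance regions are dropped at fit time with a warning. Loadings
follow a deterministic sign convention (the largest-magnitude entry of
each column is positive), so runs are reproducible across BLAS builds.

Component selection replaces a visual judgement with a deterministic
criterion: among the first 10 components, rank by the absolute
standardized mean difference between cases and controls of the fitting
cohort scores and take the top two (ties to the lower index). The
selection can be overridden (`manual_dims`) when an analyst prefers a
visually chosen pair.

## The single-unit classifier

One unit, output $\tanh(w_1 s_1 + w_2 s_2 + b)$, targets $\pm 1$,
full-batch gradient descent on squared error. Hyperparameters (learning
rate 0.05, at most 5000 epochs, initialization uniform on $(-1, 1)$,
1000 restarts) are fixed defaults, all configurable and all logged in
the returned object. All restarts are trained simultaneously
(vectorized) from one seed; the returned classifier maximizes
(sensitivity, AUC, specificity) lexicographically on the fitting
cohort. In practice the squared-error surface for 2-D inputs has
essentially one basin up to scale, so the restarts are chiefly a
determinism device — which is exactly their role: a linear boundary with
multiple equivalent solutions is pinned to one reproducible choice.
Predictions threshold the unit output at zero; AUC uses the rank
(Mann–Whitney) form on the continuous output with ties counting one
half. Any strictly monotone transform of the output — including using
the pre-activation instead — leaves the AUC unchanged (property-tested),
so nothing hinges on the saturating activation.

The boundary $w_1 s_1 + w_2 s_2 + b = 0$ is reported as slope
$m = -w_1/w_2$ and intercept $c = -b/w_2$, and decomposed relative to
the vertical reference boundary through the origin: a clockwise rotation
by $\theta = \mathrm{atan2}(1, m)$ followed by a vertical translation of
$c$. The identity is checked numerically on every call (rotating the
vertical direction clockwise by $\theta$ must land on a line of slope
$m$ to $10^{-9}$); for example, slope 0.214 and intercept 0.664
decompose to (77.92 degrees, 0.664). A vertical target boundary is a
flagged special case with the translation reported along the first
score axis.

## Annotation conventions

Assignment is by region midpoint — forcing exactly one category per
region so the summary table partitions — with precedence promoter-TSS >
TTS > exon > intron > intergenic. The promoter window is −1000..+100 bp
around the TSS and the TTS window −100..+1000 bp, both strand-aware and
configurable. Within exon hits, 5'UTR and 3'UTR (from CDS extents)
outrank coding exon; exons of non-coding transcripts map to the
`non-coding` category. Gene types map from raw biotypes through an
explicit dictionary (`default_biotype_map()`); unmapped biotypes become
`other`. Percentages are emitted at full precision twice over: category
shares of each column total, and gene-type shares within each category.

## The synthetic generator

`simulate_cohort()` draws exactly the structure the analysis assumes:
NB counts with a log-link mean combining a baseline, a per-pair
*per-window* random effect shared by co-twins (within-pair correlation
of local 5hmC), lognormal library scaling of a given CV, Dirichlet
leukocyte fractions with granulocyte-dominant means typical of adult
blood, pair-shared ages uniform on 55–65, optional global confounding
linking one covariate to all window means, and spiked intervals whose
case co-twins (of carrier pairs, per penetrance) are shifted by the
requested log2 fold change. Defaults — a 5 Mb two-chromosome toy genome,
19 MZ + 19 DZ pairs, 50 bp windows, 200 bp fragments, baseline 20
fragments/window, dispersion 0.3, pair-effect SD 0.3, library CV 0.2 —
are chosen once for statistical power at desk scale; genome-wide scale
is a configuration choice, not a requirement.

With `emit_fragments = TRUE` the generator instead draws per-window
fragment anchors from the same law, lays 200 bp fragments uniformly
within each anchor window (clipped at chromosome ends, with a message),
and *defines* the count matrix by binning them — so
`bin_fragments(emit_fragments(cohort))` reproduces the counts exactly,
by construction, and the round trip tests the binning code rather than
the generator. In this mode the marginal law of a window count is a sum
over neighboring anchors; the clean NB marginal holds in the default
(count-level) mode, which is where the moment-recovery tests run.

What the generator does **not** emulate: GC or mappability bias, capture
chemistry, fragment-length variation, read-level sequence content, or
correlated baseline structure along the genome. Passing tests therefore
establish the pipeline's statistical behavior under its own model
assumptions, not performance on real enrichment data.

## Numerical and boundary conventions

* Coordinates are 0-based half-open (BED) everywhere in the public
  interface; `GenomicRanges` does interval work internally.
* Windows tile from 0 in steps of 50 bp; the final window is truncated
  at the chromosome end. A fragment counts in every window it overlaps
  by at least 1 bp; read starts extend 200 bp in the 5'→3' direction.
* A join gap exactly equal to 200 bp joins (<=, not <); a merged region
  of exactly 150 bp is kept.
* Sample cutoffs: smallest integer c with
  (expected windows at >= c under Poisson at the sample's mean rate) /
  max(observed, 1) <= 0.05; an all-zero sample gets cutoff 1 with a
  warning and can never nominate a window.
* The per-count-level FDR rule is stratified BH by integer-rounded mean
  normalized count, with signal defined at or above the lowest level
  whose minimum q falls below 0.10. This interpretation is isolated in
  `filter_noise_windows()` so alternatives can be swapped.
* GLM convergence: IRLS to relative deviance change 1e-10, at most 100
  iterations; non-converged or rank-deficient region fits are flagged,
  carried with p = 1 and excluded from selection.
* BH is delegated to `stats::p.adjust(method = "BH")` behind a
  validating wrapper; tests compare it against a literal step-up
  implementation.

## Problem sizes used by the tests

The suite simulates at desk scale, chosen so the full run stays in the
minutes range: 5000-window matrices for filter calibration, 2000 null
regions for ANODEV calibration, 500-region cohorts (20 spiked) for
recovery — with sensitivity estimated over replicate cohorts, since a
single 12-pair draw has substantial luck-of-the-covariates variance —
and a 0.5 Mb bundled end-to-end fixture. The determinism checks compare
byte-identical run summaries across repeated runs.

## Known limitations

* The $\chi^2_1$ reference for the deviance test is asymptotic; at 7
  validation pairs even the pair-matched model is near its small-sample
  limits, and the calibration tests document (rather than remove) the
  residual approximation error.
* The leukocyte-covariate models spend 5 of ~11 within-pair degrees of
  freedom on nuisance terms; with 12 pairs this costs real power and is
  inherent to the design, not the implementation.
* Midpoint annotation ignores regions spanning category boundaries by
  construction.
* The classifier is intentionally minimal — no regularization, no
  cross-validation — because its role is a reproducible linear boundary
  on two scores, not a general-purpose learner.
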