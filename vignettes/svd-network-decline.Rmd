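---
title: "Structural network decline and cognition in small vessel disease: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural network decline and cognition in small vessel disease: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Cerebral small vessel disease (SVD) — visible on MRI as white matter
hyperintensities (WMH), lacunes and microbleeds — is the leading vascular
contributor to cognitive decline and dementia in older adults. A central
mechanistic hypothesis is that SVD acts by disrupting the brain's white
matter *network*: diffusion tractography yields a weighted graph over grey
matter regions, and SVD-related damage should register as falling
connection strength and integration, particularly among the densely
interconnected hub regions known as the *rich club*. `svdnet` implements
the complete analysis chain for testing that hypothesis in a two-wave
longitudinal cohort: connectome construction, graph measures, the
rich-club connection-class decomposition, composite cognition scores,
longitudinal change statistics, and mediation models linking WMH burden to
cognitive decline and dementia through network measures.

Because cohort data of this kind are typically shareable only on request,
the package pairs the analysis chain with a synthetic cohort generator
whose defaults are calibrated to published population parameters; every
analysis stage can therefore be validated against known injected effects.

## Connectome model

Nodes are the 90 cortical and subcortical regions of the AAL parcellation
(cerebellum excluded). The connection weight between regions $i$ and $j$
is the scaled sum of inverse streamline lengths over all tractography
streamlines terminating in the pair:

$$w_{ij} = s \sum_{k \in \text{streamlines}(i,j)} \frac{1}{l_k},$$

with $l_k$ the streamline length in mm and $s$ a subject-level
seed-density correction. Summing $1/l$ rather than counting streamlines
corrects deterministic tractography's linear bias towards long fibres.
Weights below a threshold (default 1) are zeroed to suppress
noise-driven spurious connections. The seed-density factor has no
standard closed form (it depends on acquisition geometry), so the package
takes it as a given per-subject positive constant, default 1; weights are
therefore in units of 1/mm up to that constant.

Graph measures follow the standard weighted-connectome conventions:

* **degree** — number of connections of a region;
* **density** — present connections over $n(n-1)/2$ possible;
* **total strength** — sum of weights over undirected edges;
* **global efficiency** — $\frac{1}{n(n-1)} \sum_{i \ne j} 1/d_{ij}$,
  where $d_{ij}$ is the weighted shortest-path length with per-edge
  length $1/w$; disconnected pairs contribute 0. Shortest paths are
  delegated to igraph; the test suite verifies the result against a
  brute-force Floyd–Warshall oracle to $10^{-9}$. Whether efficiency is
  computed on weighted or binarized matrices is a genuine degree of
  freedom in the field's toolboxes; the weighted form is the default and
  a `weighted = FALSE` flag gives hop-count efficiency.

The rich club is fixed a priori — bilateral superior frontal gyrus,
precuneus, superior parietal gyrus and insula — rather than detected from
normalized rich-club coefficient curves; `degree_rank_report()` provides
the empirical check that these regions indeed rank among the
highest-degree nodes. Edges are classed as *rich-club* (both endpoints in
the club), *feeder* (exactly one) or *peripheral* (neither); a class's
strength is the mean weight of its *present* edges, and an empty class is
reported missing, never 0 — averaging absent edges as zeros would
conflate sparsity with weakness.

## Cognition model

Raw test scores from both waves are z-scored against the mean and SD of
the *baseline* population, so change scores are in baseline-SD units. For
timed tests a speed–accuracy trade-off (SAT) score is used, defined here
as correct responses per second (the conventional form; the package
exposes it as a replaceable hook since published batteries differ).
Stroop interference is the colour-word SAT divided by the mean of the
reading and naming SATs; under the SAT convention lower values mean more
interference, and the score is used as-is. The verbal series attention
test enters executive function without sign inversion by default — its
SAT already points in the better-is-higher direction — with an
`invert_vsat` option for batteries scored the other way.

Composites are arithmetic means of constituent z-scores: the cognitive
index over all 13 derived test scores; memory (verbal learning and
complex-figure recall, 2/3-letter memory scanning SATs); psychomotor
speed (1-letter memory scanning, Stroop reading and naming, symbol-digit
substitution); executive function (Stroop interference, fluency, verbal
series attention SAT). A composite uses whatever constituents are
non-missing (minimum one); complete-case filtering is deferred to the
statistics layer, which records its n per output.

## Longitudinal statistics

With two waves, the repeated-measures ANOVA time effect is identical to a
paired t test ($F = t^2$), and the group-by-time interaction is identical
to a two-sample t test on per-subject change scores;
`paired_change_test()` and `group_time_interaction()` exploit these
identities (the latter is still computed as a within-subject-stratum
ANOVA, with the t-test identity used as a test oracle). Severity strata
come from a median split of baseline WMH volume; ties go to the mild
stratum — deterministic and conservative for the severe group. WMH
volumes are log-transformed before regression because of their strong
right skew. Association tables use standardized betas: outcome and
continuous predictors are z-scored on the analysed complete cases before
ordinary least squares. No multiple-testing correction is applied; raw
p-values are reported.

## Mediation model

`fit_mediation()` fits the single-mediator triangular model: path $a$
from `m ~ x + covariates`, paths $b$ and $c'$ from
`y ~ m + x + covariates`, indirect effect $a \cdot b$, on standardized
continuous variables. A binary outcome (dementia) is modelled by default
as a linear-probability model, which keeps the product identity
$\text{total} = c' + a b$ exact (verified in the tests to $10^{-9}$); a
probit option exists but its indirect effect lives on the latent scale.
Inference for the indirect and direct effects is a nonparametric
percentile bootstrap (default 2000 resamples) resampling subjects, with
standardization recomputed within each resample; the Sobel normal-theory
test is reported as a cross-check. Bootstrap CIs are suppressed below 500
resamples. All fits are reproducible given data and seed.

## The synthetic cohort generator

`generate_cohort()` draws a complete two-wave cohort from one master seed
(routed through named substreams — demographics, networks, cognition,
dementia — so modules can be regression-tested independently). Its
defaults are the study conditions the package is calibrated to:

* n = 270 subjects, two waves 3.4 ± 0.2 years apart; age 67.9 ± 7.8 y,
  59.6% male, education 10.1 ± 1.5 y.
* Baseline WMH volume log-normal with median 2.8 ml and IQR 1.3–7.8 ml,
  fitted by matching the median exactly and the quartile ratio
  ($\sigma = \log(q_3/q_1) / (2 \Phi^{-1}(0.75))$); a latent burden
  variable drives WMH, Poisson lacune and microbleed counts (calibrated
  to 25.4% / 17.3% prevalence of at least one), hypertension, and
  network weakening.
* Baseline connectomes perturb a distance-penalized random geometric
  template graph (density target 0.20) in which the 8 rich-club regions
  carry a hub premium on their connection probabilities and the 28
  club-internal edges are always present; the generator redraws until all
  8 rich regions rank in the top-12 degrees and errors if the
  configuration cannot achieve it. Edge weights are gamma-distributed
  around per-class means (rich 12, feeder 6, peripheral 4, in 1/mm),
  floored at 2.5 so that decline never crosses the edge threshold of 1,
  scaled per subject by a log-normal factor that shrinks with burden.
* Follow-up matrices apply per-class multiplicative decline scaled so
  that each subject's class mean strength falls by exactly its drawn
  decline: rich-club −0.44 ± 1.5, feeder −0.03 ± 0.40, peripheral
  −0.02 ± 0.18 over the follow-up interval (the spread chosen so the
  n = 270 confidence intervals match the calibration source's widths).
  Decline correlates −0.3 with the WMH progression latent. Decline
  parameters are defined per follow-up interval, not per year, because
  the calibration anchors are interval changes.
* Cognitive composite change is a linear function of standardized
  peripheral-strength decline (effect 0.35) with a configurable *direct*
  WMH effect defaulting to 0 — the mediation of cognition by network
  decline is complete by construction. Dementia at follow-up is
  Bernoulli with log-odds linear in standardized baseline global
  efficiency (−0.6) and peripheral strength (−0.5), the intercept solved
  so the in-sample mean probability equals 23/329, and a direct WMH term
  defaulting to 0.

What the generator deliberately does **not** emulate: edge count changes
over time (density is constant across waves by construction, whereas real
cohorts show small density declines — the price of keeping the per-class
decline recovery exactly unbiased); per-subject variation in which edges
exist (all subjects share the template topology at baseline); distinct
mediating roles for the different baseline class strengths (they are
strongly collinear here, so the dementia mediations through rich-club,
feeder and peripheral strength behave alike, unlike in real data);
attrition, practice effects, scanner drift, or any image-space process.
Passing tests on this cohort therefore demonstrate that the pipeline's
estimators recover known effects embedded in realistic marginal
distributions — not that the generator is a faithful model of SVD.

Raw-test mode (`raw_tests = TRUE`) synthesizes a full neuropsychological
battery from the composite-level scores (constituent test z = domain
score + scatter, timed tests expressed as item counts and completion
times, the Stroop colour-word condition back-computed from a target
interference ratio). Module-computed composites then *track* the
generated composites (r ≈ 0.9) rather than reproduce them exactly; the
mode exists to exercise the cognition module end-to-end, and the
composite columns remain the ground truth.

## Numerical and design choices

* Thresholding keeps weights exactly at the threshold (`w < t` is
  pruned, `w == t` retained).
* Degenerate paired tests (all change scores identical) return p = 1 at
  zero mean difference rather than NaN.
* Dense ranking for degree ties: tied degrees share a rank, so "top-k"
  means "among the k largest distinct degrees".
* Median-split ties go to mild; an all-constant marker is an error, not
  an arbitrary split.
* Bootstrap p-values are the usual two-sided percentile inversion,
  `2 * min(P(stat <= 0), P(stat >= 0))`, capped at 1.
* Resamples in which a variable degenerates to zero variance are dropped
  from the percentile CI (counted in `boot$n_effective`).
* The run manifest hashes the configuration (32-bit FNV-style) and
  records per-stage row counts and exclusion reasons; manifests are
  written even when a stage fails. Output tables contain no timestamps,
  so identical config + seed give byte-identical tables.

## Problem sizes used by the shipped checks

The test suite validates graph measures on 200 random graphs (n ≤ 12)
against brute-force oracles, partition completeness on 500 random
matrices, the two-level ANOVA identities on 100 random data sets,
standardized-regression recovery on 200 simulations at n = 270,
mediation recovery on 200 replicates at n = 500 with 2000 bootstrap
resamples (plus 200 full-mediation replicates at n = 400), and
generator-level decline recovery over 50 seeds at n = 270 plus one
n = 2000 WMH calibration draw. These sizes keep the full suite within a
few minutes on one CPU while leaving Monte-Carlo error well below the
tolerances being asserted.

## Known limitations

Tractography, registration and segmentation are out of scope: the
package starts from streamline endpoint records and takes the
seed-density factor as given. The mediation model is a single-mediator
triangular path model — no latent variables, no multiple mediators, no
FIML handling of missingness (complete cases throughout). The
linear-probability outcome model can in principle predict probabilities
outside [0, 1]; for the rare-outcome, standardized-predictor settings it
is used in here that is a second-order concern, and the probit flag is
available where it matters.
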