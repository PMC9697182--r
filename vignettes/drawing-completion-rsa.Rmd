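---
title: "Quantifying drawing-completion behavior with representational dissimilarity"
author: "drawrsa authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drawing-completion behavior with representational dissimilarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drawrsa)
```

## The task and the measurement problem

In a drawing-completion task a child is shown a partial drawing — the
outline of an object, its inner features, or those inner features in
scrambled positions — and draws freely on it. The task probes how the child
integrates what is on the page (bottom-up, sensory evidence) with what the
child expects or prefers to draw (top-down priors). Twelve stimuli are used:
four object categories (face, house, car, human figure) crossed with the
three presentation conditions. Each participant receives one of four
prepared sets of six stimuli (two per condition, no category more than
twice).

Two complementary measurements are implemented:

* **Crowd ratings.** Adult raters score seven statements per drawing on a
  0–100 scale (two completion statements, two scribbling statements, one
  each for tracing, coloring, and whether the produced part relates to the
  presented part), plus a known-answer question about the object category of
  the presented part, used for rater quality control.
* **Convolutional features.** Drawings are passed through a VGG-style
  network and compared with the Pearson correlation distance between layer
  activations,

  $$ d(x_i, x_j) \;=\; 1 - \frac{\operatorname{cov}(x_i, x_j)}
     {\sqrt{\operatorname{var}(x_i)\,\operatorname{var}(x_j)}} \in [0, 2], $$

  at seven analysis layers (`pool1`–`pool5`, `fc6`, `fc7`), ordered from
  local to global features. Pairwise distances between per-stimulus average
  feature vectors form a representational dissimilarity matrix (RDM); the
  mean off-diagonal entry of a child's own 6×6 RDM (the *RDM score*)
  measures how distinctly that child adapted to different stimuli.

Because the original museum cohort is external data, the package ships a
synthetic cohort generator that reproduces the statistical structure the
analysis relies on, with the generative ground truth exposed for recovery
testing.

## The synthetic cohort model

Each child agent has an age (months, uniform over 25–99), a drawing-style
mixture over `{none, scribble, trace, color, complete, off_target}`, an
adaptation probability $\alpha \in [0,1]$, a fixed off-target motif, and a
latent questionnaire propensity. A drawing is simulated by sampling a style
from the mixture; with probability $\alpha$ the strokes are conditioned on
the stimulus (completion adds the complementary template strokes; tracing
re-draws the presented strokes with jitter; coloring hatches the dominant
enclosed region; scribbling stays inside the stimulus bounding box), and
with probability $1-\alpha$ the agent draws its fixed motif regardless of
the stimulus. Adults always complete with $\alpha = 1$ and draw on every
stimulus, twice with probability 0.8 (five adults, about 108 drawings).

Style mixtures follow logistic age trends on a softmax scale
(`cohort_params()`): the completion logit rises and the scribbling logit
falls with scaled age $z = (\text{age} - 55)/16$; the other styles have
constant logits. The mean of $\alpha$ follows its own logistic trend. The
defaults were chosen once so that the cohort reproduces the qualitative
developmental pattern of the emulated study: scribbling dominates before
about age 3.5, completion dominates after about age 5.5, and the oldest age
group (68+ months) behaves near-adult-like, so that its group RDM is only
marginally distinguishable from the adult reference while the younger
groups differ clearly. The trends are deliberately steep: the synthetic
styles (star motifs, dense hatching) are far more extreme in feature space
than real children's drawings, so a milder mixture would exaggerate
child–adult differences at the group level relative to the study being
emulated. Child completions are jittered with SD 0.008 canvas units; adult
completions use 0.012, reflecting free-hand repetition.

Raters score each statement at a style-conditional mean (85 where the
statement matches the drawing's true style, 10 otherwise, with the
relatedness statement high for adapted completion/tracing/coloring) plus
Gaussian noise (SD 10 by default), clipped to $[0, 100]$; their
known-answer accuracy is drawn from a Beta(9, 1.2), giving mostly reliable
raters with a careless tail that the >70 % quality-control rule removes.
Questionnaire sheets have 50 binary items drawn from the child's
propensity, with 3 % per-item missingness.

What the generator does **not** emulate: perceptual realism of strokes,
motor development, pen dynamics, semantic content of off-target drawings,
and rater biases beyond independent Gaussian noise. Passing recovery tests
therefore shows that the pipeline's statistics recover the structure the
generator encodes — not that the feature extractor would behave identically
on real scans.

## Scoring rules

Ratings of raters whose known-answer accuracy is not strictly above 70 %
are discarded entirely. Statement scores are averaged within rater, then
across raters; the completion score is the rater-mean of
$\tfrac{1}{2}(s_1 + s_2)$ and the scribbling score of
$\tfrac{1}{2}(s_3 + s_4)$. Drawings with an empty produced layer are
assigned 0 on every statement regardless of any ratings. Style sets collect
drawings whose average style score is strictly above the cutoff (70 by
default; 60 and 80 as robustness variants). The questionnaire total is
scaled by $50/n_\text{answered}$ when at least 40 of 50 items are answered
and is missing otherwise; totals of 32 or more are flagged, never filtered.
A child's dominant style is the argmax of the per-child mean style scores,
with exact ties broken in the fixed order completion > scribbling > tracing
> coloring.

## Image processing and the backbone

Drawings render at 224×224 px (stroke width 2 px; any canvas size is
supported — 512 px with width 3 gives the same analysis after the bilinear
resize to 224×224). Presented strokes are black, produced strokes blue.
Before feature extraction blue is recolored to black (channel-dominance
rule with a 40-intensity margin, exact for the renderer's pure blue and
tolerant of anti-aliased scans). For same-stimulus comparisons (the
style-versus-adult analysis) the full recolored drawing is used; for
across-stimulus comparisons (all RDMs) the presented layer is removed at
the stroke level — the produced layer is re-rendered alone, which avoids
halo artifacts that pixel subtraction would leave at stroke crossings.
Inputs are mean-centered per channel using the backbone's constants.

The default backbone (`make_test_backbone()`) is a narrow VGG-style
network: five conv(3×3)+ReLU+maxpool(2×2) blocks with 4, 8, 8, 16, 16
channels and two 128-unit fully connected layers, with He-scaled Gaussian
weights fully determined by a seed. Random convolutional features preserve
image geometry well enough for *relative* dissimilarity comparisons, which
is all the analysis uses; no classification is ever performed. A pretrained
VGG19 can be plugged in from a local weights file
(`load_pretrained_backbone()`), exposing the identical seven-layer
interface; it is optional and never required by the tests. Features are
taken after each layer's ReLU, the usual convention for activation-based
representational analysis.

## Statistics

* **Distance conventions.** Population (divide-by-$n$) moments are used in
  the Pearson distance; the ratio is identical under the sample convention.
  If a feature vector is constant (e.g. an empty drawing's all-white image
  yields constant activations) the distance is undefined; it is totalized
  as 0 when both vectors are constant and equal and 2 otherwise, with a
  warning, so that downstream matrices remain total.
* **Group RDMs** average feature vectors per stimulus within a group, then
  take pairwise distances (average-then-distance, 12×12). The
  `block_contrast()` summary — mean between-category minus mean
  within-category off-diagonal distance — formalizes the near-diagonal
  clustering visible in adult-like RDMs.
* **Group versus adult.** The paired difference of off-diagonal entries is
  tested by sign-flip permutation of the paired differences with statistic
  $|\overline{d}|$ and the add-one two-sided p-value
  $(1 + \#\{|\overline{d}^\ast| \ge |\overline{d}|\})/(1 + B)$. A paired
  permutation is used because RDM entries share stimuli and are not
  independent, which would invalidate a two-sample t-test. No correction
  across the four age groups is applied; the output flags this.
* **Mixed models.** Fixed-effect terms are tested by likelihood-ratio
  tests between nested linear mixed models fit by maximum likelihood (not
  REML, as required for fixed-effect comparisons), with
  $\chi^2 = 2\,\Delta\ell$ clamped at zero and degrees of freedom equal to
  the parameter-count difference. Random-intercept terms with fewer than
  two levels are dropped with a warning; rater identity belongs in the
  model only for rating-level responses and is omitted once scores are
  aggregated per drawing.
* **Individual differences.** The per-child RDM (produced-only features,
  `fc7`, children with all six stimuli) yields the RDM score; its Pearson
  correlation with the per-child mean completion score is reported with the
  t-based p-value on $n-2$ degrees of freedom.

## Numerical and design choices

Age groups split at 44/45, 58/59 and 67/68 months. Stimulus templates are
hand-authored polylines; only the categorical and conditional structure
matters for relative dissimilarities, not visual fidelity. The scrambled
condition permutes part positions cyclically (never the identity). Stroke
rasterization stamps a disk of half the stroke width along densely sampled
polyline points; rendering, preprocessing and feature extraction are fully
deterministic, and every simulation consumes a single seed from which stage
seeds are derived at fixed offsets, so a pipeline run is byte-reproducible.

Problem sizes used by the test-suite and the acceptance script were chosen
as the smallest that give stable recovery statistics: 100 children for the
recovery and age-group analyses, 40 children per replicate (10 replicates)
for the style-versus-adult direction, 200 simulated null datasets for the
LRT calibration, and 1,000 permutations for group comparisons.

## Known limitations

The test backbone's random features cannot capture semantic similarity
(e.g. that a drawn sun and a drawn face are both round objects); it
measures geometry and ink distribution. The oldest synthetic age group's
permutation p-value against adults is intentionally marginal and therefore
varies from cohort to cohort, exactly as a single real cohort draw would.
The RDM score conflates stimulus adaptation with the amount of ink and
its placement; this is a property of the measure itself, inherited by any
backbone. Questionnaire effects are simulated as null (propensity is
independent of drawing behavior), so the AQ stages demonstrate correct
mechanics, not a discoverable effect.
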