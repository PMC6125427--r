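---
title: "Methods: differential expression and set logic for short-duration altered-gravity transcriptomics"
author: "gravitrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: altered-gravity differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravitrans)
```

## The experimental setting

`gravitrans` analyses bulk transcriptome responses of cells exposed to
seconds-to-minutes of altered gravity on two flight platforms. A parabolic
flight provides ~20 s of 1.8 g hypergravity followed by ~20 s of
microgravity; a suborbital ballistic rocket provides ~75 s of launch
hypergravity (up to 13.5 g) followed by ~300 s of microgravity. Cells are
lysed at fixed points of each profile, giving the groups encoded in
`loadDesign()`:

* parabolic flight (`"PFC"`, 28 samples): hardware 1 g ground control
  (n = 6), 1 g in-flight control (n = 8), hypergravity baseline (n = 6) and
  microgravity (n = 8);
* rocket (`"TEXUS"`, 26 samples): ground control (n = 6), hypergravity
  launch baseline (n = 5), microgravity (n = 7), and two groups treated
  with the wide-range cation-channel inhibitor SKF-96365 — microgravity
  (n = 4) and ground control (n = 4).

Because the microgravity phase always follows the hypergravity phase, the
hypergravity group doubles as the *baseline* (BL) for microgravity
contrasts, and dedicated control contrasts (in-flight vs ground control;
baseline vs ground control) are used to strip flight-condition and
protracted-hypergravity effects from the gravity-attributed sets.

## Fold change and differential expression

Expression values are handled on the **linear** scale (an RMA export on the
log2 scale can be declared with `log2Input = TRUE` and is exponentiated on
load). For each contrast the group means are averaged on the linear scale
and their ratio $r$ is reported with the negative-reciprocal sign
convention:

$$\mathrm{FC} = \begin{cases} r & r \ge 1 \\ -1/r & r < 1 \end{cases}$$

so $|\mathrm{FC}| \ge 1$ always, a doubling is $+2$ and a halving is $-2$.
A transcript is differentially expressed (DE) when
$\mathrm{FC} \ge +1.3$ or $\mathrm{FC} \le -1.3$ (boundary **inclusive**)
*and* a two-sided two-sample t-test gives $p < 0.05$ (boundary **strict**).
No multiple-testing correction enters the calls — this reproduces the
original uncorrected procedure; a Benjamini–Hochberg column is emitted for
information only, and with ~45k transcripts per contrast the uncorrected
expected false-positive count is accordingly large. That consequence is
inherent to the reproduced definition, not to this implementation.

Two deliberately exposed switches (`compareGroups()`):

* `testVariant`: `"welch"` (default) or `"pooled"`. The source procedure
  says only that t-tests were performed; Welch is the safer default under
  unequal variances. At the study's group sizes (4–8 samples) the
  Welch–Satterthwaite approximation is slightly *conservative*: its
  measured null rejection rate at $p<0.05$ is ≈ 0.044–0.047 rather than
  0.050, on either test scale. The pooled two-sample t is exactly
  calibrated when the two groups share a distribution, which is how the
  package's calibration tests assert the 5% level two-sidedly; the Welch
  default is asserted to be conservative, never anticonservative.
* `testScale`: `"linear"` (default, the closest literal reading of the
  averaged linear values) or `"log2"`. Fold changes are always linear-scale
  ratios regardless of this switch.

Transcripts with an undefined t statistic (zero variance in both groups and
equal means) are deterministically called `none` with a warning; zero
variance with unequal means gives $p = 0$ and an ordinary call.

## Control-filtered gravisensitive sets

`exclusionFilter()` removes from an experimental DE set the transcripts
also DE in a control contrast, in one of two modes: `any_direction`
(the response exists without the gravity stimulus, so it is not
gravity-attributable) and `same_direction` (the response continues from the
preceding phase — a protracted effect — while an *opposite*-direction
control response does not disqualify). The platform set builders
(`pfcGravisets()`, `texusGravisets()`) transcribe the study's rules:

* hypergravity-sensitive: DE in baseline vs ground control (no filter on
  the rocket; on the parabolic flight additionally the in-flight-controlled
  variant, any-direction filtered);
* microgravity-sensitive, BL-controlled: DE in microgravity vs baseline,
  same-direction filtered against baseline vs ground control;
* microgravity-sensitive, BL- and in-flight-controlled: additionally
  any-direction filtered against in-flight vs ground control and
  same-direction filtered against baseline vs in-flight, exactly as the
  published header reads. Both modes are first-class, so a different
  reading can be configured.

A member's direction and fold change are frozen from the defining
comparison at construction; downstream analyses never re-derive them.

`skfAttribution()` splits a microgravity-sensitive set by the inhibitor:
candidates must be DE in microgravity + SKF vs microgravity and *not* DE in
ground control + SKF vs ground control (which would mark a
gravity-independent drug response). Same-direction candidates are
*enhanced*, opposite-direction *attenuated*; the two partition the
candidates.

## Concordance and adaptation

`doubleSensitive()` intersects two sets by probeset ID (the same array
design is used on both platforms, so cross-platform matching is by
probeset) and `concordanceCounts()` tallies same- vs opposite-direction
pairs. `classifyAdaptation()` maps the (early, late) DE directions of a
transcript to one of four categories: `continuous` (same direction twice),
`adapted` (early response that vanishes or reverses), `late_response`,
`no_response`. The adaptation percentage reported by
`adaptationSummary()` is $100 \times \mathrm{adapted} /
(\mathrm{adapted} + \mathrm{continuous})$ over the initially altered pool,
rounded half-to-even at two decimals.

Half-even rounding (`percentage()`, `foldRatio()`) was chosen so printed
values are reproducible and auditable; raw unrounded values are retained in
every TSV. One published inconsistency is worth documenting: the
hypergravity adaptation share 10234/10345 is printed in one place as
98.92% and in another as 98.93%; the computed half-even value is 98.93, and
that is what the package emits — the discrepancy is documented rather than
patched. The published whole-array percentages with denominators near
38 786 are not reconstructible from the printed category counts (which sum
to 38 782) and are therefore not reproduced as a default output; the
`no_response` count is reported over whatever universe the caller supplies.

## The planted-truth simulator

Real arrays of this study are not redistributable at desk scale, so every
downstream stage is validated against simulated matrices with known ground
truth. `generateTruth()` assigns each transcript one regulation class
(`truthClassLabels()` documents which groups each class shifts), a
direction, and a multiplicative effect size; allocation is by largest
remainder, so every class count is within one transcript of its target
proportion and degenerate specifications (a single class) behave exactly.

`simulateExpression()` draws per-transcript baseline log2 abundance
$\sim N(8, 2^2)$, adds the planted class/group shift
$\pm\log_2(\text{effectFold})$, adds per-sample measurement noise
$N(0, 0.25^2)$ on the log2 scale, and returns $2^{(\cdot)}$ — a log-normal
noise model, the standard choice for RMA-scale intensities; the source
study states no distributional facts about its arrays, so these defaults
are conventional, configurable, and not fitted. Shifts are additive on the
log2 scale, hence multiplicative on the linear scale, matching the FC
semantics; in the noise-free limit the observed FC equals the planted
effect fold exactly.

Adapting classes take a `lateMode` parameter: at the late time point the
early effect either `"vanish"`es or `"reverse"`s (default), the default
reflecting that over 92% of cross-platform double-sensitive transcripts
were counter-directed. Late responders shift only the late platform's
microgravity groups; hypergravity late response is not modelled separately.
The SKF classes leave ground control + SKF unshifted and move
microgravity + SKF either further in the planted direction (enhanced) or
past the baseline in the opposite direction (attenuated).

One global seed expands into fixed, named substreams (truth allocation,
directions, effect sizes, annotation, baselines, noise), so identical
inputs give byte-identical matrices and adding a stage never perturbs the
others.

What the simulator does *not* emulate: probe-level effects, batch and
spatial artifacts, dye bias, correlated transcripts, heavy-tailed noise,
and the real arrays' unknown effect-size distribution. Passing recovery
tests therefore demonstrates that the inference chain is correct *given
its own definitions* — they are not evidence about biological effect sizes
or about type-I behaviour on non-log-normal data.

## Problem sizes and test design

The package's own validation uses 5 000-transcript simulations (the full
45 034 remain available by configuration), 20 seeds for recovery studies,
250 replicate null comparisons for calibration, and 1 000 randomized small
universes for brute-force equivalence of the set logic — sizes chosen to
keep the whole suite a desk-scale run while leaving Monte-Carlo standard
errors far below the asserted margins. Recovery assertions use effect
folds ≥ 2 at residual SD 0.25, where the planted effects are comfortably
detectable at n = 5–8; the defaults (effect folds 1.4–2.5) include
regimes near the detection boundary on purpose.

## Known limitations

* The uncorrected DE definition is reproduced faithfully; anyone using
  these calls for discovery rather than reproduction should use the
  emitted BH column.
* The equal- vs unequal-variance and linear- vs log-scale testing choices
  are unstated in the source procedure; both are config switches rather
  than guesses presented as fact, and the defaults are logged in every
  pipeline run.
* Group display names contain the micro sign; all programmatic interfaces
  use ASCII slugs.
* GEO download, RMA normalisation from scanner images, and GO enrichment
  are out of scope; the reader accepts already-normalised matrices.
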