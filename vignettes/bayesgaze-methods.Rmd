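---
title: "Methods: strategy classification and gaze analytics for two-event Bayesian reasoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strategy classification and gaze analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesgaze)
```

## The statistical situation

A scenario couples two binary events — A (e.g. having breast cancer,
attending an economics course) and B (a positive mammogram, being
career-oriented) — through their joint distribution
$(p_{11}, p_{10}, p_{01}, p_{00})$ plus a reference population size $N$.
Sixteen probabilities can be read off such a situation: the four marginals,
the four conjoints, and the eight conditionals. Conditioning in the same
direction as the canonical tree's first split (on A) gives the plain
conditionals $P(B\mid A)$, $P(\neg B\mid A)$, ...; conditioning on B or
$\neg B$ inverts the tree and requires a Bayesian update,

$$
P(A\mid B) \;=\; \frac{P(B\mid A)\,P(A)}
{P(B\mid A)\,P(A) + P(B\mid \neg A)\,P(\neg A)},
$$

which for the packaged mammography scenario (prevalence 1%, sensitivity
80%, false-alarm rate 9.6%) evaluates to 7.8%. Natural frequencies express
the same information as paired counts on the frequency tree
($A \to B, C \to D, E, F, G$): the same posterior becomes "80 out of
1,030".

```{r}
mam <- builtin_scenario("mammography")
frequency_tree(mam)
answer_query(mam, inference_query("P(A|B)", "natural_frequency"))
```

### Expected-frequency rounding

Tree counts are expected frequencies rounded half-away-from-zero;
$E = B - D$ and $G = C - F$ are then derived by subtraction so that the
tree is exactly additive. This matters for the mammography tree, where
$9{,}900 \times 9.6\% = 950.4$ is displayed as 950, forcing $G = 8{,}950$.
Conditionals with a conditioning margin of exactly zero are a typed error
(`bg_undefined_conditional`), never a silent `NaN`: a propagated
non-number would corrupt downstream strategy classification.

## The strategy catalog and its generalization

The error catalog is written for the canonical task "$P(X\mid Y)$ from a
tree splitting first on X's event". We generalize each formula to all four
Bayesian queries by structural role — target cell $P(X \cap Y)$,
conditioning margin $P(Y)$, inverse conditional $P(Y\mid X)$ — so that,
for instance, the Fisherian answer to $P(\neg A\mid \neg B)$ is
$P(\neg B\mid \neg A)$ (90.4% in the mammography context) and the
joint-occurrence answer to the economics $P(\neg A\mid \neg B)$ is the
cell value 45%. This generalization is the package's own design choice; it
is consistent with how the documented wrong answers for the
negative-direction queries arise. Applicability is restricted where a
strategy has no sensible output: pre-Bayes is frequency-only, while
likelihood subtraction/addition and the likelihood-ratio error are
probability-oriented. `likelihood_addition` defaults to
$P(Y\mid X)+P(Y\mid\neg X)$ (reproducing the "80% + 9.6% = 89.6%"
pattern); a conjoint-sum variant — which collapses onto the evidence
margin — is available via
`predict_answer(..., likelihood_addition_variant = "conjoint")`.

## Classification

An observed probability answer matches a candidate if both round to the
same integer percent **or** differ by at most 0.5 percentage points. This
double rule operationalizes the coding convention that answers near the
7.8% posterior count as correct when they fall between 7 and 8%; the
half-width is configurable (`classifier_config()`). Frequency answers
match as exact pairs by default, because participants' natural-frequency
answers are reported unreduced ("80 out of 1,030"); a `ratio_equivalent`
mode accepts reduced pairs and flags them.

The candidate space for a query contains every applicable catalog
strategy, plus *quantity confusions*: the other fifteen quantities, each
frequency quantity offered both with its natural conditioning set and with
the whole population as denominator. This covers reference-class errors
such as answering a conjoint question "20 out of 100" (the count within
the 100 diseased) instead of "20 out of 10,000". Complement-misread
variants — a strategy applied after reading an event as its complement —
are generated for Bayesian queries; when only such a variant matches, the
classification carries `misread_flag = TRUE`.

Ties are never resolved silently: candidates with identical predictions
are collapsed with merged labels, any multiple match sets
`ambiguous = TRUE`, and the assigned label follows a priority order
(correct, Fisherian, joint occurrence, ...) that ranks strategies by how
often they are reported to occur. `separability_audit()` lists, per
scenario and query, which strategy pairs are indistinguishable at the
configured tolerance — e.g. near-90% answers in the mammography
$P(\neg A\mid \neg B)$ task, where Fisherian and conjoint-style errors
nearly coincide.

## AOI layouts and gaze descriptives

Four stimulus variants are supported: tree diagrams and 2×2 tables, each
with frequencies or probabilities, on a 1280×1024 px canvas. Frequency
trees get 7 equal-sized node AOIs plus a larger question AOI (8 total);
probability trees use node-plus-branch AOIs because the numbers sit on the
branches; tables get 4 inner cells, 4 event-label cells, 2 marginal cells
and 1 total cell (11) plus the question (12). The exact pixel geometry of
the original stimuli is not published, so the layouts are parametric with
package defaults; all semantics are carried by the symbol map (AOI ↔
quantity symbol), and `relevant_aois()` derives the task-relevant AOIs
from the correct strategy's formula — e.g. $\{E, G, A\}$ for $P(\neg B)$
on a frequency tree.

Rectangles are half-open ($[x_0,x_1)\times[y_0,y_1)$, origin top-left) so
boundary fixations have a deterministic owner; anything outside every AOI
is whitespace. Indicators per AOI are: mean rank of first visit in the
collapsed scan path (unvisited trials excluded, never-visited AOIs
reported as missing), dwell time in seconds and percent, fixation count,
and hit ratio. Dwell percentages are pooled over trials by default —
whether the original tables pooled or averaged per trial is not stated —
with `per_trial = TRUE` as the alternative. Heat maps deposit one
duration-weighted Gaussian per fixation (defaults: 4 px grid, σ = 30 px),
with the kernel normalized on the grid so total mass equals summed
duration exactly; grids are therefore additive across participants and
classification strata.

## The synthetic cohort

`simulate_experiment()` emulates the full design: 24 participants × 20
inferences; block 1 is ten mammography questions on tree diagrams, block 2
ten economics questions on 2×2 tables; within each block the six
non-Bayesian inferences precede the four Bayesian ones, each group
shuffled, with formats balanced 5/5; 30 s per trial. A latent strategy is
drawn per trial from a mixture keyed by (inference class, format). The
default mixtures are the package's stand-in for a plausible cohort —
mostly correct on non-Bayesian items, Fisherian and joint occurrence
dominating Bayesian errors, frequency formats easier than probability
formats. They (and the 5% answer-noise rate) were chosen once as
simulator definitions; they are not estimates of any real cohort, and no
distribution of real fixation durations or counts is available, so the
lognormal duration model (median 250 ms), the Poisson execution-phase
length (mean 18), the 4:1 relevant-to-irrelevant dwell weight and the
question-revisit probabilities (0.3, raised to 0.5 for Bayesian queries,
mirroring the tendency to re-read hard questions) are documented synthetic
stand-ins.

Simulated answers are rounded to one decimal of a percent by default
(spoken answers like "90.4%"); an integer mode coarsens them further.
Simulated gaze has four phases — question reading, an orientation sweep
top-to-bottom/left-to-right, execution fixations concentrated on the AOIs
of the latent strategy's formula with Gaussian positional jitter (σ = 15
px, so some land on whitespace), and question revisits — truncated to the
30 s cap. Randomization uses one master seed with per-participant derived
substreams, so each participant's data do not depend on how many others
are simulated, and identical configurations give byte-identical CSV logs.

Because the generator conditions fixation targets on the latent strategy
through the same symbol map the analysis uses, passing gaze tests shows
the *plumbing* is correct (assignment, indicators, conservation,
relevant-AOI contrast), not that real gaze looks like this: the generator
has no saccade dynamics, no reading of numbers within an AOI, no fatigue
or learning across blocks.

## What the tests establish

The suite verifies, among others: the Bayesian update computed from branch
probabilities agrees with the cell-ratio conditional to $10^{-10}$ over
1,000 random scenarios; every noise-free strategy prediction is recovered
in its own candidate set; injected strategy mixtures are recovered from
classified answers within binomial sampling error at 192 Bayesian trials
per run over 20 seeds; dwell percentages, frequency trees and heat-map
mass obey their conservation laws; and the full cohort simulation plus
report completes in well under two minutes on a single CPU (the report
uses a 16 px heat-map grid by default at cohort scale; single-query maps
default to 4 px).

## Known limitations

The economics scenario is a synthetic reconstruction from its published
cell values (the only reconstruction consistent with 20%, 5%, 45% and the
counts 300/200 of 1,000); the second conditional of the design is posed as
$P(\neg B\mid A)$, whose correct economics answer is 20% — the
inconsistent direction printed in the source material is treated as a typo
rather than propagated. Classification is purely answer-based; gaze
evidence is reported alongside (indicator tables, stratified heat maps)
but never fused automatically into the label. Inferential statistics on
real cohorts, fixation detection from raw samples, and vendor file formats
are out of scope.
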