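---
title: "Calibrating crowdsourced photo annotation: consensus, tiered workflow and crowd size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating crowdsourced photo annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photocrowd)
```

## The measurement problem

Surveillance photographs — storefronts, street corners, points of sale —
carry detailed information that only a human can currently extract: is a
tobacco advertisement visible, which brand, at what price, and where in
the frame. Crowdsourcing platforms supply large numbers of untrained,
independent raters cheaply, but each individual rater is noisy. The
package treats the crowd as a measurement instrument with three design
questions:

1. **Aggregation** — how do many noisy answers become one decision, and
   what happens when they disagree?
2. **Workflow** — how are complex annotations decomposed into small
   tasks so that irrelevant photos are filtered out early, hard photos
   get extra scrutiny, and redundant work is avoided?
3. **Calibration** — how many raters per photo are enough for a given
   question difficulty and a target reliability?

## Consensus model

For a binary or categorical question, the crowd's answer is the
plurality (optionally supermajority) vote over `n` independent raters.
Exact ties and sub-threshold pluralities deliberately return
*no consensus* rather than a random winner: disagreement is a signal,
and the workflow routes such photos to expert review. The continuous
counterpart of the vote is the **vote fraction** — the share of raters
reporting the target present — which serves as the per-photo classifier
score for ROC analysis and reduces to majority vote when thresholded at
0.5.

If each rater is correct independently with probability $p$, an odd
crowd of size $n$ is correct with probability
$P(\mathrm{Bin}(n, p) > n/2)$, implemented in `consensus_accuracy()`.
This closed form anchors the simulation tests: empirical majority
accuracy over large simulated studies must match it to Monte-Carlo
error, across a grid of $(n, p)$.

## Crowd-size resampling

`crowd_size_curve()` implements the calibration procedure. From a pool
of $R$ raters who all rated the same photos, it draws $M$ random
subsets of size $k$ (without replacement within a draw, independent
across draws) for each candidate crowd size $k$, scores every photo by
the subset's vote fraction, and computes each draw's AUC against the
gold standard. The AUC is the trapezoidal area under the tie-grouped
ROC curve and is required — and exhaustively tested — to equal the
Mann–Whitney estimator

$$\widehat{\mathrm{AUC}} = \frac{\#\{s_i > s_j\} + \tfrac12\#\{s_i = s_j\}}{n_+ n_-},$$

over positive–negative photo pairs $(i, j)$. Grouping tied scores into
single ROC steps (diagonal segments) is what makes this identity exact;
any other tie convention breaks it.

Per crowd size the curve reports the mean AUC, the 2.5/97.5 percentile
interval of the $M$ draws (the "pointwise CI"), and the between-draw
SD. Two scan operations summarise it: `minimal_crowd_size()` returns
the smallest tested $k$ whose mean (or CI lower bound — the stricter
reading of "reliably above target") reaches a target AUC, and
`stabilization_point()` returns the smallest $k$ from which the
between-draw SD stays below a tolerance (default 0.02 AUC units; at
$k = R$ there is only one subset and the SD is exactly zero).

Design choices worth stating, since the procedure is often described
only operationally:

* *Resampling is repeated simple random subsampling*, not leave-one-out
  jackknife — that is what "50 random samples of 2 raters, then 50 of
  3, ..." describes operationally, and it is the only variant defined
  at every $k$.
* *The consensus score entering the ROC is the vote fraction.* Nothing
  else both uses all $k$ ratings and reduces to the majority vote.
* *Percentile intervals* over the draws are used rather than a normal
  approximation: AUC draws near 1 are strongly skewed.

## The tiered workflow

A `workflow_def()` is a directed acyclic graph of `task_tier()` nodes.
Each tier asks one question of a fixed number of raters, applies a
consensus rule, and routes on the outcome in declaration order (first
match wins — deterministic and auditable). Three terminal actions
exist: `RESOLVE` (annotated), `FILTER` (photo lacks the target; no
downstream tasks are ever issued for it), and `ESCALATE` (no consensus;
the photo joins an expert queue — the expert process itself is a hook,
not modelled). Every run satisfies a conservation law, checked in the
tests: resolved + escalated + filtered photos equal the photos that
entered, and the audit log replays to the identical final state.

The reverse-crop ("black-out") operations support iterative discovery:
`apply_reverse_crop()` masks already-found regions (mask area is the
area of the *union* of boxes — overlapping crops are not double
counted), `deduplicate_discoveries()` matches boxes across rounds by
IoU clustering and assigns each distinct item its first-discovery
round, and `compute_payment()` pays credited discoveries
$\text{base} \times m^{r-1}$ for discovery round $r$ — a geometric
schedule chosen as the simplest monotone formula implementing "harder
finds pay more"; redundant re-finds earn the base rate only.

Crop geometry uses pixel coordinates with origin top-left and half-open
extents $[x_0, x_1) \times [y_0, y_1)$, so areas are exact pixel counts
and adjacent boxes do not overlap. Boxes with the same tag are
considered the same item when IoU ≥ 0.5 (the conventional
detection-overlap threshold; configurable), and clusters are connected
components under single linkage — checked against brute-force graph
search on every small instance.

## What the synthetic generator does and does not emulate

`generate_study()` draws a study from a `sim_config()`: photos with
Bernoulli feature assignments at stated prevalence, one true crop box
per photo, a true price plus a salient cheap distractor price, and a
rater pool with per-rater sensitivity/specificity (optionally
heterogeneous via a clamped normal). Rating errors are independent
across raters and photos; price readers report the distractor with a
configurable probability and otherwise the true price plus Gaussian
noise; crop edges get independent Gaussian jitter clamped to the frame.

Defaults encode the reference calibration design: a 500-rater pool on 8
photos, sensitivity = specificity = 0.75 (a working assumption for an
untrained crowd, not an estimate of any real pool), prevalence 0.5,
price noise SD $0.45, distractor price $2.59 against a true $6.34, and
5 px crop jitter. Difficulty is modelled by lowering
sensitivity/specificity — the simplest mechanism that reproduces the
qualitative finding that harder targets need larger crowds.

The generator deliberately omits: correlated rater errors (shared
difficulty shocks, copying), rater learning or fatigue over time,
photo-level difficulty beyond the feature-level accuracy, and any pixel
content. Passing tests therefore demonstrate the *machinery* —
aggregation, routing, resampling — under the independence assumptions
the reliability mathematics already makes; they do not certify accuracy
numbers for any real crowd, where correlated errors would lower the
effective crowd size.

## Numerical and edge-case conventions

* Ties in `majority_vote()` break to *no consensus*; the reported vote
  fraction is that of the lexicographically smallest leading answer, so
  outputs are deterministic.
* Sample SD uses the $n-1$ denominator and is undefined (`NA`) for a
  single reading; prices are parsed as decimal currency with `$` and
  thousands separators stripped and rounded to cents.
* The chi-square homogeneity test is Pearson's without continuity
  correction, df from the table shape; zero-margin tables are rejected
  as degenerate.
* Proportions are reported with Wilson score intervals, which behave
  sensibly at 0/n and n/n.
* An AUC is undefined (error) when the gold standard contains only one
  class.
* All randomized procedures take an explicit seed, restore the caller's
  RNG state, and are reproducible byte for byte (`write_study()`
  records the full configuration in `manifest.json`).

## Problem sizes used in the test suite

The suite exercises the pipeline at sizes chosen to make Monte-Carlo
bounds tight while keeping a full run around twenty seconds: 10,000
photos per cell for the closed-form consensus grid, 2,000 resamples for
the subset-enumeration check, 20 independent seeds for the
monotonicity-in-$k$ property, 500 random instances for the clustering
oracle, and 200-photo/60-rater studies for the headline crowd-size
experiments (50 subsamples per crowd size, matching the reference
plan). The acceptance script reruns the two headline experiments end to
end from a user-supplied seed.

## Known limitations

Majority and plurality aggregation only — no latent rater-quality
models (Dawid–Skene and relatives are out of scope by design, since the
calibration question is about crowd *size* under simple consensus).
ROC analysis is unadjusted — no covariate ROC regression. The workflow
engine executes a given ratings stream; it does not post tasks to any
crowdsourcing platform, handle payment execution, or render images.
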