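# photocrowd

Tools for running and calibrating crowdsourced annotation of field
photographs, of the kind used in point-of-sale tobacco-advertising
surveillance: many untrained, independent raters each answer small
questions about a photo (is an ad present? which brand? the lowest
price? draw a box around it), and the crowd's answers are aggregated
into a consensus whose reliability must be engineered, not assumed.

The package is for study designers who need to answer, before
spending money on a crowdsourcing platform: *how many raters per photo
does this question need?* Its core is the **crowd-size resampling
procedure**: from a pool of R raters who all rated the same gold-standard
photos, draw M random subsamples of k raters for each candidate crowd
size k, score every photo by the subsample's vote fraction (the share
of raters reporting the target present), and measure each subsample's
agreement with the gold standard by the area under the ROC curve,

    AUC = ( #{s_pos > s_neg} + ½ #{s_pos = s_neg} ) / (n_pos · n_neg),

the Mann–Whitney form, which the trapezoidal area under the
tie-grouped ROC curve equals exactly. The spread of AUC across
subsamples at each k yields pointwise percentile intervals; the curve
of mean AUC and its lower bound identifies the smallest crowd that
reliably reaches a target (say AUC ≥ 0.90) and the point where
between-sample variation stabilises.

Around that core the package provides plurality/supermajority
consensus with deterministic no-consensus on ties, price-reading
summaries, IoU clustering of near-duplicate crop boxes, a tiered
adaptive workflow (filter irrelevant photos early, escalate
disagreement to experts, black out already-found regions, pay harder
discoveries more), and a synthetic-study generator with heterogeneous
rater sensitivity/specificity so the whole pipeline runs end to end
with no platform and no real images.

## Worked example: how many raters does a hard question need?

Simulate a pool of 40 raters with sensitivity = specificity = 0.70 — a
difficult target, like deciding whether an ad is for a menthol
product — all rating 100 photos, and resample the crowd size:

```r
library(photocrowd)
study   <- generate_study(sim_config(n_photos = 100, n_raters = 40,
                                     sensitivity = 0.7, specificity = 0.7,
                                     seed = 11))
ratings <- simulate_binary_ratings(study, "ad_presence", seed = 12)
curve   <- crowd_size_curve(ratings, study$gold,
                            k = c(2, 3, 5, 7, 10, 15, 20),
                            n_samples = 50, seed = 13)
curve
#> Crowd-size resampling curve (7 sizes, 50 subsamples each)
#>   k mean_auc  ci_lo  ci_hi   sd_auc n_samples
#>   2   0.7806 0.7122 0.8858 0.049035        50
#>   3   0.8421 0.7641 0.9012 0.036792        50
#>   5   0.9013 0.8438 0.9463 0.027477        50
#>   7   0.9428 0.8976 0.9784 0.023463        50
#>  10   0.9656 0.9277 0.9873 0.018338        50
#>  15   0.9873 0.9679 0.9987 0.008076        50
#>  20   0.9961 0.9875 1.0000 0.003461        50

minimal_crowd_size(curve, 0.90, "mean")      # 5
minimal_crowd_size(curve, 0.90, "ci_lower")  # 10
stabilization_point(curve, 0.02)             # 10
```

Read: a crowd of 5 reaches AUC 0.90 *on average*, but its subsamples
are volatile (SD ≈ 0.027, lower bound 0.84) — a study using 5 raters
per photo would sometimes confidently agree on wrong answers. Ten or
more raters keep even the unlucky subsamples above 0.90 and stabilise
the between-sample SD below 0.02: for a question this hard, budget a
low-double-digit crowd.

The aggregation primitives print readable summaries:

```r
majority_vote(c("present", "present", "present", "absent", "present"))
#> Consensus: present (4/5 raters, vote fraction 0.800)
aggregate_prices(c(7.29, 7.29, 7.29, 6.34))
#> Price summary: mean $7.05 (SD 0.48), min $6.34, n = 4
```

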