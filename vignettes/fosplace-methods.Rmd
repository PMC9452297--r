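---
title: "Methods: from calcium transients to cross-day place-field stability"
author: "fosplace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from calcium transients to cross-day place-field stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosplace)
```

# Scope and model

`fosplace` implements the analysis chain used to relate immediate-early-gene
(Fos) induction to hippocampal place coding in head-fixed mice navigating a
200-cm circular virtual track with a hidden 20-cm reward zone. The chain runs:
significant-transient calling on dF/F traces; trial segmentation, lick
classification and a licking-selectivity score; spatially binned tuning with
a block-permutation shuffle null, place-field calling and spatial
information; Poisson naive-Bayes position decoding; fold-induction image
quantification and decile grouping; trial-wise ensemble correlation and
affinity-propagation clustering; and activity-weighted cross-day stability
maps. Because no public dataset accompanies the original experiments, the
package ships a synthetic-data generator with known ground truth so that
every stage is testable end to end.

# Significant transients

Raw traces are converted to dF/F against a 30th-percentile baseline in a
60-s moving window. Whether that window is centred or trailing is an open
choice; we centre it (truncated at the recording edges) and expose
`centered` as an argument, since a centred window has no systematic phase
lag relative to the events.

Transient significance is an empirical false-positive-rate criterion.
After standardizing a trace by its median and *plain sample* standard
deviation (the median already centres robustly, so no robust scale is used),
positive excursions above each threshold t in 1.0–4.0 sigma (0.2 steps) are
candidates. For a candidate n frames long,

FPR(t, n) = (# runs below −t of length ≥ n) / (# runs above +t of length ≥ n),

and the candidate is significant when FPR < 0.001. Negative-going runs are
the noise model: noise is symmetric, real transients are not. The
denominator counts the candidate itself, so FPR is always finite. Frames
significant at any threshold form the final mask (union), runs separated by
fewer than 2 frames are merged (gap frames recover their dF/F), runs shorter
than 2 frames are dropped, and non-significant frames are set to exactly
zero. Run counts for the FPR are taken before merging, following the order
in which the rules are stated. Each retained transient records an accepting
(t, n) pair so the bound can be re-audited post hoc.

# Behaviour

Trials are laps, cut at circular position wraps. Licks inside the reward
zone after reward delivery are consumption licks and are excluded from all
selectivity counts. A trial enters place-field analyses only if it has at
least 3 test licks, lasts 4–60 s, has no experimenter-triggered reward, and
starts before 1.2 ml of cumulative reward.

Licking selectivity compares test-lick counts in the 10 cm immediately
before the reward zone against an equally sized zone 100 cm away —
diametrically opposite on the circular track: (pre − opposite)/(pre +
opposite). Counts are pooled over the session (the formula is a single count
ratio); a session with zero licks in both zones yields a missing value and
is excluded from averages. Permutation p-values throughout the package use
the add-one estimator, p ≥ 1/(n+1), so no test ever reports p = 0.

# Spatial tuning and place fields

Only running frames (speed > 5 cm/s) of eligible trials contribute. The
track is divided into 40 bins of 5 cm; mean significant-transient dF/F per
bin is smoothed with a circular Gaussian kernel (sigma = 1 bin). Bins
unvisited on a given trial are missing for that trial and are excluded
pairwise from trial-wise correlations; session-mean bins with no occupancy
are bridged by renormalizing the smoothing kernel over present neighbours.

The null pairs the fixed traces with perturbed behaviour: per shuffle, the
behaviour streams are circularly shifted by a uniform random offset, cut
into six contiguous blocks of near-equal length (counts differ by at most
one, remainder to the leading blocks), and the block order is permuted. This
preserves the autocorrelation of both signals while destroying their
pairing. Bins where the smoothed curve strictly exceeds the elementwise 99th
percentile of 1,000 shuffles are significant (ties are not significant);
fields are maximal circular runs of at least 3 significant bins (bin 39 is
adjacent to bin 0), and any cell with a field is a place cell.

Spatial information is H = sum_i p_i a_i log2(a_i / a) with a = sum_i p_i
a_i, using the *unsmoothed* binned activity (the formula references binned
activity directly; a smoothed variant is switchable). Terms with a_i = 0
contribute zero, a silent cell has H = 0, and H is normalized by the mean H
of the same 1,000 shuffles, so H_norm is approximately 1 for untuned cells.

# Decoding

The decoder assumes Poisson activity and independent cells with a uniform
prior. Templates f_i(pos) are mean binned activity over the even-numbered
eligible trials (1-based numbering in session order, so the first eligible
trial is a test trial); odd trials are decoded. The log posterior of bin pos
given frame activity a is sum_i a_i log f_i(pos) − tau sum_i f_i(pos), with
tau one frame (1/30 s), normalized by log-sum-exp; argmax ties resolve to
the lowest bin. The per-frame activity entering the exponent is the raw
significant-transient dF/F (the most literal reading; no thresholding or
binarization). Templates are floored at 1% of the population-mean nonzero
template value before taking logs — an explicit, reported regularizer that
avoids log 0 — and bins never visited in training are removed from the
posterior support. Decoding error is the circular distance between bin
centres, at most 100 cm.

Group comparisons subsample both groups to the smaller group's size clamped
to [10, 100] cells, with identical train/test frames, 100 times; sessions
whose smaller group has fewer than 10 cells are excluded. Induction deciles
are decoded independently; "low" is the mean of deciles 1–2 and "high" of
deciles 9–10.

Activity matching balances integrated dF/F (alpha) between groups: ten
equal-width bins of log10(alpha) over the whole population (log-transformed
because the raw distribution is long-tailed), then within each bin an
iterative draw in which the group currently ahead in mean alpha draws from
the less active half of its remaining members and the other group from its
more active half, until either group's bin members are exhausted. The first
draw in a bin is unconstrained.

# Fold-induction quantification

The post/pre GFP ratio image is divided by its own 2-D median filter
(square window of ~50 µm, rounded to an odd pixel count) — the background
absorbs smooth, non-uniform brightness changes while sparse nuclear GFP,
much smaller than the window, survives. Edges are handled by reflective
padding; excluded (artefact) and nonpositive-pre pixels propagate missing
values rather than infinities. Per-cell values average the fold map in a
10-µm-diameter disc at the cell body, clipped at image borders; cells with
more than half of their disc excluded are flagged. Deciles are assigned on
ranks with ties broken by cell id (fully deterministic; exact 20%
high/low groups at n = 100), and any strictly monotone transform of the
values leaves the grouping unchanged. Image time courses are standardized
per image by median and MAD and rescaled by the series-wide MAD (A) and
median (B) before fold maps are computed against the first image.

# Ensembles

The trial-wise place-field activation matrix holds, per eligible trial and
place cell, the mean activity within that cell's own field bins — a
position-independent readout. Within-group correlation is the mean Pearson
correlation over distinct cell pairs, computed pairwise-complete over
shared non-missing trials (pairs sharing fewer than 3 trials are skipped).
For clustering, which needs a complete similarity matrix, missing entries
are imputed as 0; the two conventions are deliberate and logged.

Clustering is affinity propagation on the pairwise correlations with
preference −1 on the diagonal (the standard convention: the preference
replaces self-similarity) and a 5,000-iteration cap. No R implementation
was available in the target environment, so the package implements the
responsibility/availability message-passing updates directly, with damping
0.9 — a high-damping regime consistent with such a large iteration cap —
and a 100-iteration stable-exemplar convergence window. Non-convergence
returns labels with a flag. Same-cluster enrichment divides the observed
within-group co-membership probability by its mean under permutations of
the group labels over the fixed clustering.

# Stability

For each ordered session pair (positive session gap, each unordered pair
used once) and each group defined on the *reference* session, per-cell
Pearson correlations x between reference and target tuning are combined
into a per-bin map: each cell's reference tuning (the smoothed mean curve,
switchable to unsmoothed) is normalized to sum to one, so each field
contributes equally and only where the cell was active, and stability(i) is
the weight-normalized mean of x at bin i. At least 20 cells are required per
group by default. Zone summaries average bins in a peri-reward zone (reward
zone ± 20 cm — no single extent is canonical, so it is configurable and
reported alongside results, never hard-coded as ground truth) versus the
remaining no-reward bins. Group differences are tested by paired
sign-flip permutation across session comparisons — the only exchangeable
structure in paired maps — two-sided with add-one smoothing.

# The synthetic generator

The generator emulates the statistical structure the analyses assume, not
the biophysics. Behaviour: laps at 30 Hz with piecewise-constant per-trial
speed drawn from a lognormal (mean 25 cm/s), slowed 2x inside the reward
zone; standard/crutch/probe trials at 65/25/10%; an "expert" lick policy
concentrating test licks in the 10 cm before the zone and inside it, a
"novice" policy licking uniformly. Traces: each tuned cell fires its field
per trial with probability `reliability`; the drive is a Gaussian spatial
envelope convolved with a 0.5-s single-exponential kernel and normalized so
the event peak equals the cell's drawn amplitude (1.5–3 dF/F) regardless of
field width and running speed; additive Gaussian noise has s.d. 0.1.
Untuned cells emit position-independent Poisson events. Fold induction is
baseline + gain x standardized integrated dF/F + noise (defaults 1, 0.3,
0.1; the true effect magnitude is unreported, so these are order-of-
magnitude choices, all config-exposed). A per-trial shared lognormal gain
(s.d. 0.5 in log) multiplies event amplitudes of the top reliability tier,
planting ensemble-like co-fluctuation; each cell's day-to-day field
persistence probability interpolates [0.5, 0.95] over its reliability, so
high-induction cells are also more stable — the two planted directions the
end-to-end recovery suite checks. Ground truth records per-frame event
masks at the half-maximum extent of each event, so detector sensitivity is
scoreable.

What the generator does not emulate: imaging optics, motion artefacts,
neuropil contamination, spike-to-calcium nonlinearity, theta timescale
structure, or behaviour-activity couplings beyond place tuning (e.g. speed
cells). Passing tests therefore demonstrate correctness of the analysis
chain under its own assumptions, not performance on real recordings.

# Numerical choices and problem sizes

One master seed drives named RNG substreams per generated artefact, so each
artefact is independently reproducible; all analyses that resample
(shuffles, subsampling, permutations) take explicit seeds and are
deterministic given them. Test-suite problem sizes are chosen for desk-scale
runs: 500 cells and 1,000 shuffles for the place-field specificity check,
50 random 2,000-frame traces for detector-oracle equivalence, and an
end-to-end cohort of 20 seeded replicates of 200 cells x 2 sessions at 200
shuffles. At that cohort size the per-group stability-map minimum is set to
10 cells (the full-experiment-scale default of 20 stands in the API), mirroring the
decoder's own 10-cell floor; low-reliability groups at desk scale otherwise
rarely reach 20 reference-session place cells.

Known limitations: the affinity-propagation implementation breaks exact
ties by first index, so degenerate similarity matrices with exact symmetry
may depend on cell order; the EBImage median-filter backend quantizes
intensities into 2^16 levels over the padded image range (relative error
~1e-5 on fold maps); and the decoder's template floor, while reported, is a
heuristic — decoding comparisons should always be made between groups
treated identically, which the API enforces by sharing train/test frames.
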