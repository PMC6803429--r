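---
title: "Anchor-based batch adjustment: model, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-based batch adjustment: model, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(anchornorm)
```

## The problem

Mass cytometry (CyTOF) measures ~40 protein markers per cell as metal-ion
counts. Barcoding pools up to 20 samples into one stained, acquired tube, so
within a barcode set (a *batch*) technical variability is small — but a
powered human study needs many batches run over months, and reagent lots,
instrument calibration, and staining conditions drift between them.
Regression-style batch correction built for bulk omics (ComBat, SVA, RUV)
assumes a genes-by-samples matrix and homogeneous batch composition; neither
holds for collections of single-cell event clouds from small, heterogeneous
batches.

The design this package supports sidesteps composition assumptions entirely:
every batch carries an *anchor* — an aliquot of one technical-replicate donor
sample, processed with the batch. Anchors are biologically identical across
batches, so any difference between a batch anchor and the anchor of a
designated *reference batch* is a technical batch effect, and whatever
transformation aligns the anchors can be applied to every sample in that
batch.

## The adjustment model

For batch $b$ and channel $c$, let $s(\cdot)$ be a descriptive summary
statistic of the anchor's event intensities (over **all** events, zeros
included). The scale factor is

$$ g_{b,c} \;=\; \frac{s(\text{reference anchor}_c)}{s(\text{batch anchor}_{b,c})}, $$

and every event intensity $v$ of every sample in batch $b$ becomes
$g_{b,c} \, v$ in channel $c$ (raw space). Implemented statistics: mean,
median, standard deviation (divisor $n-1$, applied multiplicatively about
zero so counts stay nonnegative), and an arbitrary percentile. Percentiles
use linear interpolation between order statistics at rank
$1 + (n-1)\,p/100$ — the default convention of the surrounding R ecosystem;
the choice matters only at small event counts.

Because all these statistics are positively homogeneous
($s(g\,v) = g\, s(v)$), the adjusted batch anchor's statistic equals the
reference anchor's *exactly* (to floating-point error), which is the
"statistic closure" property the test suite asserts at relative tolerance
$10^{-6}$.

Factors may instead be computed and applied in arcsinh space:
$v \mapsto c_0 \sinh\!\big(g \cdot \operatorname{asinh}(v/c_0)\big)$ with
cofactor $c_0$ (default 5, the CyTOF display convention). Back in ion-count
space this is a non-linear but still monotone, zero-preserving adjustment;
closure then holds for the statistic computed on arcsinh-transformed values.

Quantile normalization (`method = "quantile_norm"`) replaces the single
factor with a monotone piecewise-linear map from the batch anchor's
empirical quantiles onto the reference anchor's, on an evenly spaced
probability grid.

Key contracts, all property-tested: rank order of events within a channel is
preserved by every path; zeros map to zeros (scale paths); nonnegative input
gives nonnegative output; adjusting the reference batch is a no-op; and
re-deriving factors from already-adjusted anchors returns 1.

## Parameters that matter

- **`method` / `percentile_p`** — percentile scaling at $p = 95$ (high end,
  robust to outliers) and $p = 80$ (low end, stays meaningful when many
  events are zero) are the settings of primary practical interest; the 95th
  percentile in raw space is the default. The median breaks in any channel
  where more than half the events are zero: the statistic is 0 and the
  factor undefined.
- **`skip_on_zero_stat`** (default `TRUE`) — a channel with a zero anchor
  statistic is left unadjusted and the reason recorded in the factor table,
  the log, and the output FCS keywords. Silent division by zero would be
  strictly worse than no adjustment; nothing in the degenerate case
  prescribes a principled fix.
- **`space` / `cofactor`** — raw space makes the adjustment linear and is
  the default; arcsinh space (cofactor 5) is exposed because either may be
  preferred for a given panel, and the literature leaves the choice open.
- **`n_knots`** (quantile normalization, default 10001, clamped to the
  smaller anchor's event count) — resolution/memory trade-off; at $10^5$
  events the mapped anchor's KS distance to the reference is bounded by
  roughly $2/n_\text{knots}$ plus sampling noise.
- **`qn_zero_handling`** — `"ecdf"` (default) maps every value through
  $Q_\text{ref}(F_\text{batch}(x))$, ties at zero occupying their full
  probability mass. When zero fractions differ between anchors this
  *necessarily* inflates surplus zeros to positive values or squashes the
  lowest positive values to zero — the well-known artifact of per-channel
  quantile normalization on zero-inflated counts, reproduced by
  construction and asserted in the tests. `"preserve"` pins zeros to zero
  and maps only the positive parts, trading distribution match for zero
  preservation.

Factors are calibrated once per (batch, channel) from anchors only, never
per study sample: the anchor is the batch's representative, and per-sample
recalibration would re-introduce the biological variability the design
removes.

## Validation statistics

Three measures quantify whether an adjustment helped:

1. **Mean pairwise KS** per channel: the two-sample Kolmogorov–Smirnov
   statistic $\sup_x |F_i(x) - F_j(x)|$ averaged over all replicate pairs.
   Computed exactly on the pooled support (ties handled); on raw
   intensities by default, which is equivalent to any monotone transform of
   them except under subsampling.
2. **Total variance** of a replicates-by-features matrix (channel means, or
   gated population fractions): the sum of per-feature sample variances,
   equal to the trace and the eigenvalue sum of the feature covariance
   matrix — asserted numerically at $10^{-9}$ relative tolerance, along
   with invariance to feature permutation and orthogonal rotation.
3. **Permutation test** of the change in total variance: each replicate's
   pre/post labels are exchangeable under the null, so all $2^n$ label-swap
   subsets are enumerated (exactly for $n \le$ `max_exact_n`, default 20)
   and the one-sided p-value is the fraction of null changes at or below
   the observed one. The identity swap is counted, so $p > 0$ always and
   $p$ is a multiple of $2^{-n}$; with 8 batches the smallest attainable
   p-value is $1/256$. Beyond `max_exact_n` a seeded Monte-Carlo sample of
   assignments is used (identity always included); when the requested
   sample size covers the whole $2^n$ space the implementation enumerates
   it exhaustively instead, so the two paths agree exactly there.

Gating is out of scope, so population-fraction matrices from external
gating are accepted as CSV. As an internal analog of "gates drawn on the
reference and applied unchanged everywhere",
`positive_fraction_matrix()` computes per-channel positive-event fractions
at thresholds fixed from the reference anchor (default its per-channel
median): a batch's multiplicative shift moves events across the fixed cut
exactly the way it moves cells across a gate boundary, and adjustment
should move them back.

## What the synthetic generator emulates — and what it does not

`generate_experiment()` draws each sample from a mixture of cell
populations; each population's channel intensity is zero-inflated
log-normal (a point mass at exactly 0 for the ion-count zero phenomenon,
log-normal positive part for the right-skewed nonnegative marginal). Batch
effects are injected as per-(batch, channel) multipliers plus optional
additive perturbations of the zero probability; the reference batch is
identity by construction. Anchors use the same mixture weights in every
batch (technical replicates); study samples get log-normally perturbed
weights (biological variability); an optional validation replicate per
batch mirrors a second (e.g. unstimulated) anchor set that is adjusted with
factors calibrated on the designated anchors.

This emulates the *structure* that the method exploits — replicate anchors,
per-batch multiplicative distortions, varying zero fractions (including
pushing a channel past the 50%-zeros median breakdown) — but not real CyTOF
features such as multimodal marker distributions, spillover, acquisition
drift within a run, doublets, or correlated channel noise. Passing tests
therefore demonstrate that the algorithms honor their contracts and recover
known injected effects; they do not certify performance on any particular
real panel, which is what the graphical diagnostics are for.

Log-normal location/scale defaults (meanlog 2–4, sdlog 0.5, zero fractions
5–40% across channels) were chosen once as qualitatively realistic
ion-count marginals. Default problem sizes in the test and acceptance
workflows are deliberately moderate — 3–8 batches, 20 channels, 4k–20k
events per sample for pipeline-level checks, and 100k events where a
quantity's sampling error matters (factor recovery, quantile-map KS) — a
scale at which the 95th-percentile factor estimate has well under 1%
sampling error. A 12-batch, 38-channel, 300k-event file round-trip is
exercised once to confirm paper-scale dimensions pose no problem.

## Numerical and design notes

- **FCS I/O** is implemented in the package: FCS 2.0/3.0/3.1 reading
  (float32/float64/integer data, both byte orders) and FCS 3.1 float32
  little-endian writing, the layout of contemporary CyTOF exports. Float32
  storage means a write/read round-trip is exact only to single precision
  (~7 significant digits); all byte-identity guarantees (re-running a batch
  reproduces its outputs bit-for-bit) hold because the writer is fully
  deterministic — no timestamps or environment-dependent keywords are
  emitted. Carried TEXT keywords are preserved; structural keywords are
  regenerated from the data; adjustment provenance goes under the
  `ANCHORNORM_` prefix that other readers ignore. Only the first dataset of
  a multi-dataset file is read. Doubled-delimiter escapes in TEXT values
  are not un-escaped (values containing the delimiter are rejected on
  write).
- **Rolling basis**: each batch's outputs depend only on its anchor, the
  reference anchor, and the configuration, so new batches can be adjusted
  later without touching finished ones; the suite verifies superset reruns
  byte-identically.
- **Degenerate inputs**: empty channels and zero-event files are rejected
  at construction; constant channels give sd 0 and hence a skip; a
  quantile map whose source collapses to a single value maps everything to
  the top target knot (the ECDF convention at a total point mass).
- **Tie-breaks in quantile maps**: duplicated source knots (a probability
  mass) map to the highest corresponding target, i.e.
  $Q_\text{ref}(F_\text{batch}(x))$; `cummax()` guards monotonicity against
  floating-point jitter.
- **Factor serialization** uses open formats: a CSV factor table plus a CSV
  knot sidecar for quantile maps, written at full precision (17 significant
  digits survive the round-trip).
- **Manifest-first orchestration**: an explicit CSV manifest is the primary
  interface; filename-token discovery (`discover_batches()`) is a
  convenience for strictly named collections, and refuses ambiguous anchor
  assignments rather than guessing. The reference batch is always
  user-chosen — an outlier reference contaminates every batch, and the
  factor-overview diagnostic exists precisely to catch that before
  committing.
- **Condition tags** (e.g. stim/unstim) are carried through but never
  interpreted: calibration uses only the designated anchor role, and a
  second replicate set rides along as study samples.

## Limitations

Adjustment is per-channel and at most monotone: it cannot repair effects
that reorder events within a channel or couple channels (no affine
location+scale or multi-channel latent-variable correction). Channels with
grossly inconsistent zero fractions across batches may admit no
satisfactory per-channel adjustment at all; the skip mechanism and the
diagnostics make that visible rather than hiding it. Upstream steps — bead
normalization, debarcoding, pre-gating cleanup — are assumed done and are
out of scope.
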