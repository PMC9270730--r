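---
title: "Detecting chromatin loops with per-distance continuous negative binomial models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromatin loops with per-distance continuous negative binomial models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbloop)
```

## The problem

Hi-C assays produce, per chromosome, a symmetric contact matrix whose entry
$(i, j)$ counts read pairs linking genomic bins $i$ and $j$. Chromatin
loops — pairwise contacts between distal loci, typically CTCF/cohesin
anchored — appear as localized enrichments a few bins wide, sitting on a
background that decays steeply with the genomic distance $d = |i - j|$ and
is strongly overdispersed relative to a Poisson model. `nbloop` detects
such loops in balanced matrices restricted to a diagonal band (loop anchors
rarely exceed 2 Mb separation, so the band both focuses the search
biologically and bounds memory).

## The model and the procedure

**Observed/expected normalization.** Each stored contact is divided by the
expected value at its distance, $m^*_{ij} = icm_{ij} / exp_d$. Three
expected-value definitions are available: the mean over *nonzero* entries
at $d$ (default), the mean over *all* $n - d$ positions, and a
ligation-corrected variant that modulates the nonzero expectation by the
coverage product $rowsum_i \cdot rowsum_j / total$. Distances whose entries
are all zero carry no expected value and are skipped outright rather than
forced to zero.

**Per-distance continuous negative binomial.** Balanced matrices are
real-valued, so the discrete negative binomial is continued to real
arguments by replacing factorials with gamma functions:
$$f(k, r, p) = \frac{\Gamma(k+r)}{\Gamma(k+1)\,\Gamma(r)}\, p^k (1-p)^r,
\qquad k \ge 0,\; r > 0,\; 0 < p < 1,$$
with mean $rp/(1-p)$ and variance $rp/(1-p)^2$. For every distance $d$ the
nonzero observed/expected values at or above the prefit threshold are
fitted independently to this family. The right-tail p-value of an observed
value $m^* > 0$ is the regularized incomplete beta continuation of the
discrete tail,
$$P(X \ge m^*) = I_p(m^*, r),$$
which at integer $m^*$ equals the discrete tail sum exactly, decreases
continuously in $m^*$, and tends to 1 as $m^* \to 0^+$, joining the
convention that a zero contact has p-value exactly 1.

**Candidate selection.** A pixel is a candidate iff (i) its distance has a
fitted model, (ii) $m^* \ge$ `obs_exp_threshold`, (iii) its tail p-value is
below `p_value_preselection`, and (iv) its *uncorrected* count is at least
`peak_interaction_threshold` — low-count pixels are indistinguishable from
noise no matter how enriched they look after normalization.

**Pooling and the donut test.** Candidates within one neighborhood are
pooled: only the highest observed/expected candidate within Chebyshev
distance `window_size` survives (ties break deterministically by higher
value, then smaller distance, then smaller row). Around each
representative, the `(2*window_size+1)^2` window splits into the central
`(2*peak_width+1)^2` peak, a horizontal strip above/below the peak, a
vertical strip left/right of it, and the bottom-left corner block (toward
the main diagonal, where domain-corner artifacts concentrate). A candidate
is rejected immediately if the mean of all non-peak window cells reaches
the peak mean — a singular outlier is not a loop. Otherwise the peak is
tested one-sidedly against each of the three regions with Wilcoxon
rank-sum tests, and the loop is accepted only if all three p-values fall
below `p_value`. No multiple-testing correction is applied across
candidates or regions; the significance level is per test.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `peak_width` | 2 | bins (inradius) | side of the peak square is `2w+1` |
| `window_size` | 5 | bins (inradius) | neighborhood side is `2w+1`; must exceed `peak_width` |
| `p_value_preselection` | 0.1 | — | per-distance right-tail threshold |
| `p_value` | 0.025 | — | per rank-sum test |
| `peak_interaction_threshold` | 10 | raw counts | minimum uncorrected count |
| `obs_exp_threshold` | 1.5 | — | prefit thinning *and* candidate gate |
| `expected_mode` | `nonzero` | — | expected-value definition |
| `min_distance` | 4 bins | bp | near-diagonal exclusion |
| `max_distance` | 2 Mb | bp | band (search-space) limit |
| `min_background_elements` | 25 | cells | testability after border truncation |
| `min_fit_values` | 100 | values | minimum per-distance fit input |

A window of inradius 5 offers 121 neighborhood elements; a startup warning
notes that several hundred elements per neighborhood are advisable, so at
coarse resolutions the window should grow with the bin size.

### Choosing the expected-value mode

`nonzero` is the default because it detects the most loops on deeply
sequenced matrices. In *sparse* matrices it has a structural failure mode:
with integer counts the mean of nonzero counts is always at least 1, so
observed/expected values are compressed, and after thinning at
`obs_exp_threshold` every per-distance sample ends up *underdispersed*
(variance below mean). Underdispersed samples admit no negative binomial —
the fit is skipped by design rather than forced — so no distance gets a
model and nothing can be called. The `all` mode divides by the true
per-distance mean (well below 1 in sparse data), preserves the
overdispersion of the ratio scale, and is therefore the mode used in this
package's simulation studies and recommended for matrices with per-pixel
means of order 1.

## Numerical choices

* The density and likelihood are evaluated in log space (`lgamma`); no
  overflow or underflow up to at least $k = 10^4$, $r = 10^3$.
* Fitting is method-of-moments ($p = 1 - m/v$, $r = m^2/(v-m)$) refined by
  Nelder–Mead maximum likelihood on the continuous density; if the
  optimizer fails or does not improve, the moment estimate stands. Samples
  that are too small (< `min_fit_values`), constant, or underdispersed are
  skipped with `fit_ok = FALSE`.
* Rank-sum tests use the exact distribution when both groups have at most
  25 values and no ties occur, otherwise the normal approximation with tie
  and continuity correction. All-equal inputs return p = 1.
* Window cells beyond the matrix or outside the distance band are
  truncated (absent), never imputed; in-band positions missing from the
  sparse store count as zeros. Window cells in the three corners other
  than the bottom-left belong to no test region but do enter the mean
  filter's background.
* Pooling, sorting and merging are fully deterministic, and neighborhood
  evaluation is free of randomness, so results are identical across
  worker counts (`threads`).

## The synthetic generator

`synthetic_spec()` / `generate_dataset()` emulate a single-chromosome
10 kb matrix: counts at distance $d$ bins are drawn from a negative
binomial with mean $c\, d^{-\alpha} + f$ and variance `dispersion` times
the mean; planted loops multiply the mean in a patch by a kernel with a
flat $3\times3$ core at the full enrichment factor and an exponentially
decaying shoulder (25% of the excess two bins out, halving per further
bin) — a sharp peak with an enriched direct neighborhood, the shape loop
pileups show at this resolution. Optional sparsity and zeroed "faulty"
regions emulate unmappable stretches. Everything is deterministic given
the seed.

The defaults (`decay_scale` 8192, `decay_alpha` 2.5, `decay_floor` 0.02,
`dispersion` 3, 20 loops at 8-fold enrichment with anchor distances
cycling through 16–18 bins) were calibrated once, as a test-bed design,
to place the fixture in the regime where every stage of the method is
exercised *and* well-posed:

* loop anchors sit in the deep part of the band (per-pixel means near 8
  counts), where the raw-count filter is reliably cleared and rank-sum
  separations are strong;
* several loops share each anchor distance, so the enriched pixels
  themselves make those distances overdispersed on the observed/expected
  scale and hence fittable — in the matched null matrix the same
  distances are underdispersed and are skipped, which is exactly the
  behavior the fit-skipping rule is meant to produce;
* the steep decay leaves the far band sparse, starving the null matrix of
  high-count noise pixels that could reach candidacy.

The generator does **not** emulate TADs or compartments, balancing
artifacts, trans contacts, resolution-dependent blur, or the shallower
decay exponent (near 1) of typical real matrices — its slope is
deliberately steeper so a 2 Mb band spans the full dense-to-sparse range.
Passing the simulation studies therefore demonstrates the internal
correctness and calibration of the pipeline under its model assumptions,
not loop-calling accuracy on real tissue data.

## Known limitations

* Like all statistics-first loop callers, isolated noisy regions whose
  peak and background happen to separate in rank can pass the tests;
  on real data a small false-discovery floor is unavoidable.
* The loop-count trend across `obs_exp_threshold` settings (stricter
  threshold, fewer loops) is a large-sample trend. Because the threshold
  doubles as the prefit filter, changing it refits every distance model,
  and the set of fittable distances is not nested across thresholds;
  on a 20-loop fixture the count can jitter by a single loop against the
  trend (the acceptance suite computes exactly this sweep).
* Distances are modeled independently; no smoothing across $d$ is done,
  so very sparse matrices lose distances (and their loops) to the
  `min_fit_values` floor.
* Only intra-chromosomal, single-resolution detection is supported.
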