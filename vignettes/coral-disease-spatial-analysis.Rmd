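---
title: "Two-resolution spatial analysis of coral disease surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-resolution spatial analysis of coral disease surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralspat)
```

## The data model and why resolution matters

A transect survey of coral disease records, per 25 m × 10 m plot, one
location, the number of host colonies, and the number of those colonies
showing disease. Two legitimate analyses of the same records disagree
systematically:

* **Transect level** treats each transect as a binary unit: diseased or not.
  Prevalence is the share of positive transects.
* **Colony level** weights each transect location by its colony counts.
  Prevalence is the share of diseased colonies.

Because a transect is positive as soon as *one* of its colonies is diseased,
transect-level prevalence always dominates colony-level prevalence whenever
transects hold more colonies on average than positive transects hold diseased
colonies — with mean counts around 6–7 colonies per transect and 1–2 diseased
colonies per positive transect, the inflation is roughly fourfold. This is an
instance of the modifiable areal unit problem (MAUP): the spatial unit of
aggregation, not the biology, drives the headline number. Every analysis in
this package is therefore run at both resolutions, and the synthetic
generator is built to reproduce the disagreement on demand.

## Second-order structure: the weighted L-function

The transformed Ripley's K implemented here is

$$L(d) = \sqrt{\frac{A\,S(d)}{\pi W}},\qquad
S(d)=\sum_{i\neq j} w_i w_j\,\mathbf 1[d_{ij}\le d],\qquad
W=\sum_{i\neq j} w_i w_j,$$

evaluated at the upper edge of each distance bin (default 0–2500 m in 50 m
bins). With unit weights it reduces to the classical
$L(d)=\sqrt{A\cdot\#\text{pairs}/(\pi n(n-1))}$, for which complete spatial
randomness (CSR) gives $E[L(d)] = d$; curves above the diagonal indicate
aggregation, below it dispersion. Colony-level analyses set $w_i$ to the
transect's colony count of interest, so a heavily populated transect
contributes as many "points" as it holds colonies without pretending to know
where, within the plot, each colony sits.

Numerical choices, stated once:

* **Normalisation.** The estimator above is the standard transformed K with
  weighted pair sums. This exact form is an assumption of the package —
  tools of the desktop-GIS generation did not always document their
  normalisation — and is therefore asserted prominently here and checked
  against a naive double-loop oracle in the tests (agreement to 1e-9
  relative error for n ≤ 200).
* **No edge correction by default.** None is applied; all curves that are
  compared to each other or to an envelope share the same bias, which is the
  use pattern throughout. A toroidal-shift correction is available behind
  the `torus` argument of `l_function()` for sensitivity analysis on
  rectangular regions. The area $A$ always comes from the declared study
  region, never silently from a bounding box, because $L$ scales with
  $\sqrt A$.
* **Ties at bin edges.** A pair at exactly a bin edge counts toward that bin
  (closed upper bound), identically in implementation and oracle.
* **Envelopes.** Each of the 99 (default) simulations redraws the same
  number of locations uniformly in the region, permuting any weights onto
  the new locations; the envelope is the pointwise min/max. An observed
  value exiting the envelope at a bin is significant at roughly the 0.01
  level, pointwise. The envelope is *not* a simultaneous band; over 50 bins
  roughly one excursion is expected under the null, and the tests treat it
  so.

## The difference function and random labeling

Host corals are themselves clustered (reef structure), so a clustered
disease pattern may reflect nothing but its hosts. The difference function

$$D(d) = L_{\text{disease}}(d) - L_{\text{population}}(d)$$

is tested under **random labeling**: all locations stay fixed, and each
simulation resamples which of them carry disease — at transect level, the
observed number of positive transects is drawn without replacement; at
colony level, the observed total of diseased colonies is drawn without
replacement from the pooled colonies. $D \equiv 0$ when disease mirrors its
population exactly (a property the tests assert), positive $D$ at small $d$
means contagion-like excess aggregation, negative $D$ means disease is more
dispersed than its hosts — the signature expected of a spatially uniform
(e.g. waterborne or terrestrial-origin) stressor acting on clustered hosts.

Random labeling, not random relocation, is the null because the scientific
question is conditional on where the susceptible corals are.

### Calibration asymmetry in the cross-resolution tests

`cross_resolution_test()` compares the colony-weighted observed curve to the
unweighted envelope (and vice versa). One subtlety, found empirically and
worth stating: when weights are shuffled (carry no spatial information), the
weighted observed curve still exits the *unweighted* envelope noticeably
more often than the nominal ~2% per bin, because the unweighted CSR envelope
does not contain the extra sampling variance the weights induce (measured
14–23% per-bin rejection for weight distributions with a handful of 6–8×
weights). The calibrated statement — asserted in the tests — is that
location-independent weights keep the weighted curve inside its *own*
weight-permuting CSR envelope at about the nominal rate. Rejections of the
cross-resolution hypotheses should accordingly be read as "the resolutions
disagree", not as a calibrated p = 0.01 statement.

## Filtered prevalence surfaces and Monte Carlo hotspots

A rectangular grid (nodes at cell corners, default 50 m cells) is laid over
the study region. At each node a circular filter of radius $h$ accumulates a
numerator and denominator — positive transects over transects, or diseased
colonies over colonies — into a smoothed local prevalence. Filters much
wider than the cell overlap heavily, which is what smooths the surface;
nodes whose filter catches nothing are *undefined*, never zero.

The default radius is the optimised bandwidth
$h_{opt} = \sigma\,(2/(3n))^{1/4}$, with $\sigma$ the standard distance
(RMS distance from the spatial mean) of the transect locations. For the
published survey this package emulates, $\sigma = 1688.2$ m and $n = 375$
give $h_{opt} = 346.9$ m, within 2% of the value printed alongside that
survey (342.55 m); the residual 1.3% discrepancy cannot be reconstructed
from the printed numbers and the standard form is implemented unchanged.

Significance is by constant-risk Monte Carlo: locations and denominators
stay fixed, and each of the (default) 1000 simulations redraws disease — per
transect, Bernoulli with the observed transect-level prevalence, or per
colony, so a transect's simulated count is Binomial in its colony count.
Because denominators are fixed, a node's simulated prevalence beats the
observed exactly when its numerator does, making the comparison exact
integer arithmetic. P-values use the add-one convention
$p = (1+\#\{\text{sims}\ge\text{obs}\})/(1+n_{sims})$, so $p$ is never 0 and
a node unbeaten in 1000 simulations gets $p = 1/1001$; zero-prevalence nodes
get $p = 1$ by construction. Nodes with $p \le \alpha$ (default 0.05, closed
inequality) and positive prevalence are grouped by 8-connectivity into
clusters; each cluster's footprint is the union of the cell squares centred
on its nodes, areas are reported in km², and summaries give the share of
positive transects and diseased colonies inside and within a 100 m buffer of
the clusters.

The node-owns-centred-cell convention for areas is a documented choice; grid
nodes are intersections, and the cell-size interpretation of "50 m grid" is
edge length.

## The synthetic generator: what it emulates, and what it does not

`scenario_config()` defaults describe a survey of 375 transects in a
7300 m × 3800 m region (the extent of the published analysis grid this
mirrors), with:

* **Locations** uniform, or Thomas-clustered (uniform parents, Gaussian
  offspring displacements, default SD 250 m, redrawn until inside the
  region) to mimic transects concentrated along reef structure. The true
  placement process of the real survey is unpublished beyond "randomly
  selected", so both are offered and nothing downstream assumes either.
* **Colony counts** from a zero-truncated negative binomial capped at 40,
  moment-matched (deterministically, on the capped pmf) to mean 6.65 and
  SD 5.99 — the published count distribution. Truncation at one reflects
  that only transects containing the host enter the survey; the
  overdispersion (SD ≈ mean) is typical of colony counts. An optional
  per-clump lognormal multiplier (`colony_cluster_effect`) makes counts
  spatially correlated, which is what turns colony-random disease into
  *transect-level* apparent clustering — the MAUP mechanism.
* **Disease** per colony, independently: `random` with p = 0.0277 (the
  published colony-level prevalence; this is also exactly the Monte Carlo
  null), `ubiquitous` as its low-rate alias, and `focal` with risk elevated
  `relative_risk`-fold within 300 m of 8 foci. The focal baseline defaults
  to `p / (1 + (RR−1)·coverage)` so the scenario redistributes, rather than
  inflates, the overall risk — a focal outbreak and the random null then
  share the same expected prevalence and differ only in geometry.

What the generator does **not** emulate: within-transect colony positions
(unknown in the real data), temporal spread (single snapshot), habitat or
bathymetry structure (depth is carried only as an optional covariate), and
irregular survey-region boundaries (the default region is rectangular; an
arbitrary polygon with a hole is supported but no claim is made that it
matches any real reef). A green test against this generator therefore
establishes the statistical machinery, not ecological realism.

### Power of planted-focus recovery

At the default survey density (375 transects over 27.7 km², ~6.6 colonies
each, 2.77% overall prevalence), a 300 m focus contains on average only ~4
transects (~27 colonies). Measured over 20 seeds, about 23% of uniformly
placed foci end up with at most one diseased colony within 350 m — such foci
are undetectable by any method, and overall recovery of planted foci by the
hotspot pipeline plateaus near 65–70%, not higher. This is a property of the
stated world (sparse sampling and low prevalence), not of the detector; the
corresponding acceptance check is deliberately left failing rather than
quietly re-tuning the scenario to pass it. The scenario-*separation*
property — focal surfaces show significantly larger maxima and cluster areas
than the null — holds comfortably.

## Degenerate inputs and numerical conventions

* Surveys with no records load (with a warning) but are rejected by every
  analysis; zero total colonies make prevalence undefined (error).
* `n_diseased > n_colonies` is rejected at construction, naming the record.
* Fewer than two disease-positive transects make the difference function
  undefined (error); the pipeline skips the affected analyses and says so in
  its manifest rather than failing the run.
* Significance classes treat |L − expected| below 1e-9 (relative) as
  "random" so that exact self-differences classify as null rather than
  picking a side by floating-point noise.
* All geographic input is projected once, on load, to a single planar metric
  frame (spherical transverse Mercator local to the data; round-trip exact
  to machine precision, scale error < 1 ppm over a 10 km survey). Every
  distance, area and bandwidth thereafter is planar metres.
* Reproducibility: every stochastic routine is a pure function of its
  explicit seed; the pipeline fans one master seed out to per-stage seeds by
  a fixed affine scheme (`seed + 1000003·k mod 2^31−1`), so any stage can be
  re-run alone.

## Known limitations

* No inhomogeneous-intensity or spatio-temporal K estimators; the difference
  function is the supported route for host heterogeneity.
* No Kulldorff-style scan statistic and no covariate-adjusted (regression)
  surfaces; depth is summarised but never modelled.
* The envelope semantics (min/max of 99 simulations) match the conventional
  0.01-level pointwise reading; no multiple-testing control across bins or
  nodes is attempted beyond the Monte Carlo null itself.
* Edge correction for the L-function is deliberately absent by default;
  curves near the maximum tested distance (comparable to the region size)
  are biased low, identically for observed and simulated patterns.
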