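---
title: "Measuring destination accessibility: methods behind dlumr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring destination accessibility: methods behind dlumr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlumr)
```

## The measurement problem

Neighbourhoods that put shops, schools, eateries, entertainment venues and
parks within walking distance of home tend to support more active transport
and physical activity, especially in adolescents. "Destination
accessibility" can, however, be operationalised in many ways, and indicators
that behave sensibly in a low-density suburb can misbehave in an ultra-dense
city. dlumr implements a family of twelve destination and land-use mix
(DLUM) indicators that together span three constructs:

* **intensity** — how much non-residential land, or how many non-residential
  parcels, a neighbourhood offers (`dlum1`, `dlum2`, `dlum3a`, `dlum3b`,
  `dlum4`);
* **heterogeneity** — how evenly that offer is spread across different kinds
  of destinations (`dlum5`, `dlum6`);
* **hybrids** — intensity weighted up by heterogeneity (`dlum7`–`dlum10`).

All indicators are computed inside a *sausage buffer*: the region within a
fixed offset (default 25 m) of every street segment reachable within a fixed
network distance (default 1000 m) of the participant's home. Unlike crow-fly
circles, sausage buffers respect the street fabric people actually walk, and
the 25 m offset captures the parcels adjacent to those streets.

## The neighbourhood unit: snapping, reachability, buffering

The street network is an undirected planar graph built by welding polyline
endpoints within a small tolerance (default 0.01 m). A home point is snapped
to the nearest point on the nearest edge (ties broken by smallest edge id;
snaps beyond `max_snap`, default 100 m, are errors rather than silently
distant attachments). From the snapped origin a shortest-path tree is grown:
edges whose farthest point lies within the threshold are kept whole, and
partially reachable edges are cut by linear referencing along their
polylines — never by straight-line chords — at the residual distance. An
edge reachable from both of its ends contributes the union of its reachable
portions, so loops are never double-counted.

Buffering uses round caps and round joins and dissolves overlaps into a
single region (holes appear naturally where a block interior is farther than
the offset from any street). Arcs are discretised to stay within 0.1% of the
offset radius, which keeps polygon areas within a few parts in 10^5 of the
analytic value; the test suite pins the buffer of a single straight 1000 m
segment against the closed form $2rL + \pi r^2$ at 0.1%.

Street intersections are network nodes with **three or more** incident
edges, the walkability-literature convention for "true" intersections;
degree-2 vertices (cartographic shape points, subdivision artefacts) never
count, and the suite verifies the count is invariant under edge subdivision.
The valence is configurable (`min_valence`) because template conventions
differ between studies.

## Parcels: clipped areas, whole counts

A parcel enters a buffer summary when it overlaps the buffer with positive
area. Its **area** contribution is the clipped area of the intersection —
this keeps area ratios geometrically consistent — while its **count**
contribution is 1 regardless of overlap fraction: a destination parcel
touched by the walkable street fabric is one destination. Whether
boundary-straddling parcels should count once, by centroid, or only on
majority overlap is genuinely undocumented across GIS templates, so the
count rule is configurable (`count_mode = "intersects"` (default),
`"centroid"`, `"majority"`); the default matches the buffer's purpose of
capturing parcels adjacent to the road. Parcels are single-use by
construction; mixed-use sources must be pre-split or mapped to a dominant
class by the reader's mapping configuration.

All areas are carried in km², densities per km², and the readers reject
coordinates that look geographic (lon/lat) instead of silently reprojecting;
a metres-vs-kilometres mix-up trips the same guard.

## The entropy indices

Both land-use-mix indices are normalised Shannon entropies over the five
non-residential use groups (commercial/retail/office, institutional/civic,
food-related, entertainment, parks):

$$\mathrm{LUM} = -\sum_{k} p_k \ln p_k \,/\, \ln N$$

with $p_k$ the proportion of non-residential **area** (`dlum5`) or
**parcel count** (`dlum6`) in group $k$, the convention $0\ln 0 := 0$, and
$N$ fixed at the number of categories in the classification scheme (5), not
the number present in a given buffer. The fixed-$N$ choice follows the
entropy tradition in walkability research and keeps the index comparable
across buffers: a buffer containing two perfectly balanced uses scores
$\ln 2 / \ln 5 \approx 0.431$, not 1. Whether residential land should enter
as a sixth category is not settled in the literature; dlumr uses the 5-use
non-residential composition, with `n_categories` exposed for sensitivity
analyses. The index is clamped to $[0,1]$ against floating-point residue; an
all-zero composition is undefined (`NA` with reason code), because "the mix
of nothing" is not a zero mix.

## Undefined values are flagged, never zeroed

Ratio indicators have honest failure modes: no residential land (`dlum1`),
no dwelling units (`dlum2`, and net residential density), no non-residential
land (`dlum4`, `dlum5`). These produce `NA` with a machine-readable reason
code (e.g. `dlum2:no_dwelling_units`) that propagates through the hybrids,
so downstream ranking can distinguish "no residential land" from "no
destinations". Silently substituting 0 or ±Inf would bias site means and
ranks in opposite directions.

`dlum2`/`dlum8` are reported per 100 dwelling units (`du_scale = 100`, the
reporting convention; set 1 for the plain ratio).

## Ranking sites and judging construct validity

`site_means()` collapses participant rows to per-site means (ignoring
undefined values), `rank_sites()` ranks sites within each indicator with
rank 1 for the largest mean and average ranks on ties (each column sums to
$n(n+1)/2$), and `ranking_summary()` reports each site's mean rank and its
**sample** (n−1) standard deviation across indicators. The n−1 convention is
pinned by a published 12-site rank table reproduced in the test suite: its
printed SD row matches only the sample estimator. Between-indicator
correlations default to Spearman — the indicators are strongly right-skewed
and often related monotonically but not linearly — with Pearson available.

`validity_association()` formalises the qualitative criterion "a consistent
correlate in the expected direction across sites": per site it computes the
Spearman correlation between an indicator and a criterion (a perceived
accessibility composite, or a physical-activity outcome) with one-sided
permutation p-values (default 999 permutations, seeded), and returns
`"consistent-positive"` only when every site's correlation is positive and
no site shows significant evidence of a negative association at
$\alpha = 0.05$; anything else is `"mixed"`. Sites with fewer than
`min_pairs` (default 10) complete pairs are skipped with a warning rather
than contributing noise. The permutation p-values are verified approximately
uniform under the null in the test suite.

## What the synthetic city emulates — and what it does not

Because participant-level built-environment data are rarely shareable, the
package ships a seeded generator that emulates the *structure* such data
take: an orthogonal grid of blocks (default 6×6 blocks of 150 m) whose
streets form the network; each block tiled by 4×4 rectangular single-use
parcels drawn i.i.d. from a six-class mixture (default 55% residential,
15% commercial/retail/office, 10% food-related, 8% institutional/civic,
8% park, 4% entertainment — a mixed-use urban fabric); dwelling counts on
residential parcels from a negative binomial (mean 40, size 5, floor of 1,
giving roughly 16,000 dwellings/km² of residential land, mid-way on the
international density spectrum); homes sampled uniformly within residential
parcels. Perceived proximity items are generated by banding network
distances to the nearest destination of each group into the 1–5 walking-time
scores used by neighbourhood-walkability surveys (5 for ≤5 min down to 1 for
>30 min at 80 m/min, the common planning walking speed; the intermediate
10/20/30-minute cut-offs are a stated assumption, since only the end anchors
of such scales are standardised). Entertainment has no perception item,
matching the instruments in use. Physical-activity outcomes follow the
association structure validity analyses estimate: weekly non-school active
transport is Poisson with log-mean $\alpha + \beta z$ (defaults
$\alpha = \ln 5$, matching typical weekly trip frequencies, $\beta = 0.3$),
regular walking to school is Bernoulli on the logit scale (intercept at 42%
prevalence).

What the generator deliberately does **not** emulate: curvilinear and
irregular street morphology, mixed-use and multi-storey parcels, spatial
autocorrelation of land uses (shopping streets, park clusters),
socioeconomically stratified recruitment, and measurement error in
geocoding. Tests passing on synthetic cities therefore certify the
*computational* contract — geometry, aggregation, index algebra, ranking
arithmetic, calibration of the permutation tests — not that any indicator
will correlate with behaviour in a particular real city.

## Numerical choices

* Welding tolerance 0.01 m by default; welding is single-linkage within the
  tolerance, so chains of nearby endpoints merge.
* Ties in snapping resolve to the smallest edge id; all randomness flows
  from explicit integer seeds and every generator is deterministic given its
  seed.
* Buffer arcs: `arctol = offset/1000` (>16 vertices per quarter circle).
* Polygon overlap below 1e-6 m² counts as boundary contact, not overlap.
* Zero-length self-loops produced by welding are dropped with a warning.
* Shortest paths and components come from igraph; polygon booleans and
  polyline offsetting from polyclip (Clipper); both are exact-arithmetic
  robust implementations, so no bespoke epsilon-tuning is layered on top.

## Problem sizes used in the shipped checks

The test suite and the reproduction script favour many small, fully checked
configurations over few large ones: grid fixtures up to 4×4 blocks, random
networks up to 30 edges (checked against an independent subdivision oracle
of the reachable length), 1000-row random summaries for the algebraic
identities, 100 replicates of the slope-recovery simulation at n = 2000, and
500 replicates of the permutation-calibration check at 199 permutations.
These sizes give each statistical check comfortable Monte-Carlo margins
while keeping a full run in the low minutes on one CPU.

## Known limitations

* The network is undirected with no one-way streets, turn penalties or
  pedestrian impedances; distances are planar metric, so inputs must be in a
  projected CRS appropriate to the study area.
* Indicators are 2-D: floor-space and destination-count refinements (which
  matter most in high-rise, mixed-use cities) need data the parcel model
  does not carry.
* Site means are simple arithmetic means; model-adjusted marginal means
  (e.g. mixed models over recruitment strata) are out of scope, so rankings
  from `rank_sites()` reflect raw between-site composition.
* GeoJSON is the only spatial interchange format read and written.
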