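---
title: "hingehic: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hingehic: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind each stage of the package, the
parameters that matter, the synthetic-data generator and its calibration,
and the numerical decisions a maintainer would want written down.

## Coordinates, containers, and scope

All coordinates are 0-based half-open, the native convention of BED,
bedGraph and the internal pairs table; `.pairs` inputs can be declared
1-based (`pairs_base = 1`) and are shifted on read. Assemblies may carry
two namespaces (sample and spike-in) so that merged-genome workflows can
be filtered to one genome; spike-in chromosomes are carried as tags only —
no spike-in count normalization is performed, since spike-ins in this kind
of experiment serve as a qualitative technical control.

Analysis is strictly per-chromosome and cis-only. Trans contacts are
tallied during binning and then dropped: every downstream statistic
(insulation, compartments, flares) is a cis feature. Matrices are stored
dense; at the package's desk-scale defaults (chromosomes of tens of Mb at
10–100-kb bins, at most a few thousand bins) a dense matrix is small, and
a sparse representation would add a second code path without changing any
result.

## Balancing and its edge artifact

`balance_matrix()` implements Sinkhorn-style iterative correction: bins
with raw marginal below `mask_frac` (default 0.1) times the median
non-zero marginal are masked, then rows and columns are rescaled until all
valid-bin marginals agree with their mean within `tol` (default 1e-5,
`max_iter` 500). Masked bins become NA rows/columns, so undefined values
propagate explicitly rather than silently becoming zeros.

Forcing equal marginals has a systematic side effect at chromosome ends:
an edge bin cannot reach partners on one side, so its raw marginal is
genuinely smaller, and balancing inflates its remaining (short-range)
entries — by up to a factor of two at the outermost bins, decaying over
roughly a megabase. On decay-only data this masquerades as megabase-scale
"positive insulation" at every chromosome end. `insulation_scores()`
therefore applies an expected-model edge correction by default
(`edge_correct = TRUE`): it builds the distance-only expected matrix from
the balanced map's own per-diagonal means, computes that model matrix's
iterative-correction weights — which capture exactly the positional
inflation the equal-marginal constraint imposes — and multiplies the
balanced matrix by their outer product. For uniform-coverage data this
provably removes the positional component while leaving coverage
normalization intact; on the package's synthetic null maps the corrected
diamond means are flat to within counting noise across the whole
chromosome.

## Insulation scores and boundary calling

For window `w` (a multiple of the resolution, `w/resolution >= 2`), the
raw insulation of bin *i* is the mean of the balanced (edge-corrected)
matrix over the off-diagonal diamond spanning `w` bins on each side of
*i*. Two representations are kept per window:

- `scores`: the per-chromosome z-score of `log2(raw + 1e-6)` — the track's
  sign semantics (positive = contact enrichment, negative = depletion) and
  the flare-caller input;
- `log2_dev`: the centered log2 value — the same quantity in absolute
  contact-fold units.

Both are needed because the z-score deliberately removes scale: on a
structureless map, pure counting noise still spans |z| ≈ 3, so a z
threshold alone cannot distinguish a real boundary from noise. The
centered-log2 track restores the absolute scale (and makes both tracks
exactly invariant under global scaling of the matrix). `summary` is the
mean across windows and is defined only where every window is defined;
bins within the largest window of a chromosome end, masked bins, and bins
with fully masked diamonds are NA. The z-score of a constant vector is
defined as zero.

Default windows are {100, 200, 400, 800} kb at 25-kb resolution for
TAD-scale work. `call_boundaries()` places a boundary at bin *i* when the
summary is a strict local minimum within ± `min_separation` bins (default:
the smallest window in bins — using the largest window here would let the
boundaries of adjacent sub-megabase domains suppress one another), the
dip reaches `-min_depth` (default 1.5 z), the z prominence (smaller of the
rises to the highest flank on either side of the neighborhood) is at least
`min_prominence` (default 1.5), and the same prominence measured on the
centered-log2 summary is at least `min_log2_drop` (default 0.3, i.e. a
~23% real contact depletion). The defaults come from a calibration on the
package's own synthetic data: on decay-only maps the deepest noise minima
stay an order of magnitude below 0.3 in log2 units, while true
domain-junction dips at the generator's default enrichment sit well above
it; the test suite pins both sides (false positives ≤ 1 per 10 Mb on null
maps, recall and precision ≥ 0.9 on the TAD preset).

## Compartments

`compartment_pc1()` takes the Pearson correlation matrix of the O/E map
(pairwise over mutually defined entries), mean-centers its columns, and
uses the leading principal component of the valid-bin submatrix, computed
per chromosome — never genome-wide, since the eigenvector basis is not
comparable across chromosomes. PC1 is variance-normalized and its sign is
anchored by correlation with an external orientation track (gene density
or GC content binned at the analysis resolution); A = PC1 > 0. A
degenerate leading eigenpair (top two eigenvalues within 1e-9) is refused
rather than silently picking an arbitrary direction. Compartment analysis
defaults to 100-kb bins: checkerboard blocks are megabase-scale and the
correlation matrix at finer bins mostly adds noise.

## Flares (hinge-like domains)

A hinge at pivot *p* enriches contacts between loci equidistant from *p*:
pairs `(p-d, p+d)` up to a petal half-width *W*. In an insulation track
this appears as a run of elevated scores centered on the pivot whose
footprint is capped by `min(window, 2W)`. The recommended operating point,
fixed during calibration and used by the test suite and acceptance
script, is 10-kb matrices with windows {50, 200} kb:

- the bin size must not exceed the anti-diagonal jitter (σ = 25 kb in the
  generator); at 25-kb bins the band covers only about half of each
  matrix cell and the per-cell enrichment is diluted ~2×;
- the largest window sets the footprint; 200 kb yields called widths that
  recover a 150-kb petal half-width, while windows much larger than 2W
  blur neighboring flares together (pivots are only ~1 Mb apart).

`call_flares()` extracts maximal runs of largest-window scores above
`threshold` (default 0.15 z), merges runs within `merge_gap` (50 kb,
inclusive), drops candidates overlapping the blacklist, and keeps those
with width ≥ `min_width` (50 kb), peak z ≥ `min_peak` (0.5) and peak
centered-log2 ≥ `min_peak_log2` (0.15). The threshold default departs from
a strict "> 0" rule for the same reason the boundary caller carries a
log2 criterion: on a per-chromosome z-scored track, zero is approximately
the background mode, so a literal positive-value extraction marks a third
of background bins and gap-merging welds them into megabase artifacts.
0.15 z plus the absolute log2 peak filter reproduces the intent —
extracting the genuinely enriched runs — with false calls controlled at
or below the level the width/peak filter was designed to replace (the
original workflow's manual curation of assembly artifacts). The pivot is
the maximal-score bin (first on ties); `pivot_symmetry_score()` then reads
the mean O/E along the anti-diagonal through the pivot, which is 1 under
the null and equals the embedded enrichment on noise-free fixtures.

Width histograms use left-closed bins labeled by bin center, ties to the
smaller width; spacing is midpoint-to-midpoint between consecutive flares
on a chromosome, with pairs excluded when the intervening span touches
the blacklist (an assembly gap would otherwise distort the distance).

## ROSE-style enhancer stratification

Constituent peaks (by construction the intersection of two activating
marks; `intersect_peaks()` is provided) are first TSS-filtered: a peak
fully contained in TSS-midpoint ± `tss_excl` (2,000 bp) is removed,
partial overlaps are kept. Survivors are stitched across gaps ≤
`stitch_gap` (12,500 bp, the conventional ROSE default) and scored by the
sum over the stitched span of per-bin `signal − control`, floored at 0 per
bin, with track values treated as per-bin densities (weighted by
overlapped width / bin width). The super-enhancer cutoff rescales the
ascending rank-score curve to the unit square and takes the point of
maximal vertical distance below the unit diagonal — where a slope-one line
is tangent to the convex curve. This tangent construction, rather than a
literal scan for the first sub-unit discrete slope from the top, is what
the standard implementation of the algorithm computes, and it matters in
practice: with realistic score noise among the top regions, a discrete
slope scan triggers on the first pair of near-tied super-enhancers and
truncates the SE set. Ties in the tangent point resolve to the top of the
curve, so a perfectly linear curve yields zero super-enhancers; an
all-equal score vector warns and yields zero.

Non-SE regions are split by rank into `n_groups` (3) contiguous cohorts,
G3 strongest; a remainder goes to the weakest cohorts so the strong groups
are never larger than stated. `insulation_composition()` turns maximal
positive-summary runs into regions, assigns each the stratum of its
maximum score (default bounds 0.1/0.2/0.3 — kept from the conventional
presentation of positive-insulation strata; with z-scored tracks these
bounds are configuration, not physics) and the highest-priority
overlapping group (SE > G3 > G2 > G1 > none). Region-level counting is
the default; per-bin counting is available (`mode = "bin"`) since the
choice of denominator is a genuine ambiguity.

## Contamination mixing

`mix_pairs()` draws exactly `round(n·fraction_b)` pairs (round-half-even)
without replacement from the contaminating set and the remainder from the
background set, deterministically per seed, tagging provenance.
`boundary_dip()` rebuilds matrices from the mixture, computes insulation,
and centers a metaplot on reference boundaries (those called on the pure
structured sample); the dip depth is the mean of the two flank-edge
columns minus the central column. A mixture is called detectable when the
depth reaches τ = 0.3 z with a 500-kb flank — the operational criterion is
a package decision, reported alongside results, since "detectable
genome-wide" is qualitative. `mixing_sweep()` runs one seeded mixture per
fraction at fixed total depth (2×10⁶ pairs by default) and reports the
minimal detectable fraction.

## The synthetic-data generator

`generate_contact_pairs()` draws each pair as anchor + signed distance,
with distances from a truncated power law `P(s) ∝ s^(-alpha)` on
`[min_dist, max_dist]`, optionally mixed with a lognormal bump
(mode-parameterized) for condensed, mitotic-like maps. Structure enters
through acceptance weights on the proposal: ×β when both ends fall in one
true contact domain, ×γ when both ends share a compartment checkerboard
label, ×η when the pair lies within σ of the anti-diagonal through the
nearest hinge pivot with both ends within the petal half-width W.
Rejection sampling renormalizes, so the output is exactly `n_pairs`
records, byte-identical for a given spec and seed (one seeded generator,
fixed per-stage and per-chromosome sub-seeds).

Preset conditions (two 20-Mb chromosomes, 2×10⁶ pairs — sizes chosen so
the full suite runs in minutes on one CPU):

- `null`: α = 1, distances 20 kb–chromosome length; nothing else.
- `tads`: gamma-distributed domain sizes (mean 500 kb, CV 0.3), β = 3.
- `compartments`: 1-Mb alternating blocks, γ = 2.
- `sperm`: hinge pivots every Δ = 1 Mb, petal half-width W = 150 kb,
  η = 3, jitter σ = 25 kb; decay α = 0.45 with a lognormal bump at 2 Mb
  (sdlog 0.35, weight 0.25). The bump weight was calibrated once so that
  the log-binned distance distribution — the representation in which a
  long-range interaction peak is read — peaks beyond 1 Mb while the map
  retains a realistic share of short-range contacts; at these settings
  the per-pivot insulation signal-to-noise is about 2–4 z at the flare
  operating point, which is what makes detection non-trivial rather than
  automatic.
- `post_zga_enhancers`: graded enhancers on a 500-kb slot grid (per
  chromosome: 6 SE, 10 each of G3/G2/G1), with 90-kb contact domains
  (β = 3) embedded at SE and G3 positions — strong enhancers sit inside
  small contact domains, weak ones do not.

`generate_signal_tracks()` renders enhancers as Gaussian kernels
(sd 15 kb) on a 10-kb binned track with additive Gaussian noise
(sd 0.5): G1/G2/G3 heights 2/4/8, super-enhancers as clusters of three
constituent peaks 12 kb apart with heights drawn from U(10, 20) — the
spread keeps the top of the rank curve steep, and the clustering makes
stitching produce one large high-score region per SE. TSS decoys carry
their own kernels and peaks fully inside the ±2-kb exclusion window, so a
failure of TSS exclusion shows up as a ranking error.

What the generator emulates is the *map-level statistics* the detectors
consume: decay slopes, block enrichment, checkerboards, anti-diagonal
flares, graded signal. What it does not emulate: polymer mechanics or
loop extrusion, coverage bias along the genome (mappability, GC),
restriction-fragment granularity, duplicates and trans noise, or
assembly gaps. Passing tests therefore demonstrate that the estimators
recover known structure from realistic counting noise — not that they are
robust to every artifact of real libraries; on real data the blacklist
arguments and the masking fraction do that work.

## Numerical choices and degenerate inputs

- ε = 1e-6 inside `log2(raw + ε)`; zero-coverage diamonds are NA, not 0.
- z-score of a constant vector: all zeros (avoids 0/0).
- Feature centers: `floor((start + end)/2)`; even-length ties resolve to
  the lower coordinate.
- "Within 50 kb" merging is inclusive (gap ≤ 50,000 bp).
- `round-half-even` for mixture composition; exact composition reported.
- Empirical p-values use the add-one rule, `(1 + #{null ≥ obs})/(n_perm
  + 1)`, so p is never 0; two-sided doubles the smaller tail, capped at 1.
- Permutation shuffles relocate intervals uniformly within their own
  chromosome, length-preserving, rejecting blacklist overlaps with a
  bounded retry (error on failure, never a silent partial shuffle).
- Balancing refuses an all-masked matrix ("matrix too sparse") rather
  than returning an empty result.

## Known limitations

- Cis-only, per-chromosome: no trans maps, no genome-wide eigenvectors.
- The insulation score is this package's own definition (z-scored log2
  diamond mean with an absolute log2 companion); it matches the sign
  semantics and multi-window shape of the common TAD-separation scores
  but does not numerically reproduce any specific external tool.
- The composition strata defaults (0.1/0.2/0.3) are presentation
  conventions; with z-scored tracks their physical meaning depends on the
  data, and they are exposed as configuration.
- The flare-width histogram's bin-center labeling means a delta
  distribution at exactly a bin edge is reported at the covering bin's
  center (half-bin offset); all width comparisons in the tests allow for
  half a histogram bin.
- The generator's acceptance-weight scheme produces the right map-level
  signatures but is not a mechanistic chromatin model; η, β, γ are
  phenomenological enrichment factors.
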