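---
title: "Modelling regulatory reallocation after chromosomal inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling regulatory reallocation after chromosomal inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neotad)
library(dplyr)
```

This vignette is the package's account of its models: what each layer
assumes, which parameters matter, what the simulators do and do not
emulate, and where genuinely open design choices were resolved.

## The problem

Topologically associating domains (TADs) constrain which enhancers a
promoter can sample. Their borders are concentrations of occupied CTCF
sites, and boundaries flanked by convergently oriented site groups are
the ones that insulate effectively. A chromosomal inversion that moves a
boundary can therefore fuse previously separated domain fragments into a
neo-TAD and hand a gene a foreign enhancer repertoire. `neotad`
implements that causal chain as five composable layers: genome
reconstruction, boundary modelling, contact-map comparison, interval
statistics, and single-cell expression inference.

## Coordinates and the segment map

All internal coordinates are 0-based half-open, the BED/chain
convention. Published breakpoint pairs in 1-based "chrN: start–end"
style are accepted via `convention = "paper"` in
`rearrangement_spec()`, which treats the two printed positions as the
flanks of the rearranged segment: the segment becomes
`[start − 1, end − 1)` and its length `end − start`. For the motivating
inversion this yields 963,246 bp, i.e. 963 kb at the reported precision.
Whether the printed positions are segment endpoints or flanking bases is
ambiguous at the ±1 bp level; the kb-rounded value is insensitive to the
choice, and we fixed the flanking-base reading once.

`compile_rearrangement()` turns disjoint inversion/deletion/duplication
operations into a `segment_map` whose mutant blocks tile
`[0, mutant_length)` — an invariant asserted on every compile. Nested or
overlapping operations are rejected: every allele considered here is
expressible without nesting, and refusing them keeps liftover
single-valued except where duplication genuinely makes it multi-valued
(there, `lift_position()` returns all hits rather than failing).
Features that straddle a block junction are split into suffixed
sub-features or dropped and counted — never silently lost.

## The toy locus

`make_toy_hoxd_locus()` is a deterministic ~10× scaled model (400 kb at
1 kb working resolution) of a *HoxD*-like locus. It encodes the features
that matter for reallocation and nothing else:

* five CTCF boundary groups `B1`–`B5`, with the intra-cluster pair
  `B2`/`B3` bidirectional (both orientations above the weight
  threshold) and the flanks orientation-biased;
* a distal (centromeric) enhancer domain whose bulk (`GCR`, `IslandA`)
  lies centromeric of the inversion's 5′ breakpoint and so stays in
  place, plus one distal enhancer (`Prox`) inside the inverted segment
  adjacent to *Hoxd13*;
* a proximal (telomeric) enhancer domain with a strong enhancer
  (`CS65`) just inside the 3′ breakpoint and a weak series
  (`CS68`, `PLE01`–`PLE05`) beyond it, which is therefore never
  inverted.

With this geometry the package's same-domain assignment rule reproduces
the expected biology: in the wild type *Hoxd13* shares a domain only
with distal enhancers; after the main inversion it sits in a fused
domain (bounded by the relocated `B2` and the distal `B5`) together with
`Prox` and the weak proximal series but not `CS65`; with the
alternative breakpoints (`"ulnaless"`, cutting inside the `Lnpk` body
and centromeric of `CS65`) it additionally captures `CS65`. Absolute
coordinates are fixture constants defined in one function.

The locus's boundary *weights* are free parameters: published maps show
boundary strength only qualitatively (triangle sizes), so the fixture
gives the large groups unit weights and the small mid-domain group 0.8
per site, enough to clear the default `min_strength = 1`. Nothing
downstream depends on the precise values as long as all five groups
qualify.

## Boundary model

`cluster_ctcf()` is single-linkage clustering along the chromosome with
`max_gap` (default 20 kb at genome scale, 2 kb for the toy locus — both
roughly two bins of the corresponding contact maps) and classes clusters
bidirectional when each orientation reaches
`min_weight_per_orientation`. `predict_partition()` places domain edges
at boundary-cluster *midpoints*: midpoints give a deterministic tiling,
whereas cluster edges would leave gaps. Adjacent boundary pairs are
annotated convergent when forward sites on the left face reverse sites
on the right; this annotation is descriptive — the partition itself uses
only strength, a deliberate simplification that ignores loop-level
specificity. Enhancer–gene assignment is by feature midpoints, so it is
invariant to within-domain position shuffling (a property the tests
exercise).

## Contact-map model and operations

The simulator draws symmetric matrices with
`E[c_ij] = C · (|i−j|+1)^(−α) · ∏ f_b`, the product running over
boundaries strictly between bins `i` and `j`. The `+1` keeps the
diagonal finite (distance-0 convention). Defaults `C = 100`, `α = 1`,
`f_b = 0.4` give desk-scale maps with realistic contrast; `noise =
"poisson"` samples the upper triangle and mirrors it. The model ignores
everything else real Capture Hi-C has — capture-probe bias, mappability,
loops, compartments — so passing tests demonstrate that the *operations*
are correct, not that the model fits real chromatin.

`subtract_contacts()` normalizes both operands to an equal total before
differencing. Equal-total scaling was chosen over matrix balancing
(ICE/KR) because the comparison of interest is between two captures of
the same locus in different genotypes, where a single global scale
difference is the dominant nuisance; balancing is out of scope.
`remap_to_reference()` assigns each mutant bin to the wild-type bin
containing the lift of its midpoint. Midpoint assignment (rather than
fractional splitting) keeps the operation a permutation whenever
breakpoints are bin-aligned — then mass is conserved exactly — and any
mass lost through deleted regions is reported in an attribute, never
silently. The insulation score is the plain diamond mean over a
`w × w` window (default `w = 5` bins) with edge bins masked `NA`;
boundary calls are local minima filtered by prominence. The multi-scale
z-score machinery of the established TAD-calling tools is intentionally
not reproduced: on the generative model above, the raw diamond mean
already recovers a planted `f_b = 0.2` boundary within ±1 bin in ≥ 95%
of Poisson-noise simulations at `C = 100`.

## Peak-set statistics

Overlap uses the ≥ 1 bp criterion (the bedtools default) with no
reciprocal-fraction option. Directional counts are reported with the
reference stated, because a single published overlap count can come from
either side's convention or from merged fragments; the report carries
all three. Percentages round half up: the two printed percentages used
as fixed checks (37% and 70%) reproduce exactly under this rule, while
one published figure (6182/24141, printed as 25%) computes to 25.6% and
rounds to 26 — the package documents its rounding and does not force the
printed value.

## Zero-proportion inference

For UMI counts the zero proportion `p0` of a gene is a monotone proxy
for its mean expression. The rate model inverts the observable
`p0 = mean_c P0(s_c · r)` over cells `c` with depth `s_c`, where
`P0(μ) = e^(−μ)` (Poisson) or `(θ/(θ+μ))^θ` (negative binomial). The
right-hand side is strictly decreasing in `r`, so a bracketed root
search (relative tolerance 1e−8) inverts it deterministically; `p0 = 0`
or `1` returns a flagged boundary rate. This is a deliberate
deterministic stand-in for full posterior deconvolution of expression
distributions: it estimates a single rate per subset, with uncertainty
from a cell-level percentile bootstrap (default `n_boot = 1000`, no BCa
correction) rather than from a posterior.

Three caveats shape correct use, and the tests encode them:

* **Family matters.** Inverting negative-binomial zeros with the
  Poisson formula biases *ratios* of rates, not just levels; fold-change
  coverage drops badly if the family is misspecified. θ is a user
  parameter or a per-gene method-of-moments estimate; there is no
  shrinkage across genes.
* **Depth confounds p0.** Two samples with equal rates but different
  depths differ in detection. Comparisons of raw detection proportions
  are only valid at matched depth, which is why `downsample_depth()`
  does exact multivariate-hypergeometric downsampling (sequential
  hypergeometric draws per cell) instead of size-factor scaling — zero
  proportions are only comparable when every cell has the same total.
* **Shared depth induces dependence.** Because all genes share a cell's
  depth, detection of any two genes is positively associated even
  without biological coupling; a true independence null needs
  constant-depth simulation. Real-data conditional-detection odds ratios
  should be read with this in mind.

Detection thresholds are `count > 0`; detection CIs are Wilson at 0.95.
`correlation_sign()` rank-correlates depth-normalized counts and reports
`p_opposite`, the bootstrap probability that the correlation's sign is
wrong — the quantity to quote when the claim is "these two genes are
anti-correlated".

## The count simulator

`simulate_counts()` draws per-cell depth factors from a log-normal
(default median 5000, sdlog 0.35 — typical droplet-experiment
variation), then gene counts from a negative binomial with mean
`depth × rate × fold` and gene dispersion θ. Planted gene–gene
correlation uses a shared per-cell latent factor multiplying one gene's
rate and dividing the other's: unlike a copula it approximately
preserves the NB marginals and inverts trivially (coefficient 0 is exact
independence). The defaults emulate the package's motivating experiment:
two genotypes, two proximal-limb clusters of 500 cells each, a planted
2-fold gain of *Hoxd13* in the mutant, and an anti-correlation between
*Hoxd13* and *Hoxa11*. The published real-data effect ranges (a 1.7–3.0
fold *Hoxd13* gain, a 40–55% *Hoxa11* decrease) come from a specific
archived dataset and are not reproduction targets at desk scale; the
simulation studies substitute coverage checks at the planted 2-fold
condition.

## Numerical and testing choices

* Seeds are explicit arguments everywhere; no function consumes global
  RNG state undocumented, and every simulator is bitwise reproducible.
* Problem sizes used by the test and acceptance studies: 400-bin
  contact maps for the toy locus, 60-bin maps for boundary-recovery
  studies (50 seeds), 500–2000 cells per genotype for the single-cell
  studies, 100 random rearrangements with exhaustive per-base liftover
  checks. These sizes put Monte-Carlo error well below the asserted
  margins while keeping a full run in minutes.
* At `n = 2000` cells a single zero-proportion draw carries ~4–6%
  sampling error, so rate-recovery accuracy is asserted on the mean
  signed error across seeds; single-draw assertions use closed-form
  fixtures where the answer is exact.
* Symmetry of contact matrices is enforced at 1e−9 relative tolerance;
  masked bins are `NA`, never 0.

## Known limitations

The boundary model is threshold-based, not learned; insulation strength
is not fitted to real contact data, and the mapping from occupancy
weight to `f_b` is a free parameter. The contact model has no loops or
compartments. Liftover refuses nested rearrangements. The zero-
proportion model estimates one rate per subset and cannot see bimodal
expression within a subset. None of these limit the package's purpose —
propagating rearrangement geometry through domain logic to testable
regulatory predictions — but all of them matter before applying it to
data that violate the assumptions.
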