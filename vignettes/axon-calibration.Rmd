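---
title: "Calibrating streamline connectomes to absolute axon counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating streamline connectomes to absolute axon counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axoncount)
```

## The estimation problem

Diffusion-MRI (dMRI) tractography yields, for every pair of cortical parcels,
a streamline count in arbitrary, pipeline-specific units. Many questions —
wiring budgets, volume constraints, the plausibility of direct interareal
communication — require the *absolute* number of axons. The corpus callosum
makes a conversion possible: essentially all interhemispheric corticocortical
axons pass through it, its cross-sectional area $A_{cc}$ is measurable per
subject from structural MRI, and its axon packing density $\rho$ has been
measured histologically (the default is $\rho = 3.7\times10^{5}$ axons/mm²,
shrinkage-corrected). For subject $s$ the number of callosal axons is
$A_{cc,s}\,\rho$, and dividing by the subject's total interhemispheric
streamline sum gives a conversion ratio

$$ c_s \;=\; \frac{A_{cc,s}\,\rho}{\sum_{i\in L,\,j\in R} S^{(s)}_{ij}} , $$

with the cohort ratio $\bar c$ the arithmetic mean of the per-subject
quotients. `axon_calibration()` is the package's core fit; its `coef()` is
$\bar c$ and its `predict()` method maps a streamline matrix $S$ to the
axon-count matrix $N = \bar c\, S$. The procedure is invariant to the overall
scale of the dMRI metric — rescaling all streamline matrices by $k$ rescales
every $c_s$ by $1/k$ and leaves $N$ unchanged — which is asserted numerically
in the test suite to $10^{-10}$ relative tolerance. We also report the
ratio of cohort means, $\overline{A_{cc}\rho}/\overline{\sum S}$, as a
diagnostic; it differs from the mean of quotients when areas and streamline
totals covary across subjects.

Key assumptions inherited by everything downstream:

* streamline counts are proportional to axon counts, with the same
  proportionality for intra- and interhemispheric connections;
* each interareal axon belongs to exactly one projecting pyramidal neuron
  (used by the projection-fraction bounds);
* the matrices are undirected: all statistics pool unordered parcel pairs,
  each counted once, and the interhemispheric total is the sum of the
  left-by-right block.

## Downstream analyses

**Connectivity summaries** (`summarize_connectivity()`): total interareal
axons; median pairwise counts, intra- and interhemispheric; the fraction of
axons terminating in physically adjacent parcels; the implied upper bounds on
the fraction of pyramidal cells projecting outside their parcel and beyond
its neighbors; per-parcel totals and area-normalized densities; and
log10-binned histograms (0.25 dex bins, range auto-fit — purely
presentational). Medians include zero-count pairs by default
(`include_zero_pairs = FALSE` drops them); the median is invariant under any
strictly monotone rescaling applied uniformly to all pairs, a property used
repeatedly by the sensitivity analyses and unit-tested directly.
"Hemisphere-averaged" matrices are the mean of the left and right
intrahemispheric blocks after matching homologous parcels by name.

**Distance parity** (`bin_by_length()`, `parity_test()`): transferring a
callosally calibrated ratio to intrahemispheric pairs presumes tractography
treats the two pair sets similarly at matched fiber lengths.
`bin_by_length()` averages connectivity in 15 equal-width length bins
(configurable) with seeded percentile-bootstrap 95% CIs, resampling parcel
pairs within bins; empty bins are reported, never dropped. `parity_test()`
restricts both pair sets to the intersection of their length ranges
("distance-matched" — no pairwise 1:1 matching), fits OLS of
log-connectivity on length in each set, and bootstraps the slope and
intercept differences. The correlation comparison is a seeded permutation
test on the intra/inter labels; because the two sets have different length
distributions even inside the common domain, labels are permuted *within
equal-width length strata* (default 15), so each permuted set keeps its
length profile. An unstratified permutation would reject under the null
merely because length spread drives the correlation. A Fisher-z comparison is
reported as a secondary statistic. The exact published form of the "paired r"
comparison is not recoverable, so the permutation construction is this
package's own choice and its printed p-value is not comparable figure by
figure. Pairs with zero connectivity cannot be log-transformed; they are
excluded from regressions and counted in the output.

**Volume accounting** (`effective_axon_area()`, `occupied_wm_volume()`,
`interface_area()`, `neural_density()`, `subcortical_budget()`): the
effective per-axon cross-sectional area is $1/\rho \approx 2.7\times10^{-6}$
mm²/axon and deliberately includes myelin, glia and extracellular space,
because $\rho$ counts axons per mm² of whole tissue. Occupied white-matter
volume is $\sum_{i<j} N_{ij} L_{ij} / \rho$; interface area is total axons
over $\rho$, expressed as a fraction of the white–gray interface area
(default $1.77\times10^{5}$ mm²). Reference volumes and areas are always
user-supplied inputs, never computed from images. All of these are exactly
linear in the axon matrix, and the implementations are tested against
brute-force pairwise loops.

**Trans-terminal tract fractions** (`tract_spec()`,
`trans_terminal_fraction()`): a fasciculus' total axon capacity is its
mid-tract cross-sectional area times the ipsilateral packing density
(default $3.5\times10^{5}$ axons/mm²); the trans-terminal count is the
calibrated axon sum between its two termination fields within a hemisphere.
Field definitions are data, not code: conservative and liberal AF/SLF
specifications (Broca- and Wernicke-centered parcel sets, with published AF
and SLF cross-sections) ship as YAML under `inst/extdata/`. The fraction
assumes every field-to-field axon runs through the tract, so it is an upper
bound; it is monotone in field inclusion, linear in the axon matrix, and
homogeneous of degree $-1$ in density — each property unit-tested.

**Sensitivity simulations** (`adjust_uniform_short()`,
`adjust_inverse_length()`, `sensitivity_sweep()`): the calibration rests on
callosal fibers, which are long, so errors are most plausible for short
fibers. Two what-if engines: (1) multiply all pairs shorter than a threshold
(default 40 mm) by a factor (default 2); (2) scale each pair by
$m(L) = 1 + k\,(1/L - 1/L_{\mathrm{ref}})$, which is largest for the
shortest fibers and vanishes at $L_{\mathrm{ref}}$ (default: the longest
observed fiber, where the calibration is trusted). Published slope
parameters for such adjustments are not tied to a stated length unit, so the
user-facing `slope` here is $k$ in mm — the multiplier increase per unit
inverse length — and `multiplier_at_min` offers the unambiguous
parameterization "multiplier at the shortest observed length"
(`multiplier_at_min = 2` is the doubled-density/halved-sensitivity
scenario). Because total hemispheric WM volume is anatomically fixed, with
`hold_volume_constant` the effective per-axon area is rescaled by the ratio
of baseline to adjusted occupied volume (a single global factor, i.e. a
reciprocal density change), making occupied volume exactly invariant. The
engines report percentage changes in the total and in both medians, flag
whether global rank order was preserved (when it is, medians of a uniformly
boosted upper tail do not move), and are monotone in their adjustment
parameters.

**Demographics** (`group_compare()`): one-way F tests of per-subject
interhemispheric axon totals on sex and age group plus their interaction,
with seeded bootstrap 95% CIs of group means. Across-subject totals are
treated as approximately normal (across *pairs*, counts are log-normal; the
two distributions live on different axes).

## The synthetic-cohort generator

`generator_config()` + `generate_parcel_table()` +
`generate_length_matrix()` + `generate_cohort()` produce seeded cohorts with
the statistical structure the analyses assume, so the whole pipeline is
testable without any imaging data. What it emulates:

* 180 parcels per hemisphere with mirror-symmetric names, areas, networks
  and adjacency; areas are gamma-distributed and rescaled to sum to the
  white–gray interface area ($1.77\times10^{5}$ mm² by default).
* Abstract geometry: each hemisphere's parcels are embedded in a planar
  disc, the right hemisphere mirroring the left; adjacency is the union of a
  k-nearest-neighbor graph (k = 3) and a minimum spanning tree, so it is
  connected and "planar-like". Fiber lengths are affine-rescaled embedding
  distances with the two discs physically separated, so interhemispheric
  fibers are systematically longer; all lengths lie in `length_range`
  (default 10–300 mm). No meshes, no tracking — the pipeline only consumes a
  length matrix.
* An exponential distance rule with hemispheric parity built in:
  $E[S_{ij}] = S_0 e^{-\lambda L_{ij}}$ with one $\lambda$ for all pairs.
  The default $\lambda = 0.05$/mm spans about 6 decades of connectivity over
  the length range, which together with the pair noise reproduces the
  several-orders-of-magnitude spread seen in real parcellated connectomes.
* Log-normal pair noise with $\sigma = 1$ by default, drawn symmetrically
  per subject and *mean-one* ($e^{\sigma z - \sigma^2/2}$), so the expected
  streamline matrix equals the noise-free base matrix and mean
  log-streamlines decline at exactly $-\lambda$ per mm. Nonadjacent log
  weights are Gaussian by construction (checked with a Shapiro–Wilk test).
* Disproportionally strong adjacent pairs: within-hemisphere neighbor pairs
  are multiplied by `adjacency_boost` (default 8, chosen so that the few
  adjacent pairs carry roughly half of all axons, the regime the real
  connectome occupies).
* Calibration closure: the streamline scale $S_0$ is set so that
  `callosal_area_mean` $\times$ `calibration_density` equals
  `true_axons_per_streamline` $\times$ the noise-free interhemispheric sum.
  Calibration on a noise-free cohort then recovers the manifest's
  ground-truth ratio exactly, and on noisy cohorts within Monte-Carlo error —
  the package's central closure test.
* Per-subject callosal areas from a normal truncated at zero
  (mean 689.45 mm², SD 80 mm² — the across-subject SD is not published and
  is a free parameter), plus sex and HCP-style age-group labels.

What it does **not** emulate: zero-count pairs (all synthetic weights are
positive), directed asymmetries, network-structured connectivity beyond
adjacency, parcel-area-dependent connectivity, and any form of
tractography-specific bias. Passing tests on synthetic cohorts therefore
demonstrate the correctness of the estimators and their invariances, not the
real data's values: synthetic medians and totals are on a different scale
than published ones, and the package makes no claim that they match.

## Numerical and design choices

* Matrices are validated on read: NA and negative entries are errors;
  asymmetry up to $10^{-8}$ relative is averaged away (float round-trip),
  beyond that it is an error naming the worst cell. Diagonals are forced to
  zero. Internal ids are 0-based and on-disk tables carry explicit ids, so
  ordering is never positional-only.
* Dense CSV/TSV are the canonical interchange formats; YAML for histology
  parameters and tract specs; JSON for manifests and reports.
* Medians over even-sized pair sets are the usual midpoint convention of
  `median()`.
* All bootstrap and permutation procedures take explicit seeds and restore
  the caller's RNG state; identical (config, seed) reproduce cohorts
  byte-identically.
* Densities are taken as already shrinkage-corrected; the
  `shrinkage_corrected` flag is metadata and no correction arithmetic is
  performed.
* Problem sizes in the shipped tests are deliberately modest (typically
  12–40 parcels per hemisphere and 1–60 subjects, with the full 360-parcel,
  50-subject default exercised in the acceptance script); all targeted
  properties are scale-free, so small cohorts test the same mathematics the
  full atlas would.

## Known limitations

* The conversion ratio is global; true axons-per-streamline likely varies
  somewhat by connection microstructure. The sensitivity engines bound the
  consequences but cannot remove the assumption.
* Trans-terminal fractions are upper bounds by construction.
* The permutation form of the correlation comparison is a design choice (see
  above); slope/intercept bootstrap differences are the primary parity
  statistics.
* Real connectomes must be converted to the TSV/CSV schema upstream; no
  CIFTI/GIFTI/NIfTI parsing is provided.
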