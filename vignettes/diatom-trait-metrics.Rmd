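---
title: "Trait-based diatom metrics along a periphyton phosphorus gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based diatom metrics along a periphyton phosphorus gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diatomtraits)
```

## The problem

Oligotrophic wetlands such as the Big Cypress / greater Everglades
landscape respond to phosphorus enrichment long before water-column
measurements register it, because the periphyton mat both concentrates
phosphorus and hosts a diatom assemblage whose composition tracks
availability.  Monitoring programs therefore score **mat P** -- total
phosphorus of the periphyton mat, in µg P per g dry mass -- and translate
the diatom assemblage counted from the mat into numeric metrics of
biological condition.  `diatomtraits` implements the full metric-development
workflow: assigning low-P / high-P **traits** to taxa, computing a factorial
suite of trait metrics per sample, scoring metric performance along the
stressor and a geographic disturbance surrogate, and deriving candidate
management benchmarks.

Everything operates on a taxon-by-sample matrix of valve counts plus a
per-sample metadata table, and a seeded assemblage simulator supplies
synthetic data with the statistical structure the analyses assume, so the
whole pipeline is testable without field data.

## Counting effort and standardization

Valve counts differ slightly in effort between samples, so all counts are
rarefied to a fixed effort of 600 valves: a uniform random subsample drawn
without replacement, equivalent to ranking every physically counted valve
by a random number and keeping the lowest 600.  Samples already at or
below the target are *kept and flagged*, never silently dropped -- an
under-effort count is a data problem the analyst must see.  The expected
rarefied count of a taxon is its hypergeometric mean
$600 \cdot A_{ij}/V_j$, which the test suite verifies by Monte Carlo.

## Trait assignment

Three independent sources can assign each taxon a `lowP`, `highP`, or
`unassigned` trait; a long trait table keeps one row per taxon and source,
and disagreements between sources are reported rather than resolved
silently.

**Gradient regression** (`assign_traits_regression`).  For taxa occurring
in at least 5 samples (inclusive bound; below that neither regression nor
indicator analysis has useful power), relative abundance is regressed on
$\log_2$(mat P).  A significant linear slope assigns the trait by its
sign.  Otherwise a quadratic fit catches unimodal responses; because a
parabola has no single sign, we use the sign of the fitted change from the
gradient minimum to its maximum.  This end-point rule is our construction:
it reduces to the slope sign for monotone fits and classifies a unimodal
taxon by where its response ultimately heads across the *observed*
gradient.  When neither stage is significant at `alpha` (default 0.05 per
test) the taxon stays unassigned.  The two-stage procedure's familywise
null assignment rate is $1 - (1-\alpha)^2 \approx 0.0975$, which the
acceptance checks confirm empirically.  Taxa for which the two stages would
be individually significant with conflicting directions are not arbitrated;
the linear stage simply takes precedence when significant.

**TITAN** (`titan_assemblage`).  Threshold indicator taxa analysis scans
every admissible split of the gradient (ties in mat P kept on one side --
a threshold on a measured value cannot separate equal values; at least
`min_split = 5` samples per side) and scores each side's
Dufrêne–Legendre indicator value
$\mathrm{IndVal}_g = 100 \cdot A_g \cdot B_g$, where specificity $A_g$ is
the group mean abundance over the sum of the two group means and fidelity
$B_g$ the occurrence frequency in the group.  The larger side's IndVal is
standardized into a z score against permutations of the sample–gradient
association; the changepoint maximizes z (maximizing raw IndVal is
available via `select_by`), and the direction is `z-` for decreasers
(low-P taxa) and `z+` for increasers.  Permutations are shared across taxa
within an assemblage -- the association is permuted once per iteration for
the whole matrix -- so identical taxa receive identical profiles and
community sums are coherent.

Two numerical choices deserve note.  First, the per-taxon permutation *p*
is a **maximum-statistic** exceedance probability: the observed
candidate-wise maximum IndVal against the permutation distribution of that
maximum.  A naive exceedance *p* at the selected changepoint is
anti-conservative (the candidate is chosen for extremeness); the
max-statistic test is exactly calibrated, which the acceptance checks
verify against the null simulator.  Second, reported changepoints are the
midpoint of the two straddling gradient values.

Bootstrap resampling of samples (default 500 replicates; replicates where
the taxon drops under `min_split` occurrences are redrawn up to 10 times)
yields **purity** (direction agreement with the observed run) and
**reliability** (fraction of replicates with $p \le 0.05$).  Taxa passing
both filters (defaults 0.95, the conventional thresholds; the defining
publication of this workflow states only the bootstrap count) are assigned
`lowP`/`highP` by direction.

**Literature lookups** are user-supplied tables, merged as a third source.

**Weighted-average optima** are computed for *all* taxa, with no
occurrence filter, because weighted-average inference is most precise with
every taxon in the model: $u_i = \sum_j y_{ij} x_j / \sum_j y_{ij}$ and
tolerance $t_i$ the abundance-weighted standard deviation, on relative
abundances so samples weigh equally, and on raw mat P (µg g⁻¹) so optima
are reported in the units practitioners use (a log-scale option exists).
On a skewed gradient raw-scale optima sit slightly high of the response
peak; rank order -- what the inference uses -- is preserved.

## The metric suite

For each trait source and each trait, four calculation types give the
24-metric factorial (4 types × 3 sources × 2 traits); three diversity
metrics and two weighted-average metrics complete the 29-metric suite.
With $A_{ijt}$ the standardized count of taxon $i$ with trait $t$ in
sample $j$:

* **PropValves** $= \sum_t v_{ijt} / V_j$ -- proportion of valves, where
  $V_j$ counts valves of *trait-assigned* taxa only;
* **PropTaxa** $= t_{tj} / T_j$ -- proportion of taxa, same restriction;
* **noTaxa** $= t_{tj}$ -- the count of present taxa with the trait;
* **RlogA** -- relative log abundance: each assigned present taxon
  contributes $\ln A_{ijt} / \sum \ln A_{ij}$, and the sample metric is
  the trait sum of these shares over the all-assigned sum, which reduces
  algebraically to $\sum_{i \in t} \ln A_{ij} / \sum_{i} \ln A_{ij}$.
  The logarithm damps the influence of dominance fluctuations -- small
  growth-rate differences that move an abundant taxon's count a lot.
  **Sharp edge:** the formula is kept literal, so a taxon counted once
  contributes $\ln 1 = 0$ weight; there is no $+1$ shift.  If every
  assigned taxon present has count ≤ 1 the metric is undefined (`NA`).

The lowP and highP versions of the three proportional types are exact
complements (they sum to 1 where defined), a property the tests assert.
Restricting denominators to trait-assigned taxa follows the defining
formulas; `include_unassigned = TRUE` widens them for sensitivity
analysis.

Diversity metrics are richness on the standardized counts, Shannon $H$
(natural logs), and Pielou $J = H/\ln S$ (undefined at $S = 1$).  The two
weighted-average metrics infer mat P per sample: the **simple** variant is
the abundance-weighted mean of present taxa's optima; the **tol** variant
weights by $y_i / t_i^2$ so narrow-niche taxa count more (zero tolerances
are floored at the smallest positive tolerance observed).  The source
publication does not spell out which two weighted-average variants it
used; this simple/tolerance pair is our interpretation, and no deshrinking
is applied because none is described.

## Evaluating metric performance

Each metric is regressed on $\log_2$(mat P) -- the log evens a gradient
with many more low-P than high-P samples -- and scored by adjusted $R^2$
(kept negative when it is negative, since rankings depend on it), and
against a latitude + longitude + interaction model, the geographic
surrogate for the human-disturbance gradient.  Family comparisons use
one-way ANOVA with Tukey HSD on the 24 factorial adjusted $R^2$ values,
and Kruskal–Wallis tests on within-group ranks computed under three
schemes that each control for the other two attributes: the 4 types ranked
within source × trait groups, the 3 sources within type × trait groups,
and the 2 traits within type × source groups, ties mid-ranked.

## Benchmarks

Three routes to candidate management benchmarks along mat P:

1. **Regression-tree changepoints** (`tree_changepoints`): recursive
   binary splitting of mat P minimizing within-group SSE of a metric.
   Each split must pass a permutation test (`n_perm = 999`, default
   $\alpha = 0.01$): the observed SSE reduction against the best-split
   reduction after permuting the metric values within the node.  The
   permutation test is our construction -- the workflow this implements
   reports significant breakpoints without naming a test -- chosen because
   it is distribution-free and reproducible.  Splits match an exhaustive
   scan exactly (tested), and breakpoints are reported at midpoints.
2. **Cluster-group percentiles** (`hierarchical_groups`): Bray–Curtis
   dissimilarity on relative abundances, average-linkage agglomeration by
   default (the linkage is not stated in the source workflow; complete and
   Ward are options), cut at dissimilarity 0.75; per group the 50th/75th/
   90th mat P percentiles (type-7 linear interpolation, stated because
   percentile benchmarks depend on it) and mean within-group
   dissimilarity.  A cut above the tree top yields a single group rather
   than an error.
3. **TITAN community changepoint** (`community_profile`): per candidate,
   the z scores of filtered taxa are summed by direction, with negative z
   truncated at zero (below-null association carries no indicator
   evidence; truncation also keeps the profile non-negative).  The
   community benchmark is the sum(z⁻) argmax; bootstrap replicates give
   cumulative-frequency curves of community changepoints.

The benchmark report evaluates the 13-metric subset -- 3 diversity, 2
weighted-average, 8 TITAN-trait metrics -- excluding literature- and
regression-trait metrics as redundant with the better-performing TITAN
traits, and adds mat P percentiles of user-designated minimally disturbed
regions.

## The simulator

`sim_config()` defines Gaussian species responses **on the log₂ gradient**:
$f_i(x) = h_i \exp\!\big(-(\log_2 x - \log_2 u_i)^2 / (2\sigma_i^2)\big)$,
normalized per sample and observed as a single multinomial draw at fixed
600-valve effort -- a fixed-effort count, not independent Poisson noise.
Responses on the log scale make raw-scale weighted-average optima sit
slightly high, mirroring real skew.  Gradient values are drawn
log-uniformly over 52–1200 µg g⁻¹, reproducing the left-heavy mat P
distribution of these wetlands.  Latitude is generated so that
$\log_2$(mat P) is linear in position plus noise, giving the geographic
model something real to find; longitude is uninformative; regions are
latitude terciles with `"NW"` the low-P reference.

The `bcnp_like` preset has 10 low-P taxa (optima 60–280 µg g⁻¹; the four
dominants' peak shares sum to 0.65, so the oligotrophic end is dominated
by a few low-P taxa), 40 high-P taxa (optima 350–1250 µg g⁻¹), and 15
flat background taxa -- many more high-P than low-P taxa, and richness
rising along the gradient.  All presets multiply expected abundances by
lognormal noise with sd 0.5: real fixed-effort counts are overdispersed
through taxon-level growth variability, precisely the fluctuation the
RlogA metric is designed to damp, and a pure-multinomial world would be
unrealistically clean.  `step_threshold` switches every trait taxon's
response sharply at 400 µg g⁻¹ to plant one community transition;
`null` flattens every response for type-I calibration.

What the simulator does *not* emulate: spatial autocorrelation beyond the
linear latitude surrogate, repeat visits to sites, taxonomic error, or
secondary gradients (pH, conductivity).  Passing tests therefore show the
algorithms recover the structure they assume, not that any particular
field system satisfies those assumptions.

## Problem sizes and reproducibility

The packaged checks run the simulator at 40–80 samples, 100–250
permutations and 40–500 bootstrap replicates -- sizes we chose so the full
suite exercises every stage at useful statistical resolution.  Every
stochastic stage derives an independent sub-seed from one master seed and
a stage label (`derive_seed`), so reruns are bit-identical and changing
one stage's random consumption never perturbs another's.  The pipeline
writes a JSON manifest (version, parameters, seed) beside its CSV outputs.

## Known limitations

* The polynomial end-point classification rule and the tree-split
  permutation test are reasoned constructions, not published conventions.
* RlogA's literal $\ln$ makes singleton counts weightless; analysts used
  to $\ln(x+1)$ transforms should note the difference.
* Community bootstrap curves recompute per-taxon profiles per replicate
  and are the most expensive operation at full defaults.
* Weighted-average inference uses no deshrinking, so inferred mat P is
  compressed toward the gradient centre at the extremes.
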