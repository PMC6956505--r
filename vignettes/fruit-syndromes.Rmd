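---
title: "Models and methods for fruit-syndrome comparative analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for fruit-syndrome comparative analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

drupevol analyses how suites of fleshy-fruit traits — color as a bird sees
it, nutritional content, and fruit/endocarp morphology — evolve together on
a phylogeny, and how discrete fruit-color categories move between states
over evolutionary time. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic-data generator
does and does not emulate.

```{r setup}
library(drupevol)
```

## Avian color space

Raw reflectance spectra (wavelength in nm, reflectance as a fraction) are
binned to 5 nm bands on the fixed 300–700 nm grid, smoothed once with a
centered running mean, and clamped at zero. The smoothing window (default
3 bands) is the single knob for both noise and background-artifact
suppression; wider windows trade chromatic resolution for stability.
Constant spectra pass through unchanged because edge bands use partial
windows.

The visual model is a four-cone (ultraviolet-, short-, medium-, long-wave
sensitive) system. By default the sensitivities are Gaussians peaking at
370, 445, 508 and 565 nm with a 40 nm standard deviation, each normalised
to unit area — a generic UV-sensitive bird. Published sensitivity templates
can be substituted via the `sensitivities` argument of
`avian_visual_model()`; the analysis depends only on the four curves being
non-negative and on a common grid. The illuminant is flat by default, so
relative quantum catches depend only on reflectance and sensitivities; any
illuminant spectrum may be supplied. Relative catches are invariant to
overall brightness by construction, which is why the analysis works with
chromatic position rather than intensity.

Catches are mapped onto a regular tetrahedron with centroid at the origin
(vertices at unit circumradius), so the achromatic point is the origin and
each pure cone maps to a vertex. Category separation is measured as
convex-hull volume overlap. Because no 3-D hull library is assumed, hulls
are represented by their supporting half-spaces found by brute-force plane
enumeration — exact and fast for the few dozen species per category this
analysis handles — and intersection volumes are estimated by Monte-Carlo
rejection sampling over the intersected bounding box. The sample count and
seed are recorded in the output. Two overlap conventions are reported:
overlap divided by the smaller hull volume (`fraction`) and by the union
(`fraction_union`); the smaller-hull convention is the headline number
because it is 1 for nested hulls.

## Trait derivation

Fruit and endocarp volumes are ellipsoids from length, width and height
(diameters, mm); pulp volume is the fruit volume fraction not occupied by
the endocarp; endocarp flatness is the width/height ratio in cross-section
(1 = round, larger = flatter). Protein is 6.25 × Kjeldahl nitrogen;
carbohydrate is the fresh-mass remainder after moisture, lipid, protein and
ash. All composition is stored on the fresh basis (dispersers eat fresh
pulp); `fresh_to_dry()` converts on demand. Per-species values are means of
per-fruit derivations — derivation first, averaging second — because the
ratio of means is not the mean of ratios for quantities like pulp volume.

## Phylogenetically corrected statistics

All methods assume Brownian motion (BM), under which trait covariance
across species is proportional to the phylogenetic covariance matrix `C`
of shared root-to-ancestor path lengths. Zero-length terminal branches are
tolerated; a diagonal floor of 1e-8 times the tree depth is added before
inversion when `C` is numerically singular.

**Phylogenetic PCA.** The ancestral mean is the GLS estimate
`a = (1'C⁻¹1)⁻¹ 1'C⁻¹X`; the evolutionary covariance is
`R = (X−1a)' C⁻¹ (X−1a)/(n−1)`; the axes are eigenvectors of `R` or, with
`scale = TRUE` (the default, matching the convention of centering and
scaling all variables), of its correlation analogue. Pre-scaling the data
and using the evolutionary correlation matrix are equivalent only
approximately under GLS centering; both modes are exposed via `scale`
because the choice is genuinely open, and the correlation mode is the
default on the grounds that the five syndrome traits are on incommensurate
scales. Eigenvector signs are fixed by making each column's
largest-magnitude loading positive.

**Independent contrasts.** Felsenstein's algorithm (via `ape::pic`), with
polytomies first resolved deterministically to zero-length branches in
tip-label order. Contrast regressions are through the origin, since
contrast signs are arbitrary. The Bonferroni family size defaults to the
number of regressions in the batch — five when the five syndrome traits
are regressed on short-wave stimulation.

**Phylogenetic ANOVA.** The description "ANOVA corrected for phylogeny via
the covariance matrix of the dependent variable" is ambiguous between a
GLS test and a simulation-based null. The package uses the simulation
method (the standard behavior of the usual implementation): the observed
statistic is the ordinary one-way F, and its null distribution comes from
`nsim` BM simulations on the tree with group labels held fixed, with
p = (exceedances + 1)/(nsim + 1). This keeps F interpretable and makes the
phylogenetic correction explicit; the parametric p is reported alongside.
The BM rate is estimated from the mean squared contrast, though F is
scale-invariant so this matters only for diagnostics. Groups with fewer
than two members are an error by default; `drop_small = TRUE` (used by the
pipeline, where a single-species category is common) drops them with a
warning. The endocarp-shape test operates on the natural log of flatness.

Brown–Forsythe (ANOVA on absolute deviations from group medians) and
Kruskal–Wallis (tie-corrected, chi-squared reference) accompany the
phylogenetic test because group variances and sample sizes are typically
unequal across color categories.

## Discrete fruit-color evolution

Five states are modeled: black-sequential, black-synchronous, red, yellow,
blue. Each decomposes into developmental attributes — final color stage,
presence of intermediate color stages, synchronicity of ripening, and
structural blue coloration — and both constrained models derive from this
decomposition (`color_states()`), which is overridable.

**Step matrix.** The parsimony cost of a transition counts elementary
developmental changes: replacing the final stage costs 2 (one loss + one
gain), gaining/losing the intermediate-stage suite costs 1 (truncation of
the intermediate sequence is a single developmental event), and each of
synchronicity and structural blue costs 1. This metric reproduces the two
anchor costs — black-sequential↔blue = 3 and red↔black-synchronous = 2 —
and, being a sum of pseudometrics, satisfies the triangle inequality over
all state triples. Where a complete published cost table is available it
can be passed directly to `sankoff()`.

**Paedomorphy model.** The ML counterpart constrains the Mk rate matrix:
only pairs connected by a single paedomorphic change are allowed
(black-sequential with each of black-synchronous, red, yellow — truncation
of intermediate or final stages — plus black-synchronous with blue, the
derivation of structural blue), each with its own symmetric rate;
black-sequential→blue is fixed at zero. The allowed set is a constructor
argument because reasonable decompositions differ.

**Likelihood machinery.** Felsenstein pruning over arbitrary (possibly
multifurcating) rooted trees; ambiguous tips are partial-likelihood vectors
(`"a|b"` or `NA`). The root prior is flat over the modeled states — the
common default of ML reconstruction software — for likelihood, ancestral
states and stochastic maps alike. `P(t) = exp(Qt)` uses the
eigendecomposition of `Q`, computed once per likelihood evaluation and
verified against identity reconstruction; a scaling-and-squaring series is
the fallback for defective eigenbases. Rows of `P(t)` are clamped and
renormalised, and per-node scaling guards against underflow on large trees.

**Fitting.** Rates are optimised on the log scale. A single free rate uses
golden-section search, which cannot be trapped by the likelihood plateau at
saturating rates; multi-parameter patterns use Nelder-Mead followed by a
box-constrained quasi-Newton polish, with multiple deterministic restarts
(default 3) around a characteristic rate of one expected change per total
tree length. AICc uses the number of tips as the sample size, the
convention for Mk fits; model comparison sorts by AICc with ties broken
toward fewer parameters.

**Stochastic mapping.** Joint node states are drawn root-down from their
conditional distributions, then each branch path is simulated conditional
on its endpoints by rejection sampling (cap 500 attempts) with a
uniformization fallback that samples the number of jumps from its
endpoint-conditioned distribution and the jump chain by backward smoothing.
Transition counts are averaged over `nsim` histories; each result records
its seed and `nsim`.

## Synthetic data: what it does and does not emulate

The generator mirrors the structure of a clade-scale fruit study: an
ultrametric birth–death tree (rescaled to unit depth so rates are
comparable across sizes), a color category evolving under a symmetric Mk
process, five continuous traits evolving as BM around category-specific
means, and 20 noisy reflectance spectra per species drawn from per-category
templates (blue peaking in the short wavelengths, red at long wavelengths,
the black categories dark and nearly flat). Default fixture sizes mirror a
real study of this kind: 29 species for the syndrome analysis, 115 for the
endocarp-shape comparison, 163 tips for color evolution. Because such
studies deliberately sample species spanning all color categories, the
syndrome generator conditions the simulated history on every category
being represented (a stratified-sampling analogue); the per-category trait
means encode the generating syndrome — blue fruits high-lipid, low-moisture,
with large round endocarps; red fruits the watery, flat-endocarp opposite.

Category mean shifts are applied at the tips rather than as
Ornstein–Uhlenbeck optima: it is the simplest structure consistent with
the BM-based tests, and adequate for sign- and order-recovery checks. The
generator therefore does *not* emulate selective regimes along branches,
intraspecific variation in traits other than spectra, measurement error in
morphology, or the topology of any real clade. Passing tests demonstrate
that the estimators recover known generating structure under BM — not that
real fruits evolve by BM.

Every generator is a pure function of its seed; derived stages use fixed
small offsets from the master seed.

## Problem sizes and numerical tolerances

The test suite exercises the likelihood against exhaustive enumeration
(100 random instances, ≤ 5 tips, ≤ 3 states, 1e-10 relative error),
parsimony against unit-cost Fitch counts (100 random 8-tip instances),
star-tree reductions of the phylogenetic methods to their ordinary
counterparts, type-I error calibration at n = 29 over 500 BM replicates,
rate recovery at 200 tips (50 replicates), history recovery at 100 tips,
and hull-overlap geometry against an analytic box intersection at 10⁶
Monte-Carlo samples. These sizes were chosen to give tight sampling error
while keeping the default suite runnable on a single CPU in minutes.

## Known limitations

* No receptor-noise discriminability (JND) modeling; color-space distances
  are geometric, not perceptual.
* No hidden-rate or covarion Mk variants, no Bayesian sampling over `Q`,
  and no joint (max-joint) ancestral reconstruction.
* The phylogenetic ANOVA's GLS variant is not implemented; the simulation
  method is the only mode.
* Hull volumes assume 3-D points; degenerate (coplanar) categories are
  reported with zero volume and a flag rather than a lower-dimensional
  measure.
* Mk fits on very small state samples (a category observed once) are
  identifiable only through the constraint pattern; AICc comparisons across
  different state spaces should be read with care.
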