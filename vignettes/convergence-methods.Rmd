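---
title: "Models and methods behind infantgut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind infantgut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infantgut)
```

`infantgut` analyses dense longitudinal OTU count data from infant cohorts:
library normalization, beta diversity, ordination, a contemporaneous
convergence analysis on an interpolated pseudo-day grid, dynamic-time-warp
clustering of phylum trajectories, and twin-similarity testing. This
vignette explains the models, the tunable parameters, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## The statistical pipeline

### Common scaling

Library sizes in amplicon data vary over orders of magnitude. Rather than
rarefying (randomly subsampling reads, which injects noise), every count `c`
in a library of size `L` is multiplied by `S/L`, where `S` is the smallest
library size in the table, and rounded to the nearest integer
(half-away-from-zero; the phrase "nearest integer" leaves the half case
open, and halves are measure-zero in practice so the choice is cosmetic).
This is the expectation of infinitely repeated rarefaction. The smallest
library is returned unchanged. Two consequences worth knowing: scaled row
sums lie within `±n_OTUs/2` of `S` (rounding bound), and singleton counts in
deep libraries can round to zero — which is why presence/absence summaries
(`prevalence_spectrum()`) operate on the unscaled table.

### Beta diversity

Bray–Curtis is `Σ|x−y| / Σ(x+y)`. Generalized UniFrac weights each branch
`b` of a rooted phylogeny by its length `L_b` and the relative-abundance
mass `p_b`, `q_b` below it in the two samples:

d(x, y) = Σ_b L_b (p_b+q_b)^α |p_b−q_b|/(p_b+q_b) / Σ_b L_b (p_b+q_b)^α

summed over branches with `p_b + q_b > 0`. At `α = 1` this is
abundance-weighted normalized UniFrac; the default `α = 0.5` moderates the
influence of dominant lineages. The implementation precomputes a branch
table (one post-order traversal yielding an OTUs × branches incidence
matrix) so that a full 365-pseudo-day × 55-pair profile is a handful of
matrix products rather than thousands of tree traversals; its equivalence to
direct per-branch summation is asserted against a brute-force oracle in the
test suite. Unrooted input trees are midpoint-rooted with a warning. The
contemporaneous analysis uses the abundance-weighted (generalized) form
throughout; presence/absence UniFrac is deliberately out of scope.

### Ordination and inference

`nmds()` is Kruskal-style non-metric MDS: initialization by classical
metric scaling, then alternating (i) isotonic regression of the
configuration distances on the rank order of the dissimilarities
(pool-adjacent-violators; ties in the dissimilarities are broken by the
current configuration distance, the "primary" tie treatment that favours
monotonicity) and (ii) a Guttman-transform descent step. Stress-1 is
`sqrt(Σ(d̂−δ)² / Σδ²)`. Only stress-improving steps are accepted, so stress
is non-increasing; iteration stops at relative change `< tol`. Since nMDS
axes are defined only up to rotation and sign, axis 1 is fixed as the
largest-variance coordinate with sign chosen so its correlation with sample
order is non-negative — and all downstream reporting uses R², which is
sign-invariant.

`permanova()` implements one-factor PERMANOVA:
`SS_total = Σ_{i<j} d²/n`, `SS_within = Σ_g Σ_{i<j∈g} d²/n_g`, pseudo-F
`= (SS_among/(a−1))/(SS_within/(n−a))`, with labels permuted by a seeded
generator and the add-one p-value `(1+#{F* ≥ F})/(1+P)` — never exactly
zero, with resolution `1/(P+1)`.

`smooth_fit()` replaces a penalized additive-model smooth with an
*unpenalized* least-squares fit on a cubic B-spline basis of exactly `df`
functions (interior knots at quantiles of the predictor). This keeps the
fit deterministic and dependency-free while pinning the flexibility to the
conventional `df = 9`; R² is reported the same way as for a penalized
smooth, and pointwise 95% bands come from the exact linear-model
covariance. The difference from a penalized fit matters mostly near the
boundaries, where unpenalized spline derivatives are noisy — see the window
detector below.

### Pseudo-day interpolation and the convergence profile

Infants are sampled on irregular, individually different days, so series
are aligned by interpolating each infant's composition onto 365 equally
spaced "pseudo-days" spanning that infant's own `[first_day, last_day]`.
With near-full-year coverage a pseudo-day is approximately a calendar day.
Each feature is interpolated independently by a cubic spline with
exact-cubic end conditions (a single cubic through the four boundary
points), the classical `fmm` construction; this reproduces any global cubic
exactly, which the tests exploit as an oracle. Interpolation runs on
relative abundances, since every downstream quantity is relative. Cubic
interpolation can overshoot below zero between knots; negative values are
clipped to zero and each pseudo-day composition renormalized to sum to one,
so that distances on the grid remain well defined for both metrics.
Duplicate-day samples are averaged before fitting; fewer than four distinct
days is an error (the end condition needs four points).

Infants whose sampling begins at or after day 54 are excluded from
cross-infant contemporaneous analyses (`exclude_late_starters()`): their
early pseudo-days would be extrapolations into a period where infant
microbiotas change fastest.

For every pseudo-day, the profile holds the distance between each unordered
infant pair, each infant's mean distance to the others, and the grand mean.
These satisfy an exact aggregation identity (mean over pairs = mean over
per-infant means), asserted to 1e-12 in the tests.

### Window detection

The convergence window is read off a `df = 9` smooth of the grand-mean
profile: let `m` be the most negative fitted derivative; the window is the
maximal contiguous run of pseudo-days containing that steepest descent on
which the derivative stays below `slope_fraction × m` (default 10%). Two
deliberate choices:

* The steepest-descent anchor is sought over the interior of the grid only
  (the outermost 5% of points on each side are excluded, configurable via
  `boundary_exclude`), because unpenalized spline fits have unreliable
  derivatives at the grid boundary and a boundary wiggle can otherwise
  masquerade as a descent. The detected run may still extend into the
  boundary region.
* With a `df = 9` basis on 365 points the inter-knot spacing is ~60 days,
  so window *edges* are localized to roughly half a knot span (±15 days);
  the window *midpoint* is much more stable. Profiles that never descend
  return no window.

`convergence_trend()` reports the OLS slope, R² and p of the grand mean on
pseudo-day index — the "does beta diversity decline overall" summary —
knowing full well that the profile is strongly non-linear; the smooth's R²
is reported alongside.

### OTU–convergence correlations and twins

`otu_convergence_correlation()` correlates each OTU's cohort-mean
interpolated abundance with the grand-mean distance across the pseudo-days
inside the window (Pearson, two-sided p). The cohort-mean construction is
one defensible reading — per-pair abundance/distance pairings would be
another — and is stated in the output documentation.

`twin_similarity_test()` compares the 365 twin-pair contemporaneous
distances against the pooled per-pseudo-day mean distances from each twin
to all non-twin infants (2 × 365 values), with a one-sided Welch t-test.
The pseudo-days are strongly autocorrelated, so the nominal sample size
overstates the information content and the p-value is anti-conservative;
it should be read comparatively, not literally. This caveat is inherent to
any t-test on interpolated grids.

### DTW clustering of phylum trajectories

Dynamic time warping aligns two series of possibly different lengths by a
monotone warping path. The local cost is `|x_i − y_j|`; the symmetric2 step
pattern scores `D(i,j) = min(D(i−1,j)+c, D(i,j−1)+c, D(i−1,j−1)+2c)` with
no global path constraint, and the normalized distance divides by `n + m`,
the normalization this step pattern admits ("series length" alone does not
fix a formula; `n+m` is the standard choice and is what the package
reports). DTW runs on the *observed* day-ordered series, not interpolated
grids — handling unequal lengths is exactly what DTW is for. Per infant
pair, the four dominant phyla (Actinobacteria, Bacteroidetes, Firmicutes,
Proteobacteria — taxa present in every individual) give four normalized
distances whose arithmetic mean is the combined matrix; complete-linkage
agglomeration (inter-cluster distance = maximum pairwise distance, merge
ties broken by the lexicographically smallest pair of cluster indices, for
determinism) yields the dendrogram, exportable as newick with cumulative
heights. The DTW recursion and the agglomeration are both verified against
brute-force path enumeration and naive re-implementation in the tests.

## The synthetic cohort generator

Real cohorts of this kind exist only as raw sequence archives behind an
upstream bioinformatics pipeline, so the package ships a generator that
plants every signal the analyses are meant to find. Ground truth (bloom
OTU, window, twin pair) is returned alongside the data, making recovery
tests possible.

Per infant `i` and OTU `o`, latent log-abundance on day `t` is

base_o + envelope(t) · [wiggle_{i,o}(t) + age(t) · ν_{i,o}] + age(t) · μ_o + bloom_o(t)

softmax-normalized to a daily composition, where:

* `base_o` — phylum baseline `log(fraction/n_phylum)` plus a lognormal
  spread (`otu_spread_sd = 1.5`) shared by all infants, producing a
  realistic abundance hierarchy (the top-20 OTUs carry ~77% of reads under
  defaults). Default phylum fractions are 32.5/16.2/35.7/15.6%
  (Bacteroidetes/Actinobacteria/Firmicutes/Proteobacteria).
* `wiggle` — a standardized random walk on 30-day knots, cubic-spline
  interpolated: autocorrelated individual variation with constant marginal
  sd (`individuality_sd = 1`) rather than a full Gaussian process, for
  simplicity and determinism.
* `μ` (common maturation drift, sd 2) — a cohort-shared direction of
  change from day 1 to 365. It moves every infant steadily through
  community space (the common developmental signal) while cancelling out of
  contemporaneous between-infant distances.
* `ν` (individual maturation drift, sd 1) — each infant's own directional
  deviation.
* `envelope(t)` — an early colonization ramp (amplitude 0.5 → 1 over days
  1–60: newborn pioneer communities start relatively similar and
  individualize) times a linear decay (`cohort_convergence = 0.75`) that
  shrinks individual variation with age and produces the cohort-wide
  negative distance trend.
* `bloom_o(t)` — on one designated Actinobacteria OTU (given the cohort's
  top baseline, mirroring the empirical pattern that the blooming
  *Bifidobacterium* is the single most abundant taxon), a log-boost that
  rises sigmoidally (normal CDF, scale `half_width/2`) centered on day 95
  and decays after day 130. The *rise* of a shared dominant taxon is what
  pulls the infants together, so this timing places the distance descent —
  the convergence window — at `center ± half_width` = days 60–130, which is
  exactly the ground-truth window the generator records. (A bump *centered*
  at day 95 would put the descent at days ~25–95 instead; the sigmoid-rise
  construction is what makes "window center" and "bloom center day"
  coincide.) The boost height (`bloom_peak_boost = 4`) has no empirical
  anchor and is chosen so recovery is robust across seeds; softmax
  renormalization supplies the compensatory depression of all other taxa —
  visibly, a Firmicutes decline — inside the window.

The twin pair shares one wiggle-and-drift draw plus independent knot noise
(`coupling_noise_sd = 0.15`). Counts are Dirichlet-multinomial (concentration
200 — visible but not overwhelming overdispersion) around the latent
composition, with log-normal library sizes calibrated to a mean of 1,642
reads (±544 sd) — a 100× scale-down of the ~164,000-read depth typical of
deep amplicon studies, keeping a full pipeline run under a minute on one
CPU; problem sizes used throughout the tests are 12 infants × ~225 samples ×
150 OTUs. Sampling days are independent inclusions at rate 0.65 within each
infant's own first/last-day range (first days 1–9, one designated late
starter beginning at day 54 to exercise the exclusion rule).

`strong_trend_config()` is a documented variant (common drift sd 6, wiggle
sd 0.3, bloom boost 1.5, concentration 1000) in which age dominates every
other source of within-infant variance. Under the *default* conditions the
bloom's round trip through community space often claims the
largest-variance ordination axis, so per-infant axis-1-versus-age R² is
modest (~0.3 on average); under strong-trend settings it is 0.89–0.97. Real
cohorts sit in between (axis-1 R² ≈ 0.5–0.9): real maturation is more
monotone than the default generator's and less extreme than the
strong-trend variant's.

### What the generator does not emulate

No sequence-level artefacts (chimeras, primer bias), no mechanistic
antibiotic or diet perturbations, no preservation-method effects (carried
as metadata only), no seasonal or travel effects. The planted bloom also
inflates the realized annual Actinobacteria mean (~40% under defaults)
well above its 16% baseline fraction, because a shared dominant taxon
occupies much of the mid-year composition; the baseline fractions should be
read as pre-bloom targets. Passing recovery tests on these cohorts
demonstrates that the pipeline finds the signals it is designed to find at
realistic noise levels — not that real infant data contain those signals.

## Numerical choices and degenerate inputs

* Rounding in `common_scale()` is half-away-from-zero; zero-sum libraries
  are errors naming the sample.
* `isotonic_fit()` preserves the weighted mean exactly; empty input errors.
* nMDS accepts only stress-improving iterations; a rank-deficient classical
  start is jittered by a seeded 1e-6 perturbation; all-zero distance
  matrices error.
* Branches with zero combined mass are skipped in both UniFrac sums (the
  formula's stated domain); two samples with no shared tree mass error.
* Interpolated compositions that clip to all-zero (pathological) error
  rather than silently renormalizing.
* The twin t-test returns `NA` statistics when both samples are constant
  (identical infants) instead of failing.
* All simulation randomness flows through explicit seeds; identical
  config + seed gives byte-identical cohorts, and the generator restores
  the caller's RNG state.

## Known limitations

* The pseudo-day t-test and the in-window correlations both treat
  autocorrelated grid points as independent observations; their p-values
  are optimistic.
* Window-edge localization inherits the ±(half knot span) resolution of
  the fixed-df smooth; reporting focuses on the midpoint.
* PERMANOVA is one-factor only; multi-factor designs and penalized
  smoothness selection are out of scope.
* The unpenalized `df = 9` smooth can oscillate near boundaries; the
  interior-anchored window detector works around this, but fitted values in
  the outer ~5% of the grid should be read cautiously.
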