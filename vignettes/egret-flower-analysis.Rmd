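---
title: "Quantifying egret-flower lips and SSR population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying egret-flower lips and SSR population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagisou)
```

`sagisou` analyses two complementary kinds of evidence about fragmented
populations of the egret flower *Habenaria radiata*: the geometry of the
fringed lip (labellum), and diversity at microsatellite (SSR) loci. This
vignette explains the models and procedures, the parameters that matter,
what the synthetic generators do and do not emulate, and the numerical
choices made where the design was genuinely open.

## 1. Lip morphometrics

### The measured factors

A lip is supplied as a closed vector contour in millimetres plus
landmarks — the package deliberately takes digitized outlines as its
contract and leaves photograph segmentation out of scope, since all the
defined quantities are purely geometric. The lip is decomposed into a
central *body* and two lateral *wings*. Eight quantities are reported by
`measure_lip()`:

| quantity | definition |
|---|---|
| area | shoelace area of the whole lip polygon (mm²) |
| perimeter | edge length of the whole lip, closing edge included (mm) |
| dissection index (DI) | perimeter/√area **of the left wing** |
| body length | distance from body base to body tip landmark (mm) |
| body width | length of the body-width landmark segment (mm) |
| wing length | distance from wing base to wing tip landmark (mm) |
| angle | unsigned angle between body and wing axes, in (0°, 180°) |
| serration number | tooth count on the left wing's fringed margin |

DI is dimensionless and scale invariant, bounded below by 2√π ≈ 3.5449
(isoperimetric inequality, equality only for circles); the package
asserts this bound up to a discretization tolerance of 10⁻³ on every
closed contour it generates. Whole-lip area and perimeter are reported
alongside the left-wing DI because both scales of complexity are of
interest. Raw DI values of real wings are a few units; the *normalized*
DI (divided by 40, below) is two orders of magnitude smaller — the
package reports both and leaves the choice to the analyst.

Degenerate configurations are errors, not clamps: a zero-area polygon, a
self-intersecting outline, or exactly parallel body and wing axes all
raise rather than returning a boundary value.

### Serration counting

Teeth are local maxima of the margin's deviation from its smooth
baseline, kept when their topographic prominence reaches a threshold
(default 0.2 mm; plateaus count once). For the baseline we fit a
least-squares (Kasa) circle through the margin vertices and take signed
radial residuals. The natural alternative — the raw distance from each
vertex to the chord joining the margin endpoints — fails in two ways on
fan-shaped wings: a perfectly smooth arc still has one broad
chord-distance maximum (its apex would count as a phantom tooth), and
near the steep ends of a wide arc a genuine tooth degenerates into a
shoulder with no local maximum at all. The circle fit removes the arc
background exactly in the smooth case, so a plain arc yields zero teeth,
and generalizes the chord: for margins too straight for a stable fit
(fitted radius beyond 50× the margin span, or a rank-deficient system)
the implementation falls back to the literal signed chord distance. One
tunable parameter remains — the prominence threshold, in millimetres —
and detection is exact for generated teeth whose amplitude is at least
twice the threshold, for counts up to 50 across the tested range of arc
extents.

### Radar profiles

Six factors are divided by fixed maxima — dissection index 40, body
length 30 mm, body width 10 mm, wing length 40 mm, angle 90°, serration
number 50 — giving the DI/BL/BW/WL/A/Se radar profile.
`summarize_population()` reports the per-trait mean, sample standard
deviation (n − 1 denominator, 0 when n = 1) and count;
`autoplot()` draws the polygon on polar axes.

## 2. The synthetic lip generator

`generate_lip_contour()` builds a star-shaped polygon around the lip
base: a drop-shaped body lobe (the lower half of an ellipse with the
requested length and width) and two circular-sector wing fans placed
symmetrically at the body–wing angle; the radial function is the
pointwise maximum of the lobes plus a small sinus radius, so the outline
is simple (non-self-intersecting) by construction and oriented
counterclockwise. Serrations are a sinusoidal radial modulation
r(θ) = R + a·sin(2πk·θ′) over the left wing's distal arc, realizing
exactly k teeth of radial amplitude a. Landmarks are placed analytically,
so the generated ground truth is exact: body length, width, wing length
and angle are recovered to machine precision, teeth exactly.

Parameter combinations whose lobes would collide — wing fans overlapping
each other, a fan engulfing the body axis, teeth deeper than half the
wing radius, or another lobe protruding into the serrated arc — are
rejected with an explicit error instead of producing a degenerate
outline.

Vertex density defaults to 10 vertices/mm (perimeter discretization
error well under 0.1%), with at least 24 vertices per tooth. Optional
Gaussian vertex jitter (seeded) emulates digitization noise; note that
jitter inflates perimeter-type quantities by a small positive bias of
order σ²/spacing, so jitter should stay well below the vertex spacing.
What the generator does **not** emulate: real lips are not radial
functions (deep sinuses that fold back), margins wear and tear in the
field, and photographed outlines carry correlated segmentation error —
passing tests certify the measurement chain, not robustness to such
artefacts.

## 3. SSR diversity statistics

Genotypes live in a long tibble (`population`, `individual`, `locus`,
`allele_1`, `allele_2`), alleles as positive integer fragment sizes, with
explicit `NA` for missing calls (files use the conventional 0 / −9
sentinels). Individuals missing at a locus are excluded there only, so
deleting one call perturbs no other locus's summaries.

Per locus and population: Ho is the fraction of heterozygous typed
individuals; He is Nei's unbiased gene diversity
(2n/(2n−1))(1 − Σp²). Per population (`population_table()`): N, the
unweighted means of He and Ho across loci with data, and the fixation
index F = 1 − H̄o/H̄e. F is computed from locus-averaged
heterozygosities rather than averaged per-locus F, which stays stable
when some loci have near-zero diversity; users can compare alternatives
from `locus_table()`. He = 0 makes F undefined (reported `NA`).

Significance of F uses a within-population permutation test: allele
copies are permuted among typed individuals independently per locus
(He is invariant under this, so only Ho moves), F recomputed each
replicate, two-sided p = (b + 1)/(reps + 1) counting |F_perm| ≥ |F_obs|.
The significance flag uses α = 0.05 with no multiple-testing correction
by default (a Bonferroni option exists), matching common reporting
practice for such tables.

The exact Hardy–Weinberg test conditions on allele counts:
P(table) = N!/∏n_ij! · 2^het · ∏m_a!/(2N)!, and the p-value sums the
probabilities of tables no more probable than the observed one. All
tables are enumerated when at most 10⁶ exist; otherwise `reps` seeded
permutations of the allele vector approximate the tail, reported with
the add-one correction. Two caveats are documented deliberately: the
test is *conservative* at small n because the null distribution is
discrete (its true size at n = 20 and p = 0.5 is about 0.024 at nominal
0.05 — an intrinsic property of exact conditional tests, not an
implementation artefact), and which HWE variant and which of several
null-allele estimators the field's usual desktop tools run is not always
documented, so the package states its choices: the probability-ordering
exact test and Chakraborty's r = (He − Ho)/(He + Ho), negative values
reported as-is (they indicate heterozygote excess).

## 4. The genotype simulator

Per population and locus, allele frequencies are drawn from a symmetric
Dirichlet (concentration 1 by default; smaller values give skewed
spectra). Genotypes are drawn with inbreeding coefficient F:
P(homozygote i) = p_i² + F·p_i(1−p_i), P(heterozygote ij) =
2p_i p_j(1−F). Negative F combinations that would need a negative
probability raise an error — clamping would silently change the target
F. Defaults mirror the field survey the package models: 8 populations
with 5–18 plants (9, 9, 9, 7, 10, 9, 5, 18), 21 loci, and 5 alleles per
locus with fragment sizes on a dinucleotide ladder (100, 102, …) —
5 alleles is a typical mid-polymorphism SSR panel, chosen once as the
realistic default. Admixture mode instead draws per-individual
proportions q ~ Dirichlet(α) over ancestral clusters and each allele
copy from a q-chosen cluster; combining admixture with non-zero F is
rejected (no analysis here needs the joint regime). Clonal mode draws a
few distinct founder genotypes at Hardy–Weinberg equilibrium and fills
the population by copying them — the bulb-propagation regime in which
Ho exceeds He and F goes negative whenever founders happen to be
heterozygous. With 3 founders, 18 plants and 20 loci this yields
negative F in ~96% of seeds, but the *significantly* negative rate is
lower (~85–90%): seeds whose founders land largely homozygous carry no
signal any test could flag, a feature of the regime worth knowing when
interpreting single-population surveys.

One root seed drives everything; each stage derives a child seed from a
deterministic hash of the root and a component label, so stages are
individually reproducible and bitwise stable.

## 5. Nei distance, neighbor-joining, bootstrap

Nei's standard distance between units X, Y averages, over loci typed in
both, J_X = Σx², J_Y = Σy², J_XY = Σx_i y_i and returns
D = −ln(J_XY/√(J_X J_Y)). Units are individuals by default — each plant
a frequency vector of 0/0.5/1, the convention used when single plants
are placed on a tree — with population mode available. D is symmetric
and non-negative but *not* a metric; no triangle property is assumed
anywhere. A pair sharing no alleles has infinite D: this is an error
unless the caller supplies a finite `cap` (the pipeline defaults to 30,
far beyond any Nei distance arising from shared alleles), because
silently capping would change tree topology without the user's consent.

Neighbor-joining follows the Saitou–Nei agglomeration with the standard
Q-criterion and two-point branch-length formulas; negative estimated
branch lengths are clamped to zero, and ties in Q break deterministically
to the first minimal pair in column-major order. On additive matrices the
true tree is recovered exactly (to 10⁻⁹), verified against both an
independent NJ implementation and exhaustive minimum-evolution search
over all 15 five-leaf topologies.

Bootstrap resamples *loci* with replacement (the standard multilocus
unit), recomputes distances and the NJ tree per replicate, and reports
for each internal edge of the full-data tree the percentage of
replicates containing the same bipartition — supports are mapped onto
the single original tree, not a consensus. Replicates whose resampled
loci leave some pair with undefined distance are redrawn (up to 10× the
replicate count). Supports below the display threshold (50% by default)
are suppressed only when plotting; the data model keeps them all.
Newick export writes branch lengths at 6 decimals and integer supports
as internal node labels, quoting labels that contain metacharacters.

## 6. Admixture model and K selection

The Gibbs sampler implements the basic admixture model with independent
allele frequencies: each individual i has proportions q_i over K
clusters, each cluster k a frequency vector per locus, and each allele
copy a latent origin Z. Per sweep: P ~ Dirichlet(λ + counts),
Q ~ Dirichlet(α + counts), Z ∝ q_ik p_k(allele), and α by a Metropolis
step under a Uniform(0, 10) prior (proposal SD 0.05). Missing copies are
skipped in counts and likelihood. The correlated-frequencies variant is
*not* implemented; when the reference desktop tool was run with that
prior instead, results can diverge — a documented risk, not a silent
assumption.

Run scoring uses ln P(D) = mean − variance/2 of the (thinned,
post-burn-in) data log-likelihood trace, the estimator the original
software prints, with the sample (n−1) variance. Evanno's table then
gives L′(K), L″(K) and ΔK = |L″(K)|/sd(K) over runs; ΔK is undefined at
the boundary K values and wherever the across-run SD is zero, the
optimal K is the interior argmax with ties broken toward smaller K, and
an all-zero-curvature table is reported as inconclusive (`NA`) rather
than forcing a winner.

Defaults are desk-scale (burn-in 5,000, 20,000 sweeps); the field-scale
protocol (50,000 / 1,000,000, K = 1..8, 10 runs per K) is available
through the same arguments and simply costs time. The package's own
checks run a reduced chain (burn-in 2,000, 10,000 sweeps, K = 1..4,
4 runs per K, two simulated populations of 25 plants at 20 loci), which
already separates the clusters at q > 0.95 and picks K = 2; chain
length, not model structure, is the only thing scaled down.

Cluster labels are arbitrary per run, so runs are aligned before
averaging: an exhaustive search over all k! column permutations
(k ≤ 8 ⇒ at most 40,320) minimizes the total absolute difference to the
first run — the first run as reference keeps alignment deterministic,
where a consensus reference would depend on iteration order. A greedy
matcher is provided and agrees with the exhaustive search on
well-separated runs.

## 7. File formats and pipeline

Genepop reading accepts comma- or line-separated locus names, any case
of `Pop`, and 2- or 3-digit allele codes auto-detected from token width;
`00`/`000` is missing; population names come from the last individual's
label prefix (the format itself carries no population names — in memory
the package always carries population as an explicit field, and this
parsing-time inference is the single documented exception). Writing
defaults to the 3-digit dialect since SSR fragment sizes exceed 99.
STRUCTURE files support one- and two-row layouts with −9 for missing.
All readers reject malformed input with the offending line number —
nothing is silently repaired — and both formats round-trip simulated
datasets exactly.

`run_pipeline()` chains simulate → morphometrics → popgen table →
NJ + bootstrap → admixture + Evanno, writes all artifacts as CSV /
Genepop / STRUCTURE / Newick plus a manifest of versions, seeds,
parameters and file digests, logs timings to stderr, and is
byte-reproducible given the seed.

## 8. Known limitations

* Image analysis is out of scope: contours and landmarks must be
  digitized upstream.
* The admixture sampler is single-chain per run; convergence is attested
  by parameter recovery on simulations, not by formal diagnostics.
* The exact HWE test's conservatism at small n is inherent; at the
  survey's sample sizes (5–18 plants) per-locus HWE p-values have limited
  power either way.
* Synthetic genotypes are drawn i.i.d. given frequencies — no linkage,
  no mutation model, no spatial structure — so tests certify estimator
  arithmetic and pipeline integrity, not behaviour under those realities.
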