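---
title: "Methods: host mosaics, visual matching and local-adaptation tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host mosaics, visual matching and local-adaptation tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicadapt)
```

## The question the pipeline answers

Host-associated divergence in herbivorous insects is often attributed to
competition, but an alternative driver is spatial turnover in which
host-plant species are actually available: if no host spans the herbivore's
whole range, different populations are forced onto different hosts and can
adapt locally to them. `mosaicadapt` implements the full inference chain
for that argument on a herbivore and its candidate host plants:

1. quantify the **geographic mosaic** of host availability from occurrence
   records;
2. test **host-preference divergence** between population pairs with
   repeated binary choice trials;
3. test **morphological divergence** (body width, stockiness);
4. test **camouflage colour matching** against host leaf sheaths in the
   eyes of an avian predator.

Every stage consumes plain CSV files and is backed by a seeded synthetic
generator, so the complete chain is testable without any field data.

## Range geometry

Species ranges are estimated as convex hulls of occurrence points
(monotone-chain construction, lexicographic tie-break, collinear boundary
points pruned). All coordinates are planar; lon/lat input is pre-projected
with the equirectangular convention $x = \mathrm{lon}\cos(\overline{\mathrm{lat}})$,
$y = \mathrm{lat}$. The quantities of interest are *area ratios* over a
regional extent, which are insensitive to the projection; full GIS
reprojection is deliberately out of scope.

For a herbivore hull $H$ and host hull $P_h$ the directional overlap is
$o_h = \mathrm{area}(H \cap P_h)/\mathrm{area}(H)$, computed by half-plane
clipping (exact for convex polygons) and the shoelace formula. The
symmetric overlap of two hosts is the mean of the two directional
overlaps. Intersections of measure zero (shared edges or points) count as
empty: they cannot affect an area ratio.

The availability summary bootstraps the mean of $\{o_h\}$ over hosts
(percentile method, default 10,000 resamples, seeded) and reports a
one-sided upper bound at the 95% level: an upper bound below 1 means no
single host covers the herbivore's range. Hosts enter the analysis only if
at least `min_records = 2` herbivore captures are attributed to them.

## Receptor-noise-limited colour matching

Camouflage is scored in the visual space of an avian predator. For a
reflectance spectrum $R(\lambda)$, illuminant $I(\lambda)$ and receptor
sensitivities $S_i(\lambda)$, quantum catches are
$Q_i = \int R\, I\, S_i \,\mathrm{d}\lambda$ (trapezoidal quadrature on a
300–700 nm, 1 nm working grid). Catches are von Kries-normalized by the
catches of the adapting background ($q_i = Q_i/Q_i^{b}$; default an ideal
flat background), which cancels illuminant intensity. With log contrasts
$\Delta f_i = \ln q_i(a) - \ln q_i(b)$ and receptor noise
$e_i = w\sqrt{\eta_{\mathrm{ref}}/\eta_i}$, the chromatic distance in
just-noticeable differences is the standard receptor-noise-limited
quadratic form; for a dichromat it reduces to
$|\Delta f_1 - \Delta f_2| / \sqrt{e_1^2 + e_2^2}$, and the tri- and
tetrachromatic forms are implemented generically (the pair/triple
subset-product expansion) and verified in the tests against a longhand
expansion and against the dichromat limit.

**Substitute receptor set.** The published average violet-sensitive avian
phenotype is defined inside proprietary tabulations that are not shipped
here. The default `visual_system()` is therefore an explicitly *synthetic*
stand-in: four Gaussian templates peaking at 416, 478, 542 and 607 nm
(width 40 nm), densities 1:2:2:4, Weber fraction 0.1 of the most abundant
receptor, CIE D65 at 10 nm interpolated to the grid and renormalized to
unit mean. Measured sensitivity curves can be supplied as a matrix.
Because the distance is a relative quantity and all comparisons use the
same system, the qualitative host/non-host contrasts do not depend on the
template details; absolute JND values do, and should not be compared with
values from other software.

An insect's match score against a plant species is the **minimum** JND
distance between the insect's spectrum and any sheath measurement in the
species' cluster (sheath replicates are averaged per plant first). Each
insect in a comparison gets two scores — own host and alternative host —
which feed the split-plot ANOVA below.

## Preference: marginal binomial model

Each individual is offered both hosts and observed at 12, 15, 18, 21 and
24 h; the response is the binary choice of the reference host. Repeated
choices of one individual are correlated, so the population, sex and time
effects are estimated with a binomial GEE under an exchangeable working
correlation: working covariance
$V_i = \phi A_i^{1/2} R(\alpha) A_i^{1/2}$, $\alpha$ by the moment
estimator over within-individual Pearson-residual pairs (denominator
$\sum_i n_i(n_i-1)/2 - p$), $\phi$ the mean squared Pearson residual, and
Fisher scoring on $\beta$ until $\max|\Delta\beta| < 10^{-8}$ (at most
100 iterations, initialized from the independence GLM). Inference uses
the robust sandwich covariance $B^{-1}MB^{-1}$ throughout, so conclusions
do not hinge on the working correlation. Time enters as a linear covariate
in hours.

The default link is **logit**. The source analysis nominally used a log
link yet back-transformed to a 0–1 preference probability compared
against 0.5 — the logit workflow; both links are provided and the
discrepancy is surfaced rather than hidden. Cell summaries are
back-transformed marginal means per population × sex with Wald 95%
intervals formed on the link scale (normal quantile 1.959964), the linear
predictor evaluated at the mean of the design's observation times
(averaging over times and evaluating at the mean time coincide because
time is linear). A preference is called only when the interval excludes
0.5.

Effect sizes use Hedges' $d$ with the small-sample correction
$J = 1 - 3/(4m - 1)$ and variance
$(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))$. For binary choice cells the
group standard deviation is the binomial plug-in $\sqrt{p(1-p)}$ at the
GEE cell mean — the standard binary-trait convention — with $n$ the number
of individuals, and the two sexes of a population are collapsed by an
individual-weighted average before comparing populations.

## Group comparisons

Body width and stockiness (width / elytron length) are analysed per
comparison by two-way fixed-effects ANOVA with host population and sex.
Sums of squares are **Type II** by default (the conventional choice when
the interaction is not of interest; equal to sequential SS for balanced
data), with Type I/III behind a flag and the host × sex interaction off by
default. Factors collapsed to one level drop out, reducing to a one-way
analysis. Pairwise cell contrasts use Tukey–Kramer $q$ statistics with
tail probabilities from the studentized-range distribution and an
insert-and-absorb compact letter display.

Colour matching uses a 2×2 **split-plot** ANOVA per sex: population origin
(between subjects) × target plant species (within subjects, two levels),
individual as the random stratum. The between factor is tested against
subject-within-group error; the within factor and the origin × species
interaction — the local-adaptation signal — against the species × subject
residual. With two within levels the decomposition is exact (sphericity is
trivial), group sizes may differ, and the interaction $F$ is identically
the squared pooled t statistic on within-subject difference scores — a
property the test suite asserts on arbitrary random inputs. Degenerate
zero-variance inputs return flagged $F = 0$, $p = 1$ instead of erroring,
so batch pipelines keep running.

Culm thickness is summarized as medians per species and position
(apex/base) only; the original analysis of those data is not described
precisely enough to reproduce.

## Synthetic data: what it emulates

Generator defaults mirror the field design:

* **Occurrences** — 44 herbivore records and 11 host ranges (60 records
  each) drawn uniformly from convex generating polygons; ellipse ranges
  are represented as 72-gons so analytic overlaps of generating ranges are
  available. The default mosaic is heterogeneous: hosts range from
  near-disjoint with the herbivore to near-complete overlap.
* **Choice trials** — two populations × two sexes × 45 individuals, five
  time points. The config specifies the *marginal* choice probability per
  cell; the generator solves for the conditional logit intercept by
  Gauss–Hermite quadrature and adds a normal individual intercept
  (s.d. `sigma_indiv`), inducing exchangeable within-individual
  correlation. Matching on the marginal scale is deliberate: a GEE
  estimates marginal means, so parameter-recovery tests compare like with
  like. The true within-individual correlation of the insects is unknown;
  fixtures default to an ICC of 0.3, a moderate value for repeated
  behavioural assays, set via `sigma_for_icc()`.
* **Morphometrics** — normal draws per cell truncated at zero, females
  broader than males, the population on the thicker-culmed host broader
  overall (≈2 mm widths, ≈7 mm elytra, s.d. 0.12/0.35 mm).
* **Spectra** — base curve = logistic ramp plus optional Gaussian bump,
  per-group reflectance offsets, i.i.d. reflectance-scale noise
  (s.d. 0.02) clipped to [0, 1]; sheath clusters of 18/15/12/10/11 plants
  measured in duplicate, 30 insects per origin. Offsets are smooth and
  analytically controllable, which real plant spectra are not; the
  generator does not emulate specular glare, UV structure or
  within-plant gradients, so passing tests demonstrate correctness of the
  *computation*, not realism of any particular spectrum.

One master seed; each generator draws from a stream at a fixed offset, so
outputs are bit-identical under a fixed config and independent across
modules.

`sim_study()` composes a full three-comparison study. Preference effects
place marginal probabilities at 0.7/0.3 (versus 0.5/0.5 under no effect);
colour effects put each insect group on its own host's sheath offset,
while no-effect comparisons give both insect groups the reference host's
colour, producing parallel match profiles. By default divergence is
generated in the low- and moderate-overlap comparisons and not in the
high-overlap one, mirroring the motivating field pattern.

## Decision rules and numerical choices

* Divergence declaration in the report: preference — population Wald
  $p < 0.05$; colour — interaction $p < 0.05$ **in both sexes**. Requiring
  both sexes matches the sex-separate analysis design (the motivating
  positive case was significant in both) and keeps the family-wise
  false-positive rate of the colour call near $0.05^2$ rather than
  doubling it.
* Bootstrap: percentile method; the resample count (default 10,000) is a
  convention, the original count being unstated.
* GEE: $|\alpha|$ clamped inside the positive-definite region
  $(-1/(n_{\max}-1), 1)$; non-convergence is flagged and returned with a
  warning, never silently dropped; singular designs error.
* JND computation requires strictly positive normalized catches; spectra
  are clipped to non-negative reflectance and resampled by linear
  interpolation with no extrapolation beyond a configurable tolerance.
* Tests and acceptance checks run at reduced but statistically meaningful
  sizes chosen as a design matter: e.g. 500 null and 200 effect replicates
  for GEE size/power, 200 property cases for the split-plot identity, 50
  end-to-end runs, 500 points per species for mosaic recovery.

## Known limitations

* Hull ranges ignore concavity and outliers by construction; alpha shapes
  and distribution modelling are out of scope.
* The default visual system is a labelled substitute, not the published
  avian phenotype; absolute JNDs are not comparable across software.
* The GEE is marginal: subject-specific (GLMM) effects and QIC-based model
  selection are out of scope, as is multiple-testing correction across
  comparisons (none was applied originally).
* The equirectangular pre-projection is a documented convention, not a
  reconstruction of the original GIS workflow.

## A minimal run

```{r example, eval = FALSE}
study <- sim_study(seed = 1)
report <- run_pipeline(list(
  seed = 1,
  data = study[c("occurrences", "trials", "morph", "spectra")],
  comparisons = unname(study$comparisons)))
print(report)
```
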