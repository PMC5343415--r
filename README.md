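# mosaicadapt

Does spatial turnover in host-plant availability drive host-associated
divergence in a herbivore? `mosaicadapt` implements the complete inference
chain for that question in evolutionary ecology, for analysts working with
occurrence records, behavioural choice assays, morphometrics and
reflectance spectra. It was built around the study system of a camouflaged
restio leafhopper and its Restionaceae host plants, but every stage is
generic.

The pipeline has four statistical cores:

* **Geographic host mosaic** — species ranges as convex hulls of
  occurrence points; directional overlap
  `o_h = area(H ∩ P_h) / area(H)` of each host hull with the herbivore
  hull; symmetric pairwise overlap `(o_AB + o_BA) / 2`; and a seeded
  percentile bootstrap of the mean per-host overlap with a one-sided
  upper 95% bound (an upper bound below 1 means no host spans the
  herbivore's range).
* **Receptor-noise-limited visual model** — quantum catches
  `Q_i = ∫ R(λ) I(λ) S_i(λ) dλ`, von Kries normalization against the
  adapting background, receptor noise `e_i = w √(η_ref / η_i)`, and the
  chromatic distance ΔS in just-noticeable differences (JNDs) for 2–4
  receptors. An insect's match score against a plant is its minimum ΔS to
  the plant's cluster of sheath spectra.
* **Marginal preference model** — binomial GEE with exchangeable working
  correlation and robust sandwich covariance for repeated binary host
  choices (population + sex + time), Wald term tests, back-transformed
  population × sex means with 95% intervals, preference calls against
  0.5, and Hedges' d with binomial plug-in standard deviations.
* **Group comparisons** — two-way fixed-effects ANOVA (Type II SS) with
  Tukey–Kramer post hocs and compact letter displays for body width and
  stockiness, and a 2×2 split-plot repeated-measures ANOVA per sex whose
  origin × plant-species interaction is the local-adaptation signal in
  colour matching.

A seeded synthetic-data module (`sim_config()`, `gen_occurrences()`,
`gen_choice_trials()`, `gen_morphometrics()`, `gen_spectra()`,
`sim_study()`) generates inputs with the statistical structure the
analyses assume, so the whole chain runs and is tested without any
external data. See the methods vignette
(`vignettes/mosaicadapt-methods.Rmd`) for models, assumptions, defaults
and limitations.

## Worked example

Simulate a three-comparison study (divergence generated in the low- and
moderate-overlap comparisons, none in the high-overlap one) and run the
full pipeline:

```r
library(mosaicadapt)
study <- sim_study(seed = 1)
report <- run_pipeline(list(
  seed = 1,
  data = study[c("occurrences", "trials", "morph", "spectra")],
  comparisons = unname(study$comparisons)))
print(report)
#> Pipeline report
#> mosaic: mean host overlap 0.206 (upper bound 0.332)
#> low: preference Wald p = 2.27e-12 [divergent]; colour interaction 2.91e-47/1.93e-45 [divergent]
#> moderate: preference Wald p = 6.24e-17 [divergent]; colour interaction 2.82e-46/8.15e-47 [divergent]
#> high: preference Wald p = 0.82 [ns]; colour interaction 0.603/0.78 [ns]
```

The mosaic block says the average host co-occurs with the herbivore over
only ~21% of its range, and even the upper bootstrap bound (33%) is far
from full coverage — populations must differ in the hosts available to
them. Divergence is then declared exactly where it was generated: the
population Wald test and the sex-separate colour interactions are
significant in the low and moderate comparisons and not in the high one.

Cell-level preference estimates for one comparison:

```r
report$comparisons$moderate$preference$means
#>      population sex  mean lower upper  n                call
#> 1  M_spathulata   F 0.649 0.559 0.729 45   prefers reference
#> 11 M_spathulata   M 0.747 0.684 0.802 45   prefers reference
#> 12       E_nuda   F 0.227 0.160 0.311 45 prefers alternative
#> 13       E_nuda   M 0.319 0.246 0.403 45 prefers alternative
report$comparisons$moderate$preference$effect_size$d
#> [1] 0.9353269
```

Each population prefers its own host (intervals exclude 0.5 on opposite
sides), with a large standardized divergence (Hedges' d ≈ 0.94).

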