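---
title: "Parental age and offspring telomere length: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parental age and offspring telomere length: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telopac)
```

## The scientific question

In humans, offspring of older fathers tend to have longer leukocyte
telomeres — a paternal-age-at-conception (PAC) effect attributed to
telomere elongation in the sperm of ageing males. Whether the effect
generalises to other mammals, especially promiscuous species under strong
sperm competition, is open. The test case implemented here is a wild Soay
sheep population: 389 measurements of relative leukocyte telomere length
(RTL) on 318 animals of known age, sex and parentage, with maternal (MAC)
and paternal (PAC) ages at conception recorded in integer years. Unlike
human populations, MAC and PAC are essentially uncorrelated in this
system, so the two effects are separable.

`telopac` implements the full quantitative pipeline for this design:

1. **qPCR processing** — raw per-well amplification curves to
   calibrator-normalised RTL with quality control;
2. **mixed modelling** — crossed random-intercept LMMs and
   likelihood-ratio tests (LRTs) for parental-age terms;
3. **power analysis** — Monte-Carlo power of the PAC test and
   slope-to-correlation effect-size conversion;
4. **synthetic data** — a generator reproducing the design's statistical
   structure, so every stage is testable without the real dataset.

## Relative telomere length from qPCR

RTL is the amount of telomeric sequence relative to a single-copy
reference gene (beta-2-microglobulin, B2M), normalised to a calibrator
sample run on every plate:

$$\mathrm{RTL} = \frac{E_\mathrm{TEL}^{\,Cq_\mathrm{TEL}[\mathrm{Cal}] - Cq_\mathrm{TEL}[\mathrm{Sample}]}}{E_\mathrm{B2M}^{\,Cq_\mathrm{B2M}[\mathrm{Cal}] - Cq_\mathrm{B2M}[\mathrm{Sample}]}}$$

where \(E\) is the plate-mean amplification efficiency of the amplicon
group (per-cycle fold change, 2 = perfect doubling) and \(Cq\) values are
triplicate means. The calibrator normalises to RTL = 1 by construction
and absorbs plate-to-plate variation.

`process_plates()` derives every ingredient from raw curves:

* **Baseline correction** (`correct_baseline()`): a linear fit over the
  first 8 cycles (default) is subtracted per well. The early-cycle count
  is configurable; 8 keeps the window clear of detectable amplification
  for the Cq range simulated here. `n_baseline_cycles = 0` skips the step
  for curves that are already baseline-free.
* **Window of linearity** (`estimate_efficiency_and_cq()`): among all
  runs of 4–6 consecutive cycles between the noise floor and the plateau
  onset (first cycle within 5% of the curve maximum), the window
  maximising the R² of the log-fluorescence regression is selected;
  windows whose fluorescence span contains the constant threshold are
  preferred, since the threshold is set within the window of linearity
  and Cq and efficiency should describe the same exponential phase. Ties
  (exact in noiseless curves) resolve to the later window. Efficiency is
  `exp(slope)`; Cq is the log-linear interpolation of the threshold
  crossing. The default thresholds are 0.222 (TEL) and 0.193 (B2M), the
  protocol's published constants.
* **Group threshold** (`set_group_threshold()`): the convention of fixing
  a constant threshold from the average Cq across the first 6 plates is
  underdetermined as stated, so the package's reconstruction is explicit:
  each well's provisional Cq is the midpoint of its window of linearity,
  and the threshold is solved (by `uniroot` within the wells' common
  window-fluorescence span) so that the mean interpolated Cq equals the
  mean provisional Cq. Any threshold inside every window would be
  defensible; this choice is deterministic and reproduces the "average
  Cq" anchoring.
* **Quality control**: triplicates fail if the CV (sample SD / mean of
  the three Cqs, on the cycle scale — the literal reading of the rule)
  exceeds 5% on either amplicon; a replicate whose efficiency deviates
  more than 5% from the plate-amplicon mean excludes the whole sample
  (exclusion language is sample-level, so two clean replicates are never
  averaged as a fallback); fewer than three amplifying replicates is the
  distinct failure `replicate_missing`. Filters commute; when several
  fail, the primary reason is attributed in the fixed order
  replicate-missing, CV, efficiency. Plate-mean efficiencies average all
  QC-passing sample and calibrator wells of the amplicon (never NTCs);
  `use_all_wells = TRUE` restores the alternative of averaging before
  well exclusion.
* **DNA QC** (`dna_sample_qc()`): yield ≥ 20 ng/µl, 260/280 in
  [1.7, 2.0], 260/230 in [1.8, 2.2], gel integrity score ≤ 2 (boundaries
  non-strict at printed interval endpoints, strict where the rule says
  "higher than"); one re-extraction is allowed before final exclusion.

## The mixed model

RTL is modelled with a Gaussian linear mixed model:

$$\mathrm{rtl}_{i} = \beta_0 + \beta_\mathrm{year}\,\mathrm{year}_i +
\beta_\mathrm{age}\,\mathrm{age}_i + \beta_\mathrm{sex}\,\mathrm{sex}_i +
\beta_\mathrm{age:sex}\,\mathrm{age}_i\mathrm{sex}_i +
u_{m(i)} + u_{f(i)} + u_{p(i)} + \varepsilon_i$$

with crossed random intercepts for mother \(m\), father \(f\) and qPCR
plate \(p\). Individual identity is deliberately *not* a random term by
default, matching the published random-term list for this dataset (389
observations on 318 animals); `random_terms = c(..., "animal_id")` adds
it. Fitting is by ML (required whenever fixed structures are compared)
through lme4 behind `fit_rtl_lmm()`; the suite independently verifies the
maximised log-likelihood against a direct covariance-matrix optimiser.

Parental-age effects are tested by LRT (`test_parental_age()`): the
linear test adds MAC or PAC to the base model (1 df); the quadratic test
is a *joint* 2-df comparison of base + term + term² against the base
model, matching the 2-df statistics reported for this design, not a
sequential 1-df pair. MAC/PAC are mean-centred before squaring to limit
collinearity — whether the original analysis centred is unstated, but the
LRT is invariant to it. In lamb mode the base model drops age and
age×sex (all lambs are the same age). Variance components may sit at the
0 boundary; they are flagged (`singular`) but never refitted without the
term, and p-values are plain upper-tail χ² with no boundary correction,
as in standard LRT usage for fixed effects.

`variance_proportions()` reports each random intercept's share of the
summed random-intercept variance, reading "proportion of variance in the
random effects component" as shares among the three fitted intercepts;
`include_residual = TRUE` switches to shares of total variance. Because
the published shares could come from the base or the augmented model, the
pipeline driver reports the base model; the augmented fits are returned
by `test_parental_age()` for the alternative.

## Effect sizes and power

Because qPCR RTL is a relative quantity, slopes are compared across
studies on the correlation scale:
\(r = b \cdot \mathrm{SD}_\mathrm{PAC} / \mathrm{SD}_\mathrm{RTL}\)
(`slope_to_r()`, exactly inverted by `r_to_slope()`). With the study SDs
(\(\mathrm{SD}_\mathrm{PAC} = 2.121\),
\(\mathrm{SD}_\mathrm{RTL} = 0.185\)), a slope of 0.012 RTL/year implies
r ≈ 0.14, and the chimpanzee-reported r = 0.378 back-converts to a slope
of ≈ 0.033.

`estimate_power()` resamples the full design — parents, plates,
covariates, random effects — fresh in every replicate from
`soay_structure()` with the candidate slope injected, runs the 1-df
linear PAC LRT at α = 0.05, and reports the rejection fraction with its
binomial standard error. One master seed spawns per-replicate seeds, so
grids are reproducible and embarrassingly parallel. Replicates that fail
to converge are dropped from the denominator with a warning; more than 2%
dropped aborts the run (in practice none drop).
`minimum_detectable_effect()` inverts an isotonic regression of the power
curve at the target power and reports the bracketing grid points.

**The variance partition behind the power target.** The published
summaries fix the total RTL SD (0.185) and the mother/father shares of
explained random variation (16% and 2%) but not the absolute plate and
residual components. `soay_structure()` therefore partitions total
variance as mother 16%, father 2%, plate 5%, residual 77% — plate effects
kept small, residual absorbing the remainder. Simulated power under this
default is ≈ 78–80% at slope 0.012 (Monte-Carlo SE ≈ 2% at 500
replicates), consistent with the reported 80% minimum-detectable-effect
statement, and 100% at the chimpanzee-equivalent slope. Power is mildly
sensitive to how the unidentified 82% remainder is split: pushing
variance from residual into plate raises power slightly (plate intercepts
are absorbed by the model, residual is not), so the default is the
conservative end. The partition is a single fixed choice, not a fitting
target; `population_params()` accepts any partition for sensitivity
analyses.

## What the synthetic data do and do not emulate

`sample_population()` reproduces the design's statistical skeleton:

* 389 observations of 318 animals (the surplus measured once in each of
  two years, with the same parents, ages advanced one year, fresh
  residual — mirroring the two-year cross-sectional sampling); whether
  real repeats changed plates between years is unknown, so
  `same_plate_repeats` is a switch (default: plates drawn independently).
* MAC and PAC drawn *independently* (their observed correlation was
  0.007) as truncated-geometric integers on [1, 14] and [1, 10]. Only the
  ranges and \(\mathrm{SD}_\mathrm{PAC} = 2.121\) are recoverable from
  the published summaries; the geometric decay is tuned by `uniroot` to
  hit the target SD exactly, and the MAC SD (2.5) and adult-age SD (2.2)
  are field-plausible choices for a population where most breeders are
  young. Sex (70% female) and lamb fraction (164/389) follow the reported
  sample composition.
* Fixed-effect coefficients default to zero — the published text reports
  no coefficient values, and the parental-age LRTs are invariant to them;
  they are configurable for sensitivity work.
* Raw plates (`plates_from_phenotypes()`) invert the RTL formula: each
  sample's true B2M Cq is drawn around the calibrator's (DNA-input
  variation, SD 0.4 cycles) and its TEL Cq solved so the formula returns
  the record's RTL exactly; wells add Gaussian Cq noise (default SD 0.05
  cycles) and render curves as linear baseline + plateau-capped
  exponential with lognormal per-cycle noise,
  \(F_0 = T \cdot E^{-Cq}\) anchoring the threshold crossing. Under pure
  Cq noise the recovered-RTL error follows the delta-method propagation
  \(\mathrm{SD}(\log \mathrm{RTL}) = \sqrt{2/3}\,\sigma\sqrt{\log^2
  E_\mathrm{TEL} + \log^2 E_\mathrm{B2M}}\), which the suite verifies
  empirically.

Not emulated: pedigree genotypes and parentage inference, extraction
failures beyond the configurable QC flags, melting curves, inter-run
calibration beyond the single-calibrator scheme, and any non-Gaussian
features of real RTL (heavy tails, plate-position effects). Passing tests
therefore demonstrate that the *pipeline* is correct under the stated
model, not that the model captures every feature of field data.

## Numerical choices and problem sizes

* Noiseless identities (round trip, calibrator self-normalisation) are
  asserted at 1e-6 or tighter; the direct-likelihood cross-check at 1e-3
  on a seeded n = 40 dataset; invariances (row permutation, identifier
  relabelling) at 1e-8.
* Monte-Carlo checks use 1000 null replicates (test size and the χ²(1)
  distribution of the null LRT, judged against 99% binomial envelopes and
  a Kolmogorov–Smirnov p > 0.01), 500 replicates at slope 0.012, and 200
  at slope 0.033; variance-share recovery uses one n = 10 000 population
  with 200 plates so the plate share is estimable to ±3 points. These
  sizes keep the binomial error well inside the asserted margins.
* The LRT statistic is clipped at 0 (optimizer noise can make the nested
  difference infinitesimally negative); `df = 0` comparisons return
  p = 1.

## Limitations

* The group-threshold reconstruction and the variance partition are
  explicit package choices where the published description
  underdetermines the procedure; both are documented above and
  configurable.
* Power results are conditional on the Gaussian, independent-MAC/PAC
  generator; they are a design property, not a reanalysis of the real
  data.
* The real supplementary dataset, when available, enters through
  `map_phenotypes()` (a column-mapping layer, so no external column names
  are hard-coded) and `test_parental_age()` reproduces the published LRT
  machinery on it; the printed χ² statistics can only be recomputed with
  that file present.

## A worked example

```{r example, eval = FALSE}
library(telopac)

# simulate the study design with a modest true PAC effect
pop <- sample_population(soay_structure(pac_slope = 0.02), seed = 1)

# raw plates -> RTL with QC
curves <- plates_from_phenotypes(pop, qpcr_plate_spec(), seed = 1)
proc <- process_plates(curves)
proc

# merge measured RTL and test PAC
measured <- dplyr::inner_join(
  dplyr::select(pop, -rtl),
  dplyr::filter(tidy(proc), !excluded)[, c("sample_id", "rtl")],
  by = "sample_id"
)
test_parental_age(measured, "PAC", "linear")

# power curve around the design's minimum detectable effect
pw <- estimate_power(c(0, 0.006, 0.012, 0.02, 0.033), n_reps = 200, seed = 1)
autoplot(pw)
minimum_detectable_effect(pw, 0.8)
```
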