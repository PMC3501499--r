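---
title: "Methods: rodent community stable-isotope analysis with rodiso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rodent community stable-isotope analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodiso)
```

## The problem

Oxygen and carbon isotope ratios of mammalian bioapatite are standard
proxies for past climate and diet.  Small rodents are attractive recorders —
abundant, short-lived, with tiny home ranges — but their skeletal tissues
integrate isotope input over very different time windows: permanently
growing (hypselodont) incisors record only the last 4–7 weeks of life,
arvicolid molars roughly 8–12 weeks, and bone close to the whole
post-weaning life span.  Because owl-pellet death assemblages are biased
toward the late-summer population maximum, tooth and bone values from the
same community can differ systematically, and calibration equations
developed on one tissue class are biased when applied to the other.

`rodiso` implements the complete analysis chain for such a dataset, plus a
synthetic-community generator that reproduces exactly this structure so the
chain can be validated against known truth.

## Core quantities

**Delta notation.** All values are per-mil deltas,
$\delta = (R_\mathrm{sample}/R_\mathrm{standard} - 1)\times 1000$, vs VSMOW
(oxygen) and VPDB (carbon); `delta_from_ratios()` is the primitive.

**Carbonate–phosphate offset.** Bioapatite carries oxygen in both the
phosphate and the structural carbonate moiety.  The package-wide sign
convention is $\Delta^{18}O_{CO_3\text{-}PO_4} = \delta^{18}O_{CO_3} -
\delta^{18}O_{PO_4}$ (positive, ~9–11‰).  `estimate_offset()` computes the
per-pair offsets, their arithmetic mean and sample SD (always the $n-1$
denominator; SD is *absent*, not zero, for a single pair).  Uncertainty
propagation in `co3_to_po4()` is first order with independence assumed —
only ±1σ summaries are available, no covariances.

**Calibration inversion.** Equations are stored exactly as published, in
the form $\delta^{18}O_{LW} = (\delta^{18}O_{PO_4} - a)/b$; the forward map
is derived algebraically rather than stored, which removes one class of
transcription error.  The registry ships with the three rodent equations
(rat bone $a=17.88, b=0.49$; wild murid/arvicolid bone $a=23.07, b=1.14$;
arvicolid tooth $a=20.98, b=0.572$).  A tissue-basis mismatch between
equation and data is deliberately a *warning*, not an error: the mismatched
comparison is itself scientifically informative (it measures the seasonal
tissue bias), so the package performs it while flagging it.  The rat-bone
line is additionally flagged as an extrapolation for reconstructed water
below −4‰, because it was calibrated on waters enriched relative to
temperate NW-European precipitation; the bound is configurable since no
numeric range was published.

**Diet.** `apatite_to_diet()` subtracts a single scalar diet-to-bioapatite
enrichment (default +9.9‰, the rodent bone value; the literature spans
9–15‰ but one taxon-appropriate scalar is used deliberately).
`c4_fraction()` mixes two end-members (C3 −27‰, C4 −13‰) linearly and
clips to [0, 1]; raw fractions outside ±0.05 of that interval are flagged
rather than silently clamped, so subcanopy-depleted C3 diets (−36 to −32‰)
surface as flags.  CAM plants are ignored.

**Community statistics.** `one_way_anova()`, `tukey_hsd()` and
`kruskal_wallis()` are authored from the classical formulas (fixed-effects
decomposition; Tukey–Kramer harmonic-mean SE for unequal $n$; tie-corrected
$H$ with the $\chi^2$ approximation) and are cross-checked in the test
suite against the independent base-R implementations.  Tie handling in the
Kruskal–Wallis test uses the standard correction; which variant the
original analyses used is not documented, so the tie-corrected form is the
package's single behaviour.  `flag_outliers()` uses a leave-one-out rule —
$|x_i - \mathrm{median}| > k \cdot \mathrm{SD}(x_{-i})$, $k = 3$ by
default — so a gross outlier cannot inflate the SD that judges it; flagging
is report-only and exclusion is always an explicit caller decision.

**Bootstrap minimum sample size.** For each subsample size $n_{sub} \in
[2, n-1]$, `bootstrap_min_sample_size()` draws 1000 random subsamples
*without replacement* (they are subsamples of distinct specimens; the
procedure is often loosely called bootstrapping, and a with-replacement
mode exists behind `replace = TRUE` for sensitivity analysis), counts
subsample means inside the boundary-inclusive ±1σ window of the full
sample (full-sample $n-1$ SD), and averages the count over 100 repeats.
$n_{sub}$ is adequate at 95% (99%) confidence when the averaged count
reaches 950 (990) of 1000.  Inclusive boundaries make the zero-variance
case well defined (all counts equal the replicate number, flagged
degenerate).  One master seed spawns a fixed hashed substream per
$(n_{sub}, \text{repeat})$, so results are reproducible and independent of
evaluation order.  Published count tables with ">990"-style cells are
parsed as lower bounds and compared with ≥ semantics: a bound of 990 can
prove thresholds up to 990 and nothing above.

## The synthetic community: what it emulates, and what it does not

`generate_community()` states a world with analytic truth:

* **Water**: a single cosine,
  $\delta^{18}O_{LW}(t) = -7.3 + 2.0\cos(2\pi(t-196)/365)$‰ — annual mean
  −7.3‰ (long-term local precipitation), half-amplitude 2‰ peaking
  mid-July (day 196).  A cosine rather than an empirical monthly curve
  keeps every window average analytically checkable; users with monthly
  station exports can register their own series by editing the config.
* **Tissues**: each tooth draws a formation window uniformly within its
  stated range (incisors 28–49 d, molars 56–84 d) and averages the water
  curve over the window ending at death; bone averages from weaning
  (day 21) to death, truncated with a flag if the window predates weaning.
* **Mortality**: death months are drawn from relative weights rising from
  1 in late winter to 4 in August–September, a reduced-form stand-in for
  prey-population-tracking pellet deposition (no numeric profile was
  published, so the weights are config-exposed).
* **Lifespans**: truncated Normal(300, 80) days with a 90-day floor —
  pellet assemblages mix spring-born juveniles with overwintered adults
  and bone is described as recording "approaching the life span", i.e.
  most of a year.  Individuals under 120 days are labelled juvenile and
  can receive a configurable suckling 18O enrichment (default 0).
* **Noise**: one biological shift per individual (SD 0.5‰, shared across
  its tissues), a Gaussian carbonate–phosphate offset per record
  (10.9 ± 0.8‰), and per-analyte measurement noise (0.1, 0.2, 0.04‰ for
  δ18O~CO3~, δ18O~PO4~, δ13C — the published analytical precisions).
* **Diet**: per-species Gaussian apatite-scale δ13C (the seven-species
  incisor means/SDs), with an optional two-component C4-contamination
  mixture (off by default) and an optional seasonal diet modulation (off).

Not emulated: predator functional response, spatial structure, diagenesis,
age-structured bone turnover, humidity effects on plant δ13C.  A green
recovery test therefore establishes that the *pipeline* is unbiased under
the stated generating process — not that the process is a complete model
of a real taphocoenosis.

With the default summer-biased configuration the generator reproduces the
qualitative fingerprint of real pellet communities: roughly 60–70% of
individuals show higher incisor than bone δ18O~CO3~ (the published
community shows 85%, whose excess plausibly reflects stronger mortality
concentration or younger age structure than the defaults assume), the mean
incisor–bone offset grows with seasonal amplitude, and with amplitude zero
it vanishes to within Monte-Carlo error.

## Numerical conventions

* Reporting rounds half away from zero to 0.1‰ (`round_report()`);
  internal arithmetic is never rounded.  Full-precision means are reported
  even where a published table's rounded cell differs in the last digit
  (e.g. an incisor-offset mean of 11.14 prints as 11.1 here against a
  published 11.2 evidently averaged before rounding); the overall, M1 and
  bone offset means agree either way.
* Missing values are `NA` throughout; sanity-window violations (δ18O
  outside [0, 50]‰, δ13C outside [−40, 10]‰) flag records but never drop
  them.
* The canonical exchange format is a fixed-header UTF-8/LF CSV;
  write-after-read is byte-identical.
* p-values are numbers; "<0.01"-style banding belongs to report renderers.

## Known limitations

* The community tooth mean of 16.8‰ (phosphate scale, n = 70) used for
  the calibration comparison is only reproducible from individual-level
  data with outlier handling; from the printed species means one obtains
  16.5‰.  The package computes from whatever records it is given and does
  not special-case either value.
* Exact reproduction of the published per-species bootstrap counts and the
  community ANOVA F requires the individual-level supplementary dataset,
  which is not redistributable here; the test suite instead validates the
  procedures on hand-computable examples, cross-implementation oracles and
  the published summary tables.
* Whether the original subsampling allowed repeated identical subsamples
  across the 1000 replicates is unstated; this implementation draws them
  independently (repeats allowed), which is the simplest well-defined
  choice and matches the published thresholds.
```{r example}
tab3 <- read_dataset(system.file("extdata", "table3_arvicola.csv",
                                 package = "rodiso"))
estimate_offset(tab3)
reconstruct_water(tab3, "longinelli_2003",
                  offset = estimate_offset(tab3), tissue = "bone")
```
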