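# tandemdose

Dosimetry-guided design and efficacy analysis for preclinical tandem
alpha/beta radioligand therapy studies.

## The problem

Targeted radionuclide therapy can deliver its tumor dose with beta particles
(Lu-177: mean beta energy ~133 keV, millimetre tissue range), alpha
particles (Ac-225: an 8-member decay series releasing ~28 MeV per parent
decay over <0.1 mm), or both at once ("tandem" therapy). Comparing these
mechanisms fairly in a mouse model requires injecting activities that
deposit the *same absorbed tumor dose* — which means walking from nuclear
decay data and ex vivo gamma-counting biodistribution measurements all the
way to an activity prescription, and then analysing the resulting
longitudinal tumor-burden and survival data. `tandemdose` implements that
entire chain as tested, reusable R code, with a seeded synthetic-cohort
generator standing in for the animal data so every stage can be verified.

## The model

The core dose statistic is MIRD-style self-dose:

    D = Ã · Δ / m

* **Ã (cumulated activity)** — time-integral of tumor activity, obtained by
  fitting A₁e^(−λ₁t) + A₂e^(−λ₂t) to the %IA time–activity curve (AICc
  model selection between mono- and bi-exponential candidates) and
  integrating analytically with physical decay re-applied:
  Ã = Σᵢ Aᵢ/(λᵢ + λ_phys).
* **Δ (dose constant)** — energy released per disintegration, from bundled
  emission tables: alphas + beta continuum means, yields ≥ 1%, photons
  excluded, absorbed fraction 1. For the alpha chain, progeny are weighted
  by cumulative branch probability (secular equilibrium, verified by a
  branched Bateman solver: every Ac-225 chain member equilibrates within
  24 h, the delayed-counting rule the quantification layer enforces).
* **Equal-dose matching** — A_target = A_ref · D_ref/D_target, then tandem
  prescriptions scale each matched mono activity by a fraction (½ + ½ by
  default), reported to integer MBq/kBq with halves rounded down
  (35/2 → 17 MBq).
* **Efficacy** — per-arm radiance summaries with a minimum-survivor masking
  rule, fold change from the treatment week, per-week one-way ANOVA with
  Bonferroni contrasts, Kaplan–Meier medians and Mantel–Cox log-rank tests
  (built on `survival`).

## Worked example

```r
library(tandemdose)

nuclide_dose_constant("225Ac")
#> Dose constant Delta[Ac-225] = 5.9380e-01 Gy.g/(uCi.h)  (27.8243 MeV/decay, filter reference, cutoff 0.01)
nuclide_dose_constant("177Lu")
#> Dose constant Delta[Lu-177] = 2.8633e-03 Gy.g/(uCi.h)  (0.1342 MeV/decay, filter reference, cutoff 0.01)
```

The ~207× dose-constant ratio is why microcurie-scale alpha activities match
megabecquerel-scale beta activities. A kidney-uptake group comparison from
summary statistics (mean ± SD, n = 5 per group):

```r
w <- welch_compare(25.9, 3.5, 5, 13.3, 1.6, 5)
#> Welch t = 7.32, df = 5.6, p = 0.00045    (significant early kidney difference)
```

Run the whole synthetic pipeline — biodistribution cohorts for both
isotopes, uptake quantification, TAC fitting, dosimetry, activity matching,
tandem prescription, trial simulation and efficacy analysis:

```r
fx <- end_to_end_fixture(sim_config(seed = 3))

fx$lu$fit
#> Fit (mono_exp): A1 = 4.385 %IA, lambda1 = 0.007351 /h ...
#> (at the 5-point design the 4-parameter candidate has no defined AICc
#>  and is excluded with a notice, so the mono-exponential is selected)

fx$lu$dose$dose_per_injected_activity   # 0.0967 cGy/kBq
fx$ac$dose$dose_per_injected_activity   # 31.7   cGy/kBq
fx$dose_ratio                           # 327  (configured truth: 355)

fx$ac_matched_kbq                       # 106.9 kBq of Ac-225 matches 35 MBq Lu-177
fx$tandem
#> Activity prescription (tandem):
#>   Lu-177   17 MBq (raw 17500 kBq)
#>   Ac-225   53 kBq (raw 53.4505 kBq)

fx$km$medians
#>      arm  n events median
#> 1     Ac 10      9   14.0
#> 2     Lu 10     10    7.4
#> 3     NT 10     10    8.4
#> 4 tandem 10     10   11.9
fx$logrank[[4]]                         # Ac vs Lu: chi2 = 16.41, p = 5.1e-05
```

The medians scatter around the configured arm medians (NT 8.3, Lu 9.4,
tandem 14.1, Ac 15.3 weeks) with the sampling noise of 10 mice per arm; the
alpha-containing arms separate clearly from the beta-only arm, while
untreated vs beta does not reach significance — the qualitative pattern the
generator is calibrated to.

A thin CLI wraps the same functions (see `?tandem_cli`):

```sh
Rscript inst/scripts/tandemdose doseconst --nuclide 225Ac --mode reference --cutoff 0.01
Rscript inst/scripts/tandemdose simulate --seed 1 --out fixtures/
```

## Documentation

The methods vignette (`vignettes/tandem-dosimetry.Rmd`) documents the model
assumptions, the numerical choices (fitting bounds, identifiability of the
fast kinetic component, equilibrium tolerances, rounding rules), what the
synthetic generator does and does not emulate, and known limitations.
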