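---
title: "Methods: dosimetry-guided design and efficacy analysis for tandem alpha/beta radioligand therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tandem alpha/beta dosimetry and efficacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemdose)
```

# Scope and model

`tandemdose` implements the quantitative chain that turns ex vivo
biodistribution counting of two radioligands — a medium-energy beta emitter
(Lu-177, half-life 6.647 d) and an alpha emitter with a multi-alpha decay
series (Ac-225, half-life 9.92 d) — into an equal-tumor-dose prescription for
a tandem (simultaneous dual-isotope) therapy experiment, plus the
longitudinal tumor-burden and survival statistics used to compare the
treatment arms. Every stage is driven by a seeded synthetic-cohort generator
so the pipeline is testable end to end without animal data.

The dose model is deliberately minimal MIRD-style self-dose:

$$D = \tilde A \cdot \Delta / m$$

where $\tilde A$ is the cumulated activity in the tumor (time-integral of
activity, proportional to the number of disintegrations occurring there),
$\Delta$ the equilibrium dose constant (energy released per disintegration,
expressed in Gy·g/(µCi·h)), and $m$ the tumor mass. The absorbed fraction is
1 for the emissions counted into $\Delta$ and cross-dose from neighbouring
organs is ignored. Photon transport, S-value phantoms, microdosimetry and RBE
weighting are out of scope.

# Decay data and dose constants

The bundled emission table (`inst/extdata/decay_emissions.csv`) holds
ENSDF/ICRP-107-style mean energies and yields for Lu-177 (stable daughter
Hf-177) and the eight-member Ac-225 series, including the Bi-213 branch
point (97.84% beta branch through Po-213, 2.16% alpha branch through
Tl-209), truncated at Bi-209, which is treated as stable.

The `reference` emission filter defines $\Delta$ from locally deposited
radiation only: alphas plus beta-continuum *mean* energies, photons always
excluded (their absorbed fraction in a sub-gram tumor is essentially zero,
so counting them would be inconsistent with the absorbed-fraction-1
assumption for charged particles). Emissions with yield below 1% are
ignored; the cutoff is configurable. On this convention the bundled tables
give

```{r}
nuclide_dose_constant("177Lu")
nuclide_dose_constant("225Ac")
```

i.e. 2.863e-3 and 5.938e-1 Gy·g/(µCi·h). These match the conventional
printed pair (2.838e-3 and 5.934e-1) to +0.9% and +0.07%; the Lu-177 offset
is the difference between our ENSDF-style beta branch means (134.2 keV
total) and the 133.0 keV the printed constant back-calculates to. A
`charged_all` filter additionally counts conversion and Auger electrons and
therefore deviates from the reference pair by construction. Note the
physically forced assignment: the ~27.8 MeV/decay chain owns the large
constant and the 133 keV beta spectrum the small one; a source that lists
them in the opposite order is simply ordering the nuclides differently than
the values.

The chain constant weights every member's per-decay energy by its cumulative
branch probability (e.g. the Po-213 alpha by 0.9784). This is the secular
equilibrium assumption, justified quantitatively by the kinetics below.

# Branched Bateman kinetics and the 24-hour counting rule

`bateman_activities()` evaluates the closed-form solution of the linear
decay-chain equations for an initially pure parent, propagating
partial-fraction coefficients down the DAG. The implementation requires all
decay constants to be distinct (true here by ten orders of magnitude);
near-degenerate rates raise an error instead of returning an
ill-conditioned answer. Values with magnitude below 1e-9 (relative to unit
parent activity) are clipped to zero, and the $t = 0$ column is set to the
exact initial condition, because the closed form evaluates tiny activities
as differences of large coefficient products.

Ac-225 itself emits no usable gamma line for well counting; quantification
uses the 218 keV line of its granddaughter Fr-221 (window 170–260 keV), so a
counted sample must first re-establish equilibrium after the parent is
separated from its progeny at excision. `equilibrium_time()` reports when
each member's activity ratio to the parent stays within tolerance of its
asymptote: about 0.5 h for Fr-221, 5 h for Bi-213, and 23 h for Pb-209 at
1%. The slowest member therefore sets the 24 h delayed-counting rule, which
`quantify_samples()` enforces for Ac-225: earlier counts are kept but
flagged, never silently accepted.

The test suite checks the closed form against an independent fixed-step RK4
integration of the rate equations in which the two ultra-short-lived members
(At-217, 32.6 ms; Po-213, 3.7 µs) are slaved by quasi-steady-state — the
standard way to remove stiffness from a chain integrator. Agreement is
within 0.1% over 0–240 h; the residual is dominated by the oracle's QSS
hand-off lag at the earliest comparison time, not by the closed form.

# Biodistribution quantification

Percent injected activity is decay-corrected to the injection time, the
standard %IA convention (the alternative — correcting to euthanasia — is not
stated by the sources this design emulates; the choice is recorded and
applied consistently, including in the generator, so round trips are exact).
%IA/g uses the wet sample mass at collection. Group comparisons use Welch's
unequal-variance t statistic with Welch–Satterthwaite degrees of freedom on
per-cell summaries; per-comparison p-values are reported at α = 0.05 without
family-wise adjustment, mirroring the multiple-t-test convention, with an
optional Holm flag (off by default). Degenerate zero-variance groups follow
the documented convention p = 1 (equal means) / p = 0 (different means).

# Time–activity fitting and cumulated activity

Tumor TACs (group-mean %IA at 1, 4, 24, 48, 168 h) are fitted with
$A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}$ and its mono-exponential
special case, by multi-start nonlinear least squares: a log-spaced rate grid
spanning $[1/(10\,t_{max}),\ 10/t_{min}]$, amplitudes seeded by a clamped
linear solve, quasi-Newton refinement on log-parameters, and an `nls` port
polish. Fits are unweighted on the means by default (the emulated software's
options are unknown); 1/SD² weighting is available. Model choice is by
AICc, $n\ln(\mathrm{rss}/n) + 2k + 2k(k+1)/(n-k-1)$, with candidates whose
$n-k-1 \le 0$ excluded with a notice — at the 5-point design this correctly
refuses to score the 4-parameter model, so selection between mono and bi
requires more than 5 points.

Two numerical choices deserve emphasis:

* **Box bounds.** Unconstrained sum-of-exponential LS admits a degenerate
  "spike" optimum: an arbitrarily large amplitude on a rate faster than the
  first sampling time, fitting the first point only. Amplitudes are %IA, so
  the search is bounded at `max(100, 3 max(y))` and rates at the multi-start
  window; the spike (which implies >10⁴ %IA in the tumor at t = 0) is thereby
  excluded on physical grounds.
* **Identifiability.** Even bounded, the design {1, 4, 24, 48, 168} h
  identifies only $A_1 e^{-\lambda_1 t_1}$ for a genuinely fast component —
  the likelihood has a flat ridge in $(A_1, \lambda_1)$. Consequently
  asymptotic (Wald) standard errors on that ridge are meaningless, and the
  recovery tests use the estimator's Monte-Carlo sampling SE across seeded
  replicates instead. The integral that feeds dosimetry, $\tilde A$, is
  ridge-invariant for all practical purposes: its median relative error at
  the emulated design and noise is ~6%.

The fitted data are treated as decay-corrected, so the physical decay
constant is added back to each biological rate before integration:
$\tilde A = \sum_i A_i/(\lambda_i + \lambda_{phys})$ (infinite horizon by
default; a finite horizon is available). Non-positive effective rates make
the infinite integral diverge and are an error, never a silent zero.

# Dose, matching and the tandem prescription

`self_dose()` applies the dose equation with exact unit handling (37 kBq =
1 µCi; internal bookkeeping in Gy/kBq/h, µCi and cGy only at presentation).
`match_activity()` solves $A_{target} D_{target} = A_{ref} D_{ref}$ exactly,
and `tandem_prescription()` scales matched mono prescriptions by per-component
fractions (the emulated design halves both). Reported activities are rounded
to integer MBq (beta emitter) or integer kBq (alpha emitter) with halves
rounded *down* — that rule reproduces the published 35/2 → 17 MBq choice —
while raw values are retained for all arithmetic, so tandem dose remains the
exact fraction-weighted sum of mono doses.

# Efficacy analysis

Whole-body radiance is summarised per arm and week on the linear scale
(mean ± SD), masking weeks where fewer than 5 mice remain rather than
averaging a shrinking group. Per-mouse fold change is relative to the
treatment week. Cross-sectional arm comparisons use one-way ANOVA with
pooled-variance pairwise contrasts multiplied by the number of contrasts
(Bonferroni, clipped at 1); fold change is the default analysed quantity at
week 5 post-treatment, with raw radiance available by a switch. Survival
uses Kaplan–Meier curves and the Mantel–Cox log-rank test via the
`survival` package, with medians defined as the earliest time the estimated
curve reaches 0.5 (not-reached reported as `NA`), death times at 0.1-week
resolution, standard tie handling, and right-censoring at the analysis
cutoff.

# The synthetic cohort: what it does and does not emulate

The generator's defaults are the stated world of the emulated experiment:

* Biodistribution: 5 animals per time point at {1, 4, 24, 48, 168} h;
  bi-exponential organ kinetics whose slow components are anchored so the
  truth curves pass exactly through the printed setpoints — tumor 14.4
  (beta) / 14.1 (alpha) %IA/g at 4 h and 6.3 / 9.3 %IA/g at 168 h, kidney
  13.3 / 25.9 %IA/g at 1 h with identical late-time kinetics (no late
  difference). Fast components, the remaining organs (liver, submandibular
  salivary glands, intestines), organ masses (tumor 0.3 g ≈ 300 mm³) and
  per-organ proportional noise (tumor 25%, kidney 13%, others 20–30%,
  consistent with the printed SD/mean ratios) are field-typical choices
  fixed once. Noise is relative normal, truncated at zero (negligible bias
  at these levels). Injected activities: 30 MBq / 40 kBq.
* Trial: four arms (untreated, beta, alpha, tandem), 10 mice per arm,
  treated 3 or 5 weeks after inoculation. Each mouse's tumor burden grows
  exponentially from the treatment week; euthanasia triggers when burden
  crosses a threshold 10³ above baseline. Growth rates are calibrated in
  closed form so each arm's median survival equals the configured cohort
  medians (3-wk: 8.3/9.4/14.1/15.3 wk; 5-wk: 7.9/10.3/13.2/14.6 wk);
  lognormal inter-mouse heterogeneity on the growth rate (σ = 0.3, a free
  parameter not recoverable from printed summaries) is median-preserving.
  Observed radiance is burden times a per-mouse lognormal optical coupling
  (σ = 0.5). Death is triggered by *burden*, not observed radiance — with a
  lognormal intercept a radiance threshold would bias the calibrated
  medians; the optical factor then cancels in fold change, keeping BLI and
  survival internally consistent.

One global seed fans out to named substreams, so stages can be regenerated
independently and byte-identically.

What a green test therefore establishes: the analysis chain recovers the
quantities its own stated world defines (kinetic parameters within sampling
uncertainty, the configured alpha:beta dose-per-activity ratio within
Monte-Carlo tolerance, calibrated survival medians, nominal log-rank size).
What it does not establish: agreement with the published per-activity doses
(0.00758 / 65.03 cGy/kBq) or efficacy p-values, which depend on figure-only
fit parameters and the actual animal data — and whose printed ratio
(~8600) is internally inconsistent with the published "roughly 850 times"
and with the chosen activities (35000/40 = 875). The package records both
and adjudicates neither; within the synthetic world the analogous ratio is
~360, dominated by the ≈207× dose-constant ratio times tumor-retention and
half-life effects.

# Known limitations

* Self-dose only; no cross-organ dose, no lesion-size/pathlength modelling —
  the mechanistic reason alpha therapy outperforms on microscopic disease is
  outside the computation.
* The TAC model set is {mono, bi}-exponential (plus a variant with the slow
  rate pinned at the physical decay constant); no compartmental or
  mixed-effects kinetics.
* Counting windows are metadata, not simulated spectroscopy; detector
  efficiency and dead time are out of scope.
* The generator's inter-mouse heterogeneity and fast-component kinetics are
  free parameters of the stated world, not estimates.
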