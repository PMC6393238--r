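---
title: "Methods: dual-luciferase editing reporter screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-luciferase editing reporter screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscreen)
library(dplyr)
```

## The reporter and its readout

The assay couples A-to-I editing to bioluminescence. A reporter
transcript carries firefly luciferase (FFL) upstream of an editable
amber stop codon and nanoluciferase (Nluc) downstream, in frame. Every
transcript yields FFL; only transcripts edited at the stop codon read
through and yield an FFL–Nluc fusion. The per-well **Nluc/FFL ratio**
is therefore a cell-number- and expression-normalized editing readout:
a global attenuation of both channels (fewer cells, less substrate)
cancels from the ratio, which is what makes it robust for
single-concentration screening.

`editscreen` models the expectation of the two channels with four
parameters (`reporter_params()`):

| parameter   | meaning                                            | default | units |
|-------------|----------------------------------------------------|---------|-------|
| `beta`      | Nluc per-molecule brightness relative to FFL       | 150     | —     |
| `s`         | steady-state FFL–Nluc fusion level vs free FFL     | 0.01    | —     |
| `e0`        | baseline editing fraction of the cell line         | 0.39    | —     |
| `amplitude` | transcript/translation scale                       | 1e6     | RLU   |

With editing fraction $e$,

$$\mathrm{FFL} = A\,[(1-e) + s\,e], \qquad
  \mathrm{Nluc} = A\, e\, s\, \beta .$$

The *naive* arithmetic (`naive_ratio()`) ignores fusion instability and
FFL depletion: ratio $= \beta e$, i.e. 1.5 at 1% editing and 150 at
100% for $\beta = 150$. Measured ratios sit far below that line; the
mechanistic model attributes the gap to the fusion stability $s$. The
fusion protein is degraded much faster than free FFL, and $s = 0.01$
makes the defaults reproduce that qualitative observation (the
default negative-control ratio is ≈ 0.95 rather than ≈ 58). $s$ is a
free simulator parameter, not an estimate: no published measurement
pins it down, and none of the screening statistics depend on its exact
value because they are ratio- and control-normalized.

`e0 = 0.39` is the editing level of the high-editing HeLa reporter
clone used for screening, measured by Sanger peak heights; it sets the
simulator's negative-control operating point.

Compound action (`compound_effect()`) is one of five classes —
inactive, editing inhibitor, editing activator, Nluc enzyme inhibitor,
cytotoxic — all driven by a single Hill occupancy
$f(d) = m\, d^h / (d^h + \mathrm{IC50}^h)$. One potency/shape
parameterization keeps the generator minimal and matches how the
positive-control Nluc inhibitors behave (concentration-dependent Nluc
loss with untouched FFL; IC50 0.08 µM for the control inhibitor).
Editing inhibitors scale $e_0$ by $(1-f)$, activators move $e$ toward 1
symmetrically (activator hits are observed in such screens but their
mechanism is unknown, so symmetry is the minimal assumption), Nluc
enzyme inhibitors multiply only Nluc by $(1-f)$, cytotoxics multiply
both channels by $(1-f)$.

`editing_dose_curve()` supplies the saturating link
$e(x) = e_{\max}(1 - e^{-kx})$ between an ADAR expression surrogate and
editing. It is a self-consistent stand-in chosen so the simulated chain
reproduces the qualitative shape seen when the reporter is co-expressed
with increasing ADAR: ratio roughly linear in expression, editing
logarithmic in expression, ratio convex (exponential-like) in editing
percentage. It is not a fitted enzymological model.

## What the simulator emulates — and what it does not

`simulate_screen()` generates the full campaign: 384-well plates with
compounds in columns 1–22, 0.1% DMSO negative controls in column 23 and
10 µM Nluc-inhibitor positive controls in column 24; latent mechanisms
drawn from `library_spec()` proportions; log-uniform IC50s; expected
signals from the mechanistic model; and **multiplicative lognormal well
noise** per channel (mean 1, configured CV). Lognormal rather than
additive Gaussian noise keeps counts positive and CVs scale-free.

Numerical/default choices:

* **Noise CV 0.075 per channel.** Independent lognormal noise on the
  two channels gives a control-ratio CV of
  $\sqrt{e^{2\sigma^2}-1} \approx 0.106$ (with
  $\sigma^2 = \log(1+0.075^2)$), and a closed-form plate
  Z′ of $1 - 3\,\mathrm{cv}_r(\mu_n+\mu_p)/(\mu_n-\mu_p) \approx 0.68$ —
  the average plate quality reported for the campaign this package is
  calibrated to (0.67 ± 0.11). This was fixed at configuration time
  from that published operating point.
* **No plate gradients by default** (no significant plate effects were
  observed in the assay); `gradient_strength` adds a linear row/column
  gradient for robustness experiments.
* **Substrate decay** is a static per-channel factor
  $(1-\text{decay})^{t}$ (FFL half-life ≈ 1 h, Nluc stable). Being
  common to a channel it cancels from all ratio statistics; it exists
  so absolute counts are realistic, not to model read-time kinetics.
* **Mechanism mix** defaults (98% inactive, 0.8% editing inhibitors,
  0.2% activators, 0.5% Nluc enzyme inhibitors, 0.5% cytotoxic) are
  illustrative: they bracket a ~1% primary hit rate, but the true
  mechanism composition behind any real hit list is unobservable
  without counter-screens.

The simulator does **not** model cell growth, transfection efficiency,
interferon kinetics, compound fluorescence/quench interference, edge
evaporation, or correlated (plate-batch) noise. Passing tests on
simulated screens therefore demonstrate that the statistics are
implemented correctly and behave as designed under their stated noise
model — not that a real campaign will achieve the same recall.

## Screening statistics

All control summaries are per-plate means and sample SDs (matching the
μ/σ in the Z′ definition), and normalization is per plate, so results
from different plates and runs are comparable.

* `zprime(neg, pos)` implements
  $Z' = 1 - 3(\sigma_p + \sigma_n)/|\mu_p - \mu_n|$ on control ratios;
  plates pass at $Z' \ge 0.4$ by default (the assay's acceptable
  floor; well-run plates reach ≈ 0.7). Z′ is invariant under affine
  transforms of both control groups.
* `pct_inhibition(r, μ_n, μ_p) = 100(μ_n - r)/(μ_n - μ_p)`: 0% at the
  negative-control mean, 100% at the positive-control mean; values
  above μ_n are negative (activation), values below μ_p exceed 100%.
* `ffl_inhibition()` normalizes the FFL channel to the negative
  control only, because the positive control inhibits the Nluc enzyme
  without altering FFL.
* `call_hits()` applies, in order: the toxicity filter
  (FFL inhibition **strictly greater than** 40% — "higher than" is read
  literally), then the hit cut (**≥** 70%) and the activator cut
  (≤ −50%). The activator threshold is a package convention — roughly
  symmetric to the hit cut and configurable — since no published
  threshold exists for the activator side.
* No multiple-testing correction is applied anywhere: the procedure
  uses fixed thresholds on normalized effect sizes, not p-values.

Open details the source protocol does not settle — ≥ vs > at the hit
cut, means vs medians for control summaries, per-plate vs global FFL
normalization — are resolved as above and all configurable; a robust
(median/MAD) option was considered and left out of the default path to
keep the Z′ μ/σ semantics exact.

### The designed false-positive class, and a caveat on the FFL filter

Nluc enzyme inhibitors pass the ratio threshold and are
indistinguishable from editing inhibitors in the primary readout; only
a counter-screen against the luciferases separates them. The simulator
plants them deliberately and `ground_truth` labels let tests quantify
the confusion: on a noiseless screen the hit set is *exactly* the
editing inhibitors plus the Nluc enzyme inhibitors.

A second, less obvious confusion emerged from the mechanistic model:
**strong editing activators deplete free FFL**, because edited
transcripts produce the unstable fusion instead of free FFL. At
saturating activation with $s = 0.01$, FFL drops by ~97% and the
compound is removed by the 40% toxicity filter before it can be called
an activator. Moderate activation (occupancy ≲ 0.4 from an $e_0$ of
0.39) stays below the filter and is called correctly. Analysts using
an FFL-based toxicity filter should be aware it can discard genuine
strong activators.

## Confirmation and dose–response

`retest()` re-measures each primary hit at 2.5/5/10 µM against fresh
per-dose control sets (positive controls stay at 10 µM, as in the
bench protocol). A hit is `confirmed` when inhibition is monotone
non-decreasing with dose — with dips up to 10 percentage points
tolerated between adjacent doses as noise allowance — and reaches the
hit threshold at the top dose.

`fit_4pl()` fits
$y = b + (t - b)/(1 + (\mathrm{IC50}/d)^h)$ by Levenberg–Marquardt on
a $\log_{10}\mathrm{IC50}$ parameterization (starting values: asymptotes
from the data range, Hill 1, IC50 at the median log dose). The
`converged` flag is honest: optimizer failure, flat responses
(range < 1e-8 relative) and fitted IC50s more than two decades outside
the tested dose span all return `converged = FALSE` without an
exception. For three-dose confirmation data the full 4PL is not
identifiable, so `top`/`bottom` can be fixed (typically 100/0 on the
percent-inhibition scale), leaving a two-parameter fit.

## Sanger quantification

Editing percentage is `100 · G/(A+G)` on **peak heights** (not areas)
at the site, C and T ignored; the statistic is invariant to a common
scaling of all peaks. No baseline subtraction is applied — a
documented divergence risk against chromatogram viewers that
background-correct. Coordinates are 1-based throughout, the R
convention. `locate_site()` finds a unique anchor (≥ 10 nt, e.g. an
RT-PCR primer) on either strand, flipping the offset direction for
reverse-complement matches; zero or multiple matches are errors naming
the count. `offtarget_scan()` evaluates every reference-A within a
window of the primary site — ADARs frequently edit neighbouring
adenosines (e.g. a 12% site ~39 nt downstream of the primary site at
high ADAR levels) — suppressing calls below `min_pct` from the report
while counting them in the summary attributes. Binary trace files are
out of scope; the package consumes per-site peak-height CSVs
(`read_trace_csv()`), and `simulate_trace()` produces them with planted
dual peaks for testing (exact round trip at zero noise).

## Perturbation statistics

`fold_change()` compares treated vs control ratio values: fold = mean
ratio of means, significance by a two-sided Student's t-test (pooled
variance, matching the classical test's name; Welch via
`var_equal = FALSE`), stars at 0.01/0.001. Replicates are taken as
already normalized per replicate before averaging. The statistic is
scale-invariant.

## Problem sizes used in the test suite

The shipped tests run single- and two-plate screens (352–704
compounds) for unit checks, 60 simulated plates for the Z′ closed-form
comparison, 10 seeds × 352 compounds for planted-inhibitor recall,
20 seeds for IC50 recovery, and one full-scale 33 000-compound /
94-plate end-to-end campaign — sizes chosen so the whole suite
completes in well under a minute while keeping Monte-Carlo error small
relative to the asserted tolerances.

## Known limitations

* The reporter model is steady-state; no luciferase reaction kinetics
  or time-resolved reads.
* Fusion stability `s` and the editing–expression link are
  self-consistent stand-ins, not estimates; conclusions about absolute
  ratios (as opposed to control-normalized statistics) should not be
  drawn from the defaults.
* One well per compound: no intra-plate replicate handling in the
  primary pass (duplicated compounds are an error by design).
* No B-score or spatial-effect correction, no compound-structure
  analysis, no counter-screen deconvolution of the Nluc-inhibitor
  false-positive class.

```{r example}
scr <- simulate_screen(lib = library_spec(n_compounds = 704),
                       noise = noise_config(seed = 1))
res <- analyze_screen(scr$wells)
glance(res)
```
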