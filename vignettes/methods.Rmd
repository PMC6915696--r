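---
title: "Average polyQ length from antibody avidity bias: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Average polyQ length from antibody avidity bias: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyQavg)
```

## The measurement problem

Somatic CAG instability makes the expanded *HTT* allele a moving target: in
striatum or cortex the mutant protein is not one species but a distribution
of polyQ lengths. Bivalent polyQ-targeting detection antibodies produce more
signal per molecule the longer the tract (avidity bias), while a
non-polyQ-targeting antibody reports total protein only. The ratio of the
two channels therefore carries the *average* polyQ length of the
population, independent of protein amount — provided both channels are read
in their proportional (linear dynamic) range. This package implements that
chain end to end, together with the height-weighted average-CAG computation
used on the DNA side.

## Dose–response model and fitting

Each standard curve is a four-parameter logistic in concentration $x$:

$$y = \mathrm{Bottom} + \frac{x^{H}(\mathrm{Top}-\mathrm{Bottom})}{x^{H} + \mathrm{EC50}^{H}}$$

fitted by weighted least squares with $w_i = 1/y_i^2$ (observed signals),
the standard weighting for immunoassays whose noise is approximately
constant on the relative scale. Numerical choices in `fit_four_pl()`:

* **Parameterisation.** The optimiser works in
  $(\mathrm{Bottom}, \log(\mathrm{Top}-\mathrm{Bottom}), \log \mathrm{EC50},
  \log H)$, which enforces $\mathrm{Top} \ge \mathrm{Bottom}$,
  $\mathrm{EC50} > 0$, $H > 0$ without constrained optimisation.
* **Multi-start.** Levenberg–Marquardt iterations from a deterministic list
  of data-driven starts (Bottom = min signal, Top = max signal, EC50 = the
  concentration whose signal is nearest half-range, $H \in \{0.5, 1, 2\}$,
  plus EC50 bracketing at $\times 0.2$ and $\times 5$); the best weighted
  SSE wins, so fits are reproducible and ordering-invariant.
* **Guards.** Fewer than 5 distinct concentrations is an error, as is any
  non-positive signal under $1/y^2$ weighting (rejected, never clamped);
  non-convergence is flagged on the result rather than silently returned.
  Parameter SDs come from the weighted Gauss–Newton covariance.

## Linear dynamic range

Quantification assumes $y - \mathrm{Bottom} = x \cdot \mathrm{slope}$. The
window over which that holds is made operational in
`determine_linear_range()`: scanning windows of consecutive standards
(widest first, ties toward lower concentrations), a window is accepted when

1. the $1/y^2$-weighted through-origin fit (after subtracting the fitted
   Bottom) has uncentred $R^2 \ge 0.98$, and
2. every point back-calculates to within ±20% of its nominal concentration.

These are conventional immunoassay-validation accuracy criteria; they are a
documented reconstruction, chosen here to make "linear dynamic range"
testable, not a transcription of any instrument vendor's rule. The slope SD
comes from the weighted regression. Saturating standards fail criterion 2
and drop out; a fully saturated series raises a `no-linear-range` error
naming the failed criterion.

## The polyQ calibration and its inverse

Per-standard slope ratios (polyQ channel / total channel, SD by the
quadrature rule) are regressed on Q with four candidate families — linear
$a+bQ$, logarithmic $a+b\ln Q$, power $aQ^b$, exponential $ae^{bQ}$ — and
the highest-$R^2$ family wins, ties (within $10^{-9}$) broken toward the
simpler family in the order linear > logarithmic > power > exponential.
Two details are deliberate:

* **Fitting scale.** The curved families are seeded by log-linear OLS and
  refined by nonlinear least squares *on the ratio scale*, and $R^2$ is
  computed on the ratio scale for all four, so the selection compares like
  with like. (Selecting on log-scale $R^2$ would systematically favour the
  log-linearisable families.)
* **Direction.** The calibration is always fitted as ratio $= f(Q)$ and
  inverted analytically, never refitted with Q as the response; with
  replicate-level input the reported $R^2$ is at the level supplied.

`estimate_average_polyq()` inverts $f$ in closed form and propagates the
ratio SD by the delta method, $\sigma_Q = \sigma_r |dQ/dr|$; a Monte-Carlo
inversion mode exists for strongly nonlinear families at large relative
SDs. Estimates whose ratio falls outside the training ratio range are
returned with an `extrapolated` flag, never clipped — the calibration is
legitimately applied far beyond the standards (knock-in models run to
Q ≈ 140+), and the flag, not a hard wall, is the honest representation.

Both calibration routes the method admits are implemented in
`build_calibration()`: `slope_ratio` (ratios of linear-range slopes, the
standard-curve route) and `signal_ratio` (ratios of background-subtracted
replicate means at one matched load). They coincide in the proportional
regime. The signal-ratio route is the one to use for samples, which are
measured at a single matched total-protein load; it also avoids the
window-selection variability of the slope route, where noise can tip the
accepted window between adjacent widths and move the slope by several
percent.

## Mixtures, accuracy and precision

For a mixture with molar fractions $f_i$ of components $Q_i$, the
theoretical average is $\sum_i f_i Q_i$. If the calibration is linear in Q
and every species responds in its linear range, additivity gives exactly

$$\frac{\sum_i f_i c\, s_p(Q_i)}{c\, s_t} = f\!\left(\sum_i f_i Q_i\right),$$

so the estimator recovers the fraction-weighted mean with zero bias — the
package asserts this identity to $10^{-9}$ on synthetic mixtures. Accuracy
and precision are summarised as
$\%RE = 100\,|\hat Q - Q_{theo}|/Q_{theo}$ (absolute difference: deviations
in either direction count) and $Cv = 100\,\sigma/\mu$. The packaged
validation dataset (16 mixture conditions of Q25/Q38/Q48/Q55/Q72)
reproduces the reference %RE and Cv entries to the last printed digit,
with one exception: the avgQ58 row's published Cv (2.53) is internally
inconsistent with its own published mean and SD
($100 \times 1.51 / 60.94 = 2.48$); the package asserts the recomputed
arithmetic there. Fractions are treated as molar fractions throughout —
the convention under which signal additivity per molecule holds — and
theoretical averages are computed from the component fractions, not from
rounded row labels (e.g. the "45.5" recipe's fractions give 45.48), which
is required to reproduce the printed %RE values.

## Average CAG from peak traces

The six-step procedure per sample: (1) analyse each allele individually;
(2) within each allele group, drop peaks below 5% of that group's tallest
peak; (3) normalise surviving heights to sum to 1; (4–5) take the
height-weighted mean repeat length; (6) average the allele values. Two
under-specified points are resolved as follows and exposed as options:

* **Threshold scope.** The 5% threshold is applied per allele group
  (default), because alleles are analysed individually and wild-type peaks
  would otherwise be erased whenever the expanded allele amplifies more
  strongly; `threshold_scope = "global"` is available.
* **Allele splitting.** No rule is given for partitioning a trace; the
  default splits at the largest repeat-length gap (requiring ≥ 2 repeats),
  which is unambiguous in practice because wild-type and expanded alleles
  are far apart, with explicit `allele_windows` as the override. A
  contiguous cluster with no adequate gap raises an `ambiguous-split`
  error rather than guessing.

Fragment sizes in bases convert via
`repeat = round((size − flank_length)/3)` with a user-supplied flank
length; peaks landing on the same repeat after conversion merge by summing
heights. All outputs are invariant to rescaling heights.

## The synthetic-data generator

`simulation_config()` encodes the generative structure the validation rests
on: per-Q 4PL curves whose Top and EC50 depend on Q in the polyQ channel
but not in the total channel, shared Bottom and HillSlope, duplicate wells,
and multiplicative log-normal noise (mean exactly 1) of coefficient
`noise_cv`. Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `noise_cv` | 0.05 | a typical plate-immunoassay well CV |
| `q_standards` | 19–72 (8 levels) | the purified-standard panel span |
| `bottom` | 100 counts | small background relative to signal |
| `hillslope` | 1 | proportional low-dose regime; required for additive mixtures |
| polyQ `Top(Q)` | $500\,Q$ | strictly increasing, gives a linear ratio-vs-Q rule |
| total `Top` | 20000 | constant: total signal independent of Q |
| `EC50` | 500 pM (both) | matched channels; linear range ≲ 125 pM |
| ladder | 6.25–1600 pM | 2-fold dilutions spanning linear range to saturation |

The mixture generator implements linear-range additivity
(`signal = Bottom + Σ fᵢ·c·slope(Qᵢ)`, slope = (Top−Bottom)/EC50), which is
exact only at HillSlope = 1, so it refuses other Hill slopes; components
pushed beyond 0.25·EC50 (where the 4PL deviates > 20% from proportionality)
are recorded on the output. Peak traces draw molecules from a discretised
normal kernel centred at `modal_cag + expansion_bias`, truncated at
repeat ≥ 1, with an optional one-sided geometric tail for expansion skew;
the kernel is a modelling choice, since no reference trace data are
available to fit. Cohorts draw integer true average CAG values uniformly
(default 105–135, the expanded-allele range of an *Hdh*^Q140^-style
knock-in cohort), map polyQ length 1:1 to CAG repeat length, and generate
duplicate-well signals at a matched 100 pM load.

What the generator does **not** emulate: plate-position and batch effects,
heteroscedastic background, antibody cross-reactivity, matrix interference,
PCR stutter and preferential short-allele amplification, or the
full-length-vs-fragment HTT detection differences that prevent absolute
polyQ interpolation on endogenous protein. Passing tests therefore
demonstrate the *analysis chain* is correct under the stated generative
assumptions, not that real lysates meet those assumptions.

## Problem sizes and the precision envelope

The test suite runs its statistical checks at deliberately modest sizes:
8-standard panels with duplicate wells, 14-sample cohorts, 200-replicate
sampling-distribution checks, $10^6$-draw Monte-Carlo oracles and
1,000-trace brute-force comparisons — enough for the assertions' tolerances
while keeping a full run in seconds.

One calibration of the headline recovery property deserves record. With
duplicate wells, the propagated ratio Cv behaves like
$cv\sqrt{\chi^2_2/2}$: at a per-well CV of 5% its *expectation* is ≈ 4.4%
and roughly half of all samples exceed 4%, so a per-sample Cv ≤ 4% bound
cannot hold at that noise level by construction. The reference validation
tables' propagated Cvs (0.23–3.55%) imply per-well scatter near 2%, and
the end-to-end recovery property (every cohort sample within %RE ≤ 13 and
Cv ≤ 4) is accordingly exercised at `noise_cv = 0.02`, inside the stated
≤ 0.05 envelope and matching the precision the validation data actually
exhibit; the generator default stays at 5%.

## Known limitations

* The linear-range selection rule is a reconstruction; other defensible
  rules (e.g. LLOQ/ULOQ anchoring) would shift slope values slightly,
  though ratios are robust to shared-window choices.
* Delta-method SDs understate uncertainty for strongly curved families at
  large relative SDs; use the Monte-Carlo inversion mode there.
* Duplicate-based propagated SDs are themselves noisy (2 df): "within
  3 SD" checks against them have heavier-than-normal tails.
* The avgQ58 published Cv entry is asserted against recomputed arithmetic
  (see above), not the printed value.
* Average-CAG results depend on the 5% threshold convention when allele
  height scales differ strongly; the per-allele default is one documented
  choice, not the only one.
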