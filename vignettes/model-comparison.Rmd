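---
title: "Comparing dose-response models of ocular torsion and visual tilt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing dose-response models of ocular torsion and visual tilt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvsfit)
```

## The scientific question

Galvanic vestibular stimulation (GVS) — a direct current applied over the
mastoids — activates vestibular afferents and produces two measurable
responses: a static torsion of the eyes about the line of sight (toward the
anode) and a perceived tilt of the visual scene (away from the anode). If the
vestibulo-ocular reflex alone stabilised vision, visual tilt would simply be
the geometric consequence of ocular torsion, and the two responses would stay
proportional as the stimulation current grows. If instead torsion saturates
while tilt keeps rising, part of the tilt must arise from central processing
of the vestibular signal rather than from eye rotation.

`gvsfit` turns that question into a model comparison. For each measure
$T$ (degrees, unsigned) as a function of current $V$ (mA) it fits three
candidate forms:

* **lin** — free-intercept linear, $T = aV + b$. Biologically awkward: a
  non-zero $b$ implies the eye sits in two different orientations at zero
  stimulation, depending on the polarity from which zero is approached.
* **lin-prop** — directly proportional, $T = aV$: zero response at zero
  input, the form the reflex-only account predicts.
* **exp** — saturating exponential, $T = b\,(1 - e^{-V/a})$: initial slope
  $b/a$, response bounded by the asymptote $b$; the form a ceiling on ocular
  torsion predicts. Note the units of $a$ differ here (mA, a rate constant)
  from the linear families (deg/mA, a slope).

## Data

The packaged table (`zink1998_table()`) holds the published summary
statistics of Zink et al. (1998): per (intensity, polarity, measure) cell a
mean, standard deviation, range and subject count. Torsion was measured at
eight intensities (1–7 mA), tilt at four (1.5–3 mA); cells that were never
measured are absent rows. One visual-tilt measurement that the original
report attributes inconsistently (4.5 mA in its text, 3.5 mA in its figure,
absent from its table) is excluded from the fixture.

The fitting substrate is the *bilateral average*
(`average_bilateral()`): at every intensity carrying both stimulation arms,
the unsigned left- and right-anodal means are averaged arithmetically. All
magnitudes are stored unsigned; the direction conventions are metadata. The
series standard error shown in figures is a display convention only — each
arm contributes $sd/\sqrt{n}$ and the two arms are averaged — and never
enters the fit. Whether the original figures pooled their standard errors
the same way is unknown; nothing downstream depends on it.

## Fitting by full grid exploration

`gvs_fit()` minimises the unweighted residual sum of squares
$\mathrm{RSS}(a,b) = \sum_i \left(T_i - f(V_i; a, b)\right)^2$ over an
inclusive rectangular grid of nonnegative parameters. The defaults
(`default_grid()`) are the resolutions of the original analysis: $[0, 3.5]$
in steps of $0.0005$ per parameter for the linear families, $[0, 7]$ in
steps of $0.001$ for the exponential. Choices worth making explicit:

* **Unweighted, means only.** Neither cell sample sizes nor standard
  deviations weight the fit; reproducing the published slope of the
  proportional torsion model requires exactly this.
* **Grid endpoints are candidates.** Constrained optima may sit on a
  boundary, and two published estimates do: the tilt intercept pinned at
  $b = 0$ (the unconstrained OLS intercept is negative, $-1.025$°, so the
  nonnegative grid collapses onto the proportional solution) and the tilt
  asymptote at the grid maximum $b = 7$ (four low-intensity points cannot
  pin an asymptote).
* **The exponential grid skips $a = 0$.** The $a \to 0$ limit is
  discontinuous at $V = 0$ (it tends to $b$ for $V > 0$ but is $0$ at
  $V = 0$), so the rate grid effectively starts at its first positive step.
* **Ties.** Points whose RSS is within $10^{-12}$ of the minimum resolve to
  the lexicographically smallest $(a, b)$, for determinism across platforms.
* **Vectorised exact evaluation.** Both two-parameter families are linear in
  $b$, so $\mathrm{RSS}(a, b) = q_0(a) - 2b\,q_1(a) + b^2 q_2(a)$; the scan
  evaluates this expansion for every candidate pair in blocks along the $a$
  axis. This is the identical quantity a per-point loop would compute — the
  default exponential grid has about 49 million candidate pairs and
  completes in a few seconds — and the test suite cross-checks it against a
  literal brute-force scan on coarse grids.
* **Parameters stay on the grid** (`a = a_min + k·step`). One published
  estimate lands on a half-step grid point (the torsion intercept,
  $0.9125$), which prints as $0.913$ under half-up three-decimal rounding.

Model comparison uses the fraction of variance explained,
$R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ with TSS about the series mean, for
*every* family — including the through-origin ones, where other conventions
exist. This uniform convention is what the published percentages use; it can
be negative for fits worse than the series mean.

`ols_fit()` provides the closed-form unconstrained least-squares solutions
for the linear families. It exists as an independent oracle for the grid
search, not as an alternative fitter: its negative tilt intercept is what
*explains* the boundary solution above. One subtlety: because slope and
intercept estimates are correlated, the joint grid optimum need not lie
within one grid step of the unconstrained intercept (on the torsion series
it sits $1.7$ b-steps away); the correct invariants, which the tests assert,
are that the slope is within one step, the intercept within half a step of
its conditional optimum at the fitted slope, and that the grid point fits at
least as well as the rounded closed-form point.

## Relating tilt to torsion

At the three intensities where both measures were recorded (1.5, 2.0,
3.0 mA), the observed (torsion, tilt) pairs can be compared with three model
combinations evaluated on a common current sweep ($[0, 3]$ mA in steps of
0.01 — the sweep is a display choice): proportional–proportional
(**lin–lin**), exponential–exponential (**exp–exp**), and exponential
torsion with proportional tilt (**exp–lin**). No refitting occurs; the
curves simply replot the per-measure fits in the shared plane. Because no
printed metric ranks these combinations, the report operationalises their
fit as the summed squared Euclidean distance between curve and observed
pairs at the shared intensities; on the packaged data this ranks exp–lin
best and lin–lin worst — the pattern expected if torsion saturates while
tilt keeps growing, i.e. if vision is stabilised centrally once the reflex
runs out of range.

## The synthetic-study generator

`simulate_study()` emulates the design the analysis assumes: a chosen
generative curve, two stimulation arms, `n_per_cell` subjects per cell, and
additive between-subject Gaussian noise, with each per-subject draw clipped
by absolute value to keep the unsigned-magnitude convention. Its defaults
describe a torsion-like study — the eight published intensities, seven
subjects per cell, noise of 0.5° (a between-subject spread consistent with
the published cell standard deviations at moderate currents) — and an
optional polarity asymmetry splits the two arms by $\pm\mathrm{asym}/2$
around the curve, leaving the bilateral average unbiased. One stream is
seeded per table; replicate $r$ of an experiment uses `seed + r`, so every
simulation in the package is reproducible from one integer.

What the generator deliberately does **not** model: within-subject
measurement error (the source reports none), dropout at painful high
currents beyond letting `n_per_cell` vary by intensity, and any polarity
asymmetry in the real data. Passing recovery tests therefore show that the
*procedure* recovers parameters under the assumed noise structure, not that
the assumed structure is the true one.

`recovery_experiment()` runs the full pipeline — simulate, average the two
arms, grid-fit — over replicates and reports per-parameter bias, MAE and
RMSE. Under study-like conditions (exponential truth $a = 3.722$,
$b = 4.714$; torsion design; noise 0.5°; 200 replicates) both parameters are
recovered with mean absolute error under 10%; with a tilt-like four-point,
low-intensity design the asymptote's RMSE is several times larger — the
design-sensitivity result that explains why the tilt asymptote pins at the
grid bound.

## Numerical and testing choices

Simulation-heavy tests and the recovery experiments use a coarsened
exponential grid (step 0.005, about 2 million candidates per fit) — the
recovery tolerances are orders of magnitude wider than the grid resolution,
so nothing is lost; all reproduction checks of published estimates use the
full published grids. Degenerate inputs fail loudly: empty series, grids
with no candidates, constant series (undefined variance), exponential rate
zero. `run_reanalysis()` is pure (its input table is never mutated) and
deterministic given table and grids.

## Limitations

Only printed summary statistics exist; per-subject data cannot be
reconstructed, so the fits describe cell means and all uncertainty
statements come from simulation under an assumed noise model. The package
reports point estimates only — the original comparison is by variance
explained, and no AIC/BIC or likelihood-ratio machinery is attached. The
torsion–tilt combination ranking is an operationalisation of a verbal
claim, and is labelled as such in the report object.
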