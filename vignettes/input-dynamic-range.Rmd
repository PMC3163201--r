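---
title: "Negative auto-regulation and the input dynamic range of gene input functions"
author: "narange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative auto-regulation and the input dynamic range of gene input functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(narange)
```

## The question

A gene *input function* is the steady-state activity of a promoter as a
function of the concentration of its inducing signal.  Its *input dynamic
range* is the span of signal concentrations over which the output actually
changes: following the Goldbeter–Koshland convention, we quantify it as
the ratio

$$R = s_{90} / s_{10},$$

where $s_{10}$ and $s_{90}$ are the inputs at which the response reaches
10% and 90% of its maximum.  For a Hill curve
$f(s) = \beta s^n / (K^n + s^n)$ this ratio has the closed form
$R = 81^{1/n}$: a Michaelis–Menten response ($n = 1$) spans 81-fold in
input, a cooperative $n = 2$ response only 9-fold, $n = 4$ only 3-fold.
Cooperativity buys specificity and steepness at the price of a narrow
responsive range.

Negative auto-regulation (NAR) — a transcription factor repressing its own
promoter — is one of the most common motifs in bacterial transcription
networks.  In the arabinose utilization system of *E. coli*, the regulator
AraC represses its own promoter with its inducer-free form, while its
arabinose-bound form activates the catabolic operon *araBAD*.  Because
rising inducer concentrations relieve the auto-repression, the regulator
level itself climbs with the signal, and the downstream response is
stretched over a much wider input range than the cooperativity of the
promoter alone would allow.  This package implements the analysis chain
needed to measure and model that effect: reporter-kinetics simulation,
promoter-activity extraction, Hill fitting with dynamic-range statistics,
a steady-state NAR model with a parameter scan, and a mass-action model of
the dual activator/repressor regulator.

## The steady-state NAR model

The regulator $X$ binds its inducer $s$ with dissociation constant $K_s$;
the bound (active) form is $X^* = X s/(K_s + s)$ and the free form is
$X_f = X - X^*$.  The downstream promoter responds to $X^*$ with a Hill
occupancy of cooperativity $n$ and dissociation constant $K_z$.  Without
auto-regulation, $X$ is a constant $X_0$, and in the regime $K_z \ll X_0$
the composed response at $n = 2$ is a squared Michaelis–Menten function
with $R = 9$.

With auto-regulation, production of $X$ is repressed by $X_f$ with
dissociation constant $K_x$ and balanced by removal at rate $\alpha$:

$$\frac{\beta_x}{1 + X_f/K_x} = \alpha X .$$

Under strong self-repression ($K_x \ll X_f$) the balance has the
closed-form solution

$$X(s) = A\,\sqrt{1 + s/K_s}, \qquad A^2 = K_x \beta_x / \alpha ,$$

i.e. the regulator level grows as the *square root* of the signal.
Substituted into the downstream occupancy with $n = 2$ and $K_z \gg A$,
the composed input function becomes Michaelis–Menten-like in $s$ and spans
$R = 81$ — nine-fold wider than its constitutive counterpart, with the
halfway induction point at $s_{1/2} \approx (K_z/A)^2 K_s$.
`x_steady_closed_form()` implements the square-root law;
`x_steady_exact()` solves the full balance without the strong-binding
assumption, by bracketed bisection in log space (the left side is
nonincreasing and the right side increasing in $X$, so the positive root
is unique; brackets are $[10^{-12}\beta_x/\alpha,\;
\beta_x/\alpha\,(1+s/K_s)]$ and the default relative tolerance is
$10^{-10}$).

```{r model}
p <- nar_params(beta_x = 1e6, alpha = 1, K_x = 1e-6, K_s = 1,
                beta_z = 1, K_z = 100, n = 2)
dynamic_range_numeric(input_function_with_nar(p, "closed_form"))
dynamic_range_numeric(input_function_no_nar(
  nar_params(K_s = 1, beta_z = 1, K_z = 1, n = 2, X0 = 1000)))
```

### Numeric dynamic range

`dynamic_range_numeric()` normalizes by the curve's *supremum* — its
fitted or asymptotic maximum — rather than the largest sampled value.
This choice keeps $R$ well defined when the top plateau is only barely
reached within the measured range (as it is for the constitutive mutant,
whose 90% point sits near the highest usable arabinose concentration),
and it makes the numeric statistic agree with the analytic $81^{1/n}$ for
exact Hill curves.  Crossings are bracketed on a log grid and refined
with Brent's method on $\log_{10} s$ to a relative tolerance of
$10^{-8}$; the evaluation domain ($s/K_s \in [10^{-8}, 10^{12}]$ for
model curves) is extended adaptively, two decades at a time, when a
crossing falls outside it.  Monotonicity is checked on a 97-point log
grid; zero-concentration points are excluded from that check (the curves
are defined, and zero, at $s = 0$).

### The cooperativity scan

Only dimensionless combinations determine $R$: the signal enters in units
of $K_s$, and the regulator circuit through $K_z/A$ and $K_x/A$ (output
scales cancel in the normalization — asserted by the dimensional-
invariance tests).  `scan_max_dynamic_range()` therefore scans a
log-spaced grid (default $60 \times 60$ points over $[10^{-4}, 10^4]$ per
axis) of these two groups for each promoter cooperativity $n$, computing
$R$ for every composed curve.  For speed, each grid point's crossings are
first interpolated log-log on a dense 481-point response table (24 points
per decade, which locates crossings to about $10^{-3}$ relative); the top
five candidates per $n$ are then re-evaluated with the full bisection
machinery, and the best refined value is reported next to the analytic
no-NAR benchmark $81^{1/n}$.  With auto-regulation the attainable range
exceeds the benchmark at every cooperativity; at large $K_z/A$ and small
$K_x/A$, where the response saturates through the regulator's own ceiling
$\beta_x/\alpha$ rather than through promoter occupancy, it can exceed it
by orders of magnitude.

## Synthetic plate-reader experiments

No public raw plates exist for this system, so the generator reproduces
the *statistical structure* the analysis assumes, with every condition
fixed up front:

* **Design** — 12 arabinose levels: 0 plus half-log steps from 0.01 to
  1000 mM, covering the 10 µM–135 mM induction range reported for the
  system with margin on both sides; genotypes `parental_NAR`,
  `mutant_noNAR`, `promoterless`; 3 replicate wells per condition (a
  typical plate-assay choice; the source study does not state its
  replicate count); samples every 8 minutes for 20 h.
* **Growth** — logistic, $OD_0 = 0.005$ (a 1:600 inoculation),
  $OD_{max} = 0.5$, $r = 0.7\,h^{-1}$, so the 5–7 h analysis window lies
  in exponential phase (about 1–2 generations).  The growth curves of the
  original assay are shown but not parameterized in print; these values
  reproduce their qualitative shape.
* **Reporter** — GFP accumulates as $dG/dt = PA(c)\,OD(t)$ (trapezoidal
  integration on the sampling grid) plus an autofluorescence term
  $100 \cdot OD(t)$; GFP is treated as stable (the gfpmut2 variant used
  in such reporter libraries is long-lived), so no degradation term
  appears and dilution is implicit in the promoter-activity definition.
* **Noise** — multiplicative per-sample Gaussian noise, 3% on
  fluorescence and 2% on OD.  Each well draws from its own stream seeded
  by (experiment seed, genotype, concentration, replicate), so adding or
  removing wells never perturbs the remaining wells' data.

The mutant plate for the headline recovery runs is generated from a Hill
input function with $\beta = 1400$, $K = 42$ mM, $n = 1.9$ — the
published mutant fit values, with the plateau at 70% of the parental one
as reported for the constitutive strain.  The parental plate is generated
from the NAR model itself operating in its square-root regime
($n = 2$, $K_z/A = 100$, $K_s = 1.1\times10^{-4}$ mM), which places the
10–90% range at roughly 0.1–10 mM, where the wild-type response was
measured.

What the generator does **not** emulate: intrinsic (cell-to-cell)
expression noise, lag phases, evaporation and plate-edge effects, carbon-
source shifts, or transporter-mediated positive feedback on intracellular
arabinose.  Passing recovery tests therefore show that the analysis chain
is unbiased and correctly calibrated *for this error model*, not that
every real plate artifact is handled.

## Promoter-activity extraction

Promoter activity is the accumulation rate of reporter per cell density,
$PA = (dGFP/dt)/OD$.  The derivative is estimated as the ordinary
least-squares slope over a centered 5-sample sliding sub-window (40 min
at 8-min sampling) — robust to a few percent of measurement noise where
two-point differences are not — divided by the OD at the sub-window
center, and averaged over the 5–7 h window.  The curvature bias of the
windowed slope is $O((r\,\Delta t)^2)$, under 0.5% at the default
settings; the zero-noise round trip through simulate → subtract →
extract reproduces the generating input function to better than 2% at
every concentration, which is the tolerance the tests enforce.  Wells
whose OD never clears a $10^{-3}$ floor inside the window raise an error
rather than returning NaN.  Within-window drift of PA is visible in the
per-point series returned by `promoter_activity()`; it is reported, not
gated on.

Background: the GFP of promoterless control wells is averaged per time
point and subtracted from every reporter well (no per-well pairing rule
is published, so all background replicates are pooled).  Because the same
control mean is subtracted everywhere, its noise is a *plate-wide common
offset* on all activities; `extract_input_functions()` estimates the
standard deviation of that offset from the spread of the control wells'
own residual activities and hands it to the fit.

## Hill fitting and its error model

`fit_hill()` minimizes weighted squared error with Levenberg–Marquardt,
restarted from a grid of log-spaced $K$ and several $n$ values.  Three
parameters are fitted ($\beta$, $K$, $n$), matching the published
three-parameter induction fits; a basal-offset fourth parameter is
available behind a flag.  Zero-concentration points participate in the
fit (the Hill form is 0 there).

Weights derive from the per-concentration standard errors, but not
naively: replicate SEMs from three wells carry two degrees of freedom
each, and raw $1/\mathrm{se}^2$ weights make the fit chase whichever
point's error happened to be underestimated.  The fit therefore
stabilizes them with a two-component variance model
$\mathrm{se}^2 = a^2 + (c\,y)^2$ fitted across concentrations (additive
floor plus proportional part, the natural structure for
background-subtracted fluorimetry), floors the additive component at half
the lower-quartile variance, and undoes the small-sample bias of the
sample standard deviation (c4 correction).  In repeated-plate
simulations this variance-stabilized estimator has both a smaller spread
of $\hat n$ and far lighter tails than the raw-weight version.

Standard errors come from a seeded parametric bootstrap (default 200
resamples): activities are redrawn from the variance model around the
fitted curve, plus one shared offset per resample drawn at the estimated
background-subtraction scale, and the fit is repeated.  The tests verify
that the bootstrap standard error of $\hat n$ agrees with the true
across-plate spread over 100 simulated plates to within 30%.  The
dynamic range is reported twice, as the analytic $R = 81^{1/\hat n}$ with
a first-order propagated error
$\mathrm{se}_R = R \ln(81)\, \mathrm{se}_n / \hat n^2$, and as the
numeric $R$ of the fitted curve — the published parental value could have
been computed either way, so both are available.

## The dual activator/repressor model

The fuller mass-action picture treats the regulator as a *dual*
transcription factor: its inducer-bound form $X^*$ activates the target
promoter while its free form $X_f$ represses it (the DNA-looping mode of
AraC), on top of the auto-repression of its own promoter.  The target
occupancy used here is

$$\beta_z\,\frac{basal + (X^*/K_{act})^{n_{act}}}
  {1 + (X_f/K_{rep})^{n_{rep}} + (X^*/K_{act})^{n_{act}}},$$

the minimal independent-site equilibrium form with both arms and a basal
term; looped and unlooped promoter states are deliberately collapsed into
these Hill terms, and transporter feedback on intracellular arabinose is
outside scope (an effective $K_s$ absorbs it).  The regulator's own
promoter activity is $\beta_c/(1+X_f/K_c)$, which rises with inducer —
the auto-regulated regulator is itself induced, with an apparent
coefficient near one-half in the strong-binding regime (its shallow,
molar-scale response mirrors the published regulator-promoter curve).

This structure can express the full observed phenotype contrast.  With a
small $K_s$ and basal transcription relieved from looping repression,
the parental strain has $X_f \propto 1/\sqrt{s}$ (the square-root law)
and hence an apparent first-order response, while the constitutive
mutant — its regulator clamped at the induced parental level — has
$X_f \propto 1/s$ and responds with apparent cooperativity two, shifted
to higher concentrations because the clamped regulator supplies more
repressor at low signal.  That is exactly the direction of the measured
changes: disrupting NAR steepens the curve, raises $K$, and cuts $R$ by
an order of magnitude.

`fit_dual_model()` fits this model jointly to parental and mutant input
functions (optionally also the regulator-promoter curve) by weighted
least squares in log-activity space, so that each decade of a
four-decade dose-response contributes evenly.  Only dimensionless
combinations are identifiable from dose-response shapes, so the
concentration scale is fixed at $A = 1$, $\alpha = 1$; the mutant's
clamped level defaults to the parental steady state at the highest
plated concentration (the constitutive strain was engineered to match
the induced wild-type level); activities below $10^{-4}$ of each curve's
maximum are floored before taking logs; and optimization is Nelder–Mead
from multiple seeded starts.  Point estimates of individual constants
are not unique — several parameter combinations produce the same curves
— so the reported, tested quantities are the model-implied observables:
the halfway induction points and numeric dynamic ranges of both
genotypes.

## Problem sizes and numerical choices at a glance

* Default plate: 75 wells (12 concentrations × 2 genotypes × 3
  replicates + 3 background), 151 time points each.
* Recovery tests: 100 simulated mutant plates for the estimator-spread
  check; 10 plates × 200 bootstrap resamples for the calibration check.
* Scan: 60 × 60 dimensionless grid per cooperativity, dense-grid
  crossing interpolation with top-5 refinement.
* Root finding: vectorized log-space bisection, relative tolerance
  $10^{-10}$ (steady states) and $10^{-8}$ (crossings); occupancies are
  computed through logs so that $(X/K)^n$ terms cannot overflow at high
  cooperativity.
* Ties and degeneracies: zero growth rate and a carrying capacity equal
  to the inoculum are exact constants; `basal = 0` and `s = 0` give
  exactly zero target activity; degenerate (constant) input functions
  and non-monotone curves raise errors instead of returning values.

## Known limitations

* The error model is multiplicative Gaussian; real fluorimetry has
  additive read noise at the bottom of the dynamic range, which the
  two-component variance model absorbs only at the fitting stage.
* Bootstrap standard errors on the synthetic plates are tighter than
  typical published fit errors, because the generator omits biological
  between-day variability; the recovery tests therefore check point
  estimates against the published error bands, not the error bars
  themselves.
* The dual-regulator reconstruction is one minimal occupancy form
  consistent with a dual transcription factor; the original supplement's
  exact equations and best-fit constants are not reproduced, and only
  directional claims (which genotype is steeper, which $K$ is larger)
  are tested against it.
* The simple NAR scan covers the two dimensionless groups that determine
  $R$ in the simple model; the mass-action model's larger parameter
  space is explored only through the fit, not exhaustively scanned.
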