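# narange

Input dynamic range of negatively auto-regulated gene circuits, modelled
on the L-arabinose utilization system of *Escherichia coli*.

## What this package is for

The *input function* of a gene is its steady-state promoter activity as a
function of inducer concentration, and its *input dynamic range* is the
ratio

    R = s90 / s10

of the inputs at which the response reaches 90% and 10% of its maximum.
For a Hill input function `f(s) = β sⁿ/(Kⁿ + sⁿ)` this is exactly
`R = 81^(1/n)`: a hyperbolic response spans 81-fold in input, a
cooperative n = 2 response only 9-fold.

Negative auto-regulation (NAR) — a transcription factor repressing its
own promoter, as AraC does in the arabinose system — couples the
regulator level to its own inducer.  In the strong-self-repression limit
the steady-state regulator level follows a square-root law,

    X(s) = A √(1 + s/Ks),   A² = Kx βx / α,

which halves the effective steepness of the downstream response and
widens its input range (at promoter cooperativity n = 2, from R = 9 for
a constitutive regulator to R = 81 with NAR).  The package is for people
studying gene-circuit dose-responses from plate-reader reporter
kinetics: it provides

* a seeded synthetic plate generator (logistic growth, GFP accumulation
  proportional to promoter activity × OD, autofluorescence background,
  multiplicative measurement noise) emulating a parental/NAR,
  constitutive-mutant and promoterless-background design;
* promoter-activity extraction, `PA = (dGFP/dt)/OD`, with background
  subtraction and a 5–7 h exponential-phase averaging window;
* Hill fitting with a stabilized variance model, seeded parametric
  bootstrap errors, and both analytic (`81^(1/n)`) and numeric
  (bisection on the fitted curve) dynamic ranges;
* the steady-state NAR model with exact and closed-form regulator
  solvers, and a scan of the maximal attainable R over the model's
  dimensionless parameter groups for cooperativities n = 1…5;
* a mass-action model of a dual activator/repressor transcription factor
  (activating arm driven by inducer-bound regulator, repressing arm by
  the free regulator) fitted jointly to parental and mutant input
  functions;
* an end-to-end pipeline with YAML configs, deterministic per seed, plus
  a thin command-line wrapper (`inst/scripts/narange.R`).

## Worked example

Simulate the reference experiment — a parental plate generated from the
NAR model in its square-root regime and a mutant plate from a Hill input
function with n = 1.9, K = 42 mM — then extract activities, fit, and
compare:

```r
library(narange)
report <- run_pipeline(default_run_config(seed = 42))
print(report)
#> narange pipeline report (seed 42)
#>
#> Fitted input functions:
#>      genotype beta K_mM     n     R R_numeric se_beta se_K_mM    se_n  se_R
#>  parental_NAR 2008  1.1 0.992 83.79     83.79    12.0  0.0221 0.00898 3.359
#>  mutant_noNAR 1402 41.9 1.912  9.96      9.96    17.4  1.0309 0.04023 0.482
#>
#> Parental vs mutant comparison:
#>  n_parental n_mutant K_parental_mM K_mutant_mM R_parental R_mutant
#>       0.992     1.91           1.1        41.9       83.8     9.96
#>  R_fold_change se_R_fold_change
#>           8.41            0.529
```

Reading the output: the auto-regulated (parental) input function is
hyperbolic (apparent Hill coefficient ≈ 1) with halfway induction near
1 mM and an input dynamic range of ~84-fold; the constitutive mutant is
steep (n ≈ 1.9), shifted to K ≈ 42 mM, and spans only ~10-fold —
disrupting auto-regulation narrows the responsive input range by almost
an order of magnitude (fold-change row).

The model pieces are available directly:

```r
dynamic_range_analytic(c(1, 2, 4))
#> [1] 81  9  3

p <- nar_params(K_s = 1, beta_z = 1, K_z = 100, n = 2)   # K_z/A = 100
dynamic_range_numeric(input_function_with_nar(p, "closed_form"))
#> Input dynamic range R = 80.93 (s10 = 1112, s90 = 9e+04, max = 1)

scan_max_dynamic_range(n_grid = c(1, 2, 4), resolution = 30)
#>   n R_no_nar R_max_nar      kz_A      kx_A n_skipped
#> 1 1       81 6092.9302   62.1017 0.0001000         0
#> 2 2        9  127.3481 5298.3169 0.0001000         0
#> 3 4        3   50.5057 10000.000 0.0023950         0
```

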