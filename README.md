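# loewe

Null reference models for two-compound dose–response surfaces under
Loewe Additivity.

## What it is for

Checkerboard drug-combination screens call a compound pair synergistic
or antagonistic by comparing the measured response matrix to the
surface expected *without* interaction.  Under Loewe Additivity that
surface is extrapolated from the two single-compound (conditional)
Hill curves

    f(x) = y_inf + (y0 - y_inf) / (1 + (x/e)^s),

and there is more than one way to do the extrapolation:

* the classical **General Isobole equation** (implicit — the response
  `y` at `(x1, x2)` solves `x1/f1⁻¹(y) + x2/f2⁻¹(y) = 1`, one root
  find per cell),
* the **explicit substitution surfaces**
  `f_2→1(x1,x2) = f1(x1 + f1⁻¹(f2(x2)))` and
  `f_1→2(x1,x2) = f2(f2⁻¹(f1(x1)) + x2)` (closed form, asymmetric),
* and their symmetric **explicit mean**
  `f_mean = (f_2→1 + f_1→2)/2` (with a geometric-mean variant).

These agree exactly when the two Hill curves differ only in their
half-effect dose `e` — the *Loewe Additivity Consistency Condition*
(equivalently: a dose and its effect-equivalent are proportional).
Real conditional curves routinely violate it through unequal slopes or
unequal maximal effects, the models then disagree, and the package
provides the diagnostics (`check_lacc`, `population_lacc_test`) and
the bias/MSE comparison machinery (`evaluate_record`,
`compare_models`) to decide which surface describes data better —
plus constrained shared-`y0` Hill fitting, isobole extraction, unequal
maximal-effect fallbacks, a synthetic checkerboard generator, and a
small CLI (`inst/cli/loewe.R`).

For users of drc-style dose–response tooling: this package fits the
conditional curves itself (Levenberg–Marquardt, deterministic
multistart) so that the two curves can share the zero-dose response.

## Worked example

```r
library(loewe)

## a consistent pair: same y0, y_inf, slope; EC50s 1 and 2
pair <- curve_pair(hill_curve(y0 = 1, y_inf = 0, e = 1, s = 2),
                   hill_curve(y0 = 1, y_inf = 0, e = 2, s = 2))
check_lacc(pair)
#> LACC report: proportional = TRUE, c_hat = 0.5, max asymmetry = 2.22e-16
general_isobole(pair, 1, 2)   # implicit model at (x1 = 1, x2 = 2)
#> [1] 0.2
explicit_mean(pair, 1, 2)     # identical here: the condition holds
#> [1] 0.2

## a violating pair: different slopes and maximal effects
pv <- curve_pair(hill_curve(1, 0.3, 1, 1), hill_curve(1, 0, 1, 2))
check_lacc(pv)
#> LACC report: proportional = FALSE, c_hat = 1, max asymmetry = 0.218
general_isobole(pv, 1, 2); explicit_mean(pv, 1, 2)
#> [1] 0.2
#> [1] 0.1590064

## which model explains noisy checkerboards generated from the mean truth?
recs <- simulate_population(20, scenario = "both", truth_kind = "mean",
                            noise_sd = 0.02, seed = 11)
compare_models(recs, models = c("gi", "mean"))
#> Model comparison gi vs mean on 20 records (0 dropped)
#>   median mse: gi = 0.001053, mean = 0.0004281
#>   paired Wilcoxon (mse gi 'greater'): p = 4.78e-05

bench_models(pv, linear8_design(4, 4), reps = 100)
#> Benchmark (100 reps, 64 grid points): implicit GI 0.0075 s,
#>   explicit mean 0.000235 s, ratio 31.9
```

Reading the output: `c_hat` is the estimated proportionality constant
`e1/e2` (dimensionless only when both axes share a unit);
`max asymmetry` is the largest disagreement between the two
substitution orders over the evaluation grid, in response units — zero
means the two compounds are exchangeable.  In the comparison, the
paired one-sided Wilcoxon p-value says the implicit model's per-record
mean squared errors are systematically larger than the explicit
mean's, as expected when the explicit mean generated the data; the
benchmark shows why one might care — the closed-form surface is about
an order of magnitude and a half cheaper per grid evaluation.

See `vignettes/loewe-null-models.Rmd` for the model derivations,
fallback rules for unequal maximal effects, and all numerical choices.

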