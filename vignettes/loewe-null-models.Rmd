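---
title: "Implicit and explicit Loewe Additivity null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Implicit and explicit Loewe Additivity null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loewe)
```

## The problem

High-throughput checkerboard screens measure the response of a cell line
(viability, growth) to all combinations of two compounds over a dose
grid.  Synergy and antagonism are defined as deviation from a *null
reference surface*: the response expected if the compounds do not
interact.  Everything therefore hinges on how that surface is
extrapolated from the two single-compound (*conditional*) dose-response
curves — the first row and column of the checkerboard.

This package works with the Loewe Additivity principle, whose core idea
is dose equivalence: if dose $x_1^*$ of compound 1 and dose $x_2^*$ of
compound 2 produce the same response on their own, the two doses are
exchangeable, and in the absence of interaction every combination on the
straight line between $(x_1^*, 0)$ and $(0, x_2^*)$ produces that same
response.

## Models

Conditional curves are modeled as four-parameter log-logistic (Hill)
curves

$$f(x) = y_\infty + \frac{y_0 - y_\infty}{1 + (x/e)^s},$$

with zero-dose response $y_0$, asymptotic response $y_\infty$
(the maximal effect), half-effect dose $e$ (in the record's
concentration units), and slope $s > 0$; the orientation is inhibitory
($y_0 > y_\infty$, response decreases with dose).  The curve has the
closed-form inverse $f^{-1}(y) = e\,((y_0-y)/(y-y_\infty))^{1/s}$.

Four null models are built on a fitted pair $(f_1, f_2)$:

* **General Isobole (GI)** — the classical implicit model:
  $f_{GI}(x_1, x_2)$ is the response $y$ solving
  $x_1 / f_1^{-1}(y) + x_2 / f_2^{-1}(y) = 1$.  Its isoboles (contours
  of constant response) are straight by construction, but every
  evaluation needs a numerical root find.
* **Explicit substitution surfaces** — replace one compound's dose by
  its *effect-equivalent* dose of the other,
  $x_1^{equiv}(x_2) = f_1^{-1}(f_2(x_2))$:
  $$f_{2\to1}(x_1,x_2) = f_1(x_1 + f_1^{-1}(f_2(x_2))), \qquad
    f_{1\to2}(x_1,x_2) = f_2(f_2^{-1}(f_1(x_1)) + x_2).$$
  These are closed-form but asymmetric: the two substitution orders
  need not agree.
* **Explicit mean** — their arithmetic average, which restores symmetry
  and, among weighted combinations, stays closest to the implicit
  surface under mild violations of consistency.  A geometric-mean
  variant is available (`variant = "geometric"`); responses are floored
  at 0 before the product so the root is always defined.

## The consistency condition

Requiring the two substitution orders to agree everywhere
($f_{2\to1} = f_{1\to2}$ for all doses) is the *Loewe Additivity
Consistency Condition*.  It holds exactly when a dose and its
equivalent are proportional, $f_1^{-1}(f_2(x_2)) = c\,x_2$ — i.e. the
two conditional curves are horizontal shifts of each other on the
log-dose axis.  For Hill curves this means: equal $y_0$, equal
$y_\infty$, equal $s$; only $e$ may differ, and then $c = e_1/e_2$.
When the condition holds all four models coincide and the isoboles are
parallel straight lines; when it fails (different slopes or different
maximal effects, which is common in real screens) the models genuinely
disagree and "Loewe Additivity" is ambiguous.

`check_lacc()` tests the Hill-specific parameter criterion (relative
tolerance `1e-6`; the condition is mathematically exact, the tolerance
only absorbs floating point) and measures the surface asymmetry
$\max |f_{2\to1} - f_{1\to2}|$ on a dose grid — a finite surrogate for
the "for all doses" quantifier; the default grid is $20 \times 20$ over
$[0, 4e]$ per axis, and callers can pass the record's own design or a
denser grid.  The package verifies the proportionality theorem
numerically (both directions) in its test suite rather than
symbolically.

`population_lacc_test()` lifts the question to a set of fitted records:
paired Wilcoxon signed-rank tests on the per-record slope pairs and
asymptote pairs.  Sidedness is two-sided by default here (the question
is "different at all?"), while the model-comparison test below defaults
to one-sided, each overridable.  All-zero difference sets return p = 1
and are flagged degenerate rather than erroring.

### Unequal maximal effects

If compound 2 can push the response below compound 1's asymptote, doses
in that range have no equivalent and the defining expressions break
down.  The package adopts the standard fallback: for the implicit
model, the unreachable compound's term is dropped, so
$f_{GI} = f_2(x_2)$ whenever $f_2(x_2) \le y_{\infty,1}$ (mirrored for
the other side; ties within the solver tolerance are routed to the
fallback to avoid an unbounded inverse).  For the explicit surfaces the
same reasoning gives $f_{2\to1} = f_2(x_2)$ while $f_{1\to2}$ keeps its
original definition, so the explicit mean genuinely differs from the
implicit model in this regime — the two models extrapolate
incompatible answers, which is precisely why their fit to data is worth
comparing.

## Numerical choices

* **Implicit solve.**  $g(y) = x_1/f_1^{-1}(y) + x_2/f_2^{-1}(y) - 1$
  is strictly increasing in $y$ on
  $(\max(y_{\infty,1}, y_{\infty,2}),\; y_0)$, so each combination cell
  is solved by bracketed bisection on that interval (relative bracket
  padding `1e-12` keeps the inverses finite), to an absolute response
  tolerance `y_tol = 1e-9` with an iteration cap of 200.  Bisection is
  chosen over derivative-based methods because $g'$ is unbounded near
  the bracket ends.  The solve is per cell — the implicit model has no
  closed form, and a failed cell reports its own bracket and dose
  combination.  Axis cells ($x_1 = 0$ or $x_2 = 0$) return the
  conditional response exactly rather than through the solver.
* **Fitting.**  `fit_pair()` fits both conditional series jointly with
  a shared $y_0$ (both curves describe the same untreated wells): seven
  free parameters, unweighted least squares via Levenberg-Marquardt,
  with $e$ optimized as $\log_{10} e$ for conditioning.  Starting
  values are a deterministic multistart: slopes from
  $\{0.5, 1, 2, 4\}$ (shared by both curves per start) with
  data-driven $y_0$, $y_\infty$ and $e$ starts; best final SSR wins,
  ties to the earlier start.  A full outer product of $e$- and
  $s$-starts across both curves was rejected as combinatorial overkill:
  the data-driven $e$ start (dose nearest the half-way response) is
  reliable on any design that brackets the EC50.  Fits with
  non-positive slope or EC50 are excluded — on fixed-range screens many
  compounds show no response over the tested range and their fitted
  curves are meaningless — while other pathologies (e.g.
  $y_\infty \ge y_0$) are only flagged, since exclusion rules beyond
  slope and EC50 are not part of the screening convention this follows.
* **Isobole extraction.**  Contours are extracted by marching squares
  (linear interpolation on grid cells) from a surface matrix.  Grid
  density is the caller's concern; there is no adaptive refinement.
  One caveat worth knowing: at a response level where the two
  conditional curves cross ($f_1^{-1}(y) = f_2^{-1}(y)$, e.g. the
  half-effect level when $e_1 = e_2$) the contour can run diagonally
  through grid nodes whose solved values equal the level within solver
  noise; the extracted polyline then wiggles at noise level no matter
  how fine the grid.  Choose levels away from the crossing response
  when measuring straightness.
* **Timing.**  `bench_models()` compares the per-evaluation cost of the
  implicit and explicit mean surfaces.  A single explicit grid
  evaluation is faster than the wall-clock resolution, so each
  measurement times a calibrated block of evaluations (at least 20 ms)
  and divides back; medians over the requested repetitions are
  reported.  The ratio is hardware- and grid-dependent and is reported
  for orientation only.

## The synthetic generator

`make_pair()` reproduces the canonical illustration parameter sets in
fixture mode — the consistent pair ($y_0 = 1$, $y_\infty = 0$, $s = 2$,
$e_1 = 1$, $e_2 = 2$) and the three violation scenarios built from
$s_1 = 1$ vs $s_2 = 2$ and/or $y_{\infty,1} = 0.3$ vs
$y_{\infty,2} = 0$ — and in randomized mode draws $e$ log-uniform on
$[0.25, 4]$, $s$ uniform on $[0.5, 4]$ and $y_\infty$ uniform on
$[0, 0.4]$, enforcing each scenario's equalities by shared draws and
its inequalities by rejection sampling with margins (0.2 in $s$, 0.1 in
$y_\infty$) so that "violated" never means "violated by an
undetectable hair".

`simulate_record()` evaluates a chosen truth surface on a design grid
and adds i.i.d. homoscedastic Gaussian noise — the simplest model that
supports the bias/MSE machinery; responses are deliberately not clipped
to $[0,1]$, matching raw viability readouts.  Two standard layouts are
built in: the 6-dose 4-fold-dilution series (top dose, four 4-fold
dilutions, zero) of one-to-all 6×6 viability screens, and the 8-dose
linear series of 8×8 factorial growth screens.  `simulate_population()`
defaults to the linear design with per-axis top dose $4e$, emulating
screens that dose-range each compound around its own potency; per-record
seeds derive from the master seed by a fixed affine rule, so populations
are reproducible as a whole and record by record.  Default noise is
$\sigma = 0.02$ response units — a few percent of the dynamic range,
typical of replicate scatter in viability screens.

What the generator does *not* emulate: plate and edge effects,
heteroscedastic noise (variance growing toward mid-response),
interaction effects (no synergy/antagonism terms), and non-Hill
conditional shapes.  Passing tests on this generator therefore
demonstrate correctness of the machinery and identifiability under the
stated noise model, not robustness to real-plate artifacts.

## Model evaluation

`evaluate_record()` summarizes the residuals
$\hat y_i - y_i$ (predicted minus observed) of one model on one record
as $bias = \frac1N \sum_i (\hat y_i - y_i)$ and
$mse = \frac1N \sum_i (\hat y_i - y_i)^2$; all measured cells including
the conditionals enter by default (`combination_only` flips that).  An
optional, off-by-default outlier rule excludes cells beyond a MAD
multiple of the record's own residuals — this package's choice of
robustness device for real screens, not needed on synthetic data.
`compare_models()` runs the full pipeline — fit, build both surfaces,
evaluate, and a paired Wilcoxon signed-rank test on the per-record mse
values, one-sided by default with the alternative "the first model's
errors are greater".

```{r example}
set.seed(1)
recs <- simulate_population(20, scenario = "both", truth_kind = "mean",
                            noise_sd = 0.02, seed = 11)
cmp <- compare_models(recs, models = c("gi", "mean"))
cmp
```

Because the generating surface here is the explicit mean and every pair
violates the consistency condition, the implicit model's mse is
systematically larger — the paired test picks this up even at 20
records.  Simulating from the implicit truth reverses the verdict,
which is exactly the identifiability property the test suite checks at
scale (20 seeded 50-record batches).  The suite also calibrates the
population consistency test under an equal-slope truth (empirical
type-I rate at nominal 0.05 over 200 seeded repeats) — problem sizes
chosen to make the checks statistically meaningful while keeping the
whole suite comfortably runnable on a laptop.

## Limitations

* The proportionality shortcut in `check_lacc()` is Hill-specific; the
  asymmetry grid works for any monotone curve family, but no other
  family is implemented.
* The implicit solver's fallback tie-handling (`y_tol` band around the
  asymptote) means responses within solver tolerance of an asymptote
  are attributed to the driving compound.
* Bias/MSE compare surfaces to measurements pointwise; no spatial
  correlation across the plate is modeled, and outlier exclusion is a
  heuristic, not an inference.
* Weighted combinations of the two substitution surfaces other than
  the fixed arithmetic/geometric means are not exposed.
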