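# subimpute

Subdistribution-weight censoring imputation for discrete-time
competing-risks survival data.

## The problem

Many survival learners — in particular the deep discrete-time
architectures built for a *single* event of interest — cannot handle
competing risks. Simply treating competing events as censoring biases the
Kaplan–Meier complement upward as an estimate of the type-1 cumulative
incidence function (CIF)
F<sub>1</sub>(t|x) = P(T ≤ t, ε = 1 | x):
an individual who died of another cause is not "still at risk" in the way
independent censoring assumes.

`subimpute` converts a discrete competing-risks dataset
(T̃<sub>i</sub>, Δ<sub>i</sub>ε<sub>i</sub>, x<sub>i</sub>) on a grid of
k intervals into a *single-event* dataset that any discrete-time survival
learner can consume while still estimating the type-1 CIF without bias.
Following the Fine–Gray subdistribution view, an individual with a
competing event at T̃<sub>i</sub> has subdistribution time
ϑ<sub>i</sub> = ∞ and should remain in the type-1 risk set until censored
— but that censoring time was never observed. The package imputes it:

1. Estimate the censoring survival function G(t) = P(C > t) with a
   nonparametric life table (reverse-Kaplan–Meier tie rule: events within
   an interval precede censoring).
2. Form the subdistribution weights
   w<sub>it</sub> = Ĝ(t−1) / Ĝ(T̃<sub>i</sub>−1) for t > T̃<sub>i</sub>
   (w<sub>it</sub> = 1 for t ≤ T̃<sub>i</sub>) — the probability that
   individual *i* is still in the type-1 risk set at t, given membership
   at T̃<sub>i</sub>.
3. Sample an imputed censoring time Ĉ<sub>i</sub> from the discrete
   distribution induced by the weight decrements, i.e. the estimated
   conditional law of C given C ≥ T̃<sub>i</sub>, truncated at k−1. The
   record becomes (Ĉ<sub>i</sub>, event = 0, x<sub>i</sub>); records with
   Δ<sub>i</sub>ε<sub>i</sub> ∈ {0, 1} pass through unchanged.

The construction satisfies P(Ĉ<sub>i</sub> ≥ t) = w<sub>it</sub> exactly,
so the Kaplan–Meier complement computed from the imputed single-event data
reproduces the Aalen–Johansen type-1 CIF of the original competing-risks
data (to sup-norm a few 10⁻³ at n = 30,000 in the package's validation
suite).

The package also ships:

* `crsim()` — a simulator for discrete competing-risks data from a
  discretized subdistribution hazard model
  F<sub>1</sub>(t|x) = 1 − (1 − q + q·e<sup>−t</sup>)^exp(x'γ₁), with
  exponential competing times, empirical-quantile discretization into
  k = 20 intervals, and censoring P(C = t) = b^(k+1−t) / Σ b^i;
* `fit_hazard()` — a reference discrete-time logistic hazard learner with
  per-interval intercepts, an optional one-hidden-layer variant, the
  two-term loss (1−α)L<sub>l</sub> + αL<sub>z</sub>, and validation-based
  early stopping;
* `aalen_johansen()`, `km_complement()`, `calibration_curves()`,
  `cindex_ipcw()` — evaluation: nonparametric CIF references, calibration
  gaps, and the competing-risks IPCW concordance index
  C₁(t) = P(M(t,x<sub>i</sub>) > M(t,x<sub>j</sub>) | ε<sub>i</sub>=1,
  T<sub>i</sub> ≤ t, (T<sub>i</sub> < T<sub>j</sub> or ε<sub>j</sub>=2));
* `run_experiment()` / `compare_modes()` — the full
  simulate → split → preprocess → fit → evaluate protocol with R
  repetitions and paired imputed-versus-naive reporting.

## Worked example

```r
library(subimpute)

d <- crsim(n = 30000, q = 0.2, b = 1, k = 20, seed = 42)
d
#> Discrete competing-risks dataset: n = 30000 , k = 20 , J = 2 , p = 4
#>   status counts: 0=14138, 1=3491, 2=12371

sp <- stratified_split(d, seed = 1)              # 1/2, 1/6, 1/3
se <- impute_dataset(sp$train, seed = 2)         # single-event training data
se
#> Single-event discrete survival dataset: n = 14999 , k = 20 , p = 4
#>   events: 1745  censored: 13254

fit <- fit_hazard(se, impute_dataset(sp$validation, seed = 3), seed = 4)
cif <- predict_cif(fit, sp$test$x)               # 10000 x 20 matrix
aj  <- aalen_johansen(sp$test, 1)                # nonparametric reference

calibration_gap(cif, aj)
#> [1] 0.0099
mean_cindex(cindex_curve(sp$test, cif))
#> [1] 0.6546
```

The calibration gap is the sup-norm distance between the test-averaged
predicted CIF and the Aalen–Johansen curve: 0.0099 means the model's
average cumulative incidence tracks the nonparametric truth to within one
percentage point. Fitting the same learner on naively censored data
(`naive_censor(sp$train)`) yields a gap of 0.1978 — a twenty-fold
mis-calibration — while the imputed preprocessing also attains a mean
time-averaged C-index of 0.65. The paired protocol is one call:

```r
cm <- compare_modes(experiment_config(q = 0.2, R = 10, seed = 5))
cm
#> Imputed vs naive preprocessing (q = 0.2)
#>   gap  imputed 0.0077 | naive 0.1849 | imputed better in 10/10 reps
```

## CLI

A thin command-line front end wraps the exported functions:

```sh
Rscript inst/cli/subimpute.R simulate --n 30000 --q 0.2 --seed 1 --output sim.csv
Rscript inst/cli/subimpute.R impute --input sim.csv --output imputed.csv --seed 2
Rscript inst/cli/subimpute.R impute --input sim.csv --output naive.csv --naive
Rscript inst/cli/subimpute.R run-experiment --q 0.2 --mode imputed --reps 10 --outdir results/
```

See `vignettes/subdistribution-imputation.Rmd` for the full account of the
method, its conventions, and its limitations.
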