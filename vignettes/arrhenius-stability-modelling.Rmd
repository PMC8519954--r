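---
title: "Arrhenius kinetic modelling of accelerated stability data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arrhenius kinetic modelling of accelerated stability data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabkin)
```

## The problem

Liquid formulations of therapeutic proteins (monoclonal antibodies, fusion
proteins) are stored at 2--8 °C with shelf-lives of two to three years.
Waiting for real-time stability data is a bottleneck of early development, so
studies are run in parallel at accelerated (25 °C) and stress (40 °C and
above) conditions, where degradation is fast enough to be measured within
weeks to months. The question is whether those short, hot studies can predict
the slow change at the intended 5 °C condition — and with what confidence.

`stabkin` implements an apparent first-order degradation model coupled to the
Arrhenius rate law, fitted jointly across all storage temperatures, with
Monte-Carlo prediction intervals for the extrapolated 5 °C trajectory. It
also provides the ICH-style linear-regression baseline for comparison, a
temperature sub-sampling diagnostic for detecting non-Arrhenius regimes, and
coverage/width statistics for verifying predictions against held-out
long-term data.

## The model

Quality attributes are tracked as percent of total (chromatographic relative
areas, relative potency). Degradation is approximated as a one-step apparent
first-order reaction. On the percent scale, a purity-like (decreasing)
attribute follows

$$A(t, T) = A_0\, e^{-k(T)\,t},$$

and an impurity-like (increasing) attribute, using conservation of total
material $A + B = 100\%$,

$$B(t, T) = 100 - (100 - B_0)\, e^{-k(T)\,t}.$$

The literature form of the conservation identity is written on the fraction
scale (total = 1); since all assays report percent, the package transcribes
the total as 100 throughout.

Temperature enters through the Arrhenius law. Rather than the classical
frequency-factor form $k(T) = A_f e^{-E_a / RT}$, fitting uses the
numerically better-conditioned reference-temperature parameterization

$$k(T) = k(T_\mathrm{ref})\, e^{-\frac{E_a}{R}\left(\frac{1}{T} -
\frac{1}{T_\mathrm{ref}}\right)},$$

with $T_\mathrm{ref} = 278.15$ K (5 °C) so that the fitted rate constant is
directly the degradation rate at the intended storage condition. The two
parameterizations are algebraically identical under
$A_f = k_\mathrm{ref} e^{E_a/(R T_\mathrm{ref})}$, and the package asserts
their agreement to relative $10^{-12}$ in its test suite. $R$ is kept in
kcal/(mol·K) because activation energies in this field are reported in
kcal/mol (typical mAb degradation processes cluster around 20--25 kcal/mol).

Model assumptions worth stating explicitly:

* a single degradation pathway dominates in the fitted temperature range;
* changes are modest (roughly up to 20% over the study), so second-order
  aggregation at constant protein concentration is adequately approximated
  by first-order kinetics;
* degradation is monotone — the model cannot represent non-monotonic
  attributes (e.g. basic variants that rise and fall) or biphasic kinetics.

## Fitting

`fit_kinetic()` estimates $(E_a, k_\mathrm{ref}, \mathrm{level}_0)$ by
unweighted nonlinear least squares over **all measurements at all
temperatures jointly** — the joint fit in time and temperature is what makes
the extrapolation robust, because the hot series pin down $E_a$ while the
cold series pin down the level. A study design has a single analytical
measurement at $t = 0$ shared by every temperature series; it is one row of
the dataset and enters the residual sum exactly once.

The initial level is a free parameter rather than being pinned to the
$t = 0$ measurement: the $t = 0$ value is data like any other point, and
fitting the level is the standard least-squares treatment.

The solver is bounded Levenberg--Marquardt (`minpack.lm::nls.lm`) with an
analytic Jacobian. Bounds are $E_a \in [0, 100]$ kcal/mol,
$k_\mathrm{ref} \in [0, 10]$ /month, $\mathrm{level}_0 \in [0, 100]$ %:
wide enough to cover observed mAb activation energies with a large margin
while keeping the trust region away from unphysical values. Starting values
are $E_a = 20$ kcal/mol, the $t = 0$ measurement for the level, and a
two-point log-linear rate estimate at the hottest temperature translated to
$T_\mathrm{ref}$. Convergence tolerances are $10^{-13}$ on the relative
reduction of the objective and on the step; on non-convergence up to ten
deterministic jittered restarts (rate scaled by factors 0.01--100, $E_a$
from 5 to 50) are attempted, and failure is reported as `converged = FALSE`
with diagnostics rather than as an exception. These bounds, starts and
restart rules are implementation choices of this package.

Goodness of fit is the pooled coefficient of determination
$R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$ over all fitted points at all
temperatures (consistent with the joint objective). When all measurements
are identical, $SS_\mathrm{tot} = 0$ and `goodness_of_fit()` returns `NA`
rather than dividing by zero. Fits with $R^2 < 0.9$ are treated as
unreliable throughout (the default gate in the verification stage).

## Prediction intervals

`monte_carlo_band()` constructs pointwise intervals by parametric bootstrap:

1. generate `n_replicates` (default 399) perturbed copies of the study by
   adding independent $\mathcal{N}(0, \sigma^2)$ noise to every measurement,
   where $\sigma$ is the assay accuracy (`accuracy_sd`); the shared $t = 0$
   row is perturbed once per replicate, mirroring the single-measurement
   design; perturbed values are clipped to the physical $[0, 100]$ % range;
2. refit the model to each copy and evaluate its trajectory at the target
   temperature on a monthly grid;
3. the pointwise 2.5th and 97.5th percentiles of the replicate trajectories
   form the 95% **confidence** band; the **prediction** band adds an
   independent measurement-error draw to every replicate trajectory point
   before taking percentiles, accounting for the dispersion of a future
   individual measurement.

Lower and upper bounds are computed separately, so bands can be asymmetric
(the impurity trajectory is convex in its parameters near saturation).
Replicate fits that fail to converge are dropped and counted; more than 5%
failures aborts the band. With 399 replicates the 2.5th/97.5th percentiles
are the conventional order statistics of a parametric bootstrap at the 95%
level. The measurement-error draws are taken after all refits, so
`kind = "confidence"` and `kind = "prediction"` under the same seed share
identical replicate fits and are directly comparable.

The adopted prediction-interval rule — replicate-trajectory percentiles
after adding one independent measurement-error draw per point — is the
standard parametric-bootstrap prediction interval; on well-specified
synthetic data its empirical coverage is 93--97% across ensemble seeds
(see the acceptance script), consistent with the nominal 95% level.

## Temperature sub-sampling

Arrhenius extrapolation is only as good as the assumption that the same
mechanism operates at 40--60 °C as at 5 °C. `subset_analysis()` refits the
model on every subset of at least three temperatures (for $m$ temperatures,
$2^m - 1 - m - \binom{m}{2}$ subsets: 5 for four temperatures, 42 for six,
219 for eight) and charts fitted $E_a$ against the subset's highest
temperature. A flat scatter indicates one mechanism across the range;
inflated $E_a$ or $R^2 < 0.9$ in subsets reaching the hottest conditions
indicates an additional pathway, and `max_arrhenius_temperature()` reports
the largest temperature below which the passing subsets agree (default
relative $E_a$ spread 20% — the published analyses judge this by eye, so
the threshold is configurable and reported).

## Linear baseline

`fit_linear()` and `linear_prediction_interval()` implement the ICH-style
baseline: ordinary least squares of level against time using only the
intended-condition series, with the textbook two-sided prediction interval
(Student-t quantile at $n - 2$ degrees of freedom, half-width
$t_{1-\alpha/2}\, s \sqrt{1 + 1/n + (t - \bar x)^2 / S_{xx}}$) on the
identity scale. The closed form is cross-checked against
`predict(lm(...), interval = "prediction")` to $10^{-9}$ in the tests.
`compare_kinetic_vs_linear()` fits both arms on the same training window
and compares interval widths at the horizon: because the linear arm sees
only the slow 5 °C series, its extrapolated interval is dominated by
residual uncertainty amplified by the long lever arm, while the kinetic arm
borrows strength from the hot series.

## Verification statistics

`coverage()` classifies each held-out intended-condition point (after the
training window, within the band's horizon) as inside or outside the band,
interpolating linearly between grid points; points exactly on a bound count
as inside (boundary handling is unspecified in the source analyses; the
closed-interval convention is this package's choice). `study_summary()`
pools across batches as the sum of inside counts over the sum of held-out
counts — not the mean of per-batch fractions — excluding and counting
batches whose training fit fails the $R^2 \ge 0.9$ gate.

`width_ratio()` reports band width relative to the platform specification
width. One-sided platform limits are converted to widths against the natural
range of a percent measurement: width = (upper or 100) − (lower or 0), so
purity ≥ 90% gives 10, aggregates ≤ 5% gives 5, potency 50--150% gives 100,
and the charge-variant rules (initial ± 10%, initial rounded to the nearest
five) follow from `charge_variant_limit()`.

## The synthetic-study generator

No public mAb stability data exist at this granularity, so validation runs
on `simulate_study()`, which draws from the same first-order Arrhenius model
with Gaussian assay noise at the per-method accuracies (SEC aggregates
0.1%, SEC purity 0.2%, CEX 1.5%, nrCE-SDS fragments 0.3% / purity 0.5%,
potency 10% — the conservative end of the published assay-accuracy ranges).
The `"classic"` preset is the canonical design: 5/25/40 °C with pulls at 0,
1, 2, 3 and 6 months plus a held-out 5 °C extension to 36 months. True
parameters ($E_a$ 22--25 kcal/mol; 5 °C rates chosen so aggregates grow by
roughly 0.1--0.2% per year and acid variants by a few tenths of a percent,
the magnitudes typical of stable mAb formulations) are fixed defaults of
the generator, not tuning knobs. `"rapid"` emulates a four-week 25--60 °C
study with weekly pulls (week = 12/52 month); `"switch"` adds a second
aggregation pathway above 45 °C (an additive first-order term with higher
activation energy, contributing half the primary rate at the switch
temperature — the simplest construction that inflates apparent $E_a$ in
hot subsets); `"multibatch"` generates 23 batches with log-normal
between-batch variation of the rate constant only, reflecting that batch
variability originates in the production process, not in chemistry.

Because generator and model share the same kinetic family, passing coverage
tests demonstrates that the fitting and interval machinery is calibrated
**when the model is correctly specified**. They say nothing about model
misspecification on real data — non-monotonic charge variants, biphasic
aggregation, non-Arrhenius particle formation — which is precisely what the
$R^2$ gate and the sub-sampling diagnostic are for.

## Numerical choices and edge cases

* Temperatures are stored in °C in files and converted to Kelvin only inside
  rate computations; times are months throughout (weekly pulls are
  fractional months).
* Flat (no-degradation) data drive $k_\mathrm{ref}$ to its lower bound 0 and
  the level to the mean; $R^2$ is `NA` there by construction.
* Perturbed and simulated values are clipped to $[0, 100]$ %; clipping is a
  property of the measurement process (relative areas cannot leave that
  range).
* Replicate seeds and simulation sub-seeds are derived deterministically
  from one master seed; the RNG state of the caller is saved and restored.
* Problem sizes used in validation: coverage is assessed on ensembles of
  200 studies with 399 replicates per band and three held-out pulls per
  study (600 Bernoulli trials, binomial 95% interval of roughly ±2 points
  around the nominal level); the kinetic-versus-linear width comparison
  uses 100 studies.

## Known limitations

* Only first-order closed forms are implemented; reaction order is not a
  model-selection dimension.
* Bands are pointwise, not simultaneous; no analytic (delta-method)
  intervals are offered.
* No poolability testing across batches; each batch is modelled
  independently.
* The linear baseline is fitted on the identity scale only.
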