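---
title: "Methods: moderation in two-instance repeated measures designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moderation in two-instance repeated measures designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmmod)
```

## The statistical problem

In a two-instance repeated measures design each participant is observed on
the same outcome exactly twice — in two conditions, or before and after a
treatment. A between-participant variable $W$ (measured once, assumed
constant across instances) *moderates* the condition effect when the
within-person difference depends on $W$. The generating model assumed
throughout is, for participant $i$ in condition $j \in \{1, 2\}$:

$$Y_{ij} = b_{0j} + \textstyle\sum_k b_{kj} W_{ki} + \epsilon_{ij},$$

with the error pair $(\epsilon_{i1}, \epsilon_{i2})$ bivariate normal, mean
zero, standard deviations $\sigma_1, \sigma_2$, within-person correlation
$\rho$, and independence across participants. Subtracting the two
condition equations cancels the shared structure — including any covariate
whose effect does not differ by condition — and leaves an ordinary
regression of the difference score on the moderators:

$$Y_{Di} = b_0 + \textstyle\sum_k b_k W_{ki} + \epsilon_i,
  \qquad b_k = \Delta_j\, b_{kj},$$

so a standard OLS $t$ test of $b_k$ is the condition $\times W_k$
interaction test, with residual error variance
$\sigma_1^2 + \sigma_2^2 - 2\rho\sigma_1\sigma_2$. This identity —
difference-model coefficients equal differences of per-condition
coefficients — holds algebraically for any design matrix shared by the two
per-condition fits, and the test suite verifies it to $10^{-10}$ on random
fixtures.

Two model families are supported for $m$ moderators. *Additive*: only the
$m$ main terms. *Multiplicative*: all $2^m - 1$ products over nonempty
moderator subsets, ordered by subset size then input order, so with two
moderators the product coefficient is a three-way condition
$\times W_1 \times W_2$ interaction. With one moderator the families
coincide.

## Probing

The conditional effect of condition at moderator values
$w = (w_1, \dots, w_m)$ is the linear combination $\theta = l'b$ whose
contrast vector $l$ evaluates each design term at $w$ (1 for the intercept,
$w_k$ for main terms, products for product terms). Its variance is
$l' \Sigma l$ with $\Sigma = \hat\sigma^2 (X'X)^{-1}$, and
$\theta / \mathrm{se}(\theta)$ is referred to $t_{n-q-1}$, where $q$ is the
number of non-intercept design columns. The per-condition effect of a
moderator (the other probing direction) needs no contrast machinery: it is
the moderator's coefficient in the per-condition fit.

The Johnson–Neyman procedure applies to a single continuous moderator.
Setting $|\theta(W)| / \mathrm{se}(\theta(W)) = t^*$ and squaring yields

$$\big(b_1^2 - t^{*2}\mathrm{var}(b_1)\big) W^2
 + \big(2 b_0 b_1 - 2 t^{*2}\mathrm{cov}(b_0, b_1)\big) W
 + \big(b_0^2 - t^{*2}\mathrm{var}(b_0)\big) = 0,$$

solved in closed form. Roots may be complex or lie outside the observed
moderator range; both raw solutions are retained with flags, but only real,
in-range roots are reported as boundaries of significance, and no claims
are made beyond the data. A useful consequence of the algebra: when
$b_1 = 0$ with a significant intercept (and zero covariance) the
discriminant is $-4ac > 0$, so the boundaries are *real* but typically far
outside the data — the conditional effect loses significance only where the
extrapolated variance has grown — and the whole observed range is
significant.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `model` | additive | additive vs multiplicative moderator entry |
| `center` | `TRUE` | mean-center continuous moderators (outcome-unit coefficients are unaffected; the intercept becomes the condition effect at the sample-average moderator) |
| `alpha` | 0.05 | level for every test, interval and the JN critical $t$ |
| `probe` | mean ± SD | automatic probe values; `"percentile"` uses the 16th/50th/84th percentiles, which are guaranteed to lie inside the observed range |
| `wmodval` | none | extra probe values, interpreted on the *original* (uncentered) scale and translated internally |
| `grid_n` | 21 | evenly spaced points in the JN region table, with in-range boundaries spliced in; 21 balances readability against resolution |

Design choices made where the convention was genuinely open:

* **Subtraction order.** The analysed difference is first-listed minus
  second-listed outcome, so with outcomes listed (pre, post) a positive
  effect means the measure fell. The simulation harness instead reports the
  condition-2 minus condition-1 estimand $b^{(2)} - b^{(1)}$, matching the
  generator's parameterisation; the two orders differ only by a global
  sign.
* **Centering and products.** Product terms are formed from centered
  columns (not centered products), so each lower-order coefficient is a
  conditional effect at the other moderators' sample means.
* **Dichotomous numeric moderators** (0/1 codes) are never centered and
  are probed at their observed values; categorical moderators are coded
  (indicator with the first sorted label as reference, or Helmert) into
  $k-1$ columns that enter as an additive set — the two codings span the
  same column space and give identical $R^2$.
* **Degrees of freedom.** The coefficient covariance uses the unbiased
  residual variance with denominator $n - q - 1$.
* **JN applicability.** The procedure is refused, with an explanatory
  message rather than numbers, for more than one moderator or for a
  moderator with fewer than three distinct values.
* **Percent above a boundary** uses a strict inequality; ties count below.
* **Quantiles** use linear interpolation between order statistics
  (R type 7), fixed so results are bit-stable.

## Numerical choices

The OLS engine uses a QR decomposition; the coefficient covariance is
recovered from the $R$ factor. Singularity is a deterministic error, not a
silent column drop: exact rank deficiency is detected via the QR rank (the
offending columns are named), and near-singularity via a condition-number
threshold of $10^{12}$ on the column-scaled design. A constant response
yields $R^2 =$ `NA` rather than a misleading 0 or 1. In the JN quadratic,
$|a| < 10^{-12}$ relative to the coefficient scale is treated as linear
(single root $-c/b$); a negative discriminant reports no real boundaries.
Probe grids order the Cartesian product with the last moderator varying
fastest. Reports print every number at a fixed (default 4) decimal
precision straight from the stored fit objects, so identical inputs render
byte-identical text.

## What the generator emulates — and what it does not

`generate_two_instance()` draws moderators from user-specified
distributions (normal, Bernoulli 0/1, uniform), then outcomes from the
bivariate-normal error model above. The defaults describe a realistic
behavioural pre/post trial: $n = 40$ participants, one standardized
continuous moderator, per-condition slopes 0.0293 and 0.43 (a condition
effect that declines by roughly 0.4 outcome units per moderator unit, with
intercept difference 0.20), $\sigma_1 = \sigma_2 = 1.2$ and $\rho = 0.5$,
which imply a difference-score residual SD of about 1.2 and a slope
standard error near 0.19 at that sample size. A single integer seed drives
all randomness; the replication harness derives the stream for replicate
$r$ as seed $+\, r$, so any replicate is individually reproducible.

The generator deliberately omits features of real repeated-measures data:
non-normal or heteroscedastic errors, floor/ceiling effects and regression
to the mean, measurement error in the moderators, missingness that is not
completely at random, and carryover/order effects. Passing tests therefore
establish that the estimator and probing machinery are correct *under the
stated model*, not that the model describes any particular dataset.

## Validation design and problem sizes

The suite checks each layer against an independent route: the QR engine
against a brute-force normal-equations solve and `lm()` on random designs
($n \le 30$, $q \le 4$, $10^{-8}$ relative); closed-form JN roots against a
$10^5$-point grid scan for sign changes of $|t(W)| - t^*$, plus
back-substitution of every reported root to $|t| = t^*$ within $10^{-6}$;
pick-a-point estimates against recentered refits (shift the moderators so
the probe point is the origin and read the intercept) to $10^{-10}$ on 100
random fixtures; and the desk calculations of a published single- and
two-moderator example from their printed coefficient tables. Operating
characteristics use 2000 replicates at $n = 100$: the null rejection rate
of the interaction test is required to fall within $0.05 \pm 0.015$
(3 binomial Monte-Carlo SEs) and the coverage of the 95% interval for the
conditional effect at the moderator mean within $0.95 \pm 0.02$. Bias
checks run 300 replicates per cell over
$n \in \{30, 100\} \times \rho \in \{0, 0.5\}$ with unequal error SDs.

## Limitations

Designs with more than two instances (contrast-based analyses), long-format
multilevel structures with replicates per condition, residualized-change
and autoregressive (ANCOVA) change models, missing-data imputation or
likelihood-based handling, latent moderators, robust/sandwich standard
errors, and JN regions over two or more moderators are out of scope. A
covariate whose effect is constant across conditions cancels in the
difference and need not be modelled; one whose effect may differ by
condition should simply be entered as a moderator.
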