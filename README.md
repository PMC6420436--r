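# rmmod

Moderation analysis for **two-instance repeated measures designs**: each
participant is measured on the same outcome twice (two conditions, or pre-
and post-treatment), and one or more *between-participant* variables may
moderate the within-person effect of condition. Typical users are
psychologists, clinical-trial analysts and behavioural researchers who would
otherwise run separate subgroup analyses or a between-participant moderation
tool that does not apply to repeated measures.

## The model

Write the outcome of participant *i* in condition *j* ∈ {1, 2} as a linear
function of the moderators, with condition-specific coefficients and
within-person correlated errors:

    Y_ij = b_0j + b_1j W_1i + ... + b_mj W_mi + e_ij,
    (e_i1, e_i2) ~ bivariate normal, SDs sigma_1, sigma_2, correlation rho

Moderation of the condition effect by W_k means b_k1 ≠ b_k2. Subtracting the
two equations eliminates everything constant within a person and yields a
single ordinary regression on the difference score Y_D:

    Y_D = Y_first − Y_second = b_0 + b_1 W_1 + ... + b_m W_m + e,

where each b_k estimates the condition difference in W_k's slope, i.e. the
condition × W_k interaction; the intercept b_0 is the condition effect when
every moderator term is zero. Moderators can enter **additively** (main
terms only) or **multiplicatively** (all products among moderators, so two
moderators carry a three-way condition × W1 × W2 interaction).

Interactions are probed two ways:

* **Pick-a-point (simple slopes).** The conditional effect of condition at
  moderator values (w_1, ..., w_m) is the linear combination θ = l′b with
  contrast vector l built from the design terms, standard error
  √(l′Σl) (Σ = coefficient covariance matrix) and a t reference with
  n − q − 1 degrees of freedom.
* **Johnson–Neyman.** Solving |θ(W)| / se(θ(W)) = t* for a single
  continuous moderator gives a quadratic whose real roots are the
  *boundaries of significance*; roots outside the observed moderator range
  are flagged but never interpreted, and a region table shows where the
  condition effect is and is not significant.

A synthetic-data module generates two-instance datasets from exactly this
error model (per-condition coefficient vectors, error SDs, within-person
correlation rho) and a replication harness estimates type-I error, power,
coverage and bias of the procedure.

## Worked example

```r
library(rmmod)

# 40 participants, one standardized continuous moderator; defaults emulate a
# pre/post behavioural pain trial in which the condition effect declines by
# about 0.4 outcome units per moderator unit
d <- generate_two_instance(n = 40, seed = 11)
res <- rmmod(d, jn = TRUE, wmodval = list(0.85))
print(res)
```

Key parts of the printed report (abridged):

```
Overall model (difference score)
  R-sq = 0.0961,  F(1, 38) = 4.0421,  p = 0.0515

Coefficients
  term      estimate  se      t        p       ci_low   ci_high
  constant  0.3396    0.1941  1.7501   0.0882  -0.0532  0.7325
  W1        -0.5101   0.2537  -2.0105  0.0515  -1.0237  0.0035

Conditional effect of condition ('X') on Y at values of the moderator(s)
  W1       estimate  se      t        p       ci_low   ci_high
  -0.7747  0.7348    0.2762  2.6602   0.0114  0.1756   1.2940
  0.0000   0.3396    0.1941  1.7501   0.0882  -0.0532  0.7325
  0.7747   -0.0555   0.2762  -0.2010  0.8418  -0.6147  0.5037
  1.1696   -0.2570   0.3546  -0.7247  0.4731  -0.9748  0.4608

Johnson-Neyman procedure
  critical t = 2.0244 at alpha = 0.05, df = 38
  Boundaries of significance:
    boundary  pct_above  boundary_original
    -0.1127   52.5000    -0.4323
```

Reading it: the interaction coefficient (−0.51, p = .0515) says the
first-minus-second difference shrinks as the moderator grows. The
pick-a-point table probes the condition effect at the moderator mean and
±1 SD (centered scale) plus the user-requested original-scale value 0.85
(centered 1.1696): the effect is significant only at low moderator values.
The Johnson–Neyman boundary −0.11 (centered; −0.43 original scale) splits
the observed range into a significant region below and a nonsignificant
region above, with 52.5% of participants above the boundary.

The same analysis runs from a shell on any wide-form CSV:

```sh
Rscript inst/exec/rmmod --data mydata.csv --y pre post --w inflame \
    --model 3 --jn --wmodval 0.85 --json out.json
```

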