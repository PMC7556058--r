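# fcmrisk

Medical decision support for **three-level gastric cancer (GC) risk
stratification** built on fuzzy cognitive maps (FCMs), for
biostatisticians and clinical-informatics researchers who want a
transparent, expert-driven alternative to black-box classifiers.

## The method

An FCM is a signed directed graph: concepts hold activations
$A_i \in [0,1]$, edges hold causal weights $w_{ji} \in [-1,1]$, and the
state evolves synchronously under

$$A_i(k+1) = f\Big(A_i(k) + \sum_{j\neq i} w_{ji}\,A_j(k)\Big),\qquad
f(x)=\frac{1}{1+e^{-\lambda x}} .$$

The shipped GC map has 28 concepts — 27 risk factors (demographics, diet,
systemic and stomach conditions) plus a central GC output — joined by 38
signed edges. Edge weights come from multi-expert linguistic judgments
(*very low … very high*): the experts' triangular membership functions are
pooled by pointwise **SUM aggregation** and collapsed by **centroid
defuzzification** into a number in $[-1,1]$, with the sign decided by
majority vote. A patient record is encoded onto the input concepts, the map
is iterated to a steady state, and the converged GC activation is
thresholded at tertiles into **low / medium / high** risk.

Weights can be refined on a labeled cohort by **Nonlinear Hebbian Learning
(NHL)**, applied only to expert-declared edges:

$$w_{ji}(k) = \gamma\,w_{ji}(k-1) + \eta\,A_i(k-1)\big(A_j(k-1) -
\mathrm{sgn}(w_{ji})\,w_{ji}(k-1)\,A_i(k-1)\big),$$

with learning rate $\eta\in(0,0.1)$, decay $\gamma\in(0.9,1)$ and dual
termination criteria: $F_1=\sum_j (OC_j-T_j)^2$ against the class-target
midpoints, and $F_2$, stability of the output concept to within
$e = 0.002$ between consecutive iterations. Because the private
560-patient reference cohort is unavailable, the package also ships a
**synthetic cohort generator** that reproduces its published per-feature
marginal frequencies, and the full **evaluation suite** (three-class
confusion matrix; accuracy, recall, precision, MAE, RMSE with the
reference tables' truncation-style reporting).

## Worked example

```r
library(fcmrisk)

bundle <- gc_bundle()          # 28 concepts, 38 signed edges
cohort <- label_cohort(sample_cohort(560, seed = 1), bundle)
table(cohort$risk_label)
#>    low medium   high
#>     63    196    301

sp  <- split_cohort(cohort, 0.7, seed = 1)   # 392 train / 168 test
fit <- fcm_nhl(bundle, sp$train, control = nhl_control(seed = 1))
fit
#> FCM trained by Nonlinear Hebbian Learning
#>   eta = 0.045, gamma = 0.98, e = 0.002
#>   392 training record(s), 1 epoch(s), terminated by F2

assess_risk(sp$test[1:3, ], bundle)
#>     risk  oc_value converged
#> 1 medium 0.5225599      TRUE
#> 2 medium 0.4828277      TRUE
#> 3 medium 0.6354603      TRUE
```

`oc_value` is the converged activation of the GC concept; `risk` is its
tertile class. Re-scoring the published held-out confusion matrix of the
NHL-FCM benchmark reproduces its printed metrics exactly:

```r
metrics_report(reference_results("classifiers")$nhl_fcm)
#> Confusion matrix (rows predicted, columns actual):
#>          actual
#> predicted high medium low
#>    high     55      1   1
#>    medium    1     60   1
#>    low      0      3  46
#>   class recall % precision %
#>    high    98.21       96.49
#>  medium    93.75       96.77
#>     low    95.83       93.87
#> overall accuracy: 95.83%
```

A command-line front end wraps the same functions
(`system.file("cli", "fcmrisk.R", package = "fcmrisk")`) with subcommands
`assess`, `simulate`, `train`, `evaluate` and `grid`; every run writes a
JSON manifest of its full configuration.

See `vignettes/fcm-gastric-risk.Rmd` for the model's assumptions, the
training regime, the generator's scope, and known limitations (including
why NHL refinement should be gentle: the rule is unsupervised and heavy
retraining drifts weights toward a co-activation attractor).

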