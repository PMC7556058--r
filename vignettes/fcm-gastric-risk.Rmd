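---
title: "Gastric cancer risk assessment with NHL-trained fuzzy cognitive maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gastric cancer risk assessment with NHL-trained fuzzy cognitive maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmrisk)
```

## The model

A fuzzy cognitive map (FCM) is a signed directed graph whose nodes
("concepts") carry activations $A_i \in [0,1]$ and whose edges carry causal
weights $w_{ji} \in [-1,1]$. The gastric cancer (GC) map has 28 concepts:
27 risk factors elicited from domain experts — personal features (sex, blood
group, BMI, age, physical activity, alcohol, occupational chemical exposure,
smoking), diet (salt, vegetables, smoked/fast/fried food, milk, fruit, food
containers), systemic conditions (allergy history, family cancer history,
cardiovascular history, general status) and stomach conditions (reflux,
surgery, *H. pylori* infection history, mucosa status, gastric
inflammation) — plus a central GC concept that collects their influences
through 38 signed edges. Positive weights promote disease risk; negative
weights (vegetables, fruit, milk, allergy history, cardiovascular history,
physical activity) are protective.

States evolve synchronously:

$$A_i(k+1) = f\Big(A_i(k) + \sum_{j \ne i} w_{ji} A_j(k)\Big), \qquad
  f(x) = \frac{1}{1 + e^{-\lambda x}}.$$

The squashing function is not prescribed by the method itself; we use the
logistic sigmoid with $\lambda = 1$ (configurable), the standard choice in
the Hebbian-FCM literature, because it keeps activations in the open unit
interval that the concept scale requires and has a bounded slope
($\lambda/4$) that makes the uncoupled map a contraction. Iteration stops
when the max-norm change of the full state falls below `eps` (default
0.002, mirroring the training tolerance) or after `max_iter` (default 100)
steps. The converged GC activation is thresholded into low / medium / high
risk at tertiles $(1/3, 2/3)$ by default; the cutoffs are configuration,
not data, and they double as the per-class target ranges used during
training.

### Input clamping

The update above is defined for every concept, and `fcm_model()` leaves all
concepts free by default. The shipped GC bundle, however, *clamps* the 27
risk-factor concepts at their encoded values. The reason is structural:
with a sigmoid transfer, an unclamped map contracts to a single fixed point
that does not depend on the initial state, so every patient would converge
to the same risk score and the assessment would carry no information.
Clamping treats risk factors as exogenous patient attributes — which they
are: smoking status does not evolve during a consultation — and leaves the
GC concept as the dynamic variable. The flag is per-model configuration
(`clamp_inputs`), so scenario analyses over a free-running map remain
available.

## From linguistic judgments to weights

Experts state each causal link as a sign plus one of five linguistic terms
(*very low … very high*). Each term has a triangular membership function on
the magnitude axis $[0,1]$; the default bank places peaks at
$0.1, 0.3, \dots, 0.9$ with half-width $0.25$, truncated to the axis. The
outer two triangles are therefore shoulder-like: their centroids are
$0.1329$ and $0.8671$ rather than their peaks, while the three interior
(genuinely symmetric) terms defuzzify exactly to their peaks.

Multi-expert opinions are pooled by the SUM technique — pointwise addition
of the membership curves, deliberately *not* clipped at 1, because the
centroid is scale-invariant and clipping would discard the multiplicity of
agreeing experts (a bounded-sum mode is available). The pooled curve is
collapsed by centroid defuzzification,
$\int x\,\mu(x)\,dx \big/ \int \mu(x)\,dx$, computed by trapezoidal
quadrature on a grid of step $10^{-4}$; the test suite holds this to within
$10^{-6}$ of an independent $10^{-5}$-grid quadrature. Signs are decided by
majority vote across experts while magnitudes pool *all* opinions sign-free
(the elicitation protocol fixes the direction first, then the strength); an
exact sign tie is reported as a consensus failure rather than resolved
silently.

```{r weights}
ops <- data.frame(source = "C4", target = "GC", sign = 1,
                  term = c("high", "very_high", "very_high"),
                  expert = c("e1", "e2", "e3"))
weights_from_opinions(ops, c("C4", "GC"))["C4", "GC"]
```

## Patient encoding

Each feature's levels are ordered by increasing intensity of the factor
itself (e.g. vegetables: monthly < weekly < daily) and encoded equally
spaced on $[0,1]$; binary features map to $\{0,1\}$. The *direction* of the
health effect lives in the edge sign, not in the level order — encoding
protective factors in "risk order" while also giving them negative weights
would double-count the protection. The encoding map is data (shipped as a
YAML dictionary) and can be overridden per deployment.

## Nonlinear Hebbian Learning

Expert weights are refined on a labeled cohort with the NHL recurrence,
applied only to the expert-declared (nonzero) edges:

$$w_{ji}(k) = \gamma\, w_{ji}(k-1) +
  \eta\, A_i(k-1)\big(A_j(k-1) - \mathrm{sgn}(w_{ji})\, w_{ji}(k-1)\, A_i(k-1)\big).$$

The learning rate must satisfy $0 < \eta < 0.1$ and the decay
$0.9 < \gamma < 1$ (defaults $\eta = 0.045$, $\gamma = 0.98$, the
best-performing pair of the reference grid). Two termination functions
govern the process: $F_1 = \sum_j (OC_j - T_j)^2$, the squared distance of
the output concepts from their class-target midpoints
$T = (T_{\min}+T_{\max})/2$, and $F_2$, which holds when the output concept
changes by strictly less than $e = 0.002$ between consecutive iterations.

Several aspects of the training regime are genuinely open in the method's
description; the package fixes them as follows and exposes each in
`nhl_control()`:

* records are visited in a seed-shuffled order each epoch;
* per record, one synchronous state step is alternated with one Hebbian
  sweep over all nonzero weights (using the pre-step activations, matching
  the recurrence's $k-1$ indexing) until $F_2$ holds or a per-record cap
  (default 100) is reached;
* the epoch $F_1$ is the record mean; training stops when every record of
  an epoch terminated via $F_2$, when $F_1$ stops improving by more than
  $10^{-6}$ for 3 consecutive epochs, or at `max_epochs` (default 20);
* updates are clipped to $[-1,1]$, zero weights are never touched or
  created, and an update that would flip an expert-declared sign is floored
  at magnitude $10^{-6}$ instead — the learner may re-weigh a causal link
  but not reverse the experts' direction.

## The synthetic cohort generator

The reference study's 560-patient dataset is private, so the package ships
a generator that emulates its printed per-feature marginal frequencies:
each feature is drawn independently from its reported level distribution
(`gc_marginals()`), and ground-truth labels come from running the shipped
map on each record (`label_cohort()`). Because only marginals were
published, **no between-feature dependence is modelled**; a `dependence`
hook accepts a user-supplied joint sampler but ships empty. Consequences:
passing tests demonstrate the pipeline's correctness and internal
consistency on marginally faithful data, not calibration on real patients —
real risk factors are correlated (smoking with alcohol, reflux with BMI),
and no claim about clinical performance follows from these simulations.

Reporting quirks of the printed reference tables are handled explicitly:
percentages are *truncated*, not rounded (85/560 reports as 15.17), since
that is the only convention consistent with most printed cells; counts are
treated as authoritative where the percent column disagrees (the printed
"low risk 8.39%" against counts 74/560, several percent cells, and the BMI
counts summing to 558 rather than 560 — the sampler normalises each feature
by its own total). The baking-dish levels account for only 421 of 560
records; the shipped marginal adds an `other` level carrying the remainder.

The shipped weight fixture itself is a documented, plausible configuration
— signs follow the documented risk directions, magnitudes come from a
*synthetic* three-expert opinion table — and is labeled as such; the
original study's learned matrix is published only as a figure and is not
reproduced. The synthetic experts' terms were chosen once so that a
560-record cohort spans all three risk classes in proportions close to the
reference (about 11/35/54%), and then frozen.

## Evaluation conventions

The three-class confusion matrix is oriented rows = predicted,
columns = actual (class order high, medium, low), the orientation under
which the reference tables are internally consistent: column sums then
equal the published 56/64/48 test-set class counts. Accuracy is
trace/total; recall and precision are the one-vs-rest column and row
ratios; MAE normalises by the number of records $N$ only (per its
reference definition) while RMSE normalises by $NC$. Reported percentages
are truncated to the printed precision; full-precision values are kept
alongside.

Two cells of the published benchmark are arithmetically inconsistent with
their own printed matrices: the MLP-ANN matrix sums to 176 rather than 168
(its implied accuracy is 152/176 = 86.36, not the printed 90.47 = 152/168,
and its implied low-class recall is 45/56 = 80.35, not 93.75 = 45/48), and
the Naïve Bayes medium-class precision implies a row sum of 72 where the
matrix gives 68 (82.35 vs the printed 77.77). The test suite asserts every
reproducible cell of all five classifiers and the full grid accuracy
column, and asserts the two defective cells at the values their matrices
actually imply.

## Numerical choices

* Defuzzification grid step $10^{-4}$; all bank knots are multiples of
  0.05, so the piecewise-linear curves are sampled exactly at their kinks.
* Convergence is a strict inequality on the max-norm; the uncoupled map's
  fixed point ($\approx 0.65905$ for $\lambda = 1$) is matched to $10^{-9}$
  against a one-dimensional root-finding oracle in the tests.
* Classification is left-closed: an output exactly at a threshold takes the
  upper class.
* Percent truncation adds a $10^{-9}$ nudge before flooring so that exact
  values such as 37.5 are not pulled down by binary representation error.
* All samplers take explicit seeds and restore the caller's RNG state.

## Known limitations

* **Parameter recovery is limited by the learning rule.** NHL is
  unsupervised: class labels enter only through the termination functions,
  never through the weight update, so retraining cannot actively undo a
  perturbation of the weights. Moreover, sequentially updating one global
  matrix across hundreds of records applies the decay $\gamma$ thousands of
  times, which forgets the initial matrix and drags weights toward a
  co-activation attractor that inflates positive edges and flattens
  negative ones. On the packaged recovery experiment (560 synthetic
  records, truth perturbed by $\pm 0.2$, 70/30 split) the held-out accuracy
  after training is about 54% at seed 1 — *below* the untrained perturbed
  matrix — and the acceptance suite records this property as failing its
  90% bar rather than altering the learner to pass it. Practically, the
  expert matrix is the model and NHL should be used for gentle, few-epoch
  refinement, not for recovery from substantial weight noise.
* The shipped weight fixture is plausible, not learned; no clinical
  validation is implied.
* Independence of the sampled features (above) limits what synthetic
  results say about real cohorts.
* Only the synchronous update scheme is implemented; asynchronous and
  continuous-time FCM variants, other defuzzifiers (bisector,
  mean-of-maxima), non-triangular membership banks and other FCM learners
  (AHL, DD-NHL, population-based) are out of scope.

## Problem sizes

The test suite and the acceptance script run cohorts of 25–560 records
(10,000 for marginal-fidelity checks), 50-epoch training runs on 25
records, 1,000 random maps for boundedness properties, and 100 random
membership sums against the quadrature oracle — sizes chosen to exercise
every contract at full fidelity while keeping a complete run in the order
of a minute.
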