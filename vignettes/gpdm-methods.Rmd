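---
title: "Methods: saturated diagnosis modeling for polytomous responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saturated diagnosis modeling for polytomous responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpdm)
```

## The model

A diagnostic test measures K binary attributes; an examinee's mastery
profile is one of the $L = 2^K$ patterns $\alpha_l$. The binary
Q-matrix declares which attributes each item requires; item $j$'s
q-vector reduces $\alpha_l$ to the **reduced attribute vector**
$\eta_{jh}$ over the $G_j$ required attributes, collapsing the $L$
classes into $H_j = 2^{G_j}$ latent groups. Throughout the package,
patterns are ordered lexicographically with attribute 1 as the most
significant bit, so class and group indices are reproducible across
functions and runs.

A polytomous item with $C_j$ score categories is split graded-response
style through cumulative probabilities
$P^*_c(\eta_{jh}) = P(X_j \ge c \mid \eta_{jh})$, with
$P^*_c - P^*_{c+1} = P_c$, $P^*_0 = 1$ and $P^*_{C_j} = 0$. The model
is parameterized directly by the conditional probabilities
$P_c(\eta_{jh})$: $(C_j - 1) H_j$ free item parameters, the saturated
count. A linking function $F$ (identity, logit or log) expands each
category's probabilities into baseline, main-effect and interaction
terms,

$$F[P_c(\eta_{jh})] = \beta_{jc0} + \sum_g \beta_{jcg}\eta_{hg}
  + \sum_{g<g'} \beta_{jcgg'}\eta_{hg}\eta_{hg'} + \cdots,$$

and the saturated design matrix (entry $(h, S) = 1$ iff group $h$
masters every attribute in subset $S$; effect columns ordered baseline,
mains by attribute index, then interactions in lexicographic subset
order) makes the probability/effect map an exact linear bijection.
With all $C_j = 2$ the model coincides with the saturated dichotomous
(G-DINA-type) model; the same code path estimates both.

The polytomous DINA and DINO reductions keep two parameters per
above-zero category (baseline plus a conjunction / disjunction effect).
Their two-column design matrices, the class-size-weighted projection
$(D'WD)^{-1}D'W\hat P$ with $W = \mathrm{diag}(N_{jh})$, and
guessing/slip re-expressions are in `pdina_design()`, `pdino_design()`,
`effects_from_probs()` and `guess_slip()`. Additive reductions (one
main effect per attribute) are *not* linearly recoverable from the
saturated fit except for single-attribute items, and are therefore used
here only as a generating model, never estimated directly.

## Estimation

`fit_gpdm()` maximizes the marginal likelihood
$\prod_i \sum_l L(X_i\mid\alpha_l)\, p(\alpha_l)$ over the item tables
and an unconstrained structural distribution ($2^K - 1$ free
parameters) with the standard latent-class EM: the E-step applies Bayes
rule per class and accumulates expected group sizes
$N_{jh} = \sum_i p(\eta_{jh}\mid X_i)$ and category counts $R_{jhc}$;
the M-step is closed-form, $\hat P_c(\eta_{jh}) = R_{jhc}/N_{jh}$ and
$\hat p(\alpha_l) = N^{-1}\sum_i p(\alpha_l\mid X_i)$. This closed-form
update is the unique EM for this complete-data likelihood and is the
package's own reconstruction of the estimation routine; it is verified
in the test suite against brute-force maximization of the marginal
likelihood on small cases. Empty groups ($N_{jh}=0$) retain their
previous values and are flagged.

Numerical choices, each deliberate:

* **Stopping rule**: absolute log-likelihood change below `tol`
  (default $10^{-6}$) or `max_iter` (default 2000). The log-likelihood
  is non-decreasing across iterations when no constraint is projected,
  and the tests assert this every iteration.
* **Initialization**: uniform structural distribution; item cumulative
  probabilities start at $0.2 + 0.6\,m/G_j$ for a group mastering $m$
  required attributes, split evenly across categories. The monotone
  orientation breaks the label-switching ambiguity toward the intended
  interpretation of mastery; `init_jitter` adds seeded uniform noise
  for multistart exploration.
* **Ties in MAP classification** go to the lowest class index —
  documented so classifications are reproducible; EAP thresholds the
  marginal mastery posterior at 0.5 (inclusive).
* **Missing responses are rejected at load.** Dropping terms from the
  conditional likelihood would silently change the model, so the
  package refuses rather than guesses.

Standard errors (`information_se()`) come from the inverse of the
empirical outer-product information of the per-examinee scores of the
free probabilities and structural parameters — a cross-product
approximation chosen over an analytic Hessian because it is exact at
the same asymptotic order, simple to audit, and verified in tests
against the binomial closed form in the hard-classification limit.
Covariance blocks per item and category feed the delta method for
transformed effects. A singular information matrix (non-identified or
boundary fits) yields missing SEs with a warning rather than a
pseudo-inverse, so downstream consumers cannot mistake them for real
precision.

## Monotonicity

The monotonicity assumption states that cumulative probabilities never
decrease along the mastery partial order
($\eta_{jh} \ge \eta_{jh'}$ elementwise). The default is
`monotone = "off"` with post-hoc checking via `check_monotonicity()` —
the choice used in the real-data style of analysis, where violations
are themselves diagnostic information for item development. With
`monotone = "updown"`, each EM iteration projects the tables top-down:
the top category first ($P^*_{C-1} = P_{C-1}$), then
$P^*_{C-2} = P_{C-2} + P^*_{C-1}$, and so on, each row projected by
**weighted isotonic regression over the partial order** with weights
$N_{jh}$, then clamped to $[P^*_{c+1}, 1]$ so recovered conditional
probabilities stay non-negative. The projection solves the exact
weighted least-squares isotonic problem by the lower/upper-set min-max
characterization for $H_j \le 16$ (the package enumerates the lattice's
monotone sets) and falls back on cyclic pairwise pooling above that;
the exact branch is validated in tests against Dykstra's alternating
projections.

## Model-fit assessment

`assess_fit()` simulates `M` examinees (default $100N$ — "large" is
deliberately tied to the observed sample so the predicted correlations
are an order of magnitude more precise than the observed ones) from the
fitted structural distribution and item tables, and compares observed
and predicted item-pair Pearson correlations on the Fisher-z scale:
$r_{jj'} = |Z[\rho(X_j, X_{j'})] - Z[\rho(\tilde X_j, \tilde X_{j'})]|$
with $SE = (N-3)^{-1/2}$, $N$ the observed sample size. Polytomous
responses enter the correlation as their integer scores. The maximum
z-score is tested against the two-sided Bonferroni critical value over
all $J(J-1)/2$ pairs; item- and test-level RMS statistics $sr_j$ and
$sr$ summarize residual structure and the largest $sr_j$ names the
**hit item**, the prime suspect under Q-matrix misspecification.
Because a single simulated replicate leaves Monte-Carlo noise in the
z-scores, `n_pred` optionally averages the residual matrices over
several predicted data sets; the default of one replicate matches the
method as usually described. Model comparison uses
$\mathrm{AIC} = -2LL + 2\,\mathrm{NP}$ and
$\mathrm{BIC} = -2LL + \mathrm{NP}\ln N$, with
$\mathrm{NP} = \sum_j (C_j-1)2^{G_j} + 2^K - 1$ for the saturated
model and $\sum_j 2(C_j-1) + 2^K - 1$ for the two-parameter
reductions. Reduced-model fits (`model = "pdina"`/`"pdino"`) apply the
weighted design-matrix projection after every M-step, which is
equivalent to direct MML estimation of the reduced model.

## The simulation harness

`run_study()` reproduces the classification-accuracy design:

* **Attributes** by the multivariate-normal threshold method: latent
  $MVN(0, \Sigma)$ with unit variances and common correlation
  $R = 0.5$, dichotomized at per-attribute thresholds. The thresholds
  default to zero (prevalence 0.5 per attribute) — the natural neutral
  choice when no other value is given — and are configurable for
  sensitivity analysis.
* **True item parameters** from the additive identity-link model with
  equal main effects: per item, $P^*_1(\mathbf 0) \sim U(0, 0.3)$ and
  $P^*_1(\mathbf 1) \sim U(0.7, 1.0)$ with $P^*_2 = P^*_1/2$. This is
  the unique construction that keeps the cumulative ordering
  $P^*_1 \ge P^*_2$, places the stated uniform ranges at the mastery
  extremes, and makes the two above-zero categories contribute equally
  ($P_1 = P_2$ at both extremes); intermediate groups interpolate each
  conditional probability linearly in the fraction of mastered
  required attributes. Parameters are redrawn each replicate.
* **Per replicate**: simulate responses, fit the saturated polytomous
  model, optionally recode to top-category-vs-rest and fit the
  dichotomous saturated model, classify (MAP for the whole pattern,
  marginal-EAP thresholding for single attributes — pattern accuracy is
  a whole-vector criterion, per-attribute accuracy a marginal one, and
  each estimator is optimal for its own criterion), and score accuracy
  against the generating attributes. Bias and RMSE of
  $\hat P_c(\mathbf 0)$ and $\hat P_c(\mathbf 1)$ are pooled over items
  and replicates.
* **Seeding**: replicate $r$ re-seeds deterministically with
  `seed + r`, so any replicate can be reproduced in isolation and the
  whole study is reproducible bit for bit.

The default replicate count in the package's own replication runs is
100 (the full design convention is 500); at 100 replicates the
Monte-Carlo standard error of a cell mean is about 0.005, comfortably
inside the reporting precision. The acceptance script and the test
suite run the J = 20/N = 500 cell (with the dichotomized comparison),
the J = 40/N = 500 cell and the J = 40/N = 1000 cell — the J = 40
Q-matrix is the J = 20 matrix stacked twice — which together exercise
both sample-size and test-length effects at roughly ten minutes of
single-CPU compute.

What the generator does **not** emulate about real data: attribute
hierarchies or non-exchangeable attribute correlations, Q-matrix
misspecification, missing responses, item-specific category counts
within a study cell, and examinee covariates. Passing the replication
cells therefore shows that the estimator recovers the generating
process under the stated conditions — not that any particular empirical
data set satisfies the model's assumptions; for real data, the residual
assessment and post-hoc monotonicity checks are the relevant tools.

## Known limitations

* The practical cap of $K \le 15$ reflects explicit enumeration of all
  $2^K$ classes; larger attribute spaces need structured priors that
  are out of scope here.
* Identifiability is the user's responsibility beyond a warning for
  never-measured attributes: short tests (e.g. three items on two
  attributes) can yield singular information matrices, which the
  package reports as missing standard errors.
* Additive reduced models (one effect per required attribute) are
  generation-only; estimating them requires a second optimization that
  the linear transform cannot replace.
* The residual z-scores rely on the Fisher-transform normal
  approximation; for very small samples ($N < 100$ or so) the
  Bonferroni max-z test is conservative at best.
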