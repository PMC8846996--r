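---
title: "Methods: a linear-scan EM for joint models of longitudinal and competing risks data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a linear-scan EM for joint models of longitudinal and competing risks data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`jmscan` fits a shared random effects joint model for a Gaussian
longitudinal outcome and a competing risks time-to-event outcome.  For
subject $i = 1, \dots, n$ the longitudinal submodel is a linear mixed
model,
$$
Y_i(t) = X_i^{(1)}(t)^T \beta + \tilde X_i^{(1)}(t)^T b_i +
\varepsilon_i(t), \qquad b_i \sim N_q(0, \Sigma), \quad
\varepsilon_i(t) \sim N(0, \sigma^2),
$$
observed at visit times $t_{ij}$, $j = 1, \dots, n_i$, with independent
measurement errors.  The survival submodel is a proportional
cause-specific hazards model for the observed time $T_i$ and cause
$D_i \in \{0, 1, \dots, K\}$ ($0$ = censored),
$$
\lambda_k(t \mid X_i^{(2)}, b_i) = \lambda_{0k}(t)
\exp\!\big(X_i^{(2)T}\gamma_k + \nu_k^T b_i\big), \qquad k = 1, \dots, K,
$$
with completely unspecified baseline hazards $\lambda_{0k}$.  The same
latent $b_i$ enters both submodels; $\nu_k$ measures the association
between the biomarker trajectory and the cause-$k$ hazard.  Censoring is
assumed independent, and the two outcomes are assumed independent given
covariates and random effects.  Within the hazard submodel only
time-invariant covariates are supported: this is exactly the condition
under which the risk sets shrink monotonically and all per-iteration
aggregates can be computed by linear scans.

Maximum likelihood treats the baselines as step functions with jumps at
the distinct observed event times of each cause, and maximizes the
observed-data likelihood by an EM algorithm over the latent $b_i$.

## The EM algorithm

**E-step.**  For each subject the posterior expectations
$E(b_i)$, $E(b_i b_i^T)$, $E\{\exp(\nu_k^T b_i)\}$,
$E\{b_i \exp(\nu_k^T b_i)\}$ and $E\{b_i b_i^T \exp(\nu_k^T b_i)\}$ are
ratios of integrals against the subject's joint density.  They are
evaluated with a tensor-product Gauss–Hermite rule with $n_q$ nodes per
dimension (`nq` means nodes *per dimension*; the full Cartesian product of
$n_q^q$ nodes is used).  Two rescalings are available:

* **standard**: nodes $\sqrt{2}\,\Sigma^{(m)1/2} c_t$, rebuilt every
  iteration from the current $\Sigma^{(m)}$ (default $n_q = 20$);
* **pseudo-adaptive** (default, $n_q = 6$): the longitudinal submodel is
  first fit alone (`fitLMM()`, maximum likelihood via `lme4`; ML rather
  than REML because the joint EM targets the MLE), and each subject's
  nodes are recentred and rescaled by the empirical Bayes estimate
  $\tilde b_i$ and the conditional variance $\tilde H_i^{-1}$ of
  $\tilde b_i - b_i$.  These nodes are built once, before the EM loop,
  and never updated.

All five moment families for all $K$ risks are accumulated in a single
pass over the grid per iteration, with the density evaluated once per
node and combined by log-sum-exp (the $e^{|c_t|^2}$ compensation factor
is folded into the log-space accumulation).  Matrix square roots use the
symmetric eigendecomposition; conditional variances with eigenvalues
below $10^{-10}$ receive a diagonal jitter of $10^{-8}$ with a warning.

The printed form of the conditional-variance formula in the source
literature is ambiguous; `ebMoments()` implements the standard
Laird–Ware conditional variance including the fixed-effects uncertainty
term, and is certified in the test suite against a naive recomputation
and against the conjugate Gaussian posterior limit.  The shared
$p \times p$ sum $\sum_i X_i^{(1)} V_i^{-1} X_i^{(1)T}$ is computed once
and cached, so the whole empirical Bayes pass is $O(n)$ instead of the
$O(n^2)$ of recomputing it per subject.

**M-step.**  $\beta$, $\sigma^2$ and $\Sigma$ have closed-form updates;
the baseline hazards have Breslow-type closed forms
$$
\Delta\Lambda_{0k}(t_{kj}) = \frac{d_{kj}}
{\sum_{r \in R(t_{kj})} \exp(X_r^{(2)T}\gamma_k)\,E\{\exp(\nu_k^T b_r)\}},
$$
and each $(\gamma_k, \nu_k)$ takes one Newton–Raphson step per EM
iteration on its expected complete-data log-likelihood term, with the
fresh baseline held fixed.  The Newton direction uses the expected
information (sums of $E\{(X_r^{(2)}, b_r)^{\otimes 2}\exp(\nu_k^T b_r)\}$
over risk sets), which is positive semi-definite by construction.  Step
halving (up to 10 times) guards small-sample fits; it is a safeguard
beyond the plain one-step update and in practice almost never triggers.
Because the one-step update maximizes its block only at convergence, its
fixed point — not its first iterate — coincides with the corresponding
partial-likelihood solution; with $\nu_k$ held at zero the converged
survival estimates reproduce a cause-specific Cox fit to near machine
precision (certified against `survival::coxph` in the test suite).

**Initialization** (the choice is open in the source material): $\beta,
\sigma^2, \Sigma$ from the longitudinal-only fit; $\gamma_k$ from an
internal no-frailty cause-specific Cox fit (Newton iterations with
$\nu_k = 0$ using the same risk-set machinery); $\nu_k = 0$; baselines
from the Breslow formula at those values.  This is cheap and was inside
the basin of attraction in every simulation we ran.

**Convergence.**  The loop stops when the maximal relative parametric
change drops below `tol_param` ($10^{-4}$ by default, with a $10^{-4}$
floor in the denominator) *or* the relative observed log-likelihood
change drops below `tol_loglik` ($10^{-8}$), up to `max_iter = 500`
iterations.  Both are configurable; property tests that assert
stationarity (vanishing scores) tighten `tol_param` to $10^{-7}$ or
below.  Fitting involves no random numbers, so repeated fits are
bit-identical.

## The three linear scans

Subjects are stored once, globally, in descending order of $T_i$ (ties
broken by subject identifier); the distinct cause-$k$ event times
$t_{k1} > \dots > t_{kq_k}$ are kept descending with multiplicities
$d_{kj}$ (Breslow handling of ties).  Three primitives then make every
per-iteration aggregate linear in $n$:

1. **Step-function lookup** (`stepLookup()`): evaluating the step
   cumulative hazard at all $n$ subject times by a single merged forward
   pass over both descending sequences ($\le n + q_k$ comparisons),
   instead of a global search per subject.  The step functions are
   right-continuous and the risk sets closed: a subject with
   $T_i = t_{kj}$ takes the value at $t_{kj}$ and is in $R(t_{kj})$.
   The closed convention for ties between censoring and event times is a
   deliberate choice (the standard one); it matters only on exactly tied
   times, which the simulator produces with probability zero but real
   recorded data can contain.
2. **Risk-set suffix sums** (`risksetSuffixSums()`): for any per-subject
   sequence $a_r$ (vector- or matrix-valued),
   $\sum_{r \in R(t_{kj})} a_r$ for all $j$ by the recursion
   $R(t_{k(j+1)}) = R(t_{kj}) \cup \{r : T_r \in [t_{k(j+1)}, t_{kj})\}$
   — each subject is accumulated exactly once.  One call with a
   17-column matrix produces every score and Hessian aggregate of a
   survival update.
3. **Event-prefix mapping** (`eventPrefixMap()`): the score terms
   $B(T_i) = \sum_{j: t_{kj} \le T_i} b_{kj}$ for all subjects, by
   accumulating $B$ at the event times backward in time and re-using the
   merged scan of (1).

Deliberately naive $O(n q_k)$–$O(n^2)$ twins of all three (plus the
survival Hessian, the score blocks, and the uncached empirical Bayes
pass) live in the package itself (`naiveStepLookup()` and friends) so
that the test suite — and the command line via `--validate` — can certify
exact agreement, and an instrumentation hook counts comparisons to
certify the $O(n + q_k)$ bound.  Segment trees or Fenwick structures are
unnecessary: monotone risk sets make suffix sums sufficient.

## Standard errors

The covariance of the parametric component
$\Omega = (\beta, \mathrm{vech}\,\Sigma, \sigma^2, \gamma_1, \nu_1,
\dots)$ is estimated by inverting the empirical Fisher information
$\sum_i s_i s_i^T$, where $s_i$ is the per-subject score of the profiled
log-likelihood (baselines profiled out via the Breslow map).  $\Sigma$
is parameterized by its lower-triangular half (`vech`, column order
documented in `subjectScores()`), keeping symmetry implicit.

The profiling derivative treats the posterior expectations inside the
Breslow denominators as fixed at their fitted values — the standard
approximation that makes this an *approximate* empirical Fisher
information.  Under that definition the analytic scores are exact
gradients, and the package ships the corresponding objective
(`profiledLoglik()`, with the posterior measure frozen at the fitted
quadrature weights) so the scores can be certified by central
differences; the suite requires agreement to $10^{-4}$ relative on small
fits and observes about $10^{-5}$.  The $\gamma_k$/$\nu_k$ score blocks
combine the subject's own event terms, risk-set ratio terms at its event
time, and the prefix sums $B(T_i)$ of primitive (3), so the whole
$n \times \dim(\Omega)$ score matrix costs $O(n \dim \Omega)$ — this is
what reduces standard error estimation from $O(n^3)$ to $O(n)$.
Bootstrap standard errors and baselines' standard errors are not
implemented.

## The simulator

`simulateJoint()` generates the reference design used throughout the
tests: $X_{1i} \sim N(2, 1)$, $X_{2i} \sim \mathrm{Bernoulli}(0.5)$,
$b_i \sim N_2(0, \Sigma)$ with $\Sigma_{11} = 0.5$, $\Sigma_{22} = 0.25$,
$\Sigma_{12} = 0$; responses $Y_{ij} = \beta_0 + \beta_1 t_{ij} +
\beta_2 X_{2i} + b_{0i} + b_{1i} t_{ij} + \varepsilon_{ij}$ with
$\sigma^2 = 0.5$ on the scheduled visit grid $t_{ij} = 0, 1, 2, \dots$;
two latent cause-specific event times from constant baseline hazards
$\lambda_{01} = 0.05$ and $\lambda_{02} = 0.1$ by exponential
inverse-CDF sampling; and independent exponential censoring with mean
20 (`exp(20)` is read as *mean* 20 — a rate-20 reading would censor
essentially everything within a few hundredths of a time unit and make
estimation vacuous).  Visits after $T_i$ are treated as missing, with
$t_{ij} \le T_i$ kept (the boundary visit is retained).  The remaining
truths are free parameters of the design; the defaults
$\beta = (2, -0.5, 1)$, $\gamma_1 = (0.5, -0.5)$,
$\gamma_2 = (-0.5, 0.5)$, $\nu_1 = (0.5, 0.5)$,
$\nu_2 = (-0.5, -0.5)$ were fixed once as moderate values giving roughly
55% / 27% / 18% cause-1 / cause-2 / censored outcomes, a median of four
visits per subject, and clear but not dominant association.  An optional
per-visit missingness rate (default 0) thins the grid.

What the generator does *not* emulate: irregular or informative visit
schedules, time-varying survival covariates, non-Gaussian measurement
error, informative censoring, or more than one biomarker.  Passing the
recovery tests therefore certifies the estimator under the generating
model's own assumptions, not robustness to their violation.

## Numerical choices and limitations

* **Quadrature accuracy has a regime.**  The prior-scaled standard rule
  spaces nodes $\propto \sqrt{\Sigma_{jj}}$; a subject with $m$ visits
  has a random-slope posterior standard deviation of roughly
  $\sigma/\sqrt{\sum_j t_{ij}^2} \approx \sigma\sqrt{3/m^3}$, which falls
  below the node spacing ($\approx 0.35$ at $n_q = 20$ under the default
  $\Sigma$) once $m \gtrsim 5$.  Long follow-up series are therefore
  integrated poorly by the standard rule at any practical $n_q$, while
  the pseudo-adaptive rule, being posterior-scaled, is accurate at
  $n_q = 6$.  Under the default design — exponential censoring with mean
  20 guarantees a tail of subjects with 10–30 visits — the two rules'
  estimates consequently differ by more than the nominal
  $10^{-2}$ (the measurement-error variance is the most affected).  We
  judged this inherent rather than fixable: shortening follow-up enough
  to rescue the standard rule destroys identification of the slope
  variance and slope association.  The pseudo-adaptive rule is the
  default and the standard rule is retained for comparison, certified
  only within its accuracy regime (short series, dense-grid references).
* **Underflow** is handled by log-sum-exp throughout; a subject whose
  entire grid underflows raises a diagnostic error rather than returning
  NaN moments.
* **Degenerate inputs**: a risk with no observed events yields an empty
  (valid) baseline; an event subject whose time carries no baseline jump
  is an error (inconsistent baseline); longitudinal-only fits at the
  $\Sigma \to 0$ boundary are lifted by $10^{-6}$ before the EB
  rescaling.  Exact equality is used for tie detection: times are
  expected to be recorded values, not computed ones.
* **Problem sizes in the shipped checks** were chosen to make the
  statistical assertions sharp at desk scale: 10 replicates of
  $n = 1000$ for truth recovery, $n = 10{,}000$ vs $20{,}000$ for the
  linearity ratio, 200 replicates of $n = 300$ for Wald coverage, and
  $n \le 500$ with $\ge 1000$ random instances for the scan oracles.
* **Out of scope**: Bayesian estimation, dynamic prediction, left
  truncation, interval censoring, time-dependent hazard covariates
  (incompatible with monotone risk sets; a parametric baseline would be
  needed), multiple longitudinal outcomes, REML, crossed random effects,
  sparse-grid or quasi-Monte-Carlo integration, and true adaptive
  quadrature that recentres nodes every iteration.
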