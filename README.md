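# jmscan

Fast maximum-likelihood fitting of a **semiparametric joint model** for a
Gaussian longitudinal outcome and a **competing risks** time-to-event
outcome, linked by shared random effects — with every per-iteration
computation and the standard-error step **linear in the number of
subjects**.

For whom: biostatisticians analysing cohorts where a repeatedly measured
biomarker and an event time (with possibly several competing causes, and
informative dropout) must be modelled jointly, at sample sizes where
conventional joint-model implementations become impractically slow.

## Model

For subject *i*, a linear mixed submodel and a proportional
cause-specific hazards submodel share the random effects
*b<sub>i</sub>* ~ *N<sub>q</sub>*(0, Σ):

$$Y_i(t) = X_i^{(1)}(t)^T\beta + \tilde X_i^{(1)}(t)^T b_i + \varepsilon_i(t),
\qquad \varepsilon_i(t)\sim N(0,\sigma^2),$$

$$\lambda_k(t \mid X_i^{(2)}, b_i) = \lambda_{0k}(t)\,
\exp\big(X_i^{(2)T}\gamma_k + \nu_k^T b_i\big),\qquad k = 1,\dots,K,$$

with unspecified baseline hazards λ<sub>0k</sub>.  Estimation is by an
EM algorithm: Gauss–Hermite quadrature in the E-step (a standard
prior-scaled rule, or the default *pseudo-adaptive* rule that recentres
each subject's nodes on its empirical Bayes estimate from a preliminary
mixed-model fit, built once before the loop); closed-form M-step updates
for β, σ², Σ and Breslow-type baselines; one Newton–Raphson step per
iteration for each (γ<sub>k</sub>, ν<sub>k</sub>).  Standard errors come
from the inverse of the empirical Fisher information of the profiled
likelihood.  Three scan algorithms over the descending-time subject
ordering (merged step-function lookup, risk-set suffix sums, event-prefix
mapping) replace the naive *O(n²)*–*O(n³)* aggregations with *O(n)* ones;
deliberately naive reference implementations ship in the package so the
linear algorithms can be certified on any dataset.

## Worked example

```r
library(jmscan)
dat <- simulateJoint(simTruth(n = 300, seed = 7))   # the reference design
fit <- jmFit(dat)                                    # pseudo-adaptive, nq = 6
print(fit)
```

```
Semiparametric joint model (EM, pseudo-adaptive Gauss-Hermite, nq = 6 )
  n = 300 subjects, converged after 29 iterations, log-likelihood -3116.4366
               Estimate     SE        z
beta.intercept   2.0687 0.0720  28.7139
beta.time       -0.5830 0.0447 -13.0471
beta.x2          0.9300 0.1023   9.0931
Sigma[1,1]       0.4566 0.0653   6.9922
Sigma[2,1]      -0.0379 0.0361  -1.0510
Sigma[2,2]       0.2678 0.0327   8.1930
sigma2           0.4844 0.0243  19.9566
gamma1.x1        0.5349 0.1058   5.0572
gamma1.x2       -0.5357 0.1972  -2.7158
nu1.1            0.6364 0.1829   3.4797
nu1.2            0.3212 0.2718   1.1819
gamma2.x1       -0.4516 0.1480  -3.0509
gamma2.x2        0.9145 0.2651   3.4500
nu2.1           -0.2273 0.2706  -0.8399
nu2.2           -0.0801 0.3070  -0.2609
```

The generating truth was β = (2, −0.5, 1), Σ₁₁ = 0.5, Σ₂₂ = 0.25,
Σ₁₂ = 0, σ² = 0.5, γ₁ = (0.5, −0.5), γ₂ = (−0.5, 0.5), ν₁ = (0.5, 0.5),
ν₂ = (−0.5, −0.5): every estimate is within about two standard errors of
its truth.  `nu1.1 > 0` says subjects with higher latent intercepts fail
from cause 1 at a higher rate — the association a separate analysis of
the two outcomes would miss.  `cumBaseHazard(fit, 1, 5) / 5` estimates
the (here constant, 0.05) cause-1 baseline hazard.

A thin command line wraps the same functions:

```sh
jmscan simulate --n 1000 --seed 1 --out-prefix sim
jmscan fit --long sim_long.csv --surv sim_surv.csv --config model.yaml --validate
```

(`--validate` first certifies the fast scans against the naive
implementations on your own data.)

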