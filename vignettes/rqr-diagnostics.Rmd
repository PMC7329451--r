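---
title: "Randomized quantile residuals for diagnosing count regression models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomized quantile residuals for diagnosing count regression models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rqrdiag)
```

## Models

The package fits four regression families for a non-negative integer
response $y_i$:

* **Poisson**: $y_i \sim \mathrm{Pois}(\lambda_i)$;
* **NB**: mean $\lambda_i$, shape $k$, variance $\lambda_i +
  \lambda_i^2/k$ (so $k \to \infty$ recovers the Poisson and small $k$
  means strong over-dispersion);
* **ZIP**: a structural zero with probability $p_i$, otherwise
  $\mathrm{Pois}(\lambda_i)$, giving mass
  $p_i + (1-p_i)e^{-\lambda_i}$ at zero, marginal mean
  $\mu_i = (1-p_i)\lambda_i$ and variance
  $(1-p_i)\lambda_i(1+p_i\lambda_i)$;
* **ZINB**: the same mixture with an NB count component.

The count mean uses a log link, $\log \lambda_i = X_i^\top\beta$, and the
structural-zero probability a logit link, $\mathrm{logit}(p_i) =
Z_i^\top\gamma$. All PMF/CDF evaluation is done on the log scale
internally (mixture masses at zero via a log-sum-exp), so small $\lambda$
or large $y$ do not underflow. The lower CDF limit on integer support is
$F(y-) = F(y-1)$ with $F(-1) \equiv 0$.

## Estimation

`fit_count_model()` maximizes the joint log-likelihood over
$(\beta, \gamma, \log k)$ with BFGS and analytic gradients. Choices that
matter:

* $k$ is estimated on the log scale, making the problem smooth and
  unconstrained; its standard error is reported on that scale.
* Starting values: $\beta$ from a Poisson working fit; the $\gamma$
  intercept from the logit of the observed excess-zero fraction
  (floored at $10^{-3}$); $k$ by method of moments, clipped to
  $[0.05, 10^4]$. These are robust for zero-inflated mixtures, where a
  cold start can stall in a flat region of the likelihood.
* Out-of-range proposals during line search (an overflowing
  $\exp(X\beta)$) receive a large finite penalty rather than an error, so
  the optimizer backtracks.
* Standard errors come from the inverse observed information (numerical
  Hessian at the optimum). When the data carry no evidence of zero
  inflation the zero-part intercept drifts to a large negative value
  ($\hat p \approx 0$) with an enormous SE; this is reported as-is rather
  than treated as a failure, because it is the correct summary of a
  boundary fit.
* A fit is flagged `converged` only if the optimizer reports success
  *and* the score has max-norm below $10^{-3}(1+|\ell|)$. Diagnostics
  refuse unconverged fits.

## Residuals

Four residual types are computed from a fit:

* **Pearson** $(y_i-\hat\mu_i)/\sqrt{\widehat V(y_i)}$, with the
  family-specific variance. For ZINB the denominator uses the
  conventional printed form
  $(1-\hat p)(\hat\lambda + \hat\lambda^2/k) + \hat\lambda^2(\hat p^2 +
  \hat p)$; note this differs from the exact ZINB variance, whose last
  term is $\hat\lambda^2 \hat p(1-\hat p)$. The distribution utilities
  (`count_mean_var()`) return the exact variance; the Pearson residual
  keeps the conventional scaling so its values match what practitioners
  of this diagnostic expect.
* **Deviance** $\mathrm{sign}(y_i-\hat\mu_i)\sqrt{d_i}$ with
  $d_i = 2(\ell_{\mathrm{sat},i} - \ell_{\mathrm{fit},i})$. The saturated
  model is Poisson$(y_i)$ for Poisson *and* ZIP, and NB$(y_i, \hat k)$
  for NB and ZINB — the saturated mixture degenerates to its count
  component. A $d_i$ below $-10^{-10}$ raises an error (it would mean the
  "saturated" model is not actually saturated); smaller negatives are
  floating-point noise and are clamped to zero.
* **MQR**: $\Phi^{-1}\{F(y_i-) + 0.5\,p(y_i)\}$, deterministic.
* **RQR**: $\Phi^{-1}\{F(y_i-) + u_i\,p(y_i)\}$ with
  $u_i \sim U(0,1)$. The PIT value is clipped to
  $[10^{-16}, 1-10^{-16}]$ before inversion so that a catastrophic misfit
  (a huge count under a Poisson fit) yields a large finite residual
  instead of $\pm\infty$, keeping the Shapiro-Wilk statistic computable.
  An equivalent formulation draws $u$ uniformly between $F(y-)$ and
  $F(y)$; it is algebraically identical and not separately implemented.

RQRs are standardized by default to mean 0 and unit sample variance
($n-1$ denominator), per vector, after randomization. The SW test is
location-scale invariant, so standardization changes no p-value; it makes
the residuals directly comparable to N(0,1) in plots and summaries.
Supplying `seed` makes a draw bitwise reproducible while leaving the
caller's RNG stream untouched.

## Goodness of fit

`sw_gof()` applies the Shapiro-Wilk normality test to a residual vector
(valid for $3 \le n \le 5000$; larger samples are refused with advice to
subsample rather than silently switching to another normality test — the
procedure is SW-specific). Because one RQR draw is random,
`replicated_sw()` repeats the draw $R$ times and reports the p-value
vector, its mean, and the proportion above a level $\alpha$. No
significance is attached to the mean p-value: its null distribution is
an open question, so the summary is descriptive.

`moments_summary()` reports mean, variance ($n-1$), skewness
$m_3/m_2^{3/2}$ and excess kurtosis $m_4/m_2^2-3$ with population-style
central-moment estimators — the simplest convention, adequate at the
sample sizes involved. It is reported for raw and standardized residuals
alike; note the first two moments of a standardized vector are 0 and 1
by construction, so only the shape measures carry information there.

`qq_envelope()` implements the classical simulate-refit envelope:
simulate `n_sim` (default 100) responses from the fitted parameters on
the same design, refit the same family to each, sort each refit's
residuals, and take the 2.5%/97.5% percentiles per order statistic
(linear interpolation between order statistics). Theoretical quantiles
use the normal-scores approximation $\Phi^{-1}\{(i-3/8)/(n+1/4)\}$.
Refits that fail are dropped and counted; more than 10% failures aborts
the envelope, since the bands would no longer mean what they claim. The
envelope is built around *refit* residuals, so it accounts for parameter
estimation noise; its pointwise coverage makes roughly 5% of order
statistics fall outside under a correct model, which is what the
`prop_outside` summary is calibrated against in the test suite.

## Simulation harness

The generators encode the study conditions under which the diagnostics
were evaluated:

| scenario | truth | wrong model | parameter |
|---|---|---|---|
| `illustrative` | Poisson, $\log\mu = -1+2\sin 2x$, $x\sim U(0,2\pi)$ | linear-in-$x$ Poisson | — |
| `nonlinearity` | NB, $\log\mu = \beta_1 x^2$, $x\sim U(-1.5,1.5)$, $k=2$ | linear-in-$x$ NB | $\beta_1 \in \{0.5,1,2\}$ |
| `overdispersion` | NB, $\log\mu = 1+2x$, $x\sim U(-1,2)$ | Poisson, same mean | $k \in \{1,2,10\}$ |
| `zeroinflation` | ZIP, $\lambda=e^{1+2x}$, $x\sim U(-1,2)$, constant $p$ | Poisson, same $\lambda$ | $p \in \{0.1,0.3,0.5\}$ |

The NB dispersion is parameterized directly by the shape $k$ (variance
$\lambda+\lambda^2/k$); the generators default to the middle setting of
each scenario. `run_type1_power()` simulates, fits the true and/or the
wrong model, computes all four residual types (one standardized RQR draw
per replicate — replicated-RQR averaging is a separate diagnostic, not
part of the rejection-rate design), SW-tests each, and tabulates
rejection rates with Monte-Carlo standard errors
$\sqrt{r(1-r)/\text{reps}}$. Replicates whose fit does not converge are
excluded and counted, not scored as rejections. A master seed spawns one
substream per replicate, so runs are fully reproducible and
embarrassingly parallel in structure.

The default of 1000 replicates per cell gives an MC SE of about 0.007 at
a 5% rate — enough to check calibration claims at desk scale; the
package's test suite uses 1000 replicates at $n=400$ for the type-I-error
check, 300 replicates at $n=1000$ for the power checks, and 100
replications of a 100-simulation envelope at $n=200$ for envelope
coverage. Scaling `reps` up (e.g. to 5000) is a config knob, not a code
change.

## What the generators do and do not emulate

The simulations cover independent observations, a single continuous
covariate, correctly specified links, and three canonical
misspecifications (curvature, over-dispersion, zero inflation). They do
not emulate clustered or longitudinal dependence, covariate measurement
error, many-covariate designs with collinearity, or hurdle-type zero
processes. A clean bill of health from these tests therefore supports the
implementation's correctness and the diagnostics' behaviour under the
stated conditions — it does not certify performance on data with
structure the generators never produce.

## Known limitations

* The SW-based test is mildly conservative in some true-model scenarios
  at moderate $n$ (parameter estimation pulls residuals slightly toward
  normality); the type-I-error machinery in the test suite measures this
  directly rather than assuming exact nominal behaviour.
* The zero part of a ZI fit is weakly identified when zero inflation is
  absent; expect boundary estimates with huge SEs, not errors.
* `shapiro.test`'s $n \le 5000$ limit is inherited deliberately.
* Deviance residuals for the ZI families depend on the saturated-model
  convention described above; other conventions exist and would shift
  the residuals, though not the qualitative diagnostics.
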