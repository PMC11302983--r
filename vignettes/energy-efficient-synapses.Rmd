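---
title: "Energy-efficient synaptic noise: model, training and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-efficient synaptic noise: model, training and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effsyn)
```

## The question

Synaptic transmission is noisy, yet some synapses transmit almost without
failure, so the noise is not a hard constraint — it is a choice. `effsyn`
implements a normative account: precision has an energetic price, and a
circuit minimising task error *plus* energetic costs will buy precision only
where it matters. The package covers the full chain of that argument:
biophysical cost scalings, networks with trainable Gaussian synapses,
diagnostics tying the optimised variability to synapse importance, and the
formal connection to variational Bayesian inference.

## Quantal release and the four reliability costs

Under the binomial quantal model, `n` docked vesicles each release with
probability `p`, each contributing a PSP of size `q`:
$$\mu = npq, \qquad \sigma^2 = np(1-p)q^2.$$
Quantal size is taken constant across vesicles within a PSP (variability is
attributed to release, not to `q`), and scales with vesicle volume,
$q \propto r^3$.

Each cost mechanism is analysed at *fixed PSP mean*: one biophysical
variable is swept and another absorbs the mean constraint, with all
proportionality constants set to 1 (the data constrain scalings, not
absolute ATP budgets).

* **Trafficking, actin, surface** sweep the vesicle radius `r` at fixed
  `p`, with $q = r^3$ and $n = \mu/(pq)$. Then
  $\sigma^2 = \mu(1-p)r^3$, so $\sigma \propto r^{3/2}$, and a cost
  $n r^k$ scales as $r^{k-3} = \sigma^{2(k-3)/3}$: exponents $-2$
  (trafficking, $k=0$), $-4/3$ (actin, $k=1$) and $-2/3$ (surface,
  $k=2$). These are exact power laws at every point of the sweep.
* **Calcium** sweeps the release probability `p`, with release coupled to
  calcium through a Hill equation $p = Ca^m/(K^m + Ca^m)$ and the cost of
  pumping calcium back out proportional to $Ca = K\,(p/(1-p))^{1/m}$. The
  mean constraint is absorbed by the quantal size at fixed `n`
  ($q = \mu/(np)$), under which
  $$\frac{p}{1-p} = \frac{\mu^2}{n\,\sigma^2}$$
  holds *exactly*, so the cost is an exact power law
  $\sigma^{-2/m}$ over the whole sweep — $\sigma^{-1/2}$ at the default
  Hill coefficient $m = 4$, the value consistent with the steep calcium
  cooperativity of release. Had the mean instead been absorbed by `n` at
  fixed `q`, the local slope would be $-1/(2p)$, reaching $-1/2$ only
  asymptotically as $p \to 1$; the q-elimination was adopted because it
  reproduces the printed exponent exactly and is equally legitimate
  biophysically (a synapse can trade quantal size as well as vesicle count
  against release probability). The default calcium sweep still runs over
  the high-reliability segment $p \in [0.9, 0.999]$.

`fit_power_exponent()` recovers each exponent from the generated curves to
floating-point accuracy, and the test suite pins each curve against the
closed-form elimination above, pointwise.

## The objective

Training minimises, over synaptic means $\mu_i$ and noise levels
$\sigma_i$,
$$\text{performance} + \lambda\sum_i|\mu_i| + c\sum_i\sigma_i^{-\rho},$$
with cross-entropy as the performance cost. Parameters, units and defaults:

| parameter | meaning | default |
|---|---|---|
| `c` | reliability-cost weight (energy per unit of $\sigma^{-\rho}$, arbitrary units) | experiment-specific |
| `rho` | power-law exponent of the dominant mechanism | 2 |
| `lambda` | L1 magnitude-cost weight | 1e-4 |
| `s` | scale at which the power-law cost touches the entropy bound | 0.01 |

Noise is parameterised as $\sigma_i = \mathrm{softplus}(\phi_i)$, keeping
$\sigma_i > 0$ structurally rather than by clipping. Biases are
deterministic, trained, and excluded from both energetic costs: the costs
index synapses, and a bias is not a synapse.

**Entropy bound.** For any $\sigma, \rho, s > 0$,
$$\frac{s^\rho}{\rho}\sigma^{-\rho} - \log s - \frac1\rho \;\ge\; -\log\sigma,$$
an instance of $\log x \le x - 1$ at $x = (\sigma/s)^{-\rho}$, with
equality exactly at $\sigma = s$. With the tangency choice
$c = s^\rho/\rho$ (`c_from_scale()`), the power-law reliability cost
therefore upper-bounds the negative-entropy term of the evidence lower
bound, and the whole objective upper-bounds the negative ELBO up to
additive constants: lowering the energetic cost tightens a variational
bound. The Gaussian entropy's additive constant $\tfrac12\log 2\pi e$ is
dropped throughout — only differences and bounds are ever used. Two
conventions for `s` appear in the experiments: reporting reliability costs
on a common axis uses $s = 1$ (so the reported cost is
$\rho^{-1}\sum\sigma^{-\rho}$), while the variability-diagnostics runs use
$s = 0.001$, which places the cost scale in the regime where trained
$\sigma$ spreads over decades.

## Training

Each step draws one weight sample per minibatch by the reparameterisation
$w_i = \mu_i + \sigma_i\xi_i$ (per-example sampling is available via
`network_config(sample_per_example = TRUE)`; per-minibatch is the default
because the sampling granularity is not otherwise constrained and it is the
cheapest standard practice). Backpropagation gives, with $g_i$ the gradient
with respect to the realised weight,
$$\partial_{\mu_i} = g_i + \lambda\,\mathrm{sign}(\mu_i), \qquad
\partial_{\phi_i} = \left(g_i\xi_i - c\rho\,\sigma_i^{-\rho-1}\right)
\mathrm{sigmoid}(\phi_i).$$
Updates are Adam's: the per-parameter rate
$\eta_i = \eta_{\text{base}}/\sqrt{\langle g_i^2\rangle}$ makes important
synapses learn slowly, which is itself one of the model's predictions. In
homogeneous mode a single $\phi$ is shared by the whole network and
receives the summed gradient (per-layer sharing is available as an option).

Numerical choices:

* The reliability gradient applies a floor $\max(\sigma, 10^{-8})$ inside
  $\sigma^{-\rho-1}$ only: at the initial $\sigma = 10^{-4}$ with large `c`
  the raw gradient would overflow. Reported $\sigma$ values are never
  floored.
* Divergence (a non-finite objective term at an epoch boundary) aborts with
  an error naming the offending term.
* All randomness (initialisation, batch order, noise draws) derives from one
  integer seed, and every generator restores the caller's RNG state, so runs
  are bit-reproducible.

**Optimiser memory at reduced scale.** The full-size regime (784-100-100-10,
50 epochs, minibatch 20, $\eta_{\text{base}} = 5\times10^{-4}$,
$\beta_2 = 0.999$) takes roughly $10^5$ gradient steps. The package's
reduced-scale experiments (4 classes, 100 features, 4000 samples, widths
100-32-32-4, 30 epochs) take ~5000. That difference interacts with the
adaptive rate: starting from $\sigma = 10^{-4}$, the reliability gradient
is enormous and then decays exponentially as $\phi$ climbs. When the
gradient decays faster than the second-moment memory forgets, the
normalised update shrinks geometrically and the climb speed is capped by
$\beta_2$, *not* by $\eta_{\text{base}}$ — with $\beta_2 = 0.999$ the noise
parameters cannot reach their `c`-dependent stationary values within a few
thousand steps (empirically, all `c > 0` runs then produce identical
$\sigma$ trajectories). The reduced-scale configuration therefore uses
$\beta_2 = 0.99$ with $\eta_{\text{base}} = 5\times10^{-3}$, under which
the sweep reproduces the qualitative tradeoff; `train_config()` defaults
keep the long-schedule values. The same short-memory setting is used by the
quadratic-toy and variational fitters, which run a few thousand steps.

**Quadratic toys as ground truth.** On
$L(w) = \sum_i \tfrac12 h_i (w_i - w_i^*)^2$ the Hessian is exactly
$\mathrm{diag}(h)$ and the expected objective in each $\sigma_i$ is
$\tfrac12 h_i\sigma_i^2 + c\sigma_i^{-\rho}$, with stationary point
$\sigma_i^* = (c\rho/h_i)^{1/(\rho+2)}$. `train_quadratic()` recovers this
to a fraction of a percent (median) across curvatures spanning three
decades; reported $\sigma$ averages the final quarter of the trajectory to
smooth sampling jitter around the stationary point, as does the variational
fitter.

## The synthetic task

`make_classification_task()` emulates the two properties of
handwritten-digit data the experiments rest on: (i) class structure easily
learnable by a small MLP, via Gaussian class templates with within-class
jitter clipped to $[0,1]$; and (ii) per-feature mean activation ("input
rate") spanning orders of magnitude, via a per-feature scale drawn
log-uniformly from $[10^{-h}, 1]$ (default $h = 3$, matching the
several-decade spread of per-pixel means in digit images). Splits default
to 80/10/10 train/val/test; a validation split exists because
hyperparameters are meant to be chosen on it.

What the generator does *not* emulate: spatial pixel correlations, class
manifolds of realistic complexity, label noise, and the coupling between a
feature's mean rate and its class-discriminative content. Passing tests on
this task therefore demonstrate the mechanism — precision allocation under
energetic costs — not image-classification performance. A reader with real
digit data can use `load_idx_images()` (IDX format) and the `"paper"`
scale of `experiment_config()`.

## Diagnostics

`empirical_fisher()` freezes $w = \mu$ and averages squared per-synapse
performance-cost gradients over 10 passes of the training data — the
empirical Fisher approximation $H_{ii} \approx \langle g_i^2\rangle$ to
the Hessian diagonal. A presynaptic unit that never fires yields exactly
zero importance for its outgoing synapses. `diagnostics_report()` analyses
the weights between the two hidden layers by default (the layer with both
presynaptic and postsynaptic heterogeneity), pairing $H_{ii}$, the
adaptive rate $\eta_i = \eta_{\text{base}}/(\sqrt{H_{ii}} + \epsilon)$,
the presynaptic mean absolute rate, and $\sigma_i^2$.

The three signatures are tested as *signs* of Spearman rank correlations on
log axes — importance–variance negative, learning-rate–variance positive,
rate–variance negative — because the trends are monotone but heavy-tailed
and no magnitude is pinned by theory. Pairs with non-positive entries
(silent units, exactly-zero gradients) are dropped and counted.

## The Bayesian comparison

The Laplace route, $\sigma_{\text{post}} = H_{ii}^{-1/2}$, is the default
posterior-spread estimate: deterministic, cheap, and exact for quadratic
problems. Combining it with the analytic noise level gives the slope law
$$\log\sigma_i^* = \text{const} + \frac{2}{\rho+2}\,\log\sigma_{\text{post},i},$$
so the fitted log-log slope equals $2/(\rho+2)$ exactly for the analytic
noise and within sampling error for trained noise. The slope is below one
for every $\rho > 0$ — energy-efficient variability is systematically
*less heterogeneous* than posterior uncertainty — and approaches one as
$\rho \to 0$. For comparisons across exponents, `c` is set by the tangency
convention $c = s^\rho/\rho$ at $s = 10^{-2}$, which keeps the noise scale
comparable across $\rho$; the multiplier sweep fixes $\rho = 1/2$ and uses
the grid $\{0.112, 0.2, 0.356\}$.

`fit_variational_posterior()` is the independent cross-check: mean-field
Bayes by backprop on linear-Gaussian models, where the conjugate posterior
is known in closed form. One caveat it makes explicit: on correlated
designs, mean-field variational inference recovers the *diagonal-precision*
spread (the Laplace value), not the marginal posterior sd, so exact
agreement with the full posterior is asserted only for the one-weight
model.

## Problem sizes

The shipped experiments and tests run at: reduced task 4×100×4000 with
widths 100-32-32-4 (1024 synapses in the analysed layer), 30 epochs;
quadratic ensembles of 20 synapses with curvatures over three decades,
4000 steps; variational fits of ≤3 weights, 3000 steps; cost curves of 50
points. These sizes were chosen so a full reproduction runs on one CPU in
a few minutes while every qualitative result — the four exponents, the
tradeoff, the three correlation signs, the slope law, the entropy bound —
remains intact.

## Known limitations

* No off-diagonal Hessian anywhere: importance, Laplace spread and the
  analytic noise are all diagonal notions.
* Quantal size is noiseless within a PSP; quantal variability would add a
  $\sigma$ floor the cost curves do not model.
* Costs attach to synapses only; biases carry neither noise nor cost.
* The reduced-scale tradeoff uses one exponent ($\rho = 2$) for the
  acceptance sweep; the pipeline runs all four, at proportionally higher
  cost.
* Mean accuracy under noise is estimated from 10 weight samples by
  default; mean-weight evaluation is available and is used for the
  per-epoch history.
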