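---
title: "Context models and multifilter LN models for spiking neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context models and multifilter LN models for spiking neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfctx)
```

## The modelling problem

A sensory neuron is probed with a binary bar movie: each frame shows
`nBars` bars, each independently dark or bright, presented at 60 Hz, and the
response is the spike count $y_i$ in each frame. A receptive-field (RF)
model maps the recent stimulus history — the input vector $x_i$, a
bars-by-lags window ending at frame $i$ (16 bars by 16 frames, i.e. 267 ms,
in the canonical geometry) — to a similarity score $z_i$ and then through a
static nonlinearity $f$ to a predicted rate $\hat y_i = f(z_i)$.

`rfctx` implements and compares two families of extensions of the classical
single-filter linear-nonlinear (LN) model:

* **Context models.** One RF plus one or more *context fields* (CFs). Each
  RF element $x_{ij}$ is multiplicatively gated by the dot product between a
  CF and the local stimulus patch $\tilde x_{ij}$ around that element:
  $$z_i = w_0 + \sum_l \sum_{j \in ctx_l} w^{rf}_j x_{ij}
  \bigl(1 + \textstyle\sum_k w^{cf_l}_k \tilde x_{ijk}\bigr).$$
  The CF expresses the stimulus context a cell needs before an RF element
  can drive it; the assumption is that a few local contexts, not a
  low-dimensional subspace, shape the response.
* **Multifilter LN models.** A small set of linear filters spans the
  stimulus subspace that matters, and a free (histogram) nonlinearity maps
  the joint projection to a rate. Estimators: spike-triggered covariance
  (STC), the Gaussian information-maximizing subspace search (iSTAC),
  low-rank quadratic models fitted by maximum noise entropy (MNE), and
  direct single-spike-information maximization (MID).

Both families are scored with the same primary measure — bias-corrected
single-spike information between scores and spikes — plus the Pearson
correlation between predicted and observed responses as a secondary measure,
under a shared five-fold protocol.

## Fitting context models

The joint problem is non-convex because RF and CF weights multiply each
other, but it is convex in either field alone. `alternatingFit()` therefore
alternates two convex subproblems: solve for the RF with the CFs fixed, then
for all CFs with the RF fixed. The score is linear in the active field,
$z_i = w_0 + k_i + w^\top \nabla_w z_i$, where the per-sample constant $k_i$
is zero in the RF step and $w_0 + w_{rf}^\top x_i$ in the CF step. Each
subproblem is a linear, logistic, or Poisson regression — corresponding to
an identity, logistic, or exponential model nonlinearity — of the form
$$L = C \sum_i \ell(y_i, z_i) + \tfrac12 \lVert \Gamma w \rVert^2 .$$
The linear case has the closed-form solution
$w = (A^\top A + \tfrac{1}{2C}\Gamma^\top\Gamma)^{-1} A^\top (y - k)$; the
logistic and Poisson cases are solved by a damped Newton method with
analytic gradient and Hessian (the per-sample offset $k_i$ is why stock GLM
routines cannot be substituted). Logistic fits use signed targets
$\tilde y_i = -1$ iff $y_i = 0$ and weights $\beta_i = \max(y_i, 1)$, so
multi-spike frames count multiple times.

Settings that matter:

* **Regularization.** `regKind = "l2"` (ridge) or `"laplacian"` — the
  two-dimensional discrete Laplace operator over the field grid, favouring
  smooth fields. The algorithm iterates at fixed `C = 0.1` until the
  relative loss decrease falls below 0.01 % (`convRel = 1e-4`), then runs
  one extra iteration in which `C` is chosen by 5-fold cross-validation on
  the training data, independently for the RF and the CF step, over a
  log-spaced grid $10^{-3}\dots10^2$ (11 points; ties go to the strongest
  regularization). Selecting `C` jointly for the two steps would also be
  defensible; we chose independent selection because the two fields have
  very different sizes and smoothness.
* **CF geometry.** The window is configurable; the default is 9 bars by 9
  lags with the origin three elements from the right edge (so two future
  frames can carry suppressive or facilitating context) and centered
  spatially. The origin coefficient is structurally zero — the CF contains
  interaction terms only. Context windows are padded with zeros outside the
  stimulus, so out-of-range cells contribute nothing to any dot product.
* **Initialization.** RF from a regularized GLM with all CFs at zero; CFs
  from zero plus seeded jitter of standard deviation $10^{-3}$ (the exactly
  zero field is a stationary point of the CF step only when the RF is also
  zero, but the jitter costs nothing and guards the degenerate corner).
* **Sign convention.** RF–CF sign flips leave the data fit almost unchanged,
  so when a fitted RF's most negative entry exceeds its most positive in
  magnitude, `flipAndRestart()` negates all fields and re-runs the
  alternating loop to completion.
* **Monotonicity.** The trace of the joint regularized loss is checked to be
  non-increasing across outer iterations at fixed `C`; an increase beyond
  numerical tolerance aborts the fit with diagnostics, since it would mean a
  subproblem was not solved.

Double-CF space-time-intensity models (`fitDoubleCfIntensity()`) run on the
concatenated bright+dark basis (dark bars coded 1 in the dark half, bright
bars in the bright half): stage one fits a single shared CF, stage two
re-fits with one CF for the bright half of the RF and one for the dark half,
both initialized from the stage-one field.

## Multifilter estimators

`spikeTriggeredStats()` forms the count-weighted spike-triggered average
$\mu$ and covariance $\Lambda$; by default the design is standardized first,
which for i.i.d. binary bars is an exact whitening. STC filters are the
eigenvectors of $\Lambda$ whose eigenvalues deviate most from the stimulus
variance (catching excitatory and suppressive directions alike); *null
features* are the eigenvectors closest to the stimulus variance and carry no
stimulus–response information.

iSTAC maximizes the Gaussian information of the subspace spanned by
orthonormal columns $B$,
$$I(B) = \frac{\mathrm{Tr}\!\left(B^\top(\Lambda + \mu\mu^\top)B\right)
  - \ln\lvert B^\top \Lambda B \rvert - m}{2\ln 2}\ \text{bits},$$
the KL divergence between the Gaussian spike-triggered ensemble and the
whitened prior. The gradient
$\bigl((\Lambda+\mu\mu^\top)B - \Lambda B (B^\top\Lambda B)^{-1}\bigr)/\ln 2$
drives a greedy projected-gradient search (each new column initialized from
the best of the STA direction and leading STC eigenvectors, re-orthonormalized
every step, 500-step cap, tolerance $10^{-6}$). Binary bars violate the
Gaussian assumption behind STC and iSTAC; the estimators are implemented
as-is and their resulting disadvantage on such stimuli is expected.

MNE fits the quadratic-logistic model $z_i = c + x_i^\top v + x_i^\top J x_i$
by weighted logistic maximum likelihood with an $\ell_2$ penalty; quadratic
features are formed on the fly (never an $N \times d^2$ matrix) and the
optimizer is L-BFGS on the analytic gradient, with $J$ symmetrized on exit
(scores are invariant under symmetrization). Low-rank selection keeps the
$N_{filters}-1$ eigenvectors of $J$ with the largest absolute eigenvalues,
projects them out of $v$, and picks the final filter as the $v$-residual or
the next eigenvector, whichever scores higher single-spike information.
Selected filters can then be refined by gradient descent on the low-rank
logistic loss, with the regularization strength and stopping point chosen on
a hold-out validation set; the first-stage `C` is instead chosen by training
performance, which empirically yields structured rather than noisy filters
and is corrected by the validated refinement stage.

MID (`midAscent()`) refines any initial model — filter banks or context
models — by ascending the histogram estimate of single-spike information.
The bin-wise gradient uses conditional mean score-gradients and a
finite-difference derivative of $P(z|spike)/P(z)$ across bins. Declared
settings, chosen once: 15 bins per dimension during ascent (coarser than
evaluation, to tame gradient noise), relative step
$0.05\,\lVert\theta\rVert/\lVert\nabla\rVert$ with geometric backoff, at most
200 steps, early stopping at the iterate with the highest validation
information (so refinement never ends worse than its initialization by that
measure). Histogram MID is limited to two score dimensions. Filters are
re-normalized after every step; this also suppresses the spurious radial
(pure-rescaling) component that the discretized gradient formula acquires at
finite bin width.

Because the ascent objective is non-convex, a single starting subspace can
converge to a local optimum well below the attainable information — we
observed stalls some 0.2 bits under the value reached from the generating
filters on the simulated two-input cell. `fitBestLn()` therefore runs the
ascent from three standard starting points (STC, iSTAC, and the leading
low-rank filters of an MNE fit on standardized inputs) and keeps the run
with the highest validation information; this multi-start fit is what the
network comparisons use.

## Information evaluation and finite-sample bias

`singleSpikeInfo()` computes
$I = \sum_b P(z_b|spike)\log_2[P(z_b|spike)/P(z_b)]$ from shared-edge
histograms in which every frame counts once in $P(z)$ and $y_i$ times in
$P(z|spike)$. Histogram estimates are biased upward in small samples,
especially in two dimensions. Two corrections are implemented:

* **Null-feature correction** (`biasCorrectedInfoNull()`): information
  measured on null-feature projections estimates the bias as a function of
  the average number of occupied bins; the sampled curve is interpolated
  linearly (constant beyond its ends) at the occupancy of the scores under
  evaluation and subtracted. Ten null features are used by default (the
  count is a declared default; fewer than three triggers a warning).
* **Quadratic extrapolation** (`biasCorrectedInfoQE()`): naive information on
  random subsamples at fractions $1.0, 0.9, \dots, 0.5$ (10 repeats,
  seeded), quadratically extrapolated in $1/N$ to infinite data.

Both are computed per histogram resolution; the reported value is the mean
of the corrected estimates over 25–35 bins per dimension, where the
corrected curve is flat for well-sampled scores. The output nonlinearity
(`estimateNonlinearity()`) uses Bayes' rule
$f(z) = P(spike)\,P(z|spike)/P(z)$ at 20 bins per dimension; empty bins fall
back to the global mean rate and out-of-range test scores clamp to edge
bins, so predictions are always finite. The construction conserves the mean
rate exactly.

`crossvalProtocol()` splits the samples into five contiguous temporal blocks
(contiguity respects the temporal dependence of the lagged design; shuffled
folds would leak train information into test windows), holds each block out
for testing once, and splits the remainder 80/20 (in temporal order) into
training and validation. For 1,000 usable samples this gives 200 test, 640
training, and 160 validation samples per fold. Reported values are means
over the five folds with their standard errors, and `normalizedScores()`
expresses each model relative to the best model of the cell.

## The synthetic complex cell

`simulateComplexNetwork()` generates all test data: nine leaky
integrate-and-fire (LIF) input cells with one shared spatiotemporal RF
template, each shifted by one bar, drive a LIF output cell through
excitatory depressing synapses — the hierarchical picture of a complex cell.
Depression follows the standard resource model: a presynaptic spike releases
$w\,u\,R$ and depletes $R \to R(1-u)$; between spikes $R$ recovers as
$dR/dt = (1-R)/\tau_{rec}$, with $u = 0.9$ and $\tau_{rec} = 200$ ms. The
simplified variant keeps only bank positions 4 and 6 and disables
depression, approximating a cell driven by a two-dimensional stimulus
subspace.

The LIF constants and the RF template are declared defaults of this package
(the comparison frameworks do not pin them): membrane time constant 20 ms,
threshold 1 over reset 0, absolute refractory period 2 ms, Euler step 1 ms,
per-step Gaussian membrane noise of standard deviation 0.02, input gain 1.6
and synaptic weight 0.9 (sub-threshold, so the output integrates over
coincident input spikes), and a center-surround spatial profile
$(-0.5, 1, -0.5)$ with a biphasic two-frame temporal kernel. These values
were fixed once, to give physiological rates (roughly 10 Hz inputs, 8 Hz
output on the depressing network) and sparse output spiking, and are all
exposed through `networkConfig()`/`lifParams()`. With them, the depressing
network is far better described by a single-CF context model than by a
two-filter LN model, and the ordering reverses on the simplified two-input
network, with absolute bias-corrected information close to the values the
original study conditions produce for the context models on both networks
and for the LN model on the simplified one. The two-filter information on
the depressing network sits lower than in the original study conditions: in
this network family the nine shifted input RFs span a stimulus subspace that
is poorly approximated by any two dimensions, so the two-filter ceiling —
which we verified against an oracle quadrature pair built from the
generating templates — is itself low. The orderings, not the absolute
values, are the robust claims of the comparison.

What the simulator does *not* emulate about recorded data: slow drifts in
responsiveness and adaptation beyond synaptic depression, correlated
(non-white) stimuli, bursting and other non-Poisson spike statistics, and
measurement artifacts. Passing parameter-recovery and ordering tests on
these synthetic data therefore demonstrates correctness of the estimators
under the stated model family, not performance on any particular recorded
cell.

The package also provides LN-Poisson and context-Poisson generators
(`generateLnPoisson()`, `generateContextPoisson()`) used by the
parameter-recovery tests: Poisson counts per frame with rate $f(z_i)$ under
a known planted model.

## Numerical choices and degenerate inputs

* Newton solver tolerance $10^{-3}$ (relative gradient norm), step halving
  on any non-finite or increasing loss, 100-iteration cap; the outer
  alternating loop is capped at 100 iterations.
* A singular linear subproblem without regularization falls back to the
  pseudoinverse and flags the result.
* Constant scores occupy a single histogram bin and carry zero information;
  zero-spike inputs are errors everywhere a spike-conditional distribution
  is required.
* Ties in cross-validation scores resolve to the smallest `C` (strongest
  regularization).
* Degenerate subsamples without spikes are redrawn inside the quadratic
  extrapolation.

## Limitations

* Histogram MID supports at most two filters; beyond that the method's own
  density estimates break down.
* The STC/iSTAC estimators assume (approximately) whitened Gaussian
  stimuli; on binary bars they are consistent only up to that approximation.
* Bias correction for two-dimensional scores can under-correct on short test
  sets; the residual positive slope of corrected information versus
  resolution is a useful warning sign.
* Subunit models, explainable-variance analysis for repeated stimuli, and
  online estimation are out of scope.
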