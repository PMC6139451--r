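# rfctx

Receptive-field models for spiking sensory neurons driven by binary bar
stimuli, built to compare two modelling frameworks on equal terms:

* **Context models** — a single receptive field (RF) whose elements are
  multiplicatively gated by *context fields* (CFs), local windows that
  describe the stimulus context a cell needs before an RF element can drive
  it. The similarity score is
  z_i = w0 + Σ_l Σ_{j∈ctx_l} w_j^rf x_ij (1 + Σ_k w_k^cf_l x̃_ijk),
  fitted by alternating convex subproblems (linear, logistic, or Poisson
  regression — identity, logistic, or exponential nonlinearity), with l2 or
  discrete-Laplacian smoothing and cross-validated regularization.
* **Multifilter linear-nonlinear (LN) models** — a few linear filters plus a
  histogram nonlinearity estimated via Bayes' rule. Estimators: STC
  eigenanalysis, the Gaussian information-maximizing subspace search (iSTAC),
  low-rank quadratic models via maximum noise entropy (MNE), and direct
  gradient ascent on single-spike information (MID).

Model quality is measured as bias-corrected single-spike information
I = Σ_z P(z|spike) log2[P(z|spike)/P(z)] (finite-sample bias estimated from
null STC features or by quadratic extrapolation in 1/N) and as the
correlation between predicted and recorded responses, under a five-fold
training/validation/testing protocol. A leaky integrate-and-fire
complex-cell network simulator with Tsodyks–Markram short-term synaptic
depression (u = 0.9, tau_rec = 200 ms) generates all synthetic data: nine
spatially shifted LIF input cells driving one output cell, plus a simplified
two-input variant without depression.

## Worked example

Simulate the depressing complex-cell network, fit a single-CF context model
and a two-filter LN model, and score both on a held-out block:

```r
library(rfctx)

stim <- makeBarStimulus(16, 20000, frameRate = 60, seed = 1)
cell <- simulateComplexNetwork(presetNetwork("nine-depressing"), stim,
                               seed = 2)
cell
#> StimulusEnsemble: 16 bars x 20000 frames at 60 Hz (basis 'raw')
#>   total spikes: 2736, mean rate 0.137 per frame

design <- buildLaggedDesign(applyBasis(cell, "bright"), 16)
train <- design[1:12789]
val   <- design[12790:15986]
test  <- design[15987:19985]

cfg <- solverConfig(family = "poisson", regKind = "laplacian")
fit <- flipAndRestart(alternatingFit(train, contextModelInit(train, 1), cfg),
                      train, cfg)
fit
#> ContextFit (poisson): 23 outer iterations, final loss 418.437, sign-flipped
#> ContextModel: 16 x 16 RF, 1 context field(s)
#>   CF 9 x 9 (origin 5,7) gating 256 RF elements

stats <- spikeTriggeredStats(train)
ln <- midAscent(stcFilters(stats, 2), train, val)

nullB <- nullFilters(stats, 20)
biasCorrectedInfoNull(similarityScores(fit@params, test), spikeCounts(test),
                      makeNullScores(test, nullB, 1))
#> InfoEstimate (null): 0.7873 bits (mean over 11 resolutions)
biasCorrectedInfoNull(similarityScores(ln, test), spikeCounts(test),
                      makeNullScores(test, nullB, 2))
#> InfoEstimate (null): 0.2784 bits (mean over 11 resolutions)
```

Each spike of this synthetic complex cell carries about 0.79 bits about the
context-model score but only about 0.28 bits about the best two-filter
projection: with nine shifted input RFs pooled through depressing synapses,
no two-dimensional subspace describes the cell well, while the RF-plus-CF
factorization does. The fitted CF also exposes the mechanism — its trailing
opposite-sign region in time (tail energy
`cfTailEnergy(fit@params@cfs[[1]])` ≈ 0.054 here) is the signature of
synaptic depression, and it disappears when the simulation is rerun with
depression disabled. On the simplified two-input network without depression
the ordering reverses: the two-filter LN model wins, because that cell
genuinely lives in a two-dimensional stimulus subspace.

A thin command-line interface over these functions is installed at
`inst/cli/rfctx.R` (`simulate`, `fit-context`, `fit-ln`, `refine-mid`,
`evaluate`, `compare --config run.yaml`); `runComparison()` is the
corresponding package entry point for multi-model rosters on shared folds.

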