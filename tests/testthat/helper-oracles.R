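## Independent oracles used across the suite. These deliberately use naive
## loops / closed forms so they stay independent of the implementation paths
## they check.

## Eq.-by-eq. nested-sum evaluation of the context-model similarity score.
bruteScores <- function(model, design) {
  nb <- design@nBars
  vapply(seq_along(design@sampleFrames), function(i) {
    z <- model@w0
    if (!length(model@cfs)) return(z + sum(model@rf * design@X[i, ]))
    for (cf in model@cfs) {
      for (j in cf@rfAssignment) {
        xij <- design@X[i, j]
        ctx <- extractContextVector(design, i, j, cf@spec)
        z <- z + model@rf[j] * xij * (1 + sum(as.vector(cf@weights) * ctx))
      }
    }
    z
  }, 1)
}

## Hand-enumerated lagged windows by explicit loops.
bruteLagged <- function(frames, nLags) {
  nb <- nrow(frames); nf <- ncol(frames)
  n <- nf - nLags + 1
  t(vapply(seq_len(n), function(i)
    as.vector(frames[, i:(i + nLags - 1), drop = FALSE]),
    numeric(nb * nLags)))
}

## Central-difference gradient of a scalar function.
numGrad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, 1)
}

## Gaussian KL divergence KL(N(mu, Sig) || N(0, I)) in bits.
gaussKlBits <- function(mu, Sig) {
  m <- length(mu)
  as.numeric((sum(diag(Sig)) + sum(mu^2) - m -
                determinant(Sig, logarithm = TRUE)$modulus) / (2 * log(2)))
}

## Count-replication oracle for spike-weighted statistics.
replicateRows <- function(X, y) X[rep(seq_len(nrow(X)), y), , drop = FALSE]

cosSim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

## A small reusable context-Poisson ground truth + data set.
makePlantedContextData <- function(nBars = 8, nLags = 8, nFrames = 20000,
                                   seedStim = 3, seedSpikes = 5,
                                   w0 = -5) {
  stim <- applyBasis(makeBarStimulus(nBars, nFrames, seed = seedStim),
                     "bright")
  spec <- contextWindowSpec(5, 5, origin = c(3, 3))
  rfTrue <- as.vector(outer(exp(-((1:nBars) - (nBars / 2 + 0.5))^2 / 3),
                            exp(-((1:nLags) - (nLags - 2))^2 / 4)))
  rfTrue <- rfTrue / sqrt(sum(rfTrue^2))
  cfW <- matrix(0, 5, 5)
  cfW[, 2] <- c(0.2, 0.5, 0.8, 0.5, 0.2)
  cfW[3, 4] <- -0.6
  cfW[3, 3] <- 0
  cfTrue <- contextField(spec, seq_len(nBars * nLags), cfW)
  mTrue <- contextModel(nBars, nLags, w0 = w0, rf = rfTrue,
                        cfs = list(cfTrue))
  ens <- generateContextPoisson(mTrue, exp, stim, seed = seedSpikes)
  list(model = mTrue, ensemble = ens, spec = spec,
       design = buildLaggedDesign(ens, nLags))
}
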