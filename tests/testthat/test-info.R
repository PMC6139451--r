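## Plain LaggedDesign wrapper around an arbitrary design matrix, for tests
## that exercise score-based machinery directly.
wrapDesign <- function(X, y) {
  new("LaggedDesign", X = X, y = y, frames = matrix(0, ncol(X), 1),
      nBars = ncol(X), nLags = 1L, sampleFrames = seq_len(nrow(X)),
      frameRate = 60, basis = "bright")
}

test_that("score histograms match the spike-replication oracle", {
  set.seed(1)
  z <- rnorm(300)
  y <- sample(0:3, 300, replace = TRUE)
  d <- scoreDistribution(z, y, 12)
  expect_equal(sum(d@pZ), 1)
  expect_equal(sum(d@pZSpike), 1)
  ## replicating each sample y_i times and histogramming unweighted on the
  ## same edges reproduces P(z | spike)
  zr <- rep(z, y)
  b <- findInterval(zr, d@edges[[1]], rightmost.closed = TRUE,
                    all.inside = TRUE)
  expect_equal(as.vector(d@pZSpike), tabulate(b, 12) / length(zr))

  ## degenerate constant score: one occupied bin, zero information
  dc <- scoreDistribution(rep(2, 100), rbinom(100, 1, 0.3), 10)
  expect_equal(sum(dc@pZ > 0), 1)
  expect_equal(singleSpikeInfo(dc), 0)
  expect_error(scoreDistribution(z, rep(0, 300)), "no spikes")
  expect_error(scoreDistribution(matrix(z, 100, 3), y[1:100]),
               "two score dimensions")
})

test_that("single-spike information matches closed forms and bounds", {
  ## binary equiprobable score, spikes only at the high value: exactly 1 bit
  z <- rep(c(0, 1), each = 500)
  y <- c(rep(0, 500), rep(1, 500))
  expect_equal(singleSpikeInfo(scoreDistribution(z, y, 2)), 1)

  ## identical distributions: zero bits
  expect_equal(singleSpikeInfo(scoreDistribution(z, rep(1, 1000), 2)), 0)

  ## three-bin hand computation
  pz <- c(0.5, 0.3, 0.2); pzs <- c(0.2, 0.3, 0.5)
  dd <- new("ScoreDistribution", edges = list(0:3), pZ = array(pz),
            pZSpike = array(pzs), pSpike = 0.1)
  expect_equal(singleSpikeInfo(dd), sum(pzs * log2(pzs / pz)))

  ## nonnegativity and the occupied-bin bound over random histograms
  set.seed(2)
  for (rep in 1:20) {
    zz <- rnorm(400)
    yy <- rpois(400, 0.4)
    if (sum(yy) == 0) next
    ddd <- scoreDistribution(zz, yy, 8)
    I <- singleSpikeInfo(ddd)
    expect_gte(I, 0)
    expect_lte(I, log2(sum(ddd@pZ > 0)))
  }

  ## spikes independent of the score: information near zero
  set.seed(3)
  zi <- rnorm(20000); yi <- rbinom(20000, 1, 0.2)
  expect_lt(singleSpikeInfo(scoreDistribution(zi, yi, 15)), 0.01)
})

test_that("information is invariant under monotone transforms of z", {
  set.seed(4)
  ## discrete score levels so every strictly monotone transform maps
  ## occupied bins one-to-one (the continuum invariance, realized exactly)
  z <- sample(seq(0.1, 1, by = 0.1), 5000, replace = TRUE)
  y <- rbinom(5000, 1, plogis(-2 + 2 * z))
  i0 <- singleSpikeInfo(scoreDistribution(z, y, 200))
  expect_equal(singleSpikeInfo(scoreDistribution(2 * z + 1, y, 200)), i0)
  expect_equal(singleSpikeInfo(scoreDistribution(z^3, y, 200)), i0)

  ## for continuous scores an affine map leaves the histogram exactly
  ## invariant as well
  zc <- rnorm(5000)
  yc <- rbinom(5000, 1, plogis(-1.5 + zc))
  expect_equal(singleSpikeInfo(scoreDistribution(2 * zc + 1, yc, 20)),
               singleSpikeInfo(scoreDistribution(zc, yc, 20)))
})

test_that("adding an informative dimension never loses training information", {
  set.seed(5)
  n <- 30000
  z1 <- rnorm(n); z2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2.5 + z1 + 0.8 * z2^2))
  i1 <- singleSpikeInfo(scoreDistribution(z1, y, 12))
  i12 <- singleSpikeInfo(scoreDistribution(cbind(z1, z2), y, 12))
  expect_gte(i12, i1)
})

test_that("the information gradient matches a smoothed finite difference", {
  set.seed(6)
  d <- 5; n <- 100000
  X <- matrix(rnorm(n * d), n, d)
  w <- rnorm(d); w <- w / sqrt(sum(w^2))
  y <- rbinom(n, 1, plogis(-2 + 2 * as.vector(X %*% w)))
  des <- wrapDesign(X, y)
  ## evaluate away from the optimum, where the derivative is substantial
  set.seed(7)
  u <- rnorm(d); u <- u - sum(u * w) * w; u <- u / sqrt(sum(u^2))
  wp <- w + 0.6 * u; wp <- wp / sqrt(sum(wp^2))
  bank <- new("FilterBank", filters = matrix(wp, ncol = 1),
              values = numeric(0), kind = "mid", center = rep(0, d),
              scale = rep(1, d))
  g <- infoGradient(bank, des, bins = 15)[, 1]
  iOf <- function(wv) singleSpikeInfo(scoreDistribution(X %*% wv, y, 15))
  eps <- seq(-0.1, 0.1, length.out = 11)
  fd <- coef(lm(vapply(eps, function(e) iOf(wp + e * u), 1) ~ eps))[2]
  expect_lt(abs(fd - sum(g * u)) / abs(fd), 0.1)

  ## independence: gradient collapses toward zero
  yI <- rbinom(n, 1, 0.12)
  gI <- infoGradient(bank, wrapDesign(X, yI), bins = 15)[, 1]
  expect_lt(sqrt(sum(gI^2)), 0.1 * sqrt(sum(g^2)))
})

test_that("information ascent improves filters and never hurts validation", {
  set.seed(8)
  d <- 5; n <- 20000
  X <- matrix(rnorm(n * d), n, d)
  w <- rnorm(d); w <- w / sqrt(sum(w^2))
  y <- rbinom(n, 1, plogis(-2 + 2 * as.vector(X %*% w)))
  des <- wrapDesign(X, y)
  dTr <- des[1:14000]; dVal <- des[14001:n]

  wBad <- w + 0.8 * rnorm(d); wBad <- wBad / sqrt(sum(wBad^2))
  bank <- new("FilterBank", filters = matrix(wBad, ncol = 1),
              values = numeric(0), kind = "mid", center = rep(0, d),
              scale = rep(1, d))
  valI <- function(m) singleSpikeInfo(
    scoreDistribution(similarityScores(m, dVal), dVal@y, 15))
  ref <- midAscent(bank, dTr, dVal, bins = 15, maxSteps = 120)
  expect_gte(attr(ref, "valInfo"), valI(bank))   # never worse than the start
  expect_gt(attr(ref, "valInfo"), valI(bank) + 0.05)  # and actually improves
  expect_gt(cosSim(ref@filters[, 1], w), 0.98)

  ## an already-optimal initialization is returned unchanged by the
  ## best-validation-iterate rule
  bankOpt <- new("FilterBank", filters = matrix(w, ncol = 1),
                 values = numeric(0), kind = "mid", center = rep(0, d),
                 scale = rep(1, d))
  refOpt <- midAscent(bankOpt, dTr, dVal, bins = 15, maxSteps = 30)
  expect_gte(attr(refOpt, "valInfo"), valI(bankOpt))
  expect_gt(cosSim(refOpt@filters[, 1], w), 0.995)
})

test_that("information ascent applies to context models", {
  dat <- makePlantedContextData(nBars = 6, nLags = 5, nFrames = 12000,
                                w0 = -2.2)
  d <- dat$design
  dTr <- d[1:8000]; dVal <- d[8001:nrow(d@X)]
  ## start from a degraded version of the true model
  m <- dat$model
  set.seed(9)
  m@rf <- m@rf + rnorm(length(m@rf), 0, 0.15)
  g <- infoGradient(m, dTr, bins = 15)
  expect_equal(length(g$rf), length(m@rf))
  expect_equal(g$cfs[[1]][3, 3], 0)   # origin pinned at zero
  ref <- midAscent(m, dTr, dVal, bins = 15, maxSteps = 40)
  valI <- function(mm) singleSpikeInfo(
    scoreDistribution(similarityScores(mm, dVal), dVal@y, 15))
  expect_gte(attr(ref, "valInfo"), valI(m) - 1e-12)
  expect_equal(ref@cfs[[1]]@weights[3, 3], 0)
})
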