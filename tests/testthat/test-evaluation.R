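test_that("the histogram nonlinearity obeys Bayes-rule identities", {
  set.seed(1)
  n <- 40000
  z <- rnorm(n)
  y <- rpois(n, exp(-2.5 + 1.2 * z))
  nl <- estimateNonlinearity(z, y, bins = 20)
  expect_equal(length(as.vector(nl@f)), 20)   # 20 parameters in 1-D

  ## rate conservation: sum_b f(b) P(z_b) equals the mean training rate
  dist <- scoreDistribution(z, y, 20)
  expect_equal(sum(as.vector(nl@f) * as.vector(dist@pZ)), mean(y),
               tolerance = 1e-10)

  ## generative check: estimated f tracks the true exponential nonlinearity
  ## in the well-sampled bins
  mid <- (nl@edges[[1]][-1] + nl@edges[[1]][-21]) / 2
  occ <- as.vector(dist@pZ) > 0.03
  expect_lt(max(abs(nl@f[occ] - exp(-2.5 + 1.2 * mid[occ])) /
                  exp(-2.5 + 1.2 * mid[occ])), 0.25)

  ## independence: f is flat at the mean rate in well-sampled bins
  yI <- rpois(n, 0.15)
  nlI <- estimateNonlinearity(z, yI, 20)
  expect_lt(max(abs(as.vector(nlI@f)[occ] - mean(yI))), 0.05)

  ## two-dimensional scores need 400 parameters
  nl2 <- estimateNonlinearity(cbind(z, rnorm(n)), y, 20)
  expect_equal(length(as.vector(nl2@f)), 400)
  expect_error(estimateNonlinearity(z, rep(0, n)), "no spikes")
})

test_that("rate prediction clamps out-of-range scores and beats shuffles", {
  dat <- makePlantedContextData(nBars = 6, nLags = 5, nFrames = 15000,
                                w0 = -2.2)
  d <- dat$design
  n <- nrow(d@X)
  dTr <- d[1:10000]; dTest <- d[10001:n]
  zTr <- similarityScores(dat$model, dTr)
  nl <- estimateNonlinearity(zTr, dTr@y, 20)
  pred <- predictRate(dat$model, dTest, nl)
  expect_true(all(is.finite(pred)))

  ## constant score predicts the constant mean training rate
  mz <- dat$model; mz@rf[] <- 0
  cz <- contextModel(6, 5, w0 = 1)
  nlC <- estimateNonlinearity(similarityScores(cz, dTr), dTr@y, 20)
  expect_equal(unique(predictRate(cz, dTest, nlC)), mean(dTr@y))

  ## shifted scores only clamp, never produce NaN
  nlShift <- estimateNonlinearity(zTr + 100, dTr@y, 20)
  expect_true(all(is.finite(predictRate(dat$model, dTest, nlShift))))

  r <- correlationScore(pred, dTest@y)
  set.seed(2)
  rShuffle <- correlationScore(sample(pred), dTest@y)
  expect_gt(r, rShuffle)
  expect_gt(r, 0.1)
})

test_that("null-feature bias correction recovers a known information value", {
  set.seed(3)
  n <- 60000
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 1.5 * z))
  ## discretization-free oracle on a fine grid
  grid <- seq(-5, 5, length.out = 4001)
  pz <- dnorm(grid); pz <- pz / sum(pz)
  pzg <- plogis(-2 + 1.5 * grid)
  pzs <- pz * pzg / sum(pz * pzg)
  iTrue <- sum(ifelse(pzs > 0, pzs * log2(pzs / pz), 0))

  nulls <- lapply(1:10, function(i) rnorm(n))
  est <- biasCorrectedInfoNull(z, y, nulls)
  expect_s4_class(est, "InfoEstimate")
  expect_equal(est@corrected, est@naive - est@bias)
  expect_lt(abs(est@value - iTrue), 0.05)

  ## 1-D bias is negligible relative to the information itself
  expect_lt(max(abs(est@bias)), 0.05 * est@value)

  ## resolution stability after correction: drift across 25..35 bins is
  ## within one percent of the estimate
  drift <- diff(range(est@corrected))
  expect_lt(drift, 0.02 * est@value)

  expect_warning(biasCorrectedInfoNull(z, y, nulls[1:2]), "fewer than 3")
})

test_that("two-dimensional naive information inflates while corrected stays flat", {
  set.seed(4)
  n <- 50000
  z2 <- cbind(rnorm(n), rnorm(n))
  y <- rbinom(n, 1, plogis(-2.5 + z2[, 1] + z2[, 2]^2))
  nulls <- lapply(1:5, function(i) cbind(rnorm(n), rnorm(n)))
  est <- biasCorrectedInfoNull(z2, y, nulls)
  ## the naive value keeps growing with resolution...
  expect_gt(est@naive[11] - est@naive[1], 0.005)
  expect_gt(est@bias[11], est@bias[1])
  ## ...but the corrected one is much flatter
  nSlope <- coef(lm(est@naive ~ est@resolutions))[2]
  cSlope <- coef(lm(est@corrected ~ est@resolutions))[2]
  expect_lt(abs(cSlope), 0.5 * abs(nSlope))
})

test_that("quadratic extrapolation agrees with the null-feature correction", {
  set.seed(5)
  n <- 40000
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 1.5 * z))
  nulls <- lapply(1:10, function(i) rnorm(n))
  estN <- biasCorrectedInfoNull(z, y, nulls)
  estQ <- biasCorrectedInfoQE(z, y, seed = 7)
  expect_lt(abs(estN@value - estQ@value), 0.03)

  ## constant score: zero information at every fraction, corrected zero
  estC <- biasCorrectedInfoQE(rep(1, n), y, seed = 7)
  expect_equal(estC@value, 0, tolerance = 1e-10)

  ## the leading bias term scales as 1/N: naive bias roughly halves
  ## when the sample doubles
  idx <- sample.int(n, n / 2)
  bHalf <- mean(biasCorrectedInfoNull(z[idx], y[idx], lapply(
    nulls[1:6], function(s) s[idx]))@bias)
  bFull <- mean(estN@bias)
  expect_gt(bHalf, bFull * 1.4)
  expect_lt(bHalf, bFull * 3)

  expect_error(biasCorrectedInfoQE(z, y, fractions = c(1, 0.5)),
               "three distinct")
})

test_that("correlation scoring covers exact and degenerate cases", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(correlationScore(x, x), 1)
  expect_equal(correlationScore(-x, x), -1)
  y <- c(2, 1, 4, 3, 6)
  expect_equal(correlationScore(x, y),
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  expect_warning(r0 <- correlationScore(rep(1, 5), y), "constant")
  expect_true(is.na(r0))
  expect_error(correlationScore(x, y[1:3]), "equal length")
})

test_that("the five-fold protocol splits 1000 samples into 200/640/160", {
  dat <- makePlantedContextData(nBars = 4, nLags = 3, nFrames = 1002,
                                w0 = -1.2)
  d <- dat$design
  expect_equal(nrow(d@X), 1000)
  ## instrumented model spec records the split sizes
  sizes <- list()
  spec <- list(name = "probe", dim = 1,
               fit = function(dTr, dVal) {
                 sizes[[length(sizes) + 1]] <<-
                   c(train = nrow(dTr@X), val = nrow(dVal@X))
                 contextModel(4, 3, w0 = 0, rf = rnorm(12))
               })
  rep <- crossvalProtocol(d, spec, seed = 1, folds = 5, resolutions = 25:27,
                          nNull = 4)
  expect_equal(nrow(rep@table), 5)     # five fitted model versions
  expect_true(all(vapply(sizes, function(s) s["train"], 1) == 640))
  expect_true(all(vapply(sizes, function(s) s["val"], 1) == 160))
  ## fold-mean consistency
  expect_equal(unname(rep@summary["meanITest"]), mean(rep@table$ITest))
})

test_that("normalized scores give the best model one and preserve order", {
  mk <- function(name, i, r) new("EvalReport", model = name,
    table = data.frame(fold = 1, ITrain = i, ITest = i, rTrain = r,
                       rTest = r),
    summary = c(meanITest = i, seITest = 0, meanRTest = r, seRTest = 0,
                meanITrain = i, meanRTrain = r))
  tab <- normalizedScores(list(mk("a", 0.5, 0.2), mk("b", 1.0, 0.4)))
  expect_equal(tab$INorm, c(0.5, 1.0))
  expect_equal(tab$rNorm, c(0.5, 1.0))
  ## ordering preserved under normalization for random tables
  set.seed(6)
  for (q in 1:5) {
    vals <- runif(4, 0.1, 2)
    reps <- lapply(seq_along(vals), function(i)
      mk(letters[i], vals[i], vals[i] / 2))
    tb <- normalizedScores(reps)
    expect_equal(order(tb$INorm), order(vals))
    expect_equal(max(tb$INorm), 1)
  }
  expect_error(normalizedScores(list(mk("a", 1, 1))), "two models")
})

test_that("identical data in every fold yields zero fold variance", {
  ## a block of frames repeated five times, an injected deterministic model
  set.seed(7)
  block <- matrix(sample(0:1, 4 * 200, replace = TRUE), 4, 200)
  frames <- do.call(cbind, rep(list(block), 5))
  z <- as.vector(rep(colSums(block), 5))
  counts <- ifelse(z > median(z), 2, 0)
  ens <- stimulusEnsemble(frames, counts = counts, basis = "bright")
  d <- buildLaggedDesign(ens, 1)
  spec <- list(name = "fixed", dim = 1,
               fit = function(dTr, dVal) contextModel(4, 1, rf = rep(1, 4)))
  rep <- crossvalProtocol(d, spec, seed = 1, folds = 5,
                          resolutions = 25:27, nNull = 4)
  expect_equal(unname(rep@summary["seITest"]), 0, tolerance = 1e-10)
})
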