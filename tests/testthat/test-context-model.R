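## Shared toy model: 5 bars x 4 lags, one 3x3 context field.
makeToy <- function(seed = 42, nFrames = 30) {
  set.seed(seed)
  ens <- applyBasis(makeBarStimulus(5, nFrames, seed = seed), "bright")
  d <- buildLaggedDesign(ens, 4)
  spec <- contextWindowSpec(3, 3, origin = c(2, 2))
  W <- matrix(rnorm(9), 3, 3); W[2, 2] <- 0
  cf <- contextField(spec, 1:20, W)
  m <- contextModel(5, 4, w0 = 0.3, rf = rnorm(20), cfs = list(cf))
  list(d = d, m = m, spec = spec)
}

test_that("similarity scores match the brute-force nested-sum oracle", {
  toy <- makeToy()
  expect_equal(similarityScores(toy$m, toy$d), bruteScores(toy$m, toy$d),
               tolerance = 1e-12)

  ## all-zero context fields reduce to the traditional linear score
  m0 <- toy$m
  m0@cfs[[1]]@weights[] <- 0
  expect_equal(similarityScores(m0, toy$d),
               m0@w0 + as.vector(toy$d@X %*% m0@rf))

  ## zero RF gives a constant score equal to the bias
  mz <- toy$m; mz@rf[] <- 0
  expect_equal(similarityScores(mz, toy$d),
               rep(0.3, nrow(toy$d@X)))
})

test_that("the two score representations (RF-linear and CF-linear) agree", {
  toy <- makeToy(7)
  z1 <- similarityScores(toy$m, toy$d)
  A <- cfDesignRows(toy$m, toy$d, 1)
  k <- toy$m@w0 + as.vector(toy$d@X %*% toy$m@rf)
  z2 <- k + as.vector(A %*% as.vector(toy$m@cfs[[1]]@weights))
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("RF and CF design rows are the exact score gradients", {
  toy <- makeToy(11)
  d <- toy$d; m <- toy$m
  Arf <- rfDesignRows(m, d)
  ## identity z = w0 + Arf rf
  expect_equal(similarityScores(m, d), m@w0 + as.vector(Arf %*% m@rf))
  ## with zero CFs the RF rows are the raw design
  m0 <- m; m0@cfs[[1]]@weights[] <- 0
  expect_equal(rfDesignRows(m0, d), d@X)

  ## central differences, a handful of (sample, coordinate) pairs
  Acf <- cfDesignRows(m, d, 1)
  for (i in c(2, 9)) {
    gRf <- numGrad(function(rf) {
      mm <- m; mm@rf <- rf; similarityScores(mm, d)[i]
    }, m@rf)
    expect_equal(gRf, Arf[i, ], tolerance = 1e-6)
    gCf <- numGrad(function(wv) {
      mm <- m; mm@cfs[[1]]@weights <- matrix(wv, 3, 3)
      similarityScores(mm, d)[i]
    }, as.vector(m@cfs[[1]]@weights))
    ## origin coordinate structurally ignored
    expect_equal(gCf[-5], Acf[i, -5], tolerance = 1e-6)
  }

  ## zero RF zeroes the CF rows
  mz <- m; mz@rf[] <- 0
  expect_true(all(cfDesignRows(mz, d, 1) == 0))
  ## empty assignment is a configuration error
  mbad <- m; mbad@cfs[[1]]@rfAssignment <- integer(0)
  expect_error(cfDesignRows(mbad, d, 1), "empty")
})

test_that("the analytic linear subproblem matches a ridge oracle", {
  set.seed(3)
  A <- matrix(rnorm(100), 20, 5)
  y <- rnorm(20); k <- rnorm(20, 0, 0.1)
  G <- diag(5)
  for (C in c(0.1, 1, 10)) {
    w <- solveLinearSubproblem(A, y, k, C, G)$w
    oracle <- solve(crossprod(A) + diag(5) / (2 * C), crossprod(A, y - k))
    expect_equal(w, as.vector(oracle), tolerance = 1e-8)
  }
  ## identity system
  expect_equal(solveLinearSubproblem(diag(4), c(1, 2, 3, 4), rep(0, 4), 1,
                                     matrix(0, 4, 4))$w, c(1, 2, 3, 4))
  ## strong regularization shrinks to zero
  wTiny <- solveLinearSubproblem(A, y, k, 1e-9, G)$w
  expect_lt(sqrt(sum(wTiny^2)), 1e-5)
  ## singular unregularized system is flagged and pseudo-solved
  As <- cbind(A[, 1], A[, 1])
  res <- solveLinearSubproblem(As, y, k, 1, matrix(0, 2, 2))
  expect_true(res$flagged)
})

test_that("GLM subproblems recover closed-form intercepts and match FD", {
  set.seed(4)
  n <- 400
  A1 <- matrix(1, n, 1)
  G0 <- matrix(0, 1, 1)
  y <- rep(c(0, 1), n / 2)
  wLogit <- solveGlmSubproblem(A1, y, rep(0, n), 1, G0, "logistic",
                               tol = 1e-8)$w
  expect_equal(wLogit, 0, tolerance = 1e-6)       # logit(0.5)
  yP <- rpois(n, 2.3)
  wPois <- solveGlmSubproblem(A1, yP, rep(0, n), 1, G0, "poisson",
                              tol = 1e-8)$w
  expect_equal(wPois, log(mean(yP)), tolerance = 1e-6)

  ## analytic gradient/Hessian against central differences, both families,
  ## including the per-sample constant k
  A <- matrix(rnorm(60), 20, 3)
  yy <- rpois(20, 1)
  k <- rnorm(20, 0, 0.2)
  G <- diag(3) * 0.5
  Cc <- 2
  for (fam in c("logistic", "poisson")) {
    w <- rnorm(3, 0, 0.3)
    lossOf <- function(w) {
      z <- k + as.vector(A %*% w)
      dl <- if (fam == "logistic") {
        yt <- ifelse(yy == 0, -1, 1); beta <- pmax(yy, 1)
        sum(beta * log(1 + exp(-yt * z)))
      } else sum(exp(z) - yy * z)
      Cc * dl + 0.5 * sum((G %*% w)^2)
    }
    z <- k + as.vector(A %*% w)
    yt <- ifelse(yy == 0, -1, 1); beta <- pmax(yy, 1)
    gAn <- if (fam == "logistic")
      as.vector(crossprod(G) %*% w) +
        Cc * as.vector(crossprod(A, beta * (plogis(yt * z) - 1) * yt))
    else as.vector(crossprod(G) %*% w) +
      Cc * as.vector(crossprod(A, exp(z) - yy))
    expect_equal(gAn, numGrad(lossOf, w), tolerance = 1e-5)
    ## the solver reaches a point with (near) zero gradient
    fit <- solveGlmSubproblem(A, yy, k, Cc, G, fam, tol = 1e-6)
    expect_lt(max(abs(numGrad(lossOf, fit$w))), 1e-3)
  }
})

test_that("regularizers implement identity and grid-Laplacian stencils", {
  expect_equal(makeRegularizer("l2", c(3, 4)), diag(12))
  L <- makeRegularizer("laplacian", c(3, 3))
  ## interior cell: classical 5-point stencil
  expect_equal(L[5, 5], 4)
  expect_equal(sort(which(L[5, ] == -1)), c(2, 4, 6, 8))
  ## constant fields are annihilated (including boundaries)
  expect_equal(as.vector(L %*% rep(1, 9)), rep(0, 9))
  ## explicit hand-built stencil for the full 3x3 grid
  idx <- function(r, c) (c - 1) * 3 + r
  Lh <- matrix(0, 9, 9)
  for (r in 1:3) for (c in 1:3) {
    nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= 3 & nb[, 2] >= 1 & nb[, 2] <= 3, ,
             drop = FALSE]
    Lh[idx(r, c), idx(r, c)] <- nrow(nb)
    for (q in seq_len(nrow(nb))) Lh[idx(r, c), idx(nb[q, 1], nb[q, 2])] <- -1
  }
  expect_equal(L, Lh)
  ## block-diagonal composition never couples blocks
  Lb <- makeRegularizer("laplacian", list(c(2, 2), c(2, 2)))
  expect_equal(Lb[1:4, 5:8], matrix(0, 4, 4))
})
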