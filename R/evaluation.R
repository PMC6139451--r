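#' Estimate the output nonlinearity from training scores
#'
#' Bayes-rule histogram nonlinearity
#' \deqn{f(z) = P(spike | z) = P(spike) \frac{P(z | spike)}{P(z)},}
#' with P(spike) the mean spike count per frame. Empty bins inherit the
#' global mean rate; out-of-range scores later clamp to the edge bins. The
#' construction conserves the mean rate:
#' \eqn{\sum_b f(b) P(z_b)} equals the training mean exactly.
#'
#' @param zTrain training similarity scores (vector or two-column matrix).
#' @param countsTrain training spike counts.
#' @param bins bins per dimension (default 20).
#' @return a [NonlinearityHistogram-class].
#' @export
estimateNonlinearity <- function(zTrain, countsTrain, bins = 20) {
  if (sum(countsTrain) <= 0) stop("no spikes in the training data")
  dist <- scoreDistribution(zTrain, countsTrain, bins)
  meanRate <- mean(countsTrain)
  f <- dist@pZ
  occ <- dist@pZ > 0
  f[occ] <- meanRate * dist@pZSpike[occ] / dist@pZ[occ]
  f[!occ] <- meanRate
  new("NonlinearityHistogram", edges = dist@edges, f = f,
      meanRate = meanRate, bins = as.integer(bins))
}

#' Predict firing rates on new data
#'
#' Applies the fitted histogram nonlinearity to the model's similarity
#' scores: \eqn{\hat y_i = f(z_i)}.
#'
#' @param model a fitted model with a [similarityScores()] method.
#' @param design a [LaggedDesign-class].
#' @param nl a [NonlinearityHistogram-class] fitted on the same model's
#'   training scores.
#' @return predicted rate per sample.
#' @export
predictRate <- function(model, design, nl) {
  z <- as.matrix(similarityScores(model, design))
  if (ncol(z) != length(nl@edges))
    stop("score dimensionality does not match the nonlinearity")
  idx <- binIndex(z[, 1], nl@edges[[1]])
  if (ncol(z) == 2L) {
    nb1 <- length(nl@edges[[1]]) - 1L
    idx <- idx + (binIndex(z[, 2], nl@edges[[2]]) - 1L) * nb1
  }
  as.vector(nl@f)[idx]
}

#' Null-feature score sets for bias estimation
#'
#' Projects a design onto null features (STC eigenvectors whose eigenvalues
#' sit at the stimulus variance); the resulting scores carry no
#' stimulus-response information, so their measured information estimates the
#' finite-sample bias. For two-dimensional scores, consecutive features are
#' paired.
#'
#' @param design the [LaggedDesign-class] to project.
#' @param bank a null [FilterBank-class] (see [nullFilters()]).
#' @param d score dimensionality (1 or 2).
#' @return list of score vectors (d = 1) or two-column matrices (d = 2).
#' @export
makeNullScores <- function(design, bank, d = 1) {
  P <- similarityScores(bank, design)
  if (d == 1L) return(lapply(seq_len(ncol(P)), function(j) P[, j]))
  nPairs <- ncol(P) %/% 2L
  lapply(seq_len(nPairs), function(k) P[, c(2L * k - 1L, 2L * k)])
}

#' Bias-corrected information via null features
#'
#' For each histogram resolution: compute the naive single-spike information
#' of \code{z} and its average number of occupied bins; interpolate the bias
#' curve sampled from the null-feature scores (information of null scores as
#' a function of their occupied-bin count, pooled over features and
#' resolutions) at that occupancy; subtract. The reported value is the mean
#' of the corrected values over the evaluation resolutions.
#'
#' @param z scores (vector or two-column matrix).
#' @param counts spike counts.
#' @param nullScores list of null score sets of the same dimensionality (see
#'   [makeNullScores()]); fewer than three triggers a warning.
#' @param resolutions evaluation resolutions (default 25..35 bins per
#'   dimension).
#' @param curveResolutions resolutions at which the bias curve is sampled;
#'   defaults to a range bracketing \code{resolutions}.
#' @return an [InfoEstimate-class].
#' @export
biasCorrectedInfoNull <- function(z, counts, nullScores,
                                  resolutions = 25:35,
                                  curveResolutions = NULL) {
  if (length(nullScores) < 3L)
    warning("fewer than 3 null features: bias estimate will be noisy")
  if (is.null(curveResolutions))
    curveResolutions <- sort(unique(round(c(
      seq(max(2, min(resolutions) * 0.4), min(resolutions),
          length.out = 4),
      resolutions,
      seq(max(resolutions), max(resolutions) * 1.6, length.out = 4)))))
  eff <- numeric(0); inull <- numeric(0)
  for (s in nullScores) for (r in curveResolutions) {
    d <- scoreDistribution(s, counts, r)
    eff <- c(eff, effectiveBins(d))
    inull <- c(inull, singleSpikeInfo(d))
  }
  biasAt <- stats::approxfun(eff, inull, rule = 2, ties = mean)
  resolutions <- as.integer(resolutions)
  naive <- bias <- numeric(length(resolutions))
  for (i in seq_along(resolutions)) {
    d <- scoreDistribution(z, counts, resolutions[i])
    naive[i] <- singleSpikeInfo(d)
    bias[i] <- biasAt(effectiveBins(d))
  }
  corrected <- naive - bias
  new("InfoEstimate", resolutions = resolutions, naive = naive, bias = bias,
      corrected = corrected, value = mean(corrected), method = "null")
}

#' Bias-corrected information via quadratic extrapolation
#'
#' Computes naive information on random subsamples at several data fractions
#' and extrapolates the quadratic fit of I versus 1/N to infinite data; the
#' intercept is the corrected value. Computed per evaluation resolution; the
#' reported value is their mean.
#'
#' @param z scores.
#' @param counts spike counts.
#' @param fractions subsampling fractions (at least three distinct values).
#' @param nRepeats random subsamples per fraction.
#' @param seed RNG seed.
#' @param resolutions evaluation resolutions.
#' @return an [InfoEstimate-class].
#' @export
biasCorrectedInfoQE <- function(z, counts, fractions = seq(1, 0.5, by = -0.1),
                                nRepeats = 10, seed = 1,
                                resolutions = 25:35) {
  if (length(unique(fractions)) < 3L)
    stop("quadratic extrapolation needs at least three distinct fractions")
  z <- as.matrix(z)
  n <- nrow(z)
  set.seed(seed)
  resolutions <- as.integer(resolutions)
  naive <- corrected <- numeric(length(resolutions))
  for (i in seq_along(resolutions)) {
    r <- resolutions[i]
    mI <- vapply(fractions, function(fr) {
      m <- max(2L, round(fr * n))
      reps <- if (fr >= 1) 1L else nRepeats
      vals <- vapply(seq_len(reps), function(q) {
        for (tries in 1:20) {
          idx <- if (fr >= 1) seq_len(n) else sample.int(n, m)
          if (sum(counts[idx]) > 0) break
        }
        singleSpikeInfo(scoreDistribution(z[idx, , drop = FALSE],
                                          counts[idx], r))
      }, 1)
      mean(vals)
    }, 1)
    invN <- 1 / (round(fractions * n))
    fit <- stats::lm(mI ~ invN + I(invN^2))
    naive[i] <- mI[which.max(fractions)]
    corrected[i] <- unname(stats::coef(fit)[1])
  }
  bias <- naive - corrected
  new("InfoEstimate", resolutions = resolutions, naive = naive, bias = bias,
      corrected = corrected, value = mean(corrected), method = "qe")
}

#' Pearson correlation between predictions and observations
#'
#' @param predicted,observed equal-length numeric vectors.
#' @return the correlation, or NA (with a warning) when either input is
#'   constant.
#' @export
correlationScore <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("correlation undefined for constant input")
    return(NA_real_)
  }
  stats::cor(predicted, observed)
}

#' Five-fold training/validation/testing protocol
#'
#' Splits the design rows into \code{folds} contiguous temporal blocks. Each
#' fold is held out for testing once; the remaining rows are split (in
#' temporal order) into training (80 percent) and validation (20 percent).
#' Per fold the model is fitted on training data (with the validation set
#' available for early stopping / hyperparameters), the nonlinearity is
#' estimated from training scores, and bias-corrected information plus the
#' prediction correlation are evaluated on the held-out test fold. Fold
#' failures are recorded as missing with a warning.
#'
#' @param design a [LaggedDesign-class].
#' @param modelSpec list with elements \code{name}, \code{fit} (a
#'   \code{function(designTrain, designVal)} returning a fitted model with a
#'   [similarityScores()] method), and \code{dim} (score dimensionality,
#'   1 or 2).
#' @param seed RNG seed (subsampling inside information estimates).
#' @param folds number of folds.
#' @param resolutions evaluation resolutions for the bias-corrected
#'   information.
#' @param nNull null features for bias estimation.
#' @param bins nonlinearity resolution.
#' @return an [EvalReport-class].
#' @export
crossvalProtocol <- function(design, modelSpec, seed = 1, folds = 5,
                             resolutions = 25:35, nNull = 10, bins = 20) {
  n <- nrow(design@X)
  if (n < folds) stop("not enough samples for the requested folds")
  set.seed(seed)
  foldId <- cut(seq_len(n), folds, labels = FALSE)
  rows <- lapply(seq_len(folds), function(f) {
    test <- which(foldId == f)
    rest <- which(foldId != f)
    nTrain <- floor(0.8 * length(rest))
    list(train = rest[seq_len(nTrain)],
         val = rest[(nTrain + 1):length(rest)], test = test)
  })
  tab <- data.frame(fold = seq_len(folds), ITrain = NA_real_,
                    ITest = NA_real_, rTrain = NA_real_, rTest = NA_real_)
  for (f in seq_len(folds)) {
    sp <- rows[[f]]
    dTrain <- design[sp$train]; dVal <- design[sp$val]
    dTest <- design[sp$test]
    model <- tryCatch(modelSpec$fit(dTrain, dVal), error = function(e) {
      warning(sprintf("fold %d failed: %s", f, conditionMessage(e)))
      NULL
    })
    if (is.null(model)) next
    zTrain <- similarityScores(model, dTrain)
    nl <- estimateNonlinearity(zTrain, dTrain@y, bins)
    nullDim <- modelSpec$dim %||% 1L
    stats <- spikeTriggeredStats(dTrain)
    bank <- nullFilters(stats, if (nullDim == 2L) 2L * nNull else nNull)
    infoOn <- function(d) {
      zz <- similarityScores(model, d)
      ns <- makeNullScores(d, bank, nullDim)
      biasCorrectedInfoNull(zz, d@y, ns, resolutions)@value
    }
    tab$ITrain[f] <- infoOn(dTrain)
    tab$ITest[f] <- infoOn(dTest)
    tab$rTrain[f] <- suppressWarnings(
      correlationScore(predictRate(model, dTrain, nl), dTrain@y))
    tab$rTest[f] <- suppressWarnings(
      correlationScore(predictRate(model, dTest, nl), dTest@y))
  }
  s <- c(meanITest = mean(tab$ITest, na.rm = TRUE),
         seITest = stats::sd(tab$ITest, na.rm = TRUE) /
           sqrt(sum(!is.na(tab$ITest))),
         meanRTest = mean(tab$rTest, na.rm = TRUE),
         seRTest = stats::sd(tab$rTest, na.rm = TRUE) /
           sqrt(sum(!is.na(tab$rTest))),
         meanITrain = mean(tab$ITrain, na.rm = TRUE),
         meanRTrain = mean(tab$rTrain, na.rm = TRUE))
  new("EvalReport", model = modelSpec$name %||% "model", table = tab,
      summary = s)
}

#' Normalize per-model scores by the best model
#'
#' Divides each model's mean test information and correlation by the maximum
#' across models, so the best model scores 1.0 in each measure.
#'
#' @param reports list of [EvalReport-class] objects for one cell.
#' @return data.frame with columns model, I, r, INorm, rNorm.
#' @export
normalizedScores <- function(reports) {
  if (length(reports) < 2L) stop("need at least two models to normalize")
  I <- vapply(reports, function(r) unname(r@summary["meanITest"]), 1)
  r <- vapply(reports, function(r) unname(r@summary["meanRTest"]), 1)
  nm <- vapply(reports, function(r) r@model, "")
  iMax <- max(I, na.rm = TRUE); rMax <- max(r, na.rm = TRUE)
  if (!is.finite(iMax) || iMax <= 0) {
    warning("nonpositive maximum information: normalization undefined")
    iMax <- NA_real_
  }
  if (!is.finite(rMax) || rMax <= 0) {
    warning("nonpositive maximum correlation: normalization undefined")
    rMax <- NA_real_
  }
  data.frame(model = nm, I = I, r = r, INorm = I / iMax, rNorm = r / rMax)
}

#' Trailing-context energy of a context field
#'
#' Mean absolute weight in the lag columns preceding the field's peak
#' column (the column holding the largest absolute weight). Synaptic
#' depression expresses itself as an opposite-sign trailing region in time,
#' which raises this statistic.
#'
#' @param cf a [ContextField-class] or a weight matrix.
#' @return numeric.
#' @export
cfTailEnergy <- function(cf) {
  W <- if (is(cf, "ContextField")) cf@weights else cf
  peakCol <- which.max(apply(abs(W), 2, max))
  if (peakCol <= 1L) return(0)
  mean(abs(W[, seq_len(peakCol - 1L)]))
}
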