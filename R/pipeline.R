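#' Resolve a model name into a fit specification
#'
#' Supported names follow the estimation-method naming convention:
#' traditional LN models (\code{LinReg}, \code{LogReg}, \code{PoiReg}),
#' spike-triggered subspace models (\code{STC2}, \code{iSTAC2},
#' \code{MID1_iSTAC1}), low-rank quadratic models (\code{MNE2}, \code{MNE4}),
#' information-maximized two-filter models (\code{MID2_STC2},
#' \code{MID2_iSTAC2}, \code{MID2_MNE2}), single-CF context models
#' (\code{LinRegCtx}, \code{LogRegCtx}, \code{PoiRegCtx},
#' \code{MID_PoiRegCtx}) and double-CF space-time-intensity context models
#' (\code{LinRegCtx2Int}, \code{LogRegCtx2Int}, \code{PoiRegCtx2Int}).
#'
#' @param name model name.
#' @param window context-window geometry for context models.
#' @param regKind regularization for context models.
#' @param mneCGrid candidate C values for the first MNE stage (chosen by
#'   training information, as this yields structured filters).
#' @param midBins,midSteps information-ascent settings.
#' @param seed RNG seed forwarded to the solvers.
#' @return list with \code{name}, \code{basis} ("bright" or "bright+dark"),
#'   \code{dim} (score dimensionality) and \code{fit(designTrain,
#'   designVal)}.
#' @export
modelSpec <- function(name, window = contextWindowSpec(),
                      regKind = "laplacian", mneCGrid = 10^seq(-2, 0, 1),
                      midBins = 15, midSteps = 200, seed = 1) {
  family <- if (grepl("^LinReg", name)) "linear"
            else if (grepl("^LogReg", name)) "logistic"
            else "poisson"
  cfgOf <- function() solverConfig(family = family, regKind = regKind,
                                   seed = seed)
  ctxFit <- function(dTrain, dVal) {
    fit <- alternatingFit(dTrain, contextModelInit(dTrain, 1, window),
                          cfg = cfgOf())
    flipAndRestart(fit, dTrain, cfgOf())@params
  }
  mneSelect <- function(dTrain, dVal, nFilters) {
    infos <- -Inf; best <- NULL
    for (C in mneCGrid) {
      m <- mneFit(dTrain, C = C)
      sel <- lowrankSelect(m, nFilters, dTrain)
      I <- singleSpikeInfo(scoreDistribution(qnScore(sel, dTrain@X),
                                             dTrain@y, 20))
      if (I > infos) { infos <- I; best <- sel }
    }
    refineFilters(best, dTrain, validation = list(design = dVal,
                                                  counts = dVal@y))
  }
  midFrom <- function(base) function(dTrain, dVal) {
    midAscent(base(dTrain, dVal), dTrain, dVal, bins = midBins,
              maxSteps = midSteps)
  }
  bankFrom <- function(model, dTrain) {
    if (is(model, "QNModel")) {
      ## orthonormalized selected filters as a general two-filter LN start
      Q <- qr.Q(qr(model@filters))
      new("FilterBank", filters = Q, values = numeric(0), kind = "mid")
    } else model
  }
  spec <- switch(name,
    LinReg = , LogReg = , PoiReg =
      list(dim = 1, basis = "bright",
           fit = function(dT, dV) fitTraditionalLn(dT, cfgOf())@params),
    LinRegCtx = , LogRegCtx = , PoiRegCtx =
      list(dim = 1, basis = "bright", fit = ctxFit),
    LinRegCtx2Int = , LogRegCtx2Int = , PoiRegCtx2Int =
      list(dim = 1, basis = "bright+dark",
           fit = function(dT, dV)
             fitDoubleCfIntensity(dT, cfgOf(), window)$fit@params),
    MID_PoiRegCtx =
      list(dim = 1, basis = "bright", fit = midFrom(ctxFit)),
    STC2 = list(dim = 2, basis = "bright",
                fit = function(dT, dV) stcFilters(spikeTriggeredStats(dT),
                                                  2)),
    iSTAC2 = list(dim = 2, basis = "bright",
                  fit = function(dT, dV)
                    istacFit(spikeTriggeredStats(dT), 2)),
    MID1_iSTAC1 = list(dim = 1, basis = "bright",
                       fit = midFrom(function(dT, dV)
                         istacFit(spikeTriggeredStats(dT), 1))),
    MID2_STC2 = list(dim = 2, basis = "bright",
                     fit = midFrom(function(dT, dV)
                       stcFilters(spikeTriggeredStats(dT), 2))),
    MID2_iSTAC2 = list(dim = 2, basis = "bright",
                       fit = midFrom(function(dT, dV)
                         istacFit(spikeTriggeredStats(dT), 2))),
    MNE2 = list(dim = 1, basis = "bright",
                fit = function(dT, dV) mneSelect(dT, dV, 2)),
    MNE4 = list(dim = 1, basis = "bright",
                fit = function(dT, dV) mneSelect(dT, dV, 4)),
    MID2_MNE2 = list(dim = 2, basis = "bright",
                     fit = midFrom(function(dT, dV)
                       bankFrom(mneSelect(dT, dV, 2), dT))),
    stop("unknown model name: ", name))
  spec$name <- name
  spec
}

#' Run a configured multi-model comparison
#'
#' Executes the five-fold protocol for every model in the roster on shared
#' folds of one data set (simulated or loaded), and returns per-model
#' reports, the normalized score table, and the winner by mean test
#' information. All randomness derives from the configured seed; rerunning
#' the same configuration reproduces the report.
#'
#' @param cfg configuration list (or path to a YAML file) with entries
#'   \itemize{
#'   \item \code{data}: either \code{simulator = list(preset, frames, seed)}
#'     or \code{frames_csv}/\code{counts_csv}/\code{frame_rate};
#'   \item \code{models}: character vector of model names
#'     (see [modelSpec()]);
#'   \item \code{evaluation}: optional list(lags, folds, nNull, seed,
#'     resolutions);
#'   \item \code{output_dir}: optional directory for CSV/JSON outputs.
#'   }
#' @return list with \code{reports} (per model), \code{scores} (normalized
#'   table), \code{winner}, and \code{configChecksum}.
#' @export
runComparison <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  ev <- cfg$evaluation %||% list()
  lags <- ev$lags %||% 16
  folds <- ev$folds %||% 5
  seed <- ev$seed %||% 1
  nNull <- ev$nNull %||% 10
  resolutions <- ev$resolutions %||% 25:35
  checksum <- sum(utf8ToInt(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                             force = TRUE)))

  raw <- if (!is.null(cfg$data$simulator)) {
    sim <- cfg$data$simulator
    stim <- makeBarStimulus(sim$bars %||% 16, sim$frames %||% 50000,
                            seed = sim$seed %||% seed)
    simulateComplexNetwork(presetNetwork(sim$preset %||% "nine-depressing"),
                           stim, seed = (sim$seed %||% seed) + 1)
  } else {
    readStimulusCsv(cfg$data$frames_csv, cfg$data$counts_csv,
                    frameRate = cfg$data$frame_rate %||% 60)
  }
  designs <- list()
  designFor <- function(basis) {
    if (is.null(designs[[basis]]))
      designs[[basis]] <<- buildLaggedDesign(applyBasis(raw, basis), lags)
    designs[[basis]]
  }

  reports <- list()
  failures <- character(0)
  for (name in unlist(cfg$models)) {
    if (name %in% names(reports)) stop("duplicate model name: ", name)
    spec <- modelSpec(name, seed = seed)
    rep <- tryCatch(
      crossvalProtocol(designFor(spec$basis), spec, seed = seed,
                       folds = folds, resolutions = resolutions,
                       nNull = nNull),
      error = function(e) {
        failures <<- c(failures, sprintf("%s: %s", name,
                                         conditionMessage(e)))
        NULL
      })
    if (!is.null(rep)) reports[[name]] <- rep
  }
  scores <- if (length(reports) >= 2) normalizedScores(reports) else NULL
  winner <- if (length(reports)) {
    I <- vapply(reports, function(r) unname(r@summary["meanITest"]), 1)
    names(reports)[which.max(I)]
  } else NA_character_

  out <- list(reports = reports, scores = scores, winner = winner,
              failures = failures, configChecksum = checksum)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- do.call(rbind, lapply(reports, function(r)
      cbind(model = r@model, r@table)))
    utils::write.csv(tab, file.path(cfg$output_dir, "folds.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(winner = winner, configChecksum = checksum,
           failures = failures,
           summary = lapply(reports, function(r) as.list(r@summary))),
      file.path(cfg$output_dir, "summary.json"), auto_unbox = TRUE,
      digits = NA)
    if (!is.null(scores))
      utils::write.csv(scores, file.path(cfg$output_dir, "scores.csv"),
                       row.names = FALSE)
  }
  out
}
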