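#' @include ensemble-sim.R
NULL

#' Activity-density grids
#'
#' `jGridDefault()` is the 9-value grid 0.4-2% in steps of 0.2.
#' `jGridEightPoint()` is the 8-value preset used for the 100-field accuracy
#' figure, which omits 1.2%.
#'
#' @return numeric vector of activity densities (percent)
#' @export
jGridDefault <- function() seq(0.4, 2.0, by = 0.2)

#' @rdname jGridDefault
#' @export
jGridEightPoint <- function() c(0.4, 0.6, 0.8, 1.0, 1.4, 1.6, 1.8, 2.0)

#' Derive child seeds from a master seed
#'
#' Deterministically expands one master seed into `n` distinct child seeds
#' (all < 2^31) by drawing them from R's RNG seeded with the master seed.
#' Each replicate of an experiment runs under its own child seed, so any
#' single replicate can be re-run in isolation from the seed ledger.
#'
#' @param masterSeed integer master seed
#' @param n number of child seeds
#' @return integer vector of length `n`
#' @export
childSeeds <- function(masterSeed, n) {
  withr::with_seed(as.integer(masterSeed),
                   sample.int(.Machine$integer.max - 1L, n))
}

.checkGrid <- function(x, name) {
  if (!length(x) || any(!is.finite(x)))
    stop(name, " must be a non-empty finite vector")
  if (is.unsorted(x, strictly = TRUE))
    stop(name, " must be strictly ascending")
  x
}

#' Precision sweep over activity density
#'
#' Precision is the spread (SD) of the 700 per-glomerulus output values of a
#' single field. For each activity density on the grid, `replicates`
#' independent conversions are run and the within-field SD of the glomerular
#' output recorded; the per-point table reports the mean within-field SD
#' (and the mean output level). Increasing activity density widens the range
#' of input counts with non-negligible probability and so inflates this SD.
#'
#' @param jValues ascending activity-density grid (percent)
#' @param params a \linkS4class{ConnectivityParams}
#' @param config an \linkS4class{EnsembleConfig}
#' @param replicates conversions per grid point (default 100)
#' @param seed master seed
#' @return a \linkS4class{SweepResult} (`sweepVariable = "j"`) whose
#'   `perPoint` has columns `j`, `meanOutput`, `sdWithin`, and whose
#'   `details` holds one row per replicate
#' @export
precisionSweep <- function(jValues = jGridDefault(),
                           params = ConnectivityParams(),
                           config = EnsembleConfig(),
                           replicates = 100L, seed) {
  .checkGrid(jValues, "jValues")
  seeds <- matrix(childSeeds(seed, length(jValues) * replicates),
                  nrow = replicates)
  det <- vector("list", length(jValues))
  for (a in seq_along(jValues)) {
    j <- jValues[a]
    wsd <- fm <- numeric(replicates)
    for (r in seq_len(replicates)) {
      res <- runConversion(j, params, config, seeds[r, a])
      g <- glomerularValues(res)
      wsd[r] <- stats::sd(g); fm[r] <- mean(g)
    }
    det[[a]] <- data.frame(j = j, replicate = seq_len(replicates),
                           seed = seeds[, a], fieldMean = fm, withinSD = wsd)
  }
  details <- do.call(rbind, det)
  pp <- do.call(rbind, lapply(det, function(d) data.frame(
    j = d$j[1], meanOutput = mean(d$fieldMean), sdWithin = mean(d$withinSD))))
  new("SweepResult", sweepVariable = "j", grid = as.numeric(jValues),
      replicates = as.integer(replicates), perPoint = pp, details = details,
      masterSeed = as.integer(seed))
}

#' Accuracy sweep over activity density
#'
#' Accuracy is reproducibility: how tightly grouped the per-field mean
#' output is across many fields. For each activity density, `nFields`
#' independent conversions are run and each field's mean of the 700
#' glomerular values recorded; the SD of those field means measures
#' accuracy (higher SD = lower accuracy). With `replicates > 1` the whole
#' `nFields`-field experiment is repeated and the per-point SD is the mean
#' of the within-sweep SDs, which stabilises the accuracy estimate.
#' The grand mean output is linear in activity density.
#'
#' @param jValues ascending activity-density grid (percent)
#' @param nFields independent fields per grid point (default 100, >= 2)
#' @param params a \linkS4class{ConnectivityParams}
#' @param config an \linkS4class{EnsembleConfig}
#' @param replicates replicate `nFields`-field sweeps (default 1)
#' @param seed master seed
#' @return a \linkS4class{SweepResult} whose `perPoint` has columns `j`,
#'   `grandMean`, `sdOfMeans`; `details` holds one row per field
#' @export
accuracySweep <- function(jValues = jGridDefault(), nFields = 100L,
                          params = ConnectivityParams(),
                          config = EnsembleConfig(),
                          replicates = 1L, seed) {
  .checkGrid(jValues, "jValues")
  if (!.scalarCount(nFields) || nFields < 2) stop("nFields must be >= 2")
  nj <- length(jValues)
  seeds <- array(childSeeds(seed, nj * replicates * nFields),
                 dim = c(nFields, replicates, nj))
  det <- vector("list", nj)
  pp <- vector("list", nj)
  for (a in seq_len(nj)) {
    j <- jValues[a]
    rows <- vector("list", replicates)
    sdPerSweep <- numeric(replicates)
    for (r in seq_len(replicates)) {
      fm <- numeric(nFields)
      for (f in seq_len(nFields))
        fm[f] <- mean(glomerularValues(runConversion(j, params, config,
                                                     seeds[f, r, a])))
      sdPerSweep[r] <- stats::sd(fm)
      rows[[r]] <- data.frame(j = j, replicate = r, field = seq_len(nFields),
                              seed = seeds[, r, a], fieldMean = fm)
    }
    det[[a]] <- do.call(rbind, rows)
    pp[[a]] <- data.frame(j = j, grandMean = mean(det[[a]]$fieldMean),
                          sdOfMeans = mean(sdPerSweep))
  }
  new("SweepResult", sweepVariable = "j", grid = as.numeric(jValues),
      replicates = as.integer(replicates), perPoint = do.call(rbind, pp),
      details = do.call(rbind, det), masterSeed = as.integer(seed))
}

#' Linearity of grand mean output in activity density
#'
#' Regresses the grand mean output of an accuracy sweep on activity density.
#' Because every stage is an unbiased average, the expected output equals
#' the expected dendritic input count, which is proportional to the number
#' of active fibres and hence to `j`.
#'
#' @param sweep a \linkS4class{SweepResult} from [accuracySweep()]
#' @return list with `slope`, `intercept` and `r.squared`
#' @export
sweepLinearity <- function(sweep) {
  stopifnot(is(sweep, "SweepResult"), sweepVariable(sweep) == "j")
  pp <- perPoint(sweep)
  if (!"grandMean" %in% names(pp))
    stop("sweepLinearity needs an accuracy sweep (grandMean per point)")
  fit <- stats::lm(grandMean ~ j, data = pp)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r.squared = summary(fit)$r.squared)
}

#' Gap-junction group-size sweep
#'
#' Re-runs the conversion with different gap-junction group sizes at fixed
#' activity density and records, per replicate, the within-field SD of the
#' glomerular output and the SD of the stage-2 group means. Larger groups
#' average over more dendrites, so the group-mean SD shrinks roughly as
#' `1/sqrt(size)` — a rapidly diminishing return, with almost no gain above
#' a group size of about 6. Per point the table reports the mean within-field
#' SD (`sdWithin`), the pooled group-mean SD (`sdGroupPooled`, root mean of
#' per-run variances) and the pooled dendritic-input SD (`sdInputPooled`),
#' whose ratio is the empirical variance-contraction factor of stage 2.
#'
#' @param sizes ascending group sizes, each >= 1 and < total dendrites
#' @param j activity density (percent), default 1
#' @param params a \linkS4class{ConnectivityParams}
#' @param config an \linkS4class{EnsembleConfig} (its `gapGroupSize` is
#'   overridden by each swept size)
#' @param replicates conversions per size (default 100)
#' @param seed master seed
#' @return a \linkS4class{SweepResult} (`sweepVariable = "gapGroupSize"`)
#' @export
groupSizeSweep <- function(sizes = c(2L, 4L, 6L, 8L, 10L, 12L), j = 1,
                           params = ConnectivityParams(),
                           config = EnsembleConfig(),
                           replicates = 100L, seed) {
  .checkGrid(sizes, "sizes")
  nDend <- totalDendrites(config)
  if (any(sizes < 1 | sizes >= nDend))
    stop("group sizes must be >= 1 and smaller than the total dendrite count")
  seeds <- matrix(childSeeds(seed, length(sizes) * replicates),
                  nrow = replicates)
  det <- vector("list", length(sizes))
  for (a in seq_along(sizes)) {
    cfg <- config
    cfg@gapGroupSize <- as.integer(sizes[a])
    validObject(cfg)
    wsd <- gsd <- isd <- numeric(replicates)
    for (r in seq_len(replicates)) {
      res <- runConversion(j, params, cfg, seeds[r, a])
      wsd[r] <- stats::sd(glomerularValues(res))
      gsd[r] <- stats::sd(groupMeans(res))
      isd[r] <- stats::sd(dendriticInputs(res))
    }
    det[[a]] <- data.frame(gapGroupSize = sizes[a],
                           replicate = seq_len(replicates),
                           seed = seeds[, a], withinSD = wsd,
                           groupMeanSD = gsd, inputSD = isd)
  }
  details <- do.call(rbind, det)
  pp <- do.call(rbind, lapply(det, function(d) data.frame(
    gapGroupSize = d$gapGroupSize[1],
    sdWithin = mean(d$withinSD),
    sdGroupPooled = sqrt(mean(d$groupMeanSD^2)),
    sdInputPooled = sqrt(mean(d$inputSD^2)))))
  new("SweepResult", sweepVariable = "gapGroupSize",
      grid = as.numeric(sizes), replicates = as.integer(replicates),
      perPoint = pp, details = details, masterSeed = as.integer(seed))
}

#' Repeated conversions at fixed activity density
#'
#' Runs the full conversion `nRuns` times at the same activity density, each
#' run independently re-sampled from the same input distribution, and
#' tracks per run the mean dendritic input count, the mean of the
#' gap-junction group means, the mean somatic value and the mean glomerular
#' output (the field mean). The group-mean series tracks the dendritic
#' series closely; the output series varies independently of the input
#' series except in its mean and SD, and the across-run SD of the output is
#' governed by activity density.
#'
#' @param j activity density (percent)
#' @param nRuns number of repeated conversions (default 100)
#' @param params a \linkS4class{ConnectivityParams}
#' @param config an \linkS4class{EnsembleConfig}
#' @param seed master seed
#' @return a \linkS4class{RepeatedRunsResult}
#' @export
repeatedRuns <- function(j, nRuns = 100L, params = ConnectivityParams(),
                         config = EnsembleConfig(), seed) {
  if (!.scalarCount(nRuns) || nRuns < 1) stop("nRuns must be >= 1")
  seeds <- childSeeds(seed, nRuns)
  dm <- gm <- sm <- om <- numeric(nRuns)
  for (r in seq_len(nRuns)) {
    res <- runConversion(j, params, config, seeds[r])
    dm[r] <- mean(dendriticInputs(res))
    gm[r] <- mean(groupMeans(res))
    sm[r] <- mean(somaticValues(res))
    om[r] <- mean(glomerularValues(res))
  }
  runs <- data.frame(run = seq_len(nRuns), seed = seeds,
                     dendriticMean = dm, groupMeanMean = gm,
                     somaticMean = sm, glomerularMean = om)
  new("RepeatedRunsResult", j = j, masterSeed = as.integer(seed), runs = runs)
}
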