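#' @include probability-model.R
NULL

# Stage functions consume the current RNG stream; runConversion() wraps the
# whole chain in one seeded generator with a fixed order of consumption
# (dendritic draw; gap-junction samples in index order; somatic permutation;
# glomerular sample sizes, then per-glomerulus samples in order).

#' Stage 1: dendritic input generation
#'
#' One independent draw of the active-input count per apical dendrite in the
#' ensemble, from a per-dendrite input distribution.
#'
#' @param dist an \linkS4class{ActiveInputDistribution} with
#'   `scope = "dendrite"`
#' @param config an \linkS4class{EnsembleConfig}
#' @return integer vector of length `totalDendrites(config)`
#' @export
generateDendriticInputs <- function(dist, config = EnsembleConfig()) {
  if (!is(dist, "ActiveInputDistribution"))
    stop("dist must be an ActiveInputDistribution")
  if (distScope(dist) != "dendrite")
    stop("dendritic inputs need a per-dendrite distribution (scope = 'dendrite')")
  nDend <- totalDendrites(config)
  if (dist@nActive == 0L) return(integer(nDend))
  stats::rbinom(nDend, dist@nActive, dist@prob)
}

.gapPool <- function(i, n, includeSelf, window) {
  if (is.finite(window)) {
    lo <- max(1L, i - as.integer(window)); hi <- min(n, i + as.integer(window))
    pool <- lo:hi
    if (!includeSelf) pool <- pool[pool != i]
  } else {
    pool <- if (includeSelf) seq_len(n) else seq_len(n)[-i]
  }
  pool
}

#' Stage 2: gap-junction charge equalisation
#'
#' Models charge sharing in gap-junction groups as sample-mean computation:
#' the value at each dendrite index is replaced by the mean of a random
#' sample of `gapGroupSize` distinct surrounding index positions (the focal
#' dendrite excluded unless `includeSelf`). All group means are taken from
#' the same pre-update snapshot, so the result does not depend on the order
#' in which positions are processed. By default partners are drawn uniformly
#' from the whole ensemble; a finite `neighbourhoodWindow` in the config
#' restricts partners to nearby indices.
#'
#' @param inputs numeric vector of per-dendrite values (stage 1 output)
#' @param config an \linkS4class{EnsembleConfig}
#' @return numeric vector of group means, same length as `inputs`
#' @export
gapJunctionEqualise <- function(inputs, config = EnsembleConfig()) {
  n <- length(inputs)
  if (n != totalDendrites(config))
    stop("inputs must have one value per dendrite (", totalDendrites(config), ")")
  s <- gapGroupSize(config)
  incl <- config@includeSelf
  w <- config@neighbourhoodWindow
  maxPool <- if (incl) n else n - 1L
  if (s > maxPool)
    stop("gapGroupSize (", s, ") exceeds the number of available sampling partners")
  snapshot <- as.numeric(inputs)
  out <- numeric(n)
  if (!is.finite(w) && !incl && n >= 2L) {
    # common case: uniform over the other n-1 indices; draw from 1..n-1 and
    # skip over the focal index
    for (i in seq_len(n)) {
      idx <- sample.int(n - 1L, s)
      idx <- idx + (idx >= i)
      out[i] <- sum(snapshot[idx]) / s
    }
  } else {
    for (i in seq_len(n)) {
      pool <- .gapPool(i, n, incl, w)
      if (length(pool) < s)
        stop("dendrite ", i, " has fewer than gapGroupSize sampling partners ",
             "under the neighbourhood window")
      out[i] <- mean(snapshot[pool[sample.int(length(pool), s)]])
    }
  }
  out
}

#' Stage 3: somatic integration
#'
#' The group means are randomly divided into pre-assigned disjoint groups of
#' `dendritesPerCell` (one group per Golgi cell) and averaged, representing
#' somatic integration of dendritic charge. On the normalised scale the
#' somatic value also represents the cell's firing rate. The partition is a
#' uniformly random disjoint partition fixed once per run; it is returned in
#' the `"partition"` attribute (a `dendritesPerCell x nSomata` index matrix).
#'
#' @param values numeric vector of group means (stage 2 output); its length
#'   must be divisible by `dendritesPerCell(config)`
#' @param config an \linkS4class{EnsembleConfig}
#' @return numeric vector of `length(values) / dendritesPerCell` somatic
#'   means, with the partition as an attribute
#' @export
somaticIntegration <- function(values, config = EnsembleConfig()) {
  d <- dendritesPerCell(config)
  n <- length(values)
  if (n %% d != 0L)
    stop("length of values (", n, ") is not divisible by dendritesPerCell (", d, ")")
  part <- matrix(sample.int(n), nrow = d)
  out <- colMeans(matrix(as.numeric(values)[part], nrow = d))
  attr(out, "partition") <- part
  out
}

#' Stage 4: glomerular sampling of Golgi cell rates
#'
#' Each glomerulus in the middle field receives convergent innervation from a
#' random subset of the ensemble's Golgi cells and its inhibition level is
#' the mean of their rates. For each glomerulus a sample size is drawn
#' uniformly from `convergenceMin:convergenceMax` (individually per
#' glomerulus), that many distinct somata are drawn uniformly, and their
#' mean is recorded. Samples are independent across glomeruli (any
#' glomerulus can receive any subset, regardless of the others).
#'
#' @param somatic numeric vector of somatic values (stage 3 output)
#' @param config an \linkS4class{EnsembleConfig}
#' @param nGlomeruli number of glomeruli to sample (default
#'   `glomeruliPerField(config)`)
#' @return numeric vector of `nGlomeruli` glomerular means
#' @export
glomerularOutput <- function(somatic, config = EnsembleConfig(),
                             nGlomeruli = glomeruliPerField(config)) {
  nSoma <- length(somatic)
  cr <- convergenceRange(config)
  if (cr[2] > nSoma)
    stop("convergenceMax (", cr[2], ") exceeds the number of somata (", nSoma, ")")
  somatic <- as.numeric(somatic)
  sizes <- if (cr[1] == cr[2]) rep.int(cr[1], nGlomeruli)
           else cr[1] - 1L + sample.int(cr[2] - cr[1] + 1L, nGlomeruli, replace = TRUE)
  out <- numeric(nGlomeruli)
  for (g in seq_len(nGlomeruli))
    out[g] <- sum(somatic[sample.int(nSoma, sizes[g])]) / sizes[g]
  out
}

#' Run one full ensemble conversion
#'
#' Chains the four stages — dendritic input generation, gap-junction
#' equalisation, somatic integration, glomerular sampling — under a single
#' seeded generator, and returns all four stage vectors with per-stage
#' summaries. Identical `(j, params, config, seed)` give a bit-identical
#' result. The caller's RNG state is left untouched.
#'
#' @param j activity density in percent (> 0; densities small enough to give
#'   zero active fibres propagate zeros through every stage)
#' @param params a \linkS4class{ConnectivityParams}
#' @param config an \linkS4class{EnsembleConfig}
#' @param seed integer run seed
#' @return a \linkS4class{ConversionResult}
#' @examples
#' res <- runConversion(j = 1, seed = 1L)
#' stageSummary(res)
#' @export
runConversion <- function(j, params = ConnectivityParams(),
                          config = EnsembleConfig(), seed) {
  if (missing(seed) || !.scalarCount(seed)) stop("an integer run seed is required")
  seed <- as.integer(seed)
  dist <- buildDistribution(params, j, scope = "dendrite")
  withr::with_seed(seed, {
    dend <- generateDendriticInputs(dist, config)
    grp  <- gapJunctionEqualise(dend, config)
    som  <- somaticIntegration(grp, config)
    glom <- glomerularOutput(som, config)
    new("ConversionResult", j = j, seed = seed,
        dendriticInputs = as.integer(dend), groupMeans = grp,
        somaticValues = as.numeric(som), glomerularValues = glom,
        somaticPartition = attr(som, "partition"),
        params = params, config = config)
  })
}
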