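#' @include AllGenerics.R
NULL

.scalarCount <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}

# ---------------------------------------------------------------------------
# ConnectivityParams
# ---------------------------------------------------------------------------

#' Parallel fibre to Golgi cell connectivity parameters
#'
#' Anatomical constants that parameterize the binomial model of active
#' parallel-fibre input counts: the number of parallel fibres passing through
#' the territory of a single apical dendrite, the probability that any one
#' active fibre contacts the cell, and the number of apical dendrites per
#' Golgi cell (contact probability per dendrite is the per-cell probability
#' divided by the dendrite count).
#'
#' @slot fibresPerTerritory number of parallel fibres passing through a
#'   single-dendrite territory (default 175,000)
#' @slot contactProbability probability that an active parallel fibre contacts
#'   the cell (default 0.00342, i.e. 1,200 contacts out of ~350,000 fibres in
#'   a whole-cell territory, 1 in ~292)
#' @slot dendritesPerCell apical dendrites per Golgi cell (default 3)
#' @export
setClass("ConnectivityParams",
  slots = c(
    fibresPerTerritory = "numeric",
    contactProbability = "numeric",
    dendritesPerCell   = "integer"
  ),
  prototype = list(
    fibresPerTerritory = 175000,
    contactProbability = 0.00342,
    dendritesPerCell   = 3L
  )
)

setValidity("ConnectivityParams", function(object) {
  msg <- character()
  if (!.scalarCount(object@fibresPerTerritory) || object@fibresPerTerritory <= 0)
    msg <- c(msg, "fibresPerTerritory must be a positive integer count")
  p <- object@contactProbability
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    msg <- c(msg, "contactProbability must lie strictly between 0 and 1")
  if (!.scalarCount(object@dendritesPerCell) || object@dendritesPerCell < 1L)
    msg <- c(msg, "dendritesPerCell must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn ConnectivityParams-class constructor with anatomical defaults
#' @param fibresPerTerritory,contactProbability,dendritesPerCell see slots
#' @export
ConnectivityParams <- function(fibresPerTerritory = 175000,
                               contactProbability = 0.00342,
                               dendritesPerCell = 3L) {
  new("ConnectivityParams",
      fibresPerTerritory = as.numeric(fibresPerTerritory),
      contactProbability = as.numeric(contactProbability),
      dendritesPerCell = as.integer(dendritesPerCell))
}

setMethod("fibresPerTerritory", "ConnectivityParams", function(x) x@fibresPerTerritory)
setMethod("contactProbability", "ConnectivityParams", function(x) x@contactProbability)
setMethod("dendritesPerCell", "ConnectivityParams", function(x) x@dendritesPerCell)

setMethod("show", "ConnectivityParams", function(object) {
  cat("ConnectivityParams\n",
      "  parallel fibres per dendritic territory: ",
      format(object@fibresPerTerritory, big.mark = ","), "\n",
      "  contact probability (per cell): ", object@contactProbability, "\n",
      "  apical dendrites per cell: ", object@dendritesPerCell,
      "  (per-dendrite p = ",
      signif(object@contactProbability / object@dendritesPerCell, 4), ")\n",
      sep = "")
})

# ---------------------------------------------------------------------------
# EnsembleConfig
# ---------------------------------------------------------------------------

#' Golgi cell ensemble architecture
#'
#' The architecture of one ensemble: a sagittal row of three fields whose
#' Golgi cells all inhibit the middle field. Defaults give 3 dendrites/cell
#' x 10 cells/field x 3 fields = 90 apical dendrites and 30 somata, 700
#' glomeruli in the middle field, a gap-junction group size of 6 and a
#' Golgi-to-glomerulus convergence of 8-12 cells.
#'
#' @slot fieldsPerEnsemble fields per ensemble (default 3)
#' @slot cellsPerField Golgi cells per field (default 10)
#' @slot dendritesPerCell apical dendrites per cell (default 3)
#' @slot gapGroupSize dendrites sampled per gap-junction group (default 6)
#' @slot glomeruliPerField glomeruli in the middle field (default 700)
#' @slot convergenceMin,convergenceMax range of Golgi cells innervating one
#'   glomerulus (defaults 8 and 12)
#' @slot includeSelf whether a dendrite's own value enters its gap-junction
#'   sample (default `FALSE`: samples are taken from surrounding positions)
#' @slot neighbourhoodWindow maximum index distance of gap-junction sampling
#'   partners; `Inf` (default) samples uniformly from the whole ensemble
#' @export
setClass("EnsembleConfig",
  slots = c(
    fieldsPerEnsemble = "integer",
    cellsPerField     = "integer",
    dendritesPerCell  = "integer",
    gapGroupSize      = "integer",
    glomeruliPerField = "integer",
    convergenceMin    = "integer",
    convergenceMax    = "integer",
    includeSelf       = "logical",
    neighbourhoodWindow = "numeric"
  ),
  prototype = list(
    fieldsPerEnsemble = 3L, cellsPerField = 10L, dendritesPerCell = 3L,
    gapGroupSize = 6L, glomeruliPerField = 700L,
    convergenceMin = 8L, convergenceMax = 12L,
    includeSelf = FALSE, neighbourhoodWindow = Inf
  )
)

setValidity("EnsembleConfig", function(object) {
  msg <- character()
  for (nm in c("fieldsPerEnsemble", "cellsPerField", "dendritesPerCell",
               "gapGroupSize", "glomeruliPerField",
               "convergenceMin", "convergenceMax")) {
    v <- slot(object, nm)
    if (!.scalarCount(v) || v < 1L)
      msg <- c(msg, paste0(nm, " must be a positive integer"))
  }
  if (length(msg)) return(msg)
  nDend <- object@fieldsPerEnsemble * object@cellsPerField * object@dendritesPerCell
  nSoma <- object@fieldsPerEnsemble * object@cellsPerField
  if (object@gapGroupSize >= nDend)
    msg <- c(msg, sprintf("gapGroupSize (%d) must be smaller than the total number of dendrites (%d)",
                          object@gapGroupSize, nDend))
  if (object@convergenceMin > object@convergenceMax)
    msg <- c(msg, "convergenceMin must not exceed convergenceMax")
  if (object@convergenceMax > nSoma)
    msg <- c(msg, sprintf("convergenceMax (%d) exceeds the number of somata (%d)",
                          object@convergenceMax, nSoma))
  if (length(object@includeSelf) != 1L || is.na(object@includeSelf))
    msg <- c(msg, "includeSelf must be TRUE or FALSE")
  w <- object@neighbourhoodWindow
  if (length(w) != 1L || is.na(w) || w < 1)
    msg <- c(msg, "neighbourhoodWindow must be >= 1 (Inf for unrestricted)")
  else if (is.finite(w) && w < object@gapGroupSize)
    msg <- c(msg, "neighbourhoodWindow must be at least gapGroupSize so every dendrite has enough sampling partners")
  if (length(msg)) msg else TRUE
})

#' @describeIn EnsembleConfig-class constructor with ensemble defaults
#' @param fieldsPerEnsemble,cellsPerField,dendritesPerCell,gapGroupSize see slots
#' @param glomeruliPerField,convergenceMin,convergenceMax see slots
#' @param includeSelf,neighbourhoodWindow see slots
#' @export
EnsembleConfig <- function(fieldsPerEnsemble = 3L, cellsPerField = 10L,
                           dendritesPerCell = 3L, gapGroupSize = 6L,
                           glomeruliPerField = 700L,
                           convergenceMin = 8L, convergenceMax = 12L,
                           includeSelf = FALSE, neighbourhoodWindow = Inf) {
  new("EnsembleConfig",
      fieldsPerEnsemble = as.integer(fieldsPerEnsemble),
      cellsPerField = as.integer(cellsPerField),
      dendritesPerCell = as.integer(dendritesPerCell),
      gapGroupSize = as.integer(gapGroupSize),
      glomeruliPerField = as.integer(glomeruliPerField),
      convergenceMin = as.integer(convergenceMin),
      convergenceMax = as.integer(convergenceMax),
      includeSelf = isTRUE(includeSelf),
      neighbourhoodWindow = as.numeric(neighbourhoodWindow))
}

setMethod("fieldsPerEnsemble", "EnsembleConfig", function(x) x@fieldsPerEnsemble)
setMethod("cellsPerField", "EnsembleConfig", function(x) x@cellsPerField)
setMethod("dendritesPerCell", "EnsembleConfig", function(x) x@dendritesPerCell)
setMethod("gapGroupSize", "EnsembleConfig", function(x) x@gapGroupSize)
setMethod("glomeruliPerField", "EnsembleConfig", function(x) x@glomeruliPerField)
setMethod("convergenceRange", "EnsembleConfig",
          function(x) c(x@convergenceMin, x@convergenceMax))
setMethod("totalDendrites", "EnsembleConfig",
          function(x) x@fieldsPerEnsemble * x@cellsPerField * x@dendritesPerCell)
setMethod("totalSomata", "EnsembleConfig",
          function(x) x@fieldsPerEnsemble * x@cellsPerField)

setMethod("show", "EnsembleConfig", function(object) {
  cat("EnsembleConfig\n",
      "  ", object@dendritesPerCell, " dendrites/cell x ",
      object@cellsPerField, " cells/field x ", object@fieldsPerEnsemble,
      " fields = ", totalDendrites(object), " dendrites, ",
      totalSomata(object), " somata\n",
      "  gap-junction group size: ", object@gapGroupSize,
      if (object@includeSelf) " (focal dendrite included)" else "", "\n",
      "  glomeruli in middle field: ", object@glomeruliPerField,
      "; convergence ", object@convergenceMin, "-", object@convergenceMax, "\n",
      sep = "")
  if (is.finite(object@neighbourhoodWindow))
    cat("  sampling restricted to index distance <=",
        object@neighbourhoodWindow, "\n")
})

# ---------------------------------------------------------------------------
# ActiveInputDistribution
# ---------------------------------------------------------------------------

#' Distribution of active parallel-fibre input counts
#'
#' The probability distribution of the number of active parallel fibres
#' contacting a Golgi cell (`scope = "cell"`) or one apical dendrite
#' (`scope = "dendrite"`) when a percentage `j` of the general parallel-fibre
#' population is active. The count is binomial: `n` active fibres pass the
#' territory (`n = round(j/100 * fibresPerTerritory)`), each contacting
#' independently with probability `contactProbability` (per cell) or
#' `contactProbability / dendritesPerCell` (per dendrite).
#'
#' @slot j activity density: percentage of parallel fibres active
#' @slot scope `"cell"` or `"dendrite"`
#' @slot nActive number of active fibres in the territory
#' @slot prob per-trial contact probability at this scope
#' @slot pmf full probability mass over k = 0..nActive (names are k)
#' @slot truncationThreshold display floor for [truncatedPmf()] (default 0.001)
#' @seealso [buildDistribution()], [pmfActiveInputs()], [sampleInputCounts()]
#' @export
setClass("ActiveInputDistribution",
  slots = c(
    j = "numeric",
    scope = "character",
    nActive = "integer",
    prob = "numeric",
    pmf = "numeric",
    truncationThreshold = "numeric"
  )
)

setValidity("ActiveInputDistribution", function(object) {
  msg <- character()
  if (!object@scope %in% c("cell", "dendrite"))
    msg <- c(msg, "scope must be 'cell' or 'dendrite'")
  if (object@nActive < 0L)
    msg <- c(msg, "nActive must be non-negative")
  if (length(object@pmf) != object@nActive + 1L)
    msg <- c(msg, "pmf must have one entry per k = 0..nActive")
  if (any(object@pmf < 0 | object@pmf > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (abs(sum(object@pmf) - 1) > 1e-12)
    msg <- c(msg, "full pmf must sum to 1 within 1e-12")
  if (length(msg)) msg else TRUE
})

setMethod("activityDensity", "ActiveInputDistribution", function(x) x@j)
setMethod("nActive", "ActiveInputDistribution", function(x) x@nActive)
setMethod("distScope", "ActiveInputDistribution", function(x) x@scope)
setMethod("pmfValues", "ActiveInputDistribution", function(x) x@pmf)

setMethod("show", "ActiveInputDistribution", function(object) {
  mu <- object@nActive * object@prob
  cat("ActiveInputDistribution (", object@scope, ")\n",
      "  j = ", object@j, "% active -> n = ", object@nActive,
      " active fibres, p = ", signif(object@prob, 4), "\n",
      "  mean active inputs: ", signif(mu, 4),
      "; k with P > ", object@truncationThreshold, ": ",
      sum(object@pmf > object@truncationThreshold), "\n", sep = "")
})

# ---------------------------------------------------------------------------
# ConversionResult
# ---------------------------------------------------------------------------

#' Result of one ensemble conversion
#'
#' The four per-stage value vectors of a single seeded ensemble run:
#' dendritic active-input counts, gap-junction group means, somatic values
#' (on the normalised scale, somatic charge and firing rate are the same
#' numbers) and per-glomerulus output values (inhibition), plus per-stage
#' summary statistics. Each stage is an average of values from the previous
#' stage, so each stage's range is contained in the previous stage's range.
#'
#' @slot j activity density used
#' @slot seed the run seed
#' @slot dendriticInputs integer active-input counts, one per dendrite
#' @slot groupMeans gap-junction group means, one per dendrite
#' @slot somaticValues somatic means, one per Golgi cell
#' @slot glomerularValues glomerular sample means, one per middle-field glomerulus
#' @slot somaticPartition integer matrix (dendrites/cell x somata) recording
#'   which group means were averaged into each soma
#' @slot params the \linkS4class{ConnectivityParams} used
#' @slot config the \linkS4class{EnsembleConfig} used
#' @export
setClass("ConversionResult",
  slots = c(
    j = "numeric",
    seed = "integer",
    dendriticInputs = "integer",
    groupMeans = "numeric",
    somaticValues = "numeric",
    glomerularValues = "numeric",
    somaticPartition = "matrix",
    params = "ConnectivityParams",
    config = "EnsembleConfig"
  )
)

setValidity("ConversionResult", function(object) {
  msg <- character()
  cfg <- object@config
  if (length(object@dendriticInputs) != totalDendrites(cfg))
    msg <- c(msg, "dendriticInputs length must equal the total dendrite count")
  if (length(object@groupMeans) != totalDendrites(cfg))
    msg <- c(msg, "groupMeans length must equal the total dendrite count")
  if (length(object@somaticValues) != totalSomata(cfg))
    msg <- c(msg, "somaticValues length must equal the total soma count")
  if (length(object@glomerularValues) != glomeruliPerField(cfg))
    msg <- c(msg, "glomerularValues length must equal glomeruliPerField")
  tol <- 1e-9
  contained <- function(x, y)  # every value of x inside range(y), up to fp error
    length(x) == 0L || (min(x) >= min(y) - tol && max(x) <= max(y) + tol)
  if (!contained(object@groupMeans, object@dendriticInputs))
    msg <- c(msg, "group means must lie within the range of dendritic inputs")
  if (!contained(object@somaticValues, object@groupMeans))
    msg <- c(msg, "somatic values must lie within the range of group means")
  if (!contained(object@glomerularValues, object@somaticValues))
    msg <- c(msg, "glomerular values must lie within the range of somatic values")
  if (length(msg)) msg else TRUE
})

setMethod("activityDensity", "ConversionResult", function(x) x@j)
setMethod("runSeed", "ConversionResult", function(x) x@seed)
setMethod("dendriticInputs", "ConversionResult", function(x) x@dendriticInputs)
setMethod("groupMeans", "ConversionResult", function(x) x@groupMeans)
setMethod("somaticValues", "ConversionResult", function(x) x@somaticValues)
setMethod("glomerularValues", "ConversionResult", function(x) x@glomerularValues)
setMethod("somaticPartition", "ConversionResult", function(x) x@somaticPartition)

setMethod("stageSummary", "ConversionResult", function(x) {
  stages <- list(dendritic = as.numeric(x@dendriticInputs),
                 group = x@groupMeans,
                 somatic = x@somaticValues,
                 glomerular = x@glomerularValues)
  data.frame(stage = names(stages),
             n = vapply(stages, length, integer(1)),
             mean = vapply(stages, mean, numeric(1)),
             sd = vapply(stages, stats::sd, numeric(1)),
             row.names = NULL)
})

setMethod("show", "ConversionResult", function(object) {
  cat("ConversionResult: j =", object@j, "% active, seed", object@seed, "\n")
  print(stageSummary(object), digits = 4)
})

# ---------------------------------------------------------------------------
# SweepResult
# ---------------------------------------------------------------------------

#' Result of a parameter sweep
#'
#' Per-grid-point summary of replicate ensemble conversions, produced by
#' [precisionSweep()], [accuracySweep()] or [groupSizeSweep()]. `perPoint`
#' has one row per grid value; `details` has one row per individual field /
#' replicate with its own child seed, so any row can be re-derived in
#' isolation.
#'
#' @slot sweepVariable `"j"` or `"gapGroupSize"`
#' @slot grid the swept values, in order
#' @slot replicates replicate conversions per grid point
#' @slot perPoint data.frame of per-grid-value summaries
#' @slot details data.frame of per-replicate values (includes seeds)
#' @slot masterSeed the master seed the child seeds were derived from
#' @export
setClass("SweepResult",
  slots = c(
    sweepVariable = "character",
    grid = "numeric",
    replicates = "integer",
    perPoint = "data.frame",
    details = "data.frame",
    masterSeed = "integer"
  )
)

setValidity("SweepResult", function(object) {
  msg <- character()
  if (!object@sweepVariable %in% c("j", "gapGroupSize"))
    msg <- c(msg, "sweepVariable must be 'j' or 'gapGroupSize'")
  if (nrow(object@perPoint) != length(object@grid))
    msg <- c(msg, "perPoint must have one row per grid value")
  sdCols <- grep("^sd", names(object@perPoint), value = TRUE)
  for (cn in sdCols)
    if (any(object@perPoint[[cn]] < 0, na.rm = TRUE))
      msg <- c(msg, paste0("negative SD in column ", cn))
  if (length(msg)) msg else TRUE
})

setMethod("sweepVariable", "SweepResult", function(x) x@sweepVariable)
setMethod("sweepGrid", "SweepResult", function(x) x@grid)
setMethod("perPoint", "SweepResult", function(x) x@perPoint)
setMethod("sweepDetails", "SweepResult", function(x) x@details)
setMethod("runSeed", "SweepResult", function(x) x@masterSeed)

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult over", object@sweepVariable,
      sprintf("(%d grid points x %d replicates, master seed %d)\n",
              length(object@grid), object@replicates, object@masterSeed))
  print(object@perPoint, digits = 4)
})

# ---------------------------------------------------------------------------
# RepeatedRunsResult
# ---------------------------------------------------------------------------

#' Repeated conversions at fixed activity density
#'
#' Produced by [repeatedRuns()]: the ensemble conversion re-run `nRuns` times
#' at the same activity density, each run independently re-sampled from the
#' same input distribution. Per run the table records the mean dendritic
#' input count, the mean of the gap-junction group means, the mean somatic
#' value and the mean glomerular output (the field mean).
#'
#' @slot j activity density
#' @slot masterSeed master seed
#' @slot runs data.frame with one row per run
#' @export
setClass("RepeatedRunsResult",
  slots = c(j = "numeric", masterSeed = "integer", runs = "data.frame")
)

setValidity("RepeatedRunsResult", function(object) {
  need <- c("run", "seed", "dendriticMean", "groupMeanMean",
            "somaticMean", "glomerularMean")
  if (!all(need %in% names(object@runs)))
    return(paste("runs table must contain columns:", paste(need, collapse = ", ")))
  TRUE
})

setMethod("activityDensity", "RepeatedRunsResult", function(x) x@j)
setMethod("runSeed", "RepeatedRunsResult", function(x) x@masterSeed)
setMethod("runTable", "RepeatedRunsResult", function(x) x@runs)

setMethod("show", "RepeatedRunsResult", function(object) {
  cat("RepeatedRunsResult: j =", object@j, "% active,",
      nrow(object@runs), "runs, master seed", object@masterSeed, "\n")
  cat(sprintf("  field-mean output: mean %.4g, SD %.4g\n",
              mean(object@runs$glomerularMean),
              stats::sd(object@runs$glomerularMean)))
})
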