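#' Accessor generics
#'
#' Accessors for the parameter, distribution and result classes. Slot access
#' (`@`) is internal; user code should go through these.
#'
#' @param x an object of the documented class
#' @param ... further arguments for methods
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fibresPerTerritory", function(x) standardGeneric("fibresPerTerritory"))

#' @rdname accessors
#' @export
setGeneric("contactProbability", function(x) standardGeneric("contactProbability"))

#' @rdname accessors
#' @export
setGeneric("dendritesPerCell", function(x) standardGeneric("dendritesPerCell"))

#' @rdname accessors
#' @export
setGeneric("fieldsPerEnsemble", function(x) standardGeneric("fieldsPerEnsemble"))

#' @rdname accessors
#' @export
setGeneric("cellsPerField", function(x) standardGeneric("cellsPerField"))

#' @rdname accessors
#' @export
setGeneric("gapGroupSize", function(x) standardGeneric("gapGroupSize"))

#' @rdname accessors
#' @export
setGeneric("glomeruliPerField", function(x) standardGeneric("glomeruliPerField"))

#' @rdname accessors
#' @export
setGeneric("convergenceRange", function(x) standardGeneric("convergenceRange"))

#' @rdname accessors
#' @export
setGeneric("totalDendrites", function(x) standardGeneric("totalDendrites"))

#' @rdname accessors
#' @export
setGeneric("totalSomata", function(x) standardGeneric("totalSomata"))

#' @rdname accessors
#' @export
setGeneric("activityDensity", function(x) standardGeneric("activityDensity"))

#' @rdname accessors
#' @export
setGeneric("nActive", function(x) standardGeneric("nActive"))

#' @rdname accessors
#' @export
setGeneric("distScope", function(x) standardGeneric("distScope"))

#' @rdname accessors
#' @export
setGeneric("pmfValues", function(x) standardGeneric("pmfValues"))

#' @rdname accessors
#' @export
setGeneric("truncatedPmf", function(x) standardGeneric("truncatedPmf"))

#' @rdname accessors
#' @export
setGeneric("dendriticInputs", function(x) standardGeneric("dendriticInputs"))

#' @rdname accessors
#' @export
setGeneric("groupMeans", function(x) standardGeneric("groupMeans"))

#' @rdname accessors
#' @export
setGeneric("somaticValues", function(x) standardGeneric("somaticValues"))

#' @rdname accessors
#' @export
setGeneric("glomerularValues", function(x) standardGeneric("glomerularValues"))

#' @rdname accessors
#' @export
setGeneric("somaticPartition", function(x) standardGeneric("somaticPartition"))

#' @rdname accessors
#' @export
setGeneric("stageSummary", function(x) standardGeneric("stageSummary"))

#' @rdname accessors
#' @export
setGeneric("runSeed", function(x) standardGeneric("runSeed"))

#' @rdname accessors
#' @export
setGeneric("sweepVariable", function(x) standardGeneric("sweepVariable"))

#' @rdname accessors
#' @export
setGeneric("sweepGrid", function(x) standardGeneric("sweepGrid"))

#' @rdname accessors
#' @export
setGeneric("perPoint", function(x) standardGeneric("perPoint"))

#' @rdname accessors
#' @export
setGeneric("sweepDetails", function(x) standardGeneric("sweepDetails"))

#' @rdname accessors
#' @export
setGeneric("runTable", function(x) standardGeneric("runTable"))

#' Serialize a simulation result to disk
#'
#' @param x a \linkS4class{ConversionResult}, \linkS4class{SweepResult} or
#'   \linkS4class{RepeatedRunsResult}
#' @param path output file path
#' @param format `"csv"` (tidy table) or `"json"`
#' @return (invisibly) a manifest entry: a list with the path, format and
#'   schema of what was written
#' @export
setGeneric("writeResults", function(x, path, format = c("csv", "json"))
  standardGeneric("writeResults"))
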