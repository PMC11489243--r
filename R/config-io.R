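#' @include experiments.R
NULL

.configKeys <- list(
  connectivity = c("fibres_per_territory", "contact_probability",
                   "dendrites_per_cell"),
  ensemble = c("fields_per_ensemble", "cells_per_field", "dendrites_per_cell",
               "gap_group_size", "glomeruli_per_field",
               "convergence_min", "convergence_max",
               "include_self", "neighbourhood_window"),
  distribution = "truncation_threshold",
  experiment = c("j_grid", "replicates", "n_fields", "group_sizes",
                 "n_runs", "seed")
)

.snakeToArg <- function(x) gsub("_(.)", "\\U\\1", x, perl = TRUE)

#' Load and validate a configuration
#'
#' Reads a YAML or JSON configuration file (extension `.yaml`/`.yml` or
#' `.json`), applies `overrides` on top (overrides always win), rejects
#' unknown keys, and returns fully-resolved parameter objects with the
#' anatomical defaults filled in for everything unspecified. With
#' `path = NULL` the defaults alone are returned (optionally modified by
#' `overrides`).
#'
#' Recognised keys (all snake_case, flat): `fibres_per_territory`,
#' `contact_probability`, `dendrites_per_cell`, `truncation_threshold`,
#' `fields_per_ensemble`, `cells_per_field`, `gap_group_size`,
#' `glomeruli_per_field`, `convergence_min`, `convergence_max`,
#' `include_self`, `neighbourhood_window`, `j_grid`, `replicates`,
#' `n_fields`, `group_sizes`, `n_runs`, `seed`.
#'
#' @param path path to a YAML or JSON file, or `NULL` for defaults
#' @param overrides named list of keys overriding the file
#' @return list with elements `connectivity`
#'   (\linkS4class{ConnectivityParams}), `ensemble`
#'   (\linkS4class{EnsembleConfig}), `truncationThreshold`, and `experiment`
#'   (list of experiment settings)
#' @export
loadConfig <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    raw <- switch(ext,
      yaml = , yml = yaml::read_yaml(path),
      json = jsonlite::fromJSON(path, simplifyVector = TRUE),
      stop("unsupported config format '.", ext, "' (use YAML or JSON)"))
    if (is.null(raw)) raw <- list()
  }
  if (length(overrides) && (is.null(names(overrides)) || any(names(overrides) == "")))
    stop("overrides must be a named list")
  raw[names(overrides)] <- overrides
  known <- unique(unlist(.configKeys))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))

  take <- function(keys) {
    got <- raw[intersect(keys, names(raw))]
    stats::setNames(got, .snakeToArg(names(got)))
  }
  connectivity <- tryCatch(
    do.call(ConnectivityParams, take(.configKeys$connectivity)),
    error = function(e) stop("invalid connectivity configuration: ",
                             conditionMessage(e), call. = FALSE))
  ensemble <- tryCatch(
    do.call(EnsembleConfig, take(.configKeys$ensemble)),
    error = function(e) stop("invalid ensemble configuration: ",
                             conditionMessage(e), call. = FALSE))
  thr <- raw[["truncation_threshold"]]
  if (is.null(thr)) thr <- 0.001
  if (!is.numeric(thr) || length(thr) != 1L || thr < 0 || thr >= 1)
    stop("truncation_threshold must be a probability in [0, 1)")
  experiment <- list(
    jGrid = if (is.null(raw$j_grid)) jGridDefault() else as.numeric(raw$j_grid),
    replicates = if (is.null(raw$replicates)) 100L else as.integer(raw$replicates),
    nFields = if (is.null(raw$n_fields)) 100L else as.integer(raw$n_fields),
    groupSizes = if (is.null(raw$group_sizes)) c(2L, 4L, 6L, 8L, 10L, 12L)
                 else as.integer(raw$group_sizes),
    nRuns = if (is.null(raw$n_runs)) 100L else as.integer(raw$n_runs),
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  )
  list(connectivity = connectivity, ensemble = ensemble,
       truncationThreshold = thr, experiment = experiment)
}

# full-precision numeric formatting so CSV round-trips are bit-exact
.fmtFull <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

.writeTidyCSV <- function(df, path) {
  out <- df
  for (nm in names(out)) if (is.double(out[[nm]])) out[[nm]] <- .fmtFull(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Tidy data.frame views of results
#'
#' `as.data.frame` on a \linkS4class{ConversionResult} gives the long table
#' `stage,index,value` (stages `dendritic`, `group`, `somatic`,
#' `glomerular`); on a \linkS4class{SweepResult} the per-replicate `details`
#' table; on a \linkS4class{RepeatedRunsResult} the per-run table.
#'
#' @param x the result object
#' @param row.names,optional,... ignored (standard `as.data.frame` signature)
#' @return a data.frame
#' @name result-coercion
NULL

#' @rdname result-coercion
#' @export
setMethod("as.data.frame", "ConversionResult",
  function(x, row.names = NULL, optional = FALSE, ...) {
    stages <- list(dendritic = as.numeric(dendriticInputs(x)),
                   group = groupMeans(x),
                   somatic = somaticValues(x),
                   glomerular = glomerularValues(x))
    data.frame(
      stage = rep(names(stages), lengths(stages)),
      index = unlist(lapply(stages, seq_along), use.names = FALSE),
      value = unlist(stages, use.names = FALSE))
  })

#' @rdname result-coercion
#' @export
setMethod("as.data.frame", "SweepResult",
  function(x, row.names = NULL, optional = FALSE, ...) sweepDetails(x))

#' @rdname result-coercion
#' @export
setMethod("as.data.frame", "RepeatedRunsResult",
  function(x, row.names = NULL, optional = FALSE, ...) runTable(x))

.manifestEntry <- function(x, path, format, schema) {
  list(path = path, format = format, schema = schema,
       class = class(x)[1], written = format(Sys.time(), tz = "UTC"))
}

#' @rdname writeResults
#' @export
setMethod("writeResults", "ConversionResult",
  function(x, path, format = c("csv", "json")) {
    format <- match.arg(format)
    if (format == "csv") {
      .writeTidyCSV(as.data.frame(x), path)
      schema <- "stage,index,value"
    } else {
      payload <- list(
        j = x@j, seed = x@seed,
        dendritic_inputs = dendriticInputs(x),
        group_means = groupMeans(x),
        somatic_values = somaticValues(x),
        glomerular_values = glomerularValues(x),
        summary = stageSummary(x))
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
      schema <- "conversion-v1"
    }
    invisible(.manifestEntry(x, path, format, schema))
  })

.writeSweepLike <- function(x, path, format, df, jsonPayload, schema) {
  if (format == "csv") {
    .writeTidyCSV(df, path)
    schema <- paste(names(df), collapse = ",")
  } else {
    jsonlite::write_json(jsonPayload, path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(.manifestEntry(x, path, format, schema))
}

#' @rdname writeResults
#' @export
setMethod("writeResults", "SweepResult",
  function(x, path, format = c("csv", "json")) {
    format <- match.arg(format)
    .writeSweepLike(x, path, format, sweepDetails(x),
                    list(sweep_variable = sweepVariable(x),
                         grid = sweepGrid(x), replicates = x@replicates,
                         master_seed = x@masterSeed,
                         per_point = perPoint(x), details = sweepDetails(x)),
                    "sweep-v1")
  })

#' @rdname writeResults
#' @export
setMethod("writeResults", "RepeatedRunsResult",
  function(x, path, format = c("csv", "json")) {
    format <- match.arg(format)
    .writeSweepLike(x, path, format, runTable(x),
                    list(j = x@j, master_seed = x@masterSeed,
                         runs = runTable(x)),
                    "repeated-runs-v1")
  })

.paramsAsList <- function(params, config) {
  list(
    fibres_per_territory = fibresPerTerritory(params),
    contact_probability = contactProbability(params),
    dendrites_per_cell = dendritesPerCell(params),
    fields_per_ensemble = fieldsPerEnsemble(config),
    cells_per_field = cellsPerField(config),
    gap_group_size = gapGroupSize(config),
    glomeruli_per_field = glomeruliPerField(config),
    convergence_min = convergenceRange(config)[1],
    convergence_max = convergenceRange(config)[2],
    include_self = config@includeSelf,
    neighbourhood_window = config@neighbourhoodWindow)
}

#' Build and write a run manifest
#'
#' A manifest records everything needed to regenerate an experiment's
#' outputs bit-exactly: package version, the fully resolved parameter set,
#' the master seed, and the entries returned by [writeResults()] for each
#' output file. Timestamps are informational and excluded from
#' reproducibility comparisons.
#'
#' @param params a \linkS4class{ConnectivityParams}
#' @param config an \linkS4class{EnsembleConfig}
#' @param masterSeed integer master seed of the experiment
#' @param outputs list of manifest entries from [writeResults()]
#' @param extra optional named list of extra settings (e.g. the j grid)
#' @return manifest as a named list
#' @export
runManifest <- function(params = ConnectivityParams(),
                        config = EnsembleConfig(),
                        masterSeed, outputs = list(), extra = list()) {
  list(
    tool = "GolgiEnsemble",
    version = as.character(utils::packageVersion("GolgiEnsemble")),
    created = format(Sys.time(), tz = "UTC"),
    parameters = .paramsAsList(params, config),
    master_seed = as.integer(masterSeed),
    settings = extra,
    outputs = outputs)
}

#' @rdname runManifest
#' @param manifest a manifest list from [runManifest()]
#' @param path output path for the JSON manifest
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
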