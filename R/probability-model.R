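#' @include AllClasses.R
NULL

#' Number of active parallel fibres in a dendritic territory
#'
#' At activity density `j` (percentage of the general parallel-fibre
#' population active), `round(j/100 * fibresPerTerritory)` fibres passing a
#' single-dendrite territory are active: 700 at 0.4%, 1,050 at 0.6%, 1,400
#' at 0.8%, and so on. Non-integer products are rounded to the nearest
#' integer because the count model needs an integer number of trials.
#'
#' @param params a \linkS4class{ConnectivityParams}
#' @param j activity density in percent (vectorised); must be >= 0
#' @return integer vector of active fibre counts
#' @examples
#' activeFibreCount(ConnectivityParams(), c(0.4, 0.6, 0.8))
#' @export
activeFibreCount <- function(params = ConnectivityParams(), j) {
  if (!is.numeric(j) || any(!is.finite(j)) || any(j < 0))
    stop("activity density j must be a finite percentage >= 0")
  as.integer(round(j / 100 * fibresPerTerritory(params)))
}

.scopeProb <- function(params, scope) {
  scope <- match.arg(scope, c("cell", "dendrite"))
  p <- contactProbability(params)
  if (scope == "dendrite") p <- p / dendritesPerCell(params)
  p
}

#' Probability of k active inputs
#'
#' Probability that exactly `k` of the active parallel fibres make contact on
#' a Golgi cell (`scope = "cell"`) or on a single apical dendrite
#' (`scope = "dendrite"`) at activity density `j`. This is the binomial mass
#' `B(k; n, p)` with `n = round(j/100 * fibresPerTerritory)` trials and
#' per-fibre contact probability `p = contactProbability` (cell) or
#' `contactProbability / dendritesPerCell` (dendrite). The factorial form is
#' evaluated in log space via `lgamma`, so it is stable for tens of
#' thousands of trials where literal factorials overflow.
#'
#' @param params a \linkS4class{ConnectivityParams}
#' @param j activity density in percent, scalar, >= 0
#' @param k number of contacting active fibres (vectorised, >= 0)
#' @param scope `"cell"` or `"dendrite"`
#' @return numeric vector of probabilities; 0 where `k > n`
#' @examples
#' pmfActiveInputs(j = 0.4, k = 0:5, scope = "dendrite")
#' @export
pmfActiveInputs <- function(params = ConnectivityParams(), j, k,
                            scope = c("cell", "dendrite")) {
  if (length(j) != 1L || !is.finite(j) || j < 0)
    stop("activity density j must be a single finite percentage >= 0")
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 0) || any(k != round(k)))
    stop("k must be non-negative integer counts")
  p <- .scopeProb(params, match.arg(scope))
  n <- activeFibreCount(params, j)
  out <- numeric(length(k))
  if (n == 0L) {            # degenerate: zero contacts certain
    out[k == 0] <- 1
    return(out)
  }
  ok <- k <= n
  kk <- k[ok]
  logp <- lgamma(n + 1) - lgamma(kk + 1) - lgamma(n - kk + 1) +
    kk * log(p) + (n - kk) * log1p(-p)
  out[ok] <- exp(logp)
  out
}

#' Build the full input-count distribution
#'
#' Tabulates the probability mass of active-input counts `k = 0..n` for a
#' given activity density and scope, as an
#' \linkS4class{ActiveInputDistribution}. The full pmf always sums to 1; the
#' `truncationThreshold` only governs the tabular display returned by
#' [truncatedPmf()] (entries with probability above the threshold), never
#' sampling.
#'
#' @param params a \linkS4class{ConnectivityParams}
#' @param j activity density in percent; must be > 0 (at j = 0 the
#'   distribution is degenerate and there is nothing to tabulate)
#' @param scope `"cell"` or `"dendrite"`
#' @param truncationThreshold display floor, default 0.001
#' @return an \linkS4class{ActiveInputDistribution}
#' @examples
#' d <- buildDistribution(j = 0.4, scope = "dendrite")
#' truncatedPmf(d)
#' @export
buildDistribution <- function(params = ConnectivityParams(), j,
                              scope = c("cell", "dendrite"),
                              truncationThreshold = 0.001) {
  if (length(j) != 1L || !is.finite(j) || j <= 0)
    stop("activity density j must be a single percentage > 0")
  scope <- match.arg(scope)
  n <- activeFibreCount(params, j)
  p <- .scopeProb(params, scope)
  k <- 0:max(n, 0L)
  pmf <- pmfActiveInputs(params, j, k, scope)
  # guard against accumulated rounding in the tail sum
  pmf <- pmf / sum(pmf)
  names(pmf) <- k
  new("ActiveInputDistribution", j = j, scope = scope, nActive = n,
      prob = p, pmf = pmf, truncationThreshold = truncationThreshold)
}

#' @rdname accessors
#' @export
setMethod("truncatedPmf", "ActiveInputDistribution", function(x) {
  x@pmf[x@pmf > x@truncationThreshold]
})

#' Sample active-input counts
#'
#' Draws `nSamples` input counts from the full (untruncated) distribution.
#' Since the full pmf is binomial the draws come from `rbinom` with the
#' distribution's `n` and `p`. If `seed` is given the draws are made under
#' that seed without touching the caller's RNG state; otherwise the current
#' RNG stream is consumed.
#'
#' @param dist an \linkS4class{ActiveInputDistribution}
#' @param nSamples number of draws, >= 1
#' @param seed optional integer seed for reproducible draws
#' @return integer vector of counts
#' @export
sampleInputCounts <- function(dist, nSamples, seed = NULL) {
  if (!is(dist, "ActiveInputDistribution")) stop("dist must be an ActiveInputDistribution")
  if (!.scalarCount(nSamples) || nSamples < 1) stop("nSamples must be >= 1")
  draw <- function() {
    if (dist@nActive == 0L) integer(nSamples)
    else stats::rbinom(nSamples, dist@nActive, dist@prob)
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Probability table across an activity-density grid
#'
#' Long-format table of the truncated distributions for a grid of activity
#' densities, with paired scopes per `j` (whole cell, then single dendrite):
#' columns `j`, `scope`, `k`, `probability`. Only entries with probability
#' above the truncation threshold appear, which is the conventional display
#' rule for these tables.
#'
#' @param params a \linkS4class{ConnectivityParams}
#' @param jValues activity-density grid in percent (default 0.4-2 step 0.2)
#' @param truncationThreshold display floor, default 0.001
#' @return data.frame with columns `j`, `scope`, `k`, `probability`
#' @export
probabilityTable <- function(params = ConnectivityParams(),
                             jValues = jGridDefault(),
                             truncationThreshold = 0.001) {
  rows <- lapply(jValues, function(j) {
    do.call(rbind, lapply(c("cell", "dendrite"), function(sc) {
      pm <- truncatedPmf(buildDistribution(params, j, sc, truncationThreshold))
      if (!length(pm)) return(NULL)
      data.frame(j = j, scope = sc, k = as.integer(names(pm)),
                 probability = unname(pm))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Active contacts as a fraction of the general population
#'
#' The expected number of active inputs to a whole Golgi cell, expressed as
#' a percentage of the general parallel-fibre population: with about 1,200
#' contacts out of the ~350,000 fibres crossing a whole-cell territory,
#' active inputs at 1% activity are 0.00343% of the population. Computed as
#' `(j/100) * contactsPerCell / populationFibres * 100`.
#'
#' @param j activity density in percent
#' @param contactsPerCell parallel fibres contacting one Golgi cell (default 1,200)
#' @param populationFibres parallel fibres crossing the whole-cell territory
#'   (default 350,000, i.e. two single-dendrite territories of 175,000)
#' @return percentage of the general population
#' @export
activeContactFraction <- function(j, contactsPerCell = 1200,
                                  populationFibres = 350000) {
  if (any(j < 0)) stop("activity density j must be >= 0")
  (j / 100) * contactsPerCell / populationFibres * 100
}
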