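#' @include config-io.R
NULL

#' Plot the four stages of one conversion
#'
#' Four panels, one per stage, value against index, with a shaded band at
#' mean +/- SD. Visualises the progressive variance contraction along the
#' conversion chain.
#'
#' @param x a \linkS4class{ConversionResult}
#' @param ... passed to [graphics::plot()]
#' @export
plotConversion <- function(x, ...) {
  stopifnot(is(x, "ConversionResult"))
  stages <- list(`dendritic inputs` = as.numeric(dendriticInputs(x)),
                 `group means` = groupMeans(x),
                 `somatic values` = somaticValues(x),
                 `glomerular output` = glomerularValues(x))
  op <- graphics::par(mfrow = c(1, 4), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  ylim <- range(unlist(stages))
  for (nm in names(stages)) {
    v <- stages[[nm]]
    graphics::plot(seq_along(v), v, pch = 16, cex = 0.5, col = "grey30",
                   xlab = "index", ylab = "active inputs (normalised scale)",
                   main = nm, ylim = ylim, ...)
    m <- mean(v); s <- stats::sd(v)
    graphics::rect(0, m - s, length(v) + 1, m + s,
                   col = grDevices::adjustcolor("firebrick", 0.15), border = NA)
    graphics::abline(h = m, col = "firebrick")
  }
  invisible(x)
}

#' Plot a sweep summary
#'
#' Mean output level (where available) and SD against the swept variable.
#'
#' @param x a \linkS4class{SweepResult}
#' @param ... passed to [graphics::plot()]
#' @export
plotSweep <- function(x, ...) {
  stopifnot(is(x, "SweepResult"))
  pp <- perPoint(x)
  sdCol <- intersect(c("sdWithin", "sdOfMeans"), names(pp))[1]
  meanCol <- intersect(c("meanOutput", "grandMean"), names(pp))
  panels <- 1L + length(meanCol)
  op <- graphics::par(mfrow = c(1, panels), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  xv <- pp[[1]]
  if (length(meanCol))
    graphics::plot(xv, pp[[meanCol[1]]], type = "b", pch = 16,
                   xlab = sweepVariable(x), ylab = meanCol[1],
                   main = "mean output", ...)
  graphics::plot(xv, pp[[sdCol]], type = "b", pch = 16,
                 xlab = sweepVariable(x), ylab = sdCol,
                 main = "spread (SD)", ...)
  invisible(x)
}
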