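#' @include plots.R
NULL

#' @importFrom methods new is slot validObject setValidity
#' @importFrom stats rbinom sd lm coef setNames
#' @importFrom utils write.csv packageVersion
NULL
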