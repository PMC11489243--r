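# shared fixtures, built in code

defaultParams <- ConnectivityParams()
defaultConfig <- EnsembleConfig()

# direct evaluation of the binomial mass by cumulative products of rationals:
# choose(n, k) built term by term, times p^k (1-p)^(n-k). Independent of the
# package's log-gamma route and of dbinom.
directPmf <- function(n, p, k) {
  vapply(k, function(kk) {
    if (kk > n) return(0)
    coef <- 1
    if (kk > 0) for (i in seq_len(kk)) coef <- coef * (n - kk + i) / i
    coef * p^kk * (1 - p)^(n - kk)
  }, numeric(1))
}

# an activity density small enough that no parallel fibre is active
jDegenerate <- 1e-4
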