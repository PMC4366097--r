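# Classical rank-difference Spearman formula, exact in the absence of
# ties; independent of the package's Pearson-on-ranks implementation.
spearman_classical <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
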