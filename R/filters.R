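# Zero-phase (forward-backward) IIR filtering with odd-reflection edge
# padding, so that edge transients are absorbed in the padding rather than
# leaking into the output. The signal mean is removed before filtering and
# restored scaled by the filter's squared DC gain, which keeps constants
# exact for both low- and high-pass designs.
filter_zerophase <- function(flt, x, padlen) {
  n <- length(x)
  pl <- min(padlen, n - 1L)
  mu <- mean(x)
  xc <- x - mu
  ext <- c(2 * xc[1] - xc[(pl + 1L):2],
           xc,
           2 * xc[n] - xc[(n - 1L):(n - pl)])
  y <- signal::filter(flt, ext)
  y <- rev(as.numeric(signal::filter(flt, rev(as.numeric(y)))))
  dc_gain <- (sum(flt$b) / sum(flt$a))^2
  y[(pl + 1L):(pl + n)] + mu * dc_gain
}
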