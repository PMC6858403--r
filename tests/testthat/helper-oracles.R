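# Independent oracle: separable 2-D circular convolution computed by a
# literal double loop over filter taps, y[i,j] = sum_{k,l} fr[k] fc[l]
# x[(i-k) mod M, (j-l) mod N].  Deliberately naive and independent of the
# package's filtering code.
brute_circ_conv2 <- function(x, f_row, f_col) {
  m <- nrow(x); n <- ncol(x)
  y <- matrix(0, m, n)
  for (k in seq_along(f_row)) {
    for (l in seq_along(f_col)) {
      ri <- ((seq_len(m) - 1 - (k - 1)) %% m) + 1
      ci <- ((seq_len(n) - 1 - (l - 1)) %% n) + 1
      y <- y + f_row[k] * f_col[l] * x[ri, ci]
    }
  }
  y
}
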