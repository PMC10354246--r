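# shared small fixtures; everything is generated in code under fixed seeds

small_encoder <- function(d = 61L, m = 2L, ell = 0.2, seed = 3L, ...) {
  ssp_encoder(d, m, length_scale = ell, seed = seed, ...)
}

# brute-force circular convolution: sum_k a_k b_{(n-k) mod d}
conv_oracle <- function(a, b) {
  d <- length(a)
  vapply(seq_len(d) - 1L, function(n)
    sum(vapply(seq_len(d) - 1L, function(k) a[k + 1L] * b[((n - k) %% d) + 1L],
               0)), 0)
}

rand_unit <- function(d) {
  g <- rnorm(d)
  g / sqrt(sum(g^2))
}
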