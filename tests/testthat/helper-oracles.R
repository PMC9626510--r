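# Brute-force nested-loop convolution oracles, deliberately independent of
# the package's vectorized/GEMM implementations.

oracle_depthconv <- function(x, W, b, stride, padding) {
  d <- dim(x)  # (epochs, time, channels)
  h <- nrow(W)
  H2 <- floor((d[2] + 2 * padding - h) / stride) + 1
  out <- array(0, c(d[1], H2, d[3]))
  for (e in seq_len(d[1])) for (cc in seq_len(d[3])) {
    xp <- c(rep(0, padding), x[e, , cc], rep(0, padding))
    for (t in seq_len(H2)) {
      acc <- 0
      for (k in seq_len(h)) acc <- acc + xp[(t - 1) * stride + k] * W[k, cc]
      out[e, t, cc] <- acc + b[cc]
    }
  }
  out
}

oracle_pointconv <- function(x, W, b) {
  d <- dim(x)
  Fo <- ncol(W)
  out <- array(0, c(d[1], d[2], Fo))
  for (e in seq_len(d[1])) for (t in seq_len(d[2])) for (f in seq_len(Fo)) {
    acc <- 0
    for (cc in seq_len(d[3])) acc <- acc + x[e, t, cc] * W[cc, f]
    out[e, t, f] <- acc + b[f]
  }
  out
}

oracle_stdconv <- function(x, W, b, stride, padding) {
  d <- dim(x)
  h <- dim(W)[1]; Fo <- dim(W)[3]
  H2 <- floor((d[2] + 2 * padding - h) / stride) + 1
  out <- array(0, c(d[1], H2, Fo))
  for (e in seq_len(d[1])) for (f in seq_len(Fo)) for (t in seq_len(H2)) {
    acc <- 0
    for (cc in seq_len(d[3])) {
      xp <- c(rep(0, padding), x[e, , cc], rep(0, padding))
      for (k in seq_len(h)) acc <- acc + xp[(t - 1) * stride + k] * W[k, cc, f]
    }
    out[e, t, f] <- acc + b[f]
  }
  out
}

# Run one internal layer on a user-layout (epochs, time, channels) tensor and
# return the result in the same layout.
run_layer <- function(kind, x, params, stride = 1L, padding = 0L) {
  d <- dim(x)
  xc <- p300sep:::to_cbt(x)
  fwd <- switch(kind,
    depthconv = {
      h <- nrow(params$W)
      H2 <- conv_output_len(d[2], h, stride, padding)
      l <- p300sep:::layer_desc("depthconv", c(H2, d[3]), kernel = h,
                                channels = d[3], stride = stride,
                                padding = padding)
      p300sep:::depthconv_forward(xc, params, l)
    },
    pointconv = {
      l <- p300sep:::layer_desc("pointconv", c(d[2], ncol(params$W)),
                                in_channels = d[3],
                                out_channels = ncol(params$W))
      p300sep:::pointconv_forward(xc, params, l)
    },
    stdconv = {
      h <- dim(params$W)[1]; Fo <- dim(params$W)[3]
      H2 <- conv_output_len(d[2], h, stride, padding)
      l <- p300sep:::layer_desc("stdconv", c(H2, Fo), kernel = h,
                                in_channels = d[3], out_channels = Fo,
                                stride = stride, padding = padding)
      p300sep:::stdconv_forward(xc, params, l)
    })
  aperm(fwd$y, c(2, 3, 1))
}
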