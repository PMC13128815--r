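# Shared fixture builders: everything is generated in code, no files.

make_channels <- function(kinds) {
  lapply(seq_along(kinds), function(i)
    channel_spec(sprintf("%s%d", kinds[i], i), kinds[i]))
}

# deterministic little recording: ncol(kinds) channels of smooth signals
make_recording <- function(n = 120, rate = 200,
                           kinds = c("emg", "angle"), seed = 1) {
  set.seed(seed)
  mat <- sapply(seq_along(kinds), function(i)
    sin(2 * pi * i * seq_len(n) / n) + 0.1 * rnorm(n))
  signal_recording(mat, make_channels(kinds), rate)
}

# aligned bundle with p predictor and q moment channels
make_bundle <- function(n = 120, rate = 200, p = 2, q = 2, seed = 1) {
  pred <- make_recording(n, rate, rep(c("emg", "angle"), length.out = p),
                         seed)
  targ <- make_recording(n, rate, rep("moment", q), seed + 1)
  align_bundle(pred, targ)
}

# tiny normalized window set ready for training
make_window_set <- function(n = 200, window_len = 12, stride = 1,
                            p = 3, seed = 1) {
  b <- make_bundle(n = n, p = p, seed = seed)
  ws <- segment_windows(b, window_len, stride)
  apply_normalizer(ws, fit_normalizer(ws))
}

# scalar (double-loop) oracle for an affine+ReLU layer: W (m x n), x (n)
oracle_dense_relu <- function(W, b, x) {
  m <- nrow(W)
  out <- numeric(m)
  for (i in seq_len(m)) {
    acc <- b[i]
    for (j in seq_len(ncol(W))) acc <- acc + W[i, j] * x[j]
    out[i] <- max(acc, 0)
  }
  out
}
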