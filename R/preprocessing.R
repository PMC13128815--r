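#' Segment an aligned bundle into overlapping windows
#'
#' Cuts the predictor channels into fixed-length overlapping windows and
#' pairs each window with the moment vector at one of its samples.  Window
#' `i` (1-based) covers samples `[(i-1)*stride + 1, (i-1)*stride + window_len]`;
#' the number of windows is `floor((n_time - window_len)/stride) + 1`.
#'
#' @param bundle A `recording_bundle` from [align_bundle()].
#' @param window_len Window length in samples (e.g. 60 samples = 300 ms at
#'   200 Hz).
#' @param stride Hop between consecutive windows, in samples (default 1,
#'   i.e. maximum overlap).
#' @param label One of `"last"` (causal: target taken at the final sample
#'   of the window, the default) or `"center"` (target at the middle
#'   sample).
#' @return A `window_set` with fields `windows` (array
#'   `n_windows x window_len x n_pred_channels`), `targets` (matrix
#'   `n_windows x n_targets`), `window_len`, `stride`, `rate`,
#'   `channel_names`, `target_names`, `norm_stats` (`NULL` until
#'   [apply_normalizer()] is used).
#' @export
segment_windows <- function(bundle, window_len, stride = 1L,
                            label = c("last", "center")) {
  stopifnot(inherits(bundle, "recording_bundle"), isTRUE(bundle$aligned))
  label <- match.arg(label)
  if (!is.numeric(stride) || stride < 1) stop("stride must be >= 1",
                                              call. = FALSE)
  window_len <- as.integer(window_len); stride <- as.integer(stride)
  X <- bundle$predictors$samples
  Y <- bundle$targets$samples
  n_time <- nrow(X)
  if (n_time < window_len)
    stop(sprintf("recording too short: %d samples < window_len %d",
                 n_time, window_len), call. = FALSE)
  n_win <- (n_time - window_len) %/% stride + 1L
  n_ch <- ncol(X)
  starts <- (seq_len(n_win) - 1L) * stride
  # windows[i, t, c] = X[starts[i] + t, c]
  idx <- outer(starts, seq_len(window_len), `+`)      # n_win x window_len
  win <- array(X[as.vector(idx), , drop = FALSE],
               dim = c(n_win, window_len, n_ch))
  label_off <- if (label == "last") window_len else (window_len + 1L) %/% 2L
  targets <- Y[starts + label_off, , drop = FALSE]
  structure(list(windows = win, targets = targets,
                 window_len = window_len, stride = stride,
                 rate = bundle$predictors$rate,
                 channel_names = colnames(X),
                 target_names = colnames(Y),
                 norm_stats = NULL),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d samples x %d channel(s) @ %g Hz (stride %d)%s\n",
              dim(x$windows)[1], x$window_len, dim(x$windows)[3], x$rate,
              x$stride, if (is.null(x$norm_stats)) "" else ", normalized"))
  invisible(x)
}

#' Fit per-channel z-score statistics on a training window set
#'
#' Computes mean and population standard deviation (divisor N) per
#' predictor channel over all windows and time points.  Targets are never
#' normalized (moments stay in N·m).
#'
#' @param train A `window_set`.
#' @return A `norm_stats` object: list with numeric vectors `mean` and
#'   `sd`, one entry per predictor channel.
#' @export
fit_normalizer <- function(train) {
  stopifnot(inherits(train, "window_set"))
  n_ch <- dim(train$windows)[3]
  mu <- numeric(n_ch); sd_ <- numeric(n_ch)
  for (c in seq_len(n_ch)) {
    v <- as.vector(train$windows[, , c])
    mu[c] <- mean(v)
    sd_[c] <- sqrt(mean((v - mu[c])^2))
    if (!is.finite(sd_[c]) || sd_[c] <= 0)
      stop(sprintf("degenerate (constant) channel: %s",
                   train$channel_names[c]), call. = FALSE)
  }
  structure(list(mean = mu, sd = sd_, channel_names = train$channel_names),
            class = "norm_stats")
}

#' Apply z-score statistics to a window set
#'
#' @param ws A `window_set`.
#' @param stats A `norm_stats` object from [fit_normalizer()] (typically
#'   fitted on the training set and applied to both splits).
#' @return The normalized `window_set`, with `norm_stats` recorded.
#' @export
apply_normalizer <- function(ws, stats) {
  stopifnot(inherits(ws, "window_set"), inherits(stats, "norm_stats"))
  if (length(stats$mean) != dim(ws$windows)[3])
    stop("norm_stats channel count does not match window set", call. = FALSE)
  for (c in seq_along(stats$mean))
    ws$windows[, , c] <- (ws$windows[, , c] - stats$mean[c]) / stats$sd[c]
  ws$norm_stats <- stats
  ws
}

# FFT magnitude of every window/channel: X (B, L, C) -> (B, L, C).
# Full two-sided transform, R's unnormalized convention, so Parseval reads
# sum |X_k|^2 = L * sum x_t^2.
window_fft_mag <- function(X, what = c("mod", "arg")) {
  what <- match.arg(what)
  d <- dim(X)
  Xm <- matrix(aperm(X, c(2, 1, 3)), nrow = d[2], ncol = d[1] * d[3])
  F <- stats::mvfft(Xm)
  M <- if (what == "mod") Mod(F) else Arg(F)
  aperm(array(M, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
}

#' Transform windows to the frequency domain
#'
#' Computes the full (two-sided) discrete Fourier transform of every
#' window and channel and keeps the magnitude `|X_k|` for
#' `k = 0 .. window_len - 1`, so the spectral feature length equals the
#' window length (60 input neurons for a 60-sample window).  The two-sided
#' magnitude is conjugate-symmetric for real input; the redundancy is
#' accepted so that feature length matches the window length.  Phase is
#' kept only in `magnitude_and_phase` mode.
#'
#' @param ws A (normalized) `window_set`.
#' @param fft_mode `"magnitude"` (default) or `"magnitude_and_phase"`.
#' @return A `spectral_window` with fields `magnitudes` (array shaped like
#'   `ws$windows`), `phase` (same shape, or `NULL`), `fft_mode`, plus the
#'   window-set bookkeeping fields.
#' @export
spectral_transform <- function(ws, fft_mode = c("magnitude",
                                                "magnitude_and_phase")) {
  stopifnot(inherits(ws, "window_set"))
  fft_mode <- match.arg(fft_mode)
  mag <- window_fft_mag(ws$windows, "mod")
  ph <- if (fft_mode == "magnitude_and_phase")
    window_fft_mag(ws$windows, "arg") else NULL
  structure(list(magnitudes = mag, phase = ph, fft_mode = fft_mode,
                 targets = ws$targets, window_len = ws$window_len,
                 stride = ws$stride, rate = ws$rate,
                 channel_names = ws$channel_names,
                 target_names = ws$target_names),
            class = "spectral_window")
}
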