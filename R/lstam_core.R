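#' Create LSTM cell parameters
#'
#' Gate input matrices `W_i, W_f, W_o, W_c` (`hidden x feature`), recurrent
#' matrices `U_i, U_f, U_o, U_c` (`hidden x hidden`), and optional bias
#' vectors.  The printed gate equations carry no bias terms; biases are
#' included by default as standard practice and can be zeroed for strict
#' equation conformance.
#'
#' @param feature Input feature dimension per time step.
#' @param hidden Hidden state dimension.
#' @param init `"kaiming"` (uses current RNG state) or `"zero"`.
#' @param bias Include bias vectors (default `TRUE`; they are initialized
#'   to zero either way).
#' @return An `lstm_params` list.
#' @export
lstm_params <- function(feature, hidden, init = c("kaiming", "zero"),
                        bias = TRUE) {
  init <- match.arg(init)
  mk <- function(nr, nc) if (init == "zero") matrix(0, nr, nc) else
    init_mat(nr, nc, fan_in = nc)
  p <- list()
  for (g in c("i", "f", "o", "c")) {
    p[[paste0("W_", g)]] <- mk(hidden, feature)
    p[[paste0("U_", g)]] <- mk(hidden, hidden)
    p[[paste0("b_", g)]] <- numeric(hidden)
  }
  p$feature <- as.integer(feature); p$hidden <- as.integer(hidden)
  p$bias <- isTRUE(bias)
  structure(p, class = "lstm_params")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM cell update
#'
#' Computes the gate activations and new state exactly as
#' \deqn{I = \sigma(W_i t + U_i H_{t-1}),\; F = \sigma(W_f t + U_f H_{t-1}),\;
#'       O = \sigma(W_o t + U_o H_{t-1}),\; \tilde C = \tanh(W_c t + U_c H_{t-1})}
#' \deqn{C_t = F \odot C_{t-1} + I \odot \tilde C,\qquad
#'       H_t = O \odot \tanh(C_t).}
#' Biases are added only when `params$bias` is `TRUE` (they are zero unless
#' set explicitly).
#'
#' @param t Input vector of length `feature` for the current step.
#' @param prev List with `C` and `H`, each of length `hidden` (use
#'   [lstm_state0()] for the zero initial state).
#' @param params An [lstm_params()] bundle.
#' @return List with the new `C` and `H`; every entry of `H` lies in
#'   (-1, 1).
#' @export
lstm_step <- function(t, prev, params) {
  stopifnot(inherits(params, "lstm_params"))
  if (length(t) != params$feature)
    stop(sprintf("input length %d, expected %d", length(t), params$feature),
         call. = FALSE)
  if (!all(is.finite(t)) || !all(is.finite(prev$C)) || !all(is.finite(prev$H)))
    stop("non-finite input to lstm_step", call. = FALSE)
  lin <- function(W, U, b) drop(W %*% t + U %*% prev$H) +
    (if (params$bias) b else 0)
  I <- sigmoid(lin(params$W_i, params$U_i, params$b_i))
  F_ <- sigmoid(lin(params$W_f, params$U_f, params$b_f))
  O <- sigmoid(lin(params$W_o, params$U_o, params$b_o))
  Ctil <- tanh(lin(params$W_c, params$U_c, params$b_c))
  C <- F_ * prev$C + I * Ctil
  list(C = C, H = O * tanh(C))
}

#' Zero LSTM state
#' @param hidden Hidden dimension.
#' @return List with zero vectors `C` and `H`.
#' @export
lstm_state0 <- function(hidden) list(C = numeric(hidden),
                                     H = numeric(hidden))

#' Attention pooling over a sequence of hidden states
#'
#' Scores every hidden state by its inner product with the attention weight
#' vector, turns the scores into a probability vector with a softmax
#' (computed with max subtraction for numerical stability — mathematically
#' identical), and returns the weighted sum of hidden states:
#' \deqn{s_t = x_t \cdot W,\quad a = \mathrm{softmax}(s),\quad
#'       c = \sum_t a_t x_t.}
#'
#' @param x Matrix `T x hidden` of hidden states (rows are time steps), or
#'   a vector for `T = 1`.
#' @param w Attention weight vector of length `hidden`.
#' @return List with `context` (length `hidden`), `weights` (length `T`,
#'   nonnegative, summing to 1), `scores`.
#' @export
attention <- function(x, w) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (nrow(x) < 1L) stop("empty hidden-state sequence", call. = FALSE)
  if (ncol(x) != length(w))
    stop("attention weight length does not match hidden dimension",
         call. = FALSE)
  scores <- drop(x %*% w)
  e <- exp(scores - max(scores))
  weights <- e / sum(e)
  list(context = drop(crossprod(x, weights)), weights = weights,
       scores = scores)
}

#' Model configuration
#'
#' Collects the architecture and training hyper-parameters.  Defaults
#' follow the published experimental setting: 300 ms windows of 60 samples
#' at 200 Hz, a single-layer LSTM, Adam with learning rate 0.001, MSE loss,
#' dropout 0.2, 30 epochs, batch size 60.
#'
#' @param variant Ablation variant `"I"` (plain LSTM on raw windows),
#'   `"II"` (+ attention), `"III"` (FFT + MLP autoencoder + LSTM), `"IV"`
#'   (+ attention), `"V"` (+ convolutional refiner; the complete model).
#' @param window_len Window length in samples; must be divisible by 4.
#' @param stride Window hop in samples.
#' @param hidden LSTM hidden dimension.
#' @param conv_kernel Odd kernel length of the refiner.
#' @param fft_mode `"magnitude"` or `"magnitude_and_phase"`.
#' @param dropout Dropout probability on the context vector.
#' @param lr Adam learning rate.
#' @param epochs Training epochs (no early stopping).
#' @param batch Minibatch size.
#' @param n_targets Number of jointly predicted moments.
#' @param aux_recon_weight Weight of the auxiliary spectral reconstruction
#'   loss (variants III–V); set to 0 to train on prediction MSE only.
#' @param label Target alignment within the window, `"last"` or
#'   `"center"`.
#' @param seed Integer seed controlling initialization, batch order and
#'   dropout.
#' @return A `model_config` list; `latent_dim` is derived as
#'   `window_len / 4`.
#' @export
model_config <- function(variant = c("V", "I", "II", "III", "IV"),
                         window_len = 60L, stride = 1L, hidden = 64L,
                         conv_kernel = 3L,
                         fft_mode = c("magnitude", "magnitude_and_phase"),
                         dropout = 0.2, lr = 0.001, epochs = 30L,
                         batch = 60L, n_targets = 2L,
                         aux_recon_weight = 0.1,
                         label = c("last", "center"), seed = 1L) {
  variant <- match.arg(as.character(variant), c("V", "I", "II", "III", "IV"))
  fft_mode <- match.arg(fft_mode)
  label <- match.arg(label)
  if (window_len %% 4L != 0L)
    stop("window_len must be divisible by 4", call. = FALSE)
  if (conv_kernel %% 2L != 1L)
    stop("conv_kernel must be odd", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("dropout must be in [0, 1)", call. = FALSE)
  structure(list(variant = variant, window_len = as.integer(window_len),
                 stride = as.integer(stride), hidden = as.integer(hidden),
                 latent_dim = as.integer(window_len) %/% 4L,
                 conv_kernel = as.integer(conv_kernel),
                 fft_mode = fft_mode, dropout = dropout, lr = lr,
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 n_targets = as.integer(n_targets),
                 aux_recon_weight = aux_recon_weight, label = label,
                 seed = as.integer(seed)),
            class = "model_config")
}

variant_flags <- function(variant) {
  switch(variant,
         "I"   = list(use_fft = FALSE, use_mlp = FALSE, use_conv = FALSE,
                      use_attn = FALSE),
         "II"  = list(use_fft = FALSE, use_mlp = FALSE, use_conv = FALSE,
                      use_attn = TRUE),
         "III" = list(use_fft = TRUE, use_mlp = TRUE, use_conv = FALSE,
                      use_attn = FALSE),
         "IV"  = list(use_fft = TRUE, use_mlp = TRUE, use_conv = FALSE,
                      use_attn = TRUE),
         "V"   = list(use_fft = TRUE, use_mlp = TRUE, use_conv = TRUE,
                      use_attn = TRUE),
         stop(sprintf("unknown variant '%s'", variant), call. = FALSE))
}

#' Build an ablation variant
#'
#' Instantiates the components implied by the variant flag:
#' * **I** — LSTM over the raw time axis, last hidden state to the head;
#' * **II** — as I plus attention pooling over the hidden states;
#' * **III** — FFT magnitudes, shared-weight MLP encoder per channel, LSTM
#'   over the latent-feature axis, last hidden state to the head;
#' * **IV** — as III plus attention;
#' * **V** — as IV plus the convolutional refiner (the complete model).
#'
#' In the spectral variants the LSTM iterates over the per-window latent
#' axis (`window_len / 4` steps) with the predictor channels as step
#' features; variants I–II iterate over the raw time axis (`window_len`
#' steps).  Initialization is seeded from `cfg$seed`.
#'
#' @param cfg A [model_config()].
#' @param n_channels Number of predictor channels (default 6: 4 EMG + 2
#'   angles).
#' @return An `lstam_model` list with `cfg`, `flags`, `params`,
#'   `n_channels`.
#' @export
build_variant <- function(cfg, n_channels = 6L) {
  stopifnot(inherits(cfg, "model_config"))
  fl <- variant_flags(cfg$variant)
  set.seed(cfg$seed)
  p <- list()
  if (fl$use_mlp) {
    feat_len <- cfg$window_len *
      (if (cfg$fft_mode == "magnitude_and_phase") 2L else 1L)
    p$ae <- autoencoder_params(feat_len)
  }
  if (fl$use_conv) p$conv <- conv_refiner_params(n_channels,
                                                 cfg$conv_kernel)
  p$lstm <- lstm_params(feature = n_channels, hidden = cfg$hidden)
  if (fl$use_attn) {
    lim <- sqrt(6 / cfg$hidden)
    p$attn_w <- stats::runif(cfg$hidden, -lim, lim)
  }
  lim <- sqrt(6 / cfg$hidden)
  p$head_W <- matrix(stats::runif(cfg$n_targets * cfg$hidden, -lim, lim),
                     cfg$n_targets, cfg$hidden)
  p$head_b <- numeric(cfg$n_targets)
  structure(list(cfg = cfg, flags = fl, params = p,
                 n_channels = as.integer(n_channels)),
            class = "lstam_model")
}

#' @export
print.lstam_model <- function(x, ...) {
  on <- names(Filter(isTRUE, x$flags))
  cat(sprintf("<lstam_model> variant %s (hidden %d, window %d, %d channels)%s\n",
              x$cfg$variant, x$cfg$hidden, x$cfg$window_len, x$n_channels,
              if (length(on)) paste0(" [", paste(sub("use_", "", on),
                                                 collapse = "+"), "]")
              else " [lstm only]"))
  invisible(x)
}

#' Count trainable parameters of a model
#' @param model An `lstam_model`.
#' @return Integer number of scalar parameters.
#' @export
count_parameters <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.numeric(x)) n <<- n + length(x)
    else if (is.list(x) && !is.null(names(x)))
      for (nm in names(x))
        if (!nm %in% c("feature", "hidden", "bias", "input_dim",
                       "kernel_len"))
          walk(x[[nm]])
  }
  walk(model$params)
  n
}
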