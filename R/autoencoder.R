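relu <- function(x) pmax(x, 0)

# Uniform Kaiming-style fan-in init: U(-sqrt(6/fan_in), +sqrt(6/fan_in)).
init_mat <- function(nrow, ncol, fan_in = ncol) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Create MLP autoencoder parameters
#'
#' The encoder compresses a spectral vector of length `input_dim` to
#' `input_dim / 2` and then to `input_dim / 4`; the decoder mirrors the two
#' layers back to `input_dim`.  Every layer is affine followed by ReLU.
#'
#' @param input_dim Input feature length; must be divisible by 4.
#' @param init `"kaiming"` (seeded uniform fan-in scaling, uses the current
#'   RNG state) or `"zero"`.
#' @return An `autoencoder_params` list with weight matrices `W1..W4` and
#'   bias vectors `b1..b4` of the shapes
#'   `W1: (d/2 x d)`, `W2: (d/4 x d/2)`, `W3: (d/2 x d/4)`, `W4: (d x d/2)`.
#' @export
autoencoder_params <- function(input_dim, init = c("kaiming", "zero")) {
  init <- match.arg(init)
  if (input_dim %% 4 != 0)
    stop("input_dim must be divisible by 4", call. = FALSE)
  d <- as.integer(input_dim); h <- d %/% 2L; q <- d %/% 4L
  mk <- function(nr, nc) if (init == "zero") matrix(0, nr, nc) else
    init_mat(nr, nc)
  structure(list(W1 = mk(h, d), b1 = numeric(h),
                 W2 = mk(q, h), b2 = numeric(q),
                 W3 = mk(h, q), b3 = numeric(h),
                 W4 = mk(d, h), b4 = numeric(d),
                 input_dim = d),
            class = "autoencoder_params")
}

#' Encode a spectral vector to its latent code
#'
#' `D = ReLU(W2 . ReLU(W1 . E + b1) + b2)`; the latent code has length
#' `input_dim / 4` and is elementwise nonnegative.
#'
#' @param E Numeric vector of length `input_dim`, or a matrix with one
#'   vector per row.
#' @param params An [autoencoder_params()] bundle.
#' @return Latent vector of length `input_dim / 4` (or matrix of rows).
#' @export
ae_encode <- function(E, params) {
  stopifnot(inherits(params, "autoencoder_params"))
  vec <- is.null(dim(E))
  E <- if (vec) matrix(E, nrow = 1L) else as.matrix(E)
  if (ncol(E) != params$input_dim)
    stop(sprintf("expected input length %d, got %d", params$input_dim,
                 ncol(E)), call. = FALSE)
  Z1 <- relu(sweep(E %*% t(params$W1), 2L, params$b1, `+`))
  D <- relu(sweep(Z1 %*% t(params$W2), 2L, params$b2, `+`))
  if (vec) drop(D) else D
}

#' Decode a latent code back to the input dimension
#'
#' `E_hat = ReLU(W4 . ReLU(W3 . D + b3) + b4)`, length `input_dim`.
#'
#' @param D Latent vector of length `input_dim / 4` (or matrix of rows).
#' @param params An [autoencoder_params()] bundle.
#' @return Reconstruction of length `input_dim`, elementwise nonnegative.
#' @export
ae_decode <- function(D, params) {
  stopifnot(inherits(params, "autoencoder_params"))
  vec <- is.null(dim(D))
  D <- if (vec) matrix(D, nrow = 1L) else as.matrix(D)
  if (ncol(D) != params$input_dim %/% 4L)
    stop(sprintf("expected latent length %d, got %d",
                 params$input_dim %/% 4L, ncol(D)), call. = FALSE)
  Z3 <- relu(sweep(D %*% t(params$W3), 2L, params$b3, `+`))
  Eh <- relu(sweep(Z3 %*% t(params$W4), 2L, params$b4, `+`))
  if (vec) drop(Eh) else Eh
}

#' Create 1-D convolutional refiner parameters
#'
#' One convolution layer operating along the latent-feature axis and mixing
#' predictor channels, with same-length zero padding and ReLU.  Kernel
#' length must be odd so the padding is symmetric.
#'
#' @param n_channels Number of input = output channels.
#' @param kernel_len Odd kernel length (default 3).
#' @param init `"kaiming"`, `"zero"`, or `"identity"` (center tap 1 on the
#'   diagonal, so the refiner is the identity on nonnegative input).
#' @return A `conv_refiner_params` list with `kernels` (array
#'   `n_out x n_in x kernel_len`) and `biases` (length `n_out`).
#' @export
conv_refiner_params <- function(n_channels, kernel_len = 3L,
                                init = c("kaiming", "zero", "identity")) {
  init <- match.arg(init)
  if (kernel_len %% 2L != 1L)
    stop("kernel_len must be odd", call. = FALSE)
  k <- array(0, dim = c(n_channels, n_channels, kernel_len))
  if (init == "kaiming") {
    fan_in <- n_channels * kernel_len
    lim <- sqrt(6 / fan_in)
    k[] <- stats::runif(length(k), -lim, lim)
  } else if (init == "identity") {
    mid <- (kernel_len + 1L) %/% 2L
    for (c in seq_len(n_channels)) k[c, c, mid] <- 1
  }
  structure(list(kernels = k, biases = numeric(n_channels),
                 kernel_len = as.integer(kernel_len)),
            class = "conv_refiner_params")
}

# Linear part of the conv refiner on an array (B, S, C_in) -> (B, S, C_out).
conv1d_pre <- function(A, kernels, biases) {
  d <- dim(A); B <- d[1]; S <- d[2]; Cin <- d[3]
  kl <- dim(kernels)[3]; Cout <- dim(kernels)[1]
  pad <- (kl - 1L) %/% 2L
  Ap <- array(0, dim = c(B, S + 2L * pad, Cin))
  Ap[, pad + seq_len(S), ] <- A
  pre <- array(rep(biases, each = B * S), dim = c(B, S, Cout))
  for (o in seq_len(Cout))
    for (i in seq_len(Cin))
      for (kk in seq_len(kl)) {
        w <- kernels[o, i, kk]
        if (w != 0)
          pre[, , o] <- pre[, , o] + w * Ap[, (kk - 1L) + seq_len(S), i]
      }
  pre
}

#' Convolutional refinement of latent features
#'
#' Applies the 1-D convolution of [conv_refiner_params()] along the latent
#' axis (zero padding keeps the length), mixes channels, and applies ReLU.
#' With an averaging kernel this blurs transient spikes in the latent
#' trajectory, which is its role in the pipeline: suppressing residual
#' local features before the recurrent stage.
#'
#' @param latent Array `(n_windows, latent_dim, n_channels)` — or a plain
#'   matrix `(latent_dim, n_channels)` for a single window.
#' @param params A `conv_refiner_params` bundle.
#' @return Refined latent features, same shape as the input when
#'   `n_out_channels == n_in_channels`.
#' @export
conv_refine <- function(latent, params) {
  stopifnot(inherits(params, "conv_refiner_params"))
  single <- length(dim(latent)) == 2L
  A <- if (single) array(latent, dim = c(1L, dim(latent))) else latent
  if (dim(A)[3] != dim(params$kernels)[2])
    stop("channel count does not match conv kernels", call. = FALSE)
  out <- relu(conv1d_pre(A, params$kernels, params$biases))
  if (single) array(out, dim = dim(latent)) else out
}
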