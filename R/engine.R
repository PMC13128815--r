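# Batched forward pass and hand-written reverse-mode gradients for the
# full model family.  Layout conventions:
#   X        windows array (B, L, C), z-scored predictors
#   E        spectral features, matrix (B*C, feat_len), row r = b + (c-1)*B
#   seq axis latent features (B, S, C) for spectral variants, raw time
#            (B, L, C) for variants I-II; the LSTM step feature is always
#            the channel axis.
# Spectral magnitudes are scaled by 2/window_len before entering the
# encoder (amplitude-spectrum normalization); this is a fixed numerical
# choice, not a trainable quantity.

row_slice <- function(A, s) matrix(A[, s, ], dim(A)[1], dim(A)[3])

spectral_features <- function(model, X) {
  L <- dim(X)[2]; B <- dim(X)[1]; C <- dim(X)[3]
  E <- matrix(aperm(window_fft_mag(X, "mod") * (2 / L), c(1, 3, 2)),
              nrow = B * C)
  if (model$cfg$fft_mode == "magnitude_and_phase")
    E <- cbind(E, matrix(aperm(window_fft_mag(X, "arg") / pi, c(1, 3, 2)),
                         nrow = B * C))
  E
}

# Forward pass over a batch.  When train = TRUE the dropout mask is drawn
# from the current RNG state and every intermediate needed for gradients is
# cached.
model_forward <- function(model, X, train = FALSE) {
  cfg <- model$cfg; fl <- model$flags; p <- model$params
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  ca <- list(B = B, L = L, C = C)
  if (fl$use_fft) {
    E <- spectral_features(model, X)
    A1 <- sweep(E %*% t(p$ae$W1), 2L, p$ae$b1, `+`); Z1 <- relu(A1)
    A2 <- sweep(Z1 %*% t(p$ae$W2), 2L, p$ae$b2, `+`); Z2 <- relu(A2)
    S <- ncol(Z2)
    seqX <- aperm(array(Z2, c(B, C, S)), c(1, 3, 2))
    ca[c("E", "A1", "Z1", "A2", "Z2")] <- list(E, A1, Z1, A2, Z2)
  } else {
    seqX <- X; S <- L
  }
  if (fl$use_conv) {
    pre <- conv1d_pre(seqX, p$conv$kernels, p$conv$biases)
    seq2 <- relu(pre)
    ca$conv_pre <- pre; ca$conv_in <- seqX
  } else seq2 <- seqX
  H <- cfg$hidden
  tW <- lapply(p$lstm[c("W_i", "W_f", "W_o", "W_c")], t)
  tU <- lapply(p$lstm[c("U_i", "U_f", "U_o", "U_c")], t)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  steps <- vector("list", S)
  Harr <- array(0, dim = c(B, S, H))
  for (s in seq_len(S)) {
    xs <- row_slice(seq2, s)
    gi <- sigmoid(sweep(xs %*% tW$W_i + h %*% tU$U_i, 2L, p$lstm$b_i, `+`))
    gf <- sigmoid(sweep(xs %*% tW$W_f + h %*% tU$U_f, 2L, p$lstm$b_f, `+`))
    go <- sigmoid(sweep(xs %*% tW$W_o + h %*% tU$U_o, 2L, p$lstm$b_o, `+`))
    gg <- tanh(sweep(xs %*% tW$W_c + h %*% tU$U_c, 2L, p$lstm$b_c, `+`))
    c_new <- gf * cc + gi * gg
    tc <- tanh(c_new)
    steps[[s]] <- list(x = xs, h_prev = h, c_prev = cc,
                       i = gi, f = gf, o = go, g = gg, tc = tc)
    h <- go * tc; cc <- c_new
    Harr[, s, ] <- h
  }
  if (fl$use_attn) {
    scores <- matrix(matrix(Harr, B * S, H) %*% p$attn_w, B, S)
    mx <- scores[cbind(seq_len(B), max.col(scores, "first"))]
    ex <- exp(scores - mx)
    wts <- ex / rowSums(ex)
    ctx <- matrix(0, B, H)
    for (s in seq_len(S)) ctx <- ctx + wts[, s] * row_slice(Harr, s)
    ca$wts <- wts
  } else ctx <- h
  if (train && cfg$dropout > 0) {
    mask <- matrix((stats::runif(B * H) >= cfg$dropout) / (1 - cfg$dropout),
                   B, H)
    ctx_d <- ctx * mask
    ca$mask <- mask
  } else ctx_d <- ctx
  Y <- sweep(ctx_d %*% t(p$head_W), 2L, p$head_b, `+`)
  ca[c("seq2", "steps", "Harr", "ctx", "ctx_d", "S")] <-
    list(seq2, steps, Harr, ctx, ctx_d, S)
  list(Y = Y, cache = ca)
}

conv1d_backward <- function(dpre, A, kernels) {
  d <- dim(A); B <- d[1]; S <- d[2]; Cin <- d[3]
  kl <- dim(kernels)[3]; Cout <- dim(kernels)[1]
  pad <- (kl - 1L) %/% 2L
  Ap <- array(0, dim = c(B, S + 2L * pad, Cin))
  Ap[, pad + seq_len(S), ] <- A
  dAp <- array(0, dim = dim(Ap))
  dK <- array(0, dim = dim(kernels)); db <- numeric(Cout)
  for (o in seq_len(Cout)) {
    dpo <- matrix(dpre[, , o], B, S)
    db[o] <- sum(dpo)
    for (i in seq_len(Cin))
      for (kk in seq_len(kl)) {
        sl <- (kk - 1L) + seq_len(S)
        dK[o, i, kk] <- sum(dpo * matrix(Ap[, sl, i], B, S))
        dAp[, sl, i] <- matrix(dAp[, sl, i], B, S) + kernels[o, i, kk] * dpo
      }
  }
  list(dK = dK, db = db, dA = dAp[, pad + seq_len(S), , drop = FALSE])
}

# Loss and gradients for one batch; Tm is the (B, n_targets) target matrix.
# Returns list(loss, pred_loss, grads) with grads mirroring the trainable
# leaves of model$params.
model_loss_grads <- function(model, X, Tm, train = TRUE) {
  cfg <- model$cfg; fl <- model$flags; p <- model$params
  fw <- model_forward(model, X, train = train)
  ca <- fw$cache
  B <- ca$B; C <- ca$C; S <- ca$S; H <- cfg$hidden
  Y <- fw$Y
  pred_loss <- mean((Y - Tm)^2)
  loss <- pred_loss
  g <- list()
  dY <- 2 * (Y - Tm) / length(Y)
  g$head_W <- crossprod(dY, ca$ctx_d)
  g$head_b <- colSums(dY)
  dctx <- dY %*% p$head_W
  if (!is.null(ca$mask)) dctx <- dctx * ca$mask
  dHarr <- array(0, dim = c(B, S, H))
  if (fl$use_attn) {
    wts <- ca$wts
    dw <- matrix(0, B, S)
    for (s in seq_len(S)) dw[, s] <- rowSums(dctx * row_slice(ca$Harr, s))
    dscore <- wts * (dw - rowSums(wts * dw))
    g$attn_w <- drop(crossprod(matrix(ca$Harr, B * S, H),
                               as.vector(dscore)))
    for (s in seq_len(S))
      dHarr[, s, ] <- wts[, s] * dctx + outer(dscore[, s], p$attn_w)
  } else {
    dHarr[, S, ] <- dctx
  }
  gl <- list(W_i = 0, W_f = 0, W_o = 0, W_c = 0,
             U_i = 0, U_f = 0, U_o = 0, U_c = 0,
             b_i = 0, b_f = 0, b_o = 0, b_c = 0)
  dh_rec <- matrix(0, B, H); dc_rec <- matrix(0, B, H)
  dseq <- array(0, dim = c(B, S, C))
  for (s in rev(seq_len(S))) {
    st <- ca$steps[[s]]
    dh <- row_slice(dHarr, s) + dh_rec
    do_ <- dh * st$tc
    dc <- dh * st$o * (1 - st$tc^2) + dc_rec
    di <- dc * st$g; dg <- dc * st$i; df <- dc * st$c_prev
    dc_rec <- dc * st$f
    ai <- di * st$i * (1 - st$i)
    af <- df * st$f * (1 - st$f)
    ao <- do_ * st$o * (1 - st$o)
    ag <- dg * (1 - st$g^2)
    gl$W_i <- gl$W_i + crossprod(ai, st$x)
    gl$W_f <- gl$W_f + crossprod(af, st$x)
    gl$W_o <- gl$W_o + crossprod(ao, st$x)
    gl$W_c <- gl$W_c + crossprod(ag, st$x)
    gl$U_i <- gl$U_i + crossprod(ai, st$h_prev)
    gl$U_f <- gl$U_f + crossprod(af, st$h_prev)
    gl$U_o <- gl$U_o + crossprod(ao, st$h_prev)
    gl$U_c <- gl$U_c + crossprod(ag, st$h_prev)
    gl$b_i <- gl$b_i + colSums(ai)
    gl$b_f <- gl$b_f + colSums(af)
    gl$b_o <- gl$b_o + colSums(ao)
    gl$b_c <- gl$b_c + colSums(ag)
    dseq[, s, ] <- ai %*% p$lstm$W_i + af %*% p$lstm$W_f +
      ao %*% p$lstm$W_o + ag %*% p$lstm$W_c
    dh_rec <- ai %*% p$lstm$U_i + af %*% p$lstm$U_f +
      ao %*% p$lstm$U_o + ag %*% p$lstm$U_c
  }
  g$lstm <- gl
  if (fl$use_conv) {
    dpre <- dseq * (ca$conv_pre > 0)
    cb <- conv1d_backward(dpre, ca$conv_in, p$conv$kernels)
    g$conv <- list(kernels = cb$dK, biases = cb$db)
    dseqX <- cb$dA
  } else dseqX <- dseq
  if (fl$use_mlp) {
    dZ2 <- matrix(aperm(dseqX, c(1, 3, 2)), B * C, S)
    ga <- list(W1 = 0, b1 = 0, W2 = 0, b2 = 0,
               W3 = matrix(0, nrow(p$ae$W3), ncol(p$ae$W3)),
               b3 = numeric(length(p$ae$b3)),
               W4 = matrix(0, nrow(p$ae$W4), ncol(p$ae$W4)),
               b4 = numeric(length(p$ae$b4)))
    if (cfg$aux_recon_weight > 0) {
      A3 <- sweep(ca$Z2 %*% t(p$ae$W3), 2L, p$ae$b3, `+`); Z3 <- relu(A3)
      A4 <- sweep(Z3 %*% t(p$ae$W4), 2L, p$ae$b4, `+`); Eh <- relu(A4)
      recon <- mean((Eh - ca$E)^2)
      loss <- loss + cfg$aux_recon_weight * recon
      dEh <- 2 * cfg$aux_recon_weight * (Eh - ca$E) / length(Eh)
      dA4 <- dEh * (A4 > 0)
      ga$W4 <- crossprod(dA4, Z3); ga$b4 <- colSums(dA4)
      dZ3 <- dA4 %*% p$ae$W4
      dA3 <- dZ3 * (A3 > 0)
      ga$W3 <- crossprod(dA3, ca$Z2); ga$b3 <- colSums(dA3)
      dZ2 <- dZ2 + dA3 %*% p$ae$W3
    }
    dA2 <- dZ2 * (ca$A2 > 0)
    ga$W2 <- crossprod(dA2, ca$Z1); ga$b2 <- colSums(dA2)
    dZ1 <- dA2 %*% p$ae$W2
    dA1 <- dZ1 * (ca$A1 > 0)
    ga$W1 <- crossprod(dA1, ca$E); ga$b1 <- colSums(dA1)
    g$ae <- ga
  }
  list(loss = loss, pred_loss = pred_loss, grads = g)
}

# --- Adam -------------------------------------------------------------

adam_state_like <- function(g) {
  if (is.list(g)) lapply(g, adam_state_like) else g * 0
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    if (is.list(grads[[nm]])) {
      upd <- adam_update(params[[nm]], grads[[nm]],
                         list(m = state$m[[nm]], v = state$v[[nm]]),
                         lr, t, beta1, beta2, eps)
      params[[nm]] <- upd$params
      state$m[[nm]] <- upd$state$m
      state$v[[nm]] <- upd$state$v
    } else {
      m <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
      v <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
      state$m[[nm]] <- m
      state$v[[nm]] <- v
    }
  }
  list(params = params, state = state)
}

#' Train a model on a window set
#'
#' Runs exactly `cfg$epochs` epochs of minibatch Adam (batch size
#' `cfg$batch`, learning rate `cfg$lr`) on the MSE between predicted and
#' actual moments, plus `cfg$aux_recon_weight` times the spectral
#' reconstruction MSE for the autoencoder variants (III-V).  There is no
#' early stopping.  Batch order and dropout are seeded from `cfg$seed`, so
#' two runs with identical configuration produce identical loss histories.
#'
#' @param model An `lstam_model` from [build_variant()].
#' @param train_ws A normalized `window_set` (see [apply_normalizer()]).
#' @param verbose Print the epoch loss while training.
#' @return The trained model, with `loss_history` (mean batch training
#'   loss per epoch, length `cfg$epochs`) attached.
#' @export
train_model <- function(model, train_ws, verbose = FALSE) {
  stopifnot(inherits(model, "lstam_model"), inherits(train_ws, "window_set"))
  if (is.null(train_ws$norm_stats))
    stop("training windows must be normalized (see apply_normalizer)",
         call. = FALSE)
  n <- dim(train_ws$windows)[1]
  if (n < 1L) stop("empty training set", call. = FALSE)
  cfg <- model$cfg
  if (ncol(train_ws$targets) != cfg$n_targets)
    stop("target count does not match cfg$n_targets", call. = FALSE)
  set.seed(cfg$seed + 1L)
  state <- NULL
  t_step <- 0L
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    starts <- seq.int(1L, n, by = cfg$batch)
    ep_loss <- 0
    for (b0 in starts) {
      bi <- idx[b0:min(b0 + cfg$batch - 1L, n)]
      X <- train_ws$windows[bi, , , drop = FALSE]
      Tm <- train_ws$targets[bi, , drop = FALSE]
      lg <- model_loss_grads(model, X, Tm, train = TRUE)
      if (!is.finite(lg$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", ep),
             call. = FALSE)
      if (is.null(state))
        state <- list(m = adam_state_like(lg$grads),
                      v = adam_state_like(lg$grads))
      t_step <- t_step + 1L
      upd <- adam_update(model$params, lg$grads, state, cfg$lr, t_step)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + lg$loss
    }
    history[ep] <- ep_loss / length(starts)
    if (verbose)
      message(sprintf("epoch %3d/%d  loss %.5f", ep, cfg$epochs,
                      history[ep]))
  }
  model$loss_history <- history
  model
}

#' Predict joint moments for a window set
#'
#' Eval-mode forward pass (dropout off); deterministic for a fixed model
#' and input.
#'
#' @param object A (trained) `lstam_model`.
#' @param ws A normalized `window_set`, or a raw windows array
#'   `(n, window_len, n_channels)`.
#' @param chunk Number of windows per forward chunk (memory control).
#' @param ... Unused.
#' @return Matrix `(n_windows, n_targets)` of predicted moments in N·m.
#' @export
predict.lstam_model <- function(object, ws, chunk = 512L, ...) {
  X <- if (inherits(ws, "window_set")) ws$windows else ws
  n <- dim(X)[1]
  out <- matrix(0, n, object$cfg$n_targets)
  for (b0 in seq.int(1L, n, by = chunk)) {
    bi <- b0:min(b0 + chunk - 1L, n)
    out[bi, ] <- model_forward(object, X[bi, , , drop = FALSE],
                               train = FALSE)$Y
  }
  colnames(out) <- if (inherits(ws, "window_set") &&
                       !is.null(ws$target_names) &&
                       length(ws$target_names) == ncol(out))
    ws$target_names else NULL
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single binary file; a JSON sidecar
#' (`<path>.json`) records the configuration, seed and parameter shapes.
#'
#' @param model A trained `lstam_model`.
#' @param path Checkpoint file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  shapes <- rapply(model$params, function(x)
    paste(if (is.null(dim(x))) length(x) else dim(x), collapse = "x"),
    classes = "ANY", how = "list")
  side <- list(config = unclass(model$cfg), n_channels = model$n_channels,
               shapes = shapes)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "lstam_model"))
  model
}
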