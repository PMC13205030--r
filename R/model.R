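#' Specification of the dual-input detector
#'
#' Architecture and training hyper-parameters of the beat-morphology + HRV
#' classifier: a shared-weight (TimeDistributed) 1-D convolutional encoder
#' per beat (32 filters, kernel 5 then kernel 3, each block batch-normalized,
#' ReLU, max-pooled by 2 and dropped out at 0.2), per-beat flattening, a
#' bidirectional LSTM (64 hidden units) over the beat sequence and a dense
#' 32-unit ECG embedding; a dense 32 + batch-norm HRV branch; and a fusion
#' head 64 -> 32 (batch-normalized, ReLU) -> 16 -> softmax over 2 classes.
#'
#' @param n_beats beats per window fed to the model.
#' @param beat_len samples per beat (200).
#' @param n_features HRV indices (31).
#' @param conv_filters,kernels,dropout,pool convolutional block settings.
#' @param lstm_hidden bidirectional LSTM hidden units (per direction).
#' @param ecg_embed,hrv_embed branch embedding widths.
#' @param fusion fusion layer widths.
#' @param classes output classes.
#' @param lr,batch,max_epochs Adam learning rate, batch size, epoch cap.
#' @param es_min_delta,es_patience early stopping: stop when the monitored
#'   (training) loss fails to improve by at least `es_min_delta` for
#'   `es_patience` consecutive epochs.
#' @param focal_gamma,focal_alpha focal-loss parameters.
#' @param inputs which branches to use: "both", "ecg" or "hrv" (ablations).
#' @param seed initialization / shuffling seed.
#' @return a `model_spec`.
#' @export
model_spec <- function(n_beats, beat_len = 200, n_features = 31,
                       conv_filters = 32, kernels = c(5, 3), dropout = 0.2,
                       pool = 2, lstm_hidden = 64, ecg_embed = 32,
                       hrv_embed = 32, fusion = c(64, 32, 16), classes = 2,
                       lr = 0.001, batch = 32, max_epochs = 1000,
                       es_min_delta = 0.001, es_patience = 30,
                       focal_gamma = 2, focal_alpha = 0.25,
                       inputs = c("both", "ecg", "hrv"), seed = 1L) {
  inputs <- match.arg(inputs)
  stopifnot(n_beats >= 1, beat_len == 200, n_features == 31,
            all(c(conv_filters, lstm_hidden, lr, batch, max_epochs) > 0))
  structure(as.list(environment()), class = "model_spec")
}

#' Build an untrained dual-input model
#'
#' @param spec a [model_spec()].
#' @return a `glyco_model` environment holding parameters, batch-norm running
#'   state, optimizer state and the spec.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(spec$seed)
  Fc <- spec$conv_filters
  L <- spec$beat_len
  D <- (L / 4) * Fc                      # flattened per-beat features
  H <- spec$lstm_hidden
  # layers feeding straight into batch norm carry no bias (it is absorbed)
  p <- list(
    c1_W = glorot(spec$kernels[1], Fc, c(spec$kernels[1] * 1, Fc)),
    bn1_g = rep(1, Fc), bn1_b = rep(0, Fc),
    c2_W = glorot(spec$kernels[2] * Fc, Fc),
    bn2_g = rep(1, Fc), bn2_b = rep(0, Fc)
  )
  lf <- lstm_init(D, H); lb <- lstm_init(D, H)
  p <- c(p, list(lf_Wx = lf$Wx, lf_Wh = lf$Wh, lf_b = lf$b,
                 lb_Wx = lb$Wx, lb_Wh = lb$Wh, lb_b = lb$b,
                 de_W = glorot(2 * H, spec$ecg_embed), de_b = rep(0, spec$ecg_embed),
                 dh_W = glorot(spec$n_features, spec$hrv_embed),
                 bnh_g = rep(1, spec$hrv_embed), bnh_b = rep(0, spec$hrv_embed)))
  fuse_in <- switch(spec$inputs, both = spec$ecg_embed + spec$hrv_embed,
                    ecg = spec$ecg_embed, hrv = spec$hrv_embed)
  p <- c(p, list(
    f1_W = glorot(fuse_in, spec$fusion[1]),
    bn3_g = rep(1, spec$fusion[1]), bn3_b = rep(0, spec$fusion[1]),
    f2_W = glorot(spec$fusion[1], spec$fusion[2]),
    bn4_g = rep(1, spec$fusion[2]), bn4_b = rep(0, spec$fusion[2]),
    f3_W = glorot(spec$fusion[2], spec$fusion[3]), f3_b = rep(0, spec$fusion[3]),
    out_W = glorot(spec$fusion[3], spec$classes), out_b = rep(0, spec$classes)
  ))
  model <- new.env(parent = emptyenv())
  model$params <- p
  model$state <- list()
  model$opt <- list(t = 0, m = list(), v = list())
  model$spec <- spec
  class(model) <- "glyco_model"
  model
}

# Forward pass. beats: (B, T, L) array (ignored for hrv-only); hrv: (B, 31)
# matrix (ignored for ecg-only). Returns probs, logits and a cache for
# backward. Updates BN running state when training.
model_forward <- function(model, beats, hrv, training = FALSE) {
  sp <- model$spec
  p <- model$params
  cache <- list(training = training)
  use_ecg <- sp$inputs %in% c("both", "ecg")
  use_hrv <- sp$inputs %in% c("both", "hrv")
  if (use_ecg) {
    B <- dim(beats)[1]; TT <- dim(beats)[2]; L <- dim(beats)[3]
    N <- B * TT
    A0 <- matrix(as.vector(matrix(beats, N, L)), N * L, 1)
    cv1 <- conv_fwd(A0, N, L, 1, sp$kernels[1], p$c1_W)
    bn1 <- bn_fwd(cv1$Z, p$bn1_g, p$bn1_b, model$state, "bn1", training)
    model$state <- bn1$state
    r1 <- relu(bn1$Y)
    pl1 <- pool_fwd(r1, N, L)
    dp1 <- dropout_fwd(pl1$Y, sp$dropout, training)
    L2 <- L / 2
    cv2 <- conv_fwd(dp1$Y, N, L2, sp$conv_filters, sp$kernels[2], p$c2_W)
    bn2 <- bn_fwd(cv2$Z, p$bn2_g, p$bn2_b, model$state, "bn2", training)
    model$state <- bn2$state
    r2 <- relu(bn2$Y)
    pl2 <- pool_fwd(r2, N, L2)
    dp2 <- dropout_fwd(pl2$Y, sp$dropout, training)
    L3 <- L2 / 2
    Fm <- matrix(as.vector(dp2$Y), N, L3 * sp$conv_filters)
    xs <- lapply(seq_len(TT), function(t) Fm[((t - 1) * B + 1):(t * B), , drop = FALSE])
    lf <- lstm_fwd(xs, p$lf_Wx, p$lf_Wh, p$lf_b)
    lb <- lstm_fwd(rev(xs), p$lb_Wx, p$lb_Wh, p$lb_b)
    Hcat <- cbind(lf$h, lb$h)
    Ze <- addc(Hcat %*% p$de_W, p$de_b)
    E <- pmax(Ze, 0)
    cache$ecg <- list(B = B, TT = TT, L = L, N = N, cv1 = cv1, bn1 = bn1$cache,
                      r1 = r1, pl1 = pl1, dp1mask = dp1$mask,
                      cv2 = cv2, bn2 = bn2$cache, r2 = r2,
                      pl2 = pl2, dp2mask = dp2$mask, xs = xs, lf = lf, lb = lb,
                      Hcat = Hcat, Zemask = Ze > 0)
  } else E <- NULL
  if (use_hrv) {
    Zh <- hrv %*% p$dh_W
    bnh <- bn_fwd(Zh, p$bnh_g, p$bnh_b, model$state, "bnh", training)
    model$state <- bnh$state
    Hh <- pmax(bnh$Y, 0)
    cache$hrv <- list(X = hrv, bnh = bnh$cache, mask = bnh$Y > 0)
  } else Hh <- NULL
  U <- cbind(E, Hh)
  Z1 <- U %*% p$f1_W
  bn3 <- bn_fwd(Z1, p$bn3_g, p$bn3_b, model$state, "bn3", training)
  model$state <- bn3$state
  A1 <- pmax(bn3$Y, 0)
  Z2 <- A1 %*% p$f2_W
  bn4 <- bn_fwd(Z2, p$bn4_g, p$bn4_b, model$state, "bn4", training)
  model$state <- bn4$state
  A2 <- pmax(bn4$Y, 0)
  A3 <- addc(A2 %*% p$f3_W, p$f3_b)
  logits <- addc(A3 %*% p$out_W, p$out_b)
  probs <- softmax(logits)
  cache$fuse <- list(U = U, bn3 = bn3$cache, m3 = bn3$Y > 0, A1 = A1,
                     bn4 = bn4$cache, m4 = bn4$Y > 0, A2 = A2, A3 = A3)
  list(probs = probs, logits = logits, cache = cache)
}

# Backward pass from dlogits. Returns parameter grads plus input gradients
# d_beats (B, T, L) and d_hrv.
model_backward <- function(model, cache, dlogits) {
  sp <- model$spec
  p <- model$params
  g <- list()
  fz <- cache$fuse
  g$out_W <- crossprod(fz$A3, dlogits); g$out_b <- colSums(dlogits)
  dA3 <- tcrossprod(dlogits, p$out_W)
  g$f3_W <- crossprod(fz$A2, dA3); g$f3_b <- colSums(dA3)
  dA2 <- tcrossprod(dA3, p$f3_W)
  dZb4 <- dA2 * fz$m4
  b4 <- bn_bwd(dZb4, fz$bn4, p$bn4_g)
  g$bn4_g <- b4$dg; g$bn4_b <- b4$db
  g$f2_W <- crossprod(fz$A1, b4$dX)
  dA1 <- tcrossprod(b4$dX, p$f2_W)
  dZb3 <- dA1 * fz$m3
  b3 <- bn_bwd(dZb3, fz$bn3, p$bn3_g)
  g$bn3_g <- b3$dg; g$bn3_b <- b3$db
  g$f1_W <- crossprod(fz$U, b3$dX)
  dU <- tcrossprod(b3$dX, p$f1_W)
  d_beats <- NULL; d_hrv <- NULL
  off <- 0
  if (!is.null(cache$ecg)) {
    ec <- cache$ecg
    dE <- dU[, 1:sp$ecg_embed, drop = FALSE]
    off <- sp$ecg_embed
    dZe <- dE * ec$Zemask
    g$de_W <- crossprod(ec$Hcat, dZe); g$de_b <- colSums(dZe)
    dHcat <- tcrossprod(dZe, p$de_W)
    H <- sp$lstm_hidden
    bf <- lstm_bwd(dHcat[, 1:H, drop = FALSE], ec$xs, ec$lf$caches, p$lf_Wx, p$lf_Wh)
    bb <- lstm_bwd(dHcat[, (H + 1):(2 * H), drop = FALSE], rev(ec$xs), ec$lb$caches,
                   p$lb_Wx, p$lb_Wh)
    g$lf_Wx <- bf$dWx; g$lf_Wh <- bf$dWh; g$lf_b <- bf$db
    g$lb_Wx <- bb$dWx; g$lb_Wh <- bb$dWh; g$lb_b <- bb$db
    B <- ec$B; TT <- ec$TT; L <- ec$L; N <- ec$N
    L2 <- L / 2; L3 <- L / 4; Fc <- sp$conv_filters
    dFm <- matrix(0, N, L3 * Fc)
    for (t in seq_len(TT)) {
      rows <- ((t - 1) * B + 1):(t * B)
      dFm[rows, ] <- bf$dxs[[t]] + bb$dxs[[TT + 1 - t]]
    }
    dP2 <- matrix(as.vector(dFm), N * L3, Fc)
    if (!is.null(ec$dp2mask)) dP2 <- dP2 * ec$dp2mask
    dR2 <- pool_bwd(dP2, ec$pl2, N, L2, Fc)
    dZb2 <- relu_bwd(dR2, ec$r2)
    b2 <- bn_bwd(dZb2, ec$bn2, p$bn2_g)
    g$bn2_g <- b2$dg; g$bn2_b <- b2$db
    cb2 <- conv_bwd(b2$dX, ec$cv2, N, L2, Fc, sp$kernels[2], p$c2_W)
    g$c2_W <- cb2$dW
    dP1 <- cb2$dA
    if (!is.null(ec$dp1mask)) dP1 <- dP1 * ec$dp1mask
    dR1 <- pool_bwd(dP1, ec$pl1, N, L, Fc)
    dZb1 <- relu_bwd(dR1, ec$r1)
    b1 <- bn_bwd(dZb1, ec$bn1, p$bn1_g)
    g$bn1_g <- b1$dg; g$bn1_b <- b1$db
    cb1 <- conv_bwd(b1$dX, ec$cv1, N, L, 1, sp$kernels[1], p$c1_W)
    g$c1_W <- cb1$dW
    d_beats <- array(as.vector(matrix(cb1$dA, N, L)), c(B, TT, L))
  }
  if (!is.null(cache$hrv)) {
    hc <- cache$hrv
    dHh <- dU[, (off + 1):(off + sp$hrv_embed), drop = FALSE]
    dZbh <- dHh * hc$mask
    bh <- bn_bwd(dZbh, hc$bnh, p$bnh_g)
    g$bnh_g <- bh$dg; g$bnh_b <- bh$db
    g$dh_W <- crossprod(hc$X, bh$dX)
    d_hrv <- tcrossprod(bh$dX, p$dh_W)
  }
  list(grads = g, d_beats = d_beats, d_hrv = d_hrv)
}

#' Predict class probabilities
#'
#' @param object a trained `glyco_model`.
#' @param beats `(B, n_beats, 200)` array of beat matrices (mV).
#' @param hrv `(B, 31)` matrix of normalized HRV features.
#' @param ... unused.
#' @return `(B, 2)` matrix of probabilities; column 2 is hyperglycemia.
#' @export
predict.glyco_model <- function(object, beats = NULL, hrv = NULL, ...) {
  model_forward(object, beats, hrv, training = FALSE)$probs
}

#' Train the dual-input detector
#'
#' Adam (lr from the spec), batch size 32, focal loss, up to `max_epochs`
#' epochs with early stopping on the training loss: training stops when the
#' loss has not improved on its running minimum by at least `es_min_delta`
#' for `es_patience` consecutive epochs. Seeded shuffling and dropout make
#' runs reproducible.
#'
#' @param model a `glyco_model` from [build_model()].
#' @param beats `(n, n_beats, 200)` array.
#' @param hrv `(n, 31)` matrix of normalized features (NAs imputed to 0, the
#'   z-score center, before training).
#' @param labels character or factor; positive class "hyperglycemia".
#' @param verbose print per-epoch loss.
#' @return the model, with `history` (per-epoch mean loss) attached.
#' @export
train_model <- function(model, beats, hrv, labels, verbose = FALSE) {
  sp <- model$spec
  y <- as.integer(labels == "hyperglycemia") + 1L   # class index: 1 eu, 2 hyper
  if (length(unique(y)) < 2) stop("training set must contain both classes")
  n <- length(y)
  if (!is.null(hrv)) hrv[!is.finite(hrv)] <- 0
  set.seed(sp$seed + 1L)
  best <- Inf; wait <- 0; history <- numeric(0)
  for (epoch in seq_len(sp$max_epochs)) {
    ord <- sample(n)
    losses <- numeric(0)
    for (b0 in seq(1, n, by = sp$batch)) {
      ix <- ord[b0:min(b0 + sp$batch - 1, n)]
      bb <- if (sp$inputs != "hrv") beats[ix, , , drop = FALSE] else NULL
      hh <- if (sp$inputs != "ecg") hrv[ix, , drop = FALSE] else NULL
      fw <- model_forward(model, bb, hh, training = TRUE)
      pt <- fw$probs[cbind(seq_along(ix), y[ix])]
      losses <- c(losses, focal_loss(pt, sp$focal_gamma, sp$focal_alpha))
      dlog <- focal_loss_grad(fw$probs, y[ix], sp$focal_gamma, sp$focal_alpha)
      bw <- model_backward(model, fw$cache, dlog)
      st <- adam_step(model$params, bw$grads, model$opt, sp$lr)
      model$params <- st$params
      model$opt <- st$opt
    }
    ep_loss <- mean(losses)
    history <- c(history, ep_loss)
    if (verbose) message(sprintf("epoch %d loss %.5f", epoch, ep_loss))
    if (ep_loss < best - sp$es_min_delta) {
      best <- ep_loss; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= sp$es_patience) break
    }
  }
  model$history <- history
  model
}
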