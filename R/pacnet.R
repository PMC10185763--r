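# PACNet: a compact convolutional decoder over the mixed filter-bank
# signals, with one independent temporal convolution branch per rhythm
# band so that features of the four mixed signals do not interfere before
# spatial mixing. Architecture per branch/trunk:
#
#   per band: temporal conv (F1 filters, kernel K, same padding) + batch
#   norm -> feature-map concatenation across bands -> depthwise spatial
#   conv over channels (multiplier D) -> ELU -> average pool p1 ->
#   separable temporal conv (depthwise kernel K2 + pointwise to F2) ->
#   ELU -> average pool p2 -> dropout -> dense softmax.
#
# The network is implemented directly (forward and backward passes in R
# over compiled 1-D convolution kernels) with Adam and early stopping, so
# training is fully deterministic under a seed on CPU.

.elu <- function(x) ifelse(x > 0, x, expm1(x))
.elu_grad <- function(x) ifelse(x > 0, 1, exp(x))

.resolve_net_config <- function(config, input_shape, branches) {
  d <- config
  B <- branches; C <- input_shape[2]; T <- input_shape[3]
  K <- if (is.null(d$kernel)) max(8L, T %/% 4L) else as.integer(d$kernel)
  if (K > T) stop("temporal kernel (", K, ") exceeds trial length (", T, ")")
  p1 <- as.integer(d$pool1); p2 <- as.integer(d$pool2)
  T1 <- T %/% p1
  if (T1 < 1L) stop("pool1 too large for trial length")
  T2 <- T1 %/% p2
  if (T2 < 1L) stop("pool2 too large for trial length")
  K2 <- min(as.integer(d$kernel_len2), T1)
  list(B = B, C = C, T = T, K = K, K2 = K2,
       F1 = as.integer(d$f1), D = as.integer(d$depth_mult),
       F2 = as.integer(d$f2), p1 = p1, p2 = p2, T1 = T1, T2 = T2,
       M = B * as.integer(d$f1),
       M1 = B * as.integer(d$f1) * as.integer(d$depth_mult),
       nfeat = T2 * as.integer(d$f2),
       dropout = d$dropout, n_classes = as.integer(d$n_classes),
       lr = d$lr, batch = as.integer(d$batch),
       epochs = as.integer(d$epochs), patience = as.integer(d$patience),
       val_fraction = d$val_fraction,
       off1 = (K - 1L) %/% 2L, off2 = (min(as.integer(d$kernel_len2), T1) - 1L) %/% 2L)
}

.init_params <- function(net, seed) {
  set.seed(seed)
  with(net, list(
    W1 = lapply(seq_len(B), function(b)
      matrix(stats::rnorm(K * F1, sd = sqrt(1 / K)), K, F1)),
    g1 = matrix(1, B, F1),
    b1 = matrix(0, B, F1),
    W2 = array(stats::rnorm(C * D * M, sd = sqrt(1 / C)), c(C, D, M)),
    Wd = matrix(stats::rnorm(K2 * M1, sd = sqrt(1 / K2)), K2, M1),
    Wp = matrix(stats::rnorm(M1 * F2, sd = sqrt(1 / M1)), M1, F2),
    bp = numeric(F2),
    Wo = matrix(stats::rnorm(nfeat * n_classes, sd = sqrt(1 / nfeat)),
                nfeat, n_classes),
    bo = numeric(n_classes)))
}

#' Build the split-branch PACNet decoder
#'
#' Constructs an untrained PACNet: one temporal convolution branch per
#' rhythm band over the mixed filter-bank signals, merged by feature-map
#' concatenation into a depthwise-separable convolutional trunk ending in
#' a dense softmax. The temporal kernel defaults to a quarter of the trial
#' length (half the sampling rate for 2-s epochs).
#'
#' @param config The `decoder` section of a [default_config()] (a plain
#'   list of hyperparameters).
#' @param input_shape Integer `c(bands, channels, samples)`; `bands` must
#'   equal `config$n_branches`.
#' @param seed Seed for weight initialization.
#' @return An object of class `pacnet_model`. Train with [train_model()];
#'   query size with [n_params()]; predict with [predict.pacnet_model()].
#' @export
build_pacnet <- function(config = default_config()$decoder,
                         input_shape, seed = 1L) {
  if (length(input_shape) != 3L)
    stop("input_shape must be c(bands, channels, samples)")
  if (input_shape[1] != config$n_branches)
    stop("shape mismatch: input has ", input_shape[1],
         " band(s) but the decoder expects ", config$n_branches)
  net <- .resolve_net_config(config, input_shape, as.integer(input_shape[1]))
  params <- .init_params(net, seed)
  structure(list(params = params,
                 bn = list(mu = matrix(0, net$B, net$F1),
                           var = matrix(1, net$B, net$F1)),
                 net = net, seed = as.integer(seed),
                 levels = NULL, trained = FALSE, history = NULL),
            class = "pacnet_model")
}

#' Build the single-branch (no-PAC) baseline decoder
#'
#' The same trunk as [build_pacnet()] with a single temporal branch taking
#' one broadband signal (conventionally the 70-200 Hz high-gamma
#' bandpass), used as the ablation control.
#'
#' @param config As in [build_pacnet()].
#' @param input_shape Integer `c(channels, samples)`.
#' @param seed Seed for weight initialization.
#' @return A `pacnet_model` with one branch.
#' @export
build_baseline <- function(config = default_config()$decoder,
                           input_shape, seed = 1L) {
  if (length(input_shape) != 2L)
    stop("input_shape must be c(channels, samples)")
  cfg <- config
  cfg$n_branches <- 1L
  build_pacnet(cfg, c(1L, input_shape), seed)
}

#' Number of trainable parameters
#'
#' @param model A `pacnet_model`.
#' @return Integer parameter count (a deterministic function of the
#'   configuration and input shape).
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "pacnet_model"))
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, 0)) else length(x)
  as.integer(cnt(model$params))
}

#' @export
print.pacnet_model <- function(x, ...) {
  n <- x$net
  cat(sprintf(
    "<pacnet_model: %d branch(es), input %d ch x %d samples, %d classes, %d parameters%s>\n",
    n$B, n$C, n$T, n$n_classes, n_params(x),
    if (x$trained) ", trained" else ""))
  invisible(x)
}

#' @export
summary.pacnet_model <- function(object, ...) {
  n <- object$net
  cat(sprintf("PACNet decoder (%d parameters)\n", n_params(object)))
  cat(sprintf("  %d temporal branch(es): kernel %d, %d filters each\n",
              n$B, n$K, n$F1))
  cat(sprintf("  depthwise spatial conv: %d channels x multiplier %d -> %d maps\n",
              n$C, n$D, n$M1))
  cat(sprintf("  separable temporal conv: kernel %d -> %d feature maps\n",
              n$K2, n$F2))
  cat(sprintf("  pooling %d then %d; dropout %.2f; dense %d -> %d\n",
              n$p1, n$p2, n$dropout, n$nfeat, n$n_classes))
  if (object$trained)
    cat(sprintf("  trained for %d epoch(s); best val loss %.4f\n",
                nrow(object$history), min(object$history$val_loss)))
  invisible(object)
}

# Convert a [N, B, C, T] (or [N, C, T]) array into per-band T x (C * N)
# matrices, channel-fastest column order.
.to_band_mats <- function(arr) {
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr)[1], 1L, dim(arr)[2:3])
  d <- dim(arr)
  lapply(seq_len(d[2]), function(b) {
    s <- arr[, b, , , drop = FALSE]
    dim(s) <- d[c(1L, 3L, 4L)]
    matrix(aperm(s, c(3L, 2L, 1L)), nrow = d[4])
  })
}

.band_cols <- function(idx, C) rep((idx - 1L) * C, each = C) + seq_len(C)

.pool_mean <- function(A, p, Tout) {
  d <- dim(A)
  A <- A[seq_len(Tout * p), , , drop = FALSE]
  dim(A) <- c(p, Tout, d[2], d[3])
  out <- colMeans(A, dims = 1L)
  dim(out) <- c(Tout, d[2], d[3])
  out
}

.pool_mean_grad <- function(G, p, Tin) {
  d <- dim(G)   # Tout, N, M
  out <- array(0, c(Tin, d[2], d[3]))
  out[seq_len(d[1] * p), , ] <- G[rep(seq_len(d[1]), each = p), , ,
                                  drop = FALSE] / p
  out
}

# Forward pass. Xb: list per band of T x (C*N) matrices. Returns class
# probabilities (n_classes x N) and, when train = TRUE, the cache needed
# by the backward pass. Batch statistics update the running batch-norm
# moments with momentum 0.9 during training.
.pac_forward <- function(params, bn, net, Xb, train = FALSE) {
  B <- net$B; C <- net$C; Tn <- net$T; F1 <- net$F1; D <- net$D
  N <- ncol(Xb[[1]]) %/% C
  S <- array(0, c(Tn, N, net$M1))
  cache <- if (train) list(A1 = vector("list", B),
                           xhat = vector("list", B),
                           istd = matrix(0, B, F1),
                           Xp = vector("list", net$M)) else NULL
  bn_new <- bn
  eps <- 1e-5
  for (b in seq_len(B)) {
    A1 <- cpp_conv_same(Xb[[b]], params$W1[[b]], net$off1)   # T x CN x F1
    xhat_b <- if (train) array(0, dim(A1)) else NULL
    for (f in seq_len(F1)) {
      x <- A1[, , f]
      if (train) {
        mu <- mean(x); v <- mean((x - mu)^2)
        bn_new$mu[b, f] <- 0.9 * bn_new$mu[b, f] + 0.1 * mu
        bn_new$var[b, f] <- 0.9 * bn_new$var[b, f] + 0.1 * v
      } else {
        mu <- bn$mu[b, f]; v <- bn$var[b, f]
      }
      istd <- 1 / sqrt(v + eps)
      xh <- (x - mu) * istd
      if (train) {
        xhat_b[, , f] <- xh
        cache$istd[b, f] <- istd
      }
      h <- params$g1[b, f] * xh + params$b1[b, f]
      # depthwise spatial convolution for map m = (b, f)
      m <- (b - 1L) * F1 + f
      dim(h) <- c(Tn, C, N)
      Xp <- matrix(aperm(h, c(1L, 3L, 2L)), Tn * N, C)
      if (train) cache$Xp[[m]] <- Xp
      S[, , ((m - 1L) * D + 1L):(m * D)] <- Xp %*% params$W2[, , m]
    }
    if (train) { cache$A1[[b]] <- A1; cache$xhat[[b]] <- xhat_b }
  }
  E <- .elu(S)
  P <- .pool_mean(E, net$p1, net$T1)
  Q <- array(0, c(net$T1, N, net$M1))
  for (m in seq_len(net$M1)) {
    Pm <- P[, , m]
    if (!is.matrix(Pm)) dim(Pm) <- c(net$T1, N)
    Q[, , m] <- cpp_conv_same(Pm, params$Wd[, m, drop = FALSE], net$off2)[, , 1]
  }
  Qm <- matrix(Q, net$T1 * N, net$M1)
  R0 <- Qm %*% params$Wp + matrix(params$bp, net$T1 * N, net$F2, byrow = TRUE)
  G <- .elu(R0)
  dim(G) <- c(net$T1, N, net$F2)
  Fp <- .pool_mean(G, net$p2, net$T2)
  feat <- matrix(aperm(Fp, c(1L, 3L, 2L)), net$nfeat, N)
  if (train && net$dropout > 0) {
    mask <- matrix((stats::runif(net$nfeat * N) >= net$dropout) /
                     (1 - net$dropout), net$nfeat, N)
    featd <- feat * mask
  } else {
    mask <- NULL
    featd <- feat
  }
  Z <- t(params$Wo) %*% featd + params$bo
  Z <- sweep(Z, 2L, apply(Z, 2L, max))
  ex <- exp(Z)
  probs <- sweep(ex, 2L, colSums(ex), "/")
  if (train) {
    cache$S <- S; cache$P <- P; cache$Qm <- Qm; cache$R0 <- R0
    cache$mask <- mask; cache$featd <- featd; cache$N <- N
  }
  list(probs = probs, cache = cache, bn = bn_new)
}

# Backward pass: cross-entropy gradient through the whole trunk down to
# the temporal convolution weights (the input itself needs no gradient).
.pac_backward <- function(params, net, Xb, cache, probs, y_idx) {
  B <- net$B; C <- net$C; Tn <- net$T; F1 <- net$F1; D <- net$D
  N <- cache$N
  dZ <- probs
  dZ[cbind(y_idx, seq_len(N))] <- dZ[cbind(y_idx, seq_len(N))] - 1
  dZ <- dZ / N
  g <- list()
  g$Wo <- cache$featd %*% t(dZ)
  g$bo <- rowSums(dZ)
  dfeat <- params$Wo %*% dZ
  if (!is.null(cache$mask)) dfeat <- dfeat * cache$mask
  dim(dfeat) <- c(net$T2, net$F2, N)
  dFp <- aperm(dfeat, c(1L, 3L, 2L))
  dG <- .pool_mean_grad(dFp, net$p2, net$T1)
  dR0 <- matrix(dG, net$T1 * N, net$F2) * .elu_grad(cache$R0)
  g$Wp <- t(cache$Qm) %*% dR0
  g$bp <- colSums(dR0)
  dQm <- dR0 %*% t(params$Wp)
  dQ <- array(dQm, c(net$T1, N, net$M1))
  dP <- array(0, c(net$T1, N, net$M1))
  g$Wd <- matrix(0, net$K2, net$M1)
  for (m in seq_len(net$M1)) {
    Pm <- cache$P[, , m, drop = TRUE]
    dQm_ <- dQ[, , m, drop = TRUE]
    if (is.null(dim(Pm))) { Pm <- matrix(Pm, net$T1, N); dQm_ <- matrix(dQm_, net$T1, N) }
    g$Wd[, m] <- cpp_conv_gradw(Pm, array(dQm_, c(net$T1, N, 1L)),
                                net$K2, net$off2)
    wrev <- matrix(rev(params$Wd[, m]), net$K2, 1L)
    dP[, , m] <- cpp_conv_same(dQm_, wrev, net$K2 - 1L - net$off2)[, , 1]
  }
  dE <- .pool_mean_grad(dP, net$p1, Tn)
  dS <- dE * .elu_grad(cache$S)
  g$W2 <- array(0, dim(params$W2))
  g$g1 <- matrix(0, B, F1)
  g$b1 <- matrix(0, B, F1)
  g$W1 <- vector("list", B)
  n_el <- Tn * C * N
  for (b in seq_len(B)) {
    dA1 <- array(0, c(Tn, C * N, F1))
    for (f in seq_len(F1)) {
      m <- (b - 1L) * F1 + f
      dSm <- dS[, , ((m - 1L) * D + 1L):(m * D)]
      dim(dSm) <- c(Tn * N, D)
      g$W2[, , m] <- t(cache$Xp[[m]]) %*% dSm
      dXp <- dSm %*% t(params$W2[, , m])     # (T*N) x C
      dim(dXp) <- c(Tn, N, C)
      dh <- matrix(aperm(dXp, c(1L, 3L, 2L)), Tn, C * N)
      xh <- cache$xhat[[b]][, , f]
      g$g1[b, f] <- sum(dh * xh)
      g$b1[b, f] <- sum(dh)
      # batch-norm backward (batch statistics over all T x C x N elements)
      coefs <- params$g1[b, f] * cache$istd[b, f] / n_el
      dA1[, , f] <- coefs * (n_el * dh - sum(dh) - xh * sum(dh * xh))
    }
    g$W1[[b]] <- cpp_conv_gradw(Xb[[b]], dA1, net$K, net$off1)
  }
  g
}

.adam_init <- function(params) {
  zeros <- function(x) if (is.list(x)) lapply(x, zeros) else {
    z <- numeric(length(x)); dim(z) <- dim(x); z
  }
  list(m = zeros(params), v = zeros(params), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.null(names(p))) g <- g[names(p)]   # align by name, not position
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mh <- m / (1 - beta1^state$t)
      vh <- v / (1 - beta2^state$t)
      upd <- p - lr * mh / (sqrt(vh) + eps)
      dim(upd) <- dim(p)   # keep plain vectors plain
      list(p = upd, m = m, v = v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

.xent <- function(probs, y_idx)
  -mean(log(pmax(probs[cbind(y_idx, seq_along(y_idx))], 1e-12)))

.coerce_decoder_input <- function(x) {
  if (inherits(x, "filter_bank_output")) list(arr = x$data, labels = x$labels)
  else if (is.array(x)) list(arr = x, labels = NULL)
  else stop("x must be a filter_bank_output or an array")
}

#' Train a PACNet (or baseline) decoder
#'
#' Mini-batch Adam on the cross-entropy loss with early stopping on
#' validation loss (patience from the configuration); the best-validation
#' parameters are restored at the end. Fully deterministic under the
#' model's seed on CPU.
#'
#' @param model An untrained [build_pacnet()] / [build_baseline()] model.
#' @param x Training input: a [build_mixed_signals()] result or an array
#'   `trials x bands x channels x samples` (bands omitted for a
#'   single-branch model).
#' @param y Integer labels (defaults to the labels carried by `x`). At
#'   least 2 classes must be present.
#' @param x_val,y_val Optional explicit validation set; when absent, a
#'   stratified fraction `val_fraction` of the training trials is held
#'   out.
#' @return The trained model; `$history` is a data frame with per-epoch
#'   `train_loss`, `val_loss`, `val_acc`.
#' @export
train_model <- function(model, x, y = NULL, x_val = NULL, y_val = NULL) {
  stopifnot(inherits(model, "pacnet_model"))
  net <- model$net
  inp <- .coerce_decoder_input(x)
  if (is.null(y)) y <- inp$labels
  if (is.null(y)) stop("labels are required")
  levels <- sort(unique(y))
  if (length(levels) < 2L) stop("single-class training set")
  if (length(levels) > net$n_classes)
    stop("more classes than the decoder was built for")
  y_idx <- match(y, levels)
  arr <- inp$arr
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr)[1], 1L, dim(arr)[2:3])
  set.seed(model$seed + 1L)
  if (is.null(x_val)) {
    hold <- unlist(lapply(split(seq_along(y), y), function(i)
      sample(i, max(1L, round(length(i) * net$val_fraction)))))
    tr_i <- setdiff(seq_along(y), hold)
    arr_val <- arr[hold, , , , drop = FALSE]; yv_idx <- y_idx[hold]
    arr <- arr[tr_i, , , , drop = FALSE]; y_idx <- y_idx[tr_i]
  } else {
    vinp <- .coerce_decoder_input(x_val)
    if (is.null(y_val)) y_val <- vinp$labels
    arr_val <- vinp$arr
    if (length(dim(arr_val)) == 3L)
      dim(arr_val) <- c(dim(arr_val)[1], 1L, dim(arr_val)[2:3])
    yv_idx <- match(y_val, levels)
  }
  if (anyNA(yv_idx)) stop("validation labels outside the training classes")
  Xb <- .to_band_mats(arr)
  Xv <- .to_band_mats(arr_val)
  N <- dim(arr)[1]
  params <- model$params; bn <- model$bn
  adam <- .adam_init(params)
  best <- list(loss = Inf, params = params, bn = bn)
  wait <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  C <- net$C
  for (ep in seq_len(net$epochs)) {
    ord <- sample.int(N)
    losses <- numeric(0)
    for (start in seq(1L, N, by = net$batch)) {
      sel <- ord[start:min(start + net$batch - 1L, N)]
      cols <- .band_cols(sel, C)
      Xs <- lapply(Xb, function(m) m[, cols, drop = FALSE])
      fw <- .pac_forward(params, bn, net, Xs, train = TRUE)
      bn <- fw$bn
      losses <- c(losses, .xent(fw$probs, y_idx[sel]))
      grads <- .pac_backward(params, net, Xs, fw$cache, fw$probs, y_idx[sel])
      upd <- .adam_step(params, grads, adam, net$lr)
      params <- upd$params; adam <- upd$state
    }
    vfw <- .pac_forward(params, bn, net, Xv, train = FALSE)
    vloss <- .xent(vfw$probs, yv_idx)
    vacc <- mean(apply(vfw$probs, 2L, which.max) == yv_idx)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_loss = vloss, val_acc = vacc))
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = params, bn = bn)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= net$patience) break
    }
  }
  model$params <- best$params
  model$bn <- best$bn
  model$levels <- levels
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Predict from a trained decoder
#'
#' @param object A trained `pacnet_model`.
#' @param newdata A [build_mixed_signals()] result or input array.
#' @param type `"prob"` for per-class probabilities (rows sum to 1) or
#'   `"class"` for hard labels.
#' @param ... Ignored.
#' @return A `trials x classes` probability matrix, or a label vector.
#' @export
predict.pacnet_model <- function(object, newdata,
                                 type = c("prob", "class"), ...) {
  type <- match.arg(type)
  inp <- .coerce_decoder_input(newdata)
  arr <- inp$arr
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr)[1], 1L, dim(arr)[2:3])
  Xb <- .to_band_mats(arr)
  fw <- .pac_forward(object$params, object$bn, object$net, Xb, train = FALSE)
  probs <- t(fw$probs)
  lv <- object$levels %||% seq_len(object$net$n_classes)
  colnames(probs) <- as.character(lv)
  if (type == "prob") probs
  else lv[apply(probs, 1L, which.max)]
}
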