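#' Mean squared error loss
#'
#' `mean((observed - predicted)^2)`: the training loss of the yield
#' regression head.
#'
#' @param predicted,observed equal-length numeric vectors (grams).
#' @return A single non-negative number.
#' @export
mse_loss <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed lengths differ")
  if (length(observed) == 0L) stop("empty loss input")
  mean((observed - predicted)^2)
}

#' Class-weighted cross-entropy loss
#'
#' \eqn{-\sum_i w_{c(i)} \log \hat p_{i,c(i)} / \sum_i w_{c(i)}}: the
#' negative log-likelihood of the true class of each sample, weighted by
#' its class weight and normalised by the summed weights (a weighted mean,
#' so unit weights recover the ordinary cross-entropy). `"balanced"`
#' weights are \eqn{w_j = N / (C n_j)}, making every class contribute
#' equally in expectation regardless of size. Natural logarithm.
#' Probabilities below `1e-12` at the true class are clamped, with a
#' warning.
#'
#' @param predicted_probs N x C matrix; each row a probability simplex.
#' @param labels true classes: integers in 1..C, or values matching
#'   `colnames(predicted_probs)`.
#' @param class_weights positive numeric of length C, or `"balanced"`.
#' @return A single non-negative number.
#' @export
weighted_ce_loss <- function(predicted_probs, labels,
                             class_weights = "balanced") {
  P <- as.matrix(predicted_probs)
  n <- nrow(P); C <- ncol(P)
  if (any(abs(rowSums(P) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  cls <- if (is.numeric(labels)) as.integer(labels)
         else match(as.character(labels), colnames(P))
  if (anyNA(cls) || any(cls < 1L) || any(cls > C)) stop("labels outside 1..C")
  if (identical(class_weights, "balanced")) {
    nj <- tabulate(cls, nbins = C)
    class_weights <- n / (C * pmax(nj, 1L))
  }
  if (length(class_weights) != C || any(class_weights <= 0))
    stop("class weights must be ", C, " positive values")
  p_true <- P[cbind(seq_len(n), cls)]
  if (any(p_true < 1e-12)) {
    warning("zero probability at true class clamped to 1e-12")
    p_true <- pmax(p_true, 1e-12)
  }
  w <- class_weights[cls]
  -sum(w * log(p_true)) / sum(w)
}

#' Configuration of the CNN training harness
#'
#' The harness mirrors a transfer-learning protocol: a backbone extracts
#' features and a task-specific fully-connected head emits 1 (yield), 2
#' (top-performers) or 3 (score classes) outputs. The default backbone
#' `tiny_test_net` is a compact three-conv-block network that trains in
#' minutes on a CPU; the four large published backbones are recognised
#' configuration values but require pretrained weights that this package
#' does not ship, and raise an informative error. With
#' `use_pretrained = TRUE` the backbone is frozen (only the head trains);
#' otherwise all parameters update.
#'
#' @param backbone one of `"tiny_test_net"`, `"vgg16"`, `"densenet161"`,
#'   `"efficientnet_v2"`, `"resnet50"`.
#' @param use_pretrained freeze the backbone and train only the head.
#' @param head_outputs 1, 2 or 3, matching the task.
#' @param epochs training epochs (default 15).
#' @param class_weights `"balanced"`, `NULL` (unit), or per-class positive
#'   numerics (classification heads).
#' @param batch_size,learning_rate optimiser settings (Adam); neither is
#'   tuned by the harness.
#' @param input_size images are bilinearly resized to this square size.
#' @param rng_seed integer seed; a fixed seed gives identical training
#'   traces.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(backbone = "tiny_test_net", use_pretrained = FALSE,
                       head_outputs = 1L, epochs = 15L,
                       class_weights = "balanced", batch_size = 32L,
                       learning_rate = 1e-3, input_size = 32L,
                       rng_seed = 1L) {
  backbone <- match.arg(backbone, c("tiny_test_net", "vgg16", "densenet161",
                                    "efficientnet_v2", "resnet50"))
  stopifnot(head_outputs %in% 1:3, epochs >= 1L, batch_size >= 1L,
            learning_rate > 0, input_size %% 8L == 0L)
  structure(list(backbone = backbone, use_pretrained = use_pretrained,
                 head_outputs = as.integer(head_outputs),
                 epochs = as.integer(epochs), class_weights = class_weights,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 input_size = as.integer(input_size),
                 rng_seed = as.integer(rng_seed)),
            class = "cnn_config")
}

# ---- minimal conv-net machinery (im2col convolutions) --------------------

resize_bilinear <- function(px, S) {
  d <- dim(px); H <- d[1]; W <- d[2]
  src_pos <- function(n_src, n_dst) {
    p <- (seq_len(n_dst) - 0.5) * n_src / n_dst - 0.5
    i0 <- pmax(1L, pmin(n_src - 1L, floor(p) + 1L))
    list(i0 = i0, fr = pmax(0, pmin(1, p - (i0 - 1L))))
  }
  rp <- src_pos(H, S); cp <- src_pos(W, S)
  out <- array(0, c(S, S, d[3]))
  for (ch in seq_len(d[3])) {
    M <- px[, , ch]
    Mr <- M[rp$i0, , drop = FALSE] * (1 - rp$fr) +
      M[rp$i0 + 1L, , drop = FALSE] * rp$fr
    out[, , ch] <- Mr[, cp$i0, drop = FALSE] *
      rep(1 - cp$fr, each = S) +
      Mr[, cp$i0 + 1L, drop = FALSE] * rep(cp$fr, each = S)
  }
  out
}

im2col <- function(X, k = 3L, pad = 1L) {
  d <- dim(X); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Xp <- array(0, c(H + 2L * pad, W + 2L * pad, C, N))
  Xp[pad + seq_len(H), pad + seq_len(W), , ] <- X
  out <- matrix(0, k * k * C, H * W * N)
  r <- 0L
  for (ch in seq_len(C)) for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    r <- r + 1L
    out[r, ] <- as.vector(Xp[di + seq_len(H), dj + seq_len(W), ch, ])
  }
  out
}

col2im <- function(cols, H, W, C, N, k = 3L, pad = 1L) {
  Gp <- array(0, c(H + 2L * pad, W + 2L * pad, C, N))
  r <- 0L
  for (ch in seq_len(C)) for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    r <- r + 1L
    Gp[di + seq_len(H), dj + seq_len(W), ch, ] <-
      Gp[di + seq_len(H), dj + seq_len(W), ch, ] + array(cols[r, ], c(H, W, N))
  }
  Gp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
}

conv_forward <- function(X, Wm, b) {
  d <- dim(X); H <- d[1]; W <- d[2]; N <- d[4]
  cols <- im2col(X)
  out <- Wm %*% cols + b
  A <- array(t(out), c(H, W, N, nrow(Wm)))
  list(out = aperm(A, c(1, 2, 4, 3)), cols = cols, dim_in = d)
}

conv_backward <- function(dY, cache, Wm) {
  d <- dim(dY); H <- d[1]; W <- d[2]; Cout <- d[3]; N <- d[4]
  dYm <- t(matrix(aperm(dY, c(1, 2, 4, 3)), H * W * N, Cout))
  dW <- dYm %*% t(cache$cols)
  db <- rowSums(dYm)
  dcols <- t(Wm) %*% dYm
  dX <- col2im(dcols, cache$dim_in[1], cache$dim_in[2], cache$dim_in[3],
               cache$dim_in[4])
  list(dX = dX, dW = dW, db = db)
}

maxpool_forward <- function(X) {
  d <- dim(X)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  cand <- list(X[i1, j1, , , drop = FALSE], X[i2, j1, , , drop = FALSE],
               X[i1, j2, , , drop = FALSE], X[i2, j2, , , drop = FALSE])
  M <- pmax(cand[[1]], cand[[2]], cand[[3]], cand[[4]])
  amax <- array(4L, dim(M))
  for (k in 3:1) amax[cand[[k]] == M] <- k
  list(out = M, amax = amax, dim_in = d)
}

maxpool_backward <- function(dM, cache) {
  d <- cache$dim_in
  G <- array(0, d)
  sub <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  for (k in 1:4) {
    m <- cache$amax == k
    if (!any(m)) next
    Gk <- array(0, dim(dM)); Gk[m] <- dM[m]
    ri <- seq(sub[[k]][1], d[1], 2L); ci <- seq(sub[[k]][2], d[2], 2L)
    G[ri, ci, , ] <- G[ri, ci, , ] + Gk
  }
  G
}

tiny_net_init <- function(input_size, head_outputs) {
  ch <- c(3L, 8L, 16L, 32L)
  init_mat <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
  feat_dim <- (input_size / 8L)^2 * ch[4]
  hidden <- 64L
  list(
    conv1 = list(W = init_mat(ch[2], 9L * ch[1]), b = numeric(ch[2])),
    conv2 = list(W = init_mat(ch[3], 9L * ch[2]), b = numeric(ch[3])),
    conv3 = list(W = init_mat(ch[4], 9L * ch[3]), b = numeric(ch[4])),
    fc1 = list(W = init_mat(hidden, feat_dim), b = numeric(hidden)),
    fc2 = list(W = init_mat(head_outputs, hidden), b = numeric(head_outputs)))
}

tiny_net_forward <- function(params, X, keep_cache = TRUE) {
  cache <- list()
  A <- X
  for (i in 1:3) {
    nm <- paste0("conv", i)
    cv <- conv_forward(A, params[[nm]]$W, params[[nm]]$b)
    relu_mask <- cv$out > 0
    A <- cv$out * relu_mask
    mp <- maxpool_forward(A)
    A <- mp$out
    if (keep_cache)
      cache[[nm]] <- list(conv = cv, relu = relu_mask, pool = mp)
  }
  d <- dim(A)
  Fmat <- matrix(A, prod(d[1:3]), d[4])
  H1 <- params$fc1$W %*% Fmat + params$fc1$b
  R1 <- H1 * (H1 > 0)
  Z <- params$fc2$W %*% R1 + params$fc2$b
  if (keep_cache)
    cache$fc <- list(Fmat = Fmat, dim_feat = d, H1 = H1, R1 = R1)
  list(out = Z, cache = cache)
}

tiny_net_backward <- function(params, cache, dZ, train_backbone = TRUE) {
  g <- list()
  g$fc2 <- list(W = dZ %*% t(cache$fc$R1), b = rowSums(dZ))
  dR1 <- t(params$fc2$W) %*% dZ
  dH1 <- dR1 * (cache$fc$H1 > 0)
  g$fc1 <- list(W = dH1 %*% t(cache$fc$Fmat), b = rowSums(dH1))
  if (!train_backbone) return(g)
  dF <- t(params$fc1$W) %*% dH1
  dA <- array(dF, cache$fc$dim_feat)
  for (i in 3:1) {
    nm <- paste0("conv", i)
    lc <- cache[[nm]]
    dA <- maxpool_backward(dA, lc$pool)
    dA <- dA * lc$relu
    cb <- conv_backward(dA, lc$conv, params[[nm]]$W)
    g[[nm]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dX
  }
  g
}

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "list", classes = "ANY")
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (layer in names(grads)) {
    for (pn in names(grads[[layer]])) {
      gmat <- grads[[layer]][[pn]]
      st <- state[[layer]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * gmat
      st$v <- beta2 * st$v + (1 - beta2) * gmat^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[layer]][[pn]] <- params[[layer]][[pn]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[layer]][[pn]] <- st
    }
  }
  list(params = params, state = state)
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

# Balanced accuracy over the classes present among the true labels.
ba_present <- function(true, pred, levels) {
  cm <- table(factor(true, levels = levels), factor(pred, levels = levels))
  rs <- rowSums(cm)
  mean(diag(cm)[rs > 0] / rs[rs > 0])
}

# ---- training ------------------------------------------------------------

#' Train the CNN harness on one train/validation fold
#'
#' Implements the training protocol of the image-based models: resize each
#' plot clip to the backbone's input size, standardise channels with
#' training-set statistics, and train for `epochs` epochs with Adam,
#' recording the training loss and the validation metric (R-squared for
#' the 1-output regression head, balanced accuracy otherwise) after every
#' epoch. The parameters of the best validation epoch are returned, along
#' with the full training trace.
#'
#' @param plots list of [plot_image()]s.
#' @param labels responses aligned with `plots`: numeric grams
#'   (`head_outputs = 1`) or class labels.
#' @param config a [cnn_config()].
#' @param fold list with `train_ids` and `val_ids` (plot ids), e.g. one
#'   fold of [make_splits()].
#' @return An object of class `tiny_cnn` with components `params` (best
#'   epoch weights), `trace` (data frame `epoch`, `train_loss`,
#'   `val_metric`), `best_epoch` and `best_val_metric`.
#' @export
train_cnn <- function(plots, labels, config, fold) {
  stopifnot(inherits(config, "cnn_config"))
  if (config$backbone != "tiny_test_net")
    stop("pretrained weights for backbone '", config$backbone,
         "' are not available in this installation; use backbone ",
         "'tiny_test_net'")
  ids <- vapply(plots, function(p) p$plot_id, "")
  tr_idx <- match(fold$train_ids, ids)
  va_idx <- match(fold$val_ids, ids)
  if (anyNA(tr_idx) || anyNA(va_idx))
    stop("fold ids not found among the supplied plots")
  regression <- config$head_outputs == 1L
  if (regression) {
    if (!is.numeric(labels)) stop("regression head requires numeric labels")
    class_levels <- NULL
  } else {
    labels <- as.character(labels)
    class_levels <- if (all(labels %in% c("Select", "Discard")))
      c("Select", "Discard") else sort(unique(labels))
    if (length(class_levels) != config$head_outputs)
      stop("head_outputs = ", config$head_outputs, " but labels have ",
           length(class_levels), " classes")
  }

  S <- config$input_size
  imgs <- lapply(plots, function(p) resize_bilinear(p$pixels / 255, S))
  X <- array(0, c(S, S, 3L, length(imgs)))
  for (i in seq_along(imgs)) X[, , , i] <- imgs[[i]]
  ch_mean <- apply(X[, , , tr_idx, drop = FALSE], 3, mean)
  ch_sd <- pmax(apply(X[, , , tr_idx, drop = FALSE], 3, sd), 1e-6)
  for (ch in 1:3) X[, , ch, ] <- (X[, , ch, ] - ch_mean[ch]) / ch_sd[ch]

  if (regression) {
    y_mean <- mean(labels[tr_idx]); y_sd <- max(sd(labels[tr_idx]), 1e-9)
    y_std <- (labels - y_mean) / y_sd
  } else {
    cls <- match(labels, class_levels)
    cw <- config$class_weights
    if (identical(cw, "balanced")) {
      nj <- tabulate(cls[tr_idx], nbins = length(class_levels))
      cw <- length(tr_idx) / (length(class_levels) * pmax(nj, 1L))
    } else if (is.null(cw)) cw <- rep(1, length(class_levels))
  }

  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$rng_seed)
  params <- tiny_net_init(S, config$head_outputs)
  state <- adam_init(params)
  train_backbone <- !config$use_pretrained

  n_tr <- length(tr_idx)
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_metric = numeric(0))
  best <- list(metric = -Inf, epoch = NA_integer_, params = params)
  t_step <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- tr_idx[sample.int(n_tr)]
    batch_losses <- numeric(0)
    for (start in seq(1L, n_tr, by = config$batch_size)) {
      bidx <- ord[start:min(start + config$batch_size - 1L, n_tr)]
      nb <- length(bidx)
      fw <- tiny_net_forward(params, X[, , , bidx, drop = FALSE])
      if (regression) {
        pred <- as.numeric(fw$out)
        resid <- pred - y_std[bidx]
        loss <- mean(resid^2)
        dZ <- matrix(2 * resid / nb, 1L, nb)
      } else {
        P <- softmax_cols(fw$out)
        ci <- cls[bidx]
        w <- cw[ci]
        p_true <- pmax(P[cbind(ci, seq_len(nb))], 1e-12)
        loss <- -sum(w * log(p_true)) / sum(w)
        dZ <- P
        dZ[cbind(ci, seq_len(nb))] <- dZ[cbind(ci, seq_len(nb))] - 1
        dZ <- sweep(dZ, 2, w / sum(w), "*")
      }
      batch_losses <- c(batch_losses, loss)
      grads <- tiny_net_backward(params, fw$cache, dZ, train_backbone)
      t_step <- t_step + 1L
      upd <- adam_step(params, grads, state, config$learning_rate, t_step)
      params <- upd$params; state <- upd$state
    }
    # validation metric at epoch end
    Zv <- tiny_net_forward(params, X[, , , va_idx, drop = FALSE],
                           keep_cache = FALSE)$out
    if (regression) {
      pred_v <- as.numeric(Zv) * y_sd + y_mean
      vm <- r2(labels[va_idx], pred_v)
    } else {
      pred_v <- class_levels[max.col(t(Zv), ties.method = "first")]
      vm <- ba_present(labels[va_idx], pred_v, class_levels)
    }
    trace <- rbind(trace, data.frame(epoch = epoch,
                                     train_loss = mean(batch_losses),
                                     val_metric = vm))
    if (vm > best$metric) best <- list(metric = vm, epoch = epoch,
                                       params = params)
  }
  structure(list(params = best$params, trace = trace,
                 best_epoch = best$epoch, best_val_metric = best$metric,
                 config = config, class_levels = class_levels,
                 preprocess = list(input_size = S, ch_mean = ch_mean,
                                   ch_sd = ch_sd,
                                   y_mean = if (regression) y_mean,
                                   y_sd = if (regression) y_sd)),
            class = "tiny_cnn")
}

#' @export
print.tiny_cnn <- function(x, ...) {
  cat(sprintf("<tiny_cnn: %s, %d-output head, best epoch %d/%d (val metric %.3f)>\n",
              x$config$backbone, x$config$head_outputs, x$best_epoch,
              x$config$epochs, x$best_val_metric))
  invisible(x)
}

#' Predict from a trained CNN harness
#'
#' @param object a [train_cnn()] model.
#' @param plots list of [plot_image()]s.
#' @param ... unused.
#' @return Numeric yields (regression head) or a character vector of class
#'   labels.
#' @export
predict.tiny_cnn <- function(object, plots, ...) {
  S <- object$preprocess$input_size
  X <- array(0, c(S, S, 3L, length(plots)))
  for (i in seq_along(plots))
    X[, , , i] <- resize_bilinear(plots[[i]]$pixels / 255, S)
  for (ch in 1:3)
    X[, , ch, ] <- (X[, , ch, ] - object$preprocess$ch_mean[ch]) /
      object$preprocess$ch_sd[ch]
  Z <- tiny_net_forward(object$params, X, keep_cache = FALSE)$out
  if (object$config$head_outputs == 1L)
    return(as.numeric(Z) * object$preprocess$y_sd + object$preprocess$y_mean)
  object$class_levels[max.col(t(Z), ties.method = "first")]
}
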