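test_that("mse loss matches hand arithmetic and a loop oracle", {
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse_loss(c(1, 1), c(0, 2)), 1)
  expect_error(mse_loss(1:3, 1:4), "lengths differ")
  set.seed(2)
  y <- rnorm(30); p <- rnorm(30)
  acc <- 0
  for (i in 1:30) acc <- acc + (y[i] - p[i])^2
  expect_equal(mse_loss(p, y), acc / 30, tolerance = 1e-12)
})

test_that("weighted cross-entropy matches its closed forms", {
  P3 <- matrix(1 / 3, nrow = 6, ncol = 3,
               dimnames = list(NULL, c("1", "2", "3")))
  lab <- rep(1:3, 2)
  expect_equal(weighted_ce_loss(P3, lab, rep(1, 3)), log(3))
  one_hot <- diag(3)[lab, ]
  colnames(one_hot) <- c("1", "2", "3")
  # perfect one-hot predictions give zero loss
  expect_equal(weighted_ce_loss(one_hot, lab, rep(1, 3)), 0)
  # zero probability at the true class is clamped with a warning
  wrong <- (1 - one_hot) / 2
  expect_warning(z <- weighted_ce_loss(wrong, lab, rep(1, 3)), "clamped")
  expect_gt(z, 20)
})

test_that("balanced CE weights equalise expected class contributions", {
  n <- 1000L
  sizes <- c(100L, 300L, 600L)
  lab <- rep(1:3, times = sizes)
  # expected weights proportional to (10, 10/3, 5/3)
  w <- n / (3 * sizes)
  expect_equal(w / w[3], c(6, 2, 1))
  expect_equal(sizes * w, rep(n / 3, 3))
  set.seed(1)
  P <- matrix(runif(n * 3, 0.05, 1), n, 3)
  P <- P / rowSums(P)
  got <- weighted_ce_loss(P, lab, "balanced")
  manual <- -sum(w[lab] * log(P[cbind(seq_len(n), lab)])) / sum(w[lab])
  expect_equal(got, manual, tolerance = 1e-12)
  # unit weights recover the unweighted mean cross-entropy
  expect_equal(weighted_ce_loss(P, lab, rep(1, 3)),
               -mean(log(P[cbind(seq_len(n), lab)])), tolerance = 1e-12)
})

test_that("weighted cross-entropy validates its inputs", {
  P <- matrix(c(0.9, 0.2, 0.3, 0.8), 2, 2)
  expect_error(weighted_ce_loss(P, c(1, 2), c(1, 1)), "sum to 1")
  P2 <- P / rowSums(P)
  expect_error(weighted_ce_loss(P2, c(1, 3), c(1, 1)), "1..C")
  expect_error(weighted_ce_loss(P2, c(1, 2), c(1, -1)), "positive")
})

test_that("backpropagation matches numerical gradients on a tiny batch", {
  set.seed(77)
  X <- array(rnorm(16 * 16 * 3 * 4), c(16L, 16L, 3L, 4L))
  params <- rgbpheno:::tiny_net_init(16L, 2L)
  cls <- c(1L, 2L, 1L, 2L)
  loss_of <- function(p) {
    Z <- rgbpheno:::tiny_net_forward(p, X, keep_cache = FALSE)$out
    P <- rgbpheno:::softmax_cols(Z)
    -mean(log(pmax(P[cbind(cls, 1:4)], 1e-12)))
  }
  fw <- rgbpheno:::tiny_net_forward(params, X)
  P <- rgbpheno:::softmax_cols(fw$out)
  dZ <- P; dZ[cbind(cls, 1:4)] <- dZ[cbind(cls, 1:4)] - 1; dZ <- dZ / 4
  grads <- rgbpheno:::tiny_net_backward(params, fw$cache, dZ)
  eps <- 1e-5
  for (layer in c("conv1", "conv3", "fc2")) {
    idx <- cbind(c(1L, 2L), c(3L, 1L))
    for (r in 1:2) {
      p2 <- params
      p2[[layer]]$W[idx[r, 1], idx[r, 2]] <-
        p2[[layer]]$W[idx[r, 1], idx[r, 2]] + eps
      up <- loss_of(p2)
      p2[[layer]]$W[idx[r, 1], idx[r, 2]] <-
        p2[[layer]]$W[idx[r, 1], idx[r, 2]] - 2 * eps
      down <- loss_of(p2)
      num <- (up - down) / (2 * eps)
      ana <- grads[[layer]]$W[idx[r, 1], idx[r, 2]]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
})

test_that("the harness separates a linearly separable two-class image task", {
  fx <- separable_plots(n = 100L)
  fold <- list(train_ids = fx$ids[1:70], val_ids = fx$ids[71:100])
  cfg <- cnn_config(head_outputs = 2L, epochs = 15L, rng_seed = 11L)
  m <- train_cnn(fx$plots, fx$labels, cfg, fold)
  expect_gte(m$best_val_metric, 0.9)
  expect_equal(nrow(m$trace), 15L)
  expect_equal(m$best_epoch, which.max(m$trace$val_metric))
  # training loss falls over the run (and up to the best epoch when the
  # best epoch is not the first)
  expect_lt(min(m$trace$train_loss), m$trace$train_loss[1])
  if (m$best_epoch > 1L)
    expect_lt(m$trace$train_loss[m$best_epoch], m$trace$train_loss[1])
  # prediction from the returned best-epoch weights is self-consistent
  pred <- predict(m, fx$plots[71:100])
  expect_gte(rgbpheno:::ba_present(fx$labels[71:100], pred,
                                   m$class_levels), 0.9)
})

test_that("training traces are deterministic and single-epoch runs are forced", {
  fx <- separable_plots(n = 40L, seed = 5L)
  fold <- list(train_ids = fx$ids[1:30], val_ids = fx$ids[31:40])
  cfg1 <- cnn_config(head_outputs = 2L, epochs = 1L, rng_seed = 3L)
  m1 <- train_cnn(fx$plots, fx$labels, cfg1, fold)
  expect_equal(m1$best_epoch, 1L)
  cfg <- cnn_config(head_outputs = 2L, epochs = 3L, rng_seed = 3L)
  ma <- train_cnn(fx$plots, fx$labels, cfg, fold)
  mb <- train_cnn(fx$plots, fx$labels, cfg, fold)
  expect_identical(ma$trace, mb$trace)
})

test_that("a frozen backbone still trains its head", {
  fx <- separable_plots(n = 60L, seed = 8L)
  fold <- list(train_ids = fx$ids[1:40], val_ids = fx$ids[41:60])
  cfg <- cnn_config(head_outputs = 2L, use_pretrained = TRUE, epochs = 8L,
                    rng_seed = 2L)
  m <- train_cnn(fx$plots, fx$labels, cfg, fold)
  # conv weights unchanged, head weights moved
  init <- local({
    old <- get0(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
    set.seed(2L)
    rgbpheno:::tiny_net_init(32L, 2L)
  })
  expect_identical(m$params$conv1$W, init$conv1$W)
  expect_false(identical(m$params$fc2$W, init$fc2$W))
})

test_that("unavailable backbones point the user at the test backbone", {
  fx <- separable_plots(n = 12L, seed = 1L)
  fold <- list(train_ids = fx$ids[1:8], val_ids = fx$ids[9:12])
  cfg <- cnn_config(backbone = "densenet161", head_outputs = 2L)
  expect_error(train_cnn(fx$plots, fx$labels, cfg, fold), "tiny_test_net")
  expect_error(train_cnn(fx$plots, fx$labels,
                         cnn_config(head_outputs = 3L), fold),
               "3 but labels have 2")
})

test_that("the regression head learns a yield signal", {
  fx <- separable_plots(n = 80L, seed = 6L)
  dmy <- ifelse(fx$labels == "Select", 50, 5) + rnorm(80, 0, 2)
  fold <- list(train_ids = fx$ids[1:60], val_ids = fx$ids[61:80])
  cfg <- cnn_config(head_outputs = 1L, epochs = 10L, rng_seed = 4L)
  m <- train_cnn(fx$plots, dmy, cfg, fold)
  expect_gt(m$best_val_metric, 0.5)  # validation R-squared
})
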