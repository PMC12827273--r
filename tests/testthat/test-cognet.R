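test_that("configuration invariants are validated", {
  expect_error(cognet_config(10, dropout = 1), "dropout")
  expect_error(cognet_config(10, embed_dim = 30, n_heads = 4), "divisible")
  expect_error(cognet_config(10, split_ratio = 0), "split_ratio")
  cfg <- cognet_config(35)
  expect_equal(cfg$embed_dim, 512L)
  expect_equal(cfg$attn_hidden, 18)
  expect_equal(cfg$lr, 5e-5)
  expect_equal(cfg$weight_decay, 1e-8)
  expect_equal(cfg$grad_clip_norm, 1.0)
  expect_equal(cfg$dropout, 0.3)
  expect_equal(cfg$split_ratio, 0.9)
})

test_that("zero parameters give uniform attention and X' = X / f", {
  p <- list(W1 = matrix(0, 2, 4), b1 = rep(0, 4),
            W2 = matrix(0, 4, 2), b2 = rep(0, 2))
  X <- matrix(c(1, 2, 3, 4), 2, 2)
  at <- feature_attention(X, p)
  expect_equal(at$A, matrix(0.5, 2, 2))
  expect_equal(at$X_attended, X / 2)
  # bias-only logits: softmax(ln 3, 0) = (3/4, 1/4)
  p$b2 <- c(log(3), 0)
  at2 <- feature_attention(X, p)
  expect_equal(at2$A, matrix(c(0.75, 0.75, 0.25, 0.25), 2, 2))
})

test_that("attention matches a scalar-loop oracle on random inputs", {
  set.seed(5)
  f <- 4; h <- 3; B <- 3
  p <- list(W1 = matrix(rnorm(f * h), f, h), b1 = rnorm(h),
            W2 = matrix(rnorm(h * f), h, f), b2 = rnorm(f))
  X <- matrix(rnorm(B * f), B, f)
  at <- feature_attention(X, p)
  for (i in seq_len(B)) {
    hid <- numeric(h)
    for (j in seq_len(h)) {
      hid[j] <- max(sum(X[i, ] * p$W1[, j]) + p$b1[j], 0)
    }
    logit <- numeric(f)
    for (k in seq_len(f)) {
      logit[k] <- sum(hid * p$W2[, k]) + p$b2[k]
    }
    aa <- exp(logit) / sum(exp(logit))
    expect_equal(unname(at$A[i, ]), aa, tolerance = 1e-12)
    expect_equal(unname(at$X_attended[i, ]), unname(X[i, ] * aa),
                 tolerance = 1e-12)
  }
})

test_that("attention weights are a proper distribution on random trials", {
  set.seed(6)
  for (trial in 1:100) {
    f <- sample(2:20, 1)
    p <- list(W1 = matrix(rnorm(f * 8), f, 8), b1 = rnorm(8),
              W2 = matrix(rnorm(8 * f), 8, f), b2 = rnorm(f))
    A <- feature_attention(matrix(rnorm(3 * f), 3, f), p)$A
    expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-6)
    expect_true(all(A > 0))
  }
})

test_that("evaluation-mode forward is deterministic and per-sample", {
  cfg <- tiny_net_config(5)
  pars <- getFromNamespace("cognet_init_params", "petcog")(cfg)
  fwd <- getFromNamespace("cognet_forward", "petcog")
  X <- matrix(rnorm(4 * 5), 4, 5)
  X[2, ] <- X[1, ]                         # identical rows
  y1 <- fwd(pars, X, cfg, training = FALSE)$yhat
  expect_equal(y1[1], y1[2])
  # permuting rows permutes predictions
  perm <- c(3, 1, 4, 2)
  y2 <- fwd(pars, X[perm, ], cfg, training = FALSE)$yhat
  expect_equal(y2, y1[perm])
  # single sample equals the same sample inside a batch
  y3 <- fwd(pars, X[3, , drop = FALSE], cfg, training = FALSE)$yhat
  expect_equal(y3, y1[3], tolerance = 1e-5)
})

test_that("split arithmetic: 288 rows at 90:10 give 259/29, stratified", {
  tab <- generate_cohort(small_config(n_per_group = 96))$table
  sp <- split_data(tab, 0.9, seed = 4)
  expect_equal(nrow(sp$train), 259)
  expect_equal(nrow(sp$test), 29)
  expect_setequal(c(sp$train$subject_id, sp$test$subject_id),
                  tab$subject_id)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  counts <- table(sp$test$group)
  expect_setequal(as.integer(counts), c(10, 10, 9))
  expect_identical(split_data(tab, 0.9, seed = 4)$test$subject_id,
                   sp$test$subject_id)
})

test_that("split handles small n and degenerate ratios", {
  d <- data.frame(x = 1:10)
  sp <- split_data(d, 0.9, seed = 1)
  expect_equal(nrow(sp$train), 9)
  expect_equal(nrow(sp$test), 1)
  expect_error(split_data(d[1, , drop = FALSE]), "at least 2")
  sp2 <- split_data(d, 0.01, seed = 1)     # test capped at n - 1
  expect_gte(nrow(sp2$train), 1)
})

test_that("the network overfits a tiny noiseless linear dataset", {
  set.seed(42)
  X <- matrix(rnorm(8 * 4), 8, 4)
  d <- data.frame(X)
  d$y <- drop(X %*% c(1, -2, 0.5, 0))
  cfg <- tiny_net_config(4, epochs = 600, lr = 0.01, seed = 1)
  m <- train_cognet(d, paste0("X", 1:4), "y", cfg)
  expect_lt(utils::tail(m$history$loss, 1), 0.05)
  expect_equal(m$best_loss, min(m$history$loss))
})

test_that("training is reproducible and lr = 0 is the identity", {
  set.seed(10)
  d <- data.frame(a = rnorm(24), b = rnorm(24))
  d$y <- d$a - d$b + rnorm(24, 0, 0.1)
  cfg <- tiny_net_config(2, epochs = 10, seed = 3)
  m1 <- train_cognet(d, c("a", "b"), "y", cfg)
  m2 <- train_cognet(d, c("a", "b"), "y", cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$pars, m2$pars)
  expect_identical(predict(m1, d), predict(m2, d))

  cfg0 <- tiny_net_config(2, epochs = 5, seed = 3, lr = 0)
  m0 <- train_cognet(d, c("a", "b"), "y", cfg0)
  init <- getFromNamespace("with_seed", "petcog")(
    cfg0$seed, getFromNamespace("cognet_init_params", "petcog")(cfg0))
  expect_equal(m0$pars, init)
  expect_equal(stats::sd(m0$history$loss), 0, tolerance = 1e-12)
})

test_that("regression metrics follow their definitions", {
  m <- regression_metrics(c(22, 24, 29), c(20, 25, 30))
  expect_equal(m$mse, 2.0)
  expect_equal(m$mae, 4 / 3)
  expect_equal(m$r2, 1 - 6 / 50)           # 0.88
  perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect, list(r2 = 1, mse = 0, mae = 0))
  at_mean <- regression_metrics(rep(2, 3), c(1, 2, 3))
  expect_equal(at_mean$r2, 0)
  expect_warning(z <- regression_metrics(c(1, 2), c(3, 3)), "zero-variance")
  expect_true(is.na(z$r2))
  expect_equal(z$mse, mean(c(4, 1)))
})

test_that("evaluate_model wires predictions to metrics", {
  set.seed(20)
  d <- data.frame(a = rnorm(40), b = rnorm(40))
  d$y <- 2 * d$a + rnorm(40, 0, 0.1)
  cfg <- tiny_net_config(2, epochs = 120, seed = 5)
  m <- train_cognet(d[1:32, ], c("a", "b"), "y", cfg)
  met <- evaluate_model(m, d[33:40, ])
  expect_equal(met$mse, mean((predict(m, d[33:40, ]) - d$y[33:40])^2))
  expect_error(evaluate_model(m, d[0, ]), "nonempty")
})

test_that("model checkpoints round-trip through serialization", {
  set.seed(15)
  d <- data.frame(a = rnorm(30), b = rnorm(30))
  d$y <- d$a + rnorm(30, 0, 0.1)
  m <- train_cognet(d, c("a", "b"), "y", tiny_net_config(2, epochs = 20))
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m, f)
  m2 <- readRDS(f)
  expect_identical(predict(m2, d), predict(m, d))
})

test_that("attention mass concentrates on informative features", {
  set.seed(30)
  n <- 200; f <- 10
  X <- matrix(rnorm(n * f), n, f)
  d <- data.frame(X)
  d$y <- drop(X[, 1:2] %*% c(3, -3)) + rnorm(n, 0, 0.3)
  cfg <- tiny_net_config(f, epochs = 200, seed = 8)
  m <- train_cognet(d, paste0("X", 1:f), "y", cfg)
  Xs <- sweep(sweep(as.matrix(d[paste0("X", 1:f)]), 2, m$x_center),
              2, m$x_scale, "/")
  A <- feature_attention(Xs, list(W1 = m$pars$attn.W1, b1 = m$pars$attn.b1,
                                  W2 = m$pars$attn.W2, b2 = m$pars$attn.b2))$A
  mass <- colMeans(A)
  expect_gt(mean(mass[1:2]), mean(mass[3:f]))
})
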