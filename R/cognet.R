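# Feature-wise-attention transformer regressor for tabular PET features.
#
# Architecture: a feature-wise attention block computes per-sample softmax
# weights over the f input features through a two-layer bottleneck,
#   A  = softmax(W2 %*% relu(W1 %*% x + b1) + b2),   x' = x (*) A,
# the attended vector is linearly embedded into a single embed_dim latent
# token, processed by a stack of transformer encoder layers (self-attention
# + feed-forward + layer normalization, post-norm), and mapped to a scalar
# by a fully connected regression head with ReLU and dropout.
#
# At sequence length one the query-key softmax of multi-head self-attention
# is identically 1 for every head, so the self-attention sublayer reduces
# exactly to its value and output projections; the implementation uses that
# reduction (query/key weights would receive zero gradient).
#
# Everything is plain R matrix algebra with hand-written backpropagation,
# AdamW updates, Huber loss and global gradient-norm clipping, so training
# is bit-reproducible from the seed on a fixed BLAS.

#' Network configuration
#'
#' @param n_features number of input features f (selected regions +
#'   demographics).
#' @param attn_hidden width of the attention bottleneck (default
#'   `max(ceiling(n_features / 2), 8)`).
#' @param embed_dim latent width (default 512; must be divisible by
#'   `n_heads`).
#' @param n_encoder_layers encoder stack depth (default 2).
#' @param n_heads attention heads (default 4; inert at sequence length one
#'   but kept as a shape constraint).
#' @param ff_dim encoder feed-forward width (default `2 * embed_dim`).
#' @param head_hidden regression-head hidden width (default 64).
#' @param dropout dropout probability between layers (default 0.3).
#' @param lr AdamW learning rate (default 5e-5).
#' @param weight_decay AdamW weight decay (default 1e-8).
#' @param grad_clip_norm maximum global gradient norm (default 1.0).
#' @param huber_delta Huber loss transition point (default 1.0, the
#'   SmoothL1 form).
#' @param split_ratio train fraction for [split_data()] (default 0.9).
#' @param epochs training epochs (default 100; the stack converges on
#'   cohort-sized tabular data well before that, and single-CPU runtime
#'   grows linearly).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return object of class `cognet_config`.
#' @export
cognet_config <- function(n_features,
                          attn_hidden = max(ceiling(n_features / 2), 8),
                          embed_dim = 512L, n_encoder_layers = 2L,
                          n_heads = 4L, ff_dim = 2L * embed_dim,
                          head_hidden = 64L, dropout = 0.3,
                          lr = 5e-5, weight_decay = 1e-8,
                          grad_clip_norm = 1.0, huber_delta = 1.0,
                          split_ratio = 0.9, epochs = 100L,
                          batch_size = 32L, seed = 1L) {
  check_number(n_features, "n_features", lower = 1)
  check_number(dropout, "dropout", lower = 0, upper = 1 - 1e-9)
  check_number(split_ratio, "split_ratio", lower = 1e-9, upper = 1 - 1e-9)
  if (embed_dim %% n_heads != 0) {
    stopf("configuration error: embed_dim must be divisible by n_heads")
  }
  structure(list(
    n_features = as.integer(n_features), attn_hidden = as.integer(attn_hidden),
    embed_dim = as.integer(embed_dim),
    n_encoder_layers = as.integer(n_encoder_layers),
    n_heads = as.integer(n_heads), ff_dim = as.integer(ff_dim),
    head_hidden = as.integer(head_hidden), dropout = dropout, lr = lr,
    weight_decay = weight_decay, grad_clip_norm = grad_clip_norm,
    huber_delta = huber_delta, split_ratio = split_ratio,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    seed = as.integer(seed)
  ), class = "cognet_config")
}

row_softmax <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))

#' Feature-wise attention
#'
#' Computes per-sample attention weights over the feature axis and the
#' attended features: `A = softmax(relu(X W1 + b1) W2 + b2)` (softmax per
#' row), `X' = X * A`. Each row of `A` sums to 1 with all entries > 0.
#'
#' @param X numeric matrix, batch x f.
#' @param params list with `W1` (f x h), `b1` (h), `W2` (h x f), `b2` (f).
#' @return list with `A` (batch x f attention weights) and `X_attended`.
#' @export
#' @examples
#' p <- list(W1 = matrix(0, 2, 8), b1 = rep(0, 8),
#'           W2 = matrix(0, 8, 2), b2 = c(0, 0))
#' feature_attention(matrix(1:4, 2), p)$A   # uniform 1/2
feature_attention <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(params$W1)) {
    stopf("contract error: X has %d features, W1 expects %d",
          ncol(X), nrow(params$W1))
  }
  H <- pmax(add_bias(X %*% params$W1, params$b1), 0)
  A <- row_softmax(add_bias(H %*% params$W2, params$b2))
  list(A = A, X_attended = X * A)
}

# ---- parameter initialization --------------------------------------------

# Uniform(-1/sqrt(fan_in), 1/sqrt(fan_in)), the standard dense-layer
# default of the major deep-learning frameworks. He-scaled Gaussian init
# (2.4x larger) makes the 512-d stack memorize small tabular sets instead
# of generalizing.
he_mat <- function(n_in, n_out) {
  matrix(stats::runif(n_in * n_out, -1, 1) / sqrt(n_in), n_in, n_out)
}

cognet_init_params <- function(cfg) {
  f <- cfg$n_features; h <- cfg$attn_hidden; d <- cfg$embed_dim
  ff <- cfg$ff_dim; hh <- cfg$head_hidden
  pars <- list(
    attn.W1 = he_mat(f, h), attn.b1 = rep(0, h),
    attn.W2 = he_mat(h, f), attn.b2 = rep(0, f),
    embed.W = he_mat(f, d), embed.b = rep(0, d)
  )
  for (l in seq_len(cfg$n_encoder_layers)) {
    p <- function(nm) paste0("layer", l, ".", nm)
    pars[[p("Wv")]] <- he_mat(d, d); pars[[p("Wo")]] <- he_mat(d, d)
    pars[[p("ln1.g")]] <- rep(1, d); pars[[p("ln1.b")]] <- rep(0, d)
    pars[[p("Wf1")]] <- he_mat(d, ff); pars[[p("bf1")]] <- rep(0, ff)
    pars[[p("Wf2")]] <- he_mat(ff, d); pars[[p("bf2")]] <- rep(0, d)
    pars[[p("ln2.g")]] <- rep(1, d); pars[[p("ln2.b")]] <- rep(0, d)
  }
  pars$head.W1 <- he_mat(d, hh); pars$head.b1 <- rep(0, hh)
  pars$head.W2 <- he_mat(hh, 1); pars$head.b2 <- 0
  pars
}

# ---- layer normalization --------------------------------------------------

ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = xhat * rep(g, each = nrow(X)) + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

ln_backward <- function(G, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(G * xhat); db <- colSums(G)
  dxhat <- G * rep(g, each = nrow(G))
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

dropout_forward <- function(X, p, training) {
  if (!training || p == 0) return(list(out = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= p) / (1 - p),
                 nrow(X), ncol(X))
  list(out = X * mask, mask = mask)
}

# ---- forward / backward ----------------------------------------------------

cognet_forward <- function(pars, X, cfg, training = FALSE) {
  B <- nrow(X)
  cache <- list(X = X)
  att <- feature_attention(X, list(W1 = pars$attn.W1, b1 = pars$attn.b1,
                                   W2 = pars$attn.W2, b2 = pars$attn.b2))
  cache$H1pre <- add_bias(X %*% pars$attn.W1, pars$attn.b1)
  cache$H1 <- pmax(cache$H1pre, 0)
  cache$A <- att$A; cache$Xa <- att$X_attended
  E <- add_bias(cache$Xa %*% pars$embed.W, pars$embed.b)
  cache$E0 <- E
  for (l in seq_len(cfg$n_encoder_layers)) {
    p <- function(nm) pars[[paste0("layer", l, ".", nm)]]
    lc <- list(Ein = E)
    V <- E %*% p("Wv")
    attn_out <- V %*% p("Wo")
    dr1 <- dropout_forward(attn_out, cfg$dropout, training)
    ln1 <- ln_forward(E + dr1$out, p("ln1.g"), p("ln1.b"))
    F1pre <- add_bias(ln1$out %*% p("Wf1"), p("bf1"))
    F1 <- pmax(F1pre, 0)
    dr2 <- dropout_forward(F1, cfg$dropout, training)
    O <- add_bias(dr2$out %*% p("Wf2"), p("bf2"))
    dr3 <- dropout_forward(O, cfg$dropout, training)
    ln2 <- ln_forward(ln1$out + dr3$out, p("ln2.g"), p("ln2.b"))
    lc$V <- V; lc$dr1 <- dr1; lc$ln1 <- ln1; lc$F1pre <- F1pre
    lc$dr2 <- dr2; lc$dr3 <- dr3; lc$ln2 <- ln2
    cache[[paste0("layer", l)]] <- lc
    E <- ln2$out
  }
  cache$Z <- E
  Hh_pre <- add_bias(E %*% pars$head.W1, pars$head.b1)
  Hh <- pmax(Hh_pre, 0)
  drh <- dropout_forward(Hh, cfg$dropout, training)
  yhat <- drop(add_bias(drh$out %*% pars$head.W2, pars$head.b2))
  cache$Hh_pre <- Hh_pre; cache$drh <- drh
  list(yhat = yhat, cache = cache)
}

cognet_backward <- function(pars, cfg, cache, dyhat) {
  B <- length(dyhat)
  grads <- list()
  Dy <- matrix(dyhat, B, 1)
  grads$head.W2 <- crossprod(cache$drh$out, Dy)
  grads$head.b2 <- sum(Dy)
  dHhd <- tcrossprod(Dy, pars$head.W2)
  if (!is.null(cache$drh$mask)) dHhd <- dHhd * cache$drh$mask
  dHh_pre <- dHhd * (cache$Hh_pre > 0)
  grads$head.W1 <- crossprod(cache$Z, dHh_pre)
  grads$head.b1 <- colSums(dHh_pre)
  G <- tcrossprod(dHh_pre, pars$head.W1)
  for (l in rev(seq_len(cfg$n_encoder_layers))) {
    nm <- function(x) paste0("layer", l, ".", x)
    p <- function(x) pars[[nm(x)]]
    lc <- cache[[paste0("layer", l)]]
    bl2 <- ln_backward(G, lc$ln2, p("ln2.g"))
    grads[[nm("ln2.g")]] <- bl2$dg; grads[[nm("ln2.b")]] <- bl2$db
    dres2 <- bl2$dx                      # grad wrt (ln1$out + dr3$out)
    dO <- dres2
    if (!is.null(lc$dr3$mask)) dO <- dO * lc$dr3$mask
    grads[[nm("Wf2")]] <- crossprod(lc$dr2$out, dO)
    grads[[nm("bf2")]] <- colSums(dO)
    dF1d <- tcrossprod(dO, p("Wf2"))
    if (!is.null(lc$dr2$mask)) dF1d <- dF1d * lc$dr2$mask
    dF1pre <- dF1d * (lc$F1pre > 0)
    grads[[nm("Wf1")]] <- crossprod(lc$ln1$out, dF1pre)
    grads[[nm("bf1")]] <- colSums(dF1pre)
    dZ1 <- dres2 + tcrossprod(dF1pre, p("Wf1"))
    bl1 <- ln_backward(dZ1, lc$ln1, p("ln1.g"))
    grads[[nm("ln1.g")]] <- bl1$dg; grads[[nm("ln1.b")]] <- bl1$db
    dres1 <- bl1$dx                      # grad wrt (E + dr1$out)
    dattn <- dres1
    if (!is.null(lc$dr1$mask)) dattn <- dattn * lc$dr1$mask
    grads[[nm("Wo")]] <- crossprod(lc$V, dattn)
    dV <- tcrossprod(dattn, p("Wo"))
    grads[[nm("Wv")]] <- crossprod(lc$Ein, dV)
    G <- dres1 + tcrossprod(dV, p("Wv"))
  }
  grads$embed.W <- crossprod(cache$Xa, G)
  grads$embed.b <- colSums(G)
  dXa <- tcrossprod(G, pars$embed.W)
  X <- cache$X; A <- cache$A
  dA <- dXa * X
  dS <- A * (dA - rowSums(dA * A))
  grads$attn.W2 <- crossprod(cache$H1, dS)
  grads$attn.b2 <- colSums(dS)
  dH1 <- tcrossprod(dS, pars$attn.W2)
  dH1pre <- dH1 * (cache$H1pre > 0)
  grads$attn.W1 <- crossprod(X, dH1pre)
  grads$attn.b1 <- colSums(dH1pre)
  grads
}

huber_loss <- function(diff, delta) {
  a <- abs(diff)
  mean(ifelse(a <= delta, 0.5 * diff^2, delta * (a - 0.5 * delta)))
}

huber_grad <- function(diff, delta) {
  pmin(pmax(diff, -delta), delta) / length(diff)
}

# Fused gradient clipping + AdamW step; the compiled kernel updates pars,
# m and v in place (the training loop owns them exclusively).
adamw_step <- function(pars, grads, state, cfg,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  adamw_step_cpp(pars, grads[names(pars)], state$m, state$v,
                 state$t, cfg$lr, cfg$weight_decay, cfg$grad_clip_norm,
                 beta1, beta2, eps)
  state
}

deep_copy <- function(pars) lapply(pars, function(p) p * 1)

#' Stratified train/test split
#'
#' Test size is `round((1 - split_ratio) * n)` (at least 1, at most n - 1).
#' When a `group` column is present the test rows are allocated across
#' groups by largest-remainder apportionment (ties by group name) and
#' sampled within group; splits are disjoint, exhaustive and reproducible
#' from the seed.
#'
#' @param table data.frame with at least 2 rows.
#' @param split_ratio train fraction (default 0.9).
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_data <- function(table, split_ratio = 0.9, seed = 1L) {
  n <- nrow(table)
  if (n < 2) stopf("domain error: need at least 2 rows")
  check_number(split_ratio, "split_ratio", lower = 1e-9, upper = 1 - 1e-9)
  n_test <- min(max(round((1 - split_ratio) * n), 1L), n - 1L)
  with_seed(seed, {
    if ("group" %in% names(table)) {
      groups <- sort(unique(table$group))
      n_g <- vapply(groups, function(g) sum(table$group == g), 0L)
      quota <- n_test * n_g / n
      take <- floor(quota)
      rem <- n_test - sum(take)
      if (rem > 0) {
        ord <- order(-(quota - take), groups)
        take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
      }
      test_idx <- unlist(lapply(seq_along(groups), function(i) {
        idx <- which(table$group == groups[i])
        if (take[i] == 0) integer() else sample(idx, take[i])
      }))
    } else {
      test_idx <- sample(n, n_test)
    }
    test_idx <- sort(test_idx)
    list(train = table[setdiff(seq_len(n), test_idx), , drop = FALSE],
         test = table[test_idx, , drop = FALSE])
  })
}

#' Train the attention-transformer regressor
#'
#' Features are z-scaled with training-set statistics (the target too, so
#' the Huber loss operates on a unit scale; predictions are mapped back).
#' Optimization is minibatch AdamW with Huber loss and global
#' gradient-norm clipping; the returned model carries the parameters of
#' the epoch with the best training loss.
#'
#' @param data training data.frame.
#' @param features feature column names (selected regions + demographics).
#' @param target target column name (`"mmse"` or `"faq"`).
#' @param config a [cognet_config()]; its `n_features` must equal
#'   `length(features)`.
#' @return object of class `cognet_model` with the fitted parameters,
#'   scaling statistics, config snapshot and per-epoch training history
#'   (`$history`, data.frame epoch/loss). The model is a plain R list;
#'   persist checkpoints with `saveRDS()` and restore with `readRDS()` —
#'   predictions round-trip exactly.
#' @export
train_cognet <- function(data, features, target, config) {
  stopifnot(inherits(config, "cognet_config"))
  if (length(features) != config$n_features) {
    stopf("contract error: config expects %d features, got %d",
          config$n_features, length(features))
  }
  X <- as.matrix(as.data.frame(data)[, features, drop = FALSE])
  storage.mode(X) <- "double"
  y <- as.numeric(data[[target]])
  if (nrow(X) < 1) stopf("train rows must be nonempty")
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd); x_scale[x_scale < 1e-12] <- 1
  y_center <- mean(y)
  y_scale <- stats::sd(y); if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale
  n <- nrow(Xs)

  with_seed(config$seed, {
    pars <- cognet_init_params(config)
    state <- list(t = 0L,
                  m = lapply(pars, function(p) p * 0),
                  v = lapply(pars, function(p) p * 0))
    history <- numeric(config$epochs)
    best_loss <- Inf
    best_pars <- deep_copy(pars)
    for (epoch in seq_len(config$epochs)) {
      idx <- sample(n)
      losses <- c(); sizes <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        b <- idx[start:min(start + config$batch_size - 1, n)]
        fw <- cognet_forward(pars, Xs[b, , drop = FALSE], config,
                             training = TRUE)
        diff <- fw$yhat - ys[b]
        loss <- huber_loss(diff, config$huber_delta)
        if (!is.finite(loss)) {
          stopf("divergence error: non-finite loss at epoch %d", epoch)
        }
        grads <- cognet_backward(pars, config, fw$cache,
                                 huber_grad(diff, config$huber_delta))
        state <- adamw_step(pars, grads, state, config)
        losses <- c(losses, loss); sizes <- c(sizes, length(b))
      }
      history[epoch] <- sum(losses * sizes) / sum(sizes)
      if (history[epoch] < best_loss) {
        best_loss <- history[epoch]
        best_pars <- deep_copy(pars)
      }
    }
    structure(list(pars = best_pars, config = config, features = features,
                   target = target, x_center = x_center, x_scale = x_scale,
                   y_center = y_center, y_scale = y_scale,
                   history = data.frame(epoch = seq_len(config$epochs),
                                        loss = history),
                   best_loss = best_loss),
              class = "cognet_model")
  })
}

#' Predict cognitive scores
#'
#' Deterministic evaluation-mode forward pass (dropout off); features are
#' scaled with the model's stored training statistics and predictions are
#' returned on the original score scale.
#'
#' @param object a trained `cognet_model`.
#' @param newdata data.frame containing the model's feature columns, or a
#'   numeric matrix with matching columns.
#' @param ... unused.
#' @return numeric vector of predicted scores.
#' @export
predict.cognet_model <- function(object, newdata, ...) {
  if (is.null(object$pars)) stopf("state error: model is not fitted")
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  storage.mode(X) <- "double"
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  fw <- cognet_forward(object$pars, Xs, object$config, training = FALSE)
  fw$yhat * object$y_scale + object$y_center
}

#' Regression metrics
#'
#' Mean squared error, mean absolute error and the coefficient of
#' determination `R2 = 1 - SS_res / SS_tot` (SS_tot about the mean of
#' `actual`). Zero-variance `actual` leaves R2 undefined: `r2` is `NA`
#' with a warning, `mse`/`mae` are still returned.
#'
#' @param predicted,actual numeric vectors of equal length.
#' @return list with `r2`, `mse`, `mae`.
#' @export
#' @examples
#' regression_metrics(c(22, 24, 29), c(20, 25, 30))
regression_metrics <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual), length(actual) >= 1)
  err <- predicted - actual
  mse <- mean(err^2)
  mae <- mean(abs(err))
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) {
    warning("zero-variance targets: R2 undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum(err^2) / ss_tot
  }
  list(r2 = r2, mse = mse, mae = mae)
}

#' Evaluate a trained model on held-out rows
#'
#' @param model a trained `cognet_model`.
#' @param data nonempty data.frame with the feature and target columns.
#' @param target target column; defaults to the model's training target.
#' @return list with `r2`, `mse`, `mae` (see [regression_metrics()]).
#' @export
evaluate_model <- function(model, data, target = model$target) {
  if (nrow(as.data.frame(data)) < 1) stopf("test rows must be nonempty")
  regression_metrics(predict(model, data), as.numeric(data[[target]]))
}
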