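# Encoder building blocks: embedding, attention, encoder block, heads,
# likelihood, and the analytic gradients of the full trunk.

test_that("embedding is a deterministic per-step affine map", {
  set.seed(4)
  x <- matrix(rnorm(12), 4, 3)
  w_id <- list(W = diag(3), b = rep(0, 3))
  expect_equal(embed_sequence(x, 3, weights = w_id), x)
  expect_equal(dim(embed_sequence(x, 9, seed = 2)), c(4L, 9L))
  expect_identical(embed_sequence(x, 5, seed = 7), embed_sequence(x, 5, seed = 7))
  expect_gt(max(abs(embed_sequence(x, 5, seed = 7) - embed_sequence(x, 5, seed = 8))), 0)
  expect_error(embed_sequence(matrix(c(1, NA), 1), 2), "finite")

  # an all-zero padded feature column with zero weights changes nothing
  w <- list(W = matrix(rnorm(3 * 4), 3, 4), b = rnorm(4))
  w_pad <- list(W = rbind(w$W, 0), b = w$b)
  expect_equal(embed_sequence(cbind(x, 0), 4, weights = w_pad),
               embed_sequence(x, 4, weights = w))
})

test_that("attention weights are row-stochastic and saturate correctly", {
  set.seed(9)
  x <- matrix(rnorm(6 * 8), 6, 8)
  out <- multi_head_attention(x, n_heads = 4, seed = 1)
  for (P in out$attention) {
    expect_equal(unname(rowSums(P)), rep(1, 6), tolerance = 1e-6)
    expect_true(all(P >= 0))
  }
  expect_equal(dim(out$output), dim(x))

  # single head with one dominant logit: output row ~ the dominant value row
  T_ <- 3; dm <- 2
  big <- 60
  w <- list(Wq = diag(dm) * big, Wk = diag(dm), Wv = diag(dm),
            Wo = diag(dm), bo = rep(0, dm))
  xs <- matrix(c(1, 0,
                 0, 1,
                 1, 0), T_, dm, byrow = TRUE)
  res <- multi_head_attention(xs, n_heads = 1, key_dim = dm, weights = w)
  # query row 1 = (big, 0): logits big for keys with first coord 1 (rows 1, 3)
  expect_equal(res$attention[[1]][2, 2], 1, tolerance = 1e-6)
  expect_equal(res$output[2, ], xs[2, ], tolerance = 1e-6)
})

test_that("attention matches a hand-computed two-step example", {
  # T = 2, d'' = 2, one head, hand arithmetic
  x <- matrix(c(1, 2,
                3, -1), 2, 2, byrow = TRUE)
  w <- list(Wq = matrix(c(0.5, 0, 0, 1), 2), Wk = diag(2),
            Wv = matrix(c(1, 1, 0, 1), 2), Wo = diag(2), bo = c(0, 0))
  res <- multi_head_attention(x, n_heads = 1, key_dim = 2, weights = w)
  # Q = x Wq = [[0.5, 2], [1.5, -1]]; K = x; V = x Wv = [[3, 2], [2, -1]]
  # S = Q K' / sqrt(2):
  s11 <- (0.5 * 1 + 2 * 2) / sqrt(2); s12 <- (0.5 * 3 + 2 * -1) / sqrt(2)
  s21 <- (1.5 * 1 - 1 * 2) / sqrt(2); s22 <- (1.5 * 3 + 1) / sqrt(2)
  p1 <- exp(c(s11, s12)); p1 <- p1 / sum(p1)
  p2 <- exp(c(s21, s22)); p2 <- p2 / sum(p2)
  V <- matrix(c(3, 2, 2, -1), 2, byrow = TRUE)
  expect_equal(res$attention[[1]], rbind(p1, p2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(res$output, rbind(p1 %*% V, p2 %*% V), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("encoder block is LayerNorm(FFN(A) + A) with residual passthrough", {
  set.seed(10)
  a <- matrix(rnorm(5 * 6), 5, 6)
  w0 <- list(W1 = matrix(0, 6, 9), b1 = rep(0, 9), W2 = matrix(0, 9, 6),
             b2 = rep(0, 6), gamma = rep(1, 6), beta = rep(0, 6))
  e0 <- encoder_block(a, ffn_dim = 9, weights = w0)
  # zero feed-forward: E = LayerNorm(A); rows have mean 0, variance 1
  expect_equal(unname(rowMeans(e0)), rep(0, 5), tolerance = 1e-5)
  expect_equal(unname(apply(e0, 1, function(r) mean(r^2))), rep(1, 5),
               tolerance = 1e-4)
  mu <- rowMeans(a); v <- apply(a, 1, function(r) mean((r - mean(r))^2))
  expect_equal(e0, (a - mu) / sqrt(v + 1e-5), tolerance = 1e-12)

  # eval mode is deterministic; training-mode dropout is not a no-op
  e1 <- encoder_block(a, ffn_dim = 9, seed = 3)
  e2 <- encoder_block(a, ffn_dim = 9, seed = 3)
  expect_identical(e1, e2)
  set.seed(1)
  ed <- encoder_block(a, ffn_dim = 9, seed = 3, dropout = 0.5, train = TRUE)
  expect_gt(max(abs(ed - e1)), 1e-8)
})

test_that("prediction and GP heads implement their affine contracts", {
  set.seed(12)
  e <- matrix(rnorm(4 * 6), 4, 6)
  expect_equal(predict_head(e, list(w = rep(0, 6), b = 2.5)), 2.5)
  w <- list(w = rnorm(6), b = 0)
  expect_equal(predict_head(3 * e, w), 3 * predict_head(e, w), tolerance = 1e-12)

  gw <- list(wm = rep(0, 6), bm = 7, ws = rep(0, 6), bs = 0)
  gp <- map_to_gp(e, gw)
  expect_equal(gp$mean_path, rep(7, 4))
  expect_equal(gp$variance_path, rep(log(2) + 1e-6, 4), tolerance = 1e-12)
  gp2 <- map_to_gp(e, list(wm = rnorm(6), bm = 0, ws = rnorm(6), bs = -40))
  expect_true(all(gp2$variance_path >= 1e-6))
  expect_error(gp_prediction(1:3, c(1, 1)), "equal length")
  expect_error(gp_prediction(1:3, c(1, 0, 1)), "positive")
})

test_that("negative log-likelihood matches closed forms and is monotone", {
  pred <- gp_prediction(rep(5, 4), rep(1, 4), times = 0:3)
  obs <- data.frame(time = 1, volume = 5)
  expect_equal(negative_log_likelihood(obs, pred, delta = 0),
               0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(negative_log_likelihood(obs, pred, delta = 1),
               -log(1 / sqrt(2 * pi) + 1), tolerance = 1e-12)
  expect_equal(negative_log_likelihood(obs, pred, delta = 1),
               -0.3357164, tolerance = 1e-6)
  # strictly increasing in |v - M| at fixed variance
  losses <- vapply(c(0, 0.5, 1, 2, 4), function(dv) {
    negative_log_likelihood(data.frame(time = 2, volume = 5 + dv), pred, delta = 0)
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
  # delta keeps underflowing densities finite
  expect_true(is.finite(negative_log_likelihood(
    data.frame(time = 0, volume = 1e6), pred, delta = 1e-6)))
  expect_error(negative_log_likelihood(data.frame(time = 9, volume = 1), pred),
               "align")
  # list-of-pairs interface
  expect_equal(negative_log_likelihood(list(list(1, 5), list(3, 5)), pred,
                                       delta = 0),
               2 * 0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("analytic trunk gradients match central finite differences", {
  for (shared in c(TRUE, FALSE)) {
    cfg <- mskt_config(embed_dim = 3, model_dim = 4, n_heads = 2, key_dim = 2,
                       ffn_dim = 5, n_layers = 2, dropout = 0,
                       point_weight = 0.7, shared_trunk = shared, seed = 3)
    T_ <- 5; in_dim <- 8
    set.seed(21)
    z0s <- matrix(rnorm(T_ * in_dim), T_, in_dim)
    params <- init_params(in_dim, cfg, n_steps = T_, mean_bias = 0.2, var_bias_raw = 0.1)
    posenc <- positional_encoding(T_, cfg$model_dim)
    obs_idx <- c(1L, 3L, 5L); v_obs <- c(0.5, -0.2, 1.1)
    loss_fn <- function(theta) {
      p <- msktgp:::relist_params(theta, params)
      fw <- msktgp:::model_forward(z0s, p, cfg, posenc, train = FALSE)
      msktgp:::patient_loss_grad(fw, obs_idx, v_obs, cfg)$loss
    }
    theta <- msktgp:::flatten_params(params)
    fw <- msktgp:::model_forward(z0s, params, cfg, posenc, train = FALSE)
    lg <- msktgp:::patient_loss_grad(fw, obs_idx, v_obs, cfg)
    g <- msktgp:::flatten_params(msktgp:::model_backward(fw, lg, z0s, params, cfg))
    eps <- 1e-4
    idx <- sort(sample(length(theta), 150))
    num <- vapply(idx, function(i) {
      tp <- theta; tp[i] <- theta[i] + eps; up <- loss_fn(tp)
      tp[i] <- theta[i] - eps; dn <- loss_fn(tp)
      (up - dn) / (2 * eps)
    }, numeric(1))
    rel <- abs(num - g[idx]) / pmax(1, abs(num), abs(g[idx]))
    expect_lt(max(rel), 1e-4)
  }
})

test_that("the training forward pass equals the composition of the exported ops", {
  cfg <- mskt_config(embed_dim = 3, model_dim = 6, n_heads = 2, key_dim = 3,
                     ffn_dim = 7, n_layers = 1, dropout = 0, seed = 13)
  T_ <- 6; in_dim <- 10
  set.seed(31)
  z0s <- matrix(rnorm(T_ * in_dim), T_, in_dim)
  params <- msktgp:::init_params(in_dim, cfg, T_, 0, 0)
  posenc <- positional_encoding(T_, cfg$model_dim)
  fw <- msktgp:::model_forward(z0s, params, cfg, posenc, train = FALSE)

  tp <- params$trunks[[1]]
  z <- z0s %*% tp$Wp + matrix(tp$bp, T_, cfg$model_dim, byrow = TRUE) + posenc
  lw <- tp$layers[[1]]
  a <- multi_head_attention(z, n_heads = 2, key_dim = 3,
                            weights = lw[c("Wq", "Wk", "Wv", "Wo", "bo")])$output
  e <- encoder_block(a, ffn_dim = 7,
                     weights = lw[c("W1", "b1", "W2", "b2", "gamma", "beta")])
  # heads use the residual readout [E ; Z' ; pooled Z'] with time-varying
  # terms: per-step biases bt/bst and the rank-1 interaction score * gshape
  h_in <- cbind(e, z, matrix(colMeans(z), nrow(z), ncol(z), byrow = TRUE))
  hd <- params$heads
  gp <- map_to_gp(h_in, list(wm = hd$wm, bm = hd$bm, ws = hd$ws, bs = hd$bs),
                  var_floor = cfg$var_floor)
  mean_full <- gp$mean_path + hd$bt + sum(colMeans(h_in) * hd$wg) * hd$gshape
  var_full <- msktgp:::softplus(drop(h_in %*% hd$ws) + hd$bs + hd$bst) +
    cfg$var_floor
  yp <- predict_head(h_in, list(w = hd$wy, b = hd$by))
  expect_equal(fw$mean, mean_full, tolerance = 1e-12)
  expect_equal(fw$variance, var_full, tolerance = 1e-12)
  expect_equal(fw$ypred, yp, tolerance = 1e-12)
})
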