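# Training engine: full forward pass with cache, analytic backpropagation,
# and first-order optimizers. The trunk is: standardized multi-scale kernel
# rows -> affine projection + positional encoding -> n_layers x (multi-head
# self-attention -> feed-forward -> LayerNorm(F + A)) -> heads.

init_trunk_params <- function(in_dim, cfg) {
  dm <- cfg$model_dim
  hk <- cfg$n_heads * cfg$key_dim
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    c(init_attention_weights(dm, cfg$n_heads, cfg$key_dim,
                             seed = derive_seed(cfg$seed, paste0("attn", l))),
      init_block_weights(dm, cfg$ffn_dim,
                         seed = derive_seed(cfg$seed, paste0("ffn", l))))
  })
  proj <- with_seed(derive_seed(cfg$seed, "proj"), list(
    Wp = matrix(stats::rnorm(in_dim * dm, sd = 1 / sqrt(in_dim)), in_dim, dm),
    bp = numeric(dm)))
  c(proj, list(layers = layers))
}

init_params <- function(in_dim, cfg, n_steps, mean_bias = 0, var_bias_raw = 0) {
  # Heads read the encoded sequence concatenated with the fused (projected)
  # input sequence and its time average — a residual readout that preserves
  # amplitude information through the LayerNorm bottleneck and offers a
  # measurement-noise-pooled static profile. The mean head is time-varying:
  # a per-step bias bt plus a rank-1 interaction score * gshape, where the
  # patient-level score modulates a learned growth profile; the variance
  # head carries a per-step bias bst.
  dh <- 3L * cfg$model_dim
  ramp <- seq_len(n_steps) - 1
  ramp <- (ramp - mean(ramp)) / max(stats::sd(ramp), 1)
  heads <- with_seed(derive_seed(cfg$seed, "heads"), list(
    wm = stats::rnorm(dh, sd = 0.01), bm = mean_bias, bt = numeric(n_steps),
    wg = stats::rnorm(dh, sd = 0.01), gshape = ramp,
    ws = stats::rnorm(dh, sd = 0.01), bs = var_bias_raw,
    bst = numeric(n_steps),
    wy = stats::rnorm(dh, sd = 0.01), by = mean_bias))
  trunks <- list(init_trunk_params(in_dim, cfg))
  if (!cfg$shared_trunk) {
    cfg2 <- cfg
    cfg2$seed <- derive_seed(cfg$seed, "trunk2")
    trunks[[2L]] <- init_trunk_params(in_dim, cfg2)
  }
  list(trunks = trunks, heads = heads)
}

trunk_forward <- function(z0s, tp, cfg, posenc, train = FALSE) {
  T_ <- nrow(z0s)
  Z <- z0s %*% tp$Wp + matrix(tp$bp, T_, cfg$model_dim, byrow = TRUE)
  if (cfg$positional) Z <- Z + posenc
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    w <- tp$layers[[l]]
    att <- attention_forward(Z, w, cfg$n_heads, cfg$key_dim)
    A <- att$output
    amask <- NULL
    if (train && cfg$dropout > 0) {
      amask <- matrix(stats::rbinom(length(A), 1L, 1 - cfg$dropout), nrow(A)) /
        (1 - cfg$dropout)
      A <- A * amask
    }
    blk <- ffn_ln_forward(A, w, dropout = if (train) cfg$dropout else 0, train = train)
    caches[[l]] <- list(Z = Z, att = att, amask = amask, A = A, blk = blk)
    Z <- blk$out
  }
  list(E = Z, caches = caches)
}

trunk_backward <- function(dE, fwd, z0s, tp, cfg) {
  g <- list(Wp = NULL, bp = NULL, layers = vector("list", cfg$n_layers))
  for (l in rev(seq_len(cfg$n_layers))) {
    ca <- fwd$caches[[l]]
    w <- tp$layers[[l]]
    fb <- ffn_ln_backward(dE, ca$blk, ca$A, w)
    dA <- fb$dA
    if (!is.null(ca$amask)) dA <- dA * ca$amask
    ab <- attention_backward(dA, ca$att, ca$Z, w, cfg$n_heads, cfg$key_dim)
    g$layers[[l]] <- list(Wq = ab$gWq, Wk = ab$gWk, Wv = ab$gWv, Wo = ab$gWo,
                          bo = ab$gbo, W1 = fb$gW1, b1 = fb$gb1, W2 = fb$gW2,
                          b2 = fb$gb2, gamma = fb$dgamma, beta = fb$dbeta)
    dE <- ab$dz
  }
  g$Wp <- crossprod(z0s, dE)
  g$bp <- colSums(dE)
  g
}

# Forward pass for one patient from standardized kernel rows to predictive
# paths. Returns everything backward needs. The head input per trunk is
# [E ; Z'] where Z' is the fused input sequence entering layer 1.
model_forward <- function(z0s, params, cfg, posenc, train = FALSE) {
  f1 <- trunk_forward(z0s, params$trunks[[1L]], cfg, posenc, train)
  f2 <- if (cfg$shared_trunk) f1 else trunk_forward(z0s, params$trunks[[2L]], cfg, posenc, train)
  h <- params$heads
  head_input <- function(f) {
    Z <- f$caches[[1L]]$Z
    cbind(f$E, Z, matrix(colMeans(Z), nrow(Z), ncol(Z), byrow = TRUE))
  }
  H1 <- head_input(f1)
  H2 <- if (cfg$shared_trunk) H1 else head_input(f2)
  pool <- colMeans(H1)
  # patient-level risk score: time-pooled readout modulating the growth
  # profile gshape (pooling denoises hour-to-hour measurement noise)
  score <- sum(pool * h$wg)
  s_raw <- drop(H2 %*% h$ws) + h$bs + h$bst
  variance <- softplus(s_raw) + cfg$var_floor
  list(f1 = f1, f2 = f2, H1 = H1, H2 = H2, score = score,
       mean = drop(H1 %*% h$wm) + h$bm + h$bt + score * h$gshape,
       s_raw = s_raw,
       variance = variance,
       ypred = sum(pool * h$wy) + h$by,
       pool = pool)
}

# Loss for one patient: Gaussian NLL over observed grid points plus a
# weighted squared error on the point prediction (target: last observed
# volume). obs_idx indexes the grid; v_obs are the observed volumes.
patient_loss_grad <- function(fw, obs_idx, v_obs, cfg) {
  m <- fw$mean[obs_idx]
  va <- fw$variance[obs_idx]
  dens <- stats::dnorm(v_obs, m, sqrt(va))
  nll <- -sum(log(dens + cfg$delta))
  gdens <- -1 / (dens + cfg$delta)
  resid <- v_obs - m
  d_m <- gdens * dens * resid / va
  d_va <- gdens * dens * (resid^2 / va - 1) / (2 * va)
  T_ <- length(fw$mean)
  dmean <- numeric(T_); dmean[obs_idx] <- d_m
  dvar <- numeric(T_); dvar[obs_idx] <- d_va
  ds_raw <- dvar * stats::plogis(fw$s_raw)
  target <- v_obs[length(v_obs)]
  perr <- fw$ypred - target
  point_loss <- cfg$point_weight * perr^2
  dypred <- 2 * cfg$point_weight * perr
  list(loss = nll + point_loss, nll = nll, dmean = dmean, ds_raw = ds_raw,
       dypred = dypred)
}

model_backward <- function(fw, lg, z0s, params, cfg) {
  h <- params$heads
  dm <- cfg$model_dim
  T_ <- nrow(fw$H1)
  dscore <- sum(lg$dmean * h$gshape)
  gh <- list(wm = drop(crossprod(fw$H1, lg$dmean)), bm = sum(lg$dmean),
             bt = lg$dmean,
             wg = dscore * fw$pool, gshape = lg$dmean * fw$score,
             ws = drop(crossprod(fw$H2, lg$ds_raw)), bs = sum(lg$ds_raw),
             bst = lg$ds_raw,
             wy = lg$dypred * fw$pool, by = lg$dypred)
  dH1 <- tcrossprod(lg$dmean, h$wm) +
    matrix(h$wg, T_, length(h$wg), byrow = TRUE) * (dscore / T_) +
    matrix(h$wy, T_, length(h$wy), byrow = TRUE) * (lg$dypred / T_)
  dH2 <- tcrossprod(lg$ds_raw, h$ws)
  split_h <- function(dH) {
    dZpool <- dH[, 2L * dm + seq_len(dm), drop = FALSE]
    list(dE = dH[, seq_len(dm), drop = FALSE],
         dZ = dH[, dm + seq_len(dm), drop = FALSE] +
           matrix(colSums(dZpool) / T_, T_, dm, byrow = TRUE))
  }
  s1 <- split_h(dH1)
  s2 <- split_h(dH2)
  add_direct <- function(g, dZ) {
    g$Wp <- g$Wp + crossprod(z0s, dZ)
    g$bp <- g$bp + colSums(dZ)
    g
  }
  if (cfg$shared_trunk) {
    gt <- trunk_backward(s1$dE + s2$dE, fw$f1, z0s, params$trunks[[1L]], cfg)
    gt <- list(add_direct(gt, s1$dZ + s2$dZ))
  } else {
    g1 <- add_direct(trunk_backward(s1$dE, fw$f1, z0s, params$trunks[[1L]], cfg),
                     s1$dZ)
    g2 <- add_direct(trunk_backward(s2$dE, fw$f2, z0s, params$trunks[[2L]], cfg),
                     s2$dZ)
    gt <- list(g1, g2)
  }
  list(trunks = gt, heads = gh)
}

# --- flat parameter vector utilities (for optimizers and gradient checks) ---

flatten_params <- function(p) unlist(p, use.names = FALSE)

relist_params <- function(v, skeleton) {
  stopifnot(length(v) == length(flatten_params(skeleton)))
  utils::relist(v, skeleton)
}

make_optimizer <- function(cfg, n_par) {
  state <- new.env(parent = emptyenv())
  state$m <- numeric(n_par)
  state$v <- numeric(n_par)
  state$t <- 0L
  function(theta, grad) {
    lr <- cfg$learning_rate
    # decoupled weight decay (no-op at the default weight_decay = 0)
    if (cfg$weight_decay > 0) theta <- theta * (1 - lr * cfg$weight_decay)
    switch(cfg$optimizer,
      sgd = theta - lr * grad,
      momentum = {
        state$m <- cfg$momentum * state$m + grad
        theta - lr * state$m
      },
      adam = {
        state$t <- state$t + 1L
        state$m <- 0.9 * state$m + 0.1 * grad
        state$v <- 0.999 * state$v + 0.001 * grad^2
        mhat <- state$m / (1 - 0.9^state$t)
        vhat <- state$v / (1 - 0.999^state$t)
        theta - lr * mhat / (sqrt(vhat) + 1e-8)
      },
      stop("unknown optimizer", call. = FALSE))
  }
}
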