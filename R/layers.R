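# Building blocks of the multi-scale kernel transformer: embedding,
# multi-head self-attention, encoder block, prediction and GP heads, and the
# Gaussian observation likelihood. Each block is exposed as a standalone
# function taking explicit weights so it can be probed and unit-tested; the
# fitting routine composes the same primitives.

#' Embed a feature sequence into a higher-dimensional space
#'
#' Per-time-step affine map from d to `out_dim` dimensions. With `weights =
#' NULL` a seeded Gaussian weight matrix is drawn (and the map is therefore
#' deterministic given `seed`); the fitting routine uses such a frozen random
#' embedding as the input to the kernel bank.
#'
#' @param x numeric T x d matrix (rows are time steps), finite.
#' @param out_dim output dimension d' (>= 1).
#' @param weights optional list with `W` (d x out_dim) and `b` (length
#'   out_dim).
#' @param seed seed for the default weights.
#' @return T x out_dim matrix.
#' @export
embed_sequence <- function(x, out_dim, weights = NULL, seed = 1L) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("`x` must be finite", call. = FALSE)
  out_dim <- as.integer(out_dim)
  if (out_dim < 1) stop("`out_dim` must be >= 1", call. = FALSE)
  if (is.null(weights)) weights <- init_embed_weights(ncol(x), out_dim, seed)
  x %*% weights$W + matrix(weights$b, nrow(x), out_dim, byrow = TRUE)
}

init_embed_weights <- function(d, out_dim, seed) {
  with_seed(seed, list(
    W = matrix(stats::rnorm(d * out_dim, sd = 1 / sqrt(d)), d, out_dim),
    b = numeric(out_dim)))
}

softmax_rows <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# Core attention pass with full cache (used by both the exported op and the
# training engine). `w` holds Wq, Wk, Wv (dm x H*dk), Wo (H*dk x dm), bo.
attention_forward <- function(z, w, n_heads, key_dim) {
  Q <- z %*% w$Wq
  K <- z %*% w$Wk
  V <- z %*% w$Wv
  T_ <- nrow(z)
  P <- vector("list", n_heads)
  Ocat <- matrix(0, T_, n_heads * key_dim)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * key_dim + 1L):(h * key_dim)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(key_dim)
    P[[h]] <- softmax_rows(S)
    Ocat[, idx] <- P[[h]] %*% V[, idx, drop = FALSE]
  }
  out <- Ocat %*% w$Wo + matrix(w$bo, T_, ncol(w$Wo), byrow = TRUE)
  list(Q = Q, K = K, V = V, P = P, Ocat = Ocat, output = out)
}

attention_backward <- function(dout, cache, z, w, n_heads, key_dim) {
  gWo <- crossprod(cache$Ocat, dout)
  gbo <- colSums(dout)
  dOcat <- dout %*% t(w$Wo)
  dQ <- matrix(0, nrow(z), n_heads * key_dim)
  dK <- dQ
  dV <- dQ
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * key_dim + 1L):(h * key_dim)
    P <- cache$P[[h]]
    dO <- dOcat[, idx, drop = FALSE]
    dP <- tcrossprod(dO, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(P, dO)
    dS <- P * (dP - rowSums(dP * P))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(key_dim)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(key_dim)
  }
  list(gWq = crossprod(z, dQ), gWk = crossprod(z, dK), gWv = crossprod(z, dV),
       gWo = gWo, gbo = gbo,
       dz = dQ %*% t(w$Wq) + dK %*% t(w$Wk) + dV %*% t(w$Wv))
}

#' Multi-head self-attention
#'
#' Per head h, `A_h = softmax(Q_h K_h' / sqrt(d_k)) V_h`; head outputs are
#' concatenated and affinely mixed. Every attention-weight row sums to 1.
#'
#' @param x numeric T x d'' input sequence.
#' @param n_heads number of heads H; `ncol(x)` must be divisible by H when
#'   `key_dim` is not given.
#' @param key_dim per-head key dimension d_k (default `ncol(x) / n_heads`).
#' @param weights optional list with `Wq`, `Wk`, `Wv` (d'' x H*d_k), `Wo`
#'   (H*d_k x d'') and `bo` (length d'').
#' @param seed seed for default weights.
#' @return list with `output` (T x d'') and `attention` (list of H row-
#'   stochastic T x T matrices).
#' @export
multi_head_attention <- function(x, n_heads = 4L, key_dim = NULL,
                                 weights = NULL, seed = 1L) {
  x <- as.matrix(x)
  dm <- ncol(x)
  n_heads <- as.integer(n_heads)
  if (is.null(key_dim)) {
    if (dm %% n_heads != 0L) {
      stop("`ncol(x)` must be divisible by `n_heads` when key_dim is not given",
           call. = FALSE)
    }
    key_dim <- dm %/% n_heads
  }
  key_dim <- as.integer(key_dim)
  if (is.null(weights)) weights <- init_attention_weights(dm, n_heads, key_dim, seed)
  if (ncol(weights$Wq) != n_heads * key_dim || nrow(weights$Wq) != dm) {
    stop("attention weight dimensions do not match n_heads * key_dim", call. = FALSE)
  }
  f <- attention_forward(x, weights, n_heads, key_dim)
  list(output = f$output, attention = f$P)
}

init_attention_weights <- function(dm, n_heads, key_dim, seed) {
  hk <- n_heads * key_dim
  with_seed(seed, list(
    Wq = matrix(stats::rnorm(dm * hk, sd = 1 / sqrt(dm)), dm, hk),
    Wk = matrix(stats::rnorm(dm * hk, sd = 1 / sqrt(dm)), dm, hk),
    Wv = matrix(stats::rnorm(dm * hk, sd = 1 / sqrt(dm)), dm, hk),
    Wo = matrix(stats::rnorm(hk * dm, sd = 1 / sqrt(hk)), hk, dm),
    bo = numeric(dm)))
}

layernorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = sweep(xhat, 2L, gamma, "*") + matrix(beta, nrow(x), ncol(x), byrow = TRUE),
       xhat = xhat, inv = inv)
}

layernorm_backward <- function(dout, cache, gamma) {
  dxhat <- sweep(dout, 2L, gamma, "*")
  list(dx = cache$inv * (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)),
       dgamma = colSums(dout * cache$xhat),
       dbeta = colSums(dout))
}

ffn_ln_forward <- function(a, w, dropout = 0, train = FALSE) {
  T_ <- nrow(a)
  H1 <- a %*% w$W1 + matrix(w$b1, T_, length(w$b1), byrow = TRUE)
  H1r <- pmax(H1, 0)
  mask <- NULL
  H2 <- H1r
  if (train && dropout > 0) {
    mask <- matrix(stats::rbinom(length(H1r), 1L, 1 - dropout), nrow(H1r)) / (1 - dropout)
    H2 <- H1r * mask
  }
  FF <- H2 %*% w$W2 + matrix(w$b2, T_, length(w$b2), byrow = TRUE)
  R <- FF + a
  ln <- layernorm_forward(R, w$gamma, w$beta)
  list(H1 = H1, H2 = H2, mask = mask, R = R, ln = ln, out = ln$out)
}

ffn_ln_backward <- function(dE, cache, a, w) {
  lb <- layernorm_backward(dE, cache$ln, w$gamma)
  dR <- lb$dx
  gW2 <- crossprod(cache$H2, dR)
  gb2 <- colSums(dR)
  dH2 <- dR %*% t(w$W2)
  if (!is.null(cache$mask)) dH2 <- dH2 * cache$mask
  dH1 <- dH2 * (cache$H1 > 0)
  gW1 <- crossprod(a, dH1)
  gb1 <- colSums(dH1)
  dA <- dR + dH1 %*% t(w$W1)
  list(gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2,
       dgamma = lb$dgamma, dbeta = lb$dbeta, dA = dA)
}

#' Encoder block: feed-forward with residual and layer normalization
#'
#' Given the attended sequence A, computes `F = FFN(A)` (one hidden ReLU
#' layer) and `E = LayerNorm(F + A)`; the residual wraps the feed-forward
#' only. Dropout (on the ReLU activations) is active only in training mode.
#'
#' @param x numeric T x d'' attended sequence.
#' @param ffn_dim hidden width of the feed-forward network.
#' @param weights optional list with `W1`, `b1`, `W2`, `b2`, `gamma`, `beta`.
#' @param dropout dropout rate in \[0, 1).
#' @param train logical; dropout is applied only when `TRUE`.
#' @param seed seed for default weights.
#' @return T x d'' encoded matrix E.
#' @export
encoder_block <- function(x, ffn_dim = 4L * ncol(x), weights = NULL,
                          dropout = 0, train = FALSE, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(weights)) weights <- init_block_weights(ncol(x), as.integer(ffn_dim), seed)
  ffn_ln_forward(x, weights, dropout = dropout, train = train)$out
}

init_block_weights <- function(dm, ffn_dim, seed) {
  with_seed(seed, list(
    W1 = matrix(stats::rnorm(dm * ffn_dim, sd = sqrt(2 / dm)), dm, ffn_dim),
    b1 = numeric(ffn_dim),
    W2 = matrix(stats::rnorm(ffn_dim * dm, sd = sqrt(2 / ffn_dim)), ffn_dim, dm),
    b2 = numeric(dm),
    gamma = rep(1, dm),
    beta = numeric(dm)))
}

#' Point-prediction head
#'
#' Mean-pools the encoded sequence over time and maps it affinely to a
#' scalar point prediction.
#'
#' @param e numeric T x d'' encoded matrix.
#' @param weights list with `w` (length d'') and `b` (scalar).
#' @return scalar prediction.
#' @export
predict_head <- function(e, weights) {
  e <- as.matrix(e)
  sum(colMeans(e) * weights$w) + weights$b
}

#' GP parameterization head
#'
#' Two affine heads map each encoded time step to the predictive mean (ml)
#' and, through a softplus link plus a strictly positive floor, the
#' predictive variance (ml^2) of the volume process.
#'
#' @param e numeric T x d'' encoded matrix.
#' @param weights list with `wm`, `bm` (mean head) and `ws`, `bs` (variance
#'   head); each `w*` has length d'', each `b*` is scalar.
#' @param var_floor variance floor added after softplus (default 1e-6).
#' @param times optional time stamps (hours) attached to the prediction.
#' @param point_prediction optional scalar from [predict_head()].
#' @return object of class `gp_prediction` with `mean_path`,
#'   `variance_path` (>= var_floor), `point_prediction` and `times`.
#' @export
map_to_gp <- function(e, weights, var_floor = 1e-6, times = NULL,
                      point_prediction = NA_real_) {
  e <- as.matrix(e)
  mean_path <- drop(e %*% weights$wm) + weights$bm
  variance_path <- softplus(drop(e %*% weights$ws) + weights$bs) + var_floor
  gp_prediction(mean_path, variance_path, point_prediction = point_prediction,
                times = times)
}

#' Construct a GP prediction object
#'
#' @param mean_path per-time-step predictive means (ml).
#' @param variance_path per-time-step predictive variances (ml^2), > 0.
#' @param point_prediction scalar point prediction.
#' @param times optional time stamps (hours), same length as the paths.
#' @return object of class `gp_prediction`.
#' @export
gp_prediction <- function(mean_path, variance_path,
                          point_prediction = NA_real_, times = NULL) {
  mean_path <- as.numeric(mean_path)
  variance_path <- as.numeric(variance_path)
  if (length(mean_path) != length(variance_path)) {
    stop("mean and variance paths must have equal length", call. = FALSE)
  }
  if (any(variance_path <= 0)) stop("variance path must be strictly positive", call. = FALSE)
  if (!is.null(times) && length(times) != length(mean_path)) {
    stop("`times` must match the path length", call. = FALSE)
  }
  structure(list(mean_path = mean_path, variance_path = variance_path,
                 point_prediction = point_prediction, times = times),
            class = "gp_prediction")
}

#' @export
print.gp_prediction <- function(x, ...) {
  cat(sprintf("GP prediction over %d time steps: mean %.2f-%.2f ml, sd %.3f-%.3f ml",
              length(x$mean_path), min(x$mean_path), max(x$mean_path),
              min(sqrt(x$variance_path)), max(sqrt(x$variance_path))))
  if (!is.na(x$point_prediction)) cat(sprintf(", point %.2f ml", x$point_prediction))
  cat("\n")
  invisible(x)
}

#' Negative log-likelihood of volume observations
#'
#' For each observation (t_k, v_k) the Gaussian density of the predicted
#' distribution N(M(t_k), Sigma(t_k)) is evaluated, and the loss is
#' `-sum(log(density + delta))`. The stability constant `delta > 0` keeps
#' the loss finite even when a density underflows.
#'
#' @param observations data.frame with columns `time` (hours) and `volume`
#'   (ml), or a list of such pairs.
#' @param prediction a [gp_prediction()] carrying `times`.
#' @param delta stability constant (>= 0, default 1e-6).
#' @param tol matching tolerance between observation times and grid times.
#' @return scalar loss.
#' @export
negative_log_likelihood <- function(observations, prediction, delta = 1e-6,
                                    tol = 1e-6) {
  stopifnot(inherits(prediction, "gp_prediction"))
  check_number(delta, "delta", lower = 0)
  if (is.list(observations) && !is.data.frame(observations)) {
    observations <- data.frame(
      time = vapply(observations, function(o) o[[1L]], numeric(1)),
      volume = vapply(observations, function(o) o[[2L]], numeric(1)))
  }
  times <- prediction$times %||% (seq_along(prediction$mean_path) - 1)
  idx <- vapply(observations$time, function(t) {
    i <- which(abs(times - t) <= tol)
    if (length(i) != 1L) {
      stop(sprintf("observation time %g does not align with the prediction grid", t),
           call. = FALSE)
    }
    i
  }, integer(1))
  dens <- stats::dnorm(observations$volume,
                       mean = prediction$mean_path[idx],
                       sd = sqrt(prediction$variance_path[idx]))
  -sum(log(dens + delta))
}
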