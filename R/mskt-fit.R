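# Model fitting: the multi-scale kernel transformer non-stationary Gaussian
# process (MSKT-NSGP) estimator and its S3 methods.

#' Model and training configuration
#'
#' Architecture and optimization settings for [mskt_fit()]. Defaults are
#' desk-scale: d' = 32, d'' = 64, 4 heads of key dimension 16, two encoder
#' layers, feed-forward width 128, dropout 0.1.
#'
#' @param embed_dim embedding dimension d' of the (frozen) input embedding.
#' @param model_dim encoder width d''; must be divisible by `n_heads`.
#' @param n_heads number of attention heads H.
#' @param key_dim per-head key dimension d_k.
#' @param ffn_dim feed-forward hidden width.
#' @param n_layers number of encoder layers.
#' @param dropout dropout rate in \[0, 1), active only during training.
#' @param learning_rate step size eta (>= 0).
#' @param optimizer `"sgd"` (plain stochastic gradient descent, the
#'   default), `"momentum"` or `"adam"`.
#' @param momentum momentum coefficient (used by `optimizer = "momentum"`).
#' @param delta likelihood stability constant (>= 0).
#' @param batch_size minibatch size; `Inf` recovers full-batch descent.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience in epochs (must be <
#'   `max_epochs`); monitored quantity is the validation loss.
#' @param n_folds folds for [mskt_cv()] (>= 2).
#' @param validation_fraction fraction of training patients held out to
#'   monitor early stopping (0 disables the monitor).
#' @param point_weight weight of the squared-error loss on the point
#'   prediction, added to the Gaussian NLL (joint training).
#' @param weight_decay decoupled L2 weight decay applied by the optimizer
#'   (0 disables).
#' @param input_dropout training-time dropout rate on columns of the fused
#'   multi-scale input (a feature-level regularizer; 0 disables).
#' @param augment_sd SD of Gaussian noise added to the standardized fused
#'   input at every training presentation (data augmentation against
#'   patient-fingerprint memorization; 0 disables).
#' @param init_linear if TRUE (default), the direct linear pathway from the
#'   fused input to the mean head is initialized from a ridge regression of
#'   the standardized volumes on the fused inputs, and the variance bias to
#'   the ridge residual variance; gradient descent then refines from that
#'   solution instead of from scratch.
#' @param ridge_lambda per-observation ridge penalty of the warm start.
#' @param var_floor variance floor after the softplus link (ml^2).
#' @param positional add sinusoidal positional encoding (default TRUE).
#' @param shared_trunk if TRUE (default) mean and variance heads share one
#'   encoder trunk; if FALSE two independent trunks realize the
#'   separate-networks reading of the personalized mean/variance mappings.
#' @param seed integer seed controlling initialization, data shuffling and
#'   dropout.
#' @return object of class `mskt_config`.
#' @export
mskt_config <- function(embed_dim = 32L, model_dim = 64L, n_heads = 4L,
                        key_dim = 16L, ffn_dim = 128L, n_layers = 2L,
                        dropout = 0.1, learning_rate = 0.01,
                        optimizer = c("sgd", "momentum", "adam"),
                        momentum = 0.9, delta = 1e-6, batch_size = 32L,
                        max_epochs = 100L, patience = 5L, n_folds = 10L,
                        validation_fraction = 0.15, point_weight = 1,
                        weight_decay = 0, input_dropout = 0, augment_sd = 0,
                        init_linear = TRUE, ridge_lambda = 5e-4,
                        var_floor = 1e-6, positional = TRUE,
                        shared_trunk = TRUE, seed = 1L) {
  cfg <- list(embed_dim = as.integer(embed_dim), model_dim = as.integer(model_dim),
              n_heads = as.integer(n_heads), key_dim = as.integer(key_dim),
              ffn_dim = as.integer(ffn_dim), n_layers = as.integer(n_layers),
              dropout = dropout, learning_rate = learning_rate,
              optimizer = match.arg(optimizer), momentum = momentum,
              delta = delta, batch_size = batch_size,
              max_epochs = as.integer(max_epochs), patience = as.integer(patience),
              n_folds = as.integer(n_folds),
              validation_fraction = validation_fraction,
              point_weight = point_weight, weight_decay = weight_decay,
              input_dropout = input_dropout, augment_sd = augment_sd,
              init_linear = isTRUE(init_linear), ridge_lambda = ridge_lambda,
              var_floor = var_floor,
              positional = isTRUE(positional), shared_trunk = isTRUE(shared_trunk),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(embed_dim >= 1, model_dim >= 1, n_heads >= 1, key_dim >= 1,
              ffn_dim >= 1, n_layers >= 1)
    if (model_dim %% n_heads != 0L) stop("`model_dim` must be divisible by `n_heads`", call. = FALSE)
    if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)", call. = FALSE)
    if (input_dropout < 0 || input_dropout >= 1) {
      stop("`input_dropout` must be in [0, 1)", call. = FALSE)
    }
    if (weight_decay < 0) stop("`weight_decay` must be >= 0", call. = FALSE)
    if (augment_sd < 0) stop("`augment_sd` must be >= 0", call. = FALSE)
    if (learning_rate < 0) stop("`learning_rate` must be >= 0", call. = FALSE)
    if (delta < 0) stop("`delta` must be >= 0", call. = FALSE)
    if (patience >= max_epochs) stop("`patience` must be < `max_epochs`", call. = FALSE)
    if (n_folds < 2L) stop("`n_folds` must be >= 2", call. = FALSE)
    if (validation_fraction < 0 || validation_fraction >= 1) {
      stop("`validation_fraction` must be in [0, 1)", call. = FALSE)
    }
  })
  structure(cfg, class = "mskt_config")
}

#' Assemble model-ready sequence data
#'
#' Bundles per-patient feature matrices (T x d, fully observed and finite —
#' the preprocessing contract), the volume observations used as the
#' likelihood targets (NA where unobserved), baseline volumes and the common
#' hourly time grid.
#'
#' @param features list of n numeric T x d matrices with identical
#'   dimensions and column names.
#' @param volumes numeric n x T matrix of observed hematoma volumes (ml);
#'   NA marks hours without an observation. Each patient needs >= 1
#'   observation.
#' @param v0 numeric vector of n baseline volumes (ml).
#' @param times numeric vector of T time stamps (hours), strictly
#'   increasing and uniformly spaced.
#' @param labels optional binary expansion labels (used by evaluation).
#' @param subject_ids optional identifiers.
#' @return object of class `mskt_data`.
#' @export
mskt_data <- function(features, volumes, v0, times, labels = NULL,
                      subject_ids = NULL) {
  stopifnot(is.list(features), length(features) >= 1L)
  features <- lapply(features, as.matrix)
  T_ <- nrow(features[[1L]])
  d <- ncol(features[[1L]])
  if (T_ < 2L) stop("sequences must have at least 2 time steps", call. = FALSE)
  ok <- vapply(features, function(m) {
    nrow(m) == T_ && ncol(m) == d && all(is.finite(m))
  }, logical(1))
  if (!all(ok)) stop("all feature matrices must be finite with identical T x d shape", call. = FALSE)
  volumes <- as.matrix(volumes)
  n <- length(features)
  if (nrow(volumes) != n || ncol(volumes) != T_) {
    stop("`volumes` must be an n x T matrix", call. = FALSE)
  }
  if (any(rowSums(!is.na(volumes)) == 0L)) {
    stop("every patient needs at least one observed volume", call. = FALSE)
  }
  if (length(v0) != n || any(!is.finite(v0)) || any(v0 < 0)) {
    stop("`v0` must be n finite non-negative baseline volumes", call. = FALSE)
  }
  times <- as.numeric(times)
  if (length(times) != T_ || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing with length T", call. = FALSE)
  }
  if (T_ > 2L && max(abs(diff(diff(times)))) > 1e-8) {
    stop("`times` must be uniformly spaced", call. = FALSE)
  }
  structure(list(features = features, volumes = volumes, v0 = as.numeric(v0),
                 times = times, labels = labels,
                 subject_ids = subject_ids %||% seq_len(n)),
            class = "mskt_data")
}

#' @export
print.mskt_data <- function(x, ...) {
  cat(sprintf("mskt_data: %d patients, %d time steps, %d features\n",
              length(x$features), length(x$times), ncol(x$features[[1L]])))
  invisible(x)
}

std_apply <- function(m, center, scale) sweep(sweep(m, 2L, center), 2L, scale, "/")

# Fusion input for one patient: per-time-step concatenation of the N kernel
# similarity profiles (rows of the Gram matrices) with the embedded features
# of that time step (a skip connection around the kernel layer; Gram entries
# are quadratic in the embeddings and alone attenuate patient-level feature
# levels). Columns are standardized with statistics frozen at fit time.
build_z0 <- function(x, model, standardize = TRUE) {
  xs <- std_apply(x, model$x_center, model$x_scale)
  xe <- xs %*% model$embed_weights$W +
    matrix(model$embed_weights$b, nrow(xs), ncol(model$embed_weights$W), byrow = TRUE)
  z0 <- cbind(do.call(cbind, lapply(model$kernel_specs,
                                    function(s) compute_kernel(xe, s))), xe)
  if (standardize) std_apply(z0, model$z0_center, model$z0_scale) else z0
}

#' Fit the multi-scale kernel transformer non-stationary GP model
#'
#' Trains the full architecture — frozen random embedding, multi-scale
#' kernel Gram bank, affine fusion with positional encoding, transformer
#' encoder, and mean/variance/point heads — by minibatch gradient descent on
#' the Gaussian negative log-likelihood of the observed volume trajectories
#' (plus a weighted squared error on the point prediction). A held-out
#' fraction of patients monitors the validation loss for early stopping; the
#' parameters from the best validation epoch are kept. The run is fully
#' reproducible under `config$seed`.
#'
#' @param data an [mskt_data()] object.
#' @param config an [mskt_config()].
#' @param kernels list of [kernel_spec()]s; `NULL` lengthscales are resolved
#'   once by the median pairwise-distance heuristic on the training
#'   embeddings and frozen.
#' @param verbose print per-epoch losses.
#' @return an object of class `mskt` with, among others, elements `params`
#'   (best weights), `history` (per-epoch losses), `kernel_specs` (resolved)
#'   and the frozen standardization statistics.
#' @seealso [predict.mskt()], [predict_expansion_probability()], [mskt_cv()]
#' @export
mskt_fit <- function(data, config = mskt_config(), kernels = default_kernels(),
                     verbose = FALSE) {
  stopifnot(inherits(data, "mskt_data"), inherits(config, "mskt_config"))
  cfg <- config
  n <- length(data$features)
  T_ <- length(data$times)
  d <- ncol(data$features[[1L]])

  allx <- do.call(rbind, data$features)
  x_center <- colMeans(allx)
  x_scale <- pmax(apply(allx, 2L, stats::sd), 1e-8)
  embed_weights <- init_embed_weights(d, cfg$embed_dim, derive_seed(cfg$seed, "embed"))

  # Resolve kernel lengthscales once on (a sample of) the training embeddings.
  xs_sample <- std_apply(allx[seq(1L, nrow(allx), length.out = min(nrow(allx), 2000L)), ,
                              drop = FALSE], x_center, x_scale)
  emb_sample <- xs_sample %*% embed_weights$W +
    matrix(embed_weights$b, nrow(xs_sample), cfg$embed_dim, byrow = TRUE)
  specs <- lapply(kernels, resolve_lengthscale, x = emb_sample)

  model <- list(config = cfg, kernel_specs = specs, embed_weights = embed_weights,
                x_center = x_center, x_scale = x_scale)
  z0_raw <- lapply(data$features, function(x) build_z0(x, model, standardize = FALSE))
  z0_all <- do.call(rbind, z0_raw)
  model$z0_center <- colMeans(z0_all)
  model$z0_scale <- pmax(apply(z0_all, 2L, stats::sd), 1e-8)
  z0s <- lapply(z0_raw, std_apply, center = model$z0_center, scale = model$z0_scale)

  # Volumes are standardized internally so the heads work on a unit scale;
  # predictions are transformed back to ml. The training history is on the
  # standardized scale.
  all_v <- data$volumes[!is.na(data$volumes)]
  v_center <- mean(all_v)
  v_scale <- max(stats::sd(all_v), 1e-8)
  model$v_center <- v_center
  model$v_scale <- v_scale
  obs <- lapply(seq_len(n), function(j) {
    idx <- which(!is.na(data$volumes[j, ]))
    list(idx = idx, v = (data$volumes[j, idx] - v_center) / v_scale)
  })
  params <- init_params(ncol(z0s[[1L]]), cfg, n_steps = T_,
                        mean_bias = 0, var_bias_raw = softplus_inv(1))
  posenc <- positional_encoding(T_, cfg$model_dim)

  if (cfg$init_linear && cfg$model_dim >= 3L) {
    # Warm-start the direct pathway with a ridge regression of the
    # standardized volumes on [fused inputs, fused inputs x time ramp,
    # per-step indicators]: the static block is written into the last
    # projection column (read by the mean head), the ramp-interaction block
    # into the second-to-last column (read by the time-varying-coefficient
    # head), the per-step coefficients into the mean head's time bias, and
    # the variance bias starts at the ridge residual variance. Gradient
    # descent refines from this solution instead of from scratch.
    X <- do.call(rbind, lapply(seq_len(n), function(j) {
      z0s[[j]][obs[[j]]$idx, , drop = FALSE]
    }))
    yv <- unlist(lapply(obs, `[[`, "v"))
    # empirical growth profile: per-step mean of the standardized volumes,
    # standardized; falls back to the generic ramp for flat profiles
    prof <- vapply(seq_len(T_), function(t) {
      mean(data$volumes[, t], na.rm = TRUE)
    }, numeric(1))
    prof[!is.finite(prof)] <- mean(prof, na.rm = TRUE)
    if (stats::sd(prof) > 1e-8) {
      params$heads$gshape <- (prof - mean(prof)) / stats::sd(prof)
    }
    ramp <- params$heads$gshape
    rv <- unlist(lapply(seq_len(n), function(j) ramp[obs[[j]]$idx]))
    tidx <- unlist(lapply(seq_len(n), function(j) obs[[j]]$idx))
    # the interaction block uses the patient's time-pooled profile, matching
    # the pooled-score head
    Xb <- do.call(rbind, lapply(seq_len(n), function(j) {
      matrix(colMeans(z0s[[j]]), length(obs[[j]]$idx), ncol(z0s[[j]]),
             byrow = TRUE)
    }))
    D <- matrix(0, nrow(X), T_)
    D[cbind(seq_len(nrow(X)), tidx)] <- 1
    XX <- cbind(X, Xb, Xb * rv, D)
    lam <- cfg$ridge_lambda * nrow(X)
    beta_all <- solve(crossprod(XX) + diag(lam, ncol(XX)),
                      crossprod(XX, yv - mean(yv)))
    p <- ncol(X)
    beta1 <- beta_all[seq_len(p)]             # per-step static readout
    beta1b <- beta_all[p + seq_len(p)]        # pooled static readout
    beta2 <- beta_all[2L * p + seq_len(p)]    # pooled growth score
    gam <- beta_all[3L * p + seq_len(T_)]     # per-step intercepts
    dm <- cfg$model_dim
    k1 <- dm
    k2 <- dm - 1L
    k3 <- dm - 2L
    params$trunks[[1L]]$Wp[, k1] <- beta1
    params$trunks[[1L]]$Wp[, k2] <- beta2
    params$trunks[[1L]]$Wp[, k3] <- beta1b
    params$heads$wm[] <- 0
    params$heads$wm[dm + k1] <- 1
    params$heads$wm[2L * dm + k3] <- 1
    params$heads$wg[] <- 0
    params$heads$wg[dm + k2] <- 1
    pe1 <- if (cfg$positional) posenc[, k1] else 0
    pe2 <- if (cfg$positional) mean(posenc[, k2]) else 0
    pe3 <- if (cfg$positional) mean(posenc[, k3]) else 0
    params$heads$bm <- mean(yv) - pe3
    params$heads$bt <- gam - pe1 - pe2 * ramp
    resid <- yv - mean(yv) - drop(XX %*% beta_all)
    params$heads$bs <- softplus_inv(max(stats::var(resid), 0.05))
    params$heads$by <- mean(yv)
  }

  val_idx <- integer(0)
  if (cfg$validation_fraction > 0 && n >= 5L) {
    val_idx <- with_seed(derive_seed(cfg$seed, "valsplit"),
                         sort(sample.int(n, max(1L, round(cfg$validation_fraction * n)))))
  }
  train_idx <- setdiff(seq_len(n), val_idx)

  eval_loss <- function(p, idx) {
    tot <- 0
    for (j in idx) {
      fw <- model_forward(z0s[[j]], p, cfg, posenc, train = FALSE)
      tot <- tot + patient_loss_grad(fw, obs[[j]]$idx, obs[[j]]$v, cfg)$loss
    }
    tot / length(idx)
  }

  skeleton <- params
  theta <- flatten_params(params)
  opt <- make_optimizer(cfg, length(theta))
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  bs <- if (is.finite(cfg$batch_size)) max(1L, as.integer(cfg$batch_size)) else length(train_idx)

  with_seed(derive_seed(cfg$seed, "train"), {
    wait <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(train_idx)
      ep_loss <- 0
      for (start in seq(1L, length(ord), by = bs)) {
        batch <- ord[start:min(start + bs - 1L, length(ord))]
        gsum <- 0
        for (j in batch) {
          zj <- z0s[[j]]
          if (cfg$augment_sd > 0) {
            zj <- zj + stats::rnorm(length(zj), sd = cfg$augment_sd)
          }
          if (cfg$input_dropout > 0) {
            keep <- stats::rbinom(ncol(zj), 1L, 1 - cfg$input_dropout) /
              (1 - cfg$input_dropout)
            zj <- zj * rep(keep, each = nrow(zj))
          }
          fw <- model_forward(zj, params, cfg, posenc, train = TRUE)
          lg <- patient_loss_grad(fw, obs[[j]]$idx, obs[[j]]$v, cfg)
          if (!is.finite(lg$loss)) {
            stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
                 call. = FALSE)
          }
          ep_loss <- ep_loss + lg$loss
          gsum <- gsum + flatten_params(model_backward(fw, lg, zj, params, cfg))
        }
        theta <- opt(theta, gsum / length(batch))
        params <- relist_params(theta, skeleton)
      }
      ep_loss <- ep_loss / length(train_idx)
      monitor <- if (length(val_idx)) eval_loss(params, val_idx) else ep_loss
      if (!is.finite(monitor)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
             call. = FALSE)
      }
      history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                           val_loss = monitor))
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, ep_loss, monitor))
      }
      if (monitor < best$loss - 1e-10) {
        best <- list(loss = monitor, theta = theta, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })

  params <- relist_params(best$theta, skeleton)
  model <- c(model, list(
    params = params, times = data$times, n_features = d,
    feature_names = colnames(data$features[[1L]]),
    history = history, best_epoch = best$epoch, n_patients = n,
    val_idx = val_idx, data = data, call = match.call()))
  class(model) <- "mskt"
  model
}

predict_paths <- function(model, features) {
  cfg <- model$config
  posenc <- positional_encoding(nrow(features[[1L]]), cfg$model_dim)
  lapply(features, function(x) {
    fw <- model_forward(build_z0(x, model), model$params, cfg, posenc, train = FALSE)
    gp_prediction(model$v_center + model$v_scale * fw$mean,
                  model$v_scale^2 * fw$variance,
                  point_prediction = model$v_center + model$v_scale * fw$ypred,
                  times = model$times)
  })
}

resolve_newdata <- function(object, newdata) {
  if (is.null(newdata)) return(object$data)
  if (inherits(newdata, "mskt_data")) return(newdata)
  if (is.list(newdata) && all(vapply(newdata, is.matrix, logical(1)))) {
    return(list(features = newdata, v0 = NULL, times = object$times))
  }
  stop("`newdata` must be an mskt_data object or a list of feature matrices",
       call. = FALSE)
}

#' Predict from a fitted MSKT model
#'
#' @param object a fitted [mskt_fit()] model.
#' @param newdata an [mskt_data()] object, a list of T x d feature matrices,
#'   or `NULL` for the training data.
#' @param type `"distribution"` (list of [gp_prediction()]s),
#'   `"mean"`/`"variance"` (n x T matrices), `"point"` (vector of point
#'   predictions), or `"probability"` (expansion probabilities P_j; requires
#'   baseline volumes, see [predict_expansion_probability()]).
#' @param horizon prediction window in hours for `type = "probability"`.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.mskt <- function(object, newdata = NULL,
                         type = c("distribution", "mean", "variance", "point",
                                  "probability"),
                         horizon = 24, ...) {
  type <- match.arg(type)
  nd <- resolve_newdata(object, newdata)
  if (type == "probability") {
    return(predict_expansion_probability(object, nd, horizon = horizon)$probability)
  }
  preds <- predict_paths(object, nd$features)
  switch(type,
    distribution = preds,
    mean = do.call(rbind, lapply(preds, `[[`, "mean_path")),
    variance = do.call(rbind, lapply(preds, `[[`, "variance_path")),
    point = vapply(preds, `[[`, numeric(1), "point_prediction"))
}

#' Predicted hematoma-expansion probability
#'
#' Composes the fitted model with the crossing framework: the per-patient
#' predictive distribution becomes a [volume_process()] on the grid points
#' inside the prediction window, the baseline volume defines the
#' [expansion_threshold()], and [crossing_probability()] yields P_j.
#'
#' @param object a fitted `mskt` model.
#' @param data an [mskt_data()] object carrying baseline volumes `v0`.
#' @param horizon prediction window T in hours (must cover a whole number of
#'   grid steps within the observed grid).
#' @return list with `prediction` (list of [gp_prediction()]),
#'   `crossing` (list of `crossing_result`) and `probability` (numeric P_j).
#' @export
predict_expansion_probability <- function(object, data = NULL, horizon = 24) {
  stopifnot(inherits(object, "mskt"))
  nd <- resolve_newdata(object, data)
  if (is.null(nd$v0)) stop("baseline volumes `v0` are required for expansion probabilities",
                           call. = FALSE)
  preds <- predict_paths(object, nd$features)
  times <- nd$times %||% object$times
  step <- times[2L] - times[1L]
  n_in <- round(horizon / step)
  if (abs(n_in - horizon / step) > 1e-8 || n_in < 1L || n_in > length(times)) {
    stop("`horizon` must cover a whole number of grid steps within the grid",
         call. = FALSE)
  }
  grid <- time_grid(horizon = horizon, n_points = n_in, t0 = times[1L])
  crossings <- lapply(seq_along(preds), function(j) {
    pr <- preds[[j]]
    proc <- volume_process(grid, pr$mean_path[seq_len(n_in)],
                           pr$variance_path[seq_len(n_in)])
    crossing_probability(proc, expansion_threshold(nd$v0[j]))
  })
  list(prediction = preds, crossing = crossings,
       probability = vapply(crossings, `[[`, numeric(1), "probability"))
}

#' @export
print.mskt <- function(x, ...) {
  cat("Multi-scale kernel transformer non-stationary GP model\n")
  cat(sprintf("  %d patients, %d time steps, %d features\n",
              x$n_patients, length(x$times), x$n_features))
  cat(sprintf("  kernels: %s\n",
              paste(vapply(x$kernel_specs, `[[`, character(1), "family"), collapse = ", ")))
  cat(sprintf("  encoder: %d layer(s), d''=%d, %d heads; %s optimizer\n",
              x$config$n_layers, x$config$model_dim, x$config$n_heads,
              x$config$optimizer))
  cat(sprintf("  trained %d epoch(s); best validation loss %.4f at epoch %d\n",
              nrow(x$history), min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' @export
summary.mskt <- function(object, ...) {
  np <- length(flatten_params(object$params))
  res <- residuals(object)
  out <- list(model = object, n_parameters = np,
              rmse = sqrt(mean(res^2, na.rm = TRUE)),
              mae = mean(abs(res), na.rm = TRUE),
              history = object$history)
  class(out) <- "summary.mskt"
  out
}

#' @export
print.summary.mskt <- function(x, ...) {
  print(x$model)
  cat(sprintf("  %d trainable parameters\n", x$n_parameters))
  cat(sprintf("  training-data volume fit: RMSE %.3f ml, MAE %.3f ml\n",
              x$rmse, x$mae))
  invisible(x)
}

#' @export
coef.mskt <- function(object, ...) {
  v <- unlist(object$params)
  attr(v, "n_parameters") <- length(v)
  v
}

#' @export
fitted.mskt <- function(object, ...) {
  predict(object, type = "mean")
}

#' @export
residuals.mskt <- function(object, ...) {
  object$data$volumes - fitted(object)
}

#' @export
logLik.mskt <- function(object, ...) {
  cfg <- object$config
  preds <- predict_paths(object, object$data$features)
  ll <- 0
  nobs <- 0L
  for (j in seq_along(preds)) {
    idx <- which(!is.na(object$data$volumes[j, ]))
    obs <- data.frame(time = object$times[idx], volume = object$data$volumes[j, idx])
    ll <- ll - negative_log_likelihood(obs, preds[[j]], delta = cfg$delta)
    nobs <- nobs + length(idx)
  }
  structure(ll, df = length(flatten_params(object$params)), nobs = nobs,
            class = "logLik")
}

#' Simulate volume trajectories from the fitted predictive distribution
#'
#' Draws `nsim` independent trajectories V(t_i) ~ N(M(t_i), Sigma(t_i)) per
#' patient.
#'
#' @param object a fitted `mskt` model.
#' @param nsim number of trajectories per patient.
#' @param seed integer seed.
#' @param newdata as in [predict.mskt()].
#' @param ... unused.
#' @return list of nsim x T matrices, one per patient.
#' @export
simulate.mskt <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  nd <- resolve_newdata(object, newdata)
  preds <- predict_paths(object, nd$features)
  draw <- function() {
    lapply(preds, function(p) {
      T_ <- length(p$mean_path)
      matrix(stats::rnorm(nsim * T_, mean = rep(p$mean_path, each = nsim),
                          sd = rep(sqrt(p$variance_path), each = nsim)),
             nrow = nsim)
    })
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' @export
plot.mskt <- function(x, which = c("history", "patient"), patient = 1L, ...) {
  which <- match.arg(which)
  if (which == "history") {
    h <- x$history
    graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                      lty = 1, col = c("grey40", "firebrick"),
                      xlab = "epoch", ylab = "loss", ...)
    graphics::legend("topright", c("training", "validation"), lty = 1,
                     col = c("grey40", "firebrick"), bty = "n")
  } else {
    p <- predict_paths(x, x$data$features[patient])[[1L]]
    sd <- sqrt(p$variance_path)
    lo <- p$mean_path - 1.96 * sd
    hi <- p$mean_path + 1.96 * sd
    obs <- x$data$volumes[patient, ]
    graphics::plot(x$times, p$mean_path, type = "n",
                   ylim = range(lo, hi, obs, na.rm = TRUE),
                   xlab = "hours since admission", ylab = "hematoma volume (ml)", ...)
    graphics::polygon(c(x$times, rev(x$times)), c(lo, rev(hi)),
                      col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
    graphics::lines(x$times, p$mean_path, col = "steelblue4", lwd = 2)
    graphics::points(x$times, obs, pch = 16, cex = 0.6)
  }
  invisible(x)
}

#' k-fold cross-validation for the MSKT model
#'
#' Subject-level k-fold partition; each fold is held out once while the
#' model is trained on the rest, and per-fold test metrics are reported.
#'
#' @param data an [mskt_data()] object.
#' @param config an [mskt_config()]; `config$n_folds` is used unless `k` is
#'   given.
#' @param k number of folds.
#' @param kernels kernel bank passed to [mskt_fit()].
#' @param horizon window for expansion probabilities (used for fold AUC when
#'   labels are present).
#' @return data.frame with one row per fold: `fold`, `n_test`, `nll`,
#'   `mse`, `mae` and `auc` (NA without labels).
#' @export
mskt_cv <- function(data, config = mskt_config(), k = config$n_folds,
                    kernels = default_kernels(), horizon = 24) {
  stopifnot(inherits(data, "mskt_data"))
  n <- length(data$features)
  if (k < 2L || k > n) stop("`k` must be between 2 and the number of patients", call. = FALSE)
  folds <- with_seed(derive_seed(config$seed, "cv"),
                     sample(rep_len(seq_len(k), n)))
  out <- lapply(seq_len(k), function(f) {
    te <- which(folds == f)
    tr <- which(folds != f)
    dtr <- mskt_data(data$features[tr], data$volumes[tr, , drop = FALSE],
                     data$v0[tr], data$times, labels = data$labels[tr],
                     subject_ids = data$subject_ids[tr])
    dte <- mskt_data(data$features[te], data$volumes[te, , drop = FALSE],
                     data$v0[te], data$times, labels = data$labels[te],
                     subject_ids = data$subject_ids[te])
    fit <- mskt_fit(dtr, config, kernels = kernels)
    preds <- predict_paths(fit, dte$features)
    nll <- mean(vapply(seq_along(preds), function(j) {
      idx <- which(!is.na(dte$volumes[j, ]))
      negative_log_likelihood(
        data.frame(time = dte$times[idx], volume = dte$volumes[j, idx]),
        preds[[j]], delta = config$delta)
    }, numeric(1)))
    mu <- do.call(rbind, lapply(preds, `[[`, "mean_path"))
    err <- regression_errors(mu[!is.na(dte$volumes)], dte$volumes[!is.na(dte$volumes)])
    auc <- NA_real_
    if (!is.null(dte$labels) && length(unique(dte$labels)) == 2L) {
      pj <- predict_expansion_probability(fit, dte, horizon = horizon)$probability
      auc <- roc_auc(pj, dte$labels)
    }
    data.frame(fold = f, n_test = length(te), nll = nll, mse = err$mse,
               mae = err$mae, auc = auc)
  })
  do.call(rbind, out)
}
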