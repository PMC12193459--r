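# Multi-scale kernel layer: Gram matrices over time-step embeddings.

#' Kernel specification
#'
#' Describes one member of the multi-scale kernel bank. Supported families:
#' `"linear"` (plain inner product), `"polynomial"` ((x.y + offset)^degree),
#' `"rbf"` (exp(-r^2 / (2 l^2))) and `"matern"` with smoothness nu in
#' \{0.5, 1.5, 2.5\}.
#'
#' A `NULL` lengthscale for rbf/matern means "resolve by the median pairwise
#' distance heuristic on the data the kernel is evaluated on" (the fitting
#' routine resolves it once on the training embeddings and freezes it).
#'
#' @param family one of `"linear"`, `"polynomial"`, `"rbf"`, `"matern"`.
#' @param degree polynomial degree (integer >= 1).
#' @param offset polynomial offset (>= 0).
#' @param lengthscale positive lengthscale for rbf/matern, or `NULL`.
#' @param smoothness Matern smoothness nu, one of 0.5, 1.5, 2.5.
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("linear", "polynomial", "rbf", "matern"),
                        degree = 2L, offset = 1, lengthscale = NULL,
                        smoothness = 1.5) {
  family <- match.arg(family)
  if (family == "polynomial") {
    if (!is.numeric(degree) || degree < 1 || degree != round(degree)) {
      stop("polynomial `degree` must be an integer >= 1", call. = FALSE)
    }
    check_number(offset, "offset", lower = 0)
  }
  if (family %in% c("rbf", "matern") && !is.null(lengthscale)) {
    check_number(lengthscale, "lengthscale", lower = .Machine$double.xmin)
  }
  if (family == "matern" && !smoothness %in% c(0.5, 1.5, 2.5)) {
    stop("matern `smoothness` must be one of 0.5, 1.5, 2.5", call. = FALSE)
  }
  structure(list(family = family, degree = as.integer(degree), offset = offset,
                 lengthscale = lengthscale, smoothness = smoothness),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  extra <- switch(x$family,
    polynomial = sprintf(" (degree %d, offset %g)", x$degree, x$offset),
    rbf = sprintf(" (lengthscale %s)", if (is.null(x$lengthscale)) "median heuristic" else format(x$lengthscale)),
    matern = sprintf(" (nu %g, lengthscale %s)", x$smoothness,
                     if (is.null(x$lengthscale)) "median heuristic" else format(x$lengthscale)),
    "")
  cat(sprintf("kernel: %s%s\n", x$family, extra))
  invisible(x)
}

#' Default multi-scale kernel bank
#'
#' Linear (linear relationships), polynomial degree 2 (low-order feature
#' interactions), RBF (smooth nonlinear similarity, noise and short-term
#' fluctuation), and Matern nu = 1.5 (rougher local variation).
#'
#' @return list of four [kernel_spec()] objects.
#' @export
default_kernels <- function() {
  list(kernel_spec("linear"),
       kernel_spec("polynomial", degree = 2L, offset = 1),
       kernel_spec("rbf"),
       kernel_spec("matern", smoothness = 1.5))
}

#' Median pairwise-distance lengthscale heuristic
#'
#' @param x numeric matrix (rows are points).
#' @param max_rows subsample cap for the distance computation.
#' @return positive scalar; 1 if all pairwise distances are zero.
#' @export
median_lengthscale <- function(x, max_rows = 500L) {
  x <- as.matrix(x)
  if (nrow(x) > max_rows) x <- x[seq(1L, nrow(x), length.out = max_rows), , drop = FALSE]
  d <- as.numeric(stats::dist(x))
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

resolve_lengthscale <- function(spec, x) {
  if (spec$family %in% c("rbf", "matern") && is.null(spec$lengthscale)) {
    spec$lengthscale <- median_lengthscale(x)
  }
  spec
}

#' Kernel Gram matrix over time steps
#'
#' Evaluates the kernel between every pair of rows of `x` (time-step
#' embeddings), returning the symmetric T x T Gram matrix.
#'
#' @param x numeric matrix T x d' of embedded time steps.
#' @param spec a [kernel_spec()].
#' @return symmetric T x T matrix. For rbf/matern the diagonal is 1 and all
#'   entries lie in (0, 1].
#' @export
compute_kernel <- function(x, spec) {
  if (!inherits(spec, "kernel_spec")) stop("`spec` must be a kernel_spec", call. = FALSE)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("`x` must be finite", call. = FALSE)
  g <- tcrossprod(x)
  K <- switch(spec$family,
    linear = g,
    polynomial = (g + spec$offset)^spec$degree,
    {
      spec <- resolve_lengthscale(spec, x)
      sq <- diag(g)
      r2 <- pmax(outer(sq, sq, "+") - 2 * g, 0)
      if (spec$family == "rbf") {
        exp(-r2 / (2 * spec$lengthscale^2))
      } else {
        r <- sqrt(r2) / spec$lengthscale
        switch(as.character(spec$smoothness),
          "0.5" = exp(-r),
          "1.5" = (1 + sqrt(3) * r) * exp(-sqrt(3) * r),
          "2.5" = (1 + sqrt(5) * r + 5 * r2 / (3 * spec$lengthscale^2)) * exp(-sqrt(5) * r))
      }
    })
  (K + t(K)) / 2
}

#' Stack a bank of kernel Gram matrices
#'
#' Computes one Gram matrix per spec and stacks them into the multi-scale
#' representation of shape N x T x T, preserving spec order.
#'
#' @param x numeric matrix T x d' of embedded time steps.
#' @param specs non-empty list of [kernel_spec()] objects.
#' @return object of class `kernel_stack`: list with `matrices` (list of
#'   T x T matrices) and `stacked` (array N x T x T).
#' @export
stack_kernels <- function(x, specs = default_kernels()) {
  if (inherits(specs, "kernel_spec")) specs <- list(specs)
  if (!is.list(specs) || length(specs) == 0L) {
    stop("`specs` must be a non-empty list of kernel_spec objects", call. = FALSE)
  }
  mats <- lapply(specs, function(s) compute_kernel(x, s))
  T_ <- nrow(mats[[1L]])
  stacked <- array(0, dim = c(length(mats), T_, T_))
  for (i in seq_along(mats)) stacked[i, , ] <- mats[[i]]
  structure(list(matrices = mats, stacked = stacked, specs = specs),
            class = "kernel_stack")
}

# Row-major fusion of a kernel stack: row t of the output is the
# concatenation over kernels of row t of each Gram matrix (length N * T).
stack_to_rows <- function(stack) {
  mats <- stack$matrices
  do.call(cbind, mats)
}

#' Sinusoidal positional encoding
#'
#' @param n_steps number of time steps.
#' @param dim encoding dimension.
#' @return n_steps x dim matrix of interleaved sin/cos codes.
#' @export
positional_encoding <- function(n_steps, dim) {
  pos <- seq_len(n_steps) - 1L
  pe <- matrix(0, n_steps, dim)
  for (j in seq_len(dim)) {
    k <- (j - 1L) %/% 2L
    angle <- pos / 10000^(2 * k / dim)
    pe[, j] <- if (j %% 2L == 1L) sin(angle) else cos(angle)
  }
  pe
}

#' Fuse a kernel stack into an encoder input sequence
#'
#' For each time step t the rows of all N Gram matrices indexed by t are
#' concatenated into a length N*T multi-scale similarity profile, affinely
#' projected to `model_dim`, and sinusoidal positional encoding is added
#' (the encoder is otherwise permutation-equivariant).
#'
#' @param stack a [stack_kernels()] result.
#' @param model_dim output dimension d'' (> 0).
#' @param weights optional list with `W` (N*T x model_dim) and `b`
#'   (length model_dim); defaults to a seeded Gaussian initialization.
#' @param positional logical; add positional encoding (default TRUE).
#' @param seed seed for the default weights.
#' @return T x model_dim matrix.
#' @export
kernels_to_sequence <- function(stack, model_dim, weights = NULL,
                                positional = TRUE, seed = 1L) {
  if (!inherits(stack, "kernel_stack")) stop("`stack` must be a kernel_stack", call. = FALSE)
  if (!is.numeric(model_dim) || model_dim < 1) stop("`model_dim` must be positive", call. = FALSE)
  model_dim <- as.integer(model_dim)
  Z0 <- stack_to_rows(stack)
  if (is.null(weights)) {
    weights <- with_seed(seed, list(
      W = matrix(stats::rnorm(ncol(Z0) * model_dim, sd = 1 / sqrt(ncol(Z0))),
                 ncol(Z0), model_dim),
      b = numeric(model_dim)))
  }
  Z <- Z0 %*% weights$W + matrix(weights$b, nrow(Z0), model_dim, byrow = TRUE)
  if (positional) Z <- Z + positional_encoding(nrow(Z0), model_dim)
  Z
}
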