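# Shared fixtures, all built in code.

# Volume process with constant exceedance probability `beta` at every grid
# point: mean = c + sd * qnorm(beta).
const_hazard_process <- function(beta, horizon, n_points, threshold = 30,
                                 sd = 1) {
  g <- time_grid(horizon = horizon, n_points = n_points)
  mu <- threshold + sd * qnorm(beta)
  volume_process(g, mean = rep(mu, n_points), variance = rep(sd^2, n_points))
}

# Tiny desk-model configuration for fast fitting tests.
tiny_config <- function(...) {
  defaults <- list(embed_dim = 6, model_dim = 8, n_heads = 2, key_dim = 4,
                   ffn_dim = 12, n_layers = 1, dropout = 0, batch_size = 16,
                   max_epochs = 3, patience = 2, validation_fraction = 0.2,
                   optimizer = "adam", learning_rate = 3e-3, seed = 42)
  do.call(mskt_config, utils::modifyList(defaults, list(...)))
}

# Small synthetic cohort shared across model-level tests (cached per session).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(cohort_spec(n_patients = 50, duration = 24,
                                            horizon = 12, seed = 99))
    }
    cache
  }
})

# Minimal hand-built mskt_data: mean volume depends linearly on one feature.
toy_mskt_data <- function(n = 20, T_ = 8, seed = 1) {
  set.seed(seed)
  feats <- lapply(seq_len(n), function(j) {
    m <- matrix(rnorm(T_ * 3), T_, 3)
    colnames(m) <- c("f1", "f2", "f3")
    m
  })
  v0 <- runif(n, 5, 30)
  vols <- t(vapply(seq_len(n), function(j) {
    v0[j] + cumsum(rep(0.3, T_)) + rnorm(T_, sd = 0.5)
  }, numeric(T_)))
  mskt_data(feats, vols, v0, times = 0:(T_ - 1))
}
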