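# Independent oracles for the weighted Cox partial likelihood, written from
# the explicit product form and kept free of the package's solver internals.

# Weighted log partial likelihood, Breslow risk sets, computed literally:
# sum over events of w_i * (eta_i - log sum_{j: t_j >= t_i} w_j exp(eta_j)).
oracle_logpl <- function(beta, X, time, event, w = rep(1, length(time))) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  sum(vapply(which(event == 1), function(i) {
    risk <- time >= time[i]
    w[i] * (eta[i] - log(sum(w[risk] * exp(eta[risk]))))
  }, numeric(1)))
}

# One-dimensional grid-search maximizer: coarse grid then a fine grid around
# the best point. Resolution of the final grid is 1e-6.
oracle_grid_fit_1d <- function(X, time, event, w = rep(1, length(time)),
                               lower = -3, upper = 3) {
  eval_grid <- function(grid) {
    vapply(grid, function(b) oracle_logpl(b, X, time, event, w), numeric(1))
  }
  coarse <- seq(lower, upper, by = 0.01)
  b0 <- coarse[which.max(eval_grid(coarse))]
  fine <- seq(b0 - 0.01, b0 + 0.01, by = 1e-6)
  fine[which.max(eval_grid(fine))]
}

# Multi-dimensional maximizer of the literal partial likelihood via
# derivative-free Nelder-Mead (independent of the package's Newton path).
oracle_optim_fit <- function(X, time, event, w = rep(1, length(time))) {
  X <- as.matrix(X)
  opt <- stats::optim(
    rep(0, ncol(X)),
    function(b) -oracle_logpl(b, X, time, event, w),
    method = "Nelder-Mead",
    control = list(maxit = 5000, reltol = 1e-14)
  )
  opt$par
}

# The closed-form toy instance: subjects (t=1, d=1, x=1), (t=2, d=1, x=0),
# (t=3, d=0, x=1); the score root is beta = -log(2)/2.
toy_cox_instance <- function() {
  list(X = matrix(c(1, 0, 1), ncol = 1, dimnames = list(NULL, "x")),
       time = c(1, 2, 3), event = c(1L, 1L, 0L))
}

# Paper-scale stratified allocation used throughout the study.
study_allocation <- function() {
  c(professionals = 3000, technicians = 4500, administrative = 7500)
}

# Random small survival instance with distinct times (for solver-vs-oracle
# parity checks).
random_instance <- function(n, p = 1, seed) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    time <- sort(stats::rexp(n)) + seq_len(n) * 1e-6
    event <- stats::rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1L
    w <- stats::runif(n, 0.5, 4)
  })
  list(X = X, time = time, event = as.integer(event), w = w)
}
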