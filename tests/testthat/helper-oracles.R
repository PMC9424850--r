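# Shared fixtures and independent oracles used across test files.

# --- Lorenz flow with tangent propagation (Benettin oracle) -------------
# Fixed-step RK4 on the flow; the tangent vector is advanced with RK4 on
# the frozen Jacobian and renormalised every step, accumulating the
# largest-Lyapunov-exponent estimate.
lorenz_rhs <- function(s, sigma = 10, rho = 28, beta = 8 / 3) {
  c(sigma * (s[2] - s[1]),
    s[1] * (rho - s[3]) - s[2],
    s[1] * s[2] - beta * s[3])
}

lorenz_jacobian <- function(s, sigma = 10, rho = 28, beta = 8 / 3) {
  matrix(c(-sigma, sigma, 0,
           rho - s[3], -1, -s[1],
           s[2], s[1], -beta), 3, 3, byrow = TRUE)
}

rk4_step <- function(s, h, f) {
  k1 <- f(s); k2 <- f(s + h / 2 * k1); k3 <- f(s + h / 2 * k2); k4 <- f(s + h * k3)
  s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# returns the sampled trajectory and the Benettin exponent (per time unit)
lorenz_with_benettin <- function(n_keep, h = 0.01, transient = 2000) {
  s <- c(1, 1, 20)
  for (i in seq_len(transient)) s <- rk4_step(s, h, lorenz_rhs)
  X <- matrix(0, n_keep, 3)
  v <- c(1, 0, 0); lsum <- 0
  for (i in seq_len(n_keep)) {
    J <- lorenz_jacobian(s)
    v <- rk4_step(v, h, function(vv) as.vector(J %*% vv))
    s <- rk4_step(s, h, lorenz_rhs)
    nv <- sqrt(sum(v^2)); lsum <- lsum + log(nv); v <- v / nv
    X[i, ] <- s
  }
  list(X = X, lambda = lsum / (n_keep * h), dt = h)
}

# --- brute-force nearest-neighbour oracle -------------------------------
nn_bruteforce <- function(x, theiler) {
  n <- nrow(x)
  vapply(seq_len(n), function(i) {
    d2 <- colSums((t(x) - x[i, ])^2)
    d2[abs(seq_len(n) - i) < theiler] <- Inf
    if (all(!is.finite(d2))) NA_integer_ else which.min(d2)
  }, integer(1))
}

# --- small session configs used in several files ------------------------
# aligned sampling (0.99 s cycles at 100 Hz) so that normalised phase
# points coincide with acceleration samples
synth_config_aligned <- function(seed = 5, n_cycles = 400, ...,
                                 kv_noise_sigma = 0, pert_amp = 0.1,
                                 divergence_gamma = 0.05) {
  synth_config(seed = seed, n_cycles = n_cycles,
               low = synth_height(kv_noise_sigma = kv_noise_sigma,
                                  pert_amp = pert_amp,
                                  divergence_gamma = divergence_gamma,
                                  dur_start = 0.99, dur_end = 0.99, ...))
}

# small full session (both heights) shared by io/pipeline/cli tests
small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_session(synth_config(seed = 3, n_cycles = 24,
                                              mvc_duration = 2))
    }
    cache
  }
})
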