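# Shared fixtures and oracles, all built in code at test time.

# a small two-layer parameter set with distinct values
toy_params <- function(seed = 1) {
  set.seed(seed)
  fed_params(list(W = matrix(rnorm(6), 2, 3), b = rnorm(3)))
}

# central finite differences through flatten/unflatten: the independent
# gradient oracle
numeric_grad <- function(spec, theta, x, y, h = 1e-5) {
  f <- function(v) model_loss_grad(spec, param_unflatten(v, theta), x, y)$loss
  v0 <- param_flatten(theta)
  vapply(seq_along(v0), function(i) {
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    (f(vp) - f(vm)) / (2 * h)
  }, numeric(1))
}

expect_grad_matches <- function(spec, theta, x, y, tol = 1e-4) {
  g_num <- numeric_grad(spec, theta, x, y)
  g_an <- param_flatten(model_loss_grad(spec, theta, x, y)$grad)
  # relative tolerance with an absolute floor at the finite-difference
  # noise scale
  expect_lt(max(abs(g_an - g_num) / pmax(abs(g_num), 1e-6)), tol)
}

# hand-built two-client dataset with known counts (train sizes 3 and 5)
tiny_two_client_dataset <- function() {
  mk <- function(id, ntr, nte, p = 2, C = 2) {
    set.seed(id + 10)
    fedsim:::new_client_dataset(
      id,
      matrix(rnorm(ntr * p), ntr, p), sample(0:(C - 1), ntr, replace = TRUE),
      matrix(rnorm(nte * p), nte, p), sample(0:(C - 1), nte, replace = TRUE)
    )
  }
  fedsim:::new_fed_dataset(list(mk(0, 3, 2), mk(1, 5, 3)),
                           provenance = list(n_classes = 2, n_features = 2))
}

# small heterogeneous dataset for end-to-end runs (5 clients)
small_fed_dataset <- function(seed = 0, alpha = 0.5, beta = 0.5) {
  generate_synthetic(synthetic_spec(alpha, beta, n_clients = 5,
                                    n_features = 8, n_classes = 4,
                                    seed = seed))
}

# linearly separable two-class problem
separable_client <- function(n = 40, seed = 3) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- cbind(ifelse(y == 0, -2, 2) + 0.1 * rnorm(n), rnorm(n))
  fedsim:::new_client_dataset(0, x, y, x, y)
}

expect_params_equal <- function(a, b, tol = 0) {
  expect_identical(names(a), names(b))
  if (tol == 0) {
    expect_identical(param_flatten(a), param_flatten(b))
  } else {
    expect_lt(max(abs(param_flatten(a) - param_flatten(b))), tol)
  }
}
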