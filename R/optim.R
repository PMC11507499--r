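#' Client-side optimizer configuration
#'
#' Four local-update rules share one stepping interface:
#' * `sgd` -- plain minibatch gradient descent,
#' * `pgd` -- SGD on the proximally perturbed objective
#'   `H(theta, anchor) = F(theta) + (mu/2) * ||theta - anchor||^2`, whose
#'   gradient is `grad F + mu * (theta - anchor)`,
#' * `adam` -- Adam with bias-corrected first/second moment estimates,
#' * `padam` -- Adam applied to the same perturbed gradient as `pgd`.
#'
#' With `mu = 0`, `pgd` reduces bit-exactly to `sgd` and `padam` to `adam`.
#'
#' @param kind One of `"sgd"`, `"pgd"`, `"adam"`, `"padam"`.
#' @param learning_rate Positive step size eta.
#' @param mu Nonnegative proximal weight (used by `pgd`/`padam`; ignored by
#'   the others).
#' @param beta1,beta2 Adam exponential decay rates (defaults 0.9, 0.999).
#' @param epsilon Adam denominator offset (default 1e-8).
#' @return An `opt_config` list.
#' @export
optimizer_config <- function(kind = c("sgd", "pgd", "adam", "padam"),
                             learning_rate = 0.01, mu = 0,
                             beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  kind <- match.arg(kind)
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  if (mu < 0) stop("`mu` must be nonnegative")
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1) {
    stop("`beta1` and `beta2` must lie in [0, 1)")
  }
  if (epsilon <= 0) stop("`epsilon` must be positive")
  structure(list(kind = kind, learning_rate = learning_rate, mu = mu,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon),
            class = "opt_config")
}

#' Fresh optimizer state
#'
#' Zero first/second moments, step counter 0, and the frozen round-start
#' global parameters as the proximal anchor. A fresh state is created at the
#' start of every local update round: the broadcast global model overwrites
#' the local parameters, so stale moments from an earlier round would refer
#' to a different trajectory.
#'
#' @param template `fed_params` giving the layer layout.
#' @param anchor Round-start global `fed_params` (the proximal anchor).
#' @return An `opt_state` list.
#' @export
optimizer_state <- function(template, anchor) {
  structure(list(m = param_zero_like(template),
                 v = param_zero_like(template),
                 t = 0L, anchor = anchor),
            class = "opt_state")
}

#' Proximally perturbed gradient
#'
#' `grad + mu * (theta_local - anchor)`: the gradient of the local objective
#' augmented with the proximal term `(mu/2) * ||theta_local - anchor||^2`
#' tying the client to the round-start global model.
#'
#' @param grad Raw gradient (`fed_params`).
#' @param theta_local Current local parameters.
#' @param anchor Round-start global parameters.
#' @param mu Nonnegative proximal weight.
#' @return A `fed_params`.
#' @export
perturbed_grad <- function(grad, theta_local, anchor, mu) {
  check_conformable(theta_local, anchor)
  check_conformable(grad, theta_local)
  perturbed_grad_impl(grad, theta_local, anchor, mu)
}

perturbed_grad_impl <- function(grad, theta_local, anchor, mu) {
  for (nm in names(grad)) {
    grad[[nm]] <- grad[[nm]] + mu * (theta_local[[nm]] - anchor[[nm]])
  }
  grad
}

#' One optimizer step
#'
#' Applies the configured update rule to `theta` given the raw batch
#' gradient `grad` (the proximal perturbation, when configured, is applied
#' internally against the state's anchor):
#' * sgd/pgd: `theta - eta * g`;
#' * adam/padam: `t <- t + 1`; `m <- beta1 m + (1 - beta1) g`;
#'   `v <- beta2 v + (1 - beta2) g^2`; bias-corrected `m_hat = m/(1-beta1^t)`,
#'   `v_hat = v/(1-beta2^t)`; `theta - eta * m_hat / (sqrt(v_hat) + eps)`,
#'   all entrywise.
#'
#' @param config An [optimizer_config()].
#' @param state An [optimizer_state()] (fresh or from the previous step).
#' @param theta Current `fed_params`.
#' @param grad Raw gradient `fed_params`.
#' @return `list(theta = <updated fed_params>, state = <updated opt_state>)`.
#' @export
optimizer_step <- function(config, state, theta, grad) {
  check_conformable(theta, grad)
  check_conformable(theta, state$m)
  optimizer_step_impl(config, state, theta, grad)
}

# hot path: conformability is the caller's responsibility (checked once per
# client_update, not once per minibatch)
optimizer_step_impl <- function(config, state, theta, grad) {
  g <- if (config$kind %in% c("pgd", "padam")) {
    perturbed_grad_impl(grad, theta, state$anchor, config$mu)
  } else {
    grad
  }
  if (config$kind %in% c("sgd", "pgd")) {
    for (nm in names(theta)) {
      theta[[nm]] <- theta[[nm]] - config$learning_rate * g[[nm]]
    }
    return(list(theta = theta, state = state))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - config$beta1^state$t
  bc2 <- 1 - config$beta2^state$t
  for (nm in names(theta)) {
    state$m[[nm]] <- config$beta1 * state$m[[nm]] +
      (1 - config$beta1) * g[[nm]]
    state$v[[nm]] <- config$beta2 * state$v[[nm]] +
      (1 - config$beta2) * g[[nm]]^2
    theta[[nm]] <- theta[[nm]] - config$learning_rate *
      (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + config$epsilon)
  }
  list(theta = theta, state = state)
}

# Deterministic minibatch index schedule: `epochs` blocks, each a fresh
# shuffle of 1..n cycled through `iters` batches of size `batch_size`.
# iter_mode "product" takes exactly epochs*iters steps; "epoch_pass" takes
# ceiling(n/batch_size) batches per epoch (one full pass), ignoring `iters`.
batch_schedule <- function(n, batch_size, epochs, iters, seed,
                           iter_mode = c("product", "epoch_pass")) {
  iter_mode <- match.arg(iter_mode)
  if (batch_size > n) {
    warning("batch_size ", batch_size, " exceeds the client's ", n,
            " training samples; using full-set batches", call. = FALSE)
  }
  b <- min(batch_size, n)
  out <- list()
  for (e in seq_len(epochs)) {
    perm <- with_local_seed(derive_seed(seed, "epoch", e), sample.int(n))
    n_batches <- if (iter_mode == "product") iters else ceiling(n / b)
    at <- 0L
    for (i in seq_len(n_batches)) {
      if (at + b > n) {
        at <- 0L  # cycle: restart from the front of this epoch's shuffle
      }
      out[[length(out) + 1L]] <- perm[(at + 1L):(at + b)]
      at <- at + b
    }
  }
  out
}

#' Run one client's local update
#'
#' Implements the inner loop of the federated protocol: initialise the local
#' model from the broadcast global parameters, create a fresh optimizer
#' state anchored at those parameters, and take `num_epochs x num_iters`
#' minibatch steps (batches drawn by seeded shuffled cycling over the
#' client's training split, reshuffled every epoch). Deterministic given
#' `rng_seed`; optimizer state never leaks across calls.
#'
#' @param spec Model spec.
#' @param theta_global Broadcast global `fed_params`.
#' @param client A `client_dataset`.
#' @param config An [optimizer_config()].
#' @param num_epochs,num_iters,batch_size Local loop controls (all >= 1).
#' @param rng_seed Seed for the batch schedule.
#' @param iter_mode `"product"` (default: `num_epochs * num_iters` steps) or
#'   `"epoch_pass"` (each epoch is one full pass; `num_iters` ignored).
#' @return The client's updated `fed_params`.
#' @export
client_update <- function(spec, theta_global, client, config,
                          num_epochs = 10, num_iters = 20, batch_size = 10,
                          rng_seed = 0, iter_mode = "product") {
  stopifnot(num_epochs >= 1, num_iters >= 1, batch_size >= 1)
  n <- length(client$train_y)
  if (n == 0) stop("client ", client$client_id, " has no training samples")
  batches <- batch_schedule(n, batch_size, num_epochs, num_iters, rng_seed,
                            iter_mode)
  theta <- theta_global
  state <- optimizer_state(theta_global, anchor = theta_global)
  first <- TRUE
  for (ix in batches) {
    lg <- model_loss_grad(spec, theta,
                          client$train_x[ix, , drop = FALSE],
                          client$train_y[ix])
    if (first) {
      check_conformable(theta, lg$grad)
      first <- FALSE
    }
    stepped <- optimizer_step_impl(config, state, theta, lg$grad)
    theta <- stepped$theta
    state <- stepped$state
  }
  theta
}
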