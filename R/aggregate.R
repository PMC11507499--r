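#' Sample-size weighted model averaging
#'
#' The classic server aggregation rule: the global model is the convex
#' combination of the selected clients' parameters with weights
#' `n_k / sum(n_k)`.
#'
#' @param thetas List of conformable `fed_params`, one per selected client.
#' @param n_k Positive sample counts, one per client.
#' @return The aggregated `fed_params`.
#' @export
weighted_average <- function(thetas, n_k) {
  if (length(thetas) == 0) stop("no client models to aggregate")
  if (length(n_k) != length(thetas)) {
    stop("`n_k` must have one entry per client model")
  }
  if (any(n_k <= 0)) stop("all `n_k` must be positive")
  w <- n_k / sum(n_k)
  out <- param_scale(w[1], thetas[[1]])
  for (i in seq_along(thetas)[-1]) {
    check_conformable(thetas[[1]], thetas[[i]])
    out <- param_axpy(w[i], thetas[[i]], out)
  }
  out
}

softmax_stable <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

#' Attention weights from client-server parameter distances
#'
#' Scores each client by the L2 distance `s_k` between its uploaded
#' parameters and the current global parameters, and normalizes the scores
#' with a softmax (max-subtracted for overflow safety). Distances enter the
#' softmax directly, so more distant clients receive larger weight; set
#' `negate_scores = TRUE` to softmax `-s_k` instead and favour nearby
#' clients. With `scope = "per_layer"` there is one softmax group per layer;
#' with `"whole_model"` a single group over whole-model distances.
#'
#' @param theta_global Current global `fed_params`.
#' @param thetas List of client `fed_params`.
#' @param scope `"per_layer"` (default) or `"whole_model"`.
#' @param negate_scores Softmax the negated distances (default `FALSE`).
#' @return An `attention_report`: tibble with columns `client`, `layer`
#'   (`"<whole_model>"` for whole-model scope), `distance`, `weight`.
#'   Weights sum to 1 within each layer group.
#' @export
attention_weights <- function(theta_global, thetas,
                              scope = c("per_layer", "whole_model"),
                              negate_scores = FALSE) {
  scope <- match.arg(scope)
  if (length(thetas) == 0) stop("no client models")
  for (th in thetas) check_conformable(theta_global, th)
  m <- length(thetas)
  if (scope == "whole_model") {
    s <- vapply(thetas, function(th) {
      param_l2_distance(theta_global, th, "whole_model")
    }, numeric(1))
    w <- softmax_stable(if (negate_scores) -s else s)
    out <- tibble::tibble(client = seq_len(m),
                          layer = "<whole_model>", distance = s, weight = w)
  } else {
    D <- vapply(thetas, function(th) {
      param_l2_distance(theta_global, th, "per_layer")
    }, numeric(length(theta_global)))
    D <- matrix(D, nrow = length(theta_global))  # layers x clients
    W <- t(apply(D, 1, function(s) {
      softmax_stable(if (negate_scores) -s else s)
    }))
    if (m == 1) W <- matrix(1, length(theta_global), 1)
    out <- tibble::tibble(
      client = rep(seq_len(m), each = length(theta_global)),
      layer = rep(names(theta_global), times = m),
      distance = as.numeric(D),
      weight = as.numeric(W)
    )
  }
  structure(out, class = c("attention_report", class(out)))
}

#' Attention-weighted server aggregation
#'
#' The attentive global update
#' `theta_new = theta - lambda * sum_k alpha_k * (theta - theta_k)`, applied
#' within each softmax group (per layer by default): the server moves from
#' the current global model along the attention-weighted mean of the client
#' displacement directions, with step size `lambda`. At `lambda = 1` with
#' uniform weights this reproduces the plain mean of the client models.
#'
#' @inheritParams attention_weights
#' @param stepsize Positive step size lambda.
#' @param weights Optional precomputed [attention_weights()] report (must
#'   match `scope`); computed internally when omitted.
#' @return `list(theta = <fed_params>, report = <attention_report>)`.
#' @export
attention_aggregate <- function(theta_global, thetas, stepsize = 1.2,
                                scope = c("per_layer", "whole_model"),
                                negate_scores = FALSE, weights = NULL) {
  scope <- match.arg(scope)
  if (stepsize <= 0) stop("`stepsize` must be positive")
  rep <- weights %||%
    attention_weights(theta_global, thetas, scope, negate_scores)
  out <- theta_global
  if (scope == "whole_model") {
    wv <- rep$weight
    for (nm in names(theta_global)) {
      acc <- 0
      for (k in seq_along(thetas)) {
        acc <- acc + wv[k] * (theta_global[[nm]] - thetas[[k]][[nm]])
      }
      out[[nm]] <- theta_global[[nm]] - stepsize * acc
    }
  } else {
    for (nm in names(theta_global)) {
      wl <- rep$weight[rep$layer == nm]
      acc <- 0
      for (k in seq_along(thetas)) {
        acc <- acc + wl[k] * (theta_global[[nm]] - thetas[[k]][[nm]])
      }
      out[[nm]] <- theta_global[[nm]] - stepsize * acc
    }
  }
  list(theta = out, report = rep)
}
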