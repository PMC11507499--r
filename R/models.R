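#' Client model specifications
#'
#' The simulator's client models share one contract: [init_params()] builds a
#' seeded initial `fed_params`, [model_loss_grad()] returns the mean
#' cross-entropy over a batch together with its exact gradient,
#' [model_predict()] returns argmax class labels (0-based, ties toward the
#' lowest class index) and [model_accuracy()] / [model_eval()] score a
#' labelled set.
#'
#' `logreg_spec()` describes multinomial (softmax) logistic regression on
#' dense features: layers `W` (`n_features x n_classes`) and `b`
#' (`n_classes`), zero-initialised (the problem is convex, so a deterministic
#' start is both reproducible and harmless).
#'
#' @param n_features Number of input features.
#' @param n_classes Number of classes (>= 2).
#' @param init_seed Seed for parameter initialization (unused by the
#'   zero-initialised logistic model, kept for contract uniformity).
#' @return A model spec object.
#' @export
logreg_spec <- function(n_features, n_classes, init_seed = 0) {
  stopifnot(n_features >= 1, n_classes >= 2)
  structure(list(kind = "logreg", n_features = as.integer(n_features),
                 n_classes = as.integer(n_classes),
                 init_seed = as.integer(init_seed)),
            class = c("logreg_spec", "model_spec"))
}

#' Initial parameters for a model spec
#' @param spec A model spec.
#' @return A `fed_params`.
#' @export
init_params <- function(spec) UseMethod("init_params")

#' @export
init_params.logreg_spec <- function(spec) {
  fed_params(list(W = matrix(0, spec$n_features, spec$n_classes),
                  b = numeric(spec$n_classes)))
}

#' Batch loss and gradient
#'
#' Mean cross-entropy of the true labels under the model's softmax output,
#' with its exact gradient with respect to every parameter. Pure: no state is
#' kept between calls.
#'
#' @param spec A model spec.
#' @param params Conformable `fed_params`.
#' @param x Feature matrix (`logreg`) or token-index matrix (`lstm`), one row
#'   per sample.
#' @param y Integer labels in `[0, n_classes)`.
#' @return `list(loss = <numeric>, grad = <fed_params>)`.
#' @export
model_loss_grad <- function(spec, params, x, y) UseMethod("model_loss_grad")

# Numerically stable softmax cross-entropy pieces shared by both models.
# Returns the per-row probability matrix, the mean loss, and d loss / d score
# (already divided by the batch size).
softmax_ce <- function(scores, y) {
  n <- nrow(scores)
  mx <- scores[cbind(seq_len(n), max.col(scores, ties.method = "first"))]
  ex <- exp(scores - mx)
  Z <- rowSums(ex)
  P <- ex / Z
  idx <- cbind(seq_len(n), y + 1L)
  loss <- mean(log(Z) - (scores[idx] - mx))
  G <- P
  G[idx] <- G[idx] - 1
  list(P = P, loss = loss, G = G / n)
}

#' @export
model_loss_grad.logreg_spec <- function(spec, params, x, y) {
  if (length(y) == 0) stop("empty batch")
  scores <- x %*% params$W + rep(params$b, each = nrow(x))
  ce <- softmax_ce(scores, y)
  grad <- params
  grad$W <- crossprod(x, ce$G)
  grad$b <- colSums(ce$G)
  list(loss = ce$loss, grad = grad)
}

#' Class predictions and accuracy
#'
#' @inheritParams model_loss_grad
#' @return `model_predict()`: integer vector of 0-based labels;
#'   `model_accuracy()`: fraction correct in `[0, 1]`.
#' @export
model_predict <- function(spec, params, x) UseMethod("model_predict")

#' @export
model_predict.logreg_spec <- function(spec, params, x) {
  scores <- x %*% params$W + rep(params$b, each = nrow(x))
  max.col(scores, ties.method = "first") - 1L
}

#' @rdname model_predict
#' @export
model_accuracy <- function(spec, params, x, y) {
  mean(model_predict(spec, params, x) == y)
}

#' Forward-only evaluation: accuracy and mean cross-entropy
#' @inheritParams model_loss_grad
#' @return `list(acc = <numeric>, loss = <numeric>, n = <int>)`.
#' @export
model_eval <- function(spec, params, x, y) UseMethod("model_eval")

#' @export
model_eval.logreg_spec <- function(spec, params, x, y) {
  scores <- x %*% params$W + rep(params$b, each = nrow(x))
  ce <- softmax_ce(scores, y)
  pred <- max.col(scores, ties.method = "first") - 1L
  list(acc = mean(pred == y), loss = ce$loss, n = length(y))
}
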