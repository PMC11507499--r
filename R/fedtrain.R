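ALGORITHMS <- c("fedavg", "fedprox", "fedatt", "fedpa",
                "fedavgs", "fedavgt", "fedproxp", "fedatts", "fedpap")

# algorithm -> (aggregator, optimizer) binding
algorithm_binding <- function(algorithm) {
  switch(algorithm,
    fedavg   = list(aggregator = "weighted", optimizer = "sgd"),
    fedprox  = list(aggregator = "weighted", optimizer = "pgd"),
    fedatt   = list(aggregator = "attention", optimizer = "sgd"),
    fedpa    = list(aggregator = "attention", optimizer = "pgd"),
    fedavgs  = list(aggregator = "weighted", optimizer = "adam"),
    fedavgt  = list(aggregator = "weighted", optimizer = "adam"),
    fedproxp = list(aggregator = "weighted", optimizer = "padam"),
    fedatts  = list(aggregator = "attention", optimizer = "adam"),
    fedpap   = list(aggregator = "attention", optimizer = "padam"),
    stop("unknown algorithm '", algorithm, "'; valid choices: ",
         paste(ALGORITHMS, collapse = ", "))
  )
}

#' Federated experiment configuration
#'
#' Bundles the algorithm identifier with every training hyperparameter. The
#' defaults are the benchmark settings used throughout the synthetic
#' experiments: SGD learning rate 0.01, 100 communication rounds, 10 of the
#' clients sampled per round, 10 local epochs of 20 iterations with batch
#' size 10, proximal weight `mu = 1`, attention step size 1.2. The nine
#' algorithms bind an aggregator and a local optimizer: `fedavg`/`fedprox`/
#' `fedavgs`/`fedavgt`/`fedproxp` average with sample-size weights while
#' `fedatt`/`fedpa`/`fedatts`/`fedpap` use attention aggregation; local
#' updates are SGD (`fedavg`, `fedatt`), proximal SGD (`fedprox`, `fedpa`),
#' Adam (`fedavgs`, `fedavgt`, `fedatts`) or proximal Adam (`fedproxp`,
#' `fedpap`). `fedavgs` and `fedavgt` are mathematically identical (they
#' exist as a pair so an independent Adam implementation can be validated
#' against a library one); this simulator runs the same Adam for both.
#'
#' @param algorithm One of `"fedavg"`, `"fedprox"`, `"fedatt"`, `"fedpa"`,
#'   `"fedavgs"`, `"fedavgt"`, `"fedproxp"`, `"fedatts"`, `"fedpap"`.
#' @param learning_rate Local optimizer step size (use 0.001 for the Adam
#'   family).
#' @param num_rounds Communication rounds.
#' @param clients_per_round Clients sampled uniformly without replacement
#'   each round.
#' @param num_epochs,num_iters,batch_size Local loop controls (see
#'   [client_update()]).
#' @param eval_every Evaluate the global model every this many rounds.
#' @param seed Training seed (client sampling, batching); independent of the
#'   data seed.
#' @param mu Proximal weight for `fedprox`/`fedpa`/`fedproxp`/`fedpap`.
#' @param stepsize Attention aggregation step size lambda.
#' @param scope Attention softmax grouping (see [attention_weights()]).
#' @param negate_scores Attention score sign (see [attention_weights()]).
#' @param iter_mode Local loop mode (see [client_update()]).
#' @param loss_on Evaluate loss on `"test"` (default, consistent with the
#'   accuracy metric) or `"train"`.
#' @return A `fed_config` list.
#' @export
federated_config <- function(algorithm = "fedavg", learning_rate = 0.01,
                             num_rounds = 100, clients_per_round = 10,
                             num_epochs = 10, num_iters = 20,
                             eval_every = 1, batch_size = 10, seed = 0,
                             mu = 1, stepsize = 1.2,
                             scope = "per_layer", negate_scores = FALSE,
                             iter_mode = "product", loss_on = "test") {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  stopifnot(num_rounds >= 1, clients_per_round >= 1, num_epochs >= 1,
            num_iters >= 1, eval_every >= 1, batch_size >= 1,
            learning_rate > 0, mu >= 0, stepsize > 0)
  loss_on <- match.arg(loss_on, c("test", "train"))
  structure(list(algorithm = algorithm, learning_rate = learning_rate,
                 num_rounds = as.integer(num_rounds),
                 clients_per_round = as.integer(clients_per_round),
                 num_epochs = as.integer(num_epochs),
                 num_iters = as.integer(num_iters),
                 eval_every = as.integer(eval_every),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), mu = mu, stepsize = stepsize,
                 scope = scope, negate_scores = isTRUE(negate_scores),
                 iter_mode = iter_mode, loss_on = loss_on),
            class = "fed_config")
}

#' Sample the clients participating in a round
#'
#' Uniform sample without replacement, deterministic given `(seed, round)`.
#'
#' @param n_total Number of clients in the population.
#' @param clients_per_round Number to select (<= `n_total`).
#' @param round_index 1-based round number.
#' @param seed Training seed.
#' @return Sorted integer vector of 1-based client indices.
#' @export
sample_clients <- function(n_total, clients_per_round, round_index, seed) {
  if (clients_per_round > n_total) {
    stop("clients_per_round (", clients_per_round,
         ") exceeds the population (", n_total, ")")
  }
  sort(with_local_seed(derive_seed(seed, "sample", round_index),
                       sample.int(n_total, clients_per_round)))
}

#' Evaluate the global model over every client's test set
#'
#' The weighted accuracy metric: per-client test accuracy averaged with
#' test-set-size weights, which equals pooled correct-over-total; loss is
#' the test-sample-weighted mean cross-entropy.
#'
#' @param spec Model spec.
#' @param theta Global `fed_params`.
#' @param dataset A `fed_dataset` whose clients all have test splits.
#' @param split `"test"` (default) or `"train"`.
#' @return `list(acc, loss)`.
#' @export
evaluate_global <- function(spec, theta, dataset, split = "test") {
  xs <- if (split == "test") "test_x" else "train_x"
  ys <- if (split == "test") "test_y" else "train_y"
  tot_n <- 0; tot_acc <- 0; tot_loss <- 0
  for (cl in dataset$clients) {
    ev <- model_eval(spec, theta, cl[[xs]], cl[[ys]])
    tot_n <- tot_n + ev$n
    tot_acc <- tot_acc + ev$n * ev$acc
    tot_loss <- tot_loss + ev$n * ev$loss
  }
  list(acc = tot_acc / tot_n, loss = tot_loss / tot_n)
}

#' Run a federated training experiment
#'
#' The orchestration loop: every round the server samples
#' `clients_per_round` clients, broadcasts the global parameters, each
#' sampled client runs [client_update()] with the configured optimizer, and
#' the server aggregates the uploads with sample-size weighting or attention
#' according to the algorithm binding. Every `eval_every` rounds the global
#' model is evaluated on all clients' test sets. Fully deterministic given
#' `config$seed` (training randomness) and the dataset.
#'
#' @param config A [federated_config()].
#' @param dataset A `fed_dataset`.
#' @param model_spec A model spec matching the dataset's feature layout.
#' @return A `fed_run` object: `metrics` (tibble of per-evaluation rounds),
#'   `theta` (final global `fed_params`), `config`, and `attention` (list of
#'   per-round attention reports, for attention algorithms).
#' @examples
#' ds <- generate_synthetic(synthetic_spec(n_clients = 4, n_features = 5,
#'                                         n_classes = 3))
#' cfg <- federated_config("fedavg", num_rounds = 2, clients_per_round = 2,
#'                         num_epochs = 1, num_iters = 2)
#' run <- run_federated(cfg, ds, logreg_spec(5, 3))
#' tidy(run)
#' @export
run_federated <- function(config, dataset, model_spec) {
  binding <- algorithm_binding(config$algorithm)
  n_cl <- length(dataset$clients)
  if (config$clients_per_round > n_cl) {
    stop("clients_per_round exceeds the dataset's ", n_cl, " clients")
  }
  if (inherits(model_spec, "logreg_spec")) {
    p <- ncol(dataset$clients[[1]]$train_x)
    if (p != model_spec$n_features) {
      stop("model expects ", model_spec$n_features, " features but the ",
           "dataset has ", p)
    }
  }
  opt <- optimizer_config(binding$optimizer,
                          learning_rate = config$learning_rate,
                          mu = config$mu)
  theta <- init_params(model_spec)
  metrics <- vector("list", 0)
  att_log <- list()
  t0 <- proc.time()[["elapsed"]]
  for (r in seq_len(config$num_rounds)) {
    sel <- sample_clients(n_cl, config$clients_per_round, r, config$seed)
    thetas <- vector("list", length(sel))
    n_k <- integer(length(sel))
    for (j in seq_along(sel)) {
      cl <- dataset$clients[[sel[j]]]
      thetas[[j]] <- client_update(
        model_spec, theta, cl, opt,
        num_epochs = config$num_epochs, num_iters = config$num_iters,
        batch_size = config$batch_size,
        rng_seed = derive_seed(config$seed, "batch", r, sel[j]),
        iter_mode = config$iter_mode
      )
      n_k[j] <- length(cl$train_y)
    }
    if (binding$aggregator == "weighted") {
      theta <- weighted_average(thetas, n_k)
    } else {
      agg <- attention_aggregate(theta, thetas, stepsize = config$stepsize,
                                 scope = config$scope,
                                 negate_scores = config$negate_scores)
      theta <- agg$theta
      att_log[[as.character(r)]] <- agg$report
    }
    if (r %% config$eval_every == 0 || r == config$num_rounds) {
      ev <- evaluate_global(model_spec, theta, dataset)
      loss <- if (config$loss_on == "train") {
        evaluate_global(model_spec, theta, dataset, "train")$loss
      } else {
        ev$loss
      }
      metrics[[length(metrics) + 1L]] <- tibble::tibble(
        round = r, acc = ev$acc, loss = loss,
        elapsed_ms = (proc.time()[["elapsed"]] - t0) * 1000
      )
    }
  }
  structure(list(metrics = dplyr::bind_rows(metrics), theta = theta,
                 config = config, attention = att_log),
            class = "fed_run")
}

#' @export
print.fed_run <- function(x, ...) {
  g <- glance(x)
  cat("<fed_run> ", x$config$algorithm, ": ", nrow(x$metrics),
      " evaluated rounds, max Acc ", sprintf("%.4f", g$max_acc),
      ", min loss ", sprintf("%.4f", g$min_loss), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-round metrics of a federated run
#' @param x A `fed_run`.
#' @param ... Unused.
#' @return Tibble with `algorithm`, `round`, `acc`, `loss`, `elapsed_ms`.
#' @method tidy fed_run
#' @export
tidy.fed_run <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(algorithm = x$config$algorithm),
                   x$metrics)
}

#' One-row summary of a federated run
#' @param x A `fed_run`.
#' @param ... Unused.
#' @return Tibble with `algorithm`, `max_acc`, `min_loss`, `final_acc`,
#'   `rounds`.
#' @method glance fed_run
#' @export
glance.fed_run <- function(x, ...) {
  tibble::tibble(
    algorithm = x$config$algorithm,
    max_acc = max(x$metrics$acc),
    min_loss = min(x$metrics$loss),
    final_acc = x$metrics$acc[nrow(x$metrics)],
    rounds = max(x$metrics$round)
  )
}

#' Max-Acc / min-loss comparison table for several runs
#'
#' @param runs A list of `fed_run` objects (or a single one).
#' @return Tibble with one row per run, in the style of the benchmark
#'   comparison tables.
#' @export
summarize_runs <- function(runs) {
  if (inherits(runs, "fed_run")) runs <- list(runs)
  purrr::map_dfr(runs, glance)
}
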