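test_that("client sampling is deterministic, exhaustive, and near-uniform", {
  expect_equal(sample_clients(7, 7, 1, 0), 1:7)
  expect_identical(sample_clients(30, 10, 5, 3), sample_clients(30, 10, 5, 3))
  expect_false(identical(sample_clients(30, 10, 5, 3),
                         sample_clients(30, 10, 6, 3)))
  expect_error(sample_clients(5, 6, 1, 0), "exceeds")

  counts <- integer(30)
  for (r in 1:1000) {
    sel <- sample_clients(30, 10, r, 1)
    counts[sel] <- counts[sel] + 1L
  }
  # each client expected 1000/3 times; binomial sd ~ 14.9, allow 3 sigma
  expect_true(all(abs(counts - 1000 / 3) < 3 * sqrt(1000 * (1 / 3) * (2 / 3))))
})

test_that("global evaluation weights client accuracies by test size", {
  spec <- logreg_spec(1, 2)
  # constant class-0 predictor
  theta <- fed_params(list(W = matrix(0, 1, 2), b = c(10, 0)))
  mk <- function(id, y) {
    fedsim:::new_client_dataset(id, matrix(0, 1, 1), 0L,
                                matrix(0, length(y), 1), y)
  }
  # client test sizes 2 and 6 with accuracies 1.0 and 0.5
  ds <- fedsim:::new_fed_dataset(
    list(mk(0, c(0L, 0L)), mk(1, c(0L, 0L, 0L, 1L, 1L, 1L))),
    provenance = list(n_classes = 2)
  )
  ev <- evaluate_global(spec, theta, ds)
  expect_equal(ev$acc, (2 * 1 + 6 * 0.5) / 8)
  # weighted accuracy equals pooled correct / total
  pooled_correct <- 2 + 3
  expect_equal(ev$acc, pooled_correct / 8)
})

test_that("perfect and constant classifiers bound the accuracy range", {
  ds <- tiny_two_client_dataset()
  spec <- logreg_spec(2, 2)
  theta <- init_params(spec)
  ev <- evaluate_global(spec, theta, ds)
  expect_gte(ev$acc, 0)
  expect_lte(ev$acc, 1)
})

test_that("metrics are recorded every eval_every rounds", {
  ds <- small_fed_dataset()
  cfg <- federated_config("fedavg", num_rounds = 7, clients_per_round = 2,
                          num_epochs = 1, num_iters = 2, eval_every = 3)
  run <- run_federated(cfg, ds, logreg_spec(8, 4))
  expect_equal(nrow(run$metrics), ceiling(7 / 3))
  expect_equal(run$metrics$round, c(3, 6, 7))
})

test_that("the mu = 0 reduction lattice holds bit-exactly", {
  ds <- small_fed_dataset()
  spec <- logreg_spec(8, 4)
  pairs <- list(c("fedprox", "fedavg"), c("fedpa", "fedatt"),
                c("fedproxp", "fedavgs"), c("fedpap", "fedatts"))
  for (pair in pairs) {
    runs <- lapply(pair, function(alg) {
      cfg <- federated_config(alg, num_rounds = 3, clients_per_round = 3,
                              num_epochs = 1, num_iters = 3, mu = 0,
                              seed = 1)
      run_federated(cfg, ds, spec)
    })
    expect_params_equal(runs[[1]]$theta, runs[[2]]$theta)
    expect_identical(runs[[1]]$metrics$acc, runs[[2]]$metrics$acc)
  }
})

test_that("attention runs log per-round attention reports", {
  ds <- small_fed_dataset()
  cfg <- federated_config("fedatt", num_rounds = 2, clients_per_round = 3,
                          num_epochs = 1, num_iters = 2)
  run <- run_federated(cfg, ds, logreg_spec(8, 4))
  expect_equal(length(run$attention), 2)
  rep1 <- run$attention[[1]]
  sums <- tapply(rep1$weight, rep1$layer, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("single-client federation collapses to sequential local training", {
  ds <- fedsim:::new_fed_dataset(list(separable_client()),
                                 provenance = list(n_classes = 2,
                                                   n_features = 2))
  spec <- logreg_spec(2, 2)
  cfg <- federated_config("fedavg", num_rounds = 3, clients_per_round = 1,
                          num_epochs = 1, num_iters = 4, batch_size = 5,
                          seed = 2)
  run <- run_federated(cfg, ds, spec)
  # manual chain with the same per-round batch substreams
  opt <- optimizer_config("sgd", learning_rate = cfg$learning_rate)
  theta <- init_params(spec)
  for (r in 1:3) {
    theta <- client_update(spec, theta, ds$clients[[1]], opt,
                           num_epochs = 1, num_iters = 4, batch_size = 5,
                           rng_seed = derive_seed(cfg$seed, "batch", r, 1))
  }
  expect_params_equal(run$theta, theta)
})

test_that("full participation with one full-batch step equals pooled gradient descent", {
  # with every client selected, one local step on the client's full training
  # set, and sample-size weighting, the round update is exactly one
  # full-batch gradient step on the pooled objective:
  # sum_k (n_k/n) (theta - eta grad F_k) = theta - eta grad f
  ds <- generate_synthetic(synthetic_spec(0.8, 0.8, n_clients = 6,
                                          n_features = 7, n_classes = 3,
                                          seed = 4, size_meanlog = 2))
  spec <- logreg_spec(7, 3)
  max_n <- max(vapply(ds$clients, function(cl) length(cl$train_y),
                      integer(1)))
  cfg <- federated_config("fedavg", num_rounds = 10, clients_per_round = 6,
                          num_epochs = 1, num_iters = 1,
                          batch_size = max_n, learning_rate = 0.05)
  run <- suppressWarnings(run_federated(cfg, ds, spec))

  pooled_x <- do.call(rbind, lapply(ds$clients, `[[`, "train_x"))
  pooled_y <- unlist(lapply(ds$clients, `[[`, "train_y"))
  theta <- init_params(spec)
  for (r in 1:10) {
    g <- model_loss_grad(spec, theta, pooled_x, pooled_y)$grad
    theta <- param_axpy(-0.05, g, theta)
  }
  expect_params_equal(run$theta, theta, tol = 1e-10)
})

test_that("mismatched model and dataset dimensions fail before round 1", {
  ds <- small_fed_dataset()
  cfg <- federated_config("fedavg", num_rounds = 1, clients_per_round = 2,
                          num_epochs = 1, num_iters = 1)
  expect_error(run_federated(cfg, ds, logreg_spec(99, 4)), "features")
  expect_error(federated_config("not-an-algorithm"), "fedavg")
})

test_that("tidy, glance and summaries expose the run metrics", {
  ds <- small_fed_dataset()
  cfg <- federated_config("fedavgs", learning_rate = 0.001, num_rounds = 3,
                          clients_per_round = 2, num_epochs = 1,
                          num_iters = 3)
  run <- run_federated(cfg, ds, logreg_spec(8, 4))
  td <- tidy(run)
  expect_equal(nrow(td), 3)
  expect_true(all(c("algorithm", "round", "acc", "loss") %in% names(td)))
  g <- glance(run)
  expect_equal(g$max_acc, max(td$acc))
  expect_equal(g$min_loss, min(td$loss))
  tab <- summarize_runs(list(run, run))
  expect_equal(nrow(tab), 2)
})
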