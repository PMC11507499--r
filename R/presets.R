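PRESET_DATASETS <- c("synthetic00", "synthetic0505", "synthetic11",
                     "synthetic_iid", "text_fixture")

#' Experiment presets
#'
#' One-call configurations for the benchmark experiments: any of the nine
#' algorithms on the four synthetic datasets (logistic-regression client) or
#' on a generated dialogue-corpus fixture (LSTM client). Hyperparameters
#' follow the benchmark's tuned values: SGD learning rate 0.01, Adam family
#' 0.001; attention step size 4 on synthetic data and 9 on text; proximal
#' weight 1 for `fedprox` and 0.03 for the attention/Adam proximal variants.
#' The text preset runs at reduced scale (vocabulary 500, embedding 16,
#' hidden 32, 20 rounds, 10 local steps per client) so a full experiment takes
#' minutes on one CPU.
#'
#' @param algorithm One of the nine algorithm names (see
#'   [federated_config()]).
#' @param dataset One of `"synthetic00"`, `"synthetic0505"`, `"synthetic11"`,
#'   `"synthetic_iid"`, `"text_fixture"`.
#' @param data_seed Seed of the generated dataset.
#' @param train_seed Training seed.
#' @param ... Overrides passed on to [federated_config()].
#' @return An `experiment_preset` list with elements `name`, `config`,
#'   `data_spec`, and `model` (a function of the dataset returning the model
#'   spec).
#' @export
experiment_preset <- function(algorithm, dataset = "synthetic0505",
                              data_seed = 0, train_seed = 0, ...) {
  dataset <- match.arg(dataset, PRESET_DATASETS)
  algorithm <- match.arg(algorithm, ALGORITHMS)
  adam_family <- algorithm %in% c("fedavgs", "fedavgt", "fedproxp",
                                  "fedatts", "fedpap")
  proximal <- algorithm %in% c("fedprox", "fedpa", "fedproxp", "fedpap")
  lr <- if (adam_family) 0.001 else 0.01
  mu <- if (!proximal) 0 else if (algorithm == "fedprox") 1 else 0.03
  if (dataset == "text_fixture") {
    config <- federated_config(
      algorithm, learning_rate = lr, num_rounds = 20,
      clients_per_round = 10, num_epochs = 1, num_iters = 10,
      batch_size = 10, seed = train_seed, mu = mu, stepsize = 9, ...
    )
    data_spec <- corpus_fixture_spec(n_dialogues = 60,
                                     sentences_per_dialogue_mean = 20,
                                     vocab_size = 500, n_classes = 2,
                                     label_skew = 1, seed = data_seed)
    model <- function(ds) {
      lstm_spec(vocab_size = 501, embed_dim = 16, hidden_dim = 32,
                max_len = ds$provenance$max_len %||% 30, n_classes = 2,
                init_seed = train_seed)
    }
  } else {
    ab <- switch(dataset,
                 synthetic00 = c(0, 0), synthetic0505 = c(0.5, 0.5),
                 synthetic11 = c(1, 1), synthetic_iid = c(0, 0))
    config <- federated_config(
      algorithm, learning_rate = lr, num_rounds = 100,
      clients_per_round = 10, num_epochs = 10, num_iters = 20,
      batch_size = 10, seed = train_seed, mu = mu, stepsize = 4, ...
    )
    data_spec <- synthetic_spec(alpha = ab[1], beta = ab[2],
                                iid = dataset == "synthetic_iid",
                                seed = data_seed)
    model <- function(ds) {
      logreg_spec(ds$provenance$n_features, ds$provenance$n_classes,
                  init_seed = train_seed)
    }
  }
  structure(list(name = paste(algorithm, dataset, sep = "_"),
                 algorithm = algorithm, dataset = dataset,
                 config = config, data_spec = data_spec, model = model),
            class = "experiment_preset")
}

#' Materialise a preset's dataset
#' @param preset An [experiment_preset()].
#' @param n_clients Number of clients for text fixtures (default 30).
#' @return A `fed_dataset`.
#' @export
preset_dataset <- function(preset, n_clients = 30) {
  if (preset$dataset == "text_fixture") {
    records <- generate_imcs_fixture(preset$data_spec)
    vocab <- build_vocab(fixture_tokens(preset$data_spec$vocab_size))
    build_federated_text(records, n_clients = n_clients, vocab = vocab,
                         max_len = 30, seed = preset$data_spec$seed)
  } else {
    generate_synthetic(preset$data_spec)
  }
}

#' Run an experiment preset end to end
#'
#' Generates (or accepts) the preset's dataset, builds the model and calls
#' [run_federated()].
#'
#' @param preset An [experiment_preset()].
#' @param dataset Optional pre-generated `fed_dataset` (so several presets
#'   can share one dataset).
#' @return A `fed_run`.
#' @export
run_preset <- function(preset, dataset = NULL) {
  ds <- dataset %||% preset_dataset(preset)
  run_federated(preset$config, ds, preset$model(ds))
}

#' Write / read an experiment preset as YAML
#'
#' The YAML carries the algorithm, dataset identifier, every
#' [federated_config()] key, and the data spec; a written preset reads back
#' equal.
#'
#' @param preset An [experiment_preset()].
#' @param path YAML file path.
#' @return `write_preset_yaml()` returns `path` invisibly;
#'   `read_preset_yaml()` the restored preset.
#' @export
write_preset_yaml <- function(preset, path) {
  obj <- list(name = preset$name, algorithm = preset$algorithm,
              dataset = preset$dataset,
              config = unclass(preset$config),
              data_spec = unclass(preset$data_spec))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_preset_yaml
#' @param overrides Named list applied over the stored config keys.
#' @export
read_preset_yaml <- function(path, overrides = list()) {
  obj <- yaml::read_yaml(path)
  pre <- experiment_preset(obj$algorithm, obj$dataset)
  cfg <- obj$config
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  pre$config <- do.call(federated_config, cfg)
  if (obj$dataset == "text_fixture") {
    pre$data_spec <- do.call(corpus_fixture_spec,
                             obj$data_spec[names(obj$data_spec) %in%
                                             names(formals(corpus_fixture_spec))])
  } else {
    pre$data_spec <- do.call(synthetic_spec,
                             obj$data_spec[names(obj$data_spec) %in%
                                             names(formals(synthetic_spec))])
  }
  pre$name <- obj$name %||% pre$name
  pre
}
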