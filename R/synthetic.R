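#' Specification for the synthetic(alpha, beta) heterogeneous generator
#'
#' Parameterises the classic federated-benchmark generator in which `alpha`
#' controls label-distribution skew across clients and `beta` controls
#' feature-distribution skew. Each client k receives its own softmax "teacher"
#' model `W_k, b_k` whose entries are drawn around a client effect
#' `u_k ~ N(0, alpha)`, and its own feature location `v_k` drawn around
#' `B_k ~ N(0, beta)`; features have decaying per-coordinate variance
#' `j^(-cov_exponent)`. With `iid = TRUE` a single shared teacher and feature
#' location is used for every client, giving the IID control condition.
#'
#' Per-client sample sizes follow the reference law
#' `n_k = size_base + floor(LogNormal(size_meanlog, size_sdlog))`, a heavy
#' tailed law under which a few clients dominate the sample -- the size
#' imbalance the benchmark is designed to exhibit. All constants are exposed
#' so alternatives can be configured.
#'
#' @param alpha Nonnegative label-skew parameter.
#' @param beta Nonnegative feature-skew parameter.
#' @param n_clients,n_features,n_classes Problem dimensions (defaults 30, 60,
#'   10, the benchmark's standard configuration).
#' @param iid If `TRUE`, use one shared teacher model and feature location.
#' @param seed Integer seed; controls the data only (training has its own
#'   seed in [federated_config()]).
#' @param train_fraction Fraction of each client's samples placed in the
#'   training split; the training size is `floor(train_fraction * n_k)`.
#' @param size_base,size_meanlog,size_sdlog Sample-size law constants.
#' @param cov_exponent Decay exponent of the per-feature variance profile.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(alpha = 0, beta = 0, n_clients = 30,
                           n_features = 60, n_classes = 10, iid = FALSE,
                           seed = 0, train_fraction = 0.9,
                           size_base = 50, size_meanlog = 4, size_sdlog = 2,
                           cov_exponent = 1.2) {
  if (alpha < 0 || beta < 0) stop("`alpha` and `beta` must be nonnegative")
  if (n_classes < 2) stop("`n_classes` must be at least 2")
  if (n_clients < 1 || n_features < 1) stop("dimensions must be positive")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1")
  }
  structure(list(
    alpha = alpha, beta = beta, n_clients = as.integer(n_clients),
    n_features = as.integer(n_features), n_classes = as.integer(n_classes),
    iid = isTRUE(iid), seed = as.integer(seed),
    train_fraction = train_fraction, size_base = size_base,
    size_meanlog = size_meanlog, size_sdlog = size_sdlog,
    cov_exponent = cov_exponent
  ), class = "synthetic_spec")
}

new_client_dataset <- function(client_id, train_x, train_y, test_x, test_y) {
  stopifnot(nrow(train_x) == length(train_y),
            nrow(test_x) == length(test_y))
  structure(list(client_id = as.integer(client_id),
                 train_x = train_x, train_y = as.integer(train_y),
                 test_x = test_x, test_y = as.integer(test_y)),
            class = "client_dataset")
}

new_fed_dataset <- function(clients, provenance) {
  structure(list(clients = clients, provenance = provenance),
            class = "fed_dataset")
}

#' @export
print.fed_dataset <- function(x, ...) {
  ntr <- sum(vapply(x$clients, function(cl) length(cl$train_y), integer(1)))
  nte <- sum(vapply(x$clients, function(cl) length(cl$test_y), integer(1)))
  cat("<fed_dataset> ", length(x$clients), " clients, ",
      ntr, " train / ", nte, " test samples\n", sep = "")
  invisible(x)
}

#' Number of clients in a federated dataset
#' @param ds A `fed_dataset`.
#' @return Integer.
#' @export
n_clients <- function(ds) length(ds$clients)

#' Generate a synthetic(alpha, beta) federated classification dataset
#'
#' Draws every client's sample size, teacher model, feature distribution and
#' samples as described in [synthetic_spec()], labels each sample by the
#' argmax of its teacher softmax score, and splits each client into train and
#' test. Deterministic given `spec` (including its seed): each client's
#' sizes, teacher, features and split come from named substreams of the root
#' seed, so enlarging `n_clients` leaves earlier clients' data unchanged.
#'
#' Labels are 0-based integers in `[0, n_classes)` and client ids are
#' 0-based, following the benchmark's conventions.
#'
#' @param spec A [synthetic_spec()].
#' @return A `fed_dataset` with one `client_dataset` per client.
#' @examples
#' ds <- generate_synthetic(synthetic_spec(alpha = 1, beta = 1, n_clients = 4))
#' partition_stats(ds)
#' @export
generate_synthetic <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  p <- spec$n_features
  C <- spec$n_classes
  sdiag <- sqrt((seq_len(p))^(-spec$cov_exponent))

  shared <- NULL
  if (spec$iid) {
    shared <- with_local_seed(derive_seed(spec$seed, "models", "shared"), {
      W <- matrix(stats::rnorm(p * C), p, C)
      b <- stats::rnorm(C)
      B <- stats::rnorm(1, 0, spec$beta)
      v <- stats::rnorm(p, B, 1)
      list(W = W, b = b, v = v)
    })
  }

  clients <- vector("list", spec$n_clients)
  for (k in seq_len(spec$n_clients)) {
    n_k <- with_local_seed(derive_seed(spec$seed, "sizes", k), {
      spec$size_base +
        floor(stats::rlnorm(1, spec$size_meanlog, spec$size_sdlog))
    })
    n_k <- as.integer(n_k)

    if (spec$iid) {
      W <- shared$W; b <- shared$b; v <- shared$v
    } else {
      mdl <- with_local_seed(derive_seed(spec$seed, "models", k), {
        u_k <- stats::rnorm(1, 0, spec$alpha)
        list(W = matrix(stats::rnorm(p * C, u_k, 1), p, C),
             b = stats::rnorm(C, u_k, 1))
      })
      W <- mdl$W; b <- mdl$b
      v <- with_local_seed(derive_seed(spec$seed, "features", k), {
        B_k <- stats::rnorm(1, 0, spec$beta)
        stats::rnorm(p, B_k, 1)
      })
    }

    x <- with_local_seed(derive_seed(spec$seed, "samples", k), {
      z <- matrix(stats::rnorm(n_k * p), n_k, p)
      sweep(z, 2, sdiag, `*`) + matrix(v, n_k, p, byrow = TRUE)
    })
    scores <- x %*% W + matrix(b, n_k, C, byrow = TRUE)
    y <- max.col(scores, ties.method = "first") - 1L

    n_train <- as.integer(floor(spec$train_fraction * n_k))
    perm <- with_local_seed(derive_seed(spec$seed, "split", k),
                            sample.int(n_k))
    tr <- perm[seq_len(n_train)]
    te <- perm[(n_train + 1L):n_k]
    clients[[k]] <- new_client_dataset(
      client_id = k - 1L,
      train_x = x[tr, , drop = FALSE], train_y = y[tr],
      test_x = x[te, , drop = FALSE], test_y = y[te]
    )
  }
  new_fed_dataset(clients, provenance = spec)
}

#' Per-client sample-size and class-distribution report
#'
#' Tabulates, for each client, its train and test sizes and the per-class
#' counts of its training labels -- the statistics used to inspect how
#' skewed a federated dataset is.
#'
#' @param ds A `fed_dataset`.
#' @return A tibble with columns `client_id`, `n_train`, `n_test` and one
#'   `class_<c>` column per class (training-split counts).
#' @export
partition_stats <- function(ds) {
  C <- dataset_n_classes(ds)
  rows <- purrr::map(ds$clients, function(cl) {
    counts <- tabulate(cl$train_y + 1L, nbins = C)
    names(counts) <- paste0("class_", seq_len(C) - 1L)
    tibble::tibble(client_id = cl$client_id,
                   n_train = length(cl$train_y),
                   n_test = length(cl$test_y),
                   !!!as.list(counts))
  })
  dplyr::bind_rows(rows)
}

#' Summary of a partition report
#'
#' @param stats A tibble from [partition_stats()].
#' @return One-row tibble with total sizes and the extreme client and class
#'   counts.
#' @export
partition_summary <- function(stats) {
  cls <- dplyr::select(stats, dplyr::starts_with("class_"))
  tibble::tibble(
    n_clients = nrow(stats),
    total_train = sum(stats$n_train),
    total_test = sum(stats$n_test),
    max_train = max(stats$n_train),
    min_train = min(stats$n_train),
    max_class_count = max(as.matrix(cls)),
    min_class_count = min(as.matrix(cls))
  )
}

# Infer the number of classes for a dataset (from provenance when available,
# otherwise from the labels).
dataset_n_classes <- function(ds) {
  prov <- ds$provenance
  if (!is.null(prov$n_classes)) return(as.integer(prov$n_classes))
  max(vapply(ds$clients,
             function(cl) max(cl$train_y, cl$test_y, 0L), integer(1))) + 1L
}

#' Label-distribution heterogeneity of a federated dataset
#'
#' Mean pairwise total-variation distance between the clients' normalized
#' training-label histograms; 0 when every client has the same label
#' distribution, approaching 1 under extreme label skew.
#'
#' @param ds A `fed_dataset`.
#' @return A single number in `[0, 1]`.
#' @export
label_heterogeneity <- function(ds) {
  C <- dataset_n_classes(ds)
  P <- t(vapply(ds$clients, function(cl) {
    h <- tabulate(cl$train_y + 1L, nbins = C)
    h / sum(h)
  }, numeric(C)))
  m <- nrow(P)
  if (m < 2) return(0)
  tot <- 0; np <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      tot <- tot + 0.5 * sum(abs(P[i, ] - P[j, ]))
      np <- np + 1
    }
  }
  tot / np
}

#' Export a federated dataset as a flat table
#'
#' One row per sample with `client_id`, `split`, the feature columns and the
#' integer `label`; convenient for CSV interchange.
#'
#' @param ds A `fed_dataset` with matrix features.
#' @return A tibble.
#' @export
dataset_as_tibble <- function(ds) {
  purrr::map_dfr(ds$clients, function(cl) {
    mk <- function(x, y, split) {
      df <- tibble::as_tibble(as.data.frame(x),
                              .name_repair = ~ paste0("x", seq_along(.x)))
      dplyr::bind_cols(
        tibble::tibble(client_id = cl$client_id, split = split),
        df, tibble::tibble(label = y)
      )
    }
    dplyr::bind_rows(mk(cl$train_x, cl$train_y, "train"),
                     mk(cl$test_x, cl$test_y, "test"))
  })
}

#' Write / read a federated dataset directory
#'
#' Writes a JSON manifest (`spec.json`) and a flat CSV (`data.csv`) in the
#' [dataset_as_tibble()] layout.
#'
#' @param ds A `fed_dataset` with matrix features.
#' @param dir Output directory (created if missing).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()` the
#'   restored `fed_dataset`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- ds$provenance
  jsonlite::write_json(unclass(prov), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(dataset_as_tibble(ds), file.path(dir, "data.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  prov <- jsonlite::read_json(file.path(dir, "spec.json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(file.path(dir, "data.csv"))
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  clients <- lapply(sort(unique(df$client_id)), function(cid) {
    sub <- df[df$client_id == cid, ]
    tr <- sub[sub$split == "train", ]
    te <- sub[sub$split == "test", ]
    new_client_dataset(cid,
                       as.matrix(tr[xcols]), tr$label,
                       as.matrix(te[xcols]), te$label)
  })
  new_fed_dataset(clients, provenance = prov)
}
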