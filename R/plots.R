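#' Training-curve plot for one or more federated runs
#'
#' Accuracy and loss against communication round, one line per run, in the
#' two-panel layout customary for federated-learning comparisons.
#'
#' @param runs A `fed_run`, a list of them, or a tidy metrics tibble with
#'   columns `algorithm`, `round`, `acc`, `loss` (e.g. from [tidy.fed_run()]
#'   or [read_metrics_jsonl()]).
#' @param run_names Optional names overriding the `algorithm` column.
#' @return A ggplot object.
#' @export
plot_training_curves <- function(runs, run_names = NULL) {
  df <- if (inherits(runs, "fed_run")) {
    tidy(runs)
  } else if (is.data.frame(runs)) {
    runs
  } else {
    dfs <- purrr::map(runs, tidy)
    if (!is.null(run_names)) {
      dfs <- purrr::map2(dfs, run_names,
                         function(d, nm) dplyr::mutate(d, algorithm = nm))
    }
    dplyr::bind_rows(dfs)
  }
  if (nrow(df) == 0) stop("no metrics to plot")
  long <- tidyr::pivot_longer(
    dplyr::select(df, "algorithm", "round", "acc", "loss"),
    c("acc", "loss"), names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, c("acc", "loss"),
                        c("Acc", "loss"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$round, y = .data$value,
                               colour = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, nrow = 1, scales = "free_y") +
    ggplot2::labs(x = "communication round", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_training_curves
#' @param object A `fed_run`.
#' @param ... Unused.
#' @method autoplot fed_run
#' @export
autoplot.fed_run <- function(object, ...) {
  plot_training_curves(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write / read per-round metrics as JSON lines
#'
#' One JSON object per evaluated round; the reader stacks several files into
#' one tidy tibble, tagging each with the run name (the file stem by
#' default).
#'
#' @param run A `fed_run`.
#' @param path Output `.jsonl` file.
#' @return `write_metrics_jsonl()` returns `path` invisibly.
#' @export
write_metrics_jsonl <- function(run, path) {
  df <- tidy(run)
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_metrics_jsonl
#' @param paths One or more `.jsonl` files.
#' @return `read_metrics_jsonl()`: a tidy metrics tibble with a `run`
#'   column.
#' @export
read_metrics_jsonl <- function(paths) {
  purrr::map_dfr(paths, function(p) {
    rows <- purrr::map(readLines(p, warn = FALSE), function(ln) {
      tibble::as_tibble(jsonlite::fromJSON(ln))
    })
    dplyr::bind_cols(tibble::tibble(run = sub("\\.jsonl$", "", basename(p))),
                     dplyr::bind_rows(rows))
  })
}

#' Max-Acc / min-loss table from metrics files
#'
#' @param paths `.jsonl` metrics files.
#' @return Tibble with one row per run: `run`, `algorithm`, `max_acc`,
#'   `min_loss`, `rounds`.
#' @export
summarize_metrics_files <- function(paths) {
  df <- read_metrics_jsonl(paths)
  dplyr::summarise(
    dplyr::group_by(df, .data$run, .data$algorithm),
    max_acc = max(.data$acc), min_loss = min(.data$loss),
    rounds = max(.data$round), .groups = "drop"
  )
}
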