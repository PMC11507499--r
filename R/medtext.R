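#' Read medical-dialogue JSON into dialogue records
#'
#' Parses a doctor-patient dialogue corpus in the IMCS-V2-style JSON layout:
#' an array of objects with `example_id`, optional `diagnosis` and
#' `self_report`, and `dialogue`, a list of sentences each carrying
#' `sentence_id`, `speaker`, `sentence` and (for labelled sentences) an
#' integer `symptom_type` class. Sentences without a `symptom_type` label
#' are dropped (counted and reported via a message); dialogue and sentence
#' order is preserved.
#'
#' @param path Path to a JSON file (or a JSON string).
#' @return A list of dialogue records (`example_id`, `diagnosis`,
#'   `self_report`, `sentences` -- a list of labelled sentences).
#' @export
read_imcs <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dropped <- 0L
  records <- lapply(seq_along(doc), function(i) {
    d <- doc[[i]]
    if (is.null(d$example_id)) {
      stop("dialogue #", i, " is missing `example_id`")
    }
    if (is.null(d$dialogue)) {
      stop("dialogue '", d$example_id, "' is missing `dialogue`")
    }
    sentences <- list()
    for (s in d$dialogue) {
      for (f in c("sentence_id", "speaker", "sentence")) {
        if (is.null(s[[f]])) {
          stop("dialogue '", d$example_id, "' has a sentence missing `",
               f, "`")
        }
      }
      if (is.null(s$symptom_type)) {
        dropped <<- dropped + 1L
        next
      }
      sentences[[length(sentences) + 1L]] <- list(
        sentence_id = s$sentence_id, speaker = s$speaker,
        sentence = s$sentence, symptom_type = as.integer(s$symptom_type)
      )
    }
    ids <- vapply(sentences, function(s) as.character(s$sentence_id),
                  character(1))
    if (anyDuplicated(ids)) {
      stop("dialogue '", d$example_id, "' has duplicated sentence ids")
    }
    list(example_id = d$example_id,
         diagnosis = d$diagnosis %||% "",
         self_report = d$self_report %||% "",
         sentences = sentences)
  })
  if (dropped > 0) {
    message(dropped, " unlabelled sentence(s) dropped")
  }
  records
}

#' Specification of a synthetic dialogue-corpus fixture
#'
#' Parameterises [generate_imcs_fixture()], which emits a corpus in the same
#' JSON layout [read_imcs()] reads -- so the text pipeline is exercisable
#' without any external corpus. Sentences are strings of fixed-width
#' synthetic tokens concatenated without separators (emulating unsegmented
#' text); each class has its own token distribution, so the labels are
#' learnable from token counts; `label_skew` controls how dialogue-specific
#' the class priors are (0 = one shared prior, larger = more skew, the text
#' analogue of the tabular generator's label-skew parameter).
#'
#' @param n_dialogues Number of dialogues.
#' @param sentences_per_dialogue_mean Mean of the Poisson sentence count
#'   (minimum 1 sentence per dialogue).
#' @param vocab_size Number of distinct synthetic tokens.
#' @param n_classes Number of `symptom_type` classes (default 2).
#' @param label_skew Nonnegative per-dialogue class-prior concentration.
#' @param seed Integer seed.
#' @return A `corpus_fixture_spec` list.
#' @export
corpus_fixture_spec <- function(n_dialogues = 50,
                                sentences_per_dialogue_mean = 20,
                                vocab_size = 500, n_classes = 2,
                                label_skew = 1, seed = 0) {
  stopifnot(n_dialogues >= 1, sentences_per_dialogue_mean > 0,
            vocab_size >= n_classes, n_classes >= 2, label_skew >= 0)
  structure(list(n_dialogues = as.integer(n_dialogues),
                 sentences_per_dialogue_mean = sentences_per_dialogue_mean,
                 vocab_size = as.integer(vocab_size),
                 n_classes = as.integer(n_classes),
                 label_skew = label_skew, seed = as.integer(seed)),
            class = "corpus_fixture_spec")
}

# Fixed-width synthetic token strings ("aaa", "aab", ...): unambiguous under
# greedy longest-match segmentation.
fixture_tokens <- function(n) {
  width <- max(3, ceiling(log(max(n, 2)) / log(26)))
  vapply(seq_len(n) - 1L, function(i) {
    chars <- character(width)
    for (j in seq_len(width)) {
      chars[width - j + 1] <- letters[i %% 26 + 1]
      i <- i %/% 26
    }
    paste(chars, collapse = "")
  }, character(1))
}

#' Generate a synthetic dialogue corpus fixture
#'
#' Deterministic given the spec's seed; the output round-trips through
#' [write_imcs()] / [read_imcs()] preserving every id, sentence and label.
#'
#' @param spec A [corpus_fixture_spec()].
#' @return A list of dialogue records as returned by [read_imcs()].
#' @export
generate_imcs_fixture <- function(spec) {
  C <- spec$n_classes
  V <- spec$vocab_size
  toks <- fixture_tokens(V)
  # class-conditional token distributions: each class concentrates 70% of
  # its mass on its own block of the vocabulary
  block <- split(seq_len(V), cut(seq_len(V), C, labels = FALSE))
  class_probs <- lapply(seq_len(C), function(c) {
    p <- rep(0.3 / V, V)
    p[block[[c]]] <- p[block[[c]]] + 0.7 / length(block[[c]])
    p / sum(p)
  })
  lapply(seq_len(spec$n_dialogues), function(d) {
    with_local_seed(derive_seed(spec$seed, "dialogue", d), {
      n_s <- max(1L, stats::rpois(1, spec$sentences_per_dialogue_mean))
      prior <- if (spec$label_skew == 0) {
        rep(1 / C, C)
      } else {
        g <- stats::rgamma(C, shape = 1 / spec$label_skew)
        if (sum(g) == 0) g <- rep(1, C)
        g / sum(g)
      }
      sentences <- lapply(seq_len(n_s), function(s) {
        lab <- sample.int(C, 1, prob = prior) - 1L
        len <- 3L + stats::rpois(1, 5)
        words <- sample.int(V, len, replace = TRUE,
                            prob = class_probs[[lab + 1L]])
        list(sentence_id = s,
             speaker = if (s %% 2 == 1) "doctor" else "patient",
             sentence = paste(toks[words], collapse = ""),
             symptom_type = lab)
      })
      list(example_id = sprintf("synthetic_%04d", d),
           diagnosis = sprintf("synthetic diagnosis %d", d %% C),
           self_report = "synthetic self report",
           sentences = sentences)
    })
  })
}

#' Write dialogue records as IMCS-style JSON
#'
#' @param records Dialogue records ([read_imcs()] layout).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_imcs <- function(records, path) {
  doc <- lapply(records, function(r) {
    list(example_id = r$example_id, diagnosis = r$diagnosis,
         self_report = r$self_report,
         dialogue = lapply(r$sentences, function(s) {
           list(sentence_id = s$sentence_id, speaker = s$speaker,
                sentence = s$sentence, symptom_type = s$symptom_type)
         }))
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Build a vocabulary index
#'
#' Index 0 is reserved for padding and index 1 for unknown tokens; real
#' tokens are numbered from 2 in the given order.
#'
#' @param tokens Character vector of distinct tokens.
#' @return Named integer vector mapping token to index, with attribute
#'   `unk` (= 1).
#' @export
build_vocab <- function(tokens) {
  stopifnot(!anyDuplicated(tokens))
  v <- seq_along(tokens) + 1L
  names(v) <- tokens
  attr(v, "unk") <- 1L
  v
}

#' Tokenize text by greedy longest match and map to vocabulary indices
#'
#' A language-neutral, dependency-free segmenter for unspaced text: at each
#' position the longest lexicon term matching the remaining prefix is taken;
#' if none matches, a single character is consumed and mapped to the unknown
#' index. An external segmenter can replace this by passing pre-tokenized
#' input directly to [build_federated_text()].
#'
#' @param text A character scalar.
#' @param lexicon Character vector of terms (defaults to the vocabulary's
#'   tokens).
#' @param vocab A [build_vocab()] index.
#' @return Integer vector of token indices (empty for empty text).
#' @export
tokenize_and_index <- function(text, lexicon = NULL, vocab) {
  lexicon <- lexicon %||% names(vocab)
  unk <- attr(vocab, "unk") %||% 1L
  if (is.na(text) || nchar(text) == 0) return(integer(0))
  lens <- sort(unique(nchar(lexicon)), decreasing = TRUE)
  lexset <- new.env(parent = emptyenv())
  for (term in lexicon) assign(term, TRUE, envir = lexset)
  n <- nchar(text)
  out <- integer(0)
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (L in lens) {
      if (i + L - 1L > n) next
      cand <- substr(text, i, i + L - 1L)
      if (exists(cand, envir = lexset, inherits = FALSE)) {
        hit <- cand
        break
      }
    }
    if (is.null(hit)) {
      out <- c(out, unk)
      i <- i + 1L
    } else {
      idx <- vocab[[hit]]
      out <- c(out, if (is.null(idx)) unk else idx)
      i <- i + nchar(hit)
    }
  }
  out
}

pad_or_truncate <- function(ix, max_len) {
  if (length(ix) >= max_len) return(ix[seq_len(max_len)])
  c(ix, integer(max_len - length(ix)))
}

#' Build a federated sentence-classification dataset from dialogues
#'
#' Whole dialogues are assigned to clients (seeded round-robin over the
#' shuffled dialogue order) so each client holds complete conversations --
#' the natural federation unit for consultation data -- and every labelled
#' sentence becomes one (token-index sequence, symptom_type) sample, padded
#' or truncated to `max_len`. Each client is split into train and test.
#'
#' @param records Dialogue records ([read_imcs()] layout).
#' @param n_clients Number of clients (<= number of dialogues).
#' @param vocab A [build_vocab()] index.
#' @param max_len Sequence length cap.
#' @param seed Partitioning seed.
#' @param train_fraction Per-client train fraction (each split keeps at
#'   least one sample).
#' @param lexicon Optional tokenizer lexicon (defaults to the vocabulary).
#' @return A `fed_dataset` whose clients carry token-index matrices.
#' @export
build_federated_text <- function(records, n_clients, vocab, max_len = 50,
                                 seed = 0, train_fraction = 0.9,
                                 lexicon = NULL) {
  if (n_clients > length(records)) {
    stop("n_clients (", n_clients, ") exceeds the ", length(records),
         " dialogues; some client would be empty")
  }
  ord <- with_local_seed(derive_seed(seed, "assign"),
                         sample.int(length(records)))
  assignment <- rep(seq_len(n_clients), length.out = length(records))
  clients <- vector("list", n_clients)
  for (k in seq_len(n_clients)) {
    recs <- records[ord[assignment == k]]
    xs <- list(); ys <- integer(0)
    for (r in recs) {
      for (s in r$sentences) {
        ix <- tokenize_and_index(s$sentence, lexicon, vocab)
        xs[[length(xs) + 1L]] <- pad_or_truncate(ix, max_len)
        ys <- c(ys, s$symptom_type)
      }
    }
    if (length(ys) < 2) {
      stop("client ", k, " holds fewer than 2 labelled sentences; ",
           "cannot split into train and test")
    }
    x <- do.call(rbind, xs)
    n <- length(ys)
    n_train <- min(max(1L, as.integer(floor(train_fraction * n))), n - 1L)
    perm <- with_local_seed(derive_seed(seed, "split", k), sample.int(n))
    tr <- perm[seq_len(n_train)]
    te <- perm[(n_train + 1L):n]
    clients[[k]] <- new_client_dataset(k - 1L,
                                       x[tr, , drop = FALSE], ys[tr],
                                       x[te, , drop = FALSE], ys[te])
  }
  prov <- list(kind = "text", n_clients = n_clients, max_len = max_len,
               n_classes = max(vapply(records, function(r) {
                 max(vapply(r$sentences,
                            function(s) s$symptom_type, integer(1)), 0L)
               }, integer(1))) + 1L,
               seed = seed)
  new_fed_dataset(clients, provenance = prov)
}
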