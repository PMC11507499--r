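#' LSTM sequence-classifier specification
#'
#' A single-layer LSTM text classifier: trainable token embedding ->
#' LSTM cell -> the hidden state at the last non-padding timestep -> dense
#' softmax. Token index 0 is reserved for padding; padded positions
#' contribute a zero embedding and freeze the recurrent state, so appending
#' padding beyond a sequence's true length never changes the output.
#'
#' Gates are packed in one input projection `W_x` (`embed_dim x 4*hidden`),
#' one recurrent projection `W_h` (`hidden x 4*hidden`) and a bias `b_g`
#' (`4*hidden`), in input/forget/candidate/output order. Gradients are exact
#' backpropagation through time, hand-derived and verified against central
#' finite differences in the test-suite.
#'
#' @param vocab_size Number of real tokens (indices `1..vocab_size`; 0 pads).
#' @param embed_dim,hidden_dim Embedding and hidden dimensions.
#' @param max_len Sequence length after padding/truncation (>= 1).
#' @param n_classes Number of output classes (default 2: symptom
#'   present/absent sentence labels).
#' @param init_seed Seed for the uniform(-0.08, 0.08) initialization.
#' @param embedding Optional initial embedding matrix
#'   (`vocab_size x embed_dim`), e.g. from [read_word2vec()]; trainable
#'   either way.
#' @return A model spec object.
#' @export
lstm_spec <- function(vocab_size, embed_dim = 100, hidden_dim = 128,
                      max_len = 50, n_classes = 2, init_seed = 0,
                      embedding = NULL) {
  stopifnot(vocab_size >= 1, embed_dim >= 1, hidden_dim >= 1, max_len >= 1,
            n_classes >= 2)
  if (!is.null(embedding)) {
    stopifnot(is.matrix(embedding),
              nrow(embedding) == vocab_size, ncol(embedding) == embed_dim)
  }
  structure(list(kind = "lstm", vocab_size = as.integer(vocab_size),
                 embed_dim = as.integer(embed_dim),
                 hidden_dim = as.integer(hidden_dim),
                 max_len = as.integer(max_len),
                 n_classes = as.integer(n_classes),
                 init_seed = as.integer(init_seed),
                 embedding = embedding),
            class = c("lstm_spec", "model_spec"))
}

#' @export
init_params.lstm_spec <- function(spec) {
  H <- spec$hidden_dim
  with_local_seed(derive_seed(spec$init_seed, "lstm-init"), {
    u <- function(nr, nc) matrix(stats::runif(nr * nc, -0.08, 0.08), nr, nc)
    emb <- if (is.null(spec$embedding)) {
      u(spec$vocab_size, spec$embed_dim)
    } else {
      spec$embedding
    }
    fed_params(list(
      emb = emb,
      W_x = u(spec$embed_dim, 4 * H),
      W_h = u(H, 4 * H),
      b_g = stats::runif(4 * H, -0.08, 0.08),
      W_out = u(H, spec$n_classes),
      b_out = stats::runif(spec$n_classes, -0.08, 0.08)
    ))
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass over a batch of padded token-index rows. The input
# projection of every timestep is computed in one matrix product; only the
# recurrent part runs per timestep. Returns the final hidden state and,
# when keep = TRUE, the tape needed by the backward pass.
lstm_forward <- function(spec, params, x, keep = FALSE) {
  n <- nrow(x); Tlen <- ncol(x); H <- spec$hidden_dim
  emb0 <- rbind(0, params$emb)  # row 1 = padding token 0
  idx_all <- as.integer(x)                      # column t = rows (t-1)*n+1..tn
  e_all <- emb0[idx_all + 1L, , drop = FALSE]   # (n*Tlen) x embed_dim
  xproj <- e_all %*% params$W_x + rep(params$b_g, each = n * Tlen)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  tape <- if (keep) vector("list", Tlen) else NULL
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H)
  i4 <- (3 * H + 1):(4 * H)
  for (t in seq_len(Tlen)) {
    rows <- ((t - 1L) * n + 1L):(t * n)
    m <- as.numeric(x[, t] > 0L)
    a <- xproj[rows, , drop = FALSE] + h %*% params$W_h
    gi <- sigmoid(a[, i1, drop = FALSE])
    gf <- sigmoid(a[, i2, drop = FALSE])
    gg <- tanh(a[, i3, drop = FALSE])
    go <- sigmoid(a[, i4, drop = FALSE])
    c_new <- gf * cc + gi * gg
    tc <- tanh(c_new)
    if (keep) {
      tape[[t]] <- list(m = m, gi = gi, gf = gf, gg = gg, go = go,
                        c_prev = cc, h_prev = h, tc = tc)
    }
    cc <- m * c_new + (1 - m) * cc
    h <- m * (go * tc) + (1 - m) * h
  }
  list(h = h, tape = tape, e_all = if (keep) e_all else NULL,
       idx_all = if (keep) idx_all else NULL)
}

lstm_scores <- function(spec, params, x) {
  fw <- lstm_forward(spec, params, x, keep = FALSE)
  fw$h %*% params$W_out + rep(params$b_out, each = nrow(x))
}

#' @export
model_loss_grad.lstm_spec <- function(spec, params, x, y) {
  if (length(y) == 0) stop("empty batch")
  n <- nrow(x); H <- spec$hidden_dim
  fw <- lstm_forward(spec, params, x, keep = TRUE)
  scores <- fw$h %*% params$W_out + rep(params$b_out, each = n)
  ce <- softmax_ce(scores, y)

  grad <- param_zero_like(params)
  grad$W_out <- crossprod(fw$h, ce$G)
  grad$b_out <- colSums(ce$G)

  Tlen <- ncol(x)
  tWh <- t(params$W_h)
  da_all <- matrix(0, n * Tlen, 4 * H)   # gate pre-activation gradients
  h_prev_all <- matrix(0, n * Tlen, H)
  dh <- ce$G %*% t(params$W_out)
  dc <- matrix(0, n, H)
  for (t in rev(seq_len(Tlen))) {
    tp <- fw$tape[[t]]
    m <- tp$m
    # state was frozen where m = 0: route those gradients straight past t
    dh_new <- m * dh
    dc_new <- m * dc
    dgo <- dh_new * tp$tc
    dc_inner <- dc_new + dh_new * tp$go * (1 - tp$tc^2)
    da <- cbind(dc_inner * tp$gg * tp$gi * (1 - tp$gi),
                dc_inner * tp$c_prev * tp$gf * (1 - tp$gf),
                dc_inner * tp$gi * (1 - tp$gg^2),
                dgo * tp$go * (1 - tp$go))
    rows <- ((t - 1L) * n + 1L):(t * n)
    da_all[rows, ] <- da
    h_prev_all[rows, ] <- tp$h_prev
    dh <- (1 - m) * dh + da %*% tWh
    dc <- (1 - m) * dc + dc_inner * tp$gf
  }
  grad$W_x <- crossprod(fw$e_all, da_all)
  grad$W_h <- crossprod(h_prev_all, da_all)
  grad$b_g <- colSums(da_all)
  de_all <- tcrossprod(da_all, params$W_x)
  sel <- fw$idx_all > 0L
  if (any(sel)) {
    agg <- rowsum(de_all[sel, , drop = FALSE], group = fw$idx_all[sel])
    ridx <- as.integer(rownames(agg))
    grad$emb[ridx, ] <- grad$emb[ridx, ] + agg
  }
  list(loss = ce$loss, grad = grad)
}

#' @export
model_predict.lstm_spec <- function(spec, params, x) {
  max.col(lstm_scores(spec, params, x), ties.method = "first") - 1L
}

#' @export
model_eval.lstm_spec <- function(spec, params, x, y) {
  scores <- lstm_scores(spec, params, x)
  ce <- softmax_ce(scores, y)
  pred <- max.col(scores, ties.method = "first") - 1L
  list(acc = mean(pred == y), loss = ce$loss, n = length(y))
}

#' Read word embeddings in word2vec text format
#'
#' Parses the plain-text word2vec layout (header line `"<count> <dim>"`,
#' then one `token v1 ... vd` line per word) and assembles an embedding
#' matrix aligned to `tokens`; tokens absent from the file receive a seeded
#' random vector so the result is deterministic.
#'
#' @param path Path to a word2vec text file.
#' @param tokens Character vector: the vocabulary, in index order.
#' @param seed Seed for out-of-vocabulary vectors.
#' @return A `length(tokens) x dim` numeric matrix.
#' @export
read_word2vec <- function(path, tokens, seed = 0) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  d <- hdr[2]
  tab <- new.env(parent = emptyenv())
  for (ln in lines[-1]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != d + 1) next
    assign(parts[1], as.numeric(parts[-1]), envir = tab)
  }
  out <- matrix(0, length(tokens), d)
  for (i in seq_along(tokens)) {
    v <- if (exists(tokens[i], envir = tab, inherits = FALSE)) {
      get(tokens[i], envir = tab)
    } else {
      with_local_seed(derive_seed(seed, "oov", tokens[i]),
                      stats::runif(d, -0.08, 0.08))
    }
    out[i, ] <- v
  }
  out
}
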