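# Seed plumbing: every source of randomness in the simulator draws from a
# named substream derived from one root seed, so that e.g. adding clients or
# extending a run never reshuffles draws made by unrelated components.

#' Derive a substream seed from a root seed and a stream label
#'
#' Deterministic integer hash of the root seed plus any number of label
#' components (strings or integers), mapped into `[1, 2^31 - 2]` so it is a
#' valid `set.seed()` argument. Used internally to give data generation,
#' client sampling, minibatching and initialization independent streams.
#'
#' @param root Integer root seed.
#' @param ... Label components (character or integer-ish scalars).
#' @return A single integer seed.
#' @export
derive_seed <- function(root, ...) {
  mod <- 2147483629
  h <- (as.numeric(root) %% mod + mod) %% mod
  for (part in list(...)) {
    bytes <- if (is.character(part)) {
      as.numeric(utf8ToInt(part))
    } else {
      x <- abs(as.numeric(part))
      c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, 101)
    }
    for (b in bytes) h <- (h * 131 + b + 17) %% mod
  }
  as.integer(h %% (mod - 2) + 1)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is untouched.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}
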