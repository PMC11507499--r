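#' Model parameters as an ordered collection of named arrays
#'
#' A `fed_params` object is the parameter vector theta of every model in the
#' simulator: an ordered list of named real arrays ("layers"). Layer order is
#' part of the object's identity -- attention aggregation can be applied one
#' softmax group per layer, so the order must be stable across clients and
#' rounds. All algebra on `fed_params` is pure: operands are never modified.
#'
#' @param layers Named list of numeric arrays (vectors, matrices or higher
#'   arrays). Names must be unique and non-empty; no layer may be empty.
#' @return A `fed_params` object.
#' @examples
#' p <- fed_params(list(W = matrix(0, 2, 3), b = numeric(3)))
#' n_params(p)
#' @export
fed_params <- function(layers) {
  if (!is.list(layers) || length(layers) == 0) {
    stop("`layers` must be a non-empty named list of numeric arrays")
  }
  nm <- names(layers)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("layer names must be unique and non-empty")
  }
  for (i in seq_along(layers)) {
    if (!is.numeric(layers[[i]])) {
      stop("layer '", nm[i], "' is not numeric")
    }
    if (length(layers[[i]]) == 0) {
      stop("layer '", nm[i], "' is empty")
    }
    layers[[i]] <- layers[[i]] * 1  # force double storage
  }
  structure(layers, class = "fed_params")
}

#' @export
print.fed_params <- function(x, ...) {
  cat("<fed_params> ", length(x), " layers, ",
      n_params(x), " parameters\n", sep = "")
  for (nm in names(x)) {
    d <- dim(x[[nm]])
    shape <- if (is.null(d)) length(x[[nm]]) else paste(d, collapse = "x")
    cat("  ", nm, ": [", shape, "]\n", sep = "")
  }
  invisible(x)
}

#' Total number of scalar parameters
#' @param p A `fed_params` object.
#' @return Integer count over all layers.
#' @export
n_params <- function(p) {
  sum(vapply(p, length, integer(1)))
}

# Stop with the first mismatched layer when two parameter sets do not share
# names, order and shapes. All fed_params algebra funnels through this.
check_conformable <- function(a, b) {
  na <- names(a); nb <- names(b)
  if (length(a) != length(b) || !identical(na, nb)) {
    bad <- if (length(na) == 0 || length(nb) == 0) "(none)" else {
      i <- which(na[seq_len(min(length(a), length(b)))] !=
                   nb[seq_len(min(length(a), length(b)))])
      if (length(i)) na[i[1]] else na[min(length(a), length(b)) + 1]
    }
    stop("parameters are not conformable: layer name/order mismatch at '",
         bad, "'")
  }
  for (nm in na) {
    da <- dim(a[[nm]]) %||% length(a[[nm]])
    db <- dim(b[[nm]]) %||% length(b[[nm]])
    if (!identical(da, db)) {
      stop("parameters are not conformable: shape mismatch at layer '",
           nm, "'")
    }
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Layer-wise a*x + y
#'
#' The axpy primitive underlying every aggregation and optimizer update:
#' returns `a*x + y` computed independently on each layer.
#'
#' @param a Scalar multiplier.
#' @param x,y Conformable `fed_params`.
#' @return A new `fed_params`; the operands are unchanged.
#' @export
param_axpy <- function(a, x, y) {
  check_conformable(x, y)
  out <- x
  for (nm in names(x)) out[[nm]] <- a * x[[nm]] + y[[nm]]
  out
}

#' Layer-wise scalar multiple
#' @inheritParams param_axpy
#' @param p A `fed_params` object.
#' @return `a * p` as a new `fed_params`.
#' @export
param_scale <- function(a, p) {
  for (nm in names(p)) p[[nm]] <- a * p[[nm]]
  p
}

#' All-zero parameters shaped like a template
#' @param p Template `fed_params`.
#' @return A `fed_params` of zeros with the template's layers.
#' @export
param_zero_like <- function(p) {
  for (nm in names(p)) p[[nm]] <- p[[nm]] * 0
  p
}

#' Euclidean distance between two parameter sets
#'
#' The distance s_k that drives attention aggregation: the L2 norm of the
#' difference between global and client parameters, either over the whole
#' flattened model or separately per layer.
#'
#' @param a,b Conformable `fed_params`.
#' @param scope `"whole_model"` for a single value, `"per_layer"` for one
#'   value per layer (named, in layer order).
#' @return Nonnegative numeric scalar or named vector.
#' @export
param_l2_distance <- function(a, b, scope = c("whole_model", "per_layer")) {
  scope <- match.arg(scope)
  check_conformable(a, b)
  ss <- vapply(names(a), function(nm) sum((a[[nm]] - b[[nm]])^2), numeric(1))
  if (scope == "whole_model") sqrt(sum(ss)) else sqrt(ss)
}

#' Flatten parameters to a single vector and back
#'
#' `param_flatten()` concatenates layers in order (column-major within each
#' layer); `param_unflatten()` inverts it given a template carrying the layer
#' names and shapes. `param_unflatten(param_flatten(p), p)` reproduces `p`
#' exactly.
#'
#' @param p A `fed_params` object.
#' @return `param_flatten()`: a numeric vector of length `n_params(p)`.
#' @export
param_flatten <- function(p) {
  unlist(lapply(p, as.numeric), use.names = FALSE)
}

#' @rdname param_flatten
#' @param v Numeric vector of length `n_params(template)`.
#' @param template `fed_params` supplying layer names and shapes.
#' @return `param_unflatten()`: a `fed_params` shaped like `template`.
#' @export
param_unflatten <- function(v, template) {
  need <- n_params(template)
  if (length(v) != need) {
    stop("vector length ", length(v), " does not match parameter count ", need)
  }
  at <- 0L
  out <- template
  for (nm in names(template)) {
    k <- length(template[[nm]])
    chunk <- v[(at + 1L):(at + k)]
    d <- dim(template[[nm]])
    out[[nm]] <- if (is.null(d)) chunk else array(chunk, dim = d)
    at <- at + k
  }
  out
}

#' Write / read parameters as a JSON archive
#'
#' Serializes a `fed_params` to a single JSON file holding a manifest (layer
#' names and shapes, in order) and the flattened values at full precision.
#'
#' @param p A `fed_params` object.
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   the restored `fed_params`.
#' @export
write_params <- function(p, path) {
  manifest <- lapply(p, function(l) as.integer(dim(l) %||% length(l)))
  obj <- list(
    layer_names = names(p),
    shapes = manifest,
    # %.17g round-trips IEEE doubles exactly through text
    values = sprintf("%.17g", param_flatten(p))
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  template <- list()
  for (i in seq_along(obj$layer_names)) {
    shp <- as.integer(obj$shapes[[i]])
    template[[obj$layer_names[i]]] <-
      if (length(shp) == 1) numeric(shp) else array(0, dim = shp)
  }
  param_unflatten(as.numeric(obj$values), fed_params(template))
}
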