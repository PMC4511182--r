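#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a child seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

new_prf <- function(recall, precision) {
  f <- if ((precision + recall) > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(recall = recall, precision = precision, f_measure = f),
            class = "bb_prf")
}

#' @export
print.bb_prf <- function(x, ...) {
  cat(sprintf("R = %.3f  P = %.3f  F = %.3f\n",
              x$recall, x$precision, x$f_measure))
  invisible(x)
}

prf_from_counts <- function(tp, n_pred, n_gold) {
  new_prf(recall = if (n_gold > 0) tp / n_gold else 0,
          precision = if (n_pred > 0) tp / n_pred else 0)
}

# Union-find with path compression over arbitrary string keys.
uf_new <- function(keys) {
  e <- new.env(parent = emptyenv())
  for (k in keys) assign(k, k, envir = e)
  e
}

uf_find <- function(uf, k) {
  p <- get(k, envir = uf)
  if (identical(p, k)) return(k)
  root <- uf_find(uf, p)
  assign(k, root, envir = uf)
  root
}

uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a); rb <- uf_find(uf, b)
  if (!identical(ra, rb)) assign(ra, rb, envir = uf)
  invisible(uf)
}

# Components of size >= min_size as a list of sorted key vectors.
uf_components <- function(uf, min_size = 1L) {
  keys <- ls(uf)
  if (length(keys) == 0) return(list())
  roots <- vapply(keys, function(k) uf_find(uf, k), character(1))
  comps <- split(keys, roots)
  comps <- comps[vapply(comps, length, integer(1)) >= min_size]
  comps <- lapply(comps, sort)
  names(comps) <- NULL
  comps[order(vapply(comps, `[`, character(1), 1))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
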