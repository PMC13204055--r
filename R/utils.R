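#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

## logistic function, numerically safe
sigmoid <- function(x) 1 / (1 + exp(-x))

## column-major flatten index map for reordering / sign-flipping a stack of
## flattened K x K matrices (rows of an n x K^2 matrix)
flat_transform <- function(flat, ord, signs) {
  k <- length(ord)
  idx <- matrix(seq_len(k * k), k, k)
  newidx <- as.vector(idx[ord, ord])
  sgn <- as.vector(outer(signs, signs))
  sweep(flat[, newidx, drop = FALSE], 2L, sgn, `*`)
}
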