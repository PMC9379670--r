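#' @keywords internal
"_PACKAGE"

## Small shared helpers. All randomness in the package funnels through
## `with_seed()` so that every simulation is reproducible from one integer.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so simulations are reproducible without
#' clobbering the caller's RNG state.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## derive a stream-specific child seed from a master seed (keeps values < 2^31)
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + stream * 9973) %% 2147483587
}

db <- function(x, floor_db = -120) {
  pmax(20 * log10(pmax(x, 0)), floor_db)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## separable 2-D running-maximum ("maximum filter") with a k x k box window,
## edge-replicated; k odd. Used for spatial-spectrum peak picking.
max_filter <- function(m, k = 5) {
  stopifnot(k %% 2 == 1)
  h <- (k - 1) / 2
  run1 <- function(v) {
    n <- length(v)
    idx <- outer(seq_len(n), -h:h, `+`)
    idx[idx < 1] <- 1
    idx[idx > n] <- n
    matrix(v[idx], nrow = n)
  }
  rowpass <- apply(m, 2, function(col) do.call(pmax, as.data.frame(run1(col))))
  t(apply(rowpass, 1, function(row) do.call(pmax, as.data.frame(run1(row)))))
}
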