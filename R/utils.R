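# Internal validators and small shared helpers.

stop_if_not_binary <- function(x, arg = deparse(substitute(x))) {
  if (!all(x %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary (values in {0, 1}).", arg))
  }
  invisible(x)
}

check_same_shape <- function(a, b, what = "inputs") {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (length(da) != length(db) || any(da != db)) {
    abort(sprintf(
      "%s must share a shape: got [%s] vs [%s].", what,
      paste(da, collapse = "x"), paste(db, collapse = "x")
    ))
  }
  invisible(TRUE)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All package randomness funnels through here.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of child seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- rlang::`%||%`
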